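# Comparison of acid-modulated gene sets with external expression
# signatures: ortholog mapping, 2x2 contingency with chi-squared test,
# and rank-order signature concordance.

#' Map gene symbols into another species' namespace
#'
#' Maps symbols via a user-supplied one-to-one table. When no table is
#' given, a documented fallback heuristic uppercases the symbols (the
#' usual mouse-to-human symbol convention, e.g. Mmp9 -> MMP9); this is a
#' heuristic, not a curated ortholog resource. Unmapped genes are
#' reported in the return value and via a message, never silently
#' dropped.
#'
#' @param genes Character vector of source symbols.
#' @param map Named character vector (source -> target) or two-column
#'   data frame; `NULL` to use the fallback.
#' @param fallback_uppercase Allow the uppercase heuristic when a gene
#'   is not in `map` (default: only when no map is given).
#' @return List with `mapped` (targets, same order, unmapped removed)
#'   and `unmapped` (source symbols with no mapping).
#' @export
map_orthologs <- function(genes, map = NULL, fallback_uppercase = is.null(map)) {
  if (is.null(map) && !fallback_uppercase)
    stop_config("no ortholog map supplied and the uppercase fallback is disabled")
  if (is.data.frame(map)) {
    m <- as.character(map[[2L]]); names(m) <- as.character(map[[1L]])
    map <- m
  }
  genes <- as.character(genes)
  target <- if (is.null(map)) rep(NA_character_, length(genes)) else unname(map[genes])
  if (fallback_uppercase) target[is.na(target)] <- toupper(genes[is.na(target)])
  unmapped <- genes[is.na(target)]
  if (length(unmapped))
    message(length(unmapped), " gene(s) had no ortholog mapping")
  list(mapped = target[!is.na(target)], unmapped = unmapped)
}

#' Build the signature-vs-modulation 2x2 contingency table
#'
#' Rows are the signature classes (high / low expression in the external
#' contrast); columns are the acid-modulated sets (up-regulated at the
#' threshold / down-regulated at its reciprocal). Genes in neither the
#' up nor the down set, and modulated genes the signature does not
#' classify, contribute nothing — mirroring the published table layout
#' where only classified, modulated genes are counted.
#'
#' @param signature A [reference_signature()].
#' @param up,down [gene_set()] objects (or plain character vectors)
#'   already mapped into the signature's gene namespace; must be
#'   disjoint.
#' @return A 2x2 integer matrix, rows `high`/`low`, columns `up`/`down`.
#' @export
build_contingency <- function(signature, up, down) {
  stopifnot(inherits(signature, "reference_signature"))
  up_genes <- if (inherits(up, "gene_set")) up$genes else unique(as.character(up))
  down_genes <- if (inherits(down, "gene_set")) down$genes else unique(as.character(down))
  both <- intersect(up_genes, down_genes)
  if (length(both))
    stop_config("up and down sets overlap (", paste(utils::head(both, 3), collapse = ", "),
                "...); a gene cannot be both induced and reduced")
  cls <- signature$classes
  counts <- matrix(0L, 2L, 2L, dimnames = list(c("high", "low"), c("up", "down")))
  for (cl in c("high", "low")) {
    in_class <- names(cls)[cls == cl]
    counts[cl, "up"] <- length(intersect(in_class, up_genes))
    counts[cl, "down"] <- length(intersect(in_class, down_genes))
  }
  counts
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected Pearson chi-squared by default (continuity correction is
#' switchable), df = 1, two-sided p from the chi-squared distribution.
#' A table with a zero margin has no defined test; the result is then
#' flagged degenerate with `NA` statistics rather than an error.
#'
#' @param counts 2x2 matrix of non-negative integers.
#' @param correct Apply the Yates continuity correction.
#' @return List of class `contingency_result`: `counts`, `chi2`, `p`,
#'   `df = 1`, `degenerate`, `correct`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop_config("`counts` must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("`counts` must be non-negative integers")
  degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  if (degenerate) {
    res <- list(counts = counts, chi2 = NA_real_, p = NA_real_, df = 1L,
                degenerate = TRUE, correct = correct)
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
    res <- list(counts = counts, chi2 = unname(ct$statistic),
                p = unname(ct$p.value), df = 1L,
                degenerate = FALSE, correct = correct)
  }
  structure(res, class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$counts)
  if (x$degenerate) cat("degenerate table (zero margin); test undefined\n")
  else cat(sprintf("chi2 = %.4g, df = 1, p = %.4g%s\n", x$chi2, x$p,
                   if (x$correct) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Published contingency counts against the GSE8401 signature classes
#'
#' Returns the published 2x2 counts of acid-modulated genes (two-fold
#' threshold) falling in the high/low expression classes of the three
#' GSE8401 melanoma contrasts (Mets vs primary, CTC vs primary, CTC vs
#' Mets), at each acidic condition. Shipped as a plain-text table so
#' the contingency stage can be exercised on the published numbers
#' without network access.
#'
#' @return Data frame with columns `contrast`, `condition`, `class`,
#'   `class_size`, `up`, `down`.
#' @export
published_contingency_counts <- function() {
  path <- system.file("extdata", "gse8401_contingency_counts.tsv",
                      package = "acidep")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Chi-squared tests over the published contingency counts
#'
#' Runs [chi_square_2x2()] on each (contrast, condition) block of
#' [published_contingency_counts()].
#'
#' @param correct Apply the Yates continuity correction.
#' @return Data frame with one row per block: `contrast`, `condition`,
#'   the four counts, `chi2`, `p`.
#' @export
published_contingency_tests <- function(correct = FALSE) {
  df <- published_contingency_counts()
  blocks <- unique(df[c("contrast", "condition")])
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- df[df$contrast == blocks$contrast[i] &
              df$condition == blocks$condition[i], ]
    counts <- matrix(c(b$up[b$class == "high"], b$up[b$class == "low"],
                       b$down[b$class == "high"], b$down[b$class == "low"]),
                     2L, 2L, dimnames = list(c("high", "low"), c("up", "down")))
    res <- chi_square_2x2(counts, correct = correct)
    data.frame(contrast = blocks$contrast[i], condition = blocks$condition[i],
               high_up = counts["high", "up"], high_down = counts["high", "down"],
               low_up = counts["low", "up"], low_down = counts["low", "down"],
               chi2 = res$chi2, p = res$p)
  })
  do.call(rbind, rows)
}

#' Rank-order concordance between a reference signature ordering and
#' acid-response fold changes
#'
#' The reference ordering lists genes in descending expression in the
#' external contrast. Concordance is the Spearman rank correlation
#' between that ordering and the ordering of the acid-response log2
#' fold changes (rho = 1 when the orderings agree exactly, -1 when
#' exactly reversed). Significance comes from a permutation test that
#' shuffles the fold changes over the shared genes.
#'
#' @param signature_ordering Character vector of genes, highest first.
#' @param records A `fold_change_table`.
#' @param condition Condition label whose fold changes to use.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutation test.
#' @return List: `rho`, `p_perm` (two-sided), `n_shared`, `n_perm`,
#'   `seed`.
#' @export
signature_rank_concordance <- function(signature_ordering, records, condition,
                                       n_perm = 1000, seed = 1) {
  sub <- records[records$condition == condition, , drop = FALSE]
  shared <- intersect(signature_ordering, sub$gene)
  if (length(shared) < 3L)
    stop_config("need >= 3 genes shared between the ordering and the records (got ",
                length(shared), ")")
  ref_pos <- match(shared, signature_ordering)
  l2fc <- sub$log2fc[match(shared, sub$gene)]
  # descending reference position vs descending fold change: identical
  # orderings give rho = +1
  rho <- stats::cor(ref_pos, -l2fc, method = "spearman")
  perm_rho <- with_seed(substream_seed(seed, "permute"), {
    vapply(seq_len(n_perm), function(i)
      stats::cor(ref_pos, -sample(l2fc), method = "spearman"), numeric(1))
  })
  p_perm <- (1 + sum(abs(perm_rho) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_perm = p_perm, n_shared = length(shared),
       n_perm = n_perm, seed = seed)
}
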