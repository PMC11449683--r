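# Fold-change differential expression, thresholded gene-set selection,
# Venn partitioning and top-N ranking.

# Tolerated relative round-off when testing a fold change against a
# threshold ratio: fold changes are carried through log2 space, so a
# planted ratio of exactly 4 can land one ulp below 4.0.
FC_REL_TOL <- 1e-9

log2_values <- function(x, floor_eps = 1.0) {
  if (x$scale == "log2") return(list(values = x$values, n_floored = 0L))
  v <- x$values
  n_floored <- sum(v < floor_eps)
  v[v < floor_eps] <- floor_eps
  list(values = log2(v), n_floored = n_floored)
}

cols_for <- function(x, condition) {
  idx <- which(x$samples$condition == condition)
  if (!length(idx)) stop_config("condition not present in matrix: ", condition)
  idx
}

#' Per-gene fold changes of test conditions against a control
#'
#' For each test condition, computes the ratio of mean test expression
#' to mean control expression per gene. By default means are taken on
#' the log2 scale and back-transformed (the geometric-mean ratio), the
#' natural choice for ratio-based two-color array data; the
#' arithmetic-mean ratio on linear intensities is available for
#' sensitivity analysis. Linear intensities are floored at `floor_eps`
#' before the log transform (with a warning reporting the count), so a
#' zero control mean cannot occur.
#'
#' @param x An [expression_matrix()].
#' @param control Condition label of the control group.
#' @param tests Character vector of test condition labels.
#' @param method `"geometric"` (default) or `"arithmetic"` mean ratio.
#' @param floor_eps Floor applied to linear intensities before log2.
#' @return A long data frame of class `fold_change_table` with columns
#'   `gene`, `condition`, `fc`, `log2fc` (and `p`, `degenerate` once
#'   merged via [per_gene_test()] / [add_tests()]).
#' @export
compute_fold_changes <- function(x, control, tests,
                                 method = c("geometric", "arithmetic"),
                                 floor_eps = 1.0) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expression_matrix"))
  ctrl_idx <- cols_for(x, control)
  lg <- log2_values(x, floor_eps)
  if (lg$n_floored > 0)
    warning(lg$n_floored, " value(s) floored at ", floor_eps,
            " before log2 transform", call. = FALSE)
  out <- lapply(tests, function(cond) {
    test_idx <- cols_for(x, cond)
    if (method == "geometric" || x$scale == "log2") {
      l2 <- rowMeans(lg$values[, test_idx, drop = FALSE]) -
        rowMeans(lg$values[, ctrl_idx, drop = FALSE])
      fc <- 2^l2
    } else {
      fc <- rowMeans(x$values[, test_idx, drop = FALSE]) /
        pmax(rowMeans(x$values[, ctrl_idx, drop = FALSE]), floor_eps)
      l2 <- log2(fc)
    }
    data.frame(gene = rownames(x$values), condition = cond,
               fc = unname(fc), log2fc = unname(l2))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fold_change_table", "data.frame")
  res
}

#' Per-gene two-sample t-test between a test condition and the control
#'
#' Computes a two-sided Student's t-test per gene on log2-scale values
#' (linear input is floored and log2-transformed first). The default is
#' the pooled-variance form with `df = n1 + n2 - 2`, vectorized over
#' genes; Welch's unequal-variance form is available via
#' `var_equal = FALSE`. Degenerate genes — zero variance in both groups —
#' get `p = 1` when the group means are equal and `p = 0` otherwise,
#' flagged in the `degenerate` column.
#'
#' The t statistic is signed as test mean minus control mean.
#'
#' @param x An [expression_matrix()] with at least two replicates per
#'   group.
#' @param control,test Condition labels.
#' @param var_equal Pooled (TRUE, default) vs Welch (FALSE).
#' @param bonferroni If TRUE, adds a `p_adj` column with the Bonferroni
#'   correction (factor = number of genes tested). Off by default: the
#'   volcano convention here is raw per-gene p-values.
#' @param floor_eps Floor applied to linear intensities before log2.
#' @return Data frame with columns `gene`, `t`, `df`, `p`, `degenerate`
#'   (and `p_adj` if requested).
#' @export
per_gene_test <- function(x, control, test, var_equal = TRUE,
                          bonferroni = FALSE, floor_eps = 1.0) {
  stopifnot(inherits(x, "expression_matrix"))
  ctrl_idx <- cols_for(x, control)
  test_idx <- cols_for(x, test)
  n1 <- length(test_idx); n2 <- length(ctrl_idx)
  if (n1 < 2L || n2 < 2L)
    stop_config("need >= 2 replicates per group for a t-test")
  v <- log2_values(x, floor_eps)$values
  a <- v[, test_idx, drop = FALSE]
  b <- v[, ctrl_idx, drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- !is.finite(se) | se == 0
  eq <- degenerate & (m1 == m2)
  p[degenerate] <- 0
  p[eq] <- 1
  tstat[eq] <- 0
  res <- data.frame(gene = rownames(x$values), t = unname(tstat),
                    df = unname(df), p = unname(p),
                    degenerate = unname(degenerate))
  if (bonferroni) res$p_adj <- pmin(1, res$p * nrow(res))
  res
}

#' Merge per-gene test p-values into a fold-change table
#'
#' @param records A `fold_change_table` from [compute_fold_changes()].
#' @param x,control The matrix and control label used to build it.
#' @param ... Passed to [per_gene_test()].
#' @return `records` with `p` and `degenerate` columns added.
#' @export
add_tests <- function(records, x, control, ...) {
  conds <- unique(records$condition)
  records$p <- NA_real_
  records$degenerate <- NA
  for (cond in conds) {
    tt <- per_gene_test(x, control, cond, ...)
    i <- records$condition == cond
    m <- match(records$gene[i], tt$gene)
    records$p[i] <- tt$p[m]
    records$degenerate[i] <- tt$degenerate[m]
  }
  records
}

#' Select fold-change-thresholded gene sets
#'
#' Applies the fold-change selection rule: for `direction = "up"`, genes
#' with `fc >= threshold`; for `"down"`, genes with `fc <= 1/threshold`.
#' Boundary values are included ("two-fold or more" means `>=`). The
#' comparison carries a relative tolerance of 1e-9 so ratios computed
#' through log2 space are not excluded by round-off at the boundary.
#'
#' @param records A `fold_change_table`.
#' @param condition Condition label to select in.
#' @param threshold Fold-change ratio, must be > 1.
#' @param direction `"up"` or `"down"`.
#' @return A [gene_set()].
#' @export
select_modulated <- function(records, condition, threshold,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 1)
    stop_config("`threshold` must be a single ratio > 1")
  sub <- records[records$condition == condition, , drop = FALSE]
  if (!nrow(sub)) stop_config("no records for condition ", condition)
  keep <- if (direction == "up") {
    sub$fc >= threshold * (1 - FC_REL_TOL)
  } else {
    sub$fc <= (1 / threshold) * (1 + FC_REL_TOL)
  }
  gene_set(sprintf("%s_%s_%g", condition, direction, threshold),
           sub$gene[keep], direction, threshold, condition)
}

#' Venn partition of two gene sets
#'
#' Exact set algebra over two gene sets selected with the same direction
#' and threshold (typically the two acidic conditions): genes specific
#' to A, common to both, and specific to B.
#'
#' @param setA,setB [gene_set()] objects with matching direction and
#'   threshold.
#' @return An object of class `venn_partition` with `a_only`, `common`,
#'   `b_only` gene sets and a named `counts` vector.
#' @export
venn_partition <- function(setA, setB) {
  stopifnot(inherits(setA, "gene_set"), inherits(setB, "gene_set"))
  if (setA$direction != setB$direction)
    stop_config("direction mismatch: ", setA$direction, " vs ", setB$direction)
  if (!isTRUE(all.equal(setA$threshold, setB$threshold)))
    stop_config("threshold mismatch: ", setA$threshold, " vs ", setB$threshold)
  a_only <- setdiff(setA$genes, setB$genes)
  common <- intersect(setA$genes, setB$genes)
  b_only <- setdiff(setB$genes, setA$genes)
  mk <- function(genes, nm, cond)
    gene_set(nm, genes, setA$direction, setA$threshold, cond)
  structure(list(
    a_only = mk(a_only, paste0(setA$name, "_only"), setA$condition),
    common = mk(common, "common", paste(setA$condition, setB$condition, sep = "&")),
    b_only = mk(b_only, paste0(setB$name, "_only"), setB$condition),
    counts = c(a_only = length(a_only), common = length(common),
               b_only = length(b_only)),
    threshold = setA$threshold, direction = setA$direction),
    class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition (%s, threshold %g): %d | %d | %d\n",
              x$direction, x$threshold,
              x$counts[["a_only"]], x$counts[["common"]], x$counts[["b_only"]]))
  invisible(x)
}

#' Top-N genes by fold-change magnitude
#'
#' Ranks the genes responding in the given direction by |log2 fold
#' change| (descending). Ties are broken by smaller p-value, then by
#' gene symbol, so the ordering is deterministic. Returns at most `n`
#' genes; fewer when fewer respond in that direction.
#'
#' @param records A `fold_change_table`, with a `p` column if p-value
#'   tie-breaking is wanted.
#' @param condition Condition label.
#' @param n Number of genes to return (>= 1).
#' @param direction `"up"` (induced) or `"down"` (reduced).
#' @return Character vector of gene symbols, best first.
#' @export
top_n_by_fold_change <- function(records, condition, n,
                                 direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_config("`n` must be a positive integer")
  sub <- records[records$condition == condition, , drop = FALSE]
  sub <- if (direction == "up") sub[sub$log2fc > 0, , drop = FALSE]
  else sub[sub$log2fc < 0, , drop = FALSE]
  if (!nrow(sub)) return(character(0))
  p <- if ("p" %in% names(sub)) sub$p else rep(0, nrow(sub))
  ord <- order(-abs(sub$log2fc), p, sub$gene)
  utils::head(sub$gene[ord], n)
}

#' Volcano-plot table
#'
#' Per-gene (log2 fold change, -log10 p) pairs for a condition.
#' Degenerate `p = 0` entries are capped at `-log10 p = p_cap` so the
#' table stays finite.
#'
#' @param records A `fold_change_table` with p-values merged.
#' @param condition Condition label.
#' @param p_cap Cap for `-log10(p)` when `p == 0` (default 300, about
#'   the double-precision limit).
#' @return Data frame with columns `gene`, `log2fc`, `neg_log10_p`.
#' @export
volcano_table <- function(records, condition, p_cap = 300) {
  if (!"p" %in% names(records))
    stop_config("records carry no p-values; run add_tests() first")
  sub <- records[records$condition == condition, , drop = FALSE]
  nlp <- -log10(sub$p)
  nlp[!is.finite(nlp) | nlp > p_cap] <- p_cap
  data.frame(gene = sub$gene, log2fc = sub$log2fc, neg_log10_p = nlp,
             row.names = NULL)
}
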