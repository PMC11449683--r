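# Acidic-pH dependency ("hit") scoring: per-tumor hit tallies over top
# acid-induced and acid-reduced genes against prognostic annotations,
# strict and inversion-tolerant, plus dominance typing, gene hit rates
# and pathological-stage concordance.

lookup_entry <- function(ann, gene, tumor_type) {
  i <- which(ann$gene == gene & ann$tumor_type == tumor_type)
  if (!length(i)) return(NULL)
  as.list(ann[i[1L], , drop = FALSE])
}

#' Is an annotation entry a (strict) hit for a gene role?
#'
#' A hit pairs the acid-response direction with the prognostic
#' direction: an acid-induced gene whose expression is an unfavorable
#' (shorter-survival) prognostic marker, or an acid-reduced gene whose
#' expression is a favorable (longer-survival) marker — in both cases
#' the database flags the association significant. A missing entry is
#' never a hit.
#'
#' @param gene_role `"induced"` or `"reduced"`.
#' @param entry Annotation entry: a list/one-row data frame with
#'   `direction` and `significant` fields, or `NULL` when missing.
#' @return Logical scalar.
#' @export
is_hit <- function(gene_role = c("induced", "reduced"), entry) {
  gene_role <- match.arg(gene_role)
  if (is.null(entry)) return(FALSE)
  want <- if (gene_role == "induced") "unfavorable" else "favorable"
  isTRUE(entry$direction == want) && isTRUE(as.logical(entry$significant))
}

#' Is an annotation entry an inversion-tolerant hit?
#'
#' An inverted hit is a significant association in the *opposite*
#' prognostic direction whose effect magnitude (the annotation's
#' distance-from-neutrality field, e.g. |HR - 1| or a survival-difference
#' fraction) lies within the tolerance — a "reversal within 20%" under
#' the default `tol = 0.20`. The magnitude semantics are whatever the
#' annotation table encodes; a different rule can be plugged in via
#' `predicate`.
#'
#' @param gene_role `"induced"` or `"reduced"`.
#' @param entry Annotation entry (see [is_hit()]).
#' @param tol Magnitude tolerance in `[0, 1]`, default 0.20.
#' @param predicate Optional `function(magnitude, tol)` replacing the
#'   default `magnitude <= tol` rule.
#' @return Logical scalar. A reversed entry with no magnitude recorded
#'   returns FALSE with a warning.
#' @export
is_inverted_hit <- function(gene_role = c("induced", "reduced"), entry,
                            tol = 0.20, predicate = NULL) {
  gene_role <- match.arg(gene_role)
  assert_fraction(tol, "tol")
  if (is.null(entry)) return(FALSE)
  reversed <- if (gene_role == "induced") "favorable" else "unfavorable"
  if (!isTRUE(entry$direction == reversed) ||
      !isTRUE(as.logical(entry$significant))) return(FALSE)
  mag <- entry$magnitude
  if (is.null(mag) || is.na(mag)) {
    warning("reversed entry without a magnitude cannot be tolerance-checked",
            call. = FALSE)
    return(FALSE)
  }
  if (is.null(predicate)) mag <= tol else isTRUE(predicate(mag, tol))
}

#' Score one tumor type against the top gene lists
#'
#' Tallies strict hits ([is_hit()]) and tolerant hits (strict or
#' [is_inverted_hit()]) over the top acid-induced and acid-reduced gene
#' lists, and types the tumor by which role dominates the strict
#' tallies: `induced_type` when induced hits exceed reduced hits by more
#' than `dominance_margin`, `reduced_type` for the reverse, `balanced`
#' otherwise.
#'
#' @param induced,reduced Ordered character vectors of top acid-induced
#'   and acid-reduced genes (typically top-100 each from
#'   [top_n_by_fold_change()]).
#' @param ann A `prognostic_annotation` table.
#' @param tumor_type Tumor type label to score.
#' @param tol Inversion tolerance, see [is_inverted_hit()].
#' @param dominance_margin Strict-majority margin for dominance typing
#'   (default 0).
#' @param predicate Optional inversion predicate, see
#'   [is_inverted_hit()].
#' @return Object of class `hit_score`: the tallies, totals, dominance
#'   label, a per-gene `detail` data frame with status
#'   `hit` / `inverted` / `miss` / `missing`, and the count of missing
#'   annotations (coverage visibility).
#' @export
score_tumor <- function(induced, reduced, ann, tumor_type, tol = 0.20,
                        dominance_margin = 0, predicate = NULL) {
  stopifnot(inherits(ann, "prognostic_annotation") || is.data.frame(ann))
  sub <- ann[ann$tumor_type == tumor_type, , drop = FALSE]
  score_role <- function(genes, role) {
    if (!length(genes))
      return(data.frame(gene = character(0), role = character(0),
                        status = character(0)))
    status <- vapply(genes, function(g) {
      e <- lookup_entry(sub, g, tumor_type)
      if (is.null(e)) "missing"
      else if (is_hit(role, e)) "hit"
      else if (suppressWarnings(is_inverted_hit(role, e, tol, predicate))) "inverted"
      else "miss"
    }, character(1))
    data.frame(gene = genes, role = role, status = unname(status))
  }
  detail <- rbind(score_role(induced, "induced"), score_role(reduced, "reduced"))
  tally <- function(role, statuses)
    sum(detail$role == role & detail$status %in% statuses)
  his <- tally("induced", "hit")
  hrs <- tally("reduced", "hit")
  hit_tol <- c("hit", "inverted")
  hit_ind_tol <- tally("induced", hit_tol)
  hit_red_tol <- tally("reduced", hit_tol)
  dominance <- if (his - hrs > dominance_margin) "induced_type"
  else if (hrs - his > dominance_margin) "reduced_type"
  else "balanced"
  structure(list(
    tumor_type = tumor_type,
    hits_induced_strict = his, hits_reduced_strict = hrs,
    hits_induced_tolerant = hit_ind_tol, hits_reduced_tolerant = hit_red_tol,
    total_strict = his + hrs, total_tolerant = hit_ind_tol + hit_red_tol,
    dominance = dominance,
    n_missing = sum(detail$status == "missing"),
    tol = tol, detail = detail),
    class = "hit_score")
}

#' @export
print.hit_score <- function(x, ...) {
  cat(sprintf(
    "hit_score [%s]: strict %d (induced %d / reduced %d), tolerant %d; %s; %d missing\n",
    x$tumor_type, x$total_strict, x$hits_induced_strict, x$hits_reduced_strict,
    x$total_tolerant, x$dominance, x$n_missing))
  invisible(x)
}

#' Score every tumor type in an annotation table
#'
#' @inheritParams score_tumor
#' @param tumor_types Tumor types to score; defaults to all types
#'   present in `ann`.
#' @return Named list of [score_tumor()] results.
#' @export
score_tumors <- function(induced, reduced, ann, tumor_types = NULL, ...) {
  tumor_types <- tumor_types %||% sort(unique(ann$tumor_type))
  res <- lapply(tumor_types, function(tt)
    score_tumor(induced, reduced, ann, tt, ...))
  names(res) <- tumor_types
  res
}

#' Rank tumor types by hit totals
#'
#' Orders tumors by strict hit total (descending), ties broken by
#' tolerant total then stably by tumor name, and attaches the dominance
#' labels. High-ranking tumors are the ones whose prognosis depends
#' most on acidosis-responsive genes.
#'
#' @param results List of `hit_score` objects (see [score_tumors()]).
#' @return Data frame, one row per tumor, best first.
#' @export
rank_tumors <- function(results) {
  if (!length(results)) stop_config("no hit-score results to rank")
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(tumor_type = r$tumor_type,
               hits_induced_strict = r$hits_induced_strict,
               hits_reduced_strict = r$hits_reduced_strict,
               hits_induced_tolerant = r$hits_induced_tolerant,
               hits_reduced_tolerant = r$hits_reduced_tolerant,
               total_strict = r$total_strict,
               total_tolerant = r$total_tolerant,
               dominance = r$dominance,
               n_missing = r$n_missing)))
  df <- df[order(-df$total_strict, -df$total_tolerant, df$tumor_type), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-gene hit rate across tumor types
#'
#' The fraction of evaluated tumor types in which the gene is a strict
#' hit (optionally counting inverted hits too).
#'
#' @param gene Gene symbol.
#' @param results List of `hit_score` objects.
#' @param include_inverted Count inverted hits as hits.
#' @return Fraction in `[0, 1]`.
#' @export
gene_hit_rate <- function(gene, results, include_inverted = FALSE) {
  if (!length(results)) stop_config("no tumor types evaluated")
  ok <- c("hit", if (include_inverted) "inverted")
  hits <- vapply(results, function(r) {
    st <- r$detail$status[r$detail$gene == gene]
    length(st) > 0L && st[1L] %in% ok
  }, logical(1))
  sum(hits) / length(results)
}

#' Filter genes by minimum hit rate
#'
#' Keeps genes whose hit rate across tumors is at least `min_rate`
#' (default 0.5, the "hit in half the tumor panel or more" rule used to
#' nominate genes for stage-concordance follow-up).
#'
#' @param genes Character vector of candidate genes.
#' @param results List of `hit_score` objects.
#' @param min_rate Minimum hit rate, inclusive.
#' @param include_inverted Count inverted hits.
#' @return Character vector of retained genes.
#' @export
filter_by_hit_rate <- function(genes, results, min_rate = 0.5,
                               include_inverted = FALSE) {
  assert_fraction(min_rate, "min_rate")
  rates <- vapply(genes, gene_hit_rate, numeric(1), results = results,
                  include_inverted = include_inverted)
  genes[rates >= min_rate]
}

#' Concordance of gene expression with pathological stage
#'
#' For each gene, counts the tumor types whose stage trend is concordant
#' with the gene's acid-response role: an acid-induced gene is
#' concordant when its expression is significantly higher in late-stage
#' disease (`late_stage_high`), an acid-reduced gene when significantly
#' lower (`late_stage_low`). Returns `k` concordant of `n` evaluated
#' tumor types per gene; genes absent from the annotations score
#' `(0, 0)` with a warning.
#'
#' @param genes Character vector of genes.
#' @param stage_ann A `stage_annotation` table.
#' @param roles Role per gene: single value or vector matching `genes`
#'   (`"induced"` / `"reduced"`).
#' @return Data frame with columns `gene`, `role`, `k`, `n`, sorted by
#'   `k` descending.
#' @export
stage_concordance <- function(genes, stage_ann, roles = "induced") {
  stopifnot(inherits(stage_ann, "stage_annotation") || is.data.frame(stage_ann))
  roles <- rep_len(roles, length(genes))
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    want <- if (roles[i] == "induced") "late_stage_high" else "late_stage_low"
    sub <- stage_ann[stage_ann$gene == g, , drop = FALSE]
    if (!nrow(sub)) {
      warning("gene ", g, " absent from stage annotations", call. = FALSE)
      return(data.frame(gene = g, role = roles[i], k = 0L, n = 0L))
    }
    data.frame(gene = g, role = roles[i],
               k = sum(sub$trend == want & sub$significant),
               n = nrow(sub))
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$k, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Gene-by-tumor hit status matrix
#'
#' A character matrix (genes x tumor types) of per-gene statuses
#' (`hit` / `inverted` / `miss` / `missing`) — the distribution list of
#' hit genes across the tumor panel.
#'
#' @param results List of `hit_score` objects.
#' @return Character matrix.
#' @export
hit_matrix <- function(results) {
  if (!length(results)) stop_config("no hit-score results")
  genes <- unique(unlist(lapply(results, function(r) r$detail$gene)))
  m <- matrix("missing", length(genes), length(results),
              dimnames = list(genes, vapply(results, `[[`, "", "tumor_type")))
  for (r in results) {
    m[r$detail$gene, r$tumor_type] <- r$detail$status
  }
  m
}
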