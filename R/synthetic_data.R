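# Synthetic-data generators with planted ground truth for every
# pipeline input: multi-pH expression matrices, reference signatures,
# and prognostic / stage annotation tables.
#
# The defaults emulate the study design the pipeline targets: a control
# at physiological pH (7.4) and two acidic test conditions (mild 6.8,
# severe 5.9) in quadruplicate, with planted up/down effects present at
# one or both acidic conditions in the same partition structure as the
# four-fold Venn counts (25/85/131 up, 63/118/82 down), and an
# eight-tumor annotation panel.

#' Default tumor-type panel for annotation simulation
#' @export
TUMOR_TYPES <- c("breast", "colorectal", "prostate", "gastric", "liver",
                 "lung", "head and neck", "melanoma")

#' Simulation configuration for expression data
#'
#' Planted effects are additive on the log2 scale (multiplicative on
#' intensities), matching ratio-based two-color array data. The six
#' planted classes mirror a two-condition Venn: up or down at the first
#' test condition only, at both, or at the second only.
#'
#' @param n_genes Number of genes.
#' @param control Control condition label.
#' @param tests Two test condition labels (first = mild, second =
#'   severe acidosis by default).
#' @param n_replicates Replicates per condition (default 4,
#'   quadruplicate cultures).
#' @param planted List with `up` and `down` named count vectors
#'   `(a_only, common, b_only)` giving how many genes respond at
#'   `tests[1]` only, both, or `tests[2]` only.
#' @param effect_log2 Planted effect size in log2 units (default 2.0,
#'   i.e. four-fold).
#' @param noise_sd_log2 Replicate noise SD in log2 units (default 0.25,
#'   a typical within-array replicate spread for two-color data).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline law.
#' @param seed Master seed; per-component substreams are derived from
#'   it so partial re-runs are stable.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 20000,
                              control = "pH7.4",
                              tests = c("pH6.8", "pH5.9"),
                              n_replicates = 4,
                              planted = list(
                                up = c(a_only = 25, common = 85, b_only = 131),
                                down = c(a_only = 63, common = 118, b_only = 82)),
                              effect_log2 = 2.0,
                              noise_sd_log2 = 0.25,
                              baseline_log2_mean = 8,
                              baseline_log2_sd = 2,
                              seed = 1) {
  if (n_genes < 1) stop_config("`n_genes` must be positive")
  if (length(tests) != 2L) stop_config("exactly two test conditions are expected")
  if (n_replicates < 1) stop_config("`n_replicates` must be positive")
  for (d in c("up", "down")) {
    p <- planted[[d]] %||% c(a_only = 0, common = 0, b_only = 0)
    if (!all(c("a_only", "common", "b_only") %in% names(p)))
      stop_config("planted$", d, " needs counts (a_only, common, b_only)")
    if (any(p < 0)) stop_config("planted counts must be non-negative")
    planted[[d]] <- p
  }
  if (sum(planted$up) + sum(planted$down) > n_genes)
    stop_config("planted counts exceed `n_genes`")
  if (effect_log2 <= 0) stop_config("`effect_log2` must be > 0")
  if (noise_sd_log2 < 0 || baseline_log2_sd < 0)
    stop_config("standard deviations must be >= 0")
  structure(list(n_genes = n_genes, control = control, tests = tests,
                 n_replicates = n_replicates, planted = planted,
                 effect_log2 = effect_log2, noise_sd_log2 = noise_sd_log2,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd, seed = seed),
            class = "simulation_config")
}

planted_classes <- function(config) {
  n <- config$n_genes
  cls <- rep("null", n)
  counts <- c(up_a_only = config$planted$up[["a_only"]],
              up_common = config$planted$up[["common"]],
              up_b_only = config$planted$up[["b_only"]],
              down_a_only = config$planted$down[["a_only"]],
              down_common = config$planted$down[["common"]],
              down_b_only = config$planted$down[["b_only"]])
  idx <- with_seed(substream_seed(config$seed, "assign"), sample.int(n))
  pos <- 1L
  for (k in names(counts)) {
    ct <- counts[[k]]
    if (ct > 0) {
      cls[idx[pos:(pos + ct - 1L)]] <- k
      pos <- pos + ct
    }
  }
  cls
}

#' Simulate a multi-condition expression matrix with planted effects
#'
#' Per-gene baselines are drawn from a normal law on the log2 scale;
#' each replicate value is baseline + planted effect (when the gene's
#' class responds in that condition) + normal noise. Deterministic
#' given the config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (a log2-scale [expression_matrix()]) and
#'   `truth` (data frame `gene`, `class` over the six planted classes
#'   and `null`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  cls <- planted_classes(config)
  baseline <- with_seed(substream_seed(config$seed, "baseline"),
                        stats::rnorm(n, config$baseline_log2_mean,
                                     config$baseline_log2_sd))
  conds <- c(config$control, config$tests)
  reps <- config$n_replicates
  sample_ids <- as.vector(t(outer(conds, seq_len(reps),
                                  function(c, r) paste0(c, "_rep", r))))
  samples <- data.frame(sample_id = sample_ids,
                        condition = rep(conds, each = reps),
                        replicate = rep(seq_len(reps), times = length(conds)))
  e <- config$effect_log2
  effect_of <- function(cond) {
    eff <- numeric(n)
    if (cond == config$tests[1L]) {
      eff[cls %in% c("up_a_only", "up_common")] <- e
      eff[cls %in% c("down_a_only", "down_common")] <- -e
    } else if (cond == config$tests[2L]) {
      eff[cls %in% c("up_b_only", "up_common")] <- e
      eff[cls %in% c("down_b_only", "down_common")] <- -e
    }
    eff
  }
  values <- matrix(0, n, length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids))
    values[, j] <- baseline + effect_of(samples$condition[j])
  if (config$noise_sd_log2 > 0) {
    noise <- with_seed(substream_seed(config$seed, "noise"),
                       stats::rnorm(length(values), 0, config$noise_sd_log2))
    values <- values + matrix(noise, n)
  }
  list(matrix = expression_matrix(values, samples, scale = "log2"),
       truth = data.frame(gene = genes, class = cls))
}

#' Simulate an external reference signature
#'
#' Builds a high/low gene classification whose "high" class is enriched
#' for the planted-up genes at a requested overlap probability:
#' `overlap = 1` classifies every planted-up gene high; setting
#' `overlap` equal to `base_rate` yields a null (chance-level)
#' association, useful for calibrating the contingency test.
#'
#' @param truth Truth table from [simulate_expression()].
#' @param overlap_with_planted Probability a planted-up gene is
#'   classified high.
#' @param universe_size Total genes classified (planted genes first,
#'   padded with null and synthetic external genes).
#' @param seed RNG seed.
#' @param base_rate Probability a non-planted-up gene is classified
#'   high (default 0.5).
#' @return A [reference_signature()].
#' @export
simulate_reference_signature <- function(truth, overlap_with_planted,
                                         universe_size, seed = 1,
                                         base_rate = 0.5) {
  assert_fraction(overlap_with_planted, "overlap_with_planted")
  assert_fraction(base_rate, "base_rate")
  if (universe_size < 1) stop_config("`universe_size` must be positive")
  planted_up <- truth$gene[startsWith(truth$class, "up_")]
  planted_other <- truth$gene[!startsWith(truth$class, "up_")]
  if (universe_size < length(planted_up))
    stop_config("`universe_size` smaller than the planted-up gene count")
  pad <- universe_size - length(planted_up)
  fill <- utils::head(planted_other, pad)
  if (length(fill) < pad)
    fill <- c(fill, sprintf("ext%05d", seq_len(pad - length(fill))))
  universe <- c(planted_up, fill)
  classes <- with_seed(substream_seed(seed, "signature"), {
    is_up <- universe %in% planted_up
    p_high <- ifelse(is_up, overlap_with_planted, base_rate)
    ifelse(stats::runif(length(universe)) < p_high, "high", "low")
  })
  names(classes) <- universe
  reference_signature("simulated contrast", classes, universe)
}

#' Annotation simulation configuration
#'
#' @param tumor_types Tumor panel (default the eight-type panel in
#'   [TUMOR_TYPES]).
#' @param concordance_q Per-tumor probability that an annotation is
#'   concordant with the gene's acid-response role (scalar, or named by
#'   tumor type).
#' @param inversion_fraction Among non-concordant, non-missing entries,
#'   the fraction that are significantly reversed (the rest are
#'   direction `none`).
#' @param magnitude_law Function `n -> n` magnitudes for
#'   directional entries (default uniform on `[0, 0.4]`).
#' @param missing_rate Probability a (gene, tumor) pair has no entry.
#' @param seed RNG seed.
#' @return A validated list of class `annotation_sim_config`.
#' @export
annotation_sim_config <- function(tumor_types = TUMOR_TYPES,
                                  concordance_q = 0.5,
                                  inversion_fraction = 0.3,
                                  magnitude_law = function(n) stats::runif(n, 0, 0.4),
                                  missing_rate = 0,
                                  seed = 1) {
  if (!length(tumor_types)) stop_config("need >= 1 tumor type")
  if (is.null(names(concordance_q))) {
    concordance_q <- rep_len(concordance_q, length(tumor_types))
    names(concordance_q) <- tumor_types
  }
  for (q in concordance_q) assert_fraction(q, "concordance_q")
  assert_fraction(inversion_fraction, "inversion_fraction")
  assert_fraction(missing_rate, "missing_rate")
  if (!is.function(magnitude_law)) stop_config("`magnitude_law` must be a function")
  structure(list(tumor_types = tumor_types, concordance_q = concordance_q,
                 inversion_fraction = inversion_fraction,
                 magnitude_law = magnitude_law, missing_rate = missing_rate,
                 seed = seed),
            class = "annotation_sim_config")
}

#' Simulate prognostic survival annotations with planted concordance
#'
#' For each (gene, tumor) pair: with probability `missing_rate` no
#' entry is written; otherwise with probability `concordance_q[tumor]`
#' the entry is concordant with the gene's role (induced ->
#' unfavorable, reduced -> favorable) and significant; otherwise it is
#' a significant reversal (with probability `inversion_fraction`,
#' magnitude drawn from `magnitude_law`) or a non-significant `none`.
#' Deterministic given the config seed.
#'
#' @param induced,reduced Character vectors of acid-induced and
#'   acid-reduced genes.
#' @param config An [annotation_sim_config()].
#' @return A `prognostic_annotation` data frame.
#' @export
simulate_prognostic_annotations <- function(induced, reduced, config) {
  stopifnot(inherits(config, "annotation_sim_config"))
  genes <- c(induced, reduced)
  roles <- c(rep("induced", length(induced)), rep("reduced", length(reduced)))
  rows <- with_seed(substream_seed(config$seed, "prognostic"), {
    out <- vector("list", length(config$tumor_types))
    for (ti in seq_along(config$tumor_types)) {
      tt <- config$tumor_types[ti]
      q <- config$concordance_q[[tt]]
      if (!length(genes)) { out[[ti]] <- NULL; next }
      present <- stats::runif(length(genes)) >= config$missing_rate
      u <- stats::runif(length(genes))
      concord <- u < q
      invert <- !concord & (stats::runif(length(genes)) < config$inversion_fraction)
      dir_conc <- ifelse(roles == "induced", "unfavorable", "favorable")
      dir_inv <- ifelse(roles == "induced", "favorable", "unfavorable")
      direction <- ifelse(concord, dir_conc, ifelse(invert, dir_inv, "none"))
      significant <- concord | invert
      magnitude <- ifelse(direction == "none", NA_real_,
                          config$magnitude_law(length(genes)))
      keep <- present
      out[[ti]] <- data.frame(gene = genes[keep],
                              tumor_type = rep(tt, sum(keep)),
                              direction = direction[keep],
                              significant = significant[keep],
                              magnitude = magnitude[keep])
    }
    out
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(gene = character(0), tumor_type = character(0),
                     direction = character(0), significant = logical(0),
                     magnitude = numeric(0))
  as_prognostic_annotation(df)
}

#' Simulate pathological-stage trend annotations
#'
#' Bernoulli construction per (gene, tumor): with probability
#' `concordance` the trend matches the gene's role (induced ->
#' `late_stage_high`, reduced -> `late_stage_low`) and is significant;
#' otherwise it is a significant opposite trend (half the time) or a
#' non-significant `none`.
#'
#' @param genes Character vector of genes.
#' @param tumor_types Tumor panel.
#' @param concordance Probability of a concordant significant trend.
#' @param seed RNG seed.
#' @param roles Role per gene, recycled (`"induced"` / `"reduced"`).
#' @return A `stage_annotation` data frame.
#' @export
simulate_stage_annotations <- function(genes, tumor_types = TUMOR_TYPES,
                                       concordance = 0.5, seed = 1,
                                       roles = "induced") {
  assert_fraction(concordance, "concordance")
  roles <- rep_len(roles, length(genes))
  rows <- with_seed(substream_seed(seed, "stage"), {
    out <- vector("list", length(tumor_types))
    for (ti in seq_along(tumor_types)) {
      if (!length(genes)) { out[[ti]] <- NULL; next }
      conc <- stats::runif(length(genes)) < concordance
      opp <- !conc & (stats::runif(length(genes)) < 0.5)
      want <- ifelse(roles == "induced", "late_stage_high", "late_stage_low")
      anti <- ifelse(roles == "induced", "late_stage_low", "late_stage_high")
      trend <- ifelse(conc, want, ifelse(opp, anti, "none"))
      out[[ti]] <- data.frame(gene = genes, tumor_type = tumor_types[ti],
                              trend = trend, significant = conc | opp)
    }
    out
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(gene = character(0), tumor_type = character(0),
                     trend = character(0), significant = logical(0))
  as_stage_annotation(df)
}
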