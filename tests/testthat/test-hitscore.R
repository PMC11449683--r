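test_that("strict hit definition pairs response direction with prognosis", {
  unfav <- list(direction = "unfavorable", significant = TRUE)
  fav <- list(direction = "favorable", significant = TRUE)
  expect_true(is_hit("induced", unfav))
  expect_false(is_hit("induced", fav))
  expect_true(is_hit("reduced", fav))
  expect_false(is_hit("reduced", unfav))
  expect_false(is_hit("induced", list(direction = "unfavorable",
                                      significant = FALSE)))
  expect_false(is_hit("induced", NULL))  # missing entry is never a hit
})

test_that("inverted hits require reversal, significance and magnitude within tol", {
  inv <- function(mag) list(direction = "favorable", significant = TRUE,
                            magnitude = mag)
  expect_true(is_inverted_hit("induced", inv(0.10), tol = 0.20))
  expect_false(is_inverted_hit("induced", inv(0.30), tol = 0.20))
  expect_false(is_inverted_hit("induced", inv(0.10), tol = 0))
  expect_true(is_inverted_hit("induced", inv(0), tol = 0))
  # same direction as a strict hit is not an inversion
  expect_false(is_inverted_hit("induced",
                               list(direction = "unfavorable",
                                    significant = TRUE, magnitude = 0.1)))
  expect_warning(
    expect_false(is_inverted_hit("induced", inv(NA_real_))),
    "magnitude")
  # pluggable predicate overrides the default magnitude rule
  expect_true(is_inverted_hit("induced", inv(0.9), tol = 0.2,
                              predicate = function(m, tol) TRUE))
})

test_that("tumor scoring tallies strict and tolerant hits by enumeration", {
  ann <- rbind(
    ann_row("i1", "breast", "unfavorable", TRUE),
    ann_row("i2", "breast", "unfavorable", TRUE),
    ann_row("i3", "breast", "unfavorable", TRUE),
    ann_row("i4", "breast", "favorable", TRUE, 0.1),   # inverted within tol
    ann_row("i5", "breast", "none", FALSE))
  ann <- acidep:::as_prognostic_annotation(ann)
  r <- score_tumor(paste0("i", 1:5), character(0), ann, "breast", tol = 0.2)
  expect_equal(r$hits_induced_strict, 3L)
  expect_equal(r$hits_induced_tolerant, 4L)
  expect_equal(r$total_strict, 3L)
  expect_equal(r$total_tolerant, 4L)
  expect_equal(r$dominance, "induced_type")
  expect_equal(sort(unique(r$detail$status)),
               c("hit", "inverted", "miss"))

  none <- score_tumor(paste0("i", 1:5), character(0), ann, "lung")
  expect_equal(none$total_strict, 0L)
  expect_equal(none$n_missing, 5L)
  empty <- score_tumor(character(0), character(0), ann, "breast")
  expect_equal(empty$total_tolerant, 0L)
  expect_equal(empty$dominance, "balanced")
})

test_that("tolerant tallies are monotone in tol and collapse to strict at 0", {
  set.seed(21)
  induced <- sprintf("i%02d", 1:30)
  cfg <- annotation_sim_config(tumor_types = "lung", concordance_q = 0.4,
                               inversion_fraction = 0.8, missing_rate = 0,
                               seed = 31)
  ann <- simulate_prognostic_annotations(induced, character(0), cfg)
  tols <- c(0, 0.1, 0.2, 0.4, 1)
  tot <- vapply(tols, function(tl)
    score_tumor(induced, character(0), ann, "lung", tol = tl)$total_tolerant,
    numeric(1))
  expect_true(all(diff(tot) >= 0))
  strict <- score_tumor(induced, character(0), ann, "lung", tol = 0)
  # magnitudes are drawn from U(0, 0.4), so tol = 0 removes all inversions
  expect_equal(strict$total_tolerant, strict$total_strict)
  expect_true(all(tot <= length(induced)))
})

test_that("scoring is symmetric under role and direction relabeling", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:40)
  dirs <- sample(c("unfavorable", "favorable", "none"), 40, replace = TRUE)
  sig <- ifelse(dirs == "none", FALSE, sample(c(TRUE, FALSE), 40, TRUE))
  mags <- runif(40, 0, 0.4)
  ann1 <- acidep:::as_prognostic_annotation(
    data.frame(gene = genes, tumor_type = "gastric", direction = dirs,
               significant = sig, magnitude = mags))
  flip <- c(unfavorable = "favorable", favorable = "unfavorable",
            none = "none")
  ann2 <- acidep:::as_prognostic_annotation(
    data.frame(gene = genes, tumor_type = "gastric",
               direction = unname(flip[dirs]), significant = sig,
               magnitude = mags))
  r1 <- score_tumor(genes, character(0), ann1, "gastric")
  r2 <- score_tumor(character(0), genes, ann2, "gastric")
  expect_equal(r1$hits_induced_strict, r2$hits_reduced_strict)
  expect_equal(r1$hits_induced_tolerant, r2$hits_reduced_tolerant)
  expect_equal(r1$total_strict, r2$total_strict)
})

test_that("tumor ranking recovers planted concordance order with stable ties", {
  cfg <- annotation_sim_config(
    tumor_types = c("alpha", "beta", "gamma"),
    concordance_q = c(alpha = 0.8, beta = 0.5, gamma = 0.2),
    missing_rate = 0, seed = 17)
  induced <- sprintf("i%03d", 1:100)
  reduced <- sprintf("r%03d", 1:100)
  ann <- simulate_prognostic_annotations(induced, reduced, cfg)
  res <- score_tumors(induced, reduced, ann)
  rk <- rank_tumors(res)
  expect_equal(rk$tumor_type, c("alpha", "beta", "gamma"))
  expect_equal(rk$total_strict, sort(rk$total_strict, decreasing = TRUE))

  single <- rank_tumors(res["alpha"])
  expect_equal(nrow(single), 1L)

  # equal totals order stably by tumor name
  tie <- list(
    structure(list(tumor_type = "zeta", hits_induced_strict = 1L,
                   hits_reduced_strict = 1L, hits_induced_tolerant = 1L,
                   hits_reduced_tolerant = 1L, total_strict = 2L,
                   total_tolerant = 2L, dominance = "balanced",
                   n_missing = 0L, detail = NULL), class = "hit_score"),
    structure(list(tumor_type = "eta", hits_induced_strict = 2L,
                   hits_reduced_strict = 0L, hits_induced_tolerant = 2L,
                   hits_reduced_tolerant = 0L, total_strict = 2L,
                   total_tolerant = 2L, dominance = "induced_type",
                   n_missing = 0L, detail = NULL), class = "hit_score"))
  expect_equal(rank_tumors(tie)$tumor_type, c("eta", "zeta"))
})

test_that("gene hit rates and the 50% filter use the tumor panel as denominator", {
  mk <- function(tumor, status) {
    structure(list(tumor_type = tumor,
                   detail = data.frame(gene = "g", role = "induced",
                                       status = status)),
              class = "hit_score")
  }
  results <- lapply(seq_len(8), function(i)
    mk(paste0("t", i), if (i <= 4) "hit" else "miss"))
  expect_equal(gene_hit_rate("g", results), 0.5)
  expect_equal(filter_by_hit_rate("g", results, min_rate = 0.5), "g")
  none <- lapply(seq_len(8), function(i) mk(paste0("t", i), "miss"))
  expect_equal(gene_hit_rate("g", none), 0)
  expect_length(filter_by_hit_rate("g", none, min_rate = 0.5), 0)
  all8 <- lapply(seq_len(8), function(i) mk(paste0("t", i), "hit"))
  expect_equal(gene_hit_rate("g", all8), 1)
  expect_error(gene_hit_rate("g", list()), class = "acidep_config_error")
})

test_that("stage concordance counts significant matching trends per gene", {
  tumors <- paste0("t", 1:7)
  stg <- acidep:::as_stage_annotation(data.frame(
    gene = rep("PRRX2", 7), tumor_type = tumors,
    trend = c(rep("late_stage_high", 4), "late_stage_low", "none", "none"),
    significant = c(rep(TRUE, 5), FALSE, FALSE)))
  sc <- stage_concordance("PRRX2", stg, roles = "induced")
  expect_equal(sc$k, 4L)
  expect_equal(sc$n, 7L)

  nosig <- acidep:::as_stage_annotation(data.frame(
    gene = rep("MMD", 7), tumor_type = tumors, trend = "none",
    significant = FALSE))
  expect_equal(stage_concordance("MMD", nosig)$k, 0L)
  allc <- acidep:::as_stage_annotation(data.frame(
    gene = rep("X", 3), tumor_type = tumors[1:3],
    trend = "late_stage_low", significant = TRUE))
  expect_equal(stage_concordance("X", allc, roles = "reduced")$k, 3L)
  expect_warning(sc0 <- stage_concordance("ABSENT", allc), "absent")
  expect_equal(unlist(sc0[c("k", "n")], use.names = FALSE), c(0L, 0L))
})

test_that("the hit matrix lays out per-gene statuses across the panel", {
  cfg <- annotation_sim_config(tumor_types = c("breast", "lung"),
                               concordance_q = 1, missing_rate = 0, seed = 2)
  induced <- c("i1", "i2")
  ann <- simulate_prognostic_annotations(induced, character(0), cfg)
  res <- score_tumors(induced, character(0), ann)
  hm <- hit_matrix(res)
  expect_equal(dim(hm), c(2L, 2L))
  expect_true(all(hm == "hit"))
})
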