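test_that("fold changes are geometric-mean ratios of test over control", {
  m <- make_matrix(list(
    ident = unlist(const_rows(list(100, 100, 100), 4)),
    exact4 = unlist(const_rows(list(100, 400, 100), 4)),
    geo = c(80, 125, 100, 100, 320, 500, 400, 400, rep(100, 4))))
  rec <- compute_fold_changes(m, "pH7.4", c("pH6.8", "pH5.9"))
  get <- function(g, cond, col)
    rec[rec$gene == g & rec$condition == cond, col]
  expect_equal(get("ident", "pH6.8", "fc"), 1.0)
  expect_equal(get("ident", "pH6.8", "log2fc"), 0.0)
  expect_equal(get("exact4", "pH6.8", "fc"), 4.0)
  expect_equal(get("exact4", "pH6.8", "log2fc"), 2.0)
  # hand oracle: mean log2 of (80,125,100,100) = mean log2 of control;
  # test values are 4x each replicate, so the geometric-mean ratio is
  # exactly 4 even though the arithmetic-mean ratio is 4 too but the
  # per-replicate spread differs
  l2 <- mean(log2(c(320, 500, 400, 400))) - mean(log2(c(80, 125, 100, 100)))
  expect_equal(get("geo", "pH6.8", "log2fc"), l2)
  expect_equal(get("geo", "pH6.8", "fc"), 4.0)
  expect_error(compute_fold_changes(m, "pH7.4", "pH9.9"),
               class = "acidep_config_error")
})

test_that("arithmetic-mean ratio switch and zero flooring behave", {
  m <- make_matrix(list(g = c(0, 0, 0, 0, 8, 8, 8, 8, rep(1, 4))))
  expect_warning(rec <- compute_fold_changes(m, "pH7.4", "pH6.8"),
                 "floored")
  expect_equal(rec$fc[1], 8)  # control floored to 1
  m2 <- make_matrix(list(g = c(80, 120, 100, 100, 400, 400, 400, 400,
                               rep(100, 4))))
  rec2 <- compute_fold_changes(m2, "pH7.4", "pH6.8", method = "arithmetic")
  expect_equal(rec2$fc[1], 400 / 100)
})

test_that("per-gene pooled t-test matches the reference implementation", {
  # hand/textbook case: (1,2,3,4) control vs (2,3,4,5) test
  m <- make_matrix(list(g = c(1, 2, 3, 4, 2, 3, 4, 5, rep(1, 4))),
                   scale = "log2")
  tt <- per_gene_test(m, "pH7.4", "pH6.8")
  expect_equal(tt$t[1], 1.095445, tolerance = 1e-6)
  expect_equal(tt$df[1], 6)
  expect_equal(tt$p[1], 0.3153336, tolerance = 1e-6)

  # dual route on random data: vectorized implementation vs stats::t.test
  set.seed(42)
  vals <- matrix(rnorm(20 * 8, 8, 1), 20, 8,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  conds <- rep(c("pH7.4", "pH6.8"), each = 4)
  colnames(vals) <- paste0(conds, "_rep", rep(1:4, 2))
  mm <- expression_matrix(vals, data.frame(sample_id = colnames(vals),
                                           condition = conds,
                                           replicate = rep(1:4, 2)),
                          scale = "log2")
  for (ve in c(TRUE, FALSE)) {
    mine <- per_gene_test(mm, "pH7.4", "pH6.8", var_equal = ve)
    ref <- apply(vals, 1, function(v)
      stats::t.test(v[5:8], v[1:4], var.equal = ve)$p.value)
    expect_equal(mine$p, unname(ref), tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance genes are flagged with p of 0 or 1", {
  m <- make_matrix(list(equal = rep(2, 12),
                        shifted = c(rep(1, 4), rep(2, 4), rep(1, 4))),
                   scale = "log2")
  tt <- per_gene_test(m, "pH7.4", "pH6.8")
  expect_true(all(tt$degenerate))
  expect_equal(tt$p[tt$gene == "equal"], 1)
  expect_equal(tt$t[tt$gene == "equal"], 0)
  expect_equal(tt$p[tt$gene == "shifted"], 0)
})

test_that("Bonferroni column multiplies by the number of genes tested", {
  set.seed(7)
  vals <- matrix(rnorm(10 * 8), 10, 8,
                 dimnames = list(sprintf("g%02d", 1:10), NULL))
  conds <- rep(c("pH7.4", "pH6.8"), each = 4)
  colnames(vals) <- paste0(conds, "_rep", rep(1:4, 2))
  mm <- expression_matrix(vals, data.frame(sample_id = colnames(vals),
                                           condition = conds,
                                           replicate = rep(1:4, 2)),
                          scale = "log2")
  tt <- per_gene_test(mm, "pH7.4", "pH6.8", bonferroni = TRUE)
  expect_equal(tt$p_adj, pmin(1, tt$p * 10))
})

test_that("threshold selection includes the boundary and respects direction", {
  rec <- fc_table(c("a", "b", "c", "d", "e"), c(4.0, 3.9, 0.25, 0.26, 1.0))
  up4 <- select_modulated(rec, "pH6.8", 4, "up")
  expect_equal(up4$genes, "a")  # fc = 4.0 sits on the boundary, included
  down4 <- select_modulated(rec, "pH6.8", 4, "down")
  expect_equal(down4$genes, "c")
  expect_error(select_modulated(rec, "pH6.8", 1, "up"),
               class = "acidep_config_error")
  expect_error(select_modulated(rec, "pH5.9", 2, "up"),
               class = "acidep_config_error")
})

test_that("selection is monotone in the threshold and directions are exclusive", {
  set.seed(11)
  for (i in 1:25) {
    rec <- fc_table(sprintf("g%03d", 1:60), 2^rnorm(60, 0, 2))
    th <- sort(1 + rexp(2))
    for (dir in c("up", "down")) {
      lo <- select_modulated(rec, "pH6.8", th[1], dir)
      hi <- select_modulated(rec, "pH6.8", th[2], dir)
      expect_true(all(hi$genes %in% lo$genes))
    }
    up <- select_modulated(rec, "pH6.8", th[1], "up")
    dn <- select_modulated(rec, "pH6.8", th[1], "down")
    expect_length(intersect(up$genes, dn$genes), 0)
  }
})

test_that("venn partition is exact set algebra and rejects mismatched sets", {
  A <- gene_set("A", c("g1", "g2", "g3"), "up", 4, "pH6.8")
  B <- gene_set("B", c("g2", "g3", "g4"), "up", 4, "pH5.9")
  v <- venn_partition(A, B)
  expect_equal(unname(v$counts), c(1L, 2L, 1L))
  expect_equal(v$a_only$genes, "g1")
  expect_setequal(v$common$genes, c("g2", "g3"))
  expect_equal(v$b_only$genes, "g4")

  same <- venn_partition(A, A)
  expect_equal(unname(same$counts), c(0L, 3L, 0L))
  expect_setequal(same$common$genes, A$genes)

  D <- gene_set("D", "g9", "down", 4, "pH5.9")
  expect_error(venn_partition(A, D), "direction",
               class = "acidep_config_error")
  B2 <- gene_set("B2", "g1", "up", 2, "pH5.9")
  expect_error(venn_partition(A, B2), "threshold",
               class = "acidep_config_error")
})

test_that("venn partition agrees with naive membership on random small sets", {
  set.seed(13)
  pool <- sprintf("g%02d", 1:50)
  for (i in 1:40) {
    a <- sample(pool, sample(0:30, 1))
    b <- sample(pool, sample(0:30, 1))
    v <- venn_partition(gene_set("a", a, "up", 2, "x"),
                        gene_set("b", b, "up", 2, "y"))
    # brute-force oracle: classify every gene of the union by membership
    for (g in union(a, b)) {
      region <- if (g %in% a && g %in% b) "common"
      else if (g %in% a) "a_only" else "b_only"
      expect_true(g %in% v[[region]]$genes)
    }
    expect_equal(sum(v$counts), length(union(a, b)))
  }
})

test_that("top-N ranking orders by |log2fc| with p then symbol tie-breaks", {
  rec <- fc_table(c("e", "d", "c", "b", "a"), c(16, 8, 4, 2, 1.5))
  expect_equal(top_n_by_fold_change(rec, "pH6.8", 3, "up"),
               c("e", "d", "c"))
  expect_equal(top_n_by_fold_change(rec, "pH6.8", 99, "up"),
               c("e", "d", "c", "b", "a"))  # saturates at what exists

  tie <- fc_table(c("z", "y"), c(4, 4), p = c(0.04, 0.01))
  expect_equal(top_n_by_fold_change(tie, "pH6.8", 2, "up"), c("y", "z"))
  tie2 <- fc_table(c("z", "y"), c(4, 4), p = c(0.02, 0.02))
  expect_equal(top_n_by_fold_change(tie2, "pH6.8", 2, "up"), c("y", "z"))

  down <- fc_table(c("u", "v", "w"), c(1 / 16, 1 / 2, 3))
  expect_equal(top_n_by_fold_change(down, "pH6.8", 2, "down"), c("u", "v"))
})

test_that("volcano table maps p-values to finite -log10 with a cap", {
  rec <- fc_table(c("a", "b", "c"), c(1, 4, 2), p = c(1, 0.01, 0))
  v <- volcano_table(rec, "pH6.8")
  expect_equal(v$neg_log10_p, c(0, 2, 300))
  expect_equal(v$log2fc[1], 0)
  rec2 <- fc_table("a", 2)
  expect_error(volcano_table(rec2, "pH6.8"), class = "acidep_config_error")
})
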