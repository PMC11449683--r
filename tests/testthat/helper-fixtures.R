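# In-code fixtures shared across test files.

# A minimal linear-scale matrix: 3 conditions x `reps` replicates, with
# per-gene row values supplied as a list of per-condition vectors.
make_matrix <- function(rows, conds = c("pH7.4", "pH6.8", "pH5.9"),
                        reps = 4, scale = "linear") {
  values <- do.call(rbind, lapply(rows, function(r) unlist(r)))
  sample_ids <- as.vector(t(outer(conds, seq_len(reps),
                                  function(c, r) paste0(c, "_rep", r))))
  colnames(values) <- sample_ids
  meta <- data.frame(sample_id = sample_ids,
                     condition = rep(conds, each = reps),
                     replicate = rep(seq_len(reps), length(conds)))
  expression_matrix(values, meta, scale)
}

# Constant-replicate rows: one value per condition, repeated `reps` times.
const_rows <- function(per_cond, reps = 4) {
  lapply(per_cond, function(v) rep(v, each = reps))
}

# A small fold-change table built directly (bypassing a matrix).
fc_table <- function(genes, fc, condition = "pH6.8", p = NULL) {
  df <- data.frame(gene = genes, condition = condition, fc = fc,
                   log2fc = log2(fc))
  if (!is.null(p)) df$p <- p
  class(df) <- c("fold_change_table", "data.frame")
  df
}

# One prognostic annotation row.
ann_row <- function(gene, tumor, direction, significant, magnitude = NA_real_) {
  data.frame(gene = gene, tumor_type = tumor, direction = direction,
             significant = significant, magnitude = magnitude)
}

# Closed-form Pearson chi-squared for a 2x2 table (the independent
# oracle used against the implementation).
pearson_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
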