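# Expression matrix container and text-format IO.
#
# The matrix layout follows the common microarray convention: features
# (probes or gene symbols) in rows, samples in columns, with a separate
# sample table carrying condition labels (e.g. pH7.4 / pH6.8 / pH5.9) and
# replicate indices. Values are either linear intensities (non-negative)
# or log2-scale ratios/intensities.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, features in rows (rownames are feature
#'   ids), samples in columns (colnames are sample ids).
#' @param samples Data frame with columns `sample_id`, `condition`,
#'   `replicate` (positive integer), one row per column of `values`.
#' @param scale Either `"linear"` (non-negative intensities) or `"log2"`.
#' @return An object of class `expression_matrix`.
#' @examples
#' v <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    condition = rep(c("pH7.4", "pH6.8"), each = 2),
#'                    replicate = rep(1:2, 2))
#' expression_matrix(v, meta)
#' @export
expression_matrix <- function(values, samples, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_format("`values` must carry feature ids (rownames) and sample ids (colnames)")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop_format("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values)))
    stop_format("expression values must all be finite")
  if (scale == "linear" && any(values < 0))
    stop_format("linear-scale intensities must be non-negative")
  samples <- as.data.frame(samples)
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(samples)))
    stop_config("sample metadata must have columns: ", paste(req, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L))
    stop_config("replicate indices must be positive integers")
  if (nrow(samples) != ncol(values))
    stop_config("sample metadata rows (", nrow(samples),
                ") do not match sample columns (", ncol(values), ")")
  miss <- setdiff(colnames(values), samples$sample_id)
  if (length(miss))
    stop_config("sample(s) missing condition metadata: ", paste(miss, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$samples$condition)
  cat(sprintf("expression_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Condition labels present in an expression matrix
#' @param x An `expression_matrix`.
#' @export
conditions <- function(x) unique(x$samples$condition)

# Parse "<condition>_rep<k>" sample names into a metadata table; NULL if
# any name does not match the pattern.
meta_from_sample_names <- function(ids) {
  m <- regmatches(ids, regexec("^(.+)_rep([0-9]+)$", ids))
  if (any(vapply(m, length, 1L) != 3L)) return(NULL)
  data.frame(sample_id = ids,
             condition = vapply(m, `[`, "", 2L),
             replicate = as.integer(vapply(m, `[`, "", 3L)))
}

read_sample_meta <- function(meta) {
  if (is.data.frame(meta)) return(meta)
  if (!file.exists(meta)) stop_config("metadata file not found: ", meta)
  utils::read.delim(meta, stringsAsFactors = FALSE)
}

#' Read an expression table from text
#'
#' Reads a features-in-rows, samples-in-columns table. Two dialects are
#' supported: plain TSV (first column = feature id, header = sample ids)
#' and the GEO series-matrix dialect, where the table is the block between
#' the `!series_matrix_table_begin` and `!series_matrix_table_end` marker
#' lines and the preamble is discarded.
#'
#' Sample condition/replicate metadata comes from `meta` (a path to a TSV
#' with columns sample_id, condition, replicate, or an equivalent data
#' frame); when `meta` is omitted, sample ids of the form
#' `<condition>_rep<k>` are parsed instead. Anything else is a
#' configuration error: silent condition guessing is never done.
#'
#' Non-numeric cells are an error, not a silent `NA`; duplicated feature
#' ids are reported by name.
#'
#' @param path Path to the expression table.
#' @param meta Sample metadata table or path (see Details); optional when
#'   sample ids encode condition and replicate.
#' @param dialect `"tsv"` or `"geo_series_matrix"`.
#' @param scale Scale of the stored values, `"linear"` or `"log2"`.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, meta = NULL,
                                  dialect = c("tsv", "geo_series_matrix"),
                                  scale = c("linear", "log2")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop_config("expression table not found: ", path)
  lines <- readLines(path)
  if (dialect == "geo_series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop_format("series-matrix markers not found or empty table in ", path)
    lines <- lines[(beg + 1L):(end - 1L)]
    lines <- gsub('"', "", lines, fixed = TRUE)
  } else {
    lines <- lines[!startsWith(lines, "#")]
  }
  if (length(lines) < 2L) stop_format("no data rows in ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  sample_ids <- header[-1L]
  if (!length(sample_ids)) stop_format("header row defines no samples in ", path)
  body <- cells[-1L]
  if (any(vapply(body, length, 1L) != length(header)))
    stop_format("ragged rows in ", path)
  feat <- vapply(body, `[[`, "", 1L)
  dup <- unique(feat[duplicated(feat)])
  if (length(dup))
    stop_format("duplicate feature id(s): ", paste(dup, collapse = ", "))
  raw <- t(vapply(body, function(r) r[-1L], character(length(sample_ids))))
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num) & !is.na(raw) & nzchar(raw), arr.ind = TRUE)
  if (nrow(bad))
    stop_format("unparseable numeric cell at feature '", feat[bad[1, 1]],
                "', sample '", sample_ids[bad[1, 2]], "'")
  if (anyNA(num)) stop_format("missing values are not supported in ", path)
  dimnames(num) <- list(feat, sample_ids)
  meta_df <- if (!is.null(meta)) read_sample_meta(meta) else meta_from_sample_names(sample_ids)
  if (is.null(meta_df))
    stop_config("no sample metadata: supply `meta` or use '<condition>_rep<k>' sample ids")
  expression_matrix(num, meta_df, scale)
}

#' Write an expression matrix as TSV
#'
#' Writes the value table to `path` and the sample metadata to
#' `meta_path` (default `<path>` with a `.meta.tsv` suffix). The pair
#' round-trips through [read_expression_table()].
#'
#' @param x An `expression_matrix`.
#' @param path Output path for the value table.
#' @param meta_path Output path for the sample metadata table.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path,
                                   meta_path = paste0(path, ".meta.tsv")) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene level
#'
#' Maps probe ids to gene symbols and merges multi-probe genes. Unmapped
#' probes are dropped (their count is reported via a message and the
#' `n_unmapped` attribute), matching the convention that downstream gene
#' lists are reported as symbols only.
#'
#' @param x An `expression_matrix` whose features are probe ids.
#' @param map Probe-to-gene map: a named character vector
#'   (`names` = probe ids, values = gene symbols) or a two-column data
#'   frame `(probe_id, gene_symbol)`. Many probes may map to one gene;
#'   each probe maps to at most one gene.
#' @param method `"median"` takes the per-sample median across a gene's
#'   probes; `"max_abs_change"` keeps the single probe with the widest
#'   value range across samples (the most responsive probe).
#' @return An `expression_matrix` with one row per gene symbol.
#' @export
collapse_probes <- function(x, map, method = c("median", "max_abs_change")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expression_matrix"))
  if (is.data.frame(map)) {
    m <- as.character(map[[2L]])
    names(m) <- as.character(map[[1L]])
    map <- m
  }
  if (anyDuplicated(names(map)))
    stop_format("probe map lists a probe id more than once")
  probes <- rownames(x$values)
  mapped <- probes[probes %in% names(map)]
  n_unmapped <- length(probes) - length(mapped)
  if (!length(mapped))
    stop_format("probe map covers none of the matrix features")
  if (n_unmapped > 0)
    message(n_unmapped, " unmapped probe(s) dropped")
  genes <- map[mapped]
  vals <- x$values[mapped, , drop = FALSE]
  if (method == "median") {
    out <- rowsum(vals, genes, reorder = TRUE)  # placeholder shape
    for (g in rownames(out)) {
      sub <- vals[genes == g, , drop = FALSE]
      out[g, ] <- apply(sub, 2L, stats::median)
    }
  } else {
    pick <- tapply(seq_along(genes), genes, function(idx) {
      rng <- apply(vals[idx, , drop = FALSE], 1L, function(v) diff(range(v)))
      idx[which.max(rng)]
    })
    out <- vals[unlist(pick), , drop = FALSE]
    rownames(out) <- names(pick)
  }
  res <- expression_matrix(out, x$samples, x$scale)
  attr(res, "n_unmapped") <- n_unmapped
  res
}

#' Gene sets with direction, threshold and condition labels
#'
#' A gene set records the selection that produced it: the fold-change
#' threshold (a ratio > 1), the direction (`up` for induced, `down` for
#' reduced genes) and the condition it was selected in.
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols (deduplicated, order
#'   preserved).
#' @param direction `"up"` or `"down"`.
#' @param threshold Fold-change ratio used for selection; must be > 1.
#' @param condition Condition label the set was selected in.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, direction = c("up", "down"),
                     threshold = 2, condition = NA_character_) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 1)
    stop_config("`threshold` must be a single ratio > 1")
  genes <- unique(as.character(genes))
  structure(list(name = name, genes = genes, direction = direction,
                 threshold = threshold, condition = as.character(condition)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes, %s, threshold %g, condition %s\n",
              x$name, length(x$genes), x$direction, x$threshold, x$condition))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Write / read a gene set
#'
#' Plain text, one gene per line, preceded by a single `#`-prefixed JSON
#' header line carrying name, direction, threshold and condition.
#' `write_gene_set()` then `read_gene_set()` is the identity.
#'
#' @param set A [gene_set()].
#' @param path File path.
#' @return `read_gene_set()` returns a `gene_set`.
#' @export
write_gene_set <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  header <- jsonlite::toJSON(
    list(name = set$name, direction = set$direction,
         threshold = set$threshold, condition = set$condition),
    auto_unbox = TRUE)
  writeLines(c(paste0("#", header), set$genes), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop_config("gene-set file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#"))
    stop_format("gene-set file lacks its JSON header line: ", path)
  hdr <- tryCatch(jsonlite::fromJSON(sub("^#", "", lines[1L])),
                  error = function(e) stop_format("malformed gene-set header in ", path))
  for (f in c("name", "direction", "threshold", "condition"))
    if (is.null(hdr[[f]])) stop_format("gene-set header missing field '", f, "'")
  if (!hdr$direction %in% c("up", "down"))
    stop_format("invalid gene-set direction '", hdr$direction, "'")
  genes <- lines[-1L]
  genes <- genes[nzchar(genes)]
  gene_set(hdr$name, genes, hdr$direction, hdr$threshold, hdr$condition)
}

#' External reference signatures
#'
#' A reference signature is a per-gene high/low classification from a
#' published contrast (e.g. metastasized vs primary tumor cells), plus
#' the gene universe the classification was made over.
#'
#' @param contrast Name of the contrast (e.g. `"Mets vs primary"`).
#' @param classes Named character vector, gene -> `"high"` or `"low"`.
#' @param universe Character vector of all genes considered; classified
#'   genes must be a subset. Defaults to the classified genes.
#' @return An object of class `reference_signature`.
#' @export
reference_signature <- function(contrast, classes, universe = names(classes)) {
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stop_format("`classes` must be a named vector (gene -> class)")
  if (!all(classes %in% c("high", "low")))
    stop_format("signature classes must be 'high' or 'low'")
  universe <- unique(as.character(universe))
  if (!all(names(classes) %in% universe))
    stop_format("classified genes must lie inside the signature universe")
  structure(list(contrast = contrast, classes = classes, universe = universe),
            class = "reference_signature")
}

#' Write / read a reference signature
#'
#' The classification is a two-column TSV (gene, class); the contrast
#' name and gene universe travel in a JSON sidecar at `<path>.json`.
#' When the sidecar is missing on read, the universe defaults to the
#' classified genes.
#'
#' @param sig A [reference_signature()].
#' @param path TSV path; sidecar written/read at `<path>.json`.
#' @export
write_reference_signature <- function(sig, path) {
  stopifnot(inherits(sig, "reference_signature"))
  utils::write.table(
    data.frame(gene = names(sig$classes), class = unname(sig$classes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(contrast = sig$contrast, universe = sig$universe),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference_signature
#' @export
read_reference_signature <- function(path) {
  if (!file.exists(path)) stop_config("signature file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  classes <- df$class
  names(classes) <- df$gene
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    reference_signature(meta$contrast, classes, meta$universe)
  } else reference_signature(basename(path), classes)
}

#' Read prognostic survival annotations
#'
#' A TSV with columns `gene`, `tumor_type`, `direction`
#' (`unfavorable` / `favorable` / `none`), `significant` (logical), and
#' optional `magnitude` (effect distance from prognostic neutrality,
#' a non-negative real). At most one row per (gene, tumor_type);
#' `direction = "none"` rows must not be flagged significant.
#'
#' @param path TSV path.
#' @return A validated data frame of class `prognostic_annotation`.
#' @export
read_prognostic_annotations <- function(path) {
  if (!file.exists(path)) stop_config("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_prognostic_annotation(df)
}

as_prognostic_annotation <- function(df) {
  req <- c("gene", "tumor_type", "direction", "significant")
  if (!all(req %in% names(df)))
    stop_format("prognostic annotations need columns: ", paste(req, collapse = ", "))
  if (!"magnitude" %in% names(df)) df$magnitude <- NA_real_
  if (!all(df$direction %in% c("unfavorable", "favorable", "none")))
    stop_format("prognostic direction must be unfavorable/favorable/none")
  df$significant <- as.logical(df$significant)
  if (any(df$direction == "none" & df$significant))
    stop_format("direction 'none' entries cannot be significant")
  if (anyDuplicated(df[c("gene", "tumor_type")]))
    stop_format("duplicate (gene, tumor_type) annotation entries")
  class(df) <- c("prognostic_annotation", "data.frame")
  df
}

#' Read pathological-stage trend annotations
#'
#' A TSV with columns `gene`, `tumor_type`, `trend`
#' (`late_stage_high` / `late_stage_low` / `none`) and `significant`.
#'
#' @param path TSV path.
#' @return A validated data frame of class `stage_annotation`.
#' @export
read_stage_annotations <- function(path) {
  if (!file.exists(path)) stop_config("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_stage_annotation(df)
}

as_stage_annotation <- function(df) {
  req <- c("gene", "tumor_type", "trend", "significant")
  if (!all(req %in% names(df)))
    stop_format("stage annotations need columns: ", paste(req, collapse = ", "))
  if (!all(df$trend %in% c("late_stage_high", "late_stage_low", "none")))
    stop_format("stage trend must be late_stage_high/late_stage_low/none")
  df$significant <- as.logical(df$significant)
  if (anyDuplicated(df[c("gene", "tumor_type")]))
    stop_format("duplicate (gene, tumor_type) stage entries")
  class(df) <- c("stage_annotation", "data.frame")
  df
}
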