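# End-to-end orchestration: differential expression -> Venn ->
# signature comparison -> hit scoring -> stage concordance, with a
# machine-readable JSON summary and reproducible outputs.

#' Pipeline configuration
#'
#' Inputs come either from files (`matrix` + `meta`, annotation TSVs,
#' signature TSV) or from the synthetic generators (`simulate`,
#' `annotation_sim`, `signature_sim`, `stage_sim`). Every tunable has
#' its conventional default: fold-change thresholds 2 and 4, top-100
#' gene lists, 20% inversion tolerance, 50% minimum hit rate.
#'
#' @param matrix,meta Paths to an expression table and its sample
#'   metadata (see [read_expression_table()]); ignored when `simulate`
#'   is given.
#' @param dialect,scale Passed to [read_expression_table()].
#' @param simulate A [simulation_config()] to generate the matrix.
#' @param annotations Path to a prognostic annotation TSV.
#' @param annotation_sim An [annotation_sim_config()] used when
#'   `annotations` is absent.
#' @param stage_annotations Path to a stage annotation TSV.
#' @param stage_sim List `(concordance, seed)` to simulate stage
#'   annotations for the hit-rate-filtered genes.
#' @param signature Path to a reference signature TSV.
#' @param signature_sim List `(overlap, universe_size, seed)` to
#'   simulate one from the planted truth (requires `simulate`).
#' @param control Control condition label.
#' @param tests Test condition labels; defaults to the non-control
#'   conditions of the matrix.
#' @param thresholds Fold-change thresholds (> 1) for set selection.
#' @param top_n Size of the induced/reduced top lists.
#' @param tol Inversion tolerance for tolerant hit tallies.
#' @param hit_rate_min Minimum hit rate for the stage follow-up list.
#' @param rank_condition Condition used to rank the top lists; default
#'   the last (most severe) test condition.
#' @param seed Master seed for all stochastic stages.
#' @param out_dir Output directory; `NULL` for no file output.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix = NULL, meta = NULL, dialect = "tsv",
                            scale = "linear", simulate = NULL,
                            annotations = NULL, annotation_sim = NULL,
                            stage_annotations = NULL, stage_sim = NULL,
                            signature = NULL, signature_sim = NULL,
                            control = "pH7.4", tests = NULL,
                            thresholds = c(2, 4), top_n = 100, tol = 0.20,
                            hit_rate_min = 0.5, rank_condition = NULL,
                            seed = 1, out_dir = NULL) {
  if (any(thresholds <= 1)) stop_config("all thresholds must be > 1")
  if (top_n < 1) stop_config("`top_n` must be >= 1")
  assert_fraction(tol, "tol")
  assert_fraction(hit_rate_min, "hit_rate_min")
  if (is.null(matrix) && is.null(simulate))
    stop_config("either `matrix` or `simulate` must be given")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments;
#' `simulate` and `annotation_sim` blocks are passed to
#' [simulation_config()] / [annotation_sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$planted)) {
      y$simulate$planted <- lapply(y$simulate$planted, function(p) unlist(p))
    }
    y$simulate <- do.call(simulation_config, y$simulate)
  }
  if (!is.null(y$annotation_sim))
    y$annotation_sim <- do.call(annotation_sim_config, y$annotation_sim)
  do.call(pipeline_config, y)
}

#' Run the full acidosis-dependency pipeline
#'
#' Stages: (1) obtain the expression matrix (file or simulation);
#' (2) fold changes and per-gene t-tests for each test condition vs the
#' control; (3) thresholded up/down gene sets per condition and their
#' Venn partitions; (4) optional signature contingency (chi-squared) at
#' the smallest threshold; (5) top-N induced/reduced lists, per-tumor
#' hit scoring against prognostic annotations, tumor ranking, gene hit
#' rates; (6) optional stage concordance for genes passing the hit-rate
#' filter. Identical inputs and config give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `acidep_bundle` with all stage outputs and
#'   the config echo; written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  bundle <- tryCatch({
    truth <- NULL
    if (!is.null(config$simulate)) {
      sim <- simulate_expression(config$simulate)
      mat <- sim$matrix
      truth <- sim$truth
      control <- config$simulate$control
      tests <- config$simulate$tests
    } else {
      mat <- read_expression_table(config$matrix, config$meta,
                                   dialect = config$dialect,
                                   scale = config$scale)
      control <- config$control
      tests <- config$tests %||% setdiff(conditions(mat), control)
    }

    stage <- "diffexpr"
    records <- compute_fold_changes(mat, control, tests)
    min_reps <- min(table(mat$samples$condition))
    if (min_reps >= 2L) records <- add_tests(records, mat, control)

    stage <- "venn"
    venns <- list()
    sets <- list()
    for (th in config$thresholds) {
      for (dir in c("up", "down")) {
        per_cond <- lapply(tests, function(cc)
          select_modulated(records, cc, th, dir))
        names(per_cond) <- tests
        sets[[sprintf("%s_%g", dir, th)]] <- per_cond
        if (length(tests) == 2L) {
          vp <- venn_partition(per_cond[[1L]], per_cond[[2L]])
          venns[[sprintf("%s_%g", dir, th)]] <- vp
        }
      }
    }

    stage <- "signature_compare"
    signature_results <- NULL
    sig <- NULL
    if (!is.null(config$signature)) {
      sig <- read_reference_signature(config$signature)
    } else if (!is.null(config$signature_sim) && !is.null(truth)) {
      ss <- config$signature_sim
      sig <- simulate_reference_signature(truth, ss$overlap, ss$universe_size,
                                          seed = ss$seed %||% config$seed)
    }
    if (!is.null(sig)) {
      th0 <- min(config$thresholds)
      signature_results <- lapply(tests, function(cc) {
        key_up <- sets[[sprintf("up_%g", th0)]][[cc]]
        key_dn <- sets[[sprintf("down_%g", th0)]][[cc]]
        chi_square_2x2(build_contingency(sig, key_up, key_dn))
      })
      names(signature_results) <- tests
    }

    stage <- "hitscore"
    rank_cond <- config$rank_condition %||% tests[length(tests)]
    induced <- top_n_by_fold_change(records, rank_cond, config$top_n, "up")
    reduced <- top_n_by_fold_change(records, rank_cond, config$top_n, "down")
    ann <- if (!is.null(config$annotations)) {
      read_prognostic_annotations(config$annotations)
    } else if (!is.null(config$annotation_sim)) {
      simulate_prognostic_annotations(induced, reduced, config$annotation_sim)
    } else NULL
    results <- ranking <- hit_rates <- filtered <- NULL
    if (!is.null(ann)) {
      tumor_types <- if (!is.null(config$annotation_sim))
        config$annotation_sim$tumor_types else sort(unique(ann$tumor_type))
      results <- score_tumors(induced, reduced, ann, tumor_types,
                              tol = config$tol)
      ranking <- rank_tumors(results)
      all_genes <- c(induced, reduced)
      hit_rates <- vapply(all_genes, gene_hit_rate, numeric(1),
                          results = results)
      filtered <- filter_by_hit_rate(all_genes, results, config$hit_rate_min)
    }

    stage <- "stage_concordance"
    stage_table <- NULL
    if (!is.null(filtered) && length(filtered)) {
      roles <- ifelse(filtered %in% induced, "induced", "reduced")
      stage_ann <- if (!is.null(config$stage_annotations)) {
        read_stage_annotations(config$stage_annotations)
      } else if (!is.null(config$stage_sim)) {
        simulate_stage_annotations(filtered,
                                   concordance = config$stage_sim$concordance,
                                   seed = config$stage_sim$seed %||% config$seed,
                                   roles = roles)
      } else NULL
      if (!is.null(stage_ann))
        stage_table <- stage_concordance(filtered, stage_ann, roles)
    }

    structure(list(
      config = config, matrix_dim = dim(mat$values), truth = truth,
      records = records, sets = sets, venns = venns,
      signature_results = signature_results,
      induced = induced, reduced = reduced,
      results = results, ranking = ranking,
      hit_rates = hit_rates, filtered = filtered,
      stage_table = stage_table, complete = TRUE),
      class = "acidep_bundle")
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

config_echo <- function(config) {
  keep <- c("control", "tests", "thresholds", "top_n", "tol",
            "hit_rate_min", "rank_condition", "seed", "dialect", "scale")
  echo <- config[keep]
  if (!is.null(config$simulate))
    echo$simulate <- unclass(config$simulate)
  if (!is.null(config$annotation_sim)) {
    a <- unclass(config$annotation_sim)
    a$magnitude_law <- NULL  # functions are not serializable; law is config code
    echo$annotation_sim <- a
  }
  echo
}

bundle_summary <- function(bundle) {
  list(
    package_version = as.character(utils::packageVersion("acidep")),
    config = config_echo(bundle$config),
    n_features = bundle$matrix_dim[1L], n_samples = bundle$matrix_dim[2L],
    venn_counts = lapply(bundle$venns, function(v) as.list(v$counts)),
    signature = if (!is.null(bundle$signature_results))
      lapply(bundle$signature_results, function(s)
        list(counts = as.vector(s$counts), chi2 = s$chi2, p = s$p,
             degenerate = s$degenerate)),
    n_induced = length(bundle$induced), n_reduced = length(bundle$reduced),
    ranking = bundle$ranking,
    n_hit_rate_filtered = length(bundle$filtered),
    stage_table = bundle$stage_table)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle_summary(bundle),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  utils::write.table(bundle$records, file.path(out_dir, "fold_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$sets))
    for (cc in names(bundle$sets[[nm]]))
      write_gene_set(bundle$sets[[nm]][[cc]],
                     file.path(out_dir, sprintf("set_%s_%s.txt", nm, cc)))
  if (!is.null(bundle$results)) {
    hm <- hit_matrix(bundle$results)
    utils::write.table(data.frame(gene = rownames(hm), hm,
                                  check.names = FALSE),
                       file.path(out_dir, "hit_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$ranking, file.path(out_dir, "tumor_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Human-readable pipeline report
#'
#' Formats the per-tumor hit table (strict and tolerant tallies with
#' dominance labels), the leading hit-rate genes and the stage
#' concordance table from a completed pipeline bundle.
#'
#' @param bundle An `acidep_bundle` from [run_pipeline()].
#' @param top_genes How many top hit-rate genes to list.
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
make_report <- function(bundle, top_genes = 10) {
  if (!inherits(bundle, "acidep_bundle") || !isTRUE(bundle$complete))
    stop_config("incomplete pipeline bundle; run run_pipeline() first")
  lines <- c("== acidosis-dependency pipeline report ==", "")
  for (nm in names(bundle$venns)) {
    v <- bundle$venns[[nm]]
    lines <- c(lines, sprintf(
      "venn %-9s a_only %4d | common %4d | b_only %4d",
      nm, v$counts[["a_only"]], v$counts[["common"]], v$counts[["b_only"]]))
  }
  if (!is.null(bundle$ranking)) {
    lines <- c(lines, "", "tumor ranking (strict | tolerant hits, dominance):")
    r <- bundle$ranking
    lines <- c(lines, sprintf("  %-14s %4d | %4d  %s", r$tumor_type,
                              r$total_strict, r$total_tolerant, r$dominance))
  }
  if (!is.null(bundle$hit_rates) && length(bundle$hit_rates)) {
    hr <- sort(bundle$hit_rates, decreasing = TRUE)
    hr <- utils::head(hr, top_genes)
    lines <- c(lines, "", "top hit-rate genes:",
               sprintf("  %-12s %.2f", names(hr), hr))
  }
  if (!is.null(bundle$stage_table) && nrow(bundle$stage_table)) {
    s <- utils::head(bundle$stage_table, top_genes)
    lines <- c(lines, "", "stage concordance (k/n):",
               sprintf("  %-12s %d/%d", s$gene, s$k, s$n))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
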