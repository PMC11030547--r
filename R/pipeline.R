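#' Run the full inflammaging analysis pipeline from a config file
#'
#' Executes the configured stages in order — `simulate` (or reading input
#' files), `age_index` (both sexes), `classify`, `sex_bias`, `train`,
#' `predict`, `enrich` — writing every result as TSV into `out_dir`
#' together with a run manifest (package version, R version, seed,
#' parameters, input checksums) and a plain-text report. All randomness
#' flows from the single `seed` in the config. Outputs are deterministic:
#' rerunning an identical config reproduces every file byte-identically
#' except the manifest timestamp.
#'
#' The config is YAML (or an equivalent named list) with a top-level `seed`
#' and one block per stage; every block mirrors the corresponding function's
#' arguments. Without a `simulate` block, `inputs: {matrix: ..., metadata:
#' ...}` must name the input files. The `enrich` block's `sets` entry is
#' either a gene-set file path or the string `"planted"` (test the planted
#' truth groups of a simulated cohort against the model's coefficient-sign
#' lists).
#'
#' @param config path to a YAML file, or a named list.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_("`config` must be a file path or a named list")
  out_dir <- out_dir %||% config$out_dir %||% stop_("config is missing field 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% stop_("config is missing field 'seed'")
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  results <- list()
  paths <- character()
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  ## --- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    results$sim <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      sim <- simulate_cohort(do.call(sim_config, args))
      emit("matrix.tsv", function(p) write_expression_table(sim$matrix, p))
      emit("metadata.tsv", function(p) write_sample_metadata(sim$meta, p))
      emit("truth.tsv", function(p) write.table(sim$truth$genes, p, sep = "\t",
                                                quote = FALSE, row.names = FALSE))
      sim
    })
    mat <- results$sim$matrix
    meta <- results$sim$meta
  } else {
    inp <- config$inputs
    if (is.null(inp$matrix)) stop_("config is missing field 'inputs.matrix'")
    if (is.null(inp$metadata)) stop_("config is missing field 'inputs.metadata'")
    mat <- stage("read_matrix", read_expression_table(inp$matrix))
    meta <- stage("read_metadata", read_sample_metadata(inp$metadata))
  }

  ## --- AGE-Index per sex ----------------------------------------------
  if (!is.null(config$age_index)) {
    a <- config$age_index
    for (sx in c("female", "male")) {
      results$age_index[[sx]] <- stage(paste0("age_index_", sx), {
        tab <- compute_age_index(mat, meta, sex = sx,
                                 young = unlist(a$young %||% c(3, 10)),
                                 old = unlist(a$old %||% 30),
                                 old_mode = a$old_mode %||% "min",
                                 pseudocount = a$pseudocount %||% 0)
        emit(paste0("age_index_", sx, ".tsv"),
             function(p) write_age_index(tab, p))
        tab
      })
    }
  }

  ## --- pattern classification -----------------------------------------
  if (!is.null(config$classify)) {
    results$patterns <- stage("classify", {
      if (is.null(results$age_index)) stop("requires the age_index stage")
      params <- do.call(pattern_params, config$classify %||% list())
      calls <- classify_patterns(results$age_index$female, results$age_index$male, params)
      emit("pattern_calls.tsv", function(p) write.table(calls, p, sep = "\t",
                                                        quote = FALSE, row.names = FALSE))
      calls
    })
  }

  ## --- sex bias ---------------------------------------------------------
  if (!is.null(config$sex_bias)) {
    results$sex_bias <- stage("sex_bias", {
      b <- config$sex_bias
      bias <- sex_bias_log2(mat, meta,
                            age_window = unlist(b$age_window %||% c(3, 10)),
                            pseudocount = b$pseudocount %||% 0.5)
      emit("sex_bias.tsv", function(p) write.table(bias, p, sep = "\t",
                                                   quote = FALSE, row.names = FALSE))
      bias
    })
  }

  ## --- clock ------------------------------------------------------------
  if (!is.null(config$train)) {
    results$clock <- stage("train", {
      tr <- config$train
      genes <- if (!is.null(tr$genes)) read_gene_sets(tr$genes) else NULL
      out <- train_diage(mat, meta, gene_subset = genes,
                         sex_filter = tr$sex_filter %||% "all",
                         split = tr$split %||% 0.7,
                         alpha = tr$alpha %||% 0.5,
                         seed = tr$seed %||% seed,
                         k = tr$k %||% 10L,
                         criterion = tr$criterion %||% "mse",
                         rule = tr$rule %||% "min")
      emit("model.diage", function(p) write_diage_model(out$model, p))
      out
    })
    results$predictions <- stage("predict", {
      pred <- predict_diage(results$clock$model, mat)
      emit("predictions.tsv", function(p) write.table(pred, p, sep = "\t",
                                                      quote = FALSE, row.names = FALSE))
      pred
    })
  }

  ## --- enrichment -------------------------------------------------------
  if (!is.null(config$enrich)) {
    results$enrichment <- stage("enrich", {
      if (is.null(results$clock)) stop("requires the train stage")
      spec <- config$enrich$sets %||% "planted"
      sets <- if (identical(spec, "planted")) {
        if (is.null(results$sim)) stop("sets: planted requires the simulate stage")
        g <- results$sim$truth$genes
        split(g$gene, g$group)[c("inflammaging", "male_biased", "female_suppressed")]
      } else {
        read_gene_sets(spec)
      }
      sets <- Filter(Negate(is.null), sets)
      signs <- coefficient_sign_lists(results$clock$model)
      universe <- results$clock$model$gene_universe
      enr <- lapply(names(signs), function(sgn) {
        if (!length(signs[[sgn]])) return(NULL)
        cbind(coefficient_sign = sgn,
              hypergeometric_enrichment(signs[[sgn]], sets, universe))
      })
      enr <- do.call(rbind, Filter(Negate(is.null), enr))
      emit("enrichment.tsv", function(p) write.table(enr, p, sep = "\t",
                                                     quote = FALSE, row.names = FALSE))
      enr
    })
  }

  ## --- manifest + report ------------------------------------------------
  manifest <- list(
    package = "diage",
    version = as.character(packageVersion("diage")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    output_checksums = as.list(tools::md5sum(unlist(paths)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  report <- c("inflammaging pipeline report", "===========================")
  if (!is.null(results$sim)) {
    report <- c(report, sprintf("simulated cohort: %d genes x %d samples (seed %s)",
                                nrow(results$sim$matrix), ncol(results$sim$matrix), seed))
  }
  if (!is.null(results$age_index)) {
    for (sx in names(results$age_index)) {
      t <- results$age_index[[sx]]
      report <- c(report, sprintf("AGE-Index (%s): %d genes, %d with index >= 5",
                                  sx, nrow(t), sum(t$age_index >= 5, na.rm = TRUE)))
    }
  }
  if (!is.null(results$patterns)) {
    tb <- table(results$patterns$label)
    report <- c(report, paste("pattern calls:",
                              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
  if (!is.null(results$clock)) {
    m <- results$clock$metrics
    report <- c(report, sprintf(
      "clock: %d nonzero genes, held-out MAE %.3f T_age units (%.2f days), RMSE %.3f (%.2f days)",
      length(results$clock$model$beta), m$mae_t_age, m$mae_days, m$rmse_t_age, m$rmse_days))
  }
  if (!is.null(results$enrichment)) {
    top <- results$enrichment[1L, ]
    report <- c(report, sprintf("top enrichment: %s genes vs set '%s', overlap %d, p = %.3g",
                                top$coefficient_sign, top$set, top$overlap, top$p_value))
  }
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(results)
}
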