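#' Transformed age scale of the inflammatory-age clock
#'
#' The clock regresses on `T_age = (age_days - 1) / 5`, so eclosion (day 1)
#' maps to 0 and every T_age unit is exactly 5 days. `inverse_t_age()`
#' inverts it exactly; errors reported in T_age units convert to days by the
#' same factor of 5.
#'
#' @param age_days age in days post-eclosion, >= 1.
#' @return transformed age (T_age units).
#' @export
t_age <- function(age_days) {
  if (any(!is.finite(age_days)) || any(age_days < 1)) {
    stop_("age_days must be >= 1 (days post-eclosion; eclosion = day 1)")
  }
  (age_days - 1) / 5
}

#' @rdname t_age
#' @param t age on the T_age scale.
#' @export
inverse_t_age <- function(t) 5 * t + 1

#' Per-gene min-max normalization
#'
#' `fit_minmax()` records each gene's minimum and maximum over the training
#' samples; `apply_minmax()` maps expression to
#' `(x - min) / (max - min)` so training values lie in \[0, 1\] (mimicking
#' the bounded beta-value inputs of methylation clocks). Genes whose
#' training values are constant are flagged degenerate, emitted as 0, and
#' excluded from modeling. At prediction time, values outside \[0, 1\] are
#' clipped by default, bounding extrapolation beyond the training range.
#'
#' @param matrix an [expression_matrix()] (genes x samples), >= 2 samples.
#' @return `fit_minmax()`: a `minmax_params` data.frame with columns `gene`,
#'   `min`, `max`, `degenerate`.
#' @export
fit_minmax <- function(matrix) {
  if (ncol(matrix) < 2L) stop_("min-max normalization needs at least two samples")
  mn <- apply(matrix, 1, min)
  mx <- apply(matrix, 1, max)
  structure(data.frame(gene = rownames(matrix), min = mn, max = mx,
                       degenerate = mx == mn, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("minmax_params", "data.frame"))
}

#' @rdname fit_minmax
#' @param params a `minmax_params`.
#' @param clip clip out-of-range values to \[0, 1\]? Default `TRUE`.
#' @return `apply_minmax()`: normalized matrix restricted to the params'
#'   genes (in their order), with an `n_out_of_range` per-sample attribute
#'   counting values that fell outside \[0, 1\] before clipping.
#' @export
apply_minmax <- function(matrix, params, clip = TRUE) {
  clip <- check_flag(clip, "clip")
  missing <- setdiff(params$gene, rownames(matrix))
  if (length(missing)) {
    stop_("matrix is missing %d gene(s) required by the normalization: %s",
          length(missing), paste(head(missing, 5L), collapse = ", "))
  }
  m <- matrix[params$gene, , drop = FALSE]
  rng <- params$max - params$min
  rng[params$degenerate] <- 1                       # emit 0 for degenerate genes
  norm <- (m - params$min) / rng
  norm[params$degenerate, ] <- 0
  oor <- colSums(norm < 0 | norm > 1)
  if (clip) norm <- pmin(pmax(norm, 0), 1)
  attr(norm, "n_out_of_range") <- oor
  norm
}

#' Train the DiAge inflammatory-age clock
#'
#' Full training pipeline: filter samples by sex, optionally restrict to a
#' gene set (e.g. an immune-defense list, giving the DiAge model proper),
#' split samples 70:30 into training and test, fit the per-gene min-max
#' normalization on the training split only, transform ages to the T_age
#' scale, select the elastic-net penalty by k-fold cross-validation on the
#' training split, fit the final model, and report held-out MAE and RMSE in
#' T_age units and days.
#'
#' Mixed- and unknown-sex samples participate only when `sex_filter = "all"`.
#'
#' @param matrix an [expression_matrix()].
#' @param meta sample metadata.
#' @param gene_subset optional character vector (or single gene set) to
#'   restrict predictors to.
#' @param sex_filter `"all"` (default), `"female"`, or `"male"`.
#' @param split training fraction, default 0.7.
#' @param alpha elastic-net mixing parameter, default 0.5.
#' @param seed seed controlling the split and the CV folds.
#' @param k CV fold count, default 10.
#' @param criterion CV criterion, `"mse"` (default) or `"mae"`.
#' @param rule lambda rule, `"min"` (default) or `"1se"`.
#' @param clip clip normalized test values to \[0, 1\]? Default `TRUE`.
#' @return list with elements `model` (a `diage_model`) and `metrics`
#'   (held-out MAE/RMSE in T_age units and days, and sample counts).
#' @export
train_diage <- function(matrix, meta, gene_subset = NULL,
                        sex_filter = c("all", "female", "male"),
                        split = 0.7, alpha = 0.5, seed = 1L, k = 10L,
                        criterion = "mse", rule = "min", clip = TRUE) {
  sex_filter <- match.arg(sex_filter)
  split <- check_number(split, "split", 0, 1)
  al <- align_samples(matrix, meta)
  matrix <- al$matrix; meta <- al$meta
  if (sex_filter != "all") meta <- meta[meta$sex == sex_filter, , drop = FALSE]
  if (nrow(meta) < 10L) stop_("need at least 10 samples after filtering, have %d", nrow(meta))
  if (!is.null(gene_subset)) {
    gene_subset <- unlist(gene_subset, use.names = FALSE)
    keep <- intersect(rownames(matrix), gene_subset)
    if (!length(keep)) stop_("gene_subset shares no genes with the matrix")
    matrix <- matrix[keep, , drop = FALSE]
  }
  matrix <- matrix[, meta$sample_id, drop = FALSE]

  n <- nrow(meta)
  train_idx <- with_seed(seed, sample.int(n, round(split * n)))
  train_ids <- meta$sample_id[train_idx]
  test_ids <- setdiff(meta$sample_id, train_ids)
  if (!length(test_ids)) stop_("empty test split")

  minmax <- fit_minmax(matrix[, train_ids, drop = FALSE])
  usable <- minmax[!minmax$degenerate, , drop = FALSE]
  if (!nrow(usable)) stop_("all genes are constant on the training split")
  Xtr <- t(apply_minmax(matrix[, train_ids, drop = FALSE], usable, clip = FALSE))
  ytr <- t_age(meta$age_days[match(train_ids, meta$sample_id)])

  cv <- cv_select_lambda(Xtr, ytr, alpha = alpha, k = min(k, length(train_ids)),
                         criterion = criterion, seed = seed, rule = rule)
  fit <- elastic_net_fit(Xtr, ytr, alpha = alpha, lambda = cv$chosen)

  model <- structure(list(
    intercept = fit$b0,
    beta = fit$beta[fit$beta != 0],
    minmax = minmax,
    gene_universe = usable$gene,
    alpha = alpha, lambda = cv$chosen,
    sex_filter = sex_filter, seed = as.integer(seed),
    train_ids = train_ids, cv = cv[c("lambda_min", "lambda_1se", "rule", "criterion", "k")]
  ), class = "diage_model")

  pred <- predict_diage(model, matrix[, test_ids, drop = FALSE], clip = clip)
  ytest <- t_age(meta$age_days[match(test_ids, meta$sample_id)])
  metrics <- clock_metrics(pred$predicted_t_age, ytest,
                           n_train = length(train_ids), n_test = length(test_ids))
  list(model = model, metrics = metrics)
}

## held-out error summary; days are exactly 5x the T_age-unit values.
clock_metrics <- function(pred_t, true_t, n_train = NA_integer_, n_test = NA_integer_) {
  err <- pred_t - true_t
  mae <- mean(abs(err)); rmse <- sqrt(mean(err^2))
  list(mae_t_age = mae, rmse_t_age = rmse,
       mae_days = 5 * mae, rmse_days = 5 * rmse,
       n_train = n_train, n_test = n_test)
}

#' Assess the clock by repeated random splits
#'
#' Runs `repeats` independent 70:30 split-train-evaluate cycles (split seeds
#' derived deterministically from `seed`) and reports the per-repeat MAE and
#' RMSE with their mean, median and sd — the resampling view of clock
#' accuracy.
#'
#' @inheritParams train_diage
#' @param repeats number of random splits, >= 2.
#' @return list of class `diage_resample`: `per_repeat` (data.frame) and
#'   `summary` (mean/median/sd of MAE and RMSE in T_age units and days).
#' @export
resample_assess <- function(matrix, meta, gene_subset = NULL,
                            sex_filter = "all", split = 0.7, alpha = 0.5,
                            seed = 1L, repeats = 20L, k = 10L,
                            criterion = "mse", rule = "min") {
  repeats <- check_count(repeats, "repeats", 2L)
  per <- lapply(seq_len(repeats), function(i) {
    m <- train_diage(matrix, meta, gene_subset = gene_subset,
                     sex_filter = sex_filter, split = split, alpha = alpha,
                     seed = seed + i, k = k, criterion = criterion,
                     rule = rule)$metrics
    data.frame(repeat_id = i, mae_t_age = m$mae_t_age, rmse_t_age = m$rmse_t_age,
               mae_days = m$mae_days, rmse_days = m$rmse_days)
  })
  per <- do.call(rbind, per)
  summ <- function(v) c(mean = mean(v), median = median(v), sd = sd(v))
  structure(list(per_repeat = per,
                 summary = list(mae_t_age = summ(per$mae_t_age),
                                rmse_t_age = summ(per$rmse_t_age),
                                mae_days = summ(per$mae_days),
                                rmse_days = summ(per$rmse_days)),
                 repeats = repeats, seed = seed),
            class = "diage_resample")
}

#' @export
print.diage_resample <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Resampling assessment over %d random 70:30 splits:\n", x$repeats))
  cat(sprintf("  MAE : mean %.3f (%.2f days), median %.3f (%.2f days), sd %.3f\n",
              s$mae_t_age["mean"], s$mae_days["mean"],
              s$mae_t_age["median"], s$mae_days["median"], s$mae_t_age["sd"]))
  cat(sprintf("  RMSE: mean %.3f (%.2f days), median %.3f (%.2f days), sd %.3f\n",
              s$rmse_t_age["mean"], s$rmse_days["mean"],
              s$rmse_t_age["median"], s$rmse_days["median"], s$rmse_t_age["sd"]))
  invisible(x)
}

#' Predict inflammatory age with a fitted clock
#'
#' Normalizes the new samples with the model's training min-max parameters
#' (clipped to \[0, 1\] by default), applies the linear model on the T_age
#' scale, and converts to days via `age = 5 * T_age + 1`. Predictions below
#' day 0 are reported as-is with a warning flag rather than truncated.
#'
#' @param model a `diage_model`.
#' @param matrix an [expression_matrix()] containing every model gene.
#' @param clip clip normalized values to \[0, 1\]? Default `TRUE`.
#' @return data.frame: `sample_id`, `predicted_t_age`, `predicted_age_days`,
#'   `out_of_range_gene_count`, `negative_flag`.
#' @export
predict_diage <- function(model, matrix, clip = TRUE) {
  norm <- apply_minmax(matrix, model$minmax[match(model$gene_universe, model$minmax$gene), , drop = FALSE],
                       clip = clip)
  x <- t(norm)
  beta <- setNames(numeric(length(model$gene_universe)), model$gene_universe)
  beta[names(model$beta)] <- model$beta
  pred_t <- model$intercept + drop(x %*% beta)
  days <- inverse_t_age(pred_t)
  neg <- days < 0
  if (any(neg)) {
    warning(sprintf("%d prediction(s) below day 0 (reported as-is)", sum(neg)), call. = FALSE)
  }
  data.frame(sample_id = colnames(matrix),
             predicted_t_age = unname(pred_t),
             predicted_age_days = unname(days),
             out_of_range_gene_count = unname(attr(norm, "n_out_of_range")),
             negative_flag = unname(neg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare predicted inflammatory age between two groups
#'
#' Welch two-sample t-test on predicted ages (days), e.g. high-fat-diet
#' versus normal-diet samples.
#'
#' @param predictions numeric vector of predicted ages in days.
#' @param groups vector with exactly two distinct labels, parallel to
#'   `predictions`; each group needs >= 2 samples.
#' @return list: `group_means`, `difference` (first minus second level),
#'   `t`, `df`, `p_value`.
#' @export
compare_diage_groups <- function(predictions, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop_("`groups` must have exactly two levels, got %d", nlevels(groups))
  counts <- table(groups)
  if (any(counts < 2L)) {
    stop_("each group needs at least 2 samples (%s)",
          paste(sprintf("%s: %d", names(counts), counts), collapse = ", "))
  }
  a <- predictions[groups == levels(groups)[1L]]
  b <- predictions[groups == levels(groups)[2L]]
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    ## identical constant groups: Welch statistic degenerates to 0/0
    return(list(group_means = setNames(c(mean(a), mean(b)), levels(groups)),
                difference = 0, t = 0, df = length(a) + length(b) - 2, p_value = 1))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(group_means = setNames(c(mean(a), mean(b)), levels(groups)),
       difference = mean(a) - mean(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' @export
print.diage_model <- function(x, ...) {
  cat(sprintf("DiAge clock: %d nonzero of %d genes, alpha=%g lambda=%.4g, sex=%s\n",
              length(x$beta), length(x$gene_universe), x$alpha, x$lambda, x$sex_filter))
  cat(sprintf("  trained on %d samples (seed %d); intercept %.4g T_age units\n",
              length(x$train_ids), x$seed, x$intercept))
  invisible(x)
}

#' Serialize a DiAge model to a self-describing text file
#'
#' The format is a tab-separated header of scalars (`alpha`, `lambda`,
#' `intercept`, `sex_filter`, `seed`, `train_ids`) followed by one row per
#' gene in the model universe: `gene, min, max, beta`. Numbers are written
#' with 17 significant digits so that write-read round trips are lossless
#' and write-read-write is byte-identical.
#'
#' @param model a `diage_model`.
#' @param path file path (conventionally `.diage`).
#' @export
write_diage_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  hdr <- c("#diage_model\tv1",
           paste0("alpha\t", num(model$alpha)),
           paste0("lambda\t", num(model$lambda)),
           paste0("intercept\t", num(model$intercept)),
           paste0("sex_filter\t", model$sex_filter),
           paste0("seed\t", model$seed),
           paste0("train_ids\t", paste(model$train_ids, collapse = ",")),
           "gene\tmin\tmax\tbeta")
  mm <- model$minmax[match(model$gene_universe, model$minmax$gene), , drop = FALSE]
  beta <- setNames(numeric(length(model$gene_universe)), model$gene_universe)
  beta[names(model$beta)] <- model$beta
  rows <- paste(mm$gene, num(mm$min), num(mm$max), num(beta), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_diage_model
#' @export
read_diage_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#diage_model")) stop_("not a diage model file: %s", path)
  kv <- strsplit(lines[2:7], "\t", fixed = TRUE)
  vals <- setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  tab <- read.delim(text = paste(lines[-(1:7)], collapse = "\n"),
                    sep = "\t", stringsAsFactors = FALSE)
  beta <- setNames(tab$beta, tab$gene)
  structure(list(
    intercept = as.numeric(vals[["intercept"]]),
    beta = beta[beta != 0],
    minmax = structure(data.frame(gene = tab$gene, min = tab$min, max = tab$max,
                                  degenerate = FALSE, stringsAsFactors = FALSE),
                       class = c("minmax_params", "data.frame")),
    gene_universe = tab$gene,
    alpha = as.numeric(vals[["alpha"]]), lambda = as.numeric(vals[["lambda"]]),
    sex_filter = vals[["sex_filter"]], seed = as.integer(vals[["seed"]]),
    train_ids = strsplit(vals[["train_ids"]], ",", fixed = TRUE)[[1L]],
    cv = NULL
  ), class = "diage_model")
}
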