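test_that("the T_age transform and its inverse are exact", {
  expect_equal(t_age(1), 0)
  expect_equal(t_age(31), 6)
  expect_equal(t_age(9.5), 1.7)
  expect_equal(inverse_t_age(t_age(c(1, 3.5, 45, 60))), c(1, 3.5, 45, 60))
  expect_error(t_age(0.5), "day 1")
})

test_that("min-max normalization maps training values into [0, 1] and flags degenerate genes", {
  m <- tiny_matrix(c(2, 6, 10,
                     5, 5, 5,
                     0, 1, 4), genes = c("a", "const", "c"), samples = c("s1", "s2", "s3"))
  mm <- fit_minmax(m)
  expect_equal(mm$degenerate, c(FALSE, TRUE, FALSE))
  norm <- apply_minmax(m, mm)
  expect_equal(unname(norm["a", ]), c(0, 0.5, 1))
  expect_equal(unname(norm["const", ]), c(0, 0, 0))
  expect_true(all(norm >= 0 & norm <= 1))
  expect_error(fit_minmax(m[, 1, drop = FALSE]), "two samples")
})

test_that("out-of-range values at prediction are counted and clipped", {
  train <- tiny_matrix(c(2, 10), genes = "a", samples = c("s1", "s2"))
  mm <- fit_minmax(train)
  new <- tiny_matrix(c(14, 1), genes = "a", samples = c("n1", "n2"))
  clipped <- apply_minmax(new, mm, clip = TRUE)
  expect_equal(unname(clipped["a", ]), c(1, 0))
  expect_equal(unname(attr(clipped, "n_out_of_range")), c(1, 1))
  raw <- apply_minmax(new, mm, clip = FALSE)
  expect_equal(unname(raw["a", ]), c(1.5, -0.125))
  missing <- tiny_matrix(1:2, genes = "zz", samples = c("n1", "n2"))
  expect_error(apply_minmax(missing, mm), "a")
})

test_that("a noiseless linear cohort is predicted essentially exactly", {
  lc <- linear_cohort()
  # unpenalized fit on the exact-linear genes predicts training ages to 1e-6 days
  mm <- fit_minmax(lc$matrix)
  usable <- mm[!mm$degenerate, ]
  X <- t(apply_minmax(lc$matrix, usable, clip = FALSE))
  fit <- elastic_net_fit(X, lc$t_age, alpha = 0.5, lambda = 0, tol = 1e-13)
  model <- structure(list(intercept = fit$b0, beta = fit$beta[fit$beta != 0],
                          minmax = mm, gene_universe = usable$gene,
                          alpha = 0.5, lambda = 0, sex_filter = "all",
                          seed = 1L, train_ids = colnames(lc$matrix)),
                     class = "diage_model")
  pred <- predict_diage(model, lc$matrix)
  expect_lt(max(abs(pred$predicted_age_days - lc$meta$age_days)), 1e-6)

  # the full pipeline stays essentially exact held out; the residual is the
  # shrinkage bias of the smallest lambda on the CV grid (1e-4 of lambda_max)
  res <- train_diage(lc$matrix, lc$meta, seed = 4, k = 5)
  expect_lte(res$metrics$mae_t_age, 0.05)
  expect_equal(res$metrics$mae_days, 5 * res$metrics$mae_t_age)
  expect_equal(res$metrics$rmse_days, 5 * res$metrics$rmse_t_age)
})

test_that("training hygiene: normalization and penalty come from the training split only", {
  lc <- linear_cohort(n = 50, seed = 21)
  res <- train_diage(lc$matrix, lc$meta, seed = 2, k = 5)
  model <- res$model
  mm_train <- fit_minmax(lc$matrix[, model$train_ids, drop = FALSE])
  expect_equal(model$minmax$min, mm_train$min)
  expect_equal(model$minmax$max, mm_train$max)
  expect_equal(length(model$train_ids), round(0.7 * 50))
  # same seed, same split
  res2 <- train_diage(lc$matrix, lc$meta, seed = 2, k = 5)
  expect_identical(res$model$train_ids, res2$model$train_ids)
  expect_identical(res$metrics, res2$metrics)
})

test_that("predictions are a pure function of the expression column", {
  lc <- linear_cohort(n = 40, seed = 31)
  res <- train_diage(lc$matrix, lc$meta, seed = 3, k = 5)
  dup <- lc$matrix[, c(1, 1, 2), drop = FALSE]
  colnames(dup) <- c("a", "b", "c")
  pred <- predict_diage(res$model, expression_matrix(dup, unit = "raw"))
  expect_equal(pred$predicted_t_age[1], pred$predicted_t_age[2])
  # permuting sample order permutes predictions
  perm <- sample(ncol(lc$matrix))
  p1 <- predict_diage(res$model, lc$matrix)
  p2 <- predict_diage(res$model, lc$matrix[, perm, drop = FALSE])
  expect_equal(p2$predicted_t_age, p1$predicted_t_age[perm])
})

test_that("an all-zero sample predicts the intercept when training minima are zero", {
  m <- tiny_matrix(c(0, 5, 10,
                     0, 2, 8), genes = c("a", "b"), samples = c("s1", "s2", "s3"))
  mm <- fit_minmax(m)
  model <- structure(list(intercept = 1.25, beta = c(a = 2, b = -1),
                          minmax = mm, gene_universe = c("a", "b"),
                          alpha = 0.5, lambda = 0.1, sex_filter = "all",
                          seed = 1L, train_ids = colnames(m)),
                     class = "diage_model")
  zero <- tiny_matrix(c(0, 0), genes = c("a", "b"), samples = "z")
  pred <- predict_diage(model, zero)
  expect_equal(pred$predicted_t_age, 1.25)
  # strongly negative intercepts flag negative-day predictions
  model$intercept <- -2
  expect_warning(pred <- predict_diage(model, zero), "below day 0")
  expect_true(pred$negative_flag)
})

test_that("a sex-filtered model with no signal in that sex cannot beat the mean predictor", {
  set.seed(55)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  sex <- rep(c("female", "male"), length.out = n)
  age <- round(runif(n, 3, 60) * 2) / 2
  t <- (age - 1) / 5
  m <- matrix(exp(rnorm(100 * n, 3, 1)), 100, n,
              dimnames = list(sprintf("g%03d", 1:100), ids))
  m[1:5, sex == "male"] <- outer(1:5, t[sex == "male"])  # signal in males only
  mat <- expression_matrix(m, unit = "raw")
  meta <- meta_for(ids, sex, age)
  res <- train_diage(mat, meta, sex_filter = "female", seed = 6, k = 5)
  ytr <- t_age(meta$age_days[match(res$model$train_ids, meta$sample_id)])
  test_ids <- setdiff(meta$sample_id[meta$sex == "female"], res$model$train_ids)
  yte <- t_age(meta$age_days[match(test_ids, meta$sample_id)])
  mae_const <- mean(abs(yte - mean(ytr)))
  expect_gte(res$metrics$mae_t_age, 0.9 * mae_const)
})

test_that("resampling assessment is deterministic and honest about dispersion", {
  sim <- simulate_cohort(sim_config(n_samples = 80, n_genes = 200,
                                    n_inflammaging = 15, onset_day = 3,
                                    noise_sd = 0.2, seed = 41))
  r1 <- resample_assess(sim$matrix, sim$meta, repeats = 3, seed = 10, k = 5)
  r2 <- resample_assess(sim$matrix, sim$meta, repeats = 3, seed = 10, k = 5)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(nrow(r1$per_repeat), 3L)
  r <- resample_assess(sim$matrix, sim$meta, repeats = 8, seed = 10, k = 5)
  expect_lt(r$summary$mae_t_age["sd"], r$summary$mae_t_age["mean"])
  expect_equal(unname(r$summary$mae_days["mean"]), 5 * unname(r$summary$mae_t_age["mean"]))
})

test_that("doubling the noise degrades the resampled accuracy", {
  mk <- function(noise) simulate_cohort(sim_config(n_samples = 80, n_genes = 200,
                                                   n_inflammaging = 15, onset_day = 3,
                                                   noise_sd = noise, seed = 43))
  lo <- mk(0.15); hi <- mk(0.45)
  m_lo <- resample_assess(lo$matrix, lo$meta, repeats = 5, seed = 20, k = 5)
  m_hi <- resample_assess(hi$matrix, hi$meta, repeats = 5, seed = 20, k = 5)
  expect_gt(unname(m_hi$summary$mae_t_age["mean"]), unname(m_lo$summary$mae_t_age["mean"]))
})

test_that("group comparison is a Welch t-test with sane boundary behavior", {
  same <- compare_diage_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  big <- compare_diage_groups(c(1, 2, 3, 11, 12, 13) + rnorm(6, 0, 1e-4),
                              rep(c("nd", "hfd"), each = 3))
  expect_lt(big$p_value, 0.001)
  expect_error(compare_diage_groups(1:3, c("a", "a", "b")), "at least 2")
  expect_error(compare_diage_groups(1:6, rep("a", 6)), "two levels")
})

test_that("a diet effect planted in females only is detected in females only", {
  # small planted abundance keeps the model's weight on the planted genes
  # themselves, so the intervention acts directly through them
  sim <- simulate_cohort(sim_config(n_samples = 160, n_genes = 300,
                                    n_inflammaging = 20, onset_day = 3,
                                    inflammaging_fold = 8,
                                    special_baseline_scale = 0.1,
                                    noise_sd = 0.2, seed = 47))
  res <- train_diage(sim$matrix, sim$meta, seed = 7, k = 5)
  planted <- sim$truth$genes$gene[sim$truth$genes$group == "inflammaging"]
  # build an intervention cohort: half the samples get an "aging acceleration"
  # of the planted genes equivalent to +10 days, in females only
  k_slope <- log2(8) / (45 - 3)                  # log2 trend per day
  accel <- 2^(10 * k_slope)
  # sexes alternate in the simulated design, so period-4 assignment keeps
  # both diets balanced within each sex
  cond <- rep(c("normal_diet", "normal_diet", "high_fat_diet", "high_fat_diet"),
              length.out = ncol(sim$matrix))
  m2 <- unclass(sim$matrix)
  fem_hfd <- sim$meta$sex == "female" & cond == "high_fat_diet"
  m2[planted, fem_hfd] <- m2[planted, fem_hfd] * accel
  m2 <- sweep(m2, 2, colSums(m2), "/") * 1e6
  pred <- predict_diage(res$model, expression_matrix(m2, unit = "TPM", validate = FALSE))
  # compare age-matched groups (the young stage), as diet studies do:
  # otherwise the groups' own age spread swamps the diet shift
  young <- sim$meta$age_days <= 10
  fem <- sim$meta$sex == "female" & young
  mal <- sim$meta$sex == "male" & young
  res_f <- compare_diage_groups(pred$predicted_age_days[fem], cond[fem])
  res_m <- compare_diage_groups(pred$predicted_age_days[mal], cond[mal])
  expect_lt(res_f$p_value, 0.01)
  expect_gt(res_m$p_value, 0.05)
  expect_gt(res_f$group_means[["high_fat_diet"]], res_f$group_means[["normal_diet"]])
})

test_that("models serialize to text losslessly and byte-stably", {
  lc <- linear_cohort(n = 40, seed = 61)
  model <- train_diage(lc$matrix, lc$meta, seed = 5, k = 5)$model
  p1 <- withr::local_tempfile(fileext = ".diage")
  p2 <- withr::local_tempfile(fileext = ".diage")
  write_diage_model(model, p1)
  back <- read_diage_model(p1)
  write_diage_model(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$beta, model$beta)
  expect_equal(back$lambda, model$lambda)
  pred1 <- predict_diage(model, lc$matrix)
  pred2 <- predict_diage(back, lc$matrix)
  expect_equal(pred1$predicted_t_age, pred2$predicted_t_age)
})

test_that("training validates its inputs", {
  lc <- linear_cohort(n = 40)
  expect_error(train_diage(lc$matrix, lc$meta[1:5, ]), "at least 10 samples")
  expect_error(train_diage(lc$matrix, lc$meta, gene_subset = c("nope1", "nope2")),
               "no genes")
})
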