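# Fixtures built in code: tiny expression matrices and metadata tables used
# across test files.

tiny_matrix <- function(values, genes = NULL, samples = NULL, unit = "raw") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expression_matrix(m, unit = unit)
}

# young/old, two sexes; ages in days
meta_for <- function(sample_ids, sex, age_days, ...) {
  validate_sample_metadata(data.frame(sample_id = sample_ids, sex = sex,
                                      age_days = age_days, ...,
                                      stringsAsFactors = FALSE))
}

# matrix with one gene whose female young/old means are known by construction
# plus a filler gene; samples: 2 young + 2 old per sex
ratio_fixture <- function(young_vals = c(10, 20), old_vals = c(30, 60)) {
  ids <- c("fy1", "fy2", "fo1", "fo2", "my1", "my2", "mo1", "mo2")
  meta <- meta_for(ids,
                   sex = rep(c("female", "male"), each = 4),
                   age_days = rep(c(5, 7, 35, 45), 2))
  m <- tiny_matrix(c(young_vals, old_vals, young_vals, old_vals,
                     rep(1, 8)),
                   genes = c("DptA", "filler"), samples = ids)
  list(matrix = m, meta = meta)
}

# elastic-net objective in the glmnet parameterization
elnet_objective <- function(X, y, b0, beta, alpha, lambda) {
  r <- y - b0 - as.numeric(X %*% beta)
  sum(r^2) / (2 * length(y)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# cohort with genes that are exact linear functions of T_age plus constant
# background genes; no renormalization, no noise
linear_cohort <- function(n = 60, n_signal = 10, n_background = 50, seed = 11) {
  set.seed(seed)
  age <- round(runif(n, 3, 60) * 2) / 2
  t <- (age - 1) / 5
  ids <- sprintf("s%03d", seq_len(n))
  slopes <- seq(0.5, 5, length.out = n_signal)
  intercepts <- seq(1, 10, length.out = n_signal)
  sig <- t(outer(t, slopes) + matrix(intercepts, n, n_signal, byrow = TRUE))
  bg <- matrix(rep(exp(seq(0, 4, length.out = n_background)), n), n_background, n)
  m <- rbind(sig, bg)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_signal + n_background)), ids)
  meta <- meta_for(ids, sex = rep(c("female", "male"), length.out = n), age_days = age)
  list(matrix = expression_matrix(m, unit = "raw"), meta = meta, t_age = t)
}
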