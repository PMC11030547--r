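#' Configuration for a synthetic inflammaging cohort
#'
#' Defines the generative model used by [simulate_cohort()]. The cohort
#' emulates the statistical structure of aging Drosophila bulk RNA-Seq
#' compendia: a young-heavy age distribution (ages 3-60 days), a minority of
#' inflammaging genes whose expression rises multiplicatively with age, a few
#' genes with very high constitutive male expression (reproductive-tract
#' style, which masks whole-body old/young ratios in males), a few genes
#' suppressed in young females (which inflates female ratios), multiplicative
#' log-normal noise, and per-sample renormalization to TPM.
#'
#' Per sample `i` with age `a` and sex `s`, the pre-noise abundance of gene
#' `g` is `base_g * eff_g(a, s)` where:
#' * background genes: `eff = 1`;
#' * inflammaging genes: `eff = trend(a)` with `log2 trend` rising linearly
#'   from 0 at `a <= onset_day` to `log2(fold)` at day 45 (and continuing
#'   linearly beyond);
#' * male-biased genes: females follow `trend(a)` with `male_biased_fold`;
#'   males get an additive constitutive component,
#'   `eff = male_bias_mult - 1 + trend(a)`, so young males express
#'   `male_bias_mult`-fold more than young females while the male old/young
#'   ratio stays near 1 — the constitutive term dominates the denominator;
#' * female-suppressed genes: `eff = trend(a)` (with `female_suppressed_fold`)
#'   times `female_young_mult` for females aged <= 10 days.
#'
#' Noise multiplies each value by `exp(e)`, `e ~ Normal(0, noise_sd^2)`
#' (natural-log scale), and every sample column is then rescaled to sum to
#' 1,000,000 (TPM convention). Ages are drawn from `[3, 10]` with probability
#' `p_young` and from `[11, 60]` otherwise, reported at 0.5-day resolution;
#' sexes alternate female/male for a balanced design.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param p_young probability that a sample's age is drawn uniformly from
#'   3-10 days (otherwise 11-60 days). Default 0.6, a young-heavy skew.
#' @param n_inflammaging,n_male_biased,n_female_suppressed sizes of the
#'   disjoint special gene groups (their union must not exceed `n_genes`).
#' @param inflammaging_fold planted old/young expression ratio at day 45
#'   versus the young stage (> 1). Default 8, a typical strong antimicrobial-
#'   peptide induction.
#' @param onset_day age at which the inflammaging trend starts rising.
#'   Default 20 (inflammaging minimal by day ~30, strong by day 45).
#' @param male_bias_mult constitutive young-male/young-female expression
#'   ratio of male-biased genes (> 1). Default 8.
#' @param male_biased_fold trend fold of male-biased genes; defaults to
#'   `inflammaging_fold` so the masking mechanic is present.
#' @param female_young_mult multiplier (< 1) applied to female-suppressed
#'   genes in females aged <= 10 days. Default 0.2.
#' @param female_suppressed_fold trend fold of female-suppressed genes;
#'   default 1 (flat trend; suppression alone drives their ratio).
#' @param baseline_logmean,baseline_logsd natural-log mean and sd of the
#'   per-gene baseline abundance (log-normal). Defaults 3 and 1.5 span about
#'   four orders of magnitude of TPM, as real transcriptomes do.
#' @param special_baseline_scale multiplier applied to the baselines of the
#'   special gene groups (default 1). Setting it below 1 keeps the special
#'   genes a small fraction of total abundance so that TPM renormalization
#'   perturbs ratios negligibly.
#' @param noise_sd sd of the multiplicative log-normal noise, natural-log
#'   scale. Default 0.2 (about 20% coefficient of variation, typical of bulk
#'   RNA-Seq replicates).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @param group_seed seed for the placement of the special gene groups,
#'   separate from `seed` (default 101). Cohorts drawn with different
#'   `seed`s but the same `group_seed` and group sizes plant the *same*
#'   genes, emulating replicate datasets that share their inflammaging
#'   markers.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 120L, n_genes = 2000L, p_young = 0.6,
                       n_inflammaging = 40L, inflammaging_fold = 8,
                       onset_day = 20, n_male_biased = 5L, male_bias_mult = 8,
                       male_biased_fold = inflammaging_fold,
                       n_female_suppressed = 5L, female_young_mult = 0.2,
                       female_suppressed_fold = 1,
                       baseline_logmean = 3, baseline_logsd = 1.5,
                       special_baseline_scale = 1,
                       noise_sd = 0.2, seed = 1L, group_seed = 101L) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples", 2L),
    n_genes = check_count(n_genes, "n_genes", 1L),
    p_young = check_number(p_young, "p_young"),
    n_inflammaging = check_count(n_inflammaging, "n_inflammaging"),
    inflammaging_fold = check_number(inflammaging_fold, "inflammaging_fold"),
    onset_day = check_number(onset_day, "onset_day", 0),
    n_male_biased = check_count(n_male_biased, "n_male_biased"),
    male_bias_mult = check_number(male_bias_mult, "male_bias_mult", 1),
    male_biased_fold = check_number(male_biased_fold, "male_biased_fold", 1),
    n_female_suppressed = check_count(n_female_suppressed, "n_female_suppressed"),
    female_young_mult = check_number(female_young_mult, "female_young_mult"),
    female_suppressed_fold = check_number(female_suppressed_fold, "female_suppressed_fold", 1),
    baseline_logmean = check_number(baseline_logmean, "baseline_logmean"),
    baseline_logsd = check_number(baseline_logsd, "baseline_logsd", 0),
    special_baseline_scale = check_number(special_baseline_scale, "special_baseline_scale"),
    noise_sd = check_number(noise_sd, "noise_sd", 0),
    seed = check_count(seed, "seed"),
    group_seed = check_count(group_seed, "group_seed")
  )
  if (cfg$p_young <= 0 || cfg$p_young >= 1) stop_("`p_young` must be strictly between 0 and 1")
  if (cfg$inflammaging_fold <= 1) stop_("`inflammaging_fold` must be > 1")
  if (cfg$female_young_mult <= 0 || cfg$female_young_mult >= 1) {
    stop_("`female_young_mult` must be in (0, 1)")
  }
  if (cfg$special_baseline_scale <= 0) stop_("`special_baseline_scale` must be > 0")
  if (cfg$onset_day >= 45) stop_("`onset_day` must be below 45, the day the planted fold is anchored at")
  n_special <- cfg$n_inflammaging + cfg$n_male_biased + cfg$n_female_suppressed
  if (n_special > cfg$n_genes) {
    stop_("special gene groups (%d genes) exceed n_genes (%d)", n_special, cfg$n_genes)
  }
  structure(cfg, class = "sim_config")
}

## trend multiplier at age a for a gene with the given fold and onset:
## log2 trend rises linearly from 0 at a <= onset to log2(fold) at day 45
## and keeps the same slope beyond.
sim_trend <- function(age, fold, onset) {
  2^(pmax(age - onset, 0) * log2(fold) / (45 - onset))
}

## deterministic (noise-free, pre-normalization) effect multiplier of one
## gene group at the given age/sex; baseline cancels out of all ratios.
sim_effect <- function(age, sex, group, cfg) {
  switch(group,
    background = rep(1, length(age)),
    inflammaging = sim_trend(age, cfg$inflammaging_fold, cfg$onset_day),
    male_biased = {
      tr <- sim_trend(age, cfg$male_biased_fold, cfg$onset_day)
      ifelse(sex == "male", cfg$male_bias_mult - 1 + tr, tr)
    },
    female_suppressed = {
      tr <- sim_trend(age, cfg$female_suppressed_fold, cfg$onset_day)
      tr * ifelse(sex == "female" & age <= 10, cfg$female_young_mult, 1)
    },
    stop_("unknown gene group '%s'", group))
}

#' Simulate a synthetic inflammaging cohort with known ground truth
#'
#' Draws a cohort from the generative model described in [sim_config()] and
#' returns the TPM expression matrix, the sample metadata, and the full
#' ground truth (`SimTruth`) that downstream recovery tests use as oracle.
#'
#' @param config a [sim_config()].
#' @return a list of class `diage_sim` with elements `matrix`
#'   (an [expression_matrix()], columns summing to 1e6), `meta` (sample
#'   metadata data.frame), and `truth` (list with per-gene data.frame
#'   `genes`: gene, group, baseline, fold, multiplier; per-sample data.frame
#'   `samples`; and the `config`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    p <- cfg$n_genes
    age <- ifelse(runif(n) < cfg$p_young, runif(n, 3, 10), runif(n, 11, 60))
    age <- round(age * 2) / 2                      # 0.5-day resolution
    sex <- rep(c("female", "male"), length.out = n)
    sample_ids <- sprintf("s%04d", seq_len(n))
    gene_ids <- sprintf("g%04d", seq_len(p))

    group <- rep("background", p)
    n_special <- cfg$n_inflammaging + cfg$n_male_biased + cfg$n_female_suppressed
    special <- with_seed(cfg$group_seed, sample.int(p, n_special))
    idx <- split(special, rep(c("inflammaging", "male_biased", "female_suppressed"),
                              c(cfg$n_inflammaging, cfg$n_male_biased, cfg$n_female_suppressed)))
    for (g in names(idx)) group[idx[[g]]] <- g

    baseline <- exp(rnorm(p, cfg$baseline_logmean, cfg$baseline_logsd))
    baseline[group != "background"] <- baseline[group != "background"] * cfg$special_baseline_scale

    m <- matrix(baseline, nrow = p, ncol = n)
    for (grp in c("inflammaging", "male_biased", "female_suppressed")) {
      rows <- which(group == grp)
      if (length(rows)) {
        eff <- sim_effect(age, sex, grp, cfg)       # length n
        m[rows, ] <- m[rows, ] * matrix(eff, length(rows), n, byrow = TRUE)
      }
    }
    if (cfg$noise_sd > 0) m <- m * exp(matrix(rnorm(p * n, 0, cfg$noise_sd), p, n))
    m <- sweep(m, 2, colSums(m), "/") * 1e6
    dimnames(m) <- list(gene_ids, sample_ids)

    meta <- data.frame(sample_id = sample_ids, sex = sex, age_days = age,
                       tissue = "whole_body", strain = "synthetic",
                       condition = "normal", dataset = "simulated",
                       stringsAsFactors = FALSE)
    fold <- ifelse(group == "inflammaging", cfg$inflammaging_fold,
            ifelse(group == "male_biased", cfg$male_biased_fold,
            ifelse(group == "female_suppressed", cfg$female_suppressed_fold, 1)))
    mult <- ifelse(group == "male_biased", cfg$male_bias_mult,
            ifelse(group == "female_suppressed", cfg$female_young_mult, 1))
    truth <- list(
      genes = data.frame(gene = gene_ids, group = group, baseline = baseline,
                         fold = fold, multiplier = mult, stringsAsFactors = FALSE),
      samples = data.frame(sample_id = sample_ids, age_days = age, sex = sex,
                           stringsAsFactors = FALSE),
      config = cfg)
    structure(list(matrix = expression_matrix(m, unit = "TPM", validate = FALSE),
                   meta = meta, truth = truth),
              class = "diage_sim")
  })
}

#' Closed-form expected AGE-Index of a simulated cohort
#'
#' The noise-free, pre-normalization old/young ratio of every gene: the
#' gene's deterministic effect at `old_day` divided by the mean effect over
#' the simulated samples of the given sex whose age falls in `young_window`.
#' Exact for `noise_sd = 0` cohorts up to the compositional perturbation
#' introduced by per-sample TPM renormalization (small when the special genes
#' are a small fraction of total abundance).
#'
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @param young_window numeric length-2, young age window in days.
#' @param old_day age (days) of the old stage; must exceed the window. May
#'   be a vector of old ages (e.g. the simulated ages of the old samples),
#'   in which case the numerator is the mean effect over those ages,
#'   mirroring how the realized index averages over old samples.
#' @param sex `"female"` or `"male"`.
#' @return named numeric vector of expected ratios, one per gene.
#' @export
expected_age_index <- function(truth, young_window = c(3, 10), old_day = 45,
                               sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (any(old_day <= young_window[2L])) stop_("`old_day` must exceed the young window")
  cfg <- truth$config
  s <- truth$samples
  young_ages <- s$age_days[s$sex == sex &
                           s$age_days >= young_window[1L] &
                           s$age_days <= young_window[2L]]
  if (!length(young_ages)) stop_("no simulated %s samples in the young window", sex)
  groups <- unique(truth$genes$group)
  ratio_by_group <- vapply(groups, function(grp) {
    old_eff <- mean(sim_effect(old_day, rep(sex, length(old_day)), grp, cfg))
    young_eff <- mean(sim_effect(young_ages, rep(sex, length(young_ages)), grp, cfg))
    old_eff / young_eff
  }, numeric(1))
  setNames(ratio_by_group[truth$genes$group], truth$genes$gene)
}

#' @export
print.diage_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Synthetic inflammaging cohort: %d genes x %d samples (seed %d)\n",
              nrow(x$matrix), ncol(x$matrix), cfg$seed))
  cat(sprintf("  gene groups: %s\n",
              paste(sprintf("%s=%d", names(table(x$truth$genes$group)),
                            table(x$truth$genes$group)), collapse = ", ")))
  cat(sprintf("  ages %.1f-%.1f days (median %.1f), noise sd %.2f\n",
              min(x$meta$age_days), max(x$meta$age_days),
              median(x$meta$age_days), cfg$noise_sd))
  invisible(x)
}

#' Write a simulated cohort to TSV files
#'
#' Writes `<prefix>matrix.tsv`, `<prefix>metadata.tsv` and `<prefix>truth.tsv`
#' (the per-gene truth table).
#'
#' @param sim a [simulate_cohort()] result.
#' @param prefix output path prefix.
#' @export
write_cohort <- function(sim, prefix) {
  dir.create(dirname(paste0(prefix, "x")), recursive = TRUE, showWarnings = FALSE)
  write_expression_table(sim$matrix, paste0(prefix, "matrix.tsv"))
  write_sample_metadata(sim$meta, paste0(prefix, "metadata.tsv"))
  write.table(sim$truth$genes, paste0(prefix, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
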