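#' Parameters of the inflammaging pattern classification
#'
#' The shared versus sex-skewed distinction is drawn in the literature as
#' regions of the female-vs-male AGE-Index plane; these parameters make that
#' rule explicit and numeric. `inflammaging_threshold` is the index a gene
#' must reach to count as inflammaging at all (the conventional
#' name-the-gene threshold of 5); a gene is skewed toward one sex when the
#' other sex's index is near 1 (`low_partner_ceiling`) or much lower
#' (`skew_ratio`-fold). The defaults classify the canonical exemplars as
#' described: a 24.8/4.7 female/male pair is female-skewed, a 6/6 pair shared.
#'
#' @param inflammaging_threshold index threshold T (> 1), default 5.
#' @param low_partner_ceiling "close to 1" ceiling L (>= 1) for the other
#'   sex's index, default 2.
#' @param skew_ratio minimum between-sex index ratio R (> 1), default 3.
#' @return a `pattern_params` list.
#' @export
pattern_params <- function(inflammaging_threshold = 5, low_partner_ceiling = 2,
                           skew_ratio = 3) {
  p <- list(inflammaging_threshold = check_number(inflammaging_threshold, "inflammaging_threshold"),
            low_partner_ceiling = check_number(low_partner_ceiling, "low_partner_ceiling"),
            skew_ratio = check_number(skew_ratio, "skew_ratio"))
  if (p$inflammaging_threshold <= 1) stop_("`inflammaging_threshold` must be > 1")
  if (p$low_partner_ceiling < 1) stop_("`low_partner_ceiling` must be >= 1")
  if (p$skew_ratio <= 1) stop_("`skew_ratio` must be > 1")
  structure(p, class = "pattern_params")
}

#' Classify inflammaging patterns from female and male AGE-Index values
#'
#' Applies, in order: (1) `female_skewed` if the female index reaches the
#' inflammaging threshold and the male index is either at most the
#' low-partner ceiling or at least `skew_ratio`-fold lower; (2) `male_skewed`
#' by the mirror rule; (3) `shared` if both sexes reach the threshold;
#' (4) `not_inflammaging` otherwise. Evaluating skew before shared is
#' deliberate: a gene at 30/6 is female-skewed even though both values
#' exceed the threshold.
#'
#' @param female_index,male_index numeric vectors of defined, positive
#'   AGE-Index values (resolve undefined records with a pseudocount first).
#' @param params a [pattern_params()].
#' @return character vector of labels.
#' @export
classify_pattern <- function(female_index, male_index, params = pattern_params()) {
  if (length(female_index) != length(male_index)) stop_("index vectors must have equal length")
  if (anyNA(female_index) || anyNA(male_index)) {
    stop_("undefined AGE-Index value(s); recompute with a pseudocount before classifying")
  }
  if (any(female_index <= 0) || any(male_index <= 0)) stop_("indices must be > 0")
  T_ <- params$inflammaging_threshold
  L <- params$low_partner_ceiling
  R <- params$skew_ratio
  fs <- female_index >= T_ & (male_index <= L | female_index / male_index >= R)
  ms <- male_index >= T_ & (female_index <= L | male_index / female_index >= R)
  sh <- female_index >= T_ & male_index >= T_
  ifelse(fs, "female_skewed",
  ifelse(ms, "male_skewed",
  ifelse(sh, "shared", "not_inflammaging")))
}

#' Classify patterns by joining a female and a male AGE-Index table
#'
#' @param female_table,male_table `age_index_table`s for the two sexes over
#'   the same genes.
#' @param params a [pattern_params()].
#' @return data.frame with columns `gene`, `female_index`, `male_index`,
#'   `label`; the params are recorded in a `provenance` attribute (the
#'   numeric boundaries are this package's operationalization of the
#'   visual rule).
#' @export
classify_patterns <- function(female_table, male_table, params = pattern_params()) {
  common <- intersect(female_table$gene, male_table$gene)
  if (!length(common)) stop_("tables share no genes")
  f <- setNames(female_table$age_index, female_table$gene)[common]
  m <- setNames(male_table$age_index, male_table$gene)[common]
  out <- data.frame(gene = common, female_index = unname(f), male_index = unname(m),
                    label = classify_pattern(unname(f), unname(m), params),
                    stringsAsFactors = FALSE)
  structure(out, provenance = list(params = unclass(params)))
}

#' Per-gene log2 female-to-male expression bias
#'
#' For each gene, `log2((mean_F + e) / (mean_M + e))` over the samples whose
#' age falls in `age_window`, where the means are taken across female and
#' male samples respectively. A strictly positive pseudocount is required
#' because tissue-level datasets contain exact zeros. Negative values mean
#' male-biased expression (a constitutively male gene at 8-fold gives -3).
#'
#' @param matrix an [expression_matrix()].
#' @param meta sample metadata.
#' @param age_window length-2 numeric window in days, default `c(3, 10)`.
#' @param pseudocount pseudocount e > 0 in expression units, default 0.5.
#' @return data.frame with columns `gene`, `mean_female`, `mean_male`,
#'   `log2_ratio`; window and pseudocount recorded as attributes.
#' @export
sex_bias_log2 <- function(matrix, meta, age_window = c(3, 10), pseudocount = 0.5) {
  pseudocount <- check_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) stop_("`pseudocount` must be > 0")
  al <- align_samples(matrix, meta)
  matrix <- al$matrix; meta <- al$meta
  inwin <- meta$age_days >= age_window[1L] & meta$age_days <= age_window[2L]
  fem <- meta$sample_id[inwin & meta$sex == "female"]
  mal <- meta$sample_id[inwin & meta$sex == "male"]
  if (!length(fem)) stop_("no female samples in the age window [%g, %g]", age_window[1L], age_window[2L])
  if (!length(mal)) stop_("no male samples in the age window [%g, %g]", age_window[1L], age_window[2L])
  mf <- rowMeans(matrix[, fem, drop = FALSE])
  mm <- rowMeans(matrix[, mal, drop = FALSE])
  out <- data.frame(gene = rownames(matrix), mean_female = mf, mean_male = mm,
                    log2_ratio = log2((mf + pseudocount) / (mm + pseudocount)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, age_window = age_window, pseudocount = pseudocount)
}
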