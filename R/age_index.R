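#' Compute the AGE-Index per gene for one sex
#'
#' The AGE-Index of a gene is the ratio of its mean expression in old samples
#' (by convention 30+ days post-eclosion) to its mean expression in young
#' samples (3-10 days), computed separately for each sex because several
#' innate-immune genes differ strongly between male and female adults. It is
#' conceptually a fold change, and is scale-free: any common rescaling of the
#' selected samples cancels.
#'
#' Zero handling: with `pseudocount = 0` (the default) a gene whose young
#' mean is exactly 0 gets `defined = FALSE` and an `NA` index rather than a
#' silently clamped value, preserving genuinely extreme ratios; with
#' `pseudocount = e > 0` the index is `(old_mean + e) / (young_mean + e)`.
#'
#' @param matrix an [expression_matrix()] (genes x samples).
#' @param meta sample metadata (see [read_sample_metadata()]); only samples
#'   present in both inputs are used.
#' @param sex `"female"` or `"male"`. Mixed or unknown-sex samples are always
#'   excluded; requesting them is an error because the index is only defined
#'   per sex.
#' @param young length-2 numeric, the young window in days (inclusive).
#'   Default `c(3, 10)`; some studies use the narrower 3-7 days.
#' @param old either a single number interpreted per `old_mode`, or a vector
#'   of explicit old ages.
#' @param old_mode `"min"` (default): old samples are those aged `>= old[1]`
#'   days; `"exact"`: old samples are those whose age matches an element of
#'   `old`.
#' @param pseudocount non-negative pseudocount added to both means.
#' @param line_col optional name of a metadata column identifying replicate
#'   lines; when given, the index is computed per line and then averaged
#'   across lines (as done for multi-line selection experiments), instead of
#'   pooling all samples.
#' @param dataset label recorded in the table's provenance.
#' @return a data.frame of class `age_index_table` with columns `gene`,
#'   `sex`, `young_mean`, `old_mean`, `n_young`, `n_old`, `age_index`,
#'   `defined`, and a `provenance` attribute.
#' @export
compute_age_index <- function(matrix, meta, sex, young = c(3, 10), old = 30,
                              old_mode = c("min", "exact"), pseudocount = 0,
                              line_col = NULL, dataset = "default") {
  old_mode <- match.arg(old_mode)
  if (!sex %in% c("female", "male")) {
    stop_("the AGE-Index is always calculated separately for males and females; `sex` must be 'female' or 'male', got '%s'", sex)
  }
  pseudocount <- check_number(pseudocount, "pseudocount", 0)
  if (length(young) != 2L || young[1L] > young[2L]) stop_("`young` must be an increasing length-2 window")
  al <- align_samples(matrix, meta)
  matrix <- al$matrix; meta <- al$meta
  meta <- meta[meta$sex == sex, , drop = FALSE]
  if (!nrow(meta)) stop_("no %s samples available", sex)
  is_young <- meta$age_days >= young[1L] & meta$age_days <= young[2L]
  is_old <- if (old_mode == "min") meta$age_days >= old[1L] else meta$age_days %in% old
  if (!any(is_young)) stop_("no %s samples in the young window [%g, %g] days", sex, young[1L], young[2L])
  if (!any(is_old)) {
    stop_("no %s samples in the old window (%s %s days)", sex,
          if (old_mode == "min") ">=" else "age in", paste(old, collapse = ", "))
  }

  one_stratum <- function(ids_young, ids_old) {
    ym <- rowMeans(matrix[, ids_young, drop = FALSE])
    om <- rowMeans(matrix[, ids_old, drop = FALSE])
    defined <- pseudocount > 0 | ym > 0
    idx <- ifelse(defined, (om + pseudocount) / (ym + pseudocount), NA_real_)
    list(young_mean = ym, old_mean = om, age_index = idx, defined = defined)
  }

  if (is.null(line_col)) {
    st <- one_stratum(meta$sample_id[is_young], meta$sample_id[is_old])
    aggregation <- "pooled"
  } else {
    if (is.null(meta[[line_col]])) stop_("metadata has no column '%s'", line_col)
    lines <- unique(meta[[line_col]])
    per_line <- lapply(lines, function(l) {
      sel <- meta[[line_col]] == l
      if (!any(sel & is_young) || !any(sel & is_old)) return(NULL)
      one_stratum(meta$sample_id[sel & is_young], meta$sample_id[sel & is_old])
    })
    per_line <- Filter(Negate(is.null), per_line)
    if (!length(per_line)) stop_("no line has samples in both age windows")
    avg <- function(field) rowMeans(do.call(cbind, lapply(per_line, `[[`, field)))
    defined <- Reduce(`&`, lapply(per_line, `[[`, "defined"))
    idx <- rowMeans(do.call(cbind, lapply(per_line, `[[`, "age_index")))
    st <- list(young_mean = avg("young_mean"), old_mean = avg("old_mean"),
               age_index = ifelse(defined, idx, NA_real_), defined = defined)
    aggregation <- sprintf("per-line mean over %d lines", length(per_line))
  }

  out <- data.frame(gene = rownames(matrix), sex = sex,
                    young_mean = st$young_mean, old_mean = st$old_mean,
                    n_young = sum(is_young), n_old = sum(is_old),
                    age_index = st$age_index, defined = st$defined,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out,
            provenance = list(dataset = dataset, young_window = young,
                              old = old, old_mode = old_mode,
                              pseudocount = pseudocount,
                              aggregation = aggregation,
                              transformed = "none"),
            class = c("age_index_table", "data.frame"))
}

#' Rank the top inflammaging markers of an AGE-Index table
#'
#' Genes are sorted by descending AGE-Index (undefined records excluded),
#' ties broken lexicographically by gene id, and the list truncated to `n` —
#' the "top 12 with the highest AGE-Index" style ranking.
#'
#' @param table an `age_index_table`.
#' @param n number of genes to return.
#' @param restrict_to optional character vector (or single gene set) to
#'   restrict the ranking to, e.g. an immune-defense list.
#' @return character vector of gene ids, best first.
#' @export
rank_top_markers <- function(table, n = 12L, restrict_to = NULL) {
  n <- check_count(n, "n")
  if (n <= 0L) stop_("`n` must be positive")
  tab <- table[table$defined & !is.na(table$age_index), , drop = FALSE]
  if (!is.null(restrict_to)) {
    restrict_to <- unlist(restrict_to, use.names = FALSE)
    tab <- tab[tab$gene %in% restrict_to, , drop = FALSE]
  }
  ord <- order(-tab$age_index, tab$gene)
  head(tab$gene[ord], n)
}

#' Intersect inflammaging markers across datasets
#'
#' Returns the genes whose AGE-Index reaches `threshold` in at least
#' `min_datasets` of the supplied tables, sorted by the number of supporting
#' datasets and then by mean index — the cross-dataset "shared core" of
#' inflammaging markers.
#'
#' @param tables a named list of `age_index_table`s (>= 2), one per dataset.
#' @param threshold AGE-Index threshold (default 5).
#' @param min_datasets minimum number of supporting datasets.
#' @return data.frame with columns `gene`, `n_datasets`, `mean_index`, and
#'   one index column per dataset.
#' @export
shared_markers <- function(tables, threshold = 5, min_datasets = 2L) {
  if (length(tables) < 2L) stop_("need at least two AGE-Index tables")
  min_datasets <- check_count(min_datasets, "min_datasets", 1L)
  if (min_datasets > length(tables)) {
    stop_("min_datasets (%d) exceeds the number of tables (%d)", min_datasets, length(tables))
  }
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  idx <- vapply(tables, function(t) {
    v <- setNames(t$age_index, t$gene)[genes]
    unname(v)
  }, numeric(length(genes)))
  idx <- matrix(idx, nrow = length(genes),
                dimnames = list(genes, names(tables)))
  support <- rowSums(!is.na(idx) & idx >= threshold)
  keep <- support >= min_datasets
  out <- data.frame(gene = genes[keep], n_datasets = support[keep],
                    mean_index = rowMeans(idx, na.rm = TRUE)[keep],
                    idx[keep, , drop = FALSE],
                    row.names = NULL, stringsAsFactors = FALSE, check.names = FALSE)
  out[order(-out$n_datasets, -out$mean_index, out$gene), , drop = FALSE]
}

#' Log2-transform an AGE-Index table
#'
#' Replaces every index by its log2, as done when plotting wide-range index
#' distributions; genes with decreased old-age expression become negative.
#' All indices must be defined and strictly positive.
#'
#' @param table an `age_index_table`.
#' @return the table with `age_index <- log2(age_index)` and provenance
#'   noting the transformation.
#' @export
log2_table <- function(table) {
  if (any(!table$defined) || any(is.na(table$age_index))) {
    stop_("cannot log2-transform: %d undefined index record(s); use a pseudocount first",
          sum(!table$defined | is.na(table$age_index)))
  }
  if (any(table$age_index <= 0)) stop_("cannot log2-transform non-positive indices")
  prov <- attr(table, "provenance")
  prov$transformed <- "log2"
  table$age_index <- log2(table$age_index)
  structure(table, provenance = prov, class = class(table))
}

#' Write or read an AGE-Index table as TSV
#' @param table an `age_index_table`.
#' @param path file path.
#' @export
write_age_index <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_age_index
#' @export
read_age_index <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  structure(df, class = c("age_index_table", "data.frame"))
}
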