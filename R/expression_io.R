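#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique gene identifiers
#' as row names, unique sample identifiers as column names, and non-negative
#' finite values. The expression unit (TPM by convention) is carried as an
#' attribute and is metadata, not enforced arithmetic: every downstream ratio
#' statistic is scale-free. When the declared unit is `"TPM"`, columns whose
#' sums deviate from 1,000,000 by more than 1% trigger a validation warning
#' (not an error, since subset matrices are legal).
#'
#' @param values numeric matrix, genes as rows, samples as columns, with
#'   row and column names set.
#' @param unit expression unit label, default `"TPM"`.
#' @param validate run [validate_expression_matrix()]? Default `TRUE`.
#' @return the matrix with the `unit` attribute set.
#' @export
expression_matrix <- function(values, unit = "TPM", validate = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_("`values` must be a numeric matrix")
  }
  attr(values, "unit") <- as.character(unit)[1L]
  if (validate) validate_expression_matrix(values)
  values
}

#' @rdname expression_matrix
#' @param x an expression matrix.
#' @export
validate_expression_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_("expression matrix must have gene row names and sample column names")
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) stop_("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) stop_("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(x))
    stop_("negative or non-finite value at gene '%s', sample '%s'",
          rownames(x)[i[1L]], colnames(x)[i[2L]])
  }
  if (identical(attr(x, "unit"), "TPM") && ncol(x) > 0L) {
    cs <- colSums(x)
    off <- abs(cs - 1e6) > 0.01 * 1e6
    if (any(off)) {
      warning(sprintf(
        "%d sample column(s) sum to values more than 1%% away from 1,000,000 (e.g. '%s': %.1f); matrix may be a subset",
        sum(off), colnames(x)[which(off)[1L]], cs[which(off)[1L]]), call. = FALSE)
    }
  }
  invisible(x)
}

#' Read or write a gene-by-sample expression table
#'
#' Tab-separated text, UTF-8, "." decimal separator: first column gene id,
#' header row of sample ids. This single dialect is used everywhere so that
#' write-then-read is the identity.
#'
#' @param path file path.
#' @param unit expression unit recorded on the matrix, default `"TPM"`.
#' @return `read_expression_table()`: an [expression_matrix()].
#' @export
read_expression_table <- function(path, unit = "TPM") {
  if (!file.exists(path)) stop_("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) stop_("empty expression table: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_("expression table needs a gene id column plus >=1 sample column")
  genes <- as.character(df[[1L]])
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop_("non-numeric value at row %d, column '%s'", bad, names(vals)[j])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop_("negative value at gene '%s', sample '%s'",
          genes[neg[1L, 1L]], colnames(m)[neg[1L, 2L]])
  }
  expression_matrix(m, unit = unit)
}

#' @rdname read_expression_table
#' @param x an expression matrix.
#' @export
write_expression_table <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated text with required columns `sample_id`, `sex`, `age_days`;
#' optional `tissue`, `strain`, `condition`, `dataset` (and any extra columns,
#' which are preserved). Missing optional columns are filled with defaults
#' `tissue = "whole_body"`, `strain = "unknown"`, `condition = "normal"`,
#' `dataset = "default"`. Sex must be one of `female`, `male`, `mixed`,
#' `unknown`; ages are days post-eclosion with eclosion = day 1, so
#' `age_days >= 1`.
#'
#' @param path file path.
#' @return a data.frame of sample records.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param meta a data.frame of sample records.
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "sex", "age_days")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_("metadata is missing required column(s): %s", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) stop_("sample_id collision: %s", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(meta$sex), SEX_LEVELS)
  if (length(bad)) {
    stop_("invalid sex value(s) %s; allowed: %s",
          paste(sQuote(bad), collapse = ", "), paste(SEX_LEVELS, collapse = ", "))
  }
  meta$age_days <- as.numeric(meta$age_days)
  if (anyNA(meta$age_days)) stop_("non-numeric age_days")
  if (any(meta$age_days < 1)) {
    stop_("age_days < 1 for sample(s) %s (ages are days post-eclosion, eclosion = day 1)",
          paste(meta$sample_id[meta$age_days < 1], collapse = ", "))
  }
  defaults <- c(tissue = "whole_body", strain = "unknown",
                condition = "normal", dataset = "default")
  for (col in names(defaults)) {
    if (is.null(meta[[col]])) meta[[col]] <- defaults[[col]]
  }
  meta
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix and metadata to their common samples
#'
#' Both inputs are restricted to the intersection of their sample ids,
#' preserving each side's original order. The numbers of samples dropped from
#' each side are returned alongside.
#'
#' @param matrix an expression matrix.
#' @param meta a sample metadata data.frame.
#' @return a list with elements `matrix`, `meta`, `n_dropped_matrix`,
#'   `n_dropped_meta`.
#' @export
align_samples <- function(matrix, meta) {
  meta <- validate_sample_metadata(meta)
  common <- intersect(colnames(matrix), meta$sample_id)
  if (!length(common)) stop_("no samples in common between matrix and metadata")
  keep_m <- colnames(matrix) %in% common
  keep_s <- meta$sample_id %in% common
  out_m <- matrix[, keep_m, drop = FALSE]
  attr(out_m, "unit") <- attr(matrix, "unit")
  list(matrix = out_m,
       meta = meta[keep_s, , drop = FALSE],
       n_dropped_matrix = sum(!keep_m),
       n_dropped_meta = sum(!keep_s))
}

#' Read gene sets
#'
#' Two plain-text formats are accepted and auto-detected per line count of
#' tab-separated fields:
#' * GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`;
#' * one gene id per line: the whole file is a single set named after the
#'   file (or `name` if given). Lines of the form `gene<TAB>set` assign each
#'   gene to the named set.
#'
#' @param path file path.
#' @param name set name used for one-gene-per-line files; defaults to the
#'   file base name.
#' @return a named list of unique character vectors.
#' @export
read_gene_sets <- function(path, name = NULL) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_("empty gene-set file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (all(nf >= 3L)) {                      # GMT
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, "", 1L)
  } else if (all(nf == 2L)) {               # gene<TAB>set
    g <- vapply(parts, `[[`, "", 1L)
    s <- vapply(parts, `[[`, "", 2L)
    sets <- lapply(split(g, s), unique)
  } else if (all(nf == 1L)) {               # one gene per line
    sets <- list(unique(trimws(lines)))
    names(sets) <- name %||% sub("\\.[^.]*$", "", basename(path))
  } else {
    stop_("cannot detect gene-set format of %s (mixed field counts)", path)
  }
  if (any(!lengths(sets))) stop_("empty gene set in %s", path)
  sets
}
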