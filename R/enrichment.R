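#' Gene-set over-representation by the hypergeometric test
#'
#' For each set, counts the overlap `k` between the selected genes (e.g. the
#' positive-coefficient genes of a fitted clock) and the set restricted to
#' the universe, and computes the one-sided over-representation p-value
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with universe size `N`, set
#' size `K` and selection size `n`, followed by Benjamini-Hochberg
#' adjustment across the tested sets.
#'
#' @param selected character vector of selected genes; must be a subset of
#'   `universe`.
#' @param sets named list of character vectors (see [read_gene_sets()]).
#' @param universe character vector of background genes (typically the
#'   model's gene universe).
#' @return data.frame: `set`, `overlap` (k), `selected_size` (n),
#'   `set_size` (K, within universe), `universe_size` (N), `p_value`,
#'   `q_value`.
#' @export
hypergeometric_enrichment <- function(selected, sets, universe) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (!length(universe)) stop_("empty universe")
  if (!length(selected)) stop_("empty selected gene list")
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stop_("%d selected gene(s) are not in the universe (e.g. %s)",
          length(extra), paste(head(extra, 3L), collapse = ", "))
  }
  if (!length(sets)) stop_("no gene sets supplied")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  N <- length(universe)
  n <- length(selected)
  res <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], selected))
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, selected_size = n, set_size = K,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set), , drop = FALSE]
}

#' Split model coefficients by sign for enrichment
#'
#' Convenience accessor returning the positive- and negative-coefficient
#' gene lists of a fitted clock, the inputs usually tested for
#' over-representation against immune-process sets.
#'
#' @param model a `diage_model`.
#' @return list with elements `positive` and `negative`.
#' @export
coefficient_sign_lists <- function(model) {
  list(positive = names(model$beta)[model$beta > 0],
       negative = names(model$beta)[model$beta < 0])
}
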