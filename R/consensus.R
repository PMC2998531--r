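#' Percentile ranks of prediction scores
#'
#' Ranks each score within the evaluated set after orientation (rank 1 =
#' best prediction), with average ranks on ties, and divides by the number of
#' scores. The result lies in (0, 1], is invariant under monotone transforms
#' of the raw scores, and is the unit in which methods are combined by the
#' consensus.
#'
#' @param scores Numeric scores.
#' @param orientation `"lower"` (default) when smaller raw scores are better.
#' @return Numeric vector of rank fractions in (0, 1].
#' @examples
#' percentile_rank(c(10, 100, 1000))      # 1/3, 2/3, 1
#' percentile_rank(c(5, 5, 5))            # all (n+1)/(2n) = 2/3
#' @export
percentile_rank <- function(scores, orientation = c("lower", "higher")) {
  s <- -orient_scores(scores, orientation)  # smaller = better after this
  rank(s) / length(s)
}

check_method_scores <- function(method_scores) {
  need <- c("sequence", "method", "score")
  if (!all(need %in% names(method_scores))) {
    stop("method scores need columns sequence, method, score", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(method_scores[, need], names_from = "method",
                             values_from = "score")
  if (anyNA(wide)) {
    stop("every method must score every peptide exactly once", call. = FALSE)
  }
  wide
}

#' Median-rank consensus prediction
#'
#' Combines two or more prediction methods by converting each method's scores
#' to percentile ranks within the evaluated peptide set and scoring each
#' peptide by the median of its per-method ranks (mean of the two central
#' values for an even method count). Lower consensus scores are better. The
#' result is invariant to monotone rescaling of any member method and to the
#' order in which methods are listed.
#'
#' @param method_scores Long tibble with columns `sequence`, `method`,
#'   `score`: one row per (peptide, method), every method covering the same
#'   peptide list.
#' @param orientation Single orientation for all methods, or a named vector
#'   keyed by method name (`"lower"` = smaller raw score is better).
#' @return Tibble with `sequence`, `method = "consensus"`, `score` (the
#'   median percentile rank) and `n_methods`.
#' @export
median_rank_consensus <- function(method_scores, orientation = "lower") {
  wide <- check_method_scores(method_scores)
  methods <- setdiff(names(wide), "sequence")
  if (length(methods) < 2L) {
    stop("consensus needs at least 2 methods", call. = FALSE)
  }
  ranks <- vapply(methods, function(m) {
    ori <- if (length(orientation) == 1L) orientation else orientation[[m]]
    percentile_rank(wide[[m]], ori)
  }, numeric(nrow(wide)))
  tibble::tibble(sequence = wide$sequence, method = "consensus",
                 score = apply(ranks, 1, median),
                 n_methods = length(methods))
}

#' Leave-one-out contribution of each method to a consensus
#'
#' Recomputes the median-rank consensus with each member method removed in
#' turn and reports the AUC of every reduced consensus next to the
#' full-consensus baseline, identifying methods whose removal helps or hurts.
#'
#' @inheritParams median_rank_consensus
#' @param labels Tibble with columns `sequence` and `binder`, or a logical
#'   vector aligned with the distinct peptides of `method_scores`.
#' @return Tibble with `method_removed` (`"none"` for the full consensus),
#'   `n_methods` and `auc`.
#' @export
leave_one_out_consensus <- function(method_scores, labels,
                                    orientation = "lower") {
  wide <- check_method_scores(method_scores)
  methods <- setdiff(names(wide), "sequence")
  if (length(methods) < 3L) {
    stop("leave-one-out needs at least 3 methods", call. = FALSE)
  }
  if (is.data.frame(labels)) {
    labels <- labels$binder[match(wide$sequence, labels$sequence)]
  }
  one <- function(drop) {
    keep <- method_scores$method != drop
    cons <- median_rank_consensus(method_scores[keep, , drop = FALSE],
                                  orientation)
    lab <- labels[match(cons$sequence, wide$sequence)]
    tibble::tibble(method_removed = if (nzchar(drop)) drop else "none",
                   n_methods = cons$n_methods[1],
                   auc = roc_auc(cons$score, lab, "lower")$auc)
  }
  dplyr::bind_rows(lapply(c("", methods), one))
}

#' Consensus over a selected method subset with per-allele fallback
#'
#' Restricts the consensus to a primary method list (e.g. the three
#' strongest), substituting fallback methods, in order, for alleles where a
#' primary is unavailable. With an `allele` column present the substitution
#' is applied independently per allele; otherwise the table is treated as one
#' allele.
#'
#' @inheritParams median_rank_consensus
#' @param primary Character vector of preferred method names.
#' @param fallback Character vector of substitute method names, tried in
#'   order, for each missing primary.
#' @return Tibble as [median_rank_consensus()], plus `allele` when grouped,
#'   and a `methods_used` attribute naming the members chosen per allele.
#' @export
subset_consensus <- function(method_scores, primary, fallback = character(),
                             orientation = "lower") {
  groups <- if ("allele" %in% names(method_scores)) {
    split(method_scores, method_scores$allele)
  } else {
    list(method_scores)
  }
  used <- list()
  out <- lapply(groups, function(g) {
    avail <- unique(g$method[!is.na(g$score)])
    chosen <- intersect(primary, avail)
    missing_n <- length(primary) - length(chosen)
    if (missing_n > 0L) {
      subs <- setdiff(intersect(fallback, avail), chosen)
      chosen <- c(chosen, head(subs, missing_n))
    }
    if (length(chosen) < 2L) {
      stop("no valid method subset for allele ",
           if ("allele" %in% names(g)) g$allele[1] else "<unnamed>",
           call. = FALSE)
    }
    used[[length(used) + 1L]] <<- chosen
    cons <- median_rank_consensus(g[g$method %in% chosen, , drop = FALSE],
                                  orientation)
    if ("allele" %in% names(g)) cons$allele <- g$allele[1]
    cons
  })
  res <- dplyr::bind_rows(out)
  names(used) <- names(groups)
  attr(res, "methods_used") <- used
  res
}
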