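#' Peptide sequence similarity
#'
#' Two peptides are *similar* when they share an identical contiguous 9-mer
#' subsequence, or when their best ungapped alignment exceeds 80% sequence
#' identity. Identity is computed over all ungapped relative offsets with at
#' least one aligned residue: with `M` the maximum number of identical aligned
#' residues over all offsets, identity is `M / min(L1, L2)`. The threshold is
#' strict (`> 0.80`), so two 15-mers differing at exactly 3 positions
#' (identity 0.80) are not similar by the identity condition.
#'
#' @param p1,p2 Character vectors of peptide sequences (recycled to a common
#'   length).
#' @param identity_threshold Strict identity threshold, default 0.8.
#' @return `ungapped_identity()`: numeric in \[0, 1\]; `shares_9mer()` and
#'   `is_similar()`: logical. All are symmetric in their arguments.
#' @examples
#' ungapped_identity("ACDEFGHIKLMNPQR", "ACDEFGHIKLMNPQW")  # 14/15
#' shares_9mer("ACDEFGHIKLMNPQR", "GGEFGHIKLMNGGGG")        # shared EFGHIKLMN
#' is_similar("AAAAAAAAAAAAAAA", "KKKKKKKKKKKKKKK")
#' @export
ungapped_identity <- function(p1, p2) {
  check_pep <- function(p) {
    if (any(!nzchar(p))) stop("peptides must be non-empty", call. = FALSE)
  }
  check_pep(p1); check_pep(p2)
  mapply(cpp_ungapped_identity, p1, p2, USE.NAMES = FALSE)
}

#' @rdname ungapped_identity
#' @export
shares_9mer <- function(p1, p2) {
  mapply(cpp_shares_9mer, p1, p2, USE.NAMES = FALSE)
}

#' @rdname ungapped_identity
#' @export
is_similar <- function(p1, p2, identity_threshold = 0.8) {
  mapply(cpp_is_similar, p1, p2,
         MoreArgs = list(threshold = identity_threshold), USE.NAMES = FALSE)
}

#' All similar pairs within a peptide list
#'
#' @param peptides Character vector of peptides.
#' @param identity_threshold Strict identity threshold, default 0.8.
#' @return Tibble with integer columns `i`, `j` (`i < j`, positions in
#'   `peptides`) listing every similar unordered pair.
#' @export
similar_pairs <- function(peptides, identity_threshold = 0.8) {
  m <- cpp_similar_pairs(as.character(peptides), identity_threshold)
  tibble::tibble(i = m[, 1], j = m[, 2])
}

#' Count similar partners per peptide
#'
#' For each peptide, the number of *other* peptides in the list similar to it
#' (the `N_similarity` statistic driving Hobohm ordering). Identical peptides
#' count each other, so `k` copies of one sequence each count `k - 1`.
#'
#' @inheritParams similar_pairs
#' @return Integer vector aligned with `peptides`.
#' @export
count_similar <- function(peptides, identity_threshold = 0.8) {
  n <- length(peptides)
  pr <- similar_pairs(peptides, identity_threshold)
  tabulate(c(pr$i, pr$j), nbins = n)
}

new_reduction_result <- function(peptides, kept_idx, counts, algorithm,
                                 seed = NULL) {
  kept_idx <- sort(kept_idx)
  structure(list(
    kept = peptides[kept_idx],
    discarded = peptides[setdiff(seq_along(peptides), kept_idx)],
    kept_index = kept_idx,
    counts = counts,
    algorithm = algorithm,
    seed = seed
  ), class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("<reduction_result>", x$algorithm, "- kept", length(x$kept), "of",
      length(x$kept) + length(x$discarded), "peptides\n")
  invisible(x)
}

#' @describeIn hobohm_reduce One row per input peptide with its similarity
#'   count and kept/discarded status.
#' @param x A `reduction_result`.
#' @param ... Unused.
#' @export
tidy.reduction_result <- function(x, ...) {
  n <- length(x$counts)
  peptides <- character(n)
  peptides[x$kept_index] <- x$kept
  peptides[setdiff(seq_len(n), x$kept_index)] <- x$discarded
  tibble::tibble(peptide = peptides, n_similar = x$counts,
                 kept = seq_len(n) %in% x$kept_index)
}

#' Deterministic forward Hobohm-1 redundancy reduction
#'
#' Records each peptide's number of similar partners (`N_similarity`), sorts
#' the list by that count ascending (ties broken by lexicographic sequence
#' order, then input order), and then runs the forward selection: starting
#' from an empty kept set, each peptide is taken off the top of the sorted
#' list and kept if and only if it is not similar to any already-kept peptide.
#' The kept set is independent (no similar pair within it), maximal (every
#' discarded peptide is similar to a kept one), and deterministic across runs.
#'
#' @param peptides Character vector of peptides, order-stable.
#' @param identity_threshold Strict identity threshold, default 0.8.
#' @param counts Optional pre-computed `N_similarity` vector to use for the
#'   ordering (e.g. counts taken over a larger set); defaults to counts
#'   within `peptides`.
#' @return A `reduction_result`: kept and discarded peptides (input order),
#'   similarity counts, and the algorithm tag.
#' @export
hobohm_reduce <- function(peptides, identity_threshold = 0.8, counts = NULL) {
  peptides <- as.character(peptides)
  n <- length(peptides)
  if (is.null(counts)) counts <- count_similar(peptides, identity_threshold)
  stopifnot(length(counts) == n)
  if (n == 0L) return(new_reduction_result(peptides, integer(0), counts,
                                           "forward_hobohm"))
  pr <- similar_pairs(peptides, identity_threshold)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(pr))) {
    nbr[[pr$i[k]]] <- c(nbr[[pr$i[k]]], pr$j[k])
    nbr[[pr$j[k]]] <- c(nbr[[pr$j[k]]], pr$i[k])
  }
  # radix order: locale-independent lexicographic tie-break, then input order
  ord <- order(counts, peptides, seq_len(n), method = "radix")
  kept <- logical(n)
  for (idx in ord) {
    if (!any(kept[nbr[[idx]]])) kept[idx] <- TRUE
  }
  new_reduction_result(peptides, which(kept), counts, "forward_hobohm")
}

#' Seed-dependent random-removal redundancy reduction
#'
#' Comparator for [hobohm_reduce()] replicating an order-undefined removal
#' strategy: the peptide list is shuffled with the seed, similar pairs are
#' visited in that order, and the later member of each still-alive similar
#' pair is removed until no similar pair remains. Different seeds can keep
#' different numbers of peptides; that instability is the point of the
#' comparison.
#'
#' @inheritParams hobohm_reduce
#' @param seed Integer seed controlling the shuffle.
#' @return A `reduction_result` with algorithm `"random_removal"`.
#' @export
random_reduce <- function(peptides, seed, identity_threshold = 0.8) {
  peptides <- as.character(peptides)
  n <- length(peptides)
  counts <- count_similar(peptides, identity_threshold)
  if (n == 0L) return(new_reduction_result(peptides, integer(0), counts,
                                           "random_removal", seed))
  pr <- similar_pairs(peptides, identity_threshold)
  simkey <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(nrow(pr))) {
    assign(paste(pr$i[k], pr$j[k]), TRUE, envir = simkey)
  }
  o <- with_seed(seed, sample.int(n))
  alive <- rep(TRUE, n)
  for (a in seq_len(n - 1L)) {
    if (!alive[o[a]]) next
    for (b in seq((a + 1L), n)) {
      if (!alive[o[b]]) next
      key <- paste(min(o[a], o[b]), max(o[a], o[b]))
      if (!is.null(simkey[[key]])) alive[o[b]] <- FALSE
    }
  }
  new_reduction_result(peptides, which(alive), counts, "random_removal", seed)
}

#' Build the ALL / SR / SP dataset hierarchy for an affinity table
#'
#' Partitions each allele's peptides into binders and non-binders at the
#' 1000 nM cutoff, reduces each partition independently with the forward
#' Hobohm-1 algorithm, and recombines them into the similarity-reduced (SR)
#' set, preserving the original row order. Singular peptides (SP) are those
#' with no similar partner anywhere in the allele's full (ALL) set, so
#' SP is a subset of SR which is a subset of ALL. Similar pairs straddling the
#' binder/non-binder boundary may survive in SR by construction.
#'
#' @param data Affinity tibble with columns `allele`, `sequence`, `ic50`,
#'   `binder` (see [affinity_table()]).
#' @param scope Where `N_similarity` used for the Hobohm ordering is counted:
#'   within each binder/non-binder `"partition"` (default) or across the
#'   whole per-allele `"dataset"`.
#' @param identity_threshold Strict identity threshold, default 0.8.
#' @return The input tibble with added columns `n_similar_all` (similar
#'   partners within the allele's ALL set), `in_sr` and `in_sp` (logical set
#'   membership).
#' @examples
#' d <- affinity_table("X", c("ACDEFGHIKLMNPQR", "CCDEFGHIKLMNPQR",
#'                            "WYWYWYWYWYWYWYW"), c(10, 20, 5000))
#' similarity_reduce(d)
#' @export
similarity_reduce <- function(data, scope = c("partition", "dataset"),
                              identity_threshold = 0.8) {
  scope <- match.arg(scope)
  stopifnot(all(c("allele", "sequence", "binder") %in% names(data)))
  data <- tibble::as_tibble(data)
  res <- lapply(split(seq_len(nrow(data)), data$allele), function(rows) {
    seqs <- data$sequence[rows]
    counts_all <- count_similar(seqs, identity_threshold)
    in_sr <- logical(length(rows))
    for (part in c(TRUE, FALSE)) {
      sel <- which(data$binder[rows] == part)
      if (!length(sel)) next
      cts <- if (scope == "dataset") counts_all[sel] else NULL
      red <- hobohm_reduce(seqs[sel], identity_threshold, counts = cts)
      in_sr[sel[red$kept_index]] <- TRUE
    }
    tibble::tibble(row = rows, n_similar_all = counts_all,
                   in_sr = in_sr, in_sp = counts_all == 0L)
  })
  res <- dplyr::arrange(dplyr::bind_rows(res), .data$row)
  data$n_similar_all <- res$n_similar_all
  data$in_sr <- res$in_sr
  data$in_sp <- res$in_sp
  data
}

#' Singular peptides of an affinity table
#'
#' Peptides sharing no sequence similarity with any other peptide of the same
#' allele's full dataset.
#'
#' @inheritParams similarity_reduce
#' @return The subset of rows of `data` forming the SP set.
#' @export
singular_peptides <- function(data, identity_threshold = 0.8) {
  ann <- similarity_reduce(data, identity_threshold = identity_threshold)
  dplyr::filter(ann, .data$in_sp)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  code
}
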