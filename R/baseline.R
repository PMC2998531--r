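#' Configuration for the baseline core-matrix trainer
#'
#' @param max_iterations Maximum number of E/M sweeps (default 50). `0` gives
#'   the matrix of a single M-step on leftmost cores.
#' @param pseudocount Smoothing strength: each (position, residue) cell
#'   receives this many virtual observations at the neutral ratio 1,
#'   keeping unobserved cells neutral (default 1).
#' @param sweeps Inner backfitting sweeps per M-step (default 5): cells are
#'   re-estimated cyclically from residual ratios until the additive log
#'   model stabilises.
#' @param seed Integer recorded for provenance; training itself is
#'   deterministic (initial core assignment is the leftmost window).
#' @return A `trainer_config` list.
#' @export
trainer_config <- function(max_iterations = 50L, pseudocount = 1,
                           sweeps = 5L, seed = NULL) {
  stopifnot(max_iterations >= 0, pseudocount > 0, sweeps >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 pseudocount = pseudocount, sweeps = as.integer(sweeps),
                 seed = seed),
            class = "trainer_config")
}

best_windows <- function(values, idx) {
  logv <- log(values)
  lens <- lengths(idx)
  score <- numeric(length(idx))
  start <- integer(length(idx))
  for (L in unique(lens)) {
    rows <- which(lens == L)
    s <- window_scores(logv, do.call(rbind, idx[rows]))
    w <- max.col(-s, ties.method = "first")
    start[rows] <- w
    score[rows] <- exp(s[cbind(seq_along(rows), w)])
  }
  list(score = score, start = start)
}

#' Train a 9-mer core scoring matrix from binding affinities
#'
#' A simple iterative best-core estimator providing a trainable method for
#' the cross-validation harness. Alternates (E) assigning each peptide the
#' lowest-scoring 9-mer core under the current matrix with (M) re-estimating
#' the matrix from the assigned cores. The M-step fits the additive model in
#' log space by backfitting: each (position, residue) cell is set to the
#' geometric mean of the *residual* ratios - the peptide IC50 relative to the
#' dataset geometric mean, after dividing out the current contributions of
#' the other eight core positions - smoothed by `pseudocount` virtual
#' observations at the neutral ratio 1, cycling over positions for `sweeps`
#' rounds. (Attributing the whole IC50 ratio to every cell, without the
#' residual step, washes out the motif under best-window scanning.)
#' Iteration stops when core assignments are stable or `max_iterations` is
#' reached. Training is deterministic: the initial assignment is the leftmost
#' window. The resulting matrix is IC50-like (lower product = stronger).
#'
#' @param data Affinity tibble for a single allele with columns `sequence`
#'   and `ic50`; at least 20 records, all sequences of length >= 9.
#' @param config A [trainer_config()].
#' @return A [scoring_matrix()] with `source = "trained"` and attributes
#'   `iterations` and `converged`.
#' @export
train_core_matrix <- function(data, config = trainer_config()) {
  stopifnot(inherits(config, "trainer_config"))
  seqs <- as.character(data$sequence)
  ic50 <- as.numeric(data$ic50)
  if (length(seqs) < 20L) {
    stop("need at least 20 records to train", call. = FALSE)
  }
  if (any(nchar(seqs) < N_CORE)) {
    stop("all training sequences must be at least 9 residues", call. = FALSE)
  }
  allele <- if ("allele" %in% names(data)) unique(data$allele) else "unknown"
  if (length(allele) != 1L) {
    stop("train one allele at a time", call. = FALSE)
  }
  idx <- encode_peptides(seqs)
  logratio <- log(ic50 / geomean(ic50))

  m_step <- function(start) {
    core <- t(vapply(seq_along(idx),
                     function(i) idx[[i]][start[i] + 0:(N_CORE - 1L)],
                     integer(N_CORE)))
    lv <- matrix(0, N_CORE, 20L, dimnames = list(NULL, AMINO_ACIDS))
    contrib <- matrix(0, length(idx), N_CORE)
    for (s in seq_len(config$sweeps)) {
      tot <- rowSums(contrib)
      for (p in seq_len(N_CORE)) {
        resid <- logratio - (tot - contrib[, p])
        f <- factor(core[, p], levels = seq_len(20L))
        sums <- vapply(split(resid, f), sum, numeric(1))
        cnts <- tabulate(core[, p], nbins = 20L)
        lv[p, ] <- sums / (cnts + config$pseudocount)
        tot <- tot - contrib[, p] + lv[p, core[, p]]
        contrib[, p] <- lv[p, core[, p]]
      }
    }
    exp(lv)
  }

  start <- rep(1L, length(idx))
  values <- m_step(start)
  iterations <- 0L
  converged <- FALSE
  while (iterations < config$max_iterations) {
    iterations <- iterations + 1L
    new_start <- best_windows(values, idx)$start
    if (identical(new_start, start)) {
      converged <- TRUE
      break
    }
    start <- new_start
    values <- m_step(start)
  }
  out <- scoring_matrix(values, allele = allele, source = "trained")
  attr(out, "iterations") <- iterations
  attr(out, "converged") <- converged
  out
}

#' Predictor interface: score a peptide list with any model
#'
#' Every prediction method enters the evaluation and consensus machinery
#' through this generic. Implementations return one row per input peptide in
#' input order; peptides that cannot be scored (e.g. shorter than 9 residues)
#' get an `NA` score and an explanatory `note` rather than failing the whole
#' call.
#'
#' @param model A fitted or loaded model; the built-in method covers
#'   [scoring_matrix()] objects (combinatorial-library, trained, or truth
#'   matrices).
#' @param peptides Character vector of peptides.
#' @param ... Passed to methods.
#' @return Tibble with columns `sequence`, `method`, `score`, `core_start`,
#'   `core_seq`, `note`.
#' @export
predict_many <- function(model, peptides, ...) {
  UseMethod("predict_many")
}

#' @rdname predict_many
#' @param method Method label; defaults to the matrix source.
#' @export
predict_many.scoring_matrix <- function(model, peptides, method = NULL, ...) {
  peptides <- as.character(peptides)
  if (is.null(method)) method <- model$source
  out <- tibble::tibble(sequence = peptides, method = method,
                        score = NA_real_, core_start = NA_integer_,
                        core_seq = NA_character_, note = NA_character_)
  ok <- nchar(peptides) >= N_CORE
  out$note[!ok] <- "peptide shorter than 9 residues"
  if (any(ok)) {
    p <- predict_peptides(model, peptides[ok], method = method)
    out$score[ok] <- p$score
    out$core_start[ok] <- p$core_start
    out$core_seq[ok] <- p$core_seq
  }
  out
}

#' Baseline trainer for the cross-validation harness
#'
#' @param config A [trainer_config()].
#' @return A trainer function `f(train_data) -> scoring_matrix` satisfying the
#'   contract of [cross_validate()].
#' @export
baseline_trainer <- function(config = trainer_config()) {
  force(config)
  function(train_data) train_core_matrix(train_data, config)
}
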