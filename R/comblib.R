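geomean <- function(x) exp(mean(log(x)))

#' Positional-scanning combinatorial library design
#'
#' Enumerates the 180 peptide mixtures used to characterise one MHC class II
#' molecule. Each mixture is a 13-mer with alanines at template positions 1,
#' 2, 12 and 13 and an equimolar mixture of all 20 residues at the central
#' nine positions, except for a single fixed residue. Core position `p`
#' (1-9) sits at template position `p + 2`.
#'
#' @return Tibble of 180 rows with columns `position` (core position 1-9),
#'   `residue` (fixed residue), `template_position` (3-11) and `template`
#'   (13-character string; `x` marks fully randomised positions).
#' @export
library_design <- function() {
  grid <- expand.grid(residue = AMINO_ACIDS, position = seq_len(N_CORE),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$position, grid$residue), c("position", "residue")]
  tpos <- grid$position + 2L
  template <- vapply(seq_len(nrow(grid)), function(k) {
    tpl <- c("A", "A", rep("x", 9L), "A", "A")
    tpl[tpos[k]] <- grid$residue[k]
    paste(tpl, collapse = "")
  }, character(1))
  tibble::tibble(position = grid$position, residue = grid$residue,
                 template_position = tpos, template = template)
}

check_panel <- function(panel) {
  need <- c("position", "residue", "ic50")
  if ("ic50_nM" %in% names(panel) && !"ic50" %in% names(panel)) {
    panel$ic50 <- panel$ic50_nM
  }
  if (!all(need %in% names(panel))) {
    stop("library panel needs columns position, residue, ic50", call. = FALSE)
  }
  key <- paste(panel$position, panel$residue)
  want <- paste(rep(seq_len(N_CORE), each = 20L), rep(AMINO_ACIDS, N_CORE))
  if (nrow(panel) != 180L || !setequal(key, want) || anyDuplicated(key)) {
    stop("library panel must contain exactly the 180 (position 1-9, residue) ",
         "combinations", call. = FALSE)
  }
  if (any(!is.finite(panel$ic50)) || any(panel$ic50 <= 0)) {
    stop("panel IC50 values must be finite and > 0 nM (clamp values above ",
         "assay sensitivity before derivation)", call. = FALSE)
  }
  panel[, need]
}

#' Read / write a combinatorial library panel
#'
#' Panel files are TSV with header `position<TAB>residue<TAB>ic50_nM` and
#' exactly 180 rows covering each (core position 1-9, residue) pair once.
#'
#' @param path File path.
#' @param panel Tibble with columns `position`, `residue`, `ic50`.
#' @return `read_library_panel()`: a validated tibble; `write_library_panel()`:
#'   `path`, invisibly.
#' @export
read_library_panel <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t")
  raw$position <- as.integer(raw$position)
  check_panel(tibble::as_tibble(raw))
}

#' @rdname read_library_panel
#' @export
write_library_panel <- function(panel, path) {
  panel <- check_panel(panel)
  out <- data.frame(position = panel$position, residue = panel$residue,
                    ic50_nM = format(panel$ic50, digits = 15, trim = TRUE,
                                     scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a scoring matrix from a combinatorial library panel
#'
#' Implements the average-relative-binding (ARB) derivation. Each mixture
#' IC50 is standardised as a ratio to the geometric mean IC50 of all 180
#' mixtures, then normalised within each core position so the optimal
#' (lowest, strongest-binding) value is 1. A per-position geometric mean ARB
#' is computed, and each position's normalised values are multiplied by the
#' ratio of the whole-library ARB to that position's ARB, down-weighting
#' positions with little specificity. The result is IC50-like: the product of
#' nine entries is lower for stronger predicted binders.
#'
#' @param panel Library panel tibble (columns `position`, `residue`, `ic50`),
#'   e.g. from [read_library_panel()] or [simulate_library_panel()].
#' @param weighting Apply the per-position ARB weighting (default `TRUE`).
#'   With `FALSE` the normalised values are returned unweighted; per-position
#'   rank order is identical either way.
#' @param allele Allele name recorded on the matrix.
#' @return A [scoring_matrix()] with `source = "comblib"`. The derivation
#'   trace is attached as attribute `"trace"` and retrievable with
#'   [derivation_trace()].
#' @export
derive_matrix <- function(panel, weighting = TRUE, allele = "unknown") {
  panel <- check_panel(panel)
  ic <- matrix(NA_real_, N_CORE, 20L, dimnames = list(NULL, AMINO_ACIDS))
  ic[cbind(panel$position, match(panel$residue, AMINO_ACIDS))] <- panel$ic50
  G <- geomean(as.vector(ic))
  r <- ic / G
  n <- r / apply(r, 1, min)
  arb_pos <- exp(rowMeans(log(n)))
  arb_all <- geomean(as.vector(n))
  w <- arb_all / arb_pos
  m <- if (weighting) n * w else n
  out <- scoring_matrix(m, allele = allele, source = "comblib")
  attr(out, "trace") <- list(G = G, relative = r, normalized = n,
                             arb_position = arb_pos, arb_all = arb_all,
                             position_weight = w, weighting = weighting)
  out
}

#' @rdname derive_matrix
#' @param matrix A matrix returned by `derive_matrix()`.
#' @export
derivation_trace <- function(matrix) {
  tr <- attr(matrix, "trace")
  if (is.null(tr)) stop("matrix carries no derivation trace", call. = FALSE)
  tr
}

encode_peptides <- function(peptides) {
  idx <- lapply(strsplit(toupper(peptides), ""), match, AMINO_ACIDS)
  bad <- vapply(idx, anyNA, logical(1))
  if (any(bad)) {
    stop("peptide(s) with residues outside the 20-letter alphabet: ",
         paste(head(peptides[bad], 5L), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Score a 9-mer core against a scoring matrix
#'
#' The score of a core is the product of the nine matrix entries selected by
#' its residues; lower means stronger predicted binding.
#'
#' @param matrix A [scoring_matrix()].
#' @param core Character vector of 9-mer sequences.
#' @return Numeric vector of positive scores.
#' @export
score_core <- function(matrix, core) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  if (any(nchar(core) != N_CORE)) {
    stop("cores must be exactly 9 residues long", call. = FALSE)
  }
  idx <- encode_peptides(core)
  vapply(idx, function(ii) prod(matrix$values[cbind(seq_len(N_CORE), ii)]),
         numeric(1))
}

# Log-scale scores of every 9-mer window for peptides of a single length.
# idxmat: n x L integer matrix of residue indices. Returns n x (L-8) matrix.
window_scores <- function(logv, idxmat) {
  L <- ncol(idxmat)
  nw <- L - N_CORE + 1L
  s <- matrix(0, nrow(idxmat), nw)
  for (w in seq_len(nw)) {
    for (p in seq_len(N_CORE)) {
      s[, w] <- s[, w] + logv[p, ][idxmat[, w + p - 1L]]
    }
  }
  s
}

#' Predict peptide binding by 9-mer core scanning
#'
#' Every contiguous 9-mer window of each peptide is scored as the product of
#' matrix entries; the peptide score is the best (lowest) window product and
#' the reported core is the leftmost window achieving it.
#'
#' @param matrix A [scoring_matrix()].
#' @param peptides Character vector of peptides, all of length >= 9.
#' @param method Method label stored in the result (defaults to the matrix
#'   source).
#' @return Tibble with one row per peptide: `sequence`, `method`, `score`,
#'   `core_start` (1-based offset of the best core), `core_seq`.
#' @examples
#' m <- scoring_matrix(matrix(1, 9, 20, dimnames = list(NULL, strsplit(
#'   "ACDEFGHIKLMNPQRSTVWY", "")[[1]])), "X")
#' predict_peptides(m, "ACDEFGHIKLMNPQR")
#' @export
predict_peptides <- function(matrix, peptides, method = NULL) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  peptides <- as.character(peptides)
  if (any(nchar(peptides) < N_CORE)) {
    stop("all peptides must be at least 9 residues long", call. = FALSE)
  }
  if (is.null(method)) method <- matrix$source
  if (!length(peptides)) {
    return(tibble::tibble(sequence = character(), method = character(),
                          score = numeric(), core_start = integer(),
                          core_seq = character()))
  }
  idx <- encode_peptides(peptides)
  logv <- log(matrix$values)
  lens <- lengths(idx)
  score <- numeric(length(peptides))
  start <- integer(length(peptides))
  for (L in unique(lens)) {
    rows <- which(lens == L)
    im <- do.call(rbind, idx[rows])
    s <- window_scores(logv, im)
    w <- max.col(-s, ties.method = "first")
    start[rows] <- w
    score[rows] <- exp(s[cbind(seq_along(rows), w)])
  }
  tibble::tibble(sequence = peptides, method = method, score = score,
                 core_start = start,
                 core_seq = substr(peptides, start, start + N_CORE - 1L))
}

#' Write predictions in the standard TSV dialect
#'
#' Columns: `sequence`, `method`, `score`, `core_start_1based`, `core_seq`,
#' `percentile_rank` (rank of the score within the written set, 1 = best).
#'
#' @param predictions Tibble from [predict_peptides()] or [predict_many()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- data.frame(sequence = predictions$sequence,
                    method = predictions$method,
                    score = predictions$score,
                    core_start_1based = predictions$core_start,
                    core_seq = predictions$core_seq,
                    percentile_rank = percentile_rank(predictions$score,
                                                      orientation = "lower"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
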