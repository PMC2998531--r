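#' Classify peptides as binders from measured IC50
#'
#' A peptide is a binder when its measured half-maximal inhibitory
#' concentration is strictly below 1000 nM; a peptide measured at exactly
#' 1000 nM (or weaker) is a non-binder.
#'
#' @param ic50 Numeric vector of measured IC50 values in nM; all values must
#'   be finite and positive.
#' @return Logical vector, `TRUE` for binders.
#' @examples
#' classify_binder(c(50, 999.9, 1000, 20000))
#' @export
classify_binder <- function(ic50) {
  if (!is.numeric(ic50)) {
    stop("`ic50` must be numeric (nM).", call. = FALSE)
  }
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("`ic50` values must be finite and > 0 nM.", call. = FALSE)
  }
  ic50 < BINDER_CUTOFF_NM
}

valid_sequence <- function(x) {
  nchar(x) >= 1L & !grepl(paste0("[^", paste(AMINO_ACIDS, collapse = ""), "]"), x)
}

#' Build a validated affinity table
#'
#' Assembles per-allele peptide binding measurements into the tibble used
#' throughout the package, deriving binder labels and applying the duplicate
#' policy: within an allele, the first occurrence of a sequence is kept and
#' later duplicates are dropped with a message. Row order is preserved.
#'
#' @param allele Character vector of allele names (recycled if length 1).
#' @param sequence Character vector of uppercase peptide sequences over the
#'   20-letter amino-acid alphabet.
#' @param ic50 Numeric vector of measured IC50 values in nM.
#' @param provenance Free-text tag, typically `"measured"` or `"synthetic"`.
#' @param strict If `TRUE` (default), sequences with letters outside the
#'   20-residue alphabet are an error; if `FALSE`, such rows are dropped with
#'   a warning.
#' @return A tibble with columns `allele`, `sequence`, `ic50`, `binder` and a
#'   `provenance` attribute.
#' @examples
#' affinity_table("HLA-DRB1*0101", c("ACDEFGHIKLMNPQR", "AYAAAKAAALAAAVA"),
#'                c(12, 4500))
#' @export
affinity_table <- function(allele, sequence, ic50, provenance = "measured",
                           strict = TRUE) {
  if (length(allele) == 1L) allele <- rep(allele, length(sequence))
  stopifnot(length(allele) == length(sequence),
            length(sequence) == length(ic50))
  sequence <- toupper(as.character(sequence))
  ok <- valid_sequence(sequence)
  if (any(!ok)) {
    msg <- paste0("illegal residues in sequence(s): ",
                  paste(head(which(!ok), 5L), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(paste0(msg, " - rows dropped (lenient mode)"), call. = FALSE)
  }
  out <- tibble::tibble(allele = as.character(allele)[ok],
                        sequence = sequence[ok],
                        ic50 = as.numeric(ic50)[ok])
  out$binder <- classify_binder(out$ic50)
  dup <- duplicated(paste(out$allele, out$sequence, sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate sequence(s) within allele dropped (first kept)")
    out <- out[!dup, ]
  }
  attr(out, "provenance") <- provenance
  out
}

#' Read a peptide binding-affinity table
#'
#' Reads the tab-separated affinity dialect with header columns
#' `allele`, `sequence`, `ic50_nM` (in any order). Binder labels are derived
#' at the 1000 nM cutoff and input order is preserved; malformed rows are
#' reported with their line numbers.
#'
#' @param path Path to a TSV file.
#' @inheritParams affinity_table
#' @return A tibble as returned by [affinity_table()], possibly spanning
#'   several alleles.
#' @export
read_affinity_table <- function(path, strict = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("allele", "sequence", "ic50_nM")
  if (!all(need %in% names(raw))) {
    stop("affinity table must have columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(raw), collapse = ", "), call. = FALSE)
  }
  ic50 <- suppressWarnings(as.numeric(raw$ic50_nM))
  bad <- which(!is.finite(ic50) | ic50 <= 0)
  if (length(bad)) {
    stop("non-numeric or non-positive ic50_nM at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  badseq <- which(!valid_sequence(toupper(raw$sequence)))
  if (length(badseq) && strict) {
    stop("illegal residue characters at line(s) ",
         paste(badseq + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  affinity_table(raw$allele, raw$sequence, ic50, strict = strict)
}

#' Write an affinity table
#'
#' @param data Tibble with columns `allele`, `sequence`, `ic50`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(data, path) {
  out <- data.frame(allele = data$allele, sequence = data$sequence,
                    ic50_nM = format(data$ic50, digits = 15, trim = TRUE,
                                     scientific = FALSE))
  names(out)[3] <- "ic50_nM"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peptides from a plain list or FASTA file
#'
#' Plain files hold one peptide per line; files whose first non-blank
#' character is `>` are parsed as FASTA (via Biostrings).
#'
#' @param path Input file.
#' @return Character vector of uppercase peptide sequences.
#' @export
read_peptides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(trimws(lines[[1]]), ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package", call. = FALSE)
    }
    seqs <- Biostrings::readAAStringSet(path)
    return(toupper(as.character(seqs)))
  }
  toupper(trimws(lines))
}

# ---- scoring matrices -------------------------------------------------------

#' Construct a 9 x 20 scoring matrix
#'
#' A scoring matrix holds one positive multiplicative weight per 9-mer core
#' position (rows, 1-9) and residue (columns, alphabetical one-letter codes).
#' Orientation is IC50-like: a smaller core product means stronger predicted
#' binding.
#'
#' @param values Numeric 9 x 20 matrix of positive weights. Columns may be in
#'   any order but must be named by the 20 residue letters; rows are core
#'   positions 1-9.
#' @param allele Allele name the matrix describes.
#' @param source One of `"comblib"`, `"trained"`, `"synthetic-truth"`.
#' @return A `scoring_matrix` object.
#' @seealso [derive_matrix()], [train_core_matrix()], [read_matrix()]
#' @export
scoring_matrix <- function(values, allele = "unknown",
                           source = c("comblib", "trained", "synthetic-truth")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(dim(values) == c(N_CORE, 20L))) {
    stop("scoring matrix must be a numeric 9 x 20 matrix", call. = FALSE)
  }
  if (is.null(colnames(values)) || !setequal(colnames(values), AMINO_ACIDS)) {
    stop("scoring matrix columns must be named by the 20 residue letters",
         call. = FALSE)
  }
  values <- values[, AMINO_ACIDS, drop = FALSE]
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all scoring-matrix values must be finite and > 0", call. = FALSE)
  }
  rownames(values) <- as.character(seq_len(N_CORE))
  structure(list(values = values, allele = allele, source = source),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("<scoring_matrix> allele:", x$allele, " source:", x$source, "\n")
  print(signif(x$values, 4))
  invisible(x)
}

#' @describeIn scoring_matrix Long-format view: one row per (position, residue).
#' @param x A `scoring_matrix`.
#' @param ... Unused.
#' @export
tidy.scoring_matrix <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(N_CORE), times = 20L),
    residue = rep(AMINO_ACIDS, each = N_CORE),
    value = as.vector(x$values[, AMINO_ACIDS])
  )
}

#' Write a scoring matrix to its TSV dialect
#'
#' The on-disk dialect mirrors the 9 x 20 layout: a header row
#' `residue<TAB>pos1..pos9`, then 20 data rows keyed by residue letter in
#' alphabetical order, holding linear (not log) values. Round-trips preserve
#' 12 significant digits.
#'
#' @param matrix A [scoring_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  v <- matrix$values
  if (any(v <= 0)) stop("refusing to write non-positive matrix values")
  lines <- c(
    paste(c("residue", paste0("pos", seq_len(N_CORE))), collapse = "\t"),
    vapply(AMINO_ACIDS, function(a) {
      paste(c(a, formatC(v[, a], digits = 15, format = "g")), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a scoring matrix from its TSV dialect
#'
#' @param path Matrix file written by [write_matrix()].
#' @param allele,source Metadata for the returned object.
#' @return A [scoring_matrix()].
#' @export
read_matrix <- function(path, allele = "unknown", source = "comblib") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) != 20L || names(raw)[1] != "residue" ||
      !setequal(raw$residue, AMINO_ACIDS)) {
    stop("matrix file must have a 'residue' column with exactly the 20 ",
         "residue letters", call. = FALSE)
  }
  if (!identical(names(raw)[-1], paste0("pos", seq_len(N_CORE)))) {
    stop("matrix file must have columns pos1..pos9", call. = FALSE)
  }
  vals <- apply(as.matrix(raw[, -1]), 2, as.numeric)
  if (any(!is.finite(vals))) stop("non-numeric matrix entries", call. = FALSE)
  m <- t(vals)                       # positions x residues
  colnames(m) <- raw$residue
  scoring_matrix(m, allele = allele, source = source)
}

#' @describeIn scoring_matrix Heatmap of log10 matrix values by core position
#'   and residue.
#' @param object A `scoring_matrix`.
#' @export
autoplot.scoring_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue,
                                   y = factor(.data$position, levels = 9:1),
                                   fill = log10(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "log10 weight") +
    ggplot2::labs(x = "residue", y = "core position",
                  title = paste0(object$allele, " (", object$source, ")"),
                  subtitle = "lower value = stronger predicted binding") +
    ggplot2::theme_minimal()
}
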