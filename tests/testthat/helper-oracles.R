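# Independent brute-force oracles. Deliberately naive implementations used
# only to check the package's optimized code paths on small instances.

oracle_identity <- function(p1, p2) {
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  la <- length(a)
  lb <- length(b)
  best <- 0L
  for (d in seq(-(la - 1L), lb - 1L)) {
    i <- seq(max(1L, 1L - d), min(la, lb - d))
    best <- max(best, sum(a[i] == b[i + d]))
  }
  best / min(la, lb)
}

oracle_shares_9mer <- function(p1, p2) {
  kmers <- function(p) {
    n <- nchar(p)
    if (n < 9L) return(character(0))
    substring(p, 1:(n - 8L), 9:n)
  }
  length(intersect(kmers(p1), kmers(p2))) > 0L
}

oracle_similar <- function(p1, p2) {
  oracle_shares_9mer(p1, p2) || oracle_identity(p1, p2) > 0.8
}

oracle_count_similar <- function(peptides) {
  n <- length(peptides)
  counts <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && oracle_similar(peptides[i], peptides[j])) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

# Pairwise concordance AUC: fraction of (binder, non-binder) pairs where the
# binder is scored better, ties counting one half. lower = better.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Spearman via the classical sum-of-squared-rank-differences formula
# (valid without ties).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

rand_peptides <- function(n, len = 15L, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(aa, if (length(len) > 1L) sample(len, 1L) else len,
                 replace = TRUE), collapse = "")
  }, character(1))
}

# Chain fixture: A ~ B (shared 9-mer), B ~ C (shared 9-mer), A !~ C.
chain_abc <- function() {
  a <- "ACACACACACACACA"
  c_ <- "DEDEDEDEDEDEDED"
  b <- paste0(substr(a, 1, 9), substr(c_, 1, 9))
  c(A = a, B = b, C = c_)
}

all_ones_matrix <- function(allele = "TEST") {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  scoring_matrix(matrix(1, 9, 20, dimnames = list(NULL, aa)), allele,
                 source = "comblib")
}

uniform_panel <- function(ic50 = 100) {
  d <- library_design()
  tibble::tibble(position = d$position, residue = d$residue, ic50 = ic50)
}
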