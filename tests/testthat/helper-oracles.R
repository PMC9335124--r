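# Independent brute-force oracles and fixture builders used across tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_peptides <- function(n, len = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Longest common subsequence length = maximum number of identical aligned
# positions over all global alignments (gap cost 0); oracle for
# alignment-based identity.
lcs_length <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  m <- matrix(0L, length(ca) + 1, length(cb) + 1)
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      m[i + 1, j + 1] <- if (ca[i] == cb[j]) m[i, j] + 1L
                         else max(m[i, j + 1], m[i + 1, j])
    }
  }
  m[length(ca) + 1, length(cb) + 1]
}

# AUROC by exhaustive positive-negative pair comparison.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Naive double-loop dipeptide counter.
naive_dpc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- stats::setNames(numeric(400),
                         as.vector(t(outer(AA20, AA20, paste0))))
  for (i in seq_len(L - 1)) {
    dp <- paste0(chars[i], chars[i + 1])
    out[dp] <- out[dp] + 1
  }
  out / (L - 1)
}

# Naive gapped group-pair counter.
naive_cksaagp <- function(seq, k_values = 0:2) {
  groups <- list(aliphatic = c("G","A","V","L","M","I"),
                 aromatic = c("F","Y","W"),
                 positive = c("K","R","H"),
                 negative = c("D","E"),
                 uncharged = c("S","T","C","P","N","Q"))
  gof <- rep(names(groups), lengths(groups))
  names(gof) <- unlist(groups)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  pair_levels <- as.vector(t(outer(names(groups), names(groups),
                                   paste, sep = "_")))
  out <- numeric(0)
  for (k in k_values) {
    block <- stats::setNames(numeric(25), pair_levels)
    for (i in seq_len(L - k - 1)) {
      pr <- paste(gof[chars[i]], gof[chars[i + k + 1]], sep = "_")
      block[pr] <- block[pr] + 1
    }
    out <- c(out, block / (L - (k + 1)))
  }
  out
}

# Write a 4-line-per-record FASTQ file (optionally gzipped); quality is a
# constant Phred score.
write_fastq_fixture <- function(path, dna, qual_char = "I", ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(dna))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (i in seq_along(dna)) {
    writeLines(c(paste0("@", ids[i]), dna[i], "+",
                 strrep(qual_char, nchar(dna[i]))), con)
  }
  path
}

# Small hyperparameter grids to keep unit-test SVM fits fast.
SMALL_C_GRID <- 2^seq(-1, 7, by = 2)
SMALL_GAMMA_GRID <- 2^seq(-7, -1, by = 2)
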