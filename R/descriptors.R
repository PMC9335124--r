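# Sequence descriptors: amino acid composition (AAC, 20), dipeptide
# composition (DPC, 400), Chou-type pseudo amino acid composition
# (PseAAC, 20 + lambda), and the composition of k-spaced amino acid group
# pairs (CKSAAGP, 25 per k). The full encoding concatenates
# AAC | DPC | PseAAC | CKSAAGP into 519 named dimensions; submodels store
# feature indices, so the order is part of the contract and never changes.

aac_names <- function() paste0("AAC_", AA_ALPHABET20)

dpc_names <- function() {
  paste0("DPC_", as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0))))
}

pseaac_names <- function(lam = 4L) {
  c(paste0("PseAAC_", AA_ALPHABET20), paste0("PseAAC_lam", seq_len(lam)))
}

cksaagp_names <- function(k_values = 0:2) {
  grp <- names(AA_GROUPS)
  pairs <- as.vector(t(outer(grp, grp, paste, sep = "_")))
  unlist(lapply(k_values, function(k) paste0("CKSAAGP_k", k, "_", pairs)))
}

#' Amino acid composition (AAC)
#'
#' Fraction of each of the 20 residues in the peptide; components sum to 1.
#'
#' @param seq A single peptide sequence.
#' @return Named numeric vector of length 20.
#' @export
aac <- function(seq) {
  seq <- validate_peptides(seq)
  chars <- strsplit(seq, "")[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET20))
  stats::setNames(as.numeric(counts) / length(chars), aac_names())
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each of the 400 ordered residue pairs among the L-1
#' overlapping dipeptides; components sum to 1.
#'
#' @param seq A single peptide sequence of length >= 2.
#' @return Named numeric vector of length 400.
#' @export
dpc <- function(seq) {
  seq <- validate_peptides(seq)
  L <- nchar(seq)
  if (L < 2) stop("DPC requires at least 2 residues")
  chars <- strsplit(seq, "")[[1]]
  dipep <- paste0(chars[-L], chars[-1])
  counts <- table(factor(dipep, levels = sub("^DPC_", "", dpc_names())))
  stats::setNames(as.numeric(counts) / (L - 1), dpc_names())
}

#' Composition of k-spaced amino acid group pairs (CKSAAGP)
#'
#' Residues are mapped to five physicochemical groups (aliphatic, aromatic,
#' positive-charged, negative-charged, uncharged). For each spacing k, the
#' frequency of each of the 25 ordered group pairs separated by k residues
#' is n / (L - (k + 1)); the blocks for all k are concatenated. Each k-block
#' sums to 1.
#'
#' @param seq A single peptide sequence with `nchar(seq) >= max(k_values)+2`.
#' @param k_values Integer spacings (default 0:2, suited to 12-mers).
#' @return Named numeric vector of length `25 * length(k_values)`.
#' @export
cksaagp <- function(seq, k_values = 0:2) {
  seq <- validate_peptides(seq)
  L <- nchar(seq)
  if (L < max(k_values) + 2) {
    stop("CKSAAGP with k = ", max(k_values), " requires length >= ",
         max(k_values) + 2)
  }
  grp <- names(AA_GROUPS)
  groups <- AA_GROUP_OF[strsplit(seq, "")[[1]]]
  pair_levels <- as.vector(t(outer(grp, grp, paste, sep = "_")))
  out <- numeric(0)
  for (k in k_values) {
    i <- seq_len(L - k - 1L)
    pairs <- paste(groups[i], groups[i + k + 1L], sep = "_")
    counts <- table(factor(pairs, levels = pair_levels))
    out <- c(out, as.numeric(counts) / (L - (k + 1L)))
  }
  stats::setNames(out, cksaagp_names(k_values))
}

#' Pseudo amino acid composition (PseAAC)
#'
#' Chou's type-1 pseudo amino acid composition: the 20 residue frequencies
#' augmented by `lam` sequence-order correlation factors weighted by `w`.
#' Three residue property scales (hydrophobicity, hydrophilicity, side-chain
#' mass) are standardized to zero mean and unit variance over the 20
#' residues; the correlation function Theta(Ri, Rj) is the mean of the
#' squared differences of the three standardized properties, and
#' theta_tau averages Theta over all residue pairs tau positions apart.
#' All `20 + lam` components sum to 1.
#'
#' @param seq A single peptide sequence with `nchar(seq) > lam`.
#' @param lam Number of correlation tiers (default 4, suited to short
#'   peptides while retaining sequence-order signal).
#' @param w Weight of the sequence-order terms (default 0.4).
#' @return Named numeric vector of length `20 + lam`.
#' @export
pseaac <- function(seq, lam = 4L, w = 0.4) {
  seq <- validate_peptides(seq)
  L <- nchar(seq)
  lam <- as.integer(lam)
  if (L <= lam) stop("PseAAC requires length > lambda (", lam, ")")
  if (w <= 0) stop("w must be positive")
  # standardize each property over the 20 residues (population SD)
  props <- PSEAAC_PROPS
  props <- (props - rowMeans(props)) /
    sqrt(rowMeans((props - rowMeans(props))^2))
  chars <- strsplit(seq, "")[[1]]
  pmat <- props[, chars, drop = FALSE]  # 3 x L standardized property track
  theta <- vapply(seq_len(lam), function(tau) {
    i <- seq_len(L - tau)
    mean(colMeans((pmat[, i, drop = FALSE] -
                     pmat[, i + tau, drop = FALSE])^2))
  }, numeric(1))
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET20))) / L
  denom <- sum(f) + w * sum(theta)
  stats::setNames(c(f / denom, w * theta / denom), pseaac_names(lam))
}

#' Encode peptides as 519-dimensional descriptor vectors
#'
#' Concatenates AAC (20), DPC (400), PseAAC (24), and CKSAAGP (75) into a
#' fixed-order, named 519-dimensional feature vector per peptide. The
#' column order is stable across calls and package versions; trained
#' submodels reference features by index into this layout.
#'
#' @param seqs Character vector of peptide sequences (length 5 to 50).
#' @param lam,w PseAAC parameters (defaults 4 and 0.4).
#' @param k_values CKSAAGP spacings (default 0:2).
#' @return Numeric matrix, one row per peptide, 519 named columns,
#'   rownames = sequences.
#' @export
encode_peptides <- function(seqs, lam = 4L, w = 0.4, k_values = 0:2) {
  seqs <- validate_peptides(seqs)
  if (any(nchar(seqs) < 5)) {
    stop("peptides must have at least 5 residues to be encoded (got '",
         seqs[nchar(seqs) < 5][1], "')")
  }
  feat_names <- c(aac_names(), dpc_names(), pseaac_names(lam),
                  cksaagp_names(k_values))
  out <- matrix(0, nrow = length(seqs), ncol = length(feat_names),
                dimnames = list(seqs, feat_names))
  for (i in seq_along(seqs)) {
    out[i, ] <- c(aac(seqs[i]), dpc(seqs[i]), pseaac(seqs[i], lam, w),
                  cksaagp(seqs[i], k_values))
  }
  out
}
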