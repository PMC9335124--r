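# Dataset preparation: pairwise sequence identity, greedy redundancy
# removal, target-unrelated-peptide screening, and balanced sub-dataset
# construction for ensemble training.

#' Pairwise sequence identity
#'
#' For equal-length sequences this is the ungapped fraction of matching
#' positions. For unequal lengths, identical positions in a global alignment
#' are counted and divided by the length of the shorter sequence (the
#' convention of greedy incremental clustering tools such as CD-HIT).
#'
#' @param a,b Peptide sequences (single strings).
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- validate_peptides(a); b <- validate_peptides(b)
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    return(sum(ca == cb) / nchar(a))
  }
  mat <- matrix(0L, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  diag(mat) <- 1L
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = mat,
    # near-zero gap cost: the alignment then maximizes the number of
    # identical aligned positions, the quantity the identity ratio needs
    gapOpening = 0, gapExtension = 0.01
  )
  min(1, Biostrings::nmatch(aln) / min(nchar(a), nchar(b)))
}

#' Remove redundant peptides by greedy identity clustering
#'
#' Deterministic greedy incremental clustering: peptides are visited longest
#' first (ties broken lexicographically); each peptide joins the first
#' existing cluster representative it matches at identity >= `threshold`,
#' otherwise it founds a new cluster. The representatives are returned in
#' their original input order.
#'
#' @param peptides Character vector of sequences or a peptide data.frame.
#' @param threshold Identity threshold in (0, 1], default 0.8.
#' @return Object of the same kind as the input, restricted to cluster
#'   representatives.
#' @export
remove_redundancy <- function(peptides, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  df <- as_peptide_df(peptides)
  seqs <- df$seq
  ord <- order(-nchar(seqs), seqs)
  reps <- integer(0)  # indices into seqs, in visiting order
  for (i in ord) {
    matched <- FALSE
    for (r in reps) {
      if (seqs[r] == seqs[i] ||
          pairwise_identity(seqs[r], seqs[i]) >= threshold) {
        matched <- TRUE
        break
      }
    }
    if (!matched) reps <- c(reps, i)
  }
  keep <- sort(reps)
  if (is.character(peptides)) seqs[keep] else df[keep, , drop = FALSE]
}

#' Screen peptides against a table of target-unrelated peptides
#'
#' Looks each peptide up (exact sequence match) in a local table of peptides
#' recovered in screens against other targets. A peptide recorded with
#' `min_targets` or more entirely different targets is flagged as a putative
#' target-unrelated peptide (TUP); such promiscuous binders are selection
#' artifacts, not target-specific hits.
#'
#' @param peptides Character vector of sequences or peptide data.frame.
#' @param tup_table Data.frame with columns `seq` and `target` (one row per
#'   peptide-target pair), or `seq` and `n_targets` (pre-aggregated).
#' @param min_targets Minimum number of distinct targets to call a TUP
#'   (default 4).
#' @return Data.frame with columns `seq`, `n_targets`, `status`
#'   (`"clean"` or `"putative_TUP"`).
#' @export
screen_tups <- function(peptides, tup_table, min_targets = 4L) {
  df <- as_peptide_df(peptides)
  if ("target" %in% names(tup_table)) {
    agg <- tapply(tup_table$target, tup_table$seq,
                  function(t) length(unique(t)))
  } else if ("n_targets" %in% names(tup_table)) {
    agg <- stats::setNames(tup_table$n_targets, tup_table$seq)
  } else {
    stop("tup_table needs columns (seq, target) or (seq, n_targets)")
  }
  n <- unname(agg[df$seq])
  n[is.na(n)] <- 0L
  data.frame(
    seq = df$seq,
    n_targets = as.integer(n),
    status = ifelse(n >= min_targets, "putative_TUP", "clean"),
    stringsAsFactors = FALSE
  )
}

#' Build balanced positive/negative sub-datasets
#'
#' Samples `n_pairs * length(positives)` negatives without replacement,
#' partitions them into `n_pairs` disjoint groups, and pairs each group with
#' the full positive set, yielding `n_pairs` balanced sub-datasets (one
#' ensemble submodel is trained per sub-dataset). Deterministic given `seed`.
#'
#' @param positives,negatives Character vectors of peptide sequences.
#' @param n_pairs Number of sub-datasets (default 10).
#' @param seed Random seed for the negative sampling (default 1).
#' @return List of `n_pairs` lists, each with elements `positives` and
#'   `negatives` (equal-length character vectors).
#' @export
build_sub_datasets <- function(positives, negatives, n_pairs = 10L,
                               seed = 1L) {
  positives <- validate_peptides(positives)
  negatives <- validate_peptides(negatives)
  overlap <- intersect(positives, negatives)
  if (length(overlap) > 0) {
    stop("sequence present in both classes: ", overlap[1])
  }
  need <- n_pairs * length(positives)
  if (length(negatives) < need) {
    stop("need at least ", need, " negatives (", n_pairs, " x ",
         length(positives), "); got ", length(negatives))
  }
  chosen <- with_seed(seed, sample(negatives, need, replace = FALSE))
  groups <- split(chosen, rep(seq_len(n_pairs), each = length(positives)))
  lapply(groups, function(neg) list(positives = positives, negatives = neg))
}
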