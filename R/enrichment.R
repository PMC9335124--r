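# Enrichment analysis: per-sample peptide lists -> count matrix -> ppm
# normalization -> ratio + one-tailed Welch t-test hit calling against
# control selections, plus BLOSUM62-based clustering of the hits.

#' Build a peptide-by-sample count matrix
#'
#' @param per_sample_peptides Named list mapping `sample_id` to a character
#'   vector of observed peptides (with multiplicity).
#' @param meta Data.frame with columns `sample_id`, `condition`, `replicate`
#'   describing each sample. `(condition, replicate)` pairs must be unique.
#' @return An object of class `count_matrix`: list with `counts` (integer
#'   matrix, peptides x samples) and `samples` (the metadata, column order
#'   matching the matrix).
#' @export
build_count_matrix <- function(per_sample_peptides, meta) {
  required <- c("sample_id", "condition", "replicate")
  if (!all(required %in% names(meta))) {
    stop("sample sheet must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         meta$sample_id[duplicated(meta$sample_id)][1])
  }
  key <- paste(meta$condition, meta$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, replicate) pair: ", key[duplicated(key)][1])
  }
  unknown <- setdiff(names(per_sample_peptides), meta$sample_id)
  if (length(unknown) > 0) {
    stop("sample_id not in sample sheet: ", unknown[1])
  }
  peptides <- sort(unique(unlist(per_sample_peptides, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(peptides), ncol = nrow(meta),
                   dimnames = list(peptides, meta$sample_id))
  for (sid in meta$sample_id) {
    obs <- per_sample_peptides[[sid]]
    if (is.null(obs) || length(obs) == 0) {
      message("sample '", sid, "' has no observed peptides (zero column)")
      next
    }
    tab <- table(obs)
    counts[names(tab), sid] <- as.integer(tab)
  }
  structure(list(counts = counts, samples = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "peptides x", ncol(x$counts),
      "samples\n")
  cat("conditions:",
      paste(sprintf("%s(%d)", names(table(x$samples$condition)),
                    table(x$samples$condition)), collapse = " "), "\n")
  invisible(x)
}

#' Normalize counts to parts-per-million
#'
#' Each column is scaled so its entries sum to 1e6: the normalized abundance
#' of a peptide is its read count divided by the sample's total accepted
#' reads, times 10^6.
#'
#' @param cm A `count_matrix` or a plain numeric matrix.
#' @return Numeric matrix of ppm values, same dimnames.
#' @export
normalize_ppm <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  csum <- colSums(counts)
  if (any(csum == 0)) {
    stop("zero total count in sample: ",
         colnames(counts)[csum == 0][1])
  }
  sweep(counts, 2, csum, "/") * 1e6
}

#' One-tailed Welch t-test (unequal variances)
#'
#' Tests whether `mean(a) > mean(b)` using the Welch statistic with
#' Welch-Satterthwaite degrees of freedom; the p-value is the upper tail.
#' Degenerate inputs with zero pooled standard error are handled explicitly:
#' equal means give (t = 0, p = 0.5), otherwise t is +/-Inf with p 0 or 1,
#' which count data with constant replicates can produce.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @return Named numeric vector `c(t = ..., p = ...)`.
#' @export
welch_t_one_tailed <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least two replicates in each group")
  }
  res <- welch_rows(matrix(a, nrow = 1), matrix(b, nrow = 1))
  c(t = res$t[1], p = res$p[1])
}

# Vectorized Welch test over matrix rows: A [n x ra] vs B [n x rb].
welch_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- pmax(0, (rowSums(A * A) - na * ma^2) / (na - 1))
  vb <- pmax(0, (rowSums(B * B) - nb * mb^2) / (nb - 1))
  se2 <- va / na + vb / nb
  t <- ifelse(se2 > 0, (ma - mb) / sqrt(se2),
              ifelse(ma == mb, 0, ifelse(ma > mb, Inf, -Inf)))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               1)
  p <- ifelse(is.finite(t), stats::pt(t, df, lower.tail = FALSE),
              ifelse(t > 0, 0, 1))
  p[t == 0] <- 0.5
  list(t = t, p = p, df = df)
}

#' Call target-enriched peptides against control selections
#'
#' For each peptide and each control condition, computes the enrichment
#' ratio of mean target ppm over mean control ppm (the denominator floored
#' at `pseudo_ppm` to tolerate zero-count controls) and a one-tailed Welch
#' t-test p-value on the replicate ppm vectors. A peptide is a hit only if
#' ratio >= `min_ratio` AND p <= `alpha` against EVERY control condition.
#'
#' @param cm A `count_matrix` with replicate metadata.
#' @param target Condition label of the target selection (needs >= 2
#'   replicates).
#' @param controls Character vector of control condition labels, each with
#'   >= 2 replicates. With `control_mode = "pooled"` all control samples are
#'   pooled into a single group.
#' @param min_ratio Minimum enrichment ratio (default 2).
#' @param alpha Maximum raw p-value (default 0.05; no multiple-testing
#'   correction is applied).
#' @param pseudo_ppm Floor applied to the control mean in the ratio
#'   denominator (default 1 ppm).
#' @param control_mode `"each"` (default) tests every control condition
#'   separately; `"pooled"` tests one pooled control group.
#' @return Data.frame with one row per peptide: `peptide`, a `ratio_*` and
#'   `p_*` column per control group, and `is_hit`.
#' @export
call_enriched <- function(cm, target, controls,
                          min_ratio = 2, alpha = 0.05, pseudo_ppm = 1,
                          control_mode = c("each", "pooled")) {
  control_mode <- match.arg(control_mode)
  stopifnot(inherits(cm, "count_matrix"))
  conds <- cm$samples$condition
  for (cond in c(target, controls)) {
    if (!cond %in% conds) stop("condition absent from matrix: ", cond)
    if (sum(conds == cond) < 2) {
      stop("condition '", cond, "' needs >= 2 replicates")
    }
  }
  ppm <- normalize_ppm(cm)
  tgt <- ppm[, conds == target, drop = FALSE]
  groups <- if (control_mode == "pooled") {
    stats::setNames(list(unique(controls)), "pooled")
  } else {
    stats::setNames(as.list(controls), controls)
  }
  out <- data.frame(peptide = rownames(ppm), stringsAsFactors = FALSE)
  hit <- rep(TRUE, nrow(ppm))
  for (g in names(groups)) {
    ctl <- ppm[, conds %in% groups[[g]], drop = FALSE]
    ratio <- rowMeans(tgt) / pmax(rowMeans(ctl), pseudo_ppm)
    w <- welch_rows(tgt, ctl)
    out[[paste0("ratio_", g)]] <- ratio
    out[[paste0("p_", g)]] <- w$p
    hit <- hit & ratio >= min_ratio & w$p <= alpha
  }
  out$is_hit <- hit
  rownames(out) <- NULL
  out
}

#' Cluster hit peptides by BLOSUM62 profile similarity
#'
#' Each peptide of length L is embedded as the concatenation of the 20
#' BLOSUM62 substitution-score rows of its residues (20*L dimensions);
#' peptides are then clustered by average-linkage agglomerative clustering
#' on Euclidean distances and the tree is cut at `n_clusters`. Every peptide
#' receives a cluster id.
#'
#' @param hits Character vector of equal-length peptides.
#' @param n_clusters Number of clusters to cut the tree at.
#' @return Named integer vector mapping peptide to cluster id (1-based).
#' @export
cluster_hits <- function(hits, n_clusters) {
  hits <- validate_peptides(hits)
  if (length(unique(nchar(hits))) != 1) {
    stop("all hit peptides must have equal length")
  }
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1 || n_clusters > length(hits)) {
    stop("n_clusters must be between 1 and the number of hits")
  }
  emb <- blosum62_embed(hits)
  d <- stats::dist(emb, method = "euclidean")
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = n_clusters)
  stats::setNames(as.integer(cl), hits)
}

# 20*L-dimensional BLOSUM62 row-concatenation embedding of equal-length
# peptides.
blosum62_embed <- function(seqs) {
  blosum <- get_blosum62()[AA_ALPHABET20, AA_ALPHABET20]
  L <- nchar(seqs[1])
  emb <- matrix(0, nrow = length(seqs), ncol = 20L * L)
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (j in seq_len(L)) {
    emb[, (j - 1L) * 20L + seq_len(20L)] <- blosum[chars[, j], , drop = FALSE]
  }
  rownames(emb) <- seqs
  emb
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}
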