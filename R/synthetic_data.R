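# Synthetic data: motif-biased peptide sets with tunable separability, and
# phage-display count matrices with planted round-to-round enrichment.
# These emulate the shape of a real selection experiment (a 12-mer random
# library, background negatives, binders enriched only in target arms) so
# every pipeline stage can be exercised without any external data.

#' Construct a positional motif model
#'
#' A motif is a per-position residue probability matrix plus an implant
#' strength mixing the motif with a uniform background.
#'
#' @param consensus Consensus sequence defining the motif positions.
#' @param strength Implant strength in `[0, 1]`: 1 draws every position
#'   from the motif distribution, 0 from the background.
#' @param consensus_weight Probability mass put on the consensus residue at
#'   each motif position (default 1, a deterministic motif; lower values
#'   spread the remainder uniformly so even a fully implanted motif retains
#'   within-motif diversity). Sequence diversity at the default comes from
#'   the implant-strength mixture with the background.
#' @return Object of class `motif_model` with fields `length`, `pwm`
#'   (20 x L), and `implant_strength`.
#' @export
motif_model <- function(consensus = "NYSKPTDRQVWF", strength = 1,
                        consensus_weight = 1) {
  consensus <- validate_peptides(consensus)
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  L <- nchar(consensus)
  chars <- strsplit(consensus, "")[[1]]
  pwm <- matrix((1 - consensus_weight) / 19, nrow = 20, ncol = L,
                dimnames = list(AA_ALPHABET20, NULL))
  for (j in seq_len(L)) pwm[chars[j], j] <- consensus_weight
  structure(list(length = L, pwm = pwm, implant_strength = strength),
            class = "motif_model")
}

#' Generate background peptides
#'
#' I.i.d. residues drawn from `aa_freqs` (uniform by default), emulating a
#' naive random peptide library.
#'
#' @param n Number of peptides (>= 1).
#' @param length Peptide length (default 12).
#' @param aa_freqs Named residue probabilities over the 20-letter alphabet,
#'   summing to 1 (default uniform).
#' @param seed Random seed.
#' @return Character vector of `n` peptides.
#' @export
gen_background_peptides <- function(n, length = 12L, aa_freqs = NULL,
                                    seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(aa_freqs)) {
    aa_freqs <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
  }
  if (!setequal(names(aa_freqs), AA_ALPHABET20) ||
      abs(sum(aa_freqs) - 1) > 1e-8 || any(aa_freqs < 0)) {
    stop("aa_freqs must be named probabilities over the 20 residues, ",
         "summing to 1")
  }
  with_seed(seed, {
    chars <- sample(AA_ALPHABET20, n * length, replace = TRUE,
                    prob = aa_freqs[AA_ALPHABET20])
    apply(matrix(chars, nrow = n), 1, paste, collapse = "")
  })
}

#' Generate motif-implanted positive peptides
#'
#' Each position is drawn from the mixture
#' `implant_strength * motif + (1 - implant_strength) * uniform background`.
#'
#' @param n Number of peptides.
#' @param motif A [motif_model()].
#' @param seed Random seed.
#' @return Character vector of `n` peptides of the motif's length.
#' @export
gen_motif_positives <- function(n, motif = motif_model(), seed = 1L) {
  stopifnot(inherits(motif, "motif_model"))
  s <- motif$implant_strength
  mix <- s * motif$pwm + (1 - s) * (1 / 20)
  with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      out[i] <- paste(vapply(seq_len(motif$length), function(j) {
        sample(AA_ALPHABET20, 1, prob = mix[, j])
      }, character(1)), collapse = "")
    }
    out
  })
}

#' Configuration for a simulated phage-display selection
#'
#' @param library_size Number of distinct peptides in the library.
#' @param depth Sequencing reads per sample.
#' @param replicates Named integer vector of replicates per condition
#'   (default mirrors a two-round screen: library before selection R0 x3,
#'   first round R1 x3, second-round target arm x6, bead and
#'   unrelated-antibody control arms x3 each).
#' @param enrichment_factor Per-round weight multiplier for planted binders
#'   in target arms (>= 1).
#' @param concentration Symmetric Dirichlet concentration for the initial
#'   library abundances (default 1; smaller = more skewed).
#' @param replicate_noise SD of the lognormal per-replicate abundance
#'   jitter (default 0.05).
#' @param seed Random seed.
#' @return List of class `ngpd_sim_config`.
#' @export
ngpd_sim_config <- function(library_size = 5000L, depth = 1e5L,
                            replicates = c(R0 = 3L, R1 = 3L,
                                           R2_target = 6L, R2_beads = 3L,
                                           R2_unrelated = 3L),
                            enrichment_factor = 10, concentration = 1,
                            replicate_noise = 0.05, seed = 1L) {
  stopifnot(library_size >= 1, depth >= 1, enrichment_factor >= 1,
            concentration > 0, all(replicates >= 1))
  structure(list(library_size = as.integer(library_size),
                 depth = as.integer(depth), replicates = replicates,
                 enrichment_factor = enrichment_factor,
                 concentration = concentration,
                 replicate_noise = replicate_noise,
                 seed = as.integer(seed)),
            class = "ngpd_sim_config")
}

#' Simulate a phage-display count matrix with planted binders
#'
#' Initial library abundances are symmetric-Dirichlet distributed. In
#' target arms, planted binders' weights are multiplied by
#' `enrichment_factor` per selection round (R1 once, the second-round
#' target arm twice). Control arms pan the round-1 pool without any
#' further target enrichment and re-sample their replicate noise
#' independently, so planted binders stand out only through genuine
#' enrichment. Per-sample counts are multinomial draws of `depth` reads
#' from lognormally jittered weights.
#'
#' @param cfg An [ngpd_sim_config()].
#' @param library_peptides Optional character vector of library sequences
#'   (generated from the config seed when NULL).
#' @param planted Optional character vector of true binders; must be a
#'   subset of the library. When NULL, `n_planted` library members are
#'   picked at random.
#' @param n_planted Number of binders to plant when `planted` is NULL
#'   (default 20).
#' @return List with `counts` (a [build_count_matrix()] style
#'   `count_matrix`), `truth` (character vector of planted binders), and
#'   `config`.
#' @export
gen_ngpd_counts <- function(cfg, library_peptides = NULL, planted = NULL,
                            n_planted = 20L) {
  stopifnot(inherits(cfg, "ngpd_sim_config"))
  if (is.null(library_peptides)) {
    library_peptides <- gen_background_peptides(cfg$library_size,
                                                seed = cfg$seed)
    library_peptides <- unique(library_peptides)
  }
  n <- length(library_peptides)
  with_seed(cfg$seed + 1L, {
    if (is.null(planted)) {
      planted <- sample(library_peptides, n_planted)
    } else if (!all(planted %in% library_peptides)) {
      stop("planted peptide absent from library: ",
           setdiff(planted, library_peptides)[1])
    }
    is_planted <- library_peptides %in% planted
    f <- cfg$enrichment_factor
    w0 <- stats::rgamma(n, shape = cfg$concentration)
    w0 <- w0 / sum(w0)
    round_weight <- function(rounds_of_enrichment) {
      w <- w0
      w[is_planted] <- w[is_planted] * f^rounds_of_enrichment
      w / sum(w)
    }
    base_w <- list(R0 = round_weight(0), R1 = round_weight(1),
                   R2_target = round_weight(2),
                   R2_beads = round_weight(1),    # panned from the R1 pool
                   R2_unrelated = round_weight(1))
    meta <- do.call(rbind, lapply(names(cfg$replicates), function(cond) {
      data.frame(sample_id = paste0(cond, "_rep", seq_len(cfg$replicates[[cond]])),
                 condition = cond, replicate = seq_len(cfg$replicates[[cond]]),
                 stringsAsFactors = FALSE)
    }))
    counts <- matrix(0L, nrow = n, ncol = nrow(meta),
                     dimnames = list(library_peptides, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      w <- base_w[[meta$condition[j]]] *
        exp(stats::rnorm(n, 0, cfg$replicate_noise))
      counts[, j] <- stats::rmultinom(1, cfg$depth, w)[, 1]
    }
    cm <- structure(list(counts = counts, samples = meta),
                    class = "count_matrix")
    list(counts = cm, truth = sort(planted), config = cfg)
  })
}

#' Generate a labeled benchmark peptide set
#'
#' Positives are motif-implanted at `separation`, negatives are background;
#' the combined set is shuffled and labeled. `separation = 1` yields a
#' strongly learnable signal, `separation = 0` a pure null.
#'
#' @param n_pos,n_neg Class sizes.
#' @param separation Implant strength in `[0, 1]`.
#' @param length Peptide length (default 12).
#' @param seed Random seed.
#' @return Data.frame with columns `id`, `seq`, `label`.
#' @export
gen_benchmark <- function(n_pos = 80L, n_neg = 800L, separation = 1,
                          length = 12L, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  motif <- motif_model(strength = separation)
  if (motif$length != length) {
    motif <- motif_model(
      consensus = substr(paste(rep("NYSKPTDRQVWF", ceiling(length / 12)),
                               collapse = ""), 1, length),
      strength = separation)
  }
  pos <- gen_motif_positives(n_pos, motif, seed = seed)
  neg <- gen_background_peptides(n_neg, length = length, seed = seed + 1L)
  # background peptides that collide with a positive sequence would make
  # the labeling contradictory; regenerate those few deterministically
  clash <- which(neg %in% pos)
  tries <- 0L
  while (length(clash) > 0 && tries < 100L) {
    neg[clash] <- gen_background_peptides(length(clash), length = length,
                                          seed = seed + 2L + tries)
    clash <- which(neg %in% pos)
    tries <- tries + 1L
  }
  df <- data.frame(
    id = c(paste0("pos", seq_len(n_pos)), paste0("neg", seq_len(n_neg))),
    seq = c(pos, neg),
    label = rep(c("positive", "negative"), c(n_pos, n_neg)),
    stringsAsFactors = FALSE
  )
  df[with_seed(seed + 1000L, sample(nrow(df))), , drop = FALSE]
}
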