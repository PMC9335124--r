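# Shared sequence alphabet, amino-acid group scheme, and residue property
# tables used by the descriptor encoders.

#' The 20 standard amino-acid one-letter codes, alphabetical order
#'
#' All peptide-facing functions in the package validate sequences against this
#' alphabet; ambiguous codes (B, J, O, U, X, Z) are rejected.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Physicochemical group scheme used by the grouped k-spaced pair descriptor.
# Five groups partitioning the 20 residues; group order is fixed because
# feature positions depend on it.
AA_GROUPS <- list(
  aliphatic = c("G", "A", "V", "L", "M", "I"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  uncharged = c("S", "T", "C", "P", "N", "Q")
)

# residue -> group name lookup
AA_GROUP_OF <- {
  g <- rep(names(AA_GROUPS), lengths(AA_GROUPS))
  names(g) <- unlist(AA_GROUPS, use.names = FALSE)
  g[AA_ALPHABET20]
}

# Residue property tables for the pseudo amino acid composition: Chou-type
# hydrophobicity, hydrophilicity and side-chain mass scales.
PSEAAC_PROPS <- local({
  aa <- AA_ALPHABET20
  hydrophobicity <- c(
    A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
    H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
    P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
    W = 0.81, Y = 0.26
  )
  hydrophilicity <- c(
    A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
    H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
    P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
    W = -3.4, Y = -2.3
  )
  side_chain_mass <- c(
    A = 15, C = 47, D = 59, E = 73, F = 91, G = 1,
    H = 82, I = 57, K = 73, L = 57, M = 75, N = 58,
    P = 42, Q = 72, R = 101, S = 31, T = 45, V = 43,
    W = 130, Y = 107
  )
  rbind(
    hydrophobicity = hydrophobicity[aa],
    hydrophilicity = hydrophilicity[aa],
    side_chain_mass = side_chain_mass[aa]
  )
})

#' Validate peptide sequences
#'
#' Checks that every sequence is non-empty, at most `max_len` residues, and
#' contains only the 20 standard amino-acid letters. Sequences are upper-cased
#' before checking.
#'
#' @param seqs Character vector of peptide sequences.
#' @param max_len Maximum allowed length (default 50; longer chains are
#'   treated as proteins, not peptides).
#' @param what Label used in error messages.
#' @return The validated, upper-cased character vector, invisibly usable.
#' @export
validate_peptides <- function(seqs, max_len = 50L, what = "peptide") {
  if (length(seqs) == 0L) return(character(0))
  if (!is.character(seqs)) stop(what, " sequences must be a character vector")
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty ", what, " sequence at position ",
         which(!nzchar(seqs))[1])
  }
  too_long <- nchar(seqs) > max_len
  if (any(too_long)) {
    stop(what, " '", substr(seqs[too_long][1], 1, 20), "...' exceeds ",
         max_len, " residues")
  }
  bad <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop("illegal residue in ", what, " '", seqs[bad][1],
         "': only the 20 standard amino-acid letters are allowed")
  }
  seqs
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps generators pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env)
    on.exit({
      if (had) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    })
    set.seed(seed)
  }
  expr
}
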