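# Readers/writers for the formats the pipeline touches (FASTA, FASTQ, TSV
# peptide tables) and extraction of displayed peptides from raw reads.

#' Read peptides from a FASTA file
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return A data.frame with columns `id`, `seq`, `label` (one row per
#'   record, order preserved, sequences upper-cased). Labels default to
#'   `"unknown"`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e))
  )
  seqs <- validate_peptides(as.character(set))
  if (length(seqs) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids))) {
    auto <- paste0("pep", seq_along(seqs))
    if (is.null(ids)) ids <- auto else ids[!nzchar(ids)] <- auto[!nzchar(ids)]
  }
  data.frame(id = unname(ids), seq = unname(seqs), label = "unknown",
             stringsAsFactors = FALSE)
}

#' Write peptides to a FASTA file
#'
#' @param peptides Data.frame with columns `id` and `seq`, or a character
#'   vector of sequences (ids auto-generated).
#' @param path Output path.
#' @export
write_fasta <- function(peptides, path) {
  peptides <- as_peptide_df(peptides)
  set <- Biostrings::BStringSet(peptides$seq)
  names(set) <- peptides$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Coerce a character vector or data.frame into the canonical peptide
# data.frame (id, seq, label).
as_peptide_df <- function(x, validate = TRUE) {
  if (is.character(x)) {
    x <- data.frame(id = paste0("pep", seq_along(x)), seq = x,
                    label = "unknown", stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || !"seq" %in% names(x)) {
    stop("expected a character vector or a data.frame with a 'seq' column")
  }
  if (!"id" %in% names(x)) x$id <- paste0("pep", seq_len(nrow(x)))
  if (!"label" %in% names(x)) x$label <- "unknown"
  if (validate) x$seq <- validate_peptides(x$seq)
  bad <- !x$label %in% c("positive", "negative", "unknown")
  if (any(bad)) stop("labels must be positive/negative/unknown; got '",
                     x$label[bad][1], "'")
  x
}

#' Read a FASTQ file into read records
#'
#' Reads Sanger-encoded (Phred+33) FASTQ, plain or gzip-compressed.
#'
#' @param path Path to the FASTQ file.
#' @return A data.frame with columns `id`, `dna`, and `qual` (a list column
#'   of integer Phred scores, one vector per read).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # the 4-line record convention: a trailing partial record is a
  # truncation, which the downstream parser would silently drop
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ record ", length(lines) %/% 4 + 1, " in ", path)
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e))
  )
  dna <- as.character(set)
  quals <- S4Vectors::mcols(set)$qualities
  phred <- methods::as(Biostrings::PhredQuality(quals), "IntegerList")
  qlens <- lengths(phred)
  mismatch <- which(qlens != nchar(dna))
  if (length(mismatch) > 0) {
    stop("sequence/quality length mismatch at FASTQ record ", mismatch[1])
  }
  data.frame(
    id = if (is.null(names(set))) paste0("read", seq_along(dna))
         else unname(names(set)),
    dna = unname(dna),
    qual = I(as.list(phred)),
    stringsAsFactors = FALSE
  )
}

#' Extract the displayed-peptide insert from a read
#'
#' Locates `flank5` (exact match), checks that `flank3` occurs exactly
#' `insert_nt` bases downstream, and returns the insert between them.
#' Non-conforming reads (missing flank, wrong spacing, N in the insert)
#' yield `NA` rather than an error; enrichment statistics tolerate read loss.
#'
#' @param dna Character vector of read sequences.
#' @param flank5,flank3 Constant vector sequences immediately 5' and 3' of
#'   the randomized insert.
#' @param insert_nt Insert length in nucleotides; must be a positive multiple
#'   of 3.
#' @return Character vector of inserts (`NA` where extraction failed).
#' @export
extract_insert <- function(dna, flank5, flank3, insert_nt = 36L) {
  insert_nt <- as.integer(insert_nt)
  if (insert_nt <= 0L || insert_nt %% 3L != 0L) {
    stop("insert_nt must be a positive multiple of 3")
  }
  if (!nzchar(flank5) || !nzchar(flank3)) stop("flanks must be non-empty")
  dna <- toupper(dna)
  pos5 <- regexpr(toupper(flank5), dna, fixed = TRUE)
  start <- ifelse(pos5 > 0, pos5 + nchar(flank5), NA_integer_)
  insert <- ifelse(is.na(start), NA_character_,
                   substr(dna, start, start + insert_nt - 1L))
  after <- ifelse(is.na(start), NA_character_,
                  substr(dna, start + insert_nt,
                         start + insert_nt + nchar(flank3) - 1L))
  ok <- !is.na(insert) &
    nchar(insert) == insert_nt &
    after == toupper(flank3) &
    !grepl("N", insert, fixed = TRUE)
  ifelse(ok, insert, NA_character_)
}

#' Translate insert DNA to peptide sequence
#'
#' Standard genetic code. Inserts containing a stop codon or any ambiguous
#' base yield `NA`.
#'
#' @param dna Character vector of DNA sequences with length divisible by 3.
#' @return Character vector of peptides (`NA` where translation failed).
#' @export
translate_insert <- function(dna) {
  if (length(dna) == 0) return(character(0))
  out <- rep(NA_character_, length(dna))
  todo <- which(!is.na(dna))
  if (any(nchar(dna[todo]) %% 3 != 0)) {
    stop("insert length not divisible by 3")
  }
  code <- Biostrings::GENETIC_CODE
  for (i in todo) {
    codons <- substring(dna[i], seq(1, nchar(dna[i]), 3),
                        seq(3, nchar(dna[i]), 3))
    aa <- unname(code[codons])
    if (anyNA(aa) || any(aa == "*")) next  # ambiguous codon or stop
    out[i] <- paste(aa, collapse = "")
  }
  out
}

#' Extract displayed peptides from a FASTQ file
#'
#' Convenience pipeline: read FASTQ, drop reads whose mean Phred quality over
#' the insert is below `qmin`, extract inserts between the flanks, and
#' translate. Returns the peptides plus a log summary of read attrition.
#'
#' @inheritParams extract_insert
#' @param path FASTQ path (plain or .gz).
#' @param qmin Minimum mean Phred quality over the insert (default 20).
#' @return A list with `peptides` (character vector, one entry per accepted
#'   read) and `log` (named counts: total, flank_fail, low_quality,
#'   stop_or_ambiguous, accepted).
#' @export
extract_peptides_from_fastq <- function(path, flank5, flank3,
                                        insert_nt = 36L, qmin = 20) {
  reads <- read_fastq(path)
  n_total <- nrow(reads)
  inserts <- extract_insert(reads$dna, flank5, flank3, insert_nt)
  has_insert <- !is.na(inserts)
  # mean quality over the insert region only
  pos5 <- regexpr(toupper(flank5), toupper(reads$dna), fixed = TRUE)
  qual_ok <- rep(FALSE, n_total)
  for (i in which(has_insert)) {
    s <- pos5[i] + nchar(flank5)
    q <- reads$qual[[i]][s:(s + insert_nt - 1L)]
    qual_ok[i] <- mean(q) >= qmin
  }
  peptides <- translate_insert(ifelse(has_insert & qual_ok, inserts,
                                      NA_character_))
  accepted <- !is.na(peptides)
  list(
    peptides = peptides[accepted],
    log = c(total = n_total,
            flank_fail = sum(!has_insert),
            low_quality = sum(has_insert & !qual_ok),
            stop_or_ambiguous = sum(has_insert & qual_ok & !accepted),
            accepted = sum(accepted))
  )
}

#' Read a TSV peptide table
#'
#' Expects a header with at least a `seq` column; `id` and `label` are
#' filled in when absent. Extra columns are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return Data.frame with columns `id`, `seq`, `label`, plus any extras.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"seq" %in% names(df)) {
    stop("peptide table ", path, " is missing required column 'seq'")
  }
  as_peptide_df(df)
}

#' Write a TSV peptide table
#'
#' @param peptides Data.frame with at least `id` and `seq` columns.
#' @param path Output path.
#' @export
write_peptide_table <- function(peptides, path) {
  peptides <- as_peptide_df(peptides)
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
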