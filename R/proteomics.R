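AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  if (grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence))
    stop("invalid residue in sequence (allowed: ",
         paste(AA_ALPHABET, collapse = ""), ")")
  invisible(sequence)
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine (K) and arginine (R),
#' with cleavage suppressed when the next residue is proline (P) unless
#' \code{suppress_proline = FALSE}. With \code{missed_cleavages = m}, every
#' run of up to \code{m + 1} adjacent fully-cleaved fragments is also
#' reported. The zero-missed-cleavage peptides always concatenate back to
#' the input sequence.
#'
#' @param sequence Uppercase amino-acid string (20-letter alphabet).
#' @param missed_cleavages Number of missed cleavages allowed (default 0).
#' @param suppress_proline Suppress cleavage before proline (default TRUE,
#'   the conventional trypsin rule).
#' @return Character vector of peptides. For \code{missed_cleavages = 0}
#'   these are the consecutive fragments in sequence order; for m > 0 the
#'   fragments are followed by the merged peptides, ordered by start
#'   position then length.
#' @examples
#' tryptic_digest("AAAAKGGGGGGRCCCCCCC")  # AAAAK GGGGGGR CCCCCCC
#' tryptic_digest("AAKPGGR")              # AAKPGGR (KP does not cleave)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L, suppress_proline = TRUE) {
  validate_sequence(sequence)
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  pattern <- if (suppress_proline) "(?<=[KR])(?!P)" else "(?<=[KR])"
  frags <- strsplit(sequence, pattern, perl = TRUE)[[1]]
  m <- as.integer(missed_cleavages)
  if (m == 0L || length(frags) == 1L) return(frags)
  out <- character(0)
  nf <- length(frags)
  for (i in seq_len(nf)) {
    for (j in i:min(i + m, nf)) {
      out <- c(out, paste(frags[i:j], collapse = ""))
    }
  }
  out
}

#' iBAQ absolute-abundance ranking
#'
#' For each protein, the theoretical observable-peptide count is the number
#' of fully tryptic peptides (with \code{ibaq_missed_cleavages} missed
#' cleavages) whose length falls in
#' [\code{ibaq_pep_len_min}, \code{ibaq_pep_len_max}] amino acids; iBAQ is
#' the protein's summed MS intensity divided by that count. Proteins with
#' no observable peptide have no defined iBAQ: they are excluded from the
#' ranking and reported separately.
#'
#' @param entries Data frame with columns \code{accession},
#'   \code{sequence}, \code{intensity} (non-negative).
#' @param config An \code{\link{atlas_config}}.
#' @return A list with \code{ranked} (data.frame \code{accession},
#'   \code{n_observable_peptides}, \code{ibaq}, \code{rank}; sorted by
#'   descending iBAQ, ties broken by accession) and \code{unquantified}
#'   (data.frame \code{accession}, \code{n_observable_peptides} for
#'   zero-peptide proteins).
#' @examples
#' e <- data.frame(accession = "P1", sequence = "AAAAKGGGGGGRCCCCCCC",
#'                 intensity = 10)
#' compute_ibaq(e)$ranked$ibaq  # 10 / 2 observable peptides = 5
#' @export
compute_ibaq <- function(entries, config = atlas_config()) {
  need <- c("accession", "sequence", "intensity")
  if (!all(need %in% names(entries)))
    stop("entries must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(entries$accession)) stop("accessions must be unique")
  if (any(entries$intensity < 0)) stop("intensities must be >= 0")
  npep <- vapply(entries$sequence, function(s) {
    pep <- tryptic_digest(s, config$ibaq_missed_cleavages)
    len <- nchar(pep)
    sum(len >= config$ibaq_pep_len_min & len <= config$ibaq_pep_len_max)
  }, integer(1), USE.NAMES = FALSE)
  res <- data.frame(accession = entries$accession,
                    n_observable_peptides = npep,
                    ibaq = ifelse(npep > 0, entries$intensity / npep, NA_real_),
                    stringsAsFactors = FALSE)
  unq <- res[res$n_observable_peptides == 0L, c("accession", "n_observable_peptides")]
  ranked <- res[res$n_observable_peptides > 0L, , drop = FALSE]
  ord <- order(-ranked$ibaq, ranked$accession, method = "radix")
  ranked <- ranked[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  rownames(unq) <- NULL
  list(ranked = ranked, unquantified = unq)
}

#' Read protein sequences and intensities
#'
#' Joins a FASTA of protein sequences with a TSV of per-protein summed MS
#' intensities (columns \code{accession}, \code{intensity}) into the entry
#' table \code{\link{compute_ibaq}} consumes. FASTA ids are taken up to the
#' first whitespace.
#'
#' @param fasta_path Path to the protein FASTA.
#' @param intensity_path Path to the intensity TSV.
#' @return Data frame with columns \code{accession}, \code{sequence},
#'   \code{intensity}.
#' @export
read_protein_entries <- function(fasta_path, intensity_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  acc <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(acc)) stop("duplicate accession in FASTA")
  intens <- utils::read.delim(intensity_path, header = TRUE, sep = "\t",
                              colClasses = "character", quote = "")
  if (!all(c("accession", "intensity") %in% names(intens)))
    stop("intensity table must have columns accession, intensity")
  i <- match(acc, intens$accession)
  if (anyNA(i))
    stop("no intensity for accession(s): ", paste(acc[is.na(i)], collapse = ", "))
  data.frame(accession = acc,
             sequence = as.character(seqs),
             intensity = as.numeric(intens$intensity[i]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-species proteome overlap counting
#'
#' For each species, counts the distinct query proteins with at least one
#' alignment hit passing E-value <= \code{overlap_max_evalue} and identity
#' >= \code{overlap_min_identity}, and reports the overlap fraction as an
#' integer percentage of that species' total self-protein count. Duplicate
#' hit rows do not change the result (distinct-query semantics).
#'
#' @param hits Data frame with columns \code{query_id}, \code{species},
#'   \code{pident}, \code{evalue}.
#' @param totals Per-species self-protein counts: either a named numeric
#'   vector or a data.frame with columns \code{species}, \code{n_total}.
#' @param config An \code{\link{atlas_config}}.
#' @return Data frame with columns \code{species}, \code{n_total},
#'   \code{n_overlap}, \code{fraction} (integer percent, rounded half away
#'   from zero), one row per species in \code{totals}.
#' @export
overlap_analysis <- function(hits, totals, config = atlas_config()) {
  need <- c("query_id", "species", "pident", "evalue")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  if (is.data.frame(totals)) {
    totals <- stats::setNames(totals$n_total, totals$species)
  }
  unknown <- setdiff(unique(hits$species), names(totals))
  if (length(unknown))
    stop("species in hits absent from totals: ", paste(unknown, collapse = ", "))
  pass <- hits$evalue <= config$overlap_max_evalue &
    hits$pident >= config$overlap_min_identity
  passing <- hits[pass, c("query_id", "species")]
  out <- do.call(rbind, lapply(names(totals), function(sp) {
    n_over <- length(unique(passing$query_id[passing$species == sp]))
    n_tot <- as.integer(totals[[sp]])
    if (n_over > n_tot)
      stop("species '", sp, "': more passing queries (", n_over,
           ") than total proteins (", n_tot, ")")
    data.frame(species = sp, n_total = n_tot, n_overlap = n_over,
               fraction = round_half_up(100 * n_over / n_tot, 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
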