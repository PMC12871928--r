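#' The standard genetic code as a codon table
#'
#' Returns the 64 codon-to-amino-acid assignments of the standard nuclear
#' genetic code (DNA alphabet, `*` for the three stop codons TAA/TAG/TGA),
#' taken from [Biostrings::GENETIC_CODE].
#'
#' @return Named character vector of length 64; names are codons, values are
#'   one-letter amino-acid codes or `"*"`.
#' @examples
#' codonTable()[["ATG"]]  # "M"
#' @export
codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  out <- as.character(gc)
  names(out) <- names(gc)
  out
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.senseCodons <- function() setdiff(names(Biostrings::GENETIC_CODE), .STOP_CODONS)

#' Cyclic codon rotation for shifted reading of homopolymeric codon runs
#'
#' When a run of one codon `b1 b2 b3` is read in the +1 frame, every codon of
#' the run (away from its edges) becomes `b2 b3 b1`; in the -1 frame it becomes
#' `b3 b1 b2`. This models how a homorepeat's codon is perceived in an
#' alternative reading frame.
#'
#' @param codon A 3-letter DNA codon (A/C/G/T).
#' @param shift `+1` or `-1`.
#' @return The rotated codon.
#' @examples
#' rotateCodon("GAG", +1)  # "AGG": a poly-Glu run reads as poly-Arg
#' @export
rotateCodon <- function(codon, shift) {
  .check(is.character(codon) && length(codon) == 1L && nchar(codon) == 3L &&
           grepl("^[ACGT]{3}$", codon),
         "invalid codon '%s': must be 3 letters over ACGT", as.character(codon)[1L])
  .check(shift %in% c(1L, -1L, 1, -1), "shift must be +1 or -1")
  b <- .chars(codon)
  if (shift == 1) paste0(b[2L], b[3L], b[1L]) else paste0(b[3L], b[1L], b[2L])
}

#' Full rotation map over the 64 codons
#'
#' @return A data.frame with one row per codon: `codon`, `aa` (main frame),
#'   `plus1`, `plus1_aa`, `minus1`, `minus1_aa`. Both rotations are bijections
#'   on the 64 codons.
#' @export
codonRotationMap <- function() {
  ct <- codonTable()
  codons <- names(ct)
  plus1 <- vapply(codons, rotateCodon, character(1), shift = +1)
  minus1 <- vapply(codons, rotateCodon, character(1), shift = -1)
  data.frame(codon = codons, aa = unname(ct),
             plus1 = unname(plus1), plus1_aa = unname(ct[plus1]),
             minus1 = unname(minus1), minus1_aa = unname(ct[minus1]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Codons whose shifted reading yields arginine
#'
#' Enumerates the 64 codons and returns those whose rotation under `shift`
#' is one of the six Arg codons, together with the amino acid each encodes in
#' the main frame. Because rotation is a bijection there are exactly six such
#' codons per shift; under +1 three of them (GAG, TCG, GCG) encode Glu, Ser
#' and Ala -- the residues that dominate reference homorepeats -- which is the
#' codon-level driver of the arginine surge in frameshifted repeats.
#'
#' @param shift `+1` or `-1`.
#' @return data.frame with columns `codon`, `main_aa`, `rotated` (the Arg
#'   codon produced).
#' @export
argSourceCodons <- function(shift) {
  map <- codonRotationMap()
  col <- if (shift == 1) "plus1" else "minus1"
  aa_col <- paste0(col, "_aa")
  hit <- map[[aa_col]] == "R"
  out <- data.frame(codon = map$codon[hit], main_aa = map$aa[hit],
                    rotated = map[[col]][hit], stringsAsFactors = FALSE)
  out[order(out$codon), , drop = FALSE]
}

#' Conserved-codon frequency
#'
#' Frequency of conserved codons within a tandem repeat's DNA units,
#' as a percentage: `n_conserved / (n_conserved + n_variable) * 100`.
#'
#' @param n_conserved,n_variable Non-negative counts; their sum must be > 0.
#' @return Percentage in \[0, 100\].
#' @examples
#' conservedCodonFrequency(8, 2)  # 80
#' @export
conservedCodonFrequency <- function(n_conserved, n_variable) {
  .check(n_conserved >= 0 && n_variable >= 0, "counts must be non-negative")
  .check(n_conserved + n_variable > 0,
         "conserved-codon frequency undefined when both counts are zero")
  100 * n_conserved / (n_conserved + n_variable)
}

#' Classify codon positions of a repeat's DNA units as conserved or variable
#'
#' A codon position within the repeat unit is conserved if the codon is
#' identical across all unit copies; a single DNA-level difference makes it
#' variable.
#'
#' @param dna_units Character vector of >= 2 equal-length DNA unit strings;
#'   length must be a multiple of 3 (in-phase codon units).
#' @return Named integer vector `c(n_conserved =, n_variable =)`.
#' @examples
#' classifyCodonConservation(c("CAGCAG", "CAGCAA"))  # 1 conserved, 1 variable
#' @export
classifyCodonConservation <- function(dna_units) {
  .check(length(dna_units) >= 2L,
         "codon conservation undefined with fewer than 2 unit copies")
  lens <- nchar(dna_units)
  .check(length(unique(lens)) == 1L, "ragged units: all units must have equal length")
  .check(lens[1L] %% 3L == 0L, "unit length %d is not a multiple of 3", lens[1L])
  n_codons <- lens[1L] %/% 3L
  conserved <- vapply(seq_len(n_codons), function(j) {
    cods <- substr(dna_units, 3L * (j - 1L) + 1L, 3L * j)
    length(unique(cods)) == 1L
  }, logical(1))
  c(n_conserved = sum(conserved), n_variable = sum(!conserved))
}

#' Codon usage of a set of coding sequences (main frame)
#'
#' Counts frame-0 codons over all sequences; frequencies are normalized over
#' the 61 sense codons, stop-codon counts are reported with frequency `NA`.
#'
#' @param cds A [Biostrings::DNAStringSet] (or character vector) of CDSs.
#' @param context Label stored in the `context` column.
#' @return data.frame with columns `context`, `codon`, `aa`, `count`, `frequency`.
#' @export
codonUsage <- function(cds, context = "all") {
  seqs <- as.character(cds)
  counts <- integer(64)
  names(counts) <- names(codonTable())
  for (s in seqs) {
    n <- nchar(s) %/% 3L
    if (n == 0L) next
    cod <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  .codonUsageFromCounts(counts, context)
}

.codonUsageFromCounts <- function(counts, context) {
  ct <- codonTable()
  sense <- .senseCodons()
  total_sense <- sum(counts[sense])
  freq <- rep(NA_real_, 64)
  names(freq) <- names(ct)
  if (total_sense > 0) freq[sense] <- counts[sense] / total_sense
  data.frame(context = context, codon = names(ct), aa = unname(ct),
             count = unname(counts[names(ct)]),
             frequency = unname(freq[names(ct)]),
             stringsAsFactors = FALSE, row.names = NULL)
}
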