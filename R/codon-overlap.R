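# Codon usage restricted to main-frame regions overlapped by frameshifted
# homorepeats, and DNA-unit extraction for codon-conservation statistics.

#' Codon usage in main-frame regions overlapping frameshifted homorepeats
#'
#' Each frameshifted homorepeat's residue span is projected back to CDS
#' nucleotide coordinates through its fragment's provenance (`nt_start`), and
#' the main-frame codons whose nucleotide span it touches are collected. Only
#' homorepeats overlapping at least `min_overlap_aa` main-frame codons
#' contribute; counts are pooled into one usage table with context
#' `"overlap"`.
#'
#' @param cds Named [Biostrings::DNAStringSet] (or character vector) of the
#'   source coding sequences.
#' @param fs_homorepeats A [TRRegionSet-class] of homorepeats (unit length 1)
#'   detected on frameshift fragments.
#' @param fragments The [FragmentSet-class] carrying the fragments'
#'   nucleotide provenance.
#' @param min_overlap_aa Minimum number of overlapped main-frame codons for a
#'   homorepeat to be counted (default 9).
#' @return Codon-usage data.frame as from [codonUsage()].
#' @export
overlapCodonUsage <- function(cds, fs_homorepeats, fragments,
                              min_overlap_aa = 9L) {
  seqs <- .namedSeqs(cds)
  .check(!is.null(names(seqs)), "CDS set must be named")
  df <- as.data.frame(fs_homorepeats)
  df <- df[df$unit_len == 1L, , drop = FALSE]
  meta <- as.data.frame(fragments)
  counts <- integer(64L)
  names(counts) <- names(codonTable())
  for (i in seq_len(nrow(df))) {
    m <- meta[meta$fragment_id == df$fragment_id[i], , drop = FALSE]
    .check(nrow(m) == 1L,
           "fragment '%s' lacks provenance in the fragment set",
           df$fragment_id[i])
    cds_seq <- seqs[[m$cds_id]]
    .check(!is.null(cds_seq) && !is.na(cds_seq),
           "CDS '%s' referenced by fragment '%s' is missing",
           m$cds_id, df$fragment_id[i])
    nt_s <- m$nt_start + 3L * df$aa_start[i]
    nt_e <- m$nt_start + 3L * df$aa_end[i]
    k0 <- max(nt_s %/% 3L, 0L)
    k1 <- min((nt_e + 2L) %/% 3L, nchar(cds_seq) %/% 3L)   # half-open codons
    if (k1 - k0 < min_overlap_aa) next
    ks <- seq.int(k0, k1 - 1L)
    cod <- substring(cds_seq, 3L * ks + 1L, 3L * ks + 3L)
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  .codonUsageFromCounts(counts, "overlap")
}

#' Extract the DNA unit copies underlying a reference-frame tandem repeat
#'
#' Projects a TR region on a reference (frame 0) fragment back to the CDS and
#' returns the DNA strings of its complete unit copies (each
#' `3 * unit_len` nucleotides, in phase). These feed
#' [classifyCodonConservation()].
#'
#' @param tr One region (one-row data.frame or list with `fragment_id`,
#'   `aa_start`, `aa_end`, `unit_len`).
#' @param fragments The [FragmentSet-class] with provenance.
#' @param cds Named DNA sequence set.
#' @return Character vector of complete DNA units (>= 1).
#' @export
extractDnaUnits <- function(tr, fragments, cds) {
  meta <- as.data.frame(fragments)
  m <- meta[meta$fragment_id == tr$fragment_id, , drop = FALSE]
  .check(nrow(m) == 1L, "fragment '%s' not found", tr$fragment_id)
  s <- .namedSeqs(cds)[[m$cds_id]]
  u_nt <- 3L * as.integer(tr$unit_len)
  n_units <- (as.integer(tr$aa_end) - as.integer(tr$aa_start)) %/%
    as.integer(tr$unit_len)
  start_nt <- m$nt_start + 3L * as.integer(tr$aa_start)
  .check(start_nt + n_units * u_nt <= nchar(s),
         "TR region extends beyond CDS '%s'", m$cds_id)
  vapply(seq_len(n_units) - 1L, function(j)
    substr(s, start_nt + j * u_nt + 1L, start_nt + (j + 1L) * u_nt),
    character(1))
}

#' Conserved-codon frequency of a set of reference-frame TRs
#'
#' Pools conserved/variable codon counts over the regions (each region's DNA
#' units classified with [classifyCodonConservation()]; regions with fewer
#' than two complete units are skipped) and returns the pooled percentage.
#'
#' @param tr_regions A [TRRegionSet-class] on reference fragments.
#' @param fragments The [FragmentSet-class] with provenance.
#' @param cds Named DNA sequence set.
#' @return List with `n_conserved`, `n_variable` and `frequency` (percent).
#' @export
conservedCodonStats <- function(tr_regions, fragments, cds) {
  df <- as.data.frame(tr_regions)
  nc <- 0L
  nv <- 0L
  for (i in seq_len(nrow(df))) {
    units <- extractDnaUnits(df[i, ], fragments, cds)
    if (length(units) < 2L) next
    cl <- classifyCodonConservation(units)
    nc <- nc + cl[["n_conserved"]]
    nv <- nv + cl[["n_variable"]]
  }
  list(n_conserved = nc, n_variable = nv,
       frequency = if (nc + nv > 0) conservedCodonFrequency(nc, nv) else NA_real_)
}
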