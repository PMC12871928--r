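#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

.FRAMES <- c("0", "+1", "-1")
.frameOffset <- function(frame) c(`0` = 0L, `+1` = 1L, `-1` = 2L)[[frame]]

#' FragmentSet: stop-free protein fragments from the three reading frames
#'
#' A `FragmentSet` holds amino-acid fragments obtained by translating coding
#' sequences in the main (0) and shifted (+1/-1) frames and splitting at stop
#' codons. The sequences are an [Biostrings::AAStringSet] named by
#' `fragment_id`; per-fragment provenance lives in its metadata columns:
#' `cds_id`, `frame` (one of `"0"`, `"+1"`, `"-1"`), `nt_start` (0-based
#' offset of the fragment's first codon in the CDS) and `set_label`
#' (`"reference"` or `"frameshift"`).
#'
#' @slot sequences An `AAStringSet` with the metadata columns above.
#' @export
setClass("FragmentSet", representation(sequences = "AAStringSet"))

setValidity("FragmentSet", function(object) {
  seqs <- object@sequences
  md <- S4Vectors::mcols(seqs)
  need <- c("cds_id", "frame", "nt_start", "set_label")
  if (is.null(md) || !all(need %in% colnames(md)))
    return(sprintf("metadata columns %s are required",
                   paste(need, collapse = ", ")))
  if (length(seqs) == 0L) return(TRUE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    return("fragment names (fragment_id) must be present and unique")
  if (!all(md$frame %in% .FRAMES))
    return("frame must be one of '0', '+1', '-1'")
  if (!all(md$set_label %in% c("reference", "frameshift")))
    return("set_label must be 'reference' or 'frameshift'")
  offs <- vapply(as.character(md$frame), .frameOffset, integer(1))
  if (!all(md$nt_start %% 3L == offs))
    return("nt_start must be congruent to the frame offset modulo 3")
  letters_ok <- grepl(sprintf("^[%s]*$", paste(AA_ALPHABET20, collapse = "")),
                      as.character(seqs))
  if (!all(letters_ok))
    return("fragment sequences must use only the 20 amino-acid letters (no '*')")
  TRUE
})

#' Construct a FragmentSet
#'
#' @param aa_seq Character vector of amino-acid sequences (20-letter alphabet).
#' @param fragment_id,cds_id Character vectors of identifiers.
#' @param frame Character vector over `"0"`, `"+1"`, `"-1"`.
#' @param nt_start Integer vector, 0-based offset of the first codon in the CDS.
#' @param set_label `"reference"` or `"frameshift"` per fragment.
#' @return A [FragmentSet-class] object.
#' @export
FragmentSet <- function(aa_seq = character(), fragment_id = character(),
                        cds_id = character(), frame = character(),
                        nt_start = integer(), set_label = character()) {
  seqs <- Biostrings::AAStringSet(aa_seq)
  names(seqs) <- fragment_id
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    cds_id = as.character(cds_id), frame = as.character(frame),
    nt_start = as.integer(nt_start), set_label = as.character(set_label))
  new("FragmentSet", sequences = seqs)
}

#' TRRegionSet: detected tandem-repeat regions on protein fragments
#'
#' A table of tandem-repeat regions. Coordinates are 0-based, half-open,
#' residue-level, local to the fragment named by `fragment_id`. Each region
#' carries its repeat `unit_len`, phase-majority `consensus` (a primitive
#' string of length `unit_len`), `copy_number` (region length / unit length),
#' `purity` (fraction of positions matching the consensus letter at their
#' phase) and length `group` (1-5).
#'
#' @slot regions A data.frame with the columns above.
#' @export
setClass("TRRegionSet", representation(regions = "data.frame"))

setValidity("TRRegionSet", function(object) {
  df <- object@regions
  need <- c("fragment_id", "aa_start", "aa_end", "unit_len", "consensus",
            "copy_number", "purity", "group")
  if (!all(need %in% colnames(df)))
    return(sprintf("missing columns: %s",
                   paste(setdiff(need, colnames(df)), collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  len <- df$aa_end - df$aa_start
  if (any(df$unit_len < 1L)) return("unit_len must be >= 1")
  if (any(len < 2L * df$unit_len)) return("regions must span at least two unit copies")
  if (any(abs(df$copy_number - len / df$unit_len) > 1e-9))
    return("copy_number must equal (aa_end - aa_start) / unit_len")
  if (any(df$purity < 0 | df$purity > 1)) return("purity must lie in [0, 1]")
  if (any(nchar(df$consensus) != df$unit_len))
    return("consensus length must equal unit_len")
  if (any(vapply(df$consensus, .isStringPeriodic, logical(1))))
    return("consensus must be primitive (not a repetition of a shorter string)")
  if (any(df$group != vapply(df$unit_len, assignGroup, integer(1))))
    return("group must follow the unit-length grouping scheme")
  TRUE
})

#' Construct a TRRegionSet
#'
#' @param fragment_id Character vector.
#' @param aa_start,aa_end Integer vectors, 0-based half-open residue interval.
#' @param unit_len Integer vector of repeat-unit lengths.
#' @param consensus Character vector of consensus units (length `unit_len`).
#' @param purity Numeric vector in \[0, 1\].
#' @return A [TRRegionSet-class]; `copy_number` and `group` are derived.
#' @export
TRRegionSet <- function(fragment_id = character(), aa_start = integer(),
                        aa_end = integer(), unit_len = integer(),
                        consensus = character(), purity = numeric()) {
  df <- data.frame(fragment_id = as.character(fragment_id),
                   aa_start = as.integer(aa_start),
                   aa_end = as.integer(aa_end),
                   unit_len = as.integer(unit_len),
                   consensus = as.character(consensus),
                   copy_number = (as.integer(aa_end) - as.integer(aa_start)) /
                     pmax(as.integer(unit_len), 1L),
                   purity = as.numeric(purity),
                   stringsAsFactors = FALSE, row.names = NULL)
  df$group <- if (nrow(df)) vapply(df$unit_len, assignGroup, integer(1)) else integer()
  new("TRRegionSet", regions = df)
}
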