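# Frame translation: reference (0) and shifted (+1/-1) reading of CDSs,
# fragmentation at stop codons, exact-sequence deduplication.

#' Translate a coding sequence in one of the three same-strand frames
#'
#' Frames `"0"`, `"+1"` and `"-1"` start at nucleotide offsets 0, 1 and 2 of
#' the same strand (no reverse complement): a frameshift of a coding message
#' re-reads it, it does not read the antisense strand. A trailing partial
#' codon is discarded; stop codons translate to `"*"`.
#'
#' @param cds A DNA string (character or [Biostrings::DNAString]) over ACGT.
#' @param frame One of `"0"`, `"+1"`, `"-1"` (numeric 0/1/-1 also accepted).
#' @return Amino-acid string of length `floor((nchar(cds) - offset) / 3)`,
#'   possibly empty.
#' @examples
#' translateFrame("ATGGCTTAA", "0")    # "MA*"
#' translateFrame("ATGGAGGAGGAG", "+1")  # "WRR"
#' @export
translateFrame <- function(cds, frame) {
  frame <- .normalizeFrame(frame)
  s <- as.character(cds)
  .check(grepl("^[ACGT]*$", s), "CDS contains characters outside ACGT")
  off <- .frameOffset(frame)
  n_codon <- (nchar(s) - off) %/% 3L
  if (n_codon < 1L) return("")
  sub <- substr(s, off + 1L, off + 3L * n_codon)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE))
}

.normalizeFrame <- function(frame) {
  f <- as.character(frame)
  if (f == "1") f <- "+1"
  .check(f %in% .FRAMES, "frame must be one of 0, +1, -1 (got '%s')", f)
  f
}

#' Split a frame translation into stop-free protein fragments
#'
#' For frameshift translations, the maximal `*`-free substrings of length at
#' least `min_len` are kept (the short debris between frequent alternative-
#' frame stops is discarded). For the reference frame the whole translation is
#' kept after stripping one trailing `*`; an internal stop in a reference
#' frame triggers a warning and truncation at the first stop.
#'
#' @param translation Amino-acid string, `*` marking stops.
#' @param min_len Minimum fragment length for frameshift fragments
#'   (default 60 residues).
#' @param set_label `"reference"` or `"frameshift"`.
#' @param cds_id Identifier of the source CDS (used to build fragment ids).
#' @param frame Frame label, needed to compute each fragment's `nt_start`.
#' @return A [FragmentSet-class] (possibly empty). Fragment ids are
#'   `"<cds_id>_f<frame>_<nt_start>"`.
#' @export
splitFragments <- function(translation, min_len = 60L,
                           set_label = c("frameshift", "reference"),
                           cds_id = "cds", frame = "0") {
  set_label <- match.arg(set_label)
  frame <- .normalizeFrame(frame)
  off <- .frameOffset(frame)
  if (set_label == "reference") {
    aa <- sub("\\*$", "", translation)
    if (grepl("*", aa, fixed = TRUE)) {
      warning(sprintf("internal stop codon in reference frame of '%s'; truncating",
                      cds_id), call. = FALSE)
      aa <- sub("\\*.*$", "", aa)
    }
    if (!nchar(aa)) return(FragmentSet())
    starts_aa <- 0L
    seqs <- aa
  } else {
    pieces <- gregexpr("[^*]+", translation)[[1L]]
    if (pieces[1L] == -1L) return(FragmentSet())
    starts_aa <- as.integer(pieces) - 1L
    lens <- attr(pieces, "match.length")
    keep <- lens >= min_len
    if (!any(keep)) return(FragmentSet())
    starts_aa <- starts_aa[keep]
    seqs <- substring(translation, starts_aa + 1L, starts_aa + lens[keep])
  }
  nt_start <- off + 3L * starts_aa
  FragmentSet(aa_seq = seqs,
              fragment_id = sprintf("%s_f%s_%d", cds_id, frame, nt_start),
              cds_id = cds_id, frame = frame, nt_start = nt_start,
              set_label = set_label)
}

#' Translate a CDS set in all three frames and collect fragments
#'
#' The reference set is the frame-0 translation of each CDS (trailing stop
#' stripped); the frameshift set pools the stop-free fragments of the +1 and
#' -1 translations that reach `min_fragment_len` residues. CDSs containing
#' ambiguity codes are skipped with a warning.
#'
#' @param cds A named [Biostrings::DNAStringSet] (or named character vector).
#' @param min_fragment_len Minimum frameshift fragment length (default 60).
#' @param dedup Remove exact duplicate fragment sequences within each set
#'   label (default TRUE, mirroring 100%-identity clustering of the inputs).
#' @return A [FragmentSet-class].
#' @export
translateCdsSet <- function(cds, min_fragment_len = 60L, dedup = TRUE) {
  seqs <- .namedSeqs(cds)
  ids <- names(seqs)
  .check(!is.null(ids) && all(nzchar(ids)), "CDS set must be named")
  parts <- vector("list", 3L * length(seqs))
  k <- 0L
  for (i in seq_along(seqs)) {
    if (!grepl("^[ACGT]+$", seqs[[i]])) {
      warning(sprintf("CDS '%s' contains non-ACGT characters; skipped", ids[[i]]),
              call. = FALSE)
      next
    }
    for (fr in .FRAMES) {
      lab <- if (fr == "0") "reference" else "frameshift"
      tr <- translateFrame(seqs[[i]], fr)
      k <- k + 1L
      parts[[k]] <- splitFragments(tr, min_len = min_fragment_len,
                                   set_label = lab, cds_id = ids[[i]], frame = fr)
    }
  }
  out <- .bindFragmentSets(parts[seq_len(k)])
  if (dedup) out <- dedupExact(out) else out
}

.bindFragmentSets <- function(sets) {
  sets <- Filter(function(s) length(s) > 0L, sets)
  if (!length(sets)) return(FragmentSet())
  dfs <- do.call(rbind, lapply(sets, as.data.frame))
  FragmentSet(aa_seq = dfs$aa_seq, fragment_id = dfs$fragment_id,
              cds_id = dfs$cds_id, frame = dfs$frame,
              nt_start = dfs$nt_start, set_label = dfs$set_label)
}

#' Remove exact duplicate fragment sequences
#'
#' Keeps one representative (the first in input order) per identical
#' amino-acid sequence within each set label, the in-package analogue of
#' clustering at 100% sequence identity. The number of removed duplicates is
#' reported via `message()`.
#'
#' @param fragments A [FragmentSet-class].
#' @return A [FragmentSet-class] with duplicates removed.
#' @export
dedupExact <- function(fragments) {
  if (length(fragments) == 0L) return(fragments)
  key <- paste(setLabels(fragments), as.character(aaSequences(fragments)))
  dup <- duplicated(key)
  if (any(dup))
    message(sprintf("dedupExact: removed %d duplicate fragment(s)", sum(dup)))
  fragments[!dup]
}
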