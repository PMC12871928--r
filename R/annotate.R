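# Repeat-length groups and amino-acid composition profiles.

#' Physico-chemical amino-acid categories
#'
#' The category partition used for composition summaries: hydrophobic
#' (I, F, V, L, W, M, A, Y), hydrophilic (S, T, H, N, Q), negatively charged
#' (E, D), positively charged (K, R), and the singletons Gly, Pro and Cys.
#'
#' @return Named list of character vectors partitioning the 20 amino acids.
#' @export
aaCategories <- function() {
  list(hydrophobic = c("I", "F", "V", "L", "W", "M", "A", "Y"),
       hydrophilic = c("S", "T", "H", "N", "Q"),
       negative = c("E", "D"),
       positive = c("K", "R"),
       Gly = "G", Pro = "P", Cys = "C")
}

#' Assign a tandem repeat to its length group
#'
#' Group 1: single-residue units (homorepeats); group 2: two-residue units;
#' group 3: units of 3-8 residues; group 4: 9-50 residues; group 5: longer
#' than 50 residues.
#'
#' @param unit_len Repeat-unit length in residues (>= 1).
#' @return Integer group, 1-5.
#' @examples
#' assignGroup(7)   # 3
#' assignGroup(51)  # 5
#' @export
assignGroup <- function(unit_len) {
  .check(length(unit_len) == 1L && !is.na(unit_len) && unit_len >= 1,
         "unit_len must be a single value >= 1")
  u <- as.integer(unit_len)
  if (u == 1L) 1L
  else if (u == 2L) 2L
  else if (u <= 8L) 3L
  else if (u <= 50L) 4L
  else 5L
}

# Residues inside the TR intervals of a set, pooled (each residue once;
# regions are non-overlapping after resolveOverlaps).
.pooledResidues <- function(tr_regions, fragments) {
  df <- as.data.frame(tr_regions)
  if (!nrow(df)) return(character())
  seqs <- as.character(aaSequences(fragments))
  names(seqs) <- fragmentIds(fragments)
  .check(all(df$fragment_id %in% names(seqs)),
         "TR regions reference fragments missing from the fragment set")
  .check(all(df$aa_end <= nchar(seqs[df$fragment_id])),
         "TR region extends beyond its fragment")
  unlist(lapply(seq_len(nrow(df)), function(i) {
    .chars(substr(seqs[[df$fragment_id[i]]], df$aa_start[i] + 1L, df$aa_end[i]))
  }), use.names = FALSE)
}

#' Amino-acid composition of a set of TR regions
#'
#' Pools every residue lying inside the TR intervals of the set and computes
#' the per-amino-acid frequency (count of that amino acid / count of all
#' residues in the set) plus category frequencies over the
#' [aaCategories()] partition. Pooling is set-level, not a per-region
#' average.
#'
#' @param tr_regions A [TRRegionSet-class].
#' @param fragments The [FragmentSet-class] the regions live on.
#' @return A `CompositionProfile`: list with `aa` (named frequencies over the
#'   20 amino acids), `categories`, `n_residues` and `empty`. For an empty
#'   region set all frequencies are zero and `empty` is `TRUE`.
#' @export
aaComposition <- function(tr_regions, fragments) {
  res <- .pooledResidues(tr_regions, fragments)
  aa <- stats::setNames(numeric(20L), AA_ALPHABET20)
  n <- length(res)
  if (n > 0L) {
    tab <- table(factor(res, levels = AA_ALPHABET20))
    aa[] <- as.numeric(tab) / n
  }
  cats <- vapply(aaCategories(), function(members) sum(aa[members]), numeric(1))
  structure(list(aa = aa, categories = cats, n_residues = n, empty = n == 0L),
            class = "CompositionProfile")
}

#' @export
print.CompositionProfile <- function(x, ...) {
  cat(sprintf("CompositionProfile over %d residues%s\n", x$n_residues,
              if (x$empty) " (empty)" else ""))
  top <- sort(x$aa, decreasing = TRUE)[1:5]
  cat("  top AAs:", paste(sprintf("%s=%.1f%%", names(top), 100 * top),
                          collapse = " "), "\n")
  invisible(x)
}

#' Composition differences between two profiles
#'
#' Signed differences (`profile_fs - profile_ref`) per amino acid and per
#' category; used to contrast frameshifted against reference TR sets.
#'
#' @param profile_ref,profile_fs Non-empty `CompositionProfile`s from
#'   [aaComposition()].
#' @return List with `aa` and `categories` delta vectors.
#' @export
compositionDelta <- function(profile_ref, profile_fs) {
  .check(!profile_ref$empty && !profile_fs$empty,
         "composition deltas require non-empty profiles")
  list(aa = profile_fs$aa - profile_ref$aa,
       categories = profile_fs$categories - profile_ref$categories)
}

#' Composition tables per set label and group
#'
#' Convenience writer-level summary: one row per (set_label, group,
#' amino acid) with count and percentage, and a companion category table.
#'
#' @param tr_regions A [TRRegionSet-class].
#' @param fragments The [FragmentSet-class] the regions live on.
#' @return List of two data.frames, `aa` and `categories`.
#' @export
compositionTables <- function(tr_regions, fragments) {
  df <- as.data.frame(tr_regions)
  labels <- stats::setNames(setLabels(fragments), fragmentIds(fragments))
  aa_rows <- list(); cat_rows <- list()
  if (nrow(df)) {
    df$set_label <- labels[df$fragment_id]
    for (lab in unique(df$set_label)) for (g in sort(unique(df$group[df$set_label == lab]))) {
      sel <- df$set_label == lab & df$group == g
      prof <- aaComposition(new("TRRegionSet", regions = df[sel, seq_len(8)]),
                            fragments)
      aa_rows[[length(aa_rows) + 1L]] <- data.frame(
        set_label = lab, group = g, aa = names(prof$aa),
        count = round(prof$aa * prof$n_residues),
        percentage = 100 * unname(prof$aa), stringsAsFactors = FALSE)
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        set_label = lab, group = g, category = names(prof$categories),
        percentage = 100 * unname(prof$categories), stringsAsFactors = FALSE)
    }
  }
  list(aa = if (length(aa_rows)) do.call(rbind, aa_rows) else
         data.frame(set_label = character(), group = integer(), aa = character(),
                    count = numeric(), percentage = numeric()),
       categories = if (length(cat_rows)) do.call(rbind, cat_rows) else
         data.frame(set_label = character(), group = integer(),
                    category = character(), percentage = numeric()))
}
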