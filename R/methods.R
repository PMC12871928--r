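# Accessors, show methods and basic verbs for the S4 containers.

#' @describeIn FragmentSet-class Number of fragments.
#' @param x A `FragmentSet`.
#' @export
setMethod("length", "FragmentSet", function(x) length(x@sequences))

#' Fragment accessors
#'
#' `aaSequences()` returns the underlying [Biostrings::AAStringSet];
#' `fragmentIds()`, `cdsIds()`, `fragmentFrames()`, `ntStarts()` and
#' `setLabels()` return the per-fragment metadata vectors.
#'
#' @param x A [FragmentSet-class].
#' @return See each accessor's description.
#' @name fragment-accessors
NULL

#' @rdname fragment-accessors
#' @export
aaSequences <- function(x) x@sequences

#' @rdname fragment-accessors
#' @export
fragmentIds <- function(x) names(x@sequences)

#' @rdname fragment-accessors
#' @export
cdsIds <- function(x) as.character(S4Vectors::mcols(x@sequences)$cds_id)

#' @rdname fragment-accessors
#' @export
fragmentFrames <- function(x) as.character(S4Vectors::mcols(x@sequences)$frame)

#' @rdname fragment-accessors
#' @export
ntStarts <- function(x) as.integer(S4Vectors::mcols(x@sequences)$nt_start)

#' @rdname fragment-accessors
#' @export
setLabels <- function(x) as.character(S4Vectors::mcols(x@sequences)$set_label)

setMethod("show", "FragmentSet", function(object) {
  lab <- setLabels(object)
  cat(sprintf("FragmentSet with %d fragments (%d reference, %d frameshift)\n",
              length(object), sum(lab == "reference"), sum(lab == "frameshift")))
  if (length(object)) {
    lens <- Biostrings::width(object@sequences)
    cat(sprintf("  lengths: %d-%d AA (median %g)\n",
                min(lens), max(lens), stats::median(lens)))
  }
})

#' @param i Row/element indices.
#' @describeIn FragmentSet-class Subset fragments.
#' @export
setMethod("[", "FragmentSet", function(x, i) {
  new("FragmentSet", sequences = x@sequences[i])
})

#' Coerce a FragmentSet to a data.frame index
#'
#' One row per fragment: `fragment_id`, `cds_id`, `frame`, `nt_start`,
#' `set_label`, `length`, `aa_seq`.
#'
#' @param x A [FragmentSet-class].
#' @param ... Ignored.
#' @export
#' @method as.data.frame FragmentSet
as.data.frame.FragmentSet <- function(x, ...) {
  data.frame(fragment_id = fragmentIds(x), cds_id = cdsIds(x),
             frame = fragmentFrames(x), nt_start = ntStarts(x),
             set_label = setLabels(x),
             length = if (length(x)) Biostrings::width(x@sequences) else integer(),
             aa_seq = as.character(x@sequences),
             stringsAsFactors = FALSE, row.names = NULL)
}

setAs("FragmentSet", "data.frame", function(from) as.data.frame.FragmentSet(from))

#' @describeIn TRRegionSet-class Number of regions.
#' @param x A `TRRegionSet`.
#' @export
setMethod("length", "TRRegionSet", function(x) nrow(x@regions))

#' TR region accessors
#'
#' Column accessors for a [TRRegionSet-class]: unit lengths, purities,
#' consensus units and length groups.
#'
#' @param x A [TRRegionSet-class].
#' @name trregion-accessors
NULL

#' @rdname trregion-accessors
#' @export
unitLengths <- function(x) x@regions$unit_len

#' @rdname trregion-accessors
#' @export
purities <- function(x) x@regions$purity

#' @rdname trregion-accessors
#' @export
consensusUnits <- function(x) x@regions$consensus

#' @rdname trregion-accessors
#' @export
trGroups <- function(x) x@regions$group

setMethod("show", "TRRegionSet", function(object) {
  cat(sprintf("TRRegionSet with %d regions\n", length(object)))
  if (length(object)) {
    tab <- table(factor(trGroups(object), levels = 1:5))
    cat("  by group:", paste(sprintf("g%s=%d", names(tab), as.integer(tab)),
                             collapse = " "), "\n")
  }
})

#' @param i Row indices.
#' @describeIn TRRegionSet-class Subset regions.
#' @export
setMethod("[", "TRRegionSet", function(x, i) {
  new("TRRegionSet", regions = x@regions[i, , drop = FALSE])
})

#' @param ... Ignored.
#' @describeIn TRRegionSet-class Region table as a data.frame.
#' @export
#' @method as.data.frame TRRegionSet
as.data.frame.TRRegionSet <- function(x, ...) {
  df <- x@regions
  row.names(df) <- NULL
  df
}

setAs("TRRegionSet", "data.frame", function(from) as.data.frame.TRRegionSet(from))

# rbind-style combination of region sets
.combineTRRegionSets <- function(...) {
  dfs <- lapply(list(...), as.data.frame)
  new("TRRegionSet", regions = do.call(rbind, dfs))
}
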