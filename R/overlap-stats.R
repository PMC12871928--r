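# Overlap of structural annotations (IDR/AR/EAR/TM/domain intervals) with TR
# regions: per-region and set-level coverage, reference-vs-frameshift
# comparison, and hydrophobic-homorepeat length distributions.

.ANNOTATION_KINDS <- c("IDR", "AR", "EAR", "TM", "DOMAIN")

#' Read an annotation interval table
#'
#' Tab-separated file with columns `fragment_id`, `kind`, `aa_start`,
#' `aa_end`. Coordinates are 0-based half-open by default; with
#' `one_based = TRUE` the file is interpreted as 1-based inclusive and
#' converted.
#'
#' @param path File path.
#' @param one_based Input dialect flag (default FALSE).
#' @return data.frame of annotation intervals.
#' @export
readAnnotations <- function(path, one_based = FALSE) {
  .check(file.exists(path), "annotation file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("fragment_id", "kind", "aa_start", "aa_end")
  .check(all(need %in% colnames(df)), "annotation table must have columns %s",
         paste(need, collapse = ", "))
  if (one_based) {
    df$aa_start <- df$aa_start - 1L
  }
  .validateAnnotations(df)
  df
}

.validateAnnotations <- function(ann) {
  .check(all(ann$kind %in% .ANNOTATION_KINDS),
         "unknown annotation kind(s): %s",
         paste(setdiff(unique(ann$kind), .ANNOTATION_KINDS), collapse = ", "))
  .check(all(ann$aa_end > ann$aa_start), "annotation intervals must be non-empty")
  invisible(ann)
}

# Union of one kind's intervals per fragment, as an IRangesList-like lookup.
.annotationUnion <- function(ann, kind) {
  a <- ann[ann$kind == kind, , drop = FALSE]
  lapply(split(a, a$fragment_id), function(d)
    IRanges::reduce(IRanges::IRanges(start = d$aa_start + 1L, end = d$aa_end)))
}

#' Annotation coverage of each TR region
#'
#' For every region, the number of its residues lying inside the union of
#' the given kind's annotation intervals on the same fragment, and the
#' resulting coverage fraction.
#'
#' @param tr_regions A [TRRegionSet-class].
#' @param annotations Annotation data.frame (see [readAnnotations()]).
#' @param kind One of `"IDR"`, `"AR"`, `"EAR"`, `"TM"`, `"DOMAIN"`.
#' @param fragments Optional [FragmentSet-class]; if given, regions are
#'   checked to lie within their fragments.
#' @return data.frame: `fragment_id`, `aa_start`, `aa_end`, `kind`,
#'   `covered_residues`, `coverage`.
#' @export
coverageByTr <- function(tr_regions, annotations, kind, fragments = NULL) {
  .check(kind %in% .ANNOTATION_KINDS, "unknown annotation kind '%s'", kind)
  .validateAnnotations(annotations)
  df <- as.data.frame(tr_regions)
  if (!is.null(fragments) && nrow(df)) {
    lens <- stats::setNames(Biostrings::width(aaSequences(fragments)),
                            fragmentIds(fragments))
    .check(all(df$aa_end <= lens[df$fragment_id]),
           "TR region outside fragment bounds")
  }
  un <- .annotationUnion(annotations, kind)
  covered <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    ir <- un[[df$fragment_id[i]]]
    if (is.null(ir)) next
    tr_ir <- IRanges::IRanges(start = df$aa_start[i] + 1L, end = df$aa_end[i])
    covered[i] <- sum(IRanges::width(IRanges::intersect(tr_ir, ir)))
  }
  data.frame(fragment_id = df$fragment_id, aa_start = df$aa_start,
             aa_end = df$aa_end, kind = rep(kind, nrow(df)),
             covered_residues = covered,
             coverage = if (nrow(df)) covered / (df$aa_end - df$aa_start)
                        else numeric(),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Set-level annotation coverage of TR regions
#'
#' Total annotated residues inside the regions divided by the total region
#' length, in percent -- the length-weighted (not unweighted) mean of the
#' per-region coverages.
#'
#' @inheritParams coverageByTr
#' @return Percentage in \[0, 100\].
#' @export
setCoverage <- function(tr_regions, annotations, kind, fragments = NULL) {
  df <- as.data.frame(tr_regions)
  .check(nrow(df) > 0L, "set coverage undefined for an empty TR set")
  cov <- coverageByTr(tr_regions, annotations, kind, fragments)
  100 * sum(cov$covered_residues) / sum(df$aa_end - df$aa_start)
}

#' Compare per-region coverage distributions (reference vs frameshift)
#'
#' Two-sided Welch t-test on per-region coverage values with the usual star
#' labels: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise. If both samples are constant the comparison is flagged
#' degenerate and no p-value is produced.
#'
#' @param dist_ref,dist_fs Numeric vectors of per-region coverages (n >= 2
#'   each).
#' @return List with `t`, `p`, `stars`, `degenerate`.
#' @export
compareCoverage <- function(dist_ref, dist_fs) {
  .check(length(dist_ref) >= 2L && length(dist_fs) >= 2L,
         "both samples need at least 2 observations")
  if (stats::var(dist_ref) == 0 && stats::var(dist_fs) == 0) {
    return(list(t = NA_real_, p = NA_real_, stars = NA_character_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(dist_ref, dist_fs, alternative = "two.sided",
                      var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       stars = .pStars(tt$p.value), degenerate = FALSE)
}

.pStars <- function(p) {
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Coverage summary per set label, group and annotation kind
#'
#' Per-region coverages summarised (n, mean, median, IQR) for reference and
#' frameshift sets within each group, with the Welch comparison of the two
#' distributions attached to each (group, kind).
#'
#' @param tr_regions A [TRRegionSet-class].
#' @param fragments The [FragmentSet-class] the regions live on.
#' @param annotations Annotation data.frame.
#' @param kinds Kinds to summarise (default the kinds present).
#' @return data.frame with one row per (set_label, group, kind).
#' @export
coverageSummary <- function(tr_regions, fragments, annotations,
                            kinds = unique(annotations$kind)) {
  df <- as.data.frame(tr_regions)
  labels <- stats::setNames(setLabels(fragments), fragmentIds(fragments))
  rows <- list()
  for (kind in kinds) {
    cov <- coverageByTr(tr_regions, annotations, kind, fragments)
    cov$set_label <- labels[cov$fragment_id]
    cov$group <- df$group
    for (g in sort(unique(cov$group))) {
      byset <- split(cov$coverage[cov$group == g],
                     cov$set_label[cov$group == g])
      cmp <- if (all(c("reference", "frameshift") %in% names(byset)) &&
                 all(lengths(byset[c("reference", "frameshift")]) >= 2L))
        compareCoverage(byset$reference, byset$frameshift)
      else list(t = NA_real_, p = NA_real_, stars = NA_character_,
                degenerate = NA)
      for (lab in names(byset)) {
        v <- byset[[lab]]
        rows[[length(rows) + 1L]] <- data.frame(
          set_label = lab, group = g, kind = kind, n = length(v),
          mean = mean(v), median = stats::median(v),
          iqr = stats::IQR(v), t = cmp$t, p = cmp$p, stars = cmp$stars,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(set_label = character(), group = integer(),
                      kind = character(), n = integer(), mean = numeric(),
                      median = numeric(), iqr = numeric(), t = numeric(),
                      p = numeric(), stars = character()))
  }
  do.call(rbind, rows)
}

#' Length distribution of hydrophobic homorepeats
#'
#' Per-length frequency of hydrophobic homorepeats, with the count of all
#' homorepeats of the set (hydrophobic or not) as denominator. Bin summaries
#' give the mean per-length frequency over lengths 11-20 (runs with high
#' aggregation potential) and over lengths >= 21 (runs long enough to form a
#' transmembrane helix).
#'
#' @param homorepeats A [TRRegionSet-class] of unit-length-1 regions.
#' @param hydrophobic_set Residues counted as hydrophobic (default
#'   I, F, V, L, W, M, A, Y).
#' @return List with `freq` (data.frame: `length`, `count_hydrophobic`,
#'   `frequency`), `n_homorepeats`, and `bins` (named numeric:
#'   `aggregation_11_20`, `tm_21_plus`).
#' @export
homorepeatLengthHistogram <- function(homorepeats,
                                      hydrophobic_set = aaCategories()$hydrophobic) {
  df <- as.data.frame(homorepeats)
  .check(nrow(df) > 0L, "empty homorepeat set")
  .check(all(df$unit_len == 1L), "homorepeats must have unit length 1")
  len <- df$aa_end - df$aa_start
  is_h <- df$consensus %in% hydrophobic_set
  n_all <- nrow(df)
  lmax <- max(len)
  lengths_seen <- seq(min(len), lmax)
  counts <- vapply(lengths_seen, function(L) sum(is_h & len == L), integer(1))
  freq <- counts / n_all
  freq_at <- function(L) if (L %in% lengths_seen) freq[lengths_seen == L] else 0
  agg_lengths <- 11:20
  tm_lengths <- if (lmax >= 21L) 21:lmax else integer()
  bins <- c(aggregation_11_20 = mean(vapply(agg_lengths, freq_at, numeric(1))),
            tm_21_plus = if (length(tm_lengths))
              mean(vapply(tm_lengths, freq_at, numeric(1))) else 0)
  list(freq = data.frame(length = lengths_seen, count_hydrophobic = counts,
                         frequency = freq),
       n_homorepeats = n_all, bins = bins)
}
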