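# Tandem-repeat detection on amino-acid fragments.
#
# Three detectors cover the unit-length spectrum: exact single-residue runs
# (homorepeats), short-period arrays (unit 2-8, tolerant of mismatches), and
# k-mer-seeded long repeats (unit >= 9). One shared acceptance criterion ties
# them to the exhaustive smallest-period oracle: a region's purity against the
# phase-majority consensus must reach 1 - max_mismatch_frac, and the emitted
# unit length is the smallest period achieving that on the final interval.

#' Detector configuration
#'
#' Thresholds of the repeat detector. The source study states no numeric
#' thresholds for its repeat finders, so all are exposed here with the
#' package defaults.
#'
#' @param min_run Minimum homorepeat run length (default 5).
#' @param min_purity Minimum purity of an emitted region (default 0.7).
#' @param max_mismatch_frac Maximum tolerated fraction of positions differing
#'   from the phase consensus during region extension (default 0.1).
#' @param min_copies_short Minimum copy number for unit lengths 2-3
#'   (default 2.5).
#' @param min_copies_long Minimum copy number for unit lengths >= 4
#'   (default 2).
#' @param min_unit_identity Minimum identity of a candidate unit to the
#'   running consensus when growing long repeats (default 0.5).
#' @param max_unit Largest unit length searched (default 100).
#' @param seed_k Exact k-mer length used to seed long-repeat candidates
#'   (default 5).
#' @return A named list of class `detectorConfig`.
#' @export
detectorConfig <- function(min_run = 5L, min_purity = 0.7,
                           max_mismatch_frac = 0.1, min_copies_short = 2.5,
                           min_copies_long = 2.0, min_unit_identity = 0.5,
                           max_unit = 100L, seed_k = 5L) {
  .check(min_run >= 2, "min_run must be >= 2")
  .check(min_purity > 0 && min_purity <= 1, "min_purity must be in (0, 1]")
  .check(max_mismatch_frac >= 0 && max_mismatch_frac < 0.5,
         "max_mismatch_frac must be in [0, 0.5)")
  structure(list(min_run = as.integer(min_run), min_purity = min_purity,
                 max_mismatch_frac = max_mismatch_frac,
                 min_copies_short = min_copies_short,
                 min_copies_long = min_copies_long,
                 min_unit_identity = min_unit_identity,
                 max_unit = as.integer(max_unit), seed_k = as.integer(seed_k)),
            class = "detectorConfig")
}

.minCopiesFor <- function(p, cfg) {
  if (p <= 3L) cfg$min_copies_short else cfg$min_copies_long
}

# Phase-majority consensus and purity of a segment at period p.
# Ties in the majority vote are broken alphabetically.
.phasePurity <- function(ch, p) {
  n <- length(ch)
  cons <- character(p)
  matched <- 0L
  for (q in seq_len(p)) {
    idx <- seq.int(q, n, by = p)
    tab <- tabulate(match(ch[idx], LETTERS), nbins = 26L)
    m <- max(tab)
    cons[q] <- LETTERS[which(tab == m)[1L]]
    matched <- matched + m
  }
  list(consensus = paste(cons, collapse = ""), purity = matched / n)
}

#' Exhaustive smallest-period oracle
#'
#' Brute-force reference for the detector: tests every period
#' `p <= length/2` in increasing order and returns the smallest one whose
#' phase-majority consensus reaches purity `>= 1 - max_mismatch_frac`.
#'
#' @param segment Amino-acid string (intended for test-scale segments,
#'   a few hundred residues).
#' @param max_mismatch_frac Mismatch tolerance (default 0.1).
#' @return `list(p, purity, consensus)` or `NULL` if no period qualifies.
#' @examples
#' oracleSmallestPeriod("ABABAB")  # p = 2, purity 1
#' @export
oracleSmallestPeriod <- function(segment, max_mismatch_frac = 0.1) {
  ch <- .chars(segment)
  n <- length(ch)
  thr <- 1 - max_mismatch_frac
  for (p in seq_len(n %/% 2L)) {
    r <- .phasePurity(ch, p)
    if (r$purity >= thr - 1e-9) return(list(p = p, purity = r$purity,
                                     consensus = r$consensus))
  }
  NULL
}

# Finalize a candidate interval [a, b] (1-based inclusive) at candidate
# period p: trim impure edges, reduce to the smallest period meeting the
# purity threshold (the oracle's criterion), and apply emission filters.
# Returns a one-row data.frame or NULL.
.makeRegion <- function(fragment_id, ch, a, b, p, cfg, drop_unit1 = TRUE) {
  thr <- 1 - cfg$max_mismatch_frac
  # Edge cleanup against the consensus of the candidate interval: drop an end
  # while it mismatches or its flanking 2p-window is majority mismatch (the
  # purity budget of a long pure region can drag in short stretches of
  # unrelated sequence at the edges).
  r <- .phasePurity(ch[a:b], p)
  cons <- .chars(r$consensus)
  mism <- ch[a:b] != cons[(seq.int(a, b) - a) %% p + 1L]
  w <- 2L * p
  repeat {
    len <- b - a + 1L
    if (len <= 2L * p) break
    tail_win <- mism[(len - min(w, len) + 1L):len]
    if (mism[len] || mean(tail_win) > 0.5) {
      b <- b - 1L
      mism <- mism[-len]
    } else break
  }
  repeat {
    len <- b - a + 1L
    if (len <= 2L * p) break
    head_win <- mism[seq_len(min(w, len))]
    if (mism[1L] || mean(head_win) > 0.5) {
      a <- a + 1L
      mism <- mism[-1L]
      cons <- c(cons[-1L], cons[1L])
    } else break
  }
  len <- b - a + 1L
  if (len < 2L * p) return(NULL)
  seg <- ch[a:b]
  final_p <- p
  final <- .phasePurity(seg, p)
  for (pp in seq_len(p)) {             # smallest period passing the threshold
    rr <- if (pp == p) final else .phasePurity(seg, pp)
    if (rr$purity >= thr - 1e-9) {
      final_p <- pp
      final <- rr
      break
    }
  }
  if (drop_unit1 && final_p == 1L) return(NULL)       # homorepeat territory
  if (len / final_p < .minCopiesFor(final_p, cfg)) return(NULL)
  if (final$purity < cfg$min_purity) return(NULL)
  if (.isStringPeriodic(final$consensus)) return(NULL)  # degenerate consensus
  data.frame(fragment_id = fragment_id, aa_start = a - 1L, aa_end = b,
             unit_len = final_p, consensus = final$consensus,
             purity = final$purity, stringsAsFactors = FALSE)
}

#' Find homorepeats (single-residue runs)
#'
#' Maximal runs of one identical residue with length at least `min_run`;
#' unit length 1, purity 1.
#'
#' @param aa_seq Amino-acid string.
#' @param min_run Minimum run length (default 5).
#' @param fragment_id Fragment identifier recorded in the output.
#' @return A [TRRegionSet-class].
#' @examples
#' findHomorepeats("MAAAAAK", min_run = 5)
#' @export
findHomorepeats <- function(aa_seq, min_run = 5L, fragment_id = "frag") {
  .check(min_run >= 2, "min_run must be >= 2")
  ch <- .chars(aa_seq)
  if (!length(ch)) return(TRRegionSet())
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths       # 0-based starts
  keep <- r$lengths >= min_run
  TRRegionSet(fragment_id = rep(fragment_id, sum(keep)),
              aa_start = starts[keep], aa_end = ends[keep],
              unit_len = rep(1L, sum(keep)), consensus = r$values[keep],
              purity = rep(1, sum(keep)))
}

#' Find short-period tandem arrays (unit lengths 2-8)
#'
#' For each period p, regions are seeded where two consecutive units agree
#' (purity of the 2p-window meets `1 - max_mismatch_frac`) and extended
#' greedily to the right to the largest interval whose purity against the
#' phase-majority consensus stays above that threshold; impure edges are then
#' trimmed and the unit reduced to its primitive period.
#'
#' @param aa_seq Amino-acid string.
#' @param unit_len_range Integer vector of periods to test (default `2:8`).
#' @param min_copies Optional single minimum copy number overriding the
#'   per-period defaults in `config`.
#' @param max_mismatch_frac Mismatch tolerance (default from `config`).
#' @param config A [detectorConfig()].
#' @param fragment_id Fragment identifier recorded in the output.
#' @return A [TRRegionSet-class] (possibly overlapping across periods; pass
#'   through [resolveOverlaps()] to obtain a final non-overlapping set).
#' @export
findShortPeriod <- function(aa_seq, unit_len_range = 2:8, min_copies = NULL,
                            max_mismatch_frac = NULL,
                            config = detectorConfig(), fragment_id = "frag") {
  .check(all(unit_len_range >= 2 & unit_len_range <= 8),
         "short-period units must lie in 2..8")
  cfg <- config
  if (!is.null(max_mismatch_frac)) cfg$max_mismatch_frac <- max_mismatch_frac
  if (!is.null(min_copies)) {
    cfg$min_copies_short <- min_copies
    cfg$min_copies_long <- min_copies
  }
  ch <- .chars(aa_seq)
  n <- length(ch)
  thr <- 1 - cfg$max_mismatch_frac
  rows <- list()
  for (p in sort(unique(as.integer(unit_len_range)))) {
    if (n < 2L * p) next
    # seed score: number of agreeing positions between adjacent units
    eq <- as.integer(ch[seq_len(n - p)] == ch[(p + 1L):n])
    win <- cumsum(eq)
    win <- c(win[p], diff(win, lag = p))        # rolling sum over p pairs
    need <- ceiling(p * (2 * thr - 1) - 1e-9)
    seeds <- which(win >= need)                 # candidate starts (1-based)
    cursor <- 1L
    for (i in seeds) {
      if (i < cursor) next
      reg <- .extendShort(ch, i, p, thr, n)
      if (is.null(reg)) {
        cursor <- i + 1L
        next
      }
      row <- .makeRegion(fragment_id, ch, reg[1L], reg[2L], p, cfg)
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      cursor <- reg[2L] + 1L
    }
  }
  .regionsToSet(rows)
}

# Greedy rightward extension from seed i at period p: returns the largest
# b such that purity([i, b]) >= thr, or NULL. Maintains per-phase letter
# counts incrementally; the purity deficit (positions not matching the phase
# majority) is non-decreasing, which bounds the lookahead.
.extendShort <- function(ch, i, p, thr, n) {
  counts <- matrix(0L, nrow = p, ncol = 26L)
  phase_max <- integer(p)
  sum_max <- 0L
  max_deficit <- (1 - thr) * (n - i + 1L) + 1e-9
  last_valid <- 0L
  b <- i
  while (b <= n) {
    q <- (b - i) %% p + 1L
    l <- match(ch[b], LETTERS)
    counts[q, l] <- counts[q, l] + 1L
    if (counts[q, l] > phase_max[q]) {
      phase_max[q] <- counts[q, l]
      sum_max <- sum_max + 1L
    }
    len <- b - i + 1L
    deficit <- len - sum_max
    if (deficit > max_deficit) break
    if (len >= 2L * p && deficit <= (1 - thr) * len + 1e-9) last_valid <- b
    b <- b + 1L
  }
  if (last_valid == 0L) NULL else c(i, last_valid)
}

#' Find long tandem repeats (unit lengths >= 9) via k-mer seeding
#'
#' Candidate periods are proposed wherever an exact k-mer recurs at a
#' distance d within `unit_len_range`; the region is grown unit-by-unit in
#' both directions while each unit's identity to the running per-column
#' majority consensus stays at or above `min_unit_identity`, then reduced to
#' its primitive period and filtered like all other regions.
#'
#' @param aa_seq Amino-acid string.
#' @param unit_len_range Periods to consider (default `9:config$max_unit`).
#' @param seed_k Seed k-mer length (default from `config`).
#' @param config A [detectorConfig()].
#' @param fragment_id Fragment identifier recorded in the output.
#' @return A [TRRegionSet-class].
#' @export
findLongRepeats <- function(aa_seq, unit_len_range = NULL, seed_k = NULL,
                            config = detectorConfig(), fragment_id = "frag") {
  cfg <- config
  if (!is.null(seed_k)) cfg$seed_k <- as.integer(seed_k)
  if (is.null(unit_len_range)) unit_len_range <- 9:cfg$max_unit
  ch <- .chars(aa_seq)
  n <- length(ch)
  k <- cfg$seed_k
  dmin <- min(unit_len_range)
  dmax <- min(max(unit_len_range), n %/% 2L)
  if (n < 2L * dmin + k - 1L) return(TRRegionSet())
  kmers <- substring(aa_seq, seq_len(n - k + 1L), k:n)
  occ <- split(seq_len(n - k + 1L), kmers)
  cand <- list()
  for (pos in occ) {
    if (length(pos) < 2L) next
    d <- diff(pos)
    ok <- which(d >= dmin & d <= dmax)
    for (j in ok) cand[[length(cand) + 1L]] <- c(pos[j], d[j])
  }
  if (!length(cand)) return(TRRegionSet())
  cand <- unique(do.call(rbind, cand))
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  rows <- list()
  seen <- character()
  for (r in seq_len(nrow(cand))) {
    grown <- .growLongRepeat(ch, cand[r, 1L], cand[r, 2L], cfg, n)
    if (is.null(grown)) next
    key <- paste(grown, collapse = ":")
    if (key %in% seen) next
    seen <- c(seen, key)
    row <- .makeRegion(fragment_id, ch, grown[1L], grown[2L],
                       as.integer(cand[r, 2L]), cfg)
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  resolveOverlaps(as.data.frame(.regionsToSet(rows)))
}

# Grow whole units of length d around anchor a while each added unit matches
# the running consensus at >= min_unit_identity. Returns c(start, end)
# (1-based inclusive, whole units) or NULL.
.growLongRepeat <- function(ch, a, d, cfg, n) {
  if (a + 2L * d - 1L > n) return(NULL)
  counts <- matrix(0L, nrow = d, ncol = 26L)
  addUnit <- function(u) {
    idx <- cbind(seq_len(d), match(u, LETTERS))
    counts[idx] <<- counts[idx] + 1L
  }
  consLetters <- function() LETTERS[apply(counts, 1L, which.max)]
  u0 <- ch[a:(a + d - 1L)]
  u1 <- ch[(a + d):(a + 2L * d - 1L)]
  if (mean(u0 == u1) < cfg$min_unit_identity) return(NULL)
  addUnit(u0); addUnit(u1)
  right <- a + 2L * d
  repeat {
    if (right + d - 1L > n) break
    u <- ch[right:(right + d - 1L)]
    if (mean(u == consLetters()) < cfg$min_unit_identity) break
    addUnit(u)
    right <- right + d
  }
  left <- a
  repeat {
    if (left - d < 1L) break
    u <- ch[(left - d):(left - 1L)]
    if (mean(u == consLetters()) < cfg$min_unit_identity) break
    addUnit(u)
    left <- left - d
  }
  c(left, right - 1L)
}

#' Resolve overlapping repeat regions on one fragment
#'
#' Candidates are ranked deterministically by (1) higher purity, (2) smaller
#' unit length, (3) smaller start and accepted greedily. A lower-ranked
#' candidate overlapping an accepted region is not discarded outright: when
#' the fragment sequences are supplied, it is trimmed to its largest
#' uncovered subinterval, re-derived (consensus, purity, primitive unit) and
#' re-validated against the emission thresholds; without sequences it is
#' dropped. Exact duplicates are removed first.
#'
#' @param regions A [TRRegionSet-class] (or its data.frame form); resolution
#'   is applied per fragment.
#' @param fragments Optional [FragmentSet-class] (or named character vector
#'   of fragment sequences) enabling trim-and-revalidate resolution.
#' @param config A [detectorConfig()], used when re-validating trimmed
#'   regions.
#' @return A non-overlapping [TRRegionSet-class] sorted by fragment,
#'   start and unit length.
#' @export
resolveOverlaps <- function(regions, fragments = NULL,
                            config = detectorConfig()) {
  df <- if (is(regions, "TRRegionSet")) as.data.frame(regions) else regions
  if (!nrow(df)) return(TRRegionSet())
  seqs <- NULL
  if (!is.null(fragments)) {
    seqs <- if (is(fragments, "FragmentSet"))
      stats::setNames(as.character(aaSequences(fragments)),
                      fragmentIds(fragments))
    else fragments
  }
  df <- unique(df[, c("fragment_id", "aa_start", "aa_end", "unit_len",
                      "consensus", "purity")])
  out <- lapply(split(df, df$fragment_id), function(d) {
    fid <- d$fragment_id[1L]
    ch <- if (!is.null(seqs) && fid %in% names(seqs)) .chars(seqs[[fid]])
          else NULL
    d <- d[order(-d$purity, d$unit_len, d$aa_start), , drop = FALSE]
    acc <- d[0L, , drop = FALSE]
    occupied <- logical(if (is.null(ch)) max(d$aa_end) else length(ch))
    for (i in seq_len(nrow(d))) {
      span <- seq.int(d$aa_start[i] + 1L, d$aa_end[i])
      if (!any(occupied[span])) {
        acc <- rbind(acc, d[i, ])
        occupied[span] <- TRUE
        next
      }
      if (is.null(ch)) next
      free <- span[!occupied[span]]
      if (!length(free)) next
      # largest contiguous uncovered piece, leftmost on ties
      pieces <- split(free, cumsum(c(TRUE, diff(free) != 1L)))
      lens <- lengths(pieces)
      piece <- pieces[[which.max(lens)]]
      if (length(piece) < 2L * d$unit_len[i]) next
      row <- .makeRegion(fid, ch, piece[1L], piece[length(piece)],
                         d$unit_len[i], config,
                         drop_unit1 = d$unit_len[i] > 1L)
      if (is.null(row)) next
      # a trimmed remainder was never independently seeded: it must stand on
      # its own at the extension purity threshold, not just the floor
      if (row$purity < 1 - config$max_mismatch_frac - 1e-9) next
      if (row$unit_len == 1L && row$aa_end - row$aa_start < config$min_run) next
      span2 <- seq.int(row$aa_start + 1L, row$aa_end)
      if (any(occupied[span2])) next
      acc <- rbind(acc, row[, colnames(d)])
      occupied[span2] <- TRUE
    }
    acc
  })
  df <- do.call(rbind, out)
  df <- df[order(df$fragment_id, df$aa_start, df$unit_len), , drop = FALSE]
  TRRegionSet(fragment_id = df$fragment_id, aa_start = df$aa_start,
              aa_end = df$aa_end, unit_len = df$unit_len,
              consensus = df$consensus, purity = df$purity)
}

.regionsToSet <- function(rows) {
  if (!length(rows)) return(TRRegionSet())
  df <- unique(do.call(rbind, rows))
  TRRegionSet(fragment_id = df$fragment_id, aa_start = df$aa_start,
              aa_end = df$aa_end, unit_len = df$unit_len,
              consensus = df$consensus, purity = df$purity)
}

#' Detect tandem repeats on every fragment of a set
#'
#' Runs the homorepeat, short-period and long-repeat detectors on each
#' fragment and resolves overlaps into one non-overlapping region set.
#' Output is deterministic: regions are sorted by fragment id, start and
#' unit length.
#'
#' @param fragments A [FragmentSet-class].
#' @param config A [detectorConfig()].
#' @return A [TRRegionSet-class].
#' @export
detectRepeats <- function(fragments, config = detectorConfig()) {
  if (length(fragments) == 0L) return(TRRegionSet())
  ids <- fragmentIds(fragments)
  seqs <- as.character(aaSequences(fragments))
  per_frag <- lapply(seq_along(ids), function(i) {
    hr <- as.data.frame(findHomorepeats(seqs[[i]], min_run = config$min_run,
                                        fragment_id = ids[[i]]))
    sp <- as.data.frame(findShortPeriod(seqs[[i]], config = config,
                                        fragment_id = ids[[i]]))
    lr <- as.data.frame(findLongRepeats(seqs[[i]], config = config,
                                        fragment_id = ids[[i]]))
    rbind(hr, sp, lr)
  })
  all_df <- do.call(rbind, per_frag)
  if (!nrow(all_df)) return(TRRegionSet())
  resolveOverlaps(all_df, fragments = fragments, config = config)
}
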