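# Synthetic CDS sets with planted, ground-truthed DNA-level tandem repeats.
#
# The generator emulates the shape of the study inputs -- coding sequences
# containing homopolymeric codon runs, short microsatellite-like arrays and
# long tandem duplications, over a configurable background codon usage --
# so that every downstream stage can be exercised against a known truth.

#' Default background codon usage
#'
#' Uniform over the 61 sense codons; the three stop codons have probability
#' zero (interior positions of a coding sequence).
#'
#' @return Named numeric vector over the 64 codons summing to 1.
#' @export
defaultCodonUsage <- function() {
  p <- stats::setNames(numeric(64L), names(codonTable()))
  sense <- .senseCodons()
  p[sense] <- 1 / length(sense)
  p
}

#' Specification of one planted repeat
#'
#' @param kind `"homopolymer_codon"` (unit is one codon, 3 nt),
#'   `"short_unit_nt"` (unit 1-24 nt) or `"long_duplication"` (unit
#'   27-300 nt).
#' @param unit DNA unit string over ACGT.
#' @param copies Number of tandem copies (>= 2).
#' @param mutation_rate Per-nucleotide substitution probability applied to
#'   the planted array after assembly (default 0).
#' @param position_mode `"random"` or `"fixed"`.
#' @param offset Codon-boundary insertion offset when `position_mode` is
#'   `"fixed"`.
#' @return A list of class `plantSpec`.
#' @export
plantSpec <- function(kind = c("homopolymer_codon", "short_unit_nt",
                               "long_duplication"),
                      unit, copies, mutation_rate = 0,
                      position_mode = c("random", "fixed"), offset = NA_integer_) {
  kind <- match.arg(kind)
  position_mode <- match.arg(position_mode)
  .check(is.character(unit) && length(unit) == 1L && grepl("^[ACGT]+$", unit),
         "PlantSpec(%s, '%s'): unit must be a non-empty DNA string over ACGT",
         kind, as.character(unit)[1L])
  ul <- nchar(unit)
  ok <- switch(kind, homopolymer_codon = ul == 3L,
               short_unit_nt = ul >= 1L && ul <= 24L,
               long_duplication = ul >= 27L && ul <= 300L)
  .check(ok, "PlantSpec(%s, '%s'): unit length %d outside the allowed range",
         kind, unit, ul)
  .check(copies >= 2, "PlantSpec(%s, '%s'): copies must be >= 2", kind, unit)
  .check(mutation_rate >= 0 && mutation_rate <= 1,
         "mutation_rate must be a probability")
  structure(list(kind = kind, unit = unit, copies = as.integer(copies),
                 mutation_rate = mutation_rate, position_mode = position_mode,
                 offset = as.integer(offset)),
            class = "plantSpec")
}

#' Simulation configuration
#'
#' @param n_sequences Number of CDSs to generate (default 20).
#' @param background_codon_usage Codon probability vector (names = codons,
#'   non-negative, summing to 1 within 1e-9). Interior codons are drawn from
#'   its restriction to sense codons; each CDS ends with a TAA stop.
#' @param planted_repeats List of [plantSpec()]s; every CDS receives each
#'   spec once, at non-overlapping codon-aligned positions.
#' @param min_cds_len_nt Minimum CDS length in nucleotides (default 300).
#' @param seed Integer seed driving all randomness of the generator.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(n_sequences = 20L,
                      background_codon_usage = defaultCodonUsage(),
                      planted_repeats = list(), min_cds_len_nt = 300L,
                      seed = 1L) {
  p <- background_codon_usage
  .check(!is.null(names(p)) && all(names(p) %in% names(codonTable())),
         "background_codon_usage must be named by codons")
  .check(all(p >= 0), "background probabilities must be non-negative")
  .check(abs(sum(p) - 1) <= 1e-9, "background probabilities must sum to 1")
  for (ps in planted_repeats)
    .check(inherits(ps, "plantSpec"), "planted_repeats must be plantSpec objects")
  structure(list(n_sequences = as.integer(n_sequences),
                 background_codon_usage = p,
                 planted_repeats = planted_repeats,
                 min_cds_len_nt = as.integer(min_cds_len_nt),
                 seed = as.integer(seed)),
            class = "simConfig")
}

# Sample n interior codons from the sense-codon restriction of the usage.
.sampleCodons <- function(n, usage) {
  sense <- .senseCodons()
  p <- usage[sense]
  .check(sum(p) > 0, "background usage has no mass on sense codons")
  sample(sense, n, replace = TRUE, prob = p / sum(p))
}

#' Generate a CDS set with planted repeats and its ground truth
#'
#' Each CDS is assembled from i.i.d. background codons with every planted
#' array inserted once at a codon-aligned position (distinct positions per
#' CDS; arrays whose length is not a multiple of 3 are followed by 1-2
#' random pad bases to keep the CDS codon-aligned). Per-nucleotide
#' substitutions are applied to each array at its `mutation_rate`, then a
#' TAA stop closes the CDS. For every planted array and every frame in which
#' its translation is stop-free, the ground truth records the repeat's
#' residue interval in that frame's full translation (0-based half-open) and
#' the primitive amino-acid unit length of the unmutated repeat.
#'
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [simConfig()].
#' @return List with `cds` (named [Biostrings::DNAStringSet]) and
#'   `ground_truth` (data.frame: `cds_id`, `frame`, `aa_start`, `aa_end`,
#'   `unit_len_aa`).
#' @export
generateCdsSet <- function(config) {
  .check(inherits(config, "simConfig"), "config must come from simConfig()")
  set.seed(config$seed)
  specs <- config$planted_repeats
  plant_nt <- vapply(specs, function(s) {
    len <- nchar(s$unit) * s$copies
    len + (3L - len %% 3L) %% 3L      # with pad
  }, integer(1))
  seqs <- character(config$n_sequences)
  gt <- list()
  for (ci in seq_len(config$n_sequences)) {
    cds_id <- sprintf("cds%03d", ci)
    n_bg <- max(ceiling((config$min_cds_len_nt - sum(plant_nt)) / 3),
                length(specs) + 2L, 10L)
    bg <- .sampleCodons(n_bg, config$background_codon_usage)
    # codon-boundary insertion slots (0 .. n_bg), distinct per plant
    slots <- integer(0)
    if (length(specs)) {
      fixed <- vapply(specs, function(s) s$position_mode == "fixed", logical(1))
      slots <- integer(length(specs))
      slots[fixed] <- vapply(specs[fixed], function(s) s$offset, integer(1))
      .check(all(slots[fixed] >= 0L & slots[fixed] <= n_bg),
             "fixed offset outside the background (0..%d codons)", n_bg)
      free <- setdiff(0:n_bg, slots[fixed])
      if (any(!fixed))
        slots[!fixed] <- sort(free[sample.int(length(free), sum(!fixed))])
    }
    ord <- order(slots)
    pieces <- character(0)
    spans <- matrix(0L, nrow = length(specs), ncol = 2L)  # nt spans, 0-based
    prev_slot <- 0L
    pos <- 0L
    clean_pieces <- character(0)
    for (j in ord) {
      s <- specs[[j]]
      before <- paste(bg[seq_len(slots[j] - prev_slot) + prev_slot],
                      collapse = "")
      arr <- strrep(s$unit, s$copies)
      arr_len <- nchar(arr)
      pad_n <- (3L - arr_len %% 3L) %% 3L
      pad <- if (pad_n) paste(sample(c("A", "C", "G", "T"), pad_n,
                                     replace = TRUE), collapse = "") else ""
      mut <- .mutateArray(arr, s$mutation_rate)
      pos <- pos + nchar(before)
      spans[j, ] <- c(pos, pos + arr_len)
      pos <- pos + arr_len + pad_n
      pieces <- c(pieces, before, mut, pad)
      clean_pieces <- c(clean_pieces, before, arr, pad)
      prev_slot <- slots[j]
    }
    tail_bg <- if (prev_slot < n_bg)
      paste(bg[seq.int(prev_slot + 1L, n_bg)], collapse = "") else ""
    cds <- paste(c(pieces, tail_bg, "TAA"), collapse = "")
    clean <- paste(c(clean_pieces, tail_bg, "TAA"), collapse = "")
    seqs[ci] <- cds
    for (j in seq_along(specs))
      gt[[length(gt) + 1L]] <- .groundTruthRows(cds_id, cds, clean,
                                                spans[j, 1L], spans[j, 2L])
  }
  names(seqs) <- sprintf("cds%03d", seq_len(config$n_sequences))
  cds_set <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(cds_set) <- S4Vectors::DataFrame(
    species = rep("synthetic", length(cds_set)))
  gt_df <- if (length(gt)) do.call(rbind, gt) else
    data.frame(cds_id = character(), frame = character(),
               aa_start = integer(), aa_end = integer(),
               unit_len_aa = integer())
  list(cds = cds_set, ground_truth = gt_df)
}

.mutateArray <- function(arr, rate) {
  if (rate <= 0) return(arr)
  ch <- .chars(arr)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# Ground-truth rows of one planted array over the three frames. The aa unit
# length is the primitive period of the unmutated translation of the span;
# frames where the (mutated) translation contains a stop are dropped.
.groundTruthRows <- function(cds_id, cds, clean_cds, nt_s, nt_e) {
  rows <- list()
  for (fr in .FRAMES) {
    off <- .frameOffset(fr)
    j0 <- as.integer(ceiling((nt_s - off) / 3))
    j1 <- as.integer(floor((nt_e - off) / 3))
    if (j0 < 0L) j0 <- 0L
    n_aa <- (nchar(cds) - off) %/% 3L
    if (j1 > n_aa) j1 <- n_aa
    if (j1 - j0 < 2L) next
    tr <- translateFrame(cds, fr)
    span <- substr(tr, j0 + 1L, j1)
    if (grepl("*", span, fixed = TRUE)) next
    clean_span <- substr(translateFrame(clean_cds, fr), j0 + 1L, j1)
    u_aa <- .exactPeriod(clean_span)
    if ((j1 - j0) < 2L * u_aa) next
    rows[[length(rows) + 1L]] <- data.frame(
      cds_id = cds_id, frame = fr, aa_start = j0, aa_end = j1,
      unit_len_aa = u_aa, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(cds_id = character(), frame = character(), aa_start = integer(),
               aa_end = integer(), unit_len_aa = integer())
}

#' Write a generated fixture to disk
#'
#' FASTA of the CDSs (wrapped at 60 characters) plus a tab-separated
#' ground-truth table (`cds_id`, `frame`, `aa_start`, `aa_end`,
#' `unit_len_aa`; 0-based half-open coordinates).
#'
#' @param cds Named [Biostrings::DNAStringSet].
#' @param ground_truth Ground-truth data.frame from [generateCdsSet()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector with paths `fasta` and `ground_truth`.
#' @export
writeFixture <- function(cds, ground_truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(out_dir, "cds.fasta")
  tsv <- file.path(out_dir, "ground_truth.tsv")
  tryCatch({
    Biostrings::writeXStringSet(cds, fa, width = 60L)
    utils::write.table(ground_truth, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, error = function(e) stop(sprintf("failed writing fixture to '%s': %s",
                                      out_dir, conditionMessage(e)),
                              call. = FALSE))
  c(fasta = fa, ground_truth = tsv)
}

#' Read a CDS FASTA
#'
#' @param path FASTA file of coding sequences.
#' @return Named [Biostrings::DNAStringSet].
#' @export
readCdsFasta <- function(path) {
  .check(file.exists(path), "FASTA not found: %s", path)
  Biostrings::readDNAStringSet(path)
}

#' Generate plausible annotation intervals for a fragment set
#'
#' Random typed intervals (IDR/AR/... per `kinds`) on each fragment so the
#' coverage machinery can be exercised without external structure
#' predictors. With `bias_regions` given, a configurable share of the
#' intervals is centred on detected TR regions, emulating the enrichment of
#' disorder in low-complexity repeats.
#'
#' @param fragments A [FragmentSet-class].
#' @param kinds Annotation kinds to emit (default IDR and AR).
#' @param lambda Mean number of intervals per fragment and kind (Poisson).
#' @param mean_len Mean interval length, residues (geometric, min 5).
#' @param bias_regions Optional [TRRegionSet-class] to bias intervals onto.
#' @param bias_prob Probability that an interval is TR-centred when a TR is
#'   available on the fragment (default 0.5).
#' @param seed Integer seed.
#' @return Annotation data.frame (`fragment_id`, `kind`, `aa_start`,
#'   `aa_end`), 0-based half-open.
#' @export
generateAnnotations <- function(fragments, kinds = c("IDR", "AR"),
                                lambda = 1.5, mean_len = 30, bias_regions = NULL,
                                bias_prob = 0.5, seed = 1L) {
  set.seed(seed)
  ids <- fragmentIds(fragments)
  lens <- Biostrings::width(aaSequences(fragments))
  trs <- if (!is.null(bias_regions)) as.data.frame(bias_regions) else NULL
  rows <- list()
  for (i in seq_along(ids)) {
    for (kind in kinds) {
      k <- stats::rpois(1L, lambda)
      for (r in seq_len(k)) {
        L <- min(5L + stats::rgeom(1L, 1 / max(mean_len - 5, 1)), lens[i])
        tr_here <- if (!is.null(trs)) trs[trs$fragment_id == ids[i], ] else NULL
        if (!is.null(tr_here) && nrow(tr_here) && stats::runif(1L) < bias_prob) {
          j <- sample.int(nrow(tr_here), 1L)
          centre <- (tr_here$aa_start[j] + tr_here$aa_end[j]) %/% 2L
          s <- max(0L, centre - L %/% 2L)
        } else {
          s <- sample.int(max(lens[i] - L + 1L, 1L), 1L) - 1L
        }
        e <- min(s + L, lens[i])
        if (e > s)
          rows[[length(rows) + 1L]] <- data.frame(
            fragment_id = ids[i], kind = kind, aa_start = s, aa_end = e,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(fragment_id = character(), kind = character(),
                      aa_start = integer(), aa_end = integer()))
  }
  do.call(rbind, rows)
}

#' Evaluate planted-repeat recovery
#'
#' Maps detected TR regions back to full-frame coordinates via each
#' fragment's `nt_start` and scores every ground-truth repeat by its best
#' Jaccard overlap with a detected region on the same CDS and frame.
#'
#' @param tr_regions Detected [TRRegionSet-class].
#' @param fragments The [FragmentSet-class] the detections live on.
#' @param ground_truth Ground-truth data.frame from [generateCdsSet()].
#' @param jaccard_min Overlap threshold counting as recovered (default 0.9).
#' @return List with `per_truth` (ground truth + `best_jaccard` +
#'   `recovered`) and `recall`.
#' @export
evaluateRecovery <- function(tr_regions, fragments, ground_truth,
                             jaccard_min = 0.9) {
  det <- as.data.frame(tr_regions)
  meta <- as.data.frame(fragments)
  det <- merge(det, meta[, c("fragment_id", "cds_id", "frame", "nt_start")],
               by = "fragment_id", sort = FALSE)
  off <- vapply(det$frame, .frameOffset, integer(1))
  det$fr_start <- (det$nt_start - off) %/% 3L + det$aa_start
  det$fr_end <- (det$nt_start - off) %/% 3L + det$aa_end
  gt <- ground_truth
  best <- numeric(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    d <- det[det$cds_id == gt$cds_id[i] & det$frame == gt$frame[i], ,
             drop = FALSE]
    if (!nrow(d)) next
    inter <- pmax(0L, pmin(d$fr_end, gt$aa_end[i]) -
                    pmax(d$fr_start, gt$aa_start[i]))
    uni <- (d$fr_end - d$fr_start) + (gt$aa_end[i] - gt$aa_start[i]) - inter
    best[i] <- max(inter / uni)
  }
  gt$best_jaccard <- best
  gt$recovered <- best >= jaccard_min
  list(per_truth = gt,
       recall = if (nrow(gt)) mean(gt$recovered) else NA_real_)
}
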