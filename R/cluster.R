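# Consensus frequency profiles of TR units and density-based motif clustering.

#' Build a per-position consensus profile of a tandem repeat
#'
#' The region is chopped into in-phase unit windows (a final partial window
#' is ignored) and per-position amino-acid frequencies are computed over the
#' windows. The cyclic phase of a repeat unit is arbitrary, so the profile is
#' rotated to a canonical phase: the lexicographically smallest cyclic
#' rotation of the consensus string. The flattened matrix (positions in
#' canonical order, amino acids alphabetical within each position) is the
#' clustering vector.
#'
#' @param tr One region: a one-row data.frame (or list) with `aa_start`,
#'   `aa_end`, `unit_len` and optionally `fragment_id`.
#' @param fragment The amino-acid sequence of the fragment (character).
#' @return A `ConsensusProfile` list: `tr_ref`, `unit_len`, `matrix`
#'   (`unit_len` x 20, rows sum to 1), `consensus`, `canonical_consensus`,
#'   `vector` (length `unit_len * 20`).
#' @examples
#' p <- buildProfile(list(aa_start = 0, aa_end = 6, unit_len = 2), "SRSRSR")
#' p$canonical_consensus  # "RS"
#' @export
buildProfile <- function(tr, fragment) {
  u <- as.integer(tr$unit_len)
  a <- as.integer(tr$aa_start)
  b <- as.integer(tr$aa_end)
  seg <- substr(as.character(fragment), a + 1L, b)
  n_win <- nchar(seg) %/% u
  .check(n_win >= 2L, "profile requires at least 2 complete unit windows")
  ch <- .chars(substr(seg, 1L, n_win * u))
  mat <- matrix(0, nrow = u, ncol = 20L,
                dimnames = list(NULL, AA_ALPHABET20))
  cons <- character(u)
  for (q in seq_len(u)) {
    letters <- ch[seq.int(q, n_win * u, by = u)]
    tab <- table(factor(letters, levels = AA_ALPHABET20))
    mat[q, ] <- as.numeric(tab) / n_win
    cons[q] <- .majorityLetter(letters)
  }
  consensus <- paste(cons, collapse = "")
  rot <- .canonicalRotation(consensus)
  idx <- ((seq_len(u) - 1L + rot) %% u) + 1L
  mat <- mat[idx, , drop = FALSE]
  canonical <- paste(cons[idx], collapse = "")
  list(tr_ref = if (!is.null(tr$fragment_id))
         sprintf("%s:%d-%d", tr$fragment_id, a, b) else sprintf("%d-%d", a, b),
       unit_len = u, matrix = mat, consensus = consensus,
       canonical_consensus = canonical,
       vector = as.vector(t(mat)))
}

# 0-based offset of the lexicographically smallest cyclic rotation.
.canonicalRotation <- function(s) {
  u <- nchar(s)
  if (u == 1L) return(0L)
  rots <- vapply(seq_len(u) - 1L, function(r)
    paste0(substr(s, r + 1L, u), substr(s, 1L, r)), character(1))
  which.min(rank(rots, ties.method = "first")) - 1L
  }

#' Build profiles for every region of a set
#'
#' @param tr_regions A [TRRegionSet-class].
#' @param fragments The [FragmentSet-class] the regions live on.
#' @return List of `ConsensusProfile`s (regions with fewer than two complete
#'   windows are skipped).
#' @export
buildProfiles <- function(tr_regions, fragments) {
  df <- as.data.frame(tr_regions)
  seqs <- stats::setNames(as.character(aaSequences(fragments)),
                          fragmentIds(fragments))
  out <- list()
  for (i in seq_len(nrow(df))) {
    if ((df$aa_end[i] - df$aa_start[i]) %/% df$unit_len[i] < 2L) next
    out[[length(out) + 1L]] <- buildProfile(df[i, ], seqs[[df$fragment_id[i]]])
  }
  out
}

# Plain DBSCAN over a point matrix with Euclidean distance. Deterministic
# given the input order; labels: 0 = noise, 1..k = clusters.
.dbscan <- function(X, eps, min_pts) {
  n <- nrow(X)
  if (n == 0L) return(integer())
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Cluster consensus profiles with DBSCAN
#'
#' Density-based clustering of the flattened profile vectors: a core point
#' has at least `min_pts` neighbours (itself included) within Euclidean
#' distance `eps`; clusters are connected core neighbourhoods; border points
#' join a neighbouring core's cluster; the rest are noise. Clustering runs
#' within one unit-length stratum -- profile vectors of different unit
#' lengths have different dimensions and are not comparable.
#'
#' @param profiles List of `ConsensusProfile`s sharing one `unit_len`.
#' @param eps Neighbourhood radius (default 0.15).
#' @param min_pts Core-point threshold (default 5).
#' @return List with `clusters` (data.frame: `cluster_id`, `size`,
#'   `representative_motif`) and `membership` (data.frame: `tr_ref`,
#'   `canonical_consensus`, `cluster_id`; noise points have `cluster_id` NA).
#' @export
clusterProfiles <- function(profiles, eps = 0.15, min_pts = 5L) {
  .check(length(profiles) > 0L, "no profiles to cluster")
  units <- vapply(profiles, `[[`, integer(1), "unit_len")
  .check(length(unique(units)) == 1L,
         "mixed unit lengths: cluster each unit-length stratum separately")
  X <- do.call(rbind, lapply(profiles, `[[`, "vector"))
  labels <- .dbscan(X, eps, min_pts)
  cons <- vapply(profiles, `[[`, character(1), "canonical_consensus")
  refs <- vapply(profiles, `[[`, character(1), "tr_ref")
  ids <- sort(unique(labels[labels > 0L]))
  clusters <- data.frame(
    cluster_id = ids,
    size = vapply(ids, function(k) sum(labels == k), integer(1)),
    representative_motif = vapply(ids, function(k) {
      tab <- table(cons[labels == k])
      sort(names(tab)[tab == max(tab)])[1L]
    }, character(1)),
    stringsAsFactors = FALSE)
  membership <- data.frame(tr_ref = refs, canonical_consensus = cons,
                           cluster_id = ifelse(labels > 0L, labels, NA_integer_),
                           stringsAsFactors = FALSE)
  list(clusters = clusters, membership = membership)
}

#' Rank motif clusters by size
#'
#' Descending by size, ties broken alphabetically by representative motif;
#' optionally truncated to the top k (15 in the headline motif tables).
#'
#' @param clusters The `clusters` data.frame from [clusterProfiles()] (or
#'   the list it returns).
#' @param top_k Keep at most this many clusters (default all).
#' @return The ranked data.frame with a `rank` column prepended.
#' @export
rankClusters <- function(clusters, top_k = Inf) {
  if (is.list(clusters) && !is.data.frame(clusters) &&
      !is.null(clusters$clusters)) clusters <- clusters$clusters
  if (!nrow(clusters)) {
    return(data.frame(rank = integer(), cluster_id = integer(),
                      size = integer(), representative_motif = character()))
  }
  ord <- order(-clusters$size, clusters$representative_motif)
  out <- clusters[ord, , drop = FALSE]
  out <- utils::head(out, top_k)
  data.frame(rank = seq_len(nrow(out)), cluster_id = out$cluster_id,
             size = out$size, representative_motif = out$representative_motif,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ranked motif table per set label and group
#'
#' Builds profiles, clusters each (set label, group, unit length) stratum
#' with DBSCAN and returns the ranked cluster table.
#'
#' @param tr_regions A [TRRegionSet-class].
#' @param fragments The [FragmentSet-class] the regions live on.
#' @param eps,min_pts DBSCAN parameters (see [clusterProfiles()]).
#' @param top_k Top clusters kept per (set label, group) (default 15).
#' @return data.frame: `set_label`, `group`, `rank`, `representative_motif`,
#'   `size`.
#' @export
motifClusterTable <- function(tr_regions, fragments, eps = 0.15, min_pts = 5L,
                              top_k = 15L) {
  df <- as.data.frame(tr_regions)
  empty <- data.frame(set_label = character(), group = integer(),
                      rank = integer(), representative_motif = character(),
                      size = integer())
  if (!nrow(df)) return(empty)
  labels <- stats::setNames(setLabels(fragments), fragmentIds(fragments))
  df$set_label <- labels[df$fragment_id]
  rows <- list()
  for (lab in sort(unique(df$set_label))) for (g in sort(unique(df$group)))
    for (u in sort(unique(df$unit_len[df$set_label == lab & df$group == g]))) {
      sel <- df$set_label == lab & df$group == g & df$unit_len == u
      profs <- buildProfiles(new("TRRegionSet", regions = df[sel, seq_len(8)]),
                             fragments)
      if (length(profs) == 0L) next
      cl <- clusterProfiles(profs, eps = eps, min_pts = min_pts)
      if (!nrow(cl$clusters)) next
      rk <- rankClusters(cl$clusters)
      rk$set_label <- lab
      rk$group <- g
      rows[[length(rows) + 1L]] <- rk
    }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # re-rank within (set_label, group) across unit strata, then truncate
  res <- list()
  for (lab in unique(out$set_label)) for (g in unique(out$group[out$set_label == lab])) {
    d <- out[out$set_label == lab & out$group == g, , drop = FALSE]
    d <- d[order(-d$size, d$representative_motif), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    res[[length(res) + 1L]] <- utils::head(d, top_k)
  }
  out <- do.call(rbind, res)
  out[, c("set_label", "group", "rank", "representative_motif", "size")]
}
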