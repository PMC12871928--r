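# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no stored data files.

# Random amino-acid string over the 20-letter alphabet.
randomAA <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

# Random string with a planted tandem array of the given unit length and
# copy count; returns the string plus the planted 0-based interval and unit.
plantArray <- function(flank_left = 20, flank_right = 20, unit_len = 3,
                       copies = 5, n_mut = 0) {
  unit <- randomAA(unit_len)
  arr <- strrep(unit, copies)
  if (n_mut > 0) {
    ch <- strsplit(arr, "")[[1]]
    pos <- sample(seq_along(ch), n_mut)
    for (i in pos) ch[i] <- sample(setdiff(strsplit(randomAA(20), "")[[1]],
                                           ch[i]), 1)
    arr <- paste(ch, collapse = "")
  }
  s <- paste0(randomAA(flank_left), arr, randomAA(flank_right))
  list(seq = s, aa_start = flank_left, aa_end = flank_left + nchar(arr),
       unit = unit, unit_len = unit_len)
}

# The homopolymer fixture whose +1 readings are all arginine runs:
# GAG (Glu), TCG (Ser), GCG (Ala) rotate to AGG, CGT, CGG.
argSurgeConfig <- function(seed = 5, n_sequences = 30) {
  simConfig(n_sequences = n_sequences,
            planted_repeats = list(
              plantSpec("homopolymer_codon", "GAG", 40),
              plantSpec("homopolymer_codon", "TCG", 40),
              plantSpec("homopolymer_codon", "GCG", 40)),
            min_cds_len_nt = 900, seed = seed)
}

# Mixed-kind config used by the recovery tests.
mixedPlantConfig <- function(seed, mutation_rate = 0) {
  simConfig(n_sequences = 6,
            planted_repeats = list(
              plantSpec("homopolymer_codon", "CAG", 30,
                        mutation_rate = mutation_rate),
              plantSpec("short_unit_nt", "AGTCGG", 10,
                        mutation_rate = mutation_rate),
              plantSpec("long_duplication", strrep("GCTGAAGTT", 5), 3,
                        mutation_rate = mutation_rate)),
            min_cds_len_nt = 600, seed = seed)
}

# Brute-force DBSCAN reference, written directly from the definition:
# cores have >= min_pts neighbours within eps (self included); clusters are
# the connected components of the core-core eps-graph; border points join
# the cluster of their first core neighbour in input order; rest is noise.
bruteDbscan <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- which(vapply(nb, length, integer(1)) >= min_pts)
  labels <- integer(n)
  if (length(core)) {
    adj <- matrix(FALSE, length(core), length(core))
    for (i in seq_along(core)) for (j in seq_along(core))
      adj[i, j] <- D[core[i], core[j]] <= eps
    comp <- integer(length(core))
    cl <- 0
    for (i in seq_along(core)) {
      if (comp[i] != 0) next
      cl <- cl + 1
      stack <- i
      while (length(stack)) {
        v <- stack[1]; stack <- stack[-1]
        if (comp[v] != 0) next
        comp[v] <- cl
        stack <- c(stack, which(adj[v, ] & comp == 0))
      }
    }
    labels[core] <- comp
    for (i in seq_len(n)) {
      if (labels[i] != 0) next
      cn <- intersect(nb[[i]], core)
      if (length(cn)) labels[i] <- labels[cn[1]]
    }
  }
  labels
}

# Partition-equality of two clusterings up to label renaming (noise = 0
# must match exactly).
samePartition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0, b == 0)) return(FALSE)
  key <- paste(a, b)
  length(unique(key[a != 0])) == length(unique(a[a != 0])) &&
    length(unique(key[a != 0])) == length(unique(b[b != 0]))
}
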