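test_that("plant specifications are validated", {
  expect_error(plantSpec("homopolymer_codon", "CAGX", 5), "ACGT")
  expect_error(plantSpec("homopolymer_codon", "CAGA", 5), "range")
  expect_error(plantSpec("short_unit_nt", strrep("A", 25), 5), "range")
  expect_error(plantSpec("long_duplication", "ACGACG", 3), "range")
  expect_error(plantSpec("homopolymer_codon", "CAG", 1), "copies")
  expect_error(simConfig(background_codon_usage = c(AAA = 0.5)), "sum to 1")
})

test_that("generated CDSs are codon-aligned, long enough and ACGT-only", {
  cfg <- mixedPlantConfig(seed = 4)
  res <- generateCdsSet(cfg)
  expect_equal(length(res$cds), cfg$n_sequences)
  lens <- Biostrings::width(res$cds)
  expect_true(all(lens %% 3 == 0))
  expect_true(all(lens >= cfg$min_cds_len_nt))
  expect_true(all(grepl("^[ACGT]+$", as.character(res$cds))))
})

test_that("a clean CAG homopolymer plants a poly-Gln truth in frame 0", {
  cfg <- simConfig(n_sequences = 2,
                   planted_repeats = list(
                     plantSpec("homopolymer_codon", "CAG", 30)),
                   min_cds_len_nt = 300, seed = 1)
  res <- generateCdsSet(cfg)
  expect_true(all(grepl("CAGCAGCAG", as.character(res$cds))))
  gt0 <- res$ground_truth[res$ground_truth$frame == "0", ]
  expect_equal(nrow(gt0), 2L)
  expect_true(all(gt0$unit_len_aa == 1))
  tr <- translateFrame(as.character(res$cds[[1]]), "0")
  span <- substr(tr, gt0$aa_start[1] + 1, gt0$aa_end[1])
  expect_equal(span, strrep("Q", 30))
})

test_that("a GAG run's +1 ground truth is a poly-Arg run", {
  cfg <- simConfig(n_sequences = 1,
                   planted_repeats = list(
                     plantSpec("homopolymer_codon", "GAG", 20)),
                   min_cds_len_nt = 300, seed = 2)
  res <- generateCdsSet(cfg)
  gt1 <- res$ground_truth[res$ground_truth$frame == "+1", ]
  expect_equal(nrow(gt1), 1L)
  tr <- translateFrame(as.character(res$cds[[1]]), "+1")
  span <- substr(tr, gt1$aa_start + 1, gt1$aa_end)
  expect_equal(span, strrep("R", nchar(span)))  # AGG codons
  expect_gte(nchar(span), 18)
})

test_that("generation is deterministic: same config, byte-identical output", {
  cfg <- mixedPlantConfig(seed = 77)
  a <- generateCdsSet(cfg)
  b <- generateCdsSet(cfg)
  expect_identical(as.character(a$cds), as.character(b$cds))
  expect_identical(a$ground_truth, b$ground_truth)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- writeFixture(a$cds, a$ground_truth, d1)
  p2 <- writeFixture(b$cds, b$ground_truth, d2)
  expect_identical(readLines(p1[["fasta"]]), readLines(p2[["fasta"]]))
  expect_identical(readLines(p1[["ground_truth"]]),
                   readLines(p2[["ground_truth"]]))
})

test_that("fixtures round-trip through FASTA and handle the empty set", {
  cfg <- simConfig(n_sequences = 10, planted_repeats = list(
    plantSpec("homopolymer_codon", "CAG", 10)), min_cds_len_nt = 120, seed = 3)
  res <- generateCdsSet(cfg)
  d <- tempfile()
  paths <- writeFixture(res$cds, res$ground_truth, d)
  back <- readCdsFasta(paths[["fasta"]])
  expect_equal(length(back), 10L)
  expect_identical(as.character(back), as.character(res$cds))
  gt_back <- read.delim(paths[["ground_truth"]])
  expect_equal(nrow(gt_back), nrow(res$ground_truth))
  # degenerate: no sequences
  paths0 <- writeFixture(Biostrings::DNAStringSet(),
                         res$ground_truth[0, ], tempfile())
  expect_equal(length(readCdsFasta(paths0[["fasta"]])), 0L)
  expect_equal(nrow(read.delim(paths0[["ground_truth"]])), 0L)
})

test_that("planted repeats are recovered across unit lengths 1-50", {
  # mutation_rate = 0; recall must reach 0.9 at Jaccard 0.9
  specs <- list(plantSpec("homopolymer_codon", "CAG", 30),
                plantSpec("short_unit_nt", "AGTC", 15),        # 4-aa unit
                plantSpec("short_unit_nt", "AGTCGG", 10),      # 2-aa unit
                plantSpec("long_duplication", strrep("GCTGAAGTTCCATCA", 3), 3),
                plantSpec("long_duplication",
                          paste0(strrep("GAC", 24), strrep("TTC", 26)), 2))
  # last spec: 150-nt unit = 50-aa unit, two copies
  cfg <- simConfig(n_sequences = 5, planted_repeats = specs,
                   min_cds_len_nt = 900, seed = 31)
  res <- generateCdsSet(cfg)
  expect_true(50 %in% res$ground_truth$unit_len_aa)
  fr <- translateCdsSet(res$cds, min_fragment_len = 5)
  trs <- detectRepeats(fr)
  ev <- evaluateRecovery(trs, fr, res$ground_truth, jaccard_min = 0.9)
  expect_gte(ev$recall, 0.9)
})

test_that("frame-0 retranslation reproduces the generator's protein", {
  cfg <- mixedPlantConfig(seed = 8)
  res <- generateCdsSet(cfg)
  for (i in seq_along(res$cds)) {
    tr <- translateFrame(as.character(res$cds[[i]]), "0")
    # single terminal stop; interior stop-free unless a plant spells one
    expect_equal(substr(tr, nchar(tr), nchar(tr)), "*")
  }
})

test_that("alt-frame fragment loss grows with stop-spelling codon mass", {
  # Backgrounds with increasing weight on codons that assemble alternative-
  # frame stops (ATA/GTA/ATG raise TA|A and TG|A junctions in the +1 frame).
  frac_short <- function(w, seed) {
    # base: codons over {C,G} only -- no stop can be spelled in any frame;
    # boost: mass w on the codons whose junctions spell +1-frame stops
    p <- stats::setNames(numeric(64), names(codonTable()))
    base <- c("CCC", "CCG", "CGC", "CGG", "GCC", "GCG", "GGC", "GGG")
    boost <- c("ATA", "GTA", "ATG")
    p[base] <- (1 - w) / length(base)
    p[boost] <- w / length(boost)
    cfg <- simConfig(n_sequences = 60, background_codon_usage = p / sum(p),
                     planted_repeats = list(), min_cds_len_nt = 450,
                     seed = seed)
    res <- generateCdsSet(cfg)
    short <- 0; total <- 0
    for (s in as.character(res$cds)) {
      for (fr in c("+1", "-1")) {
        pieces <- strsplit(translateFrame(s, fr), "*", fixed = TRUE)[[1]]
        pieces <- pieces[nzchar(pieces)]
        total <- total + length(pieces)
        short <- short + sum(nchar(pieces) < 60)
      }
    }
    short / total
  }
  fr0 <- frac_short(0, 101)
  fr1 <- frac_short(0.1, 102)
  fr2 <- frac_short(0.3, 103)
  expect_lt(fr0, fr1)
  expect_lt(fr1, fr2)
})
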