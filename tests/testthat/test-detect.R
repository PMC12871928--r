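test_that("homorepeat finder reports maximal runs above the length cutoff", {
  r <- as.data.frame(findHomorepeats("MAAAAAK", min_run = 5))
  expect_equal(r[, c("aa_start", "aa_end", "unit_len", "consensus")],
               data.frame(aa_start = 1L, aa_end = 6L, unit_len = 1L,
                          consensus = "A"))
  expect_equal(r$copy_number, 5)
  expect_equal(length(findHomorepeats("MAAAK", min_run = 5)), 0L)
  r2 <- as.data.frame(findHomorepeats(strrep("Q", 10), min_run = 5))
  expect_equal(c(r2$aa_start, r2$aa_end, r2$copy_number), c(0, 10, 10))
})

test_that("short-period finder handles exact, mismatched and reducible arrays", {
  r <- as.data.frame(findShortPeriod(strrep("SR", 5)))
  expect_equal(r[, c("aa_start", "aa_end", "unit_len", "consensus", "purity")],
               data.frame(aa_start = 0L, aa_end = 10L, unit_len = 2L,
                          consensus = "SR", purity = 1))
  # one substitution out of 10 positions: purity 0.9, still one region
  r2 <- as.data.frame(findShortPeriod("SRSRSASRSR"))
  expect_equal(c(r2$aa_start, r2$aa_end, r2$unit_len), c(0, 10, 2))
  expect_equal(r2$purity, 0.9)
  # primitive-period reduction: GPPGPP... is unit GPP, never GPPGPP
  r3 <- as.data.frame(findShortPeriod("GPPGPPGPPGPP"))
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$unit_len, 3L)
  expect_equal(r3$consensus, "GPP")
  # units with internal letter repetition are still primitive
  r4 <- as.data.frame(findShortPeriod(strrep("LKL", 5)))
  expect_equal(r4$unit_len, 3L)
})

test_that("long-repeat finder recovers exact and mutated duplications", {
  set.seed(42)
  u <- randomAA(30)
  s <- paste0(randomAA(25), strrep(u, 3), randomAA(25))
  r <- as.data.frame(findLongRepeats(s))
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$aa_start, r$aa_end, r$unit_len), c(25, 115, 30))
  # two copies, 6 substitutions in the second (identity 0.8)
  ch <- strsplit(u, "")[[1]]
  pos <- sample(30, 6)
  for (i in pos) ch[i] <- sample(setdiff(LETTERS[1:20], ch[i]), 1)
  s2 <- paste0(randomAA(20), u, paste(ch, collapse = ""), randomAA(20))
  r2 <- as.data.frame(findLongRepeats(s2))
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$unit_len, 30L)
  # negative control: random 200-mers yield no unit >= 9 region
  for (i in 1:20) expect_equal(length(findLongRepeats(randomAA(200))), 0L)
})

test_that("the smallest-period oracle matches hand-computed cases", {
  r <- oracleSmallestPeriod("ABABAB")
  expect_equal(c(r$p, r$purity), c(2, 1))
  r2 <- oracleSmallestPeriod("AAAAAA")
  expect_equal(c(r2$p, r2$purity), c(1, 1))
  # consensus ABC, one mismatch (D) out of 9 positions
  r3 <- oracleSmallestPeriod("ABCABDABC", max_mismatch_frac = 0.12)
  expect_equal(r3$p, 3L)
  expect_equal(r3$purity, 8 / 9)
  expect_equal(r3$consensus, "ABC")
  expect_null(oracleSmallestPeriod("ABCDEFGH", max_mismatch_frac = 0.1))
})

test_that("overlap resolution prefers purity, then smaller unit, then start", {
  # rule 1: homorepeat (purity 1) beats impure period-2 on the same span
  df <- data.frame(fragment_id = "f", aa_start = c(0, 0), aa_end = c(10, 10),
                   unit_len = c(1, 2), consensus = c("A", "AB"),
                   purity = c(1, 0.8))
  expect_equal(as.data.frame(resolveOverlaps(df))$unit_len, 1L)
  # rule 2: equal purity, smaller unit wins
  df2 <- data.frame(fragment_id = "f", aa_start = c(0, 0), aa_end = c(10, 10),
                    unit_len = c(4, 2), consensus = c("ABCD", "AB"),
                    purity = c(0.9, 0.9))
  expect_equal(as.data.frame(resolveOverlaps(df2))$unit_len, 2L)
  # disjoint regions both kept
  df3 <- data.frame(fragment_id = "f", aa_start = c(0, 20), aa_end = c(10, 30),
                    unit_len = c(2, 2), consensus = c("AB", "CD"),
                    purity = c(1, 1))
  expect_equal(nrow(as.data.frame(resolveOverlaps(df3))), 2L)
})

test_that("losing candidates are trimmed to their free remainder, not lost", {
  # a small pure LK region overlaps the head of a long LKL array
  s <- paste0("VLKLK", strrep("LKL", 12), "W")
  trs <- detectRepeats(FragmentSet(s, "f1", "c1", "0", 0L, "reference"))
  df <- as.data.frame(trs)
  expect_true(any(df$unit_len == 3 & df$consensus == "LKL" &
                    (df$aa_end - df$aa_start) >= 30))
  # the final set is always non-overlapping
  by_frag <- split(df, df$fragment_id)
  for (d in by_frag) {
    d <- d[order(d$aa_start), ]
    if (nrow(d) > 1) expect_true(all(d$aa_start[-1] >= d$aa_end[-nrow(d)]))
  }
})

test_that("detector agrees with the exhaustive oracle on planted strings", {
  # 500 seeded random strings (length <= 200) with planted arrays of varying
  # unit length and mutation load; every emitted region's unit length must
  # equal the oracle's smallest period on that interval.
  set.seed(2024)
  n_checked <- 0
  for (i in 1:500) {
    unit_len <- sample(c(1:8, 10, 15, 25), 1)
    copies <- sample(3:6, 1)
    if (unit_len * copies > 160) copies <- max(2, 160 %/% unit_len)
    n_mut <- sample(0:1, 1)
    px <- plantArray(flank_left = sample(5:20, 1),
                     flank_right = sample(5:20, 1),
                     unit_len = unit_len, copies = copies, n_mut = n_mut)
    trs <- detectRepeats(FragmentSet(px$seq, "f1", "c1", "0", 0L, "reference"))
    df <- as.data.frame(trs)
    for (j in seq_len(nrow(df))) {
      seg <- substr(px$seq, df$aa_start[j] + 1, df$aa_end[j])
      orc <- oracleSmallestPeriod(seg, max_mismatch_frac = 0.1)
      expect_false(is.null(orc))
      expect_equal(df$unit_len[j], orc$p)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 300)  # the oracle comparison must actually exercise
})

test_that("emitted regions always satisfy the structural invariants", {
  set.seed(99)
  for (i in 1:40) {
    px <- plantArray(unit_len = sample(1:12, 1), copies = sample(2:8, 1),
                     n_mut = sample(0:2, 1))
    trs <- detectRepeats(FragmentSet(px$seq, "f1", "c1", "0", 0L, "reference"))
    df <- as.data.frame(trs)
    if (!nrow(df)) next
    expect_true(all(df$copy_number >= 2))
    expect_true(all(df$purity >= 0.7 & df$purity <= 1))
    expect_true(all(nchar(df$consensus) == df$unit_len))
    # primitive units: no consensus is a repetition of a shorter string
    for (cns in df$consensus) {
      u <- nchar(cns)
      divs <- setdiff(which(u %% seq_len(u) == 0), u)
      for (d in divs)
        expect_false(identical(strrep(substr(cns, 1, d), u / d), cns))
    }
  }
})

test_that("detection is deterministic and sorted", {
  set.seed(3)
  s <- paste0(randomAA(30), strrep("QA", 8), randomAA(20), strrep("W", 7),
              randomAA(30))
  fr <- FragmentSet(s, "f1", "c1", "0", 0L, "reference")
  a <- as.data.frame(detectRepeats(fr))
  b <- as.data.frame(detectRepeats(fr))
  expect_identical(a, b)
  expect_true(!is.unsorted(a$aa_start[order(a$fragment_id)]))
})
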