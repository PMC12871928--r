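mkAnn <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(fragment_id = r[[1]], kind = r[[2]],
               aa_start = as.integer(r[[3]]), aa_end = as.integer(r[[4]]),
               stringsAsFactors = FALSE)))
}

test_that("per-region coverage intersects with the union of intervals", {
  trs <- TRRegionSet("f1", 0L, 100L, 1L, "Q", 1)
  ann <- mkAnn(list("f1", "IDR", 0, 30), list("f1", "IDR", 50, 77))
  cov <- coverageByTr(trs, ann, "IDR")
  expect_equal(cov$covered_residues, 57L)
  expect_equal(cov$coverage, 0.57)
  # no annotations on the fragment: zero coverage
  cov0 <- coverageByTr(trs, mkAnn(list("f2", "IDR", 0, 10)), "IDR")
  expect_equal(cov0$coverage, 0)
  # annotation exactly equal to the TR: full coverage
  cov1 <- coverageByTr(trs, mkAnn(list("f1", "IDR", 0, 100)), "IDR")
  expect_equal(cov1$coverage, 1)
  # overlapping annotation intervals are unioned before intersecting
  cov2 <- coverageByTr(trs, mkAnn(list("f1", "IDR", 0, 30),
                                  list("f1", "IDR", 20, 40)), "IDR")
  expect_equal(cov2$covered_residues, 40L)
})

test_that("coverage is monotone in the annotation set", {
  set.seed(20)
  trs <- TRRegionSet("f1", 10L, 60L, 1L, "Q", 1)
  ann <- mkAnn(list("f1", "IDR", 0, 20))
  base <- coverageByTr(trs, ann, "IDR")$covered_residues
  for (i in 1:10) {
    s <- sample(0:80, 1)
    ann <- rbind(ann, mkAnn(list("f1", "IDR", s, s + sample(5:20, 1))))
    now <- coverageByTr(trs, ann, "IDR")$covered_residues
    expect_gte(now, base)
    base <- now
  }
})

test_that("set coverage is the length-weighted mean of per-region coverage", {
  trs <- TRRegionSet(c("f1", "f1"), c(0L, 20L), c(10L, 30L), c(1L, 1L),
                     c("Q", "S"), c(1, 1))
  ann <- mkAnn(list("f1", "AR", 0, 10))
  expect_equal(setCoverage(trs, ann, "AR"), 50)
  expect_equal(setCoverage(trs, mkAnn(list("f1", "AR", 0, 30)), "AR"), 100)
  expect_error(setCoverage(TRRegionSet(), ann, "AR"), "empty")
  # algebraic identity on random instances with unequal lengths
  set.seed(30)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    starts <- cumsum(sample(5:20, n))
    lens <- sample(5:30, n, replace = TRUE)
    trs2 <- TRRegionSet(rep("f1", n), starts, starts + lens,
                        rep(1L, n), rep("Q", n), rep(1, n))
    ann2 <- mkAnn(list("f1", "IDR", 0, sample(20:200, 1)))
    cov <- coverageByTr(trs2, ann2, "IDR")
    expect_equal(setCoverage(trs2, ann2, "IDR"),
                 100 * sum(cov$coverage * lens) / sum(lens),
                 tolerance = 1e-9)
  }
})

test_that("the coverage comparison is a two-sided Welch t-test with stars", {
  # textbook Welch check against the closed form
  x <- c(0.2, 0.25, 0.18, 0.22, 0.30)
  y <- c(0.50, 0.55, 0.48, 0.60)
  res <- compareCoverage(x, y)
  sx2 <- var(x) / length(x)
  sy2 <- var(y) / length(y)
  t_manual <- (mean(x) - mean(y)) / sqrt(sx2 + sy2)
  df_manual <- (sx2 + sy2)^2 / (sx2^2 / (length(x) - 1) +
                                  sy2^2 / (length(y) - 1))
  p_manual <- 2 * pt(abs(t_manual), df_manual, lower.tail = FALSE)
  expect_equal(res$t, t_manual, tolerance = 1e-6)
  expect_equal(res$p, p_manual, tolerance = 1e-6)
  # strong separation earns four stars
  set.seed(40)
  a <- rnorm(50, 0.2, 0.05)
  b <- rnorm(50, 0.8, 0.05)
  expect_equal(compareCoverage(a, b)$stars, "****")
  # identical constant samples are degenerate
  dg <- compareCoverage(rep(0.5, 5), rep(0.5, 5))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p))
})

test_that("type-I error of the comparison is near nominal", {
  set.seed(50)
  ns <- 0
  for (i in 1:100) {
    x <- rnorm(30, 0.5, 0.1)
    y <- rnorm(30, 0.5, 0.1)
    if (compareCoverage(x, y)$stars == "ns") ns <- ns + 1
  }
  expect_gte(ns, 90)
})

test_that("hydrophobic homorepeat histograms use the all-homorepeat denominator", {
  trs <- TRRegionSet(rep("f1", 4), c(0L, 20L, 50L, 70L),
                     c(12L, 45L, 62L, 78L), rep(1L, 4),
                     c("L", "L", "Q", "S"), rep(1, 4))
  h <- homorepeatLengthHistogram(trs)
  expect_equal(h$n_homorepeats, 4L)
  expect_equal(h$freq$frequency[h$freq$length == 12], 0.25)  # poly-L x12
  expect_equal(h$freq$frequency[h$freq$length == 25], 0.25)  # poly-L x25
  # poly-Q and poly-S never contribute to the numerator
  expect_equal(sum(h$freq$count_hydrophobic), 2L)
  # bins: length 12 is aggregation-range, length 25 is TM-range
  expect_gt(h$bins[["aggregation_11_20"]], 0)
  expect_gt(h$bins[["tm_21_plus"]], 0)
  expect_error(homorepeatLengthHistogram(TRRegionSet()), "empty")
  expect_error(homorepeatLengthHistogram(
    TRRegionSet("f1", 0L, 10L, 2L, "LK", 1)), "unit length 1")
})

test_that("annotation IO validates kinds and converts 1-based input", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(fragment_id = "f1", kind = "IDR",
                         aa_start = 1, aa_end = 10),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  a0 <- readAnnotations(f)                  # half-open as written
  expect_equal(c(a0$aa_start, a0$aa_end), c(1, 10))
  a1 <- readAnnotations(f, one_based = TRUE)  # 1-based inclusive -> [0,10)
  expect_equal(c(a1$aa_start, a1$aa_end), c(0, 10))
  write.table(data.frame(fragment_id = "f1", kind = "WEIRD",
                         aa_start = 0, aa_end = 10),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readAnnotations(f), "unknown annotation kind")
})

test_that("coverage summaries compare reference and frameshift per group", {
  cfg <- argSurgeConfig(seed = 5, n_sequences = 15)
  res <- generateCdsSet(cfg)
  fr <- translateCdsSet(res$cds)
  trs <- detectRepeats(fr)
  ann <- generateAnnotations(fr, kinds = "IDR", lambda = 2,
                             bias_regions = trs, seed = 9)
  sm <- coverageSummary(trs, fr, ann, kinds = "IDR")
  expect_true(all(c("reference", "frameshift") %in% sm$set_label))
  expect_true(all(sm$mean >= 0 & sm$mean <= 1))
  expect_true(all(sm$kind == "IDR"))
})
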