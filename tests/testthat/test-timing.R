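.mkVariants <- function(alt, depth, copies = 3L, purity = 1) {
  data.frame(case_id = "c1", chromosome = "4", position = seq_along(alt),
             alt_reads = alt, depth = depth, total_copies = copies,
             purity = purity)
}

test_that("timing classification follows the expected VAF structure", {
  v <- classifyTiming(.mkVariants(c(40L, 20L), 60L))
  expect_identical(v$timing, c("BTRI", "B_ATRI"))
  # off-trisomy contexts are not applicable
  v <- classifyTiming(.mkVariants(30L, 60L, copies = 2L))
  expect_identical(v$timing, "not_applicable")
  # reads right between the two hypotheses are ambiguous
  v <- classifyTiming(.mkVariants(30L, 60L))
  expect_identical(v$timing, "ambiguous")
  # low depth forces ambiguity even for clear fractions
  v <- classifyTiming(.mkVariants(4L, 6L), minDepth = 10L)
  expect_identical(v$timing, "ambiguous")
  expect_error(classifyTiming(.mkVariants(0L, 0L)), "zero depth")
  # window method partitions cleanly at VAF 0.5
  v <- classifyTiming(.mkVariants(c(31L, 29L), 60L), method = "window")
  expect_identical(v$timing, c("BTRI", "B_ATRI"))
})

test_that("purity adjustment shifts the expected VAFs", {
  expect_equal(unname(expectedTimingVafs(1)), c(2 / 3, 1 / 3))
  ev <- expectedTimingVafs(0.8)
  expect_equal(unname(ev["btri"]), 1.6 / 2.8)
  # at high depth, classification tracks the purity-adjusted expectation
  v <- .mkVariants(as.integer(round(400 * ev["btri"])), 400L, purity = 0.8)
  expect_identical(classifyTiming(v)$timing, "BTRI")
})

test_that("homologue assignment is a two-threshold monotone rule", {
  expect_identical(assignHomologue(c(0.70, 0.35, 0.50)),
                   c("hom1", "hom2", "unassigned"))
  af <- seq(0, 1, by = 0.01)
  lab <- assignHomologue(af)
  expect_identical(unique(lab), c("hom2", "unassigned", "hom1"))
  # monotone: once hom1 starts it never reverts
  expect_identical(lab, lab[order(af)])
  expect_identical(sum(diff(match(lab, c("hom2", "unassigned", "hom1"))) != 0), 2L)
})

test_that("BTRI fractions reproduce the headline arithmetic", {
  v <- data.frame(
    case_id = "c1",
    chromosome = "4",
    position = 1:(15828 + 819),
    alt_reads = 1L, depth = 2L, total_copies = 3L,
    timing = c(rep("BTRI", 536), rep("B_ATRI", 15828 - 536),
               rep("BTRI", 9), rep("B_ATRI", 819 - 9)),
    group = c(rep("pos", 15828), rep("neg", 819))
  )
  fr <- btriFractionByGroup(v)$fractions
  expect_equal(round(100 * fr$fraction[fr$group == "pos"], 2), 3.39)
  expect_equal(round(100 * fr$fraction[fr$group == "neg"], 2), 1.10)
  expect_equal(fr$fraction[fr$group == "pos"], 536 / 15828)
  expect_equal(fr$fraction[fr$group == "neg"], 9 / 819)
})

test_that("all-BTRI input gives unit fractions and an uninformative test", {
  v <- data.frame(case_id = rep(c("a", "b"), each = 4),
                  chromosome = "4", position = 1:8,
                  alt_reads = 40L, depth = 60L, total_copies = 3L,
                  timing = "BTRI",
                  group = rep(c("pos", "neg"), 4))
  out <- btriFractionByGroup(v)
  expect_true(all(out$fractions$fraction == 1))
  expect_equal(out$pValue, 1)
})

test_that("timing recovery on synthetic variants reaches 95% at depth 60", {
  set.seed(61)
  k <- diploidKaryotype()
  k[c("4", "14", "21"), "hom1"] <- 2L
  v <- generateVariants(k, nBtri = 400, nBatri = 400, depth = 60, purity = 1)
  cls <- classifyTiming(v)
  called <- cls$timing %in% c("BTRI", "B_ATRI")
  acc <- mean(cls$timing[called] == cls$truth[called])
  expect_gte(acc, 0.95)
  # and at purity 0.8 the recovery remains high
  v <- generateVariants(k, nBtri = 400, nBatri = 400, depth = 60, purity = 0.8)
  cls <- classifyTiming(v)
  called <- cls$timing %in% c("BTRI", "B_ATRI")
  expect_gte(mean(cls$timing[called] == cls$truth[called]), 0.95)
})

test_that("newer trisomies show higher BTRI fractions (direction check)", {
  set.seed(62)
  k <- diploidKaryotype()
  k[c("4", "1"), "hom1"] <- 2L    # one strong-pos, one neg trisomy
  # strong-pos trisomy arose later: more of its mutation history predates
  # the gain, so a larger share of its SNVs are duplicated (BTRI)
  posV <- generateVariants(k, nBtri = 60, nBatri = 140, depth = 60)
  posV$chromosome <- "4"
  posV$group <- "pos"
  negV <- generateVariants(k, nBtri = 5, nBatri = 195, depth = 60)
  negV$chromosome <- "1"
  negV$group <- "neg"
  v <- classifyTiming(rbind(posV, negV))
  fr <- btriFractionByGroup(v)$fractions
  expect_gt(fr$fraction[fr$group == "pos"], fr$fraction[fr$group == "neg"])
})

test_that("homologue concordance votes across informative variants", {
  diag <- data.frame(chromosome = "4", position = 1:6,
                     alt_reads = c(40L, 42L, 38L, 15L, 30L, 41L), depth = 60L)
  sameRel <- diag
  out <- homologueConcordance(diag, sameRel)
  expect_identical(out$call, "same")
  # relapse with the opposite duplicated homologue flips the fractions
  flipRel <- diag
  flipRel$alt_reads <- as.integer(60L - diag$alt_reads)
  out <- homologueConcordance(diag, flipRel)
  expect_identical(out$call, "different")
  # no positional overlap: uninformative
  rel <- diag
  rel$position <- rel$position + 100L
  out <- homologueConcordance(diag, rel)
  expect_identical(out$call, "uninformative")
  # UPID mode: high-BAF variants screened in the relapse
  diagU <- data.frame(chromosome = "9", position = 1:4,
                      alt_reads = c(55L, 56L, 57L, 58L), depth = 60L)
  out <- homologueConcordance(diagU, diagU, mode = "upid")
  expect_identical(out$call, "same")
  lowRel <- diagU
  lowRel$alt_reads <- c(5L, 4L, 6L, 3L)
  out <- homologueConcordance(diagU, lowRel, mode = "upid")
  expect_identical(out$call, "different")
})

test_that("variant tables round-trip through TSV", {
  set.seed(63)
  k <- diploidKaryotype()
  k["4", "hom1"] <- 2L
  v <- generateVariants(k, 5, 5, depth = 30)
  f <- tempfile(fileext = ".tsv")
  writeVariantTable(v, f)
  v2 <- readVariantTable(f)
  expect_equal(v2$alt_reads, v$alt_reads)
  expect_identical(v2$chromosome, v$chromosome)
  unlink(f)
})
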