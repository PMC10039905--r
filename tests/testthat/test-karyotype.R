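test_that("mcn sums homologue copies over the 23 chromosome pairs", {
  expect_identical(mcn(diploidKaryotype()), 46L)

  k <- diploidKaryotype()
  k["21", "hom1"] <- 2L
  k["X", "hom2"] <- 2L
  expect_identical(mcn(k), 48L)

  # (2,2) on 21, (2,1) on the other strong-pos chromosomes, (1,1) elsewhere
  k <- diploidKaryotype()
  k["21", ] <- c(2L, 2L)
  for (ch in c("X", "4", "6", "10", "14", "17", "18")) k[ch, "hom1"] <- 2L
  expect_identical(mcn(k), 4L + 3L * 7L + 2L * 15L)   # 55, by brute-force sum
})

test_that("mcn is additive: one extra copy raises it by exactly 1", {
  set.seed(11)
  for (i in 1:20) {
    k <- diploidKaryotype()
    k[] <- matrix(sample(0:3, 46, replace = TRUE), 23)
    ch <- sample(23, 1)
    k2 <- k
    k2[ch, 1] <- k2[ch, 1] + 1L
    expect_identical(mcn(k2), mcn(k) + 1L)
  }
})

test_that("chromosome states follow the homologue-pair table, symmetrically", {
  expect_identical(classifyChromosome(1, 1), "heterodisomy")
  expect_identical(classifyChromosome(2, 0), "UPID")
  expect_identical(classifyChromosome(3, 1), "tetrasomy_3_1")
  expect_identical(classifyChromosome(2, 2), "tetrasomy_2_2")
  expect_identical(classifyChromosome(4, 0), "tetrasomy_4_0")
  expect_identical(classifyChromosome(0, 0), "nullisomy")
  expect_identical(classifyChromosome(0, 1), "monosomy")
  expect_identical(classifyChromosome(2, 1), "trisomy")
  expect_identical(classifyChromosome(5, 1), "pentasomy_plus")
  # symmetry, exhaustively up to 6 copies per homologue
  grid <- expand.grid(a = 0:6, b = 0:6)
  expect_identical(classifyChromosome(grid$a, grid$b),
                   classifyChromosome(grid$b, grid$a))
})

test_that("aneuploidy penalty matches quadrature of the beta law", {
  cfg <- SelectionConfig()   # cumulative form, shapes (0.65, 0.18)
  expect_identical(sAneuploidy(46, cfg), 0)
  expect_identical(sAneuploidy(40, cfg), 0)
  for (m in c(47, 67)) {
    u <- (m - 46) / 46 / 1.8
    expect_equal(sAneuploidy(m, cfg),
                 betaKernelOracle(u, 0.65, 0.18, "cdf"), tolerance = 1e-6)
  }
  cfgD <- SelectionConfig(penaltyForm = "density")
  for (m in c(47, 67)) {
    u <- (m - 46) / 46 / 1.8
    expect_equal(sAneuploidy(m, cfgD),
                 betaKernelOracle(u, 0.65, 0.18, "density") / 1.8,
                 tolerance = 1e-6)
  }
  # printed-order shapes remain available and follow the same law
  cfgP <- SelectionConfig(penaltyShape1 = 0.18, penaltyShape2 = 0.65)
  u <- (55 - 46) / 46 / 1.8
  expect_equal(sAneuploidy(55, cfgP),
               betaKernelOracle(u, 0.18, 0.65, "cdf"), tolerance = 1e-6)
  # zero at or below 46, non-negative and monotone above it (cumulative)
  v <- sAneuploidy(40:120, cfg)
  expect_true(all(v >= 0))
  expect_true(all(v[1:7] == 0))
  expect_true(all(diff(v[8:81]) >= 0))
})

test_that("survival score is 0.5 for diploid cells and follows the formula", {
  for (form in c("cumulative", "density")) {
    cfg <- SelectionConfig(penaltyForm = form)
    expect_identical(sScore(diploidKaryotype(), cfg), 0.5)
  }
  cfg <- SelectionConfig()
  # NT_g1 = 2, NT_g2 = 1, NT_g3 = 0  ->  0.5 + 4/23 - penalty(MCN)
  k <- diploidKaryotype()
  k["4", "hom1"] <- 2L
  k["6", "hom1"] <- 2L
  k["21", "hom1"] <- 2L
  expect_equal(sScore(k, cfg), 0.5 + 4 / 23 - sAneuploidy(49, cfg))
  # a single group-3b trisomy: 0.5 - 1/23 - penalty(47)
  k <- diploidKaryotype()
  k["1", "hom1"] <- 2L
  expect_equal(sScore(k, cfg), 0.5 - 1 / 23 - sAneuploidy(47, cfg))
  # four-group form rewards a weak-pos gain with weight 0.02
  cfg4 <- SelectionConfig(scoreForm = "fourGroup")
  k <- diploidKaryotype()
  k["5", "hom1"] <- 2L
  expect_equal(sScore(k, cfg4), 0.5 + 0.02 / 23 - sAneuploidy(47, cfg4))
  # penalty can be switched off (tetraploid/sequential convention)
  expect_equal(sScore(k, cfg4, aneuploidyPenalty = FALSE), 0.5 + 0.02 / 23)
})

test_that("loss from a trisomy matches exhaustive enumeration", {
  expect_equal(lossOutcomes(c(2, 1)),
               c(heterodisomy = 2 / 3, UPID = 1 / 3))
  expect_equal(lossOutcomes(c(3, 0)), c(heterodisomy = 0, UPID = 1))
  for (pair in list(c(2, 1), c(1, 2), c(3, 0), c(0, 3)))
    expect_equal(lossOutcomes(pair), lossEnumOracle(pair))
  expect_error(lossOutcomes(c(2, 2)), "trisomic")
})

test_that("UPID frequency counts UPIDs over tracked disomies", {
  p <- founderPopulation("diploid_sequential", 3)
  expect_identical(upidFrequency(p), 0)
  # one cell: 13 heterodisomies + 1 UPID among the 14 tracked
  h1 <- matrix(1L, 23, 1, dimnames = list(chromosomeNames(), NULL))
  h2 <- h1
  h1["1", 1] <- 2L
  h2["1", 1] <- 0L
  p <- CellPopulation(h1, h2)
  expect_equal(upidFrequency(p), 1 / 14)
  # allTracked denominator uses every tracked slot
  expect_equal(upidFrequency(p, denominator = "allTracked"), 1 / 14)
  h1["21", 1] <- 2L   # a non-tracked gain changes neither statistic
  p <- CellPopulation(h1, h2)
  expect_equal(upidFrequency(p), 1 / 14)
  expect_error(upidFrequency(CellPopulation(h1[, 0, drop = FALSE],
                                            h2[, 0, drop = FALSE])),
               "empty")
})

test_that("karyotypes round-trip through the long TSV format", {
  set.seed(3)
  p <- founderPopulation("mitotic_catastrophe", 7)
  f <- tempfile(fileext = ".tsv")
  writeKaryotypes(p, f)
  q <- readKaryotypes(f)
  expect_identical(q@hom1, p@hom1)
  expect_identical(q@hom2, p@hom2)
  unlink(f)
})
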