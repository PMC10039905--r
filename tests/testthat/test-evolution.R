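test_that("division conserves per-chromosome totals across daughters", {
  set.seed(31)
  cfg <- SelectionConfig(mMisseg = 0.2)   # exaggerated rate to hit events
  p <- founderPopulation("diploid_tripolar", 200)
  d <- divideCells(p, cfg)
  expect_identical(ncells(d), 400L)
  momTot <- p@hom1 + p@hom2
  dTot <- d@hom1 + d@hom2
  expect_identical(dTot[, 1:200] + dTot[, 201:400], momTot + momTot)
  # some missegregation must have happened at this rate
  expect_gt(sum(dTot[, 1:200] != momTot), 0)
})

test_that("missegregation probability scales with copy number", {
  set.seed(32)
  cfg <- SelectionConfig(mMisseg = 0.02)
  n <- 4000
  # disomic chromosomes: event probability 2 * m
  p <- founderPopulation("diploid_sequential", n)
  d <- divideCells(p, cfg)
  ev <- colSums(d@hom1[, 1:n, drop = FALSE] != p@hom1) +
        colSums(d@hom2[, 1:n, drop = FALSE] != p@hom2)
  rate <- sum(ev > 0) / n    # per-cell: 1 - (1 - 2m)^23
  expectRate <- 1 - (1 - 2 * 0.02)^23
  expect_equal(rate, expectRate, tolerance = 0.1)
  # a trisomic chromosome missegregates 1.5x as often as a disomic one
  h1 <- matrix(2L, 23, n, dimnames = list(chromosomeNames(), NULL))
  h2 <- matrix(1L, 23, n, dimnames = list(chromosomeNames(), NULL))
  p3 <- CellPopulation(h1, h2)
  d3 <- divideCells(p3, cfg)
  ev3 <- mean(d3@hom1[1, 1:n] != 2L | d3@hom2[1, 1:n] != 1L)
  expect_equal(ev3, 3 * 0.02, tolerance = 0.2)
})

test_that("a 2:1 trisomy losing its single homologue yields a UPID daughter", {
  set.seed(33)
  cfg <- SelectionConfig(mMisseg = 0.3)
  n <- 2000
  h1 <- matrix(1L, 23, n, dimnames = list(chromosomeNames(), NULL))
  h2 <- h1
  h1[1, ] <- 2L      # chromosome 1 trisomic (2,1)
  d <- divideCells(CellPopulation(h1, h2), cfg)
  a1 <- d@hom1[1, ]
  a2 <- d@hom2[1, ]
  lab <- classifyChromosome(a1, a2)
  # events split 2/3 toward the duplicated homologue: daughters (3,1)/(1,1),
  # and 1/3 toward the single one: daughters (2,2)/(2,0) - the UPID route
  expect_gt(sum(lab == "UPID"), 0)
  expect_gt(sum(lab == "tetrasomy_2_2"), 0)
  evTypes <- table(lab[lab != "trisomy"])
  hetRoute <- sum(evTypes[c("tetrasomy_3_1", "heterodisomy")])
  upidRoute <- sum(evTypes[c("tetrasomy_2_2", "UPID")])
  expect_equal(hetRoute / (hetRoute + upidRoute), 2 / 3, tolerance = 0.15)
})

test_that("tetraploid loss removes ~35% of chromosomes and can kill", {
  set.seed(34)
  cfg <- SelectionConfig()
  p <- founderPopulation("tetraploid_sequential", 1000)
  q <- applyTetraploidLoss(p, cfg)
  lost <- sum(p@hom1 + p@hom2) - sum(q@hom1 + q@hom2)
  expect_equal(lost / (23 * 1000), 0.35, tolerance = 0.05)
  # (2,2) losing one copy is always (2,1) up to homologue order
  tot <- q@hom1 + q@hom2
  expect_true(all(tot %in% c(3L, 4L)))
  # a (1,0) chromosome hit by loss becomes nullisomic
  h1 <- matrix(1L, 23, 500, dimnames = list(chromosomeNames(), NULL))
  h2 <- matrix(0L, 23, 500, dimnames = list(chromosomeNames(), NULL))
  q2 <- applyTetraploidLoss(CellPopulation(h1, h2), cfg)
  expect_gt(sum(q2@hom1 + q2@hom2 == 0L), 0)
})

test_that("survival follows the clamped score and kills nullisomic cells", {
  set.seed(35)
  cfg <- SelectionConfig()
  n <- 20000
  p <- founderPopulation("diploid_sequential", n)
  s <- survivalFilter(p, cfg)
  # diploid cells survive at 50%, within 3 binomial SE
  se <- sqrt(0.25 / n)
  expect_lt(abs(ncells(s) / n - 0.5), 3 * se)
  # a nullisomic cell never survives
  h1 <- p@hom1[, 1:100, drop = FALSE]
  h2 <- p@hom2[, 1:100, drop = FALSE]
  h1[5, ] <- 0L
  h2[5, ] <- 0L
  expect_identical(ncells(survivalFilter(CellPopulation(h1, h2), cfg)), 0L)
  # score >= 1 always survives (tetraploid/sequential without penalty
  # and with maximal gains is not the case here; construct directly)
  h1 <- matrix(1L, 23, 50, dimnames = list(chromosomeNames(), NULL))
  h2 <- h1
  for (ch in c("X", "4", "6", "10", "14", "17", "18", "21")) h1[ch, ] <- 2L
  pop <- CellPopulation(h1, h2)
  sc <- sScore(pop, cfg, aneuploidyPenalty = FALSE)
  expect_true(all(sc < 1))   # 0.5 + 9/23 < 1: not a certain survivor
})

test_that("culling and replenishment restore the configured size", {
  set.seed(36)
  cfg <- SelectionConfig(popSize = 500L)
  big <- founderPopulation("diploid_sequential", 900)
  expect_identical(ncells(cullAndReplenish(big, "diploid_sequential", cfg)), 500L)
  small <- founderPopulation("diploid_tripolar", 490)
  topped <- cullAndReplenish(small, "diploid_tripolar", cfg)
  expect_identical(ncells(topped), 500L)
  # resample mode duplicates survivors instead of drawing founders
  cfgR <- SelectionConfig(popSize = 500L, replenishMode = "resample")
  h1 <- matrix(1L, 23, 10, dimnames = list(chromosomeNames(), NULL))
  h1[1, ] <- 3L                      # marker absent from fresh founders
  pop <- CellPopulation(h1, h1 * 0L + 1L)
  topped <- cullAndReplenish(pop, "diploid_sequential", cfgR)
  expect_true(all(topped@hom1[1, ] == 3L))
  # an empty population is fully re-founded even in resample mode
  empty <- CellPopulation(h1[, 0, drop = FALSE], h1[, 0, drop = FALSE])
  expect_identical(ncells(cullAndReplenish(empty, "diploid_sequential", cfgR)),
                   500L)
})

test_that("simulation runs are bit-reproducible under a fixed seed", {
  cfg <- SelectionConfig(popSize = 400L, maxGenerations = 15L)
  a <- runSimulation("diploid_tripolar", cfg, seed = 99, stopRule = FALSE)
  b <- runSimulation("diploid_tripolar", cfg, seed = 99, stopRule = FALSE)
  expect_identical(finalPopulation(a)@hom1, finalPopulation(b)@hom1)
  expect_identical(telemetry(a), telemetry(b))
  c <- runSimulation("diploid_tripolar", cfg, seed = 100, stopRule = FALSE)
  expect_false(identical(finalPopulation(a)@hom1, finalPopulation(c)@hom1))
})

test_that("without variation, a clonal population's composition is static", {
  # practically zero missegregation: selection without variation can
  # change frequencies only, and a diploid founder population is clonal
  cfg <- SelectionConfig(popSize = 300L, maxGenerations = 10L,
                         mMisseg = 1e-15)
  r <- runSimulation("diploid_sequential", cfg, seed = 5, stopRule = FALSE)
  fp <- finalPopulation(r)
  expect_true(all(fp@hom1 == 1L) && all(fp@hom2 == 1L))
  expect_true(all(telemetry(r)$upidFrequency == 0))
})

test_that("no nullisomic cell survives into any recorded population", {
  cfg <- SelectionConfig(popSize = 300L, maxGenerations = 8L)
  for (m in c("tetraploid_sequential", "mitotic_catastrophe")) {
    r <- runSimulation(m, cfg, seed = 7, stopRule = FALSE)
    fp <- finalPopulation(r)
    expect_true(all(colSums(fp@hom1 + fp@hom2 == 0L) == 0))
  }
})

test_that("trajectory summaries preserve constants and founder levels", {
  cfg <- SelectionConfig(popSize = 300L, maxGenerations = 12L,
                         mMisseg = 1e-15)
  r <- runSimulation("diploid_sequential", cfg, seed = 8, stopRule = FALSE)
  tr <- trajectorySummary(list(r, r))
  expect_true(all(tr$medianMCN == 46))
  expect_equal(tr$smoothed, rep(46, nrow(tr)), tolerance = 1e-8)
  # diploid/tripolar trajectories start near the founder expectation (~61)
  cfg2 <- SelectionConfig(popSize = 2000L, maxGenerations = 3L)
  r2 <- runSimulation("diploid_tripolar", cfg2, seed = 9, stopRule = FALSE)
  expect_gt(telemetry(r2)$medianMCN[1], 55)
})
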