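# The generation loop. All heavy lifting happens on bare 23-by-n integer
# matrices; CellPopulation objects are built only at API boundaries.

# one round of mitoses: every cell produces two daughters. Per chromosome,
# a missegregation event occurs with probability mMisseg * N (N = copy
# number, at most one event per chromosome per division); the moved copy
# comes from a homologue chosen proportionally to its copy number and is
# assigned +1/-1 to a uniformly chosen daughter. Totals across the two
# daughters always sum to twice the mother's.
.divideAll <- function(h1, h2, config) {
  m <- ncol(h1)
  N <- h1 + h2
  ev <- which(stats::runif(23L * m) < config@mMisseg * N)
  d1 <- matrix(0L, 23L, m)
  d2 <- matrix(0L, 23L, m)
  if (length(ev)) {
    pickHom1 <- stats::runif(length(ev)) * N[ev] < h1[ev]
    sgn <- sample(c(-1L, 1L), length(ev), replace = TRUE)
    d1[ev[pickHom1]] <- sgn[pickHom1]
    d2[ev[!pickHom1]] <- sgn[!pickHom1]
  }
  list(h1 = cbind(h1 + d1, h1 - d1), h2 = cbind(h2 + d2, h2 - d2))
}

# tetraploid/sequential loss process: per chromosome per daughter, with
# probability tetraploidLossProb one copy (uniform among copies) is lost
.applyLoss <- function(h1, h2, config) {
  m <- ncol(h1)
  N <- h1 + h2
  lose <- which(stats::runif(23L * m) < config@tetraploidLossProb & N > 0L)
  if (length(lose)) {
    fromHom1 <- stats::runif(length(lose)) * N[lose] < h1[lose]
    i1 <- lose[fromHom1]
    i2 <- lose[!fromHom1]
    h1[i1] <- h1[i1] - 1L
    h2[i2] <- h2[i2] - 1L
  }
  list(h1 = h1, h2 = h2)
}

#' Divide every cell of a population
#'
#' Runs one synchronous round of mitoses: the returned population holds
#' both daughters of every input cell (twice as many cells), after
#' missegregation with per-chromosome probability `mMisseg * N`.
#'
#' @param x A [CellPopulation].
#' @param config A [SelectionConfig].
#' @return A [CellPopulation] with `2 * ncells(x)` cells.
#' @examples
#' set.seed(1)
#' p <- founderPopulation("diploid_sequential", 10)
#' ncells(divideCells(p, SelectionConfig()))   # 20
#' @export
divideCells <- function(x, config = SelectionConfig()) {
  d <- .divideAll(x@hom1, x@hom2, config)
  CellPopulation(d$h1, d$h2, generation = x@generation + 1L)
}

#' Chromosome-loss step of the tetraploid/sequential model
#'
#' Applies the per-division loss process: each chromosome of each cell
#' independently loses one copy (uniform among its copies) with
#' probability `tetraploidLossProb`. Cells driven to nullisomy are
#' removed by the next [survivalFilter()].
#'
#' @inheritParams divideCells
#' @return A [CellPopulation].
#' @export
applyTetraploidLoss <- function(x, config = SelectionConfig()) {
  d <- .applyLoss(x@hom1, x@hom2, config)
  CellPopulation(d$h1, d$h2, generation = x@generation)
}

#' Survival selection
#'
#' Each cell survives independently with probability equal to its
#' survival score clamped to `[0, 1]`; cells with any nullisomic
#' chromosome are removed unconditionally.
#'
#' @inheritParams divideCells
#' @param aneuploidyPenalty Set `FALSE` for the tetraploid/sequential
#'   model, whose score omits the aneuploidy penalty.
#' @return A [CellPopulation] of the survivors.
#' @export
survivalFilter <- function(x, config = SelectionConfig(),
                           aneuploidyPenalty = TRUE) {
  keep <- .survive(x@hom1, x@hom2, config, aneuploidyPenalty)
  CellPopulation(x@hom1[, keep, drop = FALSE],
                 x@hom2[, keep, drop = FALSE],
                 generation = x@generation)
}

.survive <- function(h1, h2, config, aneuploidyPenalty) {
  sc <- .scoreMatrices(h1, h2, config, aneuploidyPenalty)
  noNulli <- colSums((h1 + h2) == 0L) == 0L
  noNulli & (stats::runif(ncol(h1)) < pmin(pmax(sc, 0), 1))
}

#' Cull or replenish a population to the configured size
#'
#' Uniformly subsamples populations above `popSize`; populations below it
#' are topped up, either with fresh founder draws of the initiation model
#' (`replenishMode = "founders"`) or by resampling survivors with
#' replacement (`"resample"`; falls back to founder draws when no
#' survivors remain).
#'
#' @inheritParams divideCells
#' @param model Initiation model supplying fresh founders.
#' @return A [CellPopulation] with exactly `popSize` cells.
#' @export
cullAndReplenish <- function(x, model, config = SelectionConfig()) {
  d <- .cull(x@hom1, x@hom2, model, config)
  CellPopulation(d$h1, d$h2, generation = x@generation)
}

.cull <- function(h1, h2, model, config) {
  n <- config@popSize
  k <- ncol(h1)
  if (k > n) {
    idx <- sample.int(k, n)
    h1 <- h1[, idx, drop = FALSE]
    h2 <- h2[, idx, drop = FALSE]
  } else if (k < n) {
    add <- n - k
    if (config@replenishMode == "resample" && k > 0L) {
      idx <- sample.int(k, add, replace = TRUE)
      f <- list(h1 = h1[, idx, drop = FALSE], h2 = h2[, idx, drop = FALSE])
    } else {
      f <- .drawFounders(model, add)
    }
    h1 <- cbind(h1, f$h1)
    h2 <- cbind(h2, f$h2)
  }
  list(h1 = h1, h2 = h2)
}

#' Run the clonal-evolution simulation
#'
#' Initializes `popSize` founder cells of the chosen initiation model and
#' iterates division (with missegregation), the loss process (for
#' tetraploid/sequential only), survival selection, and
#' culling/replenishment, until the tracked-chromosome UPID frequency
#' reaches `upidStop` or `maxGenerations` generations have elapsed. The
#' stop statistic is evaluated after culling each generation. Runs are
#' bit-reproducible given `(model, config, seed)`.
#'
#' Telemetry records, per generation: the number of division survivors,
#' the UPID frequency, and the median MCN of a subsample of at most
#' 10000 cells.
#'
#' @param model One of [initiationModels()].
#' @param config A [SelectionConfig].
#' @param seed Integer seed for the run.
#' @param stopRule Set `FALSE` to disable the UPID stopping rule and run
#'   for exactly `maxGenerations` generations (used to study long-run
#'   UPID plateaus).
#' @return A [SimRun].
#' @examples
#' cfg <- SelectionConfig(popSize = 500L, maxGenerations = 30L)
#' r <- runSimulation("tetraploid_sequential", cfg, seed = 1)
#' stopGeneration(r)
#' @export
runSimulation <- function(model, config = SelectionConfig(), seed = 1L,
                          stopRule = TRUE) {
  model <- match.arg(model, .MODELS)
  set.seed(as.integer(seed))
  penalty <- model != "tetraploid_sequential"
  trackedIdx <- match(config@trackedChromosomes, .CHR)
  f <- .drawFounders(model, config@popSize)
  h1 <- f$h1
  h2 <- f$h2
  gens <- integer(0)
  survivors <- integer(0)
  upid <- numeric(0)
  medMCN <- numeric(0)
  stopReason <- "max_generations"
  stopGen <- config@maxGenerations
  uf <- .upidStat(h1, h2, trackedIdx, config@upidDenominator)
  if (stopRule && uf >= config@upidStop) {
    stopGen <- 0L
    stopReason <- "upid_threshold"
  } else {
    for (g in seq_len(config@maxGenerations)) {
      d <- .divideAll(h1, h2, config)
      if (model == "tetraploid_sequential") d <- .applyLoss(d$h1, d$h2, config)
      keep <- .survive(d$h1, d$h2, config, penalty)
      h1 <- d$h1[, keep, drop = FALSE]
      h2 <- d$h2[, keep, drop = FALSE]
      nSurv <- ncol(h1)
      d <- .cull(h1, h2, model, config)
      h1 <- d$h1
      h2 <- d$h2
      uf <- .upidStat(h1, h2, trackedIdx, config@upidDenominator)
      sub <- if (ncol(h1) > 10000L) sample.int(ncol(h1), 10000L) else seq_len(ncol(h1))
      gens[g] <- g
      survivors[g] <- nSurv
      upid[g] <- uf
      medMCN[g] <- stats::median(colSums(h1[, sub, drop = FALSE] +
                                         h2[, sub, drop = FALSE]))
      if (stopRule && uf >= config@upidStop) {
        stopGen <- g
        stopReason <- "upid_threshold"
        break
      }
      if (g == config@maxGenerations) stopGen <- g
    }
  }
  new("SimRun",
      model = model, config = config,
      stopGeneration = as.integer(stopGen), stopReason = stopReason,
      finalPopulation = CellPopulation(h1, h2, generation = as.integer(stopGen)),
      telemetry = data.frame(generation = gens, nSurvivors = survivors,
                             upidFrequency = upid, medianMCN = medMCN),
      seed = as.integer(seed))
}

#' Median-MCN trajectory across replicate runs
#'
#' Pools the per-generation median MCN telemetry of replicate runs and
#' smooths the median-of-medians curve with LOESS (tricube-weighted local
#' linear regression). Used to distinguish punctuated initiation (curve
#' starts high and stays flat) from gradual sequential gain (curve starts
#' at 46 and rises).
#'
#' @param runs A list of [SimRun] objects (or a single run).
#' @param span LOESS span (default 0.3).
#' @return A data.frame with columns `generation`, `medianMCN` (median
#'   across runs of the per-run median MCN) and `smoothed`.
#' @export
trajectorySummary <- function(runs, span = 0.3) {
  if (is(runs, "SimRun")) runs <- list(runs)
  stopifnot(length(runs) >= 1L)
  tel <- lapply(runs, function(r) telemetry(r)[, c("generation", "medianMCN")])
  all <- do.call(rbind, tel)
  agg <- stats::aggregate(medianMCN ~ generation, all, stats::median)
  agg <- agg[order(agg$generation), ]
  if (nrow(agg) >= 10L && stats::sd(agg$medianMCN) > 0) {
    fit <- tryCatch(
      stats::loess(medianMCN ~ generation, agg, span = span, degree = 1L),
      error = function(e) NULL)
    agg$smoothed <- if (is.null(fit)) agg$medianMCN else stats::predict(fit)
  } else {
    agg$smoothed <- agg$medianMCN
  }
  rownames(agg) <- NULL
  agg
}
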