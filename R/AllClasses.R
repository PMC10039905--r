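#' @import methods
NULL

#' Chromosome complement used throughout the package
#'
#' The simulator models a female (46,XX) genome: autosomes 1-22 plus X,
#' giving 23 chromosome pairs. Y is never part of the simulator state
#' (cohort tables may still carry Y records for male cases; those are
#' handled by the cohort functions, not by the simulator).
#'
#' @return Character vector of the 23 chromosome names, `"1"`..`"22"`, `"X"`.
#' @examples
#' chromosomeNames()
#' @export
chromosomeNames <- function() c(as.character(1:22), "X")

.CHR <- c(as.character(1:22), "X")

# default selection groups (chromosome names)
.G1_DEFAULT <- c("X", "4", "6", "10", "14", "17", "18")
.G2_DEFAULT <- "21"
.G3B_DEFAULT <- c("1", "2", "3", "7", "9", "13", "15", "16", "19", "20")
.G4_DEFAULT <- c("5", "8", "11", "12", "22")
.TRACKED_DEFAULT <- c("1", "2", "3", "5", "7", "8", "11", "12", "13",
                      "15", "16", "19", "20", "22")

.MODELS <- c("diploid_sequential", "tetraploid_sequential",
             "diploid_tripolar", "tetraploid_tripolar",
             "mitotic_catastrophe")

#' @rdname SelectionConfig
#' @export
setClass("SelectionConfig",
  representation(
    group1 = "character",
    group2 = "character",
    group3b = "character",
    group4 = "character",
    baseSurvival = "numeric",
    group2Weight = "numeric",
    group4Weight = "numeric",
    mMisseg = "numeric",
    tetraploidLossProb = "numeric",
    penaltyShape1 = "numeric",
    penaltyShape2 = "numeric",
    penaltyLoc = "numeric",
    penaltyScale = "numeric",
    penaltyForm = "character",
    scoreForm = "character",
    ntCounting = "character",
    popSize = "integer",
    upidStop = "numeric",
    upidDenominator = "character",
    maxGenerations = "integer",
    trackedChromosomes = "character",
    replenishMode = "character"
  )
)

setValidity("SelectionConfig", function(object) {
  msg <- character(0)
  g3 <- setdiff(.CHR, c(object@group1, object@group2))
  if (!all(object@group1 %in% .CHR)) msg <- c(msg, "group1 contains unknown chromosomes")
  if (!all(object@group2 %in% .CHR)) msg <- c(msg, "group2 contains unknown chromosomes")
  if (length(intersect(object@group1, object@group2)))
    msg <- c(msg, "group1 and group2 overlap")
  if (!setequal(c(object@group3b, object@group4), g3))
    msg <- c(msg, "group3b and group4 must partition the complement of group1/group2")
  if (length(intersect(object@group3b, object@group4)))
    msg <- c(msg, "group3b and group4 overlap")
  probs <- c(object@baseSurvival, object@tetraploidLossProb, object@upidStop)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@mMisseg <= 0) msg <- c(msg, "mMisseg must be positive")
  if (object@popSize < 1L) msg <- c(msg, "popSize must be at least 1")
  if (object@maxGenerations < 1L) msg <- c(msg, "maxGenerations must be at least 1")
  if (!object@penaltyForm %in% c("cumulative", "density"))
    msg <- c(msg, "penaltyForm must be 'cumulative' or 'density'")
  if (!object@scoreForm %in% c("threeGroup", "fourGroup"))
    msg <- c(msg, "scoreForm must be 'threeGroup' or 'fourGroup'")
  if (!object@ntCounting %in% c("gainsAndLosses", "trisomyOnly"))
    msg <- c(msg, "ntCounting must be 'gainsAndLosses' or 'trisomyOnly'")
  if (!object@upidDenominator %in% c("disomies", "allTracked"))
    msg <- c(msg, "upidDenominator must be 'disomies' or 'allTracked'")
  if (!object@replenishMode %in% c("founders", "resample"))
    msg <- c(msg, "replenishMode must be 'founders' or 'resample'")
  if (!all(object@trackedChromosomes %in% .CHR))
    msg <- c(msg, "trackedChromosomes contains unknown chromosomes")
  if (length(msg)) msg else TRUE
})

#' Selection and simulation parameters
#'
#' `SelectionConfig` bundles every tunable parameter of the clonal-evolution
#' simulator: the chromosome selection groups, the missegregation rate, the
#' aneuploidy-penalty law, the population size, and the stopping rule.
#'
#' The survival/proliferation score of a cell is
#' \deqn{S = 0.5 + (NT_{g1} + 2\,NT_{g2} - NT_{g3})/23 - S_{aneuploidy}}
#' in the three-group form, where \eqn{NT_{g1}} counts group-1 chromosomes
#' in a gained state, \eqn{NT_{g2}} counts chromosome-21 gain, and
#' \eqn{NT_{g3}} counts aberrant chromosomes of the remaining group. The
#' four-group form splits the remainder into a negatively selected group 3b
#' and a weakly positively selected group 4 (weight 0.02). The aneuploidy
#' penalty is a beta law in \eqn{x = (MCN - 46)/46}; see [sAneuploidy()]
#' for the form and the choice of shape parameters.
#'
#' @param group1 Chromosomes under strong positive selection when gained
#'   (default X, 4, 6, 10, 14, 17, 18).
#' @param group2 Chromosome whose gain carries double weight (default 21).
#' @param group3b Negatively selected chromosomes in the four-group score.
#' @param group4 Weakly positively selected chromosomes in the four-group
#'   score (default 5, 8, 11, 12, 22; weight `group4Weight`).
#' @param baseSurvival Survival probability of a normal diploid cell (0.5).
#' @param group2Weight Weight of a group-2 gain in the score (2).
#' @param group4Weight Weight of a group-4 gain in the four-group score (0.02).
#' @param mMisseg Missegregation rate per chromosome copy per mitosis
#'   (15e-4); the per-chromosome event probability is `mMisseg` times the
#'   chromosome's copy number.
#' @param tetraploidLossProb Per-chromosome probability of losing one copy
#'   at division in the tetraploid/sequential model (0.35).
#' @param penaltyShape1,penaltyShape2 Shape parameters of the beta penalty
#'   law (defaults 0.65 and 0.18; see [sAneuploidy()] for why this role
#'   assignment, rather than the reverse, is the default).
#' @param penaltyLoc,penaltyScale Location (0) and scale (1.8) of the beta law.
#' @param penaltyForm `"cumulative"` (monotone increasing penalty, default)
#'   or `"density"` (scaled beta density).
#' @param scoreForm `"threeGroup"` (default) or `"fourGroup"`.
#' @param ntCounting How aberrant chromosomes are counted:
#'   `"gainsAndLosses"` (default; group-3 chromosomes count whenever the
#'   copy total differs from 2, positively selected groups count when the
#'   total is 3 or more) or `"trisomyOnly"` (only exact trisomies count).
#' @param popSize Number of virtual cells carried between generations (50000).
#' @param upidStop UPID-frequency stopping threshold (0.025).
#' @param upidDenominator Denominator of the stop statistic: `"disomies"`
#'   (UPIDs over all disomic tracked chromosomes, default) or `"allTracked"`
#'   (UPIDs over all tracked chromosome slots).
#' @param maxGenerations Hard generation cap (2000).
#' @param trackedChromosomes Chromosomes entering the UPID stop statistic
#'   (default 1-3, 5, 7, 8, 11-13, 15, 16, 19, 20, 22).
#' @param replenishMode How a population below `popSize` is topped up:
#'   `"founders"` (fresh draws from the initiation model, default) or
#'   `"resample"` (resampling survivors with replacement).
#'
#' @return A validated `SelectionConfig` object.
#' @examples
#' cfg <- SelectionConfig(popSize = 1000L)
#' cfg
#' @export
SelectionConfig <- function(group1 = .G1_DEFAULT,
                            group2 = .G2_DEFAULT,
                            group3b = .G3B_DEFAULT,
                            group4 = .G4_DEFAULT,
                            baseSurvival = 0.5,
                            group2Weight = 2,
                            group4Weight = 0.02,
                            mMisseg = 15e-4,
                            tetraploidLossProb = 0.35,
                            penaltyShape1 = 0.65,
                            penaltyShape2 = 0.18,
                            penaltyLoc = 0,
                            penaltyScale = 1.8,
                            penaltyForm = c("cumulative", "density"),
                            scoreForm = c("threeGroup", "fourGroup"),
                            ntCounting = c("gainsAndLosses", "trisomyOnly"),
                            popSize = 50000L,
                            upidStop = 0.025,
                            upidDenominator = c("disomies", "allTracked"),
                            maxGenerations = 2000L,
                            trackedChromosomes = .TRACKED_DEFAULT,
                            replenishMode = c("founders", "resample")) {
  new("SelectionConfig",
      group1 = as.character(group1), group2 = as.character(group2),
      group3b = as.character(group3b), group4 = as.character(group4),
      baseSurvival = baseSurvival, group2Weight = group2Weight,
      group4Weight = group4Weight, mMisseg = mMisseg,
      tetraploidLossProb = tetraploidLossProb,
      penaltyShape1 = penaltyShape1, penaltyShape2 = penaltyShape2,
      penaltyLoc = penaltyLoc, penaltyScale = penaltyScale,
      penaltyForm = match.arg(penaltyForm),
      scoreForm = match.arg(scoreForm),
      ntCounting = match.arg(ntCounting),
      popSize = as.integer(popSize), upidStop = upidStop,
      upidDenominator = match.arg(upidDenominator),
      maxGenerations = as.integer(maxGenerations),
      trackedChromosomes = as.character(trackedChromosomes),
      replenishMode = match.arg(replenishMode))
}

#' Group-3 chromosomes of a configuration
#'
#' The chromosomes under negative selection in the three-group score: the
#' complement of `group1` and `group2` (equivalently, group 3b plus group 4).
#'
#' @param config A [SelectionConfig] object.
#' @return Character vector of chromosome names.
#' @export
group3Chromosomes <- function(config) {
  setdiff(.CHR, c(config@group1, config@group2))
}

#' @rdname CellPopulation
#' @export
setClass("CellPopulation",
  representation(
    hom1 = "matrix",
    hom2 = "matrix",
    generation = "integer"
  )
)

setValidity("CellPopulation", function(object) {
  msg <- character(0)
  if (!identical(dim(object@hom1), dim(object@hom2)))
    msg <- c(msg, "hom1 and hom2 must have identical dimensions")
  if (nrow(object@hom1) != 23L)
    msg <- c(msg, "homologue matrices must have 23 rows (chromosomes 1-22, X)")
  if (!identical(rownames(object@hom1), .CHR))
    msg <- c(msg, "homologue matrices must have rownames 1..22, X")
  if (!is.integer(object@hom1) || !is.integer(object@hom2))
    msg <- c(msg, "homologue counts must be integer")
  if (length(object@hom1) && (min(object@hom1) < 0L || min(object@hom2) < 0L))
    msg <- c(msg, "homologue counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Homologue-resolved cell population
#'
#' A generation of virtual cells. Each cell is a homologue-resolved
#' karyotype over the 23 chromosome pairs (1-22, X): slot `hom1` holds the
#' copy number of one parental homologue and `hom2` the other, as
#' 23-by-n integer matrices (cells in columns). The homologue labels are
#' abstract bookkeeping labels; no parental phasing is implied.
#'
#' @param hom1,hom2 23-by-n integer matrices of homologue copy numbers,
#'   rows named `chromosomeNames()`.
#' @param generation Generation index of this population (0 for founders).
#' @return A `CellPopulation` object.
#' @seealso [founderPopulation()], [runSimulation()], [mcn()],
#'   [upidFrequency()]
#' @examples
#' p <- founderPopulation("diploid_sequential", 5)
#' mcn(p)
#' @export
CellPopulation <- function(hom1, hom2, generation = 0L) {
  storage.mode(hom1) <- "integer"
  storage.mode(hom2) <- "integer"
  rownames(hom1) <- .CHR
  rownames(hom2) <- .CHR
  new("CellPopulation", hom1 = hom1, hom2 = hom2,
      generation = as.integer(generation))
}

#' @rdname SimRun
#' @export
setClass("SimRun",
  representation(
    model = "character",
    config = "SelectionConfig",
    stopGeneration = "integer",
    stopReason = "character",
    finalPopulation = "CellPopulation",
    telemetry = "data.frame",
    seed = "integer"
  )
)

setValidity("SimRun", function(object) {
  msg <- character(0)
  if (!object@model %in% .MODELS)
    msg <- c(msg, paste("model must be one of:", paste(.MODELS, collapse = ", ")))
  if (!object@stopReason %in% c("upid_threshold", "max_generations"))
    msg <- c(msg, "stopReason must be 'upid_threshold' or 'max_generations'")
  if (object@stopGeneration > object@config@maxGenerations)
    msg <- c(msg, "stopGeneration exceeds maxGenerations")
  if (length(msg)) msg else TRUE
})

#' Result of one simulation run
#'
#' Holds the stopping point, the final population, and per-generation
#' telemetry (UPID frequency, median MCN, population size) of a single
#' seeded run of [runSimulation()].
#'
#' Accessors: [stopGeneration()], [stopReason()], [finalPopulation()],
#' [telemetry()].
#'
#' @name SimRun
#' @seealso [runSimulation()], [trajectorySummary()]
NULL
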