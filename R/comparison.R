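# RMSE comparison of simulated populations against a cohort profile,
# on the two profile families used for model discrimination:
#  (a) per-MCN mean trisomy and tetrasomy counts,
#  (b) per-chromosome aberration-class frequencies
#      (monosomy, UPID, trisomy, tetrasomy 2:2, tetrasomy 3:1, pentasomy+).

#' Root-mean-square error between two aligned profiles
#'
#' @param observed,simulated Numeric vectors of equal length over aligned
#'   bins.
#' @return `sqrt(mean((observed - simulated)^2))`.
#' @examples
#' rmse(c(0, 1, 2), c(1, 1, 1))   # sqrt(2/3)
#' @export
rmse <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stop("profile length mismatch: ", length(observed), " vs ",
         length(simulated))
  if (!length(observed)) stop("profiles must have length >= 1")
  sqrt(mean((observed - simulated)^2))
}

.ABERRATION_CLASSES <- c("monosomy", "UPID", "trisomy", "tetrasomy_2_2",
                         "tetrasomy_3_1", "pentasomy_plus")

#' Build the comparison profiles of a cohort
#'
#' Computes the two profile families used for model ranking: the per-MCN
#' mean trisomy/tetrasomy curves and the per-chromosome frequencies of
#' the aberration classes (monosomy, UPID, trisomy, tetrasomy 2:2,
#' tetrasomy 3:1, pentasomy and above), as fractions of cases.
#' Chromosome Y records are excluded so that simulator output (46,XX
#' model) and patient cohorts are compared on the same 23 pairs.
#'
#' @param cohort A cohort table (see [readCohortTable()]).
#' @return A list with `perMCN` (data.frame: mcn, nCases, meanTrisomies,
#'   meanTetrasomies) and `perChromosome` (23-row data.frame of class
#'   frequencies), plus `nCases`.
#' @export
cohortProfile <- function(cohort) {
  .checkCohort(cohort)
  cohort <- cohort[cohort$chromosome != "Y", , drop = FALSE]
  prof <- mcnProfiles(cohort)
  dom <- .dominant(cohort)
  nCases <- length(unique(dom$case_id))
  lab <- classifyChromosome(dom$hom1, dom$hom2)
  lab[lab == "heterodisomy"] <- "disomy"      # not an aberration class
  lab[lab == "tetrasomy_4_0"] <- "tetrasomy_3_1"  # rare; pooled with 3:1
  per <- do.call(rbind, lapply(.CHR, function(ch) {
    ll <- lab[dom$chromosome == ch]
    row <- vapply(.ABERRATION_CLASSES,
                  function(cl) if (length(ll)) mean(ll == cl) else 0,
                  numeric(1))
    data.frame(chromosome = ch, t(row))
  }))
  rownames(per) <- NULL
  list(perMCN = prof$perMCN, perChromosome = per, nCases = nCases)
}

#' Compare simulated models against a cohort profile by RMSE
#'
#' Samples cells from each model's final population(s), builds the same
#' profile families as [cohortProfile()], and scores each model by RMSE
#' against the cohort: separately for the per-MCN trisomy curve, the
#' per-MCN tetrasomy curve, and the per-chromosome aberration-frequency
#' profile, plus their sum as a single ranking score (the summation is a
#' convenience of this package; the component RMSEs are the primary
#' output). MCN bins absent from the cohort are skipped, not
#' zero-filled.
#'
#' @param cohort A cohort table, or a profile list from [cohortProfile()].
#' @param runs A named list: one entry per model, each a [SimRun], a
#'   [CellPopulation], or a list of them.
#' @param sampleSize Cells sampled per model (default 1e6, capped at the
#'   available cells).
#' @param seed Integer seed for the subsampling.
#' @return A data.frame with one row per model: `rmseTrisomyMCN`,
#'   `rmseTetrasomyMCN`, `rmsePerChromosome`, `rmseTotal` and `rank`
#'   (1 = best, i.e. lowest total).
#' @export
compareModels <- function(cohort, runs, sampleSize = 1e6, seed = 1L) {
  prof <- if (is.data.frame(cohort) || is.null(cohort$perChromosome))
    cohortProfile(cohort) else cohort
  set.seed(as.integer(seed))
  rows <- lapply(names(runs), function(model) {
    simCohort <- populationToCohort(runs[[model]], sampleSize = sampleSize)
    simProf <- cohortProfile(simCohort)
    # align per-MCN curves on the cohort's bins; skip bins the simulation
    # never produced (both absences are informative but incomparable)
    m <- merge(prof$perMCN, simProf$perMCN, by = "mcn",
               suffixes = c(".obs", ".sim"))
    rTri <- if (nrow(m)) rmse(m$meanTrisomies.obs, m$meanTrisomies.sim) else NA_real_
    rTet <- if (nrow(m)) rmse(m$meanTetrasomies.obs, m$meanTetrasomies.sim) else NA_real_
    obs <- as.matrix(prof$perChromosome[, .ABERRATION_CLASSES])
    sim <- as.matrix(simProf$perChromosome[, .ABERRATION_CLASSES])
    rChr <- rmse(as.vector(obs), as.vector(sim))
    data.frame(model = model, rmseTrisomyMCN = rTri, rmseTetrasomyMCN = rTet,
               rmsePerChromosome = rChr,
               rmseTotal = rTri + rTet + rChr)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$model), ]            # order-invariant output
  out$rank <- rank(out$rmseTotal, ties.method = "min")
  rownames(out) <- NULL
  out
}
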