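# Cohort-level karyotype statistics. A cohort table is a long-format
# data.frame with one row per case, chromosome and clone:
#   case_id, sex ("F"/"M"), chromosome ("1".."22","X","Y"), hom1, hom2,
#   clonal_fraction in (0,1], and optionally state_annotation.
# The dominant clone of a case/chromosome is the record with
# clonal_fraction >= 0.5; additional records are subclones.

.COHORT_COLS <- c("case_id", "sex", "chromosome", "hom1", "hom2",
                  "clonal_fraction")

.checkCohort <- function(cohort) {
  if (!all(.COHORT_COLS %in% names(cohort)))
    stop("cohort table must have columns: ",
         paste(.COHORT_COLS, collapse = ", "))
  bad <- !cohort$chromosome %in% c(.CHR, "Y")
  if (any(bad))
    stop("unknown chromosome labels: ",
         paste(unique(cohort$chromosome[bad]), collapse = ", "))
  if (any(cohort$hom1 < 0, na.rm = TRUE) || any(cohort$hom2 < 0, na.rm = TRUE))
    stop("homologue copy numbers must be non-negative")
  if (any(cohort$clonal_fraction <= 0 | cohort$clonal_fraction > 1))
    stop("clonal_fraction must lie in (0, 1]")
  invisible(cohort)
}

.dominant <- function(cohort) cohort[cohort$clonal_fraction >= 0.5, , drop = FALSE]

.totalCopies <- function(cohort) cohort$hom1 + cohort$hom2

.stateFromTotal <- function(tot) {
  cut(tot, breaks = c(-1, 0, 1, 2, 3, 4, Inf),
      labels = c("nullisomy", "monosomy", "disomy", "trisomy",
                 "tetrasomy", "pentasomy_plus"))
}

#' Read or write a cohort karyotype table
#'
#' Long-format TSV with columns `case_id`, `sex`, `chromosome`, `hom1`,
#' `hom2`, `clonal_fraction` (and optionally `state_annotation`).
#'
#' @param file Path to the TSV file.
#' @param cohort A cohort data.frame.
#' @return `readCohortTable()` returns the validated data.frame;
#'   `writeCohortTable()` returns `file` invisibly.
#' @export
readCohortTable <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = list(chromosome = "character",
                                            case_id = "character"))
  .checkCohort(df)
}

#' @rdname readCohortTable
#' @export
writeCohortTable <- function(cohort, file) {
  .checkCohort(cohort)
  utils::write.table(cohort, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Copy-state spectrum of a cohort
#'
#' Counts and fractions of chromosome pairs per copy state (dominant
#' clone records only), pooled over the whole cohort.
#'
#' @param cohort A cohort table (see [readCohortTable()]).
#' @return A data.frame with columns `state`, `count`, `fraction`;
#'   fractions sum to 1.
#' @examples
#' set.seed(1)
#' co <- generateCohort(cohortGeneratorConfig(nCases = 50))
#' copyStateSpectrum(co)
#' @export
copyStateSpectrum <- function(cohort) {
  .checkCohort(cohort)
  dom <- .dominant(cohort)
  st <- .stateFromTotal(.totalCopies(dom))
  tab <- table(st)
  data.frame(state = names(tab),
             count = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab))
}

#' Tetrasomy 2:2 versus 3:1 typing
#'
#' Among dominant-clone tetrasomies with homologue resolution, the share
#' of the 2:2 type (both homologues duplicated), the 3:1 type (one
#' homologue triplicated) and the 4:0 type, overall and per chromosome.
#' Records without homologue resolution (by convention, the total copy
#' number in `hom1` and `NA` in `hom2`) are excluded and counted.
#'
#' @param cohort A cohort table.
#' @return A list with `overall` (named fractions plus `n`),
#'   `perChromosome` (data.frame) and `nUnresolved`.
#' @export
tetrasomyTypeFractions <- function(cohort) {
  .checkCohort(cohort)
  dom <- .dominant(cohort)
  tot <- ifelse(is.na(dom$hom2), dom$hom1, dom$hom1 + dom$hom2)
  tet <- dom[!is.na(tot) & tot == 4L, , drop = FALSE]
  unresolved <- is.na(tet$hom1) | is.na(tet$hom2)
  res <- tet[!unresolved, , drop = FALSE]
  hi <- pmax(res$hom1, res$hom2)
  type <- c("2" = "tetrasomy_2_2", "3" = "tetrasomy_3_1",
            "4" = "tetrasomy_4_0")[as.character(hi)]
  overall <- c(
    frac_2_2 = mean(type == "tetrasomy_2_2"),
    frac_3_1 = mean(type == "tetrasomy_3_1"),
    frac_4_0 = mean(type == "tetrasomy_4_0"),
    n = nrow(res)
  )
  per <- do.call(rbind, lapply(split(type, res$chromosome), function(tt) {
    data.frame(n = length(tt),
               frac_2_2 = mean(tt == "tetrasomy_2_2"),
               frac_3_1 = mean(tt == "tetrasomy_3_1"))
  }))
  if (!is.null(per)) per <- cbind(chromosome = rownames(per), per)
  rownames(per) <- NULL
  list(overall = overall, perChromosome = per,
       nUnresolved = sum(unresolved))
}

#' Per-chromosome UPID / all-disomy ratio
#'
#' For every chromosome, the fraction of dominant-clone disomies that are
#' uniparental isodisomies (2:0). Chromosomes with no disomies are
#' reported as `NA`.
#'
#' @param cohort A cohort table.
#' @return A data.frame with columns `chromosome`, `nDisomy`, `nUPID`,
#'   `ratio`.
#' @export
upidDisomyRatio <- function(cohort) {
  .checkCohort(cohort)
  dom <- .dominant(cohort)
  tot <- .totalCopies(dom)
  dis <- dom[!is.na(tot) & tot == 2L, , drop = FALSE]
  chroms <- intersect(c(.CHR, "Y"), unique(dom$chromosome))
  out <- do.call(rbind, lapply(chroms, function(ch) {
    d <- dis[dis$chromosome == ch, , drop = FALSE]
    nUP <- sum(pmax(d$hom1, d$hom2) == 2L, na.rm = TRUE)
    data.frame(chromosome = ch, nDisomy = nrow(d), nUPID = nUP,
               ratio = if (nrow(d)) nUP / nrow(d) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Per-case MCN and per-MCN trisomy/tetrasomy profiles
#'
#' Computes each case's modal chromosome number (sum of dominant-clone
#' copy totals) and the number of trisomic, tetrasomic, pentasomic and
#' monosomic chromosomes, then the mean trisomy and tetrasomy counts at
#' each observed MCN. The cohort is additionally split at MCN 62, where
#' the trisomy-per-MCN relationship changes in hyperdiploid leukaemia
#' cohorts.
#'
#' @param cohort A cohort table.
#' @param splitAt MCN value separating the low and high groups (62).
#' @return A list with `perCase` (case_id, mcn, nTrisomy, nTetrasomy,
#'   nPentasomy, nMonosomy), `perMCN` (mcn, nCases, meanTrisomies,
#'   meanTetrasomies) and `groups` (case counts below/at-or-above the
#'   split).
#' @export
mcnProfiles <- function(cohort, splitAt = 62L) {
  .checkCohort(cohort)
  dom <- .dominant(cohort)
  tot <- .totalCopies(dom)
  perCase <- do.call(rbind, lapply(split(tot, dom$case_id), function(tt) {
    data.frame(mcn = sum(tt),
               nTrisomy = sum(tt == 3L), nTetrasomy = sum(tt == 4L),
               nPentasomy = sum(tt >= 5L), nMonosomy = sum(tt == 1L))
  }))
  perCase <- cbind(case_id = rownames(perCase), perCase)
  rownames(perCase) <- NULL
  perMCN <- do.call(rbind, lapply(split(perCase, perCase$mcn), function(d) {
    data.frame(mcn = d$mcn[1L], nCases = nrow(d),
               meanTrisomies = mean(d$nTrisomy),
               meanTetrasomies = mean(d$nTetrasomy))
  }))
  perMCN <- perMCN[order(perMCN$mcn), ]
  rownames(perMCN) <- NULL
  list(perCase = perCase, perMCN = perMCN,
       groups = c(low = sum(perCase$mcn < splitAt),
                  high = sum(perCase$mcn >= splitAt)))
}

#' Exact binomial test for subclonal disomy/trisomy versus UPID/trisomy
#'
#' Subclonality between a trisomy and a disomy can arise by loss of one
#' of the three chromosome copies; the lost copy is the single-copy
#' homologue with probability 1/3, producing a UPID, and one of the
#' duplicated copies with probability 2/3, producing a heterodisomy.
#' This test asks whether observed counts of the two subclonality forms
#' are consistent with that 2:1 expectation, using a two-sided exact
#' binomial test (minimum-likelihood method: the p-value sums the
#' probabilities of all outcomes no more likely than the observed one)
#' with success probability 1/3 for the UPID form.
#'
#' @param nDisomyTrisomy Number of cases with subclonal
#'   heterodisomy/trisomy.
#' @param nUpidTrisomy Number of cases with subclonal UPID/trisomy.
#' @return The two-sided p-value.
#' @examples
#' subclonalityRatioTest(2, 1)    # exactly the expected ratio: p = 1
#' @export
subclonalityRatioTest <- function(nDisomyTrisomy, nUpidTrisomy) {
  stopifnot(nDisomyTrisomy >= 0, nUpidTrisomy >= 0)
  n <- nDisomyTrisomy + nUpidTrisomy
  if (n < 1) stop("at least one observation is required")
  stats::binom.test(nUpidTrisomy, n, p = 1 / 3,
                    alternative = "two.sided")$p.value
}

#' Convert simulated populations to a cohort table
#'
#' Treats each sampled cell as one "case" with fully clonal records
#' (clonal fraction 1), enabling the cohort statistics and the model
#' comparison to run on simulator output.
#'
#' @param x A [CellPopulation], [SimRun], or list of either.
#' @param sampleSize Number of cells to sample (uniformly, pooled over
#'   all supplied populations); `Inf` keeps every cell.
#' @return A cohort table data.frame.
#' @export
populationToCohort <- function(x, sampleSize = Inf) {
  pops <- if (is(x, "CellPopulation")) list(x)
          else if (is(x, "SimRun")) list(finalPopulation(x))
          else lapply(x, function(e) if (is(e, "SimRun")) finalPopulation(e) else e)
  h1 <- do.call(cbind, lapply(pops, function(p) p@hom1))
  h2 <- do.call(cbind, lapply(pops, function(p) p@hom2))
  n <- ncol(h1)
  if (is.finite(sampleSize) && sampleSize < n) {
    idx <- sample.int(n, sampleSize)
    h1 <- h1[, idx, drop = FALSE]
    h2 <- h2[, idx, drop = FALSE]
    n <- ncol(h1)
  }
  data.frame(
    case_id = rep(paste0("cell", seq_len(n)), each = 23L),
    sex = "F",
    chromosome = rep(.CHR, n),
    hom1 = as.vector(h1),
    hom2 = as.vector(h2),
    clonal_fraction = 1
  )
}
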