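# Synthetic-data generators. These produce cohort tables, somatic
# variant tables and single-cell matrices with the statistical structure
# the analysis modules assume, calibrated to the marginal frequencies
# reported for large HeH ALL cohorts, so that every stage of the package
# can be exercised and validated by parameter recovery without access to
# patient-level data.

#' Configuration of the synthetic cohort generator
#'
#' Per-chromosome gain, tetrasomy and UPID probabilities defaulting to
#' the marginal frequencies reported for a 577-case HeH ALL cohort:
#' gains 21 (100\%), X (97\%), 14 (95\%), 6 (89\%), 18 (83\%), 4 (82\%),
#' 17 (78\%), 10 (74\%), 8 (38\%), 5 (23\%), 9 (19\%), 11 (14\%),
#' 12 (14\%), 22 (11\%), all others 5\%; per-case tetrasomy 21 (81\%),
#' X (20\%), 14 (17\%), 18 (12\%), 10 (8.3\%), 8 (2.6\%), 4 (1.7\%);
#' pentasomy 21 in 4.5\% of cases; 5\% of tetrasomies of the 3:1 type;
#' UPID in 2.5\% of disomic chromosomes except chromosome 9 (17\%).
#' Chromosome gains are sampled independently per chromosome (the
#' marginals are all that is known); `mcnRange` optionally rejects cases
#' outside the karyotype range of a diagnosed HeH cohort.
#'
#' @param nCases Number of cases to generate.
#' @param gainProb,tetraProb,pentaProb,upidProb Named probability
#'   vectors (see defaults).
#' @param tetra31Share Share of tetrasomies drawn as 3:1 rather than
#'   2:2 (0.05).
#' @param maleFraction Fraction of male cases (0.5). Male cases carry a
#'   Y record: gained (as XXYY-style co-gain) in 21\% and nullisomic in
#'   4\% of male cases.
#' @param subcloneRate Fraction of cases carrying one detectable
#'   subclonal whole-chromosome record (0.28).
#' @param subcloneFloor Bulk detectability floor for subclones (0.2);
#'   injected subclones are drawn with clonal fractions in
#'   `[subcloneFloor, 0.5)`.
#' @param mcnRange Optional integer range `c(lo, hi)`; cases outside it
#'   are redrawn (rejection), e.g. `c(51, 67)` for a diagnosis-style
#'   ascertainment. `NULL` (default) disables the constraint.
#' @return A list of class `cohortGeneratorConfig`.
#' @export
cohortGeneratorConfig <- function(nCases = 577L,
                                  gainProb = NULL, tetraProb = NULL,
                                  pentaProb = NULL, upidProb = NULL,
                                  tetra31Share = 0.05,
                                  maleFraction = 0.5,
                                  subcloneRate = 0.28,
                                  subcloneFloor = 0.2,
                                  mcnRange = NULL) {
  gp <- stats::setNames(rep(0.05, 23L), .CHR)
  gp[c("21", "X", "14", "6", "18", "4", "17", "10")] <-
    c(1.00, 0.97, 0.95, 0.89, 0.83, 0.82, 0.78, 0.74)
  gp[c("8", "5", "9", "11", "12", "22")] <-
    c(0.38, 0.23, 0.19, 0.14, 0.14, 0.11)
  tp <- stats::setNames(rep(0, 23L), .CHR)
  tp[c("21", "X", "14", "18", "10", "8", "4")] <-
    c(0.81, 0.20, 0.17, 0.12, 0.083, 0.026, 0.017)
  pp <- stats::setNames(rep(0, 23L), .CHR)
  pp["21"] <- 0.045
  up <- stats::setNames(rep(0.025, 23L), .CHR)
  up["9"] <- 0.17
  cfg <- list(nCases = as.integer(nCases),
              gainProb = if (is.null(gainProb)) gp else gainProb,
              tetraProb = if (is.null(tetraProb)) tp else tetraProb,
              pentaProb = if (is.null(pentaProb)) pp else pentaProb,
              upidProb = if (is.null(upidProb)) up else upidProb,
              tetra31Share = tetra31Share,
              maleFraction = maleFraction,
              subcloneRate = subcloneRate,
              subcloneFloor = subcloneFloor,
              mcnRange = mcnRange)
  stopifnot(all(unlist(cfg[c("gainProb", "tetraProb", "pentaProb",
                             "upidProb")]) >= 0),
            all(unlist(cfg[c("gainProb", "tetraProb", "pentaProb",
                             "upidProb")]) <= 1))
  class(cfg) <- "cohortGeneratorConfig"
  cfg
}

.drawCase <- function(cfg) {
  tot <- integer(23L)
  for (i in seq_along(.CHR)) {
    ch <- .CHR[i]
    if (stats::runif(1) < cfg$gainProb[ch]) {
      # gained chromosome: tetrasomy/pentasomy probabilities are
      # per-case marginals, so conditional on gain they are scaled by
      # the gain probability
      u <- stats::runif(1)
      p5 <- cfg$pentaProb[ch] / cfg$gainProb[ch]
      p4 <- cfg$tetraProb[ch] / cfg$gainProb[ch]
      tot[i] <- if (u < p5) 5L else if (u < p5 + p4) 4L else 3L
    } else tot[i] <- 2L
  }
  tot
}

#' Generate a synthetic cohort table
#'
#' Samples `nCases` homologue-resolved case karyotypes at the configured
#' marginal frequencies: each chromosome is gained independently with
#' its gain probability, promoted to tetrasomy/pentasomy with the
#' configured per-case rates, split 2:2 versus 3:1, and disomic
#' chromosomes become UPIDs at their configured rates. Subclonal records
#' below the bulk detectability floor are never emitted (they are merged
#' into the major clone); injected detectable subclones follow the
#' loss-from-trisomy rule (2/3 heterodisomy, 1/3 UPID).
#'
#' @param config A [cohortGeneratorConfig()].
#' @param seed Optional integer seed (seeds the RNG when supplied).
#' @return A cohort table data.frame (see [readCohortTable()]).
#' @examples
#' co <- generateCohort(cohortGeneratorConfig(nCases = 20), seed = 1)
#' copyStateSpectrum(co)
#' @export
generateCohort <- function(config = cohortGeneratorConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- config
  rows <- vector("list", cfg$nCases)
  if (cfg$nCases == 0L)
    return(data.frame(case_id = character(0), sex = character(0),
                      chromosome = character(0), hom1 = integer(0),
                      hom2 = integer(0), clonal_fraction = numeric(0)))
  for (k in seq_len(cfg$nCases)) {
    repeat {
      tot <- .drawCase(cfg)
      mcnCase <- sum(tot)
      if (is.null(cfg$mcnRange) ||
          (mcnCase >= cfg$mcnRange[1L] && mcnCase <= cfg$mcnRange[2L])) break
    }
    h1 <- integer(23L)
    h2 <- integer(23L)
    for (i in seq_len(23L)) {
      h <- switch(as.character(tot[i]),
        "2" = if (stats::runif(1) < cfg$upidProb[.CHR[i]]) c(2L, 0L) else c(1L, 1L),
        "3" = c(2L, 1L),
        "4" = if (stats::runif(1) < cfg$tetra31Share) c(3L, 1L) else c(2L, 2L),
        "5" = c(3L, 2L),
        c(1L, 1L))
      if (stats::runif(1) < 0.5) h <- rev(h)   # homologue labels are arbitrary
      h1[i] <- h[1L]
      h2[i] <- h[2L]
    }
    sex <- if (stats::runif(1) < cfg$maleFraction) "M" else "F"
    df <- data.frame(case_id = sprintf("case%03d", k), sex = sex,
                     chromosome = .CHR, hom1 = h1, hom2 = h2,
                     clonal_fraction = 1)
    if (sex == "M") {
      # males: the X slot models the X of an XY genome (still generated
      # above for simplicity); add a Y record: co-gained in 21% of male
      # cases, nullisomic in 4%
      u <- stats::runif(1)
      yTot <- if (u < 0.21) 2L else if (u < 0.25) 0L else 1L
      df <- rbind(df, data.frame(case_id = df$case_id[1L], sex = sex,
                                 chromosome = "Y",
                                 hom1 = yTot, hom2 = 0L,
                                 clonal_fraction = 1))
    }
    if (stats::runif(1) < cfg$subcloneRate) {
      tri <- which(tot == 3L)
      if (length(tri)) {
        i <- if (length(tri) == 1L) tri else sample(tri, 1L)
        frac <- stats::runif(1, cfg$subcloneFloor, 0.5)
        sub <- if (stats::runif(1) < 1 / 3) c(2L, 0L) else c(1L, 1L)
        df <- rbind(df, data.frame(case_id = df$case_id[1L], sex = sex,
                                   chromosome = .CHR[i],
                                   hom1 = sub[1L], hom2 = sub[2L],
                                   clonal_fraction = frac))
      }
    }
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic somatic variants with known timing
#'
#' Draws BTRI variants (on the duplicated homologue of a trisomic
#' chromosome, expected VAF 2/3 at purity 1) and B/ATRI variants
#' (single-homologue, expected VAF 1/3) with binomial read counts at the
#' given depth, purity-adjusted via [expectedTimingVafs()]. The true
#' label is kept in the `truth` column for recovery tests.
#'
#' @param karyotype A 23-by-2 karyotype matrix (see
#'   [diploidKaryotype()]); variants are placed on its trisomic
#'   chromosomes.
#' @param nBtri,nBatri Numbers of variants of each class.
#' @param depth Sequencing depth per variant (60).
#' @param purity Tumour purity (1).
#' @param seed Optional integer seed.
#' @return A variant table with columns `case_id`, `chromosome`,
#'   `position`, `ref`, `alt`, `alt_reads`, `depth`, `sample_phase`,
#'   `total_copies`, `purity`, `truth`.
#' @export
generateVariants <- function(karyotype, nBtri, nBatri, depth = 60L,
                             purity = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  .checkKaryotype(karyotype)
  tri <- rownames(karyotype)[rowSums(karyotype) == 3L]
  if (!length(tri) && (nBtri > 0L || nBatri > 0L))
    stop("karyotype has no trisomic chromosome to place variants on")
  n <- nBtri + nBatri
  if (n == 0L)
    return(data.frame(case_id = character(0), chromosome = character(0),
                      position = integer(0), ref = character(0),
                      alt = character(0), alt_reads = integer(0),
                      depth = integer(0), sample_phase = character(0),
                      total_copies = integer(0), purity = numeric(0),
                      truth = character(0)))
  ev <- expectedTimingVafs(purity)
  truth <- c(rep("BTRI", nBtri), rep("B_ATRI", nBatri))
  vaf <- ifelse(truth == "BTRI", ev["btri"], ev["batri"])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  data.frame(
    case_id = "synthetic",
    chromosome = sample(tri, n, replace = TRUE),
    position = sample.int(1e8, n),
    ref = ref,
    alt = vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1)),
    alt_reads = stats::rbinom(n, depth, vaf),
    depth = as.integer(depth),
    sample_phase = "diagnosis",
    total_copies = 3L,
    purity = purity,
    truth = truth
  )
}

#' Generate a synthetic single-cell copy-number matrix
#'
#' Draws cells from clone profiles at the given fractions, then perturbs
#' each entry by +/-1 with probability `noiseRate` (floored at 0),
#' emulating whole-chromosome copy-number calls on a clone-structured
#' cell population. True clone labels are kept in the `truth` attribute.
#'
#' @param cloneProfiles A clones-by-chromosomes matrix (or a single
#'   profile vector).
#' @param cloneFractions Clone fractions summing to 1.
#' @param nCells Number of cells.
#' @param noiseRate Per-entry perturbation probability (0).
#' @param seed Optional integer seed.
#' @return A cells-by-chromosomes integer matrix with attribute
#'   `"truth"` (clone index per cell).
#' @export
generateCellMatrix <- function(cloneProfiles, cloneFractions = 1,
                               nCells = 100L, noiseRate = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(dim(cloneProfiles)))
    cloneProfiles <- matrix(cloneProfiles, nrow = 1L)
  if (abs(sum(cloneFractions) - 1) > 1e-8)
    stop("clone fractions must sum to 1")
  stopifnot(nrow(cloneProfiles) == length(cloneFractions))
  idx <- sample.int(nrow(cloneProfiles), nCells, replace = TRUE,
                    prob = cloneFractions)
  mat <- cloneProfiles[idx, , drop = FALSE]
  if (noiseRate > 0) {
    hit <- matrix(stats::runif(length(mat)) < noiseRate, nrow(mat))
    delta <- matrix(sample(c(-1L, 1L), length(mat), replace = TRUE), nrow(mat))
    mat <- pmax(mat + hit * delta, 0L)
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- paste0("cell", seq_len(nCells))
  if (is.null(colnames(mat)) && ncol(mat) == 23L) colnames(mat) <- .CHR
  attr(mat, "truth") <- idx
  mat
}
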