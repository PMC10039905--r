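# Mutation timing on gained chromosomes. An SNV on a trisomic chromosome
# that arose BEFORE the gain and sits on the duplicated homologue is
# present on 2 of the 3 copies (expected VAF ~2/3 in a pure tumour); an
# SNV that arose after the gain, or before it on the homologue that was
# not duplicated, sits on 1 of 3 copies (VAF ~1/3). The former are BTRI
# ("before trisomy") calls, the latter B/ATRI ("before/after trisomy").
# A variant table is a data.frame with columns:
#   case_id, chromosome, position, ref, alt, alt_reads, depth,
#   sample_phase ("diagnosis"/"remission"/"relapse"), total_copies,
#   purity (tumour cell fraction), and optionally group / truth columns.

.VARIANT_COLS <- c("chromosome", "position", "alt_reads", "depth",
                   "total_copies")

.checkVariants <- function(v) {
  if (!all(.VARIANT_COLS %in% names(v)))
    stop("variant table must have columns: ",
         paste(.VARIANT_COLS, collapse = ", "))
  if (any(v$depth < 0) || any(v$alt_reads < 0) || any(v$alt_reads > v$depth))
    stop("need 0 <= alt_reads <= depth")
  invisible(v)
}

#' Expected variant allele fractions on a trisomic chromosome
#'
#' In a tumour/normal mixture with tumour purity `p`, a trisomic locus
#' has `3p + 2(1-p)` allele copies per cell on average; a duplicated-
#' homologue (BTRI) mutation contributes `2p` mutant copies and a
#' single-homologue (B/ATRI) mutation `p`.
#'
#' @param purity Tumour cell fraction in `[0, 1]`.
#' @return Named vector with expected VAFs `btri` and `batri`.
#' @examples
#' expectedTimingVafs(1)     # 2/3 and 1/3
#' @export
expectedTimingVafs <- function(purity = 1) {
  stopifnot(purity >= 0, purity <= 1)
  denom <- 3 * purity + 2 * (1 - purity)
  c(btri = 2 * purity / denom, batri = purity / denom)
}

#' Classify SNV timing relative to a trisomy
#'
#' Assigns each variant the label `BTRI` (expected VAF ~2/3, purity-
#' adjusted) or `B_ATRI` (~1/3) by comparing binomial read-count
#' likelihoods; `ambiguous` when the log-likelihood ratio is below
#' `llrThreshold` or the depth below `minDepth`; `not_applicable` for
#' variants outside a trisomic context. A fixed-VAF-window rule
#' (`method = "window"`: BTRI when VAF > 0.5, on trisomies, no
#' ambiguity band) is available for threshold-style analyses.
#'
#' @param variants A variant table (see [generateVariants()] for the
#'   column layout). A `purity` column is used when present (default 1).
#' @param minDepth Minimum read depth for a confident call (10).
#' @param llrThreshold Minimum natural-log likelihood ratio (2).
#' @param method `"likelihood"` (default) or `"window"`.
#' @return The input data.frame with a `timing` column added.
#' @export
classifyTiming <- function(variants, minDepth = 10L, llrThreshold = 2,
                           method = c("likelihood", "window")) {
  .checkVariants(variants)
  method <- match.arg(method)
  if (any(variants$depth == 0L)) stop("variants with zero depth")
  purity <- if ("purity" %in% names(variants)) variants$purity else 1
  ev <- vapply(purity, function(p) expectedTimingVafs(p), numeric(2))
  vaf <- variants$alt_reads / variants$depth
  lab <- rep("not_applicable", nrow(variants))
  tri <- variants$total_copies == 3L
  if (method == "likelihood") {
    llB <- stats::dbinom(variants$alt_reads, variants$depth, ev["btri", ], log = TRUE)
    llA <- stats::dbinom(variants$alt_reads, variants$depth, ev["batri", ], log = TRUE)
    llr <- llB - llA
    lab[tri] <- ifelse(abs(llr[tri]) < llrThreshold, "ambiguous",
                       ifelse(llr[tri] > 0, "BTRI", "B_ATRI"))
    lab[tri & variants$depth < minDepth] <- "ambiguous"
  } else {
    lab[tri] <- ifelse(vaf[tri] > 0.5, "BTRI", "B_ATRI")
  }
  variants$timing <- lab
  variants
}

#' BTRI fractions by chromosome selection group
#'
#' Computes, per chromosome group, the fraction of classified variants
#' that are BTRI (of BTRI + B/ATRI), and compares per-case BTRI
#' fractions between the two groups with a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test. Chromosomes gained late in clonal evolution
#' have had less time to accumulate pre-gain mutations on the duplicated
#' homologue, so a higher BTRI fraction indicates a newer trisomy.
#'
#' @param variants A classified variant table (see [classifyTiming()])
#'   with a `group` column (e.g. `"pos"` for strong-pos/weak-pos
#'   chromosomes, `"neg"` for the rest) and a `case_id` column for the
#'   per-case test.
#' @return A list with `fractions` (per group: nBTRI, nClassified,
#'   fraction), and `pValue` (Mann-Whitney on per-case fractions; NA
#'   when fewer than two groups have data).
#' @examples
#' # the arithmetic of the headline counts:
#' # 536 BTRI of 15828 classified = 3.39%; 9 of 819 = 1.09%
#' @export
btriFractionByGroup <- function(variants) {
  stopifnot(all(c("timing", "group") %in% names(variants)))
  cls <- variants[variants$timing %in% c("BTRI", "B_ATRI"), , drop = FALSE]
  fr <- do.call(rbind, lapply(split(cls, cls$group), function(d) {
    data.frame(nBTRI = sum(d$timing == "BTRI"), nClassified = nrow(d),
               fraction = mean(d$timing == "BTRI"))
  }))
  fr <- cbind(group = rownames(fr), fr)
  rownames(fr) <- NULL
  p <- NA_real_
  if ("case_id" %in% names(cls) && length(unique(cls$group)) == 2L) {
    perCase <- stats::aggregate(timing ~ case_id + group, cls,
                                function(tt) mean(tt == "BTRI"))
    gg <- split(perCase$timing, perCase$group)
    if (all(lengths(gg) > 0L)) {
      if (stats::sd(perCase$timing) == 0) {
        p <- 1   # identical fractions everywhere: no evidence either way
      } else {
        p <- suppressWarnings(
          stats::wilcox.test(gg[[1L]], gg[[2L]], exact = FALSE)$p.value)
      }
    }
  }
  list(fractions = fr, pValue = p)
}

#' Assign a heterozygous variant to a chromosomal homologue
#'
#' On a gained chromosome the two homologues carry unequal copy numbers,
#' so germline-heterozygous variants separate by allele fraction:
#' fractions above 0.6 are assigned to one homologue, below 0.4 to the
#' other, and the dead zone in between is left unassigned.
#'
#' @param alleleFraction Numeric vector of allele fractions in `[0, 1]`.
#' @return Character vector: `"hom1"`, `"hom2"` or `"unassigned"`.
#' @examples
#' assignHomologue(c(0.70, 0.35, 0.50))
#' @export
assignHomologue <- function(alleleFraction) {
  stopifnot(all(alleleFraction >= 0), all(alleleFraction <= 1))
  ifelse(alleleFraction > 0.6, "hom1",
         ifelse(alleleFraction < 0.4, "hom2", "unassigned"))
}

#' Homologue concordance between diagnosis and relapse
#'
#' Determines, per chromosome, whether the homologue involved in a gain
#' (or retained in a UPID) is the same at diagnosis and relapse.
#' Trisomy mode: variants informative at diagnosis (allele fraction
#' > 0.6 or < 0.4) are matched by position in the relapse sample and a
#' majority vote over matched variants decides `same` (majority keep
#' their homologue assignment) versus `different`. UPID mode: variants
#' with diagnosis BAF above 0.8 (homozygous-appearing on the retained
#' homologue) are screened in the relapse sample; relapse BAF of 0.5 or
#' more votes for the same retained homologue.
#'
#' @param diagnosisVariants,relapseVariants Variant tables with
#'   `chromosome`, `position`, `alt_reads`, `depth`.
#' @param mode `"trisomy"` (default) or `"upid"`.
#' @return A data.frame with columns `chromosome`, `nInformative`,
#'   `call` (`"same"`, `"different"`, `"uninformative"`).
#' @export
homologueConcordance <- function(diagnosisVariants, relapseVariants,
                                 mode = c("trisomy", "upid")) {
  mode <- match.arg(mode)
  d <- diagnosisVariants
  r <- relapseVariants
  d$baf <- d$alt_reads / d$depth
  r$baf <- r$alt_reads / r$depth
  key <- function(v) paste(v$chromosome, v$position)
  m <- match(key(d), key(r))
  chroms <- unique(d$chromosome)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    i <- which(d$chromosome == ch & !is.na(m))
    if (mode == "trisomy") {
      i <- i[d$baf[i] > 0.6 | d$baf[i] < 0.4]
      if (!length(i))
        return(data.frame(chromosome = ch, nInformative = 0L,
                          call = "uninformative"))
      dHom <- assignHomologue(d$baf[i])
      rHom <- assignHomologue(r$baf[m[i]])
      informative <- rHom != "unassigned"
      if (!any(informative))
        return(data.frame(chromosome = ch, nInformative = 0L,
                          call = "uninformative"))
      agree <- mean(dHom[informative] == rHom[informative])
      data.frame(chromosome = ch, nInformative = sum(informative),
                 call = if (agree >= 0.5) "same" else "different")
    } else {
      i <- i[d$baf[i] > 0.8]
      if (!length(i))
        return(data.frame(chromosome = ch, nInformative = 0L,
                          call = "uninformative"))
      sameVotes <- mean(r$baf[m[i]] >= 0.5)
      data.frame(chromosome = ch, nInformative = length(i),
                 call = if (sameVotes >= 0.5) "same" else "different")
    }
  }))
  rownames(out) <- NULL
  out
}

#' Read a somatic variant table from TSV
#'
#' Reads the package's variant-table dialect: a TSV with at least the
#' columns `chromosome`, `position`, `alt_reads`, `depth`,
#' `total_copies`, and optionally `case_id`, `ref`, `alt`,
#' `sample_phase`, `purity`, `group`.
#'
#' @param file Path to the TSV.
#' @return A validated variant data.frame.
#' @export
readVariantTable <- function(file) {
  v <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = list(chromosome = "character"))
  .checkVariants(v)
}

#' @rdname readVariantTable
#' @param variants A variant data.frame.
#' @export
writeVariantTable <- function(variants, file) {
  .checkVariants(variants)
  utils::write.table(variants, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
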