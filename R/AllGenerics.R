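#' Modal chromosome number
#'
#' Total chromosome count of a karyotype (the sum of both homologue copy
#' numbers over all 23 chromosome pairs). A diploid 46,XX cell has MCN 46.
#'
#' @param x A karyotype matrix (see [diploidKaryotype()]) or a
#'   [CellPopulation].
#' @return An integer (karyotype) or integer vector with one entry per
#'   cell (population).
#' @examples
#' mcn(diploidKaryotype())
#' @export
setGeneric("mcn", function(x) standardGeneric("mcn"))

#' UPID frequency of a population
#'
#' Fraction of tracked chromosomes in the uniparental-isodisomy state
#' (two copies of the same homologue, 2:0), pooled over all cells. With
#' `denominator = "disomies"` (default) the denominator is the number of
#' tracked chromosomes in any disomic state; with `"allTracked"` it is the
#' number of tracked chromosome slots. The simulator's stopping rule
#' compares this statistic against `upidStop` of the [SelectionConfig].
#'
#' @param x A [CellPopulation].
#' @param tracked Chromosome names entering the statistic (default: the
#'   tracked set of the default [SelectionConfig]).
#' @param denominator `"disomies"` or `"allTracked"`.
#' @return A fraction in `[0, 1]`; 0 when no disomies exist.
#' @examples
#' p <- founderPopulation("diploid_sequential", 10)
#' upidFrequency(p)   # 0: all chromosomes heterodisomic
#' @export
setGeneric("upidFrequency",
           function(x, tracked = .TRACKED_DEFAULT,
                    denominator = c("disomies", "allTracked"))
             standardGeneric("upidFrequency"))

#' Survival/proliferation score
#'
#' The selection score determining a cell's survival probability; see
#' [SelectionConfig] for the formula. The returned value is the raw score;
#' the survival probability is the score clamped to `[0, 1]`.
#'
#' @param x A karyotype matrix or a [CellPopulation].
#' @param config A [SelectionConfig].
#' @param aneuploidyPenalty Logical; set `FALSE` to omit the aneuploidy
#'   penalty (used for the tetraploid/sequential model, where no initial
#'   tetraploid cell would otherwise survive).
#' @return A numeric score (karyotype) or numeric vector (population).
#' @examples
#' sScore(diploidKaryotype(), SelectionConfig())   # 0.5
#' @export
setGeneric("sScore",
           function(x, config, aneuploidyPenalty = TRUE)
             standardGeneric("sScore"))

#' @rdname accessors
#' @export
setGeneric("ncells", function(x) standardGeneric("ncells"))

#' @rdname accessors
#' @export
setGeneric("stopGeneration", function(x) standardGeneric("stopGeneration"))

#' @rdname accessors
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))

#' @rdname accessors
#' @export
setGeneric("finalPopulation", function(x) standardGeneric("finalPopulation"))

#' @rdname accessors
#' @export
setGeneric("telemetry", function(x) standardGeneric("telemetry"))

#' Accessors for simulation objects
#'
#' `ncells()` returns the number of cells in a [CellPopulation];
#' `stopGeneration()`, `stopReason()`, `finalPopulation()` and
#' `telemetry()` extract the corresponding parts of a [SimRun].
#'
#' @param x A [CellPopulation] or [SimRun].
#' @return See the individual descriptions.
#' @name accessors
NULL
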