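#' Initiation models
#'
#' The five aneuploidy-initiation mechanisms and their founder-karyotype
#' distributions:
#'
#' * `diploid_sequential`: a normal diploid cell; aneuploidy accrues only
#'   through later missegregation.
#' * `tetraploid_sequential`: a doubled genome (2:2 everywhere, MCN 92)
#'   followed by per-chromosome losses during clonal evolution.
#' * `diploid_tripolar`: a diploid cell divides on a three-poled spindle;
#'   each replicated homologue's sister-chromatid pair disjoins to two
#'   distinct poles chosen uniformly among the three pole pairs, and the
#'   founder inherits two fixed poles (bipolar cytokinesis of the tripolar
#'   spindle). Per chromosome the copy total is 2, 3, or 4 with
#'   probabilities 4/9, 4/9, 1/9; no losses and no UPIDs are possible.
#' * `tetraploid_tripolar`: a tetraploid cell divides tripolarly and the
#'   founder inherits a single pole; per homologue the founder receives
#'   0, 1, or 2 copies with probabilities 1/9, 4/9, 4/9.
#' * `mitotic_catastrophe`: complete loss of sister-chromatid cohesion;
#'   all 92 chromatids of a replicated diploid segregate independently to
#'   one of two daughters, and the founder is one daughter (per homologue
#'   Binomial(2, 1/2) copies).
#'
#' Founders containing any nullisomic chromosome are redrawn, so the
#' requested population size is exact.
#'
#' @return `initiationModels()` returns the five model names.
#' @examples
#' initiationModels()
#' @export
initiationModels <- function() .MODELS

#' Single founder karyotypes
#'
#' Draw one founder cell under each initiation mechanism.
#' `foundDiploid()` and `foundTetraploid()` are deterministic; the other
#' three draw from the mechanism's founder distribution (seed the RNG
#' beforehand for reproducibility).
#'
#' @return A 23-by-2 integer karyotype matrix.
#' @examples
#' mcn(foundDiploid())       # 46
#' mcn(foundTetraploid())    # 92
#' set.seed(1); mcn(foundDiploidTripolar())
#' @export
foundDiploid <- function() diploidKaryotype()

#' @rdname foundDiploid
#' @export
foundTetraploid <- function() tetraploidKaryotype()

#' @rdname foundDiploid
#' @export
foundDiploidTripolar <- function() .popKaryotype(.drawFounders("diploid_tripolar", 1L))

#' @rdname foundDiploid
#' @export
foundTetraploidTripolar <- function() .popKaryotype(.drawFounders("tetraploid_tripolar", 1L))

#' @rdname foundDiploid
#' @export
foundMitoticCatastrophe <- function() .popKaryotype(.drawFounders("mitotic_catastrophe", 1L))

.popKaryotype <- function(f, i = 1L) {
  m <- cbind(hom1 = f$h1[, i], hom2 = f$h2[, i])
  rownames(m) <- .CHR
  m
}

# internal vectorized founder draws on bare matrices; nullisomic draws
# are rejected and redrawn
.drawFounders <- function(model, n) {
  if (n == 0L) {
    e <- matrix(integer(0), 23L, 0L, dimnames = list(.CHR, NULL))
    return(list(h1 = e, h2 = e))
  }
  if (model == "diploid_sequential")
    return(list(h1 = matrix(1L, 23L, n, dimnames = list(.CHR, NULL)),
                h2 = matrix(1L, 23L, n, dimnames = list(.CHR, NULL))))
  if (model == "tetraploid_sequential")
    return(list(h1 = matrix(2L, 23L, n, dimnames = list(.CHR, NULL)),
                h2 = matrix(2L, 23L, n, dimnames = list(.CHR, NULL))))
  h1 <- matrix(integer(0), 23L, 0L)
  h2 <- matrix(integer(0), 23L, 0L)
  while (ncol(h1) < n) {
    m <- max(2L * (n - ncol(h1)), 64L)
    if (model == "diploid_tripolar") {
      # one homologue contributes 2 copies to the retained pole pair when
      # its chromatids land on exactly those two poles (prob 1/3), else 1
      a <- matrix(1L + (stats::runif(23L * m) < 1 / 3), 23L, m)
      b <- matrix(1L + (stats::runif(23L * m) < 1 / 3), 23L, m)
    } else if (model == "tetraploid_tripolar") {
      # two chromatid pairs per homologue; each lands on the retained
      # pole with probability 2/3
      a <- matrix((stats::runif(23L * m) < 2 / 3) + (stats::runif(23L * m) < 2 / 3), 23L, m)
      b <- matrix((stats::runif(23L * m) < 2 / 3) + (stats::runif(23L * m) < 2 / 3), 23L, m)
    } else if (model == "mitotic_catastrophe") {
      # each of the two chromatids per homologue independently to one
      # daughter with probability 1/2
      a <- matrix(stats::rbinom(23L * m, 2L, 0.5), 23L, m)
      b <- matrix(stats::rbinom(23L * m, 2L, 0.5), 23L, m)
    } else stop("unknown model: ", model)
    storage.mode(a) <- "integer"
    storage.mode(b) <- "integer"
    ok <- colSums((a + b) == 0L) == 0L
    h1 <- cbind(h1, a[, ok, drop = FALSE])
    h2 <- cbind(h2, b[, ok, drop = FALSE])
  }
  h1 <- h1[, seq_len(n), drop = FALSE]
  h2 <- h2[, seq_len(n), drop = FALSE]
  rownames(h1) <- .CHR
  rownames(h2) <- .CHR
  list(h1 = h1, h2 = h2)
}

#' Founder population of an initiation model
#'
#' Draws `n` founder cells of the given mechanism (nullisomic draws
#' rejected). Seed the RNG for reproducibility.
#'
#' @param model One of [initiationModels()].
#' @param n Number of founder cells.
#' @return A [CellPopulation] at generation 0.
#' @examples
#' set.seed(1)
#' p <- founderPopulation("diploid_tripolar", 100)
#' table(mcn(p))
#' @export
founderPopulation <- function(model, n) {
  model <- match.arg(model, .MODELS)
  f <- .drawFounders(model, as.integer(n))
  CellPopulation(f$h1, f$h2, generation = 0L)
}
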