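# Clone bookkeeping on single-cell whole-chromosome copy-number
# matrices: cells in rows, the 23 chromosomes in columns (extra columns,
# e.g. annotated structural events, are allowed and enter the clone
# definition unchanged).

.checkCellMatrix <- function(mat, minCells = 1L) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("cell matrix must be numeric")
  if (nrow(mat) < minCells)
    stop("cell matrix must have at least ", minCells, " cells (rows)")
  if (any(mat < 0)) stop("copy numbers must be non-negative")
  mat
}

#' Call clones from a single-cell copy-number matrix
#'
#' Cells with identical profiles (all columns equal) are grouped; groups
#' of two or more cells are clones, labelled `A`, `B`, ... in decreasing
#' size order, and singletons are counted as unique genomes.
#'
#' @param mat A cells-by-chromosomes numeric matrix (rows may be named
#'   with cell ids).
#' @return A list with `assignment` (per-cell clone label, `NA` for
#'   unique genomes), `clones` (data.frame: clone, nCells, fraction) and
#'   `nUniqueGenomes`.
#' @examples
#' m <- rbind(c(2, 3, 2), c(2, 3, 2), c(2, 3, 2), c(2, 2, 2))
#' callClones(m)$clones      # one clone of 3 cells (75%)
#' @export
callClones <- function(mat) {
  mat <- .checkCellMatrix(mat, 1L)
  profile <- apply(mat, 1L, paste, collapse = ",")
  tab <- sort(table(profile), decreasing = TRUE)
  cloneProfiles <- names(tab)[tab >= 2L]
  labels <- if (length(cloneProfiles)) {
    stats::setNames(LETTERS[seq_along(cloneProfiles)], cloneProfiles)
  } else character(0)
  assignment <- unname(labels[profile])
  clones <- data.frame(
    clone = unname(labels),
    nCells = as.integer(tab[cloneProfiles]),
    fraction = as.numeric(tab[cloneProfiles]) / nrow(mat)
  )
  list(assignment = assignment, clones = clones,
       nUniqueGenomes = sum(tab == 1L))
}

#' Pairwise Manhattan distance matrix of single cells
#'
#' @param mat A cells-by-chromosomes numeric matrix with at least two
#'   cells.
#' @return A symmetric matrix of city-block distances with zero
#'   diagonal.
#' @export
manhattanMatrix <- function(mat) {
  mat <- .checkCellMatrix(mat, 2L)
  as.matrix(stats::dist(mat, method = "manhattan"))
}

#' Whole-chromosome heterogeneity score
#'
#' A simple dispersion summary of a single-cell matrix: the mean
#' per-cell Manhattan distance to the population's per-chromosome modal
#' profile, divided by the number of chromosomes (23). It is 0 exactly
#' when every cell equals the modal profile, and grows with both the
#' fraction of divergent cells and the size of their deviations. This
#' score is a surrogate defined by this package; it is not numerically
#' comparable to genome-wide heterogeneity scores produced by bin-level
#' copy-number callers.
#'
#' @param mat A cells-by-chromosomes numeric matrix with at least two
#'   cells.
#' @return A non-negative score.
#' @examples
#' m <- matrix(2, 10, 23); m[1, 5] <- 3
#' heterogeneityScore(m)    # 1 / (10 * 23)
#' @export
heterogeneityScore <- function(mat) {
  mat <- .checkCellMatrix(mat, 2L)
  modal <- apply(mat, 2L, function(col) {
    tab <- table(col)
    as.numeric(names(tab)[which.max(tab)])   # ties: smallest value
  })
  mean(abs(sweep(mat, 2L, modal))) # == mean cell distance / ncol
}

#' Read or write a single-cell copy-number matrix
#'
#' TSV with a header of chromosome names and one row per cell; an
#' optional first column `cell_id` provides rownames.
#'
#' @param file Path to the TSV.
#' @param mat A cells-by-chromosomes matrix.
#' @return `readCellMatrix()` returns a numeric matrix;
#'   `writeCellMatrix()` returns `file` invisibly.
#' @export
readCellMatrix <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (names(df)[1L] == "cell_id") {
    rn <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
    mat <- as.matrix(df)
    rownames(mat) <- rn
  } else mat <- as.matrix(df)
  .checkCellMatrix(mat)
}

#' @rdname readCellMatrix
#' @export
writeCellMatrix <- function(mat, file) {
  mat <- .checkCellMatrix(mat)
  df <- data.frame(cell_id = if (is.null(rownames(mat)))
    paste0("cell", seq_len(nrow(mat))) else rownames(mat),
    mat, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
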