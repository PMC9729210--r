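#' Jaccard and Sørensen-Dice segmentation accuracy
#'
#' Overlap accuracy of a predicted binary mask `x` against a reference `y`:
#' Jaccard \eqn{J = |X \cap Y| / |X \cup Y|} and Dice
#' \eqn{D = 2|X \cap Y| / (|X| + |Y|)}; the two are related by
#' \eqn{D = 2J/(1+J)}. Both are symmetric and lie in `[0, 1]`, 1 meaning a
#' perfect match. Two empty masks compare as 1 (flagged with attribute
#' `both_empty = TRUE`); one empty mask against a non-empty one gives 0.
#'
#' @param x,y Binary masks: logical matrices or numeric matrices of strictly
#'   0/1 values, with identical shape.
#' @return Single number in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2, 2)
#' b <- matrix(c(1, 0, 1, 0), 2, 2)
#' jaccard(a, b)  # 1/3
#' dice(a, b)     # 0.5
#' @export
jaccard <- function(x, y) {
  m <- check_masks(x, y)
  inter <- sum(m$x & m$y)
  uni <- sum(m$x | m$y)
  if (uni == 0)
    return(structure(1, both_empty = TRUE))
  inter / uni
}

#' @rdname jaccard
#' @export
dice <- function(x, y) {
  m <- check_masks(x, y)
  tot <- sum(m$x) + sum(m$y)
  if (tot == 0)
    return(structure(1, both_empty = TRUE))
  2 * sum(m$x & m$y) / tot
}

check_masks <- function(x, y) {
  as_bin <- function(m, name) {
    if (is.logical(m)) return(m)
    if (is.numeric(m) && all(m %in% c(0, 1))) return(m == 1)
    stop("'", name, "' must be a logical or strictly 0/1 matrix")
  }
  x <- as_bin(x, "x")
  y <- as_bin(y, "y")
  if (!is.matrix(x) || !is.matrix(y) || !all(dim(x) == dim(y)))
    stop("mask shapes do not match")
  list(x = x, y = y)
}
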