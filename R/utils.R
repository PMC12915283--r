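#' Min-max scale a vector to [0, 1]
#'
#' Rescales values as `(x - min(x)) / (max(x) - min(x))`, mapping the minimum
#' to 0 and the maximum to 1 while preserving order. Used for display output
#' (e.g. dyad correlation plots), never for the statistics themselves.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector in `[0, 1]`.
#' @export
#' @examples
#' minmax_scale(c(0, 5, 10))
minmax_scale <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("minmax_scale() needs a numeric vector of length >= 2", call. = FALSE)
  }
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng))) stop("non-finite values in input", call. = FALSE)
  if (rng[1] == rng[2]) {
    stop("minmax_scale() is undefined for a constant vector", call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Pearson correlation of each row of A with the matching row of B.
# Rows with zero variance give NA.
.row_cor <- function(A, B) {
  stopifnot(identical(dim(A), dim(B)))
  n <- ncol(A)
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  num <- rowSums(Ac * Bc)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
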