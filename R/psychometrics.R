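#' Psychometric sigmoid
#'
#' Evaluates `f(x) = b + L / (1 + exp(-k (x - x0)))`: `b` baseline, `L`
#' upper-asymptote span, `k` slope, `x0` the threshold (the intensity at the
#' inflection point, where the response is half-maximal). Evaluation is
#' overflow-safe for any finite arguments.
#'
#' @param x stimulus intensity (uA), vectorized.
#' @param b,L,k,x0 sigmoid parameters.
#' @return numeric vector of responses.
#' @export
#' @examples
#' sigmoid_response(250, b = 0, L = 1, k = 0.02, x0 = 250)  # b + L/2
sigmoid_response <- function(x, b, L, k, x0) {
  stopifnot(is.finite(b), is.finite(L), is.finite(k), is.finite(x0))
  b + L * stats::plogis(k * (x - x0))
}

#' Scale responses to [0, 1] for fitting
#'
#' Per-animal min-max scaling of the intensity-response values before the
#' sigmoid fit: the minimum maps to 0, the maximum to 1, order is preserved.
#'
#' @param responses numeric vector with at least two distinct values.
#' @return scaled vector in `[0, 1]`.
#' @export
normalize_for_fit <- function(responses) {
  if (length(responses) < 2 || length(unique(responses)) < 2) {
    stop("responses are constant; cannot prepare a psychometric fit", call. = FALSE)
  }
  minmax_scale(responses)
}

#' Fit a psychometric sigmoid
#'
#' Nonlinear least-squares fit of [sigmoid_response()] to per-intensity
#' responses. Intensities are max-scaled to `[0, 1]` and responses min-max
#' scaled per animal before fitting; the threshold is reported back in uA.
#' Starting values: `b = min(y)`, `L = range(y)`, `x0` at the level nearest
#' half-maximum, slope `4 / range(x)`; bounds keep `L >= 0`, `x0` within
#' the tested range and the slope non-negative (at most 1 per uA), while
#' the baseline may go moderately negative on the scaled axis (min-max
#' scaling pins the smallest observation, not the lower asymptote).
#'
#' @param intensities stimulus intensities in uA; >= 4 distinct levels.
#' @param responses matching responses (replicates per level are averaged).
#' @return object of class `psychometric_fit`: list with `b`, `L` (scaled
#'   response units), `k` (per uA), `x0` (uA, the threshold), `r2`,
#'   `converged`, plus the scaled data used (`data`) and a `message` on
#'   failure.
#' @export
fit_psychometric <- function(intensities, responses) {
  if (length(intensities) != length(responses)) {
    stop("`intensities` and `responses` must have the same length", call. = FALSE)
  }
  keep <- is.finite(intensities) & is.finite(responses)
  d <- aggregate(list(y = responses[keep]),
                 by = list(x = intensities[keep]), FUN = mean)
  if (nrow(d) < 4) {
    stop("need >= 4 distinct intensity levels (4 free parameters)", call. = FALSE)
  }
  xmax <- max(d$x)
  if (xmax <= 0) stop("intensities must include positive levels", call. = FALSE)
  xn <- d$x / xmax
  yn <- normalize_for_fit(d$y)

  half <- (min(yn) + max(yn)) / 2
  start <- list(
    b = min(yn), L = diff(range(yn)),
    k = 4 / diff(range(xn)), x0 = xn[which.min(abs(yn - half))]
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yn ~ b + L * stats::plogis(k * (xn - x0)),
      start = start,
      # the scaled baseline can sit slightly below the smallest data point
      # (min-max scaling pins the smallest *observation*, not the asymptote),
      # so b may go moderately negative
      lower = c(b = -0.5, L = 0, k = 0, x0 = min(xn)),
      upper = c(b = 1.5, L = 2.5, k = xmax, x0 = max(xn)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                           ptol = 1e-13)
    ),
    error = function(e) e
  )
  out <- list(
    b = NA_real_, L = NA_real_, k = NA_real_, x0 = NA_real_,
    r2 = NA_real_, converged = FALSE,
    data = data.frame(intensity = d$x, response = yn),
    message = NULL
  )
  class(out) <- "psychometric_fit"
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  cf <- stats::coef(fit)
  out$b <- unname(cf["b"])
  out$L <- unname(cf["L"])
  out$k <- unname(cf["k"]) / xmax     # back to per-uA
  out$x0 <- unname(cf["x0"]) * xmax   # back to uA
  out$converged <- TRUE
  out$r2 <- goodness_of_fit(
    sigmoid_response(d$x, out$b, out$L, out$k, out$x0), yn
  )
  out
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<psychometric_fit> threshold x0 = %.1f uA, k = %.4f/uA, b = %.3f, L = %.3f, R^2 = %.4f\n",
      x$x0, x$k, x$b, x$L, x$r2
    ))
  } else {
    cat("<psychometric_fit> did not converge:", x$message %||% "", "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`; 1 for a perfect fit, 0 for a fit no better
#' than the mean, negative for a worse-than-mean fit (allowed and reported).
#'
#' @param predicted fitted values.
#' @param observed observed values (non-zero variance).
#' @return scalar R^2.
#' @export
goodness_of_fit <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have the same length", call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("observed values have zero variance; R^2 undefined", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / sst
}

#' Spearman correlation of paired thresholds
#'
#' Rank correlation between two sets of per-animal thresholds (e.g.
#' pupillary vs locomotor), with a two-sided p-value. The p-value is exact
#' (enumeration over all rank permutations, tie-aware) for n <= 8 and uses
#' the t approximation otherwise.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
correlate_thresholds <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("degenerate input: a variable is constant", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 8) {
    perms <- .permutations(n)
    rho_null <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
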