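#' Fourier phase-scramble an image stack
#'
#' Randomizes the 2-D Fourier phase of every frame while preserving its
#' amplitude spectrum exactly, so physical low-level parameters (power per
#' spatial frequency, mean luminance) are unchanged but all spatial
#' structure is destroyed. This is the construction behind
#' structure-removed control movies. Conjugate symmetry is enforced by
#' drawing the random phase field from the FFT of a real white-noise image,
#' so the output is real; the zero-frequency component (mean luminance) is
#' kept untouched.
#'
#' @param frames a numeric 3-D array (height x width x n_frames) or a single
#'   matrix.
#' @param seed integer seed; each frame gets its own phase field.
#' @return array/matrix of the same shape.
#' @export
phase_scramble_frames <- function(frames, seed = 1L) {
  single <- is.matrix(frames)
  if (single) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3 || any(dim(frames) == 0)) {
    stop("`frames` must be a non-empty matrix or 3-D array", call. = FALSE)
  }
  if (!is.numeric(frames)) stop("`frames` must be real-valued", call. = FALSE)
  set.seed(seed)
  d <- dim(frames)
  out <- array(0, dim = d)
  for (f in seq_len(d[3])) {
    Fo <- fft(frames[, , f])
    # phases of a real random field satisfy conjugate symmetry exactly
    Fr <- fft(matrix(rnorm(d[1] * d[2]), d[1], d[2]))
    phase <- Fr / Mod(Fr)
    phase[Mod(Fr) == 0] <- 1
    Fn <- Mod(Fo) * phase
    Fn[1, 1] <- Fo[1, 1]  # preserve mean luminance (DC) exactly
    out[, , f] <- Re(fft(Fn, inverse = TRUE)) / (d[1] * d[2])
  }
  if (single) out[, , 1] else out
}

#' Vertically invert an image stack
#'
#' Reverses the row order of every frame (an upside-down control stimulus);
#' applying it twice returns the input.
#'
#' @param frames a numeric 3-D array (height x width x n_frames) or matrix.
#' @return array/matrix of the same shape with rows reversed.
#' @export
invert_frames <- function(frames) {
  if (is.matrix(frames)) return(frames[rev(seq_len(nrow(frames))), , drop = FALSE])
  if (!is.array(frames) || length(dim(frames)) != 3 || any(dim(frames) == 0)) {
    stop("`frames` must be a non-empty matrix or 3-D array", call. = FALSE)
  }
  frames[rev(seq_len(dim(frames)[1])), , , drop = FALSE]
}
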