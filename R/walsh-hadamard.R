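# Walsh-Hadamard spectral analysis of complete landscapes and band-pass
# denoising.  The Fourier ({-1,+1}) basis uses characters
# phi_S(s) = prod_{i in S} (1 - 2 s_i); with the 2^-L normalization chosen
# here the order-0 coefficient equals the mean fitness and Parseval reads
# sum_s F(s)^2 = 2^L * sum_S a_S^2.

# In-place fast Walsh-Hadamard transform (unnormalized, self-inverse up to
# a factor 2^L).
#' @keywords internal
.fwht <- function(a) {
  n <- length(a)
  h <- 1L
  while (h < n) {
    step <- 2L * h
    for (start in seq(1L, n, by = step)) {
      i <- start:(start + h - 1L)
      j <- i + h
      x <- a[i]
      y <- a[j]
      a[i] <- x + y
      a[j] <- x - y
    }
    h <- step
  }
  a
}

#' Walsh-Hadamard spectrum of a complete landscape
#'
#' @param ls A `fitness_landscape` (or a numeric fitness table of length
#'   `2^L`).
#' @return A `fourier_spectrum`: coefficients indexed by subset bitmask
#'   (code + 1), their interaction `order` (subset cardinality) and
#'   `basis_tag = "fourier"`.
#' @export
wh_transform <- function(ls) {
  f <- if (inherits(ls, "fitness_landscape")) ls$fitness else as.numeric(ls)
  n <- length(f)
  L <- as.integer(round(log2(n)))
  if (2^L != n) stop("incomplete landscape: table size ", n, " is not a power of two")
  structure(list(L = L, coef = .fwht(f) / n, order = .popcount(0:(n - 1L)),
                 basis_tag = "fourier",
                 site_labels = if (inherits(ls, "fitness_landscape")) ls$site_labels
                               else as.character(seq_len(L))),
            class = "fourier_spectrum")
}

#' Inverse Walsh-Hadamard transform
#'
#' @param spec A `fourier_spectrum` with `basis_tag == "fourier"`.
#' @return The reconstructed `fitness_landscape`.
#' @export
inverse_wh_transform <- function(spec) {
  stopifnot(inherits(spec, "fourier_spectrum"))
  if (spec$basis_tag != "fourier") spec <- convert_spectrum(spec, "fourier")
  fitness_landscape(.fwht(spec$coef), site_labels = spec$site_labels)
}

#' Convert a spectrum between the Taylor ({0,1}) and Fourier ({-1,+1}) bases
#'
#' Both encodings carry one coefficient per subset of sites; the map
#' between them is the invertible composition of the two subset transforms
#' and preserves order-limited support in both directions.
#'
#' @param spec A `fourier_spectrum`.
#' @param basis `"taylor"` or `"fourier"`.
#' @return A `fourier_spectrum` in the requested basis.
#' @export
convert_spectrum <- function(spec, basis = c("taylor", "fourier")) {
  stopifnot(inherits(spec, "fourier_spectrum"))
  basis <- match.arg(basis)
  if (identical(spec$basis_tag, basis)) return(spec)
  n <- 2^spec$L
  if (basis == "taylor") {
    f <- .fwht(spec$coef)               # fitness table
    spec$coef <- .mobius_transform(f, spec$L)
  } else {
    f <- .zeta_transform(spec$coef, spec$L)
    spec$coef <- .fwht(f) / n
  }
  spec$basis_tag <- basis
  spec
}

#' Band-pass denoising by interaction-order truncation
#'
#' Zeroes every Walsh-Hadamard coefficient of order greater than
#' `max_order` (higher-order terms reflect measurement noise), inverts the
#' transform, and re-references the result so the germline has zero
#' fitness.  Order truncation makes this a projection: applying it twice
#' equals applying it once.
#'
#' @param x A `fitness_landscape` or `fourier_spectrum`.
#' @param max_order Highest interaction order kept (default 3).
#' @param magnitude_threshold Optional: additionally zero retained
#'   coefficients of order >= 1 with `|a| <` this value (default off).
#' @return The denoised `fitness_landscape` (germline fitness exactly 0).
#' @export
bandpass_denoise <- function(x, max_order = 3, magnitude_threshold = 0) {
  spec <- if (inherits(x, "fourier_spectrum")) convert_spectrum(x, "fourier")
          else wh_transform(x)
  if (max_order > spec$L) stop("invalid cutoff: max_order ", max_order,
                               " exceeds L = ", spec$L)
  spec$coef[spec$order > max_order] <- 0
  if (magnitude_threshold > 0) {
    spec$coef[spec$order >= 1 & abs(spec$coef) < magnitude_threshold] <- 0
  }
  out <- inverse_wh_transform(spec)
  out$fitness <- out$fitness - out$fitness[1]
  out
}
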