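# Plane-wise linear (Wiener) deconvolution with a 2D Lorentzian PSF.
#
# STED resolution is modelled by a 2D Lorentzian of 50 nm FWHM; stacks are
# deconvolved plane by plane in the frequency domain with a single
# noise-to-signal regularization constant. Boundary handling is periodic
# (FFT-native); callers can pad beforehand if edge wrap matters.

#' 2D Lorentzian point spread function
#'
#' `k(r) = 1 / (1 + (2 r / fwhm)^2)` sampled at pixel centers on an odd
#' square support, then normalized to sum 1. By construction the
#' unnormalized value at `r = fwhm / 2` is half the central value.
#'
#' @param fwhm full width at half maximum, nm.
#' @param pixel_pitch lateral pixel size, nm.
#' @param support_px odd kernel side length in pixels.
#' @return a `psf_model`: list with `fwhm`, `pixel_pitch`, and the
#'   normalized `kernel` matrix.
#' @export
lorentzian_psf <- function(fwhm = 50, pixel_pitch = 20, support_px = 11) {
  stopifnot(fwhm > 0, pixel_pitch > 0)
  if (support_px %% 2 == 0) stop("PSF support must be odd, got ", support_px)
  half <- (support_px - 1) / 2
  off <- (-half:half) * pixel_pitch
  r2 <- outer(off^2, off^2, `+`)
  kernel <- 1 / (1 + 4 * r2 / fwhm^2)
  structure(list(fwhm = fwhm, pixel_pitch = pixel_pitch,
                 kernel = kernel / sum(kernel)),
            class = "psf_model")
}

# optical transfer function: kernel zero-padded to the image size and
# circularly shifted so its center sits at (1, 1)
#' @noRd
psf_otf <- function(psf, dims) {
  k <- psf$kernel
  if (any(dim(k) > dims))
    stop("PSF support exceeds the image size")
  pad <- matrix(0, dims[1], dims[2])
  pad[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  half <- (nrow(k) - 1) / 2
  shift <- function(m, by) {
    n <- length(by)
    m[c((by[1] + 1):nrow(m), seq_len(by[1])),
      c((by[2] + 1):ncol(m), seq_len(by[2]))]
  }
  pad <- shift(pad, c(half, half))
  stats::fft(pad)
}

#' Convolve one image plane with a PSF (periodic boundaries)
#'
#' @param image numeric matrix.
#' @param psf a [lorentzian_psf()].
#' @return convolved matrix, same shape.
#' @export
convolve_plane <- function(image, psf) {
  H <- psf_otf(psf, dim(image))
  Re(stats::fft(stats::fft(image) * H, inverse = TRUE)) / length(image)
}

#' Wiener-deconvolve one image plane
#'
#' Applies the frequency-domain filter `conj(H) / (|H|^2 + reg)` where `H`
#' is the PSF's transfer function. Deterministic and linear in the image.
#'
#' @param image numeric matrix, finite.
#' @param psf a [lorentzian_psf()].
#' @param reg noise-to-signal regularization constant, >= 0. The default is
#'   1e-2 of the peak `|H|^2` (the PSF kernel is normalized, so peak
#'   `|H| = 1` at DC). `reg = 0` is only allowed when `|H|` has no
#'   (near-)zeros.
#' @return deconvolved matrix, same shape, real-valued.
#' @export
wiener_deconvolve_plane <- function(image, psf, reg = 1e-2) {
  if (!all(is.finite(image))) stop("image must be finite")
  if (reg < 0) stop("reg must be >= 0")
  H <- psf_otf(psf, dim(image))
  H2 <- Mod(H)^2
  if (reg == 0 && any(H2 < 1e-12))
    stop("|H| has zeros; use reg > 0 for a stable Wiener inverse")
  G <- Conj(H) / (H2 + reg)
  Re(stats::fft(stats::fft(image) * G, inverse = TRUE)) / length(image)
}

#' Wiener-deconvolve a stack plane by plane
#'
#' Each plane is deconvolved independently; there is no coupling across z,
#' matching 2D deconvolution of anisotropic stacks whose axial resolution
#' is much poorer than lateral.
#'
#' @param stack a [spine_stack()] or 3D array.
#' @param psf a [lorentzian_psf()].
#' @param reg regularization constant, see [wiener_deconvolve_plane()].
#' @return deconvolved [spine_stack()], plane order preserved.
#' @export
deconvolve_stack <- function(stack, psf, reg = 1e-2) {
  if (is.matrix(stack)) stack <- spine_stack(stack)
  out <- array(0, dim(stack))
  for (p in seq_len(dim(stack)[3])) {
    res <- tryCatch(wiener_deconvolve_plane(stack[, , p], psf, reg),
                    error = function(e)
                      stop("plane ", p, ": ", conditionMessage(e),
                           call. = FALSE))
    out[, , p] <- res
  }
  spine_stack(out,
              pixel_nm = attr(stack, "pixel_nm") %||% psf$pixel_pitch,
              pitch_nm = attr(stack, "pitch_nm") %||% 300)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
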