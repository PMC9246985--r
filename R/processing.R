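# Conversion of CEST profiles between the offset domain and the fixed-size
# time-domain representation used by the transformation network: dip
# transform, real Fourier transform, zero-filling and inverse-FT upsampling.

# Fixed constants of the architecture: input profiles are capped at 128
# offsets, so their real Fourier transform has at most 65 non-redundant
# complex points; everything is zero-filled to exactly that size.
.PACKED_SIZE <- 65L
.UPSAMPLED_SIZE <- 128L

#' Dip transform of a CEST profile
#'
#' `max(I/I0) - I/I0`: turns the dips of a CEST profile into positive peaks
#' so that the profile resembles a simple 1D NMR spectrum (and its real
#' Fourier transform resembles an FID).
#'
#' @param profile A [cest_profile()] or a numeric vector of intensities.
#' @return A numeric vector with minimum 0.
#' @export
dip_transform <- function(profile) {
  x <- if (inherits(profile, "cest_profile")) profile$intensity else
    as.numeric(profile)
  if (length(x) == 0) stop("empty profile", call. = FALSE)
  max(x) - x
}

#' Real Fourier transform
#'
#' Discrete Fourier transform of a real vector, returning only the
#' non-redundant coefficients: for `N` input points the output is
#' `floor(N/2) + 1` complex values (the remaining points are fixed by
#' Hermitian symmetry: `N/2 - 1` redundant points for even `N`,
#' `(N - 1)/2` for odd `N`).
#'
#' @param x Real vector, `length(x) >= 2`.
#' @return Complex vector of length `floor(length(x)/2) + 1`.
#' @seealso [inverse_real_ft()]
#' @export
real_ft <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least two points", call. = FALSE)
  stats::fft(x)[seq_len(n %/% 2 + 1)]
}

#' Inverse real Fourier transform
#'
#' Reconstructs `n_out` real points from the non-redundant coefficients of a
#' real Fourier transform. When `n_out` exceeds the original sampling the
#' reconstruction is the band-limited (sinc) interpolation of the original
#' profile; `scale` should then be the original number of points so that
#' amplitudes are preserved (defaults to the value consistent with an
#' unpadded round trip).
#'
#' @param coef Complex coefficients (length `m`).
#' @param n_out Number of real points to reconstruct (`n_out >= 2*(m-1)`).
#' @param scale Normalization, the number of originally sampled points.
#' @return Real vector of length `n_out`.
#' @export
inverse_real_ft <- function(coef, n_out, scale = NULL) {
  m <- length(coef)
  if (n_out < 2 * (m - 1)) {
    stop("n_out too small for the given number of coefficients",
         call. = FALSE)
  }
  if (is.null(scale)) scale <- n_out
  full <- complex(n_out)
  full[seq_len(m)] <- coef
  if (n_out %% 2 == 0 && m == n_out / 2 + 1) {
    # Nyquist coefficient of an even-length transform must be real
    full[m] <- complex(real = Re(coef[m]), imaginary = 0)
  }
  k <- seq(2, min(m, n_out - m + 2))
  mirror <- n_out + 2 - k
  mirror_ok <- mirror > m
  full[mirror[mirror_ok]] <- Conj(coef[k[mirror_ok]])
  Re(stats::fft(full, inverse = TRUE)) / scale
}

#' Zero-fill a time-domain CEST profile to the fixed packed size
#'
#' Appends zeros to the complex time-domain coefficients until exactly 65
#' points, and extends the time axis on the same uniform grid (spacing
#' `1/SW` with `SW` the offset span in Hz).
#'
#' @param td Complex coefficients from [real_ft()] (at most 65).
#' @param sw_hz Sweep width: the offset span of the original profile in Hz.
#' @param n_original Number of offsets in the original profile.
#' @param target Packed size (fixed at 65 by the architecture).
#' @return An object of class `packed_time_domain`: a list with fields
#'   `coef` (65 complex values), `t0` (65 time points, s), `n_original` and
#'   `sw_hz`.
#' @export
zero_fill <- function(td, sw_hz, n_original = 2L * (length(td) - 1L),
                      target = .PACKED_SIZE) {
  m <- length(td)
  if (m > target) {
    stop("more than ", target, " complex points; input profiles are capped ",
         "at ", 2L * (target - 1L), " offsets", call. = FALSE)
  }
  coef <- complex(target)
  coef[seq_len(m)] <- td
  # For an even-length input, td's last value is its Nyquist coefficient;
  # inside the longer zero-filled spectrum it is an ordinary bin whose
  # mirror image is restored on inversion, so it must carry half the
  # weight for the reconstruction to be the band-limited interpolant.
  if (n_original %% 2 == 0 && m == n_original / 2 + 1 && m < target) {
    coef[m] <- complex(real = Re(td[m]) / 2, imaginary = 0)
  }
  dt <- 1 / sw_hz
  structure(
    list(coef = coef, t0 = dt * (seq_len(target) - 1), sw_hz = sw_hz,
         n_original = as.integer(n_original)),
    class = "packed_time_domain"
  )
}

#' Pack a time-domain profile into the fixed-size network input
#'
#' Lays out a [zero_fill()]ed time-domain profile as the two length-130
#' vectors consumed by the transformation network: the first holds the real
#' parts of the 65 complex coefficients in slots 1-65 and the imaginary
#' parts in slots 66-130; the second holds the matching time points
#' (duplicated across the two halves so both vectors share the layout).
#'
#' @param ptd A `packed_time_domain`.
#' @return A list with numeric vectors `coef` and `time`, both length 130.
#' @seealso [unpack_input()]
#' @export
pack_input <- function(ptd) {
  stopifnot(inherits(ptd, "packed_time_domain"))
  list(coef = c(Re(ptd$coef), Im(ptd$coef)),
       time = c(ptd$t0, ptd$t0))
}

#' @rdname pack_input
#' @param packed A list as returned by [pack_input()].
#' @param n_original Number of originally sampled offsets.
#' @export
unpack_input <- function(packed, n_original = .UPSAMPLED_SIZE) {
  stopifnot(length(packed$coef) == 2L * .PACKED_SIZE)
  m <- .PACKED_SIZE
  coef <- complex(real = packed$coef[seq_len(m)],
                  imaginary = packed$coef[m + seq_len(m)])
  dt <- packed$time[2] - packed$time[1]
  structure(
    list(coef = coef, t0 = packed$time[seq_len(m)], sw_hz = 1 / dt,
         n_original = as.integer(n_original)),
    class = "packed_time_domain"
  )
}

#' Upsample a packed time-domain profile to 128 offsets
#'
#' Inverse real Fourier transform of the 65 complex time-domain points to
#' exactly 128 real points spanning the original offset range. Because the
#' packed representation is zero-filled, this is the band-limited (sinc)
#' interpolation of the original profile; a profile originally sampled at
#' 128 offsets round-trips exactly.
#'
#' @param td65 A `packed_time_domain`, or a complex vector of 65 values
#'   (then `n_original` must be given).
#' @param n_original Number of originally sampled offsets (amplitude
#'   normalization).
#' @return Numeric vector of 128 values.
#' @export
upsample_to_offsets <- function(td65, n_original = NULL) {
  if (inherits(td65, "packed_time_domain")) {
    n_original <- td65$n_original
    td65 <- td65$coef
  }
  if (is.null(n_original)) {
    stop("n_original is required when passing a bare coefficient vector",
         call. = FALSE)
  }
  stopifnot(length(td65) == .PACKED_SIZE)
  inverse_real_ft(td65, .UPSAMPLED_SIZE, scale = n_original)
}

#' Full packing chain for an anti-phase profile
#'
#' Dip-transforms a profile, applies the real Fourier transform, zero-fills
#' to 65 complex points and packs the result into the two length-130 input
#' vectors.
#'
#' @param profile A [cest_profile()].
#' @param b0 Static field (T), used to convert the offset span to Hz;
#'   defaults to the profile metadata.
#' @return A list with `coef`, `time` (both length 130), `n_original`,
#'   `sw_hz`, and `dip_max` (the profile maximum subtracted by the dip
#'   transform).
#' @export
pack_profile <- function(profile, b0 = NULL) {
  stopifnot(inherits(profile, "cest_profile"))
  if (is.null(b0)) b0 <- attr(profile, "b0")
  if (is.na(b0)) stop("profile has no B0 metadata", call. = FALSE)
  n <- nrow(profile)
  span_ppm <- max(profile$offset) - min(profile$offset)
  sw_hz <- ppm_to_hz(span_ppm, b0)
  dip <- dip_transform(profile)
  ptd <- zero_fill(real_ft(dip), sw_hz = sw_hz, n_original = n)
  out <- pack_input(ptd)
  out$n_original <- n
  out$sw_hz <- sw_hz
  out$dip_max <- max(profile$intensity)
  out
}
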