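# Hilbert spectral analysis of IMFs.
#
# For each IMF the analytic signal gives an instantaneous amplitude A(t) and
# an unwrapped phase whose derivative is the instantaneous frequency f(t).
# The Hilbert spectrum (HS) is the pair (f(t), A(t)^2) over time; integrating
# the HS along the time axis yields the marginal Hilbert spectrum (MHS)
# h(f), energy per frequency bin. The area centroid of the MHS summarizes
# each IMF by one (frequency, energy) pair — the frequency-domain features.

#' Hilbert spectrum of an IMF
#'
#' Computes the analytic signal by FFT, the instantaneous amplitude
#' `A(t) = |z(t)|`, and the instantaneous frequency as the central
#' difference of the unwrapped phase divided by 2*pi, clipped to
#' \[0, Nyquist\]. A fraction of samples at each end (default 5%) is
#' discarded: the Hilbert transform and the phase derivative are unreliable
#' at the boundaries.
#'
#' @param imf numeric IMF.
#' @param sample_rate Hz.
#' @param trim fraction of samples dropped at each end (default 0.05).
#' @return An object of class `hilbert_spectrum`: list with `t` (s),
#'   `freq` (Hz), `energy` (amplitude^2, deg^2), and `sample_rate`. An
#'   all-zero IMF yields an empty spectrum.
#' @export
hilbert_spectrum <- function(imf, sample_rate, trim = 0.05) {
  n <- length(imf)
  stopifnot(n >= 8, sample_rate > 0, trim >= 0, trim < 0.5)
  empty <- structure(list(t = numeric(0), freq = numeric(0),
                          energy = numeric(0), sample_rate = sample_rate),
                     class = "hilbert_spectrum")
  if (all(imf == 0)) return(empty)

  # analytic signal z = imf + i * H(imf) via the FFT one-sided spectrum
  X <- stats::fft(imf)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n

  amp <- Mod(z)
  phase <- signal::unwrap(Arg(z))
  dt <- 1 / sample_rate
  freq <- numeric(n)
  freq[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / (4 * pi * dt)
  freq[1] <- (phase[2] - phase[1]) / (2 * pi * dt)
  freq[n] <- (phase[n] - phase[n - 1]) / (2 * pi * dt)
  freq <- pmin(pmax(freq, 0), sample_rate / 2)

  keep <- seq_len(n)
  ntrim <- floor(n * trim)
  if (ntrim > 0) keep <- (ntrim + 1):(n - ntrim)
  structure(list(t = (keep - 1) * dt, freq = freq[keep],
                 energy = amp[keep]^2, sample_rate = sample_rate),
            class = "hilbert_spectrum")
}

#' Marginal Hilbert spectrum
#'
#' Integrates the Hilbert spectrum along the time axis: each sample
#' contributes `A(t)^2 * dt` to the bin containing its instantaneous
#' frequency. Bins cover \[0, Nyquist\].
#'
#' @param hs a [hilbert_spectrum()].
#' @param bin_width frequency bin width in Hz (default 0.05; the exercises
#'   live below a few Hz, so sub-0.1-Hz resolution is needed there).
#' @return An object of class `marginal_spectrum`: list with `freq` (bin
#'   centers, Hz) and `h` (binned energy, deg^2 s).
#' @export
marginal_spectrum <- function(hs, bin_width = 0.05) {
  stopifnot(inherits(hs, "hilbert_spectrum"))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  nyq <- hs$sample_rate / 2
  nbin <- ceiling(nyq / bin_width)
  edges <- (0:nbin) * bin_width
  h <- numeric(nbin)
  if (length(hs$freq) > 0) {
    dt <- 1 / hs$sample_rate
    idx <- pmin(pmax(findInterval(hs$freq, edges, rightmost.closed = TRUE), 1L), nbin)
    contrib <- hs$energy * dt
    h <- as.numeric(tapply(contrib, factor(idx, levels = seq_len(nbin)), sum,
                           default = 0))
  }
  structure(list(freq = edges[-1] - bin_width / 2, h = h),
            class = "marginal_spectrum")
}

#' Area centroid of a marginal Hilbert spectrum
#'
#' Summarizes the MHS by the abscissa of its area centroid (the
#' energy-weighted mean frequency) and its total area (the IMF's total
#' energy). A spectrum with zero total energy yields `(0, 0)` with a
#' warning.
#'
#' @param mhs a [marginal_spectrum()].
#' @param energy_coord `"area"` (default): energy = total area `sum(h)`;
#'   `"geometric"`: the geometric y-centroid `sum(h^2)/2 / sum(h)`.
#' @return Named numeric `c(freq = , energy = )` (Hz, deg^2 s).
#' @export
mhs_centroid <- function(mhs, energy_coord = c("area", "geometric")) {
  stopifnot(inherits(mhs, "marginal_spectrum"))
  energy_coord <- match.arg(energy_coord)
  tot <- sum(mhs$h)
  if (tot <= 0) {
    warning("marginal spectrum has zero total energy")
    return(c(freq = 0, energy = 0))
  }
  fc <- sum(mhs$freq * mhs$h) / tot
  ec <- if (energy_coord == "area") tot else sum(mhs$h^2) / 2 / tot
  c(freq = fc, energy = ec)
}

#' Dump an EMD result or marginal spectrum to CSV for inspection
#'
#' `write_imfs_csv` writes one column per IMF plus the residue;
#' `write_mhs_csv` writes `f,h` rows.
#'
#' @param dec an [emd()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_imfs_csv <- function(dec, path) {
  stopifnot(inherits(dec, "imf_set"))
  cols <- c(dec$imfs, list(dec$residue))
  names(cols) <- c(paste0("IMF", seq_along(dec$imfs)), "residue")
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imfs_csv
#' @param mhs a [marginal_spectrum()].
#' @export
write_mhs_csv <- function(mhs, path) {
  stopifnot(inherits(mhs, "marginal_spectrum"))
  utils::write.csv(data.frame(f = mhs$freq, h = mhs$h), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' HHT configuration
#'
#' @param max_imfs IMFs retained per axis series (default 3).
#' @param sd_tol,max_sift sifting controls, see [sift()].
#' @param bin_width MHS bin width in Hz.
#' @param trim boundary trim fraction for the Hilbert spectrum.
#' @param energy_coord see [mhs_centroid()].
#' @param zero_fill if `TRUE` (default), axes with fewer than `max_imfs`
#'   extractable IMFs contribute `(0, 0)` centroids (with a warning);
#'   if `FALSE` this is an error.
#' @return A list of class `hht_config`.
#' @export
hht_config <- function(max_imfs = 3, sd_tol = 0.25, max_sift = 100,
                       bin_width = 0.05, trim = 0.05,
                       energy_coord = "area", zero_fill = TRUE) {
  structure(list(max_imfs = max_imfs, sd_tol = sd_tol, max_sift = max_sift,
                 bin_width = bin_width, trim = trim,
                 energy_coord = energy_coord, zero_fill = zero_fill),
            class = "hht_config")
}

#' Marginal-spectrum centroid features of one axis series
#'
#' Composes [emd()] (first `max_imfs` IMFs), [hilbert_spectrum()],
#' [marginal_spectrum()] and [mhs_centroid()] into the six frequency-domain
#' features of one axis: the centroid frequencies and energies of IMF1-IMF3.
#'
#' @param x numeric series (relative angles of one axis), length >= 8.
#' @param sample_rate Hz.
#' @param cfg an [hht_config()].
#' @return Named numeric of length 6:
#'   `IMF1_f, IMF2_f, IMF3_f, IMF1_e, IMF2_e, IMF3_e`.
#' @export
hht_features <- function(x, sample_rate, cfg = hht_config()) {
  stopifnot(length(x) >= 8)
  k <- cfg$max_imfs
  dec <- emd(x, max_imfs = k, sd_tol = cfg$sd_tol, max_sift = cfg$max_sift)
  freqs <- numeric(k)
  energies <- numeric(k)
  n_found <- length(dec$imfs)
  if (n_found < k) {
    msg <- sprintf("only %d of %d IMFs extracted; missing centroids set to 0",
                   n_found, k)
    if (cfg$zero_fill) warning(msg) else stop(msg, call. = FALSE)
  }
  for (j in seq_len(n_found)) {
    imf <- dec$imfs[[j]]
    if (all(imf == 0)) next
    hs <- hilbert_spectrum(imf, sample_rate, trim = cfg$trim)
    mhs <- marginal_spectrum(hs, bin_width = cfg$bin_width)
    if (sum(mhs$h) <= 0) next
    cen <- mhs_centroid(mhs, energy_coord = cfg$energy_coord)
    freqs[j] <- cen[["freq"]]
    energies[j] <- cen[["energy"]]
  }
  stats::setNames(c(freqs, energies),
                  c(paste0("IMF", 1:k, "_f"), paste0("IMF", 1:k, "_e")))
}
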