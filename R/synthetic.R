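#' Configuration for a synthetic paired-instrument scenario
#'
#' Describes a Beer-Lambert linear mixture measured on two NIR instruments
#' that differ by smooth affine distortions. Pure component spectra are
#' sums of Gaussian absorption bands; sample spectra are concentration-
#' weighted sums plus a per-sample low-order polynomial baseline and iid
#' Gaussian noise; the slave instrument additionally applies a smooth
#' multiplicative gain curve, a smooth additive offset curve, an optional
#' fractional wavelength shift, and per-sample multiplicative scatter.
#' The defaults describe a moderate affine inter-instrument difference of
#' the kind transfer methods are designed for; the analyte is the first
#' mixture component and both instruments' samples draw concentrations from
#' the same range.
#'
#' @param n_cal,n_test calibration and test set sizes.
#' @param p number of wavelength channels.
#' @param wl_start,wl_step wavelength axis start and spacing (nm).
#' @param k_components number of mixture components (analyte first).
#' @param peak_count_per_component Gaussian bands per pure spectrum.
#' @param concentration_range interval the analyte and interferent
#'   concentrations are drawn from, uniformly; shared by both instruments.
#' @param baseline_amplitude scale of the per-sample quadratic baseline
#'   (absorbance).
#' @param gain_scale overall amplitude ratio between the instruments
#'   (detector sensitivity / effective pathlength); the first-order
#'   difference between real spectrometers, and one that maps predictions
#'   exactly affinely.
#' @param gain_amplitude amplitude of the slave's smooth wavelength-
#'   dependent gain deviation (dimensionless); unlike `gain_scale` this
#'   also mixes interferent signal into the analyte prediction, which no
#'   affine correction can remove.
#' @param offset_amplitude amplitude of the slave's smooth additive offset
#'   curve (absorbance).
#' @param wavelength_shift slave wavelength shift in channels (may be
#'   fractional; 0 keeps the grids aligned — the affine family).
#' @param scatter_sd standard deviation of the slave's per-sample
#'   multiplicative scatter factor around 1.
#' @param noise_sd_master,noise_sd_slave iid absorbance noise levels.
#' @param seed integer seed; the generator uses R's default Mersenne
#'   Twister stream, restored afterwards, so scenarios are reproducible and
#'   leave the session RNG untouched.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_cal = 60, n_test = 20, p = 200,
                            wl_start = 1100, wl_step = 2,
                            k_components = 3,
                            peak_count_per_component = 4,
                            concentration_range = c(0, 1),
                            baseline_amplitude = 0.002,
                            gain_scale = 1.2,
                            gain_amplitude = 0.05,
                            offset_amplitude = 0.05,
                            wavelength_shift = 0,
                            scatter_sd = 0.005,
                            noise_sd_master = 0.002,
                            noise_sd_slave = 0.002,
                            seed = 1) {
  cfg <- list(n_cal = as.integer(n_cal), n_test = as.integer(n_test),
              p = as.integer(p), wl_start = wl_start, wl_step = wl_step,
              k_components = as.integer(k_components),
              peak_count_per_component =
                as.integer(peak_count_per_component),
              concentration_range = as.numeric(concentration_range),
              baseline_amplitude = baseline_amplitude,
              gain_scale = gain_scale,
              gain_amplitude = gain_amplitude,
              offset_amplitude = offset_amplitude,
              wavelength_shift = wavelength_shift,
              scatter_sd = scatter_sd,
              noise_sd_master = noise_sd_master,
              noise_sd_slave = noise_sd_slave,
              seed = as.integer(seed),
              rng = "Mersenne-Twister")
  with(cfg, {
    stopifnot(n_cal > 0, n_test > 0, p > 1, k_components > 0,
              peak_count_per_component > 0, wl_step > 0,
              scatter_sd >= 0, noise_sd_master >= 0, noise_sd_slave >= 0,
              baseline_amplitude >= 0,
              diff(range(concentration_range)) > 0)
  })
  if (abs(cfg$wavelength_shift) >= cfg$p)
    stop("wavelength_shift must be smaller than the channel count",
         call. = FALSE)
  class(cfg) <- "scenario_config"
  cfg
}

# Smooth pseudo-random curve over [0,1] grid: a few low-frequency sinusoids,
# scaled to unit maximum amplitude. Draws from the current RNG stream.
.smooth_curve <- function(p) {
  u <- seq(0, 1, length.out = p)
  f <- rowSums(vapply(1:3, function(k)
    stats::rnorm(1) * sin(2 * pi * (k * u + stats::runif(1))),
    numeric(p)))
  f / max(abs(f))
}

# Clean mixture spectra for a concentration matrix (no noise, no baseline).
.mixture_spectra <- function(conc, pure) conc %*% pure

#' Apply a synthetic instrument difference to master spectra
#'
#' Produces the slave instrument's view of the given spectra: a smooth
#' multiplicative gain curve `1 + gain_amplitude * f(lambda)`, a smooth
#' additive offset curve, a fractional wavelength shift (linear
#' interpolation, endpoints extended), per-sample multiplicative scatter
#' `1 + N(0, scatter_sd)`, then iid Gaussian noise. With all parameters
#' zero the input is returned unchanged.
#'
#' @param master a [spectra_set()] (or matrix) of master-instrument spectra.
#' @param gain_scale,gain_amplitude,offset_amplitude,wavelength_shift,scatter_sd,noise_sd
#'   distortion parameters as in [scenario_config()].
#' @param seed integer seed.
#' @return An object of the same type as `master` with distorted spectra.
#' @export
make_affine_slave <- function(master, gain_scale = 1.2,
                              gain_amplitude = 0.05,
                              offset_amplitude = 0.05,
                              wavelength_shift = 0, scatter_sd = 0.005,
                              noise_sd = 0.002, seed = 1) {
  is_set <- inherits(master, "spectra_set")
  X <- if (is_set) master$spectra else as.matrix(master)
  n <- nrow(X); p <- ncol(X)
  if (abs(wavelength_shift) >= p)
    stop("wavelength_shift must be smaller than the channel count",
         call. = FALSE)
  out <- withr_seed(seed, {
    gain <- gain_scale * (if (gain_amplitude != 0)
      1 + gain_amplitude * .smooth_curve(p) else rep(1, p))
    offset <- if (offset_amplitude != 0)
      offset_amplitude * .smooth_curve(p) else rep(0, p)
    Y <- X
    if (wavelength_shift != 0) {
      pos <- pmin(pmax(seq_len(p) + wavelength_shift, 1), p)
      lo <- floor(pos); hi <- ceiling(pos); frac <- pos - lo
      Y <- sweep(X[, lo, drop = FALSE], 2L, 1 - frac, `*`) +
        sweep(X[, hi, drop = FALSE], 2L, frac, `*`)
    }
    Y <- sweep(Y, 2L, gain, `*`)
    Y <- sweep(Y, 2L, offset, `+`)
    if (scatter_sd > 0) Y <- Y * (1 + stats::rnorm(n, 0, scatter_sd))
    if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
    Y
  })
  if (is_set) spectra_set(out, master$wavelengths, master$reference,
                          master$ids) else out
}

#' Generate a synthetic paired-instrument scenario
#'
#' Draws pure component spectra and concentration sets, renders
#' master-instrument spectra, and distorts the slave sets with
#' [make_affine_slave()]. The calibration samples are the same physical
#' specimens measured on both instruments — the typical situation when an
#' existing calibration set is re-scanned on a new spectrometer — while
#' the test samples are new specimens, measured on the slave only, with
#' concentrations from the same shared range (the working assumption of
#' standard-free transfer). The slave sets carry their ground-truth analyte
#' values in `reference` for evaluation only; a transfer method must not
#' use them. The same seed reproduces the scenario bit for bit.
#'
#' @param cfg a [scenario_config()].
#' @return A list of class `"synthetic_scenario"` with elements
#'   `master_cal`, `slave_cal`, `slave_test` ([spectra_set()]s),
#'   `slave_cal_master_view`, `slave_test_master_view` (the same samples as
#'   the master instrument would have measured them — for oracle checks),
#'   `pure_spectra` (k x p) and `config`.
#' @export
generate_scenario <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  wl <- cfg$wl_start + cfg$wl_step * (seq_len(cfg$p) - 1)
  res <- withr_seed(cfg$seed, {
    u <- seq(0, 1, length.out = cfg$p)
    pure <- t(vapply(seq_len(cfg$k_components), function(k) {
      centers <- stats::runif(cfg$peak_count_per_component)
      widths <- stats::runif(cfg$peak_count_per_component, 0.02, 0.08)
      amps <- stats::runif(cfg$peak_count_per_component, 0.2, 1)
      rowSums(vapply(seq_len(cfg$peak_count_per_component), function(j)
        amps[j] * exp(-(u - centers[j])^2 / (2 * widths[j]^2)),
        numeric(cfg$p)))
    }, numeric(cfg$p)))
    draw_conc <- function(n)
      matrix(stats::runif(n * cfg$k_components,
                          cfg$concentration_range[1],
                          cfg$concentration_range[2]),
             n, cfg$k_components)
    # the calibration samples are the same physical specimens measured on
    # both instruments (the usual situation when a calibration set is
    # re-scanned on a new spectrometer); their reference values are still
    # never shown to the transfer method
    conc_m <- draw_conc(cfg$n_cal)
    render <- function(conc, noise_sd) {
      n <- nrow(conc)
      Xc <- .mixture_spectra(conc, pure)
      if (cfg$baseline_amplitude > 0) {
        B <- cbind(1, u, u^2)
        cf <- matrix(stats::rnorm(n * 3, 0, cfg$baseline_amplitude), n, 3)
        Xc <- Xc + tcrossprod(cf, B)
      }
      if (noise_sd > 0)
        Xc <- Xc + matrix(stats::rnorm(n * cfg$p, 0, noise_sd), n, cfg$p)
      Xc
    }
    conc_s <- conc_m
    conc_t <- draw_conc(cfg$n_test)
    list(pure = pure,
         conc_m = conc_m, conc_s = conc_s, conc_t = conc_t,
         Xm = render(conc_m, cfg$noise_sd_master),
         Xs_clean = render(conc_s, 0),
         Xt_clean = render(conc_t, 0))
  })
  distort <- function(X, seed_offset)
    make_affine_slave(X, gain_scale = cfg$gain_scale,
                      gain_amplitude = cfg$gain_amplitude,
                      offset_amplitude = cfg$offset_amplitude,
                      wavelength_shift = cfg$wavelength_shift,
                      scatter_sd = cfg$scatter_sd,
                      noise_sd = cfg$noise_sd_slave,
                      seed = cfg$seed + seed_offset)
  # the slave's gain/offset curves must be shared between its calibration
  # and test sets (one instrument), so both use the same distortion seed;
  # sample-level scatter and noise then differ only through sample count
  Xs <- distort(rbind(res$Xs_clean, res$Xt_clean), 1L)
  n_s <- nrow(res$Xs_clean)
  master_noise <- function(X, seed_offset) withr_seed(
    cfg$seed + seed_offset,
    X + matrix(stats::rnorm(length(X), 0, cfg$noise_sd_master),
               nrow(X), ncol(X)))
  structure(list(
    master_cal = spectra_set(res$Xm, wl, reference = res$conc_m[, 1]),
    slave_cal = spectra_set(Xs[seq_len(n_s), , drop = FALSE], wl,
                            reference = res$conc_s[, 1]),
    slave_test = spectra_set(Xs[-seq_len(n_s), , drop = FALSE], wl,
                             reference = res$conc_t[, 1]),
    slave_cal_master_view = spectra_set(
      master_noise(res$Xs_clean, 2L), wl, reference = res$conc_s[, 1]),
    slave_test_master_view = spectra_set(
      master_noise(res$Xt_clean, 3L), wl, reference = res$conc_t[, 1]),
    pure_spectra = res$pure,
    config = cfg), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Synthetic paired-instrument scenario (seed %d): ",
                     "%d cal + %d test samples, %d channels, ",
                     "%d components\n"),
              cfg$seed, cfg$n_cal, cfg$n_test, cfg$p, cfg$k_components))
  cat(sprintf("  slave distortion: gain %.3g, offset %.3g, shift %.3g, ",
              cfg$gain_amplitude, cfg$offset_amplitude,
              cfg$wavelength_shift))
  cat(sprintf("scatter %.3g, noise %.3g\n", cfg$scatter_sd,
              cfg$noise_sd_slave))
  invisible(x)
}
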