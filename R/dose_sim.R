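# Dose simulation: insertion of properly scaled quantum and electronic noise
# into acquired projection data so that the output is statistically
# equivalent (to first order) to a direct acquisition at a reduced dose,
# plus the automated water-phantom calibration loop for the inserted-noise
# scale.

#' Noise model for dose simulation
#'
#' @param alpha dose fraction in (0, 1]: the simulated scan corresponds to
#'   `alpha` times the acquired dose (tube current).
#' @param sigma_e electronic noise SD in count units; defaults to the value
#'   recorded on the sinogram's protocol when `NULL`.
#' @param calib_factor dimensionless multiplier `c` on the inserted noise
#'   variance; 1 is the nominal model, the calibration loop refines it.
#' @param mode `"gaussian"` inserts zero-mean Gaussian noise in the
#'   line-integral domain with the ray-dependent variance gap between the
#'   target dose and the acquired dose; `"thinning"` instead thins the
#'   detected counts binomially to the dose fraction and re-logs. Both
#'   reproduce the first-order statistics of a direct low-dose acquisition.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(alpha, sigma_e = NULL, calib_factor = 1,
                        mode = c("gaussian", "thinning")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("alpha must be a finite scalar", call. = FALSE)
  if (alpha > 1)
    stop("dose increase cannot be simulated (alpha must be <= 1)",
         call. = FALSE)
  if (alpha <= 0)
    stop("alpha must be positive", call. = FALSE)
  if (calib_factor <= 0) stop("calib_factor must be > 0", call. = FALSE)
  structure(
    list(alpha = alpha, sigma_e = sigma_e, calib_factor = calib_factor,
         mode = mode),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model> alpha = %g, sigma_e = %s, c = %g, mode = %s\n",
    x$alpha, if (is.null(x$sigma_e)) "(protocol)" else format(x$sigma_e),
    x$calib_factor, x$mode
  ))
  invisible(x)
}

# Per-ray projection variance of the log-transformed measurement at expected
# count lambda with electronic noise sd sigma_e (delta method):
# Var[p] = 1/lambda + sigma_e^2/lambda^2.
ray_log_variance <- function(lambda, sigma_e) {
  1 / lambda + sigma_e^2 / lambda^2
}

#' Insert noise to simulate a reduced-dose scan
#'
#' The central operation: given a noisy acquisition and a dose fraction
#' `alpha`, produces a sinogram whose per-ray noise matches a direct
#' acquisition at `alpha` times the dose. The expected count per ray is
#' estimated from the measurement itself (`lambda_hat = N0 * exp(-p)`), the
#' target variance `c * (1/lambda_a + sigma_e^2/lambda_a^2)` with
#' `lambda_a = alpha * lambda_hat` is compared with the variance already
#' present, and the gap is inserted. In `"gaussian"` mode the gap is added
#' as zero-mean Gaussian noise in the line-integral domain (unbiased, so
#' mean attenuation is preserved); in `"thinning"` mode counts are thinned
#' binomially (Poisson thinning) and the electronic component topped up to
#' its full-dose-equivalent level. The output protocol records
#' `eff_mas * alpha`.
#'
#' @param sino a noisy `sinogram` carrying its acquisition protocol.
#' @param model a [noise_model()].
#' @param seed integer seed; identical seeds give identical output.
#' @return a `sinogram` at the reduced dose, with attribute `alpha`.
#' @export
insert_noise <- function(sino, model, seed = 1L) {
  stopifnot(inherits(sino, "sinogram"), inherits(model, "noise_model"))
  if (is.null(sino$protocol))
    stop("sinogram carries no acquisition protocol (N0 unknown)",
         call. = FALSE)
  alpha <- model$alpha
  sigma_e <- if (is.null(model$sigma_e)) sino$protocol$sigma_e else model$sigma_e
  n0 <- protocol_n0(sino$protocol)
  p <- sino$values
  out_protocol <- scan_protocol(
    eff_mas = sino$protocol$eff_mas * alpha,
    kv_label = sino$protocol$kv_label,
    photons_per_mas = sino$protocol$photons_per_mas,
    sigma_e = sigma_e
  )

  if (alpha == 1 && model$calib_factor == 1 && model$mode == "gaussian") {
    out <- new_sinogram(p, sino$angles, sino$bin_spacing, out_protocol,
                        sino$mu_water, noisy = TRUE)
    attr(out, "alpha") <- 1
    return(out)
  }

  lambda_hat <- n0 * exp(-p)
  lambda_a <- alpha * lambda_hat

  if (model$mode == "gaussian") {
    var_target <- model$calib_factor * ray_log_variance(lambda_a, sigma_e)
    var_have <- ray_log_variance(lambda_hat, sigma_e)
    gap <- pmax(var_target - var_have, 0)  # clamp: no noise removal
    set.seed(substream_seed(seed, "insert_gaussian"))
    p_new <- p + rnorm(length(p), 0, sqrt(gap))
  } else {
    # Poisson thinning: Binomial(N, alpha) of a Poisson(lambda) count is
    # Poisson(alpha * lambda); the electronic component is scaled by alpha
    # through thinning, so it is topped up to sigma_e with an independent
    # Gaussian of sd sigma_e * sqrt(1 - alpha^2). The calibration factor
    # scales the *inserted* variance via an additional Gaussian term.
    counts <- pmax(round(lambda_hat), 0)
    set.seed(substream_seed(seed, "insert_thin"))
    thinned <- rbinom(length(counts), as.integer(pmin(counts, .Machine$integer.max)),
                      alpha)
    set.seed(substream_seed(seed, "insert_thin_elec"))
    thinned <- thinned + rnorm(length(counts), 0, sigma_e * sqrt(1 - alpha^2))
    p_new <- -log(pmax(thinned, 1) / (alpha * n0))
    if (model$calib_factor != 1) {
      extra <- (model$calib_factor - 1) *
        ray_log_variance(lambda_a, sigma_e)
      set.seed(substream_seed(seed, "insert_thin_extra"))
      p_new <- p_new + rnorm(length(p), 0, sqrt(pmax(extra, 0)))
    }
  }

  out <- new_sinogram(matrix(p_new, sino$n_views, sino$n_bins),
                      sino$angles, sino$bin_spacing, out_protocol,
                      sino$mu_water, noisy = TRUE)
  attr(out, "alpha") <- alpha
  out
}

#' Calibrate the inserted-noise scale on a water phantom
#'
#' Reproduces the automated calibration loop: acquire the water phantom at
#' the reference protocol, measure the image noise in a central circular ROI
#' of the reconstruction, predict the expected low-dose noise from the
#' variance model (the quantum part scales as `1/alpha`), then repeatedly
#' insert noise at `target_alpha`, reconstruct, and rescale `c`
#' multiplicatively until the achieved ROI SD is within `tol` of the
#' expected level.
#'
#' The update is `c <- c * (SD_target^2 - SD_full^2) / (SD_meas^2 -
#' SD_full^2)`: reconstruction is linear, so the inserted variance in the
#' image is proportional to `c` and the iteration is strongly contracting.
#' Each iteration averages the measured SD over `n_rep` independent
#' insertions with iteration-fixed seeds, which makes the whole loop
#' deterministic for a given `seed`.
#'
#' @param model starting [noise_model()] (its `alpha` is ignored;
#'   `target_alpha` is used).
#' @param water_map a uniform water phantom [attenuation_map()].
#' @param protocol reference [scan_protocol()] (200 eff. mAs in the
#'   canonical calibration).
#' @param roi_diameter central ROI diameter in mm (default 50, the 5-cm
#'   calibration ROI).
#' @param target_alpha dose fraction calibrated at (default 0.0625, i.e.
#'   a 6.25 percent target dose level).
#' @param tol relative tolerance on the achieved ROI SD (default 0.01).
#' @param max_iter maximum iterations (default 20).
#' @param seed root seed for the loop.
#' @param n_rep insertions averaged per iteration.
#' @param n_views,n_bins scan geometry; `recon_fov`, `recon_grid` the
#'   reconstruction used for the noise measurement.
#' @param kernel reconstruction kernel.
#' @return the calibrated `noise_model` (with `alpha = target_alpha`), with
#'   attributes `achieved_sd`, `target_sd`, `full_sd`, `iterations`,
#'   `residual` (relative), and `converged`.
#' @export
calibrate <- function(model, water_map, protocol,
                      roi_diameter = 50, target_alpha = 0.0625,
                      tol = 0.01, max_iter = 20, seed = 1L, n_rep = 8,
                      n_views = 360, n_bins = 600,
                      recon_fov = 180, recon_grid = 256,
                      kernel = "hann") {
  stopifnot(inherits(model, "noise_model"),
            inherits(water_map, "attenuation_map"),
            inherits(protocol, "scan_protocol"))
  if (target_alpha <= 0 || target_alpha >= 1)
    stop("target_alpha must be in (0, 1)", call. = FALSE)

  roi <- roi_spec(0, 0, roi_diameter, "calibration")
  sino0 <- forward_project(water_map, n_views, n_bins)

  roi_sd <- function(sino) {
    img <- fbp(sino, kernel, fov = recon_fov, grid_size = recon_grid)
    roi_stats(img, roi)$sd
  }
  # full-dose reference noise, averaged over n_rep acquisitions
  full_sds <- vapply(seq_len(n_rep), function(i) {
    roi_sd(acquire(sino0, protocol, seed = substream_seed(seed, paste0("calib_full_", i))))
  }, numeric(1))
  sd_full <- mean(full_sds)

  # expected low-dose noise from the variance model: image variance is a
  # fixed linear functional of the per-ray projection variance, so the
  # predicted SD scales with the root of the per-ray variance ratio,
  # averaged over the rays that traverse the ROI (the rays whose noise the
  # central-ROI SD actually measures)
  n0 <- protocol_n0(protocol)
  tsel <- abs(bin_positions(sino0$n_bins, sino0$bin_spacing)) <= roi_diameter / 2
  lambda <- n0 * exp(-sino0$values[, tsel])
  v_full <- mean(ray_log_variance(lambda, protocol$sigma_e))
  v_target <- mean(ray_log_variance(target_alpha * lambda, protocol$sigma_e))
  sd_target <- sd_full * sqrt(v_target / v_full)

  # one reference acquisition that every iteration inserts into
  ref <- acquire(sino0, protocol, seed = substream_seed(seed, "calib_ref"))

  cc <- model$calib_factor
  converged <- FALSE
  resid <- NA_real_
  sd_meas <- NA_real_
  for (it in seq_len(max_iter)) {
    m_it <- noise_model(target_alpha, sigma_e = model$sigma_e,
                        calib_factor = cc, mode = model$mode)
    sds <- vapply(seq_len(n_rep), function(r) {
      roi_sd(insert_noise(ref, m_it,
                          seed = substream_seed(seed, paste0("calib_it_", r))))
    }, numeric(1))
    sd_meas <- mean(sds)
    resid <- abs(sd_meas - sd_target) / sd_target
    if (resid <= tol) { converged <- TRUE; break }
    gain <- (sd_target^2 - sd_full^2) / (sd_meas^2 - sd_full^2)
    if (!is.finite(gain) || gain <= 0)
      stop("calibration failed: measured noise not above the full-dose level",
           call. = FALSE)
    cc <- cc * gain
  }
  if (!converged)
    stop(sprintf(
      "calibration did not converge in %d iterations (last residual %.3f)",
      max_iter, resid), call. = FALSE)

  out <- noise_model(target_alpha, sigma_e = model$sigma_e,
                     calib_factor = cc, mode = model$mode)
  attr(out, "achieved_sd") <- sd_meas
  attr(out, "target_sd") <- sd_target
  attr(out, "full_sd") <- sd_full
  attr(out, "iterations") <- it
  attr(out, "residual") <- resid
  attr(out, "converged") <- converged
  out
}
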