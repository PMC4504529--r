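# Orchestration of the phantom validation experiment: true scans at reduced
# tube current versus dose simulations derived from the reference scan, with
# ROI tables and the statistical comparisons between the two arms.

#' Experiment configuration
#'
#' @param spec head-phantom [phantom_spec()].
#' @param protocol reference [scan_protocol()] (the full-dose acquisition
#'   the simulations are derived from; canonical reference 160 eff. mAs).
#' @param fractions dose fractions, each in (0, 1], containing 1 (the
#'   reference level). Default `c(1, 0.75, 0.5, 0.25)`.
#' @param n_realizations independent noise realizations per dose level in
#'   each arm; a single physical scan per level corresponds to 1, the
#'   default 10 gives the comparisons statistical power.
#' @param rois ROI set (default [head_phantom_rois()] of `spec`: 10 tube
#'   ROIs, 5 per dilution).
#' @param seed root seed; every random stage derives a named substream
#'   from it.
#' @param grid_size,fov phantom/scan geometry; `n_views`, `n_bins` the
#'   sinogram geometry; `recon_fov`, `recon_grid`, `kernel` the
#'   reconstruction.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(spec = phantom_spec("head"),
                              protocol = scan_protocol(eff_mas = 160),
                              fractions = c(1, 0.75, 0.5, 0.25),
                              n_realizations = 10,
                              rois = head_phantom_rois(spec),
                              seed = 1L,
                              grid_size = 512, fov = 250,
                              n_views = 360, n_bins = 600,
                              recon_fov = 180, recon_grid = 256,
                              kernel = "hann") {
  if (any(fractions <= 0 | fractions > 1))
    stop("dose fractions must lie in (0, 1]", call. = FALSE)
  if (!any(fractions == 1))
    stop("the reference fraction 1 must be present", call. = FALSE)
  structure(
    list(spec = spec, protocol = protocol,
         fractions = sort(unique(fractions), decreasing = TRUE),
         n_realizations = n_realizations, rois = rois, seed = seed,
         grid_size = grid_size, fov = fov,
         n_views = n_views, n_bins = n_bins,
         recon_fov = recon_fov, recon_grid = recon_grid, kernel = kernel),
    class = "experiment_config"
  )
}

#' Reconstruct a dose series from one acquisition
#'
#' For each fraction, inserts noise into the acquired sinogram (fraction 1
#' means no insertion) and reconstructs; provenance records the fraction.
#'
#' @param sino a noisy acquired `sinogram`.
#' @param fractions dose fractions in (0, 1].
#' @param model base [noise_model()] whose `sigma_e`, `calib_factor` and
#'   `mode` are reused at each fraction.
#' @param seed root seed (one substream per fraction).
#' @param fov,grid_size,kernel reconstruction settings.
#' @return named list of [recon_image()], one per fraction.
#' @export
run_dose_series <- function(sino, fractions, model = noise_model(1),
                            seed = 1L, fov = 180, grid_size = 256,
                            kernel = "hann") {
  if (any(fractions <= 0))
    stop("dose fractions must be positive", call. = FALSE)
  if (any(fractions > 1))
    stop("dose increase cannot be simulated (fraction > 1)", call. = FALSE)
  out <- list()
  for (f in fractions) {
    s <- if (f == 1) sino else {
      insert_noise(sino,
                   noise_model(f, sigma_e = model$sigma_e,
                               calib_factor = model$calib_factor,
                               mode = model$mode),
                   seed = substream_seed(seed, paste0("series_", f)))
    }
    img <- fbp(s, kernel, fov = fov, grid_size = grid_size)
    img$provenance$alpha <- f
    out[[sprintf("alpha_%g", f)]] <- img
  }
  out
}

#' Run the phantom validation experiment
#'
#' For every dose fraction and realization, a *true* scan is acquired at
#' `fraction * eff_mas` and, for fractions below 1, a *simulated* scan is
#' derived from the matched reference (full-dose) acquisition by noise
#' insertion. All images share the ROI set; the report contains the full
#' per-realization ROI table, a per-(fraction x ROI) summary averaging SD
#' over realizations, and per-fraction comparisons: an exact sign test on
#' the paired per-ROI SDs (noise) and a Mann-Whitney U test on the ROI
#' mean attenuations, true versus simulated.
#'
#' @param cfg an [experiment_config()].
#' @param model base [noise_model()] used for the insertions.
#' @param roi_only if `TRUE`, reconstruct only the pixels covered by the
#'   ROI set (identical values there, see [fbp()]'s `mask`); the ROI
#'   tables are unchanged and large realization ensembles become cheap.
#' @return list of class `experiment_report`: `config_echo`, `roi_table`,
#'   `summary`, `tests`, `seed`.
#' @export
run_phantom_experiment <- function(cfg, model = noise_model(1),
                                   roi_only = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  phantom <- make_head_phantom(cfg$spec, cfg$grid_size, cfg$fov)
  sino0 <- forward_project(phantom, cfg$n_views, cfg$n_bins)
  mask <- if (roi_only) roi_mask(cfg$rois, cfg$recon_grid, cfg$recon_fov)
          else NULL

  rows <- list()
  add_rows <- function(img, arm, fraction, realization) {
    tb <- replicate_rois(cfg$rois, list(img = img))
    tb$arm <- arm; tb$fraction <- fraction; tb$realization <- realization
    rows[[length(rows) + 1]] <<- tb
  }

  for (f in cfg$fractions) {
    for (r in seq_len(cfg$n_realizations)) {
      p_true <- scan_protocol(cfg$protocol$eff_mas * f,
                              kv_label = cfg$protocol$kv_label,
                              photons_per_mas = cfg$protocol$photons_per_mas,
                              sigma_e = cfg$protocol$sigma_e)
      s_true <- acquire(sino0, p_true,
                        seed = substream_seed(cfg$seed, sprintf("true_%g_%d", f, r)))
      add_rows(fbp(s_true, cfg$kernel, cfg$recon_fov, cfg$recon_grid,
                   mask = mask),
               "true", f, r)
      if (f < 1) {
        ref <- acquire(sino0, cfg$protocol,
                       seed = substream_seed(cfg$seed, sprintf("ref_%d", r)))
        s_sim <- insert_noise(
          ref,
          noise_model(f, sigma_e = model$sigma_e,
                      calib_factor = model$calib_factor, mode = model$mode),
          seed = substream_seed(cfg$seed, sprintf("sim_%g_%d", f, r))
        )
        add_rows(fbp(s_sim, cfg$kernel, cfg$recon_fov, cfg$recon_grid,
                     mask = mask),
                 "sim", f, r)
      }
    }
  }
  roi_table <- do.call(rbind, rows)
  roi_table$image <- NULL
  rownames(roi_table) <- NULL

  # per (fraction x ROI x arm) mean over realizations
  agg <- stats::aggregate(
    cbind(mean_hu = mean, sd_hu = sd) ~ arm + fraction + label,
    data = roi_table, FUN = mean
  )

  # Paired sign test per fraction on per-ROI SDs. ROIs within one tube
  # overlap spatially, so SDs measured on the same realization are
  # correlated across ROIs; each ROI therefore gets its own block of
  # realizations, making the ten paired signs independent under the null.
  labels <- sort(unique(roi_table$label))
  n_blocks <- min(length(labels), cfg$n_realizations)
  block_of_real <- ((seq_len(cfg$n_realizations) - 1) %% n_blocks) + 1

  tests <- list()
  for (f in setdiff(cfg$fractions, 1)) {
    block_sd <- function(arm) {
      vapply(seq_along(labels), function(i) {
        b <- ((i - 1) %% n_blocks) + 1
        sel <- roi_table$arm == arm & roi_table$fraction == f &
          roi_table$label == labels[i] &
          block_of_real[roi_table$realization] == b
        mean(roi_table$sd[sel])
      }, numeric(1))
    }
    st <- sign_test(block_sd("true"), block_sd("sim"))
    # Mann-Whitney on mean attenuation: one pooled tube mean per
    # realization and arm (independent sampling units within each arm)
    pool_mean <- function(arm) {
      sel <- roi_table$arm == arm & roi_table$fraction == f
      as.numeric(tapply(roi_table$mean[sel], roi_table$realization[sel], mean))
    }
    mw <- mann_whitney(pool_mean("true"), pool_mean("sim"))
    tr <- agg[agg$arm == "true" & agg$fraction == f, ]
    si <- agg[agg$arm == "sim" & agg$fraction == f, ]
    tr <- tr[order(tr$label), ]; si <- si[order(si$label), ]
    tests[[sprintf("alpha_%g", f)]] <- data.frame(
      fraction = f,
      sign_p_sd = st$p_value,
      mw_p_mean = mw$p_value,
      max_rel_sd_gap = max(abs(si$sd_hu - tr$sd_hu) / tr$sd_hu),
      stringsAsFactors = FALSE
    )
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL

  structure(
    list(
      config_echo = list(
        fractions = cfg$fractions, n_realizations = cfg$n_realizations,
        eff_mas = cfg$protocol$eff_mas, seed = cfg$seed,
        kernel = cfg$kernel, n_rois = length(cfg$rois)
      ),
      roi_table = roi_table, summary = agg, tests = tests,
      seed = cfg$seed
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(
    "<experiment_report> %d ROIs x fractions {%s} x %d realizations (seed %d)\n",
    x$config_echo$n_rois,
    paste(x$config_echo$fractions, collapse = ", "),
    x$config_echo$n_realizations, x$seed
  ))
  if (!is.null(x$tests)) {
    cat("true vs simulated comparisons:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Writes `report.json` (config echo, tests, summary), `roi_table.csv` and
#' `summary.csv` into `dir`.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = report$config_echo, tests = report$tests,
         summary = report$summary),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  utils::write.csv(report$roi_table, file.path(dir, "roi_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}
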