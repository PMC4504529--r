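# The noise-insertion contract: output statistics match a direct
# acquisition at the reduced dose. The direct acquisition is the oracle
# throughout.

test_that("alpha = 1 with nominal calibration is the identity", {
  pr <- scan_protocol(eff_mas = 80)
  sn <- acquire(small_water_sino(), pr, seed = 4)
  out <- insert_noise(sn, noise_model(1), seed = 9)
  expect_identical(out$values, sn$values)
  expect_identical(attr(out, "alpha"), 1)
})

test_that("dose increase and non-positive fractions are rejected", {
  expect_error(noise_model(1.2), "dose increase")
  expect_error(noise_model(0), "positive")
  expect_error(noise_model(-0.5), "positive")
})

test_that("insertion is reproducible from its seed", {
  pr <- scan_protocol(eff_mas = 80)
  sn <- acquire(small_water_sino(), pr, seed = 4)
  a <- insert_noise(sn, noise_model(0.5), seed = 21)
  b <- insert_noise(sn, noise_model(0.5), seed = 21)
  expect_identical(a$values, b$values)
})

test_that("insertion preserves the per-ray mean (unbiasedness oracle)", {
  pr <- scan_protocol(eff_mas = 80)
  sn <- acquire(small_water_sino(), pr, seed = 4)
  idx <- seq(1, length(sn$values), by = 97)
  nrep <- 500
  reps <- vapply(seq_len(nrep),
                 function(i) insert_noise(sn, noise_model(0.25),
                                          seed = 100 + i)$values[idx],
                 numeric(length(idx)))
  lam_a <- 0.25 * protocol_n0(pr) * exp(-sn$values[idx])
  se <- sqrt((1 / lam_a + pr$sigma_e^2 / lam_a^2) / nrep)
  expect_true(all(abs(rowMeans(reps) - sn$values[idx]) < 3 * se + 1e-4))
})

test_that("both insertion modes reproduce a direct low-dose acquisition", {
  # oracle equivalence on the small instance: per-ray SDs agree within 5%
  # on average and a two-sample location test is not rejected at 1%
  s0 <- small_water_sino()
  pr <- scan_protocol(eff_mas = 160)
  alpha <- 0.25
  pr_low <- scan_protocol(eff_mas = 160 * alpha)
  idx <- seq(1, length(s0$values), by = 199)
  nrep <- 300
  direct <- vapply(seq_len(nrep),
                   function(i) acquire(s0, pr_low, seed = 3000 + i)$values[idx],
                   numeric(length(idx)))
  for (mode in c("gaussian", "thinning")) {
    sim <- vapply(seq_len(nrep), function(i) {
      ref <- acquire(s0, pr, seed = 1000 + i)
      insert_noise(ref, noise_model(alpha, mode = mode),
                   seed = 2000 + i)$values[idx]
    }, numeric(length(idx)))
    ratio <- apply(sim, 1, sd) / apply(direct, 1, sd)
    expect_equal(mean(ratio), 1, tolerance = 0.05)
    # pooled standardized values: same location in both arms
    for (j in c(1, length(idx) %/% 2)) {
      p <- mann_whitney(sim[j, ], direct[j, ])$p_value
      expect_gt(p, 0.01)
    }
  }
})

test_that("two-step insertion composes to the single-step dose level", {
  s0 <- small_water_sino()
  pr <- scan_protocol(eff_mas = 160)
  idx <- seq(1, length(s0$values), by = 199)
  nrep <- 300
  one <- vapply(seq_len(nrep), function(i) {
    ref <- acquire(s0, pr, seed = 1000 + i)
    insert_noise(ref, noise_model(0.25), seed = 4000 + i)$values[idx]
  }, numeric(length(idx)))
  two <- vapply(seq_len(nrep), function(i) {
    ref <- acquire(s0, pr, seed = 1000 + i)
    half <- insert_noise(ref, noise_model(0.5), seed = 5000 + i)
    insert_noise(half, noise_model(0.5), seed = 6000 + i)$values[idx]
  }, numeric(length(idx)))
  ratio <- apply(two, 1, sd) / apply(one, 1, sd)
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("the simulated protocol records the reduced effective mAs", {
  pr <- scan_protocol(eff_mas = 160)
  sn <- acquire(small_water_sino(), pr, seed = 4)
  out <- insert_noise(sn, noise_model(0.75), seed = 1)
  expect_equal(out$protocol$eff_mas, 120)
})

test_that("reconstructed ROI noise is non-increasing in the dose fraction", {
  # property at alpha in {1, .75, .5, .25}, averaged over 10 realizations
  s0 <- small_water_sino()
  pr <- scan_protocol(eff_mas = 160)
  roi <- roi_spec(0, 0, 20, "c")
  mk <- roi_mask(list(roi), 64, 48)
  sd_at <- function(alpha) {
    mean(vapply(1:10, function(i) {
      ref <- acquire(s0, pr, seed = 800 + i)
      s <- if (alpha == 1) ref else
        insert_noise(ref, noise_model(alpha), seed = 900 + i)
      roi_stats(fbp(s, "hann", fov = 48, grid_size = 64, mask = mk), roi)$sd
    }, numeric(1)))
  }
  sds <- vapply(c(1, 0.75, 0.5, 0.25), sd_at, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("calibration finds the fixed point from a nominal start", {
  # small-geometry water calibration: starting at c = 1 stays near 1
  wp <- make_water_phantom(200, 256, 250)
  pr <- scan_protocol(eff_mas = 200)
  m <- calibrate(noise_model(0.0625), wp, pr, seed = 5, n_rep = 6,
                 n_views = 240, n_bins = 300, recon_grid = 128)
  expect_true(attr(m, "converged"))
  expect_lt(abs(m$calib_factor - 1), 0.05)
  expect_lte(attr(m, "iterations"), 20)
  expect_lt(attr(m, "residual"), 0.01 + 1e-9)
})

test_that("calibration rejects an invalid target dose level", {
  wp <- make_water_phantom(48, 64, 64)
  pr <- scan_protocol(eff_mas = 100)
  expect_error(calibrate(noise_model(0.5), wp, pr, target_alpha = 1.5),
               "target_alpha")
})
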