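make_recording <- function(cycle_gradients, n_cycles_per_meas = 3L) {
  n <- length(cycle_gradients)
  meas <- rep(seq_len(ceiling(n / n_cycles_per_meas)),
              each = n_cycles_per_meas)[seq_len(n)]
  cyc <- ((seq_len(n) - 1L) %% n_cycles_per_meas) + 1L
  data.frame(
    measurement = rep(meas, each = 2L), cycle = rep(cyc, each = 2L),
    position = rep(c("inner", "outer"), n),
    voltage_uV = as.vector(rbind(cycle_gradients, 0)))
}

test_that("site gradients average inner-minus-outer over all cycles", {
  expect_equal(site_gradient(make_recording(c(50, 48, 52, 49, 51, 50))), 50)
  expect_equal(site_gradient(make_recording(rep(0, 6))), 0)
  one <- data.frame(measurement = 1, cycle = 1,
                    position = c("inner", "outer"),
                    voltage_uV = c(40, 10))
  expect_equal(site_gradient(one), 30)
  expect_equal(site_gradient(make_recording(c(0, 0, 0, 0, 0, 600)),
                             aggregate = "median"), 0)
  # missing outer sample in a cycle
  broken <- one[1, , drop = FALSE]
  expect_error(site_gradient(broken), "malformed")
})

test_that("reference gradients average across reference recordings", {
  tr <- synthetic_truth(c(ileum = 0), n_sites = c(ileum = 1, rectum = 0),
                        noise_sd_uV = 0, drift_uV_per_min = 0)
  ds <- simulate_scan(tr, default_calibration("K"), seed = 1)
  # overwrite with two hand-built references of gradient -10 and -20
  ref1 <- make_recording(rep(-10, 6)); ref1$site_id <- "r1"
  ref2 <- make_recording(rep(-20, 6)); ref2$site_id <- "r2"
  refs <- rbind(ref1, ref2)
  refs$ordinal <- NA; refs$region_hint <- NA; refs$is_reference <- TRUE
  refs$time_s <- seq_len(nrow(refs))
  tissue <- ds$samples[!ds$samples$is_reference, ]
  tissue$time_s <- nrow(refs) + seq_len(nrow(tissue))
  ds$samples <- rbind(refs[names(tissue)], tissue)
  expect_equal(reference_gradient(ds), -15)
  ds$samples <- tissue
  expect_error(reference_gradient(ds), "no reference")
})

test_that("reference correction is a plain subtraction", {
  expect_equal(correct_gradient(36.3, -13.1), 49.4)  # control K+ means
  expect_equal(correct_gradient(-45.1, -23.1), -22)  # control Na+ means
  expect_equal(correct_gradient(7.3, 0), 7.3)
})

test_that("background concentration supports measured and nominal modes", {
  tr <- synthetic_truth(c(ileum = 0), n_sites = c(ileum = 1, rectum = 0),
                        noise_sd_uV = 0, drift_uV_per_min = 0)
  cal <- default_calibration("K")
  ds <- simulate_scan(tr, cal, selectivity = no_interference("K"),
                      bath = pure_bath("K"), seed = 1)
  expect_equal(background_concentration(ds, "measured"), 3.4)
  expect_equal(background_concentration(ds, "nominal"), 3.4)
  # half the samples at 15 mM-equivalent, half at 150 mM-equivalent
  n <- nrow(ds$samples)
  ds$samples$voltage_uV <- rep(c(electrode_voltage(c(K = 15), cal),
                                 electrode_voltage(c(K = 150), cal)),
                               length.out = n)
  expect_equal(background_concentration(ds, "measured"), 82.5,
               tolerance = 0.02)  # grid may be odd-length
})

test_that("concentration gradients follow the exponential inversion", {
  # frozen oracles from direct evaluation of C_B (10^(dV/S) - 1)
  expect_equal(concentration_gradient(49.4, 3.4, 55600), 6.963e-3,
               tolerance = 1e-4)
  expect_equal(concentration_gradient(-22.0, 20, 59000), -1.7165e-2,
               tolerance = 1e-4)
  expect_equal(concentration_gradient(0, 7, 55600), 0)
  expect_error(concentration_gradient(10, 3.4, 0), "slope")
  expect_error(concentration_gradient(10, -1, 55600), "> 0")
  # strictly increasing in the corrected gradient
  dv <- seq(-300, 300, by = 10)
  dc <- concentration_gradient(dv, 3.4, 55600)
  expect_true(all(diff(dc) > 0))
})

test_that("Fick's-law flux scales correctly in all units", {
  expect_equal(fick_flux(6.963e-3, 1.92e-5, 0.005), 26.7,
               tolerance = 2e-3)
  expect_equal(fick_flux(-1.7165e-2, 1.55e-5, 0.005), -53.2,
               tolerance = 2e-3)
  expect_equal(fick_flux(0, 1.92e-5, 0.005), 0)
  # doubling the excursion halves the flux exactly
  expect_equal(fick_flux(0.01, 1.92e-5, 0.01),
               fick_flux(0.01, 1.92e-5, 0.005) / 2)
  expect_error(fick_flux(0.01, 0, 0.005), "positive")
  expect_error(fick_flux(0.01, 1.92e-5, -1), "positive")
})

test_that("signal:noise reproduces the printed confidence ratios", {
  expect_equal(signal_to_noise(-45.1, -23.1), 1.95, tolerance = 1e-2)
  expect_equal(signal_to_noise(36.3, -13.1), 2.77, tolerance = 1e-2)
  expect_true(is.na(signal_to_noise(10, 0)))
  expect_equal(signal_to_noise(c(10, -10), c(5, 5)), c(2, 2))
})

test_that("noise-free estimates recover truth across the flux range", {
  # inversion consistency, interferent-free: the first-order inversion
  # dC = C_B (10^(dV/S) - 1) carries a relative error of about
  # dC / (2 C_B), so K+ (bath 3.4 mM) is held to 0.5% up to
  # ~120 pmol cm-2 s-1 and to 2% at higher fluxes; Na+ (bath 20 mM) meets
  # 0.5% across the whole range.
  cases <- list(
    list(ion = "Na", fluxes = c(-500, -130, -26.7, -1, 1, 53.2, 500),
         tol = 0.005),
    list(ion = "K", fluxes = c(-120, -26.7, -1, 1, 26.7, 120),
         tol = 0.005),
    list(ion = "K", fluxes = c(-500, 500), tol = 0.02))
  for (cs in cases) {
    cal <- default_calibration(cs$ion)
    for (j in cs$fluxes) {
      tr <- synthetic_truth(c(ileum = j),
                            n_sites = c(ileum = 1, rectum = 0),
                            noise_sd_uV = 0, drift_uV_per_min = 0)
      est <- estimate_fluxes(simulate_scan(
        tr, cal, selectivity = no_interference(cs$ion),
        bath = pure_bath(cs$ion), seed = 1))
      expect_lt(abs(est$flux - j) / abs(j), cs$tol)
      expect_equal(est$direction, if (j > 0) "absorption" else "secretion")
    }
  }
})

test_that("small-signal linearization matches the full inversion within 1%", {
  s <- 55600; c_b <- 3.4; d <- 1.92e-5; dx <- 0.005
  for (dv in c(-50, -5, 5, 50)) {  # |dV/S| < 1e-3
    j_full <- fick_flux(concentration_gradient(dv, c_b, s), d, dx)
    j_lin <- 1e6 * d * c_b * log(10) * dv / (s * dx)
    expect_lt(abs(j_full - j_lin) / abs(j_lin), 0.01)
  }
})

test_that("flux sign follows the corrected gradient and direction labels", {
  s <- 55600
  dv <- c(-40, -1, 0, 1, 40)
  dc <- concentration_gradient(dv, 3.4, s)
  j <- fick_flux(dc, 1.92e-5, 0.005)
  expect_equal(sign(j), sign(dv))
  expect_equal(sign(dc), sign(dv))
  # apical-surface scans flip the transport labels, not the flux values
  tr <- synthetic_truth(c(ileum = 26.7), n_sites = c(ileum = 1, rectum = 0),
                        noise_sd_uV = 0, drift_uV_per_min = 0)
  ds <- simulate_scan(tr, default_calibration("K"), seed = 1)
  basal <- estimate_fluxes(ds, surface = "basal")
  apical <- estimate_fluxes(ds, surface = "apical")
  expect_equal(basal$direction, "absorption")
  expect_equal(apical$direction, "secretion")
  expect_equal(basal$flux, apical$flux)
})

test_that("estimate_fluxes reports errors with preparation context", {
  tr <- synthetic_truth(c(ileum = 10), n_sites = c(ileum = 2, rectum = 0),
                        noise_sd_uV = 0)
  ds <- simulate_scan(tr, default_calibration("K"),
                      preparation_id = "prep-X", seed = 1)
  ds$samples <- ds$samples[!ds$samples$is_reference, ]
  expect_error(estimate_fluxes(ds), "prep-X")
})
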