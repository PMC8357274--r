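flat_stack <- function(k = 0.5, depths = seq(0, 5, 0.5),
                       lam = seq(400, 900, 2)) {
  e0 <- incident_spectrum(lam)
  spectral_stack(lam, depths, outer(e0, exp(-k * depths)))
}

test_that("linear Savitzky-Golay smoothing preserves polynomials of degree <= 1", {
  lam <- seq(400, 700, 2)
  const <- rep(3.2, length(lam))
  expect_equal(smooth_spectrum(const, lam), const)
  line <- 0.5 + 0.003 * lam
  expect_equal(smooth_spectrum(line, lam), line, tolerance = 1e-12)
  # smoothing contracts white noise around a smooth baseline
  set.seed(11)
  smoothv <- sin(lam / 50)
  noisy <- smoothv + rnorm(length(lam), sd = 0.1)
  out <- smooth_spectrum(noisy, lam)
  expect_lt(stats::var(out - smoothv), stats::var(noisy - smoothv))
  expect_error(smooth_spectrum(noisy, lam, window_nm = 1000), "wider")
})

test_that("normalization divides by the interface spectrum and is idempotent", {
  st <- flat_stack(k = 0.7)
  nm <- normalize_stack(st)
  expect_equal(nm$irradiance[, 1], rep(1, length(st$wavelength)))
  nm2 <- normalize_stack(nm)
  expect_equal(nm2$irradiance, nm$irradiance)
  # the surface spectrum cancels: normalized values are exp(-k z)
  expect_equal(nm$irradiance[10, ], exp(-0.7 * st$depth), tolerance = 1e-12)
})

test_that("attenuation spectra recover a pure exponential decay at all wavelengths", {
  st <- flat_stack(k = 0.9)
  att <- attenuation_spectra(st)
  expect_equal(length(att$depth), length(st$depth) - 1)
  expect_true(all(abs(att$attenuation - 0.9) < 1e-10))
})

test_that("pigment-band quantification uses the chord baseline over a 10-nm window", {
  lam <- seq(600, 760, 1)
  depths <- c(0, 1)
  band <- band_definition("chl_a", 674)
  # flat attenuation: chord equals curve, abundance 0
  flat_att <- structure(list(wavelength = lam, depth = 0.5,
                             attenuation = matrix(0.4, length(lam), 1)),
                        class = "attenuation_stack")
  expect_equal(pigment_abundance(flat_att, band)$abundance, 0)
  # spectrally linear attenuation is rejected by the baseline
  lin_att <- structure(list(wavelength = lam, depth = 0.5,
                            attenuation = matrix(0.1 + 0.002 * lam,
                                                 length(lam), 1)),
                       class = "attenuation_stack")
  expect_equal(pigment_abundance(lin_att, band)$abundance, 0)
  # Gaussian band: abundance matches the numerically integrated
  # baseline-subtracted Gaussian within 2 %, and is linear in amplitude
  amp <- 0.8; sig <- 4
  gau <- function(l) amp * exp(-(l - 674)^2 / (2 * sig^2))
  g_att <- structure(list(wavelength = lam, depth = 0.5,
                          attenuation = matrix(0.2 + gau(lam),
                                               length(lam), 1)),
                     class = "attenuation_stack")
  got <- pigment_abundance(g_att, band)$abundance
  lam_w <- seq(669, 679, 0.01)
  chord <- gau(669) + (gau(679) - gau(669)) * (lam_w - 669) / 10
  want <- sum(diff(lam_w) * (head(gau(lam_w) - chord, -1) +
                               tail(gau(lam_w) - chord, -1)) / 2)
  expect_lt(abs(got - want) / want, 0.02)
  g2 <- g_att
  g2$attenuation <- 0.2 + 2 * (g_att$attenuation - 0.2)
  expect_equal(pigment_abundance(g2, band)$abundance, 2 * got,
               tolerance = 1e-10)
  expect_error(pigment_abundance(g_att, band_definition("x", 900)),
               "outside")
})

test_that("channel profiles integrate UV, PAR and NIR and decay with the stack", {
  st <- flat_stack(k = 0.6, lam = seq(200, 950, 1))
  ch <- channel_profiles(st, normalize = TRUE)
  # spectrally flat attenuation: all channels share the same decay curve
  expect_equal(ch$uv, exp(-0.6 * st$depth), tolerance = 1e-12)
  expect_equal(ch$par, exp(-0.6 * st$depth), tolerance = 1e-12)
  expect_equal(ch$nir, exp(-0.6 * st$depth), tolerance = 1e-12)
  # disjoint support: light only in 500-600 nm leaves UV and NIR empty
  lam <- seq(500, 600, 1)
  st2 <- spectral_stack(lam, c(0, 1), matrix(1, length(lam), 2))
  ch2 <- channel_profiles(st2, normalize = FALSE)
  expect_true(all(is.na(ch2$uv)))
  expect_true(all(is.na(ch2$nir)))
  expect_false(any(is.na(ch2$par)))
  # interface values are exactly 1 after normalization
  expect_equal(unlist(ch[ch$depth_mm == 0, c("uv", "par", "nir")]),
               c(uv = 1, par = 1, nir = 1))
})

test_that("attenuation depth inverts an exponential decay in closed form", {
  k <- log(100) / 3.5
  z <- seq(0, 6, 0.4)
  pr <- data.frame(depth_mm = z, par = exp(-k * z))
  expect_equal(attenuation_depth(pr, 1.0), 0)
  expect_equal(attenuation_depth(pr, 0.01), 3.5, tolerance = 1e-9)
  # monotone: smaller fraction, greater or equal depth
  fr <- c(0.5, 0.1, 0.05, 0.01, 0.001)
  d <- vapply(fr, function(f) attenuation_depth(pr, f), numeric(1))
  expect_true(all(diff(d) >= 0))
  # never reached: documented +Inf sentinel
  expect_identical(attenuation_depth(pr, 1e-9), Inf)
  expect_error(attenuation_depth(pr, 0), "fraction")
})
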