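ctx_sample <- function(a, A = 200 - a, t = 23400, phi = 0.35, so4 = 300,
                       top = 0, bottom = 3.2, blank = FALSE) {
  tracer_samples("c1", top, bottom, 0.125 * (bottom - top), a, A, so4, phi,
                 t, is_blank = blank)
}

test_that("the radiotracer rate equation evaluates as the hand calculation", {
  # a/(a+A) = 1e-3 with the canonical context
  s <- ctx_sample(a = 0.2, A = 199.8)
  got <- compute_srr(s)$rate
  expect_equal(got, 300 * 0.35 * 1e-3 * 1.06 / 23400)
  expect_equal(got, 4.756410256e-06, tolerance = 1e-9)
  # zero TRIS activity: zero rate
  expect_equal(compute_srr(ctx_sample(a = 0))$rate, 0)
  # scaling: doubling t halves; doubling a (a << A) doubles within 0.1 %
  expect_equal(compute_srr(ctx_sample(a = 0.2, t = 46800))$rate, got / 2)
  r2 <- compute_srr(ctx_sample(a = 0.4, A = 199.8))$rate
  expect_lt(abs(r2 - 2 * got) / (2 * got), 1e-3)
  # homogeneity in sulfate and porosity
  expect_equal(compute_srr(ctx_sample(a = 0.2, so4 = 600))$rate, 2 * got)
  expect_equal(compute_srr(ctx_sample(a = 0.2, phi = 0.7))$rate, 2 * got)
  # blanks are rejected
  expect_error(compute_srr(ctx_sample(a = 0.2, blank = TRUE)),
               "detection_limit")
})

test_that("the detection limit is the blank mean plus three standard deviations", {
  # zero apparent TRIS activity: MDL 0
  zero_blanks <- ctx_sample(a = c(0, 0, 0), A = 200, blank = TRUE)
  expect_equal(detection_limit(zero_blanks), 0)
  # blanks constructed so mean + 3 sd of apparent rates is 5e-8 exactly:
  # rate_i = k * f_i with k = 300 * 0.35 * 1.06 / 23400; choose f mean m
  # and sd s so k * (m + 3 s) = 5e-8
  k <- 300 * 0.35 * 1.06 / 23400
  f <- c(8e-6, 9e-6, 10e-6)
  m <- mean(f); s <- stats::sd(f)
  target <- k * (m + 3 * s)
  # a = 200 f, A = 200 (1 - f) so a/(a+A) = f exactly
  blanks <- ctx_sample(a = 200 * f, A = 200 * (1 - f), blank = TRUE)
  got <- detection_limit(blanks)
  expect_equal(got, target, tolerance = 1e-12)
  expect_equal(got, 5e-8, tolerance = 0.2) # same order as a typical MDL
  # permutation invariance
  perm <- ctx_sample(a = 200 * f[c(3, 1, 2)], A = 200 * (1 - f[c(3, 1, 2)]),
                     blank = TRUE)
  expect_equal(detection_limit(perm), got)
  expect_error(detection_limit(blanks[1, ]), "at least 2")
})

test_that("censoring flags rates below the MDL and keeps their values", {
  res <- compute_srr(ctx_sample(a = c(0.001, 0.2, 0.5),
                                A = c(199.999, 199.8, 199.5),
                                top = c(0, 3.2, 11.2),
                                bottom = c(3.2, 11.2, 19.2)))
  mdl <- 1e-6
  cen <- censor_rates(res, mdl)
  expect_equal(cen$below_mdl, res$rate < mdl)
  expect_equal(attr(cen, "n_below_mdl"), sum(res$rate < mdl))
  expect_equal(cen$rate, res$rate) # values retained, not zeroed
  expect_true(all(censor_rates(res, Inf)$below_mdl))
  expect_false(any(censor_rates(res, 0)$below_mdl))
})

test_that("depth aggregation is a volume-weighted mean with tiling validation", {
  mk <- function(rates, edges = c(0, 3.2, 11.2, 19.2, 27.2, 30)) {
    n <- length(rates)
    structure(data.frame(core_id = "c1", section_top = edges[-(n + 1)],
                         section_bottom = edges[-1],
                         depth_mid = (edges[-1] + edges[-(n + 1)]) / 2,
                         rate = rates, below_mdl = NA),
              class = c("srr_results", "data.frame"))
  }
  # uniform rate: both averages equal it
  agg <- depth_aggregate(mk(rep(2e-6, 5)), mat_bottom = 6)
  expect_equal(agg$mat_avg, 2e-6)
  expect_equal(agg$horizon_avg, 2e-6)
  # hand-computed weighted mean over two sections
  two <- mk(c(0, 3e-6), edges = c(0, 3.2, 11.2))
  agg2 <- depth_aggregate(two, mat_bottom = 11.2, horizon = 11.2)
  expect_equal(agg2$horizon_avg, (0 * 3.2 + 3e-6 * 8) / 11.2)
  # areal consistency: horizon_avg * 0.03 m equals the exact integral of
  # the sectionwise-constant profile
  r5 <- c(0.5, 4.4, 2.6, 1.4, 0.9) * 1e-6
  agg3 <- depth_aggregate(mk(r5), mat_bottom = 6)
  integral <- sum(r5 * diff(c(0, 3.2, 11.2, 19.2, 27.2, 30)) / 1000)
  expect_equal(agg3$horizon_avg * 0.03, integral, tolerance = 1e-12)
  # splitting a section leaves the averages unchanged
  split <- mk(c(0.5, 4.4, 4.4, 2.6, 1.4, 0.9) * 1e-6,
              edges = c(0, 3.2, 7, 11.2, 19.2, 27.2, 30))
  agg4 <- depth_aggregate(split, mat_bottom = 6)
  expect_equal(agg4$mat_avg, agg3$mat_avg)
  expect_equal(agg4$horizon_avg, agg3$horizon_avg)
  # gaps are rejected, naming the offender
  gap <- mk(c(1e-6, 1e-6), edges = c(0, 3.2, 11.2))
  gap$section_top[2] <- 4
  expect_error(depth_aggregate(gap, mat_bottom = 6, horizon = 11.2),
               "tile")
})

test_that("tracer core generation inverts compute_srr exactly at zero noise", {
  sc <- example_scenario(noise = "none")
  cores <- generate_tracer_cores(sc, n_replicates = 2)
  res <- compute_srr(cores)
  truth <- rep(sc$srr_truth$rate, 2)
  expect_equal(res$rate, truth, tolerance = 1e-12)
  # single-section inversion round trip for rate 1e-6
  one <- rate_profile(1.6, 1.0e-6, interval_edges = c(0, 3.2))
  core1 <- generate_tracer_cores(sc, true_srr = one, n_replicates = 1)
  expect_equal(compute_srr(core1)$rate, 1.0e-6, tolerance = 1e-12)
  # zero rate gives zero activities
  zero <- rate_profile(1.6, 0, interval_edges = c(0, 3.2))
  expect_equal(generate_tracer_cores(sc, true_srr = zero,
                                     n_replicates = 1)$tris_kBq, 0)
  # tracer exhaustion is unphysical
  huge <- rate_profile(1.6, 1, interval_edges = c(0, 3.2))
  expect_error(generate_tracer_cores(sc, true_srr = huge), "exhaustion")
})

test_that("tracer noise honours the seed contract", {
  sc <- example_scenario(seed = 5) # default noise includes activity_sdlog
  a <- generate_tracer_cores(sc)
  b <- generate_tracer_cores(sc)
  expect_identical(a$tris_kBq, b$tris_kBq)
  c2 <- generate_tracer_cores(example_scenario(seed = 6))
  expect_false(identical(a$tris_kBq, c2$tris_kBq))
  # noisy activities still sum to the injected tracer
  expect_equal(a$tris_kBq + a$sulfate_residual_kBq,
               rep(200, nrow(a)))
})
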