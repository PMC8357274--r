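test_that("total-sulfur diffusivity is 0.64 of the oxygen diffusivity", {
  expect_equal(stot_diffusivity(1.5e-9), 9.6e-10)
  expect_equal(signif(stot_diffusivity(1.5e-9), 1), 1e-9)
  expect_equal(stot_diffusivity(1), 0.64)
  expect_equal(stot_diffusivity(2 * 1.5e-9), 2 * stot_diffusivity(1.5e-9))
  expect_error(stot_diffusivity(0), "> 0")
})

test_that("sulfide speciation follows the first dissociation equilibrium", {
  z <- seq(0, 5, 0.5)
  h2s <- depth_profile(z, rep(0.1, length(z)), quantity = "H2S")
  # at pH = pK1, half dissociated: Stot = 2 * H2S exactly
  ph7 <- depth_profile(z, rep(7, length(z)), quantity = "pH")
  expect_equal(total_sulfide(h2s, ph7, pk1 = 7)$value, rep(0.2, length(z)))
  # acid limit: Stot ~ H2S within 0.01 %
  ph3 <- depth_profile(z, rep(3, length(z)), quantity = "pH")
  expect_equal(total_sulfide(h2s, ph3, pk1 = 7)$value, rep(0.1, length(z)),
               tolerance = 1e-4)
  # zero sulfide stays zero at any pH
  zero <- depth_profile(z, rep(0, length(z)), quantity = "H2S")
  ph9 <- depth_profile(z, rep(9, length(z)), quantity = "pH")
  expect_equal(total_sulfide(zero, ph9)$value, rep(0, length(z)))
  # mismatched grids error without interpolation, work with it
  ph_off <- depth_profile(z + 0.25, rep(7, length(z)), quantity = "pH")
  expect_error(total_sulfide(h2s, ph_off), "interpolate")
  st <- total_sulfide(h2s, ph_off, pk1 = 7, interpolate = TRUE)
  expect_true(all(abs(st$value - 0.2) < 1e-12))
})

test_that("diffusive flux reproduces Fick's first law", {
  spec <- diffusion_spec("O2", 1.5e-9, porosity = 0.3)
  z <- seq(0, 2, 0.25)
  # uniform concentration: no flux
  flat <- depth_profile(z, rep(0.2, length(z)))
  expect_equal(diffusive_flux(flat, spec)$flux, rep(0, length(z) - 1))
  # linear profile with slope -1000 mol m-3 per m: J = phi * D0 * 1000
  lin <- depth_profile(z, 0.25 - 1000 * (z / 1000))
  expect_equal(diffusive_flux(lin, spec)$flux,
               rep(0.3 * 1.5e-9 * 1000, length(z) - 1), tolerance = 1e-12)
  expect_equal(0.3 * 1.5e-9 * 1000, 4.5e-7) # hand value
  # flux of the solver's parabola is linear and matches the analytic derivative
  phi <- 0.5; d_eff <- phi * 1.5e-9; r <- 1e-4; L <- 5e-3; c0 <- 0.3
  zz <- seq(0, 5, 0.05)
  para <- depth_profile(zz, c0 - (r / (2 * d_eff)) * (2 * L * (zz / 1000) - (zz / 1000)^2))
  fl <- diffusive_flux(para, diffusion_spec("O2", 1.5e-9, 0.5))
  exact <- r * (L - fl$depth_mm / 1000)
  expect_lt(max(abs(fl$flux - exact)) / max(abs(exact)), 1e-3)
  # errors
  expect_error(diffusive_flux(depth_profile(0, 0.1), spec), "2 depth points")
})

test_that("local rates are the discrete flux divergence", {
  spec <- diffusion_spec("O2", 1.5e-9, 0.5)
  d_eff <- effective_diffusivity(spec)
  z <- seq(0, 5, 0.05)
  # constant flux -> zero rates
  lin <- depth_profile(z, 0.3 - 0.01 * z)
  r0 <- local_rates(diffusive_flux(lin, spec))
  expect_lt(max(abs(r0$rate)), 1e-15)
  # C = a z^2 -> uniform rate -2 a D_eff (consumption)
  a <- 5e3 # mol m-3 per m^2
  quad <- depth_profile(z, 0.05 + a * (z / 1000)^2)
  rr <- local_rates(diffusive_flux(quad, spec))
  expect_equal(rr$rate, rep(-2 * a * d_eff, nrow(rr)), tolerance = 1e-6)
  # a two-point profile yields one flux value: too few for a divergence
  two <- depth_profile(c(0, 1), c(0.3, 0.2))
  expect_error(local_rates(diffusive_flux(two, spec)), "2 flux points")
})

test_that("three-layer round trip recovers the layer rates and sign pattern", {
  true_rates <- c(-8e-5, 1.5e-4, -6e-5)
  bounds <- c(0, 2, 4, 6)
  sc <- mat_scenario(
    bounds, rates = list(X = true_rates), diffusivity = list(X = 1.5e-9),
    porosity = 0.3,
    boundary_conditions = list(
      X = list(top = list(type = "concentration", value = 0.3),
               bottom = list(type = "concentration", value = 0.1))))
  p <- suppressWarnings(solve_steady_state(sc, "X", grid_step = 0.05))
  rec <- local_rates(diffusive_flux(p, diffusion_spec("X", 1.5e-9, 0.3)))
  for (i in 1:3) {
    core <- rec$depth_mm > bounds[i] + 0.1 & rec$depth_mm < bounds[i + 1] - 0.1
    lm_rate <- mean(rec$rate[core])
    expect_equal(sign(lm_rate), sign(true_rates[i]))
    expect_lt(abs(lm_rate - true_rates[i]) / abs(true_rates[i]), 0.05)
  }
})

test_that("areal rates integrate exactly and telescope to the boundary fluxes", {
  # uniform production R over thickness L: R * L exactly
  edges <- seq(0, 3, 0.5)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  r <- rate_profile(mids, rep(2e-5, length(mids)), interval_edges = edges)
  expect_equal(areal_rate(r), 2e-5 * 3e-3)
  expect_equal(areal_rate(rate_profile(mids, rep(0, length(mids)),
                                       interval_edges = edges)), 0)
  # conservation: net areal rate equals the boundary-flux difference
  sc <- random_scenario(3)
  p <- suppressWarnings(solve_steady_state(sc, "X", 0.05))
  fl <- diffusive_flux(p, diffusion_spec("X", 1.5e-9, 0.3))
  rr <- local_rates(fl)
  net <- areal_rate(rr)
  dj <- fl$flux[nrow(fl)] - fl$flux[1]
  expect_lt(abs(net - dj) / max(abs(dj), 1e-30), 1e-10)
  # ... and over arbitrary aligned subintervals (telescoping identity)
  i <- 5; j <- 40
  sub <- areal_rate(rr, zone = c(fl$depth_mm[i], fl$depth_mm[j]))
  expect_lt(abs(sub - (fl$flux[j] - fl$flux[i])) /
              max(abs(fl$flux[j] - fl$flux[i]), 1e-30), 1e-10)
  # sign selection: production and consumption partition the net
  expect_equal(areal_rate(rr, sign = "production") -
                 areal_rate(rr, sign = "consumption"), net, tolerance = 1e-12)
  expect_error(areal_rate(rr, zone = c(2, 2)), "empty zone")
})

test_that("oxic-masked volumetric average honours the oxygen mask", {
  edges <- seq(0, 4, 0.5)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  z <- seq(0, 4, 0.25)
  # O2 > 0 everywhere: mean of a uniform rate is that rate
  o2 <- depth_profile(z, rep(0.1, length(z)))
  r_uni <- rate_profile(mids, rep(3e-5, length(mids)), interval_edges = edges)
  expect_equal(avg_volumetric(r_uni, o2), 3e-5)
  # rate arbitrary in the anoxic half is excluded by the mask
  o2_half <- depth_profile(z, ifelse(z < 2, 0.1, 0))
  r_mix <- rate_profile(mids, ifelse(mids < 2, 3e-5, 999), interval_edges = edges)
  expect_equal(avg_volumetric(r_mix, o2_half), 3e-5)
  # hand-computed weighted mean with unequal intervals
  edges2 <- c(0, 1, 3)
  r2 <- rate_profile(c(0.5, 2), c(1e-5, 4e-5), interval_edges = edges2)
  o2_all <- depth_profile(c(0, 3), c(0.1, 0.1))
  expect_equal(avg_volumetric(r2, o2_all), (1e-5 * 1 + 4e-5 * 2) / 3)
  expect_error(avg_volumetric(r_uni, depth_profile(z, rep(0, length(z)))),
               "no depth satisfies")
})

test_that("interfacial sulfide flux follows Fick's law on the sub-oxic gradient", {
  spec <- diffusion_spec("Stot", stot_diffusivity(1.5e-9), 0.3)
  z <- seq(0, 6, 0.1)
  g <- 50 # mol m-3 per m
  stot <- depth_profile(z, pmax(0, (z - 2) / 1000 * g), quantity = "Stot")
  fl <- interfacial_sulfide_flux(stot, spec, oxic_lower_bound = 2.5)
  expect_equal(as.numeric(fl), effective_diffusivity(spec) * g,
               tolerance = 1e-10)
  expect_equal(attr(fl, "direction"), "upward")
  flat <- depth_profile(z, rep(0.2, length(z)), quantity = "Stot")
  expect_equal(as.numeric(interfacial_sulfide_flux(flat, spec, 2.5)), 0)
  expect_error(interfacial_sulfide_flux(stot, spec, 5.95, window_mm = 0.01),
               "fewer than 2")
})

test_that("pools are trapezoidal means or integrals over the zone", {
  z <- seq(0, 5, 0.25)
  uni <- depth_profile(z, rep(0.2, length(z)), quantity = "Stot")
  expect_equal(pool(uni, mode = "depth_averaged"), 0.2)
  expect_equal(pool(uni, mode = "depth_integrated"), 0.2 * 5e-3)
  lin <- depth_profile(z, 0.4 * z / 5, quantity = "Stot")
  expect_equal(pool(lin, mode = "depth_averaged"), 0.2)
  expect_equal(pool(depth_profile(z, rep(0, length(z)))), 0)
})

test_that("turnover time and fold changes reproduce the worked budget numbers", {
  tt <- turnover_time(0.2, 2.4e-6)
  expect_equal(tt, 0.2 / 2.4e-6)
  expect_equal(round(turnover_days(tt), 2), 0.96)
  expect_equal(round(turnover_days(tt)), 1)
  expect_equal(turnover_time(0, 1e-6), 0)
  expect_equal(turnover_time(0.2, 2 * 2.4e-6), tt / 2)
  expect_error(turnover_time(0.2, 0), "rate <= 0")
  expect_equal(fold_format(fold_change(1.9e-7, 2.1e-8)), "9-fold")
  expect_equal(fold_format(fold_change(1.1e-6, 6.2e-8)), "18-fold")
  expect_equal(fold_change(3.3, 3.3), 1)
  expect_error(fold_change(1, 0), "denominator")
})

test_that("the whole inversion chain is linear in the concentration scale", {
  sc <- random_scenario(3)
  p <- suppressWarnings(solve_steady_state(sc, "X", 0.1))
  spec <- diffusion_spec("X", 1.5e-9, 0.3)
  c_scale <- 3.7
  p2 <- depth_profile(p$depth_mm, p$value * c_scale)
  f1 <- diffusive_flux(p, spec); f2 <- diffusive_flux(p2, spec)
  expect_equal(f2$flux, c_scale * f1$flux)
  r1 <- local_rates(f1); r2 <- local_rates(f2)
  expect_equal(r2$rate, c_scale * r1$rate)
  expect_equal(areal_rate(r2), c_scale * areal_rate(r1))
  expect_equal(pool(p2), c_scale * pool(p))
})

test_that("halving the grid step changes recovered layer means by under 1 %", {
  sc <- mat_scenario(
    c(0, 2, 4, 6), rates = list(X = c(-8e-5, 1.5e-4, -6e-5)),
    diffusivity = list(X = 1.5e-9), porosity = 0.3,
    boundary_conditions = list(
      X = list(top = list(type = "concentration", value = 0.3),
               bottom = list(type = "concentration", value = 0.1))))
  layer_means <- function(step) {
    p <- suppressWarnings(solve_steady_state(sc, "X", step))
    rec <- local_rates(diffusive_flux(p, diffusion_spec("X", 1.5e-9, 0.3)))
    vapply(1:3, function(i) {
      core <- rec$depth_mm > sc$layer_boundaries[i] + 0.2 &
        rec$depth_mm < sc$layer_boundaries[i + 1] - 0.2
      mean(rec$rate[core])
    }, numeric(1))
  }
  m1 <- layer_means(0.05); m2 <- layer_means(0.025)
  expect_true(all(abs(m2 - m1) / abs(m1) < 0.01))
})
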