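# Independent analytic oracle for the steady-state reaction-diffusion
# problem with piecewise-constant rates: on each layer the solution is a
# quadratic C_i(z) = -(R_i / 2D) z^2 + a_i z + c_i; the 2n coefficients
# are found by matching concentration and flux at the n-1 interfaces plus
# the two boundary conditions, via a dense linear solve. This shares no
# code with the package's finite-volume solver.
analytic_piecewise_solution <- function(bounds_mm, rates, d_eff,
                                        bc_top, bc_bottom) {
  b <- bounds_mm / 1000 # m
  n <- length(rates)
  A <- matrix(0, 2 * n, 2 * n)
  rhs <- numeric(2 * n)
  row <- 0
  # particular part and derivatives of layer i at z
  cp <- function(i, z) -(rates[i] / (2 * d_eff)) * z^2
  cp1 <- function(i, z) -(rates[i] / d_eff) * z
  # interface continuity: C and dC/dz
  for (i in seq_len(n - 1)) {
    z <- b[i + 1]
    row <- row + 1
    A[row, 2 * i - 1] <- z; A[row, 2 * i] <- 1
    A[row, 2 * i + 1] <- -z; A[row, 2 * i + 2] <- -1
    rhs[row] <- cp(i + 1, z) - cp(i, z)
    row <- row + 1
    A[row, 2 * i - 1] <- 1; A[row, 2 * i + 1] <- -1
    rhs[row] <- cp1(i + 1, z) - cp1(i, z)
  }
  # top boundary at b[1]
  row <- row + 1
  if (bc_top$type == "concentration") {
    A[row, 1] <- b[1]; A[row, 2] <- 1
    rhs[row] <- bc_top$value - cp(1, b[1])
  } else {
    A[row, 1] <- 1
    rhs[row] <- -cp1(1, b[1])
  }
  # bottom boundary at b[n + 1]
  row <- row + 1
  z <- b[n + 1]
  if (bc_bottom$type == "concentration") {
    A[row, 2 * n - 1] <- z; A[row, 2 * n] <- 1
    rhs[row] <- bc_bottom$value - cp(n, z)
  } else {
    A[row, 2 * n - 1] <- 1
    rhs[row] <- -cp1(n, z)
  }
  coef <- solve(A, rhs)
  function(z_mm) {
    z <- z_mm / 1000
    layer <- pmin(pmax(findInterval(z, b, rightmost.closed = TRUE), 1), n)
    vapply(seq_along(z), function(k) {
      i <- layer[k]
      cp(i, z[k]) + coef[2 * i - 1] * z[k] + coef[2 * i]
    }, numeric(1))
  }
}

# random multi-layer scenario for property suites
random_scenario <- function(n_layers = sample(1:5, 1),
                            bottom_fixed = runif(1) < 0.5) {
  bounds <- c(0, sort(runif(n_layers - 1, 0.5, 5.5)), 6)
  if (n_layers == 1) bounds <- c(0, 6)
  # metabolically realistic magnitudes (1e-5..2e-4 mol m-3 s-1), random sign
  rates <- sample(c(-1, 1), n_layers, replace = TRUE) *
    runif(n_layers, 2e-5, 2e-4)
  bc_bottom <- if (bottom_fixed) {
    list(type = "concentration", value = runif(1, 0, 0.3))
  } else {
    list(type = "zero_flux")
  }
  mat_scenario(
    layer_boundaries = bounds,
    rates = list(X = rates),
    diffusivity = list(X = 1.5e-9),
    porosity = 0.3,
    boundary_conditions = list(
      X = list(top = list(type = "concentration", value = runif(1, 0.1, 0.5)),
               bottom = bc_bottom)),
    noise_sd = list(concentration = 0, irradiance = 0, activity_sdlog = 0),
    seed = 1L)
}

expect_profile_positive <- function(p) {
  expect_true(all(p$value >= -1e-12))
}
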