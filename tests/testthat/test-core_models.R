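test_that("presets match the published parameter sets and validate", {
  p <- toggle_preset("reference")
  expect_equal(unlist(p[c("a1", "a2", "a3", "a4", "a5", "a6")]),
               c(a1 = 20, a2 = 20, a3 = 10, a4 = 10, a5 = 3, a6 = 3))
  expect_equal(unlist(p[c("nX", "nY", "nG", "nR")]),
               c(nX = 3, nY = 3, nG = 3, nR = 3))
  expect_true(all(unlist(p[c("gamma_x", "gamma_y", "gamma_g", "gamma_r")]) == 0))
  expect_equal(c(p$delta_g, p$delta_r, p$delta_e, p$rho), c(1, 1, 0.5, 0.8))

  m <- toggle_preset("modified")
  expect_equal(c(m$a1, m$a2), c(100, 100))
  expect_equal(c(m$nX, m$nY, m$nG, m$nR), c(2, 2, 1, 2))
  expect_true(all(unlist(m[c("gamma_x", "gamma_y", "gamma_g", "gamma_r")]) == 0.01))
  # untouched fields inherit the reference values
  expect_equal(c(m$a3, m$a5, m$delta_e), c(10, 3, 0.5))

  expect_error(toggle_params(delta_g = 0), "delta_g")
  expect_error(toggle_params(nX = 0.5), "Hill")
  expect_error(toggle_params(rho = 1.2), "rho")
  expect_error(toggle_preset("reference", bogus = 1), "unknown")
})

test_that("vector fields at the origin follow the leakiness-free limits", {
  p <- toggle_preset("reference")
  sS <- population_spec("S", 1)
  expect_equal(unname(s_rhs(rep(0, 6), p, sS)), c(20, 20, 3, 3, 0, 0))
  sA <- population_spec("A", 1)
  expect_equal(unname(a_rhs(rep(0, 4), p, sA)), c(20, 20, 3, 0))
  # repression saturation: huge y shuts the a1 term down
  z <- c(0, 1e3, 0, 0)
  expect_equal(a_rhs(z, toggle_params(), sA)[[1]], 20 / (1 + 1e9),
               tolerance = 1e-12)
  # dimension guards
  expect_error(s_rhs(rep(0, 5), p, sS), "length")
  expect_error(s_rhs(rep(0, 6), p, population_spec("A", 1)), "model")
})

test_that("single-toggle equilibria match the fixed-point oracles", {
  p <- toggle_preset("reference", d = 0)
  # oracle values, frozen: S G-state and A G-state at the reference set
  oS <- oracle_s_single(p)
  expect_equal(unname(oS), c(29.643, 7.678e-4, 3.000, 1.152e-4),
               tolerance = 1e-3)
  sS <- population_spec("S", 1)
  eq <- find_equilibrium(c(oS, 0, 0), p, sS)
  expect_lt(eq$residual_norm, 1e-10)
  expect_equal(unname(eq$state[1:4]), unname(oS), tolerance = 1e-7)
  expect_true(eq$stable)

  oA <- oracle_a_single(p)
  expect_equal(unname(oA), c(20.000, 2.4997e-3, 3.750e-4), tolerance = 1e-3)
  sA <- population_spec("A", 1)
  eqA <- find_equilibrium(c(oA, 0), p, sA)
  expect_lt(eqA$residual_norm, 1e-10)
  expect_equal(unname(eqA$state[1:3]), unname(oA), tolerance = 1e-7)
})

test_that("mirror map is an involution and an equivariance of the S field", {
  p <- toggle_preset("reference")
  spec <- population_spec("S", 3)
  for (seed in 1:20) {
    z <- rand_state(spec, seed)
    mz <- mirror_map(z, spec)
    expect_equal(unname(mirror_map(mz, spec)), unname(z))
    expect_equal(unname(s_rhs(mz, p, spec)),
                 unname(mirror_map(s_rhs(z, p, spec), spec)))
  }
  expect_error(mirror_map(rep(0, 4), population_spec("A", 1)), "S model")
  # parameter swap: reference is a fixed point, modified is not
  expect_true(is_mirror_symmetric(toggle_preset("reference")))
  res <- mirror_map(rand_state(spec, 1), spec, toggle_preset("modified"))
  expect_true("nG/nR" %in% res$asymmetry)
  expect_false(is_mirror_symmetric(toggle_preset("modified")))
  expect_equal(mirror_params(mirror_params(p)), p)
})

test_that("analytic Jacobians agree with finite differences", {
  skip_if_not_installed("numDeriv")
  p <- toggle_preset("modified", d = 0.7)   # asymmetric, leaky: worst case
  cases <- list(list("S", c(2, 1)), list("A", 3))
  for (cs in cases) {
    spec <- population_spec(cs[[1]], cs[[2]])
    for (seed in 1:8) {
      z <- rand_state(spec, 100 + seed, lo = 1e-2, hi = 30)
      J <- toggle_jacobian(z, p, spec)
      Jfd <- numDeriv::jacobian(function(u) toggle_rhs(u, p, spec), z)
      expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
    }
  }
  # dimensions: S with N = 10 is a 42-dimensional system
  s10 <- population_spec("S", 10)
  expect_identical(s10$n_state, 42L)
  expect_equal(dim(toggle_jacobian(rand_state(s10, 1), p, s10)), c(42, 42))
})

test_that("flow preserves the non-negative orthant and the bounding box", {
  p <- toggle_preset("reference", d = 0.5)
  for (model in c("S", "A")) {
    spec <- population_spec(model, 2)
    for (seed in 1:25) {
      z <- rand_state(spec, 200 + seed, lo = 1e-2, hi = 10)
      kill <- seq(seed %% spec$n_state + 1)   # zero out a leading subset
      z[kill] <- 0
      f <- toggle_rhs(z, p, spec)
      expect_true(all(f[kill] >= 0))
    }
  }
  # boundedness: trajectories started inside the box stay inside
  spec <- population_spec("S", 2)
  top <- c(p$gamma_x + p$a1 + p$a3, p$gamma_y + p$a2 + p$a4,
           (p$gamma_g + p$a5) / p$delta_g + 20, (p$gamma_r + p$a6) / p$delta_r + 20)
  box_hi <- population_state(spec, matrix(top, 1), c(50, 50))
  sol <- integrate_toggles(rand_state(spec, 9, hi = 10), p, spec, times = 50,
                           stop_at_equilibrium = FALSE)
  expect_true(all(sol$states >= -1e-9))
  expect_true(all(sweep(sol$states, 2, box_hi, `<=`)))
})

test_that("cell relabelling within a subpopulation is an equivariance", {
  p <- toggle_preset("reference", d = 1)
  spec <- population_spec("S", c(2, 2))
  z <- rand_state(spec, 5)
  swap <- function(u, i, j) {      # swap cells i and j (both in subpop 1)
    bi <- (i - 1) * 4 + 1:4; bj <- (j - 1) * 4 + 1:4
    v <- u; v[bi] <- u[bj]; v[bj] <- u[bi]; v
  }
  expect_equal(unname(s_rhs(swap(z, 1, 2), p, spec)),
               unname(swap(s_rhs(z, p, spec), 1, 2)))
})

test_that("nondimensionalization reproduces the scaling formulas", {
  ones <- as.list(rep(1, 25))
  names(ones) <- c("b_x", "b_y", "b_u", "b_w", "k_x", "k_y", "k_u", "k_w",
                   "k_G", "k_R", "P_X", "P_Y", "P_G", "P_R",
                   "K_X", "K_Y", "K_G", "K_R", "D_G", "D_R",
                   "r_d", "r_G", "r_R", "mu", "mu_e")
  dm <- do.call(dimensional_params, ones)
  p <- nondimensionalize(dm)
  expect_equal(c(p$a1, p$a5, p$delta_g, p$delta_e), c(1/2, 1/4, 1, 1/2))
  # doubling (r_d + mu) quarters a5, a6 and halves a1..a4
  ones2 <- ones; ones2$r_d <- 3
  p2 <- nondimensionalize(do.call(dimensional_params, ones2))
  expect_equal(p2$a1 / p$a1, 1/2)
  expect_equal(p2$a5 / p$a5, 1/4)
  expect_equal(p2$a6 / p$a6, 1/4)
  # delta_g = 1 iff r_G = r_d
  expect_equal(p$delta_g, 1)
  expect_error(dimensional_params(), "missing")
})

test_that("parameter presets round-trip through JSON and YAML", {
  p <- toggle_preset("modified", d = 2.5)
  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    expect_equal(read_params(f), p)
    unlink(f)
  }
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a1 = 3, nonsense = 1), f, auto_unbox = TRUE)
  expect_error(read_params(f), "unknown key")
  unlink(f)
})

test_that("state vectors round-trip through CSV", {
  for (model in c("S", "A")) {
    spec <- population_spec(model, c(2, 1))
    z <- rand_state(spec, 3)
    names(z) <- state_names(spec)
    f <- tempfile(fileext = ".csv")
    write_state_csv(z, spec, f)
    expect_equal(read_state_csv(f, spec), z)
    unlink(f)
  }
})
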