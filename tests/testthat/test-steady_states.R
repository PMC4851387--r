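test_that("Newton finds, refines and classifies the basic equilibria", {
  p <- toggle_preset("reference", d = 0)
  spec <- population_spec("S", 1)
  eq <- find_equilibrium(c(30, 0, 3, 0, 0, 0), p, spec)
  expect_lt(eq$residual_norm, 1e-10)
  expect_equal(unname(eq$state[1:4]), unname(oracle_s_single(p)),
               tolerance = 1e-7)
  expect_true(eq$stable)
  expect_identical(eq$signature$labels, "G")
  # mirrored guess lands exactly on the sigma-image
  eqR <- find_equilibrium(mirror_map(eq$state, spec), p, spec)
  expect_equal(unname(eqR$state), unname(mirror_map(eq$state, spec)),
               tolerance = 1e-8)
  expect_identical(eqR$signature$labels, "R")
  # spectra of sigma-paired equilibria coincide
  expect_equal(sort(Re(eqR$eigenvalues)), sort(Re(eq$eigenvalues)),
               tolerance = 1e-8)
  # the interior saddle lies on the mirror-fixed subspace and is unstable
  sym <- single_toggle_equilibria(p, "S")
  sad <- sym[!sym$stable, ]
  expect_identical(nrow(sad), 1L)
  expect_equal(sad$x, sad$y, tolerance = 1e-9)
  eqS <- find_equilibrium(c(sad$x, sad$y, sad$g, sad$r, 0, 0), p, spec)
  expect_false(eqS$stable)
  expect_gt(max(Re(eqS$eigenvalues)), 0)
  # non-convergence carries the last iterate
  err <- tryCatch(find_equilibrium(c(30, 0, 3, 0, 0, 0), p, spec,
                                   max_iter = 1, tol = 1e-14),
                  error = identity)
  expect_s3_class(err, "qstoggle_no_convergence")
  expect_length(err$last_iterate, 6)
})

test_that("classify_stability separates stable, marginal and unstable", {
  expect_identical(classify_stability(c(-1, -2))$verdict, "stable")
  expect_identical(classify_stability(c(-1, 1e-9))$verdict, "marginal")
  expect_identical(classify_stability(c(-1, 0.1))$verdict, "unstable")
  expect_identical(classify_stability(complex(real = c(-2, -1),
                                              imaginary = c(3, -3)))$verdict,
                   "stable")
  expect_equal(classify_stability(c(-3, 0.2, 0.5))$n_unstable, 2)
})

test_that("multistart enumeration finds the known equilibrium sets", {
  p <- toggle_preset("reference", d = 0)
  spec <- population_spec("S", 1)
  eqs <- enumerate_equilibria(p, spec, seed = 11)
  expect_identical(sum(vapply(eqs, `[[`, logical(1), "stable")), 2L)
  expect_identical(length(eqs), 3L)
  # denser multistart finds the identical set (completeness)
  eqs2 <- enumerate_equilibria(p, spec, n_lattice = 10, n_random = 200,
                               seed = 12)
  expect_identical(length(eqs2), 3L)
  key <- function(es) sort(vapply(es, function(e) round(e$state[1], 5),
                                  numeric(1)))
  expect_equal(key(eqs2), key(eqs))
  # reduced S_R design (a1 = a2 = 0): bistability persists
  p0 <- toggle_preset("reference", d = 0); p0$a1 <- 0; p0$a2 <- 0
  eqs0 <- enumerate_equilibria(p0, spec, seed = 13)
  expect_identical(sum(vapply(eqs0, `[[`, logical(1), "stable")), 2L)
  # A toggle at reference: bistable as well
  specA <- population_spec("A", 1)
  eqsA <- enumerate_equilibria(p, specA, seed = 14)
  expect_identical(sum(vapply(eqsA, `[[`, logical(1), "stable")), 2L)
  # agreement with the 1-D reduction route
  dfA <- single_toggle_equilibria(p, "A")
  stab <- vapply(eqsA, `[[`, logical(1), "stable")
  expect_equal(sort(dfA$x[dfA$stable]),
               sort(vapply(eqsA[stab], function(e) unname(e$state[1]),
                           numeric(1))),
               tolerance = 1e-6)
})

test_that("signatures of stable reference S equilibria are strict", {
  p <- toggle_preset("reference", d = 0.2)
  for (counts in list(2L, c(1L, 1L))) {
    eq <- make_population_state(counts, p, "S")
    expect_true(inherits(eq, "equilibrium_record"))
    expect_false(eq$signature$tied)
    expect_true(all(eq$signature$labels %in% c("G", "R")))
  }
})

test_that("bistability scan flags the expected regions on a coarse grid", {
  # coarse grid here; the full published-resolution scan runs in acceptance
  p <- toggle_preset("reference")
  grid <- seq(0, 50, by = 10)
  mS <- bistability_scan("S", p, grid, grid)
  expect_true(all(mS$counts >= 2))
  mA <- bistability_scan("A", p, grid, grid)
  expect_true(any(mA$counts >= 2))
  expect_true(any(mA$counts < 2))
  expect_identical(mA$counts[grid == 20, grid == 20], 2L)  # reference point
  f <- tempfile(fileext = ".csv")
  write_region_csv(mS, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), length(grid)^2)
  unlink(f)
})

test_that("spectrum reduction reproduces full spectra for all mixtures", {
  p <- toggle_preset("reference", d = 1)
  # homogeneous populations: reduction to two toggles, N-independent
  for (N in c(2L, 4L, 8L)) {
    eq <- make_population_state(N, p, "S")
    chk <- reduced_spectrum_check(eq)
    expect_true(chk$ok)
    expect_lt(chk$max_mismatch, 1e-6)
    expect_true(chk$multiplicity_ok)
    expect_identical(chk$reduction_size, 2L)
  }
  # N = 2 homogeneous: the reduction is the identity
  eq2 <- make_population_state(2L, p, "S")
  chk2 <- reduced_spectrum_check(eq2)
  expect_equal(sort(Re(chk2$reduced)), sort(Re(chk2$full)), tolerance = 1e-8)
  # (1:1)-mixed: three-toggle construction (mirror-paired anti-sync blocks)
  p01 <- toggle_preset("reference", d = 0.1)
  for (N2 in c(2L, 3L)) {
    eq <- make_population_state(c(N2, N2), p01, "S")
    chk <- reduced_spectrum_check(eq)
    expect_true(chk$ok)
    expect_identical(chk$reduction_size, 3L)
  }
  # (9:1) and other unequal mixtures: four-toggle construction
  eq91 <- make_population_state(c(9L, 1L), p01, "S")
  chk91 <- reduced_spectrum_check(eq91)
  expect_true(chk91$ok)
  expect_lt(chk91$max_mismatch, 1e-6)
  expect_identical(chk91$reduction_size, 4L)
  eq31 <- make_population_state(c(3L, 1L), p01, "S")
  expect_true(reduced_spectrum_check(eq31)$ok)
  # A model too: the block argument is model-independent
  eqA <- make_population_state(c(3L, 1L), p01, "A")
  expect_true(reduced_spectrum_check(eqA)$ok)
})

test_that("mirror pairing of equilibria holds at symmetric parameters", {
  p <- toggle_preset("reference", d = 0.4)
  spec <- population_spec("S", 2)
  eqG <- make_population_state(2L, p, "S")
  st <- mirror_map(eqG$state, spec)
  eqR <- find_equilibrium(st, p, spec)
  expect_equal(unname(eqR$state), unname(st), tolerance = 1e-7)
  expect_equal(sort(Re(eqG$eigenvalues)), sort(Re(eqR$eigenvalues)),
               tolerance = 1e-7)
})
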