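test_that("influence graphs carry the expected signed edges", {
  p <- toggle_preset("reference")
  g <- influence_graph(population_spec("S", 1), p)
  key <- with(g$edges, paste(from, to, sign))
  expect_setequal(key, c("y1 x1 -1", "g1 x1 1", "x1 y1 -1", "r1 y1 1",
                         "y1 g1 -1", "g_e g1 1", "x1 r1 -1", "r_e r1 1",
                         "g1 g_e 1", "r1 r_e 1"))
  expect_identical(nrow(g$edges), 10L)

  gA <- influence_graph(population_spec("A", 1), p)
  keyA <- with(gA$edges, paste(from, to, sign))
  expect_setequal(keyA, c("y1 x1 -1", "r1 x1 1", "x1 y1 -1", "x1 r1 -1",
                          "r_e r1 1", "r1 r_e 1"))
  # a zero rate removes its edge
  g0 <- influence_graph(population_spec("S", 1), toggle_preset("reference"),
                        n_check = 0)
  p0 <- toggle_preset("reference"); p0$a3 <- 0
  g3 <- influence_graph(population_spec("S", 1), p0, n_check = 0)
  expect_true("g1 x1" %in% paste(g0$edges$from, g0$edges$to))
  expect_false("g1 x1" %in% paste(g3$edges$from, g3$edges$to))
})

test_that("orthant partition matches the published split and brute force", {
  p <- toggle_preset("reference")
  for (N in c(1, 2)) {                    # brute force needs <= 12 nodes
    g <- influence_graph(population_spec("S", N), p, n_check = 0)
    part <- find_orthant_partition(g)
    expect_true(part$balanced)
    expect_true(oracle_balanced(g))
    i <- seq_len(N)
    expect_setequal(part$S_plus, c(paste0("x", i), paste0("g", i), "g_e"))
    expect_setequal(part$S_minus, c(paste0("y", i), paste0("r", i), "r_e"))
  }
  for (N in c(5, 10)) {                   # beyond brute force: BFS only
    g <- influence_graph(population_spec("S", N), p, n_check = 0)
    expect_true(find_orthant_partition(g)$balanced)
  }
  for (N in c(1, 2, 5, 10)) {
    gA <- influence_graph(population_spec("A", N), p, n_check = 0)
    pA <- find_orthant_partition(gA)
    expect_false(pA$balanced)
    if (N == 1) expect_false(oracle_balanced(gA))
    # witness is a closed walk with an odd number of negative edges
    w <- pA$witness
    expect_identical(w[1], w[length(w)])
    sgn <- vapply(seq_len(length(w) - 1), function(k) {
      e <- gA$edges
      fwd <- which(e$from == w[k] & e$to == w[k + 1])
      bwd <- which(e$to == w[k] & e$from == w[k + 1])
      # prefer the direction actually traversed; anti-parallel edge pairs
      # (r <-> r_e) share a sign, the x/r pair does not
      s <- e$sign[c(fwd, bwd)]
      if (length(unique(s)) == 1) s[1] else e$sign[fwd[1]]
    }, numeric(1))
    expect_equal(sum(sgn < 0) %% 2, 1)
  }
  # degenerate single-node graph
  g1 <- structure(list(nodes = "x1",
                       edges = data.frame(from = character(), to = character(),
                                          sign = numeric()),
                       spec = population_spec("S", 1)),
                  class = "influence_graph")
  p1 <- find_orthant_partition(g1)
  expect_true(p1$balanced)
  expect_identical(p1$S_plus, "x1")
  expect_length(p1$S_minus, 0)
})

test_that("strong connectivity holds for S, fails with parameter nodes", {
  p <- toggle_preset("reference")
  for (N in c(1, 2, 5)) {
    g <- influence_graph(population_spec("S", N), p, n_check = 0)
    sc <- is_strongly_connected(g, certificate = TRUE)
    expect_true(as.logical(sc))
    if (N >= 2) {
      path <- attr(sc, "path")
      expect_identical(path[1], "x2")
      expect_identical(path[length(path)], "x1")
    }
  }
  # constant parameter nodes cannot be reached back: connectivity breaks
  g <- influence_graph(population_spec("S", 2), p, n_check = 0)
  gx <- g
  gx$nodes <- c(g$nodes, "a1", "delta_g")
  gx$edges <- rbind(g$edges,
                    data.frame(from = c("a1", "a1", "delta_g", "delta_g"),
                               to = c("x1", "x2", "g1", "g2"),
                               sign = c(1, 1, -1, -1)))
  expect_false(as.logical(is_strongly_connected(gx)))
})

test_that("sampled Jacobian signs validate and sign flips are caught", {
  p <- toggle_preset("reference")
  expect_silent(influence_graph(population_spec("S", 2), p, n_check = 50))
  # a corrupted edge label must be detected by the numeric validation
  g <- influence_graph(population_spec("S", 1), p, n_check = 0)
  g$edges$sign[1] <- -g$edges$sign[1]
  expect_error(qstoggle:::validate_graph_signs(g, p, 20, 1),
               "sign-indefiniteness")
})

test_that("Kamke order preservation holds for ordered S pairs", {
  p <- toggle_preset("reference", d = 0.1)
  spec <- population_spec("S", 2)
  part <- find_orthant_partition(influence_graph(spec, p, n_check = 0))
  sgn <- ifelse(state_names(spec) %in% part$S_plus, 1, -1)
  eq <- make_population_state(c(1, 1), p, "S")
  # the worked example: bump one x upward, whole trajectory stays ordered
  hi <- eq$state; hi["x2"] <- hi["x2"] * 1.1
  rep1 <- kamke_order_check(eq$state, hi, p, spec, part, horizon = 30)
  expect_true(rep1$ok)
  # identical states: order holds with equality
  rep2 <- kamke_order_check(eq$state, eq$state, p, spec, part, horizon = 5)
  expect_true(rep2$ok)
  # random ordered pairs
  for (seed in 1:20) {
    set.seed(300 + seed)
    base <- rand_state(spec, 300 + seed, lo = 0.01, hi = 20)
    bump <- abs(rnorm(spec$n_state, 0, 0.1))
    hi <- base + sgn * bump               # larger on S_plus, smaller on S_minus
    hi <- pmax(hi, 0)
    lo <- pmin(base, base + sgn * 0)      # base itself
    res <- kamke_order_check(lo, hi, p, spec, part, horizon = 20)
    expect_true(res$ok)
  }
  # unordered inputs are rejected
  bad <- eq$state; bad["y1"] <- bad["y1"] + 1   # wrong direction on S_minus
  expect_error(kamke_order_check(eq$state, bad, p, spec, part), "not ordered")
})

test_that("A model order violations are reported, not asserted", {
  p <- toggle_preset("reference", d = 1)
  spec <- population_spec("A", 2)
  # harness the A model with the S-style split {x} vs {y, r, r_e}: the x<-r
  # activation breaks it, so violations are legitimate outcomes
  part <- structure(list(balanced = TRUE,
                         S_plus = c("x1", "x2"),
                         S_minus = c("y1", "y2", "r1", "r2", "r_e")),
                    class = "orthant_partition")
  viol <- 0L
  for (seed in 1:10) {
    base <- rand_state(spec, 400 + seed, lo = 0.05, hi = 10)
    sgn <- ifelse(state_names(spec) %in% part$S_plus, 1, -1)
    hi <- pmax(base + sgn * 0.2, 0)
    res <- kamke_order_check(base, hi, p, spec, part, horizon = 20)
    if (!res$ok) {
      viol <- viol + 1L
      expect_true(is.finite(res$first_violation$magnitude))
    }
  }
  expect_gte(viol, 1L)
})

test_that("stable equilibria shift monotonically with the eight parameters", {
  p <- toggle_preset("reference", d = 0.1)
  eqG <- make_population_state(2, p, "S")      # stable G-homogeneous
  expect_true(eqG$stable)
  up <- parametric_monotonicity_check(eqG, "a5", 0.05 * p$a5)
  expect_true(up$ok)
  spec <- eqG$spec
  plus <- state_names(spec) %in% paste0(c("x", "g"), rep(1:2, each = 2)) |
    state_names(spec) == "g_e"
  expect_true(all(up$shift[plus] >= -1e-9))
  expect_true(all(up$shift[!plus] <= 1e-9))
  # zero increment: zero shift
  z0 <- parametric_monotonicity_check(eqG, "a5", 0)
  expect_equal(max(abs(z0$shift)), 0, tolerance = 1e-9)
  # delta_g decrease at the stable (1:1)-mixed state: green side rises
  eqM <- make_population_state(c(1, 1), p, "S")
  dn <- parametric_monotonicity_check(eqM, "delta_g", -0.05)
  expect_true(dn$ok)
  expect_true(all(dn$shift[plus] >= -1e-9))
  # the remaining monotone parameters at the homogeneous state
  for (pn in c("a1", "a2", "a3", "a4", "a6", "delta_r")) {
    res <- parametric_monotonicity_check(eqG, pn, 0.02 * max(p[[pn]], 1))
    expect_true(res$ok)
  }
  expect_error(parametric_monotonicity_check(eqG, "d", 0.1), "monotone")
})

test_that("graph and partition exports are well-formed", {
  g <- influence_graph(population_spec("S", 1), toggle_preset("reference"),
                       n_check = 0)
  f <- tempfile(fileext = ".dot")
  write_dot(g, f)
  txt <- readLines(f)
  expect_true(any(grepl("digraph", txt)))
  expect_identical(sum(grepl("->", txt)), 10L)
  unlink(f)
  part <- find_orthant_partition(g)
  fj <- tempfile(fileext = ".json")
  write_partition_json(part, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_setequal(back$S_plus, part$S_plus)
  unlink(fj)
})
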