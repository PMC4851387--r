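# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package internals they check.

# Damped fixed-point iteration on the scalar equilibrium equations of a
# single decoupled S toggle (d = 0):
#   x = a1/(1+y^nY) + a3 g^nG/(1+g^nG),  g = a5/(dg (1+y^nY)),
#   y = a2/(1+x^nX) + a4 r^nR/(1+r^nR),  r = a6/(dr (1+x^nX)).
oracle_s_single <- function(p, start = c(30, 0, 3, 0), damp = 0.5,
                            iters = 2000) {
  x <- start[1]; y <- start[2]; g <- start[3]; r <- start[4]
  H <- function(u, n) u^n / (1 + u^n)
  for (k in seq_len(iters)) {
    xn <- p$gamma_x + p$a1 / (1 + y^p$nY) + p$a3 * H(g, p$nG)
    yn <- p$gamma_y + p$a2 / (1 + x^p$nX) + p$a4 * H(r, p$nR)
    gn <- (p$gamma_g + p$a5 / (1 + y^p$nY)) / p$delta_g
    rn <- (p$gamma_r + p$a6 / (1 + x^p$nX)) / p$delta_r
    x <- damp * xn + (1 - damp) * x
    y <- damp * yn + (1 - damp) * y
    g <- damp * gn + (1 - damp) * g
    r <- damp * rn + (1 - damp) * r
  }
  c(x = x, y = y, g = g, r = r)
}

# Same for the single A toggle: x = a1/(1+y^nY) + a4 r^nR/(1+r^nR),
# y = a2/(1+x^nX), r = a6/(dr (1+x^nX)).
oracle_a_single <- function(p, start = c(20, 0, 0), damp = 0.5,
                            iters = 2000) {
  x <- start[1]; y <- start[2]; r <- start[3]
  H <- function(u, n) u^n / (1 + u^n)
  for (k in seq_len(iters)) {
    xn <- p$gamma_x + p$a1 / (1 + y^p$nY) + p$a4 * H(r, p$nR)
    yn <- p$gamma_y + p$a2 / (1 + x^p$nX)
    rn <- (p$gamma_r + p$a6 / (1 + x^p$nX)) / p$delta_r
    x <- damp * xn + (1 - damp) * x
    y <- damp * yn + (1 - damp) * y
    r <- damp * rn + (1 - damp) * r
  }
  c(x = x, y = y, r = r)
}

# Brute-force balance check of a signed graph: try all 2-colourings.
oracle_balanced <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  stopifnot(n <= 12)
  for (mask in 0:(2^(n - 1) - 1)) {       # fix colour of node 1
    colr <- c(1L, ifelse(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0, 1L, -1L))
    names(colr) <- nodes
    ok <- all(colr[graph$edges$to] ==
                graph$edges$sign * colr[graph$edges$from])
    if (ok) return(TRUE)
  }
  FALSE
}

ref_d <- function(d, ...) toggle_preset("reference", d = d, ...)

rand_state <- function(spec, seed, lo = 1e-3, hi = 1e2) {
  set.seed(seed)
  exp(stats::runif(spec$n_state, log(lo), log(hi)))
}
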