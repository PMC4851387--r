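#' Hill functions
#'
#' `hill_act(u, n) = u^n / (1 + u^n)` and `hill_rep(u, n) = 1 / (1 + u^n)`.
#' The argument is clamped to `u >= 0` before exponentiation so that transient
#' solver overshoots below zero cannot produce NaNs; the state space proper is
#' the non-negative orthant.
#'
#' @param u concentration (clamped to be >= 0).
#' @param n Hill coefficient (>= 1).
#' @return function value; `hill_deriv` returns `d/du (u^n/(1+u^n))`, which
#'   equals `n u^(n-1) / (1+u^n)^2` and is finite at `u = 0` for `n >= 1`.
#' @keywords internal
hill_act <- function(u, n) {
  un <- pmax(u, 0)^n
  un / (1 + un)
}

hill_rep <- function(u, n) 1 / (1 + pmax(u, 0)^n)

hill_deriv <- function(u, n) {
  u <- pmax(u, 0)
  if (n < 1) stop("Hill derivative unbounded at 0 for n < 1", call. = FALSE)
  # u^(n-1) is 1 at u=0 when n=1, 0 when n>1
  un1 <- if (n == 1) rep(1, length(u)) else u^(n - 1)
  n * un1 / (1 + un1 * u)^2
}

#' Model right-hand sides
#'
#' `toggle_rhs` evaluates the vector field of the population model named by
#' `spec$model`; `s_rhs` and `a_rhs` are the model-specific entry points.
#'
#' For the S model, cell `i` obeys
#' \deqn{\dot x_i = \gamma_x + a_1/(1+y_i^{n_Y}) + a_3 g_i^{n_G}/(1+g_i^{n_G}) - x_i}
#' \deqn{\dot y_i = \gamma_y + a_2/(1+x_i^{n_X}) + a_4 r_i^{n_R}/(1+r_i^{n_R}) - y_i}
#' \deqn{\dot g_i = \gamma_g + a_5/(1+y_i^{n_Y}) + d(g_e-g_i) - \delta_g g_i}
#' \deqn{\dot r_i = \gamma_r + a_6/(1+x_i^{n_X}) + d(r_e-r_i) - \delta_r r_i}
#' and the shared medium obeys
#' \deqn{\dot g_e = (\rho/N)\sum_i d(g_i-g_e) - \delta_e g_e,\qquad
#'       \dot r_e = (\rho/N)\sum_i d(r_i-r_e) - \delta_e r_e.}
#' The A model drops the green quorum-sensing arm: `x_i` is activated by the
#' red autoinducer (`a4` term), `y_i` has no activation, and only `r_i, r_e`
#' are communicated.
#'
#' @param state packed state vector (see [population_state()]).
#' @param params a [toggle_params()] object.
#' @param spec a [population_spec()]; `s_rhs` requires `spec$model == "S"`,
#'   `a_rhs` requires `"A"`.
#' @return derivative vector, same shape and names as `state`.
#' @export
toggle_rhs <- function(state, params, spec) {
  if (spec$model == "S") s_rhs(state, params, spec)
  else a_rhs(state, params, spec)
}

#' @rdname toggle_rhs
#' @export
s_rhs <- function(state, params, spec) {
  if (spec$model != "S") stop("s_rhs: spec$model must be 'S'", call. = FALSE)
  check_state(state, spec)
  p <- params
  N <- spec$N
  ii <- seq_len(N)
  x <- state[4 * ii - 3]; y <- state[4 * ii - 2]
  g <- state[4 * ii - 1]; r <- state[4 * ii]
  ge <- state[4 * N + 1]; re <- state[4 * N + 2]
  repx <- hill_rep(x, p$nX); repy <- hill_rep(y, p$nY)
  out <- numeric(spec$n_state)
  out[4 * ii - 3] <- p$gamma_x + p$a1 * repy + p$a3 * hill_act(g, p$nG) - x
  out[4 * ii - 2] <- p$gamma_y + p$a2 * repx + p$a4 * hill_act(r, p$nR) - y
  out[4 * ii - 1] <- p$gamma_g + p$a5 * repy + p$d * (ge - g) - p$delta_g * g
  out[4 * ii]     <- p$gamma_r + p$a6 * repx + p$d * (re - r) - p$delta_r * r
  out[4 * N + 1] <- (p$rho / N) * sum(p$d * (g - ge)) - p$delta_e * ge
  out[4 * N + 2] <- (p$rho / N) * sum(p$d * (r - re)) - p$delta_e * re
  names(out) <- names(state)
  out
}

#' @rdname toggle_rhs
#' @export
a_rhs <- function(state, params, spec) {
  if (spec$model != "A") stop("a_rhs: spec$model must be 'A'", call. = FALSE)
  check_state(state, spec)
  p <- params
  N <- spec$N
  ii <- seq_len(N)
  x <- state[3 * ii - 2]; y <- state[3 * ii - 1]; r <- state[3 * ii]
  re <- state[3 * N + 1]
  repx <- hill_rep(x, p$nX)
  out <- numeric(spec$n_state)
  out[3 * ii - 2] <- p$gamma_x + p$a1 * hill_rep(y, p$nY) +
    p$a4 * hill_act(r, p$nR) - x
  out[3 * ii - 1] <- p$gamma_y + p$a2 * repx - y
  out[3 * ii]     <- p$gamma_r + p$a6 * repx + p$d * (re - r) - p$delta_r * r
  out[3 * N + 1] <- (p$rho / N) * sum(p$d * (r - re)) - p$delta_e * re
  names(out) <- names(state)
  out
}

#' Analytic Jacobian of the population models
#'
#' Assembles the dense Jacobian of [toggle_rhs()] at `state`. The matrix has
#' the block structure exploited by the spectrum reductions: identical-format
#' per-cell blocks on the diagonal, a rank-one-per-species mean-field coupling
#' into the extracellular rows (`rho d / N` each), and a uniform feedback `d`
#' from the extracellular columns.
#'
#' @inheritParams toggle_rhs
#' @return square matrix of dimension `spec$n_state`.
#' @export
toggle_jacobian <- function(state, params, spec) {
  check_state(state, spec)
  p <- params
  N <- spec$N
  n <- spec$n_state
  ii <- seq_len(N)
  J <- matrix(0, n, n)
  if (spec$model == "S") {
    x <- state[4 * ii - 3]; y <- state[4 * ii - 2]
    g <- state[4 * ii - 1]; r <- state[4 * ii]
    dhx <- hill_deriv(x, p$nX); dhy <- hill_deriv(y, p$nY)
    dhg <- hill_deriv(g, p$nG); dhr <- hill_deriv(r, p$nR)
    ix <- 4 * ii - 3; iy <- 4 * ii - 2; ig <- 4 * ii - 1; ir <- 4 * ii
    J[cbind(ix, ix)] <- -1
    J[cbind(ix, iy)] <- -p$a1 * dhy
    J[cbind(ix, ig)] <- p$a3 * dhg
    J[cbind(iy, iy)] <- -1
    J[cbind(iy, ix)] <- -p$a2 * dhx
    J[cbind(iy, ir)] <- p$a4 * dhr
    J[cbind(ig, ig)] <- -(p$d + p$delta_g)
    J[cbind(ig, iy)] <- -p$a5 * dhy
    J[ig, 4 * N + 1] <- p$d
    J[cbind(ir, ir)] <- -(p$d + p$delta_r)
    J[cbind(ir, ix)] <- -p$a6 * dhx
    J[ir, 4 * N + 2] <- p$d
    J[4 * N + 1, ig] <- p$rho * p$d / N
    J[4 * N + 1, 4 * N + 1] <- -(p$rho * p$d + p$delta_e)
    J[4 * N + 2, ir] <- p$rho * p$d / N
    J[4 * N + 2, 4 * N + 2] <- -(p$rho * p$d + p$delta_e)
  } else {
    x <- state[3 * ii - 2]; y <- state[3 * ii - 1]; r <- state[3 * ii]
    dhx <- hill_deriv(x, p$nX); dhy <- hill_deriv(y, p$nY)
    dhr <- hill_deriv(r, p$nR)
    ix <- 3 * ii - 2; iy <- 3 * ii - 1; ir <- 3 * ii
    J[cbind(ix, ix)] <- -1
    J[cbind(ix, iy)] <- -p$a1 * dhy
    J[cbind(ix, ir)] <- p$a4 * dhr
    J[cbind(iy, iy)] <- -1
    J[cbind(iy, ix)] <- -p$a2 * dhx
    J[cbind(ir, ir)] <- -(p$d + p$delta_r)
    J[cbind(ir, ix)] <- -p$a6 * dhx
    J[ir, 3 * N + 1] <- p$d
    J[3 * N + 1, ir] <- p$rho * p$d / N
    J[3 * N + 1, 3 * N + 1] <- -(p$rho * p$d + p$delta_e)
  }
  dimnames(J) <- list(state_names(spec), state_names(spec))
  J
}

#' Mirror involution on S-population states (and parameters)
#'
#' The mirror map sigma exchanges the green and red arms: within every cell
#' `x_i <-> y_i` and `g_i <-> r_i`, and in the medium `g_e <-> r_e`. With
#' mirror-symmetric parameters the S vector field is equivariant:
#' `s_rhs(sigma(z)) = sigma(s_rhs(z))`. Applying the map twice is the
#' identity. If `params` is supplied, the swapped parameter set
#' ([mirror_params()]) is returned alongside, plus an `asymmetry` flag naming
#' the parameter pairs (if any) whose values differ, i.e. those that break
#' the symmetry.
#'
#' @param state packed S-model state vector.
#' @param spec a [population_spec()] with `model == "S"`.
#' @param params optional [toggle_params()].
#' @return If `params` is `NULL`, the mirrored state vector; otherwise a list
#'   with `state`, `params`, and `asymmetry` (character vector, empty when
#'   the parameter set is a fixed point of the swap).
#' @export
mirror_map <- function(state, spec, params = NULL) {
  if (spec$model != "S")
    stop("mirror_map is defined for the S model only", call. = FALSE)
  check_state(state, spec)
  N <- spec$N
  perm <- c(as.vector(t(matrix(c(2, 1, 4, 3), nrow = N, ncol = 4, byrow = TRUE) +
                           4 * (seq_len(N) - 1))),
            4 * N + 2, 4 * N + 1)
  out <- state[perm]
  names(out) <- names(state)
  if (is.null(params)) return(out)
  q <- mirror_params(params)
  asym <- vapply(.mirror_pairs, function(pr) {
    if (params[[pr[1]]] != params[[pr[2]]]) paste(pr, collapse = "/") else NA_character_
  }, character(1))
  list(state = out, params = q, asymmetry = asym[!is.na(asym)])
}
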