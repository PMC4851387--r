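# Dormand-Prince 5(4) embedded Runge-Kutta with PI step control.
# The toggle models are only mildly stiff at desk scale (the fastest decay
# rate is d + delta, <= ~110 at the largest coupling studied), so a 5th-order
# explicit pair at rtol 1e-8 is both accurate and cheap; see the vignette.

.dp5 <- local({
  A <- matrix(0, 7, 7)
  A[2, 1] <- 1 / 5
  A[3, 1:2] <- c(3 / 40, 9 / 40)
  A[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
  A[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
  A[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656)
  A[7, 1:6] <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  b5 <- A[7, 1:7]                      # 5th order (FSAL)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640,
          -92097 / 339200, 187 / 2100, 1 / 40)
  list(A = A, e = b5 - c(b4, 0)[1:7])
})

#' Integrate a toggle population
#'
#' Adaptive Dormand-Prince 5(4) integration of [toggle_rhs()]. The solution is
#' recorded at the requested sample times (reached exactly by step clipping).
#' When `stop_at_equilibrium` is set, integration ends early once the
#' sup-norm of the vector field drops below `equilibrium_tol` (the trailing
#' sample times are then filled with the terminal state, flagged in the
#' report).
#'
#' @param state initial packed state vector.
#' @param params a [toggle_params()].
#' @param spec a [population_spec()].
#' @param times increasing numeric vector of sample times starting at 0, or a
#'   single horizon (expanded to 101 equidistant samples).
#' @param rtol,atol relative / absolute local error tolerances.
#' @param stop_at_equilibrium logical; stop once `||f||_inf < equilibrium_tol`.
#' @param equilibrium_tol see above.
#' @param rhs,n_state optional overrides used internally to integrate derived
#'   systems (e.g. the coupled pair system of [kamke_order_check()]); `rhs`
#'   must be `function(z)` of the packed vector alone.
#' @param max_steps step budget guard.
#' @return list with `times`, `states` (one row per sample time), `converged`
#'   (equilibrium detected), `t_end`, `f_norm` (terminal `||f||_inf`), and
#'   `steps`.
#' @export
integrate_toggles <- function(state, params, spec, times = 500,
                              rtol = 1e-8, atol = 1e-10,
                              stop_at_equilibrium = TRUE,
                              equilibrium_tol = 1e-9,
                              rhs = NULL, n_state = NULL,
                              max_steps = 2e6) {
  if (is.null(rhs)) {
    check_state(state, spec)
    f <- function(z) toggle_rhs(z, params, spec)
  } else f <- rhs
  y <- as.numeric(state)
  n <- length(y)
  if (length(times) == 1L) times <- seq(0, times, length.out = 101L)
  stopifnot(times[1] == 0, !is.unsorted(times))
  nt <- length(times)
  out <- matrix(NA_real_, nt, n)
  out[1, ] <- y
  A <- .dp5$A; ec <- .dp5$e
  t <- 0
  tend <- times[nt]
  k <- matrix(0, n, 7)
  k[, 1] <- f(y)
  h <- min(0.01, tend / 10)
  next_i <- 2L
  steps <- 0L
  converged <- FALSE
  errold <- 1
  while (next_i <= nt && t < tend) {
    if (steps >= max_steps) stop("integrate_toggles: step budget exceeded")
    clip <- FALSE
    if (t + h >= times[next_i] - 1e-14) { h <- times[next_i] - t; clip <- TRUE }
    for (s in 2:7) {
      k[, s] <- f(y + h * (k[, 1:(s - 1), drop = FALSE] %*% A[s, 1:(s - 1)]))
    }
    ynew <- y + h * as.vector(k[, 1:7] %*% A[7, ])
    err <- h * as.vector(k %*% ec)
    sc <- atol + rtol * pmax(abs(y), abs(ynew))
    en <- sqrt(mean((err / sc)^2))
    steps <- steps + 1L
    if (en <= 1 || h <= 1e-12) {
      t <- t + h
      y <- ynew
      k[, 1] <- k[, 7]            # FSAL
      while (next_i <= nt && t >= times[next_i] - 1e-12) {
        out[next_i, ] <- y
        next_i <- next_i + 1L
      }
      if (stop_at_equilibrium && max(abs(k[, 1])) < equilibrium_tol) {
        converged <- TRUE
        break
      }
      # PI controller
      fac <- 0.9 * en^(-0.7 / 5) * errold^(0.4 / 5)
      errold <- max(en, 1e-4)
      h <- h * min(5, max(0.2, fac))
      if (clip && next_i <= nt) h <- min(h, times[next_i] - t)
    } else {
      h <- h * max(0.2, 0.9 * en^(-1 / 5))
    }
  }
  if (next_i <= nt) out[next_i:nt, ] <- matrix(y, nt - next_i + 1L, n,
                                               byrow = TRUE)
  fend <- f(y)
  list(times = times, states = out, converged = converged,
       t_end = t, f_norm = max(abs(fend)), steps = steps)
}
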