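#' Per-cell transcription signature and population ratio
#'
#' A cell is labelled `"G"` when its LacI level exceeds its TetR level
#' (`x_i > y_i`), `"R"` when `y_i > x_i`, and `"?"` on a tie (flagged).
#'
#' @param state packed state vector.
#' @param spec a [population_spec()].
#' @return list with `labels` (per cell), `ratio` string `"p:q"` in counts
#'   (e.g. `"9:1"`), and `tied` flag.
#' @export
state_signature <- function(state, spec) {
  u <- unpack_state(state, spec)
  dx <- unname(u$cells[, "x"] - u$cells[, "y"])
  labels <- ifelse(dx > 0, "G", ifelse(dx < 0, "R", "?"))
  nG <- sum(labels == "G")
  nR <- sum(labels == "R")
  div <- if (nG > 0 && nR > 0) gcd2(nG, nR) else max(nG, nR, 1L)
  list(labels = labels,
       ratio = paste0(nG / div, ":", nR / div),
       counts = c(G = nG, R = nR),
       tied = any(labels == "?"))
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Newton refinement of an equilibrium
#'
#' Damped (Armijo line-searched) Newton iteration on the model vector field
#' using the analytic Jacobian. On convergence the result is projected onto
#' the non-negative orthant (a warning is issued if the projection actually
#' moved a component beyond round-off — the equilibrium then sits on the
#' boundary), the Jacobian spectrum is computed, and the equilibrium is
#' classified.
#'
#' @param guess finite, non-negative starting state.
#' @param params a [toggle_params()].
#' @param spec a [population_spec()].
#' @param tol residual sup-norm tolerance (`newton_tol`).
#' @param max_iter iteration cap.
#' @param stability_margin half-width of the "marginal" eigenvalue band.
#' @return An `equilibrium_record`: list with `state`, `params`, `spec`,
#'   `residual_norm`, `eigenvalues`, `max_re`, `stable`, `marginal`,
#'   `signature`.
#' @export
find_equilibrium <- function(guess, params, spec, tol = 1e-10,
                             max_iter = 200, stability_margin = 1e-7) {
  check_state(guess, spec)
  if (any(!is.finite(guess))) stop("guess must be finite", call. = FALSE)
  z <- as.numeric(guess)
  fz <- toggle_rhs(z, params, spec)
  for (it in seq_len(max_iter)) {
    if (max(abs(fz)) < tol) break
    J <- toggle_jacobian(z, params, spec)
    dz <- tryCatch(solve(J, -fz), error = function(e) NULL)
    if (is.null(dz)) stop("find_equilibrium: singular Jacobian at iterate ",
                          it, call. = FALSE)
    f0 <- sum(fz^2)
    lam <- 1
    repeat {
      z1 <- z + lam * dz
      f1 <- toggle_rhs(z1, params, spec)
      if (sum(f1^2) <= f0 * (1 - 1e-4 * lam) || lam < 1e-8) break
      lam <- lam / 2
    }
    z <- z1
    fz <- f1
  }
  if (max(abs(fz)) >= tol) {
    cond <- structure(class = c("qstoggle_no_convergence", "error", "condition"),
                      list(message = sprintf(
                        "Newton did not converge (residual %.3e after %d iterations)",
                        max(abs(fz)), max_iter),
                        call = sys.call(-1), last_iterate = z))
    stop(cond)
  }
  if (any(z < 0)) {
    if (any(z < -1e-8))
      warning("equilibrium crossed the orthant boundary; projected to >= 0")
    z <- pmax(z, 0)
  }
  names(z) <- state_names(spec)
  ev <- eigen(toggle_jacobian(z, params, spec), only.values = TRUE)$values
  mre <- max(Re(ev))
  structure(list(state = z, params = params, spec = spec,
                 residual_norm = max(abs(toggle_rhs(z, params, spec))),
                 eigenvalues = ev, max_re = mre,
                 stable = mre < -stability_margin,
                 marginal = abs(mre) <= stability_margin,
                 signature = state_signature(z, spec)),
            class = "equilibrium_record")
}

#' @export
print.equilibrium_record <- function(x, ...) {
  cat(sprintf("<equilibrium_record> %s model, N=%d, signature %s (%s)\n",
              x$spec$model, x$spec$N, x$signature$ratio,
              if (x$stable) "stable" else if (x$marginal) "marginal"
              else "unstable"))
  cat(sprintf("  residual %.2e, max Re(lambda) = %.6g\n",
              x$residual_norm, x$max_re))
  invisible(x)
}

#' Stability verdict of an equilibrium record
#'
#' Exponentially stable iff the leading eigenvalue real part is below
#' `-margin`; within `[-margin, margin]` the verdict is `"marginal"`
#' (bifurcation vicinity).
#'
#' @param eq an `equilibrium_record` (or any list with `eigenvalues`).
#' @param margin the `stability_margin`.
#' @return list with `verdict` in `c("stable", "marginal", "unstable")`,
#'   `leading` (eigenvalue with largest real part), and `n_unstable`.
#' @export
classify_stability <- function(eq, margin = 1e-7) {
  ev <- if (is.list(eq)) eq$eigenvalues else eq
  re <- Re(ev)
  mre <- max(re)
  verdict <- if (mre < -margin) "stable"
  else if (mre <= margin) "marginal"
  else "unstable"
  list(verdict = verdict, leading = ev[which.max(re)],
       n_unstable = sum(re > margin))
}

#' Single-toggle equilibria at d = 0 via the exact 1-D reduction
#'
#' With the cell decoupled from the medium (`d = 0`), the autoinducer levels
#' are explicit functions of the repressors, and the equilibrium problem
#' reduces to one scalar equation. For the S model, `x = F(y)` with
#' `F(y) = gamma_x + a1/(1+y^nY) + a3 H(g(y))`, `g(y) = (gamma_g +
#' a5/(1+y^nY))/delta_g`, and the roots of `psi(y) = G(x = F(y)) - y` are
#' bracketed on a log-spaced grid and refined by bisection. The A model
#' reduces analogously to a scalar equation in `x`. Stability is read from
#' the full cell-block Jacobian.
#'
#' @param params a [toggle_params()] (its `d` is ignored; `d = 0` enforced).
#' @param model `"S"` or `"A"`.
#' @param grid_n bracketing grid size.
#' @return data.frame with one row per equilibrium: repressor levels,
#'   autoinducer levels, `stable`, `label`.
#' @export
single_toggle_equilibria <- function(params, model = c("S", "A"),
                                     grid_n = 400) {
  model <- match.arg(model)
  # hoisted locals: these scalar reductions run inside dense grid scans
  a1 <- params$a1; a2 <- params$a2; a3 <- params$a3; a4 <- params$a4
  a5 <- params$a5; a6 <- params$a6
  nX <- params$nX; nY <- params$nY; nG <- params$nG; nR <- params$nR
  gx <- params$gamma_x; gy <- params$gamma_y
  gg <- params$gamma_g; gr <- params$gamma_r
  dg <- params$delta_g; dr <- params$delta_r
  H <- function(u, n) { un <- u^n; un / (1 + un) }   # args are >= 0 here
  if (model == "S") {
    gfun <- function(y) (gg + a5 / (1 + y^nY)) / dg
    rfun <- function(x) (gr + a6 / (1 + x^nX)) / dr
    Fx <- function(y) gx + a1 / (1 + y^nY) + a3 * H(gfun(y), nG)
    psi <- function(y) {
      x <- Fx(y)
      gy + a2 / (1 + x^nX) + a4 * H(rfun(x), nR) - y
    }
    roots <- bracket_roots(psi, 0, gy + a2 + a4 + 1, grid_n)
    if (!length(roots)) return(empty_single_df(model))
    x <- Fx(roots)
    out <- cbind(x = x, y = roots, g = gfun(roots), r = rfun(x))
  } else {
    yfun <- function(x) gy + a2 / (1 + x^nX)
    rfun <- function(x) (gr + a6 / (1 + x^nX)) / dr
    psi <- function(x) gx + a1 / (1 + yfun(x)^nY) + a4 * H(rfun(x), nR) - x
    roots <- bracket_roots(psi, 0, gx + a1 + a4 + 1, grid_n)
    if (!length(roots)) return(empty_single_df(model))
    out <- cbind(x = roots, y = yfun(roots), r = rfun(roots))
  }
  p <- params
  df <- as.data.frame(out)
  p0 <- p; p0$d <- 0
  spec1 <- population_spec(model, 1)
  df$stable <- vapply(seq_len(nrow(df)), function(i) {
    cell <- unlist(df[i, seq_len(spec1$n_cell)])
    z <- population_state(spec1, matrix(cell, 1))
    nc <- spec1$n_cell
    Jc <- toggle_jacobian(z, p0, spec1)[seq_len(nc), seq_len(nc)]
    max(Re(eigen(Jc, only.values = TRUE)$values)) < 0
  }, logical(1))
  df$label <- ifelse(df$x > df$y, "G", ifelse(df$x < df$y, "R", "?"))
  df
}

empty_single_df <- function(model) {
  cols <- if (model == "S") c("x", "y", "g", "r") else c("x", "y", "r")
  df <- as.data.frame(matrix(numeric(0), 0, length(cols),
                             dimnames = list(NULL, cols)))
  df$stable <- logical(0)
  df$label <- character(0)
  df
}

# sign-change bracketing on [lo, hi] followed by simultaneous (vectorized)
# bisection of every bracket; fn must be vectorized
bracket_roots <- function(fn, lo, hi, n, iter = 52) {
  xs <- seq(lo, hi, length.out = n)
  vs <- fn(xs)
  exact <- which(vs == 0)
  i <- which(!is.na(vs[-n]) & !is.na(vs[-1]) & vs[-n] * vs[-1] < 0)
  if (!length(i)) return(xs[exact])
  a <- xs[i]; b <- xs[i + 1]; fa <- vs[i]
  for (k in seq_len(iter)) {
    m <- (a + b) / 2
    fm <- fn(m)
    left <- fa * fm < 0
    b[left] <- m[left]
    a[!left] <- m[!left]
    fa[!left] <- fm[!left]
  }
  sort(c(xs[exact], (a + b) / 2))
}

#' Enumerate coexisting equilibria by multistart Newton
#'
#' Newton refinement from a deterministic lattice of guesses augmented with
#' seeded random log-uniform guesses, deduplicated by relative sup-norm
#' distance and sorted by signature.
#'
#' @param params a [toggle_params()].
#' @param spec a [population_spec()].
#' @param n_lattice points per repressor axis of the deterministic lattice
#'   (guesses are corner-like block states).
#' @param n_random additional random guesses.
#' @param seed RNG seed for the random guesses.
#' @param dedup_tol relative distance below which two solutions are merged.
#' @param ... passed to [find_equilibrium()].
#' @return list of `equilibrium_record`s (possibly empty).
#' @export
enumerate_equilibria <- function(params, spec, n_lattice = 6, n_random = 60,
                                 seed = 1, dedup_tol = 1e-6, ...) {
  p <- params
  xtop <- p$gamma_x + p$a1 + p$a3
  ytop <- p$gamma_y + p$a2 + p$a4
  lat <- seq(0, 1, length.out = n_lattice)
  guesses <- list()
  for (u in lat) for (v in lat) {
    x <- u * xtop; y <- v * ytop
    g <- (p$gamma_g + p$a5 * hill_rep(y, p$nY)) / p$delta_g
    r <- (p$gamma_r + p$a6 * hill_rep(x, p$nX)) / p$delta_r
    cell <- if (spec$model == "S") c(x, y, g, r) else c(x, y, r)
    guesses[[length(guesses) + 1L]] <- population_state(spec, matrix(cell, 1))
  }
  if (n_random > 0) {
    rng <- local_rng(seed)
    for (k in seq_len(n_random)) {
      z <- exp(stats::runif(spec$n_state, log(1e-3), log(50)))
      guesses[[length(guesses) + 1L]] <- z
    }
    restore_rng(rng)
  }
  found <- list()
  for (gz in guesses) {
    eq <- tryCatch(find_equilibrium(gz, params, spec, ...),
                   error = function(e) NULL)
    if (is.null(eq)) next
    dup <- FALSE
    for (f in found) {
      ref <- pmax(max(abs(f$state)), 1)
      if (max(abs(f$state - eq$state)) / ref < dedup_tol) { dup <- TRUE; break }
    }
    if (!dup) found[[length(found) + 1L]] <- eq
  }
  ord <- order(vapply(found, function(e) e$signature$ratio, character(1)),
               vapply(found, function(e) e$state[1], numeric(1)))
  found[ord]
}

#' Bistability region scan over the (a1, a2) plane
#'
#' Counts the stable equilibria of a single decoupled toggle (`d = 0`) on a
#' rectangular `(a1, a2)` grid, via the exact 1-D reduction of
#' [single_toggle_equilibria()]. A point belongs to the bistability region
#' when the count is at least 2. Solver failures are flagged with count
#' `NA_integer_`, never dropped.
#'
#' @param model `"S"` or `"A"`.
#' @param base_params [toggle_params()] supplying every parameter other than
#'   `a1`, `a2` (use `gamma_*` to set leakiness).
#' @param a1,a2 grid coordinate vectors (default `0:50`).
#' @return A `region_map`: list with `a1`, `a2`, `counts` matrix
#'   (`length(a1)` x `length(a2)`), and `model`.
#' @export
bistability_scan <- function(model, base_params, a1 = 0:50, a2 = 0:50) {
  counts <- matrix(NA_integer_, length(a1), length(a2))
  p <- base_params
  for (i in seq_along(a1)) {
    for (j in seq_along(a2)) {
      p$a1 <- a1[i]; p$a2 <- a2[j]
      df <- tryCatch(single_toggle_equilibria(p, model),
                     error = function(e) NULL)
      counts[i, j] <- if (is.null(df)) NA_integer_ else sum(df$stable)
    }
  }
  structure(list(a1 = a1, a2 = a2, counts = counts, model = model),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  tab <- table(factor(x$counts, levels = 0:max(2, x$counts, na.rm = TRUE)))
  cat(sprintf("<region_map> %s model, %d x %d grid; stable-count table:\n",
              x$model, length(x$a1), length(x$a2)))
  print(tab)
  invisible(x)
}

#' Export a region map as CSV
#' @param map a `region_map`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_region_csv <- function(map, path) {
  df <- expand.grid(a1 = map$a1, a2 = map$a2)
  df$n_stable <- as.vector(map$counts)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' N-independent spectrum reduction check
#'
#' At an equilibrium with subpopulation structure `(N1, ..., Nm)` the
#' population Jacobian consists of identical per-cell blocks within each
#' subpopulation, a mean-field rank-one coupling of weight `rho d / N` per
#' cell into the extracellular rows, and a uniform feedback `d` from the
#' extracellular columns. Its eigenvalues therefore split into symmetry
#' classes: the synchronous class, governed by a reduced matrix holding one
#' representative cell block per subpopulation (coupling weight
#' `rho p_k d` for subpopulation fraction `p_k`) plus the extracellular
#' block, and, for each subpopulation with `Nk >= 2`, an anti-synchronous
#' class equal to the bare cell block with multiplicity `Nk - 1`. The
#' distinct eigenvalues of the full linearization thus coincide with those
#' of auxiliary systems of 2 (homogeneous), 3 ((1:1), by mirror pairing) or
#' 4 (general (N1:N2)) toggles, independently of N. This function builds the
#' reduced construction and verifies the coincidence numerically.
#'
#' @param eq an `equilibrium_record` for a population.
#' @param tol eigenvalue matching tolerance.
#' @return list with `ok`, `max_mismatch`, `full` (sorted full spectrum),
#'   `reduced` (union of class spectra), `multiplicity_ok` (full spectrum size
#'   accounted for by block repetition), `reduction_size` (the 2/3/4-toggle
#'   count), and on failure `offending` (worst-matched eigenvalue).
#' @export
reduced_spectrum_check <- function(eq, tol = 1e-6) {
  spec <- eq$spec
  params <- eq$params
  z <- eq$state
  J <- toggle_jacobian(z, params, spec)
  nc <- spec$n_cell
  N <- spec$N
  m <- length(spec$counts)
  sub <- cell_subpop(spec)
  first <- match(seq_len(m), sub)            # representative cell per subpop
  blocks <- lapply(first, function(i) {
    idx <- (i - 1L) * nc + seq_len(nc)
    J[idx, idx, drop = FALSE]
  })
  # synchronous reduced matrix: m cell blocks + extracellular block
  rdim <- m * nc + spec$n_ext
  Rm <- matrix(0, rdim, rdim)
  eidx_full <- N * nc + seq_len(spec$n_ext)
  eidx_red <- m * nc + seq_len(spec$n_ext)
  pfrac <- subpop_fractions(spec)
  for (k in seq_len(m)) {
    ridx <- (k - 1L) * nc + seq_len(nc)
    fidx <- (first[k] - 1L) * nc + seq_len(nc)
    Rm[ridx, ridx] <- blocks[[k]]
    Rm[ridx, eidx_red] <- J[fidx, eidx_full, drop = FALSE]
    # mean-field row: Nk cells contribute rho*d/N each -> rho*p_k*d
    Rm[eidx_red, ridx] <- N * pfrac[k] * J[eidx_full, fidx, drop = FALSE]
  }
  Rm[eidx_red, eidx_red] <- J[eidx_full, eidx_full, drop = FALSE]
  ev_sync <- eigen(Rm, only.values = TRUE)$values
  ev_anti <- list()
  for (k in seq_len(m)) {
    if (spec$counts[k] >= 2L)
      ev_anti[[length(ev_anti) + 1L]] <-
        eigen(blocks[[k]], only.values = TRUE)$values
  }
  reduced <- c(ev_sync, unlist(ev_anti))
  full <- eigen(J, only.values = TRUE)$values
  # every full eigenvalue must be near a reduced one and vice versa
  d1 <- vapply(full, function(l) min(Mod(l - reduced)), numeric(1))
  d2 <- vapply(reduced, function(l) min(Mod(l - full)), numeric(1))
  worst <- max(c(d1, d2))
  # expected total count: sync (m*nc+ne) + sum (Nk-1)*nc = N*nc + ne
  mult_ok <- (m * nc + spec$n_ext +
                sum(pmax(spec$counts - 1L, 0L)) * nc) == spec$n_state
  red_size <- if (m == 1L) 2L else if (m == 2L &&
    spec$counts[1] == spec$counts[2] && is_mirror_symmetric(params)) 3L else 4L
  out <- list(ok = worst <= tol, max_mismatch = worst,
              full = full[order(Re(full), Im(full))],
              reduced = reduced[order(Re(reduced), Im(reduced))],
              multiplicity_ok = mult_ok, reduction_size = red_size)
  if (!out$ok) out$offending <- full[which.max(d1)]
  out
}

# seed handling: isolate RNG use, restoring the caller's stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
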