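# One-parameter pseudo-arclength continuation of equilibrium branches with
# fold (LP) and branch-point (BP) detection.
#
# Conventions: the augmented unknown is w = (u, p) with u the state and p the
# free parameter. Corrector solves f(u, p) = 0 together with the arclength
# condition t.(w - w_pred) = 0 for the previous unit tangent t. Test
# functions monitored between consecutive accepted points:
#   LP:  sign change of the parameter component of the unit tangent
#        (the branch folds back in p);
#   BP:  sign change of det([J  f_p; t']) (the bordered square matrix is
#        singular at a transcritical/pitchfork crossing but not at a fold).
# Events are localized by bisection to a parameter tolerance.

params_with <- function(params, name, value) {
  params[[name]] <- value
  params
}

cont_fp <- function(state, params, spec, pname, eps = 1e-6) {
  p <- params[[pname]]
  h <- eps * max(1, abs(p))
  (toggle_rhs(state, params_with(params, pname, p + h), spec) -
     toggle_rhs(state, params_with(params, pname, p - h), spec)) / (2 * h)
}

# unit tangent at (u, p): solve [J f_p; ref'] t = e_{n+1}, normalize;
# orientation aligned with `ref`
cont_tangent <- function(state, params, spec, pname, ref) {
  J <- toggle_jacobian(state, params, spec)
  fp <- cont_fp(state, params, spec, pname)
  n <- length(state)
  M <- rbind(cbind(J, fp), ref)
  t <- tryCatch(solve(M, c(rep(0, n), 1)), error = function(e) NULL)
  if (is.null(t)) return(NULL)
  t <- unname(t) / sqrt(sum(t^2))
  if (sum(t * ref) < 0) t <- -t
  t
}

bordered_det <- function(state, params, spec, pname, tang) {
  J <- toggle_jacobian(state, params, spec)
  fp <- cont_fp(state, params, spec, pname)
  M <- rbind(cbind(J, fp), tang)
  # only the sign of the determinant is used by the event logic
  as.numeric(determinant(M, logarithm = TRUE)$sign)
}

# Newton corrector for the arclength system from predictor wpred with tangent t
cont_correct <- function(wpred, tang, params, spec, pname, tol = 1e-10,
                         max_iter = 25) {
  n <- length(wpred) - 1L
  w <- wpred
  for (k in seq_len(max_iter)) {
    pcur <- params_with(params, pname, w[n + 1])
    f <- toggle_rhs(w[seq_len(n)], pcur, spec)
    g <- sum(tang * (w - wpred))
    if (max(abs(f)) < tol && abs(g) < tol) return(list(w = w, ok = TRUE))
    J <- toggle_jacobian(w[seq_len(n)], pcur, spec)
    fp <- cont_fp(w[seq_len(n)], pcur, spec, pname)
    M <- rbind(cbind(J, fp), tang)
    dw <- tryCatch(unname(solve(M, -c(f, g))), error = function(e) NULL)
    if (is.null(dw)) return(list(w = w, ok = FALSE))
    w <- w + dw
    if (max(abs(dw)) > 1e6) return(list(w = w, ok = FALSE))
  }
  list(w = w, ok = FALSE)
}

#' Pseudo-arclength continuation of an equilibrium branch
#'
#' Secant-predictor / Newton-corrector continuation of `f(u, p) = 0` in one
#' model parameter, with adaptive arclength step control, eigenvalues and a
#' stability verdict at every accepted point, and detection plus bisection
#' localization of fold (`LP`) and branch (`BP`) points.
#'
#' @param start an `equilibrium_record` at the lower (or upper) end of the
#'   sweep; its `params` supply all fixed parameters.
#' @param param_name name of the free parameter (e.g. `"d"`, `"a5"`).
#' @param bounds length-2 numeric sweep interval; continuation starts at
#'   `start$params[[param_name]]` and proceeds towards `bounds[2]`.
#' @param step0,step_min,step_max arclength step control (halve on corrector
#'   failure, grow 1.3x after 4 consecutive successes).
#' @param event_tol parameter localization tolerance for events.
#' @param max_points accepted-point budget.
#' @return A `branch` object: list with `param_name`, `points` (data.frame:
#'   parameter, state columns, `max_re`, `stable`), `states` (matrix),
#'   `events` (list of `kind`, `param`, `state`, `test_bracket`), and
#'   `termination` reason.
#' @export
continue_equilibrium <- function(start, param_name, bounds,
                                 step0 = 0.01, step_min = 1e-5,
                                 step_max = 0.1, event_tol = 1e-4,
                                 max_points = 2000) {
  spec <- start$spec
  params <- start$params
  if (!param_name %in% names(params)) stop("unknown parameter: ", param_name)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  n <- spec$n_state
  p0 <- params[[param_name]]
  u0 <- as.numeric(start$state)
  dirn <- if (abs(bounds[2] - p0) >= abs(p0 - bounds[1])) +1 else -1
  ref <- c(rep(0, n), dirn)
  tang <- cont_tangent(u0, params_with(params, param_name, p0), spec,
                       param_name, ref)
  if (is.null(tang)) stop("cannot compute initial tangent (singular point?)")
  pts <- list()
  events <- list()
  record <- function(w) {
    pcur <- params_with(params, param_name, w[n + 1])
    ev <- eigen(toggle_jacobian(w[seq_len(n)], pcur, spec),
                only.values = TRUE)$values
    list(w = w, max_re = max(Re(ev)))
  }
  cur <- record(c(u0, p0))
  pts[[1]] <- cur
  tcur <- tang
  bd_cur <- bordered_det(u0, params_with(params, param_name, p0), spec,
                         param_name, tcur)
  h <- step0
  succ <- 0L
  termination <- "bounds reached"
  while (length(pts) < max_points) {
    wpred <- cur$w + h * tcur
    sol <- cont_correct(wpred, tcur, params, spec, param_name)
    if (!sol$ok) {
      h <- h / 2
      if (h < step_min) { termination <- "step-size underflow"; break }
      next
    }
    tnew <- cont_tangent(sol$w[seq_len(n)],
                         params_with(params, param_name, sol$w[n + 1]),
                         spec, param_name, tcur)
    if (is.null(tnew)) { h <- h / 2; next }
    new <- record(sol$w)
    bd_new <- bordered_det(sol$w[seq_len(n)],
                           params_with(params, param_name, sol$w[n + 1]),
                           spec, param_name, tnew)
    # --- event tests between cur and new
    if (sign(bd_new) != sign(bd_cur) && sign(bd_cur) != 0) {
      ev <- locate_bp(cur, tcur, h, params, spec, param_name, event_tol)
      events[[length(events) + 1L]] <- ev
    } else if (sign(tnew[n + 1]) != sign(tcur[n + 1]) && tcur[n + 1] != 0) {
      ev <- locate_lp(cur, tcur, h, params, spec, param_name, event_tol)
      events[[length(events) + 1L]] <- ev
    }
    pts[[length(pts) + 1L]] <- new
    cur <- new
    tcur <- tnew
    bd_cur <- bd_new
    succ <- succ + 1L
    if (succ >= 4L) { h <- min(h * 1.3, step_max); succ <- 0L }
    pcur <- cur$w[n + 1]
    if (pcur > bounds[2] + 1e-12 || pcur < bounds[1] - 1e-12) break
  }
  if (length(pts) >= max_points) termination <- "point budget"
  mk_branch(pts, events, param_name, spec, params, termination)
}

mk_branch <- function(pts, events, param_name, spec, params, termination) {
  n <- spec$n_state
  W <- do.call(rbind, lapply(pts, `[[`, "w"))
  mre <- vapply(pts, `[[`, numeric(1), "max_re")
  df <- data.frame(param = W[, n + 1], max_re = mre, stable = mre < -1e-7)
  states <- W[, seq_len(n), drop = FALSE]
  colnames(states) <- state_names(spec)
  structure(list(param_name = param_name, points = df, states = states,
                 events = events, spec = spec, params = params,
                 termination = termination),
            class = "branch")
}

#' @export
print.branch <- function(x, ...) {
  rng <- range(x$points$param)
  cat(sprintf("<branch> in '%s' over [%.4g, %.4g], %d points, %d event(s); %s\n",
              x$param_name, rng[1], rng[2], nrow(x$points),
              length(x$events), x$termination))
  for (e in x$events)
    cat(sprintf("  %s at %s = %.6g%s\n", e$kind, x$param_name, e$param,
                if (isTRUE(e$localized)) "" else " (unlocalized)"))
  invisible(x)
}

# bisection along corrected arclength steps from `from` on the step (0, h]
# for a sign change of `testfun(point)`; returns event structure
bisect_event <- function(kind, from, tang, h, params, spec, pname,
                         event_tol, testfun) {
  n <- length(from$w) - 1L
  corr_at <- function(hh) {
    sol <- cont_correct(from$w + hh * tang, tang, params, spec, pname)
    if (!sol$ok) return(NULL)
    tn <- cont_tangent(sol$w[seq_len(n)],
                       params_with(params, pname, sol$w[n + 1]),
                       spec, pname, tang)
    if (is.null(tn)) return(NULL)
    list(w = sol$w, tang = tn)
  }
  f0 <- testfun(list(w = from$w, tang = tang))
  a <- 0; b <- h; fa <- f0
  pa <- from$w[n + 1]
  pb <- NA_real_
  fb <- NA_real_
  ptb <- corr_at(b)
  if (!is.null(ptb)) { fb <- testfun(ptb); pb <- ptb$w[n + 1] }
  if (is.null(ptb) || is.na(fb) || sign(fa) == sign(fb)) {
    return(list(kind = kind, param = NA_real_, state = NULL,
                localized = FALSE, test_bracket = c(fa, fb)))
  }
  best <- ptb
  for (k in seq_len(60)) {
    if (abs(pb - pa) < event_tol) break
    m <- (a + b) / 2
    ptm <- corr_at(m)
    if (is.null(ptm)) break
    fm <- testfun(ptm)
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm; pa <- ptm$w[n + 1] }
    else { b <- m; fb <- fm; pb <- ptm$w[n + 1]; best <- ptm }
  }
  list(kind = kind, param = (pa + pb) / 2, state = best$w[seq_len(n)],
       tangent = best$tang, localized = abs(pb - pa) < event_tol * 10,
       test_bracket = c(fa, fb))
}

locate_bp <- function(from, tang, h, params, spec, pname, event_tol) {
  n <- length(from$w) - 1L
  bisect_event("BP", from, tang, h, params, spec, pname, event_tol,
               function(pt) {
                 pcur <- params_with(params, pname, pt$w[n + 1])
                 bordered_det(pt$w[seq_len(n)], pcur, spec, pname, pt$tang)
               })
}

locate_lp <- function(from, tang, h, params, spec, pname, event_tol) {
  n <- length(from$w) - 1L
  bisect_event("LP", from, tang, h, params, spec, pname, event_tol,
               function(pt) pt$tang[n + 1])
}

#' Plot an equilibrium branch
#'
#' Renders a bifurcation-diagram view of one branch: the continuation
#' parameter against a selected state component, solid where stable and
#' dashed where unstable, with localized events marked (BP as filled blue,
#' LP as filled red circles).
#'
#' @param x a `branch`.
#' @param component state component to plot (name or index; default `"x1"`).
#' @param file optional output path ending in `.svg` or `.png`; when `NULL`
#'   the current device is used.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.branch <- function(x, component = "x1", file = NULL, ...) {
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 5)
    else if (grepl("\\.png$", file)) grDevices::png(file, width = 900,
                                                   height = 640, res = 120)
    else stop("unsupported plot format for '", file, "' (use .svg/.png)")
    on.exit(grDevices::dev.off())
  }
  yv <- x$states[, component]
  pv <- x$points$param
  plot(pv, yv, type = "n", xlab = x$param_name, ylab = component,
       main = sprintf("branch in %s", x$param_name))
  st <- x$points$stable
  runs <- rle(st)
  i0 <- 1L
  for (k in seq_along(runs$lengths)) {
    i1 <- i0 + runs$lengths[k] - 1L
    idx <- max(1L, i0 - 1L):i1          # overlap one point for continuity
    graphics::lines(pv[idx], yv[idx], lty = if (runs$values[k]) 1 else 2,
                    lwd = if (runs$values[k]) 2 else 1)
    i0 <- i1 + 1L
  }
  for (e in x$events) {
    if (!isTRUE(e$localized)) next
    graphics::points(e$param, e$state[[match(component, colnames(x$states))]],
                     pch = 19, cex = 1.2,
                     col = if (e$kind == "BP") "blue" else "red")
    graphics::text(e$param, e$state[[match(component, colnames(x$states))]],
                   labels = e$kind, pos = 3)
  }
  invisible(x)
}

#' Switch onto the branch emanating from a branch point
#'
#' Perturbs the state along the critical eigenvector of the Jacobian at a
#' localized BP (both orientations), steps the parameter slightly past the
#' event, and Newton-corrects at fixed parameter. Candidates that fall back
#' onto the original branch are rejected. For the mirror-symmetric S model
#' the two returned points are sigma-images of each other.
#'
#' @param event a localized `BP` event from [continue_equilibrium()].
#' @param params,spec model context (the branch's `params` and `spec`).
#' @param param_name the continuation parameter.
#' @param p_offset parameter offset past the event at which to correct.
#' @param eps_scale perturbation magnitudes tried along the eigenvector.
#' @return list of `equilibrium_record`s on the bifurcating branch(es)
#'   (one per orientation that converged away from the original branch).
#' @export
branch_switch <- function(event, params, spec, param_name,
                          p_offset = 0.02, eps_scale = c(1, 2, 4, 8)) {
  if (!identical(event$kind, "BP"))
    stop("branch_switch requires a BP event, got ", event$kind)
  if (!isTRUE(event$localized)) stop("BP event is not localized")
  pstar <- event$param + p_offset
  pc <- params_with(params, param_name, pstar)
  pc_bp <- params_with(params, param_name, event$param)
  J <- toggle_jacobian(event$state, pc_bp, spec)
  ei <- eigen(J)
  i0 <- which.min(abs(Re(ei$values)))
  v <- Re(ei$vectors[, i0])
  v <- v / sqrt(sum(v^2))
  base <- tryCatch(find_equilibrium(event$state, pc, spec),
                   error = function(e) NULL)
  out <- list()
  for (orient in c(1, -1)) {
    for (eps in eps_scale) {
      cand <- tryCatch(find_equilibrium(pmax(event$state + orient * eps * v, 0),
                                        pc, spec),
                       error = function(e) NULL)
      if (is.null(cand)) next
      if (!is.null(base) &&
          max(abs(cand$state - base$state)) < 1e-4 * max(1, max(abs(base$state))))
        next                                    # fell back to original branch
      dup <- any(vapply(out, function(o)
        max(abs(o$state - cand$state)) < 1e-6, logical(1)))
      if (!dup) out[[length(out) + 1L]] <- cand
      break
    }
  }
  if (!length(out))
    stop("branch switch failed: corrector returned to the original branch ",
         "(try a larger perturbation)")
  out
}

#' Existence interval of a mixed state in the diffusion parameter
#'
#' Builds the requested `(p:q)`-mixed equilibrium at `bounds[1]`, continues
#' it in `d`, and reports the interval over which it keeps its signature and
#' stability together with the terminating event, or that it persists to the
#' upper bound.
#'
#' @param ratio length-2 integer vector `(N1, N2)` of subpopulation sizes.
#' @param params a [toggle_params()]; `params$d` is overridden by
#'   `bounds[1]`.
#' @param model `"S"` or `"A"`.
#' @param bounds `d` sweep interval.
#' @param ... passed to [continue_equilibrium()].
#' @return list with `stable_interval`, `terminal_event` (`"LP"`, `"BP"`, or
#'   `"persists"`), `branch`.
#' @export
mixed_state_elimination_scan <- function(ratio, params, model = "S",
                                         bounds = c(0.1, 10), ...) {
  spec <- population_spec(model, ratio)
  p0 <- params_with(params, "d", bounds[1])
  eq <- make_population_state(ratio, p0, model)
  if (!inherits(eq, "equilibrium_record"))
    stop("no stable mixed state at d = ", bounds[1])
  br <- continue_equilibrium(eq, "d", bounds, ...)
  stab <- br$points$stable
  # first loss of stability along the branch
  loss <- which(!stab)[1]
  if (length(br$events)) {
    ev1 <- br$events[[1]]
    hi <- ev1$param
    kind <- ev1$kind
  } else if (!is.na(loss)) {
    hi <- br$points$param[loss]
    kind <- "stability lost (no localized event)"
  } else {
    hi <- max(br$points$param)
    kind <- if (hi >= bounds[2] - 1e-6) "persists" else br$termination
  }
  list(stable_interval = c(bounds[1], hi), terminal_event = kind, branch = br)
}
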