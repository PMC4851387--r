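#' Perturbation plan for flip / neighborhood sampling experiments
#'
#' Describes how seeded synthetic initial conditions are generated around a
#' homogeneous equilibrium: a fraction of cells is flipped to the opposite
#' state's per-cell block and every component then receives multiplicative
#' lognormal noise.
#'
#' @param flip_fraction fraction of cells flipped, in `[0, 1]`.
#' @param noise_scale standard deviation of the log-multiplicative noise
#'   (`0.05` = 5% neighborhood).
#' @param n_samples number of sampled initial conditions.
#' @param seed integer seed; each sample uses the deterministic stream
#'   derived from `(seed, sample index)`.
#' @return A `perturbation_plan` object.
#' @export
perturbation_plan <- function(flip_fraction = 0.1, noise_scale = 0.05,
                              n_samples = 25, seed = 1) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1, noise_scale >= 0,
            n_samples >= 1)
  structure(list(flip_fraction = flip_fraction, noise_scale = noise_scale,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "perturbation_plan")
}

#' Construct a (p:q)-mixed population equilibrium
#'
#' Builds the block initial guess — cells of the first subpopulation at the
#' single-toggle G-state, cells of the second at the R-state, extracellular
#' variables at their mean-field balance — and Newton-refines. If Newton
#' converges to a state whose signature differs from the requested ratio the
#' requested mixed state does not exist there and a nonexistence report is
#' returned instead.
#'
#' @param ratio integer vector of subpopulation sizes, G-cells first (e.g.
#'   `c(9, 1)`; a single number or `c(n, 0)` gives a homogeneous G
#'   population).
#' @param params a [toggle_params()] (its `d` is used as-is).
#' @param model `"S"` or `"A"`.
#' @return An `equilibrium_record`, or a list with `exists = FALSE`, the
#'   requested ratio, and the record actually found.
#' @export
make_population_state <- function(ratio, params, model = c("S", "A")) {
  model <- match.arg(model)
  ratio <- as.integer(ratio)
  ratio_nz <- ratio[ratio > 0]
  spec <- population_spec(model, ratio_nz)
  single <- single_toggle_equilibria(params, model)
  sst <- single[single$stable, , drop = FALSE]
  G <- sst[sst$label == "G", , drop = FALSE]
  R <- sst[sst$label == "R", , drop = FALSE]
  if (nrow(G) < 1 || (length(ratio) > 1 && ratio[2] > 0 && nrow(R) < 1))
    stop("required single-toggle states not found (not bistable here?)")
  nc <- spec$n_cell
  gblk <- unlist(G[1, seq_len(nc)])
  rblk <- if (nrow(R)) unlist(R[1, seq_len(nc)]) else gblk
  nG <- ratio[1]
  nR <- if (length(ratio) > 1) ratio[2] else 0L
  cells <- matrix(gblk, nG, nc, byrow = TRUE)
  if (nR > 0) cells <- rbind(cells, matrix(rblk, nR, nc, byrow = TRUE))
  # mean-field balance of the medium: e = rho d mean(intracellular)/(rho d + delta_e)
  p <- params
  coef <- p$rho * p$d / (p$rho * p$d + p$delta_e)
  ext <- if (model == "S") {
    c(coef * mean(cells[, 3]), coef * mean(cells[, 4]))
  } else coef * mean(cells[, 3])
  guess <- population_state(spec, cells, ext)
  eq <- tryCatch(find_equilibrium(guess, params, spec),
                 qstoggle_no_convergence = function(e) NULL)
  if (is.null(eq))
    return(list(exists = FALSE, requested = ratio, found = NULL))
  want <- c(G = nG, R = nR)
  got <- eq$signature$counts
  if (got["G"] != want["G"] || got["R"] != want["R"]) {
    return(list(exists = FALSE, requested = ratio, found = eq))
  }
  eq
}

#' Generate seeded initial conditions around a homogeneous state
#'
#' For each sample: start from the base equilibrium, replace the designated
#' fraction of cells (the trailing ones) by the opposite equilibrium's
#' per-cell block, then multiply every component by `exp(eps)` with
#' `eps ~ Normal(0, noise_scale^2)` drawn from the deterministic stream for
#' `(seed, sample index)`. Bit-for-bit reproducible for a fixed seed.
#'
#' @param base an `equilibrium_record` of a homogeneous population.
#' @param opposite an `equilibrium_record` of the opposite homogeneous
#'   population (ignored when `flip_fraction = 0`).
#' @param plan a [perturbation_plan()].
#' @return list of packed state vectors, with attribute `n_flipped`.
#' @export
generate_initial_conditions <- function(base, opposite, plan) {
  spec <- base$spec
  N <- spec$N
  nflip_raw <- plan$flip_fraction * N
  nflip <- as.integer(round(nflip_raw))
  if (abs(nflip_raw - nflip) > 1e-9)
    warning("flip_fraction * N = ", nflip_raw, " is not integral; rounded to ",
            nflip)
  z0 <- as.numeric(base$state)
  if (nflip > 0) {
    opp <- unpack_state(opposite$state, spec)$cells
    nc <- spec$n_cell
    for (k in seq_len(nflip)) {
      i <- N - k + 1L                       # flip the trailing cells
      z0[(i - 1L) * nc + seq_len(nc)] <- opp[i, ]
    }
  }
  out <- vector("list", plan$n_samples)
  for (s in seq_len(plan$n_samples)) {
    rng <- local_rng(plan$seed * 10007L + s)
    eps <- stats::rnorm(spec$n_state, 0, plan$noise_scale)
    restore_rng(rng)
    z <- z0 * exp(eps)
    names(z) <- state_names(spec)
    out[[s]] <- z
  }
  attr(out, "n_flipped") <- nflip
  out
}

#' Majority-vote self-correction experiment
#'
#' Implements the three-step protocol, in order, for each diffusion value:
#' (1) find the stable G- and R-homogeneous population equilibria, (2) flip
#' the plan's fraction of cells of the G-homogeneous state to the R block,
#' (3) sample initial conditions in the multiplicative neighborhood of the
#' flipped configuration and integrate each to a long horizon. A sample is
#' `corrected` when the trajectory converges to an equilibrium whose cells
#' all carry the majority's original signature; `correction_time` is the
#' first sampled time from which every cell holds that signature through the
#' end of the run. Samples that do not converge within the horizon are
#' reported `undecided`, never counted as corrected.
#'
#' @param model `"S"` or `"A"`.
#' @param params a [toggle_params()] (its `d` is overridden per run).
#' @param d_values diffusion coefficients to test.
#' @param N population size.
#' @param plan a [perturbation_plan()].
#' @param horizon integration horizon (dimensionless time).
#' @param majority `"G"` (default; for the mirror-symmetric S design the
#'   R-majority case is its sigma-image).
#' @return data.frame with one row per `(d, sample)`: terminal ratio,
#'   `corrected`, `correction_time`, `converged`, `terminal_residual`.
#' @export
self_correction_experiment <- function(model, params, d_values = c(0.01, 10, 100),
                                       N = 10, plan = perturbation_plan(),
                                       horizon = 500, majority = "G") {
  out <- list()
  for (d in d_values) {
    p <- params_with(params, "d", d)
    spec <- population_spec(model, N)
    homG <- make_population_state(N, p, model)
    if (!inherits(homG, "equilibrium_record") || !homG$stable)
      stop("no stable G-homogeneous state at d = ", d)
    # R-homogeneous state: mirror image (S) or direct construction (A)
    homR <- homogeneous_R_state(N, p, model, spec)
    base <- if (majority == "G") homG else homR
    oppo <- if (majority == "G") homR else homG
    ics <- generate_initial_conditions(base, oppo, plan)
    for (s in seq_along(ics)) {
      res <- run_correction_sample(ics[[s]], p, spec, horizon, majority)
      out[[length(out) + 1L]] <- cbind(data.frame(d = d, sample = s), res)
    }
  }
  do.call(rbind, out)
}

homogeneous_R_state <- function(N, params, model, spec) {
  if (model == "S" && is_mirror_symmetric(params)) {
    eqG <- make_population_state(N, params, model)
    st <- mirror_map(eqG$state, spec)
    find_equilibrium(st, params, spec)
  } else {
    single <- single_toggle_equilibria(params, model)
    R <- single[single$stable & single$label == "R", , drop = FALSE]
    if (!nrow(R)) stop("no stable single-toggle R state")
    nc <- spec$n_cell
    cells <- matrix(unlist(R[1, seq_len(nc)]), N, nc, byrow = TRUE)
    coef <- params$rho * params$d / (params$rho * params$d + params$delta_e)
    ext <- if (model == "S") coef * c(mean(cells[, 3]), mean(cells[, 4]))
           else coef * mean(cells[, 3])
    find_equilibrium(population_state(spec, cells, ext), params, spec)
  }
}

run_correction_sample <- function(z0, params, spec, horizon, majority) {
  # the vector-field norm near an equilibrium scales with the fastest rate
  # (~ d + delta), so the early-stop tolerance must too; final convergence is
  # then certified by a Newton polish (the trajectory has entered the basin)
  rate <- max(1, params$d)
  sol <- integrate_toggles(z0, params, spec,
                           times = seq(0, horizon, length.out = 201),
                           stop_at_equilibrium = TRUE,
                           equilibrium_tol = 1e-6 * rate)
  nt_real <- if (sol$converged) sum(sol$times <= sol$t_end) + 1L
             else length(sol$times)
  nt_real <- min(nt_real, length(sol$times))
  zT <- sol$states[nrow(sol$states), ]
  polish <- if (sol$converged || sol$f_norm < 1e-4 * rate) {
    tryCatch(find_equilibrium(zT, params, spec),
             error = function(e) NULL)
  } else NULL
  converged <- !is.null(polish) && polish$stable &&
    max(abs(polish$state - zT)) < 1e-3 * (1 + max(abs(polish$state)))
  if (converged) zT <- polish$state
  sig <- state_signature(zT, spec)
  all_major <- function(z) {
    s <- state_signature(z, spec)
    all(s$labels == majority)
  }
  corrected <- converged && all_major(zT)
  ctime <- NA_real_
  if (corrected) {
    # first sampled time from which the majority signature holds through the end
    ok <- vapply(seq_len(nt_real), function(i) all_major(sol$states[i, ]),
                 logical(1))
    run <- rev(cumprod(rev(ok)))          # 1 where suffix is all-TRUE
    ctime <- sol$times[which(run == 1)[1]]
  }
  data.frame(terminal_ratio = sig$ratio,
             corrected = corrected,
             correction_time = ctime,
             converged = converged,
             undecided = !converged,
             terminal_residual = sol$f_norm)
}

#' Global convergence probe
#'
#' Integrates seeded random initial conditions (componentwise log-uniform
#' over `[1e-3, 50]`) and reports, per trajectory, whether the terminal
#' vector-field norm certifies convergence to an equilibrium and whether the
#' sustained-oscillation probe fires. For the strongly monotone S design
#' every typical trajectory must converge with no sustained oscillation.
#'
#' @param model `"S"` or `"A"`.
#' @param params a [toggle_params()].
#' @param n_ic number of random initial conditions.
#' @param N population size.
#' @param horizon integration horizon (0 leaves every trajectory undecided).
#' @param seed RNG seed.
#' @param conv_tol terminal `||f||_inf` declaring convergence.
#' @return data.frame: one row per trajectory with `converged`,
#'   `oscillating`, `f_norm`, `ratio` of the reached state.
#' @export
convergence_probe <- function(model, params, n_ic = 50, N = 3, horizon = 500,
                              seed = 1, conv_tol = 1e-8) {
  spec <- population_spec(model, N)
  rng <- local_rng(seed)
  ics <- lapply(seq_len(n_ic), function(k)
    exp(stats::runif(spec$n_state, log(1e-3), log(50))))
  restore_rng(rng)
  rows <- lapply(seq_len(n_ic), function(k) {
    sol <- integrate_toggles(ics[[k]], params, spec,
                             times = seq(0, horizon, length.out = 101),
                             stop_at_equilibrium = TRUE,
                             equilibrium_tol = min(conv_tol, 1e-9))
    osc <- detect_oscillation(sol)
    conv <- horizon > 0 && (sol$converged || sol$f_norm < conv_tol)
    data.frame(ic = k,
               converged = conv,
               undecided = !conv,
               oscillating = osc$oscillating,
               f_norm = sol$f_norm,
               ratio = state_signature(sol$states[nrow(sol$states), ],
                                       spec)$ratio)
  })
  do.call(rbind, rows)
}
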