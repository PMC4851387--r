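#' Dimensionless toggle model parameters
#'
#' Constructs and validates the full dimensionless parameter set shared by the
#' S (symmetric, two quorum-sensing arms) and A (asymmetric, one arm) toggle
#' population models. All quantities are dimensionless after scaling time by
#' the repressor decay rate; see the package vignette for the scaling.
#'
#' @param a1,a2 maximal repression-controlled synthesis rates of the two
#'   repressors (LacI, TetR).
#' @param a3,a4 maximal autoinducer-activated synthesis rates of the
#'   repressors (C14-HSL acting on `x`, C4-HSL acting on `y`).
#' @param a5,a6 maximal synthesis rates of the intracellular autoinducers.
#' @param nX,nY,nG,nR Hill coefficients (>= 1) for repression by LacI/TetR and
#'   activation by C14-HSL/C4-HSL respectively.
#' @param gamma_x,gamma_y,gamma_g,gamma_r promoter leakiness (basal synthesis).
#' @param d dimensionless membrane diffusion (export/import) coefficient; the
#'   usual bifurcation parameter.
#' @param delta_g,delta_r lumped dilution-degradation rates of the
#'   intracellular autoinducers (> 0).
#' @param delta_e extracellular autoinducer dilution rate (> 0).
#' @param rho population density in `[0, 1]`.
#' @return An object of class `toggle_params` (a named list).
#' @seealso [toggle_preset()], [mirror_params()], [nondimensionalize()]
#' @export
#' @examples
#' p <- toggle_preset("reference")
#' p$a1
toggle_params <- function(a1 = 20, a2 = 20, a3 = 10, a4 = 10, a5 = 3, a6 = 3,
                          nX = 3, nY = 3, nG = 3, nR = 3,
                          gamma_x = 0, gamma_y = 0, gamma_g = 0, gamma_r = 0,
                          d = 0.1, delta_g = 1, delta_r = 1, delta_e = 0.5,
                          rho = 0.8) {
  p <- list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6,
            nX = nX, nY = nY, nG = nG, nR = nR,
            gamma_x = gamma_x, gamma_y = gamma_y,
            gamma_g = gamma_g, gamma_r = gamma_r,
            d = d, delta_g = delta_g, delta_r = delta_r, delta_e = delta_e,
            rho = rho)
  p <- lapply(p, function(v) {
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
    as.numeric(v)
  })
  validate_toggle_params(p)
  structure(p, class = "toggle_params")
}

validate_toggle_params <- function(p) {
  nonneg <- c("a1", "a2", "a3", "a4", "a5", "a6",
              "gamma_x", "gamma_y", "gamma_g", "gamma_r", "d")
  for (f in nonneg)
    if (p[[f]] < 0) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  for (f in c("delta_g", "delta_r", "delta_e"))
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0", call. = FALSE)
  for (f in c("nX", "nY", "nG", "nR"))
    if (p[[f]] < 1) stop("Hill coefficient '", f, "' must be >= 1", call. = FALSE)
  if (p$rho < 0 || p$rho > 1) stop("'rho' must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Named parameter presets
#'
#' `"reference"` is the working parameter set used throughout the analysis:
#' zero leakiness, `a1 = a2 = 20`, `a3 = a4 = 10`, `a5 = a6 = 3`, all Hill
#' coefficients 3, `delta_g = delta_r = 1`, `delta_e = 0.5`, `rho = 0.8`.
#' `"modified"` overrides it with nonzero leakiness 0.01, `a1 = a2 = 100`,
#' `nX = nY = 2`, `nG = 1`, `nR = 2`; since `nG != nR` this set deliberately
#' breaks the mirror symmetry of the S design. The diffusion coefficient `d`
#' is not part of either published set (it is the bifurcation parameter); the
#' presets carry the weak-coupling default `d = 0.1`, override as needed.
#'
#' @param name `"reference"` or `"modified"`.
#' @param ... individual parameter overrides passed on top of the preset,
#'   e.g. `d = 10`.
#' @return A [toggle_params()] object.
#' @export
toggle_preset <- function(name = c("reference", "modified"), ...) {
  name <- match.arg(name)
  base <- list(a1 = 20, a2 = 20, a3 = 10, a4 = 10, a5 = 3, a6 = 3,
               nX = 3, nY = 3, nG = 3, nR = 3,
               gamma_x = 0, gamma_y = 0, gamma_g = 0, gamma_r = 0,
               d = 0.1, delta_g = 1, delta_r = 1, delta_e = 0.5, rho = 0.8)
  if (name == "modified") {
    base[c("gamma_x", "gamma_y", "gamma_g", "gamma_r")] <- 0.01
    base[c("a1", "a2")] <- 100
    base[c("nX", "nY")] <- 2
    base$nG <- 1
    base$nR <- 2
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    base[names(over)] <- over
  }
  do.call(toggle_params, base)
}

#' @export
print.toggle_params <- function(x, ...) {
  cat("<toggle_params>\n")
  cat(sprintf("  rates      a1..a6 = %s\n",
              paste(unlist(x[c("a1", "a2", "a3", "a4", "a5", "a6")]),
                    collapse = ", ")))
  cat(sprintf("  Hill       nX=%g nY=%g nG=%g nR=%g\n", x$nX, x$nY, x$nG, x$nR))
  cat(sprintf("  leakiness  %g, %g, %g, %g\n",
              x$gamma_x, x$gamma_y, x$gamma_g, x$gamma_r))
  cat(sprintf("  d=%g delta_g=%g delta_r=%g delta_e=%g rho=%g\n",
              x$d, x$delta_g, x$delta_r, x$delta_e, x$rho))
  if (is_mirror_symmetric(x)) cat("  mirror-symmetric\n")
  invisible(x)
}

# parameter pairs exchanged by the green<->red mirror involution
.mirror_pairs <- list(c("a1", "a2"), c("a3", "a4"), c("a5", "a6"),
                      c("nX", "nY"), c("nG", "nR"),
                      c("gamma_x", "gamma_y"), c("gamma_g", "gamma_r"),
                      c("delta_g", "delta_r"))

#' Mirror involution on parameters
#'
#' Swaps the parameter pairs exchanged by the green/red mirror symmetry of the
#' S design: `a1<->a2`, `a3<->a4`, `a5<->a6`, `nX<->nY`, `nG<->nR`,
#' `gamma_x<->gamma_y`, `gamma_g<->gamma_r`, `delta_g<->delta_r`. Applying it
#' twice is the identity.
#'
#' @param params a [toggle_params()] object.
#' @return The mirrored `toggle_params`.
#' @export
mirror_params <- function(params) {
  stopifnot(inherits(params, "toggle_params"))
  q <- params
  for (pr in .mirror_pairs) {
    q[[pr[1]]] <- params[[pr[2]]]
    q[[pr[2]]] <- params[[pr[1]]]
  }
  q
}

#' Is a parameter set a fixed point of the mirror swap?
#'
#' @inheritParams mirror_params
#' @param tol comparison tolerance.
#' @return `TRUE` when every mirrored pair has equal values, i.e. the S model
#'   with these parameters is equivariant under the mirror map.
#' @export
is_mirror_symmetric <- function(params, tol = 0) {
  all(vapply(.mirror_pairs, function(pr) {
    abs(params[[pr[1]]] - params[[pr[2]]]) <= tol
  }, logical(1)))
}

#' Dimensional (biochemical) parameters
#'
#' Container for the dimensional rates from which the dimensionless model
#' parameters derive: burst sizes `b_*`, transcription/synthesis rates `k_*`,
#' promoter copy numbers `P_X`..`P_R`, repression thresholds `K_X`, `K_Y`,
#' activation thresholds `K_G`, `K_R`, autoinducer export rates `D_G`, `D_R`,
#' degradation rates `r_d` (repressors), `r_G`, `r_R` (autoinducers), and
#' growth rates `mu` (cellular) and `mu_e` (medium flow). All strictly
#' positive.
#'
#' @param ... named positive scalars; all of the fields listed above must be
#'   supplied (no defaults, these are experiment-specific).
#' @return An object of class `dimensional_params`.
#' @seealso [nondimensionalize()]
#' @export
dimensional_params <- function(...) {
  vals <- list(...)
  need <- c("b_x", "b_y", "b_u", "b_w", "k_x", "k_y", "k_u", "k_w",
            "k_G", "k_R", "P_X", "P_Y", "P_G", "P_R",
            "K_X", "K_Y", "K_G", "K_R", "D_G", "D_R",
            "r_d", "r_G", "r_R", "mu", "mu_e")
  miss <- setdiff(need, names(vals))
  if (length(miss)) stop("missing dimensional parameter(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(names(vals), need)
  if (length(bad)) stop("unknown dimensional parameter(s): ",
                        paste(bad, collapse = ", "))
  for (f in need) {
    v <- vals[[f]]
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
    if (v <= 0) stop("dimensional parameter '", f, "' must be > 0")
  }
  structure(vals[need], class = "dimensional_params")
}

#' Convert dimensional parameters to the dimensionless set
#'
#' Time is scaled by the total repressor decay rate `r_d + mu`. The rate
#' groups become
#' `a1 = b_x k_x P_Y / (K_X (r_d + mu))`, `a2 = b_y k_y P_X / (K_Y (r_d + mu))`,
#' `a3 = b_x k_x P_G / (K_X (r_d + mu))`, `a4 = b_y k_y P_R / (K_Y (r_d + mu))`,
#' `a5 = b_u k_u k_G P_Y / (K_G (r_d + mu)^2)`,
#' `a6 = b_w k_w k_R P_X / (K_R (r_d + mu)^2)`,
#' the diffusion coefficients `d_g = D_G / (r_d + mu)`,
#' `d_r = D_R / (r_d + mu)`, and the degradation ratios
#' `delta_g = (r_G + mu) / (r_d + mu)`, `delta_r = (r_R + mu) / (r_d + mu)`,
#' `delta_e = mu_e / (r_d + mu)`.
#'
#' The two arms may have different dimensional export rates; the dimensionless
#' models use a single `d`, so the result carries `d = d_g` together with the
#' attribute `d_r` for callers that need the red-arm value.
#'
#' @param dim a [dimensional_params()] object.
#' @param hill optional named list of Hill coefficients (`nX`, `nY`, `nG`,
#'   `nR`), which are already dimensionless; default all 3.
#' @return A [toggle_params()] object (leakiness zero, `rho = 0.8` default).
#' @export
nondimensionalize <- function(dim, hill = list()) {
  stopifnot(inherits(dim, "dimensional_params"))
  s <- dim$r_d + dim$mu
  h <- list(nX = 3, nY = 3, nG = 3, nR = 3)
  h[names(hill)] <- hill
  p <- toggle_params(
    a1 = dim$b_x * dim$k_x * dim$P_Y / (dim$K_X * s),
    a2 = dim$b_y * dim$k_y * dim$P_X / (dim$K_Y * s),
    a3 = dim$b_x * dim$k_x * dim$P_G / (dim$K_X * s),
    a4 = dim$b_y * dim$k_y * dim$P_R / (dim$K_Y * s),
    a5 = dim$b_u * dim$k_u * dim$k_G * dim$P_Y / (dim$K_G * s^2),
    a6 = dim$b_w * dim$k_w * dim$k_R * dim$P_X / (dim$K_R * s^2),
    nX = h$nX, nY = h$nY, nG = h$nG, nR = h$nR,
    d = dim$D_G / s,
    delta_g = (dim$r_G + dim$mu) / s,
    delta_r = (dim$r_R + dim$mu) / s,
    delta_e = dim$mu_e / s)
  attr(p, "d_r") <- dim$D_R / s
  p
}

#' Read / write parameter presets
#'
#' Serializes a parameter set to JSON or YAML (chosen by file extension) as a
#' flat mapping with the exact field names of [toggle_params()]. On reading,
#' unknown keys are rejected.
#'
#' @param params a [toggle_params()] object.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_params` returns a `toggle_params`; `write_params` returns
#'   `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "toggle_params"))
  vals <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else stop("unsupported extension for '", path, "' (use .json/.yaml)")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("unsupported extension for '", path, "' (use .json/.yaml)")
  known <- names(formals(toggle_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown key(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  do.call(toggle_params, vals)
}
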