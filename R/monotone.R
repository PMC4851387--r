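#' Signed species-influence graph
#'
#' One node per state variable; a directed edge `j -> i` labelled +1
#' (activation) or -1 (inhibition) whenever the Jacobian entry
#' `d f_i / d z_j` is sign-definite and not identically zero over the
#' positive orthant. Self-edges are excluded regardless of the diagonal
#' sign. Edges and signs are derived from the analytic model structure and
#' additionally validated by sampling the Jacobian at random positive states
#' (components log-uniform in `[1e-3, 1e2]`); a sampled sign flip anywhere
#' raises an error, since the monotonicity framework assumes globally
#' constant signs.
#'
#' @param spec a [population_spec()].
#' @param params a [toggle_params()]; an edge whose sign claim depends on a
#'   rate (e.g. `a3 > 0` for the `g -> x` edge) is dropped when that rate is
#'   zero.
#' @param n_check number of random states for the numeric validation
#'   (0 skips it).
#' @param seed RNG seed for the validation sample.
#' @return An `influence_graph`: list with `nodes`, `edges`
#'   (data.frame `from, to, sign`), and `spec`.
#' @export
influence_graph <- function(spec, params = toggle_preset("reference"),
                            n_check = 100, seed = 1) {
  nodes <- state_names(spec)
  N <- spec$N
  p <- params
  ed <- function(from, to, sign) data.frame(from = from, to = to, sign = sign)
  edges <- list()
  add <- function(e) edges[[length(edges) + 1L]] <<- e
  for (i in seq_len(N)) {
    x <- paste0("x", i); y <- paste0("y", i); r <- paste0("r", i)
    if (spec$model == "S") {
      g <- paste0("g", i)
      if (p$a1 > 0) add(ed(y, x, -1))
      if (p$a3 > 0) add(ed(g, x, +1))
      if (p$a2 > 0) add(ed(x, y, -1))
      if (p$a4 > 0) add(ed(r, y, +1))
      if (p$a5 > 0) add(ed(y, g, -1))
      if (p$d > 0) { add(ed("g_e", g, +1)); add(ed(g, "g_e", +1)) }
      if (p$a6 > 0) add(ed(x, r, -1))
      if (p$d > 0) { add(ed("r_e", r, +1)); add(ed(r, "r_e", +1)) }
    } else {
      if (p$a1 > 0) add(ed(y, x, -1))
      if (p$a4 > 0) add(ed(r, x, +1))
      if (p$a2 > 0) add(ed(x, y, -1))
      if (p$a6 > 0) add(ed(x, r, -1))
      if (p$d > 0) { add(ed("r_e", r, +1)); add(ed(r, "r_e", +1)) }
    }
  }
  edges <- unique(do.call(rbind, edges))
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges, spec = spec),
                 class = "influence_graph")
  if (n_check > 0) validate_graph_signs(g, params, n_check, seed)
  g
}

# sample the Jacobian at random positive states; check off-diagonal signs
# agree with the declared edge structure everywhere
validate_graph_signs <- function(graph, params, n_check, seed) {
  spec <- graph$spec
  nodes <- graph$nodes
  key <- paste(graph$edges$from, graph$edges$to)
  sgn <- graph$edges$sign[order(key)]
  key <- sort(key)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  for (k in seq_len(n_check)) {
    z <- exp(stats::runif(spec$n_state, log(1e-3), log(1e2)))
    J <- toggle_jacobian(z, params, spec)
    off <- which(J != 0 & row(J) != col(J), arr.ind = TRUE)
    kk <- paste(nodes[off[, 2]], nodes[off[, 1]])
    pos <- match(kk, key)
    if (anyNA(pos))
      stop("sign-indefiniteness: Jacobian entry outside declared edges at ",
           paste(kk[is.na(pos)], collapse = "; "), call. = FALSE)
    if (any(sign(J[off]) != sgn[pos]))
      stop("sign-indefiniteness: sampled Jacobian sign contradicts edge label",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.influence_graph <- function(x, ...) {
  cat(sprintf("<influence_graph> %s model, %d nodes, %d edges (%d+, %d-)\n",
              x$spec$model, length(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

as_igraph <- function(graph) {
  ig <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                      vertices = graph$nodes)
  igraph::E(ig)$sign <- ifelse(graph$edges$sign > 0, "+", "-")
  ig
}

#' Export an influence graph in DOT format
#' @param graph an [influence_graph()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_dot <- function(graph, path) {
  lines <- c("digraph influence {",
             sprintf("  \"%s\";", graph$nodes),
             sprintf("  \"%s\" -> \"%s\" [sign=\"%s\"];",
                     graph$edges$from, graph$edges$to,
                     ifelse(graph$edges$sign > 0, "+", "-")),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Orthant partition of a signed graph (balance test)
#'
#' A system is monotone with respect to an orthant order iff its signed
#' influence graph is balanced: the nodes can be 2-coloured so that +1 edges
#' join like colours and -1 edges join unlike colours. The partition is found
#' by BFS sign propagation over the undirected support; on failure a cycle
#' with an odd number of negative edges is returned as witness.
#'
#' @param graph an [influence_graph()].
#' @return If balanced, an `orthant_partition`: list with `balanced = TRUE`,
#'   `S_plus`, `S_minus` (node sets; the component containing `x1` is placed
#'   in `S_plus`). Otherwise `balanced = FALSE` plus `witness`, a closed node
#'   walk with an odd number of negative edges.
#' @export
find_orthant_partition <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  colr <- rep(NA_integer_, n)
  names(colr) <- nodes
  # undirected adjacency with signs; parallel edges of conflicting sign would
  # themselves be a 2-cycle witness
  adj <- vector("list", n)
  names(adj) <- nodes
  for (e in seq_len(nrow(graph$edges))) {
    f <- graph$edges$from[e]; t <- graph$edges$to[e]; s <- graph$edges$sign[e]
    adj[[f]] <- rbind(adj[[f]], data.frame(to = t, sign = s))
    adj[[t]] <- rbind(adj[[t]], data.frame(to = f, sign = s))
  }
  parent <- rep(NA_character_, n)
  names(parent) <- nodes
  for (root in nodes) {
    if (!is.na(colr[root])) next
    colr[root] <- 1L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (e in seq_len(nrow(nb))) {
        w <- nb$to[e]
        want <- colr[v] * nb$sign[e]
        if (is.na(colr[w])) {
          colr[w] <- want
          parent[w] <- v
          queue <- c(queue, w)
        } else if (colr[w] != want) {
          # odd-negative cycle: path(v..root) + path(w..root) + edge (v,w)
          pv <- path_to_root(v, parent)
          pw <- path_to_root(w, parent)
          common <- intersect(pv, pw)
          anc <- common[1]
          cyc <- c(rev(pv[seq_len(match(anc, pv))]), # anc .. v
                   pw[seq_len(match(anc, pw) - 1)])  # w .. just below anc
          return(list(balanced = FALSE,
                      witness = c(cyc, cyc[1])))
        }
      }
    }
  }
  # orient so the green arm (x nodes) sits in S_plus
  if (!is.na(colr["x1"]) && colr["x1"] < 0) colr <- -colr
  structure(list(balanced = TRUE,
                 S_plus = nodes[colr > 0],
                 S_minus = nodes[colr < 0]),
            class = "orthant_partition")
}

path_to_root <- function(v, parent) {
  out <- v
  while (!is.na(parent[v])) {
    v <- parent[v]
    out <- c(out, v)
  }
  out
}

#' @export
print.orthant_partition <- function(x, ...) {
  cat("<orthant_partition>\n  S_plus:  ", paste(x$S_plus, collapse = ", "),
      "\n  S_minus: ", paste(x$S_minus, collapse = ", "), "\n")
  invisible(x)
}

#' Export a partition as JSON
#' @param partition an `orthant_partition`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(list(S_plus = partition$S_plus,
                            S_minus = partition$S_minus),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' Strong connectivity of the influence graph
#'
#' Decides strong connectivity of the directed graph ignoring signs. With
#' `certificate = TRUE` also returns, for the first two cells, a directed
#' path `x_j -> ... -> x_i` through both quorum-sensing arms witnessing
#' inter-cell reachability.
#'
#' @param graph an [influence_graph()].
#' @param certificate return a witness path.
#' @return logical, with attribute `path` when requested.
#' @export
is_strongly_connected <- function(graph, certificate = FALSE) {
  ig <- as_igraph(graph)
  ok <- igraph::is_connected(ig, mode = "strong")
  if (certificate && ok && graph$spec$N >= 2) {
    sp <- igraph::shortest_paths(ig, from = "x2", to = "x1", mode = "out")
    attr(ok, "path") <- names(sp$vpath[[1]])
  }
  ok
}

#' Kamke order-preservation check
#'
#' For a monotone flow, initial conditions ordered in the orthant order stay
#' ordered for all time. The orthant order used here is oriented "larger =
#' greener": components in `S_plus` (the `x, g, g_e` arm) compare with `>=`
#' and components in `S_minus` (`y, r, r_e`) with `<=`. Both trajectories
#' are integrated together as one coupled system with a shared adaptive step
#' sequence, so discretization errors are strongly correlated and the order
#' comparison is meaningful at tight tolerance.
#'
#' @param state_lo,state_hi initial states with `state_lo <= state_hi` in the
#'   orthant order (checked; violation is an error).
#' @param params a [toggle_params()].
#' @param spec a [population_spec()].
#' @param partition an `orthant_partition` for `spec` (default: computed).
#' @param horizon integration horizon.
#' @param n_times number of sample times at which the order is asserted.
#' @param tol absolute tolerance absorbing integrator round-off.
#' @return list with `ok`, and on failure `first_violation` (time, component,
#'   magnitude).
#' @export
kamke_order_check <- function(state_lo, state_hi, params, spec,
                              partition = NULL, horizon = 50, n_times = 26,
                              tol = 1e-9) {
  if (is.null(partition))
    partition <- find_orthant_partition(influence_graph(spec, params,
                                                        n_check = 0))
  if (!isTRUE(partition$balanced))
    stop("kamke_order_check needs a balanced (monotone) partition")
  sgn <- ifelse(state_names(spec) %in% partition$S_plus, 1, -1)
  gap0 <- sgn * (state_hi - state_lo)
  if (any(gap0 < -tol))
    stop("initial states are not ordered (state_lo <= state_hi required)")
  n <- spec$n_state
  pair_rhs <- function(z) c(toggle_rhs(z[seq_len(n)], params, spec),
                            toggle_rhs(z[n + seq_len(n)], params, spec))
  sol <- integrate_toggles(c(state_lo, state_hi), params, spec,
                           times = seq(0, horizon, length.out = n_times),
                           rhs = pair_rhs, stop_at_equilibrium = FALSE)
  lo <- sol$states[, seq_len(n), drop = FALSE]
  hi <- sol$states[, n + seq_len(n), drop = FALSE]
  gap <- sweep(hi - lo, 2, sgn, `*`)
  bad <- which(gap < -tol, arr.ind = TRUE)
  if (nrow(bad)) {
    w <- which.min(gap)
    ij <- arrayInd(w, dim(gap))
    return(list(ok = FALSE,
                first_violation = list(time = sol$times[bad[1, 1]],
                                       component = state_names(spec)[bad[1, 2]],
                                       magnitude = -min(gap))))
  }
  list(ok = TRUE, min_gap = min(gap))
}

# partition side of the eight monotone parameters: +1 if the parameter node
# would be coloured with S_plus, -1 for S_minus
.param_side <- c(a1 = +1, a2 = -1, a3 = +1, a4 = -1, a5 = +1, a6 = -1,
                 delta_g = -1, delta_r = +1)

#' Monotone parametric-shift check at a stable equilibrium
#'
#' The eight rate/degradation parameters `a1..a6, delta_g, delta_r` embed as
#' constant state variables of the extended monotone system, each acquiring a
#' side of the orthant partition (e.g. `a5` drives `g`, so it sits with the
#' green set; `delta_g` degrades `g`, so it sits with the red set). For a
#' stable equilibrium, increasing a green-side parameter must weakly increase
#' every `S_plus` component and weakly decrease every `S_minus` component,
#' and symmetrically. This function re-solves the equilibrium at the
#' incremented parameter (Newton continuation from the old state) and
#' verifies the componentwise directions.
#'
#' @param eq a stable `equilibrium_record` of the S model.
#' @param param_name one of `a1..a6`, `delta_g`, `delta_r`.
#' @param increment additive parameter change (may be negative).
#' @param tol weak-inequality tolerance.
#' @return list with `ok`, `shift` (componentwise change), `expected_sign`,
#'   and `new_eq`.
#' @export
parametric_monotonicity_check <- function(eq, param_name, increment,
                                          tol = 1e-7) {
  if (!param_name %in% names(.param_side))
    stop("'", param_name, "' is not one of the eight monotone parameters")
  if (!eq$stable) stop("equilibrium must be exponentially stable")
  spec <- eq$spec
  p1 <- eq$params
  p1[[param_name]] <- p1[[param_name]] + increment
  validate_toggle_params(p1)
  new_eq <- tryCatch(find_equilibrium(eq$state, p1, spec),
                     error = function(e)
                       stop("equilibrium lost within the increment ",
                            "(fold crossed?): ", conditionMessage(e),
                            call. = FALSE))
  if (!identical(new_eq$signature$labels, eq$signature$labels))
    stop("equilibrium lost within the increment (signature changed)",
         call. = FALSE)
  part <- find_orthant_partition(influence_graph(spec, p1, n_check = 0))
  sgn <- ifelse(state_names(spec) %in% part$S_plus, 1, -1)
  dir <- sign(increment) * .param_side[[param_name]]
  shift <- new_eq$state - eq$state
  ok <- all(dir * sgn * shift >= -tol)
  list(ok = ok, shift = shift, expected_sign = dir * sgn, new_eq = new_eq)
}

#' Sustained-oscillation probe
#'
#' A trajectory is flagged non-convergent when, within its last 20% time
#' window, some component's derivative changes sign at least `min_flips`
#' times with oscillation amplitude above `amplitude`. Damped ringing below
#' the amplitude floor does not trigger the flag.
#'
#' @param sol result of [integrate_toggles()].
#' @param min_flips sign-change count threshold.
#' @param amplitude peak-to-trough amplitude floor.
#' @return list with `oscillating`, `worst_component`, `flips`.
#' @export
detect_oscillation <- function(sol, min_flips = 3, amplitude = 1e-6) {
  nt <- length(sol$times)
  w <- sol$times >= sol$times[nt] * 0.8
  if (sum(w) < 4) return(list(oscillating = FALSE, worst_component = NA,
                              flips = 0))
  seg <- sol$states[w, , drop = FALSE]
  flips <- integer(ncol(seg))
  for (j in seq_len(ncol(seg))) {
    dv <- diff(seg[, j])
    s <- sign(dv[abs(dv) > 0])
    nf <- if (length(s) > 1) sum(diff(s) != 0) else 0L
    amp <- max(seg[, j]) - min(seg[, j])
    flips[j] <- if (amp > amplitude) nf else 0L
  }
  worst <- which.max(flips)
  list(oscillating = any(flips >= min_flips),
       worst_component = worst, flips = max(flips))
}
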