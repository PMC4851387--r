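#' Population specification
#'
#' Describes a population of toggles: which model (S or A) and how the `N`
#' cells split into subpopulations by transcription signature. The state
#' dimension is `4 N + 2` for the S model (per-cell `x, y, g, r` plus shared
#' extracellular `g_e, r_e`) and `3 N + 1` for the A model (per-cell
#' `x, y, r` plus shared `r_e`).
#'
#' @param model `"S"` or `"A"`.
#' @param counts ordered vector of positive subpopulation sizes
#'   `(N1, N2, ...)`; a single number gives a homogeneous population.
#' @return An object of class `population_spec` with fields `model`, `counts`,
#'   `N`, and `n_state`.
#' @export
#' @examples
#' population_spec("S", c(9, 1))  # a (9:1)-mixed population of 10 S toggles
population_spec <- function(model = c("S", "A"), counts = 1) {
  model <- match.arg(model)
  counts <- as.integer(counts)
  stopifnot(length(counts) >= 1, all(counts >= 1))
  N <- sum(counts)
  structure(list(model = model, counts = counts, N = N,
                 n_cell = if (model == "S") 4L else 3L,
                 n_ext = if (model == "S") 2L else 1L,
                 n_state = if (model == "S") 4L * N + 2L else 3L * N + 1L),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s model, N = %d (%s), %d state variables\n",
              x$model, x$N, paste(x$counts, collapse = ":"), x$n_state))
  invisible(x)
}

#' Subpopulation fractions
#' @param spec a [population_spec()].
#' @return `counts / N`; sums to 1.
#' @export
subpop_fractions <- function(spec) spec$counts / spec$N

#' State variable names
#'
#' The layout is fixed: per-cell blocks in cell order (`x_i, y_i, g_i, r_i`
#' for S; `x_i, y_i, r_i` for A) followed by the extracellular variables
#' (`g_e, r_e` for S; `r_e` for A).
#'
#' @param spec a [population_spec()].
#' @return character vector of length `spec$n_state`.
#' @export
state_names <- function(spec) {
  i <- seq_len(spec$N)
  if (spec$model == "S") {
    c(as.vector(rbind(paste0("x", i), paste0("y", i),
                      paste0("g", i), paste0("r", i))), "g_e", "r_e")
  } else {
    c(as.vector(rbind(paste0("x", i), paste0("y", i), paste0("r", i))), "r_e")
  }
}

# index of component `var` (1 = x, 2 = y, ...) of cell i in the packed vector
cell_slot <- function(spec, i, var) (i - 1L) * spec$n_cell + var

# subpopulation id of each cell, in cell order
cell_subpop <- function(spec) rep(seq_along(spec$counts), spec$counts)

#' Pack / unpack population states
#'
#' `population_state` builds the packed state vector from a per-cell matrix
#' and the extracellular levels; `unpack_state` is the inverse.
#'
#' @param spec a [population_spec()].
#' @param cells matrix with one row per cell and `4` (S) or `3` (A) columns,
#'   or a single row recycled over cells.
#' @param ext extracellular levels, length 2 (S: `g_e, r_e`) or 1 (A: `r_e`).
#' @return `population_state`: a plain numeric vector with names from
#'   [state_names()]. `unpack_state`: a list with elements `cells` (matrix)
#'   and `ext`.
#' @export
population_state <- function(spec, cells, ext = NULL) {
  cells <- matrix(as.numeric(cells), ncol = spec$n_cell, byrow = FALSE)
  if (nrow(cells) == 1L) cells <- cells[rep(1L, spec$N), , drop = FALSE]
  stopifnot(nrow(cells) == spec$N)
  if (is.null(ext)) ext <- numeric(spec$n_ext)
  stopifnot(length(ext) == spec$n_ext)
  z <- c(as.vector(t(cells)), as.numeric(ext))
  names(z) <- state_names(spec)
  z
}

#' @rdname population_state
#' @param state packed numeric state vector of length `spec$n_state`.
#' @export
unpack_state <- function(state, spec) {
  check_state(state, spec)
  nc <- spec$n_cell * spec$N
  cells <- matrix(state[seq_len(nc)], ncol = spec$n_cell, byrow = TRUE)
  colnames(cells) <- if (spec$model == "S") c("x", "y", "g", "r")
                     else c("x", "y", "r")
  list(cells = cells, ext = state[(nc + 1L):spec$n_state])
}

check_state <- function(state, spec) {
  if (!is.numeric(state) || length(state) != spec$n_state)
    stop("state has length ", length(state), " but the ", spec$model,
         " model with N = ", spec$N, " needs ", spec$n_state, call. = FALSE)
  invisible(state)
}

#' Serialize a population state as CSV
#'
#' One row per cell with columns `cell_index, x, y, g, r` (`g` empty for the
#' A model) followed by trailing rows with `cell_index` `"e"` holding the
#' extracellular levels in the `g` / `r` columns.
#'
#' @param state packed state vector.
#' @param spec a [population_spec()].
#' @param path output file.
#' @return `path`, invisibly; `read_state_csv` returns the packed vector.
#' @export
write_state_csv <- function(state, spec, path) {
  u <- unpack_state(state, spec)
  df <- as.data.frame(u$cells)
  if (spec$model == "A") df$g <- NA_real_
  df <- df[, c("x", "y", "g", "r")]
  df <- cbind(cell_index = as.character(seq_len(spec$N)), df)
  ext <- data.frame(cell_index = "e", x = NA_real_, y = NA_real_,
                    g = if (spec$model == "S") u$ext[[1]] else NA_real_,
                    r = u$ext[[length(u$ext)]])
  utils::write.csv(rbind(df, ext), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_csv
#' @export
read_state_csv <- function(path, spec) {
  df <- utils::read.csv(path, colClasses = c(cell_index = "character"))
  cells <- df[df$cell_index != "e", , drop = FALSE]
  ext <- df[df$cell_index == "e", , drop = FALSE]
  stopifnot(nrow(cells) == spec$N, nrow(ext) == 1L)
  cols <- if (spec$model == "S") c("x", "y", "g", "r") else c("x", "y", "r")
  ev <- if (spec$model == "S") c(ext$g, ext$r) else ext$r
  population_state(spec, as.matrix(cells[, cols]), ev)
}
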