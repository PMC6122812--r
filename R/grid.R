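#' Build the spatial grid for a population sheet
#'
#' Each neural population is a rectangular 2D sheet discretized into `nodes`
#' uniform cells with equal spacing along both axes. By default the sheet is
#' square and `nodes` must be a perfect square; a rectangular sheet is obtained
#' by giving `longside`, the number of nodes along the x axis, in which case
#' `nodes` must be divisible by it. The cell size is `dx = length / nx` and is
#' shared by both axes, so the physical y-extent is `ly = ny * dx`.
#'
#' Nodes are labeled 1..N in row-major order with x varying fastest: node 1
#' sits at the lower-left cell, node 2 one cell to its east. The outer corner
#' of node 1's cell is the origin (0, 0).
#'
#' @param nodes Total number of grid cells N.
#' @param length Physical length of the x axis in meters.
#' @param longside Optional number of nodes along the x axis (`Longside nodes`
#'   in configuration files). When omitted the grid is square.
#' @return An object of class `nf_grid` with fields `n`, `nx`, `ny`, `lx`,
#'   `ly`, `dx`, `dy`.
#' @examples
#' g <- nf_grid(12, 0.8, longside = 4) # 4 x 3 sheet, dx = 0.2 m
#' node_center(g, 1)                   # c(0.1, 0.1)
#' @export
nf_grid <- function(nodes, length, longside = NULL) {
  stopifnot(is.numeric(nodes), base::length(nodes) == 1, nodes >= 1,
            is.numeric(length), base::length(length) == 1, length > 0)
  nodes <- as.integer(round(nodes))
  if (is.null(longside)) {
    nx <- sqrt(nodes)
    if (abs(nx - round(nx)) > 1e-9) {
      stop("`nodes` (", nodes, ") is not a perfect square; ",
           "either choose a square node count or supply `longside`")
    }
    nx <- as.integer(round(nx))
  } else {
    longside <- as.integer(round(longside))
    if (longside < 1 || nodes %% longside != 0) {
      stop("`nodes` (", nodes, ") is not divisible by `longside` (",
           longside, ")")
    }
    nx <- longside
  }
  ny <- nodes %/% nx
  dx <- length / nx
  structure(
    list(n = nodes, nx = nx, ny = ny,
         lx = length, ly = ny * dx, dx = dx, dy = dx),
    class = "nf_grid"
  )
}

#' @export
print.nf_grid <- function(x, ...) {
  cat(sprintf("<nf_grid> %d nodes (%d x %d), dx = %g m, Lx = %g m, Ly = %g m\n",
              x$n, x$nx, x$ny, x$dx, x$lx, x$ly))
  invisible(x)
}

#' Physical center of a grid cell
#'
#' Node n occupies the cell with 1-based x index `(n - 1) %% nx + 1` and y
#' index `(n - 1) %/% nx + 1`; its center lies half a cell in from the cell's
#' lower-left corner.
#'
#' @param grid An [nf_grid()].
#' @param node 1-based node index (may be a vector).
#' @return A numeric vector `c(x, y)` in meters, or an n-by-2 matrix when
#'   `node` has length > 1.
#' @export
node_center <- function(grid, node) {
  stopifnot(inherits(grid, "nf_grid"))
  node <- as.integer(node)
  if (any(node < 1L | node > grid$n)) {
    stop("node index out of range 1..", grid$n)
  }
  i <- (node - 1L) %% grid$nx
  j <- (node - 1L) %/% grid$nx
  xy <- cbind(x = (i + 0.5) * grid$dx, y = (j + 0.5) * grid$dy)
  if (nrow(xy) == 1L) c(x = unname(xy[1, 1]), y = unname(xy[1, 2])) else xy
}

#' Convert between node indices and matrix layout
#'
#' Fields are stored as `nx` x `ny` matrices whose column-major linear index
#' equals the node label, i.e. `as_field(grid, v)[n] == v[n]`.
#'
#' @param grid An [nf_grid()].
#' @param values Numeric vector of length `grid$n` (or a scalar, recycled).
#' @return An `nx` x `ny` matrix.
#' @export
as_field <- function(grid, values) {
  stopifnot(inherits(grid, "nf_grid"))
  if (length(values) == 1L) values <- rep(values, grid$n)
  stopifnot(length(values) == grid$n)
  matrix(values, nrow = grid$nx, ncol = grid$ny)
}

#' Pad a field with periodic ghost cells
#'
#' Wraps the toroidal topology of the sheet into an `(nx + 2) x (ny + 2)`
#' array: the ghost border holds copies of the opposite edge, and corner
#' ghosts hold the diagonally opposite interior cells, so a five-point (or
#' nine-point) stencil evaluated on any interior cell sees periodic
#' neighbours.
#'
#' @param field An `nx` x `ny` numeric matrix (rows index x, columns y).
#' @return An `(nx + 2) x (ny + 2)` matrix whose interior equals `field`.
#' @export
pad_periodic <- function(field) {
  if (!is.matrix(field)) stop("`field` must be a matrix")
  nx <- nrow(field); ny <- ncol(field)
  ri <- c(nx, seq_len(nx), 1L)   # wrap rows  (x direction)
  ci <- c(ny, seq_len(ny), 1L)   # wrap cols  (y direction)
  field[ri, ci, drop = FALSE]
}

#' Five-point stencil values from a padded field
#'
#' Returns the centre value and its four nearest neighbours (north, south,
#' east, west) for an interior cell of a [pad_periodic()] array. North/south
#' step along y, east/west along x.
#'
#' @param padded Padded `(nx + 2) x (ny + 2)` matrix.
#' @param i,j 1-based interior cell indices into the *original* field
#'   (i along x, j along y).
#' @return Named numeric vector `c(c, n, s, e, w)`.
#' @export
stencil_neighbors <- function(padded, i, j) {
  nx <- nrow(padded) - 2L; ny <- ncol(padded) - 2L
  if (i < 1L || i > nx || j < 1L || j > ny) {
    stop("stencil centre must be an interior cell (i in 1..", nx,
         ", j in 1..", ny, ")")
  }
  ip <- i + 1L; jp <- j + 1L  # indices in the padded array
  c(c = padded[ip, jp],
    n = padded[ip, jp + 1L],
    s = padded[ip, jp - 1L],
    e = padded[ip + 1L, jp],
    w = padded[ip - 1L, jp])
}

#' Sum of the four periodic nearest neighbours for every cell
#'
#' Vectorized equivalent of looping [stencil_neighbors()] over the whole
#' field: element `[i, j]` is `n + s + e + w` under periodic wrapping. This is
#' the spatial workhorse of the explicit wave scheme.
#'
#' @param field An `nx` x `ny` numeric matrix.
#' @return Matrix of the same shape.
#' @export
neighbor_sum <- function(field) {
  nx <- nrow(field); ny <- ncol(field)
  e <- field[c(nx, seq_len(nx - 1L)), , drop = FALSE] +
       field[c(seq_len(nx - 1L) + 1L, 1L), , drop = FALSE]
  n <- field[, c(ny, seq_len(ny - 1L)), drop = FALSE] +
       field[, c(seq_len(ny - 1L) + 1L, 1L), drop = FALSE]
  e + n
}
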