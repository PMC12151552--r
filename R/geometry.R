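#' Build the cubic cell grid for a box and cutoff
#'
#' The box is tiled by `floor(box/cutoff)` cells per axis, so every cell edge
#' is at least the pairwise cutoff (cells are stretched rather than leaving a
#' remainder slab). Atoms are assigned separately by
#' [assign_atoms_to_cells()].
#'
#' @param box length-3 box edges (Angstrom); a scalar is recycled.
#' @param cutoff direct-space pairwise cutoff (Angstrom).
#' @return A `cell_grid` with `n_cells` (per axis), `cell_edge` (per axis),
#'   `box` and `cutoff`.
#' @export
build_cell_grid <- function(box, cutoff) {
  if (length(box) == 1) box <- rep(box, 3)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff) || cutoff <= 0)
    stop_arg("cutoff must be a positive number")
  if (any(box < cutoff))
    stop_arg("invalid geometry: cutoff ", cutoff, " exceeds a box edge (",
             paste(signif(box, 6), collapse = " x "), ")")
  n_cells <- pmax(1L, as.integer(floor(box / cutoff)))
  structure(list(n_cells = n_cells, cell_edge = box / n_cells,
                 box = as.numeric(box), cutoff = cutoff),
            class = "cell_grid")
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("cell_grid: %d x %d x %d cells, edges %s A (cutoff %.4g A)%s\n",
              x$n_cells[1], x$n_cells[2], x$n_cells[3],
              paste(signif(x$cell_edge, 6), collapse = " x "), x$cutoff,
              if (!is.null(x$cell_start)) sprintf(", %d atoms assigned",
                                                  length(x$cell_of_atom)) else ""))
  invisible(x)
}

# linear (1-based) cell index for positions; clips the exact upper box face
cell_index_of <- function(positions, grid) {
  nx <- grid$n_cells
  i <- pmin(nx[1] - 1L, as.integer(floor(positions[, 1] / grid$cell_edge[1])))
  j <- pmin(nx[2] - 1L, as.integer(floor(positions[, 2] / grid$cell_edge[2])))
  k <- pmin(nx[3] - 1L, as.integer(floor(positions[, 3] / grid$cell_edge[3])))
  i + nx[1] * (j + nx[2] * k) + 1L
}

#' Assign atoms to cells and sort them cell-contiguously
#'
#' A stable counting sort by cell index (atoms within a cell keep their
#' original relative order). The returned grid carries the cell-sorted copy
#' of the system plus the bookkeeping needed to map results back.
#'
#' @param system a [particle_system].
#' @param grid a `cell_grid` built for the system's box.
#' @return The grid, extended with `cell_of_atom` (per original atom),
#'   `cell_count`, `cell_start` (0-based offsets of length `n_cells + 1`),
#'   `sorted_order` (original index of each sorted slot) and `system`
#'   (the reordered [particle_system]).
#' @export
assign_atoms_to_cells <- function(system, grid) {
  if (!identical(as.numeric(grid$box), as.numeric(system$box)))
    stop_arg("grid was built for a different box")
  for (d in 1:3)
    if (any(system$positions[, d] < 0 | system$positions[, d] >= system$box[d]))
      stop_arg("position out of bounds on axis ", d, " (no wrapping is applied)")
  ncells <- prod(grid$n_cells)
  idx <- cell_index_of(system$positions, grid)
  counts <- tabulate(idx, nbins = ncells)
  ord <- order(idx)  # radix sort on integers: stable
  sorted <- particle_system(system$positions[ord, , drop = FALSE],
                            system$charges[ord], system$box,
                            labels = system$labels[ord])
  grid$cell_of_atom <- idx
  grid$cell_count <- counts
  grid$cell_start <- c(0L, cumsum(counts))
  grid$sorted_order <- ord
  grid$system <- sorted
  grid
}

#' Smallest Ewald convergence parameter meeting a shell's error bound
#'
#' Returns the smallest `alpha` such that `erfc(alpha * d_min) / d_min <=
#' epsilon`, i.e. the neglected complementary-error-function remainder of the
#' Coulomb split is below threshold at the shell's closest approach (internal
#' units, unit charges). Solved by bisection to relative tolerance 1e-12.
#'
#' @param d_min minimum atom-atom distance of the shell (Angstrom, > 0).
#' @param epsilon target error threshold in (0, 1).
#' @return alpha in 1/Angstrom.
#' @export
choose_alpha <- function(d_min, epsilon) {
  if (!is.numeric(d_min) || length(d_min) != 1 || d_min <= 0)
    stop_arg("d_min must be a positive distance")
  check_epsilon(epsilon)
  f <- function(a) pracma::erfc(a * d_min) / d_min - epsilon
  if (f(0) <= 0) return(1e-6)  # bound already met at (near-)zero alpha
  hi <- 1 / d_min
  while (f(hi) > 0) hi <- hi * 2
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-12 * hi) break
  }
  hi
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 || epsilon >= 1)
    stop_arg("epsilon must lie strictly between 0 and 1")
  invisible(epsilon)
}

# zeta from the radial truncation rule exp(-zeta^2) <= epsilon/10
zeta_for <- function(epsilon) sqrt(log(10 / epsilon))

#' Construct the alpha groups (doubling-thickness cell shells)
#'
#' Chebyshev cell separations 0 and 1 are short-range; separations >= 2 are
#' tiled by shells `[2,2], [3,4], [5,8], [9,16], ...` (thickness doubling),
#' clipped at the grid maximum. Each shell gets its own Ewald parameter from
#' [choose_alpha()] (via the shell's closest-corner distance) and radial
#' truncation `zeta`; cubatures are attached later by calibration.
#'
#' Grids with fewer than 4 cells on the largest axis get no groups: all cell
#' pairs are then handled by the direct short-range stage.
#'
#' @param grid a `cell_grid`.
#' @param epsilon target error threshold in (0, 1).
#' @return An `alpha_groups` list; each element has `index`, `shell_min`,
#'   `shell_max`, `d_min`, `d_max`, `alpha`, `zeta` and a `cubature` slot
#'   (`NULL` until calibrated).
#' @export
build_alpha_groups <- function(grid, epsilon) {
  check_epsilon(epsilon)
  max_sep <- max(grid$n_cells) - 1L
  groups <- list()
  if (max(grid$n_cells) >= 4L) {
    smin <- 2L
    thick <- 1L
    g <- 1L
    while (smin <= max_sep) {
      smax <- min(smin + thick - 1L, max_sep)
      d_min <- (smin - 1) * min(grid$cell_edge)
      d_max <- sqrt(3) * (smax + 1) * max(grid$cell_edge)
      groups[[g]] <- structure(
        list(index = g, shell_min = smin, shell_max = smax,
             d_min = d_min, d_max = d_max,
             alpha = choose_alpha(d_min, epsilon),
             zeta = zeta_for(epsilon), epsilon = epsilon, cubature = NULL),
        class = "alpha_group")
      smin <- smax + 1L
      thick <- thick * 2L
      g <- g + 1L
    }
  }
  structure(groups, class = "alpha_groups")
}

#' @export
print.alpha_groups <- function(x, ...) {
  cat(sprintf("alpha_groups: %d shell(s)\n", length(x)))
  for (g in x)
    cat(sprintf("  group %d: cells [%d,%d], d in [%.4g, %.4g] A, alpha %.5g 1/A, zeta %.4g%s\n",
                g$index, g$shell_min, g$shell_max, g$d_min, g$d_max, g$alpha,
                g$zeta, if (is.null(g$cubature)) "" else
                  sprintf(", %d nodes", g$cubature$n_nodes)))
  invisible(x)
}

#' Classify every cell pair as short-range or long-range
#'
#' Chebyshev separation 0 is the cell itself, 1 a short-range neighbor, and
#' >= 2 belongs to the unique alpha group whose shell covers it. Lists stop
#' at the box boundary (open boundaries, no wrap). When the grid has no
#' alpha groups every other cell is short-range (full direct interaction).
#'
#' @param grid a `cell_grid`.
#' @param groups an `alpha_groups` list for the grid.
#' @return A `cell_neighbor_list`: `short[[c]]` is an integer vector of cell
#'   indices; `long[[g]][[c]]` the long-range cells of cell `c` under group
#'   `g`.
#' @export
build_cell_neighbor_list <- function(grid, groups) {
  nc <- grid$n_cells
  ncells <- prod(nc)
  ix <- rep.int(0:(nc[1] - 1L), nc[2] * nc[3])
  iy <- rep.int(rep(0:(nc[2] - 1L), each = nc[1]), nc[3])
  iz <- rep(0:(nc[3] - 1L), each = nc[1] * nc[2])
  max_sep <- max(nc) - 1L
  no_groups <- length(groups) == 0
  if (!no_groups) {
    covered <- unlist(lapply(groups, function(g) g$shell_min:g$shell_max))
    need <- seqformax(max_sep)
    if (anyDuplicated(covered))
      stop("internal consistency error: alpha-group shells overlap", call. = FALSE)
    if (!all(need %in% covered))
      stop("internal consistency error: Chebyshev separations ",
           paste(setdiff(need, covered), collapse = ","),
           " are not covered by any alpha group", call. = FALSE)
  } else if (max(nc) >= 4L) {
    stop("internal consistency error: separations >= 2 exist but no alpha groups were supplied",
         call. = FALSE)
  }
  short <- vector("list", ncells)
  long <- lapply(groups, function(g) vector("list", ncells))
  for (c0 in seq_len(ncells)) {
    sep <- pmax(abs(ix - ix[c0]), pmax(abs(iy - iy[c0]), abs(iz - iz[c0])))
    if (no_groups) {
      short[[c0]] <- which(sep >= 1L)
    } else {
      short[[c0]] <- which(sep == 1L)
      for (gi in seq_along(groups))
        long[[gi]][[c0]] <- which(sep >= groups[[gi]]$shell_min &
                                    sep <= groups[[gi]]$shell_max)
    }
  }
  structure(list(short = short, long = long, n_cells = ncells,
                 grid_dims = nc),
            class = "cell_neighbor_list")
}

seqformax <- function(max_sep) if (max_sep >= 2L) 2L:max_sep else integer(0)
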