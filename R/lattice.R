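# The 3D on-lattice world: single-occupancy patches, Moore neighborhoods,
# cell density.
#
# Patches are addressed by 0-based integer triples (x, y, z); z = 0 is the
# culture surface. Internally occupancy is an integer array (0 = empty,
# otherwise the cell's registry index). Boundaries are solid walls: the
# neighborhood is truncated, never wrapped.

#' Create a lattice world
#'
#' @param nx,ny,nz Patch counts per dimension; `nz` defaults to the 8-layer
#'   culture geometry.
#' @param patch_size Patch edge length in micrometers.
#' @return An environment of class `lattice_world` with fields `dim`,
#'   `occ` (occupancy array), `nb_total` (per-patch neighbor counts) and
#'   `patch_size`.
#' @export
lattice_world <- function(nx, ny, nz = 8, patch_size = 15) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  w <- new.env(parent = emptyenv())
  w$dim <- c(nx, ny, nz)
  w$occ <- array(0L, dim = c(nx, ny, nz))
  w$patch_size <- patch_size
  ext <- function(n, len) ifelse(n == 0 | n == len - 1, 2, 3)
  gx <- ext(rep(0:(nx - 1), times = ny * nz), nx)
  gy <- ext(rep(rep(0:(ny - 1), each = nx), times = nz), ny)
  gz <- ext(rep(0:(nz - 1), each = nx * ny), nz)
  # Moore neighborhood size = product of per-axis extents minus the patch
  w$nb_total <- array(pmin(gx, 3) * pmin(gy, 3) * pmin(gz, 3) - 1L,
                      dim = c(nx, ny, nz))
  # per-patch neighbor linear-index lists (hot path of the event loops)
  off <- moore_offsets()
  npatch <- nx * ny * nz
  p0 <- seq_len(npatch) - 1L
  X <- p0 %% nx; Y <- (p0 %/% nx) %% ny; Z <- p0 %/% (nx * ny)
  w$nb_lin <- lapply(seq_len(npatch), function(i) {
    xs <- X[i] + off[, 1]; ys <- Y[i] + off[, 2]; zs <- Z[i] + off[, 3]
    keep <- xs >= 0L & xs < nx & ys >= 0L & ys < ny & zs >= 0L & zs < nz
    as.integer(xs[keep] + nx * (ys[keep] + ny * zs[keep]) + 1L)
  })
  class(w) <- "lattice_world"
  w
}

check_patch <- function(world, p) {
  p <- as.integer(p)
  if (length(p) != 3 || any(p < 0) || any(p >= world$dim))
    stop("patch outside the simulation domain")
  p
}

moore_offsets <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off[rowSums(abs(off)) > 0, , drop = FALSE]
}

#' Moore neighborhood of a patch
#'
#' The 26-connected 3D neighborhood, truncated at the domain boundary
#' (no wrap-around).
#'
#' @param world A `lattice_world`.
#' @param p Integer triple `(x, y, z)`, 0-based.
#' @return Integer matrix of neighbor coordinates (one row per neighbor,
#'   columns `x`, `y`, `z`).
#' @export
#' @examples
#' w <- lattice_world(5, 5, 5)
#' nrow(lw_neighbors(w, c(2, 2, 2)))  # 26
#' nrow(lw_neighbors(w, c(0, 0, 0)))  # 7
lw_neighbors <- function(world, p) {
  p <- check_patch(world, p)
  nb <- sweep(moore_offsets(), 2, p, "+")
  keep <- nb[, 1] >= 0 & nb[, 1] < world$dim[1] &
    nb[, 2] >= 0 & nb[, 2] < world$dim[2] &
    nb[, 3] >= 0 & nb[, 3] < world$dim[3]
  m <- nb[keep, , drop = FALSE]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Vacant neighbors of a patch
#'
#' @inheritParams lw_neighbors
#' @return Integer matrix of unoccupied neighbor coordinates (possibly zero
#'   rows when the cell is fully surrounded, in which case no relocation or
#'   daughter placement can occur).
#' @export
lw_vacant_neighbors <- function(world, p) {
  nb <- lw_neighbors(world, p)
  occ <- world$occ[nb + 1L]
  nb[occ == 0L, , drop = FALSE]
}

#' Normalized cell density around a patch
#'
#' The number of occupied patches in the Moore neighborhood divided by the
#' neighborhood size, hence a value in `[0, 1]` independent of cell ids.
#'
#' @inheritParams lw_neighbors
#' @return Numeric scalar in `[0, 1]`.
#' @export
lw_cell_density <- function(world, p) {
  nb <- lw_neighbors(world, p)
  sum(world$occ[nb + 1L] > 0L) / nrow(nb)
}

# occupied-neighbor counts for ALL patches at once; the 3x3x3 Moore box
# sum is separable into per-axis length-3 running sums (zero fill at the
# walls), after which the patch itself is subtracted. Used every
# simulation step for density and vacancy screening.
axis_sum3 <- function(a, ax) {
  d <- dim(a); n <- d[ax]
  if (n == 1L) return(a)
  out <- a
  if (ax == 1L) {
    out[2:n, , ] <- out[2:n, , ] + a[1:(n - 1), , ]
    out[1:(n - 1), , ] <- out[1:(n - 1), , ] + a[2:n, , ]
  } else if (ax == 2L) {
    out[, 2:n, ] <- out[, 2:n, ] + a[, 1:(n - 1), ]
    out[, 1:(n - 1), ] <- out[, 1:(n - 1), ] + a[, 2:n, ]
  } else {
    out[, , 2:n] <- out[, , 2:n] + a[, , 1:(n - 1)]
    out[, , 1:(n - 1)] <- out[, , 1:(n - 1)] + a[, , 2:n]
  }
  out
}

occupied_neighbor_counts <- function(world) {
  a <- (world$occ > 0L) * 1L
  box <- axis_sum3(axis_sum3(axis_sum3(a, 1L), 2L), 3L)
  box - a
}

#' Check the single-occupancy invariant
#'
#' Verifies that the occupancy map and a cell position registry are
#' mutually consistent: every live cell occupies exactly the patch the map
#' says it does, and no patch holds more than one cell.
#'
#' @param world A `lattice_world`.
#' @param pos Integer matrix of live-cell coordinates (0-based, one row per
#'   cell), or `NULL` to check only the occupancy map against itself.
#' @return Invisibly `TRUE`; stops on inconsistency.
#' @export
lw_check_occupancy <- function(world, pos = NULL) {
  n_occ <- sum(world$occ > 0L)
  if (!is.null(pos)) {
    if (nrow(pos) != n_occ)
      stop("occupancy map and cell registry disagree on cell count")
    idx <- world$occ[pos + 1L]
    if (any(idx == 0L)) stop("live cell on a patch marked empty")
    if (anyDuplicated(idx)) stop("two cells share a patch")
  }
  invisible(TRUE)
}

#' @export
print.lattice_world <- function(x, ...) {
  cat(sprintf("<lattice_world> %d x %d x %d patches (%g um), %d occupied\n",
              x$dim[1], x$dim[2], x$dim[3], x$patch_size,
              sum(x$occ > 0L)))
  invisible(x)
}
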