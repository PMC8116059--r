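#' Grid specification for 2D membrane maps
#'
#' Defines the square-cell lateral grid that per-lipid descriptors are
#' stamped onto. The nominal cell edge is adjusted per axis so that an
#' integer number of cells tiles the periodic box exactly.
#'
#' @param box Numeric `c(Lx, Ly, Lz)` or `c(Lx, Ly)` in Angstrom.
#' @param cell_edge Nominal cell edge in Angstrom (> 0, default 1).
#' @param stamp_radius Stamping radius in Angstrom (>= 0, default 2.6, a
#'   typical coarse-grained ester-bead van der Waals radius).
#' @return A `grid_spec` list with `nx`, `ny`, `ex`, `ey` (actual cell
#'   edges), `Lx`, `Ly`, `stamp_radius`.
#' @export
grid_spec <- function(box, cell_edge = 1, stamp_radius = 2.6) {
  if (cell_edge <= 0) abort("`cell_edge` must be positive")
  if (stamp_radius < 0) abort("`stamp_radius` must be >= 0")
  Lx <- box[1]; Ly <- box[2]
  nx <- max(1L, as.integer(round(Lx / cell_edge)))
  ny <- max(1L, as.integer(round(Ly / cell_edge)))
  structure(
    list(
      nx = nx, ny = ny, ex = Lx / nx, ey = Ly / ny,
      Lx = Lx, Ly = Ly, stamp_radius = stamp_radius
    ),
    class = "grid_spec"
  )
}

# Cell centers along each axis.
grid_centers <- function(grid) {
  list(
    x = (seq_len(grid$nx) - 0.5) * grid$ex,
    y = (seq_len(grid$ny) - 0.5) * grid$ey
  )
}

#' Protein footprint (lateral exclusion disc)
#'
#' A disc in the membrane plane standing in for the protein cross-section:
#' no lipids are generated inside it, distances for enrichment profiles are
#' measured from its boundary, and interface sectors are laid out about its
#' center. `radius = 0` gives a point anchor.
#'
#' @param center Numeric `c(x, y)` in Angstrom.
#' @param radius Disc radius in Angstrom (>= 0).
#' @return A `protein_footprint` list.
#' @export
protein_footprint <- function(center, radius) {
  if (radius < 0) abort("`radius` must be >= 0")
  structure(list(center = as.numeric(center), radius = radius),
            class = "protein_footprint")
}

# Is each lateral point strictly inside the footprint (periodic-aware)?
in_footprint <- function(footprint, x, y, box) {
  dx <- pbc_delta(x - footprint$center[1], box[1])
  dy <- pbc_delta(y - footprint$center[2], box[2])
  sqrt(dx^2 + dy^2) < footprint$radius
}

# Signed-truncated distance from lateral points to the footprint boundary:
# 0 on/inside the boundary, Euclidean distance outside (minimum image).
footprint_distance <- function(footprint, x, y, box) {
  dx <- pbc_delta(x - footprint$center[1], box[1])
  dy <- pbc_delta(y - footprint$center[2], box[2])
  pmax(0, sqrt(dx^2 + dy^2) - footprint$radius)
}

# Stamp lateral points onto the grid: returns a tibble (point, cell) of the
# unique cells whose center lies within `radius` of each point, with periodic
# wrapping. `point_id` groups beads belonging to the same datum so that the
# union over a datum's beads is counted once.
stamp_cells <- function(grid, px, py, point_id) {
  r <- grid$stamp_radius
  ic <- as.integer(floor(px / grid$ex))        # 0-based column of the point
  jc <- as.integer(floor(py / grid$ey))
  mx <- as.integer(ceiling(r / grid$ex)) + 1L
  my <- as.integer(ceiling(r / grid$ey)) + 1L
  offs <- tidyr::expand_grid(oi = -mx:mx, oj = -my:my)
  n <- length(px)
  k <- nrow(offs)
  i <- rep(ic, each = k) + rep(offs$oi, times = n)
  j <- rep(jc, each = k) + rep(offs$oj, times = n)
  pid <- rep(point_id, each = k)
  cx <- (i + 0.5) * grid$ex
  cy <- (j + 0.5) * grid$ey
  dx <- pbc_delta(rep(px, each = k) - cx, grid$Lx)
  dy <- pbc_delta(rep(py, each = k) - cy, grid$Ly)
  # A datum always stamps the cell containing the bead, plus every cell
  # whose center falls within the stamp radius.
  keep <- dx * dx + dy * dy <= r * r + 1e-12 |
    (rep(offs$oi, times = n) == 0L & rep(offs$oj, times = n) == 0L)
  i <- i %% grid$nx
  j <- j %% grid$ny
  cell <- (i + j * grid$nx + 1L)[keep]
  pid <- pid[keep]
  key <- as.numeric(pid) * (grid$nx * grid$ny + 1) + cell
  dup <- duplicated(key)
  tibble(point_id = pid[!dup], cell = cell[!dup])
}

#' Stamp per-lipid values onto a grid accumulator
#'
#' For every `(frame, lipid_id, value)` datum, the value is added once to
#' every grid cell whose center lies within the stamp radius of the lateral
#' position of either of the lipid's two ester beads (union of the two
#' discs, no double counting), and the cell occupancy count is incremented
#' identically. Periodic wrapping is respected.
#'
#' @param config A [bead_config()] containing the referenced lipids.
#' @param values Tibble with columns `frame`, `lipid_id`, `value`.
#' @param grid A [grid_spec()].
#' @return A `grid_accumulator`: list with matrices `sum` and `occupancy`
#'   (`nx` rows by `ny` columns), the grid, and `n_frames`.
#' @export
grid_stamp <- function(config, values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  esters <- config |>
    filter(.data$role == "ester") |>
    select("frame", "lipid_id", "x", "y")
  dat <- values |>
    mutate(datum = dplyr::row_number()) |>
    left_join(esters, by = c("frame", "lipid_id"),
              relationship = "one-to-many")
  if (any(is.na(dat$x))) {
    bad <- unique(dat$lipid_id[is.na(dat$x)])
    abort(paste0(
      "value table references lipids absent from the configuration: ",
      toString(head(bad, 5))
    ))
  }
  hits <- stamp_cells(grid, dat$x, dat$y, dat$datum)
  val_of <- values$value
  ncell <- grid$nx * grid$ny
  occ <- tabulate(hits$cell, nbins = ncell)
  rs <- rowsum(val_of[hits$point_id], hits$cell, reorder = FALSE)
  sum_full <- numeric(ncell)
  sum_full[as.integer(rownames(rs))] <- as.numeric(rs)
  structure(
    list(
      sum = matrix(sum_full, grid$nx, grid$ny),
      occupancy = matrix(occ, grid$nx, grid$ny),
      grid = grid,
      n_frames = length(unique(values$frame))
    ),
    class = "grid_accumulator"
  )
}

#' Combine two accumulators on the same grid
#' @param a,b `grid_accumulator`s from [grid_stamp()] with identical grids.
#' @return A `grid_accumulator`.
#' @export
grid_combine <- function(a, b) {
  stopifnot(identical(a$grid[c("nx", "ny")], b$grid[c("nx", "ny")]))
  structure(
    list(
      sum = a$sum + b$sum, occupancy = a$occupancy + b$occupancy,
      grid = a$grid, n_frames = max(a$n_frames, b$n_frames)
    ),
    class = "grid_accumulator"
  )
}

#' Finalize an accumulator into a masked scalar map
#'
#' Converts stamped sums into occupancy-weighted means and applies the
#' statistical-significance mask: cells whose occupancy falls below
#' `occupancy_fraction` times the mean occupancy (mean taken over cells with
#' occupancy > 0) are masked out and reported as `NA`.
#'
#' @param acc A `grid_accumulator` from [grid_stamp()].
#' @param occupancy_fraction Masking threshold as a fraction of the mean
#'   occupancy (default 0.40).
#' @param descriptor,units,leaflet Metadata recorded on the map.
#' @return A `scalar_map`: tibble with columns `x`, `y` (cell centers,
#'   Angstrom), `value` (`NA` where masked), `occupancy`, `mask`; grid and
#'   metadata stored as attributes.
#' @export
grid_finalize <- function(acc, occupancy_fraction = 0.40,
                          descriptor = "value", units = "",
                          leaflet = "both") {
  stopifnot(inherits(acc, "grid_accumulator"))
  occ <- acc$occupancy
  nonzero <- occ[occ > 0]
  if (length(nonzero) == 0) {
    warn("empty accumulator: all cells masked")
    mean_occ <- 0
  } else {
    mean_occ <- mean(nonzero)
  }
  mask <- occ > 0 & occ >= occupancy_fraction * mean_occ
  if (length(nonzero) > 0 && !any(mask)) {
    warn("all cells fall below the occupancy threshold; map fully masked")
  }
  vals <- ifelse(mask, acc$sum / occ, NA_real_)
  ctr <- grid_centers(acc$grid)
  out <- tibble(
    x = rep(ctr$x, times = acc$grid$ny),
    y = rep(ctr$y, each = acc$grid$nx),
    value = as.vector(vals),
    occupancy = as.vector(occ),
    mask = as.vector(mask)
  )
  new_scalar_map(out, acc$grid, descriptor, units, leaflet, acc$n_frames)
}

new_scalar_map <- function(df, grid, descriptor, units, leaflet, n_frames) {
  out <- as_tibble(df)
  attr(out, "grid") <- grid
  attr(out, "descriptor") <- descriptor
  attr(out, "units") <- units
  attr(out, "leaflet") <- leaflet
  attr(out, "map_frames") <- n_frames
  class(out) <- c("scalar_map", class(tibble()))
  out
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf(
    "<scalar_map> %s [%s], leaflet %s: %d x %d cells, %d unmasked\n",
    attr(x, "descriptor"), attr(x, "units"), attr(x, "leaflet"),
    attr(x, "grid")$nx, attr(x, "grid")$ny, sum(x$mask)
  ))
  NextMethod()
}

#' Map values as a matrix
#' @param map A `scalar_map`.
#' @param what `"value"` or `"occupancy"`.
#' @return An `nx` by `ny` matrix (`NA` where masked for `"value"`).
#' @export
map_matrix <- function(map, what = c("value", "occupancy")) {
  what <- match.arg(what)
  grid <- attr(map, "grid")
  matrix(map[[what]], grid$nx, grid$ny)
}

#' Radial distance-shell masks around a footprint
#'
#' Builds, for each requested distance, the mask of grid cells whose lateral
#' distance to the footprint boundary lies in `[d - width/2, d + width/2)`.
#' Distances are Euclidean in the membrane plane, periodic-aware, measured
#' from the footprint boundary (so a point footprint gives plain annuli).
#' Cells inside the footprint are never selected.
#'
#' @param grid A [grid_spec()].
#' @param footprint A [protein_footprint()].
#' @param distances Numeric vector of shell-center distances in Angstrom
#'   (>= 0).
#' @param width Shell width in Angstrom (default 10).
#' @return A named list of logical `nx` by `ny` matrices, one per distance,
#'   each with attribute `"shell"` = `c(lower, upper)` bounds.
#' @export
radial_shells <- function(grid, footprint, distances, width = 10) {
  stopifnot(inherits(grid, "grid_spec"), inherits(footprint, "protein_footprint"))
  if (any(distances < 0)) abort("`distances` must be >= 0")
  if (width <= 0) abort("`width` must be positive")
  ctr <- grid_centers(grid)
  cx <- rep(ctr$x, times = grid$ny)
  cy <- rep(ctr$y, each = grid$nx)
  box <- c(grid$Lx, grid$Ly)
  d <- footprint_distance(footprint, cx, cy, box)
  inside <- in_footprint(footprint, cx, cy, box)
  masks <- purrr::map(distances, function(d0) {
    sel <- !inside & d >= d0 - width / 2 & d < d0 + width / 2
    m <- matrix(sel, grid$nx, grid$ny)
    attr(m, "shell") <- c(lower = d0 - width / 2, upper = d0 + width / 2)
    m
  })
  names(masks) <- paste0("d", distances)
  masks
}

#' 3D number-density histogram of selected beads
#'
#' Time-averaged per-voxel number density (per cubic Angstrom) of beads
#' matching the role/species selection, optionally restricted to the
#' vicinity of a protein footprint (lateral distance to the footprint
#' boundary below `near_protein`).
#'
#' @param config A [bead_config()].
#' @param roles,species Optional character vectors to select beads by role
#'   and/or species (`NULL` keeps all).
#' @param voxel Voxel edge in Angstrom (> 0).
#' @param footprint Optional [protein_footprint()].
#' @param near_protein Optional lateral cutoff in Angstrom; requires
#'   `footprint`.
#' @return Tibble of non-empty voxels: `x`, `y`, `z` (voxel centers),
#'   `count`, `density` (count per voxel volume per frame).
#' @export
density_3d <- function(config, roles = NULL, species = NULL, voxel = 2,
                       footprint = NULL, near_protein = NULL) {
  if (voxel <= 0) abort("`voxel` must be positive")
  box <- bead_box(config)
  sel <- config
  if (!is.null(roles)) sel <- sel[sel$role %in% roles, ]
  if (!is.null(species)) sel <- sel[sel$species %in% species, ]
  if (!is.null(near_protein)) {
    if (is.null(footprint)) abort("`near_protein` requires a `footprint`")
    keep <- footprint_distance(footprint, sel$x, sel$y, box[1:2]) <= near_protein
    sel <- sel[keep, ]
  }
  nf <- n_frames(config)
  if (nrow(sel) == 0) {
    warn("empty selection: zero density grid")
    return(tibble(x = numeric(), y = numeric(), z = numeric(),
                  count = integer(), density = numeric()))
  }
  ix <- floor(pbc_wrap(sel$x, box[1]) / voxel)
  iy <- floor(pbc_wrap(sel$y, box[2]) / voxel)
  iz <- floor(sel$z / voxel)
  counts <- tibble(ix = ix, iy = iy, iz = iz) |>
    count(.data$ix, .data$iy, .data$iz, name = "count")
  counts |>
    mutate(
      x = (.data$ix + 0.5) * voxel,
      y = (.data$iy + 0.5) * voxel,
      z = (.data$iz + 0.5) * voxel,
      density = .data$count / (voxel^3 * nf)
    ) |>
    select("x", "y", "z", "count", "density")
}
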