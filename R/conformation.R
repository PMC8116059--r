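#' Time-averaged lipid conformation in a region
#'
#' For every frame in which a lipid's ester midpoint falls inside the region,
#' its bead positions are accumulated in a frame-local coordinate system
#' centered laterally on that lipid's ester midpoint (z is kept absolute);
#' the mean position per bead is reported. Under isotropic dynamics
#' (uniformly random azimuth) the average collapses onto a straight vertical
#' structure with both tails superposed; a consistent planted azimuth
#' preserves the tilted geometry.
#'
#' @param config A [bead_config()] with leaflets assigned.
#' @param region Either a logical `nx` by `ny` cell mask on `grid`, or a
#'   function of `(x, y)` returning logical.
#' @param grid A [grid_spec()]; required when `region` is a cell mask.
#' @param species Optional `"PO"` or `"DL"` restriction.
#' @param leaflet `"outer"` or `"inner"`.
#' @return Tibble with one row per bead: `bead`, `role`, `tail_index`,
#'   `bead_index`, mean `x`, `y` (relative to the ester midpoint) and `z`
#'   (absolute), and `n_samples` (lipid-frames accumulated; zero rows when
#'   no lipid resides in the region).
#' @export
average_conformation <- function(config, region, grid = NULL,
                                 species = NULL,
                                 leaflet = c("outer", "inner")) {
  leaflet <- match.arg(leaflet)
  box <- bead_box(config)
  em <- ester_midpoints(config)
  if (is.function(region)) {
    resident <- region(em$x, em$y)
  } else {
    if (is.null(grid)) abort("a cell-mask `region` requires `grid`")
    ix <- pmin(grid$nx, floor(pbc_wrap(em$x, grid$Lx) / grid$ex) + 1L)
    iy <- pmin(grid$ny, floor(pbc_wrap(em$y, grid$Ly) / grid$ey) + 1L)
    resident <- region[cbind(ix, iy)]
  }
  em <- em[resident, , drop = FALSE]
  em <- em[em$leaflet == leaflet, , drop = FALSE]
  if (!is.null(species)) em <- em[em$species %in% species, , drop = FALSE]
  if (nrow(em) == 0) {
    return(tibble(bead = character(), role = character(),
                  tail_index = integer(), bead_index = integer(),
                  x = numeric(), y = numeric(), z = numeric(),
                  n_samples = integer()))
  }
  sel <- config |>
    inner_join(em |> select("frame", "lipid_id", cx = "x", cy = "y"),
               by = c("frame", "lipid_id")) |>
    mutate(
      rx = pbc_delta(.data$x - .data$cx, box[1]),
      ry = pbc_delta(.data$y - .data$cy, box[2])
    )
  sel |>
    summarise(
      role = .data$role[1], tail_index = .data$tail_index[1],
      bead_index = .data$bead_index[1],
      x = mean(.data$rx), y = mean(.data$ry), z = mean(.data$z),
      n_samples = dplyr::n(),
      .by = "bead"
    )
}

#' Cumulative solvation-shell mixing fraction
#'
#' For each lipid, the running fraction of all other same-leaflet lipids
#' that have at some point (up to and including each frame) been within
#' `shell_cutoff` of its ester midpoint in the membrane plane. The curve is
#' monotone non-decreasing; the reported curve is the mean over lipids.
#' Complete mixing drives the final value to 1.
#'
#' @param trajectory A multi-frame [bead_config()] with leaflets assigned.
#' @param shell_cutoff First-solvation-shell radius in Angstrom (default 10).
#' @return Tibble `frame`, `time`, `fraction` (mean over lipids), with the
#'   per-lipid final fractions attached as attribute `"per_lipid"`.
#' @export
mixing_fraction <- function(trajectory, shell_cutoff = 10) {
  if (n_frames(trajectory) < 2) abort("`trajectory` needs >= 2 frames")
  box <- bead_box(trajectory)
  em <- ester_midpoints(trajectory)
  frames <- sort(unique(em$frame))
  times <- trajectory |>
    distinct(.data$frame, .data$time) |>
    arrange(.data$frame)
  out <- purrr::map_dfr(c("outer", "inner"), function(lf) {
    sub <- em[em$leaflet == lf, , drop = FALSE]
    ids <- sort(unique(sub$lipid_id))
    n <- length(ids)
    if (n < 2) abort("mixing fraction undefined with a single lipid per leaflet")
    seen <- matrix(FALSE, n, n)
    purrr::map_dfr(frames, function(f) {
      fr <- sub[sub$frame == f, ]
      fr <- fr[match(ids, fr$lipid_id), ]
      dx <- pbc_delta(outer(fr$x, fr$x, "-"), box[1])
      dy <- pbc_delta(outer(fr$y, fr$y, "-"), box[2])
      close <- (dx * dx + dy * dy) <= shell_cutoff^2
      diag(close) <- FALSE
      seen <<- seen | close
      tibble(frame = f, leaflet = lf,
             fraction = mean(rowSums(seen) / (n - 1)),
             per_lipid = list(setNames(rowSums(seen) / (n - 1), ids)))
    })
  })
  curve <- out |>
    summarise(fraction = mean(.data$fraction), .by = "frame") |>
    left_join(times, by = "frame") |>
    select("frame", "time", "fraction")
  final <- out |> filter(.data$frame == max(.data$frame))
  attr(curve, "per_lipid") <- setNames(final$per_lipid, final$leaflet)
  curve
}
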