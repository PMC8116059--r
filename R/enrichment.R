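#' Per-species grid occupancy
#'
#' Stamps a count of 1 for every (frame, lipid) of the requested species,
#' yielding the per-cell lipid occupancy number used by the enrichment
#' statistics. Leaflets may be combined (default) or restricted.
#'
#' @param config A [bead_config()].
#' @param grid A [grid_spec()].
#' @param species `"PO"` or `"DL"`.
#' @param leaflet `"both"` (default), `"outer"` or `"inner"`.
#' @return A `grid_accumulator` whose `occupancy` matrix is the species
#'   occupancy number.
#' @export
species_occupancy <- function(config, grid, species,
                              leaflet = c("both", "outer", "inner")) {
  leaflet <- match.arg(leaflet)
  lip <- config |>
    filter(.data$role == "ester", .data$species == !!species)
  if (leaflet != "both") lip <- lip[lip$leaflet == leaflet, ]
  vals <- lip |>
    distinct(.data$frame, .data$lipid_id) |>
    mutate(value = 1)
  grid_stamp(config, vals, grid)
}

#' Bulk DL/PO occupancy ratio
#'
#' The expected DL/PO ratio if both species were distributed evenly: the
#' ratio of global per-frame species counts (the preset proportions of the
#' system). In small boxes where a localized enrichment is a non-negligible
#' area fraction, the global ratio is itself inflated by the enriched
#' region; a far-field `region` restricted to unperturbed membrane avoids
#' that.
#'
#' @param config A [bead_config()].
#' @param region Optional far-field selector: function of the ester-midpoint
#'   `(x, y)` returning logical.
#' @return A single number (> 0 when any DL is present).
#' @export
bulk_ratio <- function(config, region = NULL) {
  lip <- config |> filter(.data$role == "ester")
  if (!is.null(region)) {
    em <- ester_midpoints(config)
    keep <- em[region(em$x, em$y), c("frame", "lipid_id")]
    lip <- lip |> dplyr::semi_join(keep, by = c("frame", "lipid_id"))
  }
  counts <- lip |>
    distinct(.data$frame, .data$lipid_id, .data$species) |>
    count(.data$species)
  n_dl <- sum(counts$n[counts$species == "DL"])
  n_po <- sum(counts$n[counts$species == "PO"])
  if (n_po == 0) abort("no PO lipids in the system; bulk ratio undefined")
  n_dl / n_po
}

#' Percent-enrichment map
#'
#' Per-cell percent enrichment of DL relative to PO:
#' `%E_i = 100 * ((rho_DL / rho_PO)_i - r_B) / r_B` with `r_B` the bulk
#' DL/PO ratio. Cells with zero PO occupancy, or failing the occupancy mask
#' computed on the combined (DL + PO) occupancy, are masked.
#'
#' @param occ_dl,occ_po `grid_accumulator`s from [species_occupancy()] on
#'   identical grids.
#' @param bulk Bulk DL/PO ratio (> 0), e.g. from [bulk_ratio()].
#' @param occupancy_fraction Masking threshold on the combined occupancy.
#' @return A `scalar_map` of percent enrichment.
#' @export
enrichment_map <- function(occ_dl, occ_po, bulk,
                           occupancy_fraction = 0.40) {
  stopifnot(inherits(occ_dl, "grid_accumulator"),
            inherits(occ_po, "grid_accumulator"))
  if (!is.numeric(bulk) || bulk <= 0) {
    abort("`bulk` ratio must be positive (no DL in the system?)")
  }
  total <- grid_combine(occ_dl, occ_po)
  occ <- total$occupancy
  nonzero <- occ[occ > 0]
  mean_occ <- if (length(nonzero)) mean(nonzero) else 0
  mask <- occ > 0 & occ >= occupancy_fraction * mean_occ &
    occ_po$occupancy > 0
  ratio <- ifelse(mask, occ_dl$occupancy / occ_po$occupancy, NA_real_)
  vals <- 100 * (ratio - bulk) / bulk
  grid <- occ_dl$grid
  ctr <- grid_centers(grid)
  out <- tibble(
    x = rep(ctr$x, times = grid$ny),
    y = rep(ctr$y, each = grid$nx),
    value = as.vector(vals),
    occupancy = as.vector(occ),
    mask = as.vector(mask)
  )
  new_scalar_map(out, grid, descriptor = "percent_enrichment", units = "%",
                 leaflet = "both", n_frames = total$n_frames)
}

#' Angular interface sectors about a footprint
#'
#' Assigns every cell outside the footprint to a named angular sector about
#' the footprint center. The first sector is centered on `dimer_axis`
#' (degrees, measured counterclockwise from +x); sector widths must sum to
#' 360.
#'
#' @param grid A [grid_spec()].
#' @param footprint A [protein_footprint()].
#' @param dimer_axis Direction of the dimerization interface, degrees.
#' @param sector_angles Numeric widths in degrees summing to 360 (default
#'   three 120-degree sectors for a three-interface monomer).
#' @param sector_names Optional names (default `interface`, `other1`, ...).
#' @return An `nx` by `ny` character matrix of sector names (`NA` inside the
#'   footprint).
#' @export
interface_sectors <- function(grid, footprint, dimer_axis = 0,
                              sector_angles = c(120, 120, 120),
                              sector_names = NULL) {
  if (abs(sum(sector_angles) - 360) > 1e-8) {
    abort("`sector_angles` must cover 360 degrees")
  }
  if (is.null(sector_names)) {
    sector_names <- c("interface",
                      paste0("other", seq_len(length(sector_angles) - 1)))
  }
  stopifnot(length(sector_names) == length(sector_angles))
  ctr <- grid_centers(grid)
  cx <- rep(ctr$x, times = grid$ny)
  cy <- rep(ctr$y, each = grid$nx)
  dx <- pbc_delta(cx - footprint$center[1], grid$Lx)
  dy <- pbc_delta(cy - footprint$center[2], grid$Ly)
  # Angle relative to the dimer axis, wrapped to [-first/2, 360 - first/2).
  ang <- (atan2(dy, dx) * 180 / pi - dimer_axis + sector_angles[1] / 2) %% 360
  edges <- cumsum(c(0, sector_angles))
  idx <- findInterval(ang, edges, rightmost.closed = TRUE)
  idx[idx > length(sector_names)] <- length(sector_names)
  sect <- sector_names[idx]
  sect[in_footprint(footprint, cx, cy, c(grid$Lx, grid$Ly))] <- NA_character_
  matrix(sect, grid$nx, grid$ny)
}

#' Distance-resolved enrichment profile
#'
#' Percent enrichment integrated over distance shells (and optionally
#' interface sectors):
#' `%E_d = 100 * ((sum_M rho_DL / sum_M rho_PO) - r_B) / r_B`, where the sum
#' runs over the grid cells of each mask M. Shells are sliding masks of
#' fixed width by default; `mode = "cumulative"` grows the masks from the
#' footprint outward instead. Leaflets are combined by passing combined
#' occupancies. Empty shell-sector intersections are reported as missing.
#'
#' @param occ_dl,occ_po `grid_accumulator`s from [species_occupancy()].
#' @param bulk Bulk DL/PO ratio (> 0).
#' @param shells List of logical cell masks from [radial_shells()].
#' @param sectors Optional sector matrix from [interface_sectors()].
#' @param mode `"sliding"` (default) or `"cumulative"`.
#' @return Tibble: `sector`, `distance` (shell center, Angstrom),
#'   `enrichment` (%), `occ_dl`, `occ_po`, `n_cells`.
#' @export
enrichment_profile <- function(occ_dl, occ_po, bulk, shells,
                               sectors = NULL,
                               mode = c("sliding", "cumulative")) {
  mode <- match.arg(mode)
  if (!is.numeric(bulk) || bulk <= 0) abort("`bulk` ratio must be positive")
  grid <- occ_dl$grid
  sector_names <- if (is.null(sectors)) "all" else
    sort(unique(as.vector(sectors[!is.na(sectors)])))
  if (mode == "cumulative") {
    acc <- matrix(FALSE, grid$nx, grid$ny)
    shells <- purrr::map(shells, function(m) {
      sh <- attr(m, "shell")
      acc <<- acc | m
      out <- acc
      attr(out, "shell") <- sh
      out
    })
  }
  purrr::map_dfr(seq_along(shells), function(k) {
    m <- shells[[k]]
    sh <- attr(m, "shell")
    d_center <- mean(sh)
    purrr::map_dfr(sector_names, function(sn) {
      sel <- m
      if (!is.null(sectors)) sel <- sel & !is.na(sectors) & sectors == sn
      n_cells <- sum(sel)
      s_dl <- sum(occ_dl$occupancy[sel])
      s_po <- sum(occ_po$occupancy[sel])
      enr <- if (n_cells == 0 || s_po == 0) NA_real_ else
        100 * ((s_dl / s_po) - bulk) / bulk
      tibble(sector = sn, distance = d_center, enrichment = enr,
             occ_dl = s_dl, occ_po = s_po, n_cells = n_cells)
    })
  })
}
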