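# Stamp a descriptor table restricted to one leaflet (or all) and finalize.
stamp_descriptor <- function(config, table, grid, leaflet = NULL,
                             occupancy_fraction = 0.40,
                             descriptor = "value", units = "") {
  if (!is.null(leaflet)) table <- table[table$leaflet %in% leaflet, ]
  acc <- grid_stamp(config, table[, c("frame", "lipid_id", "value")], grid)
  grid_finalize(
    acc, occupancy_fraction = occupancy_fraction,
    descriptor = descriptor, units = units,
    leaflet = if (is.null(leaflet)) "both" else leaflet
  )
}

#' Per-leaflet map of a per-lipid descriptor
#'
#' Generic wrapper: stamps a descriptor table (from [lipid_tilt()],
#' [lipid_end_to_end()], [lipid_order_parameter()],
#' [interleaflet_contacts()] or [neighbor_counts()]) onto a grid and applies
#' the occupancy mask, separately per leaflet.
#'
#' @param config A [bead_config()] with leaflets assigned.
#' @param table Descriptor tibble (`frame`, `lipid_id`, `leaflet`, `value`).
#' @param grid A [grid_spec()].
#' @param occupancy_fraction Masking threshold (see [grid_finalize()]).
#' @param descriptor,units Metadata for the maps.
#' @return Named list with `outer` and `inner` `scalar_map`s.
#' @export
descriptor_map <- function(config, table, grid, occupancy_fraction = 0.40,
                           descriptor = "value", units = "") {
  purrr::map(
    setNames(c("outer", "inner"), c("outer", "inner")),
    function(lf) {
      stamp_descriptor(config, table, grid, leaflet = lf,
                       occupancy_fraction = occupancy_fraction,
                       descriptor = descriptor, units = units)
    }
  )
}

#' Bilayer thickness map
#'
#' Per cell, the difference between the occupancy-weighted mean z of the
#' chosen layer's beads stamped from the outer leaflet and from the inner
#' leaflet, in Angstrom. Cells where either leaflet fails its occupancy mask
#' are masked. `species` optionally restricts the lipids entering the
#' calculation (for per-species thickness curves).
#'
#' @param config A [bead_config()] with leaflets assigned.
#' @param grid A [grid_spec()].
#' @param layer `"ester"` (default) or `"headgroup"`.
#' @param species Optional `"PO"` or `"DL"` restriction.
#' @param occupancy_fraction Masking threshold per leaflet surface.
#' @return A `scalar_map` of thickness (Angstrom), with the two leaflet
#'   surface maps attached as attribute `"surfaces"`.
#' @export
thickness_map <- function(config, grid, layer = c("ester", "headgroup"),
                          species = NULL, occupancy_fraction = 0.40) {
  layer <- match.arg(layer)
  beads <- config |> filter(.data$role == layer)
  if (!is.null(species)) beads <- beads[beads$species %in% species, ]
  zvals <- beads |>
    summarise(value = mean(.data$z),
              leaflet = .data$leaflet[1],
              .by = c("frame", "lipid_id"))
  surfaces <- purrr::map(
    setNames(c("outer", "inner"), c("outer", "inner")),
    function(lf) {
      stamp_descriptor(config, zvals, grid, leaflet = lf,
                       occupancy_fraction = occupancy_fraction,
                       descriptor = paste0(layer, "_surface_z"), units = "A")
    }
  )
  thick <- surfaces$outer$value - surfaces$inner$value
  both <- surfaces$outer$mask & surfaces$inner$mask
  out <- tibble(
    x = surfaces$outer$x,
    y = surfaces$outer$y,
    value = ifelse(both, thick, NA_real_),
    occupancy = surfaces$outer$occupancy + surfaces$inner$occupancy,
    mask = both
  )
  out <- new_scalar_map(out, attr(surfaces$outer, "grid"),
                        descriptor = paste0("thickness_", layer), units = "A",
                        leaflet = "both",
                        n_frames = attr(surfaces$outer, "map_frames"))
  attr(out, "surfaces") <- surfaces
  out
}

#' Lipid tilt-angle map
#'
#' Per-leaflet maps of the mean lipid tilt angle (degrees, measured against
#' the downward bilayer normal so that vertical outer-leaflet lipids score 0
#' and vertical inner-leaflet lipids 180).
#'
#' @inheritParams thickness_map
#' @return Named list with `outer` and `inner` `scalar_map`s (degrees).
#' @export
tilt_map <- function(config, grid, occupancy_fraction = 0.40) {
  descriptor_map(config, lipid_tilt(config), grid,
                 occupancy_fraction = occupancy_fraction,
                 descriptor = "tilt", units = "deg")
}

#' Chain order-parameter map
#' @inheritParams thickness_map
#' @return Named list with `outer` and `inner` `scalar_map`s (dimensionless).
#' @export
order_parameter_map <- function(config, grid, occupancy_fraction = 0.40) {
  descriptor_map(config, lipid_order_parameter(config), grid,
                 occupancy_fraction = occupancy_fraction,
                 descriptor = "order_parameter", units = "")
}

#' Acyl-chain end-to-end distance map
#' @inheritParams thickness_map
#' @param species Optional `"PO"` or `"DL"` restriction.
#' @return Named list with `outer` and `inner` `scalar_map`s (Angstrom).
#' @export
end_to_end_map <- function(config, grid, species = NULL,
                           occupancy_fraction = 0.40) {
  tab <- lipid_end_to_end(config)
  if (!is.null(species)) tab <- tab[tab$species %in% species, ]
  descriptor_map(config, tab, grid,
                 occupancy_fraction = occupancy_fraction,
                 descriptor = "end_to_end", units = "A")
}

#' Interleaflet acyl-chain contact map
#' @inheritParams thickness_map
#' @param cutoff Contact distance in Angstrom (default 6).
#' @param species_scope Which lipids are scored (`"all"`, `"PO"`, `"DL"`);
#'   contacts are counted against all opposing chains.
#' @return Named list with `outer` and `inner` `scalar_map`s (contacts per
#'   chain).
#' @export
interleaflet_contacts_map <- function(config, grid, cutoff = 6,
                                      species_scope = "all",
                                      occupancy_fraction = 0.40) {
  tab <- interleaflet_contacts(config, cutoff = cutoff,
                               species_scope = species_scope)
  descriptor_map(config, tab, grid,
                 occupancy_fraction = occupancy_fraction,
                 descriptor = "interleaflet_contacts", units = "pairs/chain")
}

#' Lipid neighbor-density map
#' @inheritParams thickness_map
#' @param radius Neighbor radius in Angstrom (default 15).
#' @param level Reference bead level (`"ester"`, `"headgroup"`, `"chain"`).
#' @return Named list with `outer` and `inner` `scalar_map`s (neighbors).
#' @export
neighbor_density_map <- function(config, grid, radius = 15,
                                 level = "ester",
                                 occupancy_fraction = 0.40) {
  tab <- neighbor_counts(config, radius = radius, level = level)
  descriptor_map(config, tab, grid,
                 occupancy_fraction = occupancy_fraction,
                 descriptor = "neighbor_density", units = "lipids")
}

#' Water penetration map
#'
#' Per cell, the time-averaged count of water beads whose z lies strictly
#' between the local outer and inner ester surfaces (the occupancy-weighted
#' surfaces from [thickness_map()] intermediates). Using local rather than
#' global surfaces matters exactly where a thinning defect is present. Cells
#' lacking either ester surface are masked.
#'
#' @inheritParams thickness_map
#' @return A `scalar_map` (water beads per cell column per frame).
#' @export
water_penetration_map <- function(config, grid, occupancy_fraction = 0.40) {
  tk <- thickness_map(config, grid, layer = "ester",
                      occupancy_fraction = occupancy_fraction)
  surfaces <- attr(tk, "surfaces")
  zo <- map_matrix(surfaces$outer)
  zi <- map_matrix(surfaces$inner)
  water <- config |> filter(.data$role == "water")
  nf <- n_frames(config)
  counts <- matrix(0, nrow(zo), ncol(zo))
  if (nrow(water) > 0) {
    ix <- pmin(attr(tk, "grid")$nx,
               floor(pbc_wrap(water$x, attr(tk, "grid")$Lx) /
                       attr(tk, "grid")$ex) + 1L)
    iy <- pmin(attr(tk, "grid")$ny,
               floor(pbc_wrap(water$y, attr(tk, "grid")$Ly) /
                       attr(tk, "grid")$ey) + 1L)
    lin <- cbind(ix, iy)
    upper <- zo[lin]
    lower <- zi[lin]
    inside <- !is.na(upper) & !is.na(lower) &
      water$z < upper & water$z > lower
    if (any(inside)) {
      tab <- table(ix[inside] + (iy[inside] - 1L) * nrow(zo))
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  mask <- !is.na(zo) & !is.na(zi)
  ctr <- grid_centers(attr(tk, "grid"))
  out <- tibble(
    x = rep(ctr$x, times = ncol(zo)),
    y = rep(ctr$y, each = nrow(zo)),
    value = ifelse(as.vector(mask), as.vector(counts) / nf, NA_real_),
    occupancy = tk$occupancy,
    mask = as.vector(mask)
  )
  new_scalar_map(out, attr(tk, "grid"), descriptor = "water_penetration",
                 units = "beads/cell/frame", leaflet = "both", n_frames = nf)
}
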