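#' Assign leaflets from headgroup position
#'
#' Tags each lipid `outer` if its headgroup bead lies above the instantaneous
#' membrane midplane (the mean z of all ester beads in the frame), else
#' `inner`. Water beads keep `NA`. Tags are constant within a frame.
#'
#' @param config A [bead_config()].
#' @return The configuration with the `leaflet` column (re)filled.
#' @export
assign_leaflets <- function(config) {
  mid <- config |>
    filter(.data$role == "ester") |>
    summarise(midplane = mean(.data$z), .by = "frame")
  tags <- config |>
    filter(.data$role == "headgroup") |>
    left_join(mid, by = "frame") |>
    mutate(leaflet_new = ifelse(.data$z > .data$midplane, "outer", "inner")) |>
    select("frame", "lipid_id", "leaflet_new")
  if (nrow(tags) > 0 && length(unique(tags$leaflet_new)) == 1) {
    warn("all lipids assigned to one leaflet: monolayer configuration?")
  }
  out <- config |>
    left_join(tags, by = c("frame", "lipid_id")) |>
    mutate(leaflet = ifelse(.data$role == "water", NA_character_,
                            .data$leaflet_new)) |>
    select(-"leaflet_new")
  restore_config(out, config)
}

# Lipid axis per (frame, lipid): ester midpoint -> tail-end midpoint, plus
# the tilt angle in degrees measured against the -z axis (outer-leaflet
# vertical lipid = 0 degrees, inner = 180).
lipid_axes <- function(config) {
  em <- ester_midpoints(config)
  tail_end <- config |>
    filter(.data$role == "chain") |>
    filter(.data$bead_index == max(.data$bead_index),
           .by = c("frame", "lipid_id", "tail_index")) |>
    summarise(tx = mean(.data$x), ty = mean(.data$y), tz = mean(.data$z),
              .by = c("frame", "lipid_id"))
  box <- bead_box(config)
  em |>
    inner_join(tail_end, by = c("frame", "lipid_id")) |>
    mutate(
      ax = pbc_delta(.data$tx - .data$x, box[1]),
      ay = pbc_delta(.data$ty - .data$y, box[2]),
      az = .data$tz - .data$z,
      len = sqrt(.data$ax^2 + .data$ay^2 + .data$az^2)
    )
}

#' Per-lipid tilt angle
#'
#' Angle between the lipid axis (ester midpoint to tail-end midpoint) and the
#' downward bilayer normal (-z), in degrees. A vertical outer-leaflet lipid
#' scores 0 degrees, a vertical inner-leaflet lipid 180 degrees. Degenerate
#' zero-length axes are dropped with a warning.
#'
#' @param config A [bead_config()] with leaflets assigned.
#' @return Descriptor tibble: `frame`, `lipid_id`, `species`, `leaflet`,
#'   `value` (degrees).
#' @export
lipid_tilt <- function(config) {
  ax <- lipid_axes(config)
  bad <- ax$len < 1e-9
  if (any(bad)) {
    warn(sprintf("dropping %d lipids with zero-length axis", sum(bad)))
    ax <- ax[!bad, ]
  }
  ax |>
    mutate(value = acos(pmin(1, pmax(-1, -.data$az / .data$len))) * 180 / pi) |>
    select("frame", "lipid_id", "species", "leaflet", "value")
}

#' Per-lipid mean acyl-chain end-to-end distance
#'
#' Euclidean distance from the first to the last chain bead of each tail,
#' averaged over the lipid's tails, in Angstrom. Single-bead tails are
#' dropped.
#'
#' @inheritParams lipid_tilt
#' @return Descriptor tibble (`value` in Angstrom).
#' @export
lipid_end_to_end <- function(config) {
  box <- bead_box(config)
  chains <- config |> filter(.data$role == "chain")
  per_tail <- chains |>
    summarise(
      n_beads = dplyr::n(),
      dx = pbc_delta(.data$x[which.max(.data$bead_index)] -
                       .data$x[which.min(.data$bead_index)], box[1]),
      dy = pbc_delta(.data$y[which.max(.data$bead_index)] -
                       .data$y[which.min(.data$bead_index)], box[2]),
      dz = .data$z[which.max(.data$bead_index)] -
        .data$z[which.min(.data$bead_index)],
      species = .data$species[1], leaflet = .data$leaflet[1],
      .by = c("frame", "lipid_id", "tail_index")
    ) |>
    filter(.data$n_beads >= 2)
  per_tail |>
    mutate(ee = sqrt(.data$dx^2 + .data$dy^2 + .data$dz^2)) |>
    summarise(
      value = mean(.data$ee), species = .data$species[1],
      leaflet = .data$leaflet[1], .by = c("frame", "lipid_id")
    ) |>
    select("frame", "lipid_id", "species", "leaflet", "value")
}

#' Per-lipid second-rank chain order parameter
#'
#' For every consecutive chain-bond vector b the quantity
#' P2 = (3 cos^2 theta - 1) / 2 is evaluated with theta the angle between b
#' and the z axis; the per-lipid value is the mean over all chain bonds.
#' All-vertical chains give exactly 1; bonds at the magic angle give 0;
#' isotropic bonds average to 0.
#'
#' @inheritParams lipid_tilt
#' @return Descriptor tibble (`value` dimensionless, in `[-0.5, 1]`).
#' @export
lipid_order_parameter <- function(config) {
  box <- bead_box(config)
  chains <- config |>
    filter(.data$role == "chain") |>
    arrange(.data$frame, .data$lipid_id, .data$tail_index, .data$bead_index)
  bonds <- chains |>
    mutate(
      dx = pbc_delta(dplyr::lead(.data$x) - .data$x, box[1]),
      dy = pbc_delta(dplyr::lead(.data$y) - .data$y, box[2]),
      dz = dplyr::lead(.data$z) - .data$z,
      last = .data$bead_index == max(.data$bead_index),
      .by = c("frame", "lipid_id", "tail_index")
    ) |>
    filter(!.data$last)
  bonds |>
    mutate(
      cos2 = .data$dz^2 / (.data$dx^2 + .data$dy^2 + .data$dz^2),
      p2 = (3 * .data$cos2 - 1) / 2
    ) |>
    summarise(
      value = mean(.data$p2), species = .data$species[1],
      leaflet = .data$leaflet[1], .by = c("frame", "lipid_id")
    ) |>
    select("frame", "lipid_id", "species", "leaflet", "value")
}

#' Per-lipid interleaflet acyl-chain contacts
#'
#' For each acyl chain, counts the bead pairs formed between its chain beads
#' and any chain bead of the opposing leaflet lying within `cutoff`
#' (3D distance, periodic in x and y). The per-lipid value is the mean count
#' per chain. `species_scope` restricts which lipids are scored, while
#' contacts are always counted against all opposing chains.
#'
#' @param config A [bead_config()] with leaflets assigned.
#' @param cutoff Contact distance in Angstrom (> 0, default 6).
#' @param species_scope `"all"`, `"PO"` or `"DL"`.
#' @return Descriptor tibble (`value` = contacts per chain).
#' @export
interleaflet_contacts <- function(config, cutoff = 6,
                                  species_scope = c("all", "PO", "DL")) {
  species_scope <- match.arg(species_scope)
  if (cutoff <= 0) abort("`cutoff` must be positive")
  box <- bead_box(config)
  chains <- config |>
    filter(.data$role == "chain", !is.na(.data$leaflet))
  out <- purrr::map_dfr(split(chains, chains$frame), function(fr) {
    per_leaflet <- split(fr, fr$leaflet)
    if (length(per_leaflet) < 2) return(tibble())
    purrr::map_dfr(c("outer", "inner"), function(lf) {
      mine <- per_leaflet[[lf]]
      other <- per_leaflet[[setdiff(c("outer", "inner"), lf)]]
      if (species_scope != "all") {
        mine <- mine[mine$species == species_scope, ]
      }
      if (nrow(mine) == 0) return(tibble())
      counts <- count_pairs_within(
        cbind(mine$x, mine$y, mine$z),
        cbind(other$x, other$y, other$z),
        cutoff, box
      )
      mine |>
        mutate(hits = counts) |>
        summarise(pair_count = sum(.data$hits),
                  .by = c("frame", "lipid_id", "tail_index", "species",
                          "leaflet")) |>
        summarise(
          value = mean(.data$pair_count), species = .data$species[1],
          leaflet = .data$leaflet[1], .by = c("frame", "lipid_id")
        )
    })
  })
  out |> select("frame", "lipid_id", "species", "leaflet", "value")
}

# For each row of `a` (n x 3), the number of rows of `b` within `cutoff`
# (periodic x, y; free z). Blockwise to bound memory.
count_pairs_within <- function(a, b, cutoff, box, block = 512L) {
  n <- nrow(a)
  out <- integer(n)
  if (n == 0 || nrow(b) == 0) return(out)
  c2 <- cutoff^2
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1L, n)
    dx <- pbc_delta(outer(a[s:e, 1], b[, 1], "-"), box[1])
    dy <- pbc_delta(outer(a[s:e, 2], b[, 2], "-"), box[2])
    dz <- outer(a[s:e, 3], b[, 3], "-")
    out[s:e] <- rowSums(dx * dx + dy * dy + dz * dz <= c2)
  }
  out
}

#' Per-lipid same-leaflet neighbor count
#'
#' Counts, for each lipid, the same-leaflet lipids whose reference-bead
#' centroid lies within `radius` in the membrane plane (periodic lateral
#' distance). The reference level is the headgroup bead, the ester midpoint,
#' or the acyl-chain centroid.
#'
#' @param config A [bead_config()] with leaflets assigned.
#' @param radius Neighbor radius in Angstrom (default 15).
#' @param level `"headgroup"`, `"ester"` or `"chain"`.
#' @return Descriptor tibble (`value` = neighbor count).
#' @export
neighbor_counts <- function(config, radius = 15,
                            level = c("ester", "headgroup", "chain")) {
  level <- match.arg(level)
  box <- bead_box(config)
  pts <- config |>
    filter(.data$role == level) |>
    summarise(
      x = mean(.data$x), y = mean(.data$y),
      species = .data$species[1], leaflet = .data$leaflet[1],
      .by = c("frame", "lipid_id")
    )
  purrr::map_dfr(split(pts, interaction(pts$frame, pts$leaflet, drop = TRUE)),
    function(gr) {
      n <- nrow(gr)
      if (n == 0) return(tibble())
      cnt <- count_pairs_within(
        cbind(gr$x, gr$y, 0), cbind(gr$x, gr$y, 0), radius, box
      ) - 1L  # remove self
      gr |> mutate(value = cnt)
    }
  ) |>
    select("frame", "lipid_id", "species", "leaflet", "value")
}
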