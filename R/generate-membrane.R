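# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Coerce a planted field (constant or function of x, y) to a vectorized
# function.
as_field <- function(f, name) {
  if (is.function(f)) return(f)
  if (is.numeric(f) && length(f) == 1) return(function(x, y) rep(f, length(x)))
  abort(paste0("`", name, "` must be a single number or a function(x, y)"))
}

#' Planted ground-truth fields for a synthetic bilayer
#'
#' Bundles the controllable fields used by [generate_defect_bilayer()]: a
#' local thickness field (ester-plane separation), a lipid tilt field, a
#' local DL mole-fraction field, an optional protein footprint (a lateral
#' exclusion zone standing in for the protein), and a water number density
#' for the slabs outside the acyl core. Each field may be a constant or a
#' function of the lateral coordinates `(x, y)` in Angstrom.
#'
#' @param thickness Ester-to-ester bilayer thickness in Angstrom (> 0).
#' @param tilt Lipid tilt in degrees within `[0, 90]`; applied about the
#'   ester midpoint with a uniformly random azimuth.
#' @param dl_fraction Probability in `[0, 1]` that a lipid placed at `(x, y)`
#'   is the short-chain DL species.
#' @param footprint A [protein_footprint()] or `NULL`.
#' @param water_density Water beads per cubic Angstrom in the two slabs
#'   between the ester planes (+3 Angstrom headgroup offset) and the box
#'   faces.
#' @return A `planted_field` list.
#' @export
planted_field <- function(thickness = 38, tilt = 0, dl_fraction = 0,
                          footprint = NULL, water_density = 0) {
  structure(
    list(
      thickness = as_field(thickness, "thickness"),
      tilt = as_field(tilt, "tilt"),
      dl_fraction = as_field(dl_fraction, "dl_fraction"),
      footprint = footprint,
      water_density = water_density
    ),
    class = "planted_field"
  )
}

# Lateral lattice of n sites in an Lx x Ly box (row-major, cell centers).
lattice_sites <- function(n, Lx, Ly) {
  nx <- ceiling(sqrt(n * Lx / Ly))
  ny <- ceiling(n / nx)
  grid <- tidyr::expand_grid(i = seq_len(nx), j = seq_len(ny))
  grid <- grid[seq_len(n), ]
  tibble(
    x = (grid$i - 0.5) * Lx / nx,
    y = (grid$j - 0.5) * Ly / ny
  )
}

# Rotation matrix tilting the local z axis by `tilt` degrees toward azimuth
# `phi` (radians): Rz(phi) %*% Ry(tilt) %*% Rz(-phi).
tilt_rotation <- function(tilt_deg, phi) {
  th <- tilt_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cp <- cos(phi); sp <- sin(phi)
  rbind(
    c(cp^2 * ct + sp^2, cp * sp * (ct - 1), cp * st),
    c(cp * sp * (ct - 1), sp^2 * ct + cp^2, sp * st),
    c(-cp * st, -sp * st, ct)
  )
}

# Build bead rows for one leaflet. `sites` carries x, y, species, half_z
# (signed ester-plane z), tilt (deg), phi (azimuth, radians).
place_leaflet <- function(sites, leaflet) {
  sign_z <- if (leaflet == "outer") 1 else -1
  templates <- list(PO = lipid_spec("PO"), DL = lipid_spec("DL"))
  rows <- purrr::pmap_dfr(
    sites,
    function(x, y, species, half_z, tilt, phi, lipid_id, ...) {
      tmpl <- templates[[species]]
      local <- cbind(tmpl$lx, tmpl$ly, tmpl$lz)
      if (tilt != 0) local <- local %*% t(tilt_rotation(tilt, phi))
      tibble(
        lipid_id = lipid_id, species = species,
        bead = tmpl$bead, role = tmpl$role,
        tail_index = tmpl$tail_index, bead_index = tmpl$bead_index,
        leaflet = leaflet,
        x = x + local[, 1], y = y + local[, 2],
        z = half_z + sign_z * local[, 3]
      )
    }
  )
  rows
}

# Uniform water beads in the two slabs outside the acyl core.
make_water <- function(density, box, z_lo, z_hi) {
  if (density <= 0) return(tibble())
  if (z_hi <= z_lo) {
    warn("box too shallow for water slabs; none placed")
    return(tibble())
  }
  vol <- box[1] * box[2] * (z_hi - z_lo)
  n <- round(density * vol)
  if (n == 0) return(tibble())
  purrr::map_dfr(c(1, -1), function(s) {
    tibble(
      lipid_id = 0L, species = "W", bead = "W", role = "water",
      tail_index = NA_integer_, bead_index = NA_integer_,
      leaflet = NA_character_,
      x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
      z = s * runif(n, z_lo, z_hi)
    )
  })
}

#' Generate a flat two-species bilayer
#'
#' Places `n_lipids_per_leaflet` lipids per leaflet on a lateral lattice with
#' ester planes at `z = +/- thickness / 2`, lipid axes perpendicular to the
#' membrane plane, and species assigned by independent Bernoulli draws with
#' probability `dl_fraction` of being DL. Optional Gaussian positional noise
#' (standard deviation `positional_noise`, applied as a rigid per-lipid
#' displacement in x, y and z) and interstitial water slabs.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (>= 4).
#' @param dl_fraction Probability a lipid is DL, in `[0, 1]`.
#' @param thickness Ester-plane separation in Angstrom (> 0).
#' @param box Numeric `c(Lx, Ly, Lz)` in Angstrom, or `NULL` to size the
#'   lateral box at 65 square Angstrom per lipid with `Lz = thickness + 40`.
#' @param positional_noise Standard deviation of the rigid per-lipid
#'   displacement, Angstrom (>= 0).
#' @param water_density Water beads per cubic Angstrom outside the acyl core.
#' @param seed Optional integer seed; fixed seeds give identical output.
#' @return A [bead_config()] with one frame at time 0.
#' @examples
#' cfg <- generate_flat_bilayer(16, dl_fraction = 0.5, seed = 1)
#' @export
generate_flat_bilayer <- function(n_lipids_per_leaflet, dl_fraction = 0,
                                  thickness = 38, box = NULL,
                                  positional_noise = 0, water_density = 0,
                                  seed = NULL) {
  if (!is.numeric(thickness) || thickness <= 0) {
    abort("`thickness` must be positive (Angstrom)")
  }
  if (n_lipids_per_leaflet < 4) abort("`n_lipids_per_leaflet` must be >= 4")
  if (dl_fraction < 0 || dl_fraction > 1) {
    abort("`dl_fraction` must be within [0, 1]")
  }
  if (positional_noise < 0) abort("`positional_noise` must be >= 0")
  if (is.null(box)) {
    L <- sqrt(n_lipids_per_leaflet * 65)
    box <- c(L, L, thickness + 40)
  }
  if (any(box <= 0)) abort("`box` edges must be positive")
  generate_defect_bilayer(
    planted_field(
      thickness = thickness, tilt = 0, dl_fraction = dl_fraction,
      water_density = water_density
    ),
    n_lipids_per_leaflet = n_lipids_per_leaflet, box = box,
    positional_noise = positional_noise, seed = seed
  )
}

#' Generate a bilayer with planted structural ground truth
#'
#' Places lipids so that the local ester-plane separation follows the planted
#' thickness field, lipid axes follow the planted tilt field (with uniformly
#' random azimuth), and species labels are drawn per position from the
#' planted DL-fraction field. No lipid is placed with its ester midpoint
#' inside the protein footprint. With uniform fields the output reduces to
#' [generate_flat_bilayer()] statistics.
#'
#' @param planted A [planted_field()].
#' @param n_lipids_per_leaflet Lattice sites per leaflet before footprint
#'   exclusion (>= 4).
#' @param box Numeric `c(Lx, Ly, Lz)` in Angstrom.
#' @param positional_noise Standard deviation of the rigid per-lipid Gaussian
#'   displacement, Angstrom.
#' @param n_frames Number of independent placement draws (default 1). With
#'   `n_frames > 1`, every frame places lipids at lattice sites jittered
#'   uniformly within their lattice cell, fields evaluated at the jittered
#'   positions: an ensemble of snapshots that samples the planted fields
#'   densely, as a time-averaged map would.
#' @param seed Optional integer seed.
#' @return A [bead_config()] with the planted field attached as attribute
#'   `"planted"`.
#' @export
generate_defect_bilayer <- function(planted, n_lipids_per_leaflet, box,
                                    positional_noise = 0, n_frames = 1,
                                    seed = NULL) {
  stopifnot(inherits(planted, "planted_field"))
  if (length(box) != 3 || any(box <= 0)) {
    abort("`box` must be three positive edge lengths")
  }
  if (n_lipids_per_leaflet < 4) abort("`n_lipids_per_leaflet` must be >= 4")
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  with_seed(seed, {
    frames <- purrr::map(seq_len(n_frames), function(f) {
      generate_defect_frame(planted, n_lipids_per_leaflet, box,
                            positional_noise, frame = f,
                            jitter = n_frames > 1)
    })
    out <- bead_config(bind_rows(frames), box)
    attr(out, "planted") <- planted
    out
  })
}

generate_defect_frame <- function(planted, n_lipids_per_leaflet, box,
                                  positional_noise, frame, jitter) {
  {
    sites0 <- lattice_sites(n_lipids_per_leaflet, box[1], box[2])
    if (jitter) {
      nx <- ceiling(sqrt(n_lipids_per_leaflet * box[1] / box[2]))
      ny <- ceiling(n_lipids_per_leaflet / nx)
      sx <- box[1] / nx
      sy <- box[2] / ny
      sites0$x <- pbc_wrap(sites0$x +
                             runif(nrow(sites0), -sx / 2, sx / 2), box[1])
      sites0$y <- pbc_wrap(sites0$y +
                             runif(nrow(sites0), -sy / 2, sy / 2), box[2])
    }
    beads <- purrr::map_dfr(c("outer", "inner"), function(leaflet) {
      sites <- sites0
      if (!is.null(planted$footprint)) {
        keep <- !in_footprint(planted$footprint, sites$x, sites$y, box)
        sites <- sites[keep, ]
      }
      n <- nrow(sites)
      if (n == 0) abort("footprint excludes every lattice site")
      thick <- planted$thickness(sites$x, sites$y)
      if (any(thick <= 0)) abort("thickness field must be positive everywhere")
      tilt <- planted$tilt(sites$x, sites$y)
      if (any(tilt < 0 | tilt > 90)) {
        abort("tilt field must lie within [0, 90] degrees")
      }
      dlf <- planted$dl_fraction(sites$x, sites$y)
      if (any(dlf < 0 | dlf > 1)) {
        abort("dl_fraction field must lie within [0, 1]")
      }
      sites$species <- ifelse(rbinom(n, 1, dlf) == 1, "DL", "PO")
      sites$half_z <- (if (leaflet == "outer") 0.5 else -0.5) * thick
      sites$tilt <- tilt
      sites$phi <- runif(n, 0, 2 * pi)
      sites$lipid_id <- seq_len(n) +
        (if (leaflet == "inner") n_lipids_per_leaflet else 0L) +
        2L * n_lipids_per_leaflet * (frame - 1L)
      place_leaflet(sites, leaflet)
    })
    if (positional_noise > 0) {
      noise <- beads |>
        distinct(.data$lipid_id) |>
        mutate(
          dx = rnorm(dplyr::n(), 0, positional_noise),
          dy = rnorm(dplyr::n(), 0, positional_noise),
          dz = rnorm(dplyr::n(), 0, positional_noise)
        )
      beads <- beads |>
        left_join(noise, by = "lipid_id") |>
        mutate(x = .data$x + .data$dx, y = .data$y + .data$dy,
               z = .data$z + .data$dz) |>
        select(-"dx", -"dy", -"dz")
    }
    water <- make_water(
      planted$water_density, box,
      z_lo = max(abs(beads$z)) + 3, z_hi = box[3] / 2
    )
    bind_rows(beads, water) |>
      mutate(
        frame = as.integer(frame), time = as.numeric(frame - 1L),
        x = pbc_wrap(.data$x, box[1]), y = pbc_wrap(.data$y, box[2])
      ) |>
      select(
        "frame", "time", "lipid_id", "species", "bead", "role",
        "tail_index", "bead_index", "leaflet", "x", "y", "z"
      )
  }
}
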