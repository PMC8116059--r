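# Shared fixtures, built in code at test time.

# Small mixed flat bilayer with leaflets assigned.
flat_mixed <- function(n = 100, dl = 1/3, thickness = 38, seed = 42, ...) {
  assign_leaflets(generate_flat_bilayer(
    n, dl_fraction = dl, thickness = thickness, seed = seed, ...
  ))
}

# Defect bilayer with a Gaussian thinning well centered on the footprint
# boundary (so its minimum is sampled by lipids), planted tilt inside the
# well, and a DL bump.
defect_fixture <- function(n = 240, seed = 7, depth = 8, sigma = 15,
                           tilt_deg = 0, dl_bulk = 0, dl_bump = 0,
                           bump_sigma = 14, box = c(125, 125, 80),
                           fp_center = c(45, 62.5), fp_radius = 8,
                           n_frames = 1) {
  well <- c(fp_center[1] + fp_radius, fp_center[2])  # on the boundary
  thick_f <- function(x, y) {
    38 - depth * exp(-((x - well[1])^2 + (y - well[2])^2) / (2 * sigma^2))
  }
  tilt_f <- function(x, y) {
    tilt_deg * exp(-((x - well[1])^2 + (y - well[2])^2) / (2 * sigma^2))
  }
  dl_f <- function(x, y) {
    pmin(1, dl_bulk + dl_bump *
           exp(-((x - well[1])^2 + (y - well[2])^2) / (2 * bump_sigma^2)))
  }
  pf <- planted_field(
    thickness = thick_f, tilt = tilt_f, dl_fraction = dl_f,
    footprint = protein_footprint(fp_center, fp_radius)
  )
  cfg <- generate_defect_bilayer(pf, n, box = box, n_frames = n_frames,
                                 seed = seed)
  list(
    config = assign_leaflets(cfg), planted = pf, well = well,
    footprint = protein_footprint(fp_center, fp_radius),
    thick_f = thick_f, tilt_f = tilt_f, dl_f = dl_f
  )
}

# Hand-built configuration from explicit lipid placements. `lipids` is a
# tibble with columns: lipid_id, species, leaflet, x, y, ester_z, tilt, phi.
hand_config <- function(lipids, box = c(60, 60, 80), water = NULL) {
  rows <- purrr::pmap_dfr(lipids, function(lipid_id, species, leaflet,
                                           x, y, ester_z, tilt, phi, ...) {
    tmpl <- lipid_spec(species)
    local <- cbind(tmpl$lx, tmpl$ly, tmpl$lz)
    if (tilt != 0) {
      th <- tilt * pi / 180
      cp <- cos(phi); sp <- sin(phi); ct <- cos(th); st <- sin(th)
      R <- rbind(
        c(cp^2 * ct + sp^2, cp * sp * (ct - 1), cp * st),
        c(cp * sp * (ct - 1), sp^2 * ct + cp^2, sp * st),
        c(-cp * st, -sp * st, ct)
      )
      local <- local %*% t(R)
    }
    s <- if (leaflet == "outer") 1 else -1
    tibble::tibble(
      frame = 1L, time = 0, lipid_id = lipid_id, species = species,
      bead = tmpl$bead, role = tmpl$role, tail_index = tmpl$tail_index,
      bead_index = tmpl$bead_index, leaflet = leaflet,
      x = x + local[, 1], y = y + local[, 2], z = ester_z + s * local[, 3]
    )
  })
  if (!is.null(water)) rows <- dplyr::bind_rows(rows, water)
  bead_config(rows, box)
}

water_rows <- function(x, y, z, frame = 1L) {
  tibble::tibble(
    frame = frame, time = as.numeric(frame - 1L), lipid_id = 0L,
    species = "W", bead = "W", role = "water", tail_index = NA_integer_,
    bead_index = NA_integer_, leaflet = NA_character_, x = x, y = y, z = z
  )
}

# Independent brute-force disk rasterization: number of cell centers within
# radius r of at least one of the points (periodic box).
brute_disk_cells <- function(points, grid, r) {
  ctr_x <- (seq_len(grid$nx) - 0.5) * grid$ex
  ctr_y <- (seq_len(grid$ny) - 0.5) * grid$ey
  hit <- matrix(FALSE, grid$nx, grid$ny)
  for (k in seq_len(nrow(points))) {
    dx <- ctr_x - points[k, 1]
    dx <- dx - grid$Lx * round(dx / grid$Lx)
    dy <- ctr_y - points[k, 2]
    dy <- dy - grid$Ly * round(dy / grid$Ly)
    hit <- hit | (outer(dx^2, dy^2, "+") <= r^2 + 1e-12)
  }
  sum(hit)
}

# Numeric mass-action oracle: solve Keq = chi_D / chi_M^2 with
# chi* = chi_M + 2 chi_D for chi_M by bisection, polished with Newton steps
# to machine precision; return F = 2 chi_D / chi*.
mass_action_f <- function(keq, chi_star) {
  # bracket chi_m on a log scale (it spans many decades with Keq), then
  # polish with Newton to machine precision
  g <- function(chi_m) chi_m + 2 * keq * chi_m^2 - chi_star
  h <- function(t) g(exp(t))
  t_root <- uniroot(h, c(log(chi_star) - 60, log(chi_star)),
                    tol = 1e-14)$root
  chi_m <- exp(t_root)
  for (i in 1:8) {
    chi_m <- chi_m - g(chi_m) / (1 + 4 * keq * chi_m)
  }
  2 * keq * chi_m^2 / chi_star
}
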