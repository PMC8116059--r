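test_that("leaflet assignment follows the headgroup side of the midplane", {
  cfg <- generate_flat_bilayer(50, seed = 1)
  cfg <- assign_leaflets(cfg)
  tags <- cfg |>
    dplyr::filter(role == "headgroup") |>
    dplyr::count(leaflet)
  expect_equal(sort(tags$n), c(50, 50))
  hg <- cfg |> dplyr::filter(role == "headgroup")
  expect_true(all(hg$z[hg$leaflet == "outer"] > 0))
  expect_true(all(hg$z[hg$leaflet == "inner"] < 0))
  # strongly tilted defect lipids keep the leaflet of their headgroup
  fx <- defect_fixture(tilt_deg = 60, seed = 21)
  hg2 <- fx$config |> dplyr::filter(role == "headgroup")
  expect_true(all((hg2$z > 0) == (hg2$leaflet == "outer")))
  # monolayer warns
  mono <- cfg |> dplyr::filter(leaflet == "outer" | role == "water")
  expect_warning(assign_leaflets(bead_config(mono, bead_box(cfg))),
                 "monolayer")
})

test_that("thickness map is exact on flat bilayers and recovers defects", {
  cfg <- flat_mixed(n = 100, dl = 0, seed = 2)
  g <- grid_spec(bead_box(cfg), cell_edge = 2)
  tm <- thickness_map(cfg, g)
  expect_true(all(abs(tm$value[tm$mask] - 38) < 1e-9))
  # planted 8 A Gaussian thinning recovered within 0.5 A
  fx <- defect_fixture(depth = 8, sigma = 15, seed = 3, n_frames = 15)
  g2 <- grid_spec(bead_box(fx$config), cell_edge = 2)
  tm2 <- thickness_map(fx$config, g2, occupancy_fraction = 0.2)
  observed_min <- min(tm2$value, na.rm = TRUE)
  planted_min <- 38 - 8
  expect_lt(abs(observed_min - planted_min), 0.5)
  # the minimum sits near the planted well
  at_min <- tm2[which.min(tm2$value), ]
  expect_lt(sqrt((at_min$x - fx$well[1])^2 + (at_min$y - fx$well[2])^2), 6)
})

test_that("species-restricted thickness agrees across species when esters align", {
  cfg <- assign_leaflets(generate_defect_bilayer(
    planted_field(thickness = 38, dl_fraction = 0.5),
    150, box = c(100, 100, 80), n_frames = 6, seed = 4
  ))
  g <- grid_spec(bead_box(cfg), cell_edge = 4)
  t_po <- thickness_map(cfg, g, species = "PO", occupancy_fraction = 0.1)
  t_dl <- thickness_map(cfg, g, species = "DL", occupancy_fraction = 0.1)
  both <- t_po$mask & t_dl$mask
  expect_gt(sum(both), 10)
  expect_true(all(abs(t_po$value[both] - t_dl$value[both]) < 1e-9))
})

test_that("tilt convention: vertical lipids score 0 (outer) and 180 (inner)", {
  cfg <- flat_mixed(n = 36, seed = 5)
  tl <- lipid_tilt(cfg)
  expect_true(all(abs(tl$value[tl$leaflet == "outer"]) < 1e-9))
  expect_true(all(abs(tl$value[tl$leaflet == "inner"] - 180) < 1e-9))
  expect_true(all(tl$value >= 0 & tl$value <= 180))
})

test_that("planted uniform tilt is recovered by the tilt map within 2 deg", {
  fx <- defect_fixture(depth = 0, tilt_deg = 60, sigma = 15, seed = 6,
                       n_frames = 15)
  g <- grid_spec(bead_box(fx$config), cell_edge = 2)
  tmaps <- tilt_map(fx$config, g, occupancy_fraction = 0.2)
  # outer leaflet: at the well center the planted tilt is 60 degrees
  outer_map <- tmaps$outer
  near <- outer_map$mask &
    sqrt((outer_map$x - fx$well[1])^2 + (outer_map$y - fx$well[2])^2) < 3
  expect_gt(sum(near), 0)
  expect_lt(abs(max(outer_map$value[near]) - 60), 2)
  # inner leaflet reports 180 - planted at the same location
  inner_map <- tmaps$inner
  near_i <- inner_map$mask &
    sqrt((inner_map$x - fx$well[1])^2 + (inner_map$y - fx$well[2])^2) < 3
  expect_lt(abs(min(inner_map$value[near_i]) - 120), 2)
})

test_that("tilt azimuths planted isotropically leave no net lateral direction", {
  fx <- defect_fixture(depth = 0, tilt_deg = 40, sigma = 1e6, seed = 7,
                       n = 400)
  ax <- fx$config |>
    dplyr::filter(role %in% c("ester", "chain")) |>
    memsolv:::lipid_axes()
  # mean azimuthal direction vanishes as 1/sqrt(n)
  ux <- ax$ax / ax$len
  uy <- ax$ay / ax$len
  expect_lt(abs(mean(ux)), 3 / sqrt(nrow(ax)))
  expect_lt(abs(mean(uy)), 3 / sqrt(nrow(ax)))
})

test_that("order parameter hits the exact reference values", {
  cfg <- flat_mixed(n = 25, seed = 8)
  op <- lipid_order_parameter(cfg)
  expect_true(all(abs(op$value - 1) < 1e-12))
  # chains planted at the magic angle give P2 = 0
  magic <- acos(1 / sqrt(3)) * 180 / pi
  lip <- tibble::tibble(lipid_id = 1:2, species = "PO",
                        leaflet = c("outer", "inner"),
                        x = c(10, 30), y = c(10, 30),
                        ester_z = c(19, -19), tilt = magic, phi = c(0.3, 1.1))
  cfgm <- hand_config(lip)
  opm <- lipid_order_parameter(cfgm)
  expect_true(all(abs(opm$value) < 1e-12))
  # isotropic random bonds average near 0
  set.seed(99)
  n <- 4000
  u <- stats::runif(n, -1, 1)
  p2 <- (3 * u^2 - 1) / 2
  expect_lt(abs(mean(p2)), 3 * stats::sd(p2) / sqrt(n))
})

test_that("end-to-end distance is exact and species-ordered", {
  cfg <- flat_mixed(n = 100, dl = 0.4, seed = 9)
  ee <- lipid_end_to_end(cfg)
  expect_equal(unique(ee$value[ee$species == "DL"]), 6)
  expect_equal(unique(ee$value[ee$species == "PO"]), 12)
  g <- grid_spec(bead_box(cfg), cell_edge = 4)
  m_po <- descriptor_map(cfg, ee[ee$species == "PO", ], g,
                         occupancy_fraction = 0.1)$outer
  m_dl <- descriptor_map(cfg, ee[ee$species == "DL", ], g,
                         occupancy_fraction = 0.1)$outer
  both <- m_po$mask & m_dl$mask
  expect_true(all(m_dl$value[both] < m_po$value[both]))
})

test_that("interleaflet contacts match a brute-force hand fixture", {
  # two interdigitated lipids: thickness small enough for tail overlap
  lip <- tibble::tibble(
    lipid_id = 1:2, species = "PO", leaflet = c("outer", "inner"),
    x = c(20, 21), y = c(20, 20), ester_z = c(9, -9), tilt = 0, phi = 0
  )
  cfg <- hand_config(lip)
  cutoff <- 6
  ic <- interleaflet_contacts(cfg, cutoff = cutoff)
  # brute-force pair count between the chain beads of the two lipids
  ch <- cfg[cfg$role == "chain", ]
  a <- ch[ch$lipid_id == 1, ]
  b <- ch[ch$lipid_id == 2, ]
  dmat <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
    outer(a$z, b$z, "-")^2
  k <- sum(dmat <= cutoff^2)
  expect_gt(k, 0)
  # per-lipid value is pairs per chain (2 chains each)
  expect_equal(ic$value[ic$lipid_id == 1], k / 2)
  expect_equal(ic$value[ic$lipid_id == 2], k / 2)
  # global bead-pair symmetry: outer-counted total equals inner-counted
  per_lipid_total <- ic$value * 2
  expect_equal(per_lipid_total[1], per_lipid_total[2])
  expect_error(interleaflet_contacts(cfg, cutoff = 0), "cutoff")
})

test_that("contacts vanish when leaflets are far apart and split by species", {
  cfg <- flat_mixed(n = 36, dl = 0.5, thickness = 60, seed = 10)
  ic <- interleaflet_contacts(cfg, cutoff = 6)
  expect_true(all(ic$value == 0))
  # thin mixed bilayer: DL chains (shorter) form fewer contacts than PO
  cfg2 <- flat_mixed(n = 100, dl = 0.5, thickness = 26, seed = 11)
  ic2 <- interleaflet_contacts(cfg2, cutoff = 6)
  mean_po <- mean(ic2$value[ic2$species == "PO"])
  mean_dl <- mean(ic2$value[ic2$species == "DL"])
  expect_gt(mean_po, mean_dl)
  # species_scope restricts scoring but not the opposing set
  ic_dl <- interleaflet_contacts(cfg2, cutoff = 6, species_scope = "DL")
  expect_setequal(unique(ic_dl$species), "DL")
  merged <- dplyr::inner_join(
    ic2[ic2$species == "DL", c("lipid_id", "value")],
    ic_dl[, c("lipid_id", "value")],
    by = "lipid_id"
  )
  expect_equal(merged$value.x, merged$value.y)
})

test_that("neighbor counts match a hexagonal-lattice oracle", {
  # hexagonal lattice, spacing 8 A, radius 15: brute-force count per lipid
  s <- 8
  rows <- 8
  cols <- 8
  pts <- purrr::map_dfr(seq_len(rows), function(r) {
    tibble::tibble(
      x = s * (seq_len(cols) + ifelse(r %% 2 == 0, 0.5, 0)),
      y = s * sqrt(3) / 2 * r
    )
  })
  box <- c(s * (cols + 1), s * sqrt(3) / 2 * (rows + 1), 80)
  lip <- tibble::tibble(
    lipid_id = seq_len(nrow(pts)), species = "PO", leaflet = "outer",
    x = pts$x, y = pts$y, ester_z = 19, tilt = 0, phi = 0
  )
  cfg <- hand_config(lip, box = box)
  nc <- neighbor_counts(cfg, radius = 15, level = "ester")
  # brute force with the same periodic metric
  brute <- purrr::map_int(seq_len(nrow(pts)), function(i) {
    dx <- pts$x - pts$x[i]; dx <- dx - box[1] * round(dx / box[1])
    dy <- pts$y - pts$y[i]; dy <- dy - box[2] * round(dy / box[2])
    sum(dx^2 + dy^2 <= 15^2) - 1L
  })
  expect_equal(nc$value[order(nc$lipid_id)], brute)
  # a single lipid has zero neighbors
  one <- hand_config(lip[1, ])
  expect_equal(neighbor_counts(one)$value, 0)
})

test_that("water penetration counts planted interior waters locally", {
  lip <- tidyr::expand_grid(ix = 1:6, iy = 1:6) |>
    dplyr::mutate(
      lipid_id = dplyr::row_number(), species = "PO",
      leaflet = rep(c("outer", "inner"), length.out = 36),
      x = ix * 9, y = iy * 9,
      ester_z = ifelse(leaflet == "outer", 19, -19), tilt = 0, phi = 0
    ) |>
    dplyr::select(-ix, -iy)
  # duplicate lattice so both leaflets cover the same area
  lip2 <- lip |>
    dplyr::mutate(
      lipid_id = lipid_id + 100,
      leaflet = ifelse(leaflet == "outer", "inner", "outer"),
      ester_z = -ester_z
    )
  lips <- dplyr::bind_rows(lip, lip2)
  w <- water_rows(x = rep(27, 5), y = rep(27, 5), z = seq(-5, 5, length.out = 5))
  cfg <- hand_config(lips, box = c(63, 63, 80), water = w)
  g <- grid_spec(bead_box(cfg), cell_edge = 3, stamp_radius = 5)
  wp <- water_penetration_map(cfg, g, occupancy_fraction = 0.1)
  at <- wp[wp$mask & abs(wp$x - 27) < 1.6 & abs(wp$y - 27) < 1.6, ]
  expect_equal(sum(at$value), 5)
  away <- wp[wp$mask & (abs(wp$x - 27) > 6 | abs(wp$y - 27) > 6), ]
  expect_true(all(away$value == 0))
  # no interior water -> zero everywhere
  cfg0 <- hand_config(lips, box = c(63, 63, 80))
  wp0 <- water_penetration_map(cfg0, g, occupancy_fraction = 0.1)
  expect_true(all(wp0$value[wp0$mask] == 0))
})

test_that("average conformation reproduces static geometry and azimuthal averaging", {
  # static vertical lipid: its own geometry exactly
  lip <- tibble::tibble(lipid_id = 1L, species = "PO", leaflet = "outer",
                        x = 30, y = 30, ester_z = 19, tilt = 0, phi = 0)
  cfg <- hand_config(lip)
  ac <- average_conformation(cfg, function(x, y) rep(TRUE, length(x)),
                             leaflet = "outer")
  tmpl <- lipid_spec("PO")
  merged <- dplyr::inner_join(ac, tmpl, by = "bead")
  expect_equal(merged$x, merged$lx, tolerance = 1e-12)
  expect_equal(merged$z, 19 + merged$lz, tolerance = 1e-12)
  # uniformly random azimuth at fixed 60 degrees: averaging the rotation
  # over azimuth contracts lateral offsets by (1 + cos 60)/2 = 0.75 and the
  # axial extent by cos 60 = 0.5; the tail-end midpoint is exactly vertical.
  n <- 2000
  set.seed(123)
  lips <- tibble::tibble(
    lipid_id = seq_len(n), species = "PO", leaflet = "outer",
    x = 60, y = 60, ester_z = 19, tilt = 60,
    phi = stats::runif(n, 0, 2 * pi)
  )
  cfgr <- hand_config(lips, box = c(120, 120, 80))
  acr <- average_conformation(cfgr, function(x, y) rep(TRUE, length(x)),
                              leaflet = "outer")
  # Monte-Carlo oracle with the same seed/draws, computed independently from
  # the closed-form rotation of the template bead (-1.5, 0, -15):
  th <- pi / 3
  phi <- lips$phi
  v <- c(-1.5, 0, -15)
  mc <- vapply(phi, function(p) {
    cp <- cos(p); sp <- sin(p); ct <- cos(th); st <- sin(th)
    R <- rbind(
      c(cp^2 * ct + sp^2, cp * sp * (ct - 1), cp * st),
      c(cp * sp * (ct - 1), sp^2 * ct + cp^2, sp * st),
      c(-cp * st, -sp * st, ct)
    )
    R %*% v
  }, numeric(3))
  oracle <- rowMeans(mc)
  tail_a <- acr[acr$bead == "C5A", ]
  expect_equal(c(tail_a$x, tail_a$y, tail_a$z - 19), oracle,
               tolerance = 1e-3)
  # closed-form contraction: lateral factor (1+cos)/2, axial factor cos,
  # within 3 standard errors of the azimuth-sampling noise
  se3 <- 3 * apply(mc, 1, stats::sd) / sqrt(n)
  expect_lt(abs(oracle[1] - (-1.5) * (1 + cos(th)) / 2), se3[1])
  expect_lt(abs(oracle[3] - (-15) * cos(th)), se3[3])
  # both tails superpose: tail-end midpoint has no lateral displacement
  # beyond sampling noise of the axial term (amplitude 15 sin(th))
  tail_b <- acr[acr$bead == "C5B", ]
  se_mid <- 3 * 15 * sin(th) / sqrt(2) / sqrt(n)
  expect_lt(abs((tail_a$x + tail_b$x) / 2), se_mid)
  expect_lt(abs((tail_a$y + tail_b$y) / 2), se_mid)
  # consistent azimuth preserves the tilted structure: the tail-end midpoint
  # sits on the planted 60-degree axis
  lipc <- lips |> dplyr::mutate(phi = 0.7)
  acc <- average_conformation(hand_config(lipc, box = c(120, 120, 80)),
                              function(x, y) rep(TRUE, length(x)),
                              leaflet = "outer")
  ta <- acc[acc$bead == "C5A", ]
  tb <- acc[acc$bead == "C5B", ]
  mx <- (ta$x + tb$x) / 2
  my <- (ta$y + tb$y) / 2
  mz <- (ta$z + tb$z) / 2 - 19
  axis_angle <- acos(-mz / sqrt(mx^2 + my^2 + mz^2))
  expect_equal(axis_angle * 180 / pi, 60, tolerance = 1e-9)
  # empty region: zero rows
  none <- average_conformation(cfg, function(x, y) rep(FALSE, length(x)),
                               leaflet = "outer")
  expect_equal(nrow(none), 0)
})

test_that("mixing fraction is constant when frozen and saturates when stirred", {
  cfg <- flat_mixed(n = 30, seed = 13)
  frozen <- generate_trajectory(cfg, 5, 0, seed = 1)
  mf <- mixing_fraction(assign_leaflets(frozen), shell_cutoff = 10)
  expect_equal(length(unique(round(mf$fraction, 12))), 1)
  expect_true(all(diff(mf$fraction) >= 0))
  # heavy stirring: coverage approaches 1
  stirred <- generate_trajectory(cfg, 80, step_sd = 12, seed = 2)
  mf2 <- mixing_fraction(assign_leaflets(stirred), shell_cutoff = 12)
  expect_true(all(diff(mf2$fraction) >= -1e-12))
  expect_gt(dplyr::last(mf2$fraction), 0.9)
  # single lipid per leaflet errors
  single <- cfg |>
    dplyr::filter(lipid_id %in% c(1, 31))
  tr1 <- generate_trajectory(bead_config(single, bead_box(cfg)), 3, 1,
                             seed = 3)
  expect_error(mixing_fraction(assign_leaflets(tr1)), "single lipid")
})
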