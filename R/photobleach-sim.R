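#' Simulate a liposome compartment population
#'
#' Draws per-liposome membrane areas (expressed as lipid-count equivalents,
#' outer + inner leaflet) from a lognormal size distribution, optionally a
#' two-component mixture, and tags a fraction as multilamellar. The default
#' parameters emulate a 400 nm extruded vesicle preparation: median around
#' 2e5 lipids per liposome with a broad spread, and a quarter of the vesicles
#' multilamellar.
#'
#' @param n_liposomes Number of compartments to draw.
#' @param meanlog,sdlog Lognormal parameters of the lipid-count distribution.
#' @param mixture Optional second mode: list with `weight`, `meanlog`,
#'   `sdlog`.
#' @param fraction_multilamellar Fraction tagged multilamellar in `[0, 1]`
#'   (they contribute area but are not otherwise distinguished).
#' @param seed Optional integer seed.
#' @return Tibble: `liposome`, `area_lipids`, `multilamellar`.
#' @export
simulate_population <- function(n_liposomes, meanlog = log(2e5), sdlog = 0.8,
                                mixture = NULL,
                                fraction_multilamellar = 0.25, seed = NULL) {
  if (!all(is.finite(c(n_liposomes, meanlog, sdlog, fraction_multilamellar)))) {
    abort("population parameters must be finite")
  }
  if (fraction_multilamellar < 0 || fraction_multilamellar > 1) {
    abort("`fraction_multilamellar` must lie in [0, 1]")
  }
  with_seed(seed, {
    if (!is.null(mixture) && (mixture$weight %||% 0) > 0) {
      from2 <- rbinom(n_liposomes, 1, mixture$weight) == 1
      areas <- ifelse(
        from2,
        rlnorm(n_liposomes, mixture$meanlog, mixture$sdlog),
        rlnorm(n_liposomes, meanlog, sdlog)
      )
    } else {
      areas <- rlnorm(n_liposomes, meanlog, sdlog)
    }
    tibble(
      liposome = seq_len(n_liposomes),
      area_lipids = areas,
      multilamellar = runif(n_liposomes) < fraction_multilamellar
    )
  })
}

#' Simulate a photobleaching step-count experiment
#'
#' Monte-Carlo model of the subunit-capture assay: the bulk monomer/dimer
#' split is set by the dimerization isotherm at `(keq, chi* = chi / 2)`
#' (equilibration happens in large fused membranes before extrusion traps
#' the distribution); dimers and monomers are then assigned to liposomes by
#' independent Poisson draws with means proportional to liposome area; every
#' subunit carries a label with probability `p_label`; a spot is a liposome
#' with at least one fluorophore, and its step count is the total fluorophore
#' count, truncated into the bins 1, 2 and 3+. Co-capture of multiple
#' species in one liposome is allowed (fluorophores add).
#'
#' @param keq Association constant (> 0).
#' @param chi_protein Protein mole fraction, subunits/lipid (> 0).
#' @param p_label Labeling yield per subunit (default 0.663).
#' @param n_spots Target number of observed spots.
#' @param population_args List of arguments forwarded to
#'   [simulate_population()] (sizes are drawn in batches until `n_spots`
#'   spots have accumulated).
#' @param exclude_multilamellar Drop multilamellar compartments from the spot
#'   statistics (default `FALSE`: they were counted in imaging).
#' @param seed Optional integer seed.
#' @return Tibble with one row: counts `n1`, `n2`, `n3plus`, probabilities
#'   `p1`, `p2`, `p3plus`, `chi` (= `chi_protein`), `chi_star`, and the
#'   generating truth `keq`, `f_dimer_true`, `p_label`. A warning is issued
#'   when 3+ steps dominate (occupancy beyond the assay's dynamic range).
#' @export
simulate_capture <- function(keq, chi_protein, p_label = 0.663,
                             n_spots = 5000, population_args = list(),
                             exclude_multilamellar = FALSE, seed = NULL) {
  if (keq <= 0 || chi_protein <= 0) {
    abort("`keq` and `chi_protein` must be positive")
  }
  chi_star <- chi_protein / 2
  f_dimer <- isotherm_fraction(keq, chi_star)
  # Mass-action bookkeeping on the reactive pool: chi_D = F chi*/2 dimers
  # and chi_M = (1 - F) chi* monomers per lipid.
  dimer_density <- f_dimer * chi_star / 2
  monomer_density <- (1 - f_dimer) * chi_star
  with_seed(seed, {
    steps <- integer(0)
    guard <- 0
    batch <- max(1000L, as.integer(n_spots))
    while (length(steps) < n_spots && guard < 60) {
      guard <- guard + 1
      pop <- do.call(
        simulate_population,
        c(list(n_liposomes = batch), population_args)
      )
      if (exclude_multilamellar) pop <- pop[!pop$multilamellar, ]
      n_dim <- rpois(nrow(pop), dimer_density * pop$area_lipids)
      n_mon <- rpois(nrow(pop), monomer_density * pop$area_lipids)
      # Labels: dimers contribute Binomial(2p) per dimer, monomers
      # Binomial(1, p) each.
      fl <- rbinom(nrow(pop), 2 * n_dim, p_label) +
        rbinom(nrow(pop), n_mon, p_label)
      steps <- c(steps, fl[fl > 0])
      # adapt the batch size to the observed spot yield
      rate <- max(length(steps) / (guard * batch), 1e-7)
      remaining <- n_spots - length(steps)
      if (remaining > 0) {
        batch <- as.integer(min(5e6, max(1000, ceiling(1.3 * remaining / rate))))
      }
    }
    if (length(steps) < n_spots) {
      warn(sprintf(
        "spot yield too low: returning %d of %d requested spots",
        length(steps), n_spots
      ))
    }
    steps <- head(steps, n_spots)
    n1 <- sum(steps == 1)
    n2 <- sum(steps == 2)
    n3 <- sum(steps >= 3)
    if (n3 > n1 + n2) {
      warn("3+ steps dominate: occupancy outside the assay's dynamic range")
    }
    total <- n1 + n2 + n3
    tibble(
      n1 = n1, n2 = n2, n3plus = n3,
      p1 = n1 / total, p2 = n2 / total, p3plus = n3 / total,
      chi = chi_protein, chi_star = chi_star,
      keq = keq, f_dimer_true = f_dimer, p_label = p_label
    )
  })
}

#' Simulate matched monomer and dimer control experiments
#'
#' The fixed monomer and dimer reference distributions of the subunit-capture
#' assay, generated under the same protein density, labeling yield and
#' liposome population as the sample (mirroring the role of the
#' interface-mutant monomer control and the cross-linked dimer control):
#' association is forced off (`keq` tiny) or saturated (`keq` huge). Using
#' matched controls makes the linear-combination dimer-fraction fit robust to
#' compartment co-capture, which distorts sample and controls alike.
#'
#' @inheritParams simulate_capture
#' @return List with elements `monomer` and `dimer`, each a
#'   [simulate_capture()] row.
#' @export
simulate_controls <- function(chi_protein, p_label = 0.663, n_spots = 5000,
                              population_args = list(), seed = NULL) {
  list(
    monomer = simulate_capture(
      keq = 1e-15, chi_protein = chi_protein, p_label = p_label,
      n_spots = n_spots, population_args = population_args,
      seed = if (is.null(seed)) NULL else seed
    ),
    dimer = simulate_capture(
      keq = 1e15, chi_protein = chi_protein, p_label = p_label,
      n_spots = n_spots, population_args = population_args,
      seed = if (is.null(seed)) NULL else seed + 1
    )
  )
}

#' Simulate a short-chain lipid titration experiment
#'
#' Runs [simulate_capture()] on each point of a DL grid with a
#' condition-dependent association constant (the planted truth), sharing the
#' population specification across conditions.
#'
#' @param keq_truth Function mapping `pct_dl` to Keq, or a data frame with
#'   columns `pct_dl`, `keq`.
#' @param dl_grid Numeric vector of DL percentages (matched against
#'   `keq_truth`).
#' @param chi_protein Protein mole fraction (default 1e-6 subunits/lipid).
#' @param p_label Labeling yield (default 0.663).
#' @param n_spots Spots per condition (default 5000).
#' @param population_args Forwarded to [simulate_population()].
#' @param seed Optional integer seed (conditions use derived sub-seeds).
#' @return Tidy tibble with one row per condition: `pct_dl`, the
#'   [simulate_capture()] columns, and the planted `keq`.
#' @export
simulate_titration <- function(keq_truth, dl_grid, chi_protein = 1e-6,
                               p_label = 0.663, n_spots = 5000,
                               population_args = list(), seed = NULL) {
  if (length(dl_grid) == 0) abort("`dl_grid` must be non-empty")
  keq_of <- if (is.function(keq_truth)) {
    keq_truth
  } else {
    stopifnot(all(c("pct_dl", "keq") %in% names(keq_truth)))
    function(dl) {
      keq_truth$keq[match(dl, keq_truth$pct_dl)]
    }
  }
  keqs <- keq_of(dl_grid)
  if (any(!is.finite(keqs) | keqs <= 0)) {
    abort("`keq_truth` must be positive on every grid point")
  }
  seeds <- if (is.null(seed)) {
    vector("list", length(dl_grid))
  } else {
    as.list(seed + seq_along(dl_grid))
  }
  purrr::map2_dfr(seq_along(dl_grid), seeds, function(i, s) {
    simulate_capture(
      keq = keqs[i], chi_protein = chi_protein, p_label = p_label,
      n_spots = n_spots, population_args = population_args,
      seed = if (is.null(s)) NULL else s
    ) |>
      mutate(pct_dl = dl_grid[i], .before = 1)
  })
}
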