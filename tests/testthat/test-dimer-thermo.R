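test_that("label distribution matches binomial arithmetic", {
  expect_equal(
    as.numeric(expected_label_distribution(1, 2)),
    c(0, 1, 0)
  )
  expect_equal(
    as.numeric(expected_label_distribution(0.3, 1)),
    c(1, 0, 0)
  )
  # direct binomial arithmetic at the reported labeling yield
  p <- 0.663
  norm <- 1 - (1 - p)^2
  expect_equal(
    as.numeric(expected_label_distribution(p, 2)),
    c(2 * p * (1 - p) / norm, p^2 / norm, 0),
    tolerance = 1e-12
  )
  expect_equal(round(expected_label_distribution(p, 2)$p1, 4), 0.5041)
  expect_equal(round(expected_label_distribution(p, 2)$p2, 4), 0.4959)
  # distributions sum to 1 for any n
  for (n in 1:5) {
    expect_equal(sum(expected_label_distribution(0.4, n)), 1)
  }
  # P1 = P2 crossover for a dimer at exactly p = 2/3 (2pq = p^2)
  at <- expected_label_distribution(2/3, 2)
  expect_equal(at$p1, at$p2, tolerance = 1e-12)
  below <- expected_label_distribution(2/3 - 0.01, 2)
  expect_gt(below$p1, below$p2)
  above <- expected_label_distribution(2/3 + 0.01, 2)
  expect_lt(above$p1, above$p2)
  expect_error(expected_label_distribution(0, 2), "p_label")
})

test_that("dimer-fraction estimator is exact on noiseless mixtures", {
  mono <- expected_label_distribution(0.663, 1)
  dim2 <- expected_label_distribution(0.663, 2)
  expect_equal(fit_fraction_dimer(dim2, mono, dim2)$f_dimer, 1)
  expect_equal(fit_fraction_dimer(mono, mono, dim2)$f_dimer, 0)
  for (f in c(0.1, 0.3, 0.77)) {
    mix <- f * as.numeric(dim2) + (1 - f) * as.numeric(mono)
    fit <- fit_fraction_dimer(mix, mono, dim2)
    expect_equal(fit$f_dimer, f, tolerance = 1e-9)
    expect_false(fit$clipped)
    # permutation equivariance of the probability components
    perm <- c(2, 3, 1)
    fit_p <- fit_fraction_dimer(mix[perm], as.numeric(mono)[perm],
                                as.numeric(dim2)[perm])
    expect_equal(fit_p$f_dimer, f, tolerance = 1e-9)
  }
  # identical controls are unidentifiable
  expect_error(fit_fraction_dimer(mono, mono, mono), "unidentifiable")
  # clipping flagged outside [0, 1]
  beyond <- 1.3 * as.numeric(dim2) - 0.3 * as.numeric(mono)
  beyond <- pmax(beyond, 0)
  expect_true(fit_fraction_dimer(beyond, mono, dim2)$clipped)
})

test_that("isotherm matches the numeric mass-action oracle over 12 decades", {
  us <- 10^seq(-6, 6, by = 0.5)
  chi_star <- 5e-7
  f_iso <- isotherm_fraction(us / chi_star, chi_star)
  f_ma <- vapply(us / chi_star, mass_action_f, numeric(1),
                 chi_star = chi_star)
  expect_lt(max(abs(f_iso - f_ma) / pmax(f_ma, 1e-300)), 1e-10)
  expect_true(all(diff(f_iso) > 0))   # monotone in Keq * chi*
  # exact anchor points
  expect_equal(isotherm_fraction(1, 1), 0.5)
  expect_equal(isotherm_fraction(4e7, 5e-7), 0.8539, tolerance = 1e-4)
  # series regime agrees with the closed form evaluated in higher precision
  u <- 1e-10
  expect_equal(isotherm_fraction(u, 1), 2 * u - 8 * u^2, tolerance = 1e-6)
  expect_error(isotherm_fraction(-1, 1), "positive")
})

test_that("free energy is an exact, invertible map", {
  expect_equal(free_energy(1), 0)
  expect_equal(free_energy(1 / 4.2e-6, 298.15), -7.34, tolerance = 1e-3)
  keq <- 10^stats::runif(20, -3, 12)
  expect_equal(keq_from_dg(free_energy(keq)), keq, tolerance = 1e-12)
  # strictly decreasing
  expect_true(all(diff(free_energy(sort(keq))) < 0))
  expect_error(free_energy(2, temperature = -1), "temperature")
})

test_that("isotherm fitting recovers noiseless and noisy truths", {
  keq_true <- 1e6
  chi <- 10^seq(-7.5, -4.5, length.out = 8)
  pts <- tibble::tibble(chi_star = chi,
                        f_dimer = isotherm_fraction(keq_true, chi))
  fit <- fit_isotherm(pts)
  expect_equal(fit$log10_keq, 6, tolerance = 1e-6)
  expect_equal(fit$dg, free_energy(keq_true), tolerance = 1e-5)
  # single-point closed form agrees with numeric inversion of the isotherm
  f1 <- isotherm_fraction(keq_true, 1e-6)
  k1 <- keq_from_point(f1, 1e-6)
  expect_equal(k1, keq_true, tolerance = 1e-9)
  inv <- uniroot(function(lk) isotherm_fraction(10^lk, 1e-6) - f1,
                 c(0, 12), tol = 1e-12)$root
  expect_equal(10^inv, k1, tolerance = 1e-6)
  single <- fit_isotherm(tibble::tibble(chi_star = 1e-6, f_dimer = f1))
  expect_equal(single$keq, keq_true, tolerance = 1e-6)
  # lower-limit flag when the reaction saturates the assay
  sat <- tibble::tibble(chi_star = chi,
                        f_dimer = isotherm_fraction(1e9, chi))
  expect_true(fit_isotherm(sat)$lower_limit_only)
  expect_error(
    fit_isotherm(tibble::tibble(chi_star = chi, f_dimer = rep(1, 8))),
    "unidentifiable"
  )
  # noisy recovery: median |dG error| under 0.3 kcal/mole at se = 0.05
  set.seed(2024)
  errs <- replicate(100, {
    noisy <- pts
    noisy$f_dimer <- pmin(0.999, pmax(1e-4,
                                      pts$f_dimer + rnorm(8, 0, 0.05)))
    noisy$se <- 0.05
    abs(fit_isotherm(noisy)$dg - free_energy(keq_true))
  })
  expect_lt(median(errs), 0.3)
})

test_that("titration models recover planted decays and nest correctly", {
  dl <- c(0, 0.5, 1, 2, 5, 10, 20, 40, 80)
  single_truth <- 0.86 * exp(-0.13 * dl)
  fit_s <- fit_titration(tibble::tibble(pct_dl = dl, f_dimer = single_truth),
                         model = "single")
  expect_equal(unname(fit_s$coef["f0"]), 0.86, tolerance = 1e-6)
  expect_equal(unname(fit_s$coef["lambda"]), 0.13, tolerance = 1e-6)
  expect_gt(fit_s$r_squared, 0.999999)
  # two-phase with lambda1 >> lambda2: lambda2 recovered within 5% noiseless
  two_truth <- 0.86 * (0.4 * exp(-8 * dl) + 0.6 * exp(-0.05 * dl))
  fit_2 <- fit_titration(tibble::tibble(pct_dl = dl, f_dimer = two_truth),
                         model = "two_phase", f0_fixed = 0.86)
  lam2 <- min(fit_2$coef[c("lambda1", "lambda2")])
  expect_lt(abs(lam2 - 0.05) / 0.05, 0.05)
  # the single model cannot fit two-phase data as well: strictly larger RSS
  fit_s2 <- fit_titration(tibble::tibble(pct_dl = dl, f_dimer = two_truth),
                          model = "single", f0_fixed = 0.86)
  expect_gt(fit_s2$rss, fit_2$rss + 1e-6)
  expect_error(fit_titration(tibble::tibble(pct_dl = 1:2, f_dimer = 1:2 / 4)),
               ">= 3")
})

test_that("linear ddG regression matches lm, bootstrap and the slope scaling", {
  # exact line: R^2 = 1 and vanishing CI width
  dl <- c(2, 5, 10, 20, 40, 60, 80)
  ddg <- 1.65 + 0.078 * dl
  fit <- suppressWarnings(
    fit_linear_ddg(tibble::tibble(pct_dl = dl, ddg = ddg), "pct_dl")
  )
  expect_equal(fit$slope, 0.078, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_lt(diff(fit$ci_slope), 1e-9)
  # per-10% scaling as reported: 0.078 * 10 rounds to 0.8
  expect_equal(round(fit$slope * 10, 1), 0.8)
  # noisy fixture: standard errors match a bootstrap within 10%
  set.seed(7)
  x <- seq_len(12)
  y <- 0.5 + 0.2 * x + rnorm(12, 0, 0.3)
  f2 <- fit_linear_ddg(tibble::tibble(pct_dl = x, ddg = y), "pct_dl")
  boots <- replicate(1e4, {
    idx <- sample(12, replace = TRUE)
    if (length(unique(x[idx])) < 2) return(NA_real_)
    coef(lm(y[idx] ~ x[idx]))[2]
  })
  expect_equal(f2$se_slope, sd(boots, na.rm = TRUE), tolerance = 0.1)
  # log abscissa is derived from pct_dl when absent
  lowdl <- 10^seq(-8, 0, length.out = 9)
  f3 <- suppressWarnings(fit_linear_ddg(
    tibble::tibble(pct_dl = lowdl, ddg = 1.61 + 0.135 * log10(lowdl)),
    "log10_pct_dl"
  ))
  expect_equal(f3$slope, 0.135, tolerance = 1e-10)
  expect_error(
    fit_linear_ddg(tibble::tibble(pct_dl = rep(1, 5), ddg = 1:5), "pct_dl"),
    "degenerate"
  )
})

test_that("delta_delta_g subtracts and propagates in quadrature", {
  dd <- delta_delta_g(-7.4, -10.9, se = 0.2, se_ref = 0.1)
  expect_equal(dd$ddg, 3.5)
  expect_equal(dd$se, sqrt(0.2^2 + 0.1^2))
})

test_that("fit objects expose tidy/glance summaries", {
  chi <- 10^seq(-7.5, -5, length.out = 6)
  fit <- fit_isotherm(tibble::tibble(
    chi_star = chi, f_dimer = isotherm_fraction(1e6, chi)
  ))
  td <- tidy(fit)
  expect_setequal(td$term, c("log10_keq", "dg"))
  gl <- glance(fit)
  expect_equal(gl$keq, fit$keq)
  expect_s3_class(td, "tbl_df")
})
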