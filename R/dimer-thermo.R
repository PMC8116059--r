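#' Expected photobleaching step distribution of a labeled n-mer
#'
#' Probabilities of observing 1, 2, or 3+ bleaching steps for a spot arising
#' from one n-subunit species whose subunits are labeled independently with
#' probability `p_label`, conditioned on the spot being visible (at least one
#' label): `P_k = C(n, k) p^k (1-p)^(n-k) / (1 - (1-p)^n)`.
#'
#' @param p_label Labeling yield per subunit, in `(0, 1]`.
#' @param n_subunits Subunits per species (>= 1).
#' @return Tibble with one row: `p1`, `p2`, `p3plus`.
#' @examples
#' expected_label_distribution(0.663, 2)
#' @export
expected_label_distribution <- function(p_label, n_subunits) {
  if (!is.numeric(p_label) || p_label <= 0 || p_label > 1) {
    abort("`p_label` must lie in (0, 1]: an unlabeled population is unobservable")
  }
  if (n_subunits < 1) abort("`n_subunits` must be >= 1")
  k <- seq_len(n_subunits)
  pk <- dbinom(k, n_subunits, p_label) / (1 - (1 - p_label)^n_subunits)
  tibble(
    p1 = pk[1],
    p2 = if (n_subunits >= 2) pk[2] else 0,
    p3plus = if (n_subunits >= 3) sum(pk[3:n_subunits]) else 0
  )
}

# Coerce a step distribution (length-3 numeric, or a one-row data frame with
# p1/p2/p3plus or n1/n2/n3plus columns) to a normalized numeric triple.
as_step_probs <- function(x, name = "distribution") {
  if (is.data.frame(x)) {
    if (all(c("p1", "p2", "p3plus") %in% names(x))) {
      x <- c(x$p1[1], x$p2[1], x$p3plus[1])
    } else if (all(c("n1", "n2", "n3plus") %in% names(x))) {
      x <- c(x$n1[1], x$n2[1], x$n3plus[1])
    } else {
      abort(paste0("`", name, "` needs p1/p2/p3plus or n1/n2/n3plus columns"))
    }
  }
  x <- as.numeric(x)
  if (length(x) != 3 || any(x < 0) || sum(x) <= 0) {
    abort(paste0("`", name, "` must be three non-negative numbers"))
  }
  x / sum(x)
}

#' Dimer fraction from photobleaching distributions
#'
#' Least-squares estimate of the fraction of subunits in dimers, by fitting
#' the observed (P1, P2, P3+) distribution as the linear combination
#' `F * P_dimer + (1 - F) * P_monomer` of fixed monomer and dimer control
#' distributions, with `F` constrained to `[0, 1]`.
#'
#' @param observed,monomer,dimer Step distributions (length-3 numerics or
#'   one-row data frames with `p1`, `p2`, `p3plus` or `n1`, `n2`, `n3plus`).
#' @param weights Optional length-3 weights for the residuals (default
#'   unweighted; use inverse multinomial variances for a weighted fit).
#' @return An object of class `fdimer_fit`: list with `f_dimer`, `se`
#'   (linearized standard error), `clipped` (`TRUE` when the unconstrained
#'   optimum fell outside `[0, 1]`), `residuals`, and the inputs.
#' @export
fit_fraction_dimer <- function(observed, monomer, dimer, weights = NULL) {
  p_obs <- as_step_probs(observed, "observed")
  p_mon <- as_step_probs(monomer, "monomer")
  p_dim <- as_step_probs(dimer, "dimer")
  d <- p_dim - p_mon
  if (sum(d^2) < 1e-12) {
    abort("monomer and dimer control distributions are identical: F is unidentifiable")
  }
  w <- if (is.null(weights)) rep(1, 3) else as.numeric(weights)
  f_raw <- sum(w * d * (p_obs - p_mon)) / sum(w * d^2)
  f <- min(1, max(0, f_raw))
  resid <- p_obs - (f * p_dim + (1 - f) * p_mon)
  # Linearized SE: sigma^2 * (X'WX)^-1 with X = d and 2 residual dof.
  sigma2 <- sum(w * resid^2) / 2
  se <- sqrt(sigma2 / sum(w * d^2))
  structure(
    list(
      f_dimer = f, se = se, clipped = (f_raw < 0 || f_raw > 1),
      residuals = resid, observed = p_obs, monomer = p_mon, dimer = p_dim
    ),
    class = "fdimer_fit"
  )
}

#' Convert a spot-mixture coefficient to a subunit dimer fraction
#'
#' The mixture coefficient fitted by [fit_fraction_dimer()] weighs dimer and
#' monomer control distributions per visible spot. Because a dimer carries
#' two subunits but is one spot (visible with probability `1 - (1-p)^2`
#' versus `p` for a monomer), the spot fraction g relates to the fraction F
#' of subunits in dimers by `g = F a / (F a + (1 - F) b)` with
#' `a = (1 - (1-p)^2) / 2` and `b = p`. This inverts that relation:
#' `F = g b / (a (1 - g) + g b)`.
#'
#' @param g Spot-mixture coefficient in `[0, 1]`.
#' @param p_label Labeling yield per subunit, in `(0, 1]`.
#' @return Fraction of subunits in dimers.
#' @export
subunit_fraction <- function(g, p_label) {
  if (any(p_label <= 0 | p_label > 1)) abort("`p_label` must lie in (0, 1]")
  a <- (1 - (1 - p_label)^2) / 2
  b <- p_label
  g * b / (a * (1 - g) + g * b)
}

#' Equilibrium dimerization isotherm
#'
#' Fraction of subunits in dimers at equilibrium for association constant
#' `keq` (per mole fraction, standard state 1 subunit/lipid) and reactive
#' protein mole fraction `chi_star`:
#' `F = (1 + 4 Keq chi* - sqrt(1 + 8 Keq chi*)) / (4 Keq chi*)`.
#' Evaluated through the algebraically equivalent conjugate form
#' `F = 4 u / (1 + 4 u + sqrt(1 + 8 u))` with `u = Keq chi*`, which is free
#' of the subtractive cancellation the textbook form suffers for small `u`
#' (it reduces smoothly to the dilute-limit series `2 u - 8 u^2 + ...`).
#'
#' @param keq Association constant (> 0); vectorized.
#' @param chi_star Reactive mole fraction, subunits/lipid (> 0); `chi* =
#'   chi / 2` for a randomly oriented reconstitution.
#' @return Dimer fraction in `[0, 1)`.
#' @examples
#' isotherm_fraction(1, 1)      # Keq * chi* = 1 -> exactly 0.5
#' @export
isotherm_fraction <- function(keq, chi_star) {
  if (any(keq <= 0) || any(chi_star <= 0)) {
    abort("`keq` and `chi_star` must be positive")
  }
  u <- keq * chi_star
  4 * u / (1 + 4 * u + sqrt(1 + 8 * u))
}

#' Invert the isotherm at a single point
#'
#' Closed-form association constant through one `(chi*, F)` pair:
#' `Keq = F / (2 chi* (1 - F)^2)` (exact algebraic inversion of the
#' isotherm).
#'
#' @param f_dimer Dimer fraction in `(0, 1)`.
#' @param chi_star Reactive mole fraction (> 0).
#' @return Keq (per mole fraction).
#' @export
keq_from_point <- function(f_dimer, chi_star) {
  if (any(f_dimer <= 0 | f_dimer >= 1)) {
    abort("single-point inversion requires 0 < F < 1")
  }
  f_dimer / (2 * chi_star * (1 - f_dimer)^2)
}

#' Standard dimerization free energy
#'
#' `dG = -R T ln(Keq)` in kcal/mole, with R = 1.9872e-3 kcal/(mole K) and
#' standard state 1 subunit/lipid.
#'
#' @param keq Association constant (> 0); vectorized.
#' @param temperature Kelvin (> 0, default 298.15).
#' @return Free energy in kcal/mole.
#' @export
free_energy <- function(keq, temperature = 298.15) {
  if (any(temperature <= 0)) abort("`temperature` must be positive (K)")
  if (any(keq <= 0)) abort("`keq` must be positive")
  -.R_KCAL * temperature * log(keq)
}

#' Association constant from a free energy
#' @param dg Free energy in kcal/mole.
#' @param temperature Kelvin (> 0).
#' @return Keq (per mole fraction).
#' @export
keq_from_dg <- function(dg, temperature = 298.15) {
  if (any(temperature <= 0)) abort("`temperature` must be positive (K)")
  exp(-dg / (.R_KCAL * temperature))
}

#' Free-energy difference relative to a reference condition
#'
#' `ddG = dG_x - dG_ref`, with uncertainties propagated in quadrature when
#' standard errors are supplied.
#'
#' @param dg,dg_ref Free energies in kcal/mole.
#' @param se,se_ref Optional standard errors.
#' @return Tibble with `ddg` and `se`.
#' @export
delta_delta_g <- function(dg, dg_ref, se = NA_real_, se_ref = NA_real_) {
  tibble(ddg = dg - dg_ref, se = sqrt(se^2 + se_ref^2))
}

#' Fit the dimerization isotherm
#'
#' Nonlinear least squares of measured dimer fractions against the isotherm,
#' parameterized on log10(Keq). Points may carry standard errors (inverse
#' variance weights). The fit is flagged `lower_limit_only` when the observed
#' fractions never fall below 0.9 or the fitted K_D lies beyond the sampled
#' chi* range (the reaction falls out of the assay's dynamic range, so Keq is
#' only bounded from below).
#'
#' @param data Data frame with columns `chi_star`, `f_dimer` and optionally
#'   `se`.
#' @param temperature Kelvin, for the derived free energy.
#' @return An `isotherm_fit`: list with `keq`, `log10_keq`, `se_log10_keq`,
#'   `kd`, `dg`, `se_dg`, `r_squared`, `temperature`, `lower_limit_only`,
#'   `data`.
#' @export
fit_isotherm <- function(data, temperature = 298.15) {
  stopifnot(all(c("chi_star", "f_dimer") %in% names(data)))
  pts <- as_tibble(data)
  if (nrow(pts) < 2 && length(unique(pts$chi_star)) < 2) {
    if (nrow(pts) == 1) {
      keq <- keq_from_point(pts$f_dimer, pts$chi_star)
      return(structure(
        list(
          keq = keq, log10_keq = log10(keq), se_log10_keq = NA_real_,
          kd = 1 / keq, dg = free_energy(keq, temperature), se_dg = NA_real_,
          r_squared = NA_real_, temperature = temperature,
          lower_limit_only = pts$f_dimer > 0.9, data = pts
        ),
        class = "isotherm_fit"
      ))
    }
    abort("need >= 2 points with distinct chi_star (or exactly 1 point)")
  }
  if (all(pts$f_dimer <= 0) || all(pts$f_dimer >= 1)) {
    abort("all dimer fractions at 0 or 1: Keq unidentifiable")
  }
  w <- if ("se" %in% names(pts) && all(is.finite(pts$se)) && all(pts$se > 0)) {
    1 / pts$se^2
  } else {
    rep(1, nrow(pts))
  }
  rss <- function(lk) {
    sum(w * (pts$f_dimer - isotherm_fraction(10^lk, pts$chi_star))^2)
  }
  opt <- optimize(rss, interval = c(-3, 20), tol = 1e-10)
  lk <- opt$minimum
  # Linearized SE via the numeric Jacobian dF/dlog10Keq at the optimum.
  h <- 1e-5
  jac <- (isotherm_fraction(10^(lk + h), pts$chi_star) -
            isotherm_fraction(10^(lk - h), pts$chi_star)) / (2 * h)
  dof <- max(1, nrow(pts) - 1)
  sigma2 <- opt$objective / dof
  jtj <- sum(w * jac^2)
  se_lk <- if (jtj > 0) sqrt(sigma2 / jtj) else NA_real_
  keq <- 10^lk
  wmean <- sum(w * pts$f_dimer) / sum(w)
  tss <- sum(w * (pts$f_dimer - wmean)^2)
  r2 <- if (tss > 0) 1 - opt$objective / tss else NA_real_
  se_dg <- .R_KCAL * temperature * log(10) * se_lk
  lower_limit <- min(pts$f_dimer) > 0.9 ||
    (1 / keq) < min(pts$chi_star) / 10 || (1 / keq) > max(pts$chi_star) * 10
  structure(
    list(
      keq = keq, log10_keq = lk, se_log10_keq = se_lk, kd = 1 / keq,
      dg = free_energy(keq, temperature), se_dg = se_dg,
      r_squared = r2, temperature = temperature,
      lower_limit_only = lower_limit, data = pts
    ),
    class = "isotherm_fit"
  )
}

#' Exponential titration models for the dimer fraction
#'
#' Fits the dimer fraction as a function of the short-chain lipid percentage:
#' single-phase `F = F0 exp(-lambda DL)` or two-phase
#' `F = F0 (F1 exp(-lambda1 DL) + (1 - F1) exp(-lambda2 DL))` with
#' `F1` constrained to `[0, 1]` and rates to `>= 0`. `F0` may be fixed to a
#' supplied value (e.g. the mean fraction with no short-chain lipid).
#'
#' @param data Data frame with columns `pct_dl` and `f_dimer`.
#' @param model `"single"` or `"two_phase"`.
#' @param f0_fixed Optional fixed `F0`.
#' @return A `titration_fit`: list with `model`, `coef` (named vector),
#'   `r_squared`, `rss`, `fitted`, `data`, `f0_fixed`.
#' @export
fit_titration <- function(data, model = c("single", "two_phase"),
                          f0_fixed = NULL) {
  model <- match.arg(model)
  stopifnot(all(c("pct_dl", "f_dimer") %in% names(data)))
  pts <- as_tibble(data)
  min_pts <- if (model == "single") 3 else 5
  if (nrow(pts) < min_pts) {
    abort(sprintf("`%s` model needs >= %d points", model, min_pts))
  }
  dl <- pts$pct_dl
  f <- pts$f_dimer
  # Rate scale heuristic from the decay over the observed span.
  f0_start <- f0_fixed %||% max(f)
  pos <- f > 0 & dl > 0
  lam_start <- if (any(pos)) {
    max(1e-3, stats::median(-log(pmin(1, f[pos] / f0_start)) / dl[pos],
                            na.rm = TRUE))
  } else 0.1
  fit <- if (model == "single") {
    if (is.null(f0_fixed)) {
      minpack.lm::nlsLM(
        f_dimer ~ f0 * exp(-lambda * pct_dl), data = pts,
        start = list(f0 = f0_start, lambda = lam_start),
        lower = c(0, 0), upper = c(1.5, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        f_dimer ~ f0_fixed * exp(-lambda * pct_dl), data = pts,
        start = list(lambda = lam_start), lower = 0,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    }
  } else {
    start2 <- list(f1 = 0.3, lambda1 = lam_start * 50, lambda2 = lam_start)
    if (is.null(f0_fixed)) {
      minpack.lm::nlsLM(
        f_dimer ~ f0 * (f1 * exp(-lambda1 * pct_dl) +
                          (1 - f1) * exp(-lambda2 * pct_dl)),
        data = pts,
        start = c(list(f0 = f0_start), start2),
        lower = c(0, 0, 0, 0), upper = c(1.5, 1, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    } else {
      minpack.lm::nlsLM(
        f_dimer ~ f0_fixed * (f1 * exp(-lambda1 * pct_dl) +
                                (1 - f1) * exp(-lambda2 * pct_dl)),
        data = pts,
        start = start2, lower = c(0, 0, 0), upper = c(1, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    }
  }
  co <- coef(fit)
  fitted_vals <- stats::fitted(fit)
  rss <- sum((f - fitted_vals)^2)
  tss <- sum((f - mean(f))^2)
  structure(
    list(
      model = model, coef = co,
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      rss = rss, fitted = as.numeric(fitted_vals),
      data = pts, f0_fixed = f0_fixed
    ),
    class = "titration_fit"
  )
}

#' Linear free-energy regression against lipid content
#'
#' Ordinary least squares of `ddg` against either the short-chain lipid
#' percentage (`abscissa = "pct_dl"`, the regime above 1%) or its base-10
#' logarithm (`abscissa = "log10_pct_dl"`, the trace regime below 1%), with
#' t-based standard errors and 95% confidence intervals.
#'
#' @param data Data frame with a `ddg` column and either `pct_dl` or a
#'   precomputed abscissa column named as in `abscissa`.
#' @param abscissa `"pct_dl"` or `"log10_pct_dl"`.
#' @return A `ddg_fit`: list wrapping the `lm` with `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `ci_slope`, `ci_intercept`, `r_squared`,
#'   `abscissa`.
#' @export
fit_linear_ddg <- function(data, abscissa = c("pct_dl", "log10_pct_dl")) {
  abscissa <- match.arg(abscissa)
  pts <- as_tibble(data)
  stopifnot("ddg" %in% names(pts))
  x <- if (abscissa %in% names(pts)) {
    pts[[abscissa]]
  } else if (abscissa == "log10_pct_dl" && "pct_dl" %in% names(pts)) {
    log10(pts$pct_dl)
  } else {
    abort(paste0("no `", abscissa, "` (or `pct_dl`) column in `data`"))
  }
  if (nrow(pts) < 3) abort("need >= 3 points")
  if (sd(x) < 1e-12) abort("degenerate abscissa: no spread in x")
  df <- tibble(x = x, ddg = pts$ddg)
  fit <- lm(ddg ~ x, data = df)
  s <- summary(fit)$coefficients
  ci <- confint(fit, level = 0.95)
  structure(
    list(
      fit = fit, slope = s["x", "Estimate"],
      intercept = s["(Intercept)", "Estimate"],
      se_slope = s["x", "Std. Error"],
      se_intercept = s["(Intercept)", "Std. Error"],
      ci_slope = ci["x", ], ci_intercept = ci["(Intercept)", ],
      r_squared = summary(fit)$r.squared,
      abscissa = abscissa, data = df
    ),
    class = "ddg_fit"
  )
}
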