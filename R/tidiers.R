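#' @export
tidy.isotherm_fit <- function(x, ...) {
  tibble(
    term = c("log10_keq", "dg"),
    estimate = c(x$log10_keq, x$dg),
    std.error = c(x$se_log10_keq, x$se_dg)
  )
}

#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble(
    keq = x$keq, kd = x$kd, dg = x$dg, se_dg = x$se_dg,
    r.squared = x$r_squared, temperature = x$temperature,
    lower_limit_only = x$lower_limit_only, nobs = nrow(x$data)
  )
}

#' @export
tidy.titration_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.titration_fit <- function(x, ...) {
  tibble(
    model = x$model, r.squared = x$r_squared, rss = x$rss,
    nobs = nrow(x$data)
  )
}

#' @export
tidy.ddg_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope),
    conf.low = c(x$ci_intercept[1], x$ci_slope[1]),
    conf.high = c(x$ci_intercept[2], x$ci_slope[2])
  )
}

#' @export
glance.ddg_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, abscissa = x$abscissa, nobs = nrow(x$data)
  )
}

#' @export
tidy.efflux_fit <- function(x, ...) {
  tibble(
    term = c("f0_vol", "k_leak", "k_p", "k_init"),
    estimate = c(x$f0_vol, x$k_leak, x$k_p, x$k_init)
  )
}

#' @export
glance.efflux_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    flags = paste(x$flags, collapse = ";"),
    nobs = nrow(x$data)
  )
}

#' @export
tidy.fdimer_fit <- function(x, ...) {
  tibble(term = "f_dimer", estimate = x$f_dimer, std.error = x$se)
}

#' @export
glance.fdimer_fit <- function(x, ...) {
  tibble(f_dimer = x$f_dimer, se = x$se, clipped = x$clipped)
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf(
    "<isotherm_fit> Keq = %.4g (K_D = %.4g subunits/lipid)\n  ΔG° = %.3f ± %.3f kcal/mole at %.2f K (1 subunit/lipid standard state)\n  R² = %.3f%s\n",
    x$keq, x$kd, x$dg, x$se_dg, x$temperature, x$r_squared,
    if (isTRUE(x$lower_limit_only)) "  [lower limit only]" else ""
  ))
  invisible(x)
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> %s decay: %s; R² = %.3f\n",
              x$model,
              paste(sprintf("%s = %.4g", names(x$coef), x$coef),
                    collapse = ", "),
              x$r_squared))
  invisible(x)
}

#' @export
print.ddg_fit <- function(x, ...) {
  cat(sprintf(
    "<ddg_fit> ΔΔG ~ %s: slope %.4g ± %.4g (95%% CI %.4g..%.4g), R² = %.3f\n",
    x$abscissa, x$slope, x$se_slope, x$ci_slope[1], x$ci_slope[2],
    x$r_squared
  ))
  invisible(x)
}

#' @export
print.efflux_fit <- function(x, ...) {
  cat(sprintf(
    "<efflux_fit> F0,vol = %.3f, k_leak = %.4g /s, k_P = %.4g /s, k_init = %.4g /s; R² = %.3f%s\n",
    x$f0_vol, x$k_leak, x$k_p, x$k_init, x$r_squared,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
    else ""
  ))
  invisible(x)
}

#' @export
print.fdimer_fit <- function(x, ...) {
  cat(sprintf("<fdimer_fit> F_Dimer = %.4f ± %.4f%s\n", x$f_dimer, x$se,
              if (x$clipped) " (clipped to [0, 1])" else ""))
  invisible(x)
}
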