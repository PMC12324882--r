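# Carreau-Yasuda blood rheology and Reynolds-number checks.

#' Carreau-Yasuda blood parameters
#'
#' Shear-thinning viscosity model
#' `mu(g) = mu_inf + (mu_0 - mu_inf) * (1 + (lambda g)^a)^((n - 1)/a)`.
#' Defaults follow the standard blood-rheology literature values
#' (`mu_0 = 0.056` Pa s, `mu_inf = 0.00345` Pa s, `lambda = 1.902` s,
#' `n = 0.22`, `a = 1.25`, density 1050 kg/m^3); all are configurable.
#'
#' @param mu_zero Zero-shear viscosity (Pa s).
#' @param mu_inf Infinite-shear viscosity (Pa s).
#' @param lambda_time Relaxation time lambda (s).
#' @param power_n Power-law index n in (0, 1).
#' @param yasuda_a Yasuda exponent a (> 0).
#' @param density Fluid density (kg/m^3).
#' @return A list of class `carreau_yasuda`.
#' @export
carreau_yasuda <- function(mu_zero = 0.056, mu_inf = 0.00345,
                           lambda_time = 1.902, power_n = 0.22,
                           yasuda_a = 1.25, density = 1050) {
  if (!(mu_zero > mu_inf && mu_inf > 0)) abort("need mu_zero > mu_inf > 0.")
  stopifnot_positive(lambda_time, "lambda_time")
  if (power_n <= 0 || power_n >= 1) abort("`power_n` must lie in (0, 1).")
  stopifnot_positive(yasuda_a, "yasuda_a")
  stopifnot_positive(density, "density")
  structure(list(mu_zero = mu_zero, mu_inf = mu_inf,
                 lambda_time = lambda_time, power_n = power_n,
                 yasuda_a = yasuda_a, density = density),
            class = "carreau_yasuda")
}

#' @export
print.carreau_yasuda <- function(x, ...) {
  cat(sprintf(
    "<carreau_yasuda> mu0=%g, muInf=%g Pa s, lambda=%g s, n=%g, a=%g, rho=%g kg/m^3\n",
    x$mu_zero, x$mu_inf, x$lambda_time, x$power_n, x$yasuda_a, x$density))
  invisible(x)
}

#' Carreau-Yasuda apparent viscosity
#'
#' @param shear_rate Shear rate (1/s), non-negative; vectorised.
#' @param params A [carreau_yasuda()] parameter set.
#' @return Apparent viscosity (Pa s), strictly decreasing in shear rate and
#'   bounded in `(mu_inf, mu_zero]`.
#' @export
viscosity <- function(shear_rate, params = carreau_yasuda()) {
  if (any(shear_rate < 0)) abort("`shear_rate` must be non-negative.")
  with(params,
       mu_inf + (mu_zero - mu_inf) *
         (1 + (lambda_time * shear_rate) ^ yasuda_a) ^
         ((power_n - 1) / yasuda_a))
}

#' Tube Reynolds number
#'
#' `Re = 4 rho Q / (pi d mu)`. The default viscosity choice is the
#' infinite-shear limit, the conservative (largest-Re) choice for a
#' shear-thinning fluid.
#'
#' @param flow Volumetric flow rate (m^3/s).
#' @param diameter Tube diameter (m).
#' @param params A [carreau_yasuda()] parameter set.
#' @param viscosity_choice `"infinite_shear"`, `"zero_shear"`, or a shear
#'   rate (1/s) at which to evaluate the apparent viscosity.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(flow, diameter, params = carreau_yasuda(),
                            viscosity_choice = "infinite_shear") {
  stopifnot_positive(flow, "flow")
  stopifnot_positive(diameter, "diameter")
  mu <- if (is.numeric(viscosity_choice)) {
    viscosity(viscosity_choice, params)
  } else {
    switch(match.arg(viscosity_choice, c("infinite_shear", "zero_shear")),
           infinite_shear = params$mu_inf,
           zero_shear = params$mu_zero)
  }
  4 * params$density * flow / (pi * diameter * mu)
}

#' Laminar-flow check
#'
#' @inheritParams reynolds_number
#' @param threshold Reynolds number above which the flow is flagged.
#' @return `TRUE` when `Re < threshold`.
#' @export
is_laminar <- function(flow, diameter, params = carreau_yasuda(),
                       threshold = 2000) {
  reynolds_number(flow, diameter, params) < threshold
}
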