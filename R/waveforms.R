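#' Define a volumetric inflow waveform
#'
#' A waveform describes the cycle-resolved volumetric flow rate `Q(t)` over one
#' cardiac cycle of period `period`. All shapes are normalised analytically so
#' that the cycle mean of `Q(t)` equals `cycle_mean` exactly.
#'
#' Shapes:
#' \describe{
#'   \item{`steady`}{constant `Q(t) = cycle_mean`.}
#'   \item{`cosine_offset`}{`cycle_mean * (1 + a cos(2 pi t / T))` with
#'     pulsatility amplitude `a = shape_params$amplitude` (default 0.5).}
#'   \item{`square_reversal`}{piecewise constant: forward for `(1 - f) T`,
#'     reversed for `f T`, `f = shape_params$reversed_fraction` (default 0.25),
#'     magnitudes equal, scaled so the signed mean is `cycle_mean`.}
#'   \item{`coronary_generic`}{two raised-cosine lobes with diastolic
#'     dominance: a diastolic fraction of the period
#'     (`shape_params$diastolic_fraction`, default 0.6) carries
#'     `shape_params$diastolic_volume_fraction` (default 0.7) of the cycle
#'     volume, the systolic lobe the rest. A generic left-coronary stand-in;
#'     patient waveforms are not emulated.}
#' }
#'
#' @param period Cycle period T in seconds.
#' @param shape One of `"steady"`, `"cosine_offset"`, `"square_reversal"`,
#'   `"coronary_generic"`.
#' @param cycle_mean Cycle-mean volumetric flow rate (any consistent unit).
#' @param shape_params Named list of shape parameters (see Details).
#' @return An object of class `waveform_spec`.
#' @examples
#' w <- waveform_spec(0.8, "coronary_generic", cycle_mean = 1.4e-6)
#' waveform_eval(w, seq(0, 0.8, length.out = 5))
#' @export
waveform_spec <- function(period, shape = c("steady", "cosine_offset",
                                            "square_reversal",
                                            "coronary_generic"),
                          cycle_mean = 1, shape_params = list()) {
  shape <- match.arg(shape)
  stopifnot_positive(period, "period")
  if (!is.finite(cycle_mean)) abort("`cycle_mean` must be finite.")
  defaults <- switch(shape,
    steady = list(),
    cosine_offset = list(amplitude = 0.5),
    square_reversal = list(reversed_fraction = 0.25),
    coronary_generic = list(diastolic_fraction = 0.6,
                            diastolic_volume_fraction = 0.7)
  )
  shape_params <- utils::modifyList(defaults, shape_params)
  if (shape == "square_reversal") {
    f <- shape_params$reversed_fraction
    if (f < 0 || f >= 0.5) {
      abort("`reversed_fraction` must lie in [0, 0.5) for a nonzero mean.")
    }
  }
  structure(list(period = period, shape = shape, cycle_mean = cycle_mean,
                 shape_params = shape_params),
            class = "waveform_spec")
}

#' Evaluate a waveform at given times
#'
#' @param wave A [waveform_spec()].
#' @param t Times in seconds; reduced modulo the period.
#' @return Numeric vector of flow rates `Q(t)`.
#' @export
waveform_eval <- function(wave, t) {
  stopifnot(inherits(wave, "waveform_spec"))
  T <- wave$period
  tm <- t %% T
  # map t == T (mod) back to T so closed cycles keep their endpoint
  tm[t != 0 & tm == 0] <- T
  qm <- wave$cycle_mean
  p <- wave$shape_params
  switch(wave$shape,
    steady = rep(qm, length(t)),
    cosine_offset = qm * (1 + p$amplitude * cos(2 * pi * tm / T)),
    square_reversal = {
      f <- p$reversed_fraction
      mag <- qm / (1 - 2 * f)
      ifelse(tm <= (1 - f) * T, mag, -mag)
    },
    coronary_generic = {
      fd <- p$diastolic_fraction
      vd <- p$diastolic_volume_fraction
      Ts <- (1 - fd) * T
      Td <- fd * T
      As <- 2 * (1 - vd) * qm * T / Ts   # lobe peak heights: each raised
      Ad <- 2 * vd * qm * T / Td         # cosine integrates to peak*width/2
      ifelse(tm <= Ts,
             As * (1 - cos(2 * pi * tm / Ts)) / 2,
             Ad * (1 - cos(2 * pi * (tm - Ts) / Td)) / 2)
    })
}

#' Cycle mean of a waveform by quadrature
#'
#' Numerical check of the analytic normalisation; used by validation tests.
#'
#' @inheritParams waveform_eval
#' @param n Number of quadrature nodes.
#' @return Scalar cycle-mean flow.
#' @export
waveform_mean <- function(wave, n = 20001L) {
  t <- seq(0, wave$period, length.out = n)
  if (wave$shape == "square_reversal") {
    # place the jump exactly on a panel boundary so midpoints stay one-sided
    a <- (1 - wave$shape_params$reversed_fraction) * wave$period
    t <- sort(unique(c(t, a)))
  }
  # midpoint rule: exact for aligned piecewise constants, spectrally accurate
  # for the smooth periodic shapes
  mid <- (t[-1] + t[-length(t)]) / 2
  sum(waveform_eval(wave, mid) * diff(t)) / wave$period
}

#' Rescale a waveform to a target cycle mean
#'
#' Multiplicative rescaling: the shape is preserved and every ordinate scales
#' by `target_mean / cycle_mean`.
#'
#' @inheritParams waveform_eval
#' @param target_mean Desired cycle-mean flow rate.
#' @return A new `waveform_spec` with `cycle_mean = target_mean`.
#' @export
scale_waveform <- function(wave, target_mean) {
  stopifnot(inherits(wave, "waveform_spec"))
  if (wave$cycle_mean == 0) abort("Cannot rescale a zero-mean waveform.")
  wave$cycle_mean <- target_mean
  wave
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf("<waveform_spec> shape=%s, period=%g s, cycle mean=%g\n",
              x$shape, x$period, x$cycle_mean))
  invisible(x)
}

#' Tabulate a waveform over one cycle
#'
#' @inheritParams waveform_eval
#' @param n_steps Number of samples (inclusive of both endpoints).
#' @return A tibble with columns `time` and `flow`.
#' @export
waveform_table <- function(wave, n_steps = 101L) {
  t <- seq(0, wave$period, length.out = n_steps)
  tibble(time = t, flow = waveform_eval(wave, t))
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line labs
#' @export
autoplot.waveform_spec <- function(object, n_steps = 201L, ...) {
  ggplot(waveform_table(object, n_steps), aes(.data$time, .data$flow)) +
    geom_line() +
    labs(x = "time (s)", y = "flow rate", title = object$shape)
}
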