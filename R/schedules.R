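#' Growth-schedule model families
#'
#' The ten candidate families used both to generate synthetic per-year
#' cementum growth schedules and to model measured mass-specific growth
#' rate (msGR) series. Each family maps a year of life \eqn{t = 1, 2, \dots}
#' to an expected annual increment width (or msGR). Parameter order, by
#' family:
#'
#' \describe{
#'   \item{linear}{`a + b*t` — params `(a, b)`}
#'   \item{quadratic}{`a + b*t + c*t^2` — params `(a, b, c)`}
#'   \item{gaussian}{`a * exp(-(t - b)^2 / (2*c^2))` — params `(a, b, c)`}
#'   \item{exponential}{`a * exp(b*t) + c` — params `(a, b, c)`}
#'   \item{hill_sigmoid}{`c + (a - c) / (1 + (t/e)^h)` — params
#'     `(a, c, e, h)`; decreasing from `a` toward `c` for `h > 0`}
#'   \item{von_bertalanffy}{`a * (1 - b*exp(-k*t))` — params `(a, b, k)`}
#'   \item{logistic}{`a / (1 + exp(b*(t - c)))` — params `(a, b, c)`;
#'     decreasing for `b > 0`}
#'   \item{gompertz}{`a * exp(-b * exp(-k*t))` — params `(a, b, k)`}
#'   \item{power}{`a * t^b` — params `(a, b)`}
#'   \item{logarithmic}{`a + b*log(t)` — params `(a, b)`}
#' }
#'
#' @name growth_families
#' @keywords internal
NULL

#' Names of the supported growth model families
#' @return Character vector of the ten family names.
#' @export
growth_families <- function() {
  c("quadratic", "gaussian", "exponential", "hill_sigmoid",
    "von_bertalanffy", "logistic", "gompertz", "linear", "power",
    "logarithmic")
}

.family_npar <- c(
  linear = 2L, quadratic = 3L, gaussian = 3L, exponential = 3L,
  hill_sigmoid = 4L, von_bertalanffy = 3L, logistic = 3L, gompertz = 3L,
  power = 2L, logarithmic = 2L
)

#' Evaluate a growth family at given years
#'
#' @param family One of [growth_families()].
#' @param params Numeric coefficient vector in family order (see
#'   [growth_families]).
#' @param t Numeric vector of years of life (t >= 1 for `power` and
#'   `logarithmic` to stay finite).
#' @return Numeric vector of schedule values at `t`.
#' @export
eval_family <- function(family, params, t) {
  family <- match.arg(family, growth_families())
  np <- .family_npar[[family]]
  if (length(params) != np) {
    stop(sprintf("family '%s' needs %d parameters, got %d",
                 family, np, length(params)), call. = FALSE)
  }
  p <- as.numeric(params)
  switch(family,
    linear          = p[1] + p[2] * t,
    quadratic       = p[1] + p[2] * t + p[3] * t^2,
    gaussian        = p[1] * exp(-(t - p[2])^2 / (2 * p[3]^2)),
    exponential     = p[1] * exp(p[2] * t) + p[3],
    hill_sigmoid    = p[2] + (p[1] - p[2]) / (1 + (t / p[3])^p[4]),
    von_bertalanffy = p[1] * (1 - p[2] * exp(-p[3] * t)),
    logistic        = p[1] / (1 + exp(p[2] * (t - p[3]))),
    gompertz        = p[1] * exp(-p[2] * exp(-p[3] * t)),
    power           = p[1] * t^p[2],
    logarithmic     = p[1] + p[2] * log(t)
  )
}

#' Construct a growth schedule
#'
#' A growth schedule defines the expected width of each annual growth
#' layer group over a life span, as `base_width_um` scaled by the shape
#' of the chosen family normalised to its first-year value.
#'
#' @param model_family One of [growth_families()].
#' @param params Coefficients in family order.
#' @param n_years Positive integer life span in years.
#' @param base_width_um First-year width in micrometers before scaling.
#' @return An object of class `growth_schedule`.
#' @export
growth_schedule <- function(model_family, params, n_years,
                            base_width_um = 10) {
  model_family <- match.arg(model_family, growth_families())
  stopifnot(n_years >= 1, base_width_um > 0)
  n_years <- as.integer(n_years)
  sched <- structure(
    list(model_family = model_family, params = as.numeric(params),
         n_years = n_years, base_width_um = base_width_um),
    class = "growth_schedule")
  w <- schedule_widths(sched)   # validates positivity
  stopifnot(all(is.finite(w)))
  sched
}

#' Per-year widths of a growth schedule
#'
#' @param sched A [growth_schedule()].
#' @return Numeric vector of length `n_years` with strictly positive
#'   per-year widths in micrometers.
#' @export
schedule_widths <- function(sched) {
  stopifnot(inherits(sched, "growth_schedule"))
  t <- seq_len(sched$n_years)
  raw <- eval_family(sched$model_family, sched$params, t)
  bad <- which(!is.finite(raw) | raw <= 0)
  if (length(bad)) {
    stop(sprintf(
      "schedule '%s' produces a non-positive width in year %d (value %.4g)",
      sched$model_family, bad[1], raw[bad[1]]), call. = FALSE)
  }
  sched$base_width_um * raw / raw[1]
}

#' @export
print.growth_schedule <- function(x, ...) {
  cat(sprintf("<growth_schedule> %s, %d years, base %.3g um\n",
              x$model_family, x$n_years, x$base_width_um))
  invisible(x)
}
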