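#' Predicted first-year growth layer group width from body mass
#'
#' Exponential allometry between log10 body mass and log10 first-year
#' cementum increment width fitted on extant therians:
#' \deqn{\log_{10} w_1 = 0.270\,e^{0.340 \log_{10} M} + 0.564}
#' with `M` in grams and `w1` in micrometers.
#'
#' @param mass_g Body mass in grams (positive).
#' @return Predicted first growth layer group width in micrometers.
#' @export
predict_first_width <- function(mass_g) {
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("mass_g must be positive", call. = FALSE)
  }
  10^(0.270 * exp(0.340 * log10(mass_g)) + 0.564)
}

#' Mass-specific growth ratio strategy
#'
#' msGR conversion divides measured widths by a mass-dependent ratio
#' equal to 1 at `reference_mass_g`. The default strategy uses the
#' predicted first-year width allometry:
#' `ratio(M) = predict_first_width(M) / predict_first_width(M_ref)`.
#' A `"direct_mass"` strategy (`ratio(M) = M / M_ref`) is provided for
#' sensitivity checks.
#'
#' @param name `"first_width"` (default) or `"direct_mass"`.
#' @param reference_mass_g Mass at which the ratio is 1 (default 1 g).
#' @return Object of class `msgr_strategy`.
#' @export
msgr_strategy <- function(name = c("first_width", "direct_mass"),
                          reference_mass_g = 1) {
  name <- match.arg(name)
  stopifnot(reference_mass_g > 0)
  structure(list(name = name, reference_mass_g = reference_mass_g),
            class = "msgr_strategy")
}

#' Mass ratio of an msGR strategy
#' @param strategy An [msgr_strategy()].
#' @param mass_g Body mass in grams.
#' @return Dimensionless ratio, 1 at the reference mass.
#' @export
msgr_ratio <- function(strategy, mass_g) {
  stopifnot(inherits(strategy, "msgr_strategy"))
  switch(strategy$name,
    first_width = predict_first_width(mass_g) /
      predict_first_width(strategy$reference_mass_g),
    direct_mass = mass_g / strategy$reference_mass_g)
}

#' Convert per-year widths to mass-specific growth rates
#'
#' @param widths_um Per-year increment widths (micrometers, positive).
#' @param mass_g Body mass in grams.
#' @param strategy An [msgr_strategy()].
#' @return Per-year msGR (micrometers year^-1 g^-1) with the strategy
#'   recorded in attribute `"strategy"`.
#' @export
msgr <- function(widths_um, mass_g, strategy = msgr_strategy()) {
  stopifnot(all(widths_um > 0))
  out <- widths_um / msgr_ratio(strategy, mass_g)
  attr(out, "strategy") <- strategy$name
  out
}

#' Mass-specific standard metabolic rate from life span
#'
#' Clade-specific log-log regressions of msSMR (ml O2 hour^-1 g^-1,
#' synonymous with msBMR in mammals) on maximum life span:
#' mammals \eqn{\log_{10} msSMR = -0.237 \log_{10} L - 0.083};
#' non-avian reptiles \eqn{\log_{10} msSMR = -0.83 \log_{10} L - 0.31}.
#'
#' @param lifespan_years Life span in years (positive).
#' @param clade `"mammal"` or `"reptile"`.
#' @return msSMR in ml O2 hour^-1 g^-1.
#' @export
lifespan_to_mssmr <- function(lifespan_years, clade = c("mammal", "reptile")) {
  clade <- match.arg(clade)
  if (any(!is.finite(lifespan_years)) || any(lifespan_years <= 0)) {
    stop("lifespan_years must be positive", call. = FALSE)
  }
  L <- log10(lifespan_years)
  switch(clade,
    mammal  = 10^(-0.237 * L - 0.083),
    reptile = 10^(-0.83 * L - 0.31))
}

#' Dentary length from lower first molar length
#'
#' Linear scaling relationship for small-bodied fossil mammaliaforms:
#' `dentary (mm) = lm1 (mm) * 10.184 + 8.026`.
#'
#' @param lm1_mm Mesiodistal lm1 length in millimeters (positive).
#' @return Dentary length in millimeters.
#' @export
dentary_length_from_lm1 <- function(lm1_mm) {
  if (any(!is.finite(lm1_mm)) || any(lm1_mm <= 0)) {
    stop("lm1_mm must be positive", call. = FALSE)
  }
  lm1_mm * 10.184 + 8.026
}

#' Configurable log-log dentary-length to body-mass regression
#'
#' The published dentary-to-mass coefficients live in the cited source,
#' not in the primary text, so they are user-supplied configuration:
#' `log10(mass_g) = slope * log10(dentary_mm) + intercept`.
#'
#' @param slope,intercept Regression coefficients on the log10 scale.
#' @param source Free-text provenance string recorded with results.
#' @return Object of class `allometry_model`.
#' @export
mass_regression <- function(slope, intercept, source = "user-supplied") {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept, source = source),
            class = "allometry_model")
}

#' Body mass from dentary length
#'
#' @param dentary_mm Dentary length in millimeters (positive).
#' @param regression An [mass_regression()] object; required because the
#'   coefficients are external configuration.
#' @return Body mass in grams, with the regression provenance attached
#'   as attribute `"source"`.
#' @export
mass_from_dentary <- function(dentary_mm, regression) {
  if (missing(regression) || !inherits(regression, "allometry_model")) {
    stop(paste("supply a mass_regression(slope, intercept):",
               "the dentary-mass coefficients are configuration"),
         call. = FALSE)
  }
  if (any(!is.finite(dentary_mm)) || any(dentary_mm <= 0)) {
    stop("dentary_mm must be positive", call. = FALSE)
  }
  out <- 10^(regression$slope * log10(dentary_mm) + regression$intercept)
  attr(out, "source") <- regression$source
  out
}

#' Invert a mass regression (dentary length from mass)
#' @param mass_g Body mass in grams.
#' @param regression An [mass_regression()].
#' @return Dentary length in millimeters.
#' @export
dentary_from_mass <- function(mass_g, regression) {
  stopifnot(inherits(regression, "allometry_model"), all(mass_g > 0),
            regression$slope != 0)
  10^((log10(mass_g) - regression$intercept) / regression$slope)
}
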