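# Shell-length and body-mass prediction from stylopodial measurements.
#
# The shipped coefficient set reproduces the published summary equations for
# estimating straight carapace length (SCL, mm) from humerus or femur
# length: a global (Testudinata) equation per element, with and without the
# terrestrial-ecology covariate for the humerus, plus clade-specific
# equations for sea turtles (Pan-Chelonioidea) and softshell relatives
# (Pan-Trionychia, with a trionychid 0/1 covariate). Covariate coding is
# 1 = yes (terrestrial / trionychid), 0 = no.

#' Shipped shell-length estimation equations
#'
#' @return data frame of the published coefficient set: `clade`, `element`,
#'   `intercept`, `slope`, `covariate` (NA, `"terrestrial"` or
#'   `"trionychid"`) and `covariate_coef`.
#' @export
scl_equations <- function() {
  data.frame(
    clade = c("Testudinata", "Testudinata", "Testudinata",
              "Pan-Chelonioidea", "Pan-Chelonioidea",
              "Pan-Trionychia", "Pan-Trionychia"),
    element = c("humerus", "humerus", "femur", "humerus", "femur",
                "humerus", "femur"),
    intercept = c(0.85, 0.84, 0.64, 1.13, 1.41, 0.98, 0.97),
    slope = c(0.89, 0.88, 0.96, 0.80, 0.71, 0.86, 0.89),
    covariate = c("terrestrial", NA, NA, NA, NA, "trionychid", "trionychid"),
    covariate_coef = c(-0.05, NA, NA, NA, NA, -0.14, -0.20),
    stringsAsFactors = FALSE
  )
}

#' Predict straight carapace length from a stylopodial measurement
#'
#' Evaluates `SCL = 10^(a + b * log10(x) + c * covariate)` in millimetres.
#' With the default `fit = NULL` the shipped published equations are used
#' (see [scl_equations()]): pass `clade` to select a clade-specific
#' equation, and `terrestrial` / `trionychid` where the equation carries
#' that covariate (the global humerus equation without ecology is used when
#' `terrestrial` is NA). Shipped-equation predictions are point estimates
#' only. When a fitted model is supplied, its coefficients are used instead,
#' and a bootstrap object yields a 95 percent interval: the spread of the
#' linear predictor over bootstrap replicates plus (for
#' `interval = "prediction"`) the model residual variance
#' `sigma2 * mean tip depth` on the log10 scale, the extra scatter a new
#' observation carries.
#'
#' @param length_mm stylopodial length(s) in mm (> 0).
#' @param element `"humerus"` or `"femur"`.
#' @param clade equation label: `"Testudinata"` (global),
#'   `"Pan-Chelonioidea"` or `"Pan-Trionychia"`.
#' @param terrestrial 0/1 (or NA when ecology is unknown).
#' @param trionychid 0/1; required by the Pan-Trionychia equations.
#' @param fit optional `"pgls_fit"` whose coefficients replace the shipped
#'   equation; predictor order must be (intercept, log10 length, covariate).
#' @param boot optional `"pgls_boot"` for the same model, used for the
#'   interval.
#' @param interval `"prediction"` (default; includes residual variance) or
#'   `"coefficient"` (spread of the regression line only).
#' @param covariate_value covariate value (0/1) applied with `fit` when the
#'   fitted model has a third coefficient.
#' @return data frame of class `"scl_prediction"`: `element`, `basis`,
#'   `length_mm`, `scl_mm`, `lower`, `upper` (NA without a bootstrap).
#' @export
predict_scl <- function(length_mm, element = c("humerus", "femur"),
                        clade = "Testudinata", terrestrial = NA,
                        trionychid = NA, fit = NULL, boot = NULL,
                        interval = c("prediction", "coefficient"),
                        covariate_value = 0) {
  element <- match.arg(element)
  interval <- match.arg(interval)
  if (any(!is.finite(length_mm)) || any(length_mm <= 0))
    stop("lengths must be positive", call. = FALSE)
  lx <- log10(length_mm)

  if (is.null(fit)) {
    eq <- scl_equations()
    eq <- eq[eq$clade == clade & eq$element == element, ]
    if (!nrow(eq))
      stop("no shipped equation for clade '", clade, "' and element '",
           element, "'", call. = FALSE)
    if (nrow(eq) > 1) {  # global humerus: with vs. without ecology
      eq <- if (length(terrestrial) == 1 && is.na(terrestrial))
        eq[is.na(eq$covariate), ] else eq[!is.na(eq$covariate), ]
    }
    cov_val <- 0
    if (!is.na(eq$covariate)) {
      cov_val <- switch(eq$covariate, terrestrial = terrestrial,
                        trionychid = trionychid)
      if (any(is.na(cov_val)))
        stop("equation requires covariate '", eq$covariate,
             "' (0/1) but it is missing", call. = FALSE)
    }
    eta <- eq$intercept + eq$slope * lx +
      (if (is.na(eq$covariate)) 0 else eq$covariate_coef * cov_val)
    out <- data.frame(element = element, basis = clade,
                      length_mm = length_mm, scl_mm = 10^eta,
                      lower = NA_real_, upper = NA_real_,
                      stringsAsFactors = FALSE)
    class(out) <- c("scl_prediction", "data.frame")
    return(out)
  }

  ct <- fit$coefficients
  if (fit$k < 2) stop("fitted model has no slope term", call. = FALSE)
  eta <- ct$estimate[1] + ct$estimate[2] * lx +
    (if (fit$k >= 3) ct$estimate[3] * covariate_value else 0)
  lower <- upper <- rep(NA_real_, length(eta))
  if (!is.null(boot)) {
    d <- boot$draws
    for (i in seq_along(eta)) {
      eta_b <- d[, 1] + d[, 2] * lx[i] +
        (if (ncol(d) >= 3) d[, 3] * covariate_value else 0)
      if (interval == "prediction") {
        extra <- fit$sigma2 * (fit$mean_tip_depth %||% 1)
        half <- stats::qnorm(0.975) * sqrt(var(eta_b) + extra)
        lower[i] <- 10^(eta[i] - half)
        upper[i] <- 10^(eta[i] + half)
      } else {
        q <- quantile(eta_b, c(0.025, 0.975), names = FALSE)
        lower[i] <- 10^q[1]
        upper[i] <- 10^q[2]
      }
    }
  }
  out <- data.frame(element = element, basis = "fitted",
                    length_mm = length_mm, scl_mm = 10^eta,
                    lower = lower, upper = upper, stringsAsFactors = FALSE)
  class(out) <- c("scl_prediction", "data.frame")
  out
}

#' Predict body mass from straight carapace length
#'
#' Evaluates the published phylogenetic regression of body mass on shell
#' length for turtles, `log10(BM) = slope * log10(SCL) + intercept` with BM
#' in grams and SCL in millimetres; the shipped defaults are the
#' coefficients fitted to 111 extant species (slope 2.73, intercept -3.18).
#' A slope below the isometric expectation of 3 means mass grows more
#' slowly than the cube of shell length.
#'
#' @param scl_mm straight carapace length(s) in mm (> 0).
#' @param slope,intercept regression coefficients on the log10 scale.
#' @return data frame: `scl_mm`, `bm_g` (grams), `bm_kg`.
#' @examples
#' predict_bm(519)   # ~17 kg
#' @export
predict_bm <- function(scl_mm, slope = 2.73, intercept = -3.18) {
  if (any(!is.finite(scl_mm)) || any(scl_mm <= 0))
    stop("SCL must be positive", call. = FALSE)
  g <- 10^(slope * log10(scl_mm) + intercept)
  data.frame(scl_mm = scl_mm, bm_g = g, bm_kg = g / 1000)
}
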