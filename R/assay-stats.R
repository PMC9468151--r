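# Closed-form assay statistics and a four-parameter logistic (4PL)
# dose-response fitter.  Percent quantities are carried on the printed
# 0-100 scale throughout, never as fractions.

#' Osteoclast inhibitory ratio
#'
#' Percent inhibition of osteoclast counts, normalised between the
#' unstimulated baseline and the untreated (stimulated) control:
#' `100 - (treated - unstimulated) / (untreated - unstimulated) * 100`.
#' Values outside `[0, 100]` (treated count outside the control range) are
#' returned as-is with attribute `flagged = TRUE`.
#'
#' @param oc_treated,oc_untreated,oc_unstimulated non-negative osteoclast
#'   counts per well; `oc_untreated` must exceed `oc_unstimulated`.
#' @return Inhibition in percent.
#' @examples
#' oc_inhibition_ratio(26, 50, 2)  # 50
#' @export
oc_inhibition_ratio <- function(oc_treated, oc_untreated, oc_unstimulated) {
  if (any(c(oc_treated, oc_untreated, oc_unstimulated) < 0)) {
    stop("osteoclast counts must be non-negative")
  }
  denom <- oc_untreated - oc_unstimulated
  if (denom <= 0) {
    stop("untreated count must exceed the unstimulated baseline")
  }
  ratio <- 100 - (oc_treated - oc_unstimulated) / denom * 100
  if (ratio < 0 || ratio > 100) attr(ratio, "flagged") <- TRUE
  ratio
}

#' Cell growth inhibition ratio
#'
#' `(OD_vehicle - OD_treated) / OD_vehicle * 100`, from MTT absorbance
#' readings at 570 nm.
#'
#' @param od_vehicle,od_treated optical densities; `od_vehicle` must be
#'   positive.
#' @return Inhibition in percent.
#' @export
growth_inhibition_ratio <- function(od_vehicle, od_treated) {
  if (od_vehicle <= 0) stop("vehicle OD must be positive")
  (od_vehicle - od_treated) / od_vehicle * 100
}

#' Equilibrium dissociation constant from kinetic rates
#'
#' `KD = kd / ka` as used to summarise SPR sensorgram fits.  Units
#' propagate: ka in 1/(M s) and kd in 1/s give KD in M.
#'
#' @param ka association rate constant (> 0).
#' @param kd_rate dissociation rate constant (>= 0).
#' @return KD in the concentration unit implied by `ka`.
#' @examples
#' kd_from_rates(2e5, 1e-2)  # 5e-8 M
#' @export
kd_from_rates <- function(ka, kd_rate) {
  if (ka <= 0) stop("association rate ka must be positive")
  if (kd_rate < 0) stop("dissociation rate must be non-negative")
  kd_rate / ka
}

#' Selectivity index from two dissociation constants
#'
#' `SI = KD(reference form) / KD(primary form)`; SI > 1 means the ligand
#' binds the primary form preferentially.  The rounded value uses
#' half-away-from-zero rounding to the nearest integer, matching how such
#' indices are reported (e.g. 124 / 5.78 = 21.45 -> 21).
#'
#' @param kd_primary KD against the primary (intended) form.
#' @param kd_reference KD against the reference (counter-screen) form, in
#'   the same units.
#' @return A list with `si_raw` and `si_rounded`.
#' @examples
#' selectivity_index(5.78, 124)$si_rounded  # 21
#' @export
selectivity_index <- function(kd_primary, kd_reference) {
  if (kd_primary <= 0 || kd_reference <= 0) {
    stop("dissociation constants must be positive")
  }
  si <- kd_reference / kd_primary
  list(si_raw = si, si_rounded = as.integer(floor(abs(si) + 0.5) * sign(si)))
}

#' Organ coefficient
#'
#' Organ mass relative to body mass, `organ_mass [mg] / body_mass [g]`.
#'
#' @param organ_mass_mg organ wet mass in milligram (> 0).
#' @param body_mass_g body mass in gram (> 0).
#' @return Coefficient in mg/g.
#' @export
organ_coefficient <- function(organ_mass_mg, body_mass_g) {
  if (organ_mass_mg <= 0 || body_mass_g <= 0) {
    stop("masses must be positive")
  }
  organ_mass_mg / body_mass_g
}

# ---- four-parameter logistic dose-response -----------------------------

.logistic4_eval <- function(dose, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill)`
#' on the log-dose scale, the standard sigmoid used for IC50 estimation.
#' With `hill > 0` the response falls from `top` (low dose) to `bottom`
#' (high dose), the usual shape for an inhibition assay.
#'
#' Initialisation is deterministic: `bottom = min(response)`,
#' `top = max(response)`, `hill = 1`, and `ic50` at the dose where the
#' response crosses the half-range (log-linear interpolation).  The hill
#' slope is bounded to `[0.1, 10]`.  If the first Levenberg-Marquardt run
#' fails, up to five jittered restarts are tried from a fixed restart
#' seed, so the fit is reproducible.
#'
#' @param doses strictly increasing positive concentrations (same unit as
#'   the returned `ic50`).
#' @param responses response values in percent (or any linear scale),
#'   same length as `doses`; at least 5 points.
#' @return An object of class `"logistic4"` with components
#'   `coefficients` (`bottom`, `top`, `ic50`, `hill`), `fitted`,
#'   `residuals`, `rss`, `doses`, `responses`, `converged`.  Supports
#'   `coef()`, `predict()`, `residuals()`, `fitted()`, `summary()` and
#'   `plot()`.
#' @export
fit_logistic4 <- function(doses, responses) {
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses)) {
    stop("doses and responses must have equal length")
  }
  if (length(doses) < 5L) stop("at least 5 dose points are required")
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  span <- diff(range(responses))
  if (span < .Machine$double.eps^0.5 * max(1, abs(mean(responses)))) {
    stop("flat responses: hill slope and ic50 are unidentifiable")
  }

  half <- (min(responses) + max(responses)) / 2
  ld <- log10(doses)
  # dose at the half-range crossing, interpolated on log-dose
  cross <- which(diff(sign(responses - half)) != 0)
  ic50_0 <- if (length(cross) > 0L) {
    i <- cross[1]
    f <- (half - responses[i]) / (responses[i + 1] - responses[i])
    10^(ld[i] + f * (ld[i + 1] - ld[i]))
  } else {
    10^stats::median(ld)
  }
  start <- c(bottom = min(responses), top = max(responses),
             lic50 = log10(ic50_0), hill = 1)
  lower <- c(-Inf, -Inf, min(ld) - 3, 0.1)
  upper <- c(Inf, Inf, max(ld) + 3, 10)

  fit_once <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        responses ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - lic50))),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  fit <- fit_once(start)
  if (is.null(fit)) {
    jit_rng <- .stream_rng(977L, 1L)   # fixed restart seed, input-independent
    for (r in seq_len(5L)) {
      st <- start
      st["lic50"] <- start[["lic50"]] + jit_rng(1) * 0.5
      st["hill"] <- min(max(start[["hill"]] * exp(jit_rng(1) * 0.3), 0.1), 10)
      fit <- fit_once(st)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) {
    stop("4PL fit failed to converge after 5 restarts; ",
         "check the dose-response data for a sigmoidal trend")
  }

  cf <- stats::coef(fit)
  coefficients <- c(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                    ic50 = unname(10^cf["lic50"]), hill = unname(cf["hill"]))
  fitted_vals <- .logistic4_eval(doses, coefficients["bottom"],
                                 coefficients["top"], coefficients["ic50"],
                                 coefficients["hill"])
  res <- responses - fitted_vals
  structure(
    list(coefficients = coefficients, fitted = fitted_vals,
         residuals = res, rss = sum(res^2),
         doses = doses, responses = responses, converged = TRUE),
    class = "logistic4"
  )
}

#' @export
coef.logistic4 <- function(object, ...) object$coefficients

#' @export
fitted.logistic4 <- function(object, ...) object$fitted

#' @export
residuals.logistic4 <- function(object, ...) object$residuals

#' Predict from a fitted 4PL curve
#' @param object a [fit_logistic4()] fit.
#' @param newdata optional vector of doses; defaults to the fitted doses.
#' @param ... unused.
#' @export
predict.logistic4 <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$doses else as.numeric(newdata)
  cf <- object$coefficients
  .logistic4_eval(d, cf["bottom"], cf["top"], cf["ic50"], cf["hill"])
}

#' @export
print.logistic4 <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "4PL dose-response fit: ic50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g\n",
    cf["ic50"], cf["hill"], cf["top"], cf["bottom"]))
  cat(sprintf("  %d dose points, RSS = %.4g\n", length(x$doses), x$rss))
  invisible(x)
}

#' @export
summary.logistic4 <- function(object, ...) {
  print(object)
  cat("residuals:\n")
  print(summary(object$residuals))
  invisible(object)
}

#' @export
plot.logistic4 <- function(x, ...) {
  grid <- 10^seq(log10(min(x$doses)), log10(max(x$doses)), length.out = 200)
  plot(x$doses, x$responses, log = "x",
       xlab = "dose", ylab = "response", ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$coefficients["ic50"], lty = 2)
  invisible(x)
}
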