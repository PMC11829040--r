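# Calibration-based nucleoside quantification, guanosine normalization,
# conversion yields and log-logistic dose-response fitting.

#' Build a calibration series
#'
#' A calibration series pairs spiked amounts (pmol) with analyte/internal-
#' standard response ratios for one nucleoside. The default experimental
#' design is a 12-point 1:1 serial dilution.
#'
#' @param code Nucleoside code.
#' @param amount Numeric vector of amounts in pmol (strictly positive).
#' @param response Numeric vector of response ratios (analyte / stable-
#'   isotope-labeled internal standard), same length.
#' @return A `calibration_series` (data.frame with attributes).
#' @export
calibration_series <- function(code, amount, response) {
  stopifnot(length(amount) == length(response))
  if (any(amount <= 0)) stop("calibration amounts must be strictly positive")
  structure(data.frame(amount = amount, response = response),
            class = c("calibration_series", "data.frame"), code = code)
}

#' Fit a calibration curve
#'
#' Ordinary least squares of response ratio on amount (the regression the
#' instrument software applies); optional 1/x weighting down-weights the
#' top of the dilution series.
#'
#' @param series A [calibration_series()] with at least 3 points.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return A `calibration_curve`: slope, intercept, r_squared, valid `range`
#'   (min/max calibrated pmol), `usable` flag (slope > 0) and the code.
#' @export
fit_calibration <- function(series, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(series, "calibration_series"))
  if (nrow(series) < 3) stop("need at least 3 calibration points")
  if (length(unique(series$amount)) < 2) {
    stop("degenerate calibration series: all amounts equal")
  }
  w <- if (weighting == "1/x") 1 / series$amount else NULL
  fit <- stats::lm(response ~ amount, data = series, weights = w)
  co <- stats::coef(fit)
  structure(list(
    slope = unname(co[["amount"]]),
    intercept = unname(co[["(Intercept)"]]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    range = range(series$amount),
    n = nrow(series),
    usable = unname(co[["amount"]]) > 0,
    code = attr(series, "code"),
    weighting = weighting
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration %s> response = %.5g * pmol + %.5g (R2 = %.4f, n = %d, %.3g-%.4g pmol)\n",
              x$code %||% "?", x$slope, x$intercept, x$r_squared, x$n,
              x$range[1], x$range[2]))
  invisible(x)
}

#' Inverse-predict an amount from a response ratio
#'
#' @param response Observed response ratio(s).
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @return Amount(s) in pmol, with attribute `out_of_range` flagging
#'   predictions outside the calibrated range.
#' @export
quantify <- function(response, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration curve has non-positive slope")
  amount <- (response - curve$intercept) / curve$slope
  attr(amount, "out_of_range") <- amount < curve$range[1] | amount > curve$range[2]
  amount
}

#' Per-molecule nucleoside counts by reference normalization
#'
#' Normalizes measured amounts to molecule counts using a reference
#' nucleoside of known per-molecule count — guanosine by default, because it
#' is untouched by hydrazine: `molecules = amount[ref] / count[ref]`, then
#' `count[x] = amount[x] / molecules`.
#'
#' @param amounts Named numeric vector of amounts (pmol) per nucleoside
#'   code.
#' @param reference Reference code, default `"G"`.
#' @param reference_count Known per-molecule count of the reference (e.g.
#'   from the RNA sequence).
#' @return Named numeric vector of per-molecule counts (the reference maps
#'   to `reference_count`).
#' @export
per_molecule_counts <- function(amounts, reference = "G", reference_count) {
  if (!reference %in% names(amounts)) {
    stop("reference nucleoside '", reference, "' missing from amounts")
  }
  if (amounts[[reference]] <= 0) stop("reference amount must be positive")
  stopifnot(reference_count > 0)
  molecules <- amounts[[reference]] / reference_count
  amounts / molecules
}

#' Hydrazine conversion yield
#'
#' `c.y. = 1 - treated/control`, clipped to `[0, 1]`; the raw (unclipped)
#' value is retained as an attribute because measurement noise can put
#' treated above control.
#'
#' @param control Per-molecule count (or amount) in the untreated sample,
#'   > 0.
#' @param treated Matching count in the treated sample.
#' @return Conversion yield(s) in `[0, 1]` with attribute `raw`.
#' @examples
#' conversion_yield(16, 12)  # 0.25
#' @export
conversion_yield <- function(control, treated) {
  if (any(control <= 0)) stop("control count must be positive")
  raw <- 1 - treated / control
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "raw") <- raw
  out
}

#' Fit a log-logistic dose-response to a concentration series
#'
#' Fits the remaining-fraction model
#' `remaining(c) = 1 - ceiling / (1 + (ec50/c)^slope)` by bounded
#' Levenberg-Marquardt least squares (ceiling constrained to `[0, 1]`).
#' Flat series (no response) return `ceiling ~ 0` with an
#' `ec50_unidentifiable` flag; near-step series are flagged `steep`.
#'
#' @param concentration Hydrazine concentrations (% v/v), at least 4
#'   including 0.
#' @param remaining Remaining fraction of the nucleoside at each
#'   concentration (1 at c = 0 up to noise).
#' @param start Optional named list of start values (`ec50`, `slope`,
#'   `ceiling`).
#' @param fix_ceiling Optional known maximal converted fraction. When the
#'   concentration range does not reach the response plateau, the free
#'   3-parameter fit is weakly identified (ceiling and EC50 trade off);
#'   fixing the ceiling (typically at 1 for species known to convert
#'   completely) restores identifiability.
#' @return A `dose_response_fit`: `ec50`, `slope`, `ceiling`, standard
#'   errors, `flags` (character vector), `converged`, and the underlying
#'   `nls` fit (or NULL).
#' @export
fit_dose_response <- function(concentration, remaining, start = NULL,
                              fix_ceiling = NULL) {
  stopifnot(length(concentration) == length(remaining))
  if (length(concentration) < 4) stop("need at least 4 concentrations")
  if (!any(concentration == 0)) stop("the series must include concentration 0")
  df <- data.frame(conc = concentration, rem = remaining)
  flags <- character(0)

  drop <- max(0, 1 - min(df$rem))
  if (drop < 0.05) {
    # essentially flat: ceiling ~ 0, EC50 carries no information
    return(structure(list(ec50 = NA_real_, slope = NA_real_, ceiling = drop,
                          se = c(ec50 = NA_real_, slope = NA_real_,
                                 ceiling = NA_real_),
                          flags = c("flat", "ec50_unidentifiable"),
                          converged = TRUE, fit = NULL),
                     class = "dose_response_fit"))
  }
  if (is.null(start)) {
    pos <- df[df$conc > 0, ]
    half <- 1 - drop / 2
    i <- which.min(abs(pos$rem - half))
    start <- list(ec50 = max(pos$conc[i], 1e-3), slope = 2,
                  ceiling = min(drop, 1))
  }
  fit <- tryCatch(
    if (is.null(fix_ceiling)) {
      minpack.lm::nlsLM(
        rem ~ 1 - dose_response_fraction(conc, ec50, slope, ceiling),
        data = df, start = start,
        lower = c(ec50 = 1e-6, slope = 0.1, ceiling = 0),
        upper = c(ec50 = 10 * max(df$conc), slope = 50, ceiling = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      stopifnot(fix_ceiling > 0, fix_ceiling <= 1)
      df$ceiling_fixed <- fix_ceiling
      minpack.lm::nlsLM(
        rem ~ 1 - dose_response_fraction(conc, ec50, slope, ceiling_fixed),
        data = df, start = start[c("ec50", "slope")],
        lower = c(ec50 = 1e-6, slope = 0.1),
        upper = c(ec50 = 100 * max(df$conc), slope = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(ec50 = NA_real_, slope = NA_real_,
                          ceiling = NA_real_,
                          se = c(ec50 = NA_real_, slope = NA_real_,
                                 ceiling = NA_real_),
                          flags = c("non_convergence",
                                    conditionMessage(fit)),
                          converged = FALSE, fit = NULL),
                     class = "dose_response_fit"))
  }
  co <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) stats::setNames(rep(NA_real_,
                                                         length(co)),
                                                     names(co)))
  if (co[["slope"]] >= 20) flags <- c(flags, "steep")
  ceiling_hat <- if (is.null(fix_ceiling)) unname(co[["ceiling"]]) else fix_ceiling
  ceiling_se <- if (is.null(fix_ceiling)) unname(se[["ceiling"]]) else 0
  structure(list(ec50 = unname(co[["ec50"]]), slope = unname(co[["slope"]]),
                 ceiling = ceiling_hat,
                 se = c(ec50 = unname(se[["ec50"]]),
                        slope = unname(se[["slope"]]),
                        ceiling = ceiling_se),
                 flags = flags, converged = TRUE, fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose-response fit> EC50 = %.3g%%, slope = %.3g, ceiling = %.3g%s\n",
              x$ec50, x$slope, x$ceiling,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}
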