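# Time-integrated activity coefficients and organ absorbed doses per unit
# injected activity, for beta/gamma-emitting radiolabels (default Lu-177).

#' Physical nuclide data
#'
#' Half-life and mean emitted energy per decay, split into electrons
#' (beta + conversion + Auger, absorbed locally in the local-deposition
#' model) and photons (ignored by it). Defaults are the ICRP-107 values for
#' Lu-177.
#'
#' @param half_life_h physical half-life (h, > 0).
#' @param delta_electron_keV mean electron energy per decay (keV, > 0).
#' @param delta_photon_keV mean photon energy per decay (keV, > 0).
#' @return object of class `nuclide_data` with derived `lambda_phys` (1/h).
#' @export
nuclide_data <- function(half_life_h = 159.53, delta_electron_keV = 147.9,
                         delta_photon_keV = 28.7) {
  stopifnot(half_life_h > 0, delta_electron_keV > 0, delta_photon_keV > 0)
  structure(list(half_life_h = half_life_h,
                 delta_electron_keV = delta_electron_keV,
                 delta_photon_keV = delta_photon_keV,
                 lambda_phys = log(2) / half_life_h),
            class = "nuclide_data")
}

#' Lutetium-177 nuclide data
#' @return a [nuclide_data()] object with Lu-177 constants.
#' @export
lu177 <- function() nuclide_data()

#' Normalized time-activity curve
#'
#' Organ activity as a fraction of injected activity versus time. The
#' `decay_corrected` flag records whether physical decay has been removed
#' from the values (as is usual for gamma-counter biodistribution data);
#' integration routines re-apply it when set.
#'
#' @param organ organ name.
#' @param times time points (h), strictly increasing.
#' @param values normalized activity (fraction of injected), >= 0.
#' @param decay_corrected logical flag.
#' @return object of class `ntac`.
#' @export
ntac <- function(organ, times, values, decay_corrected = TRUE) {
  stopifnot(length(times) == length(values))
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("'values' must be nonnegative", call. = FALSE)
  structure(list(organ = organ, times = as.numeric(times),
                 values = as.numeric(values),
                 decay_corrected = isTRUE(decay_corrected)),
            class = "ntac")
}

#' Bi-exponential fit of a normalized time-activity curve
#'
#' Fits A1 exp(-l1 t) + A2 exp(-l2 t) by least squares. With
#' `monotone = TRUE` (the default) amplitudes and decay constants are kept
#' positive via log parameterisation, so the fitted curve is monotonically
#' decreasing; when such a constrained fit explains the data poorly
#' (R-squared below `r2_threshold`, e.g. for uptake-then-washout curves) a
#' `non_monotone` flag is raised to signal that trapezoidal integration
#' should be used instead.
#'
#' @param x an [ntac()] with at least 4 points, at least 3 of them positive.
#' @param monotone constrain to a decreasing bi-exponential.
#' @param r2_threshold R-squared below which the non-monotone flag is set.
#' @return list of class `biexp_fit`: `A1`, `lambda1`, `A2`, `lambda2`
#'   (ordered so `lambda1 <= lambda2`), `r_squared`, `non_monotone`,
#'   `fitted`, `residuals`.
#' @export
fit_biexponential <- function(x, monotone = TRUE, r2_threshold = 0.9) {
  stopifnot(inherits(x, "ntac"))
  t <- x$times; y <- x$values
  if (length(t) < 4L) stop("under-determined: need at least 4 points", call. = FALSE)
  if (sum(y > 0) < 3L) stop("under-determined: need at least 3 positive values", call. = FALSE)

  # amplitudes positive (log scale) when monotone; free sign otherwise
  amp <- if (monotone) function(a) exp(a) else function(a) a
  ampinv <- if (monotone) function(a) log(max(a, 1e-8)) else function(a) a
  model <- function(p) amp(p[1]) * exp(-exp(p[2]) * t) + amp(p[3]) * exp(-exp(p[4]) * t)
  y0 <- max(abs(y))
  span <- max(t) - min(t)
  starts <- list(
    c(ampinv(y0 * 0.7), log(1 / span), ampinv(y0 * 0.3), log(10 / span)),
    c(ampinv(y0 * 0.9), log(0.3 / span), ampinv(y0 * 0.1), log(3 / span)))
  if (!monotone)
    starts <- c(starts, list(c(y0, log(0.5 / span), -y0, log(10 / span))))
  best <- NULL
  for (p0 in starts) {
    f <- tryCatch(minpack.lm::nls.lm(par = p0, fn = function(p) y - model(p),
                                     control = minpack.lm::nls.lm.control(maxiter = 500)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2))) best <- f
  }
  if (is.null(best)) stop("bi-exponential fit failed", call. = FALSE)
  p <- best$par
  A <- amp(p[1]); A <- c(A, amp(p[3])); l <- exp(p[c(2, 4)])
  ord <- order(l)
  A <- A[ord]; l <- l[ord]
  fitted <- model(p)
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  structure(list(A1 = A[1], lambda1 = l[1], A2 = A[2], lambda2 = l[2],
                 r_squared = r2, non_monotone = monotone && r2 < r2_threshold,
                 fitted = fitted, residuals = y - fitted),
            class = "biexp_fit")
}

#' Analytic time-integrated activity of a bi-exponential curve
#'
#' Integral over (0, infinity) of A1 exp(-l1 t) + A2 exp(-l2 t), i.e.
#' A1/l1 + A2/l2, in MBq.h/MBq when amplitudes are fractions of injected
#' activity and decay constants are per hour.
#'
#' @param A1,lambda1,A2,lambda2 bi-exponential parameters; decay constants
#'   must be strictly positive (the integral diverges otherwise). `A2 = 0`
#'   reduces to a mono-exponential.
#' @return time-integrated activity coefficient (h).
#' @export
tiac_analytic <- function(A1, lambda1, A2 = 0, lambda2 = 1) {
  if (lambda1 <= 0 || (A2 != 0 && lambda2 <= 0))
    stop("divergent integral: decay constants must be > 0", call. = FALSE)
  A1 / lambda1 + if (A2 != 0) A2 / lambda2 else 0
}

#' TIAC by trapezoidal integration with a physical-decay tail
#'
#' Integrates the measured curve by the trapezoid rule from t = 0 to the
#' last measurement and adds an analytic mono-exponential tail governed by
#' the physical decay constant beyond it. If the curve is flagged
#' decay-corrected, physical decay is re-applied before integration. When
#' no measurement exists at t = 0, a starting value is prepended according
#' to `t0`: `"extrapolate"` back-extrapolates the first two points linearly
#' (floored at 0, suitable for blood-borne organs), `"zero"` starts at 0,
#' `"first"` carries the first value back.
#'
#' @param x an [ntac()].
#' @param nuclide a [nuclide_data()].
#' @param t0 policy for the value at time zero.
#' @return time-integrated activity coefficient (MBq.h/MBq).
#' @export
tiac_trapezoid_tail <- function(x, nuclide = lu177(),
                                t0 = c("extrapolate", "zero", "first")) {
  stopifnot(inherits(x, "ntac"), inherits(nuclide, "nuclide_data"))
  t0 <- match.arg(t0)
  t <- x$times; y <- x$values
  if (x$decay_corrected) y <- y * exp(-nuclide$lambda_phys * t)
  if (t[1] > 0) {
    y0 <- switch(t0,
      zero = 0,
      first = y[1],
      extrapolate = if (length(t) >= 2L)
        max(0, y[1] - (y[2] - y[1]) / (t[2] - t[1]) * t[1]) else y[1])
    t <- c(0, t); y <- c(y0, y)
  }
  if (all(y == 0)) return(0)
  trap <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  tail_int <- y[length(y)] / nuclide$lambda_phys
  trap + tail_int
}

#' Organ absorbed dose per unit injected activity
#'
#' Local-deposition model: all electron energy emitted in the organ is
#' absorbed there and photons are neglected, giving
#' D = TIAC x 3.6e9 decays/(MBq.h) x Delta_e / mass. Alternatively a
#' user-supplied S matrix (mGy per MBq.h, target x source) combines the
#' TIACs of several source organs.
#'
#' @param tiac time-integrated activity coefficient(s) (MBq.h/MBq). For
#'   `model = "s_matrix"`, a named vector over source organs.
#' @param mass_g organ mass (g, > 0); required for local deposition.
#' @param nuclide a [nuclide_data()].
#' @param model `"local_deposition"` or `"s_matrix"`.
#' @param s_matrix named matrix (targets x sources) of S values
#'   (mGy/(MBq.h)) when `model = "s_matrix"`.
#' @param organ organ name recorded in the result (local deposition) .
#' @return data frame of class `dose_record` with columns `organ`,
#'   `mass_g`, `tiac`, `absorbed_dose_mGy_MBq`, `model`.
#' @export
absorbed_dose <- function(tiac, mass_g = NULL, nuclide = lu177(),
                          model = c("local_deposition", "s_matrix"),
                          s_matrix = NULL, organ = "organ") {
  model <- match.arg(model)
  if (model == "local_deposition") {
    stopifnot(length(tiac) == 1L, tiac >= 0)
    if (is.null(mass_g) || mass_g <= 0) stop("'mass_g' must be > 0", call. = FALSE)
    joule_per_decay_keV <- 1.602176634e-19 * 1e3   # J per keV
    energy_J <- tiac * 3.6e9 * nuclide$delta_electron_keV * joule_per_decay_keV
    dose <- 1e3 * energy_J / (mass_g / 1e3)        # mGy
    out <- data.frame(organ = organ, mass_g = mass_g, tiac = tiac,
                      absorbed_dose_mGy_MBq = dose, model = model)
  } else {
    if (is.null(s_matrix) || is.null(colnames(s_matrix)) || is.null(rownames(s_matrix)))
      stop("'s_matrix' with named rows (targets) and columns (sources) required",
           call. = FALSE)
    miss <- setdiff(names(tiac), colnames(s_matrix))
    if (length(miss))
      stop("S matrix lacks source column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    dose <- drop(s_matrix[, names(tiac), drop = FALSE] %*% tiac)
    out <- data.frame(organ = rownames(s_matrix),
                      mass_g = NA_real_, tiac = NA_real_,
                      absorbed_dose_mGy_MBq = dose, model = model)
  }
  rownames(out) <- NULL
  class(out) <- c("dose_record", "data.frame")
  out
}

#' Absorbed-dose ratio between two organs
#'
#' @param doses a `dose_record` data frame (or any data frame with columns
#'   `organ` and `absorbed_dose_mGy_MBq`).
#' @param numerator,denominator organ names.
#' @param digits optional rounding of the reported ratio.
#' @return the dose ratio (numeric scalar).
#' @export
dose_ratio <- function(doses, numerator, denominator, digits = NULL) {
  g <- function(o) {
    i <- match(o, doses$organ)
    if (is.na(i)) stop("organ not present: ", o, call. = FALSE)
    doses$absorbed_dose_mGy_MBq[i]
  }
  den <- g(denominator)
  if (den == 0) stop("denominator dose is zero", call. = FALSE)
  r <- g(numerator) / den
  if (!is.null(digits)) r <- round(r, digits)
  r
}

#' TIAC with uncertainty from mean and spread curves
#'
#' Computes the TIAC at the mean curve and at mean +/- SD curves, reporting
#' the half-range as the uncertainty.
#'
#' @param times time points (h).
#' @param mean_values,sd_values mean and SD of the normalized activity at
#'   each time.
#' @param organ organ name.
#' @param nuclide a [nuclide_data()].
#' @param decay_corrected whether the values are decay-corrected.
#' @param ... passed to [tiac_trapezoid_tail()].
#' @return data frame with `organ`, `tiac`, `tiac_lo`, `tiac_hi`,
#'   `uncertainty`.
#' @export
tiac_with_uncertainty <- function(times, mean_values, sd_values, organ = "organ",
                                  nuclide = lu177(), decay_corrected = TRUE, ...) {
  f <- function(v) tiac_trapezoid_tail(
    ntac(organ, times, pmax(v, 0), decay_corrected), nuclide, ...)
  ti <- f(mean_values)
  hi <- f(mean_values + sd_values)
  lo <- f(mean_values - sd_values)
  data.frame(organ = organ, tiac = ti, tiac_lo = lo, tiac_hi = hi,
             uncertainty = (hi - lo) / 2)
}
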