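# Chelator-to-antibody ratio from deconvoluted mass spectra and
# immunoreactive fraction from Lindmo cell-binding assays.

#' Deconvoluted mass-spectrum peak list
#'
#' Container for a deconvoluted intact-protein mass spectrum of a
#' chelator-conjugated antibody: a set of peaks (mass, intensity) together
#' with the mass of the unmodified antibody and the mass added per attached
#' chelator. The default masses correspond to an scFv-Fc fusion antibody
#' (108,394 Da) conjugated with p-SCN-Bn-DOTA (551 Da net addition).
#'
#' @param mass numeric vector of deconvoluted peak masses (Da).
#' @param intensity numeric vector of peak intensities (arbitrary units,
#'   nonnegative, at least one positive).
#' @param base_mass mass of the unmodified antibody (Da).
#' @param adduct_mass mass added per attached chelator (Da), strictly positive.
#' @return An object of class `spectrum_peaks`: a data frame with columns
#'   `mass` and `intensity` and attributes `base_mass`, `adduct_mass`.
#' @seealso [compute_dar()], [mass_to_adduct_count()]
#' @export
spectrum_peaks <- function(mass, intensity, base_mass = 108394, adduct_mass = 551) {
  stopifnot(is.numeric(mass), is.numeric(intensity), length(mass) == length(intensity))
  if (!is.numeric(adduct_mass) || length(adduct_mass) != 1L || adduct_mass <= 0)
    stop("'adduct_mass' must be a single positive number", call. = FALSE)
  if (any(intensity < 0)) stop("peak intensities must be nonnegative", call. = FALSE)
  if (!any(intensity > 0)) stop("degenerate peak list: all intensities are zero", call. = FALSE)
  if (any(mass < base_mass - adduct_mass / 2))
    stop("peak mass below the unmodified antibody mass by more than half an adduct", call. = FALSE)
  out <- data.frame(mass = as.numeric(mass), intensity = as.numeric(intensity))
  attr(out, "base_mass") <- base_mass
  attr(out, "adduct_mass") <- adduct_mass
  class(out) <- c("spectrum_peaks", "data.frame")
  out
}

#' Number of attached chelators implied by a deconvoluted peak mass
#'
#' Rounds the mass excess over the unmodified antibody to the nearest whole
#' number of adducts (ties away from zero), floored at zero.
#'
#' @param mass peak mass (Da); may be a vector.
#' @param base_mass unmodified antibody mass (Da).
#' @param adduct_mass mass per attached chelator (Da), > 0.
#' @return integer vector of adduct counts.
#' @export
mass_to_adduct_count <- function(mass, base_mass, adduct_mass) {
  if (!is.numeric(adduct_mass) || length(adduct_mass) != 1L || adduct_mass <= 0)
    stop("'adduct_mass' must be a single positive number", call. = FALSE)
  x <- (mass - base_mass) / adduct_mass
  # round half away from zero (x >= -0.5 here, so this is round-half-up)
  n <- floor(x + 0.5)
  pmax(as.integer(n), 0L)
}

#' Intensity-weighted drug-to-antibody ratio
#'
#' Computes the average number of chelators per antibody from a deconvoluted
#' mass spectrum as the intensity-weighted mean of per-peak adduct counts,
#' sum(n * Int) / sum(Int). Invariant under uniform rescaling of intensities
#' and always bounded by the smallest and largest per-peak count.
#'
#' @param peaks a [spectrum_peaks()] object.
#' @return a single numeric DAR value.
#' @export
compute_dar <- function(peaks) {
  stopifnot(inherits(peaks, "spectrum_peaks"))
  n <- mass_to_adduct_count(peaks$mass, attr(peaks, "base_mass"), attr(peaks, "adduct_mass"))
  sum(n * peaks$intensity) / sum(peaks$intensity)
}

#' Lindmo cell-binding assay data
#'
#' One immunoreactivity assay: increasing cell concentrations incubated with
#' a fixed trace concentration of radiolabelled antibody, recording the
#' fraction of added activity bound per tube. An optional blocked control
#' (binding under a large excess of unlabelled antibody) estimates
#' nonspecific binding and is subtracted pointwise.
#'
#' @param cells cells per tube (strictly positive, not all equal).
#' @param bound_fraction fraction of added activity bound, in \[0, 1\].
#' @param blocked_fraction optional nonspecific bound fraction, in \[0, 1\].
#' @param tracer_pmol_ml tracer concentration (pmol/mL), metadata only.
#' @return An object of class `lindmo_assay`.
#' @seealso [fit_lindmo()]
#' @export
lindmo_assay <- function(cells, bound_fraction, blocked_fraction = NULL,
                         tracer_pmol_ml = 0.659) {
  stopifnot(length(cells) == length(bound_fraction))
  if (any(cells <= 0)) stop("cell concentrations must be strictly positive", call. = FALSE)
  if (length(unique(cells)) < 2L) stop("cell concentrations must not all be equal", call. = FALSE)
  chk01 <- function(x, nm) {
    if (any(x < 0 | x > 1)) stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
  }
  chk01(bound_fraction, "bound_fraction")
  if (!is.null(blocked_fraction)) {
    stopifnot(length(blocked_fraction) == length(cells))
    chk01(blocked_fraction, "blocked_fraction")
  }
  structure(
    list(cells = as.numeric(cells),
         bound_fraction = as.numeric(bound_fraction),
         blocked_fraction = if (is.null(blocked_fraction)) NULL else as.numeric(blocked_fraction),
         tracer_pmol_ml = tracer_pmol_ml),
    class = "lindmo_assay")
}

# specific binding with pointwise nonspecific subtraction, clipped at 0
.lindmo_specific <- function(assay) {
  b <- assay$bound_fraction
  if (!is.null(assay$blocked_fraction)) b <- b - assay$blocked_fraction
  if (any(b < 0)) {
    warning("negative specific binding after nonspecific subtraction; clipped at 0")
    b <- pmax(b, 0)
  }
  b
}

#' Immunoreactive fraction by extrapolation to infinite cell concentration
#'
#' Fits the one-site trace-ligand binding curve B(c) = IR * c / (c + K) to
#' specific bound fractions by nonlinear least squares and reports the
#' asymptote IR (the immunoreactive fraction) with its standard error. The
#' bounds IR in \[0, 1\] and K > 0 are enforced by a logit/log parameter
#' transform; standard errors are propagated back through the transform by
#' the delta method.
#'
#' @param assay a [lindmo_assay()] object with at least 4 distinct cell
#'   concentrations.
#' @return list of class `lindmo_fit` with elements `ir` (immunoreactive
#'   fraction), `se` (its standard error), `k` (half-saturation cell
#'   concentration), `k_se`, `residuals`, `fitted`, `converged`, and
#'   `boundary` (TRUE when IR is pinned near 0 or 1).
#' @export
fit_lindmo <- function(assay) {
  stopifnot(inherits(assay, "lindmo_assay"))
  c_ <- assay$cells
  if (length(unique(c_)) < 4L)
    stop("need at least 4 distinct cell concentrations", call. = FALSE)
  b <- .lindmo_specific(assay)

  model <- function(p) stats::plogis(p[1]) * c_ / (c_ + exp(p[2]))
  resid_fn <- function(p) b - model(p)

  # start: IR near the plateau of the observed curve, K near median cells
  ir0 <- min(max(max(b) * 1.05, 1e-3), 1 - 1e-3)
  p0 <- c(stats::qlogis(ir0), log(stats::median(c_)))
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0L, 9L)) {
    err <- structure(class = c("immunopk_fit_failure", "error", "condition"),
                     list(message = "Lindmo fit did not converge",
                          call = sys.call(), residuals = fit$fvec))
    stop(err)
  }
  p <- fit$par
  ir <- stats::plogis(p[1])
  k <- exp(p[2])
  # delta-method SEs on the natural scale
  se_p <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 2))
  se_ir <- se_p[1] * ir * (1 - ir)
  se_k <- se_p[2] * k
  boundary <- ir < 1e-4 || ir > 1 - 1e-4
  if (boundary) warning("immunoreactive fraction pinned at a parameter bound")
  structure(list(ir = ir, se = se_ir, k = k, k_se = se_k,
                 residuals = fit$fvec, fitted = model(p),
                 converged = TRUE, boundary = boundary),
            class = "lindmo_fit")
}

#' Classic Lindmo double-inverse linearisation
#'
#' Cross-check estimator: regresses total/bound (1/B) on 1/cells; the
#' intercept estimates 1/IR. Agrees with [fit_lindmo()] on noiseless
#' one-site data; less robust under noise (kept as an oracle, not the
#' primary estimator).
#'
#' @inheritParams fit_lindmo
#' @return list with `ir` and the underlying `lm` fit.
#' @export
lindmo_linearize <- function(assay) {
  stopifnot(inherits(assay, "lindmo_assay"))
  b <- .lindmo_specific(assay)
  keep <- b > 0
  if (sum(keep) < 2L) stop("too few positive specific-binding points", call. = FALSE)
  fit <- stats::lm(I(1 / b[keep]) ~ I(1 / assay$cells[keep]))
  list(ir = 1 / unname(stats::coef(fit)[1]), lm = fit)
}

#' Conjugate profile
#'
#' Label, chelator-to-antibody ratio and immunoreactive fraction of one
#' labelled antibody variant.
#'
#' @param label identifier (e.g. `"DAR1"`).
#' @param dar average chelators per antibody, >= 0.
#' @param immunoreactive_fraction fraction in \[0, 1\], or `NA` when not
#'   measured (downstream code may impute, see [default_study_design()]).
#' @return object of class `conjugate_profile`.
#' @export
conjugate_profile <- function(label, dar, immunoreactive_fraction = NA_real_) {
  stopifnot(is.numeric(dar), length(dar) == 1L, dar >= 0)
  ir <- immunoreactive_fraction
  if (!is.na(ir) && (ir < 0 || ir > 1))
    stop("'immunoreactive_fraction' must lie in [0, 1]", call. = FALSE)
  structure(list(label = as.character(label), dar = dar,
                 immunoreactive_fraction = ir),
            class = "conjugate_profile")
}

#' @export
print.conjugate_profile <- function(x, ...) {
  cat(sprintf("<conjugate %s>  DAR = %g, IR = %s\n", x$label, x$dar,
              if (is.na(x$immunoreactive_fraction)) "NA"
              else sprintf("%.1f%%", 100 * x$immunoreactive_fraction)))
  invisible(x)
}

#' @export
print.lindmo_fit <- function(x, ...) {
  cat(sprintf("Lindmo fit: IR = %.1f%% (SE %.1f), K = %.3g cells\n",
              100 * x$ir, 100 * x$se, x$k))
  invisible(x)
}
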