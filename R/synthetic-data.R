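# Synthetic study generator: six DOTA-conjugated antibody variants, n = 3
# mice per time point, full 4 h - 6 d time courses for the 1- and 3-DOTA
# arms and 24 h only for the others. Produces biodistribution tables,
# Lindmo assays and mass-spectrum peak lists so the whole pipeline runs
# without animal data.

#' Impute a missing immunoreactive fraction by interpolation in DAR
#'
#' Linear interpolation (constant extrapolation at the ends) of measured
#' immunoreactive fractions against DAR; used for conjugates whose assay
#' was not performed.
#'
#' @param dar DAR value(s) to impute at.
#' @param known_dar,known_ir measured DAR values and their immunoreactive
#'   fractions.
#' @return imputed immunoreactive fraction(s).
#' @export
impute_ir <- function(dar, known_dar, known_ir) {
  stats::approx(known_dar, known_ir, xout = dar, rule = 2)$y
}

#' Default six-conjugate study design
#'
#' DAR values 1, 2.5, 3, 6, 8.5 and 11 with measured immunoreactive
#' fractions 85.1, 86.2, 87.5, 78 and 24% (the 2.5-DAR conjugate, never
#' assayed, is imputed by [impute_ir()]). The 1- and 3-DAR arms carry full
#' time courses at 4, 24, 48, 72 and 144 h; the others a single 24 h point;
#' 3 mice per point. Per-organ coefficients of variation default to the
#' spread seen in such gamma-counting studies (blood and tumor ~6-8%,
#' other organs 15%).
#'
#' @param n_mice mice per conjugate per time point.
#' @param cv named per-organ coefficient of variation for measurement
#'   noise; entries missing from the list fall back to `cv_default`.
#' @param cv_default CV for organs not named in `cv`.
#' @return object of class `study_design`: list with `profiles` (named list
#'   of [conjugate_profile()]), `time_points` (named list of hour vectors),
#'   `n_mice`, `cv` (named, complete over organs and blood).
#' @export
default_study_design <- function(n_mice = 3,
                                 cv = c(blood = 0.06, tumor = 0.08),
                                 cv_default = 0.15) {
  dars <- c(1, 2.5, 3, 6, 8.5, 11)
  irs <- c(0.851, NA, 0.862, 0.875, 0.78, 0.24)
  irs[is.na(irs)] <- impute_ir(dars[is.na(irs)], dars[!is.na(irs)], irs[!is.na(irs)])
  labels <- paste0("DAR", dars)
  profiles <- stats::setNames(
    mapply(conjugate_profile, labels, dars, irs, SIMPLIFY = FALSE), labels)
  full <- c(4, 24, 48, 72, 144)
  time_points <- stats::setNames(
    lapply(dars, function(d) if (d %in% c(1, 3)) full else 24), labels)
  series <- c("blood", pk_organs())
  cv_full <- stats::setNames(rep(cv_default, length(series)), series)
  cv_full[names(cv)] <- cv
  structure(list(profiles = profiles, time_points = time_points,
                 n_mice = n_mice, cv = cv_full),
            class = "study_design")
}

#' Calibration truth for model-mode simulation
#'
#' The covariate model and shared kinetic parameters used as ground truth
#' by the model-mode generator. The values are a calibration chosen so that
#' the simulated 24-h endpoints approximate the behaviour of a
#' DOTA-conjugated scFv-Fc antibody in tumor-bearing mice (blood ~10 %IA/g
#' at DAR 1 falling to ~2 at DAR 11; tumor ~19 %IA/g at low DAR falling to
#' ~5; liver rising with DAR); they are not fitted estimates.
#'
#' @return list with `cov` (a [covariate_model()]) and `shared` (a
#'   [pk_model()]).
#' @export
default_truth <- function() {
  masses <- default_masses()
  shared <- pk_model(
    organs = pk_organs(),
    k_up = c(tumor = 0.004, liver = 0.0065, spleen = 0.0004,
             kidneys = 0.0012, lungs = 0.0006, uterus = 0.001,
             bone = 0.002, remainder = 0.0284),
    k_ret = c(tumor = 0.0117, liver = 0.00035, spleen = 0.005,
              kidneys = 0.005, lungs = 0.005, uterus = 0.005,
              bone = 0.005, remainder = 0.005),
    k_ex = 0.0464,
    f_b = c(tumor = 0.05, liver = 0.35, spleen = 0.03, kidneys = 0.05,
            lungs = 0.03, uterus = 0.02, bone = 0.05, remainder = 0.30),
    organ_masses = masses$organ_masses, blood_mass = masses$blood_mass)
  cov <- covariate_model(
    alpha_liver = 0.0065,
    tumor = c(0.00085, 0.0041),
    uterus = c(0.0001, 0.0011),
    spleen = c(0.0003, 0.0007),
    bone = c(0.0018, 0.0015))
  list(cov = cov, shared = shared)
}

# truncated-normal sampler (truncation at 0) by rejection
.rtruncnorm0 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 0
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
    bad <- out < 0
  }
  out
}

#' Printed-summary calibration for the 24-h generator
#'
#' Per-conjugate 24-h means and SDs (%IA/g) for blood, tumor and liver.
#' The anchors are the study-level endpoints (blood 10.2 +/- 0.6 at DAR 1
#' to 2.2 +/- 0.7 at DAR 11; tumor 18.8 +/- 1.5 up to DAR 3 to
#' 5.3 +/- 1.6 at DAR 11; tumor/liver ratio 2 at DAR 1 to 0.15 at DAR 11);
#' values between anchors are interpolated, not measured.
#'
#' @param dars DAR values to tabulate.
#' @return data frame with columns `dar`, `organ`, `mean`, `sd`.
#' @export
summary_calibration_24h <- function(dars = c(1, 2.5, 3, 6, 8.5, 11)) {
  blood_mean <- 10.2 - 0.8 * (dars - 1)
  blood_sd <- 0.6 + 0.01 * (dars - 1)
  tumor_mean <- ifelse(dars <= 3, 18.8, 18.8 - 13.5 * (dars - 3) / 8)
  tumor_sd <- ifelse(dars <= 3, 1.5, 1.5 + 0.1 * (dars - 3) / 8)
  ratio <- 2 * (0.15 / 2)^((dars - 1) / 10)
  liver_mean <- tumor_mean / ratio
  liver_sd <- 0.15 * liver_mean
  out <- rbind(
    data.frame(dar = dars, organ = "blood", mean = blood_mean, sd = blood_sd),
    data.frame(dar = dars, organ = "tumor", mean = tumor_mean, sd = tumor_sd),
    data.frame(dar = dars, organ = "liver", mean = liver_mean, sd = liver_sd))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic biodistribution table
#'
#' Model mode solves the compartment model per conjugate under `truth` and
#' samples per-mouse %IA/g from a zero-truncated normal with the design's
#' per-organ CV. Summary mode bypasses the model and samples around the
#' 24-h calibration table ([summary_calibration_24h()]), for
#' generator-calibration checks. Deterministic for a fixed `seed`.
#'
#' @param design a [default_study_design()]-style design.
#' @param truth list with `cov` and `shared` (see [default_truth()]); used
#'   in model mode only.
#' @param mode `"model"` or `"summary"`.
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @param cv_scale multiplier on all CVs (0 gives noiseless model output).
#' @return data frame with columns `conjugate`, `dar`, `time_h`, `organ`,
#'   `animal_id`, `pct_ia_per_g`.
#' @export
generate_biodistribution <- function(design = default_study_design(),
                                     truth = default_truth(),
                                     mode = c("model", "summary"),
                                     seed = NULL, cv_scale = 1) {
  mode <- match.arg(mode)
  if (cv_scale < 0) stop("'cv_scale' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (lb in names(design$profiles)) {
    pr <- design$profiles[[lb]]
    if (mode == "model") {
      m <- rates_for_conjugate(truth$cov, truth$shared, pr)
      times <- design$time_points[[lb]]
      conc <- predict_concentrations(m, pk_solve(m, times))
    } else {
      cal <- summary_calibration_24h(pr$dar)
      conc <- data.frame(time_h = 24, organ = cal$organ, pct_ia_per_g = cal$mean,
                         sd_abs = cal$sd)
    }
    for (i in seq_len(nrow(conc))) {
      mu <- conc$pct_ia_per_g[i]
      sd <- if (mode == "model") design$cv[[conc$organ[i]]] * cv_scale * mu
            else conc$sd_abs[i] * cv_scale
      vals <- if (sd > 0) .rtruncnorm0(design$n_mice, rep(mu, design$n_mice),
                                       rep(sd, design$n_mice))
              else rep(mu, design$n_mice)
      rows[[length(rows) + 1L]] <- data.frame(
        conjugate = lb, dar = pr$dar, time_h = conc$time_h[i],
        organ = conc$organ[i], animal_id = seq_len(design$n_mice),
        pct_ia_per_g = vals)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic Lindmo assay
#'
#' Bound fractions follow the one-site curve B(c) = IR c / (c + K) plus a
#' nonspecific floor, with multiplicative Gaussian noise; blocked controls
#' carry the nonspecific fraction with the same noise model.
#'
#' @param true_ir true immunoreactive fraction in \[0, 1\].
#' @param true_k half-saturation cell concentration (cells).
#' @param cells cell concentrations per tube; the classic series spans
#'   0.25-8 million cells.
#' @param n_rep replicates per concentration.
#' @param cv multiplicative noise CV.
#' @param nonspecific nonspecific bound fraction (added to all tubes and
#'   reported as the blocked control).
#' @param seed integer seed or `NULL`.
#' @return a [lindmo_assay()].
#' @export
generate_lindmo <- function(true_ir, true_k = 1e6,
                            cells = c(0.25, 0.5, 1, 2, 4, 8) * 1e6,
                            n_rep = 3, cv = 0.05, nonspecific = 0.02,
                            seed = NULL) {
  stopifnot(true_ir >= 0, true_ir <= 1, true_k > 0)
  if (!is.null(seed)) set.seed(seed)
  cc <- rep(cells, each = n_rep)
  specific <- true_ir * cc / (cc + true_k)
  noise <- function(x) pmin(pmax(x * (1 + stats::rnorm(length(x), 0, cv)), 0), 1)
  bound <- noise(specific + nonspecific)
  blocked <- noise(rep(nonspecific, length(cc)))
  lindmo_assay(cc, bound, blocked)
}

#' Generate a synthetic deconvoluted mass-spectrum peak list
#'
#' Places one peak at `base_mass + n * adduct_mass` for each adduct count
#' with probability mass, with intensities proportional to the
#' probabilities times multiplicative noise. With zero noise,
#' [compute_dar()] on the output equals the distribution mean exactly.
#'
#' @param probs probability vector over adduct counts `0, 1, ..., length - 1`
#'   (must sum to 1).
#' @param base_mass,adduct_mass see [spectrum_peaks()].
#' @param intensity_cv multiplicative intensity noise CV.
#' @param seed integer seed or `NULL`.
#' @return a [spectrum_peaks()] object (zero-probability peaks dropped).
#' @export
generate_peaklist <- function(probs, base_mass = 108394, adduct_mass = 551,
                              intensity_cv = 0, seed = NULL) {
  if (abs(sum(probs) - 1) > 1e-8) stop("'probs' must sum to 1", call. = FALSE)
  if (any(probs < 0)) stop("'probs' must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- seq_along(probs) - 1L
  keep <- probs > 0
  intensity <- probs[keep]
  if (intensity_cv > 0)
    intensity <- pmax(intensity * (1 + stats::rnorm(sum(keep), 0, intensity_cv)), 1e-12)
  spectrum_peaks(base_mass + n[keep] * adduct_mass, intensity,
                 base_mass, adduct_mass)
}
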