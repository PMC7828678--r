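# Simultaneous (global) fit across conjugates: one shared kinetic
# parameter set, with liver uptake proportional to DAR and tumor, uterus,
# spleen and bone uptake tied linearly to the immunoreactive fraction.

#' Covariate laws linking uptake rates to DAR and immunoreactivity
#'
#' Liver uptake is strictly proportional to the chelator-to-antibody ratio:
#' `k_up[liver] = alpha_liver * DAR` (zero intercept). Tumor and uterus
#' uptake increase linearly with the immunoreactive fraction IR
#' (`a + b * IR`); spleen and bone uptake increase with its loss
#' (`a + b * (1 - IR)`), so all slope coefficients stay nonnegative.
#'
#' @param alpha_liver liver uptake per unit DAR (1/h per chelator, >= 0).
#' @param tumor,uterus length-2 numeric `c(a, b)`: intercept and IR slope
#'   (both >= 0).
#' @param spleen,bone length-2 numeric `c(a, b)`: intercept and (1 - IR)
#'   slope (both >= 0).
#' @return object of class `covariate_model`.
#' @export
covariate_model <- function(alpha_liver, tumor, uterus, spleen, bone) {
  chk <- function(x, nm) {
    if (length(x) != 2L || any(x < 0))
      stop(sprintf("'%s' must be c(a, b) with both >= 0", nm), call. = FALSE)
    stats::setNames(as.numeric(x), c("a", "b"))
  }
  if (alpha_liver < 0) stop("'alpha_liver' must be >= 0", call. = FALSE)
  structure(list(alpha_liver = alpha_liver,
                 tumor = chk(tumor, "tumor"), uterus = chk(uterus, "uterus"),
                 spleen = chk(spleen, "spleen"), bone = chk(bone, "bone")),
            class = "covariate_model")
}

#' Instantiate the compartment model for one conjugate
#'
#' Applies the covariate laws to a shared-parameter template: liver uptake
#' becomes `alpha_liver * dar`, tumor/uterus uptake `a + b * IR`,
#' spleen/bone uptake `a + b * (1 - IR)`; every other rate, blood fraction
#' and mass is copied from `shared`.
#'
#' @param cov a [covariate_model()].
#' @param shared a [pk_model()] holding the shared parameters.
#' @param profile a [conjugate_profile()] with non-missing DAR and IR.
#' @return a [pk_model()] for this conjugate.
#' @export
rates_for_conjugate <- function(cov, shared, profile) {
  stopifnot(inherits(cov, "covariate_model"), inherits(shared, "pk_model"),
            inherits(profile, "conjugate_profile"))
  ir <- profile$immunoreactive_fraction
  if (is.na(ir))
    stop("conjugate '", profile$label, "' has no immunoreactive fraction; ",
         "impute one (see default_study_design) before building rates", call. = FALSE)
  k <- shared$k_up
  k[["liver"]] <- cov$alpha_liver * profile$dar
  k[["tumor"]] <- cov$tumor[["a"]] + cov$tumor[["b"]] * ir
  k[["uterus"]] <- cov$uterus[["a"]] + cov$uterus[["b"]] * ir
  k[["spleen"]] <- cov$spleen[["a"]] + cov$spleen[["b"]] * (1 - ir)
  k[["bone"]] <- cov$bone[["a"]] + cov$bone[["b"]] * (1 - ir)
  if (any(k < 0)) stop("covariate law produced a negative uptake rate", call. = FALSE)
  shared$k_up <- k
  shared
}

# organs whose uptake is governed by the covariate laws
.cov_organs <- c("liver", "tumor", "uterus", "spleen", "bone")

# parameter table for the global fit: covariate coefficients + shared rates
.global_par_table <- function(cov, shared, fix = list()) {
  organs <- shared$organs
  shared_up <- setdiff(organs, .cov_organs)
  tab <- data.frame(
    name = c("alpha_liver",
             "tumor.a", "tumor.b", "uterus.a", "uterus.b",
             "spleen.a", "spleen.b", "bone.a", "bone.b",
             paste0("k_up.", shared_up), paste0("k_ret.", organs), "k_ex",
             paste0("f_b.", organs)),
    type = c(rep("rate", 9L + length(shared_up) + length(organs) + 1L),
             rep("frac", length(organs))),
    value = unname(c(cov$alpha_liver, cov$tumor, cov$uterus, cov$spleen, cov$bone,
                     shared$k_up[shared_up], shared$k_ret, shared$k_ex, shared$f_b)),
    stringsAsFactors = FALSE)
  tab$free <- TRUE
  for (nm in names(fix)) {
    i <- match(nm, tab$name)
    if (is.na(i)) stop(sprintf("unknown parameter '%s' in 'fix'", nm), call. = FALSE)
    tab$value[i] <- fix[[nm]]
    tab$free[i] <- FALSE
  }
  tab
}

.global_unpack <- function(tab, shared) {
  v <- stats::setNames(tab$value, tab$name)
  cov <- covariate_model(alpha_liver = v[["alpha_liver"]],
                         tumor = c(v[["tumor.a"]], v[["tumor.b"]]),
                         uterus = c(v[["uterus.a"]], v[["uterus.b"]]),
                         spleen = c(v[["spleen.a"]], v[["spleen.b"]]),
                         bone = c(v[["bone.a"]], v[["bone.b"]]))
  g <- function(prefix, organs) {
    out <- stats::setNames(numeric(length(organs)), organs)
    for (o in organs) {
      nm <- paste0(prefix, ".", o)
      if (nm %in% names(v)) out[[o]] <- v[[nm]]
    }
    out
  }
  shared$k_up[setdiff(shared$organs, .cov_organs)] <-
    g("k_up", setdiff(shared$organs, .cov_organs))
  shared$k_ret <- g("k_ret", shared$organs)
  shared$f_b <- g("f_b", shared$organs)
  shared$k_ex <- v[["k_ex"]]
  list(cov = cov, shared = shared)
}

#' Simultaneous fit of all conjugates with one shared parameter set
#'
#' Concatenates the weighted residuals of every conjugate's biodistribution
#' data (full time courses for some arms, a single time point for others)
#' into one objective and minimises it by Levenberg-Marquardt over the
#' covariate coefficients and the shared kinetic parameters.
#'
#' When the profiles carry fewer than two distinct immunoreactive fractions
#' the intercept and slope of the tumor and uterus laws are not separable;
#' in that case the intercepts are fixed at 0 and this is noted in the
#' returned report.
#'
#' @param data biodistribution data frame with columns `conjugate`,
#'   `organ`, `time_h`, `animal_id`, `pct_ia_per_g` spanning all conjugates.
#' @param profiles named list of [conjugate_profile()] objects; names must
#'   match the `conjugate` column.
#' @param cov starting [covariate_model()].
#' @param shared starting shared [pk_model()].
#' @param weights `"auto"`, `"uniform"`, or a numeric vector per row.
#' @param fix named list of parameters to hold fixed (names as in the
#'   `estimates` table).
#' @return object of class `global_fit`: list with `cov`, `shared`,
#'   `estimates`, `residuals`, `rss`, `converged`, `rank_note`, `n_obs`.
#' @export
fit_global <- function(data, profiles, cov, shared, weights = "auto", fix = list()) {
  stopifnot(inherits(cov, "covariate_model"), inherits(shared, "pk_model"))
  labels <- unique(data$conjugate)
  miss <- setdiff(labels, names(profiles))
  if (length(miss))
    stop("no profile for conjugate(s): ", paste(miss, collapse = ", "), call. = FALSE)
  irs <- vapply(profiles[labels], `[[`, numeric(1), "immunoreactive_fraction")
  if (anyNA(irs))
    stop("missing immunoreactive fraction for: ",
         paste(labels[is.na(irs)], collapse = ", "),
         "; impute before fitting", call. = FALSE)

  rank_note <- NULL
  if (length(unique(round(irs, 10))) < 2L) {
    fix <- utils::modifyList(list(tumor.a = 0, uterus.a = 0), fix)
    rank_note <- "single distinct IR: tumor/uterus intercepts fixed at 0"
  }
  tab <- .global_par_table(cov, shared, fix)

  # per-conjugate blocks, weights computed within block
  blocks <- split(seq_len(nrow(data)), data$conjugate)
  w <- if (is.character(weights)) {
    wv <- numeric(nrow(data))
    for (b in blocks) wv[b] <- biodist_weights(data[b, , drop = FALSE], weights)
    wv
  } else as.numeric(weights)
  stopifnot(length(w) == nrow(data), all(w > 0))
  sw <- sqrt(w)

  free_idx <- which(tab$free)
  if (length(free_idx) >= nrow(data))
    stop("under-identified: more free parameters than observations", call. = FALSE)
  p0 <- mapply(.par_trans, tab$value[free_idx], tab$type[free_idx])
  fn <- function(p) {
    tab$value[free_idx] <- mapply(.par_untrans, p, tab$type[free_idx])
    pars <- .global_unpack(tab, shared)
    unlist(lapply(labels, function(lb) {
      m <- rates_for_conjugate(pars$cov, pars$shared, profiles[[lb]])
      b <- blocks[[lb]]
      .pk_residuals(m, data[b, , drop = FALSE], sw[b])
    }), use.names = FALSE)
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  conv <- fit$info %in% 1:4
  if (!conv) warning("global fit did not converge: ", fit$message)
  tab$value[free_idx] <- mapply(.par_untrans, fit$par, tab$type[free_idx])
  pars <- .global_unpack(tab, shared)

  se_t <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, length(free_idx)))
  nat <- tab$value[free_idx]
  est <- data.frame(name = tab$name[free_idx], estimate = nat,
                    se = se_t * mapply(.par_dnat, nat, tab$type[free_idx]),
                    stringsAsFactors = FALSE)

  structure(list(cov = pars$cov, shared = pars$shared, estimates = est,
                 residuals = fit$fvec, rss = sum(fit$fvec^2),
                 converged = conv, rank_note = rank_note, n_obs = nrow(data)),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("<global_fit> %d obs, %d free parameters, RSS = %.4g, %s\n",
              x$n_obs, nrow(x$estimates), x$rss,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$rank_note)) cat("note:", x$rank_note, "\n")
  invisible(x)
}

#' Predicted 24-hour biodistribution panel across conjugates
#'
#' Deterministic model predictions of %IA/g at a reference time (24 h by
#' default) for every conjugate, in the layout used to compare modelled
#' against measured biodistributions, plus the tumor/liver concentration
#' ratio per conjugate.
#'
#' @param cov a [covariate_model()].
#' @param shared shared [pk_model()].
#' @param profiles list of [conjugate_profile()] objects.
#' @param time_h reference time (h).
#' @return list with `panel` (data frame: conjugate, dar, organ,
#'   pct_ia_per_g) and `ratios` (data frame: conjugate, dar,
#'   tumor_liver_ratio).
#' @export
predict_24h_panel <- function(cov, shared, profiles, time_h = 24) {
  rows <- lapply(profiles, function(pr) {
    m <- rates_for_conjugate(cov, shared, pr)
    traj <- pk_solve(m, time_h)
    conc <- predict_concentrations(m, traj)
    cbind(conjugate = pr$label, dar = pr$dar, conc[, c("organ", "pct_ia_per_g")])
  })
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  ratios <- do.call(rbind, lapply(split(panel, panel$conjugate), function(d) {
    data.frame(conjugate = d$conjugate[1], dar = d$dar[1],
               tumor_liver_ratio = d$pct_ia_per_g[d$organ == "tumor"] /
                 d$pct_ia_per_g[d$organ == "liver"])
  }))
  ratios <- ratios[order(ratios$dar), ]
  rownames(ratios) <- NULL
  list(panel = panel, ratios = ratios)
}
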