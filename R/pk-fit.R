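# Weighted Levenberg-Marquardt fitting of the compartment model to one
# conjugate's biodistribution time course. Rates are fitted on the log
# scale and blood fractions on the logit scale so positivity/bounds are
# enforced by the parameterisation rather than by clipping.

# --- parameter bookkeeping -------------------------------------------------

# natural <-> transformed scale
.par_trans <- function(value, type) {
  switch(type, rate = log(value), frac = stats::qlogis(value))
}
.par_untrans <- function(tvalue, type) {
  switch(type, rate = exp(tvalue), frac = stats::plogis(tvalue))
}
# |d natural / d transformed| at the estimate, for delta-method SEs
.par_dnat <- function(nat, type) {
  switch(type, rate = nat, frac = nat * (1 - nat))
}

# parameter table for a single-conjugate fit
.single_par_table <- function(model, fix = list()) {
  organs <- model$organs
  tab <- data.frame(
    name = c(paste0("k_up.", organs), paste0("k_ret.", organs), "k_ex",
             paste0("f_b.", organs)),
    type = c(rep("rate", 2L * length(organs) + 1L), rep("frac", length(organs))),
    value = unname(c(model$k_up, model$k_ret, model$k_ex, model$f_b)),
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

.apply_par_table <- function(model, tab) {
  g <- function(prefix) {
    v <- tab$value[startsWith(tab$name, paste0(prefix, "."))]
    names(v) <- sub(paste0("^", prefix, "\\."), "",
                    tab$name[startsWith(tab$name, paste0(prefix, "."))])
    v[model$organs]
  }
  model$k_up <- g("k_up"); model$k_ret <- g("k_ret"); model$f_b <- g("f_b")
  model$k_ex <- tab$value[tab$name == "k_ex"]
  model
}

# --- observation weights ---------------------------------------------------

#' Observation weights for weighted least squares
#'
#' With `scheme = "auto"`, weights are 1/SD^2 where the SD is taken across
#' animals within each (organ, time) group; if any group has fewer than two
#' animals or zero spread, uniform weights are used throughout. The returned
#' vector is normalised to mean 1.
#'
#' @param data biodistribution data frame (`organ`, `time_h`,
#'   `pct_ia_per_g`, `animal_id`).
#' @param scheme `"auto"` or `"uniform"`.
#' @return numeric weight per row of `data`.
#' @export
biodist_weights <- function(data, scheme = c("auto", "uniform")) {
  scheme <- match.arg(scheme)
  n <- nrow(data)
  if (scheme == "uniform") return(rep(1, n))
  key <- interaction(data$organ, data$time_h, drop = TRUE)
  sds <- tapply(data$pct_ia_per_g, key, stats::sd)
  cnt <- tapply(data$pct_ia_per_g, key, length)
  if (any(cnt < 2L) || any(!is.finite(sds)) || any(sds <= 0)) return(rep(1, n))
  w <- 1 / sds[key]^2
  unname(w / mean(w))
}

# residual vector for a model against long-format observations
.pk_residuals <- function(model, data, sqrt_w) {
  times <- sort(unique(data$time_h))
  traj <- pk_solve(model, times)
  pred <- predict_concentrations(model, traj)
  idx <- match(paste(data$organ, data$time_h), paste(pred$organ, pred$time_h))
  if (anyNA(idx)) stop("observations refer to organs absent from the model", call. = FALSE)
  sqrt_w * (data$pct_ia_per_g - pred$pct_ia_per_g[idx])
}

# --- single-conjugate fit --------------------------------------------------

#' Fit the compartment model to one conjugate's biodistribution data
#'
#' Minimises the weighted sum of squared differences between observed and
#' predicted %IA/g over all organs (and blood, when present) by
#' Levenberg-Marquardt on transformed parameters.
#'
#' @param model starting [pk_model()]; its rate values are the initial guess
#'   and its organ set defines the compartments.
#' @param data data frame with columns `organ`, `time_h`, `animal_id`,
#'   `pct_ia_per_g` for a single conjugate.
#' @param weights `"auto"`, `"uniform"`, or a numeric vector per row of
#'   `data` (see [biodist_weights()]).
#' @param fix named list of parameters to hold fixed, e.g.
#'   `list(k_ret.liver = 0)`. Names follow `k_up.<organ>`, `k_ret.<organ>`,
#'   `k_ex`, `f_b.<organ>`.
#' @return object of class `pk_fit`: list with `model` (fitted), `estimates`
#'   (data frame: name, estimate, se, lower95, upper95), `residuals`,
#'   `rss`, `aic`, `converged`, `message`, `n_obs`.
#' @export
fit_single <- function(model, data, weights = "auto", fix = list()) {
  stopifnot(inherits(model, "pk_model"))
  need <- c("organ", "time_h", "pct_ia_per_g")
  if (!all(need %in% names(data)))
    stop("data must have columns organ, time_h, pct_ia_per_g", call. = FALSE)
  tab <- .single_par_table(model, fix)
  n_free <- sum(tab$free)
  if (n_free >= nrow(data))
    stop("under-identified: more free parameters than observations", call. = FALSE)
  any_kret_free <- any(tab$free & startsWith(tab$name, "k_ret."))
  if (any_kret_free && length(unique(data$time_h)) < 2L)
    stop("under-identified: free return rates need at least 2 time points", call. = FALSE)
  w <- if (is.character(weights)) biodist_weights(data, weights) else as.numeric(weights)
  stopifnot(length(w) == nrow(data), all(w > 0))
  sw <- sqrt(w)

  free_idx <- which(tab$free)
  p0 <- mapply(.par_trans, tab$value[free_idx], tab$type[free_idx])
  fn <- function(p) {
    tab$value[free_idx] <- mapply(.par_untrans, p, tab$type[free_idx])
    .pk_residuals(.apply_par_table(model, tab), data, sw)
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  conv <- fit$info %in% 1:4
  tab$value[free_idx] <- mapply(.par_untrans, fit$par, tab$type[free_idx])
  fitted_model <- .apply_par_table(model, tab)

  se_t <- rep(NA_real_, n_free)
  se_t_try <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
  if (!is.null(se_t_try)) se_t <- se_t_try
  nat <- tab$value[free_idx]
  est <- data.frame(
    name = tab$name[free_idx],
    estimate = nat,
    se = se_t * mapply(.par_dnat, nat, tab$type[free_idx]),
    lower95 = mapply(.par_untrans, fit$par - 1.96 * se_t, tab$type[free_idx]),
    upper95 = mapply(.par_untrans, fit$par + 1.96 * se_t, tab$type[free_idx]),
    stringsAsFactors = FALSE)

  rss <- sum(fit$fvec^2)
  n <- nrow(data)
  out <- structure(list(model = fitted_model, estimates = est,
                        residuals = fit$fvec, rss = rss,
                        aic = n * log(rss / n) + 2 * n_free,
                        converged = conv, message = fit$message, n_obs = n),
                   class = "pk_fit")
  if (!conv) warning("fit did not converge: ", fit$message, " (best-so-far returned)")
  out
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> %d obs, %d free parameters, RSS = %.4g, AIC = %.1f, %s\n",
              x$n_obs, nrow(x$estimates), x$rss, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
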