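# Linear multi-compartment biodistribution model: a central blood
# compartment exchanging with one compartment per counted organ plus a
# remainder compartment, and an irreversible excretion sink from blood.
# Amounts are carried in %IA; the measurement model converts to %IA/g.

#' Default organ set of the murine biodistribution model
#'
#' Counted organs plus a `remainder` compartment for all uncounted tissue.
#' @return character vector of organ names.
#' @export
pk_organs <- function() {
  c("tumor", "liver", "spleen", "kidneys", "lungs", "uterus", "bone", "remainder")
}

#' Default organ and blood masses (g) for an ~18.4 g mouse
#'
#' Mean dissected organ masses; `remainder` is the body mass left after the
#' counted organs and blood. Blood mass defaults to 7.7% of body mass.
#'
#' @param body_mass_g total body mass (g).
#' @return named list with `organ_masses` (named numeric, g) and
#'   `blood_mass` (g).
#' @export
default_masses <- function(body_mass_g = 18.44) {
  m <- c(tumor = 0.21, liver = 1.13, spleen = 0.10, kidneys = 0.31,
         lungs = 0.15, uterus = 0.11, bone = 2.20)
  blood <- 0.077 * body_mass_g
  m <- c(m, remainder = body_mass_g - sum(m) - blood)
  list(organ_masses = m, blood_mass = blood)
}

#' Multi-compartment biodistribution model
#'
#' @param organs character vector of organ names (order defines the state
#'   vector).
#' @param k_up named per-organ uptake rate from blood (1/h, >= 0).
#' @param k_ret named per-organ return (wash-out) rate to blood (1/h, >= 0).
#' @param k_ex excretion rate from blood (1/h, >= 0).
#' @param f_b named per-organ blood-content fraction in \[0, 1); the share of
#'   blood activity counted with the dissected organ. Must sum to <= 1.
#' @param organ_masses named organ masses (g, > 0).
#' @param blood_mass blood mass (g, > 0).
#' @return object of class `pk_model`.
#' @export
pk_model <- function(organs = pk_organs(), k_up, k_ret, k_ex, f_b,
                     organ_masses = default_masses()$organ_masses,
                     blood_mass = default_masses()$blood_mass) {
  pick <- function(x, nm) {
    if (is.null(names(x))) {
      stopifnot(length(x) == length(organs))
      names(x) <- organs
    }
    miss <- setdiff(organs, names(x))
    if (length(miss)) stop(sprintf("missing %s for organ(s): %s", nm,
                                   paste(miss, collapse = ", ")), call. = FALSE)
    x[organs]
  }
  k_up <- pick(k_up, "k_up"); k_ret <- pick(k_ret, "k_ret"); f_b <- pick(f_b, "f_b")
  organ_masses <- pick(organ_masses, "organ mass")
  if (any(c(k_up, k_ret, k_ex) < 0)) stop("rate constants must be nonnegative", call. = FALSE)
  if (any(f_b < 0 | f_b >= 1)) stop("blood fractions must lie in [0, 1)", call. = FALSE)
  if (sum(f_b) > 1) stop("blood fractions must sum to at most 1", call. = FALSE)
  if (any(organ_masses <= 0) || blood_mass <= 0) stop("masses must be positive", call. = FALSE)
  structure(list(organs = organs, k_up = k_up, k_ret = k_ret, k_ex = k_ex,
                 f_b = f_b, organ_masses = organ_masses, blood_mass = blood_mass),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("<pk_model> %d organs + blood + excretion; k_ex = %.4g/h\n",
              length(x$organs), x$k_ex))
  print(data.frame(k_up = x$k_up, k_ret = x$k_ret, f_b = x$f_b,
                   mass_g = x$organ_masses))
  invisible(x)
}

# system matrix of the linear ODE in state order (blood, organs..., excreted)
.pk_matrix <- function(model) {
  n <- length(model$organs)
  A <- matrix(0, n + 2L, n + 2L)
  A[1L, 1L] <- -(sum(model$k_up) + model$k_ex)
  A[1L, 2L:(n + 1L)] <- model$k_ret
  A[2L:(n + 1L), 1L] <- model$k_up
  diag(A)[2L:(n + 1L)] <- -model$k_ret
  A[n + 2L, 1L] <- model$k_ex
  A
}

#' Solve the biodistribution model
#'
#' Integrates the linear compartment system with a stiff-capable solver
#' (`deSolve::lsoda`, tight tolerances). All activity injected into blood at
#' t = 0; total activity (blood + organs + excreted) is conserved.
#'
#' @param model a [pk_model()].
#' @param times sorted nonnegative time points (h). A leading 0 is added
#'   internally if absent.
#' @param initial injected activity placed in blood at t = 0 (%IA, > 0).
#' @return object of class `pk_trajectory`: data frame with columns `time_h`,
#'   `blood`, one column per organ, and `excreted` (all %IA), with the model
#'   attached as an attribute.
#' @export
pk_solve <- function(model, times, initial = 100) {
  stopifnot(inherits(model, "pk_model"))
  if (is.unsorted(times) || any(times < 0)) stop("'times' must be sorted and >= 0", call. = FALSE)
  if (initial <= 0) stop("'initial' must be positive", call. = FALSE)
  A <- .pk_matrix(model)
  y0 <- c(initial, numeric(length(model$organs) + 1L))
  tt <- unique(c(0, times))
  sol <- deSolve::lsoda(y0, tt, func = function(t, y, p) list(A %*% y),
                        rtol = 1e-10, atol = 1e-12)
  sol <- sol[match(times, tt), , drop = FALSE]
  out <- as.data.frame(sol[, -1L, drop = FALSE])
  names(out) <- c("blood", model$organs, "excreted")
  out <- cbind(time_h = times, out)
  rownames(out) <- NULL
  attr(out, "model") <- model
  class(out) <- c("pk_trajectory", "data.frame")
  out
}

#' Predicted tissue concentrations from a solved trajectory
#'
#' Applies the measurement model: the counted concentration of an organ is
#' its compartment content plus its share of blood activity, divided by the
#' organ mass; blood is reported as blood content over blood mass.
#'
#' @param model the [pk_model()] used to produce `trajectory`.
#' @param trajectory a `pk_trajectory` from [pk_solve()].
#' @return long data frame with columns `time_h`, `organ` (including
#'   `"blood"`), `pct_ia_per_g`.
#' @export
predict_concentrations <- function(model, trajectory) {
  stopifnot(inherits(model, "pk_model"), inherits(trajectory, "pk_trajectory"))
  if (!all(model$organs %in% names(trajectory)))
    stop("trajectory organ set does not match the model", call. = FALSE)
  if (any(is.na(model$organ_masses))) stop("missing organ mass", call. = FALSE)
  res <- lapply(model$organs, function(o) {
    conc <- (trajectory[[o]] + model$f_b[[o]] * trajectory$blood) / model$organ_masses[[o]]
    data.frame(time_h = trajectory$time_h, organ = o, pct_ia_per_g = conc)
  })
  blood <- data.frame(time_h = trajectory$time_h, organ = "blood",
                      pct_ia_per_g = trajectory$blood / model$blood_mass)
  out <- do.call(rbind, c(list(blood), res))
  rownames(out) <- NULL
  out
}
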