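# Shared fixtures. The matrix-exponential oracle below builds the system
# matrix itself (independently of the package internals) and propagates the
# state with Matrix::expm, so it can vouch for the numerical ODE solver.

expm_trajectory <- function(model, times, initial = 100) {
  organs <- model$organs
  n <- length(organs)
  A <- matrix(0, n + 2L, n + 2L)
  A[1, 1] <- -(sum(model$k_up) + model$k_ex)
  for (i in seq_len(n)) {
    A[1, 1 + i] <- model$k_ret[[organs[i]]]
    A[1 + i, 1] <- model$k_up[[organs[i]]]
    A[1 + i, 1 + i] <- -model$k_ret[[organs[i]]]
  }
  A[n + 2L, 1] <- model$k_ex
  y0 <- c(initial, numeric(n + 1L))
  out <- t(vapply(times, function(t)
    as.numeric(Matrix::expm(A * t) %*% y0), numeric(n + 2L)))
  colnames(out) <- c("blood", organs, "excreted")
  cbind(time_h = times, as.data.frame(out))
}

random_pk_model <- function(seed) {
  set.seed(seed)
  organs <- pk_organs()
  n <- length(organs)
  f_b <- stats::runif(n, 0, 0.1)
  pk_model(organs,
           k_up = stats::setNames(stats::runif(n, 0.0001, 0.05), organs),
           k_ret = stats::setNames(stats::runif(n, 0, 0.02), organs),
           k_ex = stats::runif(1, 0, 0.02),
           f_b = stats::setNames(f_b / max(1, sum(f_b)), organs))
}

# multiplicative perturbation of the simulation truth, used as a fit start
perturb_truth <- function(tr, up = 1.3) {
  tr$cov$alpha_liver <- tr$cov$alpha_liver * up
  tr$cov$tumor <- tr$cov$tumor * c(up, 1 / up)
  tr$cov$uterus <- tr$cov$uterus * c(1 / up, up)
  tr$cov$spleen <- tr$cov$spleen * c(up, 1 / up)
  tr$cov$bone <- tr$cov$bone * c(1 / up, up)
  tr$shared$k_up <- tr$shared$k_up * up
  tr$shared$k_ret <- tr$shared$k_ret / up
  tr$shared$k_ex <- tr$shared$k_ex * up
  tr$shared$f_b <- pmin(tr$shared$f_b * 1.15, 0.9)
  tr
}

truth_param_vector <- function(tr) {
  c(tr$cov$alpha_liver, tr$cov$tumor, tr$cov$uterus, tr$cov$spleen, tr$cov$bone,
    tr$shared$k_up[c("kidneys", "lungs", "remainder")],
    tr$shared$k_ret, tr$shared$k_ex, tr$shared$f_b)
}
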