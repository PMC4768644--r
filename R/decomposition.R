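# Per-timestep decomposition of observed growth into an asymptotic part
# (the dominant eigenvalue of the current matrix) and a transient part
# (reactivity: one-step amplification or attenuation caused by deviation
# of the current stage structure from the stable stage structure).
#
# On the log scale the decomposition is additive,
#   log lambda_obs(t) = log lambda_max(t) + log reactivity(t),
# and the underlying "absolute dynamic" sums the magnitudes of the two
# components, distinguishing strong-but-opposing forces from weak ones:
#   log lambda_abs(t) = |log lambda_max(t)| + |log reactivity(t)|.

#' Observed one-step growth rate
#'
#' \eqn{\lambda_{obs} = \lVert A x \rVert_1 / \lVert x \rVert_1}: the
#' realized multiplicative change in total abundance over one projection
#' step from stage structure `x`.
#'
#' @param A projection matrix.
#' @param x stage vector with nonzero one-norm.
#' @return a positive scalar; 0 (with attribute `extinguished = TRUE`) if
#'   `A %*% x` is identically zero.
#' @export
observed_growth <- function(A, x) {
  y <- project(A, x)
  nx <- sum(x)
  if (nx <= 0)
    stop_stochtrans("stage vector has zero one-norm", "degenerate_input_error")
  lam <- sum(y) / nx
  if (lam == 0) attr(lam, "extinguished") <- TRUE
  lam
}

#' One-step reactivity
#'
#' \eqn{\lVert (A/\lambda_{max}) \, x/\lVert x\rVert_1 \rVert_1}: growth of
#' the normalized stage vector under the matrix rescaled to unit asymptotic
#' growth.  Values above 1 indicate transient amplification ("boom"),
#' below 1 attenuation ("bust"); at the stable stage structure reactivity
#' is exactly 1.
#'
#' @inheritParams observed_growth
#' @return positive scalar.
#' @export
reactivity <- function(A, x) {
  lam_max <- dominant_eigenvalue(A)
  if (lam_max <= 0)
    stop_stochtrans("dominant eigenvalue must be positive",
                    "degenerate_input_error")
  as.numeric(observed_growth(A, x)) / lam_max
}

#' Decompose one projection step
#'
#' Computes the full per-step quartet on the log scale: net growth, its
#' asymptotic and transient components, and the absolute dynamic.
#'
#' @inheritParams observed_growth
#' @return a list of class `step_decomposition` with elements
#'   `log_lambda_obs`, `log_lambda_max`, `log_reactivity`,
#'   `log_lambda_abs`.
#' @examples
#' A <- matrix(c(0, 1, 2, 0), 2, 2)
#' decompose_step(A, c(1, 0))  # net zero growth masking opposing forces
#' @export
decompose_step <- function(A, x) {
  lam_max <- dominant_eigenvalue(A)
  lam_obs <- observed_growth(A, x)
  if (as.numeric(lam_obs) == 0)
    stop_stochtrans("population extinguished in one step; log growth undefined",
                    "decomposition_undefined_error")
  log_max <- log(lam_max)
  log_react <- log(as.numeric(lam_obs) / lam_max)
  structure(list(
    log_lambda_obs = log(as.numeric(lam_obs)),
    log_lambda_max = log_max,
    log_reactivity = log_react,
    log_lambda_abs = absolute_dynamic(log_max, log_react)
  ), class = "step_decomposition")
}

#' @export
print.step_decomposition <- function(x, ...) {
  cat(sprintf(
    paste0("<step_decomposition>\n",
           "  log lambda_obs : %+.5f  (net growth)\n",
           "  log lambda_max : %+.5f  (asymptotic)\n",
           "  log reactivity : %+.5f  (transient)\n",
           "  log lambda_abs :  %.5f  (absolute dynamic)\n"),
    x$log_lambda_obs, x$log_lambda_max, x$log_reactivity,
    x$log_lambda_abs))
  invisible(x)
}

#' Absolute dynamic from log components
#'
#' \eqn{\log \lambda_{abs} = |\log\lambda_{max}| + |\log reactivity|}.
#' When the asymptotic and transient components have opposite signs the
#' absolute dynamic strictly exceeds the magnitude of net growth,
#' revealing antagonism that the net decomposition hides.
#'
#' @param log_lambda_max,log_reactivity finite reals.
#' @return non-negative scalar.
#' @export
absolute_dynamic <- function(log_lambda_max, log_reactivity) {
  if (!all(is.finite(log_lambda_max)) || !all(is.finite(log_reactivity)))
    stop_stochtrans("non-finite log component", "propagation_error")
  abs(log_lambda_max) + abs(log_reactivity)
}
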