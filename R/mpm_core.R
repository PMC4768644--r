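# Eigen-analysis and structural diagnostics for single projection matrices.

#' Internal condition constructor
#'
#' All package errors are classed conditions so callers can distinguish
#' structural problems (bad matrices) from degenerate data.
#' @noRd
stop_stochtrans <- function(message, class, call. = FALSE, ...) {
  cond <- structure(
    class = c(class, "stochtrans_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Validate a projection matrix
#'
#' Checks that `A` is a numeric, square, non-negative matrix of dimension
#' at least 2, the structural requirements of a stage-classified projection
#' matrix whose entries are per-capita annual rates.
#'
#' @param A numeric matrix.
#' @return `A`, invisibly, if valid; otherwise an error of class
#'   `invalid_matrix_error`.
#' @export
validate_projection_matrix <- function(A) {
  if (!is.matrix(A) || !is.numeric(A))
    stop_stochtrans("projection matrix must be a numeric matrix",
                    "invalid_matrix_error")
  if (nrow(A) != ncol(A))
    stop_stochtrans(sprintf("projection matrix must be square (got %d x %d)",
                            nrow(A), ncol(A)), "invalid_matrix_error")
  if (anyNA(A) || any(!is.finite(A)))
    stop_stochtrans("projection matrix contains non-finite entries",
                    "invalid_matrix_error")
  if (any(A < 0))
    stop_stochtrans("projection matrix has negative entries",
                    "invalid_matrix_error")
  invisible(A)
}

# relative tolerance under which the dominant eigenvalue's imaginary part is
# treated as floating-point dust
.IMAG_TOL <- 1e-8

#' Dominant eigenvalue of a projection matrix
#'
#' Returns the eigenvalue of maximum modulus (the asymptotic, or stable,
#' growth rate \eqn{\lambda_{max}}).  For an irreducible primitive
#' non-negative matrix this is guaranteed real, positive and simple
#' (Perron–Frobenius); for merely irreducible matrices it is still real and
#' positive, though other eigenvalues may share its modulus.
#'
#' @param A non-negative square numeric matrix.
#' @param check_ergodic if `TRUE`, a dominant eigenvalue whose imaginary
#'   part exceeds tolerance raises a `numerical_consistency_error` instead
#'   of being silently truncated.
#' @return the real part of the eigenvalue of maximum modulus.
#' @examples
#' dominant_eigenvalue(matrix(c(0, 0.5, 2, 0), 2, 2))  # 1
#' @export
dominant_eigenvalue <- function(A, check_ergodic = FALSE) {
  validate_projection_matrix(A)
  ev <- eigen(A, only.values = TRUE)$values
  # among modulus-maximal eigenvalues take the one of largest real part:
  # for a non-negative matrix that is the Perron root even when complex
  # eigenvalues share its modulus (periodic patterns)
  cand <- ev[Mod(ev) >= max(Mod(ev)) * (1 - 1e-12)]
  lam <- cand[which.max(Re(cand))]
  if (check_ergodic &&
      abs(Im(lam)) > .IMAG_TOL * (1 + abs(Re(lam))))
    stop_stochtrans(
      "dominant eigenvalue has a non-negligible imaginary part",
      "numerical_consistency_error")
  Re(lam)
}

#' Stable stage structure
#'
#' The right eigenvector `w` associated with the dominant eigenvalue,
#' rescaled to unit one-norm.  At this structure one step of projection
#' multiplies total abundance by exactly \eqn{\lambda_{max}}.
#'
#' @param A non-negative square numeric matrix; must have a one-dimensional
#'   dominant eigenspace (irreducibility suffices).
#' @return numeric vector of length `nrow(A)`, entries summing to 1.
#' @export
stable_structure <- function(A) {
  validate_projection_matrix(A)
  eg <- eigen(A)
  mods <- Mod(eg$values)
  cand <- which(mods >= max(mods) * (1 - 1e-12))
  i <- cand[which.max(Re(eg$values[cand]))]
  lam <- eg$values[i]
  # a repeated dominant eigenvalue (equal value, not merely equal modulus)
  # means the stable structure is not unique up to scale
  same <- which(abs(eg$values - lam) <= 1e-9 * (1 + Mod(lam)))
  if (length(same) > 1L)
    stop_stochtrans(
      "dominant eigenspace is not one-dimensional; matrix is not ergodic",
      "ergodicity_error")
  w <- Re(eg$vectors[, i])
  w <- w / sum(w)
  if (any(w < -1e-8))
    stop_stochtrans(
      "dominant right eigenvector is not sign-definite; matrix is reducible",
      "ergodicity_error")
  pmax(w, 0) / sum(pmax(w, 0))
}

#' Project a stage vector one time step
#'
#' @param A projection matrix.
#' @param x non-negative stage-abundance vector, length `nrow(A)`.
#' @return the vector `A %*% x` as a plain numeric vector.
#' @export
project <- function(A, x) {
  validate_projection_matrix(A)
  if (length(x) != nrow(A))
    stop_stochtrans(sprintf(
      "stage vector length %d does not match matrix dimension %d",
      length(x), nrow(A)), "dimension_error")
  as.numeric(A %*% x)
}

# boolean matrix product, used for reachability powers without overflow
.bool_mult <- function(P, Q) (P %*% Q) > 0

# P^k on the boolean pattern via binary exponentiation
.bool_pow <- function(P, k) {
  R <- diag(nrow(P)) > 0
  while (k > 0) {
    if (k %% 2 == 1) R <- .bool_mult(R, P)
    P <- .bool_mult(P, P)
    k <- k %/% 2
  }
  R
}

#' Ergodicity diagnosis of a projection matrix
#'
#' Irreducibility is tested as strong connectivity of the digraph of the
#' nonzero pattern: \eqn{(I + B)^{s-1} > 0} where `B` is the Boolean
#' pattern of `A`.  Primitivity uses Wielandt's bound: an irreducible
#' Boolean pattern is primitive iff \eqn{B^{s^2 - 2s + 2} > 0}.
#'
#' @param A non-negative square numeric matrix.
#' @return a list with logical elements `ergodic`, `irreducible`,
#'   `primitive` (`ergodic = irreducible & primitive`).
#' @examples
#' is_ergodic(matrix(c(0, 0.5, 2, 0), 2, 2))  # irreducible, imprimitive
#' @export
is_ergodic <- function(A) {
  validate_projection_matrix(A)
  s <- nrow(A)
  B <- A > 0
  irred <- all(.bool_pow((diag(s) > 0) | B, s - 1L))
  prim <- irred && all(.bool_pow(B, s^2 - 2L * s + 2L))
  list(ergodic = irred && prim, irreducible = irred, primitive = prim)
}

#' Element-wise mean of a set of projection matrices
#'
#' The mean matrix underlies the "stable growth rate of the mean projection
#' matrix" used in reactivity–growth association analyses.
#'
#' @param matrices non-empty list of same-dimension projection matrices.
#' @return a single matrix of the same dimension.
#' @export
mean_matrix <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop_stochtrans("need a non-empty list of matrices", "dimension_error")
  dims <- vapply(matrices, function(m) nrow(m), integer(1))
  if (length(unique(dims)) != 1L ||
      !all(vapply(matrices, function(m) ncol(m) == nrow(m), logical(1))))
    stop_stochtrans("matrices must all share one square dimension",
                    "dimension_error")
  for (m in matrices) validate_projection_matrix(m)
  Reduce(`+`, matrices) / length(matrices)
}
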