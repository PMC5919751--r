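# Type-specific sequencing-error estimation and correction.
#
# The error model is a 4x4 row-stochastic matrix e, with e(a,b) the
# probability of reading base b when the truth is a. A read-level channel
# turns a true base-frequency vector p_G (column) into the observed
# p_T = t(e) %*% p_G; correction inverts that product. At the level of the
# four-population 256-pattern distribution the channel factorises as the
# Kronecker product of the per-population matrices, so inversion only ever
# touches 4x4 factors.

#' Validate / construct an error matrix
#'
#' @param e 4x4 numeric matrix, rows = true base (A,C,G,T), columns =
#'   observed base; rows must sum to 1.
#' @param tol tolerance on the row sums.
#' @return the matrix with dimnames set, class `error_matrix`.
#' @export
error_matrix <- function(e, tol = 1e-9) {
  e <- as.matrix(e)
  stopifnot(all(dim(e) == c(4, 4)))
  if (any(e < -tol) || any(e > 1 + tol))
    stop("error-matrix entries must lie in [0,1]")
  if (any(abs(rowSums(e) - 1) > tol))
    stop("error-matrix rows must sum to 1")
  if (any(e[row(e) != col(e)] > 0.5))
    warning("off-diagonal error rate above 0.5; check base order")
  dimnames(e) <- list(true = BASES, observed = BASES)
  class(e) <- c("error_matrix", class(e))
  e
}

# Euclidean projection of each row onto the probability simplex.
project_rows_simplex <- function(m) {
  t(apply(m, 1, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (1 - css[rho]) / rho
    pmax(v + theta, 0)
  }))
}

#' Estimate a type-specific error matrix from a (T, R, O) trio
#'
#' Compares an error-prone individual T and an error-free individual R,
#' both against an outgroup O, in the tree ((T,R),O). Counting observed
#' bases of T and of R stratified by the outgroup base gives conditional
#' distributions `P_T(b|a)` and `P_R(g|a)`; because T and R share their
#' true base distribution given the outgroup base, `P_T = P_R %*% e`.
#' The error matrix is recovered by least squares constrained to the
#' row-stochastic non-negative matrices (projected gradient descent,
#' initialised at the row-projected exact solution).
#'
#' @param counts_T_vs_O 4x4 integer matrix: rows = outgroup base, columns
#'   = observed base of the error-prone individual.
#' @param counts_R_vs_O same for the error-free individual.
#' @param max_iter,tol optimiser controls.
#' @return an [error_matrix()] estimate of e.
#' @export
estimate_error_matrix <- function(counts_T_vs_O, counts_R_vs_O,
                                  max_iter = 5000, tol = 1e-14) {
  A0 <- as.matrix(counts_R_vs_O); B0 <- as.matrix(counts_T_vs_O)
  stopifnot(all(dim(A0) == c(4, 4)), all(dim(B0) == c(4, 4)))
  rowsA <- rowSums(A0); rowsB <- rowSums(B0)
  use <- rowsA >= 1 & rowsB >= 1
  if (!all(use))
    warning("outgroup base(s) ", paste(BASES[!use], collapse = ","),
            " have no observations and are excluded")
  if (sum(use) < 2) stop("too few informative outgroup bases")
  A <- A0[use, , drop = FALSE] / rowsA[use]
  B <- B0[use, , drop = FALSE] / rowsB[use]
  if (nrow(A) == 4) {
    if (rcond(A) < 1e-10)
      stop("ill-conditioned reference distribution; more sites needed")
    e0 <- solve(A, B)
  } else {
    e0 <- qr.solve(A, B)
  }
  e <- project_rows_simplex(e0)
  # projected gradient on ||A e - B||_F^2 (convex, tiny problem)
  L <- 2 * norm(crossprod(A), "2")
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    G <- 2 * crossprod(A, A %*% e - B)
    e <- project_rows_simplex(e - G / L)
    obj <- sum((A %*% e - B)^2)
    if (abs(obj_old - obj) < tol) break
    obj_old <- obj
  }
  error_matrix(e, tol = 1e-6)
}

#' Error-correct an observed base-frequency vector (per individual)
#'
#' Inverts the read-level channel `p_T = t(e) %*% p_G`: returns
#' `solve(t(e), p_observed)`. Strong error matrices can produce negative
#' entries; these are handled by the configured negativity policy.
#'
#' @param p_observed length-4 observed base-frequency vector.
#' @param e 4x4 error matrix.
#' @param negativity `"clamp"` (zero and renormalise) or `"strict"`.
#' @return corrected length-4 vector.
#' @export
correct_individual_freqs <- function(p_observed, e, negativity = "clamp") {
  if (rcond(as.matrix(e)) < 1e-12) stop("error matrix is not invertible")
  p <- solve(t(unclass(e)), p_observed)
  apply_negativity_policy(as.vector(p), negativity)
}

#' Mean error matrix of a population
#'
#' Entrywise arithmetic mean of per-individual error matrices; this is the
#' population-level matrix used by the group (pattern-space) correction.
#'
#' @param mats list of 4x4 error matrices (at least one).
#' @return an [error_matrix()].
#' @export
mean_population_error <- function(mats) {
  stopifnot(length(mats) >= 1)
  error_matrix(Reduce(`+`, lapply(mats, unclass)) / length(mats), tol = 1e-6)
}

# Apply M_j (4x4, orientation new_b = sum_a M[a,b] old_a) along pattern
# position j of a 256-vector or blocks x 256 matrix.
apply_pattern_mode <- function(p, M, pos) {
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, 1)
  nb <- nrow(p)
  # array dims: (a4, a3, a2, a1, block) -- position j is dim 5 - j
  A <- array(t(p), dim = c(4, 4, 4, 4, nb))
  d <- 5L - pos
  perm <- c(d, setdiff(1:5, d))
  A <- aperm(A, perm)
  dim(A) <- c(4, 64 * nb)
  A <- crossprod(M, A)                      # t(M) %*% A : new_b = sum_a M[a,b] old_a
  dim(A) <- c(4, 4, 4, 4, nb)[perm]
  A <- aperm(A, order(perm))
  out <- t(matrix(A, 256, nb))
  if (vec) as.vector(out) else out
}

#' Group error operator on the 256-pattern space
#'
#' Builds the four-population error operator whose entry for patterns
#' `(a1:4, b1:4)` is `e1(a1,b1) e2(a2,b2) e3(a3,b3) e4(a4,b4)` (error
#' rates independent between populations). The operator is kept in
#' factored (Kronecker) form: application and inversion act through the
#' four 4x4 factors, and the inverse is the product of the factor
#' inverses. A dense 256x256 matrix is materialised only on request.
#'
#' @param e1,e2,e3,e4 4x4 row-stochastic error matrices (population order
#'   H1..H4).
#' @param dense also materialise the dense matrix `E` (patterns in
#'   lexicographic order AAAA..TTTT)?
#' @return object of class `group_error` with fields `factors`, functions
#'   `apply(p)` (true -> observed) and `correct(p)` (observed -> true),
#'   and optionally `E`.
#' @export
build_group_error_matrix <- function(e1, e2, e3, e4, dense = FALSE) {
  factors <- list(e1, e2, e3, e4)
  for (f in factors)
    if (rcond(as.matrix(f)) < 1e-12)
      stop("error-matrix factor is not invertible")
  inv <- lapply(factors, function(f) solve(unclass(f)))
  obj <- list(
    factors = factors,
    apply = function(p) {
      for (j in 1:4) p <- apply_pattern_mode(p, unclass(factors[[j]]), j)
      p
    },
    correct = function(p) {
      for (j in 1:4) p <- apply_pattern_mode(p, inv[[j]], j)
      p
    })
  if (dense)
    obj$E <- unclass(e1) %x% unclass(e2) %x% unclass(e3) %x% unclass(e4)
  structure(obj, class = "group_error")
}

#' Error-correct a 256-pattern distribution
#'
#' Applies the inverse of the group error operator (factored inverses; no
#' 256x256 solve) to an observed pattern distribution, then the negativity
#' policy. Operates row-wise on a `blocks x 256` matrix so that the
#' correction precedes the jackknife.
#'
#' @param P_error length-256 vector or `blocks x 256` matrix of observed
#'   pattern masses.
#' @param e_list list of four 4x4 error matrices (populations H1..H4), or
#'   a `group_error` object.
#' @param negativity `"clamp"` or `"strict"`.
#' @return corrected vector/matrix of the same shape.
#' @export
correct_pattern_probs <- function(P_error, e_list, negativity = "clamp") {
  ge <- if (inherits(e_list, "group_error")) e_list
        else build_group_error_matrix(e_list[[1]], e_list[[2]],
                                      e_list[[3]], e_list[[4]])
  apply_negativity_policy(ge$correct(P_error), negativity)
}
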