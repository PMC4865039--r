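#' Sample covariance of a gene subset
#'
#' Unbiased (divisor m-1) sample covariance over the selected genes, computed
#' across samples.  All dependence measures in this package are functions of
#' such covariance blocks under the multivariate-Gaussian model.
#'
#' @param expr an [expression_matrix()] or plain genes-by-samples matrix.
#' @param genes character vector of gene identifiers (default: all genes).
#'   A duplicated gene yields a rank-deficient (determinant-zero) matrix.
#' @return symmetric numeric matrix with the selected genes as dimnames.
#' @export
gene_covariance <- function(expr, genes = NULL) {
  em <- as_expression_matrix(expr)
  if (ncol(em$values) < 2) stop("need at least 2 samples to estimate covariance")
  if (is.null(genes)) genes <- rownames(em$values)
  if (!length(genes)) stop("empty gene subset")
  bad <- setdiff(genes, rownames(em$values))
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  C <- stats::cov(t(em$values[genes, , drop = FALSE]))
  dimnames(C) <- list(genes, genes)
  C
}

# log determinant with singularity guard; dets <= 1e-300 are treated as singular
logdet_guarded <- function(C) {
  if (nrow(C) == 0) return(0)
  d <- determinant(C, logarithm = TRUE)
  if (d$sign <= 0 || d$modulus < log(1e-300))
    stop("singular covariance (determinant <= 0 within tolerance)")
  as.numeric(d$modulus)
}

#' Differential entropy of a Gaussian
#'
#' Entropy (in nats) of a d-dimensional Gaussian with covariance `C`:
#' `H = (d/2) log(2*pi*e) + (1/2) log det C`.
#'
#' @param C covariance matrix (may be 1x1).
#' @return entropy in nats.
#' @examples
#' gauss_entropy(matrix(1))           # 0.5 * log(2*pi*e) ~= 1.4189
#' @export
gauss_entropy <- function(C) {
  C <- as.matrix(C)
  0.5 * nrow(C) * log(2 * pi * exp(1)) + 0.5 * logdet_guarded(C)
}

# --- covariance-indexed kernels -------------------------------------------
# All take a full covariance matrix S and integer/character indices, so the
# PC loop can precompute S once.

mi_cov <- function(S, x, y) {
  # canonical argument order, so MI(X,Y) and MI(Y,X) are bit-identical
  o <- order(c(x, y), method = "radix")
  x2 <- c(x, y)[o[1]]; y2 <- c(x, y)[o[2]]
  x <- x2; y <- y2
  vx <- S[x, x]; vy <- S[y, y]
  if (vx <= 0 || vy <= 0)
    stop("degenerate gene (zero marginal variance)")
  ld2 <- logdet_guarded(S[c(x, y), c(x, y)])
  max(0, 0.5 * (log(vx) + log(vy) - ld2))
}

cmi_cov <- function(S, x, y, z = NULL) {
  if (!length(z)) {
    # empty conditioning set: |C(Z)| = 1 and the expression reduces to MI
    return(mi_cov(S, x, y))
  }
  ldxz  <- logdet_guarded(S[c(x, z), c(x, z)])
  ldyz  <- logdet_guarded(S[c(y, z), c(y, z)])
  ldz   <- logdet_guarded(S[z, z, drop = FALSE])
  ldxyz <- logdet_guarded(S[c(x, y, z), c(x, y, z)])
  max(0, 0.5 * (ldxz + ldyz - ldz - ldxyz))
}

# linear solve that reports ill-conditioning as a singular-covariance error
solve_guarded <- function(A, b) {
  tryCatch(solve(A, b), error = function(e)
    stop("singular covariance block: ", conditionMessage(e), call. = FALSE))
}

# Gaussian KL divergence KL(N(0,Sp) || N(0,Sq)), both d-dimensional
kl_gauss <- function(Sp, Sq) {
  d <- nrow(Sp)
  0.5 * (sum(diag(solve_guarded(Sq, Sp))) - d +
           logdet_guarded(Sq) - logdet_guarded(Sp))
}

# Covariance of the interventional factorization q in which the response
# variable `yi` keeps its dependence on the conditioning block but its direct
# input `xi` is severed by averaging over the input's marginal:
#   q(x, y, z) = p(x, z) * \int p(y | x', z) p(x') dx'
# Under a joint Gaussian the mixture integral is again Gaussian: Y | Z keeps
# its regression on Z while the x-coefficient's contribution is folded into
# the residual variance (s + a^2 Var X).
interventional_cov <- function(S, xi, yi, zi) {
  wi <- c(xi, zi)
  beta <- solve_guarded(S[wi, wi], S[wi, yi])
  a <- beta[1]
  b <- if (length(zi)) beta[-1] else numeric(0)
  s <- S[yi, yi] - drop(S[yi, wi] %*% beta)   # residual variance of Y | X,Z
  Sq <- S
  if (length(zi)) {
    Szz <- S[zi, zi, drop = FALSE]
    Sq[yi, yi] <- drop(t(b) %*% Szz %*% b) + s + a^2 * S[xi, xi]
    Sq[yi, zi] <- Sq[zi, yi] <- drop(Szz %*% b)
    Sq[yi, xi] <- Sq[xi, yi] <- drop(t(b) %*% S[zi, xi, drop = FALSE])
  } else {
    Sq[yi, yi] <- s + a^2 * S[xi, xi]
    Sq[yi, xi] <- Sq[xi, yi] <- 0
  }
  Sq
}

cmi2_cov <- function(S, x, y, z = NULL) {
  idx <- c(x, y, z)
  Ss <- S[idx, idx, drop = FALSE]
  d <- nrow(Ss)
  zi <- if (d > 2) 3:d else integer(0)
  Sq1 <- interventional_cov(Ss, xi = 1, yi = 2, zi = zi)
  Sq2 <- interventional_cov(Ss, xi = 2, yi = 1, zi = zi)
  v <- 0.5 * (kl_gauss(Ss, Sq1) + kl_gauss(Ss, Sq2))
  if (v < -1e-9) stop("CMI2 negative beyond numerical tolerance; ill-conditioned covariance")
  max(0, v)
}

# --- user-facing wrappers --------------------------------------------------

#' Gaussian mutual information between two genes
#'
#' `MI(X,Y) = (1/2) log( |C(X)| |C(Y)| / |C(X,Y)| )` in nats, estimated from
#' the unbiased sample covariance.  For bivariate data with correlation
#' `rho` this equals `-(1/2) log(1 - rho^2)`.
#'
#' @inheritParams gene_covariance
#' @param x,y gene identifiers, `x != y`.
#' @return nonnegative numeric (nats).
#' @export
gauss_mi <- function(expr, x, y) {
  if (identical(x, y)) stop("x and y must differ")
  S <- gene_covariance(expr, c(x, y))
  mi_cov(S, x, y)
}

#' Gaussian conditional mutual information
#'
#' `CMI(X,Y|Z) = (1/2) log( |C(X,Z)| |C(Y,Z)| / (|C(Z)| |C(X,Y,Z)|) )` in
#' nats.  With an empty conditioning set it reduces exactly to [gauss_mi()].
#' This is the measure used by classical PC-over-CMI inference; it is kept as
#' a comparison mode ([rpni()] with `measure = "cmi"`).
#'
#' @inheritParams gauss_mi
#' @param z character vector of conditioning genes (may be empty), disjoint
#'   from `x` and `y`.
#' @return nonnegative numeric (nats).
#' @export
gauss_cmi <- function(expr, x, y, z = character()) {
  check_xyz(x, y, z)
  S <- gene_covariance(expr, c(x, y, z))
  cmi_cov(S, x, y, z)
}

#' Conditional mutual inclusive information (CMI2)
#'
#' CMI2 scores the dependence of `x` and `y` given conditioning genes `z` as
#' the average of two Kullback-Leibler divergences, each between the joint
#' distribution and an interventional factorization in which one direction of
#' the x-y coupling is severed (the conditional of one endpoint is averaged
#' over its partner's marginal, a do-calculus operation).  Unlike CMI, it does
#' not vanish when the conditioning set d-separates the pair only spuriously,
#' which corrects CMI's underestimation of regulatory strength.  Under the
#' package's Gaussian model both interventional distributions are Gaussian and
#' the divergences have closed forms in covariance blocks (see the package
#' vignette for the derivation).
#'
#' With empty `z` the value coincides with [gauss_mi()]; the inference loop
#' uses plain MI at order 0.
#'
#' @inheritParams gauss_cmi
#' @return nonnegative numeric (nats), symmetric in `x` and `y`.
#' @export
cmi2 <- function(expr, x, y, z = character()) {
  check_xyz(x, y, z)
  S <- gene_covariance(expr, c(x, y, z))
  cmi2_cov(S, x, y, z)
}

check_xyz <- function(x, y, z) {
  if (identical(x, y)) stop("x and y must differ")
  if (x %in% z || y %in% z) stop("conditioning set must not contain x or y")
  invisible(NULL)
}
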