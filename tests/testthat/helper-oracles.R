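# Shared fixtures and independent oracles used across the test files.

toy5_path <- function() {
  p <- system.file("extdata", "toy5_expr.tsv", package = "rpni")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", "toy5_expr.tsv")
  p
}

# study conditions of the end-to-end recovery experiments
recovery_config <- list(
  n_genes = 10, density = 0.2, m = 500, theta = 0.03,
  n_seeds = 20, mcc_target = 0.8, auc_target = 0.9,
  theta_grid = c(0.001, 0.003, 0.01, 0.02, 0.03, 0.05, 0.08, 0.12,
                 0.2, 0.35, 0.6, 1, 2)
)

random_spd <- function(d, jitter = 0.5) {
  A <- matrix(rnorm(d * d), d)
  S <- crossprod(A) + diag(d) * jitter
  dimnames(S) <- list(paste0("V", seq_len(d)), paste0("V", seq_len(d)))
  S
}

# expression matrix whose empirical covariance equals S exactly
expr_with_cov <- function(S, m = 3 * nrow(S) + 5) {
  D <- MASS::mvrnorm(m, rep(0, nrow(S)), S, empirical = TRUE)
  expression_matrix(t(D))
}

# determinant by recursive cofactor expansion (small matrices only)
det_cofactor <- function(M) {
  n <- nrow(M)
  if (n == 1) return(M[1, 1])
  sum(vapply(seq_len(n), function(j)
    (-1)^(1 + j) * M[1, j] * det_cofactor(M[-1, -j, drop = FALSE]),
    numeric(1)))
}

# log density of a zero-mean multivariate Gaussian at rows of X
ldmvn <- function(X, S) {
  L <- chol(S)
  -0.5 * rowSums((X %*% solve(L))^2) -
    0.5 * ncol(S) * log(2 * pi) - sum(log(diag(L)))
}

# Monte-Carlo + quadrature oracle for CMI2 on a 3-variable Gaussian
# (X = col 1, Y = col 2, Z = col 3 of S).  Draws from N(0, S) and averages
# log p - (log q1 + log q2)/2, with each interventional density evaluated
# pointwise: q1(x,y,z) = p(x,z) * \int p(y|x',z) p(x') dx', the integral done
# by quadrature over a grid of x'.  Returns the estimate and its standard
# error.  Shares no code with the closed-form implementation under test.
cmi2_mc_oracle <- function(S, n_draws = 2e5, nodes = 151, chunk = 1e5) {
  stopifnot(nrow(S) == 3)
  X <- matrix(rnorm(n_draws * 3), n_draws, 3) %*% chol(S)
  lp <- ldmvn(X, S)
  lq <- function(yi, xi, zi) {
    wi <- c(xi, zi)
    beta <- solve(S[wi, wi], S[wi, yi])
    a <- beta[1]; b <- beta[2]
    s <- S[yi, yi] - drop(S[yi, wi] %*% beta)
    sdx <- sqrt(S[xi, xi])
    xs <- seq(-8 * sdx, 8 * sdx, length.out = nodes)
    wts <- dnorm(xs, 0, sdx); wts <- wts / sum(wts)
    g <- numeric(n_draws)
    for (ii in split(seq_len(n_draws), ceiling(seq_len(n_draws) / chunk))) {
      mu <- outer(X[ii, zi] * b, a * xs, "+")
      g[ii] <- drop(dnorm(X[ii, yi] - mu, 0, sqrt(s)) %*% wts)
    }
    log(pmax(g, 1e-300)) + ldmvn(X[, c(xi, zi)], S[c(xi, zi), c(xi, zi)])
  }
  v <- lp - 0.5 * (lq(yi = 2, xi = 1, zi = 3) + lq(yi = 1, xi = 2, zi = 3))
  list(est = mean(v), se = sd(v) / sqrt(n_draws))
}

# Straightforward PC reference over correlation algebra (orders 0 and 1),
# conditioning on all common neighbors, deleting on a live graph in
# lexicographic order.  MI and CMI are computed from (partial) correlations,
# an algebraic route independent of the covariance-determinant kernels.
reference_pc1 <- function(expr, theta) {
  v <- as_expression_matrix(expr)$values
  R <- cor(t(v))
  g <- sort(rownames(v), method = "radix")
  adj <- matrix(TRUE, length(g), length(g), dimnames = list(g, g))
  diag(adj) <- FALSE
  prs <- t(combn(g, 2))
  for (r in seq_len(nrow(prs))) {
    a <- prs[r, 1]; b <- prs[r, 2]
    if (-0.5 * log(1 - R[a, b]^2) < theta)
      adj[a, b] <- adj[b, a] <- FALSE
  }
  for (r in seq_len(nrow(prs))) {
    a <- prs[r, 1]; b <- prs[r, 2]
    if (!adj[a, b]) next
    cn <- g[adj[a, ] & adj[b, ]]
    if (!length(cn)) next
    cmis <- vapply(cn, function(z) {
      pr <- (R[a, b] - R[a, z] * R[z, b]) /
        sqrt((1 - R[a, z]^2) * (1 - R[z, b]^2))
      -0.5 * log(1 - pr^2)
    }, numeric(1))
    if (max(cmis) < theta) adj[a, b] <- adj[b, a] <- FALSE
  }
  adj
}

# AUC by explicit rectangle + triangle decomposition of the staircase
auc_rect_tri <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  u <- sort(unique(fpr))
  ty <- vapply(u, function(f) max(tpr[fpr == f]), numeric(1))
  a <- 0
  for (i in seq_len(length(u) - 1)) {
    dx <- u[i + 1] - u[i]
    lo <- min(ty[i], ty[i + 1])
    a <- a + dx * lo + 0.5 * dx * abs(ty[i + 1] - ty[i])
  }
  a
}

# deterministic sub-seed derivation for multi-seed experiments
sub_seed <- function(base, k) (base + 7919L * k) %% 2147483647L
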