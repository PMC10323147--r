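# Shared fixtures and an independent GLS/conditional-expectation oracle.

# the built-in two-trait, two-cue example parameters
toy_gp <- function() genetic_params()

# single-trait, no-plasticity parameters (q = 0)
q0_gp <- function(Gaa = 0.2, sigma_v2 = 0.2, p = 1) {
  genetic_params(
    Gaa = diag(Gaa, p), Gab = matrix(0, p, 0), Gbb = matrix(0, 0, 0),
    sigma_v2 = rep(sigma_v2, p), sigma_eta2 = matrix(0, p, 0)
  )
}

# random dense PSD genetic parameters for property tests
random_gp <- function(p, q, rng_scale = 0.3) {
  d <- p * (1 + q)
  L <- matrix(rnorm(d * d, sd = rng_scale), d)
  G <- crossprod(L) + diag(0.05, d)
  genetic_params(
    Gaa = G[seq_len(p), seq_len(p), drop = FALSE],
    Gab = G[seq_len(p), p + seq_len(p * q), drop = FALSE],
    Gbb = G[p + seq_len(p * q), p + seq_len(p * q), drop = FALSE],
    sigma_v2 = runif(p, 0.1, 0.4),
    sigma_eta2 = matrix(runif(p * q, 0.02, 0.1), p, q)
  )
}

# a random phenotype/fitness instance on given genetic parameters
random_instance <- function(gp, n, rel = identity_relatedness(n),
                            u = rnorm(gp$q)) {
  mean <- mean_params(abar = rep(0, gp$p),
                      Bbar = matrix(0, gp$p, max(gp$q, 0)))
  coh <- make_cohort(mean, gp, rel, u, theta = rnorm(gp$p), n = n)
  list(coh = coh, u = u, rel = rel)
}

# Independent GLS / conditional-expectation oracle for the BLUP solution:
# beta_hat from generalised least squares with V = Z G Z' + R, and
# xhat = G Z' V^{-1} (y - X beta_hat). Written directly from the marginal
# model, with no shared code with the Henderson solver.
gls_blup_oracle <- function(y, gp, rel, u) {
  n <- nrow(y); p <- gp$p; q <- gp$q
  A <- if (rel$kind == "identity") diag(n) else rel$A
  Zt <- cbind(diag(p),
              if (q > 0) kronecker(diag(p), matrix(u, 1)) else NULL)
  Ztilde <- kronecker(Zt, diag(n))
  X <- kronecker(diag(p), matrix(1, n, 1))
  r <- gp$sigma_v2 + if (q > 0) as.numeric(gp$sigma_eta2 %*% u^2) else 0
  Rtilde <- diag(rep(r, each = n))
  Gt <- kronecker(gp$G, A)
  V <- Ztilde %*% Gt %*% t(Ztilde) + Rtilde
  Vinv <- solve(V)
  yv <- as.numeric(y)
  beta <- solve(t(X) %*% Vinv %*% X, t(X) %*% Vinv %*% yv)
  xhat_vec <- Gt %*% t(Ztilde) %*% Vinv %*% (yv - X %*% beta)
  list(ybar_hat = as.numeric(beta), xhat = matrix(xhat_vec, nrow = n))
}
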