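test_that("incidence matrices have the documented structure", {
  inc <- build_incidence(c(1.5, -2), p = 2, q = 2, n = 3)
  expect_equal(unname(inc$Zt),
               rbind(c(1, 0, 1.5, -2, 0, 0),
                     c(0, 1, 0, 0, 1.5, -2)))
  expect_equal(inc$Ztilde, kronecker(unname(inc$Zt), diag(3)),
               ignore_attr = TRUE)
  expect_equal(inc$X, kronecker(diag(2), matrix(1, 3, 1)))
  # u = 0 degenerates to the no-plasticity design
  inc0 <- build_incidence(c(0, 0), p = 2, q = 2, n = 2)
  expect_equal(unname(inc0$Zt), cbind(diag(2), matrix(0, 2, 4)))
  # p = q = 1 is the simple intercept-slope model
  inc1 <- build_incidence(0.7, p = 1, q = 1, n = 2)
  expect_equal(unname(inc1$Zt), rbind(c(1, 0.7)))
})

test_that("residual variance tracks the squared cues", {
  gp <- toy_gp()
  expect_equal(build_residual(c(0, 0), gp, 5)$r, c(0.2, 0.2))
  # only each trait's own cue is active in the example parameters
  expect_equal(build_residual(c(1, 1), gp, 5)$r, c(0.25, 0.25))
  expect_equal(build_residual(c(2, 0), gp, 5)$r, c(0.2 + 0.05 * 4, 0.2))
  r1 <- build_residual(c(1, 1), gp, 5)$r
  r2 <- build_residual(c(2, 2), gp, 5)$r
  expect_true(all(r2 > r1))
  gp_bad <- genetic_params(sigma_v2 = c(0, 0))
  expect_error(build_residual(c(0, 0), gp_bad, 5), "unidentifiable")
})

test_that("Kronecker random-effect covariance", {
  gp <- toy_gp()
  rel <- band_relatedness(2)
  Gt <- build_gtilde(gp, rel)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(Gt[(i - 1) * 2 + 1:2, (j - 1) * 2 + 1:2],
                 gp$G[i, j] * rel$A, ignore_attr = TRUE)
  }
  # spectrum is the outer product of the factor spectra
  ev <- sort(eigen(Gt, symmetric = TRUE, only.values = TRUE)$values)
  ev_expected <- sort(as.numeric(outer(
    eigen(gp$G, symmetric = TRUE, only.values = TRUE)$values,
    eigen(rel$A, symmetric = TRUE, only.values = TRUE)$values)))
  expect_equal(ev, ev_expected, tolerance = 1e-10)
})

test_that("constant phenotypes give zero random effects and the constant mean", {
  gp <- toy_gp()
  n <- 8; u <- c(0.4, -0.2)
  y <- matrix(rep(c(1.7, -0.3), each = n), n)
  fit <- blup_solve(y, build_incidence(u, 2, 2, n),
                    build_residual(u, gp, n), build_gtilde(gp, identity_relatedness(n)))
  expect_equal(fit$ybar_hat, c(1.7, -0.3))
  expect_lt(max(abs(fit$xhat)), 1e-10)
})

test_that("single-trait no-plasticity BLUP is heritability times the deviation", {
  gp1 <- q0_gp(Gaa = 0.2, sigma_v2 = 0.2)
  set.seed(13)
  y <- matrix(rnorm(20, 1, 0.6))
  fit <- blup_fit(y, gp1, identity_relatedness(20), numeric(0))
  h2 <- 0.2 / (0.2 + 0.2)
  expect_equal(fit$xhat[, 1], h2 * (y[, 1] - mean(y)), ignore_attr = TRUE)
  expect_equal(fit$ybar_hat, mean(y))
})

test_that("Henderson solve equals the GLS/conditional-expectation oracle", {
  set.seed(71)
  for (case in 1:12) {
    p <- sample(1:2, 1)
    q <- sample(0:2, 1)
    n <- sample(2:20, 1)
    gp <- random_gp(p, q)
    rel <- switch(sample(3, 1),
                  identity_relatedness(n),
                  band_relatedness(n),
                  relatedness_matrix(band_relatedness(n)$A))
    u <- rnorm(q)
    inst <- random_instance(gp, n, rel, u)
    fit <- blup_solve(inst$coh$y, build_incidence(u, p, q, n),
                      build_residual(u, gp, n), build_gtilde(gp, rel))
    oracle <- gls_blup_oracle(inst$coh$y, gp, rel, u)
    expect_lt(max(abs(fit$ybar_hat - oracle$ybar_hat)), 1e-8)
    expect_lt(max(abs(fit$xhat - oracle$xhat)), 1e-8)
  }
})

test_that("the factorized unrelated-population path equals the Henderson solve", {
  set.seed(72)
  gp <- toy_gp()
  for (n in c(2, 7, 30)) {
    rel <- identity_relatedness(n)
    u <- rnorm(2)
    inst <- random_instance(gp, n, rel, u)
    f_fac <- blup_fit(inst$coh$y, gp, rel, u, solver = "factorized")
    f_mme <- blup_fit(inst$coh$y, gp, rel, u, solver = "mme")
    expect_lt(max(abs(f_fac$xhat - f_mme$xhat)), 1e-10)
    expect_lt(max(abs(f_fac$ybar_hat - f_mme$ybar_hat)), 1e-10)
  }
})

test_that("random-effect estimates average to zero for unrelated individuals", {
  set.seed(73)
  gp <- toy_gp()
  inst <- random_instance(gp, 25, u = c(0.8, -0.3))
  fit <- blup_fit(inst$coh$y, gp, identity_relatedness(25), inst$u)
  expect_lt(max(abs(colMeans(fit$xhat))), 1e-8)
})

test_that("solution is equivariant under trait translation", {
  set.seed(74)
  gp <- toy_gp()
  n <- 15; u <- c(0.5, 0.2)
  rel <- band_relatedness(n)
  inst <- random_instance(gp, n, rel, u)
  fit0 <- blup_fit(inst$coh$y, gp, rel, u)
  y_shift <- inst$coh$y
  y_shift[, 1] <- y_shift[, 1] + 2.5
  fit1 <- blup_fit(y_shift, gp, rel, u)
  expect_equal(fit1$ybar_hat, fit0$ybar_hat + c(2.5, 0), tolerance = 1e-8)
  expect_lt(max(abs(fit1$xhat - fit0$xhat)), 1e-8)
})

test_that("tidiers expose fixed and random effects", {
  set.seed(75)
  gp <- toy_gp()
  inst <- random_instance(gp, 10, u = c(0.1, 0.1))
  fit <- blup_fit(inst$coh$y, gp, identity_relatedness(10), inst$u)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 2)
  tr <- tidy(fit, effects = "random")
  expect_equal(nrow(tr), 10 * 6)
  expect_equal(glance(fit)$n, 10)
})
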