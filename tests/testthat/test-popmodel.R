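test_that("banded relatedness reproduces the n = 6 pattern exactly", {
  A6 <- band_relatedness(6)$A
  expected <- matrix(1 / 4, 6, 6)
  expected[abs(row(expected) - col(expected)) == 1] <- 1 / 2
  diag(expected) <- 1
  expect_identical(A6, expected)
  expect_identical(A6[1, ], c(1, 1/2, 1/4, 1/4, 1/4, 1/4))
  r1 <- band_relatedness(1)
  expect_equal(r1$A, matrix(1))
  expect_equal(r1$A_M, matrix(1))
})

test_that("A_M is a symmetric matrix square root of A", {
  rel <- band_relatedness(100)
  expect_true(isSymmetric(rel$A_M))
  expect_lt(max(abs(rel$A_M %*% rel$A_M - rel$A)), 1e-10)
})

test_that("relatedness CSV round-trips and warns on non-unit diagonal", {
  rel <- band_relatedness(8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_relatedness_csv(rel, path)
  back <- read_relatedness_csv(path)
  expect_equal(back$A, rel$A, tolerance = 1e-12)
  inbred <- diag(1.2, 3)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(inbred, path2, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  expect_warning(read_relatedness_csv(path2), "diagonal")
})

test_that("sampled additive deviations have covariance G for unrelated individuals", {
  gp <- toy_gp()
  set.seed(31)
  z <- sample_additive(gp, identity_relatedness(1e5), 1e5)
  emp <- cov(z)
  act <- which(diag(gp$G) > 0)
  expect_lt(max(abs(emp[act, act] - gp$G[act, act])) /
              max(abs(gp$G)), 0.05)
  expect_true(all(z[, diag(gp$G) == 0] == 0))
  expect_equal(colMeans(z), rep(0, 6), ignore_attr = TRUE)
  # zero G -> all zeros
  gp0 <- genetic_params(Gaa = matrix(0, 2, 2), Gbb = matrix(0, 4, 4),
                        sigma_v2 = c(0.1, 0.1))
  expect_true(all(sample_additive(gp0, identity_relatedness(10), 10) == 0))
})

test_that("banded relatedness reduces realised variances to about 75% of nominal", {
  gp <- toy_gp()
  rel <- band_relatedness(100)
  act <- which(diag(gp$G) > 0)
  set.seed(8)
  ratios <- replicate(200, {
    z <- sample_additive(gp, rel, 100)
    mean(apply(z[, act], 2, var) / diag(gp$G)[act])
  })
  expect_gt(mean(ratios), 0.70)
  expect_lt(mean(ratios), 0.80)
})

test_that("cohort phenotypes reconstruct the reaction-norm model exactly", {
  gp <- toy_gp()
  set.seed(5)
  mn <- mean_params(abar = c(0.3, -0.2),
                    Bbar = matrix(c(-0.5, 0.1, 0, -0.4), 2, byrow = TRUE))
  u <- c(1.3, -0.7); theta <- c(0.2, 0.1)
  coh <- make_cohort(mn, gp, identity_relatedness(50), u, theta, n = 50)
  q <- gp$q
  for (j in 1:2) {
    cols <- (j - 1) * q + seq_len(q)
    manual <- mn$abar[j] + coh$x_true[, j] + coh$v[, j] +
      (matrix(rep(mn$Bbar[j, ], each = 50), 50) +
         coh$x_true[, 2 + cols] + coh$eta[, cols]) %*% u
    expect_equal(coh$y[, j], as.numeric(manual), ignore_attr = TRUE)
  }
  expect_true(all(coh$W == as.integer(coh$W)))
  expect_true(all(coh$W >= 0 & coh$W <= 4))
  expect_equal(mean(coh$w), 1)
})

test_that("deterministic cohorts: zero variances give the mean reaction norm", {
  gp0 <- genetic_params(Gaa = matrix(0, 2, 2), Gbb = matrix(0, 4, 4),
                        sigma_v2 = c(1e-9, 1e-9),
                        sigma_eta2 = matrix(0, 2, 2))
  mn <- mean_params(abar = c(0, 0),
                    Bbar = matrix(c(-0.5, 0, 0, -0.5), 2, byrow = TRUE))
  coh <- make_cohort(mn, gp0, identity_relatedness(5), u = c(1, 2),
                     theta = c(0, 0), n = 5)
  expect_equal(coh$y[, 1], rep(-0.5, 5), tolerance = 1e-3)
  expect_equal(coh$y[, 2], rep(-1.0, 5), tolerance = 1e-3)
})

test_that("phenotypic variance matches Paa for the example parameters", {
  gp <- toy_gp()
  set.seed(44)
  coh <- make_cohort(mean_params(), gp, identity_relatedness(1e5),
                     u = c(0, 0), theta = c(0, 0), n = 1e5)
  expect_lt(abs(var(coh$y[, 1]) - 0.4) / 0.4, 0.05)
  expect_lt(abs(var(coh$y[, 2]) - 0.4) / 0.4, 0.05)
})

test_that("fitness values follow the Gaussian-selection formula", {
  fit <- fitness_config(W_max = 4, omega2 = 10)
  theta <- c(1, -1)
  expect_identical(fitness_values(theta, theta, fit), 4L)
  # squared distance where expected fitness is exactly half the peak
  d2 <- 2 * 10 * log(2)
  y_half <- theta + c(sqrt(d2), 0)
  expect_identical(fitness_values(y_half, theta, fit), 2L)
  expect_identical(fitness_values(theta + 100, theta, fit), 0L)
  # translation invariance and monotone decay in distance
  y <- rbind(c(0.5, 0), c(2, 1), c(5, 4))
  expect_identical(fitness_values(y, theta, fit),
                   fitness_values(y + 3, theta + 3, fit))
  dist <- sqrt(rowSums(sweep(y, 2, theta)^2))
  W <- fitness_values(y, theta, fit)
  expect_true(all(diff(W[order(dist)]) <= 0))
})

test_that("relative fitness normalises to mean one and flags extinction", {
  expect_equal(relative_fitness(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(relative_fitness(c(0L, 4L)), c(0, 2))
  set.seed(2)
  W <- sample(0:4, 50, replace = TRUE)
  expect_equal(mean(relative_fitness(W)), 1)
  expect_error(relative_fitness(c(0, 0, 0)), "extinct")
})

test_that("optimal stationary slopes", {
  expect_identical(optimal_slope(0.5, -0.25), -0.5)
  expect_identical(optimal_slope(0.1875, -0.09375), -0.5)
  expect_identical(optimal_slope(0.7, 0), 0)
  expect_error(optimal_slope(0, 1), "var_u")
})
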