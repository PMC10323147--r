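#' Additive and phenotypic covariance structure of a reaction-norm model
#'
#' Collects the genetic parameters of a `p`-trait, `q`-cue linear
#' reaction-norm model. Random effects are ordered trait-major throughout
#' the package: first the `p` intercept deviations `a'_1..a'_p`, then the
#' slope deviations by trait with cues within trait
#' (`b'_11..b'_1q, ..., b'_p1..b'_pq`). The additive covariance matrix is
#' `G = [[Gaa, Gab], [Gab', Gbb]]` in this ordering; the phenotypic
#' covariance adds the nonadditive variances on the diagonal:
#' `Paa = Gaa + diag(sigma_v2)` and `Pbb = Gbb + diag(vec(sigma_eta2))`.
#'
#' The defaults are the package's built-in two-trait, two-cue example, in
#' which each trait responds to its own cue only: the cross-trait slope
#' effects `b'_12` and `b'_21` have zero additive and nonadditive variance,
#' so `G` is singular in the full ordering (the BLUP solver handles this by
#' excluding the zero-variance effects).
#'
#' @param Gaa `p` x `p` additive covariance of the intercepts.
#' @param Gab `p` x `pq` additive intercept-slope covariance.
#' @param Gbb `pq` x `pq` additive covariance of the slopes (trait-major).
#' @param sigma_v2 Length-`p` nonadditive intercept variances.
#' @param sigma_eta2 `p` x `q` matrix of nonadditive slope variances.
#'
#' @return An object of class `genetic_params` with elements `p`, `q`, the
#'   blocks above, and derived `G` (full additive covariance), `P` (full
#'   phenotypic covariance), `Paa`, `Pbb`.
#' @export
#' @examples
#' gp <- genetic_params()
#' gp$G
genetic_params <- function(Gaa = matrix(c(0.2, 0.1, 0.1, 0.2), 2),
                           Gab = matrix(0, nrow(Gaa),
                                        nrow(sigma_eta2) * ncol(sigma_eta2)),
                           Gbb = default_Gbb(),
                           sigma_v2 = c(0.2, 0.2),
                           sigma_eta2 = matrix(c(0.05, 0, 0, 0.05), 2,
                                               byrow = TRUE)) {
  Gaa <- as.matrix(Gaa)
  p <- nrow(Gaa)
  sigma_eta2 <- as.matrix(sigma_eta2)
  if (nrow(sigma_eta2) != p) abort("`sigma_eta2` must have p rows.")
  q <- ncol(sigma_eta2)
  Gbb <- as.matrix(Gbb)
  Gab <- as.matrix(Gab)
  if (!all(dim(Gbb) == c(p * q, p * q))) {
    abort(sprintf("`Gbb` must be %d x %d (pq x pq).", p * q, p * q))
  }
  if (!all(dim(Gab) == c(p, p * q))) {
    abort(sprintf("`Gab` must be %d x %d (p x pq).", p, p * q))
  }
  sigma_v2 <- rep_len(as.numeric(sigma_v2), p)
  if (any(sigma_v2 < 0) || any(sigma_eta2 < 0)) {
    abort("nonadditive variances must be nonnegative.")
  }
  G <- rbind(cbind(Gaa, Gab), cbind(t(Gab), Gbb))
  check_psd(G, "G")
  eta_vec <- as.numeric(t(sigma_eta2))     # trait-major vec, cues within trait
  Paa <- Gaa + diag(sigma_v2, nrow = p)
  Pbb <- Gbb + diag(eta_vec, nrow = p * q)
  P <- rbind(cbind(Paa, Gab), cbind(t(Gab), Pbb))
  check_psd(P, "P")
  structure(
    list(p = p, q = q, Gaa = Gaa, Gab = Gab, Gbb = Gbb,
         sigma_v2 = sigma_v2, sigma_eta2 = sigma_eta2,
         G = G, P = P, Paa = Paa, Pbb = Pbb,
         eta_vec = eta_vec, d = p * (1 + q)),
    class = "genetic_params"
  )
}

#' @rdname genetic_params
#' @export
default_Gbb <- function() {
  Gbb <- matrix(0, 4, 4)
  Gbb[1, 1] <- Gbb[4, 4] <- 0.05
  Gbb[1, 4] <- Gbb[4, 1] <- 0.025
  Gbb
}

# names for the trait-major effect ordering: a1..ap, b11..b1q, ..., bp1..bpq
effect_names <- function(p, q) {
  if (q == 0) return(paste0("a", seq_len(p)))
  c(paste0("a", seq_len(p)),
    as.vector(t(outer(seq_len(p), seq_len(q), function(j, k)
      paste0("b", j, k)))))
}

#' Mean reaction-norm parameters
#'
#' The evolving state of the population: mean intercepts `abar` (length
#' `p`) and the `p` x `q` matrix of mean plasticity slopes `Bbar`. The mean
#' trait in environment `u` is `ybar = abar + Bbar %*% u`.
#'
#' @param abar Length-`p` mean intercepts.
#' @param Bbar `p` x `q` matrix of mean slopes.
#' @return An object of class `mean_params`.
#' @export
mean_params <- function(abar = c(0, 0),
                        Bbar = matrix(c(-0.5, 0, 0, -0.5), 2, byrow = TRUE)) {
  abar <- as.numeric(abar)
  Bbar <- as.matrix(Bbar)
  if (nrow(Bbar) != length(abar)) {
    abort("`Bbar` must have one row per element of `abar`.")
  }
  if (!all(is.finite(abar)) || !all(is.finite(Bbar))) {
    abort("mean parameters must be finite.")
  }
  structure(list(abar = abar, Bbar = Bbar,
                 p = length(abar), q = ncol(Bbar)),
            class = "mean_params")
}

#' Mean trait values in a given environment
#'
#' @param mean A [mean_params()].
#' @param u Length-`q` cue vector.
#' @return Length-`p` vector of mean traits `abar + Bbar u`.
#' @export
mean_traits <- function(mean, u) {
  as.numeric(mean$abar + mean$Bbar %*% u)
}

#' Fitness function configuration
#'
#' Gaussian stabilising selection around the fitness peak: expected fitness
#' is `W_max * exp(-||y - theta||^2 / (2 omega2))`, realised as the rounded
#' integer number of descendants (see [fitness_values()]). The defaults
#' (`W_max = 4`, `omega2 = 10`) give integer fitness values from 0 to 4.
#'
#' @param W_max Peak fitness (number of descendants at the optimum).
#' @param omega2 Width of the fitness function, in squared trait units.
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(W_max = 4, omega2 = 10) {
  if (W_max < 1) abort("`W_max` must be >= 1.")
  if (omega2 <= 0) abort("`omega2` must be > 0.")
  structure(list(W_max = W_max, omega2 = omega2), class = "fitness_config")
}

#' Integer fitness values under Gaussian stabilising selection
#'
#' `W_i = round(W_max * exp(-sum_j (y_ji - theta_j)^2 / (2 omega2)))`, with
#' rounding half away from zero, giving integers in `0..W_max` interpreted
#' as numbers of descendants.
#'
#' @param y `n` x `p` phenotype matrix (or length-`p` vector for one
#'   individual).
#' @param theta Length-`p` fitness-peak location.
#' @param fit A [fitness_config()].
#' @return Length-`n` integer vector.
#' @export
fitness_values <- function(y, theta, fit = fitness_config()) {
  y <- rbind(y)  # vector -> 1 x p
  d2 <- rowSums(sweep(y, 2, theta)^2)
  as.integer(round_half_away(fit$W_max * exp(-d2 / (2 * fit$omega2))))
}

#' Relative fitness
#'
#' `w_i = W_i / mean(W)`; the result averages to exactly 1. A population in
#' which every individual has zero fitness is extinct and raises an error.
#'
#' @param W Vector of (absolute) fitness values.
#' @return Numeric vector of relative fitness.
#' @export
relative_fitness <- function(W) {
  if (length(W) < 1) abort("`W` must be nonempty.")
  Wbar <- mean(W)
  if (Wbar <= 0) abort("population extinct: mean fitness is zero.")
  W / Wbar
}

#' Optimal stationary reaction-norm slope
#'
#' In a stationary stochastic environment the mean slope that minimises the
#' expected squared distance between trait and fitness peak,
#' `J = E(y - theta)^2`, is the regression coefficient of the peak on the
#' cue: `cov(u, theta) / var(u)`.
#'
#' @param var_u Stationary variance of the cue (must be positive).
#' @param cov_u_theta Stationary covariance between the cue and the
#'   fitness-peak location.
#' @return The optimal mean slope.
#' @export
#' @examples
#' optimal_slope(0.5, -0.25)  # -0.5
optimal_slope <- function(var_u, cov_u_theta) {
  if (var_u <= 0) abort("`var_u` must be > 0.")
  cov_u_theta / var_u
}

#' Sample additive genetic deviations
#'
#' Draws the `n` x `p(1+q)` matrix of individual additive deviations of the
#' reaction-norm parameters. Columns are jointly distributed with
#' covariance `G` across effects (independent across individuals); when the
#' relatedness matrix is not the identity, each effect column is
#' transformed by the symmetric matrix square root `A_M` of the relatedness
#' matrix, which induces covariance `A` among individuals. All columns are
#' then mean-centred, so realised means are exactly zero. Under a banded
#' high-relatedness structure the transformation plus centring reduces the
#' realised variances below the nominal `G` diagonal (to roughly 75% for
#' the banded matrix at `n = 100`).
#'
#' @param gp A [genetic_params()].
#' @param rel A relatedness object ([identity_relatedness()],
#'   [band_relatedness()] or [relatedness_matrix()]).
#' @param n Number of individuals.
#' @return `n` x `p(1+q)` matrix with effect-name columns.
#' @export
sample_additive <- function(gp, rel, n) {
  stopifnot(inherits(gp, "genetic_params"), inherits(rel, "rel_matrix"))
  if (rel$n != n) abort("`rel` dimension does not match `n`.")
  z <- draw_mvn(n, gp$G)
  if (rel$kind != "identity") {
    z <- rel$A_M %*% z
  }
  z <- scale(z, center = TRUE, scale = FALSE)
  dimnames(z) <- list(NULL, effect_names(gp$p, gp$q))
  attr(z, "scaled:center") <- NULL
  z
}

# draw everything random in a cohort once, so that competing update rules
# can be compared on shared draws
draw_cohort_deviations <- function(gp, rel, n) {
  x_true <- sample_additive(gp, rel, n)
  v <- draw_mvn(n, diag(gp$sigma_v2, nrow = gp$p))
  eta <- draw_mvn(n, diag(gp$eta_vec, nrow = gp$p * gp$q))
  list(x_true = x_true, v = v, eta = eta, n = n)
}

# phenotypes, fitness and relative fitness for given mean parameters and
# pre-drawn deviations
realize_cohort <- function(mean, devs, u, theta, gp,
                           fit = fitness_config()) {
  p <- gp$p; q <- gp$q; n <- devs$n
  a_ind <- sweep(devs$x_true[, seq_len(p), drop = FALSE] + devs$v,
                 2, mean$abar, `+`)
  b_dev <- devs$x_true[, p + seq_len(p * q), drop = FALSE] + devs$eta
  y <- a_ind
  for (j in seq_len(p)) {
    cols <- (j - 1) * q + seq_len(q)
    y[, j] <- y[, j] +
      b_dev[, cols, drop = FALSE] %*% u + sum(mean$Bbar[j, ] * u)
  }
  colnames(y) <- paste0("y", seq_len(p))
  W <- fitness_values(y, theta, fit)
  structure(
    list(n = n, x_true = devs$x_true, v = devs$v, eta = devs$eta,
         y = y, W = W, w = relative_fitness(W),
         u = u, theta = theta, mean = mean),
    class = "cohort"
  )
}

#' Draw one generation of the population
#'
#' Samples a cohort of `n` individuals: additive deviations via
#' [sample_additive()] (optionally relatedness-correlated and
#' mean-centred), iid zero-mean nonadditive intercept and slope deviations
#' (never centred), phenotypes from the linear reaction-norm model
#' `y_j = abar_j + a'_j + v_j + sum_k (Bbar_jk + b'_jk + eta_jk) u_k`, and
#' integer fitness under Gaussian stabilising selection around `theta`.
#'
#' @param mean A [mean_params()].
#' @param gp A [genetic_params()].
#' @param rel A relatedness object.
#' @param u Length-`q` cue vector for the generation.
#' @param theta Length-`p` fitness-peak location.
#' @param fit A [fitness_config()].
#' @param n Number of individuals.
#' @return An object of class `cohort` with elements `x_true` (additive
#'   deviations), `v`, `eta` (nonadditive draws), `y` (phenotypes), `W`
#'   (integer fitness), `w` (relative fitness).
#' @export
make_cohort <- function(mean, gp, rel, u, theta, fit = fitness_config(),
                        n = 100) {
  devs <- draw_cohort_deviations(gp, rel, n)
  realize_cohort(mean, devs, u, theta, gp, fit)
}

#' @exportS3Method tibble::as_tibble
as_tibble.cohort <- function(x, ...) {
  out <- tibble(individual = seq_len(x$n))
  for (j in seq_len(ncol(x$y))) out[[colnames(x$y)[j]]] <- x$y[, j]
  out$W <- x$W
  out$w <- x$w
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> n = %d, %d trait(s); mean fitness %.3f\n",
              x$n, ncol(x$y), mean(x$W)))
  invisible(x)
}
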