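#' Selection covariance
#'
#' Population covariance `sum((w_i - wbar)(v_i - vbar)) / n` between
#' relative fitness and any individual value. The `1/n` (population)
#' normalisation follows the Price-equation convention, in which the
#' covariance is taken over the realised population; every update rule in
#' the package uses this single implementation, so the closed-form
#' identities between rules hold exactly.
#'
#' @param w Length-`n` relative fitness.
#' @param v Length-`n` individual values.
#' @return The population covariance (a scalar).
#' @export
selection_cov <- function(w, v) {
  n <- length(w)
  if (n < 2) abort("selection_cov needs n >= 2.")
  if (length(v) != n) abort("`w` and `v` must have equal length.")
  mean((w - mean(w)) * (v - mean(v)))
}

# selection covariances of w with each column of a matrix
selection_cov_cols <- function(w, m) {
  apply(as.matrix(m), 2, function(v) selection_cov(w, v))
}

new_update_result <- function(delta, method, p, q) {
  delta <- as.numeric(delta)
  names(delta) <- effect_names(p, q)
  structure(list(delta = delta, method = method, p = p, q = q),
            class = "update_result")
}

#' @export
print.update_result <- function(x, ...) {
  cat(sprintf("<update_result> method = %s\n", x$method))
  print(round(x$delta, 6))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.update_result <- function(x, ...) {
  tibble(term = names(x$delta), delta = unname(x$delta), method = x$method)
}

#' Robertson update of the mean reaction-norm parameters
#'
#' The core updating rule: by Robertson's secondary theorem of natural
#' selection, the between-generation change in each mean reaction-norm
#' parameter equals the selection covariance between relative fitness and
#' the BLUP-estimated individual additive deviations of that parameter,
#' `delta_m = cov(w_i, xhat_im)`. The systematic shrinkage of the BLUP
#' random effects (see [shrinkage_variance()]) is exactly what turns
#' phenotypic selection into the correct additive-genetic response.
#'
#' @param fit A [blup_fit()] for the current parent generation.
#' @param w Relative fitness of the same individuals, in the same order.
#' @return An `update_result` with the `p(1+q)` incremental changes.
#' @export
robertson_update <- function(fit, w) {
  stopifnot(inherits(fit, "blup_fit"))
  if (length(w) != fit$n) abort("`w` length must match the fitted cohort.")
  delta <- selection_cov_cols(w, fit$xhat)
  new_update_result(delta, "robertson", fit$p, fit$q)
}

#' Closed-form BLUP update (unrelated population)
#'
#' For `A = I` the Robertson/BLUP update has the closed form
#' \deqn{\Delta = G (Z' R^{-1} Z G + I)^{-1} Z' R^{-1}
#'   \mathrm{cov}(w, y)}
#' with `Z = [I_p | U']` and `R` the per-individual residual covariance in
#' the current environment. Agrees with [robertson_update()] applied to an
#' identity-relatedness BLUP fit for any `n >= 2`.
#'
#' @param u Length-`q` cue vector.
#' @param gp A [genetic_params()].
#' @param w Relative fitness.
#' @param y `n` x `p` phenotype matrix.
#' @return An `update_result`.
#' @export
blup_closed_update <- function(u, gp, w, y) {
  y <- as.matrix(y)
  Zt <- build_incidence(u, gp$p, gp$q, n = 1)$Zt
  Rt <- build_residual(u, gp, n = 1)$Rt
  cw <- selection_cov_cols(w, y)
  ZtRinv <- t(Zt) %*% solve(Rt)
  d <- gp$d
  inner <- ZtRinv %*% Zt %*% gp$G + diag(d)
  delta <- gp$G %*% solve(inner, ZtRinv %*% cw)
  new_update_result(delta, "blup_closed", gp$p, gp$q)
}

#' Selection-gradient (GRAD) update
#'
#' The identifiable form of the multivariate breeder's equation expressed
#' through observable phenotypes:
#' \deqn{\Delta = G Z' P_{yy}^{-1} \mathrm{cov}(w, y)}
#' with the phenotypic covariance in the current environment
#' `Pyy = Paa + Gab U + (Gab U)' + U' Pbb U` (the cross term is
#' symmetrised so `Pyy` is symmetric for nonzero `Gab`). Algebraically
#' identical to [blup_closed_update()] for every `n >= 2`, and to the
#' Robertson/BLUP update when `A = I`; it differs from BLUP when the
#' population is genetically related.
#'
#' @inheritParams blup_closed_update
#' @return An `update_result`.
#' @export
grad_update <- function(u, gp, w, y) {
  y <- as.matrix(y)
  inc <- build_incidence(u, gp$p, gp$q, n = 1)
  GabU <- gp$Gab %*% inc$Ut               # p x p
  Pyy <- gp$Paa + GabU + t(GabU) + t(inc$Ut) %*% gp$Pbb %*% inc$Ut
  cw <- selection_cov_cols(w, y)
  delta <- gp$G %*% t(inc$Zt) %*% solve(Pyy, cw)
  new_update_result(delta, "grad", gp$p, gp$q)
}

#' Multivariate breeder's-equation update (simulation-only)
#'
#' `Delta = G P^{-1} [cov(w, a_i); cov(w, b_i)]` applied to the true
#' individual reaction-norm parameters `a_i = abar + a'_i + v_i`,
#' `b_i = Bbar + b'_i + eta_i`. These individual parameters are not
#' observable in field data (only phenotypes are), so this rule is a
#' simulation-only comparator; for finite `n` it differs from the
#' GRAD/BLUP updates, with the gap shrinking as `n` grows. Effects with
#' zero phenotypic variance are excluded from the `P` solve and get a zero
#' increment.
#'
#' @param gp A [genetic_params()].
#' @param w Relative fitness.
#' @param x_true `n` x `p(1+q)` true additive deviations (from the
#'   simulated cohort).
#' @param v `n` x `p` nonadditive intercept draws.
#' @param eta `n` x `pq` nonadditive slope draws.
#' @return An `update_result`.
#' @export
breeder_update <- function(gp, w, x_true, v, eta) {
  p <- gp$p; q <- gp$q
  z <- cbind(x_true[, seq_len(p), drop = FALSE] + v,
             x_true[, p + seq_len(p * q), drop = FALSE] + eta)
  cw <- selection_cov_cols(w, z)
  act <- which(diag(gp$P) > .dynblup_tol * max(diag(gp$P), 1))
  delta <- numeric(gp$d)
  delta[act] <- gp$G[act, act, drop = FALSE] %*%
    solve(gp$P[act, act, drop = FALSE], cw[act])
  new_update_result(delta, "breeder", p, q)
}

#' @rdname breeder_update
#' @param cohort A `cohort`; convenience wrapper passing its fitness and
#'   stored draws.
#' @export
breeder_update_cohort <- function(cohort, gp) {
  breeder_update(gp, cohort$w, cohort$x_true, cohort$v, cohort$eta)
}

#' Overlapping-generations scaling
#'
#' With surviving parents only a fraction `ft` of a generation are new
#' offspring, and the per-generation change in the mean reaction-norm
#' parameters is reduced accordingly: `delta <- ft * delta`.
#'
#' @param res An `update_result`.
#' @param ft Fraction of new offspring, in `(0, 1]`.
#' @return The scaled `update_result`.
#' @export
overlap_scale <- function(res, ft) {
  stopifnot(inherits(res, "update_result"))
  if (!(is.numeric(ft) && length(ft) == 1 && ft > 0 && ft <= 1)) {
    abort("`ft` must be a single number in (0, 1].")
  }
  res$delta <- res$delta * ft
  res
}

#' Apply an update to the mean reaction-norm parameters
#'
#' Adds the incremental changes (intercepts first, then slopes trait-major)
#' to the current means.
#'
#' @param mean A [mean_params()].
#' @param res An `update_result`.
#' @return The updated `mean_params`.
#' @export
apply_update <- function(mean, res) {
  stopifnot(inherits(mean, "mean_params"), inherits(res, "update_result"))
  p <- mean$p; q <- mean$q
  if (length(res$delta) != p * (1 + q)) {
    abort("update length does not match the mean parameters.")
  }
  mean$abar <- mean$abar + unname(res$delta[seq_len(p)])
  if (q > 0) {
    mean$Bbar <- mean$Bbar +
      matrix(res$delta[p + seq_len(p * q)], nrow = p, byrow = TRUE)
  }
  mean
}

#' BLUP shrinkage of the random-effect variance
#'
#' With diagonal `G` and `P` (and `A = I`) the BLUP estimate of an additive
#' deviation is `ahat' = G/(G + sigma_v2) * (a' + v)`, so its variance is
#' `G^2 / (G + sigma_v2)` — strictly less than the true additive variance
#' whenever `sigma_v2 > 0`. This underestimation is not a defect: it is
#' required for the Robertson update to give the correct response.
#'
#' @param Gjj Additive variance of the effect.
#' @param sigma_vj2 Nonadditive variance of the corresponding deviation.
#' @return The variance of the BLUP-estimated effect.
#' @export
#' @examples
#' shrinkage_variance(0.2, 0.2)  # 0.1
shrinkage_variance <- function(Gjj, sigma_vj2) {
  if (Gjj + sigma_vj2 <= 0) abort("`Gjj + sigma_vj2` must be > 0.")
  Gjj^2 / (Gjj + sigma_vj2)
}
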