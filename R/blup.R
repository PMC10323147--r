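#' Environment-dependent incidence matrices of the reaction-norm mixed model
#'
#' For the linear mixed model `y = X ybar + Ztilde x + e`, builds the
#' per-individual incidence matrix `Zt = [I_p | Ut']` (row `j` carries a 1
#' in intercept column `j` and the current cues in trait `j`'s slope
#' columns), its Kronecker expansion `Ztilde = Zt %x% I_n`, the cue matrix
#' `Ut` and the fixed-effect design `X` (a block of ones per trait). These
#' matrices change with the environment, which is what makes the BLUP model
#' dynamical.
#'
#' @param u Length-`q` cue vector (use `numeric(0)` for `q = 0`, the
#'   no-plasticity case, where `Zt` degenerates to `I_p`).
#' @param p Number of traits.
#' @param q Number of cues.
#' @param n Number of individuals.
#' @return An object of class `incidence_set` with elements `Zt`
#'   (`p` x `p(1+q)`), `Ut` (`pq` x `p`), `Ztilde` (`pn` x `p(1+q)n`), `X`
#'   (`pn` x `p`), and the dimensions.
#' @export
build_incidence <- function(u, p, q, n) {
  u <- as.numeric(u)
  if (length(u) != q) abort("`u` must have length q.")
  if (q > 0) {
    slope_block <- kronecker(diag(p), matrix(u, nrow = 1))  # p x pq
    Zt <- cbind(diag(p), slope_block)
    Ut <- t(slope_block)                                    # pq x p
  } else {
    Zt <- diag(p)
    Ut <- matrix(0, 0, p)
  }
  colnames(Zt) <- effect_names(p, q)
  structure(
    list(Zt = Zt, Ut = Ut,
         Ztilde = kronecker(Zt, diag(n)),
         X = kronecker(diag(p), matrix(1, n, 1)),
         p = p, q = q, n = n),
    class = "incidence_set"
  )
}

#' Environment-dependent residual covariance of the mixed model
#'
#' Because the nonadditive slope deviations enter the phenotype multiplied
#' by the cues, the residual variance per trait is
#' `r_j = sigma_v2_j + sum_k u_k^2 * sigma_eta2_jk`: it grows with the
#' squared cue values. `Rt` is the diagonal `p` x `p` per-individual
#' residual covariance; the full-model residual covariance is
#' `Rtilde = Rt %x% I_n`, stored as its diagonal.
#'
#' @inheritParams build_incidence
#' @param gp A [genetic_params()].
#' @return An object of class `residual_set` with elements `r` (length-`p`
#'   residual variances), `Rt`, `rtilde` (length-`pn` diagonal of
#'   `Rt %x% I_n`, trait-major) and the dimensions.
#' @export
build_residual <- function(u, gp, n) {
  u <- as.numeric(u)
  if (length(u) != gp$q) abort("`u` must have length q.")
  r <- gp$sigma_v2 + as.numeric(gp$sigma_eta2 %*% u^2)
  if (any(r <= 0)) {
    abort(paste0(
      "residual variance r_j <= 0 for trait(s) ",
      paste(which(r <= 0), collapse = ", "),
      "; the model is unidentifiable (increase the nonadditive variances)."
    ))
  }
  structure(
    list(r = r, Rt = diag(r, nrow = gp$p),
         rtilde = rep(r, each = n), p = gp$p, n = n),
    class = "residual_set"
  )
}

#' Kronecker covariance of the random effects
#'
#' `Gtilde = G %x% A`: the covariance of the stacked random-effect vector
#' (effect-major blocks of `n` individuals) combining the effect covariance
#' `G` with the additive genetic relationship matrix `A`.
#'
#' @param gp A [genetic_params()].
#' @param rel A relatedness object.
#' @return A `p(1+q)n` x `p(1+q)n` positive semidefinite matrix.
#' @export
build_gtilde <- function(gp, rel) {
  kronecker(gp$G, rel_A(rel))
}

# indices of random effects with nonzero additive variance; checks that
# dropped effects have identically zero covariance with the rest
active_effects <- function(G, tol = .dynblup_tol) {
  act <- which(diag(G) > tol * max(diag(G), 1))
  drop <- setdiff(seq_len(nrow(G)), act)
  if (length(drop) && any(abs(G[drop, , drop = FALSE]) > tol)) {
    abort("G has zero-variance effects with nonzero covariances; not PSD.")
  }
  act
}

#' Solve Henderson's mixed-model equations
#'
#' The primary BLUP solver: forms and solves the dense symmetric
#' mixed-model equations
#' \deqn{\left[\begin{array}{cc} X'R^{-1}X & X'R^{-1}Z \\
#'   Z'R^{-1}X & Z'R^{-1}Z + G^{-1}\end{array}\right]
#'   \left[\begin{array}{c}\hat{\bar y}\\ \hat x\end{array}\right] =
#'   \left[\begin{array}{c}X'R^{-1}y\\ Z'R^{-1}y\end{array}\right]}
#' for the fixed effects (mean traits) and the per-individual additive
#' random effects. Observations are stacked trait-major (all individuals of
#' trait 1, then trait 2, ...), consistently with `X` and `Ztilde`.
#'
#' Random effects with zero additive variance (singular `G`) are excluded
#' from the system and reported as exact zeros, which is the zero-variance
#' limit of the equations.
#'
#' @param y `n` x `p` phenotype matrix.
#' @param inc An [build_incidence()] object.
#' @param res A [build_residual()] object.
#' @param Gt The random-effect covariance `G %x% A` from [build_gtilde()].
#' @param Gt_inv Optional precomputed inverse of the active block of `Gt`
#'   (used by [blup_fit()] to exploit the Kronecker identity
#'   `(G %x% A)^{-1} = G^{-1} %x% A^{-1}`).
#' @return An object of class `blup_fit` with elements `ybar_hat` (length
#'   `p`) and `xhat` (`n` x `p(1+q)`, effect-name columns).
#' @export
blup_solve <- function(y, inc, res, Gt, Gt_inv = NULL) {
  y <- as.matrix(y)
  n <- inc$n; p <- inc$p; q <- inc$q
  d <- p * (1 + q)
  if (!all(dim(y) == c(n, p))) abort("`y` must be n x p.")
  yv <- as.numeric(y)                    # trait-major stacking
  # active-effect reduction (per-effect blocks of n in Gt)
  Gdiag_blocks <- vapply(seq_len(d), function(m) {
    idx <- (m - 1) * n + 1
    Gt[idx, idx]
  }, numeric(1))
  act <- which(Gdiag_blocks > .dynblup_tol * max(Gdiag_blocks, 1))
  # verify dropped blocks are all-zero in Gt
  blk <- function(m) (m - 1) * n + seq_len(n)
  idx_act <- unlist(lapply(act, blk))
  if (length(idx_act) < d * n) {
    drop_idx <- setdiff(seq_len(d * n), idx_act)
    if (any(Gt[drop_idx, ] != 0)) {
      abort("Gt has zero-variance effect blocks with nonzero covariances.")
    }
  }
  Ga <- Gt[idx_act, idx_act, drop = FALSE]
  Za <- inc$Ztilde[, idx_act, drop = FALSE]
  rinv <- 1 / res$rtilde
  if (is.null(Gt_inv)) {
    Gt_inv <- tryCatch(solve(Ga), error = function(e) {
      abort("G %x% A is singular; supply a positive definite A (or drop zero-variance effects).")
    })
  }
  XtR <- t(inc$X * rinv)                 # p x pn
  ZtR <- t(Za * rinv)                    # dn_act x pn
  M <- rbind(
    cbind(XtR %*% inc$X, XtR %*% Za),
    cbind(ZtR %*% inc$X, ZtR %*% Za + Gt_inv)
  )
  rhs <- c(XtR %*% yv, ZtR %*% yv)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    abort(paste0(
      "mixed-model equations are singular; consider larger nonadditive ",
      "variances or n >= 2 (", conditionMessage(e), ")"
    ))
  })
  ybar_hat <- sol[seq_len(p)]
  xa <- matrix(sol[-seq_len(p)], nrow = n)
  xhat <- matrix(0, n, d, dimnames = list(NULL, effect_names(p, q)))
  xhat[, act] <- xa
  new_blup_fit(ybar_hat, xhat, p, q, solver = "mme")
}

new_blup_fit <- function(ybar_hat, xhat, p, q, solver) {
  structure(
    list(ybar_hat = as.numeric(ybar_hat), xhat = xhat,
         p = p, q = q, n = nrow(xhat), solver = solver),
    class = "blup_fit"
  )
}

#' Fit the dynamical BLUP model to one generation
#'
#' High-level interface: assembles the environment-dependent incidence and
#' residual matrices for the current cues and solves for the mean traits
#' and individual additive deviations. For an unrelated population
#' (`A = I`) the mixed model factorises across individuals — the
#' generalised-least-squares fixed effects are the per-trait sample means
#' and \eqn{\hat x_i = G Z' V_1^{-1} (y_i - \hat{\bar y})} with
#' \eqn{V_1 = Z G Z' + R} the `p` x `p` per-individual phenotypic
#' covariance — so the solve is O(n) and exactly equals the mixed-model
#' equations. For `A != I` the dense Henderson system [blup_solve()] is
#' used, with `(G %x% A)^{-1} = G^{-1} %x% A^{-1}` for stability.
#'
#' @param y `n` x `p` phenotype matrix (or a `cohort`, whose `y` is used).
#' @param gp A [genetic_params()].
#' @param rel A relatedness object describing the parent generation.
#' @param u Length-`q` cue vector.
#' @param solver `"auto"` (factorised path for the identity relatedness,
#'   Henderson otherwise), `"mme"` to force the dense solve, or
#'   `"factorized"` (identity relatedness only).
#' @return A `blup_fit`; see [blup_solve()].
#' @export
#' @examples
#' gp <- genetic_params()
#' coh <- make_cohort(mean_params(), gp, identity_relatedness(50),
#'                    u = c(0.5, 0.1), theta = c(0, 0), n = 50)
#' fit <- blup_fit(coh, gp, identity_relatedness(50), u = c(0.5, 0.1))
#' tidy(fit)
blup_fit <- function(y, gp, rel, u,
                     solver = c("auto", "mme", "factorized")) {
  solver <- match.arg(solver)
  if (inherits(y, "cohort")) y <- y$y
  y <- as.matrix(y)
  n <- nrow(y)
  if (rel$n != n) abort("`rel` dimension does not match nrow(y).")
  if (solver == "auto") {
    solver <- if (rel$kind == "identity") "factorized" else "mme"
  }
  if (solver == "factorized") {
    if (rel$kind != "identity") {
      abort("the factorized solver requires the identity relatedness.")
    }
    return(blup_solve_factorized(y, gp, u))
  }
  inc <- build_incidence(u, gp$p, gp$q, n)
  res <- build_residual(u, gp, n)
  act <- active_effects(gp$G)
  Ga <- gp$G[act, act, drop = FALSE]
  A <- rel_A(rel)
  Gt_inv <- tryCatch(
    kronecker(solve(Ga), solve(A)),
    error = function(e) {
      warn("A (or active G) is singular; using a pseudo-inverse for G %x% A.")
      MASS::ginv(kronecker(Ga, A))
    }
  )
  blup_solve(y, inc, res, build_gtilde(gp, rel), Gt_inv = Gt_inv)
}

# exact per-individual BLUP under A = I (see blup_fit docs)
blup_solve_factorized <- function(y, gp, u) {
  n <- nrow(y); p <- gp$p; q <- gp$q
  Zt <- build_incidence(u, p, q, n = 1)$Zt
  Rt <- build_residual(u, gp, n = 1)$Rt
  V1 <- Zt %*% gp$G %*% t(Zt) + Rt
  ybar_hat <- colMeans(y)
  K <- gp$G %*% t(Zt) %*% solve(V1)      # d x p
  xhat <- sweep(y, 2, ybar_hat) %*% t(K)
  colnames(xhat) <- effect_names(p, q)
  new_blup_fit(ybar_hat, xhat, p, q, solver = "factorized")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("<blup_fit> n = %d, p = %d, q = %d (%s solver)\n",
              x$n, x$p, x$q, x$solver))
  cat("  mean traits:", format(x$ybar_hat, digits = 4), "\n")
  invisible(x)
}

#' Tidy a BLUP fit
#'
#' `tidy()` returns the fixed effects (estimated mean traits) or, with
#' `effects = "random"`, the per-individual random-effect estimates in long
#' form. `glance()` gives a one-row model summary, and `augment()` attaches
#' the random-effect estimates to an individual-level tibble.
#'
#' @param x,object A `blup_fit`.
#' @param effects `"fixed"` or `"random"`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.blup_fit <- function(x, effects = c("fixed", "random"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    tibble(term = paste0("ybar", seq_len(x$p)), estimate = x$ybar_hat)
  } else {
    as_tibble(x$xhat) %>%
      mutate(individual = seq_len(x$n), .before = 1) %>%
      tidyr::pivot_longer(-"individual", names_to = "term",
                          values_to = "estimate")
  }
}

#' @rdname tidy.blup_fit
#' @exportS3Method generics::glance
glance.blup_fit <- function(x, ...) {
  tibble(n = x$n, p = x$p, q = x$q, solver = x$solver,
         n_effects = ncol(x$xhat))
}

#' @rdname tidy.blup_fit
#' @exportS3Method generics::augment
augment.blup_fit <- function(x, ...) {
  out <- tibble(individual = seq_len(x$n))
  dplyr::bind_cols(out, as_tibble(x$xhat))
}
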