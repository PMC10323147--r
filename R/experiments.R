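#' Simulation run configuration
#'
#' Bundles everything a generation-loop run needs. The default is the
#' package's built-in two-trait, two-cue example: `n = 100` individuals, 60
#' generations, ramps starting at generation 10, Gaussian stabilising
#' selection with width 10 and peak fitness 4, and an unrelated population.
#' Unless given, the initial means are `abar = 0` with the stationary
#' optimal slopes `Bbar[j, k] = cov(u_k, theta_j) / var(u_k)` computed from
#' the environment's noise covariance (so the population starts fully
#' adapted to the stationary environment).
#'
#' @param env An [env_config()].
#' @param gp A [genetic_params()].
#' @param fit A [fitness_config()].
#' @param rel `"identity"`, `"band"`, a `rel_matrix`, or a path to a dense
#'   relatedness CSV.
#' @param n Population size (constant across generations).
#' @param methods Subset of `c("robertson", "grad", "breeder")`.
#' @param ft Overlapping-generations fraction in `(0, 1]`.
#' @param init_mean A [mean_params()] or `NULL` for the stationary-optimal
#'   default.
#' @param seed Integer seed for the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(env = env_config(), gp = genetic_params(),
                       fit = fitness_config(), rel = "identity",
                       n = 100, methods = c("robertson", "grad", "breeder"),
                       ft = 1, init_mean = NULL, seed = NULL) {
  stopifnot(inherits(env, "env_config"), inherits(gp, "genetic_params"),
            inherits(fit, "fitness_config"))
  if (env$p != gp$p || env$q != gp$q) {
    abort("`env` and `gp` disagree on the trait/cue dimensions.")
  }
  bad <- setdiff(methods, c("robertson", "grad", "breeder"))
  if (length(bad)) {
    abort(paste0("unknown method(s): ", paste(bad, collapse = ", ")))
  }
  if (!(ft > 0 && ft <= 1)) abort("`ft` must be in (0, 1].")
  if (n < 2) abort("`n` must be >= 2 (selection covariances need n >= 2).")
  if (is.null(init_mean)) init_mean <- stationary_optimal_mean(env)
  stopifnot(inherits(init_mean, "mean_params"))
  structure(
    list(env = env, gp = gp, fit = fit, rel = rel, n = n,
         methods = methods, ft = ft, init_mean = init_mean, seed = seed),
    class = "run_config"
  )
}

#' Stationary-optimal initial mean parameters
#'
#' Zero mean intercepts and, for each trait-cue pair, the slope that
#' minimises the expected squared trait-peak distance in the stationary
#' environment, `cov(u_k, theta_j) / var(u_k)` read off the environment's
#' noise covariance. With the default noise covariance this gives slopes
#' of -0.5 for each trait on its own cue and 0 elsewhere.
#'
#' @param env An [env_config()].
#' @return A [mean_params()].
#' @export
stationary_optimal_mean <- function(env) {
  q <- env$q; p <- env$p
  B <- matrix(0, p, q)
  for (j in seq_len(p)) {
    for (k in seq_len(q)) {
      B[j, k] <- optimal_slope(env$noise_cov[k, k], env$noise_cov[k, q + j])
    }
  }
  mean_params(abar = rep(0, p), Bbar = B)
}

# resolve the rel field of a run_config into a rel_matrix of size n
resolve_rel <- function(rel, n) {
  if (inherits(rel, "rel_matrix")) {
    if (rel$n != n) abort("relatedness matrix size does not match `n`.")
    return(rel)
  }
  if (is.character(rel) && length(rel) == 1) {
    if (rel == "identity") return(identity_relatedness(n))
    if (rel == "band") return(band_relatedness(n))
    if (file.exists(rel)) {
      out <- read_relatedness_csv(rel)
      if (out$n != n) abort("relatedness CSV size does not match `n`.")
      return(out)
    }
    abort(sprintf("unknown relatedness specification '%s'.", rel))
  }
  if (is.matrix(rel)) return(relatedness_matrix(rel))
  abort("`rel` must be 'identity', 'band', a matrix, or a CSV path.")
}

mean_row <- function(mean) {
  p <- mean$p; q <- mean$q
  vals <- c(mean$abar, as.numeric(t(mean$Bbar)))
  setNames(as.list(vals), c(paste0("abar", seq_len(p)),
                            if (q > 0) names_b(p, q)))
}

names_b <- function(p, q) {
  as.vector(t(outer(seq_len(p), seq_len(q),
                    function(j, k) paste0("bbar", j, k))))
}

#' Run the generation loop
#'
#' Simulates `n_gen` generations: each generation a fresh cohort is drawn
#' (additive deviations through the relatedness structure, iid nonadditive
#' deviations), phenotypes and integer fitness are realised in the current
#' environment, and each requested update rule computes its incremental
#' change of the mean reaction-norm parameters, scaled by the
#' overlapping-generations fraction and applied before the next
#' generation. All methods share the same cohort draws within a
#' generation, so their trajectories are directly comparable; only the
#' mean parameters (and hence phenotypes and fitness) differ between
#' methods. Inheritance is carried entirely by the mean parameters —
#' individual deviations are redrawn every generation.
#'
#' The `"robertson"` method fits the dynamical BLUP model to the cohort
#' each generation and applies [robertson_update()]; `"grad"` uses the
#' selection-gradient form [grad_update()]; `"breeder"` uses the
#' simulation-only multivariate breeder's equation [breeder_update()].
#'
#' @param cfg A [run_config()].
#' @param seed Seed for the run; defaults to `cfg$seed`.
#' @param env Optionally, a pre-generated `env_trajectory` to reuse (its
#'   dimensions must match the configuration).
#' @return A tibble of class `rn_trajectory` with one row per generation
#'   and method: `t`, `method`, the environment snapshot (`u*`, `theta*`),
#'   the mean parameters at the start of the generation (`abar*`,
#'   `bbar*`), the mean traits `ybar*` (from the mean parameters and the
#'   current cues), and the realised mean absolute fitness `Wbar`.
#' @export
#' @examples
#' cfg <- run_config(env = env_config(n_gen = 5), n = 40,
#'                   methods = "robertson", seed = 1)
#' run_generation_loop(cfg)
run_generation_loop <- function(cfg, seed = cfg$seed, env = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(env)) env <- make_env_trajectory(cfg$env, seed = NULL)
  u_mat <- env_u_matrix(env)
  th_mat <- env_theta_matrix(env)
  n_gen <- nrow(env)
  rel <- resolve_rel(cfg$rel, cfg$n)
  state <- setNames(rep(list(cfg$init_mean), length(cfg$methods)),
                    cfg$methods)
  rows <- vector("list", n_gen * length(cfg$methods))
  ri <- 0L
  for (t in seq_len(n_gen)) {
    u <- u_mat[t, ]
    theta <- th_mat[t, ]
    devs <- draw_cohort_deviations(cfg$gp, rel, cfg$n)
    for (m in cfg$methods) {
      coh <- realize_cohort(state[[m]], devs, u, theta, cfg$gp, cfg$fit)
      upd <- switch(
        m,
        robertson = robertson_update(
          blup_fit(coh$y, cfg$gp, rel, u), coh$w),
        grad = grad_update(u, cfg$gp, coh$w, coh$y),
        breeder = breeder_update_cohort(coh, cfg$gp)
      )
      upd <- overlap_scale(upd, cfg$ft)
      ri <- ri + 1L
      rows[[ri]] <- c(
        list(t = t, method = m),
        setNames(as.list(u), paste0("u", seq_len(cfg$gp$q))),
        setNames(as.list(theta), paste0("theta", seq_len(cfg$gp$p))),
        mean_row(state[[m]]),
        setNames(as.list(mean_traits(state[[m]], u)),
                 paste0("ybar", seq_len(cfg$gp$p))),
        list(Wbar = mean(coh$W))
      )
      state[[m]] <- apply_update(state[[m]], upd)
    }
  }
  out <- dplyr::bind_rows(lapply(rows, as_tibble))
  structure(out, class = c("rn_trajectory", class(out)),
            config = cfg, seed = seed)
}

# parameter columns of a trajectory
param_cols <- function(traj) {
  grep("^(abar|bbar)", names(traj), value = TRUE)
}

#' Maximum parameter gap between two methods' trajectories
#'
#' The maximum over generations and mean reaction-norm parameters of the
#' absolute difference between two trajectories (or two methods within one
#' combined trajectory). Zero means the methods evolved identically; the
#' BLUP and GRAD rules give a gap at numerical noise level for an
#' unrelated population and a clearly nonzero gap under genetic
#' relatedness.
#'
#' @param trajA,trajB `rn_trajectory` tibbles, or (if `trajB` is a method
#'   name) one combined trajectory and two method names.
#' @return The maximum absolute difference (a scalar).
#' @export
method_gap_summary <- function(trajA, trajB) {
  if (is.character(trajB)) {
    abort("pass two trajectories, or use method_gap(traj, a, b).")
  }
  if (nrow(trajA) != nrow(trajB)) abort("trajectories differ in length.")
  cols <- intersect(param_cols(trajA), param_cols(trajB))
  max(abs(as.matrix(trajA[cols]) - as.matrix(trajB[cols])))
}

#' @rdname method_gap_summary
#' @param traj A combined `rn_trajectory`.
#' @param method_a,method_b Method names present in `traj`.
#' @export
method_gap <- function(traj, method_a, method_b) {
  a <- dplyr::filter(traj, .data$method == method_a) %>% arrange(.data$t)
  b <- dplyr::filter(traj, .data$method == method_b) %>% arrange(.data$t)
  if (nrow(a) == 0 || nrow(b) == 0) abort("method not found in trajectory.")
  method_gap_summary(a, b)
}

#' Overlapping-generations experiment
#'
#' Runs the generation loop once per value of the offspring fraction `ft`,
#' with shared random draws (same seed), and summarises the time-averaged
#' mean fitness per `ft` over the ramp period. Smaller `ft` slows the
#' response to the moving fitness peak, so the population lags further
#' behind and realises lower mean fitness.
#'
#' @param cfg A [run_config()].
#' @param ft_values Offspring fractions to compare.
#' @param seed Seed shared across the runs.
#' @return A list with `trajectories` (combined tibble with an `ft`
#'   column) and `summary` (per-`ft` time-averaged `Wbar` over the ramp
#'   period, i.e. generations at or after the configured ramp start).
#' @export
overlap_experiment <- function(cfg, ft_values = c(1, 0.5),
                               seed = cfg$seed) {
  if (is.null(seed)) seed <- 1L
  runs <- lapply(ft_values, function(f) {
    cfg_f <- cfg
    cfg_f$ft <- f
    run_generation_loop(cfg_f, seed = seed) %>% mutate(ft = f)
  })
  traj <- dplyr::bind_rows(runs)
  summ <- traj %>%
    filter(.data$t >= cfg$env$ramp_start) %>%
    group_by(.data$ft, .data$method) %>%
    summarise(mean_W = mean(.data$Wbar), .groups = "drop")
  list(trajectories = traj, summary = summ)
}

#' Drift of the mean intercept in a stationary environment
#'
#' Runs `reps` independent replicates of the full loop (default: the
#' Robertson/BLUP method alone) in a stationary stochastic environment (no
#' ramps) and reports the across-replicate mean and standard deviation of
#' the total change of the first mean intercept,
#' `abar1(t = n_gen) - abar1(t = 1)`. The spread ("standard error" in the
#' drift sense) is the SD across replicates, not the SD of the mean. Both
#' the cue and fitness-peak noise are re-randomised jointly in every
#' replicate.
#'
#' At very small population sizes a replicate can go extinct (every
#' individual draws zero descendants); such replicates cannot complete the
#' 60 generations and are excluded from the drift statistics, with their
#' count reported. At the default size (`n = 100`) extinction does not
#' occur.
#'
#' @param cfg A [run_config()]; its environment must have zero ramp slopes.
#' @param reps Number of replicates.
#' @param seed Seed for the experiment (per-replicate seeds are drawn from
#'   it).
#' @return A list with `mean_change`, `sd_change`, the per-replicate
#'   `changes` (`NA` for extinct replicates), and `n_extinct`.
#' @export
drift_experiment <- function(cfg, reps = 100, seed = cfg$seed) {
  if (any(cfg$env$cue_ramp_slopes != 0)) {
    abort("drift_experiment requires a stationary environment (zero ramp slopes).")
  }
  if (reps < 2) abort("`reps` must be >= 2.")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  changes <- vapply(seq_len(reps), function(r) {
    tryCatch({
      traj <- run_generation_loop(cfg, seed = rep_seeds[r])
      traj <- dplyr::filter(traj, .data$method == cfg$methods[1])
      traj$abar1[nrow(traj)] - traj$abar1[1]
    }, error = function(e) {
      if (grepl("extinct", conditionMessage(e))) NA_real_ else stop(e)
    })
  }, numeric(1))
  n_extinct <- sum(is.na(changes))
  if (n_extinct > 0) {
    inform(sprintf("%d of %d replicates went extinct and were excluded.",
                   n_extinct, reps))
  }
  list(mean_change = mean(changes, na.rm = TRUE),
       sd_change = sd(changes, na.rm = TRUE),
       changes = changes, n_extinct = n_extinct)
}

#' Environmental drift diagnostic
#'
#' Quantifies how much apparent trend the stationary cue noise alone
#' produces: per replicate, generates the cue series over the configured
#' number of generations (no ramps) and measures the endpoint change of
#' the least-squares line through the first cue
#' ([ls_line_endpoint_change()]); returns the across-replicate mean and
#' SD. The analytic SD is `(T-1) * sqrt(var_u / sum((t - tbar)^2))`.
#'
#' @param cfg A [run_config()] (only its environment block is used); ramp
#'   slopes must be zero.
#' @param reps Number of replicates.
#' @param seed Experiment seed.
#' @return A list with `mean_change`, `sd_change`, and the per-replicate
#'   `changes`.
#' @export
env_drift_diagnostic <- function(cfg, reps = 100, seed = cfg$seed) {
  env_cfg <- if (inherits(cfg, "run_config")) cfg$env else cfg
  stopifnot(inherits(env_cfg, "env_config"))
  if (any(env_cfg$cue_ramp_slopes != 0)) {
    abort("env_drift_diagnostic requires zero ramp slopes.")
  }
  if (!is.null(seed)) set.seed(seed)
  changes <- vapply(seq_len(reps), function(r) {
    env <- make_env_trajectory(env_cfg, seed = NULL)
    ls_line_endpoint_change(env$u1)
  }, numeric(1))
  list(mean_change = mean(changes), sd_change = sd(changes),
       changes = changes)
}

#' Plot a simulation trajectory
#'
#' Mean reaction-norm parameters (and mean traits) against generation, one
#' panel per parameter, coloured by update method.
#'
#' @param object An `rn_trajectory`.
#' @param what `"params"` (default) or `"traits"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rn_trajectory <- function(object, what = c("params", "traits"),
                                   ...) {
  what <- match.arg(what)
  cols <- if (what == "params") param_cols(object) else
    grep("^(ybar|theta)", names(object), value = TRUE)
  long <- object %>%
    select(dplyr::all_of(c("t", "method", cols))) %>%
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "parameter",
                        values_to = "value")
  ggplot(long, aes(x = .data$t, y = .data$value, colour = .data$method)) +
    geom_line() +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "generation", y = NULL)
}

#' Write a trajectory as tidy CSV
#'
#' Long format with columns `t, method, parameter, value`.
#'
#' @param traj An `rn_trajectory`.
#' @param path File path.
#' @return `traj`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  long <- as_tibble(traj) %>%
    tidyr::pivot_longer(-c("t", "method"), names_to = "parameter",
                        values_to = "value")
  readr::write_csv(long, path)
  invisible(traj)
}
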