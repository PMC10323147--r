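#' Environment generator configuration
#'
#' Describes the stochastic environment driving the simulation: `q`
#' environmental cues and `p` fitness-peak locations, each the sum of a
#' deterministic ramp (zero before `ramp_start`, linear after) and jointly
#' normal white noise. Cues are stored as deviations from their reference
#' values, so the reference environment is zero throughout.
#'
#' The default configuration is the package's built-in two-cue, two-trait
#' example: ramps start at generation 10, the mean fitness-peak locations are
#' coupled to the mean cues by theta-bar = -2 u-bar per channel, and the
#' white-noise covariance has cue variances 0.5 and 0.1875, peak variances 2
#' and 1, cue-cue covariance 0.25 and cue-peak covariances -0.25 and
#' -0.09375 (all other cross-covariances zero).
#'
#' @param q Number of environmental cues.
#' @param p Number of phenotypic traits (fitness-peak channels).
#' @param n_gen Number of generations to simulate.
#' @param ramp_start Generation at which the ramps start (1-based); mean cue
#'   deviations are zero for all generations up to and including
#'   `ramp_start`.
#' @param cue_ramp_slopes Length-`q` drift of the mean cue per generation
#'   after `ramp_start`, in cue units.
#' @param theta_coupling `p` x `q` matrix mapping the mean cue deviation to
#'   the mean fitness-peak location.
#' @param noise_cov `(q+p)` x `(q+p)` covariance matrix of the white noise on
#'   `(u, theta)`, cues first.
#' @param seed Optional integer seed stored with the configuration and used
#'   by [make_env_trajectory()] when no seed is passed there.
#'
#' @return An object of class `env_config`.
#' @seealso [make_env_trajectory()], [default_noise_cov()]
#' @export
#' @examples
#' cfg <- env_config()
#' env <- make_env_trajectory(cfg, seed = 1)
#' head(env)
env_config <- function(q = 2, p = 2, n_gen = 60, ramp_start = 10,
                       cue_ramp_slopes = c(0.05, 0.015),
                       theta_coupling = diag(-2, p, q),
                       noise_cov = default_noise_cov(),
                       seed = NULL) {
  if (q < 1 || p < 0) abort("`q` must be >= 1 and `p` >= 0.")
  if (n_gen < 1) abort("`n_gen` must be >= 1.")
  if (ramp_start < 1) abort("`ramp_start` must be >= 1.")
  cue_ramp_slopes <- rep_len(as.numeric(cue_ramp_slopes), q)
  theta_coupling <- as.matrix(theta_coupling)
  if (!all(dim(theta_coupling) == c(p, q))) {
    abort("`theta_coupling` must be a p x q matrix.")
  }
  noise_cov <- as.matrix(noise_cov)
  if (!all(dim(noise_cov) == c(q + p, q + p))) {
    abort(sprintf("`noise_cov` must be %d x %d ((q+p) x (q+p)).",
                  q + p, q + p))
  }
  check_psd(noise_cov, "noise_cov")
  structure(
    list(q = q, p = p, n_gen = n_gen, ramp_start = ramp_start,
         cue_ramp_slopes = cue_ramp_slopes, theta_coupling = theta_coupling,
         noise_cov = noise_cov, seed = seed),
    class = "env_config"
  )
}

#' Default white-noise covariance of cues and fitness peaks
#'
#' The stationary-noise covariance of the built-in two-cue, two-trait
#' example, ordered `(u1, u2, theta1, theta2)`: cue variances 0.5 and
#' 0.1875, peak variances 2 and 1, cov(u1, u2) = 0.25,
#' cov(u1, theta1) = -0.25, cov(u2, theta2) = -0.09375, remaining
#' cross-covariances zero. The negative cue-peak covariances make larger
#' cue values go with lower optimal phenotypes, which is what gives the
#' stationary optimal slopes of -0.5 (see [optimal_slope()]).
#'
#' @return A 4 x 4 covariance matrix.
#' @export
default_noise_cov <- function() {
  S <- diag(c(0.5, 0.1875, 2, 1))
  S[1, 2] <- S[2, 1] <- 0.25
  S[1, 3] <- S[3, 1] <- -0.25
  S[2, 4] <- S[4, 2] <- -0.09375
  dimnames(S) <- rep(list(c("u1", "u2", "theta1", "theta2")), 2)
  S
}

#' Generate a stochastic environment trajectory
#'
#' Draws per-generation cue deviations and fitness-peak locations: a
#' deterministic ramp component (zero mean before `ramp_start`) plus jointly
#' normal white noise across the `q + p` channels. Noise is drawn fresh each
#' generation with no autocorrelation; cue-peak covariances are honoured
#' within a generation through the joint draw.
#'
#' @param cfg An [env_config()].
#' @param seed Integer seed; defaults to `cfg$seed`. `NULL` leaves the RNG
#'   state untouched (the draw then continues the current stream).
#'
#' @return A tibble of class `env_trajectory` with columns `t` (1-based
#'   generation), `u1..uq` and `theta1..thetap`. The configuration is kept
#'   in the `"config"` attribute.
#' @export
make_env_trajectory <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "env_config"))
  if (!is.null(seed)) set.seed(seed)
  tt <- seq_len(cfg$n_gen)
  ramp <- pmax(tt - cfg$ramp_start, 0)
  mu_u <- outer(ramp, cfg$cue_ramp_slopes)                  # n_gen x q
  mu_theta <- mu_u %*% t(cfg$theta_coupling)                # n_gen x p
  noise <- draw_mvn(cfg$n_gen, cfg$noise_cov)
  u <- mu_u + noise[, seq_len(cfg$q), drop = FALSE]
  theta <- mu_theta + noise[, cfg$q + seq_len(cfg$p), drop = FALSE]
  out <- tibble(t = tt)
  for (k in seq_len(cfg$q)) out[[paste0("u", k)]] <- u[, k]
  for (j in seq_len(cfg$p)) out[[paste0("theta", j)]] <- theta[, j]
  structure(out, class = c("env_trajectory", class(out)), config = cfg)
}

# cue / peak matrices from an env_trajectory tibble
env_u_matrix <- function(env) {
  as.matrix(env[grep("^u[0-9]+$", names(env))])
}

env_theta_matrix <- function(env) {
  as.matrix(env[grep("^theta[0-9]+$", names(env))])
}

#' Endpoint change of a least-squares line through a series
#'
#' Fits an ordinary least-squares straight line to `series` against its
#' 1-based index and returns the fitted value at the last index minus the
#' fitted value at the first, i.e. `(T - 1)` times the OLS slope. Used as
#' the drift diagnostic for the environmental cues: in a stationary
#' environment the expected change is zero, but its replicate-to-replicate
#' spread quantifies how much apparent trend pure noise produces.
#'
#' @param series Numeric vector of length at least 2.
#' @return The fitted-line change over the series (a scalar).
#' @export
#' @examples
#' ls_line_endpoint_change(c(1, 2, 3, 4))  # exactly 3
ls_line_endpoint_change <- function(series) {
  n <- length(series)
  if (n < 2) abort("`series` must have length >= 2.")
  idx <- seq_len(n)
  slope <- cov(idx, series) / var(idx)
  (n - 1) * slope
}

#' Write / read an environment trajectory as CSV
#'
#' Plain CSV with header columns `t, u1..uq, theta1..thetap`; generation
#' index is 1-based.
#'
#' @param env An `env_trajectory` tibble.
#' @param path File path.
#' @return `write_env_csv()` returns `env` invisibly; `read_env_csv()`
#'   returns a tibble of class `env_trajectory` (without the generating
#'   configuration attribute).
#' @export
write_env_csv <- function(env, path) {
  readr::write_csv(as_tibble(env), path)
  invisible(env)
}

#' @rdname write_env_csv
#' @export
read_env_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t", "u1")
  if (!all(need %in% names(out))) {
    abort("environment CSV must have at least columns `t` and `u1`.")
  }
  structure(out, class = c("env_trajectory", class(out)))
}

#' Plot an environment trajectory
#'
#' One panel per channel (cues and fitness-peak locations) against
#' generation.
#'
#' @param object An `env_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.env_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"t",
                              names_to = "channel", values_to = "value")
  ggplot(long, aes(x = .data$t, y = .data$value)) +
    geom_line(colour = "steelblue") +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "generation", y = NULL)
}
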