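#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file and returns a fully validated
#' [run_config()], filling the package defaults (the built-in two-trait,
#' two-cue example: `p = q = 2`, `n = 100`, 60 generations, fitness width
#' 10, peak fitness 4) for any absent field. An empty file therefore gives
#' the full default configuration. Validation errors name the offending
#' field.
#'
#' Recognised top-level blocks (all optional): `env` (fields of
#' [env_config()]: `q`, `p`, `n_gen`, `ramp_start`, `cue_ramp_slopes`,
#' `theta_coupling`, `noise_cov`), `genetic` (fields of
#' [genetic_params()]), `fitness` (`W_max`, `omega2`), plus scalar fields
#' `rel`, `n`, `methods`, `ft`, `seed`, and `init_mean` (`abar`, `Bbar`).
#' Matrices are given as lists of rows.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @param seed Optional seed overriding the file's `seed` field.
#' @return A [run_config()].
#' @export
load_config <- function(path, seed = NULL) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found.", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  # YAML 1.1 parses a bare `n:` key as the boolean FALSE; map it back
  if (!("n" %in% names(raw)) && ("FALSE" %in% names(raw))) {
    names(raw)[names(raw) == "FALSE"] <- "n"
  }
  config_from_list(raw, seed = seed)
}

as_config_matrix <- function(x, name) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) return(x)
  if (is.list(x)) {
    out <- tryCatch(do.call(rbind, lapply(x, as.numeric)),
                    error = function(e) NULL)
    if (is.null(out)) abort(sprintf("`%s` must be a matrix (list of rows).",
                                    name))
    return(out)
  }
  if (is.numeric(x)) return(rbind(as.numeric(x)))
  abort(sprintf("`%s` must be a matrix (list of rows).", name))
}

call_with <- function(fn, supplied, allowed, block) {
  bad <- setdiff(names(supplied), allowed)
  if (length(bad)) {
    abort(sprintf("unknown field(s) in `%s`: %s", block,
                  paste(bad, collapse = ", ")))
  }
  do.call(fn, supplied)
}

#' @rdname load_config
#' @param raw A named list with the structure described above.
#' @export
config_from_list <- function(raw, seed = NULL) {
  env_raw <- raw$env %||% list()
  for (nm in c("theta_coupling", "noise_cov")) {
    if (!is.null(env_raw[[nm]])) {
      env_raw[[nm]] <- as_config_matrix(env_raw[[nm]], nm)
    }
  }
  env <- call_with(env_config, env_raw,
                   c("q", "p", "n_gen", "ramp_start", "cue_ramp_slopes",
                     "theta_coupling", "noise_cov", "seed"), "env")
  gp_raw <- raw$genetic %||% list()
  for (nm in c("Gaa", "Gab", "Gbb", "sigma_eta2")) {
    if (!is.null(gp_raw[[nm]])) {
      gp_raw[[nm]] <- as_config_matrix(gp_raw[[nm]], nm)
    }
  }
  gp <- call_with(genetic_params, gp_raw,
                  c("Gaa", "Gab", "Gbb", "sigma_v2", "sigma_eta2"),
                  "genetic")
  fit <- call_with(fitness_config, raw$fitness %||% list(),
                   c("W_max", "omega2"), "fitness")
  init_mean <- NULL
  if (!is.null(raw$init_mean)) {
    init_mean <- mean_params(
      abar = as.numeric(raw$init_mean$abar),
      Bbar = as_config_matrix(raw$init_mean$Bbar, "init_mean$Bbar")
    )
  }
  run_config(
    env = env, gp = gp, fit = fit,
    rel = raw$rel %||% "identity",
    n = raw$n %||% 100,
    methods = raw$methods %||% c("robertson", "grad", "breeder"),
    ft = raw$ft %||% 1,
    init_mean = init_mean,
    seed = seed %||% raw$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a run configuration
#'
#' `config_to_list()` converts a [run_config()] into plain lists (matrices
#' as lists of rows) suitable for YAML/JSON; `write_config()` writes it as
#' YAML. `write_config()` followed by [load_config()] round-trips.
#'
#' @param cfg A [run_config()].
#' @return A named list.
#' @export
config_to_list <- function(cfg) {
  mat2rows <- function(m) lapply(seq_len(nrow(m)), function(i)
    as.numeric(m[i, ]))
  rel <- if (inherits(cfg$rel, "rel_matrix")) cfg$rel$kind else cfg$rel
  list(
    env = list(q = cfg$env$q, p = cfg$env$p, n_gen = cfg$env$n_gen,
               ramp_start = cfg$env$ramp_start,
               cue_ramp_slopes = cfg$env$cue_ramp_slopes,
               theta_coupling = mat2rows(cfg$env$theta_coupling),
               noise_cov = mat2rows(cfg$env$noise_cov)),
    genetic = list(Gaa = mat2rows(cfg$gp$Gaa), Gab = mat2rows(cfg$gp$Gab),
                   Gbb = mat2rows(cfg$gp$Gbb),
                   sigma_v2 = cfg$gp$sigma_v2,
                   sigma_eta2 = mat2rows(cfg$gp$sigma_eta2)),
    fitness = list(W_max = cfg$fit$W_max, omega2 = cfg$fit$omega2),
    rel = rel, n = cfg$n, methods = cfg$methods, ft = cfg$ft,
    init_mean = list(abar = cfg$init_mean$abar,
                     Bbar = mat2rows(cfg$init_mean$Bbar)),
    seed = cfg$seed
  )
}

#' @rdname config_to_list
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(cfg)
}

#' Run a named command
#'
#' The programmatic core of the command-line interface. Commands:
#' `simulate` (generation loop; writes the tidy trajectory CSV), `drift`
#' (stationary-intercept drift experiment), `overlap`
#' (overlapping-generations comparison), `compare` (BLUP-vs-GRAD gap
#' summary), `envcheck` (environmental drift diagnostic). Every command
#' writes a `summary.json` and a `run_log.txt` recording the seed, package
#' version and the fully resolved configuration into `out_dir`.
#'
#' @param command One of `"simulate"`, `"drift"`, `"overlap"`,
#'   `"compare"`, `"envcheck"`.
#' @param config A [run_config()], a path to a YAML/JSON config, or `NULL`
#'   for the defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override (takes precedence over the config
#'   file's seed).
#' @param methods Optional method-selection override.
#' @param ft Optional overlap-fraction override.
#' @param rel Optional relatedness override (`"identity"`, `"band"`, or a
#'   CSV path).
#' @param reps Replicates for `drift`/`envcheck`.
#' @return Invisibly, `0L` on success (errors propagate as conditions).
#' @export
run_command <- function(command = c("simulate", "drift", "overlap",
                                    "compare", "envcheck"),
                        config = NULL, out_dir = ".", seed = NULL,
                        methods = NULL, ft = NULL, rel = NULL,
                        reps = 100) {
  command <- match.arg(command)
  cfg <- if (is.null(config)) {
    run_config(seed = seed)
  } else if (inherits(config, "run_config")) {
    config
  } else {
    load_config(config, seed = seed)
  }
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(methods)) {
    cfg <- run_config(env = cfg$env, gp = cfg$gp, fit = cfg$fit,
                      rel = cfg$rel, n = cfg$n, methods = methods,
                      ft = cfg$ft, init_mean = cfg$init_mean,
                      seed = cfg$seed)
  }
  if (!is.null(ft)) cfg$ft <- ft
  if (!is.null(rel)) cfg$rel <- rel
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  summary <- switch(
    command,
    simulate = {
      traj <- run_generation_loop(cfg)
      write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
      traj %>% group_by(.data$method) %>%
        summarise(mean_W = mean(.data$Wbar),
                  final_abar1 = .data$abar1[which.max(.data$t)],
                  .groups = "drop") %>%
        as.list()
    },
    drift = {
      cfg$env$cue_ramp_slopes[] <- 0
      res <- drift_experiment(cfg, reps = reps)
      list(mean_change = res$mean_change, sd_change = res$sd_change,
           reps = reps)
    },
    overlap = {
      res <- overlap_experiment(cfg)
      write_trajectory_csv(
        dplyr::rename(res$trajectories, method_ft = "method") %>%
          mutate(method = paste0(.data$method_ft, "_ft", .data$ft)) %>%
          select(-"method_ft", -"ft"),
        file.path(out_dir, "trajectory.csv"))
      as.list(res$summary)
    },
    compare = {
      cfg$methods <- c("robertson", "grad")
      traj <- run_generation_loop(cfg)
      write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
      list(max_gap = method_gap(traj, "robertson", "grad"))
    },
    envcheck = {
      cfg$env$cue_ramp_slopes[] <- 0
      res <- env_drift_diagnostic(cfg, reps = reps)
      list(mean_change = res$mean_change, sd_change = res$sd_change,
           reps = reps)
    }
  )
  out <- list(command = command, seed = cfg$seed, summary = summary,
              config = config_to_list(cfg))
  jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("dynblup %s", as.character(utils::packageVersion("dynblup"))),
    sprintf("command: %s", command),
    sprintf("seed: %s", cfg$seed),
    sprintf("runtime_s: %.2f", as.numeric(Sys.time() - t0, units = "secs")),
    "config:",
    yaml::as.yaml(config_to_list(cfg))
  ), file.path(out_dir, "run_log.txt"))
  invisible(0L)
}
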