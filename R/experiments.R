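#' Run a predefined experiment and write its result bundle
#'
#' Drives the simulator and analytic models for one of the named study
#' designs and writes a TSV results table, a JSON metadata record (fully
#' resolved parameters and seed) and a plain-text log to `out_dir`.
#' Results are deterministic given the seed.
#'
#' Available experiment types:
#' * `"force-velocity-curve"` / `"velocity-vs-N"`: replicate-mean cluster
#'   velocity over a grid of motor numbers `N` and forces `f`.
#' * `"bound-distribution"`: time-weighted occupancy histograms of the
#'   number of bound motors, one per window size `M` (scenario A) or for
#'   the variable sequence-preserving window (scenario B).
#' * `"stall-vs-N"`: closed-form processive stall, analytic
#'   non-processive stall and (optionally) the simulated stall per `N`.
#' * `"run-length"`: run-length statistics per `N` at fixed force.
#' * `"furuta-comparison"`: zero-load velocity against motor number for
#'   processive kinesin-1 and non-processive Ncd, using the single-motor
#'   stepping-rate presets for `N = 1` and the multi-motor presets for
#'   `N > 1` (DNA-scaffold assemblies couple motors and slightly lower
#'   the multi-motor rates).
#' * `"pilling-prediction"`: velocity and run-length distributions of
#'   weakly non-processive axonal kinesin-1 under load, per candidate
#'   motor number, for comparison with mitochondrial tracking data.
#'
#' @param config A named list, or the path to a YAML file holding one,
#'   with at least `experiment` and either `preset` (a [motor_preset()]
#'   name) or `params` (a named list of [motor_params()] arguments).
#'   Optional entries: `N` (vector), `f` (vector), `M` (vector or
#'   scalar), `scenario`, `dt`, `n_steps`, `burn_in`, `n_runs`, `seed`,
#'   `simulate` (logical, `"stall-vs-N"` only), `engine`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, an object of class `motor_experiment`: a list with
#'   the results `table`, resolved `metadata` and output `files`.
#' @examples
#' \donttest{
#' cfg <- list(experiment = "force-velocity-curve",
#'             preset = "kinesin1-processive", N = 2, f = c(0, 2),
#'             n_steps = 2e4, burn_in = 1000, n_runs = 4, seed = 7)
#' res <- run_experiment(cfg, out_dir = tempfile("mlx"))
#' res$table
#' }
#' @export
run_experiment <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot("config must be a named list" = is.list(config))
  types <- c("force-velocity-curve", "velocity-vs-N", "bound-distribution",
             "stall-vs-N", "run-length", "furuta-comparison",
             "pilling-prediction")
  if (is.null(config$experiment) || !(config$experiment %in% types)) {
    stop("unknown experiment '", config$experiment,
         "'; available experiments: ", paste(types, collapse = ", "),
         call. = FALSE)
  }
  params <- resolve_params(config)
  defaults <- list(N = 1:5, f = 0, M = NA, scenario = NULL, dt = 1e-3,
                   n_steps = NULL, burn_in = NULL, n_runs = 100, seed = 1,
                   simulate = FALSE, engine = "fixed")
  cfg <- modifyList(defaults, config[setdiff(names(config),
                                             c("experiment", "preset",
                                               "params"))])
  if (is.null(cfg$scenario)) {
    cfg$scenario <- if (is_processive(params)) "processive" else "B"
  }
  if (length(cfg$f) == 0) {
    stop("empty force grid", call. = FALSE)
  }

  table <- switch(
    config$experiment,
    "force-velocity-curve" = ,
    "velocity-vs-N" = exp_velocity_grid(params, cfg),
    "bound-distribution" = exp_bound_distribution(params, cfg),
    "stall-vs-N" = exp_stall_vs_n(params, cfg),
    "run-length" = exp_run_length(params, cfg),
    "furuta-comparison" = exp_furuta(cfg),
    "pilling-prediction" = exp_pilling(cfg)
  )

  metadata <- list(
    experiment = config$experiment,
    params = unclass(params),
    controls = cfg[c("N", "f", "M", "scenario", "dt", "n_steps", "burn_in",
                     "n_runs", "seed", "engine")],
    package_version = as.character(utils::packageVersion("motorlattice")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(out_dir, config$experiment)
  files <- c(table = paste0(stem, "-results.tsv"),
             metadata = paste0(stem, "-metadata.json"),
             log = paste0(stem, ".log"))
  write.table(table, files[["table"]], sep = "\t", quote = FALSE,
              row.names = FALSE, dec = ".")
  jsonlite::write_json(metadata, files[["metadata"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(sprintf("experiment: %s", config$experiment),
               sprintf("rows: %d", nrow(table)),
               sprintf("seed: %d", as.integer(cfg$seed)),
               sprintf("written: %s", metadata$timestamp)),
             files[["log"]])

  out <- structure(list(table = table, metadata = metadata, files = files),
                   class = "motor_experiment")
  invisible(out)
}

#' @export
print.motor_experiment <- function(x, ...) {
  cat(sprintf("Experiment '%s' (%d result rows)\n",
              x$metadata$experiment, nrow(x$table)))
  cat("  files:", paste(basename(unname(x$files)), collapse = ", "), "\n")
  invisible(x)
}

resolve_params <- function(config) {
  if (!is.null(config$preset)) {
    motor_preset(config$preset)
  } else if (!is.null(config$params)) {
    do.call(motor_params, config$params)
  } else {
    stop("config must name a 'preset' or give explicit 'params'",
         call. = FALSE)
  }
}

make_cfg <- function(cfg, scenario, N, f, M = NA, seed_offset = 0L) {
  sim_config(scenario = scenario, N = N, f = f, dt = cfg$dt,
             n_steps = cfg$n_steps, burn_in = cfg$burn_in,
             n_runs = cfg$n_runs,
             seed = (cfg$seed + seed_offset) %% (.Machine$integer.max - 1L),
             M = if (is.na(M)) NULL else M)
}

exp_velocity_grid <- function(params, cfg) {
  grid <- expand.grid(N = cfg$N, f = cfg$f)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    N <- grid$N[i]; f <- grid$f[i]
    sim <- simulate_cluster(
      make_cfg(cfg, cfg$scenario, N, f,
               M = if (cfg$scenario == "A") cfg$M[1] else NA,
               seed_offset = i),
      params, engine = cfg$engine, keep_raw = FALSE)
    v <- cluster_velocity(sim)
    data.frame(N = N, f = f, velocity = v[["mean"]], sd = v[["sd"]],
               se = v[["se"]],
               velocity_um_s = v[["mean"]] * params$dx / 1000)
  })
  do.call(rbind, rows)
}

exp_bound_distribution <- function(params, cfg) {
  Ms <- if (cfg$scenario == "A") cfg$M else NA
  rows <- lapply(seq_along(Ms), function(i) {
    sim <- simulate_cluster(
      make_cfg(cfg, cfg$scenario, cfg$N[1], cfg$f[1], M = Ms[i],
               seed_offset = i),
      params, engine = cfg$engine, keep_raw = FALSE)
    occ <- occupancy_distribution(sim)
    occ$N <- cfg$N[1]
    occ$M <- if (is.na(Ms[i])) mean(sim$replicates$mean_window) else Ms[i]
    occ[, c("N", "M", "n", "prob", "se")]
  })
  do.call(rbind, rows)
}

exp_stall_vs_n <- function(params, cfg) {
  rows <- lapply(seq_along(cfg$N), function(i) {
    N <- cfg$N[i]
    f_proc <- stall_force(params, N, processive = TRUE)
    f_ana <- if (params$k_on > 0) {
      stall_force(params, N, processive = FALSE)
    } else NA_real_
    f_sim <- NA_real_
    if (isTRUE(cfg$simulate)) {
      grid <- seq(0, f_proc, length.out = 8)
      est <- estimate_stall_force(params, make_cfg(cfg, cfg$scenario, N, 0,
                                                   seed_offset = i),
                                  f_grid = grid)
      f_sim <- est$f_stall
    }
    data.frame(N = N, stall_processive = f_proc,
               stall_analytic_nonprocessive = f_ana,
               stall_simulated = f_sim)
  })
  do.call(rbind, rows)
}

exp_run_length <- function(params, cfg) {
  rows <- lapply(seq_along(cfg$N), function(i) {
    sim <- simulate_cluster(make_cfg(cfg, cfg$scenario, cfg$N[i], cfg$f[1],
                                     seed_offset = i),
                            params, engine = cfg$engine)
    rl <- run_length_stats(sim)
    data.frame(N = cfg$N[i], f = cfg$f[1], mean_run_length = rl$mean,
               sd = rl$sd, se = rl$se, frac_negative = rl$frac_negative,
               n_runs_observed = rl$n,
               mean_run_length_um = rl$mean * params$dx / 1000)
  })
  do.call(rbind, rows)
}

# Zero-load velocity vs motor number for kinesin-1 and Ncd assemblies;
# single motors use their own stepping-rate presets.
exp_furuta <- function(cfg) {
  species <- list(
    kinesin1 = list(single = "kinesin1-single",
                    multi = "kinesin1-processive", scenario = "processive"),
    ncd = list(single = "ncd-single", multi = "ncd", scenario = "B")
  )
  rows <- list()
  for (sp in names(species)) {
    info <- species[[sp]]
    for (N in cfg$N) {
      pr <- motor_preset(if (N == 1) info$single else info$multi)
      if (N == 1 && sp == "ncd") {
        # lone Ncd detaches and re-attaches with the same kinetics
        pr$k_on <- motor_preset(info$multi)$k_on
        pr$k_off <- motor_preset(info$multi)$k_off
      }
      scen <- if (is_processive(pr)) "processive" else info$scenario
      sim <- simulate_cluster(make_cfg(cfg, scen, N, 0,
                                       seed_offset = N + 100L * match(
                                         sp, names(species))),
                              pr, engine = cfg$engine, keep_raw = FALSE)
      v <- cluster_velocity(sim, units = "um")
      v_ana <- if (is_processive(pr)) {
        leading_motor_velocity(pr, 0, N) * pr$dx / 1000
      } else {
        average_cluster_velocity(pr, 0, N) * pr$dx / 1000
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, N = N, velocity_um_s = v[["mean"]], sd = v[["sd"]],
        se = v[["se"]], analytic_um_s = v_ana)
    }
  }
  do.call(rbind, rows)
}

# Velocity and run-length summaries for axonal kinesin-1 under load f = 2,
# per candidate motor number.
exp_pilling <- function(cfg) {
  pr <- motor_preset("kinesin1-axonal")
  f <- if (identical(cfg$f, 0)) 2 else cfg$f[1]
  rows <- lapply(seq_along(cfg$N), function(i) {
    sim <- simulate_cluster(make_cfg(cfg, "B", cfg$N[i], f, seed_offset = i),
                            pr, engine = cfg$engine)
    v <- cluster_velocity(sim, units = "um")
    rl <- run_length_stats(sim, units = "um")
    ep <- do.call(rbind, sim$episode_velocities)
    v_sd <- if (!is.null(ep) && nrow(ep) > 1) {
      vw <- ep$velocity * pr$dx / 1000
      m <- sum(vw * ep$duration) / sum(ep$duration)
      sqrt(sum(ep$duration * (vw - m)^2) / sum(ep$duration))
    } else NA_real_
    data.frame(N = cfg$N[i], f = f,
               velocity_um_s = v[["mean"]],
               velocity_sd = v_sd,
               run_length_um = rl$mean, run_length_sd = rl$sd,
               frac_negative_runs = rl$frac_negative)
  })
  do.call(rbind, rows)
}

#' Overlay analytic predictions on simulated results
#'
#' Appends the analytic velocity and a z-score
#' `(simulated - analytic) / se` to a velocity table produced by
#' [run_experiment()] (experiment types `"force-velocity-curve"` or
#' `"velocity-vs-N"`).
#'
#' @param experiment A `motor_experiment` object (or a results data frame
#'   with columns `N`, `f`, `velocity`, `se` plus a `params` attribute).
#' @param model `"leading_motor"` for the bound-cluster force-velocity
#'   relation (processive runs), `"unlimited"` or `"limited"` for the
#'   binding-averaged velocity of non-processive motors; `"limited"`
#'   requires an `M` entry in the experiment controls.
#' @param M Binding-site limit for `model = "limited"`; defaults to the
#'   experiment's `M` control.
#' @return The annotated table with columns `analytic` and `z`.
#' @export
compare_to_analytic <- function(experiment,
                                model = c("leading_motor", "unlimited",
                                          "limited"),
                                M = NULL) {
  model <- match.arg(model)
  if (inherits(experiment, "motor_experiment")) {
    table <- experiment$table
    params <- do.call(motor_params, experiment$metadata$params)
    if (is.null(M)) {
      M_ctl <- experiment$metadata$controls$M
      if (!is.null(M_ctl) && !all(is.na(M_ctl))) M <- M_ctl[1]
    }
  } else {
    table <- experiment
    params <- attr(experiment, "params")
    if (is.null(params)) {
      stop("experiment lacks parameter metadata", call. = FALSE)
    }
  }
  if (nrow(table) == 0) {
    table$analytic <- numeric(0)
    table$z <- numeric(0)
    return(table)
  }
  stopifnot("table must have N, f, velocity, se columns" =
              all(c("N", "f", "velocity", "se") %in% names(table)))
  if (model != "leading_motor" && params$k_on == 0) {
    stop("binding-averaged models require k_on > 0; the experiment was ",
         "parameterized as processive", call. = FALSE)
  }
  if (model == "limited" && is.null(M)) {
    stop("model 'limited' needs a binding-site limit M", call. = FALSE)
  }
  table$analytic <- vapply(seq_len(nrow(table)), function(i) {
    switch(model,
           leading_motor = leading_motor_velocity(params, table$f[i],
                                                  table$N[i]),
           unlimited = average_cluster_velocity(params, table$f[i],
                                                table$N[i]),
           limited = average_cluster_velocity(params, table$f[i],
                                              table$N[i], M = M))
  }, numeric(1))
  table$z <- (table$velocity - table$analytic) / table$se
  table
}

#' Infer the number of motors from observed transport statistics
#'
#' Simulates candidate motor numbers and ranks them by agreement with an
#' observed (velocity, run length) pair, scoring each candidate by the
#' sum of squared z-distances scaled by the observed standard deviations.
#'
#' @param velocity Observed velocity as `c(mean, sd)` in um/s.
#' @param run_length Observed run length as `c(mean, sd)` in um.
#' @param candidates Candidate motor numbers (within 1..20).
#' @param params A [motor_params()] object for the motor species (e.g.
#'   `motor_preset("kinesin1-axonal")`).
#' @param f Dimensionless load used in the simulations (default 2).
#' @param n_steps,burn_in,n_runs,dt,seed Simulation controls (see
#'   [sim_config()]).
#' @return A data frame ranked by score: columns `N`, `velocity_um_s`,
#'   `run_length_um`, `z2` and `rank`. The best candidate is row 1.
#' @examples
#' \donttest{
#' infer_motor_number(c(0.26, 0.10), c(1.82, 1.19), candidates = 2:4,
#'                    params = motor_preset("kinesin1-axonal"),
#'                    n_steps = 2e5, n_runs = 4, seed = 1)
#' }
#' @export
infer_motor_number <- function(velocity, run_length, candidates, params,
                               f = 2, n_steps = NULL, burn_in = NULL,
                               n_runs = 20, dt = 1e-3, seed = 1) {
  stopifnot(
    "velocity must be c(mean, sd) with sd > 0" =
      is.numeric(velocity) && length(velocity) == 2L && velocity[2] > 0,
    "run_length must be c(mean, sd) with sd > 0" =
      is.numeric(run_length) && length(run_length) == 2L && run_length[2] > 0,
    "candidates must lie within 1..20" =
      is.numeric(candidates) && length(candidates) >= 1 &&
        all(candidates >= 1 & candidates <= 20),
    inherits(params, "motor_params")
  )
  rows <- lapply(seq_along(candidates), function(i) {
    N <- candidates[i]
    cfg <- sim_config("B", N = N, f = f, dt = dt, n_steps = n_steps,
                      burn_in = burn_in, n_runs = n_runs,
                      seed = (seed + i) %% (.Machine$integer.max - 1L))
    sim <- simulate_cluster(cfg, params)
    v <- cluster_velocity(sim, units = "um")
    rl <- run_length_stats(sim, units = "um")
    if (!is.na(v[["sd"]]) && v[["sd"]] == 0) {
      warning("candidate N = ", N,
              " excluded: degenerate simulated velocity (sd = 0)",
              call. = FALSE)
      return(NULL)
    }
    z2 <- ((v[["mean"]] - velocity[1]) / velocity[2])^2 +
      ((rl$mean - run_length[1]) / run_length[2])^2
    data.frame(N = N, velocity_um_s = v[["mean"]], velocity_sd = v[["sd"]],
               run_length_um = rl$mean, run_length_sd = rl$sd, z2 = z2)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    stop("all candidates were excluded", call. = FALSE)
  }
  out <- out[order(out$z2), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
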