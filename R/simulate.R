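#' Simulation controls for the lattice Monte Carlo engines
#'
#' @param scenario `"processive"` (motors never unbind; all bound from the
#'   start), `"A"` (binding restricted to a fixed window of `M` sites whose
#'   left edge tracks the rearmost bound motor; rebinding motors may swap
#'   positions) or `"B"` (binding window follows the bound cluster plus one
#'   site beyond each end and the motor sequence is preserved on
#'   rebinding).
#' @param N Total number of motors attached to the cargo.
#' @param f Dimensionless load force.
#' @param dt Time step (s). The default `1e-3` s keeps every transition
#'   probability well below 1 for the built-in presets at moderate loads.
#' @param n_steps Total number of time steps. Defaults: `5e6` for
#'   processive runs, `5e7` for non-processive runs.
#' @param burn_in Steps discarded before measurement. Defaults: `1000`
#'   (processive), `2500` (non-processive, `N <= 10`), `25000` (`N > 10`).
#' @param n_runs Number of independent replicates (default 100).
#' @param seed Integer seed for the root random stream; each replicate
#'   draws its own sub-seed from it.
#' @param M Window size in sites for scenario `"A"` (ignored otherwise).
#' @return An object of class `sim_config`.
#' @examples
#' sim_config("B", N = 3, f = 2, n_steps = 1e5, n_runs = 4, seed = 1)
#' @export
sim_config <- function(scenario = c("processive", "A", "B"), N, f = 0,
                       dt = 1e-3, n_steps = NULL, burn_in = NULL,
                       n_runs = 100, seed = 1, M = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(
    "N must be a positive count" =
      is.numeric(N) && length(N) == 1L && N >= 1 && N == floor(N),
    "f must be a single finite number" =
      is.numeric(f) && length(f) == 1L && is.finite(f),
    "dt must be positive" = is.numeric(dt) && length(dt) == 1L && dt > 0,
    "n_runs must be a positive count" =
      is.numeric(n_runs) && length(n_runs) == 1L && n_runs >= 1,
    "seed must be a single integer" =
      is.numeric(seed) && length(seed) == 1L && is.finite(seed)
  )
  if (is.null(n_steps)) {
    n_steps <- if (scenario == "processive") 5e6 else 5e7
  }
  if (is.null(burn_in)) {
    burn_in <- if (scenario == "processive") 1000
               else if (N <= 10) 2500 else 25000
  }
  stopifnot(
    "n_steps must be positive" = n_steps >= 1,
    "burn_in must be smaller than n_steps" =
      burn_in >= 0 && burn_in < n_steps
  )
  if (scenario == "A") {
    if (is.null(M) || !is.numeric(M) || length(M) != 1L || M < 1 ||
        M != floor(M)) {
      stop("scenario A requires a fixed window size M >= 1", call. = FALSE)
    }
  } else {
    M <- NA_integer_
  }
  structure(
    list(scenario = scenario, N = as.integer(N), f = f, dt = dt,
         n_steps = n_steps, burn_in = burn_in, n_runs = as.integer(n_runs),
         seed = as.integer(seed), M = M),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: scenario %s, N = %d, f = %g\n",
              x$scenario, x$N, x$f))
  cat(sprintf("  dt = %g s, %g steps (burn-in %g), %d replicates, seed %d\n",
              x$dt, x$n_steps, x$burn_in, x$n_runs, x$seed))
  if (x$scenario == "A") cat(sprintf("  binding window M = %d sites\n", x$M))
  invisible(x)
}

scenario_code <- function(scenario) {
  match(scenario, c("processive", "A", "B")) - 1L
}

# Transition-probability sanity check: first-order discretization bias is
# negligible for max(rate)*dt <= 0.1; above 1 the probabilities are invalid.
check_dt <- function(params, config) {
  rates <- leading_motor_rates(params, config$f)
  r_max <- max(params$p, params$q, params$k_on, params$k_off,
               rates$p1, rates$q1)
  if (r_max * config$dt > 1) {
    stop(sprintf(paste0("dt too large: max rate x dt = %.3g > 1 is not a ",
                        "probability; reduce dt"), r_max * config$dt),
         call. = FALSE)
  }
  if (r_max * config$dt > 0.1) {
    warning(sprintf(paste0("max rate x dt = %.3g > 0.1: fixed-step ",
                           "discretization bias may be noticeable"),
                    r_max * config$dt), call. = FALSE)
  }
  invisible(r_max * config$dt)
}

#' Initial lattice state
#'
#' Builds the starting state of a run. Processive runs place the `N`
#' motors, all bound, at distinct uniformly sampled sites within the
#' initial cargo width (10 sites for `N < 10`, `N + 10` sites for
#' `N >= 10`); results are insensitive to this width. Non-processive runs
#' start with every motor unbound and a binding window anchored at the
#' origin (`M` sites for scenario A; three sites, the nucleation site plus
#' one on each side, for scenario B).
#'
#' @param config A [sim_config()] object.
#' @param params A [motor_params()] object (only used for validation).
#' @return A `lattice_state` list with `positions`, `bound` and `window`.
#' @examples
#' st <- lattice_init(sim_config("processive", N = 2, n_steps = 10,
#'                               burn_in = 0, seed = 1),
#'                    motor_preset("kinesin1-processive"))
#' @export
lattice_init <- function(config, params) {
  stopifnot(inherits(config, "sim_config"), inherits(params, "motor_params"))
  N <- config$N
  if (config$scenario == "processive") {
    width <- if (N < 10) 10L else N + 10L
    if (N > width) {
      stop("N exceeds the initial cargo width", call. = FALSE)
    }
    positions <- sort(sample.int(width, N)) - 1L
    bound <- rep(TRUE, N)
    window <- c(min(positions), max(positions))
  } else {
    positions <- rep(0L, N)
    bound <- rep(FALSE, N)
    window <- if (config$scenario == "A") c(0L, config$M - 1L) else c(-1L, 1L)
  }
  structure(list(positions = positions, bound = bound, window = window,
                 scenario = config$scenario, N = N),
            class = "lattice_state")
}

#' Advance a lattice state by a fixed number of time steps
#'
#' Low-level access to the fixed time-step kernel, mainly for inspecting
#' the dynamics step by step: returns the updated state together with the
#' full per-step history of positions and bound flags.
#'
#' @param state A `lattice_state` from [lattice_init()] (or a previous
#'   call).
#' @param config,params As in [simulate_cluster()].
#' @param n Number of steps to advance.
#' @return The updated `lattice_state`; attributes `pos_hist` and
#'   `bound_hist` hold the `n x N` per-step history.
#' @export
lattice_steps <- function(state, config, params, n = 1) {
  stopifnot(inherits(state, "lattice_state"), n >= 1)
  check_dt(params, config)
  res <- .run_fixed_cpp(
    N = config$N, p = params$p, q = params$q, delta = params$delta,
    kon = params$k_on, koff = params$k_off, f = config$f, dt = config$dt,
    n_steps = n, burn_in = 0, scenario = scenario_code(config$scenario),
    M_fixed = if (is.na(config$M)) 0L else config$M,
    init_pos = as.integer(state$positions), init_bound = state$bound,
    record_states = TRUE
  )
  out <- structure(
    list(positions = res$positions, bound = res$bound, window = res$window,
         scenario = config$scenario, N = config$N),
    class = "lattice_state"
  )
  attr(out, "pos_hist") <- res$pos_hist
  attr(out, "bound_hist") <- res$bound_hist
  out
}

#' Simulate a motor cluster
#'
#' Runs `config$n_runs` independent replicates of the configured process
#' with the chosen engine and collects the observables: per-replicate mean
#' episode velocity of the leading motor (an episode is one motor's tenure
#' as the forwardmost bound motor), the end-to-end steady-state velocity
#' (processive runs), the time-weighted occupancy histogram of the number
#' of bound motors, signed cargo run lengths (displacement between first
#' attachment and complete detachment), and the time-averaged binding
#' window size.
#'
#' All velocities are in lattice steps per second and displacements in
#' sites; multiply by `params$dx` (nm) for physical units, or use
#' [cluster_velocity()] / [run_length_stats()] which do so on request.
#'
#' @param config A [sim_config()] object.
#' @param params A [motor_params()] object.
#' @param engine `"fixed"` for the fixed time-step Monte Carlo kernel
#'   (default; the production engine) or `"gillespie"` for the exact
#'   event-driven sampler used as a correctness oracle. With
#'   `"gillespie"`, `n_steps` and `burn_in` are interpreted through
#'   `n_steps * dt` seconds of simulated time.
#' @param keep_raw Keep the per-replicate vectors of episode velocities
#'   and run lengths (default `TRUE`; set `FALSE` to save memory on long
#'   runs).
#' @return An object of class `motor_sim`.
#' @examples
#' cfg <- sim_config("processive", N = 2, f = 2, n_steps = 2e4,
#'                   burn_in = 1000, n_runs = 4, seed = 42)
#' sim <- simulate_cluster(cfg, motor_preset("kinesin1-processive"))
#' cluster_velocity(sim)
#' @export
simulate_cluster <- function(config, params,
                             engine = c("fixed", "gillespie"),
                             keep_raw = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(params, "motor_params"))
  engine <- match.arg(engine)
  if (config$scenario != "processive" &&
      params$k_on == 0 && params$k_off == 0) {
    warning("non-processive scenario with k_on = k_off = 0: ",
            "no motor will ever bind", call. = FALSE)
  }
  check_dt(params, config)

  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_runs)

  n_rep <- config$n_runs
  rep_stats <- vector("list", n_rep)
  occupancy <- matrix(NA_real_, n_rep, config$N + 1L,
                      dimnames = list(NULL, paste0("P", 0:config$N)))
  ep_list <- if (keep_raw) vector("list", n_rep)
  rl_list <- if (keep_raw) vector("list", n_rep)

  for (i in seq_len(n_rep)) {
    set.seed(rep_seeds[i])
    state <- lattice_init(config, params)
    res <- if (engine == "fixed") {
      .run_fixed_cpp(
        N = config$N, p = params$p, q = params$q, delta = params$delta,
        kon = params$k_on, koff = params$k_off, f = config$f,
        dt = config$dt, n_steps = config$n_steps, burn_in = config$burn_in,
        scenario = scenario_code(config$scenario),
        M_fixed = if (is.na(config$M)) 0L else config$M,
        init_pos = as.integer(state$positions), init_bound = state$bound,
        record_states = FALSE
      )
    } else {
      .run_gillespie_cpp(
        N = config$N, p = params$p, q = params$q, delta = params$delta,
        kon = params$k_on, koff = params$k_off, f = config$f,
        total_time = config$n_steps * config$dt,
        burn_in_time = config$burn_in * config$dt,
        scenario = scenario_code(config$scenario),
        M_fixed = if (is.na(config$M)) 0L else config$M,
        init_pos = as.integer(state$positions), init_bound = state$bound,
        record_events = FALSE
      )
    }
    w <- res$occupancy_weights
    occupancy[i, ] <- if (sum(w) > 0) w / sum(w) else NA_real_
    ev <- res$episode_velocities
    ew <- res$episode_durations
    rl <- res$run_lengths
    rep_stats[[i]] <- data.frame(
      run = i,
      seed = rep_seeds[i],
      steady_state_velocity = res$steady_state_velocity,
      n_episodes = length(ev),
      episode_velocity = if (length(ev)) sum(ev * ew) / sum(ew) else NA_real_,
      episode_velocity_unweighted = if (length(ev)) mean(ev) else NA_real_,
      n_runs_completed = length(rl),
      mean_run_length = if (length(rl)) mean(rl) else NA_real_,
      mean_window = res$mean_window
    )
    if (keep_raw) {
      ep_list[[i]] <- data.frame(velocity = ev, duration = ew)
      rl_list[[i]] <- rl
    }
  }

  structure(
    list(config = config, params = params, engine = engine,
         replicates = do.call(rbind, rep_stats),
         occupancy = occupancy,
         episode_velocities = ep_list,
         run_lengths = rl_list),
    class = "motor_sim"
  )
}

#' @export
print.motor_sim <- function(x, ...) {
  v <- cluster_velocity(x)
  cat(sprintf("Motor cluster simulation (%s engine)\n", x$engine))
  print(x$config)
  cat(sprintf("  velocity: %.4g +/- %.3g steps/s (replicate mean +/- sd; %s)\n",
              v[["mean"]], v[["sd"]],
              if (x$config$scenario == "processive") "end-to-end"
              else "episode average"))
  rl <- x$replicates$mean_run_length
  if (any(!is.na(rl))) {
    cat(sprintf("  run length: %.4g sites (mean over replicates)\n",
                mean(rl, na.rm = TRUE)))
  }
  invisible(x)
}

#' Replicate-level velocity of a simulated cluster
#'
#' For processive runs the end-to-end steady-state velocity of the leading
#' motor; for non-processive runs the episode velocity of successive
#' leading motors (an episode spans one motor's tenure as the forwardmost
#' bound motor). With the default `"duration_weighted"` estimator each
#' episode contributes in proportion to its duration, i.e. the total
#' leader displacement divided by the total leader-attached time; this
#' converges to the occupancy-averaged cluster velocity. The unweighted
#' mean over episodes (`"episode_mean"`) gives equal weight to the many
#' very short leaderships that occur while few motors are bound, and
#' therefore sits systematically below the duration-weighted value.
#' Statistics are across replicates.
#'
#' @param sim A `motor_sim` from [simulate_cluster()].
#' @param units `"steps"` (steps/s, default) or `"um"` (micrometres/s,
#'   using the simulation's `dx`).
#' @param estimator `"duration_weighted"` (default) or `"episode_mean"`;
#'   ignored for processive runs.
#' @return Named vector with `mean`, `sd` and `se` (sd across replicates /
#'   sqrt(number of replicates with data)).
#' @export
cluster_velocity <- function(sim, units = c("steps", "um"),
                             estimator = c("duration_weighted",
                                           "episode_mean")) {
  stopifnot(inherits(sim, "motor_sim"))
  units <- match.arg(units)
  estimator <- match.arg(estimator)
  v <- if (sim$config$scenario == "processive") {
    sim$replicates$steady_state_velocity
  } else if (estimator == "duration_weighted") {
    sim$replicates$episode_velocity
  } else {
    sim$replicates$episode_velocity_unweighted
  }
  v <- v[!is.na(v)]
  if (!length(v)) {
    return(c(mean = NA_real_, sd = NA_real_, se = NA_real_))
  }
  scale <- if (units == "um") sim$params$dx / 1000 else 1
  m <- mean(v) * scale
  s <- if (length(v) > 1) sd(v) * scale else NA_real_
  c(mean = m, sd = s, se = s / sqrt(length(v)))
}

#' Run-length statistics of a simulated cluster
#'
#' Pools the signed run lengths (cargo displacement between first
#' attachment and complete detachment of the cluster) over replicates.
#'
#' @inheritParams cluster_velocity
#' @return A list with the pooled `mean`, `sd`, replicate-level `se` of
#'   the mean, the fraction of negative (backward) runs and the number of
#'   completed runs.
#' @export
run_length_stats <- function(sim, units = c("steps", "um")) {
  stopifnot(inherits(sim, "motor_sim"))
  units <- match.arg(units)
  scale <- if (match.arg(units) == "um") sim$params$dx / 1000 else 1
  rep_means <- sim$replicates$mean_run_length
  rep_means <- rep_means[!is.na(rep_means)]
  pooled <- if (!is.null(sim$run_lengths)) unlist(sim$run_lengths)
            else numeric(0)
  if (!length(rep_means)) {
    return(list(mean = NA_real_, sd = NA_real_, se = NA_real_,
                frac_negative = NA_real_, n = 0L))
  }
  list(
    mean = mean(rep_means) * scale,
    sd = if (length(pooled) > 1) sd(pooled) * scale else NA_real_,
    se = if (length(rep_means) > 1)
           sd(rep_means) / sqrt(length(rep_means)) * scale else NA_real_,
    frac_negative = if (length(pooled)) mean(pooled < 0) else NA_real_,
    n = if (length(pooled)) length(pooled)
        else sum(sim$replicates$n_runs_completed, na.rm = TRUE)
  )
}

#' Occupancy distribution of a simulated cluster
#'
#' Time-weighted distribution of the number of bound motors, with
#' replicate-level standard errors per bin.
#'
#' @inheritParams cluster_velocity
#' @return A data frame with columns `n`, `prob` (mean over replicates)
#'   and `se`.
#' @export
occupancy_distribution <- function(sim) {
  stopifnot(inherits(sim, "motor_sim"))
  occ <- sim$occupancy
  data.frame(
    n = 0:(ncol(occ) - 1L),
    prob = colMeans(occ, na.rm = TRUE),
    se = apply(occ, 2, function(z) {
      z <- z[!is.na(z)]
      if (length(z) > 1) sd(z) / sqrt(length(z)) else NA_real_
    }),
    row.names = NULL
  )
}

#' Estimate the stall force by simulation
#'
#' Scans a grid of dimensionless forces, measuring the cluster velocity at
#' each, and declares stall at the first force whose velocity has dropped
#' to at most `threshold` times the zero-force velocity; the bracket
#' around that grid point is then refined by bisection to a resolution of
#' `resolution` in `f`. Because the measured velocity near stall
#' fluctuates around zero with a sampling error far above
#' `threshold * V(0)`, the criterion is applied one-sidedly (velocity at
#' or below the threshold), which locates the zero crossing.
#'
#' @param params A [motor_params()] object.
#' @param config A [sim_config()] template; its `f` is ignored and
#'   replaced by each evaluation force. Sub-seeds for the evaluations are
#'   derived from `config$seed`.
#' @param f_grid Increasing grid of forces to scan, starting at 0 (or the
#'   reference force for `V_0`).
#' @param threshold Stall threshold on `|V_f / V_0|` (default `1e-5`).
#' @param resolution Final bisection resolution in `f` (default 0.05).
#' @return A list with `f_stall`, the `evaluations` table of
#'   (f, velocity) pairs, and `threshold_met`. If no grid force meets the
#'   criterion, `f_stall` is `NA` and a warning reports the last measured
#'   velocity.
#' @export
estimate_stall_force <- function(params, config, f_grid, threshold = 1e-5,
                                 resolution = 0.05) {
  stopifnot(inherits(params, "motor_params"), inherits(config, "sim_config"),
            is.numeric(f_grid), length(f_grid) >= 2,
            !is.unsorted(f_grid, strictly = TRUE))
  evals <- data.frame(f = numeric(0), velocity = numeric(0))
  k <- 0L
  measure <- function(f) {
    k <<- k + 1L
    cfg <- config
    cfg$f <- f
    cfg$seed <- (config$seed + 7919L * k) %% (.Machine$integer.max - 1L)
    v <- cluster_velocity(simulate_cluster(cfg, params,
                                           keep_raw = FALSE))[["mean"]]
    evals <<- rbind(evals, data.frame(f = f, velocity = v))
    v
  }
  v0 <- measure(f_grid[1])
  stalled <- function(v) v <= threshold * abs(v0)
  hit <- NA_integer_
  for (i in seq_along(f_grid)[-1]) {
    if (stalled(measure(f_grid[i]))) { hit <- i; break }
  }
  if (is.na(hit)) {
    warning(sprintf(paste0("stall threshold not met on the grid; last ",
                           "velocity %.4g steps/s at f = %.3g"),
                    evals$velocity[nrow(evals)], evals$f[nrow(evals)]),
            call. = FALSE)
    return(list(f_stall = NA_real_, evaluations = evals,
                threshold_met = FALSE))
  }
  lo <- f_grid[hit - 1L]
  hi <- f_grid[hit]
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (stalled(measure(mid))) hi <- mid else lo <- mid
  }
  list(f_stall = hi, evaluations = evals, threshold_met = TRUE)
}
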