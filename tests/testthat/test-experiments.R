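test_that("run_experiment writes a reproducible result bundle", {
  out1 <- tempfile("mlx")
  out2 <- tempfile("mlx")
  cfg <- list(experiment = "force-velocity-curve",
              preset = "kinesin1-processive", N = c(1, 2), f = c(0, 2),
              n_steps = 2e4, burn_in = 1000, n_runs = 3, seed = 7)
  r1 <- run_experiment(cfg, out_dir = out1)
  r2 <- run_experiment(cfg, out_dir = out2)
  expect_true(all(file.exists(r1$files)))
  # deterministic given the seed
  expect_identical(r1$table, r2$table)
  # the TSV round-trips the aggregated numbers
  tab <- read.delim(r1$files[["table"]])
  expect_equal(tab$velocity, r1$table$velocity)
  meta <- jsonlite::read_json(r1$files[["metadata"]])
  expect_equal(meta$params$p, 100)
  expect_equal(meta$controls$seed, 7)
})

test_that("invalid experiment configurations are rejected", {
  expect_error(run_experiment(list(experiment = "nope", preset = "ncd")),
               "force-velocity-curve")
  expect_error(
    run_experiment(list(experiment = "force-velocity-curve",
                        preset = "ncd", f = numeric(0))),
    "empty force grid")
  expect_error(run_experiment(list(experiment = "force-velocity-curve")),
               "preset")
})

test_that("yaml configuration files drive the same experiment", {
  cfg <- list(experiment = "stall-vs-N", preset = "ncd", N = c(1, 3))
  path <- tempfile(fileext = ".yml")
  yaml::write_yaml(cfg, path)
  r <- run_experiment(path, out_dir = tempfile("mlx"))
  expect_equal(r$table$stall_processive, c(1, 3) * log(10))
  expect_true(all(r$table$stall_analytic_nonprocessive <=
                    r$table$stall_processive))
})

test_that("analytic overlay annotates velocity tables with z-scores", {
  cfg <- list(experiment = "force-velocity-curve",
              preset = "kinesin1-processive", N = 5, f = c(0, 2),
              dt = 2e-4, n_steps = 4e5, burn_in = 5000, n_runs = 6,
              seed = 21)
  r <- run_experiment(cfg, out_dir = tempfile("mlx"))
  ann <- compare_to_analytic(r, model = "leading_motor")
  expect_named(ann, c(names(r$table), "analytic", "z"), ignore.order = TRUE)
  expect_equal(ann$analytic,
               leading_motor_velocity(motor_preset("kinesin1-processive"),
                                      ann$f, 5))
  expect_true(all(abs(ann$z) < 3))
  # binding-averaged models need binding kinetics
  expect_error(compare_to_analytic(r, model = "unlimited"), "k_on")
  # empty tables stay empty
  empty <- r
  empty$table <- r$table[0, ]
  expect_equal(nrow(compare_to_analytic(empty)), 0)
})

test_that("motor-number inference is self-consistent", {
  ax <- motor_preset("kinesin1-axonal")
  candidates <- 2:4
  ranked <- infer_motor_number(c(0.26, 0.10), c(1.82, 1.19), candidates,
                               params = ax, n_steps = 2e5, n_runs = 4,
                               seed = 31)
  expect_setequal(ranked$N, candidates)
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  # feeding a candidate's own simulated pair back must select it
  row4 <- ranked[ranked$N == 4, ]
  again <- infer_motor_number(c(row4$velocity_um_s, 0.10),
                              c(row4$run_length_um, 1.19), candidates,
                              params = ax, n_steps = 2e5, n_runs = 4,
                              seed = 31)
  expect_equal(again$N[1], 4)
  # a single candidate is returned trivially with its distance
  solo <- infer_motor_number(c(0.26, 0.10), c(1.82, 1.19), 3, params = ax,
                             n_steps = 1e5, n_runs = 3, seed = 33)
  expect_equal(solo$N, 3)
  expect_true(is.finite(solo$z2))
})

test_that("observed-velocity validation rejects degenerate inputs", {
  ax <- motor_preset("kinesin1-axonal")
  expect_error(infer_motor_number(c(0.2, 0), c(1, 1), 2, params = ax), "sd")
  expect_error(infer_motor_number(c(0.2, 0.1), c(1, 1), 25, params = ax),
               "1..20")
})
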