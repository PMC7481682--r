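kin <- motor_preset("kinesin1-processive")
ncd <- motor_preset("ncd")

test_that("processive initialization respects the cargo-width rule", {
  cfg <- sim_config("processive", N = 4, n_steps = 10, burn_in = 0,
                    seed = 5)
  set.seed(5)
  st <- lattice_init(cfg, kin)
  expect_true(all(st$bound))
  expect_length(unique(st$positions), 4L)
  expect_true(all(st$positions >= 0 & st$positions <= 9))
  # N >= 10 widens the cargo to N + 10 sites
  cfg12 <- sim_config("processive", N = 12, n_steps = 10, burn_in = 0)
  set.seed(1)
  st12 <- lattice_init(cfg12, kin)
  expect_true(all(st12$positions <= 21))
  expect_length(unique(st12$positions), 12L)
})

test_that("non-processive runs start with every motor unbound", {
  cfgB <- sim_config("B", N = 10, n_steps = 10, burn_in = 0)
  stB <- lattice_init(cfgB, ncd)
  expect_false(any(stB$bound))
  cfgA <- sim_config("A", N = 10, n_steps = 10, burn_in = 0, M = 25)
  stA <- lattice_init(cfgA, ncd)
  expect_false(any(stA$bound))
  expect_equal(diff(stA$window) + 1L, 25L)
})

test_that("identical seeds give identical initial states and trajectories", {
  cfg <- sim_config("B", N = 5, f = 1, n_steps = 5e3, burn_in = 100,
                    n_runs = 2, seed = 99)
  s1 <- simulate_cluster(cfg, ncd)
  s2 <- simulate_cluster(cfg, ncd)
  expect_identical(s1$replicates, s2$replicates)
  expect_identical(s1$occupancy, s2$occupancy)
})

test_that("simple exclusion holds at every recorded step", {
  for (scen in c("processive", "A", "B")) {
    cfg <- sim_config(scen, N = 5, f = 0, n_steps = 2000, burn_in = 0,
                      seed = 7, M = if (scen == "A") 12 else NULL)
    set.seed(7)
    st <- lattice_init(cfg, ncd)
    st <- lattice_steps(st, cfg, ncd, n = 2000)
    ph <- attr(st, "pos_hist")
    bh <- attr(st, "bound_hist")
    clash <- vapply(seq_len(nrow(ph)), function(i) {
      pos <- ph[i, bh[i, ] == 1]
      anyDuplicated(pos) > 0
    }, logical(1))
    expect_false(any(clash))
  }
})

test_that("scenario B preserves the motor sequence at every step", {
  cfg <- sim_config("B", N = 8, f = 1, n_steps = 4000, burn_in = 0,
                    seed = 11)
  set.seed(11)
  st <- lattice_init(cfg, ncd)
  st <- lattice_steps(st, cfg, ncd, n = 4000)
  ph <- attr(st, "pos_hist")
  bh <- attr(st, "bound_hist")
  ordered <- vapply(seq_len(nrow(ph)), function(i) {
    pos <- ph[i, bh[i, ] == 1]
    !is.unsorted(pos, strictly = TRUE)
  }, logical(1))
  expect_true(all(ordered))
})

test_that("scenario B end extension admits only the two flanking sites", {
  # one bound motor at site 5 with stepping frozen: rebinding can only
  # land one site in front of (higher-index motor) or behind it
  sticky <- motor_params(p = 0, q = 0, k_on = 50, k_off = 0)
  cfg <- sim_config("B", N = 2, n_steps = 400, burn_in = 0, seed = 3)
  front_sites <- back_sites <- integer(0)
  for (s in 1:25) {
    set.seed(s)
    st <- lattice_init(cfg, sticky)
    st$positions <- c(5L, 5L)
    st$bound <- c(TRUE, FALSE)   # motor 2 must bind in front
    st <- lattice_steps(st, cfg, sticky, n = 400)
    if (st$bound[2]) front_sites <- c(front_sites, st$positions[2])
    set.seed(s + 1000)
    st <- lattice_init(cfg, sticky)
    st$positions <- c(5L, 5L)
    st$bound <- c(FALSE, TRUE)   # motor 1 must bind behind
    st <- lattice_steps(st, cfg, sticky, n = 400)
    if (st$bound[1]) back_sites <- c(back_sites, st$positions[1])
  }
  expect_gt(length(front_sites), 0)
  expect_gt(length(back_sites), 0)
  expect_true(all(front_sites == 6L))
  expect_true(all(back_sites == 4L))
})

test_that("a single unblocked motor advances at rate p", {
  uni <- motor_params(p = 100, q = 0)
  cfg <- sim_config("processive", N = 1, f = 0, n_steps = 2e4, burn_in = 0,
                    seed = 13)
  set.seed(13)
  st <- lattice_init(cfg, uni)
  x0 <- st$positions
  st <- lattice_steps(st, cfg, uni, n = 2e4)
  moved <- st$positions - x0
  # Binomial(2e4, 0.1): mean 2000, sd ~42
  expect_gt(moved, 2000 - 5 * 45)
  expect_lt(moved, 2000 + 5 * 45)
})

test_that("a trailing motor cannot pass or share a site with the leader", {
  uni <- motor_params(p = 100, q = 0)
  cfg <- sim_config("processive", N = 2, f = 5, n_steps = 3000, burn_in = 0,
                    seed = 17)
  set.seed(17)
  st <- lattice_init(cfg, uni)
  st$positions <- c(0L, 1L)   # adjacent: trailing forward moves must fail
  st <- lattice_steps(st, cfg, uni, n = 3000)
  ph <- attr(st, "pos_hist")
  expect_true(all(ph[, 2] > ph[, 1]))
})

test_that("occupancy histogram normalizes and run lengths can be negative", {
  cfg <- sim_config("B", N = 1, f = 2, n_steps = 2e5, burn_in = 1000,
                    n_runs = 3, seed = 23)
  sim <- simulate_cluster(cfg, ncd)
  occ <- occupancy_distribution(sim)
  expect_equal(sum(occ$prob), 1, tolerance = 1e-12)
  rl <- unlist(sim$run_lengths)
  expect_gt(length(rl), 50)
  # a lone Ncd under load frequently runs backwards
  expect_gt(mean(rl < 0), 0.05)
})

test_that("simulated processive velocity matches the biased-walk rate", {
  cfg <- sim_config("processive", N = 1, f = 0, n_steps = 2e5,
                    burn_in = 1000, n_runs = 6, seed = 29)
  v <- cluster_velocity(simulate_cluster(cfg, kin))
  expect_lt(abs(v[["mean"]] - 90), 3 * v[["se"]])
})

test_that("overlarge time steps are rejected and large rates warned", {
  fast <- motor_params(p = 2000, q = 200)
  cfg <- sim_config("processive", N = 1, f = 0, n_steps = 100, burn_in = 0)
  expect_error(simulate_cluster(cfg, fast), "dt too large")
  warm <- motor_params(p = 500, q = 50)
  expect_warning(simulate_cluster(cfg, warm), "bias")
})
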