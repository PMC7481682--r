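kin <- motor_params(p = 100, q = 10)
ncd <- motor_params(p = 22, q = 2.2, k_on = 20, k_off = 10)

tv_dist <- function(a, b) 0.5 * sum(abs(as.numeric(a) - as.numeric(b)))

test_that("mean-field force-velocity relation evaluates and validates", {
  # zero load returns the unloaded velocity; collective stall gives zero
  expect_equal(mean_field_velocity(800, 6, 2, F = 0, n = 3), 800)
  expect_equal(mean_field_velocity(800, 6, 2, F = 18, n = 3), 0)
  expect_equal(mean_field_velocity(1000, 5, 2, F = 5, n = 2), 750)
  expect_lt(mean_field_velocity(800, 6, 1, F = 30, n = 3), 0)
  expect_error(mean_field_velocity(800, 6, 2, F = -1, n = 3), "F")
  expect_error(mean_field_velocity(800, 6, 2, F = 1, n = 0), "n")
})

test_that("leading-motor rates follow the Boltzmann reweighting", {
  r0 <- leading_motor_rates(kin, 0)
  expect_equal(r0$p1, 100)
  expect_equal(r0$q1, 10)
  r <- leading_motor_rates(kin, 2)
  expect_equal(r$p1, 100 * exp(-1))
  expect_equal(r$q1, 10 * exp(1))
  # delta = 1 loads only the forward rate
  d1 <- motor_params(p = 100, q = 10, delta = 1)
  r1 <- leading_motor_rates(d1, 3)
  expect_equal(r1$p1, 100 * exp(-3))
  expect_equal(r1$q1, 10)
})

test_that("cluster force-velocity relation has the stated limits", {
  # zero force collapses to p - q for every n
  for (n in c(1, 2, 5, 20)) {
    expect_equal(leading_motor_velocity(kin, 0, n), 90)
  }
  # unidirectional reduction
  uni <- motor_params(p = 100, q = 0)
  expect_equal(leading_motor_velocity(uni, 2, 3), 100 * exp(-1))
  # the velocity vanishes at f = n log(p/q)
  for (n in c(1, 3, 7)) {
    expect_equal(leading_motor_velocity(kin, n * log(10), n), 0,
                 tolerance = 1e-12)
  }
  # degenerate stepping
  expect_equal(leading_motor_velocity(motor_params(0, 0), 1, 2), 0)
  expect_error(leading_motor_velocity(motor_params(0, 5), 1, 2),
               "forward-biased")
})

test_that("cluster velocity is strictly decreasing in force", {
  f <- seq(0, 8, by = 0.25)
  for (n in c(1, 2, 10)) {
    v <- leading_motor_velocity(kin, f, n)
    expect_true(all(diff(v) < 0))
  }
})

test_that("unlimited bound-motor distribution is the two-state binomial", {
  two <- motor_params(p = 1, q = 0.1, k_on = 20, k_off = 10)
  d1 <- bound_distribution(two, N = 1)
  expect_equal(as.numeric(d1), c(1, 2) / 3)
  sym <- motor_params(p = 1, q = 0.1, k_on = 5, k_off = 5)
  expect_equal(as.numeric(bound_distribution(sym, N = 2)),
               c(0.25, 0.5, 0.25))
  # independent per-motor occupancy: Binomial(N, k_on/(k_on+k_off))
  d10 <- bound_distribution(two, N = 10)
  expect_equal(as.numeric(d10), dbinom(0:10, 10, 2 / 3), tolerance = 1e-12)
  expect_equal(sum(d10), 1, tolerance = 1e-12)
})

test_that("limited distribution truncates, shifts down and converges", {
  d11 <- bound_distribution(ncd, N = 1, M = 1)
  expect_equal(as.numeric(d11), c(10, 20) / 30)
  # entries above min(N, M) vanish
  d_trunc <- bound_distribution(ncd, N = 5, M = 3)
  expect_equal(as.numeric(d_trunc)[5:6], c(0, 0))
  # limited case is stochastically lower than unlimited
  m_lim <- sum(0:10 * bound_distribution(ncd, 10, 20))
  m_unl <- sum(0:10 * bound_distribution(ncd, 10))
  expect_lt(m_lim, m_unl)
  # total-variation convergence to the unlimited form, monotone in M
  unl <- bound_distribution(ncd, 10)
  tv <- vapply(c(20, 30, 100, 1e4),
               function(M) tv_dist(bound_distribution(ncd, 10, M), unl),
               numeric(1))
  expect_true(all(diff(tv) < 0))
  expect_lt(tv[4], 1e-3)
  # normalization and non-negativity hold over a parameter sweep
  for (N in c(1, 7, 150)) {
    for (M in c(1, 12, 180, Inf)) {
      d <- bound_distribution(ncd, N, M)
      expect_true(all(d >= 0))
      expect_equal(sum(d), 1, tolerance = 1e-12)
    }
  }
})

test_that("k_off = 0 is the all-bound limit", {
  glue <- motor_params(p = 1, q = 0.1, k_on = 3, k_off = 0)
  expect_equal(as.numeric(bound_distribution(glue, 4)), c(0, 0, 0, 0, 1))
  expect_equal(as.numeric(bound_distribution(glue, 4, M = 2)),
               c(0, 0, 1, 0, 0))
})

test_that("master-equation steady state matches the closed forms", {
  for (N in c(1, 5, 17, 50)) {
    for (M in c(3, 25, 50, Inf)) {
      ss <- master_equation_steady_state(ncd, N, M)
      cf <- bound_distribution(ncd, N, M)
      expect_lt(tv_dist(ss, cf), 1e-10)
    }
  }
  expect_error(master_equation_steady_state(motor_params(1, 0.1), 3),
               "singular")
})

test_that("master-equation steady state satisfies detailed balance", {
  for (M in c(12, Inf)) {
    N <- 8
    P <- as.numeric(master_equation_steady_state(ncd, N, M))
    for (n in 1:N) {
      kon_eff <- if (is.finite(M)) {
        (N - n + 1) * max(M - n + 1, 0) * ncd$k_on / M
      } else {
        (N - n + 1) * ncd$k_on
      }
      expect_equal(kon_eff * P[n], n * ncd$k_off * P[n + 1],
                   tolerance = 1e-10)
    }
  }
})

test_that("binding-averaged cluster velocity has the stated structure", {
  # single motor: conditioning removes the binding dependence entirely
  expect_equal(average_cluster_velocity(ncd, 1.3, N = 1),
               leading_motor_velocity(ncd, 1.3, 1))
  # zero force gives p - q whatever N and M
  for (N in c(1, 4, 12)) {
    for (M in c(6, Inf)) {
      expect_equal(average_cluster_velocity(ncd, 0, N, M), 19.8)
    }
  }
  # large clusters behave like bound processive clusters
  expect_equal(average_cluster_velocity(ncd, 2, N = 100),
               leading_motor_velocity(ncd, 2, 100), tolerance = 1e-3)
  # never-bound condition
  dead <- motor_params(p = 22, q = 2.2, k_on = 0, k_off = 10)
  expect_error(average_cluster_velocity(dead, 0, 3), "k_on")
})

test_that("processive stall force is N log(p/q) and matches bisection", {
  expect_equal(stall_force(kin, 1), log(10))
  expect_equal(stall_force(kin, 2), 2 * log(10))
  # exact linearity
  for (N in 1:10) {
    expect_identical(stall_force(kin, N), N * stall_force(kin, 1))
  }
  # independent root-finding on the force-velocity relation agrees
  for (N in c(1, 4, 10)) {
    root <- uniroot(function(f) leading_motor_velocity(kin, f, N),
                    c(0, N * log(10) + 1), tol = 1e-9)$root
    expect_equal(root, N * log(10), tolerance = 1e-6)
  }
  expect_error(stall_force(motor_params(100, 0), 1), "no finite stall")
  expect_error(stall_force(motor_params(10, 20), 1), "p > q")
})

test_that("non-processive stall is below the processive stall", {
  # a single motor is unaffected by binding statistics
  expect_equal(stall_force(ncd, 1, processive = FALSE), log(10),
               tolerance = 1e-6)
  for (N in 2:10) {
    f_np <- stall_force(ncd, N, processive = FALSE)
    expect_lt(f_np, stall_force(ncd, N))
    # it is a root of the binding-averaged velocity
    expect_equal(average_cluster_velocity(ncd, f_np, N), 0,
                 tolerance = 1e-5)
  }
})
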