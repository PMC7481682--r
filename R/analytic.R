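#' Mean-field force-velocity relation
#'
#' Velocity of a cargo pulled by `n` motors when the load `F` is shared
#' equally, with a nonlinear force-velocity exponent `w`:
#' `V_n(F) = v * (1 - (F / (Fs * n))^w)`. The linear relation is `w = 1`.
#' This is the equal-sharing alternative to the leading-motor load rule;
#' the rest of the package uses the latter, and this function is provided
#' for comparison.
#'
#' @param v Unloaded velocity (nm/s), `>= 0`.
#' @param Fs Single-motor stall force (pN), `> 0`.
#' @param w Nonlinearity exponent, `> 0`.
#' @param F Applied load (pN), `>= 0` (may be a vector).
#' @param n Number of bound motors sharing the load, `>= 1`.
#' @return Velocity in nm/s; negative for loads beyond the collective
#'   stall `Fs * n`.
#' @examples
#' mean_field_velocity(v = 1000, Fs = 5, w = 2, F = 5, n = 2)  # 750
#' @export
mean_field_velocity <- function(v, Fs, w, F, n) {
  stopifnot(
    "v must be a single non-negative number" =
      is.numeric(v) && length(v) == 1L && v >= 0,
    "Fs must be a single positive number" =
      is.numeric(Fs) && length(Fs) == 1L && Fs > 0,
    "w must be a single positive number" =
      is.numeric(w) && length(w) == 1L && w > 0,
    "F must be non-negative" = is.numeric(F) && all(F >= 0),
    "n must be a positive count" =
      is.numeric(n) && length(n) == 1L && n >= 1
  )
  v * (1 - (F / (Fs * n))^w)
}

#' Load-modified stepping rates of the leading motor
#'
#' Under the leading-motor load rule the entire dimensionless force `f`
#' acts on the forwardmost bound motor, whose rates become
#' `p1 = p * exp(-f * delta)` and `q1 = q * exp(f * (1 - delta))`.
#' Trailing motors keep the bare rates `p`, `q`.
#'
#' @param params A [motor_params()] object.
#' @param f Dimensionless force (may be a vector).
#' @return A list with components `p1` and `q1` (s^-1).
#' @examples
#' leading_motor_rates(motor_params(100, 10), f = 2)
#' @export
leading_motor_rates <- function(params, f) {
  stopifnot(
    "params must be a motor_params object" = inherits(params, "motor_params"),
    "f must be finite numeric" = is.numeric(f) && all(is.finite(f))
  )
  list(p1 = params$p * exp(-f * params$delta),
       q1 = params$q * exp(f * (1 - params$delta)))
}

#' Force-velocity relation of a cluster of bound motors (leading-motor load)
#'
#' Average velocity, in steps per second, of a cluster of `n` motors that
#' remain bound while the leading motor carries the whole load `f`:
#' \deqn{V_n = \frac{p\,(1 - e^{f} (q/p)^n)\,(1 - q/p)}
#'       {e^{f\delta}(1 - q/p) + e^{f}\,((q/p) - (q/p)^n)}.}{
#'  V_n = p (1 - e^f (q/p)^n) (1 - q/p) /
#'        (e^{f delta} (1 - q/p) + e^f ((q/p) - (q/p)^n)).}
#' For unidirectional motors (`q = 0`) this reduces to
#' `V_n = p * exp(-f * delta)`, and at `f = 0` it collapses to `p - q` for
#' every `n`. Multiply by `dx` to obtain nm/s.
#'
#' @param params A [motor_params()] object with `p > 0` (or `p = q = 0`,
#'   which gives zero velocity).
#' @param f Dimensionless force (may be a vector).
#' @param n Number of bound motors, `>= 1`.
#' @return Velocity in steps/s; negative beyond the stall force
#'   `f = n * log(p/q)`.
#' @examples
#' leading_motor_velocity(motor_params(100, 10), f = 0, n = 5)  # 90
#' @export
leading_motor_velocity <- function(params, f, n) {
  stopifnot(
    "params must be a motor_params object" = inherits(params, "motor_params"),
    "f must be finite numeric" = is.numeric(f) && all(is.finite(f)),
    "n must be a positive count" =
      is.numeric(n) && length(n) == 1L && n >= 1 && n == floor(n)
  )
  p <- params$p
  q <- params$q
  delta <- params$delta
  if (p == 0 && q == 0) {
    return(rep(0, length(f)))
  }
  if (p == 0) {
    stop("leading_motor_velocity assumes forward-biased stepping (p > 0)",
         call. = FALSE)
  }
  if (q == 0) {
    return(p * exp(-f * delta))
  }
  r <- q / p
  num <- p * (1 - exp(f) * r^n) * (1 - r)
  den <- exp(f * delta) * (1 - r) + exp(f) * (r - r^n)
  num / den
}

#' Steady-state distribution of the number of bound motors
#'
#' Closed-form stationary distribution `P_n`, `n = 0..N`, of the
#' birth-death chain describing `N` motors that bind at rate `k_on` per
#' unbound motor and unbind at rate `k_off` per bound motor.
#'
#' With unlimited binding sites (`M = Inf`) detailed balance gives
#' `P_n` proportional to `choose(N, n) * (k_on/k_off)^n` -- a binomial
#' distribution with success probability `k_on / (k_on + k_off)`.
#'
#' When only `M` sites are accessible the per-site binding rate is
#' `k_on_s = k_on / M` and the binding rate in state `n` is
#' `(N - n)(M - n) k_on_s`, giving
#' `P_n` proportional to
#' `N! M! / (n! (N-n)! (M-n)!) * (k_on_s / k_off)^n` for
#' `n <= min(N, M)` and zero above. All factors are accumulated in log
#' space and normalized by log-sum-exp, so the form is exact (to ~1e-12
#' relative) for `N`, `M` well beyond the range where factorials overflow.
#'
#' `k_off = 0` with `k_on > 0` is treated as the all-bound limit (all mass
#' at `n = min(N, M)`), recovering the processive case smoothly.
#'
#' @param params A [motor_params()] object; `k_on + k_off` must be positive.
#' @param N Total number of motors on the cargo, `>= 1`.
#' @param M Number of accessible binding sites; `Inf` (default) for the
#'   unlimited-site convention.
#' @return A numeric vector of class `bound_motor_distribution` with
#'   names `"P0"..."PN"`, summing to 1.
#' @examples
#' bound_distribution(motor_params(22, 2.2, k_on = 20, k_off = 10), N = 10)
#' bound_distribution(motor_params(22, 2.2, k_on = 20, k_off = 10),
#'                    N = 10, M = 20)
#' @export
bound_distribution <- function(params, N, M = Inf) {
  stopifnot(
    "params must be a motor_params object" = inherits(params, "motor_params"),
    "N must be a positive count" =
      is.numeric(N) && length(N) == 1L && N >= 1 && N == floor(N),
    "M must be a positive count or Inf" =
      is.numeric(M) && length(M) == 1L && M >= 1 &&
        (is.infinite(M) || M == floor(M)),
    "k_on + k_off must be positive" = params$k_on + params$k_off > 0
  )
  k_on <- params$k_on
  k_off <- params$k_off
  n <- 0:N
  n_max <- if (is.finite(M)) min(N, M) else N

  if (k_on == 0) {
    probs <- c(1, rep(0, N))
  } else if (k_off == 0) {
    probs <- rep(0, N + 1)
    probs[n_max + 1L] <- 1
  } else {
    ratio <- if (is.finite(M)) (k_on / M) / k_off else k_on / k_off
    logw <- rep(-Inf, N + 1)
    nn <- 0:n_max
    lw <- lchoose(N, nn) + nn * log(ratio)
    if (is.finite(M)) {
      lw <- lw + lgamma(M + 1) - lgamma(M - nn + 1)
    }
    logw[nn + 1L] <- lw
    logz <- max(lw) + log(sum(exp(lw - max(lw))))
    probs <- exp(logw - logz)
  }
  structure(probs, names = paste0("P", n), class = "bound_motor_distribution")
}

#' @export
print.bound_motor_distribution <- function(x, digits = 4, ...) {
  cat("Bound-motor distribution (N =", length(x) - 1L, "motors)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Numerical steady state of the bound-motor master equation
#'
#' Solves the stationarity condition of the full birth-death master
#' equation for the number of bound motors by linear algebra (null space
#' of the transposed generator with a normalization row), independently of
#' the closed form returned by [bound_distribution()]. In state `n` the
#' binding rate is `(N - n) k_on` (unlimited) or `(N - n)(M - n) k_on / M`
#' (limited to `M` sites) and the unbinding rate is `n k_off`. The result
#' satisfies the detailed-balance condition
#' `(N - n + 1) k_on P_{n-1} = n k_off P_n` (with the `(M - n + 1)/M`
#' factor in the limited case) and matches the closed form to ~1e-12.
#'
#' @inheritParams bound_distribution
#' @return A `bound_motor_distribution` vector of length `N + 1`.
#' @examples
#' ncd <- motor_params(22, 2.2, k_on = 20, k_off = 10)
#' master_equation_steady_state(ncd, N = 5, M = 10)
#' @export
master_equation_steady_state <- function(params, N, M = Inf) {
  stopifnot(
    "params must be a motor_params object" = inherits(params, "motor_params"),
    "N must be a positive count" =
      is.numeric(N) && length(N) == 1L && N >= 1 && N == floor(N),
    "M must be a positive count or Inf" =
      is.numeric(M) && length(M) == 1L && M >= 1 &&
        (is.infinite(M) || M == floor(M))
  )
  if (params$k_on + params$k_off == 0) {
    stop("singular chain: k_on = k_off = 0 has no unique steady state",
         call. = FALSE)
  }
  n <- 0:N
  up <- (N - n) * params$k_on
  if (is.finite(M)) up <- up * pmax(M - n, 0) / M
  down <- n * params$k_off

  # Degenerate absorbing cases (k_on = 0 or k_off = 0): the chain is not
  # irreducible; return the absorbing state directly.
  if (params$k_on == 0 || params$k_off == 0) {
    return(bound_distribution(params, N, M))
  }

  # Generator transpose A with A %*% P = 0; replace last row by sum(P) = 1.
  A <- matrix(0, N + 1, N + 1)
  for (i in seq_len(N + 1)) {
    A[i, i] <- -(up[i] + down[i])
    if (i > 1) A[i, i - 1] <- up[i - 1]
    if (i < N + 1) A[i, i + 1] <- down[i + 1]
  }
  A[N + 1, ] <- 1
  b <- c(rep(0, N), 1)
  probs <- solve(A, b)
  probs[probs < 0 & probs > -1e-14] <- 0
  structure(probs, names = paste0("P", n), class = "bound_motor_distribution")
}

#' Average velocity of a cluster of non-processive motors
#'
#' Combines the force-velocity relation of `n` bound motors with the
#' steady-state bound-motor distribution: the average velocity, given that
#' at least one motor is bound, is
#' `sum_{n=1}^{N} P_n V_n / (1 - P_0)`, with `V_n` from
#' [leading_motor_velocity()] and `P_n` from [bound_distribution()]
#' (unlimited or limited according to `M`). The underlying quasi-static
#' assumption is that stepping is fast compared with binding and
#' unbinding, so each `n`-motor episode travels at its steady velocity.
#'
#' @inheritParams bound_distribution
#' @param f Dimensionless force (may be a vector).
#' @return Velocity in steps/s (same length as `f`).
#' @examples
#' ncd <- motor_params(22, 2.2, k_on = 20, k_off = 10)
#' average_cluster_velocity(ncd, f = 0, N = 5)   # p - q = 19.8
#' @export
average_cluster_velocity <- function(params, f, N, M = Inf) {
  stopifnot(
    "k_on must be positive (otherwise no motor ever binds)" =
      inherits(params, "motor_params") && params$k_on > 0
  )
  probs <- unname(as.numeric(bound_distribution(params, N, M)))
  if (1 - probs[1] < 1e-300) {
    stop("never-bound condition: P_0 = 1, conditional velocity undefined",
         call. = FALSE)
  }
  vn <- vapply(seq_len(N), function(n) leading_motor_velocity(params, f, n),
               numeric(length(f)))
  if (length(f) == 1L) vn <- matrix(vn, nrow = 1L)
  unname(drop(vn %*% probs[-1])) / (1 - probs[1])
}

#' Stall force of a motor cluster
#'
#' The dimensionless force at which the cluster velocity vanishes. For
#' processive motors the force-velocity relation has the closed-form root
#' `f_s(N) = N * log(p / q)`, linear in the number of motors. For
#' non-processive motors the stall force is the root in `f` of
#' [average_cluster_velocity()], located by bracketed bisection on
#' `[0, N log(p/q)]` (the velocity is continuous and strictly decreasing
#' there, so the bracket is guaranteed); it is at most the processive
#' value at the same `N`.
#'
#' @inheritParams bound_distribution
#' @param processive If `TRUE` (default), the closed-form processive
#'   result; if `FALSE`, the numerical root for motors that bind/unbind.
#' @param tol Bisection tolerance on `f` (non-processive case).
#' @return Dimensionless stall force (scalar).
#' @examples
#' kin <- motor_params(100, 10)
#' stall_force(kin, N = 2)                     # 2 * log(10)
#' ncd <- motor_params(22, 2.2, k_on = 20, k_off = 10)
#' stall_force(ncd, N = 5, processive = FALSE)
#' @export
stall_force <- function(params, N, processive = TRUE, M = Inf, tol = 1e-8) {
  stopifnot(
    "params must be a motor_params object" = inherits(params, "motor_params"),
    "N must be a positive count" =
      is.numeric(N) && length(N) == 1L && N >= 1 && N == floor(N)
  )
  if (params$q == 0) {
    stop("no finite stall force: q = 0 motors never stall", call. = FALSE)
  }
  if (params$p <= params$q) {
    stop("finite positive stall requires p > q", call. = FALSE)
  }
  f_max <- N * log(params$p / params$q)
  if (processive) {
    return(f_max)
  }
  velocity <- function(f) average_cluster_velocity(params, f, N, M)
  bisect_root(velocity, 0, f_max, tol = tol)
}

# Bracketed bisection for a continuous monotone-decreasing function with
# g(lo) > 0 >= g(hi). Returns the root to within tol.
bisect_root <- function(g, lo, hi, tol = 1e-8) {
  g_lo <- g(lo)
  g_hi <- g(hi)
  if (g_lo < 0) return(lo)
  if (g_hi > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
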