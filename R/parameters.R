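#' Kinetic parameters of a single motor species
#'
#' Bundles the stepping and binding kinetics of one motor type. A motor
#' steps forward at rate `p` and backward at rate `q` (both in s^-1) on a
#' lattice of period `dx` nanometres. Under a dimensionless load `f` the
#' leading motor's rates are reweighted by Boltzmann factors controlled by
#' the load-distribution exponent `delta` (see [leading_motor_rates()]).
#' Non-processive motors additionally unbind at rate `k_off` and rebind at
#' rate `k_on`; the processive convention is `k_on = k_off = 0`.
#'
#' @param p Forward stepping rate (s^-1), `>= 0`.
#' @param q Backward stepping rate (s^-1), `>= 0`.
#' @param delta Load-distribution exponent, in `[0, 1]`. `delta = 1` puts
#'   the whole load penalty on the forward rate.
#' @param k_on Binding rate of one unbound motor under the unlimited-site
#'   convention (s^-1), `>= 0`.
#' @param k_off Unbinding rate of one bound motor (s^-1), `>= 0`.
#' @param dx Motor step size (nm), `> 0`. Defaults to 8 nm, the
#'   tubulin-dimer repeat stepped by kinesins.
#'
#' @return An object of class `motor_params` (a named list).
#' @seealso [motor_preset()] for ready-made parameter sets.
#' @examples
#' kin <- motor_params(p = 100, q = 10)
#' ncd <- motor_params(p = 22, q = 2.2, k_on = 20, k_off = 10)
#' @export
motor_params <- function(p, q, delta = 0.5, k_on = 0, k_off = 0, dx = 8) {
  stopifnot(
    "p must be a single non-negative number" =
      is.numeric(p) && length(p) == 1L && is.finite(p) && p >= 0,
    "q must be a single non-negative number" =
      is.numeric(q) && length(q) == 1L && is.finite(q) && q >= 0,
    "delta must lie in [0, 1]" =
      is.numeric(delta) && length(delta) == 1L && is.finite(delta) &&
        delta >= 0 && delta <= 1,
    "k_on must be a single non-negative number" =
      is.numeric(k_on) && length(k_on) == 1L && is.finite(k_on) && k_on >= 0,
    "k_off must be a single non-negative number" =
      is.numeric(k_off) && length(k_off) == 1L && is.finite(k_off) &&
        k_off >= 0,
    "dx must be a single positive number" =
      is.numeric(dx) && length(dx) == 1L && is.finite(dx) && dx > 0
  )
  structure(
    list(p = p, q = q, delta = delta, k_on = k_on, k_off = k_off, dx = dx),
    class = "motor_params"
  )
}

#' @export
print.motor_params <- function(x, ...) {
  cat("Motor parameters\n")
  cat(sprintf("  stepping : p = %g /s, q = %g /s, delta = %g\n",
              x$p, x$q, x$delta))
  cat(sprintf("  binding  : k_on = %g /s, k_off = %g /s%s\n",
              x$k_on, x$k_off,
              if (x$k_on == 0 && x$k_off == 0) "  (processive)" else ""))
  cat(sprintf("  step size: dx = %g nm\n", x$dx))
  invisible(x)
}

is_processive <- function(params) params$k_on == 0 && params$k_off == 0

#' Built-in motor parameter presets
#'
#' Named kinetic parameter sets for the motor species studied with this
#' model. All presets keep the forward/backward rate ratio at `p = 10 q`.
#'
#' * `"kinesin1-processive"`: p = 100, q = 10 (s^-1), processive.
#' * `"kinesin1-single"`: p = 110, q = 11, single-motor stepping rate
#'   observed for lone kinesin-1 in DNA-scaffold assemblies.
#' * `"ncd"`: p = 22, q = 2.2, k_on = 20, k_off = 10, the non-processive
#'   kinesin-14 Ncd in multi-motor assemblies.
#' * `"ncd-single"`: p = 11, q = 1.1, lone Ncd.
#' * `"kinesin1-axonal"`: p = 100, q = 10, k_on = 5, k_off = 1, weakly
#'   non-processive kinesin-1 pulling axonal mitochondria.
#'
#' All use `delta = 0.5` and `dx = 8` nm.
#'
#' @param name Preset name, one of the catalog names.
#' @return For `motor_preset()`, a [motor_params()] object; for
#'   `preset_catalog()`, a named list of all presets.
#' @examples
#' motor_preset("ncd")
#' names(preset_catalog())
#' @export
motor_preset <- function(name) {
  catalog <- preset_catalog()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(catalog))) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: ", paste(names(catalog), collapse = ", "),
         call. = FALSE)
  }
  catalog[[name]]
}

#' @rdname motor_preset
#' @export
preset_catalog <- function() {
  list(
    "kinesin1-processive" = motor_params(p = 100, q = 10),
    "kinesin1-single"     = motor_params(p = 110, q = 11),
    "ncd"                 = motor_params(p = 22, q = 2.2,
                                         k_on = 20, k_off = 10),
    "ncd-single"          = motor_params(p = 11, q = 1.1),
    "kinesin1-axonal"     = motor_params(p = 100, q = 10,
                                         k_on = 5, k_off = 1)
  )
}

#' Convert a dimensionless load to a physical force
#'
#' The load on the cargo is expressed throughout the model as the
#' dimensionless force `f`; the corresponding physical force is
#' `F = f * kBT / dx` in piconewtons when `kBT` is in pN nm and `dx` in nm.
#'
#' @param f Dimensionless force (may be a vector).
#' @param kBT Thermal energy in pN nm. Defaults to 4.28 pN nm
#'   (T = 310 K, physiological temperature).
#' @param dx Motor step size in nm, `> 0`.
#' @return Physical force in pN.
#' @examples
#' force_to_piconewtons(2)          # 1.07 pN at dx = 8 nm
#' @export
force_to_piconewtons <- function(f, kBT = 4.28, dx = 8) {
  stopifnot(
    "kBT must be positive" = is.numeric(kBT) && length(kBT) == 1L && kBT > 0,
    "dx must be positive" = is.numeric(dx) && length(dx) == 1L && dx > 0,
    "f must be numeric" = is.numeric(f)
  )
  f * kBT / dx
}
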