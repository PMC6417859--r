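#' Static + ELF magnetic field protocol
#'
#' Collects the field parameters of a simulation: the static (geomagnetic)
#' field B0, the peak amplitude B1 of a linearly polarised 50/60 Hz field
#' aligned with it, and a static offset dB0 for geomagnetic comparisons.
#' Because magnetically sensitive radical pairs live microseconds while the
#' ELF period is 20 ms, the ELF field is treated as static over each pair's
#' lifetime; its phase alpha is uniform on (0, pi) across the ensemble.
#'
#' Taylor-expansion based estimators additionally require `B1_uT <= 0.2 *
#' B0_uT` and `|dB0_uT| <= 0.2 * B0_uT`; this is enforced at the point of use.
#'
#' @param B0_uT Static field, uT (> 0).  Default 50, a typical mid-latitude
#'   geomagnetic strength.
#' @param B1_uT ELF peak amplitude, uT (>= 0).  Default 1, the peak value
#'   corresponding to the ~0.7 uT rms exposures discussed in epidemiology.
#' @param dB0_uT Static field offset, uT.  Default -1.
#' @return An object of class `field_protocol`.
#' @examples
#' field_protocol()
#' @export
field_protocol <- function(B0_uT = 50, B1_uT = 1, dB0_uT = -1) {
  if (B0_uT <= 0) stop("'B0_uT' must be positive", call. = FALSE)
  if (B1_uT < 0) stop("'B1_uT' must be non-negative", call. = FALSE)
  structure(list(B0_uT = B0_uT, B1_uT = B1_uT, dB0_uT = dB0_uT),
            class = "field_protocol")
}

#' @export
print.field_protocol <- function(x, ...) {
  cat(sprintf("<field_protocol> B0 = %g uT, B1 = %g uT, dB0 = %g uT\n",
              x$B0_uT, x$B1_uT, x$dB0_uT))
  invisible(x)
}

.check_taylor_bound <- function(amp, B0, what) {
  if (abs(amp) > 0.2 * B0) {
    stop(sprintf("Taylor-based estimate requires |%s| <= 0.2 * B0 (got %g vs B0 = %g uT)",
                 what, amp, B0), call. = FALSE)
  }
}

.new_mfe_result <- function(value, method, tau_s, phi_ref) {
  structure(list(value = value, ppm = value * 1e6, method = method,
                 tau_s = tau_s, phi_ref = phi_ref),
            class = "mfe_result")
}

#' @export
print.mfe_result <- function(x, ...) {
  # 2 significant figures in the printed view; full precision kept in $value
  cat(sprintf("<mfe_result> %s ppm (method %s, tau = %g s, Phi_ref = %.6f)\n",
              format(signif(x$ppm, 2)), x$method, x$tau_s, x$phi_ref))
  invisible(x)
}

# ---- sweeps ---------------------------------------------------------------

.new_sweep_result <- function(axis_name, axis_values, values, metadata = list()) {
  if (length(axis_values) != length(values)) {
    stop("axis and value lengths differ", call. = FALSE)
  }
  if (is.unsorted(axis_values, strictly = TRUE) &&
      is.unsorted(rev(axis_values), strictly = TRUE)) {
    stop("'axis_values' must be strictly monotone", call. = FALSE)
  }
  structure(list(axis_name = axis_name, axis_values = axis_values,
                 values = values, metadata = metadata),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s: %d points in [%g, %g]\n", x$axis_name,
              length(x$axis_values), min(x$axis_values), max(x$axis_values)))
  if (length(x$metadata)) {
    cat("  ", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                    sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Triplet yield as a function of static field strength
#'
#' Evaluates \eqn{\Phi_T} at each field of a grid, with a fresh spectral
#' decomposition per field.  At lifetimes around 1 us the curve shows the
#' characteristic biphasic shape: a low-field-effect "bump" (a small rise of
#' \eqn{\Phi_T} below ~1 mT) followed by a larger decrease that levels out by
#' a few mT.
#'
#' @param system A [radical_pair_system()].
#' @param kin A [reaction_kinetics()].
#' @param B_grid_uT Vector of field values, uT (>= 0), strictly monotone.
#' @param cache Optional spectral cache (internal reuse).
#' @return A `sweep_result` with `axis_name = "B0_uT"`.
#' @examples
#' sw <- phi_vs_field(rp_preset("FAD-Z"), reaction_kinetics(tau = 1e-6, r = 1e6),
#'                    c(0, 50, 500, 5000))
#' sw$values
#' @export
phi_vs_field <- function(system, kin, B_grid_uT, cache = NULL) {
  if (length(B_grid_uT) == 0) stop("empty field grid", call. = FALSE)
  if (any(B_grid_uT < 0)) stop("fields must be >= 0", call. = FALSE)
  if (is.null(cache)) cache <- .spectral_cache(system)
  vals <- vapply(B_grid_uT, function(b) .phi_cached(cache, b, kin$k, kin$r),
                 numeric(1))
  .new_sweep_result("B0_uT", B_grid_uT, vals,
                    list(system = system$name, k = kin$k, r = kin$r,
                         quantity = "Phi_T"))
}

# ---- derivatives ----------------------------------------------------------

# central difference of given order at step h, using cached yields
.central_diff <- function(cache, B0, k, r, h, order) {
  if (order == 1L) {
    (.phi_cached(cache, B0 + h, k, r) - .phi_cached(cache, B0 - h, k, r)) /
      (2 * h)
  } else {
    (.phi_cached(cache, B0 + h, k, r) - 2 * .phi_cached(cache, B0, k, r) +
       .phi_cached(cache, B0 - h, k, r)) / h^2
  }
}

# Richardson-extrapolated derivative; both central differences have O(h^2)
# leading error, so (4 D(h/2) - D(h)) / 3 cancels it.
# Returns c(coarse, fine) extrapolants built from steps (h, h/2) and (h/2, h/4).
.richardson_pair <- function(cache, B0, k, r, h, order) {
  d1 <- .central_diff(cache, B0, k, r, h,     order)
  d2 <- .central_diff(cache, B0, k, r, h / 2, order)
  d3 <- .central_diff(cache, B0, k, r, h / 4, order)
  c((4 * d2 - d1) / 3, (4 * d3 - d2) / 3)
}

#' Field derivatives of the triplet yield
#'
#' First or second derivative of \eqn{\Phi_T(B)} at B0, by Richardson-
#' extrapolated central finite differences with default step h = 0.05 uT.
#' The value is reported only if the two finest extrapolants (built from
#' steps h, h/2 and h/2, h/4) agree to `tol` relative; otherwise an error of
#' class `radicalpair_accuracy_error` is signalled carrying both estimates.
#'
#' @param system A [radical_pair_system()].
#' @param kin A [reaction_kinetics()].
#' @param B0_uT Field at which to differentiate, uT (> 0).
#' @param order Derivative order, 1 or 2.
#' @param h Base finite-difference step, uT.
#' @param tol Relative agreement required between the two finest estimates.
#' @param cache Optional spectral cache (internal reuse).
#' @return The derivative, per uT (order 1) or per uT^2 (order 2).
#' @examples
#' kin <- reaction_kinetics(tau = 1e-6, r = 1e6)
#' phi_derivative(rp_preset("FAD-Z"), kin, 50, order = 1)
#' @export
phi_derivative <- function(system, kin, B0_uT, order = 1L, h = 0.05,
                           tol = 1e-3, cache = NULL) {
  if (B0_uT <= 0) stop("'B0_uT' must be positive", call. = FALSE)
  if (!order %in% c(1L, 2L)) stop("'order' must be 1 or 2", call. = FALSE)
  if (is.null(cache)) cache <- .spectral_cache(system)
  est <- .richardson_pair(cache, B0_uT, kin$k, kin$r, h, order)
  # absolute floor: yields are O(1), so differences below ~1e-12 (order 1)
  # or ~1e-10/h (order 2) are numerically zero, not non-convergent
  floor_abs <- if (order == 1L) 1e-12 else 1e-10
  if (abs(est[2] - est[1]) > max(tol * abs(est[2]), floor_abs)) {
    cond <- structure(
      class = c("radicalpair_accuracy_error", "error", "condition"),
      list(message = sprintf(
        "derivative stencil did not converge: estimates %.6e and %.6e",
        est[1], est[2]),
        call = sys.call(-1), estimates = est))
    stop(cond)
  }
  est[2]
}

# unguarded two-level Richardson derivative for grid scans, where points far
# from the extremum may sit at the noise floor without affecting the result
.phi_deriv_fast <- function(cache, B0, k, r, h, order) {
  d1 <- .central_diff(cache, B0, k, r, h,     order)
  d2 <- .central_diff(cache, B0, k, r, h / 2, order)
  (4 * d2 - d1) / 3
}

# ---- ELF and GMF effects --------------------------------------------------

#' ELF magnetic field effect, Taylor-series estimate
#'
#' Fractional change of the triplet yield caused by a weak ELF field of peak
#' amplitude B1 aligned with the static field B0, from the second-order
#' Taylor expansion of \eqn{\Phi_T(B)} about B0:
#' \deqn{\mathrm{mfe}_{ELF} \approx \frac{1}{4} B_1^2
#'   \frac{\Phi_T^{(2)}(B_0)}{\Phi_T(B_0)}.}
#' The effect is proportional to the curvature of the yield curve and to the
#' square of the ELF amplitude; it vanishes where the yield is locally linear
#' in field.  Requires `B1 <= 0.2 B0` (the expansion assumes B1 << B0).
#'
#' @param system A [radical_pair_system()].
#' @param kin A [reaction_kinetics()].
#' @param proto A [field_protocol()].
#' @param cache Optional spectral cache (internal reuse).
#' @return An `mfe_result`; `$ppm` is the fractional change in parts per
#'   million, negative where the yield curve is concave downward.
#' @examples
#' mfe_elf_taylor(rp_preset("FAD-Z"), reaction_kinetics(tau = 1e-6, r = 1e6),
#'                field_protocol(50, 1))
#' @export
mfe_elf_taylor <- function(system, kin, proto, cache = NULL) {
  stopifnot(inherits(proto, "field_protocol"))
  .check_taylor_bound(proto$B1_uT, proto$B0_uT, "B1")
  if (is.null(cache)) cache <- .spectral_cache(system)
  phi0 <- .phi_cached(cache, proto$B0_uT, kin$k, kin$r)
  if (proto$B1_uT == 0) {
    return(.new_mfe_result(0, "taylor", kin$tau, phi0))
  }
  d2 <- phi_derivative(system, kin, proto$B0_uT, order = 2L, cache = cache)
  .new_mfe_result(0.25 * proto$B1_uT^2 * d2 / phi0, "taylor", kin$tau, phi0)
}

#' ELF magnetic field effect by phase-average quadrature
#'
#' Direct evaluation of the phase average
#' \deqn{\bar{\Phi}_T = \frac{1}{\pi} \int_0^\pi \Phi_T(B_0 + B_1 \cos\alpha)
#'   \, d\alpha}
#' by Gauss-Legendre quadrature (20 nodes, doubled until the relative change
#' of the resulting mfe is below `tol`), then
#' \eqn{\mathrm{mfe}_{ELF} = (\bar{\Phi}_T - \Phi_T(B_0)) / \Phi_T(B_0)}.
#' Unlike [mfe_elf_taylor()] this makes no small-amplitude assumption beyond
#' `B1 < B0`.
#'
#' @inheritParams mfe_elf_taylor
#' @param n_nodes Starting number of quadrature nodes.
#' @param tol Relative convergence tolerance on the mfe under node doubling.
#' @param max_nodes Node count at which non-convergence becomes an error.
#' @return An `mfe_result` with method `"quadrature"`.
#' @examples
#' mfe_elf_quadrature(rp_preset("FAD-Z"), reaction_kinetics(tau = 1e-6, r = 1e6),
#'                    field_protocol(50, 1))
#' @export
mfe_elf_quadrature <- function(system, kin, proto, n_nodes = 20L, tol = 1e-4,
                               max_nodes = 320L, cache = NULL) {
  stopifnot(inherits(proto, "field_protocol"))
  if (proto$B1_uT >= proto$B0_uT) stop("requires B1 < B0", call. = FALSE)
  if (is.null(cache)) cache <- .spectral_cache(system)
  phi0 <- .phi_cached(cache, proto$B0_uT, kin$k, kin$r)
  if (proto$B1_uT == 0) {
    return(.new_mfe_result(0, "quadrature", kin$tau, phi0))
  }
  mfe_prev <- NULL
  n <- n_nodes
  while (n <= max_nodes) {
    gl <- pracma::gaussLegendre(n, 0, pi)
    phis <- vapply(gl$x, function(alpha) {
      .phi_cached(cache, proto$B0_uT + proto$B1_uT * cos(alpha), kin$k, kin$r)
    }, numeric(1))
    phi_bar <- sum(gl$w * phis) / pi
    mfe <- (phi_bar - phi0) / phi0
    if (!is.null(mfe_prev) &&
        abs(mfe - mfe_prev) <= tol * max(abs(mfe), 1e-15)) {
      return(.new_mfe_result(mfe, "quadrature", kin$tau, phi0))
    }
    mfe_prev <- mfe
    n <- n * 2L
  }
  cond <- structure(
    class = c("radicalpair_accuracy_error", "error", "condition"),
    list(message = sprintf(
      "phase-average quadrature did not converge below %d nodes", max_nodes),
      call = sys.call(-1), estimates = mfe_prev))
  stop(cond)
}

#' Geomagnetic field effect
#'
#' Fractional change of the triplet yield when the static field changes from
#' B0 to B0 + dB0 with no ELF field present.  Method `"exact_difference"`
#' evaluates \eqn{(\Phi_T(B_0 + \Delta B_0) - \Phi_T(B_0)) / \Phi_T(B_0)}
#' directly; method `"linear"` uses the first-order expansion
#' \eqn{\Delta B_0 \, \Phi_T^{(1)}(B_0) / \Phi_T(B_0)}, which is linear in
#' dB0 (contrast the quadratic B1-dependence of the ELF effect).
#'
#' @inheritParams mfe_elf_taylor
#' @param method `"exact_difference"` or `"linear"`.
#' @return An `mfe_result`.
#' @examples
#' mfe_gmf(rp_preset("FAD-Z"), reaction_kinetics(tau = 1e-6, r = 1e6),
#'         field_protocol(50, 1, -1))
#' @export
mfe_gmf <- function(system, kin, proto,
                    method = c("exact_difference", "linear"), cache = NULL) {
  stopifnot(inherits(proto, "field_protocol"))
  method <- match.arg(method)
  dB0 <- proto$dB0_uT
  if (abs(dB0) >= proto$B0_uT) stop("requires |dB0| < B0", call. = FALSE)
  if (is.null(cache)) cache <- .spectral_cache(system)
  phi0 <- .phi_cached(cache, proto$B0_uT, kin$k, kin$r)
  if (dB0 == 0) return(.new_mfe_result(0, method, kin$tau, phi0))
  value <- if (method == "exact_difference") {
    (.phi_cached(cache, proto$B0_uT + dB0, kin$k, kin$r) - phi0) / phi0
  } else {
    .check_taylor_bound(dB0, proto$B0_uT, "dB0")
    d1 <- phi_derivative(system, kin, proto$B0_uT, order = 1L, cache = cache)
    dB0 * d1 / phi0
  }
  .new_mfe_result(value, method, kin$tau, phi0)
}

# ---- lifetime sweeps and extrema ------------------------------------------

# signed mfe value at a single lifetime, using the fast (unguarded) derivative
.mfe_at_tau <- function(cache, mode, tau, r, proto, h = 0.05) {
  k <- 1 / tau
  phi0 <- .phi_cached(cache, proto$B0_uT, k, r)
  if (mode == "elf") {
    d2 <- .phi_deriv_fast(cache, proto$B0_uT, k, r, h, 2L)
    0.25 * proto$B1_uT^2 * d2 / phi0
  } else {
    d1 <- .phi_deriv_fast(cache, proto$B0_uT, k, r, h, 1L)
    proto$dB0_uT * d1 / phi0
  }
}

#' ELF or geomagnetic effect as a function of radical pair lifetime
#'
#' Sweeps the lifetime \eqn{\tau = 1/k} at fixed relaxation rate and field
#' protocol, returning the signed fractional yield change in ppm at each
#' lifetime.  Spectral decompositions are computed once per field value and
#' shared across the whole sweep.
#'
#' @param system A [radical_pair_system()].
#' @param r Spin relaxation rate constant, s\eqn{^{-1}}.
#' @param proto A [field_protocol()].
#' @param taus Vector of lifetimes, s, strictly monotone.
#' @param mode `"elf"` or `"gmf"`.
#' @param method For `"elf"`: `"taylor"` (default) or `"quadrature"`.
#' @param cache Optional spectral cache (internal reuse).
#' @return A `sweep_result` with `axis_name = "tau_s"` and values in ppm.
#' @examples
#' sw <- mfe_vs_lifetime(rp_preset("FAD-Z"), 1e6, field_protocol(50, 1),
#'                       taus = 10^seq(-8, -5, length.out = 7))
#' sw$values
#' @export
mfe_vs_lifetime <- function(system, r, proto, taus, mode = c("elf", "gmf"),
                            method = c("taylor", "quadrature"), cache = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (length(taus) == 0) stop("empty lifetime grid", call. = FALSE)
  if (is.null(cache)) cache <- .spectral_cache(system)
  vals <- if (mode == "elf" && method == "quadrature") {
    vapply(taus, function(tau) {
      mfe_elf_quadrature(system, reaction_kinetics(tau = tau, r = r), proto,
                         cache = cache)$value
    }, numeric(1))
  } else {
    vapply(taus, function(tau) .mfe_at_tau(cache, mode, tau, r, proto),
           numeric(1))
  }
  .new_sweep_result("tau_s", taus, vals * 1e6,
                    list(system = system$name, r = r, mode = mode,
                         method = if (mode == "elf") method else "linear",
                         B0_uT = proto$B0_uT, B1_uT = proto$B1_uT,
                         dB0_uT = proto$dB0_uT, quantity = "mfe_ppm"))
}

#' Largest magnetic field effect over a range of lifetimes
#'
#' Scans a log-spaced lifetime grid (>= 25 points per decade), locates the
#' lifetime of largest |mfe|, and refines it by golden-section search to a
#' relative tolerance of 1e-3 in \eqn{\tau}.  The signed mfe at the extremum
#' is returned; ELF and GMF extrema found this way generally occur at
#' (slightly) different lifetimes.
#'
#' @param system A [radical_pair_system()].
#' @param r Spin relaxation rate constant, s\eqn{^{-1}}.
#' @param proto A [field_protocol()].
#' @param mode `"elf"` (uses the Taylor estimate) or `"gmf"` (linearised).
#' @param tau_range Lifetime range, s, `c(min, max)` with `0 < min < max`.
#'   Default 1 ns to 1 ms.
#' @param points_per_decade Grid density of the initial scan.
#' @param cache Optional spectral cache (internal reuse).
#' @return An object of class `lifetime_extremum`: list with `tau_star` (s),
#'   `mfe` (an `mfe_result`, computed at `tau_star` with the convergence-
#'   guarded derivative), `mode`, `degenerate` (TRUE when the response is
#'   flat, |mfe| < 1e-12 everywhere, in which case `tau_star` is `NA`), and
#'   `grid` (data frame of the scanned curve, ppm).
#' @examples
#' ext <- lifetime_extremum(rp_preset("FAD-Z"), 1e6, field_protocol(50, 1),
#'                          mode = "elf")
#' ext$mfe$ppm  # about -14
#' @export
lifetime_extremum <- function(system, r, proto, mode = c("elf", "gmf"),
                              tau_range = c(1e-9, 1e-3),
                              points_per_decade = 25L, cache = NULL) {
  mode <- match.arg(mode)
  if (length(tau_range) != 2L || any(tau_range <= 0) ||
      tau_range[1] >= tau_range[2]) {
    stop("'tau_range' must be positive with min < max", call. = FALSE)
  }
  if (is.null(cache)) cache <- .spectral_cache(system)
  lo <- log10(tau_range[1]); hi <- log10(tau_range[2])
  n <- max(2L, ceiling((hi - lo) * points_per_decade) + 1L)
  taus <- 10^seq(lo, hi, length.out = n)
  vals <- vapply(taus, function(tau) .mfe_at_tau(cache, mode, tau, r, proto),
                 numeric(1))
  grid <- data.frame(tau_s = taus, mfe_ppm = vals * 1e6)

  if (all(abs(vals) < 1e-12)) {
    warning("flat response over the lifetime range; no extremum", call. = FALSE)
    phi0 <- .phi_cached(cache, proto$B0_uT, 1 / taus[1], r)
    return(structure(list(tau_star = NA_real_,
                          mfe = .new_mfe_result(0, if (mode == "elf") "taylor"
                                                else "linear", NA_real_, phi0),
                          mode = mode, degenerate = TRUE, grid = grid),
                     class = "lifetime_extremum"))
  }

  i <- which.max(abs(vals))
  bracket <- log10(taus[c(max(1L, i - 1L), min(n, i + 1L))])
  opt <- stats::optimize(
    function(lt) abs(.mfe_at_tau(cache, mode, 10^lt, r, proto)),
    interval = bracket, maximum = TRUE, tol = log10(1 + 1e-3))
  tau_star <- 10^opt$maximum
  kin <- reaction_kinetics(tau = tau_star, r = r)
  mfe <- if (mode == "elf") {
    mfe_elf_taylor(system, kin, proto, cache = cache)
  } else {
    mfe_gmf(system, kin, proto, method = "linear", cache = cache)
  }
  structure(list(tau_star = tau_star, mfe = mfe, mode = mode,
                 degenerate = FALSE, grid = grid),
            class = "lifetime_extremum")
}

#' @export
print.lifetime_extremum <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<lifetime_extremum> %s: flat response (degenerate)\n", x$mode))
  } else {
    cat(sprintf("<lifetime_extremum> %s: %s ppm at tau* = %.3g s\n",
                x$mode, format(signif(x$mfe$ppm, 2)), x$tau_star))
  }
  invisible(x)
}

#' Ratio of maximal geomagnetic to maximal ELF effects
#'
#' Computes \eqn{\Omega = \mathrm{mfe}_{GMF}^{max} / \mathrm{mfe}_{ELF}^{max}},
#' each extremised independently over the lifetime range (their optimal
#' lifetimes may differ).  Since the ELF effect scales as \eqn{B_1^2} and the
#' geomagnetic effect linearly in \eqn{\Delta B_0}, \eqn{\Omega} scales as
#' \eqn{\Delta B_0 / B_1^2}.
#'
#' @inheritParams lifetime_extremum
#' @param B0_uT,B1_uT,dB0_uT Field protocol components.
#' @return A list with `omega` (dimensionless), `elf` and `gmf` (the two
#'   `lifetime_extremum` objects).
#' @examples
#' omega_ratio(rp_preset("FAD-Z"), 1e6)$omega  # about 150
#' @export
omega_ratio <- function(system, r = 1e6, B0_uT = 50, B1_uT = 1, dB0_uT = -1,
                        tau_range = c(1e-9, 1e-3), cache = NULL) {
  proto <- field_protocol(B0_uT, B1_uT, dB0_uT)
  if (is.null(cache)) cache <- .spectral_cache(system)
  elf <- lifetime_extremum(system, r, proto, "elf", tau_range, cache = cache)
  gmf <- lifetime_extremum(system, r, proto, "gmf", tau_range, cache = cache)
  if (elf$degenerate || abs(elf$mfe$value) < .Machine$double.xmin) {
    stop("maximal ELF effect is zero; ratio undefined", call. = FALSE)
  }
  list(omega = gmf$mfe$value / elf$mfe$value, elf = elf, gmf = gmf)
}

#' Static field change equivalent to an ELF field
#'
#' Given the ratio \eqn{\Omega} of maximal geomagnetic to maximal ELF
#' effects, the static field offset that produces the same fractional yield
#' change as an ELF field of peak amplitude B1 is \eqn{\Delta B_0 = -B_1
#' \cdot 10^3 / \Omega} nT (the sign matching the ELF effect, since the
#' reference geomagnetic offset is negative).
#'
#' @param omega The ratio from [omega_ratio()] (nonzero).
#' @param B1_uT ELF peak amplitude, uT.
#' @return Equivalent static field change, nT.
#' @examples
#' equivalent_static_change(280, 1)  # about -3.6 nT
#' @export
equivalent_static_change <- function(omega, B1_uT = 1) {
  if (!is.numeric(omega) || omega == 0) {
    stop("'omega' must be nonzero", call. = FALSE)
  }
  -B1_uT * 1e3 / omega
}
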