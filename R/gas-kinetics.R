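#' Construct a pressure trace for one incubation bottle
#'
#' A pressure trace is the raw record of one bottle in an automated gas
#' production system: gauge pressure (psi above ambient) sampled on a fixed
#' grid, together with the pressure released at each vent event. Venting
#' resets the gauge to zero at the vent timestamp, so the cumulative gas is
#' reconstructed as current gauge pressure plus the sum of all vented
#' pressures ([cumulative_gas()]).
#'
#' @param bottle_id Identifier for the bottle.
#' @param time_h Reading times in hours, strictly increasing, starting at 0.
#' @param psi Gauge pressure readings in psi (>= 0), one per time point;
#'   the reading at time 0 must be 0.
#' @param vented_psi Pressure released by a vent at each time point (0 where
#'   no vent occurred).
#' @param substrate_mass_g As-weighed substrate mass in g.
#' @param dm_fraction Dry matter fraction of the substrate, in \[0, 1\].
#' @param is_blank Logical; blanks contain no substrate and their gas is
#'   kept on a per-bottle (mL) basis.
#' @param final_ph Optional pH measured at the end of the incubation.
#' @return An object of class `pressure_trace`.
#' @seealso [cumulative_gas()], [simulate_incubation()]
#' @export
pressure_trace <- function(bottle_id, time_h, psi, vented_psi = 0,
                           substrate_mass_g = NA_real_, dm_fraction = 1,
                           is_blank = FALSE, final_ph = NA_real_) {
  time_h <- as.numeric(time_h)
  psi <- as.numeric(psi)
  vented_psi <- rep_len(as.numeric(vented_psi), length(time_h))
  if (length(time_h) != length(psi)) {
    stop("time_h and psi must have the same length", call. = FALSE)
  }
  if (length(time_h) < 1L || time_h[1L] != 0) {
    stop("trace must start at time 0", call. = FALSE)
  }
  if (any(diff(time_h) <= 0)) {
    stop("reading times must be strictly increasing", call. = FALSE)
  }
  if (psi[1L] != 0) {
    stop("first reading must be 0 psi (gauge zeroed at start)", call. = FALSE)
  }
  if (any(psi < 0) || any(vented_psi < 0)) {
    stop("gauge and vented pressures must be non-negative", call. = FALSE)
  }
  if (!is_blank) {
    if (!is.finite(substrate_mass_g) || substrate_mass_g <= 0) {
      stop("substrate_mass_g must be positive for non-blank bottles",
           call. = FALSE)
    }
    if (!is.finite(dm_fraction) || dm_fraction <= 0 || dm_fraction > 1) {
      stop("dm_fraction must be in (0, 1]", call. = FALSE)
    }
  }
  structure(
    list(
      bottle_id = bottle_id,
      is_blank = isTRUE(is_blank),
      substrate_mass_g = substrate_mass_g,
      dm_fraction = dm_fraction,
      final_ph = final_ph,
      readings = data.frame(time_h = time_h, psi = psi,
                            vented_psi = vented_psi)
    ),
    class = "pressure_trace"
  )
}

#' @export
print.pressure_trace <- function(x, ...) {
  r <- x$readings
  cat(sprintf("Pressure trace '%s'%s: %d readings over %.1f h, %d vents\n",
              as.character(x$bottle_id),
              if (x$is_blank) " (blank)" else "",
              nrow(r), max(r$time_h), sum(r$vented_psi > 0)))
  if (!x$is_blank) {
    cat(sprintf("  substrate: %.3f g as-weighed, DM fraction %.3f\n",
                x$substrate_mass_g, x$dm_fraction))
  }
  invisible(x)
}

#' Convert pressure to moles of gas by the ideal gas law
#'
#' n = p V / (R T) for a fixed headspace: the moles of gas that raise the
#' gauge pressure of the bottle headspace by `pressure_kpa`.
#'
#' @param pressure_kpa Gauge pressure in kPa (>= 0); vectorised.
#' @param constants An [incubation_constants()] object.
#' @return Moles of gas.
#' @examples
#' pressure_to_moles(5.17107, incubation_constants())
#' @export
pressure_to_moles <- function(pressure_kpa, constants = incubation_constants()) {
  stopifnot(inherits(constants, "incubation_constants"))
  if (any(pressure_kpa < 0, na.rm = TRUE)) {
    stop("pressure must be non-negative", call. = FALSE)
  }
  pressure_kpa * constants$headspace_l /
    (constants$gas_constant * constants$temperature_k)
}

#' Convert moles of gas to volume at standard conditions
#'
#' One mole of ideal gas occupies 22,400 mL at 273.15 K and 101.325 kPa.
#'
#' @param n Moles of gas (>= 0); vectorised.
#' @param constants An [incubation_constants()] object.
#' @return Gas volume in mL.
#' @export
moles_to_ml <- function(n, constants = incubation_constants()) {
  stopifnot(inherits(constants, "incubation_constants"))
  if (any(n < 0, na.rm = TRUE)) stop("moles must be non-negative", call. = FALSE)
  n * constants$molar_volume_ml
}

#' Reconstruct the cumulative gas curve from a vented pressure trace
#'
#' At each reading the cumulative gauge-equivalent pressure is the current
#' gauge reading plus the sum of all pressure released by vents up to and
#' including that reading. This is converted psi -> kPa -> moles -> mL and,
#' for substrate bottles, normalised per gram of substrate dry matter.
#' Blanks are kept on a per-bottle mL basis so they can be subtracted before
#' DM normalisation ([blank_correct()]).
#'
#' Sensor noise can make the reconstruction dip slightly; dips within
#' `tol_psi` are absorbed by a running maximum, while a larger drop without
#' a vent event is an inconsistent trace and raises an error.
#'
#' @param trace A [pressure_trace()].
#' @param constants An [incubation_constants()] object.
#' @param tol_psi Largest admissible spurious decrease in the reconstructed
#'   cumulative pressure, in psi.
#' @return An object of class `gas_curve`: a data frame with columns
#'   `time_h` and `gas` (mL/g DM for substrate bottles, mL/bottle for
#'   blanks), with attributes `bottle_id`, `per_g_dm` and `g_dm`.
#' @export
cumulative_gas <- function(trace, constants = incubation_constants(),
                           tol_psi = 0.05) {
  stopifnot(inherits(trace, "pressure_trace"))
  r <- trace$readings
  cum_psi <- r$psi + cumsum(r$vented_psi)
  drops <- diff(cum_psi)
  if (any(drops < -tol_psi)) {
    k <- which(drops < -tol_psi)[1L] + 1L
    stop(sprintf(
      "inconsistent trace '%s': cumulative pressure drops by %.3f psi at t = %.3f h without a vent event",
      as.character(trace$bottle_id), -drops[k - 1L], r$time_h[k]),
      call. = FALSE)
  }
  cum_psi <- cummax(cum_psi)
  ml <- moles_to_ml(
    pressure_to_moles(cum_psi * constants$psi_to_kpa, constants), constants)
  if (trace$is_blank) {
    g_dm <- NA_real_
    gas <- ml
  } else {
    g_dm <- trace$substrate_mass_g * trace$dm_fraction
    gas <- ml / g_dm
  }
  structure(
    data.frame(time_h = r$time_h, gas = gas),
    bottle_id = trace$bottle_id,
    per_g_dm = !trace$is_blank,
    g_dm = g_dm,
    class = c("gas_curve", "data.frame")
  )
}

#' Subtract the mean blank gas production from a substrate curve
#'
#' Blank bottles (inoculum and buffer, no substrate) produce gas of their
#' own; their timepoint-wise mean volume (mL/bottle, interpolated linearly
#' onto the curve's time grid where grids differ) is subtracted from the
#' substrate bottle's gas before DM normalisation, i.e. the correction
#' applied on the mL/g DM scale is mean blank mL divided by the bottle's
#' grams of substrate DM. Corrected values may go negative; they are kept
#' and counted in the `n_negative` attribute rather than clamped.
#'
#' @param curve A `gas_curve` from a substrate bottle (mL/g DM).
#' @param blanks A list of `gas_curve` objects from blank bottles
#'   (mL/bottle). An empty list leaves the curve unchanged with a warning.
#' @return The corrected `gas_curve` (attribute `blank_corrected = TRUE`).
#' @export
blank_correct <- function(curve, blanks) {
  stopifnot(inherits(curve, "gas_curve"))
  if (inherits(blanks, "gas_curve")) blanks <- list(blanks)
  if (length(blanks) == 0L) {
    warning("no blank curves supplied; returning curve unchanged")
    return(curve)
  }
  if (!isTRUE(attr(curve, "per_g_dm"))) {
    stop("blank_correct() expects a substrate curve in mL/g DM", call. = FALSE)
  }
  g_dm <- attr(curve, "g_dm")
  blank_ml <- vapply(blanks, function(b) {
    stopifnot(inherits(b, "gas_curve"))
    if (isTRUE(attr(b, "per_g_dm"))) {
      stop("blank curves must be on a per-bottle (mL) basis", call. = FALSE)
    }
    if (length(b$time_h) == length(curve$time_h) &&
        all(b$time_h == curve$time_h)) {
      b$gas
    } else {
      stats::approx(b$time_h, b$gas, xout = curve$time_h, rule = 2)$y
    }
  }, numeric(nrow(curve)))
  mean_blank <- rowMeans(blank_ml)
  out <- curve
  out$gas <- curve$gas - mean_blank / g_dm
  attr(out, "blank_corrected") <- TRUE
  attr(out, "n_negative") <- sum(out$gas < 0)
  out
}

#' Monophasic sigmoidal gas production model
#'
#' G(t) = A / (1 + (B/t)^C): the single-phase member of the summed
#' sigmoidal degradation family. A is the asymptotic (maximum) gas
#' production in mL/g DM, B the time in h at which half of A is reached
#' (G(B) = A/2 exactly), and C a dimensionless shape constant. G(0) is 0 by
#' continuity (t appears in a denominator exponent).
#'
#' @param t Incubation time in h (>= 0); vectorised.
#' @param A Asymptotic gas production, mL/g DM (> 0).
#' @param B Half-time, h (> 0).
#' @param C Shape constant (> 0).
#' @return Gas produced at `t`, mL/g DM.
#' @examples
#' monophasic_gas(c(0, 5, 10, 48), A = 150, B = 10, C = 1.5)
#' @export
monophasic_gas <- function(t, A, B, C) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (any(A <= 0) || any(B <= 0) || any(C <= 0)) {
    stop("A, B and C must be positive", call. = FALSE)
  }
  g <- A / (1 + (B / t)^C)
  g[t == 0] <- 0
  g
}

#' Time of maximum rate of gas production
#'
#' t_RM = B (C - 1)^(1/C), the inflection point of the monophasic curve.
#' For C <= 1 the curve has no interior inflection and t_RM is undefined;
#' `NA` is returned for those elements.
#'
#' @param B Half-time in h (> 0); vectorised.
#' @param C Shape constant (> 0); vectorised.
#' @return t_RM in h, `NA` where C <= 1. For C = 2, t_RM equals B exactly.
#' @examples
#' t_rm(8.3, 1.62)
#' t_rm(10, 2)     # equals B
#' t_rm(10, 0.9)   # NA: no interior inflection
#' @export
t_rm <- function(B, C) {
  n <- max(length(B), length(C))
  B <- rep_len(B, n)
  C <- rep_len(C, n)
  if (any(B <= 0) || any(!is.finite(B))) {
    stop("B must be positive", call. = FALSE)
  }
  if (any(C <= 0) || any(!is.finite(C))) {
    stop("C must be positive", call. = FALSE)
  }
  out <- rep(NA_real_, n)
  ok <- C > 1
  out[ok] <- B[ok] * (C[ok] - 1)^(1 / C[ok])
  out
}

#' Dry matter disappearance
#'
#' 100 (feed in - residue) / feed in, both on a dry matter basis. Used for
#' both the in vitro incubation (48 h bottle residue) and the mobile bag
#' residue. Values outside \[0, 100\] are kept but trigger a warning: they
#' indicate a weighing problem, not an arithmetic one.
#'
#' @param feed_in_g Feed put in, g DM (> 0); vectorised.
#' @param residue_g Residue recovered, g DM (>= 0); vectorised.
#' @return Disappearance in percent.
#' @examples
#' dm_disappearance(1.1 * 0.93, 0.306)
#' @export
dm_disappearance <- function(feed_in_g, residue_g) {
  if (any(!is.finite(feed_in_g)) || any(feed_in_g <= 0)) {
    stop("feed_in_g must be positive", call. = FALSE)
  }
  if (any(residue_g < 0, na.rm = TRUE)) {
    stop("residue_g must be non-negative", call. = FALSE)
  }
  d <- 100 * (feed_in_g - residue_g) / feed_in_g
  if (any(d < 0 | d > 100, na.rm = TRUE)) {
    warning("disappearance outside [0, 100]% for ",
            sum(d < 0 | d > 100, na.rm = TRUE), " value(s)")
  }
  d
}
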