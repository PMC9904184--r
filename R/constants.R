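#' Physical constants and settings for an in vitro incubation
#'
#' Bundles the quantities needed to turn a gauge-pressure reading from a
#' sealed incubation bottle into a gas volume: headspace volume, incubation
#' temperature, the gas constant, the molar volume of an ideal gas at
#' standard conditions, the psi-to-kPa conversion factor, and the pressure
#' threshold at which the module vents the bottle.
#'
#' The defaults describe a 250 mL bottle charged with 66 mL buffer and
#' 34 mL caecal inoculum (headspace 0.150 L, substrate volume ignored),
#' incubated at 39 degrees C, vented whenever gauge pressure exceeds
#' 0.75 psi.
#'
#' @param headspace_l Headspace volume of the bottle in litres.
#' @param temperature_k Absolute incubation temperature in kelvin.
#' @param gas_constant Gas constant in L kPa K^-1 mol^-1.
#' @param molar_volume_ml Volume in mL occupied by one mole of ideal gas at
#'   standard conditions (273.15 K, 101.325 kPa).
#' @param psi_to_kpa kPa per psi.
#' @param vent_threshold_psi Gauge pressure in psi above which the bottle is
#'   vented.
#' @return An object of class `incubation_constants` (a named list).
#' @examples
#' incubation_constants()
#' incubation_constants(temperature_k = 310.15)
#' @export
incubation_constants <- function(headspace_l = 0.150,
                                 temperature_k = 312.15,
                                 gas_constant = 8.314472,
                                 molar_volume_ml = 22400,
                                 psi_to_kpa = 6.894757,
                                 vent_threshold_psi = 0.75) {
  x <- list(
    headspace_l = headspace_l,
    temperature_k = temperature_k,
    gas_constant = gas_constant,
    molar_volume_ml = molar_volume_ml,
    psi_to_kpa = psi_to_kpa,
    vent_threshold_psi = vent_threshold_psi
  )
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid incubation constants: '", nm,
           "' must be a single positive finite number", call. = FALSE)
    }
  }
  class(x) <- "incubation_constants"
  x
}

#' @export
print.incubation_constants <- function(x, ...) {
  cat("Incubation constants:\n")
  cat(sprintf("  headspace volume : %.4g L\n", x$headspace_l))
  cat(sprintf("  temperature      : %.2f K\n", x$temperature_k))
  cat(sprintf("  gas constant     : %.6f L kPa/K/mol\n", x$gas_constant))
  cat(sprintf("  molar volume     : %g mL/mol\n", x$molar_volume_ml))
  cat(sprintf("  psi -> kPa       : %.6f\n", x$psi_to_kpa))
  cat(sprintf("  vent threshold   : %.2f psi\n", x$vent_threshold_psi))
  invisible(x)
}

# run expr with a temporary RNG state seeded by `seed`; restores the caller's
# state afterwards so generators are pure functions of (scenario, seed)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
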