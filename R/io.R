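#' Flatten pressure traces to the CSV schemas
#'
#' Two flat tables: `traces` with one row per reading (`bottle_id`,
#' `time_h`, `psi`, `vented_psi`) and `bottles` with one row of metadata
#' per bottle.
#'
#' @param traces A list of [pressure_trace()] objects.
#' @return List of two data frames, `traces` and `bottles`.
#' @export
traces_to_df <- function(traces) {
  stopifnot(is.list(traces),
            all(vapply(traces, inherits, TRUE, "pressure_trace")))
  tr <- do.call(rbind, lapply(traces, function(x) {
    data.frame(bottle_id = as.character(x$bottle_id), x$readings,
               stringsAsFactors = FALSE)
  }))
  bt <- do.call(rbind, lapply(traces, function(x) {
    data.frame(bottle_id = as.character(x$bottle_id), is_blank = x$is_blank,
               substrate_mass_g = x$substrate_mass_g,
               dm_fraction = x$dm_fraction, final_ph = x$final_ph,
               stringsAsFactors = FALSE)
  }))
  list(traces = tr, bottles = bt)
}

#' Rebuild pressure traces from the flat CSV schemas
#'
#' @param traces_df Data frame with columns `bottle_id`, `time_h`, `psi`,
#'   `vented_psi`.
#' @param bottles_df Data frame with columns `bottle_id`, `is_blank`,
#'   `substrate_mass_g`, `dm_fraction`, and optionally `final_ph`.
#' @return A list of [pressure_trace()] objects.
#' @export
df_to_traces <- function(traces_df, bottles_df) {
  need_t <- c("bottle_id", "time_h", "psi", "vented_psi")
  need_b <- c("bottle_id", "is_blank", "substrate_mass_g", "dm_fraction")
  if (!all(need_t %in% names(traces_df))) {
    stop("traces need columns: ", paste(need_t, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_b %in% names(bottles_df))) {
    stop("bottles need columns: ", paste(need_b, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(bottles_df)), function(i) {
    b <- bottles_df[i, ]
    r <- traces_df[traces_df$bottle_id == b$bottle_id, , drop = FALSE]
    if (nrow(r) == 0L) {
      stop("no readings for bottle '", b$bottle_id, "'", call. = FALSE)
    }
    r <- r[order(r$time_h), ]
    pressure_trace(
      bottle_id = b$bottle_id, time_h = r$time_h, psi = r$psi,
      vented_psi = r$vented_psi, substrate_mass_g = b$substrate_mass_g,
      dm_fraction = b$dm_fraction, is_blank = isTRUE(b$is_blank) ||
        identical(b$is_blank, "TRUE") || identical(b$is_blank, 1),
      final_ph = if ("final_ph" %in% names(b)) b$final_ph else NA_real_)
  })
}

check_row <- function(ok, file, row, message) {
  data.frame(file = file, row = row, ok = ok,
             message = if (ok) "" else message, stringsAsFactors = FALSE)
}

#' Validate pipeline input tables against their schemas
#'
#' Row-level checks on the flat CSV tables the pipeline consumes: required
#' columns, recovery hours inside the 1-10 h magnet-check window for
#' caecal bags, non-negative masses and pressures, and per-bottle
#' monotonicity of the reconstructed cumulative pressure (gauge + summed
#' vents) so that a sensor glitch is caught before fitting.
#'
#' @param traces_df,bottles_df Gas tables (either may be `NULL` to skip).
#' @param bags_df Mobile-bag table (`NULL` to skip).
#' @param tol_psi Admissible spurious decrease in cumulative pressure, psi.
#' @return Data frame report: `file`, `row`, `ok`, `message`. Attribute
#'   `passed` is `TRUE` when every check passed.
#' @export
validate_inputs <- function(traces_df = NULL, bottles_df = NULL,
                            bags_df = NULL, tol_psi = 0.05) {
  rep <- list()
  add <- function(x) rep[[length(rep) + 1L]] <<- x

  if (!is.null(traces_df)) {
    need <- c("bottle_id", "time_h", "psi", "vented_psi")
    miss <- setdiff(need, names(traces_df))
    if (length(miss)) {
      add(check_row(FALSE, "traces", NA,
                    paste("missing required column(s):",
                          paste(miss, collapse = ", "))))
    } else {
      bad <- which(traces_df$psi < 0 | traces_df$vented_psi < 0)
      for (i in bad) add(check_row(FALSE, "traces", i, "negative pressure"))
      for (id in unique(traces_df$bottle_id)) {
        r <- traces_df[traces_df$bottle_id == id, ]
        r <- r[order(r$time_h), ]
        cum <- r$psi + cumsum(r$vented_psi)
        k <- which(diff(cum) < -tol_psi)
        if (length(k)) {
          add(check_row(FALSE, "traces", NA, sprintf(
            "bottle '%s': cumulative pressure drops at t = %.3f h without a vent event",
            id, r$time_h[k[1L] + 1L])))
        }
      }
      if (!length(bad)) add(check_row(TRUE, "traces", NA, ""))
    }
  }
  if (!is.null(bottles_df)) {
    need <- c("bottle_id", "is_blank", "substrate_mass_g", "dm_fraction")
    miss <- setdiff(need, names(bottles_df))
    if (length(miss)) {
      add(check_row(FALSE, "bottles", NA,
                    paste("missing required column(s):",
                          paste(miss, collapse = ", "))))
    } else {
      bad <- which(!bottles_df$is_blank &
                     (is.na(bottles_df$substrate_mass_g) |
                        bottles_df$substrate_mass_g <= 0))
      for (i in bad) {
        add(check_row(FALSE, "bottles", i,
                      "non-blank bottle without positive substrate mass"))
      }
      if (!length(bad)) add(check_row(TRUE, "bottles", NA, ""))
    }
  }
  if (!is.null(bags_df)) {
    need <- c("bag_id", "grass", "harvest", "pore_um", "feed_in_g",
              "recovery_site", "recovery_hour")
    miss <- setdiff(need, names(bags_df))
    if (length(miss)) {
      add(check_row(FALSE, "bags", NA,
                    paste("missing required column(s):",
                          paste(miss, collapse = ", "))))
    } else {
      cc <- !is.na(bags_df$recovery_site) & bags_df$recovery_site == "caecum"
      bad <- which(cc & (is.na(bags_df$recovery_hour) |
                           bags_df$recovery_hour < 1 |
                           bags_df$recovery_hour > 10))
      for (i in bad) {
        add(check_row(FALSE, "bags", i, sprintf(
          "caecal recovery_hour %s outside the 1-10 h window",
          format(bags_df$recovery_hour[i]))))
      }
      bad2 <- which(bags_df$feed_in_g <= 0)
      for (i in bad2) add(check_row(FALSE, "bags", i, "non-positive feed_in_g"))
      if (!length(bad) && !length(bad2)) add(check_row(TRUE, "bags", NA, ""))
    }
  }
  out <- if (length(rep)) do.call(rbind, rep) else
    data.frame(file = character(), row = integer(), ok = logical(),
               message = character(), stringsAsFactors = FALSE)
  attr(out, "passed") <- all(out$ok)
  out
}

#' Run the full mobile-bag analysis
#'
#' From bag records, per-bag residue compositions and feed compositions:
#' transit time and recovery rates, pooled residues by grass x harvest x
#' pore x interval, the per-pool nutrient disappearance table, the
#' washing-loss table, and the common-slope regression of per-bag dry
#' matter disappearance on residence-time midpoint.
#'
#' @param bags A `bag_records` data frame with recovery and residue fields.
#' @param residues Per-bag residue composition data frame.
#' @param feeds Feed composition data frame.
#' @return List with elements `summary` (transit time and recovery rates),
#'   `pooled`, `disappearance`, `washing_loss`, `regression` (a
#'   [common_slope_fit()]).
#' @export
analyze_bag_study <- function(bags, residues, feeds) {
  tt <- transit_time(bags)
  rr <- recovery_rate(bags)
  pooled <- pool_residues(bags, residues)
  disap <- disappearance_table(pooled, feeds)
  wl <- washing_loss(bags, residues, feeds)

  cc <- bags[!is.na(bags$recovery_site) & bags$recovery_site == "caecum", ,
             drop = FALSE]
  cc$ddm <- dm_disappearance(cc$feed_in_g, cc$residue_g)
  cc$midpoint_h <- cc$recovery_hour - 0.5
  cc$group <- paste(cc$grass, cc$harvest, sep = ".")
  reg <- common_slope_fit(ddm ~ midpoint_h, cc, group = "group")

  list(summary = data.frame(transit_time_h = tt,
                            caecal_recovery_pct = rr[["caecal"]],
                            total_recovery_pct = rr[["total"]]),
       pooled = pooled, disappearance = disap, washing_loss = wl,
       regression = reg)
}

#' Print a pipeline report
#'
#' Renders the fitted gas kinetics (one row per substrate: A, B, C, t_RM,
#' dDM, pH), the common-slope regression equations, and the nutrient
#' disappearance table, together with the seed used for the run. Empty
#' sections print their headers only.
#'
#' @param gas_fits Data frame from [fit_gas_study()] (or `NULL`).
#' @param bag_results List from [analyze_bag_study()] (or `NULL`).
#' @param seed The seed the run used, echoed into the report.
#' @return The assembled report list, invisibly.
#' @export
digestion_report <- function(gas_fits = NULL, bag_results = NULL,
                             seed = NA) {
  cat("==== Forage digestion report ====\n")
  cat(sprintf("seed: %s\n\n", format(seed)))
  cat("-- In vitro gas kinetics (per bottle) --\n")
  if (!is.null(gas_fits) && nrow(gas_fits)) {
    print(gas_fits[, intersect(c("bottle_id", "substrate", "A", "B", "C",
                                 "t_rm", "dDM", "final_ph", "converged"),
                               names(gas_fits))],
          digits = 4, row.names = FALSE)
  } else {
    cat("(no fits)\n")
  }
  cat("\n-- Dry matter disappearance over residence time --\n")
  if (!is.null(bag_results)) {
    print(bag_results$regression)
    cat("\n-- Transit and recovery --\n")
    print(bag_results$summary, row.names = FALSE, digits = 3)
    cat("\n-- Nutrient disappearance (%) --\n")
    if (nrow(bag_results$disappearance)) {
      print(bag_results$disappearance, digits = 3, row.names = FALSE)
    } else {
      cat("(empty)\n")
    }
  } else {
    cat("(no bag results)\n")
  }
  invisible(list(gas_fits = gas_fits, bag_results = bag_results, seed = seed))
}
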