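#' Fit the monophasic gas production model to a cumulative gas curve
#'
#' Nonlinear least squares of G(t) = A / (1 + (B/t)^C) against observed
#' cumulative gas. The fit is initialised from the data (A at 1.1 x the
#' largest observed gas, B at the linearly interpolated half-rise time,
#' C at 1.5) and run with Levenberg-Marquardt under box bounds
#' A in (0, 5 max G], B in (0, 96], C in \[0.1, 10\]; if that fails, a
#' bounded Gauss-Newton ("port") fit is attempted. The time of maximum
#' rate of gas production, t_RM = B (C-1)^(1/C), is attached ([t_rm()]).
#'
#' The point at t = 0 carries no information (G(0) = 0 identically) and is
#' excluded from the residual sum of squares.
#'
#' @param curve A `gas_curve` from [cumulative_gas()], or a data frame with
#'   columns `time_h` and `gas` (mL/g DM).
#' @param start Optional named list/vector with elements `A`, `B`, `C`
#'   overriding the data-driven start values.
#' @param lower,upper Named bounds on `c(A, B, C)`.
#' @param maxiter Maximum number of optimiser iterations.
#' @param tol Convergence tolerance on the parameters.
#' @return An object of class `monophasic_fit` with elements `A`, `B`, `C`,
#'   `t_rm`, `rss`, `converged`, `n_points`, `sigma` (residual standard
#'   deviation), `data`, `message` and `bottle_id`. A fit that does not
#'   converge is returned flagged (`converged = FALSE`), never silently.
#' @seealso [monophasic_gas()], [t_rm()], [simulate_incubation()]
#' @examples
#' tt <- seq(0, 48, by = 1 / 6)
#' g <- monophasic_gas(tt, A = 164.5, B = 9.7, C = 1.8)
#' fit <- fit_monophasic(data.frame(time_h = tt, gas = g))
#' coef(fit)
#' @export
fit_monophasic <- function(curve, start = NULL,
                           lower = c(A = 1e-6, B = 1e-6, C = 0.1),
                           upper = c(A = NA, B = 96, C = 10),
                           maxiter = 1000, tol = 1e-8) {
  if (!is.data.frame(curve) || !all(c("time_h", "gas") %in% names(curve))) {
    stop("curve must be a gas_curve or a data frame with columns time_h and gas",
         call. = FALSE)
  }
  d <- data.frame(t = curve$time_h, g = curve$gas)
  d <- d[d$t > 0, , drop = FALSE]
  if (nrow(d) < 6L) {
    stop("need at least 6 points with t > 0 to fit", call. = FALSE)
  }
  if (any(!is.finite(d$g))) stop("gas values must be finite", call. = FALSE)
  gmax <- max(d$g)
  if (gmax <= 0) {
    stop("degenerate input: curve has no positive gas production", call. = FALSE)
  }
  if (is.na(upper[["A"]])) upper[["A"]] <- 5 * gmax

  if (is.null(start)) {
    A0 <- 1.1 * gmax
    # first crossing of A0/2, linearly interpolated
    half <- A0 / 2
    idx <- which(d$g >= half)[1L]
    B0 <- if (is.na(idx)) {
      max(d$t)
    } else if (idx == 1L) {
      d$t[1L]
    } else {
      t1 <- d$t[idx - 1L]; t2 <- d$t[idx]
      g1 <- d$g[idx - 1L]; g2 <- d$g[idx]
      if (g2 > g1) t1 + (half - g1) * (t2 - t1) / (g2 - g1) else t2
    }
    start <- c(A = A0, B = B0, C = 1.5)
  }
  start <- unlist(start)[c("A", "B", "C")]
  start <- pmin(pmax(start, lower + 1e-9), upper - 1e-9)

  fit <- NULL
  msg <- ""
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = tol^2,
                                     ptol = tol^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ A / (1 + (B / t)^C), data = d,
                      start = as.list(start), lower = lower, upper = upper,
                      control = ctrl),
    error = function(e) { msg <<- conditionMessage(e); NULL })
  if (is.null(fit)) {
    fit <- tryCatch(
      stats::nls(g ~ A / (1 + (B / t)^C), data = d,
                 start = as.list(start), lower = lower, upper = upper,
                 algorithm = "port",
                 control = stats::nls.control(maxiter = maxiter, tol = tol,
                                              warnOnly = TRUE)),
      error = function(e) { msg <<- paste(msg, conditionMessage(e)); NULL })
  }

  if (is.null(fit)) {
    out <- list(A = unname(start["A"]), B = unname(start["B"]),
                C = unname(start["C"]),
                t_rm = t_rm(unname(start["B"]), unname(start["C"])),
                rss = sum((d$g - monophasic_gas(d$t, start["A"], start["B"],
                                                start["C"]))^2),
                converged = FALSE, n_points = nrow(d),
                sigma = NA_real_, data = d, message = msg,
                bottle_id = attr(curve, "bottle_id"))
    class(out) <- "monophasic_fit"
    return(out)
  }

  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  conv <- isTRUE(fit$convInfo$isConv) || inherits(fit, "nls")
  out <- list(
    A = unname(cf["A"]), B = unname(cf["B"]), C = unname(cf["C"]),
    t_rm = t_rm(unname(cf["B"]), unname(cf["C"])),
    rss = sum(res^2),
    converged = conv,
    n_points = nrow(d),
    sigma = sqrt(sum(res^2) / max(1L, nrow(d) - 3L)),
    data = d,
    message = msg,
    bottle_id = attr(curve, "bottle_id")
  )
  class(out) <- "monophasic_fit"
  out
}

#' @export
print.monophasic_fit <- function(x, digits = 4, ...) {
  id <- if (is.null(x$bottle_id)) "" else sprintf(" '%s'", x$bottle_id)
  cat(sprintf("Monophasic gas production fit%s (%d points%s)\n", id,
              x$n_points, if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  A    = %s mL/g DM (asymptotic gas production)\n",
              format(x$A, digits = digits)))
  cat(sprintf("  B    = %s h (half-time)\n", format(x$B, digits = digits)))
  cat(sprintf("  C    = %s (shape)\n", format(x$C, digits = digits)))
  cat(sprintf("  t_RM = %s h (time of maximum rate)\n",
              if (is.na(x$t_rm)) "undefined (C <= 1)"
              else format(x$t_rm, digits = digits)))
  cat(sprintf("  RSS  = %s on %d points\n", format(x$rss, digits = digits),
              x$n_points))
  invisible(x)
}

#' @export
coef.monophasic_fit <- function(object, ...) {
  c(A = object$A, B = object$B, C = object$C)
}

#' @export
fitted.monophasic_fit <- function(object, ...) {
  monophasic_gas(object$data$t, object$A, object$B, object$C)
}

#' @export
residuals.monophasic_fit <- function(object, ...) {
  object$data$g - fitted(object)
}

#' @export
deviance.monophasic_fit <- function(object, ...) object$rss

#' Predict gas production from a fitted monophasic model
#'
#' @param object A `monophasic_fit`.
#' @param newdata Optional data frame with a `time_h` column (or a numeric
#'   vector of times); defaults to the times used in the fit.
#' @param ... Unused.
#' @return Predicted cumulative gas in mL/g DM.
#' @export
predict.monophasic_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) {
    object$data$t
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata$time_h
  }
  monophasic_gas(tt, object$A, object$B, object$C)
}

#' @export
summary.monophasic_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.monophasic_fit")
}

#' @export
print.summary.monophasic_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  residual sd = %s mL/g DM\n", format(f$sigma, digits = 4)))
  cat(sprintf("  G(B) = A/2 check: %.6g vs %.6g\n",
              monophasic_gas(f$B, f$A, f$B, f$C), f$A / 2))
  invisible(x)
}

#' Plot a fitted monophasic gas production curve
#'
#' Observed cumulative gas with the fitted curve overlaid; base graphics.
#'
#' @param x A `monophasic_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.monophasic_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$g, xlab = "Incubation time (h)",
                 ylab = "Cumulative gas (mL/g DM)", pch = 16, cex = 0.5,
                 col = "grey40", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(tt, monophasic_gas(tt, x$A, x$B, x$C), col = "firebrick",
                  lwd = 2)
  if (!is.na(x$t_rm)) graphics::abline(v = x$t_rm, lty = 3)
  invisible(x)
}

#' Fit every bottle of an in vitro gas study
#'
#' Converts each pressure trace to a cumulative gas curve, optionally
#' subtracts the mean blank, fits the monophasic model to every substrate
#' bottle, and assembles one row per bottle with the kinetic parameters and
#' (when residue masses are supplied) the dry matter disappearance.
#'
#' @param traces A list of [pressure_trace()] objects (blanks included).
#' @param constants An [incubation_constants()] object.
#' @param blank_correction Subtract the mean blank curve before fitting?
#' @param residue_g Optional named vector of 48 h residue masses (g DM) by
#'   bottle id, used for dDM.
#' @param substrate Optional named character vector of substrate labels by
#'   bottle id, carried into the output.
#' @return A data frame with one row per substrate bottle: `bottle_id`,
#'   `substrate`, `A`, `B`, `C`, `t_rm`, `rss`, `converged`, `n_points`,
#'   `dDM`, `final_ph`.
#' @export
fit_gas_study <- function(traces, constants = incubation_constants(),
                          blank_correction = TRUE, residue_g = NULL,
                          substrate = NULL) {
  stopifnot(is.list(traces), all(vapply(traces, inherits, TRUE,
                                        "pressure_trace")))
  curves <- lapply(traces, cumulative_gas, constants = constants)
  is_blank <- vapply(traces, function(x) x$is_blank, TRUE)
  blanks <- curves[is_blank]
  rows <- lapply(which(!is_blank), function(i) {
    cv <- curves[[i]]
    if (blank_correction && length(blanks) > 0L) cv <- blank_correct(cv, blanks)
    f <- fit_monophasic(cv)
    id <- as.character(traces[[i]]$bottle_id)
    g_dm <- traces[[i]]$substrate_mass_g * traces[[i]]$dm_fraction
    ddm <- if (!is.null(residue_g) && id %in% names(residue_g)) {
      dm_disappearance(g_dm, residue_g[[id]])
    } else {
      NA_real_
    }
    data.frame(
      bottle_id = id,
      substrate = if (!is.null(substrate) && id %in% names(substrate))
        substrate[[id]] else NA_character_,
      A = f$A, B = f$B, C = f$C, t_rm = f$t_rm, rss = f$rss,
      converged = f$converged, n_points = f$n_points,
      dDM = ddm, final_ph = traces[[i]]$final_ph,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
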