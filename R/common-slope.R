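#' Common-slope regression of disappearance on residence time
#'
#' Fits parallel lines by ordinary least squares: one shared slope of
#' disappearance (%) on residence time (h) and a separate intercept for
#' each group (typically grass x harvest) - a dummy-coded ANCOVA with no
#' interaction. The shared slope equals the pooled within-group slope
#' sum_g S_xy(g) / sum_g S_xx(g), and each intercept is the group mean
#' response minus the slope times the group mean time.
#'
#' @param formula A two-sided formula `response ~ time`, e.g.
#'   `ddm ~ midpoint_h`.
#' @param data Data frame holding the formula variables and the grouping
#'   variable.
#' @param group Name of the grouping column in `data` (or a vector of group
#'   labels, one per row).
#' @return An object of class `common_slope_fit` with elements `slope`,
#'   `intercepts` (named by group), `r_squared`, `n`, `sigma`, `lm` (the
#'   underlying [stats::lm] fit), `data`, `response`, `time`, `call`.
#' @examples
#' d <- expand.grid(grp = c("a", "b"), t = 1:5)
#' d$y <- ifelse(d$grp == "a", 10, 20) + 0.5 * d$t
#' fit <- common_slope_fit(y ~ t, d, group = "grp")
#' coef(fit)
#' @export
common_slope_fit <- function(formula, data, group) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  mf <- stats::model.frame(formula, data = data)
  y <- mf[[1L]]
  tt <- mf[[2L]]
  g <- if (length(group) == 1L && is.character(group)) {
    data[[group]]
  } else {
    group
  }
  if (is.null(g)) stop("grouping column '", group, "' not found", call. = FALSE)
  if (length(g) != length(y)) {
    stop("group labels and data rows differ in length", call. = FALSE)
  }
  g <- factor(g)
  if (length(unique(tt)) < 2L) {
    stop("singular design: need at least 2 distinct times", call. = FALSE)
  }
  if (any(tabulate(g) == 0L)) g <- droplevels(g)

  d <- data.frame(.y = y, .t = tt, .g = g)
  fit <- stats::lm(.y ~ 0 + .g + .t, data = d)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("singular design: common-slope model is rank deficient",
         call. = FALSE)
  }
  slope <- unname(cf[".t"])
  intercepts <- cf[grep("^\\.g", names(cf))]
  names(intercepts) <- sub("^\\.g", "", names(intercepts))

  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  out <- list(
    slope = slope,
    intercepts = intercepts,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n = length(y),
    sigma = sqrt(rss / max(1L, length(y) - length(cf))),
    lm = fit,
    data = d,
    response = deparse(formula[[2L]]),
    time = deparse(formula[[3L]]),
    call = match.call()
  )
  class(out) <- "common_slope_fit"
  out
}

#' @export
print.common_slope_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Common-slope regression of %s on %s (%d points, %d groups)\n",
    x$response, x$time, x$n, length(x$intercepts)))
  for (g in names(x$intercepts)) {
    cat(sprintf("  %-12s %s = %s %s + %s\n", g, x$response,
                format(x$slope, digits = digits), x$time,
                format(x$intercepts[[g]], digits = digits)))
  }
  cat(sprintf("  R-squared %.4f, residual sd %s\n", x$r_squared,
              format(x$sigma, digits = digits)))
  invisible(x)
}

#' @export
coef.common_slope_fit <- function(object, ...) {
  c(slope = object$slope, object$intercepts)
}

#' @export
fitted.common_slope_fit <- function(object, ...) {
  unname(stats::fitted(object$lm))
}

#' @export
residuals.common_slope_fit <- function(object, ...) {
  unname(stats::resid(object$lm))
}

#' Predict disappearance at new times and groups
#'
#' @param object A `common_slope_fit`.
#' @param newdata Data frame with columns `time` and `group` (h and group
#'   label); defaults to the fitted data.
#' @param ... Unused.
#' @return Predicted response.
#' @export
predict.common_slope_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  if (!all(c("time", "group") %in% names(newdata))) {
    stop("newdata needs columns 'time' and 'group'", call. = FALSE)
  }
  ic <- object$intercepts[as.character(newdata$group)]
  if (any(is.na(names(ic)))) stop("unknown group in newdata", call. = FALSE)
  unname(ic + object$slope * newdata$time)
}

#' @export
summary.common_slope_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.common_slope_fit")
}

#' @export
print.summary.common_slope_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying least-squares fit:\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' Plot a common-slope fit
#'
#' Scatter of the data coloured by group with the fitted parallel lines.
#'
#' @param x A `common_slope_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.common_slope_fit <- function(x, ...) {
  d <- x$data
  cols <- stats::setNames(seq_along(levels(d$.g)) + 1L, levels(d$.g))
  graphics::plot(d$.t, d$.y, col = cols[as.character(d$.g)], pch = 16,
                 xlab = paste0(x$time, " (h)"), ylab = paste0(x$response, " (%)"),
                 ...)
  for (g in names(x$intercepts)) {
    graphics::abline(a = x$intercepts[[g]], b = x$slope, col = cols[[g]])
  }
  graphics::legend("topleft", legend = names(x$intercepts),
                   col = cols[names(x$intercepts)], pch = 16, bty = "n")
  invisible(x)
}
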