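# 10-minute grid over 48 h, as recorded by the automated system
grid_10min <- function(duration_h = 48) seq(0, duration_h, by = 1 / 6)

# noiseless cumulative gas curve for known kinetics
make_curve <- function(A, B, C, tt = grid_10min()) {
  structure(data.frame(time_h = tt, gas = monophasic_gas(tt, A, B, C)),
            per_g_dm = TRUE, g_dm = 1, class = c("gas_curve", "data.frame"))
}

# independent NLS oracle: Nelder-Mead on log-parameters, no shared code
# with fit_monophasic
oracle_fit <- function(tt, g) {
  rss <- function(lp) {
    p <- exp(lp)
    sum((g - p[1] / (1 + (p[2] / tt)^p[3]))^2)
  }
  o <- optim(log(c(max(g), stats::median(tt), 1.5)), rss,
             control = list(maxit = 5000, reltol = 1e-14))
  o <- optim(o$par, rss, control = list(maxit = 5000, reltol = 1e-14))
  setNames(exp(o$par), c("A", "B", "C"))
}

# independent pooled within-group slope oracle for the ANCOVA
oracle_common_slope <- function(y, t, g) {
  g <- factor(g)
  sxy <- sxx <- 0
  for (lev in levels(g)) {
    i <- g == lev
    sxy <- sxy + sum((t[i] - mean(t[i])) * (y[i] - mean(y[i])))
    sxx <- sxx + sum((t[i] - mean(t[i]))^2)
  }
  slope <- sxy / sxx
  ints <- vapply(levels(g), function(lev) {
    i <- g == lev
    mean(y[i]) - slope * mean(t[i])
  }, numeric(1))
  list(slope = slope, intercepts = ints)
}

# noiseless per-bag points from a common-slope model at check midpoints
make_parallel_points <- function(slope, intercepts, times = seq(0.5, 9.5, 1)) {
  d <- expand.grid(group = names(intercepts), midpoint_h = times,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$ddm <- intercepts[d$group] + slope * d$midpoint_h
  d
}
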