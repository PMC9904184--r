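#' Crude protein from Kjeldahl nitrogen
#'
#' CP = N x 6.25, the standard conversion from total nitrogen to crude
#' protein; linear and order-preserving.
#'
#' @param nitrogen_g_kg Nitrogen content in g/kg DM (>= 0); vectorised.
#' @return Crude protein in g/kg DM.
#' @examples
#' crude_protein(16)  # 100 g/kg DM
#' @export
crude_protein <- function(nitrogen_g_kg) {
  if (any(nitrogen_g_kg < 0, na.rm = TRUE)) {
    stop("nitrogen must be non-negative", call. = FALSE)
  }
  6.25 * nitrogen_g_kg
}

# nutrient columns expected in a feeds table (g/kg DM)
feed_nutrients <- function() {
  c("cp", "andfom", "wsc", "glucose", "fructose", "sucrose", "fructan", "ash")
}

# accept percent-of-DM tables: if values look like percentages, convert
normalize_feed_units <- function(feeds, quiet = FALSE) {
  nut <- intersect(feed_nutrients(), names(feeds))
  mx <- suppressWarnings(max(unlist(feeds[nut]), na.rm = TRUE))
  if (is.finite(mx) && mx <= 100) {
    if (!quiet) message("feed nutrients look like % of DM; converting to g/kg (x10)")
    feeds[nut] <- feeds[nut] * 10
  }
  feeds
}

#' Check water-soluble carbohydrate component consistency
#'
#' The WSC fraction of cool-season grasses is the sum of glucose, fructose,
#' sucrose and fructan. Enzymatic assays of the components need not sum
#' exactly to the total, so a sample is flagged only when the component sum
#' deviates from WSC by more than `tol` (relative), or when a single
#' component alone exceeds WSC by more than the tolerance.
#'
#' @param feeds Data frame with columns `wsc`, `glucose`, `fructose`,
#'   `sucrose`, `fructan` (g/kg DM), typically also `grass`/`harvest` keys.
#' @param tol Relative tolerance (default 0.15).
#' @return `feeds` with added columns `component_sum`, `rel_dev` and `pass`
#'   (a report; no error is raised).
#' @export
wsc_consistency <- function(feeds, tol = 0.15) {
  comp <- c("glucose", "fructose", "sucrose", "fructan")
  need <- c("wsc", comp)
  if (!all(need %in% names(feeds))) {
    stop("feeds must carry columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  # sequential sum in canonical order so exactly-consistent tables pass
  # at tolerance 0 despite floating point
  s <- feeds$glucose + feeds$fructose + feeds$sucrose + feeds$fructan
  rel <- (s - feeds$wsc) / feeds$wsc
  single_over <- apply(feeds[comp] > feeds$wsc * (1 + tol), 1L, any)
  out <- feeds
  out$component_sum <- s
  out$rel_dev <- rel
  out$pass <- abs(rel) <= tol & !single_over
  out
}

#' Rank grass pairs by contrast in soluble carbohydrate and digestibility
#'
#' Screens candidate grasses for a follow-up in vivo study by ranking all
#' pairs by their combined standardised distance in (mean WSC content,
#' mean asymptotic gas production A). Both axes are z-scored across
#' grasses, so the ranking is invariant to unit rescaling of either axis.
#' The most contrasting pair ranks first; deterministic given its inputs.
#'
#' @param feeds Data frame with `grass`, `harvest` and `wsc` (g/kg DM).
#' @param fits Data frame with `grass`, `harvest` and `A` (mL/g DM), e.g.
#'   aggregated from [fit_gas_study()].
#' @return Data frame of grass pairs with columns `grass1`, `grass2`,
#'   `distance`, `rank`, sorted most-contrasting first.
#' @export
select_contrasting <- function(feeds, fits) {
  for (nm in c("grass", "harvest", "wsc")) {
    if (!nm %in% names(feeds)) stop("feeds lacks column '", nm, "'",
                                    call. = FALSE)
  }
  for (nm in c("grass", "harvest", "A")) {
    if (!nm %in% names(fits)) stop("fits lacks column '", nm, "'",
                                   call. = FALSE)
  }
  grasses <- sort(unique(feeds$grass))
  missing_fit <- setdiff(grasses, unique(fits$grass))
  if (length(missing_fit)) {
    stop("no gas fits for grass(es): ", paste(missing_fit, collapse = ", "),
         call. = FALSE)
  }
  wsc <- tapply(feeds$wsc, feeds$grass, mean)[grasses]
  A <- tapply(fits$A, fits$grass, mean)[grasses]
  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  zw <- zs(wsc)
  za <- zs(A)
  pairs <- utils::combn(grasses, 2L)
  dist <- apply(pairs, 2L, function(p) {
    sqrt((zw[p[1L]] - zw[p[2L]])^2 + (za[p[1L]] - za[p[2L]])^2)
  })
  out <- data.frame(grass1 = pairs[1L, ], grass2 = pairs[2L, ],
                    distance = unname(dist), stringsAsFactors = FALSE)
  out <- out[order(-out$distance, out$grass1, out$grass2), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
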