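#' Design of a mobile-bag digestion study
#'
#' Describes the factorial layout of a mobile nylon-bag experiment: grass
#' species x harvest time x bag pore size, with a number of intubated
#' replicate bags per combination plus never-intubated wash-control bags
#' used to measure washing loss. Intubated bags are distributed over a
#' horses x periods Latin square in which each grass x harvest feed occurs
#' once per horse and once per period.
#'
#' The defaults reproduce a 2 x 2 x 2 design with 40 intubated and 4 wash
#' replicates per combination (352 bags in total), 0.5 g feed in a bag with
#' a 24 cm2 usable face (2 cm x 12 cm), giving a feed-to-surface-area of
#' about 21 mg/cm2.
#'
#' @param grasses Character vector of grass species codes.
#' @param harvests Character vector of harvest times.
#' @param pore_sizes_um Numeric vector of bag pore sizes in micrometres.
#' @param intubated_reps Intubated replicate bags per combination.
#' @param wash_reps Wash-control bags per combination.
#' @param horses Number of horses (Latin square rows).
#' @param periods Number of periods (Latin square columns).
#' @param feed_mass_g Feed per bag, g.
#' @param bag_face_area_cm2 Usable bag face area, cm2.
#' @return An object of class `design_plan`.
#' @examples
#' plan <- design_plan()
#' n_bags(plan)
#' @export
design_plan <- function(grasses = c("CF", "PR"),
                        harvests = c("early", "late"),
                        pore_sizes_um = c(15, 36),
                        intubated_reps = 40, wash_reps = 4,
                        horses = 4, periods = 4,
                        feed_mass_g = 0.5, bag_face_area_cm2 = 24) {
  stopifnot(length(grasses) >= 1, length(harvests) >= 1,
            length(pore_sizes_um) >= 1,
            intubated_reps >= 0, wash_reps >= 0,
            horses >= 1, periods >= 1,
            feed_mass_g > 0, bag_face_area_cm2 > 0)
  structure(list(grasses = grasses, harvests = harvests,
                 pore_sizes_um = pore_sizes_um,
                 intubated_reps = intubated_reps, wash_reps = wash_reps,
                 horses = horses, periods = periods,
                 feed_mass_g = feed_mass_g,
                 bag_face_area_cm2 = bag_face_area_cm2),
            class = "design_plan")
}

#' @export
print.design_plan <- function(x, ...) {
  cat(sprintf(
    "Mobile-bag design: %d grass(es) x %d harvest(s) x %d pore size(s)\n",
    length(x$grasses), length(x$harvests), length(x$pore_sizes_um)))
  cat(sprintf("  %d intubated + %d wash bags per combination -> %d bags\n",
              x$intubated_reps, x$wash_reps, n_bags(x)))
  cat(sprintf("  %d horses x %d periods; %.2f g feed, %.0f cm2 face (FSA %.1f mg/cm2)\n",
              x$horses, x$periods, x$feed_mass_g, x$bag_face_area_cm2,
              fsa(x$feed_mass_g, x$bag_face_area_cm2)))
  invisible(x)
}

#' Total number of bags implied by a design plan
#' @param plan A [design_plan()].
#' @return Integer bag count.
#' @export
n_bags <- function(plan) {
  stopifnot(inherits(plan, "design_plan"))
  length(plan$grasses) * length(plan$harvests) * length(plan$pore_sizes_um) *
    (plan$intubated_reps + plan$wash_reps)
}

# n x n cyclic Latin square with rows/columns/symbols permuted by the
# current RNG state (call inside with_seed)
latin_square <- function(n, randomize = TRUE) {
  sq <- (outer(seq_len(n), seq_len(n), `+`) - 2L) %% n + 1L
  if (randomize) {
    sq <- sq[sample.int(n), sample.int(n), drop = FALSE]
    sq[] <- sample.int(n)[sq]
  }
  sq
}

#' Enumerate the bags of a mobile-bag study
#'
#' Expands a [design_plan()] into one skeleton record per bag. Intubated
#' bags are assigned to horse x period cells through a randomised Latin
#' square over the grass x harvest feeds (each feed once per horse and per
#' period); the replicates of a feed are split evenly over its cells and,
#' within a cell, balanced over pore sizes. Wash-control bags get
#' `recovery_site = "wash_control"` and no horse or period.
#'
#' @param plan A [design_plan()].
#' @param seed Seed for the Latin square randomisation; `NULL` leaves the
#'   square in its cyclic form.
#' @return A data frame (class `bag_records`) with columns `bag_id`,
#'   `horse`, `period`, `grass`, `harvest`, `pore_um`, `feed_in_g`,
#'   `recovery_site` (`NA` for intubated bags until the study is run),
#'   `recovery_hour`, `residue_g`.
#' @examples
#' bags <- enumerate_bags(design_plan(), seed = 1)
#' nrow(bags)  # 352
#' @export
enumerate_bags <- function(plan, seed = NULL) {
  stopifnot(inherits(plan, "design_plan"))
  feeds <- expand.grid(grass = plan$grasses, harvest = plan$harvests,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_feeds <- nrow(feeds)
  use_square <- plan$intubated_reps > 0 && n_feeds > 1
  if (use_square && (plan$horses != n_feeds || plan$periods != n_feeds)) {
    stop(sprintf(
      "Latin square needs horses = periods = number of feeds (%d); got %d horses, %d periods",
      n_feeds, plan$horses, plan$periods), call. = FALSE)
  }
  sq <- if (use_square) {
    with_seed(seed, latin_square(n_feeds, randomize = !is.null(seed)))
  } else {
    matrix(1L, nrow = plan$horses, ncol = plan$periods)
  }

  rows <- list()
  for (f in seq_len(n_feeds)) {
    cells <- which(sq == f, arr.ind = TRUE)
    if (nrow(cells) == 0L || plan$intubated_reps == 0L) next
    for (pore in plan$pore_sizes_um) {
      # round-robin the replicates of this feed x pore over its cells
      cell_idx <- rep_len(seq_len(nrow(cells)), plan$intubated_reps)
      rows[[length(rows) + 1L]] <- data.frame(
        horse = cells[cell_idx, "row"], period = cells[cell_idx, "col"],
        grass = feeds$grass[f], harvest = feeds$harvest[f],
        pore_um = pore, stringsAsFactors = FALSE)
    }
  }
  intub <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(intub)) intub <- intub[order(intub$horse, intub$period), ]
  wash <- expand.grid(grass = plan$grasses, harvest = plan$harvests,
                      pore_um = plan$pore_sizes_um,
                      rep = seq_len(plan$wash_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- rbind(
    if (!is.null(intub)) data.frame(
      horse = intub$horse, period = intub$period, grass = intub$grass,
      harvest = intub$harvest, pore_um = intub$pore_um,
      recovery_site = NA_character_, stringsAsFactors = FALSE),
    if (nrow(wash)) data.frame(
      horse = NA_integer_, period = NA_integer_, grass = wash$grass,
      harvest = wash$harvest, pore_um = wash$pore_um,
      recovery_site = "wash_control", stringsAsFactors = FALSE)
  )
  out <- data.frame(
    bag_id = sprintf("bag%03d", seq_len(nrow(out))),
    out,
    feed_in_g = plan$feed_mass_g,
    recovery_hour = NA_real_,
    residue_g = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- out[, c("bag_id", "horse", "period", "grass", "harvest", "pore_um",
                 "feed_in_g", "recovery_site", "recovery_hour", "residue_g")]
  class(out) <- c("bag_records", "data.frame")
  out
}

#' Feed-to-surface-area ratio of a mobile bag
#'
#' FSA = 1000 feed mass / face area, in mg/cm2. Controls how much substrate
#' is exposed per unit of bag surface.
#'
#' @param feed_mass_g Feed mass in g.
#' @param face_area_cm2 Usable bag face area in cm2 (> 0).
#' @return FSA in mg/cm2.
#' @examples
#' fsa(0.5, 24)  # ~21 mg/cm2
#' @export
fsa <- function(feed_mass_g, face_area_cm2) {
  if (any(face_area_cm2 <= 0)) stop("face area must be positive", call. = FALSE)
  1000 * feed_mass_g / face_area_cm2
}

#' Mean transit time of mobile bags from stomach to caecum
#'
#' Sum over hourly checks of t_i M_i, where t_i is the midpoint of the i-th
#' hourly check (a bag first seen at the check at hour k is assigned
#' t_i = k - 0.5 h) and M_i the fraction of all caecum-recovered bags found
#' at that check. Being a convex combination of midpoints, the result always
#' lies between the earliest and latest midpoint, and is invariant to
#' duplicating every record.
#'
#' @param records A `bag_records` data frame; only rows with
#'   `recovery_site == "caecum"` contribute.
#' @return Mean transit time in h.
#' @export
transit_time <- function(records) {
  cc <- records[!is.na(records$recovery_site) &
                  records$recovery_site == "caecum", , drop = FALSE]
  if (nrow(cc) == 0L) stop("no caecum-recovered bags", call. = FALSE)
  hr <- cc$recovery_hour
  if (any(is.na(hr)) || any(hr < 1) || any(hr > 10)) {
    stop("caecal recovery_hour must be in [1, 10]", call. = FALSE)
  }
  mid <- hr - 0.5
  w <- tapply(rep(1, length(mid)), mid, sum) / length(mid)
  sum(as.numeric(names(w)) * w)
}

#' Recovery rate of intubated mobile bags
#'
#' Caecal recovery is the share of intubated bags retrieved through the
#' caecal cannula within the 10 h collection window; total recovery adds
#' the bags later collected in faeces.
#'
#' @param records A `bag_records` data frame. Wash controls are ignored;
#'   every other row counts as intubated.
#' @return Named vector `c(caecal = , total = )` in percent.
#' @export
recovery_rate <- function(records) {
  intub <- records[is.na(records$recovery_site) |
                     records$recovery_site != "wash_control", , drop = FALSE]
  if (nrow(intub) == 0L) stop("no intubated bags", call. = FALSE)
  site <- intub$recovery_site
  c(caecal = 100 * sum(site == "caecum", na.rm = TRUE) / nrow(intub),
    total = 100 * sum(site %in% c("caecum", "feces")) / nrow(intub))
}

#' Pooling interval for a caecal recovery hour
#'
#' Bags recovered from the caecum are pooled into three residence-time
#' intervals before chemical analysis: 1-3, 4-6 and 7-10 h.
#'
#' @param recovery_hour Integer hourly check in \[1, 10\]; vectorised.
#' @return Factor with levels `"1-3"`, `"4-6"`, `"7-10"`.
#' @examples
#' assign_interval(c(1, 3, 4, 10))
#' @export
assign_interval <- function(recovery_hour) {
  if (any(is.na(recovery_hour)) || any(recovery_hour < 1) ||
      any(recovery_hour > 10) || any(recovery_hour != round(recovery_hour))) {
    stop("recovery_hour must be an integer in [1, 10]", call. = FALSE)
  }
  cut(recovery_hour, breaks = c(0, 3, 6, 10), labels = c("1-3", "4-6", "7-10"))
}

#' Midpoint of a pooling interval
#'
#' Midpoint residence time assigned to a pooled sample when per-bag times
#' are not available: 2, 5 and 8.5 h for the 1-3, 4-6 and 7-10 h pools.
#'
#' @param interval Factor or character as returned by [assign_interval()].
#' @return Midpoint in h.
#' @export
interval_midpoint <- function(interval) {
  m <- c("1-3" = 2, "4-6" = 5, "7-10" = 8.5)
  out <- m[as.character(interval)]
  if (any(is.na(out))) stop("unknown interval label", call. = FALSE)
  unname(out)
}

#' Per-nutrient disappearance from a bag or pool
#'
#' 100 (feed nutrient in - residue nutrient out) / feed nutrient in, with
#' nutrient masses formed as mass (g DM) x composition (g/kg DM). The
#' result is scale-invariant: multiplying feed and residue masses by the
#' same factor leaves it unchanged.
#'
#' @param feed_in_g Feed mass, g DM.
#' @param feed_comp Named numeric vector of feed composition, g/kg DM.
#' @param residue_g Residue mass, g DM.
#' @param residue_comp Named numeric vector of residue composition, g/kg DM.
#' @param nutrients Nutrients to compute; defaults to those present in both
#'   compositions. A requested nutrient missing from either is an error.
#' @return Named vector of disappearance percentages.
#' @examples
#' nutrient_disappearance(0.5, c(wsc = 200), 0.25, c(wsc = 8))
#' @export
nutrient_disappearance <- function(feed_in_g, feed_comp, residue_g,
                                   residue_comp, nutrients = NULL) {
  if (is.null(nutrients)) {
    nutrients <- intersect(names(feed_comp), names(residue_comp))
  }
  missing_f <- setdiff(nutrients, names(feed_comp))
  missing_r <- setdiff(nutrients, names(residue_comp))
  if (length(missing_f) || length(missing_r)) {
    stop("nutrient(s) missing from ",
         if (length(missing_f)) paste0("feed composition: ",
                                       paste(missing_f, collapse = ", ")),
         if (length(missing_f) && length(missing_r)) "; ",
         if (length(missing_r)) paste0("residue composition: ",
                                       paste(missing_r, collapse = ", ")),
         call. = FALSE)
  }
  fin <- feed_in_g * feed_comp[nutrients]
  if (any(fin <= 0)) {
    stop("feed nutrient mass must be positive", call. = FALSE)
  }
  rout <- residue_g * residue_comp[nutrients]
  out <- 100 * (fin - rout) / fin
  names(out) <- nutrients
  out
}

#' Washing loss of nutrients from never-intubated bags
#'
#' Applies the disappearance formula to the wash-control bags: the nutrient
#' fraction lost during the standardised wash, i.e. the soluble, instantly
#' lost fraction. Reported alongside (never subtracted from) the in vivo
#' disappearance.
#'
#' @param records A `bag_records` data frame; only
#'   `recovery_site == "wash_control"` rows are used.
#' @param residues Data frame of per-bag residue composition: `bag_id` plus
#'   one numeric column per nutrient (g/kg DM).
#' @param feeds Data frame of feed composition with columns `grass`,
#'   `harvest` plus one numeric column per nutrient (g/kg DM).
#' @param nutrients Nutrient columns to use; defaults to those shared by
#'   `residues` and `feeds`.
#' @return Data frame with one row per grass x harvest x pore size and one
#'   column of washing-loss percent per nutrient.
#' @export
washing_loss <- function(records, residues, feeds, nutrients = NULL) {
  wash <- records[!is.na(records$recovery_site) &
                    records$recovery_site == "wash_control", , drop = FALSE]
  if (nrow(wash) == 0L) stop("no wash-control bags", call. = FALSE)
  if (is.null(nutrients)) {
    nutrients <- intersect(setdiff(names(residues), "bag_id"),
                           setdiff(names(feeds), c("grass", "harvest", "block")))
  }
  wash <- merge(wash, residues, by = "bag_id")
  combos <- unique(wash[, c("grass", "harvest", "pore_um")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    sel <- wash$grass == cb$grass & wash$harvest == cb$harvest &
      wash$pore_um == cb$pore_um
    sub <- wash[sel, , drop = FALSE]
    fc <- feeds[feeds$grass == cb$grass & feeds$harvest == cb$harvest, ,
                drop = FALSE]
    if (nrow(fc) == 0L) {
      stop(sprintf("no feed composition for %s %s", cb$grass, cb$harvest),
           call. = FALSE)
    }
    fcv <- colMeans(fc[, nutrients, drop = FALSE])
    # pool the wash bags of the combination (mass-weighted)
    pooled_mass <- sum(sub$residue_g)
    pooled_comp <- colSums(sub[, nutrients, drop = FALSE] * sub$residue_g) /
      pooled_mass
    d <- nutrient_disappearance(sum(sub$feed_in_g), fcv, pooled_mass,
                                pooled_comp, nutrients)
    cbind(cb, as.data.frame(as.list(d)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool caecum-recovered bag residues for chemical analysis
#'
#' Residues are pooled by grass x harvest x pore size x recovery interval
#' (1-3, 4-6, 7-10 h); bags recovered in faeces or lost are excluded. The
#' pooled mass is the sum of member residue masses and the pooled
#' composition the residue-mass-weighted mean of member compositions, so
#' disappearance computed on the pool equals the feed-mass-weighted
#' bookkeeping over its members. Empty combinations are flagged with
#' `n_bags = 0`, not dropped silently.
#'
#' @param records A `bag_records` data frame with caecal recoveries filled
#'   in.
#' @param residues Optional data frame of per-bag residue composition
#'   (`bag_id` + nutrient columns, g/kg DM); without it only masses are
#'   pooled.
#' @return Data frame with columns `grass`, `harvest`, `pore_um`,
#'   `interval`, `n_bags`, `feed_in_g`, `pooled_mass_g`, `midpoint_h`, and
#'   one column per nutrient.
#' @export
pool_residues <- function(records, residues = NULL) {
  cc <- records[!is.na(records$recovery_site) &
                  records$recovery_site == "caecum", , drop = FALSE]
  if (nrow(cc) == 0L) stop("no caecum-recovered bags to pool", call. = FALSE)
  cc$interval <- assign_interval(cc$recovery_hour)
  nutrients <- character(0)
  if (!is.null(residues)) {
    nutrients <- setdiff(names(residues), "bag_id")
    cc <- merge(cc, residues, by = "bag_id", all.x = TRUE)
  }
  grid <- expand.grid(grass = unique(records$grass),
                      harvest = unique(records$harvest),
                      pore_um = unique(records$pore_um),
                      interval = levels(cc$interval),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- cc[cc$grass == g$grass & cc$harvest == g$harvest &
                cc$pore_um == g$pore_um & cc$interval == g$interval, ,
              drop = FALSE]
    base <- data.frame(g, n_bags = nrow(sub),
                       feed_in_g = sum(sub$feed_in_g),
                       pooled_mass_g = sum(sub$residue_g),
                       midpoint_h = interval_midpoint(g$interval),
                       stringsAsFactors = FALSE)
    if (length(nutrients)) {
      comp <- if (nrow(sub) == 0L || sum(sub$residue_g) == 0) {
        rep(NA_real_, length(nutrients))
      } else {
        colSums(sub[, nutrients, drop = FALSE] * sub$residue_g) /
          sum(sub$residue_g)
      }
      base <- cbind(base, as.data.frame(as.list(stats::setNames(comp,
                                                                nutrients))))
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$n_bags == 0L)) {
    warning(sum(out$n_bags == 0L), " empty pool(s) flagged (n_bags = 0)")
  }
  out
}

#' Nutrient disappearance table from pooled residues
#'
#' Applies [nutrient_disappearance()] to every non-empty pool, giving the
#' disappearance percent per grass x harvest x pore size x interval x
#' nutrient.
#'
#' @param pooled Output of [pool_residues()] (with nutrient columns).
#' @param feeds Feed composition data frame (`grass`, `harvest` + nutrient
#'   columns, g/kg DM).
#' @param nutrients Nutrients to tabulate; defaults to those shared by both
#'   inputs.
#' @return Long data frame: `grass`, `harvest`, `pore_um`, `interval`,
#'   `midpoint_h`, `nutrient`, `disappearance`.
#' @export
disappearance_table <- function(pooled, feeds, nutrients = NULL) {
  if (is.null(nutrients)) {
    nutrients <- intersect(
      setdiff(names(pooled), c("grass", "harvest", "pore_um", "interval",
                               "n_bags", "feed_in_g", "pooled_mass_g",
                               "midpoint_h")),
      setdiff(names(feeds), c("grass", "harvest", "block")))
  }
  rows <- lapply(seq_len(nrow(pooled)), function(i) {
    p <- pooled[i, ]
    if (p$n_bags == 0L) return(NULL)
    fc <- feeds[feeds$grass == p$grass & feeds$harvest == p$harvest, ,
                drop = FALSE]
    fcv <- colMeans(fc[, nutrients, drop = FALSE])
    rcv <- unlist(p[nutrients])
    d <- nutrient_disappearance(p$feed_in_g, fcv, p$pooled_mass_g, rcv,
                                nutrients)
    data.frame(grass = p$grass, harvest = p$harvest, pore_um = p$pore_um,
               interval = p$interval, midpoint_h = p$midpoint_h,
               nutrient = nutrients, disappearance = unname(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
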