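test_that("enumerate_bags reproduces the factorial design and Latin square balance", {
  plan <- design_plan()
  bags <- enumerate_bags(plan, seed = 1)
  expect_equal(nrow(bags), 352)
  expect_equal(n_bags(plan), 352)

  wash <- bags[!is.na(bags$recovery_site) &
                 bags$recovery_site == "wash_control", ]
  intub <- bags[is.na(bags$recovery_site), ]
  expect_equal(nrow(wash), 2 * 2 * 2 * 4)
  expect_equal(nrow(intub), 2 * 2 * 2 * 40)

  # 40 intubated replicates of every grass x harvest x pore combination
  counts <- table(intub$grass, intub$harvest, intub$pore_um)
  expect_true(all(counts == 40))
  # 20 bags per horse per period; each feed once per horse and per period
  expect_true(all(table(intub$horse, intub$period) == 20))
  feed <- paste(intub$grass, intub$harvest)
  expect_true(all(table(feed, intub$horse) == 20))
  expect_true(all(table(feed, intub$period) == 20))

  # reduced plans
  p1 <- design_plan(grasses = "CF", harvests = "early", pore_sizes_um = 15,
                    wash_reps = 0)
  expect_equal(nrow(enumerate_bags(p1)), 40)
  expect_error(enumerate_bags(design_plan(horses = 3)), "Latin square")
})

test_that("FSA is proportional feed mass per bag face area", {
  expect_equal(fsa(0.5, 24), 20.83333, tolerance = 1e-6)
  expect_equal(round(fsa(0.5, 24)), 21)
  expect_equal(fsa(0.24, 24), 10)
  expect_equal(fsa(0.5, 12), 2 * fsa(0.5, 24))
  expect_error(fsa(0.5, 0), "positive")
})

test_that("transit time is the midpoint-weighted mean of recovery checks", {
  mk <- function(hours) data.frame(
    bag_id = seq_along(hours), grass = "CF", harvest = "early", pore_um = 15,
    feed_in_g = 0.5, recovery_site = "caecum", recovery_hour = hours,
    residue_g = 0.3)

  expect_equal(transit_time(mk(rep(5, 7))), 4.5)
  expect_equal(transit_time(mk(c(2, 2, 4, 4))), 2.5)

  # convex combination: always inside [min, max] midpoint; invariant to
  # duplicating all records
  set.seed(3)
  for (i in 1:20) {
    h <- sample(1:10, 15, replace = TRUE)
    tt <- transit_time(mk(h))
    expect_gte(tt, min(h) - 0.5)
    expect_lte(tt, max(h) - 0.5)
    expect_equal(transit_time(mk(rep(h, 3))), tt)
  }
  expect_error(transit_time(mk(5)[0, ]), "no caecum")
})

test_that("recovery rates count caecal and total recoveries among intubated bags", {
  mk <- function(sites) data.frame(
    bag_id = seq_along(sites), grass = "CF", harvest = "early", pore_um = 15,
    feed_in_g = 0.5, recovery_site = sites, recovery_hour = NA,
    residue_g = NA)

  expect_equal(recovery_rate(mk(rep("lost", 4)))[["caecal"]], 0)
  expect_equal(recovery_rate(mk(rep("caecum", 4)))[["caecal"]], 100)
  rr <- recovery_rate(mk(c(rep("caecum", 250), rep("feces", 61),
                           rep("lost", 9))))
  expect_equal(rr[["caecal"]], 78.125)
  expect_equal(rr[["total"]], 97.1875)
  expect_lte(rr[["caecal"]], rr[["total"]])
  expect_lte(rr[["total"]], 100)
  # wash controls are excluded from the denominator
  rr2 <- recovery_rate(mk(c(rep("caecum", 3), "wash_control")))
  expect_equal(rr2[["caecal"]], 100)
})

test_that("recovery hours map onto the three pooling intervals", {
  expect_equal(as.character(assign_interval(c(1, 3, 4, 6, 7, 10))),
               c("1-3", "1-3", "4-6", "4-6", "7-10", "7-10"))
  expect_error(assign_interval(0), "1, 10")
  expect_error(assign_interval(12), "1, 10")
  expect_equal(interval_midpoint(c("1-3", "4-6", "7-10")), c(2, 5, 8.5))
})

test_that("nutrient disappearance is a mass-ratio bookkeeping, scale invariant", {
  expect_equal(unname(nutrient_disappearance(0.5, c(wsc = 200), 0,
                                             c(wsc = 0))), 100)
  expect_equal(unname(nutrient_disappearance(0.5, c(wsc = 200), 0.5,
                                             c(wsc = 200))), 0)
  expect_equal(unname(nutrient_disappearance(0.5, c(wsc = 200), 0.25,
                                             c(wsc = 8))), 98,
               tolerance = 1e-6)
  # scale invariance
  d1 <- nutrient_disappearance(0.5, c(cp = 150), 0.3, c(cp = 100))
  d2 <- nutrient_disappearance(5, c(cp = 150), 3, c(cp = 100))
  expect_equal(d1, d2)
  expect_error(nutrient_disappearance(0.5, c(cp = 150), 0.3, c(ndf = 10),
                                      "cp"), "missing")
})

test_that("pooling conserves mass and reproduces mass-weighted disappearance", {
  sim <- simulate_bag_study(bag_scenario(seed = 5))
  pooled <- suppressWarnings(pool_residues(sim$bags, sim$residues))

  # 2 x 2 x 2 x 3 pools with the default design
  expect_equal(nrow(pooled), 24)
  cc <- sim$bags[!is.na(sim$bags$recovery_site) &
                   sim$bags$recovery_site == "caecum", ]
  expect_equal(sum(pooled$pooled_mass_g), sum(cc$residue_g))
  expect_equal(sum(pooled$n_bags), nrow(cc))

  # pooled disappearance equals mass-weighted per-bag bookkeeping (equal
  # feed composition within a pool)
  one <- pooled[which(pooled$n_bags > 1)[1], ]
  sel <- cc$grass == one$grass & cc$harvest == one$harvest &
    cc$pore_um == one$pore_um &
    as.character(assign_interval(cc$recovery_hour)) == one$interval
  members <- merge(cc[sel, ], sim$residues, by = "bag_id")
  fc <- sim$feeds[sim$feeds$grass == one$grass &
                    sim$feeds$harvest == one$harvest, ]
  per_bag <- vapply(seq_len(nrow(members)), function(i) {
    unname(nutrient_disappearance(members$feed_in_g[i], c(cp = fc$cp),
                                  members$residue_g[i],
                                  c(cp = members$cp[i])))
  }, numeric(1))
  pool_d <- unname(nutrient_disappearance(one$feed_in_g, c(cp = fc$cp),
                                          one$pooled_mass_g, c(cp = one$cp)))
  w <- members$feed_in_g / sum(members$feed_in_g)
  expect_equal(pool_d, sum(w * per_bag), tolerance = 1e-9)

  # one bag per pool -> pool equals that bag
  single <- cc[1, , drop = FALSE]
  expect_warning(p1 <- pool_residues(rbind(single), sim$residues),
                 "empty pool")
  p1 <- p1[p1$n_bags == 1, ]
  expect_equal(p1$pooled_mass_g, single$residue_g)
  expect_equal(p1$cp,
               sim$residues$cp[sim$residues$bag_id == single$bag_id])
})

test_that("washing loss recovers the soluble fractions of wash-control bags", {
  sim <- simulate_bag_study(bag_scenario(seed = 9))
  wl <- washing_loss(sim$bags, sim$residues, sim$feeds)
  expect_equal(nrow(wl), 8)           # grass x harvest x pore
  # compositions are generated noiselessly from the soluble fractions
  nm <- default_nutrient_model()
  for (nut in c("andfom", "wsc", "glucose", "fructan")) {
    target <- 100 * nm$soluble[nm$nutrient == nut]
    expect_equal(unname(unlist(wl[[nut]])), rep(target, 8), tolerance = 0.5)
  }
  # fructan washing loss sits near 70%
  expect_equal(mean(wl$fructan), 70, tolerance = 1)
})

test_that("common_slope_fit matches its closed-form oracle and recovers parallel lines", {
  ints <- c(PR.early = 38.01, PR.late = 32.51, CF.early = 35.29,
            CF.late = 21.37)
  d <- make_parallel_points(0.608, ints)

  fit <- common_slope_fit(ddm ~ midpoint_h, d, group = "group")
  expect_equal(fit$slope, 0.608, tolerance = 1e-10)
  expect_equal(fit$intercepts[names(ints)], ints, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # oracle agreement on noisy data
  set.seed(13)
  dn <- d
  dn$ddm <- dn$ddm + rnorm(nrow(dn), 0, 2)
  f2 <- common_slope_fit(ddm ~ midpoint_h, dn, group = "group")
  orc <- oracle_common_slope(dn$ddm, dn$midpoint_h, dn$group)
  expect_equal(f2$slope, orc$slope, tolerance = 1e-10)
  expect_equal(f2$intercepts[names(orc$intercepts)], orc$intercepts,
               tolerance = 1e-10, ignore_attr = TRUE)

  # zero-slope flat groups
  d0 <- data.frame(group = rep(c("a", "b"), each = 4),
                   midpoint_h = rep(1:4, 2), ddm = 50)
  f0 <- common_slope_fit(ddm ~ midpoint_h, d0, group = "group")
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  expect_equal(unname(f0$intercepts), c(50, 50), tolerance = 1e-12)

  # affine equivariance: shifting all responses shifts intercepts only
  ds <- dn
  ds$ddm <- ds$ddm + 7
  fs <- common_slope_fit(ddm ~ midpoint_h, ds, group = "group")
  expect_equal(fs$slope, f2$slope, tolerance = 1e-10)
  expect_equal(unname(fs$intercepts), unname(f2$intercepts) + 7,
               tolerance = 1e-10)

  expect_error(common_slope_fit(ddm ~ midpoint_h,
                                data.frame(group = "a", midpoint_h = 1,
                                           ddm = 1),
                                group = "group"), "singular")
})

test_that("common_slope_fit methods are coherent", {
  ints <- c(a = 10, b = 20)
  d <- make_parallel_points(0.5, ints, times = 1:6)
  f <- common_slope_fit(ddm ~ midpoint_h, d, group = "group")
  expect_equal(unname(coef(f)), c(0.5, 10, 20), tolerance = 1e-10)
  expect_equal(predict(f, data.frame(time = 2, group = "b")), 21,
               tolerance = 1e-10)
  expect_equal(fitted(f), d$ddm, tolerance = 1e-10)
  expect_equal(sum(residuals(f)^2), 0, tolerance = 1e-12)
  expect_output(print(f), "Common-slope regression")
  expect_output(suppressWarnings(print(summary(f))), "least-squares")
})
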