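test_that("leaf trait derivations follow their definitions", {
  expect_equal(ldmc(0.2, 1.0), 0.2)
  expect_equal(ldmc(0.6, 0.6), 1.0)
  expect_equal(ldmc(0.15, 0.60), 0.25)
  expect_error(ldmc(0.2, 0), "saturated mass")
  expect_error(ldmc(0.7, 0.6), "exceeds")

  expect_equal(sla(30, 0.1), 300)
  expect_equal(sla(1, 1), 1)
  expect_equal(sla(12.5, 0.05), 250)
  expect_error(sla(30, 0), "dry mass")

  ind <- data.frame(leaf_area_cm2 = c(30, 12.5), leaf_dry_mass_g = c(0.1, 0.05),
                    leaf_sat_mass_g = c(0.5, 0.2))
  out <- derive_traits(ind)
  expect_equal(out$sla_cm2_g, c(300, 250))
  expect_equal(out$ldmc_g_g, c(0.2, 0.25))
})

test_that("community-weighted mean is a bounded weighted average", {
  expect_equal(cwm(c(10, 20), c(1, 3)), 17.5)
  expect_equal(cwm(c(4, 8), c(1, 1)), 6)
  expect_equal(cwm(7, 2), 7)
  expect_true(is.na(cwm(c(1, 2), c(0, 0))))
  expect_error(cwm(c(1, 2), c(-1, 2)), "non-negative")

  set.seed(5)
  for (i in 1:20) {
    tr <- rnorm(4, 10, 5)
    w <- runif(4)
    v <- cwm(tr, w)
    expect_gte(v, min(tr))
    expect_lte(v, max(tr))
    expect_equal(cwm(rep(3.3, 4), w), 3.3)  # constant trait
  }
})

test_that("coefficient of variation is the scaled sample SD", {
  expect_equal(cv(c(2, 2, 2)), 0)
  expect_equal(cv(c(1, 2, 3)), 0.5)  # sd = 1, mean = 2
  expect_equal(cv(5 * c(1, 2, 3)), cv(c(1, 2, 3)))  # scale invariance
  expect_true(is.na(cv(3)))
  expect_true(is.na(cv(c(-1, 1))))  # zero mean
})

test_that("hull volumes match analytic fixtures", {
  expect_equal(convhull_volume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(convhull_volume(rbind(c(0, 0, 0), diag(3))), 1 / 6)
  # interior points leave the hull unchanged
  sq <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  expect_equal(convhull_volume(sq), 4)
  expect_equal(convhull_volume(rbind(sq, c(1, 1), c(0.5, 0.3))), 4)
  # translation invariance
  expect_equal(convhull_volume(sweep(sq, 2, c(100, -7))), 4)
  # degenerate in ambient dimension
  expect_equal(convhull_volume(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  # unit cube via its 8 corners (coplanar facet points)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convhull_volume(cube), 1)
})

test_that("hull volume matches the 2-D shoelace oracle on random sets", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    expect_equal(convhull_volume(pts), oracle_hull_area_2d(pts),
                 tolerance = 1e-9)
  }
  # monotone non-decreasing under point addition
  pts <- matrix(rnorm(12), 6, 2)
  v1 <- convhull_volume(pts)
  v2 <- convhull_volume(rbind(pts, rnorm(2, sd = 3)))
  expect_gte(v2 + 1e-12, v1)
})

test_that("functional richness reduces degenerate configurations", {
  # 3 points in 5-trait space: projected to 2 principal axes
  set.seed(9)
  m <- matrix(rnorm(15), 3, 5)
  fr <- fric(m)
  expect_equal(fr$dim, 2)
  expect_false(fr$degenerate)
  expect_gt(fr$volume, 0)
  # volume equals the triangle area in the projected plane
  pc <- prcomp(m)$x[, 1:2]
  expect_equal(fr$volume, oracle_hull_area_2d(pc), tolerance = 1e-9)

  expect_true(fric(matrix(rnorm(10), 2, 5))$degenerate)   # too few points
  expect_true(is.na(fric(matrix(1, 4, 3))$volume))        # zero spread
})

test_that("weekly FPAR averaging validates its inputs", {
  expect_equal(fpar_plot_week(c(40, 50, 60)), 50)
  expect_equal(fpar_plot_week(c(33, 33, 33)), 33)
  expect_equal(fpar_plot_week(c(0, 0, 0)), 0)
  expect_error(fpar_plot_week(c(40, 120, 60)), "\\[0, 100\\]")
})

test_that("trait summaries recover convergence built into the generator", {
  ds <- small_dataset(sigma = 0.1, delta = 0.3, gamma = 0.3, seed = 12,
                      sd_shrink_same = 0.6)
  trs <- trait_summaries(ds)
  pt <- merge(trs$plot_traits, ds$design, by = "plot_id")

  # CWM bounded by species means within each plot
  sp <- trs$species_traits[trs$species_traits$trait == "height_cm", ]
  rng <- do.call(rbind, lapply(split(sp$mean, sp$plot_id), range))
  idx <- match(rownames(rng), pt$plot_id)
  expect_true(all(pt$cwm_height_cm[idx] >= rng[, 1] - 1e-9))
  expect_true(all(pt$cwm_height_cm[idx] <= rng[, 2] + 1e-9))

  # dispersion shrink: community trait CVs lower under same history
  expect_lt(mean(pt$cv_ldmc_g_g[pt$history_class == "same"], na.rm = TRUE),
            mean(pt$cv_ldmc_g_g[pt$history_class == "different"], na.rm = TRUE))
  expect_lt(mean(pt$cv_height_cm[pt$history_class == "same"], na.rm = TRUE),
            mean(pt$cv_height_cm[pt$history_class == "different"], na.rm = TRUE))

  # FRic defined for every community plot, with its reduced dimension
  expect_true(all(is.finite(pt$fric)))
  expect_true(all(pt$fric >= 0))
  expect_true(all(pt$fric_dim[pt$richness == 1] <= 2))
})
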