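test_that("worked partition example and brute-force covariance agree", {
  res <- partition_effects(c(1.5, 2.5), c(2, 4))
  expect_equal(res$NE, 1.0)
  expect_equal(res$CE, 1.125)
  expect_equal(res$SE, -0.125)
  expect_equal(res$NE, res$CE + res$SE)
  # independent check: SE = N * population covariance
  dRY <- c(1.5 / 2 - 0.5, 2.5 / 4 - 0.5)
  expect_equal(res$SE, 2 * oracle_cov_pop(dRY, c(2, 4)))
})

test_that("partition identity NE = CE + SE is exact on random inputs", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    M <- runif(n, 0.5, 30)
    Yo <- runif(n, 0, 25)
    res <- partition_effects(Yo, M)
    expect_equal(res$NE, res$CE + res$SE, tolerance = 1e-12)
    expect_equal(res$NE, sum(Yo) - mean(M), tolerance = 1e-12)
    # permutation invariance
    o <- sample(n)
    res2 <- partition_effects(Yo[o], M[o])
    expect_equal(res2$CE, res$CE, tolerance = 1e-12)
    expect_equal(res2$SE, res$SE, tolerance = 1e-12)
  }
})

test_that("uniform proportional overyielding has zero selection effect", {
  # Yo_i = k * r_i * M_i => dRY_i = (k - 1) r_i, constant => SE = 0
  M <- c(3, 6, 9)
  k <- 1.4
  res <- partition_effects(k * M / 3, M)
  expect_equal(res$SE, 0, tolerance = 1e-12)
  expect_equal(res$CE, res$NE)
  expect_equal(res$NE, (k - 1) * mean(M), tolerance = 1e-12)
})

test_that("expected yield is the proportion-weighted monocrop mean", {
  expect_equal(expected_yield(c(2, 4), c(0.5, 0.5)), 3)
  expect_equal(expected_yield(5, 1), 5)
  expect_equal(expected_yield(c(1, 2, 3, 4)), 2.5)
  expect_error(expected_yield(c(2, 4), c(0.7, 0.5)), "sum to 1")
  expect_error(expected_yield(c(-2, 4)), "positive")
  expect_true(is.na(expected_yield(c(NA, 4))))
})

test_that("partition input contracts are enforced", {
  expect_error(partition_effects(1, 2), "at least two species")
  expect_error(partition_effects(c(1, 2), c(2, 0)), "positive")
  res <- partition_effects(c(1, 2), c(2, NA))
  expect_true(is.na(res$NE) && is.na(res$CE) && is.na(res$SE))
})

test_that("monocrop reference averages plot yields per stratum", {
  des <- data.frame(plot_id = paste0("P", 1:3),
                    kind = "monoculture", fertilized = TRUE,
                    history_class = c("same", "same", "different"),
                    stringsAsFactors = FALSE)
  plots <- data.frame(plot_id = paste0("P", 1:3), species = "Le",
                      yield_g = c(10, 14, 20), stringsAsFactors = FALSE)
  ref <- build_monocrop_reference(plots, des)
  expect_equal(ref$monocrop_yield_g[ref$history_class == "same"], 12)
  expect_equal(ref$n_reps[ref$history_class == "same"], 2L)
  expect_equal(ref$monocrop_yield_g[ref$history_class == "different"], 20)
  expect_equal(ref$n_reps[ref$history_class == "different"], 1L)
})

test_that("total yield sums species seed mass", {
  expect_equal(total_yield(c(3, 4)), 7)
  expect_equal(total_yield(5), 5)
  expect_equal(total_yield(c(0, 0)), 0)
  expect_error(total_yield(c(-1, 2)), "non-negative")
})

test_that("plot-level partition matches history-stratified references", {
  ds <- small_dataset(sigma = 0, delta = 0, gamma = 0, c_intra = 1,
                      c_inter = 1)
  part <- compute_partition(ds)$partition
  # no competition, no noise: mixtures behave exactly as monocultures
  expect_true(all(abs(part$NE) < 1e-9))
  expect_true(all(abs(part$CE) < 1e-9))
  expect_true(all(abs(part$SE) < 1e-9))

  ds2 <- small_dataset(sigma = 0.2, delta = 0.3, gamma = 0.2, seed = 5)
  part2 <- compute_partition(ds2)$partition
  expect_true(all(is.finite(part2$NE)))
  expect_equal(part2$NE, part2$CE + part2$SE, tolerance = 1e-9)
  expect_equal(part2$NE, part2$Yo - part2$YE, tolerance = 1e-12)

  # removing a monoculture stratum nulls dependent mixtures with a reason
  ds3 <- ds2
  drop <- ds3$design$plot_id[ds3$design$kind == "monoculture" &
                               ds3$design$members == "Le"]
  ds3$plots <- ds3$plots[!(ds3$plots$plot_id %in% drop), ]
  part3 <- compute_partition(ds3)$partition
  le_mix <- ds3$design$plot_id[ds3$design$kind == "mixture" &
                                 grepl("Le", ds3$design$members)]
  expect_true(all(is.na(part3$NE[part3$plot_id %in% le_mix])))
  expect_true(all(part3$reason[part3$plot_id %in% le_mix] ==
                    "missing-monocrop-reference"))
})
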