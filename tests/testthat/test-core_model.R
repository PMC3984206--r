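test_that("trophic levels solve simple chains and mixtures exactly", {
  m <- chain_model()
  tl <- compute_trophic_levels(m)
  expect_equal(unname(tl), c(1, 2, 3), tolerance = 1e-12)

  ## consumer eating 50% producer (TL 1) and 50% herbivore (TL 2)
  groups <- data.frame(index = 1:3, name = c("p", "h", "omni"),
                       class = c("producer", "consumer", "consumer"),
                       habitat = "shelf", stanza = "none",
                       biomass = c(10, 1, 0.1), pb = c(10, 2, 1),
                       qb = c(0, 8, 4), ee = NA_real_, pq = NA_real_, ba = 0)
  diet <- matrix(0, 3, 3)
  diet[1, 2] <- 1
  diet[c(1, 2), 3] <- 0.5
  m2 <- food_web_model(groups, diet)
  expect_equal(unname(compute_trophic_levels(m2)), c(1, 2, 2.5), tolerance = 1e-12)
})

test_that("trophic levels match the iterated-substitution oracle on random webs", {
  for (seed in 1:5) {
    b <- balanced_synth(seed, n_consumers = 6)
    tl <- compute_trophic_levels(b)
    expect_equal(unname(tl), unname(tl_substitution_oracle(b)), tolerance = 1e-10)
    expect_true(all(tl >= 1))
    ## linear-system residual straight from the definition
    dc <- b$diet
    basal <- b$groups$class != "consumer"
    rhs <- 1 + as.numeric(t(dc) %*% tl)
    expect_lt(max(abs((tl - rhs)[!basal])), 1e-10)
  }
})

test_that("trophic levels use renormalisation over modelled prey under import", {
  groups <- data.frame(index = 1:2, name = c("p", "c"),
                       class = c("producer", "consumer"), habitat = "shelf",
                       stanza = "none", biomass = c(10, 1), pb = c(10, 1),
                       qb = c(0, 5), ee = NA_real_, pq = NA_real_, ba = 0)
  diet <- matrix(0, 2, 2); diet[1, 2] <- 0.6
  m <- food_web_model(groups, diet, import = c(0, 0.4))
  ## import must not shift the consumer off a pure-herbivore level
  expect_equal(unname(compute_trophic_levels(m))[2], 2, tolerance = 1e-12)
  expect_equal(unname(compute_trophic_levels(m, import_tl = 3))[2],
               1 + 0.6 * 1 + 0.4 * 3, tolerance = 1e-12)
})

test_that("balance recovers EE from flows: two-group textbook case", {
  ## producer B=10, P/B=1; consumer B=1, Q/B=5 eating it entirely
  groups <- data.frame(index = 1:2, name = c("p", "c"),
                       class = c("producer", "consumer"), habitat = "shelf",
                       stanza = "none", biomass = c(10, 1), pb = c(1, 1),
                       qb = c(0, 5), ee = NA_real_, pq = NA_real_, ba = 0)
  diet <- matrix(0, 2, 2); diet[1, 2] <- 1
  b <- balance(food_web_model(groups, diet))
  expect_equal(b$groups$ee[1], 0.5, tolerance = 1e-12)
  expect_equal(b$groups$ee[2], 0, tolerance = 1e-12)  # nothing eats the consumer
})

test_that("balance solves missing biomass jointly and is idempotent", {
  truth <- balanced_synth(7, n_consumers = 5)
  g <- truth$groups
  ## hide two biomasses, give their EE instead
  hide <- which(g$class == "consumer")[c(2, 4)]
  g2 <- g
  g2$biomass[hide] <- NA
  g2$ee[-hide] <- NA
  m2 <- food_web_model(g2, truth$diet, truth$landings,
                       banc_groups = truth$banc_groups, pba = truth$pba)
  b2 <- balance(m2)
  expect_equal(b2$groups$biomass, g$biomass, tolerance = 1e-9)
  ## solving an already-solved model changes nothing (solve o solve = solve)
  g3 <- b2$groups
  g3$ee[hide] <- NA
  b3 <- balance(food_web_model(g3, truth$diet, truth$landings,
                               banc_groups = truth$banc_groups, pba = truth$pba))
  expect_equal(b3$groups$ee, b2$groups$ee, tolerance = 1e-12)
})

test_that("balanced synthetic webs satisfy the master equation to 1e-9", {
  for (seed in c(2, 11, 23)) {
    b <- balanced_synth(seed, n_consumers = 7, fleet_count = 2)
    expect_lt(max(abs(master_residuals(b))), 1e-9)
    expect_equal(nrow(b$balance$ee_violations), 0L)
    ## q_matrix row sums equal each predator's non-import consumption
    g <- b$groups
    expect_equal(unname(rowSums(b$q_matrix)),
                 unname(g$biomass * g$qb * (1 - b$import)), tolerance = 1e-9)
  }
})

test_that("EE above 1 is reported, not clamped", {
  ## consumer demand exceeding producer production
  groups <- data.frame(index = 1:2, name = c("p", "c"),
                       class = c("producer", "consumer"), habitat = "shelf",
                       stanza = "none", biomass = c(1, 2), pb = c(1, 1),
                       qb = c(0, 5), ee = NA_real_, pq = NA_real_, ba = 0)
  diet <- matrix(0, 2, 2); diet[1, 2] <- 1
  expect_warning(b <- balance(food_web_model(groups, diet)), "EE > 1")
  expect_gt(b$groups$ee[1], 1)
  expect_identical(b$balance$ee_violations$group, "p")
})

test_that("over- and under-determined groups are rejected with names", {
  groups <- data.frame(index = 1:2, name = c("p", "c"),
                       class = c("producer", "consumer"), habitat = "shelf",
                       stanza = "none", biomass = c(10, NA), pb = c(1, NA),
                       qb = c(0, 5), ee = NA_real_, pq = NA_real_, ba = 0)
  diet <- matrix(0, 2, 2); diet[1, 2] <- 1
  expect_error(balance(food_web_model(groups, diet)), "more than one unknown")
})

test_that("mortality components add up to P/B for every group", {
  b <- balanced_synth(5, n_consumers = 6, fleet_count = 1)
  mp <- mortality_partition(b)
  expect_lt(max(abs(mp$F + mp$M2 + mp$M0 + mp$BA - mp$PB)), 1e-9)
  ## an unfished, unpreyed top consumer loses everything to other mortality
  b2 <- balanced_synth(5, n_consumers = 6, fleet_count = 0)
  mp2 <- mortality_partition(b2)
  top <- which(mp2$F == 0 & mp2$M2 < 1e-12)
  expect_true(length(top) >= 1)
  expect_equal(mp2$M0[top], mp2$PB[top], tolerance = 1e-9)
})

test_that("diet columns failing the sum-to-one invariant are named", {
  groups <- data.frame(index = 1:3, name = c("p1", "p2", "badcol"),
                       class = c("producer", "producer", "consumer"),
                       habitat = "shelf",
                       stanza = "none", biomass = c(10, 10, 1), pb = c(1, 1, 1),
                       qb = c(0, 0, 5), ee = NA_real_, pq = NA_real_, ba = 0)
  diet <- matrix(0, 3, 3); diet[1, 3] <- 0.5; diet[2, 3] <- 0.51
  expect_error(food_web_model(groups, diet), "badcol")
})
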