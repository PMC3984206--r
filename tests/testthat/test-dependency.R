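test_that("direct MPA consumption sums the right flow columns", {
  b <- balance(chain_model())
  qd <- direct_banc_consumption(b)
  g <- b$groups
  ## the grazer's whole intake is the resident producer; the predator none
  expect_equal(unname(qd), c(0, g$biomass[2] * g$qb[2], 0), tolerance = 1e-12)

  for (seed in 1:3) {
    bs <- balanced_synth(seed)
    qd <- direct_banc_consumption(bs)
    brute <- rowSums(bs$q_matrix[, bs$banc_groups, drop = FALSE])
    expect_equal(unname(qd), unname(brute), tolerance = 1e-12)
  }
})

test_that("transfer fractions follow both stated conventions", {
  b <- balanced_synth(3, fleet_count = 1)
  g <- b$groups
  P <- g$biomass * g$pb
  Y <- rowSums(b$landings)
  t_prod <- transfer_fraction(b, "production")
  t_flow <- transfer_fraction(b, "flow")
  cons <- g$class == "consumer"
  expect_equal(unname(t_flow[cons]), unname((b$m2 * g$biomass / P)[cons]),
               tolerance = 1e-12)
  expect_equal(unname(t_prod[cons]),
               unname((g$ee * (1 - Y / P))[cons]), tolerance = 1e-12)  # ba = 0 here
  expect_true(all(t_prod >= 0 & t_prod < 1))
  ## unfished groups: both conventions collapse to EE
  unf <- cons & Y == 0
  expect_equal(unname(t_prod[unf]), unname(g$ee[unf]), tolerance = 1e-12)
  expect_equal(unname(t_flow[unf]), unname(g$ee[unf]), tolerance = 1e-12)
})

test_that("a pure chain routes all consumption back to the MPA producer", {
  for (ee in c(0.5, 0.8, 1 - 1e-6)) {
    b <- balance(chain_model(ee_grazer = ee))
    dep <- iterate_dependency(b)
    ## the grazer feeds wholly in the MPA; the predator's only food is the
    ## grazer's production, so its dependency is also complete, for any EE
    expect_equal(dep$per_group$pqba[2:3], c(1, 1), tolerance = 1e-9)
  }
})

test_that("first-rank consumers depend on the MPA exactly by their diet share", {
  for (seed in c(4, 9)) {
    b <- balanced_synth(seed, n_consumers = 5)
    dep <- iterate_dependency(b)
    first <- which(b$groups$name == "consumer 1")
    share <- sum(b$diet[b$banc_groups, first])
    expect_equal(dep$per_group$pqba[first], share, tolerance = 1e-9)
    expect_equal(share, b$pba[first], tolerance = 1e-9)
  }
})

test_that("fixed point agrees with path enumeration on acyclic webs", {
  for (seed in 1:6) {
    b <- balanced_synth(seed, n_consumers = 5, n_banc_sedentary = 2,
                        n_shelf_sedentary = 1, fleet_count = 1)
    dep <- iterate_dependency(b, tol = 1e-12, nba_full = FALSE)
    oracle <- dependency_by_paths(b)
    expect_lt(max(abs(dep$per_group$qba_total - oracle)), 1e-8)
    expect_lte(dep$iterations, 200)
    pg <- dep$per_group
    expect_true(all(pg$pqba >= 0 & pg$pqba <= 1))
    expect_true(all(pg$qba_total >= pg$qba_dir - 1e-12))
    g <- b$groups
    expect_true(all(pg$qba_total <= g$biomass * g$qb + 1e-9))
  }
})

test_that("dependency is zero exactly off the MPA's reachability set", {
  b <- balanced_synth(12, n_consumers = 6, pba_range = c(0, 0.9))
  dep <- iterate_dependency(b, nba_full = FALSE)
  ## breadth-first reachability from the sedentary set over predation links
  n <- nrow(b$groups)
  reach <- rep(FALSE, n)
  frontier <- b$banc_groups
  while (length(frontier)) {
    reach[frontier] <- TRUE
    preds <- which(rowSums(b$q_matrix[, frontier, drop = FALSE]) > 0)
    frontier <- setdiff(preds, which(reach))
  }
  pos <- dep$per_group$qba_total > 1e-12
  cons <- b$groups$class == "consumer"
  expect_identical(pos[cons], reach[cons] & TRUE)
})

test_that("a web with no MPA prey yields an all-zero result", {
  b <- balanced_synth(2, n_banc_sedentary = 0)
  expect_error(iterate_dependency(b, banc_groups = integer()), "empty")
  b2 <- balanced_synth(2, n_banc_sedentary = 1, pba_range = c(0, 0))
  dep2 <- iterate_dependency(b2, nba_full = FALSE)
  mobile <- b2$groups$habitat == "coastal"
  expect_true(all(dep2$per_group$qba_total[mobile] == 0))
})

test_that("ecosystem totals are weighted means and hit 100% when fully fed inside", {
  groups <- data.frame(index = 1:2, name = c("ba producer", "feeder"),
                       class = c("producer", "consumer"),
                       habitat = c("banc_sedentary", "coastal"), stanza = "none",
                       biomass = c(50, 1), pb = c(10, 1), qb = c(0, 5),
                       ee = NA_real_, pq = NA_real_, ba = 0)
  diet <- matrix(0, 2, 2); diet[1, 2] <- 1
  landings <- matrix(c(0, 0.5), 2, 1, dimnames = list(NULL, "fleet"))
  b <- balance(food_web_model(groups, diet, landings, banc_groups = 1,
                              pba = c(0, 1)))
  dep <- iterate_dependency(b)
  tot <- ecosystem_totals(dep, b, banc_producers = 1)
  expect_equal(unlist(tot$totals), c(pct_Q = 100, pct_P_animals = 100,
                                     pct_P_with_producers = 100, pct_Y = 100),
               tolerance = 1e-9)
  expect_error(ecosystem_totals(dep, b, subsets = list(none = integer())),
               "empty")
})

test_that("subset totals are consumption-weighted means of member proportions", {
  b <- balanced_synth(8, n_consumers = 5)
  dep <- iterate_dependency(b)
  g <- b$groups
  ix <- which(g$name %in% c("consumer 2", "consumer 4"))
  tot <- ecosystem_totals(dep, b, subsets = list(two = ix))
  Q <- g$biomass * g$qb
  expect_equal(tot$by_subset["two", "pct_Q"],
               100 * sum(dep$per_group$pqba[ix] * Q[ix]) / sum(Q[ix]),
               tolerance = 1e-12)
})
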