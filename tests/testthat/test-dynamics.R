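test_that("arena calibration reproduces the base flows exactly at t = 0", {
  b <- balanced_synth(5, n_consumers = 6, fleet_count = 1)
  g <- b$groups
  for (v in list(2, 10, rep(3, nrow(g)))) {
    cal <- arena_calibration(b, v)
    B <- g$biomass
    q_t0 <- ifelse(cal$donor,
                   cal$q0 / cal$bi0 * ifelse(cal$det_prey, cal$bi0, B[cal$ip]),
                   cal$a * cal$vr * B[cal$ip] * B[cal$jp] /
                     (2 * cal$vr + cal$a * B[cal$jp]))
    expect_equal(q_t0, cal$q0, tolerance = 1e-12)
  }
  ## the bottom-up limit is donor control
  cal1 <- arena_calibration(b, 1)
  expect_true(all(cal1$donor))
  expect_error(arena_calibration(b, 0.5), ">= 1")
})

test_that("the base year is an equilibrium under unit effort", {
  b <- balanced_synth(3, n_consumers = 6, fleet_count = 1)
  run <- simulate_foodweb(b, v = 2, effort = NULL, years = 1991:1995)
  drift <- abs(run$B_end / b$groups$biomass - 1)
  expect_lt(max(drift[b$groups$class != "detritus"]), 0.005)
  expect_null(run$clamp_events)
})

test_that("trajectories match an independent fine-step ODE reference", {
  skip_if_not_installed("deSolve")
  b <- balance(chain_model(ee_grazer = 0.8, fy_pred = 0.3))
  ef <- effort_series(1991:2000,
                      matrix(seq(1, 2.5, length.out = 10), 10, 1,
                             dimnames = list(NULL, "artisanal")))
  run <- simulate_foodweb(b, v = 3, effort = ef, years = 1991:2000)

  ## reference: same arena/producer equations re-assembled from scratch and
  ## integrated with lsoda at tight tolerance, year by year (stepwise effort)
  g <- b$groups
  cal <- arena_calibration(b, 3)
  Fb <- rowSums(b$landings) / g$biomass
  rhs <- function(t, B, parms) {
    q <- numeric(length(cal$ip))
    for (k in seq_along(cal$ip)) {
      i <- cal$ip[k]; j <- cal$jp[k]
      q[k] <- cal$a[k] * cal$vr[k] * B[i] * B[j] / (2 * cal$vr[k] + cal$a[k] * B[j])
    }
    dB <- numeric(3)
    dB[1] <- 3 * g$pb[1] * g$biomass[1] * B[1] / (B[1] + 2 * g$biomass[1]) -
      sum(q[cal$ip == 1]) - b$m0[1] * B[1]
    for (j in 2:3) {
      dB[j] <- g$pq[j] * sum(q[cal$jp == j]) - sum(q[cal$ip == j]) -
        (b$m0[j] + parms$F[j]) * B[j]
    }
    list(dB)
  }
  B <- g$biomass
  for (yi in 1:10) {
    sol <- deSolve::lsoda(B, seq(0, 1, by = 0.05), rhs,
                          parms = list(F = Fb * ef$effort[yi, 1]),
                          rtol = 1e-10, atol = 1e-12)
    B <- as.numeric(sol[nrow(sol), -1])
  }
  expect_equal(unname(run$B_end), B, tolerance = 1e-3)
})

test_that("fictive-fleet mortality follows the doubling-and-cap rule", {
  pba <- c(1, 0.5, 0)
  caps <- c(0.4, 0.8, 0.8)
  expect_equal(unname(fictive_fleet_F(pba, 1991, caps)[1, ]),
               c(0.02, 0.01, 0))
  ## 1996: 0.02 * 2^5 = 0.64, capped at 0.4 for the juvenile-type group
  expect_equal(unname(fictive_fleet_F(pba, 1996, caps)[1, ]),
               c(0.4, 0.32, 0))
  expect_equal(unname(fictive_fleet_F(pba, 2020, caps)[1, ]),
               c(0.4, 0.4, 0))
  expect_error(fictive_fleet_F(pba, 1990, caps), "before")
  g <- data.frame(stanza = c("juvenile", "none", "none"),
                  name = c("x", "Coastal S", "big"))
  expect_equal(default_fictive_caps(g), c(0.4, 0.4, 0.8))
})

test_that("raising one fleet's effort cannot raise its target's biomass", {
  b <- balance(chain_model(fy_pred = 0.2))
  base <- simulate_foodweb(b, v = 2, years = 1991:2010)
  up <- simulate_foodweb(b, v = 2,
                         effort = effort_series(1991:1992,
                           matrix(c(1, 2), 2, 1,
                                  dimnames = list(NULL, "artisanal"))),
                         years = 1991:2010)
  expect_lt(up$B_end["predator"], base$B_end["predator"])
  ## and the prey of the harvested predator is released
  expect_gt(up$B_end["grazer"], base$B_end["grazer"])
})

test_that("habitat-loss forcing drives an unconnected group to the floor only", {
  groups <- data.frame(
    index = 1:3, name = c("plants", "grazer", "lone producer"),
    class = c("producer", "consumer", "producer"),
    habitat = c("producer", "shelf", "banc_sedentary"), stanza = "none",
    biomass = c(100, 5, 30), pb = c(10, 2, 20), qb = c(0, 8, 0),
    ee = NA_real_, pq = c(NA, 0.25, NA), ba = 0)
  diet <- matrix(0, 3, 3); diet[1, 2] <- 1
  b <- balance(food_web_model(groups, diet, banc_groups = 3))
  sq <- scenario_statusquo(b, v = 2, years = 1991:2015)
  hl <- scenario_habitat_loss(b, v = 2, years = 1991:2015, forced = 3,
                              soft_groups = character())
  expect_lte(hl$B_end["lone producer"], hl$floor[3] * (1 + 1e-9))
  expect_equal(unname(hl$B_end[1:2]), unname(sq$B_end[1:2]), tolerance = 1e-9)

  ratios <- end_state_ratios(hl, sq)
  expect_true(ratios$per_group$undefined[3] ||
                ratios$per_group$ratio[3] < 1e-6)
  same <- end_state_ratios(sq, sq)
  expect_equal(same$per_group$ratio, rep(1, 3), tolerance = 1e-12)
})

test_that("vulnerability fitting flags non-identifiable flat series", {
  b <- balanced_synth(3, n_consumers = 5, fleet_count = 1)
  g <- b$groups
  fished <- g$name[g$class == "consumer" & rowSums(b$landings) > 0][1]
  ef <- effort_series(1991:1996, matrix(1, 6, 1,
                                        dimnames = list(NULL, "fleet1")))
  obs <- data.frame(year = 1991:1996, type = "biomass", group = fished,
                    value = g$biomass[match(fished, g$name)])
  fit <- fit_vulnerabilities(b, ef, obs, groups_to_fit = fished)
  expect_true(fit$diagnostics$flat[1])
  expect_equal(unname(fit$v[fished]), 1)
})

test_that("noise-free observations are refit with near-zero error at the truth", {
  spec <- synth_spec(n_consumers = 4, n_banc_sedentary = 1,
                     n_shelf_sedentary = 1, fleet_count = 1,
                     effort_trend = 1.15, n_years = 12, seed = 21)
  web <- generate_web(spec)
  ef <- generate_effort(spec, web)
  obs <- generate_observations(web, v_truth = 2, effort = ef, noise_sd = 0)
  fit <- fit_vulnerabilities(obs$balanced, ef, obs$series,
                             groups_to_fit = unique(obs$series$group),
                             v_init = 2)
  expect_lt(fit$ss_initial, 1e-12)
  expect_lte(fit$ss, fit$ss_initial + 1e-12)
})
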