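#' Specification for a synthetic two-habitat food web
#'
#' Describes the shape of a randomly generated, balanced-by-construction web
#' emulating the study design: sedentary producer/invertebrate groups inside
#' the protected area mirrored by shelf counterparts, mobile consumers whose
#' invertebrate feeding splits across the two habitats by a per-consumer
#' `pBA` share, multi-fleet catches, trending effort, and log-normal
#' observation noise.
#'
#' @param n_consumers number of mobile consumer groups (>= 1).
#' @param n_banc_sedentary,n_shelf_sedentary numbers of sedentary
#'   invertebrate groups in the MPA and on the shelf.
#' @param connectance fraction of permitted (lower-ranked) prey links
#'   realised per consumer, in (0, 1].
#' @param pba_range range from which each consumer's MPA feeding share is
#'   drawn.
#' @param fleet_count number of fleets.
#' @param effort_trend per-fleet yearly geometric growth of effort (recycled
#'   to `fleet_count`).
#' @param obs_noise_sd log-scale standard deviation of observation noise.
#' @param n_years length of the emulated observation period.
#' @param seed integer seed making every generated artefact reproducible.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_consumers = 6, n_banc_sedentary = 2,
                       n_shelf_sedentary = 2, connectance = 0.6,
                       pba_range = c(0.2, 0.8), fleet_count = 1,
                       effort_trend = 1.07, obs_noise_sd = 0.1,
                       n_years = 16, seed = 1) {
  stopifnot(n_consumers >= 1, n_banc_sedentary >= 0, n_shelf_sedentary >= 1,
            connectance > 0, connectance <= 1, fleet_count >= 0, n_years >= 2)
  structure(list(n_consumers = n_consumers,
                 n_banc_sedentary = n_banc_sedentary,
                 n_shelf_sedentary = n_shelf_sedentary,
                 connectance = connectance, pba_range = pba_range,
                 fleet_count = fleet_count,
                 effort_trend = rep(effort_trend, length.out = max(fleet_count, 1)),
                 obs_noise_sd = obs_noise_sd, n_years = n_years, seed = seed),
            class = "synth_spec")
}

#' Generate a balanced two-habitat food web
#'
#' Builds an acyclic (by trophic ordering) web: one producer per habitat,
#' sedentary invertebrates feeding on their habitat's producer, and mobile
#' consumers feeding on invertebrates (split between habitats by a drawn
#' `pBA`) and on lower-ranked consumers.  Parameters are drawn in plausible
#' ranges (consumption rates decreasing with rank, gross efficiency in
#' 0.05-0.3); biomasses are then assigned from the top of the web downwards
#' so every group's ecotrophic efficiency equals its drawn target in
#' (0.3, 0.95) exactly - the web passes [balance()] with zero violations by
#' construction.  Ground-truth dependency is recoverable with
#' [dependency_by_paths()].
#'
#' @param spec a [synth_spec()].
#' @return A [food_web_model()] with all parameters filled, plus attributes
#'   `truth` (list: `pba`, `ee`, drawn fished fractions).
#' @export
generate_web <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed_(spec$seed, generate_web_impl(spec))
}

generate_web_impl <- function(spec, max_retry = 10) {
  for (try in seq_len(max_retry)) {
    web <- tryCatch(generate_web_once(spec), error = function(e) e)
    if (!inherits(web, "error")) return(web)
  }
  stopf("could not generate a balanced web after %d attempts: %s",
        max_retry, conditionMessage(web))
}

generate_web_once <- function(spec) {
  nb <- spec$n_banc_sedentary; ns <- spec$n_shelf_sedentary
  nc <- spec$n_consumers
  has_ba <- nb > 0
  ## order: producers, banc inverts, shelf inverts, consumers (by rank), detritus
  names <- c(if (has_ba) "BA producer", "shelf producer",
             if (nb) paste0("BA invert ", seq_len(nb)),
             paste0("shelf invert ", seq_len(ns)),
             paste0("consumer ", seq_len(nc)), "detritus")
  n <- length(names)
  class <- c(rep("producer", 1 + has_ba), rep("consumer", nb + ns + nc), "detritus")
  habitat <- c(if (has_ba) "producer", "producer",
               rep("banc_sedentary", nb), rep("shelf_sedentary", ns),
               rep("coastal", nc), "detritus")
  prod_ba <- if (has_ba) 1L else NA_integer_
  prod_sh <- 1L + has_ba
  inv_ba <- if (nb) prod_sh + seq_len(nb) else integer()
  inv_sh <- prod_sh + nb + seq_len(ns)
  cons <- prod_sh + nb + ns + seq_len(nc)
  deti <- n

  qb <- pb <- pq <- ee_t <- fy <- numeric(n)
  pq[c(inv_ba, inv_sh)] <- stats::runif(nb + ns, 0.1, 0.3)
  qb[c(inv_ba, inv_sh)] <- stats::runif(nb + ns, 8, 30)
  pq[cons] <- stats::runif(nc, 0.05, 0.3)
  qb[cons] <- exp(seq(log(9), log(2.5), length.out = nc)) * stats::runif(nc, 0.8, 1.2)
  pb[class == "consumer"] <- (pq * qb)[class == "consumer"]
  pb[c(prod_ba, prod_sh)[!is.na(c(prod_ba, prod_sh))]] <- stats::runif(1 + has_ba, 20, 80)
  ee_t[class == "consumer"] <- stats::runif(nb + ns + nc, 0.3, 0.95)
  ee_t[c(prod_ba, prod_sh)[!is.na(c(prod_ba, prod_sh))]] <- stats::runif(1 + has_ba, 0.2, 0.9)

  ## fleets fish some consumers (never the top-of-web EE slack breakers)
  nf <- spec$fleet_count
  fished <- if (nf) cons[stats::runif(nc) < 0.5] else integer()
  fy[fished] <- stats::runif(length(fished), 0.05, 0.2)

  ## diets: consumer r eats invertebrates (split by pba) and lower consumers
  dc <- matrix(0, n, n)
  pba <- numeric(n)
  for (k in seq_len(nb + ns)) {
    i <- c(inv_ba, inv_sh)[k]
    src <- if (i %in% inv_ba) prod_ba else prod_sh
    dc[src, i] <- 1
  }
  for (r in seq_len(nc)) {
    j <- cons[r]
    pba_j <- if (has_ba) stats::runif(1, spec$pba_range[1], spec$pba_range[2]) else 0
    pba[j] <- pba_j
    lower_cons <- cons[seq_len(r - 1)]
    pick <- lower_cons[stats::runif(length(lower_cons)) < spec$connectance]
    w_cons <- if (length(pick)) stats::runif(length(pick), 0.2, 1) else numeric()
    inv_share <- if (r == 1 || !length(pick)) 1 else stats::runif(1, 0.3, 0.8)
    ## invertebrate part split between habitats by pba
    w_ba <- if (nb) stats::runif(nb, 0.2, 1) else numeric()
    w_sh <- stats::runif(ns, 0.2, 1)
    dc[inv_ba, j] <- pba_j * inv_share * w_ba / sum(w_ba)
    dc[inv_sh, j] <- (1 - pba_j) * inv_share * w_sh / sum(w_sh)
    if (length(pick))
      dc[pick, j] <- (1 - inv_share) * w_cons / sum(w_cons)
  }

  ## biomasses top-down so realised EE equals its target
  B <- rep(NA_real_, n)
  Y <- numeric(n)
  for (j in rev(c(inv_ba, inv_sh, cons))) {
    demand <- sum(B * qb * dc[j, ], na.rm = TRUE)
    if (demand <= 0) {            # top of the web: biomass drawn, EE = fished share
      B[j] <- stats::runif(1, 0.5, 2)
      ee_t[j] <- fy[j]
    } else {
      if (ee_t[j] - fy[j] < 0.05) ee_t[j] <- min(fy[j] + 0.3, 0.95)
      B[j] <- demand / (pb[j] * (ee_t[j] - fy[j]))
    }
    Y[j] <- fy[j] * pb[j] * B[j]
  }
  for (p in c(prod_ba, prod_sh)[!is.na(c(prod_ba, prod_sh))]) {
    demand <- sum(B * qb * dc[p, ], na.rm = TRUE)
    B[p] <- max(demand, 1e-6) / (pb[p] * ee_t[p])
  }
  B[deti] <- sum(B[-deti] * pb[-deti], na.rm = TRUE)  # nominal detrital pool

  landings <- if (nf) {
    L <- matrix(0, n, nf, dimnames = list(names, paste0("fleet", seq_len(nf))))
    if (length(fished)) {
      shares <- matrix(stats::runif(length(fished) * nf), ncol = nf)
      shares <- shares / rowSums(shares)
      L[fished, ] <- Y[fished] * shares
    }
    L
  } else NULL

  groups <- data.frame(index = seq_len(n), name = names, class = class,
                       habitat = habitat,
                       stanza = "none",
                       biomass = B, pb = pb,
                       qb = ifelse(class == "consumer", qb, 0),
                       ee = NA_real_,            # left for balance() to recover
                       pq = ifelse(class == "consumer", pq, NA_real_),
                       ba = 0)
  web <- food_web_model(groups, dc, landings,
                        banc_groups = c(if (has_ba) prod_ba, inv_ba),
                        pba = pba)
  attr(web, "truth") <- list(pba = pba, ee = ee_t, fished_fraction = fy)
  web
}

#' Generate a trending effort series for a synthetic web
#'
#' @param spec a [synth_spec()].
#' @param web the matching [generate_web()] output.
#' @param start_year first year (default 1991).
#' @return An [effort_series()] of `spec$n_years` years with per-fleet
#'   geometric growth `effort_trend`.
#' @export
generate_effort <- function(spec, web, start_year = 1991) {
  years <- start_year + seq_len(spec$n_years) - 1
  nf <- length(web$fleets)
  if (!nf) stopf("web has no fleets")
  E <- vapply(seq_len(nf), function(f)
    spec$effort_trend[[min(f, length(spec$effort_trend))]]^(seq_along(years) - 1),
    numeric(length(years)))
  colnames(E) <- web$fleets
  effort_series(years, E)
}

#' Generate noisy observation series from a simulated truth
#'
#' Simulates the web under known vulnerabilities and effort, then multiplies
#' the annual biomass and total catch of the requested groups by independent
#' log-normal noise `exp(N(0, noise_sd^2))`.  With `noise_sd = 0` the
#' observations equal the simulation output exactly, and catches are
#' consistent with `F * B` before noise.
#'
#' @param web a balanced-by-construction [generate_web()] output (it is
#'   [balance()]d internally).
#' @param v_truth vulnerabilities used as ground truth.
#' @param effort an [effort_series()].
#' @param noise_sd log-scale observation noise.
#' @param seed RNG seed for the noise draws.
#' @param groups group names to observe (default: all fished consumers).
#' @return List with `series` (data frame `year`, `type`, `group`, `value`),
#'   `run` (the noise-free `scenario_run`) and `balanced`.
#' @export
generate_observations <- function(web, v_truth, effort, noise_sd = 0.1,
                                  seed = 1, groups = NULL) {
  balanced <- balance(web)
  g <- balanced$groups
  if (is.null(groups))
    groups <- g$name[g$class == "consumer" & total_landings(balanced) > 0]
  run <- simulate_foodweb(balanced, v_truth, effort, effort$years)
  yi <- seq_along(effort$years)
  ser <- do.call(rbind, lapply(groups, function(nm) {
    gi <- match(nm, g$name)
    rbind(data.frame(year = effort$years, type = "biomass", group = nm,
                     value = run$biomass[yi, gi]),
          data.frame(year = effort$years, type = "catch", group = nm,
                     value = rowSums(run$catch[yi, gi, , drop = FALSE], dims = 1)))
  }))
  ser <- ser[ser$value > 0, , drop = FALSE]
  ser$value <- with_seed_(seed,
    ser$value * exp(stats::rnorm(nrow(ser), 0, noise_sd)))
  list(series = ser, run = run, balanced = balanced)
}
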