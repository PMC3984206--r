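#' Fleet effort series
#'
#' @param years ordered integer years.
#' @param effort numeric matrix, years by fleets, of effort multipliers
#'   relative to the base (first) year; the first row must be 1 for every
#'   fleet and all entries non-negative.
#' @return data structure of class `effort_series`.
#' @export
effort_series <- function(years, effort) {
  effort <- as.matrix(effort)
  if (nrow(effort) != length(years)) stopf("effort must have one row per year")
  if (any(effort < 0)) stopf("efforts must be non-negative")
  if (any(abs(effort[1, ] - 1) > 1e-9)) stopf("base-year effort must be 1 for every fleet")
  if (is.unsorted(years, strictly = TRUE)) stopf("years must be strictly increasing")
  structure(list(years = as.integer(years), effort = effort), class = "effort_series")
}

effort_at <- function(es, year, fleets) {
  if (is.null(es)) return(stats::setNames(rep(1, length(fleets)), fleets))
  E <- es$effort[, fleets, drop = FALSE]
  i <- findInterval(year, es$years)
  if (i < 1) i <- 1                      # before series: base effort
  E[min(i, nrow(E)), ]                   # after series: hold last value
}

#' Foraging-arena calibration of consumption rates
#'
#' For every trophic link the vulnerable-pool exchange rate is
#' `v = V * Q0 / B_prey0` (with `V` the dimensionless vulnerability
#' multiplier, `V = 1` the bottom-up limit) and the arena search rate `a` is
#' chosen so the flow at the base state equals the mass-balance flow `Q0`
#' exactly: `Q(B) = a v B_i B_j / (2 v + a B_j)` with
#' `a = 2 v / (B_j0 (V - 1))`.  Links with `V` at 1 are donor-controlled
#' (`Q = Q0 B_i / B_i0`); flows out of detritus use the (constant) detritus
#' pool as donor biomass.
#'
#' @param balanced a [balance()]d model.
#' @param v vulnerability multipliers: a single number, a per-predator named
#'   or unnamed vector (recycled over that predator's prey links), or a full
#'   per-link matrix (predator rows by prey columns).  All values `>= 1`.
#' @return Internal calibration object used by [simulate_foodweb()].
#' @export
arena_calibration <- function(balanced, v = 2) {
  g <- balanced$groups
  n <- nrow(g)
  Vm <- expand_vuln(v, n)
  if (any(Vm < 1 - 1e-9)) stopf("vulnerability multipliers must be >= 1")
  Qm <- balanced$q_matrix
  link <- which(Qm > 0, arr.ind = TRUE)          # [pred, prey]
  jp <- link[, 1]; ip <- link[, 2]
  q0 <- Qm[link]
  bi0 <- g$biomass[ip]; bj0 <- g$biomass[jp]
  V <- Vm[link]
  vr <- V * q0 / bi0
  donor <- V <= 1 + 1e-9
  a <- ifelse(donor, NA_real_, 2 * vr / (bj0 * (V - 1)))
  list(ip = ip, jp = jp, q0 = q0, bi0 = bi0, vr = vr, a = a, donor = donor,
       det_prey = g$class[ip] == "detritus",
       n = n, V = Vm)
}

expand_vuln <- function(v, n) {
  if (is.matrix(v)) {
    if (!all(dim(v) == n)) stopf("vulnerability matrix must be %d x %d", n, n)
    return(v)
  }
  if (length(v) == 1) return(matrix(v, n, n))
  if (length(v) != n) stopf("per-predator vulnerabilities must have length %d", n)
  matrix(rep(v, each = n), n, n, byrow = TRUE)   # row j = predator j's value
}

#' Simulate effort-driven biomass dynamics
#'
#' Integrates the foraging-arena biomass ODEs
#' `dB_j/dt = (P/Q)_j * sum Q_in - sum Q_out - (M0_j + F_j(t) + Mx_j(t)) B_j`
#' with producers following a saturating primary-production response
#' (`P(B) = 3 (P/B)_0 B_0 B / (B + 2 B_0)`, half-saturation at twice the
#' base biomass) and detritus held at its base pool.  Rates are calibrated so
#' the model starts exactly at the mass-balance flows; with unit effort and
#' no accumulation terms the base state is an equilibrium.  Fishing mortality
#' is the base fleet pattern scaled by yearly effort multipliers plus any
#' extra per-group forcing.  Integration is classic RK4 with automatic
#' stability-based substepping of the base monthly step; states falling below
#' `floor_frac` times the initial biomass are clamped to that floor and the
#' event logged.
#'
#' @param balanced a [balance()]d model.
#' @param v vulnerabilities, as in [arena_calibration()].
#' @param effort an [effort_series()] or `NULL` (unit effort throughout).
#' @param years integer vector of simulated years (e.g. `1991:2041`).
#' @param extra_F optional matrix (years by groups) of additional fishing
#'   mortality (yr^-1), credited to a fleet named `"fictive"`.
#' @param extra_M optional matrix (years by groups) of additional
#'   non-fishery mortality forcing (yr^-1).
#' @param steps_per_year base integration steps per year (default 12).
#' @param floor_frac extinction floor as a fraction of initial biomass.
#' @return Object of class `scenario_run`: `years`, `biomass` (matrix with
#'   one row per year start plus the final state), `catch` (array year by
#'   group by fleet, t km^-2 yr^-1), `clamp_events`, and the final-year state
#'   `B_end`.
#' @export
simulate_foodweb <- function(balanced, v = 2, effort = NULL, years,
                             extra_F = NULL, extra_M = NULL,
                             steps_per_year = 12, floor_frac = 1e-10) {
  g <- balanced$groups
  n <- nrow(g)
  cal <- arena_calibration(balanced, v)
  det <- g$class == "detritus"
  prod <- g$class == "producer"
  cons <- g$class == "consumer"
  B0 <- g$biomass
  pq <- ifelse(cons, g$pb / pmax(g$qb, 1e-300), 0)
  M0 <- ifelse(det, 0, balanced$m0)
  imp_coef <- ifelse(cons, g$qb * balanced$import, 0)
  fleets <- balanced$fleets
  Fbase <- if (length(fleets)) t(balanced$landings / pmax(B0, 1e-300)) else
    matrix(0, 0, n)                              # fleet rows x group cols
  has_fic <- !is.null(extra_F)
  out_fleets <- c(fleets, if (has_fic) "fictive")

  ny <- length(years)
  if (!is.null(extra_F) && (!all(dim(extra_F) == c(ny, n))))
    stopf("extra_F must be %d x %d", ny, n)
  if (!is.null(extra_M) && (!all(dim(extra_M) == c(ny, n))))
    stopf("extra_M must be %d x %d", ny, n)

  ip <- cal$ip; jp <- cal$jp
  det_link_B <- ifelse(cal$det_prey, cal$bi0, NA_real_)

  ## fast link-to-group aggregation matrices
  nl <- length(ip)
  Ain <- matrix(0, n, nl);  Ain[cbind(jp, seq_len(nl))] <- 1
  Aout <- matrix(0, n, nl); Aout[cbind(ip, seq_len(nl))] <- ifelse(cal$det_prey, 0, 1)

  link_flows <- function(B) {
    Bi <- ifelse(cal$det_prey, det_link_B, B[ip])
    Bj <- B[jp]
    qv <- ifelse(cal$donor,
                 cal$q0 / cal$bi0 * Bi,
                 cal$a * cal$vr * Bi * Bj / (2 * cal$vr + cal$a * Bj))
    pmax(qv, 0)
  }
  deriv <- function(B, Fv, Mx) {
    ql <- link_flows(B)
    qin <- as.numeric(Ain %*% ql)
    qout <- as.numeric(Aout %*% ql)
    gain <- numeric(n)
    gain[cons] <- pq[cons] * (qin[cons] + imp_coef[cons] * B[cons])
    gain[prod] <- 3 * g$pb[prod] * B0[prod] * B[prod] / (B[prod] + 2 * B0[prod])
    dB <- gain - qout - (M0 + Fv + Mx) * B
    dB[det] <- 0
    ## stiffness estimate: per-biomass turnover (gains and losses)
    list(dB = dB, loss_rate = ifelse(B > 0, (qout + gain) / B, 0) + M0 + Fv + Mx,
         qin = qin)
  }

  floorB <- floor_frac * pmax(B0, 1e-300)
  B <- B0
  biomass <- matrix(NA_real_, ny + 1, n, dimnames = list(NULL, g$name))
  catch <- array(0, c(ny, n, length(out_fleets)),
                 dimnames = list(years, g$name, out_fleets))
  clamp_events <- list()
  dt0 <- 1 / steps_per_year

  for (yi in seq_len(ny)) {
    biomass[yi, ] <- B
    ef <- effort_at(effort, years[yi], fleets)
    Fmat <- if (length(fleets)) Fbase * ef else Fbase   # fleet x group
    Fv <- if (length(fleets)) colSums(Fmat) else numeric(n)
    xF <- if (has_fic) extra_F[yi, ] else numeric(n)
    Mx <- if (!is.null(extra_M)) extra_M[yi, ] else numeric(n)
    Ftot <- Fv + xF
    for (s in seq_len(steps_per_year)) {
      d1 <- deriv(B, Ftot, Mx)
      lam <- max(d1$loss_rate, 1e-9)
      nsub <- max(1L, ceiling(lam * dt0 / 1.5))
      h <- dt0 / nsub
      for (ss in seq_len(nsub)) {
        k1 <- deriv(B, Ftot, Mx)$dB
        k2 <- deriv(pmax(B + h / 2 * k1, floorB), Ftot, Mx)$dB
        k3 <- deriv(pmax(B + h / 2 * k2, floorB), Ftot, Mx)$dB
        k4 <- deriv(pmax(B + h * k3, floorB), Ftot, Mx)$dB
        Bn <- B + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        if (any(!is.finite(Bn))) stopf("non-finite biomass at year %d", years[yi])
        low <- which(Bn < floorB & !det)
        if (length(low)) {
          Bn[low] <- floorB[low]
          clamp_events[[length(clamp_events) + 1]] <-
            data.frame(year = years[yi], group = g$name[low])
        }
        Bn[det] <- B0[det]
        ## accrue catch over the substep
        if (length(fleets))
          catch[yi, , seq_along(fleets)] <- catch[yi, , seq_along(fleets)] +
            t(Fmat * rep(Bn, each = length(fleets))) * h
        if (has_fic)
          catch[yi, , length(out_fleets)] <- catch[yi, , length(out_fleets)] +
            xF * Bn * h
        B <- Bn
      }
    }
  }
  biomass[ny + 1, ] <- B
  structure(list(years = years, biomass = biomass, catch = catch,
                 fleets = out_fleets, B_end = stats::setNames(B, g$name),
                 clamp_events = if (length(clamp_events))
                   do.call(rbind, clamp_events) else NULL,
                 floor = floorB),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> %d years (%d-%d), %d groups, %d fleet(s), %d clamp event(s)\n",
              length(x$years), min(x$years), max(x$years), ncol(x$biomass),
              length(x$fleets), NROW(x$clamp_events)))
  invisible(x)
}

#' Fictive-fleet fishing mortality inside the MPA
#'
#' Additional fishing mortality for a hypothetical fleet operating inside
#' the protected area, proportional to each group's share of invertebrate
#' feeding taken there: `F_{y,i} = pBA_i * min(F0 * 2^(y - start), cap_i)`,
#' with the fleet-wide mortality starting at `F0 = 0.02` in the start year
#' and doubling yearly until the per-group cap (0.4 yr^-1 for juveniles and
#' the small coastal/shelf fish, 0.8 yr^-1 otherwise).
#'
#' @param pba per-group MPA feeding proportion.
#' @param year simulation year (scalar or vector).
#' @param caps per-group cap vector (see [default_fictive_caps()]).
#' @param start_year first year of the fleet (default 1991).
#' @param f0 initial fleet mortality (default 0.02 yr^-1).
#' @return Matrix of per-group F additions, years by groups.
#' @export
fictive_fleet_F <- function(pba, year, caps, start_year = 1991, f0 = 0.02) {
  if (any(year < start_year)) stopf("year before fleet start %d", start_year)
  if (length(caps) != length(pba)) stopf("caps and pba lengths differ")
  out <- vapply(year, function(y) {
    fy <- f0 * 2^(y - start_year)
    pba * pmin(fy, caps)
  }, numeric(length(pba)))
  t(out)
}

#' Default fictive-fleet mortality caps
#'
#' 0.4 yr^-1 for juvenile stanzas and for small coastal and shelf fish
#' (less targeted due to body size), 0.8 yr^-1 for all other groups.
#'
#' @param groups the model's group table.
#' @param small_names group names receiving the low cap in addition to
#'   juveniles.
#' @return Numeric vector of caps.
#' @export
default_fictive_caps <- function(groups,
                                 small_names = c("Coastal S", "Shelf S", "shelf S")) {
  ifelse(groups$stanza == "juvenile" | groups$name %in% small_names, 0.4, 0.8)
}

#' Status-quo projection
#'
#' Projects the system under constant (last observed, default unit) effort.
#'
#' @inheritParams simulate_foodweb
#' @return A `scenario_run`.
#' @export
scenario_statusquo <- function(balanced, v = 2, effort = NULL, years,
                               steps_per_year = 12) {
  simulate_foodweb(balanced, v, effort, years, steps_per_year = steps_per_year)
}

#' Fictive-fleet scenario
#'
#' Adds the MPA fictive fleet ([fictive_fleet_F()]) on top of the baseline
#' effort pattern and projects forward.
#'
#' @inheritParams simulate_foodweb
#' @param caps per-group F caps; default [default_fictive_caps()].
#' @param start_year fleet start (default the first simulated year).
#' @param f0 initial fleet mortality.
#' @return A `scenario_run`.
#' @export
scenario_fictive_fleet <- function(balanced, v = 2, effort = NULL, years,
                                   caps = NULL, start_year = min(years),
                                   f0 = 0.02, steps_per_year = 12) {
  g <- balanced$groups
  caps <- caps %||% default_fictive_caps(g)
  xF <- fictive_fleet_F(balanced$pba, years, caps, start_year, f0)
  ## only exploited classes are targeted
  xF[, g$class != "consumer"] <- 0
  simulate_foodweb(balanced, v, effort, years, extra_F = xF,
                   steps_per_year = steps_per_year)
}

#' Habitat-loss scenario
#'
#' Applies an additional mortality to the groups resident in the MPA,
#' starting at `m_init` (0.02 yr^-1) and doubling yearly (growth
#' configurable), to emulate a progressive destruction of the habitat.  For
#' the macrophyte group(s) listed in `soft_groups` the forcing is capped at
#' `soft_cap_frac * (P/B)`: with the saturating production response
#' `P(B)/B = 3 (P/B)_0 B_0/(B + 2 B_0)`, an extra mortality of
#' `(3/2.6 - 1) (P/B)_0 ~= 0.154 (P/B)_0` moves the producer equilibrium to
#' 60% of its base biomass, the reported seagrass response; all other forced
#' groups are driven to the extinction floor (forcing capped only at
#' `hard_cap` for integrator sanity).
#'
#' @inheritParams simulate_foodweb
#' @param forced integer indices of forced groups (default: the model's
#'   sedentary set plus the MPA macrophytes named in `soft_groups`).
#' @param m_init initial forcing (yr^-1).
#' @param growth yearly growth factor of the forcing (default 2).
#' @param soft_groups names of forced producers that decline but persist.
#' @param soft_cap_frac forcing cap for `soft_groups`, as a fraction of P/B.
#' @param hard_cap numeric cap (yr^-1) for all other forced groups.
#' @return A `scenario_run`.
#' @export
scenario_habitat_loss <- function(balanced, v = 2, effort = NULL, years,
                                  forced = NULL, m_init = 0.02, growth = 2,
                                  soft_groups = "algae and eelgrass",
                                  soft_cap_frac = 3 / 2.6 - 1,
                                  hard_cap = 256, steps_per_year = 12) {
  g <- balanced$groups
  n <- nrow(g)
  if (is.null(forced)) {
    forced <- union(balanced$banc_groups, which(g$name %in% soft_groups))
  }
  caps <- rep(hard_cap, n)
  soft <- which(g$name %in% soft_groups)
  caps[soft] <- soft_cap_frac * g$pb[soft]
  ny <- length(years)
  Mx <- matrix(0, ny, n)
  for (yi in seq_len(ny)) {
    m <- m_init * growth^(yi - 1)
    Mx[yi, forced] <- pmin(m, caps[forced])
  }
  simulate_foodweb(balanced, v, effort, years, extra_M = Mx,
                   steps_per_year = steps_per_year)
}

#' End-state biomass ratios against a baseline run
#'
#' @param run,baseline `scenario_run`s over the same years and groups.
#' @param subsets named list of integer index sets to aggregate
#'   (biomass-weighted: ratio of summed end biomasses).
#' @return List with `per_group` (data frame: group, b_run, b_base, ratio,
#'   `undefined` flag where the baseline sits at the extinction floor) and
#'   `aggregates`.
#' @export
end_state_ratios <- function(run, baseline, subsets = list()) {
  if (!identical(run$years, baseline$years)) stopf("runs cover different years")
  b1 <- run$B_end; b0 <- baseline$B_end
  if (length(b1) != length(b0)) stopf("runs have different groups")
  undef <- b0 <= baseline$floor * (1 + 1e-9)
  per_group <- data.frame(group = names(b1), b_run = b1, b_base = b0,
                          ratio = ifelse(undef, NA_real_, b1 / b0),
                          undefined = undef, row.names = NULL)
  aggregates <- if (length(subsets)) {
    vapply(subsets, function(ix) sum(b1[ix]) / sum(b0[ix]), numeric(1))
  } else NULL
  list(per_group = per_group, aggregates = aggregates)
}
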