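#' Direct consumption on the protected area's sedentary groups
#'
#' For every predator, sums its consumption flows on the members of the
#' sedentary (Banc) set: `Qba_dir_j = sum_{i in Nba} Q[j, i]`.
#'
#' @param balanced a [balance()]d model.
#' @param banc_groups integer index set of sedentary MPA groups; defaults to
#'   the model's own set.
#' @return Named numeric vector, t km^-2 yr^-1.
#' @export
direct_banc_consumption <- function(balanced, banc_groups = balanced$banc_groups) {
  g <- balanced$groups
  check_banc_set(balanced, banc_groups)
  qd <- rowSums(balanced$q_matrix[, banc_groups, drop = FALSE])
  names(qd) <- g$name
  qd
}

check_banc_set <- function(balanced, banc_groups) {
  g <- balanced$groups
  if (!length(banc_groups)) stopf("empty sedentary group set")
  if (min(banc_groups) < 1 || max(banc_groups) > nrow(g))
    stopf("banc_groups out of range")
  mobile <- banc_groups[g$habitat[banc_groups] %in%
                          c("migratory", "pelagic", "coastal", "shelf")]
  if (length(mobile))
    warnf("sedentary set contains mobile group(s): %s",
          paste(g$name[mobile], collapse = ", "))
  invisible(banc_groups)
}

#' Fraction of a group's production passed on to its predators
#'
#' The share of production that is neither lost to detritus (via `EE`), nor
#' fished, nor accumulated.  Two conventions are available:
#' \describe{
#'   \item{`"production"`}{the literal product
#'     `EE * (1 - fY) * (1 - fBA)` with `fY = Y / P` the fished fraction of
#'     production and `fBA = ba / (P/B)` the accumulated fraction;}
#'   \item{`"flow"`}{the flow-accounting ratio `M2 * B / P`, i.e. exactly the
#'     share of production consumed by in-system predators.}
#' }
#' The two agree when fishing and accumulation are absent.
#'
#' @param balanced a [balance()]d model.
#' @param convention `"production"` (default) or `"flow"`.
#' @return Numeric vector of fractions in `[0, 1)`.
#' @export
transfer_fraction <- function(balanced, convention = c("production", "flow")) {
  convention <- match.arg(convention)
  g <- balanced$groups
  P <- g$biomass * g$pb
  t_j <- numeric(nrow(g))
  live <- g$class != "detritus" & P > 0
  if (convention == "production") {
    fY <- ifelse(live, total_landings(balanced) / P, 0)
    fBA <- ifelse(live & g$pb > 0, balanced$ba_flow / P, 0)
    t_j[live] <- (g$ee * pmax(1 - fY, 0) * pmax(1 - fBA, 0))[live]
  } else {
    t_j[live] <- (balanced$m2 * g$biomass / P)[live]
  }
  if (any(t_j >= 1))
    stopf("transfer fraction >= 1 for group(s) %s; dependency iteration would diverge",
          paste(g$name[t_j >= 1], collapse = ", "))
  names(t_j) <- g$name
  pmax(t_j, 0)
}

#' Iterative direct + indirect MPA dependency
#'
#' Computes, for every group, the consumption originating directly or
#' indirectly from the MPA's sedentary groups, as the fixed point of
#' \deqn{Qba_j \leftarrow Qba^{dir}_j + \sum_i (P/Q)_i \, t_i \, Qba_i \,
#'       Q_{j,i} / {\textstyle\sum_k} Q_{k,i}}
#' where the sum runs over consumer prey outside the sedentary set (their
#' consumption on sedentary groups is already in the direct term), `t_i` is
#' the [transfer_fraction()], and `Q_{j,i}/sum_k Q_{k,i}` is predator `j`'s
#' share of the predation on `i`.  Afterwards the proportions of consumption,
#' production and catch from the MPA coincide:
#' `pqba_j = ppba_j = pyba_j = Qba_j / Q_j`.
#'
#' Members of the sedentary set themselves live inside the MPA; their
#' proportions are reported as 1 when `nba_full = TRUE` (the default used by
#' the ecosystem totals).
#'
#' @param balanced a [balance()]d model.
#' @param banc_groups sedentary index set (default: the model's).
#' @param tol convergence tolerance on the max absolute change of `Qba`
#'   (t km^-2 yr^-1), default `1e-10`.
#' @param max_iter iteration cap, default 1000.
#' @param convention passed to [transfer_fraction()].
#' @param nba_full report sedentary-set members as fully MPA-origin.
#' @return Object of class `dependency_result`: data frame `per_group` with
#'   `qba_dir`, `qba_total`, `pqba`, `ppba`, `pyba`, plus `iterations` and
#'   the inputs needed by [ecosystem_totals()].
#' @export
iterate_dependency <- function(balanced, banc_groups = balanced$banc_groups,
                               tol = 1e-10, max_iter = 1000,
                               convention = "production", nba_full = TRUE) {
  g <- balanced$groups
  n <- nrow(g)
  check_banc_set(balanced, banc_groups)
  qd <- rowSums(balanced$q_matrix[, banc_groups, drop = FALSE])
  t_j <- transfer_fraction(balanced, convention)
  pq <- ifelse(g$qb > 0, g$pb / g$qb, 0)
  pred_flow <- colSums(balanced$q_matrix)              # total predation on each prey

  ## propagation matrix: contribution of prey i's Qba to predator j
  carriers <- which(g$class == "consumer" & !(seq_len(n) %in% banc_groups))
  W <- matrix(0, n, n)
  for (i in carriers) {
    if (pred_flow[i] <= 0) next
    W[, i] <- pq[i] * t_j[i] * balanced$q_matrix[, i] / pred_flow[i]
  }

  qba <- qd
  it <- 0L
  repeat {
    it <- it + 1L
    qba_new <- qd + as.numeric(W %*% qba)
    delta <- max(abs(qba_new - qba))
    qba <- qba_new
    if (delta < tol) break
    if (it >= max_iter) {
      sr <- max(abs(eigen(W, only.values = TRUE)$values))
      stopf("dependency iteration did not converge in %d iterations (spectral radius %.4f)",
            max_iter, sr)
    }
  }

  Q_tot <- g$biomass * g$qb
  p <- ifelse(Q_tot > 0, qba / Q_tot, 0)
  if (nba_full) {
    p[banc_groups] <- ifelse(g$class[banc_groups] == "consumer", 1, p[banc_groups])
    qba[banc_groups] <- ifelse(g$class[banc_groups] == "consumer",
                               Q_tot[banc_groups], qba[banc_groups])
  }
  p <- pmin(pmax(p, 0), 1)
  per_group <- data.frame(index = g$index, group = g$name,
                          qba_dir = qd, qba_total = qba,
                          pqba = p, ppba = p, pyba = p, row.names = NULL)
  structure(list(per_group = per_group, iterations = it,
                 banc_groups = banc_groups, convention = convention,
                 nba_full = nba_full),
            class = "dependency_result")
}

#' @export
print.dependency_result <- function(x, ...) {
  cat(sprintf("<dependency_result> %d groups, converged in %d iterations\n",
              nrow(x$per_group), x$iterations))
  top <- utils::head(x$per_group[order(-x$per_group$ppba), c("group", "ppba")], 5)
  cat("  most dependent:",
      paste(sprintf("%s (%.0f%%)", top$group, 100 * top$ppba), collapse = ", "), "\n")
  invisible(x)
}

#' Exact dependency by path enumeration (acyclic webs)
#'
#' Independent reference computation of [iterate_dependency()]: enumerates
#' every directed prey-to-predator path leaving the sedentary set, weighting
#' each traversed consumer `i` by `(P/Q)_i * t_i * Q[j,i] / sum_k Q[k,i]`.
#' Only valid on acyclic webs (it errors on cycles); complexity is
#' exponential in web size, so intended for small test webs and for the
#' ground-truth output of the synthetic generator.
#'
#' @inheritParams iterate_dependency
#' @return Named vector of total MPA-origin consumption `Qba` per group.
#' @export
dependency_by_paths <- function(balanced, banc_groups = balanced$banc_groups,
                                convention = "production") {
  g <- balanced$groups
  n <- nrow(g)
  qd <- rowSums(balanced$q_matrix[, banc_groups, drop = FALSE])
  t_j <- transfer_fraction(balanced, convention)
  pq <- ifelse(g$qb > 0, g$pb / g$qb, 0)
  pred_flow <- colSums(balanced$q_matrix)
  carriers <- which(g$class == "consumer" & !(seq_len(n) %in% banc_groups))

  qba <- qd
  ## depth-first expansion of the Neumann series, path by path
  expand <- function(i, mass, visited) {
    ## mass = Qba contribution carried at node i, to be passed to predators
    pass <- pq[i] * t_j[i] * mass
    if (pass <= 0 || pred_flow[i] <= 0) return(invisible())
    preds <- which(balanced$q_matrix[, i] > 0)
    for (j in preds) {
      if (j %in% visited) stopf("cycle detected; path enumeration requires an acyclic web")
      contrib <- pass * balanced$q_matrix[j, i] / pred_flow[i]
      qba[j] <<- qba[j] + contrib
      if (j %in% carriers) expand(j, contrib, c(visited, j))
    }
  }
  for (i in carriers) if (qd[i] > 0) expand(i, qd[i], i)
  names(qba) <- g$name
  qba
}

#' Ecosystem-level dependency totals
#'
#' Consumption-, production- and catch-weighted aggregates of the per-group
#' MPA-origin proportions, for the whole system and for named subsets.
#' `pct_P_with_producers` additionally counts the MPA's own primary
#' producers' production fully in the numerator, and all producers in the
#' denominator.
#'
#' @param dep a [iterate_dependency()] result.
#' @param balanced the same [balance()]d model.
#' @param subsets named list of integer index vectors (e.g. coastal, pelagic,
#'   shelf memberships); each must be non-empty.
#' @param banc_producers indices of primary producers resident in the MPA.
#' @return List with `totals` (data frame: pct_Q, pct_P_animals,
#'   pct_P_with_producers, pct_Y for the full system) and `by_subset`.
#'   Percentages on the 0-100 scale.
#' @export
ecosystem_totals <- function(dep, balanced, subsets = list(),
                             banc_producers = integer()) {
  g <- balanced$groups
  pg <- dep$per_group
  cons <- which(g$class == "consumer")
  Q <- g$biomass * g$qb
  P <- g$biomass * g$pb
  Y <- total_landings(balanced)

  agg <- function(ix) {
    ix <- intersect(ix, cons)
    if (!length(ix)) stopf("empty group subset")
    c(pct_Q = 100 * sum(pg$pqba[ix] * Q[ix]) / sum(Q[ix]),
      pct_P_animals = 100 * sum(pg$ppba[ix] * P[ix]) / sum(P[ix]),
      pct_Y = if (sum(Y[ix]) > 0)
        100 * sum(pg$pyba[ix] * Y[ix]) / sum(Y[ix]) else NA_real_)
  }
  whole <- agg(cons)
  prods <- which(g$class == "producer")
  num_p2 <- sum(pg$ppba[cons] * P[cons]) + sum(P[intersect(banc_producers, prods)])
  den_p2 <- sum(P[cons]) + sum(P[prods])
  totals <- data.frame(pct_Q = whole[["pct_Q"]],
                       pct_P_animals = whole[["pct_P_animals"]],
                       pct_P_with_producers = 100 * num_p2 / den_p2,
                       pct_Y = whole[["pct_Y"]])
  by_subset <- if (length(subsets)) {
    t(vapply(subsets, agg, numeric(3)))
  } else NULL
  list(totals = totals, by_subset = by_subset)
}
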