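#' Compute trophic levels from the diet matrix
#'
#' Producers and detritus are assigned trophic level 1; each consumer gets
#' `1 + ` the diet-weighted mean trophic level of its prey, solved as a
#' linear system.  Diet imported from outside the system is, by default,
#' assigned the consumer's own diet-weighted mean prey level (equivalently,
#' the diet is renormalised over modelled prey), the convention of the
#' standard mass-balance software.
#'
#' @param model a [food_web_model()].
#' @param import_tl either `"renormalise"` (default) or a fixed numeric
#'   trophic level to assign to imported diet.
#' @return Numeric vector of trophic levels (all `>= 1`).
#' @export
compute_trophic_levels <- function(model, import_tl = "renormalise") {
  g <- model$groups
  n <- nrow(g)
  dc <- model$diet
  imp <- model$import
  basal <- g$class %in% c("producer", "detritus")

  A <- diag(n)
  b <- rep(1, n)
  for (j in seq_len(n)) {
    if (basal[j]) next
    w <- dc[, j]
    s <- sum(w)
    if (is.numeric(import_tl)) {
      b[j] <- 1 + imp[j] * import_tl
    } else {
      if (s <= 0)
        stopf("consumer '%s' has an all-import diet; trophic level undefined under renormalisation",
              g$name[j])
      w <- w / s
    }
    A[j, ] <- A[j, ] - if (is.numeric(import_tl)) dc[, j] else w
    A[j, j] <- A[j, j] + 0  # diagonal already includes identity
  }
  ## rows for basal groups: x_j = 1 (A row is identity, b = 1)
  tl <- tryCatch(solve(A, b), error = function(e) {
    bad <- which(!basal & abs(dc[cbind(seq_len(n), seq_len(n))]) >= 1)
    stopf("trophic-level system is singular%s: %s",
          if (length(bad)) sprintf(" (offending column(s) %s)",
                                   paste(g$name[bad], collapse = ", ")) else "",
          conditionMessage(e))
  })
  if (any(tl < 1 - 1e-8))
    stopf("trophic-level solution below 1; diet matrix inconsistent")
  names(tl) <- g$name
  pmax(tl, 1)
}

## Resolve the P/Q parameterisation: fill pb (or qb) from pq where possible.
resolve_pq <- function(groups) {
  g <- groups
  cons <- g$class == "consumer"
  fill_pb <- cons & is.na(g$pb) & !is.na(g$pq) & !is.na(g$qb)
  g$pb[fill_pb] <- g$pq[fill_pb] * g$qb[fill_pb]
  fill_qb <- cons & is.na(g$qb) & !is.na(g$pq) & !is.na(g$pb)
  g$qb[fill_qb] <- g$pb[fill_qb] / g$pq[fill_qb]
  g$qb[g$class != "consumer"] <- 0
  g$pb[g$class == "detritus"] <- 0
  g
}

#' Solve the static mass balance
#'
#' For every group the master equation
#' `B_i * (P/B)_i * EE_i = Y_i + sum_j B_j * (Q/B)_j * DC[i,j] + BA_i * B_i`
#' must hold, where `Y_i` is the fleet-summed landings and `BA_i = ba_i * B_i`
#' the biomass accumulation.  Each consumer/producer group must have exactly
#' one unknown among biomass, P/B and EE after the P/Q substitution
#' (`P/B = P/Q * Q/B`).  Unknown biomasses are solved jointly as a linear
#' system; unknown EE and P/B follow directly.  Detritus EE is diagnosed from
#' the detrital flow budget (unassimilated consumption plus other mortality).
#'
#' @param model a [food_web_model()].
#' @param unassimilated fraction of consumer intake routed to detritus
#'   (Ecopath `GS`, default 0.2), used only for the detritus diagnostics.
#' @param ba_absolute if `TRUE`, the `ba` column is interpreted as an
#'   absolute flow (t km^-2 yr^-1) instead of a relative rate (yr^-1).
#' @return A `balanced_model`: the input model with all parameters filled,
#'   plus `tl` (trophic levels), `q_matrix` (consumption flows, predator rows
#'   by prey columns, t km^-2 yr^-1), `f_rate`, `m2`, `m0` (yr^-1) and a
#'   `balance` report listing any ecotrophic efficiency above 1 (returned
#'   with a warning, never silently clamped).
#' @export
balance <- function(model, unassimilated = 0.2, ba_absolute = FALSE) {
  g <- resolve_pq(model$groups)
  n <- nrow(g)
  cons <- g$class == "consumer"
  det <- g$class == "detritus"
  Y <- total_landings(model)
  dc <- model$diet

  unk <- lapply(seq_len(n), function(i) {
    if (det[i]) return(character())
    cand <- c("biomass", "pb", "ee")
    cand[vapply(cand, function(p) is.na(g[[p]][i]), logical(1))]
  })
  n_unk <- lengths(unk)
  if (any(cons & is.na(g$qb)))
    stopf("group(s) %s lack Q/B and cannot be derived from P/Q",
          paste(g$name[cons & is.na(g$qb)], collapse = ", "))
  if (any(n_unk > 1))
    stopf("group(s) %s have more than one unknown among {B, P/B, EE}",
          paste(g$name[n_unk > 1], collapse = ", "))

  ba_rate <- g$ba
  ## per-group BA flow = ba * B (relative convention) or ba (absolute)
  ba_flow_coef <- if (ba_absolute) numeric(n) else ba_rate
  ba_flow_const <- if (ba_absolute) ba_rate else numeric(n)

  u_b <- which(vapply(unk, function(u) identical(u, "biomass"), logical(1)))
  known_b <- setdiff(seq_len(n), u_b)
  B <- g$biomass
  qb <- g$qb

  ## predation demand rows: B_i pb_i ee_i - ba_i B_i - sum_j B_j qb_j DC[i,j] = Y_i + ba_const
  if (length(u_b)) {
    A <- matrix(0, length(u_b), length(u_b))
    rhs <- numeric(length(u_b))
    for (k in seq_along(u_b)) {
      i <- u_b[k]
      if (is.na(g$pb[i]) || is.na(g$ee[i]))
        stopf("group '%s': biomass unknown requires P/B and EE", g$name[i])
      A[k, k] <- g$pb[i] * g$ee[i] - ba_flow_coef[i]
      for (m in seq_along(u_b)) {
        j <- u_b[m]
        A[k, m] <- A[k, m] - qb[j] * dc[i, j]
      }
      pred_known <- sum(B[known_b] * qb[known_b] * dc[i, known_b], na.rm = TRUE)
      rhs[k] <- Y[i] + ba_flow_const[i] + pred_known
    }
    sol <- tryCatch(solve(A, rhs), error = function(e)
      stopf("biomass subsystem singular: %s", conditionMessage(e)))
    if (any(!is.finite(sol) | sol <= 0))
      stopf("biomass solution non-positive for group(s) %s",
            paste(g$name[u_b[!is.finite(sol) | sol <= 0]], collapse = ", "))
    B[u_b] <- sol
  }
  if (any(is.na(B[!det])))
    stopf("biomass missing and not estimable for group(s) %s",
          paste(g$name[is.na(B) & !det], collapse = ", "))
  B[det & is.na(B)] <- 0

  ## consumption flows now fully determined
  Bq <- B * qb
  Bq[qb == 0] <- 0                             # detritus biomass may be absent
  pred_flow <- as.numeric(dc %*% Bq)           # predation on each prey
  ba_flow <- ba_flow_coef * B + ba_flow_const

  pb <- g$pb; ee <- g$ee
  for (i in which(!det)) {
    u <- unk[[i]]
    if (identical(u, "ee")) {
      P <- B[i] * pb[i]
      if (P <= 0) stopf("group '%s': zero production, EE undefined", g$name[i])
      ee[i] <- (Y[i] + pred_flow[i] + ba_flow[i]) / P
    } else if (identical(u, "pb")) {
      if (is.na(ee[i]) || ee[i] <= 0)
        stopf("group '%s': P/B unknown requires positive EE", g$name[i])
      pb[i] <- (Y[i] + pred_flow[i] + ba_flow[i]) / (B[i] * ee[i])
    }
  }

  ## detritus budget: inflow = unassimilated intake + other mortality (+import?)
  if (any(det)) {
    gs <- ifelse(cons, unassimilated, 0)
    inflow <- sum(B * qb * gs, na.rm = TRUE) +
      sum((B * pb * pmax(1 - ee, 0))[!det], na.rm = TRUE)
    for (i in which(det)) {
      pb[i] <- 0
      ee[i] <- if (inflow > 0) pred_flow[i] / inflow else 0
    }
  }

  q_matrix <- t(dc) * Bq              # predator rows x prey columns
  dimnames(q_matrix) <- list(g$name, g$name)
  f_rate <- ifelse(B > 0, Y / B, 0)
  m2 <- ifelse(B > 0, pred_flow / B, 0)
  m0 <- ifelse(det, 0, pb * (1 - ee))

  over <- which(!det & ee > 1 + 1e-9)
  report <- data.frame(group = g$name[over], ee = ee[over])
  if (length(over))
    warnf("unbalanced model: EE > 1 for %s",
          paste(sprintf("%s (%.3f)", g$name[over], ee[over]), collapse = ", "))

  g$biomass <- B; g$pb <- pb; g$qb <- qb; g$ee <- ee
  g$pq <- ifelse(qb > 0, pb / qb, NA_real_)
  out <- model
  out$groups <- g
  out$tl <- compute_trophic_levels(model)
  out$q_matrix <- q_matrix
  out$f_rate <- f_rate
  out$m2 <- m2
  out$m0 <- m0
  out$ba_flow <- ba_flow
  out$balance <- list(ee_violations = report, unassimilated = unassimilated,
                      ba_absolute = ba_absolute)
  class(out) <- c("balanced_model", "food_web_model")
  out
}

#' @export
print.balanced_model <- function(x, ...) {
  NextMethod()
  nv <- nrow(x$balance$ee_violations)
  cat(sprintf("  balanced; %s\n",
              if (nv) sprintf("%d EE violation(s)", nv) else "all EE in [0, 1]"))
  invisible(x)
}

#' Partition total mortality of each group
#'
#' Splits each group's production rate (P/B) into fishing mortality `F`,
#' predation mortality `M2`, other mortality `M0` and the biomass
#' accumulation rate, which sum to P/B by the master equation.
#'
#' @param balanced a [balance()]d model.
#' @return Data frame with columns `group`, `F`, `M2`, `M0`, `BA` (all
#'   yr^-1) and `PB` for reference.
#' @export
mortality_partition <- function(balanced) {
  g <- balanced$groups
  keep <- g$class != "detritus"
  if (any(g$biomass[keep] <= 0))
    stopf("zero biomass for group(s) %s",
          paste(g$name[keep][g$biomass[keep] <= 0], collapse = ", "))
  ba_r <- ifelse(g$biomass > 0, balanced$ba_flow / g$biomass, 0)
  data.frame(group = g$name[keep],
             F = balanced$f_rate[keep],
             M2 = balanced$m2[keep],
             M0 = balanced$m0[keep],
             BA = ba_r[keep],
             PB = g$pb[keep],
             row.names = NULL)
}
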