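## Independent reference computations, kept deliberately naive.

## Trophic levels by iterated substitution until the update stops moving.
tl_substitution_oracle <- function(model, tol = 1e-12, max_iter = 10000) {
  g <- model$groups
  n <- nrow(g)
  basal <- g$class %in% c("producer", "detritus")
  tl <- rep(1, n)
  dc <- model$diet
  ## renormalise consumer columns over modelled prey
  for (j in which(!basal)) dc[, j] <- dc[, j] / sum(dc[, j])
  for (k in seq_len(max_iter)) {
    new <- ifelse(basal, 1, 1 + as.numeric(t(dc) %*% tl))
    if (max(abs(new - tl)) < tol) return(new)
    tl <- new
  }
  stop("substitution oracle did not converge")
}

## Master-equation residuals, straight from the definition.
master_residuals <- function(balanced) {
  g <- balanced$groups
  Y <- rowSums(balanced$landings)
  if (!length(Y)) Y <- numeric(nrow(g))
  pred <- colSums(balanced$q_matrix)
  resid <- g$biomass * g$pb * g$ee - Y - pred - balanced$ba_flow
  resid[g$class == "detritus"] <- 0
  resid
}
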