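#' Mixed trophic impact matrix
#'
#' Net direct-plus-indirect impact of a marginal biomass increase of each
#' group on every other group, scaled to about `[-1, 1]`.  The direct net
#' impact of `i` on `j` is the benefit of `i` as food (`DC[i, j]`, the share
#' of `i` in `j`'s diet) minus the harm of `i` as a predator (the share of
#' `i` in the total predation on `j`, including catches when fleets are
#' present).  Indirect routes are closed over all path lengths with the
#' Leontief-type inverse `(I - q)^{-1} - I`.
#'
#' @param balanced a [balance()]d model.
#' @param include_fleets append one pseudo-group per fleet, whose "predation"
#'   on a group is its landings and whose "diet" is its catch composition.
#' @return Object of class `mti_matrix`: list with `mti` (impacting rows by
#'   impacted columns) and `labels`.
#' @export
mti_matrix <- function(balanced, include_fleets = FALSE) {
  g <- balanced$groups
  n <- nrow(g)
  Qm <- balanced$q_matrix                       # predator rows x prey cols
  Y <- balanced$landings
  nf <- if (include_fleets) ncol(Y) else 0L
  m <- n + nf
  labels <- c(g$name, if (nf) balanced$fleets)

  ## predation (+ catch) pressure on each group
  mort_flow <- colSums(Qm) + if (nf) rowSums(Y) else 0

  q <- matrix(0, m, m, dimnames = list(labels, labels))
  for (j in seq_len(n)) {
    ## benefit of prey i to predator j
    q[seq_len(n), j] <- balanced$diet[, j]
    ## harm of predator i to prey j
    if (mort_flow[j] > 0)
      q[seq_len(n), j] <- q[seq_len(n), j] - Qm[, j] / mort_flow[j]
  }
  if (nf) {
    for (f in seq_len(nf)) {
      fi <- n + f
      ## fleet as predator on groups
      sel <- which(mort_flow[seq_len(n)] > 0)
      q[fi, sel] <- q[fi, sel] - Y[sel, f] / mort_flow[sel]
      tot <- sum(Y[, f])
      if (tot > 0) q[seq_len(n), fi] <- Y[, f] / tot   # catch composition "diet"
    }
  }
  IM <- diag(m) - q
  inv <- tryCatch(solve(IM), error = function(e)
    stopf("(I - q) is singular; MTI undefined: %s", conditionMessage(e)))
  mti <- inv - diag(m)
  structure(list(mti = mti, labels = labels, include_fleets = include_fleets),
            class = "mti_matrix")
}

#' @export
print.mti_matrix <- function(x, ...) {
  cat(sprintf("<mti_matrix> %d x %d, range [%.3f, %.3f]\n",
              nrow(x$mti), ncol(x$mti), min(x$mti), max(x$mti)))
  invisible(x)
}

#' Simplified impact web
#'
#' Edge list of impactor/impacted pairs whose absolute mixed trophic impact
#' exceeds a threshold, sorted by magnitude; self-impacts are excluded.
#'
#' @param mti an [mti_matrix()].
#' @param threshold absolute-impact cutoff (default 0.1).
#' @return Data frame with `impactor`, `impacted`, `sign`, `magnitude`.
#' @export
simplified_web <- function(mti, threshold = 0.1) {
  M <- mti$mti
  diag(M) <- 0
  idx <- which(abs(M) > threshold, arr.ind = TRUE)
  out <- data.frame(impactor = mti$labels[idx[, 1]],
                    impacted = mti$labels[idx[, 2]],
                    sign = ifelse(M[idx] > 0, "+", "-"),
                    magnitude = abs(M[idx]),
                    mti = M[idx], row.names = NULL)
  out[order(-out$magnitude), , drop = FALSE]
}
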