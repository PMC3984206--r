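## Small hand-built webs used across the suite.

## producer -> grazer -> predator chain; the producer is the MPA resident.
## Every parameter is chosen so the mass balance closes exactly by hand.
chain_model <- function(ee_grazer = 0.8, fy_pred = 0, pq_grazer = 0.25,
                        pq_pred = 0.2) {
  qb_g <- 10; qb_p <- 4
  pb_g <- pq_grazer * qb_g
  pb_p <- pq_pred * qb_p
  B_p <- 1
  Y_p <- fy_pred * pb_p * B_p
  ## grazer biomass so that predation + catch exhaust the target EE
  B_g <- (B_p * qb_p) / (pb_g * ee_grazer)
  B_prod <- 10 * B_g                        # ample producer pool
  groups <- data.frame(
    index = 1:3, name = c("banc producer", "grazer", "predator"),
    class = c("producer", "consumer", "consumer"),
    habitat = c("banc_sedentary", "coastal", "coastal"), stanza = "none",
    biomass = c(B_prod, B_g, B_p), pb = c(50, pb_g, pb_p),
    qb = c(0, qb_g, qb_p), ee = NA_real_,
    pq = c(NA, pq_grazer, pq_pred), ba = 0)
  diet <- matrix(0, 3, 3)
  diet[1, 2] <- 1; diet[2, 3] <- 1
  landings <- if (fy_pred > 0) matrix(c(0, 0, Y_p), 3, 1,
                                      dimnames = list(NULL, "artisanal")) else NULL
  food_web_model(groups, diet, landings, banc_groups = 1,
                 pba = c(0, 1, 0))
}

## two-group predator-prey pair with an external producer; used for MTI signs
pair_model <- function() {
  groups <- data.frame(
    index = 1:3, name = c("plants", "prey", "pred"),
    class = c("producer", "consumer", "consumer"),
    habitat = c("producer", "shelf", "shelf"), stanza = "none",
    biomass = c(100, 10, 1), pb = c(10, 2, 0.5),
    qb = c(0, 8, 2.5), ee = NA_real_, pq = c(NA, 0.25, 0.2), ba = 0)
  diet <- matrix(0, 3, 3)
  diet[1, 2] <- 1; diet[2, 3] <- 1
  food_web_model(groups, diet)
}

balanced_synth <- function(seed = 1, ...) {
  spec <- synth_spec(seed = seed, ...)
  balance(generate_web(spec))
}
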