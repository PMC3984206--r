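#' Load a food-web model from CSV files
#'
#' Reads the group table ([read_groups_csv()]) and diet matrix
#' ([read_diet_csv()]), validates them (diet columns must sum to 1 within
#' `1e-6`; violations are reported with the offending predator), and
#' assembles a [food_web_model()].
#'
#' @param groups_path,diet_path file paths.
#' @param banc_groups,pba,subsets model configuration (see
#'   [food_web_model()]); `subsets` is attached as an attribute.
#' @return A [food_web_model()].
#' @export
load_model <- function(groups_path, diet_path, banc_groups = integer(),
                       pba = NULL, subsets = NULL) {
  gr <- read_groups_csv(groups_path)
  dt <- read_diet_csv(diet_path)
  model <- food_web_model(gr$groups, dt$diet, gr$landings, gr$fleets,
                          banc_groups = banc_groups, pba = pba,
                          import = dt$import)
  if (!is.null(subsets)) attr(model, "subsets") <- subsets
  model
}

#' Run the full analysis pipeline
#'
#' Chains mass balance, MPA dependency, mixed trophic impacts, trophic
#' spectra and (optionally) the three long-term scenarios (status quo,
#' fictive MPA fleet, habitat loss) with end-state ratios against the status
#' quo.  Each stage's result is returned in a named list; when `out_dir` is
#' given the tabular results are also written as CSV.
#'
#' @param model a [food_web_model()].
#' @param subsets named list of index sets for the totals (defaults to the
#'   model's `subsets` attribute, if any).
#' @param banc_producers producer indices counted fully in the
#'   with-producers production total.
#' @param scenarios run the dynamic scenarios (default FALSE; they dominate
#'   runtime).
#' @param v vulnerabilities for the scenarios.
#' @param years scenario years (default 1991:2056, the published horizon:
#'   a 16-year observation window plus a 50-year projection).
#' @param mti_threshold simplified-web cutoff.
#' @param out_dir optional output directory for CSV files.
#' @return List with `balanced`, `dependency`, `totals`, `mti`,
#'   `simplified`, `spectra` and (if requested) `scenario_runs`, `ratios`.
#' @export
run_pipeline <- function(model, subsets = NULL, banc_producers = integer(),
                         scenarios = FALSE, v = 2, years = 1991:2056,
                         mti_threshold = 0.1, out_dir = NULL) {
  subsets <- subsets %||% attr(model, "subsets") %||% list()
  if (!length(banc_producers))
    banc_producers <- attr(model, "banc_producers") %||% integer()
  balanced <- balance(model)
  dep <- iterate_dependency(balanced)
  totals <- ecosystem_totals(dep, balanced, subsets, banc_producers)
  mti <- mti_matrix(balanced)
  simp <- simplified_web(mti, mti_threshold)
  g <- balanced$groups
  P <- g$biomass * g$pb
  spec_P <- build_spectrum(P, balanced$tl)
  spec_Pba <- build_spectrum(P * dep$per_group$ppba, balanced$tl)
  spectra <- list(biomass = build_spectrum(g$biomass, balanced$tl),
                  production = spec_P,
                  catch = build_spectrum(total_landings(balanced), balanced$tl),
                  dependency_ratio = spectrum_ratio(spec_Pba, spec_P))
  out <- list(balanced = balanced, dependency = dep, totals = totals,
              mti = mti, simplified = simp, spectra = spectra)

  if (scenarios) {
    sq <- scenario_statusquo(balanced, v, years = years)
    fic <- scenario_fictive_fleet(balanced, v, years = years)
    loss <- scenario_habitat_loss(balanced, v, years = years)
    high_tl <- which(g$class == "consumer" &
                       !(seq_len(nrow(g)) %in% balanced$banc_groups) &
                       !(g$habitat %in% c("banc_sedentary", "shelf_sedentary")))
    sets <- c(list(higher_tl = high_tl), subsets)
    out$scenario_runs <- list(statusquo = sq, fictive = fic, habitat_loss = loss)
    out$ratios <- list(fictive = end_state_ratios(fic, sq, sets),
                       habitat_loss = end_state_ratios(loss, sq, sets))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    bal_df <- cbind(balanced$groups, tl = balanced$tl, f = balanced$f_rate,
                    m2 = balanced$m2, m0 = balanced$m0)
    utils::write.csv(bal_df, file.path(out_dir, "balanced.csv"), row.names = FALSE)
    utils::write.csv(dep$per_group, file.path(out_dir, "dependency.csv"),
                     row.names = FALSE)
    utils::write.csv(totals$totals, file.path(out_dir, "totals.csv"),
                     row.names = FALSE)
    if (!is.null(totals$by_subset))
      utils::write.csv(data.frame(subset = rownames(totals$by_subset),
                                  totals$by_subset),
                       file.path(out_dir, "totals_by_subset.csv"),
                       row.names = FALSE)
    utils::write.csv(simp, file.path(out_dir, "simplified_web.csv"),
                     row.names = FALSE)
    spec_df <- data.frame(tl = spectra$biomass$mids,
                          biomass = spectra$biomass$values,
                          production = spectra$production$values,
                          catch = spectra$catch$values,
                          dependency_ratio = spectra$dependency_ratio$values)
    utils::write.csv(spec_df, file.path(out_dir, "spectra.csv"), row.names = FALSE)
  }
  out
}
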