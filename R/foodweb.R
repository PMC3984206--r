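#' Construct a food-web model
#'
#' Bundles the functional-group parameter table, the diet-composition matrix,
#' fleet landings and the description of which groups are the sedentary
#' residents of the protected area (the "Banc" set), prior to mass balancing.
#'
#' @param groups data frame with one row per functional group and columns
#'   `index` (1-based, file order), `name`, `class` (one of `"consumer"`,
#'   `"producer"`, `"detritus"`), `habitat`, `stanza` (`"none"`, `"juvenile"`
#'   or `"adult"`), and the Ecopath parameters `biomass` (t km^-2), `pb`
#'   (production/biomass, yr^-1), `qb` (consumption/biomass, yr^-1), `ee`
#'   (ecotrophic efficiency), `pq` (gross efficiency P/Q) and `ba` (biomass
#'   accumulation rate, yr^-1).  `NA` marks a parameter to be estimated.
#' @param diet square numeric matrix of diet proportions, prey rows by
#'   predator columns, in group order.
#' @param landings numeric matrix, groups by fleets, of landings
#'   (t km^-2 yr^-1).  `NULL` means no fisheries.
#' @param fleets character vector of fleet names; defaults to the column
#'   names of `landings`.
#' @param banc_groups integer indices of the sedentary groups resident in the
#'   protected area.
#' @param pba numeric vector, per-group proportion of invertebrate/plankton
#'   feeding taken inside the protected area (used by scenario forcing).
#' @param import per-predator proportion of diet imported from outside the
#'   system (defaults to zero).
#' @return An object of class `food_web_model`.
#' @seealso [balance()], [compute_trophic_levels()], [generate_web()]
#' @export
food_web_model <- function(groups, diet, landings = NULL, fleets = NULL,
                           banc_groups = integer(), pba = NULL,
                           import = NULL) {
  groups <- as.data.frame(groups)
  n <- nrow(groups)
  required <- c("index", "name", "class")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols))
    stopf("groups table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  for (col in c("habitat", "stanza"))
    if (!col %in% names(groups)) groups[[col]] <- if (col == "stanza") "none" else "shelf"
  for (col in c("biomass", "pb", "qb", "ee", "pq", "ba"))
    if (!col %in% names(groups)) groups[[col]] <- NA_real_
  groups$ba[is.na(groups$ba)] <- 0
  if (anyDuplicated(groups$index)) stopf("duplicate group indices")
  if (!all(groups$class %in% c("consumer", "producer", "detritus")))
    stopf("class must be consumer, producer or detritus")

  diet <- as.matrix(diet)
  if (!all(dim(diet) == n))
    stopf("diet matrix must be %d x %d (prey x predator)", n, n)
  dimnames(diet) <- list(groups$name, groups$name)
  if (is.null(import)) import <- numeric(n)
  if (length(import) != n) stopf("import must have one entry per group")
  if (any(diet < -1e-12) || any(diet > 1 + 1e-9))
    stopf("diet proportions must lie in [0, 1]")
  diet[diet < 0] <- 0

  is_cons <- groups$class == "consumer"
  csum <- colSums(diet) + import
  bad <- which(is_cons & abs(csum - 1) > 1e-6)
  if (length(bad))
    stopf("diet columns of consumer(s) %s do not sum to 1 (+import): %s",
          paste(groups$name[bad], collapse = ", "),
          paste(signif(csum[bad], 8), collapse = ", "))
  ## renormalise tiny drift so downstream identities are exact
  for (j in which(is_cons)) {
    s <- sum(diet[, j]) + import[j]
    if (s > 0) { diet[, j] <- diet[, j] / s; import[j] <- import[j] / s }
  }
  nz <- which(!is_cons & colSums(diet) > 0)
  if (length(nz))
    stopf("producer/detritus column(s) must be all zero: %s",
          paste(groups$name[nz], collapse = ", "))

  if (is.null(landings)) {
    landings <- matrix(0, n, 0)
  } else {
    landings <- as.matrix(landings)
    if (nrow(landings) != n) stopf("landings must have one row per group")
    if (any(landings < 0)) stopf("landings must be non-negative")
  }
  fleets <- fleets %||% colnames(landings) %||% character()
  colnames(landings) <- fleets
  rownames(landings) <- groups$name

  banc_groups <- sort(unique(as.integer(banc_groups)))
  if (length(banc_groups) && (min(banc_groups) < 1 || max(banc_groups) > n))
    stopf("banc_groups out of range 1..%d", n)
  if (is.null(pba)) pba <- numeric(n)
  if (length(pba) != n || any(pba < -1e-12 | pba > 1 + 1e-12))
    stopf("pba must be a per-group vector of proportions in [0, 1]")

  structure(list(groups = groups, diet = diet, import = import,
                 landings = landings, fleets = fleets,
                 banc_groups = banc_groups, pba = pmin(pmax(pba, 0), 1)),
            class = "food_web_model")
}

#' @export
print.food_web_model <- function(x, ...) {
  g <- x$groups
  cat(sprintf("<food_web_model> %d groups (%d consumers, %d producers, %d detritus), %d fleet(s)\n",
              nrow(g), sum(g$class == "consumer"), sum(g$class == "producer"),
              sum(g$class == "detritus"), length(x$fleets)))
  if (length(x$banc_groups))
    cat("  MPA sedentary groups:", paste(x$banc_groups, collapse = ", "), "\n")
  invisible(x)
}

n_groups <- function(model) nrow(model$groups)

total_landings <- function(model) {
  if (ncol(model$landings) == 0) numeric(n_groups(model))
  else rowSums(model$landings)
}

#' Read a functional-group table from CSV
#'
#' Expected columns: `index,name,class,habitat,stanza,biomass,pb,qb,ee,pq,ba`
#' plus one `landings_<fleet>` column per fleet.  Empty cells mark parameters
#' to be estimated by [balance()].
#'
#' @param path file path.
#' @return list with components `groups` (data frame), `landings` (matrix)
#'   and `fleets` (character).
#' @export
read_groups_csv <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fleet_cols <- grep("^landings_", names(g), value = TRUE)
  fleets <- sub("^landings_", "", fleet_cols)
  landings <- as.matrix(g[, fleet_cols, drop = FALSE])
  landings[is.na(landings)] <- 0
  colnames(landings) <- fleets
  groups <- g[, setdiff(names(g), fleet_cols), drop = FALSE]
  list(groups = groups, landings = landings, fleets = fleets)
}

#' Read a diet-composition matrix from CSV
#'
#' Square matrix of prey rows by predator columns with a leading `prey` name
#' column; an optional final `import` row gives the diet share from outside
#' the system.
#'
#' @param path file path.
#' @return list with `diet` (matrix) and `import` (vector).
#' @export
read_diet_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  m[is.na(m)] <- 0
  imp_row <- which(tolower(rn) == "import")
  import <- if (length(imp_row)) m[imp_row, ] else numeric(ncol(m))
  if (length(imp_row)) { m <- m[-imp_row, , drop = FALSE]; rn <- rn[-imp_row] }
  rownames(m) <- rn
  list(diet = m, import = as.numeric(import))
}

#' Write a model's group table and diet matrix to CSV files
#'
#' @param model a [food_web_model()].
#' @param groups_path,diet_path output file paths (`NULL` skips that file).
#' @return Invisibly, the model.
#' @export
write_model_csv <- function(model, groups_path = NULL, diet_path = NULL) {
  if (!is.null(groups_path)) {
    g <- model$groups
    if (ncol(model$landings)) {
      L <- as.data.frame(model$landings)
      names(L) <- paste0("landings_", model$fleets)
      g <- cbind(g, L)
    }
    utils::write.csv(g, groups_path, row.names = FALSE, na = "")
  }
  if (!is.null(diet_path)) {
    d <- rbind(model$diet, import = model$import)
    utils::write.csv(data.frame(prey = rownames(d), d, check.names = FALSE),
                     diet_path, row.names = FALSE)
  }
  invisible(model)
}
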