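#' yieldparts: yield decomposition and comparative analysis for domestication experiments
#'
#' Decomposes per-plant seed yield of cereals and pulses into growth/allocation
#' and seed-packaging components, apportions the variance in yield among traits
#' by a first-order delta method with covariances, estimates size-corrected
#' relative growth rates from four-parameter logistic fits, and tests
#' crop-versus-progenitor contrasts on species means with phylogenetic
#' generalized least squares (maximum-likelihood Pagel's lambda). A
#' synthetic-data generator reproduces the statistical structure of the
#' randomized-block greenhouse design so every stage can be exercised without
#' external data.
#'
#' @keywords internal
"_PACKAGE"

# Canonical trait-table columns. Seed masses are stored in mg in files and in
# the record table; conversion to g happens once, inside deriveComponents().
.trait_columns <- c(
  "species", "status", "family", "accession", "experiment", "block",
  "seed_mass_sown", "biomass_total", "mass_vegetative", "mass_reproductive",
  "mass_chaff", "mass_grain", "seed_mass_harvest", "n_seeds_total",
  "n_seeds_per_infructescence", "n_infructescences", "duration_days", "height"
)

.mandatory_columns <- setdiff(
  .trait_columns,
  c("n_seeds_per_infructescence", "n_infructescences", "height")
)

.mass_tol <- 1e-8

#' Construct a validated plant-record table
#'
#' Checks a data frame of per-plant trait measurements against the record
#' invariants (non-negative masses, chaff + grain not exceeding reproductive
#' mass, reproductive mass not exceeding total biomass, positive growth
#' duration) and returns it classed as \code{plant_records}. Records lacking
#' the per-infructescence packaging columns (pulses, for which pods were not
#' counted) are permitted; their packaging fields are \code{NA}.
#'
#' @param df data frame with the canonical trait columns; seed masses in mg,
#'   plant masses in g.
#' @return \code{df} with class \code{plant_records}; invalid rows raise an
#'   error naming the offending row numbers.
#' @seealso [readTraitTable()], [validatePlantRecords()]
#' @export
plantRecords <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.mandatory_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.trait_columns, names(df))) df[[col]] <- NA_real_
  df <- df[, .trait_columns]
  df$species <- as.character(df$species)
  df$status <- as.character(df$status)
  df$family <- as.character(df$family)
  bad_status <- !df$status %in% c("crop", "progenitor")
  if (any(bad_status)) {
    stop("status must be 'crop' or 'progenitor'; offending rows: ",
         paste(utils::head(which(bad_status), 10L), collapse = ", "))
  }
  bad_family <- !df$family %in% c("grass", "legume")
  if (any(bad_family)) {
    stop("family must be 'grass' or 'legume'; offending rows: ",
         paste(utils::head(which(bad_family), 10L), collapse = ", "))
  }
  issues <- validatePlantRecords(df)
  hard <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(hard) > 0L) {
    stop("invalid plant records:\n",
         paste(sprintf("  row %d: %s", hard$row, hard$message), collapse = "\n"))
  }
  class(df) <- c("plant_records", "data.frame")
  df
}

#' Validate plant records without failing
#'
#' Applies the record invariants row by row and returns every breach as one
#' row of a diagnostics table instead of raising. Severity \code{"error"}
#' marks breaches of hard invariants; \code{"warning"} marks biologically odd
#' but admissible values (a total seed count that disagrees with the product
#' of the packaging counts can arise from spike subsampling and is never
#' silently reconciled).
#'
#' @param df data frame with the canonical trait columns.
#' @return data frame with columns \code{row}, \code{severity}, \code{message};
#'   zero rows when the table is clean.
#' @export
validatePlantRecords <- function(df) {
  issues <- list()
  note <- function(rows, severity, message) {
    rows <- rows[!is.na(rows)]
    if (length(rows) > 0L) {
      issues[[length(issues) + 1L]] <<- data.frame(
        row = rows, severity = severity, message = message,
        stringsAsFactors = FALSE)
    }
  }
  mass_cols <- c("seed_mass_sown", "biomass_total", "mass_vegetative",
                 "mass_reproductive", "mass_chaff", "mass_grain",
                 "seed_mass_harvest")
  for (col in mass_cols) {
    neg <- which(!is.na(df[[col]]) & df[[col]] < 0)
    note(neg, "error", paste0("negative ", col))
  }
  over <- which(!is.na(df$mass_chaff) & !is.na(df$mass_grain) &
                !is.na(df$mass_reproductive) &
                df$mass_chaff + df$mass_grain >
                  df$mass_reproductive * (1 + .mass_tol) + .mass_tol)
  note(over, "error", "mass_chaff + mass_grain exceeds mass_reproductive")
  over2 <- which(!is.na(df$mass_reproductive) & !is.na(df$biomass_total) &
                 df$mass_reproductive > df$biomass_total * (1 + .mass_tol) + .mass_tol)
  note(over2, "error", "mass_reproductive exceeds biomass_total")
  nonpos_d <- which(!is.na(df$duration_days) & df$duration_days <= 0)
  note(nonpos_d, "error", "duration_days must be positive")
  if (all(c("n_seeds_per_infructescence", "n_infructescences") %in% names(df))) {
    both <- !is.na(df$n_seeds_per_infructescence) & !is.na(df$n_infructescences) &
      !is.na(df$n_seeds_total)
    prod_ <- df$n_seeds_per_infructescence * df$n_infructescences
    off <- which(both & abs(prod_ - df$n_seeds_total) >
                   1e-6 * pmax(1, abs(df$n_seeds_total)))
    note(off, "warning",
         "n_seeds_total differs from n_seeds_per_infructescence * n_infructescences (subsampled?)")
  }
  if (length(issues) == 0L) {
    return(data.frame(row = integer(), severity = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  out[order(out$row), , drop = FALSE]
}

#' Read a per-plant trait table from CSV
#'
#' @param path path to a CSV file with the canonical column names (header row,
#'   decimal point "."). Seed masses are expected in mg, plant masses in g.
#' @return a validated [plantRecords()] table.
#' @export
readTraitTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  plantRecords(df)
}

#' Write a per-plant trait table to CSV
#'
#' The inverse of [readTraitTable()]: values are written at full precision so
#' a write/read round trip reproduces every number exactly.
#'
#' @param records a \code{plant_records} table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTraitTable <- function(records, path) {
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a phylogeny from a Newick file
#'
#' Reads a rooted, ultrametric tree and optionally checks its tip set against
#' the species of a trait table. The comparative analyses assume an
#' ultrametric tree: under Brownian motion on such a tree all tips share the
#' same expected variance, which is what makes the Pagel's-lambda rescaling of
#' the off-diagonal covariances interpretable as a signal strength.
#'
#' @param path Newick file with branch lengths.
#' @param species optional character vector of expected tip labels.
#' @param tol relative tolerance for the ultrametricity check.
#' @return an \code{ape} \code{phylo} object.
#' @export
readPhylogeny <- function(path, species = NULL, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths: ", path)
  checkPhylogeny(tree, species = species, tol = tol)
  tree
}

#' Check a phylogeny against the analysis assumptions
#'
#' @param tree a \code{phylo} object.
#' @param species optional expected tip label set.
#' @param tol relative ultrametricity tolerance.
#' @return \code{tree}, invisibly; errors name any offending tip labels.
#' @export
checkPhylogeny <- function(tree, species = NULL, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (diff(range(depths)) > tol * max(depths)) {
    stop("tree is not ultrametric within tolerance ", tol)
  }
  if (!is.null(species)) {
    species <- unique(as.character(species))
    extra <- setdiff(tree$tip.label, species)
    missing_ <- setdiff(species, tree$tip.label)
    if (length(extra) > 0L || length(missing_) > 0L) {
      stop("tree tips and trait-table species disagree; ",
           if (length(extra)) paste0("tips absent from table: ",
                                     paste(extra, collapse = ", "), "; ") else "",
           if (length(missing_)) paste0("species absent from tree: ",
                                        paste(missing_, collapse = ", ")) else "")
    }
  }
  invisible(tree)
}

#' Per-trait transforms used for the comparative analysis
#'
#' Size-like traits (yield, seed masses, biomass, infructescence mass, counts,
#' height) are analysed on the natural-log scale, so crop-versus-progenitor
#' effects back-transform to ratios; the rates and proportions (duration,
#' reproductive allocation, chaff proportion, average and size-corrected RGR)
#' stay untransformed and effects are absolute differences.
#'
#' @return named character vector mapping trait names to \code{"log"} or
#'   \code{"identity"}.
#' @export
traitTransforms <- function() {
  c(yield = "log",
    seed_mass_sown = "log",
    seed_mass_harvest = "log",
    biomass = "log",
    infructescence_mass = "log",
    n_seeds_total = "log",
    n_seeds_per_infructescence = "log",
    n_infructescences = "log",
    height = "log",
    duration = "identity",
    reproductive_allocation = "identity",
    chaff_proportion = "identity",
    rgr_average = "identity",
    rgr_at_size = "identity")
}

#' Species means on the analysis scale
#'
#' Aggregates plant records to one row per species, the unit of the
#' comparative analysis. Log-scale traits are transformed first and then
#' averaged (the species value is the mean log, i.e. the log geometric mean);
#' proportions and rates are averaged untransformed, per [traitTransforms()].
#' Missing values are dropped per trait, so a trait measured in only one of
#' the two experiments still gets a species mean from the plants that carry
#' it.
#'
#' @param records a \code{plant_records} table.
#' @param by_accession if \code{TRUE}, average within accessions first and
#'   then across accessions within species, instead of pooling all plants of a
#'   species directly (the default).
#' @return data frame with one row per species: \code{species}, \code{status},
#'   \code{family}, \code{n_plants}, then one column per trait on its analysis
#'   scale (log traits prefixed \code{ln_}).
#' @export
speciesMeans <- function(records, by_accession = FALSE) {
  df <- as.data.frame(records)
  comp <- deriveComponents(records)
  base <- data.frame(
    species = df$species, status = df$status, family = df$family,
    accession = df$accession,
    ln_yield = log(comp$Y),
    ln_seed_mass_sown = log(comp$Ms_sown),
    ln_seed_mass_harvest = log(comp$Ms_harvest),
    ln_biomass = log(comp$Md),
    ln_infructescence_mass = log(df$mass_reproductive / df$n_infructescences),
    ln_n_seeds_total = log(comp$N_total),
    ln_n_seeds_per_infructescence = log(comp$Ns),
    ln_n_infructescences = log(comp$Ni),
    ln_height = log(df$height),
    duration = comp$d,
    reproductive_allocation = comp$Ar,
    chaff_proportion = comp$c,
    rgr_average = comp$lambda_bar,
    harvest_index = comp$harvest_index,
    stringsAsFactors = FALSE)
  trait_cols <- setdiff(names(base), c("species", "status", "family", "accession"))
  agg_mean <- function(d, by) {
    out <- stats::aggregate(d[trait_cols], by = by, FUN = mean, na.rm = TRUE)
    for (col in trait_cols) out[[col]][is.nan(out[[col]])] <- NA_real_
    out
  }
  if (by_accession) {
    acc <- agg_mean(base, list(species = base$species, accession = base$accession))
    sp <- agg_mean(acc, list(species = acc$species))
  } else {
    sp <- agg_mean(base, list(species = base$species))
  }
  meta <- unique(df[, c("species", "status", "family")])
  if (anyDuplicated(meta$species)) {
    stop("species with inconsistent status/family labels: ",
         paste(meta$species[duplicated(meta$species)], collapse = ", "))
  }
  n_plants <- as.data.frame(table(species = df$species), stringsAsFactors = FALSE)
  names(n_plants)[2] <- "n_plants"
  out <- merge(meta, sp, by = "species")
  out <- merge(out, n_plants, by = "species")
  out <- out[order(out$family, out$species),
             c("species", "status", "family", "n_plants", trait_cols)]
  rownames(out) <- NULL
  out
}
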