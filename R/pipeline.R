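#' Read a run configuration from YAML
#'
#' A run configuration holds either a \code{simulate} block (arguments for
#' [simConfig()]) or an \code{inputs} block with paths to a trait CSV, a
#' growth CSV and a Newick tree — exactly one of the two — plus an optional
#' \code{replication_mode} flag (use the archived common sizes 42.1/64.7 mg
#' instead of data-derived ones).
#'
#' @param path YAML file.
#' @return list of class \code{run_config}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_sim <- !is.null(cfg$simulate)
  has_inp <- !is.null(cfg$inputs)
  if (has_sim == has_inp) {
    stop("run config must contain exactly one of 'simulate' or 'inputs'")
  }
  if (has_sim) cfg$sim_config <- do.call(simConfig, cfg$simulate)
  cfg$replication_mode <- isTRUE(cfg$replication_mode)
  class(cfg) <- "run_config"
  cfg
}

#' Simulate a dataset and write it to disk
#'
#' Writes the four files the analysis stage consumes: the per-plant trait
#' table (\code{traits.csv}), the growth-analysis series
#' (\code{growth.csv}), the phylogeny (\code{tree.nwk}) and the planted
#' species-level truth (\code{truth.csv}). Identical seeds give
#' byte-identical files.
#'
#' @param config a \code{sim_config} (or a \code{run_config} carrying one).
#' @param dir output directory, created if absent.
#' @return named character vector of the file paths, invisibly.
#' @export
simulateDataset <- function(config, dir) {
  if (inherits(config, "run_config")) config <- config$sim_config
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  sim <- simulateTraitTable(config)
  growth <- simulateGrowthSeries(config)
  paths <- c(traits = file.path(dir, "traits.csv"),
             growth = file.path(dir, "growth.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.csv"))
  writeTraitTable(sim$records, paths[["traits"]])
  .writeCsvFull(growth$series, paths[["growth"]])
  ape::write.tree(sim$tree, paths[["tree"]])
  .writeCsvFull(sim$truth, paths[["truth"]])
  invisible(paths)
}

.writeCsvFull <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline on a dataset
#'
#' Orchestrates every stage on a dataset directory (as written by
#' [simulateDataset()], or any directory with the same three input files):
#' derives per-plant yield components, aggregates species means, runs both
#' variance decompositions for all species / cereals / pulses, fits the
#' growth curves and size-corrected RGR, and fits the PGLS
#' crop-versus-progenitor contrast for every trait. Writes CSV outputs, a
#' markdown report and a plain-text run log into \code{out_dir}. A stage
#' that fails is recorded in the report and the remaining stages still run.
#'
#' @param dir dataset directory containing \code{traits.csv},
#'   \code{growth.csv} and \code{tree.nwk} (or pass explicit paths).
#' @param out_dir output directory; defaults to \code{file.path(dir,
#'   "analysis")}.
#' @param traits,growth,tree optional explicit input paths overriding
#'   \code{dir}.
#' @param replication_mode use the archived common sizes
#'   ([commonSizeDefaults]) for the RGR-at-size stage instead of
#'   data-derived ones.
#' @return list with every stage's result (\code{components}, \code{means},
#'   \code{contributions1}, \code{contributions2}, \code{growth_fits},
#'   \code{pgls}, \code{failed}) plus the output paths, invisibly classed
#'   \code{yieldparts_analysis}.
#' @export
analyseDataset <- function(dir = NULL, out_dir = NULL,
                           traits = NULL, growth = NULL, tree = NULL,
                           replication_mode = FALSE) {
  if (!is.null(dir)) {
    if (is.null(traits)) traits <- file.path(dir, "traits.csv")
    if (is.null(growth)) growth <- file.path(dir, "growth.csv")
    if (is.null(tree)) tree <- file.path(dir, "tree.nwk")
    if (is.null(out_dir)) out_dir <- file.path(dir, "analysis")
  }
  if (is.null(out_dir)) stop("out_dir must be given when dir is not")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  failed <- character()
  log_lines <- c(sprintf("yieldparts %s | %s",
                         as.character(utils::packageVersion("yieldparts")),
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("inputs: traits=%s growth=%s tree=%s",
                         traits, growth, tree))
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      failed <<- c(failed, name)
      log_lines <<- c(log_lines, sprintf("stage %s FAILED: %s",
                                         name, conditionMessage(e)))
      NULL
    })
    if (!name %in% failed) log_lines <<- c(log_lines, sprintf("stage %s ok", name))
    out
  }

  records <- stage("read_traits", readTraitTable(traits))
  phylo <- stage("read_tree", readPhylogeny(tree, species = unique(records$species)))
  comp <- stage("components", deriveComponents(records))
  means <- stage("species_means", speciesMeans(records))
  contrib1 <- stage("variance_decomposition_1", contributionSummary(comp, 1))
  contrib2 <- stage("variance_decomposition_2", contributionSummary(comp, 2))
  growth_df <- stage("read_growth", {
    if (!file.exists(growth)) stop("growth file not found: ", growth)
    utils::read.csv(growth, stringsAsFactors = FALSE)
  })
  gfits <- stage("growth_curves", growthAnalysis(
    growth_df,
    common_sizes = if (replication_mode) commonSizeDefaults else NULL))
  pg <- stage("pgls", {
    m <- means
    if (!is.null(gfits)) {
      m <- merge(m, gfits[, c("species", "lambda_s")], by = "species",
                 all.x = TRUE)
      names(m)[names(m) == "lambda_s"] <- "rgr_at_size"
    }
    pglsTable(m, phylo)
  })

  paths <- list()
  emit <- function(obj, file) {
    if (is.null(obj)) return(invisible(NULL))
    p <- file.path(out_dir, file)
    utils::write.csv(obj, p, row.names = FALSE)
    paths[[file]] <<- p
  }
  emit(as.data.frame(comp), "components_per_plant.csv")
  emit(means, "species_means.csv")
  if (!is.null(contrib1)) {
    emit(contrib1$shares, "contribution_shares_growth.csv")
    emit(.flattenMatrices(contrib1$tables), "contribution_matrices_growth.csv")
  }
  if (!is.null(contrib2)) {
    emit(contrib2$shares, "contribution_shares_packaging.csv")
    emit(.flattenMatrices(contrib2$tables), "contribution_matrices_packaging.csv")
  }
  emit(gfits, "growth_fits.csv")
  emit(pg, "pgls_contrasts.csv")

  report <- .renderReport(comp, means, contrib1, contrib2, gfits, pg, failed)
  writeLines(report, file.path(out_dir, "report.md"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  out <- list(components = comp, means = means,
              contributions1 = contrib1, contributions2 = contrib2,
              growth_fits = gfits, pgls = pg,
              failed = failed, out_dir = out_dir, paths = paths)
  class(out) <- "yieldparts_analysis"
  invisible(out)
}

.flattenMatrices <- function(tables) {
  traits <- unique(unlist(lapply(tables, function(t) rownames(t$C))))
  do.call(rbind, lapply(names(tables), function(gr) {
    C <- tables[[gr]]$C
    df <- as.data.frame(matrix(NA_real_, nrow(C), length(traits),
                               dimnames = list(NULL, traits)))
    df[, colnames(C)] <- C
    cbind(group = gr, trait = rownames(C), df, row.names = NULL)
  }))
}

.renderReport <- function(comp, means, contrib1, contrib2, gfits, pg, failed) {
  fmt_shares <- function(cs, label) {
    if (is.null(cs)) return(sprintf("Stage failed: %s", label))
    df <- cs$shares
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.2f", v))
    c(sprintf("## Variance decomposition (%s)", label), "",
      paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1L, paste, collapse = " | "), "")
  }
  lines <- c("# yieldparts analysis report", "")
  if (length(failed) > 0L) {
    lines <- c(lines, paste("**Failed stages:**", paste(failed, collapse = ", ")), "")
  }
  if (!is.null(means)) {
    lines <- c(lines, sprintf("Species analysed: %d (%d crops, %d progenitors).",
                              nrow(means), sum(means$status == "crop"),
                              sum(means$status == "progenitor")), "")
  }
  lines <- c(lines,
             fmt_shares(contrib1, "growth/allocation components"),
             fmt_shares(contrib2, "seed packaging components"))
  if (!is.null(pg)) {
    show <- pg[, c("trait", "n_species", "ratio", "pct_of_progenitor",
                   "lambda", "F", "df1", "df2", "p")]
    num <- vapply(show, is.numeric, logical(1))
    show[num] <- lapply(show[num], function(v) ifelse(is.na(v), "",
                                                      sprintf("%.3g", v)))
    lines <- c(lines, "## PGLS crop-vs-progenitor contrasts", "",
               paste(names(show), collapse = " | "),
               paste(rep("---", ncol(show)), collapse = " | "),
               apply(show, 1L, paste, collapse = " | "), "")
  }
  if (!is.null(gfits)) {
    lines <- c(lines, sprintf(
      "## Growth analysis\n\n%d species fitted; %d converged; common sizes: %s mg.",
      nrow(gfits), sum(gfits$converged),
      paste(sprintf("%s %.1f", unique(gfits$family),
                    gfits$common_mass_mg[!duplicated(gfits$family)]),
            collapse = ", ")), "")
  }
  lines
}

#' @export
print.yieldparts_analysis <- function(x, ...) {
  cat("yieldparts analysis:",
      if (length(x$failed)) paste("FAILED stages:", paste(x$failed, collapse = ", "))
      else "all stages completed", "\n")
  cat("outputs in", x$out_dir, "\n")
  invisible(x)
}
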