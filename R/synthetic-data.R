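#' Species roster of the simulated experiment
#'
#' The 17 taxa of the crop-versus-progenitor comparison: five cereal pairs
#' (barley, einkorn and emmer wheat as primary domesticates; oat and rye as
#' secondary) and three pulse pairs (chickpea, lentil, pea), with two
#' candidate wild pea progenitors, both treated as progenitors in the
#' contrast.
#'
#' @return data frame with columns \code{species}, \code{status},
#'   \code{family}, \code{pair}, \code{secondary}.
#' @export
speciesRoster <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
species status family pair secondary
Avena_sativa crop grass avena TRUE
Avena_sterilis progenitor grass avena TRUE
Hordeum_vulgare crop grass hordeum FALSE
Hordeum_spontaneum progenitor grass hordeum FALSE
Secale_cereale crop grass secale TRUE
Secale_vavilovii progenitor grass secale TRUE
Triticum_monococcum_monococcum crop grass einkorn FALSE
Triticum_monococcum_aegilopoides progenitor grass einkorn FALSE
Triticum_turgidum_dicoccon crop grass emmer FALSE
Triticum_turgidum_dicoccoides progenitor grass emmer FALSE
Cicer_arietinum crop legume cicer FALSE
Cicer_reticulatum progenitor legume cicer FALSE
Lens_culinaris crop legume lens FALSE
Lens_orientalis progenitor legume lens FALSE
Pisum_sativum crop legume pisum FALSE
Pisum_elatius progenitor legume pisum FALSE
Pisum_elatius_pumilio progenitor legume pisum FALSE
")
  df
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic experiment. The
#' defaults emulate the design of the two yield experiments (20 + 10
#' randomized blocks; oat and rye absent from the second experiment, so 30
#' replicates for most species and 20 for those four) and plant the
#' domestication effect multipliers reported for landraces versus wild
#' progenitors: sown seed mass 1.9x, final biomass 1.4x, seeds per
#' infructescence 1.3x, chaff proportion reduced by 38 percent, with no
#' planted change in reproductive allocation, growth duration, total seed
#' number per gram, or growth rate. Progenitor baselines are declared
#' constants at plausible magnitudes (grass seed 10 mg, legume seed 30 mg,
#' biomass 20 g, reproductive allocation 0.4, chaff proportion 0.39, duration
#' 100 days), anchored to the one printed progenitor chaff mean; they are
#' configuration, not ground truth.
#'
#' @param seed integer root seed; every stream of random numbers in the
#'   generator derives from it.
#' @param n_blocks_exp1,n_blocks_exp2 block counts of the two experiments.
#' @param n_accessions accessions per species; replicates are divided evenly.
#' @param multipliers named list of crop:progenitor effect multipliers on the
#'   natural scale (\code{seed_mass}, \code{biomass}, \code{ar},
#'   \code{chaff}, \code{ns}, \code{duration}, \code{height}).
#' @param baselines per-family progenitor baselines, see Details in the
#'   package vignette.
#' @param noise named list of noise standard deviations: \code{species_ln_*}
#'   are Brownian-motion SDs over unit tree depth on the log (or logit)
#'   scale; \code{block_ln} the block effect SD; \code{resid_*} per-plant
#'   residual SDs.
#' @param noiseless zero out every noise source (species effects, block
#'   effects, residuals), so plant records equal their planted component
#'   means exactly.
#' @param attenuate_secondary shrink the multipliers of the secondary
#'   domesticates (oat, rye) toward 1 (exponent \code{attenuation}),
#'   emulating their weaker domestication effect. Off by default.
#' @param attenuation exponent used when \code{attenuate_secondary} is on.
#' @param growth list of four-parameter-logistic baselines for the growth
#'   analysis experiment: per-family lower asymptote \code{A} (ln g), upper
#'   asymptote \code{B}, inflection \code{t_mid}, scale \code{s}, their
#'   between-species SDs, harvest \code{days}, plants per harvest, and
#'   ln-mass residual SD.
#' @return validated list of class \code{sim_config}.
#' @export
simConfig <- function(seed = 1L,
                      n_blocks_exp1 = 20L,
                      n_blocks_exp2 = 10L,
                      n_accessions = 3L,
                      multipliers = list(),
                      baselines = list(),
                      noise = list(),
                      noiseless = FALSE,
                      attenuate_secondary = FALSE,
                      attenuation = 0.25,
                      growth = list()) {
  mult <- utils::modifyList(list(
    seed_mass = 1.9, biomass = 1.4, ar = 1.0, chaff = 1 - 0.38,
    ns = 1.3, duration = 1.0, height = 1.0), multipliers)
  base <- utils::modifyList(list(
    grass = list(seed_mass_mg = 10, biomass = 20, ar = 0.4, chaff = 0.39,
                 duration = 100, ns = 20, height = 100),
    legume = list(seed_mass_mg = 30, biomass = 20, ar = 0.4, chaff = 0.39,
                  duration = 100, ns = NA_real_, height = 60)), baselines)
  nz <- utils::modifyList(list(
    species_ln_seed = 0.40, species_ln_biomass = 0.30,
    species_logit_ar = 0.15, species_logit_chaff = 0.20,
    species_ln_d = 0.08, species_ln_ns = 0.25, species_ln_height = 0.20,
    block_ln = 0.10,
    resid_ln_seed = 0.10, resid_ln_biomass = 0.20,
    resid_logit_ar = 0.10, resid_logit_chaff = 0.12,
    resid_ln_d = 0.05, resid_ln_ns = 0.15, resid_ln_height = 0.10,
    harvest_seed_ln = 0.05), noise)
  gr <- utils::modifyList(list(
    A = c(grass = -5.2, legume = -4.6), A_sd = 0.30,
    B = c(grass = 0.7, legume = 0.7), B_sd = 0.20,
    t_mid = 16, t_mid_sd = 1.5,
    s = 3.5, ln_s_sd = 0.10,
    days = c(8, 12, 16, 20, 24, 28),
    plants_per_harvest = 2L, n_blocks = 6L,
    resid_ln_mass = 0.10), growth)
  if (isTRUE(noiseless)) {
    nz[] <- 0
    gr$A_sd <- gr$B_sd <- gr$t_mid_sd <- gr$ln_s_sd <- gr$resid_ln_mass <- 0
  }
  cfg <- list(seed = as.integer(seed),
              n_blocks_exp1 = as.integer(n_blocks_exp1),
              n_blocks_exp2 = as.integer(n_blocks_exp2),
              n_accessions = as.integer(n_accessions),
              multipliers = mult, baselines = base, noise = nz,
              noiseless = isTRUE(noiseless),
              attenuate_secondary = isTRUE(attenuate_secondary),
              attenuation = attenuation,
              growth = gr,
              roster = speciesRoster())
  if (any(unlist(mult) <= 0)) stop("effect multipliers must be positive")
  for (fam in names(base)) {
    cb <- base[[fam]]$chaff
    if (cb <= 0 || cb >= 1 || cb * mult$chaff <= 0 || cb * mult$chaff >= 1) {
      stop("chaff proportion must stay inside (0, 1) after the planted effect")
    }
    if (base[[fam]]$ar <= 0 || base[[fam]]$ar * mult$ar > 1) {
      stop("reproductive allocation must stay inside (0, 1] after the planted effect")
    }
  }
  if (any(gr$days < 8 | gr$days > 28)) {
    stop("growth harvest days must lie within day 8 to day 28")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Effect ratios implied by a simulation configuration
#'
#' The generator plants component multipliers and enforces the exact
#' decomposition identities, so the crop:progenitor ratios of the derived
#' quantities follow from the components: yield = biomass x allocation x
#' (1 - chaff) ratios; infructescence count = yield / (seed mass x seeds per
#' infructescence); total seed number = yield / seed mass.
#'
#' @param config a \code{sim_config}.
#' @return named vector of implied crop:progenitor ratios, including the
#'   planted component multipliers, plus \code{chaff_reduction_pct}.
#' @export
impliedEffects <- function(config) {
  m <- config$multipliers
  cb <- config$baselines$grass$chaff
  yield <- m$biomass * m$ar * (1 - cb * m$chaff) / (1 - cb)
  c(yield = yield,
    seed_mass = m$seed_mass,
    biomass = m$biomass,
    ar = m$ar,
    chaff = m$chaff,
    chaff_reduction_pct = 100 * (1 - m$chaff),
    ns = m$ns,
    ni = yield / (m$seed_mass * m$ns),
    n_total = yield / m$seed_mass,
    duration = m$duration,
    height = m$height)
}

#' Synthetic ultrametric phylogeny of the 17 taxa
#'
#' A fixed topology with a grass clade (Avena sister to the Triticeae:
#' Hordeum, then Secale and the two Triticum pairs) and a legume clade
#' (Cicer sister to Lens + Pisum), each crop sister to its own progenitor and
#' the two wild peas forming a clade sister to the domesticated pea. Branch
#' lengths make the tree ultrametric with unit root depth. This is a
#' stand-in topology for simulation, not an inferred chronogram.
#'
#' @param config a \code{sim_config} (unused fields tolerated; present so
#'   that all generator entry points share one signature).
#' @return an \code{ape} \code{phylo}, ultrametric, 17 tips.
#' @export
makeTree <- function(config = simConfig()) {
  nwk <- paste0(
    "((((Hordeum_vulgare:0.1,Hordeum_spontaneum:0.1):0.45,",
    "((Secale_cereale:0.1,Secale_vavilovii:0.1):0.35,",
    "((Triticum_monococcum_monococcum:0.1,Triticum_monococcum_aegilopoides:0.1):0.2,",
    "(Triticum_turgidum_dicoccon:0.1,Triticum_turgidum_dicoccoides:0.1):0.2):0.15):0.1):0.15,",
    "(Avena_sativa:0.1,Avena_sterilis:0.1):0.6):0.3,",
    "((Cicer_arietinum:0.1,Cicer_reticulatum:0.1):0.5,",
    "((Lens_culinaris:0.1,Lens_orientalis:0.1):0.3,",
    "((Pisum_elatius:0.05,Pisum_elatius_pumilio:0.05):0.05,",
    "Pisum_sativum:0.1):0.3):0.2):0.4):0;")
  tree <- ape::read.tree(text = nwk)
  checkPhylogeny(tree, species = speciesRoster()$species, tol = 1e-9)
  tree
}

# Brownian deviates on the tree: one draw per tip, Cov = sigma^2 * vcv(tree).
.bmDeviates <- function(tree, sigma, order_species) {
  n <- ape::Ntip(tree)
  if (sigma == 0) return(stats::setNames(rep(0, n), order_species))
  C <- ape::vcv(tree)[order_species, order_species]
  z <- as.numeric(t(chol(C)) %*% stats::rnorm(n)) * sigma
  stats::setNames(z, order_species)
}

# Planted species-level component means: family baseline x Brownian deviate
# (log or logit scale) x status multiplier (natural scale).
.speciesTruth <- function(config, tree) {
  roster <- config$roster
  sp <- roster$species
  m <- config$multipliers
  nz <- config$noise
  mult_for <- function(name) {
    out <- ifelse(roster$status == "crop", m[[name]], 1)
    if (config$attenuate_secondary) {
      att <- roster$status == "crop" & roster$secondary
      out[att] <- m[[name]]^config$attenuation
    }
    out
  }
  base_of <- function(field) {
    vapply(roster$family, function(f) config$baselines[[f]][[field]], numeric(1))
  }
  ln_trait <- function(field, sigma, mult) {
    base_of(field) * exp(.bmDeviates(tree, sigma, sp)) * mult
  }
  logit_trait <- function(field, sigma, mult) {
    v <- invlogit(logit(base_of(field)) + .bmDeviates(tree, sigma, sp)) * mult
    if (any(v <= 0 | v >= 1)) stop("simulated proportion left (0, 1)")
    v
  }
  truth <- data.frame(
    species = sp, status = roster$status, family = roster$family,
    pair = roster$pair, secondary = roster$secondary,
    seed_mass_mg = ln_trait("seed_mass_mg", nz$species_ln_seed, mult_for("seed_mass")),
    biomass = ln_trait("biomass", nz$species_ln_biomass, mult_for("biomass")),
    ar = logit_trait("ar", nz$species_logit_ar, mult_for("ar")),
    chaff = logit_trait("chaff", nz$species_logit_chaff, mult_for("chaff")),
    duration = ln_trait("duration", nz$species_ln_d, mult_for("duration")),
    ns = ln_trait("ns", nz$species_ln_ns, mult_for("ns")),
    height = ln_trait("height", nz$species_ln_height, mult_for("height")),
    stringsAsFactors = FALSE)
  truth$ns[truth$family == "legume"] <- NA_real_
  truth$yield <- truth$biomass * truth$ar * (1 - truth$chaff)
  truth
}

#' Simulate a per-plant trait table
#'
#' Generates plant records with the statistical structure of the two yield
#' experiments: species-level component means are the family baseline times a
#' Brownian-motion deviate on the tree (log scale for sizes, logit for
#' proportions) times the status multiplier; plant records multiply in a
#' log-normal block effect and residual noise; masses are then derived from
#' the components so that the decomposition identities hold exactly. Cereal
#' infructescence counts are derived from the packaging identity
#' Ni = Y / (Ms_harvest x Ns); pulses carry no per-infructescence counts.
#' Oat and rye appear only in experiment 1. In noiseless mode every plant
#' equals its species' planted component means.
#'
#' @param config a \code{sim_config}.
#' @param tree phylogeny from [makeTree()]; regenerated when omitted.
#' @return list with \code{records} (a validated \code{plant_records} table),
#'   \code{truth} (planted species-level component means plus the multiplier
#'   set and implied ratios as attributes) and \code{tree}.
#' @export
simulateTraitTable <- function(config = simConfig(), tree = NULL) {
  if (is.null(tree)) tree <- makeTree(config)
  seeds <- childSeeds(config$seed, c("species", "plants", "growth"))
  truth <- withSeed(seeds[["species"]], .speciesTruth(config, tree))
  nz <- config$noise

  exp1_only <- truth$pair %in% c("avena", "secale")
  plan <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    b1 <- data.frame(species = truth$species[i], experiment = 1L,
                     block = seq_len(config$n_blocks_exp1))
    if (exp1_only[i] || config$n_blocks_exp2 == 0L) return(b1)
    b2 <- data.frame(species = truth$species[i], experiment = 2L,
                     block = config$n_blocks_exp1 + seq_len(config$n_blocks_exp2))
    rbind(b1, b2)
  }))

  records <- withSeed(seeds[["plants"]], {
    n_blocks <- config$n_blocks_exp1 + config$n_blocks_exp2
    block_eff <- stats::rnorm(n_blocks, 0, nz$block_ln)
    i <- match(plan$species, truth$species)
    n <- nrow(plan)
    rln <- function(sd) if (sd == 0) rep(0, n) else stats::rnorm(n, 0, sd)
    ms_sown_mg <- truth$seed_mass_mg[i] * exp(rln(nz$resid_ln_seed))
    md <- truth$biomass[i] * exp(block_eff[plan$block] + rln(nz$resid_ln_biomass))
    ar <- invlogit(logit(truth$ar[i]) + rln(nz$resid_logit_ar))
    cc <- invlogit(logit(truth$chaff[i]) + rln(nz$resid_logit_chaff))
    d <- truth$duration[i] * exp(rln(nz$resid_ln_d))
    ms_harv_mg <- ms_sown_mg * exp(rln(nz$harvest_seed_ln))
    repro <- ar * md
    grain <- (1 - cc) * repro
    chaff <- cc * repro
    veg <- md - repro
    is_cereal <- truth$family[i] == "grass"
    ns <- ifelse(is_cereal, truth$ns[i] * exp(rln(nz$resid_ln_ns)), NA_real_)
    ni <- ifelse(is_cereal, grain / ((ms_harv_mg / 1000) * ns), NA_real_)
    n_total <- ifelse(is_cereal, ns * ni, grain / (ms_harv_mg / 1000))
    height <- truth$height[i] * exp(rln(nz$resid_ln_height))
    acc_idx <- (plan$block - 1L) %% config$n_accessions + 1L
    data.frame(
      species = plan$species,
      status = truth$status[i], family = truth$family[i],
      accession = paste0(plan$species, "_acc", acc_idx),
      experiment = plan$experiment, block = plan$block,
      seed_mass_sown = ms_sown_mg,
      biomass_total = md,
      mass_vegetative = veg,
      mass_reproductive = repro,
      mass_chaff = chaff,
      mass_grain = grain,
      seed_mass_harvest = ms_harv_mg,
      n_seeds_total = n_total,
      n_seeds_per_infructescence = ns,
      n_infructescences = ni,
      duration_days = d,
      height = height,
      stringsAsFactors = FALSE)
  })

  attr(truth, "multipliers") <- config$multipliers
  attr(truth, "implied_effects") <- impliedEffects(config)
  attr(truth, "seed") <- config$seed
  list(records = plantRecords(records), truth = truth, tree = tree)
}

#' Simulate a growth-analysis harvest series
#'
#' Per species, a four-parameter logistic curve of ln mass against day is
#' planted (family baseline parameters plus independent between-species
#' scatter; growth parameters carry no crop-versus-progenitor effect, so the
#' planted size-corrected RGR difference is null) and observed at six harvest
#' days between day 8 and day 28, two plants per species per harvest across
#' six blocks, with log-normal mass noise.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{series} (data frame: \code{species},
#'   \code{status}, \code{family}, \code{accession}, \code{block},
#'   \code{day}, \code{mass} in g) and \code{truth} (planted 4PL parameters
#'   per species).
#' @export
simulateGrowthSeries <- function(config = simConfig()) {
  seeds <- childSeeds(config$seed, c("species", "plants", "growth"))
  roster <- config$roster
  gr <- config$growth
  withSeed(seeds[["growth"]], {
    n <- nrow(roster)
    truth <- data.frame(
      species = roster$species, status = roster$status, family = roster$family,
      A = gr$A[roster$family] + stats::rnorm(n, 0, gr$A_sd),
      B = gr$B[roster$family] + stats::rnorm(n, 0, gr$B_sd),
      t_mid = gr$t_mid + stats::rnorm(n, 0, gr$t_mid_sd),
      s = exp(log(gr$s) + stats::rnorm(n, 0, gr$ln_s_sd)),
      stringsAsFactors = FALSE)
    series <- do.call(rbind, lapply(seq_len(n), function(i) {
      obs <- expand.grid(day = gr$days, plant = seq_len(gr$plants_per_harvest))
      lnm <- logistic4(obs$day, truth$A[i], truth$B[i], truth$t_mid[i], truth$s[i]) +
        (if (gr$resid_ln_mass == 0) 0 else stats::rnorm(nrow(obs), 0, gr$resid_ln_mass))
      data.frame(
        species = truth$species[i], status = truth$status[i],
        family = truth$family[i],
        accession = paste0(truth$species[i], "_acc",
                           (obs$plant - 1L) %% config$n_accessions + 1L),
        block = (match(obs$day, gr$days) + obs$plant - 2L) %% gr$n_blocks + 1L,
        day = obs$day, mass = exp(lnm),
        stringsAsFactors = FALSE)
    }))
    rownames(series) <- NULL
    list(series = series, truth = truth)
  })
}
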