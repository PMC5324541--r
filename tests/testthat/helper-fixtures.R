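# Shared fixtures, all built in code.

# One fully-specified cereal record with exactly consistent masses.
consistentRecordDf <- function() {
  data.frame(
    species = "Hordeum_vulgare", status = "crop", family = "grass",
    accession = "a1", experiment = 1L, block = 1L,
    seed_mass_sown = 40,          # mg
    biomass_total = 10,           # g
    mass_vegetative = 6,
    mass_reproductive = 4,
    mass_chaff = 1,
    mass_grain = 3,
    seed_mass_harvest = 40,
    n_seeds_total = 75,
    n_seeds_per_infructescence = 15,
    n_infructescences = 5,
    duration_days = 100,
    height = 80,
    stringsAsFactors = FALSE)
}

# Small balanced crop/progenitor design on a 4-tip ultrametric tree.
smallTree <- function() {
  ape::read.tree(text = "((A:0.2,B:0.2):0.8,(D:0.2,E:0.2):0.8);")
}

defaultTree <- local({
  tree <- NULL
  function() {
    if (is.null(tree)) tree <<- makeTree()
    tree
  }
})

defaultStatus <- function(species) {
  r <- speciesRoster()
  r$status[match(species, r$species)]
}
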