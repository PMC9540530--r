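# Synthetic-data generator: complete, self-consistent input bundles (dated
# tree ensembles, mixed-type trait tables, regions, status records) with
# the statistical structure the analysis assumes — a continental species
# pool of ~228 mammals, ~45 regions of which the islands are depauperate
# and experience proportionally more turnover, and a deterministic
# single-region "continental" fixture reproducing the published counts.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is meant for:
#' 228 species, 45 regions with 40% islands, islands starting with far
#' fewer natives (mean 25 vs 120) and experiencing relatively more
#' extirpation and introduction. Tree ensembles default to 100 trees (the
#' full-scale analyses use 1000).
#'
#' @param n_species,n_trees,n_regions pool sizes.
#' @param island_fraction fraction of regions that are islands.
#' @param meanRichnessIsland,meanRichnessContinental mean 8000 BP native
#'   richness per region class.
#' @param pExtIsland,pExtContinental per-native extirpation probability.
#' @param pRegainIsland,pRegainContinental probability an extirpated
#'   (globally extant) species is regained.
#' @param meanIntroIsland,meanIntroContinental Poisson mean of introduced
#'   species per region.
#' @param meanColonist Poisson mean of natural colonists per region.
#' @param pRecent probability a change event is recent (1945 or later).
#' @param logMassMean,logMassSd log10 body-mass distribution (grams) for
#'   non-volant species.
#' @param dietConcentration Dirichlet concentration of the 7 diet
#'   percentages (values < 1 give realistic, specialist-heavy diets).
#' @param pVolant fraction of volant (bat-like, small-bodied) species.
#' @param nExtinct number of globally extinct species in the pool.
#' @param pSurrogate probability a globally extinct species has a living
#'   surrogate (domestic descendant or close relative).
#' @param seed mandatory integer seed.
#' @return list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(n_species = 228, n_trees = 100, n_regions = 45,
                             island_fraction = 0.4,
                             meanRichnessIsland = 25,
                             meanRichnessContinental = 120,
                             pExtIsland = 0.2, pExtContinental = 0.06,
                             pRegainIsland = 0.2, pRegainContinental = 0.35,
                             meanIntroIsland = 12, meanIntroContinental = 8,
                             meanColonist = 2, pRecent = 0.5,
                             logMassMean = 2.0, logMassSd = 1.0,
                             dietConcentration = 0.5,
                             pVolant = 0.08, nExtinct = 12,
                             pSurrogate = 0.5, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  probs <- c(island_fraction, pExtIsland, pExtContinental, pRegainIsland,
             pRegainContinental, pRecent, pVolant, pSurrogate)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0, 1]")
  if (n_species < 2) stop("need at least two species")
  structure(cfg, class = "SimulationConfig")
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

speciesLabels <- function(n) sprintf("sp%04d", seq_len(n))

# Deterministic largest-remainder rounding of non-negative x to integers
# summing to `total`.
roundToSum <- function(x, total = 100) {
  scaled <- x / sum(x) * total
  base <- floor(scaled)
  short <- total - sum(base)
  if (short > 0) {
    order_ <- order(scaled - base, seq_along(x), decreasing = c(TRUE, FALSE),
                    method = "radix")
    base[order_[seq_len(short)]] <- base[order_[seq_len(short)]] + 1
  }
  base
}

#' Simulate an ensemble of dated ultrametric trees
#'
#' Pure-birth (Yule) trees with exponential waiting times via
#' [ape::rphylo()] with zero extinction; all trees share the tip set
#' `sp0001 ... spNNNN`. Reproducible under the config seed.
#'
#' @param config a [simulationConfig()].
#' @return A [TreeEnsemble-class].
#' @export
simulateTrees <- function(config) {
  n <- config$n_species
  withSeed(config$seed + 1L, {
    trees <- lapply(seq_len(config$n_trees), function(i) {
      tr <- ape::rphylo(n, birth = 1, death = 0)
      tr$tip.label <- speciesLabels(n)[sample.int(n)]
      tr
    })
    TreeEnsemble(trees)
  })
}

#' Simulate a species trait table
#'
#' log10 body mass is normal (volant species are drawn small-bodied); the
#' seven diet percentages are Dirichlet draws rounded to integers summing
#' to 100 by the largest-remainder method; foraging stratum, activity
#' flags (at least one guaranteed) and habitat flags are categorical /
#' Bernoulli; `nExtinct` species are flagged globally extinct, a subset of
#' which have living surrogates.
#'
#' @param config a [simulationConfig()].
#' @return A [SpeciesTable-class].
#' @export
simulateTraits <- function(config) {
  n <- config$n_species
  withSeed(config$seed + 2L, {
    ids <- speciesLabels(n)
    volant <- runif(n) < config$pVolant
    logMass <- ifelse(volant,
                      rnorm(n, 1.0, 0.35),
                      rnorm(n, config$logMassMean, config$logMassSd))
    diet <- t(vapply(seq_len(n), function(i) {
      g <- rgamma(7, shape = config$dietConcentration)
      while (sum(g) == 0) g <- rgamma(7, shape = config$dietConcentration)
      roundToSum(g, 100)
    }, numeric(7)))
    colnames(diet) <- dietColumns()
    stratum <- ifelse(volant, "aerial",
                      sample(c("ground", "scansorial", "arboreal"), n,
                             replace = TRUE, prob = c(0.6, 0.25, 0.15)))
    act <- cbind(act_nocturnal = runif(n) < 0.45,
                 act_crepuscular = runif(n) < 0.25,
                 act_diurnal = runif(n) < 0.5)
    none <- rowSums(act) == 0
    act[cbind(which(none), sample.int(3, sum(none), replace = TRUE))] <- TRUE
    habitatLabels <- c("forest", "grassland", "shrubland", "wetland",
                       "rocky", "desert", "urban", "freshwater")
    hab <- matrix(runif(n * 8) < 0.3, n, 8)
    none <- rowSums(hab) == 0
    hab[cbind(which(none), sample.int(8, sum(none), replace = TRUE))] <- TRUE
    habitat <- apply(hab, 1, function(h)
      paste(habitatLabels[h], collapse = ";"))
    extinct <- rep(FALSE, n)
    extinct[sample.int(n, min(config$nExtinct, n))] <- TRUE
    surrogate <- extinct & runif(n) < config$pSurrogate
    SpeciesTable(data.frame(
      species_id = ids, name = paste("Species", ids), mass_g = 10^logMass,
      diet, foraging_stratum = stratum, act,
      habitat_flags = habitat, volant = volant, globally_extinct = extinct,
      surrogate_available = surrogate, stringsAsFactors = FALSE))
  })
}

#' Simulate per-region status records and region metadata
#'
#' Islands draw fewer natives and experience proportionally more
#' extirpation and introduction than continental regions. Globally extinct
#' species are extirpated wherever they were native (by definition they
#' persist nowhere) and are never introduced or colonists. Every
#' extirpated, non-regained species that is globally extant — or extinct
#' with a surrogate — is marked `FUTURE_POTENTIAL` for that region. The
#' BP8000/Y2020 set identity of the status algebra holds by construction.
#'
#' @param config a [simulationConfig()].
#' @param species a [SpeciesTable-class] (typically from [simulateTraits()]).
#' @return list with elements `status` ([StatusTable-class]) and `regions`
#'   ([RegionTable-class]).
#' @export
simulateStatus <- function(config, species) {
  sp <- speciesData(species)
  n <- nrow(sp)
  withSeed(config$seed + 3L, {
    nr <- config$n_regions
    island <- runif(nr) < config$island_fraction
    regions <- data.frame(
      region_id = sprintf("r%02d", seq_len(nr)),
      name = paste0(ifelse(island, "Island ", "Mainland "), seq_len(nr)),
      island = island, stringsAsFactors = FALSE)
    rows <- vector("list", nr)
    for (r in seq_len(nr)) {
      isl <- island[r]
      meanRich <- if (isl) config$meanRichnessIsland else
        config$meanRichnessContinental
      rich <- round(rnorm(1, meanRich, 0.25 * meanRich))
      rich <- max(6, min(n - 5, rich))
      natives <- sample(sp$species_id, rich)
      extinctHere <- sp$globally_extinct[match(natives, sp$species_id)]
      pExt <- if (isl) config$pExtIsland else config$pExtContinental
      lost <- extinctHere | runif(rich) < pExt
      pReg <- if (isl) config$pRegainIsland else config$pRegainContinental
      regained <- lost & !extinctHere & runif(rich) < pReg
      category <- ifelse(!lost, "NATIVE_PERSISTING",
                         ifelse(regained, "NATIVE_REGAINED",
                                "NATIVE_EXTIRPATED"))
      outside <- setdiff(sp$species_id[!sp$globally_extinct], natives)
      meanIntro <- if (isl) config$meanIntroIsland else
        config$meanIntroContinental
      nIntro <- min(length(outside), stats::rpois(1, meanIntro))
      introduced <- sample(outside, nIntro)
      outside <- setdiff(outside, introduced)
      nCol <- min(length(outside), stats::rpois(1, config$meanColonist))
      colonists <- sample(outside, nCol)
      df <- data.frame(
        species_id = c(natives, introduced, colonists),
        region_id = regions$region_id[r],
        category = c(category, rep("INTRODUCED", nIntro),
                     rep("NATIVE_COLONIST", nCol)),
        stringsAsFactors = FALSE)
      df$recent <- ifelse(df$category == "NATIVE_PERSISTING", NA,
                          runif(nrow(df)) < config$pRecent)
      restorable <- natives[lost & !regained &
                              (!extinctHere |
                                 sp$surrogate_available[match(natives,
                                                              sp$species_id)])]
      if (length(restorable))
        df <- rbind(df, data.frame(
          species_id = restorable, region_id = regions$region_id[r],
          category = "FUTURE_POTENTIAL", recent = NA,
          stringsAsFactors = FALSE))
      rows[[r]] <- df
    }
    list(status = StatusTable(do.call(rbind, rows)),
         regions = RegionTable(regions))
  })
}

#' Simulate a complete input bundle
#'
#' @param config a [simulationConfig()].
#' @return A validated [FaunalData-class].
#' @export
simulateFauna <- function(config) {
  species <- simulateTraits(config)
  st <- simulateStatus(config, species)
  FaunalData(species, st$status, st$regions, simulateTrees(config))
}

#' Deterministic continental fixture
#'
#' A single-region ("continent") bundle reproducing the published
#' continental counts: 228 species in total, 198 natives at 8000 BP of
#' which 17 were extirpated from the whole region (12 of them globally
#' extinct, 3 of those with living surrogates; the 5 globally extant ones
#' plus the 3 surrogates form the future-potential set), and 30 introduced
#' species, giving 211 species in 2020. Traits and a small tree ensemble
#' are generated under a fixed internal seed, so the fixture is fully
#' deterministic and independent of the caller's RNG state.
#'
#' @param n_trees number of trees in the fixture ensemble (default 10).
#' @return A validated [FaunalData-class].
#' @export
continentalFixture <- function(n_trees = 10) {
  cfg <- simulationConfig(n_species = 228, n_trees = n_trees, n_regions = 1,
                          nExtinct = 0, seed = 20220707L)
  species <- simulateTraits(cfg)
  df <- speciesData(species)
  ids <- df$species_id
  extirpated <- ids[1:17]        # extirpated Europe-wide, never regained
  extinct <- ids[1:12]           # the 12 global extinctions
  surrogates <- ids[1:3]         # extinct but survived by domestic descendants
  persisting <- ids[18:198]
  introduced <- ids[199:228]
  df$globally_extinct <- ids %in% extinct
  df$surrogate_available <- ids %in% surrogates
  species <- SpeciesTable(df)
  future <- c(surrogates, ids[13:17])  # restorable: surrogate or extant elsewhere
  status <- StatusTable(data.frame(
    species_id = c(persisting, extirpated, introduced, future),
    region_id = "continent",
    category = c(rep("NATIVE_PERSISTING", length(persisting)),
                 rep("NATIVE_EXTIRPATED", length(extirpated)),
                 rep("INTRODUCED", length(introduced)),
                 rep("FUTURE_POTENTIAL", length(future))),
    recent = c(rep(NA, length(persisting)),
               rep(FALSE, length(extirpated)),
               rep(seq_along(introduced) %% 2 == 0),
               rep(NA, length(future))),
    stringsAsFactors = FALSE))
  regions <- RegionTable(data.frame(region_id = "continent",
                                    name = "Whole continent", island = FALSE,
                                    stringsAsFactors = FALSE))
  FaunalData(species, status, regions, simulateTrees(cfg))
}
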