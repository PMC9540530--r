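#' Status categories and timepoints
#'
#' The five historic status categories record what happened to a species in
#' a region between 8000 BP and 2020; `FUTURE_POTENTIAL` is an overlay
#' marking species that could be restored to a region (extirpated species
#' still extant elsewhere, or globally extinct species with a living
#' surrogate such as a domestic descendant).
#'
#' @return Character vector of category (or timepoint) names.
#' @export
statusCategories <- function() {
  c("NATIVE_PERSISTING", "NATIVE_EXTIRPATED", "NATIVE_REGAINED",
    "NATIVE_COLONIST", "INTRODUCED", "FUTURE_POTENTIAL")
}

#' @rdname statusCategories
#' @export
timepoints <- function() c("BP8000", "Y1945", "Y2020", "FUTURE")

dietColumns <- function() {
  c("diet_inv", "diet_vert", "diet_fish", "diet_scav",
    "diet_fruit", "diet_seed", "diet_plant")
}

activityColumns <- function() c("act_nocturnal", "act_crepuscular", "act_diurnal")

speciesTableColumns <- function() {
  c("species_id", "name", "mass_g", dietColumns(), "foraging_stratum",
    activityColumns(), "habitat_flags", "volant", "globally_extinct",
    "surrogate_available")
}

# ---- SpeciesTable -----------------------------------------------------------

#' SpeciesTable: the species trait table
#'
#' One row per species: body mass (g), seven diet-category percentages
#' summing to 100, a foraging-stratum label, three activity-period flags
#' (at least one set), semicolon-separated habitat flags, and booleans for
#' volancy, global extinction, and surrogate availability.
#'
#' @slot data data.frame with the columns of `speciesTableColumns()`.
#' @export
setClass("SpeciesTable", representation(data = "data.frame"))

setValidity("SpeciesTable", function(object) {
  df <- object@data
  msg <- character()
  missing <- setdiff(speciesTableColumns(), names(df))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(df$species_id))
    msg <- c(msg, "duplicated species_id")
  if (nrow(df)) {
    if (any(!is.finite(df$mass_g)) || any(df$mass_g <= 0))
      msg <- c(msg, "mass_g must be positive and finite")
    dietSum <- rowSums(df[dietColumns()])
    if (any(abs(dietSum - 100) > 1e-6))
      msg <- c(msg, "diet percentages must sum to 100 (tolerance 1e-6)")
    if (any(df[dietColumns()] < 0))
      msg <- c(msg, "diet percentages must be non-negative")
    act <- as.matrix(df[activityColumns()])
    if (any(rowSums(act) < 1))
      msg <- c(msg, "each species needs at least one activity flag")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a SpeciesTable
#'
#' @param data data.frame with the documented columns.
#' @return A validated [SpeciesTable-class] object.
#' @export
SpeciesTable <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c(activityColumns(), "volant", "globally_extinct",
                "surrogate_available"))
    if (col %in% names(data)) data[[col]] <- as.logical(data[[col]])
  new("SpeciesTable", data = data)
}

# ---- StatusTable ------------------------------------------------------------

#' StatusTable: per-region species status records
#'
#' One row per (species, region) event. The five historic categories are
#' mutually exclusive per (species, region); `FUTURE_POTENTIAL` rows form a
#' separate overlay (a future-restorable species is typically also recorded
#' as `NATIVE_EXTIRPATED` for the same region). `recent` dichotomizes change
#' events at 1945 (TRUE = 1945 or later) and is `NA` exactly for
#' `NATIVE_PERSISTING` and `FUTURE_POTENTIAL` rows, which record no event.
#'
#' @slot data data.frame with columns species_id, region_id, category, recent.
#' @export
setClass("StatusTable", representation(data = "data.frame"))

setValidity("StatusTable", function(object) {
  df <- object@data
  msg <- character()
  need <- c("species_id", "region_id", "category", "recent")
  missing <- setdiff(need, names(df))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  bad <- setdiff(unique(df$category), statusCategories())
  if (length(bad))
    msg <- c(msg, paste("unknown categories:", paste(bad, collapse = ", ")))
  future <- df$category == "FUTURE_POTENTIAL"
  key <- paste(df$species_id, df$region_id)
  if (anyDuplicated(key[!future]))
    msg <- c(msg, "duplicate (species, region) among historic records")
  if (anyDuplicated(key[future]))
    msg <- c(msg, "duplicate (species, region) among FUTURE_POTENTIAL records")
  noEvent <- df$category %in% c("NATIVE_PERSISTING", "FUTURE_POTENTIAL")
  if (any(!is.na(df$recent[noEvent])))
    msg <- c(msg, "recent must be NA for NATIVE_PERSISTING and FUTURE_POTENTIAL")
  if (any(is.na(df$recent[!noEvent])))
    msg <- c(msg, "recent must be set for change-event categories")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a StatusTable
#' @param data data.frame with columns species_id, region_id, category, recent.
#' @return A validated [StatusTable-class] object.
#' @export
StatusTable <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if ("recent" %in% names(data)) data$recent <- as.logical(data$recent)
  new("StatusTable", data = data)
}

# ---- RegionTable ------------------------------------------------------------

#' RegionTable: region metadata
#' @slot data data.frame with columns region_id, name, island (logical).
#' @export
setClass("RegionTable", representation(data = "data.frame"))

setValidity("RegionTable", function(object) {
  df <- object@data
  missing <- setdiff(c("region_id", "name", "island"), names(df))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(df$region_id)) return("duplicated region_id")
  TRUE
})

#' Construct a RegionTable
#' @param data data.frame with columns region_id, name, island.
#' @return A validated [RegionTable-class] object.
#' @export
RegionTable <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if ("island" %in% names(data)) data$island <- as.logical(data$island)
  new("RegionTable", data = data)
}

# ---- TreeEnsemble -----------------------------------------------------------

#' TreeEnsemble: an ordered ensemble of dated trees on one tip set
#'
#' Wraps an `ape` multiPhylo list; all trees must share the same tip-label
#' set (tip order and topology may differ, as across posterior samples) and
#' have non-negative branch lengths.
#'
#' @slot trees list of `phylo` objects.
#' @export
setClass("TreeEnsemble", representation(trees = "list"))

setValidity("TreeEnsemble", function(object) {
  trs <- object@trees
  if (!length(trs)) return("ensemble is empty")
  if (!all(vapply(trs, inherits, logical(1), "phylo")))
    return("all elements must be ape 'phylo' trees")
  ref <- sort(trs[[1]]$tip.label)
  for (i in seq_along(trs)) {
    tr <- trs[[i]]
    if (anyDuplicated(tr$tip.label))
      return(sprintf("tree %d has duplicated tip labels", i))
    if (!identical(sort(tr$tip.label), ref))
      return(sprintf("tree %d has a different tip set", i))
    if (is.null(tr$edge.length) || any(tr$edge.length < 0))
      return(sprintf("tree %d has missing or negative branch lengths", i))
  }
  TRUE
})

#' Construct a TreeEnsemble
#' @param trees a `multiPhylo`, list of `phylo`, or single `phylo`.
#' @return A validated [TreeEnsemble-class] object.
#' @export
TreeEnsemble <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  new("TreeEnsemble", trees = unclass(trees))
}

# ---- TraitSpace -------------------------------------------------------------

#' TraitSpace: species coordinates on retained principal-coordinate axes
#'
#' @slot species_ids character vector, row order of `coordinates`.
#' @slot coordinates n x k numeric matrix of PCoA coordinates.
#' @slot eigenvalues the k retained (positive, non-increasing) eigenvalues.
#' @slot varianceRepresented fraction of positive-eigenvalue variance kept.
#' @slot globalVolume convex-hull volume of all species (the FRic denominator).
#' @export
setClass("TraitSpace", representation(
  species_ids = "character",
  coordinates = "matrix",
  eigenvalues = "numeric",
  varianceRepresented = "numeric",
  globalVolume = "numeric"))

setValidity("TraitSpace", function(object) {
  n <- length(object@species_ids)
  k <- ncol(object@coordinates)
  msg <- character()
  if (nrow(object@coordinates) != n)
    msg <- c(msg, "coordinates rows must match species_ids")
  if (length(object@eigenvalues) != k)
    msg <- c(msg, "one eigenvalue per retained axis")
  if (k >= n) msg <- c(msg, "k must be smaller than the number of species")
  if (any(object@eigenvalues <= 0))
    msg <- c(msg, "retained eigenvalues must be strictly positive")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

# ---- FaunalData -------------------------------------------------------------

#' FaunalData: a complete input bundle
#'
#' @slot species [SpeciesTable-class]
#' @slot status [StatusTable-class]
#' @slot regions [RegionTable-class]
#' @slot trees [TreeEnsemble-class]
#' @export
setClass("FaunalData", representation(
  species = "SpeciesTable",
  status = "StatusTable",
  regions = "RegionTable",
  trees = "TreeEnsemble"))

setValidity("FaunalData", function(object) {
  sp <- speciesIds(object@species)
  msg <- character()
  badSp <- setdiff(unique(object@status@data$species_id), sp)
  if (length(badSp))
    msg <- c(msg, paste("status records cite unknown species:",
                        paste(badSp, collapse = ", ")))
  badRg <- setdiff(unique(object@status@data$region_id),
                   object@regions@data$region_id)
  if (length(badRg))
    msg <- c(msg, paste("status records cite unknown regions:",
                        paste(badRg, collapse = ", ")))
  tipSet <- sort(object@trees@trees[[1]]$tip.label)
  if (!identical(sort(sp), tipSet))
    msg <- c(msg, "tree tip set must equal the species table")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a FaunalData bundle
#' @param species,status,regions,trees the four component objects.
#' @return A validated [FaunalData-class] object.
#' @export
FaunalData <- function(species, status, regions, trees) {
  new("FaunalData", species = species, status = status,
      regions = regions, trees = trees)
}

# ---- RegionalAssemblage -----------------------------------------------------

#' RegionalAssemblage: the species set of one region at one timepoint
#' @slot region_id region identifier.
#' @slot timepoint one of `timepoints()`.
#' @slot species_ids character vector of member species.
#' @export
setClass("RegionalAssemblage", representation(
  region_id = "character", timepoint = "character", species_ids = "character"))
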