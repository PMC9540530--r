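# Status-category algebra: turning per-(species, region) status records into
# species sets at each timepoint and into loss/gain sets.

statusForRegion <- function(status, region) {
  df <- if (is(status, "StatusTable")) status@data else
    if (is(status, "FaunalData")) status@status@data else
      as.data.frame(status)
  df[df$region_id == region, , drop = FALSE]
}

#' Assemble the species set of a region at a timepoint
#'
#' Membership is derived from status categories:
#' \describe{
#'   \item{BP8000}{natives present at the baseline: persisting, extirpated,
#'     and regained species.}
#'   \item{Y2020}{persisting and regained natives, natural colonists, and
#'     introduced species.}
#'   \item{Y1945}{the baseline set minus losses completed before 1945 and
#'     not yet regained, plus gains completed before 1945. Concretely:
#'     persisting natives, extirpations with `recent = TRUE` (loss after
#'     1945, so still present in 1945), regains with `recent = FALSE`
#'     (back by 1945), and colonists/introductions with `recent = FALSE`.
#'     For a regained species the `recent` flag dates the regain; its loss
#'     is taken to precede 1945 when the regain is recent.}
#'   \item{FUTURE}{the 2020 set plus the `FUTURE_POTENTIAL` overlay.}
#' }
#'
#' @param status a [StatusTable-class], [FaunalData-class], or data.frame of
#'   status records.
#' @param region region identifier (must occur in the records, unless the
#'   record set is empty).
#' @param timepoint one of `timepoints()`.
#' @param knownRegions optional character vector of valid region ids
#'   (checked when `status` carries no region table).
#' @return A [RegionalAssemblage-class].
#' @export
assemble <- function(status, region, timepoint, knownRegions = NULL) {
  if (!timepoint %in% timepoints())
    stop("unknown timepoint: ", timepoint)
  if (is(status, "FaunalData")) knownRegions <- regionIds(status)
  if (!is.null(knownRegions) && !region %in% knownRegions)
    stop("unknown region: ", region)
  df <- statusForRegion(status, region)
  if (anyDuplicated(paste(df$species_id, df$region_id, df$category != "FUTURE_POTENTIAL")))
    stop("duplicate (species, region) records for region ", region)
  cat_ <- df$category
  ids <- switch(timepoint,
    BP8000 = df$species_id[cat_ %in% c("NATIVE_PERSISTING", "NATIVE_EXTIRPATED",
                                       "NATIVE_REGAINED")],
    Y2020 = df$species_id[cat_ %in% c("NATIVE_PERSISTING", "NATIVE_REGAINED",
                                      "NATIVE_COLONIST", "INTRODUCED")],
    Y1945 = df$species_id[
      cat_ == "NATIVE_PERSISTING" |
      (cat_ == "NATIVE_EXTIRPATED" & df$recent) |
      (cat_ %in% c("NATIVE_REGAINED", "NATIVE_COLONIST", "INTRODUCED") &
         !df$recent)],
    FUTURE = union(
      df$species_id[cat_ %in% c("NATIVE_PERSISTING", "NATIVE_REGAINED",
                                "NATIVE_COLONIST", "INTRODUCED")],
      df$species_id[cat_ == "FUTURE_POTENTIAL"]))
  new("RegionalAssemblage", region_id = region, timepoint = timepoint,
      species_ids = sort(unique(ids)))
}

#' Loss and gain sets of a region
#'
#' The loss set holds every species removed from the baseline pool at some
#' point (extirpated, plus regained species, which were lost before
#' returning); the gain set holds every species added to the 2020 pool
#' (regained, colonist, introduced). A regained species appears in both, so
#' that `(BP8000 \ loss) U gain = Y2020` holds exactly and the loss/gain
#' decomposition is additive.
#'
#' @inheritParams assemble
#' @return list with character vectors `loss` and `gain`.
#' @export
lossGainSets <- function(status, region, knownRegions = NULL) {
  if (is(status, "FaunalData")) knownRegions <- regionIds(status)
  if (!is.null(knownRegions) && !region %in% knownRegions)
    stop("unknown region: ", region)
  df <- statusForRegion(status, region)
  list(
    loss = sort(unique(df$species_id[
      df$category %in% c("NATIVE_EXTIRPATED", "NATIVE_REGAINED")])),
    gain = sort(unique(df$species_id[
      df$category %in% c("NATIVE_REGAINED", "NATIVE_COLONIST", "INTRODUCED")])))
}

#' Future-potential set of a region
#'
#' Species in the `FUTURE_POTENTIAL` overlay: regionally extirpated species
#' still extant elsewhere, or globally extinct species with a living
#' surrogate whose traits and phylogenetic position stand in for the
#' ancestor's.
#'
#' @inheritParams assemble
#' @param species optional [SpeciesTable-class] used to verify that every
#'   future-potential species resolves to usable traits (globally extinct
#'   species must have `surrogate_available`).
#' @return character vector of species ids.
#' @export
futureSet <- function(status, region, species = NULL) {
  if (is(status, "FaunalData") && is.null(species)) species <- status@species
  df <- statusForRegion(status, region)
  fut <- sort(unique(df$species_id[df$category == "FUTURE_POTENTIAL"]))
  if (!is.null(species) && length(fut)) {
    sp <- speciesData(species)
    idx <- match(fut, sp$species_id)
    if (anyNA(idx))
      stop("future-potential species missing from species table: ",
           paste(fut[is.na(idx)], collapse = ", "))
    bad <- fut[sp$globally_extinct[idx] & !sp$surrogate_available[idx]]
    if (length(bad))
      stop("future-potential species globally extinct with no surrogate: ",
           paste(bad, collapse = ", "))
  }
  fut
}

#' Filter species by mass/volancy subgroup
#'
#' `large_nonvolant` keeps non-volant species strictly heavier than 2 kg;
#' `small_nonvolant` keeps non-volant species of 2 kg or less, so the two
#' groups partition the non-volant species; `all` is the identity.
#'
#' @param species a [SpeciesTable-class] or its data.frame.
#' @param group one of `"all"`, `"large_nonvolant"`, `"small_nonvolant"`.
#' @return character vector of species ids in the subgroup.
#' @export
subgroupFilter <- function(species, group = c("all", "large_nonvolant",
                                              "small_nonvolant")) {
  group <- match.arg(group)
  df <- if (is(species, "SpeciesTable")) species@data else
    if (is(species, "FaunalData")) speciesData(species) else
      as.data.frame(species)
  if (group == "all") return(df$species_id)
  if (anyNA(df$mass_g))
    stop("missing mass for species: ",
         paste(df$species_id[is.na(df$mass_g)], collapse = ", "))
  keep <- if (group == "large_nonvolant") df$mass_g > 2000 & !df$volant
          else df$mass_g <= 2000 & !df$volant
  df$species_id[keep]
}
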