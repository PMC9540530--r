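# Accessors and show methods for the core classes.

#' Accessors for faunadiv classes
#'
#' `speciesIds` returns the species identifiers of an object; `nSpecies`
#' counts them; `regionIds` lists region identifiers; `traitCoordinates`
#' extracts PCoA coordinates (optionally for a subset of species);
#' `treeList` unwraps a [TreeEnsemble-class] as an `ape` multiPhylo.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesIds", function(x, ...) standardGeneric("speciesIds"))

#' @rdname accessors
#' @export
setMethod("speciesIds", "SpeciesTable", function(x, ...) x@data$species_id)

#' @rdname accessors
#' @export
setMethod("speciesIds", "TraitSpace", function(x, ...) x@species_ids)

#' @rdname accessors
#' @export
setMethod("speciesIds", "RegionalAssemblage", function(x, ...) x@species_ids)

#' @rdname accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname accessors
#' @export
setMethod("nSpecies", "SpeciesTable", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("nSpecies", "RegionalAssemblage", function(x) length(x@species_ids))

#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname accessors
#' @export
setMethod("regionIds", "RegionTable", function(x) x@data$region_id)

#' @rdname accessors
#' @export
setMethod("regionIds", "FaunalData", function(x) x@regions@data$region_id)

#' @rdname accessors
#' @param species optional character vector of species to extract.
#' @export
setGeneric("traitCoordinates",
           function(x, species = NULL) standardGeneric("traitCoordinates"))

#' @rdname accessors
#' @export
setMethod("traitCoordinates", "TraitSpace", function(x, species = NULL) {
  co <- x@coordinates
  rownames(co) <- x@species_ids
  if (is.null(species)) return(co)
  missing <- setdiff(species, x@species_ids)
  if (length(missing))
    stop("species missing from trait space: ", paste(missing, collapse = ", "))
  co[species, , drop = FALSE]
})

#' @rdname accessors
#' @export
setGeneric("treeList", function(x) standardGeneric("treeList"))

#' @rdname accessors
#' @export
setMethod("treeList", "TreeEnsemble", function(x) {
  trs <- x@trees
  class(trs) <- "multiPhylo"
  trs
})

#' @rdname accessors
#' @export
setGeneric("statusData", function(x) standardGeneric("statusData"))

#' @rdname accessors
#' @export
setMethod("statusData", "StatusTable", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("statusData", "FaunalData", function(x) x@status@data)

#' @rdname accessors
#' @export
setGeneric("speciesData", function(x) standardGeneric("speciesData"))

#' @rdname accessors
#' @export
setMethod("speciesData", "SpeciesTable", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("speciesData", "FaunalData", function(x) x@species@data)

#' @rdname accessors
#' @export
setGeneric("regionData", function(x) standardGeneric("regionData"))

#' @rdname accessors
#' @export
setMethod("regionData", "RegionTable", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("regionData", "FaunalData", function(x) x@regions@data)

# ---- show methods -----------------------------------------------------------

setMethod("show", "SpeciesTable", function(object) {
  df <- object@data
  cat(sprintf("SpeciesTable: %d species (%d volant, %d globally extinct)\n",
              nrow(df), sum(df$volant), sum(df$globally_extinct)))
})

setMethod("show", "StatusTable", function(object) {
  df <- object@data
  cat(sprintf("StatusTable: %d records, %d regions\n",
              nrow(df), length(unique(df$region_id))))
  print(table(df$category))
})

setMethod("show", "RegionTable", function(object) {
  df <- object@data
  cat(sprintf("RegionTable: %d regions (%d islands, %d continental)\n",
              nrow(df), sum(df$island), sum(!df$island)))
})

setMethod("show", "TreeEnsemble", function(object) {
  cat(sprintf("TreeEnsemble: %d trees on %d shared tips\n",
              length(object@trees), length(object@trees[[1]]$tip.label)))
})

setMethod("show", "TraitSpace", function(object) {
  cat(sprintf(
    "TraitSpace: %d species on %d axes (%.1f%% of positive variance)\n",
    length(object@species_ids), ncol(object@coordinates),
    100 * object@varianceRepresented))
  cat(sprintf("global hull volume: %.4g\n", object@globalVolume))
})

setMethod("show", "FaunalData", function(object) {
  cat("FaunalData bundle\n")
  show(object@species); show(object@regions); show(object@trees)
})

setMethod("show", "RegionalAssemblage", function(object) {
  cat(sprintf("RegionalAssemblage: %s @ %s, %d species\n",
              object@region_id, object@timepoint, length(object@species_ids)))
})
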