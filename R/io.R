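# Readers and writers for the package's file formats.
#
# CSV dialect: UTF-8, comma-separated, mandatory header row, "." decimal.
# Missing metric values are serialized as empty fields, never 0. Newick
# ensembles are one tree per line with mandatory branch lengths.

checkHeader <- function(path, expected) {
  got <- names(utils::read.csv(path, nrows = 0, check.names = FALSE))
  if (!identical(got, expected))
    stop(sprintf("malformed header in %s: expected '%s', found '%s'",
                 path, paste(expected, collapse = ","),
                 paste(got, collapse = ",")))
}

#' Read and write the species trait table
#'
#' @param path CSV file path.
#' @return `readSpeciesTable` returns a [SpeciesTable-class].
#' @export
readSpeciesTable <- function(path) {
  checkHeader(path, speciesTableColumns())
  df <- utils::read.csv(path, colClasses = c(
    species_id = "character", name = "character", habitat_flags = "character",
    foraging_stratum = "character"))
  df$habitat_flags[is.na(df$habitat_flags)] <- ""
  SpeciesTable(df)
}

#' @rdname readSpeciesTable
#' @param x the object to write.
#' @export
writeSpeciesTable <- function(x, path) {
  utils::write.csv(x@data[speciesTableColumns()], path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read and write the status table
#' @inheritParams readSpeciesTable
#' @return `readStatusTable` returns a [StatusTable-class].
#' @export
readStatusTable <- function(path) {
  checkHeader(path, c("species_id", "region_id", "category", "recent"))
  df <- utils::read.csv(path, colClasses = c(
    species_id = "character", region_id = "character",
    category = "character", recent = "logical"))
  StatusTable(df)
}

#' @rdname readStatusTable
#' @param x the object to write.
#' @export
writeStatusTable <- function(x, path) {
  utils::write.csv(x@data[c("species_id", "region_id", "category", "recent")],
                   path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read and write the region table
#' @inheritParams readSpeciesTable
#' @return `readRegionTable` returns a [RegionTable-class].
#' @export
readRegionTable <- function(path) {
  checkHeader(path, c("region_id", "name", "island"))
  df <- utils::read.csv(path, colClasses = c(
    region_id = "character", name = "character", island = "logical"))
  RegionTable(df)
}

#' @rdname readRegionTable
#' @param x the object to write.
#' @export
writeRegionTable <- function(x, path) {
  utils::write.csv(x@data[c("region_id", "name", "island")], path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read and write a multi-tree Newick ensemble
#'
#' One tree per line; every tip must be labelled and every branch must have
#' a length.
#'
#' @inheritParams readSpeciesTable
#' @return `readTreeEnsemble` returns a [TreeEnsemble-class].
#' @export
readTreeEnsemble <- function(path) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no trees parsed from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (any(!nzchar(tr$tip.label)) || anyNA(tr$tip.label))
      stop(sprintf("%s: tree %d has unlabelled tips", path, i))
    if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge))
      stop(sprintf("%s: tree %d is missing branch lengths", path, i))
  }
  TreeEnsemble(trees)
}

#' @rdname readTreeEnsemble
#' @param x the object to write.
#' @export
writeTreeEnsemble <- function(x, path) {
  ape::write.tree(treeList(x), path)
  invisible(path)
}

#' Read a complete input bundle
#'
#' @param speciesPath,statusPath,regionsPath,treesPath file paths.
#' @return A validated [FaunalData-class].
#' @export
readFaunalData <- function(speciesPath, statusPath, regionsPath, treesPath) {
  FaunalData(readSpeciesTable(speciesPath), readStatusTable(statusPath),
             readRegionTable(regionsPath), readTreeEnsemble(treesPath))
}

#' Write a complete input bundle
#'
#' @param x a [FaunalData-class].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
writeFaunalData <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(species = file.path(dir, "species.csv"),
             status = file.path(dir, "status.csv"),
             regions = file.path(dir, "regions.csv"),
             trees = file.path(dir, "trees.nwk"))
  writeSpeciesTable(x@species, paths[["species"]])
  writeStatusTable(x@status, paths[["status"]])
  writeRegionTable(x@regions, paths[["regions"]])
  writeTreeEnsemble(x@trees, paths[["trees"]])
  invisible(paths)
}

#' Export / import a dissimilarity matrix as square CSV
#'
#' Species ids form both the header row and the first column.
#'
#' @param D symmetric matrix with species-id dimnames.
#' @param path CSV file path.
#' @export
writeDissimilarity <- function(D, path) {
  df <- data.frame(species_id = rownames(D), D, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDissimilarity
#' @export
readDissimilarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(species_id = "character"))
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df$species_id
  if (!identical(rownames(D), colnames(D)))
    stop("row and column species ids disagree in ", path)
  D
}
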