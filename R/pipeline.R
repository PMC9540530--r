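# Per-region, per-timepoint diversity, the loss/gain/net decomposition,
# future-reintroduction scenarios, hull-occupancy overlap, and cross-region
# summaries.
#
# All three metrics are scaled to [0, 1] against the full species pool:
# richness by the pool size, phylogenetic diversity by each tree's total
# branch length, functional richness by the all-species hull volume. The
# denominators stay global also in subgroup runs, so subgroup values remain
# comparable with the main analysis.

metricNames <- function() c("richness", "pd", "fric")

#' Scaled species richness
#'
#' @param tips character vector (or count) of species present.
#' @param total size of the full species pool.
#' @return `length(tips) / total`.
#' @export
richnessScaled <- function(tips, total) {
  if (total <= 0) stop("total species count must be positive")
  n <- if (is.numeric(tips) && length(tips) == 1) tips else length(tips)
  n / total
}

# Metric evaluator factory: returns D(speciesSet) for one metric, sharing
# the trait-space / ensemble context. NA is returned where fric is
# undefined (|S| <= k or degenerate cloud).
metricEvaluator <- function(data, traitSpace, metric = metricNames()) {
  metric <- match.arg(metric)
  total <- nSpecies(data@species)
  switch(metric,
    richness = function(tips) richnessScaled(tips, total),
    pd = function(tips) scaledPD(data@trees, tips)$mean,
    fric = function(tips) {
      if (length(tips) == 0) return(NA_real_)
      sub <- traitCoordinates(traitSpace, tips)
      h <- convexHull(sub)
      if (!h$defined) return(NA_real_)
      h$volume / traitSpace@globalVolume
    })
}

assemblageTips <- function(data, region, timepoint, subgroup = "all") {
  tips <- speciesIds(assemble(data, region, timepoint))
  if (subgroup != "all") tips <- intersect(tips, subgroupFilter(data, subgroup))
  tips
}

#' All three scaled diversity metrics for one region and timepoint
#'
#' @param data a [FaunalData-class] bundle.
#' @param region region id.
#' @param timepoint one of `timepoints()`.
#' @param traitSpace a [TraitSpace-class] built on the full species table.
#' @param subgroup `"all"`, `"large_nonvolant"`, or `"small_nonvolant"`;
#'   restricts the assemblage before computing all metrics.
#' @return One-row data.frame with columns region_id, timepoint, subgroup,
#'   n_species, richness_scaled, pd_scaled, pd_sd, fric_scaled.
#'   `fric_scaled` is `NA` when the assemblage does not exceed the axis
#'   count (the hull is then undefined, not zero).
#' @export
regionDiversity <- function(data, region, timepoint, traitSpace,
                            subgroup = "all") {
  tips <- assemblageTips(data, region, timepoint, subgroup)
  missingTree <- setdiff(tips, data@trees@trees[[1]]$tip.label)
  missingTrait <- setdiff(tips, speciesIds(traitSpace))
  if (length(missingTree) || length(missingTrait))
    stop("species missing from tree/trait inputs: ",
         paste(union(missingTree, missingTrait), collapse = ", "))
  total <- nSpecies(data@species)
  pd <- scaledPD(data@trees, tips)
  fric <- metricEvaluator(data, traitSpace, "fric")(tips)
  data.frame(region_id = region, timepoint = timepoint, subgroup = subgroup,
             n_species = length(tips),
             richness_scaled = richnessScaled(tips, total),
             pd_scaled = pd$mean, pd_sd = pd$sd, fric_scaled = fric,
             stringsAsFactors = FALSE)
}

#' Loss/gain/net decomposition of one region's diversity change
#'
#' With S0 the 8000 BP set, Sp = S0 minus the loss set, and S1 the 2020
#' set: `loss = D(Sp) - D(S0)` (losses applied first, following the
#' narrative sequence losses-then-gains), `gain = D(S1) - D(Sp)`, and
#' `net = loss + gain`, which equals `D(S1) - D(S0)` because D(Sp) is
#' evaluated once and shared. For the fric metric the decomposition is
#' `NA` whenever any of the three sets has an undefined hull.
#'
#' @inheritParams regionDiversity
#' @param metric one of `"richness"`, `"pd"`, `"fric"`.
#' @return One-row data.frame with columns region_id, metric, loss
#'   (<= 0), gain (>= 0), net.
#' @export
decomposeChange <- function(data, region, traitSpace,
                            metric = metricNames(), subgroup = "all") {
  metric <- match.arg(metric)
  sub <- if (subgroup == "all") NULL else subgroupFilter(data, subgroup)
  restrict <- function(x) if (is.null(sub)) x else intersect(x, sub)
  s0 <- restrict(speciesIds(assemble(data, region, "BP8000")))
  s1 <- restrict(speciesIds(assemble(data, region, "Y2020")))
  lg <- lossGainSets(data, region)
  sp <- setdiff(s0, restrict(lg$loss))
  stopifnot(setequal(union(sp, restrict(lg$gain)), s1))
  if (metric == "richness") {
    # single division of the signed count difference, so the richness
    # decomposition equals set cardinalities / total exactly
    total <- nSpecies(data@species)
    loss <- (length(sp) - length(s0)) / total
    gain <- (length(s1) - length(sp)) / total
  } else {
    D <- metricEvaluator(data, traitSpace, metric)
    d0 <- D(s0); dp <- D(sp); d1 <- D(s1)
    loss <- dp - d0
    gain <- d1 - dp
  }
  data.frame(region_id = region, metric = metric,
             loss = loss, gain = gain, net = loss + gain,
             stringsAsFactors = FALSE)
}

#' Diversity gain from future reintroductions
#'
#' For each metric, `D(Y2020 + future set) - D(Y2020)`, where the future
#' set holds the region's restorable species (extirpated but globally
#' extant, or extinct with a living surrogate that carries the ancestor's
#' traits and tree position). Non-negative for richness and pd by
#' monotonicity; regions whose historic losses were all surrogate-less
#' global extinctions gain nothing.
#'
#' @inheritParams regionDiversity
#' @return data.frame with one row per metric: region_id, metric, gain.
#' @export
futureGain <- function(data, region, traitSpace, subgroup = "all") {
  s1 <- assemblageTips(data, region, "Y2020", subgroup)
  fut <- futureSet(data, region)
  if (subgroup != "all") fut <- intersect(fut, subgroupFilter(data, subgroup))
  sF <- union(s1, fut)
  rows <- lapply(metricNames(), function(m) {
    D <- metricEvaluator(data, traitSpace, m)
    data.frame(region_id = region, metric = m, gain = D(sF) - D(s1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Occupancy overlap between the 8000 BP and 2020 trait-space hulls
#'
#' Fraction of the functional space occupied at 8000 BP that is still
#' occupied in 2020 (hull intersection volume divided by the 8000 BP hull
#' volume).
#'
#' @inheritParams regionDiversity
#' @return Fraction in \[0, 1\], or `NA` (with a message) when either hull
#'   is undefined.
#' @export
occupancyOverlap <- function(data, region, traitSpace, subgroup = "all") {
  t0 <- assemblageTips(data, region, "BP8000", subgroup)
  t1 <- assemblageTips(data, region, "Y2020", subgroup)
  k <- ncol(traitSpace@coordinates)
  if (length(t0) <= k || length(t1) <= k) {
    message("occupancy overlap undefined for region ", region,
            ": assemblage not larger than axis count")
    return(NA_real_)
  }
  p0 <- traitCoordinates(traitSpace, t0)
  p1 <- traitCoordinates(traitSpace, t1)
  if (!convexHull(p0)$defined || !convexHull(p1)$defined) {
    message("occupancy overlap undefined for region ", region,
            ": degenerate hull")
    return(NA_real_)
  }
  hullOverlapFraction(p0, p1)
}

#' Mean body mass and diet composition of an assemblage
#'
#' @inheritParams regionDiversity
#' @return One-row data.frame: region_id, timepoint, n_species,
#'   mean_mass_g, and the mean of each diet-percentage column; all-`NA`
#'   metrics for an empty assemblage.
#' @export
assemblageProfiles <- function(data, region, timepoint, subgroup = "all") {
  tips <- assemblageTips(data, region, timepoint, subgroup)
  sp <- speciesData(data)
  rows <- sp[match(tips, sp$species_id), , drop = FALSE]
  out <- data.frame(region_id = region, timepoint = timepoint,
                    n_species = length(tips), stringsAsFactors = FALSE)
  if (length(tips) == 0) {
    out$mean_mass_g <- NA_real_
    for (dc in dietColumns()) out[[dc]] <- NA_real_
  } else {
    out$mean_mass_g <- mean(rows$mass_g)
    for (dc in dietColumns()) out[[dc]] <- mean(rows[[dc]])
  }
  out
}

#' Diversity table across regions and timepoints
#'
#' @inheritParams regionDiversity
#' @param timepointSet timepoints to evaluate (default 8000 BP and 2020).
#' @param overlap also compute the per-region 8000 BP vs 2020 hull overlap
#'   (column `overlap_8000_2020`, repeated on each of the region's rows).
#' @return data.frame, one row per region x timepoint.
#' @export
diversityTable <- function(data, traitSpace,
                           timepointSet = c("BP8000", "Y2020"),
                           subgroup = "all", overlap = TRUE) {
  rows <- list()
  for (r in regionIds(data)) {
    ov <- if (overlap) occupancyOverlap(data, r, traitSpace, subgroup)
          else NA_real_
    for (tp in timepointSet) {
      row <- regionDiversity(data, r, tp, traitSpace, subgroup)
      row$overlap_8000_2020 <- ov
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Decomposition table across regions and metrics
#'
#' @inheritParams decomposeChange
#' @return data.frame, one row per region x metric.
#' @export
decompositionTable <- function(data, traitSpace, subgroup = "all") {
  rows <- list()
  for (r in regionIds(data))
    for (m in metricNames())
      rows[[length(rows) + 1L]] <-
        decomposeChange(data, r, traitSpace, m, subgroup)
  do.call(rbind, rows)
}

#' Future-gain table across regions
#'
#' @inheritParams futureGain
#' @return data.frame, one row per region x metric.
#' @export
futureTable <- function(data, traitSpace, subgroup = "all") {
  do.call(rbind, lapply(regionIds(data), function(r)
    futureGain(data, r, traitSpace, subgroup)))
}

#' Cross-region summary of levels and net changes
#'
#' Per metric: how many regions increased / decreased / showed no change
#' (ties are exact zeros for richness and |net| < `tieTol` for the
#' continuous metrics), the median and range of net change, an island vs
#' continental breakdown, and pairwise Spearman and Pearson correlations
#' among metric levels and among net changes.
#'
#' @param decomposition output of [decompositionTable()].
#' @param diversity optional output of [diversityTable()]; enables the
#'   level correlations.
#' @param regions optional [RegionTable-class]; enables the island
#'   breakdown.
#' @param tieTol no-change tolerance for pd and fric nets (default 1e-9).
#' @return Nested list (JSON-serializable).
#' @export
summarizeRegions <- function(decomposition, diversity = NULL, regions = NULL,
                             tieTol = 1e-9) {
  out <- list()
  for (m in metricNames()) {
    d <- decomposition[decomposition$metric == m, ]
    net <- d$net[!is.na(d$net)]
    tol <- if (m == "richness") 0 else tieTol
    entry <- list(
      n_regions = length(net),
      increased = sum(net > tol),
      decreased = sum(net < -tol),
      no_change = sum(abs(net) <= tol),
      median_net = if (length(net)) median(net) else NA_real_,
      range_net = if (length(net)) range(net) else c(NA_real_, NA_real_))
    if (!is.null(regions)) {
      isl <- regionData(regions)$region_id[regionData(regions)$island]
      byClass <- split(d$net, ifelse(d$region_id %in% isl,
                                     "island", "continental"))
      entry$median_net_by_class <- lapply(byClass, function(x)
        median(x, na.rm = TRUE))
    }
    out[[m]] <- entry
  }
  nets <- do.call(cbind, lapply(metricNames(), function(m)
    decomposition$net[decomposition$metric == m]))
  colnames(nets) <- metricNames()
  keep <- stats::complete.cases(nets)
  out$net_correlations <- list(
    spearman = cor(nets[keep, , drop = FALSE], method = "spearman"),
    pearson = cor(nets[keep, , drop = FALSE], method = "pearson"))
  if (!is.null(diversity)) {
    lv <- diversity[, c("richness_scaled", "pd_scaled", "fric_scaled")]
    keep <- stats::complete.cases(lv)
    out$level_correlations <- list(
      spearman = cor(lv[keep, , drop = FALSE], method = "spearman"),
      pearson = cor(lv[keep, , drop = FALSE], method = "pearson"))
  }
  out
}

#' Run the full pipeline on a bundle
#'
#' Builds the trait space, then computes the diversity, decomposition, and
#' future tables and the cross-region summary.
#'
#' @inheritParams regionDiversity
#' @param k number of PCoA axes (default 5).
#' @param tieTol passed to [summarizeRegions()].
#' @param overlap compute per-region hull overlaps (the slowest step).
#' @return list with elements traitSpace, diversity, decomposition,
#'   future, summary.
#' @export
runPipeline <- function(data, k = 5, subgroup = "all", tieTol = 1e-9,
                        overlap = TRUE) {
  ts <- buildTraitSpace(data@species, k = k)
  div <- diversityTable(data, ts, subgroup = subgroup, overlap = overlap)
  dec <- decompositionTable(data, ts, subgroup = subgroup)
  fut <- futureTable(data, ts, subgroup = subgroup)
  list(traitSpace = ts, diversity = div, decomposition = dec, future = fut,
       summary = summarizeRegions(dec, div, data@regions, tieTol = tieTol))
}
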