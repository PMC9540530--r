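# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: PD by unioning edges on all pairwise tip-to-tip
# paths, hull volumes by rejection-sampling Monte Carlo, summaries by
# direct recomputation.

# Faith's PD oracle: union of the edges lying on any tip-to-tip path within
# the selected set (equivalently, the MRCA-rooted spanning subtree).
bruteForcePD <- function(tree, tips) {
  if (length(tips) <= 1) return(0)
  idx <- match(tips, tree$tip.label)
  stopifnot(!anyNA(idx))
  edges <- matrix(nrow = 0, ncol = 2)
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i >= j) next
    path <- ape::nodepath(tree, idx[i], idx[j])
    edges <- rbind(edges, cbind(path[-length(path)], path[-1]))
  }
  key <- apply(edges, 1, function(e) paste(sort(e), collapse = "-"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  total <- 0
  for (r in seq_len(nrow(edges))) {
    hit <- which((tree$edge[, 1] == edges[r, 1] & tree$edge[, 2] == edges[r, 2]) |
                 (tree$edge[, 1] == edges[r, 2] & tree$edge[, 2] == edges[r, 1]))
    total <- total + tree$edge.length[hit]
  }
  total
}

# Monte-Carlo hull volume: fraction of bounding-box samples inside the
# facet system times the box volume.
mcHullVolume <- function(points, nSamples = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- convexHull(points)
  stopifnot(h$defined)
  lo <- apply(points, 2, min); hi <- apply(points, 2, max)
  inside <- 0
  chunk <- 2e4
  done <- 0
  while (done < nSamples) {
    m <- min(chunk, nSamples - done)
    X <- sapply(seq_along(lo), function(j) runif(m, lo[j], hi[j]))
    inside <- inside + sum(insideHull(X, h))
    done <- done + m
  }
  inside / nSamples * prod(hi - lo)
}

# Monte-Carlo overlap fraction: of samples inside hull A, the fraction
# also inside hull B.
mcOverlapFraction <- function(pointsA, pointsB, nSamples = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hA <- convexHull(pointsA); hB <- convexHull(pointsB)
  stopifnot(hA$defined, hB$defined)
  lo <- apply(pointsA, 2, min); hi <- apply(pointsA, 2, max)
  inA <- 0; inBoth <- 0
  done <- 0
  while (done < nSamples) {
    m <- min(2e4, nSamples - done)
    X <- sapply(seq_along(lo), function(j) runif(m, lo[j], hi[j]))
    a <- insideHull(X, hA)
    inA <- inA + sum(a)
    if (any(a)) inBoth <- inBoth + sum(insideHull(X[a, , drop = FALSE], hB))
    done <- done + m
  }
  stopifnot(inA > 0)
  inBoth / inA
}

# The toy tree used in several tests: ((A:1,B:1):2,(C:3,D:1):1);
toyTree <- function() ape::read.tree(text = "((A:1,B:1):2,(C:3,D:1):1);")

# Small random Yule tree with relabelled tips.
randomTree <- function(ntips) {
  tr <- ape::rphylo(ntips, birth = 1, death = 0)
  tr$tip.label <- sample(paste0("t", seq_len(ntips)))
  tr
}

# A minimal valid species data.frame for data-model tests.
toySpecies <- function(ids, mass = 100, volant = FALSE) {
  n <- length(ids)
  diet <- matrix(0, n, 7, dimnames = list(NULL, dietColumns()))
  diet[, 1] <- 100
  data.frame(species_id = ids, name = ids, mass_g = rep_len(mass, n), diet,
             foraging_stratum = "ground", act_nocturnal = TRUE,
             act_crepuscular = FALSE, act_diurnal = FALSE,
             habitat_flags = "forest", volant = rep_len(volant, n),
             globally_extinct = FALSE, surrogate_available = FALSE,
             stringsAsFactors = FALSE)
}
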