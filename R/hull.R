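# Convex-hull functional richness (FRic) and hull-intersection occupancy
# overlap in k dimensions. The hull engine (src/convexhull.cpp) returns the
# facet half-spaces {x : n . x <= b} alongside the volume, which makes
# membership tests and polytope intersections cheap downstream.

affineRank <- function(points, tol = 1e-9) {
  centered <- sweep(points, 2, colMeans(points))
  sv <- svd(centered, nu = 0, nv = 0)$d
  sum(sv > tol * max(1, sv[1]))
}

#' Convex hull of a point cloud
#'
#' @param points n x k numeric matrix.
#' @return list with `defined` (FALSE when n <= k or the points are
#'   affinely degenerate, in which case no volume is reported), `volume`,
#'   `vertices` (row indices on the hull), and the facet half-spaces
#'   `normals` (f x k) and `offsets` (length f) with
#'   `normals %*% x <= offsets` inside.
#' @export
convexHull <- function(points) {
  points <- as.matrix(points)
  if (any(!is.finite(points))) stop("non-finite coordinates")
  n <- nrow(points); k <- ncol(points)
  if (k < 1) stop("need at least one dimension")
  undefined <- list(defined = FALSE, volume = NA_real_, vertices = integer(),
                    normals = NULL, offsets = NULL)
  if (n <= k) return(undefined)
  if (k == 1) {
    x <- points[, 1]
    if (diff(range(x)) <= 1e-12 * max(1, max(abs(x)))) return(undefined)
    return(list(defined = TRUE, volume = diff(range(x)),
                vertices = c(which.min(x), which.max(x)),
                normals = matrix(c(1, -1), 2, 1),
                offsets = c(max(x), -min(x)),
                facets = matrix(c(which.max(x), which.min(x)), 2, 1),
                interior = mean(range(x))))
  }
  if (affineRank(points) < k) return(undefined)
  res <- .qhull_cpp(points)
  list(defined = TRUE, volume = res$volume, vertices = res$vertices,
       normals = res$normals, offsets = as.numeric(res$offsets),
       facets = res$facets, interior = as.numeric(res$interior))
}

#' Convex-hull volume (functional richness)
#'
#' @inheritParams convexHull
#' @return list with `volume` (k-dimensional volume; `NA` when undefined),
#'   `vertices`, and `defined`. Following the dimensionality constraint of
#'   hull-based functional richness, the hull is undefined — not an error —
#'   when the number of points does not exceed the number of axes or the
#'   cloud is rank-deficient.
#' @export
hullVolume <- function(points) {
  h <- convexHull(points)
  list(volume = h$volume, vertices = h$vertices, defined = h$defined)
}

#' Functional richness scaled to the global hull
#'
#' Ratio of the subset's hull volume to the all-species hull volume, in
#' \[0, 1\]. Undefined subset hulls (too few species, or a degenerate
#' cloud) yield `NA` rather than 0, keeping "cannot be measured" distinct
#' from "no volume".
#'
#' @param subsetPoints,globalPoints coordinate matrices; the subset must
#'   use the same axes as the global cloud.
#' @return Numeric ratio, or `NA` when the subset hull is undefined.
#' @export
fricScaled <- function(subsetPoints, globalPoints) {
  g <- convexHull(globalPoints)
  if (!g$defined) stop("global hull undefined")
  s <- convexHull(subsetPoints)
  if (!s$defined) return(NA_real_)
  s$volume / g$volume
}

#' Test points against a hull's facet half-spaces
#'
#' @param points m x k matrix of query points.
#' @param hull a defined hull from [convexHull()].
#' @param tol slack added to each facet offset.
#' @return Logical vector: inside (or on) the hull.
#' @export
insideHull <- function(points, hull, tol = 1e-9) {
  if (!hull$defined) stop("hull undefined")
  points <- as.matrix(points)
  viol <- points %*% t(hull$normals) -
    matrix(hull$offsets, nrow(points), length(hull$offsets), byrow = TRUE)
  apply(viol <= tol, 1, all)
}

# Largest-margin feasible point of the half-space system A x <= b, found by
# scanning candidate points and polishing the best with Nelder-Mead on the
# (concave, piecewise-linear) minimum normalized slack. Any strictly
# feasible point is sufficient for the exact dual construction below; only
# the feasible/infeasible decision depends on this search.
interiorPoint <- function(A, b, candidates, tol) {
  norms <- sqrt(rowSums(A^2))
  slack <- function(x) min((b - as.numeric(A %*% x)) / norms)
  vals <- apply(candidates, 1, slack)
  best <- candidates[which.max(vals), ]
  for (i in 1:3) {
    opt <- stats::optim(best, function(x) -slack(x), method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    if (-opt$value <= slack(best) + tol * 1e-3) { best <- opt$par; break }
    best <- opt$par
  }
  if (slack(best) <= tol) return(NULL)
  best
}

# Volume of the bounded polytope P = {x : A x <= b} given a strictly
# interior point x0: translate x0 to the origin and polar-dualize each
# half-space a . x <= b' (b' > 0) to the point a / b'. In the dual hull,
# facets (simplices of d dual points) correspond to vertices of P
# (facet n . y <= c, c > 0, maps to vertex n / c), and dual vertices
# correspond to facets of P. P is then integrated as pyramids from the
# origin over its facets: each dual vertex i contributes
# (1/d) * dist(0, hyperplane_i) * vol_{d-1} of the facet spanned by the
# primal vertices of the dual facets incident to i.
halfspaceVolume <- function(A, b, x0) {
  d <- ncol(A)
  bb <- as.numeric(b - A %*% x0)
  dual <- A / bb
  dh <- convexHull(dual)
  if (!dh$defined) return(0)
  V <- dh$normals / dh$offsets  # primal vertices, one per dual facet
  nf <- nrow(dh$facets)
  incidence <- split(rep(seq_len(nf), d), as.vector(dh$facets))
  vol <- 0
  for (i in dh$vertices) {
    rows <- incidence[[as.character(i)]]
    if (is.null(rows) || length(rows) < d) next
    Vi <- V[rows, , drop = FALSE]
    height <- 1 / sqrt(sum(dual[i, ]^2))
    c0 <- colMeans(Vi)
    dirs <- sweep(Vi, 2, c0)
    basis <- qr.Q(qr(t(dirs)))[, seq_len(d - 1), drop = FALSE]
    W <- dirs %*% basis
    area <- if (d == 2) {
      diff(range(W))
    } else {
      hW <- convexHull(W)
      if (!hW$defined) next
      hW$volume
    }
    vol <- vol + area * height / d
  }
  vol
}

# Exact volume of simplex-intersect-halfspaces: the simplex's own facets
# plus the active cutting planes form a small system; an interior point is
# sought among deterministic candidates (simplex vertices, centroid, edge
# midpoints) polished by minimum-slack maximization. Returns 0 when no
# strictly interior point exists.
clippedSimplexVolume <- function(simplexVerts, planes, offsets, tol) {
  hS <- convexHull(simplexVerts)
  if (!hS$defined) return(0)
  A <- rbind(hS$normals, planes)
  b <- c(hS$offsets, offsets)
  d <- ncol(simplexVerts)
  mids <- (simplexVerts[rep(seq_len(d + 1), each = d + 1), , drop = FALSE] +
           simplexVerts[rep(seq_len(d + 1), times = d + 1), , drop = FALSE]) / 2
  cand <- rbind(simplexVerts, colMeans(simplexVerts), mids)
  x0 <- interiorPoint(A, b, cand, tol)
  if (is.null(x0)) return(0)
  halfspaceVolume(A, b, x0)
}

#' Fraction of one hull's volume lying inside another
#'
#' Computes vol(H_A intersect H_B) / vol(H_A) exactly and piecewise: hull
#' A is decomposed into pyramid simplices (one per facet, apex at an
#' interior point), and each simplex is classified against the facets of
#' B that cut into A. Simplices entirely inside B contribute their full
#' volume, simplices entirely beyond some facet of B contribute nothing,
#' and the few straddling simplices are clipped exactly by polar duality
#' around an interior point of the clipped piece. The piecewise scheme
#' keeps every geometric subproblem small even when the full intersection
#' polytope has combinatorially many vertices. Disjoint or merely touching
#' (measure-zero) intersections give 0.
#'
#' @param pointsA,pointsB coordinate matrices on the same axes; both hulls
#'   must be defined.
#' @return Fraction in \[0, 1\].
#' @export
hullOverlapFraction <- function(pointsA, pointsB) {
  pointsA <- as.matrix(pointsA); pointsB <- as.matrix(pointsB)
  hA <- convexHull(pointsA)
  hB <- convexHull(pointsB)
  if (!hA$defined || !hB$defined) stop("input hull undefined")
  k <- ncol(pointsA)
  if (k == 1) {
    lo <- max(min(pointsA), min(pointsB))
    hi <- min(max(pointsA), max(pointsB))
    return(max(0, hi - lo) / hA$volume)
  }
  scale <- max(1, max(abs(pointsA)), max(abs(pointsB)))
  tol <- 1e-9 * scale
  vA <- pointsA[hA$vertices, , drop = FALSE]
  vB <- pointsB[hB$vertices, , drop = FALSE]

  # B-facets whose half-space contains every vertex of A contain all of A
  # and cannot cut the intersection. When no B-facet cuts A, A lies inside
  # B; when no A-facet is violated by B's vertices, B lies inside A.
  bCutsA <- rowSums(sweep(hB$normals %*% t(vA), 1, hB$offsets) > tol) > 0
  if (!any(bCutsA)) return(1)  # A contained in B
  aCutsB <- rowSums(sweep(hA$normals %*% t(vB), 1, hA$offsets) > tol) > 0
  if (!any(aCutsB)) return(hB$volume / hA$volume)  # B contained in A
  planes <- hB$normals[bCutsA, , drop = FALSE]
  offs <- hB$offsets[bCutsA]

  apex <- hA$interior
  fv <- hA$facets
  # signed excess of every hull-A point and the apex beyond every cutting
  # plane: the basis for classifying each pyramid simplex
  excessP <- sweep(pointsA %*% t(planes), 2, offs)   # n x nPlanes
  excessApex <- as.numeric(planes %*% apex) - offs
  vol <- 0
  d <- k
  for (f in seq_len(nrow(fv))) {
    idx <- fv[f, ]
    sVerts <- rbind(pointsA[idx, , drop = FALSE], apex)
    ex <- rbind(excessP[idx, , drop = FALSE], excessApex)  # (d+1) x planes
    outCount <- colSums(ex > tol)
    if (all(outCount == 0)) {           # simplex entirely inside B
      vol <- vol + abs(det(sweep(sVerts[-(d + 1), , drop = FALSE], 2,
                                 apex))) / factorial(d)
    } else if (any(outCount == d + 1)) {  # entirely beyond one plane of B
      next
    } else {
      active <- outCount > 0
      vol <- vol + clippedSimplexVolume(sVerts,
                                        planes[active, , drop = FALSE],
                                        offs[active], tol)
    }
  }
  min(1, max(0, vol / hA$volume))
}
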