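# Principal coordinates analysis (classical metric MDS) of a dissimilarity
# matrix, retaining a fixed number of positive axes.

#' Principal coordinates analysis
#'
#' Double-centers the squared dissimilarities (Gower centering,
#' B = -1/2 J D^2 J), eigendecomposes, and retains the top `k` axes with
#' strictly positive eigenvalues. Coordinates are eigenvectors scaled by
#' the square root of their eigenvalue, so Euclidean distances between
#' rows approximate (and for Euclidean input, reproduce) the input
#' dissimilarities. Axis orientation is made deterministic by flipping
#' each axis so its first nonzero loading is positive.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param k number of axes to retain (1 <= k < n).
#' @param negTol error if the most negative eigenvalue exceeds this
#'   fraction of the largest positive one (default 0.05); a large negative
#'   eigenvalue means the matrix is strongly non-Euclidean and a square-root
#'   transform should be applied first.
#' @return list with `coordinates` (n x k), `eigenvalues` (retained, positive,
#'   non-increasing), and `varianceRepresented` (retained / all positive).
#' @export
pcoaAxes <- function(D, k, negTol = 0.05) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-8 * max(1, max(abs(D)))))
    stop("D must be a symmetric square matrix")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  if (k < 1 || k >= n) stop("need n > k >= 1")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  tolPos <- 1e-8 * max(abs(vals))
  pos <- vals > tolPos
  if (sum(pos) < k)
    stop(sprintf("only %d positive eigenvalues; cannot retain %d axes",
                 sum(pos), k))
  if (min(vals) < 0 && -min(vals) > negTol * max(vals))
    stop(sprintf(
      paste0("most negative eigenvalue is %.1f%% of the largest ",
             "(tolerance %.0f%%); apply sqrtTransform() to the ",
             "dissimilarities first"),
      -100 * min(vals) / max(vals), 100 * negTol))
  co <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  for (j in seq_len(k)) {
    nz <- which(abs(co[, j]) > 1e-8)
    if (length(nz) && co[nz[1], j] < 0) co[, j] <- -co[, j]
  }
  rownames(co) <- rownames(D)
  list(coordinates = co,
       eigenvalues = vals[seq_len(k)],
       varianceRepresented = sum(vals[seq_len(k)]) / sum(vals[pos]))
}

#' Build the functional trait space for a species table
#'
#' Convenience pipeline: weighted Gower dissimilarity, element-wise square
#' root, PCoA with `k` retained axes, and the all-species convex hull
#' volume that serves as the functional-richness denominator.
#'
#' @inheritParams gowerDist
#' @param k number of PCoA axes to retain (default 5).
#' @param sqrt apply the square-root transform before PCoA (default TRUE).
#' @param negTol passed to [pcoaAxes()].
#' @return A [TraitSpace-class] object.
#' @export
buildTraitSpace <- function(species, k = 5, weights = NULL,
                            massTransform = c("log10", "identity"),
                            sqrt = TRUE, negTol = 0.05) {
  df <- if (is(species, "SpeciesTable")) species@data else
    as.data.frame(species)
  D <- gowerDist(df, weights = weights, massTransform = massTransform)
  if (sqrt) D <- sqrtTransform(D)
  ax <- pcoaAxes(D, k = k, negTol = negTol)
  hull <- hullVolume(ax$coordinates)
  if (!hull$defined)
    stop("global convex hull undefined: species cloud is degenerate")
  new("TraitSpace",
      species_ids = df$species_id,
      coordinates = ax$coordinates,
      eigenvalues = ax$eigenvalues,
      varianceRepresented = ax$varianceRepresented,
      globalVolume = hull$volume)
}
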