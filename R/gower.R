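# Weighted Gower dissimilarity on the mixed-type mammal trait table.
#
# Each trait *group* (mass, diet, foraging stratum, activity, habitat)
# carries total weight 1, split equally among its variables: the seven diet
# percentages get 1/7 each, the three activity flags 1/3 each, and so on.
# Continuous variables are range-normalized (Gower's built-in
# standardization); categorical and binary variables contribute 0/1
# mismatches. Body mass enters on a log10 scale by default, the only
# defensible choice across five orders of magnitude.

gowerVariables <- function(df, massTransform = c("log10", "identity")) {
  massTransform <- match.arg(massTransform)
  vars <- list()
  mass <- if (massTransform == "log10") log10(df$mass_g) else df$mass_g
  vars[["mass"]] <- list(group = "mass", type = "continuous", x = mass)
  for (dc in dietColumns())
    vars[[dc]] <- list(group = "diet", type = "continuous", x = df[[dc]])
  vars[["foraging_stratum"]] <- list(group = "stratum", type = "categorical",
                                     x = as.character(df$foraging_stratum))
  for (ac in activityColumns())
    vars[[ac]] <- list(group = "activity", type = "binary",
                       x = as.logical(df[[ac]]))
  flags <- strsplit(ifelse(is.na(df$habitat_flags), "", df$habitat_flags), ";",
                    fixed = TRUE)
  labels <- sort(unique(unlist(flags)))
  labels <- labels[nzchar(labels)]
  for (lab in labels)
    vars[[paste0("habitat_", lab)]] <- list(
      group = "habitat", type = "binary",
      x = vapply(flags, function(f) lab %in% f, logical(1)))
  vars
}

#' Weighted Gower dissimilarity matrix
#'
#' @param species a [SpeciesTable-class] (or its data.frame).
#' @param weights optional named numeric vector of per-variable weights;
#'   by default each trait group (mass, diet, stratum, activity, habitat)
#'   receives total weight 1 split equally among its variables. Scaling all
#'   weights by a constant leaves the result unchanged.
#' @param massTransform transform applied to `mass_g` before
#'   range-normalization (default `"log10"`).
#' @return Symmetric n x n matrix with zero diagonal and entries in
#'   \[0, 1\], dimnames = species ids. Variables that are constant across
#'   all species have zero range and are dropped with a warning.
#' @export
gowerDist <- function(species, weights = NULL,
                      massTransform = c("log10", "identity")) {
  df <- if (is(species, "SpeciesTable")) species@data else
    as.data.frame(species)
  n <- nrow(df)
  if (n < 2) stop("need at least two species")
  vars <- gowerVariables(df, massTransform)

  if (is.null(weights)) {
    groups <- vapply(vars, `[[`, character(1), "group")
    gsize <- table(groups)
    weights <- setNames(1 / as.numeric(gsize[groups]), names(vars))
  } else {
    missing <- setdiff(names(vars), names(weights))
    if (length(missing))
      stop("weights missing for variables: ", paste(missing, collapse = ", "))
    weights <- weights[names(vars)]
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be positive")
  }

  num <- matrix(0, n, n)  # sum of w_v * d_v over comparable variables
  den <- matrix(0, n, n)  # sum of w_v over comparable variables
  for (v in names(vars)) {
    vr <- vars[[v]]
    x <- vr$x
    ok <- !is.na(x)
    if (vr$type == "continuous") {
      rng <- diff(range(x[ok]))
      if (!length(x[ok]) || rng == 0) {
        warning("dropping zero-range variable: ", v)
        next
      }
      d <- abs(outer(x, x, "-")) / rng
    } else {
      d <- outer(x, x, "!=") * 1
    }
    comp <- outer(ok, ok, "&")
    d[!comp] <- 0
    num <- num + weights[[v]] * d
    den <- den + weights[[v]] * comp
  }
  offdiag <- row(den) != col(den)
  if (any(den[offdiag] == 0))
    stop("species pair with no comparable variables")
  den[den == 0] <- 1  # diagonal of an all-NA corner case
  D <- num / den
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(df$species_id, df$species_id)
  D
}

#' Element-wise square-root transform of a dissimilarity matrix
#'
#' Applied before PCoA because the weighted Gower matrix is generally
#' non-Euclidean; the square root strongly reduces the negative-eigenvalue
#' mass while preserving the \[0, 1\] range, zero diagonal, and symmetry.
#'
#' @param D symmetric non-negative dissimilarity matrix.
#' @return Matrix of element-wise square roots.
#' @export
sqrtTransform <- function(D) {
  if (any(D < 0)) stop("dissimilarities must be non-negative")
  sqrt(D)
}
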