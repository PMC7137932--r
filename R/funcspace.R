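#' Build the reduced trait space by principal coordinates analysis
#'
#' Classical metric scaling of the Gower matrix. Gower distances are usually
#' not exactly Euclidean-embeddable; when materially negative eigenvalues
#' appear, the square-root correction (PCoA on `sqrt(d)`) is applied, which
#' renders most Gower matrices embeddable. Coordinates are centred at the
#' origin. The number of retained axes defaults to
#' `min(3, min community richness - 1)` so hulls stay computable for
#' species-poor communities.
#'
#' @param d symmetric Gower distance matrix with species labels.
#' @param n_axes integer number of axes, or `"auto"`.
#' @param correction `"sqrt"` (default, applied only when needed) or
#'   `"none"`.
#' @param community_sizes optional integer vector of community richness
#'   values used by the `"auto"` rule; defaults to the pool size.
#' @return a `trait_space`: list with `species`, `coords` (species x m),
#'   `m`, `eigenvalues`, `correction` (the correction actually applied) and
#'   `stress` (relative embedding error against `d`).
#' @export
build_trait_space <- function(d, n_axes = "auto", correction = c("sqrt", "none"),
                              community_sizes = NULL) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stop_np("dimension_error", "need at least 4 species, got %d", n)
  applied <- "none"
  pc <- suppressWarnings(cmdscale(as.dist(d), k = n - 1, eig = TRUE))
  eig <- pc$eig
  neg_tol <- -1e-8 * max(abs(eig))
  if (correction == "sqrt" && any(eig < neg_tol)) {
    pc <- suppressWarnings(cmdscale(as.dist(sqrt(d)), k = n - 1, eig = TRUE))
    eig <- pc$eig
    applied <- "sqrt"
  }
  pos_tol <- 1e-8 * max(abs(eig))
  n_pos <- sum(eig > pos_tol)
  m <- if (identical(n_axes, "auto")) {
    smin <- if (is.null(community_sizes)) n else min(community_sizes)
    max(2L, min(3L, smin - 1L, n_pos))
  } else {
    as.integer(n_axes)
  }
  if (m > n_pos)
    stop_np("dimension_error",
            "requested %d axes but only %d positive eigenvalues", m, n_pos)
  if (m < 1) stop_np("dimension_error", "need at least 1 axis")
  coords <- pc$points[, seq_len(m), drop = FALSE]
  rownames(coords) <- rownames(d)
  emb <- as.matrix(dist(coords))
  stress <- sqrt(sum((emb - d)^2) / sum(d^2))
  structure(list(species = rownames(d), coords = coords, m = m,
                 eigenvalues = eig, correction = applied, stress = stress),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("trait_space: %d species on %d axes (correction: %s, stress %.3f)\n",
              length(x$species), x$m, x$correction, x$stress))
  invisible(x)
}

#' Convex hull volume of a point set
#'
#' Lebesgue measure of the convex hull: length for 1 axis, area for 2,
#' volume for 3. Degenerate (affinely dependent) point sets yield `NA`
#' rather than an error.
#'
#' @param points numeric matrix, one row per point, 1-3 columns.
#' @return non-negative volume, or `NA` if degenerate.
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < ncol(points) + 1)
    stop_np("dimension_error", "need at least m + 1 points for an m-dim hull")
  .hull_volume_cpp(points)
}

#' Functional richness (FRic) of a community
#'
#' Volume of the smallest convex set containing the community's species in
#' the reduced trait space; optionally standardized by the species-pool hull
#' volume so values fall in `(0, 1]`. Undefined (with a reason code) when
#' richness is below `m + 1` or the community's points are degenerate.
#'
#' @param community_species character vector of species present.
#' @param space a `trait_space`.
#' @param standardize divide by the pool hull volume (default TRUE).
#' @return list with `site_id = NA`, `metric = "FRic"`, `value`, `richness`,
#'   `defined`, `reason`.
#' @export
fric <- function(community_species, space, standardize = TRUE) {
  stopifnot(inherits(space, "trait_space"))
  unknown <- setdiff(community_species, space$species)
  if (length(unknown) > 0)
    stop_np("data_error", "species not in trait space: %s",
            paste(unknown, collapse = ", "))
  S <- length(community_species)
  m <- space$m
  if (S < m + 1) {
    return(list(metric = "FRic", value = NA_real_, richness = S,
                defined = FALSE, reason = sprintf("richness %d < m + 1 = %d", S, m + 1)))
  }
  v <- .hull_volume_cpp(space$coords[community_species, , drop = FALSE])
  if (is.na(v)) {
    return(list(metric = "FRic", value = NA_real_, richness = S,
                defined = FALSE, reason = "degenerate point set"))
  }
  if (standardize) {
    vp <- pool_hull_volume(space)
    v <- v / vp
  }
  list(metric = "FRic", value = v, richness = S, defined = TRUE, reason = NA_character_)
}

pool_hull_volume <- function(space) {
  if (is.null(space$pool_volume)) {
    v <- .hull_volume_cpp(space$coords)
    if (is.na(v)) stop_np("dimension_error", "species pool hull is degenerate")
    v
  } else {
    space$pool_volume
  }
}

#' Mean nearest-neighbour distance (MNND) of a community
#'
#' Mean, over community members, of each species' smallest Gower distance to
#' another member — a measure of packing density in trait space. Computed on
#' the Gower matrix directly (not on the reduced coordinates).
#'
#' @param community_species character vector of species present (>= 2).
#' @param d Gower distance matrix with species labels.
#' @return list as for [fric()] with `metric = "MNND"`.
#' @export
mnnd <- function(community_species, d) {
  d <- as.matrix(d)
  unknown <- setdiff(community_species, rownames(d))
  if (length(unknown) > 0)
    stop_np("data_error", "species not in distance matrix: %s",
            paste(unknown, collapse = ", "))
  S <- length(community_species)
  if (S < 2) {
    return(list(metric = "MNND", value = NA_real_, richness = S,
                defined = FALSE, reason = "richness < 2"))
  }
  idx <- match(community_species, rownames(d))
  v <- .null_mnnd_cpp(d, matrix(idx, nrow = 1))[1]
  list(metric = "MNND", value = v, richness = S, defined = TRUE,
       reason = NA_character_)
}

#' Test points for membership of a convex hull
#'
#' A point is inside when it is a convex combination of the hull points,
#' boundary included. Implemented by facet half-space tests; when the hull
#' points are affinely dependent (degenerate hull) the test falls back to
#' membership of the affine subspace plus the lower-dimensional hull within
#' it, with a message.
#'
#' @param points query points, matrix with one row per point (or a single
#'   vector).
#' @param hull_points matrix of hull-defining points.
#' @param tol membership slack (default 1e-9).
#' @return logical vector, one per query point.
#' @export
in_hull <- function(points, hull_points, tol = 1e-9) {
  hull_points <- as.matrix(hull_points)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  storage.mode(hull_points) <- "double"
  if (ncol(points) != ncol(hull_points))
    stop_np("dimension_error", "query/hull dimension mismatch")
  res <- .in_hull_cpp(hull_points, points, tol)
  if (!anyNA(res)) return(as.logical(res))
  # Degenerate hull: test membership of the affine subspace, then recurse on
  # the projected (lower-dimensional) hull.
  message("degenerate hull: falling back to affine-subspace membership test")
  centre <- colMeans(hull_points)
  X <- sweep(hull_points, 2, centre)
  sv <- svd(X)
  scale <- max(abs(X), 1e-300)
  r <- sum(sv$d > 1e-9 * scale * sqrt(nrow(X)))
  Q <- points
  Yq <- sweep(Q, 2, centre)
  if (r == 0) {
    return(sqrt(rowSums(Yq^2)) <= max(tol, 1e-12) * max(1, scale))
  }
  basis <- sv$v[, seq_len(r), drop = FALSE]
  proj_h <- X %*% basis
  proj_q <- Yq %*% basis
  resid <- sqrt(pmax(rowSums(Yq^2) - rowSums(proj_q^2), 0))
  on_plane <- resid <= max(tol, 1e-12) * max(1, scale) * 1e3
  out <- rep(FALSE, nrow(Q))
  if (any(on_plane))
    out[on_plane] <- in_hull(proj_q[on_plane, , drop = FALSE], proj_h, tol)
  out
}

#' Distance of each pool species to the centre of functional space
#'
#' Euclidean distance of every species' reduced coordinates to the pool
#' centroid. PCoA coordinates are centred, so these are simply row norms,
#' but the centroid is recomputed for robustness to subsetting.
#'
#' @param space a `trait_space`.
#' @return named numeric vector, one entry per pool species.
#' @export
centroid_distances <- function(space) {
  stopifnot(inherits(space, "trait_space"))
  ctr <- colMeans(space$coords)
  sqrt(rowSums(sweep(space$coords, 2, ctr)^2))
}
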