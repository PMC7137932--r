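#' Build the total and regional species pools
#'
#' The total pool is the union of species over all sites; each regional pool
#' is the union over that ecoregion's sites — the species that have
#' colonized and established within local communities of the ecoregion.
#'
#' @param community a `community_data` object.
#' @return named list of `species_pool` objects (`total`, plus one per
#'   ecoregion present).
#' @export
build_pools <- function(community) {
  ab <- community$abundance
  pools <- list(total = species_pool("total",
                                     colnames(ab)[colSums(ab) > 0], "total"))
  for (eco in unique(community$ecoregion)) {
    rows <- community$ecoregion == eco
    sp <- colnames(ab)[colSums(ab[rows, , drop = FALSE]) > 0]
    if (length(sp) == 0)
      stop_np("pool_error", "ecoregion %s holds no species", eco)
    pools[[eco]] <- species_pool(eco, sp, "regional")
  }
  pools
}

species_pool <- function(name, species, definition) {
  structure(list(name = name, species = sort(unique(species)),
                 definition = definition),
            class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("species_pool '%s' (%s): %d species\n",
              x$name, x$definition, length(x$species)))
  invisible(x)
}

#' Draw one randomized community from a species pool
#'
#' Uniform draw of `S` distinct species, without replacement and without
#' abundance or occupancy weighting — the identity-randomization null.
#' Consumes the caller's RNG stream.
#'
#' @param S community richness to preserve.
#' @param pool a `species_pool`.
#' @return character vector of `S` species.
#' @export
randomize_community <- function(S, pool) {
  if (S > length(pool$species))
    stop_np("infeasible_draw_error", "S = %d exceeds pool size %d",
            S, length(pool$species))
  pool$species[sample.int(length(pool$species), S)]
}

#' Constrain a species pool to a community's empirical trait volume
#'
#' Retains the pool species whose reduced coordinates lie inside the convex
#' hull of the focal community (boundary included), mirroring hierarchical
#' assembly: only species that could pass the community's abiotic filter are
#' candidate colonists for the packing (MNND) null. The community's own
#' species are always retained.
#'
#' @param community_species the focal community's species.
#' @param pool a `species_pool` containing the community.
#' @param space a `trait_space`.
#' @param tol hull-membership slack.
#' @return a `species_pool` with `name` suffixed by `"|constrained"`.
#' @export
constrain_pool <- function(community_species, pool, space, tol = 1e-9) {
  S <- length(community_species)
  if (S < space$m + 1)
    stop_np("constraint_error", "community richness %d below m + 1 = %d",
            S, space$m + 1)
  hull_pts <- space$coords[community_species, , drop = FALSE]
  if (is.na(.hull_volume_cpp(hull_pts)))
    stop_np("constraint_error", "degenerate community hull")
  cand <- pool$species
  inside <- in_hull(space$coords[cand, , drop = FALSE], hull_pts, tol)
  keep <- union(community_species, cand[inside])
  species_pool(paste0(pool$name, "|constrained"), keep, pool$definition)
}

#' Null distribution of a community metric under identity randomization
#'
#' Draws `n_perm` richness-preserving random communities from the pool and
#' recomputes the metric for each. Permutations where the metric is
#' undefined (hull collapse in a null draw) are recorded as `NA` and later
#' excluded from the null mean/SD.
#'
#' @param S observed community richness.
#' @param pool a `species_pool`.
#' @param metric `"FRic"` or `"MNND"`.
#' @param n_perm number of randomizations.
#' @param space `trait_space` (used for FRic).
#' @param d Gower matrix (used for MNND).
#' @param standardize standardize FRic by the pool-space hull volume.
#' @return numeric vector of length `n_perm` (may contain `NA`).
#' @export
null_distribution <- function(S, pool, metric = c("FRic", "MNND"),
                              n_perm = 1000, space = NULL, d = NULL,
                              standardize = TRUE) {
  metric <- match.arg(metric)
  npool <- length(pool$species)
  if (S > npool)
    stop_np("infeasible_draw_error", "S = %d exceeds pool size %d", S, npool)
  if (metric == "FRic") {
    stopifnot(inherits(space, "trait_space"))
    labels <- space$species
  } else {
    d <- as.matrix(d)
    labels <- rownames(d)
  }
  pool_idx <- match(pool$species, labels)
  if (anyNA(pool_idx))
    stop_np("data_error", "pool species missing from trait data")
  idx <- t(vapply(seq_len(n_perm),
                  function(i) pool_idx[sample.int(npool, S)],
                  integer(S)))
  if (metric == "FRic") {
    v <- .null_fric_cpp(space$coords, idx)
    if (standardize) v <- v / pool_hull_volume(space)
    v
  } else {
    .null_mnnd_cpp(d, idx)
  }
}

#' Standardized effect size
#'
#' `(observed - null mean) / null SD`, with the sample (n-1) standard
#' deviation; undefined (`NA`) when the null SD is zero or fewer than two
#' valid null values exist.
#'
#' @param observed observed metric value.
#' @param null_values numeric vector of null metric values (`NA`s are the
#'   degenerate permutations and are dropped).
#' @return a single numeric SES, or `NA`.
#' @export
ses <- function(observed, null_values) {
  v <- null_values[!is.na(null_values)]
  if (length(v) < 2 || is.na(observed)) return(NA_real_)
  s <- sd(v)
  if (s == 0) return(NA_real_)
  (observed - mean(v)) / s
}

#' Run the full null-model analysis over all sites
#'
#' For every site x metric x pool definition x applicable variant, draws the
#' null distribution, computes the standardized effect size, and returns one
#' result row. The hull-constrained variant is computed for MNND only: under
#' the constraint, null FRic can never exceed the observed FRic, so its SES
#' carries no information. Each cell gets its own RNG stream derived from
#' `cfg$seed` and the cell key, so results are independent of evaluation
#' order. Per-site failures (degenerate hulls, undersized communities)
#' become flagged rows, never an aborted batch.
#'
#' @param community a `community_data`.
#' @param space a `trait_space` over the total pool.
#' @param d Gower distance matrix over the total pool.
#' @param cfg a [run_config()].
#' @return `data.frame` of class `null_model_results`.
#' @export
run_null_analysis <- function(community, space, d, cfg = run_config()) {
  pools <- build_pools(community)
  d <- as.matrix(d)
  pool_defs <- switch(cfg$pool_definition,
                      both = c("total", "regional"),
                      cfg$pool_definition)
  variants <- switch(cfg$model_variant,
                     both = c("unconstrained", "constrained"),
                     cfg$model_variant)
  rows <- list()
  for (site in rownames(community$abundance)) {
    sp_comm <- colnames(community$abundance)[community$abundance[site, ] > 0]
    S <- length(sp_comm)
    obs_fric <- fric(sp_comm, space, standardize = cfg$standardize_fric)
    obs_mnnd <- mnnd(sp_comm, d)
    for (pd in pool_defs) {
      pool <- if (pd == "total") pools$total else pools[[community$ecoregion[site]]]
      for (variant in variants) {
        metrics <- if (variant == "unconstrained") c("FRic", "MNND") else "MNND"
        for (metric in metrics) {
          obs <- if (metric == "FRic") obs_fric else obs_mnnd
          cell_seed <- derive_seed(cfg$seed, site, metric, pd, variant)
          row <- list(site_id = site, metric = metric, pool_definition = pd,
                      pool = pool$name, variant = variant, richness = S,
                      observed = obs$value, null_mean = NA_real_,
                      null_sd = NA_real_, ses = NA_real_,
                      n_perm = cfg$n_permutations, n_valid_perm = 0L,
                      seed = cell_seed, defined = FALSE, reason = NA_character_)
          if (!obs$defined) {
            row$reason <- obs$reason
            rows[[length(rows) + 1]] <- row
            next
          }
          use_pool <- pool
          if (variant == "constrained") {
            if (!obs_fric$defined) {
              row$reason <- paste("constraint skipped:", obs_fric$reason)
              rows[[length(rows) + 1]] <- row
              next
            }
            use_pool <- tryCatch(
              constrain_pool(sp_comm, pool, space, cfg$hull_tolerance),
              error = function(e) e)
            if (inherits(use_pool, "error")) {
              row$reason <- conditionMessage(use_pool)
              rows[[length(rows) + 1]] <- row
              next
            }
            row$pool <- use_pool$name
          }
          nd <- with_seed(cell_seed,
                          null_distribution(S, use_pool, metric,
                                            n_perm = cfg$n_permutations,
                                            space = space, d = d,
                                            standardize = cfg$standardize_fric))
          valid <- nd[!is.na(nd)]
          row$n_valid_perm <- length(valid)
          if (length(valid) >= 2) {
            row$null_mean <- mean(valid)
            row$null_sd <- sd(valid)
            row$ses <- ses(obs$value, nd)
            row$defined <- TRUE
            if (is.na(row$ses))
              row$reason <- "null SD is zero (degenerate null)"
          } else {
            row$reason <- "fewer than 2 valid permutations"
          }
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("null_model_results", "data.frame")
  out
}
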