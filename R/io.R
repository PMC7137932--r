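#' Read a specimen-level morphometric table
#'
#' Expects one row per captured individual with columns `specimen_id`
#' (optional), `species`, `site_id`, `session_id` (optional) and the ten
#' measurement columns `WT, HB, T, HF, E, CI, GW, IW, UTR, LTR`. Malformed
#' numeric cells (e.g. `"na"`, `"-"`) become `NA` with a warning; measurement
#' values that are zero or negative are physically impossible and are also
#' set to `NA` with a warning. Missingness is always encoded as `NA`, never 0.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default comma).
#' @return a `data.frame` of specimen records, row order preserved.
#' @export
read_specimens <- function(path, sep = ",") {
  if (!file.exists(path)) stop_np("io_error", "file not found: %s", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  mandatory <- c("species", "site_id", MEASUREMENTS)
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0)
    stop_np("schema_error", "missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0)
    stop_np("empty_input_error", "no specimen rows in %s", path)
  if (!"specimen_id" %in% names(df))
    df$specimen_id <- sprintf("spec_%04d", seq_len(nrow(df)))
  if (!"session_id" %in% names(df)) df$session_id <- NA_character_
  for (m in MEASUREMENTS) {
    raw <- df[[m]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "" & trimws(raw) != "" &
      !toupper(trimws(raw)) %in% c("NA", "NAN") & is.na(num)
    if (any(bad))
      warn_np("column %s: %d malformed cell(s) set to missing", m, sum(bad))
    nonpos <- !is.na(num) & num <= 0
    if (any(nonpos)) {
      warn_np("column %s: %d non-positive value(s) set to missing", m, sum(nonpos))
      num[nonpos] <- NA_real_
    }
    df[[m]] <- num
  }
  if (any(!nzchar(df$species)) || any(!nzchar(df$site_id)))
    stop_np("schema_error", "species and site_id must be non-empty")
  df[, c("specimen_id", "species", "site_id", "session_id", MEASUREMENTS)]
}

#' Select trapping sessions usable for community analysis
#'
#' Sites can have several trapping sessions; sessions spanning a seasonal
#' transition are discarded, and when several single-season sessions remain
#' at a site, only the session with the highest total shrew abundance (record
#' count) is kept, ties broken towards the lexicographically smallest
#' `session_id` (logged). Sites whose sessions are all impure are dropped
#' with a warning. Records with no session metadata pass through unchanged.
#'
#' @param records specimen `data.frame` as from [read_specimens()].
#' @param sessions `data.frame` with columns `session_id`, `site_id`,
#'   `season_pure` (logical).
#' @return the filtered specimen `data.frame`.
#' @export
select_sessions <- function(records, sessions) {
  stopifnot(all(c("session_id", "site_id", "season_pure") %in% names(sessions)))
  keep <- rep(TRUE, nrow(records))
  for (s in unique(records$site_id)) {
    in_site <- records$site_id == s
    sess_here <- unique(records$session_id[in_site])
    sess_here <- sess_here[!is.na(sess_here)]
    if (length(sess_here) == 0) next   # no session metadata: pass through
    meta <- sessions[sessions$site_id == s & sessions$session_id %in% sess_here, ]
    pure <- meta$session_id[isTRUE_vec(meta$season_pure)]
    if (length(pure) == 0) {
      warn_np("site %s: no single-season session; site dropped", s)
      keep[in_site] <- FALSE
      next
    }
    if (length(pure) == 1) {
      keep[in_site & !records$session_id %in% pure] <- FALSE
      next
    }
    ab <- vapply(pure, function(ss) sum(in_site & records$session_id == ss), 0L)
    best <- pure[ab == max(ab)]
    if (length(best) > 1) {
      best <- sort(best)[1]
      warn_np("site %s: abundance tie; keeping session %s", s, best)
    }
    keep[in_site & records$session_id != best] <- FALSE
  }
  records[keep, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Construct the site-by-species community object
#'
#' @param abundance non-negative integer matrix, sites in rows (named),
#'   species in columns (named).
#' @param ecoregion named character vector mapping site_id to `"CLF"`/`"NLF"`.
#' @param locality named character vector mapping site_id to locality.
#' @return an object of class `community_data`.
#' @export
community_data <- function(abundance, ecoregion, locality = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop_np("metadata_error", "abundance matrix must have site and species names")
  if (any(abundance < 0) || any(abundance != round(abundance)))
    stop_np("metadata_error", "abundance must be non-negative integer counts")
  if (any(rowSums(abundance) == 0))
    stop_np("metadata_error", "every site must hold at least one individual")
  missing_eco <- setdiff(rownames(abundance), names(ecoregion))
  if (length(missing_eco) > 0)
    stop_np("metadata_error", "site(s) without ecoregion: %s",
            paste(missing_eco, collapse = ", "))
  eco <- ecoregion[rownames(abundance)]
  if (any(is.na(eco)) || !all(eco %in% ECOREGIONS))
    stop_np("metadata_error", "ecoregion must be one of %s",
            paste(ECOREGIONS, collapse = "/"))
  if (is.null(locality)) {
    locality <- setNames(rep(NA_character_, nrow(abundance)), rownames(abundance))
  }
  structure(list(abundance = abundance,
                 ecoregion = eco,
                 locality = locality[rownames(abundance)]),
            class = "community_data")
}

#' @export
print.community_data <- function(x, ...) {
  cat(sprintf("community_data: %d sites x %d species (%s)\n",
              nrow(x$abundance), ncol(x$abundance),
              paste(sprintf("%s: %d", names(table(x$ecoregion)),
                            table(x$ecoregion)), collapse = ", ")))
  invisible(x)
}

#' Species richness per site
#' @param community a `community_data` object.
#' @return named integer vector of per-site richness.
#' @export
richness <- function(community) {
  rowSums(community$abundance > 0)
}

#' Build the community matrix from specimen records
#'
#' Abundance is the raw capture count per species per site; species columns
#' are the union over all sites in stable (sorted) order.
#'
#' @param records specimen `data.frame`.
#' @param site_meta `data.frame` with columns `site_id`, `ecoregion` and
#'   optionally `locality`.
#' @return a `community_data` object.
#' @export
build_community_matrix <- function(records, site_meta) {
  if (nrow(records) == 0) stop_np("empty_input_error", "no specimen records")
  missing_sites <- setdiff(unique(records$site_id), site_meta$site_id)
  if (length(missing_sites) > 0)
    stop_np("metadata_error", "site(s) missing from site metadata: %s",
            paste(missing_sites, collapse = ", "))
  species <- sort(unique(records$species))
  sites <- site_meta$site_id[site_meta$site_id %in% records$site_id]
  ab <- table(factor(records$site_id, levels = sites),
              factor(records$species, levels = species))
  ab <- matrix(as.integer(ab), nrow = length(sites),
               dimnames = list(sites, species))
  eco <- setNames(as.character(site_meta$ecoregion), site_meta$site_id)
  loc <- if ("locality" %in% names(site_meta)) {
    setNames(as.character(site_meta$locality), site_meta$site_id)
  } else NULL
  community_data(ab, eco, loc)
}

#' Write null-model results to CSV
#'
#' One row per (site, metric, pool, variant); numeric cells are serialized
#' with 17 significant digits so that a round-trip read reproduces them
#' bit-exactly.
#'
#' @param results `data.frame` of class `null_model_results`.
#' @param path output file path.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0)
    stop_np("empty_input_error", "no results to write")
  out <- results
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_np("io_error", "cannot write results to %s", path)
  invisible(path)
}

#' Read back a null-model results CSV written by [write_results()]
#' @param path file path.
#' @return `data.frame` with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  numcols <- c("observed", "null_mean", "null_sd", "ses")
  for (nc in intersect(numcols, names(df))) df[[nc]] <- as.numeric(df[[nc]])
  for (ic in intersect(c("n_perm", "n_valid_perm", "seed"), names(df)))
    df[[ic]] <- as.integer(df[[ic]])
  class(df) <- c("null_model_results", "data.frame")
  df
}

#' Run configuration for the null-model pipeline
#'
#' @param n_permutations number of identity randomizations per null
#'   distribution (default 1000).
#' @param pool_definition `"total"`, `"regional"`, or `"both"`.
#' @param model_variant `"unconstrained"`, `"constrained"`, or `"both"`; the
#'   hull-constrained variant applies to MNND only.
#' @param n_axes number of trait-space axes, or `"auto"`
#'   (min(3, min community richness - 1)).
#' @param seed base RNG seed.
#' @param min_richness_fric minimum richness for FRic (>= 3, default 3).
#' @param hull_tolerance slack for hull-membership tests.
#' @param standardize_fric divide community hull volumes by the pool hull
#'   volume (default TRUE; SES is invariant to this scaling).
#' @return a `run_config` list.
#' @export
run_config <- function(n_permutations = 1000,
                       pool_definition = c("both", "total", "regional"),
                       model_variant = c("both", "unconstrained", "constrained"),
                       n_axes = "auto",
                       seed = 42L,
                       min_richness_fric = 3L,
                       hull_tolerance = 1e-9,
                       standardize_fric = TRUE) {
  pool_definition <- match.arg(pool_definition)
  model_variant <- match.arg(model_variant)
  if (n_permutations < 1) stop_np("config_error", "n_permutations must be >= 1")
  if (min_richness_fric < 3) stop_np("config_error", "min_richness_fric must be >= 3")
  if (!identical(n_axes, "auto") && (!is.numeric(n_axes) || n_axes < 1))
    stop_np("config_error", "n_axes must be a positive integer or 'auto'")
  if (hull_tolerance <= 0) stop_np("config_error", "hull_tolerance must be > 0")
  structure(list(n_permutations = as.integer(n_permutations),
                 pool_definition = pool_definition,
                 model_variant = model_variant,
                 n_axes = n_axes,
                 seed = as.integer(seed),
                 min_richness_fric = as.integer(min_richness_fric),
                 hull_tolerance = hull_tolerance,
                 standardize_fric = isTRUE(standardize_fric)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param cfg a `run_config` object.
#' @param path file path.
#' @rdname config_yaml
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_yaml
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}
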