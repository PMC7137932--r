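#' Derive analysis traits from raw measurements
#'
#' Most raw morphometric measurements correlate strongly with body size, and
#' functional-diversity metrics shrink as positive trait correlations grow,
#' so the appendage lengths are expressed relative to body length and the
#' cranial measurements relative to condylo-incisive length. Absolute WT, HB
#' and CI are retained as size traits. Ratios are computed per individual;
#' a missing numerator or denominator propagates to the affected slot only.
#'
#' @param records specimen `data.frame` (one row per individual) carrying the
#'   ten measurement columns.
#' @return `data.frame` with `specimen_id`, `species`, `site_id` and the ten
#'   derived trait columns `WT, HB, CI, T_rel, HF_rel, E_rel, GW_rel, IW_rel,
#'   UTR_rel, LTR_rel`.
#' @export
derive_traits <- function(records) {
  for (den in c("HB", "CI")) {
    bad <- !is.na(records[[den]]) & records[[den]] <= 0
    if (any(bad))
      stop_np("data_error", "%s must be strictly positive (%d offending row(s))",
              den, sum(bad))
  }
  out <- data.frame(specimen_id = records$specimen_id,
                    species = records$species,
                    site_id = records$site_id,
                    WT = records$WT,
                    HB = records$HB,
                    CI = records$CI,
                    T_rel = records$T / records$HB,
                    HF_rel = records$HF / records$HB,
                    E_rel = records$E / records$HB,
                    GW_rel = records$GW / records$CI,
                    IW_rel = records$IW / records$CI,
                    UTR_rel = records$UTR / records$CI,
                    LTR_rel = records$LTR / records$CI,
                    stringsAsFactors = FALSE)
  out
}

#' Flag outliers by the 1.5 x IQR rule
#'
#' A value is an outlier when it lies below Q1 - 1.5 IQR or above
#' Q3 + 1.5 IQR, with quartiles by linear interpolation between order
#' statistics (`quantile(type = 7)`). With fewer than 4 finite values the
#' quartiles are too unstable, so nothing is flagged; `NA`s are never
#' flagged.
#'
#' @param values numeric vector.
#' @return logical vector of the same length.
#' @export
flag_iqr_outliers <- function(values) {
  flags <- rep(FALSE, length(values))
  finite <- is.finite(values)
  if (sum(finite) < 4) return(flags)
  q <- quantile(values[finite], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  flags[finite] <- values[finite] < lo | values[finite] > hi
  flags
}

#' Aggregate individuals to a species-by-trait matrix
#'
#' Per species and derived trait, individual values are screened with
#' [flag_iqr_outliers()] (gross measurement/transcription errors, pregnancy
#' mass and the like) and the surviving values averaged. Screening is done
#' within species and per trait, so one aberrant measurement does not discard
#' the whole specimen.
#'
#' @param records specimen `data.frame` with raw measurements (derivation is
#'   applied internally), or a `data.frame` already carrying the derived
#'   trait columns.
#' @return a `species_trait_matrix`: numeric matrix (species x 10 traits)
#'   with attribute `n_specimens` (named count of individuals per species).
#' @export
aggregate_species <- function(records) {
  derived <- if (all(TRAIT_NAMES %in% names(records)) &&
                 !"T" %in% names(records)) {
    records
  } else {
    derive_traits(records)
  }
  species <- sort(unique(derived$species))
  vals <- matrix(NA_real_, length(species), length(TRAIT_NAMES),
                 dimnames = list(species, TRAIT_NAMES))
  n_spec <- setNames(integer(length(species)), species)
  for (sp in species) {
    rows <- derived[derived$species == sp, , drop = FALSE]
    n_spec[sp] <- nrow(rows)
    for (tr in TRAIT_NAMES) {
      v <- rows[[tr]]
      keep <- !is.na(v) & !flag_iqr_outliers(v)
      if (!any(keep)) {
        if (any(!is.na(v)))
          warn_np("species %s, trait %s: all values flagged as outliers", sp, tr)
        next
      }
      vals[sp, tr] <- mean(v[keep])
    }
  }
  empty <- rowSums(!is.na(vals)) == 0
  if (any(empty))
    stop_np("data_error", "species with no usable trait values: %s",
            paste(species[empty], collapse = ", "))
  structure(vals, n_specimens = n_spec, class = c("species_trait_matrix", "matrix"))
}

#' @export
print.species_trait_matrix <- function(x, ...) {
  cat(sprintf("species_trait_matrix: %d species x %d traits\n", nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), , drop = FALSE], digits = 3)
  invisible(x)
}

#' Gower distance matrix between species
#'
#' Range-normalized mean absolute trait difference: for each species pair,
#' the mean over traits non-missing in both of `|x_i - x_j| / range`, with
#' ranges taken over all species. Bounded in `[0, 1]`; missing traits are
#' handled by pairwise deletion. Traits with zero range carry no information
#' and are dropped with a warning.
#'
#' @param m species-by-trait numeric matrix (rows named by species).
#' @return symmetric distance matrix with zero diagonal, species labels on
#'   both margins.
#' @export
gower_matrix <- function(m) {
  m <- unclass(as.matrix(m))
  rng <- apply(m, 2, function(col) {
    f <- is.finite(col)
    if (!any(f)) return(NA_real_)
    diff(range(col[f]))
  })
  drop_tr <- which(is.na(rng) | rng <= 0)
  if (length(drop_tr) > 0) {
    warn_np("dropping zero-range trait(s): %s",
            paste(colnames(m)[drop_tr], collapse = ", "))
    m <- m[, -drop_tr, drop = FALSE]
    rng <- rng[-drop_tr]
  }
  if (ncol(m) == 0) stop_np("data_error", "no informative traits left")
  n <- nrow(m)
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (k in seq_len(ncol(m))) {
    x <- m[, k]
    ok <- is.finite(x)
    both <- outer(ok, ok, `&`)
    dk <- abs(outer(x, x, `-`)) / rng[k]
    dk[!both] <- 0
    acc <- acc + dk
    cnt <- cnt + both
  }
  d <- acc / cnt
  if (any(cnt == 0 & row(cnt) != col(cnt))) {
    warn_np("species pair(s) share no traits; distance undefined (NA)")
    d[cnt == 0] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Export the species trait matrix as CSV
#' @param m a `species_trait_matrix`.
#' @param path file path.
#' @export
write_species_traits <- function(m, path) {
  df <- data.frame(species = rownames(m), unclass(m),
                   n_specimens = attr(m, "n_specimens")[rownames(m)],
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
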