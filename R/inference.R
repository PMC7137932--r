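#' Wilcoxon signed-rank test against a location
#'
#' Two-sided one-sample signed-rank test of whether the values (typically
#' standardized effect sizes) differ from `mu0`. Zero differences are
#' dropped before ranking; ties get midranks. For n <= 25 the exact null
#' distribution of the signed-rank statistic is computed by the shift
#' algorithm over doubled midranks (equivalent to enumerating all 2^n sign
#' patterns, exact also under ties); beyond that, the normal approximation
#' with continuity and tie correction is used.
#'
#' @param values numeric vector.
#' @param mu0 hypothesized location (default 0).
#' @return list with `n` (non-zero differences used), `statistic` (V, sum of
#'   positive ranks), `p_value`, `direction` (sign of the median difference),
#'   and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(values, mu0 = 0) {
  dif <- values[!is.na(values)] - mu0
  dif <- dif[dif != 0]
  n <- length(dif)
  if (n == 0) {
    return(list(n = 0L, statistic = NA_real_, p_value = 1,
                direction = 0, method = "degenerate"))
  }
  r <- rank(abs(dif))
  V <- sum(r[dif > 0])
  direction <- sign(median(dif))
  if (n <= 25) {
    # distribution of 2*V over all sign assignments, by polynomial product
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- c(1, rep(0, tot))          # f[s + 1] = #assignments with 2V = s
    for (w in r2) {
      g <- f
      g[(w + 1):(tot + 1)] <- g[(w + 1):(tot + 1)] + f[1:(tot + 1 - w)]
      f <- g
    }
    total <- 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(f[1:(v2 + 1)]) / total
    p_ge <- sum(f[(v2 + 1):(tot + 1)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(n = n, statistic = V, p_value = p, direction = direction, method = method)
}

#' Type-II ANCOVA of a community metric on richness and ecoregion
#'
#' Fully factorial least-squares model `response ~ S + E + S:E` with species
#' richness `S` as covariate and ecoregion `E` as factor. Type-II sums of
#' squares: each main effect is adjusted for the other main effect (the
#' interaction excluded from its comparison); the interaction is adjusted
#' for both mains. F statistics use the full-model residual mean square.
#'
#' @param response numeric response (metric or SES per site).
#' @param richness integer covariate.
#' @param ecoregion factor (2+ levels).
#' @return `data.frame` with one row per term (`S`, `E`, `S:E`): `sum_sq`,
#'   `df`, `F`, `p_value`; residual df/SS as attributes.
#' @export
ancova_type2 <- function(response, richness, ecoregion) {
  ok <- !is.na(response) & !is.na(richness) & !is.na(ecoregion)
  y <- response[ok]
  S <- as.numeric(richness[ok])
  E <- factor(ecoregion[ok])
  if (nlevels(E) < 2) stop_np("model_error", "need >= 2 ecoregion levels")
  if (length(y) <= 5) stop_np("model_error", "need n > 5 observations")
  for (lev in levels(E)) {
    if (length(unique(S[E == lev])) < 2)
      stop_np("model_error",
              "richness is constant within level %s (collinear with ecoregion)", lev)
  }
  rss <- function(formula) {
    X <- model.matrix(formula, data = data.frame(S = S, E = E))
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss_E <- rss(~E)
  rss_S <- rss(~S)
  rss_SE <- rss(~S + E)
  rss_full <- rss(~ S * E)
  df_E <- nlevels(E) - 1
  df_int <- df_E
  df_res <- length(y) - (2 + 2 * df_E)
  if (df_res < 1) stop_np("model_error", "no residual degrees of freedom")
  ms_res <- rss_full / df_res
  terms <- data.frame(
    term = c("S", "E", "S:E"),
    sum_sq = c(rss_E - rss_SE, rss_S - rss_SE, rss_SE - rss_full),
    df = c(1, df_E, df_int),
    stringsAsFactors = FALSE)
  terms$F <- (terms$sum_sq / terms$df) / ms_res
  terms$p_value <- pf(terms$F, terms$df, df_res, lower.tail = FALSE)
  attr(terms, "df_residual") <- df_res
  attr(terms, "rss_residual") <- rss_full
  terms
}

#' Pearson correlation of SES with richness, per ecoregion
#'
#' Within each ecoregion, the Pearson correlation between the sites'
#' standardized effect sizes and their empirical species richness.
#'
#' @param results a `null_model_results` data.frame (pre-filtered to one
#'   metric/pool/variant combination).
#' @param community a `community_data` supplying the site-to-ecoregion map.
#' @return `data.frame` with one row per ecoregion: `group`, `kind`, `r`,
#'   `p_value`, `n`, `defined`.
#' @export
ses_richness_correlation <- function(results, community) {
  out <- list()
  for (eco in sort(unique(community$ecoregion))) {
    sites <- names(community$ecoregion)[community$ecoregion == eco]
    sub <- results[results$site_id %in% sites & !is.na(results$ses), , drop = FALSE]
    n <- nrow(sub)
    row <- data.frame(group = eco, kind = "pearson", r = NA_real_,
                      p_value = NA_real_, n = n, defined = FALSE,
                      stringsAsFactors = FALSE)
    if (n >= 3 && length(unique(sub$richness)) > 1 && sd(sub$ses) > 0) {
      ct <- stats::cor.test(sub$ses, sub$richness, method = "pearson")
      row$r <- unname(ct$estimate)
      row$p_value <- ct$p.value
      row$defined <- TRUE
    }
    out[[eco]] <- row
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Spearman correlation of functional centrality with average abundance
#'
#' Tests whether species far from the centre of functional space (peripheral
#' species) tend to be locally rarer. Average abundance is the mean count
#' across all sites of the ecoregion(s) in which the species occurs,
#' including zeros (a regional mean-density proxy); set
#' `occupied_only = TRUE` to average over occupied sites instead. P-value by
#' exact permutation for n <= 10, t-approximation otherwise.
#'
#' @param space a `trait_space` over the pool.
#' @param community a `community_data`.
#' @param occupied_only average abundance over occupied sites only.
#' @return list with `kind`, `rho`, `p_value`, `n`, `method`.
#' @export
centrality_abundance_correlation <- function(space, community,
                                             occupied_only = FALSE) {
  ab <- community$abundance
  species <- intersect(space$species, colnames(ab))
  if (length(species) < 3)
    stop_np("data_error", "need >= 3 species with abundance data")
  cd <- centroid_distances(space)[species]
  avg <- vapply(species, function(sp) {
    occ_sites <- rownames(ab)[ab[, sp] > 0]
    if (length(occ_sites) == 0) return(NA_real_)
    if (occupied_only) return(mean(ab[occ_sites, sp]))
    ecos <- unique(community$ecoregion[occ_sites])
    sites <- rownames(ab)[community$ecoregion %in% ecos]
    mean(ab[sites, sp])
  }, numeric(1))
  ok <- !is.na(avg)
  cd <- cd[ok]
  avg <- avg[ok]
  n <- length(cd)
  rx <- rank(cd)
  ry <- rank(avg)
  rho <- suppressWarnings(cor(rx, ry))
  if (n <= 10) {
    p <- .spearman_perm_p_cpp(rx, ry)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  list(kind = "spearman", rho = rho, p_value = min(1, p), n = n, method = method)
}

#' Occupancy per species
#'
#' Fraction of sampled sites at which each species occurs, over all sites or
#' within one ecoregion.
#'
#' @param community a `community_data`.
#' @param ecoregion optional single ecoregion to restrict the site set.
#' @return named numeric vector in `[0, 1]`.
#' @export
occupancy <- function(community, ecoregion = NULL) {
  ab <- community$abundance
  if (!is.null(ecoregion)) {
    stopifnot(ecoregion %in% community$ecoregion)
    ab <- ab[community$ecoregion == ecoregion, , drop = FALSE]
  }
  colMeans(ab > 0)
}
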