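# Independent oracles used across the suite. Each deliberately takes a
# different route than the package implementation it checks.

# Brute-force Gower: explicit double loop over species pairs.
gower_oracle <- function(m) {
  m <- as.matrix(m)
  rng <- apply(m, 2, function(col) diff(range(col[is.finite(col)])))
  keep <- is.finite(rng) & rng > 0
  m <- m[, keep, drop = FALSE]
  rng <- rng[keep]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      terms <- numeric(0)
      for (k in seq_len(ncol(m))) {
        if (is.finite(m[i, k]) && is.finite(m[j, k]))
          terms <- c(terms, abs(m[i, k] - m[j, k]) / rng[k])
      }
      d[i, j] <- if (length(terms)) mean(terms) else NA_real_
    }
  }
  d
}

# 2-D hull area via base chull + shoelace (independent of the C++ path).
shoelace_area <- function(pts) {
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) return(NA_real_)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  abs(s) / 2
}

# Volume of an m-simplex from the determinant formula.
simplex_volume <- function(pts) {
  m <- ncol(pts)
  stopifnot(nrow(pts) == m + 1)
  abs(det(t(pts[-1, , drop = FALSE]) - pts[1, ])) / factorial(m)
}

# Exhaustive MNND: double loop over community members.
mnnd_oracle <- function(comm, d) {
  d <- as.matrix(d)
  vals <- vapply(comm, function(i) {
    min(vapply(setdiff(comm, i), function(j) d[i, j], numeric(1)))
  }, numeric(1))
  mean(vals)
}

# Literal 2^n sign-pattern enumeration of the signed-rank null (midranks).
wilcoxon_enum_oracle <- function(dif) {
  dif <- dif[dif != 0]
  n <- length(dif)
  stopifnot(n <= 12)
  r <- rank(abs(dif))
  V_obs <- sum(r[dif > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Vs <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(Vs <= V_obs + 1e-9)
  p_ge <- mean(Vs >= V_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Type-II SS by refitting nested lm() models and differencing deviances.
ancova_refit_oracle <- function(y, S, E) {
  df <- data.frame(y = y, S = as.numeric(S), E = factor(E))
  rss <- function(f) deviance(lm(f, data = df))
  full <- lm(y ~ S * E, data = df)
  df_res <- df.residual(full)
  ms <- deviance(full) / df_res
  ss <- c(S = rss(y ~ E) - rss(y ~ S + E),
          E = rss(y ~ S) - rss(y ~ S + E),
          `S:E` = rss(y ~ S + E) - deviance(full))
  dfs <- c(1, nlevels(df$E) - 1, nlevels(df$E) - 1)
  Fv <- (ss / dfs) / ms
  data.frame(term = names(ss), sum_sq = unname(ss), df = dfs, F = unname(Fv),
             p_value = pf(unname(Fv), dfs, df_res, lower.tail = FALSE))
}

# LP-feasibility oracle: batch of cases through one python/scipy process.
lp_in_hull_oracle <- function(cases) {
  payload <- lapply(cases, function(cs) {
    list(hull = apply(unname(cs$hull), 1, as.list),
         queries = apply(unname(cs$queries), 1, as.list))
  })
  infile <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  script <- test_path("lp_oracle.py")
  out <- system2("python", shQuote(script), stdout = TRUE,
                 stdin = infile)
  lapply(jsonlite::fromJSON(paste(out, collapse = ""),
                            simplifyVector = FALSE),
         function(x) as.logical(unlist(x)))
}

# Exhaustive null mean/sd over all C(|pool|, S) communities.
null_enum_oracle <- function(S, pool_species, metric, space = NULL, d = NULL,
                             standardize = FALSE) {
  combos <- utils::combn(pool_species, S, simplify = FALSE)
  vals <- vapply(combos, function(comm) {
    if (metric == "FRic") {
      f <- fric(comm, space, standardize = standardize)
      if (f$defined) f$value else NA_real_
    } else {
      mnnd_oracle(comm, d)
    }
  }, numeric(1))
  vals
}
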