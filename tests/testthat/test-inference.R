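test_that("wilcoxon_signed_rank exact branch matches hand values and enumeration", {
  # {1,2,3}: V = 6, the extreme statistic in 1/8 of sign patterns per tail
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$p_value, 0.25)
  expect_equal(r$statistic, 6)
  expect_equal(r$method, "exact")

  # perfectly antisymmetric sample
  expect_equal(wilcoxon_signed_rank(c(-2, 2))$p_value, 1)
  # all differences zero -> degenerate p = 1
  expect_equal(wilcoxon_signed_rank(c(0, 0, 0))$p_value, 1)

  # DP shift algorithm equals literal 2^n enumeration, ties included
  set.seed(131)
  for (rep in 1:20) {
    n <- sample(4:11, 1)
    x <- round(rnorm(n, 0.3), sample(0:1, 1))  # rounding induces ties/zeros
    x <- x[x != 0]
    if (length(x) < 2) next
    expect_equal(wilcoxon_signed_rank(x)$p_value, wilcoxon_enum_oracle(x),
                 tolerance = 1e-12, label = paste(x, collapse = ","))
  }
})

test_that("wilcoxon_signed_rank normal branch agrees with stats::wilcox.test", {
  set.seed(137)
  for (rep in 1:10) {
    x <- rnorm(30, 0.4)
    ours <- wilcoxon_signed_rank(x)
    expect_equal(ours$method, "normal")
    ref <- wilcox.test(x, mu = 0, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
  # with ties the tie-corrected approximation should still match
  y <- round(rnorm(40, 0.3), 1)
  y <- y[y != 0]
  expect_equal(wilcoxon_signed_rank(y)$p_value,
               suppressWarnings(wilcox.test(y, exact = FALSE, correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("exact and approximate wilcoxon branches agree near the switch point", {
  set.seed(139)
  for (rep in 1:10) {
    x <- rnorm(24, 0.5)
    exact_p <- wilcoxon_signed_rank(x)$p_value
    approx_p <- suppressWarnings(wilcox.test(x, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact_p - approx_p), 0.011)
  }
})

test_that("ancova_type2 reduces to type-I in balanced orthogonal designs", {
  set.seed(149)
  S <- rep(c(4, 6, 8, 10), times = 2)
  E <- rep(c("CLF", "NLF"), each = 4)   # S orthogonal to E by construction
  y <- rnorm(8)
  ours <- ancova_type2(y, S, E)
  a1 <- anova(lm(y ~ S * E, data = data.frame(y = y, S = S, E = factor(E))))
  expect_equal(ours$sum_sq, a1$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(ours$p_value, a1$`Pr(>F)`[1:3], tolerance = 1e-10)
})

test_that("ancova_type2 exact-fit limit: response = 2*S leaves nothing to E", {
  set.seed(151)
  S <- c(4, 5, 6, 7, 8, 9, 4, 6, 8, 10)
  E <- rep(c("CLF", "NLF"), each = 5)
  y <- 2 * S
  res <- ancova_type2(y, S, E)
  expect_lt(res$p_value[res$term == "S"], 1e-10)
  expect_equal(res$sum_sq[res$term == "E"], 0, tolerance = 1e-18)
  expect_equal(res$sum_sq[res$term == "S:E"], 0, tolerance = 1e-18)
})

test_that("ancova_type2 equals the nested-refit oracle on unbalanced designs", {
  set.seed(157)
  for (rep in 1:25) {
    n <- sample(12:40, 1)
    E <- sample(c("CLF", "NLF"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(E)) < 2) next
    S <- sample(4:12, n, replace = TRUE)
    if (any(tapply(S, E, function(v) length(unique(v))) < 2)) next
    y <- 0.3 * S + (E == "NLF") * rnorm(1) + rnorm(n)
    ours <- ancova_type2(y, S, E)
    oracle <- ancova_refit_oracle(y, S, E)
    expect_equal(ours$sum_sq, oracle$sum_sq, tolerance = 1e-8)
    expect_equal(ours$F, oracle$F, tolerance = 1e-8)
    expect_equal(ours$p_value, oracle$p_value, tolerance = 1e-8)
    expect_true(all(ours$p_value >= 0 & ours$p_value <= 1))
  }
})

test_that("ancova_type2 rejects rank-deficient and undersized designs", {
  expect_error(ancova_type2(rnorm(10), rep(5, 10), rep(c("CLF", "NLF"), 5)),
               class = "model_error")
  expect_error(ancova_type2(rnorm(4), 1:4, c("CLF", "CLF", "NLF", "NLF")),
               class = "model_error")
  expect_error(ancova_type2(rnorm(10), 1:10, rep("CLF", 10)),
               class = "model_error")
})

test_that("ses_richness_correlation computes per-ecoregion Pearson r", {
  ab <- matrix(1L, 8, 3, dimnames = list(paste0("s", 1:8), c("A", "B", "C")))
  ab[, 2] <- rep(c(0L, 1L), 4)  # vary richness across sites
  ab[1:2, 3] <- 0L
  cd <- community_data(ab, setNames(rep(c("CLF", "NLF"), each = 4),
                                    paste0("s", 1:8)))
  rich <- richness(cd)
  res <- data.frame(site_id = names(rich), richness = as.integer(rich),
                    ses = as.numeric(rich), stringsAsFactors = FALSE)
  out <- ses_richness_correlation(res, cd)
  expect_equal(out$r[out$group == "CLF"], 1, tolerance = 1e-12)
  expect_equal(out$r[out$group == "NLF"], 1, tolerance = 1e-12)

  # a group with a single usable site is flagged undefined
  res2 <- res[c(1, 5:8), ]
  out2 <- ses_richness_correlation(res2, cd)
  expect_false(out2$defined[out2$group == "CLF"])

  # independence: |r| small on simulated data
  set.seed(163)
  res3 <- data.frame(site_id = rep(names(rich), 50),
                     richness = sample(4:12, 400, replace = TRUE),
                     ses = rnorm(400))
  cd3 <- cd
  out3 <- ses_richness_correlation(res3, cd3)
  expect_true(all(abs(out3$r) < 0.15))
})

test_that("centrality_abundance_correlation has the right sign and exact p", {
  set.seed(167)
  coords <- matrix(rnorm(16), ncol = 2,
                   dimnames = list(paste0("sp", 1:8), NULL))
  sp <- space_from_coords(coords)
  cdist <- centroid_distances(sp)
  # abundance strictly decreasing in centroid distance -> rho = -1
  ab <- matrix(0L, 4, 8, dimnames = list(paste0("s", 1:4), names(cdist)))
  for (j in seq_len(8)) ab[, j] <- as.integer(round(100 - 10 * rank(cdist)[j]))
  cd <- community_data(ab, setNames(rep(c("CLF", "NLF"), 2), paste0("s", 1:4)))
  r <- centrality_abundance_correlation(sp, cd)
  expect_equal(r$rho, -1)
  expect_equal(r$method, "exact permutation")
  expect_lt(r$p_value, 0.001)

  # exact permutation p matches cor.test's exact p when there are no ties
  set.seed(173)
  ab2 <- matrix(rpois(4 * 8, 5) + 1L, 4, 8,
                dimnames = list(paste0("s", 1:4), names(cdist)))
  cd2 <- community_data(ab2, setNames(rep(c("CLF", "NLF"), 2), paste0("s", 1:4)))
  r2 <- centrality_abundance_correlation(sp, cd2, occupied_only = TRUE)
  avg <- colMeans(ab2)
  if (!anyDuplicated(avg) && !anyDuplicated(cdist)) {
    ref <- cor.test(cdist, avg, method = "spearman", exact = TRUE)
    expect_equal(r2$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(r2$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_lte(abs(r2$rho), 1)
})

test_that("centrality-abundance permutation p is calibrated under independence", {
  set.seed(179)
  n_sp <- 12
  coords <- matrix(rnorm(2 * n_sp), ncol = 2,
                   dimnames = list(paste0("sp", 1:n_sp), NULL))
  sp <- space_from_coords(coords)
  rhos <- replicate(300, {
    ab <- matrix(rpois(3 * n_sp, 4) + 1L, 3, n_sp,
                 dimnames = list(paste0("s", 1:3), paste0("sp", 1:n_sp)))
    cd <- community_data(ab, setNames(c("CLF", "NLF", "NLF"), paste0("s", 1:3)))
    centrality_abundance_correlation(sp, cd)$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("occupancy is the fraction of occupied sites, optionally by ecoregion", {
  ab <- matrix(0L, 36, 3, dimnames = list(sprintf("s%02d", 1:36),
                                          c("ubiquitous", "quarter", "south")))
  ab[, "ubiquitous"] <- 1L
  ab[1:9, "quarter"] <- 1L
  eco <- setNames(rep(c("CLF", "NLF"), c(15, 21)), rownames(ab))
  ab[eco == "CLF", "south"] <- 1L
  cd <- community_data(ab, eco)
  occ <- occupancy(cd)
  expect_equal(unname(occ["ubiquitous"]), 1)
  expect_equal(unname(occ["quarter"]), 0.25)
  expect_equal(unname(occupancy(cd, "NLF")["south"]), 0)
})
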