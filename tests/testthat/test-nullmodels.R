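make_tiny_community <- function() {
  ab <- rbind(s1 = c(2L, 1L, 0L, 0L), s2 = c(0L, 3L, 1L, 0L),
              s3 = c(0L, 0L, 2L, 2L))
  colnames(ab) <- c("A", "B", "C", "D")
  community_data(ab, c(s1 = "CLF", s2 = "CLF", s3 = "NLF"))
}

test_that("build_pools derives total and regional pools by set logic", {
  cd <- make_tiny_community()
  pools <- build_pools(cd)
  expect_setequal(pools$total$species, c("A", "B", "C", "D"))
  expect_setequal(pools$CLF$species, c("A", "B", "C"))
  expect_setequal(pools$NLF$species, c("C", "D"))
  # D is NLF-only: in NLF and total, not CLF
  expect_false("D" %in% pools$CLF$species)
  expect_true(all(pools$CLF$species %in% pools$total$species))

  # saturation: every species at every site -> total = CLF = NLF
  ab2 <- matrix(1L, 2, 3, dimnames = list(c("x", "y"), c("A", "B", "C")))
  pools2 <- build_pools(community_data(ab2, c(x = "CLF", y = "NLF")))
  expect_equal(pools2$CLF$species, pools2$total$species)
  expect_equal(pools2$NLF$species, pools2$total$species)

  # disjoint regional faunas partition the total pool
  ab3 <- rbind(x = c(1L, 1L, 0L, 0L), y = c(0L, 0L, 1L, 1L))
  colnames(ab3) <- c("A", "B", "C", "D")
  pools3 <- build_pools(community_data(ab3, c(x = "CLF", y = "NLF")))
  expect_length(intersect(pools3$CLF$species, pools3$NLF$species), 0)
  expect_setequal(union(pools3$CLF$species, pools3$NLF$species),
                  pools3$total$species)
})

test_that("randomize_community draws uniformly without replacement", {
  pool <- pool_of(c("A", "B", "C", "D"))
  expect_setequal(randomize_community(4, pool), pool$species)
  expect_error(randomize_community(5, pool), class = "infeasible_draw_error")

  # determinism under a fixed seed
  d1 <- local({ set.seed(5); replicate(10, randomize_community(2, pool)) })
  d2 <- local({ set.seed(5); replicate(10, randomize_community(2, pool)) })
  expect_identical(d1, d2)

  # uniformity: S = 1 from pool of 4, 10,000 draws, freq 0.25 +/- 0.02
  set.seed(101)
  draws <- replicate(10000, randomize_community(1, pool))
  freq <- table(factor(draws, levels = pool$species)) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
  chisq <- sum((table(draws) - 2500)^2 / 2500)
  expect_lt(chisq, qchisq(0.999, df = 3))
})

test_that("constrain_pool keeps exactly the species inside the community hull", {
  coords <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), d = c(0.3, 0.3),
                  e = c(5, 5), f = c(0.9, 0.9))
  sp <- space_from_coords(coords)
  pool <- pool_of(rownames(coords))
  comm <- c("a", "b", "c")
  cp <- constrain_pool(comm, pool, sp)
  expect_true(all(comm %in% cp$species))   # self-containment
  expect_true("d" %in% cp$species)         # interior point retained
  expect_false("e" %in% cp$species)        # periphery excluded
  expect_false("f" %in% cp$species)        # outside the triangle

  # pool = community -> constrained pool = community
  cp2 <- constrain_pool(comm, pool_of(comm), sp)
  expect_setequal(cp2$species, comm)

  # degenerate hull is a constraint error
  coll <- space_from_coords(rbind(a = c(0, 0), b = c(1, 1), c = c(2, 2),
                                  d = c(3, 3)))
  expect_error(constrain_pool(c("a", "b", "c"), pool_of(letters[1:4]), coll),
               class = "constraint_error")
})

test_that("null_distribution matches exhaustive enumeration for tiny pools", {
  set.seed(103)
  m <- random_trait_matrix(3, 4)
  d <- gower_matrix(m)
  pool <- pool_of(rownames(m))
  # S = 2 from a pool of 3: support is exactly the 3 pairwise distances
  nd <- local({ set.seed(1); null_distribution(2, pool, "MNND", 3000, d = d) })
  pairs <- c(d[1, 2], d[1, 3], d[2, 3])
  expect_true(all(vapply(nd, function(v) any(abs(v - pairs) < 1e-12), logical(1))))
  expect_setequal(round(unique(nd), 12), round(pairs, 12))

  # degenerate null: pool = community -> all values equal, sd 0, SES NA
  poolAB <- pool_of(c("sp01", "sp02"))
  ndeg <- local({ set.seed(2); null_distribution(2, poolAB, "MNND", 50, d = d) })
  expect_equal(sd(ndeg), 0)
  expect_true(is.na(ses(d[1, 2], ndeg)))
  expect_length(ndeg, 50)
})

test_that("permutation null mean/sd agree with full enumeration within MC error", {
  set.seed(107)
  m <- random_trait_matrix(8, 6)
  d <- gower_matrix(m)
  space <- build_trait_space(d, n_axes = 2)
  pool <- pool_of(rownames(m))
  for (metric in c("MNND", "FRic")) {
    for (S in c(3, 4)) {
      enum <- null_enum_oracle(S, pool$species, metric, space = space, d = d)
      enum <- enum[!is.na(enum)]
      nperm <- 2000
      nd <- local({
        set.seed(7)
        null_distribution(S, pool, metric, nperm, space = space, d = d,
                          standardize = FALSE)
      })
      nd <- nd[!is.na(nd)]
      se_mean <- sd(enum) / sqrt(length(nd))
      expect_lt(abs(mean(nd) - mean(enum)), 3 * se_mean + 1e-12)
      # sd comparison at a coarse Monte-Carlo tolerance
      expect_lt(abs(sd(nd) - sd(enum)), 4 * sd(enum) / sqrt(length(nd)) + 0.02 * sd(enum))
    }
  }
})

test_that("ses follows the (obs - mean)/sd definition with n-1 denominator", {
  expect_true(is.na(ses(2, c(1, 1, 1))))
  expect_equal(ses(2, c(0.5, 1, 1.5)), (2 - 1) / sd(c(0.5, 1, 1.5)))
  expect_equal(ses(1, c(0.5, 1, 1.5)), 0)
  expect_true(is.na(ses(2, c(1, NA))))  # fewer than 2 valid values
})

test_that("SES is invariant to strictly positive rescaling of the metric", {
  set.seed(109)
  m <- random_trait_matrix(8, 5)
  d <- gower_matrix(m)
  pool <- pool_of(rownames(m))
  comm <- rownames(m)[1:4]
  obs <- mnnd(comm, d)$value
  nd <- local({ set.seed(3); null_distribution(4, pool, "MNND", 500, d = d) })
  nd7 <- local({ set.seed(3); null_distribution(4, pool, "MNND", 500, d = d * 7) })
  expect_equal(ses(obs, nd), ses(obs * 7, nd7), tolerance = 1e-12)
})

test_that("constrained null draws have FRic bounded by the observed FRic", {
  set.seed(113)
  coords <- matrix(rnorm(40), ncol = 2,
                   dimnames = list(sprintf("sp%02d", 1:20), NULL))
  sp <- space_from_coords(coords)
  pool <- pool_of(sp$species)
  comm <- sample(sp$species, 8)
  obs <- fric(comm, sp, standardize = FALSE)
  cp <- constrain_pool(comm, pool, sp)
  for (i in 1:200) {
    draw <- randomize_community(length(comm), cp)
    v <- fric(draw, sp, standardize = FALSE)$value
    if (!is.na(v)) expect_lte(v, obs$value + 1e-9)
  }
})

test_that("run_null_analysis bookkeeping, determinism and flagged skips", {
  set.seed(127)
  meta <- generate_metacommunity(scenario_config(
    n_sites = c(CLF = 3L, NLF = 4L), richness_range = c(3L, 8L), seed = 12))
  traits <- aggregate_species(meta$records)
  d <- gower_matrix(traits)
  space <- build_trait_space(d, community_sizes = richness(meta$community))
  cfg <- run_config(n_permutations = 99, seed = 77)
  res <- run_null_analysis(meta$community, space, d, cfg)
  n_sites <- nrow(meta$community$abundance)
  # <= sites x (2 metrics x 2 pools unconstrained + 2 pools constrained MNND)
  expect_lte(nrow(res), n_sites * 6)
  expect_true(all(res$n_valid_perm <= res$n_perm))
  expect_true(all(res$metric[res$variant == "constrained"] == "MNND"))
  # flagged rows carry reasons instead of aborting
  expect_true(all(!is.na(res$reason[!res$defined & !is.na(res$observed) |
                                      is.na(res$observed)]) | res$defined))
  # rerun with the same seed is bit-identical
  res2 <- run_null_analysis(meta$community, space, d, cfg)
  expect_identical(res, res2)
  # order independence: site-level results survive site reordering
  perm <- rev(rownames(meta$community$abundance))
  cd_rev <- community_data(meta$community$abundance[perm, ],
                           meta$community$ecoregion,
                           meta$community$locality)
  res_rev <- run_null_analysis(cd_rev, space, d, cfg)
  key <- function(r) paste(r$site_id, r$metric, r$pool_definition, r$variant)
  shared <- intersect(key(res), key(res_rev))
  expect_equal(res$ses[match(shared, key(res))],
               res_rev$ses[match(shared, key(res_rev))])
})
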