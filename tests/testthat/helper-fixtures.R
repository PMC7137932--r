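# Programmatic fixtures; nothing is stored on disk except what a test writes
# to its own tempdir.

measurement_row <- function(specimen_id, species, site_id, session_id = NA,
                            WT = 8, HB = 80, T = 56, HF = 13, E = 8,
                            CI = 20, GW = 9, IW = 4.4, UTR = 8.8, LTR = 8) {
  data.frame(specimen_id = specimen_id, species = species, site_id = site_id,
             session_id = session_id, WT = WT, HB = HB, T = T, HF = HF, E = E,
             CI = CI, GW = GW, IW = IW, UTR = UTR, LTR = LTR,
             stringsAsFactors = FALSE)
}

tiny_records <- function() {
  rbind(
    measurement_row("s1", "crocidura_a", "site1", WT = 8.2),
    measurement_row("s2", "crocidura_a", "site1", WT = 7.9),
    measurement_row("s3", "crocidura_b", "site1", WT = 15, HB = 95, CI = 23),
    measurement_row("s4", "crocidura_b", "site2", WT = 14.5, HB = 96, CI = 23.2),
    measurement_row("s5", "sylvisorex_a", "site2", WT = 3.5, HB = 55, CI = 15))
}

tiny_site_meta <- function() {
  data.frame(site_id = c("site1", "site2"),
             locality = c("locA", "locB"),
             ecoregion = c("CLF", "NLF"),
             stringsAsFactors = FALSE)
}

# A trait_space with known coordinates (bypasses PCoA); hull-based metrics
# are rotation-invariant, so tests can reason directly in these coords.
space_from_coords <- function(coords) {
  coords <- as.matrix(coords)
  if (is.null(rownames(coords)))
    rownames(coords) <- paste0("sp", seq_len(nrow(coords)))
  structure(list(species = rownames(coords),
                 coords = coords, m = ncol(coords),
                 eigenvalues = rep(1, ncol(coords)),
                 correction = "none", stress = 0),
            class = "trait_space")
}

pool_of <- function(species, name = "total", definition = "total") {
  structure(list(name = name, species = sort(species), definition = definition),
            class = "species_pool")
}

# Random species x trait matrix with optional missingness.
random_trait_matrix <- function(n_species = 8, n_traits = 10, na_frac = 0) {
  m <- matrix(runif(n_species * n_traits), n_species,
              dimnames = list(sprintf("sp%02d", seq_len(n_species)),
                              paste0("tr", seq_len(n_traits))))
  if (na_frac > 0) {
    idx <- which(runif(length(m)) < na_frac)
    # never blank a full row
    keep <- seq_len(n_species)
    m[idx] <- NA
    for (i in keep) if (all(is.na(m[i, ]))) m[i, 1] <- runif(1)
  }
  m
}
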