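small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_proteins = 8, protein_length_range = c(120, 180)),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(ortholog_divergence = 1.2))
  expect_error(sim_config(replicates_per_type = 1))
  expect_error(sim_config(mixed_ratios = c(5, -1)))
  expect_error(sim_config(origin_mixture = c(tumor_only = 0.5,
                                             stroma_only = 0.2,
                                             mixed = 0.2)))
})

test_that("ortholog pairs preserve the tryptic map; divergence controls
          sharing", {
  pp <- simulate_proteome_pair(small_cfg(ortholog_divergence = 0.05), 3)
  expect_equal(nchar(pp$human$sequence), nchar(pp$mouse$sequence))
  for (i in seq_len(nrow(pp$human))) {
    h <- strsplit(pp$human$sequence[i], "")[[1]]
    m <- strsplit(pp$mouse$sequence[i], "")[[1]]
    krp <- h %in% c("K", "R", "P") | m %in% c("K", "R", "P")
    expect_identical(h[krp], m[krp])   # K/R/P never touched or introduced
  }

  # divergence 0: every tryptic peptide is shared
  pp0 <- simulate_proteome_pair(small_cfg(ortholog_divergence = 0), 3)
  expect_identical(pp0$human$sequence, pp0$mouse$sequence)

  # divergence 1: no peptide containing a substitutable position is shared
  pp1 <- simulate_proteome_pair(small_cfg(ortholog_divergence = 1), 3)
  hp <- unlist(lapply(pp1$human$sequence,
                      function(s) digest(s, 0, 6, 50)$peptide))
  mp <- unlist(lapply(pp1$mouse$sequence,
                      function(s) digest(s, 0, 6, 50)$peptide))
  substitutable <- function(p) {
    stringr::str_detect(p, "[^KRP]")
  }
  expect_length(intersect(hp[substitutable(hp)], mp[substitutable(mp)]), 0)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_cfg()
  a <- simulate_psm_tables(cfg, 5)
  b <- simulate_psm_tables(cfg, 5)
  expect_identical(a$psm_tables, b$psm_tables)
  expect_identical(a$proteomes, b$proteomes)
  c <- simulate_psm_tables(cfg, 6)
  expect_false(identical(a$psm_tables, c$psm_tables))
})

test_that("tumor-only proteins yield no mouse PSMs; zero decoy fraction
          yields none", {
  cfg <- small_cfg(origin_mixture = c(tumor_only = 1, stroma_only = 0,
                                      mixed = 0),
                   origin_shift_fraction = 0,
                   decoy_psm_fraction = 0)
  sim <- simulate_psm_tables(cfg, 9)
  for (tab in sim$psm_tables) {
    expect_true(all(tab$true_species == "human"))
    expect_false(any(tab$is_decoy))
  }
})

test_that("mixed-origin intensity ratios average to the configured ratio", {
  cfg <- small_cfg(n_proteins = 4,
                   ortholog_divergence = 0.1,
                   origin_mixture = c(tumor_only = 0, stroma_only = 0,
                                      mixed = 1),
                   mixed_ratios = 10,
                   origin_shift_fraction = 0,
                   replicate_sdlog = 0,
                   # abundance-independent detection keeps the two species'
                   # detection probabilities equal, so the Monte-Carlo mean
                   # of the log ratio is the configured log(10)
                   detection_max = 0.9,
                   detection_midpoint_log = -Inf)
  pp <- simulate_proteome_pair(cfg, 2)
  idx <- build_peptide_index(pp$human, pp$mouse,
                             xeno_params(max_missed_cleavages = 0))
  n_mc <- 200
  log_ratios <- vapply(seq_len(n_mc), function(i) {
    sim <- simulate_psm_tables(cfg, 1000 + i, proteomes = pp)
    tab <- sim$psm_tables[["tumorA_r1"]]
    lab <- index_lookup(idx, tab$peptide_sequence)$species_label
    log(sum(tab$precursor_intensity[lab == "human_specific"]) /
          sum(tab$precursor_intensity[lab == "mouse_specific"]))
  }, numeric(1))
  se <- stats::sd(log_ratios) / sqrt(n_mc)
  expect_lt(abs(mean(log_ratios) - log(10)), 3 * se + 1e-12)
})

test_that("ground truth restates the config: Venn arithmetic and origin
          tallies", {
  cfg <- sim_config(n_proteins = 100,
                    fraction_shared_between_tumor_types = 0.6,
                    type_specific_balance = 0.5)
  truth <- ground_truth_signature(cfg)
  expect_equal(unname(truth$venn), c(60, 20, 20))
  expect_equal(length(truth$matrisome_A), 80)
  expect_equal(length(truth$matrisome_B), 80)
  expect_setequal(c(truth$origin_same, truth$origin_shifted),
                  intersect(truth$matrisome_A, truth$matrisome_B))

  # everything shared -> no type-specific sets
  all_shared <- ground_truth_signature(
    sim_config(n_proteins = 20, fraction_shared_between_tumor_types = 1))
  expect_equal(unname(all_shared$venn), c(20, 0, 0))

  # all tumor_only origins -> no origin shifts
  no_shift <- ground_truth_signature(
    sim_config(n_proteins = 20,
               origin_mixture = c(tumor_only = 1, stroma_only = 0, mixed = 0),
               origin_shift_fraction = 0))
  expect_length(no_shift$origin_shifted, 0)
  expect_true(all(no_shift$origin_A$origin_class == "tumor_only"))
})

test_that("simulated score support respects the maximum peptide score", {
  sim <- simulate_psm_tables(small_cfg(), 4)
  for (tab in sim$psm_tables) {
    expect_true(all(tab$score >= 0 & tab$score <= 25))
    expect_true(all(tab$charge %in% 2:4))
  }
})
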