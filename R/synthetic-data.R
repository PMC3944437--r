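# Ground-truthed simulation of ortholog proteome pairs and PSM tables.

# Average amino-acid frequencies (vertebrate-like); K+R ~ 11% so tryptic
# peptides average roughly 9 residues.
AA_FREQS <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.068, F = 0.047, G = 0.074,
  H = 0.026, I = 0.038, K = 0.058, L = 0.076, M = 0.018, N = 0.045,
  P = 0.050, Q = 0.037, R = 0.052, S = 0.081, T = 0.062, V = 0.068,
  W = 0.013, Y = 0.034
)

SIM_TUMOR_TYPES <- c("tumorA", "tumorB")

#' Configuration of the synthetic xenoproteome experiment
#'
#' Defines the study conditions the simulator emulates: two tumor types with
#' two biological replicates each, proteins drawn from human/mouse ortholog
#' pairs with controlled sequence divergence, log-normal protein abundance
#' with detection probability saturating in abundance, per-charge target and
#' decoy score distributions bounded by the maximum peptide score of 25, and
#' per-protein ground-truth origin mixtures (tumor-only, stroma-only, or
#' mixed with a known human:mouse ratio).
#'
#' Gene-to-tumor-type and gene-to-origin assignments are deterministic
#' functions of the configuration (not of the seed), so
#' [ground_truth_signature()] can restate the expected downstream answer
#' from the config alone; the seed drives sequences, abundances, detection,
#' scores, and noise.
#'
#' @param n_proteins Number of ortholog pairs (genes) simulated.
#' @param protein_length_range Length range (residues) of simulated
#'   proteins.
#' @param ortholog_divergence Per-residue substitution probability between
#'   ortholog sequences; K, R, and P positions are never substituted so the
#'   tryptic map is identical in the two species and divergence controls
#'   only how many peptides are species-specific.
#' @param fraction_shared_between_tumor_types Fraction of genes present in
#'   both tumor types.
#' @param type_specific_balance Fraction of the non-shared genes assigned to
#'   tumor type A.
#' @param origin_mixture Named numeric proportions over `tumor_only`,
#'   `stroma_only`, `mixed`.
#' @param mixed_ratios Human:mouse intensity ratios cycled over the
#'   mixed-origin genes.
#' @param origin_shift_fraction Fraction of the shared genes whose coarse
#'   origin (tumor / stroma / both) differs between the two tumor types.
#' @param abundance_meanlog,abundance_sdlog Log-normal protein abundance
#'   (summed ion-current units) per gene and tumor type.
#' @param replicate_sdlog Log-normal spread of the replicate-to-replicate
#'   abundance multiplier.
#' @param detection_max,detection_midpoint_log,detection_slope Peptide
#'   detection probability `detection_max * plogis((log(A) -
#'   detection_midpoint_log) / detection_slope)` where A is the species-level
#'   protein abundance. Set `detection_max = 1, detection_midpoint_log =
#'   -Inf` for certain detection.
#' @param target_score_mean,target_score_sd,decoy_score_mean,decoy_score_sd
#'   Per-charge normal score models (named by charge, truncated to
#'   \[0, 25\]).
#' @param charge_probs Sampling probabilities of precursor charges 2/3/4.
#' @param decoy_psm_fraction Fraction of PSM rows drawn from the decoy score
#'   distribution (matched to reversed-sequence entries).
#' @param intensity_noise_sdlog Multiplicative log-normal noise on precursor
#'   intensities.
#' @param poor_quality_fraction Fraction of PSMs flagged with a poorly
#'   defined isotope cluster.
#' @param modified_psm_fraction Probability that a detected Met-containing
#'   peptide also yields an oxidized-Met PSM (exercises distinct-peptide
#'   collapsing).
#' @param replicates_per_type Biological replicates per tumor type (the
#'   membership rule needs two).
#' @param seed Default seed carried by the config.
#' @return A list of class `xeno_sim_config`.
#' @export
sim_config <- function(n_proteins = 120,
                       protein_length_range = c(240, 420),
                       ortholog_divergence = 0.05,
                       fraction_shared_between_tumor_types = 0.6,
                       type_specific_balance = 0.5,
                       origin_mixture = c(tumor_only = 0.4,
                                          stroma_only = 0.25,
                                          mixed = 0.35),
                       mixed_ratios = c(10, 1, 0.1),
                       origin_shift_fraction = 0.3,
                       abundance_meanlog = log(2e7),
                       abundance_sdlog = 1,
                       replicate_sdlog = 0.2,
                       detection_max = 0.92,
                       detection_midpoint_log = log(2e6),
                       detection_slope = 1,
                       target_score_mean = c(`2` = 13, `3` = 14, `4` = 15),
                       target_score_sd = 3.5,
                       decoy_score_mean = c(`2` = 5, `3` = 6, `4` = 7),
                       decoy_score_sd = 2.5,
                       charge_probs = c(`2` = 0.55, `3` = 0.33, `4` = 0.12),
                       decoy_psm_fraction = 0.05,
                       intensity_noise_sdlog = 0.25,
                       poor_quality_fraction = 0.02,
                       modified_psm_fraction = 0.05,
                       replicates_per_type = 2L,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$ortholog_divergence, cfg$fraction_shared_between_tumor_types,
             cfg$type_specific_balance, cfg$origin_mixture,
             cfg$origin_shift_fraction, cfg$detection_max,
             cfg$decoy_psm_fraction, cfg$poor_quality_fraction,
             cfg$modified_psm_fraction, cfg$charge_probs)
  stopifnot(
    n_proteins >= 1,
    all(probs >= 0), all(probs <= 1),
    all(mixed_ratios > 0),
    replicates_per_type >= 2,
    abs(sum(origin_mixture) - 1) < 1e-8,
    length(protein_length_range) == 2,
    protein_length_range[1] >= 30
  )
  structure(cfg, class = "xeno_sim_config")
}

#' @export
print.xeno_sim_config <- function(x, ...) {
  cat("<xeno_sim_config> ", x$n_proteins, " ortholog pairs, divergence ",
      x$ortholog_divergence, ", ", x$replicates_per_type,
      " replicates per tumor type\n", sep = "")
  invisible(x)
}

#' Deterministic gene assignments implied by a simulation config
#'
#' Restates the configuration as per-gene facts: tumor-type membership
#' (shared genes first, then type-A-specific, then type-B-specific), origin
#' class and intended human:mouse ratio per tumor type, and which shared
#' genes shift coarse origin between the types.
#'
#' @param config An [sim_config()] object.
#' @return A tibble: `gene`, `in_A`, `in_B`, `class_A`, `ratio_A`,
#'   `class_B`, `ratio_B` (`class_*` over tumor_only / stroma_only / mixed;
#'   ratios are human:mouse weights, `NA` where the gene is absent).
#' @export
config_assignments <- function(config) {
  n <- config$n_proteins
  genes <- sprintf("SIMG%03d", seq_len(n))
  n_shared <- round(n * config$fraction_shared_between_tumor_types)
  n_a_only <- round((n - n_shared) * config$type_specific_balance)
  in_a <- seq_len(n) <= n_shared | (seq_len(n) > n_shared &
                                      seq_len(n) <= n_shared + n_a_only)
  in_b <- seq_len(n) <= n_shared | seq_len(n) > n_shared + n_a_only

  base <- assign_origin_cycle(n, config$origin_mixture, config$mixed_ratios)
  class_a <- ifelse(in_a, base$class, NA)
  ratio_a <- ifelse(in_a, base$ratio, NA)

  # Type B: shifted shared genes take a different coarse origin; everything
  # else keeps the type-A assignment; B-only genes use the base cycle.
  class_b <- ifelse(in_b, base$class, NA)
  ratio_b <- ifelse(in_b, base$ratio, NA)
  n_shift <- round(n_shared * config$origin_shift_fraction)
  if (n_shift > 0) {
    idx <- seq_len(n_shift)
    shifted <- shift_origin(base$class[idx], base$ratio[idx],
                            config$mixed_ratios)
    class_b[idx] <- shifted$class
    ratio_b[idx] <- shifted$ratio
  }
  tibble::tibble(gene = genes, in_A = in_a, in_B = in_b,
                 class_A = class_a, ratio_A = ratio_a,
                 class_B = class_b, ratio_B = ratio_b)
}

# Cycle origin classes over genes in configured proportions (a repeating
# unit at 1/20 granularity, so every tumor-type subset sees every class);
# mixed genes cycle through the configured ratios.
assign_origin_cycle <- function(n, mixture, mixed_ratios) {
  unit_counts <- pmax(round(mixture * 20), ifelse(mixture > 0, 1, 0))
  unit <- rep(names(mixture), unit_counts)
  cls <- rep_len(unit, n)
  ratio <- rep(NA_real_, n)
  mixed_idx <- which(cls == "mixed")
  if (length(mixed_idx) > 0) {
    ratio[mixed_idx] <- mixed_ratios[((seq_along(mixed_idx) - 1) %%
                                        length(mixed_ratios)) + 1]
  }
  ratio[cls == "tumor_only"] <- Inf
  ratio[cls == "stroma_only"] <- 0
  list(class = cls, ratio = ratio)
}

# Deterministic alternate origin with a different coarse class.
shift_origin <- function(class, ratio, mixed_ratios) {
  new_class <- dplyr::case_when(
    class == "tumor_only" ~ "mixed",
    class == "stroma_only" ~ "mixed",
    TRUE ~ "tumor_only"
  )
  new_ratio <- dplyr::case_when(
    new_class == "tumor_only" ~ Inf,
    class == "tumor_only" ~ mixed_ratios[1],
    TRUE ~ mixed_ratios[length(mixed_ratios)]
  )
  list(class = new_class, ratio = new_ratio)
}

#' Simulate a human/mouse ortholog proteome pair
#'
#' Each human protein gets one mouse ortholog derived by independent
#' per-residue substitution at rate `ortholog_divergence`. Lysine, arginine,
#' and proline positions are never substituted (and never introduced), so
#' both orthologs share an identical tryptic cleavage map and divergence
#' controls only which peptides are species-specific.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed (defaults to the config's).
#' @return A list: `human` and `mouse` proteome tibbles, `ortholog_map`
#'   tibble (`gene`, `human_accession`, `mouse_accession`).
#' @export
simulate_proteome_pair <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_proteins
  genes <- sprintf("SIMG%03d", seq_len(n))
  lens <- sample(config$protein_length_range[1]:config$protein_length_range[2],
                 n, replace = TRUE)
  aa <- names(AA_FREQS)
  substitutable <- setdiff(aa, c("K", "R", "P"))
  sub_freqs <- AA_FREQS[substitutable] / sum(AA_FREQS[substitutable])
  human_seq <- character(n)
  mouse_seq <- character(n)
  for (i in seq_len(n)) {
    h <- sample(aa, lens[i], replace = TRUE, prob = AA_FREQS)
    m <- h
    can_sub <- !(h %in% c("K", "R", "P"))
    hit <- can_sub & stats::runif(lens[i]) < config$ortholog_divergence
    if (any(hit)) {
      m[hit] <- vapply(h[hit], function(orig) {
        sample(setdiff(substitutable, orig), 1,
               prob = sub_freqs[setdiff(substitutable, orig)] /
                 sum(sub_freqs[setdiff(substitutable, orig)]))
      }, character(1))
    }
    human_seq[i] <- paste(h, collapse = "")
    mouse_seq[i] <- paste(m, collapse = "")
  }
  human <- tibble::tibble(
    accession = paste0("HUM_", genes), species = "human",
    gene_symbol = genes, sequence = human_seq, is_decoy = FALSE
  )
  mouse <- tibble::tibble(
    accession = paste0("MOU_", genes), species = "mouse",
    gene_symbol = paste0(substr(genes, 1, 1),
                         tolower(substr(genes, 2, nchar(genes)))),
    sequence = mouse_seq, is_decoy = FALSE
  )
  list(
    human = human, mouse = mouse,
    ortholog_map = tibble::tibble(gene = genes,
                                  human_accession = human$accession,
                                  mouse_accession = mouse$accession)
  )
}

#' Matrisome annotation for the simulated genes
#'
#' The simulator emulates an ECM-enriched sample, so every simulated gene is
#' matrisome-annotated, cycling through the six categories.
#'
#' @param config An [sim_config()] object.
#' @return An `xeno_annotation` tibble.
#' @export
simulate_annotation <- function(config) {
  genes <- sprintf("SIMG%03d", seq_len(config$n_proteins))
  cats <- rep_len(c(CORE_CATEGORIES, ASSOCIATED_CATEGORIES), length(genes))
  as_annotation(tibble::tibble(
    gene = genes,
    division = ifelse(cats %in% CORE_CATEGORIES, "core_matrisome",
                      "matrisome_associated"),
    category = cats
  ))
}

#' Simulate PSM tables for both tumor types
#'
#' For each tumor type and biological replicate, every present gene draws a
#' log-normal abundance split between the human (tumor) and mouse (stroma)
#' forms according to its origin; each species' zero-missed-cleavage tryptic
#' peptides are detected with probability saturating in the species-level
#' abundance, and each detected peptide yields one PSM at a sampled charge
#' with a target-model score and an intensity proportional to the species
#' abundance under multiplicative log-normal noise. Decoy rows with
#' decoy-model scores are mixed in at the configured fraction, and a small
#' fraction of PSMs is flagged with poor isotope quality.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed (defaults to the config's).
#' @param proteomes Optionally a pre-built [simulate_proteome_pair()]
#'   result; when `NULL`, one is generated from the same config and seed.
#' @return A list: `psm_tables` (named list `<type>_r<k>` of PSM tibbles
#'   with extra ground-truth columns `true_gene`, `true_species`),
#'   `proteomes`, `annotation`, `assignments` (see [config_assignments()]),
#'   `config`, `seed`.
#' @export
simulate_psm_tables <- function(config, seed = config$seed,
                                proteomes = NULL) {
  if (is.null(proteomes)) {
    proteomes <- simulate_proteome_pair(config, seed)
  }
  set.seed(seed + 1L)
  assign <- config_assignments(config)
  params <- xeno_params(max_missed_cleavages = 0L)
  # peptide pools per gene and species (zero missed cleavages, length 6-50)
  pool <- list(
    human = split_peptides(proteomes$human, params),
    mouse = split_peptides(proteomes$mouse, params)
  )
  decoy_pool <- dplyr::bind_rows(
    digest_proteome(add_decoys(proteomes$human), params),
    digest_proteome(add_decoys(proteomes$mouse), params)
  )
  decoy_pool <- decoy_pool[decoy_pool$is_decoy, , drop = FALSE]

  charges <- as.integer(names(config$charge_probs))
  tables <- list()
  for (type in SIM_TUMOR_TYPES) {
    col_in <- if (type == "tumorA") "in_A" else "in_B"
    col_ratio <- if (type == "tumorA") "ratio_A" else "ratio_B"
    genes <- assign[assign[[col_in]], , drop = FALSE]
    for (r in seq_len(config$replicates_per_type)) {
      rows <- vector("list", nrow(genes) * 2L)
      k <- 0L
      for (gi in seq_len(nrow(genes))) {
        gene <- genes$gene[gi]
        ratio <- genes[[col_ratio]][gi]
        w_h <- if (is.infinite(ratio)) 1 else ratio / (1 + ratio)
        w_m <- 1 - w_h
        base <- stats::rlnorm(1, config$abundance_meanlog,
                              config$abundance_sdlog) *
          stats::rlnorm(1, 0, config$replicate_sdlog)
        for (sp in c("human", "mouse")) {
          w <- if (sp == "human") w_h else w_m
          if (w <= 0) next
          abund <- base * w
          peps <- pool[[sp]][[gene]]
          p_det <- detection_prob(abund, config)
          det <- peps[stats::runif(length(peps)) < p_det]
          if (length(det) == 0) next
          ch <- sample(charges, length(det), replace = TRUE,
                       prob = config$charge_probs)
          score <- trunc_score(
            stats::rnorm(length(det),
                         config$target_score_mean[as.character(ch)],
                         config$target_score_sd))
          k <- k + 1L
          rows[[k]] <- tibble::tibble(
            peptide_sequence = det,
            modifications = "",
            charge = ch,
            score = score,
            precursor_intensity = abund *
              stats::rlnorm(length(det), 0, config$intensity_noise_sdlog),
            good_isotope_quality = stats::runif(length(det)) >=
              config$poor_quality_fraction,
            sample_id = paste0(type, "_r", r),
            replicate_id = paste0("r", r),
            fraction_id = "f1",
            is_decoy = FALSE,
            true_gene = gene,
            true_species = sp
          )
        }
      }
      tab <- dplyr::bind_rows(rows[seq_len(k)])
      tab <- add_modified_psms(tab, config)
      tab <- add_decoy_psms(tab, decoy_pool, config, type, r, charges)
      tables[[paste0(type, "_r", r)]] <- tab
    }
  }
  list(
    psm_tables = tables,
    proteomes = proteomes,
    annotation = simulate_annotation(config),
    assignments = assign,
    config = config,
    seed = seed
  )
}

split_peptides <- function(proteome, params) {
  dg <- digest_proteome(proteome, params)
  key <- toupper(proteome$gene_symbol)
  split(dg$peptide, toupper(dg$gene_symbol))[key] |>
    stats::setNames(key)
}

detection_prob <- function(abundance, config) {
  if (is.infinite(config$detection_midpoint_log) &&
      config$detection_midpoint_log < 0) {
    return(config$detection_max)
  }
  config$detection_max *
    stats::plogis((log(abundance) - config$detection_midpoint_log) /
                    config$detection_slope)
}

trunc_score <- function(x) pmin(25, pmax(0, x))

# Occasional oxidized-Met duplicate PSMs of detected peptides.
add_modified_psms <- function(tab, config) {
  if (nrow(tab) == 0 || config$modified_psm_fraction <= 0) {
    return(tab)
  }
  has_m <- stringr::str_detect(tab$peptide_sequence, "M")
  pick <- which(has_m & stats::runif(nrow(tab)) < config$modified_psm_fraction)
  if (length(pick) == 0) {
    return(tab)
  }
  extra <- tab[pick, , drop = FALSE]
  mpos <- stringr::str_locate(extra$peptide_sequence, "M")[, 1]
  extra$modifications <- paste0(mpos, ":oxidation_M")
  extra$score <- trunc_score(extra$score - stats::runif(nrow(extra), 0, 4))
  extra$precursor_intensity <- extra$precursor_intensity *
    stats::runif(nrow(extra), 0.05, 0.3)
  dplyr::bind_rows(tab, extra)
}

add_decoy_psms <- function(tab, decoy_pool, config, type, r, charges) {
  if (config$decoy_psm_fraction <= 0 || nrow(tab) == 0) {
    return(tab)
  }
  n_dec <- round(nrow(tab) * config$decoy_psm_fraction /
                   (1 - config$decoy_psm_fraction))
  if (n_dec == 0) {
    return(tab)
  }
  i <- sample.int(nrow(decoy_pool), n_dec, replace = TRUE)
  ch <- sample(charges, n_dec, replace = TRUE, prob = config$charge_probs)
  dec <- tibble::tibble(
    peptide_sequence = decoy_pool$peptide[i],
    modifications = "",
    charge = ch,
    score = trunc_score(stats::rnorm(n_dec,
                                     config$decoy_score_mean[as.character(ch)],
                                     config$decoy_score_sd)),
    precursor_intensity = stats::rlnorm(n_dec,
                                        config$abundance_meanlog - 3, 1),
    good_isotope_quality = stats::runif(n_dec) >=
      config$poor_quality_fraction,
    sample_id = paste0(type, "_r", r),
    replicate_id = paste0("r", r),
    fraction_id = "f1",
    is_decoy = TRUE,
    true_gene = NA_character_,
    true_species = NA_character_
  )
  dplyr::bind_rows(tab, dec)
}

#' Expected downstream answer implied by a simulation config
#'
#' Deterministically restates the configuration as the expected
#' signature: per-type matrisome gene sets, Venn counts, expected origin
#' classes per gene and tumor type, and the same/shifted partition of the
#' shared genes under the coarse (tumor / stroma / both) classes.
#'
#' @param config An [sim_config()] object.
#' @return A list: `matrisome_A`, `matrisome_B` (gene sets), `venn` (named
#'   counts shared/A_only/B_only), `origin_A`, `origin_B` (tibbles `gene`,
#'   `origin_class`), `origin_same`, `origin_shifted` (gene sets),
#'   `assignments`.
#' @export
ground_truth_signature <- function(config) {
  assign <- config_assignments(config)
  expected_class <- function(class, ratio) {
    dplyr::case_when(
      class == "tumor_only" ~ "tumor_only",
      class == "stroma_only" ~ "stroma_only",
      ratio >= 5 ~ "both_tumor_dominant",
      ratio <= 1 / 5 ~ "both_stroma_dominant",
      TRUE ~ "both_similar"
    )
  }
  a <- assign[assign$in_A, , drop = FALSE]
  b <- assign[assign$in_B, , drop = FALSE]
  origin_a <- tibble::tibble(
    gene = a$gene, origin_class = expected_class(a$class_A, a$ratio_A))
  origin_b <- tibble::tibble(
    gene = b$gene, origin_class = expected_class(b$class_B, b$ratio_B))
  shared <- intersect(a$gene, b$gene)
  ca <- coarse_origin(origin_a$origin_class[match(shared, origin_a$gene)])
  cb <- coarse_origin(origin_b$origin_class[match(shared, origin_b$gene)])
  list(
    matrisome_A = a$gene,
    matrisome_B = b$gene,
    venn = c(shared = length(shared),
             A_only = length(setdiff(a$gene, b$gene)),
             B_only = length(setdiff(b$gene, a$gene))),
    origin_A = origin_a,
    origin_B = origin_b,
    origin_same = shared[ca == cb],
    origin_shifted = shared[ca != cb],
    assignments = assign
  )
}

#' A configuration for exact end-to-end recovery
#'
#' The default config with every stochastic nuisance switched off: certain
#' detection, zero intensity noise, zero decoy fraction, no poor-quality or
#' modified PSMs, and mixed ratios outside (1/5, 5) so every origin class is
#' deterministic.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return An [sim_config()] object.
#' @export
recovery_config <- function(...) {
  sim_config(
    detection_max = 1,
    detection_midpoint_log = -Inf,
    intensity_noise_sdlog = 0,
    replicate_sdlog = 0,
    decoy_psm_fraction = 0,
    poor_quality_fraction = 0,
    modified_psm_fraction = 0,
    mixed_ratios = c(25, 0.04),
    ...
  )
}
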