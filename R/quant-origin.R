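# Label-free quantification by summed precursor intensity of
# species-specific peptides, and the fivefold tumor/stroma origin rule.

ORIGIN_CLASSES <- c("tumor_only", "stroma_only", "both_similar",
                    "both_tumor_dominant", "both_stroma_dominant",
                    "undetermined")

#' Quantifiable peptide precursor ions of a subgroup table
#'
#' A peptide is not quantifiable when it is shared across multiple subgroups
#' of its group (its signal cannot be apportioned) or when its precursor had
#' a poorly defined isotope cluster. Remaining PSMs are reduced to precursor
#' ions: one (peptide, charge) contribution per sample, summed across
#' fractions (the best PSM per fraction carries the fraction's intensity).
#'
#' @param subgroups An `xeno_subgroups` tibble (typically after
#'   [protein_level_filter()]).
#' @param psms The FDR-filtered PSM table the subgroups were built from.
#' @return A tibble of quantifiable ions: `subgroup_id`, `gene_symbol`,
#'   `peptide`, `species_label`, `charge`, `replicate_id`, `intensity`.
#' @export
quantifiable_peptides <- function(subgroups, psms) {
  assign <- peptide_assignment(subgroups)
  assign <- assign[assign$n_subgroups_matched == 1L, , drop = FALSE]
  good <- psms[psms$good_isotope_quality & !psms$is_decoy, , drop = FALSE]
  good$peptide <- toupper(good$peptide_sequence)
  ions <- good |>
    dplyr::inner_join(assign, by = "peptide") |>
    dplyr::group_by(.data$subgroup_id, .data$gene_symbol, .data$peptide,
                    .data$species_label, .data$charge, .data$replicate_id,
                    .data$fraction_id) |>
    dplyr::summarise(intensity = max(.data$precursor_intensity),
                     .groups = "drop") |>
    dplyr::group_by(.data$subgroup_id, .data$gene_symbol, .data$peptide,
                    .data$species_label, .data$charge, .data$replicate_id) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  ions
}

# One row per (peptide, subgroup) across a subgroup table, with the
# canonical (uppercase) gene symbol.
peptide_assignment <- function(subgroups) {
  purrr::map_dfr(seq_len(nrow(subgroups)), function(i) {
    pt <- subgroups$peptides[[i]]
    tibble::tibble(
      subgroup_id = subgroups$subgroup_id[i],
      gene_symbol = toupper(subgroups$gene_symbol[i]),
      peptide = pt$peptide,
      species_label = pt$species_label,
      n_subgroups_matched = pt$n_subgroups_matched
    )
  })
}

#' Protein abundance for one species
#'
#' An individual protein's abundance is the sum of the ion current of all
#' quantifiable peptide precursor ions specific to the requested species,
#' pooled across the two replicates of a tumor type.
#'
#' @param subgroup One row of an `xeno_subgroups` tibble, or a subgroup table
#'   whose rows share a gene.
#' @param psms The FDR-filtered PSM table.
#' @param species `"human"` or `"mouse"`.
#' @return A nonnegative number (summed ion current).
#' @export
protein_abundance <- function(subgroup, psms, species = c("human", "mouse")) {
  species <- match.arg(species)
  label <- paste0(species, "_specific")
  ions <- quantifiable_peptides(subgroup, psms)
  sum(ions$intensity[ions$species_label == label])
}

#' The two-sample quantifiability rule
#'
#' Proteins are quantifiable when represented in two independent samples and
#' by at least two distinct peptides in one of the two — the same shape as
#' the matrisome membership rule, applied to quantification eligibility.
#'
#' @param counts Numeric vector of length 2: distinct-peptide counts in the
#'   two samples.
#' @return Logical.
#' @export
protein_quantifiable <- function(counts) {
  if (length(counts) != 2 || anyNA(counts)) {
    stop("exactly two per-sample peptide counts are required", call. = FALSE)
  }
  all(counts >= 1) && max(counts) >= 2
}

#' Classify tumor vs stroma origin by the fivefold rule
#'
#' With no quantifiable species-specific evidence the origin is
#' `undetermined` (rendered "?" in reports). With signal from only one
#' species the protein is `tumor_only` (human) or `stroma_only` (mouse).
#' When both species contribute, the human/mouse intensity ratio decides:
#' at least `fold_threshold`-fold (default five) in favor of the human form
#' is `both_tumor_dominant`, at least `fold_threshold`-fold in favor of the
#' mouse form is `both_stroma_dominant`, anything in between is
#' `both_similar`. The boundary ratio itself counts as dominant ("at least
#' five times more abundant"). Calls are invariant to rescaling both
#' intensities and mirror under swapping the species.
#'
#' @param human_intensity,mouse_intensity Nonnegative summed ion currents
#'   (vectorized).
#' @param fold_threshold Dominance threshold, greater than 1 (default 5).
#' @param has_species_specific_evidence Logical; `FALSE` forces
#'   `undetermined`.
#' @return Character vector over the six origin classes.
#' @export
#' @examples
#' classify_origin(1000, 0)                 # tumor_only
#' classify_origin(600, 100)                # both_tumor_dominant
#' classify_origin(300, 100)                # both_similar
#' classify_origin(0, 0, has_species_specific_evidence = FALSE)
classify_origin <- function(human_intensity, mouse_intensity,
                            fold_threshold = 5,
                            has_species_specific_evidence = TRUE) {
  if (any(human_intensity < 0) || any(mouse_intensity < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  stopifnot(fold_threshold > 1)
  n <- max(length(human_intensity), length(mouse_intensity))
  h <- rep_len(human_intensity, n)
  m <- rep_len(mouse_intensity, n)
  ev <- rep_len(has_species_specific_evidence, n)
  ratio <- ifelse(m > 0, h / m, Inf)
  dplyr::case_when(
    !ev ~ "undetermined",
    h == 0 & m == 0 ~ "undetermined",
    m == 0 ~ "tumor_only",
    h == 0 ~ "stroma_only",
    ratio >= fold_threshold ~ "both_tumor_dominant",
    ratio <= 1 / fold_threshold ~ "both_stroma_dominant",
    TRUE ~ "both_similar"
  )
}

#' Per-gene origin calls for one tumor type
#'
#' Aggregates the retained subgroups of each gene (human and mouse ortholog
#' subgroups collapse onto the canonical uppercase symbol), sums
#' quantifiable species-specific precursor-ion intensities pooled across the
#' two replicates, and applies [classify_origin()]. Distinct-peptide counts
#' per replicate feed the quantifiability flag.
#'
#' @param subgroups Retained `xeno_subgroups` for one tumor type.
#' @param psms The FDR-filtered PSM table for that tumor type (both
#'   replicates).
#' @param params An [xeno_params()] list.
#' @return A tibble: `gene`, `human_intensity`, `mouse_intensity`, `ratio`,
#'   `origin_class`, `quantifiable`, and peptide counts by mode.
#' @export
origin_calls <- function(subgroups, psms, params = xeno_params()) {
  if (nrow(subgroups) == 0) {
    return(tibble::tibble(
      gene = character(), human_intensity = numeric(),
      mouse_intensity = numeric(), ratio = numeric(),
      origin_class = character(), quantifiable = logical(),
      peptides_total = integer(), peptides_human_specific = integer(),
      peptides_mouse_specific = integer(), peptides_common = integer()
    ))
  }
  ions <- quantifiable_peptides(subgroups, psms)
  intens <- ions |>
    dplyr::group_by(gene = .data$gene_symbol) |>
    dplyr::summarise(
      human_intensity = sum(.data$intensity[.data$species_label ==
                                              "human_specific"]),
      mouse_intensity = sum(.data$intensity[.data$species_label ==
                                              "mouse_specific"]),
      has_evidence = any(.data$species_label %in%
                           c("human_specific", "mouse_specific")),
      .groups = "drop"
    )
  counts <- gene_peptide_counts(subgroups, psms)
  out <- dplyr::left_join(counts, intens, by = "gene")
  out$human_intensity[is.na(out$human_intensity)] <- 0
  out$mouse_intensity[is.na(out$mouse_intensity)] <- 0
  out$has_evidence[is.na(out$has_evidence)] <- FALSE
  out$quantifiable <- vapply(
    seq_len(nrow(out)),
    function(i) protein_quantifiable(c(out$peptides_rep1[i],
                                       out$peptides_rep2[i])),
    logical(1)
  )
  out$ratio <- dplyr::if_else(out$mouse_intensity > 0 &
                                out$human_intensity > 0,
                              out$human_intensity / out$mouse_intensity,
                              NA_real_)
  out$origin_class <- classify_origin(out$human_intensity,
                                      out$mouse_intensity,
                                      params$fold_threshold,
                                      out$has_evidence)
  dplyr::select(out, -"has_evidence")
}

# Distinct-peptide counts per gene: totals by species mode and per
# replicate (each peptide counted once per gene).
gene_peptide_counts <- function(subgroups, psms) {
  assign <- peptide_assignment(subgroups) |>
    dplyr::distinct(.data$gene_symbol, .data$peptide, .data$species_label)
  reps <- sort(unique(psms$replicate_id))
  obs <- psms[!psms$is_decoy, , drop = FALSE]
  obs$peptide <- toupper(obs$peptide_sequence)
  obs <- dplyr::distinct(obs, .data$peptide, .data$replicate_id)
  per_rep <- dplyr::inner_join(assign, obs, by = "peptide",
                               relationship = "many-to-many") |>
    dplyr::distinct(.data$gene_symbol, .data$replicate_id, .data$peptide) |>
    dplyr::count(.data$gene_symbol, .data$replicate_id)
  wide <- tidyr::pivot_wider(per_rep, names_from = "replicate_id",
                             values_from = "n", values_fill = 0L)
  for (r in reps) {
    if (!r %in% names(wide)) wide[[as.character(r)]] <- 0L
  }
  rep_cols <- as.character(reps)
  totals <- assign |>
    dplyr::group_by(gene = .data$gene_symbol) |>
    dplyr::summarise(
      peptides_total = dplyr::n_distinct(.data$peptide),
      peptides_human_specific = dplyr::n_distinct(
        .data$peptide[.data$species_label == "human_specific"]),
      peptides_mouse_specific = dplyr::n_distinct(
        .data$peptide[.data$species_label == "mouse_specific"]),
      peptides_common = dplyr::n_distinct(
        .data$peptide[.data$species_label == "shared"]),
      .groups = "drop"
    )
  totals$peptides_rep1 <- 0L
  totals$peptides_rep2 <- 0L
  i <- match(totals$gene, wide$gene_symbol)
  if (length(rep_cols) >= 1) {
    totals$peptides_rep1 <- ifelse(is.na(i), 0L, wide[[rep_cols[1]]][i])
  }
  if (length(rep_cols) >= 2) {
    totals$peptides_rep2 <- ifelse(is.na(i), 0L, wide[[rep_cols[2]]][i])
  }
  totals
}

#' Write an origin-call table as tab-separated text
#'
#' @param calls A tibble from [origin_calls()].
#' @param path Output path.
#' @param tumor_type Optional label written into a `tumor_type` column.
#' @return `path`, invisibly.
#' @export
write_origin_tsv <- function(calls, path, tumor_type = NA_character_) {
  out <- dplyr::mutate(calls, tumor_type = tumor_type, .before = 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
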