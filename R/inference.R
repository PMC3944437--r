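# Protein inference: distinct peptides, shared-peptide grouping, subgroups.

#' Collapse FDR-filtered PSMs to distinct peptides
#'
#' A distinct peptide is the single highest-scoring instance of a peptide
#' sequence. Repeated observations — different precursor charge states,
#' adjacent fractions, or modification variants such as deamidated Asn or
#' oxidized Met — collapse onto the bare sequence, keeping the maximum score.
#'
#' @param psms A filtered PSM table.
#' @return A tibble: `peptide`, `score` (best), `n_psms`, `charges`
#'   (list), `replicates` (list of replicate ids contributing).
#' @export
distinct_peptides <- function(psms) {
  psms |>
    dplyr::mutate(peptide = toupper(.data$peptide_sequence)) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      score = max(.data$score),
      n_psms = dplyr::n(),
      charges = list(sort(unique(.data$charge))),
      replicates = list(unique(.data$replicate_id)),
      .groups = "drop"
    )
}

#' Group proteins by shared peptides and spawn subgroups
#'
#' Database entries are joined into a group whenever they share a detected
#' peptide strictly longer than `grouping_min_length` residues (connected
#' components of the protein-peptide graph). Within a group, every member
#' carrying at least one distinct peptide found in no other member spawns a
#' subgroup — this is how species orthologs, isoforms, and family members
#' surface as separate `G.S` entries. Members without unique evidence join
#' the highest-scoring subgroup whose peptide set covers theirs. Groups are
#' numbered by descending total score, subgroups within a group by
#' descending subgroup score; ties break on lexicographic accession.
#'
#' @param distinct A distinct-peptide tibble from [distinct_peptides()].
#' @param index An `xeno_index` from [build_peptide_index()].
#' @param params An [xeno_params()] list (`grouping_min_length`,
#'   `subgroup_specific`).
#' @return A tibble of class `xeno_subgroups`, one row per subgroup:
#'   `group`, `subgroup`, `subgroup_id`, `representative_accession`,
#'   `gene_symbol`, `species_content`, `is_decoy`, `protein_score`,
#'   `member_accessions` (list), `peptides` (list of per-peptide tibbles
#'   with `peptide`, `score`, `species_label`, `n_subgroups_matched`,
#'   `unique_to_subgroup`), and peptide counts by mode.
#' @export
group_proteins <- function(distinct, index, params = xeno_params()) {
  if (nrow(distinct) == 0) {
    return(empty_subgroups())
  }
  rows <- index_lookup(index, distinct$peptide)
  inc <- tibble::tibble(
    peptide = rep(distinct$peptide, lengths(rows$parents)),
    score = rep(distinct$score, lengths(rows$parents)),
    species_label = rep(rows$species_label, lengths(rows$parents)),
    accession = unlist(rows$parents),
    acc_species = unlist(rows$parent_species),
    acc_decoy = unlist(rows$parent_decoy),
    acc_gene = unlist(rows$parent_genes)
  )

  # Connected components over peptides long enough to act as grouping
  # evidence; shorter shared peptides do not join proteins.
  comp <- protein_components(inc, params$grouping_min_length)
  inc$component <- comp[inc$accession]

  # Each distinct peptide belongs to exactly one group. Peptides at or below
  # the grouping length can match entries in several components; they are
  # attributed to the component of their highest-scoring parent.
  acc_score <- inc |>
    dplyr::distinct(.data$peptide, .data$score, .data$accession,
                    .data$component) |>
    dplyr::group_by(.data$accession) |>
    dplyr::mutate(acc_raw_score = sum(.data$score)) |>
    dplyr::ungroup()
  pep_comp <- acc_score |>
    dplyr::group_by(.data$peptide) |>
    dplyr::arrange(dplyr::desc(.data$acc_raw_score), .data$accession,
                   .by_group = TRUE) |>
    dplyr::summarise(component = dplyr::first(.data$component),
                     .groups = "drop")
  inc <- dplyr::inner_join(inc, pep_comp, by = c("peptide", "component"))

  parts <- split(inc, inc$component)
  built <- purrr::map(parts, build_subgroups_one_group,
                      subgroup_specific = params$subgroup_specific)
  # Group numbering: descending total group score, ties by lexicographic
  # representative accession of the top subgroup.
  group_scores <- vapply(built, function(b) b$group_score, numeric(1))
  group_reps <- vapply(built, function(b) b$subgroups$representative_accession[1],
                       character(1))
  ord <- order(-group_scores, group_reps)
  out <- purrr::imap_dfr(built[ord], function(b, i) {
    dplyr::mutate(b$subgroups,
                  group = as.integer(i),
                  subgroup_id = sprintf("%s.%d", i, .data$subgroup))
  })
  out <- dplyr::relocate(out, "group", "subgroup", "subgroup_id")
  class(out) <- c("xeno_subgroups", class(out))
  out
}

empty_subgroups <- function() {
  out <- tibble::tibble(
    group = integer(), subgroup = integer(), subgroup_id = character(),
    representative_accession = character(), gene_symbol = character(),
    species_content = character(), is_decoy = logical(),
    protein_score = numeric(), member_accessions = list(),
    peptides = list(), peptides_total = integer(),
    peptides_human_specific = integer(), peptides_mouse_specific = integer(),
    peptides_common = integer()
  )
  class(out) <- c("xeno_subgroups", class(out))
  out
}

# Connected components of the protein graph; edges are detected peptides
# strictly longer than grouping_min_length shared by two entries.
protein_components <- function(inc, grouping_min_length) {
  accs <- sort(unique(inc$accession))
  long <- inc[nchar(inc$peptide) > grouping_min_length, , drop = FALSE]
  edges <- long |>
    dplyr::group_by(.data$peptide) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(from = .data$accession[1],
                     to = list(.data$accession[-1]), .groups = "drop") |>
    tidyr::unnest("to")
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = accs)
  )
  igraph::components(g)$membership[accs]
}

# Build the subgroups of one connected component. `inc` holds one row per
# (peptide, member accession) incidence within the component.
build_subgroups_one_group <- function(inc, subgroup_specific = FALSE) {
  pep <- dplyr::distinct(inc, .data$peptide, .data$score, .data$species_label)
  members <- inc |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      species = .data$acc_species[1],
      is_decoy = .data$acc_decoy[1],
      gene_symbol = .data$acc_gene[1],
      peptides = list(unique(.data$peptide)),
      member_score = sum(.data$score[!duplicated(.data$peptide)]),
      .groups = "drop"
    )
  n_parents <- table(inc$peptide[!duplicated(paste(inc$peptide, inc$accession))])
  unique_pep <- names(n_parents)[n_parents == 1]
  spawner_of <- inc$accession[match(unique_pep, inc$peptide)]
  spawners <- unique(spawner_of)

  members <- dplyr::arrange(members, dplyr::desc(.data$member_score),
                            .data$accession)
  if (length(spawners) == 0) {
    # no unique evidence anywhere: one subgroup holding every member
    assignment <- stats::setNames(rep(1L, nrow(members)), members$accession)
    seeds <- members$accession[1]
  } else {
    seeds <- members$accession[members$accession %in% spawners]
    assignment <- stats::setNames(match(members$accession, seeds),
                                  members$accession)
    sg_peps <- lapply(seeds, function(a) {
      members$peptides[[match(a, members$accession)]]
    })
    for (a in members$accession[is.na(assignment)]) {
      p <- members$peptides[[match(a, members$accession)]]
      covered <- which(vapply(sg_peps, function(s) all(p %in% s), logical(1)))
      j <- if (length(covered) > 0) covered[1] else 1L
      assignment[a] <- j
      sg_peps[[j]] <- union(sg_peps[[j]], p)
    }
  }

  member_sub <- assignment[inc$accession]
  pep_subs <- tapply(member_sub, inc$peptide, function(s) sort(unique(s)),
                     simplify = FALSE)
  n_sub_matched <- lengths(pep_subs)

  sub_rows <- lapply(sort(unique(assignment)), function(s) {
    mem <- members[assignment[members$accession] == s, , drop = FALSE]
    peps_s <- sort(unique(unlist(mem$peptides)))
    pt <- pep[match(peps_s, pep$peptide), , drop = FALSE]
    pt$n_subgroups_matched <- as.integer(n_sub_matched[pt$peptide])
    pt$unique_to_subgroup <- pt$n_subgroups_matched == 1L
    scored <- if (subgroup_specific) pt[pt$unique_to_subgroup, ] else pt
    counted <- scored
    tibble::tibble(
      representative_accession = mem$accession[1],
      gene_symbol = mem$gene_symbol[1],
      species_content = if (length(unique(mem$species)) > 1) "mixed"
                        else mem$species[1],
      is_decoy = all(mem$is_decoy),
      protein_score = sum(scored$score),
      member_accessions = list(mem$accession),
      peptides = list(pt),
      peptides_total = nrow(counted),
      peptides_human_specific = sum(counted$species_label == "human_specific"),
      peptides_mouse_specific = sum(counted$species_label == "mouse_specific"),
      peptides_common = sum(counted$species_label == "shared")
    )
  })
  sub <- dplyr::bind_rows(sub_rows)
  sub <- dplyr::arrange(sub, dplyr::desc(.data$protein_score),
                        .data$representative_accession)
  sub$subgroup <- seq_len(nrow(sub))
  list(subgroups = sub, group_score = sum(pep$score))
}

#' Protein (subgroup) score
#'
#' The protein score is the sum of the best scores of its distinct peptides.
#' With `subgroup_specific = TRUE` only peptides unique to the subgroup
#' contribute; otherwise every peptide matching any member counts.
#'
#' @param subgroup One row of an `xeno_subgroups` tibble (or its `peptides`
#'   tibble).
#' @param subgroup_specific Logical.
#' @return A single numeric score.
#' @export
protein_score <- function(subgroup, subgroup_specific = FALSE) {
  pt <- if (is.data.frame(subgroup) && "peptides" %in% names(subgroup)) {
    subgroup$peptides[[1]]
  } else {
    subgroup
  }
  if (subgroup_specific) {
    sum(pt$score[pt$unique_to_subgroup])
  } else {
    sum(pt$score)
  }
}

#' Count distinct peptides of a subgroup by species mode
#'
#' @param subgroup One row of an `xeno_subgroups` tibble.
#' @param mode One of `"total"`, `"species_specific"` (human + mouse),
#'   `"human_specific"`, `"mouse_specific"`, `"common"`.
#' @param subgroup_specific Count only peptides unique to the subgroup.
#' @return An integer count; `total` always equals
#'   `species_specific + common`.
#' @export
peptide_counts <- function(subgroup,
                           mode = c("total", "species_specific",
                                    "human_specific", "mouse_specific",
                                    "common"),
                           subgroup_specific = FALSE) {
  mode <- match.arg(mode)
  pt <- subgroup$peptides[[1]]
  if (subgroup_specific) {
    pt <- pt[pt$unique_to_subgroup, , drop = FALSE]
  }
  switch(mode,
    total = nrow(pt),
    species_specific = sum(pt$species_label %in%
                             c("human_specific", "mouse_specific")),
    human_specific = sum(pt$species_label == "human_specific"),
    mouse_specific = sum(pt$species_label == "mouse_specific"),
    common = sum(pt$species_label == "shared")
  )
}

#' Protein-level score and FDR filter
#'
#' Drops subgroups scoring below `min_protein_score`, then raises the
#' effective cutoff until the decoy/target ratio among survivors is at most
#' `max_protein_fdr`. At the default FDR of zero this means the cutoff rises
#' just above the best surviving decoy score, so no decoy subgroup remains.
#' Decoy subgroups are removed from the returned table.
#'
#' @param subgroups An `xeno_subgroups` tibble.
#' @param min_protein_score Minimum protein score (default 20).
#' @param max_protein_fdr Maximum protein-level FDR (default 0).
#' @return The retained target subgroups, with attribute `score_cutoff`
#'   giving the effective cutoff applied.
#' @export
protein_level_filter <- function(subgroups, min_protein_score = 20,
                                 max_protein_fdr = 0) {
  surv <- subgroups[subgroups$protein_score >= min_protein_score, ,
                    drop = FALSE]
  cutoff <- min_protein_score
  if (any(surv$is_decoy)) {
    grid <- sort(unique(surv$protein_score))
    ok <- vapply(grid, function(t) {
      nt <- sum(!surv$is_decoy & surv$protein_score >= t)
      nd <- sum(surv$is_decoy & surv$protein_score >= t)
      nt > 0 && nd / nt <= max_protein_fdr
    }, logical(1))
    if (any(ok)) {
      cutoff <- grid[which(ok)[1]]
    } else {
      # no attainable cutoff on the grid: exclude every decoy
      cutoff <- max(surv$protein_score[surv$is_decoy])
      surv <- surv[surv$protein_score > cutoff, , drop = FALSE]
    }
    surv <- surv[surv$protein_score >= cutoff, , drop = FALSE]
  }
  out <- surv[!surv$is_decoy, , drop = FALSE]
  attr(out, "score_cutoff") <- cutoff
  out
}

#' Render a subgroup table as tab-separated text
#'
#' @param subgroups An `xeno_subgroups` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subgroups_tsv <- function(subgroups, path) {
  flat <- tibble::tibble(
    subgroup_id = subgroups$subgroup_id,
    representative_accession = subgroups$representative_accession,
    gene_symbol = subgroups$gene_symbol,
    species = subgroups$species_content,
    protein_score = subgroups$protein_score,
    peptides_total = subgroups$peptides_total,
    peptides_human_specific = subgroups$peptides_human_specific,
    peptides_mouse_specific = subgroups$peptides_mouse_specific,
    peptides_common = subgroups$peptides_common
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
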