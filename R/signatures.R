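# Per-tumor-type matrisomes, their comparison, and the full pipeline.

#' Coarse origin classes
#'
#' Collapses the six origin classes to tumor / stroma / both; undetermined
#' maps to `NA`.
#'
#' @param origin_class Character vector of origin classes.
#' @return Character vector over `"tumor"`, `"stroma"`, `"both"`, `NA`.
#' @export
coarse_origin <- function(origin_class) {
  dplyr::case_when(
    origin_class == "tumor_only" ~ "tumor",
    origin_class == "stroma_only" ~ "stroma",
    origin_class %in% c("both_similar", "both_tumor_dominant",
                        "both_stroma_dominant") ~ "both",
    TRUE ~ NA_character_
  )
}

#' Build one tumor type's matrisome
#'
#' Applies the two-replicate membership rule per gene (detected in both
#' biological replicates, at least two peptides in one of them; counts are
#' totals of common plus species-specific distinct peptides) and keeps
#' matrisome-annotated genes, attaching division, category, and peptide
#' counts.
#'
#' @param subgroups Retained `xeno_subgroups` for the tumor type.
#' @param psms The FDR-filtered PSM table (both replicates).
#' @param annotation An `xeno_annotation` table.
#' @return A tibble: `gene`, `division`, `category`, `peptides_rep1`,
#'   `peptides_rep2`, species-mode peptide counts, and `member` (the
#'   membership rule outcome; non-members are retained in the table for QC
#'   but carry `member = FALSE`). The tumor matrisome is
#'   `gene[member & division != "non_matrisome"]`.
#' @export
build_matrisome <- function(subgroups, psms, annotation) {
  counts <- gene_peptide_counts(subgroups, psms)
  ann <- annotate_genes(annotation, counts$gene)
  out <- dplyr::bind_cols(counts,
                          ann[, c("division", "category")])
  out$member <- vapply(
    seq_len(nrow(out)),
    function(i) matrisome_membership(c(out$peptides_rep1[i],
                                       out$peptides_rep2[i])),
    logical(1)
  )
  dplyr::relocate(out, "gene", "division", "category")
}

#' Extract the matrisome gene set from a membership table
#'
#' @param matrisome_table A table from [build_matrisome()].
#' @return Sorted gene symbols passing the membership rule and carrying a
#'   matrisome annotation.
#' @export
matrisome_genes <- function(matrisome_table) {
  sort(matrisome_table$gene[matrisome_table$member &
                              matrisome_table$division != "non_matrisome"])
}

#' Compare two tumor matrisomes (Venn sets)
#'
#' @param set_A,set_B Character vectors of gene symbols.
#' @return A list: `shared`, `A_only`, `B_only` (sorted gene sets) and
#'   `counts` (named integer vector). The three sets partition the union,
#'   and `|shared| + |A_only| = |set_A|` (dually for B).
#' @export
compare_matrisomes <- function(set_A, set_B) {
  set_A <- unique(set_A)
  set_B <- unique(set_B)
  out <- list(
    shared = sort(intersect(set_A, set_B)),
    A_only = sort(setdiff(set_A, set_B)),
    B_only = sort(setdiff(set_B, set_A))
  )
  out$counts <- c(shared = length(out$shared),
                  A_only = length(out$A_only),
                  B_only = length(out$B_only))
  out
}

#' Detect origin shifts between tumor types
#'
#' Over the genes shared by both matrisomes, compares the per-type origin
#' calls. A gene is shifted when both calls are determinate and differ;
#' a gene undetermined on either side is indeterminate. The default coarse
#' granularity compares tumor / stroma / both; the fine granularity
#' compares the six classes exactly.
#'
#' @param shared_genes Character vector of shared gene symbols.
#' @param origin_calls_A,origin_calls_B Tibbles with `gene` and
#'   `origin_class` (as from [origin_calls()]).
#' @param granularity `"coarse"` or `"fine"`.
#' @return A list of sorted gene sets `origin_same`, `origin_shifted`,
#'   `indeterminate`; their union is `shared_genes`.
#' @export
detect_origin_shifts <- function(shared_genes, origin_calls_A,
                                 origin_calls_B,
                                 granularity = c("coarse", "fine")) {
  granularity <- match.arg(granularity)
  a <- origin_calls_A$origin_class[match(shared_genes, origin_calls_A$gene)]
  b <- origin_calls_B$origin_class[match(shared_genes, origin_calls_B$gene)]
  if (granularity == "coarse") {
    a <- coarse_origin(a)
    b <- coarse_origin(b)
  } else {
    a[a == "undetermined"] <- NA
    b[b == "undetermined"] <- NA
  }
  indet <- is.na(a) | is.na(b)
  list(
    origin_same = sort(shared_genes[!indet & a == b]),
    origin_shifted = sort(shared_genes[!indet & a != b]),
    indeterminate = sort(shared_genes[indet])
  )
}

#' Assemble and validate a signature result
#'
#' Internal constructor enforcing the partition identities: shared / A-only
#' / B-only partition the union of the two matrisomes, and same / shifted /
#' indeterminate partition the shared set.
#'
#' @param matrisome_A,matrisome_B Per-type matrisome tables
#'   (see [build_matrisome()]).
#' @param venn Output of [compare_matrisomes()].
#' @param origin_A,origin_B Per-type origin-call tables.
#' @param shifts Output of [detect_origin_shifts()].
#' @param tables Optional list of intermediate tables carried along.
#' @return An object of class `xeno_signature`.
#' @export
xeno_signature <- function(matrisome_A, matrisome_B, venn, origin_A,
                           origin_B, shifts, tables = list()) {
  genes_a <- matrisome_genes(matrisome_A)
  genes_b <- matrisome_genes(matrisome_B)
  stopifnot(
    setequal(c(venn$shared, venn$A_only, venn$B_only),
             union(genes_a, genes_b)),
    length(venn$shared) + length(venn$A_only) == length(genes_a),
    length(venn$shared) + length(venn$B_only) == length(genes_b),
    !anyDuplicated(c(venn$shared, venn$A_only, venn$B_only)),
    setequal(c(shifts$origin_same, shifts$origin_shifted,
               shifts$indeterminate), venn$shared),
    length(intersect(shifts$origin_same, shifts$origin_shifted)) == 0
  )
  structure(
    list(matrisome_A = matrisome_A, matrisome_B = matrisome_B,
         venn = venn, origin_A = origin_A, origin_B = origin_B,
         shifts = shifts, tables = tables),
    class = "xeno_signature"
  )
}

#' @export
print.xeno_signature <- function(x, ...) {
  cat("<xeno_signature>\n")
  cat(sprintf("  matrisome A: %d genes; matrisome B: %d genes\n",
              length(matrisome_genes(x$matrisome_A)),
              length(matrisome_genes(x$matrisome_B))))
  cat(sprintf("  Venn: %d shared / %d A-only / %d B-only\n",
              x$venn$counts["shared"], x$venn$counts["A_only"],
              x$venn$counts["B_only"]))
  cat(sprintf("  origin over shared: %d same / %d shifted / %d indeterminate\n",
              length(x$shifts$origin_same), length(x$shifts$origin_shifted),
              length(x$shifts$indeterminate)))
  invisible(x)
}

#' Analyze one tumor type
#'
#' The per-tumor-type stage chain: spectral FDR filter per (run, charge),
#' distinct peptides across both replicates, shared-peptide grouping with
#' subgroup spawning, protein-level score/FDR filter, matrisome membership,
#' and species-resolved quantification with origin classification.
#'
#' @param psms Combined PSM table for the type's two replicates.
#' @param index An `xeno_index` over both species' databases.
#' @param annotation An `xeno_annotation` table.
#' @param params An [xeno_params()] list.
#' @return A list: `filter_report`, `subgroups` (retained), `matrisome`
#'   (membership table), `origin` (origin calls), `psms` (retained PSMs).
#' @export
analyze_tumor_type <- function(psms, index, annotation,
                               params = xeno_params()) {
  filt <- spectral_filter(psms, params)
  dp <- distinct_peptides(filt$psms)
  sg <- group_proteins(dp, index, params)
  retained <- protein_level_filter(sg, params$min_protein_score,
                                   params$max_protein_fdr)
  list(
    filter_report = filt$report,
    subgroups = retained,
    matrisome = build_matrisome(retained, filt$psms, annotation),
    origin = origin_calls(retained, filt$psms, params),
    psms = filt$psms
  )
}

#' Run the full xenoproteomic pipeline
#'
#' Executes digestion/indexing, spectral FDR filtering, protein inference,
#' matrisome membership, species-resolved quantification, and the
#' between-type comparison. The input is either a simulation configuration
#' ([sim_config()]), in which case proteomes and PSM tables are generated
#' with the given seed, or a list of file paths (`human_fasta`,
#' `mouse_fasta`, `psm_tables` — a named list `<type>_r<k>` of PSM TSV
#' paths for exactly two types — and `annotation`).
#'
#' @param config An `xeno_sim_config`, or a named list of input paths.
#' @param params An [xeno_params()] list.
#' @param seed Seed for simulated inputs.
#' @return An `xeno_signature`; `$tables` holds per-type intermediates and,
#'   for simulated inputs, the ground truth.
#' @export
run_pipeline <- function(config, params = xeno_params(),
                         seed = NULL) {
  if (inherits(config, "xeno_sim_config")) {
    seed <- if (is.null(seed)) config$seed else seed
    sim <- simulate_psm_tables(config, seed)
    proteomes <- sim$proteomes
    psm_tables <- sim$psm_tables
    annotation <- sim$annotation
    truth <- ground_truth_signature(config)
    types <- SIM_TUMOR_TYPES
  } else {
    required <- c("human_fasta", "mouse_fasta", "psm_tables", "annotation")
    missing <- setdiff(required, names(config))
    if (length(missing) > 0) {
      stop("pipeline configuration lacks: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    paths <- c(config$human_fasta, config$mouse_fasta, config$annotation,
               unlist(config$psm_tables))
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    proteomes <- read_proteomes(config$human_fasta, config$mouse_fasta)
    psm_tables <- lapply(config$psm_tables, read_psm_tsv)
    annotation <- load_annotation(config$annotation)
    types <- unique(sub("_r[0-9]+$", "", names(psm_tables)))
    if (length(types) != 2) {
      stop("expected PSM tables for exactly two tumor types, got: ",
           paste(types, collapse = ", "), call. = FALSE)
    }
    truth <- NULL
  }
  index <- build_peptide_index(proteomes$human, proteomes$mouse, params)
  per_type <- lapply(types, function(tt) {
    tabs <- psm_tables[startsWith(names(psm_tables), paste0(tt, "_"))]
    analyze_tumor_type(dplyr::bind_rows(tabs), index, annotation, params)
  })
  names(per_type) <- types
  a <- per_type[[1]]
  b <- per_type[[2]]
  venn <- compare_matrisomes(matrisome_genes(a$matrisome),
                             matrisome_genes(b$matrisome))
  shifts <- detect_origin_shifts(venn$shared, a$origin, b$origin,
                                 params$shift_granularity)
  xeno_signature(
    matrisome_A = a$matrisome, matrisome_B = b$matrisome,
    venn = venn, origin_A = a$origin, origin_B = b$origin,
    shifts = shifts,
    tables = list(per_type = per_type, index_size = nrow(index$table),
                  truth = truth, params = params, types = types)
  )
}
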