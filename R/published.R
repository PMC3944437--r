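# Reproduction of published summary counts from deposited source-data
# tables (user-supplied; see the file-format contract below).

#' Reproduce published matrisome and origin counts from deposited tables
#'
#' Re-derives the headline counts of the original xenograft study from its
#' deposited source-data tables: the per-type matrisome sizes under the
#' two-replicate membership rule, the Venn comparison of the two
#' matrisomes, and the same/shifted origin partition of the shared proteins
#' under the fivefold rule. The deposited tables are distributed as
#' spreadsheets alongside the publication (and the underlying PSMs via
#' MassIVE accession MSV000078535); they are not bundled here. Convert them
#' to two tab-separated files:
#'
#' * `membership`: columns `gene`, `peptides_A_rep1`, `peptides_A_rep2`,
#'   `peptides_B_rep1`, `peptides_B_rep2` — distinct-peptide counts per
#'   replicate for the two tumor types (0 where undetected).
#' * `origin`: columns `gene`, `human_intensity_A`, `mouse_intensity_A`,
#'   `human_intensity_B`, `mouse_intensity_B` — summed species-specific
#'   precursor intensities per tumor type (NA where the protein is absent
#'   from that type's matrisome, 0 where present without species-specific
#'   evidence).
#'
#' @param membership_path,origin_path Paths to the converted tables.
#' @param fold_threshold Dominance threshold (default 5).
#' @return A list: `n_matrisome_A`, `n_matrisome_B`, `venn` (named counts),
#'   `n_origin_same`, `n_origin_shifted` (coarse classes), and the
#'   underlying gene sets.
#' @export
reproduce_published_counts <- function(membership_path, origin_path,
                                       fold_threshold = 5) {
  for (p in c(membership_path, origin_path)) {
    if (!file.exists(p)) {
      stop("deposited source-data table not found: ", p,
           "\nConvert the published per-protein tables to TSV as described",
           " in ?reproduce_published_counts and pass their paths.",
           call. = FALSE)
    }
  }
  mem <- utils::read.delim(membership_path, stringsAsFactors = FALSE)
  ori <- utils::read.delim(origin_path, stringsAsFactors = FALSE)

  in_type <- function(r1, r2) {
    vapply(seq_along(r1),
           function(i) matrisome_membership(c(r1[i], r2[i])), logical(1))
  }
  set_a <- mem$gene[in_type(mem$peptides_A_rep1, mem$peptides_A_rep2)]
  set_b <- mem$gene[in_type(mem$peptides_B_rep1, mem$peptides_B_rep2)]
  venn <- compare_matrisomes(set_a, set_b)

  call_type <- function(h, m) {
    ev <- !(is.na(h) & is.na(m))
    h[is.na(h)] <- 0
    m[is.na(m)] <- 0
    classify_origin(h, m, fold_threshold, ev & (h > 0 | m > 0))
  }
  calls_a <- tibble::tibble(
    gene = ori$gene,
    origin_class = call_type(ori$human_intensity_A, ori$mouse_intensity_A))
  calls_b <- tibble::tibble(
    gene = ori$gene,
    origin_class = call_type(ori$human_intensity_B, ori$mouse_intensity_B))
  shifts <- detect_origin_shifts(venn$shared, calls_a, calls_b, "coarse")

  list(
    n_matrisome_A = length(unique(set_a)),
    n_matrisome_B = length(unique(set_b)),
    venn = venn$counts,
    n_origin_same = length(shifts$origin_same),
    n_origin_shifted = length(shifts$origin_shifted),
    matrisome_A = sort(unique(set_a)),
    matrisome_B = sort(unique(set_b)),
    shifts = shifts
  )
}
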