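#' Analysis parameters for the xenoproteomic pipeline
#'
#' Bundles every tunable threshold of the pipeline with the defaults used
#' throughout: spectral FDR of 1.6% per precursor charge state 2/3/4,
#' a minimum protein score of 20 with a protein-level FDR of zero, shared
#' peptides longer than 8 residues as grouping evidence, and a fivefold
#' dominance threshold for tumor-vs-stroma origin calls.
#'
#' @param spectral_fdr Target spectral-level FDR applied per (run, charge)
#'   when auto-thresholding PSM scores. Default 0.016.
#' @param charges Precursor charge states retained for analysis; PSMs at
#'   other charges (singly charged or >4) are dropped before thresholding.
#' @param min_protein_score Minimum protein (subgroup) score; scores are sums
#'   of distinct-peptide scores, each peptide score at most 25.
#' @param max_protein_fdr Maximum protein-level FDR. At the default 0, the
#'   score cutoff rises until no decoy subgroup survives.
#' @param grouping_min_length Peptides must be strictly longer than this to
#'   act as grouping evidence between database entries. Default 8.
#' @param fold_threshold Dominance threshold on the human/mouse summed
#'   precursor-intensity ratio; at least `fold_threshold`-fold difference is
#'   required to call one compartment dominant. Default 5.
#' @param max_missed_cleavages Maximum tryptic missed cleavages in the
#'   in silico digest. Default 2.
#' @param min_peptide_length,max_peptide_length Length window for digest
#'   products, in residues.
#' @param equivalence_classes Character vector of residue groups treated as
#'   indistinguishable when calling species specificity. Each element is a
#'   string of residues merged to one class; the default `"IL"` merges the
#'   mass-identical leucine/isoleucine pair. Add `"ND"` to also merge
#'   deamidation-ambiguous Asn/Asp. Use `character(0)` for literal matching.
#' @param subgroup_specific Logical; if `TRUE`, protein scores and peptide
#'   counts use only peptides unique to a subgroup.
#' @param shift_granularity `"coarse"` (tumor / stroma / both; the default,
#'   matching how origin shifts are tallied between tumor types) or `"fine"`
#'   (the full six origin classes).
#'
#' @return A list of class `xeno_params`.
#' @export
#' @examples
#' xeno_params(fold_threshold = 10)
xeno_params <- function(spectral_fdr = 0.016,
                        charges = 2:4,
                        min_protein_score = 20,
                        max_protein_fdr = 0,
                        grouping_min_length = 8L,
                        fold_threshold = 5,
                        max_missed_cleavages = 2L,
                        min_peptide_length = 6L,
                        max_peptide_length = 50L,
                        equivalence_classes = "IL",
                        subgroup_specific = FALSE,
                        shift_granularity = c("coarse", "fine")) {
  shift_granularity <- match.arg(shift_granularity)
  stopifnot(
    spectral_fdr >= 0, spectral_fdr < 1,
    all(charges == as.integer(charges)),
    min_protein_score >= 0,
    max_protein_fdr >= 0, max_protein_fdr < 1,
    grouping_min_length >= 0,
    fold_threshold > 1,
    max_missed_cleavages >= 0,
    min_peptide_length >= 1,
    max_peptide_length >= min_peptide_length
  )
  structure(
    list(
      spectral_fdr = spectral_fdr,
      charges = as.integer(charges),
      min_protein_score = min_protein_score,
      max_protein_fdr = max_protein_fdr,
      grouping_min_length = as.integer(grouping_min_length),
      fold_threshold = fold_threshold,
      max_missed_cleavages = as.integer(max_missed_cleavages),
      min_peptide_length = as.integer(min_peptide_length),
      max_peptide_length = as.integer(max_peptide_length),
      equivalence_classes = equivalence_classes,
      subgroup_specific = subgroup_specific,
      shift_granularity = shift_granularity
    ),
    class = "xeno_params"
  )
}

#' @export
print.xeno_params <- function(x, ...) {
  cat("<xeno_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
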