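# Spectral-level target-decoy FDR thresholding and sequence-motif QC.

PSM_COLUMNS <- c("peptide_sequence", "modifications", "charge", "score",
                 "precursor_intensity", "good_isotope_quality",
                 "sample_id", "replicate_id", "fraction_id", "is_decoy")

#' Validate a PSM table
#'
#' Checks the column contract of a peptide-spectrum-match table: scores in
#' [0, 25], nonnegative intensities, integer charges.
#'
#' @param psms A tibble of PSM records.
#' @return The table, invisibly; errors describe the first violation.
#' @export
validate_psms <- function(psms) {
  missing <- setdiff(PSM_COLUMNS, names(psms))
  if (length(missing) > 0) {
    stop("PSM table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(psms$score < 0 | psms$score > 25)) {
    stop("PSM scores must lie in [0, 25]", call. = FALSE)
  }
  if (any(psms$precursor_intensity < 0)) {
    stop("precursor intensities must be nonnegative", call. = FALSE)
  }
  invisible(psms)
}

# Run identifier: one LC-MS/MS run per (sample, fraction).
psm_run_id <- function(psms) {
  paste(psms$sample_id, psms$fraction_id, sep = "/")
}

#' Drop PSMs at excluded charge states
#'
#' Singly charged precursors are not triggered for MS/MS and precursors with
#' charge above 4 are excluded from searching, so only the configured charge
#' states (default 2, 3, 4) enter thresholding.
#'
#' @param psms A PSM table.
#' @param charges Integer vector of retained charge states.
#' @return The restricted table.
#' @export
restrict_charges <- function(psms, charges = 2:4) {
  dplyr::filter(psms, .data$charge %in% charges)
}

#' Score threshold achieving a target spectral FDR at one charge state
#'
#' Scans the observed score grid of the given charge and returns the smallest
#' threshold t such that the decoy/target ratio among PSMs with score >= t is
#' at most `target_fdr`. If no grid point qualifies, returns `Inf` (filtering
#' everything) with a warning.
#'
#' @param psms A PSM table (one run; pass pre-split data for per-run use).
#' @param charge The precursor charge state to threshold.
#' @param target_fdr Target spectral FDR (default 0.016).
#' @return A single numeric threshold.
#' @export
#' @examples
#' psms <- tibble::tibble(
#'   charge = 2L, score = c(10, 12, 15, 20, 11, 14),
#'   is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
#' )
#' spectral_fdr_threshold(psms, 2L, 0.30)
spectral_fdr_threshold <- function(psms, charge, target_fdr = 0.016) {
  sub <- psms[psms$charge == charge, , drop = FALSE]
  if (sum(!sub$is_decoy) == 0) {
    stop("no target PSMs at charge ", charge, call. = FALSE)
  }
  grid <- sort(unique(sub$score))
  # decreasing-threshold cumulative counts: for grid[i], counts of score >= grid[i]
  targets_ge <- vapply(grid, function(t) sum(!sub$is_decoy & sub$score >= t),
                       numeric(1))
  decoys_ge <- vapply(grid, function(t) sum(sub$is_decoy & sub$score >= t),
                      numeric(1))
  ok <- targets_ge > 0 & decoys_ge / targets_ge <= target_fdr
  if (!any(ok)) {
    warning("no score threshold attains FDR <= ", target_fdr,
            " at charge ", charge, "; filtering all PSMs", call. = FALSE)
    return(Inf)
  }
  grid[which(ok)[1]]
}

#' Per-(run, charge) spectral FDR thresholds
#'
#' Computes [spectral_fdr_threshold()] separately for every LC-MS/MS run
#' (sample x fraction) and charge state present, as thresholds are optimized
#' per charge state in each run.
#'
#' @param psms A PSM table.
#' @param target_fdr Target spectral FDR.
#' @param charges Charge states to threshold.
#' @return A tibble: `run_id`, `charge`, `threshold`, `n_targets`,
#'   `n_decoys`, `achieved_fdr` (decoy/target ratio among retained PSMs).
#' @export
compute_spectral_thresholds <- function(psms, target_fdr = 0.016,
                                        charges = 2:4) {
  psms <- restrict_charges(validate_psms(psms), charges)
  psms$run_id <- psm_run_id(psms)
  combos <- dplyr::distinct(psms, .data$run_id, .data$charge)
  purrr::pmap_dfr(combos, function(run_id, charge) {
    sub <- psms[psms$run_id == run_id, , drop = FALSE]
    thr <- spectral_fdr_threshold(sub, charge, target_fdr)
    keep <- sub$charge == charge & sub$score >= thr
    nt <- sum(keep & !sub$is_decoy)
    nd <- sum(keep & sub$is_decoy)
    tibble::tibble(
      run_id = run_id, charge = charge, threshold = thr,
      n_targets = nt, n_decoys = nd,
      achieved_fdr = if (nt > 0) nd / nt else NA_real_
    )
  })
}

#' Filter PSMs by per-(run, charge) score thresholds
#'
#' @param psms A PSM table.
#' @param thresholds Either the tibble returned by
#'   [compute_spectral_thresholds()] or a named numeric vector keyed by
#'   charge (applied to every run).
#' @return The retained PSM rows.
#' @export
filter_psms <- function(psms, thresholds) {
  psms <- validate_psms(psms)
  psms$run_id <- psm_run_id(psms)
  if (is.numeric(thresholds) && !is.null(names(thresholds))) {
    thresholds <- tidyr::expand_grid(
      run_id = unique(psms$run_id),
      tibble::tibble(charge = as.integer(names(thresholds)),
                     threshold = unname(thresholds))
    )
  }
  missing <- dplyr::anti_join(
    dplyr::distinct(psms, .data$run_id, .data$charge),
    thresholds, by = c("run_id", "charge")
  )
  if (nrow(missing) > 0) {
    stop("no threshold supplied for charge ",
         paste(unique(missing$charge), collapse = ", "),
         " (run ", paste(unique(missing$run_id), collapse = ", "), ")",
         call. = FALSE)
  }
  out <- dplyr::inner_join(psms, thresholds[, c("run_id", "charge", "threshold")],
                           by = c("run_id", "charge"))
  out <- dplyr::filter(out, .data$score >= .data$threshold)
  dplyr::select(out, -"threshold", -"run_id")
}

#' Apply the full spectral filter
#'
#' Convenience wrapper: restrict charges, compute per-(run, charge)
#' thresholds at the configured spectral FDR, and filter.
#'
#' @param psms A PSM table.
#' @param params An [xeno_params()] list.
#' @return A list: `psms` (retained rows), `report` (threshold tibble).
#' @export
spectral_filter <- function(psms, params = xeno_params()) {
  psms <- restrict_charges(validate_psms(psms), params$charges)
  report <- compute_spectral_thresholds(psms, params$spectral_fdr,
                                        params$charges)
  list(psms = filter_psms(psms, report), report = report)
}

#' Is a hydroxyproline in the expected collagen-like motif context?
#'
#' Proline hydroxylation is expected only within G-X-P-G motifs of collagen
#' domains; calls outside that context are flagged as suspect.
#'
#' @param peptide_sequence Peptide string.
#' @param position 1-based position of the modified proline.
#' @return `TRUE` iff positions (p-2, p-1, p, p+1) spell G, any, P, G within
#'   the peptide. Nonstandard residues (X, Z) never match G.
#' @export
#' @examples
#' flag_hydroxyproline_context("GAPGK", 3)
flag_hydroxyproline_context <- function(peptide_sequence, position) {
  n <- nchar(peptide_sequence)
  if (position < 1 || position > n) {
    stop("position out of range", call. = FALSE)
  }
  if (substr(peptide_sequence, position, position) != "P") {
    stop("residue at position ", position, " is not proline", call. = FALSE)
  }
  if (position < 3 || position + 1 > n) {
    return(FALSE)
  }
  substr(peptide_sequence, position - 2, position - 2) == "G" &&
    substr(peptide_sequence, position + 1, position + 1) == "G"
}

#' Infer deglycosylation sites from deamidated asparagines
#'
#' A deamidated Asn followed by the N-glycosylation sequon n-X-[S/T] likely
#' marks a site where an N-linked glycan was removed by PNGaseF treatment.
#'
#' @param peptide_sequence Peptide string.
#' @param deamidated_positions Integer positions (1-based) of N residues
#'   carrying deamidation.
#' @return The subset of positions p with an S or T at p+2 inside the
#'   peptide. Nonstandard residues never match S/T.
#' @export
#' @examples
#' infer_deglycosylation_sites("LNGSK", 2)
infer_deglycosylation_sites <- function(peptide_sequence,
                                        deamidated_positions) {
  n <- nchar(peptide_sequence)
  deamidated_positions <- as.integer(deamidated_positions)
  if (any(deamidated_positions < 1 | deamidated_positions > n)) {
    stop("deamidated position out of range", call. = FALSE)
  }
  res <- substring(peptide_sequence, deamidated_positions,
                   deamidated_positions)
  if (any(res != "N")) {
    stop("position(s) ",
         paste(deamidated_positions[res != "N"], collapse = ", "),
         " are not asparagine", call. = FALSE)
  }
  plus2 <- substring(peptide_sequence, deamidated_positions + 2L,
                     deamidated_positions + 2L)
  deamidated_positions[plus2 %in% c("S", "T")]
}

#' Write / read PSM tables as tab-separated text
#'
#' @param psms A PSM table.
#' @param path File path.
#' @return `write_psm_tsv()` returns `path` invisibly; `read_psm_tsv()`
#'   returns a validated PSM tibble.
#' @export
write_psm_tsv <- function(psms, path) {
  utils::write.table(psms[, PSM_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(modifications = "character",
                                          sample_id = "character",
                                          replicate_id = "character",
                                          fraction_id = "character"))
  raw$modifications[is.na(raw$modifications)] <- ""
  validate_psms(tibble::as_tibble(raw))
}
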