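# Matrisome annotation and the two-replicate membership rule.

MATRISOME_DIVISIONS <- c("core_matrisome", "matrisome_associated",
                         "non_matrisome")
CORE_CATEGORIES <- c("ECM_glycoproteins", "collagens", "proteoglycans")
ASSOCIATED_CATEGORIES <- c("ECM_affiliated", "ECM_regulators",
                           "secreted_factors")

#' Load a matrisome annotation table
#'
#' Reads a tab-separated file with columns `gene`, `division`, `category`.
#' The division/category pairing is checked: core-matrisome genes must be
#' ECM glycoproteins, collagens, or proteoglycans; matrisome-associated
#' genes must be ECM-affiliated proteins, ECM regulators, or secreted
#' factors; non-matrisome genes carry category `none`. Lookups are
#' case-insensitive and unknown genes resolve to `non_matrisome`.
#'
#' @param path Path to the annotation TSV. The package ships a small example
#'   under `system.file("extdata", "matrisome_annotation_demo.tsv",
#'   package = "xenomatrisome")`.
#' @return A tibble of class `xeno_annotation` with columns `gene`,
#'   `division`, `category`, plus the uppercase `gene_key`.
#' @export
load_annotation <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "division", "category")
  if (!all(required %in% names(raw))) {
    stop("annotation table needs columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  as_annotation(tibble::as_tibble(raw[, required]))
}

#' Construct an annotation table from a data frame
#'
#' @param df Data frame with `gene`, `division`, `category`.
#' @return See [load_annotation()].
#' @export
as_annotation <- function(df) {
  bad_div <- setdiff(unique(df$division), MATRISOME_DIVISIONS)
  if (length(bad_div) > 0) {
    stop("unknown matrisome division(s): ",
         paste(bad_div, collapse = ", "), call. = FALSE)
  }
  expected <- dplyr::case_when(
    df$category %in% CORE_CATEGORIES ~ "core_matrisome",
    df$category %in% ASSOCIATED_CATEGORIES ~ "matrisome_associated",
    df$category == "none" ~ "non_matrisome"
  )
  if (anyNA(expected)) {
    stop("unknown matrisome category(ies): ",
         paste(unique(df$category[is.na(expected)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- df$division != expected
  if (any(bad)) {
    stop("division/category mismatch for gene(s): ",
         paste(utils::head(df$gene[bad], 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  out$gene_key <- toupper(out$gene)
  if (anyDuplicated(out$gene_key)) {
    stop("duplicate gene symbol(s) in annotation: ",
         paste(unique(out$gene_key[duplicated(out$gene_key)]), collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("xeno_annotation", class(out))
  out
}

#' Annotate gene symbols against the matrisome
#'
#' @param annotation An `xeno_annotation` table.
#' @param genes Character vector of gene symbols (any case).
#' @return A tibble with `gene`, `division`, `category`; genes absent from
#'   the table come back as `non_matrisome` / `none`.
#' @export
annotate_genes <- function(annotation, genes) {
  i <- match(toupper(genes), annotation$gene_key)
  tibble::tibble(
    gene = genes,
    division = ifelse(is.na(i), "non_matrisome", annotation$division[i]),
    category = ifelse(is.na(i), "none", annotation$category[i])
  )
}

#' The two-replicate matrisome membership rule
#'
#' A protein belongs to a tumor's matrisome when it is detected in both of
#' the two independent biological replicates and by at least two peptides in
#' one of the two. The identical rule gates which proteins are considered
#' quantifiable (see [protein_quantifiable()]).
#'
#' @param counts Numeric vector of length 2: distinct-peptide counts in the
#'   two replicates.
#' @return `TRUE` iff both counts are at least 1 and the larger is at
#'   least 2.
#' @export
#' @examples
#' matrisome_membership(c(3, 2)) # TRUE
#' matrisome_membership(c(1, 1)) # FALSE
#' matrisome_membership(c(2, 1)) # TRUE
matrisome_membership <- function(counts) {
  if (length(counts) != 2 || anyNA(counts)) {
    stop("exactly two replicate peptide counts are required", call. = FALSE)
  }
  all(counts >= 1) && max(counts) >= 2
}
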