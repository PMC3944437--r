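# Sequence databases, in silico tryptic digestion, and species specificity.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read one species' protein sequence database
#'
#' Reads a FASTA file (plain or gzip) into a proteome tibble. Accessions are
#' taken from the first header token; UniProt-style `db|ACCESSION|NAME`
#' headers are unwrapped to the accession. Gene symbols are parsed from a
#' `GN=SYMBOL` header field when present, otherwise the accession is used.
#' Sequences are upper-cased and must use the 20 standard residues plus X.
#'
#' @param path Path to a FASTA file.
#' @param species `"human"` or `"mouse"`.
#' @return A tibble with columns `accession`, `species`, `gene_symbol`,
#'   `sequence`, `is_decoy`.
#' @export
read_fasta_proteome <- function(path, species = c("human", "mouse")) {
  species <- match.arg(species)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    stop("empty sequence database: ", path, call. = FALSE)
  }
  headers <- names(aa)
  first_tok <- stringr::str_extract(headers, "^\\S+")
  accession <- ifelse(
    stringr::str_detect(first_tok, "^[a-z]{2}\\|[^|]+\\|"),
    stringr::str_match(first_tok, "^[a-z]{2}\\|([^|]+)\\|")[, 2],
    first_tok
  )
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0) {
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  gene <- stringr::str_match(headers, "GN=(\\S+)")[, 2]
  gene <- ifelse(is.na(gene), accession, gene)
  seqs <- toupper(as.character(aa))
  bad <- stringr::str_detect(seqs, paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"))
  if (any(bad)) {
    stop("non-standard residues in entries: ",
         paste(utils::head(accession[bad], 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    accession = unname(accession),
    species = species,
    gene_symbol = unname(gene),
    sequence = unname(seqs),
    is_decoy = FALSE
  )
}

#' Read the paired human and mouse databases
#'
#' @param path_human,path_mouse FASTA paths for the human and mouse databases.
#' @return A named list with tibbles `human` and `mouse`
#'   (see [read_fasta_proteome()]).
#' @export
read_proteomes <- function(path_human, path_mouse) {
  list(
    human = read_fasta_proteome(path_human, "human"),
    mouse = read_fasta_proteome(path_mouse, "mouse")
  )
}

#' Append reversed-sequence decoy entries
#'
#' One decoy per target entry, built by full sequence reversal; decoy
#' accessions carry a `rev_` prefix and `is_decoy = TRUE`.
#'
#' @param proteome A proteome tibble.
#' @return The proteome with decoy rows appended.
#' @export
add_decoys <- function(proteome) {
  targets <- dplyr::filter(proteome, !.data$is_decoy)
  decoys <- dplyr::mutate(
    targets,
    accession = paste0("rev_", .data$accession),
    sequence = reverse_sequence(.data$sequence),
    is_decoy = TRUE
  )
  dplyr::bind_rows(dplyr::filter(proteome, !.data$is_decoy), decoys)
}

reverse_sequence <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' In silico tryptic digestion of one sequence
#'
#' Cleaves C-terminal to K or R, suppressed when the following residue is
#' proline, and enumerates all products with 0 to `max_missed_cleavages`
#' missed cleavage sites within the length window. The zero-missed-cleavage
#' products concatenate, in order, to the input sequence (when the length
#' window does not exclude any), and every product with m missed cleavages is
#' the concatenation of m+1 consecutive zero-missed products.
#'
#' @param sequence Amino-acid string.
#' @param max_missed_cleavages Maximum missed cleavage sites. Default 2.
#' @param min_length,max_length Product length window in residues.
#' @return A tibble with columns `peptide`, `missed_cleavages`, `start`,
#'   `end` (1-based coordinates on the input).
#' @export
#' @examples
#' digest("AKRPGK", max_missed_cleavages = 0, min_length = 1)
digest <- function(sequence, max_missed_cleavages = 2L,
                   min_length = 6L, max_length = 50L) {
  stopifnot(max_missed_cleavages >= 0)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0) {
    stop("cannot digest an empty sequence", call. = FALSE)
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[cut_after + 1L] != "P"]
  ends <- unique(c(cut_after, n))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  k <- length(starts)
  out <- vector("list", max_missed_cleavages + 1L)
  for (m in 0:max_missed_cleavages) {
    i <- seq_len(max(k - m, 0L))
    if (length(i) == 0) break
    s <- starts[i]
    e <- ends[i + m]
    len <- e - s + 1L
    keep <- len >= min_length & len <= max_length
    out[[m + 1L]] <- tibble::tibble(
      peptide = substring(sequence, s[keep], e[keep]),
      missed_cleavages = m,
      start = s[keep],
      end = e[keep]
    )
  }
  dplyr::bind_rows(out)
}

#' Digest every entry of a proteome
#'
#' @param proteome A proteome tibble.
#' @param params An [xeno_params()] list supplying the digestion settings.
#' @return A tibble with one row per (entry, peptide occurrence): columns
#'   `accession`, `species`, `is_decoy`, `gene_symbol`, `peptide`,
#'   `missed_cleavages`.
#' @export
digest_proteome <- function(proteome, params = xeno_params()) {
  pep <- purrr::map(proteome$sequence, digest,
    max_missed_cleavages = params$max_missed_cleavages,
    min_length = params$min_peptide_length,
    max_length = params$max_peptide_length
  )
  n <- vapply(pep, nrow, integer(1))
  dplyr::bind_cols(
    proteome[rep(seq_len(nrow(proteome)), n),
             c("accession", "species", "is_decoy", "gene_symbol")],
    dplyr::bind_rows(pep)[, c("peptide", "missed_cleavages")]
  )
}

#' Map residues through equivalence classes
#'
#' Residues within one class become indistinguishable; each class is mapped
#' to its first member. The default single class `"IL"` collapses the
#' mass-identical Leu/Ile pair that MS cannot tell apart.
#'
#' @param peptides Character vector of peptide sequences.
#' @param equivalence_classes Character vector of residue groups (see
#'   [xeno_params()]).
#' @return The mapped sequences.
#' @export
apply_equivalence <- function(peptides, equivalence_classes = "IL") {
  if (length(equivalence_classes) == 0) {
    return(peptides)
  }
  old <- character(0)
  new <- character(0)
  for (cls in equivalence_classes) {
    members <- strsplit(cls, "", fixed = TRUE)[[1]]
    old <- c(old, members[-1])
    new <- c(new, rep(members[1], length(members) - 1L))
  }
  chartr(paste(old, collapse = ""), paste(new, collapse = ""), peptides)
}

#' Classify peptides as species-specific or shared
#'
#' A peptide is `shared` when, after mapping residues through the active
#' equivalence classes, its sequence occurs in the tryptic digests of both
#' species' databases; otherwise it is specific to the single species whose
#' digest contains it. A peptide found in neither digest signals a mismatch
#' between the PSM table and the databases and is an error.
#'
#' @param peptides Character vector of peptide sequences.
#' @param human_peptides,mouse_peptides Character vectors holding each
#'   species' digest peptides (raw, unmapped).
#' @param equivalence_classes Residue groups merged before comparison.
#' @return Character vector over `"human_specific"`, `"mouse_specific"`,
#'   `"shared"`.
#' @export
#' @examples
#' classify_species_specificity("PEPTIDEK", "PEPTIDEK", "PEPTLDEK")
classify_species_specificity <- function(peptides, human_peptides,
                                         mouse_peptides,
                                         equivalence_classes = "IL") {
  p <- apply_equivalence(peptides, equivalence_classes)
  h <- p %in% apply_equivalence(human_peptides, equivalence_classes)
  m <- p %in% apply_equivalence(mouse_peptides, equivalence_classes)
  if (any(!h & !m)) {
    stop("peptide(s) absent from both digests (PSM/database mismatch): ",
         paste(utils::head(peptides[!h & !m], 5), collapse = ", "),
         call. = FALSE)
  }
  dplyr::case_when(h & m ~ "shared", h ~ "human_specific",
                   TRUE ~ "mouse_specific")
}

#' Build the combined peptide index for both species
#'
#' Digests both databases (decoy entries included) and indexes every
#' equivalence-mapped peptide with its parent accessions and species
#' specificity label. This index drives species classification, protein
#' grouping, and the orphan-peptide check.
#'
#' @param human,mouse Proteome tibbles; decoys are appended automatically if
#'   absent.
#' @param params An [xeno_params()] list.
#' @return An object of class `xeno_index`: a list with `table` (tibble:
#'   `peptide` mapped key, `species_label`, `parents` list-column of
#'   accessions, `parent_species`, `parent_decoy`, `min_missed`) plus the
#'   digestion settings used.
#' @export
build_peptide_index <- function(human, mouse, params = xeno_params()) {
  if (!any(human$is_decoy)) human <- add_decoys(human)
  if (!any(mouse$is_decoy)) mouse <- add_decoys(mouse)
  dg <- dplyr::bind_rows(
    digest_proteome(human, params),
    digest_proteome(mouse, params)
  )
  dg$key <- apply_equivalence(dg$peptide, params$equivalence_classes)
  dg <- dplyr::distinct(dg, .data$key, .data$accession, .keep_all = TRUE)
  tab <- dg |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      parents = list(.data$accession),
      parent_species = list(.data$species),
      parent_decoy = list(.data$is_decoy),
      parent_genes = list(.data$gene_symbol),
      min_missed = min(.data$missed_cleavages),
      species_label = {
        tgt <- !.data$is_decoy
        h <- any(tgt & .data$species == "human")
        m <- any(tgt & .data$species == "mouse")
        if (h && m) "shared" else if (h) "human_specific"
        else if (m) "mouse_specific" else "decoy_only"
      },
      .groups = "drop"
    ) |>
    dplyr::rename(peptide = "key")
  structure(
    list(table = tab, params = params),
    class = "xeno_index"
  )
}

#' @export
print.xeno_index <- function(x, ...) {
  cat("<xeno_index> ", nrow(x$table), " indexed peptides (",
      sum(x$table$species_label == "shared"), " shared between species)\n",
      sep = "")
  invisible(x)
}

# Look up index rows for a set of peptides; errors on orphans.
index_lookup <- function(index, peptides) {
  key <- apply_equivalence(peptides, index$params$equivalence_classes)
  i <- match(key, index$table$peptide)
  if (anyNA(i)) {
    stop("peptide(s) not found in either database digest: ",
         paste(utils::head(unique(peptides[is.na(i)]), 5), collapse = ", "),
         call. = FALSE)
  }
  index$table[i, ]
}

#' Write / read a digestion index as tab-separated text
#'
#' The on-disk format is one row per indexed peptide: `peptide`,
#' `species_label`, semicolon-joined `parents`, `min_missed`.
#'
#' @param index An `xeno_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_tsv <- function(index, path) {
  out <- tibble::tibble(
    peptide = index$table$peptide,
    species_label = index$table$species_label,
    parents = vapply(index$table$parents, paste, character(1), collapse = ";"),
    min_missed = index$table$min_missed
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
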