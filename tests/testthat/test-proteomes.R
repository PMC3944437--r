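test_that("tryptic digestion cleaves after K/R except before proline", {
  expect_setequal(
    digest("AKRPGK", max_missed_cleavages = 0, min_length = 1)$peptide,
    c("AK", "RPGK")
  )
  expect_setequal(
    digest("AKRPGK", max_missed_cleavages = 1, min_length = 1)$peptide,
    c("AK", "RPGK", "AKRPGK")
  )
  # terminal K/R leaves the whole sequence intact
  expect_equal(digest("MGR", 0, min_length = 1)$peptide, "MGR")
  expect_error(digest("", 0), "empty")
})

test_that("zero-missed peptides reconstruct the sequence and m-missed are
          concatenations of consecutive zero-missed ones", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_sequence(sample(20:120, 1))
    d0 <- digest(s, 0, min_length = 1, max_length = nchar(s))
    expect_identical(paste(d0$peptide, collapse = ""), s)
    d2 <- digest(s, 2, min_length = 1, max_length = nchar(s))
    for (m in 1:2) {
      dm <- d2[d2$missed_cleavages == m, ]
      for (j in seq_len(nrow(dm))) {
        k <- which(d0$start == dm$start[j])
        expect_identical(
          dm$peptide[j],
          paste(d0$peptide[k:(k + m)], collapse = "")
        )
      }
    }
  }
})

test_that("length bounds restrict digestion products", {
  d <- digest("AAAKGGGGGGGGGGRCCK", 0, min_length = 4, max_length = 11)
  expect_setequal(d$peptide, c("AAAK", "GGGGGGGGGGR"))
})

test_that("FASTA proteomes read with species, gene symbols and
          normalization", {
  ph <- write_temp_fasta(
    c("sp|P001|FN_HUMAN desc GN=FN1", "P002 GN=TNC", "P003"),
    c("MAKRPW", "tinyseqk", "AAAK")
  )
  pm <- write_temp_fasta(
    c("Q001 GN=Fn1", "Q002 GN=Tnc", "Q003"),
    c("MAKRPW", "TINYSEQK", "CCCK")
  )
  dbs <- read_proteomes(ph, pm)
  expect_equal(nrow(dbs$human), 3)
  expect_equal(nrow(dbs$mouse), 3)
  expect_equal(dbs$human$accession, c("P001", "P002", "P003"))
  expect_equal(dbs$human$gene_symbol[1:2], c("FN1", "TNC"))
  expect_equal(dbs$human$sequence[2], "TINYSEQK")   # upper-cased
  expect_true(all(dbs$mouse$species == "mouse"))

  dup <- write_temp_fasta(c("A1", "A1"), c("MAK", "MCK"))
  expect_error(read_fasta_proteome(dup, "human"), "A1")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta_proteome(empty, "human"), "empty")
})

test_that("decoy entries are reversed sequences flagged and prefixed", {
  prot <- tibble::tibble(accession = "P1", species = "human",
                         gene_symbol = "G1", sequence = "MAKRPW",
                         is_decoy = FALSE)
  wd <- add_decoys(prot)
  expect_equal(nrow(wd), 2)
  expect_equal(wd$sequence[wd$is_decoy], "WPRKAM")
  expect_equal(wd$accession[wd$is_decoy], "rev_P1")
})

test_that("species specificity honours residue equivalence classes", {
  h <- c("PEPTIDEK", "HUMONLYK")
  m <- c("PEPTLDEK", "MOUONLYK")
  expect_equal(classify_species_specificity("HUMONLYK", h, m), "human_specific")
  expect_equal(classify_species_specificity("MOUONLYK", h, m), "mouse_specific")
  # I == L merged by default, so the ortholog variants are shared
  expect_equal(classify_species_specificity("PEPTIDEK", h, m), "shared")
  expect_equal(
    classify_species_specificity("PEPTIDEK", h, m,
                                 equivalence_classes = character(0)),
    "human_specific"
  )
  expect_error(classify_species_specificity("ABSENTK", h, m), "mismatch")
})

test_that("specificity calls are symmetric under swapping the species", {
  set.seed(7)
  h <- replicate(30, random_sequence(8))
  m <- c(sample(h, 10), replicate(20, random_sequence(8)))
  pool <- unique(c(h, m))
  fwd <- classify_species_specificity(pool, h, m)
  rev <- classify_species_specificity(pool, m, h)
  expect_equal(fwd == "shared", rev == "shared")
  expect_equal(fwd == "human_specific", rev == "mouse_specific")
})

test_that("with equivalence disabled, shared equals literal co-occurrence
          in both digests", {
  set.seed(11)
  hseq <- replicate(4, random_sequence(60))
  mseq <- c(hseq[1], replicate(3, random_sequence(60)))
  hpep <- unlist(lapply(hseq, function(s) digest(s, 2, 1, 100)$peptide))
  mpep <- unlist(lapply(mseq, function(s) digest(s, 2, 1, 100)$peptide))
  pool <- unique(c(hpep, mpep))
  got <- classify_species_specificity(pool, hpep, mpep,
                                      equivalence_classes = character(0))
  want <- ifelse(pool %in% hpep & pool %in% mpep, "shared",
                 ifelse(pool %in% hpep, "human_specific", "mouse_specific"))
  expect_equal(got, want)
})

test_that("the combined peptide index labels species and resolves parents", {
  human <- tibble::tibble(accession = "H1", species = "human",
                          gene_symbol = "G1",
                          sequence = "AAAGGGKWEPTIDEK", is_decoy = FALSE)
  mouse <- tibble::tibble(accession = "M1", species = "mouse",
                          gene_symbol = "g1",
                          sequence = "AAAGGGKWEPTLDEK", is_decoy = FALSE)
  idx <- build_peptide_index(human, mouse,
                             xeno_params(min_peptide_length = 4))
  tab <- idx$table
  shared_row <- tab[tab$peptide == "AAAGGGK", ]
  expect_equal(shared_row$species_label, "shared")
  expect_setequal(shared_row$parents[[1]], c("H1", "M1"))
  # I/L variants of the ortholog peptide collapse onto one shared key
  il <- tab[tab$peptide == apply_equivalence("WEPTIDEK"), ]
  expect_equal(il$species_label, "shared")
  expect_true(any(tab$species_label == "decoy_only"))
})
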