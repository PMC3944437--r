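test_that("distinct peptides collapse charges, fractions and modification
          variants onto the best score", {
  psms <- dplyr::bind_rows(
    make_psms("AAAAAK", 12, charge = 2L),
    make_psms("AAAAAK", 15, charge = 3L, fraction_id = "f2"),
    make_psms("MAAAAK", 9, modifications = "1:oxidation_M"),
    make_psms("MAAAAK", 14),
    make_psms("CCCCCK", 7)
  )
  dp <- distinct_peptides(psms)
  expect_equal(nrow(dp), 3)
  expect_equal(dp$score[dp$peptide == "AAAAAK"], 15)
  expect_equal(dp$score[dp$peptide == "MAAAAK"], 14)
  expect_equal(dp$n_psms[dp$peptide == "AAAAAK"], 2L)
})

test_that("proteins sharing a long peptide group; unique evidence spawns
          subgroups as for species orthologs", {
  # two entries sharing a 10-mer, neither with unique peptides:
  # one group, one subgroup, representative = higher-scoring accession
  idx <- make_human_index(
    peptide = c("AAAAAAAAAK", "CCCCCK"),
    parents = list(c("H1", "H2"), c("H1", "H2"))
  )
  dp <- tibble::tibble(peptide = c("AAAAAAAAAK", "CCCCCK"), score = c(20, 5))
  sg <- group_proteins(dp, idx)
  expect_equal(nrow(sg), 1)
  expect_equal(sg$subgroup_id, "1.1")
  expect_setequal(sg$member_accessions[[1]], c("H1", "H2"))
  expect_equal(sg$protein_score, 25)

  # ortholog pair sharing a 10-mer, one unique peptide each:
  # one group, two subgroups G.1 and G.2
  idx2 <- make_index(tibble::tibble(
    peptide = c("AAAAAAAAAK", "HHHHHHK", "MMMMMMK"),
    parents = list(c("H1", "M1"), "H1", "M1"),
    parent_species = list(c("human", "mouse"), "human", "mouse"),
    parent_decoy = list(c(FALSE, FALSE), FALSE, FALSE)
  ))
  dp2 <- tibble::tibble(peptide = c("AAAAAAAAAK", "HHHHHHK", "MMMMMMK"),
                        score = c(18, 12, 9))
  sg2 <- group_proteins(dp2, idx2)
  expect_equal(nrow(sg2), 2)
  expect_equal(sg2$subgroup_id, c("1.1", "1.2"))
  expect_equal(sg2$representative_accession, c("H1", "M1"))
  expect_equal(sg2$species_content, c("human", "mouse"))
  # shared peptide counts toward both subgroups, unique ones toward their own
  expect_equal(sg2$protein_score, c(30, 27))
  expect_equal(sg2$peptides_common, c(1L, 1L))

  # a shared peptide of exactly 8 residues does not group (rule is "> 8")
  idx3 <- make_human_index(
    peptide = c("AAAAAAAK", "HHHHHHK", "MMMMMMK"),
    parents = list(c("H1", "H2"), "H1", "H2")
  )
  dp3 <- tibble::tibble(peptide = c("AAAAAAAK", "HHHHHHK", "MMMMMMK"),
                        score = c(18, 12, 9))
  sg3 <- group_proteins(dp3, idx3)
  expect_equal(length(unique(sg3$group)), 2)
  idx4 <- make_human_index(
    peptide = c("AAAAAAAAK", "HHHHHHK", "MMMMMMK"),
    parents = list(c("H1", "H2"), "H1", "H2")
  )
  sg4 <- group_proteins(dp3 |>
                          dplyr::mutate(peptide = replace(peptide, 1,
                                                          "AAAAAAAAK")),
                        idx4)
  expect_equal(length(unique(sg4$group)), 1)
})

test_that("grouping matches brute-force components and unique-evidence
          enumeration on random incidence structures", {
  set.seed(99)
  for (iter in 1:60) {
    inc <- random_incidence(12)
    idx <- make_human_index(inc$peptide, inc$parents)
    sg <- group_proteins(tibble::tibble(peptide = inc$peptide,
                                        score = inc$score), idx)
    og <- oracle_grouping(inc)

    # (1) reported proteins and component partition equal the oracle
    got_group <- integer(0)
    for (i in seq_len(nrow(sg))) {
      got_group[sg$member_accessions[[i]]] <- sg$group[i]
    }
    expect_setequal(names(got_group), og$reported)
    r <- og$reported
    expect_identical(unname(outer(got_group[r], got_group[r], "==")),
                     unname(outer(og$comp[r], og$comp[r], "==")))

    # (2) every distinct peptide is counted toward exactly one group
    pep_groups <- list()
    for (i in seq_len(nrow(sg))) {
      for (p in sg$peptides[[i]]$peptide) {
        pep_groups[[p]] <- union(pep_groups[[p]], sg$group[i])
      }
    }
    expect_true(all(lengths(pep_groups) == 1))
    expect_setequal(names(pep_groups), inc$peptide)

    # (3) one subgroup per unique-evidence member (one in total without
    # any), and uniquely matching peptides lie in their member's subgroup
    sub_of <- character(0)
    for (i in seq_len(nrow(sg))) {
      sub_of[sg$member_accessions[[i]]] <- sg$subgroup_id[i]
    }
    for (j in seq_len(nrow(inc))) {
      if (length(og$retained_parents[[j]]) == 1) {
        a <- og$retained_parents[[j]]
        i <- which(sg$subgroup_id == sub_of[a])
        expect_true(inc$peptide[j] %in% sg$peptides[[i]]$peptide)
      }
    }
    for (g in unique(got_group)) {
      members_g <- names(got_group)[got_group == g]
      sp_g <- intersect(og$spawners, members_g)
      expect_equal(sum(sg$group == g), max(1, length(sp_g)))
      expect_equal(length(unique(sub_of[sp_g])), length(sp_g))
    }

    # (4) protein score is the naive sum of its distinct peptide scores
    for (i in seq_len(nrow(sg))) {
      pt <- sg$peptides[[i]]
      expect_equal(sg$protein_score[i],
                   sum(inc$score[match(pt$peptide, inc$peptide)]))
    }
  }
})

test_that("protein score sums distinct peptide scores, restricted in
          subgroup-specific mode", {
  idx <- make_human_index(
    peptide = c("AAAAAAAAAK", "HHHHHHK", "MMMMMMK"),
    parents = list(c("H1", "H2"), "H1", "H2")
  )
  dp <- tibble::tibble(peptide = c("AAAAAAAAAK", "HHHHHHK", "MMMMMMK"),
                       score = c(10, 12, 9))
  sg <- group_proteins(dp, idx)
  expect_equal(protein_score(sg[1, ]), 22)
  expect_equal(protein_score(sg[1, ], subgroup_specific = TRUE), 12)
  # a single excellent-scoring peptide can pass the protein filter alone
  solo <- group_proteins(tibble::tibble(peptide = "QQQQQQQQQK", score = 25),
                         make_human_index("QQQQQQQQQK", list("H9")))
  expect_equal(solo$protein_score, 25)
  expect_equal(nrow(protein_level_filter(solo)), 1)
  # monotone: adding a peptide never lowers the score
  dp_more <- dplyr::bind_rows(dp,
                              tibble::tibble(peptide = "WWWWWWK", score = 3))
  idx_more <- make_human_index(
    peptide = c("AAAAAAAAAK", "HHHHHHK", "MMMMMMK", "WWWWWWK"),
    parents = list(c("H1", "H2"), "H1", "H2", "H1")
  )
  sg_more <- group_proteins(dp_more, idx_more)
  expect_gte(sg_more$protein_score[sg_more$representative_accession == "H1"],
             sg$protein_score[sg$representative_accession == "H1"])
})

test_that("peptide counts by species mode obey the conservation rule", {
  idx <- make_index(tibble::tibble(
    peptide = c("AAAAAAAAAK", "HHHHHHK", "WWWWWWK", "MMMMMMK"),
    parents = list(c("H1", "M1"), "H1", "H1", "M1"),
    parent_species = list(c("human", "mouse"), "human", "human", "mouse"),
    parent_decoy = list(c(FALSE, FALSE), FALSE, FALSE, FALSE)
  ))
  dp <- tibble::tibble(peptide = c("AAAAAAAAAK", "HHHHHHK", "WWWWWWK",
                                   "MMMMMMK"),
                       score = c(18, 12, 11, 9))
  sg <- group_proteins(dp, idx)
  h <- sg[sg$representative_accession == "H1", ]
  expect_equal(peptide_counts(h, "total"), 3L)
  expect_equal(peptide_counts(h, "human_specific"), 2L)
  expect_equal(peptide_counts(h, "common"), 1L)
  expect_equal(peptide_counts(h, "total"),
               peptide_counts(h, "species_specific") +
                 peptide_counts(h, "common"))
  m <- sg[sg$representative_accession == "M1", ]
  expect_equal(peptide_counts(m, "mouse_specific"), 1L)
  # only-shared subgroup has zero species-specific peptides
  only_shared <- group_proteins(
    tibble::tibble(peptide = "AAAAAAAAAK", score = 10),
    make_index(tibble::tibble(
      peptide = "AAAAAAAAAK", parents = list(c("H1", "M1")),
      parent_species = list(c("human", "mouse")),
      parent_decoy = list(c(FALSE, FALSE))
    ))
  )
  expect_equal(peptide_counts(only_shared[1, ], "species_specific"), 0L)
})

test_that("protein-level filter enforces the score floor and zero decoy
          survival", {
  mk <- function(scores, decoy) {
    idx <- make_index(tibble::tibble(
      peptide = sprintf("PEP%02dAAAAK", seq_along(scores)),
      parents = as.list(ifelse(decoy, paste0("rev_P", seq_along(scores)),
                               paste0("P", seq_along(scores)))),
      parent_species = as.list(rep("human", length(scores))),
      parent_decoy = as.list(decoy)
    ))
    dp <- tibble::tibble(peptide = sprintf("PEP%02dAAAAK", seq_along(scores)),
                         score = scores)
    group_proteins(dp, idx)
  }
  # {25, 19} targets, no decoys: only the 25 survives the floor of 20
  sg <- mk(c(25, 19), c(FALSE, FALSE))
  kept <- protein_level_filter(sg)
  expect_equal(kept$protein_score, 25)
  # target 22 below a decoy at 23: protein FDR 0 empties the list
  sg2 <- mk(c(22, 23), c(FALSE, TRUE))
  expect_equal(nrow(protein_level_filter(sg2)), 0)
  # no decoys, all targets at or above 20: everything is retained
  sg3 <- mk(c(20, 21, 24), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(protein_level_filter(sg3)), 3)
  # decoy below the surviving targets does not raise the cutoff
  sg4 <- mk(c(25, 24, 21), c(FALSE, FALSE, TRUE))
  expect_equal(nrow(protein_level_filter(sg4)), 2)
})

test_that("orphan peptides are rejected as database mismatches", {
  idx <- make_human_index("AAAAAAAAAK", list("H1"))
  expect_error(
    group_proteins(tibble::tibble(peptide = "ZZZZZZK", score = 10), idx),
    "not found"
  )
})
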