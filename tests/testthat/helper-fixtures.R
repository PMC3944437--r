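# Fixture builders and independent oracles shared across tests.

# Build an xeno_index directly from a peptide -> parents map, bypassing
# digestion, so grouping structures can be constructed at will.
# `df` needs columns: peptide, parents (list of chr), parent_species
# (list), parent_decoy (list). Optional scores are carried by the tests.
make_index <- function(df, equivalence_classes = character(0)) {
  # fixture accessions H<k>/M<k> denote an ortholog pair of gene G<k>
  df$parent_genes <- lapply(df$parents, function(p) {
    sub("^[HM](?=[0-9])", "G", sub("^rev_", "", p), perl = TRUE)
  })
  df$min_missed <- 0L
  df$species_label <- vapply(seq_len(nrow(df)), function(i) {
    tgt <- !df$parent_decoy[[i]]
    h <- any(tgt & df$parent_species[[i]] == "human")
    m <- any(tgt & df$parent_species[[i]] == "mouse")
    if (h && m) "shared" else if (h) "human_specific"
    else if (m) "mouse_specific" else "decoy_only"
  }, character(1))
  structure(
    list(table = tibble::as_tibble(df),
         params = xeno_params(equivalence_classes = equivalence_classes)),
    class = "xeno_index"
  )
}

# Shorthand: all-human target parents.
make_human_index <- function(peptide, parents) {
  make_index(tibble::tibble(
    peptide = peptide,
    parents = parents,
    parent_species = lapply(parents, function(p) rep("human", length(p))),
    parent_decoy = lapply(parents, function(p) rep(FALSE, length(p)))
  ))
}

# Minimal PSM tibble with sensible defaults.
make_psms <- function(peptide_sequence, score,
                      charge = 2L,
                      precursor_intensity = 1e6,
                      good_isotope_quality = TRUE,
                      modifications = "",
                      sample_id = "s1",
                      replicate_id = "r1",
                      fraction_id = "f1",
                      is_decoy = FALSE) {
  tibble::tibble(
    peptide_sequence = peptide_sequence,
    modifications = modifications,
    charge = as.integer(charge),
    score = score,
    precursor_intensity = precursor_intensity,
    good_isotope_quality = good_isotope_quality,
    sample_id = sample_id,
    replicate_id = replicate_id,
    fraction_id = fraction_id,
    is_decoy = is_decoy
  )
}

random_sequence <- function(len, letters = c("A", "C", "D", "E", "F", "G",
                                             "H", "I", "K", "L", "M", "N",
                                             "P", "Q", "R", "S", "T", "V",
                                             "W", "Y")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(headers, sequences) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", headers), sequences)), path)
  path
}

# --- independent oracles -----------------------------------------------

# Exhaustive-scan FDR threshold: smallest observed score t with
# decoys>=t / targets>=t <= fdr, Inf if none. Plain loops, no shared code.
oracle_fdr_threshold <- function(scores, is_decoy, fdr) {
  best <- Inf
  for (t in sort(unique(scores))) {
    nt <- 0
    nd <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= t) {
        if (is_decoy[i]) nd <- nd + 1 else nt <- nt + 1
      }
    }
    if (nt > 0 && nd / nt <= fdr) {
      best <- t
      break
    }
  }
  best
}

# Union-find connected components of proteins joined by peptides longer
# than `min_len` shared by two entries.
oracle_components <- function(pep_parents, pep_len, accs, min_len) {
  parent <- stats::setNames(accs, accs)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(pep_parents)) {
    if (pep_len[i] > min_len && length(pep_parents[[i]]) > 1) {
      r <- find(pep_parents[[i]][1])
      for (a in pep_parents[[i]][-1]) {
        parent[[find(a)]] <- r
      }
    }
  }
  vapply(accs, find, character(1))
}

# Full brute-force grouping oracle. Components by union-find; each peptide
# is then attributed to the component of its highest-raw-score parent
# (ties: lexicographic accession); proteins retaining no peptide are not
# reported; a member retaining a peptide whose in-group parents are only
# itself carries unique evidence.
oracle_grouping <- function(inc, min_len = 8) {
  accs <- sort(unique(unlist(inc$parents)))
  comp <- oracle_components(inc$parents, nchar(inc$peptide), accs, min_len)
  raw <- stats::setNames(numeric(length(accs)), accs)
  for (i in seq_len(nrow(inc))) {
    for (a in inc$parents[[i]]) raw[a] <- raw[a] + inc$score[i]
  }
  pep_comp <- character(nrow(inc))
  retained_parents <- vector("list", nrow(inc))
  for (i in seq_len(nrow(inc))) {
    ps <- inc$parents[[i]]
    best <- ps[order(-raw[ps], ps)][1]
    pep_comp[i] <- comp[[best]]
    retained_parents[[i]] <- ps[comp[ps] == pep_comp[i]]
  }
  reported <- sort(unique(unlist(retained_parents)))
  spawners <- unique(unlist(retained_parents[lengths(retained_parents) == 1]))
  list(comp = comp, pep_comp = pep_comp,
       retained_parents = retained_parents,
       reported = reported, spawners = spawners)
}

# Random peptide-protein incidence structure on <= n_max proteins.
random_incidence <- function(n_max = 12) {
  n_prot <- sample(2:n_max, 1)
  accs <- sprintf("P%02d", seq_len(n_prot))
  n_pep <- sample(4:18, 1)
  # letters exclude K/R/P so lengths are stable under any digestion logic
  peps <- character(n_pep)
  repeat {
    for (i in seq_len(n_pep)) {
      peps[i] <- random_sequence(sample(6:12, 1),
                                 letters = c("A", "D", "E", "F", "G", "S",
                                             "T", "V", "W", "Y"))
    }
    if (!anyDuplicated(peps)) break
  }
  parents <- lapply(seq_len(n_pep), function(i) {
    sort(sample(accs, sample(1:min(3, n_prot), 1)))
  })
  # every protein matched by at least one peptide
  unmatched <- setdiff(accs, unique(unlist(parents)))
  for (a in unmatched) {
    j <- sample(n_pep, 1)
    parents[[j]] <- sort(union(parents[[j]], a))
  }
  tibble::tibble(
    peptide = peps,
    parents = parents,
    score = round(stats::runif(n_pep, 1, 25), 2)
  )
}
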