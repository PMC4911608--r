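test_that("state extraction distinguishes missing residues from missing genes", {
  sim <- simulate_apomorphy_data(n_taxa = 8, tree_shape = "balanced",
                                 n_genes = 3, sites_per_gene = 20, seed = 6)
  apo <- mine_apomorphies(sim$tree, sim$matrix, sim$partition)
  cand <- filter_candidates(apo, sim$tree, sim$matrix, 1.0)
  sel <- suppressMessages(select_codes(sim$tree, cand, sim$matrix, sim$partition))
  db <- build_code_database(sel$selection, sim$tree, sim$matrix)

  tx <- "t01"
  q <- query_from_row(sim$matrix, sim$partition, tx)
  obs <- extract_states(db, q, sim$partition)
  expect_identical(obs$token,
                   unname(sim$matrix[tx, db$codes$site]))
  # drop one gene: every code on it reads "?"
  gmiss <- db$codes$gene[1]
  obs2 <- extract_states(db, q[setdiff(names(q), gmiss)], sim$partition)
  expect_true(all(obs2$token[db$codes$gene == gmiss] == "?"))
  expect_identical(obs2$token[db$codes$gene != gmiss],
                   obs$token[db$codes$gene != gmiss])
  # a gap at one code column reads "X"
  q3 <- q
  row <- match(db$codes$gene[1], sim$partition$gene)
  local_col <- db$codes$site[1] - sim$partition$start[row] + 1L
  q3[[db$codes$gene[1]]][local_col] <- "-"
  obs3 <- extract_states(db, q3, sim$partition)
  expect_identical(obs3$token[1], "X")
  # length mismatch names the gene
  q4 <- q
  q4[[gmiss]] <- q4[[gmiss]][-1]
  expect_error(extract_states(db, q4, sim$partition), gmiss)
})

test_that("every database taxon self-identifies with a complete match", {
  sim <- simulate_apomorphy_data(n_taxa = 16, tree_shape = "balanced",
                                 n_genes = 4, sites_per_gene = 30, seed = 8)
  apo <- mine_apomorphies(sim$tree, sim$matrix, sim$partition)
  cand <- filter_candidates(apo, sim$tree, sim$matrix, 1.0)
  sel <- suppressMessages(select_codes(sim$tree, cand, sim$matrix, sim$partition))
  db <- build_code_database(sel$selection, sim$tree, sim$matrix)
  for (tx in sprintf("t%02d", 1:16)) {
    a <- self_assign(db, sim, tx)
    expect_identical(db$labels[[a$assigned_id]], truth_terminal_of(db, sim$tree, tx))
    expect_true(a$complete_match)
    expect_identical(categorize(db, a, truth_terminal_of(db, sim$tree, tx)),
                     "positive")
  }
})

test_that("missing internal codes are skipped; missing terminal codes stop short", {
  db <- db_from_table1()
  fx <- table1_fixture()
  for (nm in c("Odonata", "Diptera", "Hymenoptera")) {
    bc <- barcode_of(db, nm)
    # mask a strict subset of internal codes: still positive
    masked <- bc
    masked$state[seq_len(nrow(bc) - 1)] <- "X"
    a <- assign_query(db, observation_from_barcode(db, masked))
    expect_identical(categorize(db, a, nm), "positive")
    expect_false(a$complete_match)
    # mask the terminal code: false negative
    masked2 <- bc
    masked2$state[nrow(bc)] <- "?"
    a2 <- assign_query(db, observation_from_barcode(db, masked2))
    expect_identical(categorize(db, a2, nm), "false_negative")
    # corrupt the terminal state to a non-designed amino acid: negative
    wrong <- bc
    wrong$state[nrow(bc)] <- setdiff(AA_STATES, wrong$state)[1]
    a3 <- assign_query(db, observation_from_barcode(db, wrong))
    expect_identical(categorize(db, a3, nm), "negative")
  }
})

test_that("published false-negative rows stop at their printed clades", {
  db <- db_from_table1()
  fx <- table1_fixture()
  run_row <- function(species) {
    row <- fx[fx$species == species, ]
    bc <- suppressMessages(parse_barcode(row$generated))
    assign_query(db, observation_from_barcode(db, bc))
  }
  pantala <- run_row("Pantala flavescens fabricius")
  expect_identical(pantala$assigned_label, "Pterygota")
  expect_identical(categorize(db, pantala, "Odonata"), "false_negative")
  xyela <- run_row("Xyela alpigena")
  expect_identical(xyela$assigned_label, "Holometabola")
  expect_identical(categorize(db, xyela, "Hymenoptera"), "false_negative")
  anopl <- run_row("Anoplophora glabripennis")
  expect_identical(anopl$assigned_label, "Coleopterodea")
  # a verbatim designed barcode is a complete match to its terminal
  ful <- assign_query(db, observation_from_barcode(
    db, suppressMessages(parse_barcode(fx$designed[fx$species == "Ischnura elegans"]))))
  expect_identical(ful$assigned_label, "Odonata")
  expect_true(ful$complete_match)
})

test_that("assignment never descends through a non-missing mismatch", {
  db <- db_from_table1()
  bc <- barcode_of(db, "Diptera")
  # contradict an internal code (id 0X, state N): walk must stop above it
  wrong <- bc
  k <- match("0X", wrong$id)
  wrong$state[k] <- "W"
  a <- assign_query(db, observation_from_barcode(db, wrong))
  expect_false("0X" %in% a$path[a$judgments[a$path] == "match"])
  expect_true(is.na(a$assigned_id) ||
                !"0X" %in% barcode_of(db, a$assigned_id)$id)
  expect_identical(categorize(db, a, "Diptera"), "negative")
})

test_that("missingness report splits X from ? and handles empty input", {
  obs <- list(tibble::tibble(id = c("00", "01", "02"), site = NA_integer_,
                             token = c("X", "X", "?")))
  rep <- missingness_report(obs)
  expect_equal(rep$x_fraction, 2 / 3)
  expect_equal(rep$n_question, 1L)
  none <- missingness_report(list(tibble::tibble(id = "00", site = NA_integer_,
                                                 token = "A")))
  expect_true(is.na(none$x_fraction))
  expect_equal(none$n_X + none$n_question, 0L)
  # simulator with gene_missing_p = 0: every missing token is X
  sim <- simulate_apomorphy_data(n_taxa = 8, tree_shape = "balanced",
                                 n_genes = 2, sites_per_gene = 20,
                                 site_missing_p = 0.3, seed = 12)
  apo <- mine_apomorphies(sim$tree, sim$matrix, sim$partition)
  expect_true(all(sim$mask$type == "site"))
})
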