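# Gap-filling: parsimonious single-condition repair against the exhaustive
# subset oracle, iterative order sensitivity, ensemble generation.

test_that("single-condition gap-fill recovers the removed reaction and
          matches the subset-enumeration oracle", {
  m <- toy_chain_model()
  deg <- degrade_model(m, "CONV_1_1", n_decoys = 3, seed = 4)
  cond <- list(condition_id = "c1", medium = c(EX_S1 = 10), growth = TRUE)

  expect_equal(optimize_fba(set_medium(deg$draft,
                                       cond$medium))$objective_value, 0,
               tolerance = 1e-6)

  sol <- gapfill_one_condition(deg$draft, deg$universal, cond)
  expect_identical(sol$added_reaction_ids, "CONV_1_1")
  expect_gte(sol$objective_achieved, 0.05)

  oracle_min <- gapfill_subset_oracle(deg$draft, deg$universal, cond)
  expect_equal(sol$flux_sum, oracle_min, tolerance = 1e-6)
})

test_that("a model that already grows needs no repair; an inadequate
          universal raises an infeasibility naming the condition", {
  m <- toy_chain_model()
  deg <- degrade_model(m, "CONV_1_1")
  cond <- list(condition_id = "cond_x", medium = c(EX_S1 = 10), growth = TRUE)

  sol <- gapfill_one_condition(m, deg$universal, cond)
  expect_identical(sol$added_reaction_ids, character())

  uni_bad <- deg$universal
  uni_bad$reactions <- uni_bad$reactions[uni_bad$reactions$id != "CONV_1_1", ]
  expect_error(gapfill_one_condition(deg$draft, uni_bad, cond), "cond_x")

  no_growth <- cond; no_growth$growth <- FALSE
  expect_error(gapfill_one_condition(deg$draft, deg$universal, no_growth),
               "no-growth")
})

test_that("decoy dead-end reactions never enter a solution", {
  m <- make_toy_model(fixture_spec(n_carbon_sources = 2))
  deg <- degrade_model(m, c("CONV_1_1", "CONV_2_1"), n_decoys = 4, seed = 8)
  conds <- make_phenotype_table(
    m, list(c1 = c(EX_S1 = 10), c2 = c(EX_S2 = 10)))
  for (i in seq_len(nrow(conds))) {
    sol <- gapfill_one_condition(deg$draft, deg$universal, conds[i, ])
    expect_length(grep("^DECOY_", sol$added_reaction_ids), 0)
  }
  res <- iterative_gapfill(deg$draft, deg$universal, conds)
  expect_length(grep("^DECOY_", res$added_reaction_ids), 0)
  expect_setequal(res$added_reaction_ids, c("CONV_1_1", "CONV_2_1"))
})

test_that("iterative gap-fill satisfies every condition and is
          order-sensitive on the two-pathway fixture", {
  fx <- make_two_pathway_fixture()

  r12 <- iterative_gapfill(fx$draft, fx$universal, fx$phenotypes)
  r21 <- iterative_gapfill(fx$draft, fx$universal, fx$phenotypes[2:1, ])

  expect_setequal(r12$added_reaction_ids, c("RAP", "RBA"))
  expect_setequal(r21$added_reaction_ids, c("RBP", "RAB"))

  for (r in list(r12, r21)) {
    for (i in seq_len(nrow(fx$phenotypes))) {
      m <- set_medium(r$model, fx$phenotypes$medium[[i]])
      expect_gte(optimize_fba(m)$objective_value, 0.05)
    }
  }
})

test_that("single-condition iterative gap-fill reduces to the one-shot case", {
  m <- toy_chain_model()
  deg <- degrade_model(m, "CONV_1_1")
  cond <- tibble::tibble(condition_id = "c1", growth = TRUE,
                         medium = list(c(EX_S1 = 10)))
  one <- gapfill_one_condition(deg$draft, deg$universal, cond)
  iter <- iterative_gapfill(deg$draft, deg$universal, cond)
  expect_identical(sort(iter$added_reaction_ids),
                   sort(one$added_reaction_ids))
  expect_true(all(one$added_reaction_ids %in% iter$model$reactions$id))
})

test_that("gap-fill ensembles contain the unique variants, reproducibly", {
  fx <- make_two_pathway_fixture()
  ens <- generate_gapfill_ensemble(fx$draft, fx$universal, fx$phenotypes,
                                   cycles = 20, condition_fraction = 1,
                                   seed = 7)
  expect_gte(nrow(ens$members), 2)

  # all members have distinct added-reaction sets
  bin <- feature_state_table(ens, binarize = TRUE)
  keys <- apply(bin[, -1, drop = FALSE], 1, paste, collapse = "")
  expect_identical(anyDuplicated(keys), 0L)

  # every member grows on the conditions of its cycle
  for (mid in member_ids(ens)) {
    prov <- ens$members$provenance[ens$members$member_id == mid]
    used <- regmatches(prov, gregexpr("c[0-9]+", prov))[[1]]
    m <- extract_member(ens, mid)
    for (cid in used) {
      medium <- fx$phenotypes$medium[[match(cid, fx$phenotypes$condition_id)]]
      expect_gte(optimize_fba(set_medium(m, medium))$objective_value, 0.05)
    }
  }

  # bit-identical reproduction under the same seed, including the archive
  ens2 <- generate_gapfill_ensemble(fx$draft, fx$universal, fx$phenotypes,
                                    cycles = 20, condition_fraction = 1,
                                    seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  save_ensemble(ens, d1); save_ensemble(ens2, d2)
  for (f in c("base.xml", "ensemble.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a universal with exactly one feasible repair gives a one-member,
          zero-feature ensemble", {
  m <- toy_chain_model()
  deg <- degrade_model(m, "CONV_1_1", n_decoys = 2)
  pheno <- make_phenotype_table(m, list(c1 = c(EX_S1 = 10)))
  ens <- generate_gapfill_ensemble(deg$draft, deg$universal, pheno,
                                   cycles = 5, seed = 3)
  expect_identical(nrow(ens$members), 1L)
  expect_identical(nrow(ens$features), 0L)
  expect_true("CONV_1_1" %in% ens$base_model$reactions$id)
})

test_that("no-growth conditions are excluded from gap-filling", {
  m <- toy_chain_model()
  deg <- degrade_model(m, "CONV_1_1")
  pheno <- tibble::tibble(
    condition_id = c("pos", "neg"),
    growth = c(TRUE, FALSE),
    medium = list(c(EX_S1 = 10), c(EX_S1 = 0)))
  ens <- generate_gapfill_ensemble(deg$draft, deg$universal, pheno,
                                   cycles = 3, seed = 2)
  expect_false(any(grepl("neg", ens$members$provenance)))
  expect_error(iterative_gapfill(deg$draft, deg$universal, pheno), "neg")
})

test_that("fractional condition subsampling uses ceiling and stays seeded", {
  m <- make_toy_model(fixture_spec(n_carbon_sources = 2))
  deg <- degrade_model(m, c("CONV_1_1", "CONV_2_1"))
  pheno <- make_phenotype_table(m, list(c1 = c(EX_S1 = 10),
                                        c2 = c(EX_S2 = 10)))
  ens <- generate_gapfill_ensemble(deg$draft, deg$universal, pheno,
                                   cycles = 6, condition_fraction = 0.5,
                                   seed = 11)
  # ceiling(0.5 * 2) = 1 condition per cycle: each provenance names one
  expect_true(all(grepl("condition order: c[12]$", ens$members$provenance)))
})
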