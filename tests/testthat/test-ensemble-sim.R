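# Ensemble-scale simulations: member selection, oracle equivalence against
# the single-model layer, worker determinism, infeasible flagging.

test_that("member selection covers all, explicit lists, and fractions", {
  syn <- make_test_ensemble(n_members = 10, seed = 2)
  ens <- syn$ensemble
  ids <- member_ids(ens)

  expect_identical(select_members(ens, "all"), sort(ids))
  expect_identical(select_members(ens, ids[c(3, 1)]), sort(ids[c(1, 3)]))

  half <- select_members(ens, 0.5, seed = 42)
  expect_length(half, 5)
  expect_identical(half, select_members(ens, 0.5, seed = 42))
  expect_length(select_members(ens, 0.3, seed = 1), 3)  # ceiling(0.3 * 10)
  expect_length(select_members(ens, 1.0, seed = 1), 10)

  expect_error(select_members(ens, 0), "fraction")
  expect_error(select_members(ens, 1.5), "fraction")
  expect_error(select_members(ens, "ghost"), "ghost")
})

test_that("every ensemble row equals the single-model result on the
          extracted member", {
  syn <- make_test_ensemble(n_members = 6, seed = 31)
  ens <- syn$ensemble

  fba <- ensemble_fba(ens)
  fva <- ensemble_fva(ens, fraction_of_optimum = 1,
                      reactions = c("EX_S1", "BIOMASS", "CONV_2_1"))
  del <- ensemble_deletions(ens, "reaction",
                            targets = c("TRANS_1", "CONV_2_1"))

  for (mid in member_ids(ens)) {
    m <- extract_member(ens, mid)
    sol <- optimize_fba(m)
    row <- fba[fba$member_id == mid, ]
    expect_equal(row$objective, sol$objective_value, tolerance = 1e-6)
    expect_equal(unlist(row[, names(sol$fluxes)]),
                 sol$fluxes, tolerance = 1e-6, info = mid)

    fva_single <- run_fva(m, 1, c("EX_S1", "BIOMASS", "CONV_2_1"))
    frow <- fva[fva$member_id == mid, ]
    for (i in seq_len(nrow(fva_single))) {
      rid <- fva_single$reaction[i]
      expect_equal(frow[[paste0(rid, "_min")]], fva_single$min[i],
                   tolerance = 1e-6, info = paste(mid, rid))
      expect_equal(frow[[paste0(rid, "_max")]], fva_single$max[i],
                   tolerance = 1e-6, info = paste(mid, rid))
    }

    del_single <- run_single_deletions(m, "reaction",
                                       c("TRANS_1", "CONV_2_1"))
    drow <- del[del$member_id == mid, ]
    expect_equal(unlist(drow[, del_single$target]),
                 setNames(del_single$objective, del_single$target),
                 tolerance = 1e-6, info = mid)
  }
})

test_that("result tables are identical for any worker count", {
  syn <- make_test_ensemble(n_members = 8, seed = 17)
  ens <- syn$ensemble
  expect_identical(tibble::as_tibble(ensemble_fba(ens, workers = 1)),
                   tibble::as_tibble(ensemble_fba(ens, workers = 4)))
  expect_identical(
    tibble::as_tibble(ensemble_deletions(ens, "reaction",
                                         targets = "CONV_2_1", workers = 1)),
    tibble::as_tibble(ensemble_deletions(ens, "reaction",
                                         targets = "CONV_2_1", workers = 4)))
})

test_that("subset simulation returns exactly the requested rows", {
  syn <- make_test_ensemble(n_members = 10, seed = 3)
  ens <- syn$ensemble
  ids <- member_ids(ens)[c(2, 7)]
  r <- ensemble_fba(ens, members = ids)
  expect_identical(r$member_id, sort(ids))
  expect_identical(nrow(r), 2L)
})

test_that("infeasible members are flagged rows, not crashes", {
  # a member forced to carry flux through a dead-end is infeasible
  base <- toy_chain_model()
  base$metabolites <- dplyr::bind_rows(
    base$metabolites, tibble::tibble(id = "D", name = "D", compartment = "c"))
  base$reactions <- dplyr::bind_rows(
    base$reactions,
    tibble::tibble(id = "DEAD", lower_bound = 0, upper_bound = 0,
                   gene_rule = "", stoichiometry = list(c(P = -1, D = 1))))
  feats <- tibble::tibble(feature_id = "DEAD__lower_bound",
                          component_id = "DEAD", attribute = "lower_bound")
  states <- tibble::tibble(member_id = c("ok", "broken"),
                           DEAD__lower_bound = c(0, 1))
  # the broken member needs its upper bound open too
  base$reactions$upper_bound[match("DEAD", base$reactions$id)] <- 0
  feats <- dplyr::bind_rows(
    feats, tibble::tibble(feature_id = "DEAD__upper_bound",
                          component_id = "DEAD", attribute = "upper_bound"))
  states$DEAD__upper_bound <- c(0, 1)
  ens <- new_ensemble("flagtest", base, feats,
                      tibble::tibble(member_id = c("ok", "broken"),
                                     provenance = ""),
                      states)
  r <- ensemble_fba(ens)
  expect_identical(r$status[r$member_id == "broken"], "infeasible")
  expect_true(is.na(r$objective[r$member_id == "broken"]))
  expect_identical(r$status[r$member_id == "ok"], "optimal")
  expect_identical(nrow(r), 2L)
})

test_that("FVA intervals at relaxed optimum contain the strict intervals
          and min <= max everywhere", {
  syn <- make_test_ensemble(n_members = 5, seed = 13)
  ens <- syn$ensemble
  rxns <- c("EX_S1", "EX_S2", "BIOMASS")
  strict <- ensemble_fva(ens, fraction_of_optimum = 1, reactions = rxns)
  relaxed <- ensemble_fva(ens, fraction_of_optimum = 0, reactions = rxns)
  for (rid in rxns) {
    expect_true(all(strict[[paste0(rid, "_min")]] <=
                      strict[[paste0(rid, "_max")]] + 1e-6))
    expect_true(all(relaxed[[paste0(rid, "_min")]] <=
                      strict[[paste0(rid, "_min")]] + 1e-6))
    expect_true(all(strict[[paste0(rid, "_max")]] <=
                      relaxed[[paste0(rid, "_max")]] + 1e-6))
  }
})

test_that("deleting a reaction absent in a member is a no-op for it", {
  fx_m1 <- toy_chain_model(); fx_m1$id <- "m1"
  fx_m2 <- fx_m1; fx_m2$id <- "m2"
  fx_m2$reactions <- fx_m2$reactions[fx_m2$reactions$id != "CONV_1_1", ]
  ens <- build_from_models(list(fx_m1, fx_m2))
  undeleted <- ensemble_fba(ens)
  del <- ensemble_deletions(ens, "reaction", targets = "CONV_1_1")
  expect_equal(del$CONV_1_1, c(0, 0), tolerance = 1e-6)  # essential in m1...
  expect_equal(del$CONV_1_1[del$member_id == "m2"],
               undeleted$objective[undeleted$member_id == "m2"],
               tolerance = 1e-6)  # ...but already absent (objective 0) in m2
  ess <- essentiality_frequency(del)
  expect_equal(ess$essentiality, 1)

  # the ensemble base model is restored after simulation
  expect_identical(ensemble_fba(ens)$objective, undeleted$objective)
})

test_that("tidy and glance summarise result tables", {
  syn <- make_test_ensemble(n_members = 5, seed = 41)
  r <- ensemble_fba(syn$ensemble)
  long <- tidy(r)
  expect_true(all(c("member_id", "variable", "value") %in% names(long)))
  g <- glance(r)
  expect_identical(g$n_members, 5L)
  expect_true(g$mean_objective >= 10 - 1e-6)

  fva <- ensemble_fva(syn$ensemble, reactions = "BIOMASS")
  tf <- tidy(fva)
  expect_true(all(c("member_id", "reaction", "min", "max") %in% names(tf)))
})
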