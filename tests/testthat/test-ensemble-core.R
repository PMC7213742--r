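# Ensemble representation: construction from model collections, state
# switching, extraction, curation edits, serialization, compression.

two_member_fixture <- function() {
  m1 <- toy_chain_model()
  m1$id <- "m1"
  # m1 with the conversion reaction made reversible so absence produces two
  # bound features, matching the presence/absence encoding
  i <- match("CONV_1_1", m1$reactions$id)
  m1$reactions$lower_bound[i] <- -1000
  m2 <- m1
  m2$id <- "m2"
  m2$reactions <- m2$reactions[m2$reactions$id != "CONV_1_1", ]
  list(m1 = m1, m2 = m2)
}

test_that("identical sources give an ensemble with members but no features", {
  m <- toy_chain_model()
  a <- m; a$id <- "a"
  b <- m; b$id <- "b"
  ens <- build_from_models(list(a, b))
  expect_identical(nrow(ens$members), 2L)
  expect_identical(nrow(ens$features), 0L)
  tbl <- feature_state_table(ens)
  expect_identical(dim(tbl), c(2L, 1L))  # member_id column only
})

test_that("a missing reaction becomes two (0,0) bound features", {
  fx <- two_member_fixture()
  ens <- build_from_models(list(fx$m1, fx$m2))
  expect_setequal(ens$features$feature_id,
                  c("CONV_1_1__lower_bound", "CONV_1_1__upper_bound"))
  st <- feature_state_table(ens)
  expect_equal(st$CONV_1_1__lower_bound[st$member_id == "m2"], 0)
  expect_equal(st$CONV_1_1__upper_bound[st$member_id == "m2"], 0)
  # binarized view: m2 row is all zeros
  bin <- feature_state_table(ens, binarize = TRUE)
  expect_equal(unlist(bin[bin$member_id == "m2", -1]),
               c(CONV_1_1__lower_bound = 0L, CONV_1_1__upper_bound = 0L))

  # extracted members reproduce the inputs
  e1 <- extract_member(ens, "m1")
  e2 <- extract_member(ens, "m2")
  expect_equal(optimize_fba(e1)$objective_value,
               optimize_fba(fx$m1)$objective_value, tolerance = 1e-6)
  expect_equal(get_bound(e2, "CONV_1_1", "lower_bound"), 0)
  expect_equal(get_bound(e2, "CONV_1_1", "upper_bound"), 0)
  expect_equal(optimize_fba(e2)$objective_value,
               optimize_fba(fx$m2)$objective_value, tolerance = 1e-6)
})

test_that("construction is independent of batch size and source order", {
  fx <- two_member_fixture()
  d <- tempfile(); dir.create(d)
  p1 <- file.path(d, "m1.json"); write_model(fx$m1, p1)
  p2 <- file.path(d, "m2.json"); write_model(fx$m2, p2)

  e_b1 <- build_from_models(c(p1, p2), batch_size = 1)
  e_b2 <- build_from_models(c(p1, p2), batch_size = 2)
  expect_identical(e_b1$features, e_b2$features)
  expect_identical(e_b1$states, e_b2$states)
  expect_identical(e_b1$members$member_id, c("m1", "m2"))

  # reversed source order: same features, same per-member behaviour
  e_rev <- build_from_models(c(p2, p1), batch_size = 1)
  expect_setequal(e_rev$features$feature_id, e_b1$features$feature_id)
  for (mid in c("m1", "m2")) {
    expect_equal(
      optimize_fba(extract_member(e_rev, mid))$objective_value,
      optimize_fba(extract_member(e_b1, mid))$objective_value,
      tolerance = 1e-6)
  }
})

test_that("conflicting stoichiometry for a shared reaction id is an error", {
  m1 <- toy_chain_model(); m1$id <- "m1"
  m2 <- toy_chain_model(); m2$id <- "m2"
  i <- match("CONV_1_1", m2$reactions$id)
  m2$reactions$stoichiometry[[i]] <- c(S1_c = -2, P = 1)
  expect_error(build_from_models(list(m1, m2)), "CONV_1_1")
  expect_error(build_from_models(list()), "at least one")
})

test_that("state switching is exact and member extraction is isolated", {
  fx <- two_member_fixture()
  ens <- build_from_models(list(fx$m1, fx$m2))

  ens <- set_member_state(ens, "m2")
  expect_equal(get_bound(ens$base_model, "CONV_1_1", "upper_bound"), 0)
  expect_identical(ens$current_member, "m2")

  # m1 -> m2 -> m1 is identical to a single m1 application
  ens_a <- set_member_state(ens, "m1")
  ens_b <- set_member_state(set_member_state(ens_a, "m2"), "m1")
  expect_identical(ens_a$base_model$reactions, ens_b$base_model$reactions)

  # impersonation equals extraction
  sol_imp <- optimize_fba(set_member_state(ens, "m2")$base_model)
  sol_ext <- optimize_fba(extract_member(ens, "m2"))
  expect_equal(sol_imp$objective_value, sol_ext$objective_value,
               tolerance = 1e-6)

  # mutating an extracted model does not touch the ensemble
  e1 <- extract_member(ens, "m1")
  e1$reactions$upper_bound[1] <- 1
  expect_equal(
    feature_state_table(ens)$CONV_1_1__upper_bound,
    c(1000, 0))

  expect_error(set_member_state(ens, "ghost"), "ghost")
  expect_error(extract_member(ens, "ghost"), "ghost")
})

test_that("state table reconstruction reproduces member behaviour", {
  fx <- two_member_fixture()
  ens <- build_from_models(list(fx$m1, fx$m2))
  st <- feature_state_table(ens)
  for (mid in st$member_id) {
    m <- ens$base_model
    for (fid in ens$features$feature_id) {
      k <- match(fid, ens$features$feature_id)
      m <- gemsemble:::set_reaction_attr(
        m, ens$features$component_id[k], ens$features$attribute[k],
        st[[fid]][st$member_id == mid])
    }
    expect_equal(optimize_fba(m)$objective_value,
                 optimize_fba(extract_member(ens, mid))$objective_value,
                 tolerance = 1e-6, info = mid)
  }
})

test_that("blocking a feature across members lowers the FBA distribution", {
  syn <- make_test_ensemble(n_members = 12, seed = 5)
  ens <- syn$ensemble
  before <- ensemble_fba(ens)
  ens2 <- set_feature_across_members(ens, syn$causal_feature, 0)
  expect_true(all(feature_state_table(ens2)[[syn$causal_feature]] == 0))
  after <- ensemble_fba(ens2)
  # tightening a bound can never raise an LP optimum
  expect_true(all(after$objective <= before$objective + 1e-6))

  # idempotence: setting an already-uniform value changes nothing
  ens3 <- set_feature_across_members(ens2, syn$causal_feature, 0)
  expect_tables_equal(ensemble_fba(ens3), after)

  expect_error(set_feature_across_members(ens, "ghost", 0), "ghost")
  expect_error(set_feature_across_members(ens, syn$causal_feature, "x"),
               "numeric")
})

test_that("ensemble archives round-trip exactly", {
  syn <- make_test_ensemble(n_members = 8, seed = 9)
  ens <- syn$ensemble
  d <- tempfile()
  save_ensemble(ens, d)
  ens2 <- load_ensemble(d)
  expect_identical(feature_state_table(ens2), feature_state_table(ens))
  expect_tables_equal(ensemble_fba(ens2), ensemble_fba(ens))

  # corrupt archive and version mismatch are explicit errors
  expect_error(load_ensemble(tempfile()), "archive")
  doc <- jsonlite::read_json(file.path(d, "ensemble.json"))
  doc$format_version <- 999
  jsonlite::write_json(doc, file.path(d, "ensemble.json"), auto_unbox = TRUE)
  expect_error(load_ensemble(d), "version")
})

test_that("the archive stores |members| x |features| state entries and is
          at least 10x smaller than per-member model files", {
  syn <- make_test_ensemble(n_members = 100, seed = 23)
  ens <- syn$ensemble
  d <- tempfile()
  save_ensemble(ens, d)

  doc <- jsonlite::read_json(file.path(d, "ensemble.json"))
  n_entries <- sum(lengths(doc$states))
  expect_identical(n_entries, nrow(ens$members) * nrow(ens$features))

  archive_size <- sum(file.size(list.files(d, full.names = TRUE,
                                           recursive = TRUE)))
  d2 <- tempfile(); dir.create(d2)
  for (mid in member_ids(ens)) {
    write_model(extract_member(ens, mid),
                file.path(d2, paste0(mid, ".xml")))
  }
  individual_size <- sum(file.size(list.files(d2, full.names = TRUE)))
  expect_gte(individual_size / archive_size, 10)
})
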