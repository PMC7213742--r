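# Synthetic fixtures: deterministic toy networks, degraded drafts with a
# universal repair database, phenotype tables, and ensembles with a planted
# causal feature. Every generator is seeded and asserts its own ground truth
# on creation, so the whole package is testable without any external data.

#' Specification for synthetic fixtures
#'
#' @param seed Integer seed; identical specs give identical fixtures.
#' @param n_carbon_sources Number of independent carbon-source chains (>= 1).
#' @param n_pathway_alternatives Parallel conversion reactions per chain
#'   (>= 1); values above 1 create redundancy for deletion tests.
#' @param noise_sd Nonnegative noise standard deviation used when fixtures
#'   generate synthetic outcome values.
#' @param uptake_bound Maximum uptake rate per carbon source (mmol/gDW/hr).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_carbon_sources = 1L,
                         n_pathway_alternatives = 1L, noise_sd = 0.1,
                         uptake_bound = 10) {
  stopifnot(n_carbon_sources >= 1, n_pathway_alternatives >= 1,
            noise_sd >= 0, uptake_bound > 0)
  structure(list(seed = as.integer(seed),
                 n_carbon_sources = as.integer(n_carbon_sources),
                 n_pathway_alternatives = as.integer(n_pathway_alternatives),
                 noise_sd = noise_sd, uptake_bound = uptake_bound),
            class = "fixture_spec")
}

#' Build a toy linear-chain metabolic model
#'
#' One exchange + transporter + conversion chain per carbon source, all
#' feeding a common precursor drained by a biomass reaction. The FBA optimum
#' is hand-computable: with all sources open it equals
#' `uptake_bound * n_carbon_sources`.
#'
#' Chain for source k: `EX_Sk` (exchange, bounds `(-uptake, 1000)`),
#' `TRANS_k` (`Sk_e -> Sk_c`, GPR `gT_k`), `CONV_k_j`
#' (`Sk_c -> P`, GPR `gC_k_ja or gC_k_jb`, one per pathway alternative),
#' and the shared `BIOMASS` (`P ->`, the objective).
#'
#' @param spec A [fixture_spec()].
#' @return A `metabolic_model`.
#' @export
make_toy_model <- function(spec = fixture_spec()) {
  ns <- spec$n_carbon_sources
  na <- spec$n_pathway_alternatives
  mets <- tibble::tibble(
    id = c(paste0("S", seq_len(ns), "_e"), paste0("S", seq_len(ns), "_c"), "P"),
    name = c(paste0("source ", seq_len(ns), " extracellular"),
             paste0("source ", seq_len(ns), " cytosol"),
             "biomass precursor"),
    compartment = c(rep("e", ns), rep("c", ns), "c"))

  rows <- list()
  for (k in seq_len(ns)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("EX_S%d", k), lower_bound = -spec$uptake_bound,
      upper_bound = 1000, gene_rule = "",
      stoichiometry = list(stats::setNames(-1, sprintf("S%d_e", k))))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("TRANS_%d", k), lower_bound = 0, upper_bound = 1000,
      gene_rule = sprintf("gT_%d", k),
      stoichiometry = list(stats::setNames(c(-1, 1),
                                           c(sprintf("S%d_e", k),
                                             sprintf("S%d_c", k)))))
    for (j in seq_len(na)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("CONV_%d_%d", k, j), lower_bound = 0, upper_bound = 1000,
        gene_rule = sprintf("gC_%d_%da or gC_%d_%db", k, j, k, j),
        stoichiometry = list(stats::setNames(c(-1, 1),
                                             c(sprintf("S%d_c", k), "P"))))
    }
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    id = "BIOMASS", lower_bound = 0, upper_bound = 1000, gene_rule = "",
    stoichiometry = list(c(P = -1)))

  model <- metabolic_model(
    id = sprintf("toy_%dsrc", ns), metabolites = mets,
    reactions = dplyr::bind_rows(rows), objective = c(BIOMASS = 1))

  sol <- optimize_fba(model)
  stopifnot(sol$status == "optimal",
            abs(sol$objective_value - spec$uptake_bound * ns) < 1e-6)
  model
}

#' A one-source toy chain model
#'
#' Convenience wrapper around [make_toy_model()] with a single carbon source
#' and uptake bound 10; its FBA optimum is 10.
#' @return A `metabolic_model`.
#' @export
toy_chain_model <- function() make_toy_model(fixture_spec())

#' Degrade a model into a draft plus a universal repair database
#'
#' Removes the given reactions from the model (the "draft") and places them
#' in a universal reaction database together with seeded decoy reactions.
#' Decoys produce dead-end metabolites that nothing consumes, so mass balance
#' forces their flux to zero in any feasible steady state: they can never
#' appear in a flux-minimal gap-fill solution. This provides exact ground
#' truth for gap-filling tests.
#'
#' @param model A `metabolic_model`.
#' @param remove Character vector of non-exchange reaction ids to remove.
#' @param n_decoys Number of decoy reactions to seed into the universal
#'   database (default 3).
#' @param seed Integer seed controlling decoy placement.
#' @return A list with elements `draft`, `universal` (both
#'   `metabolic_model`), and `ground_truth` (the removed ids).
#' @export
degrade_model <- function(model, remove, n_decoys = 3L, seed = 1L) {
  ex <- exchange_reactions(model)
  bad <- intersect(remove, ex)
  if (length(bad)) {
    stop("cannot remove exchange reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(remove, model$reactions$id)
  if (length(unknown)) {
    stop("unknown reaction(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  draft <- model
  keep <- !draft$reactions$id %in% remove
  draft$reactions <- draft$reactions[keep, ]
  draft$objective <- draft$objective[names(draft$objective) %in%
                                       draft$reactions$id]
  draft$id <- paste0(model$id, "_draft")

  internal_mets <- setdiff(
    unique(unlist(lapply(model$reactions$stoichiometry, names))),
    character(0))
  rows <- model$reactions[model$reactions$id %in% remove, ]
  decoy_mets <- character(n_decoys)
  decoy_rows <- list()
  substrates <- with_local_seed(seed, {
    sample(internal_mets, n_decoys, replace = TRUE)
  })
  for (j in seq_len(n_decoys)) {
    decoy_mets[j] <- sprintf("DEADEND_%d", j)
    decoy_rows[[j]] <- tibble::tibble(
      id = sprintf("DECOY_%d", j), lower_bound = 0, upper_bound = 1000,
      gene_rule = "",
      stoichiometry = list(stats::setNames(c(-1, 1),
                                           c(substrates[j], decoy_mets[j]))))
  }
  uni_rxns <- dplyr::bind_rows(c(list(rows), decoy_rows))
  uni_met_ids <- unique(unlist(lapply(uni_rxns$stoichiometry, names)))
  uni_mets <- dplyr::bind_rows(
    model$metabolites[model$metabolites$id %in% uni_met_ids, ],
    tibble::tibble(id = decoy_mets, name = "dead-end product",
                   compartment = "c"))
  uni_mets <- uni_mets[!duplicated(uni_mets$id), ]
  universal <- metabolic_model(
    id = paste0(model$id, "_universal"), metabolites = uni_mets,
    reactions = uni_rxns, objective = numeric())

  list(draft = draft, universal = universal, ground_truth = remove)
}

#' Build a growth phenotype table from a complete model
#'
#' Simulates the complete model on each candidate medium and records a binary
#' growth call (`FBA objective > growth_threshold`). This mirrors a growth
#' phenotyping experiment (e.g. a carbon-source microplate) with the complete
#' model standing in for the organism.
#'
#' @param complete_model A `metabolic_model` that grows on its media.
#' @param conditions Named list: condition id -> named numeric medium
#'   (exchange id -> max uptake rate).
#' @param growth_threshold Objective value above which growth is called
#'   (default 0.05).
#' @return A tibble with columns `condition_id`, `growth` (logical), and
#'   `medium` (list-column of named numeric vectors).
#' @export
make_phenotype_table <- function(complete_model, conditions,
                                 growth_threshold = 0.05) {
  stopifnot(is.list(conditions), length(names(conditions)) == length(conditions))
  purrr::imap_dfr(conditions, function(medium, cid) {
    m <- set_medium(complete_model, medium)  # validates exchange ids
    sol <- optimize_fba(m)
    tibble::tibble(
      condition_id = cid,
      growth = sol$status == "optimal" &&
        sol$objective_value > growth_threshold,
      medium = list(medium))
  })
}

#' Write / read a phenotype table as CSV
#'
#' The CSV has columns `condition_id`, `growth` (0/1), then one column per
#' exchange reaction id holding the maximum uptake rate (0 = not in the
#' medium).
#'
#' @param phenotypes A phenotype tibble from [make_phenotype_table()].
#' @param path CSV file path.
#' @return `write_phenotypes()` returns `path` invisibly;
#'   `read_phenotypes()` returns the phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  all_ex <- sort(unique(unlist(lapply(phenotypes$medium, names))))
  wide <- purrr::map_dfr(seq_len(nrow(phenotypes)), function(i) {
    rates <- stats::setNames(numeric(length(all_ex)), all_ex)
    med <- phenotypes$medium[[i]]
    rates[names(med)] <- unname(med)
    dplyr::bind_cols(
      tibble::tibble(condition_id = phenotypes$condition_id[i],
                     growth = as.integer(phenotypes$growth[i])),
      tibble::as_tibble(as.list(rates)))
  })
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE)
  need <- c("condition_id", "growth")
  if (!all(need %in% names(wide))) {
    stop("phenotype CSV must have condition_id and growth columns",
         call. = FALSE)
  }
  ex_cols <- setdiff(names(wide), need)
  purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    rates <- unlist(wide[i, ex_cols, drop = FALSE])
    rates <- rates[rates > 0]
    tibble::tibble(condition_id = as.character(wide$condition_id[i]),
                   growth = wide$growth[i] > 0,
                   medium = list(rates))
  })
}

#' Build a synthetic ensemble with one planted causal feature
#'
#' Constructs an ensemble over a two-source toy model in which exactly one
#' feature — the upper bound of the second source's conversion reaction,
#' i.e. a bypass pathway's capacity — changes the FBA biomass optimum
#' (open: optimum 15; blocked: optimum 10). The remaining features vary the
#' capacity of dead-end side reactions that can never carry steady-state
#' flux, so they are neutral by construction. This is the test bed for the
#' machine-learning curation loop.
#'
#' @param spec A [fixture_spec()]; `spec$seed` drives the random member
#'   states and `spec$noise_sd` is recorded for downstream outcome jitter.
#' @param n_members Number of ensemble members (default 100).
#' @param n_neutral Number of neutral (dead-end) features (default 4).
#' @return A list with `ensemble` and `causal_feature` (its feature id).
#' @export
make_synthetic_ensemble <- function(spec = fixture_spec(), n_members = 100L,
                                    n_neutral = 4L) {
  base <- make_toy_model(fixture_spec(seed = spec$seed, n_carbon_sources = 2))
  # second source's uptake capped at 5 so the causal effect is +5
  i <- match("EX_S2", base$reactions$id)
  base$reactions$lower_bound[i] <- -5
  # neutral dead-end side reactions off the optimal path
  for (j in seq_len(n_neutral)) {
    met <- sprintf("SIDE_%d", j)
    base$metabolites <- dplyr::bind_rows(
      base$metabolites,
      tibble::tibble(id = met, name = "dead-end side product",
                     compartment = "c"))
    base$reactions <- dplyr::bind_rows(
      base$reactions,
      tibble::tibble(id = sprintf("SIDE_RXN_%d", j), lower_bound = 0,
                     upper_bound = 1000, gene_rule = "",
                     stoichiometry = list(stats::setNames(c(-1, 1),
                                                          c("S1_c", met)))))
  }
  validate_metabolic_model(base)

  causal <- "CONV_2_1__upper_bound"
  feature_tbl <- tibble::tibble(
    feature_id = c(causal,
                   sprintf("SIDE_RXN_%d__upper_bound", seq_len(n_neutral))),
    component_id = c("CONV_2_1", sprintf("SIDE_RXN_%d", seq_len(n_neutral))),
    attribute = "upper_bound")

  member_ids <- sprintf("m%03d", seq_len(n_members))
  states <- with_local_seed(spec$seed, {
    vals <- matrix(sample(c(0, 1000), n_members * nrow(feature_tbl),
                          replace = TRUE),
                   nrow = n_members)
    # guarantee both causal states occur
    vals[1, 1] <- 1000
    vals[2, 1] <- 0
    vals
  })
  states_tbl <- tibble::as_tibble(
    stats::setNames(as.data.frame(states), feature_tbl$feature_id))
  states_tbl <- dplyr::bind_cols(tibble::tibble(member_id = member_ids),
                                 states_tbl)

  ens <- new_ensemble(
    id = sprintf("synthetic_causal_seed%d", spec$seed), base_model = base,
    features = feature_tbl,
    members = tibble::tibble(member_id = member_ids,
                             provenance = "synthetic causal fixture"),
    states = states_tbl)

  # self-validation: the causal feature alone moves the optimum 10 -> 15
  open_m <- states_tbl$member_id[states_tbl[[causal]] > 0][1]
  closed_m <- states_tbl$member_id[states_tbl[[causal]] == 0][1]
  v_open <- optimize_fba(extract_member(ens, open_m))$objective_value
  v_closed <- optimize_fba(extract_member(ens, closed_m))$objective_value
  stopifnot(abs(v_open - 15) < 1e-6, abs(v_closed - 10) < 1e-6)

  list(ensemble = ens, causal_feature = causal)
}

#' Two-pathway fixture: a draft whose gap-fill depends on condition order
#'
#' A draft model that can grow on two carbon sources (A and B) only after
#' gap-filling, together with a universal database offering direct
#' conversions (`RAP`: A -> P, `RBP`: B -> P) and doubling interconversions
#' (`RAB`: A -> 2 B, `RBA`: B -> 2 A) plus a dead-end decoy. Because the
#' doubling reactions halve the flux a repair needs once the other source's
#' direct conversion is present, the flux-minimal gap-fill for the second
#' condition reuses the first condition's repair: processing conditions as
#' `c1, c2` yields `{RAP, RBA}` while `c2, c1` yields `{RBP, RAB}`. The
#' fixture therefore realises, at toy scale, how condition order shapes
#' gap-filled network structure.
#'
#' @return A list with `draft`, `universal` (both `metabolic_model`) and
#'   `phenotypes` (a two-condition positive-growth phenotype tibble).
#' @export
make_two_pathway_fixture <- function() {
  mets <- tibble::tibble(
    id = c("A_e", "B_e", "A", "B", "P", "DEAD_1"),
    name = c("carbon A extracellular", "carbon B extracellular",
             "carbon A cytosol", "carbon B cytosol", "biomass precursor",
             "dead-end product"),
    compartment = c("e", "e", "c", "c", "c", "c"))
  draft_rxns <- tibble::tibble(
    id = c("EX_A", "EX_B", "TA", "TB", "BIOMASS"),
    lower_bound = c(-10, -10, 0, 0, 0),
    upper_bound = 1000,
    gene_rule = "",
    stoichiometry = list(c(A_e = -1), c(B_e = -1),
                         c(A_e = -1, A = 1), c(B_e = -1, B = 1),
                         c(P = -1)))
  draft <- metabolic_model("two_pathway_draft",
                           mets[mets$id != "DEAD_1", ], draft_rxns,
                           objective = c(BIOMASS = 1))
  uni_rxns <- tibble::tibble(
    id = c("RAP", "RBP", "RAB", "RBA", "DECOY_1"),
    lower_bound = 0, upper_bound = 1000, gene_rule = "",
    stoichiometry = list(c(A = -1, P = 1), c(B = -1, P = 1),
                         c(A = -1, B = 2), c(B = -1, A = 2),
                         c(A = -1, DEAD_1 = 1)))
  universal <- metabolic_model("two_pathway_universal", mets, uni_rxns,
                               objective = numeric())
  phenotypes <- tibble::tibble(
    condition_id = c("c1", "c2"),
    growth = TRUE,
    medium = list(c(EX_A = 10), c(EX_B = 10)))
  list(draft = draft, universal = universal, phenotypes = phenotypes)
}

# run code under a temporary RNG state so fixtures are seeded without
# clobbering the caller's random stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
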