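# Gap-filling: repair a draft model so it grows on observed media by adding
# reactions from a universal database. The per-condition step is a single
# linear program — constrain the growth objective to at least a threshold,
# then minimise the summed absolute flux through universal reactions (each
# reversible universal reaction is split into two irreversible nonnegative
# variables so the objective stays linear). Iterating over conditions in a
# shuffled order, and keeping each condition's solution in the model before
# the next, yields alternative network structures; the unique outcomes form
# an ensemble.

#' Gap-fill a model for one growth condition
#'
#' Merges the universal database into the model (universal reactions start
#' blocked, then are opened inside the LP), applies the condition's medium
#' with [set_medium()] semantics (unlisted exchanges closed), constrains the
#' model's own objective to at least `growth_threshold`, and minimises the
#' sum of absolute fluxes through universal reactions. Universal reactions
#' carrying more than `flux_tolerance` flux form the solution set.
#'
#' @param model A `metabolic_model` with a growth objective.
#' @param universal A `metabolic_model` of candidate repair reactions sharing
#'   the metabolite namespace.
#' @param condition A list or one-row tibble with elements `condition_id`,
#'   `medium` (named numeric of max uptake rates), `growth` (must be `TRUE`).
#' @param growth_threshold Minimum objective flux that counts as growth
#'   (default 0.05 mmol/gDW/hr).
#' @param flux_tolerance Flux magnitude above which a universal reaction is
#'   part of the solution (default 1e-6).
#' @return A list: `condition_id`, `added_reaction_ids` (character; empty if
#'   the model already grows), `objective_achieved` (flux through the growth
#'   objective at the parsimonious solution), and `flux_sum` (the minimised
#'   summed absolute flux through universal reactions; 0 when nothing was
#'   added). The input model is not modified.
#' @export
gapfill_one_condition <- function(model, universal, condition,
                                  growth_threshold = 0.05,
                                  flux_tolerance = 1e-6) {
  cond <- normalize_condition(condition)
  if (!isTRUE(cond$growth)) {
    stop("gap-filling is only performed on positive-growth conditions (",
         cond$condition_id, " is a no-growth condition)", call. = FALSE)
  }
  if (!length(model$objective)) {
    stop("model has no objective to gap-fill for", call. = FALSE)
  }

  # does the draft already grow on its own?
  own <- optimize_fba(set_medium(model, filter_medium(model, cond$medium)))
  if (own$status == "optimal" && own$objective_value >= growth_threshold) {
    return(list(condition_id = cond$condition_id,
                added_reaction_ids = character(),
                objective_achieved = own$objective_value,
                flux_sum = 0))
  }

  uni_ids <- setdiff(universal$reactions$id, model$reactions$id)
  merged <- add_reactions_from(model, universal, uni_ids)
  merged <- set_medium(merged, filter_medium(merged, cond$medium))

  n <- nrow(merged$reactions)
  rid <- merged$reactions$id
  uni_idx <- match(uni_ids, rid)
  S <- stoich_matrix(merged)
  # candidate reactions enter the LP with their universal-database bounds
  # (already carried over by the merge); exchanges respect the applied medium
  lb <- merged$reactions$lower_bound
  ub <- merged$reactions$upper_bound

  # split each universal reaction v_u = p_u - n_u with p, n >= 0
  n_u <- length(uni_idx)
  S_split <- cbind(S, -S[, uni_idx, drop = FALSE])
  lb_split <- c(lb, numeric(n_u))
  ub_split <- c(ub, pmax(0, -lb[uni_idx]))
  lb_split[uni_idx] <- 0                       # p >= 0
  obj_min <- numeric(n + n_u)
  obj_min[uni_idx] <- 1
  obj_min[n + seq_len(n_u)] <- 1
  # growth objective >= threshold:  -obj' v <= -threshold
  gobj <- c(objective_vector(merged), numeric(n_u))
  gobj[n + seq_len(n_u)] <- -gobj[uni_idx]
  res <- solve_lp(obj_min, S_split, lb_split, ub_split, maximize = FALSE,
                  A_extra = matrix(-gobj, nrow = 1),
                  b_extra = -growth_threshold)
  if (res$status != "optimal") {
    stop("no feasible gap-fill solution for condition ", cond$condition_id,
         " even with the full universal database", call. = FALSE)
  }
  net_flux <- res$v[uni_idx] - res$v[n + seq_len(n_u)]
  added <- uni_ids[abs(net_flux) > flux_tolerance]
  list(condition_id = cond$condition_id,
       added_reaction_ids = added,
       objective_achieved = sum(gobj * res$v),
       flux_sum = res$value)
}

normalize_condition <- function(condition) {
  if (is.data.frame(condition)) {
    stopifnot(nrow(condition) == 1L)
    condition <- list(condition_id = condition$condition_id,
                      medium = condition$medium[[1]],
                      growth = condition$growth)
  }
  stopifnot(!is.null(condition$condition_id), !is.null(condition$medium))
  if (is.null(condition$growth)) condition$growth <- TRUE
  condition
}

# keep only the medium keys that exist as exchanges in this model; a medium
# may name exchanges the draft lacks before gap-filling
filter_medium <- function(model, medium) {
  medium[names(medium) %in% exchange_reactions(model)]
}

#' Iterative gap-filling over an ordered list of conditions
#'
#' Gap-fills the model for each positive-growth condition in the given
#' order; after each condition, the solution reactions are added to the
#' model (with their universal-database bounds) before the next condition is
#' processed. The order matters: different orders can yield different final
#' networks, which is exactly the variation ensembles capture.
#'
#' @param model Draft `metabolic_model`.
#' @param universal Universal reaction database.
#' @param conditions Phenotype tibble (rows with `condition_id`, `medium`,
#'   `growth`) or list of such records; all must have `growth = TRUE`.
#' @inheritParams gapfill_one_condition
#' @return A list: `model` (the gap-filled model, which reaches
#'   `growth_threshold` on every input condition) and `added_reaction_ids`
#'   (union of the per-condition solutions, in order of first addition).
#' @export
iterative_gapfill <- function(model, universal, conditions,
                              growth_threshold = 0.05,
                              flux_tolerance = 1e-6) {
  conds <- as_condition_list(conditions)
  added_all <- character()
  current <- model
  for (pos in seq_along(conds)) {
    cond <- conds[[pos]]
    sol <- tryCatch(
      gapfill_one_condition(current, universal, cond,
                            growth_threshold, flux_tolerance),
      error = function(e) {
        stop("iterative gap-fill failed at position ", pos, " (condition ",
             cond$condition_id, "): ", conditionMessage(e), call. = FALSE)
      })
    if (length(sol$added_reaction_ids)) {
      current <- add_reactions_from(current, universal,
                                    sol$added_reaction_ids)
      added_all <- c(added_all, setdiff(sol$added_reaction_ids, added_all))
    }
  }
  list(model = current, added_reaction_ids = added_all)
}

as_condition_list <- function(conditions) {
  if (is.data.frame(conditions)) {
    conds <- lapply(seq_len(nrow(conditions)), function(i)
      normalize_condition(conditions[i, ]))
  } else {
    conds <- lapply(conditions, normalize_condition)
  }
  no_growth <- !vapply(conds, function(c) isTRUE(c$growth), logical(1))
  if (any(no_growth)) {
    stop("iterative gap-filling accepts positive-growth conditions only; ",
         "no-growth condition(s): ",
         paste(vapply(conds[no_growth], `[[`, "", "condition_id"),
               collapse = ", "), call. = FALSE)
  }
  conds
}

#' Generate an ensemble by randomized iterative gap-filling
#'
#' Runs [iterative_gapfill()] for `cycles` rounds. Each round subsamples
#' `ceiling(condition_fraction * n)` of the positive-growth conditions
#' without replacement and shuffles their order (one seeded random stream
#' drives both, so a single seed reproduces the whole run). The ensemble
#' contains one member per *unique* added-reaction set; member provenance
#' records the cycle and condition order that produced it.
#'
#' @param model Draft `metabolic_model`.
#' @param universal Universal reaction database.
#' @param phenotypes Phenotype tibble; no-growth rows are kept for
#'   bookkeeping but never gap-filled on.
#' @param cycles Number of gap-fill rounds (>= 1).
#' @param condition_fraction Fraction in `(0, 1]` of positive conditions
#'   used per round (default 1).
#' @inheritParams gapfill_one_condition
#' @param seed Integer seed; fixed seed gives a bit-identical ensemble.
#' @param skip_failed_cycles If `TRUE`, a round whose gap-fill is infeasible
#'   is logged (as a message) and skipped instead of aborting.
#' @param id Ensemble identifier.
#' @return An `ensemble` whose members are the unique gap-filled variants.
#' @export
generate_gapfill_ensemble <- function(model, universal, phenotypes,
                                      cycles = 10L, condition_fraction = 1,
                                      growth_threshold = 0.05,
                                      flux_tolerance = 1e-6, seed = 1L,
                                      skip_failed_cycles = FALSE,
                                      id = "gapfill_ensemble") {
  stopifnot(cycles >= 1, condition_fraction > 0, condition_fraction <= 1)
  conds <- as_condition_list(phenotypes[phenotypes$growth %in% TRUE, ])
  if (!length(conds)) {
    stop("no positive-growth conditions in the phenotype table", call. = FALSE)
  }
  n_pick <- ceiling(condition_fraction * length(conds))

  runs <- with_local_seed(seed, {
    lapply(seq_len(cycles), function(cycle) {
      ord <- sample(seq_along(conds), n_pick, replace = FALSE)
      list(cycle = cycle, order = ord)
    })
  })

  variants <- list()   # key: canonical added-set string -> provenance
  for (run in runs) {
    picked <- lapply(run$order, function(i) conds[[i]])
    res <- tryCatch(
      iterative_gapfill(model, universal, picked,
                        growth_threshold, flux_tolerance),
      error = function(e) {
        if (skip_failed_cycles) {
          message("skipping cycle ", run$cycle, ": ", conditionMessage(e))
          NULL
        } else {
          stop("cycle ", run$cycle, ": ", conditionMessage(e), call. = FALSE)
        }
      })
    if (is.null(res)) next
    key <- paste(sort(res$added_reaction_ids), collapse = "|")
    if (!key %in% names(variants)) {
      variants[[key]] <- list(
        added = sort(res$added_reaction_ids),
        provenance = sprintf(
          "cycle %d; condition order: %s", run$cycle,
          paste(vapply(picked, `[[`, "", "condition_id"), collapse = " -> ")))
    }
  }
  if (!length(variants)) {
    stop("all gap-fill cycles failed; no ensemble members generated",
         call. = FALSE)
  }

  member_models <- vector("list", length(variants))
  for (k in seq_along(variants)) {
    m <- add_reactions_from(model, universal, variants[[k]]$added)
    m$id <- sprintf("gapfilled_%02d", k)
    member_models[[k]] <- m
  }
  ens <- build_from_models(member_models, batch_size = length(member_models),
                           id = id)
  ens$members$provenance <- vapply(variants, `[[`, "", "provenance")
  ens
}
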