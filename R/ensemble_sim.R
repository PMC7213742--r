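# Ensemble-scale simulations. Each method applies a member's states to a
# private copy of the base model, runs the single-model computation, and
# merges rows by member id — so results are identical for any worker count
# and any evaluation order, and the ensemble is left untouched.

#' Select ensemble members for simulation
#'
#' @param ens An `ensemble`.
#' @param members `"all"`, an explicit character vector of member ids, or a
#'   single numeric fraction in `(0, 1]`. A fraction `f` of `N` members
#'   selects `ceiling(f * N)` members sampled without replacement.
#' @param seed Integer seed for fractional sampling; the same seed always
#'   selects the same members.
#' @return A sorted character vector of member ids.
#' @export
select_members <- function(ens, members = "all", seed = 1L) {
  ids <- member_ids(ens)
  if (identical(members, "all")) return(sort(ids))
  if (is.numeric(members)) {
    f <- members
    if (length(f) != 1L || f <= 0 || f > 1) {
      stop("member fraction must be a single value in (0, 1]", call. = FALSE)
    }
    n <- ceiling(f * length(ids))
    picked <- with_local_seed(seed, sample(ids, n, replace = FALSE))
    return(sort(picked))
  }
  unknown <- setdiff(members, ids)
  if (length(unknown)) {
    stop("unknown member id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sort(unique(members))
}

apply_over_members <- function(ens, ids, workers, fn) {
  run_one <- function(mid) fn(extract_member(ens, mid))
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(ids, run_one, mc.cores = workers)
  } else {
    lapply(ids, run_one)
  }
  # a worker that died returns a try-error; recompute serially for safety
  bad <- vapply(results, inherits, logical(1), what = "try-error")
  if (any(bad)) results[bad] <- lapply(ids[bad], run_one)
  stats::setNames(results, ids)
}

new_ensemble_result <- function(tbl, method, params) {
  structure(tbl, class = c("ensemble_result", class(tbl)),
            method = method, params = params)
}

#' Ensemble flux balance analysis
#'
#' Runs FBA on every selected member and returns one row per member with the
#' objective value and the flux through every reaction. The distribution of
#' the objective column across members is the ensemble analogue of a single
#' model's growth rate.
#'
#' @param ens An `ensemble` whose base model has an objective.
#' @param members Member selection as in [select_members()].
#' @param workers Number of parallel workers; the result is identical for
#'   any value.
#' @param seed Seed used only for fractional member selection.
#' @return An `ensemble_result` tibble: columns `member_id`, `status`,
#'   `objective`, then one column per reaction. Infeasible members keep
#'   their row with `status = "infeasible"` and `NA` fluxes.
#' @export
ensemble_fba <- function(ens, members = "all", workers = 1L, seed = 1L) {
  ids <- select_members(ens, members, seed)
  res <- apply_over_members(ens, ids, workers, optimize_fba)
  tbl <- purrr::map_dfr(ids, function(mid) {
    sol <- res[[mid]]
    dplyr::bind_cols(
      tibble::tibble(member_id = mid, status = sol$status,
                     objective = sol$objective_value),
      tibble::as_tibble(as.list(sol$fluxes)))
  })
  new_ensemble_result(tbl, "fba",
                      list(members = members, seed = seed))
}

#' Ensemble flux variability analysis
#'
#' Per-member FVA: for each selected member and each reaction, the minimum
#' and maximum flux attainable at `fraction_of_optimum` times that member's
#' own optimum.
#'
#' @inheritParams ensemble_fba
#' @param fraction_of_optimum Fraction in `[0, 1]` of each member's optimum
#'   to retain (default 1).
#' @param reactions Optional reaction ids to analyse (default: all).
#' @return An `ensemble_result` tibble: `member_id`, `status`, then two
#'   columns per reaction, `<rxn>_min` and `<rxn>_max`.
#' @export
ensemble_fva <- function(ens, members = "all", fraction_of_optimum = 1,
                         reactions = NULL, workers = 1L, seed = 1L) {
  ids <- select_members(ens, members, seed)
  if (is.null(reactions)) reactions <- ens$base_model$reactions$id
  res <- apply_over_members(ens, ids, workers, function(model) {
    tryCatch(list(status = "optimal",
                  fva = run_fva(model, fraction_of_optimum, reactions)),
             error = function(e) list(status = "infeasible", fva = NULL))
  })
  tbl <- purrr::map_dfr(ids, function(mid) {
    r <- res[[mid]]
    if (r$status != "optimal") {
      vals <- rep(NA_real_, 2L * length(reactions))
    } else {
      vals <- as.vector(rbind(r$fva$min, r$fva$max))
    }
    names(vals) <- as.vector(rbind(paste0(reactions, "_min"),
                                   paste0(reactions, "_max")))
    dplyr::bind_cols(
      tibble::tibble(member_id = mid, status = r$status),
      tibble::as_tibble(as.list(vals)))
  })
  new_ensemble_result(tbl, "fva",
                      list(members = members, seed = seed,
                           fraction_of_optimum = fraction_of_optimum))
}

#' Ensemble single deletions
#'
#' Runs single gene or reaction deletions on every selected member. Cell
#' `(m, t)` is the FBA objective of member `m` after deleting target `t`.
#'
#' @inheritParams ensemble_fba
#' @param kind `"reaction"` or `"gene"`.
#' @param targets Optional target ids (default: all genes / reactions of the
#'   base model).
#' @return An `ensemble_result` tibble: `member_id`, `status`, then one
#'   column per deletion target.
#' @export
ensemble_deletions <- function(ens, kind = c("reaction", "gene"),
                               members = "all", targets = NULL,
                               workers = 1L, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(targets)) {
    targets <- if (kind == "gene") ens$base_model$genes$id
               else ens$base_model$reactions$id
  }
  universe <- if (kind == "gene") ens$base_model$genes$id
              else ens$base_model$reactions$id
  unknown <- setdiff(targets, universe)
  if (length(unknown)) {
    stop("unknown ", kind, " target(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ids <- select_members(ens, members, seed)
  res <- apply_over_members(ens, ids, workers, function(model) {
    tryCatch(list(status = "optimal",
                  del = run_single_deletions(model, kind, targets)),
             error = function(e) list(status = "infeasible", del = NULL))
  })
  tbl <- purrr::map_dfr(ids, function(mid) {
    r <- res[[mid]]
    vals <- if (r$status == "optimal") {
      stats::setNames(r$del$objective, r$del$target)
    } else {
      stats::setNames(rep(NA_real_, length(targets)), targets)
    }
    dplyr::bind_cols(
      tibble::tibble(member_id = mid, status = r$status),
      tibble::as_tibble(as.list(vals)))
  })
  new_ensemble_result(tbl, paste0(kind, "_deletion"),
                      list(members = members, seed = seed, targets = targets))
}

#' Essentiality frequency across an ensemble
#'
#' The voting view of an ensemble deletion table: for each deletion target,
#' the fraction of members whose objective drops below `threshold` when the
#' target is deleted. A frequency of 1 means the target is predicted
#' essential in every member.
#'
#' @param deletions An `ensemble_result` from [ensemble_deletions()].
#' @param threshold Objective value below which a member votes "essential"
#'   (default `1e-6`).
#' @return A tibble with columns `target` and `essentiality`.
#' @export
essentiality_frequency <- function(deletions, threshold = 1e-6) {
  targets <- setdiff(names(deletions), c("member_id", "status"))
  ok <- deletions$status == "optimal"
  purrr::map_dfr(targets, function(t) {
    v <- deletions[[t]][ok]
    tibble::tibble(target = t,
                   essentiality = mean(v < threshold | is.na(v)))
  })
}
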