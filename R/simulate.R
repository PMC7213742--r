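#' Set the growth medium of a model
#'
#' Applies a medium — a named vector of maximum uptake rates keyed by exchange
#' reaction id — to a model. Uptake is negative flux by convention, so each
#' listed exchange gets `lower_bound = -rate`. Every exchange reaction *not*
#' listed is closed for uptake (`lower_bound = 0`). Upper bounds (secretion)
#' are untouched.
#'
#' @param model A `metabolic_model`.
#' @param medium Named numeric vector, exchange-reaction id -> nonnegative
#'   maximum uptake rate (mmol/gDW/hr). May be empty (all uptake closed).
#' @return The model with updated exchange bounds.
#' @examples
#' m <- toy_chain_model()
#' m <- set_medium(m, c(EX_S1 = 5))
#' optimize_fba(m)$objective_value  # 5
#' @export
set_medium <- function(model, medium = numeric()) {
  ex <- exchange_reactions(model)
  unknown <- setdiff(names(medium), ex)
  if (length(unknown)) {
    stop("medium keys are not exchange reactions in the model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(medium < 0)) stop("uptake rates must be nonnegative", call. = FALSE)
  idx <- match(ex, model$reactions$id)
  model$reactions$lower_bound[idx] <- 0
  if (length(medium)) {
    idx_on <- match(names(medium), model$reactions$id)
    model$reactions$lower_bound[idx_on] <- -unname(medium)
  }
  model
}

#' Flux balance analysis
#'
#' Maximises the model's linear objective subject to steady-state mass
#' balance (S v = 0) and the flux bounds. This is the work-horse growth
#' simulation: with a biomass objective, the optimal value is the predicted
#' growth rate.
#'
#' @param model A `metabolic_model` with a nonempty objective.
#' @return A `flux_solution`: list with `status` (`"optimal"`/`"infeasible"`),
#'   `objective_value`, and `fluxes` (named numeric over all reactions;
#'   `NA` when not optimal).
#' @examples
#' sol <- optimize_fba(toy_chain_model())
#' sol$objective_value  # 10
#' @export
optimize_fba <- function(model) {
  if (!length(model$objective)) {
    stop("model has an empty objective; set one before calling optimize_fba",
         call. = FALSE)
  }
  S <- stoich_matrix(model)
  obj <- objective_vector(model)
  res <- solve_lp(obj, S, model$reactions$lower_bound,
                  model$reactions$upper_bound, maximize = TRUE)
  fluxes <- if (res$status == "optimal") {
    stats::setNames(res$v, model$reactions$id)
  } else {
    stats::setNames(rep(NA_real_, nrow(model$reactions)), model$reactions$id)
  }
  structure(
    list(status = res$status,
         objective_value = if (res$status == "optimal") res$value else NA_real_,
         fluxes = fluxes),
    class = "flux_solution"
  )
}

objective_vector <- function(model) {
  obj <- stats::setNames(numeric(nrow(model$reactions)), model$reactions$id)
  obj[names(model$objective)] <- unname(model$objective)
  unname(obj)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s, objective: %s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.flux_solution <- function(x, ...) {
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' Flux variability analysis
#'
#' For each reaction, computes the minimum and maximum flux attainable while
#' the objective is held at at least `fraction_of_optimum` times its FBA
#' optimum. The width of each interval quantifies how poorly the optimum
#' pins down that reaction's flux.
#'
#' @param model A `metabolic_model` with an objective.
#' @param fraction_of_optimum Fraction in `[0, 1]` of the optimal objective
#'   that must be retained (default 1).
#' @param reactions Optional character vector restricting the output.
#' @return A tibble with columns `reaction`, `min`, `max`.
#' @examples
#' run_fva(toy_chain_model(), reactions = "EX_S1")  # min = max = -10
#' @export
run_fva <- function(model, fraction_of_optimum = 1, reactions = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  base <- optimize_fba(model)
  if (base$status != "optimal") {
    stop("FVA requires an optimal base model (status: ", base$status, ")",
         call. = FALSE)
  }
  if (is.null(reactions)) reactions <- model$reactions$id
  unknown <- setdiff(reactions, model$reactions$id)
  if (length(unknown)) {
    stop("unknown reaction(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  S <- stoich_matrix(model)
  obj <- objective_vector(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  # objective >= f * optimum  as  -obj' v <= -f * optimum
  A_extra <- matrix(-obj, nrow = 1)
  b_extra <- -fraction_of_optimum * base$objective_value

  out <- purrr::map_dfr(reactions, function(rid) {
    e <- numeric(length(obj))
    e[match(rid, model$reactions$id)] <- 1
    lo <- solve_lp(e, S, lb, ub, maximize = FALSE,
                   A_extra = A_extra, b_extra = b_extra)
    hi <- solve_lp(e, S, lb, ub, maximize = TRUE,
                   A_extra = A_extra, b_extra = b_extra)
    tibble::tibble(reaction = rid,
                   min = round_tol(lo$value), max = round_tol(hi$value))
  })
  out
}

# clamp solver noise below the feasibility tolerance to zero
round_tol <- function(x, tol = 1e-9) ifelse(abs(x) < tol, 0, x)

#' Single gene or reaction deletions
#'
#' Deletes each target in turn, reports the FBA objective of the perturbed
#' model, and restores the model. A reaction deletion sets that reaction's
#' bounds to `(0, 0)`. A gene deletion closes every reaction whose GPR rule
#' evaluates to `FALSE` with the gene removed.
#'
#' @param model A `metabolic_model` with an objective.
#' @param kind `"gene"` or `"reaction"`.
#' @param targets Optional id vector; defaults to all genes / all reactions.
#' @return A tibble with columns `target`, `objective`, `status`. The input
#'   model is never modified.
#' @export
run_single_deletions <- function(model, kind = c("reaction", "gene"),
                                 targets = NULL) {
  kind <- match.arg(kind)
  universe <- if (kind == "gene") model$genes$id else model$reactions$id
  if (is.null(targets)) targets <- universe
  unknown <- setdiff(targets, universe)
  if (length(unknown)) {
    stop("unknown ", kind, " target(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(targets, function(tid) {
    m2 <- delete_target(model, kind, tid)
    sol <- optimize_fba(m2)
    tibble::tibble(target = tid,
                   objective = if (sol$status == "optimal")
                     sol$objective_value else NA_real_,
                   status = sol$status)
  })
}

delete_target <- function(model, kind, tid) {
  if (kind == "reaction") {
    i <- match(tid, model$reactions$id)
    model$reactions$lower_bound[i] <- 0
    model$reactions$upper_bound[i] <- 0
    return(model)
  }
  off <- !vapply(model$reactions$gene_rule, evaluate_gene_rule, logical(1),
                 deleted = tid)
  model$reactions$lower_bound[off] <- 0
  model$reactions$upper_bound[off] <- 0
  model
}
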