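# Independent oracles used throughout the suite.

# Brute-force FBA oracle: enumerate all candidate vertices of the flux
# polytope {S v = 0, lb <= v <= ub} by fixing every size-k subset of
# variables at a bound (k = n - rank(S)) and solving the equality system for
# the rest; the optimum of a feasible bounded LP is attained at one of these
# points. Only usable for small models.
fba_vertex_oracle <- function(model) {
  S <- stoich_matrix(model)
  obj <- numeric(ncol(S))
  obj[match(names(model$objective), colnames(S))] <- unname(model$objective)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  k <- n - qr(S)$rank
  best <- -Inf
  if (k == 0L) k_sets <- list(integer()) else
    k_sets <- asplit(utils::combn(n, k), 2)
  for (idx in k_sets) {
    idx <- as.integer(idx)
    n_free <- setdiff(seq_len(n), idx)
    patterns <- if (length(idx)) 0:(2^length(idx) - 1) else 0L
    for (pattern in patterns) {
      at_ub <- bitwAnd(pattern, 2^(seq_along(idx) - 1)) > 0
      fix <- ifelse(at_ub, ub[idx], lb[idx])
      rhs <- if (length(idx)) -S[, idx, drop = FALSE] %*% fix else
        matrix(0, nrow(S), 1)
      sol <- tryCatch(qr.solve(S[, n_free, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n)
      v[idx] <- fix
      v[n_free] <- sol
      if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8)) {
        best <- max(best, sum(obj * v))
      }
    }
  }
  best
}

# Exhaustive gap-fill oracle: for every subset of universal reactions, add
# exactly that subset to the draft, apply the medium, and minimise the
# summed absolute flux through the subset under the growth constraint.
# Returns the minimum over feasible subsets (Inf if none is feasible).
gapfill_subset_oracle <- function(draft, universal, condition,
                                  growth_threshold = 0.05) {
  uni_ids <- setdiff(universal$reactions$id, draft$reactions$id)
  best <- Inf
  for (mask in 0:(2^length(uni_ids) - 1)) {
    subset <- uni_ids[bitwAnd(mask, 2^(seq_along(uni_ids) - 1)) > 0]
    m <- add_reactions_from(draft, universal, subset)
    med <- condition$medium[names(condition$medium) %in%
                              exchange_reactions(m)]
    m <- set_medium(m, med)
    val <- min_subset_flux(m, subset, growth_threshold)
    if (!is.na(val)) best <- min(best, val)
  }
  best
}

# minimise sum of |v_r| for r in `subset` subject to S v = 0, bounds, and
# model objective >= threshold; NA if infeasible
min_subset_flux <- function(model, subset, threshold) {
  S <- stoich_matrix(model)
  n <- ncol(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  gobj <- numeric(n)
  gobj[match(names(model$objective), model$reactions$id)] <-
    unname(model$objective)
  idx <- match(subset, model$reactions$id)
  # split subset columns
  n_s <- length(idx)
  S2 <- cbind(S, if (n_s) -S[, idx, drop = FALSE] else NULL)
  lb2 <- c(lb, numeric(n_s))
  ub2 <- c(ub, if (n_s) pmax(0, -lb[idx]) else numeric(0))
  if (n_s) lb2[idx] <- 0
  cost <- numeric(n + n_s)
  if (n_s) {
    cost[idx] <- 1
    cost[n + seq_len(n_s)] <- 1
  }
  g2 <- c(gobj, if (n_s) -gobj[idx] else numeric(0))
  res <- gemsemble:::solve_lp(cost, S2, lb2, ub2, maximize = FALSE,
                              A_extra = matrix(-g2, nrow = 1),
                              b_extra = -threshold)
  if (res$status != "optimal") NA_real_ else res$value
}

# a seeded toy ensemble with known structure, reused across suites
make_test_ensemble <- function(n_members = 20L, seed = 101L) {
  make_synthetic_ensemble(fixture_spec(seed = seed), n_members = n_members)
}

sort_names <- function(x) x[order(names(x))]

get_bound <- function(model, rid, attr) {
  model$reactions[[attr]][match(rid, model$reactions$id)]
}

expect_tables_equal <- function(a, b, tol = 1e-6) {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  expect_identical(names(a), names(b))
  expect_identical(a$member_id, b$member_id)
  for (cn in setdiff(names(a), c("member_id", "status"))) {
    expect_equal(a[[cn]], b[[cn]], tolerance = tol)
  }
}
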