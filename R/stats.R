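# Statistical layer: paired comparison of member-indexed result columns, and
# the machine-learning curation loop — regress a simulated outcome (e.g.
# biomass flux) on the binary feature states, rank features by importance,
# and report the top candidates for manual curation.

#' Compare two member-indexed result columns with a paired test
#'
#' Ensemble simulations under two conditions give two distributions paired by
#' member. This runs a paired t-test or Wilcoxon signed-rank test over the
#' members present in both inputs.
#'
#' @param a,b Member-indexed columns: either a named numeric vector (names =
#'   member ids) or a data frame with a `member_id` column, in which case
#'   `column` selects the value column.
#' @param test `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @param column Value column name when `a`/`b` are data frames (default:
#'   `"objective"`).
#' @return A `comparison_result`: `test_name`, `statistic`, `p_value`,
#'   `n_pairs`, `effect_estimate` (mean of `a - b`), `degenerate` (`TRUE`
#'   when all paired differences are zero, in which case `p_value = 1`),
#'   `n_dropped` (members not present in both inputs).
#' @export
compare_member_distributions <- function(a, b,
                                         test = c("paired_t",
                                                  "wilcoxon_signed_rank"),
                                         column = "objective") {
  test <- match.arg(test)
  av <- as_member_column(a, column)
  bv <- as_member_column(b, column)
  common <- intersect(names(av), names(bv))
  n_dropped <- length(union(names(av), names(bv))) - length(common)
  if (length(common) < 3L) {
    stop("need at least 3 members present in both inputs (found ",
         length(common), ")", call. = FALSE)
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " member(s) not present in both inputs were dropped",
            call. = FALSE)
  }
  d <- av[common] - bv[common]
  degenerate <- all(abs(d) == 0)
  if (degenerate) {
    stat <- NA_real_
    p <- 1
  } else if (stats::sd(d) == 0) {
    # identical nonzero shift everywhere: evidence is one-sided and exact
    stat <- NA_real_
    p <- 0
    degenerate <- TRUE
  } else if (test == "paired_t") {
    ht <- stats::t.test(av[common], bv[common], paired = TRUE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(av[common], bv[common], paired = TRUE, exact = FALSE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(
    list(test_name = test, statistic = stat, p_value = p,
         n_pairs = length(common), effect_estimate = mean(d),
         degenerate = degenerate, n_dropped = n_dropped),
    class = "comparison_result")
}

as_member_column <- function(x, column) {
  if (is.data.frame(x)) {
    if (!"member_id" %in% names(x)) {
      stop("data-frame input needs a member_id column", call. = FALSE)
    }
    if (!column %in% names(x)) {
      stop("column ", dQuote(column), " not found", call. = FALSE)
    }
    v <- stats::setNames(x[[column]], x$member_id)
  } else {
    if (is.null(names(x))) {
      stop("vector input must be named by member id", call. = FALSE)
    }
    v <- x
  }
  v[!is.na(v)]
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: p = %.3g, effect = %.4g (n = %d pairs%s)\n",
              x$test_name, x$p_value, x$effect_estimate, x$n_pairs,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @export
tidy.comparison_result <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p.value = x$p_value, estimate = x$effect_estimate,
                 n = x$n_pairs, degenerate = x$degenerate)
}

#' @export
glance.comparison_result <- function(x, ...) tidy.comparison_result(x)

#' Rank ensemble features by their influence on a simulated outcome
#'
#' Fits a regressor (by default a random forest) predicting the outcome
#' column (e.g. biomass flux from [ensemble_fba()]) from the binarized
#' member-by-feature state table, and ranks features by the fitted
#' importance scores. High-ranking features are the network components whose
#' uncertainty drives simulation uncertainty — the prime curation targets.
#'
#' @param states Binarized state table from
#'   `feature_state_table(ens, binarize = TRUE)`.
#' @param outcome Member-indexed column (named vector or data frame with
#'   `member_id`; see [compare_member_distributions()]).
#' @param regressor Optional function `f(X, y)` returning a list with
#'   `importances` (named numeric, one per column of `X`, nonnegative) and
#'   `quality` (a fit score such as out-of-bag R^2). The default fits
#'   `randomForest::randomForest` with importance enabled.
#' @param column Value column name for data-frame `outcome` (default
#'   `"objective"`).
#' @param seed Integer seed; fixed seed gives an identical ranking.
#' @return A `feature_influence`: `ranking` (tibble `feature_id`,
#'   `importance`, sorted non-increasing), `model_quality`, `seed`,
#'   `no_signal` (`TRUE` when the outcome is constant; importances are then
#'   all zero).
#' @export
rank_influential_features <- function(states, outcome, regressor = NULL,
                                      column = "objective", seed = 1L) {
  stopifnot(is.data.frame(states), "member_id" %in% names(states))
  feats <- setdiff(names(states), "member_id")
  if (length(feats) < 2L) {
    stop("need at least 2 features to rank", call. = FALSE)
  }
  y <- as_member_column(outcome, column)
  common <- intersect(states$member_id, names(y))
  if (length(common) < 10L) {
    stop("need at least 10 members with both states and outcome (found ",
         length(common), ")", call. = FALSE)
  }
  X <- as.data.frame(states[match(common, states$member_id), feats,
                            drop = FALSE])
  rownames(X) <- common
  y <- y[common]

  if (stats::sd(y) == 0) {
    ranking <- tibble::tibble(feature_id = feats,
                              importance = numeric(length(feats)))
    return(structure(list(ranking = ranking, model_quality = NA_real_,
                          seed = seed, no_signal = TRUE),
                     class = "feature_influence"))
  }

  if (is.null(regressor)) regressor <- random_forest_regressor
  fit <- with_local_seed(seed, regressor(X, y))
  imp <- fit$importances[feats]
  imp[is.na(imp) | imp < 0] <- 0
  ranking <- tibble::tibble(feature_id = feats, importance = unname(imp))
  ranking <- ranking[order(-ranking$importance, ranking$feature_id), ]
  structure(list(ranking = ranking,
                 model_quality = fit$quality, seed = seed,
                 no_signal = FALSE),
            class = "feature_influence")
}

# default regressor: random forest with permutation importance; quality is
# the out-of-bag R^2
random_forest_regressor <- function(X, y) {
  # few-unique-value outcomes (e.g. bimodal biomass) are the normal case
  # here, so muffle randomForest's regression warning about them
  rf <- withCallingHandlers(
    randomForest::randomForest(X, y, ntree = 500, importance = TRUE),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  imp_mat <- randomForest::importance(rf, type = 1)
  list(importances = stats::setNames(as.numeric(imp_mat[, 1]),
                                     rownames(imp_mat)),
       quality = rf$rsq[length(rf$rsq)])
}

#' @export
print.feature_influence <- function(x, ...) {
  cat(sprintf("<feature_influence> %d features (oob quality: %s%s)\n",
              nrow(x$ranking), format(x$model_quality, digits = 3),
              if (x$no_signal) ", no signal" else ""))
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' @export
tidy.feature_influence <- function(x, ...) x$ranking

#' @export
glance.feature_influence <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$ranking),
                 model_quality = x$model_quality,
                 no_signal = x$no_signal, seed = x$seed)
}

#' Curation report: top influential features with their ensemble context
#'
#' Joins the feature-importance ranking to the ensemble's annotation: which
#' reaction each feature modifies, which attribute, how its states are
#' distributed across members, and an outcome summary. This is the hand-off
#' point to human curation — the analyst takes the top entries to the
#' literature and then applies decisions with
#' [set_feature_across_members()].
#'
#' @param ens The `ensemble` the influence was computed on.
#' @param influence A `feature_influence` from
#'   [rank_influential_features()].
#' @param top_k Number of rows to report; values above the feature count are
#'   truncated with a message.
#' @return A tibble with columns `feature_id`, `reaction`, `attribute`,
#'   `importance`, `n_states` (distinct state values across members),
#'   `frac_active` (share of members whose binarized state permits flux),
#'   and `states` (a compact `value:count` summary).
#' @export
curation_report <- function(ens, influence, top_k = 10L) {
  stopifnot(inherits(ens, "ensemble"), inherits(influence, "feature_influence"))
  missing_feat <- setdiff(influence$ranking$feature_id,
                          ens$features$feature_id)
  if (length(missing_feat)) {
    stop("influence refers to feature(s) absent from this ensemble: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  }
  if (top_k > nrow(influence$ranking)) {
    message("top_k exceeds the number of features; truncating to ",
            nrow(influence$ranking))
    top_k <- nrow(influence$ranking)
  }
  if (top_k == 0L) {
    return(tibble::tibble(feature_id = character(), reaction = character(),
                          attribute = character(), importance = numeric(),
                          n_states = integer(), frac_active = numeric(),
                          states = character()))
  }
  top <- utils::head(influence$ranking, top_k)
  bin <- feature_state_table(ens, binarize = TRUE)
  purrr::map_dfr(seq_len(nrow(top)), function(i) {
    fid <- top$feature_id[i]
    k <- match(fid, ens$features$feature_id)
    vals <- ens$states[[fid]]
    counts <- sort(table(vals), decreasing = TRUE)
    tibble::tibble(
      feature_id = fid,
      reaction = ens$features$component_id[k],
      attribute = ens$features$attribute[k],
      importance = top$importance[i],
      n_states = length(counts),
      frac_active = mean(bin[[fid]] == 1L),
      states = paste(sprintf("%s:%d", names(counts), as.integer(counts)),
                     collapse = ", "))
  })
}

#' Summarise an ensemble result column
#'
#' Mean, standard deviation and quartiles of a member-indexed simulation
#' column — the unsupervised summary of simulation uncertainty that
#' accompanies a curation report.
#'
#' @param result An `ensemble_result` (or any data frame with `member_id`).
#' @param column Value column to summarise (default `"objective"`).
#' @return A one-row tibble: `n`, `mean`, `sd`, `q25`, `median`, `q75`.
#' @export
summarize_distribution <- function(result, column = "objective") {
  v <- as_member_column(result, column)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(n = length(v), mean = mean(v), sd = stats::sd(v),
                 q25 = q[1], median = q[2], q75 = q[3])
}
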