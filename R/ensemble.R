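# The compact ensemble representation: one base model holding the union of
# all components, a feature table naming which reaction attributes vary, and
# a member-by-feature state table. The whole ensemble stores exactly
# |members| x |features| state entries beyond the single base model — this is
# the compression contract that makes thousand-member ensembles cheap.

ENSEMBLE_FORMAT_VERSION <- 1L

#' Construct an ensemble from its parts
#'
#' Low-level constructor; most users should build ensembles with
#' [build_from_models()] or [generate_gapfill_ensemble()].
#'
#' @param id Ensemble identifier.
#' @param base_model A `metabolic_model` containing every component any
#'   member uses.
#' @param features Tibble with columns `feature_id`, `component_id`
#'   (a reaction id in the base model), `attribute` (one of `lower_bound`,
#'   `upper_bound`, `gene_rule`).
#' @param members Tibble with columns `member_id`, `provenance`.
#' @param states Tibble with a `member_id` column plus one column per
#'   feature id holding that member's value for the feature.
#' @param current_member Optional member id the base model currently
#'   impersonates.
#' @return An object of class `ensemble`.
#' @export
new_ensemble <- function(id, base_model, features, members, states,
                         current_member = NA_character_) {
  features <- tibble::as_tibble(features)
  members <- tibble::as_tibble(members)
  if (!"provenance" %in% names(members)) members$provenance <- ""
  states <- tibble::as_tibble(states)
  ens <- structure(
    list(id = id, base_model = base_model, features = features,
         members = members, states = states,
         current_member = current_member),
    class = "ensemble")
  validate_ensemble(ens)
  ens
}

#' Validate an ensemble's internal consistency
#' @param ens An `ensemble`.
#' @return The ensemble, invisibly.
#' @export
validate_ensemble <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  validate_metabolic_model(ens$base_model)
  ft <- ens$features
  if (nrow(ft)) {
    stopifnot(all(c("feature_id", "component_id", "attribute") %in% names(ft)))
    if (anyDuplicated(ft$feature_id)) stop("duplicate feature ids", call. = FALSE)
    bad_attr <- setdiff(ft$attribute, c("lower_bound", "upper_bound", "gene_rule"))
    if (length(bad_attr)) stop("unknown feature attribute(s): ",
                               paste(bad_attr, collapse = ", "), call. = FALSE)
    missing_comp <- setdiff(ft$component_id, ens$base_model$reactions$id)
    if (length(missing_comp)) {
      stop("feature component(s) absent from base model: ",
           paste(missing_comp, collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(ens$members$member_id)) {
    stop("duplicate member ids", call. = FALSE)
  }
  if (!identical(sort(ens$states$member_id), sort(ens$members$member_id))) {
    stop("state table rows do not match the member list", call. = FALSE)
  }
  if (!setequal(setdiff(names(ens$states), "member_id"), ft$feature_id)) {
    stop("state table columns do not match the feature list", call. = FALSE)
  }
  invisible(ens)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %s\n", x$id))
  cat(sprintf("  %d members x %d features over base model %s (%d reactions)\n",
              nrow(x$members), nrow(x$features), x$base_model$id,
              nrow(x$base_model$reactions)))
  if (!is.na(x$current_member)) {
    cat("  base model currently impersonates:", x$current_member, "\n")
  }
  invisible(x)
}

#' Member ids of an ensemble
#' @param ens An `ensemble`.
#' @return Character vector of member ids.
#' @export
member_ids <- function(ens) ens$members$member_id

#' Build an ensemble from a collection of models
#'
#' The base model becomes the union of all reactions across the sources; a
#' reaction absent from a source is encoded for that member as bounds
#' `(0, 0)` (blocked) on the union reaction, so every member is reachable by
#' attribute assignment alone. One feature is created for every reaction
#' attribute (`lower_bound`, `upper_bound`, `gene_rule`) whose value differs
#' across sources.
#'
#' @param sources A list of `metabolic_model` objects, or a character vector
#'   of model file paths (SBML or JSON).
#' @param batch_size When loading from paths, the number of models held in
#'   memory at once. The result is independent of `batch_size`.
#' @param id Ensemble identifier.
#' @return An `ensemble` with one member per source.
#' @details All sources must share a metabolite namespace: the same id means
#'   the same metabolite. Two sources defining the same reaction id with
#'   different stoichiometry is an error.
#' @export
build_from_models <- function(sources, batch_size = 1L, id = "ensemble") {
  if (length(sources) == 0L) stop("need at least one source model", call. = FALSE)
  stopifnot(batch_size >= 1)
  from_paths <- is.character(sources)

  member_ids <- character(length(sources))
  provenance <- character(length(sources))

  base <- NULL
  # per-source attribute records: list of named lists rxn -> c(lb, ub, rule)
  recs <- vector("list", length(sources))

  idx_batches <- split(seq_along(sources),
                       ceiling(seq_along(sources) / batch_size))
  for (batch in idx_batches) {
    models <- lapply(batch, function(i) {
      if (from_paths) read_model(sources[[i]]) else sources[[i]]
    })
    for (k in seq_along(batch)) {
      i <- batch[[k]]
      m <- models[[k]]
      validate_metabolic_model(m)
      member_ids[i] <- if (from_paths) {
        tools::file_path_sans_ext(basename(sources[[i]]))
      } else {
        m$id
      }
      provenance[i] <- if (from_paths) sources[[i]] else
        paste0("in-memory model ", m$id)
      if (is.null(base)) {
        base <- m
        base$id <- paste0(id, "_base")
      } else {
        base <- add_reactions_from(base, m, m$reactions$id)
      }
      recs[[i]] <- stats::setNames(
        lapply(seq_len(nrow(m$reactions)), function(j)
          list(lb = m$reactions$lower_bound[j],
               ub = m$reactions$upper_bound[j],
               rule = m$reactions$gene_rule[j])),
        m$reactions$id)
    }
  }

  member_ids <- make.unique(member_ids, sep = "_")

  # find varying attributes across members
  base_rxns <- base$reactions$id
  feat_rows <- list()
  state_cols <- list()
  for (rid in base_rxns) {
    j <- match(rid, base$reactions$id)
    default_rule <- base$reactions$gene_rule[j]
    lbs <- ubs <- numeric(length(sources))
    rules <- character(length(sources))
    for (i in seq_along(sources)) {
      r <- recs[[i]][[rid]]
      if (is.null(r)) {       # absent reaction: blocked
        lbs[i] <- 0; ubs[i] <- 0; rules[i] <- default_rule
      } else {
        lbs[i] <- r$lb; ubs[i] <- r$ub; rules[i] <- r$rule
      }
    }
    for (attr in c("lower_bound", "upper_bound", "gene_rule")) {
      vals <- switch(attr, lower_bound = lbs, upper_bound = ubs,
                     gene_rule = rules)
      if (length(unique(vals)) > 1L) {
        fid <- paste0(rid, "__", attr)
        feat_rows[[length(feat_rows) + 1L]] <- tibble::tibble(
          feature_id = fid, component_id = rid, attribute = attr)
        state_cols[[fid]] <- vals
      }
    }
  }
  features <- if (length(feat_rows)) dplyr::bind_rows(feat_rows) else
    tibble::tibble(feature_id = character(), component_id = character(),
                   attribute = character())
  features <- features[order(features$feature_id), ]
  states <- tibble::tibble(member_id = member_ids)
  for (fid in features$feature_id) states[[fid]] <- state_cols[[fid]]

  new_ensemble(id = id, base_model = base, features = features,
               members = tibble::tibble(member_id = member_ids,
                                        provenance = provenance),
               states = states)
}

#' Switch the base model to a member's state
#'
#' Applies every feature's recorded state for `member_id` to the base model,
#' so the base model exactly impersonates that member. Switching is absolute,
#' not incremental: the result does not depend on which member was applied
#' before.
#'
#' @param ens An `ensemble`.
#' @param member_id A member id.
#' @return The ensemble with updated `base_model` and `current_member`.
#' @export
set_member_state <- function(ens, member_id) {
  row <- match(member_id, ens$states$member_id)
  if (is.na(row)) stop("unknown member: ", member_id, call. = FALSE)
  for (k in seq_len(nrow(ens$features))) {
    ens$base_model <- set_reaction_attr(
      ens$base_model, ens$features$component_id[k], ens$features$attribute[k],
      ens$states[[ens$features$feature_id[k]]][row])
  }
  ens$current_member <- member_id
  ens
}

#' Extract one member as a standalone model
#'
#' @param ens An `ensemble`.
#' @param member_id A member id.
#' @return A `metabolic_model`, a deep copy of the base model with the
#'   member's states applied; the ensemble is not modified.
#' @export
extract_member <- function(ens, member_id) {
  row <- match(member_id, ens$states$member_id)
  if (is.na(row)) stop("unknown member: ", member_id, call. = FALSE)
  model <- copy_model(ens$base_model)
  for (k in seq_len(nrow(ens$features))) {
    model <- set_reaction_attr(
      model, ens$features$component_id[k], ens$features$attribute[k],
      ens$states[[ens$features$feature_id[k]]][row])
  }
  model$id <- member_id
  model
}

#' Member-by-feature state table
#'
#' @param ens An `ensemble`.
#' @param binarize If `TRUE`, each cell is reduced to 1 when the state
#'   permits flux (a nonzero bound, or a nonempty gene rule) and 0 otherwise,
#'   giving the binary presence/absence encoding used as machine-learning
#'   input.
#' @return A tibble with one row per member: `member_id` plus one column per
#'   feature.
#' @export
feature_state_table <- function(ens, binarize = FALSE) {
  out <- ens$states
  if (binarize && nrow(ens$features)) {
    for (fid in ens$features$feature_id) {
      col <- out[[fid]]
      out[[fid]] <- if (is.numeric(col)) as.integer(col != 0)
                    else as.integer(nzchar(col))
    }
  }
  out
}

#' Set one feature to a single value for every member
#'
#' The curation edit: after deciding (e.g. from literature) that a varying
#' reaction should be blocked or fixed, collapse its feature to one value
#' across the whole ensemble.
#'
#' @param ens An `ensemble`.
#' @param feature_id A feature id.
#' @param value New state value (numeric for bound features, character for
#'   gene-rule features).
#' @return The modified ensemble.
#' @export
set_feature_across_members <- function(ens, feature_id, value) {
  k <- match(feature_id, ens$features$feature_id)
  if (is.na(k)) stop("unknown feature: ", feature_id, call. = FALSE)
  attr_k <- ens$features$attribute[k]
  if (attr_k %in% c("lower_bound", "upper_bound")) {
    if (!is.numeric(value)) stop("feature ", feature_id,
                                 " takes a numeric value", call. = FALSE)
  } else if (!is.character(value)) {
    stop("feature ", feature_id, " takes a gene-rule string", call. = FALSE)
  }
  ens$states[[feature_id]] <- rep(value, nrow(ens$states))
  if (!is.na(ens$current_member)) {
    ens <- set_member_state(ens, ens$current_member)
  }
  ens
}

#' Save / load an ensemble archive
#'
#' The archive is a directory holding `base.xml` (the base model as SBML
#' Level 3 + fbc) and `ensemble.json` (features, members, states, provenance;
#' versioned). No per-member model copy is stored.
#'
#' @param ens An `ensemble`.
#' @param path Directory path (created if needed).
#' @return `save_ensemble()` returns `path` invisibly; `load_ensemble()`
#'   returns the `ensemble`.
#' @export
save_ensemble <- function(ens, path) {
  validate_ensemble(ens)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_model(ens$base_model, file.path(path, "base.xml"), format = "sbml")
  states <- stats::setNames(
    lapply(ens$features$feature_id, function(fid)
      as.list(stats::setNames(ens$states[[fid]], ens$states$member_id))),
    ens$features$feature_id)
  doc <- list(
    schema = "gemsemble-ensemble",
    format_version = ENSEMBLE_FORMAT_VERSION,
    id = ens$id,
    current_member = if (is.na(ens$current_member)) NULL else ens$current_member,
    features = purrr::pmap(ens$features, list),
    members = purrr::pmap(ens$members, list),
    states = states)
  jsonlite::write_json(doc, file.path(path, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  json_path <- file.path(path, "ensemble.json")
  base_path <- file.path(path, "base.xml")
  if (!file.exists(json_path) || !file.exists(base_path)) {
    stop("not an ensemble archive (missing base.xml or ensemble.json): ",
         path, call. = FALSE)
  }
  doc <- tryCatch(jsonlite::read_json(json_path),
                  error = function(e) stop("corrupt ensemble archive: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(doc$schema, "gemsemble-ensemble")) {
    stop("corrupt ensemble archive: unexpected schema", call. = FALSE)
  }
  ver <- doc$format_version
  if (is.null(ver) || ver != ENSEMBLE_FORMAT_VERSION) {
    stop("ensemble archive format version ", ver %||% "<missing>",
         " is not supported (expected ", ENSEMBLE_FORMAT_VERSION, ")",
         call. = FALSE)
  }
  base <- read_model(base_path, format = "sbml")
  features <- purrr::map_dfr(doc$features, tibble::as_tibble)
  if (!nrow(features)) {
    features <- tibble::tibble(feature_id = character(),
                               component_id = character(),
                               attribute = character())
  }
  members <- purrr::map_dfr(doc$members, tibble::as_tibble)
  state_cols <- stats::setNames(
    lapply(seq_len(nrow(features)), function(k) {
      fid <- features$feature_id[k]
      vals <- unlist(doc$states[[fid]][members$member_id],
                     use.names = FALSE)
      # JSON does not distinguish integer from real; bound features are reals
      if (features$attribute[k] == "gene_rule") as.character(vals)
      else as.numeric(vals)
    }),
    features$feature_id)
  states <- dplyr::bind_cols(
    tibble::tibble(member_id = members$member_id),
    tibble::as_tibble(state_cols))
  new_ensemble(id = doc$id, base_model = base, features = features,
               members = members, states = states,
               current_member = doc$current_member %||% NA_character_)
}
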