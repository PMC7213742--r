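#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` is the container every other function in the package
#' operates on: a stoichiometric network with flux bounds, gene-protein-
#' reaction (GPR) rules, and a linear objective (typically flux through a
#' biomass reaction with weight 1).
#'
#' @param id Character scalar model identifier.
#' @param metabolites A data frame with columns `id`, and optionally `name`
#'   and `compartment`.
#' @param reactions A data frame with columns `id`, `lower_bound`,
#'   `upper_bound`, `gene_rule` (character; `""` for none) and
#'   `stoichiometry`, a list-column of named numeric vectors mapping
#'   metabolite ids to signed coefficients (negative = consumed).
#' @param genes A data frame with column `id`, or `NULL` to derive the gene
#'   set from the GPR rules.
#' @param objective Named numeric vector of reaction-id -> weight.
#' @return An object of class `metabolic_model`.
#' @details
#' Flux bounds are in mmol per gram dry weight per hour by field convention.
#' Every bound must be finite and explicit; there are no default bounds.
#' A reaction whose stoichiometry names a single metabolite is a boundary
#' (exchange) reaction: negative flux is uptake, positive flux is secretion.
#' @examples
#' m <- toy_chain_model()
#' m
#' @export
metabolic_model <- function(id, metabolites, reactions, genes = NULL,
                            objective = numeric()) {
  metabolites <- tibble::as_tibble(metabolites)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  reactions <- tibble::as_tibble(reactions)
  if (!"gene_rule" %in% names(reactions)) reactions$gene_rule <- ""
  reactions$gene_rule[is.na(reactions$gene_rule)] <- ""
  if (is.null(genes)) {
    gids <- unique(unlist(lapply(reactions$gene_rule, gene_rule_genes)))
    genes <- tibble::tibble(id = as.character(gids %||% character()))
  } else {
    genes <- tibble::as_tibble(genes)
  }
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         genes = genes, objective = objective),
    class = "metabolic_model"
  )
  validate_metabolic_model(model)
  model
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a metabolic model's internal consistency
#'
#' Checks id uniqueness, bound ordering, that every metabolite referenced by a
#' reaction is declared, that every gene in a GPR rule is declared, and that
#' the objective references existing reactions.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_metabolic_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  if (anyDuplicated(model$metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(model$metabolites$id[duplicated(model$metabolites$id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rx$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(model$genes$id)) {
    stop("duplicate gene ids", call. = FALSE)
  }
  if (any(!nzchar(model$metabolites$id))) stop("empty metabolite id", call. = FALSE)
  bad <- rx$lower_bound > rx$upper_bound
  if (any(bad)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rx$id[bad], collapse = ", "), call. = FALSE)
  }
  refd <- unique(unlist(lapply(rx$stoichiometry, names)))
  missing_met <- setdiff(refd, model$metabolites$id)
  if (length(missing_met)) {
    stop("reaction references undeclared metabolite(s): ",
         paste(missing_met, collapse = ", "), call. = FALSE)
  }
  empty_stoich <- vapply(rx$stoichiometry, length, integer(1)) == 0L
  if (any(empty_stoich)) {
    stop("reaction(s) with empty stoichiometry: ",
         paste(rx$id[empty_stoich], collapse = ", "), call. = FALSE)
  }
  rule_genes <- unique(unlist(lapply(rx$gene_rule, gene_rule_genes)))
  missing_gene <- setdiff(rule_genes, model$genes$id)
  if (length(missing_gene)) {
    stop("gene rule references undeclared gene(s): ",
         paste(missing_gene, collapse = ", "), call. = FALSE)
  }
  missing_obj <- setdiff(names(model$objective), rx$id)
  if (length(missing_obj)) {
    stop("objective references unknown reaction(s): ",
         paste(missing_obj, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s\n", x$id))
  cat(sprintf("  %d metabolites, %d reactions (%d exchanges), %d genes\n",
              nrow(x$metabolites), nrow(x$reactions),
              length(exchange_reactions(x)), nrow(x$genes)))
  if (length(x$objective)) {
    cat("  objective:",
        paste(sprintf("%s (%g)", names(x$objective), x$objective),
              collapse = ", "), "\n")
  } else {
    cat("  objective: <none>\n")
  }
  invisible(x)
}

#' Identify exchange reactions
#'
#' A reaction is an exchange (boundary) reaction iff its stoichiometry
#' involves exactly one metabolite. By sign convention uptake is negative
#' flux and secretion positive.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  n_met <- vapply(model$reactions$stoichiometry, length, integer(1))
  model$reactions$id[n_met == 1L]
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return A dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- unname(st)
  }
  S
}

# deep-ish copy; R lists are value-semantic but keep an explicit verb for
# intent where the ensemble layer hands models out
copy_model <- function(model) {
  model
}

# replace bounds / gene rule of one reaction, returning the model
set_reaction_attr <- function(model, reaction_id, attribute, value) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id, call. = FALSE)
  if (attribute %in% c("lower_bound", "upper_bound")) {
    model$reactions[[attribute]][i] <- as.numeric(value)
  } else if (attribute == "gene_rule") {
    model$reactions$gene_rule[i] <- as.character(value)
    new_genes <- setdiff(gene_rule_genes(value), model$genes$id)
    if (length(new_genes)) {
      model$genes <- dplyr::bind_rows(model$genes,
                                      tibble::tibble(id = new_genes))
    }
  } else {
    stop("unknown attribute: ", attribute, call. = FALSE)
  }
  model
}

get_reaction_attr <- function(model, reaction_id, attribute) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id, call. = FALSE)
  model$reactions[[attribute]][i]
}

#' Add reactions from a donor model
#'
#' Appends the named reactions of `donor` (with their stoichiometry, bounds
#' and GPR rules) to `model`, declaring any metabolites and genes the model
#' lacks. A reaction id already present in `model` is an error if the two
#' stoichiometries differ, otherwise it is left untouched.
#'
#' @param model,donor `metabolic_model` objects sharing a metabolite
#'   namespace (same id means same metabolite).
#' @param reaction_ids Ids of reactions in `donor` to add.
#' @return The augmented model.
#' @export
add_reactions_from <- function(model, donor, reaction_ids) {
  for (rid in reaction_ids) {
    j <- match(rid, donor$reactions$id)
    if (is.na(j)) stop("unknown donor reaction: ", rid, call. = FALSE)
    i <- match(rid, model$reactions$id)
    if (!is.na(i)) {
      if (!identical_stoich(model$reactions$stoichiometry[[i]],
                            donor$reactions$stoichiometry[[j]])) {
        stop("conflicting stoichiometry for reaction ", rid, call. = FALSE)
      }
      next
    }
    new_mets <- setdiff(names(donor$reactions$stoichiometry[[j]]),
                        model$metabolites$id)
    if (length(new_mets)) {
      add <- donor$metabolites[donor$metabolites$id %in% new_mets, ]
      model$metabolites <- dplyr::bind_rows(model$metabolites, add)
    }
    model$reactions <- dplyr::bind_rows(model$reactions, donor$reactions[j, ])
    new_genes <- setdiff(gene_rule_genes(donor$reactions$gene_rule[j]),
                         model$genes$id)
    if (length(new_genes)) {
      model$genes <- dplyr::bind_rows(model$genes,
                                      tibble::tibble(id = new_genes))
    }
  }
  model
}

identical_stoich <- function(a, b) {
  a <- sort_by_name(a); b <- sort_by_name(b)
  identical(names(a), names(b)) && isTRUE(all.equal(unname(a), unname(b)))
}

sort_by_name <- function(x) x[order(names(x))]
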