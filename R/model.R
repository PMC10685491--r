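#' Stoichiometric metabolic model
#'
#' Constructor for the `metabolic_model` container used throughout the package:
#' a stoichiometric matrix with flux bounds, an auto-detected exchange-reaction
#' subset, and designated biomass and maintenance (NGAM) reactions. Fluxes are
#' in mmol gDW^-1 h^-1 except the biomass reaction (h^-1).
#'
#' @param id model identifier.
#' @param mets data.frame with columns `id`, `formula`, `charge` (and
#'   optionally `compartment`, default `"c"`).
#' @param rxns data.frame with columns `id`, `lb`, `ub`.
#' @param S stoichiometric matrix (metabolites x reactions); dimnames must
#'   match `mets$id` and `rxns$id`.
#' @param biomass_id,ngam_id reaction ids of the biomass and the non-growth
#'   associated maintenance reaction (or `NULL`). The NGAM convention of
#'   genome-scale E. coli models is a fixed lower bound of 6.86 mmol ATP
#'   gDW^-1 h^-1.
#'
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, mets, rxns, S, biomass_id = NULL, ngam_id = NULL) {
  mets <- as.data.frame(mets)
  rxns <- as.data.frame(rxns)
  if (is.null(mets$compartment)) mets$compartment <- "c"
  if (is.null(mets$formula)) mets$formula <- NA_character_
  if (is.null(mets$charge)) mets$charge <- 0
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- list(mets$id, rxns$id)
  m <- structure(
    list(id = id, mets = mets, rxns = rxns, S = S,
         biomass_id = biomass_id, ngam_id = ngam_id),
    class = "metabolic_model")
  validate_model(m)
  attr(m, ".dense_S") <- as.matrix(S)
  m
}

# dense copy of the stoichiometric matrix, cached for the LP hot path
dense_S <- function(model) {
  d <- attr(model, ".dense_S")
  if (!is.null(d) && all(dim(d) == dim(model$S))) d else as.matrix(model$S)
}

#' Validate a metabolic model
#'
#' Checks the container invariants: matrix dimensions and dimnames match the
#' metabolite and reaction tables, every bound pair satisfies `lb <= ub`, and
#' the designated biomass/NGAM reactions exist.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (nrow(model$S) != nrow(model$mets) || ncol(model$S) != nrow(model$rxns))
    stop("stoichiometric matrix dimensions do not match metabolite/reaction tables")
  same_ids <- function(a, b) (length(b) == 0 && length(a %||% character()) == 0) ||
    identical(as.character(a), as.character(b))
  if (!same_ids(rownames(model$S), model$mets$id) ||
      !same_ids(colnames(model$S), model$rxns$id))
    stop("stoichiometric matrix dimnames do not match metabolite/reaction ids")
  if (anyDuplicated(model$mets$id)) stop("duplicated metabolite ids")
  if (anyDuplicated(model$rxns$id)) stop("duplicated reaction ids")
  bad <- model$rxns$id[model$rxns$lb > model$rxns$ub]
  if (length(bad)) stop("lower bound exceeds upper bound for reaction(s): ",
                        paste(bad, collapse = ", "))
  for (rid in c(model$biomass_id, model$ngam_id))
    if (!is.null(rid) && !rid %in% model$rxns$id)
      stop("designated reaction not in model: ", rid)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$mets), "\n",
      "  reactions:   ", nrow(x$rxns),
      " (", length(exchanges(x)), " exchanges)\n",
      "  biomass:     ", x$biomass_id %||% "<none>", "\n",
      "  NGAM:        ", x$ngam_id %||% "<none>", "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exchange reactions of a model
#'
#' Exchange (boundary) reactions are auto-detected as reactions involving
#' exactly one metabolite. The sign convention is flux < 0 for uptake.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchanges <- function(model) {
  model$rxns$id[Matrix::colSums(model$S != 0) == 1]
}

#' Get or set flux bounds
#'
#' @param model a `metabolic_model`.
#' @param rxn reaction id(s).
#' @param lb,ub new bounds (recycled); `NULL` leaves a side unchanged.
#' @return `get_bounds`: data.frame of `id`, `lb`, `ub`; `set_bounds`: the
#'   modified model.
#' @export
set_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  i <- match(rxn, model$rxns$id)
  if (anyNA(i)) stop("unknown reaction(s): ", paste(rxn[is.na(i)], collapse = ", "))
  if (!is.null(lb)) model$rxns$lb[i] <- rep_len(lb, length(i))
  if (!is.null(ub)) model$rxns$ub[i] <- rep_len(ub, length(i))
  bad <- which(model$rxns$lb[i] > model$rxns$ub[i])
  if (length(bad)) stop("lower bound exceeds upper bound for reaction(s): ",
                        paste(model$rxns$id[i][bad], collapse = ", "))
  model
}

#' @rdname set_bounds
#' @export
get_bounds <- function(model, rxn = model$rxns$id) {
  i <- match(rxn, model$rxns$id)
  if (anyNA(i)) stop("unknown reaction(s): ", paste(rxn[is.na(i)], collapse = ", "))
  model$rxns[i, c("id", "lb", "ub")]
}

#' Add a metabolite to a model
#'
#' @param model a `metabolic_model`.
#' @param id metabolite id (must be new).
#' @param formula chemical formula string or `NA`.
#' @param charge integer charge.
#' @param compartment compartment id.
#' @return the modified model.
#' @export
add_metabolite <- function(model, id, formula = NA_character_, charge = 0,
                           compartment = "c") {
  if (id %in% model$mets$id) stop("metabolite id already exists: ", id)
  model$mets <- rbind(model$mets,
                      data.frame(id = id, formula = formula, charge = charge,
                                 compartment = compartment))
  model$S <- rbind(model$S, Matrix::Matrix(0, 1, ncol(model$S), sparse = TRUE))
  rownames(model$S) <- model$mets$id
  validate_model(model)
  attr(model, ".dense_S") <- as.matrix(model$S)
  model
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id reaction id (must be new).
#' @param stoich named numeric vector, metabolite id -> coefficient
#'   (negative = consumed). All metabolites must exist.
#' @param lb,ub flux bounds.
#' @return the modified model.
#' @export
add_reaction <- function(model, id, stoich, lb = 0, ub = 1000) {
  if (id %in% model$rxns$id) stop("reaction id already exists: ", id)
  miss <- setdiff(names(stoich), model$mets$id)
  if (length(miss)) stop("unknown metabolite(s) in reaction ", id, ": ",
                         paste(miss, collapse = ", "))
  col <- Matrix::Matrix(0, nrow(model$S), 1, sparse = TRUE)
  col[match(names(stoich), model$mets$id), 1] <- stoich
  model$S <- cbind(model$S, col)
  model$rxns <- rbind(model$rxns, data.frame(id = id, lb = lb, ub = ub))
  colnames(model$S) <- model$rxns$id
  validate_model(model)
  attr(model, ".dense_S") <- as.matrix(model$S)
  model
}

#' Reaction stoichiometry as a named vector
#'
#' @param model a `metabolic_model`.
#' @param rxn reaction id.
#' @return named numeric vector over the metabolites with nonzero coefficient.
#' @export
reaction_stoich <- function(model, rxn) {
  j <- match(rxn, model$rxns$id)
  if (is.na(j)) stop("unknown reaction: ", rxn)
  col <- model$S[, j]
  col[col != 0]
}
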