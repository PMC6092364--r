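#' Construct a metabolic model
#'
#' A `metabolic_model` holds the stoichiometric description of a metabolic
#' network: an n x m stoichiometric matrix `S` whose entry `S[i, j]` is the
#' net number of molecules of metabolite i produced (positive) or consumed
#' (negative) by reaction j, together with reaction reversibility flags,
#' flux bounds (mmol/gDW/h), an objective indicator vector and optional
#' pathway/compartment annotations.
#'
#' @param metabolite_ids character vector of unique metabolite identifiers
#'   (rows of `S`).
#' @param reaction_ids character vector of unique reaction identifiers
#'   (columns of `S`).
#' @param S numeric matrix, `length(metabolite_ids)` x `length(reaction_ids)`.
#' @param reversible logical (or 0/1) vector, one entry per reaction. A
#'   reversible reaction is unfolded into separate forward and backward
#'   direction nodes by [unfold()].
#' @param lb,ub numeric flux bounds per reaction, in mmol/gDW/h.
#' @param objective numeric indicator vector per reaction; conventionally a
#'   single 1 at the biomass reaction.
#' @param subsystem optional named character vector mapping reaction id to a
#'   pathway label.
#' @param compartment optional named character vector mapping metabolite id
#'   to a compartment label.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [load_model()], [validate_model()], [unfold()]
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, S, reversible,
                            lb, ub, objective = NULL,
                            subsystem = NULL, compartment = NULL) {
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  n <- length(metabolite_ids)
  m <- length(reaction_ids)
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (nrow(S) != n || ncol(S) != m) {
    stop("S must be ", n, " x ", m, " to match the id vectors, got ",
         nrow(S), " x ", ncol(S), call. = FALSE)
  }
  if (anyDuplicated(metabolite_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reaction_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "),
         call. = FALSE)
  }
  reversible <- as.logical(reversible)
  if (length(reversible) != m || anyNA(reversible)) {
    stop("'reversible' must be a logical vector of length ", m, call. = FALSE)
  }
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != m || length(ub) != m) {
    stop("'lb' and 'ub' must have length ", m, call. = FALSE)
  }
  if (is.null(objective)) objective <- numeric(m)
  objective <- as.numeric(objective)
  if (length(objective) != m) stop("'objective' must have length ", m, call. = FALSE)
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  if (!is.null(subsystem)) {
    subsystem <- subsystem[intersect(names(subsystem), reaction_ids)]
  }
  if (!is.null(compartment)) {
    compartment <- compartment[intersect(names(compartment), metabolite_ids)]
  }
  structure(list(
    metabolite_ids = metabolite_ids,
    reaction_ids = reaction_ids,
    S = S,
    reversible = reversible,
    lb = lb,
    ub = ub,
    objective = objective,
    subsystem = subsystem,
    compartment = compartment
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions (", sum(x$reversible),
      " reversible)\n", sep = "")
  if (!is.null(x$subsystem)) {
    cat("  subsystems: ", length(unique(x$subsystem)), "\n", sep = "")
  }
  nobj <- which(x$objective != 0)
  if (length(nobj)) {
    cat("  objective: ", paste(x$reaction_ids[nobj], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of metabolites / reactions in a model
#' @param model a [metabolic_model()].
#' @return integer count.
#' @export
n_metabolites <- function(model) length(model$metabolite_ids)

#' @rdname n_metabolites
#' @export
n_reactions <- function(model) length(model$reaction_ids)

#' Screen a model for structural oddities
#'
#' Reports findings rather than raising errors: empty stoichiometric
#' rows/columns, inverted bounds, and metabolites that are never produced or
#' never consumed once reversible reactions are unfolded. The latter are
#' legal -- the graph constructions treat them through the diagonal
#' pseudoinverse convention -- but usually indicate boundary species or
#' model gaps worth knowing about.
#'
#' @param model a [metabolic_model()].
#' @return A data frame with columns `type`, `id`, `message`; zero rows when
#'   nothing is flagged.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  findings <- list()
  add <- function(type, id, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      type = type, id = id, message = message, stringsAsFactors = FALSE)
  }
  empty_col <- colSums(abs(model$S)) == 0
  for (j in which(empty_col)) {
    add("empty_reaction", model$reaction_ids[j], "reaction has no stoichiometry")
  }
  empty_row <- rowSums(abs(model$S)) == 0
  for (i in which(empty_row)) {
    add("unused_metabolite", model$metabolite_ids[i],
        "metabolite participates in no reaction")
  }
  inv <- model$lb > model$ub
  for (j in which(inv)) {
    add("bound_inversion", model$reaction_ids[j],
        sprintf("lb (%g) exceeds ub (%g)", model$lb[j], model$ub[j]))
  }
  sys <- unfold(model)
  never_prod <- sys$wplus == 0 & !empty_row
  never_cons <- sys$wminus == 0 & !empty_row
  for (i in which(never_prod)) {
    add("never_produced", model$metabolite_ids[i],
        "no unfolded reaction direction produces this metabolite")
  }
  for (i in which(never_cons)) {
    add("never_consumed", model$metabolite_ids[i],
        "no unfolded reaction direction consumes this metabolite")
  }
  if (!length(findings)) {
    return(data.frame(type = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
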