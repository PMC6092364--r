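#' Define a growth scenario
#'
#' A scenario is a named set of flux-bound overrides (typically on exchange
#' reactions, whose bounds encode the growth medium) plus an optional
#' objective reaction replacing the model's own.
#'
#' @param name scenario label.
#' @param bound_overrides named list; each element is `c(lb, ub)` in
#'   mmol/gDW/h, names are reaction ids.
#' @param objective_reaction optional reaction id to maximise instead of
#'   the model objective.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, bound_overrides = list(), objective_reaction = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  for (id in names(bound_overrides)) {
    bo <- bound_overrides[[id]]
    if (length(bo) != 2 || !is.numeric(bo)) {
      stop("bound override for ", id, " must be numeric c(lb, ub)", call. = FALSE)
    }
    if (bo[1] > bo[2]) stop("bound override for ", id, " has lb > ub", call. = FALSE)
  }
  structure(list(name = name, bound_overrides = bound_overrides,
                 objective_reaction = objective_reaction),
            class = "scenario")
}

#' Read a scenario from a flat config file
#'
#' One line per override: `reaction_id<TAB>lb<TAB>ub`. Lines starting with
#' `#` are comments; an optional line `objective<TAB>reaction_id` sets the
#' objective.
#'
#' @param path config file.
#' @param name scenario name (defaults to the file name).
#' @return A [scenario()].
#' @export
read_scenario <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list(); objective <- NULL
  for (ln in lines) {
    parts <- strsplit(ln, "\t|[ ]+")[[1]]
    if (parts[1] == "objective") { objective <- parts[2]; next }
    if (length(parts) != 3) stop("malformed scenario line: ", ln, call. = FALSE)
    overrides[[parts[1]]] <- as.numeric(parts[2:3])
  }
  scenario(name %||% basename(path), overrides, objective)
}

apply_scenario <- function(model, scn) {
  if (is.null(scn)) return(model)
  stopifnot(inherits(scn, "scenario"))
  missing <- setdiff(names(scn$bound_overrides), model$reaction_ids)
  if (length(missing)) {
    stop("scenario '", scn$name, "' overrides unknown reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (id in names(scn$bound_overrides)) {
    j <- match(id, model$reaction_ids)
    model$lb[j] <- scn$bound_overrides[[id]][1]
    model$ub[j] <- scn$bound_overrides[[id]][2]
  }
  if (!is.null(scn$objective_reaction)) {
    j <- match(scn$objective_reaction, model$reaction_ids)
    if (is.na(j)) stop("scenario objective reaction not in model: ",
                       scn$objective_reaction, call. = FALSE)
    model$objective <- as.numeric(seq_along(model$reaction_ids) == j)
  }
  model
}

#' Solve the flux balance analysis linear programme
#'
#' Maximises the objective flux `c' v` subject to the steady-state mass
#' balance `S v = 0` and the flux bounds `lb <= v <= ub` (after applying
#' any scenario overrides), using the package's bounded-variable simplex
#' ([simplex_lp()]). The optimum vertex is deterministic for given inputs.
#' FBA optima are generally non-unique; `minimize_total_flux = TRUE` adds a
#' lexicographic second stage that, at the fixed optimal objective,
#' minimises the total absolute flux, for a reproducible representative
#' solution. It is off by default so that the primary vertex is reported
#' as-is; `$mode` records which was used.
#'
#' @param model a [metabolic_model()].
#' @param scenario optional [scenario()].
#' @param minimize_total_flux lexicographic second stage (default FALSE).
#' @param tol LP tolerance.
#' @return An object of class `flux_solution`: `status`, flux vector `v`,
#'   `objective_value`, the unfolded non-negative `v2m`, the metabolite
#'   flux `j`, and `mode`. For infeasible/unbounded problems `v` is NULL
#'   and only `status` is meaningful.
#' @export
solve_fba <- function(model, scenario = NULL, minimize_total_flux = FALSE,
                      tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"))
  mod <- apply_scenario(model, scenario)
  if (all(mod$objective == 0)) {
    stop("model has no objective reaction; set 'objective' or use a ",
         "scenario with an objective_reaction", call. = FALSE)
  }
  n <- n_metabolites(mod); m <- n_reactions(mod)
  res <- simplex_lp(mod$objective, mod$S, rep(0, n), mod$lb, mod$ub,
                    maximize = TRUE, tol = tol)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, v = NULL,
                          objective_value = NA_real_, v2m = NULL, j = NULL,
                          mode = "primary"),
                     class = "flux_solution"))
  }
  v <- res$x
  mode <- "primary"
  if (minimize_total_flux) {
    # min sum |v| at fixed objective: split v = p - q, p,q >= 0
    Aeq <- rbind(cbind(mod$S, -mod$S), c(mod$objective, -mod$objective))
    beq <- c(rep(0, n), res$value)
    lb2 <- rep(0, 2 * m); ub2 <- c(pmax(mod$ub, 0), pmax(-mod$lb, 0))
    res2 <- simplex_lp(rep(-1, 2 * m), Aeq, beq, lb2, ub2,
                       maximize = TRUE, tol = tol)
    if (res2$status == "optimal") {
      v <- res2$x[seq_len(m)] - res2$x[m + seq_len(m)]
      mode <- "min_total_flux"
    }
  }
  uf <- unfold_fluxes(v, mod)
  structure(list(status = "optimal", v = stats::setNames(v, mod$reaction_ids),
                 objective_value = res$value, v2m = uf$v2m, j = uf$j,
                 mode = mode),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective ", format(x$objective_value), " (", x$mode, "), ",
        sum(abs(x$v) > 1e-9 * max(abs(x$v))), " non-zero fluxes", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Unfold a flux vector into forward/backward components
#'
#' Positive entries become forward fluxes, negative entries backward
#' fluxes: `vplus = (abs(v) + v)/2`, `vminus = (abs(v) - v)/2`, stacked
#' into the non-negative `v2m = c(vplus, vminus)`. The metabolite flux
#' `j[k]` -- the rate at which metabolite k is produced and consumed -- is
#' computed from the production split `Splus %*% v2m`; for a balanced
#' vector it equals the consumption-side value, and a disagreement beyond
#' tolerance raises a steady-state violation error when the vector is
#' claimed balanced.
#'
#' @param v length-m flux vector.
#' @param model a [metabolic_model()].
#' @param check_balance verify the production/consumption identity
#'   (default: check only when `S v = 0` holds within `tol`).
#' @param tol relative tolerance.
#' @return list with `v2m` (length 2m) and `j` (length n, mmol/gDW/h).
#' @export
unfold_fluxes <- function(v, model, check_balance = NA, tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  v <- as.numeric(v)
  if (length(v) != n_reactions(model) || any(!is.finite(v))) {
    stop("v must be a finite vector with one flux per reaction", call. = FALSE)
  }
  scale <- max(1, abs(v))
  bad_rev <- !model$reversible & v < -tol * scale
  if (any(bad_rev)) {
    stop("negative flux on irreversible reaction(s): ",
         paste(model$reaction_ids[bad_rev], collapse = ", "), call. = FALSE)
  }
  sys <- unfold(model)
  vplus <- (abs(v) + v) / 2
  vminus <- (abs(v) - v) / 2
  vminus[!model$reversible] <- 0  # numerical dust on irreversible reactions
  vplus[!model$reversible] <- pmax(v[!model$reversible], 0)
  v2m <- c(vplus, vminus)
  j_prod <- as.vector(sys$Splus %*% v2m)
  j_cons <- as.vector(sys$Sminus %*% v2m)
  balanced <- max(abs(model$S %*% v)) <= tol * scale
  if (is.na(check_balance)) check_balance <- balanced
  if (check_balance && max(abs(j_prod - j_cons)) > tol * scale) {
    stop("steady-state violation: production and consumption fluxes ",
         "disagree by ", format(max(abs(j_prod - j_cons))), call. = FALSE)
  }
  list(v2m = stats::setNames(v2m, colnames(sys$S2m)),
       j = stats::setNames(j_prod, model$metabolite_ids))
}

resolve_exchange <- function(model, candidates) {
  hit <- candidates[candidates %in% model$reaction_ids]
  if (!length(hit)) return(NA_character_)
  hit[1]
}

#' Built-in growth scenarios for the E. coli core model
#'
#' The four growth conditions used throughout the package's E. coli
#' analyses. In every scenario the individual carbon intake rate is
#' 18.5 mmol/gDW/h for each available carbon source; oxygen is unlimited
#' except in the anaerobic scenario, where its intake upper limit is
#' 0 mmol/gDW/h; in the nutrient-limited scenario ammonium and phosphate
#' intake are capped at 4.5 and 3.04 mmol/gDW/h. All other exchange bounds
#' stay at the model's distributed defaults (rich media reading).
#'
#' @param model an e_coli_core-compatible [metabolic_model()] (exchange ids
#'   resolvable, with `__`/`_` id variants accepted).
#' @return named list of four [scenario()]s: `aerobic_glucose`,
#'   `aerobic_ethanol`, `anaerobic_glucose`, `limited_nh4_pi`.
#' @export
builtin_scenarios <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  ids <- list(
    glc = resolve_exchange(model, c("EX_glc__D_e", "EX_glc_D_e", "EX_glc_e")),
    etoh = resolve_exchange(model, c("EX_etoh_e")),
    o2 = resolve_exchange(model, c("EX_o2_e")),
    nh4 = resolve_exchange(model, c("EX_nh4_e")),
    pi = resolve_exchange(model, c("EX_pi_e")))
  missing <- names(ids)[is.na(unlist(ids))]
  if (length(missing)) {
    stop("cannot resolve exchange reaction(s) in this model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  carbon <- 18.5
  list(
    aerobic_glucose = scenario("aerobic_glucose",
      stats::setNames(list(c(-carbon, 1000)), ids$glc)),
    aerobic_ethanol = scenario("aerobic_ethanol",
      stats::setNames(list(c(0, 1000), c(-carbon, 1000)),
                      c(ids$glc, ids$etoh))),
    anaerobic_glucose = scenario("anaerobic_glucose",
      stats::setNames(list(c(-carbon, 1000), c(0, 1000)),
                      c(ids$glc, ids$o2))),
    limited_nh4_pi = scenario("limited_nh4_pi",
      stats::setNames(list(c(-carbon, 1000), c(-4.5, 1000), c(-3.04, 1000)),
                      c(ids$glc, ids$nh4, ids$pi))))
}
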