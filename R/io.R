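#' Read a metabolic model from file
#'
#' Supported formats:
#' \describe{
#'   \item{`tsv_triplet`}{The package's plain-text interchange format:
#'     `path` is a file prefix and `<path>_stoich.tsv` (columns
#'     `metabolite`, `reaction`, `coefficient`), `<path>_reactions.tsv`
#'     (columns `reaction`, `reversible`, `lb`, `ub`, `objective`, and
#'     optionally `subsystem`) and optionally `<path>_metabolites.tsv`
#'     (columns `metabolite`, `compartment`) are read.}
#'   \item{`bigg_json`}{A BiGG-style JSON model (stoichiometry, bounds,
#'     objective coefficients, subsystem annotations).}
#'   \item{`sbml`}{SBML Level 3 with the fbc package for flux bounds and
#'     objectives.}
#' }
#'
#' Reversibility is taken as: lower bound < 0 OR the model's declared
#' reversible flag. When a reaction is flagged irreversible but has a
#' negative lower bound, the bounds win (the reaction is treated as
#' reversible) with a warning, since flux behaviour must follow the bounds.
#'
#' Boundary metabolites (SBML `boundaryCondition="true"` or ids ending in
#' `_b`) are dropped from the stoichiometric rows; exchange pseudo-reactions
#' are kept as ordinary reactions.
#'
#' @param path file path (or file prefix for `tsv_triplet`).
#' @param format one of `"auto"`, `"tsv_triplet"`, `"bigg_json"`, `"sbml"`.
#'   `"auto"` guesses from the file extension.
#' @return A [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "tsv_triplet", "bigg_json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path)) "bigg_json"
      else if (grepl("\\.(xml|sbml)$", path)) "sbml"
      else "tsv_triplet"
  }
  switch(format,
    tsv_triplet = load_tsv_triplet(path),
    bigg_json = load_bigg_json(path),
    sbml = load_sbml(path))
}

resolve_reversibility <- function(flag, lb, reaction_ids) {
  conflict <- !flag & lb < 0
  if (any(conflict)) {
    warning("reaction(s) flagged irreversible but with negative lower bound, ",
            "treated as reversible: ",
            paste(reaction_ids[conflict], collapse = ", "), call. = FALSE)
  }
  flag | lb < 0
}

load_tsv_triplet <- function(prefix) {
  sf <- paste0(prefix, "_stoich.tsv")
  rf <- paste0(prefix, "_reactions.tsv")
  mf <- paste0(prefix, "_metabolites.tsv")
  for (f in c(sf, rf)) {
    if (!file.exists(f)) stop("tsv_triplet file not found: ", f, call. = FALSE)
  }
  st <- utils::read.delim(sf, stringsAsFactors = FALSE)
  rt <- utils::read.delim(rf, stringsAsFactors = FALSE)
  need_s <- c("metabolite", "reaction", "coefficient")
  need_r <- c("reaction", "reversible", "lb", "ub")
  if (!all(need_s %in% names(st))) {
    stop("malformed stoichiometry table ", sf, ": needs columns ",
         paste(need_s, collapse = ", "), call. = FALSE)
  }
  if (!all(need_r %in% names(rt))) {
    stop("malformed reaction table ", rf, ": needs columns ",
         paste(need_r, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rt$reaction)) {
    stop("duplicate reaction ids in ", rf, call. = FALSE)
  }
  rxn <- rt$reaction
  unknown <- setdiff(st$reaction, rxn)
  if (length(unknown)) {
    stop("stoichiometry references reactions missing from the reaction table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mets <- unique(st$metabolite)
  comp <- NULL
  if (file.exists(mf)) {
    mt <- utils::read.delim(mf, stringsAsFactors = FALSE)
    mets <- unique(c(mt$metabolite, mets))
    if ("compartment" %in% names(mt)) {
      comp <- stats::setNames(as.character(mt$compartment), mt$metabolite)
    }
  }
  S <- matrix(0, length(mets), length(rxn), dimnames = list(mets, rxn))
  S[cbind(match(st$metabolite, mets), match(st$reaction, rxn))] <- st$coefficient
  subsys <- NULL
  if ("subsystem" %in% names(rt)) {
    subsys <- stats::setNames(as.character(rt$subsystem), rxn)
  }
  obj <- if ("objective" %in% names(rt)) rt$objective else numeric(length(rxn))
  rev <- resolve_reversibility(as.logical(rt$reversible > 0), rt$lb, rxn)
  metabolic_model(mets, rxn, S, rev, rt$lb, rt$ub, obj,
                  subsystem = subsys, compartment = comp)
}

#' Write a metabolic model as TSV triplet files
#'
#' Inverse of `load_model(..., format = "tsv_triplet")`; numeric values are
#' written with 17 significant digits so a write/load round trip reproduces
#' `S`, bounds and reversibility exactly.
#'
#' @param model a [metabolic_model()].
#' @param prefix output file prefix; three files `<prefix>_stoich.tsv`,
#'   `<prefix>_reactions.tsv`, `<prefix>_metabolites.tsv` are written.
#' @return `prefix`, invisibly.
#' @export
write_model <- function(model, prefix) {
  stopifnot(inherits(model, "metabolic_model"))
  nz <- which(model$S != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 2], nz[, 1]), , drop = FALSE]
  st <- data.frame(
    metabolite = model$metabolite_ids[nz[, 1]],
    reaction = model$reaction_ids[nz[, 2]],
    coefficient = sprintf("%.17g", model$S[nz]),
    stringsAsFactors = FALSE)
  rt <- data.frame(
    reaction = model$reaction_ids,
    reversible = as.integer(model$reversible),
    lb = sprintf("%.17g", model$lb),
    ub = sprintf("%.17g", model$ub),
    objective = sprintf("%.17g", model$objective),
    stringsAsFactors = FALSE)
  if (!is.null(model$subsystem)) {
    rt$subsystem <- unname(model$subsystem[model$reaction_ids])
  }
  mt <- data.frame(metabolite = model$metabolite_ids, stringsAsFactors = FALSE)
  if (!is.null(model$compartment)) {
    mt$compartment <- unname(model$compartment[model$metabolite_ids])
  }
  utils::write.table(st, paste0(prefix, "_stoich.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rt, paste0(prefix, "_reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mt, paste0(prefix, "_metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

load_bigg_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse BiGG JSON ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  if (is.null(doc$reactions) || is.null(doc$metabolites)) {
    stop("BiGG JSON ", path, " lacks 'reactions'/'metabolites' lists", call. = FALSE)
  }
  mets <- vapply(doc$metabolites, function(x) x$id %||% stop_malformed(path, "metabolite id"),
                 character(1))
  comp <- vapply(doc$metabolites, function(x) as.character(x$compartment %||% NA_character_),
                 character(1))
  boundary <- grepl("_b$", mets)
  keep_mets <- mets[!boundary]
  rxn <- vapply(doc$reactions, function(x) x$id %||% stop_malformed(path, "reaction id"),
                character(1))
  m <- length(rxn)
  lb <- vapply(doc$reactions, function(x) as.numeric(x$lower_bound %||% -1000), numeric(1))
  ub <- vapply(doc$reactions, function(x) as.numeric(x$upper_bound %||% 1000), numeric(1))
  obj <- vapply(doc$reactions, function(x) as.numeric(x$objective_coefficient %||% 0), numeric(1))
  subsys <- vapply(doc$reactions, function(x) as.character(x$subsystem %||% NA_character_),
                   character(1))
  S <- matrix(0, length(keep_mets), m, dimnames = list(keep_mets, rxn))
  for (j in seq_len(m)) {
    sto <- doc$reactions[[j]]$metabolites
    if (is.null(sto)) next
    ids <- names(sto)
    ok <- ids %in% keep_mets
    if (any(!ok) && any(!grepl("_b$", ids[!ok]))) {
      stop("reaction ", rxn[j], " in ", path,
           " references unknown metabolite(s): ",
           paste(setdiff(ids[!ok][!grepl("_b$", ids[!ok])], keep_mets), collapse = ", "),
           call. = FALSE)
    }
    S[ids[ok], j] <- vapply(sto[ok], as.numeric, numeric(1))
  }
  rev <- lb < 0  # BiGG JSON has no reversible flag; bounds are the truth
  sub <- if (all(is.na(subsys))) NULL else stats::setNames(ifelse(is.na(subsys), "unassigned", subsys), rxn)
  cmp <- stats::setNames(comp[!boundary], keep_mets)
  metabolic_model(keep_mets, rxn, S, rev, lb, ub, obj,
                  subsystem = sub, compartment = cmp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_malformed <- function(path, what) {
  stop("malformed model file ", path, ": missing ", what, call. = FALSE)
}

load_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(species)) stop("SBML ", path, ": no species found", call. = FALSE)
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  sp_comp <- xml2::xml_attr(species, "compartment")
  keep <- !sp_boundary & !grepl("_b$", sub("^M_", "", sp_id))
  mets_raw <- sp_id[keep]
  mets <- sub("^M_", "", mets_raw)

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx)) stop("SBML ", path, ": no reactions found", call. = FALSE)
  rid_raw <- xml2::xml_attr(rx, "id")
  rxn <- sub("^R_", "", rid_raw)
  flag <- xml2::xml_attr(rx, "reversible") %in% "true"
  lookup_bound <- function(attr_val, default) {
    ifelse(is.na(attr_val), default,
           ifelse(attr_val %in% names(pval), unname(pval[attr_val]),
                  suppressWarnings(as.numeric(attr_val))))
  }
  lb <- lookup_bound(xml2::xml_attr(rx, "lowerFluxBound"), -1000)
  ub <- lookup_bound(xml2::xml_attr(rx, "upperFluxBound"), 1000)
  # SBML L2 kinetic-law bounds are not read; L3/fbc attributes cover the
  # models this package targets.
  lb[is.na(lb)] <- -1000; ub[is.na(ub)] <- 1000
  lb[!flag & lb < 0 & is.na(xml2::xml_attr(rx, "lowerFluxBound"))] <- 0

  S <- matrix(0, length(mets), length(rxn), dimnames = list(mets, rxn))
  for (j in seq_along(rx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx[[j]], paste0("./", side, "/speciesReference"))
      if (!length(refs)) next
      sid <- xml2::xml_attr(refs, "species")
      sto <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      sto[is.na(sto)] <- 1
      if (side == "listOfReactants") sto <- -sto
      ok <- sid %in% mets_raw
      if (!any(ok)) next
      ids <- sub("^M_", "", sid[ok])
      S[cbind(match(ids, mets), j)] <- S[cbind(match(ids, mets), j)] + sto[ok]
    }
  }

  obj <- numeric(length(rxn))
  # fbc elements keep their prefix after ns stripping; match by local name
  fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  if (length(fo)) {
    orid <- sub("^R_", "", xml2::xml_attr(fo, "reaction"))
    ocoef <- as.numeric(xml2::xml_attr(fo, "coefficient"))
    ocoef[is.na(ocoef)] <- 1
    obj[match(orid, rxn)] <- ocoef
  }
  rev <- resolve_reversibility(flag, lb, rxn)
  cmp <- stats::setNames(sp_comp[keep], mets)
  metabolic_model(mets, rxn, S, rev, lb, ub, obj, compartment = cmp)
}

#' Path to the bundled Escherichia coli core model
#'
#' The package ships the published core model of E. coli central carbon
#' metabolism (72 metabolites, 95 reactions, 11 pathways) as plain-text TSV
#' triplet files under `inst/extdata`. The stoichiometry, bounds and
#' objective are transcribed from the standard distribution of the model;
#' exchange pseudo-reactions carry the conventional reversible flag of the
#' original distribution (their bounds still encode the growth medium), and
#' the pathway labels follow the standard BiGG subsystem annotation.
#'
#' @return The TSV triplet prefix, suitable for
#'   `load_model(ecoli_core_path(), "tsv_triplet")`.
#' @export
ecoli_core_path <- function() {
  sub("_stoich\\.tsv$", "",
      system.file("extdata", "e_coli_core_stoich.tsv", package = "fluxgraphs",
                  mustWork = TRUE))
}
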