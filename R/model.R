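#' Construct a strain metabolic model
#'
#' A `strain_model` is a constraint-based (stoichiometric) model: a set of
#' metabolites split between cytosol and extracellular compartments, and a
#' set of reactions with flux bounds (mmol/gDW/h convention). Exchange
#' reactions touch exactly one extracellular metabolite and carry the
#' uptake/secretion boundary; uptake is a negative lower bound on exchange
#' flux (COBRA convention). Exactly one reaction is the biomass objective.
#' Infinite bounds are clamped to +/-1000 so every linear program is bounded.
#'
#' @param strain_id Strain identifier.
#' @param metabolites Data frame with columns `id`, `name`, `compartment`
#'   (`"cytosol"` or `"extracellular"`).
#' @param reactions Data frame with columns `id`, `stoichiometry` (list of
#'   named numeric vectors, negative = consumed), `lb`, `ub`, `is_exchange`,
#'   `is_biomass`.
#' @param biomass_reaction_id Id of the biomass reaction.
#' @return A validated `strain_model`.
#' @export
strain_model <- function(strain_id, metabolites, reactions, biomass_reaction_id) {
  model <- structure(
    list(
      strain_id = strain_id,
      metabolites = as_tibble(metabolites),
      reactions = as_tibble(reactions),
      biomass_reaction_id = biomass_reaction_id
    ),
    class = "strain_model"
  )
  validate_model(model)
}

#' Validate a strain model
#'
#' Checks the structural invariants (unique ids, known compartments,
#' well-formed stoichiometry, bounds, a unique biomass reaction, exchange
#' reactions touching exactly one extracellular metabolite) and clamps
#' infinite bounds to +/-1000.
#'
#' @param model A `strain_model`.
#' @return The model, invisibly modified (clamped bounds).
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  problems <- character(0)
  need_met <- setdiff(c("id", "compartment"), names(mets))
  need_rxn <- setdiff(c("id", "stoichiometry", "lb", "ub"), names(rxns))
  if (length(need_met) > 0) problems <- c(problems, paste0("metabolites missing: ", paste(need_met, collapse = ", ")))
  if (length(need_rxn) > 0) problems <- c(problems, paste0("reactions missing: ", paste(need_rxn, collapse = ", ")))
  if (length(problems) > 0) abort(paste(problems, collapse = "; "))
  if (!"name" %in% names(mets)) mets$name <- mets$id
  if (!"is_exchange" %in% names(rxns)) rxns$is_exchange <- FALSE
  if (!"is_biomass" %in% names(rxns)) rxns$is_biomass <- rxns$id == model$biomass_reaction_id

  if (anyDuplicated(mets$id)) problems <- c(problems, "duplicate metabolite ids")
  if (anyDuplicated(rxns$id)) problems <- c(problems, "duplicate reaction ids")
  if (!all(mets$compartment %in% c("cytosol", "extracellular"))) {
    problems <- c(problems, "compartment must be cytosol or extracellular")
  }
  rxns$lb <- pmax(rxns$lb, -1000)
  rxns$ub <- pmin(rxns$ub, 1000)
  if (any(rxns$lb > rxns$ub)) problems <- c(problems, "lower bound exceeds upper bound")
  unknown <- setdiff(unique(unlist(map(rxns$stoichiometry, names))), mets$id)
  if (length(unknown) > 0) {
    problems <- c(problems, paste0("stoichiometry references unknown metabolites: ",
      paste(unknown, collapse = ", ")))
  }
  if (any(map_lgl(rxns$stoichiometry, function(s) any(s == 0)))) {
    problems <- c(problems, "stoichiometry must list only nonzero coefficients")
  }
  if (is.null(model$biomass_reaction_id) || !model$biomass_reaction_id %in% rxns$id) {
    problems <- c(problems, "biomass_reaction_id must name an existing reaction")
  }
  ext <- mets$id[mets$compartment == "extracellular"]
  bad_ex <- rxns$id[rxns$is_exchange & !map_lgl(rxns$stoichiometry, function(s) {
    length(s) == 1 && names(s) %in% ext
  })]
  if (length(bad_ex) > 0) {
    problems <- c(problems, paste0("exchange reactions must touch exactly one extracellular metabolite: ",
      paste(bad_ex, collapse = ", ")))
  }
  if (length(problems) > 0) abort(paste(problems, collapse = "; "))
  model$metabolites <- mets
  model$reactions <- rxns
  model
}

#' @export
print.strain_model <- function(x, ...) {
  cat(sprintf(
    "<strain_model> %s: %d metabolites, %d reactions (%d exchanges), biomass = %s\n",
    x$strain_id, nrow(x$metabolites), nrow(x$reactions),
    sum(x$reactions$is_exchange), x$biomass_reaction_id
  ))
  invisible(x)
}

#' Read / write a strain model as JSON
#'
#' The schema has top-level keys `strain_id`, `metabolites`
#' (`id`,`name`,`compartment`), `reactions` (`id`, `stoichiometry` map,
#' `lb`, `ub`, `is_exchange`, `is_biomass`) and `biomass_reaction_id`.
#' Writing uses a canonical key order so that write-read round trips are
#' byte stable. SBML-style `EX_` prefixes on exchange ids are accepted on
#' read and used to infer `is_exchange` when the flag is absent.
#'
#' @param path File path.
#' @return `read_model` returns a `strain_model`; `write_model` returns the
#'   path invisibly.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- jsonlite::read_json(path)
  missing <- setdiff(c("strain_id", "metabolites", "reactions"), names(raw))
  if (length(missing) > 0) {
    abort(paste0("model JSON missing keys: ", paste(missing, collapse = ", ")))
  }
  if (is.null(raw$biomass_reaction_id)) {
    abort("model JSON missing keys: biomass_reaction_id")
  }
  mets <- tibble(
    id = map_chr(raw$metabolites, "id"),
    name = map_chr(raw$metabolites, function(m) m$name %||% m$id),
    compartment = map_chr(raw$metabolites, "compartment")
  )
  rxns <- tibble(
    id = map_chr(raw$reactions, "id"),
    stoichiometry = map(raw$reactions, function(r) unlist(r$stoichiometry)),
    lb = map_dbl(raw$reactions, "lb"),
    ub = map_dbl(raw$reactions, "ub"),
    is_exchange = map_lgl(raw$reactions, function(r) {
      isTRUE(r$is_exchange) || (is.null(r$is_exchange) && grepl("^EX_", r$id))
    }),
    is_biomass = map_lgl(raw$reactions, function(r) {
      isTRUE(r$is_biomass) || identical(r$id, raw$biomass_reaction_id)
    })
  )
  strain_model(raw$strain_id, mets, rxns, raw$biomass_reaction_id)
}

#' @rdname read_model
#' @param model A `strain_model`.
#' @export
write_model <- function(model, path) {
  out <- list(
    strain_id = model$strain_id,
    metabolites = pmap(
      model$metabolites[, c("id", "name", "compartment")],
      function(id, name, compartment) list(id = id, name = name, compartment = compartment)
    ),
    reactions = pmap(
      model$reactions[, c("id", "stoichiometry", "lb", "ub", "is_exchange", "is_biomass")],
      function(id, stoichiometry, lb, ub, is_exchange, is_biomass) {
        list(
          id = id, stoichiometry = as.list(stoichiometry),
          lb = lb, ub = ub, is_exchange = is_exchange, is_biomass = is_biomass
        )
      }
    ),
    biomass_reaction_id = model$biomass_reaction_id
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Define a growth medium
#'
#' A medium is a set of extracellular metabolites with maximal uptake fluxes
#' (all non-negative). "Defined conditions" for singleton and community
#' growth predictions are expressed as media.
#'
#' @param ... Named uptake limits (e.g. `glc = 10`), or a single named
#'   numeric vector / list.
#' @param name Optional medium name.
#' @return A `medium`: tibble with columns `metabolite_id`, `max_uptake`.
#' @export
medium <- function(..., name = "medium") {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) || (length(dots) == 1 && names(dots)[[1]] == "")) {
    dots <- as.list(dots[[1]])
  }
  vals <- unlist(dots) %||% numeric(0)
  if (length(vals) > 0 && (is.null(names(vals)) || any(!nzchar(names(vals))))) {
    abort("all medium entries must be named")
  }
  if (any(vals < 0)) abort("uptake limits must be >= 0")
  out <- tibble(metabolite_id = names(vals) %||% character(0), max_uptake = as.numeric(vals))
  attr(out, "medium_name") <- name
  structure(out, class = c("medium", class(out)))
}

#' Read a medium from YAML or TSV
#'
#' YAML: a map of metabolite id to maximal uptake flux. TSV: columns
#' `metabolite_id` and `max_uptake`.
#'
#' @param path File path.
#' @return A [medium()].
#' @export
read_medium <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    medium(unlist(raw), name = sub("\\.[^.]*$", "", basename(path)))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    medium(setNames(df$max_uptake, df$metabolite_id),
      name = sub("\\.[^.]*$", "", basename(path)))
  }
}

#' Apply a medium to a model's exchange bounds
#'
#' Sets each exchange reaction's lower bound to minus the medium's uptake
#' limit for its metabolite (0 when the metabolite is not in the medium);
#' secretion (upper) bounds are left unchanged. Medium entries without a
#' matching exchange reaction produce a warning and are ignored.
#'
#' @param model A `strain_model`.
#' @param med A [medium()].
#' @return The model with updated exchange bounds.
#' @export
apply_medium <- function(model, med) {
  rxns <- model$reactions
  ex_idx <- which(rxns$is_exchange)
  ex_met <- map_chr(rxns$stoichiometry[ex_idx], names)
  uptake <- setNames(med$max_uptake, med$metabolite_id)
  unmatched <- setdiff(med$metabolite_id, ex_met)
  if (length(unmatched) > 0) {
    warn(paste0(
      "medium names metabolites with no exchange reaction in ", model$strain_id,
      ": ", paste(unmatched, collapse = ", ")
    ))
  }
  new_lb <- ifelse(ex_met %in% names(uptake), -uptake[ex_met], 0)
  rxns$lb[ex_idx] <- as.numeric(new_lb)
  model$reactions <- rxns
  model
}
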