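#' Flux balance analysis
#'
#' Maximizes the biomass reaction flux subject to steady-state mass balance
#' (`S v = 0`) and flux bounds. Growth is declared when the optimal biomass
#' flux reaches `1e-6` (the package-wide growth threshold).
#'
#' @param model A [strain_model()] (or a community model; see
#'   [community_fba()] for the multi-member objectives).
#' @param med Optional [medium()]; when supplied, exchange bounds are set
#'   with [apply_medium()] before solving.
#' @param objective Reaction id to maximize; defaults to the model's biomass
#'   reaction.
#' @return A `flux_solution`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `objective_value`, `fluxes` (named vector) and
#'   `residual` (max steady-state violation).
#' @examples
#' m <- example_chain_model()
#' fba(m, medium(A_e = 5))$objective_value # 5
#' @export
fba <- function(model, med = NULL, objective = NULL) {
  if (!is.null(med)) model <- apply_medium(model, med)
  S <- stoich_matrix(model)
  rxns <- model$reactions
  obj <- as.numeric(rxns$id == (objective %||% model$biomass_reaction_id))
  if (sum(obj) != 1) abort("objective must name exactly one reaction")
  fit <- solve_lp(
    obj,
    Aeq = S, beq = rep(0, nrow(S)),
    lb = rxns$lb, ub = rxns$ub, maximize = TRUE
  )
  fluxes <- setNames(fit$solution, rxns$id)
  residual <- if (fit$status == "optimal") max(abs(S %*% fit$solution)) else NA_real_
  structure(
    list(
      status = fit$status,
      objective_value = fit$objective,
      fluxes = fluxes,
      residual = residual
    ),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status = %s, objective = %s\n",
    x$status, format(x$objective_value)))
  invisible(x)
}

#' Did a flux solution reach the growth threshold?
#'
#' @param solution A `flux_solution`.
#' @param threshold Growth threshold (default 1e-6).
#' @return Logical.
#' @export
grows <- function(solution, threshold = 1e-6) {
  solution$status == "optimal" && solution$objective_value >= threshold
}

#' Build a universal reaction database for gapfilling
#'
#' @param reactions Reaction tibble (same columns as in [strain_model()]).
#' @param penalty Per-reaction gapfill penalties (> 0), recycled; default 1.
#' @param metabolites Optional metabolite tibble for metabolites not present
#'   in the models being gapfilled (compartment inferred from a trailing
#'   `_e` when absent).
#' @return A `universal_reaction_db`.
#' @export
universal_reaction_db <- function(reactions, penalty = 1, metabolites = NULL) {
  reactions <- as_tibble(reactions)
  if (!"is_exchange" %in% names(reactions)) reactions$is_exchange <- FALSE
  if (!"is_biomass" %in% names(reactions)) reactions$is_biomass <- FALSE
  reactions$penalty <- rep_len(penalty, nrow(reactions))
  if (any(reactions$penalty <= 0)) abort("gapfill penalties must be > 0")
  structure(
    list(reactions = reactions, metabolites = metabolites),
    class = "universal_reaction_db"
  )
}

#' Exact minimum-penalty gapfilling
#'
#' Finds the cheapest subset of database reactions whose addition lets the
#' model grow on the medium. The search is exact: subsets are enumerated in
#' order of total penalty (ties by lexicographic reaction-id order) and the
#' first growing subset is returned, so the result is a certified
#' minimum-penalty repair. Intended for the curated small universal
#' databases used in consortium design (up to 16 reactions).
#'
#' @param model A `strain_model` that fails to grow on `med`.
#' @param med A [medium()].
#' @param db A [universal_reaction_db()] whose reaction ids are disjoint
#'   from the model's.
#' @param growth_threshold Growth threshold (default 1e-6).
#' @return A list with `status` (`"gapfilled"`, `"already_growing"` or
#'   `"infeasible"`), `added` (reaction ids), `penalty`, `model` (augmented)
#'   and `best_objective` (largest growth seen, as an infeasibility
#'   certificate).
#' @export
gapfill <- function(model, med, db, growth_threshold = 1e-6) {
  rxns <- db$reactions
  if (nrow(rxns) == 0) abort("universal reaction database is empty")
  if (nrow(rxns) > 16) {
    abort("exact gapfilling supports databases of up to 16 reactions")
  }
  clash <- intersect(rxns$id, model$reactions$id)
  if (length(clash) > 0) {
    abort(paste0("database ids clash with the model: ", paste(clash, collapse = ", ")))
  }
  base <- fba(model, med)
  if (grows(base, growth_threshold)) {
    return(list(
      status = "already_growing", added = character(0), penalty = 0,
      model = model, best_objective = base$objective_value
    ))
  }
  ord <- order(rxns$id)
  rxns <- rxns[ord, ]
  n <- nrow(rxns)
  masks <- seq_len(2^n) - 1L
  members <- map(masks, function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  penalties <- map_dbl(members, function(idx) sum(rxns$penalty[idx]))
  lex_key <- map_chr(members, function(idx) paste(rxns$id[idx], collapse = "\x01"))
  ordering <- order(penalties, lex_key)
  best_obj <- base$objective_value
  for (k in ordering) {
    idx <- members[[k]]
    if (length(idx) == 0) next
    aug <- add_reactions(model, rxns[idx, ], db$metabolites)
    sol <- fba(aug, med)
    if (sol$status == "optimal") best_obj <- max(best_obj, sol$objective_value)
    if (grows(sol, growth_threshold)) {
      return(list(
        status = "gapfilled", added = rxns$id[idx],
        penalty = penalties[[k]], model = aug,
        best_objective = sol$objective_value
      ))
    }
  }
  list(
    status = "infeasible", added = character(0), penalty = NA_real_,
    model = model, best_objective = best_obj
  )
}

# Add reactions (and any metabolites they need) to a model.
add_reactions <- function(model, new_rxns, extra_mets = NULL) {
  needed <- unique(unlist(map(new_rxns$stoichiometry, names)))
  missing <- setdiff(needed, model$metabolites$id)
  if (length(missing) > 0) {
    if (!is.null(extra_mets)) {
      extra <- as_tibble(extra_mets)
      found <- extra[extra$id %in% missing, ]
    } else {
      found <- tibble(id = character(0))
    }
    rest <- setdiff(missing, found$id)
    inferred <- tibble(
      id = rest, name = rest,
      compartment = ifelse(grepl("_e$", rest), "extracellular", "cytosol")
    )
    model$metabolites <- bind_rows(model$metabolites, found, inferred)
  }
  keep <- c("id", "stoichiometry", "lb", "ub", "is_exchange", "is_biomass")
  model$reactions <- bind_rows(model$reactions, new_rxns[, keep])
  validate_model(model)
}

#' Detect auxotrophies by single-omission growth tests
#'
#' For each probe compound, growth is tested on the complete medium with
#' that compound withheld: a strain is auxotrophic for the compound when it
#' grows on the complete medium but not without the compound. Producibility
#' is probed independently by attaching a temporary demand (sink) reaction
#' for the compound and maximizing its flux on the same withheld medium: a
#' compound the strain can make from the remaining nutrients is `produced`.
#'
#' @param model A `strain_model` that grows on `complete_medium`.
#' @param complete_medium A [medium()] supplying every probe compound.
#' @param probe_compounds Character vector of extracellular metabolite ids
#'   to probe (defaults to every compound in the medium). Probe the
#'   biosynthetic targets of interest (amino acids, vitamins, co-factors):
#'   probing the sole carbon source trivially reports it as required.
#' @param growth_threshold Growth threshold (default 1e-6).
#' @return An `auxotrophy_profile` tibble with columns `strain_id`,
#'   `compound`, `probed`, `auxotrophic`, `producible`
#'   (`"produced"`/`"not_produced"`/`NA` when not probed).
#' @export
detect_auxotrophies <- function(model, complete_medium,
                                probe_compounds = complete_medium$metabolite_id,
                                growth_threshold = 1e-6) {
  base <- fba(model, complete_medium)
  if (!grows(base, growth_threshold)) {
    abort("model does not grow on the complete medium; auxotrophy probing is undefined")
  }
  ext_ids <- model$metabolites$id[model$metabolites$compartment == "extracellular"]
  rows <- map(probe_compounds, function(cmp) {
    if (!cmp %in% model$metabolites$id) {
      return(tibble(
        strain_id = model$strain_id, compound = cmp, probed = FALSE,
        auxotrophic = NA, producible = NA_character_
      ))
    }
    med_minus <- complete_medium[complete_medium$metabolite_id != cmp, ]
    g <- fba(model, med_minus)
    auxo <- !grows(g, growth_threshold)
    # demand on the cytosolic form when the model has one, else the
    # extracellular metabolite itself
    target <- sub("_e$", "", cmp)
    if (!target %in% model$metabolites$id) target <- cmp
    dm <- tibble(
      id = paste0("DM_", target),
      stoichiometry = list(setNames(-1, target)),
      lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = FALSE
    )
    with_dm <- add_reactions(model, dm)
    prod <- fba(with_dm, med_minus, objective = dm$id)
    tibble(
      strain_id = model$strain_id, compound = cmp, probed = TRUE,
      auxotrophic = auxo,
      producible = if (grows(prod, 1e-6)) "produced" else "not_produced"
    )
  })
  out <- bind_rows(rows)
  structure(out, class = c("auxotrophy_profile", class(out)))
}

#' Compounds a strain can secrete on a medium
#'
#' Maximizes each exchange reaction's secretion flux on the medium; a
#' compound is secretable when the maximum is above `1e-6`. Cross-feeding in
#' a consortium requires export, so complementation in the designer is
#' defined through this set, not mere intracellular producibility.
#'
#' @param model A `strain_model`.
#' @param med A [medium()].
#' @return Character vector of extracellular metabolite ids.
#' @export
secretable_compounds <- function(model, med) {
  model <- apply_medium(model, med)
  ex_idx <- which(model$reactions$is_exchange)
  ex_met <- map_chr(model$reactions$stoichiometry[ex_idx], names)
  ok <- map_lgl(seq_along(ex_idx), function(k) {
    sol <- fba(model, objective = model$reactions$id[ex_idx[[k]]])
    grows(sol, 1e-6)
  })
  ex_met[ok]
}
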