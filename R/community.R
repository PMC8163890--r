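#' Merge strain models into a community model
#'
#' Builds a compartmentalized community model around a shared extracellular
#' pool: every member metabolite and reaction is prefixed `<strain_id>__`,
#' each member's former exchange reaction becomes a member-to-pool transfer
#' (bounds -1000/+1000, positive flux = secretion into the pool), the pool
#' holds the union of the members' extracellular metabolites, and
#' environment exchange reactions on the pool carry the medium bounds. Only
#' transfers connect a member to the pool; pool exchanges are the only
#' environment boundary.
#'
#' @param models List of [strain_model()]s with unique strain ids.
#' @param med A [medium()] applied to the pool's environment exchanges.
#' @return A `community_model`: list with `members`, `metabolites`,
#'   `reactions`, `biomass_reaction_ids` (named by member) and
#'   `pool_metabolites`.
#' @export
merge_models <- function(models, med = medium()) {
  if (length(models) < 1) abort("at least one model is required")
  ids <- map_chr(models, "strain_id")
  if (anyDuplicated(ids)) abort("duplicate strain_ids in community merge")

  pool_mets <- character(0)
  met_rows <- list()
  rxn_rows <- list()
  biomass_ids <- character(0)

  for (m in models) {
    pre <- function(x) paste0(m$strain_id, "__", x)
    mets <- m$metabolites
    mets$id <- pre(mets$id)
    met_rows[[length(met_rows) + 1L]] <- mets
    rxns <- m$reactions
    ex_idx <- which(rxns$is_exchange)
    ex_met <- map_chr(rxns$stoichiometry[ex_idx], names)
    pool_mets <- union(pool_mets, ex_met)
    new_rxns <- rxns
    new_rxns$id <- pre(rxns$id)
    new_rxns$stoichiometry <- map(rxns$stoichiometry, function(s) {
      setNames(as.numeric(s), pre(names(s)))
    })
    # former exchanges become member <-> pool transfers:
    #   member_met -> pool_met, positive = secretion
    for (k in seq_along(ex_idx)) {
      j <- ex_idx[[k]]
      new_rxns$id[[j]] <- pre(paste0("TR_", ex_met[[k]]))
      new_rxns$stoichiometry[[j]] <- setNames(
        c(-1, 1), c(pre(ex_met[[k]]), ex_met[[k]])
      )
      new_rxns$lb[[j]] <- -1000
      new_rxns$ub[[j]] <- 1000
      new_rxns$is_exchange[[j]] <- FALSE
    }
    rxn_rows[[length(rxn_rows) + 1L]] <- new_rxns
    biomass_ids[[m$strain_id]] <- pre(m$biomass_reaction_id)
  }

  pool_met_tbl <- tibble(id = pool_mets, name = pool_mets, compartment = "extracellular")
  uptake <- setNames(med$max_uptake, med$metabolite_id)
  pool_ex <- tibble(
    id = paste0("EX_", pool_mets),
    stoichiometry = map(pool_mets, function(p) setNames(-1, p)),
    lb = as.numeric(ifelse(pool_mets %in% names(uptake), -uptake[pool_mets], 0)),
    ub = 1000,
    is_exchange = TRUE, is_biomass = FALSE
  )
  structure(
    list(
      members = ids,
      metabolites = bind_rows(c(met_rows, list(pool_met_tbl))),
      reactions = bind_rows(c(rxn_rows, list(pool_ex))),
      biomass_reaction_ids = biomass_ids,
      pool_metabolites = pool_mets
    ),
    class = "community_model"
  )
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf(
    "<community_model> %d members (%s), %d pool metabolites, %d reactions\n",
    length(x$members), paste(x$members, collapse = ", "),
    length(x$pool_metabolites), nrow(x$reactions)
  ))
  invisible(x)
}

#' Community flux balance analysis
#'
#' Solves community-level FBA under one of two objectives. `max_total`
#' maximizes the summed member biomass fluxes. `max_min` (the default)
#' maximizes an auxiliary lower bound `t` with every member biomass at
#' least `t`; it is the objective that matches the design claim that *all*
#' members of a consortium grow, rather than a few members growing at the
#' expense of the rest. Both are subject to community-wide steady state
#' (members and pool) and bounds.
#'
#' @param community A `community_model` from [merge_models()].
#' @param scheme `"max_min"` or `"max_total"`.
#' @return A `community_solution`: list with `status`, `scheme`,
#'   `objective_value` (`t` under max_min, the sum under max_total),
#'   `member_growth` (named vector), `fluxes`, and `pool_exchange` /
#'   `transfers` tibbles.
#' @export
community_fba <- function(community, scheme = c("max_min", "max_total")) {
  scheme <- match.arg(scheme)
  S <- stoich_matrix(community)
  rxns <- community$reactions
  n <- nrow(rxns)
  bio_idx <- match(community$biomass_reaction_ids, rxns$id)

  if (scheme == "max_total") {
    obj <- numeric(n)
    obj[bio_idx] <- 1
    fit <- solve_lp(obj,
      Aeq = S, beq = rep(0, nrow(S)),
      lb = rxns$lb, ub = rxns$ub
    )
    v <- fit$solution
  } else {
    # augment with t: maximize t s.t. biomass_k - t >= 0 for every member
    obj <- c(numeric(n), 1)
    Aeq <- cbind(S, 0)
    Aub <- matrix(0, nrow = length(bio_idx), ncol = n + 1)
    for (k in seq_along(bio_idx)) {
      Aub[k, bio_idx[[k]]] <- -1
      Aub[k, n + 1] <- 1
    }
    fit <- solve_lp(obj,
      Aeq = Aeq, beq = rep(0, nrow(S)),
      Aub = Aub, bub = rep(0, length(bio_idx)),
      lb = c(rxns$lb, 0), ub = c(rxns$ub, 1000)
    )
    v <- fit$solution[seq_len(n)]
  }

  fluxes <- setNames(v, rxns$id)
  member_growth <- setNames(fluxes[bio_idx], community$members)
  transfers <- community_transfers(community, fluxes)
  ex_idx <- which(rxns$is_exchange)
  pool_exchange <- tibble(
    metabolite_id = map_chr(rxns$stoichiometry[ex_idx], names),
    flux = as.numeric(fluxes[ex_idx])
  )
  structure(
    list(
      status = fit$status,
      scheme = scheme,
      objective_value = fit$objective,
      member_growth = member_growth,
      fluxes = fluxes,
      transfers = transfers,
      pool_exchange = pool_exchange,
      diagnostic = if (fit$status != "optimal") {
        "community steady state infeasible under the given bounds"
      } else {
        NULL
      }
    ),
    class = "community_solution"
  )
}

#' @export
print.community_solution <- function(x, ...) {
  cat(sprintf("<community_solution> scheme = %s, status = %s\n", x$scheme, x$status))
  if (x$status == "optimal") {
    growth <- paste(sprintf("%s = %.4g", names(x$member_growth), x$member_growth),
      collapse = ", ")
    cat("  member growth:", growth, "\n")
  }
  invisible(x)
}

# Member <-> pool transfer fluxes at a solution (positive = secretion).
community_transfers <- function(community, fluxes) {
  rxns <- community$reactions
  tr <- grepl("__TR_", rxns$id)
  ids <- rxns$id[tr]
  parts <- stringr::str_match(ids, "^(.*)__TR_(.*)$")
  tibble(
    member = parts[, 2],
    metabolite_id = parts[, 3],
    flux = as.numeric(fluxes[ids])
  )
}

#' Strain interaction table
#'
#' Summarizes who feeds whom at a community optimum. The secretion/uptake
#' matrix records each member's net transfer flux per pool metabolite
#' (positive = secretion). Dependency edges `(consumer, producer,
#' metabolite)` are established by pairwise removal: the consumer's maximal
#' growth drops below the threshold when the producer is removed from the
#' community, and the metabolite is one the producer secretes and the
#' consumer takes up in the supporting solution.
#'
#' @param community A `community_model`.
#' @param solution An optimal `community_solution` for it.
#' @param models The member [strain_model()]s (to rebuild communities with
#'   one member removed).
#' @param med The [medium()] used.
#' @param growth_threshold Growth threshold (default 1e-6).
#' @return An `interaction_table`: list of two tibbles, `exchanges`
#'   (member, metabolite_id, flux, direction) and `dependencies`
#'   (consumer, producer, metabolite_id).
#' @export
strain_interaction_table <- function(community, solution, models, med,
                                     growth_threshold = 1e-6) {
  if (solution$status != "optimal") {
    abort("interaction table requires an optimal community solution")
  }
  tr <- solution$transfers
  exchanges <- tr |>
    filter(abs(.data$flux) > 1e-9) |>
    mutate(direction = ifelse(.data$flux > 0, "secretion", "uptake"))

  ids <- community$members
  # maximal attainable growth of each member in the full community
  full_max <- map_dbl(ids, function(i) max_member_growth(community, i))
  deps <- list()
  if (length(ids) > 1) {
    for (j in ids) {
      keep <- models[map_chr(models, "strain_id") != j]
      sub <- merge_models(keep, med)
      for (i in setdiff(ids, j)) {
        gi_without <- max_member_growth(sub, i)
        if (gi_without < growth_threshold && full_max[[match(i, ids)]] >= growth_threshold) {
          secreted <- tr$metabolite_id[tr$member == j & tr$flux > 1e-9]
          consumed <- tr$metabolite_id[tr$member == i & tr$flux < -1e-9]
          mets <- intersect(secreted, consumed)
          if (length(mets) > 0) {
            deps[[length(deps) + 1L]] <- tibble(
              consumer = i, producer = j, metabolite_id = mets
            )
          }
        }
      }
    }
  }
  dependencies <- bind_rows(deps)
  if (nrow(dependencies) == 0) {
    dependencies <- tibble(
      consumer = character(0), producer = character(0), metabolite_id = character(0)
    )
  }
  structure(
    list(exchanges = exchanges, dependencies = dependencies),
    class = "interaction_table"
  )
}

# Max attainable biomass of one member inside a community model.
max_member_growth <- function(community, member) {
  S <- stoich_matrix(community)
  rxns <- community$reactions
  obj <- as.numeric(rxns$id == community$biomass_reaction_ids[[member]])
  fit <- solve_lp(obj,
    Aeq = S, beq = rep(0, nrow(S)),
    lb = rxns$lb, ub = rxns$ub
  )
  if (fit$status == "optimal") fit$objective else 0
}

#' Single-strain dropout analysis
#'
#' Removes each member in turn, re-solves community FBA on the remaining
#' members, and reports their growth, whether the consortium collapses (any
#' remaining member below the growth threshold), and which required
#' functions lose their last carrier.
#'
#' @param models List of member [strain_model()]s.
#' @param med The [medium()].
#' @param profile Optional `function_profile` over the same strains.
#' @param required Character vector of required function ids (used with
#'   `profile` to report functions lost).
#' @param scheme Community objective passed to [community_fba()].
#' @param growth_threshold Growth threshold (default 1e-6).
#' @return A `dropout_report` tibble: one row per removed member with
#'   columns `removed`, `remaining_growth` (list of named vectors),
#'   `min_growth`, `collapse`, `functions_lost` (list).
#' @export
dropout_analysis <- function(models, med, profile = NULL, required = character(0),
                             scheme = "max_min", growth_threshold = 1e-6) {
  ids <- map_chr(models, "strain_id")
  pm <- if (!is.null(profile)) profile_matrix(profile) else NULL
  rows <- map(ids, function(j) {
    keep <- models[ids != j]
    if (length(keep) == 0) {
      return(tibble(
        removed = j, remaining_growth = list(setNames(numeric(0), character(0))),
        min_growth = NA_real_, collapse = NA,
        functions_lost = list(character(0))
      ))
    }
    sol <- community_fba(merge_models(keep, med), scheme = scheme)
    growth <- if (sol$status == "optimal") sol$member_growth else
      setNames(rep(0, length(keep)), map_chr(keep, "strain_id"))
    lost <- character(0)
    if (!is.null(pm) && length(required) > 0) {
      remaining <- setdiff(rownames(pm), j)
      covered <- colSums(pm[remaining, required, drop = FALSE]) > 0
      lost <- required[!covered]
    }
    tibble(
      removed = j, remaining_growth = list(growth),
      min_growth = min(growth), collapse = any(growth < growth_threshold),
      functions_lost = list(lost)
    )
  })
  out <- bind_rows(rows)
  structure(out, class = c("dropout_report", class(out)))
}
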