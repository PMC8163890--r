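#' Selection constraints for consortium design
#'
#' Encodes the design rules used for rational LBP consortia: per-function
#' redundancy targets (each required function carried by at least `r_f`
#' members, so no single strain is a point of failure), auxotrophy
#' complementarity (each member's required compounds secretable by at least
#' `k` co-members, creating the interdependence that prevents any strain
#' from outcompeting the rest), exclusion screening, size bounds, and an
#' optional community-viability check.
#'
#' @param required_functions Named integer vector (`function_id` -> r_f), or
#'   a character vector of function ids which all get `redundancy`.
#' @param redundancy Default redundancy target for unnamed required
#'   functions (default 2, the "improved redundancy" standard for headline
#'   functions).
#' @param k Complementarity degree (default 1).
#' @param forbid_flagged Drop strains with exclusion flags (default TRUE).
#' @param size_min,size_max Bounds on consortium size.
#' @param med Working [medium()] for model-based checks.
#' @param require_community_growth Require community max-min growth above
#'   the growth threshold (default FALSE; needs member models).
#' @return A `selection_constraints` list.
#' @export
selection_constraints <- function(required_functions = character(0),
                                  redundancy = 2, k = 1,
                                  forbid_flagged = TRUE,
                                  size_min = 0, size_max = Inf,
                                  med = medium(),
                                  require_community_growth = FALSE) {
  if (is.character(required_functions)) {
    required_functions <- setNames(
      rep(as.integer(redundancy), length(required_functions)), required_functions
    )
  }
  required_functions <- unlist(required_functions) %||% setNames(integer(0), character(0))
  if (length(required_functions) > 0 && any(required_functions < 1)) {
    abort("redundancy targets must be >= 1")
  }
  if (k < 0) abort("complementarity degree k must be >= 0")
  if (size_min > size_max) abort("size_min must be <= size_max")
  structure(
    list(
      required_functions = required_functions, k = k,
      forbid_flagged = forbid_flagged,
      size_min = size_min, size_max = size_max,
      med = med, require_community_growth = require_community_growth
    ),
    class = "selection_constraints"
  )
}

#' Assemble a candidate set
#'
#' Joins the per-strain records the designer needs: function calls,
#' auxotrophies, exclusion flags, and (when models are given) the compounds
#' each strain can secrete on the working medium.
#'
#' @param profile A `function_profile` covering the candidate strains.
#' @param auxotrophies Optional `auxotrophy_profile` (or a bound row set of
#'   them) over the same strains.
#' @param exclusions Optional `exclusion_report` rows for flagged strains.
#' @param models Optional named list of [strain_model()]s.
#' @param med Working [medium()] used to compute secretable compounds.
#' @return A `candidate_set` tibble: `strain_id`, `functions` (list),
#'   `auxotrophies` (list), `secretes` (list), `flagged`, `model` (list).
#' @export
candidate_set <- function(profile, auxotrophies = NULL, exclusions = NULL,
                          models = NULL, med = medium()) {
  strains <- unique(profile$strain_id)
  fns <- map(strains, function(s) {
    profile$function_id[profile$strain_id == s & profile$present]
  })
  auxo <- map(strains, function(s) {
    if (is.null(auxotrophies)) return(character(0))
    sub <- auxotrophies[auxotrophies$strain_id == s & !is.na(auxotrophies$auxotrophic), ]
    sub$compound[sub$auxotrophic]
  })
  flagged <- map_lgl(strains, function(s) {
    !is.null(exclusions) && s %in% exclusions$strain_id
  })
  model_list <- map(strains, function(s) {
    if (is.null(models)) NULL else models[[s]]
  })
  secretes <- map(model_list, function(m) {
    if (is.null(m)) character(0) else secretable_compounds(m, med)
  })
  out <- tibble(
    strain_id = strains, functions = fns, auxotrophies = auxo,
    secretes = secretes, flagged = flagged, model = model_list
  )
  out <- arrange(out, .data$strain_id)
  structure(out, class = c("candidate_set", class(out)))
}

# Constraint evaluation shared by the selector, the exhaustive oracle and
# verify_consortium. Purely combinatorial checks; the community-viability
# stage is run separately by the callers that enable it.
check_design <- function(selected, candidates, constraints) {
  sel <- candidates[candidates$strain_id %in% selected, ]
  req <- constraints$required_functions
  coverage <- tibble(
    function_id = names(req),
    target = as.integer(req),
    count = map_int(names(req), function(f) {
      sum(map_lgl(sel$functions, function(fs) f %in% fs))
    })
  )
  unmet_pairs <- list()
  if (constraints$k > 0 && nrow(sel) > 0) {
    for (i in seq_len(nrow(sel))) {
      for (cmp in sel$auxotrophies[[i]]) {
        others <- sel[-i, ]
        n_prod <- sum(map_lgl(others$secretes, function(sc) cmp %in% sc))
        if (n_prod < constraints$k) {
          unmet_pairs[[length(unmet_pairs) + 1L]] <- tibble(
            strain_id = sel$strain_id[[i]], compound = cmp, n_producers = n_prod
          )
        }
      }
    }
  }
  uncomplemented <- bind_rows(unmet_pairs)
  if (nrow(uncomplemented) == 0) {
    uncomplemented <- tibble(
      strain_id = character(0), compound = character(0), n_producers = integer(0)
    )
  }
  flagged_selected <- sel$strain_id[sel$flagged]
  ok <- all(coverage$count >= coverage$target) &&
    nrow(uncomplemented) == 0 &&
    (!constraints$forbid_flagged || length(flagged_selected) == 0) &&
    nrow(sel) >= constraints$size_min && nrow(sel) <= constraints$size_max
  list(
    ok = ok, coverage = coverage, uncomplemented = uncomplemented,
    flagged_selected = flagged_selected, size = nrow(sel)
  )
}

#' Select a consortium by greedy multicover with repair and prune
#'
#' The selection procedure is a deterministic staged heuristic over the
#' candidate pool (candidates are processed in sorted strain-id order):
#' flagged strains are dropped, then strains whose auxotrophies cannot be
#' complemented by `k` secretors anywhere in the remaining pool (no feasible
#' selection can ever contain them — the exclusion iterates to a fixpoint);
#' a greedy set-multicover loop adds the strain
#' covering the most unmet (function, redundancy) demand (ties: fewer own
#' auxotrophies, then lexicographic id); a repair loop adds secreting
#' strains until every member's auxotrophies are complemented by at least
#' `k` co-members; and a reverse-order prune removes any strain whose
#' removal preserves all constraints. With `require_community_growth`, a
#' final community max-min FBA must clear the growth threshold.
#'
#' @param candidates A [candidate_set()].
#' @param constraints A [selection_constraints()].
#' @param seed Integer recorded in the trace (the procedure itself is
#'   deterministic).
#' @return A `consortium_design`: list with `selected`, `status`
#'   (`"feasible"`/`"infeasible"`), `verification` (a
#'   [verify_consortium()] report for feasible designs), `trace` (tibble of
#'   stage actions), `seed` and `diagnostic`.
#' @export
select_consortium <- function(candidates, constraints, seed = 1L) {
  if (nrow(candidates) == 0) abort("candidate set is empty")
  candidates <- arrange(as_tibble(candidates), .data$strain_id)
  trace <- list()
  note <- function(stage, action, strain = NA_character_) {
    trace[[length(trace) + 1L]] <<- tibble(stage = stage, action = action, strain_id = strain)
  }

  pool <- candidates
  if (constraints$forbid_flagged) {
    for (s in pool$strain_id[pool$flagged]) note("filter", "dropped_flagged", s)
    pool <- pool[!pool$flagged, ]
  }

  # viability filter: a strain whose auxotrophic compound has fewer than k
  # secretors among the other remaining candidates can never satisfy
  # complementarity in any selection, so it is excluded up front; iterate
  # to a fixpoint because exclusions can strand other strains
  if (constraints$k > 0) {
    repeat {
      viable <- map_lgl(seq_len(nrow(pool)), function(i) {
        all(map_lgl(pool$auxotrophies[[i]], function(cmp) {
          sum(map_lgl(pool$secretes[-i], function(sc) cmp %in% sc)) >= constraints$k
        }))
      })
      if (all(viable)) break
      for (s in pool$strain_id[!viable]) note("filter", "dropped_unviable", s)
      pool <- pool[viable, ]
      if (nrow(pool) == 0) break
    }
  }

  infeasible <- function(diag) {
    structure(
      list(
        selected = character(0), status = "infeasible", verification = NULL,
        trace = bind_rows(trace), seed = as.integer(seed), diagnostic = diag
      ),
      class = "consortium_design"
    )
  }

  req <- constraints$required_functions
  producers <- map_int(names(req), function(f) {
    sum(map_lgl(pool$functions, function(fs) f %in% fs))
  })
  short <- names(req)[producers < req]
  if (length(short) > 0) {
    return(infeasible(paste0(
      "unsatisfiable redundancy for: ", paste(short, collapse = ", ")
    )))
  }

  # Stage 2: greedy set-multicover on (function, redundancy) demand
  selected <- character(0)
  unmet <- req
  n_auxo <- setNames(map_int(pool$auxotrophies, length), pool$strain_id)
  repeat {
    if (length(unmet) == 0 || all(unmet <= 0)) break
    open <- setdiff(pool$strain_id, selected)
    if (length(open) == 0) break
    gain <- map_int(open, function(s) {
      fs <- pool$functions[[match(s, pool$strain_id)]]
      sum(unmet[intersect(names(unmet)[unmet > 0], fs)] > 0)
    })
    if (max(gain) == 0) break
    best <- open[gain == max(gain)]
    best <- best[order(n_auxo[best], best)][[1]]
    selected <- c(selected, best)
    note("greedy", "added", best)
    fs <- pool$functions[[match(best, pool$strain_id)]]
    hit <- intersect(names(unmet), fs)
    unmet[hit] <- unmet[hit] - 1L
  }

  # Stage 3: repair complementarity
  if (constraints$k > 0) {
    repeat {
      chk <- check_design(selected, pool, constraints)
      needs <- chk$uncomplemented
      if (nrow(needs) == 0) break
      open <- setdiff(pool$strain_id, selected)
      fills <- map_int(open, function(s) {
        sc <- pool$secretes[[match(s, pool$strain_id)]]
        sum(needs$compound %in% sc)
      })
      if (length(open) == 0 || max(fills) == 0) {
        return(infeasible(paste0(
          "uncomplemented auxotrophies: ",
          paste(unique(paste0(needs$strain_id, ":", needs$compound)), collapse = ", ")
        )))
      }
      best <- open[fills == max(fills)]
      best <- best[order(n_auxo[best], best)][[1]]
      selected <- c(selected, best)
      note("repair", "added", best)
    }
  }

  # Stage 4: prune in reverse addition order
  for (s in rev(selected)) {
    rest <- setdiff(selected, s)
    if (check_design(rest, pool, constraints)$ok) {
      selected <- rest
      note("prune", "removed", s)
    }
  }

  if (length(selected) < constraints$size_min) {
    padding <- setdiff(pool$strain_id, selected)
    while (length(selected) < constraints$size_min && length(padding) > 0) {
      selected <- c(selected, padding[[1]])
      note("pad", "added", padding[[1]])
      padding <- padding[-1]
    }
  }
  chk <- check_design(selected, pool, constraints)
  if (!chk$ok) {
    return(infeasible("constraints not satisfiable by greedy selection"))
  }

  # Stage 5: community viability
  if (constraints$require_community_growth) {
    models <- pool$model[match(selected, pool$strain_id)]
    if (any(map_lgl(models, is.null))) {
      return(infeasible("community growth required but models are missing"))
    }
    sol <- community_fba(merge_models(models, constraints$med), scheme = "max_min")
    if (sol$status != "optimal" || sol$objective_value < 1e-6) {
      return(infeasible(paste0(
        "community max-min growth below threshold (",
        format(sol$objective_value), ")"
      )))
    }
    note("viability", "community_growth_ok")
  }

  verification <- verify_consortium(selected, candidates, constraints)
  structure(
    list(
      selected = sort(selected), status = "feasible",
      verification = verification, trace = bind_rows(trace),
      seed = as.integer(seed), diagnostic = NULL
    ),
    class = "consortium_design"
  )
}

#' @export
print.consortium_design <- function(x, ...) {
  cat(sprintf("<consortium_design> status = %s, %d strains\n",
    x$status, length(x$selected)))
  if (length(x$selected) > 0) cat(" ", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$diagnostic)) cat("  diagnostic:", x$diagnostic, "\n")
  invisible(x)
}

#' Verify a consortium against the selection constraints
#'
#' Recomputes every constraint from scratch for an externally supplied
#' strain list: per-function coverage against the redundancy targets,
#' per-member auxotrophy complementation against `k`, exclusion compliance,
#' optionally community max-min growth, and — when every redundancy target
#' is at least 2 — dropout robustness (no single removal uncovers a
#' required function).
#'
#' @param selected Character vector of strain ids.
#' @param candidates A [candidate_set()] containing them.
#' @param constraints A [selection_constraints()].
#' @return A `verification_report`: list with `passes`, `coverage`,
#'   `uncomplemented`, `flagged_selected`, `community_growth`,
#'   `dropout_robust`, `checks` (named logical vector).
#' @export
verify_consortium <- function(selected, candidates, constraints) {
  unknown <- setdiff(selected, candidates$strain_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown strain_id: ", paste(unknown, collapse = ", ")))
  }
  chk <- check_design(selected, candidates, constraints)
  checks <- c(
    coverage = all(chk$coverage$count >= chk$coverage$target),
    complementarity = nrow(chk$uncomplemented) == 0,
    exclusion = !constraints$forbid_flagged || length(chk$flagged_selected) == 0,
    size = chk$size >= constraints$size_min && chk$size <= constraints$size_max
  )
  community_growth <- NA_real_
  if (constraints$require_community_growth) {
    models <- candidates$model[match(selected, candidates$strain_id)]
    if (any(map_lgl(models, is.null))) {
      checks[["community_growth"]] <- FALSE
    } else {
      sol <- community_fba(merge_models(models, constraints$med), scheme = "max_min")
      community_growth <- if (sol$status == "optimal") sol$objective_value else 0
      checks[["community_growth"]] <- community_growth >= 1e-6
    }
  }
  dropout_robust <- NA
  req <- constraints$required_functions
  if (length(req) > 0 && all(req >= 2)) {
    sel <- candidates[candidates$strain_id %in% selected, ]
    dropout_robust <- all(map_lgl(selected, function(s) {
      rest <- sel[sel$strain_id != s, ]
      all(map_lgl(names(req), function(f) {
        any(map_lgl(rest$functions, function(fs) f %in% fs))
      }))
    }))
    checks[["dropout_robust"]] <- dropout_robust
  }
  structure(
    list(
      passes = all(checks), checks = checks,
      coverage = chk$coverage, uncomplemented = chk$uncomplemented,
      flagged_selected = chk$flagged_selected,
      community_growth = community_growth, dropout_robust = dropout_robust,
      selected = sort(selected)
    ),
    class = "verification_report"
  )
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> passes = %s\n", x$passes))
  status <- ifelse(x$checks, "ok", "FAIL")
  for (nm in names(x$checks)) cat(sprintf("  %-18s %s\n", nm, status[[nm]]))
  invisible(x)
}

#' Exhaustive minimum-cardinality consortium selection
#'
#' Enumerates all candidate subsets in order of size (ties by lexicographic
#' strain-id vector) and returns the first feasible one — the certified
#' optimum. Used as the oracle against which the greedy selector is
#' validated; limited to 15 candidates.
#'
#' @inheritParams select_consortium
#' @return A `consortium_design` with the optimal `selected` set, or
#'   status `"infeasible"`.
#' @export
exhaustive_select <- function(candidates, constraints) {
  candidates <- arrange(as_tibble(candidates), .data$strain_id)
  if (nrow(candidates) > 15) abort("exhaustive selection supports up to 15 candidates")
  pool <- if (constraints$forbid_flagged) candidates[!candidates$flagged, ] else candidates
  ids <- pool$strain_id
  sizes <- seq(max(0, constraints$size_min), min(length(ids), constraints$size_max))
  for (sz in sizes) {
    subsets <- if (sz == 0) list(character(0)) else {
      combos <- combn(ids, sz, simplify = FALSE)
      combos[order(map_chr(combos, paste, collapse = "\x01"))]
    }
    for (sel in subsets) {
      chk <- check_design(sel, pool, constraints)
      if (!chk$ok) next
      if (constraints$require_community_growth) {
        models <- pool$model[match(sel, pool$strain_id)]
        if (any(map_lgl(models, is.null))) next
        sol <- community_fba(merge_models(models, constraints$med), scheme = "max_min")
        if (sol$status != "optimal" || sol$objective_value < 1e-6) next
      }
      return(structure(
        list(
          selected = sel, status = "feasible",
          verification = verify_consortium(sel, candidates, constraints),
          trace = tibble(stage = "exhaustive", action = "optimal", strain_id = NA_character_),
          seed = NA_integer_, diagnostic = NULL
        ),
        class = "consortium_design"
      ))
    }
  }
  structure(
    list(
      selected = character(0), status = "infeasible", verification = NULL,
      trace = tibble(stage = "exhaustive", action = "infeasible", strain_id = NA_character_),
      seed = NA_integer_, diagnostic = "no feasible subset"
    ),
    class = "consortium_design"
  )
}
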