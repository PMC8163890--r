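#' Specify a synthetic strain universe
#'
#' A universe spec fixes the structural and statistical properties of a
#' generated strain collection: a shared-substrate core metabolism, one
#' two-step biosynthesis chain per essential compound, planted auxotrophies
#' (deleted chains) whose complementarity is guaranteed by construction,
#' annotation tables carrying marker terms for planted functions, and random
#' genome sequences. It stands in for the curated genome/model collections
#' used in real LBP design, so every pipeline stage can be tested against
#' known ground truth.
#'
#' @param n_strains Number of strains (default 20).
#' @param n_compounds Number of essential compounds with biosynthesis
#'   chains (default 6; forced to `n_strains` under the cyclic plan).
#' @param n_functions Number of catalog functions planted (default 6, taken
#'   from the head of [default_function_catalog()]).
#' @param auxotrophy_rate Per (strain, compound) deletion probability under
#'   the random plan (default 0.15).
#' @param plan `"cyclic"` (strain i auxotrophic exactly for compound i,
#'   producible by its neighbours — singletons fail, the full cycle grows)
#'   or `"random"` (independent deletions repaired so every auxotrophy has
#'   at least one producer among the other strains).
#' @param function_rate Per (strain, function) planting probability
#'   (default 0.5).
#' @param genome_length Length of each random genome (default 20000).
#' @param seed Integer seed; all universe randomness flows from it.
#' @return A `universe_spec` list.
#' @export
universe_spec <- function(n_strains = 20, n_compounds = 6, n_functions = 6,
                          auxotrophy_rate = 0.15,
                          plan = c("cyclic", "random"),
                          function_rate = 0.5,
                          genome_length = 20000, seed = 1L) {
  plan <- match.arg(plan)
  if (n_strains < 1 || n_compounds < 1) abort("counts must be >= 1")
  if (auxotrophy_rate < 0 || auxotrophy_rate > 1) abort("auxotrophy_rate must be in [0, 1]")
  if (plan == "cyclic") n_compounds <- n_strains
  structure(
    list(
      n_strains = n_strains, n_compounds = n_compounds,
      n_functions = n_functions, auxotrophy_rate = auxotrophy_rate,
      plan = plan, function_rate = function_rate,
      genome_length = genome_length, seed = as.integer(seed)
    ),
    class = "universe_spec"
  )
}

#' Generate a synthetic strain universe
#'
#' Builds the strain models, annotation tables, genomes and truth labels a
#' spec describes. Each strain shares a core metabolism (substrate uptake
#' `S_e -> S`, precursor synthesis `S -> P`) and a two-reaction chain
#' `S -> I_k -> c_k` per compound; planted auxotrophies delete the chain.
#' Every strain carries a reversible transporter and an exchange for each
#' compound, so retained products are secretable and missing ones can be
#' imported — the structure behind complementary-auxotrophy cross-feeding.
#' With `verify = TRUE` (the default) the generator re-derives its own truth
#' labels through [detect_auxotrophies()] (and, for the cyclic plan, the
#' singleton-fail/community-grow property) and errors on any mismatch, so a
#' universe is never emitted with inconsistent labels.
#'
#' @param spec A [universe_spec()].
#' @param verify Re-check truth labels at generation time (default TRUE).
#' @return A `synthetic_universe`: list with `spec`, `models` (named list),
#'   `annotations` (named list of [annotation_table()]s), `genomes` (named
#'   character), `minimal_medium`, `complete_medium`, `universal_db`,
#'   `truth` (list: `auxotrophies` tibble, `functions` tibble,
#'   `feasible_consortium`).
#' @export
generate_universe <- function(spec, verify = TRUE) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  strains <- sprintf("strain_%02d", seq_len(spec$n_strains))
  compounds <- sprintf("c%02d", seq_len(spec$n_compounds))

  # planted auxotrophy matrix: TRUE = chain deleted
  auxo <- matrix(FALSE, spec$n_strains, spec$n_compounds,
    dimnames = list(strains, compounds))
  if (spec$plan == "cyclic") {
    for (i in seq_len(spec$n_strains)) auxo[i, i] <- TRUE
  } else {
    auxo[] <- runif(length(auxo)) < spec$auxotrophy_rate
    # guarantee: every compound retains at least one producer, and every
    # auxotrophy has a producer among the *other* strains
    for (k in seq_len(spec$n_compounds)) {
      if (all(auxo[, k])) auxo[sample(spec$n_strains, 1), k] <- FALSE
    }
  }

  catalog <- default_function_catalog()
  catalog <- catalog[seq_len(min(spec$n_functions, nrow(catalog))), ]
  fn_planted <- matrix(
    runif(spec$n_strains * nrow(catalog)) < spec$function_rate,
    spec$n_strains, nrow(catalog),
    dimnames = list(strains, catalog$function_id)
  )

  models <- setNames(map(seq_len(spec$n_strains), function(i) {
    build_universe_model(strains[[i]], compounds, deleted = compounds[auxo[i, ]])
  }), strains)

  annotations <- setNames(map(seq_len(spec$n_strains), function(i) {
    build_universe_annotations(strains[[i]], catalog, fn_planted[i, ])
  }), strains)

  genomes <- setNames(
    map_chr(strains, function(s) random_genome(spec$genome_length)),
    strains
  )

  minimal_medium <- medium(S_e = 10, name = "minimal")
  complete <- setNames(rep(10, spec$n_compounds + 1), c("S_e", paste0(compounds, "_e")))
  complete_medium <- medium(complete, name = "complete")

  universal_db <- universe_reaction_db(compounds)

  truth <- list(
    auxotrophies = tibble(
      strain_id = rep(strains, each = spec$n_compounds),
      compound = rep(paste0(compounds, "_e"), spec$n_strains),
      auxotrophic = as.logical(t(auxo))
    ),
    functions = tibble(
      strain_id = rep(strains, each = nrow(catalog)),
      function_id = rep(catalog$function_id, spec$n_strains),
      present = as.logical(t(fn_planted))
    ),
    feasible_consortium = strains
  )

  universe <- structure(
    list(
      spec = spec, models = models, annotations = annotations,
      genomes = genomes, minimal_medium = minimal_medium,
      complete_medium = complete_medium, universal_db = universal_db,
      truth = truth, catalog = catalog
    ),
    class = "synthetic_universe"
  )
  if (verify) verify_universe(universe)
  universe
}

# Closure check: truth labels must be reproducible from the generated
# models before a universe is handed out.
verify_universe <- function(universe) {
  truth <- universe$truth
  for (s in names(universe$models)) {
    detected <- detect_auxotrophies(
      universe$models[[s]], universe$complete_medium,
      probe_compounds = unique(truth$auxotrophies$compound)
    )
    want <- truth$auxotrophies[truth$auxotrophies$strain_id == s, ]
    merged <- left_join(want, as_tibble(detected),
      by = c("strain_id", "compound"), suffix = c("_truth", "_detected"))
    if (!all(merged$auxotrophic_truth == merged$auxotrophic_detected)) {
      abort(paste0("generated universe failed auxotrophy verification for ", s))
    }
  }
  if (universe$spec$plan == "cyclic" && universe$spec$n_strains > 1) {
    singleton_growth <- map_dbl(universe$models, function(m) {
      fba(m, universe$minimal_medium)$objective_value
    })
    if (any(singleton_growth >= 1e-6)) {
      abort("cyclic universe: some singleton grows on the minimal medium")
    }
    sol <- community_fba(
      merge_models(unname(universe$models), universe$minimal_medium),
      scheme = "max_min"
    )
    if (sol$status != "optimal" || sol$objective_value < 1e-6) {
      abort("cyclic universe: full community does not grow on the minimal medium")
    }
  }
  invisible(universe)
}

# One strain's model: core S_e -> S -> P, a two-step chain per retained
# compound, a reversible transporter + exchange per compound, and a biomass
# consuming P plus every compound.
build_universe_model <- function(strain_id, compounds, deleted = character(0)) {
  retained <- setdiff(compounds, deleted)
  mets <- bind_rows(
    tibble(id = c("S_e", "S", "P"), name = c("substrate (ext)", "substrate", "precursor"),
      compartment = c("extracellular", "cytosol", "cytosol")),
    tibble(id = compounds, name = compounds, compartment = "cytosol"),
    tibble(id = paste0(compounds, "_e"), name = paste0(compounds, " (ext)"),
      compartment = "extracellular"),
    tibble(id = paste0("I_", retained), name = paste0("intermediate ", retained),
      compartment = "cytosol")
  )
  core <- tibble(
    id = c("EX_S", "T_S", "CORE"),
    stoichiometry = list(
      c(S_e = -1), c(S_e = -1, S = 1), c(S = -1, P = 1)
    ),
    lb = c(0, 0, 0), ub = 1000,
    is_exchange = c(TRUE, FALSE, FALSE), is_biomass = FALSE
  )
  chains <- bind_rows(map(retained, function(k) {
    ik <- paste0("I_", k)
    tibble(
      id = paste0(c("SYN1_", "SYN2_"), k),
      stoichiometry = list(
        setNames(c(-1, 1), c("S", ik)),
        setNames(c(-1, 1), c(ik, k))
      ),
      lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = FALSE
    )
  }))
  transporters <- bind_rows(map(compounds, function(k) {
    tibble(
      id = c(paste0("T_", k), paste0("EX_", k)),
      stoichiometry = list(
        setNames(c(-1, 1), c(paste0(k, "_e"), k)),
        setNames(-1, paste0(k, "_e"))
      ),
      lb = c(-1000, 0), ub = 1000,
      is_exchange = c(FALSE, TRUE), is_biomass = FALSE
    )
  }))
  biomass <- tibble(
    id = "BIOMASS",
    stoichiometry = list(setNames(rep(-1, length(compounds) + 1), c("P", compounds))),
    lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = TRUE
  )
  strain_model(strain_id, mets, bind_rows(core, chains, transporters, biomass), "BIOMASS")
}

# Universal database holding every biosynthesis chain (for gapfill tests).
universe_reaction_db <- function(compounds) {
  rxns <- bind_rows(map(compounds, function(k) {
    ik <- paste0("I_", k)
    tibble(
      id = paste0(c("U_SYN1_", "U_SYN2_"), k),
      stoichiometry = list(
        setNames(c(-1, 1), c("S", ik)),
        setNames(c(-1, 1), c(ik, k))
      ),
      lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = FALSE
    )
  }))
  universal_reaction_db(rxns, penalty = 1)
}

# Annotation table carrying one feature per marker group of each planted
# function, plus hypothetical-protein distractors.
build_universe_annotations <- function(strain_id, catalog, planted) {
  feats <- list()
  for (j in seq_len(nrow(catalog))) {
    if (!planted[[j]]) next
    for (g in seq_along(catalog$marker_groups[[j]])) {
      term <- catalog$marker_groups[[j]][[g]][[1]]
      feats[[length(feats) + 1L]] <- term
    }
  }
  n_real <- length(feats)
  n_noise <- max(3L, n_real)
  products <- c(unlist(feats) %||% character(0),
    sprintf("hypothetical protein %d", seq_len(n_noise)))
  annotation_table(
    strain_id,
    feature_id = sprintf("%s_f%03d", strain_id, seq_along(products)),
    product = products
  )
}

#' Generate a random genome sequence
#'
#' Uniform-composition random DNA, used as the neutral background for
#' ANI experiments (no gene structure is simulated).
#'
#' @param length Sequence length in bases.
#' @return A character string of A/C/G/T.
#' @export
random_genome <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Mutate a genome at a fixed substitution rate
#'
#' Substitutes each position independently with probability `divergence` to
#' a uniformly chosen different base; no indels, so the positional mismatch
#' count is an exact oracle for the planted divergence.
#'
#' @param seq Character string (or `DNAString`) to mutate.
#' @param divergence Substitution probability per site, in `[0, 0.75)`.
#' @param seed Optional integer seed for reproducible mutation.
#' @return The mutated sequence as a character string.
#' @export
mutate_genome <- function(seq, divergence, seed = NULL) {
  if (divergence < 0 || divergence >= 0.75) {
    abort("divergence must be in [0, 0.75)")
  }
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(as.character(seq), "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < divergence
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- map_chr(chars[hit], function(b) sample(setdiff(bases, b), 1))
  }
  paste(chars, collapse = "")
}

#' Simulate a Ct table from a known composition
#'
#' The forward model of comparative-Ct quantification: each strain's Ct is
#' `-log2(abundance) + scale` plus Gaussian noise; zero-abundance strains
#' fall below the detection limit (missing Ct). With zero noise,
#' [composition_from_ct()] inverts this exactly.
#'
#' @param composition Long tibble with columns `sample_id`, `strain_id`,
#'   `abundance` (fractions summing to 1 per sample).
#' @param scale Ct offset in cycles (default 20).
#' @param noise_sd Gaussian Ct noise in cycles (default 0).
#' @param seed Optional integer seed.
#' @return A long Ct tibble with columns `sample_id`, `target_id`, `ct`.
#' @export
simulate_ct <- function(composition, scale = 20, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  composition <- as_tibble(composition)
  ct <- ifelse(
    composition$abundance > 0,
    -log2(composition$abundance) + scale +
      rnorm(nrow(composition), 0, noise_sd),
    NA_real_
  )
  tibble(
    sample_id = composition$sample_id,
    target_id = composition$strain_id,
    ct = ct
  )
}

#' A minimal linear-chain toy model
#'
#' Substrate uptake (exchange `EX_A`), transport `A_e -> A`, conversion
#' `A -> B`, and a biomass reaction consuming `B`. On `medium(A_e = 5)` the
#' optimal biomass flux is 5, the uptake bottleneck.
#'
#' @param biomass_ub Upper bound on the biomass reaction (default 1000).
#' @return A [strain_model()].
#' @export
example_chain_model <- function(biomass_ub = 1000) {
  strain_model(
    "chain_toy",
    metabolites = tibble(
      id = c("A_e", "A", "B"), name = c("A (ext)", "A", "B"),
      compartment = c("extracellular", "cytosol", "cytosol")
    ),
    reactions = tibble(
      id = c("EX_A", "T_A", "A_to_B", "BIOMASS"),
      stoichiometry = list(
        c(A_e = -1), c(A_e = -1, A = 1), c(A = -1, B = 1), c(B = -1)
      ),
      lb = 0, ub = c(1000, 1000, 1000, biomass_ub),
      is_exchange = c(TRUE, FALSE, FALSE, FALSE),
      is_biomass = c(FALSE, FALSE, FALSE, TRUE)
    ),
    biomass_reaction_id = "BIOMASS"
  )
}
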