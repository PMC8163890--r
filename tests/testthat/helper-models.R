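# Toy models and pools built in code for the tests.

# Two-strain obligate cross-feeding pair: each member's biomass consumes
# one unit of the shared substrate A plus one unit of the partner-made
# compound; making the own compound costs one A. With pool A supply 10 the
# community max-min growth is 2.5 per member (2 g1 + 2 g2 <= 10 at g1 = g2)
# and each singleton grows 0.
cross_feeding_member <- function(strain_id, makes, needs) {
  mets <- tibble::tibble(
    id = c("A_e", "A", makes, needs, paste0(makes, "_e"), paste0(needs, "_e")),
    name = c("A_e", "A", makes, needs, paste0(makes, "_e"), paste0(needs, "_e")),
    compartment = c("extracellular", "cytosol", "cytosol", "cytosol",
      "extracellular", "extracellular")
  )
  rxns <- tibble::tibble(
    id = c("EX_A", "T_A", paste0("SYN_", makes),
      paste0("T_", makes), paste0("EX_", makes),
      paste0("T_", needs), paste0("EX_", needs), "BIOMASS"),
    stoichiometry = list(
      c(A_e = -1),
      c(A_e = -1, A = 1),
      stats::setNames(c(-1, 1), c("A", makes)),
      stats::setNames(c(-1, 1), c(paste0(makes, "_e"), makes)),
      stats::setNames(-1, paste0(makes, "_e")),
      stats::setNames(c(-1, 1), c(paste0(needs, "_e"), needs)),
      stats::setNames(-1, paste0(needs, "_e")),
      stats::setNames(c(-1, -1), c("A", needs))
    ),
    lb = c(0, 0, 0, -1000, 0, -1000, 0, 0),
    ub = 1000,
    is_exchange = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    is_biomass = c(rep(FALSE, 7), TRUE)
  )
  strain_model(strain_id, mets, rxns, "BIOMASS")
}

cross_feeding_pair <- function() {
  list(
    cross_feeding_member("alpha", makes = "x", needs = "y"),
    cross_feeding_member("beta", makes = "y", needs = "x")
  )
}

# Self-sufficient member on substrate A (no partner requirement).
prototroph_member <- function(strain_id) {
  strain_model(
    strain_id,
    metabolites = tibble::tibble(
      id = c("A_e", "A"), name = c("A_e", "A"),
      compartment = c("extracellular", "cytosol")
    ),
    reactions = tibble::tibble(
      id = c("EX_A", "T_A", "BIOMASS"),
      stoichiometry = list(c(A_e = -1), c(A_e = -1, A = 1), c(A = -1)),
      lb = 0, ub = 1000,
      is_exchange = c(TRUE, FALSE, FALSE),
      is_biomass = c(FALSE, FALSE, TRUE)
    ),
    biomass_reaction_id = "BIOMASS"
  )
}

# Branched toy used for the FBA oracle battery: two routes to biomass with
# different capacities.
branched_toy <- function() {
  strain_model(
    "branched_toy",
    metabolites = tibble::tibble(
      id = c("A_e", "A", "B", "C"), name = c("A_e", "A", "B", "C"),
      compartment = c("extracellular", "cytosol", "cytosol", "cytosol")
    ),
    reactions = tibble::tibble(
      id = c("EX_A", "T_A", "A_to_B", "A_to_C", "B_to_C", "BIOMASS"),
      stoichiometry = list(
        c(A_e = -1), c(A_e = -1, A = 1), c(A = -1, B = 1),
        c(A = -1, C = 1), c(B = -1, C = 1), c(C = -1)
      ),
      lb = 0, ub = c(1000, 1000, 3, 2, 1000, 1000),
      is_exchange = c(TRUE, rep(FALSE, 5)),
      is_biomass = c(rep(FALSE, 5), TRUE)
    ),
    biomass_reaction_id = "BIOMASS"
  )
}

# A hand-built candidate pool with a planted unique minimum feasible
# consortium {c1, c2, c3, c4} under required functions f1..f4 (r = 1) and
# complementarity k = 1: the four planted strains form a chain of
# complemented auxotrophies (m1 -> m2 -> m3); c5 carries every function
# but is exclusion-flagged; c6 has an auxotrophy nobody can feed.
planted_pool <- function() {
  tib <- tibble::tibble(
    strain_id = paste0("c", 1:6),
    functions = list(
      "f1", "f2", "f3", "f4",
      c("f1", "f2", "f3", "f4"), "f1"
    ),
    auxotrophies = list(
      character(0), "m1", "m2", "m3",
      character(0), "m9"
    ),
    secretes = list(
      "m1", "m2", "m3", character(0),
      character(0), character(0)
    ),
    flagged = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    model = vector("list", 6)
  )
  structure(tib, class = c("candidate_set", class(tib)))
}

# Random candidate pools for the selector-vs-oracle property: functions,
# auxotrophies and secretions drawn at random; no metabolic models.
random_pool <- function(n_candidates, n_functions = 4, n_compounds = 3) {
  fns <- paste0("f", seq_len(n_functions))
  cmp <- paste0("m", seq_len(n_compounds))
  tib <- tibble::tibble(
    strain_id = sprintf("s%02d", seq_len(n_candidates)),
    functions = lapply(seq_len(n_candidates), function(i) {
      fns[stats::runif(n_functions) < 0.5]
    }),
    auxotrophies = lapply(seq_len(n_candidates), function(i) {
      cmp[stats::runif(n_compounds) < 0.25]
    }),
    secretes = lapply(seq_len(n_candidates), function(i) {
      cmp[stats::runif(n_compounds) < 0.5]
    }),
    flagged = stats::runif(n_candidates) < 0.1,
    model = vector("list", n_candidates)
  )
  structure(tib, class = c("candidate_set", class(tib)))
}
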