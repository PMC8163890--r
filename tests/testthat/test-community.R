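test_that("a singleton community reproduces the individual FBA objective", {
  m <- example_chain_model()
  med <- medium(A_e = 5)
  solo <- fba(m, med)$objective_value
  com <- merge_models(list(m), med)
  for (scheme in c("max_min", "max_total")) {
    sol <- community_fba(com, scheme = scheme)
    expect_equal(sol$objective_value, solo, tolerance = 1e-6)
    expect_equal(unname(sol$member_growth), solo, tolerance = 1e-6)
  }
})

test_that("the pool is the union of member extracellular metabolites, namespaced apart", {
  members <- cross_feeding_pair()
  com <- merge_models(members, medium(A_e = 10))
  expect_setequal(com$pool_metabolites, c("A_e", "x_e", "y_e"))
  # member internals are prefixed and disjoint from the pool
  internal <- setdiff(com$metabolites$id, com$pool_metabolites)
  expect_true(all(grepl("^(alpha|beta)__", internal)))
  expect_error(merge_models(list(members[[1]], members[[1]])), "duplicate")
})

test_that("obligate cross-feeders fail alone but share growth 2.5 each together", {
  members <- cross_feeding_pair()
  med <- medium(A_e = 10)
  for (m in members) {
    expect_lt(fba(m, med)$objective_value, 1e-6)
  }
  sol <- community_fba(merge_models(members, med), scheme = "max_min")
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$member_growth), c(2.5, 2.5), tolerance = 1e-6)
})

test_that("every pool metabolite balances at the reported optimum", {
  members <- cross_feeding_pair()
  com <- merge_models(members, medium(A_e = 10))
  sol <- community_fba(com, scheme = "max_min")
  S <- consortia:::stoich_matrix(com)
  residual <- S %*% sol$fluxes
  expect_lte(max(abs(residual)), 1e-6)
  # pool rows specifically
  pool_rows <- residual[com$pool_metabolites, ]
  expect_lte(max(abs(pool_rows)), 1e-6)
})

test_that("max_total dominates the best individual objective", {
  set.seed(51)
  u <- generate_universe(universe_spec(
    n_strains = 4, n_compounds = 3, plan = "random",
    auxotrophy_rate = 0.3, seed = 99
  ), verify = FALSE)
  med <- u$minimal_medium
  best_solo <- max(vapply(u$models, function(m) fba(m, med)$objective_value, numeric(1)))
  sol <- community_fba(merge_models(unname(u$models), med), scheme = "max_total")
  expect_gte(sol$objective_value, best_solo - 1e-8)
})

test_that("the interaction table records reciprocal cross-feeding edges", {
  members <- cross_feeding_pair()
  med <- medium(A_e = 10)
  com <- merge_models(members, med)
  sol <- community_fba(com, scheme = "max_min")
  tab <- strain_interaction_table(com, sol, members, med)
  deps <- tab$dependencies
  expect_true(any(deps$consumer == "alpha" & deps$producer == "beta" &
    deps$metabolite_id == "y_e"))
  expect_true(any(deps$consumer == "beta" & deps$producer == "alpha" &
    deps$metabolite_id == "x_e"))
  # secretions visible in the exchange matrix
  secreted <- tab$exchanges[tab$exchanges$direction == "secretion", ]
  expect_true(all(c("x_e", "y_e") %in% secreted$metabolite_id))
})

test_that("prototroph pairs have no dependency edges", {
  members <- list(prototroph_member("p1"), prototroph_member("p2"))
  med <- medium(A_e = 10)
  com <- merge_models(members, med)
  sol <- community_fba(com, scheme = "max_min")
  tab <- strain_interaction_table(com, sol, members, med)
  expect_equal(nrow(tab$dependencies), 0)
})

test_that("a three-member feeding chain yields exactly its two edges", {
  # p1 self-sufficient, secretes m1; b needs m1, secretes m2; c needs m2
  mk <- function(id, needs, makes) {
    mets <- tibble::tibble(
      id = c("A_e", "A",
        if (!is.null(needs)) c(needs, paste0(needs, "_e")),
        if (!is.null(makes)) c(makes, paste0(makes, "_e"))),
      compartment = c("extracellular", "cytosol",
        if (!is.null(needs)) c("cytosol", "extracellular"),
        if (!is.null(makes)) c("cytosol", "extracellular"))
    )
    mets$name <- mets$id
    rxns <- tibble::tibble(
      id = "EX_A", stoichiometry = list(c(A_e = -1)),
      lb = 0, ub = 1000, is_exchange = TRUE, is_biomass = FALSE
    )
    rxns <- dplyr::bind_rows(rxns, tibble::tibble(
      id = "T_A", stoichiometry = list(c(A_e = -1, A = 1)),
      lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = FALSE
    ))
    bio <- c(A = -1)
    if (!is.null(needs)) {
      rxns <- dplyr::bind_rows(rxns, tibble::tibble(
        id = c(paste0("T_", needs), paste0("EX_", needs)),
        stoichiometry = list(
          stats::setNames(c(-1, 1), c(paste0(needs, "_e"), needs)),
          stats::setNames(-1, paste0(needs, "_e"))
        ),
        lb = c(-1000, 0), ub = 1000,
        is_exchange = c(FALSE, TRUE), is_biomass = FALSE
      ))
      bio <- c(bio, stats::setNames(-1, needs))
    }
    if (!is.null(makes)) {
      rxns <- dplyr::bind_rows(rxns, tibble::tibble(
        id = c(paste0("SYN_", makes), paste0("T_", makes), paste0("EX_", makes)),
        stoichiometry = list(
          stats::setNames(c(-1, 1), c("A", makes)),
          stats::setNames(c(-1, 1), c(paste0(makes, "_e"), makes)),
          stats::setNames(-1, paste0(makes, "_e"))
        ),
        lb = c(0, -1000, 0), ub = 1000,
        is_exchange = c(FALSE, FALSE, TRUE), is_biomass = FALSE
      ))
    }
    rxns <- dplyr::bind_rows(rxns, tibble::tibble(
      id = "BIOMASS", stoichiometry = list(bio),
      lb = 0, ub = 1000, is_exchange = FALSE, is_biomass = TRUE
    ))
    strain_model(id, mets, rxns, "BIOMASS")
  }
  chain <- list(
    mk("sA", needs = NULL, makes = "m1"),
    mk("sB", needs = "m1", makes = "m2"),
    mk("sC", needs = "m2", makes = NULL)
  )
  med <- medium(A_e = 12)
  com <- merge_models(chain, med)
  sol <- community_fba(com, scheme = "max_min")
  expect_gte(min(sol$member_growth), 1e-6)
  tab <- strain_interaction_table(com, sol, chain, med)
  deps <- unique(tab$dependencies[, c("consumer", "producer")])
  expect_true(any(deps$consumer == "sB" & deps$producer == "sA"))
  expect_true(any(deps$consumer == "sC" & deps$producer == "sB"))
  expect_false(any(deps$consumer == "sC" & deps$producer == "sA"))
})

test_that("dropout flags collapse when the sole producer is removed", {
  members <- cross_feeding_pair()
  med <- medium(A_e = 10)
  rep <- dropout_analysis(members, med)
  expect_true(all(rep$collapse))

  # one prototroph + one dependent: removing the prototroph collapses,
  # removing the dependent does not
  mixed <- list(prototroph_member("p1"), cross_feeding_member("dep", "x", "y"))
  rep2 <- dropout_analysis(mixed, med)
  expect_false(rep2$collapse[rep2$removed == "dep"])
})

test_that("functional redundancy keeps coverage through single dropouts", {
  tabs <- list(
    annotation_table("p1", "f1", "methylmalonyl-CoA decarboxylase"),
    annotation_table("p2", "f1", "propionate CoA-transferase")
  )
  prof <- profile_functions(tabs, default_function_catalog())
  members <- list(prototroph_member("p1"), prototroph_member("p2"))
  rep <- dropout_analysis(members, medium(A_e = 10), prof, required = "propionate")
  expect_true(all(lengths(rep$functions_lost) == 0))
  expect_false(any(rep$collapse))
})

test_that("singleton dropout produces a vacuous report entry", {
  rep <- dropout_analysis(list(prototroph_member("only")), medium(A_e = 5))
  expect_equal(nrow(rep), 1)
  expect_true(is.na(rep$collapse))
  expect_equal(length(rep$remaining_growth[[1]]), 0)
})
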