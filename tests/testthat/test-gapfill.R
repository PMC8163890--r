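# A chain model missing its conversion step, and a small database that
# contains it plus distractors.
broken_chain <- function() {
  strain_model(
    "broken",
    metabolites = tibble::tibble(
      id = c("A_e", "A", "B"), name = c("A_e", "A", "B"),
      compartment = c("extracellular", "cytosol", "cytosol")
    ),
    reactions = tibble::tibble(
      id = c("EX_A", "T_A", "BIOMASS"),
      stoichiometry = list(c(A_e = -1), c(A_e = -1, A = 1), c(B = -1)),
      lb = 0, ub = 1000,
      is_exchange = c(TRUE, FALSE, FALSE),
      is_biomass = c(FALSE, FALSE, TRUE)
    ),
    biomass_reaction_id = "BIOMASS"
  )
}

chain_db <- function() {
  universal_reaction_db(tibble::tibble(
    id = c("U_A_to_B", "U_A_to_C", "U_C_to_B"),
    stoichiometry = list(
      c(A = -1, B = 1), c(A = -1, C = 1), c(C = -1, B = 1)
    ),
    lb = 0, ub = 1000
  ))
}

test_that("a single missing reaction is recovered at penalty 1", {
  res <- gapfill(broken_chain(), medium(A_e = 5), chain_db())
  expect_equal(res$status, "gapfilled")
  expect_equal(res$added, "U_A_to_B")
  expect_equal(res$penalty, 1)
  expect_gte(fba(res$model, medium(A_e = 5))$objective_value, 1e-6)
})

test_that("penalties steer the repair to the cheaper route", {
  # make the direct route expensive: the two-step detour wins
  db <- universal_reaction_db(
    tibble::tibble(
      id = c("U_A_to_B", "U_A_to_C", "U_C_to_B"),
      stoichiometry = list(c(A = -1, B = 1), c(A = -1, C = 1), c(C = -1, B = 1)),
      lb = 0, ub = 1000
    ),
    penalty = c(5, 1, 1)
  )
  res <- gapfill(broken_chain(), medium(A_e = 5), db)
  expect_setequal(res$added, c("U_A_to_C", "U_C_to_B"))
  expect_equal(res$penalty, 2)
})

test_that("a growing model needs no repair and an empty route is infeasible", {
  grown <- gapfill(example_chain_model(), medium(A_e = 5), chain_db())
  expect_equal(grown$status, "already_growing")
  expect_equal(grown$added, character(0))

  dead_db <- universal_reaction_db(tibble::tibble(
    id = "U_A_to_C",
    stoichiometry = list(c(A = -1, C = 1)),
    lb = 0, ub = 1000
  ))
  res <- gapfill(broken_chain(), medium(A_e = 5), dead_db)
  expect_equal(res$status, "infeasible")
  expect_lt(res$best_objective, 1e-6)
})

test_that("returned sets are minimal: removing any reaction kills growth", {
  set.seed(31)
  u <- generate_universe(universe_spec(
    n_strains = 4, n_compounds = 6, plan = "random",
    auxotrophy_rate = 0.35, seed = 77
  ), verify = FALSE)
  db <- u$universal_db # 12 reactions
  med <- u$minimal_medium
  tested <- 0
  for (m in u$models) {
    if (grows(fba(m, med))) next
    res <- gapfill(m, med, db)
    if (res$status != "gapfilled") next
    tested <- tested + 1
    for (drop_id in res$added) {
      partial <- db$reactions[db$reactions$id %in% setdiff(res$added, drop_id), ]
      if (nrow(partial) == 0) {
        aug <- m
      } else {
        aug <- consortia:::add_reactions(m, partial, db$metabolites)
      }
      expect_lt(fba(aug, med)$objective_value, 1e-6,
        label = paste0("growth of ", m$strain_id, " without ", drop_id))
    }
  }
  expect_gte(tested, 1)
})

test_that("clashing ids and oversized databases are rejected", {
  db_clash <- universal_reaction_db(tibble::tibble(
    id = "BIOMASS", stoichiometry = list(c(A = -1)), lb = 0, ub = 1000
  ))
  expect_error(gapfill(broken_chain(), medium(A_e = 5), db_clash), "clash")

  big <- universal_reaction_db(tibble::tibble(
    id = sprintf("U_%02d", 1:17),
    stoichiometry = replicate(17, c(A = -1, B = 1), simplify = FALSE),
    lb = 0, ub = 1000
  ))
  expect_error(gapfill(broken_chain(), medium(A_e = 5), big), "16")
})
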