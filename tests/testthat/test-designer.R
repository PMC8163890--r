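planted_constraints <- function() {
  selection_constraints(
    required_functions = c(f1 = 1, f2 = 1, f3 = 1, f4 = 1),
    k = 1, forbid_flagged = TRUE
  )
}

test_that("greedy+prune and the exhaustive oracle find the planted optimum", {
  pool <- planted_pool()
  cons <- planted_constraints()
  oracle <- exhaustive_select(pool, cons)
  expect_equal(oracle$status, "feasible")
  expect_equal(oracle$selected, c("c1", "c2", "c3", "c4"))

  greedy <- select_consortium(pool, cons, seed = 1)
  expect_equal(greedy$status, "feasible")
  expect_lte(length(greedy$selected), 5)
  expect_true(greedy$verification$passes)
  expect_equal(greedy$selected, c("c1", "c2", "c3", "c4"))
})

test_that("empty requirements give an empty feasible consortium", {
  des <- select_consortium(planted_pool(), selection_constraints(k = 0))
  expect_equal(des$status, "feasible")
  expect_equal(des$selected, character(0))
})

test_that("unsatisfiable redundancy is infeasible and names the function", {
  pool <- planted_pool()
  cons <- selection_constraints(required_functions = c(f2 = 3), k = 0)
  des <- select_consortium(pool, cons)
  expect_equal(des$status, "infeasible")
  expect_match(des$diagnostic, "f2")
  expect_equal(exhaustive_select(pool, cons)$status, "infeasible")
})

test_that("verification lists uncomplemented (strain, compound) pairs", {
  pool <- planted_pool()
  cons <- planted_constraints()
  # c4 without its m3 feeder c3 violates complementarity
  rep <- verify_consortium(c("c1", "c2", "c4"), pool, cons)
  expect_false(rep$passes)
  expect_true(any(rep$uncomplemented$strain_id == "c4" &
    rep$uncomplemented$compound == "m3"))
  expect_error(verify_consortium("ghost", pool, cons), "unknown")
})

test_that("flagged strains are excluded from selection", {
  pool <- planted_pool()
  des <- select_consortium(pool, planted_constraints())
  expect_false("c5" %in% des$selected)
  # allowing flagged strains lets the single all-function carrier win
  cons_open <- selection_constraints(
    required_functions = c(f1 = 1, f2 = 1, f3 = 1, f4 = 1),
    k = 1, forbid_flagged = FALSE
  )
  expect_equal(exhaustive_select(pool, cons_open)$selected, "c5")
})

test_that("pruning is idempotent and designs verify on recomputation", {
  set.seed(61)
  for (rep in 1:10) {
    pool <- random_pool(sample(6:10, 1))
    cons <- selection_constraints(
      required_functions = c(f1 = 1, f2 = 1, f3 = 2),
      k = 1
    )
    des <- select_consortium(pool, cons, seed = rep)
    if (des$status != "feasible") next
    expect_true(verify_consortium(des$selected, pool, cons)$passes)
    # re-running the full selection is stable (prune idempotence included)
    des2 <- select_consortium(pool, cons, seed = rep)
    expect_identical(des$selected, des2$selected)
    expect_identical(des$trace, des2$trace)
    # no selected strain is removable
    for (s in des$selected) {
      expect_false(consortia:::check_design(
        setdiff(des$selected, s), pool, cons
      )$ok)
    }
  }
})

test_that("greedy is feasible whenever the oracle is, and never smaller", {
  set.seed(62)
  n_oracle_feasible <- 0
  for (rep in 1:12) {
    pool <- random_pool(sample(6:10, 1))
    cons <- selection_constraints(
      required_functions = c(f1 = 1, f2 = 1, f4 = 1),
      k = 1
    )
    oracle <- exhaustive_select(pool, cons)
    greedy <- select_consortium(pool, cons, seed = rep)
    if (oracle$status == "feasible") {
      n_oracle_feasible <- n_oracle_feasible + 1
      expect_equal(greedy$status, "feasible")
      expect_gte(length(greedy$selected), length(oracle$selected))
    }
  }
  expect_gte(n_oracle_feasible, 3)
})

test_that("tightening an infeasible constraint set stays infeasible", {
  pool <- planted_pool()
  base <- selection_constraints(required_functions = c(f2 = 3), k = 0)
  expect_equal(select_consortium(pool, base)$status, "infeasible")
  tighter <- selection_constraints(required_functions = c(f2 = 4), k = 1)
  expect_equal(select_consortium(pool, tighter)$status, "infeasible")
})

test_that("model-backed selection enforces community viability", {
  members <- cross_feeding_pair()
  med <- medium(A_e = 10)
  tabs <- list(
    annotation_table("alpha", "f1", "butyryl-CoA dehydrogenase; butyrate kinase"),
    annotation_table("beta", "f1", "tryptophanase")
  )
  prof <- profile_functions(tabs, default_function_catalog())
  auxo <- dplyr::bind_rows(
    detect_auxotrophies(members[[1]], medium(A_e = 10, y_e = 10),
      probe_compounds = c("x_e", "y_e")),
    detect_auxotrophies(members[[2]], medium(A_e = 10, x_e = 10),
      probe_compounds = c("x_e", "y_e"))
  )
  pool <- candidate_set(prof, auxotrophies = auxo,
    models = stats::setNames(members, c("alpha", "beta")), med = med)
  expect_setequal(pool$secretes[[which(pool$strain_id == "alpha")]],
    c("x_e"))
  cons <- selection_constraints(
    required_functions = c(butyrate = 1, indole = 1),
    k = 1, med = med, require_community_growth = TRUE
  )
  des <- select_consortium(pool, cons, seed = 3)
  expect_equal(des$status, "feasible")
  expect_setequal(des$selected, c("alpha", "beta"))
  expect_true(des$verification$checks[["community_growth"]])
})
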