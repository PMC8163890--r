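test_that("universe generation is deterministic and byte-identical per seed", {
  spec <- universe_spec(n_strains = 4, n_compounds = 3, plan = "random", seed = 19)
  u1 <- generate_universe(spec, verify = FALSE)
  u2 <- generate_universe(spec, verify = FALSE)
  expect_identical(serialize(u1, NULL), serialize(u2, NULL))
  u3 <- generate_universe(universe_spec(
    n_strains = 4, n_compounds = 3, plan = "random", seed = 20
  ), verify = FALSE)
  expect_false(identical(u1$genomes, u3$genomes))
})

test_that("zero auxotrophy rate yields all-prototroph universes", {
  u <- generate_universe(universe_spec(
    n_strains = 4, n_compounds = 3, plan = "random",
    auxotrophy_rate = 0, seed = 5
  ), verify = FALSE)
  expect_false(any(u$truth$auxotrophies$auxotrophic))
  for (m in u$models) {
    expect_gte(fba(m, u$minimal_medium)$objective_value, 1e-6)
  }
})

test_that("cyclic universes verify their own truth labels at generation", {
  u <- generate_universe(universe_spec(n_strains = 3, plan = "cyclic", seed = 8))
  # verification ran without error; spot-check the planted cycle
  expect_equal(sum(u$truth$auxotrophies$auxotrophic), 3)
  for (m in u$models) {
    expect_lt(fba(m, u$minimal_medium)$objective_value, 1e-6)
  }
  sol <- community_fba(merge_models(unname(u$models), u$minimal_medium))
  expect_gte(sol$objective_value, 1e-6)
})

test_that("planted annotations reproduce the planted function profile", {
  u <- generate_universe(universe_spec(
    n_strains = 6, n_compounds = 3, plan = "random", seed = 13
  ), verify = FALSE)
  prof <- profile_functions(unname(u$annotations), u$catalog)
  got <- dplyr::arrange(tibble::as_tibble(prof)[, c("strain_id", "function_id", "present")],
    strain_id, function_id)
  want <- dplyr::arrange(u$truth$functions, strain_id, function_id)
  expect_equal(got$present, want$present)
})

test_that("mutation rates are exact in expectation and bounded in spread", {
  set.seed(71)
  g <- random_genome(20000)
  expect_identical(mutate_genome(g, 0), g)
  m <- mutate_genome(g, 0.05, seed = 3)
  frac <- oracle_mismatch_fraction(g, m)
  # observed mismatches within 3 binomial standard deviations of the rate
  sd3 <- 3 * sqrt(0.05 * 0.95 / 20000)
  expect_lte(abs(frac - 0.05), sd3)
  expect_error(mutate_genome(g, 0.8), "divergence")
})

test_that("a 12% mutated pair is classified as a distinct species", {
  set.seed(72)
  g <- random_genome(10000)
  r <- compute_ani(g, mutate_genome(g, 0.12, seed = 4))
  expect_equal(classify_species_pair(r), "distinct_species")
})

test_that("pipeline recovery: profile, auxotrophy and design close the loop", {
  for (s in 1:2) {
    u <- generate_universe(universe_spec(
      n_strains = 5, n_compounds = 5, plan = "cyclic", seed = 300 + s
    ), verify = FALSE)
    prof <- profile_functions(unname(u$annotations), u$catalog)
    probes <- unique(u$truth$auxotrophies$compound)
    auxo <- dplyr::bind_rows(lapply(u$models, function(m) {
      detect_auxotrophies(m, u$complete_medium, probe_compounds = probes)
    }))
    pool <- candidate_set(prof, auxotrophies = auxo, models = u$models,
      med = u$minimal_medium)
    # require one well-covered planted function, full complementarity, and
    # community viability on the minimal medium
    counts <- redundancy_counts(prof, u$catalog$function_id)
    covered <- counts$function_id[counts$n_strains >= 1]
    cons <- selection_constraints(
      required_functions = stats::setNames(rep(1L, length(covered)), covered),
      k = 1, med = u$minimal_medium, require_community_growth = TRUE
    )
    des <- select_consortium(pool, cons, seed = s)
    expect_equal(des$status, "feasible")
    expect_true(des$verification$passes)
  }
})
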