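two_group_catalog <- function() {
  function_catalog(tibble::tibble(
    function_id = "butyrate",
    display_name = "Butyrate synthesis",
    marker_groups = list(list(
      "butyrate kinase",
      c("butyryl-CoA dehydrogenase", "butyryl-CoA transferase")
    ))
  ))
}

test_that("a function needs every marker group unless min_groups relaxes it", {
  cat <- two_group_catalog()
  kinase_only <- annotation_table("s1", "f1", "Butyrate Kinase")
  both <- annotation_table("s2", c("f1", "f2"),
    c("butyrate kinase", "butyryl-CoA dehydrogenase"))
  prof <- profile_functions(list(kinase_only, both), cat)
  expect_false(prof$present[prof$strain_id == "s1"])
  expect_true(prof$present[prof$strain_id == "s2"])

  relaxed <- cat
  relaxed$min_groups <- 1L
  prof2 <- profile_functions(kinase_only, relaxed)
  expect_true(prof2$present)
})

test_that("matching is case-insensitive substring on products and exact on term ids", {
  cat <- function_catalog(tibble::tibble(
    function_id = "indole", display_name = "Indole",
    marker_groups = list(list(c("tryptophanase", "K01667")))
  ))
  by_product <- annotation_table("sA", "f1", "TRYPTOPHANASE precursor")
  by_term <- annotation_table("sB", "f1", "uncharacterized enzyme", terms = list("K01667"))
  near_term <- annotation_table("sC", "f1", "uncharacterized enzyme", terms = list("K016670"))
  prof <- profile_functions(list(by_product, by_term, near_term), cat)
  expect_equal(prof$present, c(TRUE, TRUE, FALSE))
})

test_that("a strain with no matching terms gets an all-false row", {
  prof <- profile_functions(
    annotation_table("s1", "f1", "hypothetical protein"),
    default_function_catalog()
  )
  expect_false(any(prof$present))
  expect_true(all(lengths(prof$evidence) == 0))
})

test_that("profiles are permutation-invariant in strain order", {
  tabs <- list(
    annotation_table("sx", "f1", "butyryl-CoA dehydrogenase"),
    annotation_table("sy", c("f1", "f2"),
      c("butyrate kinase", "butyryl-CoA dehydrogenase")),
    annotation_table("sz", "f1", "tryptophanase")
  )
  cat <- default_function_catalog()
  m1 <- profile_matrix(profile_functions(tabs, cat))
  m2 <- profile_matrix(profile_functions(rev(tabs), cat))
  expect_equal(m1[sort(rownames(m1)), ], m2[sort(rownames(m2)), ])
})

test_that("recorded evidence re-matches the strain's annotations", {
  set.seed(11)
  u <- generate_universe(universe_spec(
    n_strains = 6, n_compounds = 3, plan = "random", seed = 31
  ), verify = FALSE)
  prof <- profile_functions(unname(u$annotations), u$catalog)
  hits <- prof[prof$present, ]
  for (i in seq_len(nrow(hits))) {
    tab <- u$annotations[[hits$strain_id[[i]]]]
    for (term in hits$evidence[[i]]) {
      expect_true(
        any(grepl(tolower(term), tolower(tab$product), fixed = TRUE)) ||
          any(vapply(tab$terms, function(t) term %in% t, logical(1)))
      )
    }
  }
})

test_that("redundancy counts are column sums over required functions", {
  tabs <- list(
    annotation_table("s1", "f1", "methylmalonyl-CoA decarboxylase"),
    annotation_table("s2", "f1", "propionate CoA-transferase"),
    annotation_table("s3", "f1", "propionyl-CoA synthase"),
    annotation_table("s4", "f1", "tryptophanase"),
    annotation_table("s5", "f1", "hypothetical protein")
  )
  prof <- profile_functions(tabs, default_function_catalog())
  counts <- redundancy_counts(prof, c("propionate", "indole"))
  expect_equal(counts$n_strains, c(3L, 1L))
  expect_equal(nrow(redundancy_counts(prof, character(0))), 0)
  expect_error(redundancy_counts(prof, "no_such_function"), "unknown")
})

test_that("exclusion screening flags AMR and virulence terms with feature ids", {
  dirty <- annotation_table("bad1",
    c("f1", "f2", "f3"),
    c("vanA vancomycin resistance protein", "Shiga toxin subunit A", "fragilysin precursor"))
  rep <- screen_exclusions(dirty)
  expect_true("transferable_AMR" %in% rep$category)
  expect_true("virulence_factor" %in% rep$category)
  vir <- rep[rep$category == "virulence_factor", ]
  expect_gte(length(unique(vir$feature_id)), 2)

  clean <- annotation_table("ok1", "f1", "butyrate kinase")
  expect_equal(nrow(screen_exclusions(clean)), 0)
})
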