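#' Profile strains for therapeutic functions
#'
#' Calls each catalog function present or absent in each strain by matching
#' the catalog's marker groups against the strain's annotations. A marker
#' term matches a feature when it is a case-insensitive substring of the
#' product text, or exactly equals one of the feature's term ids. A function
#' is present when at least `min_groups` of its marker groups have a match;
#' the matching terms are recorded as evidence.
#'
#' @param tables One [annotation_table()] or a list of them (one per strain),
#'   or a single long tibble with the `annotation_table` columns covering
#'   several strains.
#' @param catalog A [function_catalog()]; defaults to
#'   [default_function_catalog()].
#' @return A `function_profile`: a tibble with one row per (strain,
#'   function) with columns `strain_id`, `function_id`, `present` and
#'   `evidence` (list of matched marker terms). Strain order follows input
#'   order; function order follows the catalog.
#' @export
profile_functions <- function(tables, catalog = default_function_catalog()) {
  if (!inherits(catalog, "function_catalog") || nrow(catalog) == 0) {
    abort("catalog must be a non-empty function_catalog")
  }
  tables <- as_annotation_list(tables)
  if (length(tables) == 0) abort("at least one annotation table is required")
  rows <- map(tables, function(tab) {
    products <- tolower(tab$product)
    term_ids <- tab$terms
    match_term <- function(term) {
      grepl(tolower(term), products, fixed = TRUE) |
        map_lgl(term_ids, function(t) term %in% t)
    }
    per_function <- pmap(
      list(catalog$function_id, catalog$marker_groups, catalog$min_groups),
      function(fid, groups, min_groups) {
        group_hits <- map(groups, function(terms) {
          terms[map_lgl(terms, function(tm) any(match_term(tm)))]
        })
        n_hit <- sum(map_int(group_hits, length) > 0)
        present <- n_hit >= min_groups
        tibble(
          strain_id = tab$strain_id[[1]], function_id = fid,
          present = present,
          evidence = list(if (present) unlist(group_hits) else character(0))
        )
      }
    )
    bind_rows(per_function)
  })
  out <- bind_rows(rows)
  structure(out, class = c("function_profile", class(out)))
}

as_annotation_list <- function(tables) {
  if (inherits(tables, "annotation_table")) return(list(tables))
  if (is.data.frame(tables)) {
    split_ids <- unique(tables$strain_id)
    return(map(split_ids, function(s) {
      sub <- tables[tables$strain_id == s, ]
      annotation_table(s, sub$feature_id, sub$product, sub$terms)
    }))
  }
  if (is.list(tables)) return(tables)
  abort("tables must be annotation tables or a data frame of annotations")
}

#' Presence matrix of a function profile
#'
#' @param profile A `function_profile`.
#' @return A strain-by-function logical matrix.
#' @export
profile_matrix <- function(profile) {
  wide <- tidyr::pivot_wider(
    as_tibble(profile)[, c("strain_id", "function_id", "present")],
    names_from = "function_id", values_from = "present"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$strain_id
  m
}

#' Per-function redundancy counts
#'
#' Counts, for each required function, how many strains in the profile carry
#' it. Redundancy (two or more carriers of a key function) is what lets a
#' consortium survive the loss of a single strain.
#'
#' @param profile A `function_profile`.
#' @param required Character vector of function ids (subset of the profile's
#'   functions).
#' @return A tibble with columns `function_id` and `n_strains`.
#' @export
redundancy_counts <- function(profile, required) {
  known <- unique(profile$function_id)
  unknown <- setdiff(required, known)
  if (length(unknown) > 0) {
    abort(paste0("unknown function_id: ", paste(unknown, collapse = ", ")))
  }
  if (length(required) == 0) {
    return(tibble(function_id = character(0), n_strains = integer(0)))
  }
  counts <- as_tibble(profile) |>
    filter(.data$function_id %in% required) |>
    group_by(function_id = .data$function_id) |>
    summarise(n_strains = sum(.data$present), .groups = "drop")
  counts[match(required, counts$function_id), ]
}

#' Screen a strain for exclusion criteria
#'
#' Flags annotations matching either of two fixed categories:
#' `transferable_AMR` (mobile antibiotic-resistance determinants) and
#' `virulence_factor`. A strain with any flag is excluded from consortium
#' design when `forbid_flagged` is set in the selection constraints.
#'
#' @param table An [annotation_table()].
#' @param exclusion_catalog Named list with character vectors
#'   `transferable_AMR` and `virulence_factor`; defaults to
#'   [default_exclusion_catalog()].
#' @return An `exclusion_report` tibble with columns `strain_id`, `category`,
#'   `term`, `feature_id`; zero rows means the strain passes.
#' @export
screen_exclusions <- function(table, exclusion_catalog = default_exclusion_catalog()) {
  categories <- c("transferable_AMR", "virulence_factor")
  if (!all(categories %in% names(exclusion_catalog))) {
    abort("exclusion catalog must have categories transferable_AMR and virulence_factor")
  }
  products <- tolower(table$product)
  flags <- map(categories, function(cat) {
    hits <- map(exclusion_catalog[[cat]], function(term) {
      hit <- grepl(tolower(term), products, fixed = TRUE) |
        map_lgl(table$terms, function(t) term %in% t)
      if (!any(hit)) return(NULL)
      tibble(
        strain_id = table$strain_id[[1]], category = cat,
        term = term, feature_id = table$feature_id[hit]
      )
    })
    bind_rows(hits)
  })
  out <- bind_rows(flags)
  if (nrow(out) == 0) {
    out <- tibble(
      strain_id = character(0), category = character(0),
      term = character(0), feature_id = character(0)
    )
  }
  structure(out, class = c("exclusion_report", class(out)))
}
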