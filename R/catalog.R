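#' Build a therapeutic-function catalog
#'
#' A function catalog maps short function codes (e.g. `"butyrate"`,
#' `"dh_7a"`) to the annotation evidence that supports them. Each function is
#' defined by one or more *marker groups*: a group is a set of terms, and a
#' group is satisfied when at least one of its terms matches an annotation
#' (case-insensitive substring on the product text, or exact match on a
#' controlled-vocabulary term id). A function is called present when at least
#' `min_groups` of its groups are satisfied; by default all groups are
#' required, reflecting that a multi-step pathway needs all of its steps.
#'
#' @param functions A data frame (or tibble) with columns `function_id`,
#'   `display_name`, `marker_groups` (a list column: each element a list of
#'   character vectors, one vector per group), and optionally `min_groups`
#'   (integer; `NA` means "all groups").
#' @return A `function_catalog`: a tibble with one row per function.
#' @examples
#' function_catalog(tibble::tibble(
#'   function_id = "butyrate",
#'   display_name = "Butyrate synthesis",
#'   marker_groups = list(list(c("butyrate kinase", "butyryl-CoA:acetate CoA-transferase")))
#' ))
#' @export
function_catalog <- function(functions) {
  functions <- as_tibble(functions)
  required <- c("function_id", "display_name", "marker_groups")
  missing <- setdiff(required, names(functions))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(functions$function_id)) {
    abort("function_ids must be unique")
  }
  if (!"min_groups" %in% names(functions)) {
    functions$min_groups <- NA_integer_
  }
  functions$marker_groups <- map(functions$marker_groups, function(groups) {
    groups <- map(groups, as.character)
    if (length(groups) == 0) abort("every function needs at least one marker group")
    for (g in groups) {
      if (length(g) == 0 || any(!nzchar(g))) {
        abort("marker terms must be non-empty strings")
      }
    }
    groups
  })
  n_groups <- map_int(functions$marker_groups, length)
  functions$min_groups <- ifelse(
    is.na(functions$min_groups), n_groups, as.integer(functions$min_groups)
  )
  if (any(functions$min_groups < 1 | functions$min_groups > n_groups)) {
    abort("min_groups must be between 1 and the number of marker groups")
  }
  structure(functions, class = c("function_catalog", class(functions)))
}

#' Read a function catalog from YAML
#'
#' The YAML layout is a list of entries, each with `function_id`,
#' `display_name`, `marker_groups` (a list of lists of terms) and optional
#' `min_groups`.
#'
#' @param path Path to a YAML file.
#' @return A [function_catalog()].
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- yaml::read_yaml(path)
  function_catalog(tibble(
    function_id = map_chr(raw, "function_id"),
    display_name = map_chr(raw, "display_name"),
    marker_groups = map(raw, function(x) map(x$marker_groups, unlist)),
    min_groups = map_int(raw, function(x) {
      if (is.null(x$min_groups)) NA_integer_ else as.integer(x$min_groups)
    })
  ))
}

#' The default therapeutic-function catalog
#'
#' Encodes the therapeutic functions used for gut LBP design: SCFA synthesis
#' (butyrate, propionate), GABA and indole synthesis from tryptophan,
#' siderophore synthesis and heterologous siderophore uptake, antimicrobial
#' (bacteriocin/lantibiotic) synthesis, and the bile-acid enzyme repertoire
#' (choloylglycine hydrolase CGH, hydroxysteroid dehydrogenases 3a/3b/7a/7b,
#' 7a/7b-dehydratases, 3-oxo-5a-steroid-4-dehydrogenase, bile-acid CoA-ester
#' dehydrogenase, sodium-bile acid symporter). Marker terms are the enzyme
#' names and codes a consistently annotated genome would carry; the catalog
#' is deliberately small and term-list based, not an HMM library.
#'
#' @return A [function_catalog()].
#' @export
default_function_catalog <- function() {
  read_catalog(system.file("extdata", "function_catalog.yaml",
    package = "consortia", mustWork = TRUE
  ))
}

#' The default exclusion-screening term lists
#'
#' Two fixed categories are screened: `transferable_AMR` (mobile antibiotic
#' resistance determinants, e.g. vanA-type vancomycin resistance) and
#' `virulence_factor` (e.g. enterotoxins, Shiga toxin). Term lists are small
#' shipped defaults and can be replaced by the caller.
#'
#' @return A named list of two character vectors, `transferable_AMR` and
#'   `virulence_factor`.
#' @export
default_exclusion_catalog <- function() {
  raw <- yaml::read_yaml(system.file("extdata", "exclusion_terms.yaml",
    package = "consortia", mustWork = TRUE
  ))
  list(
    transferable_AMR = unlist(raw$transferable_AMR),
    virulence_factor = unlist(raw$virulence_factor)
  )
}
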