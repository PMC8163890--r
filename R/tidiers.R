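#' Tidy a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble with columns `reaction_id`, `flux`.
#' @export
tidy.flux_solution <- function(x, ...) {
  tibble(reaction_id = names(x$fluxes), flux = as.numeric(x$fluxes))
}

#' @rdname tidy.flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble(
    status = x$status, objective_value = x$objective_value,
    residual = x$residual, n_reactions = length(x$fluxes)
  )
}

#' Tidy a community solution
#'
#' @param x A `community_solution`.
#' @param ... Unused.
#' @return Tibble with columns `member`, `growth`.
#' @export
tidy.community_solution <- function(x, ...) {
  tibble(member = names(x$member_growth), growth = as.numeric(x$member_growth))
}

#' @rdname tidy.community_solution
#' @export
glance.community_solution <- function(x, ...) {
  tibble(
    status = x$status, scheme = x$scheme,
    objective_value = x$objective_value,
    min_growth = if (length(x$member_growth)) min(x$member_growth) else NA_real_,
    n_members = length(x$member_growth)
  )
}

#' Tidy a consortium design
#'
#' @param x A `consortium_design`.
#' @param ... Unused.
#' @return Tibble with one row per selected strain.
#' @export
tidy.consortium_design <- function(x, ...) {
  tibble(strain_id = x$selected)
}

#' @rdname tidy.consortium_design
#' @export
glance.consortium_design <- function(x, ...) {
  tibble(
    status = x$status, n_selected = length(x$selected),
    passes_verification = if (is.null(x$verification)) NA else x$verification$passes,
    seed = x$seed
  )
}

#' Tidy a verification report
#'
#' @param x A `verification_report`.
#' @param ... Unused.
#' @return Tibble with one row per check.
#' @export
tidy.verification_report <- function(x, ...) {
  tibble(check = names(x$checks), passed = as.logical(x$checks))
}

#' @rdname tidy.verification_report
#' @export
glance.verification_report <- function(x, ...) {
  tibble(passes = x$passes, n_selected = length(x$selected))
}
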