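#' Plot a function profile as a presence/absence tile map
#'
#' @param object A `function_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.function_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$function_id, y = .data$strain_id, fill = .data$present
  )) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey95")) +
    ggplot2::labs(x = "therapeutic function", y = NULL, fill = "present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-member growth of a community solution
#'
#' @param object A `community_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.community_solution <- function(object, ...) {
  df <- tidy.community_solution(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$member, y = .data$growth)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = 1e-6, linetype = "dashed", color = "red") +
    ggplot2::labs(
      x = NULL, y = "biomass flux (mmol/gDW/h)",
      title = paste0("community growth (", object$scheme, ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a strain-interaction exchange table
#'
#' Secretion (positive) and uptake (negative) transfer fluxes per member
#' and pool metabolite at a community optimum.
#'
#' @param object An `interaction_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interaction_table <- function(object, ...) {
  df <- object$exchanges
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$metabolite_id, y = .data$member, fill = .data$flux
  )) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac") +
    ggplot2::labs(x = "pool metabolite", y = NULL,
      fill = "flux\n(+ = secretion)") +
    ggplot2::theme_minimal()
}
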