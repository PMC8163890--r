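#' Community composition from qPCR Ct values
#'
#' Implements the comparative-Ct quantification used with strain-specific
#' single-copy gene primers: each detected target's weight is
#' `efficiency^(-Ct)` (doubling per cycle at the default efficiency of 2),
#' weights are normalized within each sample to relative abundances.
#' Targets below the detection limit (missing Ct, `NA`) get abundance 0; a
#' sample with no detected target at all is flagged.
#'
#' @param ct A Ct table: data frame with a `sample_id` column and one
#'   numeric column per target (Ct cycles, `NA` = below detection), or a
#'   long tibble with columns `sample_id`, `target_id`, `ct`.
#' @param efficiency Amplification factor per cycle (default 2).
#' @return A `composition_table`: long tibble with columns `sample_id`,
#'   `strain_id`, `abundance`, plus a `no_detection` attribute listing
#'   samples where nothing amplified.
#' @examples
#' composition_from_ct(tibble::tibble(sample_id = "s1", a = 10, b = 11))
#' @export
composition_from_ct <- function(ct, efficiency = 2) {
  long <- as_ct_long(ct)
  if (any(!is.na(long$ct) & long$ct <= 0)) abort("Ct values must be > 0")
  out <- long |>
    group_by(.data$sample_id) |>
    mutate(
      weight = ifelse(is.na(.data$ct), 0, efficiency^(-.data$ct)),
      abundance = if (sum(.data$weight) > 0) .data$weight / sum(.data$weight) else 0
    ) |>
    ungroup() |>
    select("sample_id", strain_id = "target_id", "abundance")
  none <- out |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$abundance), .groups = "drop")
  no_detection <- none$sample_id[none$total == 0]
  if (length(no_detection) > 0) {
    warn(paste0("no detection in sample(s): ", paste(no_detection, collapse = ", ")))
  }
  attr(out, "no_detection") <- no_detection
  structure(out, class = c("composition_table", class(out)))
}

as_ct_long <- function(ct) {
  ct <- as_tibble(ct)
  if (all(c("sample_id", "target_id", "ct") %in% names(ct))) {
    return(ct[, c("sample_id", "target_id", "ct")])
  }
  if (!"sample_id" %in% names(ct)) abort("Ct table needs a sample_id column")
  tidyr::pivot_longer(ct, -"sample_id", names_to = "target_id", values_to = "ct")
}

#' Expression fold change by the delta-delta-Ct method
#'
#' Computes `efficiency^-((Ct_target_case - Ct_ref_case) -
#' (Ct_target_ctrl - Ct_ref_ctrl))`: the fold change of a target
#' transcript in a case sample relative to a control sample, each
#' normalized against a reference gene. A target amplifying one cycle
#' earlier in the case (reference unchanged) doubles, giving fold change 2.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Ct values
#'   (cycles); vectors are recycled.
#' @param efficiency Amplification factor per cycle (default 2).
#' @return Numeric fold change(s).
#' @examples
#' fold_change_ddct(19, 15, 20, 15) # 2
#' @export
fold_change_ddct <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl, efficiency = 2) {
  inputs <- list(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(map_lgl(inputs, function(x) any(is.na(x)) || length(x) == 0))) {
    abort("all four Ct values are required")
  }
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  efficiency^(-ddct)
}
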