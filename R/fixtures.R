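#' Load a packaged consortium fixture
#'
#' Ships the published strain-by-function overviews of the two rationally
#' designed gut consortia as machine-readable candidate sets: `"gut103"`
#' (17 publicly available strains) and `"gut108"` (the optimized 11-strain
#' consortium). Bile-acid enzyme codes (CGH, 3a/3b/7a/7b-HSD, 7a/7b-DH,
#' 3a-DH, 3-oxo-5a, LCD, SBS) are expanded into per-enzyme function ids
#' plus the aggregate `bile_salt`; siderophore synthesis/uptake fold into
#' the aggregate `siderophore`. Strain and family names are preserved
#' verbatim. The fixtures carry function profiles only — no metabolic
#' models — so model-dependent checks (complementarity, community growth)
#' are disabled when verifying them.
#'
#' @param name `"gut103"` or `"gut108"`.
#' @return A [candidate_set()] (with empty model slots) whose rows carry
#'   additional columns `family` and `genome_id`.
#' @examples
#' nrow(load_fixture("gut103")) # 17
#' @export
load_fixture <- function(name = c("gut103", "gut108")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_functions.tsv"),
    package = "consortia", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
    quote = "", check.names = FALSE)
  flag_cols <- c("butyrate", "propionate", "gaba", "indole",
    "siderophore_synthesis", "siderophore_uptake", "antimicrobial")
  fns <- map(seq_len(nrow(df)), function(i) {
    present <- flag_cols[as.logical(unlist(df[i, flag_cols]))]
    codes <- unlist(strsplit(df$bile_codes[[i]] %||% "", ";", fixed = TRUE))
    codes <- setdiff(trimws(codes[nzchar(codes)]), "taurine_uptake")
    out <- c(present, codes)
    if (any(c("siderophore_synthesis", "siderophore_uptake") %in% out)) {
      out <- c(out, "siderophore")
    }
    if (length(codes) > 0 || nzchar(df$bile_codes[[i]] %||% "")) {
      out <- c(out, "bile_salt")
    }
    unique(out)
  })
  out <- tibble(
    strain_id = df$strain,
    functions = fns,
    auxotrophies = rep(list(character(0)), nrow(df)),
    secretes = rep(list(character(0)), nrow(df)),
    flagged = FALSE,
    model = rep(list(NULL), nrow(df)),
    family = df$family,
    genome_id = as.character(df$genome_id)
  )
  out <- arrange(out, .data$strain_id)
  structure(out, class = c("candidate_set", class(out)))
}
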