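#' Build an annotation table
#'
#' An annotation table holds one strain's gene-product annotations: one row
#' per feature, the free-text product, and optional controlled-vocabulary
#' term ids. It is the input surrogate for a consistently annotated genome.
#'
#' @param strain_id Strain identifier.
#' @param feature_id Character vector of unique feature ids.
#' @param product Character vector of product descriptions (may be `""` only
#'   when the corresponding `terms` entry is non-empty).
#' @param terms Optional list of character vectors of term ids (one per
#'   feature); defaults to empty.
#' @return An `annotation_table` tibble with columns `strain_id`,
#'   `feature_id`, `product`, `terms`.
#' @export
annotation_table <- function(strain_id, feature_id, product, terms = NULL) {
  feature_id <- as.character(feature_id)
  product <- as.character(product)
  if (length(feature_id) != length(product)) {
    abort("feature_id and product must have the same length")
  }
  if (anyDuplicated(feature_id)) {
    dup <- unique(feature_id[duplicated(feature_id)])
    abort(paste0("duplicate feature_id: ", paste(dup, collapse = ", ")))
  }
  if (is.null(terms)) terms <- rep(list(character(0)), length(feature_id))
  terms <- map(terms, as.character)
  empty_both <- !nzchar(product) & map_int(terms, length) == 0
  if (any(empty_both)) {
    abort(paste0(
      "features with empty product and no terms: ",
      paste(feature_id[empty_both], collapse = ", ")
    ))
  }
  out <- tibble(
    strain_id = strain_id, feature_id = feature_id,
    product = product, terms = terms
  )
  structure(out, class = c("annotation_table", class(out)))
}

#' Load a strain annotation table from TSV or GFF3
#'
#' The TSV format has columns `feature_id`, `product` and `terms`
#' (comma-separated term ids, may be empty). GFF3 files are scanned for CDS
#' features carrying a `product=` attribute; `Dbxref`/`Ontology_term`
#' attributes populate the term ids.
#'
#' @param path File path.
#' @param strain_id Strain identifier to attach; defaults to the file name
#'   without extension.
#' @param format `"tsv"` or `"gff3"`; guessed from the extension by default.
#' @return An [annotation_table()].
#' @export
load_annotation_table <- function(path, strain_id = NULL,
                                  format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(strain_id)) {
    strain_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 1) abort("empty annotation file")
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    idx <- match(c("feature_id", "product", "terms"), header)
    if (any(is.na(idx[1:2]))) {
      abort("TSV must have columns feature_id and product (and optionally terms)")
    }
    body <- lines[-1]
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(map_int(fields, length) < 2)
    if (length(bad) > 0) {
      abort(paste0("malformed row at line ", bad[[1]] + 1L, " of ", path))
    }
    get_col <- function(i) map_chr(fields, function(f) if (!is.na(i) && length(f) >= i) f[[i]] else "")
    terms <- strsplit(get_col(idx[3]), ",", fixed = TRUE)
    terms <- map(terms, function(x) trimws(x[nzchar(trimws(x))]))
    annotation_table(strain_id, get_col(idx[1]), get_col(idx[2]), terms)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(map_int(fields, length) != 9)
    if (length(bad) > 0) {
      abort(paste0("malformed GFF3 row at line ", bad[[1]], " of ", path))
    }
    is_cds <- map_chr(fields, 3) == "CDS"
    fields <- fields[is_cds]
    attr_str <- map_chr(fields, 9)
    parse_attr <- function(s) {
      kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      setNames(
        map_chr(kv, function(p) if (length(p) >= 2) utils::URLdecode(p[[2]]) else ""),
        map_chr(kv, 1)
      )
    }
    attrs <- map(attr_str, parse_attr)
    has_product <- map_lgl(attrs, function(a) "product" %in% names(a))
    attrs <- attrs[has_product]
    if (length(attrs) == 0) {
      abort("GFF3 contains no CDS features with a product attribute")
    }
    pick <- function(a, key) if (key %in% names(a)) a[[key]] else ""
    feature_id <- imap(attrs, function(a, i) {
      id <- pick(a, "ID")
      if (nzchar(id)) id else paste0("cds_", i)
    })
    terms <- map(attrs, function(a) {
      t <- c(pick(a, "Ontology_term"), pick(a, "Dbxref"))
      t <- unlist(strsplit(t, ",", fixed = TRUE))
      t[nzchar(t)]
    })
    annotation_table(
      strain_id, unlist(feature_id),
      map_chr(attrs, "product"), terms
    )
  }
}
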