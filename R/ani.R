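#' Fragment-based average nucleotide identity
#'
#' Computes ANI between two genomes in the fragment-based style used for
#' whole-genome species delimitation: the query is cut into consecutive
#' non-overlapping fragments of `fragment_length` (trailing remainders are
#' dropped; multi-record inputs are fragmented per record, never
#' concatenated), each fragment is placed in the subject by exact-seeded
#' search and aligned with a global-local alignment over a window of
#' `band` extra bases on each side, and fragments passing the identity and
#' coverage filters contribute their identity to the directional ANI. The
#' reverse complement of each fragment is tried when the forward strand
#' finds no placement. The symmetric `ani` is the mean of the two
#' directional values.
#'
#' @param a,b Genome sequences: character strings, `Biostrings::DNAString`,
#'   `DNAStringSet`, or paths to FASTA files.
#' @param fragment_length Fragment size in bases (default 1020).
#' @param band Alignment window slack in bases on each side (default 60).
#' @param min_fragment_identity Minimum per-fragment identity to count
#'   (default 0.3).
#' @param min_fragment_coverage Minimum fraction of the fragment aligned
#'   (default 0.7).
#' @return An `ani_result`: a one-row tibble with `genome_a`, `genome_b`,
#'   `ani`, `aligned_fraction`, `fragment_count`, the per-direction values
#'   (`ani_ab`, `ani_ba`, `coverage_ab`, `coverage_ba`) and `flagged`
#'   (`TRUE` when no fragment passed in either direction, leaving `ani`
#'   undefined).
#' @examples
#' g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
#' compute_ani(g, g, fragment_length = 500)$ani # 1
#' @export
compute_ani <- function(a, b, fragment_length = 1020, band = 60,
                        min_fragment_identity = 0.3,
                        min_fragment_coverage = 0.7) {
  seq_a <- as_dna_set(a)
  seq_b <- as_dna_set(b)
  name_a <- attr(seq_a, "genome_name") %||% "genome_a"
  name_b <- attr(seq_b, "genome_name") %||% "genome_b"
  if (max(Biostrings::width(seq_a)) < fragment_length ||
      max(Biostrings::width(seq_b)) < fragment_length) {
    abort("both sequences must contain a record of length >= fragment_length")
  }
  ab <- ani_direction(seq_a, seq_b, fragment_length, band,
    min_fragment_identity, min_fragment_coverage)
  ba <- ani_direction(seq_b, seq_a, fragment_length, band,
    min_fragment_identity, min_fragment_coverage)
  flagged <- is.na(ab$ani) && is.na(ba$ani)
  ani <- if (flagged) NA_real_ else mean(c(ab$ani, ba$ani), na.rm = TRUE)
  out <- tibble(
    genome_a = name_a, genome_b = name_b,
    ani = ani,
    aligned_fraction = mean(c(ab$aligned_fraction, ba$aligned_fraction)),
    fragment_count = ab$n_fragments + ba$n_fragments,
    ani_ab = ab$ani, ani_ba = ba$ani,
    coverage_ab = ab$aligned_fraction, coverage_ba = ba$aligned_fraction,
    flagged = flagged
  )
  structure(out, class = c("ani_result", class(out)))
}

# One direction: fragment `query`, place and align in `subject`.
ani_direction <- function(query, subject, fragment_length, band,
                          min_identity, min_coverage) {
  frags <- fragment_records(query, fragment_length)
  subject_one <- subject[[which.max(Biostrings::width(subject))]]
  sub_len <- length(subject_one)
  stats <- map(frags, function(frag) {
    align_fragment(frag, subject_one, sub_len, fragment_length, band)
  })
  identity <- map_dbl(stats, "identity")
  coverage <- map_dbl(stats, "coverage")
  pass <- !is.na(identity) & identity >= min_identity & coverage >= min_coverage
  list(
    ani = if (any(pass)) mean(identity[pass]) else NA_real_,
    aligned_fraction = mean(pass),
    n_fragments = length(frags)
  )
}

fragment_records <- function(x, fragment_length) {
  out <- list()
  for (i in seq_along(x)) {
    rec <- x[[i]]
    n <- length(rec) %/% fragment_length
    if (n == 0) next
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <-
        Biostrings::subseq(rec, (k - 1L) * fragment_length + 1L, k * fragment_length)
    }
  }
  out
}

# Seed-and-extend placement of one fragment, then banded global-local
# alignment. Returns identity over aligned columns and coverage (aligned,
# non-gap fragment positions / fragment length); NA identity = no placement.
align_fragment <- function(frag, subject, sub_len, fragment_length, band,
                           seed_length = 15L, seed_step = 48L) {
  place <- seed_placement(frag, subject, seed_length, seed_step, band)
  strand_frag <- frag
  if (is.na(place)) {
    strand_frag <- Biostrings::reverseComplement(frag)
    place <- seed_placement(strand_frag, subject, seed_length, seed_step, band)
  }
  if (is.na(place)) {
    return(list(identity = NA_real_, coverage = 0))
  }
  lo <- max(1L, place - band)
  hi <- min(sub_len, place + fragment_length - 1L + band)
  window <- Biostrings::subseq(subject, lo, hi)
  aln <- Biostrings::pairwiseAlignment(
    strand_frag, window,
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE
    ),
    gapOpening = 4, gapExtension = 2
  )
  n_match <- Biostrings::nmatch(aln)
  n_mismatch <- Biostrings::nmismatch(aln)
  aln_cols <- Biostrings::nchar(aln) # alignment length incl. gaps
  list(
    identity = n_match / aln_cols,
    coverage = (n_match + n_mismatch) / fragment_length
  )
}

# Most-voted diagonal of exact(ish) seed hits. At least two seeds must
# agree on a diagonal (within the band) for a placement to count: isolated
# seed hits on unrelated sequence are chance 15-mer matches, and forcing a
# global alignment onto them would fabricate homology.
seed_placement <- function(frag, subject, seed_length, seed_step, band = 60L) {
  frag_len <- length(frag)
  offsets <- seq(1L, frag_len - seed_length + 1L, by = seed_step)
  diagonals <- integer(0)
  for (off in offsets) {
    seed <- Biostrings::subseq(frag, off, off + seed_length - 1L)
    hits <- Biostrings::matchPattern(seed, subject, max.mismatch = 1)
    if (length(hits) > 0) {
      diagonals <- c(diagonals, Biostrings::start(hits) - off + 1L)
    }
  }
  if (length(diagonals) < 2) return(NA_integer_)
  votes <- map_int(diagonals, function(d) sum(abs(diagonals - d) <= band))
  if (max(votes) < 2) return(NA_integer_)
  diagonals[which.max(votes)]
}

as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      grepl("\\.(fa|fasta|fna)$", x, ignore.case = TRUE)) {
    out <- Biostrings::readDNAStringSet(x)
    attr(out, "genome_name") <- sub("\\.[^.]*$", "", basename(x))
    return(out)
  }
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  abort("cannot interpret input as a DNA sequence")
}

#' Classify a genome pair as same or distinct species
#'
#' Applies the whole-genome species-delimitation rule used in LBP strain
#' curation: two genomes are distinct species when they differ by more than
#' `difference_threshold` (default 10%) of their nucleotide identity.
#'
#' @param result An `ani_result` from [compute_ani()].
#' @param difference_threshold Fraction of divergence above which the pair is
#'   split (default 0.10).
#' @return `"same_species"` or `"distinct_species"`.
#' @export
classify_species_pair <- function(result, difference_threshold = 0.10) {
  if (isTRUE(result$flagged) || is.na(result$ani)) {
    abort("ANI is undefined for this pair (no passing fragments)")
  }
  if ((1 - result$ani) > difference_threshold) "distinct_species" else "same_species"
}
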