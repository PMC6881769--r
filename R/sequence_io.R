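#' Read a (multi-record) FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that additionally
#' enforces the invariants the downstream signature code relies on: every
#' record has a non-empty sequence and a unique identifier. Lowercase
#' (soft-masked) bases are uppercased by the DNA alphabet encoding; wrapped
#' lines are joined.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record identifiers (the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  recs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(recs) == 0L) {
    stop("no FASTA records in ", path, call. = FALSE)
  }
  # keep only the id token; full headers make poor matrix labels
  names(recs) <- sub("\\s.*$", "", names(recs))
  if (any(!nzchar(names(recs)))) {
    stop("FASTA record with empty identifier in ", path, call. = FALSE)
  }
  if (anyDuplicated(names(recs))) {
    dup <- names(recs)[duplicated(names(recs))][1L]
    stop("duplicate FASTA identifier '", dup, "' in ", path, call. = FALSE)
  }
  empty <- Biostrings::width(recs) == 0L
  if (any(empty)) {
    stop("empty sequence for record '", names(recs)[which(empty)[1L]],
         "' in ", path, call. = FALSE)
  }
  recs
}

as_dna_set <- function(records) {
  if (inherits(records, "DNAStringSet")) return(records)
  if (is.character(records)) return(Biostrings::DNAStringSet(records))
  stop("records must be a DNAStringSet or character vector", call. = FALSE)
}

#' Base composition of a sequence set
#'
#' Counts A/C/G/T over all records and converts them to background base
#' fractions. Ambiguity codes (including N) are excluded from both the
#' counts and the unambiguous total; they still contribute to `total_raw`.
#' These fractions are the per-position probabilities of the zero-order
#' Markov background used for expected k-mer occurrences.
#'
#' @param records A [Biostrings::DNAStringSet] (or character vector of
#'   sequences).
#' @return An object of class `composition_profile`: a list with `counts`
#'   (named integer, A/C/G/T), `fractions` (named numeric summing to 1),
#'   `total_unambiguous` and `total_raw` (base pairs).
#' @export
compute_composition <- function(records) {
  records <- as_dna_set(records)
  if (length(records) == 0L) stop("at least one record required", call. = FALSE)
  af <- Biostrings::alphabetFrequency(records, collapse = TRUE)
  counts <- af[c("A", "C", "G", "T")]
  total <- sum(counts)
  if (total == 0) {
    stop("no unambiguous A/C/G/T bases: composition undefined", call. = FALSE)
  }
  structure(
    list(
      counts = counts,
      fractions = counts / total,
      total_unambiguous = total,
      total_raw = sum(Biostrings::width(records))
    ),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("Base composition over", x$total_raw, "bp (",
      x$total_unambiguous, "unambiguous )\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Count valid k-mer windows in a sequence set
#'
#' A window is valid when its k bases are all unambiguous A/C/G/T. Windows
#' never span record (contig) boundaries, and ambiguous bases break runs, so
#' a record contributes `max(0, run_length - k + 1)` windows per maximal
#' A/C/G/T run. This is the usable genome length `l_used` entering the
#' expected-occurrence formula, and equals the total observed count summed
#' over all k-mers.
#'
#' @param records A [Biostrings::DNAStringSet] or character vector.
#' @param k Window length (integer >= 1).
#' @return Integer-valued count of valid windows.
#' @export
count_valid_windows <- function(records, k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  records <- as_dna_set(records)
  total <- 0
  for (i in seq_along(records)) {
    s <- as.character(records[[i]])
    runs <- gregexpr("[ACGT]+", s)[[1L]]
    if (runs[1L] == -1L) next
    len <- attr(runs, "match.length")
    total <- total + sum(pmax(0L, len - as.integer(k) + 1L))
  }
  total
}
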