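#' Reverse complement of A/C/G/T k-mers
#'
#' @param kmers Character vector of A/C/G/T strings.
#' @return Character vector of Watson-Crick reverse complements.
#' @export
reverse_complement <- function(kmers) {
  if (!all(grepl("^[ACGT]+$", kmers))) {
    stop("k-mers must contain only A/C/G/T", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
}

#' Is a k-mer a truncated dimer/trimer (or homopolymer) repeat?
#'
#' A k-mer counts as repetitive when it is a tiling of a 1-, 2- or 3-bp unit
#' truncated to its length, i.e. `kmer[i] == kmer[i mod p]` for some period
#' p in {1, 2, 3}. Such k-mers are removed from "common k-mer" selections
#' because simple-sequence repeats dominate raw over-representation without
#' being candidate regulatory motifs.
#'
#' @param kmers Character vector of A/C/G/T strings.
#' @return Logical vector.
#' @export
is_repetitive <- function(kmers) {
  if (!all(grepl("^[ACGT]+$", kmers))) {
    stop("k-mers must contain only A/C/G/T", call. = FALSE)
  }
  n <- nchar(kmers)
  # x has period p iff its first n-p chars equal its last n-p chars
  has_period <- function(p) {
    substr(kmers, 1L, pmax(n - p, 0L)) == substr(kmers, p + 1L, n)
  }
  has_period(1L) | has_period(2L) | has_period(3L)
}

#' Biologically relevant k-mers by the mean + 2 SD rule
#'
#' Computes the mean and (sample) standard deviation of all scores in the
#' signature and returns the k-mers whose score lies strictly above
#' `mean + sd_mult * sd` (upper tail; with `two_sided = TRUE` also those
#' below `mean - sd_mult * sd`). At the default multiplier of 2 this
#' approximates the ~5% upper z-score tail of a normal score distribution.
#'
#' @param sig A `kmer_signature` with >= 2 entries.
#' @param sd_mult Standard-deviation multiplier (default 2).
#' @param two_sided Also return the lower tail? Default `FALSE`.
#' @return A list of class `significant_kmer_set`: `species_id`, `cutoff`
#'   (the threshold actually applied), `sd_mult`, and `kmers`, a data.frame
#'   of passing entries sorted by decreasing score.
#' @export
significant_kmers <- function(sig, sd_mult = 2, two_sided = FALSE) {
  stopifnot(inherits(sig, "kmer_signature"))
  s <- sig$entries$score
  if (length(s) < 2L) {
    stop("signature needs >= 2 entries (sd undefined)", call. = FALSE)
  }
  cutoff <- mean(s) + sd_mult * sd(s)
  keep <- s > cutoff
  if (isTRUE(two_sided)) keep <- keep | s < mean(s) - sd_mult * sd(s)
  km <- sig$entries[keep, , drop = FALSE]
  km <- km[order(-km$score), , drop = FALSE]
  rownames(km) <- NULL
  structure(
    list(species_id = sig$species_id, cutoff = cutoff, sd_mult = sd_mult,
         kmers = km),
    class = "significant_kmer_set"
  )
}

#' @export
print.significant_kmer_set <- function(x, ...) {
  cat("Significant k-mers for ", x$species_id, ": ", nrow(x$kmers),
      " above cutoff ", format(x$cutoff, digits = 4),
      " (mean + ", x$sd_mult, " SD)\n", sep = "")
  print(head(x$kmers, 5L))
  invisible(x)
}

#' K-mers common to a group of species
#'
#' Selects the k-mers that score at least `min_score` in at least
#' `ceiling(min_fraction * n)` of the `n` signatures (by default: score
#' >= 0.5, i.e. observed three times more often than expected, in at least
#' half the species of the genus), optionally dropping dimer/trimer-repeat
#' k-mers.
#'
#' @param signatures List of `kmer_signature` objects of the same k.
#' @param min_score Minimum score (default 0.5).
#' @param min_fraction Minimum fraction of signatures (default 0.5); the
#'   count threshold is the ceiling of `min_fraction * n`.
#' @param exclude_repeats Drop repetitive k-mers (default `TRUE`).
#' @return Sorted character vector of k-mers.
#' @export
common_kmers <- function(signatures, min_score = 0.5, min_fraction = 0.5,
                         exclude_repeats = TRUE) {
  if (length(signatures) < 1L) stop(">= 1 signature required", call. = FALSE)
  ks <- vapply(signatures, function(s) s$k, numeric(1L))
  if (length(unique(ks)) != 1L) stop("signatures differ in k", call. = FALSE)
  need <- ceiling(min_fraction * length(signatures))
  hits <- unlist(lapply(signatures, function(s) {
    s$entries$kmer[s$entries$score >= min_score]
  }))
  tab <- table(hits)
  out <- names(tab)[tab >= need]
  if (isTRUE(exclude_repeats) && length(out) > 0L) {
    out <- out[!is_repetitive(out)]
  }
  sort(out)
}

#' Abundant high-scoring k-mers (repeat-content screen)
#'
#' Returns k-mers that are both strongly over-represented (score >=
#' `min_score`, default 0.8) and highly abundant (observed occurrence >=
#' `min_occurrence`, default 10000). These are typically repeat-derived and
#' explain depressed correlations of repeat-rich genomes. With
#' `require_revcomp_pair = TRUE` a k-mer is kept only when its reverse
#' complement also passes both thresholds (a palindromic k-mer pairs with
#' itself).
#'
#' @param sig A `kmer_signature` with observed counts (not a legacy
#'   two-column signature).
#' @param min_score Minimum score (default 0.8).
#' @param min_occurrence Minimum observed count (default 10000).
#' @param require_revcomp_pair Require the reverse complement to pass too
#'   (default `FALSE`).
#' @return Sorted character vector of k-mers.
#' @export
abundant_high_scoring <- function(sig, min_score = 0.8,
                                  min_occurrence = 10000,
                                  require_revcomp_pair = FALSE) {
  stopifnot(inherits(sig, "kmer_signature"))
  e <- sig$entries
  if (anyNA(e$observed)) {
    stop("signature has no observed counts (legacy two-column input)",
         call. = FALSE)
  }
  pass <- e$kmer[e$score >= min_score & e$observed >= min_occurrence]
  if (isTRUE(require_revcomp_pair) && length(pass) > 0L) {
    pass <- pass[reverse_complement(pass) %in% pass]
  }
  sort(pass)
}

#' Write a selected k-mer table as TSV
#'
#' @param kmers A data.frame with columns `kmer`, `observed`, `expected`,
#'   `score` (e.g. the `kmers` element of [significant_kmers()]).
#' @param path Output path.
#' @param cutoff Optional numeric cutoff recorded as a `#cutoff=` comment.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(kmers, path, cutoff = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(cutoff)) writeLines(sprintf("#cutoff=%.15g", cutoff), con)
  writeLines("kmer\tobserved\texpected\tscore", con)
  writeLines(sprintf("%s\t%s\t%.15g\t%.15g", kmers$kmer,
                     ifelse(is.na(kmers$observed), "NA",
                            as.character(kmers$observed)),
                     kmers$expected, kmers$score), con)
  invisible(path)
}
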