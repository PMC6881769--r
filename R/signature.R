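#' Expected probability of a k-mer under the zero-order Markov background
#'
#' The probability of observing a given k-mer at a random position is the
#' product of the background fractions of its bases,
#' \eqn{P = \prod_{i=1}^{k} p_{b_i}}.
#'
#' @param composition A `composition_profile` (see [compute_composition()]).
#' @param kmer A single A/C/G/T string.
#' @return Probability in \[0, 1\].
#' @export
expected_probability <- function(composition, kmer) {
  stopifnot(inherits(composition, "composition_profile"))
  if (length(kmer) != 1L || !grepl("^[ACGT]+$", kmer)) {
    stop("kmer must be a single non-empty A/C/G/T string", call. = FALSE)
  }
  bases <- strsplit(kmer, "")[[1L]]
  prod(composition$fractions[bases])
}

#' Expected occurrence of a k-mer
#'
#' `E = l_used * p`: the usable length of the genome (number of valid
#' windows) times the background probability of the k-mer.
#'
#' @param p Background probability of the k-mer, in \[0, 1\].
#' @param l_used Usable genome length (valid window count), >= 0.
#' @return Expected occurrence (non-negative real).
#' @export
expected_occurrence <- function(p, l_used) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (any(l_used < 0)) stop("l_used must be >= 0", call. = FALSE)
  l_used * p
}

#' Normalized over/under-representation score
#'
#' `S = (O - E) / (O + E)`. The score is bounded in -1..+1: it tends to +1
#' when the observed count dwarfs the expectation (over-represented k-mer),
#' to -1 when the k-mer is absent despite being expected, and is ~0 when the
#' k-mer occurs at its random rate. Notable reference points: a k-mer
#' observed at twice its expectation scores 1/3 (~0.333), at three times its
#' expectation 0.5.
#'
#' @param O Observed occurrence(s), non-negative.
#' @param E Expected occurrence(s), non-negative. `O` and `E` must not both
#'   be zero.
#' @return Score(s) in \[-1, 1\] (vectorized).
#' @export
score_kmer <- function(O, E) {
  if (any(O < 0) || any(E < 0)) stop("O and E must be >= 0", call. = FALSE)
  if (any(O + E == 0)) {
    stop("score undefined for O = 0 and E = 0", call. = FALSE)
  }
  (O - E) / (O + E)
}

base_counts_per_kmer <- function(kmers) {
  Biostrings::letterFrequency(Biostrings::DNAStringSet(kmers),
                              letters = c("A", "C", "G", "T"))
}

#' Build the k-mer signature of a sequence set
#'
#' Enumerates the motifome (all 4^k k-mers), counts observed occurrences by
#' overlapping forward-strand windows (windows containing ambiguous bases or
#' spanning record boundaries are skipped), computes expected occurrences
#' from the records' own base composition, and scores each k-mer on the
#' -1..+1 scale. K-mers with both O = 0 and E = 0 (possible only when a base
#' fraction is zero) are dropped; they are the "missing" state in pairwise
#' correlation.
#'
#' @param records A [Biostrings::DNAStringSet] or character vector.
#' @param k K-mer length (>= 1; the study range is 7-9).
#' @param species_id Label for the sequence set (species or sample name).
#' @param region_label Which region the set represents, e.g. `whole_genome`
#'   (default), `utr5`, `utr3`, `intron`.
#' @param length_mode `"valid_windows"` (default) takes `l_used` as the
#'   number of valid k-windows, which makes `sum(E)` equal `sum(O)` exactly;
#'   `"raw"` uses the raw total length of the records.
#' @param canonical If `TRUE`, counts of each k-mer and its reverse
#'   complement are pooled under the lexicographically smaller of the two
#'   (strand-symmetric counting). Default `FALSE`: forward strand only.
#' @return An object of class `kmer_signature`: list with `species_id`,
#'   `k`, `region_label`, `l_used`, `composition`, and `entries`, a
#'   data.frame with columns `kmer`, `observed`, `expected`, `score` sorted
#'   lexicographically (A < C < G < T).
#' @export
build_signature <- function(records, k, species_id,
                            region_label = "whole_genome",
                            length_mode = c("valid_windows", "raw"),
                            canonical = FALSE) {
  length_mode <- match.arg(length_mode)
  records <- as_dna_set(records)
  if (length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  comp <- compute_composition(records)
  O <- colSums(Biostrings::oligonucleotideFrequency(records, width = k))
  n_windows <- sum(O)
  if (n_windows == 0) {
    stop("no valid length-", k, " windows: signature undefined", call. = FALSE)
  }
  l_used <- if (length_mode == "valid_windows") n_windows else comp$total_raw

  nc <- base_counts_per_kmer(names(O))
  p <- comp$fractions
  E <- rep(as.numeric(l_used), length(O))
  for (b in c("A", "C", "G", "T")) {
    E <- E * p[[b]]^nc[, b]   # 0^0 = 1 handles absent bases
  }

  if (isTRUE(canonical)) {
    rc <- reverse_complement(names(O))
    canon <- ifelse(names(O) <= rc, names(O), rc)
    O <- tapply(O, canon, sum)
    E <- tapply(E, canon, sum)
    O <- O[sort(names(O))]
    E <- E[names(O)]
  }

  keep <- (O + E) > 0
  entries <- data.frame(
    kmer = names(O)[keep],
    observed = unname(O[keep]),
    expected = unname(E[keep]),
    score = unname((O[keep] - E[keep]) / (O[keep] + E[keep])),
    stringsAsFactors = FALSE
  )
  entries <- entries[order(entries$kmer), , drop = FALSE]
  rownames(entries) <- NULL

  structure(
    list(species_id = species_id, k = k, region_label = region_label,
         l_used = as.numeric(l_used), composition = comp, entries = entries),
    class = "kmer_signature"
  )
}

#' @export
print.kmer_signature <- function(x, ...) {
  cat("K-mer signature: ", x$species_id, " (", x$region_label, ", k = ",
      x$k, ")\n", sep = "")
  cat("  ", nrow(x$entries), " k-mers, l_used = ", format(x$l_used), "\n",
      sep = "")
  if (!is.null(x$composition)) {
    cat("  composition:",
        paste(sprintf("%s=%.4f", names(x$composition$fractions),
                      x$composition$fractions), collapse = " "), "\n")
  }
  print(head(x$entries, 5L))
  invisible(x)
}

#' Write a k-mer signature to a TSV file
#'
#' The format is a commented header (`#species=`, `#k=`, `#region=`,
#' `#l_used=`, `#pA= pC= pG= pT=`) followed by a tab-separated table with
#' columns `kmer`, `observed`, `expected`, `score`, rows in lexicographic
#' order. Floating-point fields carry 15 significant digits so that a
#' read/write round trip is faithful.
#'
#' @param sig A `kmer_signature`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "kmer_signature"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  p <- sig$composition$fractions
  writeLines(c(
    paste0("#species=", sig$species_id),
    paste0("#k=", sig$k),
    paste0("#region=", sig$region_label),
    paste0("#l_used=", sprintf("%.15g", sig$l_used)),
    sprintf("#pA=%.15g pC=%.15g pG=%.15g pT=%.15g",
            p[["A"]], p[["C"]], p[["G"]], p[["T"]]),
    "kmer\tobserved\texpected\tscore"
  ), con)
  e <- sig$entries
  writeLines(sprintf("%s\t%d\t%.15g\t%.15g", e$kmer, as.integer(e$observed),
                     e$expected, e$score), con)
  invisible(path)
}

parse_header_field <- function(lines, key, path, required = TRUE) {
  hit <- grep(paste0("^#", key, "="), lines, value = TRUE)
  if (length(hit) == 0L) {
    if (required) stop("signature file ", path, " missing header field '",
                       key, "'", call. = FALSE)
    return(NULL)
  }
  sub(paste0("^#", key, "="), "", hit[1L])
}

#' Read a k-mer signature from a TSV file
#'
#' Reads the format written by [write_signature()]. A legacy two-column
#' `kmer <TAB> score` file (no comment header, no observed/expected columns)
#' is also accepted; the resulting signature has `NA` observed and expected
#' values and supports correlation but not occurrence-based filters.
#'
#' @param path File path.
#' @return A `kmer_signature`.
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  body <- lines[!hdr]
  if (length(body) == 0L) stop("signature file ", path, " has no rows",
                               call. = FALSE)
  first <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  legacy <- !any(hdr) && length(first) == 2L && !identical(first[1L], "kmer")

  if (legacy) {
    tab <- read.delim(text = body, header = FALSE,
                      col.names = c("kmer", "score"),
                      colClasses = c("character", "numeric"))
    entries <- data.frame(kmer = tab$kmer, observed = NA_real_,
                          expected = NA_real_, score = tab$score,
                          stringsAsFactors = FALSE)
    species <- sub("\\.[^.]*$", "", basename(path))
    sig <- list(species_id = species, k = nchar(entries$kmer[1L]),
                region_label = "unknown", l_used = NA_real_,
                composition = NULL, entries = entries)
  } else {
    species <- parse_header_field(lines[hdr], "species", path)
    k <- as.integer(parse_header_field(lines[hdr], "k", path))
    region <- parse_header_field(lines[hdr], "region", path)
    l_used <- as.numeric(parse_header_field(lines[hdr], "l_used", path))
    pline <- grep("^#pA=", lines[hdr], value = TRUE)
    if (length(pline) == 0L) {
      stop("signature file ", path, " missing composition header",
           call. = FALSE)
    }
    pv <- as.numeric(sub(".*=", "", strsplit(pline[1L], " ")[[1L]]))
    comp_counts <- setNames(rep(NA_integer_, 4L), c("A", "C", "G", "T"))
    comp <- structure(
      list(counts = comp_counts,
           fractions = setNames(pv, c("A", "C", "G", "T")),
           total_unambiguous = NA_integer_, total_raw = NA_integer_),
      class = "composition_profile"
    )
    if (!identical(first, c("kmer", "observed", "expected", "score"))) {
      stop("signature file ", path, " has unexpected column header",
           call. = FALSE)
    }
    tab <- read.delim(text = body[-1L], header = FALSE,
                      col.names = c("kmer", "observed", "expected", "score"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric"))
    entries <- tab
    sig <- list(species_id = species, k = k, region_label = region,
                l_used = l_used, composition = comp, entries = entries)
  }

  if (anyDuplicated(sig$entries$kmer)) {
    dup <- sig$entries$kmer[duplicated(sig$entries$kmer)][1L]
    stop("duplicate k-mer '", dup, "' in ", path, call. = FALSE)
  }
  if (any(nchar(sig$entries$kmer) != sig$k)) {
    stop("k-mer length mismatch in ", path, " (expected k = ", sig$k, ")",
         call. = FALSE)
  }
  sig$entries <- sig$entries[order(sig$entries$kmer), , drop = FALSE]
  rownames(sig$entries) <- NULL
  structure(sig, class = "kmer_signature")
}
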