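# Brute-force oracles, deliberately independent of the package's code paths
# (character-level loops, no Biostrings).

random_dna <- function(len, with_ambiguous = FALSE) {
  alph <- c("A", "C", "G", "T", if (with_ambiguous) c("N", "R"))
  prob <- if (with_ambiguous) c(rep(0.235, 4), 0.03, 0.03) else rep(0.25, 4)
  paste(sample(alph, len, replace = TRUE, prob = prob), collapse = "")
}

# overlapping window counts of every k-mer, skipping non-ACGT windows,
# never spanning record boundaries
brute_count_kmers <- function(seqs, k) {
  wins <- lapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(character())
    w <- substring(s, 1:(n - k + 1), k:n)
    w[grepl("^[ACGT]+$", w)]
  })
  table(unlist(wins))
}

brute_valid_windows <- function(seqs, k) {
  sum(unlist(lapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(0L)
    w <- substring(s, 1:(n - k + 1), k:n)
    sum(grepl("^[ACGT]+$", w))
  })))
}

# minimal-period repetitiveness: kmer[i] == kmer[i mod p] for some p in 1:3
brute_repetitive <- function(kmer) {
  ch <- strsplit(kmer, "")[[1L]]
  any(vapply(1:3, function(p) {
    all(ch == ch[((seq_along(ch) - 1L) %% p) + 1L])
  }, logical(1L)))
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

# minimal in-memory signature for correlation/selection tests
make_sig <- function(scores, species_id = "s", k = NULL,
                     observed = NULL, expected = NULL) {
  kmers <- names(scores)
  if (is.null(k)) k <- nchar(kmers[1L])
  if (is.null(observed)) observed <- rep(NA_real_, length(scores))
  if (is.null(expected)) expected <- rep(NA_real_, length(scores))
  entries <- data.frame(kmer = kmers, observed = observed,
                        expected = expected, score = unname(scores),
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$kmer), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(species_id = species_id, k = k, region_label = "test",
                 l_used = NA_real_, composition = NULL, entries = entries),
            class = "kmer_signature")
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
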