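#' Read JASPAR-style position frequency matrices
#'
#' Parses the plain-text JASPAR PFM format: a header line `>ID NAME`
#' followed by four base rows, either bracketed (`A [ 4 19 0 ... ]`) or
#' bare whitespace-separated counts in A, C, G, T order. Counts are
#' normalized to per-column frequencies.
#'
#' @param path Path to a PFM file (may hold several matrices).
#' @return A list of `pwm` objects, each a list with `id`, `name`, `width`
#'   and `freq`, a 4 x width matrix (rows A, C, G, T; columns sum to 1).
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) {
    stop("no '>' matrix headers in ", path, call. = FALSE)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(hdr, "\\s+")[[1L]]
    id <- toks[1L]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    rows <- lines[seq.int(starts[i] + 1L, ends[i])]
    if (length(rows) != 4L) {
      stop("matrix ", id, " in ", path, ": expected 4 base rows, got ",
           length(rows), call. = FALSE)
    }
    parse_row <- function(r) {
      base <- NA_character_
      if (grepl("^[ACGTacgt]\\b", r)) {
        base <- toupper(substr(r, 1L, 1L))
        r <- sub("^[ACGTacgt]", "", r)
      }
      r <- gsub("[][]", " ", r)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1L]]))
      if (length(vals) == 0L || anyNA(vals)) {
        stop("matrix ", id, " in ", path, ": unparseable counts row",
             call. = FALSE)
      }
      list(base = base, vals = vals)
    }
    parsed <- lapply(rows, parse_row)
    bases <- vapply(parsed, `[[`, character(1L), "base")
    if (!anyNA(bases)) {
      if (!setequal(bases, c("A", "C", "G", "T"))) {
        stop("matrix ", id, " in ", path, ": base rows must be A, C, G, T",
             call. = FALSE)
      }
      parsed <- parsed[match(c("A", "C", "G", "T"), bases)]
    }
    widths <- lengths(lapply(parsed, `[[`, "vals"))
    if (length(unique(widths)) != 1L) {
      stop("matrix ", id, " in ", path, ": ragged rows", call. = FALSE)
    }
    counts <- do.call(rbind, lapply(parsed, `[[`, "vals"))
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) {
      stop("matrix ", id, " in ", path, ": negative counts", call. = FALSE)
    }
    csum <- colSums(counts)
    if (any(csum == 0)) {
      stop("matrix ", id, " in ", path, ": zero-sum column", call. = FALSE)
    }
    freq <- sweep(counts, 2L, csum, "/")
    structure(list(id = id, name = name, width = ncol(freq), freq = freq),
              class = "pwm")
  })
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM ", x$id, " (", x$name, "), width ", x$width, "\n", sep = "")
  print(round(x$freq, 3))
  invisible(x)
}

#' Similarity of a k-mer to a PWM at a fixed offset
#'
#' For each k-mer position aligned to a PWM column, the contribution is the
#' frequency of the k-mer's base in that column divided by the column's
#' maximum frequency; the similarity is the mean contribution over the
#' aligned overlap. On a one-hot PWM this reduces to percent identity
#' against the consensus. Positions where the k-mer overhangs the matrix
#' are excluded from the mean.
#'
#' @param kmer A single A/C/G/T string.
#' @param pwm A `pwm` object from [read_jaspar()].
#' @param offset 0-based position of the k-mer's first base within the PWM;
#'   may be negative when the k-mer overhangs to the left.
#' @param metric `"ratio"` (default, ratio-to-column-max averaged over the
#'   overlap) or `"consensus"` (fraction of aligned positions whose base
#'   attains the column maximum, ties allowed).
#' @return Similarity in \[0, 1\].
#' @export
pwm_similarity <- function(kmer, pwm, offset,
                           metric = c("ratio", "consensus")) {
  metric <- match.arg(metric)
  stopifnot(inherits(pwm, "pwm"))
  if (length(kmer) != 1L || !grepl("^[ACGT]+$", kmer)) {
    stop("kmer must be a single A/C/G/T string", call. = FALSE)
  }
  k <- nchar(kmer)
  pos <- seq_len(k)            # positions in the k-mer
  col <- offset + pos          # 1-based PWM columns
  inside <- col >= 1L & col <= pwm$width
  if (!any(inside)) stop("zero overlap between k-mer and PWM", call. = FALSE)
  bases <- strsplit(kmer, "")[[1L]][inside]
  cols <- col[inside]
  f <- pwm$freq[cbind(match(bases, c("A", "C", "G", "T")), cols)]
  cmax <- apply(pwm$freq[, cols, drop = FALSE], 2L, max)
  if (metric == "ratio") mean(f / cmax) else mean(f == cmax)
}

#' Scan candidate k-mers against a PWM collection
#'
#' Slides the shorter of k-mer and PWM over the longer through all
#' full-overlap offsets, records the best similarity per (k-mer, PWM) pair
#' (ties broken by the smallest offset), and emits a hit when the best
#' similarity reaches `cutoff`. With `both_strands = TRUE` the reverse
#' complement of each k-mer is scanned too and the better strand kept.
#'
#' @param kmers Character vector of A/C/G/T k-mers.
#' @param pwms List of `pwm` objects.
#' @param cutoff Similarity threshold in \[0, 1\] (default 0.8).
#' @param metric Passed to [pwm_similarity()].
#' @param both_strands Also scan reverse complements (default `FALSE`).
#' @return A data.frame with columns `kmer`, `pwm_id`, `pwm_name`,
#'   `offset`, `similarity`, one row per passing (k-mer, PWM) pair.
#' @export
pwm_scan <- function(kmers, pwms, cutoff = 0.8,
                     metric = c("ratio", "consensus"), both_strands = FALSE) {
  metric <- match.arg(metric)
  if (length(pwms) == 0L) stop("empty PWM list", call. = FALSE)
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]",
                                     call. = FALSE)
  best_for <- function(km, pwm) {
    k <- nchar(km)
    offsets <- if (pwm$width >= k) 0:(pwm$width - k) else -(k - pwm$width):0
    sims <- vapply(offsets, function(o) pwm_similarity(km, pwm, o, metric),
                   numeric(1L))
    i <- which.max(sims)   # first maximum = smallest offset
    c(offset = offsets[i], similarity = sims[i])
  }
  rows <- list()
  for (km in kmers) {
    variants <- if (isTRUE(both_strands)) {
      unique(c(km, reverse_complement(km)))
    } else km
    for (pwm in pwms) {
      b <- NULL
      for (v in variants) {
        cand <- best_for(v, pwm)
        if (is.null(b) || cand[["similarity"]] > b[["similarity"]]) b <- cand
      }
      if (b[["similarity"]] >= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          kmer = km, pwm_id = pwm$id, pwm_name = pwm$name,
          offset = as.integer(b[["offset"]]),
          similarity = unname(b[["similarity"]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kmer = character(), pwm_id = character(),
                      pwm_name = character(), offset = integer(),
                      similarity = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
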