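BASES <- c("A", "C", "G", "T")

# deterministic sub-seed derivation so independent parts of a fixture can be
# regenerated on their own; kept well inside 32-bit integer range
derive_seed <- function(seed, ...) {
  idx <- c(...)
  as.integer((seed + sum(idx * 7919L^seq_along(idx))) %% 2147483587)
}

check_composition <- function(composition) {
  if (is.null(names(composition))) names(composition) <- BASES
  composition <- composition[BASES]
  if (anyNA(composition) || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9) {
    stop("composition must be non-negative A/C/G/T fractions summing to 1",
         call. = FALSE)
  }
  composition
}

place_block <- function(chars, block, occupied, n_copies) {
  len <- length(block)
  L <- length(chars)
  if (len > L) stop("planted sequence longer than genome", call. = FALSE)
  starts <- sample.int(L - len + 1L)
  placed <- 0L
  for (s in starts) {
    if (placed == n_copies) break
    span <- s:(s + len - 1L)
    if (any(occupied[span])) next
    chars[span] <- block
    occupied[span] <- TRUE
    placed <- placed + 1L
  }
  if (placed < n_copies) {
    stop("could not place ", n_copies, " non-overlapping copies (genome too ",
         "small or too crowded)", call. = FALSE)
  }
  list(chars = chars, occupied = occupied)
}

#' Generate a synthetic genome with controlled composition and planted k-mers
#'
#' Background bases are drawn i.i.d. at the target composition. Each planted
#' k-mer is then written over the background at non-overlapping random
#' positions until its copy number reaches `multiplier` times its expected
#' occurrence under the background model (so the k-mer ends up roughly
#' `multiplier + 1` times over-represented, background occurrences
#' included). Tandem-repeat blocks are tiled the same way. Planting replaces
#' bases in place, so the total length is unchanged. Fully deterministic
#' given `seed`.
#'
#' @param length Genome length in bp.
#' @param composition Named A/C/G/T fractions summing to 1 (default
#'   uniform).
#' @param plants Named numeric vector: names are k-mers to plant, values
#'   their target over-representation multipliers (> 0) relative to the
#'   expected occurrence.
#' @param repeat_plants Named integer vector: names are repeat units, values
#'   the number of tandem copies to tile as one contiguous block each.
#' @param seed Integer seed; same seed, same genome.
#' @param id Record identifier (default `"chr1"`).
#' @return A single-record [Biostrings::DNAStringSet].
#' @export
generate_genome <- function(length, composition = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25),
                            plants = NULL, repeat_plants = NULL,
                            seed = 1L, id = "chr1") {
  composition <- check_composition(composition)
  if (length < 10L) stop("genome length too small", call. = FALSE)
  if (!is.null(plants)) {
    if (is.null(names(plants)) || !all(grepl("^[ACGT]+$", names(plants)))) {
      stop("plants must be a named vector with A/C/G/T k-mer names",
           call. = FALSE)
    }
    if (any(plants <= 0)) stop("plant multipliers must be > 0", call. = FALSE)
  }
  withr::with_seed(derive_seed(seed, 1L), {
    chars <- sample(BASES, length, replace = TRUE, prob = composition)
    occupied <- rep(FALSE, length)
    for (unit in names(repeat_plants)) {
      block <- rep(strsplit(unit, "")[[1L]], repeat_plants[[unit]])
      res <- place_block(chars, block, occupied, 1L)
      chars <- res$chars
      occupied <- res$occupied
    }
    for (km in names(plants)) {
      k <- nchar(km)
      p <- prod(composition[strsplit(km, "")[[1L]]])
      target <- max(1L, round(plants[[km]] * (length - k + 1) * p))
      res <- place_block(chars, strsplit(km, "")[[1L]], occupied, target)
      chars <- res$chars
      occupied <- res$occupied
    }
    out <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(out) <- id
    out
  })
}

mutate_chars <- function(chars, rate) {
  if (rate == 0) return(chars)
  n <- rbinom(1L, length(chars), rate)
  if (n == 0L) return(chars)
  pos <- sample.int(length(chars), n)
  # substitute with one of the three other bases, uniformly
  shift <- sample.int(3L, n, replace = TRUE)
  cur <- match(chars[pos], BASES)
  chars[pos] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  chars
}

#' Simulate clades of related genomes by point substitution
#'
#' A single root genome is drawn at the target composition; each clade gets
#' an ancestor derived from the root by substitutions at rate `between`
#' (expected substitutions per site), and each species is derived from its
#' clade ancestor at rate `within`. Substitutions replace a base with one of
#' the other three uniformly (Jukes-Cantor-like); there are no indels, so
#' all genomes share the same length. `within` must be smaller than
#' `between` for the clade structure to be interpretable.
#'
#' @param n_clades Number of clades.
#' @param species_per_clade Species per clade.
#' @param length Genome length in bp.
#' @param within,between Substitution rates per site in \[0, 0.75\],
#'   `within < between` (unless both are 0).
#' @param composition Root composition (default uniform).
#' @param seed Integer seed.
#' @return A list with `genomes` (named list of single-record
#'   [Biostrings::DNAStringSet], ids like `cladeA_sp1`) and `groups` (a
#'   data.frame mapping `species_id` to clade `group`).
#' @export
evolve_clades <- function(n_clades, species_per_clade, length,
                          within = 0.01, between = 0.15,
                          composition = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                          seed = 1L) {
  composition <- check_composition(composition)
  if (within < 0 || between < 0 || within > 0.75 || between > 0.75) {
    stop("divergence rates must be in [0, 0.75]", call. = FALSE)
  }
  if (within >= between && !(within == 0 && between == 0)) {
    stop("within-clade divergence must be smaller than between-clade ",
         "divergence", call. = FALSE)
  }
  root <- withr::with_seed(derive_seed(seed, 2L), {
    sample(BASES, length, replace = TRUE, prob = composition)
  })
  genomes <- list()
  groups <- list()
  for (ci in seq_len(n_clades)) {
    clade <- paste0("clade", LETTERS[ci])
    ancestor <- withr::with_seed(derive_seed(seed, 3L, ci), {
      mutate_chars(root, between)
    })
    for (si in seq_len(species_per_clade)) {
      sp <- paste0(clade, "_sp", si)
      g <- withr::with_seed(derive_seed(seed, 4L, ci, si), {
        mutate_chars(ancestor, within)
      })
      dna <- Biostrings::DNAStringSet(paste(g, collapse = ""))
      names(dna) <- "chr1"
      genomes[[sp]] <- dna
      groups[[length(groups) + 1L]] <- data.frame(species_id = sp,
                                                  group = clade,
                                                  stringsAsFactors = FALSE)
    }
  }
  list(genomes = genomes, groups = do.call(rbind, groups))
}
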