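#' Pearson correlation between two k-mer signatures
#'
#' Scores are compared over the intersection of k-mer keys (a k-mer missing
#' from either signature is omitted), in lexicographic key order. K-mers
#' with zero observed count are kept by default: their score of -1 carries
#' real under-representation information.
#'
#' @param sigA,sigB `kmer_signature` objects of the same k.
#' @param omit_zero_observed If `TRUE`, k-mers with O = 0 in either
#'   signature are also dropped from the intersection before correlating.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
pairwise_cc <- function(sigA, sigB, omit_zero_observed = FALSE) {
  stopifnot(inherits(sigA, "kmer_signature"), inherits(sigB, "kmer_signature"))
  if (sigA$k != sigB$k) {
    stop("k mismatch: ", sigA$k, " vs ", sigB$k, call. = FALSE)
  }
  ia <- match(sigB$entries$kmer, sigA$entries$kmer)
  keep <- !is.na(ia)
  a <- sigA$entries[ia[keep], ]
  b <- sigB$entries[keep, ]
  if (isTRUE(omit_zero_observed)) {
    nz <- !(a$observed %in% 0) & !(b$observed %in% 0)
    a <- a[nz, ]
    b <- b[nz, ]
  }
  if (nrow(a) < 3L) {
    stop("fewer than 3 shared k-mers between ", sigA$species_id, " and ",
         sigB$species_id, call. = FALSE)
  }
  if (sd(a$score) == 0 || sd(b$score) == 0) {
    stop("zero score variance: correlation undefined", call. = FALSE)
  }
  cor(a$score, b$score)
}

#' All-versus-all correlation matrix of k-mer signatures
#'
#' @param signatures List of `kmer_signature` objects (>= 2, same k,
#'   distinct species ids).
#' @param omit_zero_observed Passed to [pairwise_cc()].
#' @return A symmetric species-by-species numeric matrix with unit diagonal
#'   and attributes `k` and `region_label`.
#' @export
cc_matrix <- function(signatures, omit_zero_observed = FALSE) {
  if (length(signatures) < 2L) stop(">= 2 signatures required", call. = FALSE)
  ids <- vapply(signatures, function(s) s$species_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate species_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  ks <- vapply(signatures, function(s) s$k, numeric(1L))
  if (length(unique(ks)) != 1L) stop("signatures differ in k", call. = FALSE)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      cc <- pairwise_cc(signatures[[i]], signatures[[j]],
                        omit_zero_observed = omit_zero_observed)
      m[i, j] <- cc
      m[j, i] <- cc
    }
  }
  stopifnot(isSymmetric(m), all(diag(m) == 1))
  attr(m, "k") <- ks[1L]
  attr(m, "region_label") <- signatures[[1L]]$region_label
  m
}

#' Number of distinct unordered pairs among n species
#'
#' `n * (n - 1) / 2`, the number of all-versus-all comparisons excluding
#' self-pairs (e.g. 63 species give 1953 comparisons).
#'
#' @param n Number of species (>= 2).
#' @return Integer pair count.
#' @export
pair_count <- function(n) {
  if (any(n < 2) || any(n != round(n))) {
    stop("n must be an integer >= 2", call. = FALSE)
  }
  n * (n - 1) / 2
}

#' Comparison specifications for group-level CC summaries
#'
#' `group_within("X")` selects the unordered pairs inside group X;
#' `group_between("X", "Y")` the |X| x |Y| cross pairs between two groups;
#' `group_rest("X")` ("non-X") all unordered pairs among species *not* in X.
#'
#' @param group,group2 Group labels as used in the species->group mapping.
#' @return A comparison spec for [group_summaries()].
#' @export
group_within <- function(group) {
  structure(list(type = "within", group = group,
                 label = group), class = "cc_comparison")
}

#' @rdname group_within
#' @export
group_between <- function(group, group2) {
  structure(list(type = "between", group = group, group2 = group2,
                 label = paste(group, "vs.", group2)), class = "cc_comparison")
}

#' @rdname group_within
#' @export
group_rest <- function(group) {
  structure(list(type = "rest", group = group,
                 label = paste0("Non-", group)), class = "cc_comparison")
}

cc_values_for_spec <- function(m, groups, spec) {
  ids <- rownames(m)
  pick_pairs_within <- function(members) {
    idx <- which(ids %in% members)
    if (length(idx) < 2L) {
      stop("comparison '", spec$label, "' has fewer than 2 species",
           call. = FALSE)
    }
    m[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
  }
  switch(spec$type,
    within = pick_pairs_within(names(groups)[groups == spec$group]),
    rest = pick_pairs_within(names(groups)[groups != spec$group]),
    between = {
      i1 <- which(ids %in% names(groups)[groups == spec$group])
      i2 <- which(ids %in% names(groups)[groups == spec$group2])
      if (length(i1) == 0L || length(i2) == 0L) {
        stop("empty group in comparison '", spec$label, "'", call. = FALSE)
      }
      as.vector(m[i1, i2])
    },
    stop("unknown comparison type: ", spec$type, call. = FALSE)
  )
}

#' Summary statistics of CC values for group comparisons
#'
#' For each comparison spec, reports the minimum, median, mean, maximum and
#' (sample) standard deviation of the selected correlation coefficients and
#' the number of species comparisons entering them.
#'
#' @param m Correlation matrix from [cc_matrix()] (or any symmetric
#'   species-by-species matrix with dimnames).
#' @param groups Species-to-group mapping: either a named character vector
#'   (names are species ids) or a two-column data.frame
#'   `(species_id, group)`.
#' @param comparisons List of specs built with [group_within()],
#'   [group_between()], [group_rest()]. Default: within, and "non-X", for
#'   every group, plus all between-group combinations.
#' @return A data.frame with columns `label`, `min`, `median`, `mean`,
#'   `max`, `sd`, `n_comparisons`.
#' @export
group_summaries <- function(m, groups, comparisons = NULL) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups[[2L]]), as.character(groups[[1L]]))
  }
  missing_map <- setdiff(rownames(m), names(groups))
  if (length(missing_map) > 0L) {
    stop("species without a group mapping: ", missing_map[1L], call. = FALSE)
  }
  groups <- groups[rownames(m)]
  if (is.null(comparisons)) {
    gl <- unique(groups)
    comparisons <- c(
      lapply(gl, group_within),
      lapply(gl, group_rest),
      if (length(gl) > 1L) {
        combs <- utils::combn(gl, 2L, simplify = FALSE)
        lapply(combs, function(p) group_between(p[1L], p[2L]))
      }
    )
  }
  rows <- lapply(comparisons, function(spec) {
    v <- cc_values_for_spec(m, groups, spec)
    data.frame(label = spec$label, min = min(v), median = median(v),
               mean = mean(v), max = max(v),
               sd = sd(v), n_comparisons = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Welch's t-test and Cohen's d for two sets of CC values
#'
#' Tests whether within-group correlations differ from between-group
#' correlations: Welch's unequal-variance t-test (two-sided, with the
#' Welch-Satterthwaite degrees of freedom) plus Cohen's d computed with the
#' pooled standard deviation and a 95% confidence interval from the
#' normal-approximation variance
#' `Var(d) = (n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2))`.
#'
#' @param group1_ccs,group2_ccs Numeric vectors (length >= 2, finite).
#' @return A list of class `group_test_result` with `t_statistic`, `df`,
#'   `p_value`, `cohens_d`, `d_ci_low`, `d_ci_high`, `n1`, `n2`.
#' @export
welch_cohen <- function(group1_ccs, group2_ccs) {
  x <- group1_ccs
  y <- group2_ccs
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite CC values", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    # degenerate identical constants: no evidence of difference
    tt <- list(statistic = c(t = 0), parameter = c(df = n1 + n2 - 2),
               p.value = 1)
  } else {
    tt <- t.test(x, y, var.equal = FALSE)
  }
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  d <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
  var_d <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  z <- qnorm(0.975)
  structure(
    list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, cohens_d = d,
         d_ci_low = d - z * sqrt(var_d), d_ci_high = d + z * sqrt(var_d),
         n1 = n1, n2 = n2),
    class = "group_test_result"
  )
}

#' @export
print.group_test_result <- function(x, ...) {
  pv <- if (x$p_value < 1e-300) "<1e-300" else format(x$p_value, digits = 3)
  cat(sprintf("Welch t = %.3f (df = %.1f), p = %s\n", x$t_statistic, x$df, pv))
  cat(sprintf("Cohen's d = %.2f (95%% CI %.2f-%.2f), n1 = %d, n2 = %d\n",
              x$cohens_d, x$d_ci_low, x$d_ci_high, x$n1, x$n2))
  invisible(x)
}

#' Write / read a CC matrix as TSV
#'
#' Square tab-separated matrix with species ids as both header row and
#' first column, values at 6 decimal places.
#'
#' @param m Correlation matrix.
#' @param path File path.
#' @return `path` invisibly ([write_cc_matrix()]); the matrix
#'   ([read_cc_matrix()]).
#' @export
write_cc_matrix <- function(m, path) {
  out <- cbind(species = rownames(m),
               format(round(m, 6), nsmall = 6, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cc_matrix
#' @export
read_cc_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  if (!isSymmetric(unname(m))) stop("CC matrix not symmetric: ", path,
                                    call. = FALSE)
  m
}
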