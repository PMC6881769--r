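test_that("pairwise correlation matches hand Pearson computation", {
  kmers <- c("AA", "AC", "AG", "AT")
  sa <- make_sig(setNames(c(0.1, 0.2, -0.1, 0.4), kmers), "a")
  sb <- make_sig(setNames(c(-0.1, -0.2, 0.1, -0.4), kmers), "b")
  expect_equal(pairwise_cc(sa, sa), 1.0)
  expect_equal(pairwise_cc(sa, sb), -1.0)

  sc <- make_sig(setNames(c(0.0, 0.3, -0.2, 0.1), kmers), "c")
  # frozen value from the textbook Pearson formula computed independently
  expect_equal(pairwise_cc(sa, sc), 0.692307692308, tolerance = 1e-10)
})

test_that("k-mers missing from either signature are omitted", {
  kmers <- c("AA", "AC", "AG", "AT")
  sa <- make_sig(setNames(c(0.1, 0.2, -0.1, 0.4), kmers), "a")
  sc <- make_sig(setNames(c(0.0, 0.3, -0.2, 0.1), kmers), "c")
  base <- pairwise_cc(sa, sc)
  # a k-mer present in only one signature must not change the value
  sa_plus <- make_sig(setNames(c(0.1, 0.2, -0.1, 0.4, 0.9),
                               c(kmers, "TT")), "a")
  expect_equal(pairwise_cc(sa_plus, sc), base)
  # invariance under re-ordering of the shared key set
  sc_shuf <- make_sig(setNames(c(0.1, -0.2, 0.3, 0.0),
                               c("AT", "AG", "AC", "AA")), "c")
  expect_equal(pairwise_cc(sa, sc_shuf), base)
})

test_that("pairwise correlation error conditions", {
  sa <- make_sig(c(AA = 0.1, AC = 0.2, AG = 0.3), "a")
  sb2 <- make_sig(c(AAA = 0.1, ACA = 0.2, AGA = 0.3), "b")
  expect_error(pairwise_cc(sa, sb2), "k mismatch")
  tiny <- make_sig(c(AA = 0.1, AC = 0.2), "t")
  expect_error(pairwise_cc(sa, tiny), "fewer than 3")
  flat <- make_sig(c(AA = 0.5, AC = 0.5, AG = 0.5), "f")
  expect_error(pairwise_cc(sa, flat), "zero score variance")
})

test_that("omit_zero_observed drops zero-count k-mers from the overlap", {
  kmers <- c("AA", "AC", "AG", "AT", "CA")
  sa <- make_sig(setNames(c(0.1, 0.2, -0.1, 0.4, -1), kmers), "a",
                 observed = c(5, 6, 3, 9, 0), expected = rep(4, 5))
  sb <- make_sig(setNames(c(0.0, 0.3, -0.2, 0.1, 0.8), kmers), "b",
                 observed = c(4, 7, 2, 5, 30), expected = rep(4, 5))
  full <- pairwise_cc(sa, sb)
  strict <- pairwise_cc(sa, sb, omit_zero_observed = TRUE)
  sa4 <- make_sig(setNames(c(0.1, 0.2, -0.1, 0.4), kmers[1:4]), "a")
  sb4 <- make_sig(setNames(c(0.0, 0.3, -0.2, 0.1), kmers[1:4]), "b")
  expect_equal(strict, pairwise_cc(sa4, sb4))
  expect_false(isTRUE(all.equal(full, strict)))
})

test_that("cc_matrix is symmetric with unit diagonal and order-equivariant", {
  withr::local_seed(31)
  kmers <- all_kmers(3)
  sigs <- lapply(1:4, function(i) {
    make_sig(setNames(runif(length(kmers), -1, 1), kmers), paste0("sp", i))
  })
  m <- cc_matrix(sigs)
  expect_equal(diag(m), setNames(rep(1, 4), paste0("sp", 1:4)))
  expect_true(isSymmetric(m))
  expect_true(all(m >= -1 & m <= 1))
  perm <- c(3, 1, 4, 2)
  m2 <- cc_matrix(sigs[perm])
  expect_equal(m2, m[perm, perm], ignore_attr = TRUE)
  expect_equal(rownames(m2), rownames(m)[perm])

  dup <- sigs
  dup[[2L]] <- make_sig(setNames(sigs[[1L]]$entries$score, kmers), "sp1")
  expect_error(cc_matrix(dup), "duplicate species_id")
})

test_that("identical signatures under different ids correlate at 1", {
  kmers <- c("AA", "AC", "AG", "AT")
  s1 <- make_sig(setNames(c(0.1, 0.2, -0.1, 0.4), kmers), "x")
  s2 <- make_sig(setNames(c(0.1, 0.2, -0.1, 0.4), kmers), "y")
  m <- cc_matrix(list(s1, s2))
  expect_equal(m["x", "y"], 1.0)
})

test_that("pair_count gives distinct unordered pair counts", {
  expect_equal(pair_count(22), 231)
  expect_equal(pair_count(30), 435)
  expect_equal(pair_count(2), 1)
  expect_error(pair_count(1), ">= 2")
})

test_that("group summaries select the right pair sets", {
  withr::local_seed(32)
  ids <- c(paste0("a", 1:3), paste0("b", 1:4))
  n <- length(ids)
  m <- matrix(runif(n * n, 0, 1), n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  groups <- setNames(c(rep("A", 3), rep("B", 4)), ids)
  s <- group_summaries(m, groups, list(group_within("A"), group_within("B"),
                                       group_between("A", "B"),
                                       group_rest("A")))
  expect_equal(s$n_comparisons, c(3, 6, 12, 6))
  expect_true(all(s$min <= s$median & s$median <= s$max))
  # "non-A" pairs are exactly the within-B pairs here
  expect_equal(s$mean[s$label == "Non-A"], s$mean[s$label == "B"])

  expect_error(group_summaries(m, groups[-1L]), "without a group")
})

test_that("a constant pair set collapses to min = median = mean = max", {
  ids <- c("x1", "x2", "x3")
  m <- matrix(0.7, 3, 3, dimnames = list(ids, ids))
  diag(m) <- 1
  s <- group_summaries(m, setNames(rep("X", 3), ids),
                       list(group_within("X")))
  expect_equal(unlist(s[1, c("min", "median", "mean", "max")],
                      use.names = FALSE), rep(0.7, 4))
  expect_equal(s$sd, 0)
  expect_equal(s$n_comparisons, 3)
})

test_that("group summaries accept a two-column data.frame mapping", {
  ids <- c("x1", "x2", "y1", "y2")
  m <- diag(1, 4)
  dimnames(m) <- list(ids, ids)
  m[upper.tri(m)] <- 0.5
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  df <- data.frame(species_id = ids, group = c("X", "X", "Y", "Y"))
  s <- group_summaries(m, df, list(group_between("X", "Y")))
  expect_equal(s$n_comparisons, 4)
  expect_equal(s$mean, 0.5)
})

test_that("welch_cohen matches hand Welch/Cohen computation", {
  same <- welch_cohen(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$cohens_d, 0)

  # frozen values from independent textbook-formula computation
  r <- welch_cohen(c(0.95, 0.96, 0.97), c(0.70, 0.72, 0.74))
  expect_equal(r$t_statistic, 18.5903200618, tolerance = 1e-9)
  expect_equal(r$p_value, 3.8272463903e-04, tolerance = 1e-9)
  expect_equal(r$cohens_d, 15.1789327688, tolerance = 1e-9)
  expect_true(r$d_ci_low <= r$cohens_d && r$cohens_d <= r$d_ci_high)

  # d is invariant under a common affine rescaling of both samples
  r2 <- welch_cohen(2 * c(0.95, 0.96, 0.97) + 1, 2 * c(0.70, 0.72, 0.74) + 1)
  expect_equal(r2$cohens_d, r$cohens_d)
  # with sample SDs, duplication changes d only through the n-1 denominators;
  # at realistic sizes the effect is negligible
  withr::local_seed(33)
  x <- runif(60, 0.9, 1)
  y <- runif(80, 0.6, 0.8)
  expect_equal(welch_cohen(rep(x, 2), rep(y, 2))$cohens_d,
               welch_cohen(x, y)$cohens_d, tolerance = 0.01)

  expect_error(welch_cohen(1, c(1, 2)), ">= 2")
})

test_that("cc matrix TSV round-trips", {
  ids <- c("sp1", "sp2", "sp3")
  m <- matrix(c(1, .8, .3, .8, 1, .45, .3, .45, 1), 3, 3,
              dimnames = list(ids, ids))
  f <- tempfile(fileext = ".tsv")
  write_cc_matrix(m, f)
  back <- read_cc_matrix(f)
  expect_equal(back, m, tolerance = 1e-6)
})
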