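test_that("conservation profile counts ungapped and modal residues", {
  aln <- alignment_from_matrix(cbind(c("A", "A", "A", "C"),
                                     c("A", "-", "-", "-"),
                                     c("A", "A", "C", "C")))
  prof <- conservation_profile(aln)
  expect_equal(prof$n_ungapped, c(4L, 1L, 4L))
  expect_equal(prof$n_modal, c(3L, 1L, 2L))
  expect_equal(prof$modal, c("A", "A", "A"))  # tie broken alphabetically
  expect_equal(prof$tie, c(FALSE, FALSE, TRUE))
  # per-residue counts sum to n_ungapped at every column
  counts <- attr(prof, "counts")
  expect_equal(unname(colSums(counts)), prof$n_ungapped)
  expect_error(conservation_profile(
    alignment_from_matrix(matrix("A", 1, 0))), "empty")
})

test_that("logo information content matches the entropy formula", {
  one <- alignment_from_matrix(matrix("W", 50, 1))
  expect_equal(logo_matrix(one)$bits, log2(20), tolerance = 1e-9)

  unif <- alignment_from_matrix(matrix(rep(igcompare:::AA20, 3), ncol = 1))
  expect_equal(logo_matrix(unif)$bits, 0, tolerance = 1e-9)

  half <- alignment_from_matrix(matrix(rep(c("A", "C"), 20), ncol = 1))
  expect_equal(logo_matrix(half)$bits, log2(20) - 1, tolerance = 1e-9)

  # frequency mode has no bits; frequencies sum to 1 on ungapped columns
  lf <- logo_matrix(half, mode = "frequency")
  expect_null(lf$bits)
  expect_equal(unname(rowSums(lf$freq)), 1)

  # the small-sample correction lowers the information content
  small <- alignment_from_matrix(matrix("W", 5, 1))
  expect_lt(logo_matrix(small, small_sample_correction = TRUE)$bits,
            logo_matrix(small)$bits)
})

test_that("normalized Hamming distance follows the gap rules", {
  expect_equal(hamming_norm(c("A", "A"), c("A", "A")), 0)
  expect_equal(hamming_norm(strsplit("AAAA", "")[[1]],
                            strsplit("AATT", "")[[1]]), 0.5)
  # gap-gap columns drop out; gap-residue is a difference
  expect_equal(hamming_norm(c("A", "A", "-", "-"),
                            c("A", "A", "A", "-")), 1 / 3)
  expect_error(hamming_norm(c("-", "-"), c("-", "-")), "gap-gap")
  expect_error(hamming_norm(c("A"), c("A"), integer()), "non-empty")
})

test_that("Hamming distance is a metric on gap-free rows", {
  set.seed(42)
  for (rep in 1:25) {
    rows <- matrix(sample(c("A", "C", "D"), 3 * 6, replace = TRUE), 3)
    d <- function(i, j) hamming_norm(rows[i, ], rows[j, ])
    expect_equal(d(1, 2), d(2, 1))
    expect_equal(d(1, 1), 0)
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-12)
    if (!identical(rows[1, ], rows[2, ])) expect_gt(d(1, 2), 0)
  }
})

test_that("pairwise Hamming matrix summarizes off-diagonal pairs", {
  pm <- pairwise_hamming(rbind(c("A", "C"), c("A", "C"), c("C", "D")))
  expect_equal(pm$values, t(pm$values))
  expect_equal(diag(pm$values), rep(0, 3), ignore_attr = TRUE)
  expect_equal(sort(pm$values[upper.tri(pm$values)]), c(0, 1, 1))
  expect_equal(pm$summary$mean, 2 / 3)

  ident <- pairwise_hamming(matrix("A", 2, 4))
  expect_equal(ident$summary$mean, 0)

  distinct <- pairwise_hamming(rbind(c("A", "C"), c("D", "E"),
                                     c("F", "G")))
  expect_equal(distinct$summary$mean, 1)
  # summary is recomputable from the stored values
  off <- pairwise_values(distinct)
  expect_equal(distinct$summary$sd, sd(off))
})

test_that("subsampled conservation comparison flags planted differences only", {
  set.seed(9)
  # pool: 300 sequences, 6 columns at 50% conservation
  pool_mat <- matrix(sample(c("A", "C"), 300 * 6, replace = TRUE), 300)
  pool <- alignment_from_matrix(pool_mat)

  # null target: another draw from the same population
  null_mat <- matrix(sample(c("A", "C"), 90 * 6, replace = TRUE), 90)
  res_null <- bootstrap_conservation_compare(
    conservation_profile(alignment_from_matrix(null_mat)), pool,
    n_draws = 6, draw_size = 90, seed = 1)
  expect_lte(sum(res_null$flag), 1L)

  # planted target: column 1 fully conserved
  forced <- null_mat
  forced[, 1] <- "A"
  res <- bootstrap_conservation_compare(
    conservation_profile(alignment_from_matrix(forced)), pool,
    n_draws = 6, draw_size = 90, seed = 1)
  expect_true(res$flag[1])
  expect_equal(res$direction[1], "more")

  # reproducible under a fixed seed
  res2 <- bootstrap_conservation_compare(
    conservation_profile(alignment_from_matrix(forced)), pool,
    n_draws = 6, draw_size = 90, seed = 1)
  expect_identical(res, res2)

  expect_error(bootstrap_conservation_compare(
    conservation_profile(pool), pool, n_draws = 1), "n_draws")
  expect_error(bootstrap_conservation_compare(
    conservation_profile(pool),
    alignment_from_matrix(pool_mat[1:10, ]), draw_size = 90),
    "draw_size")
})

test_that("unpaired t test matches the closed-form pooled statistic", {
  same <- t_test_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shift <- t_test_unpaired(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p, 0.05)

  a <- c(1, 2); b <- c(3, 4)
  sp2 <- (stats::var(a) + stats::var(b)) / 2
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  p_manual <- 2 * stats::pt(-abs(t_manual), df = 2)
  got <- t_test_unpaired(a, b)
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$p, p_manual, tolerance = 1e-12)
  expect_equal(got$df, 2)
  # Welch variant differs when variances do
  w <- t_test_unpaired(c(1, 2, 3), c(10, 20, 35), welch = TRUE)
  s <- t_test_unpaired(c(1, 2, 3), c(10, 20, 35), welch = FALSE)
  expect_false(isTRUE(all.equal(w$df, s$df)))
})

test_that("KL divergence matches direct summation and handles support", {
  p <- c("10" = 0.5, "11" = 0.5)
  expect_equal(kl_divergence(p, p), 0)

  q <- c("10" = 0.25, "11" = 0.75)
  expect_equal(kl_divergence(p, q), 0.5 * log(2) + 0.5 * log(2 / 3),
               tolerance = 1e-12)
  expect_equal(kl_divergence(p, q), 0.1438, tolerance = 1e-3)
  expect_equal(kl_divergence(p, q, base = "2"),
               kl_divergence(p, q) / log(2), tolerance = 1e-12)

  # support violation without smoothing is explicitly infinite
  r <- c("10" = 1)
  expect_warning(v <- kl_divergence(p, r, pseudocount = 0), "support")
  expect_identical(v, Inf)
  expect_lt(kl_divergence(p, r, pseudocount = 0.5), Inf)
  expect_error(kl_divergence(p, q, pseudocount = -1), "pseudocount")
})

test_that("KL divergence is non-negative and zero only at equality", {
  set.seed(3)
  for (rep in 1:30) {
    k <- sample(3:8, 1)
    p <- stats::runif(k); p <- p / sum(p); names(p) <- 1:k
    q <- stats::runif(k); q <- q / sum(q); names(q) <- 1:k
    expect_gte(kl_divergence(p, q), 0)
  }
  u <- c("1" = 0.3, "2" = 0.7)
  expect_equal(kl_divergence(u, u, pseudocount = 0.1), 0)
})
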