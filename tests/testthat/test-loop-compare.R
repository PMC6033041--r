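test_that("loop lengths count non-gap characters on the full alignment", {
  mat <- rbind(strsplit("AB-CD", "")[[1]],
               strsplit("-----", "")[[1]],
               strsplit("ABCDE", "")[[1]])
  aln <- alignment_from_matrix(mat)
  expect_message(ll <- loop_lengths(aln, 1:5, "H1"), "all-gap")
  expect_equal(ll$records$length, c(4L, 0L, 5L))
  expect_true(ll$records$all_gap[2])
  expect_equal(ll$records$seq[1], "ABCD")
  expect_equal(ll$summary$median, 4)
})

test_that("length distributions normalize and mix linearly", {
  d <- length_distribution(c(15L, 15L, 12L))
  expect_equal(d[["15"]], 2 / 3)
  expect_equal(d[["12"]], 1 / 3)
  expect_equal(sum(d), 1)

  expect_equal(unname(length_distribution(7L)), 1)

  a <- c(10L, 10L, 12L)
  b <- c(12L, 14L, 14L)
  mix <- length_distribution(c(a, b))
  da <- length_distribution(a)
  db <- length_distribution(b)
  sup <- union(names(da), names(db))
  manual <- (ifelse(sup %in% names(da), da[sup], 0) * length(a) +
             ifelse(sup %in% names(db), db[sup], 0) * length(b)) /
    (length(a) + length(b))
  expect_equal(unname(mix[sup]), unname(manual))
})

test_that("comparing a family with itself shows no contrasts", {
  fam <- generate_family(family_spec(
    name = "null", n = 16, seed = 41,
    paratope_positions = c(28, 45, 107),
    paratope_propensity = c(0.4, 0.5, 0.4)), tempfile("null"))
  ds1 <- family_dataset(fam)
  ds2 <- family_dataset(fam)
  ds2$name <- "null2"
  rep <- run_comparison(ds1, ds2, comparison_config(seed = 3))

  expect_equal(rep$a$fr_rmsd$summary$mean, rep$b$fr_rmsd$summary$mean)
  expect_equal(rep$a$paratope$positions_full,
               rep$b$paratope$positions_full)
  for (nm in c("H1", "H2", "H3")) {
    cl <- rep$cross$loops[[nm]]
    expect_equal(cl$kl_length_a_from_b, 0, tolerance = 1e-9)
    expect_equal(cl$t_rmsd_fr_fit$t, 0, tolerance = 1e-9)
    expect_gt(cl$t_length$p, 0.99)
  }
  expect_equal(rep$cross$t_fr_rmsd$p, 1, tolerance = 1e-6)
  # identical target and pool: at most sampling noise in the flags
  expect_lte(rep$cross$bootstrap$n_flagged_a,
             ceiling(0.1 * rep$cross$bootstrap$n_common_positions))
})

test_that("planted family contrasts are recovered in direction", {
  pair <- get_small_pair(n = 20, seed = 101)
  rep <- run_comparison(family_dataset(pair$nb),
                        family_dataset(pair$ab),
                        comparison_config(seed = 5))
  # tighter framework, noisier H1/H3, longer H3, broader paratope
  expect_lt(rep$a$fr_rmsd$summary$mean, rep$b$fr_rmsd$summary$mean)
  expect_gt(rep$a$loops$H1$rmsd_self_fit$summary$mean,
            rep$b$loops$H1$rmsd_self_fit$summary$mean)
  expect_gt(rep$a$loops$H3$rmsd_fr_fit$summary$mean,
            rep$b$loops$H3$rmsd_fr_fit$summary$mean)
  expect_gt(rep$a$loops$H3$lengths$summary$mean,
            rep$b$loops$H3$lengths$summary$mean)
  expect_gt(rep$a$paratope$breadth, rep$b$paratope$breadth)
  expect_gt(rep$a$loops$H3$hamming$summary$mean,
            rep$b$loops$H3$hamming$summary$mean)
  # framework more conserved in the nb-like family
  fr_full <- reduced_to_full(rep$a$red_aln,
                             region_positions(rep$a$map, "FR"))
  boot <- rep$cross$bootstrap$a_vs_b
  fr_flags <- boot[boot$position %in% fr_full & boot$flag, ]
  expect_gt(sum(fr_flags$direction == "more"),
            sum(fr_flags$direction == "less"))
})

test_that("loop-noise ordering is recovered across independent seeds", {
  # 2x noise contrast in H3: the fitted RMSD ordering must match the
  # planted ordering in >= 95% of replicates
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    lo <- generate_family(family_spec(
      name = "lo", n = 8, seed = 500 + s, miss_frac = 0,
      loop_sigma = c(H1 = 0.6, H2 = 0.6, H3 = 1.0)),
      tempfile())
    hi <- generate_family(family_spec(
      name = "hi", n = 8, seed = 900 + s, miss_frac = 0,
      loop_sigma = c(H1 = 0.6, H2 = 0.6, H3 = 2.0)),
      tempfile())
    h3_rmsd <- function(fam) {
      ds <- family_dataset(fam)
      aln <- load_numbering_tables(ds$numbering)
      red <- reduce_alignment(aln)
      map <- region_map_from_labels(
        fam$spec$layout$labels[red$full_positions])
      coords <- coord_sets(ds$records, ds$numbering,
                           fam$spec$layout$length)
      pairwise_rmsd(coords,
                    reduced_to_full(red, region_positions(map, "H3"))
                    )$summary$mean
    }
    if (h3_rmsd(hi) > h3_rmsd(lo)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("reports serialize deterministically for a fixed seed", {
  pair <- get_small_pair(n = 20, seed = 101)
  cfg <- comparison_config(seed = 9)
  r1 <- run_comparison(family_dataset(pair$nb),
                       family_dataset(pair$ab), cfg)
  r2 <- run_comparison(family_dataset(pair$nb),
                       family_dataset(pair$ab), cfg)
  d1 <- tempfile("rep1"); d2 <- tempfile("rep2")
  write_report(r1, d1)
  write_report(r2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  # the full TSV surface is reproduced as well
  expect_identical(list.files(d1), list.files(d2))
})
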