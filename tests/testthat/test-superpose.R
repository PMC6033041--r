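test_that("kabsch recovers exact rigid motions", {
  set.seed(1)
  X <- matrix(rnorm(5 * 3), 5)
  same <- kabsch(X, X)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)

  # 90-degree rotation about z plus a translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  Y <- X %*% t(Rz) + matrix(c(5, 0, 0), 5, 3, byrow = TRUE)
  expect_equal(kabsch(X, Y)$rmsd, 0, tolerance = 1e-9)

  # invariance under arbitrary proper rigid motions of either side
  for (rep in 1:10) {
    R <- random_rotation()
    t_vec <- rnorm(3, sd = 10)
    Y2 <- X %*% t(R) + matrix(t_vec, 5, 3, byrow = TRUE)
    Ynoisy <- Y2 + matrix(rnorm(15, sd = 0.3), 5)
    base <- kabsch(X, Ynoisy)$rmsd
    moved <- kabsch(X %*% t(R) + matrix(t_vec, 5, 3, byrow = TRUE),
                    Ynoisy %*% t(R) + matrix(t_vec, 5, 3, byrow = TRUE))
    expect_equal(moved$rmsd, base, tolerance = 1e-6)
    expect_equal(det(moved$rotation), 1, tolerance = 1e-9)
  }
})

test_that("the returned transform attains the returned rmsd", {
  set.seed(2)
  X <- matrix(rnorm(6 * 3), 6)
  Y <- X + matrix(rnorm(18, sd = 0.5), 6)
  kb <- kabsch(X, Y)
  Yt <- Y %*% kb$rotation + matrix(kb$translation, 6, 3, byrow = TRUE)
  expect_equal(sqrt(mean(rowSums((X - Yt)^2))), kb$rmsd,
               tolerance = 1e-9)
})

test_that("kabsch equals numerical minimization on small point sets", {
  set.seed(7)
  for (rep in 1:6) {
    n <- sample(3:6, 1)
    X <- matrix(rnorm(n * 3, sd = 2), n)
    Y <- matrix(rnorm(n * 3, sd = 2), n)
    expect_equal(kabsch(X, Y)$rmsd, rmsd_numeric_oracle(X, Y),
                 tolerance = 1e-3)
  }
  # unit triangle with one vertex displaced by 1 A
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  Y <- X
  Y[3, ] <- Y[3, ] + c(0, 1, 0)
  expect_equal(kabsch(X, Y)$rmsd, rmsd_numeric_oracle(X, Y),
               tolerance = 1e-3)
})

test_that("degenerate and undersized inputs are reported", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)),
               "insufficient points")
  line <- cbind(0:3, 0, 0)
  expect_warning(kabsch(line, line + 0.5), "degenerate")
})

test_that("pairwise RMSD matches per-pair superposition and handles gaps", {
  set.seed(11)
  p <- 20
  base <- cbind(seq_len(p) * 2, sin(seq_len(p)), cos(seq_len(p)))
  mk <- function(sd) base + matrix(rnorm(p * 3, sd = sd), p)
  coords <- list(s1 = mk(0.3), s2 = mk(0.3), s3 = mk(0.3))

  pm <- pairwise_rmsd(coords, 1:p)
  expect_equal(pm$values, t(pm$values))
  expect_equal(diag(pm$values), rep(0, 3), ignore_attr = TRUE)
  # each entry equals an independent one-vs-one superposition
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(pm$values[i, j],
                 kabsch(coords[[i]], coords[[j]])$rmsd,
                 tolerance = 1e-12)
  }

  ident <- pairwise_rmsd(list(a = base, b = base), 1:p)
  expect_equal(ident$summary$mean, 0, tolerance = 1e-9)

  # fit == measure positions equals the direct superposition rmsd
  sub <- 3:12
  pm_sub <- pairwise_rmsd(coords[1:2], sub)
  expect_equal(pm_sub$values[1, 2],
               kabsch(coords$s1[sub, ], coords$s2[sub, ])$rmsd,
               tolerance = 1e-12)

  # measure-frame separation: fit on one region, measure another
  fitpos <- 1:10
  measpos <- 11:20
  pm_fm <- pairwise_rmsd(coords[1:2], fitpos, measpos)
  kb <- kabsch(coords$s1[fitpos, ], coords$s2[fitpos, ])
  Yt <- coords$s2[measpos, ] %*% kb$rotation +
    matrix(kb$translation, 10, 3, byrow = TRUE)
  expect_equal(pm_fm$values[1, 2],
               sqrt(mean(rowSums((coords$s1[measpos, ] - Yt)^2))),
               tolerance = 1e-12)
})

test_that("missing coordinates restrict pairs to common positions", {
  set.seed(12)
  p <- 12
  base <- cbind(seq_len(p) * 3, 0, 0) + matrix(rnorm(p * 3), p)
  a <- base; a[1:2, ] <- NA
  b <- base; b[3, ] <- NA
  pm <- pairwise_rmsd(list(a = a, b = b), 1:p)
  expect_equal(pm$n_common[1, 2], p - 3L)

  # a pair with <3 common fit positions is excluded, not fabricated
  c1 <- base; c1[4:p, ] <- NA   # only positions 1:3
  c2 <- base; c2[c(1, 4:p), ] <- NA  # only positions 2:3 -> 2 common
  expect_message(pm2 <- pairwise_rmsd(list(c1 = c1, c2 = c2), 1:p),
                 "excluded")
  expect_true(is.na(pm2$values[1, 2]))
  expect_equal(nrow(pm2$missing_pairs), 1L)
})

test_that("per-position profiles localize planted deviations", {
  set.seed(13)
  p <- 15
  base <- cbind(seq_len(p) * 2.5, sin(seq_len(p)) * 3, 0)
  coords <- lapply(1:6, function(i) {
    m <- base + matrix(rnorm(p * 3, sd = 0.05), p)
    if (i > 3) m[8, ] <- m[8, ] + c(0, 0, 2)  # displace position 8
    m
  })
  names(coords) <- paste0("s", 1:6)
  prof <- per_position_rmsd(coords, seq_len(p))
  expect_equal(which.max(prof$mean_dev), 8L)
  expect_gt(prof$mean_dev[8], max(prof$mean_dev[-8]))

  ident <- per_position_rmsd(list(a = base, b = base), seq_len(p))
  expect_equal(ident$mean_dev, rep(0, p), tolerance = 1e-9)

  # homogeneous isotropic noise: position profile mean ~ matrix mean
  coords2 <- lapply(1:8, function(i) base + matrix(rnorm(p * 3, sd = 0.4), p))
  names(coords2) <- paste0("r", 1:8)
  prof2 <- per_position_rmsd(coords2, seq_len(p))
  pm2 <- pairwise_rmsd(coords2, seq_len(p))
  expect_equal(mean(prof2$mean_dev), pm2$summary$mean, tolerance = 0.1)
})
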