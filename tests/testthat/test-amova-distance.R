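# Distance matrices, hierarchical AMOVA and Mantel correlation.

# independent brute-force variance decomposition for a one-level design,
# coded directly from the sums-of-squares definitions
brute_amova2 <- function(d2, pops) {
  n <- length(pops)
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d2[i, j]
  ss_t <- ss_t / n
  ss_w <- 0
  for (p in unique(pops)) {
    idx <- which(pops == p)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a < b) s <- s + d2[idx[a], idx[b]]
      }
    }
    ss_w <- ss_w + s / length(idx)
  }
  P <- length(unique(pops))
  sizes <- table(pops)
  ms_a <- (ss_t - ss_w) / (P - 1)
  ms_w <- ss_w / (n - P)
  nc <- (n - sum(sizes^2) / n) / (P - 1)
  sigma_a <- (ms_a - ms_w) / nc
  list(sigma_a = sigma_a, sigma_w = ms_w,
       phi_st = sigma_a / (sigma_a + ms_w))
}

test_that("AMOVA components equal the brute-force decomposition", {
  set.seed(21)
  pops <- rep(c("A", "B", "C"), each = 4)
  hg <- sample(c("x", "y", "z"), 12, replace = TRUE, prob = c(.5, .3, .2))
  tb <- toy_y_table(pops, hg, data.frame(DYS19 = rep(14L, 12)))
  d2 <- pairwise_d2(tb, "haplogroup")
  fit <- amova(d2, pops, n_perm = 0)
  oracle <- brute_amova2(d2, pops)
  expect_equal(unname(fit$sigma["among_populations"]), oracle$sigma_a,
               tolerance = 1e-12)
  expect_equal(unname(fit$sigma["within_populations"]), oracle$sigma_w,
               tolerance = 1e-12)
  expect_equal(unname(fit$phi["phi_st"]), oracle$phi_st, tolerance = 1e-12)
})

test_that("AMOVA limits: panmixia gives ~0, fixation gives 1", {
  # two populations fixed for different haplogroups
  tb <- toy_y_table(rep(c("A", "B"), each = 5),
                    rep(c("x", "y"), each = 5),
                    data.frame(DYS19 = rep(14L, 10)))
  fit <- amova(tb, n_perm = 99, seed = 3)
  expect_equal(unname(fit$phi["phi_st"]), 1)
  expect_lte(fit$p_values[["phi_st"]], 1 / 100)

  # two samples from one pool: phi near 0
  set.seed(5)
  hg <- sample(c("x", "y", "z"), 40, replace = TRUE)
  tb0 <- toy_y_table(rep(c("A", "B"), each = 20), hg,
                     data.frame(DYS19 = rep(14L, 40)))
  fit0 <- amova(tb0, n_perm = 99, seed = 4)
  expect_lt(abs(fit0$phi[["phi_st"]]), 0.15)
})

test_that("three-level AMOVA satisfies its internal identities", {
  set.seed(8)
  pops <- rep(paste0("P", 1:4), each = 5)
  groups <- setNames(c("G1", "G1", "G2", "G2"), paste0("P", 1:4))
  hg <- c(sample(c("x", "y"), 10, TRUE, c(.8, .2)),
          sample(c("y", "z"), 10, TRUE, c(.7, .3)))
  tb <- toy_y_table(pops, hg, data.frame(DYS19 = rep(14L, 20)))
  fit <- amova(tb, groups = groups, n_perm = 199, seed = 9)
  s <- fit$sigma
  expect_equal(sum(fit$percent), 100, tolerance = 1e-9)
  expect_equal(unname(fit$phi["phi_st"]),
               unname((s[1] + s[2]) / sum(s)), tolerance = 1e-12)
  expect_equal(unname(fit$phi["phi_ct"]), unname(s[1] / sum(s)),
               tolerance = 1e-12)
  expect_equal(unname(fit$phi["phi_sc"]), unname(s[2] / (s[2] + s[3])),
               tolerance = 1e-12)
  # p-values have permutation-count granularity
  expect_true(all(abs(fit$p_values * 200 -
                        round(fit$p_values * 200)) < 1e-9))
})

test_that("AMOVA errors name degenerate designs", {
  tb <- toy_y_table(c("A", "A", "B"), c("x", "y", "x"),
                    data.frame(DYS19 = rep(14L, 3)))
  expect_error(amova(tb, n_perm = 0), "B")
})

test_that("island-model divergence increases Phi_ST monotonically", {
  phi_at <- function(delta, seed) {
    set.seed(seed)
    p1 <- c(0.5 + delta / 2, 0.5 - delta / 2)
    p2 <- rev(p1)
    hg1 <- sample(c("x", "y"), 60, TRUE, p1)
    hg2 <- sample(c("x", "y"), 60, TRUE, p2)
    tb <- toy_y_table(rep(c("A", "B"), each = 60), c(hg1, hg2),
                      data.frame(DYS19 = rep(14L, 120)))
    amova(tb, n_perm = 0)$phi[["phi_st"]]
  }
  phis <- vapply(c(0.1, 0.5, 0.9), function(d) {
    mean(vapply(1:10, function(s) phi_at(d, 100 * d + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("pairwise molecular distances behave at their limits", {
  # identical populations: distance 0
  a <- toy_mt_table(rep("A", 4), rep("16224C", 4))
  b <- toy_mt_table(rep("B", 4), rep("16224C", 4))
  expect_equal(as.numeric(molecular_distance(a, b, "phi_st")), 0)
  # fixed for haplotypes differing at one site: Phi_ST = 1
  c2 <- toy_mt_table(rep("B", 4), rep("16311T", 4))
  expect_equal(as.numeric(molecular_distance(a, c2, "phi_st")), 1)
  # 3+3 toy equals the brute-force decomposition
  x <- toy_mt_table(rep("A", 3), c("16224C", "16224C", "16224C;16311T"))
  y <- toy_mt_table(rep("B", 3), c("16093C", "16093C;16126C", "16093C"))
  d <- molecular_distance(x, y, "phi_st")
  tb <- toy_mt_table(rep(c("A", "B"), each = 3),
                     c("16224C", "16224C", "16224C;16311T",
                       "16093C", "16093C;16126C", "16093C"))
  oracle <- brute_amova2(pairwise_d2(tb, "hvs"), rep(c("A", "B"), each = 3))
  expect_equal(attr(d, "raw"), oracle$phi_st, tolerance = 1e-12)
  expect_error(molecular_distance(a, a[0, ], "phi_st"), "empty")
})

test_that("R_ST uses squared repeat differences", {
  a <- toy_y_table(rep("A", 3), rep("R", 3),
                   data.frame(DYS19 = c(14L, 14L, 15L)))
  b <- toy_y_table(rep("B", 3), rep("R", 3),
                   data.frame(DYS19 = c(20L, 20L, 21L)))
  expect_gt(as.numeric(molecular_distance(a, b, "r_st")), 0.9)
})

test_that("Reynolds distance matches an independently coded formula", {
  p <- c(0.6, 0.3, 0.1); q <- c(0.2, 0.5, 0.3)
  # uncorrected textbook form, coded from scratch
  theta_u <- sum((p - q)^2) / (2 * (1 - sum(p * q)))
  expect_equal(reynolds_distance(p, q, 100, 100, corrected = FALSE),
               -log(1 - theta_u), tolerance = 1e-12)
  # corrected: identical samples of equal size give ~0
  expect_equal(reynolds_distance(c(30, 50, 20), c(30, 50, 20)), 0,
               tolerance = 1e-9)
  # disjoint fixed classes diverge
  expect_warning(
    d <- reynolds_distance(c(100, 0), c(0, 100), corrected = FALSE),
    "Inf")
  expect_identical(d, Inf)
})

test_that("great-circle distances follow the spherical closed forms", {
  m <- data.frame(population_id = c("a", "b"),
                  latitude = c(0, 0), longitude = c(0, 90))
  expect_equal(geographic_distance(m[1, ], m[2, ]), 6371 * pi / 2,
               tolerance = 1e-6)
  poles <- data.frame(population_id = c("n", "s"),
                      latitude = c(90, -90), longitude = c(0, 0))
  expect_equal(geographic_distance(poles[1, ], poles[2, ]), 6371 * pi,
               tolerance = 1e-6)
  expect_equal(geographic_distance(m[1, ], m[1, ]), 0)
  mat <- geographic_distance(m)
  expect_equal(mat["a", "b"], mat["b", "a"])
  bad <- data.frame(population_id = "x", latitude = 91, longitude = 0)
  expect_error(geographic_distance(bad), "invalid")
})

test_that("Mantel r matches hand computation and vegan, p is granular", {
  m1 <- matrix(0, 4, 4); m1[upper.tri(m1)] <- c(1, 2, 3, 4, 5, 6)
  m1 <- m1 + t(m1)
  m2 <- matrix(0, 4, 4); m2[upper.tri(m2)] <- c(2, 1, 4, 3, 6, 5)
  m2 <- m2 + t(m2)
  res <- mantel(m1, m2, n_perm = 199, seed = 1)
  # hand-coded Pearson on the 6 upper-triangle pairs
  x <- m1[upper.tri(m1)]; y <- m2[upper.tri(m2)]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$r, unname(vegan::mantel(m1, m2, permutations = 5)$statistic),
               tolerance = 1e-12)
  expect_true(abs(res$p * 200 - round(res$p * 200)) < 1e-9)

  # affinely related matrices: r = 1 at the smallest attainable p
  # (a larger matrix so no sampled permutation is self-equivalent)
  set.seed(33)
  big <- matrix(0, 8, 8)
  big[upper.tri(big)] <- runif(28)
  big <- big + t(big)
  res2 <- mantel(big, 2 * big, n_perm = 199, seed = 2)
  expect_equal(res2$r, 1)
  expect_equal(res2$p, 1 / 200)
  expect_error(mantel(matrix(1, 3, 3) - diag(3) * 0, m1[1:3, 1:3]),
               "constant|dimension")
})
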