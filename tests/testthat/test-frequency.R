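# Counting, diversity and enrichment statistics.

test_that("haplogroup counting and percentage view", {
  tb <- toy_y_table(rep("SSI", 6), c("G", "G", "E", "E", "E", NA),
                    data.frame(DYS19 = rep(14L, 6)))
  counts <- count_haplogroups(tb, "Y")
  expect_equal(unname(counts["SSI", "G"]), 2L)
  expect_equal(unname(counts["SSI", "E"]), 3L)
  expect_equal(attr(counts, "dropped"), 1L)

  pct <- haplogroup_percentages(counts)
  expect_equal(unname(pct["SSI", ]), c(60, 40))
  # empty table
  none <- toy_y_table(character(0), character(0),
                      data.frame(DYS19 = integer(0)))
  expect_equal(nrow(count_haplogroups(none, "Y")), 0)
})

test_that("row percentages sum to 100 within rounding", {
  set.seed(3)
  counts <- matrix(rpois(40, 20) + 1, nrow = 4,
                   dimnames = list(paste0("P", 1:4), paste0("H", 1:10)))
  pct <- haplogroup_percentages(counts)
  expect_true(all(abs(rowSums(pct) - 100) <= 0.5))
})

test_that("gene diversity matches direct evaluation and its properties", {
  expect_equal(gene_diversity(c(50))$H, 0)
  expect_equal(gene_diversity(c(1, 1))$H, 1)
  expect_equal(gene_diversity(c(2, 2))$H, (4 / 3) * (1 - 0.5))
  # invariant under relabeling
  expect_equal(gene_diversity(c(7, 3, 12))$H, gene_diversity(c(12, 7, 3))$H)
  # strictly increases when a monomorphic sample gains a new haplotype
  expect_gt(gene_diversity(c(49, 1))$H, gene_diversity(c(50))$H)
  expect_error(gene_diversity(c(1)), "n < 2")
  # SE agrees with the Nei variance evaluated directly
  x <- c(10, 6, 4)
  n <- sum(x); p <- x / n; s2 <- sum(p^2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  expect_equal(gene_diversity(x)$se, sqrt(v))
})

test_that("haplotype sharing counts distinct profiles and multiplicity", {
  tb <- toy_y_table(rep("P", 4), rep("R", 4),
                    data.frame(DYS19 = c(14L, 14L, 15L, 15L),
                               DYS390 = c(24L, 24L, 23L, 23L)))
  expect_equal(haplotype_sharing(tb), list(n_unique = 2L, max_shared = 2L))
  distinct <- toy_y_table(rep("P", 3), rep("R", 3),
                          data.frame(DYS19 = 14:16))
  expect_equal(haplotype_sharing(distinct),
               list(n_unique = 3L, max_shared = 1L))
  empty <- toy_y_table(character(0), character(0),
                       data.frame(DYS19 = integer(0)))
  expect_equal(haplotype_sharing(empty),
               list(n_unique = 0L, max_shared = 0L))
})

test_that("2x2 enrichment p equals the hypergeometric tail", {
  counts <- rbind(F1 = c(HG = 12, other = 88),
                  R1 = c(HG = 2, other = 98))
  res <- fisher_enrichment(counts, "F1", n_mc = 1000, seed = 1)
  # independent oracle: sum of hypergeometric point masses <= observed
  p_obs <- dhyper(12, 100, 100, 14)
  oracle <- sum(vapply(0:14, function(k) {
    pk <- dhyper(k, 100, 100, 14)
    if (pk <= p_obs * (1 + 1e-7)) pk else 0
  }, numeric(1)))
  row <- res$per_haplogroup[res$per_haplogroup$haplogroup == "HG", ]
  expect_equal(row$p, oracle, tolerance = 1e-10)
  expect_equal(row$direction, "over")

  # perfect symmetry: no enrichment signal
  sym <- rbind(A = c(x = 10, y = 90), B = c(x = 10, y = 90))
  res2 <- fisher_enrichment(sym, "A", n_mc = 1000, seed = 2)
  expect_equal(res2$per_haplogroup$p, c(1, 1))
})

test_that("Monte-Carlo r x c global p agrees with full enumeration", {
  obs <- matrix(c(6, 1, 1, 1, 5, 2, 1, 2, 5), nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("x", "y", "z")))
  # the global test pools focal vs rest; enumerate every 2x3 table with
  # the pooled margins and sum conditional probabilities <= observed
  pooled <- rbind(obs[1, ], colSums(obs[2:3, ]))
  rs <- rowSums(pooled); cs <- colSums(pooled); N <- sum(pooled)
  log_prob <- function(tab) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(tab))
  }
  lp_obs <- log_prob(pooled)
  p_exact <- 0
  for (a in 0:min(rs[1], cs[1])) {
    for (b in 0:min(rs[1] - a, cs[2])) {
      cc <- rs[1] - a - b
      if (cc > cs[3]) next
      tab <- rbind(c(a, b, cc), cs - c(a, b, cc))
      lp <- log_prob(tab)
      if (lp <= lp_obs + 1e-7) p_exact <- p_exact + exp(lp)
    }
  }
  B <- 1e5
  res <- fisher_enrichment(obs, "A", n_mc = B, seed = 7)
  mc_se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(res$global_p - p_exact), 3 * mc_se + 2 / B)
})

test_that("null enrichment p-values are uniform", {
  set.seed(11)
  ps <- vapply(1:500, function(i) {
    tab <- matrix(rmultinom(4, 40, c(0.4, 0.3, 0.2, 0.1)), nrow = 4,
                  byrow = TRUE,
                  dimnames = list(paste0("P", 1:4), paste0("H", 1:4)))
    fisher_enrichment(tab, c("P1", "P2"), n_mc = 2000,
                      seed = 1000 + i)$global_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Bonferroni chi-square comparisons follow the counting rules", {
  a <- c(R = 50, G = 30, E = 20)
  b <- c(R = 5, G = 40, E = 55)
  res <- pairwise_chisq_bonferroni(a, b, n_tests = 1)
  # closed-form continuity-corrected chi-square for the R lineage
  tab <- matrix(c(50, 50, 5, 95), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((abs(tab - e) - 0.5)^2 / e)
  expect_equal(res$p[res$haplogroup == "R"], pchisq(x2, 1, lower.tail = FALSE))

  # identical compositions: all adjusted p = 1
  same <- pairwise_chisq_bonferroni(a, a, n_tests = 3)
  expect_true(all(same$p_adjusted == 1))
  # cap at 1 and the minimum-frequency exclusion rule
  res2 <- pairwise_chisq_bonferroni(c(R = 12, G = 9, E = 100),
                                    c(R = 10, G = 50, E = 60), n_tests = 50)
  expect_false("G" %in% res2$haplogroup)  # focal count 9 < 10 excluded
  expect_true(all(res2$p_adjusted <= 1))
  expect_error(pairwise_chisq_bonferroni(a, b, n_tests = 0), "n_tests")
})
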