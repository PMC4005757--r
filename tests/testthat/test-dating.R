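# TMRCA estimation: modal haplotypes, outlier screening, the Y-STR
# variance estimator and the mtDNA rho clock.

eight_loci <- paste0("L", 1:8)
flat_rates <- setNames(rep(2e-3, 8), eight_loci)

toy_clock <- function(gen_years = 25, hvs_rate = 9058) {
  clock_config(generation_years = gen_years,
               hvs_rate_years_per_mutation = hvs_rate,
               dating_loci = eight_loci, locus_rates = flat_rates)
}

hg_table <- function(profiles, hg = "R") {
  profiles <- as.data.frame(profiles)
  toy_y_table(rep("P", nrow(profiles)), rep(hg, nrow(profiles)), profiles)
}

test_that("modal haplotype takes per-locus modes with the tie rule", {
  prof <- data.frame(L1 = c(13L, 13L, 14L, 14L, 15L),
                     L2 = c(24L, 24L, 24L, 23L, 23L))
  tb <- hg_table(prof)
  modal <- modal_haplotype(tb, c("L1", "L2"))
  # L1 ties {13:2, 14:2}: broken toward the smaller allele
  expect_equal(unname(modal["L1"]), 13L)
  expect_equal(unname(modal["L2"]), 24L)
  expect_true("L1" %in% attr(modal, "ties"))
  # brute-force check: mode of L2 by direct counting
  expect_equal(unname(modal["L2"]),
               as.integer(names(which.max(table(prof$L2)))))
  expect_error(modal_haplotype(hg_table(prof)[0, ], "L1"), "empty")
})

test_that("outlier screening removes only extreme haplotypes", {
  base <- matrix(14L, nrow = 11, ncol = 8,
                 dimnames = list(NULL, eight_loci))
  base[2:11, 1] <- c(13L, 15L, 14L, 14L, 13L, 15L, 14L, 14L, 13L, 15L)
  outlier <- base[1, , drop = FALSE] + 10L
  tb <- hg_table(rbind(base, outlier))
  kept <- flag_outliers(tb, loci = eight_loci)
  expect_equal(attr(kept, "n_removed"), 1L)
  expect_equal(attr(kept, "removed"), tb$individual_id[12])

  # homogeneous cluster: nothing removed
  clean <- hg_table(base)
  kept2 <- flag_outliers(clean, loci = eight_loci)
  expect_equal(attr(kept2, "n_removed"), 0L)

  # too small for the rule
  small <- hg_table(base[1:5, ])
  expect_warning(kept3 <- flag_outliers(small, loci = eight_loci),
                 "fewer than 8")
  expect_equal(attr(kept3, "n_removed"), 0L)
})

test_that("variance estimator obeys its algebra and refusal rules", {
  # identical haplotypes date to zero
  same <- hg_table(matrix(14L, nrow = 12, ncol = 8,
                          dimnames = list(NULL, eight_loci)))
  est <- tmrca_ystr(same, toy_clock())
  expect_equal(est$estimate_generations, 0)
  expect_equal(est$estimate_years, 0)

  # years are exactly generation_years x generations
  sim <- simulate_star_str(40, 120, setNames(rep(14L, 8), eight_loci),
                           flat_rates, seed = 31)
  est2 <- tmrca_ystr(sim, toy_clock(), remove_outliers = FALSE)
  expect_equal(est2$estimate_years, 25 * est2$estimate_generations)
  expect_equal(est2$se_years, 25 * est2$se_generations)
  # per-locus mean: recompute directly
  t_l <- vapply(eight_loci, function(l) var(sim[[l]]) / 2e-3, numeric(1))
  expect_equal(est2$estimate_generations, mean(t_l))
  expect_equal(est2$se_generations, sd(t_l) / sqrt(8))

  # shift invariance: adding a constant at one locus changes nothing
  shifted <- sim
  shifted$L3 <- shifted$L3 + 5L
  est3 <- tmrca_ystr(shifted, toy_clock(), remove_outliers = FALSE)
  expect_equal(est3$estimate_generations, est2$estimate_generations)

  # refusal below 10 usable individuals, naming the rule
  few <- hg_table(matrix(14L, nrow = 9, ncol = 8,
                         dimnames = list(NULL, eight_loci)))
  expect_error(suppressWarnings(tmrca_ystr(few, toy_clock())),
               "fewer than 10")
  # missing dating locus
  bad <- hg_table(matrix(14L, nrow = 12, ncol = 7,
                         dimnames = list(NULL, eight_loci[1:7])))
  expect_error(tmrca_ystr(bad, toy_clock()), "L8")
  # dating loci must number exactly 8
  short_clock <- clock_config(25, dating_loci = eight_loci[1:4],
                              locus_rates = flat_rates)
  expect_error(tmrca_ystr(sim, short_clock), "8 dating loci")
})

test_that("star simulations are recovered with small bias", {
  founder <- setNames(rep(14L, 8), eight_loci)
  ests <- vapply(1:60, function(i) {
    sim <- simulate_star_str(100, 160, founder, flat_rates, seed = 400 + i)
    tmrca_ystr(sim, toy_clock(), remove_outliers = FALSE)$estimate_generations
  }, numeric(1))
  expect_lt(abs(mean(ests) - 160) / 160, 0.05)
  # SE estimate of the right order: within a factor 2 of replicate SD
  sim <- simulate_star_str(100, 160, founder, flat_rates, seed = 999)
  se_hat <- tmrca_ystr(sim, toy_clock(),
                       remove_outliers = FALSE)$se_generations
  expect_lt(se_hat, 2 * sd(ests))
  expect_gt(se_hat, sd(ests) / 2)
})

test_that("rho statistic counts mutational distance to the root", {
  root <- c("16126C", "16224C")
  same <- toy_mt_table(rep("P", 5), rep(paste(root, collapse = ";"), 5))
  rs <- rho_statistic(same, root)
  expect_equal(rs$rho, 0)

  # each sequence one private variant: rho = 1 exactly
  one_off <- toy_mt_table(rep("P", 4),
                          paste0(paste(root, collapse = ";"), ";",
                                 c("16093T", "16189C", "16270T", "16311C")))
  rs1 <- rho_statistic(one_off, root)
  expect_equal(rs1$rho, 1)
  expect_equal(rs1$se, sqrt(1 / 4))

  # modal-root fallback announces itself
  expect_message(rho_statistic(same), "modal")
  expect_error(rho_statistic(same[0, ]), "hvs_variants|empty")
})

test_that("rho recovers a simulated Poisson clock age", {
  sim <- simulate_hvs(1000, c("16224C"), rate_years_per_mutation = 8000,
                      age_years = 16000, seed = 41)
  rs <- rho_statistic(sim, "16224C")
  expect_lt(abs(rs$rho - 2), 3 * rs$se)
  est <- tmrca_mtdna(rs$rho, rs$se, toy_clock(hvs_rate = 8000))
  expect_lt(abs(est$estimate_years - 16000), 3 * est$se_years)
  # linear clock arithmetic
  expect_equal(tmrca_mtdna(2, 0.1, toy_clock(hvs_rate = 10000))$estimate_years,
               20000)
  expect_equal(tmrca_mtdna(0, 0, toy_clock())$estimate_years, 0)
  no_rate <- clock_config(25, dating_loci = eight_loci,
                          locus_rates = flat_rates)
  expect_error(tmrca_mtdna(1, 0.1, no_rate), "hvs_rate")
})

test_that("the dating table mirrors the published layout", {
  founder <- setNames(rep(14L, 8), eight_loci)
  sim1 <- simulate_star_str(30, 150, founder, flat_rates, seed = 51)
  sim2 <- simulate_star_str(20, 60, founder, flat_rates, seed = 52)
  sim1$y_haplogroup <- "HG1"; sim2$y_haplogroup <- "HG2"
  few <- simulate_star_str(5, 60, founder, flat_rates, seed = 53)
  few$y_haplogroup <- "RARE"
  all3 <- rbind(as.data.frame(sim1), as.data.frame(sim2),
                as.data.frame(few))
  all3$individual_id <- make.unique(all3$individual_id)
  tb <- genotype_table(all3, "Y")
  tab <- suppressWarnings(ystr_dating_table(tb, toy_clock()))
  expect_setequal(tab$haplogroup, c("HG1", "HG2"))  # RARE has n < 10
  expect_equal(tab$n[tab$haplogroup == "HG1"], 30L)
  expect_equal(tab$tmrca_years, 25 * tab$sd_generations)
  expect_true(all(tab$pct == round(100 * tab$n / 55, 1)))
})
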