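# TMRCA estimation: Y-STR variance (SD) dating with outlier screening,
# and the mtDNA rho statistic with a linear HVS-I clock.

#' Modal haplotype of a haplogroup's STR records
#'
#' Per-locus mode of the repeat counts; ties are broken toward the smaller
#' allele (reported in the `ties` attribute).
#'
#' @param records `genotype_tbl` of one haplogroup.
#' @param loci loci to use (default: the analysis STR profile).
#' @return named integer vector, class `modal_haplotype`, with attribute
#'   `ties` listing tie-broken loci.
#' @export
modal_haplotype <- function(records, loci = str_loci(records)) {
  if (nrow(records) == 0) stop("empty haplogroup: no modal haplotype")
  ties <- character(0)
  modal <- vapply(loci, function(l) {
    tab <- table(records[[l]])
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) > 1) ties <<- c(ties, l)
    min(top)
  }, integer(1))
  structure(modal, ties = ties, class = "modal_haplotype")
}

#' Screen a haplogroup for outlier haplotypes
#'
#' Scores each individual by its mean squared repeat distance to the modal
#' haplotype over the dating loci and removes individuals whose score
#' exceeds Q3 + 3 IQR of the score distribution — single haplotypes many
#' mutational steps away would otherwise dominate the variance estimate.
#' With fewer than 8 individuals the rule is unreliable and nothing is
#' removed (with a warning).
#'
#' @param records `genotype_tbl` of one haplogroup.
#' @param modal a `modal_haplotype` (default: computed from `records`).
#' @param loci dating loci (default: the analysis STR profile).
#' @return the retained records; attribute `removed` holds the ids and
#'   `n_removed` the count.
#' @export
flag_outliers <- function(records, modal = NULL,
                          loci = str_loci(records)) {
  if (is.null(modal)) modal <- modal_haplotype(records, loci)
  n <- nrow(records)
  if (n < 8) {
    warning("fewer than 8 individuals: outlier screening skipped")
    attr(records, "removed") <- character(0)
    attr(records, "n_removed") <- 0L
    return(records)
  }
  prof <- as.matrix(records[, loci, drop = FALSE])
  score <- rowMeans(sweep(prof, 2, as.integer(modal[loci]))^2)
  q <- stats::quantile(score, c(0.25, 0.75), names = FALSE)
  cut <- q[2] + 3 * (q[2] - q[1])
  keep <- score <= cut
  out <- records[keep, , drop = FALSE]
  out <- structure(out, class = class(records),
                   marker_system = attr(records, "marker_system"),
                   str_loci = str_loci(records))
  attr(out, "removed") <- records$individual_id[!keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Y-STR variance (SD) TMRCA estimate for one haplogroup
#'
#' Under the single-step mutation model on a star genealogy the expected
#' repeat variance at a locus after t generations is rate x t, so each
#' locus dates the haplogroup as t_l = variance_l / rate_l.  The estimate
#' is the mean of t_l over the configured 8 dating loci, its SE the
#' between-locus standard deviation divided by sqrt(8), and years are
#' generations times `generation_years`; the 95% CI is estimate +/- 1.96 SE.
#' Haplogroups with fewer than 10 usable individuals are refused (sampling
#' error dominates below that).
#'
#' @param records `genotype_tbl` of one haplogroup.
#' @param clock a `clock_config` with `dating_loci` (exactly 8) and
#'   `locus_rates`.
#' @param remove_outliers apply [flag_outliers()] first (default TRUE).
#' @return a `tmrca_estimate`.
#' @export
tmrca_ystr <- function(records, clock, remove_outliers = TRUE) {
  loci <- clock$dating_loci
  if (is.null(loci) || length(loci) != 8) {
    stop("config error: exactly 8 dating loci must be configured")
  }
  miss <- setdiff(loci, names(records))
  if (length(miss)) {
    stop("dating locus missing from data: ", paste(miss, collapse = ", "))
  }
  n_removed <- 0L
  if (remove_outliers) {
    records <- flag_outliers(records, loci = loci)
    n_removed <- attr(records, "n_removed")
  }
  n <- nrow(records)
  if (n < 10) {
    stop("refusing to date a haplogroup with fewer than 10 individuals ",
         "(minimum absolute frequency rule); n = ", n)
  }
  t_l <- vapply(loci, function(l) {
    stats::var(records[[l]]) / clock$locus_rates[[l]]
  }, numeric(1))
  est <- mean(t_l)
  se <- stats::sd(t_l) / sqrt(length(loci))
  tmrca_estimate(
    haplogroup = if ("y_haplogroup" %in% names(records)) {
      records$y_haplogroup[1]
    } else NA_character_,
    n_samples = n, estimate_generations = est, se_generations = se,
    estimate_years = clock$generation_years * est,
    se_years = clock$generation_years * se,
    loci_used = loci, n_outliers_removed = n_removed)
}

#' The rho statistic for a set of HVS sequences
#'
#' Mean number of token differences (symmetric difference of variant sets,
#' restricted to the HVS-I window) between each sequence and the root
#' haplotype; the star-genealogy standard error is sqrt(rho / n).
#'
#' @param records `genotype_tbl` of one haplogroup with HVS variants.
#' @param root character vector of root variant tokens; if NULL the modal
#'   variant set (tokens carried by more than half the sequences) is used
#'   as the root, with a message.
#' @param region c(start, end) positions of the dating window (HVS-I
#'   default).
#' @return list with `rho`, `se`, `n`, `root`.
#' @export
rho_statistic <- function(records, root = NULL, region = HVS1_REGION) {
  sets <- hvs_variant_sets(records)
  if (!length(sets)) stop("empty haplogroup: rho undefined")
  clip <- function(v) {
    pos <- variant_positions(v)
    v[pos >= region[1] & pos <= region[2]]
  }
  sets <- lapply(sets, clip)
  if (is.null(root)) {
    all_tok <- unlist(sets)
    tab <- table(all_tok)
    root <- names(tab)[tab > length(sets) / 2]
    message("no root supplied: using the modal variant set (",
            length(root), " tokens)")
  } else {
    root <- clip(sort(unique(toupper(root))))
  }
  diffs <- vapply(sets, function(v) {
    length(setdiff(v, root)) + length(setdiff(root, v))
  }, numeric(1))
  rho <- mean(diffs)
  list(rho = rho, se = sqrt(rho / length(sets)), n = length(sets),
       root = root)
}

#' Convert a rho statistic to a TMRCA in years
#'
#' Linear HVS-I clock: years = rho x calibration (years per mutation, a
#' Soares-style HVS-I calibration supplied in the clock config — never
#' assumed).
#'
#' @param rho rho statistic (mean mutational distance to the root).
#' @param se_rho its standard error.
#' @param clock a `clock_config` with `hvs_rate_years_per_mutation`.
#' @param haplogroup optional label.
#' @param n_samples optional sample size.
#' @return a `tmrca_estimate`.
#' @export
tmrca_mtdna <- function(rho, se_rho, clock, haplogroup = NA_character_,
                        n_samples = NA_integer_) {
  rate <- clock$hvs_rate_years_per_mutation
  if (is.null(rate) || rate <= 0) {
    stop("config error: hvs_rate_years_per_mutation must be supplied ",
         "and > 0")
  }
  tmrca_estimate(haplogroup = haplogroup, n_samples = n_samples,
                 estimate_years = rho * rate, se_years = se_rho * rate,
                 rho = rho, region_used = "HVS-I",
                 calibration_years_per_mutation = rate)
}

tmrca_estimate <- function(haplogroup, n_samples,
                           estimate_generations = NA_real_,
                           se_generations = NA_real_,
                           estimate_years, se_years,
                           loci_used = NULL, region_used = NULL,
                           n_outliers_removed = NA_integer_,
                           rho = NA_real_,
                           calibration_years_per_mutation = NA_real_) {
  structure(list(haplogroup = haplogroup, n_samples = n_samples,
                 estimate_generations = estimate_generations,
                 se_generations = se_generations,
                 estimate_years = estimate_years, se_years = se_years,
                 ci95_years = c(max(estimate_years - 1.96 * se_years, 0),
                                estimate_years + 1.96 * se_years),
                 loci_used = loci_used, region_used = region_used,
                 n_outliers_removed = n_outliers_removed, rho = rho,
                 calibration_years_per_mutation =
                   calibration_years_per_mutation),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat("TMRCA", if (!is.na(x$haplogroup)) paste0("(", x$haplogroup, ")"),
      ":", round(x$estimate_years), "+/-", round(x$se_years), "YBP")
  if (!is.na(x$estimate_generations)) {
    cat(sprintf("  [%.1f +/- %.1f generations, %d outliers removed]",
                x$estimate_generations, x$se_generations,
                x$n_outliers_removed))
  }
  if (!is.na(x$rho)) cat(sprintf("  [rho = %.3f]", x$rho))
  cat("\n")
  invisible(x)
}

#' Dating table for the frequent haplogroups of a Y-STR data set
#'
#' Runs the variance (SD) estimator on every haplogroup with at least
#' `min_n` members and returns a table of N, %, SD (generations), SE,
#' TMRCA (years) and SE — the layout of a published uniparental dating
#' table.
#'
#' @param records a `genotype_tbl` with Y haplogroup calls.
#' @param clock a `clock_config`.
#' @param min_n minimum absolute haplogroup frequency (default 10).
#' @return data.frame, one row per dated haplogroup.
#' @export
ystr_dating_table <- function(records, clock, min_n = 10) {
  counts <- table(records$y_haplogroup)
  total <- nrow(records)
  hgs <- names(counts)[counts >= min_n]
  rows <- lapply(hgs, function(h) {
    est <- tmrca_ystr(subset_hg(records, h), clock)
    data.frame(haplogroup = h, n = as.integer(counts[[h]]),
               pct = round(100 * counts[[h]] / total, 1),
               sd_generations = est$estimate_generations,
               se_generations = est$se_generations,
               tmrca_years = est$estimate_years,
               se_years = est$se_years,
               n_outliers_removed = est$n_outliers_removed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

subset_hg <- function(records, hg) {
  sub <- records[!is.na(records$y_haplogroup) &
                   records$y_haplogroup == hg, , drop = FALSE]
  structure(sub, class = class(records),
            marker_system = attr(records, "marker_system"),
            str_loci = str_loci(records))
}
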