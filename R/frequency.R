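# Haplogroup counting, diversity indices and enrichment tests.

#' Count haplogroups per population
#'
#' Direct counting of haplogroup calls; records without a call for the
#' requested system are dropped and tallied in the `dropped` attribute.
#'
#' @param records a `genotype_tbl`.
#' @param system "Y" or "MT".
#' @return populations x haplogroups integer count matrix with attribute
#'   `dropped` (number of records without a call).
#' @export
count_haplogroups <- function(records, system = c("Y", "MT")) {
  system <- match.arg(system)
  col <- if (system == "Y") "y_haplogroup" else "mt_haplogroup"
  if (!col %in% names(records)) {
    stop("no ", col, " column in this table")
  }
  hg <- records[[col]]
  keep <- !is.na(hg) & hg != MISSING_TOKEN & nzchar(hg)
  dropped <- sum(!keep)
  if (!any(keep)) {
    out <- matrix(integer(0), nrow = 0, ncol = 0)
    attr(out, "dropped") <- dropped
    return(out)
  }
  tab <- table(records$population_id[keep], hg[keep])
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  attr(out, "dropped") <- dropped
  out
}

#' Percentage view of a count matrix
#'
#' @param counts populations x haplogroups count matrix.
#' @param digits decimals for reporting (default 1, the conventional
#'   resolution of published haplogroup-frequency tables).
#' @return matrix of row percentages, rounded.
#' @export
haplogroup_percentages <- function(counts, digits = 1) {
  counts <- as.matrix(counts)
  round(100 * counts / rowSums(counts), digits)
}

#' Nei's unbiased gene diversity with its standard error
#'
#' H = n/(n-1) (1 - sum p_i^2) over haplogroup (or allele) classes, with the
#' standard Nei (1987) sampling variance.
#'
#' @param counts non-negative integer vector of class counts (n = sum >= 2).
#' @return list with `H`, `se`, `n`, `k` (number of observed classes).
#' @export
gene_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("gene diversity undefined for n < 2")
  p <- counts / n
  s2 <- sum(p^2)
  H <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(H = H, se = sqrt(max(v, 0)), n = n, k = length(counts))
}

#' Haplotype sharing summary
#'
#' Counts distinct full haplotypes (the complete multi-locus STR profile,
#' or the complete HVS variant set) and the largest multiplicity among them.
#'
#' @param records a `genotype_tbl`.
#' @return list with `n_unique` and `max_shared`.
#' @export
haplotype_sharing <- function(records) {
  keys <- haplotype_keys(records)
  if (length(keys) == 0) return(list(n_unique = 0L, max_shared = 0L))
  tab <- table(keys)
  list(n_unique = length(tab), max_shared = as.integer(max(tab)))
}

haplotype_keys <- function(records) {
  if (nrow(records) == 0) return(character(0))
  if (!is.null(str_loci(records)) && length(str_loci(records))) {
    apply(records[, str_loci(records), drop = FALSE], 1, paste,
          collapse = "-")
  } else if ("hvs_variants" %in% names(records)) {
    vapply(hvs_variant_sets(records), paste, character(1), collapse = ";")
  } else {
    stop("no STR loci or HVS variants to define haplotypes")
  }
}

#' Per-population diversity table
#'
#' Gene diversity on haplogroup counts plus haplotype counts and haplotype
#' diversity on the full multi-locus profile, per population.
#'
#' @param records a `genotype_tbl`.
#' @param system "Y" or "MT".
#' @return data.frame, one row per population.
#' @export
diversity_table <- function(records, system = c("Y", "MT")) {
  system <- match.arg(system)
  counts <- count_haplogroups(records, system)
  pops <- rownames(counts)
  rows <- lapply(pops, function(p) {
    gd <- gene_diversity(counts[p, ])
    sub <- records[records$population_id == p, , drop = FALSE]
    attr(sub, "str_loci") <- str_loci(records)
    class(sub) <- class(records)
    keys <- haplotype_keys(sub)
    hd <- if (length(keys) >= 2) {
      gene_diversity(as.integer(table(keys)))$H
    } else NA_real_
    data.frame(population_id = p, n = gd$n,
               gene_diversity = gd$H, gene_diversity_se = gd$se,
               n_haplotypes = length(unique(keys)),
               haplotype_diversity = hd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Haplogroup enrichment tests for a focal population group
#'
#' Per haplogroup, a 2x2 Fisher exact test of (focal vs rest) x (haplogroup
#' vs all others) with the direction read off the odds ratio; globally, an
#' r x c exact test of the pooled focal-versus-rest composition with a
#' seeded Monte-Carlo p-value (full enumeration being infeasible for
#' many-population, many-haplogroup tables).
#'
#' @param counts populations x haplogroups count matrix.
#' @param focal character vector of focal population ids (strict subset of
#'   rows).
#' @param n_mc Monte-Carlo table draws for the global test.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return list with `global_p` and `per_haplogroup` data.frame
#'   (odds_ratio, p, direction, flag).
#' @export
fisher_enrichment <- function(counts, focal, n_mc = 1e5, seed = NULL) {
  counts <- as.matrix(counts)
  if (!length(focal) || !all(focal %in% rownames(counts))) {
    stop("focal group must name existing populations")
  }
  if (setequal(focal, rownames(counts))) {
    stop("focal group must be a strict subset of populations")
  }
  f <- colSums(counts[focal, , drop = FALSE])
  r <- colSums(counts[setdiff(rownames(counts), focal), , drop = FALSE])
  pooled <- rbind(focal = f, rest = r)
  keep <- colSums(pooled) > 0
  global_p <- with_seed(seed,
    stats::fisher.test(pooled[, keep, drop = FALSE],
                       simulate.p.value = TRUE, B = n_mc)$p.value)
  per <- lapply(colnames(counts), function(h) {
    tab <- matrix(c(f[h], sum(f) - f[h], r[h], sum(r) - r[h]),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(data.frame(haplogroup = h, odds_ratio = NA_real_, p = 1,
                        direction = "none", flag = "zero-margin",
                        stringsAsFactors = FALSE))
    }
    ft <- stats::fisher.test(tab)
    direction <- if (ft$estimate > 1) "over" else if (ft$estimate < 1) {
      "under"
    } else "none"
    data.frame(haplogroup = h, odds_ratio = unname(ft$estimate),
               p = ft$p.value, direction = direction, flag = "",
               stringsAsFactors = FALSE)
  })
  list(global_p = global_p, per_haplogroup = do.call(rbind, per))
}

#' Bonferroni-corrected per-lineage chi-square comparisons
#'
#' Compares single-lineage frequencies between a focal and a comparison
#' count vector with continuity-corrected 2x2 chi-square tests; lineages
#' with a focal absolute frequency below `min_focal` (default 10, the usual
#' sampling-error guard) are excluded.  P-values are multiplied by
#' `n_tests` and capped at 1.
#'
#' @param focal_counts,comparison_counts named count vectors over the same
#'   haplogroup labels.
#' @param n_tests Bonferroni multiplicity (>= 1); conventionally the number
#'   of lineages tested times the number of comparison groups.
#' @param min_focal minimum focal absolute frequency for a lineage to enter.
#' @return data.frame with raw and adjusted p-values per tested lineage.
#' @export
pairwise_chisq_bonferroni <- function(focal_counts, comparison_counts,
                                      n_tests, min_focal = 10) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  labels <- names(focal_counts)
  if (!identical(labels, names(comparison_counts))) {
    stop("count vectors must share the same haplogroup labels")
  }
  tested <- labels[focal_counts >= min_focal]
  nf <- sum(focal_counts); nc <- sum(comparison_counts)
  rows <- lapply(tested, function(h) {
    tab <- matrix(c(focal_counts[[h]], nf - focal_counts[[h]],
                    comparison_counts[[h]], nc - comparison_counts[[h]]),
                  nrow = 2, byrow = TRUE)
    p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
    data.frame(haplogroup = h,
               focal_count = focal_counts[[h]],
               comparison_count = comparison_counts[[h]],
               p = p, p_adjusted = min(1, p * n_tests),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(haplogroup = character(0), focal_count = integer(0),
                      comparison_count = integer(0), p = numeric(0),
                      p_adjusted = numeric(0)))
  }
  do.call(rbind, rows)
}
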