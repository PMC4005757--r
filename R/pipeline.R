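# Whole-survey orchestration: frequencies -> diversity -> regional
# structure (AMOVA / Fisher) -> distances + Mantel -> sPCA + tests ->
# clustering / DAPC membership -> enrichment -> TMRCA -> admixture.
# Every stage writes a TSV and logs its seed and permutation count; one
# global seed expands deterministically into per-stage seeds.

stage_seed <- function(seed, i) (seed + 7919L * i) %% 2147483647L

#' A fully synthetic input bundle for the pipeline
#'
#' Generates every input the pipeline consumes with known truth: a clinal
#' haplogroup frequency table with population metadata, star-genealogy
#' Y-STR records for two haplogroups of known age, HVS sequences of known
#' age, and a hybrid population of known admixture proportions.
#'
#' @param seed integer seed.
#' @param n_populations populations along the cline.
#' @param sample_size per-population sample size.
#' @return list with `counts`, `meta`, `records_y`, `records_mt`,
#'   `clock`, `admixture` (hybrid + parentals + truth) and the generator
#'   truths used.
#' @export
synthetic_bundle <- function(seed = 1, n_populations = 10,
                             sample_size = 60) {
  hgs <- paste0("HG", LETTERS[1:8])
  baseline <- c(0.22, 0.18, 0.15, 0.12, 0.11, 0.10, 0.07, 0.05)
  slopes <- c(0.09, -0.07, 0, 0, 0, 0, 0, 0)
  coords <- data.frame(
    # a west-east transect with coastline-like latitude zigzag (keeps the
    # configuration non-collinear so a Delaunay network exists)
    latitude = seq(34, 44, length.out = n_populations) +
      rep_len(c(-1.4, 1.1, 0.3, -0.8), n_populations),
    longitude = seq(-8, 32, length.out = n_populations))
  cline <- simulate_cline_frequencies(
    n_populations, hgs, baseline, slopes, coords,
    rep(sample_size, n_populations), seed = stage_seed(seed, 1))

  loci <- paste0("DYS", c(19, 390, 391, 392, 393, 437, 438, 439))
  rates <- stats::setNames(rep(2e-3, 8), loci)
  founder <- stats::setNames(rep(14L, 8), loci)
  clock <- clock_config(generation_years = 25,
                        hvs_rate_years_per_mutation = 9058,
                        dating_loci = loci, locus_rates = rates)
  sim_a <- simulate_star_str(60, 160, founder, rates,
                             seed = stage_seed(seed, 2))
  sim_b <- simulate_star_str(40, 80, founder, rates,
                             seed = stage_seed(seed, 3))
  sim_a$y_haplogroup <- "HG_OLD"; sim_b$y_haplogroup <- "HG_YOUNG"
  records_y <- rbind(as.data.frame(sim_a), as.data.frame(sim_b))
  records_y$individual_id <- make.unique(records_y$individual_id)
  records_y$population_id <-
    cline$meta$population_id[rep_len(seq_len(n_populations),
                                     nrow(records_y))]
  records_y <- genotype_table(records_y, "Y")

  records_mt <- simulate_hvs(80, c("16224C", "16311C"), 9058, 16000,
                             seed = stage_seed(seed, 4))
  records_mt$population_id <-
    cline$meta$population_id[rep_len(seq_len(n_populations), 80)]
  records_mt <- genotype_table(records_mt, "MT")

  parentals <- rbind(
    NCI = c(0.35, 0.25, 0.15, 0.10, 0.05, 0.04, 0.03, 0.03),
    BALK = c(0.10, 0.15, 0.30, 0.20, 0.10, 0.05, 0.05, 0.05),
    LEV = c(0.05, 0.05, 0.10, 0.15, 0.30, 0.20, 0.10, 0.05))
  colnames(parentals) <- hgs
  truth_w <- c(NCI = 0.60, BALK = 0.25, LEV = 0.15)
  hybrid <- simulate_admixed(parentals, truth_w, 400,
                             seed = stage_seed(seed, 5))
  parental_counts <- round(parentals * 200)

  list(counts = cline$counts, meta = cline$meta,
       expected = cline$expected,
       records_y = records_y, records_mt = records_mt, clock = clock,
       admixture = list(hybrid = hybrid, parentals = parental_counts,
                        truth = truth_w),
       truth = list(tmrca_old = 160, tmrca_young = 80,
                    mt_age_years = 16000, slopes = slopes))
}

#' Validate a pipeline configuration
#'
#' @param config list with at least `seed` and `out_dir`; optional
#'   `bundle` (a [synthetic_bundle()]-shaped list) or file paths
#'   (`genotype_y`, `genotype_mt`, `meta`, `clock`); optional `groupings`
#'   (named list: population_id -> group label), `n_perm`, `n_boot`.
#' @return the completed config (invisibly errors on any inconsistency
#'   before computation starts).
#' @export
pipeline_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed),
            !is.null(config$out_dir))
  for (f in c("genotype_y", "genotype_mt", "meta", "clock")) {
    if (is.character(config[[f]]) && !file.exists(config[[f]])) {
      stop("config error: file not found: ", config[[f]])
    }
  }
  config$n_perm <- config$n_perm %||% 999
  config$n_boot <- config$n_boot %||% 1000
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full population-structure pipeline
#'
#' Executes every analysis stage in survey order on the configured inputs,
#' writing one TSV per stage plus a run log (seeds, permutation counts,
#' dropped records, outliers) to `out_dir`.  Deterministic given the
#' config seed; any stage failure halts with the stage name, retaining
#' partial outputs.
#'
#' @param config a [pipeline_config()] list (a bare list is validated
#'   first).
#' @return invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  bundle <- config$bundle
  if (is.null(bundle)) {
    if (!is.null(config$genotype_y)) {
      bundle <- list(
        records_y = read_genotype_table(config$genotype_y, "Y"),
        records_mt = if (!is.null(config$genotype_mt)) {
          read_genotype_table(config$genotype_mt, "MT")
        },
        meta = utils::read.table(config$meta, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE),
        clock = if (!is.null(config$clock)) {
          read_clock_config(config$clock)
        })
      bundle$counts <- count_haplogroups(bundle$records_y, "Y")
    } else {
      bundle <- synthetic_bundle(seed)
    }
  }
  counts <- bundle$counts
  meta <- bundle$meta
  if (!is.null(config$groupings)) {
    for (g in names(config$groupings)) {
      unknown <- setdiff(names(config$groupings[[g]]),
                         meta$population_id)
      if (length(unknown)) {
        stop("config error: grouping '", g,
             "' references unknown population(s): ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  log_path <- file.path(out, "run_log.txt")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("popstruct pipeline run\n", file = log_path)
  logf("seed: ", seed, "; permutations: ", config$n_perm,
       "; bootstraps: ", config$n_boot)
  results <- list()
  run_stage <- function(name, expr) {
    logf("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  wtsv <- function(x, file, rn = TRUE) {
    utils::write.table(as.data.frame(x), file.path(out, file),
                       sep = "\t", quote = FALSE, row.names = rn,
                       col.names = if (rn) NA else TRUE)
  }

  results$freqs <- run_stage("frequencies", {
    wtsv(counts, "haplogroup_counts.tsv")
    wtsv(haplogroup_percentages(counts), "haplogroup_percentages.tsv")
    counts
  })

  results$diversity <- run_stage("diversity", {
    dv <- diversity_table(bundle$records_y, "Y")
    utils::write.table(dv, file.path(out, "diversity_y.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dv
  })

  results$regional <- run_stage("regional-structure", {
    groupings <- config$groupings %||% list(
      east_west = stats::setNames(
        ifelse(meta$longitude > stats::median(meta$longitude), "E", "W"),
        meta$population_id))
    lapply(stats::setNames(names(groupings), names(groupings)),
           function(g) {
      grp <- groupings[[g]]
      am <- amova(bundle$records_y, groups = grp,
                  n_perm = config$n_perm, seed = stage_seed(seed, 11))
      logf("  amova ", g, ": ", config$n_perm, " permutations, seed ",
           stage_seed(seed, 11))
      fe <- fisher_enrichment(counts,
                              names(grp)[grp == sort(unique(grp))[1]],
                              seed = stage_seed(seed, 12))
      wtsv(data.frame(component = names(am$sigma), sigma2 = am$sigma,
                      percent = am$percent),
           paste0("amova_", g, ".tsv"), rn = FALSE)
      list(amova = am, fisher_global_p = fe$global_p)
    })
  })

  results$distance <- run_stage("distances-mantel", {
    dr <- reynolds_matrix(counts)
    dg <- geographic_distance(meta)
    mt <- mantel(dr, dg, n_perm = config$n_perm,
                 seed = stage_seed(seed, 21))
    logf("  mantel: r = ", round(mt$r, 3), ", p = ", mt$p, ", ",
         mt$n_perm, " permutations")
    wtsv(dr, "dist_reynolds.tsv")
    wtsv(dg, "dist_geographic_km.tsv")
    list(reynolds = dr, geographic = dg, mantel = mt)
  })

  results$spca <- run_stage("spca", {
    w <- build_weights(meta)
    fit <- spca(counts, w)
    np <- max(config$n_perm, 99)  # the random tests need a floor
    gt <- spca_global_local_test(counts, w, "global", n_perm = np,
                                 seed = stage_seed(seed, 31))
    lt <- spca_global_local_test(counts, w, "local", n_perm = np,
                                 seed = stage_seed(seed, 32))
    logf("  spca: network = ", w$scheme, "; global p = ", gt$p,
         "; local p = ", lt$p)
    wtsv(fit$scores, "spca_scores.tsv")
    wtsv(fit$loadings, "spca_loadings.tsv")
    wtsv(data.frame(eigenvalue = fit$eigenvalues,
                    variance = fit$axis_variance,
                    moran_i = fit$axis_moran), "spca_eigen.tsv",
         rn = FALSE)
    list(fit = fit, global = gt, local = lt)
  })

  results$clusters <- run_stage("clustering-dapc", {
    pco <- stats::cmdscale(results$distance$reynolds,
                           k = min(3, nrow(counts) - 1))
    gm <- gaussian_mixture_bic(pco, k_range = 1:4,
                               seed = stage_seed(seed, 41))
    logf("  mclust: best k = ", gm$best_k, " (", gm$model, ")")
    memb <- if (gm$best_k >= 2) {
      freq <- counts / rowSums(counts)
      model <- dapc_fit(freq, gm$assignment)
      dapc_membership(model)
    } else NULL
    if (!is.null(memb)) wtsv(unclass(memb), "dapc_membership.tsv")
    list(mclust = gm, membership = memb)
  })

  results$enrichment <- run_stage("enrichment", {
    focal <- meta$population_id[seq_len(ceiling(nrow(meta) / 3))]
    fe <- fisher_enrichment(counts, focal, seed = stage_seed(seed, 51))
    utils::write.table(fe$per_haplogroup,
                       file.path(out, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fe
  })

  results$dating <- if (is.null(bundle$clock)) {
    logf("stage: tmrca skipped (no clock config)")
    NULL
  } else run_stage("tmrca", {
    dt <- ystr_dating_table(bundle$records_y, bundle$clock)
    utils::write.table(dt, file.path(out, "dating_y.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mt_est <- NULL
    if (!is.null(bundle$records_mt) &&
        !is.null(bundle$clock$hvs_rate_years_per_mutation)) {
      rs <- rho_statistic(bundle$records_mt,
                          root = config$mt_root %||% c("16224C", "16311C"))
      mt_est <- tmrca_mtdna(rs$rho, rs$se, bundle$clock,
                            haplogroup = bundle$records_mt$mt_haplogroup[1],
                            n_samples = rs$n)
      utils::write.table(
        data.frame(haplogroup = mt_est$haplogroup, n = rs$n, rho = rs$rho,
                   tmrca_years = mt_est$estimate_years,
                   se_years = mt_est$se_years),
        file.path(out, "dating_mt.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    logf("  dating: ", nrow(dt), " Y haplogroups; outliers removed: ",
         paste(dt$n_outliers_removed, collapse = ","))
    list(y = dt, mt = mt_est)
  })

  results$admixture <- if (is.null(bundle$admixture)) {
    logf("stage: admixture skipped (no parental model configured)")
    NULL
  } else run_stage("admixture", {
    ad <- bundle$admixture
    res <- my_bootstrap(ad$hybrid, ad$parentals,
                        n_boot = config$n_boot,
                        seed = stage_seed(seed, 61))
    logf("  admixture: ", config$n_boot, " bootstraps, seed ",
         stage_seed(seed, 61))
    utils::write.table(
      data.frame(parental = names(res$weights), weight = res$weights,
                 bootstrap_mean = res$bootstrap_mean,
                 bootstrap_sd = res$bootstrap_sd),
      file.path(out, "admixture.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    res
  })

  logf("completed")
  invisible(results)
}

#' Compare a subset's haplogroup composition with its complement
#'
#' Used e.g. to check whether a surname-selected (putatively older)
#' subsample differs from the full data set: a Monte-Carlo exact test of
#' the subset-versus-complement haplogroup table.
#'
#' @param records a `genotype_tbl`.
#' @param subset_ids individual ids forming the subset (non-empty, strict
#'   subset).
#' @param system "Y" or "MT".
#' @param n_mc Monte-Carlo draws.
#' @param seed integer seed.
#' @return the global p-value.
#' @export
subset_comparison <- function(records, subset_ids,
                              system = c("Y", "MT"), n_mc = 1e5,
                              seed = NULL) {
  system <- match.arg(system)
  unknown <- setdiff(subset_ids, records$individual_id)
  if (length(unknown)) {
    stop("subset id(s) not in data: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  if (!length(subset_ids)) stop("subset is empty")
  if (setequal(subset_ids, records$individual_id)) {
    stop("subset equals the full record set")
  }
  grp <- ifelse(records$individual_id %in% subset_ids,
                "subset", "complement")
  tmp <- records
  tmp$population_id <- grp
  tmp <- structure(tmp, class = class(records),
                   marker_system = attr(records, "marker_system"),
                   str_loci = str_loci(records))
  counts <- count_haplogroups(tmp, system)
  keep <- colSums(counts) > 0
  with_seed(seed,
    stats::fisher.test(counts[, keep, drop = FALSE],
                       simulate.p.value = TRUE, B = n_mc)$p.value)
}
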