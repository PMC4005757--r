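# Hierarchical analysis of molecular variance (AMOVA).
#
# Sums of squares are computed from squared inter-individual distances
# (SS of a set = sum of its squared distances / set size), variance
# components from the standard expected-mean-square equations for the
# one- and two-level hierarchical designs, and Phi statistics from the
# component ratios.  Significance is assessed by permutation, each Phi
# under its own permutation scheme.

ss_of_set <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx]) / (2 * length(idx))
}

amova_components <- function(d2, populations, groups = NULL) {
  n <- nrow(d2)
  pop_idx <- split(seq_len(n), populations)
  sizes <- lengths(pop_idx)
  P <- length(pop_idx)
  ss_t <- ss_of_set(d2, seq_len(n))
  ss_wp <- sum(vapply(pop_idx, function(i) ss_of_set(d2, i), numeric(1)))
  if (is.null(groups)) {
    df_a <- P - 1
    df_w <- n - P
    ms_a <- (ss_t - ss_wp) / df_a
    ms_w <- ss_wp / df_w
    n_c <- (n - sum(sizes^2) / n) / (P - 1)
    sigma_w <- ms_w
    sigma_a <- (ms_a - ms_w) / n_c
    total <- sigma_a + sigma_w
    return(list(
      sigma = c(among_populations = sigma_a, within_populations = sigma_w),
      df = c(among_populations = df_a, within_populations = df_w),
      ss = c(among_populations = ss_t - ss_wp, within_populations = ss_wp),
      phi = c(phi_st = if (total > 0) sigma_a / total else 0)))
  }
  grp_idx <- split(seq_len(n), groups)
  G <- length(grp_idx)
  ss_wg <- sum(vapply(grp_idx, function(i) ss_of_set(d2, i), numeric(1)))
  ss_ag <- ss_t - ss_wg          # among groups
  ss_ap <- ss_wg - ss_wp         # among populations within groups
  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- n - P
  ms_ag <- ss_ag / df_ag
  ms_ap <- ss_ap / df_ap
  ms_wp <- ss_wp / df_wp
  grp_sizes <- lengths(grp_idx)
  # sum over populations of n_p^2 / n_g(p)
  grp_of_pop <- vapply(names(pop_idx), function(p) {
    groups[match(p, populations)]
  }, character(1))
  s_pg <- sum(sizes^2 / grp_sizes[grp_of_pop])
  n1 <- (n - s_pg) / (P - G)
  n2 <- (s_pg - sum(sizes^2) / n) / (G - 1)
  n3 <- (n - sum(grp_sizes^2) / n) / (G - 1)
  sigma_c <- ms_wp
  sigma_b <- (ms_ap - ms_wp) / n1
  sigma_a <- (ms_ag - ms_wp - n2 * sigma_b) / n3
  total <- sigma_a + sigma_b + sigma_c
  list(
    sigma = c(among_groups = sigma_a,
              among_populations_within_groups = sigma_b,
              within_populations = sigma_c),
    df = c(among_groups = df_ag,
           among_populations_within_groups = df_ap,
           within_populations = df_wp),
    ss = c(among_groups = ss_ag,
           among_populations_within_groups = ss_ap,
           within_populations = ss_wp),
    phi = c(phi_ct = if (total > 0) sigma_a / total else 0,
            phi_sc = if (sigma_b + sigma_c > 0) {
              sigma_b / (sigma_b + sigma_c)
            } else 0,
            phi_st = if (total > 0) (sigma_a + sigma_b) / total else 0))
}

#' Hierarchical AMOVA with permutation tests
#'
#' Decomposes squared inter-individual molecular distances into within-
#' population, among-population (within groups) and among-group variance
#' components, reports the corresponding Phi statistics, and attaches
#' permutation p-values: individuals among populations for Phi_ST,
#' whole populations among groups for Phi_CT, and individuals among
#' populations within groups for Phi_SC.
#'
#' @param x a square matrix of squared inter-individual distances (e.g.
#'   from [pairwise_d2()]), or a `genotype_tbl` (then `kind` selects the
#'   distance and `populations` defaults to its population ids).
#' @param populations population assignment, one per individual.
#' @param groups optional group assignment (per individual or per
#'   population, named by population id) for the two-level design.
#' @param n_perm permutations (default 10000); 0 skips testing.
#' @param seed integer seed for the permutations.
#' @param kind distance kind when `x` is a genotype table (see
#'   [pairwise_d2()]).
#' @return an object of class `amova_result`.
#' @export
amova <- function(x, populations = NULL, groups = NULL, n_perm = 10000,
                  seed = NULL, kind = "haplogroup") {
  if (inherits(x, "genotype_tbl")) {
    if (is.null(populations)) populations <- x$population_id
    d2 <- pairwise_d2(x, kind)
  } else {
    d2 <- as.matrix(x)
    if (is.null(populations)) stop("populations required with a matrix")
  }
  n <- nrow(d2)
  populations <- as.character(populations)
  stopifnot(length(populations) == n)
  if (!is.null(groups) && length(groups) != n) {
    # per-population group labels, named by population id
    if (is.null(names(groups))) {
      stop("per-population groups must be named by population id")
    }
    groups <- unname(groups[populations])
  }
  sizes <- table(populations)
  if (any(sizes < 2)) {
    stop("population(s) of size 1 in the design: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (length(sizes) < 2) stop("at least two populations required")
  if (!is.null(groups)) {
    groups <- as.character(groups)
    gp <- tapply(groups, populations, function(g) {
      if (length(unique(g)) > 1) stop("population split across groups")
      g[1]
    })
    if (length(unique(gp)) < 2) {
      stop("at least two groups required for the two-level design")
    }
  }
  obs <- amova_components(d2, populations, groups)

  p_values <- NULL
  if (n_perm > 0) {
    p_values <- with_seed(seed, {
      if (is.null(groups)) {
        ge <- 0L
        for (b in seq_len(n_perm)) {
          perm <- sample(populations)
          st <- amova_components(d2, perm)$phi[["phi_st"]]
          if (st >= obs$phi[["phi_st"]] - 1e-12) ge <- ge + 1L
        }
        c(phi_st = (1 + ge) / (n_perm + 1))
      } else {
        ge_st <- ge_sc <- ge_ct <- 0L
        pops <- unique(populations)
        grp_of_pop <- vapply(pops, function(p) {
          groups[match(p, populations)]
        }, character(1))
        for (b in seq_len(n_perm)) {
          # Phi_ST: individuals among populations (groups follow pops)
          perm <- sample(seq_along(populations))
          st <- amova_components(d2, populations[perm],
                                 groups[perm])$phi[["phi_st"]]
          if (st >= obs$phi[["phi_st"]] - 1e-12) ge_st <- ge_st + 1L
          # Phi_CT: whole populations among groups
          g_perm <- sample(grp_of_pop)
          names(g_perm) <- pops
          ct <- amova_components(d2, populations,
                                 unname(g_perm[populations]))$phi[["phi_ct"]]
          if (ct >= obs$phi[["phi_ct"]] - 1e-12) ge_ct <- ge_ct + 1L
          # Phi_SC: individuals among populations within groups
          pop_perm <- populations
          for (g in unique(groups)) {
            idx <- which(groups == g)
            pop_perm[idx] <- sample(populations[idx])
          }
          sc <- amova_components(d2, pop_perm, groups)$phi[["phi_sc"]]
          if (sc >= obs$phi[["phi_sc"]] - 1e-12) ge_sc <- ge_sc + 1L
        }
        c(phi_ct = (1 + ge_ct) / (n_perm + 1),
          phi_sc = (1 + ge_sc) / (n_perm + 1),
          phi_st = (1 + ge_st) / (n_perm + 1))
      }
    })
  }

  floored <- pmax(obs$sigma, 0)
  negative <- any(obs$sigma < 0)
  pct <- if (sum(floored) > 0) 100 * floored / sum(floored) else {
    rep(0, length(floored))
  }
  structure(list(sigma = obs$sigma, percent = pct, df = obs$df,
                 ss = obs$ss, phi = obs$phi, p_values = p_values,
                 n_perm = n_perm, seed = seed,
                 negative_component = negative),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  tab <- data.frame(df = x$df, SS = x$ss, sigma2 = x$sigma,
                    percent = x$percent)
  print(round(tab, 4))
  cat("\nPhi statistics:\n")
  phi <- round(x$phi, 4)
  if (!is.null(x$p_values)) {
    for (k in names(phi)) {
      p <- x$p_values[[k]]
      cat(sprintf("  %s = %.4f%s\n", k, phi[[k]],
                  if (!is.null(p) && !is.na(p)) {
                    sprintf(" (P = %.4g, %d permutations)", p, x$n_perm)
                  } else ""))
    }
  } else {
    for (k in names(phi)) cat(sprintf("  %s = %.4f\n", k, phi[[k]]))
  }
  if (x$negative_component) {
    cat("note: negative variance component(s) floored at 0 in percentages\n")
  }
  invisible(x)
}
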