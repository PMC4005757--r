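# Synthetic genotype generators.
#
# Each generator encodes the probabilistic model the corresponding estimator
# assumes, with the truth (TMRCA, cline slope, admixture weights) known by
# construction, so estimator recovery can be tested without real samples.

# run expr with a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Simulate Y-STR haplotypes on a star (or Kingman) genealogy
#'
#' Each of `n_lineages` descends independently from the founder haplotype
#' for `tmrca_generations` generations.  Per locus the mutation count is
#' Poisson(rate x branch length) and every mutation moves the repeat count
#' by +1 or -1 with equal probability (single-step SMM).  On a star
#' genealogy the expected per-locus repeat variance is exactly
#' rate x TMRCA, the identity the variance dating estimator inverts.  The
#' `"coalescent"` option hangs the same mutational process on a Kingman tree
#' rescaled to the requested TMRCA, for robustness experiments.
#'
#' @param n_lineages number of sampled chromosomes (>= 2).
#' @param tmrca_generations true age of the common ancestor, generations.
#' @param founder_profile named integer vector, founder repeat counts.
#' @param locus_rates named numeric vector, mutations/locus/generation.
#' @param seed integer seed; the output is bit-reproducible given it.
#' @param genealogy "star" (default) or "coalescent".
#' @param population_id population label for the generated records.
#' @return a `genotype_tbl` of simulated Y records.
#' @export
simulate_star_str <- function(n_lineages, tmrca_generations, founder_profile,
                              locus_rates, seed = NULL,
                              genealogy = c("star", "coalescent"),
                              population_id = "SIM") {
  genealogy <- match.arg(genealogy)
  stopifnot(n_lineages >= 2, tmrca_generations > 0)
  if (any(locus_rates <= 0)) stop("all locus rates must be > 0")
  loci <- names(founder_profile)
  miss <- setdiff(loci, names(locus_rates))
  if (length(miss)) stop("no rate for locus ", paste(miss, collapse = ", "))

  with_seed(seed, {
    if (genealogy == "star") {
      prof <- sapply(loci, function(l) {
        k <- stats::rpois(n_lineages, locus_rates[[l]] * tmrca_generations)
        founder_profile[[l]] + smm_displacement(k)
      })
      prof <- matrix(prof, nrow = n_lineages,
                     dimnames = list(NULL, loci))
    } else {
      tree <- ape::rcoal(n_lineages)
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length * tmrca_generations / depth
      prof <- evolve_on_tree(tree, founder_profile, locus_rates)
    }
    df <- data.frame(
      individual_id = sprintf("%s_%04d", population_id,
                              seq_len(n_lineages)),
      population_id = population_id,
      y_haplogroup = "SIMHG",
      stringsAsFactors = FALSE)
    df[loci] <- as.data.frame(prof)
    genotype_table(df, "Y")
  })
}

# net repeat displacement after k single-step mutations, vectorised over k
smm_displacement <- function(k) {
  as.integer(2L * stats::rbinom(length(k), k, 0.5) - k)
}

# evolve SMM profiles down a phylo tree from the root state
evolve_on_tree <- function(tree, founder_profile, locus_rates) {
  loci <- names(founder_profile)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  state <- matrix(rep(as.integer(founder_profile), each = n_node),
                  nrow = n_node, dimnames = list(NULL, loci))
  # cladewise order visits every parent before its children
  tree <- ape::reorder.phylo(tree, "cladewise")
  edges <- tree$edge
  lens <- tree$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    for (l in loci) {
      k <- stats::rpois(1, locus_rates[[l]] * lens[e])
      state[child, l] <- state[par, l] + smm_displacement(k)
    }
  }
  state[seq_len(n_tip), , drop = FALSE]
}

#' Simulate HVS sequences under a Poisson molecular clock
#'
#' Every sequence carries the root variant set plus K ~ Poisson(age/rate)
#' private mutations at positions drawn uniformly from `region` (finite
#' sites: a site may be hit twice; a redrawn token toggles back off, which
#' mirrors real recurrent-mutation noise in the rho statistic).
#'
#' @param n number of sequences.
#' @param root_variants character vector of root variant tokens
#'   (e.g. "16224C").
#' @param rate_years_per_mutation clock calibration, years per mutation.
#' @param age_years true age of the root, years (>= 0).
#' @param region integer c(start, end) of the mutable window (HVS-I default).
#' @param seed integer seed.
#' @param population_id population label.
#' @return a `genotype_tbl` of simulated mtDNA records.
#' @export
simulate_hvs <- function(n, root_variants = character(0),
                         rate_years_per_mutation, age_years,
                         region = HVS1_REGION, seed = NULL,
                         population_id = "SIM") {
  if (age_years < 0) stop("age_years must be >= 0")
  if (rate_years_per_mutation <= 0) {
    stop("rate_years_per_mutation must be > 0")
  }
  lambda <- age_years / rate_years_per_mutation
  positions <- seq.int(region[1], region[2])
  with_seed(seed, {
    sets <- replicate(n, {
      vars <- sort(unique(toupper(root_variants)))
      k <- stats::rpois(1, lambda)
      if (k > 0) {
        pos <- sample(positions, k, replace = TRUE)
        base <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
        for (tok in paste0(pos, base)) {
          vars <- if (tok %in% vars) setdiff(vars, tok) else c(vars, tok)
        }
      }
      paste(sort(vars), collapse = ";")
    })
    df <- data.frame(
      individual_id = sprintf("%s_%04d", population_id, seq_len(n)),
      population_id = population_id,
      mt_haplogroup = "SIMHG",
      hvs_variants = sets,
      stringsAsFactors = FALSE)
    genotype_table(df, "MT")
  })
}

#' Simulate per-population haplogroup counts along a longitudinal cline
#'
#' Expected frequencies in each population follow a multinomial-logit
#' cline, softmax(log(baseline) + slope x longitude) — with all slopes
#' zero this returns the baseline exactly — so a haplogroup with a
#' positive slope rises monotonically (in expectation) from west to east;
#' observed counts are multinomial draws of the requested sample sizes.
#' This is the synthetic stand-in for a Mediterranean-style comparison
#' matrix with a NW-SE frequency gradient.
#'
#' @param n_populations number of populations.
#' @param haplogroup_labels haplogroup column labels.
#' @param baseline_frequencies simplex vector (sums to 1, all > 0).
#' @param cline_slope_per_degree numeric vector per haplogroup, logit units
#'   per degree of longitude (0 = no cline).
#' @param coordinates data.frame with `latitude`, `longitude` (one row per
#'   population).
#' @param sample_sizes integer vector of per-population sample sizes.
#' @param seed integer seed.
#' @return list with `counts` (populations x haplogroups matrix), `meta`
#'   (population metadata data.frame) and `expected` frequencies.
#' @export
simulate_cline_frequencies <- function(n_populations, haplogroup_labels,
                                       baseline_frequencies,
                                       cline_slope_per_degree,
                                       coordinates, sample_sizes,
                                       seed = NULL) {
  h <- length(haplogroup_labels)
  stopifnot(length(baseline_frequencies) == h,
            length(cline_slope_per_degree) == h,
            nrow(coordinates) == n_populations,
            length(sample_sizes) == n_populations)
  if (any(baseline_frequencies <= 0) ||
      abs(sum(baseline_frequencies) - 1) > 1e-8) {
    stop("baseline_frequencies must be a strictly positive simplex")
  }
  eta0 <- log(baseline_frequencies)
  expected <- t(vapply(seq_len(n_populations), function(i) {
    eta <- eta0 + cline_slope_per_degree * coordinates$longitude[i]
    w <- exp(eta - max(eta))
    w / sum(w)
  }, numeric(h)))
  pops <- sprintf("POP%02d", seq_len(n_populations))
  dimnames(expected) <- list(pops, haplogroup_labels)
  counts <- with_seed(seed, {
    t(vapply(seq_len(n_populations), function(i) {
      as.integer(stats::rmultinom(1, sample_sizes[i], expected[i, ]))
    }, integer(h)))
  })
  dimnames(counts) <- dimnames(expected)
  meta <- data.frame(population_id = pops,
                     group_label = "SIM",
                     latitude = coordinates$latitude,
                     longitude = coordinates$longitude,
                     sample_size = as.integer(sample_sizes),
                     stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, expected = expected)
}

#' Simulate a hybrid population from known parental mixtures
#'
#' Hybrid counts are multinomial with cell probabilities equal to the
#' weighted mixture of the parental frequency profiles — the generative
#' model the mY admixture estimator inverts.
#'
#' @param parental_freqs k x H matrix of parental frequency vectors (rows
#'   sum to 1).
#' @param weights mixture weights, length k, summing to 1.
#' @param n hybrid sample size.
#' @param seed integer seed.
#' @return named integer count vector over the H haplogroups.
#' @export
simulate_admixed <- function(parental_freqs, weights, n, seed = NULL) {
  parental_freqs <- as.matrix(parental_freqs)
  if (length(weights) != nrow(parental_freqs)) {
    stop("one weight per parental population required")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  mix <- as.numeric(weights %*% parental_freqs)
  counts <- with_seed(seed, as.integer(stats::rmultinom(1, n, mix)))
  stats::setNames(counts, colnames(parental_freqs))
}
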