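# Molecular, coancestry and geographic distance matrices.

#' Individual-level squared molecular distances
#'
#' Builds the squared-distance matrix the AMOVA framework decomposes:
#' `"haplogroup"` scores 0/1 mismatch of haplogroup calls (the
#' frequencies-only behaviour), `"hvs"` counts token differences between
#' HVS variant sets (pairwise sequence differences), and `"str"` sums
#' squared repeat-count differences over the analysis loci (the R_ST
#' metric).
#'
#' @param records a `genotype_tbl`.
#' @param kind "haplogroup", "hvs" or "str".
#' @param system marker system for `"haplogroup"` ("Y" or "MT").
#' @return symmetric N x N matrix of squared distances, zero diagonal.
#' @export
pairwise_d2 <- function(records, kind = c("haplogroup", "hvs", "str"),
                        system = c("Y", "MT")) {
  kind <- match.arg(kind)
  system <- match.arg(system)
  n <- nrow(records)
  if (kind == "haplogroup") {
    col <- if (system == "Y") "y_haplogroup" else "mt_haplogroup"
    hg <- records[[col]]
    d2 <- 1 - outer(hg, hg, "==")
    storage.mode(d2) <- "double"
  } else if (kind == "hvs") {
    sets <- hvs_variant_sets(records)
    d2 <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- length(setdiff(sets[[i]], sets[[j]])) +
          length(setdiff(sets[[j]], sets[[i]]))
        d2[i, j] <- d2[j, i] <- d
      }
    }
  } else {
    prof <- as.matrix(records[, str_loci(records), drop = FALSE])
    storage.mode(prof) <- "double"
    g <- tcrossprod(prof)
    sq <- diag(g)
    d2 <- outer(sq, sq, "+") - 2 * g
    d2[d2 < 0] <- 0
  }
  diag(d2) <- 0
  dimnames(d2) <- list(records$individual_id, records$individual_id)
  d2
}

#' Pairwise AMOVA-based distance between two populations
#'
#' Phi_ST (pairwise-difference distances on HVS variant sets) or R_ST
#' (squared repeat-count differences summed over STR loci) from a two-
#' population variance decomposition.  Negative estimates are truncated to
#' zero for reporting; the raw value is kept in the `raw` attribute.
#'
#' @param records_a,records_b `genotype_tbl`s of the two populations.
#' @param kind "phi_st" (HVS), "r_st" (STR) or "haplogroup" (0/1 mismatch).
#' @return the truncated distance, with attribute `raw`.
#' @export
molecular_distance <- function(records_a, records_b,
                               kind = c("phi_st", "r_st", "haplogroup")) {
  kind <- match.arg(kind)
  if (nrow(records_a) == 0 || nrow(records_b) == 0) {
    stop("cannot compute a distance to an empty population")
  }
  d2kind <- switch(kind, phi_st = "hvs", r_st = "str",
                   haplogroup = "haplogroup")
  combined <- rbind(as.data.frame(records_a), as.data.frame(records_b))
  combined$individual_id <- make.unique(combined$individual_id)
  tbl <- structure(combined, class = class(records_a),
                   marker_system = attr(records_a, "marker_system"),
                   str_loci = str_loci(records_a))
  pops <- rep(c("A", "B"), c(nrow(records_a), nrow(records_b)))
  d2 <- pairwise_d2(tbl, d2kind)
  fit <- amova(d2, pops, n_perm = 0)
  phi <- fit$phi[["phi_st"]]
  out <- max(phi, 0)
  attr(out, "raw") <- phi
  out
}

#' Matrix of pairwise Phi_ST / R_ST distances among populations
#'
#' @param records a `genotype_tbl` with multiple populations.
#' @param kind as in [molecular_distance()].
#' @return symmetric population-level distance matrix (negatives truncated
#'   to 0; raw values in attribute `raw`).
#' @export
molecular_distance_matrix <- function(records,
                                      kind = c("phi_st", "r_st",
                                               "haplogroup")) {
  kind <- match.arg(kind)
  pops <- unique(records$population_id)
  k <- length(pops)
  out <- raw <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- subset_population(records, pops[i])
      b <- subset_population(records, pops[j])
      d <- molecular_distance(a, b, kind)
      out[i, j] <- out[j, i] <- as.numeric(d)
      raw[i, j] <- raw[j, i] <- attr(d, "raw")
    }
  }
  attr(out, "raw") <- raw
  out
}

subset_population <- function(records, pop) {
  sub <- records[records$population_id %in% pop, , drop = FALSE]
  structure(sub, class = class(records),
            marker_system = attr(records, "marker_system"),
            str_loci = str_loci(records))
}

#' Reynolds coancestry distance between two populations
#'
#' D = -ln(1 - theta) with theta the Reynolds coancestry estimate treating
#' the haplogroup system as one multi-allelic locus.  The corrected variant
#' subtracts the unbiased within-population sampling variance
#' (1 - sum p^2)/(n - 1) from the squared-frequency-difference numerator;
#' the uncorrected variant is the plug-in (PHYLIP gendist) form.
#'
#' @param p,q haplogroup count vectors (same label order) or frequency
#'   vectors if `n_p`/`n_q` are given.
#' @param n_p,n_q sample sizes (required if `p`, `q` are frequencies).
#' @param corrected apply the sample-size correction (default TRUE).
#' @return distance D (>= 0; +Inf, with a warning, if theta >= 1).
#' @export
reynolds_distance <- function(p, q, n_p = NULL, n_q = NULL,
                              corrected = TRUE) {
  if (length(p) != length(q)) stop("frequency vectors differ in length")
  if (is.null(n_p)) { n_p <- sum(p); p <- p / n_p }
  if (is.null(n_q)) { n_q <- sum(q); q <- q / n_q }
  num <- sum((p - q)^2)
  if (corrected) {
    num <- num - (1 - sum(p^2)) / (n_p - 1) - (1 - sum(q^2)) / (n_q - 1)
  }
  den <- 2 * (1 - sum(p * q))
  if (den <= 0) {
    # both populations fixed for the same class
    return(0)
  }
  theta <- num / den
  theta <- min(max(theta, 0), 1)
  if (theta >= 1) {
    warning("theta >= 1 (disjoint fixed populations); distance is +Inf")
    return(Inf)
  }
  -log(1 - theta)
}

#' Reynolds distance matrix from a haplogroup count table
#'
#' @param counts populations x haplogroups count matrix.
#' @param corrected see [reynolds_distance()].
#' @return symmetric population distance matrix.
#' @export
reynolds_matrix <- function(counts, corrected = TRUE) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  out <- matrix(0, k, k, dimnames = list(rownames(counts),
                                         rownames(counts)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      out[i, j] <- out[j, i] <-
        reynolds_distance(counts[i, ], counts[j, ], corrected = corrected)
    }
  }
  out
}

#' Great-circle distance between populations, km
#'
#' Haversine distance on a spherical Earth of radius 6371 km.  With a
#' single metadata table, returns the full symmetric distance matrix.
#'
#' @param a population metadata data.frame (`latitude`, `longitude`); with
#'   `b` missing, all pairwise distances among its rows are returned.
#' @param b optional second metadata row/table for a single pair.
#' @return distance in km (scalar or labelled matrix).
#' @export
geographic_distance <- function(a, b = NULL) {
  check_coords <- function(m) {
    if (any(abs(m$latitude) > 90) || any(abs(m$longitude) > 180)) {
      stop("invalid coordinates: |lat| <= 90 and |lon| <= 180 required")
    }
  }
  if (!is.null(b)) {
    check_coords(a); check_coords(b)
    return(geosphere::distHaversine(
      c(a$longitude, a$latitude), c(b$longitude, b$latitude),
      r = 6371000) / 1000)
  }
  check_coords(a)
  xy <- cbind(a$longitude, a$latitude)
  n <- nrow(xy)
  out <- matrix(0, n, n,
                dimnames = list(a$population_id, a$population_id))
  for (i in seq_len(n)) {
    out[i, ] <- geosphere::distHaversine(xy[i, ], xy, r = 6371000) / 1000
  }
  out[abs(out) < 1e-9] <- 0
  (out + t(out)) / 2
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangles, with a
#' one-sided (upper) permutation p-value obtained by simultaneously
#' permuting rows and columns of the second matrix;
#' p = (1 + #{perm >= obs}) / (n_perm + 1).
#'
#' @param m1,m2 symmetric distance matrices with identical labels/order.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel <- function(m1, m2, n_perm = 10000, seed = NULL) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must have equal dimension")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("matrices must share the same labels in the same order")
  }
  ut <- upper.tri(m1)
  x <- m1[ut]
  if (stats::sd(x) == 0 || stats::sd(m2[ut]) == 0) {
    stop("constant distance matrix: Mantel r undefined")
  }
  r_obs <- stats::cor(x, m2[ut])
  n <- nrow(m1)
  ge <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      rp <- stats::cor(x, m2[idx, idx][ut])
      if (rp >= r_obs - 1e-12) ge <- ge + 1L
    }
  })
  list(r = r_obs, p = (1 + ge) / (n_perm + 1), n_perm = n_perm)
}
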