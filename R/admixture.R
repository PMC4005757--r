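# Moment-based admixture-proportion (mY-style) estimation for a hybrid
# population under a k-parental model, with bootstrap dispersion.
#
# For populations X and Y with haplogroup frequency vectors x, y and an
# inter-haplogroup distance matrix D, the mean pairwise molecular
# diversity between them is d(X, Y) = x' D y.  If the hybrid H is the
# mixture sum_k m_k P_k then d(H, P_j) = sum_k m_k d(P_k, P_j) for every
# parental j; the coefficients are recovered by least squares under the
# constraint sum m = 1.  With the identity (0/1 mismatch) distance this
# reduces to a pure haplogroup-frequency solution.

#' mY admixture coefficients for a hybrid population
#'
#' @param hybrid named count (or frequency) vector of the hybrid
#'   population.
#' @param parentals k x H matrix of parental counts/frequencies (rows =
#'   parental populations, sharing the hybrid's haplogroup labels).
#' @param hg_distance optional H x H symmetric inter-haplogroup molecular
#'   distance matrix; NULL (default) uses the identity 0/1 distance, i.e.
#'   frequency-only information.
#' @param condition_limit condition-number threshold above which two
#'   parental profiles are declared indistinguishable.
#' @return an `admixture_result` with raw weights (sum to 1; individual
#'   weights may fall outside [0, 1] and are then flagged, not clamped —
#'   clamping would hide model misfit).
#' @export
my_estimate <- function(hybrid, parentals, hg_distance = NULL,
                        condition_limit = 1e10) {
  parentals <- as.matrix(parentals)
  k <- nrow(parentals)
  if (k < 2) stop("at least two parental populations required")
  if (length(hybrid) != ncol(parentals)) {
    stop("hybrid and parentals must share the haplogroup label set")
  }
  if (!is.null(names(hybrid)) && !is.null(colnames(parentals)) &&
      !identical(names(hybrid), colnames(parentals))) {
    stop("hybrid and parentals must share the haplogroup label set")
  }
  h <- hybrid / sum(hybrid)
  P <- parentals / rowSums(parentals)
  H <- ncol(P)
  D <- if (is.null(hg_distance)) 1 - diag(H) else as.matrix(hg_distance)
  # d(X,Y) = x' D y ; equations d(H,Pj) = sum_k m_k d(Pk,Pj)
  G <- P %*% D %*% t(P)            # k x k parental-parental diversities
  b <- as.numeric(P %*% D %*% h)   # hybrid-parental diversities
  cn <- kappa(G, exact = TRUE)
  if (!is.finite(cn) || cn > condition_limit) {
    stop("ill-conditioned parental system (condition number ",
         format(cn, digits = 3),
         "): two parental profiles are (near-)identical")
  }
  # least squares under the constraint sum(m) = 1 (KKT system)
  A <- rbind(cbind(2 * crossprod(G), rep(1, k)),
             c(rep(1, k), 0))
  rhs <- c(2 * as.numeric(crossprod(G, b)), 1)
  m <- solve(A, rhs)[seq_len(k)]
  names(m) <- rownames(parentals)
  admixture_result(weights = m,
                   distance_mode = if (is.null(hg_distance)) {
                     "identity"
                   } else "custom")
}

admixture_result <- function(weights, distance_mode,
                             bootstrap_mean = NULL, bootstrap_sd = NULL,
                             n_bootstrap = NA_integer_) {
  structure(list(weights = weights,
                 out_of_range = any(weights < 0 | weights > 1),
                 distance_mode = distance_mode,
                 bootstrap_mean = bootstrap_mean,
                 bootstrap_sd = bootstrap_sd,
                 n_bootstrap = n_bootstrap),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat("mY admixture coefficients (", x$distance_mode,
      " distance):\n", sep = "")
  tab <- data.frame(weight = x$weights)
  if (!is.null(x$bootstrap_sd)) {
    tab$bootstrap_mean <- x$bootstrap_mean
    tab$bootstrap_sd <- x$bootstrap_sd
  }
  print(round(tab, 4))
  if (!is.na(x$n_bootstrap)) {
    cat(x$n_bootstrap, "bootstrap replicates\n")
  }
  if (x$out_of_range) {
    cat("note: weight(s) outside [0, 1] — reported raw (model misfit?)\n")
  }
  invisible(x)
}

#' Bootstrap dispersion of mY admixture coefficients
#'
#' Resamples individuals with replacement within the hybrid and each
#' parental population (multinomial resampling of the count vectors),
#' optionally first subsampling each parental to a fixed size (default 50)
#' to equalise sampling variance across parental groups, and re-estimates
#' the coefficients per replicate.
#'
#' @param hybrid named hybrid count vector.
#' @param parentals k x H matrix of parental counts.
#' @param n_boot bootstrap replicates (a warning below 100).
#' @param seed integer seed.
#' @param hg_distance optional inter-haplogroup distance matrix.
#' @param parental_subsample per-replicate parental sample size (NULL to
#'   resample at the observed sizes).
#' @return an `admixture_result` with point weights, bootstrap mean and SD.
#' @export
my_bootstrap <- function(hybrid, parentals, n_boot = 1000, seed = NULL,
                         hg_distance = NULL, parental_subsample = 50) {
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  parentals <- as.matrix(parentals)
  point <- my_estimate(hybrid, parentals, hg_distance)
  k <- nrow(parentals)
  n_h <- sum(hybrid)
  draws <- with_seed(seed, {
    replicate(n_boot, {
      hb <- as.integer(stats::rmultinom(1, n_h, hybrid / sum(hybrid)))
      pb <- t(vapply(seq_len(k), function(i) {
        size <- if (is.null(parental_subsample)) {
          sum(parentals[i, ])
        } else min(parental_subsample, sum(parentals[i, ]))
        as.integer(stats::rmultinom(1, size,
                                    parentals[i, ] / sum(parentals[i, ])))
      }, integer(ncol(parentals))))
      dimnames(pb) <- dimnames(parentals)
      names(hb) <- names(hybrid)
      my_estimate(hb, pb, hg_distance)$weights
    })
  })
  draws <- matrix(draws, nrow = k, dimnames = list(rownames(parentals)))
  admixture_result(weights = point$weights,
                   distance_mode = point$distance_mode,
                   bootstrap_mean = rowMeans(draws),
                   bootstrap_sd = apply(draws, 1, stats::sd),
                   n_bootstrap = n_boot)
}
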