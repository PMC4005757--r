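# Spatial PCA: axes maximise the product of variance and Moran's I.
#
# With column-centred frequency matrix X and symmetrised connection
# weights Omega = (W + W')/2, the criterion var(Xv) * I(Xv) equals
# v' X' Omega X v / sum(Omega) for unit v, so the axes are the
# eigenvectors of that symmetric form.  Positive eigenvalues flag global
# (cline-like) structure, negative ones local (checkerboard) structure.

#' Build a spatial connection network among populations
#'
#' Delaunay triangulation of the coordinates (default), k-nearest-neighbour
#' on great-circle distances, or inverse-distance weights.  The weight
#' matrix is symmetrised and optionally row-standardised.
#'
#' @param meta population metadata (`population_id`, `latitude`,
#'   `longitude`).
#' @param scheme "delaunay", "knn" or "inverse_distance".
#' @param k neighbours for the knn scheme.
#' @param row_standardize divide each nonzero row by its sum.
#' @return a `spatial_weights` list with elements `W`, `labels`, `scheme`.
#' @export
build_weights <- function(meta, scheme = c("delaunay", "knn",
                                           "inverse_distance"),
                          k = 2, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- nrow(meta)
  xy <- cbind(meta$longitude, meta$latitude)
  dup <- duplicated(xy) | duplicated(xy, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate coordinates for populations: ",
         paste(meta$population_id[dup], collapse = ", "))
  }
  if (scheme == "delaunay") {
    if (n < 3) {
      warning("fewer than 3 populations: falling back to a complete graph")
      W <- 1 - diag(n)
    } else {
      W <- delaunay_adjacency(xy)
      if (all(W == 0)) {
        warning("degenerate (collinear) configuration: complete graph used")
        W <- 1 - diag(n)
      }
    }
  } else {
    gd <- geographic_distance(meta)
    if (scheme == "knn") {
      W <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(gd[i, -i])[seq_len(min(k, n - 1))]
        W[i, setdiff(seq_len(n), i)[nb]] <- 1
      }
      W <- pmax(W, t(W))  # symmetrise: a link is a link
    } else {
      W <- 1 / gd
      diag(W) <- 0
    }
  }
  dimnames(W) <- list(meta$population_id, meta$population_id)
  if (row_standardize) {
    rs <- rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  structure(list(W = W, labels = meta$population_id, scheme = scheme,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

# O(n^4) empty-circumcircle Delaunay; n is a population count, so small
delaunay_adjacency <- function(xy) {
  n <- nrow(xy)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        cc <- circumcircle(xy[i, ], xy[j, ], xy[k, ])
        if (is.null(cc)) next
        others <- setdiff(seq_len(n), c(i, j, k))
        d <- sqrt((xy[others, 1] - cc$x)^2 + (xy[others, 2] - cc$y)^2)
        if (all(d > cc$r + 1e-9)) {
          W[i, j] <- W[j, i] <- 1
          W[j, k] <- W[k, j] <- 1
          W[i, k] <- W[k, i] <- 1
        }
      }
    }
  }
  W
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
  list(x = ux, y = uy, r = sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
}

#' Moran's I spatial autocorrelation index
#'
#' I = (n / sum W) * (x_c' W x_c) / (x_c' x_c) with x_c the centred
#' variable.  Under spatial randomness E[I] = -1/(n-1).
#'
#' @param x numeric vector over the populations.
#' @param weights a `spatial_weights` object (or bare matrix).
#' @return Moran's I.
#' @export
morans_i <- function(x, weights) {
  W <- if (inherits(weights, "spatial_weights")) weights$W else weights
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("constant variable: Moran's I undefined")
  (length(x) / sum(W)) * as.numeric(xc %*% W %*% xc) / denom
}

#' Spatial principal component analysis of haplogroup frequencies
#'
#' Converts counts to row frequencies, centres the columns (optionally
#' unit-scales them) and eigen-decomposes X' Omega X / sum(Omega) with
#' Omega the symmetrised weights, so that each eigenvalue equals the
#' product of the variance and the Moran's I of its score — positive
#' eigenvalues are global structures, negative ones local.  Each axis sign
#' is fixed by making the largest-magnitude loading positive.
#'
#' @param counts populations x haplogroups count (or frequency) matrix.
#' @param weights a `spatial_weights` object.
#' @param n_axes number of axes to keep on each side (default: all).
#' @param scale unit-scale the centred columns (default FALSE: compositions
#'   share a scale already).
#' @return an `spca_result` with eigenvalues, scores, loadings and per-axis
#'   variance and Moran's I.
#' @export
spca <- function(counts, weights, n_axes = NULL, scale = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 3) stop("at least 3 populations required")
  freq <- counts / rowSums(counts)
  X <- scale(freq, center = TRUE, scale = scale)
  if (scale) X[, attr(X, "scaled:scale") == 0] <- 0
  X <- X[, , drop = FALSE]
  if (all(abs(X) < 1e-12)) {
    stop("frequency matrix has rank 0 after centring")
  }
  W <- weights$W
  omega <- (W + t(W)) / 2
  S <- crossprod(X, omega %*% X) / sum(omega)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  keep <- abs(ev$values) > max(abs(ev$values)) * 1e-10
  values <- ev$values[keep]
  vectors <- ev$vectors[, keep, drop = FALSE]
  if (!is.null(n_axes)) {
    pos <- which(values > 0)[seq_len(min(n_axes, sum(values > 0)))]
    neg <- rev(which(values < 0))[seq_len(min(n_axes, sum(values < 0)))]
    sel <- sort(unique(c(pos, rev(neg))))
    values <- values[sel]
    vectors <- vectors[, sel, drop = FALSE]
  }
  # reproducible orientation
  for (j in seq_along(values)) {
    top <- which.max(abs(vectors[, j]))
    if (vectors[top, j] < 0) vectors[, j] <- -vectors[, j]
  }
  scores <- X %*% vectors
  colnames(scores) <- colnames(vectors) <-
    paste0("sPC", seq_along(values))
  rownames(vectors) <- colnames(counts)
  axis_var <- colSums(scores^2) / nrow(X)
  axis_moran <- apply(scores, 2, function(s) {
    if (stats::sd(s) == 0) NA_real_ else morans_i(s, weights)
  })
  structure(list(eigenvalues = values, scores = scores,
                 loadings = vectors, axis_variance = axis_var,
                 axis_moran = axis_moran, weights = weights,
                 centered_data = X),
            class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  cat("Spatial PCA:", length(x$eigenvalues), "axes\n")
  tab <- data.frame(eigenvalue = x$eigenvalues,
                    variance = x$axis_variance,
                    moran_i = x$axis_moran)
  print(round(tab, 4))
  cat("(eigenvalue = variance x Moran's I; positive = global,",
      "negative = local)\n")
  invisible(x)
}

#' Global / local permutation test for spatial genetic structure
#'
#' The observed statistic is the mean, over centred unit-norm haplogroup
#' frequency columns, of the summed squared projections onto the Moran
#' eigenvectors of the connection network whose Moran value is positive
#' (global side) or negative (local side) — i.e. the average share of each
#' variable's variance lying in the global (resp. local) spatial frequency
#' band.  The null distribution permutes population rows against the
#' coordinates; p = (1 + #{perm >= obs}) / (n_perm + 1).
#'
#' @param counts populations x haplogroups count matrix.
#' @param weights a `spatial_weights` object.
#' @param side "global" or "local".
#' @param n_perm permutations (>= 99).
#' @param seed integer seed.
#' @return list with `statistic`, `p`, `n_perm`, `side`.
#' @export
spca_global_local_test <- function(counts, weights,
                                   side = c("global", "local"),
                                   n_perm = 999, seed = NULL) {
  side <- match.arg(side)
  if (n_perm < 99) stop("at least 99 permutations required")
  counts <- as.matrix(counts)
  freq <- counts / rowSums(counts)
  n <- nrow(freq)
  W <- weights$W
  omega <- (W + t(W)) / 2
  ctr <- diag(n) - matrix(1 / n, n, n)
  em <- eigen(ctr %*% omega %*% ctr, symmetric = TRUE)
  nontrivial <- abs(em$values) > max(abs(em$values)) * 1e-10
  U <- em$vectors[, nontrivial, drop = FALSE]
  moran_vals <- (n / sum(omega)) * em$values[nontrivial]
  sel <- if (side == "global") moran_vals > 0 else moran_vals < 0
  if (!any(sel)) stop("no ", side, " Moran eigenvectors for this network")
  U <- U[, sel, drop = FALSE]
  stat_of <- function(M) {
    Xc <- scale(M, center = TRUE, scale = FALSE)
    norms <- sqrt(colSums(Xc^2))
    use <- norms > 1e-12
    Xu <- sweep(Xc[, use, drop = FALSE], 2, norms[use], "/")
    mean(colSums(crossprod(U, Xu)^2))
  }
  obs <- stat_of(freq)
  ge <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (stat_of(freq[sample.int(n), , drop = FALSE]) >= obs - 1e-12) {
        ge <- ge + 1L
      }
    }
  })
  list(statistic = obs, p = (1 + ge) / (n_perm + 1), n_perm = n_perm,
       side = side)
}
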