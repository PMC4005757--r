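# Gaussian-mixture cluster detection and discriminant analysis of
# principal components (the admixture-like membership barplots).

#' Gaussian-mixture cluster detection with BIC model selection
#'
#' EM fits over a range of cluster numbers and three covariance families —
#' shared spherical (EII), shared diagonal (EEI) and shared full (EEE) —
#' with selection by BIC.  The full model is skipped, with a warning, when
#' there are too few points to estimate it.  Fitting goes through the
#' mclust machinery (deterministic agglomerative initialisation) under a
#' fixed seed.
#'
#' @param points n x d coordinate matrix (e.g. principal coordinates of a
#'   distance matrix).
#' @param k_range candidate numbers of clusters.
#' @param models covariance model names (mclust codes).
#' @param seed integer seed.
#' @return list with `best_k`, `assignment`, `model`, `bic` table.
#' @importFrom mclust Mclust mclustBIC
#' @export
gaussian_mixture_bic <- function(points, k_range = 1:6,
                                 models = c("EII", "EEI", "EEE"),
                                 seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n <= d + 1 && "EEE" %in% models) {
    warning("n <= d + 1: full-covariance model skipped")
    models <- setdiff(models, "EEE")
  }
  if (!length(models)) stop("no admissible covariance model")
  fit <- with_seed(seed, {
    if (d == 1) {
      # univariate mclust model codes
      uni <- unique(ifelse(models == "EII" | models == "EEI", "E", "E"))
      mclust::Mclust(points[, 1], G = k_range, modelNames = uni,
                     verbose = FALSE)
    } else {
      mclust::Mclust(points, G = k_range, modelNames = models,
                     verbose = FALSE)
    }
  })
  if (is.null(fit)) stop("no mixture model could be fitted")
  list(best_k = fit$G,
       assignment = as.integer(fit$classification),
       model = fit$modelName,
       bic = fit$BIC)
}

#' Fit a discriminant analysis of principal components
#'
#' Centres (and by default unit-scales) the feature matrix, retains
#' `n_pcs` principal components, and finds the linear discriminant axes
#' maximising the between-group to within-group variance ratio in PC
#' space.  Axes are normalised so the pooled within-group variance along
#' each is 1, which makes the membership model a unit-variance Gaussian
#' per group.
#'
#' @param features observations x variables numeric matrix (e.g.
#'   population haplogroup frequencies).
#' @param groups group label per observation.
#' @param n_pcs principal components retained; default is the smallest
#'   number explaining >= 90% of the variance, capped at n/3 (always
#'   reported in the result).
#' @param scale unit-scale columns before PCA (default TRUE).
#' @param ridge regularisation added to a singular within-group covariance
#'   (as a fraction of its mean diagonal).
#' @return a `dapc_model`.
#' @export
dapc_fit <- function(features, groups, n_pcs = NULL, scale = TRUE,
                     ridge = 1e-8) {
  features <- as.matrix(features)
  groups <- as.factor(groups)
  n <- nrow(features)
  if (length(groups) != n) stop("one group label per observation required")
  sizes <- table(groups)
  if (nlevels(groups) > 2 && any(sizes == 1)) {
    warning("group(s) with a single member: ",
            paste(names(sizes)[sizes == 1], collapse = ", "))
  }
  ctr <- colMeans(features)
  scl <- if (scale) {
    s <- apply(features, 2, stats::sd); s[s == 0] <- 1; s
  } else rep(1, ncol(features))
  Xs <- sweep(sweep(features, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  pos <- pc$sdev > pc$sdev[1] * 1e-8
  rank <- sum(pos)
  if (is.null(n_pcs)) {
    cum <- cumsum(pc$sdev[pos]^2) / sum(pc$sdev[pos]^2)
    n_pcs <- min(which(cum >= 0.9), max(1, floor(n / 3)))
  }
  if (n_pcs < 1 || n_pcs > rank) {
    stop("n_pcs must be between 1 and the feature rank (", rank, ")")
  }
  Y <- pc$x[, seq_len(n_pcs), drop = FALSE]
  # within and between scatter in PC space
  g_means <- apply(Y, 2, tapply, groups, mean)
  g_means <- matrix(g_means, nrow = nlevels(groups),
                    dimnames = list(levels(groups), colnames(Y)))
  Wm <- matrix(0, n_pcs, n_pcs)
  for (g in levels(groups)) {
    Yg <- Y[groups == g, , drop = FALSE]
    if (nrow(Yg) > 1) {
      dev <- sweep(Yg, 2, g_means[g, ])
      Wm <- Wm + crossprod(dev)
    }
  }
  Wm <- Wm / max(n - nlevels(groups), 1)
  if (rcond_sym(Wm) < 1e-12) {
    eps <- ridge * mean(diag(Wm) + 1e-300)
    if (eps <= 0) eps <- ridge
    Wm <- Wm + diag(eps, n_pcs)
    message("singular within-group covariance: ridge ", signif(eps, 3),
            " added")
  }
  dev_b <- sweep(g_means, 2, colMeans(Y))
  Bm <- crossprod(dev_b * sqrt(as.numeric(sizes))) / n
  # generalised eigenproblem B a = lambda W a via whitening
  Wi <- chol2inv(chol(Wm))
  M <- Wi %*% Bm
  ev <- eigen(M)
  n_axes <- min(nlevels(groups) - 1, n_pcs)
  axes <- Re(ev$vectors[, seq_len(n_axes), drop = FALSE])
  # scale each axis to unit pooled within-group variance
  for (j in seq_len(n_axes)) {
    wv <- as.numeric(t(axes[, j]) %*% Wm %*% axes[, j])
    axes[, j] <- axes[, j] / sqrt(wv)
  }
  ld <- Y %*% axes
  colnames(ld) <- paste0("LD", seq_len(n_axes))
  d_means <- apply(ld, 2, tapply, groups, mean)
  d_means <- matrix(d_means, nrow = nlevels(groups),
                    dimnames = list(levels(groups), colnames(ld)))
  structure(list(center = ctr, scale = scl,
                 rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
                 axes = axes, group_means = d_means,
                 groups = levels(groups), n_pcs = n_pcs,
                 eigenvalues = Re(ev$values[seq_len(n_axes)]),
                 discriminants = ld, training_groups = groups),
            class = "dapc_model")
}

rcond_sym <- function(M) {
  e <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(e)) == 0) return(0)
  min(abs(e)) / max(abs(e))
}

#' @export
print.dapc_model <- function(x, ...) {
  cat("DAPC:", length(x$groups), "groups,", x$n_pcs,
      "PCs retained,", ncol(x$axes), "discriminant axes\n")
  invisible(x)
}

#' Posterior membership probabilities from a DAPC model
#'
#' Each observation is projected into discriminant space and scored
#' against a unit-variance Gaussian centred on each group mean (pooled
#' within-group variance, equal priors); rows are normalised to sum to 1.
#' Held-out populations not used in training may be assigned too.
#'
#' @param model a `dapc_model`.
#' @param features observations x variables matrix (defaults to the
#'   training data projection).
#' @return membership matrix (rows sum to 1), class `membership_table`.
#' @export
dapc_membership <- function(model, features = NULL) {
  ld <- if (is.null(features)) {
    model$discriminants
  } else {
    features <- as.matrix(features)
    Xs <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
    (Xs %*% model$rotation) %*% model$axes
  }
  k <- length(model$groups)
  logd <- matrix(0, nrow(ld), k,
                 dimnames = list(rownames(ld), model$groups))
  for (g in seq_len(k)) {
    dev <- sweep(ld, 2, model$group_means[g, ])
    logd[, g] <- -0.5 * rowSums(dev^2)
  }
  logd <- logd - apply(logd, 1, max)
  post <- exp(logd)
  post <- post / rowSums(post)
  structure(post, class = c("membership_table", class(post)))
}
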