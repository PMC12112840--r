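#' Z-score standardization of the parameter matrix
#'
#' Centers and scales each column to mean 0 and sample SD 1 (the n-1
#' denominator, so published-style per-cluster SDs and standardized
#' profiles are directly comparable).
#'
#' @param X n x p numeric matrix or data frame (n >= 2).
#' @return List with `Z` (standardized matrix) and `scaler` (per-column
#'   `mean` and `sd` used, for inverse transforms and profile z-scores).
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 observations to standardize")
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  bad <- sdev <= .Machine$double.eps * 100
  if (any(bad))
    stop("constant column(s), cannot z-score: ",
         paste(colnames(X)[bad] %||% which(bad), collapse = ", "))
  Z <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
  list(Z = Z, scaler = list(mean = mu, sd = sdev))
}

#' Inverse of [standardize()]
#' @param Z Standardized matrix.
#' @param scaler The `scaler` element returned by [standardize()].
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(Z, scaler) {
  sweep(sweep(as.matrix(Z), 2L, scaler$sd, "*"), 2L, scaler$mean, "+")
}

#' Principal component analysis of standardized parameters
#'
#' Thin wrapper around [stats::prcomp()] on an already-standardized
#' matrix. Retains either a fixed number of components or the smallest
#' number whose cumulative explained-variance ratio reaches a threshold.
#'
#' @param Z Standardized n x p matrix.
#' @param n_components Number of components to retain (default: all).
#' @param variance_threshold If given (in (0, 1]), retain the smallest
#'   number of components reaching this cumulative explained-variance
#'   ratio; overrides `n_components`.
#' @return List with `scores` (n x m), `loadings` (p x m, orthonormal
#'   columns), `explained_ratio`, `cumulative_ratio`, and `n_retained`.
#' @export
pca_fit_transform <- function(Z, n_components = NULL,
                              variance_threshold = NULL) {
  Z <- as.matrix(Z)
  p <- ncol(Z)
  if (!is.null(n_components) && n_components > p)
    stop("n_components exceeds the number of features (", p, ")")
  fit <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ratio <- fit$sdev^2 / sum(fit$sdev^2)
  cum <- cumsum(ratio)
  m <- if (!is.null(variance_threshold)) {
    stopifnot(variance_threshold > 0, variance_threshold <= 1)
    which(cum >= variance_threshold - 1e-12)[1L]
  } else n_components %||% p
  list(scores = fit$x[, seq_len(m), drop = FALSE],
       loadings = fit$rotation[, seq_len(m), drop = FALSE],
       explained_ratio = ratio, cumulative_ratio = cum, n_retained = m)
}

dist2_to_centers <- function(F, centers) {
  # squared Euclidean distances, n x k
  outer(rowSums(F^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(F)), rowSums(centers^2)) - 2 * F %*% t(centers)
}

# k-means++-style seeding: first center uniform, subsequent centers drawn
# with probability proportional to squared distance to the nearest chosen
# center.
kmeanspp_init <- function(F, k) {
  n <- nrow(F)
  centers <- matrix(NA_real_, k, ncol(F))
  centers[1L, ] <- F[sample.int(n, 1L), ]
  if (k > 1L) for (j in 2:k) {
    d2 <- apply(dist2_to_centers(F, centers[seq_len(j - 1L), , drop = FALSE]),
                1L, min)
    d2 <- pmax(d2, 0)
    centers[j, ] <- if (sum(d2) <= 0) F[sample.int(n, 1L), ]
                    else F[sample.int(n, 1L, prob = d2), ]
  }
  centers
}

lloyd <- function(F, centers, max_iter = 300L, tol = 1e-6) {
  k <- nrow(centers)
  labels <- integer(nrow(F))
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(F, centers)
    labels <- max.col(-d2, ties.method = "first")
    if (length(unique(labels)) < k) return(NULL)  # empty cluster: re-seed
    new_centers <- t(vapply(seq_len(k), function(j)
      colMeans(F[labels == j, , drop = FALSE]), numeric(ncol(F))))
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  list(centers = centers, labels = labels,
       wcss = sum((F - centers[labels, , drop = FALSE])^2), iter = it)
}

#' Fit k-means by restarted Lloyd iterations
#'
#' k-means++-style seeding, `n_init` independent restarts, Lloyd
#' iterations until the maximum centroid shift drops below `tol` (or 300
#' iterations), keeping the solution with the lowest within-cluster sum
#' of squares. A restart that empties a cluster is re-seeded.
#' Deterministic for a fixed `seed`.
#'
#' @param F n x p feature matrix.
#' @param k Number of clusters (1 <= k <= n).
#' @param seed Integer RNG seed.
#' @param n_init Number of random restarts.
#' @param init Optional list of warm-start center matrices tried in
#'   addition to the random restarts (used by [scan_k()] to keep the WCSS
#'   curve monotone).
#' @param tol Convergence tolerance on the centroid shift.
#' @return A `cluster_model`: list with `k`, `centers`, `labels` (1-based),
#'   `wcss`, `iter`, `seed`.
#' @export
kmeans_fit <- function(F, k, seed = 0L, n_init = 10L, init = NULL,
                       tol = 1e-6) {
  F <- as.matrix(F)
  n <- nrow(F)
  if (k < 1L || k > n) stop("k must lie in [1, n]")
  if (k == 1L) {
    ctr <- matrix(colMeans(F), 1L)
    return(structure(list(k = 1L, centers = ctr, labels = rep(1L, n),
                          wcss = sum(sweep(F, 2L, ctr)^2), iter = 1L,
                          seed = seed),
                     class = "cluster_model"))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (rep in seq_len(n_init)) {
      fit <- NULL
      tries <- 0L
      while (is.null(fit) && tries < 50L) {  # re-seed on empty clusters
        fit <- lloyd(F, kmeanspp_init(F, k), tol = tol)
        tries <- tries + 1L
      }
      if (!is.null(fit) && (is.null(best) || fit$wcss < best$wcss))
        best <- fit
    }
  })
  for (ctr in init %||% list()) {
    if (!is.matrix(ctr) || nrow(ctr) != k) next
    fit <- lloyd(F, ctr, tol = tol)
    if (!is.null(fit) && fit$wcss < best$wcss) best <- fit
  }
  if (is.null(best)) stop("k-means failed: could not avoid empty clusters")
  structure(list(k = as.integer(k), centers = best$centers,
                 labels = best$labels, wcss = best$wcss, iter = best$iter,
                 seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k=", x$k, ", wcss=", format(x$wcss), ", sizes: ",
      paste(tabulate(x$labels, x$k), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Within-cluster sum of squares
#' @param F Feature matrix.
#' @param labels Integer cluster labels (1..k).
#' @param centers Optional centroid matrix; defaults to the per-cluster
#'   means of `F` (the WCSS-minimizing centers for the given labels).
#' @return Non-negative scalar.
#' @export
wcss <- function(F, labels, centers = NULL) {
  F <- as.matrix(F)
  ks <- sort(unique(labels))
  if (is.null(centers))
    centers <- t(vapply(ks, function(j)
      colMeans(F[labels == j, , drop = FALSE]), numeric(ncol(F))))
  sum((F - centers[match(labels, ks), , drop = FALSE])^2)
}

#' Mean silhouette coefficient
#'
#' Per observation, `(b - a) / max(a, b)` with `a` its mean distance to
#' its own cluster's other members and `b` the smallest mean distance to
#' another cluster; singletons score 0. Returns the mean over all
#' observations.
#'
#' @param F Feature matrix.
#' @param labels Integer cluster labels; at least 2 distinct clusters.
#' @return Scalar in [-1, 1].
#' @export
silhouette_mean <- function(F, labels) {
  F <- as.matrix(F)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette is undefined for a single cluster")
  D <- as.matrix(stats::dist(F))
  n <- nrow(F)
  sizes <- table(factor(labels, levels = ks))
  # mean distance from each point to each cluster (n x k)
  M <- vapply(ks, function(j) rowSums(D[, labels == j, drop = FALSE]),
              numeric(n))
  own <- match(labels, ks)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ni <- sizes[[own[i]]]
    if (ni == 1L) { s[i] <- 0; next }
    a <- M[i, own[i]] / (ni - 1L)
    b <- min(M[i, -own[i]] / as.numeric(sizes[-own[i]]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' `[tr(B)/(k-1)] / [tr(W)/(n-k)]` with B and W the between- and
#' within-cluster scatter; higher = better-separated clusters.
#'
#' @inheritParams silhouette_mean
#' @return Non-negative scalar.
#' @export
calinski_harabasz <- function(F, labels) {
  F <- as.matrix(F)
  ks <- sort(unique(labels))
  k <- length(ks); n <- nrow(F)
  if (k < 2L) stop("Calinski-Harabasz is undefined for a single cluster")
  grand <- colMeans(F)
  trW <- wcss(F, labels)
  trB <- sum(vapply(ks, function(j) {
    nj <- sum(labels == j)
    nj * sum((colMeans(F[labels == j, , drop = FALSE]) - grand)^2)
  }, numeric(1L)))
  (trB / (k - 1)) / (trW / (n - k))
}

#' Davies-Bouldin index
#'
#' `(1/k) * sum_i max_{j != i} (s_i + s_j) / d_ij` with `s_i` the mean
#' distance of cluster i's members to their centroid and `d_ij` the
#' centroid distance; lower = better. Coincident centroids make the ratio
#' infinite; the index is returned as `Inf` with a warning.
#'
#' @inheritParams silhouette_mean
#' @return Non-negative scalar (possibly `Inf`).
#' @export
davies_bouldin <- function(F, labels) {
  F <- as.matrix(F)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2L) stop("Davies-Bouldin is undefined for a single cluster")
  centers <- t(vapply(ks, function(j)
    colMeans(F[labels == j, , drop = FALSE]), numeric(ncol(F))))
  s <- vapply(seq_len(k), function(i) {
    rows <- F[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2L, centers[i, ])^2)))
  }, numeric(1L))
  d <- as.matrix(stats::dist(centers))
  r <- vapply(seq_len(k), function(i) {
    ratios <- (s[i] + s[-i]) / d[i, -i]
    max(ratios)
  }, numeric(1L))
  if (any(!is.finite(r)))
    warning("coincident cluster centroids: Davies-Bouldin index is infinite")
  mean(r)
}

#' Scan candidate cluster counts
#'
#' Fits k-means for each k in `k_range` and records the four validity
#' metrics. Each fit is warm-started with the previous solution's centers
#' plus the point farthest from them (in addition to the random restarts),
#' which guarantees a non-increasing WCSS curve.
#'
#' @param F Feature matrix.
#' @param k_range Integer vector of candidate k (default 2:8).
#' @param seed Integer RNG seed.
#' @param n_init Restarts per k.
#' @return A `k_scan` data frame with columns `k`, `wcss`, `silhouette`,
#'   `calinski_harabasz`, `davies_bouldin`; the fitted models are attached
#'   as attribute `models`.
#' @export
scan_k <- function(F, k_range = 2:8, seed = 0L, n_init = 10L) {
  F <- as.matrix(F)
  if (!length(k_range)) stop("k_range must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  models <- list()
  prev <- NULL
  rows <- lapply(k_range, function(k) {
    warm <- NULL
    if (!is.null(prev) && prev$k == k - 1L) {
      d2 <- apply(dist2_to_centers(F, prev$centers), 1L, min)
      warm <- list(rbind(prev$centers, F[which.max(d2), ]))
    }
    m <- kmeans_fit(F, k, seed = seed + k, n_init = n_init, init = warm)
    prev <<- m
    models[[as.character(k)]] <<- m
    data.frame(k = k, wcss = m$wcss,
               silhouette = silhouette_mean(F, m$labels),
               calinski_harabasz = calinski_harabasz(F, m$labels),
               davies_bouldin = davies_bouldin(F, m$labels))
  })
  out <- do.call(rbind, rows)
  structure(out, models = models, class = c("k_scan", "data.frame"))
}

#' Select the number of clusters from a scan
#'
#' Strategies: `"silhouette_max"` takes the k with the largest mean
#' silhouette; `"elbow_knee"` takes the k whose WCSS point is farthest
#' (perpendicular distance) from the chord joining the first and last
#' points of the WCSS curve; `"manual"` returns the supplied `k`.
#'
#' @param scan A `k_scan` from [scan_k()].
#' @param strategy One of `"silhouette_max"`, `"elbow_knee"`, `"manual"`.
#' @param k Required for `strategy = "manual"`.
#' @return The selected integer k.
#' @export
select_k <- function(scan, strategy = c("silhouette_max", "elbow_knee",
                                        "manual"), k = NULL) {
  strategy <- match.arg(strategy)
  if (!nrow(scan)) stop("empty k scan")
  if (strategy == "manual") {
    if (is.null(k)) stop("manual strategy requires an explicit k")
    return(as.integer(k))
  }
  if (strategy == "silhouette_max")
    return(scan$k[which.max(scan$silhouette)])
  if (nrow(scan) < 3L) return(scan$k[which.min(scan$wcss)])
  x <- scan$k; y <- scan$wcss
  x1 <- x[1L]; y1 <- y[1L]; x2 <- x[nrow(scan)]; y2 <- y[nrow(scan)]
  dist <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  scan$k[which.max(dist)]
}

#' Name the three alignment phenotypes from cluster statistics
#'
#' The cluster with the highest mean lordosis is the `"normal"` type; of
#' the remaining clusters, the one with the longer mean vertical length is
#' the `"long-neck"` type and the other the `"forward-head"` type. For
#' k != 3 the rule does not apply and generic `"cluster_i"` names are
#' returned.
#'
#' @param summary A `cluster_summary` (see [cluster_summary()]).
#' @return Named character vector mapping cluster index to phenotype.
#' @export
label_clusters <- function(summary) {
  ks <- sort(unique(summary$cluster))
  out <- stats::setNames(paste0("cluster_", ks), ks)
  if (length(ks) != 3L) return(out)
  stat <- function(cl, param)
    summary$mean[summary$cluster == cl & summary$parameter == param]
  lord <- vapply(ks, stat, numeric(1L), param = "lordosis_deg")
  normal <- ks[which.max(lord)]
  rest <- setdiff(ks, normal)
  vert <- vapply(rest, stat, numeric(1L), param = "vertical_length")
  long_neck <- rest[which.max(vert)]
  forward <- setdiff(rest, long_neck)
  out[as.character(normal)] <- "normal"
  out[as.character(long_neck)] <- "long-neck"
  out[as.character(forward)] <- "forward-head"
  out
}

#' Standardized per-cluster parameter profiles
#'
#' Cluster-mean z-scores relative to the cohort: `(cluster mean - global
#' mean) / global SD` per parameter — the standardized feature profile
#' used to characterize the phenotypes.
#'
#' @param summary A `cluster_summary`.
#' @param scaler Scaler (`mean`, `sd` per parameter) from [standardize()].
#' @return Matrix, clusters x parameters.
#' @export
profile_zscores <- function(summary, scaler) {
  ks <- sort(unique(summary$cluster))
  params <- names(scaler$mean)
  out <- matrix(NA_real_, length(ks), length(params),
                dimnames = list(ks, params))
  for (i in seq_along(ks)) for (p in params) {
    m <- summary$mean[summary$cluster == ks[i] & summary$parameter == p]
    out[i, p] <- (m - scaler$mean[[p]]) / scaler$sd[[p]]
  }
  out
}
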