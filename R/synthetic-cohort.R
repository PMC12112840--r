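PARAM_NAMES <- c("sva", "lordosis_deg", "vertical_length", "curved_length")

#' Synthetic cohort configuration
#'
#' Per-cluster Gaussian generative model for the four sagittal alignment
#' parameters. Parameters are drawn independently within a cluster: only
#' marginal means and SDs are published for the reference cohort, so
#' independence is the minimal assumption.
#'
#' @param sizes Integer vector of cluster sizes (each >= 2).
#' @param means,sds Numeric matrices, one row per cluster, columns `sva`,
#'   `lordosis_deg`, `vertical_length`, `curved_length`; all SDs > 0.
#' @param seed Integer RNG seed.
#' @return A `synthetic_cohort_config` list.
#' @export
cohort_config <- function(sizes, means, sds, seed = 0L) {
  means <- as.matrix(means); sds <- as.matrix(sds)
  if (any(sizes < 2L)) stop("every cluster needs n >= 2")
  if (!all(dim(means) == c(length(sizes), 4L)) ||
      !all(dim(sds) == c(length(sizes), 4L)))
    stop("means and sds must be k x 4 matrices")
  if (any(sds <= 0)) stop("all sds must be positive")
  colnames(means) <- colnames(sds) <- PARAM_NAMES
  structure(list(sizes = as.integer(sizes), means = means, sds = sds,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Reference three-cluster cohort configuration
#'
#' The published per-cluster summary statistics of the degenerative
#' cervical myelopathy phenotyping cohort: cluster sizes 703 / 387 / 228
#' and, per cluster, mean and SD of SVA, lordosis, vertical length and
#' curved length. Cluster 1 is the forward-head type (low lordosis),
#' cluster 2 the normal type (highest lordosis), cluster 3 the long-neck
#' type (highest SVA, longest spine). Lengths are in the source dataset's
#' pixel-scale units.
#'
#' @param seed Integer RNG seed stored in the configuration.
#' @return A [cohort_config()] object.
#' @export
table1_config <- function(seed = 0L) {
  cohort_config(
    sizes = c(703L, 387L, 228L),
    means = rbind(c( 95.9,  8.3, 457.7, 550.6),
                  c( 70.6, 24.1, 465.5, 559.8),
                  c(135.6, 13.9, 648.0, 841.5)),
    sds   = rbind(c(60.2, 4.7, 53.8,  67.0),
                  c(50.2, 6.8, 56.0,  74.8),
                  c(76.7, 9.4, 95.1, 151.3)),
    seed = seed)
}

#' Simulate a parameter cohort from a cluster configuration
#'
#' Draws, for each cluster, `n` independent observations per parameter
#' from `Normal(mean, sd^2)`, then shuffles the rows (the permutation is
#' recorded). Reproducible: the same configuration and seed give a
#' bitwise-identical cohort.
#'
#' @param cfg A [cohort_config()] (e.g. [table1_config()]).
#' @return List with `parameters` (n x 4 data frame), `labels` (integer
#'   generating-cluster index per row) and `permutation` (the shuffle
#'   applied to the cluster-ordered draws).
#' @export
simulate_cohort <- function(cfg = table1_config()) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  k <- length(cfg$sizes)
  withr::with_seed(cfg$seed, {
    blocks <- lapply(seq_len(k), function(i) {
      n <- cfg$sizes[i]
      vapply(PARAM_NAMES, function(p)
        stats::rnorm(n, cfg$means[i, p], cfg$sds[i, p]), numeric(n))
    })
    X <- do.call(rbind, blocks)
    labels <- rep(seq_len(k), cfg$sizes)
    perm <- sample.int(nrow(X))
  })
  list(parameters = as.data.frame(X[perm, , drop = FALSE]),
       labels = labels[perm],
       permutation = perm)
}
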