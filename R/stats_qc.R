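#' Chi-square test of expected proportions
#'
#' Goodness-of-fit statistic `X^2 = sum((O - E)^2 / E)` with `N - 1` degrees
#' of freedom and an upper-tail p value, where the expected counts come from
#' an externally specified proportion model (for example the dwell-surface
#' shares of the field-overrepresentation test) rather than from the data.
#'
#' @param observed,expected Numeric vectors of equal length (>= 2);
#'   `expected` must be strictly positive.
#' @return List of class `chi2_result`: `statistic`, `df`, `p_value`.
#' @examples
#' chi2_expected_proportions(c(60, 40), c(50, 50))
#' @export
chi2_expected_proportions <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (length(observed) < 2) stop("need at least 2 categories")
  if (any(expected <= 0)) stop("expected counts must be positive")
  x2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = x2, df = df,
                 p_value = stats::pchisq(x2, df, lower.tail = FALSE)),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("X^2(%d) = %.4g, p = %.4g\n", x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Holm-Bonferroni correction (step-down, censor-to-0.99 variant)
#'
#' P values are ranked ascending and each compared to the cutoff
#' `alpha / (n - rank + 1)`. The first p value exceeding its cutoff, and all
#' larger ones, are declared non-significant and set to 0.99; the smaller
#' ones are returned unadjusted. This is the family-wise control used for
#' batches of chi-square or t tests against chance.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param alpha Target family-wise significance level.
#' @return Corrected p values in the original order.
#' @examples
#' holm_bonferroni(c(0.03, 0.004, 0.04))
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  n <- length(p)
  ord <- order(p)
  cutoffs <- alpha / (n - seq_len(n) + 1)
  out <- p[ord]
  fail <- which(out > cutoffs)
  if (length(fail)) out[fail[1]:n] <- 0.99
  out[order(ord)]
}

mahal_sq <- function(x, center, cov) {
  stats::mahalanobis(x, center, cov)
}

cluster_cov <- function(cluster) {
  cv <- stats::cov(cluster)
  if (!is.finite(rcond_est <- rcond(cv)) || rcond_est < 1e-12)
    stop("cluster feature covariance is singular; ",
         "consider regularizing or dropping collinear features")
  cv
}

#' Isolation distance of a spike cluster
#'
#' Squared Mahalanobis distance (under the cluster's own mean and
#' covariance) of the `n_C`-th closest non-cluster spike to the cluster
#' center, where `n_C` is the cluster size. Larger values mean better
#' isolation. Undefined when fewer than `n_C` non-cluster spikes exist.
#'
#' @param cluster Numeric matrix of in-cluster spike features
#'   (spikes x features).
#' @param noncluster Numeric matrix of non-cluster spike features.
#' @return List: `isolation_distance` (NA when undefined), `defined` flag,
#'   `n_cluster`.
#' @export
isolation_distance <- function(cluster, noncluster) {
  cluster <- as.matrix(cluster); noncluster <- as.matrix(noncluster)
  stopifnot(ncol(cluster) == ncol(noncluster))
  n_c <- nrow(cluster)
  if (nrow(noncluster) < n_c)
    return(list(isolation_distance = NA_real_, defined = FALSE, n_cluster = n_c))
  d2 <- mahal_sq(noncluster, colMeans(cluster), cluster_cov(cluster))
  list(isolation_distance = sort(d2)[n_c], defined = TRUE, n_cluster = n_c)
}

#' L and L-ratio of a spike cluster
#'
#' `L = sum over non-cluster spikes of 1 - CDF_chisq(df)(D^2)` where `D^2`
#' is the squared Mahalanobis distance to the cluster center, and
#' `L_ratio = L / n_C`. Low values indicate well-separated clusters. The
#' default 8 degrees of freedom correspond to 2 features on each of 4
#' tetrode channels.
#'
#' @inheritParams isolation_distance
#' @param df Chi-square degrees of freedom (defaults to the feature-space
#'   dimension).
#' @return List: `L`, `L_ratio`, `n_cluster`, `df`.
#' @export
l_ratio <- function(cluster, noncluster, df = ncol(as.matrix(cluster))) {
  cluster <- as.matrix(cluster); noncluster <- as.matrix(noncluster)
  stopifnot(ncol(cluster) == ncol(noncluster))
  n_c <- nrow(cluster)
  if (nrow(noncluster) == 0)
    return(list(L = 0, L_ratio = 0, n_cluster = n_c, df = df))
  d2 <- mahal_sq(noncluster, colMeans(cluster), cluster_cov(cluster))
  L <- sum(1 - stats::pchisq(d2, df))
  list(L = L, L_ratio = L / n_c, n_cluster = n_c, df = df)
}

#' Peak-to-trough width of a mean waveform
#'
#' Absolute time between the maximum and minimum amplitude of the mean
#' waveform, taken on the channel with the greatest peak amplitude. Units
#' follow `sample_us` (microseconds per sample).
#'
#' @param waveforms Numeric matrix (samples x channels) of mean waveforms,
#'   or a vector for a single channel.
#' @param sample_us Microseconds per waveform sample.
#' @return List: `width_us`, `channel`, `peak_amplitude`.
#' @export
width_of_waveform <- function(waveforms, sample_us = 1e6 / 48000) {
  w <- as.matrix(waveforms)
  if (nrow(w) < 2) stop("waveform needs at least 2 samples")
  amp <- apply(abs(w), 2, max)
  ch <- which.max(amp)
  v <- w[, ch]
  if (max(v) == min(v)) stop("flat waveform: width undefined")
  width <- abs(which.max(v) - which.min(v)) * sample_us
  list(width_us = unname(width), channel = unname(ch),
       peak_amplitude = unname(amp[ch]))
}
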