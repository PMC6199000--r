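# Duration bimodality, baseline-normalized trajectories, long/short
# contrasts and duration-connectivity correlations.

#' @importFrom mclust Mclust mclustBIC
NULL

#' Bonferroni divisor for the correlation analysis
#'
#' The duration-connectivity correlations are corrected for multiple
#' comparisons across the whole cohort: the 0.05 level is divided by
#' (number of patients) x (number of connectivity parameters).
#'
#' @param n_patients Number of patients in the cohort (12 in the reference
#'   cohort).
#' @param n_parameters Number of estimated parameters (5: u and four
#'   alphas).
#' @return Integer divisor.
#' @export
bonferroni_divisor <- function(n_patients = 12, n_parameters = 5) {
  stopifnot(n_patients >= 1, n_parameters >= 1)
  as.integer(n_patients * n_parameters)
}

#' Cluster seizure durations and select the number of populations
#'
#' Tests for uni/bi/tri-modality of a patient's seizure durations on the
#' natural-log scale.  Both k-means and Gaussian-mixture partitions are fit
#' for k = 1, 2, 3 and the optimal k for each method is chosen by the gap
#' statistic (uniform reference over the observed log-duration range,
#' `B` reference draws, first local maximum of the gap curve).
#' When both methods agree on k = 2, the long/short boundary is the
#' midpoint of the two cluster means on the log scale.
#'
#' @param durations Seizure durations, seconds (>= `min_n` values).
#' @param seed Integer seed for the reference draws and k-means restarts.
#' @param B Number of gap-statistic reference draws.
#' @param k_max Maximum number of clusters considered.
#' @param min_n Inclusion threshold (patients with fewer seizures are
#'   excluded; default 20).
#' @return List of class `sp_clusters`: `optimal_k` (the k-means choice,
#'   the headline number), `optimal_k_kmeans`, `optimal_k_gmm`,
#'   `method_agreement`, `assignments` (k-means at the optimal k, labelled
#'   so cluster 1 is the shorter population), `gap_kmeans`, `gap_gmm`
#'   (per-k gap values), `long_short_boundary_s` (NA unless k = 2).
#' @export
cluster_durations <- function(durations, seed = 1, B = 100, k_max = 3,
                              min_n = 20) {
  stopifnot(all(durations > 0))
  if (length(durations) < min_n) {
    stop("patient excluded: fewer than ", min_n, " seizures")
  }
  ld <- matrix(log(durations), ncol = 1)
  if (stats::sd(ld) == 0) {
    return(structure(list(
      optimal_k = 1L, optimal_k_kmeans = 1L, optimal_k_gmm = 1L,
      method_agreement = TRUE, assignments = rep(1L, nrow(ld)),
      gap_kmeans = NULL, gap_gmm = NULL, long_short_boundary_s = NA_real_,
      log_durations = as.numeric(ld)), class = "sp_clusters"))
  }
  km_fun <- function(x, k) {
    if (k == 1) return(list(cluster = rep(1L, nrow(x))))
    list(cluster = stats::kmeans(x, centers = k, nstart = 10)$cluster)
  }
  gmm_fun <- function(x, k) {
    fit <- mclust::Mclust(as.numeric(x), G = k, modelNames = "V",
                          verbose = FALSE)
    if (is.null(fit)) fit <- mclust::Mclust(as.numeric(x), G = k,
                                            modelNames = "E", verbose = FALSE)
    list(cluster = as.integer(fit$classification))
  }
  set.seed(seed)
  gap_km <- cluster::clusGap(ld, FUNcluster = km_fun, K.max = k_max, B = B,
                             spaceH0 = "original", verbose = FALSE)
  set.seed(seed + 1)
  gap_gm <- cluster::clusGap(ld, FUNcluster = gmm_fun, K.max = k_max, B = B,
                             spaceH0 = "original", verbose = FALSE)
  pick <- function(g) {
    cluster::maxSE(g$Tab[, "gap"], g$Tab[, "SE.sim"], method = "firstmax")
  }
  k_km <- pick(gap_km)
  k_gm <- pick(gap_gm)
  set.seed(seed + 2)
  assign_k <- max(k_km, 1L)
  cl <- km_fun(ld, assign_k)$cluster
  # relabel so cluster means are increasing in duration
  mu <- tapply(as.numeric(ld), cl, mean)
  cl <- as.integer(factor(cl, levels = names(sort(mu))))
  boundary <- NA_real_
  if (k_km == 2 && assign_k == 2) {
    mu <- sort(tapply(as.numeric(ld), cl, mean))
    boundary <- exp(mean(mu))
  }
  structure(list(
    optimal_k = k_km, optimal_k_kmeans = k_km, optimal_k_gmm = k_gm,
    method_agreement = k_km == k_gm, assignments = cl,
    gap_kmeans = gap_km$Tab, gap_gmm = gap_gm$Tab,
    long_short_boundary_s = boundary,
    log_durations = as.numeric(ld)), class = "sp_clusters")
}

#' @export
print.sp_clusters <- function(x, ...) {
  cat(sprintf(
    "<sp_clusters> n = %d, optimal k: kmeans %d / gmm %d (%s)%s\n",
    length(x$log_durations), x$optimal_k_kmeans, x$optimal_k_gmm,
    if (x$method_agreement) "agree" else "disagree",
    if (!is.na(x$long_short_boundary_s))
      sprintf(", boundary %.1f s", x$long_short_boundary_s) else ""))
  invisible(x)
}

#' Baseline-normalize a parameter trajectory
#'
#' Expresses each estimated parameter as a percentage change from its
#' pre-ictal baseline: 100 * (theta(t) - mean_b) / |mean_b|, where mean_b
#' is the mean over the baseline window (default two minutes to one minute
#' before onset).  Zero therefore means "no change from the pre-ictal
#' period"; division by |mean_b| preserves the direction of change for
#' negative baselines.  Parameters whose baseline mean is below `eps` in
#' magnitude are flagged unusable.
#'
#' @param est `sp_estimate` (times relative to onset) or a list with
#'   `time` and an n x 5 `theta` matrix.
#' @param baseline_window Two times (seconds relative to onset), default
#'   `c(-120, -60)`.
#' @param eps Smallest usable |baseline mean|.
#' @return List of class `sp_normtraj`: `time`, `pct` (n x 5), `usable`
#'   (length 5), `baseline_mean`, `duration` (if known).
#' @export
baseline_normalize <- function(est, baseline_window = c(-120, -60),
                               eps = 1e-12) {
  th <- if (!is.null(est$mean)) est$mean[, 9:13, drop = FALSE] else est$theta
  tt <- est$time
  sel <- tt >= baseline_window[1] & tt < baseline_window[2]
  if (!any(sel)) stop("baseline window not covered by the estimate")
  bmean <- colMeans(th[sel, , drop = FALSE])
  usable <- abs(bmean) >= eps
  pct <- 100 * sweep(sweep(th, 2, bmean, "-"), 2,
                     pmax(abs(bmean), eps), "/")
  colnames(pct) <- theta_names()
  structure(list(time = tt, pct = pct, usable = usable,
                 baseline_mean = bmean,
                 duration = est$duration %||% est$seizure$duration),
            class = "sp_normtraj")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# interpolate one normalized trajectory onto a fixed onset-aligned grid;
# NA beyond the seizure's own span
grid_pct <- function(norm, grid) {
  out <- matrix(NA_real_, length(grid), 5)
  inside <- grid >= min(norm$time) & grid <= max(norm$time)
  if (!is.null(norm$duration)) inside <- inside & grid <= norm$duration
  for (p in 1:5) {
    out[inside, p] <- stats::approx(norm$time, norm$pct[, p],
                                    xout = grid[inside])$y
  }
  out
}

#' Mean trajectory across seizures with per-time significance
#'
#' Onset-aligned average of baseline-normalized trajectories.  At each grid
#' time the mean is taken over the seizures still ongoing (duration >= t);
#' the 95% CI is mean +/- 1.96 SE and a two-sided one-sample t-test
#' against zero flags significant increases (+1) or decreases (-1) at
#' p < 0.05 (a per-time display statistic, not corrected for multiplicity).
#' A min-max normalized copy of the mean (to \[-1, 1\] per parameter) is
#' included.
#'
#' @param norms List of `sp_normtraj`.
#' @param grid Time grid, seconds relative to onset; default 0.25 s steps
#'   from the earliest covered time to the longest duration.
#' @param grid_dt Grid step when `grid` is NULL.
#' @param alpha Significance level for the per-time flags.
#' @param min_n Minimum seizures still ongoing for a time point to be
#'   reported.
#' @return List of class `sp_summary` with `time`, per-parameter matrices
#'   `mean`, `ci_lo`, `ci_hi`, `p`, `flag` (-1/0/+1), `n`, and `mean_minmax`.
#' @export
summarize_trajectories <- function(norms, grid = NULL, grid_dt = 0.25,
                                   alpha = 0.05, min_n = 2) {
  stopifnot(length(norms) >= 2)
  if (is.null(grid)) {
    t0 <- max(vapply(norms, function(n) min(n$time), 0))
    t1 <- max(vapply(norms, function(n) max(n$time), 0))
    grid <- seq(t0, t1, by = grid_dt)
  }
  arr <- vapply(norms, grid_pct, matrix(0, length(grid), 5), grid = grid)
  ng <- length(grid)
  mean_m <- lo <- hi <- pm <- matrix(NA_real_, ng, 5)
  flag <- matrix(0L, ng, 5)
  nmat <- matrix(0L, ng, 5)
  for (p in 1:5) {
    X <- arr[, p, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = length(norms))
    n_t <- rowSums(!is.na(X))
    nmat[, p] <- n_t
    mu <- rowMeans(X, na.rm = TRUE)
    sdv <- apply(X, 1, stats::sd, na.rm = TRUE)
    se <- sdv / sqrt(pmax(n_t, 1))
    ok <- n_t >= min_n
    mean_m[ok, p] <- mu[ok]
    lo[ok, p] <- mu[ok] - 1.96 * se[ok]
    hi[ok, p] <- mu[ok] + 1.96 * se[ok]
    tt <- ifelse(se > 0, mu / se, NA_real_)
    pv <- 2 * stats::pt(-abs(tt), df = pmax(n_t - 1, 1))
    zero_spread <- ok & !is.na(sdv) & sdv == 0 & abs(mu) > 0
    pv[zero_spread] <- 0  # all seizures identical and off baseline
    pm[ok, p] <- pv[ok]
    sig <- ok & !is.na(pv) & pv < alpha
    flag[sig & mu > 0, p] <- 1L
    flag[sig & mu < 0, p] <- -1L
  }
  mm <- apply(mean_m, 2, function(x) {
    r <- range(x, na.rm = TRUE)
    if (diff(r) == 0) return(x * 0)
    2 * (x - r[1]) / diff(r) - 1
  })
  dimnames(mean_m) <- dimnames(lo) <- dimnames(hi) <- dimnames(pm) <-
    dimnames(flag) <- dimnames(nmat) <- dimnames(mm) <-
    list(NULL, theta_names())
  structure(list(time = grid, mean = mean_m, ci_lo = lo, ci_hi = hi,
                 p = pm, flag = flag, n = nmat, mean_minmax = mm),
            class = "sp_summary")
}

#' Per-time contrast between long and short seizures
#'
#' Welch two-sample t-test at every grid time between the long and short
#' populations of a k = 2 duration split, plus the overall contrast of the
#' per-seizure average change.
#'
#' @param norms List of `sp_normtraj`, same order as the durations used for
#'   the split.
#' @param split `sp_clusters` with `optimal_k == 2` (cluster 1 = short).
#' @param grid,grid_dt,alpha As in [summarize_trajectories()].
#' @return List of class `sp_contrast`: `time`, per-parameter `p`, `flag`
#'   (TRUE where p < alpha and both groups have >= 2 seizures), and
#'   `overall` (per-parameter p-value of the whole-trajectory contrast).
#' @export
compare_long_short <- function(norms, split, grid = NULL, grid_dt = 0.25,
                               alpha = 0.05) {
  stopifnot(split$optimal_k == 2, length(norms) == length(split$assignments))
  g <- split$assignments
  if (min(table(g)) < 2) stop("a duration group has fewer than 2 seizures")
  if (is.null(grid)) {
    t0 <- max(vapply(norms, function(n) min(n$time), 0))
    t1 <- max(vapply(norms, function(n) max(n$time), 0))
    grid <- seq(t0, t1, by = grid_dt)
  }
  arr <- vapply(norms, grid_pct, matrix(0, length(grid), 5), grid = grid)
  ng <- length(grid)
  pm <- matrix(NA_real_, ng, 5)
  overall <- numeric(5)
  for (p in 1:5) {
    X <- arr[, p, , drop = TRUE]
    X1 <- X[, g == 1, drop = FALSE]
    X2 <- X[, g == 2, drop = FALSE]
    for (i in seq_len(ng)) {
      a <- X1[i, !is.na(X1[i, ])]
      b <- X2[i, !is.na(X2[i, ])]
      if (length(a) >= 2 && length(b) >= 2 &&
          (stats::sd(a) > 0 || stats::sd(b) > 0)) {
        pm[i, p] <- stats::t.test(a, b)$p.value
      } else if (length(a) >= 2 && length(b) >= 2) {
        pm[i, p] <- if (mean(a) == mean(b)) 1 else 0
      }
    }
    m1 <- colMeans(X1, na.rm = TRUE)  # per-seizure whole-trajectory mean
    m2 <- colMeans(X2, na.rm = TRUE)
    overall[p] <- tryCatch(stats::t.test(m1, m2)$p.value, error = function(e) NA)
  }
  flag <- !is.na(pm) & pm < alpha
  dimnames(pm) <- dimnames(flag) <- list(NULL, theta_names())
  structure(list(time = grid, p = pm, flag = flag,
                 overall = stats::setNames(overall, theta_names())),
            class = "sp_contrast")
}

#' Parameter means over the pre-onset / pre-offset window
#'
#' Mean of each estimated parameter over the 5 s window ending at seizure
#' onset (t in \[-width, 0\]) or at seizure offset (t in
#' \[duration - width, duration\]).
#'
#' @param est `sp_estimate` or list with `time` and `theta`; times relative
#'   to onset.
#' @param duration Seizure duration, seconds (needed for `window =
#'   "offset"`).
#' @param window `"onset"` or `"offset"`.
#' @param width Window length, seconds (default 5).
#' @return Named length-5 vector.
#' @export
theta_window_means <- function(est, duration = NULL,
                               window = c("onset", "offset"), width = 5) {
  window <- match.arg(window)
  th <- if (!is.null(est$mean)) est$mean[, 9:13, drop = FALSE] else est$theta
  tt <- est$time
  if (window == "onset") {
    sel <- tt >= -width & tt <= 0
  } else {
    if (is.null(duration)) duration <- est$duration %||% est$seizure$duration
    stopifnot(!is.null(duration))
    sel <- tt >= duration - width & tt <= duration
  }
  if (!any(sel)) stop("window not covered by the estimate")
  stats::setNames(colMeans(th[sel, , drop = FALSE]), theta_names())
}

#' Correlate connectivity with seizure duration
#'
#' Pearson (or Spearman) correlation between per-seizure parameter window
#' means (already averaged across channels) and seizure duration, one test
#' per parameter, significant if p < 0.05 / `bonferroni_m`.
#'
#' @param window_means n_seizures x 5 matrix of window means (see
#'   [theta_window_means()]).
#' @param durations Length-n vector of durations, seconds.
#' @param bonferroni_m Multiple-comparison divisor (see
#'   [bonferroni_divisor()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log_duration Correlate against log duration instead of raw.
#' @param alpha Family significance level before division.
#' @return data.frame, one row per parameter: `parameter`, `r`, `p`,
#'   `significant`, `computable`.
#' @export
correlate_duration <- function(window_means, durations, bonferroni_m = 60,
                               method = c("pearson", "spearman"),
                               log_duration = FALSE, alpha = 0.05) {
  method <- match.arg(method)
  window_means <- as.matrix(window_means)
  stopifnot(nrow(window_means) == length(durations), ncol(window_means) == 5,
            length(durations) >= 3)
  d <- if (log_duration) log(durations) else durations
  out <- data.frame(parameter = theta_names(), r = NA_real_, p = NA_real_,
                    significant = FALSE, computable = TRUE,
                    stringsAsFactors = FALSE)
  for (j in 1:5) {
    x <- window_means[, j]
    if (stats::sd(x) == 0 || stats::sd(d) == 0) {
      out$computable[j] <- FALSE
      next
    }
    ct <- stats::cor.test(x, d, method = method, exact = FALSE)
    out$r[j] <- unname(ct$estimate)
    out$p[j] <- ct$p.value
    out$significant[j] <- ct$p.value < alpha / bonferroni_m
  }
  out
}
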