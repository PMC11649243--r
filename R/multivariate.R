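# Multivariate pattern analysis: linear-combination decomposition of
# paired-condition response patterns into the two isolated patterns, the
# attentional weight-shift statistic, and pattern distances.

#' Decompose a paired-condition pattern into its isolated components
#'
#' Least-squares weights of the two isolated response patterns in the
#' paired pattern, i.e. the coordinates of the orthogonal projection of
#' `v_pair` onto the plane spanned by `v1` and `v2`. No intercept is
#' fitted: the projection plane passes through the origin, and weights
#' are unconstrained in sign. Near-collinear isolated patterns (condition
#' number above `cond_tol`) make the projection ill-posed and flag the
#' decomposition as degenerate.
#'
#' @param v_pair Numeric pattern vector of the paired condition.
#' @param v1,v2 Isolated-condition pattern vectors (same length,
#'   >= 2 voxels).
#' @param cond_tol Condition-number threshold for collinearity
#'   (default `1e6`; real multi-voxel patterns for distinct categories
#'   sit far below it).
#' @return List with elements `w_first`, `w_second`, `residual_norm`,
#'   `residual` (the component of `v_pair` orthogonal to the plane) and
#'   logical `degenerate`.
#' @export
decompose_paired <- function(v_pair, v1, v2, cond_tol = 1e6) {
  stopifnot(length(v1) == length(v2), length(v_pair) == length(v1),
            length(v1) >= 2)
  x <- cbind(v1, v2)
  sv <- svd(x, nu = 0, nv = 0)$d
  if (sv[2] <= 0 || sv[1] / sv[2] > cond_tol) {
    return(list(w_first = NA_real_, w_second = NA_real_,
                residual_norm = NA_real_, residual = NULL,
                degenerate = TRUE))
  }
  fit <- qr(x)
  w <- qr.coef(fit, v_pair)
  res <- v_pair - drop(x %*% w)
  list(w_first = unname(w[1]), w_second = unname(w[2]),
       residual_norm = sqrt(sum(res^2)), residual = res,
       degenerate = FALSE)
}

#' Normalized share of one component in a paired response
#'
#' Relative weight of one isolated pattern among the two component
#' weights of a paired-response decomposition, `w / (w + w_other)`. The
#' normalization compensates for differences in the total weight across
#' category pairs, so shares are comparable between pairs.
#'
#' @param w Weight of the component of interest.
#' @param w_other Weight of the other component.
#' @return Scalar share (unitless).
#' @export
#' @examples
#' weight_share(0.79, 0.31) # share of an attended component
weight_share <- function(w, w_other) {
  w / (w + w_other)
}

#' Attentional weight shift
#'
#' Change in the normalized share of the first isolated pattern in the
#' paired response when attention moves from the first to the second
#' stimulus: `a1/(a1+a2) - b1/(b1+b2)`, where `(a1, a2)` are the
#' component weights with the first stimulus attended and `(b1, b2)`
#' with the second attended. Equals 1 when attention perfectly removes
#' the unattended stimulus and 0 when the two paired patterns are
#' identical. Near-cancelling weight sums (below an epsilon guard) make
#' the share undefined; the result is then `NA` and should be flagged
#' degenerate by callers.
#'
#' @param a1,a2 Weights of the first and second isolated patterns when
#'   the first stimulus is attended.
#' @param b1,b2 The same weights when the second stimulus is attended.
#' @param eps_scale Relative denominator guard; a sum is treated as zero
#'   when its magnitude is below
#'   `eps_scale * (|w| + |w_other| + .Machine$double.eps)`.
#' @return Scalar weight shift, or `NA` when degenerate.
#' @export
#' @examples
#' weight_shift(1, 0, 0, 1)                 # perfect attention
#' weight_shift(0.79, 0.31, 0.43, 0.68)     # worked example, ~0.33
weight_shift <- function(a1, a2, b1, b2, eps_scale = 1e-6) {
  guard <- function(w, w_other) {
    abs(w + w_other) > eps_scale * (abs(w) + abs(w_other) +
                                      .Machine$double.eps)
  }
  if (!guard(a1, a2) || !guard(b1, b2)) return(NA_real_)
  weight_share(a1, a2) - weight_share(b1, b2)
}

#' Multivariate distance between two response patterns
#'
#' Correlation distance `1 - r(v1, v2)` (range 0 to 2; invariant to
#' separate positive affine rescaling of each pattern) or the Euclidean
#' norm of the difference (robustness variant; scale-sensitive). A
#' constant vector leaves the correlation undefined and yields `NA`.
#'
#' @param v1,v2 Pattern vectors of equal length (>= 3 voxels for the
#'   correlation metric).
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @return Scalar distance, `NA` when undefined.
#' @export
multivariate_distance <- function(v1, v2,
                                  metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(length(v1) == length(v2))
  if (metric == "euclidean") return(sqrt(sum((v1 - v2)^2)))
  if (length(v1) < 3 || stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    return(NA_real_)
  }
  1 - stats::cor(v1, v2)
}

#' Cross-validated multivariate result for one category pair
#'
#' Computes the weight shift from one data half (both paired conditions
#' of the pair decomposed against that half's isolated patterns) and the
#' multivariate category distance from the left-out half's isolated
#' patterns. Run averaging precedes vector formation.
#'
#' @param halves A `split_halves` object from [split_runs()].
#' @param pair Canonical pair identifier.
#' @param metric Distance metric, see [multivariate_distance()].
#' @param cond_tol Collinearity guard passed to [decompose_paired()].
#' @return One-row data.frame with columns `pair`, `metric`, `distance`,
#'   `a1`, `a2`, `b1`, `b2`, `delta_w`, `degenerate`.
#' @export
pair_multivariate_result <- function(halves, pair,
                                     metric = c("correlation", "euclidean"),
                                     cond_tol = 1e6) {
  metric <- match.arg(metric)
  stopifnot(inherits(halves, "split_halves"))
  pr <- as_pair_id(pair)
  p <- pair_members(pr)
  mat1 <- average_over_runs(halves$half1)
  mat2 <- average_over_runs(halves$half2)
  v1 <- mat1[, condition_id(p[1])]
  v2 <- mat1[, condition_id(p[2])]
  dec_a <- decompose_paired(mat1[, condition_id(p[1], p[2])], v1, v2,
                            cond_tol = cond_tol)
  dec_b <- decompose_paired(mat1[, condition_id(p[2], p[1])], v1, v2,
                            cond_tol = cond_tol)
  dw <- if (dec_a$degenerate || dec_b$degenerate) NA_real_ else
    weight_shift(dec_a$w_first, dec_a$w_second, dec_b$w_first,
                 dec_b$w_second)
  dist <- multivariate_distance(mat2[, condition_id(p[1])],
                                mat2[, condition_id(p[2])], metric)
  data.frame(pair = pr, metric = metric, distance = dist,
             a1 = dec_a$w_first, a2 = dec_a$w_second,
             b1 = dec_b$w_first, b2 = dec_b$w_second,
             delta_w = dw,
             degenerate = dec_a$degenerate || dec_b$degenerate || is.na(dw),
             stringsAsFactors = FALSE)
}

#' Filter voxels with significantly positive responses
#'
#' Retains voxels whose mean beta across conditions is significantly
#' positive over runs (one-sample, one-sided t test of the per-run
#' condition-mean betas against zero at level `alpha`). Used as a
#' robustness variant of the multivariate analysis.
#'
#' @param ds An [roi_dataset()] with at least 2 runs.
#' @param alpha Significance level (default 0.05).
#' @return The reduced `roi_dataset`, with attribute `n_retained`; an
#'   empty retained set is an error (the ROI is unusable under this
#'   filter).
#' @export
voxel_filter_positive <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "roi_dataset"))
  if (n_runs(ds) < 2) {
    stop("positive-voxel filter needs at least 2 runs", call. = FALSE)
  }
  per_run <- apply(ds$betas, c(1, 3), mean)  # voxel x run mean over conditions
  m <- rowMeans(per_run)
  s <- apply(per_run, 1, stats::sd)
  n <- ncol(per_run)
  t_stat <- m / (s / sqrt(n))
  p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  keep <- !is.na(p) & p < alpha
  if (!any(keep)) {
    stop(sprintf("ROI %s/%s unusable: no voxel passes the positive filter",
                 ds$participant, ds$roi), call. = FALSE)
  }
  out <- roi_dataset(ds$betas[keep, , , drop = FALSE], ds$participant, ds$roi)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Cross-validated multivariate analysis over all pairs
#'
#' Runs [pair_multivariate_result()] for all six category pairs of each
#' participant x ROI dataset, optionally after the positive-voxel
#' filter.
#'
#' @inheritParams analyze_univariate
#' @param metric Distance metric, see [multivariate_distance()].
#' @param positive_filter Apply [voxel_filter_positive()] first?
#' @param alpha Level for the positive filter.
#' @return Tidy data.frame: `participant`, `roi`, `pair`, `metric`,
#'   `distance`, `a1`, `a2`, `b1`, `b2`, `delta_w`, `degenerate`,
#'   `n_voxels`.
#' @export
analyze_multivariate <- function(datasets,
                                 scheme = c("odd_even", "first_last"),
                                 metric = c("correlation", "euclidean"),
                                 positive_filter = FALSE, alpha = 0.05) {
  scheme <- match.arg(scheme)
  metric <- match.arg(metric)
  if (inherits(datasets, "roi_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    if (positive_filter) ds <- voxel_filter_positive(ds, alpha)
    halves <- split_runs(ds, scheme)
    res <- do.call(rbind, lapply(category_pairs()$pair, function(pr) {
      pair_multivariate_result(halves, pr, metric)
    }))
    cbind(data.frame(participant = ds$participant, roi = ds$roi,
                     stringsAsFactors = FALSE),
          res, n_voxels = n_voxels(ds))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname shift_distance_correlation
#' @details `weightshift_distance_correlation()` is the multivariate
#'   counterpart, correlating the weight shift with the multivariate
#'   category distance.
#' @export
weightshift_distance_correlation <- function(results, xcol = "distance",
                                             ycol = "delta_w") {
  shift_distance_correlation(results, xcol = xcol, ycol = ycol)
}
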