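# Univariate measures of attentional modulation: per-voxel preference
# assignment, category distance from the isolated conditions, attentional
# shift from the paired conditions, and their cross-validated correlation
# across the six category pairs.

#' Assign per-voxel category preferences for a pair
#'
#' For each voxel, the category of the pair that elicits the larger
#' response in its isolated condition is labelled the more-preferred (M)
#' category, the other the less-preferred (L). Exact ties are broken
#' deterministically towards the alphabetically first category and
#' flagged.
#'
#' @param mat Run-averaged `voxel x condition` beta matrix (see
#'   [average_over_runs()]).
#' @param pair Canonical pair identifier (see [pair_id()]) or a row of
#'   [category_pairs()].
#' @return A data.frame with one row per voxel and columns `voxel`, `m`,
#'   `l`, `tied`.
#' @export
assign_preferences <- function(mat, pair) {
  p <- pair_members(as_pair_id(pair))
  r1 <- mat[, condition_id(p[1]), drop = TRUE]
  r2 <- mat[, condition_id(p[2]), drop = TRUE]
  # p is alphabetically sorted, so ties resolve to p[1]
  m <- ifelse(r1 >= r2, p[1], p[2])
  data.frame(voxel = rownames(mat), m = m,
             l = ifelse(m == p[1], p[2], p[1]),
             tied = r1 == r2,
             stringsAsFactors = FALSE, row.names = NULL)
}

as_pair_id <- function(pair) {
  if (is.data.frame(pair)) return(pair_id(pair$first[1], pair$second[1]))
  stopifnot(is.character(pair), length(pair) == 1L)
  pair_id(pair_members(pair)[1], pair_members(pair)[2])
}

#' Univariate category distance
#'
#' Mean over voxels of the difference between the isolated responses to
#' the voxel's more-preferred and less-preferred category of the pair.
#' When `prefs` is derived from the same data half the result is
#' non-negative by construction.
#'
#' @param mat Run-averaged `voxel x condition` beta matrix.
#' @param pair Canonical pair identifier.
#' @param prefs Preference assignment from [assign_preferences()]
#'   covering the same voxels.
#' @return Scalar distance in beta units.
#' @export
univariate_distance <- function(mat, pair, prefs) {
  check_prefs(mat, as_pair_id(pair), prefs)
  r_m <- mat[cbind(seq_len(nrow(mat)), match(condition_id(prefs$m),
                                             colnames(mat)))]
  r_l <- mat[cbind(seq_len(nrow(mat)), match(condition_id(prefs$l),
                                             colnames(mat)))]
  mean(r_m - r_l)
}

#' Univariate attentional shift
#'
#' Mean over voxels of the drop in response of the paired condition when
#' attention moves from the voxel's more-preferred category to the
#' less-preferred one (both stimuli present in both conditions, so the
#' difference isolates the attention effect). For cross-validated use,
#' `prefs` must come from the other data half.
#'
#' @inheritParams univariate_distance
#' @return Scalar shift in beta units.
#' @export
univariate_shift <- function(mat, pair, prefs) {
  check_prefs(mat, as_pair_id(pair), prefs)
  i_att_m <- match(condition_id(prefs$m, prefs$l), colnames(mat))
  i_att_l <- match(condition_id(prefs$l, prefs$m), colnames(mat))
  rows <- seq_len(nrow(mat))
  mean(mat[cbind(rows, i_att_m)] - mat[cbind(rows, i_att_l)])
}

check_prefs <- function(mat, pair, prefs) {
  p <- pair_members(pair)
  stopifnot(is.data.frame(prefs),
            all(c("voxel", "m", "l") %in% names(prefs)))
  if (nrow(prefs) != nrow(mat) ||
      !identical(as.character(prefs$voxel), rownames(mat))) {
    stop("preference map does not cover the matrix voxels in order",
         call. = FALSE)
  }
  if (!all((prefs$m == p[1] & prefs$l == p[2]) |
           (prefs$m == p[2] & prefs$l == p[1]))) {
    stop("preference labels do not match the pair ", pair, call. = FALSE)
  }
  invisible(TRUE)
}

#' Cross-validated univariate analysis over all pairs
#'
#' For each participant x ROI dataset: splits the runs into halves,
#' assigns voxel preferences and computes the univariate category
#' distance on one half, and computes the univariate shift on the
#' left-out half. Setting `cross_validated = FALSE` deliberately computes
#' the shift on the same half used for preference assignment (a biased
#' variant kept for demonstrating why the split matters).
#'
#' @param datasets A list of [roi_dataset()] objects (or a single one).
#' @param scheme Run-split scheme, see [split_runs()].
#' @param distance_half Half used for the distance: `"half1"` (the half
#'   that also assigns preferences, the default sequence) or `"half2"`
#'   (robustness alternative).
#' @param cross_validated Logical; compute the shift on the left-out
#'   half (default) or on the preference half.
#' @return Tidy data.frame with columns `participant`, `roi`, `pair`,
#'   `distance`, `shift`, `n_voxels`, `n_tied`.
#' @export
analyze_univariate <- function(datasets, scheme = c("odd_even", "first_last"),
                               distance_half = c("half1", "half2"),
                               cross_validated = TRUE) {
  scheme <- match.arg(scheme)
  distance_half <- match.arg(distance_half)
  if (inherits(datasets, "roi_dataset")) datasets <- list(datasets)
  pairs <- category_pairs()$pair
  rows <- lapply(datasets, function(ds) {
    halves <- split_runs(ds, scheme)
    mat1 <- average_over_runs(halves$half1)
    mat2 <- average_over_runs(halves$half2)
    dist_mat <- if (distance_half == "half1") mat1 else mat2
    shift_mat <- if (cross_validated) mat2 else mat1
    do.call(rbind, lapply(pairs, function(pr) {
      prefs <- assign_preferences(mat1, pr)
      data.frame(participant = ds$participant, roi = ds$roi, pair = pr,
                 distance = univariate_distance(dist_mat, pr, prefs),
                 shift = univariate_shift(shift_mat, pr, prefs),
                 n_voxels = nrow(prefs), n_tied = sum(prefs$tied),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-participant correlation between an attention effect and distance
#'
#' Pearson correlation across the six category pairs of one participant
#' x ROI, between a distance column and an effect column (univariate
#' shift or multivariate weight shift). Pairs with missing values
#' (degenerate decompositions) are dropped and counted; a constant
#' variable yields a flagged `NA` rather than an error.
#'
#' @param results Tidy pair-level results table containing `participant`,
#'   `roi`, the two columns named below, one row per pair.
#' @param xcol,ycol Column names to correlate (default distance vs
#'   shift).
#' @return Data.frame with columns `participant`, `roi`, `r`, `n_pairs`,
#'   `degenerate` (TRUE when r is undefined).
#' @export
shift_distance_correlation <- function(results, xcol = "distance",
                                       ycol = "shift") {
  stopifnot(all(c("participant", "roi", xcol, ycol) %in% names(results)))
  groups <- split(results, list(results$participant, results$roi),
                  drop = TRUE, sep = "/")
  out <- do.call(rbind, lapply(sort(names(groups)), function(key) {
    g <- groups[[key]]
    ok <- stats::complete.cases(g[, c(xcol, ycol)])
    x <- g[[xcol]][ok]
    y <- g[[ycol]][ok]
    degenerate <- length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0
    data.frame(participant = g$participant[1], roi = g$roi[1],
               r = if (degenerate) NA_real_ else stats::cor(x, y),
               n_pairs = length(x), degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
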