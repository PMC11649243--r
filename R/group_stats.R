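# Group-level inference over participants: one-sample tests on
# per-participant effects and correlations, multiple-comparison
# correction over the six category pairs, and report assembly.

#' One-sample t test of per-participant values against zero
#'
#' Missing or degenerate participants are dropped and counted. A
#' zero-variance sample has no valid t distribution; the result is then
#' flagged degenerate with the limiting p value (0 when the common value
#' is away from zero, 1 at zero).
#'
#' @param values Numeric vector, one value per participant.
#' @param alternative `"greater"` (default; positive effects are the
#'   directional hypothesis throughout) or `"two_sided"`.
#' @param label Optional label carried into the result.
#' @return One-row data.frame: `label`, `t_stat`, `df`, `p_raw`, `n`,
#'   `n_dropped`, `mean`, `sem`, `ci_lo`, `ci_hi` (95% two-sided CI of
#'   the mean), `degenerate`.
#' @export
one_sample_test <- function(values, alternative = c("greater", "two_sided"),
                            label = NA_character_) {
  alternative <- match.arg(alternative)
  n_dropped <- sum(!is.finite(values))
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) {
    stop("one-sample test needs at least 3 non-missing participants, got ",
         n, call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    m <- values[1]
    return(data.frame(label = label,
                      t_stat = if (m == 0) 0 else Inf * sign(m),
                      df = n - 1L,
                      p_raw = if (m == 0) 1 else
                        if (alternative == "greater" && m < 0) 1 else 0,
                      n = n, n_dropped = n_dropped,
                      mean = m, sem = 0, ci_lo = m, ci_hi = m,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(values, mu = 0,
                      alternative = if (alternative == "greater") "greater"
                      else "two.sided")
  ci <- stats::t.test(values, mu = 0, conf.level = 0.95)$conf.int
  data.frame(label = label, t_stat = unname(tt$statistic),
             df = unname(tt$parameter), p_raw = tt$p.value,
             n = n, n_dropped = n_dropped,
             mean = mean(values), sem = stats::sd(values) / sqrt(n),
             ci_lo = ci[1], ci_hi = ci[2],
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Multiple-comparison correction over a family of p values
#'
#' Bonferroni (default; multiplies by the family size and caps at 1) or
#' Holm step-down. The natural family here is the six category pairs
#' within one ROI.
#'
#' @param p_raws Numeric p values in \[0, 1\].
#' @param method `"bonferroni"` or `"holm"`.
#' @return Corrected p values, same length and order.
#' @export
correct_pvalues <- function(p_raws, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  ok <- is.na(p_raws) | (p_raws >= 0 & p_raws <= 1)
  if (!all(ok)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_raws, method = method)
}

#' Group tests of per-pair attentional shifts
#'
#' One-sample tests (shift > 0) per ROI x pair across participants,
#' corrected over the six pairs within each ROI.
#'
#' @param results Pair-level results table from [analyze_univariate()]
#'   or [analyze_multivariate()].
#' @param effect Column tested (`"shift"` or `"delta_w"`).
#' @param method Correction method, see [correct_pvalues()].
#' @return Data.frame with one row per ROI x pair including `p_raw` and
#'   `p_corrected`.
#' @export
group_shift_tests <- function(results, effect = "shift",
                              method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  stopifnot(effect %in% names(results))
  groups <- split(results, results$roi, drop = TRUE)
  out <- do.call(rbind, lapply(sort(names(groups)), function(roi) {
    g <- groups[[roi]]
    per_pair <- do.call(rbind, lapply(sort(unique(g$pair)), function(pr) {
      res <- one_sample_test(g[[effect]][g$pair == pr], "greater",
                             label = pr)
      cbind(data.frame(roi = roi, stringsAsFactors = FALSE), res)
    }))
    per_pair$p_corrected <- correct_pvalues(per_pair$p_raw, method)
    per_pair
  }))
  names(out)[names(out) == "label"] <- "pair"
  rownames(out) <- NULL
  out
}

#' Group test of per-participant effect-distance correlations
#'
#' One-sample test per ROI of the per-participant Pearson correlations
#' (raw r by default, matching how mean correlations are usually
#' summarized; Fisher z available) against zero.
#'
#' @param cor_table Output of [shift_distance_correlation()] or
#'   [weightshift_distance_correlation()].
#' @param alternative Directional hypothesis (default `"greater"`).
#' @param fisher_z Test Fisher-transformed correlations instead of raw
#'   r.
#' @return Data.frame with one row per ROI.
#' @export
group_correlation_test <- function(cor_table,
                                   alternative = c("greater", "two_sided"),
                                   fisher_z = FALSE) {
  alternative <- match.arg(alternative)
  groups <- split(cor_table, cor_table$roi, drop = TRUE)
  out <- do.call(rbind, lapply(sort(names(groups)), function(roi) {
    r <- groups[[roi]]$r
    if (fisher_z) r <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    res <- one_sample_test(r, alternative, label = roi)
    names(res)[names(res) == "label"] <- "roi"
    res
  }))
  rownames(out) <- NULL
  out
}

#' Assemble a deterministic analysis report
#'
#' Collates the univariate and multivariate pair-level tables into
#' per-ROI summaries (pair-level means and SEMs, per-participant
#' correlations, group tests, degenerate counts) plus the scatter data
#' behind shift-versus-distance and weight-shift-versus-distance plots.
#' All tables are sorted deterministically; given the same inputs the
#' report is byte-identical. With a single participant, SEM columns are
#' `NA`. An empty or `NULL` multivariate table is noted in
#' `$sections` and its tables are omitted.
#'
#' @param univariate Pair-level table from [analyze_univariate()].
#' @param multivariate Optional pair-level table from
#'   [analyze_multivariate()].
#' @param correction Multiple-comparison method for the group tests.
#' @param output_dir Optional directory; when given, every table is
#'   written there as a CSV file.
#' @return Invisibly, a named list of data.frames (`pair_summary`,
#'   `univariate_correlations`, `univariate_group`, and the
#'   multivariate counterparts when available) plus a `sections`
#'   character vector describing what the report contains.
#' @export
build_report <- function(univariate, multivariate = NULL,
                         correction = c("bonferroni", "holm"),
                         output_dir = NULL) {
  correction <- match.arg(correction)
  req <- c("participant", "roi", "pair", "distance", "shift")
  if (!all(req %in% names(univariate))) {
    stop("univariate table lacks column(s): ",
         paste(setdiff(req, names(univariate)), collapse = ", "),
         call. = FALSE)
  }
  report <- list()
  sections <- character()

  pair_summary <- function(tab, value_cols) {
    grp <- split(tab, list(tab$roi, tab$pair), drop = TRUE, sep = "\r")
    out <- do.call(rbind, lapply(sort(names(grp)), function(key) {
      g <- grp[[key]]
      row <- data.frame(roi = g$roi[1], pair = g$pair[1],
                        n_participants = length(unique(g$participant)),
                        stringsAsFactors = FALSE)
      for (col in value_cols) {
        v <- g[[col]][is.finite(g[[col]])]
        row[[paste0(col, "_mean")]] <- mean(v)
        row[[paste0(col, "_sem")]] <- if (length(v) > 1)
          stats::sd(v) / sqrt(length(v)) else NA_real_
      }
      row
    }))
    rownames(out) <- NULL
    out
  }

  n_part <- length(unique(univariate$participant))
  report$pair_summary <- pair_summary(univariate, c("distance", "shift"))
  report$univariate_correlations <- shift_distance_correlation(univariate)
  if (n_part >= 3) {
    report$univariate_group <- group_shift_tests(univariate, "shift",
                                                 correction)
  } else {
    sections <- c(sections,
                  "group tests: omitted (fewer than 3 participants)")
  }
  report$univariate_scatter <-
    univariate[order(univariate$roi, univariate$pair,
                     univariate$participant),
               c("participant", "roi", "pair", "distance", "shift")]
  rownames(report$univariate_scatter) <- NULL
  sections <- c(sections, "univariate")

  if (!is.null(multivariate) && nrow(multivariate) > 0) {
    report$multivariate_summary <-
      pair_summary(multivariate, c("distance", "delta_w"))
    report$multivariate_summary$n_degenerate <- vapply(
      seq_len(nrow(report$multivariate_summary)), function(i) {
        sel <- multivariate$roi == report$multivariate_summary$roi[i] &
          multivariate$pair == report$multivariate_summary$pair[i]
        sum(multivariate$degenerate[sel])
      }, integer(1))
    report$multivariate_correlations <-
      weightshift_distance_correlation(multivariate)
    if (n_part >= 3) {
      report$multivariate_group <-
        group_correlation_test(report$multivariate_correlations)
    }
    report$multivariate_scatter <-
      multivariate[order(multivariate$roi, multivariate$pair,
                         multivariate$participant),
                   c("participant", "roi", "pair", "distance", "delta_w",
                     "degenerate")]
    rownames(report$multivariate_scatter) <- NULL
    sections <- c(sections, "multivariate")
  } else {
    sections <- c(sections, "multivariate: absent (no results supplied)")
  }
  report$sections <- sections

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    for (nm in setdiff(names(report), "sections")) {
      data.table::fwrite(report[[nm]],
                         file.path(output_dir, paste0(nm, ".csv")))
    }
    writeLines(report$sections, file.path(output_dir, "sections.txt"))
  }
  invisible(report)
}
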