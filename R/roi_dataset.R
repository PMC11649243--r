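# RoiDataset: voxel x condition x run array of GLM beta coefficients for
# one participant x region, plus tabular I/O and run-splitting utilities.

#' Construct an ROI dataset
#'
#' Bundles the voxel-wise GLM beta coefficients of one participant and one
#' region of interest into a `voxel x condition x run` array. Every run
#' must contain all 16 task conditions over an identical voxel set.
#'
#' @param betas Numeric 3-d array indexed `(voxel, condition, run)`.
#'   Condition dimnames must be the 16 identifiers of
#'   [condition_table()]`$condition` (any order; they are reordered to
#'   canonical order). Voxel and run dimnames are optional and default to
#'   `v1..vN` / `run01..runR`.
#' @param participant Participant identifier (scalar).
#' @param roi Region-of-interest name (scalar), e.g. `"LO"`.
#' @return An object of class `roi_dataset`: a list with elements
#'   `participant`, `roi`, `betas`.
#' @export
roi_dataset <- function(betas, participant, roi) {
  stopifnot(is.array(betas), length(dim(betas)) == 3L, is.numeric(betas))
  conds <- condition_table()$condition
  dn <- dimnames(betas)
  if (is.null(dn) || is.null(dn[[2]])) {
    stop("`betas` must carry condition identifiers as dimnames[[2]]",
         call. = FALSE)
  }
  if (!setequal(dn[[2]], conds) || anyDuplicated(dn[[2]])) {
    missing <- setdiff(conds, dn[[2]])
    extra <- setdiff(dn[[2]], conds)
    stop(sprintf("condition set must be exactly the 16 design conditions%s%s",
                 if (length(missing)) paste0("; missing: ",
                                             paste(missing, collapse = ", ")) else "",
                 if (length(extra)) paste0("; unknown: ",
                                           paste(extra, collapse = ", ")) else ""),
         call. = FALSE)
  }
  if (is.null(dn[[1]])) dn[[1]] <- paste0("v", seq_len(dim(betas)[1]))
  if (is.null(dn[[3]])) dn[[3]] <- sprintf("run%02d", seq_len(dim(betas)[3]))
  dimnames(betas) <- dn
  betas <- betas[, conds, , drop = FALSE]  # canonical condition order
  structure(list(participant = as.character(participant),
                 roi = as.character(roi),
                 betas = betas),
            class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset> participant %s, ROI %s: %d voxels x %d conditions x %d runs\n",
              x$participant, x$roi, n_voxels(x), dim(x$betas)[2], n_runs(x)))
  invisible(x)
}

#' Number of voxels / runs in an ROI dataset
#'
#' @param ds An [roi_dataset()].
#' @return Integer count.
#' @export
n_voxels <- function(ds) dim(ds$betas)[1]

#' @rdname n_voxels
#' @export
n_runs <- function(ds) dim(ds$betas)[3]

#' Read a beta table into ROI datasets
#'
#' Reads a delimited text table (comma or tab separated, header required)
#' with columns `participant`, `roi`, `run`, `voxel`, `attended`,
#' `ignored`, `beta` and assembles one [roi_dataset()] per
#' `(participant, roi)`. The `ignored` column uses the sentinel `"none"`
#' for isolated conditions. Every `(voxel, condition, run)` cell must be
#' present exactly once within a participant x ROI; violations are
#' reported with row context.
#'
#' @param path Path to the table.
#' @return Named list of `roi_dataset` objects, names
#'   `"<participant>/<roi>"`, in sorted order.
#' @export
read_beta_table <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "auto",
                           colClasses = list(character = c()))
  beta_table_to_datasets(as.data.frame(tab))
}

# internal: long data.frame -> list of roi_dataset (shared by read + simulate)
beta_table_to_datasets <- function(df) {
  required <- c("participant", "roi", "run", "voxel", "attended",
                "ignored", "beta")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("beta table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$attended <- as.character(df$attended)
  df$ignored <- as.character(df$ignored)
  if (!is.numeric(df$beta)) {
    stop("`beta` column must be numeric", call. = FALSE)
  }
  bad <- which(!df$attended %in% CATEGORIES)
  if (length(bad)) {
    stop(sprintf("unknown attended category %s (first offending row %d)",
                 dQuote(df$attended[bad[1]]), bad[1]), call. = FALSE)
  }
  bad <- which(!df$ignored %in% c(CATEGORIES, NONE))
  if (length(bad)) {
    stop(sprintf("unknown ignored category %s (first offending row %d)",
                 dQuote(df$ignored[bad[1]]), bad[1]), call. = FALSE)
  }
  bad <- which(df$attended == df$ignored)
  if (length(bad)) {
    stop(sprintf("attended and ignored category coincide (%s) at row %d",
                 dQuote(df$attended[bad[1]]), bad[1]), call. = FALSE)
  }
  df$condition <- condition_id(df$attended, df$ignored)
  conds <- condition_table()$condition

  groups <- split(df, list(df$participant, df$roi), drop = TRUE, sep = "/")
  out <- lapply(sort(names(groups)), function(key) {
    g <- groups[[key]]
    voxels <- sort_stable(unique(g$voxel))
    runs <- sort_stable(unique(g$run))
    key_str <- paste(g$voxel, g$condition, g$run, sep = "\r")
    dup <- which(duplicated(key_str))
    if (length(dup)) {
      stop(sprintf("duplicated cell for %s: voxel %s, condition %s, run %s",
                   key, g$voxel[dup[1]], g$condition[dup[1]], g$run[dup[1]]),
           call. = FALSE)
    }
    arr <- array(NA_real_,
                 dim = c(length(voxels), length(conds), length(runs)),
                 dimnames = list(as.character(voxels), conds,
                                 as.character(runs)))
    arr[cbind(match(g$voxel, voxels), match(g$condition, conds),
              match(g$run, runs))] <- g$beta
    if (anyNA(arr)) {
      miss <- which(is.na(arr), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "incomplete design for %s: missing condition %s for voxel %s, run %s",
        key, conds[miss[2]], as.character(voxels)[miss[1]],
        as.character(runs)[miss[3]]), call. = FALSE)
    }
    roi_dataset(arr, participant = g$participant[1], roi = g$roi[1])
  })
  names(out) <- sort(names(groups))
  out
}

# sort character ids numerically when they all look numeric, else lexically
sort_stable <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(as.character(x))
}

#' Write ROI datasets back to a delimited beta table
#'
#' Inverse of [read_beta_table()] up to row order and floating-point text
#' formatting.
#'
#' @param datasets A single [roi_dataset()] or a list of them.
#' @param path Output path; `.tsv` extension writes tab-separated,
#'   anything else comma-separated.
#' @return `path`, invisibly.
#' @export
write_beta_table <- function(datasets, path) {
  if (inherits(datasets, "roi_dataset")) datasets <- list(datasets)
  cond <- condition_table()
  rows <- lapply(datasets, function(ds) {
    d <- dim(ds$betas)
    dn <- dimnames(ds$betas)
    idx <- expand.grid(v = seq_len(d[1]), c = seq_len(d[2]), r = seq_len(d[3]),
                       KEEP.OUT.ATTRS = FALSE)
    data.frame(participant = ds$participant, roi = ds$roi,
               run = dn[[3]][idx$r], voxel = dn[[1]][idx$v],
               attended = cond$attended[idx$c], ignored = cond$ignored[idx$c],
               beta = as.vector(ds$betas),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(tab, path, sep = sep)
  invisible(path)
}

#' Split the runs of an ROI dataset into two halves
#'
#' Partitions the runs into two disjoint halves for split-half
#' cross-validation, deterministically: `odd_even` sends runs with odd
#' ordinal position to half 1 (interleaves the halves across the session,
#' balancing slow drifts), `first_last` sends the first
#' `ceiling(n_runs / 2)` runs to half 1.
#'
#' @param ds An [roi_dataset()] with at least two runs.
#' @param scheme Partition scheme, `"odd_even"` (default) or
#'   `"first_last"`.
#' @return List of class `split_halves` with `roi_dataset` elements
#'   `half1` and `half2`; half sizes differ by at most one run.
#' @export
split_runs <- function(ds, scheme = c("odd_even", "first_last")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ds, "roi_dataset"))
  nr <- n_runs(ds)
  if (nr < 2) {
    stop("split-half cross-validation needs at least 2 runs, got ", nr,
         call. = FALSE)
  }
  ord <- seq_len(nr)
  in_half1 <- switch(scheme,
    odd_even = ord %% 2L == 1L,
    first_last = ord <= ceiling(nr / 2))
  take <- function(sel) {
    roi_dataset(ds$betas[, , sel, drop = FALSE], ds$participant, ds$roi)
  }
  structure(list(half1 = take(in_half1), half2 = take(!in_half1)),
            class = "split_halves")
}

#' Average betas over runs
#'
#' @param ds An [roi_dataset()].
#' @return Numeric `voxel x condition` matrix of run-averaged betas.
#' @export
average_over_runs <- function(ds) {
  stopifnot(inherits(ds, "roi_dataset"))
  rowMeans(ds$betas, dims = 2L)
}
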