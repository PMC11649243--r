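# Condition bookkeeping for the 16-condition attention design:
# 4 isolated conditions (one category presented and attended) plus
# 12 paired conditions (attended category superimposed with an ignored one).

CATEGORIES <- c("body", "car", "cat", "house")
NONE <- "none"

#' Object categories of the design
#'
#' The design uses a closed set of four object categories: human bodies,
#' cars, cats, and houses. All category arguments throughout the package
#' must come from this set.
#'
#' @return Character vector of the four category names, in canonical
#'   (alphabetical) order.
#' @export
#' @examples
#' categories()
categories <- function() CATEGORIES

#' Canonical condition identifier
#'
#' Builds the condition label used to index beta matrices: the attended
#' category and the ignored category joined by a dot, with `"none"` as the
#' ignored slot of isolated conditions.
#'
#' @param attended Attended category, one of [categories()].
#' @param ignored Ignored category or `"none"` (default) for isolated
#'   conditions.
#' @return Character vector of condition identifiers, e.g. `"body.none"`,
#'   `"body.car"`.
#' @export
#' @examples
#' condition_id("body")        # isolated body
#' condition_id("body", "car") # attend body, ignore car
condition_id <- function(attended, ignored = NONE) {
  paste(attended, ignored, sep = ".")
}

#' Enumerate the 16 task conditions
#'
#' @return A data.frame with columns `attended`, `ignored`, `condition`
#'   (the identifier from [condition_id()]) and logical `isolated`;
#'   exactly 16 rows: the 4 isolated conditions followed by the 12 paired
#'   conditions.
#' @export
#' @examples
#' condition_table()
condition_table <- function() {
  iso <- data.frame(attended = CATEGORIES, ignored = NONE,
                    stringsAsFactors = FALSE)
  paired <- expand.grid(ignored = CATEGORIES, attended = CATEGORIES,
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[, c("attended", "ignored")]
  paired <- paired[paired$attended != paired$ignored, ]
  out <- rbind(iso, paired)
  out$condition <- condition_id(out$attended, out$ignored)
  out$isolated <- out$ignored == NONE
  rownames(out) <- NULL
  out
}

#' Enumerate the six category pairs
#'
#' Unordered pairs of distinct categories; pair identity is
#' order-invariant and the canonical form lists members alphabetically.
#'
#' @return A data.frame with columns `first`, `second`, `pair`
#'   (e.g. `"body-car"`); exactly 6 rows.
#' @export
#' @examples
#' category_pairs()
category_pairs <- function() {
  cmb <- utils::combn(CATEGORIES, 2)
  out <- data.frame(first = cmb[1, ], second = cmb[2, ],
                    stringsAsFactors = FALSE)
  out$pair <- paste(out$first, out$second, sep = "-")
  out
}

#' Canonical pair identifier
#'
#' @param a,b The two (distinct) categories, in either order.
#' @return The canonical pair label, e.g. `pair_id("car", "body")` is
#'   `"body-car"`.
#' @export
pair_id <- function(a, b) {
  stopifnot(a %in% CATEGORIES, b %in% CATEGORIES, all(a != b))
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

# internal: members of a canonical pair id
pair_members <- function(pair) {
  strsplit(pair, "-", fixed = TRUE)[[1]]
}

assert_category <- function(x, arg = deparse(substitute(x))) {
  bad <- setdiff(unique(x), CATEGORIES)
  if (length(bad)) {
    stop(sprintf("unknown category label(s) in `%s`: %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
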