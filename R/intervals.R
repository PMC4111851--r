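# Interval helpers. All coordinates in the package are 0-based half-open
# [start, end); conversion to the 1-based closed convention happens only at
# the IRanges/BED/SAM boundaries.

#' Validate an interval table
#'
#' Checks that a data frame has `contig`, `start`, `end` columns with
#' `0 <= start < end`. Used at the entry of every interval-consuming
#' function.
#'
#' @param x A data frame with columns `contig`, `start`, `end`.
#' @param arg Name used in error messages.
#' @return `x` as a tibble, invisibly usable downstream.
#' @keywords internal
check_intervals <- function(x, arg = "x") {
  if (is.null(x)) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  x <- as_tibble(x)
  need <- c("contig", "start", "end")
  if (!all(need %in% names(x))) {
    stop(sprintf("`%s` must have columns contig, start, end", arg), call. = FALSE)
  }
  if (nrow(x) > 0 && any(x$start < 0 | x$end <= x$start)) {
    stop(sprintf("`%s` has intervals with start < 0 or end <= start", arg),
         call. = FALSE)
  }
  x
}

to_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

from_iranges <- function(ir, contig) {
  tibble(contig = contig,
         start = IRanges::start(ir) - 1L,
         end = IRanges::end(ir))
}

#' Merge overlapping intervals
#'
#' Transitive union of overlapping intervals per contig, keeping outermost
#' endpoints. By default only intervals sharing at least one base are
#' merged; abutting intervals stay separate.
#'
#' @param x Interval table (`contig`, `start`, `end`).
#' @param merge_abutting Also merge intervals that touch end-to-start.
#' @return Tibble of non-overlapping intervals sorted by contig and start.
#' @export
merge_intervals <- function(x, merge_abutting = FALSE) {
  x <- check_intervals(x)
  if (nrow(x) == 0) return(x[, c("contig", "start", "end")])
  gap <- if (merge_abutting) 1L else 0L
  x %>%
    dplyr::group_by(.data$contig) %>%
    dplyr::group_modify(function(d, key) {
      r <- IRanges::reduce(to_iranges(d), min.gapwidth = gap)
      tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$contig, .data$start)
}

#' Total bases covered by an interval set
#'
#' @param x Interval table.
#' @return Total number of distinct covered bases.
#' @export
covered_bases <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0) return(0)
  sum(m$end - m$start)
}

#' Intersect two interval sets
#'
#' @param x,y Interval tables.
#' @return Tibble of the per-contig intersection intervals.
#' @export
intersect_intervals <- function(x, y) {
  x <- check_intervals(x, "x"); y <- check_intervals(y, "y")
  contigs <- intersect(unique(x$contig), unique(y$contig))
  purrr::map_dfr(contigs, function(ctg) {
    ix <- IRanges::reduce(to_iranges(x[x$contig == ctg, ]))
    iy <- IRanges::reduce(to_iranges(y[y$contig == ctg, ]))
    from_iranges(IRanges::intersect(ix, iy), ctg)
  })
}

#' Per-interval overlap with a feature set
#'
#' For each row of `x`, the number of its bases covered by `features`.
#'
#' @param x,features Interval tables.
#' @return Integer vector along rows of `x`.
#' @export
overlap_bases <- function(x, features) {
  x <- check_intervals(x, "x"); features <- check_intervals(features, "features")
  out <- numeric(nrow(x))
  for (ctg in unique(x$contig)) {
    i <- which(x$contig == ctg)
    f <- features[features$contig == ctg, ]
    if (nrow(f) == 0) next
    ix <- to_iranges(x[i, ])
    fr <- IRanges::reduce(to_iranges(f))
    hits <- IRanges::findOverlaps(ix, fr)
    if (length(hits) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      ix[S4Vectors::queryHits(hits)], fr[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    v <- numeric(length(i))
    v[as.integer(names(agg))] <- agg
    out[i] <- v
  }
  out
}

# fraction of each x interval covered by features
overlap_fraction <- function(x, features) {
  overlap_bases(x, features) / (x$end - x$start)
}

# TRUE for rows of x overlapping >= 1 bp of features
overlaps_any <- function(x, features) {
  overlap_bases(x, features) > 0
}
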