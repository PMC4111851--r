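# Mappability-aware window construction.
#
# Hard masking replaces repeat bases with N. The original window currency
# counts non-masked characters, which is blind to fragmentation: a region of
# alternating short N and clean blocks holds many unmasked bases but no
# clean full-length read placement, so its read depth collapses and mimics
# a deletion. The enhanced currency counts "unique hits" -- distinct start
# positions where a full-length read fits entirely on unmasked bases -- so
# fragmented regions contribute no window mass and the bias disappears.

seq_is_n <- function(seq) {
  charToRaw(seq) == as.raw(78L)  # 'N'
}

# cumulative G+C and non-N counts; cum[i+1] - cum[start] style prefix sums
seq_cumulants <- function(seq) {
  x <- charToRaw(seq)
  gc <- x == as.raw(71L) | x == as.raw(67L) | x == as.raw(103L) | x == as.raw(99L)
  nn <- x != as.raw(78L) & x != as.raw(110L)
  list(gc = c(0, cumsum(gc)), acgt = c(0, cumsum(nn)))
}

resolve_seqs <- function(x) {
  if (inherits(x, "ref_bundle")) masked_seqs(x) else x
}

#' Unique-hit mappability track
#'
#' For each contig, the sorted 0-based start positions where a read of
#' `read_length` bases lies entirely on non-masked (non-N) bases — the
#' positions a clean full-length forward alignment can occupy. These
#' positions are the window-size currency of the enhanced dialect.
#'
#' @param x A `ref_bundle` (its hard-masked sequences are used) or a named
#'   character vector of masked sequences.
#' @param read_length Read length in bp (>= 1).
#' @return A `mappability_track`: list with `units` (named list of integer
#'   vectors of 0-based unit starts), `read_length`, `contig_lengths`.
#'   Contigs shorter than `read_length` get an empty unit set.
#' @examples
#' trk <- compute_unique_hit_track(c(chr = strrep("A", 300)), 100)
#' length(trk$units$chr)  # 201
#' @export
compute_unique_hit_track <- function(x, read_length = 100L) {
  stopifnot(read_length >= 1)
  seqs <- resolve_seqs(x)
  L <- as.integer(read_length)
  units <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < L) return(integer(0))
    csn <- c(0L, cumsum(seq_is_n(s)))
    p <- 0:(n - L)
    p[csn[p + L + 1L] - csn[p + 1L] == 0L]
  })
  structure(list(units = units, read_length = L,
                 contig_lengths = setNames(nchar(seqs), names(seqs))),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  cat(sprintf("<mappability_track> L=%d, %d contig(s), %s units\n",
              x$read_length, length(x$units),
              format(sum(lengths(x$units)), big.mark = ",")))
  invisible(x)
}

new_window_set <- function(df, kind, dialect, units_per_window, slide_units,
                           read_length) {
  structure(df, class = c("window_set", class(tibble())),
            kind = kind, dialect = dialect,
            units_per_window = as.integer(units_per_window),
            slide_units = as.integer(slide_units),
            read_length = as.integer(read_length))
}

restore_window_attrs <- function(df, template) {
  new_window_set(df, attr(template, "kind"), attr(template, "dialect"),
                 attr(template, "units_per_window"),
                 attr(template, "slide_units"), attr(template, "read_length"))
}

# windows over a sorted unit-position vector; span_end = last unit + end_off
emit_windows <- function(u, upw, slide, end_off) {
  n <- length(u)
  if (n == 0) return(tibble(start = integer(), end = integer(), n_units = integer()))
  if (slide == upw) {                      # tiling
    first <- seq(1L, n, by = upw)
    last <- pmin(first + upw - 1L, n)
    sizes <- last - first + 1L
    k <- length(first)
    if (k > 1 && sizes[k] < upw / 2) {     # merge short tail into previous
      last[k - 1L] <- last[k]
      sizes[k - 1L] <- sizes[k - 1L] + sizes[k]
      first <- first[-k]; last <- last[-k]; sizes <- sizes[-k]
    }
  } else {                                 # sliding
    first <- seq(1L, n, by = slide)
    last <- pmin(first + upw - 1L, n)
    sizes <- last - first + 1L
    full <- sizes == upw
    if (any(!full)) {                      # keep first trailing window iff >= half
      keep_tail <- which(!full)[1]
      keep <- full
      if (sizes[keep_tail] >= upw / 2) keep[keep_tail] <- TRUE
      first <- first[keep]; last <- last[keep]; sizes <- sizes[keep]
    }
    if (length(first) == 0) return(tibble(start = integer(), end = integer(),
                                          n_units = integer()))
  }
  tibble(start = u[first], end = u[last] + end_off, n_units = sizes)
}

#' Build long, short or copy windows
#'
#' Accumulates units in coordinate order into fixed-unit-count windows.
#' Under the original dialect the unit is a non-masked base and a window's
#' genomic span runs from its first unit to its last unit + 1; under the
#' enhanced dialect the unit is a unique-hit track position and the span
#' runs to last unit + `read_length`. Non-overlapping kinds tile
#' (`slide_units == units_per_window`); sliding kinds emit a window every
#' `slide_units` units. A trailing window holding at least half the unit
#' quota is kept, otherwise it is merged into (tiling) or dropped from
#' (sliding) the previous window.
#'
#' @param x A `ref_bundle` or named character vector of masked sequences.
#' @param dialect `"enhanced"` (unique-hit units) or `"original"`
#'   (non-masked-character units).
#' @param kind `"long"`, `"short"` or `"copy"`; sets the default geometry
#'   (5,000 units sliding by 1,000 / 1,000 tiling / 1,000 tiling).
#' @param units_per_window,slide_units Override the kind's geometry.
#' @param read_length Read length defining enhanced units and span ends.
#' @param track Optional precomputed [compute_unique_hit_track()] result.
#' @return A `window_set` tibble: `contig`, `start`, `end`, `n_units`,
#'   `gc` (GC fraction over non-masked span bases, NA if span fully
#'   masked), `read_count` (0), `rd_corrected` (NA).
#' @export
build_windows <- function(x, dialect = c("enhanced", "original"),
                          kind = c("copy", "long", "short"),
                          units_per_window = NULL, slide_units = NULL,
                          read_length = 100L, track = NULL) {
  dialect <- match.arg(dialect)
  kind <- match.arg(kind)
  defaults <- list(long = c(5000L, 1000L), short = c(1000L, 1000L),
                   copy = c(1000L, 1000L))[[kind]]
  if (is.null(units_per_window)) units_per_window <- defaults[1]
  if (is.null(slide_units)) slide_units <- defaults[2]
  stopifnot(units_per_window >= 1, slide_units >= 1,
            slide_units <= units_per_window)
  seqs <- resolve_seqs(x)
  end_off <- if (dialect == "enhanced") as.integer(read_length) else 1L
  if (dialect == "enhanced" && is.null(track)) {
    track <- compute_unique_hit_track(seqs, read_length)
  }
  res <- purrr::map_dfr(names(seqs), function(ctg) {
    u <- if (dialect == "enhanced") track$units[[ctg]] else {
      which(!seq_is_n(seqs[[ctg]])) - 1L
    }
    w <- emit_windows(u, units_per_window, slide_units, end_off)
    if (nrow(w) == 0) return(NULL)
    cum <- seq_cumulants(seqs[[ctg]])
    acgt <- cum$acgt[w$end + 1L] - cum$acgt[w$start + 1L]
    gcn <- cum$gc[w$end + 1L] - cum$gc[w$start + 1L]
    dplyr::mutate(w, contig = ctg,
                  gc = ifelse(acgt > 0, gcn / acgt, NA_real_),
                  .before = 1)
  })
  if (is.null(res) || nrow(res) == 0) {
    res <- tibble(contig = character(), start = integer(), end = integer(),
                  n_units = integer(), gc = double())
  }
  res$read_count <- 0L
  res$rd_corrected <- NA_real_
  new_window_set(res, kind, dialect, units_per_window, slide_units, read_length)
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> kind=%s dialect=%s (%d units / %d slide, L=%d)\n",
              attr(x, "kind"), attr(x, "dialect"),
              attr(x, "units_per_window"), attr(x, "slide_units"),
              attr(x, "read_length")))
  NextMethod()
}

#' GC fraction of window spans
#'
#' G+C count divided by non-masked base count within each window span;
#' `NA` (flagged, excluded from GC correction) when the span is fully
#' masked.
#'
#' @param x A `ref_bundle` or named character vector of masked sequences.
#' @param windows Interval table of window spans (`contig`, `start`, `end`).
#' @return Numeric vector of GC fractions along the rows of `windows`.
#' @export
window_gc <- function(x, windows) {
  seqs <- resolve_seqs(x)
  windows <- check_intervals(windows, "windows")
  out <- rep(NA_real_, nrow(windows))
  for (ctg in unique(windows$contig)) {
    i <- which(windows$contig == ctg)
    cum <- seq_cumulants(seqs[[ctg]])
    acgt <- cum$acgt[windows$end[i] + 1L] - cum$acgt[windows$start[i] + 1L]
    gcn <- cum$gc[windows$end[i] + 1L] - cum$gc[windows$start[i] + 1L]
    out[i] <- ifelse(acgt > 0, gcn / acgt, NA_real_)
  }
  out
}
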