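# Permutation enrichment of interval sets: random non-overlapping
# placement of query regions across the genome, empirical add-one p
# values, breakpoint GC statistics, and GC-peak detection.

#' Random non-overlapping placement of regions
#'
#' For each replicate, every region keeps its size and receives a uniform
#' random position: a contig chosen with probability proportional to its
#' room for the region, then a uniform start, resampled on overlap with
#' forbidden intervals or with regions already placed in the same
#' replicate.
#'
#' @param regions Interval table (sizes are what matters).
#' @param genome Contig table (`contig`, `length`), e.g.
#'   [contig_table()].
#' @param forbidden Interval table (assembly gaps), or `NULL`.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param max_try Retries per region before failing.
#' @return Tibble of placements with a `rep` column.
#' @export
random_placement <- function(regions, genome, forbidden = NULL,
                             n_reps = 1L, seed = NULL, max_try = 1000L) {
  regions <- check_intervals(regions, "regions")
  sizes <- regions$end - regions$start
  glen <- setNames(genome$length, genome$contig)
  if (sum(sizes) > sum(glen)) {
    stop("regions exceed the usable genome length", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  forb <- if (is.null(forbidden)) NULL else check_intervals(forbidden)
  nc <- length(glen)
  forb_s <- forb_e <- rep(list(numeric(0)), nc)
  names(forb_s) <- names(forb_e) <- names(glen)
  if (!is.null(forb)) {
    for (ctg in intersect(unique(forb$contig), names(glen))) {
      i <- forb$contig == ctg
      forb_s[[ctg]] <- forb$start[i]
      forb_e[[ctg]] <- forb$end[i]
    }
  }
  n <- length(sizes)
  out_rep <- rep(seq_len(n_reps), each = n)
  out_region <- rep(seq_len(n), n_reps)
  out_ctg <- character(n * n_reps)
  out_start <- integer(n * n_reps)
  row <- 0L
  for (rp in seq_len(n_reps)) {
    occ_s <- forb_s
    occ_e <- forb_e
    for (i in seq_len(n)) {
      len <- sizes[i]
      room <- pmax(glen - len + 1, 0)
      croom <- cumsum(room)
      total <- croom[nc]
      if (total <= 0) stop("random placement infeasible: no room", call. = FALSE)
      ok <- FALSE
      for (t in seq_len(max_try)) {
        u <- runif(1) * total
        ci <- findInterval(u, croom, left.open = TRUE) + 1L
        start <- floor(u - c(0, croom)[ci])
        if (!any(start < occ_e[[ci]] & (start + len) > occ_s[[ci]])) {
          occ_s[[ci]] <- c(occ_s[[ci]], start)
          occ_e[[ci]] <- c(occ_e[[ci]], start + len)
          row <- row + 1L
          out_ctg[row] <- names(glen)[ci]
          out_start[row] <- as.integer(start)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("random placement infeasible after max retries", call. = FALSE)
    }
  }
  tibble(rep = out_rep, region = out_region, contig = out_ctg,
         start = out_start, end = out_start + rep(as.integer(sizes), n_reps))
}

# number of `features` intervals overlapped by >= 1 of the (s, e)
# intervals on the same contig; features must be non-overlapping within a
# contig so that sorting by start also sorts the ends
make_hit_counter <- function(features) {
  sp <- split(features[, c("start", "end")], features$contig)
  sp <- lapply(sp, function(d) {
    o <- order(d$start)
    fs <- d$start[o]; fe <- d$end[o]
    if (is.unsorted(fe)) return(NULL)       # caller falls back to IRanges
    list(fs = fs, fe = fe)
  })
  if (any(vapply(sp, is.null, TRUE))) return(NULL)
  function(contig, s, e) {
    total <- 0L
    for (ctg in unique(contig)) {
      f <- sp[[ctg]]
      if (is.null(f)) next
      i <- which(contig == ctg)
      hits <- logical(length(f$fs))
      for (j in i) {
        lo <- findInterval(s[j], f$fe) + 1L      # first feature with end > s
        hi <- findInterval(e[j] - 1L, f$fs)      # last feature with start < e
        if (lo <= hi) hits[lo:hi] <- TRUE
      }
      total <- total + sum(hits)
    }
    total
  }
}

new_enrichment_result <- function(observed, null, n_reps, seed,
                                  statistic = "features_hit",
                                  extra = list()) {
  mean_null <- mean(null)
  fold <- if (observed == 0) 0
          else if (mean_null == 0) Inf
          else observed / mean_null
  p_enrich <- (1 + sum(null >= observed)) / (n_reps + 1)
  p_deplete <- (1 + sum(null <= observed)) / (n_reps + 1)
  structure(c(list(observed = observed, null = null, mean_null = mean_null,
                   fold = fold, p = p_enrich, p_depletion = p_deplete,
                   n_reps = n_reps, seed = seed, statistic = statistic),
              extra),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: observed %.4g, null mean %.4g\n",
              x$statistic, x$observed, x$mean_null))
  cat(sprintf("  fold = %.3g, p = %.4g (%d replicates)\n", x$fold, x$p,
              x$n_reps))
  invisible(x)
}

#' @export
#' @method tidy enrichment_result
tidy.enrichment_result <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         mean_null = x$mean_null, fold = x$fold, p = x$p,
         p_depletion = x$p_depletion, n_reps = x$n_reps)
}

#' @export
#' @method glance enrichment_result
glance.enrichment_result <- function(x, ...) tidy(x)

#' Permutation test of interval overlap enrichment
#'
#' The observed statistic is the number of feature intervals overlapping
#' at least one query region. The null distribution repeats the statistic
#' with the query regions randomly replaced by [random_placement()];
#' significance is the add-one empirical tail probability
#' `p = (1 + #{null >= observed}) / (n_reps + 1)` (mirrored for
#' depletion), so p is never zero and its minimum is `1 / (n_reps + 1)`.
#' Fold is observed over the null mean.
#'
#' @param query_regions,feature_regions Interval tables.
#' @param genome Contig table.
#' @param forbidden Intervals the random placements must avoid.
#' @param n_reps Number of null replicates (default 10,000).
#' @param seed Integer seed.
#' @return An `enrichment_result`; `queries_hit` holds the companion
#'   count of query regions overlapping a feature.
#' @export
enrichment_test <- function(query_regions, feature_regions, genome,
                            forbidden = NULL, n_reps = 10000L, seed = NULL) {
  query_regions <- check_intervals(query_regions, "query_regions")
  feature_regions <- check_intervals(feature_regions, "feature_regions")
  observed <- sum(overlaps_any(feature_regions, query_regions))
  null_pl <- random_placement(query_regions, genome, forbidden = forbidden,
                              n_reps = n_reps, seed = seed)
  counter <- make_hit_counter(feature_regions)
  idx <- split(seq_len(nrow(null_pl)), null_pl$rep)
  null <- vapply(idx, function(i) {
    if (!is.null(counter)) {
      as.numeric(counter(null_pl$contig[i], null_pl$start[i], null_pl$end[i]))
    } else {
      as.numeric(sum(overlaps_any(feature_regions, null_pl[i, ])))
    }
  }, 0)
  new_enrichment_result(observed, unname(null), n_reps, seed,
                        statistic = "features_hit",
                        extra = list(queries_hit =
                          sum(overlaps_any(query_regions, feature_regions))))
}

#' Breakpoint segments of CNV regions
#'
#' Each CNVR contributes two segments of `flank_total` bp centered on its
#' start and end boundaries, clipped at contig edges.
#'
#' @param cnvrs Interval table.
#' @param genome Contig table (for clipping).
#' @param flank_total Segment length in bp (even).
#' @return Interval tibble with `boundary` (`start`/`end`) and `cnvr_id`.
#' @export
breakpoint_segments <- function(cnvrs, genome, flank_total = 2000L) {
  stopifnot(flank_total %% 2 == 0)
  cnvrs <- check_intervals(cnvrs, "cnvrs")
  half <- flank_total / 2
  glen <- setNames(genome$length, genome$contig)
  dplyr::bind_rows(
    tibble(contig = cnvrs$contig, at = cnvrs$start, boundary = "start",
           cnvr_id = seq_len(nrow(cnvrs))),
    tibble(contig = cnvrs$contig, at = cnvrs$end, boundary = "end",
           cnvr_id = seq_len(nrow(cnvrs)))) %>%
    dplyr::mutate(start = pmax(0, .data$at - half),
                  end = pmin(glen[.data$contig], .data$at + half)) %>%
    dplyr::select("contig", "start", "end", "boundary", "cnvr_id") %>%
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    dplyr::arrange(.data$contig, .data$start)
}

pooled_gc_cum <- function(cums, segments = NULL) {
  gc <- 0; acgt <- 0
  if (is.null(segments)) {
    for (cum in cums) {
      gc <- gc + cum$gc[length(cum$gc)]
      acgt <- acgt + cum$acgt[length(cum$acgt)]
    }
  } else {
    for (ctg in unique(segments$contig)) {
      cum <- cums[[ctg]]
      i <- segments$contig == ctg
      gc <- gc + sum(cum$gc[segments$end[i] + 1] - cum$gc[segments$start[i] + 1])
      acgt <- acgt + sum(cum$acgt[segments$end[i] + 1] -
                           cum$acgt[segments$start[i] + 1])
    }
  }
  if (acgt == 0) return(NA_real_)
  gc / acgt
}

pooled_gc <- function(seqs, segments = NULL) {
  pooled_gc_cum(lapply(seqs, seq_cumulants), segments)
}

#' GC content of breakpoint segments versus genomic background
#'
#' Pooled GC fraction (over non-N bases) of the segments against the
#' genome-wide background, with an add-one permutation p value obtained
#' by randomly relocating the segments.
#'
#' @param segments Interval table (e.g. [breakpoint_segments()]).
#' @param ref A `ref_bundle` or named character vector of sequences.
#' @param forbidden Intervals the relocated segments must avoid.
#' @param n_reps Number of relocation replicates.
#' @param seed Integer seed.
#' @return List with `gc_segments`, `gc_background`, `p`, `n_reps`.
#' @export
gc_compare <- function(segments, ref, forbidden = NULL, n_reps = 1000L,
                       seed = NULL) {
  segments <- check_intervals(segments, "segments")
  if (nrow(segments) == 0) stop("segments must be non-empty", call. = FALSE)
  seqs <- if (inherits(ref, "ref_bundle")) ref$seqs else ref
  genome <- contig_table(seqs)
  cums <- lapply(seqs, seq_cumulants)
  gc_obs <- pooled_gc_cum(cums, segments)
  gc_bg <- pooled_gc_cum(cums)
  pl <- random_placement(segments, genome, forbidden = forbidden,
                         n_reps = n_reps, seed = seed)
  idx <- split(seq_len(nrow(pl)), pl$rep)
  null <- vapply(idx, function(i) pooled_gc_cum(cums, pl[i, ]), 0)
  p <- (1 + sum(null >= gc_obs)) / (n_reps + 1)
  list(gc_segments = gc_obs, gc_background = gc_bg, p = p,
       null = unname(null), n_reps = n_reps)
}

#' Detect GC peaks
#'
#' Slides a `local`-bp window by `step` bp; a position is a peak when its
#' local GC content is at least `fold` times the GC content of the
#' `background`-bp window centered on it (clipped at contig edges;
#' windows whose background holds no G+C or whose local span is fully
#' masked are skipped). Overlapping qualifying windows merge into one
#' peak represented by its maximum-ratio window.
#'
#' @param ref A `ref_bundle` or named character vector of sequences.
#' @param local Local window size in bp (default 500).
#' @param background Background window size in bp (default 10,000).
#' @param fold Minimum local / background GC ratio (default 1.5,
#'   inclusive).
#' @param step Slide step in bp (default 100).
#' @return A `gc_peaks` tibble: merged peak `contig`, `start`, `end` and
#'   the representative window's `peak_start`, `peak_end`, `gc_local`,
#'   `gc_background`, `ratio`.
#' @export
detect_gc_peaks <- function(ref, local = 500L, background = 10000L,
                            fold = 1.5, step = 100L) {
  stopifnot(background > local, step >= 1)
  seqs <- if (inherits(ref, "ref_bundle")) masked_seqs(ref) else ref
  purrr::map_dfr(names(seqs), function(ctg) {
    s <- seqs[[ctg]]
    n <- nchar(s)
    if (n < local) return(NULL)
    cum <- seq_cumulants(s)
    starts <- seq(0L, n - local, by = step)
    ends <- starts + local
    g_loc <- cum$gc[ends + 1] - cum$gc[starts + 1]
    a_loc <- cum$acgt[ends + 1] - cum$acgt[starts + 1]
    center <- starts + local / 2
    bs <- pmax(0, floor(center - background / 2))
    be <- pmin(n, ceiling(center + background / 2))
    g_bg <- cum$gc[be + 1] - cum$gc[bs + 1]
    a_bg <- cum$acgt[be + 1] - cum$acgt[bs + 1]
    gc_local <- ifelse(a_loc > 0, g_loc / a_loc, NA_real_)
    gc_bg <- ifelse(a_bg > 0, g_bg / a_bg, NA_real_)
    hit <- !is.na(gc_local) & !is.na(gc_bg) & gc_bg > 0 &
      gc_local >= fold * gc_bg
    if (!any(hit)) return(NULL)
    ratio_hit <- gc_local[hit] / gc_bg[hit]
    wins <- tibble(contig = ctg, start = starts[hit], end = ends[hit],
                   gc_local = gc_local[hit], gc_background = gc_bg[hit],
                   ratio = ratio_hit)
    merged <- merge_intervals(wins)
    purrr::map_dfr(seq_len(nrow(merged)), function(i) {
      inside <- wins[wins$start < merged$end[i] & wins$end > merged$start[i], ]
      best <- inside[which.max(inside$ratio), ]
      tibble(contig = ctg, start = merged$start[i], end = merged$end[i],
             peak_start = best$start, peak_end = best$end,
             gc_local = best$gc_local, gc_background = best$gc_background,
             ratio = best$ratio)
    })
  })
}

#' Association between CNV breakpoints and GC peaks
#'
#' The statistic is the proportion of breakpoint segments whose midpoint
#' lies within `distance` bp of a GC peak. The null relocates the
#' breakpoint segments at random; fold and the add-one p follow the
#' permutation convention.
#'
#' @param breakpoints Breakpoint segment intervals.
#' @param peaks A [detect_gc_peaks()] result (or any interval table).
#' @param genome Contig table.
#' @param distance Maximum midpoint-to-peak distance in bp.
#' @param forbidden Intervals the relocated segments must avoid.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return An `enrichment_result` with statistic
#'   `"breakpoints_near_peak"`; the observed value is the proportion.
#' @export
breakpoint_peak_association <- function(breakpoints, peaks, genome,
                                        distance = 1000L, forbidden = NULL,
                                        n_reps = 1000L, seed = NULL) {
  breakpoints <- check_intervals(breakpoints, "breakpoints")
  pk_split <- if (is.null(peaks)) list() else
    split(peaks[, c("start", "end")], peaks$contig)
  prop_near <- function(contig, s, e) {
    if (length(s) == 0) return(0)
    mid <- (s + e) / 2
    near <- rep(FALSE, length(s))
    for (ctg in unique(contig)) {
      pk <- pk_split[[ctg]]
      if (is.null(pk) || nrow(pk) == 0) next
      for (j in which(contig == ctg)) {
        near[j] <- any(mid[j] >= pk$start - distance &
                         mid[j] <= pk$end + distance)
      }
    }
    mean(near)
  }
  observed <- prop_near(breakpoints$contig, breakpoints$start,
                        breakpoints$end)
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(new_enrichment_result(0, rep(0, n_reps), n_reps, seed,
                                 statistic = "breakpoints_near_peak"))
  }
  pl <- random_placement(breakpoints, genome, forbidden = forbidden,
                         n_reps = n_reps, seed = seed)
  idx <- split(seq_len(nrow(pl)), pl$rep)
  null <- vapply(idx, function(i) prop_near(pl$contig[i], pl$start[i],
                                            pl$end[i]), 0)
  new_enrichment_result(observed, unname(null), n_reps, seed,
                        statistic = "breakpoints_near_peak")
}
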