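# WSSD read-depth engine: per-window counting, GC correction, iteratively
# trimmed control statistics, the 6-of-7 long-window duplication/deletion
# rule, and diploid copy-number estimation.

#' Count read placements per window
#'
#' Non-overlapping (tiling) kinds partition the units, so a placement is
#' assigned to the single window owning its start unit — the last window
#' whose span start is at or before the placement start (and whose span
#' still contains it); under the enhanced dialect consecutive tiling
#' windows' genomic spans overlap by up to a read length, but their unit
#' sets do not, and neither do the counts. Sliding kinds count a
#' placement in every window whose span contains its start (half-open).
#' Multi-mapped placements all count. Placements assigned to no window
#' are dropped and tallied in the `dropped_placements` attribute.
#'
#' @param windows A `window_set`.
#' @param placements A `placement_set` (multi-mapped: every placement
#'   counts).
#' @return The `window_set` with `read_count` filled in.
#' @export
count_reads <- function(windows, placements) {
  df <- as_tibble(windows)
  df$read_count <- 0L
  tiling <- attr(windows, "slide_units") == attr(windows, "units_per_window")
  dropped <- 0L
  for (ctg in unique(df$contig)) {
    wi <- which(df$contig == ctg)
    ws <- df$start[wi]; we <- df$end[wi]
    p <- placements$start[placements$contig == ctg]
    if (length(p) == 0) next
    if (isTRUE(tiling)) {
      lo <- findInterval(p, ws)            # unit-partition owner
      valid <- lo >= 1L & p < we[pmax(lo, 1L)]
      dropped <- dropped + sum(!valid)
      df$read_count[wi] <- tabulate(lo[valid], nbins = length(ws))
    } else {
      # spans sorted with non-decreasing start and end: the covering
      # windows form a contiguous index range [hi, lo]
      lo <- findInterval(p, ws)            # last window with start <= p
      hi <- findInterval(p, we) + 1L       # first window with end > p
      valid <- lo >= hi & lo >= 1L & hi <= length(ws)
      dropped <- dropped + sum(!valid)
      if (!any(valid)) next
      d <- numeric(length(ws) + 1L)
      add <- tabulate(hi[valid], nbins = length(ws))
      sub <- tabulate(lo[valid] + 1L, nbins = length(ws) + 1L)
      d[seq_along(ws)] <- add
      d <- d - sub
      df$read_count[wi] <- as.integer(cumsum(d)[seq_along(ws)])
    }
  }
  out <- restore_window_attrs(df, windows)
  attr(out, "dropped_placements") <- dropped
  out
}

#' Drop placements overlapping hard-masked bases
#'
#' The mapper reports every placement against the raw sequence; read depth
#' however is computed as if reads had been mapped to the hard-masked
#' genome, where a read overlapping any N cannot align. This filter
#' removes placements whose read span touches a masked base. It is also
#' the hook where any upstream read-level QC would plug in.
#'
#' @param placements A `placement_set`.
#' @param x A `ref_bundle` (hard-masked sequences derived from it) or
#'   named character vector of masked sequences.
#' @param read_length Read length; default from the placement set.
#' @return The filtered `placement_set`.
#' @export
filter_masked_placements <- function(placements, x, read_length = NULL) {
  seqs <- resolve_seqs(x)
  L <- read_length %||% attr(placements, "read_length") %||% 100L
  keep <- rep(TRUE, nrow(placements))
  for (ctg in unique(placements$contig)) {
    i <- which(placements$contig == ctg)
    cm <- c(0L, cumsum(seq_is_n(seqs[[ctg]])))
    n <- nchar(seqs[[ctg]])
    s <- placements$start[i]
    keep[i] <- (cm[pmin(s + L, n) + 1L] - cm[s + 1L]) == 0L
  }
  out <- placements[keep, ]
  structure(out, class = class(placements),
            read_length = attr(placements, "read_length"),
            individual_id = attr(placements, "individual_id"),
            n_reads = attr(placements, "n_reads"))
}

gc_bin <- function(gc) as.integer(round(gc * 100))

#' Fit GC correction factors
#'
#' Bins windows by GC percentage (1% bins) and computes, per bin, the
#' factor `global mean read count / bin mean read count` from windows
#' outside the exclusion intervals. Corrected depth is
#' `read_count * factor(gc_bin)`. Bins with fewer than `min_windows`
#' usable windows fall back to factor 1, as do windows with undefined GC.
#'
#' @param windows A `window_set` with `read_count` filled.
#' @param exclusions Interval table (known SDs, gaps) to leave out of the
#'   fit, or `NULL`.
#' @param min_windows Minimum windows per usable bin.
#' @return A `gc_correction`: tibble with `bin`, `n`, `mean_rd`, `factor`,
#'   and attribute `global_mean`.
#' @export
fit_gc_correction <- function(windows, exclusions = NULL, min_windows = 20L) {
  df <- as_tibble(windows)
  use <- !is.na(df$gc)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    use <- use & !overlaps_any(df, exclusions)
  }
  if (!any(use)) stop("all windows excluded from GC correction", call. = FALSE)
  fit <- df[use, ]
  global <- mean(fit$read_count)
  tab <- fit %>%
    dplyr::mutate(bin = gc_bin(.data$gc)) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(n = dplyr::n(), mean_rd = mean(.data$read_count)) %>%
    dplyr::mutate(factor = ifelse(.data$n >= min_windows & .data$mean_rd > 0,
                                  global / .data$mean_rd, 1))
  structure(tab, class = c("gc_correction", class(tibble())),
            global_mean = global)
}

#' Apply GC correction to a window set
#'
#' @param windows A `window_set` with `read_count`.
#' @param correction A [fit_gc_correction()] result.
#' @return The `window_set` with `rd_corrected` filled in.
#' @export
apply_gc_correction <- function(windows, correction) {
  df <- as_tibble(windows)
  fac <- setNames(correction$factor, correction$bin)
  f <- fac[as.character(gc_bin(df$gc))]
  f[is.na(f)] <- 1
  df$rd_corrected <- df$read_count * unname(f)
  restore_window_attrs(df, windows)
}

#' Control-region depth statistics by iterative trimming
#'
#' Excludes windows overlapping known SDs or gaps, then alternates between
#' estimating the mean and standard deviation of corrected depth and
#' discarding windows outside mean +/- 3 sd, until the mean moves by less
#' than `1e-6 * mean` or 100 iterations. A minimum-sd floor guards
#' degenerate near-constant depth.
#'
#' @param windows A `window_set` with `rd_corrected`.
#' @param known_sds,gaps Interval tables to exclude, or `NULL`.
#' @param min_control Minimum usable control windows (error below).
#' @param sigma_floor Lower bound on the returned sd, in reads.
#' @return List with `mu`, `sigma`, `n_control`, `n_iter`, `control_idx`
#'   (row indices of the final control set).
#' @export
fit_control_stats <- function(windows, known_sds = NULL, gaps = NULL,
                              min_control = 30L, sigma_floor = 0.5) {
  df <- as_tibble(windows)
  if (all(is.na(df$rd_corrected))) stop("windows are not GC-corrected", call. = FALSE)
  use <- !is.na(df$rd_corrected)
  excl <- dplyr::bind_rows(
    if (!is.null(known_sds)) check_intervals(known_sds, "known_sds"),
    if (!is.null(gaps)) check_intervals(gaps, "gaps"))
  if (!is.null(excl) && nrow(excl) > 0) use <- use & !overlaps_any(df, excl)
  idx <- which(use)
  if (length(idx) < min_control) {
    stop(sprintf("only %d control windows (< %d): unreliable depth model",
                 length(idx), min_control), call. = FALSE)
  }
  x <- df$rd_corrected[idx]
  keep <- rep(TRUE, length(x))
  mu <- mean(x)
  sigma <- max(sd(x), sigma_floor)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    keep_new <- x >= mu - 3 * sigma & x <= mu + 3 * sigma
    if (sum(keep_new) < min_control) {
      stop("iterative trimming left too few control windows", call. = FALSE)
    }
    mu_new <- mean(x[keep_new])
    sigma_new <- max(sd(x[keep_new]), sigma_floor)
    done <- abs(mu_new - mu) < 1e-6 * abs(mu) || n_iter >= 100L
    keep <- keep_new; mu <- mu_new; sigma <- sigma_new
    if (done) break
  }
  list(mu = mu, sigma = sigma,
       n_control = sum(keep), n_iter = n_iter, control_idx = idx[keep])
}

#' Fit the full read-depth model
#'
#' Convenience wrapper: GC correction and trimmed control statistics for
#' each provided window kind. The model converts corrected depth into
#' z-scores (calling) and diploid copy number (estimation).
#'
#' @param long,short,copy `window_set`s of the three kinds with
#'   `read_count` filled; `short` and `copy` may be `NULL`.
#' @param known_sds,gaps Exclusion intervals for control fitting.
#' @param min_control,sigma_floor Passed to [fit_control_stats()].
#' @return An `rd_model`: per-kind list of `windows` (corrected),
#'   `stats` (`mu`, `sigma`, ...), `gc` (correction table).
#' @export
fit_rd_model <- function(long, short = NULL, copy = NULL,
                         known_sds = NULL, gaps = NULL,
                         min_control = 30L, sigma_floor = 0.5) {
  fit_kind <- function(w) {
    if (is.null(w)) return(NULL)
    gc <- fit_gc_correction(w, exclusions = dplyr::bind_rows(
      if (!is.null(known_sds)) check_intervals(known_sds),
      if (!is.null(gaps)) check_intervals(gaps)))
    w <- apply_gc_correction(w, gc)
    st <- fit_control_stats(w, known_sds = known_sds, gaps = gaps,
                            min_control = min_control,
                            sigma_floor = sigma_floor)
    list(windows = w, stats = st, gc = gc)
  }
  structure(list(long = fit_kind(long), short = fit_kind(short),
                 copy = fit_kind(copy)),
            class = "rd_model")
}

#' @export
print.rd_model <- function(x, ...) {
  cat("<rd_model>\n")
  for (k in c("long", "short", "copy")) {
    if (is.null(x[[k]])) next
    cat(sprintf("  %-5s mu=%.2f sigma=%.2f (n_control=%d)\n", k,
                x[[k]]$stats$mu, x[[k]]$stats$sigma, x[[k]]$stats$n_control))
  }
  invisible(x)
}

#' @export
#' @method tidy rd_model
tidy.rd_model <- function(x, ...) {
  purrr::map_dfr(c("long", "short", "copy"), function(k) {
    if (is.null(x[[k]])) return(NULL)
    tibble(kind = k, mu = x[[k]]$stats$mu, sigma = x[[k]]$stats$sigma,
           n_control = x[[k]]$stats$n_control, n_iter = x[[k]]$stats$n_iter)
  })
}

#' @export
#' @method glance rd_model
glance.rd_model <- function(x, ...) {
  tibble(mu_long = x$long$stats$mu, sigma_long = x$long$stats$sigma,
         mu_copy = if (!is.null(x$copy)) x$copy$stats$mu else NA_real_,
         n_control_long = x$long$stats$n_control)
}

# contiguous index runs from a logical vector
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}

#' Call duplications or deletions by the 6-of-7 rule
#'
#' A seed is any stretch in which at least `min_hits` of `run_length`
#' consecutive sliding long windows deviate beyond mean +/- 3 sd of the
#' control depth (above for duplication, below for deletion). Overlapping
#' seed stretches merge; the call span is the union of the deviating
#' windows within the merged stretch. Edges are trimmed to the outermost
#' deviating short windows, calls with more than half their span in
#' assembly gaps are removed, and calls below `min_length` are dropped.
#' Under the default geometry (5,000-unit long windows sliding by 1,000)
#' the minimal callable span is 10 kb.
#'
#' @param model An [fit_rd_model()] result (uses the `long` and, when
#'   present, `short` kinds).
#' @param direction `"duplication"` or `"deletion"`.
#' @param gaps Assembly-gap intervals for artifact removal.
#' @param copy_profile Optional [estimate_copy_number()] result used to
#'   attach the mean copy number over constituent copy windows.
#' @param min_hits,run_length The x-of-y rule (defaults 6 of 7).
#' @param n_sigma Deviation threshold in control standard deviations.
#' @param min_length Minimum call span in bp.
#' @param individual_id Sample label on the calls.
#' @param gap_overlap_max Remove calls with a larger gap-covered fraction.
#' @return A `cnv_calls` tibble: `individual`, `contig`, `start`, `end`,
#'   `state`, `mean_cn`, `n_windows`.
#' @export
call_cnv <- function(model, direction = c("duplication", "deletion"),
                     gaps = NULL, copy_profile = NULL,
                     min_hits = 6L, run_length = 7L, n_sigma = 3,
                     min_length = 10000L, individual_id = NULL,
                     gap_overlap_max = 0.5) {
  direction <- match.arg(direction)
  lw <- as_tibble(model$long$windows)
  st <- model$long$stats
  if (is.null(individual_id)) individual_id <- "sample"
  thr_hi <- st$mu + n_sigma * st$sigma
  thr_lo <- st$mu - n_sigma * st$sigma
  calls <- purrr::map_dfr(unique(lw$contig), function(ctg) {
    w <- lw[lw$contig == ctg, ]
    dev <- if (direction == "duplication") w$rd_corrected > thr_hi
           else w$rd_corrected < thr_lo
    dev[is.na(dev)] <- FALSE
    n <- length(dev)
    if (n < run_length) return(NULL)
    roll <- cumsum(dev)
    roll <- roll[run_length:n] - c(0, roll)[1:(n - run_length + 1L)]
    hit_start <- which(roll >= min_hits)           # window i .. i+run_length-1
    if (length(hit_start) == 0) return(NULL)
    in_seed <- rep(FALSE, n)
    for (i in hit_start) in_seed[i:(i + run_length - 1L)] <- TRUE
    runs <- runs_of(in_seed)
    purrr::map_dfr(seq_len(nrow(runs)), function(r) {
      i <- runs$start[r]:runs$end[r]
      q <- i[dev[i]]                               # qualifying windows
      if (length(q) == 0) return(NULL)
      tibble(contig = ctg, start = min(w$start[q]), end = max(w$end[q]),
             n_windows = length(q))
    })
  })
  if (nrow(calls) == 0) {
    return(empty_calls(individual_id))
  }
  # edge refinement by short windows
  if (!is.null(model$short)) {
    sw <- as_tibble(model$short$windows)
    ss <- model$short$stats
    s_hi <- ss$mu + n_sigma * ss$sigma
    s_lo <- ss$mu - n_sigma * ss$sigma
    for (i in seq_len(nrow(calls))) {
      s <- sw[sw$contig == calls$contig[i] & sw$end > calls$start[i] &
                sw$start < calls$end[i], ]
      if (nrow(s) == 0) next
      pass <- if (direction == "duplication") s$rd_corrected > s_hi
              else s$rd_corrected < s_lo
      pass[is.na(pass)] <- FALSE
      if (!any(pass)) next
      calls$start[i] <- max(calls$start[i], min(s$start[pass]))
      calls$end[i] <- min(calls$end[i], max(s$end[pass]))
    }
  }
  # artifact removal: drop calls mostly inside assembly gaps
  if (!is.null(gaps) && nrow(gaps) > 0) {
    calls <- calls[overlap_fraction(calls, gaps) <= gap_overlap_max, ]
  }
  calls <- calls[calls$end - calls$start >= min_length, ]
  if (nrow(calls) == 0) return(empty_calls(individual_id))
  calls$state <- direction
  calls$individual <- individual_id
  calls$mean_cn <- NA_real_
  if (!is.null(copy_profile)) {
    cp <- as_tibble(copy_profile)
    for (i in seq_len(nrow(calls))) {
      cw <- cp[cp$contig == calls$contig[i] & cp$end > calls$start[i] &
                 cp$start < calls$end[i], ]
      if (nrow(cw) > 0) calls$mean_cn[i] <- mean(cw$cn)
    }
  }
  out <- calls %>%
    dplyr::select("individual", "contig", "start", "end", "state",
                  "mean_cn", "n_windows") %>%
    dplyr::arrange(.data$contig, .data$start)
  structure(out, class = c("cnv_calls", class(tibble())))
}

empty_calls <- function(individual_id = character(0)) {
  structure(tibble(individual = character(), contig = character(),
                   start = integer(), end = integer(), state = character(),
                   mean_cn = double(), n_windows = integer()),
            class = c("cnv_calls", class(tibble())))
}

#' Minimal callable span of the x-of-y rule
#'
#' The genomic span of the shortest possible call: `min_hits` consecutive
#' qualifying sliding windows, i.e. `(min_hits - 1) * slide_units +
#' units_per_window` units, which on fully mappable sequence is the same
#' number of bases.
#'
#' @param units_per_window,slide_units Long-window geometry in units.
#' @param min_hits Minimum deviating windows (default 6 of 7).
#' @return Span in units (= bp on fully mappable sequence).
#' @export
minimal_call_span <- function(units_per_window = 5000L, slide_units = 1000L,
                              min_hits = 6L) {
  (min_hits - 1L) * slide_units + units_per_window
}

#' Estimate diploid copy number per copy window
#'
#' `CN(w) = 2 * rd_corrected(w) / mu_copy`, the WSSD diploid ratio against
#' the copy-window control mean.
#'
#' @param model An [fit_rd_model()] result with a `copy` kind.
#' @param individual_id Sample label.
#' @return A `cn_profile` tibble: copy windows with a `cn` column.
#' @export
estimate_copy_number <- function(model, individual_id = NULL) {
  if (is.null(model$copy)) stop("model has no copy windows", call. = FALSE)
  mu <- model$copy$stats$mu
  if (mu <= 0) stop("copy-window control mean must be positive", call. = FALSE)
  df <- as_tibble(model$copy$windows)
  df$cn <- 2 * df$rd_corrected / mu
  df$individual <- if (is.null(individual_id)) "sample" else individual_id
  structure(df, class = c("cn_profile", class(tibble())), mu_copy = mu)
}
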