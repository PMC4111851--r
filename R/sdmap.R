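# Final SD database: WSSD duplication detection on the reference
# individual, the >=94%-identity WGAC filter against WSSD support, the
# three-way union with provenance, and ancestral-SD selection.

#' WSSD segmental duplications of the reference individual
#'
#' Runs enhanced-dialect duplication calling on the reference's own reads:
#' because reads from either copy of a high-identity SD map to both
#' copies, depth over each copy doubles and the 6-of-7 caller recovers
#' them. Copies diverged beyond the mapper's mismatch ceiling no longer
#' cross-map and are invisible to WSSD — that is the method's identity
#' floor, and why high-identity WGAC needs WSSD support rather than the
#' reverse.
#'
#' @param ref A `ref_bundle`.
#' @param placements `placement_set` of reference-derived reads.
#' @param ... Passed to [wssd_pipeline()].
#' @return An `sd_intervals` tibble with provenance `"WSSD"`.
#' @export
wssd_reference_sd <- function(ref, placements, ...) {
  res <- wssd_pipeline(ref, placements, dialect = "enhanced",
                       individual_id = "reference", ...)
  dup <- res$duplications
  if (nrow(dup) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  provenance = list(), max_identity = double()))
  }
  merge_sd_intervals(
    tibble(contig = dup$contig, start = dup$start, end = dup$end,
           identity = NA_real_), "WSSD")
}

#' Filter high-identity WGAC alignments by WSSD support
#'
#' Alignments below `id_threshold` identity pass unconditionally; those at
#' or above it pass only if at least `min_support` of the bases of the
#' union of their two intervals overlap WSSD intervals. High-identity
#' alignments without read-depth support are the signature of local
#' assembly artifacts (collapsed or duplicated contigs).
#'
#' @param wgac_alignments Alignment tibble.
#' @param wssd_intervals Interval table of WSSD SD calls.
#' @param id_threshold Identity at or above which support is required.
#' @param min_support Minimum supported base fraction (inclusive).
#' @return The filtered alignment tibble with a `wssd_support` column.
#' @export
filter_high_identity <- function(wgac_alignments, wssd_intervals,
                                 id_threshold = 0.94, min_support = 0.5) {
  a <- as_tibble(wgac_alignments)
  if (nrow(a) == 0) return(a)
  support <- vapply(seq_len(nrow(a)), function(i) {
    u <- merge_intervals(tibble(
      contig = c(a$contig_a[i], a$contig_b[i]),
      start = c(a$start_a[i], a$start_b[i]),
      end = c(a$end_a[i], a$end_b[i])))
    if (is.null(wssd_intervals) || nrow(wssd_intervals) == 0) return(0)
    sum(overlap_bases(u, wssd_intervals)) / sum(u$end - u$start)
  }, 0)
  a$wssd_support <- support
  a[a$identity < id_threshold | support >= min_support, ]
}

#' Build the final SD database
#'
#' The union of low-identity WGAC (< 94%), WSSD-filtered high-identity
#' WGAC (>= 94%) and the WSSD intervals, merged transitively into
#' non-overlapping intervals with outermost endpoints and provenance
#' sets, plus a per-contig summary and intra-contig alignment distance
#' bins.
#'
#' @param low_id_wgac,filtered_high_id_wgac Alignment tibbles (the two
#'   WGAC identity strata).
#' @param wssd `sd_intervals` from [wssd_reference_sd()].
#' @param contigs Optional contig table for the per-contig summary.
#' @return A list: `intervals` (`sd_intervals` tibble), `per_contig`
#'   (counts and total lengths), `distance_bins` (intra-contig alignment
#'   counts binned by the gap between the closest endpoints of the two
#'   intervals: <1 Mb, 1-5, 5-10, 10-20, >=20 Mb, plus inter-contig).
#' @export
build_sd_database <- function(low_id_wgac, filtered_high_id_wgac, wssd,
                              contigs = NULL) {
  pieces <- dplyr::bind_rows(
    if (nrow(low_id_wgac) > 0) dplyr::bind_rows(
      tibble(contig = low_id_wgac$contig_a, start = low_id_wgac$start_a,
             end = low_id_wgac$end_a, identity = low_id_wgac$identity,
             provenance = list("WGAC_low")),
      tibble(contig = low_id_wgac$contig_b, start = low_id_wgac$start_b,
             end = low_id_wgac$end_b, identity = low_id_wgac$identity,
             provenance = list("WGAC_low"))),
    if (nrow(filtered_high_id_wgac) > 0) dplyr::bind_rows(
      tibble(contig = filtered_high_id_wgac$contig_a,
             start = filtered_high_id_wgac$start_a,
             end = filtered_high_id_wgac$end_a,
             identity = filtered_high_id_wgac$identity,
             provenance = list("WGAC_high_filtered")),
      tibble(contig = filtered_high_id_wgac$contig_b,
             start = filtered_high_id_wgac$start_b,
             end = filtered_high_id_wgac$end_b,
             identity = filtered_high_id_wgac$identity,
             provenance = list("WGAC_high_filtered"))),
    if (!is.null(wssd) && nrow(wssd) > 0)
      tibble(contig = wssd$contig, start = wssd$start, end = wssd$end,
             identity = wssd$max_identity,
             provenance = if (is.null(wssd$provenance)) list("WSSD")
                          else wssd$provenance))
  intervals <- if (is.null(pieces) || nrow(pieces) == 0) {
    tibble(contig = character(), start = integer(), end = integer(),
           provenance = list(), max_identity = double())
  } else merge_sd_intervals(pieces, NULL)
  per_contig <- intervals %>%
    dplyr::group_by(.data$contig) %>%
    dplyr::summarise(n_intervals = dplyr::n(),
                     total_bp = sum(.data$end - .data$start))
  if (!is.null(contigs)) {
    per_contig <- dplyr::left_join(contigs, per_contig, by = "contig") %>%
      dplyr::mutate(n_intervals = tidyr::replace_na(.data$n_intervals, 0L),
                    total_bp = tidyr::replace_na(.data$total_bp, 0),
                    duplicated_fraction = .data$total_bp / .data$length)
  }
  alns <- dplyr::bind_rows(low_id_wgac, filtered_high_id_wgac)
  distance_bins <- alignment_distance_bins(alns)
  list(intervals = intervals, per_contig = per_contig,
       distance_bins = distance_bins)
}

# gap between the closest endpoints of the two intervals of each
# intra-contig alignment, binned as in a per-distance summary table
alignment_distance_bins <- function(alns) {
  levels <- c("<1Mb", "1-5Mb", "5-10Mb", "10-20Mb", ">=20Mb", "inter")
  if (is.null(alns) || nrow(alns) == 0) {
    return(tibble(bin = factor(levels, levels = levels), n = 0L))
  }
  d <- ifelse(alns$contig_a != alns$contig_b, NA_real_,
              pmax(0, pmax(alns$start_a, alns$start_b) -
                     pmin(alns$end_a, alns$end_b)))
  bin <- dplyr::case_when(
    is.na(d) ~ "inter",
    d < 1e6 ~ "<1Mb",
    d < 5e6 ~ "1-5Mb",
    d < 10e6 ~ "5-10Mb",
    d < 20e6 ~ "10-20Mb",
    TRUE ~ ">=20Mb")
  tibble(bin = factor(bin, levels = levels)) %>%
    dplyr::count(.data$bin, .drop = FALSE)
}

#' Ancestral segmental duplications
#'
#' SDs whose copies have diverged below `max_identity` (strict) are
#' postulated to be ancient; their merged non-overlapping footprint is
#' the feature set for CNVR enrichment.
#'
#' @param wgac_alignments Alignment tibble.
#' @param max_identity Strict upper identity bound (default 0.95).
#' @return Merged interval tibble with provenance `"WGAC_ancestral"`.
#' @export
ancestral_sds <- function(wgac_alignments, max_identity = 0.95) {
  sel <- wgac_alignments[wgac_alignments$identity < max_identity, ]
  merge_alignment_intervals(sel, provenance = "WGAC_ancestral")
}
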