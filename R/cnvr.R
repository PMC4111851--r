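# Cross-individual CNV regions: the transitive union of overlapping calls,
# gain/loss/both classification, hotspot selection, pairwise sharing,
# gene copy numbers and feature overlap.

#' Merge per-individual CNV calls into CNV regions
#'
#' The union of overlapping calls (>= 1 bp) across individuals, merged
#' transitively to outermost endpoints. A region's state is `gain` if all
#' carrier events are duplications, `loss` if all are deletions, `both`
#' otherwise.
#'
#' @param calls A `cnv_calls` tibble (rows from several individuals).
#' @return A `cnvr` tibble: `contig`, `start`, `end`, `state`,
#'   `n_carriers`, `carriers` (list column of per-individual state
#'   tibbles).
#' @export
merge_to_cnvrs <- function(calls) {
  calls <- check_intervals(calls, "calls")
  if (nrow(calls) == 0) {
    return(structure(tibble(contig = character(), start = integer(),
                            end = integer(), state = character(),
                            n_carriers = integer(), carriers = list()),
                     class = c("cnvr", class(tibble()))))
  }
  regions <- merge_intervals(calls)
  regions$state <- NA_character_
  regions$n_carriers <- 0L
  regions$carriers <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- calls[calls$contig == regions$contig[i] &
                   calls$start < regions$end[i] &
                   calls$end > regions$start[i], ]
    states <- unique(hit$state)
    regions$state[i] <- if (all(states == "duplication")) "gain"
      else if (all(states == "deletion")) "loss" else "both"
    car <- hit %>% dplyr::distinct(.data$individual, .data$state)
    regions$carriers[[i]] <- car
    regions$n_carriers[i] <- dplyr::n_distinct(car$individual)
  }
  structure(regions, class = c("cnvr", class(tibble())))
}

#' CNV hotspots by two-group carrier thresholds
#'
#' A CNVR is a hotspot when at least `t1` carriers belong to the first
#' group and at least `t2` to the second (e.g. two of three commercial
#' and two of ten indigenous animals).
#'
#' @param cnvrs A [merge_to_cnvrs()] result.
#' @param groups Sample sheet: data frame with `individual` and `group`
#'   columns; `group` must take exactly the two compared values.
#' @param t1,t2 Carrier thresholds for the first and second group (in the
#'   sorted order of group labels, or the order of `group_levels`).
#' @param group_levels Optional explicit order of the two group labels.
#' @return The hotspot subset of `cnvrs`, with per-group carrier counts.
#' @export
find_hotspots <- function(cnvrs, groups, t1 = 2L, t2 = 2L,
                          group_levels = NULL) {
  stopifnot(all(c("individual", "group") %in% names(groups)))
  lv <- group_levels %||% sort(unique(groups$group))
  if (length(lv) != 2) stop("exactly two groups are required", call. = FALSE)
  gmap <- setNames(as.character(groups$group), groups$individual)
  counts <- purrr::map_dfr(cnvrs$carriers, function(car) {
    g <- gmap[car$individual]
    if (any(is.na(g))) {
      stop(sprintf("individual(s) without group assignment: %s",
                   paste(unique(car$individual[is.na(g)]), collapse = ", ")),
           call. = FALSE)
    }
    ind <- unique(car$individual)
    tibble(n_group1 = sum(gmap[ind] == lv[1]),
           n_group2 = sum(gmap[ind] == lv[2]))
  })
  out <- dplyr::bind_cols(as_tibble(cnvrs), counts)
  out <- out[out$n_group1 >= t1 & out$n_group2 >= t2, ]
  structure(out, class = c("cnvr", class(tibble())))
}

#' Pairwise CNV sharing between individuals
#'
#' For every pair of individuals, the number of overlapping call pairs and
#' the total intersected bases.
#'
#' @param calls A `cnv_calls` tibble with >= 2 individuals.
#' @return List of two symmetric matrices: `count` and `bases`.
#' @export
sharing_matrix <- function(calls) {
  inds <- sort(unique(calls$individual))
  if (length(inds) < 2) stop("need calls from at least two individuals", call. = FALSE)
  n <- length(inds)
  cnt <- matrix(0L, n, n, dimnames = list(inds, inds))
  len <- matrix(0, n, n, dimnames = list(inds, inds))
  for (i in seq_len(n - 1)) {
    a <- calls[calls$individual == inds[i], ]
    for (j in (i + 1):n) {
      b <- calls[calls$individual == inds[j], ]
      for (r in seq_len(nrow(a))) {
        ov <- pmax(0, pmin(a$end[r], b$end) - pmax(a$start[r], b$start)) *
          (b$contig == a$contig[r])
        cnt[i, j] <- cnt[i, j] + sum(ov > 0)
        len[i, j] <- len[i, j] + sum(ov)
      }
      cnt[j, i] <- cnt[i, j]
      len[j, i] <- len[i, j]
    }
  }
  list(count = cnt, bases = len)
}

#' Gene copy numbers from copy-window profiles
#'
#' A gene's copy number in an individual is the median of the copy
#' numbers of the copy windows overlapping the gene span by >= 1 bp
#' (even counts take the mean of the two middle values). Genes with no
#' overlapping window are flagged with `NA`.
#'
#' @param profiles A `cn_profile`, or a list of them (one per
#'   individual), or their row-bound tibble.
#' @param genes Data frame with `gene`, `contig`, `start`, `end` and
#'   optionally `biotype`.
#' @return A `gene_cn` tibble: `gene`, `biotype`, `individual`, `cn`,
#'   `n_windows`.
#' @export
gene_copy_numbers <- function(profiles, genes) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- dplyr::bind_rows(lapply(profiles, as_tibble))
  }
  profiles <- as_tibble(profiles)
  genes <- as_tibble(genes)
  if (!"biotype" %in% names(genes)) genes$biotype <- "protein-coding"
  purrr::map_dfr(unique(profiles$individual), function(ind) {
    p <- profiles[profiles$individual == ind, ]
    purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      w <- p[p$contig == genes$contig[i] & p$start < genes$end[i] &
               p$end > genes$start[i], ]
      tibble(gene = genes$gene[i], biotype = genes$biotype[i],
             individual = ind,
             cn = if (nrow(w) == 0) NA_real_ else median(w$cn),
             n_windows = nrow(w))
    })
  })
}

#' Select copy-number-variable genes
#'
#' Protein-coding genes whose copy-number range (max - min across
#' individuals) strictly exceeds `min_range`.
#'
#' @param records A [gene_copy_numbers()] result (>= 2 individuals).
#' @param min_range Strict lower bound on the CN range.
#' @param biotypes Biotypes eligible for selection.
#' @return Tibble with `gene`, `biotype`, `cn_min`, `cn_max`, `cn_range`.
#' @export
select_cn_variable_genes <- function(records, min_range = 2.0,
                                     biotypes = "protein-coding") {
  if (dplyr::n_distinct(records$individual) < 2) {
    stop("need copy numbers from at least two individuals", call. = FALSE)
  }
  records %>%
    dplyr::filter(.data$biotype %in% biotypes, !is.na(.data$cn)) %>%
    dplyr::group_by(.data$gene, .data$biotype) %>%
    dplyr::summarise(cn_min = min(.data$cn), cn_max = max(.data$cn),
                     .groups = "drop") %>%
    dplyr::mutate(cn_range = .data$cn_max - .data$cn_min) %>%
    dplyr::filter(.data$cn_range > min_range)
}

#' Annotate features overlapping CNVRs
#'
#' Every feature overlapping a CNVR by >= 1 bp (half-open coordinates:
#' abutting intervals do not overlap), with overlap bases and a
#' completeness flag.
#'
#' @param cnvrs Interval table of CNV regions.
#' @param features Data frame with `contig`, `start`, `end` and any id
#'   columns.
#' @return The overlapping features with `overlap_bp` and `complete`
#'   (fully contained in the CNVR union) columns.
#' @export
annotate_overlaps <- function(cnvrs, features) {
  features <- check_intervals(features, "features")
  ov <- overlap_bases(features, cnvrs)
  out <- features[ov > 0, ]
  out$overlap_bp <- ov[ov > 0]
  out$complete <- out$overlap_bp == (out$end - out$start)
  out
}
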