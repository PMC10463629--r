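# Cloud quality: purity, Shannon entropy, and classification of
# enhanced clouds against a gold partition.
#
# A cloud's composition is counted over categories (reference, 200-kbp
# region): within the cloud, each reference's read positions are
# clustered by the same greedy sweep used for reference deconvolution,
# so "region" means the same thing in the metrics and in the gold
# standard.  Entropy is reported as H = -sum(p * ln p), which is zero
# iff the cloud is single-origin.

#' Composition of a read cloud
#'
#' @param positions Tibble with one row per read: `reference` and
#'   `position` (bp).  Reads without a located origin must be excluded
#'   by the caller.
#' @param region_size Region clustering span `L` in bp (default 200
#'   kbp).
#' @return Named integer vector of per-category read counts; category
#'   labels are `"<reference>#<region index>"`.
#' @export
cloud_composition <- function(positions, region_size = 200000) {
  pos <- as_tibble(positions)
  if (nrow(pos) == 0) abort("uncomputable composition: no located reads")
  pos <- pos %>% arrange(.data$reference, .data$position)
  counts <- pos %>%
    group_by(.data$reference) %>%
    mutate(region = {
      gs <- sweep_group(.data$position, region_size)
      idx <- integer(dplyr::n())
      for (g in seq_along(gs)) idx[gs[[g]]] <- g
      idx
    }) %>%
    ungroup() %>%
    count(.data$reference, .data$region)
  setNames(counts$n, paste0(counts$reference, "#", counts$region))
}

#' Purity of a composition
#'
#' The largest proportion of reads attributable to one category,
#' `P = max(p)`.
#'
#' @param counts Per-category read counts (from [cloud_composition()]).
#' @return Purity in `[0, 1]`.
#' @export
cloud_purity <- function(counts) {
  if (length(counts) == 0 || sum(counts) == 0) abort("empty composition")
  max(counts) / sum(counts)
}

#' Shannon entropy of a composition
#'
#' `H = -sum(p_i * ln(p_i))`, natural log; 0 iff one category.
#'
#' @param counts Per-category read counts.
#' @return Nonnegative entropy (nats).
#' @export
cloud_entropy <- function(counts) {
  if (length(counts) == 0 || sum(counts) == 0) abort("empty composition")
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Classify an enhanced cloud against its parent's gold fragments
#'
#' `"under"` if the read set spans two or more gold fragments,
#' `"complete"` if it equals exactly one gold fragment's read set, and
#' `"over"` if it is a proper subset of one gold fragment.
#'
#' @param read_ids Read ids of one enhanced cloud.
#' @param gold List of character vectors: the gold fragments
#'   (partition) of the parent cloud's reads.
#' @return `"under"`, `"complete"` or `"over"`.
#' @export
classify_cloud <- function(read_ids, gold) {
  read_ids <- unique(read_ids)
  hits <- which(vapply(gold, function(g) any(read_ids %in% g), logical(1)))
  if (length(hits) == 0) {
    abort("enhanced cloud shares no read with the gold partition")
  }
  if (length(hits) > 1) return("under")
  g <- unique(gold[[hits]])
  if (length(read_ids) == length(intersect(read_ids, g)) &&
      length(read_ids) == length(g)) "complete"
  else if (all(read_ids %in% g)) "over"
  else "under"
}

#' Per-cloud quality table
#'
#' Computes size, purity, entropy and (optionally) the
#' under/complete/over class of every cloud of a deconvolution result,
#' using a truth table for read origins.  Disconnected reads are
#' excluded.  The gold partition defaults to reference deconvolution
#' of the truth positions at `region_size`.
#'
#' @param result A `deconv_result` (or its assignment tibble).
#' @param truth Truth table from [sim_library()] (needs `read_id`,
#'   `mate`, `umi`, `reference`, `read_start`).
#' @param region_size Region span for composition and gold grouping
#'   (default 200 kbp).
#' @param gold Optional precomputed gold `deconv_result`; set to
#'   `FALSE` to skip classification.
#' @return Tibble `umi`, `subgroup`, `cloud_id`, `size`, `purity`,
#'   `entropy`, `class`.
#' @export
cloud_quality <- function(result, truth, region_size = 200000,
                          gold = NULL) {
  assignments <- if (inherits(result, "deconv_result")) {
    result$assignments
  } else {
    as_tibble(result)
  }
  truth <- as_tibble(truth)
  classify <- !isFALSE(gold)
  if (classify && is.null(gold)) {
    gold <- reference_deconvolve(truth_alignments(truth),
                                 max_frag = region_size)
  }
  located <- assignments %>%
    filter(!.data$disconnected) %>%
    inner_join(truth %>%
                 select("read_id", "mate", "reference",
                        position = "read_start"),
               by = c("read_id", "mate"))
  n_missing <- sum(!assignments$disconnected) - nrow(located)
  if (n_missing > 0) {
    warn(sprintf("%d reads lack a truth origin and were excluded", n_missing))
  }
  gold_frags <- NULL
  if (classify) {
    gold_frags <- gold$assignments %>%
      filter(!.data$disconnected) %>%
      mutate(gid = paste0(.data$umi, ".", .data$subgroup))
  }
  per_cloud <- located %>%
    group_by(.data$umi, .data$subgroup) %>%
    summarise(size = dplyr::n(),
              comp = {
                ref <- .data$reference
                pos <- .data$position
                list(cloud_composition(tibble(reference = ref, position = pos),
                                       region_size))
              },
              read_ids = list(unique(.data$read_id)),
              .groups = "drop")
  out <- per_cloud %>%
    mutate(cloud_id = paste0(.data$umi, ".", .data$subgroup),
           purity = vapply(.data$comp, cloud_purity, numeric(1)),
           entropy = vapply(.data$comp, cloud_entropy, numeric(1)))
  if (classify) {
    frag_sets <- gold_frags %>%
      group_by(.data$umi, .data$gid) %>%
      summarise(ids = list(unique(.data$read_id)), .groups = "drop")
    frag_by_umi <- split(frag_sets$ids, frag_sets$umi)
    out$class <- vapply(seq_len(nrow(out)), function(i) {
      g <- frag_by_umi[[out$umi[i]]]
      if (is.null(g)) return(NA_character_)
      classify_cloud(out$read_ids[[i]], g)
    }, character(1))
  } else {
    out$class <- NA_character_
  }
  out <- out %>% select("umi", "subgroup", "cloud_id", "size", "purity",
                        "entropy", "class")
  class(out) <- c("cloud_quality", class(out))
  out
}

#' Summarise cloud quality
#'
#' Mean and standard deviation of purity, entropy and size, cloud
#' count, and the under/complete/over proportions, after excluding
#' clouds of `size <= 2` (trivially pure single pairs).
#'
#' @param quality A [cloud_quality()] table.
#' @param min_size Smallest cloud size kept (default 3).
#' @param weighted Also report size-weighted mean purity.
#' @return One-row tibble of summary statistics.
#' @export
summarize_clouds <- function(quality, min_size = 3, weighted = FALSE) {
  q <- quality %>% filter(.data$size >= min_size)
  if (nrow(q) == 0) abort("empty summary: no clouds survive the size filter")
  out <- tibble(
    n_clouds = nrow(q),
    avg_purity = mean(q$purity), sd_purity = stats::sd(q$purity),
    avg_entropy = mean(q$entropy), sd_entropy = stats::sd(q$entropy),
    avg_size = mean(q$size), sd_size = stats::sd(q$size),
    prop_under = mean(q$class == "under"),
    prop_complete = mean(q$class == "complete"),
    prop_over = mean(q$class == "over")
  )
  if (weighted) {
    out$weighted_purity <- sum(q$purity * q$size) / sum(q$size)
  }
  out
}

#' Mean fragments per UMI from cloud-size averages
#'
#' The ratio of the average non-deconvolved cloud size to the average
#' reference-deconvolved cloud size, reported to one decimal.
#'
#' @param avg_size_none Average size of non-deconvolved clouds.
#' @param avg_size_reference Average size of reference-deconvolved
#'   clouds.
#' @return Fragments per UMI (1 d.p.).
#' @examples
#' fragments_per_umi(269.18, 116.19)
#' @export
fragments_per_umi <- function(avg_size_none, avg_size_reference) {
  check_scalar_number(avg_size_none, "avg_size_none")
  check_scalar_number(avg_size_reference, "avg_size_reference")
  if (avg_size_none <= 0 || avg_size_reference <= 0) {
    abort("average sizes must be > 0")
  }
  round(avg_size_none / avg_size_reference, 1)
}

#' Lower bound on the probability of a mixed read cloud
#'
#' For an equal-abundance community of `num_species` species and a
#' mean of `mean_fragments_per_umi` fragments per UMI, the chance that
#' a cloud draws fragments from more than one species is at least
#' `1 - (1/S)^(m - 1)`: after the first fragment, each of the
#' remaining `m - 1` must land on the same species.
#'
#' @param num_species Number of species `S` (>= 1).
#' @param mean_fragments_per_umi Mean fragments per UMI `m` (>= 1).
#' @return Probability lower bound in `[0, 1)`.
#' @examples
#' mixed_cloud_probability(5, 2.3)
#' @export
mixed_cloud_probability <- function(num_species, mean_fragments_per_umi) {
  check_scalar_number(num_species, "num_species", min = 1)
  check_scalar_number(mean_fragments_per_umi, "mean_fragments_per_umi",
                      min = 1)
  1 - (1 / num_species)^(mean_fragments_per_umi - 1)
}
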