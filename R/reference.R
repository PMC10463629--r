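#' Greedy sweep grouping of sorted positions
#'
#' Left-to-right sweep over sorted start positions: a new group opens
#' whenever a position lies more than `L` beyond the current group's
#' minimum, so every group spans at most `L` (a span of exactly `L`
#' stays in one group).
#'
#' @param starts Sorted (ascending) numeric positions in bp.
#' @param L Maximum span in bp (> 0).
#' @return List of integer index vectors, one per group.
#' @examples
#' sweep_group(c(0, 50000, 300000), 200000)
#' @export
sweep_group <- function(starts, L) {
  check_scalar_number(L, "L")
  if (L <= 0) abort("`L` must be > 0")
  if (length(starts) == 0) return(list())
  if (is.unsorted(starts)) abort("`starts` must be sorted ascending")
  grp <- integer(length(starts))
  g <- 1L
  anchor <- starts[1]
  for (i in seq_along(starts)) {
    if (starts[i] > anchor + L) {
      g <- g + 1L
      anchor <- starts[i]
    }
    grp[i] <- g
  }
  unname(split(seq_along(starts), grp))
}

#' Read primary alignments from a SAM file
#'
#' Converts the SAM to BAM in a scratch directory and scans it for
#' primary alignments, pulling the UMI from the `BX` tag.  Positions
#' are reported 0-based (`SAM POS - 1`).
#'
#' @param path SAM file path.
#' @return Alignment tibble: `read_id`, `mate`, `umi`, `reference`,
#'   `start` (0-based), `aligned`.
#' @export
read_sam_alignments <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "flag"),
    tag = "BX",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mate <- ifelse(bitwAnd(x$flag, 128L) > 0L, 2L, 1L)
  tibble(
    read_id = x$qname,
    mate = mate,
    umi = as.character(x$tag$BX),
    reference = as.character(x$rname),
    start = x$pos - 1L,
    aligned = !is.na(x$pos) & bitwAnd(x$flag, 4L) == 0L
  )
}

#' Gold-standard deconvolution from alignment positions
#'
#' Within each (UMI, reference) pair, reads are grouped by
#' [sweep_group()] so that the left- and right-most start positions in
#' a group are no further than `max_frag` apart; each group is a gold
#' fragment.  Mates of a pair are grouped by their own starts and then
#' unioned.  Unaligned reads go to the disconnected set.
#'
#' @param alignments Alignment tibble (`read_id`, `umi`, `reference`,
#'   `start`, `aligned`, optionally `mate`) — e.g. from
#'   [read_sam_alignments()] or a simulator truth table via
#'   [truth_alignments()].
#' @param max_frag Maximum fragment length `L` in bp (default 200
#'   kbp; halving/doubling it is a supported sensitivity analysis).
#' @return A `deconv_result` whose `fragments` element records each
#'   gold fragment's reference and start-position span.
#' @export
reference_deconvolve <- function(alignments, max_frag = 200000) {
  check_scalar_number(max_frag, "max_frag")
  a <- as_tibble(alignments)
  if (!"mate" %in% names(a)) a$mate <- 1L
  if (!"aligned" %in% names(a)) a$aligned <- !is.na(a$start)
  if (any(a$aligned & is.na(a$umi))) {
    abort("aligned record with missing UMI")
  }
  al <- a %>% filter(.data$aligned) %>%
    arrange(.data$umi, .data$reference, .data$start)
  # raw sweep groups per (umi, reference)
  al <- al %>%
    group_by(.data$umi, .data$reference) %>%
    mutate(raw_grp = {
      gs <- sweep_group(.data$start, max_frag)
      idx <- integer(dplyr::n())
      for (g in seq_along(gs)) idx[gs[[g]]] <- g
      idx
    }) %>%
    ungroup() %>%
    mutate(raw_key = paste(.data$umi, .data$reference, .data$raw_grp,
                           sep = "\r"))
  # mate forcing: union raw groups sharing a read id within a umi
  keys <- unique(al$raw_key)
  parent <- seq_along(keys)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  gi <- match(al$raw_key, keys)
  dup <- split(gi, paste(al$umi, al$read_id, sep = "\r"))
  for (g in dup) {
    g <- unique(g)
    if (length(g) > 1) {
      for (j in g[-1]) {
        ra <- find(g[1]); rb <- find(j)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  comp <- vapply(gi, find, integer(1))
  al$component <- comp
  # number subgroups per cloud by smallest member start
  al <- al %>%
    group_by(.data$umi) %>%
    mutate(subgroup = {
      fp <- tapply(.data$start, .data$component, min)
      as.integer(rank(fp, ties.method = "first")[as.character(.data$component)])
    }) %>%
    ungroup()
  fragments <- al %>%
    group_by(.data$umi, .data$subgroup, .data$reference) %>%
    summarise(n_reads = dplyr::n(), min_start = min(.data$start),
              max_start = max(.data$start), .groups = "drop")
  unal <- a %>% filter(!.data$aligned)
  assignments <- bind_rows(
    al %>% mutate(disconnected = FALSE) %>%
      select("read_id", "mate", "umi", "subgroup", "disconnected"),
    unal %>% mutate(subgroup = 0L, disconnected = TRUE) %>%
      select("read_id", "mate", "umi", "subgroup", "disconnected")
  )
  clouds <- assignments %>%
    group_by(.data$umi) %>%
    summarise(size = dplyr::n(),
              n_subgroups = dplyr::n_distinct(.data$subgroup[!.data$disconnected]),
              n_disconnected = sum(.data$disconnected), .groups = "drop")
  structure(list(assignments = assignments, clouds = clouds,
                 fragments = fragments,
                 config = list(max_frag = max_frag), method = "reference"),
            class = "deconv_result")
}

#' No-deconvolution baseline
#'
#' Wraps a read or truth table as a `deconv_result` with every cloud
#' intact (subgroup 0), for comparison against deconvolved results.
#'
#' @param reads Table with `read_id`, `umi` (and `mate` if paired).
#' @return A `deconv_result`.
#' @export
identity_deconvolve <- function(reads) {
  a <- as_tibble(reads)
  if (!"mate" %in% names(a)) a$mate <- 1L
  assignments <- a %>%
    distinct(.data$read_id, .data$mate, .data$umi) %>%
    mutate(subgroup = 0L, disconnected = FALSE)
  clouds <- assignments %>%
    group_by(.data$umi) %>%
    summarise(size = dplyr::n(), n_subgroups = 1L, n_disconnected = 0L,
              .groups = "drop")
  structure(list(assignments = assignments, clouds = clouds,
                 config = list(), method = "none"),
            class = "deconv_result")
}
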