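# Bounded-Dijkstra read cloud deconvolution.
#
# For each read the algorithm builds a forward Dijkstra neighborhood
# from its 3'-terminal vertex and a reverse one into its 5'-terminal
# vertex, both bounded by the search distance d.  A cloud-mate is
# "connected" when any vertex of its vertex sequence (or that vertex's
# conjugate) falls inside either neighborhood.  Enhanced read clouds
# are the connected components of the symmetrized relation, with mate
# pairs forced together; components of two or fewer reads and unmapped
# reads are routed to the disconnected set.

# Neighborhood target set for a read: union of forward/reverse bounded
# Dijkstra vertex sets plus their conjugates.  Cached per (vertex,
# direction) because many reads share terminal vertices.
reach_set <- function(graph, t5p, t3p, d, cache) {
  get_nbhd <- function(v, dir) {
    key <- paste0(dir, ":", v)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    csr <- graph_csr(graph, dir)
    nb <- cpp_bounded_dijkstra(csr$ptr, csr$head, csr$w, v, d)$vertex
    cache[[key]] <- nb
    nb
  }
  nb <- c(get_nbhd(t3p, "forward"), get_nbhd(t5p, "reverse"))
  unique(c(nb, graph$vertices$conjugate[nb]))
}

#' Connected read-set of a focal read
#'
#' All cloud-mates (plus the focal read itself) with a vertex — or its
#' conjugate — inside the focal read's forward (from its 3' terminal)
#' or reverse (into its 5' terminal) Dijkstra neighborhood at distance
#' `<= d`.
#'
#' @param graph An assembly graph.
#' @param paths Mapping paths of the focal read's cloud (from
#'   [map_reads()]).
#' @param focal_read Read id present in `paths`.
#' @param d Search distance in bp.
#' @return Character vector of connected read ids, including
#'   `focal_read`.
#' @export
connected_set <- function(graph, paths, focal_read, d) {
  rows <- which(paths$read_id == focal_read & paths$mapped)
  if (length(rows) == 0) {
    abort(sprintf("focal read %s is unmapped or absent", focal_read))
  }
  cache <- new.env(parent = emptyenv())
  targets <- unique(unlist(lapply(rows, function(i) {
    reach_set(graph, paths$terminal_5p[i], paths$terminal_3p[i], d, cache)
  })))
  hit <- vapply(seq_len(nrow(paths)), function(j) {
    paths$mapped[j] && any(paths$vertices[[j]] %in% targets)
  }, logical(1))
  sort(unique(c(focal_read, paths$read_id[hit])))
}

# Deconvolve one cloud.  `cloud` is the subset of the mapping-path
# tibble for a single UMI, in dataset read order.  Reads with an
# identical vertex signature are grouped and tested once: the
# connection predicate depends only on terminals and vertex sets, so
# this is exact, and it makes the per-cloud work O(signatures^2).
deconvolve_cloud_paths <- function(graph, cloud, d, size_cutoff, cache) {
  n <- nrow(cloud)
  res <- tibble(read_id = cloud$read_id, mate = cloud$mate,
                subgroup = 0L, disconnected = FALSE)
  if (n <= size_cutoff) return(res)

  mapped <- which(cloud$mapped)
  res$disconnected[!cloud$mapped] <- TRUE
  if (length(mapped) == 0) return(res)

  sig <- vapply(cloud$vertices, function(v) paste(sort(v), collapse = ","),
                character(1))
  sig[!cloud$mapped] <- NA_character_
  sig_ids <- unique(sig[mapped])
  rep_row <- match(sig_ids, sig)

  # union-find over signatures
  parent <- seq_along(sig_ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }

  # inverted index vertex -> signatures whose vertex set contains it,
  # so each focal reach set is intersected against all mates at once
  vsets <- cloud$vertices[rep_row]
  v2sig <- split(rep.int(seq_along(sig_ids), lengths(vsets)),
                 unlist(vsets))
  for (a in seq_along(sig_ids)) {
    reach_a <- reach_set(graph, cloud$terminal_5p[rep_row[a]],
                         cloud$terminal_3p[rep_row[a]], d, cache)
    hits <- unique(unlist(v2sig[as.character(reach_a)], use.names = FALSE))
    for (b in hits) if (b != a) unite(a, b)
  }
  # mate forcing: both mates mapped => same component
  comp_of_read <- vapply(mapped, function(i) find(match(sig[i], sig_ids)),
                         integer(1))
  by_id <- split(seq_along(mapped), cloud$read_id[mapped])
  for (rows in by_id) {
    if (length(rows) > 1) {
      for (r in rows[-1]) {
        unite(comp_of_read[rows[1]], comp_of_read[r])
      }
    }
  }
  comp_of_read <- vapply(comp_of_read, find, integer(1))

  # components of <= 2 reads (a lone pair or singleton) are disconnected
  tab <- table(comp_of_read)
  small <- as.integer(names(tab)[tab <= 2])
  is_small <- comp_of_read %in% small
  res$disconnected[mapped[is_small]] <- TRUE

  keep <- !is_small
  if (any(keep)) {
    # number subgroups 1..m by smallest member read id, so numbering is
    # invariant to row order and thread count
    comp <- comp_of_read[keep]
    member_id <- paste(cloud$read_id[mapped[keep]],
                       cloud$mate[mapped[keep]])
    first_id <- tapply(member_id, comp, min)
    renum <- rank(first_id, ties.method = "first")
    res$subgroup[mapped[keep]] <- as.integer(renum[as.character(comp)])
  }
  res
}

#' Deconvolution configuration
#'
#' @param d Maximum search distance in bp (default 5000).
#' @param size_cutoff Minimum cloud size that triggers deconvolution;
#'   clouds of `size <= size_cutoff` pass through intact as subgroup 0
#'   (default 6).
#' @param threads Worker processes for per-cloud parallelism (default
#'   1; the result is invariant to this).
#' @return A `deconv_config` list.
#' @export
deconv_config <- function(d = 5000, size_cutoff = 6L, threads = 1L) {
  check_scalar_number(d, "d", min = 0)
  check_scalar_number(size_cutoff, "size_cutoff", min = 0)
  check_scalar_number(threads, "threads", min = 1)
  structure(list(d = d, size_cutoff = as.integer(size_cutoff),
                 threads = as.integer(threads)),
            class = "deconv_config")
}

#' Deconvolve barcoded read clouds on an assembly graph
#'
#' Splits each read cloud (reads sharing a UMI) into enhanced read
#' clouds: maximal sets of reads whose bounded-Dijkstra neighborhoods
#' intersect (see [connected_set()]).  Clouds at or below the size
#' cutoff pass through intact as subgroup 0.  Components of two or
#' fewer reads, and unmapped reads, go to the disconnected set.  The
#' result is deterministic and invariant to cloud processing order and
#' thread count.
#'
#' @param graph An assembly graph.
#' @param reads Read table with `umi` (from [read_barcoded_fastq()] or
#'   [sim_library()]); alternatively pass precomputed `paths`.
#' @param paths Optional mapping paths from [map_reads()] (computed
#'   from `reads` when missing).  Must carry a `umi` column.
#' @param config A [deconv_config()].
#' @return A `deconv_result`: list with `assignments` (tibble
#'   `read_id`, `mate`, `umi`, `subgroup`, `disconnected`), `clouds`
#'   (per-cloud size and subgroup count) and `config`.
#' @examples
#' \dontrun{
#' lib <- sim_library(sim_genomes(seed = 1), seed = 1)
#' g <- build_graph(lib$reads$sequence, k = 21)
#' res <- deconvolve(g, lib$reads)
#' glance(res)
#' }
#' @export
deconvolve <- function(graph, reads = NULL, paths = NULL,
                       config = deconv_config()) {
  stopifnot(inherits(graph, "assembly_graph"))
  if (is.null(paths)) {
    if (is.null(reads)) abort("supply `reads` or `paths`")
    paths <- map_reads(graph, reads)
  }
  if (!"umi" %in% names(paths)) abort("`paths` must carry a `umi` column")

  umis <- unique(paths$umi)
  groups <- split(seq_len(nrow(paths)), factor(paths$umi, levels = umis))
  cache <- new.env(parent = emptyenv()) # Dijkstra memo shared across clouds
  run_one <- function(rows) {
    deconvolve_cloud_paths(graph, paths[rows, ], config$d,
                           config$size_cutoff, cache) %>%
      mutate(umi = paths$umi[rows[1]])
  }
  parts <- if (config$threads > 1L) {
    parallel::mclapply(groups, run_one, mc.cores = config$threads)
  } else {
    lapply(groups, run_one)
  }
  assignments <- bind_rows(parts) %>%
    select("read_id", "mate", "umi", "subgroup", "disconnected")
  clouds <- assignments %>%
    group_by(.data$umi) %>%
    summarise(size = dplyr::n(),
              n_subgroups = dplyr::n_distinct(.data$subgroup[!.data$disconnected]),
              n_disconnected = sum(.data$disconnected), .groups = "drop")
  structure(list(assignments = assignments, clouds = clouds,
                 config = config, method = "graph"),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf(
    "<deconv_result: %s> %d reads in %d clouds -> %d enhanced clouds, %d disconnected reads\n",
    x$method, nrow(x$assignments), nrow(x$clouds),
    nrow(enhanced_clouds(x)), sum(x$assignments$disconnected)
  ))
  invisible(x)
}

#' Enhanced read clouds of a deconvolution result
#'
#' @param result A `deconv_result`.
#' @return Tibble `umi`, `subgroup`, `cloud_id` (`"<umi>.<subgroup>"`),
#'   `size`, `read_ids` (list), excluding disconnected reads.
#' @export
enhanced_clouds <- function(result) {
  result$assignments %>%
    filter(!.data$disconnected) %>%
    group_by(.data$umi, .data$subgroup) %>%
    summarise(size = dplyr::n(), read_ids = list(unique(.data$read_id)),
              .groups = "drop") %>%
    mutate(cloud_id = paste0(.data$umi, ".", .data$subgroup)) %>%
    select("umi", "subgroup", "cloud_id", "size", "read_ids")
}

#' Write deconvolved reads as barcoded FASTQ
#'
#' Tags each read `BX:Z:<umi>.<subgroup>`; disconnected reads get the
#' suffix `.0-d`.  Mate pairing and read order are preserved, so
#' re-parsing the output reproduces the computed partition as read
#' clouds.
#'
#' @param reads Read table the deconvolution was run on.
#' @param result A `deconv_result`.
#' @param path_r1,path_r2 Output FASTQ paths.
#' @export
write_enhanced_fastq <- function(reads, result, path_r1, path_r2 = NULL) {
  key <- result$assignments %>%
    mutate(tag = if_else(is.na(.data$umi), NA_character_,
                         paste0(.data$umi, ".",
                                if_else(.data$disconnected, "0-d",
                                        as.character(.data$subgroup))))) %>%
    select("read_id", "mate", "tag")
  out <- reads %>% left_join(key, by = c("read_id", "mate"))
  if (any(is.na(out$tag) & !is.na(out$umi))) {
    abort("assignment missing for one or more barcoded reads")
  }
  write_barcoded_fastq(out, path_r1, path_r2)
}

#' Write the assignment table as TSV
#'
#' @param result A `deconv_result`.
#' @param path Output TSV path.
#' @export
write_assignments_tsv <- function(result, path) {
  readr::write_tsv(result$assignments, path)
  invisible(path)
}
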