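#' Map reads onto the assembly graph
#'
#' Exact k-mer anchoring: every k-mer of a read is located in the
#' unitig index (the graph is doubled, so a reverse-strand read
#' anchors directly on conjugate edges).  A read's mapping path is the
#' ordered set of distinct unitig edges hit from 5' to 3', its vertex
#' sequence the border vertices of those edges, and its terminal
#' vertices come from the first and last anchored edge.  Reads with no
#' anchored k-mer are returned unmapped — a value, not an error.
#'
#' @param graph An [assembly_graph][new_assembly_graph].
#' @param reads Read table (needs `read_id`, `sequence`; `mate` kept
#'   if present) or a plain character vector of sequences.
#' @return A tibble of mapping paths: `read_id`, `mate`, `mapped`,
#'   `strand` (`"fwd"` if the first anchored edge is the canonical
#'   member of its conjugate pair, else `"rc"`), `edges` and
#'   `vertices` (list columns of ids), `terminal_5p`, `terminal_3p`.
#' @export
map_reads <- function(graph, reads) {
  stopifnot(inherits(graph, "assembly_graph"))
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%d", seq_along(reads)),
                    mate = 1L, sequence = reads)
  }
  res <- cpp_map_reads(graph$edges$sequence, reads$sequence, graph$k)
  lens <- res$lengths
  paths <- vector("list", length(lens))
  if (length(res$edges) > 0) {
    idx <- rep.int(seq_along(lens), lens)
    paths[unique(idx)] <- split(res$edges, idx)
  }
  paths[lens == 0L] <- list(integer(0))

  efrom <- graph$edges$from
  eto <- graph$edges$to
  first_e <- vapply(paths, function(p) if (length(p)) p[1] else NA_integer_,
                    integer(1))
  last_e <- vapply(paths, function(p) if (length(p)) p[length(p)] else NA_integer_,
                   integer(1))
  vertices <- lapply(paths, function(p) {
    if (length(p) == 0) return(integer(0))
    unique(as.integer(rbind(efrom[p], eto[p])))
  })
  out <- tibble(
    read_id = reads$read_id,
    mate = if ("mate" %in% names(reads)) reads$mate else 1L,
    mapped = lens > 0L,
    strand = ifelse(lens == 0L, NA_character_,
                    ifelse(graph$edges$conjugate[first_e] >= first_e,
                           "fwd", "rc")),
    edges = paths,
    vertices = vertices,
    terminal_5p = ifelse(lens == 0L, NA_integer_, efrom[first_e]),
    terminal_3p = ifelse(lens == 0L, NA_integer_, eto[last_e])
  )
  if ("umi" %in% names(reads)) out$umi <- reads$umi
  class(out) <- c("mapping_paths", class(out))
  out
}

#' Terminal vertices of mapping paths
#'
#' Returns the (5', 3') terminal vertex pair of each mapped read, in
#' read orientation.  Unmapped paths have no terminals and raise an
#' error.
#'
#' @param paths Mapping-path tibble from [map_reads()] (one or more
#'   rows).
#' @return Tibble `read_id`, `mate`, `terminal_5p`, `terminal_3p`.
#' @export
terminal_vertices <- function(paths) {
  if (any(!paths$mapped)) {
    abort(sprintf("no terminals: read %s is unmapped",
                  paths$read_id[which(!paths$mapped)[1]]))
  }
  paths %>% select("read_id", "mate", "terminal_5p", "terminal_3p")
}

#' Export mapping paths as TSV
#'
#' @param paths Mapping paths from [map_reads()].
#' @param path Output TSV path (`read_id`, `mate`, `strand`,
#'   comma-separated edge ids).
#' @export
write_mapping_tsv <- function(paths, path) {
  tab <- paths %>%
    mutate(edge_ids = vapply(.data$edges, paste, character(1),
                             collapse = ",")) %>%
    select("read_id", "mate", "mapped", "strand", "edge_ids")
  readr::write_tsv(tab, path)
  invisible(path)
}
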