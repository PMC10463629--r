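#' Condensed de Bruijn assembly graph
#'
#' An `assembly_graph` is a conjugate-closed (doubled) condensed de
#' Bruijn graph: every maximal non-branching path of the k-mer graph is
#' collapsed into a single unitig edge, and every edge and vertex is
#' present together with its reverse complement ("conjugate").
#' Vertices are the (k-1)-mers at unitig junctions; an edge's sequence
#' starts with its from-vertex k-1-mer and ends with its to-vertex
#' k-1-mer.  Distances along the graph are measured in *novel* bases
#' per edge, `novel_length = nchar(sequence) - (k - 1)`, so that the
#' length of a walk matches the number of bases it spells beyond its
#' starting vertex.
#'
#' @param unitigs Character vector of unitig sequences.  Must already
#'   be closed under reverse complement (as produced by condensation).
#' @param k Odd k-mer size, `3 <= k <= 31`.
#' @return An object of class `assembly_graph`: a list with elements
#'   `k`, `vertices` (tibble: `vertex`, `kmer`, `conjugate`), `edges`
#'   (tibble: `edge`, `from`, `to`, `sequence`, `length`,
#'   `novel_length`, `conjugate`) and adjacency indices.
#' @keywords internal
new_assembly_graph <- function(unitigs, k) {
  unitigs <- sort(unique(unitigs))
  if (length(unitigs) == 0) {
    abort("no graph: empty unitig set (no usable k-mers in the input)")
  }
  len <- nchar(unitigs)
  pre <- substr(unitigs, 1L, k - 1L)
  suf <- substr(unitigs, len - k + 2L, len)
  vkmer <- sort(unique(c(pre, suf)))
  vconj <- match(revcomp(vkmer), vkmer)
  vconj[is.na(vconj)] <- which(is.na(vconj)) # degenerate palindromes
  vertices <- tibble(
    vertex = seq_along(vkmer),
    kmer = vkmer,
    conjugate = vconj
  )
  econj <- match(revcomp(unitigs), unitigs)
  econj[is.na(econj)] <- which(is.na(econj))
  edges <- tibble(
    edge = seq_along(unitigs),
    from = match(pre, vkmer),
    to = match(suf, vkmer),
    sequence = unitigs,
    length = len,
    novel_length = len - (k - 1L),
    conjugate = econj
  )
  nv <- nrow(vertices)
  adj_out <- unname(split(edges$edge, factor(edges$from, levels = seq_len(nv))))
  adj_in <- unname(split(edges$edge, factor(edges$to, levels = seq_len(nv))))
  structure(
    list(k = as.integer(k), vertices = vertices, edges = edges,
         adj_out = adj_out, adj_in = adj_in,
         cache = new.env(parent = emptyenv())),
    class = "assembly_graph"
  )
}

#' Build a condensed de Bruijn graph from sequences
#'
#' Extracts all k-mers of the input sequences and their reverse
#' complements (k-mers containing `N` are skipped), then condenses
#' every maximal non-branching path into a single unitig edge.  The
#' result is deterministic for a fixed input: edges are numbered by
#' lexicographic order of their unitig sequence.
#'
#' @param reads Character vector of DNA sequences (reads, contigs or
#'   genomes; anything of length >= `k`).
#' @param k Odd k-mer size between 3 and 31 (default 31).
#' @return An [assembly_graph][new_assembly_graph] object.
#' @examples
#' g <- build_graph(c("ACGTT", "ACGTA"), k = 3)
#' g$edges$sequence
#' @export
build_graph <- function(reads, k = 31L) {
  stopifnot(is.character(reads))
  k <- as.integer(k)
  if (k < 3L || k > 31L || k %% 2L == 0L) {
    abort("`k` must be an odd integer between 3 and 31")
  }
  reads <- reads[!is.na(reads)]
  if (length(reads) == 0 || all(nchar(reads) < k)) {
    abort("no graph: no input sequence is at least `k` bases long")
  }
  unitigs <- cpp_build_unitigs(reads, k)
  if (length(unitigs) == 0) {
    abort("no graph: no usable k-mers (sequences may be all N)")
  }
  new_assembly_graph(unitigs, k)
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf(
    "<assembly_graph> k = %d: %d vertices, %d edges (incl. conjugates), %d bp total\n",
    x$k, nrow(x$vertices), nrow(x$edges), sum(x$edges$length)
  ))
  invisible(x)
}

#' Distance-bounded Dijkstra neighborhood
#'
#' Computes the set of vertices reachable from (`direction =
#' "forward"`) or that can reach (`direction = "reverse"`) a source
#' vertex within search distance `d`, together with their exact
#' shortest distances.  Edge weights are novel lengths in bp, so `d`
#' has the units of genomic distance.  The search never expands a
#' vertex whose tentative distance exceeds `d`; ties are broken by
#' vertex id (the distances are exact either way).
#'
#' @param graph An [assembly_graph][new_assembly_graph].
#' @param source Vertex id.
#' @param d Maximum search distance in bp (>= 0).
#' @param direction `"forward"` (downstream of `source`) or
#'   `"reverse"` (upstream, i.e. vertices from which `source` is
#'   reachable).
#' @return A tibble with columns `vertex` and `distance`, sorted by
#'   distance then vertex, carrying attributes `source`, `direction`
#'   and `d`.  Always contains `source` at distance 0.
#' @export
bounded_dijkstra <- function(graph, source, d,
                             direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(graph, "assembly_graph"))
  source <- as.integer(source)
  if (is.na(source) || source < 1L || source > nrow(graph$vertices)) {
    abort(sprintf("unknown source vertex id: %s", source))
  }
  check_scalar_number(d, "d", min = 0)
  csr <- graph_csr(graph, direction)
  res <- cpp_bounded_dijkstra(csr$ptr, csr$head, csr$w, source, d)
  out <- tibble(
    vertex = res$vertex,
    distance = res$distance
  ) %>% arrange(.data$distance, .data$vertex)
  attr(out, "source") <- source
  attr(out, "direction") <- direction
  attr(out, "d") <- d
  out
}

# Compressed-sparse-row adjacency for one search direction, memoised
# on the graph's cache environment.
graph_csr <- function(graph, direction) {
  key <- paste0("csr_", direction)
  hit <- graph$cache[[key]]
  if (!is.null(hit)) return(hit)
  e <- graph$edges
  if (direction == "forward") {
    tail <- e$from; head <- e$to
  } else {
    tail <- e$to; head <- e$from
  }
  nv <- nrow(graph$vertices)
  o <- order(tail, e$edge)
  csr <- list(
    ptr = c(0L, cumsum(tabulate(tail, nbins = nv))),
    head = head[o],
    w = as.numeric(e$novel_length[o])
  )
  graph$cache[[key]] <- csr
  csr
}

#' Export unitig sequences as FASTA
#'
#' Writes one record per canonical edge (the lexicographically smaller
#' member of each conjugate pair).
#'
#' @param graph An assembly graph.
#' @param path Output FASTA path.
#' @export
write_unitigs_fasta <- function(graph, path) {
  stopifnot(inherits(graph, "assembly_graph"))
  e <- graph$edges %>% filter(.data$edge <= .data$conjugate)
  seqs <- Biostrings::DNAStringSet(e$sequence)
  names(seqs) <- sprintf("edge_%d", e$edge)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
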