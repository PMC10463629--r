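# Independent oracles, deliberately written in plain R against raw
# k-mer sets so they share no code with the package's compiled path.

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

kmers_of <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    ks <- substring(s, 1:(n - k + 1), k:n)
    out <- c(out, ks[!grepl("[^ACGT]", ks)])
  }
  unique(out)
}

# Brute-force condensation: build the raw k-mer digraph (doubled with
# reverse complements) and merge maximal non-branching paths by
# repeated scanning.  Returns the sorted unitig sequence set.
oracle_unitigs <- function(seqs, k) {
  km <- sort(unique(c(kmers_of(seqs, k), rc_chr(kmers_of(seqs, k)))))
  if (length(km) == 0) return(character(0))
  pre <- substr(km, 1, k - 1)
  suf <- substr(km, 2, k)
  nodes <- unique(c(pre, suf))
  outdeg <- table(factor(pre, nodes))
  indeg <- table(factor(suf, nodes))
  interior <- function(v) indeg[[v]] == 1 && outdeg[[v]] == 1
  used <- setNames(rep(FALSE, length(km)), km)
  succ_of <- function(v) km[pre == v]
  walk <- function(e0) {
    u <- e0
    used[e0] <<- TRUE
    repeat {
      v <- substr(u, nchar(u) - k + 2, nchar(u))
      if (!interior(v)) break
      nxt <- succ_of(v)
      if (length(nxt) != 1 || used[nxt]) break
      used[nxt] <<- TRUE
      u <- paste0(u, substr(nxt, k, k))
    }
    u
  }
  unitigs <- character(0)
  for (e in km) {
    if (!used[e] && !interior(substr(e, 1, k - 1))) {
      unitigs <- c(unitigs, walk(e))
    }
  }
  for (e in km) if (!used[e]) unitigs <- c(unitigs, walk(e))
  sort(unitigs)
}

# Shortest-path oracle via igraph on the package graph's edge list;
# returns the sorted vertex ids within distance d.
oracle_reachable <- function(graph, source, d, direction) {
  e <- graph$edges
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to),
    directed = TRUE,
    vertices = data.frame(name = graph$vertices$vertex)
  )
  mode <- if (direction == "forward") "out" else "in"
  dist <- igraph::distances(ig, v = as.character(source),
                            mode = mode, weights = e$novel_length)[1, ]
  sort(as.integer(names(dist)[is.finite(dist) & dist <= d]))
}

# Random branching sequence sets over a two-letter alphabet so small k
# produces junction-rich graphs.
random_graph_seqs <- function(n_seq = 3, len = 40, alphabet = c("A", "C")) {
  vapply(seq_len(n_seq), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Minimal number of groups partitioning sorted starts into span <= L
# windows (dynamic programme, independent of the greedy sweep).
oracle_min_groups <- function(starts, L) {
  n <- length(starts)
  if (n == 0) return(0L)
  best <- rep(Inf, n + 1)
  best[1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (starts[i] - starts[j] <= L) {
        best[i + 1] <- min(best[i + 1], best[j] + 1)
      }
    }
  }
  as.integer(best[n + 1])
}
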