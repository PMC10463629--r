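#' Read an assembly graph from GFA1
#'
#' Ingests a GFA1 file with `S` (segment) and `L` (link) records into
#' an [assembly_graph][new_assembly_graph].  All link overlaps must
#' equal `k - 1`; `k` is inferred from the overlaps (or a `KM:i:` tag
#' on the header, as written by [write_gfa()]) and may be supplied
#' explicitly for files without links.  Conjugate segments are
#' synthesized, and junction vertices are identified by shared
#' terminal (k-1)-mers — the de Bruijn semantic of a link; each link
#' record is validated against it.
#'
#' @param path GFA1 file path.
#' @param k Optional k-mer size, required when the file has no `L`
#'   records and no `KM` header tag.
#' @return An `assembly_graph`.
#' @export
read_gfa <- function(path, k = NULL) {
  lines <- readr::read_lines(path)
  segs <- character(0)
  seg_names <- character(0)
  overlaps <- integer(0)
  links <- list()
  header_k <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "H") {
      km <- grep("^KM:i:", f, value = TRUE)
      if (length(km)) header_k <- as.integer(sub("^KM:i:", "", km[1]))
    } else if (f[1] == "S") {
      if (length(f) < 3 || !grepl("^[ACGTNacgtn]+$", f[3])) {
        abort(sprintf("malformed S record at line %d of %s", i, path))
      }
      seg_names <- c(seg_names, f[2])
      segs <- c(segs, toupper(f[3]))
    } else if (f[1] == "L") {
      if (length(f) < 6 || !grepl("^[0-9]+M$", f[6]) ||
          !all(f[c(3, 5)] %in% c("+", "-"))) {
        abort(sprintf("malformed L record at line %d of %s", i, path))
      }
      overlaps <- c(overlaps, as.integer(sub("M$", "", f[6])))
      links[[length(links) + 1]] <- list(line = i, from = f[2],
                                         fo = f[3], to = f[4], to_or = f[5])
    }
  }
  if (length(segs) == 0) abort(sprintf("no S records in %s", path))
  if (anyDuplicated(seg_names)) {
    abort(sprintf("duplicated segment names in %s", path))
  }
  if (length(overlaps) > 0) {
    if (length(unique(overlaps)) != 1) {
      abort(sprintf("mixed link overlap lengths in %s: %s", path,
                    paste(unique(overlaps), collapse = ", ")))
    }
    link_k <- overlaps[1] + 1L
    if (!is.null(k) && as.integer(k) != link_k) {
      abort(sprintf("supplied k = %s contradicts link overlaps (k - 1 = %d)",
                    k, overlaps[1]))
    }
    k <- link_k
  }
  if (is.null(k)) k <- header_k
  if (is.null(k)) {
    abort("k cannot be inferred (no L records, no KM header tag): pass `k`")
  }
  k <- as.integer(k)
  if (any(nchar(segs) < k)) {
    abort(sprintf("segment shorter than k = %d in %s", k, path))
  }
  # validate links against the overlap semantic
  oriented <- function(name, orient) {
    idx <- match(name, seg_names)
    if (is.na(idx)) return(NA_character_)
    if (orient == "+") segs[idx] else revcomp(segs[idx])
  }
  for (lk in links) {
    a <- oriented(lk$from, lk$fo)
    b <- oriented(lk$to, lk$to_or)
    if (is.na(a) || is.na(b)) {
      abort(sprintf("link at line %d references a missing segment", lk$line))
    }
    if (substr(a, nchar(a) - k + 2L, nchar(a)) != substr(b, 1L, k - 1L)) {
      abort(sprintf("link at line %d does not overlap by k - 1 bases", lk$line))
    }
  }
  new_assembly_graph(unique(c(segs, revcomp(segs))), k)
}

#' Write an assembly graph as GFA1
#'
#' One `S` record per canonical edge (conjugates are implicit via
#' orientation) and one `L` record per junction adjacency, all with
#' overlap `(k-1)M`.  The header carries a `KM:i:` tag so that
#' link-less graphs round-trip.
#'
#' @param graph An assembly graph.
#' @param path Output path.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "assembly_graph"))
  e <- graph$edges
  canon <- e$edge <= e$conjugate
  seg_of <- ifelse(canon, e$edge, e$conjugate)
  orient_of <- ifelse(canon, "+", "-")
  lines <- sprintf("H\tVN:Z:1.0\tKM:i:%d", graph$k)
  ce <- e[canon, ]
  if (nrow(ce) > 0) {
    lines <- c(lines, sprintf("S\t%d\t%s", ce$edge, ce$sequence))
  }
  # adjacency e1 -> e2 whenever to(e1) == from(e2); a link and its
  # reverse-complement are the same link, keep one representative
  seen <- character(0)
  for (i in seq_len(nrow(e))) {
    v <- e$to[i]
    for (j in graph$adj_out[[v]]) {
      key <- sprintf("%d|%s|%d|%s", seg_of[i], orient_of[i],
                     seg_of[j], orient_of[j])
      rc_key <- sprintf("%d|%s|%d|%s",
                        seg_of[j], if (orient_of[j] == "+") "-" else "+",
                        seg_of[i], if (orient_of[i] == "+") "-" else "+")
      if (key %in% seen || rc_key %in% seen) next
      seen <- c(seen, key)
      lines <- c(lines, sprintf("L\t%d\t%s\t%d\t%s\t%dM",
                                seg_of[i], orient_of[i],
                                seg_of[j], orient_of[j], graph$k - 1L))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}
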