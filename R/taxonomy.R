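# UMI-consensus taxonomic promotion.
#
# Ranks follow the ladder root (R) > kingdom/domain (D) > phylum (P) >
# class (C) > order (O) > family (F) > genus (G) > species (S).
# Lineage strings are positional below root: "k_0;p_0;c_0" is a read
# classified down to class rank.  The literal lineage "root" marks a
# read classified at root only; an empty lineage marks an unclassified
# read.  Every classified read implicitly carries root, but root is
# never a consensus *target* — a consensus must be a single taxon at
# kingdom/domain rank or below.

lineage_tokens <- function(lineage) {
  lineage <- trimws(lineage)
  lapply(lineage, function(x) {
    if (is.na(x) || x == "" ) return(character(0))
    if (tolower(x) == "root") return(character(0))
    strsplit(x, ";", fixed = TRUE)[[1]]
  })
}

# rank index: 1 = R ... 8 = S; unclassified = NA
lineage_depth <- function(lineage, classified) {
  ntok <- vapply(lineage_tokens(lineage), length, integer(1))
  ifelse(classified, ntok + 1L, NA_integer_)
}

#' Read per-read taxonomic classifications
#'
#' Consumes a TSV with columns `read_id`, `cloud_id`, `lineage` where
#' `lineage` is a semicolon-joined path from kingdom/domain downward
#' (truncation only at the tail), the literal `root` for a read
#' classified at root only, or empty for an unclassified read.
#'
#' @param path TSV path (header required).
#' @return Classification tibble: `read_id`, `cloud_id`, `classified`,
#'   `lineage`, `depth` (rank index, 1 = root ... 8 = species).
#' @export
read_classifications <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("read_id", "cloud_id", "lineage")
  if (!all(need %in% names(tab))) {
    abort(sprintf("classification TSV must have columns %s",
                  paste(need, collapse = ", ")))
  }
  tab$lineage[is.na(tab$lineage)] <- ""
  toks <- lineage_tokens(tab$lineage)
  bad <- which(vapply(toks, length, integer(1)) > 7L)
  if (length(bad)) {
    abort(sprintf("line %d: lineage has more than 7 ranks below root",
                  bad[1] + 1L))
  }
  as_classifications(tab)
}

#' Construct a classification table
#'
#' @param x Data frame with `read_id`, `cloud_id`, `lineage`.
#' @return Classification tibble (see [read_classifications()]).
#' @export
as_classifications <- function(x) {
  x <- as_tibble(x)
  x$lineage <- ifelse(is.na(x$lineage), "", trimws(x$lineage))
  classified <- x$lineage != ""
  lineage <- ifelse(tolower(x$lineage) == "root", "root", x$lineage)
  tibble(
    read_id = x$read_id,
    cloud_id = as.character(x$cloud_id),
    classified = classified,
    lineage = lineage,
    depth = lineage_depth(lineage, classified)
  )
}

# Deepest rank (>= kingdom/domain) at which one taxon path is carried
# by a strict majority of the cloud's classified reads.
consensus_of_tokens <- function(toks) {
  n <- length(toks)
  if (n == 0) return(NULL)
  for (depth in 8:2) {
    m <- depth - 1L # tokens needed
    paths <- vapply(toks, function(t) {
      if (length(t) >= m) paste(t[seq_len(m)], collapse = ";")
      else NA_character_
    }, character(1))
    tab <- table(paths[!is.na(paths)])
    if (length(tab) && max(tab) * 2L > n) {
      win <- names(tab)[which.max(tab)]
      return(list(depth = depth, lineage = win,
                  taxon = strsplit(win, ";", fixed = TRUE)[[1]][m]))
    }
  }
  NULL
}

#' Majority-consensus rank of one cloud
#'
#' The deepest rank at which a single taxon is shared by a strict
#' majority (> 1/2) of the cloud's *classified* reads; unclassified
#' reads are excluded from the denominator.  Returns `NULL` when no
#' rank qualifies (including the all-unclassified cloud).
#'
#' @param classifications Classification tibble rows of one cloud.
#' @return `NULL`, or a list with `rank` (letter), `depth` (1-8),
#'   `taxon` and full `lineage`.
#' @examples
#' cl <- as_classifications(tibble::tibble(
#'   read_id = c("a", "b", "c"), cloud_id = "x",
#'   lineage = c("k0;p0", "k0;p0", "k0;p1")))
#' consensus_rank(cl)$rank
#' @export
consensus_rank <- function(classifications) {
  cl <- classifications %>% filter(.data$classified)
  res <- consensus_of_tokens(lineage_tokens(cl$lineage))
  if (is.null(res)) return(NULL)
  list(rank = RANKS[res$depth], depth = res$depth,
       taxon = res$taxon, lineage = res$lineage)
}

#' Promote one cloud to its consensus taxon
#'
#' Every classified read whose deepest rank lies strictly above the
#' cloud consensus rank *and* whose lineage is an ancestor prefix of
#' the consensus lineage is relabeled to the consensus taxon.  Reads
#' at or below the consensus rank, reads conflicting with the
#' consensus lineage, and unclassified reads are unchanged.
#'
#' @param classifications Classification tibble rows of one cloud.
#' @return List: `classifications` (updated) and `events` (tibble
#'   `read_id`, `cloud_id`, `from_rank`, `to_rank`, `to_taxon`).
#' @export
promote_cloud <- function(classifications) {
  cl <- classifications
  cons <- consensus_rank(cl)
  no_events <- tibble(read_id = character(0), cloud_id = character(0),
                      from_rank = character(0), to_rank = character(0),
                      to_taxon = character(0))
  if (is.null(cons)) {
    return(list(classifications = cl, events = no_events))
  }
  prefix_ok <- vapply(seq_len(nrow(cl)), function(i) {
    if (!cl$classified[i]) return(FALSE)
    if (cl$lineage[i] == "root") return(TRUE)
    startsWith(paste0(cons$lineage, ";"), paste0(cl$lineage[i], ";"))
  }, logical(1))
  promote <- cl$classified & cl$depth < cons$depth & prefix_ok
  events <- tibble(
    read_id = cl$read_id[promote],
    cloud_id = cl$cloud_id[promote],
    from_rank = RANKS[cl$depth[promote]],
    to_rank = cons$rank,
    to_taxon = cons$taxon
  )
  cl$lineage[promote] <- cons$lineage
  cl$depth[promote] <- cons$depth
  list(classifications = cl, events = events)
}

#' Promote every cloud of a classification table
#'
#' Applies [promote_cloud()] per `cloud_id`.
#'
#' @param classifications Classification tibble (multiple clouds).
#' @return List: `classifications` (updated, original row order) and
#'   `events` (all promotion events).
#' @export
promote_clouds <- function(classifications) {
  cl <- classifications %>% mutate(.row = row_number())
  parts <- lapply(split(cl, cl$cloud_id), promote_cloud)
  updated <- bind_rows(lapply(parts, `[[`, "classifications")) %>%
    arrange(.data$.row) %>% select(-".row")
  events <- bind_rows(lapply(parts, `[[`, "events")) %>%
    select(-dplyr::any_of(".row"))
  list(classifications = updated, events = events)
}

#' Promotion matrix
#'
#' Counts promotion events per (from rank, to rank) cell.  Only
#' strictly downward cells can be nonzero.
#'
#' @param events Event tibble from [promote_clouds()].
#' @return 8 x 8 integer matrix with ranks R..S as dimnames
#'   (`from` rows, `to` columns).
#' @export
promotion_matrix <- function(events) {
  m <- matrix(0L, 8, 8, dimnames = list(from = RANKS, to = RANKS))
  if (nrow(events) > 0) {
    tab <- table(factor(events$from_rank, RANKS),
                 factor(events$to_rank, RANKS))
    m[] <- m + as.integer(tab)
  }
  m
}

#' Proportion improvement between two promotion counts
#'
#' `(enhanced - original) / original`, reported to 3 decimals; `NA`
#' when `original` is zero.
#'
#' @param enhanced_count Reads promoted with enhanced read clouds.
#' @param original_count Reads promoted with the original clouds.
#' @return Improvement ratio (3 d.p.) or `NA`.
#' @examples
#' improvement_ratio(20214, 873)
#' @export
improvement_ratio <- function(enhanced_count, original_count) {
  check_scalar_number(enhanced_count, "enhanced_count", min = 0)
  check_scalar_number(original_count, "original_count", min = 0)
  if (original_count == 0) return(NA_real_)
  round((enhanced_count - original_count) / original_count, 3)
}
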