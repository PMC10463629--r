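#' Read barcoded paired FASTQ into a read table
#'
#' Parses one or two FASTQ files (gzip transparently handled) carrying
#' the 3' UMI either as a `BX:Z:<umi>` header tag (`dialect = "bx"`) or
#' as a `/{umi}` suffix on the read name (`dialect = "name"`; a
#' trailing `/1` or `/2` mate suffix is stripped first).  Reads with no
#' UMI are kept with `umi = NA` — the "unbarcoded" bucket.
#'
#' @param path_r1,path_r2 FASTQ paths; `path_r2 = NULL` for unpaired.
#' @param dialect UMI carriage dialect, `"bx"` or `"name"`.
#' @return A tibble with columns `read_id`, `mate` (1/2), `sequence`,
#'   `quality`, `umi`.
#' @examples
#' \dontrun{reads <- read_barcoded_fastq("r1.fq.gz", "r2.fq.gz")}
#' @export
read_barcoded_fastq <- function(path_r1, path_r2 = NULL,
                                dialect = c("bx", "name")) {
  dialect <- match.arg(dialect)
  parse_one <- function(path, mate) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) {
        abort(sprintf("FASTQ parse error in %s: %s", path, conditionMessage(e)))
      }
    )
    header <- names(x)
    id <- sub("[ \t].*$", "", header)
    id <- sub("/[12]$", "", id)
    if (dialect == "bx") {
      m <- stringr::str_match(header, "BX:Z:([!-~]+)")[, 2]
      umi <- m
    } else {
      umi <- ifelse(grepl("/", id, fixed = TRUE),
                    sub("^.*/", "", id), NA_character_)
      id <- sub("/[^/]*$", "", id)
    }
    tibble(
      read_id = id,
      mate = mate,
      sequence = unname(as.character(x)),
      quality = unname(as.character(S4Vectors::mcols(x)$qualities)),
      umi = umi
    )
  }
  r1 <- parse_one(path_r1, 1L)
  if (is.null(path_r2)) return(r1)
  r2 <- parse_one(path_r2, 2L)
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf("mismatched mate counts: %d reads in %s, %d in %s",
                  nrow(r1), path_r1, nrow(r2), path_r2))
  }
  bad <- which(r1$read_id != r2$read_id)
  if (length(bad)) {
    abort(sprintf("mate ids disagree at record %d (%s vs %s)",
                  bad[1], r1$read_id[bad[1]], r2$read_id[bad[1]]))
  }
  bind_rows(r1, r2) %>% arrange(match(.data$read_id, r1$read_id), .data$mate)
}

#' Summarise read clouds
#'
#' Groups a read table by UMI.  Cloud size counts reads, not pairs
#' (two mates contribute 2).  Unbarcoded reads (`umi = NA`) form one
#' reserved bucket reported with `umi = NA`.
#'
#' @param reads Read table from [read_barcoded_fastq()] or
#'   [sim_library()].
#' @return Tibble with `umi`, `size`, `read_ids` (list of read ids in
#'   input order), sorted by decreasing size.
#' @export
read_clouds <- function(reads) {
  reads %>%
    group_by(.data$umi) %>%
    summarise(size = dplyr::n(),
              read_ids = list(unique(.data$read_id)), .groups = "drop") %>%
    arrange(dplyr::desc(.data$size))
}

#' Write a read table as barcoded paired FASTQ
#'
#' Emits the BX dialect: headers are `<read_id> BX:Z:<tag>` where the
#' tag is taken from the `umi` column (or a `tag` column if present,
#' which [write_enhanced_fastq()] uses to append subgroup suffixes).
#' Unbarcoded reads get no BX field.
#'
#' @param reads Read table (`read_id`, `mate`, `sequence`, `quality`,
#'   `umi`, optionally `tag`).
#' @param path_r1,path_r2 Output FASTQ paths (gzip if the name ends in
#'   `.gz`); `path_r2 = NULL` writes everything to `path_r1`.
#' @export
write_barcoded_fastq <- function(reads, path_r1, path_r2 = NULL) {
  tag <- if ("tag" %in% names(reads)) reads$tag else reads$umi
  header <- ifelse(is.na(tag), reads$read_id,
                   paste0(reads$read_id, " BX:Z:", tag))
  write_part <- function(idx, path) {
    x <- Biostrings::DNAStringSet(reads$sequence[idx])
    names(x) <- header[idx]
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(reads$quality[idx]),
      compress = grepl("\\.gz$", path)
    )
  }
  if (is.null(path_r2)) {
    write_part(seq_len(nrow(reads)), path_r1)
  } else {
    write_part(which(reads$mate == 1L), path_r1)
    write_part(which(reads$mate == 2L), path_r2)
  }
  invisible(c(path_r1, path_r2))
}
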