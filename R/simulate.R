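# Truth-tracked synthetic long-read (SLR) library simulator.
#
# The generative model mirrors how SLR libraries are made: genomic DNA
# is sheared into long fragments (5-100 kbp), a handful of fragments
# (2-20) are co-partitioned under one 3' UMI, and each fragment is
# only fractionally covered by short read pairs (10-20% of its bases).
# Every emitted read carries a truth record (fragment, reference,
# position), which downstream replaces alignment for gold-standard
# deconvolution and metric computation.

#' Simulator configuration
#'
#' Defaults are the study conditions the generator emulates: fragments
#' drawn uniformly from 5-100 kbp, 2-20 fragments per UMI, 15%
#' fractional fragment coverage, 2 x 150 bp pairs with a 300 bp
#' insert, 16 bp UMIs, and a 0.1% substitution error rate.
#'
#' @param n_umis Number of UMIs (read clouds).
#' @param fragments_per_umi Either a fixed count or a length-2 range
#'   sampled uniformly (integers).
#' @param fragment_length Fixed length or length-2 uniform range, bp.
#' @param coverage_fraction Target covered fraction of each fragment's
#'   bases, in (0, 1].
#' @param read_length,insert_size Read and insert lengths, bp.
#' @param error_rate Per-base substitution probability.
#' @param umi_length UMI length, bp.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_umis = 2000, fragments_per_umi = c(2, 20),
                       fragment_length = c(5000, 100000),
                       coverage_fraction = 0.15, read_length = 150,
                       insert_size = 300, error_rate = 0.001,
                       umi_length = 16) {
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1,
            insert_size >= read_length,
            error_rate >= 0, error_rate < 1,
            all(fragment_length > 0), all(fragments_per_umi >= 1))
  structure(list(
    n_umis = as.integer(n_umis),
    fragments_per_umi = as.integer(fragments_per_umi),
    fragment_length = as.numeric(fragment_length),
    coverage_fraction = coverage_fraction,
    read_length = as.integer(read_length),
    insert_size = as.integer(insert_size),
    error_rate = error_rate,
    umi_length = as.integer(umi_length)
  ), class = "sim_config")
}

draw_range <- function(n, spec, integer = TRUE) {
  if (length(spec) == 1) return(rep(spec, n))
  x <- runif(n, spec[1], spec[2] + if (integer) 1 else 0)
  if (integer) pmin(floor(x), spec[2]) else x
}

#' Simulate reference genomes
#'
#' i.i.d. uniform-random DNA sequences standing in for mock-community
#' references.
#'
#' @param n Number of genomes.
#' @param length Genome length in bp.
#' @param seed Optional RNG seed (deterministic output when set).
#' @return Tibble `genome` (name), `sequence`.
#' @export
sim_genomes <- function(n = 5, length = 200000, seed = NULL) {
  stopifnot(n >= 1, length >= 1)
  with_seed_maybe(seed, tibble(
    genome = sprintf("genome_%02d", seq_len(n)),
    sequence = random_dna(n, length)
  ))
}

#' Write genomes as FASTA
#' @param genomes Tibble from [sim_genomes()].
#' @param path Output FASTA path.
#' @export
write_genomes_fasta <- function(genomes, path) {
  x <- Biostrings::DNAStringSet(genomes$sequence)
  names(x) <- genomes$genome
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read genomes from FASTA
#' @param path FASTA path.
#' @return Tibble `genome`, `sequence`.
#' @export
read_genomes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(genome = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)))
}

# Draw read-pair offsets within a fragment until the covered-base
# fraction target is met.  Each pair covers one contiguous block of
# `insert` bases; coverage is the union of the blocks.
sample_pairs_until <- function(flen, target, insert) {
  insert <- min(insert, flen)
  max_start <- flen - insert
  union_len <- function(p) {
    sp <- sort(p)
    if (length(sp) == 1) return(insert)
    sum(pmin(diff(sp), insert)) + insert
  }
  m0 <- max(1L, ceiling(target / insert))
  pos <- floor(runif(m0, 0, max_start + 1))
  while (union_len(pos) < target) {
    pos <- c(pos, floor(runif(1, 0, max_start + 1)))
  }
  sort(pos)
}

#' Simulate a barcoded SLR library with ground truth
#'
#' For each UMI, draws its fragment count, assigns each fragment a
#' uniform genome, start and length, then samples read pairs from the
#' fragment until the target covered-base fraction is reached.
#' Substitution errors are applied at `error_rate`.  Deterministic
#' under `seed`.
#'
#' @param genomes Genome tibble ([sim_genomes()] or
#'   [read_genomes_fasta()]).
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @param abundance Optional per-genome sampling weights (defaults to
#'   equal abundance).
#' @return A `sim_library` list: `reads` (read table as in
#'   [read_barcoded_fastq()]) and `truth` (tibble `read_id`, `mate`,
#'   `umi`, `fragment_id`, `reference`, `frag_start`, `frag_end`,
#'   `read_start`, `strand`; positions 0-based, fragment intervals
#'   half-open).
#' @export
sim_library <- function(genomes, config = sim_config(), seed = NULL,
                        abundance = NULL) {
  stopifnot(inherits(config, "sim_config"))
  glen <- nchar(genomes$sequence)
  if (any(config$fragment_length > max(glen))) {
    warn("fragment length range exceeds genome length; fragments are clipped")
  }
  with_seed_maybe(seed, {
    ng <- nrow(genomes)
    w <- if (is.null(abundance)) rep(1, ng) else abundance / sum(abundance)
    # UMIs: unique random DNA tags
    umis <- random_dna(config$n_umis, config$umi_length)
    while (anyDuplicated(umis)) {
      dup <- which(duplicated(umis))
      umis[dup] <- random_dna(length(dup), config$umi_length)
    }
    nf <- draw_range(config$n_umis, config$fragments_per_umi)
    frag <- tibble(
      umi_idx = rep.int(seq_len(config$n_umis), nf),
      fragment_id = sprintf("frag_%06d", seq_len(sum(nf))),
      gidx = sample.int(ng, sum(nf), replace = TRUE, prob = w)
    )
    frag$flen <- pmin(draw_range(nrow(frag), config$fragment_length),
                      glen[frag$gidx])
    frag$frag_start <- floor(runif(nrow(frag), 0, glen[frag$gidx] -
                                     frag$flen + 1))
    # read pairs per fragment
    offsets <- lapply(seq_len(nrow(frag)), function(i) {
      sample_pairs_until(frag$flen[i],
                         ceiling(config$coverage_fraction * frag$flen[i]),
                         config$insert_size)
    })
    npairs <- lengths(offsets)
    pr <- tibble(
      fi = rep.int(seq_len(nrow(frag)), npairs),
      offset = unlist(offsets)
    )
    pr$insert <- pmin(config$insert_size, frag$flen[pr$fi])
    pr$pair <- stats::ave(pr$fi, pr$fi, FUN = seq_along)
    rl <- config$read_length
    g1 <- frag$gidx[pr$fi]
    s1 <- frag$frag_start[pr$fi] + pr$offset            # mate 1 start
    s2 <- frag$frag_start[pr$fi] + pr$offset + pr$insert - rl
    seq1 <- substring(genomes$sequence[g1], s1 + 1, s1 + rl)
    seq2 <- revcomp(substring(genomes$sequence[g1], s2 + 1, s2 + rl))
    read_id <- sprintf("u%05d_%s_p%03d", frag$umi_idx[pr$fi],
                       sub("^frag_", "f", frag$fragment_id[pr$fi]), pr$pair)
    reads <- tibble(
      read_id = rep(read_id, 2),
      mate = rep(c(1L, 2L), each = nrow(pr)),
      sequence = c(seq1, seq2),
      quality = strrep("I", rl),
      umi = rep(umis[frag$umi_idx[pr$fi]], 2)
    )
    if (config$error_rate > 0) {
      reads$sequence <- add_substitutions(reads$sequence, config$error_rate)
    }
    truth <- tibble(
      read_id = reads$read_id,
      mate = reads$mate,
      umi = reads$umi,
      fragment_id = rep(frag$fragment_id[pr$fi], 2),
      reference = rep(genomes$genome[g1], 2),
      frag_start = rep(frag$frag_start[pr$fi], 2),
      frag_end = rep(frag$frag_start[pr$fi] + frag$flen[pr$fi], 2),
      read_start = c(s1, s2),
      strand = rep(c("+", "-"), each = nrow(pr))
    )
    ord <- order(truth$read_id, truth$mate)
    structure(list(reads = reads[ord, ], truth = truth[ord, ],
                   config = config),
              class = "sim_library")
  })
}

# substitution errors: per-read error counts are binomial, positions
# uniform, substituted base drawn from the other three
add_substitutions <- function(seqs, rate) {
  rl <- nchar(seqs)
  nerr <- rbinom(length(seqs), rl, rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(rl[i], nerr[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf(
    "<sim_library> %d reads (%d pairs) in %d clouds over %d fragments\n",
    nrow(x$reads), nrow(x$reads) / 2, length(unique(x$reads$umi)),
    length(unique(x$truth$fragment_id))
  ))
  invisible(x)
}

#' Truth table as alignment records
#'
#' Re-expresses a simulator truth table in the alignment form consumed
#' by [reference_deconvolve()], bypassing any aligner.
#'
#' @param truth Truth tibble from [sim_library()].
#' @return Alignment tibble (`read_id`, `mate`, `umi`, `reference`,
#'   `start`, `aligned`).
#' @export
truth_alignments <- function(truth) {
  as_tibble(truth) %>%
    mutate(start = .data$read_start, aligned = TRUE) %>%
    select("read_id", "mate", "umi", "reference", "start", "aligned")
}

#' Expected sequencing depth
#'
#' Fold coverage `n_reads * read_length / total_genome_length`.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length, bp.
#' @param total_genome_length Summed reference length, bp.
#' @return Fold coverage (X).
#' @examples
#' expected_depth(1e8, 150, 160092218)
#' @export
expected_depth <- function(n_reads, read_length, total_genome_length) {
  check_scalar_number(n_reads, "n_reads", min = 0)
  check_scalar_number(read_length, "read_length", min = 1)
  check_scalar_number(total_genome_length, "total_genome_length")
  if (total_genome_length <= 0) abort("total_genome_length must be > 0")
  n_reads * read_length / total_genome_length
}

#' Simulate per-read taxonomic classifications from truth
#'
#' Gives every read its genome's 8-rank lineage truncated at a rank
#' drawn from `truncation_profile` — a named probability vector over
#' `c("unclassified", "R", "D", ..., "S")` that must sum to 1.
#' Emulates the per-read output of a short-read taxonomic classifier.
#'
#' @param truth Truth tibble from [sim_library()].
#' @param taxonomy Optional tibble `reference`, `lineage` (7
#'   semicolon-joined taxa, kingdom to species); defaults to one clean
#'   lineage per genome (`k_i;p_i;...;s_i`).
#' @param truncation_profile Named probabilities; default classifies
#'   70% of reads to species, spreads 25% over higher ranks and leaves
#'   5% unclassified.
#' @param seed Optional RNG seed.
#' @param cloud_id Cloud labels per read; defaults to the truth UMIs.
#' @return Classification tibble (see [as_classifications()]).
#' @export
sim_classifications <- function(truth, taxonomy = NULL,
                                truncation_profile = NULL, seed = NULL,
                                cloud_id = NULL) {
  truth <- as_tibble(truth)
  refs <- sort(unique(truth$reference))
  if (is.null(taxonomy)) {
    taxonomy <- tibble(
      reference = refs,
      lineage = vapply(seq_along(refs), function(i) {
        paste(sprintf("%s_%d", c("k", "p", "c", "o", "f", "g", "s"), i),
              collapse = ";")
      }, character(1))
    )
  }
  levels <- c("unclassified", RANKS)
  if (is.null(truncation_profile)) {
    truncation_profile <- setNames(
      c(0.05, 0.03, 0.03, 0.03, 0.03, 0.03, 0.05, 0.05, 0.70), levels)
  }
  if (!all(names(truncation_profile) %in% levels) ||
      abs(sum(truncation_profile) - 1) > 1e-8) {
    abort("truncation_profile must be named over unclassified/R..S and sum to 1")
  }
  prof <- setNames(numeric(length(levels)), levels)
  prof[names(truncation_profile)] <- truncation_profile
  with_seed_maybe(seed, {
    lin_full <- taxonomy$lineage[match(truth$reference, taxonomy$reference)]
    lvl <- sample(levels, nrow(truth), replace = TRUE, prob = prof)
    toks <- strsplit(lin_full, ";", fixed = TRUE)
    depth <- match(lvl, RANKS) # NA for unclassified
    lineage <- vapply(seq_len(nrow(truth)), function(i) {
      if (is.na(depth[i])) return("")
      if (depth[i] == 1L) return("root")
      paste(toks[[i]][seq_len(depth[i] - 1L)], collapse = ";")
    }, character(1))
    as_classifications(tibble(
      read_id = paste0(truth$read_id, "/", truth$mate),
      cloud_id = if (is.null(cloud_id)) truth$umi else cloud_id,
      lineage = lineage
    ))
  })
}

#' Write / read a truth table as TSV
#' @param truth Truth tibble.
#' @param path TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = "c", mate = "i", umi = "c", fragment_id = "c",
    reference = "c", frag_start = "d", frag_end = "d",
    read_start = "d", strand = "c"
  ))
}
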