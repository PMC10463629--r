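test_that("genome simulation is seeded and shaped correctly", {
  g1 <- sim_genomes(5, 2000, seed = 1)
  g2 <- sim_genomes(5, 2000, seed = 1)
  g3 <- sim_genomes(5, 2000, seed = 2)
  expect_identical(g1, g2)
  expect_false(all(g1$sequence == g3$sequence))
  expect_equal(nchar(g1$sequence), rep(2000L, 5))
  f <- withr::local_tempfile(fileext = ".fa")
  write_genomes_fasta(g1, f)
  expect_equal(read_genomes_fasta(f), g1)
})

test_that("the same seed reproduces an identical library", {
  gen <- sim_genomes(2, 30000, seed = 3)
  cfg <- sim_config(n_umis = 10, fragments_per_umi = 3,
                    fragment_length = c(5000, 10000))
  l1 <- sim_library(gen, cfg, seed = 4)
  l2 <- sim_library(gen, cfg, seed = 4)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)
})

test_that("truth intervals are nested and counts are consistent", {
  gen <- sim_genomes(3, 40000, seed = 5)
  cfg <- sim_config(n_umis = 20, fragments_per_umi = c(2, 5),
                    fragment_length = c(5000, 20000))
  lib <- sim_library(gen, cfg, seed = 6)
  tr <- lib$truth
  expect_equal(nrow(lib$reads), nrow(tr))
  expect_setequal(paste(lib$reads$read_id, lib$reads$mate),
                  paste(tr$read_id, tr$mate))
  glen <- setNames(nchar(gen$sequence), gen$genome)
  expect_true(all(tr$frag_start >= 0))
  expect_true(all(tr$frag_end <= glen[tr$reference]))
  expect_true(all(tr$read_start >= tr$frag_start))
  expect_true(all(tr$read_start + 150 <= tr$frag_end))
  # every read sequence is an exact substring of its genome (error-free)
  cfg0 <- sim_config(n_umis = 5, fragments_per_umi = 2, error_rate = 0,
                     fragment_length = c(5000, 10000))
  lib0 <- sim_library(gen, cfg0, seed = 7)
  idx <- sample.int(nrow(lib0$reads), 20)
  for (i in idx) {
    r <- lib0$reads[i, ]; t <- lib0$truth[i, ]
    gseq <- gen$sequence[gen$genome == t$reference]
    sub <- substring(gseq, t$read_start + 1, t$read_start + 150)
    expect_equal(r$sequence, if (t$strand == "+") sub else revcomp(sub))
  }
})

test_that("fixed fragment multiplicity is exact; ranged matches uniform", {
  gen <- sim_genomes(2, 50000, seed = 8)
  lib <- sim_library(gen, sim_config(n_umis = 15, fragments_per_umi = 3,
                                     fragment_length = c(5000, 10000)),
                     seed = 9)
  per_umi <- tapply(lib$truth$fragment_id, lib$truth$umi,
                    function(x) length(unique(x)))
  expect_true(all(per_umi == 3))

  lib2 <- sim_library(gen, sim_config(n_umis = 400,
                                      fragments_per_umi = c(2, 5),
                                      fragment_length = c(5000, 8000),
                                      coverage_fraction = 0.1),
                      seed = 10)
  counts <- tapply(lib2$truth$fragment_id, lib2$truth$umi,
                   function(x) length(unique(x)))
  expect_setequal(sort(unique(counts)), 2:5)
  chi <- stats::chisq.test(table(factor(counts, levels = 2:5)),
                           p = rep(0.25, 4))
  expect_gt(chi$p.value, 0.001)
})

test_that("read-pair counts track the coverage target", {
  # closed form for the sampling rule: pairs are added until the union
  # of 300 bp blocks reaches 15% of a 10 kbp fragment, so the expected
  # count sits between target/block = 5 and the overlap-corrected
  # ln(1 - 0.15)/ln(1 - 300/10000) ~ 5.34 plus sampling slack
  gen <- sim_genomes(1, 50000, seed = 12)
  cfg <- sim_config(n_umis = 150, fragments_per_umi = 2,
                    fragment_length = 10000, coverage_fraction = 0.15)
  lib <- sim_library(gen, cfg, seed = 13)
  pairs_per_frag <- tapply(lib$truth$read_id, lib$truth$fragment_id,
                           function(x) length(unique(x)))
  expect_gte(mean(pairs_per_frag), 5)
  expect_lte(mean(pairs_per_frag), 6.5)
})

test_that("substitution errors appear at roughly the configured rate", {
  gen <- sim_genomes(1, 30000, seed = 14)
  cfg <- sim_config(n_umis = 30, fragments_per_umi = 2,
                    fragment_length = 8000, error_rate = 0.01)
  lib <- sim_library(gen, cfg, seed = 15)
  gseq <- gen$sequence[1]
  mism <- vapply(seq_len(nrow(lib$reads)), function(i) {
    t <- lib$truth[i, ]
    sub <- substring(gseq, t$read_start + 1, t$read_start + 150)
    if (t$strand == "-") sub <- revcomp(sub)
    sum(strsplit(lib$reads$sequence[i], "")[[1]] !=
          strsplit(sub, "")[[1]])
  }, numeric(1))
  rate <- sum(mism) / (nrow(lib$reads) * 150)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
})

test_that("depth arithmetic is linear and guards its domain", {
  expect_equal(expected_depth(0, 150, 1e6), 0)
  expect_equal(expected_depth(2000, 150, 1e6), 0.3)
  expect_error(expected_depth(10, 150, 0), "> 0")
})

test_that("classification fixtures follow the truncation profile", {
  gen <- sim_genomes(3, 30000, seed = 16)
  lib <- sim_library(gen, sim_config(n_umis = 150, fragments_per_umi = 2,
                                     fragment_length = c(5000, 8000)),
                     seed = 17)
  all_species <- sim_classifications(
    lib$truth, truncation_profile = c(S = 1), seed = 18)
  expect_true(all(all_species$depth == 8))
  none <- sim_classifications(
    lib$truth, truncation_profile = c(unclassified = 1), seed = 18)
  expect_true(all(!none$classified))
  mixed <- sim_classifications(
    lib$truth, truncation_profile = c(R = 0.3, S = 0.7), seed = 19)
  p_root <- mean(mixed$lineage == "root")
  expect_gt(p_root, 0.25); expect_lt(p_root, 0.35)
  expect_error(
    sim_classifications(lib$truth, truncation_profile = c(R = 0.5)),
    "sum to 1")
})
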