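# Two-component graph (no shared k-mers between the two unitigs) used
# by several cloud tests.
two_island_graph <- function() {
  set.seed(5)
  a <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  g <- build_graph(c(a, b), k = 31)
  list(graph = g, a = a, b = b)
}

test_that("reads sharing a unitig are all in each other's connected set", {
  ti <- two_island_graph()
  g <- ti$graph
  ea <- which(g$edges$sequence == ti$a)
  va <- c(g$edges$from[ea], g$edges$to[ea])
  cloud <- dplyr::bind_rows(lapply(1:4, function(i) {
    path_row(paste0("r", i), 1L, va, va[1], va[2], "U1")
  }))
  expect_setequal(connected_set(g, cloud, "r1", d = 0), paste0("r", 1:4))
})

test_that("reads on separate components never connect", {
  ti <- two_island_graph()
  g <- ti$graph
  ea <- which(g$edges$sequence == ti$a)
  eb <- which(g$edges$sequence == ti$b)
  va <- c(g$edges$from[ea], g$edges$to[ea])
  vb <- c(g$edges$from[eb], g$edges$to[eb])
  cloud <- dplyr::bind_rows(
    path_row("r1", 1L, va, va[1], va[2], "U1"),
    path_row("r2", 1L, vb, vb[1], vb[2], "U1")
  )
  for (d in c(0, 5000, 1e7)) {
    expect_equal(connected_set(g, cloud, "r1", d), "r1")
  }
  expect_error(connected_set(g, cloud, "missing", 0), "unmapped or absent")
})

test_that("the search distance gates connection across a 7 kbp gap", {
  g <- kbp_chain_graph()
  v <- function(km) vertex_id(g, km)
  cloud <- dplyr::bind_rows(
    path_row("near", 1L, c(v("AA"), v("CC")), v("AA"), v("CC"), "U1"),
    path_row("far", 1L, c(v("AC"), v("CA")), v("AC"), v("CA"), "U1")
  )
  expect_equal(connected_set(g, cloud, "near", d = 5000), "near")
  expect_setequal(connected_set(g, cloud, "near", d = 10000),
                  c("near", "far"))
})

test_that("a lone pair on an isolated edge joins the disconnected set", {
  ti <- two_island_graph()
  g <- ti$graph
  ea <- which(g$edges$sequence == ti$a)
  eb <- which(g$edges$sequence == ti$b)
  va <- c(g$edges$from[ea], g$edges$to[ea])
  vb <- c(g$edges$from[eb], g$edges$to[eb])
  paths <- dplyr::bind_rows(c(
    lapply(1:4, function(i) {
      dplyr::bind_rows(
        path_row(paste0("p", i), 1L, va, va[1], va[2], "U1"),
        path_row(paste0("p", i), 2L, va, va[1], va[2], "U1")
      )
    }),
    list(path_row("iso", 1L, vb, vb[1], vb[2], "U1"),
         path_row("iso", 2L, vb, vb[1], vb[2], "U1"))
  ))
  res <- deconvolve(g, paths = paths, config = deconv_config(d = 100))
  a <- res$assignments
  expect_true(all(a$disconnected[a$read_id == "iso"]))
  expect_equal(unique(a$subgroup[a$read_id != "iso"]), 1L)
  # partition: every read appears exactly once
  expect_equal(nrow(a), nrow(paths))
})

test_that("below-cutoff clouds pass through intact as subgroup 0", {
  ti <- two_island_graph()
  g <- ti$graph
  ea <- which(g$edges$sequence == ti$a)
  va <- c(g$edges$from[ea], g$edges$to[ea])
  paths <- dplyr::bind_rows(lapply(1:3, function(i) {
    path_row(paste0("r", i), 1L, va, va[1], va[2], paste0("U", i %% 2))
  }))
  res <- deconvolve(g, paths = paths, config = deconv_config(size_cutoff = 6))
  expect_true(all(res$assignments$subgroup == 0L))
  expect_false(any(res$assignments$disconnected))
})

test_that("simulated clouds split into their true fragment partition", {
  sp <- small_pipeline()
  joined <- dplyr::inner_join(
    sp$result$assignments,
    sp$lib$truth[, c("read_id", "mate", "fragment_id", "reference")],
    by = c("read_id", "mate")
  )
  active <- joined[!joined$disconnected & joined$subgroup > 0, ]
  # within a cloud, reads of one subgroup never mix reference genomes
  mix <- dplyr::summarise(
    dplyr::group_by(active, umi, subgroup),
    n_ref = dplyr::n_distinct(reference), .groups = "drop"
  )
  expect_true(all(mix$n_ref == 1))
  # clouds whose two fragments sit on different genomes split exactly
  two_genome <- dplyr::summarise(
    dplyr::group_by(joined, umi),
    n_ref = dplyr::n_distinct(reference),
    n_frag = dplyr::n_distinct(fragment_id), .groups = "drop"
  )
  split_ok <- dplyr::semi_join(active, two_genome[
    two_genome$n_ref == 2 & two_genome$n_frag == 2, ], by = "umi")
  agree <- dplyr::summarise(
    dplyr::group_by(split_ok, umi, fragment_id),
    n_sub = dplyr::n_distinct(subgroup), .groups = "drop"
  )
  expect_gt(nrow(agree), 0)
  expect_true(all(agree$n_sub == 1))
})

test_that("assignments partition every processed cloud", {
  sp <- small_pipeline()
  a <- sp$result$assignments
  expect_equal(nrow(a), nrow(sp$lib$reads))
  expect_false(anyDuplicated(paste(a$read_id, a$mate)) > 0)
  expect_true(all(a$subgroup[a$disconnected] == 0L))
})

test_that("results are invariant to processing order and thread count", {
  sp <- small_pipeline()
  key <- function(res) {
    a <- dplyr::arrange(res$assignments, read_id, mate)
    paste(a$read_id, a$mate, a$umi, a$subgroup, a$disconnected)
  }
  base <- key(sp$result)
  set.seed(3)
  shuffled <- sp$paths[sample(nrow(sp$paths)), ]
  expect_equal(key(deconvolve(sp$graph, paths = shuffled)), base)
  res_mt <- deconvolve(sp$graph, paths = sp$paths,
                       config = deconv_config(threads = 2))
  expect_equal(key(res_mt), base)
})

test_that("subgroups coarsen monotonically with the search distance", {
  gen <- sim_genomes(4, 40000, seed = 23)
  cfg <- sim_config(n_umis = 25, fragments_per_umi = 2,
                    fragment_length = c(4000, 15000), error_rate = 0)
  lib <- sim_library(gen, cfg, seed = 23)
  g <- build_graph(lib$reads$sequence, k = 31) # fragmented: low coverage
  paths <- map_reads(g, lib$reads)
  res1 <- deconvolve(g, paths = paths, config = deconv_config(d = 1000))
  res2 <- deconvolve(g, paths = paths, config = deconv_config(d = 8000))
  a1 <- res1$assignments[!res1$assignments$disconnected &
                           res1$assignments$subgroup > 0, ]
  a2 <- res2$assignments
  j <- dplyr::inner_join(a1, a2, by = c("read_id", "mate", "umi"),
                         suffix = c("_small", "_large"))
  nested <- dplyr::summarise(
    dplyr::group_by(j, umi, subgroup_small),
    n_parents = dplyr::n_distinct(subgroup_large[!disconnected_large]),
    .groups = "drop"
  )
  expect_true(all(nested$n_parents <= 1))
})

test_that("deconvolved FASTQ round-trips the partition through BX tags", {
  sp <- small_pipeline()
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_enhanced_fastq(sp$lib$reads, sp$result, f1, f2)
  back <- read_barcoded_fastq(f1, f2)
  expected <- sp$result$assignments
  tag <- ifelse(expected$disconnected, paste0(expected$umi, ".0-d"),
                paste0(expected$umi, ".", expected$subgroup))
  j <- dplyr::inner_join(back, tibble::tibble(
    read_id = expected$read_id, mate = expected$mate, tag = tag),
    by = c("read_id", "mate"))
  expect_equal(nrow(j), nrow(back))
  expect_equal(j$umi, j$tag)
})
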