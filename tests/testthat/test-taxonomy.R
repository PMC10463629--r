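test_that("the seven-read cloud reaches a family consensus", {
  cl <- seven_read_cloud()
  cons <- consensus_rank(cl)
  expect_equal(cons$rank, "F")
  expect_equal(cons$taxon, "f_0")
  expect_equal(cons$lineage, "k_0;p_0;c_0;o_0;f_0")
})

test_that("promotion relabels exactly the two high-rank reads", {
  cl <- seven_read_cloud()
  out <- promote_cloud(cl)
  expect_equal(nrow(out$events), 2)
  expect_setequal(out$events$read_id, c("read6", "read7"))
  expect_equal(unique(out$events$to_taxon), "f_0")
  expect_equal(unique(out$events$to_rank), "F")
  # the other five reads keep their lineages
  unchanged <- setdiff(cl$read_id, out$events$read_id)
  expect_equal(out$classifications$lineage[match(unchanged, cl$read_id)],
               cl$lineage[match(unchanged, cl$read_id)])
  expect_length(unchanged, 5)
  # event matrix: one order->family and one kingdom/domain->family
  m <- promotion_matrix(out$events)
  expect_equal(m["O", "F"], 1L)
  expect_equal(m["D", "F"], 1L)
  expect_equal(sum(m), 2L)
})

test_that("promotion is idempotent and never demotes", {
  cl <- seven_read_cloud()
  once <- promote_cloud(cl)
  twice <- promote_cloud(once$classifications)
  expect_equal(twice$classifications, once$classifications)
  expect_equal(nrow(twice$events), 0)
  expect_true(all(once$classifications$depth >= cl$depth))
})

test_that("consensus edge cases: unanimity, ties and lone reads", {
  full <- as_classifications(tibble::tibble(
    read_id = c("a", "b", "c"), cloud_id = "x",
    lineage = "k_0;p_0;c_0;o_0;f_0;g_0;s_0"))
  expect_equal(consensus_rank(full)$rank, "S")

  tie <- as_classifications(tibble::tibble(
    read_id = c("a", "b"), cloud_id = "x",
    lineage = c("k_0", "k_1")))
  expect_null(consensus_rank(tie)) # 1/2 is not a strict majority

  lone <- as_classifications(tibble::tibble(
    read_id = "a", cloud_id = "x", lineage = "k_0;p_0"))
  out <- promote_cloud(lone)
  expect_equal(nrow(out$events), 0)
  expect_equal(out$classifications$lineage, "k_0;p_0")

  uncl <- as_classifications(tibble::tibble(
    read_id = c("a", "b"), cloud_id = "x", lineage = c("", "")))
  expect_null(consensus_rank(uncl))
})

test_that("conflicting lineages are never relabeled", {
  cl <- as_classifications(tibble::tibble(
    read_id = paste0("r", 1:4), cloud_id = "x",
    lineage = c("k_0;p_0;c_0", "k_0;p_0;c_0", "k_0;p_0;c_0",
                "k_1;p_9") # different kingdom, higher rank
  ))
  out <- promote_cloud(cl)
  expect_equal(nrow(out$events), 0) # r4 conflicts; r1-3 already at consensus
  cl2 <- as_classifications(tibble::tibble(
    read_id = paste0("r", 1:4), cloud_id = "x",
    lineage = c("k_0;p_0;c_0", "k_0;p_0;c_0", "k_0;p_0;c_0", "k_0")
  ))
  out2 <- promote_cloud(cl2)
  expect_equal(out2$events$read_id, "r4")
  expect_equal(out2$events$from_rank, "D")
  expect_equal(out2$events$to_rank, "C")
})

test_that("root-only reads are classified, promotable, and counted", {
  cl <- as_classifications(tibble::tibble(
    read_id = paste0("r", 1:3), cloud_id = "x",
    lineage = c("k_0;p_0", "k_0;p_0", "root")))
  expect_true(cl$classified[3])
  expect_equal(cl$depth[3], 1L)
  out <- promote_cloud(cl)
  expect_equal(out$events$read_id, "r3")
  expect_equal(out$events$from_rank, "R")
  expect_equal(out$events$to_rank, "P")
})

test_that("multi-cloud promotion preserves rows and counts all events", {
  cl <- dplyr::bind_rows(
    seven_read_cloud(),
    as_classifications(tibble::tibble(
      read_id = paste0("y", 1:3), cloud_id = "cloud2",
      lineage = c("k_1;p_1;c_1", "k_1;p_1;c_1", "k_1")))
  )
  out <- promote_clouds(cl)
  expect_equal(out$classifications$read_id, cl$read_id)
  expect_equal(nrow(out$events), 3)
  m <- promotion_matrix(out$events)
  expect_equal(sum(m), nrow(out$events))
  # with rows ordered root->species, promotions only fill cells whose
  # target rank is deeper than the source: the diagonal and the
  # "upward" half must stay empty
  expect_true(all(m[lower.tri(m, diag = TRUE)] == 0))
  # no event ever points upward or sideways
  from_i <- match(out$events$from_rank, c("R","D","P","C","O","F","G","S"))
  to_i <- match(out$events$to_rank, c("R","D","P","C","O","F","G","S"))
  expect_true(all(to_i > from_i))
  expect_equal(promotion_matrix(out$events[0, ]), matrix(
    0L, 8, 8, dimnames = list(from = c("R","D","P","C","O","F","G","S"),
                              to = c("R","D","P","C","O","F","G","S"))))
})

test_that("classification TSVs parse with validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("read_id\tcloud_id\tlineage",
               "r1\tc9\tk_0;p_0",
               "r2\tc9\t",
               "r3\tc9\troot"), f)
  cl <- read_classifications(f)
  expect_equal(cl$classified, c(TRUE, FALSE, TRUE))
  expect_equal(cl$depth, c(3L, NA_integer_, 1L))
  writeLines(c("read_id\tcloud_id\tlineage",
               "r1\tc9\ta;b;c;d;e;f;g;h"), f)
  expect_error(read_classifications(f), "more than 7")
})

test_that("improvement ratios match the printed table arithmetic", {
  expect_equal(improvement_ratio(20214, 873), 22.155)
  expect_equal(improvement_ratio(100, 100), 0)
  expect_equal(improvement_ratio(0, 100), -1)
  expect_true(is.na(improvement_ratio(10, 0)))
})
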