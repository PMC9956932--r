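test_that("read_counts parses TSV/CSV, preserves order, validates cells", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "gZ\t1\t2\t3\t4",
               "gA\t5\t6\t7\t8",
               "gM\t0\t1\t2\t3"), tsv)
  x <- read_counts(tsv)
  expect_identical(gene_ids(x), c("gZ", "gA", "gM"))     # file order, no sorting
  expect_identical(sample_ids(x), c("s1", "s2", "s3", "s4"))
  expect_equal(unname(x$values["gA", ]), c(5, 6, 7, 8))
  expect_identical(x$scale, "raw")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,s1,s2", "g1,1,2", "g2,3,4"), csv)
  expect_equal(dim(read_counts(csv)$values), c(2L, 2L))  # delimiter sniffed

  neg <- withr::local_tempfile()
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t-3"), neg)
  expect_error(read_counts(neg), "negative count '-3' at gene 'g1', sample 's2'")

  nonnum <- withr::local_tempfile()
  writeLines(c("gene_id\ts1", "g1\tabc"), nonnum)
  expect_error(read_counts(nonnum), "non-numeric.*gene 'g1', sample 's1'")

  dup <- withr::local_tempfile()
  writeLines(c("gene_id\ts1", "g1\t1", "g1\t2"), dup)
  expect_error(read_counts(dup), "duplicate gene id")
})

test_that("count matrices round-trip through write_counts/read_counts", {
  x <- make_expr(matrix(c(0, 1, 2.5, 10, 1000, 3), nrow = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(x, f)
  y <- read_counts(f)
  expect_identical(gene_ids(y), gene_ids(x))
  expect_identical(sample_ids(y), sample_ids(x))
  expect_equal(y$values, x$values)
})

test_that("read_design accepts a valid two-strain file and rejects bad ones", {
  f <- withr::local_tempfile()
  writeLines(c(paste0("m", 1:10, "\tC57BL/6J"),
               paste0("m", 11:21, "\tDBA/2J")), f)
  d <- read_design(f)
  expect_s3_class(d, "strain_design")
  expect_identical(strain_order(d), c("C57BL/6J", "DBA/2J"))
  expect_equal(as.vector(table(d$strain)[strain_order(d)]), c(10L, 11L))

  one <- withr::local_tempfile()
  writeLines(paste0("s", 1:4, "\tonly"), one)
  expect_error(read_design(one), "design error")

  three <- withr::local_tempfile()
  writeLines(c("s1\ta", "s2\ta", "s3\tb", "s4\tb", "s5\tc", "s6\tc"), three)
  expect_error(read_design(three), "design error")

  small <- withr::local_tempfile()
  writeLines(c("s1\ta", "s2\ta", "s3\tb"), small)
  expect_error(read_design(small), "at least 2 samples")
})

test_that("strain_design itself enforces the two-strain contract", {
  expect_error(strain_design(c("s1", "s1", "s2", "s3"), rep(c("a", "b"), 2)),
               "duplicate sample ids")
  d <- strain_design(paste0("s", 1:5), c("b", "b", "a", "a", "a"))
  expect_identical(strain_order(d), c("b", "a"))  # order of first appearance
})

test_that("read_gene_list drops duplicates and tolerates empty files", {
  f <- withr::local_tempfile()
  writeLines(c("g1", "g2", "g3"), f)
  expect_identical(read_gene_list(f, "x")$members, c("g1", "g2", "g3"))

  dupf <- withr::local_tempfile()
  writeLines(c("g1", "g1"), dupf)
  expect_message(gs <- read_gene_list(dupf, "d"), "1 duplicate")
  expect_identical(gs$members, "g1")

  emptyf <- withr::local_tempfile()
  writeLines(character(), emptyf)
  expect_warning(gs0 <- read_gene_list(emptyf, "e"), "empty")
  expect_length(gs0$members, 0)
})

test_that("call files round-trip with parameter header and batch-sorted rows", {
  sim <- simulate_counts(synthetic_spec(n_genes = 400, seed = 7))
  calls <- suppressMessages(
    run_pipeline(sim$counts, sim$design, preset_synthetic(batch_size = 150)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "#metric=")))
  expect_true(any(startsWith(lines, "#t_std=")))

  back <- read_calls(f)
  expect_identical(back$gene_id, calls$gene_id)
  expect_identical(back$batch_index, calls$batch_index)
  expect_identical(back$stage, calls$stage)
  expect_identical(back$label, calls$label)
  expect_false(is.unsorted(back$batch_index))
  expect_identical(attr(back, "params")$metric, "euclidean")
})

test_that("an empty call set writes a header-only file", {
  x <- make_expr(matrix(rep(2^(seq(6, 6.99, by = 0.01)), each = 4),
                        ncol = 4, byrow = TRUE))
  calls <- suppressMessages(
    run_pipeline(x, tiny_design(), preset_synthetic(batch_size = 100)))
  expect_equal(nrow(calls), 0L)
  f <- withr::local_tempfile()
  write_calls(calls, f)
  body <- readLines(f)
  expect_true(all(startsWith(body, "#") | body == "gene_id\tbatch_index\tstage\tlabel"))
  expect_equal(nrow(read_calls(f)), 0L)
})
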