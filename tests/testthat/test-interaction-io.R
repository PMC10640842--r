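test_that("duplicate (plot, plant, insect) rows are summed on read", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    plot = "p1", block = "b1", treatment = "C",
    plant = c("A", "A", "B"), insect = c("x", "x", "y"),
    count = c(2L, 3L, 1L)), tf, row.names = FALSE)
  tab <- read_interactions(tf)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$count[tab$plant == "A" & tab$insect == "x"], 5L)
})

test_that("header-only file yields an empty table with a warning", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines("plot,block,treatment,plant,insect,count", tf)
  expect_warning(tab <- read_interactions(tf), "no interaction records")
  expect_equal(nrow(tab), 0)
})

test_that("schema mapping works and missing columns are named in errors", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(site = "p1", blk = "b1", trt = "C",
                       flower = "A", visitor = "x", visits = 2L),
            tf, row.names = FALSE)
  tab <- read_interactions(tf, schema = c(
    plot = "site", block = "blk", treatment = "trt",
    plant = "flower", insect = "visitor", count = "visits"))
  expect_equal(tab$plant, "A")
  expect_error(read_interactions(tf), "missing required column")
})

test_that("validation rejects bad counts, treatments and plot mappings", {
  base <- data.frame(plot = "p1", block = "b1", treatment = "C",
                     plant = "A", insect = "x", count = 1.5,
                     stringsAsFactors = FALSE)
  expect_error(as_interaction_table(base), "non-integer")
  base$count <- 1L; base$treatment <- "X"
  expect_error(as_interaction_table(base), "unknown treatment")
  two <- data.frame(plot = "p1", block = c("b1", "b2"),
                    treatment = "C", plant = c("A", "B"),
                    insect = "x", count = 1L, stringsAsFactors = FALSE)
  expect_error(as_interaction_table(two), "more than one block")
  zero <- data.frame(plot = "p1", block = "b1", treatment = "C",
                     plant = c("A", "B"), insect = "x",
                     count = c(0L, 2L), stringsAsFactors = FALSE)
  expect_warning(out <- as_interaction_table(zero), "zero-count")
  expect_equal(nrow(out), 1)
})

test_that("plot network matches hand-built matrix and degenerate shapes", {
  tab <- as_interaction_table(data.frame(
    plot = "p1", block = "b1", treatment = "C",
    plant = c("plantA", "plantB", "plantA"),
    insect = c("ins1", "ins1", "ins2"),
    count = c(2L, 1L, 4L), stringsAsFactors = FALSE))
  nw <- build_plot_network(tab, "p1")
  expect_equal(unname(nw$matrix), matrix(c(2L, 1L, 4L, 0L), 2, 2))
  expect_equal(sum(nw$matrix), 7)

  one_plant <- as_interaction_table(data.frame(
    plot = "p1", block = "b1", treatment = "C", plant = "A",
    insect = c("x", "y", "z"), count = 1L, stringsAsFactors = FALSE))
  expect_equal(dim(build_plot_network(one_plant, "p1")$matrix), c(1L, 3L))

  expect_error(build_plot_network(tab, "nope"), "empty network")
})

test_that("network construction is canonical under row shuffling", {
  tab <- toy_interactions()
  for (s in 1:5) {
    shuffled <- tab[sample(nrow(tab)), ]
    class(shuffled) <- class(tab)
    expect_identical(build_plot_network(shuffled, "p1")$matrix,
                     build_plot_network(tab, "p1")$matrix)
  }
})

test_that("weights are conserved between table, plots and treatment pools", {
  tab <- toy_interactions()
  nets <- build_all_networks(tab)
  expect_equal(sum(vapply(nets, function(nw) sum(nw$matrix), numeric(1))),
               sum(tab$count))
  pooled_total <- sum(vapply(c("C", "F", "H", "HF"), function(trt) {
    sum(pool_by_treatment(tab, trt)$matrix)
  }, numeric(1)))
  expect_equal(pooled_total, sum(tab$count))
  expect_error(pool_by_treatment(tab, "Z"), "unknown treatment")
})

test_that("treatment pooling sums counts across plots", {
  tab <- as_interaction_table(data.frame(
    plot = c("p1", "p2"), block = c("b1", "b2"), treatment = "C",
    plant = "A", insect = "x", count = 1L, stringsAsFactors = FALSE))
  pooled <- pool_by_treatment(tab, "C")
  expect_equal(unname(pooled$matrix[1, 1]), 2L)
})

test_that("metrics tables round-trip losslessly through CSV", {
  rows <- data.frame(plot = c("p1", "p2"), connectance = c(0.02173913, 0.5),
                     nodf = c(66.6666667, 0), links = c(10L, 3L),
                     stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(rows, tf)
  back <- read_metrics_table(tf)
  expect_equal(back, rows)
  write_metrics_table(rows[0, ], tf)
  expect_equal(nrow(read_metrics_table(tf)), 0)
})

test_that("metadata accepts display components and validates bounds", {
  md <- as_plot_metadata(data.frame(
    plot = "p1", block = "b1", treatment = "C", plants_bloomed = 5L,
    inflorescences = 10, inflorescence_area = 25))
  expect_equal(md$display, 250)
  expect_equal(md$display_log, log(250))
  expect_error(as_plot_metadata(data.frame(
    plot = "p1", block = "b1", treatment = "C", plants_bloomed = 9L,
    display = 1)), "plants_bloomed")
})
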