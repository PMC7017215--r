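seg_multiset <- function(circles) {
  sort(sub("^-", "", unlist(circles)))
}

test_that("canonical form identifies circles up to rotation and reflection", {
  x <- c("1", "R", "-3", "2")
  for (i in 1:4) {
    expect_equal(canonical_circle(c(x[i:4], x[seq_len(i - 1)])),
                 canonical_circle(x))
  }
  refl <- rev(ifelse(grepl("^-", x), sub("^-", "", x), paste0("-", x)))
  expect_equal(canonical_circle(refl), canonical_circle(x))
  expect_false(identical(canonical_circle(c("1", "2", "R")),
                         canonical_circle(c("1", "R", "2", "R"))))
})

test_that("direct-repeat fission splits a circle and conserves segments", {
  out <- recombine(list(c("R", "A", "R", "B")), "R")
  expect_length(out, 1)
  prods <- lapply(out[[1]], canonical_circle)
  keys <- sort(vapply(prods, paste, character(1), collapse = ","))
  expect_equal(keys, sort(c(paste(canonical_circle(c("R", "A")),
                                  collapse = ","),
                            paste(canonical_circle(c("R", "B")),
                                  collapse = ","))))
  expect_equal(seg_multiset(out[[1]]),
               seg_multiset(list(c("R", "A", "R", "B"))))
})

test_that("inverted-repeat recombination inverts the intervening segment", {
  out <- recombine(list(c("R", "A", "-R", "B")), "R")
  expect_length(out, 1)
  expect_length(out[[1]], 1)
  expect_equal(canonical_circle(out[[1]][[1]]),
               canonical_circle(c("R", "-A", "-R", "B")))
})

test_that("two circles fuse through a shared repeat copy", {
  out <- recombine(list(c("R", "A"), c("R", "B")), "R")
  expect_length(out, 1)
  expect_equal(canonical_circle(out[[1]][[1]]),
               canonical_circle(c("R", "A", "R", "B")))
  # circles sharing repeats in two orientations give two distinct products
  out2 <- recombine(list(c("R", "A", "S", "B"), c("R", "C", "S", "D")), "R")
  out3 <- recombine(list(c("R", "A", "S", "B"), c("R", "C", "S", "D")), "S")
  k2 <- paste(canonical_circle(out2[[1]][[1]]), collapse = ",")
  k3 <- paste(canonical_circle(out3[[1]][[1]]), collapse = ",")
  expect_false(identical(k2, k3))
  # a family absent from the inputs is an error
  expect_error(recombine(list(c("R", "A")), "Q"), "fewer than two")
})

test_that("recombination conserves total segment content", {
  set.seed(71)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    circ <- c(sample(as.character(1:4), n - 2, replace = TRUE), "R", "R")
    circ <- sample(circ)
    flip <- runif(n) < 0.3
    circ <- ifelse(flip, paste0("-", circ), circ)
    outs <- recombine(list(circ), "R")
    for (o in outs) {
      expect_equal(seg_multiset(o), seg_multiset(list(circ)))
    }
  }
})

test_that("fission followed by fusion regenerates the original circle", {
  mc <- c("R", "1", "2", "R", "3", "4")
  fis <- recombine(list(mc), "R")[[1]]
  fus <- recombine(fis, "R")
  keys <- vapply(fus, function(state) {
    paste(sort(vapply(state, function(cc) {
      paste(canonical_circle(cc), collapse = ",")
    }, character(1))), collapse = "|")
  }, character(1))
  expect_true(paste(canonical_circle(mc), collapse = ",") %in% keys)
})

test_that("a circle with no multi-copy repeat only yields itself", {
  e <- enumerate_isomers(c("1", "2", "3"))
  expect_length(e$isomers, 1)
  expect_length(e$subcircles, 0)
})

test_that("the five-block toy yields three masters and four subcircles", {
  e <- enumerate_isomers(toy_master_circle())
  expect_length(e$isomers, 3)
  expect_length(e$subcircles, 4)
  expect_length(e$states, 5)
  # every subcircle pair in a two-circle state partitions the block content
  multi <- e$states[vapply(e$states, length, integer(1)) == 2L]
  expect_length(multi, 2)
  for (st in multi) {
    expect_equal(sort(grep("^[0-9]+$", sub("^-", "", unlist(st)),
                           value = TRUE)),
                 as.character(1:5))
  }
  # adding one more copy of a family never shrinks the isomer set
  bigger <- c(toy_master_circle(), "R")
  e2 <- enumerate_isomers(bigger, max_states = 400)
  expect_gte(length(e2$isomers), length(e$isomers))
})

test_that("the closure cap triggers an explicit error", {
  dense <- c("R", "1", "S", "2", "R", "3", "S", "4", "R", "5", "S")
  expect_error(enumerate_isomers(dense, max_states = 5), "max_states")
})

test_that("junction support counts reads spanning each junction", {
  set.seed(72)
  X <- rand_seq(3000); Y <- rand_seq(3000); Z <- rand_seq(3000)
  segs <- c(X = X, Y = Y, Z = Z)
  assays <- dplyr::bind_rows(
    make_junction_probes(c("X", "Y"), segs, "MC1", flank = 500)[1, ],
    make_junction_probes(c("X", "Z"), segs, "MC3", flank = 500)[1, ])

  # reads from MC1 only: MC1 junction supported, MC3 junction silent
  mc1 <- paste0(X, Y)
  reads <- generate_long_reads(list(MC1 = mc1), c(MC1 = 1),
                               read_length = 2000, error_rate = 0,
                               n_reads = 60, seed = 1)
  js <- junction_support(reads, assays)
  expect_gt(js$supporting_reads[js$junction_id == "MC1(X+Y)"], 0)
  expect_equal(js$supporting_reads[js$junction_id == "MC3(X+Z)"], 0L)

  # reads shorter than the required junction core support nothing
  short <- generate_long_reads(list(MC1 = mc1), c(MC1 = 1),
                               read_length = 60, error_rate = 0,
                               n_reads = 30, seed = 2)
  js_short <- junction_support(short, assays, min_flank = 50)
  expect_equal(sum(js_short$supporting_reads), 0L)

  # 50:50 mixture: junction counts within 3 binomial SD of equality
  mc3 <- paste0(X, Z)
  mix <- generate_long_reads(list(MC1 = mc1, MC3 = mc3),
                             c(MC1 = 0.5, MC3 = 0.5),
                             read_length = 2000, error_rate = 0,
                             n_reads = 2000, seed = 3)
  jm <- junction_support(mix, assays)
  n <- sum(jm$supporting_reads)
  expect_gt(n, 100)
  dev <- abs(jm$supporting_reads[1] - n / 2)
  expect_lte(dev, 3 * sqrt(n * 0.25))
})
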