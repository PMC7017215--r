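# verification oracle: every reported anchor must occur exactly once per
# genome counting both strands, and extending it by one base must break
# the match
anchor_is_sound <- function(anchor, ga, gb) {
  seq_a <- extract_subseq(ga, anchor$start_a, anchor$end_a)
  seq_b <- extract_subseq(gb, anchor$start_b, anchor$end_b)
  if (anchor$orientation == "inverted") seq_b <- revcomp(seq_b)
  if (seq_a != seq_b) return(FALSE)
  occ <- function(g, s) {
    d <- Biostrings::DNAString(paste0(g$seq, substr(g$seq, 1,
                                                    nchar(s) - 1)))
    Biostrings::countPattern(s, d) +
      Biostrings::countPattern(revcomp(s), d)
  }
  occ(ga, seq_a) == 1L && occ(gb, seq_a) == 1L
}

test_that("anchors on identical and rearranged toy genomes are correct", {
  set.seed(3)
  s <- rand_seq(3000)
  a <- circular_seq(s, "a")
  an <- find_anchors(a, circular_seq(s, "b"), min_len = 50)
  expect_equal(nrow(an), 1)
  expect_equal(an$length, 3000L)

  # central block reverse-complemented: one inverted anchor plus one
  # wrap-merged forward anchor covering the rest of the circle
  s2 <- paste0(substr(s, 1, 1000), revcomp(substr(s, 1001, 2000)),
               substr(s, 2001, 3000))
  an2 <- find_anchors(a, circular_seq(s2, "b"), min_len = 50)
  expect_equal(nrow(an2), 2)
  inv <- an2[an2$orientation == "inverted", ]
  expect_equal(c(inv$start_a, inv$end_a), c(1001L, 2000L))
  fwd <- an2[an2$orientation == "forward", ]
  expect_equal(c(fwd$start_a, fwd$end_a), c(2001L, 1000L))  # wraps
  for (i in seq_len(nrow(an2))) {
    expect_true(anchor_is_sound(an2[i, ], a, circular_seq(s2, "b")))
  }

  # unrelated random genomes share no long anchors
  an3 <- find_anchors(a, circular_seq(rand_seq(3000), "c"), min_len = 50)
  expect_equal(nrow(an3), 0)
})

test_that("anchor finding is rotation-invariant in count and soundness", {
  set.seed(8)
  s <- rand_seq(4000)
  # two swapped segments + an inversion
  s2 <- paste0(substr(s, 2001, 3000), substr(s, 1, 1000),
               revcomp(substr(s, 3001, 4000)), substr(s, 1001, 2000))
  a <- circular_seq(s, "a"); b <- circular_seq(s2, "b")
  base <- find_anchors(a, b, min_len = 60)
  for (k in c(137, 2500)) {
    rot <- find_anchors(rotate_genome(a, k), b, min_len = 60)
    expect_equal(nrow(rot), nrow(base))
    expect_equal(sort(rot$length), sort(base$length))
    for (i in seq_len(nrow(rot))) {
      expect_true(anchor_is_sound(rot[i, ], rotate_genome(a, k), b))
    }
  }
})

test_that("block chaining bridges small gaps and filters short chains", {
  set.seed(12)
  s <- rand_seq(5000)
  # a SNP splits the match; chaining must bridge it into one block
  s2 <- s
  substr(s2, 2500, 2500) <- ifelse(substr(s, 2500, 2500) == "A", "C", "A")
  a <- circular_seq(s, circular = FALSE)
  b <- circular_seq(s2, circular = FALSE)
  an <- find_anchors(a, b, min_len = 50)
  bl <- chain_blocks(an, 5000, 5000, min_block = 500)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$orientation, "forward")
  expect_gte(bl$anchors, 2)

  # anchors shorter than min_block and unchainable -> nothing
  empty <- chain_blocks(empty_anchors <- find_anchors(
    circular_seq(rand_seq(1000)), circular_seq(rand_seq(1000)), 50),
    1000, 1000)
  expect_equal(nrow(empty), 0)
})

test_that("unique regions are the filtered complement of block coverage", {
  blocks <- tibble::tibble(start_a = 1L, end_a = 10000L)
  expect_equal(nrow(unique_regions(10000L, blocks, "a")), 0)

  blocks2 <- tibble::tibble(start_a = c(1L, 851L), end_a = c(700L, 10000L))
  expect_equal(nrow(unique_regions(10000L, blocks2, "a",
                                   min_unique_len = 200)), 0)
  got <- unique_regions(10000L, blocks2, "a", min_unique_len = 100)
  expect_equal(c(got$start, got$end, got$length), c(701L, 850L, 150L))
})

test_that("rearrangement classes separate inversions and translocations", {
  set.seed(23)
  # identical genomes: one collinear block
  s <- rand_seq(3000)
  syn0 <- synteny_decompose(s, s, min_len = 50)
  expect_equal(nrow(syn0$blocks), 1)
  expect_equal(syn0$blocks$class, "collinear")

  # nine blocks: two in-place inversions, one translocation, one
  # translocated inversion
  bl <- lapply(1:9, function(i) rand_seq(2500))
  bl[[1]] <- rand_seq(4000)   # largest block anchors the rotation
  spacer <- function() rand_seq(80)
  A <- circular_seq(paste(unlist(bl), collapse = ""))
  order_b <- list(bl[[1]], spacer(), bl[[8]], spacer(), bl[[2]], spacer(),
                  revcomp(bl[[3]]), spacer(), bl[[4]], spacer(),
                  revcomp(bl[[9]]), spacer(), bl[[5]], spacer(),
                  revcomp(bl[[6]]), spacer(), bl[[7]], spacer())
  B <- circular_seq(paste(unlist(order_b), collapse = ""))
  syn <- synteny_decompose(A, B, min_len = 60, min_block = 1000)
  expect_equal(nrow(syn$blocks), 9)
  cls <- attr(syn$blocks, "summary")
  expect_equal(unname(cls["inversion"]), 2L)
  expect_equal(unname(cls["translocation"]), 1L)
  expect_equal(unname(cls["translocation+inversion"]), 1L)
  expect_equal(unname(cls["collinear"]), 5L)

  # symmetry: swapping the genomes preserves the class counts
  syn_swap <- synteny_decompose(B, A, min_len = 60, min_block = 1000)
  expect_equal(attr(syn_swap$blocks, "summary"), cls)
})

test_that("variant calling distinguishes SNPs from indels", {
  set.seed(41)
  s <- rand_seq(6000)
  a <- circular_seq(s, circular = FALSE)

  # identical -> no variants
  syn_id <- synteny_decompose(a, a, min_len = 50)
  expect_equal(nrow(call_variants(syn_id$blocks, a, a)), 0)

  # one substitution and one 3-bp deletion (in a non-homopolymer context)
  s2 <- s
  substr(s2, 1500, 1500) <- ifelse(substr(s, 1500, 1500) == "G", "T", "G")
  s2 <- paste0(substr(s2, 1, 3499), substr(s2, 3503, 6000))
  b <- circular_seq(s2, circular = FALSE)
  syn <- synteny_decompose(a, b, min_len = 50)
  v <- call_variants(syn$blocks, a, b)
  expect_equal(sort(v$type), c("deletion", "snp"))
  del <- v[v$type == "deletion", ]
  expect_equal(nchar(del$ref), 3L)
  expect_equal(del$pos_a, 3500L)
  expect_equal(v$pos_a[v$type == "snp"], 1500L)
})

test_that("coding effects follow the standard genetic code", {
  expect_equal(classify_effect("ATGGGATAA", 5, "G", "A"), "G-E")
  expect_equal(classify_effect("ATGGGATAA", 6, "A", "G"), "synonymous")
  expect_error(classify_effect("ATGGGATAA", 5, "G", "G"), "identical")
  expect_error(classify_effect("ATGGGATAA", 5, "A", "G"), "mismatch")
  expect_equal(classify_effect("ATGGGATAA", 4, "GG", "-"), "frameshift")
  expect_equal(classify_effect("ATGGGATAA", 4, "GGA", "-"), "inframe_indel")
  # the published rps3 variation: position 551, G->A, Gly->Glu
  cds <- paste0(strrep("ATG", 183), "GGATAA")  # position 551 is codon 184/2
  expect_equal(substr(cds, 551, 551), "G")
  expect_equal(classify_effect(cds, 551, "G", "A"), "G-E")
})

test_that("blocks, unique regions and sub-threshold gaps tile the circle", {
  sim <- get_mini_sim()
  syn <- synteny_decompose(sim$cms, sim$normal)
  L <- sim$cms$length
  covered <- rep(0L, L)
  mark <- function(s, e) {
    idx <- if (e >= s) s:e else c(s:L, 1:e)
    covered[idx] <<- covered[idx] + 1L
  }
  for (i in seq_len(nrow(syn$blocks))) {
    mark(syn$blocks$start_a[i], syn$blocks$end_a[i])
  }
  expect_true(all(covered <= 1L))   # blocks never overlap
  for (i in seq_len(nrow(syn$unique_a))) {
    mark(syn$unique_a$start[i], syn$unique_a$end[i])
  }
  expect_true(all(covered <= 1L))   # unique regions fill gaps only
  # whatever remains uncovered is below the unique-region threshold
  runs <- rle(covered[order(seq_len(L))])
  gap_lens <- runs$lengths[runs$values == 0L]
  expect_true(all(gap_lens < 200L))
})

test_that("synteny decomposition is rotation-invariant on a mitogenome pair", {
  sim <- get_mini_sim()
  base <- synteny_decompose(sim$cms, sim$normal)
  rot <- synteny_decompose(rotate_genome(sim$cms, 7919), sim$normal)
  expect_equal(nrow(rot$blocks), nrow(base$blocks))
  expect_equal(sort(attr(rot$blocks, "summary")),
               sort(attr(base$blocks, "summary")))
  expect_equal(nrow(rot$unique_a), nrow(base$unique_a))
  expect_equal(sort(rot$unique_a$length), sort(base$unique_a$length))
})
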