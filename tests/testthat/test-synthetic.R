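test_that("generation is deterministic for a fixed seed", {
  p <- sim_params(genome_length = 30000, n_blocks = 6,
                  n_unique_regions = 4, n_genes = 10, n_trna = 4,
                  n_rrna = 1, short_repeat_lengths = c(300L, 150L, 90L),
                  large_repeat_length = 1200, n_snps_in_genes = 5,
                  n_snp_genes = 3, seed = 11)
  a <- generate_pair(p)
  b <- generate_pair(p)
  expect_identical(a$normal$seq, b$normal$seq)
  expect_identical(a$cms$seq, b$cms$seq)
  expect_identical(a$truth$blocks, b$truth$blocks)
  # a different seed changes the genomes
  p2 <- p; p2$seed <- 12
  expect_false(identical(generate_pair(p2)$cms$seq, a$cms$seq))
})

test_that("identity plan with no unique regions reproduces the normal genome", {
  p <- sim_params(genome_length = 20000, n_blocks = 5,
                  n_unique_regions = 0, n_genes = 8, n_trna = 2,
                  n_rrna = 1, n_snps_in_genes = 0,
                  permutation = 1:5, inversions = rep(FALSE, 5), seed = 3)
  sim <- generate_pair(p)
  expect_identical(sim$cms$seq, sim$normal$seq)
  expect_null(sim$truth$chimera)
})

test_that("default parameters plant the published structure counts", {
  sim <- get_sim()
  expect_equal(nrow(sim$truth$blocks), 18)
  expect_equal(nrow(sim$truth$unique_regions), 11)
  expect_equal(nrow(sim$truth$snps), 14)
  expect_equal(length(unique(sim$truth$snps$gene_id)), 7)
  short <- sim$truth$repeats[sim$truth$repeats$kind == "repeat", ]
  expect_equal(length(unique(short$label)), 9)
  expect_setequal(short$unit_length,
                  c(508L, 307L, 232L, 152L, 147L, 141L, 98L, 87L, 81L))
  large <- sim$truth$repeats[sim$truth$repeats$kind == "large", ]
  expect_equal(nrow(large), 2)
  expect_gt(large$unit_length[1], 1000)
  # at least five families have a copy within 200 bp of a junction
  expect_gte(length(unique(short$label[short$at_junction])), 5)
  # chimera: 128 + 1261 coding bases = 463 codons, no internal stop
  ch <- sim$truth$chimera
  expect_equal(ch$aa_count, 463L)
  orf_nt <- extract_subseq(sim$cms, ch$start, ch$end, ch$strand)
  expect_equal(nchar(orf_nt), 1392L)
  expect_equal(substr(orf_nt, 1, 3), "ATG")
  codons <- substring(orf_nt, seq(1, 1390, 3), seq(3, 1392, 3))
  expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
  # genome stats see the 33 planted protein-coding genes
  st <- genome_stats(sim$cms, sim$cms_annotations)
  expect_equal(st$n_cds, 33L)
})

test_that("conservation: CMS length equals normal plus planted insertions", {
  sim <- get_sim()
  expect_equal(sim$cms$length,
               sim$normal$length + sum(sim$truth$fillers$length))
})

test_that("infeasible packing fails explicitly", {
  p <- sim_params(genome_length = 30000, n_blocks = 6,
                  n_unique_regions = 2, seed = 5)
  expect_error(generate_pair(p), "infeasible packing")
})

test_that("noise-free Ct tables carry exact fold changes", {
  tb <- generate_ct_table(c(cal = 1, same = 1), noise_sd = 0,
                          replicates = 3, seed = 1)
  r <- ddct(tb, "cal")
  expect_equal(r$ddct, c(0, 0))
  expect_error(generate_ct_table(c(cal = 1, bad = -2)), "positive")
  expect_error(generate_ct_table(c(cal = 1), replicates = 0),
               "replicate")
})

test_that("simulated reads are exact circular substrings at zero error", {
  set.seed(91)
  circ <- rand_seq(5000)
  reads <- generate_long_reads(list(C = circ), c(C = 1), read_length = 800,
                               error_rate = 0, n_reads = 25, seed = 4)
  dbl <- strrep(circ, 2)
  for (i in seq_len(nrow(reads))) {
    probe <- if (reads$strand[i] == "-") revcomp(reads$seq[i]) else
      reads$seq[i]
    expect_true(grepl(probe, dbl, fixed = TRUE))
  }
  expect_equal(nrow(generate_long_reads(list(C = circ), c(C = 1),
                                        n_reads = 0, read_length = 100)), 0)
  expect_error(generate_long_reads(list(C = circ), c(C = 0.7),
                                   read_length = 100, n_reads = 5),
               "sum to 1")
  expect_error(generate_long_reads(list(C = circ), c(C = 1),
                                   read_length = 6000, n_reads = 5),
               "exceeds")
})

test_that("mixture sampling respects the requested fractions", {
  set.seed(92)
  c1 <- rand_seq(4000); c2 <- rand_seq(4000)
  reads <- generate_long_reads(list(A = c1, B = c2),
                               c(A = 0.5, B = 0.5), read_length = 500,
                               error_rate = 0, n_reads = 2000, seed = 5)
  nA <- sum(reads$circle == "A")
  expect_lte(abs(nA - 1000), 3 * sqrt(2000 * 0.25))
})

test_that("simulation files round-trip through FASTA/GFF3/JSON", {
  sim <- get_mini_sim()
  out <- withr::local_tempdir()
  paths <- save_simulation(sim, out)
  g <- read_genome_fasta(paths[["cms_fasta"]])
  expect_equal(g[[1]]$seq, sim$cms$seq)
  expect_true(g[[1]]$circular)
  ann <- read_annotations(paths[["cms_gff"]])
  expect_equal(nrow(ann), nrow(sim$cms_annotations))
  expect_true(attr(ann, "is_circular"))
  manifest <- jsonlite::read_json(paths[["manifest"]],
                                  simplifyVector = TRUE)
  expect_equal(nrow(manifest$blocks), nrow(sim$truth$blocks))
})
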