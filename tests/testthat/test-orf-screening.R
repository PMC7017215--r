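test_that("find_orfs agrees with the position-wise six-frame oracle", {
  set.seed(101)
  n_cases <- 120
  for (i in seq_len(n_cases)) {
    L <- sample(90:700, 1)
    circ <- i %% 2 == 0
    s <- rand_seq(L)
    g <- circular_seq(s, circular = circ)
    min_aa <- sample(c(5L, 8L, 12L), 1)
    got <- orf_table_key(find_orfs(g, min_aa = min_aa))
    want <- orf_oracle(g, min_aa = min_aa)
    expect_equal(got, want, info = sprintf("case %d (L=%d, circ=%s)",
                                           i, L, circ))
  }
})

test_that("find_orfs handles embedded, boundary and degenerate cases", {
  expect_equal(nrow(find_orfs(circular_seq(strrep("A", 300)), 70)), 0)

  # an 80-aa ORF embedded in stop-free, start-free context
  core <- paste0("ATG", strrep("GCT", 79), "TAA")
  ctx <- paste0(strrep("CAC", 40), "TAA", core, strrep("CAC", 40))
  o <- find_orfs(circular_seq(ctx, circular = FALSE), min_aa = 70)
  expect_equal(nrow(o), 1)
  expect_equal(o$aa_count, 80L)
  expect_equal(o$end - o$start + 1L, 3L * 81L)

  # threshold boundary: aa_count counts every sense codon including Met
  orf70 <- circular_seq(paste0("ATG", strrep("GCT", 69), "TAA"),
                        circular = FALSE)
  expect_equal(find_orfs(orf70, min_aa = 70)$aa_count, 70L)
  orf69 <- circular_seq(paste0("ATG", strrep("GCT", 68), "TAA"),
                        circular = FALSE)
  expect_equal(nrow(find_orfs(orf69, min_aa = 70)), 0)
  expect_equal(find_orfs(orf69, min_aa = 69)$aa_count, 69L)

  # a codon containing N can neither start, stop nor sit inside an ORF
  withN <- paste0("ATG", strrep("GCT", 30), "NAT", strrep("GCT", 30), "TAA")
  expect_equal(nrow(find_orfs(circular_seq(withN, circular = FALSE), 20)), 0)
})

test_that("ORF discovery is strand-symmetric and rotation-invariant", {
  set.seed(55)
  for (i in 1:12) {
    L <- sample(300:900, 1)
    s <- rand_seq(L)
    g <- circular_seq(s)
    o <- find_orfs(g, min_aa = 10)
    # strand symmetry: scanning the reverse complement mirrors coordinates
    oc <- find_orfs(circular_seq(revcomp(s)), min_aa = 10)
    mirrored <- sort(paste(L - oc$end + 1L, L - oc$start + 1L,
                           ifelse(oc$strand == "+", "-", "+"),
                           oc$aa_count))
    expect_equal(sort(paste(o$start, o$end, o$strand, o$aa_count)),
                 mirrored)
    # rotation shifts coordinates by the offset modulo length
    k <- sample(L - 1L, 1)
    orot <- find_orfs(rotate_genome(g, k), min_aa = 10)
    mp <- function(p) ((p - k - 1L) %% L) + 1L
    expect_equal(sort(paste(mp(o$start), mp(o$end), o$strand, o$aa_count)),
                 sort(paste(orot$start, orot$end, orot$strand,
                            orot$aa_count)))
  }
})

test_that("ORFs are named by amino-acid count with positional suffixes", {
  base <- tibble::tibble(strand = "+", frame = 0L, nt = "", protein = "")
  one <- dplyr::mutate(base, start = 10L, end = 1401L, aa_count = 463L)
  expect_equal(name_orfs(one)$name, "orf463a")

  two <- tibble::tibble(start = c(100L, 900L), end = c(355L, 1155L),
                        strand = "+", frame = 0L, aa_count = 84L,
                        nt = "", protein = "")
  expect_equal(name_orfs(two)$name, c("orf84a", "orf84b"))

  many <- tibble::tibble(start = seq(1L, by = 500L, length.out = 28),
                         end = seq(300L, by = 500L, length.out = 28),
                         strand = "+", frame = 0L, aa_count = 71L,
                         nt = "", protein = "")
  nm <- name_orfs(many)$name
  expect_equal(nm[26:28], c("orf71z", "orf71aa", "orf71ab"))

  empty <- find_orfs(circular_seq(strrep("A", 120)), 70)
  expect_equal(nrow(name_orfs(empty)), 0)
})

test_that("uniqueness is exact-match and strand-aware against genome B", {
  set.seed(77)
  orf_nt <- paste0("ATG", rand_seq(150), "TAA")
  ctx <- rand_seq(2000)
  orfs <- tibble::tibble(start = 1L, end = nchar(orf_nt), strand = "+",
                         frame = 0L, aa_count = 51L, nt = orf_nt,
                         protein = "")
  # copied verbatim -> not unique
  b1 <- circular_seq(paste0(ctx, orf_nt, rand_seq(500)))
  expect_false(classify_unique(orfs, b1)$unique)
  # present only as reverse complement -> still not unique
  b2 <- circular_seq(paste0(ctx, revcomp(orf_nt), rand_seq(500)))
  expect_false(classify_unique(orfs, b2)$unique)
  # present only across the origin of a circular genome B -> not unique
  half <- nchar(orf_nt) %/% 2
  b3 <- circular_seq(paste0(substr(orf_nt, half + 1, nchar(orf_nt)),
                            rand_seq(800), substr(orf_nt, 1, half)))
  expect_false(classify_unique(orfs, b3)$unique)
  # absent -> unique
  b4 <- circular_seq(rand_seq(2000))
  expect_true(classify_unique(orfs, b4)$unique)
})

test_that("chimera decomposition reports known and novel segments", {
  set.seed(31)
  lib <- tibble::tibble(
    gene_id = c("coxA", "nadB"),
    cds = c(paste0("ATG", rand_seq(597)), paste0("ATG", rand_seq(447))))

  # fully random ORF: one novel segment, not chimeric
  r <- detect_chimera(rand_seq(900), lib)
  expect_equal(nrow(r$chimeric_segments), 0)
  expect_equal(nrow(r$novel_segments), 1)
  expect_false(r$chimeric)

  # exact copy of a full CDS: match covers the ORF, no novel segment
  r2 <- detect_chimera(lib$cds[1], lib)
  expect_equal(nrow(r2$chimeric_segments), 1)
  expect_equal(r2$chimeric_segments$orf_start, 1L)
  expect_equal(r2$chimeric_segments$orf_end, nchar(lib$cds[1]))
  expect_equal(nrow(r2$novel_segments), 0)
  expect_false(r2$chimeric)

  # 128 bp of a known gene + 1261 bp novel = 463 codons; the novel start
  # is forced to mismatch the donor continuation so the boundary is sharp
  donor <- lib$cds[1]
  cont <- substr(donor, 129, 140)
  novel_head <- chartr("ACGT", "TGCA", cont)     # mismatches everywhere
  novel <- paste0(novel_head, rand_seq(1261 - nchar(novel_head)))
  orf <- paste0(substr(donor, 1, 128), novel)
  expect_equal(nchar(orf), 1389)
  r3 <- detect_chimera(orf, lib)
  expect_equal(nrow(r3$chimeric_segments), 1)
  expect_equal(r3$chimeric_segments$source_gene, "coxA")
  expect_equal(r3$chimeric_segments$orf_start, 1L)
  expect_equal(r3$chimeric_segments$orf_end, 128L)
  expect_equal(r3$novel_segments$orf_start, 129L)
  expect_equal(r3$novel_segments$orf_end, 1389L)
  expect_true(r3$chimeric)
  # segment accounting: match + novel + unassigned == ORF length
  covered <- sum(r3$chimeric_segments$orf_end -
                   r3$chimeric_segments$orf_start + 1L) +
    sum(r3$novel_segments$orf_end - r3$novel_segments$orf_start + 1L)
  expect_lte(covered, 1389L)
  expect_equal(covered, 1389L)
})

test_that("hydropathy windows find transmembrane stretches", {
  expect_equal(nrow(predict_tm(strrep("D", 25))), 0)
  tm <- predict_tm(strrep("L", 25))
  expect_equal(nrow(tm), 1)
  expect_equal(c(tm$start, tm$end), c(1, 25))
  expect_equal(nrow(predict_tm(strrep("L", 18))), 0)  # shorter than window
  expect_warning(out <- predict_tm(paste0(strrep("L", 20), "X",
                                          strrep("L", 20))),
                 "unknown residue")
  expect_gte(nrow(out), 1)
  # hydrophilic flanks do not leak into the reported segment
  prot <- paste0(strrep("D", 30), strrep("L", 25), strrep("D", 30))
  seg <- predict_tm(prot)
  expect_equal(nrow(seg), 1)
  expect_gte(seg$start, 25)
  expect_lte(seg$end, 62)
})

test_that("gene adjacency uses circular distance and strand-aware sides", {
  L <- 10000L
  orfs <- tibble::tibble(start = 1000L, end = 1500L, strand = "+",
                         frame = 0L, aa_count = 100L, nt = "", protein = "")
  ann <- tibble::tibble(gene_id = "g1", start = 1701L, end = 2000L,
                        strand = "+", feature = "CDS", product = NA)
  f <- flag_adjacency(orfs, ann, L, max_distance = 1000)
  expect_equal(f$adjacent_gene, "g1")
  expect_equal(f$adjacent_distance, 200L)
  expect_equal(f$adjacent_side, "downstream")
  # the same gene is upstream of a minus-strand ORF
  orfs$strand <- "-"
  expect_equal(flag_adjacency(orfs, ann, L)$adjacent_side, "upstream")

  # 1001 bp away at max 1000 -> not flagged
  ann2 <- tibble::tibble(gene_id = "g2", start = 2502L, end = 2700L,
                         strand = "+", feature = "CDS", product = NA)
  expect_true(is.na(flag_adjacency(orfs, ann2, L)$adjacent_gene))
  expect_equal(flag_adjacency(orfs, ann2, L,
                              max_distance = 1001)$adjacent_distance, 1001L)

  # circular wrap: ORF near the origin, gene at the far end
  orfs3 <- tibble::tibble(start = 50L, end = 400L, strand = "+",
                          frame = 0L, aa_count = 100L, nt = "", protein = "")
  ann3 <- tibble::tibble(gene_id = "g3", start = 9000L, end = L - 300L,
                         strand = "+", feature = "CDS", product = NA)
  f3 <- flag_adjacency(orfs3, ann3, L)
  expect_equal(f3$adjacent_distance, 349L)
})

test_that("candidate selection mirrors the published screen logic", {
  ids <- c("orf84h", "orf84g", "orf82g", "orf77f", "orf306a", "orf72f",
           "orf71i", "orf273a", "orf124a", "orf91a", "orf463a", "orf86b",
           "orf148a", "orf79e", "orf85f", "orf85e")
  tm_set <- c("orf84h", "orf306a", "orf273a", "orf463a")
  adj_set <- c("orf306a", "orf72f", "orf71i", "orf273a", "orf91a")
  orfs <- tibble::tibble(
    name = ids, start = seq_along(ids) * 100L,
    end = seq_along(ids) * 100L + 50L, strand = "+", frame = 0L,
    aa_count = 100L, nt = "", protein = "", unique = TRUE,
    in_unique_region = TRUE, chimeric = ids %in% adj_set,
    n_tm = as.integer(ids %in% tm_set),
    adjacent_gene = ifelse(ids %in% adj_set, "gene", NA_character_))
  cand <- select_candidates(orfs)
  expect_equal(nrow(cand), 7)
  expect_setequal(cand$name, union(tm_set, adj_set))
  # no flags -> no candidates
  none <- dplyr::mutate(orfs, n_tm = 0L, adjacent_gene = NA_character_)
  expect_equal(nrow(select_candidates(none)), 0)
  # non-unique ORFs never qualify
  shared <- dplyr::mutate(orfs, unique = FALSE)
  expect_equal(nrow(select_candidates(shared)), 0)
})
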