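test_that("haplotype sets parse, normalize and round-trip through FASTA", {
  hs <- haplotype_set(c(g1 = "ACGT", g2 = "ACGN"))
  expect_equal(n_genomes(hs), 2L)
  expect_equal(seq_length(hs), 4L)

  # lowercase and ambiguity codes are normalized
  hs2 <- haplotype_set(c(a = "acgt", b = "ACRT"))
  expect_equal(rawToChar(hs2$seq[, "a"]), "ACGT")
  expect_equal(rawToChar(hs2$seq[, "b"]), "ACNT")

  expect_error(haplotype_set(c(a = "ACGT", b = "ACGTA")), "length mismatch")
  expect_error(
    haplotype_set(c(a = "ACGT"),
                  meta = data.frame(genome_id = "x", population = "p",
                                    depth = 1, role = "query")),
    "missing metadata")

  set.seed(7)
  m <- rand_haps(5, 200)
  hs3 <- chr_to_hs(m, arm = "2L")
  fa <- tempfile(fileext = ".fasta")
  write_haplotype_set(hs3, fa)
  meta <- hs3$meta
  back <- read_haplotype_set(fa, meta, arm = "2L")
  expect_identical(back$seq, hs3$seq)
  expect_identical(back$meta$genome_id, hs3$meta$genome_id)
})

test_that("interval masks merge, apply idempotently, and only grow N", {
  iv <- interval_set("2L", c(10, 5, 20), c(15, 12, 30))
  expect_equal(iv$start, c(5, 20))   # overlapping intervals merged
  expect_equal(iv$end, c(15, 30))

  hs <- haplotype_set(c(a = "ACGT", b = "ACGT"))
  masked <- apply_mask(hs, interval_set("x", 1, 3))
  expect_equal(rawToChar(masked$seq[, "a"]), "ANNT")
  expect_equal(rawToChar(masked$seq[, "b"]), "ANNT")

  # genome-scoped mask
  m1 <- apply_mask(hs, interval_set("x", 0, 2, genome = "b"))
  expect_equal(rawToChar(m1$seq[, "a"]), "ACGT")
  expect_equal(rawToChar(m1$seq[, "b"]), "NNGT")

  # empty mask = identity; reapplication = idempotent
  expect_identical(apply_mask(hs, interval_set("x")), hs)
  expect_identical(apply_mask(masked, interval_set("x", 1, 3)), masked)
  expect_error(apply_mask(hs, interval_set("x", 2, 9)), "out of range")

  # monotone: N positions only grow under any mask sequence
  set.seed(1)
  hs4 <- chr_to_hs(rand_haps(3, 100))
  nN <- sum(hs4$seq == charToRaw("N"))
  for (k in 1:5) {
    s <- sample(0:90, 1)
    hs4 <- apply_mask(hs4, interval_set("arm", s, s + sample(1:10, 1)))
    nN2 <- sum(hs4$seq == charToRaw("N"))
    expect_gte(nN2, nN)
    nN <- nN2
  }
})

test_that("genetic map interpolation is piecewise-linear, adjusted, additive", {
  # uniform 2 cM/Mb pre-adjustment autosomal map: 1 Mb -> 1 cM after x1/2
  map <- recombination_map("2R", pos = c(0, 2e6), rate = c(2, 2))
  expect_equal(cm_length(map, 0, 1e6), 1.0)
  expect_equal(cm_length(map, 5e5, 5e5), 0.0)

  # X arm gets the 2/3 factor
  mapx <- recombination_map("X", pos = c(0, 1e6), rate = c(3, 3))
  expect_equal(cm_length(mapx, 0, 1e6), 2.0)

  # two-segment map with rates 1 and 3 cM/Mb: span straddling the knot
  # hand integration: 0.4 Mb at 1 + 0.5 Mb at 3 = 1.9 cM, halved = 0.95
  map2 <- recombination_map("3L", pos = c(0, 1e6, 2e6), rate = c(1, 3, 3))
  expect_equal(cm_length(map2, 6e5, 15e5), 0.5 * (0.4 * 1 + 0.5 * 3))

  # additivity
  set.seed(2)
  for (i in 1:10) {
    ab <- sort(runif(3, 0, 2e6))
    expect_equal(cm_length(map2, ab[1], ab[3]),
                 cm_length(map2, ab[1], ab[2]) +
                   cm_length(map2, ab[2], ab[3]),
                 tolerance = 1e-9)
  }
  expect_error(cm_length(map2, -5, 100), "outside map support")

  # TSV reader applies adjustment at load
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(arm = "2L", pos = c(0, 1e6), cM_per_Mb = c(2, 2)),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(cm_length(read_recombination_map(tsv, "2L"), 0, 1e6), 1.0)
})

test_that("short-intron site extraction respects length, offsets and strand", {
  ann <- data.frame(
    seqid = "2L", type = "intron",
    start = c(1000, 5000, 9000), end = c(1064, 5065, 9064),
    strand = c("+", "+", "-"))
  iv <- extract_short_intron_sites(ann, "2L")
  # 65-bp intron at 1000 (+): bp 8..30 -> 1007..1029 (1-based)
  expect_equal(iv$start[1], 1007 - 1)
  expect_equal(iv$end[1], 1029)
  # 66-bp intron excluded
  expect_false(any(iv$start > 4000 & iv$start < 6000))
  # minus strand counts from the 3' reference end
  expect_equal(iv$start[2], 9064 - 30 + 1 - 1)
  expect_equal(iv$end[2], 9064 - 8 + 1)
  expect_true(all(iv$end - iv$start == 23))

  # planted introns in a GFF3 file come back exactly
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "2L\tx\tintron\t100\t160\t.\t+\t.\tID=i1;Parent=gene1",
               "2L\tx\tintron\t300\t380\t.\t+\t.\tID=i2;Parent=gene2"),
             gff)
  iv2 <- extract_short_intron_sites(gff, "2L")
  expect_equal(length(iv2$start), 1L)       # only the 61-bp intron
  expect_equal(iv2$start, 100 + 7 - 1)
  expect_equal(iv2$end, 100 + 29)
})

test_that("mid-chromosomal regions and map-derived analysis regions", {
  regs <- mid_chromosomal_regions()
  expect_named(regs, c("X", "2L", "2R", "3L", "3R"))
  expect_equal(regs$X$start, 2222390)
  expect_equal(regs$X$end, 20054556)

  # map with low-recombination ends: largest supra-threshold run returned
  map <- recombination_map("2L",
                           pos = c(0, 2e6, 10e6, 12e6),
                           rate = c(0.5, 3, 0.5, 0.5))
  ar <- analysis_region_from_map(map)
  expect_equal(ar$start, 2e6)
  expect_equal(ar$end, 10e6)
})
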