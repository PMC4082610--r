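units_row <- function(id, strand, start, end, chrom = "chrI",
                      class = NA_character_) {
  tibble::tibble(unit_id = id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 peak_position = as.integer(start), mean_depth = 1,
                 class = class)
}

test_that("BPKM follows its closed form and is length-additive", {
  # B = 5000 over a 500-base unit in a 1e7-base library -> 1000 BPKM
  d <- rep(0, 1000); d[101:600] <- 10   # B = 5000
  cov <- cov1(d)
  cov$total_mapped_bases <- 1e7
  u <- units_row("u1", "+", 100, 600)
  expect_equal(bpkm(cov, u), 5000 / ((500 / 1000) * (1e7 / 1e6)))
  expect_equal(bpkm(cov, u), 1000)

  # doubling the library total halves BPKM
  cov2 <- cov
  cov2$total_mapped_bases <- 2e7
  expect_equal(bpkm(cov2, u), 500)

  # zero coverage -> 0
  expect_equal(bpkm(cov, units_row("z", "+", 700, 800)), 0)

  # splitting a unit: length-weighted mean of the halves equals the whole
  set.seed(11)
  d <- c(rep(0, 10), sample(0:20, 80, TRUE), rep(0, 10))
  cov <- cov1(d); cov$total_mapped_bases <- 1e6
  whole <- bpkm(cov, units_row("w", "+", 10, 90))
  parts <- bpkm(cov, units_row(c("a", "b"), "+", c(10, 40), c(40, 90)))
  expect_equal((30 * parts[1] + 50 * parts[2]) / 80, whole)

  # degenerate inputs are fatal
  expect_error(bpkm(cov, units_row("e", "+", 5, 5)), "zero-length")
  cov$total_mapped_bases <- 0
  expect_error(bpkm(cov, u), "total_mapped_bases")
})

test_that("units classify by same-orientation ORF overlap", {
  ann <- tibble::tibble(
    orf_id = c("V1", "D1"), chrom = "chrI", strand = "+",
    start = c(50L, 2000L), end = c(600L, 2500L),
    status = c("verified", "other"))
  u <- dplyr::bind_rows(
    units_row("a", "+", 100, 500),   # same-orientation verified overlap
    units_row("b", "-", 100, 500),   # opposite strand only -> ncRNA
    units_row("c", "+", 900, 1200),  # no overlap at all -> ncRNA
    units_row("d", "+", 2100, 2300)) # overlaps only a dubious ORF -> other
  got <- classify_units(u, ann)
  expect_equal(got$class, c("ORF-T", "ncRNA", "ncRNA", "other"))
})

test_that("sense-antisense pairing requires opposite strands and >= 1 bp", {
  u <- dplyr::bind_rows(
    units_row("orf1", "+", 0, 1000, class = "ORF-T"),
    units_row("nc1", "-", 999, 1200, class = "ncRNA"),    # 1-bp overlap
    units_row("orf2", "+", 1500, 2500, class = "ORF-T"),
    units_row("nc_same", "+", 1600, 1700, class = "ncRNA"), # same strand
    units_row("orf3", "+", 3000, 4000, class = "ORF-T"),
    units_row("orf4", "+", 4100, 5000, class = "ORF-T"),
    units_row("nc2", "-", 3800, 4500, class = "ncRNA"))   # spans two ORF-Ts
  pairs <- pair_sense_antisense(u)
  p1 <- pairs[pairs$antisense_id == "nc1", ]
  expect_equal(nrow(p1), 1)
  expect_equal(p1$overlap_len, 1L)
  expect_equal(p1$sense_len, 1000L)
  expect_false("nc_same" %in% pairs$antisense_id)
  p2 <- pairs[pairs$antisense_id == "nc2", ]
  expect_equal(sort(p2$sense_id), c("orf3", "orf4"))
  # primary pair is the larger overlap: orf4 (400 bp) over orf3 (200 bp)
  expect_equal(p2$sense_id[p2$primary], "orf4")
})

test_that("expressed-in-all filter keeps fully expressed pairs and is
          idempotent", {
  u <- dplyr::bind_rows(
    units_row("s1", "+", 0, 100, class = "ORF-T"),
    units_row("a1", "-", 50, 150, class = "ncRNA"),
    units_row("s2", "+", 200, 300, class = "ORF-T"),
    units_row("a2", "-", 250, 350, class = "ncRNA"))
  pairs <- pair_sense_antisense(u)
  expr <- tibble::tibble(unit_id = c("s1", "a1", "s2", "a2"),
                         Sc_ML = c(1, 2, 3, 4), Sc_ES = c(1, 2, 3, 0),
                         Sc_HS = c(5, 6, 7, 8))
  kept <- filter_expressed_all(pairs, expr)
  expect_equal(kept$sense_id, "s1")      # a2 has BPKM 0 in one sample
  expect_identical(filter_expressed_all(kept, expr), kept)
  expect_equal(nrow(filter_expressed_all(pairs[0, ], expr)), 0)
  expect_error(filter_expressed_all(pairs, expr["unit_id"]), "sample")
})

test_that("intron summary counts paired intron ORFs and intronic antisense
          starts", {
  ann <- tibble::tibble(orf_id = c("O1", "O2", "O3"), chrom = "chrI",
                        strand = "+", start = c(0L, 2000L, 4000L),
                        end = c(1000L, 3000L, 5000L), status = "verified")
  u <- dplyr::bind_rows(
    units_row("t1", "+", 0, 1000, class = "ORF-T"),
    units_row("n1", "-", 800, 1100, class = "ncRNA"),   # 5' end at 1099
    units_row("t2", "+", 2000, 3000, class = "ORF-T"),
    units_row("n2", "-", 2100, 2400, class = "ncRNA"),  # 5' end at 2399
    units_row("t3", "+", 4000, 5000, class = "ORF-T"))
  pairs <- pair_sense_antisense(u)
  introns <- tibble::tibble(orf_id = c("O1", "O2", "O3"), chrom = "chrI",
                            start = c(100L, 2300L, 4100L),
                            end = c(200L, 2500L, 4200L))
  s <- intron_overlap_summary(pairs, u, ann, introns)
  expect_equal(s$n_intron_orfs, 3)
  expect_equal(s$n_intron_orfs_paired, 2)       # O1 and O2 form pairs
  expect_equal(s$n_antisense_from_intron, 1)    # n2 starts inside O2's intron
  expect_equal(s$genome_pair_freq, 2 / 3)
  expect_error(intron_overlap_summary(pairs, u, ann, introns[0, ]), "intron")
})
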