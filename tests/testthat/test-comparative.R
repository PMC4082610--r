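test_that("expression variation is the absolute log2 difference", {
  expect_equal(expression_variation(3, 3), 0)
  expect_equal(expression_variation(4, 1), 2)
  expect_equal(expression_variation(1, 4), 2)   # symmetric
  expect_equal(expression_variation(c(2, 8), c(1, 2)), c(1, 2))
  expect_error(expression_variation(0, 1), "positive")
})

test_that("conservation score matches its closed form and is symmetric", {
  # equal fractions -> 1
  expect_equal(conservation_score(1000, 500, 2000, 1000), 1)
  # C = 0.2 vs 0.6 -> min/mean = 0.2/0.4 = 0.5
  expect_equal(conservation_score(1000, 200, 1000, 600), 0.5)
  # overlap absent in one species -> 0
  expect_equal(conservation_score(1000, 300, 1000, 0), 0)
  expect_equal(conservation_score(10, 0, 10, 0), 0)

  set.seed(31)
  L1 <- sample(100:1000, 50); L2 <- sample(100:1000, 50)
  O1 <- floor(stats::runif(50) * L1); O2 <- floor(stats::runif(50) * L2)
  s12 <- conservation_score(L1, O1, L2, O2)
  s21 <- conservation_score(L2, O2, L1, O1)
  expect_equal(s12, s21)
  expect_true(all(s12 >= 0 & s12 <= 1))
  expect_true(all((s12 == 1) == (O1 / L1 == O2 / L2 & O1 > 0)))
  expect_error(conservation_score(100, 200, 100, 50), "overlap")
})

test_that("homolog join keeps per-species geometry and O = 0 for unpaired", {
  u1 <- tibble::tibble(unit_id = c("s1", "s2"), chrom = "chrI",
                       strand = "+", start = c(0L, 500L), end = c(400L, 900L),
                       class = "ORF-T")
  u2 <- u1
  pairs1 <- tibble::tibble(sense_id = c("s1", "s2"),
                           antisense_id = c("a1", "a2"),
                           overlap_len = c(100L, 200L),
                           sense_len = c(400L, 400L))
  pairs2 <- pairs1[1, ]
  map <- tibble::tibble(orf_id_1 = c("s1", "s2"), orf_id_2 = c("s1", "s2"))
  j <- join_homologs(pairs1, pairs2, u1, u2, map)
  expect_equal(nrow(j), 2)
  expect_equal(j$O_2[j$sense_id_1 == "s2"], 0L)
  expect_equal(j$L_2[j$sense_id_1 == "s2"], 400L)  # length from the unit table
  # empty map -> empty join; duplicated ids are fatal
  expect_equal(nrow(join_homologs(pairs1, pairs2, u1, u2, map[0, ])), 0)
  expect_error(join_homologs(pairs1, pairs2, u1, u2,
                             map[c(1, 1), ]), "one-to-one")
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(13)
  e <- tibble::tibble(a = stats::runif(20, 1, 100))
  e$b <- e$a                     # duplicated column
  e$c <- 1000 / e$a              # negation in log space
  m <- correlation_matrix(e)
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_error(correlation_matrix(e[1:2, ]), "3 rows")
})

test_that("inverse classification applies the fold rule in both modes", {
  fc <- tibble::tibble(
    pair_id = c("p1", "p2", "p3", "p4"), species = "Sc", condition = "ES",
    sense_fc = c(0.5, 0.8, 1, 2), antisense_fc = c(2, 2, 1, 0.5))
  got <- classify_inverse(fc, fold_threshold = 1.5)
  expect_equal(got$category,
               c("repressed_sense_induced_antisense",
                 "repressed_sense_induced_antisense", "none",
                 "induced_sense_repressed_antisense"))
  # 0.8 > 1/1.5: not significant under the both-members rule
  expect_equal(got$significant, c(TRUE, FALSE, FALSE, TRUE))
  either <- classify_inverse(fc, fold_threshold = 1.5, mode = "either")
  expect_equal(either$significant, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(classify_inverse(fc, fold_threshold = 0.5), ">= 1")
})

test_that("classification equals brute-force enumeration and is monotone in
          the threshold", {
  set.seed(77)
  n <- 100
  fc <- tidyr::expand_grid(pair_id = sprintf("p%03d", 1:n),
                           species = c("Sc", "Sp"),
                           condition = c("ES", "HS"))
  fc$sense_fc <- 2^stats::rnorm(nrow(fc))
  fc$antisense_fc <- 2^stats::rnorm(nrow(fc))
  for (thr in c(1, 1.5)) {
    got <- classify_inverse(fc, fold_threshold = thr)
    for (i in seq_len(nrow(fc))) {
      s <- fc$sense_fc[i]; a <- fc$antisense_fc[i]
      want_cat <- if (s < 1 && a > 1) "repressed_sense_induced_antisense"
      else if (s > 1 && a < 1) "induced_sense_repressed_antisense"
      else "none"
      want_sig <- (want_cat == "repressed_sense_induced_antisense" &&
                     s <= 1 / thr && a >= thr) ||
        (want_cat == "induced_sense_repressed_antisense" &&
           a <= 1 / thr && s >= thr)
      expect_identical(got$category[i], want_cat)
      expect_identical(got$significant[i], want_sig)
    }
  }
  strict <- classify_inverse(fc, fold_threshold = 1.5)
  loose <- classify_inverse(fc, fold_threshold = 1)
  expect_true(all(loose$significant[strict$significant]))
})

test_that("inverse count table separates conserved from species-specific
          pairs", {
  fc <- tibble::tibble(
    pair_id = c("c1", "c1", "sc1", "mix", "mix"),
    species = c("Sc", "Sp", "Sc", "Sc", "Sp"),
    condition = c("ES", "ES", "HS", "ES", "HS"),
    sense_fc = 0.5, antisense_fc = 2)
  counts <- inverse_count_table(classify_inverse(fc))
  pick <- function(pat, cp) counts$n[counts$pattern == pat &
                                       counts$condition_pattern == cp &
                                       counts$category ==
                                       "repressed_sense_induced_antisense"]
  expect_equal(pick("both", "ES"), 1)   # c1: conserved in ES
  expect_equal(pick("Sc", "HS"), 1)     # sc1: Sc only
  # mix is inverse in Sc-ES and Sp-HS: no shared condition, counted per species
  expect_equal(pick("Sc", "ES"), 1)
  expect_equal(pick("Sp", "HS"), 1)
})

test_that("Fisher enrichment handles canonical tables", {
  # no association
  flat <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(enrichment_test(flat)$p_value, 1)
  # fully separated 5/0 vs 0/5: p = 2/252
  sep <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(enrichment_test(sep)$p_value, 2 / 252)
  expect_error(enrichment_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  td <- tidy(enrichment_test(flat))
  expect_equal(td$p_value, 1)
  expect_equal(td$stringent_conserved, 10)
})

test_that("conservation enrichment builds the stringent-vs-background table", {
  set.seed(3)
  n <- 40
  scored <- tibble::tibble(pair_id = sprintf("p%02d", 1:n),
                           S = rep(c(0.9, 0.2), each = n / 2))
  # stringent pairs mostly conserved in ES, background mostly Sc-only
  fc <- tidyr::expand_grid(pair_id = scored$pair_id, species = c("Sc", "Sp"),
                           condition = "ES")
  fc$sense_fc <- 0.5; fc$antisense_fc <- 2
  one_sided <- fc$pair_id %in% sprintf("p%02d", 21:38) & fc$species == "Sp"
  fc$antisense_fc[one_sided] <- 1 / 2   # kills the inversion in Sp
  rec <- classify_inverse(fc)
  enr <- conservation_enrichment(scored, rec, "ES")
  expect_equal(unname(enr$table["stringent", ]), c(20, 0))
  expect_equal(unname(enr$table["background", ]), c(2, 18))
  expect_lt(enr$p_value, 0.001)
})

test_that("proportion test is one-sided with continuity correction", {
  expect_gte(proportion_test(10, 100, 10, 100)$p_value, 0.5)
  expect_lt(proportion_test(10, 10, 0, 10)$p_value, 0.01)
  # oracle: exact enumeration of the null for the extreme 10/10 vs 0/10 case
  # (hypergeometric tail of the pooled table) bounds the p-value sensibly
  expect_equal(proportion_test(55, 173, 22, 96)$p_value,
               stats::prop.test(c(55, 22), c(173, 96),
                                alternative = "greater")$p.value)
  expect_error(proportion_test(5, 0, 1, 10), "n > 0")
})

test_that("distribution shift test is a one-sided rank-sum on logs", {
  x <- c(1, 2, 3, 4, 5); y <- c(6, 7, 8, 9, 10)
  # fully separated samples, testing the larger one: exact p = 1/252
  expect_equal(distribution_shift_test(y, x)$p_value, 1 / 252)
  expect_gte(distribution_shift_test(x, x + 1e-9)$p_value, 0.4)
  # invariant under a common monotone transform (ranks only)
  expect_equal(distribution_shift_test(y^3, x^3)$p_value,
               distribution_shift_test(y, x)$p_value)
  expect_error(distribution_shift_test(rep(2, 5), rep(2, 5)), "tied")
  expect_error(distribution_shift_test(numeric(0), x), "non-empty")
})
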