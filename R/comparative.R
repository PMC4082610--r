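#' Join the two species' sense-antisense pairs through a homology map
#'
#' Produces one row per homologous ORF-T pair that carries an antisense
#' overlap in at least one species. Per-species sense transcript length `L`
#' and sense-antisense overlap length `O` are retained; a species without an
#' antisense partner contributes `O = 0`. When a sense unit pairs with
#' several ncRNAs, its primary (maximal-overlap) pair provides the geometry.
#'
#' @param pairs_1,pairs_2 Pair tibbles from [pair_sense_antisense()] for the
#'   two species.
#' @param units_1,units_2 Classified unit tibbles (needed for sense lengths
#'   when a species has no pair).
#' @param homologs One-to-one map tibble with columns `orf_id_1`, `orf_id_2`
#'   whose ids refer to sense unit ids in the respective species.
#' @return Tibble: `sense_id_1`, `sense_id_2`, `antisense_id_1`,
#'   `antisense_id_2`, `L_1`, `O_1`, `L_2`, `O_2`.
#' @export
join_homologs <- function(pairs_1, pairs_2, units_1, units_2, homologs) {
  if (anyDuplicated(homologs$orf_id_1) || anyDuplicated(homologs$orf_id_2)) {
    rlang::abort("homology map is not one-to-one (duplicated id)")
  }
  best <- function(pairs) {
    if (nrow(pairs) == 0) {
      return(tibble::tibble(sense_id = character(),
                            antisense_id = character(),
                            O = integer(), L = integer()))
    }
    pairs |>
      dplyr::group_by(.data$sense_id) |>
      dplyr::slice_max(.data$overlap_len, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::transmute(sense_id = .data$sense_id,
                       antisense_id = .data$antisense_id,
                       O = .data$overlap_len, L = .data$sense_len)
  }
  b1 <- best(pairs_1); b2 <- best(pairs_2)
  len_of <- function(units, ids) {
    units$end[match(ids, units$unit_id)] - units$start[match(ids, units$unit_id)]
  }
  out <- homologs |>
    dplyr::rename(sense_id_1 = "orf_id_1", sense_id_2 = "orf_id_2") |>
    dplyr::left_join(dplyr::rename(b1, sense_id_1 = "sense_id",
                                   antisense_id_1 = "antisense_id",
                                   O_1 = "O", L_1 = "L"), by = "sense_id_1") |>
    dplyr::left_join(dplyr::rename(b2, sense_id_2 = "sense_id",
                                   antisense_id_2 = "antisense_id",
                                   O_2 = "O", L_2 = "L"), by = "sense_id_2") |>
    dplyr::filter(!is.na(.data$antisense_id_1) | !is.na(.data$antisense_id_2))
  out$O_1[is.na(out$O_1)] <- 0L
  out$O_2[is.na(out$O_2)] <- 0L
  out$L_1 <- ifelse(is.na(out$L_1), len_of(units_1, out$sense_id_1), out$L_1)
  out$L_2 <- ifelse(is.na(out$L_2), len_of(units_2, out$sense_id_2), out$L_2)
  out
}

#' Cross-species expression variation
#'
#' Absolute log2 expression difference between the species:
#' `|log2(e_1) - log2(e_2)|`. Inputs must be positive (the expressed-in-all
#' filter guarantees this in the pipeline).
#'
#' @param e_1,e_2 Positive BPKM values (vectorized).
#' @return Non-negative numeric vector.
#' @export
expression_variation <- function(e_1, e_2) {
  if (any(e_1 <= 0) || any(e_2 <= 0)) {
    rlang::abort("expression values must be positive")
  }
  abs(log2(e_1) - log2(e_2))
}

#' Sample-by-sample correlation matrix of log expression
#'
#' Pearson correlation of `log10(BPKM + pseudocount)` between every pair of
#' sample columns.
#'
#' @param expr Tibble whose non-`unit_id`/non-id columns are the sample BPKM
#'   columns, or a plain tibble of sample columns.
#' @param pseudocount Added before the log (default 0; inputs are normally
#'   pre-filtered positive).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, pseudocount = 0) {
  m <- as.matrix(expr[vapply(expr, is.numeric, TRUE)])
  if (nrow(m) < 3) rlang::abort("need at least 3 rows to correlate")
  stats::cor(log10(m + pseudocount))
}

#' Conservation score of sense-antisense overlap geometry
#'
#' With `C_i = O_i / L_i` the fraction of the sense transcript overlapped by
#' its antisense partner in species `i`, the conservation score is
#' `S = min(C_1, C_2) / mean(C_1, C_2)` (0 when both fractions are 0).
#' `S = 1` when the overlap fractions agree exactly, `S = 0` when the overlap
#' is absent in one species; sequence identity plays no role.
#'
#' @param L_1,O_1,L_2,O_2 Sense lengths and overlap lengths per species
#'   (vectorized; `0 <= O_i <= L_i`, `L_i > 0`).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
conservation_score <- function(L_1, O_1, L_2, O_2) {
  if (any(L_1 <= 0) || any(L_2 <= 0)) rlang::abort("sense length must be positive")
  if (any(O_1 > L_1) || any(O_2 > L_2) || any(O_1 < 0) || any(O_2 < 0)) {
    rlang::abort("overlap length must lie in [0, sense length]")
  }
  c1 <- O_1 / L_1; c2 <- O_2 / L_2
  m <- (c1 + c2) / 2
  ifelse(m > 0, pmin(c1, c2) / m, 0)
}

#' Attach overlap fractions and conservation score to a joined pair table
#'
#' @param joined Tibble from [join_homologs()].
#' @return `joined` with columns `C_1`, `C_2` and `S` added.
#' @export
conservation_records <- function(joined) {
  joined$C_1 <- joined$O_1 / joined$L_1
  joined$C_2 <- joined$O_2 / joined$L_2
  joined$S <- conservation_score(joined$L_1, joined$O_1,
                                 joined$L_2, joined$O_2)
  joined
}

#' Classify inverse sense/antisense expression changes
#'
#' For each pair, species and stress condition, fold changes relative to
#' mid-log are `sense_fc = BPKM(condition)/BPKM(ML)` and likewise for the
#' antisense member. The direction category uses the loose rule
#' (`sense_fc < 1` and `antisense_fc > 1` is *repressed sense / induced
#' antisense*; the mirror is *induced sense / repressed antisense*); the
#' `significant` flag additionally applies the fold threshold (default 1.5).
#' With `mode = "both"` both members must pass the threshold
#' (`sense_fc <= 1/fold` and `antisense_fc >= fold` or the mirror);
#' `mode = "either"` requires only one member to pass.
#'
#' @param fc Tibble with one row per pair x species x condition and columns
#'   `pair_id`, `species`, `condition`, `sense_fc`, `antisense_fc` (all fold
#'   changes positive).
#' @param fold_threshold Fold-change threshold (>= 1).
#' @param mode `"both"` (default) or `"either"`.
#' @return `fc` with `category` and `significant` columns added.
#' @export
classify_inverse <- function(fc, fold_threshold = 1.5,
                             mode = c("both", "either")) {
  mode <- rlang::arg_match(mode)
  if (!is.numeric(fold_threshold) || fold_threshold < 1) {
    rlang::abort("fold_threshold must be a number >= 1")
  }
  if (any(fc$sense_fc <= 0) || any(fc$antisense_fc <= 0)) {
    rlang::abort("fold changes must be positive (filter expression first)")
  }
  s <- fc$sense_fc; a <- fc$antisense_fc
  category <- dplyr::case_when(
    s < 1 & a > 1 ~ "repressed_sense_induced_antisense",
    s > 1 & a < 1 ~ "induced_sense_repressed_antisense",
    .default = "none")
  lo <- 1 / fold_threshold; hi <- fold_threshold
  pass <- function(down, up) {
    if (mode == "both") down <= lo & up >= hi else down <= lo | up >= hi
  }
  significant <- dplyr::case_when(
    category == "repressed_sense_induced_antisense" ~ pass(s, a),
    category == "induced_sense_repressed_antisense" ~ pass(a, s),
    .default = FALSE)
  fc$category <- category
  fc$significant <- significant
  fc
}

#' Tally inverse pairs by species pattern and condition pattern
#'
#' For each direction category, counts pairs whose significant inverse
#' change is conserved (same condition, both species) versus present in one
#' species without any conserved condition, broken down by the conditions
#' involved (first stress condition only / second only / both).
#'
#' @param records Output of [classify_inverse()].
#' @return Tibble with columns `category`, `pattern` (a species name or
#'   `"both"`), `condition_pattern`, `n`.
#' @export
inverse_count_table <- function(records) {
  sp <- sort(unique(records$species))
  conds <- sort(unique(records$condition))
  sig <- records[records$significant, ]
  rows <- list()
  for (cat in c("repressed_sense_induced_antisense",
                "induced_sense_repressed_antisense")) {
    x <- sig[sig$category == cat, ]
    per_pair <- split(x, x$pair_id)
    pat <- lapply(per_pair, function(g) {
      by_sp <- lapply(sp, function(s) sort(unique(g$condition[g$species == s])))
      names(by_sp) <- sp
      shared <- Reduce(intersect, by_sp)
      if (length(shared) > 0) {
        list(pattern = "both", conds = shared)
      } else {
        # species-specific: one row per species that shows the inversion
        lapply(sp[vapply(by_sp, length, 1L) > 0], function(s) {
          list(pattern = s, conds = by_sp[[s]])
        })
      }
    })
    flat <- list()
    for (p in pat) {
      if (!is.null(p$pattern)) flat[[length(flat) + 1L]] <- p
      else for (q in p) flat[[length(flat) + 1L]] <- q
    }
    cond_pattern <- function(cs) {
      if (length(cs) == length(conds) && length(conds) > 1) "both"
      else paste(cs, collapse = "+")
    }
    for (pattern in c(sp, "both")) {
      sel <- flat[vapply(flat, function(p) p$pattern == pattern, TRUE)]
      cps <- vapply(sel, function(p) cond_pattern(p$conds), "")
      for (cp in c(conds, "both")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          category = cat, pattern = pattern, condition_pattern = cp,
          n = sum(cps == cp))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Enrichment of conserved inverse pairs: stringent vs background geometry
#'
#' Among pairs showing a significant inverse change in the given condition in
#' at least one species, builds the 2x2 table (conservation score above
#' `stringent_cut` vs below `background_cut`) x (inverse change conserved in
#' both species vs present in only one) and applies Fisher's exact test.
#'
#' @param scored Tibble with columns `pair_id` and `S` (see
#'   [conservation_records()]).
#' @param records Output of [classify_inverse()].
#' @param condition Which stress condition to test.
#' @param stringent_cut,background_cut Conservation-score cut-offs
#'   (defaults 0.8 and 0.5).
#' @param alternative Passed to [stats::fisher.test()] (default two-sided).
#' @return An `ascons_enrichment` object: list with `table` (2x2 matrix),
#'   `p_value` and `condition`.
#' @export
conservation_enrichment <- function(scored, records, condition,
                                    stringent_cut = 0.8, background_cut = 0.5,
                                    alternative = "two.sided") {
  sp <- sort(unique(records$species))
  rc <- records[records$condition == condition & records$significant, ]
  status <- rc |>
    dplyr::summarise(
      conserved = length(unique(.data$species)) == length(sp) &&
        length(unique(.data$category)) == 1L,
      .by = "pair_id")
  status$S <- scored$S[match(status$pair_id, scored$pair_id)]
  stringent <- status[!is.na(status$S) & status$S > stringent_cut, ]
  background <- status[!is.na(status$S) & status$S < background_cut, ]
  tab <- matrix(c(sum(stringent$conserved), sum(!stringent$conserved),
                  sum(background$conserved), sum(!background$conserved)),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("stringent", "background"),
                                inverse = c("conserved", "not_conserved")))
  enrichment_test(tab, alternative = alternative, condition = condition)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' @param table 2x2 non-negative integer matrix (rows: stringent vs
#'   background conservation set; columns: conserved vs not-conserved
#'   inverse expression).
#' @param alternative Passed to [stats::fisher.test()].
#' @param condition Optional label carried into the result.
#' @return An `ascons_enrichment` object (see [conservation_enrichment()]).
#' @export
enrichment_test <- function(table, alternative = "two.sided",
                            condition = NA_character_) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    rlang::abort("need a 2x2 table of non-negative counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    rlang::abort("empty margin in contingency table")
  }
  ft <- stats::fisher.test(table, alternative = alternative)
  structure(list(table = table, p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate), condition = condition,
                 alternative = alternative),
            class = "ascons_enrichment")
}

#' @export
print.ascons_enrichment <- function(x, ...) {
  cat("<ascons_enrichment>",
      if (!is.na(x$condition)) paste0(" [", x$condition, "]"), "\n", sep = "")
  print(x$table)
  cat(sprintf("Fisher's exact test (%s): p = %.4g\n", x$alternative,
              x$p_value))
  invisible(x)
}

#' @method tidy ascons_enrichment
#' @export
tidy.ascons_enrichment <- function(x, ...) {
  tibble::tibble(condition = x$condition,
                 stringent_conserved = x$table[1, 1],
                 stringent_not_conserved = x$table[1, 2],
                 background_conserved = x$table[2, 1],
                 background_not_conserved = x$table[2, 2],
                 odds_ratio = x$odds_ratio,
                 p_value = x$p_value)
}

#' One-sided two-sample proportion test
#'
#' Normal-approximation two-sample proportion test with continuity
#' correction; the default alternative is that the first proportion exceeds
#' the second.
#'
#' @param k_1,n_1,k_2,n_2 Successes and totals of the two samples.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return One-row tibble: `estimate_1`, `estimate_2`, `statistic`,
#'   `p_value`.
#' @export
proportion_test <- function(k_1, n_1, k_2, n_2, alternative = "greater") {
  if (n_1 <= 0 || n_2 <= 0 || k_1 < 0 || k_2 < 0 || k_1 > n_1 || k_2 > n_2) {
    rlang::abort("need 0 <= k <= n with n > 0 in both samples")
  }
  pt <- stats::prop.test(c(k_1, k_2), c(n_1, n_2), alternative = alternative,
                         correct = TRUE)
  tibble::tibble(estimate_1 = k_1 / n_1, estimate_2 = k_2 / n_2,
                 statistic = unname(pt$statistic), p_value = pt$p.value)
}

#' Distribution shift of expression under stress
#'
#' One-sided two-sample Wilcoxon rank-sum test on log BPKM: is the stress
#' condition's distribution right-shifted relative to mid-log?
#'
#' @param bpkm_condition,bpkm_ml Positive BPKM samples.
#' @return One-row tibble: `statistic`, `p_value`.
#' @export
distribution_shift_test <- function(bpkm_condition, bpkm_ml) {
  if (length(bpkm_condition) == 0 || length(bpkm_ml) == 0) {
    rlang::abort("both samples must be non-empty")
  }
  if (any(bpkm_condition <= 0) || any(bpkm_ml <= 0)) {
    rlang::abort("BPKM samples must be positive")
  }
  if (length(unique(c(bpkm_condition, bpkm_ml))) < 2) {
    rlang::abort("degenerate input: all values tied")
  }
  wt <- stats::wilcox.test(log(bpkm_condition), log(bpkm_ml),
                           alternative = "greater")
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}
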