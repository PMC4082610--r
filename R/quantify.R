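#' BPKM: bases per kilobase of gene model per million mapped bases
#'
#' For a unit of length `L` with summed same-strand depth `B` over its
#' interval, in a library with `T` total mapped bases,
#' `BPKM = B / ((L / 1000) * (T / 1e6))`.
#'
#' @param cov A [stranded_coverage()] object.
#' @param units Tibble with columns `chrom`, `strand`, `start`, `end`.
#' @return Numeric vector of BPKM values, one per unit row.
#' @export
bpkm <- function(cov, units) {
  stopifnot(inherits(cov, "stranded_coverage"))
  if (cov$total_mapped_bases <= 0) {
    rlang::abort("total_mapped_bases is 0: cannot normalize")
  }
  if (any(units$end <= units$start)) rlang::abort("zero-length unit")
  b <- vapply(seq_len(nrow(units)), function(i) {
    v <- cov$depth[[units$chrom[i]]][[units$strand[i]]]
    sum(v[(units$start[i] + 1L):units$end[i]])
  }, 0)
  len <- units$end - units$start
  b / ((len / 1000) * (cov$total_mapped_bases / 1e6))
}

#' Per-sample BPKM expression table
#'
#' @param units Tibble of transcript units.
#' @param coverages Named list of [stranded_coverage()] objects, one per
#'   sample (names become column names).
#' @return Tibble: `unit_id` plus one BPKM column per sample. A unit absent
#'   from a sample simply has BPKM 0.
#' @export
expression_table <- function(units, coverages) {
  out <- tibble::tibble(unit_id = units$unit_id)
  for (nm in names(coverages)) out[[nm]] <- bpkm(coverages[[nm]], units)
  out
}

#' Classify transcript units against an ORF annotation
#'
#' A unit overlapping (by at least one base, in the same orientation) a
#' verified or uncharacterized ORF is an ORF transcript (`"ORF-T"`). A unit
#' whose only same-orientation ORF overlaps have status `"other"` (dubious
#' ORFs, non-ORF features) is classed `"other"`. Everything else — including
#' units overlapping ORFs solely on the opposite strand — is a non-coding RNA
#' (`"ncRNA"`); opposite-strand overlap is what makes a ncRNA an antisense
#' candidate.
#'
#' @param units Tibble of transcript units.
#' @param annotation ORF tibble from [load_annotation()].
#' @return `units` with the `class` column filled in.
#' @export
classify_units <- function(units, annotation) {
  if (nrow(units) == 0) return(units)
  cls <- rep("ncRNA", nrow(units))
  if (nrow(annotation) > 0) {
    ug <- GenomicRanges::GRanges(units$chrom,
                                 IRanges::IRanges(units$start + 1L, units$end),
                                 strand = units$strand)
    ag <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$start + 1L,
                                                  annotation$end),
                                 strand = annotation$strand)
    hits <- GenomicRanges::findOverlaps(ug, ag, ignore.strand = FALSE)
    st <- annotation$status[S4Vectors::subjectHits(hits)]
    qi <- S4Vectors::queryHits(hits)
    cls[unique(qi[st == "other"])] <- "other"
    cls[unique(qi[st %in% c("verified", "uncharacterized")])] <- "ORF-T"
  }
  units$class <- cls
  units
}

#' Couple sense ORF transcripts with antisense non-coding RNAs
#'
#' Every (ORF-T, ncRNA) duo on opposite strands overlapping by at least one
#' base becomes a sense-antisense pair, the ncRNA taking the antisense role.
#' A ncRNA spanning several ORF-Ts yields one pair per ORF-T; the pair with
#' the largest overlap is flagged `primary`.
#'
#' @param units Classified unit tibble (see [classify_units()]).
#' @return Tibble of pairs: `sense_id`, `antisense_id`, `chrom`,
#'   `overlap_start`, `overlap_end`, `overlap_len`, `sense_len`, `primary`.
#' @export
pair_sense_antisense <- function(units) {
  empty <- tibble::tibble(sense_id = character(), antisense_id = character(),
                          chrom = character(), overlap_start = integer(),
                          overlap_end = integer(), overlap_len = integer(),
                          sense_len = integer(), primary = logical())
  sn <- units[!is.na(units$class) & units$class == "ORF-T", ]
  as <- units[!is.na(units$class) & units$class == "ncRNA", ]
  if (nrow(sn) == 0 || nrow(as) == 0) return(empty)
  sg <- GenomicRanges::GRanges(sn$chrom,
                               IRanges::IRanges(sn$start + 1L, sn$end))
  ag <- GenomicRanges::GRanges(as$chrom,
                               IRanges::IRanges(as$start + 1L, as$end))
  hits <- GenomicRanges::findOverlaps(sg, ag, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  opp <- sn$strand[i] != as$strand[j]
  i <- i[opp]; j <- j[opp]
  if (length(i) == 0) return(empty)
  ov_start <- pmax(sn$start[i], as$start[j])
  ov_end <- pmin(sn$end[i], as$end[j])
  pairs <- tibble::tibble(
    sense_id = sn$unit_id[i],
    antisense_id = as$unit_id[j],
    chrom = sn$chrom[i],
    overlap_start = ov_start,
    overlap_end = ov_end,
    overlap_len = ov_end - ov_start,
    sense_len = sn$end[i] - sn$start[i])
  pairs |>
    dplyr::group_by(.data$antisense_id) |>
    dplyr::mutate(primary = seq_len(dplyr::n()) ==
                    which.max(.data$overlap_len)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$overlap_start)
}

#' Restrict pairs to those expressed in every sample
#'
#' The working ("stringent") set: pairs whose sense and antisense members
#' have BPKM above `min_bpkm` in all samples of the supplied expression
#' table. Idempotent by construction.
#'
#' @param pairs Pair tibble (see [pair_sense_antisense()]).
#' @param expr Expression table from [expression_table()] covering all
#'   samples of interest.
#' @param min_bpkm Expression floor (default 0, i.e. any non-zero BPKM).
#' @return The subset of `pairs` passing the filter.
#' @export
filter_expressed_all <- function(pairs, expr, min_bpkm = 0) {
  if (nrow(pairs) == 0) return(pairs)
  samples <- setdiff(names(expr), "unit_id")
  if (length(samples) == 0) rlang::abort("expression table has no sample columns")
  ok <- apply(as.matrix(expr[samples]), 1, function(v) all(v > min_bpkm))
  good <- expr$unit_id[ok]
  pairs[pairs$sense_id %in% good & pairs$antisense_id %in% good, ]
}

#' Summarize sense-antisense pairing of intron-containing ORFs
#'
#' Counts (i) ORFs carrying at least one annotated intron, (ii) how many of
#' those form a sense-antisense pair, and (iii) how many of those pairs have
#' the antisense unit's 5' end (strand-aware transcription start) inside an
#' intron of the paired ORF. The genome-wide pair frequency (fraction of
#' verified/uncharacterized ORFs whose ORF-T forms a pair) is reported for
#' comparison.
#'
#' @param pairs Pair tibble.
#' @param units Classified unit tibble.
#' @param annotation ORF tibble.
#' @param introns Intron tibble from [load_introns()].
#' @return One-row tibble: `n_intron_orfs`, `n_intron_orfs_paired`,
#'   `n_antisense_from_intron`, `intron_pair_freq`, `genome_pair_freq`.
#' @export
intron_overlap_summary <- function(pairs, units, annotation, introns) {
  if (is.null(introns) || nrow(introns) == 0) {
    rlang::abort("no intron records supplied")
  }
  orfs <- annotation[annotation$status %in% c("verified", "uncharacterized"), ]
  # ORF -> overlapping same-strand ORF-T unit(s)
  orft <- units[!is.na(units$class) & units$class == "ORF-T", ]
  link <- if (nrow(orft) == 0) {
    tibble::tibble(orf_id = character(), unit_id = character())
  } else {
    og <- GenomicRanges::GRanges(orfs$chrom,
                                 IRanges::IRanges(orfs$start + 1L, orfs$end),
                                 strand = orfs$strand)
    ug <- GenomicRanges::GRanges(orft$chrom,
                                 IRanges::IRanges(orft$start + 1L, orft$end),
                                 strand = orft$strand)
    h <- GenomicRanges::findOverlaps(og, ug, ignore.strand = FALSE)
    tibble::tibble(orf_id = orfs$orf_id[S4Vectors::queryHits(h)],
                   unit_id = orft$unit_id[S4Vectors::subjectHits(h)])
  }
  paired_units <- unique(pairs$sense_id)
  paired_orfs <- unique(link$orf_id[link$unit_id %in% paired_units])
  intron_orfs <- unique(introns$orf_id)
  intron_orfs <- intersect(intron_orfs, orfs$orf_id)
  intron_paired <- intersect(intron_orfs, paired_orfs)

  # antisense 5' start inside an intron of the paired ORF
  n_from_intron <- 0L
  if (length(intron_paired) > 0 && nrow(pairs) > 0) {
    au <- units[match(pairs$antisense_id, units$unit_id), ]
    tss <- ifelse(au$strand == "+", au$start, au$end - 1L)
    for (k in seq_len(nrow(pairs))) {
      orf_ids <- link$orf_id[link$unit_id == pairs$sense_id[k]]
      orf_ids <- intersect(orf_ids, intron_paired)
      if (length(orf_ids) == 0) next
      ii <- introns[introns$orf_id %in% orf_ids, ]
      if (any(ii$start <= tss[k] & tss[k] < ii$end)) {
        n_from_intron <- n_from_intron + 1L
      }
    }
  }
  tibble::tibble(
    n_intron_orfs = length(intron_orfs),
    n_intron_orfs_paired = length(intron_paired),
    n_antisense_from_intron = n_from_intron,
    intron_pair_freq = if (length(intron_orfs) > 0)
      length(intron_paired) / length(intron_orfs) else NA_real_,
    genome_pair_freq = if (nrow(orfs) > 0)
      length(paired_orfs) / nrow(orfs) else NA_real_)
}
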