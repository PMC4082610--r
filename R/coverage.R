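#' Stranded per-base coverage
#'
#' Container for strand-resolved read depth: one non-negative integer vector
#' per chromosome and strand, plus the library-size total used by [bpkm()].
#'
#' @param depth Named list, one element per chromosome; each element is a list
#'   with components `"+"` and `"-"`, integer vectors of per-base depth whose
#'   length equals the chromosome length.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return An object of class `stranded_coverage`: a list with elements
#'   `depth`, `chrom_sizes` and `total_mapped_bases` (the sum of all depth
#'   values over both strands — each aligned template contributes one count
#'   per base it spans).
#' @export
stranded_coverage <- function(depth, chrom_sizes) {
  chrom_sizes <- chrom_sizes[sort(names(chrom_sizes))]
  stopifnot(setequal(names(depth), names(chrom_sizes)))
  depth <- depth[names(chrom_sizes)]
  for (chr in names(depth)) {
    stopifnot(setequal(names(depth[[chr]]), c("+", "-")))
    for (s in c("+", "-")) {
      v <- depth[[chr]][[s]]
      if (length(v) != chrom_sizes[[chr]]) {
        rlang::abort(sprintf(
          "depth track for %s(%s) has length %d, chromosome length is %d",
          chr, s, length(v), chrom_sizes[[chr]]))
      }
      if (any(v < 0)) rlang::abort("negative depth values")
      storage.mode(depth[[chr]][[s]]) <- "double"
    }
  }
  total <- sum(vapply(depth, function(ch) sum(ch[["+"]]) + sum(ch[["-"]]), 0))
  structure(
    list(depth = depth, chrom_sizes = chrom_sizes, total_mapped_bases = total),
    class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat("<stranded_coverage> ", length(x$chrom_sizes), " chromosome(s), ",
      format(x$total_mapped_bases, big.mark = ","), " mapped bases\n", sep = "")
  invisible(x)
}

empty_depth <- function(chrom_sizes) {
  lapply(chrom_sizes, function(L) list(`+` = numeric(L), `-` = numeric(L)))
}

#' Read a chromosome-sizes file
#'
#' Two-column TSV (chromosome name, length in bases), no header.
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths.
#' @export
load_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$size, tab$chrom)
}

#' Load paired-end alignments as strand-resolved fragments
#'
#' Reads a SAM or BAM file and collapses each properly paired template into a
#' single fragment spanning from the leftmost to the rightmost aligned base of
#' the two mates. The transcribed strand is resolved according to the library
#' dialect: under the dUTP second-strand protocol the uridine-marked second
#' strand is destroyed, so mate 1 aligns antisense to the transcript and the
#' transcribed strand is the strand of mate 2.
#'
#' Unpaired or improperly paired records are skipped (a count is reported via
#' `message()`). Templates failing the uniqueness policy — an `NH` tag greater
#' than 1 when the tag is present, otherwise mapping quality below
#' `min_mapq` — are excluded and counted likewise.
#'
#' @param path SAM or BAM file with paired-end alignments.
#' @param dialect `"dutp"` or `"reverse"` (transcribed strand = strand of
#'   mate 2; for proper FR pairs these coincide) or `"forward"` (strand of
#'   mate 1).
#' @param unique_only Drop multi-mapping templates (default `TRUE`).
#' @param min_mapq Mapping-quality floor used when no `NH` tag is present.
#' @return A tibble of fragments with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
load_alignments <- function(path, dialect = c("dutp", "reverse", "forward"),
                            unique_only = TRUE, min_mapq = 10) {
  dialect <- rlang::arg_match(dialect)
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p_all <- Rsamtools::ScanBamParam(
    what = "flag",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  n_primary <- length(Rsamtools::scanBam(bam, param = p_all)[[1]]$flag)

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_paired <- length(rec$pos)
  if (n_primary > n_paired) {
    message(n_primary - n_paired, " unpaired/improper record(s) skipped")
  }
  if (n_paired == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  ref_width <- cigar_ref_width(rec$cigar)
  reads <- tibble::tibble(
    qname = rec$qname,
    chrom = as.character(rec$rname),
    start0 = rec$pos - 1L,
    end0 = rec$pos - 1L + ref_width,
    rev = bitwAnd(rec$flag, 16L) > 0L,
    mate2 = bitwAnd(rec$flag, 128L) > 0L,
    mapq = rec$mapq,
    nh = if (is.null(rec$tag$NH)) NA_integer_ else rec$tag$NH)

  frags <- reads |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start0),
      end = max(.data$end0),
      strand2 = .data$rev[.data$mate2][1],
      strand1 = .data$rev[!.data$mate2][1],
      max_nh = suppressWarnings(max(.data$nh, na.rm = TRUE)),
      has_nh = any(!is.na(.data$nh)),
      min_mapq_obs = min(.data$mapq),
      n = dplyr::n(),
      .by = "qname") |>
    dplyr::filter(.data$n == 2L)

  mate_rev <- if (dialect == "forward") frags$strand1 else frags$strand2
  frags$strand <- ifelse(mate_rev, "-", "+")

  if (unique_only) {
    keep <- ifelse(frags$has_nh, frags$max_nh == 1L,
                   frags$min_mapq_obs >= min_mapq)
    if (any(!keep)) message(sum(!keep), " multi-mapping template(s) excluded")
    frags <- frags[keep, ]
  }
  frags |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::select("chrom", "start", "end", "strand")
}

# reference-space width of a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Build strand-resolved per-base coverage from fragments
#'
#' Depth at a base on a strand is the number of fragments of that strand whose
#' interval contains the base; `total_mapped_bases` is the sum of fragment
#' lengths.
#'
#' @param fragments Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A [stranded_coverage()] object.
#' @export
build_coverage <- function(fragments, chrom_sizes) {
  depth <- empty_depth(chrom_sizes)
  if (nrow(fragments) > 0) {
    bad <- !(fragments$chrom %in% names(chrom_sizes)) |
      fragments$start < 0 |
      fragments$end > chrom_sizes[fragments$chrom] |
      fragments$start >= fragments$end
    if (any(bad)) {
      i <- which(bad)[1]
      rlang::abort(sprintf(
        "fragment out of bounds or invalid: %s:%d-%d (%s)",
        fragments$chrom[i], fragments$start[i], fragments$end[i],
        fragments$strand[i]))
    }
    groups <- split(fragments, list(fragments$chrom, fragments$strand),
                    drop = TRUE)
    for (g in groups) {
      chr <- g$chrom[1]; s <- g$strand[1]
      L <- chrom_sizes[[chr]]
      acc <- numeric(L + 1L)
      add <- tapply(rep(1, nrow(g)), g$start + 1L, sum)
      acc[as.integer(names(add))] <- acc[as.integer(names(add))] + add
      sub <- tapply(rep(1, nrow(g)), g$end + 1L, sum)
      acc[as.integer(names(sub))] <- acc[as.integer(names(sub))] - sub
      depth[[chr]][[s]] <- cumsum(acc)[seq_len(L)]
    }
  }
  stranded_coverage(depth, chrom_sizes)
}

#' Read / write a strand pair of bedGraph files
#'
#' One bedGraph per strand, 0-based half-open intervals. Zero-depth regions
#' may be omitted in the files; they are restored as zeros on read. Writing
#' then reading reproduces the depth arrays exactly.
#'
#' @param plus_path,minus_path bedGraph files for the + and - strand.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return [read_bedgraph_pair()]: a [stranded_coverage()].
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_sizes) {
  depth <- empty_depth(chrom_sizes)
  for (s in c("+", "-")) {
    path <- if (s == "+") plus_path else minus_path
    if (file.size(path) == 0) next   # fully silent strand
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0) next
    cov <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1L,
                          end = GenomicRanges::end(gr),
                          value = gr$score)
    if (!all(cov$chrom %in% names(chrom_sizes))) {
      rlang::abort(paste0("unknown chromosome in ", path))
    }
    for (g in split(cov, cov$chrom)) {
      g <- g[order(g$start), ]
      if (any(g$start[-1] < g$end[-nrow(g)])) {
        rlang::abort(paste0("overlapping intervals in ", path,
                            " (ambiguous depth)"))
      }
      if (any(g$end > chrom_sizes[[g$chrom[1]]])) {
        rlang::abort(paste0("interval beyond chromosome end in ", path))
      }
      v <- depth[[g$chrom[1]]][[s]]
      for (i in seq_len(nrow(g))) {
        v[(g$start[i] + 1L):g$end[i]] <- g$value[i]
      }
      depth[[g$chrom[1]]][[s]] <- v
    }
  }
  stranded_coverage(depth, chrom_sizes)
}

#' @rdname read_bedgraph_pair
#' @param cov A [stranded_coverage()] object.
#' @param prefix Output prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @return [write_bedgraph_pair()]: invisibly, the two file paths.
#' @export
write_bedgraph_pair <- function(cov, prefix) {
  paths <- c(`+` = paste0(prefix, ".plus.bedgraph"),
             `-` = paste0(prefix, ".minus.bedgraph"))
  for (s in c("+", "-")) {
    lines <- character()
    for (chr in names(cov$depth)) {
      r <- rle(cov$depth[[chr]][[s]])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chr, starts[keep],
                                  ends[keep], format(r$values[keep],
                                                     scientific = FALSE,
                                                     trim = TRUE)))
      }
    }
    writeLines(lines, paths[[s]])
  }
  invisible(unname(paths))
}
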