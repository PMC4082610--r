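#' Call transcript units from strand-resolved read depth
#'
#' Iterative peak-seeded transcript-unit caller. On each strand of each
#' chromosome, the following cycle repeats until no eligible seed remains:
#'
#' 1. **Seed.** The unmasked position of maximal depth starts a unit; a seed
#'    must have depth of at least `min_seed_depth` (default 5).
#' 2. **Grow.** The interval is extended one base at a time, alternating
#'    directions (upstream first). A direction stops once the mean depth over
#'    the current interval is at least `edge_ratio` (default 4) times the
#'    depth at the next position beyond that boundary; a masked or
#'    out-of-bounds neighbour counts as depth 0 and therefore always stops.
#' 3. **Reassign.** Each stopped boundary is extended once to cover the full
#'    span of every same-strand fragment containing the boundary base, so
#'    that reads straddling the edge are included. The extension never crosses
#'    into a previously called (masked) unit, which keeps units disjoint.
#' 4. **Mask.** The unit's interval is masked on its strand and excluded from
#'    later cycles.
#'
#' Masking is strand-specific: a unit on one strand does not block calls on
#' the other, since sense/antisense overlap is precisely what downstream
#' stages analyse. Ties for the maximal depth are broken towards the leftmost
#' position; chromosomes are processed in lexicographic order with the
#' + strand before the - strand, making the caller fully deterministic.
#'
#' @param cov A [stranded_coverage()] object.
#' @param fragments Tibble of fragments (`chrom`, `start`, `end`, `strand`)
#'   used for the boundary reassignment step, or `NULL` to skip that step
#'   (e.g. when only coverage tracks are available).
#' @param min_seed_depth Minimum depth for a position to seed a unit.
#' @param edge_ratio Mean-to-neighbour depth ratio that stops extension.
#' @param min_length Minimum unit length in bases.
#' @return Tibble of transcript units sorted by coordinate: `unit_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open), `peak_position`,
#'   `mean_depth`, `class` (`NA` until [classify_units()]).
#' @export
call_transcripts <- function(cov, fragments = NULL, min_seed_depth = 5,
                             edge_ratio = 4, min_length = 1) {
  stopifnot(inherits(cov, "stranded_coverage"))
  if (min_seed_depth <= 0 || edge_ratio <= 0 || min_length <= 0) {
    rlang::abort("min_seed_depth, edge_ratio and min_length must be positive")
  }
  out <- list()
  for (chr in names(cov$depth)) {
    for (s in c("+", "-")) {
      fs <- fe <- integer()
      if (!is.null(fragments)) {
        f <- fragments[fragments$chrom == chr & fragments$strand == s, ]
        fs <- f$start; fe <- f$end
      }
      units <- call_track(cov$depth[[chr]][[s]], fs, fe,
                          min_seed_depth, edge_ratio)
      if (nrow(units) > 0) {
        units$chrom <- chr
        units$strand <- s
        out[[paste(chr, s)]] <- units
      }
    }
  }
  units <- dplyr::bind_rows(out)
  if (nrow(units) == 0) {
    units <- tibble::tibble(start = integer(), end = integer(),
                            peak_position = integer(), mean_depth = numeric(),
                            chrom = character(), strand = character())
  }
  units <- units |>
    dplyr::filter(.data$end - .data$start >= min_length) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$strand)
  units$unit_id <- sprintf("TU%05d", seq_len(nrow(units)))
  units$class <- NA_character_
  units[, c("unit_id", "chrom", "strand", "start", "end",
            "peak_position", "mean_depth", "class")]
}

# one strand of one chromosome; frag_start/frag_end are 0-based half-open
call_track <- function(d, frag_start, frag_end, min_seed, edge_ratio) {
  L <- length(d)
  starts <- ends <- peaks <- integer()
  means <- numeric()
  if (L == 0) {
    return(tibble::tibble(start = starts, end = ends, peak_position = peaks,
                          mean_depth = means))
  }
  work <- d                       # masked positions flagged as -1
  masked <- logical(L)
  repeat {
    p <- which.max(work)          # leftmost maximum: deterministic tie-break
    if (work[p] < min_seed) break
    l <- r <- p
    tot <- d[p]; len <- 1L
    stop_l <- stop_r <- FALSE
    while (!(stop_l && stop_r)) {
      if (!stop_l) {
        nb <- l - 1L
        nd <- if (nb < 1L || masked[nb]) 0 else d[nb]
        if (tot / len >= edge_ratio * nd) stop_l <- TRUE
        else { l <- nb; tot <- tot + nd; len <- len + 1L }
      }
      if (!stop_r) {
        nb <- r + 1L
        nd <- if (nb > L || masked[nb]) 0 else d[nb]
        if (tot / len >= edge_ratio * nd) stop_r <- TRUE
        else { r <- nb; tot <- tot + nd; len <- len + 1L }
      }
    }
    # boundary reassignment: fragments containing the stop base, once per end,
    # clamped so the unit never enters a previously masked region
    if (length(frag_start) > 0) {
      hit_l <- frag_start <= (l - 1L) & (l - 1L) < frag_end
      if (any(hit_l)) {
        cand <- max(min(frag_start[hit_l]) + 1L, 1L)
        while (cand < l && masked[cand]) cand <- cand + 1L
        if (cand < l) l <- cand
      }
      hit_r <- frag_start <= (r - 1L) & (r - 1L) < frag_end
      if (any(hit_r)) {
        cand <- min(max(frag_end[hit_r]), L)
        while (cand > r && masked[cand]) cand <- cand - 1L
        if (cand > r) r <- cand
      }
    }
    masked[l:r] <- TRUE
    work[l:r] <- -1
    starts <- c(starts, l - 1L); ends <- c(ends, r)
    peaks <- c(peaks, p - 1L); means <- c(means, mean(d[l:r]))
  }
  tibble::tibble(start = starts, end = ends, peak_position = peaks,
                 mean_depth = means)
}

#' Write / read transcript units as GFF3
#'
#' Units round-trip through GFF3 with all fields preserved (`peak_position`,
#' `mean_depth` and `class` stored as attributes).
#'
#' @param units Tibble of units as returned by [call_transcripts()].
#' @param path GFF3 file path.
#' @return [read_units()]: the units tibble.
#' @export
write_units <- function(units, path) {
  lines <- "##gff-version 3"
  if (nrow(units) > 0) {
    attrs <- sprintf("ID=%s;peak_position=%d;mean_depth=%s;class=%s",
                     units$unit_id, units$peak_position,
                     sprintf("%.17g", units$mean_depth),
                     ifelse(is.na(units$class), "NA", units$class))
    lines <- c(lines, sprintf("%s\tascons\ttranscript_unit\t%d\t%d\t.\t%s\t.\t%s",
                              units$chrom, units$start + 1L, units$end,
                              units$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_units
#' @export
read_units <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(unit_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), peak_position = integer(),
                          mean_depth = numeric(), class = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) rlang::abort(paste0("malformed GFF3: ", path))
  f <- do.call(rbind, f)
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  cls <- attr_get(f[, 9], "class")
  tibble::tibble(
    unit_id = attr_get(f[, 9], "ID"),
    chrom = f[, 1],
    strand = f[, 7],
    start = as.integer(f[, 4]) - 1L,
    end = as.integer(f[, 5]),
    peak_position = as.integer(attr_get(f[, 9], "peak_position")),
    mean_depth = as.numeric(attr_get(f[, 9], "mean_depth")),
    class = ifelse(cls == "NA", NA_character_, cls))
}
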