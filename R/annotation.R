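#' Load an ORF annotation from GFF3
#'
#' GFF3 coordinates (1-based inclusive) are converted to the package-internal
#' 0-based half-open convention. ORF status is read from a record attribute
#' (`orf_classification` by default, as in SGD exports): `Verified` maps to
#' `"verified"`, `Uncharacterized` to `"uncharacterized"`; anything else,
#' including a missing attribute, maps to `"other"`.
#'
#' @param gff_path GFF3 file.
#' @param status_attr Attribute key holding the ORF status.
#' @param id_attr Attribute key holding the ORF identifier.
#' @return Tibble with columns `orf_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `status`.
#' @export
load_annotation <- function(gff_path, status_attr = "orf_classification",
                            id_attr = "ID") {
  gr <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                 error = function(e) {
                   rlang::abort(paste0("malformed GFF3 (", gff_path, "): ",
                                       conditionMessage(e)))
                 })
  if (length(gr) == 0) {
    rlang::warn(paste0("empty annotation: ", gff_path))
    return(tibble::tibble(orf_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), status = character()))
  }
  meta <- S4Vectors::mcols(gr)
  ids <- if (id_attr %in% names(meta)) as.character(meta[[id_attr]]) else
    rep(NA_character_, length(gr))
  missing_id <- is.na(ids) | ids == ""
  ids[missing_id] <- paste0("feature_", which(missing_id))
  raw_status <- if (status_attr %in% names(meta))
    as.character(meta[[status_attr]]) else rep(NA_character_, length(gr))
  status <- dplyr::case_match(tolower(raw_status),
                              "verified" ~ "verified",
                              "uncharacterized" ~ "uncharacterized",
                              .default = "other")
  out <- tibble::tibble(
    orf_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    status = status)
  if (anyDuplicated(out$orf_id)) rlang::abort("duplicate ORF ids in annotation")
  if (any(out$start >= out$end)) rlang::abort("invalid ORF interval (start >= end)")
  out
}

#' Load intron records
#'
#' Four-column TSV (`orf_id`, `chrom`, `start`, `end`), no header, with
#' 1-based inclusive coordinates (converted internally to 0-based half-open).
#'
#' @param path TSV file.
#' @return Tibble with columns `orf_id`, `chrom`, `start`, `end`.
#' @export
load_introns <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("orf_id", "chrom", "start", "end"),
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  tibble::tibble(orf_id = tab$orf_id, chrom = tab$chrom,
                 start = tab$start - 1L, end = tab$end)
}

#' Load a one-to-one ORF homology map
#'
#' Two-column TSV (first species' ORF id, second species' ORF id), no header.
#' Each id may appear at most once.
#'
#' @param path TSV file.
#' @return Tibble with columns `orf_id_1`, `orf_id_2`.
#' @export
load_homologs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("orf_id_1", "orf_id_2"),
                           colClasses = "character")
  out <- tibble::as_tibble(tab)
  if (anyDuplicated(out$orf_id_1) || anyDuplicated(out$orf_id_2)) {
    rlang::abort("homology map is not one-to-one (duplicated id)")
  }
  out
}
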