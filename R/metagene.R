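#' Sense/antisense density profile of one gene over the canonical gene model
#'
#' The gene body (TSS to TTS) is divided into 200 equal intervals; each
#' interval contributes the mean per-base depth. The 100 nucleotides upstream
#' of the TSS and downstream of the TTS contribute per-base coverage
#' directly, giving a 400-point profile (indices 1-100 upstream, 101-300
#' body, 301-400 downstream). Minus-strand genes are orientation-flipped so
#' index 1 is always the 5' side. All values are divided by `norm`,
#' conventionally the mean of the gene's sense and antisense BPKM, so genes
#' contribute on a common scale. Flank positions beyond the chromosome end
#' are padded with zeros.
#'
#' @param cov A [stranded_coverage()] object.
#' @param chrom,start,end,strand Gene interval (0-based half-open) and strand.
#' @param norm Positive per-gene normalizer.
#' @param n_bins,flank Gene-model geometry (defaults 200 body intervals,
#'   100-nt flanks).
#' @return Tibble with 400 rows: `index`, `region` (`upstream` / `body` /
#'   `downstream`), `sense`, `antisense`.
#' @export
gene_profile <- function(cov, chrom, start, end, strand, norm,
                         n_bins = 200L, flank = 100L) {
  L <- end - start
  if (L < n_bins) rlang::abort("gene body shorter than the number of intervals")
  if (norm <= 0) rlang::abort("normalizer must be positive")
  clen <- cov$chrom_sizes[[chrom]]
  track <- function(s) {
    v <- cov$depth[[chrom]][[s]]
    body <- v[(start + 1L):end]
    edges <- floor(seq_len(n_bins) * L / n_bins)
    bin <- rep(seq_len(n_bins), times = diff(c(0L, edges)))
    body_means <- as.numeric(tapply(body, bin, mean))
    up_idx <- (start - flank + 1L):start        # 1-based positions
    dn_idx <- (end + 1L):(end + flank)
    pad <- function(idx) {
      out <- numeric(length(idx))
      ok <- idx >= 1L & idx <= clen
      out[ok] <- v[idx[ok]]
      out
    }
    c(pad(up_idx), body_means, pad(dn_idx))
  }
  sense <- track(strand)
  anti <- track(setdiff(c("+", "-"), strand))
  if (strand == "-") { sense <- rev(sense); anti <- rev(anti) }
  tibble::tibble(
    index = seq_len(n_bins + 2L * flank),
    region = rep(c("upstream", "body", "downstream"),
                 times = c(flank, n_bins, flank)),
    sense = sense / norm,
    antisense = anti / norm)
}

#' Mean metagene profile across genes
#'
#' Computes [gene_profile()] for every gene and averages element-wise. Each
#' gene is normalized by the mean of its own sense and antisense BPKM over
#' its body; genes shorter than the number of body intervals or with a zero
#' normalizer are excluded (counts reported via `message()`).
#'
#' @param cov A [stranded_coverage()] object.
#' @param genes Tibble with columns `chrom`, `start`, `end`, `strand` —
#'   typically ORF-T units, so that TSS/TTS are the called transcript
#'   boundaries.
#' @inheritParams gene_profile
#' @return An `ascons_metagene`: tibble with columns `index`, `region`,
#'   `sense`, `antisense` and attribute `n_genes`.
#' @export
metagene_profile <- function(cov, genes, n_bins = 200L, flank = 100L) {
  profs <- list()
  n_short <- n_silent <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$end - g$start < n_bins) { n_short <- n_short + 1L; next }
    both <- bpkm(cov, tibble::tibble(chrom = g$chrom, strand = c("+", "-"),
                                     start = g$start, end = g$end))
    norm <- mean(both)
    if (norm <= 0) { n_silent <- n_silent + 1L; next }
    # express per-base depth on the BPKM scale (L = 1 base) before dividing
    # by the gene's mean sense/antisense BPKM, so libraries are comparable
    norm_depth <- norm * cov$total_mapped_bases / 1e9
    profs[[length(profs) + 1L]] <-
      gene_profile(cov, g$chrom, g$start, g$end, g$strand, norm_depth,
                   n_bins = n_bins, flank = flank)
  }
  if (n_short > 0) message(n_short, " gene(s) shorter than ", n_bins,
                           " bases excluded")
  if (n_silent > 0) message(n_silent, " unexpressed gene(s) excluded")
  mean_profile(profs)
}

#' Element-wise mean of gene profiles
#'
#' @param profiles List of tibbles from [gene_profile()].
#' @return An `ascons_metagene` tibble (see [metagene_profile()]).
#' @export
mean_profile <- function(profiles) {
  if (length(profiles) == 0) rlang::abort("no gene profiles to average")
  out <- profiles[[1]][, c("index", "region")]
  out$sense <- rowMeans(vapply(profiles, function(p) p$sense,
                               numeric(nrow(out))))
  out$antisense <- rowMeans(vapply(profiles, function(p) p$antisense,
                                   numeric(nrow(out))))
  structure(out, n_genes = length(profiles),
            class = c("ascons_metagene", class(out)))
}

#' Plot a metagene profile
#'
#' @param profile An `ascons_metagene` from [metagene_profile()].
#' @return A ggplot object: sense and antisense density along the canonical
#'   gene model, with TSS/TTS marked.
#' @export
plot_metagene <- function(profile) {
  flank <- sum(profile$region == "upstream")
  body <- sum(profile$region == "body")
  long <- tidyr::pivot_longer(tibble::as_tibble(profile),
                              c("sense", "antisense"),
                              names_to = "track", values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$density,
                                     colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(flank + 0.5, flank + body + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "canonical gene model (5' → 3')",
                  y = "normalized density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_metagene
#' @param object An `ascons_metagene`.
#' @param ... Ignored.
#' @method autoplot ascons_metagene
#' @export
autoplot.ascons_metagene <- function(object, ...) plot_metagene(object)
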