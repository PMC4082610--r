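# shared fixtures: in-code SAM/GFF writers, tiny coverage builders, and a
# deliberately naive transcript caller used as an independent oracle

frag_tbl <- function(chrom, start, end, strand) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

# coverage with a single chromosome and explicit depth vectors
cov1 <- function(plus, minus = rep(0, length(plus)), chrom = "chrI") {
  stranded_coverage(
    stats::setNames(list(list(`+` = plus, `-` = minus)), chrom),
    stats::setNames(length(plus), chrom))
}

write_sam <- function(path, records, chrom = "chrI", len = 10000L) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, len),
               records), path)
}

# one properly paired template; m2_plus: is mate 2 on the + strand?
sam_pair <- function(qname, left, frag_len, read_len = 50L, m2_plus = TRUE,
                     chrom = "chrI", mapq = 60L, nh = NULL) {
  pos1 <- left + 1L                       # SAM is 1-based
  pos2 <- left + frag_len - read_len + 1L
  tag <- if (is.null(nh)) "" else sprintf("\tNH:i:%d", nh)
  if (m2_plus) {
    # mate 2 forward at the left, mate 1 reverse at the right
    c(sprintf("%s\t163\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*%s",
              qname, chrom, pos1, mapq, read_len, pos2, frag_len, tag),
      sprintf("%s\t83\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*%s",
              qname, chrom, pos2, mapq, read_len, pos1, -frag_len, tag))
  } else {
    # mate 1 forward at the left, mate 2 reverse at the right
    c(sprintf("%s\t99\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*%s",
              qname, chrom, pos1, mapq, read_len, pos2, frag_len, tag),
      sprintf("%s\t147\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*%s",
              qname, chrom, pos2, mapq, read_len, pos1, -frag_len, tag))
  }
}

sam_single <- function(qname, left, read_len = 50L, chrom = "chrI") {
  sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*", qname, chrom, left + 1L,
          read_len)
}

write_gff <- function(path, df) {
  attrs <- sprintf("ID=%s;orf_classification=%s", df$id, df$classification)
  writeLines(c("##gff-version 3",
               sprintf("%s\tsrc\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       df$chrom, df$start, df$end, df$strand, attrs)), path)
}

# literal re-implementation of the four-step caller: recomputes the interval
# mean from scratch at every step and scans fragments linearly
naive_caller <- function(d, frags = NULL, min_seed = 5, edge_ratio = 4,
                         min_length = 1) {
  L <- length(d)
  masked <- rep(FALSE, L)
  out <- list()
  repeat {
    avail <- ifelse(masked, -Inf, d)
    if (length(avail) == 0 || max(avail) < min_seed) break
    p <- which(avail == max(avail))[1]
    l <- r <- p
    stop_l <- stop_r <- FALSE
    while (!(stop_l && stop_r)) {
      if (!stop_l) {
        nd <- if (l - 1 >= 1 && !masked[l - 1]) d[l - 1] else 0
        if (mean(d[l:r]) >= edge_ratio * nd) stop_l <- TRUE else l <- l - 1
      }
      if (!stop_r) {
        nd <- if (r + 1 <= L && !masked[r + 1]) d[r + 1] else 0
        if (mean(d[l:r]) >= edge_ratio * nd) stop_r <- TRUE else r <- r + 1
      }
    }
    if (!is.null(frags) && nrow(frags) > 0) {
      cl <- frags$start <= (l - 1) & (l - 1) < frags$end
      if (any(cl)) {
        cand <- max(min(frags$start[cl]) + 1, 1)
        while (cand < l && masked[cand]) cand <- cand + 1
        if (cand < l) l <- cand
      }
      cr <- frags$start <= (r - 1) & (r - 1) < frags$end
      if (any(cr)) {
        cand <- min(max(frags$end[cr]), L)
        while (cand > r && masked[cand]) cand <- cand - 1
        if (cand > r) r <- cand
      }
    }
    masked[l:r] <- TRUE
    out[[length(out) + 1]] <- data.frame(start = l - 1, end = r,
                                         peak_position = p - 1,
                                         mean_depth = mean(d[l:r]))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(start = integer(), end = integer(),
                      peak_position = integer(), mean_depth = numeric())
  }
  res <- res[res$end - res$start >= min_length, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

# convenience: run the package caller on a single + strand track
call1 <- function(d, frags = NULL, ...) {
  fr <- if (is.null(frags)) NULL else
    frag_tbl("chrI", frags$start, frags$end, "+")
  u <- call_transcripts(cov1(d), fr, ...)
  as.data.frame(u[, c("start", "end", "peak_position", "mean_depth")])
}
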