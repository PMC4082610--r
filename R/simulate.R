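#' Configuration for the synthetic two-species stranded RNA-seq generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' two species sharing a homologous gene set, three culture conditions
#' (mid-log `ML`, early stationary `ES`, heat shock `HS`), log-normal
#' expression with higher cross-species correlation for sense than antisense
#' transcription, antisense units initiating around gene 3' ends with partial
#' sense overlap, a planted fraction of pairs with exactly inverse
#' (>= `fold`) expression changes in the stress conditions, and a mix of
#' conserved and divergent overlap geometries.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_genes Number of genes per species.
#' @param gene_length_range Gene length range in bases.
#' @param gene_gap Silent gap between genes (>= 2x mean fragment length so
#'   units are separable).
#' @param antisense_fraction Fraction of genes given an antisense unit (in
#'   both species; the generator emulates the analysis' working set of
#'   paired genes).
#' @param conserved_overlap_fraction Fraction of antisense pairs whose
#'   overlap fractions nearly match across species (conservation score
#'   target > 0.8); the rest are divergent (target < 0.5).
#' @param inverse_fraction_ES,inverse_fraction_HS Fractions of pairs planted
#'   with an exact inverse expression change (sense / `fold`, antisense x
#'   `fold`) in ES and HS respectively, in both species.
#' @param fold Planted fold change (>= 1.5).
#' @param fragment_length_mean,fragment_length_sd Fragment length
#'   distribution (truncated normal, bases).
#' @param depth_scale Expected fragments per expression unit per kilobase.
#' @param sense_log_mean,antisense_log_mean Baseline log2 expression.
#' @param sense_log_sd,antisense_log_sd Log2 expression dispersions
#'   (antisense is more dispersed, as observed for antisense transcription).
#' @param cross_species_corr_sense,cross_species_corr_antisense Target
#'   cross-species correlations of log expression within a condition; sense
#'   must exceed antisense.
#' @param condition_sd_frac Fraction of the log-variance assigned to
#'   condition-specific (species-shared) effects.
#' @return A validated `ascons_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 200L,
                              gene_length_range = c(500L, 2000L),
                              gene_gap = 500L,
                              antisense_fraction = 0.6,
                              conserved_overlap_fraction = 0.5,
                              inverse_fraction_ES = 0.15,
                              inverse_fraction_HS = 0.25,
                              fold = 2,
                              fragment_length_mean = 200,
                              fragment_length_sd = 50,
                              depth_scale = 50,
                              sense_log_mean = 1,
                              antisense_log_mean = 0,
                              sense_log_sd = 0.8,
                              antisense_log_sd = 1.1,
                              cross_species_corr_sense = 0.85,
                              cross_species_corr_antisense = 0.5,
                              condition_sd_frac = 0.2) {
  cfg <- as.list(environment())
  props <- c(cfg$antisense_fraction, cfg$conserved_overlap_fraction,
             cfg$inverse_fraction_ES, cfg$inverse_fraction_HS,
             cfg$condition_sd_frac)
  if (any(props < 0 | props > 1)) rlang::abort("proportions must lie in [0, 1]")
  if (cfg$fold < 1) rlang::abort("fold must be >= 1")
  if (cfg$cross_species_corr_sense <= cfg$cross_species_corr_antisense) {
    rlang::abort("cross_species_corr_sense must exceed cross_species_corr_antisense")
  }
  if (cfg$gene_gap < 2 * cfg$fragment_length_mean) {
    rlang::abort("gene_gap must be at least twice the mean fragment length")
  }
  structure(cfg, class = "ascons_sim_config")
}

sim_species <- c("Sc", "Sp")
sim_conditions <- c("ML", "ES", "HS")

#' Simulate a ground-truthed two-species, three-condition experiment
#'
#' Deterministic given the seed. Gene intervals alternate strands along one
#' chromosome, separated by silent gaps; antisense units cover the sense 3'
#' terminus and extend a short tail beyond it. Fragment counts per transcript
#' and sample are Poisson with mean `depth_scale * expression * length/1000`;
#' fragments have truncated-normal lengths and uniform starts inside the
#' transcript.
#'
#' @param config An [simulation_config()] object.
#' @return An `ascons_simulation` list: `fragments[[species]][[condition]]`
#'   (fragment tibbles), `chrom_sizes[[species]]`,
#'   `annotation[[species]]` (ORF tibbles, status `"verified"`),
#'   `homologs`, and `truth` (list with `genes`, `antisense`, `expression`,
#'   `inverse`, `pairs`), plus the resolved `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "ascons_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_genes
  lens <- round(stats::runif(n, config$gene_length_range[1],
                             config$gene_length_range[2]))
  gap <- config$gene_gap
  starts <- gap + c(0, cumsum(lens[-n] + gap))
  ends <- starts + lens
  strands <- rep(c("+", "-"), length.out = n)
  chrom_len <- ends[n] + gap
  genes <- tibble::tibble(
    gene = sprintf("G%04d", seq_len(n)),
    chrom = "chrI", strand = strands,
    start = as.integer(starts), end = as.integer(ends))

  # --- antisense placement (per species geometry) ------------------------
  n_as <- round(config$antisense_fraction * n)
  as_genes <- sort(sample.int(n, n_as))
  n_cons <- round(config$conserved_overlap_fraction * n_as)
  geom_class <- sample(rep(c("conserved", "divergent"),
                           c(n_cons, n_as - n_cons)))
  f <- matrix(NA_real_, n_as, 2, dimnames = list(NULL, sim_species))
  cons <- geom_class == "conserved"
  f_base <- stats::runif(n_as, 0.35, 0.70)
  f[cons, 1] <- f_base[cons]
  f[cons, 2] <- pmin(f_base[cons] * stats::runif(sum(cons), 0.95, 1.05), 0.95)
  lo <- stats::runif(sum(!cons), 0.08, 0.18)
  hi <- stats::runif(sum(!cons), 0.55, 0.90)
  flip <- stats::runif(sum(!cons)) < 0.5
  f[!cons, 1] <- ifelse(flip, hi, lo)
  f[!cons, 2] <- ifelse(flip, lo, hi)
  tails <- matrix(round(stats::runif(2 * n_as, 50, 150)), n_as, 2)

  antisense <- list()
  for (k in seq_len(2)) {
    g <- genes[as_genes, ]
    ov <- pmax(1L, as.integer(round(f[, k] * (g$end - g$start))))
    tail_k <- tails[, k]
    a_start <- ifelse(g$strand == "+", g$end - ov, g$start - tail_k)
    a_end <- ifelse(g$strand == "+", g$end + tail_k, g$start + ov)
    antisense[[sim_species[k]]] <- tibble::tibble(
      gene = g$gene,
      antisense_id = paste0("AS_", g$gene),
      chrom = "chrI",
      strand = ifelse(g$strand == "+", "-", "+"),
      start = as.integer(pmax(a_start, 0L)),
      end = as.integer(pmin(a_end, chrom_len)),
      overlap_frac = f[, k],
      geometry = geom_class)
  }

  # --- expression model --------------------------------------------------
  # log2 e = mu + gene effect (shared) + condition effect (shared) +
  #          species effect + residual; shares chosen so that the
  #          within-condition cross-species correlation hits the target.
  draw_expr <- function(ids, mu, sd, rho) {
    m <- length(ids)
    csf <- config$condition_sd_frac
    a <- stats::rnorm(m, 0, sd * sqrt((1 - csf) * rho))
    e <- array(0, dim = c(m, 2, 3),
               dimnames = list(ids, sim_species, sim_conditions))
    for (ci in 1:3) {
      cc <- stats::rnorm(m, 0, sd * sqrt(csf * rho))
      for (si in 1:2) {
        b <- stats::rnorm(m, 0, sd * sqrt((1 - csf) * (1 - rho)))
        eps <- stats::rnorm(m, 0, sd * sqrt(csf * (1 - rho)))
        e[, si, ci] <- mu + a + cc + b + eps
      }
    }
    2^e
  }
  sense_e <- draw_expr(genes$gene, config$sense_log_mean,
                       config$sense_log_sd, config$cross_species_corr_sense)
  as_ids <- paste0("AS_", genes$gene[as_genes])
  anti_e <- draw_expr(as_ids, config$antisense_log_mean,
                      config$antisense_log_sd,
                      config$cross_species_corr_antisense)

  # --- planted inverse pairs (exact, both species) -----------------------
  inverse <- tibble::tibble(pair_id = character(), condition = character())
  for (cond in c("ES", "HS")) {
    frac <- if (cond == "ES") config$inverse_fraction_ES else
      config$inverse_fraction_HS
    n_inv <- round(frac * n_as)
    if (n_inv > 0) {
      picked <- sort(sample.int(n_as, n_inv))
      gi <- as_genes[picked]
      sense_e[gi, , cond] <- sense_e[gi, , "ML"] / config$fold
      anti_e[picked, , cond] <- anti_e[picked, , "ML"] * config$fold
      inverse <- dplyr::bind_rows(inverse, tibble::tibble(
        pair_id = genes$gene[gi], condition = cond))
    }
  }

  # --- fragment sampling -------------------------------------------------
  sample_frags <- function(t_start, t_end, strand, e) {
    L <- t_end - t_start
    n_frag <- stats::rpois(1, config$depth_scale * e * L / 1000)
    if (n_frag == 0) {
      return(tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), strand = character()))
    }
    fl <- round(stats::rnorm(n_frag, config$fragment_length_mean,
                             config$fragment_length_sd))
    fl <- pmin(pmax(fl, 50L), L)
    fs <- t_start + floor(stats::runif(n_frag) * (L - fl + 1))
    tibble::tibble(chrom = "chrI", start = as.integer(fs),
                   end = as.integer(fs + fl), strand = strand)
  }
  fragments <- list()
  for (si in seq_len(2)) {
    sp_name <- sim_species[si]
    fragments[[sp_name]] <- list()
    for (cond in sim_conditions) {
      parts <- vector("list", n + n_as)
      for (i in seq_len(n)) {
        parts[[i]] <- sample_frags(genes$start[i], genes$end[i],
                                   genes$strand[i], sense_e[i, si, cond])
      }
      aa <- antisense[[sp_name]]
      for (j in seq_len(n_as)) {
        parts[[n + j]] <- sample_frags(aa$start[j], aa$end[j], aa$strand[j],
                                       anti_e[j, si, cond])
      }
      fragments[[sp_name]][[cond]] <- dplyr::bind_rows(parts) |>
        dplyr::arrange(.data$chrom, .data$start, .data$end)
    }
  }

  expr_long <- dplyr::bind_rows(
    tidyr::expand_grid(transcript = genes$gene, species = sim_species,
                       condition = sim_conditions) |>
      dplyr::mutate(type = "sense",
                    value = sense_e[cbind(.data$transcript, .data$species,
                                          .data$condition)]),
    tidyr::expand_grid(transcript = as_ids, species = sim_species,
                       condition = sim_conditions) |>
      dplyr::mutate(type = "antisense",
                    value = anti_e[cbind(.data$transcript, .data$species,
                                         .data$condition)]))

  pair_truth <- tibble::tibble(
    pair_id = genes$gene[as_genes],
    geometry = geom_class,
    f_Sc = f[, 1], f_Sp = f[, 2],
    S_target = conservation_score(1, f[, 1], 1, f[, 2]))

  annotation <- lapply(sim_species, function(s) {
    tibble::tibble(orf_id = paste0(s, "_", genes$gene), chrom = genes$chrom,
                   strand = genes$strand, start = genes$start,
                   end = genes$end, status = "verified")
  })
  names(annotation) <- sim_species

  structure(list(
    fragments = fragments,
    chrom_sizes = stats::setNames(
      rep(list(c(chrI = as.integer(chrom_len))), 2), sim_species),
    annotation = annotation,
    homologs = tibble::tibble(orf_id_1 = paste0("Sc_", genes$gene),
                              orf_id_2 = paste0("Sp_", genes$gene)),
    truth = list(genes = genes, antisense = antisense,
                 expression = expr_long, inverse = inverse,
                 pairs = pair_truth),
    config = config), class = "ascons_simulation")
}

#' @export
print.ascons_simulation <- function(x, ...) {
  cat("<ascons_simulation> ", x$config$n_genes, " genes x 2 species x 3 ",
      "conditions; ", nrow(x$truth$pairs), " sense-antisense pairs\n",
      sep = "")
  invisible(x)
}

#' Per-pair truth summary
#'
#' One row per planted sense-antisense pair: overlap geometry, target
#' conservation score, planted inverse labels, and the true fold changes of
#' both members in each stress condition and species.
#'
#' @param sim An `ascons_simulation` from [simulate_experiment()].
#' @return Tibble with one row per pair.
#' @export
truth_report <- function(sim) {
  stopifnot(inherits(sim, "ascons_simulation"))
  out <- sim$truth$pairs
  ex <- sim$truth$expression
  val <- function(tr, sp, cond) {
    ex$value[ex$transcript == tr & ex$species == sp & ex$condition == cond]
  }
  for (sp in sim_species) {
    for (cond in c("ES", "HS")) {
      s_fc <- a_fc <- rep(NA_real_, nrow(out))
      for (i in seq_len(nrow(out))) {
        g <- out$pair_id[i]; a <- paste0("AS_", g)
        s_fc[i] <- val(g, sp, cond) / val(g, sp, "ML")
        a_fc[i] <- val(a, sp, cond) / val(a, sp, "ML")
      }
      out[[paste0("sense_fc_", sp, "_", cond)]] <- s_fc
      out[[paste0("antisense_fc_", sp, "_", cond)]] <- a_fc
    }
  }
  for (cond in c("ES", "HS")) {
    out[[paste0("planted_", cond)]] <- out$pair_id %in%
      sim$truth$inverse$pair_id[sim$truth$inverse$condition == cond]
  }
  out
}

#' Write a simulation to disk
#'
#' Per sample: a bedGraph pair of strand coverage tracks; per species: a
#' truth GFF3 of genes and antisense units and a chrom.sizes file; plus the
#' homology map, the truth report and the resolved configuration (YAML).
#'
#' @param sim An `ascons_simulation`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$fragments)) {
    for (cond in names(sim$fragments[[sp]])) {
      cov <- build_coverage(sim$fragments[[sp]][[cond]],
                            sim$chrom_sizes[[sp]])
      write_bedgraph_pair(cov, file.path(dir, paste0(sp, "_", cond)))
    }
    ann <- sim$annotation[[sp]]
    lines <- c("##gff-version 3",
               sprintf("%s\tascons_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;orf_classification=Verified",
                       ann$chrom, ann$start + 1L, ann$end, ann$strand,
                       ann$orf_id))
    aa <- sim$truth$antisense[[sp]]
    lines <- c(lines,
               sprintf("%s\tascons_sim\tantisense\t%d\t%d\t.\t%s\t.\tID=%s_%s",
                       aa$chrom, aa$start + 1L, aa$end, aa$strand, sp,
                       aa$antisense_id))
    writeLines(lines, file.path(dir, paste0(sp, "_truth.gff3")))
    writeLines(sprintf("%s\t%d", names(sim$chrom_sizes[[sp]]),
                       sim$chrom_sizes[[sp]]),
               file.path(dir, paste0(sp, ".chrom.sizes")))
  }
  readr::write_tsv(sim$homologs, file.path(dir, "homologs.tsv"),
                   col_names = FALSE)
  readr::write_tsv(truth_report(sim), file.path(dir, "truth_report.tsv"))
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
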