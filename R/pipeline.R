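#' Validate and normalize pipeline parameters
#'
#' Fills defaults, rejects unknown keys, and checks ranges. All schema
#' violations are reported at once. Accepts a named list or a YAML file path.
#'
#' @param config Named list of parameters, or path to a YAML file.
#' @return A complete, validated parameter list of class `ascons_params`:
#'   `min_seed_depth` (5), `edge_ratio` (4), `min_length` (1),
#'   `fold_threshold` (1.5), `fold_mode` ("both"), `stringent_cut` (0.8),
#'   `background_cut` (0.5), `min_bpkm` (0), `strand_dialect` ("dutp"),
#'   `pseudocount` (0), `seed` (1).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- list(min_seed_depth = 5, edge_ratio = 4, min_length = 1,
                   fold_threshold = 1.5, fold_mode = "both",
                   stringent_cut = 0.8, background_cut = 0.5,
                   min_bpkm = 0, strand_dialect = "dutp", pseudocount = 0,
                   seed = 1L)
  problems <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$min_seed_depth) && cfg$min_seed_depth > 0,
      "min_seed_depth must be positive")
  chk(is.numeric(cfg$edge_ratio) && cfg$edge_ratio > 0,
      "edge_ratio must be positive")
  chk(is.numeric(cfg$min_length) && cfg$min_length >= 1,
      "min_length must be >= 1")
  chk(is.numeric(cfg$fold_threshold) && cfg$fold_threshold >= 1,
      "fold_threshold must be >= 1")
  chk(cfg$fold_mode %in% c("both", "either"),
      "fold_mode must be 'both' or 'either'")
  chk(is.numeric(cfg$stringent_cut) && cfg$stringent_cut > 0 &&
        cfg$stringent_cut <= 1, "stringent_cut must lie in (0, 1]")
  chk(is.numeric(cfg$background_cut) && cfg$background_cut >= 0 &&
        cfg$background_cut < 1, "background_cut must lie in [0, 1)")
  chk(is.numeric(cfg$min_bpkm) && cfg$min_bpkm >= 0,
      "min_bpkm must be >= 0")
  chk(cfg$strand_dialect %in% c("dutp", "reverse", "forward"),
      "strand_dialect must be one of dutp/reverse/forward")
  chk(is.numeric(cfg$pseudocount) && cfg$pseudocount >= 0,
      "pseudocount must be >= 0")
  if (length(problems) > 0) {
    rlang::abort(paste0("invalid configuration:\n  - ",
                        paste(problems, collapse = "\n  - ")))
  }
  structure(cfg, class = "ascons_params")
}

#' Link annotated ORFs to called ORF-T units
#'
#' Associates each ORF with the ORF-T unit sharing the largest
#' same-strand overlap, the association used to carry a homology map from
#' ORF ids into called-unit space.
#'
#' @param units Classified unit tibble.
#' @param annotation ORF tibble from [load_annotation()].
#' @return Tibble with columns `orf_id`, `unit_id`.
#' @export
orf_unit_link <- function(units, annotation) {
  orft <- units[!is.na(units$class) & units$class == "ORF-T", ]
  if (nrow(orft) == 0 || nrow(annotation) == 0) {
    return(tibble::tibble(orf_id = character(), unit_id = character()))
  }
  og <- GenomicRanges::GRanges(annotation$chrom,
                               IRanges::IRanges(annotation$start + 1L,
                                                annotation$end),
                               strand = annotation$strand)
  ug <- GenomicRanges::GRanges(orft$chrom,
                               IRanges::IRanges(orft$start + 1L, orft$end),
                               strand = orft$strand)
  h <- GenomicRanges::findOverlaps(og, ug, ignore.strand = FALSE)
  i <- S4Vectors::queryHits(h); j <- S4Vectors::subjectHits(h)
  ov <- pmin(annotation$end[i], orft$end[j]) -
    pmax(annotation$start[i], orft$start[j])
  tibble::tibble(orf_id = annotation$orf_id[i], unit_id = orft$unit_id[j],
                 ov = ov) |>
    dplyr::group_by(.data$orf_id) |>
    dplyr::slice_max(.data$ov, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("orf_id", "unit_id")
}

#' Run the full sense-antisense conservation pipeline
#'
#' Executes, per species: coverage pooling over the three conditions,
#' transcript-unit calling, BPKM quantification per condition,
#' classification against the ORF annotation, and sense-antisense pairing.
#' Units are called once per species on pooled coverage so that a single
#' unit set underlies all per-condition fold changes. Cross-species stages
#' then join homologous pairs, score overlap-geometry conservation, restrict
#' to pairs expressed in every sample, classify inverse expression changes,
#' and run the enrichment, distribution-shift and metagene analyses.
#'
#' @param sim An `ascons_simulation` from [simulate_experiment()], or a list
#'   with the same components built from real data: `fragments` (per species,
#'   per condition fragment tibbles), `chrom_sizes`, `annotation`, `homologs`.
#' @param params An `ascons_params` list from [validate_config()].
#' @return An `ascons_report` list; see [tidy.ascons_report()] and
#'   [glance.ascons_report()].
#' @export
run_pipeline <- function(sim, params = validate_config()) {
  if (!inherits(params, "ascons_params")) params <- validate_config(params)
  species <- names(sim$fragments)
  if (length(species) != 2) rlang::abort("exactly two species required")
  for (sp in species) {
    if (!setequal(names(sim$fragments[[sp]]), sim_conditions)) {
      rlang::abort(paste0("species ", sp, " must have samples for ",
                          paste(sim_conditions, collapse = ", ")))
    }
  }
  per_species <- list()
  for (sp in species) {
    covs <- lapply(sim$fragments[[sp]], build_coverage,
                   chrom_sizes = sim$chrom_sizes[[sp]])
    pooled_frags <- dplyr::bind_rows(sim$fragments[[sp]])
    pooled <- build_coverage(pooled_frags, sim$chrom_sizes[[sp]])
    units <- call_transcripts(pooled, pooled_frags,
                              min_seed_depth = params$min_seed_depth,
                              edge_ratio = params$edge_ratio,
                              min_length = params$min_length) |>
      classify_units(sim$annotation[[sp]])
    expr <- expression_table(units, covs)
    pairs <- pair_sense_antisense(units)
    per_species[[sp]] <- list(coverages = covs, pooled = pooled,
                              units = units, expr = expr, pairs = pairs,
                              link = orf_unit_link(units,
                                                   sim$annotation[[sp]]))
  }
  s1 <- per_species[[species[1]]]; s2 <- per_species[[species[2]]]

  # homology map translated from ORF ids to sense unit ids
  map_units <- sim$homologs |>
    dplyr::inner_join(dplyr::rename(s1$link, orf_id_1 = "orf_id",
                                    unit_id_1 = "unit_id"), by = "orf_id_1") |>
    dplyr::inner_join(dplyr::rename(s2$link, orf_id_2 = "orf_id",
                                    unit_id_2 = "unit_id"), by = "orf_id_2") |>
    dplyr::distinct(.data$unit_id_1, .data$unit_id_2, .keep_all = TRUE) |>
    dplyr::filter(!duplicated(.data$unit_id_1), !duplicated(.data$unit_id_2))
  unit_map <- tibble::tibble(orf_id_1 = map_units$unit_id_1,
                             orf_id_2 = map_units$unit_id_2)

  joined <- join_homologs(s1$pairs, s2$pairs, s1$units, s2$units, unit_map) |>
    conservation_records() |>
    dplyr::mutate(pair_id = .data$sense_id_1)

  # expressed-in-all filter across both species' samples
  expressed <- function(expr, ids) {
    m <- as.matrix(expr[match(ids, expr$unit_id),
                        setdiff(names(expr), "unit_id")])
    !is.na(ids) & apply(m, 1, function(v) all(!is.na(v) & v > params$min_bpkm))
  }
  keep <- expressed(s1$expr, joined$sense_id_1) &
    expressed(s1$expr, joined$antisense_id_1) &
    expressed(s2$expr, joined$sense_id_2) &
    expressed(s2$expr, joined$antisense_id_2)
  filtered <- joined[keep, ]

  # per pair x species x condition fold changes
  fc <- list()
  for (k in 1:2) {
    sp <- species[k]; ps <- per_species[[sp]]
    sid <- filtered[[paste0("sense_id_", k)]]
    aid <- filtered[[paste0("antisense_id_", k)]]
    e <- ps$expr
    for (cond in c("ES", "HS")) {
      fc[[paste(sp, cond)]] <- tibble::tibble(
        pair_id = filtered$pair_id, species = sp, condition = cond,
        sense_fc = e[[cond]][match(sid, e$unit_id)] /
          e[["ML"]][match(sid, e$unit_id)],
        antisense_fc = e[[cond]][match(aid, e$unit_id)] /
          e[["ML"]][match(aid, e$unit_id)])
    }
  }
  records <- classify_inverse(dplyr::bind_rows(fc),
                              fold_threshold = params$fold_threshold,
                              mode = params$fold_mode)
  counts <- inverse_count_table(records)

  # sense / antisense expression matrices over the filtered pairs
  expr_wide <- function(member) {
    out <- tibble::tibble(pair_id = filtered$pair_id)
    for (k in 1:2) {
      ids <- filtered[[paste0(member, "_id_", k)]]
      e <- per_species[[species[k]]]$expr
      for (cond in sim_conditions) {
        out[[paste0(species[k], "_", cond)]] <-
          e[[cond]][match(ids, e$unit_id)]
      }
    }
    out
  }
  sense_expr <- expr_wide("sense")
  anti_expr <- expr_wide("antisense")
  correlations <- list()
  if (nrow(filtered) >= 3) {
    correlations$sense <- correlation_matrix(sense_expr[-1],
                                             pseudocount = params$pseudocount)
    correlations$antisense <- correlation_matrix(anti_expr[-1],
                                                 pseudocount = params$pseudocount)
  }

  enrichment <- list()
  for (cond in c("ES", "HS")) {
    enrichment[[cond]] <- tryCatch(
      conservation_enrichment(filtered, records, cond,
                              stringent_cut = params$stringent_cut,
                              background_cut = params$background_cut),
      error = function(e) NULL)
  }

  shift <- list()
  for (k in 1:2) {
    sp <- species[k]
    ml <- anti_expr[[paste0(sp, "_ML")]]
    for (cond in c("ES", "HS")) {
      x <- anti_expr[[paste0(sp, "_", cond)]]
      shift[[paste0(sp, "_", cond)]] <- tryCatch(
        distribution_shift_test(x, ml), error = function(e) NULL)
    }
  }

  metagene <- list()
  for (k in 1:2) {
    sp <- species[k]; ps <- per_species[[sp]]
    genes <- ps$units[ps$units$unit_id %in%
                        filtered[[paste0("sense_id_", k)]], ]
    metagene[[sp]] <- tryCatch(
      suppressMessages(metagene_profile(ps$pooled, genes)),
      error = function(e) NULL)
  }

  # transcript-class accounting (shared vs species-unique)
  class_counts <- lapply(per_species, function(ps) table(ps$units$class))
  shared_orft <- nrow(map_units)
  shared_anti <- sum(joined$O_1 > 0 & joined$O_2 > 0)

  structure(list(
    params = params, species = species,
    units = lapply(per_species, `[[`, "units"),
    expression = lapply(per_species, `[[`, "expr"),
    pairs = lapply(per_species, `[[`, "pairs"),
    joined = joined, filtered = filtered, records = records,
    counts = counts, correlations = correlations,
    enrichment = enrichment, shift_tests = shift, metagene = metagene,
    class_counts = class_counts,
    shared = list(orf_t = shared_orft, antisense = shared_anti)),
    class = "ascons_report")
}

#' @export
print.ascons_report <- function(x, ...) {
  cat("<ascons_report> species: ", paste(x$species, collapse = " / "), "\n",
      sep = "")
  for (sp in x$species) {
    cc <- x$class_counts[[sp]]
    cat(sprintf("  %s: %d units (%s)\n", sp, sum(cc),
                paste(names(cc), cc, sep = "=", collapse = ", ")))
  }
  cat("  homologous pairs joined: ", nrow(x$joined),
      "; expressed in all samples: ", nrow(x$filtered), "\n", sep = "")
  for (cond in names(x$enrichment)) {
    if (!is.null(x$enrichment[[cond]])) {
      cat(sprintf("  enrichment %s: p = %.4g\n", cond,
                  x$enrichment[[cond]]$p_value))
    }
  }
  invisible(x)
}

#' Tidy a pipeline report into a per-pair tibble
#'
#' @param x An `ascons_report` from [run_pipeline()].
#' @param ... Ignored.
#' @return The filtered per-pair tibble (overlap geometry, conservation
#'   score) joined with per-species/condition inverse classifications.
#' @method tidy ascons_report
#' @export
tidy.ascons_report <- function(x, ...) {
  wide <- x$records |>
    tidyr::pivot_wider(id_cols = "pair_id",
                       names_from = c("species", "condition"),
                       values_from = c("sense_fc", "antisense_fc",
                                       "category", "significant"))
  dplyr::left_join(x$filtered, wide, by = "pair_id")
}

#' One-row summary of a pipeline report
#'
#' @param x An `ascons_report`.
#' @param ... Ignored.
#' @return One-row tibble: unit and pair counts, cross-species sense and
#'   antisense mid-log correlations, and the enrichment p-values.
#' @method glance ascons_report
#' @export
glance.ascons_report <- function(x, ...) {
  xsp <- function(mat) {
    if (is.null(mat)) return(NA_real_)
    mat[paste0(x$species[1], "_ML"), paste0(x$species[2], "_ML")]
  }
  tibble::tibble(
    n_units_1 = nrow(x$units[[1]]), n_units_2 = nrow(x$units[[2]]),
    n_joined = nrow(x$joined), n_filtered = nrow(x$filtered),
    sense_corr_ml = xsp(x$correlations$sense),
    antisense_corr_ml = xsp(x$correlations$antisense),
    p_enrichment_ES = if (is.null(x$enrichment$ES)) NA_real_ else
      x$enrichment$ES$p_value,
    p_enrichment_HS = if (is.null(x$enrichment$HS)) NA_real_ else
      x$enrichment$HS$p_value)
}

#' Correlation heatmap of expression across species and conditions
#'
#' @param mat Correlation matrix from [correlation_matrix()] or the
#'   `correlations` element of an `ascons_report`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_correlation <- function(mat, title = NULL) {
  df <- tibble::as_tibble(as.table(mat), .name_repair = "minimal")
  names(df) <- c("row", "col", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(min(mat), 1)) +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' @rdname plot_correlation
#' @param object An `ascons_report`; plots the sense correlation heatmap.
#' @param ... Ignored.
#' @method autoplot ascons_report
#' @export
autoplot.ascons_report <- function(object, ...) {
  plot_correlation(object$correlations$sense,
                   title = "sense expression correlation (log10 BPKM)")
}
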