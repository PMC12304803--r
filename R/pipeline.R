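# End-to-end run orchestration and the standard plots: acquire -> dedup ->
# proximity filter -> annotate -> confidence filter -> distributions, with
# per-stage retained counts so a dataset's attrition can be compared
# across runs, plus serialized configuration for provenance.

#' Read cross-links from any supported format
#'
#' Dispatches on extension: `.mzid` to [read_mzid()], `.zhrm`/`.zip` to
#' [read_merox_archive()], anything else to [read_xl_table()].
#'
#' @inheritParams read_xl_table
#' @export
read_crosslinks <- function(path, dataset_id = NULL, header_map = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mzid") read_mzid(path, dataset_id = dataset_id)
  else if (ext %in% c("zhrm", "zip")) {
    read_merox_archive(path, dataset_id = dataset_id, header_map = header_map)
  } else read_xl_table(path, dataset_id = dataset_id, header_map = header_map)
}

#' Validated run configuration
#'
#' @param xl_files character vector of cross-link input files.
#' @param models_dir directory of cached model files (see [locate_model()]).
#' @param out_dir output directory.
#' @param max_spacing spacing ceiling (default 19).
#' @param plddt_cutoff confidence cutoff for helix/strand spans (default 80).
#' @param strata confidence strata for [stratify_by_plddt()].
#' @param seed RNG seed (subset standard errors).
#' @param plots emit PNG plots.
#' @param header_map optional header map for tabular inputs.
#' @return validated `run_config` list.
#' @export
run_config <- function(xl_files, models_dir, out_dir,
                       max_spacing = 19L, plddt_cutoff = 80,
                       strata = list(c(0, 60), c(60, 80), c(80, 100)),
                       seed = 1L, plots = TRUE, header_map = NULL) {
  missing_in <- xl_files[!file.exists(xl_files)]
  if (length(missing_in)) {
    stop("cross-link input files not found: ", paste(missing_in, collapse = ", "))
  }
  if (!dir.exists(models_dir)) stop("models_dir does not exist: ", models_dir)
  stopifnot(max_spacing >= 1, plddt_cutoff >= 0, plddt_cutoff <= 100)
  structure(list(xl_files = xl_files, models_dir = models_dir,
                 out_dir = out_dir, max_spacing = as.integer(max_spacing),
                 plddt_cutoff = plddt_cutoff, strata = strata,
                 seed = as.integer(seed), plots = isTRUE(plots),
                 header_map = header_map),
            class = "run_config")
}

#' Run the full annotation pipeline
#'
#' Executes acquisition, within-dataset redundancy removal, sequence
#' proximity filtering, model loading, structural annotation, confidence
#' filtering, and the distribution summaries, writing all outputs under
#' `config$out_dir`: `annotated.tsv`, `distribution.tsv` (and the
#' pre-confidence-filter `distribution_unfiltered.tsv`), `probability.tsv`,
#' per-stratum distributions, `stage_counts.tsv`, `config.json`, and plots.
#'
#' @param config a [run_config()].
#' @return list with `stage_counts`, `annotated`, `filtered`,
#'   `distribution`, `probability`, `strata`; stage counts never increase
#'   along the pipeline.
#' @export
xl_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  acquired <- do.call(rbind, lapply(config$xl_files, read_crosslinks,
                                    header_map = config$header_map))
  message("acquired ", nrow(acquired), " cross-link records")
  deduped <- deduplicate(acquired)
  shortr <- proximity_filter(deduped, max_spacing = config$max_spacing)
  models <- list()
  for (acc in unique(shortr$accession_a)) {
    p <- locate_model(acc, config$models_dir)
    if (!is.na(p)) models[[acc]] <- read_structure(p)
  }
  message("models available for ", length(models), "/",
          length(unique(shortr$accession_a)), " proteins")
  annotated <- annotate_xl(shortr, models)
  filtered <- plddt_filter(annotated, cutoff = config$plddt_cutoff)
  stage_counts <- data.frame(
    stage = c("acquisition", "redundancy_removed", "proximity_filtered",
              "annotated", "plddt_filtered"),
    n = c(nrow(acquired), nrow(deduped), nrow(shortr), nrow(annotated),
          nrow(filtered)))
  utils::write.table(stage_counts,
                     file.path(config$out_dir, "stage_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotated_tsv(filtered, file.path(config$out_dir, "annotated.tsv"))
  dist <- spacing_distribution(filtered, seed = config$seed,
                               max_spacing = config$max_spacing)
  dist_unf <- spacing_distribution(annotated, seed = config$seed,
                                   max_spacing = config$max_spacing)
  write_distribution_tsv(dist, file.path(config$out_dir, "distribution.tsv"))
  write_distribution_tsv(dist_unf,
                         file.path(config$out_dir,
                                   "distribution_unfiltered.tsv"))
  prob <- structure_probability(filtered, max_spacing = config$max_spacing)
  utils::write.table(data.frame(spacing = as.integer(rownames(prob)), prob),
                     file.path(config$out_dir, "probability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  strata <- stratify_by_plddt(annotated, ranges = config$strata,
                              seed = config$seed)
  for (nm in names(strata)) {
    write_distribution_tsv(strata[[nm]],
                           file.path(config$out_dir,
                                     paste0("distribution_plddt_", nm, ".tsv")))
  }
  if (config$plots) {
    ggplot2::ggsave(file.path(config$out_dir, "distribution.png"),
                    plot_spacing_distribution(dist), width = 9, height = 3,
                    dpi = 120)
  }
  list(stage_counts = stage_counts, annotated = annotated,
       filtered = filtered, distribution = dist, probability = prob,
       strata = strata)
}

# Category colors: helix yellow, strand red, coil pink, mixed green.
.category_colors <- c(helix = "#E6B422", strand = "#D7191C",
                      coil = "#F49AC2", mixed = "#33A02C")

#' Plot a spacing distribution
#'
#' One panel per structural category (helix yellow, strand red, coil pink,
#' mixed green), normalized frequency against residue spacing, with the
#' subset standard error as a shaded ribbon where available.
#'
#' @param dist a [spacing_distribution()].
#' @return a ggplot object.
#' @export
plot_spacing_distribution <- function(dist) {
  df <- expand.grid(category = rownames(dist$normalized),
                    spacing = as.integer(colnames(dist$normalized)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- cbind(df$category, as.character(df$spacing))
  df$normalized <- dist$normalized[key]
  df$stderr <- dist$stderr[key]
  df$category <- factor(df$category, levels = names(.category_colors))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$spacing,
                                        y = .data$normalized,
                                        color = .data$category,
                                        fill = .data$category))
  if (!all(is.na(df$stderr))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$normalized - .data$stderr),
                   ymax = .data$normalized + .data$stderr),
      alpha = 0.25, color = NA)
  }
  p + ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~category, nrow = 1) +
    ggplot2::scale_color_manual(values = .category_colors, guide = "none") +
    ggplot2::scale_fill_manual(values = .category_colors, guide = "none") +
    ggplot2::labs(x = "residue spacing",
                  y = "relative frequency (max = 100)") +
    ggplot2::theme_minimal()
}

#' Plot a grammar matrix as a heatmap
#'
#' Amino acids (ranked by cumulative effect) against sequence offset from
#' the center lysine; blue marks promotion (positive percentage
#' difference), red inhibition. Dashed lines mark one and two helical
#' pitches (3.6 and 7.2 residues).
#'
#' @param gm a `grammar_matrix`.
#' @return a ggplot object.
#' @export
plot_grammar_heatmap <- function(gm) {
  df <- expand.grid(aa = rownames(gm$value),
                    offset = as.integer(colnames(gm$value)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- gm$value[cbind(df$aa, as.character(df$offset))]
  df$aa <- factor(df$aa, levels = rev(gm$ranking))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$aa,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = c(3.6, 7.2), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_fill_gradient2(low = "#B2182B", mid = "white",
                                  high = "#2166AC", na.value = "grey85",
                                  name = "% difference") +
    ggplot2::labs(x = "offset from cross-linked lysine", y = NULL) +
    ggplot2::theme_minimal()
}
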