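#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML path or a nested list, fills defaults, and reports every
#' validation error together rather than stopping at the first. Unknown
#' keys produce a warning and are ignored.
#'
#' Sections: `seed` (integer), `simulate` (fields of [sim_config()]),
#' `inputs` (paths: `annotation`, `counts`, `design`, optional `tracks` as
#' a named map of `<feature>_<cell>` to bedGraph paths), `thresholds`
#' (`fdr_strict` 0.05, `fdr_relaxed` 0.4, `lfc_min` 0.2, `min_consistent`,
#' `q_peaks` 0.05, `q_edges` 0.05), `windows` (`flank_level` 1000,
#' `flank_metagene` 2000, `bin` 50), `network_gene_set`
#' (`"extended"` or `"misregulated"`).
#'
#' @param config Path to a YAML file, or a list.
#' @return A normalised list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config) %||% list()
  defaults <- list(
    seed = 1L,
    simulate = NULL,
    inputs = NULL,
    thresholds = list(fdr_strict = 0.05, fdr_relaxed = 0.4, lfc_min = 0.2,
                      min_consistent = NULL, q_peaks = 0.05,
                      q_edges = 0.05),
    windows = list(flank_level = 1000, flank_metagene = 2000, bin = 50),
    network_gene_set = "extended",
    write_tracks = FALSE
  )
  known <- names(defaults)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    warn(paste0("unknown config key(s) ignored: ",
                paste(unknown, collapse = ", ")))
    config <- config[intersect(names(config), known)]
  }
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  errors <- character()
  th <- cfg$thresholds
  for (nm in c("fdr_strict", "fdr_relaxed", "q_peaks", "q_edges")) {
    v <- th[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      errors <- c(errors, paste0("thresholds$", nm, " must be in (0, 1]"))
    }
  }
  if (!is.numeric(th$lfc_min) || th$lfc_min < 0) {
    errors <- c(errors, "thresholds$lfc_min must be >= 0")
  }
  for (nm in c("flank_level", "flank_metagene", "bin")) {
    v <- cfg$windows[[nm]]
    if (!is.numeric(v) || v <= 0) {
      errors <- c(errors, paste0("windows$", nm, " must be positive"))
    }
  }
  if (!cfg$network_gene_set %in% c("extended", "misregulated")) {
    errors <- c(errors, "network_gene_set must be 'extended' or 'misregulated'")
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    cfg$simulate <- list()
  }
  if (!is.null(cfg$inputs)) {
    for (nm in c("annotation", "counts", "design")) {
      if (is.null(cfg$inputs[[nm]]) || !file.exists(cfg$inputs[[nm]])) {
        errors <- c(errors, paste0("inputs$", nm, " missing or not found"))
      }
    }
  }
  if (length(errors)) {
    gp_stop("invalid pipeline config:\n  - ",
            paste(errors, collapse = "\n  - "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Mean log2 counts-per-million of one embryo group
#'
#' The per-gene expression feature used in the partial-correlation
#' networks: the mean over the group's samples of
#' `log2(cpm + pseudocount)`.
#'
#' @param counts Counts tibble (`gene_id` + samples).
#' @param design Design tibble.
#' @param group `"sperm_embryo"` or `"spermatid_embryo"`.
#' @param pseudocount Default 0.5.
#' @return Tibble with `gene_id` and `expression`.
#' @export
expression_feature <- function(counts, design, group, pseudocount = 0.5) {
  m <- count_mat(counts, design)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  cols <- design$sample[design$group == group]
  tibble(gene_id = counts$gene_id,
         expression = rowMeans(log2(cpm[, cols, drop = FALSE] +
                                      pseudocount)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> quantify -> differential expression
#' -> network integration -> enrichment from one config, writing each
#' stage's TSV outputs, a `summary.json` and a `manifest.json` (config
#' hash, seed, per-stage row counts) to `outdir`. Rerunning with an
#' identical config is a no-op unless `force = TRUE`.
#'
#' @param config A [validate_config()] result, YAML path, or list.
#' @param outdir Output directory.
#' @param force Recompute even when a manifest with the same config hash
#'   exists.
#' @param verbose Log one line per stage.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir, force = FALSE,
                         verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  old <- options(gameteprog.verbose = verbose)
  on.exit(options(old), add = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  manifest_path <- file.path(outdir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    if (identical(prev$config_hash, cfg_hash)) {
      gp_log("config unchanged; skipping (use force = TRUE to rerun)")
      return(invisible(jsonlite::read_json(file.path(outdir,
                                                     "summary.json"))))
    }
  }
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   stages = list())
  stage <- function(name, expr) {
    gp_log("stage: ", name)
    tryCatch(expr, error = function(e) {
      gp_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # --- data -----------------------------------------------------------
  sim <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, modifyList(config$simulate,
                                           list(seed = config$seed)))
      s <- simulate_study(sc)
      write_annotation_bed(s$genes, file.path(outdir, "annotation.bed"))
      readr::write_tsv(s$truth, file.path(outdir, "truth.tsv"),
                       progress = FALSE)
      readr::write_tsv(s$counts, file.path(outdir, "counts.tsv"),
                       progress = FALSE)
      readr::write_tsv(s$design, file.path(outdir, "design.tsv"),
                       progress = FALSE)
      if (isTRUE(config$write_tracks)) {
        for (nm in names(s$tracks)) {
          write_coverage(s$tracks[[nm]],
                         file.path(outdir, paste0(nm, ".bedGraph")))
        }
      }
      s
    })
    genes <- sim$genes
    counts <- sim$counts
    design <- sim$design
    tracks <- sim$tracks
  } else {
    genes <- stage("load_annotation",
                   read_annotation(config$inputs$annotation))
    cd <- stage("load_counts",
                read_counts(config$inputs$counts, config$inputs$design))
    counts <- cd$counts
    design <- cd$design
    tracks <- NULL
    if (!is.null(config$inputs$tracks)) {
      tracks <- stage("load_tracks",
                      purrr::imap(config$inputs$tracks,
                                  \(p, nm) read_coverage(p, nm)))
    }
  }
  manifest$stages$data <- list(n_genes = nrow(genes),
                               n_samples = nrow(design))

  # --- quantify -------------------------------------------------------
  th <- config$thresholds
  wd <- config$windows
  levels_by_cell <- list()
  peaks <- list()
  if (!is.null(tracks)) {
    qt <- stage("quantify", {
      for (cell in CELLS) {
        input <- tracks[[paste0("input_", cell)]]
        feats <- list()
        for (mk in MARKS) {
          trk <- tracks[[paste0(mk, "_", cell)]]
          if (is.null(trk)) next
          feats[[mk]] <- promoter_levels(genes, trk, input,
                                         flank = wd$flank_level)
          peaks[[paste0(mk, "_", cell)]] <-
            call_promoter_peaks(genes, trk, input, flank = wd$flank_level,
                                q_threshold = th$q_peaks)
        }
        for (what in c("occupancy", "meDNA")) {
          trk <- tracks[[paste0(what, "_", cell)]]
          if (!is.null(trk)) {
            feats[[what]] <- promoter_levels(genes, trk, input,
                                             flank = wd$flank_level)
          }
        }
        levels_by_cell[[cell]] <- feats
      }
      wide <- purrr::imap(levels_by_cell, function(feats, cell) {
        out <- tibble(gene_id = genes$gene_id)
        for (nm in names(feats)) {
          out[[paste0(nm, "_", cell)]] <-
            feats[[nm]]$level[match(out$gene_id, feats[[nm]]$gene_id)]
        }
        out
      }) |> purrr::reduce(left_join, by = "gene_id")
      readr::write_tsv(wide, file.path(outdir, "promoter_levels.tsv"),
                       progress = FALSE)
      pk <- purrr::imap(peaks, \(p, nm) mutate(p, track = nm)) |>
        list_rbind()
      readr::write_tsv(pk, file.path(outdir, "peaks.tsv"), progress = FALSE)
      wide
    })
    manifest$stages$quantify <- list(n_rows = nrow(qt))
  }

  # --- differential expression ---------------------------------------
  de <- stage("differential_expression", {
    d <- run_de(counts, design, min_consistent = th$min_consistent,
                fdr_strict = th$fdr_strict, fdr_relaxed = th$fdr_relaxed,
                lfc_min = th$lfc_min)
    readr::write_tsv(as_tibble(d), file.path(outdir, "de.tsv"),
                     progress = FALSE)
    d
  })
  sets <- define_gene_sets(de, th$fdr_strict, th$fdr_relaxed, th$lfc_min)
  writeLines(sets$misregulated, file.path(outdir, "misregulated.txt"))
  writeLines(sets$extended, file.path(outdir, "extended.txt"))
  manifest$stages$differential_expression <-
    list(n_tested = nrow(de), n_misregulated = length(sets$misregulated),
         n_extended = length(sets$extended))

  # --- integrate ------------------------------------------------------
  networks <- list()
  if (!is.null(tracks)) {
    networks <- stage("integrate", {
      gene_set <- sets[[config$network_gene_set]]
      nets <- list()
      for (cell in CELLS) {
        grp <- paste0(if (cell == "sperm") "sperm" else "spermatid",
                      "_embryo")
        feats <- levels_by_cell[[cell]] |>
          purrr::map(\(tbl) tbl[, c("gene_id", "level")])
        feats$expression <- expression_feature(counts, design, grp)
        fm <- build_feature_matrix(feats, gene_set)
        fit <- partial_correlation(fm, shrinkage = "auto")
        net <- build_network(edge_significance(fit),
                             q_threshold = th$q_edges,
                             nodes = fit$features)
        readr::write_tsv(tidy(net),
                         file.path(outdir, paste0("network_", cell,
                                                  ".tsv")),
                         progress = FALSE)
        nets[[cell]] <- net
      }
      nets
    })
    manifest$stages$integrate <-
      purrr::map(networks, \(n) list(n_kept = sum(n$edges$kept)))
  }

  # --- enrich ---------------------------------------------------------
  enrichment <- NULL
  if (length(peaks)) {
    enrichment <- stage("enrich", {
      rows <- purrr::imap(peaks, function(pk, nm) {
        hits_set <- sum(pk$has_peak[pk$gene_id %in% sets$misregulated])
        res <- chisq_enrichment(hits_set, length(sets$misregulated),
                                sum(pk$has_peak), nrow(pk))
        mutate(res, track = nm,
               pct_set = 100 * hits_set / length(sets$misregulated),
               pct_genome = 100 * sum(pk$has_peak) / nrow(pk))
      }) |> list_rbind()
      readr::write_tsv(rows, file.path(outdir, "enrichment.tsv"),
                       progress = FALSE)
      rows
    })
    manifest$stages$enrich <- list(n_tests = nrow(enrichment))
  }

  summary <- list(
    seed = config$seed,
    n_genes = nrow(genes),
    n_tested = nrow(de),
    n_misregulated = length(sets$misregulated),
    n_extended = length(sets$extended),
    networks = purrr::map(networks, function(n) {
      kept <- n$edges[n$edges$kept, ]
      purrr::pmap(list(kept$from, kept$to, kept$pcor),
                  \(f, t, p) list(from = f, to = t, pcor = p))
    }),
    enrichment = if (!is.null(enrichment)) {
      setNames(as.list(enrichment$p), enrichment$track)
    }
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(summary)
}

#' Per-gene feature tables for one gamete cell type
#'
#' Convenience assembly of the inputs to [build_feature_matrix()]: promoter
#' levels of each histone mark, nucleosome occupancy and DNA methylation
#' (each against the cell's input track), plus the expression of the
#' corresponding embryo group.
#'
#' @param genes Gene annotation tibble.
#' @param tracks Named list of [coverage_track()]s using the
#'   `<feature>_<cell>` naming scheme of [simulate_tracks()].
#' @param counts,design Count matrix and design tibbles.
#' @param cell `"sperm"` or `"spermatid"`.
#' @param flank Promoter window half-width in bp (default 1000).
#' @return Named list of tibbles (`gene_id`, value), one per feature.
#' @export
cell_feature_tables <- function(genes, tracks, counts, design, cell,
                                flank = 1000) {
  stopifnot(cell %in% CELLS)
  input <- tracks[[paste0("input_", cell)]]
  feats <- list()
  for (nm in c(MARKS, "occupancy", "meDNA")) {
    trk <- tracks[[paste0(nm, "_", cell)]]
    if (is.null(trk)) next
    feats[[nm]] <- promoter_levels(genes, trk, input,
                                   flank = flank)[, c("gene_id", "level")]
  }
  feats$expression <- expression_feature(counts, design,
                                         paste0(cell, "_embryo"))
  feats
}
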