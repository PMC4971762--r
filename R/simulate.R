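#' Simulation configuration
#'
#' Parameters of the synthetic study generator. The generator emulates the
#' epigenetic programming model: a small fraction of "programmed" genes
#' carry H3K27me3 in both gamete cell types but H3K4me2/3 in the spermatid
#' only, and are up-regulated in spermatid-derived embryos; the remaining
#' genes split into active (H3K4me2/3 in both cells), repressed (H3K27me3
#' and H3K9me3 in both) and unmarked classes with no expression shift.
#' Nucleosome occupancy and DNA methylation peak at every TSS with a 1.5x
#' higher amplitude in sperm.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_experiments Paired experiments (default 7).
#' @param gene_spacing TSS spacing in bp (default 5000).
#' @param chrom_length Chromosome length (default `n_genes * gene_spacing`).
#' @param fraction_programmed Fraction of programmed genes (default 0.01).
#' @param fraction_programmed_down Fraction of programmed genes that are
#'   down- rather than up-regulated (default 0: all up).
#' @param effect_logfc True log2 fold-change of programmed genes
#'   (default 1.5).
#' @param nb_dispersion NB dispersion of embryo counts (default 0.05).
#' @param library_size Expected counts per sample (default 1e6).
#' @param mark_signal_height Peak height of the Gaussian promoter bump, in
#'   signal units per base (default 10).
#' @param bump_sd Standard deviation of the promoter bump in bp
#'   (default 300).
#' @param background_noise_sd SD of the nonnegative (truncated-normal)
#'   background noise (default 0.25).
#' @param noise_bin Resolution in bp at which tracks are generated
#'   (default 50).
#' @param intensity_sdlog Log-SD of the per-(gene, feature) intensity
#'   factor (default 1.3): every mark, occupancy and methylation level has
#'   gene-to-gene variation that embryo expression responds to.
#' @param bivalency_sdlog Log-SD of the per-gene bivalency factor (default
#'   1.7). At programmed genes this factor multiplies the H3K4me2,
#'   H3K4me3 and H3K27me3 intensities jointly, so the coexisting marks
#'   covary across promoters.
#' @param track_jitter_sdlog Log-SD of the independent per-(gene, track)
#'   jitter on bump heights (default 0.1).
#' @param occupancy_sperm_ratio Sperm / spermatid amplitude ratio of the
#'   occupancy and methylation bumps (default 1.5).
#' @param activation_log2fc,repression_log2fc Class-level log2 expression
#'   shift of an active promoter state (H3K4me2/3 present; default +0.5) and
#'   per repressive mark present (H3K27me3, H3K9me3; default -2 each).
#' @param activation_slope,repression_slope Additional log2 expression
#'   change per natural-log unit of the corresponding mark's intensity
#'   (defaults 1 and 0.3): promoters with stronger activating marks are
#'   expressed higher, strongly repressed promoters lower.
#' @param meDNA_slope,occupancy_slope Log2 expression decrease per
#'   natural-log unit of promoter DNA-methylation and nucleosome-occupancy
#'   intensity (defaults 0.5 each).
#' @param seed Integer seed; fixes every downstream draw through one child
#'   stream per generator.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000, n_experiments = 7,
                       gene_spacing = 5000,
                       chrom_length = n_genes * gene_spacing,
                       fraction_programmed = 0.01,
                       fraction_programmed_down = 0,
                       effect_logfc = 1.5, nb_dispersion = 0.05,
                       library_size = 1e6, mark_signal_height = 10,
                       bump_sd = 300, background_noise_sd = 0.25,
                       noise_bin = 50, intensity_sdlog = 1.3,
                       bivalency_sdlog = 1.7,
                       track_jitter_sdlog = 0.1,
                       occupancy_sperm_ratio = 1.5,
                       activation_log2fc = 0.5, repression_log2fc = 2,
                       activation_slope = 1, repression_slope = 0.3,
                       meDNA_slope = 0.5, occupancy_slope = 0.5,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_experiments = n_experiments,
              gene_spacing = gene_spacing, chrom_length = chrom_length,
              fraction_programmed = fraction_programmed,
              fraction_programmed_down = fraction_programmed_down,
              effect_logfc = effect_logfc, nb_dispersion = nb_dispersion,
              library_size = library_size,
              mark_signal_height = mark_signal_height, bump_sd = bump_sd,
              background_noise_sd = background_noise_sd,
              noise_bin = noise_bin, intensity_sdlog = intensity_sdlog,
              bivalency_sdlog = bivalency_sdlog,
              track_jitter_sdlog = track_jitter_sdlog,
              occupancy_sperm_ratio = occupancy_sperm_ratio,
              activation_log2fc = activation_log2fc,
              repression_log2fc = repression_log2fc,
              activation_slope = activation_slope,
              repression_slope = repression_slope,
              meDNA_slope = meDNA_slope,
              occupancy_slope = occupancy_slope, seed = seed)
  pos <- c("n_genes", "n_experiments", "gene_spacing", "chrom_length",
           "library_size", "mark_signal_height", "bump_sd", "noise_bin")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      gp_stop("config field '", nm, "' must be positive")
    }
  }
  if (cfg$fraction_programmed <= 0 || cfg$fraction_programmed >= 1) {
    gp_stop("fraction_programmed must be in (0, 1)")
  }
  if (cfg$nb_dispersion < 0 || cfg$background_noise_sd < 0 ||
      cfg$effect_logfc < 0) {
    gp_stop("dispersion, noise sd and effect_logfc must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

# One child seed per generator so adding draws to one stage never perturbs
# another; kept below 2^31.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 10007 + stream) %% (2^31 - 1))
}

MARKS <- c("H3K4me2", "H3K4me3", "H3K27me3", "H3K9me3")
CELLS <- c("sperm", "spermatid")

#' Simulate a gene annotation
#'
#' Evenly spaced TSSs on one chromosome, alternating strand; deterministic
#' given the config.
#'
#' @param config A [sim_config()].
#' @return Gene annotation tibble (`gene_id`, `chrom`, `strand`, `tss`).
#' @export
simulate_annotation <- function(config) {
  n <- config$n_genes
  if (n * config$gene_spacing > config$chrom_length) {
    gp_stop("chromosome too small: need n_genes * gene_spacing <= chrom_length")
  }
  tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = "chr1",
    strand = rep_len(c("+", "-"), n),
    tss = as.integer((seq_len(n) - 1L) * config$gene_spacing +
                       config$gene_spacing %/% 2L)
  )
}

#' Write a gene annotation as BED6
#'
#' Each gene is written as the 1-bp interval containing its TSS, oriented
#' so that [read_annotation()] recovers the same TSS on both strands.
#'
#' @param genes Gene annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(genes, path) {
  readr::write_tsv(
    tibble(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1L,
           name = genes$gene_id, score = ".", strand = genes$strand),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Simulate the ground-truth gene classes
#'
#' Assigns each gene a class (programmed with probability
#' `fraction_programmed`; the remainder split active / repressed / unmarked
#' 50/25/25), the implied mark booleans per cell type, a per-gene latent
#' mark intensity factor, and the true log2 fold-change (programmed genes
#' shift by `effect_logfc`, up-regulated in spermatid-derived embryos
#' unless drawn into the optional down class).
#'
#' @param genes Gene annotation tibble.
#' @param config A [sim_config()].
#' @return Truth tibble: `gene_id`, `class`, `true_logfc`, one logical
#'   column per (cell, mark) such as `sperm_H3K27me3`, and the latent
#'   intensity columns `int_<mark>`, `int_occupancy`, `int_meDNA`.
#' @export
simulate_truth <- function(genes, config) {
  n <- nrow(genes)
  withr::with_seed(child_seed(config$seed, 1L), {
    programmed <- runif(n) < config$fraction_programmed
    other <- sample(c("active", "repressed", "unmarked"), n, replace = TRUE,
                    prob = c(0.5, 0.25, 0.25))
    class <- ifelse(programmed, "programmed", other)
    down <- runif(n) < config$fraction_programmed_down
    true_logfc <- ifelse(class == "programmed",
                         ifelse(down, -config$effect_logfc,
                                config$effect_logfc), 0)
    ints <- matrix(rlnorm(n * 6, meanlog = 0,
                          sdlog = config$intensity_sdlog),
                   nrow = n,
                   dimnames = list(NULL, paste0("int_", c(MARKS,
                                                          "occupancy",
                                                          "meDNA"))))
    # coexisting-mark coupling: one bivalency factor scales K4me2/3 and
    # K27me3 jointly at programmed promoters
    bival <- rlnorm(n, meanlog = 0, sdlog = config$bivalency_sdlog)
    for (mk in c("int_H3K4me2", "int_H3K4me3", "int_H3K27me3")) {
      ints[programmed, mk] <- ints[programmed, mk] * bival[programmed]
    }
  })
  truth <- tibble(gene_id = genes$gene_id, class = class,
                  true_logfc = true_logfc) |>
    bind_cols(as_tibble(ints))
  truth$sperm_H3K4me2 <- class == "active"
  truth$sperm_H3K4me3 <- class == "active"
  truth$sperm_H3K27me3 <- class %in% c("programmed", "repressed")
  truth$sperm_H3K9me3 <- class == "repressed"
  truth$spermatid_H3K4me2 <- class %in% c("active", "programmed")
  truth$spermatid_H3K4me3 <- class %in% c("active", "programmed")
  truth$spermatid_H3K27me3 <- class %in% c("programmed", "repressed")
  truth$spermatid_H3K9me3 <- class == "repressed"
  truth
}

#' Simulate gamete epigenome coverage tracks
#'
#' Generates, at `noise_bin` resolution: one ChIP track per (mark, cell)
#' with a Gaussian-shaped bump (sd `bump_sd`, height `mark_signal_height`
#' times the gene's latent intensity for that mark times an independent
#' per-(gene, track) jitter) at the TSS of every gene carrying that mark;
#' occupancy and DNA methylation tracks with a bump at every TSS, sperm
#' amplitude `occupancy_sperm_ratio` times the spermatid one; flat input
#' tracks (baseline 1); and nonnegative truncated-normal background noise
#' everywhere.
#'
#' @param genes Gene annotation tibble.
#' @param truth Truth tibble from [simulate_truth()].
#' @param config A [sim_config()].
#' @return Named list of [coverage_track()]s: `<mark>_<cell>`,
#'   `input_<cell>`, `occupancy_<cell>`, `meDNA_<cell>`.
#' @export
simulate_tracks <- function(genes, truth, config) {
  bin <- config$noise_bin
  n_bins <- ceiling(config$chrom_length / bin)
  centers <- (seq_len(n_bins) - 0.5) * bin
  half <- ceiling(4 * config$bump_sd / bin)

  # per-gene kernel over bins near the TSS (per-base bump value per bin)
  tss_bin <- pmin(pmax(floor(genes$tss / bin) + 1L, 1L), n_bins)
  offsets <- -half:half

  add_bumps <- function(values, gene_idx, heights) {
    for (ii in seq_along(gene_idx)) {
      g <- gene_idx[ii]
      bins <- tss_bin[g] + offsets
      keep <- bins >= 1 & bins <= n_bins
      x <- centers[bins[keep]] - genes$tss[g]
      values[bins[keep]] <- values[bins[keep]] +
        heights[ii] * exp(-x^2 / (2 * config$bump_sd^2))
    }
    values
  }

  withr::with_seed(child_seed(config$seed, 2L), {
    jitter <- matrix(
      rlnorm(nrow(genes) * (length(MARKS) * 2 + 4),
             meanlog = 0, sdlog = config$track_jitter_sdlog),
      nrow = nrow(genes))
    noise <- function() {
      if (config$background_noise_sd == 0) numeric(n_bins)
      else pmax(0, rnorm(n_bins, 0, config$background_noise_sd))
    }
    tracks <- list()
    col <- 1L
    for (cell in CELLS) {
      for (mk in MARKS) {
        marked <- which(truth[[paste0(cell, "_", mk)]])
        h <- config$mark_signal_height * truth[[paste0("int_", mk)]] *
          jitter[, col]
        v <- add_bumps(noise(), marked, h[marked])
        tracks[[paste0(mk, "_", cell)]] <- bin_track(v, bin,
                                                     config$chrom_length,
                                                     paste0(mk, "_", cell))
        col <- col + 1L
      }
    }
    for (cell in CELLS) {
      amp <- if (cell == "sperm") config$occupancy_sperm_ratio else 1
      for (what in c("occupancy", "meDNA")) {
        h <- amp * config$mark_signal_height *
          truth[[paste0("int_", what)]] * jitter[, col]
        v <- add_bumps(noise(), seq_len(nrow(genes)), h)
        tracks[[paste0(what, "_", cell)]] <- bin_track(
          v, bin, config$chrom_length, paste0(what, "_", cell))
        col <- col + 1L
      }
      tracks[[paste0("input_", cell)]] <- bin_track(
        1 + noise(), bin, config$chrom_length, paste0("input_", cell))
    }
    tracks
  })
}

# Binned per-base values -> coverage_track (run length = bin width).
bin_track <- function(values, bin, chrom_length, label) {
  lens <- rep(bin, length(values))
  extra <- sum(lens) - chrom_length
  if (extra > 0) lens[length(lens)] <- lens[length(lens)] - extra
  coverage_track(list(chr1 = S4Vectors::Rle(values, lens)), label)
}

#' Simulate paired embryo RNA-seq counts
#'
#' Baseline per-gene means are log-normal draws (meanlog 4, sdlog 1.5),
#' modulated by the paternal promoter state of the originating cell: an
#' active promoter state (H3K4me2/3) raises log2 expression by
#' `activation_log2fc` plus `activation_slope` times each present K4
#' mark's log intensity, and each repressive feature lowers it (`repression_log2fc`
#' plus `repression_slope` times log intensity for H3K27me3 / H3K9me3;
#' `meDNA_slope` and `occupancy_slope` times log intensity for methylation
#' and occupancy). Means are scaled so the sperm-embryo means sum to
#' `library_size`; spermatid-embryo means are the sperm-embryo means times
#' `2^true_logfc`. Counts are drawn independently per sample from a
#' negative binomial with dispersion `nb_dispersion` (Poisson at
#' dispersion 0).
#'
#' @param genes Gene annotation tibble.
#' @param truth Truth tibble.
#' @param config A [sim_config()].
#' @return List with `counts` (tibble, `gene_id` + `sperm_e*` /
#'   `spermatid_e*` columns) and `design` (tibble).
#' @export
simulate_counts <- function(genes, truth, config) {
  n <- nrow(genes)
  E <- config$n_experiments
  act <- truth$sperm_H3K4me2 | truth$sperm_H3K4me3
  state_shift <-
    config$activation_log2fc * act +
    config$activation_slope *
    (truth$sperm_H3K4me2 * log(truth$int_H3K4me2) +
       truth$sperm_H3K4me3 * log(truth$int_H3K4me3)) -
    config$repression_log2fc *
    (truth$sperm_H3K27me3 + truth$sperm_H3K9me3) -
    config$repression_slope *
    (truth$sperm_H3K27me3 * log(truth$int_H3K27me3) +
       truth$sperm_H3K9me3 * log(truth$int_H3K9me3)) -
    config$meDNA_slope * log(truth$int_meDNA) -
    config$occupancy_slope * log(truth$int_occupancy)
  withr::with_seed(child_seed(config$seed, 3L), {
    q <- rlnorm(n, meanlog = 4, sdlog = 1.5) * 2^state_shift
    mu_sperm <- q / sum(q) * config$library_size
    mu_td <- mu_sperm * 2^truth$true_logfc
    draw <- function(mu) {
      if (config$nb_dispersion == 0) stats::rpois(n, mu)
      else rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    }
    cols <- list()
    for (e in seq_len(E)) cols[[paste0("sperm_e", e)]] <- draw(mu_sperm)
    for (e in seq_len(E)) cols[[paste0("spermatid_e", e)]] <- draw(mu_td)
  })
  counts <- bind_cols(tibble(gene_id = genes$gene_id), as_tibble(cols))
  design <- tibble(
    sample = c(paste0("sperm_e", seq_len(E)),
               paste0("spermatid_e", seq_len(E))),
    group = rep(c("sperm_embryo", "spermatid_embryo"), each = E),
    experiment = rep(seq_len(E), 2)
  )
  list(counts = counts, design = design)
}

#' Simulate a combed-fiber set
#'
#' Fiber lengths are uniform on 50-250 kb; each fiber's replication extent
#' is Beta-distributed with mean `mean_extent` (concentration
#' `concentration`), and disjoint replicated segments are placed to realise
#' that extent exactly.
#'
#' @param n_fibers Number of fibers.
#' @param mean_extent Mean replication extent in (0, 1).
#' @param seed Integer seed.
#' @param concentration Beta concentration (a + b; default 10).
#' @return Fiber tibble (`fiber_id`, `start`, `end`, `type`) as accepted by
#'   [replication_extent()]; coordinates in kb.
#' @export
simulate_fibers <- function(n_fibers, mean_extent, seed = 1,
                            concentration = 10) {
  if (mean_extent <= 0 || mean_extent >= 1) {
    gp_stop("mean_extent must be in the open interval (0, 1)")
  }
  if (n_fibers == 0) {
    return(tibble(fiber_id = character(), start = numeric(),
                  end = numeric(), type = character()))
  }
  withr::with_seed(child_seed(seed, 4L), {
    len <- runif(n_fibers, 50, 250)
    extent <- rbeta(n_fibers, mean_extent * concentration,
                    (1 - mean_extent) * concentration)
    rows <- map(seq_len(n_fibers), function(i) {
      fid <- sprintf("fiber%04d", i)
      target <- extent[i] * len[i]
      k <- 1L + stats::rpois(1, 2)
      # split the replicated length into k parts, the gaps into k + 1
      parts <- diff(c(0, sort(runif(k - 1)), 1)) * target
      gaps <- diff(c(0, sort(runif(k)), 1)) * (len[i] - target)
      starts <- cumsum(gaps)[seq_len(k)] + c(0, cumsum(parts))[seq_len(k)]
      bind_rows(
        tibble(fiber_id = fid, start = 0, end = len[i], type = "total"),
        tibble(fiber_id = fid, start = starts, end = starts + parts,
               type = "replicated")
      )
    })
    list_rbind(rows)
  })
}

#' Simulate a complete study
#'
#' Runs every generator under one seed: annotation, truth table, epigenome
#' tracks, paired embryo counts, an identity-with-dropout ortholog map and
#' a fiber set.
#'
#' @param config A [sim_config()].
#' @param tracks Generate coverage tracks (default `TRUE`; the slowest
#'   part).
#' @param n_fibers,mean_extent Fiber-set parameters (defaults 200, 0.3).
#' @return List: `config`, `genes`, `truth`, `tracks`, `counts`, `design`,
#'   `ortholog_map`, `fibers`.
#' @export
simulate_study <- function(config = sim_config(), tracks = TRUE,
                           n_fibers = 200, mean_extent = 0.3) {
  genes <- simulate_annotation(config)
  truth <- simulate_truth(genes, config)
  trk <- if (tracks) simulate_tracks(genes, truth, config) else NULL
  cnt <- simulate_counts(genes, truth, config)
  omap <- withr::with_seed(child_seed(config$seed, 5L), {
    keep <- runif(nrow(genes)) < 0.9
    tibble(source_gene_id = genes$gene_id[keep],
           target_gene_id = paste0("HS_", toupper(genes$gene_id[keep])))
  })
  fibers <- simulate_fibers(n_fibers, mean_extent, seed = config$seed)
  list(config = config, genes = genes, truth = truth, tracks = trk,
       counts = cnt$counts, design = cnt$design, ortholog_map = omap,
       fibers = fibers)
}

#' Write a simulated study to disk
#'
#' Emits the plain-text interchange files: annotation BED, per-track
#' bedGraphs, counts and design TSVs, truth TSV, ortholog TSV and fiber
#' BED.
#'
#' @param sim Result of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_annotation_bed(sim$genes, file.path(outdir, "annotation.bed"))
  readr::write_tsv(sim$truth, file.path(outdir, "truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$counts, file.path(outdir, "counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$design, file.path(outdir, "design.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$ortholog_map, file.path(outdir, "orthologs.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    sim$fibers |>
      mutate(score = ".", strand = "+") |>
      select(all_of(c("fiber_id", "start", "end", "type", "score",
                      "strand"))),
    file.path(outdir, "fibers.bed"), col_names = FALSE, progress = FALSE)
  if (!is.null(sim$tracks)) {
    for (nm in names(sim$tracks)) {
      write_coverage(sim$tracks[[nm]],
                     file.path(outdir, paste0(nm, ".bedGraph")))
    }
  }
  invisible(outdir)
}

#' Sample from a Gaussian graphical model with planted partial correlations
#'
#' Builds the precision matrix with unit diagonal and off-diagonal
#' `-pcor_ij`, checks positive definiteness, and draws `n` multivariate
#' normal rows. Used to benchmark network recovery.
#'
#' @param n Number of rows.
#' @param pcor Symmetric matrix of planted partial correlations (diagonal
#'   ignored).
#' @param seed Integer seed.
#' @return Tibble with `gene_id` and one column per feature.
#' @export
simulate_ggm <- function(n, pcor, seed = 1) {
  k <- ncol(pcor)
  Omega <- -pcor
  diag(Omega) <- 1
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) gp_stop("planted partial correlations are not positive definite")
  Sigma <- solve(Omega)
  X <- withr::with_seed(child_seed(seed, 6L),
                        MASS::mvrnorm(n, mu = rep(0, k), Sigma = Sigma))
  colnames(X) <- colnames(pcor) %||% paste0("f", seq_len(k))
  bind_cols(tibble(gene_id = sprintf("g%05d", seq_len(n))), as_tibble(X))
}
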