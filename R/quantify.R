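#' TSS metagene profile of a coverage track
#'
#' Averages track signal in fixed-width bins across TSS-centred windows of
#' all (usable) genes. Windows of minus-strand genes are orientation-flipped
#' so that upstream sequence is always on the left. Each bin value is the
#' mean per-base signal in the bin, averaged (unweighted) over genes; genes
#' whose window is clipped at the chromosome start contribute only their
#' surviving bins.
#'
#' @param genes Gene annotation tibble ([read_annotation()]).
#' @param track A [coverage_track()].
#' @param flank Half-width of the profiled window in bp (default 2000).
#' @param bin Bin width in bp; must divide `2 * flank` (default 50).
#' @param depth_normalize Scale the track to signal-per-million before
#'   profiling (default `TRUE`).
#' @return A tibble of class `gp_metagene` with columns `bin_center`
#'   (bp relative to the TSS, negative = upstream), `mean_signal` and
#'   `n_genes` (genes contributing to the bin). The total number of usable
#'   genes is stored in `attr(, "n_genes")`.
#' @export
metagene_profile <- function(genes, track, flank = 2000, bin = 50,
                             depth_normalize = TRUE) {
  if (flank <= 0 || bin <= 0 || (2 * flank) %% bin != 0) {
    gp_stop("bin must be a positive divisor of 2*flank")
  }
  usable <- genes$chrom %in% names(track$cov)
  if (!any(usable)) gp_stop("no usable genes: no gene lies on a track chromosome")
  if (any(!usable)) {
    gp_log(sum(!usable), " gene(s) dropped: chromosome absent from track")
  }
  g <- genes[usable, ]
  scale <- 1
  if (depth_normalize) {
    if (track$total_signal <= 0) gp_stop("empty track: total signal is 0")
    scale <- 1e6 / track$total_signal
  }
  nb <- as.integer(2 * flank / bin)
  ng <- nrow(g)
  b <- rep(seq_len(nb) - 1L, times = ng)
  gi <- rep(seq_len(ng), each = nb)
  raw_start <- g$tss[gi] - as.integer(flank) + b * as.integer(bin)
  wins <- tibble(
    chrom = g$chrom[gi],
    start = pmax(0L, raw_start),
    end = pmax(0L, raw_start + as.integer(bin))
  )
  sums <- track_window_sums(track, wins) * scale
  width <- wins$end - wins$start
  # flip bin order for minus-strand genes so upstream is left
  bin_idx <- ifelse(g$strand[gi] == "+", b + 1L, nb - b)
  ok <- width > 0
  dat <- tibble(bin_idx = bin_idx[ok],
                per_base = sums[ok] / width[ok])
  prof <- dat |>
    group_by(.data$bin_idx) |>
    summarise(mean_signal = mean(.data$per_base), n_genes = dplyr::n(),
              .groups = "drop") |>
    mutate(bin_center = -flank + (.data$bin_idx - 0.5) * bin) |>
    select(all_of(c("bin_center", "mean_signal", "n_genes"))) |>
    arrange(.data$bin_center)
  attr(prof, "n_genes") <- ng
  attr(prof, "label") <- track$label
  class(prof) <- c("gp_metagene", class(prof))
  prof
}

#' Per-gene promoter signal levels (log2 IP/input)
#'
#' Quantifies the "overall level" of a mark at each promoter as the
#' depth-scaled, pseudocounted log2 ratio of IP over input signal summed in
#' the TSS +/- `flank` window:
#' `log2((ip * 1e6/ip_total + pc) / (input * 1e6/input_total + pc))`.
#'
#' @param genes Gene annotation tibble.
#' @param ip,input IP and matched input [coverage_track()]s.
#' @param flank Window half-width in bp (default 1000).
#' @param pseudocount Pseudocount in signal-per-million units (> 0,
#'   default 1).
#' @return Tibble with `gene_id`, `ip_spm`, `input_spm` (signal-per-million
#'   window sums) and `level`.
#' @export
promoter_levels <- function(genes, ip, input, flank = 1000, pseudocount = 1) {
  if (pseudocount <= 0) gp_stop("pseudocount must be > 0")
  if (ip$total_signal <= 0 || input$total_signal <= 0) {
    gp_stop("empty track: IP and input must have positive total signal")
  }
  wins <- tss_windows(genes, flank)
  ip_spm <- track_window_sums(ip, wins) * 1e6 / ip$total_signal
  input_spm <- track_window_sums(input, wins) * 1e6 / input$total_signal
  tibble(gene_id = genes$gene_id,
         ip_spm = ip_spm,
         input_spm = input_spm,
         level = log2((ip_spm + pseudocount) / (input_spm + pseudocount)))
}

#' Call promoter peaks with a Poisson window test
#'
#' Tests each promoter window for IP signal exceeding the input-derived
#' local expectation. Window signal is integerised after depth-matching the
#' input to the IP total; the per-gene p-value is the upper-tail Poisson
#' probability `P(X >= k_ip)` with rate `max(k_input_scaled, lambda_floor)`;
#' q-values are Benjamini-Hochberg across all genes of the track pair.
#'
#' @param genes Gene annotation tibble.
#' @param ip,input IP and matched input [coverage_track()]s.
#' @param flank Window half-width in bp (default 1000).
#' @param q_threshold BH q-value cutoff in (0, 1) (default 0.05).
#' @param lambda_floor Minimum Poisson rate in expected counts (default 1).
#' @return Tibble with `gene_id`, `k_ip`, `lambda`, `p`, `q`, `has_peak`.
#' @export
call_promoter_peaks <- function(genes, ip, input, flank = 1000,
                                q_threshold = 0.05, lambda_floor = 1) {
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold >= 1) {
    gp_stop("q_threshold must be in (0, 1)")
  }
  if (ip$total_signal <= 0 || input$total_signal <= 0) {
    gp_stop("empty track: IP and input must have positive total signal")
  }
  wins <- tss_windows(genes, flank)
  k_ip <- round(track_window_sums(ip, wins))
  k_in <- round(track_window_sums(input, wins) *
                  ip$total_signal / input$total_signal)
  lambda <- pmax(k_in, lambda_floor)
  p <- ppois(k_ip - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  tibble(gene_id = genes$gene_id, k_ip = k_ip, lambda = lambda,
         p = p, q = q, has_peak = q < q_threshold)
}

#' Percentage of a gene set carrying a peak
#'
#' @param peaks Peak-call tibble from [call_promoter_peaks()].
#' @param gene_set Character vector of gene ids; must all be present in
#'   `peaks`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_with_peak <- function(peaks, gene_set) {
  if (length(gene_set) == 0) gp_stop("empty gene set")
  missing <- setdiff(gene_set, peaks$gene_id)
  if (length(missing)) {
    gp_stop("gene(s) absent from peak table: ",
            paste(head(missing, 3), collapse = ", "))
  }
  100 * mean(peaks$has_peak[match(gene_set, peaks$gene_id)])
}

#' Write peak calls as BED6
#'
#' Scores are `-10 * log10(q)` capped at 1000, the usual peak-score
#' convention.
#'
#' @param peaks Peak-call tibble.
#' @param genes Gene annotation tibble used for the calls.
#' @param path Output path.
#' @param flank Window half-width used for the calls (default 1000).
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, genes, path, flank = 1000) {
  wins <- tss_windows(genes, flank)
  hit <- peaks |> filter(.data$has_peak)
  w <- wins[match(hit$gene_id, wins$gene_id), ]
  score <- pmin(1000, round(-10 * log10(pmax(hit$q, 1e-100))))
  readr::write_tsv(
    tibble(chrom = w$chrom, start = w$start, end = w$end,
           name = hit$gene_id, score = score, strand = w$strand),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.gp_metagene <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_center, y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from TSS (bp)", y = "mean signal",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}
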