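#' Coverage tracks
#'
#' A coverage track stores per-base, nonnegative signal (read pileup from
#' ChIP-seq, MNase-seq or MBD-seq) as run-length encoded vectors, one per
#' chromosome, together with the genome-wide total signal used for depth
#' normalisation (signal-per-million scaling).
#'
#' @param cov A named list of numeric vectors or an [IRanges::RleList], one
#'   element per chromosome.
#' @param label Free-text label (mark, cell type, IP/input).
#' @return An object of class `coverage_track` with fields `cov`
#'   (`RleList`), `total_signal` and `label`.
#' @export
coverage_track <- function(cov, label = "") {
  if (is.list(cov) && !methods::is(cov, "RleList")) {
    cov <- IRanges::RleList(lapply(cov, S4Vectors::Rle), compress = FALSE)
  }
  mins <- vapply(cov, function(x) if (length(x) == 0) 0 else min(S4Vectors::runValue(x)),
                 numeric(1))
  if (length(mins) && any(mins < 0)) gp_stop("coverage values must be >= 0")
  total <- sum(vapply(cov, function(x) sum(as.numeric(S4Vectors::runValue(x)) *
                                             S4Vectors::runLength(x)), numeric(1)))
  structure(list(cov = cov, total_signal = total, label = label),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$label, "\n  chromosomes: ",
      paste(names(x$cov), collapse = ", "),
      "\n  total signal: ", format(x$total_signal), "\n", sep = "")
  invisible(x)
}

#' Read a bedGraph coverage track
#'
#' bedGraph intervals are 0-based half-open. Overlapping intervals are
#' summed (additive pileup semantics); positions not covered by any interval
#' are 0. Negative values are rejected.
#'
#' @param path Path to a bedGraph file.
#' @param label Track label; defaults to the file name.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, label = basename(path)) {
  if (!file.exists(path)) gp_stop("coverage file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    return(coverage_track(IRanges::RleList(compress = FALSE), label))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) gp_stop("malformed bedGraph '", path,
                                             "': ", conditionMessage(e)))
  if (length(gr) == 0) {
    return(coverage_track(IRanges::RleList(compress = FALSE), label))
  }
  if (any(gr$score < 0)) gp_stop("negative coverage value in ", path)
  cov <- GenomicRanges::coverage(gr, weight = "score")
  coverage_track(cov, label)
}

#' Write a coverage track as bedGraph
#'
#' Zero-signal runs are omitted; re-reading the file reproduces the original
#' per-base values exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  if (length(track$cov) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- methods::as(track$cov, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# Summed signal over 0-based half-open windows. `windows` needs columns
# chrom, start, end; windows beyond the stored track extent count as zero.
# Returns a numeric vector aligned with the rows of `windows`.
track_window_sums <- function(track, windows) {
  out <- numeric(nrow(windows))
  if (nrow(windows) == 0) return(out)
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    if (!ch %in% names(track$cov)) next
    rle <- track$cov[[ch]]
    s1 <- windows$start[idx] + 1L  # to 1-based closed
    e1 <- windows$end[idx]
    need <- max(e1)
    if (need > length(rle)) {
      rle <- c(rle, S4Vectors::Rle(0, need - length(rle)))
    }
    ok <- e1 >= s1 & e1 >= 1
    if (!any(ok)) next
    v <- IRanges::Views(rle, start = pmax(s1[ok], 1L), end = e1[ok])
    out[idx[ok]] <- IRanges::viewSums(v)
  }
  out
}

# Multiply every value of a track by `factor` (used for signal-per-million
# scaling); total_signal is rescaled accordingly.
scale_track <- function(track, factor) {
  cov <- IRanges::RleList(lapply(track$cov, function(x) x * factor),
                          compress = FALSE)
  coverage_track(cov, track$label)
}
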