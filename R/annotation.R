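#' Read a gene annotation into a TSS table
#'
#' Reads gene annotation from a GTF/GFF file or a BED-like table and reduces
#' it to one row per gene with the transcription start site (TSS) as the
#' anchor coordinate. All coordinates in the package are 0-based, half-open
#' (BED convention); GTF/GFF input (1-based, closed) is converted on read.
#'
#' For a `+` strand gene the TSS is the feature start; for a `-` strand gene
#' it is `end - 1` (the last base of the feature, 0-based). Duplicated
#' `gene_id`s keep the first occurrence with a warning.
#'
#' @param path Path to a GTF/GFF file (detected by extension `.gtf`, `.gff`,
#'   `.gff3`) or a BED-like whitespace-separated table with columns
#'   chrom, start, end, name, (score), strand.
#' @param feature For GTF/GFF input, the feature type to keep (default
#'   `"gene"`; falls back to `"transcript"` then to all rows if absent).
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss` and,
#'   when available, `gene_name`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t500\tgeneA\t.\t+", "chr1\t100\t500\tgeneB\t.\t-"), bed)
#' read_annotation(bed)
#' @export
read_annotation <- function(path, feature = "gene") {
  if (!file.exists(path)) gp_stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    keep <- as.character(gr$type) == feature
    if (!any(keep) && feature == "gene") keep <- as.character(gr$type) == "transcript"
    if (any(keep)) gr <- gr[keep]
    ids <- gr$gene_id %||% gr$ID %||% gr$Name
    if (is.null(ids)) gp_stop("no gene_id/ID/Name attribute in ", path)
    tbl <- tibble(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      # GRanges is 1-based closed; internal convention is 0-based half-open
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_name = as.character(gr$gene_name %||% gr$Name %||% ids)
    )
  } else {
    tbl <- read_bedlike(path)
  }
  bad <- !tbl$strand %in% c("+", "-")
  if (any(bad)) {
    gp_stop("unknown strand symbol '", tbl$strand[which(bad)[1]],
            "' at line ", which(bad)[1])
  }
  bad_coord <- !(tbl$start >= 0 & tbl$end > tbl$start)
  if (any(bad_coord)) {
    gp_stop("malformed row (need 0 <= start < end) at line ", which(bad_coord)[1])
  }
  dup <- duplicated(tbl$gene_id)
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicated gene_id(s); keeping first occurrence"))
    tbl <- tbl[!dup, ]
  }
  tbl |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) |>
    mutate(tss = as.integer(.data$tss)) |>
    select(all_of(c("gene_id", "chrom", "strand", "tss")),
           any_of("gene_name"))
}

read_bedlike <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) gp_stop("empty annotation file: ", path)
  if (ncol(raw) < 4) gp_stop("BED-like annotation needs >= 4 columns")
  # BED6: chrom start end name score strand; BED4 variant: chrom start end
  # name strand
  strand_col <- if (ncol(raw) >= 6) 6L else if (ncol(raw) >= 5) 5L else
    gp_stop("strand column missing in ", path)
  for (ln in seq_len(nrow(raw))) {
    s <- suppressWarnings(as.numeric(raw[[2]][ln]))
    e <- suppressWarnings(as.numeric(raw[[3]][ln]))
    if (is.na(s) || is.na(e)) gp_stop("malformed row at line ", ln)
  }
  tibble(
    gene_id = as.character(raw[[4]]),
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    strand = as.character(raw[[strand_col]])
  )
}

#' TSS-centred windows for a gene table
#'
#' Builds the promoter window `[tss - flank, tss + flank)` for each gene,
#' clipped at coordinate 0 (chromosome start). Windows truncated by clipping
#' are flagged; per-base averaging downstream keeps them unbiased.
#'
#' @param genes A gene annotation tibble from [read_annotation()].
#' @param flank Half-width of the window in bp (> 0).
#' @return The input tibble with `start`, `end` and `clipped` columns added
#'   (0-based half-open).
#' @export
tss_windows <- function(genes, flank) {
  if (!is.numeric(flank) || length(flank) != 1 || flank <= 0) {
    gp_stop("flank must be a single positive number")
  }
  flank <- as.integer(flank)
  genes |>
    mutate(
      start = pmax(0L, .data$tss - flank),
      end = .data$tss + flank,
      clipped = .data$tss - flank < 0L
    )
}

#' Read a two-column ortholog map
#'
#' @param path TSV with a header and two columns: source gene id, target
#'   gene id. Duplicate pairs are allowed and collapsed downstream.
#' @return A tibble with columns `source_gene_id`, `target_gene_id`.
#' @export
read_ortholog_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2) gp_stop("ortholog map needs two columns")
  out <- tibble(source_gene_id = as.character(tbl[[1]]),
                target_gene_id = as.character(tbl[[2]]))
  bad <- is.na(out$source_gene_id) | !nzchar(out$source_gene_id) |
    is.na(out$target_gene_id) | !nzchar(out$target_gene_id)
  if (any(bad)) gp_stop("empty gene id in ortholog map (row ", which(bad)[1], ")")
  out
}
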