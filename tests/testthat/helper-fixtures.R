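# Small in-code fixtures shared across test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A coverage track built from bedGraph text lines.
track_from_text <- function(lines, label = "test") {
  read_coverage(write_lines_tmp(lines, ".bedGraph"), label)
}

# A uniform-signal track covering [0, len) of chr1.
uniform_track <- function(value, len = 10000, label = "uniform") {
  coverage_track(list(chr1 = rep(value, len)), label)
}

# Minimal annotation tibble.
toy_genes <- function(tss, strand = "+", chrom = "chr1") {
  tibble::tibble(
    gene_id = paste0("g", seq_along(tss)),
    chrom = chrom,
    strand = rep_len(strand, length(tss)),
    tss = as.integer(tss)
  )
}

# Small paired count data: E experiments, two groups.
toy_design <- function(E = 3) {
  tibble::tibble(
    sample = c(paste0("sperm_e", 1:E), paste0("spermatid_e", 1:E)),
    group = rep(c("sperm_embryo", "spermatid_embryo"), each = E),
    experiment = rep(1:E, 2)
  )
}

toy_counts <- function(mat, design) {
  tbl <- tibble::as_tibble(as.data.frame(mat))
  names(tbl) <- design$sample
  dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("g", seq_len(nrow(mat)))), tbl)
}
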