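#' Read a paired embryo count matrix and its design
#'
#' The count matrix is a TSV whose first column holds gene ids and remaining
#' columns one sample each; counts must be nonnegative integers. The design
#' TSV maps each sample to a group (`sperm_embryo` or `spermatid_embryo`)
#' and a paired experiment index; every experiment must contribute exactly
#' one sample of each group.
#'
#' @param path Counts TSV (header; first column gene ids).
#' @param design_path Design TSV with columns `sample`, `group`,
#'   `experiment`.
#' @return A list with elements `counts` (tibble, `gene_id` + one column per
#'   sample) and `design` (tibble).
#' @export
read_counts <- function(path, design_path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(counts)[1] <- "gene_id"
  counts$gene_id <- as.character(counts$gene_id)
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  names(design) <- tolower(names(design))
  validate_paired_design(counts, design)
  list(counts = counts, design = as_tibble(design))
}

#' Validate a paired two-group count design
#'
#' @param counts Tibble: `gene_id` plus one integer column per sample.
#' @param design Tibble with columns `sample`, `group` (two levels:
#'   `sperm_embryo`, `spermatid_embryo`) and `experiment` (pair index).
#' @return The validated design, invisibly.
#' @export
validate_paired_design <- function(counts, design) {
  req <- c("sample", "group", "experiment")
  if (!all(req %in% names(design))) {
    gp_stop("design needs columns: ", paste(req, collapse = ", "))
  }
  samples <- setdiff(names(counts), "gene_id")
  missing <- setdiff(samples, design$sample)
  if (length(missing)) {
    gp_stop("sample(s) in count matrix missing from design: ",
            paste(missing, collapse = ", "))
  }
  groups <- sort(unique(as.character(design$group)))
  if (!identical(groups, sort(c("sperm_embryo", "spermatid_embryo")))) {
    gp_stop("design groups must be exactly {sperm_embryo, spermatid_embryo}")
  }
  for (j in samples) {
    v <- counts[[j]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) ||
        any(v != floor(v))) {
      bad <- which(is.na(v) | v < 0 | v != floor(v))[1]
      gp_stop("non-integer or negative count in sample '", j, "' (row ",
              bad, ")")
    }
  }
  d <- design[design$sample %in% samples, ]
  for (e in sort(unique(d$experiment))) {
    g <- sort(as.character(d$group[d$experiment == e]))
    if (!identical(g, sort(c("sperm_embryo", "spermatid_embryo")))) {
      gp_stop("unpaired experiment ", e)
    }
  }
  invisible(design)
}

# counts tibble -> integer matrix (genes x samples) ordered as in design
count_mat <- function(counts, design) {
  m <- as.matrix(counts[, design$sample, drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}
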