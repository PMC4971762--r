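#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: the median, over genes positive in all
#' samples, of the ratio of the sample's count to the per-gene geometric
#' mean reference, rescaled so the factors have geometric mean 1.
#'
#' @param counts Tibble (`gene_id` + one column per sample) or numeric
#'   matrix of counts.
#' @param pseudo_reference If no gene is positive in every sample, fall back
#'   to a reference computed from `log(count + 0.5)` instead of erroring.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- if (is.data.frame(counts)) {
    as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  } else counts
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    if (!pseudo_reference) {
      gp_stop("no gene has positive counts in every sample; ",
              "set pseudo_reference = TRUE to use a pseudocounted reference")
    }
    logref <- rowMeans(log(m + 0.5))
    ratios <- log(m + 0.5) - logref
  } else {
    mm <- m[all_pos, , drop = FALSE]
    logref <- rowMeans(log(mm))
    ratios <- log(mm) - logref
  }
  sf <- exp(apply(ratios, 2, median))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene dispersion `phi = max(0, (s2 - m) / m^2)` from the pooled
#' within-group variance `s2` and grand mean `m` of size-factor-normalised
#' counts. The attribute `common` holds the median per-gene dispersion,
#' which [run_de()] uses as a common dispersion by default.
#'
#' @param counts Tibble or matrix of counts (see [size_factors()]).
#' @param design Design tibble (`sample`, `group`, `experiment`).
#' @param sf Size factors; computed with [size_factors()] when `NULL`.
#' @return Tibble with `gene_id` and `phi`; `attr(, "common")` is the
#'   median dispersion.
#' @export
estimate_dispersion <- function(counts, design, sf = NULL) {
  m <- if (is.data.frame(counts)) count_mat(counts, design) else counts
  groups <- split(seq_len(ncol(m)),
                  as.character(design$group)[match(colnames(m), design$sample)])
  if (any(lengths(groups) < 2)) {
    gp_stop("each group needs at least 2 samples to estimate dispersion")
  }
  if (is.null(sf)) sf <- size_factors(m, pseudo_reference = TRUE)
  y <- sweep(m, 2, sf[colnames(m)], "/")
  phi <- mom_dispersion(y, groups)
  out <- tibble(gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                phi = phi)
  attr(out, "common") <- median(phi)
  out
}

# y: normalised counts matrix; groups: list of column-index vectors.
# Pooled within-group variance and grand mean give a moments estimate of
# the NB dispersion, floored at 0.
mom_dispersion <- function(y, groups) {
  ss <- 0
  df <- 0
  for (idx in groups) {
    sub <- y[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu)^2)
    df <- df + length(idx) - 1
  }
  s2 <- ss / df
  mbar <- rowMeans(y)
  phi <- ifelse(mbar > 0, pmax(0, (s2 - mbar) / mbar^2), 0)
  unname(phi)
}

#' Negative-binomial conditional exact test for one gene
#'
#' Counts are scaled to a common effective library size (divided by their
#' size factors) and rounded; the test conditions on the total `S` of the
#' two group sums and enumerates the probability of every split `s = 0..S`
#' under the null, where the group sums are negative-binomial with means
#' proportional to group size and dispersions `phi / n_group`. The
#' two-sided p-value sums the probabilities of all splits no more likely
#' than the observed one. At `phi = 0` this is the exact conditional
#' binomial test.
#'
#' @param counts_a,counts_b Counts for the two groups (numeric vectors).
#' @param sf_a,sf_b Size factors matching the counts (default 1).
#' @param phi NB dispersion (>= 0).
#' @return Two-sided p-value.
#' @export
nb_exact_test <- function(counts_a, counts_b, sf_a = NULL, sf_b = NULL,
                          phi = 0) {
  if (phi < 0) gp_stop("phi must be >= 0")
  sf_a <- sf_a %||% rep(1, length(counts_a))
  sf_b <- sf_b %||% rep(1, length(counts_b))
  Sa <- round(sum(counts_a / sf_a))
  Sb <- round(sum(counts_b / sf_b))
  nb_exact_p(Sa, Sb, length(counts_a), length(counts_b), phi)
}

# Conditional two-sided p for group sums Sa, Sb with group sizes na, nb.
nb_exact_p <- function(Sa, Sb, na, nb, phi) {
  S <- Sa + Sb
  if (S == 0) {
    gp_log("gene with zero total count: p = 1 by convention")
    return(1)
  }
  prop <- na / (na + nb)
  s <- 0:S
  if (phi <= 0) {
    lw <- dbinom(s, S, prop, log = TRUE)
  } else {
    lw <- dnbinom(s, size = na / phi, mu = S * prop, log = TRUE) +
      dnbinom(S - s, size = nb / phi, mu = S * (1 - prop), log = TRUE)
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  # ties with the observed split's probability are included once
  min(1, sum(w[w <= w[Sa + 1] * (1 + 1e-12)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) (m * p_(j) / j)`, capped at 1
#' and mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) gp_stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cross-replicate sign-consistency filter
#'
#' A gene passes when at least `min_consistent` of its per-experiment
#' log fold-changes share a sign; zeros count toward neither sign.
#'
#' @param lfc Matrix (genes x experiments) or vector of per-experiment
#'   log fold-changes.
#' @param min_consistent Required number of same-sign experiments
#'   (1 <= `min_consistent` <= E).
#' @return Logical vector, one entry per gene.
#' @export
consistency_filter <- function(lfc, min_consistent) {
  if (is.vector(lfc)) lfc <- matrix(lfc, nrow = 1)
  E <- ncol(lfc)
  if (min_consistent < 1 || min_consistent > E) {
    gp_stop("min_consistent must be between 1 and the number of experiments")
  }
  npos <- rowSums(lfc > 0)
  nneg <- rowSums(lfc < 0)
  unname(pmax(npos, nneg) >= min_consistent)
}

#' Paired differential expression between sperm- and spermatid-derived embryos
#'
#' Runs the full count-based pipeline: expressed-gene filter,
#' median-of-ratios normalisation, method-of-moments common dispersion, the
#' NB conditional exact test per gene, BH adjustment, per-experiment log
#' fold-changes and the sign-consistency filter. Fold-changes are
#' `log2(spermatid_embryo / sperm_embryo)`.
#'
#' @param counts Tibble: `gene_id` plus one integer column per sample.
#' @param design Design tibble (`sample`, `group`, `experiment`); validated
#'   with [validate_paired_design()].
#' @param min_consistent Experiments required to share the fold-change sign;
#'   default `E - 1` (at least six out of seven for the seven-pair design).
#' @param fdr_strict FDR cutoff for the misregulated call (default 0.05).
#' @param fdr_relaxed,lfc_min Relaxed FDR and minimum `|logFC|` for the
#'   extended set (defaults 0.4 and 0.2).
#' @param expressed_cpm,expressed_min_samples Expressed-gene filter: keep
#'   genes with counts-per-million above `expressed_cpm` in at least
#'   `expressed_min_samples` samples (defaults 1 and 2).
#' @param dispersion `"common"` (median method-of-moments dispersion,
#'   default), `"gene"` (per-gene), or a single numeric value.
#' @param pseudocount Pseudocount for fold-change computation (default 0.5
#'   normalised counts).
#' @return A tibble of class `gp_de`: `gene_id`, `logFC`, `logCPM`, `p`,
#'   `fdr`, `consistent`, `misregulated`, `extended`, plus one
#'   `lfc_exp<e>` column per experiment. Attributes record the thresholds,
#'   dispersion and size factors.
#' @export
run_de <- function(counts, design, min_consistent = NULL,
                   fdr_strict = 0.05, fdr_relaxed = 0.4, lfc_min = 0.2,
                   expressed_cpm = 1, expressed_min_samples = 2,
                   dispersion = "common", pseudocount = 0.5) {
  validate_paired_design(counts, design)
  design <- design |> arrange(.data$experiment, .data$group)
  m <- count_mat(counts, design)
  E <- length(unique(design$experiment))
  min_consistent <- min_consistent %||% max(1L, E - 1L)

  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  expressed <- rowSums(cpm > expressed_cpm) >= expressed_min_samples
  gp_log(sum(expressed), " of ", nrow(m), " genes pass the expressed filter")
  if (!any(expressed)) gp_stop("no gene passes the expressed filter")
  m <- m[expressed, , drop = FALSE]

  sf <- size_factors(m, pseudo_reference = TRUE)
  y <- sweep(m, 2, sf, "/")
  grp <- as.character(design$group)[match(colnames(m), design$sample)]
  ia <- which(grp == "sperm_embryo")
  ib <- which(grp == "spermatid_embryo")

  phi_tbl <- estimate_dispersion(m, design, sf)
  phi <- switch(
    as.character(dispersion[1]),
    common = rep(attr(phi_tbl, "common"), nrow(m)),
    gene = phi_tbl$phi,
    rep(as.numeric(dispersion), nrow(m))
  )

  Sa <- round(rowSums(y[, ia, drop = FALSE]))
  Sb <- round(rowSums(y[, ib, drop = FALSE]))
  p <- vapply(seq_len(nrow(m)),
              function(i) nb_exact_p(Sa[i], Sb[i], length(ia), length(ib),
                                     phi[i]),
              numeric(1))
  fdr <- bh_adjust(p)

  mean_a <- rowMeans(y[, ia, drop = FALSE])
  mean_b <- rowMeans(y[, ib, drop = FALSE])
  logFC <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  logCPM <- log2(rowMeans(sweep(m, 2, colSums(m), "/") * 1e6) + pseudocount)

  exps <- sort(unique(design$experiment))
  lfc_mat <- vapply(exps, function(e) {
    sa <- design$sample[design$experiment == e &
                          design$group == "sperm_embryo"]
    sb <- design$sample[design$experiment == e &
                          design$group == "spermatid_embryo"]
    log2((y[, sb] + pseudocount) / (y[, sa] + pseudocount))
  }, numeric(nrow(m)))
  if (is.vector(lfc_mat)) lfc_mat <- matrix(lfc_mat, nrow = 1)
  colnames(lfc_mat) <- paste0("lfc_exp", exps)

  consistent <- consistency_filter(lfc_mat, min_consistent)
  out <- tibble(gene_id = rownames(m), logFC = logFC, logCPM = logCPM,
                p = p, fdr = fdr, consistent = consistent) |>
    mutate(misregulated = .data$fdr < fdr_strict & .data$consistent,
           extended = .data$fdr <= fdr_relaxed & abs(.data$logFC) >= lfc_min) |>
    bind_cols(as_tibble(lfc_mat))
  attr(out, "thresholds") <- list(fdr_strict = fdr_strict,
                                  fdr_relaxed = fdr_relaxed,
                                  lfc_min = lfc_min,
                                  min_consistent = min_consistent)
  attr(out, "size_factors") <- sf
  attr(out, "common_dispersion") <- attr(phi_tbl, "common")
  attr(out, "n_experiments") <- E
  class(out) <- c("gp_de", class(out))
  out
}

#' Misregulated and extended gene sets from a DE table
#'
#' The misregulated set is `fdr < fdr_strict` together with the
#' sign-consistency filter; the extended set relaxes to
#' `fdr <= fdr_relaxed` and `|logFC| >= lfc_min` (no consistency
#' requirement).
#'
#' @param de A `gp_de` tibble from [run_de()].
#' @param fdr_strict,fdr_relaxed,lfc_min Thresholds (defaults 0.05, 0.4,
#'   0.2).
#' @return List with character vectors `misregulated` and `extended`.
#' @export
define_gene_sets <- function(de, fdr_strict = 0.05, fdr_relaxed = 0.4,
                             lfc_min = 0.2) {
  stopifnot(all(c("fdr", "logFC", "consistent") %in% names(de)))
  if (fdr_strict <= 0 || fdr_strict >= 1 || fdr_relaxed <= 0 ||
      fdr_relaxed > 1 || lfc_min < 0) {
    gp_stop("thresholds out of range")
  }
  list(
    misregulated = de$gene_id[de$fdr < fdr_strict & de$consistent],
    extended = de$gene_id[de$fdr <= fdr_relaxed & abs(de$logFC) >= lfc_min]
  )
}

#' Pearson correlation between two expression vectors
#'
#' @param x,y Numeric vectors of equal length (per-gene expression).
#' @param subset Optional logical or integer subset (>= 3 elements after
#'   subsetting).
#' @return Pearson correlation coefficient.
#' @export
expression_correlation <- function(x, y, subset = NULL) {
  if (!is.null(subset)) {
    x <- x[subset]
    y <- y[subset]
  }
  if (length(x) < 3) gp_stop("need at least 3 genes to correlate")
  if (sd(x) == 0 || sd(y) == 0) gp_stop("zero variance in expression vector")
  cor(x, y)
}

#' @exportS3Method generics::glance
glance.gp_de <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(n_genes = nrow(x),
         n_de = sum(x$fdr < th$fdr_strict),
         n_misregulated = sum(x$misregulated),
         n_extended = sum(x$extended),
         n_experiments = attr(x, "n_experiments"),
         common_dispersion = attr(x, "common_dispersion"))
}

#' @exportS3Method generics::tidy
tidy.gp_de <- function(x, ...) {
  as_tibble(x)[, c("gene_id", "logFC", "logCPM", "p", "fdr", "consistent",
                   "misregulated", "extended")]
}

#' @exportS3Method ggplot2::autoplot
autoplot.gp_de <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$logCPM, y = .data$logFC)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fdr < th$fdr_strict),
                        size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red"),
                                 name = paste0("FDR < ", th$fdr_strict)) +
    ggplot2::labs(x = "logCPM", y = "logFC (spermatid / sperm)") +
    ggplot2::theme_minimal()
}
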