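#' Chi-squared enrichment of hits in a gene set vs background
#'
#' Pearson chi-squared on the 2x2 table (hits / non-hits in set vs
#' background), df = 1, two-sided, without continuity correction by
#' default (a flag enables the corrected variant).
#'
#' @param hits_in_set,set_size Hit count and size of the gene set.
#' @param hits_in_background,background_size Hit count and size of the
#'   background.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return Tibble with `chi2`, `p`, `direction` (`over`, `under`, `none`),
#'   and the four table cells.
#' @export
chisq_enrichment <- function(hits_in_set, set_size, hits_in_background,
                             background_size, correct = FALSE) {
  if (set_size <= 0 || background_size <= 0) gp_stop("set sizes must be > 0")
  if (hits_in_set > set_size || hits_in_background > background_size) {
    gp_stop("hits cannot exceed the set size")
  }
  tab <- rbind(c(hits_in_set, set_size - hits_in_set),
               c(hits_in_background, background_size - hits_in_background))
  p_set <- hits_in_set / set_size
  p_bg <- hits_in_background / background_size
  # equal proportions (including saturated/empty columns) define chi2 = 0;
  # only unequal proportions with a zero expected cell are degenerate
  if (p_set == p_bg) {
    return(tibble(chi2 = 0, p = 1, direction = "none",
                  hits_in_set = hits_in_set, set_size = set_size,
                  hits_in_background = hits_in_background,
                  background_size = background_size))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) gp_stop("degenerate table: an expected cell is 0")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(chi2 = unname(ct$statistic), p = unname(ct$p.value),
         direction = if (p_set > p_bg) "over" else "under",
         hits_in_set = hits_in_set, set_size = set_size,
         hits_in_background = hits_in_background,
         background_size = background_size)
}

#' Overlap of two gene sets with a hypergeometric test
#'
#' @param set_a,set_b Character vectors; both must be subsets of
#'   `universe`.
#' @param universe Character vector of all genes considered.
#' @return Tibble with the Venn counts (`only_a`, `only_b`, `both`,
#'   `neither`) and the upper-tail hypergeometric probability `p` of an
#'   overlap at least as large.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  out <- setdiff(c(set_a, set_b), universe)
  if (length(out)) {
    gp_stop("element(s) outside the universe: ",
            paste(head(out, 3), collapse = ", "))
  }
  both <- length(intersect(set_a, set_b))
  p <- phyper(both - 1, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  tibble(both = both,
         only_a = length(set_a) - both,
         only_b = length(set_b) - both,
         neither = length(universe) - length(union(set_a, set_b)),
         p = p)
}

#' Project a gene set through an ortholog map
#'
#' @param gene_set Character vector of source-species gene ids.
#' @param map Ortholog tibble (`source_gene_id`, `target_gene_id`), e.g.
#'   from [read_ortholog_map()].
#' @return Character vector: the union of targets of mapped genes
#'   (duplicates collapsed). The number of unmapped source genes is stored
#'   in `attr(, "n_unmapped")` and logged.
#' @export
project_orthologs <- function(gene_set, map) {
  if (nrow(map) == 0) gp_stop("empty ortholog map")
  gene_set <- unique(gene_set)
  mapped <- map |> filter(.data$source_gene_id %in% gene_set)
  n_unmapped <- sum(!gene_set %in% map$source_gene_id)
  if (n_unmapped > 0) gp_log(n_unmapped, " gene(s) without an ortholog")
  out <- unique(mapped$target_gene_id)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Per-term enrichment of a gene set
#'
#' One 2x2 enrichment test per term (chi-squared by default, upper-tail
#' hypergeometric optionally), comparing term membership within the gene
#' set against the universe, with BH adjustment across terms. Terms with no
#' universe members are skipped with a warning.
#'
#' @param gene_set Character vector; every gene must be in `universe`.
#' @param term_map Tibble with columns `gene_id` and `term`.
#' @param universe Character vector of all genes.
#' @param method `"chisq"` (default) or `"hypergeometric"`.
#' @return Tibble: one row per term with counts, `p`, `q` and `direction`.
#' @export
term_enrichment <- function(gene_set, term_map, universe,
                            method = c("chisq", "hypergeometric")) {
  method <- match.arg(method)
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe)) gp_stop("gene set not within universe")
  terms <- unique(term_map$term)
  rows <- map(terms, function(tm) {
    members <- unique(term_map$gene_id[term_map$term == tm])
    members <- intersect(members, universe)
    if (length(members) == 0) {
      warn(paste0("term '", tm, "' has no universe members; skipped"))
      return(NULL)
    }
    k_set <- sum(gene_set %in% members)
    if (method == "chisq") {
      res <- chisq_enrichment(k_set, length(gene_set),
                              length(members), length(universe))
      tibble(term = tm, in_set = k_set, set_size = length(gene_set),
             term_size = length(members), p = res$p,
             direction = res$direction)
    } else {
      p <- phyper(k_set - 1, length(members),
                  length(universe) - length(members), length(gene_set),
                  lower.tail = FALSE)
      tibble(term = tm, in_set = k_set, set_size = length(gene_set),
             term_size = length(members), p = p,
             direction = ifelse(
               k_set / length(gene_set) > length(members) / length(universe),
               "over", ifelse(k_set / length(gene_set) <
                                length(members) / length(universe),
                              "under", "none")))
    }
  })
  out <- list_rbind(purrr::compact(rows))
  out$q <- bh_adjust(out$p)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution with effective sample size
#' `|x||y| / (|x| + |y|)`, appropriate at the fiber-sample sizes used here.
#'
#' @param x,y Numeric samples (each nonempty).
#' @return Tibble with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) gp_stop("empty sample")
  if (identical(sort(x), sort(y))) {
    return(tibble(D = 0, p = 1))
  }
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  tibble(D = unname(kt$statistic), p = unname(kt$p.value))
}
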