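#' Assemble a genes-by-features matrix
#'
#' Inner-joins per-gene feature tables (promoter mark levels, nucleosome
#' occupancy, DNA methylation, embryo expression) on `gene_id` over a
#' selected gene set and z-scores every feature column. Genes missing any
#' feature are dropped (their count is logged); marks and expression live on
#' incomparable scales, hence the standardisation.
#'
#' @param features Named list of tibbles, each with `gene_id` and a value
#'   column (the first non-`gene_id` column is used). Names become feature
#'   names.
#' @param gene_set Character vector of gene ids to keep.
#' @param min_coverage Minimum fraction of `gene_set` each feature table
#'   must cover (default 0.8).
#' @return Tibble of class `gp_features`: `gene_id` plus one z-scored
#'   column per feature.
#' @export
build_feature_matrix <- function(features, gene_set, min_coverage = 0.8) {
  if (length(gene_set) == 0) gp_stop("empty gene set")
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    gp_stop("features must be a named list")
  }
  cols <- imap(features, function(tbl, nm) {
    val_col <- setdiff(names(tbl), "gene_id")[1]
    covered <- mean(gene_set %in% tbl$gene_id)
    if (covered < min_coverage) {
      gp_stop("feature '", nm, "' covers only ",
              round(100 * covered), "% of the gene set (need >= ",
              round(100 * min_coverage), "%)")
    }
    tibble(gene_id = tbl$gene_id, !!nm := tbl[[val_col]])
  })
  joined <- purrr::reduce(cols, inner_join, by = "gene_id")
  joined <- joined |> filter(.data$gene_id %in% gene_set)
  n_dropped <- length(gene_set) - nrow(joined)
  if (n_dropped > 0) {
    gp_log(n_dropped, " gene(s) dropped: missing at least one feature")
  }
  for (nm in names(features)) {
    v <- joined[[nm]]
    if (sd(v) == 0) gp_stop("feature '", nm, "' is constant over the gene set")
    joined[[nm]] <- (v - mean(v)) / sd(v)
  }
  class(joined) <- c("gp_features", class(joined))
  joined
}

# Closed-form shrinkage intensity toward the identity-correlation target:
# lambda* = sum of estimated variances of the off-diagonal correlations
# over the sum of their squares, clamped to [0, 1].
shrinkage_lambda <- function(X) {
  n <- nrow(X)
  Z <- scale(X)
  r <- crossprod(Z) / (n - 1)
  var_r <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(ncol(X) - 1)) {
    for (j in (i + 1):ncol(X)) {
      w <- Z[, i] * Z[, j]
      var_r[i, j] <- n / (n - 1)^3 * sum((w - mean(w))^2)
    }
  }
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  if (denom == 0) return(1)
  min(1, max(0, sum(var_r[off]) / denom))
}

# Partial correlations from a correlation/covariance matrix:
# the standardised negative precision matrix off-diagonal.
pcor_from_cov <- function(S) {
  Omega <- tryCatch(solve(S), error = function(e)
    gp_stop("singular matrix; use shrinkage > 0 for collinear features"))
  d <- sqrt(diag(Omega))
  P <- -Omega / outer(d, d)
  diag(P) <- 1
  dimnames(P) <- dimnames(S)
  P
}

#' Shrinkage partial-correlation fit
#'
#' Estimates the partial-correlation matrix of the feature columns: the
#' sample correlation matrix is shrunk toward the identity,
#' `S* = (1 - lambda) R + lambda I`, inverted, and standardised,
#' `pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`. With `shrinkage =
#' "auto"` the closed-form optimal intensity toward the identity target is
#' used; `shrinkage = 0` gives the classical estimate (requires a
#' well-conditioned correlation matrix).
#'
#' @param features A `gp_features` tibble ([build_feature_matrix()]) or any
#'   data frame with `gene_id` plus numeric feature columns.
#' @param shrinkage `"auto"` (default) or a number in `[0, 1]`.
#' @return An object of class `pcor_fit`: fields `pcor` (symmetric matrix),
#'   `lambda`, `n` (rows), `k` (features), `features` (names).
#' @export
partial_correlation <- function(features, shrinkage = "auto") {
  X <- as.matrix(features[, setdiff(names(features), "gene_id"),
                          drop = FALSE])
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) warn("fewer observations than recommended (n <= k)")
  R <- cor(X)
  lambda <- if (identical(shrinkage, "auto")) shrinkage_lambda(X) else {
    if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1) {
      gp_stop("shrinkage must be 'auto' or a number in [0, 1]")
    }
    shrinkage
  }
  S <- (1 - lambda) * R + lambda * diag(k)
  dimnames(S) <- dimnames(R)
  P <- pcor_from_cov(S)
  structure(list(pcor = P, lambda = lambda, n = n, k = k,
                 features = colnames(X)),
            class = "pcor_fit")
}

#' @export
print.pcor_fit <- function(x, ...) {
  cat("<pcor_fit> ", x$k, " features, n = ", x$n,
      ", shrinkage lambda = ", signif(x$lambda, 3), "\n", sep = "")
  print(round(x$pcor, 3))
  invisible(x)
}

#' Analytic significance of partial-correlation edges
#'
#' Each edge statistic is `t = pcor * sqrt((n - k) / (1 - pcor^2))`
#' referred to a t distribution on `n - k` degrees of freedom (two-sided;
#' `k - 2` controlled variables plus the pair), with BH adjustment over the
#' `k (k - 1) / 2` edges.
#'
#' @param fit A `pcor_fit` from [partial_correlation()].
#' @return Tibble with `from`, `to`, `pcor`, `p`, `q`.
#' @export
edge_significance <- function(fit) {
  stopifnot(inherits(fit, "pcor_fit"))
  n <- fit$n
  k <- fit$k
  if (n - k + 1 <= 2) gp_stop("too few observations: need n > k + 1")
  idx <- which(upper.tri(fit$pcor), arr.ind = TRUE)
  pc <- fit$pcor[idx]
  if (any(abs(pc) >= 1)) {
    warn("|partial correlation| = 1: p set to 0")
  }
  tstat <- ifelse(abs(pc) >= 1, Inf,
                  pc * sqrt((n - k) / (1 - pc^2)))
  p <- 2 * pt(abs(tstat), df = n - k, lower.tail = FALSE)
  tibble(from = fit$features[idx[, 1]],
         to = fit$features[idx[, 2]],
         pcor = pc, p = p, q = bh_adjust(p))
}

#' Permutation cross-check for one edge
#'
#' Re-estimates the partial correlation of one feature pair after cyclic
#' rotations of one feature column, giving a permutation null for the edge.
#' A slow, seeded cross-check for [edge_significance()]; not the default
#' test.
#'
#' @param features Feature tibble.
#' @param a,b Feature names.
#' @param n_perm Number of rotations (default 1000).
#' @param shrinkage Passed to [partial_correlation()].
#' @param seed Integer seed.
#' @return List with `pcor`, `p` (permutation p-value).
#' @export
edge_permutation_test <- function(features, a, b, n_perm = 1000,
                                  shrinkage = "auto", seed = 1) {
  fit <- partial_correlation(features, shrinkage)
  obs <- fit$pcor[a, b]
  n <- fit$n
  null <- withr::with_seed(seed, {
    offs <- sample(seq_len(n - 1), n_perm, replace = TRUE)
    vapply(offs, function(o) {
      rot <- features
      v <- rot[[a]]
      rot[[a]] <- v[c((o + 1):n, 1:o)]
      partial_correlation(rot, shrinkage)$pcor[a, b]
    }, numeric(1))
  })
  list(pcor = obs, p = (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm))
}

#' Threshold edges into a partial-correlation network
#'
#' @param edges Edge tibble from [edge_significance()].
#' @param q_threshold BH q cutoff in (0, 1) (default 0.05).
#' @param nodes Optional node names (defaults to all names in `edges`);
#'   isolated nodes are retained.
#' @return Object of class `pcor_network`: `edges` tibble (with `kept`,
#'   `sign`, `weight` columns) and `nodes`.
#' @export
build_network <- function(edges, q_threshold = 0.05, nodes = NULL) {
  if (q_threshold <= 0 || q_threshold >= 1) {
    gp_stop("q_threshold must be in (0, 1)")
  }
  edges <- edges |>
    mutate(kept = .data$q < q_threshold,
           sign = ifelse(.data$pcor > 0, "positive", "negative"),
           weight = abs(.data$pcor))
  structure(list(edges = edges,
                 nodes = nodes %||% unique(c(edges$from, edges$to)),
                 q_threshold = q_threshold),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  kept <- x$edges |> filter(.data$kept)
  cat("<pcor_network> ", length(x$nodes), " nodes, ", nrow(kept), " of ",
      nrow(x$edges), " edges kept at q < ", x$q_threshold, "\n", sep = "")
  if (nrow(kept)) print(as_tibble(kept))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pcor_fit <- function(x, ...) edge_significance(x)

#' @exportS3Method generics::glance
glance.pcor_fit <- function(x, ...) {
  tibble(n = x$n, k = x$k, lambda = x$lambda)
}

#' @exportS3Method generics::tidy
tidy.pcor_network <- function(x, ...) as_tibble(x$edges)

#' @exportS3Method generics::glance
glance.pcor_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         n_kept = sum(x$edges$kept), q_threshold = x$q_threshold)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pcor_network <- function(object, ...) {
  nodes <- object$nodes
  ang <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  layout <- tibble(node = nodes, x = cos(ang), y = sin(ang))
  kept <- object$edges |> filter(.data$kept)
  seg <- kept |>
    left_join(layout, by = c(from = "node")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(layout, by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, colour = .data$sign,
                   linewidth = .data$weight)) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$node)) +
    ggplot2::scale_colour_manual(values = c(positive = "red",
                                            negative = "blue")) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}
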