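test_that("median-of-ratios size factors match hand-derived values", {
  m <- matrix(c(10, 30, 10, 30), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # one column doubled: pre-rescale ratio 1:2
  m2 <- matrix(c(10, 30, 20, 60), ncol = 2,
               dimnames = list(NULL, c("s1", "s2")))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  m3 <- matrix(c(0, 5, 3, 0), ncol = 2,
               dimnames = list(NULL, c("s1", "s2")))
  expect_error(size_factors(m3), "pseudo_reference")
  expect_length(size_factors(m3, pseudo_reference = TRUE), 2)
})

test_that("method-of-moments dispersion follows its formula and floors", {
  design <- toy_design(2)
  # group values 10 +/- sqrt(10): pooled within-group s2 = 20, mean 10
  a <- 10 - sqrt(10)
  b <- 10 + sqrt(10)
  m <- matrix(c(a, b, a, b), nrow = 1,
              dimnames = list("g1", design$sample))
  disp <- estimate_dispersion(m, design, sf = setNames(rep(1, 4),
                                                       design$sample))
  expect_equal(disp$phi, 0.1, tolerance = 1e-12)

  # constant counts: variance below mean, floored at zero
  mc <- matrix(7, nrow = 1, ncol = 4, dimnames = list("g1", design$sample))
  expect_equal(estimate_dispersion(mc, design,
                                   sf = setNames(rep(1, 4),
                                                 design$sample))$phi, 0)

  # Poisson counts at large n: phi near 0
  set.seed(11)
  E <- 50
  dd <- toy_design(E)
  mp <- matrix(rpois(2000 * 2 * E, 100), nrow = 2000,
               dimnames = list(NULL, dd$sample))
  dp <- estimate_dispersion(mp, dd, sf = setNames(rep(1, 2 * E), dd$sample))
  expect_lt(abs(median(dp$phi)), 5e-4)
  expect_error(estimate_dispersion(m[, 1:2, drop = FALSE], toy_design(1)),
               "at least 2")
})

test_that("NB exact test reduces to the conditional binomial at phi = 0", {
  # symmetric split is modal
  expect_equal(nb_exact_test(c(2, 3), c(3, 2)), 1)
  # extreme split: 2 * (1/2)^10
  expect_equal(nb_exact_test(c(0, 0), c(4, 6)), 0.001953125)
  # random cases against the enumeration oracle
  set.seed(42)
  for (i in 1:25) {
    na <- sample(2:7, 1)
    nb <- sample(2:7, 1)
    ka <- rpois(na, 20)
    kb <- rpois(nb, 35)
    p_pkg <- nb_exact_test(ka, kb, phi = 0)
    p_orc <- binom_two_sided_oracle(sum(ka), sum(ka) + sum(kb),
                                    na / (na + nb))
    expect_equal(p_pkg, p_orc, tolerance = 1e-12)
  }
  expect_error(nb_exact_test(1, 1, phi = -0.1), "phi")
  # zero total -> p = 1 by convention
  expect_equal(nb_exact_test(c(0, 0), c(0, 0)), 1)
})

test_that("NB exact test is super-uniform under the null", {
  set.seed(7)
  n_genes <- 2000
  E <- 7
  phi <- 0.05
  mu <- 60
  counts_a <- matrix(rnbinom(n_genes * E, mu = mu, size = 1 / phi), n_genes)
  counts_b <- matrix(rnbinom(n_genes * E, mu = mu, size = 1 / phi), n_genes)
  p <- vapply(seq_len(n_genes), function(i) {
    nb_exact_test(counts_a[i, ], counts_b[i, ], phi = phi)
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.05, 5)), rep(0.05, 5))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-15)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("consistency filter counts same-sign experiments, ignoring zeros", {
  expect_true(consistency_filter(rep(1, 7), 6))
  expect_false(consistency_filter(c(1, 1, 1, 1, 1, -1, -1), 6))
  expect_true(consistency_filter(c(1, 1, 1, 1, 1, 1, -1), 6))
  expect_false(consistency_filter(c(1, 1, 1, 1, 1, 1, 0), 7))
  expect_error(consistency_filter(rep(1, 7), 8), "between 1")
})

test_that("run_de produces coherent calls and respects label swapping", {
  set.seed(5)
  E <- 7
  design <- toy_design(E)
  n <- 300
  mu <- rlnorm(n, 5, 1)
  shifted <- seq_len(20)
  m <- sapply(seq_len(2 * E), function(j) {
    f <- ifelse(seq_len(n) %in% shifted & j > E, 2^1.5, 1)
    rnbinom(n, mu = mu * f, size = 1 / 0.05)
  })
  colnames(m) <- design$sample
  counts <- toy_counts(m, design)
  de <- run_de(counts, design)

  expect_true(all(de$misregulated == (de$fdr < 0.05 & de$consistent)))
  expect_true(all(de$gene_id[de$misregulated] %in%
                    de$gene_id[de$fdr < 0.05]))
  # most planted genes are recovered with positive logFC
  planted <- paste0("g", shifted)
  expect_gt(mean(planted %in% de$gene_id[de$misregulated]), 0.6)
  expect_true(all(de$logFC[de$gene_id %in% planted & de$misregulated] > 0))

  # swapping group labels negates logFC and keeps p
  design_sw <- design
  design_sw$group <- ifelse(design$group == "sperm_embryo",
                            "spermatid_embryo", "sperm_embryo")
  de_sw <- run_de(counts, design_sw)
  common <- intersect(de$gene_id, de_sw$gene_id)
  expect_equal(de_sw$logFC[match(common, de_sw$gene_id)],
               -de$logFC[match(common, de$gene_id)], tolerance = 1e-12)
  expect_equal(de_sw$p[match(common, de_sw$gene_id)],
               de$p[match(common, de$gene_id)], tolerance = 1e-12)

  gl <- glance(de)
  expect_equal(gl$n_misregulated, sum(de$misregulated))
})

test_that("gene-set definitions apply the strict and relaxed rules", {
  de <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    logFC = c(1, 0.5, 0.1),
    fdr = c(0.01, 0.3, 0.5),
    consistent = c(TRUE, TRUE, TRUE)
  )
  sets <- define_gene_sets(de)
  expect_equal(sets$misregulated, "a")
  expect_setequal(sets$extended, c("a", "b"))
  expect_error(define_gene_sets(de, fdr_strict = 1.5), "range")
})

test_that("expression correlation matches the Pearson formula", {
  expect_equal(expression_correlation(1:10, 2 * (1:10) + 1), 1)
  expect_equal(expression_correlation(1:10, -(1:10)), -1)
  expect_equal(expression_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(expression_correlation(1:2, 1:2), "at least 3")
  expect_error(expression_correlation(rep(1, 5), 1:5), "zero variance")
})
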