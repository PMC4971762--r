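test_that("chi-squared enrichment matches the Pearson formula", {
  res <- chisq_enrichment(20, 100, 20, 100)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$direction, "none")

  # rows (30, 70) vs (10, 90): chi2 = 12.5
  res2 <- chisq_enrichment(30, 100, 10, 100)
  expect_equal(res2$chi2, 12.5, tolerance = 1e-12)
  expect_equal(res2$direction, "over")

  set.seed(9)
  for (i in 1:20) {
    a <- sample(1:50, 1); na <- a + sample(1:50, 1)
    b <- sample(1:50, 1); nb <- b + sample(1:50, 1)
    got <- chisq_enrichment(a, na, b, nb)
    expect_equal(got$chi2,
                 chisq_oracle(rbind(c(a, na - a), c(b, nb - b))),
                 tolerance = 1e-10)
  }
  expect_error(chisq_enrichment(30, 20, 5, 100), "exceed")
  # saturated and empty columns have equal proportions, hence chi2 = 0
  expect_equal(chisq_enrichment(0, 5, 0, 5)$direction, "none")
  expect_equal(chisq_enrichment(5, 5, 9, 9)$p, 1)
})

test_that("chi-squared enrichment is invariant to swapping set and background", {
  a <- chisq_enrichment(25, 80, 10, 120)
  b <- chisq_enrichment(10, 120, 25, 80)
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$p, b$p)
  expect_equal(a$direction, "over")
  expect_equal(b$direction, "under")
})

test_that("overlap test matches hypergeometric enumeration", {
  u <- paste0("g", 1:10)
  res <- overlap_test(u[1:5], u[1:4], u)
  expect_equal(res$both, 4)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)

  # identical sets: maximal overlap
  res2 <- overlap_test(u[1:4], u[1:4], u)
  expect_equal(res2$both, 4)
  # disjoint sets covering the universe
  res3 <- overlap_test(u[1:5], u[6:10], u)
  expect_equal(res3$both, 0)
  expect_equal(res3$neither, 0)

  set.seed(15)
  for (i in 1:10) {
    nu <- sample(6:12, 1)
    na <- sample(2:(nu - 1), 1)
    nb <- sample(2:(nu - 1), 1)
    uu <- paste0("x", 1:nu)
    A <- sample(uu, na)
    B <- sample(uu, nb)
    ov <- length(intersect(A, B))
    expect_equal(overlap_test(A, B, uu)$p,
                 hyper_enum_oracle(nu, na, nb, ov), tolerance = 1e-10)
  }
  expect_error(overlap_test(c(u, "zz"), u[1:2], u), "outside")
})

test_that("ortholog projection collapses duplicates and counts unmapped genes", {
  map <- tibble::tibble(source_gene_id = c("a", "b", "c", "c"),
                        target_gene_id = c("HA", "HB", "HB", "HC"))
  out <- project_orthologs(c("a", "b"), map)
  expect_setequal(out, c("HA", "HB"))
  # two sources to one target appear once; unmapped counted
  out2 <- project_orthologs(c("b", "c", "zzz"), map)
  expect_setequal(out2, c("HB", "HC"))
  expect_equal(attr(out2, "n_unmapped"), 1)
  expect_error(project_orthologs("a", map[0, ]), "empty")
})

test_that("term enrichment matches per-term single-table tests", {
  universe <- paste0("g", 1:40)
  term_map <- tibble::tibble(
    gene_id = c(paste0("g", 1:10), paste0("g", 5:20), universe),
    term = c(rep("T1", 10), rep("T2", 16), rep("ALL", 40))
  )
  gene_set <- paste0("g", 1:8)
  res <- term_enrichment(gene_set, term_map, universe)
  expect_equal(nrow(res), 3)
  # a term covering the whole universe is uninformative
  expect_equal(res$p[res$term == "ALL"], 1)
  for (tm in c("T1", "T2")) {
    members <- unique(term_map$gene_id[term_map$term == tm])
    single <- chisq_enrichment(sum(gene_set %in% members), length(gene_set),
                               length(members), length(universe))
    expect_equal(res$p[res$term == tm], single$p)
  }
  expect_equal(res$q, bh_oracle(res$p))

  # hypergeometric flag and empty-term warning
  resh <- term_enrichment(gene_set, term_map, universe,
                          method = "hypergeometric")
  expect_true(all(resh$p >= 0 & resh$p <= 1))
  tm_bad <- dplyr::bind_rows(term_map,
                             tibble::tibble(gene_id = "offworld",
                                            term = "EMPTY"))
  expect_warning(term_enrichment(gene_set, tm_bad, universe), "EMPTY")
  expect_error(term_enrichment("offworld", term_map, universe), "universe")
})

test_that("KS statistic matches the exhaustive ECDF oracle", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ks_two_sample(0, 1)$D, 1)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(x, y)$D, ks_d_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("KS statistic is invariant under monotone transforms", {
  set.seed(32)
  x <- rexp(60)
  y <- rexp(80, 0.6)
  d0 <- ks_two_sample(x, y)$D
  expect_equal(ks_two_sample(log(x), log(y))$D, d0)
  expect_equal(ks_two_sample(x^3, y^3)$D, d0)
})

test_that("replication extent merges intervals and validates fibers", {
  fib <- tibble::tibble(
    fiber_id = c("f1", "f1", "f2", "f2", "f2", "f3", "f3", "f3"),
    start = c(0, 0, 0, 0, 50, 0, 0, 20),
    end = c(100, 100, 100, 25, 75, 100, 30, 40),
    type = c("total", "replicated", "total", "replicated", "replicated",
             "total", "replicated", "replicated")
  )
  ext <- replication_extent(fib)
  expect_equal(ext$extent[ext$fiber_id == "f1"], 1)
  expect_equal(ext$extent[ext$fiber_id == "f2"], 0.5)
  expect_equal(ext$extent[ext$fiber_id == "f3"], 0.4)

  # splitting a replicated interval into adjacent pieces changes nothing
  split <- tibble::tibble(
    fiber_id = "f1", start = c(0, 0, 40), end = c(100, 40, 100),
    type = c("total", "replicated", "replicated"))
  expect_equal(replication_extent(split)$extent, 1)

  bad <- tibble::tibble(fiber_id = c("f1", "f1"), start = c(0, 50),
                        end = c(100, 120),
                        type = c("total", "replicated"))
  expect_error(replication_extent(bad), "outside fiber f1")
  orphan <- tibble::tibble(fiber_id = c("f1", "f9"), start = c(0, 0),
                           end = c(100, 10),
                           type = c("total", "replicated"))
  expect_error(replication_extent(orphan), "unknown fiber f9")
})
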