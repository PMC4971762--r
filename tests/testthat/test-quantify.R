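test_that("metagene profile recovers flat signal and averages genes", {
  g <- toy_genes(c(3000, 6000))
  trk <- uniform_track(3, len = 10000)
  prof <- metagene_profile(g, trk, flank = 1000, bin = 100,
                           depth_normalize = FALSE)
  expect_equal(nrow(prof), 20)
  expect_true(all(abs(prof$mean_signal - 3) < 1e-12))
  expect_equal(attr(prof, "n_genes"), 2)

  # two genes with constant window signal 2 and 4 average to 3
  two <- coverage_track(list(chr1 = c(rep(2, 4000), rep(4, 4000))), "two")
  g2 <- toy_genes(c(2000, 6000))
  prof2 <- metagene_profile(g2, two, flank = 1000, bin = 100,
                            depth_normalize = FALSE)
  expect_true(all(abs(prof2$mean_signal - 3) < 1e-12))
})

test_that("opposite strands give mirror-image single-gene profiles", {
  ramp <- coverage_track(list(chr1 = as.numeric(1:4000)), "ramp")
  plus <- metagene_profile(toy_genes(2000, "+"), ramp, flank = 1000,
                           bin = 50, depth_normalize = FALSE)
  minus <- metagene_profile(toy_genes(2000, "-"), ramp, flank = 1000,
                            bin = 50, depth_normalize = FALSE)
  expect_equal(plus$mean_signal, rev(minus$mean_signal))
})

test_that("metagene profile is linear in the track and validates input", {
  g <- toy_genes(c(2500, 5100, 7000), strand = c("+", "-", "+"))
  base <- coverage_track(list(chr1 = abs(sin(1:9000)) * 5), "s")
  tripled <- coverage_track(list(chr1 = abs(sin(1:9000)) * 15), "s3")
  p1 <- metagene_profile(g, base, flank = 500, bin = 50,
                         depth_normalize = FALSE)
  p3 <- metagene_profile(g, tripled, flank = 500, bin = 50,
                         depth_normalize = FALSE)
  expect_equal(p3$mean_signal, 3 * p1$mean_signal, tolerance = 1e-12)
  expect_error(metagene_profile(g, base, flank = 500, bin = 33), "divisor")
  expect_error(
    metagene_profile(toy_genes(100, chrom = "chrX"), base, 500, 50),
    "no usable genes")
})

test_that("promoter levels follow the stated log-ratio formula", {
  g <- toy_genes(5000)
  # identical IP and input -> level 0
  trk <- track_from_text(c("chr1\t4000\t6000\t2"))
  lev0 <- promoter_levels(g, trk, trk, flank = 1000)
  expect_equal(lev0$level, 0)

  # IP = 2x input everywhere: depth scaling cancels the factor -> level 0;
  # with unequal *window* enrichment the ratio survives. Use a vanishing
  # pseudocount and ip twice input within the window only.
  ip <- track_from_text(c("chr1\t4000\t6000\t4", "chr1\t8000\t9000\t2"))
  input <- track_from_text(c("chr1\t4000\t6000\t2", "chr1\t8000\t9000\t3"))
  # window spm: ip 8000/10000*1e6 = 8e5; input 4000/7000*1e6 = 5.714e5
  lev <- promoter_levels(g, ip, input, flank = 1000, pseudocount = 1e-9)
  expect_equal(lev$level, log2((8000 / 10000) / (4000 / 7000)),
               tolerance = 1e-6)

  # ip_spm 10, input_spm 0, pseudocount 1 -> log2(11) = 3.4594
  ip2 <- track_from_text(c("chr1\t4999\t5000\t10",
                           sprintf("chr1\t20000\t20001\t%d", 1000000 - 10)))
  input2 <- track_from_text("chr1\t20000\t20001\t500")
  lev2 <- promoter_levels(g, ip2, input2, flank = 1000, pseudocount = 1)
  expect_equal(lev2$level, 3.4594316, tolerance = 1e-6)

  expect_error(promoter_levels(g, ip, input, pseudocount = 0), "pseudocount")
  empty <- coverage_track(list(chr1 = numeric(0)), "empty")
  expect_error(promoter_levels(g, empty, input), "empty track")
})

test_that("promoter level is antisymmetric under IP/input swap", {
  g <- toy_genes(c(2000, 5000, 8000))
  a <- coverage_track(list(chr1 = abs(sin(1:10000)) + 0.2), "a")
  b <- coverage_track(list(chr1 = abs(cos(1:10000)) + 0.4), "b")
  ab <- promoter_levels(g, a, b, flank = 500)
  ba <- promoter_levels(g, b, a, flank = 500)
  expect_equal(ab$level, -ba$level, tolerance = 1e-10)
})

test_that("Poisson peak p-values match the summation oracle", {
  for (k in c(1, 3, 10, 20, 35, 50)) {
    for (lambda in c(0.5, 1, 5, 12.5, 20)) {
      expect_equal(ppois(k - 1, lambda, lower.tail = FALSE),
                   pois_upper_oracle(k, lambda), tolerance = 1e-10)
    }
  }
  # worked case frozen from the oracle: k = 20, lambda = 5
  expect_equal(ppois(19, 5, lower.tail = FALSE), 3.452136e-07,
               tolerance = 1e-6)
  expect_equal(ppois(19, 5, lower.tail = FALSE), pois_upper_oracle(20, 5),
               tolerance = 1e-12)
})

test_that("peak calling behaves at the boundaries", {
  g <- toy_genes(seq(2000, 20000, by = 2000))
  expect_error(call_promoter_peaks(g, uniform_track(1), uniform_track(1),
                                   q_threshold = 1.2), "q_threshold")
  # IP identical to input: no peaks anywhere
  trk <- uniform_track(2, len = 21000)
  pk <- call_promoter_peaks(g, trk, trk)
  expect_false(any(pk$has_peak))
  expect_true(all(pk$p >= 0.5))

  # a zero-count IP window can never be a peak (p = 1 at k_ip = 0)
  ip <- track_from_text("chr1\t20500\t21000\t50")  # signal away from g1
  input <- uniform_track(0.001, len = 21000)
  pk2 <- call_promoter_peaks(toy_genes(2000), ip, input)
  expect_equal(pk2$k_ip, 0)
  expect_equal(pk2$p, 1)
  expect_false(pk2$has_peak)
})

test_that("peak percentage arithmetic and validation", {
  peaks <- tibble::tibble(gene_id = paste0("g", 1:12),
                          has_peak = c(rep(TRUE, 3), rep(FALSE, 9)))
  expect_equal(percent_with_peak(peaks, peaks$gene_id), 25)
  expect_equal(percent_with_peak(peaks, paste0("g", 1:3)), 100)
  expect_equal(percent_with_peak(peaks, paste0("g", 4:6)), 0)
  expect_error(percent_with_peak(peaks, character(0)), "empty")
  expect_error(percent_with_peak(peaks, "nope"), "absent")
})
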