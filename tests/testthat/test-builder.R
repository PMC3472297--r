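test_that("dna_index is the length-weighted half mean tumour copy number", {
  expect_equal(dna_index(make_truth_df("chr1", 0, 500000, 2)), 1.0)
  tr <- make_truth_df("chr1", c(0, 500000), c(500000, 1000000), c(2, 3))
  expect_equal(dna_index(tr), 1.25)
  # subclone-weighted: CN0 (25%) + CN4 (75%) genome-wide
  trs <- make_truth_df("chr1", 0, 500000, 4, subclones = "0:0:0.25|4:2:0.75")
  expect_equal(dna_index(trs), 1.5)
  expect_error(dna_index(make_truth_df("chr1", numeric(), numeric(), integer())),
               "empty")
})

test_that("baseline shift follows the DNA-index law", {
  cfg0 <- sample_config(shift_law = c(slope = 0.6, sd = 0))
  expect_equal(draw_baseline_shift(1, cfg0), 0)
  # DI_eff = 1.5 at zero contamination
  expect_equal(draw_baseline_shift(1.5, cfg0), -0.3)
  # contamination shrinks the effective index: DI_eff = 0.5*1.5 + 0.5
  expect_equal(draw_baseline_shift(1.5, cfg0, contamination = 0.5), -0.15)

  cfg <- sample_config(shift_law = c(slope = 0.6, sd = 0.05))
  draws <- vapply(1:10000, function(i)
    draw_baseline_shift(1.5, cfg, seed = i), 0)
  se <- 0.05 / sqrt(10000)
  expect_lt(abs(mean(draws) + 0.3), 3 * se + 1e-3)
})

test_that("pattern presets are reproducible and structurally sound", {
  expect_error(build_pattern("near_hexaploid"), "valid presets")
  expect_setequal(list_presets(),
                  c("near_diploid", "near_triploid", "near_tetraploid",
                    "loh_enriched", "complex"))

  s1 <- build_pattern("near_triploid", contamination = 0.25, seed = 5,
                      config = fast_config())
  s2 <- build_pattern("near_triploid", contamination = 0.25, seed = 5,
                      config = fast_config())
  expect_identical(s1$lrr, s2$lrr)
  expect_identical(s1$baf, s2$baf)
  expect_identical(s1$truth, s2$truth)

  truth <- s1$truth
  # regions tile the SNP grid without overlap
  expect_identical(truth$snp_start[-1], truth$snp_end[-nrow(truth)])
  expect_identical(truth$snp_start[1], 0L)
  expect_identical(truth$snp_end[nrow(truth)], nrow(s1$grid))
  # fragment lengths come from the published menu
  expect_true(all(truth$n_snps %in% c(10, 20, 40, 80, 160)))
  # bp coordinates are consistent with the SNP layout per chromosome
  for (ch in unique(truth$chrom)) {
    tc <- truth[truth$chrom == ch, ]
    expect_identical(tc$start[1], 0L)
    expect_identical(tc$start[-1], tc$end[-nrow(tc)])
    expect_identical(tc$end - tc$start, tc$n_snps * 5000L)
  }
  # probes fall inside their region's bp interval ([pos-1] in [start, end))
  g <- s1$grid
  i <- 57  # arbitrary region
  probes <- g[(truth$snp_start[i] + 1):truth$snp_end[i], ]
  expect_true(all(probes$chrom == truth$chrom[i]))
  expect_true(all(probes$position - 1 >= truth$start[i] &
                    probes$position - 1 < truth$end[i]))
})

test_that("replicate sets derive distinct but reproducible samples", {
  r1 <- generate_replicates("near_diploid", 0.25, n_reps = 2, base_seed = 9,
                            config = fast_config())
  r2 <- generate_replicates("near_diploid", 0.25, n_reps = 2, base_seed = 9,
                            config = fast_config())
  expect_identical(r1[[1]]$lrr, r2[[1]]$lrr)
  expect_identical(r1[[2]]$truth, r2[[2]]$truth)
  expect_false(identical(r1[[1]]$truth$n_snps, r1[[2]]$truth$n_snps))
})

test_that("scaffold-driven samples follow the scaffold", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("length_snps\tcn\tratio\tgermline_loh",
               "100\t2\t1:1\t0"), path)
  sc <- read_scaffold(path)
  s <- build_from_scaffold(sc, contamination = 0, config = zero_noise_config(),
                           seed = 1)
  expect_identical(nrow(s$truth), 1L)
  expect_equal(s$dna_index, 1.0)
  expect_identical(nrow(s$grid), 100L)

  writeLines(c("length_snps\tcn\tratio\tgermline_loh\tfractions",
               "50\t1\t1:0\t0\t",
               "50\t3\t2:1\t0\t",
               "30\t2,4\t2:0,3:1\t0\t0.6,0.4",
               "20\t2\t1:1\t1\t"), path)
  s2 <- build_from_scaffold(read_scaffold(path), contamination = 0,
                            config = zero_noise_config(), seed = 2)
  expect_identical(nrow(s2$grid), 150L)
  expect_identical(s2$truth$loh, c("somatic", "none", "none", "germline"))
  # DNA index: (1*50 + 3*50 + (0.6*2+0.4*4)*30 + 2*20) / 150 / 2
  expect_equal(s2$dna_index, (50 + 150 + 2.8 * 30 + 40) / 150 / 2)

  writeLines(c("length_snps\tcn\tratio\tgermline_loh",
               "50\t3\t2:2\t0"), path)
  expect_error(read_scaffold(path), "record 1")
})

test_that("truth/signal consistency: zero-noise rebuild matches expectations", {
  cfg <- zero_noise_config()
  s <- build_pattern("near_tetraploid", contamination = 0.25, seed = 13,
                     config = cfg)
  truth <- s$truth
  mu <- cfg$lrr_model$mu
  for (i in sample(nrow(truth), 25)) {
    idx <- (truth$snp_start[i] + 1):truth$snp_end[i]
    cl <- strsplit(truth$subclones[i], "|", fixed = TRUE)[[1]]
    parts <- do.call(rbind, lapply(strsplit(cl, ":"), as.numeric))
    expected_lrr <- 0.25 * mu[["2"]] +
      0.75 * sum(parts[, 3] * mu[as.character(parts[, 1])]) + s$baseline_shift
    expect_equal(unique(s$lrr[idx]), expected_lrr, tolerance = 1e-12)
  }
})

test_that("the contamination sweep reproduces linear LRR contraction", {
  sweep <- lapply(c(0, 0.25, 0.5, 0.75), function(w1)
    build_pattern("near_triploid", contamination = w1, seed = 31,
                  config = zero_noise_config()))
  fit <- estimate_contraction(sweep)
  expect_equal(fit$q, 1 - c(0, 0.25, 0.5, 0.75), tolerance = 1e-6)
  expect_equal(fit$slope, 1, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.99)
})
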