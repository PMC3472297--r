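test_that("single-call overlap rule decides recall", {
  tr <- make_truth_df("chr1", 100000, 200000, 3)
  call_ok <- make_calls_df("chr1", 140000, 260000, 3)    # 60% overlap
  expect_true(region_recalled(tr[1, ], call_ok))
  call_cn <- make_calls_df("chr1", 140000, 260000, 4)
  expect_false(region_recalled(tr[1, ], call_cn))
  # two partial calls are never pooled
  call_sp <- make_calls_df("chr1", c(100000, 160000), c(140000, 190000), c(3, 3))
  expect_false(region_recalled(tr[1, ], call_sp))
  # tie at exactly half counts as recalled
  call_half <- make_calls_df("chr1", 150000, 300000, 3)
  expect_true(region_recalled(tr[1, ], call_half))
  expect_false(region_recalled(tr[1, ], call_half, min_overlap = 0.6))
  expect_error(region_recalled(tr[1, ], call_half, min_overlap = 0), "min_overlap")
})

test_that("LOH-aware matching ignores the germline/somatic distinction", {
  tr <- make_truth_df("chr1", 0, 100000, 2, loh = "somatic",
                      subclones = "2:2:1")
  call_g <- make_calls_df("chr1", 0, 100000, 2, loh = "germline")
  call_n <- make_calls_df("chr1", 0, 100000, 2, loh = "none")
  expect_true(region_recalled(tr[1, ], call_g, require_loh = TRUE))
  expect_false(region_recalled(tr[1, ], call_n, require_loh = TRUE))
  expect_true(region_recalled(tr[1, ], call_n, require_loh = FALSE))
})

test_that("recall_table excludes diploid regions and aggregates by cell", {
  tr <- make_truth_df("chr1",
                      start = (0:3) * 100000, end = (1:4) * 100000,
                      copy_number = c(2, 3, 3, 1),
                      loh = c("none", "none", "none", "somatic"))
  calls <- make_calls_df("chr1", c(100000, 300000), c(200000, 400000), c(3, 1))
  tab <- recall_table(list(tr), list(calls), contamination = 0.25,
                      by = c("contamination", "copy_number"))
  expect_identical(sum(tab$n_truth), 3L)  # diploid-het region excluded
  expect_equal(tab$recall[tab$copy_number == 3], 0.5)
  expect_equal(tab$recall[tab$copy_number == 1], 1)

  # no calls: recall 0 everywhere, n_truth unchanged
  tab0 <- recall_table(list(tr), list(make_calls_df("chr1", numeric(),
                                                    numeric(), integer())),
                       by = "copy_number")
  expect_true(all(tab0$recall == 0))
  expect_identical(sum(tab0$n_truth), 3L)

  # calls identical to truth: recall 1 in every cell
  perfect <- make_calls_df("chr1", tr$start, tr$end, tr$copy_number)
  tab1 <- recall_table(list(tr), list(perfect), by = "copy_number")
  expect_true(all(tab1$recall == 1))
})

test_that("fdr_matrix counts wrong-copy-number calls by max-overlap match", {
  tr <- make_truth_df("chr1", (0:3) * 100000, (1:4) * 100000,
                      c(3, 4, 1, 5))
  perfect <- make_calls_df("chr1", tr$start, tr$end, tr$copy_number)
  expect_equal(fdr_matrix(tr, perfect)$total_fdr, 0)

  one_wrong <- make_calls_df("chr1", tr$start, tr$end, c(3, 4, 1, 4))
  fm <- fdr_matrix(tr, one_wrong)
  expect_equal(fm$total_fdr, 0.25)
  expect_equal(fm$matrix["4", "5"], 0.25)

  # systematic +1 bias: all mass on the (true, true+1) superdiagonal
  # (avoid CN1 truth: a CN2 call would be excluded as diploid-het)
  trb <- make_truth_df("chr1", (0:3) * 100000, (1:4) * 100000, c(3, 4, 3, 5))
  plus_one <- make_calls_df("chr1", trb$start, trb$end, trb$copy_number + 1)
  fmp <- fdr_matrix(trb, plus_one)
  expect_equal(fmp$total_fdr, 1)
  for (cn in unique(trb$copy_number))
    expect_equal(fmp$matrix[as.character(cn + 1), as.character(cn)],
                 sum(trb$copy_number == cn) / 4)

  # a call overlapping no truth region lands in the "none" column
  stray <- make_calls_df("chr2", 0, 100000, 3)
  fms <- fdr_matrix(tr, stray)
  expect_equal(fms$matrix["3", "none"], 1)

  # row sums equal per-called-CN wrong fractions; total is off-diagonal sum
  expect_equal(sum(fmp$matrix), fmp$total_fdr)
})

test_that("recall and FDR equal the naive all-pairs oracle on random fixtures", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    bounds <- sort(sample(seq(0, 2e6, by = 1e5), n + 1))
    tr <- make_truth_df("chr1", bounds[-(n + 1)], bounds[-1],
                        sample(1:5, n, TRUE),
                        loh = sample(c("none", "somatic", "germline"), n, TRUE))
    m <- sample(3:15, 1)
    cs <- sample(seq(0, 2e6, by = 5e4), m)
    calls <- make_calls_df("chr1", cs, cs + sample(c(1e5, 2e5, 4e5), m, TRUE),
                           sample(1:5, m, TRUE),
                           loh = sample(c("none", "somatic", "unspecified"),
                                        m, TRUE))
    for (req in c(FALSE, TRUE)) {
      orc <- oracle_recall(tr, calls, require_loh = req)
      mine <- vapply(seq_len(nrow(orc$truth)), function(i)
        region_recalled(orc$truth[i, ], calls[!(calls$copy_number == 2 &
          !calls$loh %in% c("somatic", "germline")), ], require_loh = req), NA)
      expect_identical(mine, orc$recalled)
    }
    expect_equal(fdr_matrix(tr, calls)$total_fdr, oracle_fdr(tr, calls))
  }
})

test_that("recall is monotone non-increasing in min_overlap", {
  set.seed(5)
  tr <- make_truth_df("chr1", (0:9) * 1e5, (1:10) * 1e5, sample(c(1, 3, 4), 10, TRUE))
  cs <- sample(seq(0, 9e5, by = 2.5e4), 8)
  calls <- make_calls_df("chr1", cs, cs + 1e5, sample(c(1, 3, 4), 8, TRUE))
  fracs <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1)
  rates <- vapply(fracs, function(f)
    mean(vapply(seq_len(nrow(tr)), function(i)
      region_recalled(tr[i, ], calls, min_overlap = f), NA)), 0)
  expect_true(all(diff(rates) <= 0))
})

test_that("estimate_contraction rejects degenerate inputs", {
  s <- build_from_scaffold(list(list(n_snps = 50L, cn = 2L),
                                list(n_snps = 50L, cn = 2L)),
                           0, config = zero_noise_config(), seed = 1)
  expect_error(estimate_contraction(list(s, s)), "degenerate")
  expect_error(estimate_contraction(list(s)), "at least two")
})
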