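test_that("germline genotypes follow Binomial(2, pfb)", {
  g0 <- make_snp_grid(50, pfb = 0)
  expect_true(all(sample_normal_genotypes(g0, seed = 1) == 0L))
  g1 <- make_snp_grid(50, pfb = 1)
  expect_true(all(sample_normal_genotypes(g1, seed = 1) == 2L))

  g <- make_snp_grid(100000, pfb = 0.5)
  z <- sample_normal_genotypes(g, seed = 42)
  freq <- tabulate(z + 1L, 3L) / length(z)
  # oracle: exact binomial pmf (0.25, 0.5, 0.25)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.01))
  expect_identical(z, sample_normal_genotypes(g, seed = 42))
})

test_that("admissible tumour genotypes honour the homozygosity restriction", {
  expect_identical(enumerate_tumour_genotypes(2L, 3L), 3L)
  expect_identical(enumerate_tumour_genotypes(0L, 4L), 0L)
  expect_identical(enumerate_tumour_genotypes(1L, 3L), 0:3)
  expect_identical(enumerate_tumour_genotypes(1L, 0L), 0L)
  expect_error(enumerate_tumour_genotypes(3L, 2L), "z_normal")
  expect_error(enumerate_tumour_genotypes(1L, -1L), "x_tumour")
})

test_that("region genotype assignment is phase-coherent and reproducible", {
  # CN3, one haplotype duplicated (2:1): het SNPs take z in {2, 1} by phase
  reg <- region_spec(n_snps = 200, cn = 3L, h1_copies = 2L)
  gm <- assign_region_genotypes(reg, rep(1L, 200), seed = 7)
  expect_setequal(unique(gm$z[, 2]), c(1L, 2L))
  expect_identical(gm$z[gm$phase, 2], rep(2L, sum(gm$phase)))
  expect_identical(gm$z[!gm$phase, 2], rep(1L, sum(!gm$phase)))
  expect_length(validate_genotypes(gm), 0)
  gm2 <- assign_region_genotypes(reg, rep(1L, 200), seed = 7)
  expect_identical(gm, gm2)

  # homozygous normals force tumour homozygosity for the same allele
  regd <- region_spec(n_snps = 3, cn = 4L, h1_copies = 3L)
  gmd <- assign_region_genotypes(regd, c(0L, 2L, 1L), seed = 1)
  expect_identical(gmd$z[1, 2], 0L)
  expect_identical(gmd$z[2, 2], 4L)

  expect_error(
    assign_region_genotypes(region_spec(n_snps = 2, cn = 2L, h1_copies = 3L,
                                        label = "badreg"), c(1L, 1L)),
    "badreg")
})

test_that("the 3-subclone showcase yields the published genotype menu", {
  # clones: homozygous deletion (25%), allele duplication (50%),
  # allele triplication (25%) on a diploid-het background
  reg <- region_spec(n_snps = 500, cn = c(0L, 3L, 4L), h1_copies = c(0L, 2L, 3L),
                     fractions = c(0.25, 0.5, 0.25))
  gm <- assign_region_genotypes(reg, rep(1L, 500), seed = 3)
  expect_true(all(gm$z[, 2] == 0L))
  expect_true(all(gm$z[, 3] %in% c(1L, 2L)))
  expect_true(all(gm$z[, 4] %in% c(1L, 3L)))
  # phases are shared across clones: (z3, z4) is (2,3) or (1,1)
  expect_true(all((gm$z[, 3] == 2L) == (gm$z[, 4] == 3L)))
  expect_length(validate_genotypes(gm), 0)
})

test_that("germline-LOH regions are runs of homozygosity", {
  reg <- region_spec(n_snps = 300, cn = 2L, h1_copies = 1L, germline_loh = TRUE)
  gm <- assign_region_genotypes(reg, rep(1L, 300), pfb = rep(0.4, 300), seed = 5)
  expect_true(all(gm$z[, 1] %in% c(0L, 2L)))
  expect_true(all(gm$z[, 2] == gm$z[, 1]))  # CN2 tumour keeps the same genotype
  expect_length(validate_genotypes(gm), 0)
  expect_identical(region_loh_status(reg), "germline")
  expect_error(assign_region_genotypes(reg, rep(1L, 300)), "pfb")
})

test_that("derived LOH status distinguishes somatic, germline and none", {
  expect_identical(region_loh_status(region_spec(n_snps = 1, cn = 1L, h1_copies = 1L)),
                   "somatic")
  expect_identical(region_loh_status(region_spec(n_snps = 1, cn = 2L, h1_copies = 2L)),
                   "somatic")   # copy-neutral LOH
  expect_identical(region_loh_status(region_spec(n_snps = 1, cn = 3L, h1_copies = 2L)),
                   "none")
  expect_identical(region_loh_status(
    region_spec(n_snps = 1, cn = c(1L, 3L), h1_copies = c(1L, 3L),
                fractions = c(0.5, 0.5))), "somatic")
  expect_identical(region_loh_status(
    region_spec(n_snps = 1, cn = c(1L, 3L), h1_copies = c(1L, 2L),
                fractions = c(0.5, 0.5))), "none")
})

test_that("validate_region reports violations as diagnostics", {
  pop <- cell_population(normal_fraction = 0.25, subclone_fractions = c(0.5, 0.5))
  ok <- region_spec(n_snps = 10, cn = c(3L, 4L), h1_copies = c(2L, 2L),
                    fractions = c(0.5, 0.5))
  expect_length(validate_region(ok, pop), 0)

  bad_frac <- region_spec(n_snps = 10, cn = c(3L, 4L), fractions = c(0.7, 0.4))
  expect_match(validate_region(bad_frac), "sum != 1", all = FALSE)

  empty <- region_spec(snp_start = 5L, snp_end = 5L, cn = 2L)
  expect_match(validate_region(empty), "empty region", all = FALSE)

  high <- region_spec(n_snps = 10, cn = 7L)
  expect_match(validate_region(high), "copy number", all = FALSE)
  expect_length(validate_region(high, max_copy_number = 8L), 0)

  expect_error(cell_population(normal_fraction = 1), "normal_fraction")
  expect_error(cell_population(0.2, c(0.7, 0.4)), "sum to 1")
})

test_that("generated matrices lie in the brute-force admissible set (1 clone)", {
  # exhaustive membership for small regions: enumeration is the oracle
  for (x_t in 0:4) {
    z1 <- c(1L, 1L, 0L, 2L)
    keys <- oracle_enumerate(z1, x_t)
    for (h1 in 0:x_t) {
      reg <- region_spec(n_snps = 4, cn = x_t, h1_copies = h1)
      for (seed in 1:5) {
        gm <- assign_region_genotypes(reg, z1, seed = seed)
        expect_true(genotype_key(gm$z[, -1, drop = FALSE]) %in% keys,
                    label = sprintf("x=%d h1=%d seed=%d", x_t, h1, seed))
      }
    }
  }
})
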