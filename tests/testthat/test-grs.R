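# Hardy-Weinberg exact test, variant QC filters, allele alignment, scoring
# and association.

test_that("HWE exact p matches brute-force enumeration on canonical cases", {
  expect_equal(hwe_exact_p(100, 0, 0), 1)       # monomorphic
  expect_equal(hwe_exact_p(0, 0, 57), 1)

  expect_equal(hwe_exact_p(25, 50, 25), oracle_hwe_enum(25, 50, 25),
               tolerance = 1e-10)
  # extreme heterozygote deficit fails the 1e-6 filter
  p_deficit <- hwe_exact_p(50, 0, 50)
  expect_lt(p_deficit, 1e-6)
  expect_equal(p_deficit, oracle_hwe_enum(50, 0, 50), tolerance = 1e-10)

  expect_error(hwe_exact_p(0, 0, 0), "at least 1")
  expect_error(hwe_exact_p(-1, 2, 3), "non-negative")
})

test_that("HWE exact p agrees with enumeration for every total up to 60", {
  for (n in 1:60) {
    for (nA in 0:n) {     # symmetric in the two alleles; nA <= n covers all
      oracle <- oracle_hwe_all_hets(n, nA)
      mine <- vapply(oracle$het, function(h)
        hwe_exact_p((nA - h) / 2, h, (2 * n - nA - h) / 2), numeric(1))
      expect_equal(mine, oracle$p, tolerance = 1e-10)
    }
  }
})

make_test_panel <- function() {
  # six variants, one violating each QC rule plus one clean
  ni <- 120L
  hw <- adipoquant:::with_seed(4, rbinom(ni, 2, 0.3))
  bad_hwe <- rep(c(0, 2), length.out = ni)     # no heterozygotes at p ~ 0.5
  rare <- c(rep(1, 2), rep(0, ni - 2))         # MAF ~ 0.008
  D <- rbind(info_bad = hw, miss_bad = hw, hwe_bad = bad_hwe,
             maf_bad = rare, dup_bad = hw, clean = hw)
  v <- data.frame(variant_id = rownames(D),
                  chrom = c(1, 2, 3, 4, 5, 5),
                  pos = c(100, 200, 300, 400, 500, 500),  # dup_bad/clean share 5:500
                  coded_allele = "A", other_allele = "G",
                  frequency = rowMeans(D) / 2,
                  missingness = c(0, 0.2, 0, 0, 0, 0),
                  info_score = c(0.1, 1, 1, 1, 1, 1),
                  stringsAsFactors = FALSE)
  # the first occurrence at a duplicated position is kept, so "clean" (second
  # at 5:500) is the one logged as duplicate_position
  dosage_matrix(D, v)
}

test_that("variant filters drop exactly the offending variants with reasons", {
  dm <- make_test_panel()
  res <- filter_variants(dm)
  ex <- res$exclusions
  expect_setequal(ex$variant_id, c("info_bad", "miss_bad", "hwe_bad",
                                   "maf_bad", "clean"))
  expect_equal(ex$reason[ex$variant_id == "info_bad"], "info")
  expect_equal(ex$reason[ex$variant_id == "miss_bad"], "missingness")
  expect_equal(ex$reason[ex$variant_id == "hwe_bad"], "hwe")
  expect_equal(ex$reason[ex$variant_id == "maf_bad"], "maf")
  expect_equal(ex$reason[ex$variant_id == "clean"], "duplicate_position")
  expect_equal(rownames(res$dosages$dosages), "dup_bad")

  # kept + excluded = input; idempotent
  expect_equal(nrow(res$dosages$dosages) + nrow(ex), nrow(dm$dosages))
  res2 <- filter_variants(res$dosages)
  expect_equal(nrow(res2$exclusions), 0L)
  expect_identical(res2$dosages$dosages, res$dosages$dosages)

  # all passing -> identity
  w <- simulate_weight_table(10, seed = 3)
  g <- simulate_genotypes(genotype_spec(n_individuals = 300L, n_variants = 10L,
                                        maf_range = c(0.2, 0.5), seed = 3L), w)
  all_pass <- filter_variants(g$dosages)
  expect_equal(nrow(all_pass$exclusions), 0L)
  expect_identical(all_pass$dosages$dosages, g$dosages$dosages)
})

test_that("allele alignment flips dosages, is involutive and coding-invariant", {
  w <- simulate_weight_table(12, seed = 8)
  g <- simulate_genotypes(genotype_spec(n_individuals = 150L, n_variants = 12L,
                                        seed = 8L), w)
  dm <- g$dosages
  dm$dosages[1, 1] <- 0.5   # fractional dosage to exercise 2 - d

  # recode a random subset of variants by the other allele
  flip_idx <- adipoquant:::with_seed(9, which(runif(12) < 0.5))
  dm_flipped <- dm
  tmp <- dm_flipped$variants$coded_allele[flip_idx]
  dm_flipped$variants$coded_allele[flip_idx] <-
    dm_flipped$variants$other_allele[flip_idx]
  dm_flipped$variants$other_allele[flip_idx] <- tmp
  dm_flipped$dosages[flip_idx, ] <- 2 - dm_flipped$dosages[flip_idx, ]
  dm_flipped$variants$frequency[flip_idx] <- 1 - dm_flipped$variants$frequency[flip_idx]

  a1 <- align_alleles(dm, w)
  a2 <- align_alleles(dm_flipped, w)
  expect_equal(a1$dosages, a2$dosages)                  # coding invariance
  expect_lt(max(abs(compute_grs(a1, w) - compute_grs(a2, w))), 1e-12)

  # involution: aligning twice equals aligning once
  a11 <- align_alleles(a1, w)
  expect_equal(a11$dosages, a1$dosages)
  expect_equal(a11$variants$coded_allele, a1$variants$coded_allele)

  # explicit flip arithmetic
  one <- dosage_matrix(matrix(c(2, 0.5), 1, 2,
                              dimnames = list("v1", c("i1", "i2"))),
                       data.frame(variant_id = "v1", coded_allele = "G",
                                  other_allele = "A", frequency = 0.4,
                                  missingness = 0, info_score = 1))
  wtab <- data.frame(variant_id = "v1", effect_allele = "A",
                     other_allele = "G", weight = 1)
  flipped <- align_alleles(one, wtab)
  expect_equal(as.numeric(flipped$dosages), c(0, 1.5))

  # mismatching alleles are dropped with a warning
  wbad <- wtab; wbad$effect_allele <- "C"; wbad$other_allele <- "T"
  expect_warning(out <- align_alleles(one, wbad), "neither")
  expect_equal(nrow(out$dosages), 0L)

  # strand-ambiguous variants are flagged
  amb <- dosage_matrix(matrix(1, 1, 2, dimnames = list("v2", c("i1", "i2"))),
                       data.frame(variant_id = "v2", coded_allele = "A",
                                  other_allele = "T", frequency = 0.5,
                                  missingness = 0, info_score = 1))
  wamb <- data.frame(variant_id = "v2", effect_allele = "A",
                     other_allele = "T", weight = 1)
  expect_true(align_alleles(amb, wamb)$variants$strand_ambiguous)
  expect_equal(nrow(align_alleles(amb, wamb, drop_ambiguous = TRUE)$dosages), 0L)
})

test_that("GRS is the weighted dosage sum, linear, with mean imputation", {
  D <- matrix(c(2, 1,
                1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("v1", "v2"), c("i1", "i2")))
  v <- data.frame(variant_id = c("v1", "v2"), coded_allele = "A",
                  other_allele = "G", frequency = c(0.5, 0.3),
                  missingness = 0, info_score = 1)
  w <- data.frame(variant_id = c("v1", "v2"), effect_allele = "A",
                  other_allele = "G", weight = c(0.1, 0.2))
  sc <- compute_grs(dosage_matrix(D, v), w)
  expect_equal(unname(sc["i1"]), 0.1 * 2 + 0.2 * 1)   # 0.4
  expect_equal(unname(sc["i2"]), 0.1 * 1)

  w2 <- w; w2$weight <- 2 * w$weight
  expect_equal(unname(compute_grs(dosage_matrix(D, v), w2)), unname(2 * sc))

  Dz <- D * 0
  expect_true(all(compute_grs(dosage_matrix(Dz, v), w) == 0))

  # missing dosages: per-variant mean imputation
  Dna <- D; Dna[1, 2] <- NA
  sc_na <- compute_grs(dosage_matrix(Dna, v), w)
  expect_equal(unname(sc_na["i2"]), 0.1 * 2 + 0.2 * 0)  # mean of row 1 is 2
  expect_equal(attr(sc_na, "n_imputed"), 1L)

  wother <- data.frame(variant_id = "zzz", effect_allele = "A",
                       other_allele = "G", weight = 1)
  expect_error(compute_grs(dosage_matrix(D, v), wother), "no variants shared")
})

test_that("GRS association recovers planted effects and ignores score shifts", {
  w <- simulate_weight_table(40, seed = 19)
  g <- simulate_genotypes(genotype_spec(n_individuals = 500L, n_variants = 40L,
                                        effect_per_sd_grs = 0.2, seed = 19L), w)
  sc <- compute_grs(g$dosages, w)
  res <- grs_association(sc, g$phenotype)
  beta_per_sd <- res$beta * sd(sc)   # model is per 1-unit GRS
  se_per_sd <- res$se * sd(sc)
  expect_lt(abs(beta_per_sd - 0.2), 3 * se_per_sd)
  expect_lt(res$ci_low, res$beta); expect_gt(res$ci_high, res$beta)

  shifted <- sc + 10
  res_shift <- grs_association(shifted, g$phenotype)
  expect_equal(res_shift$beta, res$beta, tolerance = 1e-10)
  expect_equal(res_shift$p, res$p, tolerance = 1e-10)

  # RINT variant reports in SD units of the phenotype
  res_rint <- grs_association(sc, g$phenotype, rint = TRUE)
  expect_true(is.finite(res_rint$beta))
})
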