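geno_pair <- function(a) matrix(a, ncol = 2, byrow = TRUE)

test_that("genotype chi-square matches hand-computed worked examples", {
  # perfectly concordant 2x2 table [[10, 0], [0, 10]]: E = 5 per cell,
  # chi2 = 4 * (10 - 5)^2 / 5 ... over all four cells = 20, df = 1
  gA <- geno_pair(rep(c("A", "A", "C", "C"), times = c(10, 10, 10, 10)))
  res <- genotype_chisq(NULL, gA, gA)
  expect_equal(res$chi2, 20, tolerance = 1e-12)
  expect_identical(res$df, 1L)
  expect_identical(res$table_dims, c(2L, 2L))
  # identical tables with k equally frequent classes: chi2 = n * (k - 1)
  expect_equal(res$chi2, res$n * (2 - 1), tolerance = 1e-12)
})

test_that("genotype chi-square equals the manual statistic on random tables", {
  withr::with_seed(13, {
    for (i in 1:5) {
      gA <- geno_pair(sample(c("A", "C"), 2 * 60, replace = TRUE))
      gB <- geno_pair(sample(c("G", "T"), 2 * 60, replace = TRUE))
      res <- genotype_chisq(NULL, gA, gB)
      cA <- paste(pmin(gA[, 1], gA[, 2]), pmax(gA[, 1], gA[, 2]), sep = "/")
      cB <- paste(pmin(gB[, 1], gB[, 2]), pmax(gB[, 1], gB[, 2]), sep = "/")
      tab <- table(cA, cB)
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      expect_equal(res$chi2, sum((tab - E)^2 / E), tolerance = 1e-10)
      expect_identical(res$df, (nrow(tab) - 1L) * (ncol(tab) - 1L))
      expect_equal(res$p, pchisq(res$chi2, res$df, lower.tail = FALSE))
      # symmetry in the two arguments
      swapped <- genotype_chisq(NULL, gB, gA)
      expect_equal(swapped$chi2, res$chi2)
      expect_identical(swapped$df, res$df)
      # joint permutation of individuals leaves the statistic unchanged
      perm <- sample(60)
      res_p <- genotype_chisq(NULL, gA[perm, ], gB[perm, ])
      expect_equal(res_p$chi2, res$chi2)
    }
  })
})

test_that("independently shuffled genotypes give a roughly uniform p", {
  g <- simulate_genotype_cohort(geno_design(120, r2_link = 0.9, seed = 2))
  gA <- g$genotypes$geno$snpA_ce
  gB <- g$genotypes$geno$snpB_intron
  withr::with_seed(3, {
    p <- replicate(200, {
      genotype_chisq(NULL, gA, gB[sample(nrow(gB)), ])$p
    })
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("degenerate and undersized chi-square inputs are rejected", {
  mono <- geno_pair(rep("A", 20))
  di <- geno_pair(rep(c("A", "C"), 5))
  expect_error(genotype_chisq(NULL, mono, di), "degenerate|\\[2, 8\\]")
  expect_error(genotype_chisq(NULL, di[1, , drop = FALSE],
                              di[1, , drop = FALSE]), ">= 2")
})

test_that("repeat dosage counts exact motif tandems only", {
  locus <- list(ref = "A", alts = c("ACATCCATCCATC", "ACATC", "ACATCCA",
                                    "AGATCCATC"))
  d <- repeat_dosage(locus)
  expect_equal(unname(d["A"]), 0)
  expect_equal(unname(d["ACATCCATCCATC"]), 3)
  expect_equal(unname(d["ACATC"]), 1)
  expect_true(is.na(d["ACATCCA"]))    # length 6 not a multiple of 4
  expect_true(is.na(d["AGATCCATC"]))  # insert is not a CATC tandem
})

test_that("per-individual repeat dosage sums the two alleles", {
  g <- simulate_genotype_cohort(geno_design(60, seed = 6))
  dos <- individual_repeat_dosage(g$genotypes, "repeat_catc")
  expect_equal(unname(dos), g$truth$repeat_extra_units)
})

test_that("haplotype dose requires concordant risk-allele counts", {
  gt <- genotype_table(
    individuals = c("i1", "i2", "i3", "i4", "i5"),
    loci = list(
      snpB_intron = list(id = "snpB_intron", chrom = "chrT", pos = 4500L,
                         ref = "A", alts = "C", risk_allele = "C"),
      snpA_ce = list(id = "snpA_ce", chrom = "chrT", pos = 3050L,
                     ref = "C", alts = "G", risk_allele = "G")
    ),
    geno = list(
      snpB_intron = geno_pair(c("A", "C",  "C", "C",  "A", "A",
                                "A", "C",  NA, NA)),
      snpA_ce     = geno_pair(c("C", "G",  "G", "G",  "C", "C",
                                "C", "C",  "C", "G"))
    ))
  hd <- haplotype_dose(gt)
  expect_identical(hd$dose[1:3], c(1L, 2L, 0L))
  expect_true(is.na(hd$dose[4]))
  expect_identical(hd$exclusion_reason[4], "discordant")
  expect_identical(hd$exclusion_reason[5], "missing")
  # excluded + assigned = total individuals
  expect_identical(sum(is.na(hd$dose)) + sum(!is.na(hd$dose)), nrow(hd))
})

test_that("OLS association matches hand computation and flags zero residuals", {
  # Sxy / Sxx = 6.5 / 5
  res <- ols_association(c(0, 1, 2, 4), c(0, 1, 2, 3))
  expect_equal(res$beta1, 1.3, tolerance = 1e-12)
  dose <- rep(0:2, each = 10)
  exact <- ols_association(1 + 0.175 * dose, dose)
  expect_equal(exact$beta1, 0.175, tolerance = 1e-12)
  expect_true(exact$zero_residual)
  expect_true(is.na(exact$p1))
  expect_error(ols_association(rnorm(10), rep(1, 10)), "collinear|rank")
  expect_error(ols_association(c(1, 2), c(0, 1)), "n > number")
})

test_that("OLS with covariates keeps the dose coefficient interpretable", {
  withr::with_seed(8, {
    dose <- sample(0:2, 120, replace = TRUE)
    age <- rnorm(120, 65, 8)
    y <- 0.5 + 0.175 * dose + 0.02 * age + rnorm(120, 0, 0.1)
    res <- ols_association(y, dose, covariates = data.frame(age = age))
    expect_lt(abs(res$beta1 - 0.175), 0.06)
    expect_lt(res$p1, 0.01)
  })
})

test_that("Spearman correlation uses average ranks", {
  expect_equal(spearman_corr(1:10, (1:10)^3), 1.0)
  expect_equal(spearman_corr(1:10, -(1:10)^3), -1.0)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d^2 summing to 4
  expect_equal(spearman_corr(1:4, c(2, 1, 4, 3)), 0.6)
  expect_warning(r <- spearman_corr(1:5, rep(2, 5)), "variance")
  expect_true(is.na(r))
  expect_error(spearman_corr(1:2, 1:2), ">= 3")
})

test_that("delta-delta-Ct computes fold changes with the Ct-40 clamp", {
  # sample dCt = 25 - 20 = 5; reference dCt = 26 - 20 = 6; fold = 2^1 = 2
  fold <- delta_delta_ct(c(26, 25), geno_pair(c(20, 20, 20, 20))[, 1:2],
                         reference = 1L)
  expect_equal(fold, c(1, 2))
  same <- delta_delta_ct(c(24, 24), matrix(c(20, 20), ncol = 1))
  expect_equal(same, c(1, 1))
  # Ct 43 with the default limit behaves exactly like Ct 40
  clamped <- delta_delta_ct(c(30, 43), matrix(c(20, 20), ncol = 1))
  manual <- delta_delta_ct(c(30, 40), matrix(c(20, 20), ncol = 1))
  expect_equal(clamped, manual)
  expect_error(delta_delta_ct(c(30, 31), NULL), "housekeeper")
})
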