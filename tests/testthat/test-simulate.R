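test_that("identical seeds give byte-identical simulated output", {
  p <- sample_params(psi_true = 0.2, depth = 300, seed = 99)
  a <- simulate_rnaseq_sample(toy, p)
  b <- simulate_rnaseq_sample(toy, p)
  expect_identical(a, b)
  pa <- withr::local_tempfile(fileext = ".sam")
  pb <- withr::local_tempfile(fileext = ".sam")
  simulate_rnaseq_sample(toy, p, sam_path = pa)
  simulate_rnaseq_sample(toy, p, sam_path = pb)
  expect_identical(readLines(pa), readLines(pb))
})

test_that("degenerate PSI values shut off the corresponding junctions", {
  null <- simulate_rnaseq_sample(
    toy, sample_params(psi_true = 0, error_rate = 0, depth = 300, seed = 3))
  expect_identical(sum(null$truth$counts[c("e20-CE128", "e20-CE178",
                                           "CE-e21")]), 0L)
  full <- simulate_rnaseq_sample(
    toy, sample_params(psi_true = 1, error_rate = 0, depth = 200, seed = 4))
  expect_identical(full$truth$counts[["e20-e21"]], 0L)
  expect_gt(full$truth$counts[["CE-e21"]], 0L)
})

test_that("truth junction counts conserve emitted junction events", {
  for (s in 1:5) {
    sim <- simulate_rnaseq_sample(
      toy, sample_params(psi_true = 0.4, depth = 250, seed = s))
    expect_identical(sum(sim$truth$counts), sim$truth$n_junction_events)
    # at the default read length no read can span two junctions
    expect_identical(sim$truth$n_junction_events, sim$truth$n_junction_reads)
  }
})

test_that("empirical CE-read fraction converges to psi_true at depth", {
  sim <- simulate_rnaseq_sample(
    toy, sample_params(psi_true = 0.3, depth = 1e5, duplicate_rate = 0,
                       nonunique_rate = 0, error_rate = 0, seed = 8))
  cts <- sim$truth$counts
  inc <- (cts[["e20-CE128"]] + cts[["e20-CE178"]] + cts[["CE-e21"]]) / 2
  psi_hat <- inc / (inc + cts[["e20-e21"]])
  expect_lt(abs(psi_hat - 0.3), 0.01)
})

test_that("duplicate and MAPQ structure appear at the configured rates", {
  sim <- simulate_rnaseq_sample(
    toy, sample_params(depth = 3000, duplicate_rate = 0.2,
                       nonunique_rate = 0.1, seed = 21))
  r <- sim$records
  dup <- bitwAnd(r$flag, 1024L) != 0L
  nonuniq <- r$mapq < 255L
  n_base <- sum(!dup & !nonuniq)
  expect_gt(sum(dup) / n_base, 0.15); expect_lt(sum(dup) / n_base, 0.25)
  expect_gt(sum(nonuniq) / n_base, 0.06); expect_lt(sum(nonuniq) / n_base, 0.14)
  # duplicates are exact copies of retained reads apart from id and flag
  expect_true(all(r$pos[dup] %in% r$pos[!dup]))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sample_params(psi_true = 1.2), "\\[0, 1\\]")
  expect_error(sample_params(depth = 0), "depth")
  expect_error(sample_params(read_length = 10), "overhang")
})

test_that("cohort simulation respects prevalence and is reproducible", {
  des <- cohort_design(
    data.frame(label = c("control", "case"), n = c(8L, 30L),
               psi_shape1 = c(2, 2), psi_shape2 = c(8, 8),
               prevalence = c(0, 0.5)),
    defaults = sample_params(depth = 120, error_rate = 0), seed = 17)
  a <- simulate_cohort(toy, des)
  b <- simulate_cohort(toy, des)
  expect_identical(a$truth, b$truth)
  ctrl <- a$truth[a$truth$group == "control", ]
  expect_true(all(ctrl$psi_true == 0))
  ctrl_counts <- sapply(a$samples[ctrl$sample_id], function(r) {
    ct <- count_sample(r, toy)
    ct$e20_ce128 + ct$e20_ce178 + ct$ce_e21
  })
  expect_true(all(ctrl_counts == 0L))
  case_pos <- mean(a$truth$psi_true[a$truth$group == "case"] > 0)
  expect_gt(case_pos, 0.25); expect_lt(case_pos, 0.75)  # binomial band, n=30
  expect_error(cohort_design(data.frame()), "empty|columns")
})

test_that("amplicon simulation honours the inclusion odds ratio", {
  sym <- simulate_amplicon_reads(toy, inclusion_odds_ratio = 1,
                                 n_reads = 4000, seed = 31)
  share_sym <- sym$truth$ce_reads_risk /
    (sym$truth$ce_reads_risk + sym$truth$ce_reads_ref)
  expect_lt(abs(share_sym - 0.5), 0.05)
  skew <- simulate_amplicon_reads(toy, inclusion_odds_ratio = 3,
                                  n_reads = 3000, ce_fraction = 1, seed = 32)
  share_skew <- skew$truth$ce_reads_risk /
    (skew$truth$ce_reads_risk + skew$truth$ce_reads_ref)
  expect_lt(abs(share_skew - 0.75), 0.03)  # p = OR / (OR + 1)
  empty <- simulate_amplicon_reads(toy, n_reads = 0)
  expect_identical(nrow(empty$records), 0L)
  expect_identical(empty$truth$ce_reads_risk + empty$truth$ce_reads_ref, 0L)
  hom <- rep(toy$snp_ce$ref, 2)
  expect_error(simulate_amplicon_reads(toy, genotype = hom), "heterozygous")
  expect_error(simulate_amplicon_reads(toy, inclusion_odds_ratio = 0), "> 0")
})

test_that("perfect LD makes the two SNP doses identical", {
  g <- simulate_genotype_cohort(geno_design(150, r2_link = 1, seed = 41))
  expect_identical(g$truth$snpA_dose, g$truth$snpB_dose)
  expect_identical(g$truth$snpA_dose, g$truth$hap_dose)
  # risk-hom individuals carry 3-5 extra units per haplotype, ref-hom 0-2
  hom_risk <- g$truth$hap_dose == 2L
  hom_ref <- g$truth$hap_dose == 0L
  expect_true(all(g$truth$repeat_extra_units[hom_risk] %in% 6:10))
  expect_true(all(g$truth$repeat_extra_units[hom_ref] %in% 0:4))
  expect_error(geno_design(10, r2_link = 1.5), "r2_link")
})

test_that("genotype tables survive a VCF roundtrip", {
  path <- withr::local_tempfile(fileext = ".vcf")
  g <- simulate_genotype_cohort(geno_design(40, seed = 43), vcf_path = path)
  gt2 <- read_genotypes(path)
  expect_identical(gt2$individuals, g$genotypes$individuals)
  for (l in names(g$genotypes$geno))
    expect_identical(unname(gt2$geno[[l]]), unname(g$genotypes$geno[[l]]))
})

test_that("abundance simulation is an exact line at sigma zero", {
  ab <- simulate_abundance(c(0L, 1L, 2L), beta0 = 1, beta1 = 0.175, sigma = 0)
  expect_equal(ab$abundance, c(1, 1.175, 1.35))
  expect_error(simulate_abundance(c(0L, 3L)), "doses")
  expect_error(simulate_abundance(1L, sigma = -1), "sigma")
})
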