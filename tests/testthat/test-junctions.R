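test_that("CIGAR blocks are reconstructed by reference-consumption rules", {
  aln <- parse_spliced_alignment(make_record(1151L, "50M3800N50M"))
  expect_equal(unname(aln$blocks), rbind(c(1151, 1200), c(5001, 5050)),
               ignore_attr = TRUE)
  aln2 <- parse_spliced_alignment(make_record(3079L, "50M1872N50M"))
  expect_equal(unname(aln2$blocks), rbind(c(3079, 3128), c(5001, 5050)),
               ignore_attr = TRUE)
  aln3 <- parse_spliced_alignment(make_record(100L, "100M"))
  expect_equal(unname(aln3$blocks), rbind(c(100, 199)), ignore_attr = TRUE)
  # D extends a block (a deletion is not a splice); I and S consume no reference
  aln4 <- parse_spliced_alignment(make_record(100L, "10M5D10M"))
  expect_equal(unname(aln4$blocks), rbind(c(100, 124)), ignore_attr = TRUE)
  aln5 <- parse_spliced_alignment(make_record(100L, "5S10M3I10M100N10M"))
  expect_equal(unname(aln5$blocks), rbind(c(100, 119), c(220, 229)),
               ignore_attr = TRUE)
})

test_that("unsupported or malformed CIGARs are rejected", {
  expect_error(parse_spliced_alignment(make_record(100L, "10M2P10M")),
               "unsupported")
  expect_error(parse_spliced_alignment(make_record(100L, "10M2B10M")),
               "unsupported")
  expect_error(parse_spliced_alignment(make_record(100L, "*")), "CIGAR")
  expect_error(parse_spliced_alignment(make_record(100L, "")), "CIGAR")
})

test_that("duplicate and MAPQ filters mirror the pipeline contract", {
  base <- parse_spliced_alignment(make_record(100L, "100M"))
  expect_true(passes_filters(base))
  dup <- parse_spliced_alignment(make_record(100L, "100M", flag = 16L + 1024L))
  expect_false(passes_filters(dup))
  expect_true(passes_filters(dup, drop_duplicates = FALSE))
  low <- parse_spliced_alignment(make_record(100L, "100M", mapq = 3L))
  expect_false(passes_filters(low))
  expect_true(passes_filters(low, unique_mapq = 0L))
})

test_that("junction extraction enforces the 6-nt overhang rule", {
  aln <- parse_spliced_alignment(make_record(1151L, "50M3800N50M"))
  j <- extract_junctions(aln)
  expect_identical(nrow(j), 1L)
  expect_equal(c(j$start, j$end), c(1201, 5000))
  expect_equal(c(j$left_overhang, j$right_overhang), c(50, 50))
  # left overhang 5 < 6: discarded
  short <- parse_spliced_alignment(make_record(1196L, "5M3800N50M"))
  expect_identical(nrow(extract_junctions(short)), 0L)
  expect_identical(nrow(extract_junctions(short, min_overhang = 5L)), 1L)
  unspliced <- parse_spliced_alignment(make_record(100L, "100M"))
  expect_identical(nrow(extract_junctions(unspliced)), 0L)
})

test_that("junctions classify by exact boundary match, strand-aware", {
  jj <- function(s, e, chrom = "chrT")
    list(chrom = chrom, start = s, end = e)
  expect_identical(classify_junction(jj(1201, 5000), toy), "e20-e21")
  expect_identical(classify_junction(jj(3129, 5000), toy), "e20-CE128")
  expect_identical(classify_junction(jj(3179, 5000), toy), "e20-CE178")
  expect_identical(classify_junction(jj(1201, 3000), toy), "CE-e21")
  expect_identical(classify_junction(jj(5151, 7000), toy), "e19-e20")
  expect_identical(classify_junction(jj(1202, 5000), toy), "unclassified")
  expect_identical(classify_junction(jj(1201, 5000, "chr1"), toy),
                   "unclassified")
})

test_that("count_sample matches the brute-force oracle on simulated reads", {
  sim <- simulate_rnaseq_sample(
    toy, sample_params(psi_true = 0.25, depth = 400, seed = 101))
  ct <- count_sample(sim$records, toy)
  or <- oracle_count(sim$records, toy)
  expect_counts_match_oracle(ct, or)
})

test_that("a null sample yields zero CE-junction counts", {
  sim <- simulate_rnaseq_sample(
    toy, sample_params(psi_true = 0, error_rate = 0, depth = 500, seed = 7))
  ct <- count_sample(sim$records, toy)
  expect_identical(ct$e20_ce128 + ct$e20_ce178 + ct$ce_e21, 0L)
  expect_gt(ct$e20_e21, 0L)
})

test_that("raising filters never increases any count", {
  sim <- simulate_rnaseq_sample(
    toy, sample_params(psi_true = 0.3, depth = 300, seed = 5))
  cols <- c("e19_e20", "e20_ce128", "e20_ce178", "ce_e21", "e20_e21",
            "unclassified")
  base <- count_sample(sim$records, toy, min_overhang = 6L, unique_mapq = 0L,
                       drop_duplicates = FALSE)
  tighter_oh <- count_sample(sim$records, toy, min_overhang = 20L,
                             unique_mapq = 0L, drop_duplicates = FALSE)
  tighter_mq <- count_sample(sim$records, toy, min_overhang = 6L,
                             unique_mapq = 255L, drop_duplicates = TRUE)
  expect_true(all(unlist(tighter_oh[, cols]) <= unlist(base[, cols])))
  expect_true(all(unlist(tighter_mq[, cols]) <= unlist(base[, cols])))
})

test_that("adding reads never decreases any count", {
  a <- simulate_rnaseq_sample(toy, sample_params(psi_true = 0.2, depth = 200,
                                                 seed = 1))
  b <- simulate_rnaseq_sample(toy, sample_params(psi_true = 0.2, depth = 200,
                                                 seed = 2))
  cols <- c("e19_e20", "e20_ce128", "e20_ce178", "ce_e21", "e20_e21",
            "unclassified", "intron_body", "within_ce", "exonic_reads",
            "library_size")
  ct_a <- count_sample(a$records, toy)
  ct_ab <- count_sample(rbind(a$records, b$records), toy)
  expect_true(all(unlist(ct_ab[, cols]) >= unlist(ct_a[, cols])))
})

test_that("mirroring the locus to the plus strand preserves named counts", {
  plus <- mirror_locus()
  p <- sample_params(psi_true = 0.3, depth = 400, seed = 33)
  cols <- c("e19_e20", "e20_ce128", "e20_ce178", "ce_e21", "e20_e21",
            "unclassified")
  ct_minus <- count_sample(simulate_rnaseq_sample(toy, p)$records, toy)
  ct_plus <- count_sample(simulate_rnaseq_sample(plus, p)$records, plus)
  expect_identical(unlist(ct_plus[, cols]), unlist(ct_minus[, cols]))
})

test_that("intron-body, within-CE and exonic tallies follow their definitions", {
  recs <- rbind(
    make_record(4200L, "100M", qname = "intronic"),        # intron, outside CE
    make_record(3010L, "100M", qname = "inside_ce"),       # wholly inside CE178
    make_record(3150L, "100M", qname = "ce_boundary"),     # CE178 into intron
    make_record(5050L, "100M", qname = "exonic_e20"),      # inside e20
    make_record(1151L, "50M3800N50M", qname = "spliced")   # e20-e21 junction
  )
  ct <- count_sample(recs, toy)
  expect_identical(ct$intron_body, 2L)     # intronic + ce_boundary
  expect_identical(ct$within_ce, 1L)       # inside_ce
  expect_identical(ct$exonic_reads, 4L)    # all but the purely intronic read
  expect_identical(ct$e20_e21, 1L)
  expect_identical(ct$library_size, 5L)
  or <- oracle_count(recs, toy)
  expect_counts_match_oracle(ct, or)
})

test_that("file input equals in-memory input and errors are explicit", {
  path <- withr::local_tempfile(fileext = ".sam")
  sim <- simulate_rnaseq_sample(toy, sample_params(depth = 150, seed = 12),
                                sam_path = path)
  ct_file <- count_sample(path, toy, sample_id = "x")
  ct_mem <- count_sample(sim$records, toy, sample_id = "x")
  expect_identical(as.data.frame(ct_file), as.data.frame(ct_mem))
  expect_error(count_sample(file.path(tempdir(), "absent.sam"), toy),
               "not found")
  other <- build_toy_locus(chrom_name = "chrX")
  expect_error(count_sample(path, other, sample_id = "x"), "chrX")
})
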