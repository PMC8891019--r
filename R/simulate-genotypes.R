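# Genotype-cohort simulator: two biallelic SNPs and a multi-allelic
# CATC-repeat indel linked through a latent risk haplotype.

#' Genotype-cohort design
#'
#' Haplotypes carry a latent risk/reference state with frequency
#' `risk_haplotype_freq`. Each observed locus (exonic-CE SNP proxy, intronic
#' SNP proxy, repeat allele class) copies that state with probability
#' `sqrt(r2_link)` and is drawn independently otherwise, giving pairwise LD
#' r-squared equal to `r2_link`. Risk-class haplotypes carry
#' `repeat_extra_given_risk` additional motif units (default 3-5), reference
#' haplotypes `repeat_extra_given_ref` (default 0-2).
#'
#' @param n_individuals Number of diploid individuals.
#' @param risk_haplotype_freq Risk-haplotype frequency in `[0, 1]`.
#' @param r2_link LD (r-squared) between the loci and the latent haplotype
#'   structure, in `[0, 1]`.
#' @param repeat_extra_given_risk Integer range of additional repeat units on
#'   risk-class haplotypes.
#' @param repeat_extra_given_ref Integer range on reference-class haplotypes.
#' @param seed Integer seed.
#' @return List of class `geno_design`.
#' @export
geno_design <- function(n_individuals, risk_haplotype_freq = 0.35,
                        r2_link = 0.9, repeat_extra_given_risk = 3:5,
                        repeat_extra_given_ref = 0:2, seed = 1L) {
  if (risk_haplotype_freq < 0 || risk_haplotype_freq > 1)
    stop("risk_haplotype_freq must lie in [0, 1]")
  if (r2_link < 0 || r2_link > 1) stop("r2_link must lie in [0, 1]")
  if (any(repeat_extra_given_risk < 0) || any(repeat_extra_given_ref < 0))
    stop("repeat unit ranges must be non-negative")
  structure(list(n_individuals = as.integer(n_individuals),
                 risk_haplotype_freq = risk_haplotype_freq,
                 r2_link = r2_link,
                 repeat_extra_given_risk = as.integer(repeat_extra_given_risk),
                 repeat_extra_given_ref = as.integer(repeat_extra_given_ref),
                 seed = as.integer(seed)),
            class = "geno_design")
}

#' Construct a genotype table
#'
#' Container for unphased genotypes: per locus, a two-column character matrix
#' of allele strings (one row per individual; `NA` for missing calls) plus
#' locus metadata (`id`, `chrom`, `pos`, `ref`, `alts`, optional
#' `risk_allele`).
#'
#' @param individuals Character vector of individual ids.
#' @param loci Named list of locus metadata lists.
#' @param geno Named list (same names as `loci`) of n-by-2 allele matrices.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, loci, geno) {
  stopifnot(identical(sort(names(loci)), sort(names(geno))))
  for (l in names(geno)) {
    if (nrow(geno[[l]]) != length(individuals))
      stop("genotype rows must match individuals at ", l)
  }
  structure(list(individuals = individuals, loci = loci, geno = geno),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$individuals), "individuals,",
      length(x$loci), "loci\n")
  for (l in x$loci)
    cat(sprintf("  %s %s:%d ref=%s alts=%s\n", l$id, l$chrom, l$pos,
                l$ref, paste(l$alts, collapse = ",")))
  invisible(x)
}

#' Simulate a genotyped cohort with a linked repeat indel
#'
#' Draws `2n` haplotypes and emits three loci: a biallelic exonic-CE SNP
#' proxy (`snpA_ce`, C>G like the dbSNP record of the CE SNP), a biallelic
#' intronic SNP proxy (`snpB_intron`, A>C) and a multi-allelic indel
#' (`repeat_catc`) whose ALT alleles are tandem CATC insertions of the extra
#' units carried by each haplotype. Risk alleles are the ALTs. The truth
#' table records each individual's latent risk-haplotype dose and per-locus
#' risk-allele doses.
#'
#' @param design A [geno_design()] object.
#' @param vcf_path Optional path; when given a VCF v4.2 file is written.
#' @return List with `genotypes` (a `genotype_table`), `truth` (data frame:
#'   `individual`, `hap_dose`, `snpA_dose`, `snpB_dose`, `repeat_extra_units`)
#'   and `vcf_path`.
#' @export
simulate_genotype_cohort <- function(design, vcf_path = NULL) {
  stopifnot(inherits(design, "geno_design"))
  n <- design$n_individuals
  p <- design$risk_haplotype_freq
  q <- sqrt(design$r2_link)

  out <- withr::with_seed(design$seed, {
    H <- matrix(runif(2L * n) < p, ncol = 2L)          # latent risk state
    link <- function() {
      copyH <- matrix(runif(2L * n) < q, ncol = 2L)
      indep <- matrix(runif(2L * n) < p, ncol = 2L)
      ifelse(copyH, H, indep)
    }
    A <- link(); B <- link(); C <- link()
    draw <- function(vals, m) {
      if (length(vals) == 1L) rep(vals, m) else sample(vals, m, replace = TRUE)
    }
    extra <- matrix(0L, n, 2L)
    extra[C] <- draw(design$repeat_extra_given_risk, sum(C))
    extra[!C] <- draw(design$repeat_extra_given_ref, sum(!C))
    list(H = H, A = A, B = B, extra = extra)
  })

  ids <- sprintf("ind_%04d", seq_len(n))
  snp_allele <- function(M, ref, alt) {
    g <- matrix(ifelse(M, alt, ref), ncol = 2L)
    t(apply(g, 1L, sort))                               # unphased, sorted
  }
  rep_allele_str <- function(k) ifelse(k == 0L, "A",
                                       paste0("A", strrep("CATC", k)))
  rep_g <- matrix(rep_allele_str(out$extra), ncol = 2L)
  rep_g <- t(apply(rep_g, 1L, function(r) r[order(nchar(r), r)]))

  loci <- list(
    snpA_ce = list(id = "snpA_ce", chrom = "chrT", pos = 3050L,
                   ref = "C", alts = "G", risk_allele = "G"),
    snpB_intron = list(id = "snpB_intron", chrom = "chrT", pos = 4500L,
                       ref = "A", alts = "C", risk_allele = "C"),
    repeat_catc = list(id = "repeat_catc", chrom = "chrT", pos = 4000L,
                       ref = "A",
                       alts = sort(setdiff(unique(as.vector(rep_g)), "A")),
                       risk_allele = NA_character_)
  )
  geno <- list(
    snpA_ce = snp_allele(out$A, "C", "G"),
    snpB_intron = snp_allele(out$B, "A", "C"),
    repeat_catc = rep_g
  )
  gt <- genotype_table(ids, loci, geno)
  truth <- data.frame(
    individual = ids,
    hap_dose = as.integer(rowSums(out$H)),
    snpA_dose = as.integer(rowSums(out$A)),
    snpB_dose = as.integer(rowSums(out$B)),
    repeat_extra_units = as.integer(rowSums(out$extra)),
    stringsAsFactors = FALSE)
  if (!is.null(vcf_path)) write_vcf(gt, vcf_path)
  list(genotypes = gt, truth = truth, vcf_path = vcf_path)
}

#' Write a genotype table as VCF v4.2
#'
#' Emits CHROM/POS/ID/REF/ALT and per-individual unphased GT fields;
#' multi-allelic records (the repeat indel) list one ALT per observed
#' insertion allele.
#'
#' @param gt A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chrT,length=12000>",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gt$individuals), collapse = "\t"))
  for (l in gt$loci) {
    alleles <- c(l$ref, l$alts)
    g <- gt$geno[[l$id]]
    idx <- matrix(match(g, alleles) - 1L, ncol = 2L)
    if (anyNA(idx)) stop("genotype allele not among ref/alts at ", l$id)
    gts <- paste(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]), sep = "/")
    lines <- c(lines,
               paste(c(l$chrom, l$pos, l$id, l$ref,
                       paste(l$alts, collapse = ","), ".", "PASS", ".", "GT",
                       gts), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses GT fields of a VCF (v4.2; multi-allelic records allowed) into a
#' `genotype_table` of unordered allele-string pairs. Missing genotypes
#' (`./.`) become `NA` alleles.
#'
#' @param path VCF file path.
#' @return A `genotype_table`.
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt_raw)
  loci <- list()
  geno <- list()
  for (i in seq_len(nrow(fix))) {
    lid <- fix[i, "ID"]
    if (is.na(lid) || lid == ".") lid <- paste0("locus", i)
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",")[[1]])
    parts <- strsplit(gt_raw[i, ], "[/|]")
    am <- t(vapply(parts, function(pp) {
      a <- suppressWarnings(as.integer(pp)) + 1L
      al <- alleles[a]
      if (anyNA(al)) c(NA_character_, NA_character_) else sort(al)
    }, character(2)))
    loci[[lid]] <- list(id = lid, chrom = fix[i, "CHROM"],
                        pos = as.integer(fix[i, "POS"]),
                        ref = fix[i, "REF"],
                        alts = strsplit(fix[i, "ALT"], ",")[[1]],
                        risk_allele = NA_character_)
    geno[[lid]] <- unname(am)
  }
  genotype_table(ids, loci, geno)
}

#' Simulate CE abundance as a linear function of haplotype dose
#'
#' `abundance = beta0 + beta1 * dose + Normal(0, sigma)` per individual, the
#' generative counterpart of the dose-association regression.
#'
#' @param doses Integer vector of risk-haplotype doses in `{0, 1, 2}`.
#' @param beta0 Intercept.
#' @param beta1 Dose coefficient.
#' @param sigma Residual standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Data frame with `individual`, `dose`, `abundance`.
#' @export
simulate_abundance <- function(doses, beta0 = 1, beta1 = 0.175, sigma = 0.3,
                               seed = 1L) {
  if (!all(doses %in% 0:2)) stop("doses must lie in {0, 1, 2}")
  if (sigma < 0) stop("sigma must be >= 0")
  ab <- withr::with_seed(as.integer(seed),
                         beta0 + beta1 * doses + rnorm(length(doses), 0, sigma))
  data.frame(individual = sprintf("ind_%04d", seq_along(doses)),
             dose = as.integer(doses), abundance = ab,
             stringsAsFactors = FALSE)
}
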