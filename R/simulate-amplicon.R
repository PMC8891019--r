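# Amplicon-read simulator: deep sequencing of an RT-PCR product spanning
# e19 -> e21, used for allele-specific CE inclusion in heterozygous samples.

#' Simulate amplicon reads over the e19-e21 product
#'
#' Each read covers the full spliced product of one isoform (canonical,
#' CE128 or CE178). CE-class reads carry one of the heterozygote's two
#' forward-strand alleles at the CE SNP, with risk:reference odds equal to
#' `inclusion_odds_ratio` (so the expected risk-allele share among CE reads
#' is `OR / (OR + 1)`); canonical reads exclude the CE and carry no base at
#' the SNP. Reads are emitted as spliced SAM-style records against the toy
#' locus, plus the realized ground-truth tallies.
#'
#' @param locus A [build_toy_locus()] object.
#' @param genotype Character vector of the two forward-strand alleles at the
#'   CE SNP; must be heterozygous (allelic imbalance is undefined otherwise).
#' @param inclusion_odds_ratio Risk:reference inclusion odds among CE reads
#'   (> 0).
#' @param n_reads Number of amplicon reads.
#' @param ce_fraction Fraction of reads from CE-containing isoforms.
#' @param ce178_share Fraction of CE reads using the 178-bp form.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return List with `records` (SAM-field data frame), `truth` (realized
#'   class and allele counts) and `snp` (the SNP-site descriptor).
#' @export
simulate_amplicon_reads <- function(locus, genotype = snp_alleles(locus$snp_ce),
                                    inclusion_odds_ratio = 1, n_reads = 1000L,
                                    ce_fraction = 0.5, ce178_share = 0.1,
                                    error_rate = 0, seed = 1L) {
  stopifnot(inherits(locus, "toy_locus"))
  snp <- locus$snp_ce
  genotype <- unname(as.character(genotype))
  if (length(genotype) != 2L || genotype[1] == genotype[2])
    stop("genotype must be heterozygous at the CE SNP")
  if (!all(genotype %in% c(snp$ref, snp$alt)))
    stop("genotype alleles must be the SNP's ref/alt bases")
  if (inclusion_odds_ratio <= 0) stop("inclusion_odds_ratio must be > 0")
  if (ce_fraction < 0 || ce_fraction > 1 || ce178_share < 0 || ce178_share > 1)
    stop("fractions must lie in [0, 1]")
  n_reads <- as.integer(n_reads)

  al <- snp_alleles(snp)
  p_risk <- inclusion_odds_ratio / (inclusion_odds_ratio + 1)

  # one template alignment per isoform: full exon chain
  iso_names <- c("canonical", "CE128", "CE178")
  tmpl <- lapply(stats::setNames(nm = iso_names), function(iso) {
    m <- isoform_map(locus, iso)
    bl <- reads_to_blocks(m, 1L, m$tlen, locus$strand)
    rec <- blocks_to_records(bl)
    seqs <- blocks_to_seq(bl, locus$refseq, 0)
    # offset of the SNP within the forward-strand concatenated sequence
    snp_off <- NA_integer_
    hit <- which(bl$start <= snp$pos & bl$end >= snp$pos)
    if (length(hit)) {
      before <- if (hit > 1L) sum(bl$end[seq_len(hit - 1L)] -
                                    bl$start[seq_len(hit - 1L)] + 1L) else 0L
      snp_off <- before + (snp$pos - bl$start[hit] + 1L)
    }
    list(pos = rec$pos, cigar = rec$cigar, seq = seqs, snp_off = snp_off)
  })

  out <- withr::with_seed(as.integer(seed), {
    probs <- c(1 - ce_fraction, ce_fraction * (1 - ce178_share),
               ce_fraction * ce178_share)
    cls <- if (n_reads > 0L)
      sample(iso_names, n_reads, replace = TRUE, prob = probs)
    else character(0)
    is_ce <- cls != "canonical"
    allele <- rep(NA_character_, n_reads)
    allele[is_ce] <- ifelse(runif(sum(is_ce)) < p_risk,
                            al[["risk"]], al[["ref"]])
    seqs <- vapply(seq_len(n_reads), function(i) {
      t <- tmpl[[cls[i]]]
      s <- t$seq
      if (!is.na(allele[i])) substr(s, t$snp_off, t$snp_off) <- allele[i]
      s
    }, character(1))
    if (error_rate > 0 && n_reads > 0L) {
      nerr <- rbinom(n_reads, nchar(seqs), error_rate)
      for (i in which(nerr > 0L)) {
        s <- strsplit(seqs[i], "")[[1]]
        at <- sample.int(length(s), nerr[i])
        s[at] <- vapply(s[at], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1))
        seqs[i] <- paste0(s, collapse = "")
      }
    }
    records <- data.frame(
      qname = sprintf("amp_%06d", seq_len(n_reads)),
      flag = rep(if (locus$strand == "-") 16L else 0L, n_reads),
      rname = rep(locus$chrom, n_reads),
      pos = vapply(cls, function(k) tmpl[[k]]$pos, integer(1),
                   USE.NAMES = FALSE),
      mapq = rep(255L, n_reads),
      cigar = vapply(cls, function(k) tmpl[[k]]$cigar, character(1),
                     USE.NAMES = FALSE),
      seq = seqs, stringsAsFactors = FALSE)
    truth <- list(
      n_reads = n_reads,
      class_counts = stats::setNames(
        as.integer(table(factor(cls, levels = iso_names))), iso_names),
      ce_reads_risk = sum(allele == al[["risk"]], na.rm = TRUE),
      ce_reads_ref = sum(allele == al[["ref"]], na.rm = TRUE),
      odds_ratio = inclusion_odds_ratio, seed = as.integer(seed))
    list(records = records, truth = truth)
  })
  out$snp <- snp
  out
}
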