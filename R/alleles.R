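# Strand-aware allele handling and allele-specific CE inclusion from
# amplicon reads. Alleles are stored on the forward strand throughout
# (dbSNP/VCF convention); the gene-strand representation is a display
# conversion, because for a minus-strand gene the transcribed alleles are
# the reverse complement of the genotypes reported on dbSNP.

#' Convert an allele between forward-strand and gene-strand representation
#'
#' Reverse-complements the allele string when the gene is on the minus
#' strand; identity on the plus strand. For the CE SNP this maps the dbSNP
#' reference allele G to the transcribed base C (and the risk allele the
#' same way); the CATC repeat motif reads GATG on the minus strand. The
#' conversion is an involution: applying it twice returns the input.
#'
#' @param allele Character vector of allele strings over A/C/G/T.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of converted alleles.
#' @examples
#' strand_convert("G", "-")     # "C"
#' strand_convert("CATC", "-")  # "GATG"
#' @export
strand_convert <- function(allele, strand) {
  stopifnot(strand %in% c("+", "-"))
  if (strand == "+") return(allele)
  if (any(grepl("[^ACGT]", allele)))
    stop("allele must contain only A, C, G, T")
  comp <- chartr("ACGT", "TGCA", allele)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""),
         character(1))
}

iso_signature <- function(locus, iso) {
  m <- isoform_map(locus, iso)
  bl <- reads_to_blocks(m, 1L, m$tlen, locus$strand)
  paste(bl$start, bl$end, collapse = ";")
}

#' Classify an amplicon read by splice class and SNP base
#'
#' Derives the read's junction chain from its aligned blocks and matches it
#' against the three expected e19-e21 product structures (canonical, CE128,
#' CE178); anything else is class `"other"`. For CE-class reads covering the
#' CE SNP, the base at the SNP position is read from the aligned sequence and
#' reported on the forward strand; it is absent (`NA`) for canonical reads or
#' when no aligned block covers the position.
#'
#' @param aln A [parse_spliced_alignment()] object carrying `seq`.
#' @param locus A [build_toy_locus()] object.
#' @param snp SNP-site descriptor (default the locus CE SNP).
#' @return List of class `amplicon_read`: `read_id`, `class`, `base_at_snp`.
#' @export
classify_amplicon_read <- function(aln, locus, snp = locus$snp_ce) {
  sig <- paste(aln$blocks[, "start"], aln$blocks[, "end"], collapse = ";")
  sigs <- vapply(c("canonical", "CE128", "CE178"), function(i)
    iso_signature(locus, i), character(1))
  cls <- names(sigs)[match(sig, sigs)]
  if (is.na(cls)) cls <- "other"
  base <- NA_character_
  hit <- which(aln$blocks[, "start"] <= snp$pos & aln$blocks[, "end"] >= snp$pos)
  if (length(hit) && !is.na(aln$seq) && cls %in% c("CE128", "CE178")) {
    w <- aln$blocks[, "end"] - aln$blocks[, "start"] + 1L
    before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
    off <- before + (snp$pos - aln$blocks[hit, "start"] + 1L)
    base <- substr(aln$seq, off, off)
  }
  structure(list(read_id = aln$read_id, class = cls, base_at_snp = base),
            class = "amplicon_read")
}

#' Classify a table of amplicon records
#'
#' Vectorized wrapper around the per-read classification for the record
#' tables produced by [simulate_amplicon_reads()] or read via [read_sam()].
#'
#' @param records Data frame of SAM fields (`qname`, `pos`, `cigar`, `seq`).
#' @param locus A [build_toy_locus()] object.
#' @param snp SNP-site descriptor (default the locus CE SNP).
#' @return Data frame with `read_id`, `class`, `base_at_snp`.
#' @export
classify_amplicon_reads <- function(records, locus, snp = locus$snp_ce) {
  if (nrow(records) == 0L)
    return(data.frame(read_id = character(0), class = character(0),
                      base_at_snp = character(0), stringsAsFactors = FALSE))
  blocks <- alignment_blocks(records$pos, records$cigar)
  sig <- blocks[, list(sig = paste(start, end, collapse = ";")), by = rid]
  sigs <- vapply(c("canonical", "CE128", "CE178"), function(i)
    iso_signature(locus, i), character(1))
  cls <- names(sigs)[match(sig$sig, sigs)]
  cls[is.na(cls)] <- "other"

  # forward-strand offset of the SNP within each read's concatenated blocks
  blocks[, w := end - start + 1L]
  blocks[, cum_before := cumsum(c(0L, w[-.N])), by = rid]
  cov <- blocks[start <= snp$pos & end >= snp$pos]
  off <- rep(NA_integer_, nrow(sig))
  off[match(cov$rid, sig$rid)] <- cov$cum_before + (snp$pos - cov$start + 1L)
  base <- rep(NA_character_, nrow(sig))
  ce <- cls %in% c("CE128", "CE178") & !is.na(off)
  base[ce] <- substr(records$seq[sig$rid[ce]], off[ce], off[ce])
  data.frame(read_id = records$qname[sig$rid], class = cls,
             base_at_snp = base, stringsAsFactors = FALSE)
}

#' Tally CE-read alleles at the CE SNP
#'
#' Partitions CE-class reads by the forward-strand base at the SNP into
#' risk, reference and other (sequencing-error bases, excluded from the
#' percentage so as not to bias either allele). The risk percentage is
#' `risk / (risk + ref) * 100`, `NA` when there are no CE reads with a
#' called risk or reference base.
#'
#' @param reads Data frame from [classify_amplicon_reads()] (columns `class`,
#'   `base_at_snp`).
#' @param snp SNP-site descriptor.
#' @param sample_id Sample label.
#' @return One-row data frame of class `allele_tally`: `sample_id`,
#'   `ce_reads_risk`, `ce_reads_ref`, `ce_reads_other`, `canonical_reads`,
#'   `risk_pct`, `ref_pct`.
#' @export
tally_alleles <- function(reads, snp, sample_id = "sample") {
  al <- snp_alleles(snp)
  is_ce <- reads$class %in% c("CE128", "CE178")
  b <- reads$base_at_snp[is_ce]
  risk <- sum(b == al[["risk"]], na.rm = TRUE)
  ref <- sum(b == al[["ref"]], na.rm = TRUE)
  other <- sum(!is.na(b) & b != al[["risk"]] & b != al[["ref"]])
  denom <- risk + ref
  out <- data.frame(sample_id = sample_id, ce_reads_risk = risk,
                    ce_reads_ref = ref, ce_reads_other = other,
                    canonical_reads = sum(reads$class == "canonical"),
                    risk_pct = if (denom > 0) 100 * risk / denom else NA_real_,
                    ref_pct = if (denom > 0) 100 * ref / denom else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("allele_tally", "data.frame")
  out
}

#' Paired t-test for allelic imbalance of CE inclusion
#'
#' Pairs each heterozygous sample's risk and reference allele percentages
#' among CE reads and tests the mean difference with a two-sided paired
#' Student t-test: `d = risk% - ref%`, `t = mean(d) / (sd(d) / sqrt(n))`
#' with `n - 1` degrees of freedom.
#'
#' @param tallies Data frame with one row per sample and columns `risk_pct`
#'   and `ref_pct` (e.g. rbind-ed [tally_alleles()] rows), or a numeric
#'   vector of per-sample differences in percentage points.
#' @return List of class `paired_test_result`: `n_pairs`, `mean_diff`,
#'   `t_stat`, `df`, `p_two_sided`.
#' @export
paired_allele_imbalance_test <- function(tallies) {
  d <- if (is.numeric(tallies)) tallies
       else tallies$risk_pct - tallies$ref_pct
  if (anyNA(d)) stop("undefined allele percentage in input")
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired samples")
  if (sd(d) == 0) stop("degenerate variance: all paired differences equal")
  tt <- t.test(d, mu = 0, alternative = "two.sided")
  structure(list(n_pairs = n, mean_diff = mean(d),
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_two_sided = tt$p.value),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "paired allelic imbalance: n = %d, mean diff = %.2f pp, t = %.4f, df = %d, p = %.4g\n",
    x$n_pairs, x$mean_diff, x$t_stat, x$df, x$p_two_sided))
  invisible(x)
}

#' Per-sample exact binomial test of allelic balance
#'
#' Secondary check: tests each sample's risk-read count among risk+reference
#' CE reads against a 0.5 proportion with [stats::binom.test].
#'
#' @param tally One-row [tally_alleles()] result.
#' @return The `htest` object from [stats::binom.test].
#' @export
allele_binom_test <- function(tally) {
  n <- tally$ce_reads_risk + tally$ce_reads_ref
  if (n == 0L) stop("no CE reads with called alleles")
  stats::binom.test(tally$ce_reads_risk, n, p = 0.5)
}
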