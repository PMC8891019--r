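# Shared fixtures: a default locus and hand-built count rows / records.

toy <- build_toy_locus()

# a junction-count row with chosen values (defaults all zero)
make_counts <- function(sample_id = "s", e19_e20 = 0L, e20_ce128 = 0L,
                        e20_ce178 = 0L, ce_e21 = 0L, e20_e21 = 0L,
                        unclassified = 0L, intron_body = 0L, within_ce = 0L,
                        exonic_reads = 0L, library_size = 0L, naive_tpm = 0) {
  out <- data.frame(sample_id = sample_id, e19_e20 = e19_e20,
                    e20_ce128 = e20_ce128, e20_ce178 = e20_ce178,
                    ce_e21 = ce_e21, e20_e21 = e20_e21,
                    unclassified = unclassified, intron_body = intron_body,
                    within_ce = within_ce, exonic_reads = exonic_reads,
                    library_size = library_size, naive_tpm = naive_tpm,
                    stringsAsFactors = FALSE)
  class(out) <- c("junction_counts", "data.frame")
  out
}

# a single SAM-style record against the toy chromosome
make_record <- function(pos, cigar, qname = "r1", flag = 16L, mapq = 255L,
                        rname = "chrT", seq = "*") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, stringsAsFactors = FALSE)
}

# the toy locus mirrored onto the plus strand (coordinates reflected through
# the chromosome midpoint, which preserves transcript order)
mirror_locus <- function(locus = toy) {
  refl <- function(iv) sort(locus$chrom_length - rev(iv) + 1L)
  build_toy_locus(
    strand = "+",
    exons = lapply(locus$exons, refl),
    snp_ce_pos = locus$chrom_length - locus$snp_ce$pos + 1L,
    snp_intron_pos = locus$chrom_length - locus$snp_intron$pos + 1L,
    repeat_pos = locus$chrom_length - (locus$repeat_site$pos +
      4L * locus$repeat_site$baseline_units - 1L) + 1L,
    seed = locus$seed
  )
}
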