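#' Inclusive width of a 1-based genomic interval
#'
#' Width in bases of a closed interval given by its two endpoints, in either
#' order. The minus-strand convention of printing intervals high-to-low does
#' not change the width, so both `(17642414, 17642541)` and
#' `(17642541, 17642414)` give 128.
#'
#' @param start,end Integer endpoint positions (1-based, inclusive).
#' @return Integer vector of widths.
#' @examples
#' interval_width(3001, 3128)
#' @export
interval_width <- function(start, end) {
  abs(as.integer(end) - as.integer(start)) + 1L
}

DNA_BASES <- c("A", "C", "G", "T")

snp_site <- function(id, chrom, pos, ref, alt, risk_is_alt = TRUE) {
  stopifnot(ref %in% DNA_BASES, alt %in% DNA_BASES, ref != alt)
  structure(
    list(id = id, chrom = chrom, pos = as.integer(pos),
         ref = ref, alt = alt, risk_is_alt = risk_is_alt),
    class = "snp_site"
  )
}

#' Risk and reference alleles of a SNP site (forward strand)
#'
#' @param snp A SNP-site descriptor, e.g. `locus$snp_ce`.
#' @return Named character vector with elements `risk` and `ref`.
#' @export
snp_alleles <- function(snp) {
  if (isTRUE(snp$risk_is_alt)) c(risk = snp$alt, ref = snp$ref)
  else c(risk = snp$ref, ref = snp$alt)
}

default_toy_exons <- function(strand) {
  minus <- list(
    e21   = c(1001L, 1200L),
    CE128 = c(3001L, 3128L),
    CE178 = c(3001L, 3178L),
    e20   = c(5001L, 5150L),
    e19   = c(7001L, 7200L)
  )
  if (strand == "-") return(minus)
  # mirror through the chromosome midpoint so transcript order is preserved
  len <- 12000L
  lapply(minus, function(iv) sort(len - rev(iv) + 1L))
}

transcript_exon_order <- function(exons, strand) {
  # transcript order e19 -> e20 -> (CE) -> e21; genomically descending on "-"
  ord <- c("e19", "e20", "CE178", "CE128", "e21")
  starts <- vapply(exons[ord], `[`, integer(1), 1L)
  if (strand == "-") {
    stopifnot(all(diff(starts[c("e19", "e20", "CE128", "e21")]) < 0))
  } else {
    stopifnot(all(diff(starts[c("e19", "e20", "CE128", "e21")]) > 0))
  }
  invisible(TRUE)
}

validate_toy_exons <- function(exons, strand, chrom_length) {
  need <- c("e19", "e20", "CE128", "CE178", "e21")
  if (!all(need %in% names(exons)))
    stop("exon map must name: ", paste(need, collapse = ", "))
  for (nm in need) {
    iv <- exons[[nm]]
    if (length(iv) != 2L || iv[1] > iv[2])
      stop("exon ", nm, " must be c(start, end) with start <= end")
    if (iv[1] < 1L || iv[2] > chrom_length)
      stop("exon ", nm, " outside chromosome bounds")
  }
  ce1 <- exons$CE128; ce2 <- exons$CE178
  if (!(ce1[1] >= ce2[1] && ce1[2] <= ce2[2]))
    stop("CE128 must be contained in CE178")
  shared <- if (strand == "-") ce1[1] == ce2[1] else ce1[2] == ce2[2]
  if (!shared)
    stop("CE128 and CE178 must share their transcript 3' boundary")
  # pairwise non-overlap among all exons except the CE containment
  plain <- c("e19", "e20", "e21")
  ivs <- exons[c(plain, "CE178")]
  for (i in seq_along(ivs)) for (j in seq_along(ivs)) {
    if (i >= j) next
    a <- ivs[[i]]; b <- ivs[[j]]
    if (a[1] <= b[2] && b[1] <= a[2])
      stop("overlapping exons: ", names(ivs)[i], " and ", names(ivs)[j])
  }
  transcript_exon_order(exons, strand)
  invisible(TRUE)
}

#' Construct the toy UNC13A-like locus
#'
#' Builds a single-chromosome gene model emulating the geometry of the
#' *UNC13A* cryptic-exon region: a minus-strand gene with canonical exons
#' e19, e20, e21 and two overlapping cryptic exons (CE128, 128 bp; CE178,
#' 178 bp) between e20 and e21 that share the transcript 3' end (the lower
#' genomic coordinate on the minus strand), CE178 extending 50 bp further at
#' the 5' end. The intron between e20 and the cryptic exons carries an
#' exonic-CE SNP proxy (inside CE128), an intronic SNP proxy, and a
#' CATC-repeat site with a configurable baseline unit count. The reference
#' sequence is generated deterministically from `seed`.
#'
#' @param chrom_name Chromosome name (default `"chrT"`).
#' @param chrom_length Chromosome length in bases (default 12000).
#' @param strand Gene strand, `"-"` (default) or `"+"`.
#' @param exons Optional named list overriding the default exon layout; must
#'   name `e19`, `e20`, `CE128`, `CE178`, `e21`, each `c(start, end)` 1-based
#'   inclusive. Overlaps other than CE128 within CE178 are an error.
#' @param snp_ce_pos Position of the SNP inside CE128 (default 3050).
#' @param snp_intron_pos Position of the intronic SNP (default 4500).
#' @param repeat_pos Start of the repeat region (default 4000).
#' @param repeat_motif Repeat unit on the forward strand (default `"CATC"`).
#' @param repeat_baseline_units Number of motif copies in the reference
#'   (default 6).
#' @param seed Integer seed for the deterministic reference sequence.
#' @return An object of class `toy_locus`: a list with `chrom`, `chrom_length`,
#'   `strand`, `exons`, `snp_ce`, `snp_intron`, `repeat_site` and `refseq`.
#' @examples
#' locus <- build_toy_locus()
#' interval_width(locus$exons$CE128[1], locus$exons$CE128[2])
#' @export
build_toy_locus <- function(chrom_name = "chrT", chrom_length = 12000L,
                            strand = c("-", "+"), exons = NULL,
                            snp_ce_pos = 3050L, snp_intron_pos = 4500L,
                            repeat_pos = 4000L, repeat_motif = "CATC",
                            repeat_baseline_units = 6L, seed = 1L) {
  strand <- match.arg(strand)
  chrom_length <- as.integer(chrom_length)
  if (is.null(exons)) exons <- default_toy_exons(strand)
  exons <- lapply(exons, as.integer)
  validate_toy_exons(exons, strand, chrom_length)

  refseq <- withr::with_seed(as.integer(seed), {
    paste(sample(DNA_BASES, chrom_length, replace = TRUE), collapse = "")
  })
  rep_seq <- strrep(repeat_motif, repeat_baseline_units)
  rep_end <- repeat_pos + nchar(rep_seq) - 1L
  if (rep_end > chrom_length) stop("repeat region outside chromosome")
  substr(refseq, repeat_pos, rep_end) <- rep_seq

  base_at <- function(pos) substr(refseq, pos, pos)
  other_base <- function(b) DNA_BASES[match(b, DNA_BASES) %% 4L + 1L]

  if (snp_ce_pos < exons$CE128[1] || snp_ce_pos > exons$CE128[2])
    stop("snp_ce_pos must fall inside CE128")
  snp_ce <- snp_site("snp_ce", chrom_name, snp_ce_pos,
                     ref = base_at(snp_ce_pos),
                     alt = other_base(base_at(snp_ce_pos)))
  snp_intron <- snp_site("snp_intron", chrom_name, snp_intron_pos,
                         ref = base_at(snp_intron_pos),
                         alt = other_base(base_at(snp_intron_pos)))

  structure(
    list(
      chrom = chrom_name,
      chrom_length = chrom_length,
      strand = strand,
      exons = exons,
      snp_ce = snp_ce,
      snp_intron = snp_intron,
      repeat_site = list(id = "repeat_catc", chrom = chrom_name,
                         pos = as.integer(repeat_pos), motif = repeat_motif,
                         baseline_units = as.integer(repeat_baseline_units)),
      refseq = refseq,
      seed = as.integer(seed)
    ),
    class = "toy_locus"
  )
}

#' @export
print.toy_locus <- function(x, ...) {
  cat("toy_locus:", x$chrom, sprintf("(%d bp, strand %s)\n",
                                     x$chrom_length, x$strand))
  for (nm in names(x$exons)) {
    iv <- x$exons[[nm]]
    cat(sprintf("  %-5s %6d-%6d (%d bp)\n", nm, iv[1], iv[2],
                interval_width(iv[1], iv[2])))
  }
  cat(sprintf("  snp_ce @%d %s>%s; snp_intron @%d %s>%s; repeat %sx%d @%d\n",
              x$snp_ce$pos, x$snp_ce$ref, x$snp_ce$alt,
              x$snp_intron$pos, x$snp_intron$ref, x$snp_intron$alt,
              x$repeat_site$motif, x$repeat_site$baseline_units,
              x$repeat_site$pos))
  invisible(x)
}

NAMED_JUNCTIONS <- c("e19-e20", "e20-CE128", "e20-CE178", "CE-e21", "e20-e21")

intron_between <- function(exons, up, dn, strand) {
  # intron between transcript-adjacent exons `up` (upstream) and `dn`
  if (strand == "-") c(exons[[dn]][2] + 1L, exons[[up]][1] - 1L)
  else               c(exons[[up]][2] + 1L, exons[[dn]][1] - 1L)
}

#' Named junctions of a toy locus
#'
#' The five junctions the pipeline counts, each represented by the genomic
#' interval of the skipped intron (1-based, inclusive): e19-e20, e20-CE128,
#' e20-CE178, the shared CE-e21 junction (identical for both cryptic exons
#' because they share the transcript 3' end) and the exclusion junction
#' e20-e21. Naming is in transcript order, so on the minus strand the
#' genomically lower exon is transcript-downstream.
#'
#' @param locus A [build_toy_locus()] object.
#' @return A data.frame with columns `name`, `start`, `end`.
#' @export
locus_junctions <- function(locus) {
  ex <- locus$exons; s <- locus$strand
  ce_e21_128 <- intron_between(ex, "CE128", "e21", s)
  ce_e21_178 <- intron_between(ex, "CE178", "e21", s)
  stopifnot(identical(ce_e21_128, ce_e21_178)) # shared 3' end
  ivs <- rbind(
    "e19-e20"   = intron_between(ex, "e19", "e20", s),
    "e20-CE128" = intron_between(ex, "e20", "CE128", s),
    "e20-CE178" = intron_between(ex, "e20", "CE178", s),
    "CE-e21"    = ce_e21_128,
    "e20-e21"   = intron_between(ex, "e20", "e21", s)
  )
  data.frame(name = rownames(ivs), start = ivs[, 1], end = ivs[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exon chains of the three isoforms, in transcript order
#'
#' @param locus A [build_toy_locus()] object.
#' @return Named list of character vectors of exon names for the `canonical`,
#'   `CE128` and `CE178` isoforms.
#' @export
locus_isoforms <- function(locus) {
  list(
    canonical = c("e19", "e20", "e21"),
    CE128     = c("e19", "e20", "CE128", "e21"),
    CE178     = c("e19", "e20", "CE178", "e21")
  )
}

#' The intron harbouring the cryptic exons
#'
#' Genomic interval between e20 and e21 (the intron whose reads the inclusion
#' statistic is computed over).
#'
#' @param locus A [build_toy_locus()] object.
#' @return Integer vector `c(start, end)`.
#' @export
locus_ce_intron <- function(locus) {
  intron_between(locus$exons, "e20", "e21", locus$strand)
}

#' Write a toy locus gene model as GFF3
#'
#' Emits gene, mRNA and exon features for the three isoforms; exon features
#' carry `Parent` (their transcript) and `Name` (e19, e20, CE128, CE178, e21).
#'
#' @param locus A [build_toy_locus()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_gff3 <- function(locus, path) {
  iso <- locus_isoforms(locus)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", locus$chrom,
                     locus$chrom_length))
  feat <- function(type, start, end, attrs) {
    sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\t%s",
            locus$chrom, type, start, end, locus$strand, attrs)
  }
  span <- range(unlist(locus$exons))
  lines <- c(lines, feat("gene", span[1], span[2], "ID=geneT;Name=geneT"))
  for (tx in names(iso)) {
    txid <- paste0("tx_", tx)
    lines <- c(lines, feat("mRNA", span[1], span[2],
                           sprintf("ID=%s;Parent=geneT;Name=%s", txid, tx)))
    for (exn in iso[[tx]]) {
      iv <- locus$exons[[exn]]
      lines <- c(lines, feat("exon", iv[1], iv[2],
                             sprintf("Parent=%s;Name=%s", txid, exn)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' Parses exon features (with `Name` attributes naming e19, e20, CE128, CE178,
#' e21) from a GFF3 file, e.g. one written by [write_locus_gff3()]. The result
#' can be handed back to [build_toy_locus()] via its `exons`/`strand`/
#' `chrom_name` arguments to reconstitute a full locus.
#'
#' @param path GFF3 file path.
#' @return List with `chrom`, `chrom_length` (NA when the file lacks a
#'   `##sequence-region` pragma), `strand` and `exons`.
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  nm <- as.character(ex$Name)
  chrom <- as.character(GenomicRanges::seqnames(ex))[1]
  strand <- as.character(BiocGenerics::strand(ex))[1]
  exons <- list()
  for (u in unique(nm)) {
    i <- which(nm == u)[1]
    exons[[u]] <- c(GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i])
  }
  sl <- GenomeInfoDb::seqlengths(gr)[chrom]
  if (is.na(sl)) {
    # fall back to the ##sequence-region pragma
    pr <- grep("^##sequence-region", readLines(path, n = 50L), value = TRUE)
    pr <- pr[grepl(paste0("\\s", chrom, "\\s"), pr)]
    if (length(pr))
      sl <- as.integer(sub(".*\\s(\\d+)\\s*$", "\\1", pr[1]))
  }
  list(chrom = chrom,
       chrom_length = if (is.na(sl)) NA_integer_ else as.integer(sl),
       strand = strand, exons = exons)
}
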