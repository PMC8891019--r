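# Junction extraction and classification from spliced alignments.
#
# Alignment blocks are reconstructed from CIGAR strings by the SAM
# reference-consumption rules: M/D consume reference within a block, N closes
# a block and opens a gap, I/S consume only the read. Deletions (D) extend a
# block; they are not splices and never create a junction.

SUPPORTED_CIGAR_OPS <- c("M", "I", "D", "N", "S")

# Tokenize a vector of CIGAR strings into a per-op data.table with genomic
# start offsets. Internal engine shared by the scalar parser and count_sample.
cigar_op_table <- function(pos, cigar) {
  if (any(!nzchar(cigar) | cigar == "*"))
    stop("zero-length or missing CIGAR")
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))
  if (any(vapply(toks, function(t) sum(nchar(t)), integer(1)) != nchar(cigar)))
    stop("malformed CIGAR string")
  tok <- unlist(toks, use.names = FALSE)
  op <- substr(tok, nchar(tok), nchar(tok))
  bad <- setdiff(unique(op), SUPPORTED_CIGAR_OPS)
  if (length(bad))
    stop("unsupported CIGAR operator(s): ", paste(bad, collapse = ", "))
  dt <- data.table(
    rid = rep(seq_along(cigar), lengths(toks)),
    op = op,
    len = as.integer(substr(tok, 1L, nchar(tok) - 1L))
  )
  dt[, refw := ifelse(op %in% c("M", "D", "N"), len, 0L)]
  dt[, off := cumsum(c(0L, refw[-.N])), by = rid]
  dt[, gstart := pos[rid] + off]
  dt[, blk := cumsum(op == "N") - as.integer(op == "N"), by = rid]
  dt
}

# Per-read aligned blocks (1-based inclusive genomic intervals).
# Returns data.table(rid, blk, start, end) ordered by rid then start.
alignment_blocks <- function(pos, cigar) {
  dt <- cigar_op_table(pos, cigar)
  al <- dt[op %in% c("M", "D")]
  if (nrow(al) == 0L) stop("CIGAR with no aligned (M) segment")
  blocks <- al[, list(start = min(gstart), end = max(gstart + len - 1L)),
               by = c("rid", "blk")]
  setorder(blocks, rid, start)
  blocks
}

#' Parse one SAM record into a spliced alignment
#'
#' Reconstructs the aligned blocks of a read from its POS and CIGAR. Each
#' CIGAR `N` gap closes the current block and opens the next, so a read with
#' one `N` has two blocks; `D` extends a block (a deletion is not a splice)
#' and `I`/`S` consume no reference.
#'
#' @param record A single SAM line (character scalar) or a list/one-row data
#'   frame with fields `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar` and
#'   optionally `seq`.
#' @return An object of class `spliced_alignment`: list with `read_id`,
#'   `chrom`, `blocks` (two-column matrix of `start`, `end`), `mapq`,
#'   `is_duplicate` and `seq`.
#' @examples
#' aln <- parse_spliced_alignment(list(qname = "r1", flag = 0, rname = "chrT",
#'                                     pos = 1151, mapq = 255,
#'                                     cigar = "50M3800N50M"))
#' aln$blocks
#' @export
parse_spliced_alignment <- function(record) {
  if (is.character(record) && length(record) == 1L) {
    f <- strsplit(record, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) stop("malformed SAM record")
    record <- list(qname = f[1], flag = as.integer(f[2]), rname = f[3],
                   pos = as.integer(f[4]), mapq = as.integer(f[5]),
                   cigar = f[6], seq = if (length(f) >= 10L) f[10] else NA)
  }
  blocks <- alignment_blocks(as.integer(record$pos), as.character(record$cigar))
  bm <- cbind(start = blocks$start, end = blocks$end)
  flag <- as.integer(record$flag %||% 0L)
  structure(
    list(read_id = as.character(record$qname %||% NA),
         chrom = as.character(record$rname %||% NA),
         blocks = bm,
         mapq = as.integer(record$mapq %||% 0L),
         is_duplicate = bitwAnd(flag, 0x400L) != 0L,
         seq = record$seq %||% NA_character_),
    class = "spliced_alignment"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read-level filters: duplicate flag and unique-mapping MAPQ
#'
#' Mirrors the source pipeline's duplicate removal and uniqueness filter
#' (`samtools view -q 255` on an aligner emitting MAPQ 255 for unique reads):
#' a read passes iff its MAPQ is at least `unique_mapq` and, when
#' `drop_duplicates` is on, its duplicate flag is unset.
#'
#' @param aln A [parse_spliced_alignment()] object.
#' @param unique_mapq Minimum MAPQ counted as uniquely mapped (default 255).
#' @param drop_duplicates Drop reads flagged as PCR duplicates (default TRUE).
#' @return Logical flag.
#' @export
passes_filters <- function(aln, unique_mapq = 255L, drop_duplicates = TRUE) {
  aln$mapq >= unique_mapq && !(drop_duplicates && aln$is_duplicate)
}

#' Extract gap junctions from a spliced alignment
#'
#' One junction per inter-block gap whose flanking aligned blocks are each at
#' least `min_overhang` bases long (reads must map a minimum of 6 nt into each
#' exon by default); shorter-anchored gaps are discarded. The junction is the
#' 1-based inclusive genomic interval of the skipped gap.
#'
#' @param aln A [parse_spliced_alignment()] object.
#' @param min_overhang Minimum flanking block length in bases (default 6).
#' @return Data frame with columns `chrom`, `start`, `end`, `left_overhang`,
#'   `right_overhang`; zero rows for unspliced reads.
#' @export
extract_junctions <- function(aln, min_overhang = 6L) {
  b <- aln$blocks
  n <- nrow(b)
  if (n < 2L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), left_overhang = integer(0),
                      right_overhang = integer(0), stringsAsFactors = FALSE))
  }
  w <- b[, "end"] - b[, "start"] + 1L
  out <- data.frame(
    chrom = rep(aln$chrom, n - 1L),
    start = b[-n, "end"] + 1L,
    end = b[-1L, "start"] - 1L,
    left_overhang = w[-n],
    right_overhang = w[-1L],
    stringsAsFactors = FALSE
  )
  out[out$left_overhang >= min_overhang &
        out$right_overhang >= min_overhang, , drop = FALSE]
}

#' Classify a junction against the gene model
#'
#' A junction is named X-Y iff its gap interval exactly equals the genomic
#' interval between the adjacent boundaries of exons X and Y (no fuzz window).
#' e20-CE128 and e20-CE178 differ only in the CE-side boundary; CE-e21 is a
#' single junction shared by both cryptic exons. Junctions on another
#' chromosome, or matching no model junction, are `"unclassified"`.
#'
#' @param junction A list or one-row data frame with `chrom`, `start`, `end`.
#' @param locus A [build_toy_locus()] object.
#' @return A junction name among `r toString(NAMED_JUNCTIONS)`, or
#'   `"unclassified"`.
#' @export
classify_junction <- function(junction, locus) {
  if (!identical(as.character(junction$chrom), locus$chrom))
    return("unclassified")
  defs <- locus_junctions(locus)
  hit <- defs$start == junction$start & defs$end == junction$end
  if (any(hit)) defs$name[which(hit)[1]] else "unclassified"
}

jname_to_col <- function(x) {
  c("e19-e20" = "e19_e20", "e20-CE128" = "e20_ce128",
    "e20-CE178" = "e20_ce178", "CE-e21" = "ce_e21", "e20-e21" = "e20_e21")[x]
}

# union length (bp) of the model exons, CE128 folded into CE178
model_exonic_length <- function(locus) {
  ivs <- locus$exons[c("e19", "e20", "CE178", "e21")]
  sum(vapply(ivs, function(iv) interval_width(iv[1], iv[2]), integer(1)))
}

#' Count named junction reads in one sample
#'
#' Runs the full per-sample quantification: reads a SAM file (or takes an
#' in-memory record table from the simulator), applies the duplicate and
#' unique-MAPQ filters, extracts gap junctions with the overhang rule, and
#' classifies every junction against the gene model. Each filtered read
#' contributes at most once per named junction. The table also tallies
#' `unclassified` junction events, `intron_body` reads (at least one aligned
#' base strictly inside the e20-e21 intron but outside CE178), `within_ce`
#' reads (aligned wholly inside CE178), `exonic_reads` (overlapping any model
#' exon) and a naive TPM,
#' `(exonic_reads / exon_union_kb) / (library_size / 1e6)`, with
#' `library_size` the number of filtered reads.
#'
#' @param sam Path to a SAM file, or a data frame of alignment records with
#'   columns `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`.
#' @param locus A [build_toy_locus()] object.
#' @param min_overhang Minimum junction overhang in bases (default 6).
#' @param unique_mapq Minimum MAPQ counted as unique (default 255).
#' @param drop_duplicates Drop flagged PCR duplicates (default TRUE).
#' @param sample_id Sample label for the output row.
#' @return A one-row data.frame of class `junction_counts` with columns
#'   `sample_id`, `e19_e20`, `e20_ce128`, `e20_ce178`, `ce_e21`, `e20_e21`,
#'   `unclassified`, `intron_body`, `within_ce`, `exonic_reads`,
#'   `library_size`, `naive_tpm`.
#' @export
count_sample <- function(sam, locus, min_overhang = 6L, unique_mapq = 255L,
                         drop_duplicates = TRUE, sample_id = NULL) {
  if (is.character(sam) && length(sam) == 1L) {
    if (is.null(sample_id))
      sample_id <- sub("\\.sam$", "", basename(sam))
    hdr_sam <- read_sam(sam)
    sq <- attr(hdr_sam, "header_sq")
    if (length(sq) && !(locus$chrom %in% names(sq)))
      stop("locus chromosome ", locus$chrom, " absent from SAM header")
    records <- hdr_sam
  } else {
    records <- as.data.frame(sam)
  }
  if (is.null(sample_id)) sample_id <- "sample"
  if (!("rname" %in% names(records)))
    records$rname <- rep(locus$chrom, nrow(records))

  counts <- stats::setNames(integer(5), jname_to_col(NAMED_JUNCTIONS))
  out <- data.frame(sample_id = sample_id, t(counts), unclassified = 0L,
                    intron_body = 0L, within_ce = 0L, exonic_reads = 0L,
                    library_size = 0L, naive_tpm = 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("junction_counts", "data.frame")
  if (nrow(records) == 0L) return(out)

  if (!any(records$rname == locus$chrom))
    stop("no alignments on locus chromosome ", locus$chrom,
         " (chromosome mismatch)")
  records <- records[records$rname == locus$chrom, , drop = FALSE]

  keep <- records$mapq >= unique_mapq
  if (drop_duplicates) keep <- keep & bitwAnd(records$flag, 0x400L) == 0L
  records <- records[keep, , drop = FALSE]
  out$library_size <- nrow(records)
  if (nrow(records) == 0L) return(out)

  blocks <- alignment_blocks(records$pos, records$cigar)

  # junction events between consecutive blocks of the same read
  bl <- copy(blocks)
  bl[, w := end - start + 1L]
  bl[, nb := .N, by = rid]
  ju <- bl[nb > 1L,
           list(jstart = end[-.N] + 1L, jend = start[-1L] - 1L,
                lo = w[-.N], ro = w[-1L]),
           by = rid]
  if (nrow(ju)) {
    ju <- ju[lo >= min_overhang & ro >= min_overhang]
  }
  if (nrow(ju)) {
    defs <- locus_junctions(locus)
    key <- paste(ju$jstart, ju$jend)
    dkey <- paste(defs$start, defs$end)
    name <- defs$name[match(key, dkey)]
    # at most one count per read per named junction
    ev <- data.table(rid = ju$rid, name = name)
    named <- ev[!is.na(name)]
    if (nrow(named)) {
      named <- unique(named)
      tab <- named[, .N, by = name]
      out[, jname_to_col(tab$name)] <- as.integer(tab$N)
    }
    out$unclassified <- sum(is.na(name))
  }

  # read-level interval tallies
  intron <- locus_ce_intron(locus)
  ce <- locus$exons$CE178
  ovl <- function(s, e, iv) pmax(0L, pmin(e, iv[2]) - pmax(s, iv[1]) + 1L)
  bl[, ov_intron := ovl(start, end, intron)]
  bl[, ov_ce := ovl(start, end, ce)]
  exon_ivs <- locus$exons[c("e19", "e20", "CE178", "e21")]
  bl[, ov_exon := Reduce(`+`, lapply(exon_ivs, function(iv) ovl(start, end, iv)))]
  per_read <- bl[, list(
    intron_body = any(ov_intron - ov_ce > 0L),
    within_ce = all(ov_ce == end - start + 1L),
    exonic = any(ov_exon > 0L)
  ), by = rid]
  out$intron_body <- sum(per_read$intron_body)
  out$within_ce <- sum(per_read$within_ce)
  out$exonic_reads <- sum(per_read$exonic)
  kb <- model_exonic_length(locus) / 1000
  out$naive_tpm <- (out$exonic_reads / kb) / (out$library_size / 1e6)
  out
}
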