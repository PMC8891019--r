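#' Write alignment records as a SAM file
#'
#' Minimal single-reference SAM emitter used by the simulator: a `@HD`/`@SQ`
#' header for the toy chromosome followed by one line per record. POS is
#' 1-based; CIGAR uses M/N/S only; PCR duplicates carry flag bit 0x400.
#'
#' @param records Data frame with columns `qname`, `flag`, `pos`, `mapq`,
#'   `cigar`, `seq` (and optionally `rname`, defaulting to the locus
#'   chromosome).
#' @param locus A [build_toy_locus()] object supplying the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, locus, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", locus$chrom, locus$chrom_length))
  rname <- if ("rname" %in% names(records)) records$rname else
    rep(locus$chrom, nrow(records))
  body <- if (nrow(records) == 0L) character(0) else
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            records$qname, records$flag, rname, records$pos,
            records$mapq, records$cigar, records$seq)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment record table
#'
#' Parses the mandatory SAM columns of a text SAM file. The `@SQ` header
#' lines are kept in the `"header_sq"` attribute (named integer vector of
#' reference lengths).
#'
#' @param path SAM file path.
#' @return Data frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_names <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  sq_len <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  out <- if (length(body) == 0L) {
    data.frame(qname = character(0), flag = integer(0), rname = character(0),
               pos = integer(0), mapq = integer(0), cigar = character(0),
               seq = character(0), stringsAsFactors = FALSE)
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    n <- lengths(f)
    if (any(n < 11L)) stop("malformed SAM record (fewer than 11 fields)")
    m <- matrix(unlist(lapply(f, `[`, 1:11)), ncol = 11L, byrow = TRUE)
    data.frame(qname = m[, 1], flag = as.integer(m[, 2]), rname = m[, 3],
               pos = as.integer(m[, 4]), mapq = as.integer(m[, 5]),
               cigar = m[, 6], seq = m[, 10], stringsAsFactors = FALSE)
  }
  attr(out, "header_sq") <- stats::setNames(sq_len, sq_names)
  out
}
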