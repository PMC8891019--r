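# Independent brute-force re-implementation of the per-sample quantification,
# used as the oracle for count_sample(). Deliberately written as a plain
# per-read loop with its own CIGAR walk and its own junction definitions
# derived afresh from the exon coordinates.

oracle_junction_defs <- function(locus) {
  ex <- locus$exons
  if (locus$strand == "-") {
    list(
      "e19-e20"   = c(ex$e20[2] + 1L, ex$e19[1] - 1L),
      "e20-CE128" = c(ex$CE128[2] + 1L, ex$e20[1] - 1L),
      "e20-CE178" = c(ex$CE178[2] + 1L, ex$e20[1] - 1L),
      "CE-e21"    = c(ex$e21[2] + 1L, ex$CE128[1] - 1L),
      "e20-e21"   = c(ex$e21[2] + 1L, ex$e20[1] - 1L)
    )
  } else {
    list(
      "e19-e20"   = c(ex$e19[2] + 1L, ex$e20[1] - 1L),
      "e20-CE128" = c(ex$e20[2] + 1L, ex$CE128[1] - 1L),
      "e20-CE178" = c(ex$e20[2] + 1L, ex$CE178[1] - 1L),
      "CE-e21"    = c(ex$CE128[2] + 1L, ex$e21[1] - 1L),
      "e20-e21"   = c(ex$e20[2] + 1L, ex$e21[1] - 1L)
    )
  }
}

oracle_cigar_blocks <- function(pos, cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z]", cigar))[[1]]
  blocks <- list()
  cur_start <- pos
  cur_len <- 0L
  for (t in toks) {
    op <- substr(t, nchar(t), nchar(t))
    len <- as.integer(substr(t, 1L, nchar(t) - 1L))
    if (op %in% c("M", "D")) {
      cur_len <- cur_len + len
    } else if (op == "N") {
      blocks[[length(blocks) + 1L]] <- c(cur_start, cur_start + cur_len - 1L)
      cur_start <- cur_start + cur_len + len
      cur_len <- 0L
    }
    # I and S consume no reference
  }
  blocks[[length(blocks) + 1L]] <- c(cur_start, cur_start + cur_len - 1L)
  blocks
}

oracle_count <- function(records, locus, min_overhang = 6L,
                         unique_mapq = 255L, drop_duplicates = TRUE) {
  defs <- oracle_junction_defs(locus)
  ex <- locus$exons
  intron <- if (locus$strand == "-") c(ex$e21[2] + 1L, ex$e20[1] - 1L)
            else c(ex$e20[2] + 1L, ex$e21[1] - 1L)
  ce <- ex$CE178
  model_exons <- ex[c("e19", "e20", "CE178", "e21")]
  counts <- setNames(integer(length(defs)), names(defs))
  unclassified <- 0L; intron_body <- 0L; within_ce <- 0L; exonic <- 0L
  lib <- 0L
  overlaps <- function(b, iv) b[1] <= iv[2] && iv[1] <= b[2]
  n_overlap <- function(b, iv) max(0L, min(b[2], iv[2]) - max(b[1], iv[1]) + 1L)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!is.null(r$rname) && r$rname != locus$chrom) next
    if (r$mapq < unique_mapq) next
    if (drop_duplicates && bitwAnd(as.integer(r$flag), 1024L) != 0L) next
    lib <- lib + 1L
    blocks <- oracle_cigar_blocks(r$pos, r$cigar)
    hit_names <- character(0)
    if (length(blocks) > 1L) {
      for (k in seq_len(length(blocks) - 1L)) {
        lw <- blocks[[k]][2] - blocks[[k]][1] + 1L
        rw <- blocks[[k + 1L]][2] - blocks[[k + 1L]][1] + 1L
        if (lw < min_overhang || rw < min_overhang) next
        gap <- c(blocks[[k]][2] + 1L, blocks[[k + 1L]][1] - 1L)
        matched <- FALSE
        for (nm in names(defs)) {
          if (gap[1] == defs[[nm]][1] && gap[2] == defs[[nm]][2]) {
            hit_names <- c(hit_names, nm)
            matched <- TRUE
            break
          }
        }
        if (!matched) unclassified <- unclassified + 1L
      }
    }
    for (nm in unique(hit_names)) counts[nm] <- counts[nm] + 1L
    ib <- FALSE; wc <- TRUE; exn <- FALSE
    for (b in blocks) {
      if (n_overlap(b, intron) - n_overlap(b, ce) > 0L) ib <- TRUE
      if (n_overlap(b, ce) != b[2] - b[1] + 1L) wc <- FALSE
      for (mx in model_exons) if (overlaps(b, mx)) exn <- TRUE
    }
    intron_body <- intron_body + ib
    within_ce <- within_ce + wc
    exonic <- exonic + exn
  }
  model_kb <- sum(vapply(model_exons, function(iv) iv[2] - iv[1] + 1L,
                         integer(1))) / 1000
  list(counts = counts, unclassified = unclassified,
       intron_body = intron_body, within_ce = within_ce,
       exonic_reads = exonic, library_size = lib,
       naive_tpm = if (lib > 0) (exonic / model_kb) / (lib / 1e6) else 0)
}

expect_counts_match_oracle <- function(ct, or) {
  expect_identical(
    unname(unlist(ct[, c("e19_e20", "e20_ce128", "e20_ce178", "ce_e21",
                         "e20_e21")])),
    unname(or$counts))
  expect_identical(ct$unclassified, or$unclassified)
  expect_identical(ct$intron_body, or$intron_body)
  expect_identical(ct$within_ce, or$within_ce)
  expect_identical(ct$exonic_reads, or$exonic_reads)
  expect_identical(ct$library_size, or$library_size)
  expect_equal(ct$naive_tpm, or$naive_tpm)
}
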