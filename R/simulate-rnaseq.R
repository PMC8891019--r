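# Spliced-read simulator: the generative counterpart of the quantification.
# Reads are single-end with at most one gap per junction, drawn uniformly
# along each isoform so that per-junction read counts are proportional to
# isoform abundance (the property junction-PSI estimation relies on).

#' Per-sample simulation parameters
#'
#' @param psi_true CE-inclusion isoform proportion in `[0, 1]`.
#' @param ce178_share Fraction of CE transcripts using the 178-bp form
#'   (default 0.1; the 128-bp form is the much more abundant one).
#' @param depth Expected number of junction-informative unique, non-duplicate
#'   reads.
#' @param read_length Read length in bases (default 100).
#' @param duplicate_rate Fraction of reads that receive a PCR-duplicate copy
#'   (flag 0x400).
#' @param nonunique_rate Fraction of additional reads emitted with a
#'   sub-unique MAPQ.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list of class `sample_params`.
#' @export
sample_params <- function(psi_true = 0.1, ce178_share = 0.1, depth = 1000,
                          read_length = 100L, duplicate_rate = 0.05,
                          nonunique_rate = 0.02, error_rate = 0.001,
                          seed = 1L) {
  rates <- c(psi_true = psi_true, ce178_share = ce178_share,
             duplicate_rate = duplicate_rate, nonunique_rate = nonunique_rate,
             error_rate = error_rate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (depth <= 0) stop("depth must be positive")
  if (read_length < 12L)
    stop("read_length must be at least twice the 6-nt minimum overhang")
  structure(list(psi_true = psi_true, ce178_share = ce178_share,
                 depth = depth, read_length = as.integer(read_length),
                 duplicate_rate = duplicate_rate,
                 nonunique_rate = nonunique_rate, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sample_params")
}

# transcript-coordinate map of one isoform: per exon, transcript offsets
# [tstart, tend] and the genomic interval, in transcript order
isoform_map <- function(locus, iso) {
  chain <- locus_isoforms(locus)[[iso]]
  w <- vapply(locus$exons[chain], function(iv) interval_width(iv[1], iv[2]),
              integer(1))
  tend <- cumsum(w)
  tstart <- tend - w + 1L
  list(chain = chain, tstart = tstart, tend = tend, tlen = sum(w),
       gstart = vapply(locus$exons[chain], `[`, integer(1), 1L),
       gend = vapply(locus$exons[chain], `[`, integer(1), 2L))
}

# logical vector over read start positions marking junction-spanning starts
informative_starts <- function(map, read_length) {
  npos <- map$tlen - read_length + 1L
  if (npos < 1L) stop("read_length exceeds transcript length")
  inf <- logical(npos)
  bounds <- map$tend[-length(map$tend)]
  for (b in bounds) {
    lo <- max(1L, b - read_length + 2L)
    hi <- min(b, npos)
    if (lo <= hi) inf[lo:hi] <- TRUE
  }
  inf
}

# genomic blocks of reads starting at transcript positions s (one isoform);
# returns data.table(rid, start, end) in ascending genomic order per read
reads_to_blocks <- function(map, s, read_length, strand) {
  e <- s + read_length - 1L
  pieces <- vector("list", length(map$chain))
  for (j in seq_along(map$chain)) {
    ovs <- pmax(s, map$tstart[j])
    ove <- pmin(e, map$tend[j])
    k <- which(ovs <= ove)
    if (!length(k)) next
    if (strand == "-") {
      gs <- map$gend[j] - (ove[k] - map$tstart[j])
      ge <- map$gend[j] - (ovs[k] - map$tstart[j])
    } else {
      gs <- map$gstart[j] + (ovs[k] - map$tstart[j])
      ge <- map$gstart[j] + (ove[k] - map$tstart[j])
    }
    pieces[[j]] <- data.table(rid = k, start = gs, end = ge)
  }
  out <- rbindlist(pieces)
  setorder(out, rid, start)
  out
}

# assemble per-read POS and CIGAR (M/N only) from ascending blocks
blocks_to_records <- function(blocks) {
  blocks[, w := end - start + 1L]
  blocks[, list(
    pos = start[1L],
    cigar = {
      if (.N == 1L) paste0(w, "M")
      else paste0(paste0(w, "M", c(start[-1L] - end[-.N] - 1L, ""),
                         c(rep("N", .N - 1L), "")), collapse = "")
    }
  ), by = rid]
}

# read sequences from the forward-strand reference over the aligned blocks,
# with independent per-base substitution errors
blocks_to_seq <- function(blocks, refseq, error_rate) {
  seg <- substring(refseq, blocks$start, blocks$end)
  seqs <- vapply(split(seg, blocks$rid), paste0, character(1), collapse = "")
  seqs <- seqs[order(as.integer(names(seqs)))]
  if (error_rate > 0) {
    nerr <- rbinom(length(seqs), nchar(seqs), error_rate)
    for (i in which(nerr > 0L)) {
      s <- strsplit(seqs[i], "")[[1]]
      at <- sample.int(length(s), nerr[i])
      s[at] <- vapply(s[at], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
      seqs[i] <- paste0(s, collapse = "")
    }
  }
  unname(seqs)
}

# classify the junction events of constructed reads against the model
truth_junction_counts <- function(blocks, locus) {
  defs <- locus_junctions(locus)
  bl <- copy(blocks)
  bl[, nb := .N, by = rid]
  ju <- bl[nb > 1L, list(jstart = end[-.N] + 1L, jend = start[-1L] - 1L),
           by = rid]
  counts <- stats::setNames(integer(nrow(defs)), defs$name)
  n_reads <- 0L
  if (nrow(ju)) {
    nm <- defs$name[match(paste(ju$jstart, ju$jend),
                          paste(defs$start, defs$end))]
    tab <- table(nm)
    counts[names(tab)] <- as.integer(tab)
    n_reads <- length(unique(ju$rid))
  }
  list(counts = counts, n_junction_events = if (nrow(ju)) nrow(ju) else 0L,
       n_junction_reads = n_reads)
}

#' Simulate one bulk RNA-seq sample over the toy locus
#'
#' Draws single-end reads uniformly along the three isoforms (canonical,
#' CE128, CE178) with mixture proportions
#' `{1 - psi, psi * (1 - ce178_share), psi * ce178_share}`, emits them as SAM
#' records (CIGAR M/N, POS 1-based, flag 16 on the minus strand), adds
#' PCR-duplicate copies carrying flag 0x400 and extra non-unique reads with
#' MAPQ below the unique value, and records the realized per-junction ground
#' truth. The total read number is scaled by the exact junction-spanning
#' start-position fraction of each isoform so that the expected number of
#' junction-informative unique reads equals `depth`. Identical seeds and
#' parameters give byte-identical output.
#'
#' @param locus A [build_toy_locus()] object.
#' @param params A [sample_params()] object.
#' @param sam_path Optional path; when given the records are written as SAM.
#' @param sample_id Label stored in the truth record.
#' @return List with `records` (data frame of SAM fields), `truth` (list with
#'   per-junction `counts` over unique non-duplicate reads,
#'   `n_junction_events`, `n_junction_reads`, `n_records`, `psi_true`,
#'   `depth`, `seed`) and `sam_path`.
#' @export
simulate_rnaseq_sample <- function(locus, params = sample_params(),
                                   sam_path = NULL, sample_id = "sample") {
  stopifnot(inherits(locus, "toy_locus"), inherits(params, "sample_params"))
  L <- params$read_length
  mix <- c(canonical = 1 - params$psi_true,
           CE128 = params$psi_true * (1 - params$ce178_share),
           CE178 = params$psi_true * params$ce178_share)
  maps <- lapply(stats::setNames(nm = names(mix)),
                 function(i) isoform_map(locus, i))
  # uniform sequencing samples reads in proportion to abundance x length, so
  # read mixture weights are isoform proportion x start-position count; this
  # makes per-junction counts proportional to isoform abundance (unbiased PSI)
  npos <- vapply(maps, function(m) m$tlen - L + 1L, integer(1))
  frac <- vapply(maps, function(m) mean(informative_starts(m, L)), numeric(1))
  read_mix <- mix * npos
  read_mix <- read_mix / sum(read_mix)
  frac_avg <- sum(read_mix * frac)
  if (frac_avg <= 0) stop("no junction-informative positions at this read length")

  out <- withr::with_seed(params$seed, {
    n_total <- max(1L, as.integer(round(params$depth / frac_avg)))
    n_iso <- as.vector(stats::rmultinom(1L, n_total, read_mix))
    n_nu <- rbinom(1L, n_total, params$nonunique_rate)
    nu_iso <- if (n_nu > 0L) as.vector(stats::rmultinom(1L, n_nu, read_mix))
              else integer(3)

    gen_reads <- function(n_per_iso) {
      pieces <- vector("list", 3L)
      for (k in seq_len(3L)) {
        n <- n_per_iso[k]
        if (n == 0L) next
        m <- maps[[k]]
        s <- sample.int(m$tlen - L + 1L, n, replace = TRUE)
        bl <- reads_to_blocks(m, s, L, locus$strand)
        pieces[[k]] <- bl
      }
      # re-key rids so reads from different isoforms stay distinct
      offs <- cumsum(c(0L, n_per_iso[-3L]))
      for (k in seq_len(3L)) {
        if (!is.null(pieces[[k]])) pieces[[k]][, rid := rid + offs[k]]
      }
      rbindlist(pieces)
    }

    base_blocks <- gen_reads(n_iso)
    nu_blocks <- if (n_nu > 0L) gen_reads(nu_iso) else NULL

    rec_of <- function(blocks, prefix, mapq) {
      rec <- blocks_to_records(blocks)
      setorder(rec, rid)
      seqs <- blocks_to_seq(blocks, locus$refseq, params$error_rate)
      data.frame(
        qname = sprintf("%s_%06d", prefix, rec$rid),
        flag = if (locus$strand == "-") 16L else 0L,
        rname = locus$chrom, pos = rec$pos, mapq = mapq, cigar = rec$cigar,
        seq = seqs, stringsAsFactors = FALSE)
    }

    records <- rec_of(base_blocks, paste0(sample_id, "_u"), 255L)
    dup <- runif(nrow(records)) < params$duplicate_rate
    if (any(dup)) {
      dups <- records[dup, , drop = FALSE]
      dups$qname <- sub("_u_", "_d_", dups$qname, fixed = TRUE)
      dups$flag <- dups$flag + 1024L
      records <- rbind(records, dups)
    }
    if (!is.null(nu_blocks) && nrow(nu_blocks)) {
      records <- rbind(records,
                       rec_of(nu_blocks, paste0(sample_id, "_m"), 3L))
    }

    tj <- truth_junction_counts(base_blocks, locus)
    list(records = records,
         truth = c(tj, list(n_records = nrow(records),
                            psi_true = params$psi_true,
                            ce178_share = params$ce178_share,
                            depth = params$depth, seed = params$seed,
                            sample_id = sample_id)))
  })
  if (!is.null(sam_path)) {
    write_sam(out$records, locus, sam_path)
    out$sam_path <- sam_path
  }
  out
}

#' Cohort design for the simulator
#'
#' Each group has a label, a sample count, a PSI distribution for CE-positive
#' samples (`Beta(psi_shape1, psi_shape2)`, or a point mass at zero when
#' `prevalence` is 0) and a prevalence: the fraction of samples carrying any
#' CE inclusion at all.
#'
#' @param groups Data frame with columns `label`, `n`, `psi_shape1`,
#'   `psi_shape2`, `prevalence`.
#' @param defaults A [sample_params()] object giving the shared per-sample
#'   parameters (its `psi_true` is overridden per sample).
#' @param seed Cohort-level seed from which per-sample seeds are derived.
#' @return List of class `cohort_design`.
#' @export
cohort_design <- function(groups, defaults = sample_params(), seed = 1L) {
  groups <- as.data.frame(groups)
  need <- c("label", "n", "psi_shape1", "psi_shape2", "prevalence")
  if (!all(need %in% names(groups)))
    stop("groups must have columns: ", paste(need, collapse = ", "))
  if (nrow(groups) == 0L) stop("empty group list")
  if (any(groups$n < 1L)) stop("each group needs n >= 1")
  if (any(groups$prevalence < 0 | groups$prevalence > 1))
    stop("prevalence must lie in [0, 1]")
  structure(list(groups = groups, defaults = defaults,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a cohort of RNA-seq samples
#'
#' Draws each sample's PSI from its group's design (zero with probability
#' `1 - prevalence`, otherwise Beta-distributed), simulates the sample, and
#' returns the per-sample truth table. With `out_dir` set, one SAM file per
#' sample is written and its path recorded in the truth table.
#'
#' @param locus A [build_toy_locus()] object.
#' @param design A [cohort_design()] object.
#' @param out_dir Optional directory for per-sample SAM files.
#' @return List with `samples` (named list of record data frames) and `truth`
#'   (data frame: `sample_id`, `group`, `psi_true`, `depth`, `seed`,
#'   `n_junction_reads`, and `sam_path` when written).
#' @export
simulate_cohort <- function(locus, design, out_dir = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  g <- design$groups
  plan <- withr::with_seed(design$seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      n <- g$n[i]
      pos <- runif(n) < g$prevalence[i]
      psi <- ifelse(pos, rbeta(n, g$psi_shape1[i], g$psi_shape2[i]), 0)
      data.frame(group = g$label[i], psi_true = psi,
                 stringsAsFactors = FALSE)
    }))
    rows$seed <- sample.int(2147483646L, nrow(rows))
    rows
  })
  plan$sample_id <- sprintf("s%03d", seq_len(nrow(plan)))
  samples <- vector("list", nrow(plan))
  names(samples) <- plan$sample_id
  plan$n_junction_reads <- NA_integer_
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    plan$sam_path <- NA_character_
  }
  for (i in seq_len(nrow(plan))) {
    p <- design$defaults
    p$psi_true <- plan$psi_true[i]
    p$seed <- plan$seed[i]
    sp <- if (is.null(out_dir)) NULL else
      file.path(out_dir, paste0(plan$sample_id[i], ".sam"))
    sim <- simulate_rnaseq_sample(locus, p, sam_path = sp,
                                  sample_id = plan$sample_id[i])
    samples[[i]] <- sim$records
    plan$n_junction_reads[i] <- sim$truth$n_junction_reads
    if (!is.null(out_dir)) plan$sam_path[i] <- sp
  }
  plan$depth <- design$defaults$depth
  cols <- c("sample_id", "group", "psi_true", "depth", "seed",
            "n_junction_reads", if (!is.null(out_dir)) "sam_path")
  list(samples = samples, truth = plan[, cols])
}
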