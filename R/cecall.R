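# Sample-suitability gate, CE-positive criterion and inclusion statistics.
# All functions are vectorized over the rows of a junction-count table, with
# undefined values returned as NA (flag, not exception).

#' CE detection parameters
#'
#' The suitability gate admits a sample when its expression proxy passes
#' either threshold: naive TPM at least `tpm_min` (default 1.55) OR at least
#' `min_e19_e20_reads` (default 20) reads on the e19-e20 junction, which sits
#' in both the canonical and the CE isoform. A suitable sample is CE-positive
#' when its CE-junction evidence reaches `min_ce_junction_reads` (default 2).
#' All comparisons are inclusive ("at least").
#'
#' @param tpm_min Minimum TPM (default 1.55).
#' @param min_e19_e20_reads Minimum e19-e20 junction reads (default 20).
#' @param min_ce_junction_reads Minimum CE-junction reads (default 2).
#' @return List of class `ce_detection_params`.
#' @export
ce_detection_params <- function(tpm_min = 1.55, min_e19_e20_reads = 20L,
                                min_ce_junction_reads = 2L) {
  if (tpm_min < 0 || min_e19_e20_reads < 0 || min_ce_junction_reads < 0)
    stop("thresholds must be >= 0")
  structure(list(tpm_min = tpm_min,
                 min_e19_e20_reads = as.integer(min_e19_e20_reads),
                 min_ce_junction_reads = as.integer(min_ce_junction_reads)),
            class = "ce_detection_params")
}

#' Sample suitability for CE analysis
#'
#' @param counts A `junction_counts` data frame (one or more rows) from
#'   [count_sample()].
#' @param params A [ce_detection_params()] object.
#' @return Logical vector, one flag per sample row.
#' @export
is_suitable <- function(counts, params = ce_detection_params()) {
  counts$naive_tpm >= params$tpm_min |
    counts$e19_e20 >= params$min_e19_e20_reads
}

ce_junction_reads <- function(counts, mode = c("union", "per-junction")) {
  mode <- match.arg(mode)
  inc_e20 <- counts$e20_ce128 + counts$e20_ce178
  if (mode == "union") inc_e20 + counts$ce_e21
  else pmax(inc_e20, counts$ce_e21)
}

#' Call CE-positive samples
#'
#' A sample is CE-positive iff it is suitable and its CE-junction evidence
#' reaches the threshold. `mode = "union"` (default) counts reads across the
#' e20-CE and CE-e21 junction classes together; `mode = "per-junction"` is
#' the strict reading requiring the threshold at a single junction class.
#' The unsuitability gate precedes the call: an unsuitable sample is never
#' positive, whatever its CE reads.
#'
#' @inheritParams is_suitable
#' @param mode CE-evidence pooling, `"union"` or `"per-junction"`.
#' @return Data frame of class `ce_call` with columns `sample_id`,
#'   `suitable`, `ce_positive`, `inclusion_fraction`, `psi`.
#' @export
detect_ce <- function(counts, params = ce_detection_params(),
                      mode = c("union", "per-junction")) {
  mode <- match.arg(mode)
  suitable <- is_suitable(counts, params)
  positive <- suitable &
    ce_junction_reads(counts, mode) >= params$min_ce_junction_reads
  out <- data.frame(sample_id = counts$sample_id,
                    suitable = suitable,
                    ce_positive = positive,
                    inclusion_fraction = inclusion_fraction(counts),
                    psi = psi_ce(counts),
                    stringsAsFactors = FALSE)
  class(out) <- c("ce_call", "data.frame")
  out
}

#' CE inclusion fraction
#'
#' Fraction of informative reads in the e20-e21 intron that support CE
#' inclusion: the numerator counts reads spanning the e20-CE128, e20-CE178 or
#' CE-e21 junctions plus reads aligned wholly within CE178; the denominator
#' adds the exclusion-supporting e20-e21 junction reads. Unspliced
#' intron-body reads support neither and are excluded (they are tallied
#' separately in the count table). `NA` when the denominator is zero.
#'
#' @inheritParams is_suitable
#' @return Numeric vector in `[0, 1]`, `NA` where undefined.
#' @export
inclusion_fraction <- function(counts) {
  num <- counts$e20_ce128 + counts$e20_ce178 + counts$ce_e21 +
    counts$within_ce
  den <- num + counts$e20_e21
  ifelse(den > 0, num / den, NA_real_)
}

#' Junction PSI of the cryptic exon
#'
#' Simplified percent-spliced-in from junction reads: inclusion evidence is
#' the mean of the two inclusion junction measurements (e20-CE128 + e20-CE178,
#' and CE-e21) so a read spanning both is not double-counted;
#' `psi = inclusion / (inclusion + e20-e21)`. `NA` when the denominator is
#' zero.
#'
#' @inheritParams is_suitable
#' @return Numeric vector in `[0, 1]`, `NA` where undefined.
#' @export
psi_ce <- function(counts) {
  inc <- (counts$e20_ce128 + counts$e20_ce178 + counts$ce_e21) / 2
  den <- inc + counts$e20_e21
  ifelse(den > 0, inc / den, NA_real_)
}

#' Summarize CE calls per cohort group
#'
#' Positive fractions are computed over suitable samples only.
#'
#' @param calls A [detect_ce()] data frame.
#' @param labels Character vector of group labels, parallel to `calls` rows,
#'   or a data frame with columns `sample_id` and `group`.
#' @return Data frame with `group`, `n_samples`, `n_suitable`, `n_positive`,
#'   `positive_fraction`.
#' @export
summarize_cohort <- function(calls, labels) {
  if (is.data.frame(labels)) {
    i <- match(calls$sample_id, labels$sample_id)
    if (anyNA(i)) stop("unlabelled sample(s): ",
                       paste(calls$sample_id[is.na(i)], collapse = ", "))
    labels <- labels$group[i]
  }
  if (length(labels) != nrow(calls))
    stop("labels must match the number of calls")
  if (anyNA(labels)) stop("missing group label")
  out <- do.call(rbind, lapply(unique(labels), function(g) {
    k <- labels == g
    ns <- sum(calls$suitable[k])
    np <- sum(calls$ce_positive[k])
    data.frame(group = g, n_samples = sum(k), n_suitable = ns,
               n_positive = np,
               positive_fraction = if (ns > 0) np / ns else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' QC correlation between e19-e20 and e20-e21 junction counts
#'
#' Pearson correlation across samples of the two canonical-junction counts;
#' in well-behaved cohorts the two track each other closely (the source data
#' show r = 0.99). `NA` with a warning when either vector has zero variance.
#'
#' @param counts A multi-row `junction_counts` data frame.
#' @return Pearson correlation coefficient, or `NA` when undefined.
#' @export
qc_junction_correlation <- function(counts) {
  if (nrow(counts) < 3L) stop("need at least 3 samples")
  x <- counts$e19_e20; y <- counts$e20_e21
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in junction counts; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}
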