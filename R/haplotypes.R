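# LD tagging via genotype-independence chi-square, repeat-allele dosage,
# risk-haplotype dose coding, dose-abundance association, and small
# statistical utilities (Spearman, delta-delta-Ct).

genotype_class <- function(g) {
  # unordered genotype label, e.g. "A/C"; NA when either allele is missing
  ifelse(is.na(g[, 1]) | is.na(g[, 2]),
         NA_character_,
         paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]), sep = "/"))
}

#' Genotype-independence chi-square between two loci
#'
#' Builds the contingency table of genotype classes at locus A by genotype
#' classes at locus B over shared, fully genotyped individuals and tests
#' independence with the chi-square statistic (no continuity correction, no
#' cell pooling); degrees of freedom count the observed non-empty genotype
#' classes, `(rows - 1) * (cols - 1)`. This is the genotype-level
#' independence test used for LD tagging of multi-allelic sites (allele
#' counts per locus must be within 2..8 after filtering).
#'
#' @param gt A `genotype_table`, or `NULL` when `tableA`/`tableB` are given
#'   directly as two-column allele matrices.
#' @param locusA,locusB Locus ids in `gt` (or two-column allele matrices when
#'   `gt` is `NULL`).
#' @return List of class `chisq_result`: `chi2`, `df`, `p`, `table_dims`,
#'   `n`, `table`.
#' @export
genotype_chisq <- function(gt, locusA, locusB) {
  if (inherits(gt, "genotype_table")) {
    gA <- gt$geno[[locusA]]; gB <- gt$geno[[locusB]]
    if (is.null(gA) || is.null(gB)) stop("unknown locus id")
  } else {
    gA <- locusA; gB <- locusB
  }
  cA <- genotype_class(gA); cB <- genotype_class(gB)
  keep <- !is.na(cA) & !is.na(cB)
  cA <- cA[keep]; cB <- cB[keep]
  if (length(cA) < 2L) stop("need >= 2 shared genotyped individuals")
  for (cc in list(A = cA, B = cB)) {
    n_alleles <- length(unique(unlist(strsplit(unique(cc), "/", fixed = TRUE))))
    if (n_alleles < 2L || n_alleles > 8L)
      stop("allele count per locus must be within [2, 8]")
  }
  if (length(unique(cA)) < 2L || length(unique(cB)) < 2L)
    stop("degenerate locus: only one observed genotype class")
  tab <- table(cA, cB)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, table_dims = dim(tab), n = sum(tab),
                 table = tab),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("genotype independence: chi2 = %.4f, df = %d (%dx%d), n = %d, p = %.4g\n",
              x$chi2, x$df, x$table_dims[1], x$table_dims[2], x$n, x$p))
  invisible(x)
}

#' Additional repeat units of indel alleles
#'
#' For an insertion locus whose ALT alleles append tandem copies of a motif
#' to the REF allele (the CATC repeat: the reference carries the baseline
#' units, ALTs add more), computes additional units per allele as
#' `(nchar(alt) - nchar(ref)) / nchar(motif)` and verifies that the inserted
#' segment is an exact tandem of the motif; non-conforming alleles get `NA`.
#' The REF allele itself has 0 additional units.
#'
#' @param locus Locus metadata list with `ref` and `alts` (as stored in a
#'   `genotype_table`).
#' @param motif Repeat unit (default `"CATC"`).
#' @return Named numeric vector of additional units per allele (REF first),
#'   `NA` for non-conforming alleles.
#' @export
repeat_dosage <- function(locus, motif = "CATC") {
  alleles <- c(locus$ref, locus$alts)
  extra <- vapply(alleles, function(a) {
    if (a == locus$ref) return(0)
    d <- nchar(a) - nchar(locus$ref)
    if (d <= 0 || d %% nchar(motif) != 0) return(NA_real_)
    k <- d / nchar(motif)
    if (!startsWith(a, locus$ref)) return(NA_real_)
    insert <- substr(a, nchar(locus$ref) + 1L, nchar(a))
    if (insert != strrep(motif, k)) return(NA_real_)
    k
  }, numeric(1))
  stats::setNames(extra, alleles)
}

#' Per-individual repeat dosage
#'
#' Sums the additional-unit counts of an individual's two alleles at the
#' repeat locus; `NA` when either allele is missing or non-conforming.
#'
#' @param gt A `genotype_table`.
#' @param locus_id Repeat locus id.
#' @param motif Repeat unit (default `"CATC"`).
#' @return Named numeric vector of additional units per individual.
#' @export
individual_repeat_dosage <- function(gt, locus_id, motif = "CATC") {
  l <- gt$loci[[locus_id]]
  if (is.null(l)) stop("unknown locus id")
  per_allele <- repeat_dosage(l, motif)
  g <- gt$geno[[locus_id]]
  stats::setNames(per_allele[g[, 1]] + per_allele[g[, 2]], gt$individuals)
}

#' Risk-haplotype dose from two tag SNPs
#'
#' Counts risk alleles at each of the two biallelic loci; individuals whose
#' counts agree get that shared count as their haplotype dose (0, 1 or 2,
#' the unphased additive coding usable when the loci are in strong LD).
#' Individuals with discordant counts, or missing genotypes, are excluded
#' with a recorded reason.
#'
#' @param gt A `genotype_table`.
#' @param locusA,locusB Locus ids of the two tag SNPs.
#' @param riskA,riskB Risk allele at each locus (forward strand); defaults
#'   to the locus metadata `risk_allele` when present.
#' @return Data frame with `individual`, `doseA`, `doseB`, `dose` (`NA` when
#'   excluded) and `exclusion_reason` (`NA`, `"discordant"` or `"missing"`).
#' @export
haplotype_dose <- function(gt, locusA = "snpA_ce", locusB = "snpB_intron",
                           riskA = NULL, riskB = NULL) {
  lA <- gt$loci[[locusA]]; lB <- gt$loci[[locusB]]
  if (is.null(lA) || is.null(lB)) stop("unknown locus id")
  riskA <- riskA %||% lA$risk_allele
  riskB <- riskB %||% lB$risk_allele
  if (is.null(riskA) || is.na(riskA) || is.null(riskB) || is.na(riskB))
    stop("risk alleles must be given or stored in locus metadata")
  gA <- gt$geno[[locusA]]; gB <- gt$geno[[locusB]]
  dA <- rowSums(gA == riskA)
  dB <- rowSums(gB == riskB)
  missing <- is.na(dA) | is.na(dB)
  discord <- !missing & dA != dB
  dose <- ifelse(missing | discord, NA_integer_, dA)
  data.frame(individual = gt$individuals,
             doseA = as.integer(dA), doseB = as.integer(dB),
             dose = as.integer(dose),
             exclusion_reason = ifelse(missing, "missing",
                                       ifelse(discord, "discordant",
                                              NA_character_)),
             stringsAsFactors = FALSE)
}

#' Linear association of CE abundance with haplotype dose
#'
#' Fits `abundance ~ dose (+ covariates)` by ordinary least squares and
#' reports the dose coefficient with its standard error and two-sided
#' t-test. The default model has no covariates; optional covariate columns
#' are added additively.
#'
#' @param abundance Numeric response vector.
#' @param dose Numeric additive dose coding (0/1/2).
#' @param covariates Optional data frame of covariate columns.
#' @return List of class `ols_result`: `beta0`, `beta1`, `se1`, `t1`, `p1`,
#'   `n`, `zero_residual` (flag: residual variance numerically zero, p
#'   undefined) and the underlying `fit`.
#' @export
ols_association <- function(abundance, dose, covariates = NULL) {
  df <- data.frame(abundance = abundance, dose = dose)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  p_par <- ncol(df)  # intercept + dose + covariates
  if (nrow(df) <= p_par) stop("need n > number of parameters")
  fit <- lm(abundance ~ ., data = df)
  if (anyNA(coef(fit))) stop("rank-deficient (collinear) design")
  sm <- suppressWarnings(summary(fit))  # silence the exact-fit warning
  rv <- sm$sigma^2
  zero_res <- rv < .Machine$double.eps * mean(abundance)^2 ||
    !is.finite(rv) || rv == 0
  co <- sm$coefficients
  structure(list(beta0 = co["(Intercept)", 1], beta1 = co["dose", 1],
                 se1 = co["dose", 2],
                 t1 = if (zero_res) Inf * sign(co["dose", 1])
                      else co["dose", 3],
                 p1 = if (zero_res) NA_real_ else co["dose", 4],
                 n = nrow(df), zero_residual = zero_res, fit = fit),
            class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("OLS dose association: beta = %.4f (se %.4f), n = %d, p = %s%s\n",
              x$beta1, x$se1, x$n,
              if (is.na(x$p1)) "NA" else sprintf("%.4g", x$p1),
              if (x$zero_residual) " [zero residual variance]" else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#' `NA` with a warning when either vector has zero rank variance.
#'
#' @param x,y Numeric vectors (>= 3 paired finite values).
#' @return Spearman's rho, or `NA` when undefined.
#' @export
spearman_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 paired finite values")
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    warning("zero rank variance; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - mean(Ct_housekeepers)` per sample;
#' `ddCt = dCt_sample - dCt_reference`; relative expression `2^(-ddCt)`.
#' Ct values above `ct_limit` (default 40) are clamped to it before any
#' computation, matching the handling of non-amplifying wells.
#'
#' @param ct_target Numeric vector of target-gene Ct values per sample.
#' @param ct_housekeepers Numeric vector (one housekeeper) or matrix/data
#'   frame (samples x housekeepers) of control-gene Ct values.
#' @param reference Index (or logical vector) of the reference sample(s);
#'   their mean dCt is the baseline.
#' @param ct_limit Upper Ct limit (default 40).
#' @return Numeric vector of fold changes relative to the reference.
#' @export
delta_delta_ct <- function(ct_target, ct_housekeepers, reference = 1L,
                           ct_limit = 40) {
  if (is.null(ct_housekeepers) || length(ct_housekeepers) == 0L)
    stop("at least one housekeeper is required")
  hk <- as.matrix(ct_housekeepers)
  if (nrow(hk) == 1L && length(ct_target) > 1L) hk <- t(hk)
  if (nrow(hk) != length(ct_target))
    stop("housekeeper rows must match samples")
  if (anyNA(ct_target) || anyNA(hk)) stop("Ct values must be finite")
  ct_target <- pmin(ct_target, ct_limit)
  hk <- pmin(hk, ct_limit)
  dct <- ct_target - rowMeans(hk)
  ddct <- dct - mean(dct[reference])
  2^(-ddct)
}
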