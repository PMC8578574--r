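#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the allele totals, the p-value is the sum
#' of the probabilities of every heterozygote count (same parity, same
#' allele counts) whose conditional probability does not exceed that of the
#' observed count. No mid-p adjustment.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote; the labelling is symmetric)
#' @return p-value in (0, 1]
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative counts", call. = FALSE)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotype required", call. = FALSE)
  n_a <- 2 * n_aa + n_ab          # copies of one allele
  n_b <- 2 * n_bb + n_ab
  hets <- seq(n_ab %% 2, min(n_a, n_b), by = 2)
  # log conditional probability of each attainable heterozygote count
  lp <- lfactorial(n) - lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2) + hets * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Remove samples with excess missingness
#'
#' A sample is removed when its missing-call fraction over autosomal markers
#' exceeds `mind_max` (strict `>`, so a sample exactly at the boundary is
#' retained).
#'
#' @param x a [cohort]
#' @param mind_max maximum tolerated missing fraction (default 0.1)
#' @return list with the filtered `cohort` and a `report` data.frame row
#'   (stage, n_in, n_removed, n_out, threshold)
#' @export
filter_samples <- function(x, mind_max = 0.1) {
  stopifnot(mind_max >= 0, mind_max <= 1)
  auto <- is_autosome(x$variants$chrom)
  frac <- if (any(auto))
    rowMeans(is.na(x$allele1[, auto, drop = FALSE])) else
      rep(0, nrow(x$samples))
  keep <- frac <= mind_max
  if (!any(keep))
    warning("all samples removed by the missingness filter", call. = FALSE)
  out <- x[keep, ]
  report <- data.frame(stage = "sample_missingness",
                       unit = "sample",
                       n_in = nrow(x$samples),
                       n_removed = sum(!keep),
                       n_out = sum(keep),
                       threshold = mind_max,
                       stringsAsFactors = FALSE)
  list(cohort = out, report = qc_report(report))
}

is_autosome <- function(chrom) {
  !(toupper(chrom) %in% c("X", "Y", "XY", "MT", "M", "0")) &
    !is.na(suppressWarnings(as.integer(chrom)))
}

#' SNP quality-control cascade
#'
#' Stages, in order: (1) drop non-autosomal and unmapped markers; (2) drop
#' markers with call rate `<= cr_min`; (3) drop markers with minor allele
#' frequency `<= maf_min` (computed on called genotypes across the retained
#' samples); (4) drop markers with Hardy-Weinberg exact p `<= hwe_alpha`
#' computed on the pooled sample (a per-population option is exposed since
#' pooling confounds the Wahlund effect with genotyping error).
#'
#' All three thresholds remove at the boundary (inclusive `<=`).
#'
#' @param x a [cohort]
#' @param cr_min call-rate threshold (default 0.95)
#' @param maf_min minor-allele-frequency threshold (default 0.05)
#' @param hwe_alpha HWE exact-test threshold (default 0.001)
#' @param autosomes_only drop non-autosomal markers first (default TRUE)
#' @param hwe_by_pop if TRUE, the HWE test is run within each population
#'   and a marker is dropped when its smallest per-population p is
#'   `<= hwe_alpha`
#' @return list with the filtered `cohort` and a telescoping `report`
#' @export
filter_snps <- function(x, cr_min = 0.95, maf_min = 0.05,
                        hwe_alpha = 0.001, autosomes_only = TRUE,
                        hwe_by_pop = FALSE) {
  stopifnot(cr_min >= 0, cr_min <= 1, maf_min >= 0, maf_min <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1)
  rows <- list()
  stage <- function(label, keep, thr, co) {
    rows[[length(rows) + 1]] <<- data.frame(
      stage = label, unit = "marker", n_in = length(keep),
      n_removed = sum(!keep), n_out = sum(keep), threshold = thr,
      stringsAsFactors = FALSE)
    co[, keep]
  }

  if (autosomes_only) {
    keep <- is_autosome(x$variants$chrom)
    x <- stage("autosome", keep, NA_real_, x)
  }
  dos <- to_dosage(x)
  cr <- colMeans(!is.na(dos))
  x <- stage("call_rate", cr > cr_min, cr_min, x)
  dos <- dos[, cr > cr_min, drop = FALSE]

  called <- colSums(!is.na(dos))
  p <- ifelse(called > 0, colSums(dos, na.rm = TRUE) / (2 * called), 0)
  maf <- pmin(p, 1 - p)
  x <- stage("maf", maf > maf_min, maf_min, x)
  dos <- dos[, maf > maf_min, drop = FALSE]

  pvals <- hwe_pvalues(dos, if (hwe_by_pop) x$samples$pop else NULL)
  x <- stage("hwe", pvals > hwe_alpha, hwe_alpha, x)

  list(cohort = x, report = qc_report(do.call(rbind, rows)))
}

hwe_pvalues <- function(dos, pops = NULL) {
  one <- function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  }
  if (is.null(pops)) return(apply(dos, 2, one))
  apply(dos, 2, function(g)
    min(vapply(split(g, pops), one, numeric(1))))
}

qc_report <- function(df) {
  stopifnot(all(df$n_in - df$n_removed == df$n_out))
  class(df) <- c("qc_report", "data.frame")
  df
}

#' Combine QC reports
#' @param ... `qc_report` objects
#' @return a single stacked `qc_report`
#' @export
bind_qc_reports <- function(...) qc_report(rbind(...))

#' @export
print.qc_report <- function(x, ...) {
  cat("QC cascade:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-20s %6d -> %6d (removed %d%s)\n", x$stage[i],
                x$n_in[i], x$n_out[i], x$n_removed[i],
                if (is.na(x$threshold[i])) "" else
                  sprintf(", threshold %g", x$threshold[i])))
  invisible(x)
}
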