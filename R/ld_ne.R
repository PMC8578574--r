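#' Genotype r-squared between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete samples. Undefined
#' (returns `NA`) when fewer than two complete pairs remain or either locus
#' is monomorphic among them.
#'
#' @param g1,g2 dosage vectors of equal length
#' @return r-squared in [0, 1], or `NA`
#' @export
genotype_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  use <- !is.na(g1) & !is.na(g2)
  if (sum(use) < 2) return(NA_real_)
  x <- g1[use]; y <- g2[use]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Window-based LD pruning
#'
#' Greedy left-to-right scan within each chromosome: for each retained
#' locus, any later locus within `window_bp` whose r-squared with it
#' exceeds `r2_max` triggers a removal; the lower-MAF locus of the pair is
#' dropped (tie: the downstream locus). Deterministic, idempotent, and the
#' surviving set contains no within-window pair with r-squared above the
#' threshold.
#'
#' @param dos dosage matrix
#' @param variants marker map with `chrom` and `pos`; defaults to the
#'   matrix's `variants` attribute
#' @param window_bp window size in bp (default 500 kb)
#' @param r2_max r-squared threshold (default 0.5); a pair is only removed
#'   when strictly above it
#' @return integer indices (into the matrix columns) of retained loci
#' @export
ld_prune <- function(dos, variants = attr(dos, "variants"),
                     window_bp = 500000, r2_max = 0.5) {
  stopifnot(nrow(variants) == ncol(dos))
  called <- colSums(!is.na(dos))
  p <- ifelse(called > 0, colSums(dos, na.rm = TRUE) / (2 * called), 0)
  maf <- pmin(p, 1 - p)
  alive <- rep(TRUE, ncol(dos))
  for (cc in unique(variants$chrom)) {
    idx <- which(variants$chrom == cc)
    idx <- idx[order(variants$pos[idx])]
    pos <- variants$pos[idx]
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      if (!alive[i]) next
      jj <- ii + 1
      while (jj <= length(idx) && pos[jj] - pos[ii] <= window_bp) {
        j <- idx[jj]
        if (alive[j]) {
          r2 <- genotype_r2(dos[, i], dos[, j])
          if (!is.na(r2) && r2 > r2_max) {
            if (maf[i] < maf[j]) {
              alive[i] <- FALSE
              break
            } else alive[j] <- FALSE
          }
        }
        jj <- jj + 1
      }
    }
  }
  which(alive)
}

#' Bin LD decay by physical distance
#'
#' All intra-chromosomal locus pairs separated by at most `max_dist_bp`
#' (and more than `min_dist_bp`) are assigned to distance bins; each bin
#' reports its mean r-squared, pair count, mean pairwise-complete sample
#' size and midpoint map distance in Morgans (100 Mb = 1 Morgan). Empty
#' bins are omitted.
#'
#' @param dos dosage matrix
#' @param variants marker map (`chrom`, `pos`)
#' @param breaks explicit bin edges in bp, or `NULL` to cut
#'   `[min_dist_bp, max_dist_bp]` into `n_bins` equal-width bins
#' @param n_bins number of equal-width bins when `breaks` is `NULL`
#' @param min_dist_bp,max_dist_bp distance range in bp
#' @return data.frame of class `ld_bins` with columns `dist_lo`, `dist_hi`,
#'   `mid_bp`, `c_morgan`, `mean_r2`, `n_pairs`, `mean_n`
#' @export
ld_decay_bins <- function(dos, variants = attr(dos, "variants"),
                          breaks = NULL, n_bins = 20,
                          min_dist_bp = 0, max_dist_bp = 4e6) {
  stopifnot(nrow(variants) == ncol(dos))
  if (is.null(breaks))
    breaks <- seq(min_dist_bp, max_dist_bp, length.out = n_bins + 1)
  d_all <- r2_all <- n_all <- numeric(0)
  for (cc in unique(variants$chrom)) {
    idx <- which(variants$chrom == cc)
    if (length(idx) < 2) next
    idx <- idx[order(variants$pos[idx])]
    pos <- variants$pos[idx]
    g <- dos[, idx, drop = FALSE]
    cm <- if (anyNA(g)) suppressWarnings(
      stats::cor(g, use = "pairwise.complete.obs")) else
        suppressWarnings(stats::cor(g))
    pair <- which(upper.tri(cm), arr.ind = TRUE)
    d <- pos[pair[, 2]] - pos[pair[, 1]]
    keep <- d > min_dist_bp & d <= max_dist_bp
    pair <- pair[keep, , drop = FALSE]; d <- d[keep]
    r2 <- cm[pair]^2
    nn <- if (anyNA(g)) {
      called <- !is.na(g)
      (t(called * 1) %*% (called * 1))[pair]
    } else rep(nrow(g), length(d))
    d_all <- c(d_all, d); r2_all <- c(r2_all, r2); n_all <- c(n_all, nn)
  }
  bin <- cut(d_all, breaks, right = TRUE)
  ok <- !is.na(bin) & !is.na(r2_all)
  agg <- function(v) tapply(v[ok], bin[ok], mean)
  mean_r2 <- agg(r2_all)
  filled <- which(!is.na(mean_r2))
  res <- data.frame(
    dist_lo = breaks[filled], dist_hi = breaks[filled + 1],
    mid_bp = (breaks[filled] + breaks[filled + 1]) / 2,
    mean_r2 = as.numeric(mean_r2[filled]),
    n_pairs = as.numeric(tapply(ok, bin, sum)[filled]),
    mean_n = as.numeric(agg(n_all)[filled]))
  res$c_morgan <- res$mid_bp / 1e8       # 100 Mb = 1 Morgan
  class(res) <- c("ld_bins", "data.frame")
  res
}

#' Effective population size trajectory from binned LD decay
#'
#' Each distance bin is mapped to a past generation `t = 1/(2c)` and an
#' effective size `Ne = (1/(4c)) (1/r2_adj - alpha)` where
#' `r2_adj = mean r2 - 1/(beta n)` corrects for the finite sample (`beta`
#' 2 for phased data, 1 for unphased; `n = Inf` disables the correction).
#' Bins whose adjusted r-squared or Ne estimate is non-positive are flagged
#' and dropped.
#'
#' @param bins an `ld_bins` frame from [ld_decay_bins()]
#' @param n sample size used for the correction (`Inf` to disable)
#' @param alpha drift correction constant: 1 (no mutation), 2 or the
#'   mutation-adjusted 2.2 (default)
#' @param phased whether genotypes were phased; sets the default `beta`
#' @param beta override the phasing factor
#' @return data.frame of class `ne_trajectory` with columns `t`, `ne`,
#'   `c_morgan`, `r2_adj`, ordered by increasing `t`; attribute `dropped`
#'   holds the excluded bins, attribute `settings` the constants used
#' @export
ne_trajectory <- function(bins, n, alpha = 2.2, phased = FALSE,
                          beta = NULL) {
  stopifnot(nrow(bins) >= 1)
  if (!is.infinite(n) && n <= 1) stop("n must exceed 1", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (is.null(beta)) beta <- if (phased) 2 else 1
  corr <- if (is.infinite(n)) 0 else 1 / (beta * n)
  cvec <- bins$c_morgan
  r2_adj <- bins$mean_r2 - corr
  ne <- (1 / (4 * cvec)) * (1 / r2_adj - alpha)
  t <- 1 / (2 * cvec)
  keep <- r2_adj > 0 & ne > 0
  res <- data.frame(t = t[keep], ne = ne[keep], c_morgan = cvec[keep],
                    r2_adj = r2_adj[keep])
  res <- res[order(res$t), ]
  rownames(res) <- NULL
  structure(res, dropped = sum(!keep),
            settings = list(alpha = alpha, beta = beta, n = n,
                            phased = phased),
            class = c("ne_trajectory", "data.frame"))
}

#' @export
plot.ne_trajectory <- function(x, ...) {
  graphics::plot(x$t, x$ne, type = "b", log = "x",
                 xlab = "generations ago (t = 1/2c)",
                 ylab = "effective population size", ...)
  invisible(x)
}
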