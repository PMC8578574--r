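#' Per-locus population summaries used by the F-statistics
#'
#' For each population and locus: the number of called individuals, the
#' counted-allele frequency and the observed heterozygote fraction.
#' @noRd
pop_locus_stats <- function(dos, pops) {
  pops <- as.character(pops)
  lev <- unique(pops)
  L <- ncol(dos)
  n <- p <- h <- matrix(0, length(lev), L, dimnames = list(lev, NULL))
  for (k in seq_along(lev)) {
    g <- dos[pops == lev[k], , drop = FALSE]
    nk <- colSums(!is.na(g))
    n[k, ] <- nk
    p[k, ] <- ifelse(nk > 0, colSums(g, na.rm = TRUE) / (2 * nk), NA)
    h[k, ] <- ifelse(nk > 0, colSums(g == 1, na.rm = TRUE) / nk, NA)
  }
  list(lev = lev, n = n, p = p, h = h)
}

#' Weir-Cockerham variance components per locus
#'
#' Implements the biallelic moment estimator of Weir & Cockerham (1984):
#' per-locus components `a` (among populations), `b` (among individuals
#' within populations) and `c` (within individuals), with
#' `theta_l = a / (a + b + c)`. Aggregation over loci is always the ratio of
#' sums, never the mean of per-locus ratios. Loci with fewer than two
#' populations called, with a population entirely missing, or with a mean
#' sample size of one are marked undefined (`NA` components).
#'
#' @param dos dosage matrix from [to_dosage()]
#' @param pops population labels (length = rows of `dos`); defaults to the
#'   matrix's `pops` attribute
#' @param subset optional subset of population labels to use
#' @return object of class `fst_components`: data.frame with columns `a`,
#'   `b`, `c`, `theta`; attributes `theta_global` (ratio of sums) and
#'   `n_pops`
#' @export
wc_fst_per_locus <- function(dos, pops = attr(dos, "pops"), subset = NULL) {
  pops <- as.character(pops)
  if (!is.null(subset)) {
    keep <- pops %in% subset
    dos <- dos[keep, , drop = FALSE]
    pops <- pops[keep]
  }
  if (length(unique(pops)) < 2)
    stop("at least two populations required", call. = FALSE)
  st <- pop_locus_stats(dos, pops)
  n <- st$n; p <- st$p; h <- st$h
  L <- ncol(dos)
  ok <- colSums(n > 0) >= 2 & colSums(n == 0) == 0
  r <- nrow(n)
  nbar <- colMeans(n)
  ok <- ok & nbar > 1
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - matrix(pbar, r, L, byrow = TRUE))^2) /
    ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA)
  res <- data.frame(a = a, b = b, c = cc, theta = theta)
  rownames(res) <- colnames(dos)
  structure(res,
            theta_global = theta_ratio_of_sums(res),
            n_pops = r,
            class = c("fst_components", "data.frame"))
}

#' Ratio-of-sums aggregate theta
#' @param comp an `fst_components` frame (or any frame with a, b, c)
#' @return the aggregate Weir-Cockerham theta over usable loci
#' @export
theta_ratio_of_sums <- function(comp) {
  denom <- comp$a + comp$b + comp$c
  use <- !is.na(denom) & denom != 0
  sum(comp$a[use]) / sum(denom[use])
}

#' Pairwise Weir-Cockerham F_ST between populations
#'
#' @inheritParams wc_fst_per_locus
#' @return symmetric matrix of aggregate theta values, zero diagonal
#' @export
pairwise_fst <- function(dos, pops = attr(dos, "pops")) {
  pops <- as.character(pops)
  lev <- unique(pops)
  if (length(lev) < 2)
    stop("at least two populations required", call. = FALSE)
  m <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)[-length(lev)])
    for (j in seq((i + 1), length(lev))) {
      comp <- wc_fst_per_locus(dos, pops, subset = lev[c(i, j)])
      m[i, j] <- m[j, i] <- attr(comp, "theta_global")
    }
  m
}

#' Per-population diversity summary
#'
#' Per locus and population: observed heterozygosity `Ho` (heterozygote
#' fraction among called individuals), unbiased expected heterozygosity
#' `He = 2 p q * 2n/(2n - 1)` and minor allele frequency; population values
#' are means over loci (monomorphic loci included as zeros). The
#' within-population inbreeding coefficient is computed per sample from
#' excess homozygosity, `F = (O_hom - E_hom) / (L_called - E_hom)` with the
#' expected homozygosity from that population's unbiased allele
#' frequencies, then averaged over the population's samples. An `Overall`
#' row pools every sample into one population.
#'
#' @inheritParams wc_fst_per_locus
#' @return data.frame of class `diversity_summary` with columns `pop`, `n`,
#'   `He`, `Ho`, `MAF`, `Fis`
#' @export
per_population_summary <- function(dos, pops = attr(dos, "pops")) {
  pops <- as.character(pops)
  lev <- unique(pops)
  if (any(!table(factor(pops, lev))))
    stop("population with zero samples", call. = FALSE)
  rows <- lapply(c(lev, list(lev)), function(sel) {
    g <- dos[pops %in% sel, , drop = FALSE]
    one_pop_summary(g, if (length(sel) > 1) "Overall" else sel)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("diversity_summary", "data.frame")
  res
}

one_pop_summary <- function(g, label) {
  nk <- colSums(!is.na(g))
  use <- nk > 0
  p <- colSums(g, na.rm = TRUE)[use] / (2 * nk[use])
  n <- nk[use]
  ho <- colSums(g == 1, na.rm = TRUE)[use] / n
  he <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  maf <- pmin(p, 1 - p)
  # per-sample inbreeding from excess homozygosity
  ehom_l <- 1 - he                      # expected homozygosity per locus
  called <- !is.na(g[, use, drop = FALSE])
  ohom <- rowSums(g[, use, drop = FALSE] != 1, na.rm = TRUE)
  ehom <- called %*% ehom_l
  lc <- rowSums(called)
  fis <- ifelse(lc - ehom > 0, (ohom - ehom) / (lc - ehom), NA)
  data.frame(pop = label, n = nrow(g), He = mean(he), Ho = mean(ho),
             MAF = mean(maf), Fis = mean(fis, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Nei's (1972) standard genetic distance between two frequency vectors
#'
#' `D = -ln(J_xy / sqrt(J_x J_y))` with `J_x = mean(p^2 + q^2)`,
#' `J_y` likewise and `J_xy = mean(p_x p_y + q_x q_y)` over loci. A zero
#' cross-identity (`J_xy = 0`) yields `Inf` with a warning rather than an
#' error.
#'
#' @param freq_x,freq_y counted-allele frequencies at the same loci
#' @return the distance `D >= 0` (0 for identical frequency vectors)
#' @export
nei_distance <- function(freq_x, freq_y) {
  stopifnot(length(freq_x) == length(freq_y),
            all(freq_x >= 0 & freq_x <= 1, na.rm = TRUE),
            all(freq_y >= 0 & freq_y <= 1, na.rm = TRUE))
  use <- !is.na(freq_x) & !is.na(freq_y)
  px <- freq_x[use]; py <- freq_y[use]
  jx <- mean(px^2 + (1 - px)^2)
  jy <- mean(py^2 + (1 - py)^2)
  jxy <- mean(px * py + (1 - px) * (1 - py))
  if (jxy == 0) {
    warning("zero cross-identity: distance is infinite", call. = FALSE)
    return(Inf)
  }
  max(0, -log(jxy / sqrt(jx * jy)))
}

#' Pairwise Nei distances between populations
#' @inheritParams wc_fst_per_locus
#' @return symmetric matrix of Nei (1972) distances
#' @export
pairwise_nei <- function(dos, pops = attr(dos, "pops")) {
  pops <- as.character(pops)
  lev <- unique(pops)
  freqs <- lapply(lev, function(k) {
    g <- dos[pops == k, , drop = FALSE]
    nk <- colSums(!is.na(g))
    ifelse(nk > 0, colSums(g, na.rm = TRUE) / (2 * nk), NA)
  })
  m <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)[-length(lev)])
    for (j in seq(i + 1, length(lev)))
      m[i, j] <- m[j, i] <- nei_distance(freqs[[i]], freqs[[j]])
  m
}

#' Gene-diversity differentiation indices
#'
#' Per locus over the populations called there (at least two required):
#' `H_S` is the unweighted mean within-population gene diversity `2 p_i q_i`,
#' `H_T` the gene diversity of the unweighted mean frequency, `D_ST = H_T -
#' H_S`, and Jost's `D_est = (k/(k-1)) (H_T - H_S)/(1 - H_S)`. Values are
#' averaged over loci after the per-locus computation; loci with `H_S = 1`
#' are excluded from the `D_est` average.
#'
#' @inheritParams wc_fst_per_locus
#' @return named list with `Hs`, `Ht`, `Dst`, `Dest`
#' @export
differentiation_indices <- function(dos, pops = attr(dos, "pops")) {
  pops <- as.character(pops)
  if (length(unique(pops)) < 2)
    stop("at least two populations required", call. = FALSE)
  st <- pop_locus_stats(dos, pops)
  k <- colSums(st$n > 0)
  use <- k >= 2
  he <- 2 * st$p * (1 - st$p)
  hs <- colMeans(he, na.rm = TRUE)[use]
  pbar <- colMeans(st$p, na.rm = TRUE)[use]
  ht <- 2 * pbar * (1 - pbar)
  kk <- k[use]
  dest_l <- ifelse(hs < 1, kk / (kk - 1) * (ht - hs) / (1 - hs), NA)
  list(Hs = mean(hs), Ht = mean(ht), Dst = mean(ht - hs),
       Dest = mean(dest_l, na.rm = TRUE))
}

#' Select loci above a differentiation threshold
#'
#' @param theta per-locus theta values (finite or NA; NA never selected)
#' @param threshold inclusive lower bound (default 0.20, the usual
#'   "informative locus" tier; 0.40 marks the strongly differentiated tier)
#' @return integer indices with `theta >= threshold`, input order preserved
#' @export
select_informative_loci <- function(theta, threshold = 0.20) {
  which(!is.na(theta) & theta >= threshold)
}

#' @export
print.fst_components <- function(x, ...) {
  cat(sprintf(
    "<fst_components> %d loci, %d populations; global theta = %.4f\n",
    nrow(x), attr(x, "n_pops"), attr(x, "theta_global")))
  cat(sprintf("defined per-locus theta: %d; range %.3f .. %.3f\n",
              sum(!is.na(x$theta)), min(x$theta, na.rm = TRUE),
              max(x$theta, na.rm = TRUE)))
  invisible(x)
}
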