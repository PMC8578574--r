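#' Per-locus F_ST scan between two breeds
#'
#' Two-population Weir-Cockerham theta per locus (delegating to
#' [wc_fst_per_locus()]); loci undefined in either breed are omitted.
#'
#' @param dos dosage matrix
#' @param pops population labels
#' @param breed_a,breed_b the two breed labels to contrast
#' @param variants marker map (`chrom`, `pos`, `name`); defaults to the
#'   matrix's attribute
#' @return data.frame of class `fst_scan` with columns `chrom`, `pos`,
#'   `name`, `theta`, sorted by chromosome and position; attribute `pair`
#' @export
pairwise_scan <- function(dos, pops = attr(dos, "pops"), breed_a, breed_b,
                          variants = attr(dos, "variants")) {
  pops <- as.character(pops)
  for (b in c(breed_a, breed_b))
    if (!b %in% pops) stop(sprintf("unknown breed label '%s'", b),
                           call. = FALSE)
  comp <- wc_fst_per_locus(dos, pops, subset = c(breed_a, breed_b))
  res <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    name = variants$name, theta = comp$theta,
                    stringsAsFactors = FALSE)
  res <- res[!is.na(res$theta), ]
  res <- res[order(suppressWarnings(as.numeric(res$chrom)), res$chrom,
                   res$pos), ]
  rownames(res) <- NULL
  structure(res, pair = c(breed_a, breed_b),
            class = c("fst_scan", "data.frame"))
}

#' Call selection-signature regions from a scan
#'
#' Loci with `theta >= threshold` become peaks; peaks within one flank of
#' each other on the same chromosome are merged into a single region whose
#' peak is the maximum-theta locus. Each region spans `peak +/- flank_bp`,
#' clipped at the chromosome start. With `perms > 0`, a label-permutation
#' null of theta at the peak locus gives each region a p-value and only
#' regions with `p < alpha` are retained.
#'
#' @param scan an `fst_scan` (sorted by position)
#' @param threshold calling threshold on theta (default 0.25; 0.50 is the
#'   top-signature tier)
#' @param flank_bp flank size (default 1 Mb)
#' @param perms permutations for the peak-locus test (0 = no test)
#' @param alpha retention level when testing (default 1e-4)
#' @param seed RNG seed for the permutations
#' @param dos,pops genotypes and labels of the scanned samples; required
#'   when `perms > 0`
#' @return data.frame of class `signature_regions` with columns `chrom`,
#'   `start`, `end` (1-based inclusive span for reporting), `start0`,
#'   `end0` (0-based half-open), `peak_pos`, `peak_name`, `peak_theta`,
#'   `n_peaks`, `p_value`
#' @export
call_sweeps <- function(scan, threshold = 0.25, flank_bp = 1e6,
                        perms = 0, alpha = 1e-4, seed = NULL,
                        dos = NULL, pops = NULL) {
  pk <- scan[scan$theta >= threshold, , drop = FALSE]
  if (!nrow(pk)) return(empty_regions())
  regions <- list()
  for (cc in unique(pk$chrom)) {
    sub <- pk[pk$chrom == cc, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(sub$pos) > flank_bp))
    for (g in split(seq_len(nrow(sub)), grp)) {
      blk <- sub[g, , drop = FALSE]
      top <- blk[which.max(blk$theta), ]
      start0 <- max(0, top$pos - 1 - flank_bp)
      end0 <- top$pos + flank_bp
      regions[[length(regions) + 1]] <- data.frame(
        chrom = top$chrom, start = start0 + 1, end = end0,
        start0 = start0, end0 = end0,
        peak_pos = top$pos, peak_name = top$name,
        peak_theta = top$theta, n_peaks = nrow(blk),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, regions)
  res$p_value <- NA_real_
  if (perms > 0) {
    if (is.null(dos) || is.null(pops))
      stop("permutation testing needs dos and pops", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    pair <- attr(scan, "pair")
    keep <- pops %in% pair
    g <- dos[keep, , drop = FALSE]
    lab <- as.character(pops[keep])
    # one set of label permutations, shared across the peak loci
    n1 <- sum(lab == unique(lab)[1])
    M <- matrix(0, perms, length(lab))
    idx <- vapply(seq_len(perms),
                  function(i) sample.int(length(lab), n1), integer(n1))
    M[cbind(rep(seq_len(perms), each = n1), as.vector(idx))] <- 1
    for (i in seq_len(nrow(res))) {
      locus <- match(res$peak_name[i], colnames(g))
      res$p_value[i] <- peak_permutation_p(g[, locus], M,
                                           res$peak_theta[i])
    }
    res <- res[res$p_value < alpha, , drop = FALSE]
  }
  rownames(res) <- NULL
  structure(res, pair = attr(scan, "pair"),
            class = c("signature_regions", "data.frame"))
}

empty_regions <- function() {
  structure(data.frame(chrom = character(), start = integer(),
                       end = integer(), start0 = integer(),
                       end0 = integer(), peak_pos = integer(),
                       peak_name = character(), peak_theta = numeric(),
                       n_peaks = integer(), p_value = numeric(),
                       stringsAsFactors = FALSE),
            class = c("signature_regions", "data.frame"))
}

# label-permutation null of the two-population theta at one locus; the
# permutation statistics are computed in closed form from per-group sums.
# M is a perms x samples 0/1 indicator of group-1 membership.
peak_permutation_p <- function(g, M, theta_obs) {
  X <- cbind(called = !is.na(g) * 1, dos = ifelse(is.na(g), 0, g),
             het = (!is.na(g) & g == 1) * 1)
  s1 <- M %*% X                    # per-perm group-1 sums
  s2 <- matrix(colSums(X), nrow(M), 3, byrow = TRUE) - s1
  th <- wc_theta_from_sums(s1[, 1], s1[, 2], s1[, 3],
                           s2[, 1], s2[, 2], s2[, 3])
  (sum(!is.na(th) & th >= theta_obs) + 1) / (nrow(M) + 1)
}

# two-population WC theta from per-group (called n, dosage sum, het count)
wc_theta_from_sums <- function(n1, d1, h1, n2, d2, h2) {
  r <- 2
  p1 <- d1 / (2 * n1); p2 <- d2 / (2 * n2)
  hh1 <- h1 / n1; hh2 <- h2 / n2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * hh1 + n2 * hh2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  ifelse(n1 > 0 & n2 > 0 & nbar > 1 & den != 0, a / den, NA)
}

#' Annotate signature regions with gene and QTL tracks
#'
#' A feature is attached to a region when their half-open intervals overlap
#' by at least one base (a gene starting exactly at the region end is not
#' attached). QTL features are tallied by trait class; the canonical seven
#' codes are MY (milk yield), MC (milk composition), R (reproduction),
#' M/C (meat and carcass), H (health), P (production), M (morphology).
#' Unknown class labels are left untallied with a warning.
#'
#' @param regions a `signature_regions` frame
#' @param genes optional `feature_track` of genes
#' @param qtls optional `feature_track` of QTLs with trait classes
#' @return the regions with a `genes` list-column and `qtl_<class>` count
#'   columns plus `qtl_total`
#' @export
annotate_regions <- function(regions, genes = NULL, qtls = NULL) {
  qtl_classes <- c("MY", "MC", "R", "M/C", "H", "P", "M")
  nr <- nrow(regions)
  regions$genes <- replicate(nr, character(0), simplify = FALSE)
  for (cl in qtl_classes)
    regions[[paste0("qtl_", gsub("/", "_", cl))]] <- 0L
  regions$qtl_total <- 0L
  if (nr == 0) return(regions)

  overlap_idx <- function(track, i) {
    if (is.null(track) || !nrow(track)) return(integer(0))
    if (!regions$chrom[i] %in% track$chrom) {
      warning(sprintf("chromosome %s absent from track", regions$chrom[i]),
              call. = FALSE)
      return(integer(0))
    }
    which(track$chrom == regions$chrom[i] &
            track$start < regions$end0[i] &
            regions$start0[i] < track$end)
  }
  unknown <- character(0)
  for (i in seq_len(nr)) {
    gi <- overlap_idx(genes, i)
    if (length(gi)) regions$genes[[i]] <- genes$name[gi]
    qi <- overlap_idx(qtls, i)
    if (length(qi)) {
      cls <- qtls$class[qi]
      bad <- !(cls %in% qtl_classes)
      unknown <- union(unknown, cls[bad])
      tt <- table(cls[!bad])
      for (cl in names(tt))
        regions[[paste0("qtl_", gsub("/", "_", cl))]][i] <- tt[[cl]]
      regions$qtl_total[i] <- sum(tt)
    }
  }
  if (length(unknown))
    warning("unknown QTL class labels left untallied: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  regions
}

#' Two-proportion z test
#'
#' Pooled-variance two-sided z test for the difference of two binomial
#' proportions. A degenerate pooled proportion (0 or 1) returns `z = 0`,
#' `p = 1`.
#'
#' @param x1,n1 successes and trials in group 1
#' @param x2,n2 successes and trials in group 2
#' @return object of class `prop2_test`: `x1`, `n1`, `x2`, `n2`, `pooled`,
#'   `z`, `p_value`
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    z <- 0; p <- 1
  } else {
    z <- (x1 / n1 - x2 / n2) /
      sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, pooled = pooled,
                 z = z, p_value = p),
            class = "prop2_test")
}

#' @export
print.prop2_test <- function(x, ...) {
  cat(sprintf("two-proportion test: %d/%d vs %d/%d\n",
              x$x1, x$n1, x$x2, x$n2))
  cat(sprintf("pooled p = %.4f, z = %.4f, two-sided p = %.3g\n",
              x$pooled, x$z, x$p_value))
  invisible(x)
}

#' Manhattan-style plot of a scan
#' @param x an `fst_scan`
#' @param threshold horizontal reference line (default 0.25)
#' @param ... passed to plot
#' @export
plot.fst_scan <- function(x, threshold = 0.25, ...) {
  chr <- factor(x$chrom, unique(x$chrom))
  off <- c(0, cumsum(tapply(x$pos, chr, max)))
  xs <- x$pos + off[as.integer(chr)]
  graphics::plot(xs, x$theta, pch = 16, cex = 0.4,
                 col = as.integer(chr) %% 2 + 1,
                 xlab = "genome position", ylab = expression(theta), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}
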