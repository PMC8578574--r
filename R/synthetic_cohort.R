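#' Specify a synthetic multi-population SNP cohort
#'
#' The generator follows the Balding-Nichols model: each population k draws
#' its allele frequency at locus l from
#' `Beta(p_l (1 - F_k) / F_k, (1 - p_l)(1 - F_k) / F_k)`, so the divergence
#' parameter `F_k` is the F_ST being estimated downstream. Individuals are
#' either of pure ancestry or carry Dirichlet-distributed admixture
#' proportions; every allele copy picks an ancestral cluster from the
#' individual's Q row, then an allele from that cluster's frequency.
#'
#' @param n_pops number of populations K
#' @param fst per-population divergence F_k in [0, 1); recycled to `n_pops`.
#'   `F_k = 0` means the population sits exactly at the ancestral
#'   frequencies; `F_k = 1` is rejected (degenerate Beta).
#' @param n_per_pop samples per population (recycled)
#' @param n_snps number of markers
#' @param ancestry `"pure"` or `"dirichlet"`
#' @param alpha Dirichlet concentration vector (length K) for
#'   `ancestry = "dirichlet"`
#' @param p_range range of the uniform ancestral-frequency law; the default
#'   `[0.05, 0.95]` keeps the post-QC minor-allele-frequency spectrum in the
#'   0.2-0.3 band typical of SNP-array panels
#' @param missing_rate independent per-call missingness probability
#' @param n_chrom number of chromosomes markers are spread over
#' @param chrom_length_bp chromosome length used to draw positions
#' @param seed mandatory RNG seed
#' @return a `sim_spec` list
#' @export
sim_spec <- function(n_pops, fst, n_per_pop, n_snps,
                     ancestry = c("pure", "dirichlet"), alpha = NULL,
                     p_range = c(0.05, 0.95), missing_rate = 0,
                     n_chrom = 1, chrom_length_bp = 1e8, seed) {
  ancestry <- match.arg(ancestry)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  fst <- rep_len(fst, n_pops)
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  if (any(fst < 0) || any(fst >= 1))
    stop("fst must lie in [0, 1); F = 1 is a degenerate Beta", call. = FALSE)
  if (any(n_per_pop < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (ancestry == "dirichlet" && is.null(alpha)) alpha <- rep(1, n_pops)
  structure(list(n_pops = n_pops, fst = fst, n_per_pop = n_per_pop,
                 n_snps = as.integer(n_snps), ancestry = ancestry,
                 alpha = alpha, p_range = p_range,
                 missing_rate = missing_rate, n_chrom = n_chrom,
                 chrom_length_bp = chrom_length_bp, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a genotype cohort with known ground truth
#'
#' @param spec a [sim_spec]
#' @return list with elements `cohort` (a [cohort]) and `truth` (ancestral
#'   frequencies `p`, per-population frequencies `p_k` (K x loci), the true
#'   ancestry matrix `Q`, and the divergence vector `fst`)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  K <- spec$n_pops; L <- spec$n_snps; n <- sum(spec$n_per_pop)
  p <- stats::runif(L, spec$p_range[1], spec$p_range[2])
  pk <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    f <- spec$fst[k]
    pk[k, ] <- if (f == 0) p else
      stats::rbeta(L, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  pop <- rep(paste0("P", seq_len(K)), spec$n_per_pop)
  Q <- matrix(0, n, K, dimnames = list(NULL, paste0("P", seq_len(K))))
  if (spec$ancestry == "pure") {
    Q[cbind(seq_len(n), rep(seq_len(K), spec$n_per_pop))] <- 1
  } else {
    g <- matrix(stats::rgamma(n * K, shape = rep(spec$alpha, each = n)),
                n, K)
    Q <- Q + g / rowSums(g)
  }
  # two allele copies per individual: cluster ~ Q_i, then allele ~ Bern(p_kl)
  dos <- matrix(0L, n, L)
  for (copy in 1:2) {
    z <- sample_cluster(Q, L)                 # n x L cluster index
    pr <- matrix(pk[cbind(as.vector(z), rep(seq_len(L), each = n))], n, L)
    dos <- dos + (matrix(stats::runif(n * L), n, L) < pr)
  }
  ch <- assign_positions(L, spec$n_chrom, spec$chrom_length_bp)
  variants <- data.frame(chrom = ch$chrom, pos = ch$pos,
                         name = sprintf("snp%06d", seq_len(L)),
                         a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  co <- dosage_to_cohort(dos, pop, variants)
  if (spec$missing_rate > 0)
    co <- inject_missingness(co, spec$missing_rate,
                             seed = spec$seed + 1L)
  list(cohort = co,
       truth = list(p = p, p_k = pk, Q = Q, fst = spec$fst))
}

# draw, for each individual and locus, the ancestral cluster of one allele
sample_cluster <- function(Q, L) {
  n <- nrow(Q); K <- ncol(Q)
  if (K == 1) return(matrix(1L, n, L))
  cum <- t(apply(Q, 1, cumsum))
  u <- matrix(stats::runif(n * L), n, L)
  z <- matrix(1L, n, L)
  for (k in seq_len(K - 1))
    z <- z + (u > cum[, k])
  z
}

assign_positions <- function(L, n_chrom, chrom_length_bp) {
  chrom <- as.character(rep_len(seq_len(n_chrom), L))
  chrom <- chrom[order(as.integer(chrom))]
  pos <- integer(L)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(max(chrom_length_bp, length(idx)),
                                length(idx)))
  }
  list(chrom = chrom, pos = pos)
}

# dosage counts the A1 ("A") allele
dosage_to_cohort <- function(dos, pop, variants) {
  n <- nrow(dos); L <- ncol(dos)
  a1 <- matrix("G", n, L); a2 <- matrix("G", n, L)
  a1[dos >= 1] <- "A"; a2[dos == 2] <- "A"
  a1[is.na(dos)] <- NA; a2[is.na(dos)] <- NA
  cohort(data.frame(id = sprintf("ind%04d", seq_len(n)), pop = pop,
                    stringsAsFactors = FALSE),
         variants, a1, a2)
}

#' Simulate a cohort with distance-dependent linkage disequilibrium
#'
#' Haplotypes follow a first-order copying chain: a latent uniform is
#' retained from the previous locus with probability `exp(-lambda * c)` for
#' inter-locus map distance `c` (100 Mb = 1 Morgan), otherwise redrawn.
#' With a per-haplotype recombination intensity
#' `lambda ~ Gamma(shape 1/2, scale 4 Ne)` the pairwise haplotype
#' correlation at distance `c` is exactly `(1 + 4 Ne c)^(-1/2)`, so the
#' expected `r^2` follows the drift curve `1 / (1 + 4 Ne c)` at every
#' distance. Genotypes are sums of two independent haplotypes. The allele
#' frequency is drawn once per chromosome (a locus-varying frequency would
#' attenuate the coupling below the target curve).
#'
#' @param ne target effective population size (>= 10)
#' @param n_samples number of diploid individuals
#' @param chrom_length_bp chromosome length in bp
#' @param n_snps markers per chromosome (>= 2)
#' @param n_chrom number of chromosomes
#' @param p_range range of the per-chromosome allele-frequency draw
#' @param seed RNG seed
#' @return list with `cohort` and `truth` (`ne`, `map_length_morgan`,
#'   per-chromosome allele frequency `p`)
#' @export
simulate_ld_cohort <- function(ne, n_samples, chrom_length_bp, n_snps,
                               n_chrom = 1, p_range = c(0.3, 0.7), seed) {
  if (ne < 10) stop("ne must be >= 10", call. = FALSE)
  if (n_snps < 2) stop("n_snps must be >= 2", call. = FALSE)
  set.seed(seed)
  n_hap <- 2L * n_samples
  dos_all <- NULL; chrom_all <- character(0); pos_all <- integer(0)
  p_chr <- numeric(n_chrom)
  for (cc in seq_len(n_chrom)) {
    pos <- sort(sample.int(max(chrom_length_bp, n_snps), n_snps))
    d_morgan <- diff(pos) / 1e8            # 100 Mb = 1 Morgan
    p <- stats::runif(1, p_range[1], p_range[2])
    p_chr[cc] <- p
    lambda <- stats::rgamma(n_hap, shape = 0.5, scale = 4 * ne)
    keep_p <- exp(-outer(lambda, d_morgan)) # n_hap x (L-1)
    u <- matrix(stats::runif(n_hap * n_snps), n_hap, n_snps)
    for (l in 2:n_snps) {
      keep <- stats::runif(n_hap) < keep_p[, l - 1]
      u[, l] <- ifelse(keep, u[, l - 1], u[, l])
    }
    hap <- (u < p) * 1L
    dos <- hap[seq_len(n_samples), , drop = FALSE] +
      hap[n_samples + seq_len(n_samples), , drop = FALSE]
    dos_all <- cbind(dos_all, dos)
    chrom_all <- c(chrom_all, rep(as.character(cc), n_snps))
    pos_all <- c(pos_all, pos)
  }
  variants <- data.frame(chrom = chrom_all, pos = pos_all,
                         name = sprintf("ldsnp%06d", seq_along(pos_all)),
                         a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  co <- dosage_to_cohort(dos_all, rep("P1", n_samples), variants)
  list(cohort = co,
       truth = list(ne = ne, p = p_chr,
                    map_length_morgan = n_chrom * chrom_length_bp / 1e8))
}

#' Expected r-squared as a function of map distance
#'
#' The drift expectation `1 / (alpha + 4 Ne c)` plus the finite-sample term
#' `1 / (beta n)` (omitted for `n = Inf`).
#'
#' @param ne effective population size
#' @param distances_morgan map distances in Morgans (> 0)
#' @param alpha drift correction constant (> 0); 1 for no mutation, 2.2 for
#'   the mutation-adjusted constant
#' @param n sample size entering the correction term (`Inf` drops it)
#' @param beta phasing factor: 2 for phased haplotypes, 1 for unphased
#'   genotypes
#' @return vector of expected r-squared values
#' @export
expected_r2_curve <- function(ne, distances_morgan, alpha = 1, n = Inf,
                              beta = 2) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (any(distances_morgan <= 0))
    stop("distances must be > 0", call. = FALSE)
  samp <- if (is.infinite(n)) 0 else 1 / (beta * n)
  1 / (alpha + 4 * ne * distances_morgan) + samp
}

#' Set calls missing at random
#'
#' @param x a [cohort]
#' @param rate missingness probability in [0, 1)
#' @param seed RNG seed
#' @return the cohort with additional missing calls
#' @export
inject_missingness <- function(x, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(x)
  set.seed(seed)
  drop <- matrix(stats::runif(length(x$allele1)) < rate,
                 nrow(x$allele1), ncol(x$allele1))
  x$allele1[drop] <- NA
  x$allele2[drop] <- NA
  x
}
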