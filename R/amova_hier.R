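# Hierarchical AMOVA on gametic mismatch distances, and hierarchical
# F-statistics from per-locus nested ANOVA variance components.
#
# Both rest on the same machinery: individuals contribute two pseudo-gametes
# (heterozygotes split allele-count-preservingly, which leaves mismatch
# counts invariant), and sums of squares within the units of each nesting
# level are equated to their design expectations. Coefficients of the
# variance components are computed numerically from the design, so
# unbalanced layouts need no special-casing.

# split dosages into a 2N x L gamete allele matrix (0/1, NA preserved)
gamete_matrix <- function(dos) {
  h1 <- (dos >= 1) * 1L
  h2 <- (dos == 2) * 1L
  rbind(h1, h2)
}

# sum over units of (1/n_u) * sum_{i<j in u} d2[i, j]
ssd_within <- function(d2, f) {
  tot <- 0
  for (idx in split(seq_len(nrow(d2)), f))
    if (length(idx) > 1)
      tot <- tot + sum(d2[idx, idx]) / (2 * length(idx))
  tot
}

# coefficient of the component constant within units of `part_cmp` in the
# expected within-unit SS at partition `part_outer`:
# sum_u (n_u - sum_{v in u} n_v^2 / n_u); both arguments integer codes
coef_ss <- function(part_outer, part_cmp) {
  ko <- max(part_outer); kc <- max(part_cmp)
  no <- tabulate(part_outer, ko)
  nv <- tabulate((part_outer - 1L) * kc + part_cmp, ko * kc)
  pos <- which(nv > 0L)
  ou <- (pos - 1L) %/% kc + 1L
  length(part_outer) -
    sum(as.vector(rowsum(nv[pos]^2, ou)) / no[sort(unique(ou))])
}

# solve the triangular expectation system from the innermost level up
backsolve_components <- function(coefmat, ssd) {
  m <- length(ssd)
  sigma2 <- rep(NA_real_, m)
  for (j in rev(seq_len(m))) {
    later <- if (j < m) (j + 1):m else integer(0)
    rest <- sum(coefmat[j, later] * sigma2[later], na.rm = TRUE)
    if (coefmat[j, j] > 0) sigma2[j] <- (ssd[j] - rest) / coefmat[j, j]
  }
  sigma2
}

# core partition on a gametic squared-distance matrix
amova_partition <- function(d2, g_ind, g_pop, g_grp = NULL) {
  N2 <- nrow(d2)
  n <- N2 / 2
  have_groups <- !is.null(g_grp)
  npop <- length(unique(g_pop))
  ngrp <- if (have_groups) length(unique(g_grp)) else NA_integer_

  ss_tot <- sum(d2) / (2 * N2)
  ss_grp <- if (have_groups) ssd_within(d2, g_grp) else NA
  ss_pop <- ssd_within(d2, g_pop)
  ss_ind <- ssd_within(d2, g_ind)
  ssd <- c(if (have_groups) ss_tot - ss_grp,
           (if (have_groups) ss_grp else ss_tot) - ss_pop,
           ss_pop - ss_ind,
           ss_ind)

  parts <- lapply(c(list(rep(1, N2)),
                    if (have_groups) list(g_grp),
                    list(g_pop), list(g_ind)),
                  function(f) match(f, unique(f)))
  m <- length(parts)            # number of SSD levels = components
  coefmat <- matrix(0, m, m)
  for (j in seq_len(m)) {
    for (cmp in seq_len(m)) {
      part_cmp <- if (cmp == m) seq_len(N2) else parts[[cmp + 1]]
      up <- coef_ss(parts[[j]], part_cmp)
      down <- if (j == m) 0 else coef_ss(parts[[j + 1]], part_cmp)
      coefmat[j, cmp] <- up - down
    }
  }
  sigma2 <- backsolve_components(coefmat, ssd)
  df <- c(if (have_groups) ngrp - 1,
          npop - (if (have_groups) ngrp else 1),
          n - npop,
          n)
  sigma2[df == 0] <- NA          # a level with a single unit is undefined
  src <- c(if (have_groups) "among_groups",
           if (have_groups) "among_pops_within_groups" else "among_pops",
           "among_individuals_within_pops",
           "within_individuals")
  tab <- data.frame(source = src, df = df, SS = ssd, sigma2 = sigma2,
                    stringsAsFactors = FALSE)
  tab$percent <- 100 * tab$sigma2 / sum(tab$sigma2, na.rm = TRUE)
  tab
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Each individual contributes two gametic allele vectors; the squared
#' distance between gametes is the allele mismatch count over
#' pairwise-called loci, rescaled to the full locus count (pairs sharing no
#' called locus are not supported). Sums of squared deviations are
#' partitioned across up to four nested levels (among groups; among
#' populations within groups; among individuals within populations; within
#' individuals); variance components follow by equating observed SSDs to
#' their design expectations. Negative components are retained, and the
#' percentages (which sum to 100) are taken over all defined components.
#'
#' Permutation tests use the standard scheme per level: whole populations
#' among groups; individuals among populations (within groups); gametes
#' among individuals within populations; and, for the within-individual
#' stratum, gametes among individuals across the whole sample (one-sided
#' toward a deficit of within-individual variation). P-values carry the
#' `(hits + 1)/(n_perm + 1)` correction, so the smallest attainable value
#' with 1023 permutations is 1/1024.
#'
#' @param dos dosage matrix
#' @param pops population labels per sample
#' @param groups optional group labels per sample; populations must be
#'   nested in groups. Omit for a three-level analysis.
#' @param n_perm number of permutations (default 1023); 0 skips the tests
#' @param seed RNG seed for the permutations
#' @return object of class `amova` with elements `table` (source, df, SS,
#'   sigma2, percent, p_value), `n_perm`, `seed`
#' @export
amova <- function(dos, pops = attr(dos, "pops"), groups = NULL,
                  n_perm = 1023, seed = NULL) {
  pops <- as.character(pops)
  n <- nrow(dos)
  have_groups <- !is.null(groups)
  if (have_groups) {
    groups <- as.character(groups)
    if (anyNA(groups)) stop("missing group labels", call. = FALSE)
    nest <- unique(data.frame(pops, groups, stringsAsFactors = FALSE))
    if (anyDuplicated(nest$pops))
      stop("populations must be nested in groups", call. = FALSE)
    if (length(unique(groups)) < 2)
      stop("at least two groups required", call. = FALSE)
  }
  H <- gamete_matrix(dos)
  # dist(manhattan) rescales NA-dropped terms by L / L_called, which is the
  # required missing-data correction; mismatch count = squared distance
  d2 <- as.matrix(stats::dist(H, method = "manhattan"))
  if (anyNA(d2))
    stop("a pair of gametes shares no called locus", call. = FALSE)
  g_ind <- rep(seq_len(n), 2)
  g_pop <- rep(pops, 2)
  g_grp <- if (have_groups) rep(groups, 2) else NULL

  tab <- amova_partition(d2, g_ind, g_pop, g_grp)
  tab$p_value <- NA_real_

  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- rep(0, nrow(tab))
    obs <- tab$sigma2
    wi <- nrow(tab)              # within-individual row index
    for (b in seq_len(n_perm)) {
      row <- 1
      if (have_groups) {          # pops among groups
        nest_p <- nest
        nest_p$groups <- sample(nest_p$groups)
        gp <- nest_p$groups[match(pops, nest_p$pops)]
        s <- amova_partition(d2, g_ind, g_pop, rep(gp, 2))$sigma2
        if (!is.na(obs[row]) && !is.na(s[row]) && s[row] >= obs[row])
          hits[row] <- hits[row] + 1
        row <- row + 1
      }
      # individuals among populations (within groups when present)
      pp <- pops
      if (have_groups) {
        for (g in unique(groups)) {
          idx <- which(groups == g)
          pp[idx] <- pops[sample(idx)]
        }
      } else pp <- sample(pops)
      s <- amova_partition(d2, g_ind, rep(pp, 2), g_grp)$sigma2
      if (!is.na(obs[row]) && !is.na(s[row]) && s[row] >= obs[row])
        hits[row] <- hits[row] + 1
      row <- row + 1
      # gametes among individuals within populations
      ind_p <- permute_gametes(g_ind, g_pop)
      s <- amova_partition(d2, ind_p, g_pop, g_grp)$sigma2
      if (!is.na(obs[row]) && !is.na(s[row]) && s[row] >= obs[row])
        hits[row] <- hits[row] + 1
      # within individuals: gametes among all individuals, one-sided low
      ind_g <- permute_gametes(g_ind, rep(1, length(g_ind)))
      s_wi <- ssd_within(d2, ind_g) / n   # sigma2_wi = SS_w(ind) / n
      if (!is.na(obs[wi]) && s_wi <= obs[wi]) hits[wi] <- hits[wi] + 1
    }
    tab$p_value <- ifelse(is.na(obs), NA, (hits + 1) / (n_perm + 1))
  }
  structure(list(table = tab, n_perm = n_perm, seed = seed),
            class = "amova")
}

# reassign gametes to individuals by shuffling within strata
permute_gametes <- function(g_ind, strata) {
  out <- g_ind
  for (idx in split(seq_along(g_ind), strata))
    out[sample(idx)] <- g_ind[idx]
  out
}

#' @export
print.amova <- function(x, ...) {
  cat(sprintf("AMOVA (%d permutations)\n", x$n_perm))
  tab <- x$table
  tab$sigma2 <- signif(tab$sigma2, 5)
  tab$percent <- round(tab$percent, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Hierarchical F-statistics over nested grouping factors
#'
#' Per-locus moment variance components are computed by nested ANOVA at the
#' gametic level for the hierarchy total > factor 1 > ... > factor m >
#' individual > gamete (factors are made strictly nested by crossing each
#' with the levels above it), summed over loci, and converted to
#' F-statistics: the F between an inner level `u` and an enclosing level
#' `v` is the ratio of the summed components for the levels between them to
#' the summed components below `v`. For a single factor this reproduces the
#' Weir-Cockerham F_ST (against "Total") and F_IS (Individual against the
#' factor) exactly.
#'
#' @param dos dosage matrix
#' @param levels data.frame of grouping factors, ordered outermost first
#' @return object of class `hier_fstat`: `F` (upper-triangular matrix,
#'   rows = enclosing reference level, columns = inner level),
#'   `components` (per-level variance components summed over loci)
#' @export
hierarchical_fstats <- function(dos, levels) {
  levels <- as.data.frame(levels, stringsAsFactors = FALSE)
  if (!nrow(levels) || nrow(levels) != nrow(dos))
    stop("levels must have one row per sample", call. = FALSE)
  if (anyNA(levels)) stop("missing factor labels", call. = FALSE)
  n <- nrow(dos)
  m <- ncol(levels)
  H <- gamete_matrix(dos)
  called <- !is.na(H)
  y <- H; y[!called] <- 0L
  N2 <- 2L * n

  # partitions outermost -> innermost, crossed for strict nesting
  parts <- vector("list", m + 2)
  parts[[1]] <- rep("all", N2)
  acc <- NULL
  for (j in seq_len(m)) {
    acc <- if (is.null(acc)) as.character(levels[[j]])
    else paste(acc, levels[[j]], sep = "\r")
    parts[[j + 1]] <- rep(acc, 2)
  }
  parts[[m + 2]] <- as.character(rep(seq_len(n), 2))   # individuals

  L <- ncol(dos)
  n_levels <- m + 2                  # components incl. individual + error
  # per-locus unit sums / counts at each partition level
  S <- lapply(parts, function(f) rowsum(y, f))
  Ncnt <- lapply(parts, function(f) rowsum(called * 1L, f))
  Tl <- colSums(y)
  ss_w <- function(j) {              # per-locus SS within units of level j
    Nj <- Ncnt[[j]]
    frac <- S[[j]]^2 / Nj
    frac[Nj == 0] <- 0
    Tl - colSums(frac)
  }
  # SS within gametes is 0 (binary single values), so SSD(error) = ss_w at
  # the individual partition
  ssw <- lapply(seq_len(n_levels), ss_w)
  ssd <- vector("list", n_levels)
  for (j in seq_len(n_levels))
    ssd[[j]] <- if (j < n_levels) ssw[[j]] - ssw[[j + 1]] else ssw[[j]]

  # per-locus coefficient of component cmp in E[ss_w(j)]:
  # Ncalled - sum_u sum_{v in u} n_v^2 / n_u
  parent_sum <- function(inner, outer) {
    # per-locus sum over outer units of (sum_{v in u} n_v^2) / n_u
    key <- tapply(seq_along(parts[[inner]]), parts[[inner]],
                  function(i) parts[[outer]][i[1]])
    num <- rowsum(Ncnt[[inner]]^2, as.character(key[rownames(Ncnt[[inner]])]))
    den <- Ncnt[[outer]][rownames(num), , drop = FALSE]
    frac <- num / den
    frac[den == 0] <- 0
    colSums(frac)
  }
  Ncalled <- colSums(called)
  coef_of <- function(j, cmp) {
    # component cmp lives at partition cmp+1 (error: singleton gametes)
    if (cmp == n_levels)
      Ncalled - colSums({ Nj <- Ncnt[[j]]; o <- 1 * (Nj > 0); o })
    else Ncalled - parent_sum(cmp + 1, j)
  }
  coefs <- vector("list", n_levels)   # coefs[[j]][[cmp]] per locus
  for (j in seq_len(n_levels)) {
    coefs[[j]] <- vector("list", n_levels)
    for (cmp in j:n_levels) {
      up <- coef_of(j, cmp)
      down <- if (j < n_levels) coef_of(j + 1, cmp) else 0
      coefs[[j]][[cmp]] <- up - down
    }
  }
  # triangular solve per locus (vectorized over loci)
  sigma <- matrix(NA_real_, n_levels, L)
  for (j in rev(seq_len(n_levels))) {
    rest <- 0
    if (j < n_levels)
      for (cmp in (j + 1):n_levels)
        rest <- rest + coefs[[j]][[cmp]] * sigma[cmp, ]
    cj <- coefs[[j]][[j]]
    v <- (ssd[[j]] - rest) / cj
    v[cj <= 0] <- NA
    sigma[j, ] <- v
  }
  comp <- rowSums(sigma, na.rm = TRUE)
  lab <- c(names(levels), "Individual")
  names(comp) <- c(lab, "Error")

  refs <- c("Total", lab)            # enclosing levels (0 .. m+1)
  Fm <- matrix(NA_real_, length(refs), length(lab),
               dimnames = list(refs, lab))
  for (v in seq_along(refs))
    for (u in seq_along(lab))
      if (u >= v) {
        num <- sum(comp[v:u])        # components v .. u (1-based = c_v..c_u)
        den <- sum(comp[v:length(comp)])
        Fm[v, u] <- num / den
      }
  structure(list(F = Fm, components = comp), class = "hier_fstat")
}

#' @export
print.hier_fstat <- function(x, ...) {
  cat("Hierarchical F-statistics (rows: reference level; columns: level)\n")
  print(round(x$F, 4))
  invisible(x)
}
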