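#' Identity-by-state relationship matrix
#'
#' `IBS(i, j)` is the mean over pairwise-called loci of the per-locus
#' allele-sharing score `(2 - |g_i - g_j|)/2`. Diagonal 1; a pair with no
#' shared called locus gets `NA`.
#'
#' @param dos dosage matrix
#' @return symmetric samples x samples matrix
#' @export
ibs_matrix <- function(dos) {
  stopifnot(nrow(dos) >= 2)
  # dist() rescales NA-dropped terms by L / L_called, which is exactly the
  # pairwise-complete mean
  d <- as.matrix(stats::dist(dos, method = "manhattan")) / ncol(dos)
  ibs <- 1 - d / 2
  diag(ibs) <- 1
  dimnames(ibs) <- list(rownames(dos), rownames(dos))
  ibs
}

#' Classical multidimensional scaling of an IBS matrix
#'
#' Performs metric MDS (principal coordinates) of the distance
#' `D = 1 - IBS`: double-centering and eigendecomposition. The variance
#' explained by each component is its eigenvalue as a percentage of the sum
#' of positive eigenvalues. Component signs are fixed so the
#' largest-magnitude coordinate on each axis is positive.
#'
#' @param similarity IBS-style similarity matrix
#' @param n_components number of components requested (default 3); silently
#'   truncated (with a warning) to the number of positive eigenvalues
#' @return object of class `mds_projection`: list with `points` (samples x
#'   components), `var_explained` (percentages) and `eigenvalues`
#' @export
mds_projection <- function(similarity, n_components = 3) {
  d <- stats::as.dist(1 - similarity)
  fit <- stats::cmdscale(d, k = min(n_components, nrow(similarity) - 1),
                         eig = TRUE)
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  npos <- sum(pos)
  k <- ncol(fit$points)
  if (n_components > npos) {
    warning(sprintf("only %d positive eigenvalues; truncating", npos),
            call. = FALSE)
    k <- min(k, npos)
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(pts)))
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  structure(list(points = pts,
                 var_explained = 100 * eig[seq_len(k)] / sum(eig[pos]),
                 eigenvalues = eig),
            class = "mds_projection")
}

#' @export
print.mds_projection <- function(x, ...) {
  cat(sprintf("<mds_projection> %d samples, %d components\n",
              nrow(x$points), ncol(x$points)))
  cat("variance explained (%):",
      paste(sprintf("%.1f", x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.mds_projection <- function(x, comps = c(1, 2),
                                col = NULL, pch = 19, ...) {
  graphics::plot(x$points[, comps[1]], x$points[, comps[2]],
                 col = if (is.null(col)) 1 else as.integer(factor(col)),
                 pch = pch,
                 xlab = sprintf("PC%d (%.1f%%)", comps[1],
                                x$var_explained[comps[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", comps[2],
                                x$var_explained[comps[2]]), ...)
  invisible(x)
}

#' Maximum-likelihood admixture inference by EM
#'
#' Fits the admixture likelihood
#' `log L = sum_il [ g_il log(sum_k q_ik p_kl) + (2 - g_il) log(sum_k q_ik (1 - p_kl)) ]`
#' over called genotype entries by expectation-maximization: each allele
#' copy is split among clusters by responsibility, then ancestry rows `Q`
#' and cluster frequencies `P` are re-estimated from the expected copy
#' counts. This is the point-estimation counterpart of model-based
#' clustering samplers: the same likelihood, deterministic given the seed.
#'
#' @param dos dosage matrix (no fully-missing sample)
#' @param K number of ancestral clusters (1 <= K <= samples)
#' @param seed RNG seed for the random initialization
#' @param max_iter iteration cap (default 2000)
#' @param tol relative log-likelihood convergence tolerance (default 1e-6)
#' @param restarts number of random restarts; the best final likelihood is
#'   returned
#' @return object of class `admixture_fit`: `Q` (samples x K), `P`
#'   (K x loci), `loglik`, `trace`, `n_iter`, `converged`, `K`, `seed`
#' @export
admixture_em <- function(dos, K, seed, max_iter = 2000, tol = 1e-6,
                         restarts = 1) {
  n <- nrow(dos); L <- ncol(dos)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("more clusters than samples", call. = FALSE)
  if (any(rowSums(!is.na(dos)) == 0))
    stop("fully-missing sample", call. = FALSE)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, restarts)
  best <- NULL
  for (s in run_seeds) {
    fit <- admixture_em_once(dos, K, s, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$seed <- seed
  best
}

admixture_em_once <- function(dos, K, seed, max_iter, tol) {
  set.seed(seed)
  n <- nrow(dos); L <- ncol(dos)
  G <- dos
  called <- !is.na(G)
  G0 <- G; G0[!called] <- 0L               # masked copy for sums
  lcalled <- rowSums(called)
  eps <- 1e-9
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(stats::runif(K * L, 0.1, 0.9), K, L)
  loglik_of <- function(Q, P) {
    F <- Q %*% P
    F <- pmin(pmax(F, 1e-12), 1 - 1e-12)
    sum((G0 * log(F) + (2 - G0) * log1p(-F))[called])
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    F <- Q %*% P
    F <- pmin(pmax(F, 1e-12), 1 - 1e-12)
    EA_tot <- matrix(0, n, K)              # expected copies per (i, k)
    for (k in seq_len(K)) {
      ra <- (Q[, k, drop = TRUE] %o% P[k, ]) / F        # A-copy resp.
      rb <- (Q[, k, drop = TRUE] %o% (1 - P[k, ])) / (1 - F)
      Ak <- G0 * ra; Bk <- (2 - G0) * rb
      Ak[!called] <- 0; Bk[!called] <- 0
      EA_tot[, k] <- rowSums(Ak + Bk)
      colA <- colSums(Ak); colT <- colA + colSums(Bk)
      P[k, ] <- ifelse(colT > 0, colA / colT, P[k, ])
    }
    P <- pmin(pmax(P, eps), 1 - eps)
    Q <- EA_tot / (2 * lcalled)
    Q <- Q / rowSums(Q)
    ll <- loglik_of(Q, P)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * abs(ll_old)) { converged <- TRUE; break }
    ll_old <- ll
  }
  structure(list(K = K, Q = Q, P = P, loglik = trace[length(trace)],
                 trace = trace, n_iter = length(trace),
                 converged = converged),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, %d samples, %d loci\n",
              x$K, nrow(x$Q), ncol(x$P)))
  cat(sprintf("log-likelihood %.2f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$loglik,
            df = (nrow(object$Q) * (object$K - 1) +
                    object$K * ncol(object$P)),
            class = "logLik")
}

#' @export
summary.admixture_fit <- function(object, pops = NULL, ...) {
  print(object)
  if (!is.null(pops)) {
    cat("mean ancestry by population:\n")
    print(round(membership_table(object, pops), 3))
  }
  invisible(object)
}

#' @export
plot.admixture_fit <- function(x, pops = NULL, ...) {
  ord <- if (is.null(pops)) seq_len(nrow(x$Q)) else order(pops)
  graphics::barplot(t(x$Q[ord, , drop = FALSE]), border = NA,
                    space = 0, col = seq_len(x$K) + 1,
                    ylab = "ancestry proportion", ...)
  invisible(x)
}

#' Select the number of clusters by mean log-likelihood
#'
#' For each K in `k_range`, runs `runs_per_k` EM fits from seeds derived
#' deterministically from `seed` and records the mean and best final
#' log-likelihood. The selected K is the argmax of the mean curve; the raw
#' curve is returned so a plateau can be judged by eye.
#'
#' @param dos dosage matrix
#' @param k_range integer vector of K values
#' @param runs_per_k EM runs per K (>= 1)
#' @param seed master seed; per-run seeds are drawn from it
#' @param ... passed to [admixture_em()]
#' @return object of class `k_selection`: `table` (K, mean_loglik,
#'   best_loglik), `selected_k`, `fits` (best fit per K)
#' @export
choose_k <- function(dos, k_range, runs_per_k = 3, seed, ...) {
  stopifnot(runs_per_k >= 1)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             length(k_range) * runs_per_k),
                  length(k_range), runs_per_k)
  fits <- vector("list", length(k_range))
  tab <- data.frame(K = k_range, mean_loglik = NA_real_,
                    best_loglik = NA_real_)
  for (i in seq_along(k_range)) {
    lls <- numeric(runs_per_k)
    best <- NULL
    for (rn in seq_len(runs_per_k)) {
      fit <- admixture_em(dos, k_range[i], seed = seeds[i, rn], ...)
      lls[rn] <- fit$loglik
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    tab$mean_loglik[i] <- mean(lls)
    tab$best_loglik[i] <- max(lls)
    fits[[i]] <- best
  }
  structure(list(table = tab,
                 selected_k = k_range[which.max(tab$mean_loglik)],
                 fits = stats::setNames(fits, paste0("K", k_range))),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("selected K:", x$selected_k, "\n")
  invisible(x)
}

#' @export
plot.k_selection <- function(x, ...) {
  graphics::plot(x$table$K, x$table$mean_loglik, type = "b", pch = 19,
                 xlab = "K", ylab = "mean log-likelihood", ...)
  invisible(x)
}

#' Population-by-cluster mean ancestry table
#'
#' @param fit an `admixture_fit`
#' @param pops population labels covering the fitted samples
#' @return matrix (population x cluster) of mean Q; rows sum to 1
#' @export
membership_table <- function(fit, pops) {
  stopifnot(length(pops) == nrow(fit$Q))
  m <- rowsum(fit$Q, pops) / as.vector(table(pops)[sort(unique(pops))])
  m[sort(unique(as.character(pops))), , drop = FALSE]
}
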