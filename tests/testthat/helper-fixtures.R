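# Shared fixtures built in code.

# dosage matrix with attributes, from a plain matrix
as_dosage <- function(m, pops, chrom = "1", pos = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%03d", seq_len(ncol(m)))
  v <- data.frame(chrom = rep_len(chrom, ncol(m)),
                  pos = if (is.null(pos)) seq_len(ncol(m)) * 1000L else pos,
                  name = colnames(m),
                  a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  structure(m, variants = v, pops = pops)
}

# two-sample, three-marker PED/MAP text fixture; returns the two paths
write_toy_pedmap <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("toyped")
    dir.create(dir)
  }
  ped <- c("FAM1 s1 0 0 1 -9 A A A G 0 0",
           "FAM2 s2 0 0 2 -9 A G G G C C")
  map <- c("1\trs1\t0\t1000", "1\trs2\t0\t2000", "2\trs3\t0\t500")
  ped_path <- file.path(dir, "toy.ped")
  map_path <- file.path(dir, "toy.map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  c(ped = ped_path, map = map_path)
}

# literal scalar transcription of the Weir & Cockerham (1984) equations,
# used as the independent oracle for the vectorized implementation
wc84_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# exact Hardy-Weinberg enumeration oracle using the probability-ratio
# recurrence (independent of the log-factorial implementation)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  hets <- seq(n_ab %% 2, min(n_a, n_b), by = 2)
  w <- numeric(length(hets))
  w[1] <- 1
  if (length(hets) > 1)
    for (i in 2:length(hets)) {
      h <- hets[i]                       # ratio P(h) / P(h - 2)
      w[i] <- w[i - 1] * 4 * ((n_a - h + 2) / 2) * ((n_b - h + 2) / 2) /
        (h * (h - 1))
    }
  pr <- w / sum(w)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# greedy best-permutation relabeling of a Q matrix against the truth
relabel_q <- function(qhat, qtrue) {
  K <- ncol(qhat)
  perms <- if (K == 2) list(1:2, 2:1) else
    asplit(as.matrix(expand.grid(rep(list(seq_len(K)), K))), 1)
  best <- NULL; best_err <- Inf
  for (pp in perms) {
    if (length(unique(pp)) < K) next
    err <- mean(abs(qhat[, pp, drop = FALSE] - qtrue))
    if (err < best_err) { best_err <- err; best <- qhat[, pp, drop = FALSE] }
  }
  list(Q = best, mae = best_err)
}
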