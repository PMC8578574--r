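#' Cohort container
#'
#' A `cohort` bundles SNP-array genotype calls with sample metadata and a
#' marker map. Calls are stored allele-wise (two character matrices), so the
#' original PED coding survives a round trip; numeric work goes through
#' [to_dosage()].
#'
#' @param samples data.frame with at least columns `id` and `pop`
#'   (population/breed label). Optional hierarchy columns `geography`,
#'   `body_size`, `dairy_level` are carried along if present.
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (1-based bp, integer), `name` (marker id), `a1`, `a2` (allele codes).
#' @param allele1,allele2 character matrices (samples x variants) holding the
#'   two alleles of each call; both `NA` where the call is missing.
#'
#' @return An object of class `cohort`.
#' @export
cohort <- function(samples, variants, allele1, allele2) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "pop") %in% names(samples)),
            all(c("chrom", "pos", "name", "a1", "a2") %in% names(variants)))
  for (col in c("geography", "body_size", "dairy_level"))
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
  samples$id <- as.character(samples$id)
  samples$pop <- as.character(samples$pop)
  variants$chrom <- normalize_chrom(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  obj <- structure(list(samples = samples, variants = variants,
                        allele1 = allele1, allele2 = allele2),
                   class = "cohort")
  validate_cohort(obj)
}

validate_cohort <- function(x) {
  n <- nrow(x$samples); l <- nrow(x$variants)
  if (!all(dim(x$allele1) == c(n, l)) || !all(dim(x$allele2) == c(n, l)))
    stop("call matrices must be samples x variants", call. = FALSE)
  if (anyDuplicated(x$samples$id))
    stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(x$variants$name))
    stop("duplicate marker names", call. = FALSE)
  if (any(is.na(x$allele1) != is.na(x$allele2)))
    stop("half-missing calls: the two alleles must be missing together",
         call. = FALSE)
  # positions strictly increasing within a chromosome once sorted,
  # i.e. no duplicated (chrom, pos)
  if (l > 1 && anyDuplicated(x$variants[c("chrom", "pos")]))
    stop("duplicated chromosome/position pairs", call. = FALSE)
  # every non-missing allele must be one of the declared codes
  for (j in seq_len(l)) {
    ok <- c(x$variants$a1[j], x$variants$a2[j])
    al <- c(x$allele1[, j], x$allele2[, j])
    bad <- !is.na(al) & !(al %in% ok)
    if (any(bad))
      stop(sprintf("marker %s carries allele outside its declared codes",
                   x$variants$name[j]), call. = FALSE)
  }
  x
}

# Chromosome labels are kept as strings; "BTA4" style prefixes are stripped
# so feature tracks and maps agree.
normalize_chrom <- function(x) sub("^(BTA|chr)", "", as.character(x),
                                   ignore.case = TRUE)

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples x %d variants\n",
              nrow(x$samples), nrow(x$variants)))
  tab <- table(x$samples$pop)
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$allele1))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.cohort <- function(x) c(nrow(x$samples), nrow(x$variants))

#' Number of samples / variants in a cohort
#' @param x a [cohort]
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a cohort
#'
#' @param x a [cohort]
#' @param i sample index (logical, integer or sample ids)
#' @param j variant index (logical, integer or marker names)
#' @param ... ignored
#' @return a [cohort]
#' @export
`[.cohort` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$samples))
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, x$variants$name)
  cohort(x$samples[i, , drop = FALSE], x$variants[j, , drop = FALSE],
         x$allele1[i, j, drop = FALSE], x$allele2[i, j, drop = FALSE])
}

#' Attach hierarchical grouping labels to cohort samples
#'
#' Merges a metadata table (by sample id or by population label) into the
#' cohort's sample frame. Used for the grouping factors of the hierarchical
#' analyses: geography (North/South), body size (Large/Small) and dairy
#' level (High/Medium/Low).
#'
#' @param x a [cohort]
#' @param meta data.frame keyed by `id` or by `pop`, with any of the columns
#'   `geography`, `body_size`, `dairy_level`.
#' @return the cohort with updated sample metadata
#' @export
attach_metadata <- function(x, meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  key <- if (!is.null(meta$id)) "id" else if (!is.null(meta$pop)) "pop" else
    stop("metadata needs an 'id' or 'pop' key column", call. = FALSE)
  idx <- match(x$samples[[key]], meta[[key]])
  for (col in intersect(c("geography", "body_size", "dairy_level"),
                        names(meta)))
    x$samples[[col]] <- as.character(meta[[col]])[idx]
  x
}
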