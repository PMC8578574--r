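#' Read PLINK text PED/MAP files into a cohort
#'
#' The PED dialect is whitespace-delimited with six leading columns
#' (family, individual, father, mother, sex, phenotype) followed by two
#' allele columns per marker; the family column is taken as the
#' population/breed label and the phenotype column is ignored. `0 0` codes a
#' missing call. The MAP file has four columns: chromosome, marker name,
#' genetic position (cM, ignored) and bp position.
#'
#' @param ped_path path to the PED file
#' @param map_path path to the MAP file
#' @return a [cohort]; variants appear in MAP order
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character",
                           col.names = c("chrom", "name", "cm", "pos"))
  if (anyDuplicated(map$name))
    stop("duplicate marker name in MAP", call. = FALSE)
  pos <- suppressWarnings(as.integer(map$pos))
  if (anyNA(pos)) stop("non-numeric bp position in MAP", call. = FALSE)
  l <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt != 6 + 2 * l))
    stop(sprintf("PED row with %d fields; expected %d for %d markers",
                 nt[which(nt != 6 + 2 * l)[1]], 6 + 2 * l, l), call. = FALSE)
  n <- length(toks)
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  samples <- data.frame(id = tok[, 2], pop = tok[, 1],
                        stringsAsFactors = FALSE)
  a1 <- tok[, 6 + 2 * seq_len(l) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(l), drop = FALSE]
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) stop("half-missing call in PED ('0' paired with an allele)",
                      call. = FALSE)
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA

  # allele codes per marker: observed alleles, padded to two codes
  codes <- lapply(seq_len(l), function(j) {
    u <- sort(unique(c(a1[, j], a2[, j])))
    u <- u[!is.na(u)]
    if (length(u) > 2)
      stop(sprintf("marker %s has >2 alleles", map$name[j]), call. = FALSE)
    c(u, rep(".", 2 - length(u)))[1:2]
  })
  variants <- data.frame(chrom = map$chrom, pos = pos, name = map$name,
                         a1 = vapply(codes, `[`, "", 1),
                         a2 = vapply(codes, `[`, "", 2),
                         stringsAsFactors = FALSE)
  cohort(samples, variants, a1, a2)
}

#' Write a cohort as PLINK text PED/MAP
#'
#' Missing calls are emitted as `0 0`; the population label goes into the
#' family column. Re-reading the files reproduces the cohort (allele-level
#' equality).
#'
#' @param x a [cohort]
#' @param out_prefix output path prefix; `<prefix>.ped` and `<prefix>.map`
#'   are written
#' @return invisibly, the two file paths
#' @export
write_ped_map <- function(x, out_prefix) {
  ped_path <- paste0(out_prefix, ".ped")
  map_path <- paste0(out_prefix, ".map")
  if (nrow(x$variants)) {
    map <- data.frame(x$variants$chrom, x$variants$name, 0, x$variants$pos)
    utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  } else file.create(map_path)
  a1 <- x$allele1; a2 <- x$allele2
  a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
  n <- nrow(x$samples); l <- nrow(x$variants)
  geno <- matrix("", n, 2 * l)
  if (l > 0) {
    geno[, 2 * seq_len(l) - 1] <- a1
    geno[, 2 * seq_len(l)] <- a2
  }
  lead <- cbind(x$samples$pop, x$samples$id, "0", "0", "0", "-9")
  writeLines(apply(cbind(lead, geno), 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Convert a cohort to an allele-dosage matrix
#'
#' @param x a [cohort]
#' @param counted which allele to count: `"a1"` counts the A1 code of each
#'   marker; `"minor"` counts the frequency-resolved minor allele (ties
#'   broken toward the lexicographically smaller code).
#' @return integer matrix (samples x variants) with entries 0/1/2 and `NA`
#'   for missing calls; attributes `counted_allele` (character vector per
#'   marker), `variants` (the marker map) and `pops` (population labels).
#'   All-missing markers under `"minor"` keep their A1 code and are flagged
#'   in attribute `undetermined`.
#' @export
to_dosage <- function(x, counted = c("a1", "minor")) {
  counted <- match.arg(counted)
  n <- nrow(x$samples); l <- nrow(x$variants)
  ca <- x$variants$a1
  undetermined <- logical(l)
  if (counted == "minor" && l > 0) {
    for (j in seq_len(l)) {
      al <- c(x$allele1[, j], x$allele2[, j])
      al <- al[!is.na(al)]
      if (!length(al)) { undetermined[j] <- TRUE; next }
      f1 <- mean(al == x$variants$a1[j])
      ca[j] <- if (f1 < 0.5) x$variants$a1[j]
      else if (f1 > 0.5) x$variants$a2[j]
      else min(x$variants$a1[j], x$variants$a2[j])
    }
  }
  dos <- matrix(NA_integer_, n, l,
                dimnames = list(x$samples$id, x$variants$name))
  if (l > 0) {
    cmat <- matrix(ca, n, l, byrow = TRUE)
    dos[] <- (x$allele1 == cmat) + (x$allele2 == cmat)
  }
  structure(dos, counted_allele = ca, undetermined = undetermined,
            variants = x$variants, pops = x$samples$pop)
}

#' Read a feature track (BED or GFF3)
#'
#' Intervals are stored half-open 0-based internally. BED input is already
#' 0-based half-open; GFF3 (1-based closed) is shifted. The BED dialect used
#' for QTL tracks carries the trait-class label in column 5 (in place of the
#' numeric score), so BED is parsed directly; GFF3 goes through
#' \code{rtracklayer} with the feature type column as the class label.
#'
#' @param path file path; format chosen by extension (`.bed` vs
#'   `.gff`/`.gff3`)
#' @param format override the extension-based format choice ("bed"/"gff3")
#' @return a data.frame of class `feature_track` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `name`, `class`
#' @export
read_features <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
    else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
    else stop("cannot infer track format from extension", call. = FALSE)
  }
  if (format == "bed") {
    if (file.size(path) == 0)
      return(feature_track(character(), integer(), integer(),
                           character(), character()))
    tab <- utils::read.table(path, header = FALSE, sep = "",
                             colClasses = "character", comment.char = "#")
    if (ncol(tab) < 3) stop("BED needs at least 3 columns", call. = FALSE)
    tr <- feature_track(
      chrom = tab[[1]],
      start = as.integer(tab[[2]]),
      end = as.integer(tab[[3]]),
      name = if (ncol(tab) >= 4) tab[[4]] else NA_character_,
      class = if (ncol(tab) >= 5) tab[[5]] else NA_character_)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    nm <- if (!is.null(md$Name)) as.character(md$Name)
    else if (!is.null(md$ID)) as.character(md$ID) else NA_character_
    tr <- feature_track(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      name = nm,
      class = as.character(md$type))
  }
  tr
}

feature_track <- function(chrom, start, end, name, class) {
  tr <- data.frame(chrom = normalize_chrom(chrom),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(name), class = as.character(class),
                   stringsAsFactors = FALSE)
  if (any(tr$end <= tr$start))
    stop("feature with end <= start", call. = FALSE)
  class(tr) <- c("feature_track", "data.frame")
  tr
}
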