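## Reading, validating, filtering and aggregating somatic mutation data.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

MUTATION_TYPE_LABELS <- c("CpG C>T", "C>T", "CpG C>A", "C>A",
                          "CpG C>G", "C>G", "T>A", "T>C", "T>G")

#' Mutation type labels
#'
#' The nine single-nucleotide mutation classes used by the background model:
#' pyrimidine-strand substitutions C>T, C>A, C>G each split by CpG context
#' (reference C immediately followed by G on the pyrimidine strand), plus
#' T>A, T>C, T>G.
#'
#' @return character(9) of class labels, in index order.
#' @export
mutationTypeLabels <- function() MUTATION_TYPE_LABELS

#' Classify a single-nucleotide change into one of nine mutation types
#'
#' Types are strand-symmetric: substitutions with a purine reference are
#' first reverse-complemented onto the pyrimidine strand (swapping and
#' complementing the flanking context). CpG status is reference C followed
#' by G on the pyrimidine strand.
#'
#' @param ref,alt reference and alternate base (A/C/G/T), vectorized.
#' @param context5,context3 reference bases immediately 5' and 3' of the
#'   position, on the plus strand.
#' @return integer vector of type indices in 1..9; see
#'   \code{\link{mutationTypeLabels}} for the index order.
#' @examples
#' classifyMutationType("C", "T", "A", "G")  # CpG C>T -> 1
#' classifyMutationType("G", "A", "C", "T")  # reverse complement, also 1
#' @export
classifyMutationType <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  bad <- !(ref %in% DNA_BASES) | !(alt %in% DNA_BASES) |
    !(context5 %in% DNA_BASES) | !(context3 %in% DNA_BASES)
  if (any(bad)) stop("non-base character in mutation type classification")
  if (any(ref == alt)) stop("ref must differ from alt")
  ## integer encoding A=1 C=2 G=3 T=4; complement is 5 - code
  ri <- match(ref, DNA_BASES)
  ai <- match(alt, DNA_BASES)
  c5i <- match(context5, DNA_BASES)
  c3i <- match(context3, DNA_BASES)
  ## fold purine references onto the pyrimidine strand (swap and
  ## complement the flanking context)
  flip <- ri == 1L | ri == 3L
  r2 <- ifelse(flip, 5L - ri, ri)
  a2 <- ifelse(flip, 5L - ai, ai)
  c3f <- ifelse(flip, 5L - c5i, c3i)
  cpg <- r2 == 2L & c3f == 3L
  ## lookup over (pyrimidine ref, alt, CpG status)
  tab <- array(NA_integer_, c(4L, 4L, 2L))
  tab[2L, 4L, ] <- c(2L, 1L)  # C>T
  tab[2L, 1L, ] <- c(4L, 3L)  # C>A
  tab[2L, 3L, ] <- c(6L, 5L)  # C>G
  tab[4L, 1L, ] <- 7L         # T>A
  tab[4L, 2L, ] <- 8L         # T>C
  tab[4L, 3L, ] <- 9L         # T>G
  tab[cbind(r2, a2, cpg + 1L)]
}

#' Load somatic mutations from a MAF-like file and filter hypermutators
#'
#' Reads a tab-separated file with header columns \code{sample_id, chrom,
#' pos, ref, alt} (extra columns ignored, \code{#} comment lines allowed).
#' Rows that are not single-nucleotide substitutions are skipped with a
#' warning. Samples whose retained SNV count exceeds the hypermutator
#' threshold are dropped in full.
#'
#' @param path path to the MAF-like TSV.
#' @param hypermutatorMax positive count threshold, or \code{"auto"}: drop
#'   samples whose \code{log1p} count exceeds the across-sample mean plus
#'   three standard deviations of \code{log1p} counts.
#' @return list with \code{records} (data.frame of kept MutationRecords, row
#'   order preserved) and \code{report} (per-sample data.frame
#'   \code{sample_id, n_snv, status}).
#' @export
loadMutations <- function(path, hypermutatorMax = "auto") {
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("mutation file is missing required column(s): ",
         paste(miss, collapse = ", "))
  raw <- raw[need]
  raw$pos <- suppressWarnings(as.integer(raw$pos))
  snv <- raw$ref %in% DNA_BASES & raw$alt %in% DNA_BASES &
    raw$ref != raw$alt & !is.na(raw$pos) & raw$pos >= 1L
  nSkipped <- sum(!snv)
  if (nSkipped > 0)
    warning(nSkipped, " non-SNV row(s) skipped")
  rec <- raw[snv, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(list(records = rec,
                report = data.frame(sample_id = character(0),
                                    n_snv = integer(0),
                                    status = character(0),
                                    stringsAsFactors = FALSE)))
  }
  counts <- table(rec$sample_id)
  nSnv <- as.integer(counts)
  sid <- names(counts)
  if (identical(hypermutatorMax, "auto")) {
    lc <- log1p(nSnv)
    thr <- mean(lc) + 3 * stats::sd(lc)
    dropped <- if (is.na(thr)) rep(FALSE, length(lc)) else lc > thr
  } else {
    stopifnot(is.numeric(hypermutatorMax), hypermutatorMax > 0)
    dropped <- nSnv > hypermutatorMax
  }
  report <- data.frame(sample_id = sid, n_snv = nSnv,
                       status = ifelse(dropped, "dropped", "kept"),
                       stringsAsFactors = FALSE)
  keep <- !(rec$sample_id %in% sid[dropped])
  rownames(rec) <- NULL
  list(records = rec[keep, , drop = FALSE], report = report)
}

#' Aggregate mutation records onto a site table
#'
#' Each record increments the count of the site-table row matching its
#' (chrom, pos, ref, alt). Records at positions absent from the table, or
#' whose reference allele disagrees with the table, are reported and not
#' counted.
#'
#' @param records data.frame of mutation records (as from
#'   \code{\link{loadMutations}}).
#' @param sites a \code{\link{SiteTable}}.
#' @return list with \code{counts} (integer vector aligned with the site
#'   rows) and \code{unmatched} (data.frame of uncounted records with a
#'   \code{reason} column: \code{"unmatched"} or \code{"ref_mismatch"}).
#' @export
aggregateCounts <- function(records, sites) {
  stopifnot(is(sites, "SiteTable"))
  validObject(sites)
  s <- siteData(sites)
  counts <- integer(nrow(s))
  if (nrow(records) == 0L) {
    return(list(counts = counts,
                unmatched = cbind(records,
                                  reason = character(0))))
  }
  siteKey <- paste(s$chrom, s$pos, s$ref, s$alt, sep = ":")
  recKey <- paste(records$chrom, records$pos, records$ref, records$alt,
                  sep = ":")
  idx <- match(recKey, siteKey)
  hit <- !is.na(idx)
  if (any(hit)) {
    tab <- table(idx[hit])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  unmatched <- records[!hit, , drop = FALSE]
  reason <- character(nrow(unmatched))
  if (nrow(unmatched)) {
    posKey <- paste(s$chrom, s$pos, sep = ":")
    upos <- paste(unmatched$chrom, unmatched$pos, sep = ":")
    posIdx <- match(upos, posKey)
    refThere <- !is.na(posIdx)
    siteRef <- s$ref[posIdx]
    reason <- ifelse(refThere & siteRef != unmatched$ref,
                     "ref_mismatch", "unmatched")
  }
  unmatched$reason <- reason
  rownames(unmatched) <- NULL
  list(counts = counts, unmatched = unmatched)
}

#' Read a site table from a TSV file
#'
#' Expected columns: \code{gene_id, chrom, pos, ref, alt, mutation_type,
#' impact, context5, context3}, plus background features prefixed
#' \code{bg:} and binary functional features prefixed \code{fn:}.
#'
#' @param path input TSV path.
#' @return a \code{\link{SiteTable}}.
#' @export
readSiteTable <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  bgCols <- grep("^bg:", names(raw), value = TRUE)
  fnCols <- grep("^fn:", names(raw), value = TRUE)
  core <- raw[setdiff(names(raw), c(bgCols, fnCols))]
  bg <- as.matrix(raw[bgCols])
  colnames(bg) <- sub("^bg:", "", bgCols)
  fn <- as.matrix(raw[fnCols])
  colnames(fn) <- sub("^fn:", "", fnCols)
  st <- SiteTable(core, bg, fn)
  validObject(st)
  st
}

#' Write a site table to a TSV file
#'
#' @param sites a \code{\link{SiteTable}}.
#' @param path output TSV path.
#' @export
writeSiteTable <- function(sites, path) {
  out <- siteData(sites)
  bg <- bgFeatures(sites)
  fn <- fnFeatures(sites)
  if (ncol(bg)) {
    colnames(bg) <- paste0("bg:", colnames(bg))
    out <- cbind(out, bg)
  }
  if (ncol(fn)) {
    colnames(fn) <- paste0("fn:", colnames(fn))
    out <- cbind(out, fn)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-sample hypermutator report
#'
#' @param report data.frame from \code{\link{loadMutations}}.
#' @param path output TSV path.
#' @export
writeSampleReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
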