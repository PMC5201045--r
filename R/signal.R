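## Summit-centered tag quantification and the lost/shared/gained
## three-class peak classification by log2 signal fold change.

#' Read tag positions from a 2-column TSV (chrom, position)
#'
#' Positions are 0-based bp. Single-bp BED files (chrom, start, start+1)
#' are also accepted; the start coordinate is used.
#'
#' @param path File path.
#' @return A data.frame with columns `chrom`, `pos`.
#' @export
read_tags <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1]]), pos = as.numeric(df[[2]]))
}

#' Write tag positions as a 2-column TSV
#' @param tags Data.frame with columns chrom, pos.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  write.table(tags[c("chrom", "pos")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summit-centered binned tag-count matrix
#'
#' Counts tags per condition in uniform bins spanning the window
#' `[ref - flank, ref + flank)` around each region's reference point
#' (summit if stored, else midpoint). Bins are half-open, so a tag exactly
#' at the reference point falls in the bin immediately right of center.
#' Window parts outside chromosome bounds simply contribute zeros.
#'
#' @param regions A `GRanges`.
#' @param tags Named list (one element per condition) of data.frames with
#'   columns `chrom`, `pos`; positions must be non-decreasing within each
#'   chromosome.
#' @param flank Half window in bp (default 1000); must be a positive
#'   multiple of `bin_width`.
#' @param bin_width Bin width in bp (default 50).
#' @return An object of class `"SignalMatrix"`: list with `regions`,
#'   `offsets` (left edge of each bin relative to the reference point),
#'   `bin_width`, `flank`, `counts` (named list of region x bin matrices),
#'   `library_size` (total tags per condition).
#' @export
summit_matrix <- function(regions, tags, flank = 1000, bin_width = 50) {
  if (!is.numeric(flank) || flank <= 0) stop("flank must be positive")
  if (!is.numeric(bin_width) || bin_width <= 0 || flank %% bin_width != 0)
    stop("flank must be a positive multiple of bin_width")
  if (!is.list(tags) || is.null(names(tags)))
    stop("tags must be a named list of per-condition position tables")
  nbins <- as.integer(2 * flank / bin_width)
  centers <- reference_points(regions)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  counts <- lapply(names(tags), function(cond) {
    tg <- tags[[cond]]
    m <- matrix(0L, nrow = length(regions), ncol = nbins)
    for (ch in unique(chrom)) {
      p <- tg$pos[tg$chrom == ch]
      if (is.unsorted(p)) stop("tag positions must be sorted within chromosome (", cond, ", ", ch, ")")
      ri <- which(chrom == ch)
      for (i in ri) {
        lo <- centers[i] - flank
        i1 <- findInterval(lo - 0.5, p) + 1
        i2 <- findInterval(lo + 2 * flank - 0.5, p)
        if (i2 >= i1) {
          b <- (p[i1:i2] - lo) %/% bin_width
          m[i, ] <- m[i, ] + tabulate(b + 1, nbins)
        }
      }
    }
    rownames(m) <- region_ids(regions)
    m
  })
  names(counts) <- names(tags)
  structure(list(
    regions = regions,
    offsets = seq(-flank, flank - bin_width, by = bin_width),
    bin_width = bin_width, flank = flank,
    counts = counts,
    library_size = vapply(tags, nrow, numeric(1))
  ), class = "SignalMatrix")
}

region_ids <- function(regions) {
  if (!is.null(regions$name)) as.character(regions$name)
  else paste0(as.character(GenomicRanges::seqnames(regions)), ":",
              GenomicRanges::start(regions) - 1, "-",
              GenomicRanges::end(regions))
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat(sprintf("SignalMatrix: %d regions x %d bins (%d bp), +/-%d bp, conditions: %s\n",
              length(x$regions), length(x$offsets), x$bin_width, x$flank,
              paste(names(x$counts), collapse = ", ")))
  invisible(x)
}

#' Classify regions as lost/shared/gained by log2 signal fold change
#'
#' Per-region tag totals are normalised to tags per 10 million per
#' condition, a pseudocount is added, and the log2 fold change B over A is
#' thresholded at `+/-cutoff`: class 1 ("lost") when `log2fc <= -cutoff`,
#' class 3 ("gained") when `log2fc >= +cutoff`, class 2 ("shared")
#' otherwise — the boundary belongs to the extreme classes.
#'
#' @param m A `SignalMatrix`.
#' @param cond_A,cond_B Condition names in `m$counts` (fold change is B/A).
#' @param cutoff Classification cutoff in log2 units (> 0; default 1).
#' @param pseudocount Added to the normalised totals (default 1).
#' @return A data.frame of class `"ClassifiedPeakTable"` sorted by
#'   increasing log2fc: `region`, `region_index` (position in
#'   `m$regions`), `tags_A`, `tags_B` (normalised totals), `log2fc`,
#'   `class` (1/2/3), `class_label`, `rank`.
#' @export
fold_change_classify <- function(m, cond_A, cond_B, cutoff = 1.0,
                                 pseudocount = 1.0) {
  stopifnot(inherits(m, "SignalMatrix"))
  if (!all(c(cond_A, cond_B) %in% names(m$counts)))
    stop("conditions not found in SignalMatrix: ",
         paste(setdiff(c(cond_A, cond_B), names(m$counts)), collapse = ", "))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (any(m$library_size[c(cond_A, cond_B)] <= 0))
    stop("library sizes must be > 0")
  tot_a <- rowSums(m$counts[[cond_A]]) / m$library_size[[cond_A]] * 1e7
  tot_b <- rowSums(m$counts[[cond_B]]) / m$library_size[[cond_B]] * 1e7
  lfc <- log2((tot_b + pseudocount) / (tot_a + pseudocount))
  cls <- ifelse(lfc <= -cutoff, 1L, ifelse(lfc >= cutoff, 3L, 2L))
  ord <- order(lfc)
  out <- data.frame(
    region = region_ids(m$regions)[ord],
    region_index = ord,
    tags_A = tot_a[ord], tags_B = tot_b[ord],
    log2fc = lfc[ord], class = cls[ord],
    class_label = c("lost", "shared", "gained")[cls[ord]],
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ClassifiedPeakTable", "data.frame")
  out
}

#' Per-group average signal profiles
#'
#' @param m A `SignalMatrix`.
#' @param groups Vector of group labels, one per region (in `m$regions`
#'   order).
#' @param conditions Conditions to profile (default: all).
#' @return Named list (per condition) of group x bin matrices of mean
#'   counts; column names are the bin offsets.
#' @export
average_profile <- function(m, groups, conditions = names(m$counts)) {
  stopifnot(inherits(m, "SignalMatrix"))
  if (length(groups) != length(m$regions))
    stop("groups must label every region")
  if (anyNA(groups)) stop("groups must label every region (NA found)")
  f <- if (is.factor(groups)) groups else factor(groups)
  if (any(table(f) == 0)) stop("empty group")
  out <- lapply(conditions, function(cond) {
    cm <- m$counts[[cond]]
    prof <- t(vapply(levels(f), function(g) {
      colMeans(cm[f == g, , drop = FALSE])
    }, numeric(ncol(cm))))
    colnames(prof) <- m$offsets
    prof
  })
  names(out) <- conditions
  out
}

#' Write a classified peak table as TSV
#' @param x A `ClassifiedPeakTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classified_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
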