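## Interval containers and algebra. Coordinates at the API surface are
## BED-style 0-based half-open; GRanges (1-based closed) is the internal
## representation and the two are converted only here.

#' Build an interval set from BED-style coordinates
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open (BED convention);
#'   requires `0 <= start < end`.
#' @param name Optional labels.
#' @param score Optional numeric scores.
#' @param strand Optional `"+"`/`"-"` (default `"*"`).
#' @param summit Optional integer offset of the summit from `start`;
#'   must satisfy `0 <= summit < end - start`.
#' @param label Set label stored in the metadata.
#' @return A sorted [GenomicRanges::GRanges] with metadata columns
#'   `name`, `score`, `summit` where supplied.
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         strand = NULL, summit = NULL, label = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) && (any(start < 0) || any(start >= end)))
    stop("intervals must satisfy 0 <= start < end")
  if (!is.null(summit)) {
    bad <- !is.na(summit) & (summit < 0 | summit >= end - start)
    if (any(bad)) stop("summit offset must lie within the interval")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = if (is.null(strand)) rep("*", length(chrom)) else strand
  )
  if (!is.null(name)) gr$name <- as.character(name)
  if (!is.null(score)) gr$score <- as.numeric(score)
  if (!is.null(summit)) gr$summit <- as.integer(summit)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Read a BED3/BED6 file, with an optional 7th summit column
#'
#' The first six columns follow the BED standard (chrom, start, end, name,
#' score, strand; 0-based half-open). A 7th integer column, when present,
#' is the summit offset from `start`.
#'
#' @param path File path.
#' @param label Optional set label.
#' @return A [GenomicRanges::GRanges] as from [interval_set()].
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character", quote = "", comment.char = "#")
  nc <- ncol(df)
  interval_set(
    chrom = df[[1]],
    start = as.numeric(df[[2]]),
    end = as.numeric(df[[3]]),
    name = if (nc >= 4) df[[4]] else NULL,
    score = if (nc >= 5) suppressWarnings(as.numeric(df[[5]])) else NULL,
    strand = if (nc >= 6) ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*") else NULL,
    summit = if (nc >= 7) as.integer(df[[7]]) else NULL,
    label = label
  )
}

#' Write an interval set as BED (+ optional summit column)
#'
#' Emits as many of the six standard columns as are needed to carry the
#' metadata present, then the summit offset as a 7th column if stored.
#'
#' @param x A `GRanges` from [interval_set()]/[read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as_bed_frame(x)
  keep <- c(TRUE, TRUE, TRUE,
            "name" %in% names(df), "score" %in% names(df),
            "strand" %in% names(df), "summit" %in% names(df))
  cols <- c("chrom", "start", "end", "name", "score", "strand", "summit")
  have <- intersect(cols, names(df))
  ## BED columns are positional: include everything up to the last present one
  last <- max(match(have, cols))
  out <- lapply(cols[seq_len(last)], function(cl) {
    if (cl %in% names(df)) df[[cl]]
    else if (cl == "name") "."
    else if (cl == "score") 0
    else if (cl == "strand") "."
    else stop("unreachable")
  })
  out <- as.data.frame(out, optional = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a GRanges to a BED-style data frame (0-based half-open)
#' @param x A `GRanges`.
#' @return A data.frame with columns chrom, start, end and any of
#'   name, score, strand, summit.
#' @export
as_bed_frame <- function(x) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1,
    end = GenomicRanges::end(x),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(x)
  if ("name" %in% names(mc)) df$name <- mc$name
  if ("score" %in% names(mc)) df$score <- mc$score
  st <- as.character(GenomicRanges::strand(x))
  if (any(st != "*")) df$strand <- st
  if ("summit" %in% names(mc)) df$summit <- mc$summit
  df
}

#' Reference point of each interval (summit if present, else midpoint)
#'
#' Returns the 0-based genomic coordinate `start + summit` when a summit
#' offset is stored, else `floor((start + end) / 2)` in BED coordinates.
#'
#' @param x A `GRanges`.
#' @return Numeric vector of 0-based coordinates.
#' @export
reference_points <- function(x) {
  s0 <- GenomicRanges::start(x) - 1
  e0 <- GenomicRanges::end(x)
  mid <- floor((s0 + e0) / 2)
  mc <- S4Vectors::mcols(x)
  if ("summit" %in% names(mc)) {
    su <- mc$summit
    ifelse(is.na(su), mid, s0 + su)
  } else mid
}

#' Intersect two interval sets
#'
#' An interval of `a` counts as overlapping when at least one interval of
#' `b` shares at least `min_overlap` bp with it; counts are reported for
#' both directions separately (they differ when set sizes differ).
#'
#' @param a,b `GRanges` interval sets.
#' @param min_overlap Minimum shared bp (default 1).
#' @return A list of class `"overlap_report"`: `pairs` (data.frame of
#'   `a_index`, `b_index`, `overlap_bp`), `n_a_overlapping`,
#'   `n_b_overlapping`, `n_a`, `n_b`, and `intersections` (the intersected
#'   regions as a `GRanges`).
#' @export
intersect_sets <- function(a, b, min_overlap = 1) {
  if (!is.numeric(min_overlap) || length(min_overlap) != 1 || min_overlap < 1)
    stop("min_overlap must be a positive number of bp")
  hits <- suppressWarnings(  # disjoint seqlevel sets are a valid input
    GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap,
                                ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- if (length(qh)) {
    GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(a)[qh], GenomicRanges::ranges(b)[sh]))
  } else integer(0)
  structure(list(
    pairs = data.frame(a_index = qh, b_index = sh, overlap_bp = ov),
    n_a_overlapping = length(unique(qh)),
    n_b_overlapping = length(unique(sh)),
    n_a = length(a), n_b = length(b),
    intersections = {
      ab <- harmonize_seqlevels(a, b)
      GenomicRanges::intersect(ab[[1]], ab[[2]], ignore.strand = TRUE)
    }
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap report: %d/%d a-intervals and %d/%d b-intervals overlap (%d pairs)\n",
              x$n_a_overlapping, x$n_a, x$n_b_overlapping, x$n_b,
              nrow(x$pairs)))
  invisible(x)
}

#' Read a gene annotation table (gene, chrom, tss, strand)
#'
#' @param path 4-column TSV with header `gene  chrom  tss  strand`;
#'   `tss` is the 0-based TSS coordinate.
#' @return A data.frame with those columns; gene symbols must be unique.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("gene annotation needs columns: ", paste(need, collapse = ", "))
  validate_genes(df[need])
}

validate_genes <- function(genes) {
  if (!is.data.frame(genes) || nrow(genes) == 0)
    stop("gene annotation must be a non-empty data.frame")
  if (anyDuplicated(genes$gene)) stop("gene symbols must be unique")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  genes
}

#' Annotate each peak with its nearest gene TSS
#'
#' The peak reference point (summit if stored, else midpoint) is compared
#' with every TSS on the same chromosome; the gene with the smallest
#' absolute distance wins. Ties go to the lower TSS coordinate, then to
#' the lexicographically smaller gene symbol. The signed distance is
#' positive when the reference point lies downstream of the TSS in the
#' gene's reading direction.
#'
#' @param peaks A `GRanges`.
#' @param genes A data.frame with columns gene, chrom, tss, strand.
#' @return A data.frame with one row per peak: `peak` (name or index),
#'   `chrom`, `ref_point`, `gene`, `tss`, `distance`, `unassigned`.
#'   Peaks on chromosomes without genes are flagged unassigned.
#' @export
annotate_nearest_gene <- function(peaks, genes) {
  genes <- validate_genes(genes)
  ref <- reference_points(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  n <- length(peaks)
  out <- data.frame(
    peak = if (!is.null(peaks$name)) peaks$name else seq_len(n),
    chrom = chrom, ref_point = ref,
    gene = NA_character_, tss = NA_real_, distance = NA_real_,
    unassigned = TRUE, stringsAsFactors = FALSE
  )
  ## per tss coordinate only the lexicographically smallest symbol can win
  g <- genes[order(genes$chrom, genes$tss, genes$gene), ]
  g <- g[!duplicated(g[c("chrom", "tss")]), ]
  for (ch in unique(chrom)) {
    gi <- g[g$chrom == ch, ]
    pi <- which(chrom == ch)
    if (nrow(gi) == 0) next
    tss <- gi$tss
    idx <- findInterval(ref[pi], tss)
    left <- pmax(idx, 1); right <- pmin(idx + 1, length(tss))
    dl <- abs(ref[pi] - tss[left]); dr <- abs(ref[pi] - tss[right])
    ## ties between equidistant neighbours go to the lower TSS (the left one)
    use_left <- idx >= 1 & dl <= dr
    pick <- ifelse(use_left, left, right)
    out$gene[pi] <- gi$gene[pick]
    out$tss[pi] <- tss[pick]
    d <- ref[pi] - tss[pick]
    out$distance[pi] <- ifelse(gi$strand[pick] == "+", d, -d)
    out$unassigned[pi] <- FALSE
  }
  out
}

#' Venn category counts for 2-3 labelled sets
#'
#' Items may be character vectors (e.g. gene symbols; membership by
#' identity) or `GRanges` (membership by interval overlap, as in
#' [intersect_sets()]). Each input set is partitioned by its membership
#' signature across all sets, so per-set category counts sum to the set
#' size.
#'
#' @param sets Named list of 2 or 3 character vectors or `GRanges`.
#' @param min_overlap Minimum overlap bp for interval membership.
#' @return A data.frame: one row per category (e.g. `"A"`, `"A&B"`), one
#'   count column per input set.
#' @export
venn_counts <- function(sets, min_overlap = 1) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a named list")
  k <- length(sets)
  if (k < 2 || k > 3) stop("venn_counts supports 2 or 3 sets")
  labels <- names(sets)
  member <- function(items, other) {
    if (is(items, "GRanges")) {
      GenomicRanges::countOverlaps(items, other, minoverlap = min_overlap,
                                   ignore.strand = TRUE) > 0
    } else items %in% other
  }
  ## signature per item of each set
  sigs <- lapply(seq_len(k), function(i) {
    n_i <- set_size(sets[[i]])
    if (n_i == 0) return(character(0))
    m <- vapply(seq_len(k), function(j) {
      if (i == j) rep(TRUE, n_i) else member(sets[[i]], sets[[j]])
    }, logical(n_i))
    m <- matrix(m, ncol = k)
    apply(m, 1, function(r) paste(labels[r], collapse = "&"))
  })
  cats <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(labels, m, paste, collapse = "&")
  }))
  out <- data.frame(category = cats, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    tab <- table(factor(sigs[[i]], levels = cats))
    out[[labels[i]]] <- as.integer(tab)
  }
  out
}

set_size <- function(x) length(x)

harmonize_seqlevels <- function(a, b) {
  ga <- GenomicRanges::granges(a); gb <- GenomicRanges::granges(b)
  sl <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- sl
  GenomeInfoDb::seqlevels(gb) <- sl
  list(ga, gb)
}

#' Hypergeometric significance of an interval-set overlap
#'
#' Tests whether the number of `a` intervals overlapping `b` exceeds what
#' a random draw from a population of `population_size` regions would
#' give: the upper-tail p-value of a hypergeometric with `N =
#' population_size`, `K = |a|`, `n = |b|` at the observed overlap `k`.
#' When `population_size` is not given it defaults to the effective
#' genome length divided by the mean interval width of the union of the
#' two sets, rounded.
#'
#' @param a,b `GRanges` interval sets.
#' @param population_size Population size `N` (optional).
#' @param genome_length Effective genome length in bp, used only to derive
#'   the default `N`.
#' @param min_overlap Minimum overlap bp.
#' @return A list: `p_value`, `overlap` (k), `population_size`, `n_a`, `n_b`.
#' @export
overlap_significance <- function(a, b, population_size = NULL,
                                 genome_length = NULL, min_overlap = 1) {
  rep_ <- intersect_sets(a, b, min_overlap = min_overlap)
  k <- rep_$n_a_overlapping
  if (is.null(population_size)) {
    if (is.null(genome_length))
      stop("either population_size or genome_length must be given")
    ab <- harmonize_seqlevels(a, b)
    u <- GenomicRanges::union(ab[[1]], ab[[2]], ignore.strand = TRUE)
    population_size <- round(genome_length / mean(GenomicRanges::width(u)))
  }
  N <- population_size
  if (N < length(a) + length(b) - k)
    stop("population_size too small for the observed configuration")
  if (N < max(length(a), length(b)))
    stop("population_size must be at least max(|a|, |b|)")
  p <- if (length(a) == 0 || length(b) == 0) 1 else
    stats::phyper(k - 1, length(a), N - length(a), length(b),
                  lower.tail = FALSE)
  list(p_value = min(p, 1), overlap = k, population_size = N,
       n_a = length(a), n_b = length(b))
}
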