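## Bootstrap Z-score co-occurrence of footprinted motifs: the observed
## count of motif-pair instances within a bp window among hits occupied
## by foreground footprints, referenced against repeated equally sized
## without-replacement subsamples of background regions.

#' Motif co-occurrence Z-scores over a bootstrap resampling null
#'
#' A motif hit is "occupied" by a region set when its match overlaps at
#' least one interval of the set. The observed statistic for a motif pair
#' (A, B) is the number of occupied A-hit/B-hit pairs whose match centers
#' lie within `window` bp of each other (for A = B, unordered pairs). The
#' null distribution is obtained by drawing `n_subsamples` times, without
#' replacement, as many background regions as there are foreground
#' footprints, and recomputing the pair count among hits occupied by the
#' drawn regions. `z = (observed - mean) / sd` of the null counts; when
#' the null counts are constant, `z = 0` if the observation equals them
#' and `+/-Inf` otherwise.
#'
#' @param fg_footprints `GRanges` of foreground footprint intervals.
#' @param bg_regions `GRanges` of background regions; must contain at
#'   least as many intervals as `fg_footprints`.
#' @param hits Named list (per motif) of hit data.frames (columns
#'   `chrom`, `start`, `end`, ...) as from [scan_sequence()] or planted
#'   instances.
#' @param window Center-to-center distance cutoff in bp (default 50).
#' @param n_subsamples Number of background subsamples (default 1000,
#'   minimum 2).
#' @param seed Integer seed governing the subsampling.
#' @return An object of class `"cooccurrence"`: symmetric matrices `z`,
#'   `observed`, `bg_mean`, `bg_sd` (motif x motif), the clustered motif
#'   `ordering` (average-linkage hierarchical clustering of the z matrix,
#'   Euclidean distance), and the call parameters.
#' @export
cooccurrence_zscores <- function(fg_footprints, bg_regions, hits,
                                 window = 50, n_subsamples = 1000,
                                 seed = 1) {
  if (length(fg_footprints) == 0) stop("empty foreground footprint set")
  if (length(bg_regions) < length(fg_footprints))
    stop("background must contain at least as many regions as the foreground")
  if (!is.numeric(n_subsamples) || n_subsamples < 2)
    stop("n_subsamples must be >= 2")
  if (!is.list(hits) || is.null(names(hits)) || length(hits) < 1)
    stop("hits must be a non-empty named list")
  motifs <- names(hits)
  all_hits <- do.call(rbind, lapply(motifs, function(m) {
    h <- hits[[m]]
    if (is.null(h) || nrow(h) == 0) return(NULL)
    data.frame(motif = m, chrom = h$chrom,
               center = (h$start + h$end) / 2,
               start = h$start, end = h$end, stringsAsFactors = FALSE)
  }))
  k <- length(motifs)
  zeros <- matrix(0, k, k, dimnames = list(motifs, motifs))
  if (is.null(all_hits))
    return(new_cooccurrence(zeros, zeros, zeros, zeros, motifs,
                            window, n_subsamples))
  hgr <- GenomicRanges::GRanges(all_hits$chrom,
                                IRanges::IRanges(all_hits$start + 1,
                                                 all_hits$end))
  ## foreground occupancy
  fg_occ <- GenomicRanges::countOverlaps(hgr, fg_footprints,
                                         ignore.strand = TRUE) > 0
  ## hit -> background-region incidence (sparse)
  ov <- GenomicRanges::findOverlaps(hgr, bg_regions, ignore.strand = TRUE)
  M <- Matrix::sparseMatrix(i = S4Vectors::queryHits(ov),
                            j = S4Vectors::subjectHits(ov),
                            x = 1,
                            dims = c(nrow(all_hits), length(bg_regions)))
  ## subsample indicator matrix
  set.seed(seed)
  nfg <- length(fg_footprints)
  draw_idx <- replicate(n_subsamples, sample.int(length(bg_regions), nfg),
                        simplify = FALSE)
  IND <- Matrix::sparseMatrix(
    i = unlist(draw_idx),
    j = rep(seq_len(n_subsamples), each = nfg),
    x = 1, dims = c(length(bg_regions), n_subsamples))
  OCC <- as.matrix(M %*% IND) > 0  # hits x draws occupancy
  bg_capable <- Matrix::rowSums(M) > 0

  ## candidate within-window hit pairs per motif pair, among hits that can
  ## ever be occupied (fg- or bg-side)
  pair_idx <- function(ia_all, ib_all, same) {
    ## ia_all/ib_all: global hit indices, same chromosome handled inside
    res_a <- integer(0); res_b <- integer(0)
    for (ch in unique(all_hits$chrom[c(ia_all, ib_all)])) {
      ia <- ia_all[all_hits$chrom[ia_all] == ch]
      ib <- ib_all[all_hits$chrom[ib_all] == ch]
      if (!length(ia) || !length(ib)) next
      ca <- all_hits$center[ia]; cb <- all_hits$center[ib]
      ob <- order(cb); ib <- ib[ob]; cb <- cb[ob]
      lo <- findInterval(ca - window - 1e-9, cb) + 1
      hi <- findInterval(ca + window + 1e-9, cb)
      n_each <- pmax(hi - lo + 1, 0)
      if (sum(n_each) == 0) next
      aa <- rep(ia, n_each)
      bb <- ib[sequence(nvec = n_each, from = lo)]
      if (same) { keep <- aa < bb; aa <- aa[keep]; bb <- bb[keep] }
      res_a <- c(res_a, aa); res_b <- c(res_b, bb)
    }
    list(a = res_a, b = res_b)
  }

  obs <- zeros; mu <- zeros; sdev <- zeros; z <- zeros
  hit_by_motif <- split(seq_len(nrow(all_hits)), all_hits$motif)
  for (i in seq_len(k)) for (j in i:k) {
    ia_all <- hit_by_motif[[motifs[i]]]
    ib_all <- hit_by_motif[[motifs[j]]]
    if (is.null(ia_all) || is.null(ib_all)) { next }
    ## observed: pairs among fg-occupied hits
    po <- pair_idx(ia_all[fg_occ[ia_all]], ib_all[fg_occ[ib_all]], i == j)
    obs[i, j] <- obs[j, i] <- length(po$a)
    ## null: pairs among bg-capable hits, counted per draw
    pb <- pair_idx(ia_all[bg_capable[ia_all]], ib_all[bg_capable[ib_all]],
                   i == j)
    if (length(pb$a)) {
      cnt <- Matrix::colSums(OCC[pb$a, , drop = FALSE] &
                               OCC[pb$b, , drop = FALSE])
    } else cnt <- numeric(n_subsamples)
    mu[i, j] <- mu[j, i] <- mean(cnt)
    sdev[i, j] <- sdev[j, i] <- stats::sd(cnt)
    zij <- if (sdev[i, j] == 0) {
      if (obs[i, j] == mu[i, j]) 0 else sign(obs[i, j] - mu[i, j]) * Inf
    } else (obs[i, j] - mu[i, j]) / sdev[i, j]
    z[i, j] <- z[j, i] <- zij
  }
  new_cooccurrence(z, obs, mu, sdev, motifs, window, n_subsamples)
}

new_cooccurrence <- function(z, obs, mu, sdev, motifs, window, n_subsamples) {
  ordering <- if (length(motifs) > 2) {
    zc <- z
    fin <- zc[is.finite(zc)]
    cap <- if (length(fin)) max(abs(fin), 1) * 2 else 1
    zc[!is.finite(zc)] <- sign(zc[!is.finite(zc)]) * cap
    stats::hclust(stats::dist(zc), method = "average")$order
  } else seq_along(motifs)
  structure(list(z = z, observed = obs, bg_mean = mu, bg_sd = sdev,
                 motifs = motifs, ordering = ordering, window = window,
                 n_subsamples = n_subsamples),
            class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat(sprintf("motif co-occurrence: %d motifs, window %d bp, %d subsamples\n",
              length(x$motifs), x$window, x$n_subsamples))
  off <- x$z[upper.tri(x$z, diag = TRUE)]
  top <- which(x$z == max(off), arr.ind = TRUE)[1, ]
  cat(sprintf("top pair: %s-%s (z = %.2f)\n",
              x$motifs[top[1]], x$motifs[top[2]], max(off)))
  invisible(x)
}

#' Write the co-occurrence z matrix as TSV
#' @param x A `cooccurrence` object.
#' @param path Output path.
#' @param clustered Reorder rows/columns by the clustering (default TRUE).
#' @return `path`, invisibly.
#' @export
write_zmatrix <- function(x, path, clustered = TRUE) {
  z <- x$z
  if (clustered) z <- z[x$ordering, x$ordering]
  write.table(data.frame(motif = rownames(z), z, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
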