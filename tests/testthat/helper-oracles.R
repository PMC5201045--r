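# Brute-force oracles and tiny fixture builders shared across tests.
# Oracles are deliberately naive (all-pairs loops, exhaustive window
# scoring, pmf enumeration) and independent of the package internals.

bf_overlap_report <- function(a, b, min_overlap = 1) {
  adf <- as_bed_frame(a); bdf <- as_bed_frame(b)
  hit_a <- logical(nrow(adf)); hit_b <- logical(nrow(bdf)); pairs <- 0L
  for (i in seq_len(nrow(adf))) for (j in seq_len(nrow(bdf))) {
    if (adf$chrom[i] != bdf$chrom[j]) next
    ov <- min(adf$end[i], bdf$end[j]) - max(adf$start[i], bdf$start[j])
    if (ov >= min_overlap) {
      hit_a[i] <- TRUE; hit_b[j] <- TRUE; pairs <- pairs + 1L
    }
  }
  list(n_a = sum(hit_a), n_b = sum(hit_b), n_pairs = pairs)
}

bf_nearest <- function(peaks, genes) {
  ref <- reference_points(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  out <- character(length(peaks))
  for (i in seq_along(peaks)) {
    g <- genes[genes$chrom == chrom[i], ]
    if (nrow(g) == 0) { out[i] <- NA_character_; next }
    d <- abs(ref[i] - g$tss)
    g <- g[order(d, g$tss, g$gene), ]
    out[i] <- g$gene[1]
  }
  out
}

bf_scan <- function(seq, pwm, threshold) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- pwm$width
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cut <- threshold * pwm$max_score
  hits <- list()
  for (i in seq_len(length(chars) - L + 1)) {
    win <- chars[i:(i + L - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    sp <- sum(vapply(seq_len(L),
                     function(j) pwm$log_odds[win[j], j], 0))
    rcwin <- rev(unname(comp[win]))
    sm <- sum(vapply(seq_len(L),
                     function(j) pwm$log_odds[rcwin[j], j], 0))
    if (sp >= cut)
      hits[[length(hits) + 1]] <- data.frame(start = i - 1, strand = "+",
                                             score = sp)
    if (sm >= cut)
      hits[[length(hits) + 1]] <- data.frame(start = i - 1, strand = "-",
                                             score = sm)
  }
  if (!length(hits))
    return(data.frame(start = numeric(0), strand = character(0),
                      score = numeric(0)))
  df <- do.call(rbind, hits)
  df[order(df$start, df$strand), , drop = FALSE]
}

bf_hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

rand_intervals <- function(n, chroms = c("cA", "cB"), span = 2000,
                           max_w = 60, summit = FALSE) {
  start <- sample.int(span, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  interval_set(chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + w,
               name = sprintf("iv%03d", seq_len(n)),
               summit = if (summit) pmin(w - 1, sample.int(max_w, n,
                                                           replace = TRUE) - 1))
}

rand_pwm <- function(width = 5, name = "rnd") {
  pwm_from_counts(matrix(sample(0:20, 4 * width, replace = TRUE), 4, width),
                  name = name)
}

rand_seq <- function(len, n_prob = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = "")
}

## small, fast landscape spec for unit tests
small_spec <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 2, chrom_length = 2e5,
         n_peaks = 100, n_genes = 40,
         n_footprints_fg = 60, n_footprints_bg = 400,
         region_width = 200, n_extra_motifs = 3),
    list(...))
  do.call(landscape_spec, args)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
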