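## Position weight matrices, log-odds scanning on both strands, and
## motif-presence matrices over regions.

DNA <- c("A", "C", "G", "T")

#' Build a PWM with log-odds scores from a count matrix
#'
#' Column probabilities are `(count + pseudocount) / (colsum + 4 *
#' pseudocount)` and log-odds are `log2(prob / background)` in bits.
#'
#' @param counts 4 x L non-negative matrix with rows A, C, G, T (rownames
#'   optional, assumed in that order otherwise).
#' @param name Motif name.
#' @param background Background base probabilities (length 4, sums to 1;
#'   default uniform).
#' @param pseudocount Added to every count (default 1).
#' @return An object of class `"pwm"`: `name`, `counts`, `background`,
#'   `pseudocount`, `log_odds` (4 x L, bits), `width`, `max_score`,
#'   `consensus`.
#' @export
pwm_from_counts <- function(counts, name = "motif",
                            background = rep(0.25, 4), pseudocount = 1.0) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 || ncol(counts) < 1)
    stop("counts must be a 4 x L matrix (rows A, C, G, T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0))
    stop("background must be 4 positive probabilities summing to 1")
  if (pseudocount == 0 && any(colSums(counts) == 0))
    stop("all-zero column with pseudocount 0")
  rownames(counts) <- DNA
  cs <- colSums(counts) + 4 * pseudocount
  probs <- sweep(counts + pseudocount, 2, cs, "/")
  lo <- log2(probs / background)
  if (any(!is.finite(lo))) stop("log-odds not finite; increase pseudocount")
  structure(list(
    name = name, counts = counts, background = background,
    pseudocount = pseudocount, log_odds = lo, width = ncol(counts),
    max_score = sum(apply(lo, 2, max)),
    consensus = paste(DNA[apply(counts, 2, which.max)], collapse = "")
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: width %d, consensus %s, max score %.2f bits\n",
              x$name, x$width, x$consensus, x$max_score))
  invisible(x)
}

#' Read PWMs from a JASPAR-style count file
#'
#' Records start with `>name`; the following four lines are the A, C, G,
#' T count rows, with or without the JASPAR `A [ ... ]` brackets.
#'
#' @param path File path.
#' @param ... Passed to [pwm_from_counts()] (background, pseudocount).
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no '>' records in ", path)
  out <- lapply(starts, function(s) {
    nm <- sub("^>\\s*", "", lines[s])
    nm <- strsplit(nm, "\\s+")[[1]]
    nm <- nm[length(nm)]  # JASPAR: ">MAxxxx.1 NAME" -> NAME
    rows <- lapply(lines[(s + 1):(s + 4)], function(r) {
      r <- gsub("^[ACGTacgt]\\s*\\[?", "", r)
      r <- gsub("\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("ragged count rows in ", path)
    pwm_from_counts(do.call(rbind, rows), name = nm, ...)
  })
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

#' Write PWM count matrices in JASPAR format
#' @param pwms Named list of `pwm` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (i in 1:4)
      writeLines(sprintf("%s [ %s ]", DNA[i],
                         paste(format(p$counts[i, ], trim = TRUE), collapse = " ")),
                 con)
  }
  invisible(path)
}

seq_to_code <- function(seq) {
  v <- strsplit(toupper(as.character(seq)), "")[[1]]
  match(v, DNA)  # N and anything else -> NA
}

revcomp_pwm_matrix <- function(lo) {
  lo[4:1, ncol(lo):1, drop = FALSE]
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window scoring at least `threshold * max_score` is reported.
#' Windows containing non-ACGT characters are skipped. Reverse-strand
#' hits are scored with the reverse-complement matrix and reported at
#' their plus-strand leftmost coordinate with strand `"-"`.
#'
#' @param seq DNA sequence (character or `DNAString`).
#' @param pwm A `pwm` object.
#' @param threshold Fraction of the maximum attainable score in (0, 1]
#'   (default 0.8).
#' @param chrom Chromosome name recorded in the hits (default `"seq"`).
#' @param offset Added to all reported start coordinates (0-based; use
#'   when `seq` is a sub-sequence of a chromosome).
#' @return A data.frame of hits: `chrom`, `start` (0-based leftmost),
#'   `end` (`start + width`), `motif`, `strand`, `score` (bits).
#' @export
scan_sequence <- function(seq, pwm, threshold = 0.8, chrom = "seq",
                          offset = 0) {
  stopifnot(inherits(pwm, "pwm"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  code <- seq_to_code(seq)
  L <- pwm$width
  nw <- length(code) - L + 1
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), motif = character(0),
                      strand = character(0), score = numeric(0))
  if (nw < 1) return(empty)
  cut <- threshold * pwm$max_score
  score_with <- function(lo) {
    s <- numeric(nw)
    for (j in seq_len(L)) s <- s + lo[code[j:(j + nw - 1)], j]
    s  # NA wherever the window contains a non-ACGT base
  }
  sp <- score_with(pwm$log_odds)
  sm <- score_with(revcomp_pwm_matrix(pwm$log_odds))
  hp <- which(!is.na(sp) & sp >= cut)
  hm <- which(!is.na(sm) & sm >= cut)
  nh <- length(hp) + length(hm)
  out <- data.frame(
    chrom = rep(chrom, nh),
    start = c(hp, hm) - 1 + offset,
    end = c(hp, hm) - 1 + offset + L,
    motif = rep(pwm$name, nh),
    strand = rep(c("+", "-"), c(length(hp), length(hm))),
    score = c(sp[hp], sm[hm]),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a whole genome (or any set of named sequences) with several PWMs
#'
#' @param genome A named `DNAStringSet` (e.g. from
#'   [Biostrings::readDNAStringSet()]) or named character vector.
#' @param pwms Named list of `pwm` objects.
#' @param threshold Passed to [scan_sequence()].
#' @return Named list (per motif) of hit data.frames.
#' @export
scan_genome <- function(genome, pwms, threshold = 0.8) {
  if (inherits(pwms, "pwm")) pwms <- setNames(list(pwms), pwms$name)
  chroms <- names(genome)
  if (is.null(chroms)) stop("genome sequences must be named")
  out <- lapply(pwms, function(p) {
    do.call(rbind, lapply(chroms, function(ch) {
      scan_sequence(genome[[ch]], p, threshold = threshold, chrom = ch)
    }))
  })
  names(out) <- vapply(pwms, function(p) p$name, character(1))
  out
}

hits_to_granges <- function(hits) {
  GenomicRanges::GRanges(hits$chrom,
                         IRanges::IRanges(start = hits$start + 1,
                                          end = hits$end),
                         strand = if (!is.null(hits$strand)) hits$strand else "*")
}

#' Motif presence matrix over regions
#'
#' A cell is `TRUE` when at least one hit of that motif lies entirely
#' inside the region (a match flush with the region edge counts).
#'
#' @param regions A `GRanges`.
#' @param hits Named list (per motif) of hit data.frames as from
#'   [scan_sequence()].
#' @return Logical regions x motifs matrix.
#' @export
motif_presence_matrix <- function(regions, hits) {
  if (!is.list(hits) || is.null(names(hits)))
    stop("hits must be a named list of hit tables")
  m <- vapply(names(hits), function(nm) {
    h <- hits[[nm]]
    if (is.null(h) || nrow(h) == 0) return(rep(FALSE, length(regions)))
    gr <- hits_to_granges(h)
    ov <- GenomicRanges::findOverlaps(gr, regions, type = "within",
                                      ignore.strand = TRUE)
    tabulate(S4Vectors::subjectHits(ov), length(regions)) > 0
  }, logical(length(regions)))
  m <- matrix(m, nrow = length(regions),
              dimnames = list(region_ids(regions), names(hits)))
  m
}

#' Write motif hits as BED6
#'
#' Name carries the motif, score is bits x 100 rounded.
#'
#' @param hits A hit data.frame or named list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  if (is.data.frame(hits)) hits <- list(hits)
  df <- do.call(rbind, hits)
  out <- data.frame(df$chrom, df$start, df$end, df$motif,
                    round(df$score * 100), df$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motif hits back from BED6 (as written by [write_hits_bed()])
#' @param path File path.
#' @return Named list (per motif) of hit data.frames; scores in bits.
#' @export
read_hits_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  h <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                  motif = df[[4]], strand = df[[6]], score = df[[5]] / 100,
                  stringsAsFactors = FALSE)
  split(h, h$motif)
}
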