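## Expression integration: twofold differential filters, k-means
## fold-change clustering and per-peak-class expression statistics.

#' Read a log2 expression matrix and its sample metadata
#'
#' @param expr_path TSV, first column `gene`, remaining columns one per
#'   sample (log2 scale), header row of sample IDs.
#' @param meta_path Optional TSV mapping `sample` to `stage`, `condition`,
#'   `replicate`.
#' @return A list of class `"ExpressionSet2"`: `values` (genes x samples
#'   numeric matrix) and `meta` (data.frame or NULL).
#' @export
read_expression <- function(expr_path, meta_path = NULL) {
  if (!file.exists(expr_path)) stop("file not found: ", expr_path)
  df <- read.table(expr_path, sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  if (!is.numeric(vals)) stop("expression values must be numeric")
  if (any(!is.finite(vals))) stop("expression values must be finite")
  meta <- NULL
  if (!is.null(meta_path)) {
    if (!file.exists(meta_path)) stop("file not found: ", meta_path)
    meta <- read.table(meta_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    if (!all(colnames(vals) %in% meta$sample))
      stop("metadata must describe every sample")
  }
  structure(list(values = vals, meta = meta), class = "ExpressionSet2")
}

#' Mean log2 fold change per gene for a two-group contrast
#'
#' Replicates are averaged (arithmetic mean of log2 values) per side
#' before subtracting; the result is `mean(B) - mean(A)` per gene.
#'
#' @param values Genes x samples log2 matrix.
#' @param samples_A,samples_B Column names of the two sides (A is the
#'   reference, e.g. untreated).
#' @return Named numeric vector of log2 fold changes.
#' @export
contrast_log2fc <- function(values, samples_A, samples_B) {
  miss <- setdiff(c(samples_A, samples_B), colnames(values))
  if (length(miss)) stop("samples not in matrix: ", paste(miss, collapse = ", "))
  rowMeans(values[, samples_B, drop = FALSE]) -
    rowMeans(values[, samples_A, drop = FALSE])
}

#' Differentially expressed gene sets at an n-fold threshold
#'
#' A gene is "up" when its mean log2 fold change is at least
#' `log2(threshold_fold)` (inclusive — "at least n-fold") and "down" when
#' at most the negative of that. With several contrasts, a cross-contrast
#' overlap table counts how many up/down genes of each contrast are also
#' up/down in every other.
#'
#' @param values Genes x samples log2 matrix.
#' @param contrasts Named list of contrasts, each
#'   `list(A = <sample ids>, B = <sample ids>)`.
#' @param threshold_fold Fold-change threshold (> 1; default 2).
#' @return A list of class `"diff_genes"`: per contrast `log2fc`, `up`,
#'   `down`; plus `up_overlap` and `down_overlap` square count matrices
#'   (diagonal = set sizes).
#' @export
diff_genes <- function(values, contrasts, threshold_fold = 2.0) {
  if (!is.numeric(threshold_fold) || threshold_fold <= 1)
    stop("threshold_fold must be > 1")
  if (!is.list(contrasts[[1]])) contrasts <- list(contrast = contrasts)
  if (is.null(names(contrasts))) names(contrasts) <- paste0("c", seq_along(contrasts))
  thr <- log2(threshold_fold)
  per <- lapply(contrasts, function(ct) {
    lfc <- contrast_log2fc(values, ct$A, ct$B)
    list(log2fc = lfc,
         up = names(lfc)[lfc >= thr],
         down = names(lfc)[lfc <= -thr])
  })
  nms <- names(contrasts)
  ov <- function(field) {
    m <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
    for (i in nms) for (j in nms)
      m[i, j] <- length(intersect(per[[i]][[field]], per[[j]][[field]]))
    m
  }
  structure(list(contrasts = per, threshold_fold = threshold_fold,
                 up_overlap = ov("up"), down_overlap = ov("down")),
            class = "diff_genes")
}

#' K-means clustering of gene profiles
#'
#' Lloyd's algorithm with Euclidean distance, best of `n_restarts`
#' random starts by total within-cluster sum of squares; deterministic
#' given `seed`. `distance = "correlation"` standardises each row
#' (center, unit variance) first, so Euclidean distance becomes
#' equivalent to centered-correlation distance up to a monotone
#' transform.
#'
#' @param values Genes x features numeric matrix.
#' @param k Number of clusters (1 <= k <= genes).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 10).
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @return A list of class `"gene_clusters"`: `cluster` (named integer
#'   vector), `centers` (k x features), `tot_withinss`, `k`, `sizes`.
#' @export
kmeans_cluster <- function(values, k, seed = 1, n_restarts = 10,
                           distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  values <- as.matrix(values)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(values)) stop("k must not exceed the number of genes")
  x <- values
  if (distance == "correlation") {
    mu <- rowMeans(x); s <- apply(x, 1, stats::sd)
    s[s == 0] <- 1
    x <- (x - mu) / s
  }
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_restarts,
                  algorithm = "Lloyd", iter.max = 200))
  structure(list(cluster = stats::setNames(km$cluster, rownames(values)),
                 centers = km$centers, tot_withinss = km$tot.withinss,
                 k = k, sizes = km$size, distance = distance),
            class = "gene_clusters")
}

#' Per-peak-class expression fold-change statistics
#'
#' Summarises the expression log2 fold change of the genes linked to each
#' peak class (median and quartiles) and tests each class against the
#' pooled remaining genes with a two-sided Wilcoxon rank-sum test (exact
#' when both group sizes are at most 12, normal approximation above).
#' Classes with fewer than 3 genes are excluded with a warning.
#'
#' @param gene_classes Named vector (gene -> class label).
#' @param log2fc Named numeric vector (gene -> log2 fold change).
#' @return A data.frame of class `"class_expression"`: `class`, `n`,
#'   `median`, `q1`, `q3`, `p_value` (class vs pooled rest). Attribute
#'   `excluded` lists dropped classes.
#' @export
class_expression_test <- function(gene_classes, log2fc) {
  genes <- intersect(names(gene_classes), names(log2fc))
  if (length(genes) == 0) stop("no genes shared between classes and fold changes")
  cls <- gene_classes[genes]; fc <- log2fc[genes]
  tab <- table(cls)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("classes excluded (fewer than 3 genes): ",
            paste(small, collapse = ", "))
    keep <- !(cls %in% small)
    cls <- cls[keep]; fc <- fc[keep]
  }
  levs <- sort(unique(as.character(cls)))
  if (length(levs) < 2) stop("need at least 2 classes with >= 3 genes each")
  out <- do.call(rbind, lapply(levs, function(cl) {
    x <- fc[cls == cl]; y <- fc[cls != cl]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    exact <- length(x) <= 12 && length(y) <= 12
    p <- stats::wilcox.test(x, y, alternative = "two.sided",
                            exact = exact, correct = !exact)$p.value
    data.frame(class = cl, n = length(x), median = q[2], q1 = q[1],
               q3 = q[3], p_value = p, stringsAsFactors = FALSE)
  }))
  attr(out, "excluded") <- small
  class(out) <- c("class_expression", "data.frame")
  out
}
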