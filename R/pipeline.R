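## Config-driven orchestration: simulate -> classify -> annotate -> scan
## -> cooccur -> spacing -> cluster-expr -> report, with a run log.

#' Analysis configuration with the pipeline's default constants
#'
#' Defaults carry the analysis constants: +/-1000 bp summit windows,
#' +/-1 log2 class cutoffs, a 50 bp co-occurrence window, 1000
#' background subsamples, an at-least-twofold expression filter, and 7
#' (bound-gene) / 15 (differential-gene) k-means clusters. Each entry
#' records whether it is a published constant or a package convention
#' (see [show_defaults()]).
#'
#' @param ... Overrides of any default field (unknown fields are an
#'   error). Fields: `flank`, `bin_width`, `class_cutoff`,
#'   `pseudocount`, `cooccur_window`, `n_subsamples`, `scan_threshold`,
#'   `diff_threshold_fold`, `kmeans_k_bound`, `kmeans_k_diff`,
#'   `spacing_anchor` (`"end_to_start"`/`"start_to_start"`),
#'   `spacing_max_dist`, `anchor_motif`, `partner_motif`, `seed`,
#'   `outdir`.
#' @return A validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    flank = 1000, bin_width = 50, class_cutoff = 1.0, pseudocount = 1.0,
    cooccur_window = 50, n_subsamples = 1000, scan_threshold = 0.8,
    diff_threshold_fold = 2.0, kmeans_k_bound = 7, kmeans_k_diff = 15,
    spacing_anchor = "end_to_start", spacing_max_dist = 100,
    anchor_motif = "TEAD", partner_motif = "AP1",
    seed = 1, outdir = "peakgrammar_out"
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, dots)
  num <- c("flank", "bin_width", "class_cutoff", "cooccur_window",
           "n_subsamples", "scan_threshold", "diff_threshold_fold",
           "kmeans_k_bound", "kmeans_k_diff", "spacing_max_dist")
  for (f in num) {
    cfg[[f]] <- as.numeric(cfg[[f]])
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field must be positive: ", f)
  }
  if (!cfg$spacing_anchor %in% c("end_to_start", "start_to_start"))
    stop("config field spacing_anchor must be end_to_start or start_to_start")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "analysis_config")
}

#' Default parameters with their provenance
#' @return Data.frame of field, default, provenance ("published constant"
#'   vs "package convention").
#' @export
show_defaults <- function() {
  data.frame(
    field = c("flank", "bin_width", "class_cutoff", "pseudocount",
              "cooccur_window", "n_subsamples", "scan_threshold",
              "diff_threshold_fold", "kmeans_k_bound", "kmeans_k_diff",
              "spacing_anchor", "spacing_max_dist"),
    default = c("1000", "50", "1.0", "1.0", "50", "1000", "0.8", "2.0",
                "7", "15", "end_to_start", "100"),
    provenance = c("published constant", "package convention",
                   "published constant", "package convention",
                   "published constant", "published constant",
                   "package convention", "published constant",
                   "published constant", "published constant",
                   "published constant", "package convention"),
    stringsAsFactors = FALSE)
}

#' Read a flat key=value config file
#'
#' Lines are `key = value`; `[section]` headers group visually and are
#' ignored; `#` starts a comment.
#'
#' @param path File path.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("cannot parse config line: ", lines[bad][1])
  vals <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  do.call(analysis_config, vals)
}

log_line <- function(outdir, ...) {
  cat(sprintf(...), "\n", sep = "",
      file = file.path(outdir, "pipeline.log"), append = TRUE)
}

need_file <- function(path, what) {
  if (!file.exists(path))
    stop("missing input for this stage: ", what, " (", path, ")")
  path
}

#' Run the analysis pipeline
#'
#' `mode = "simulate"` writes a synthetic landscape with ground truth
#' into `config$outdir`; the analysis modes read their inputs from that
#' directory (or from files written by earlier runs) and write TSV/BED
#' outputs plus a log of parameters, input checksums and counts.
#' `"report"` aggregates class counts and fractions, the top
#' co-occurring pairs, the spacing mode and per-class expression
#' medians. `"all"` runs every stage in order.
#'
#' @param config An [analysis_config()].
#' @param mode One of `"simulate"`, `"classify"`, `"annotate"`,
#'   `"scan"`, `"cooccur"`, `"spacing"`, `"cluster-expr"`, `"report"`,
#'   `"all"`.
#' @param spec Optional [landscape_spec()] for `"simulate"` (default:
#'   `landscape_spec(seed = config$seed)`).
#' @return The output directory, invisibly. Mode `"report"` returns the
#'   report list.
#' @export
run_pipeline <- function(config = analysis_config(),
                         mode = c("all", "simulate", "classify", "annotate",
                                  "scan", "cooccur", "spacing",
                                  "cluster-expr", "report"),
                         spec = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  mode <- match.arg(mode)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out, f)
  if (mode %in% c("all", "simulate")) {
    if (is.null(spec)) spec <- landscape_spec(seed = config$seed)
    sim <- simulate_regulatory_landscape(spec)
    sim <- simulate_footprints(spec, sim)
    sim <- simulate_expression(spec, sim)
    write_landscape(sim, out)
    log_line(out, "simulate: seed=%d peaks=%d fg=%d bg=%d genes=%d",
             spec$seed, length(sim$peaks), length(sim$fg_footprints),
             length(sim$bg_regions), nrow(sim$genes))
    log_line(out, "simulate: md5 peaks.bed=%s",
             unname(tools::md5sum(p("peaks.bed"))))
  }
  steps <- if (mode == "all")
    c("classify", "annotate", "scan", "cooccur", "spacing",
      "cluster-expr", "report") else mode
  res <- NULL
  for (step in setdiff(steps, c("simulate"))) {
    res <- switch(step,
      "classify" = stage_classify(config, p, out),
      "annotate" = stage_annotate(config, p, out),
      "scan" = stage_scan(config, p, out),
      "cooccur" = stage_cooccur(config, p, out),
      "spacing" = stage_spacing(config, p, out),
      "cluster-expr" = stage_cluster_expr(config, p, out),
      "report" = stage_report(config, p, out))
  }
  if (mode == "report") res else invisible(out)
}

stage_classify <- function(config, p, out) {
  peaks <- read_bed(need_file(p("peaks.bed"), "peak BED"))
  tags <- list(untreated = read_tags(need_file(p("tags_untreated.tsv"),
                                               "untreated tags")),
               dox = read_tags(need_file(p("tags_dox.tsv"), "treated tags")))
  m <- summit_matrix(peaks, tags, flank = config$flank,
                     bin_width = config$bin_width)
  tab <- fold_change_classify(m, "untreated", "dox",
                              cutoff = config$class_cutoff,
                              pseudocount = config$pseudocount)
  write_classified_table(tab, p("classified_peaks.tsv"))
  prof <- average_profile(m, tab$class_label[order(tab$region_index)])
  for (cond in names(prof))
    write.table(data.frame(class = rownames(prof[[cond]]), prof[[cond]],
                           check.names = FALSE),
                p(sprintf("profiles_%s.tsv", cond)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  log_line(out, "classify: n=%d lost=%d shared=%d gained=%d",
           nrow(tab), sum(tab$class == 1), sum(tab$class == 2),
           sum(tab$class == 3))
  invisible(tab)
}

stage_annotate <- function(config, p, out) {
  peaks <- read_bed(need_file(p("peaks.bed"), "peak BED"))
  genes <- read_gene_annotation(need_file(p("genes.tsv"), "gene annotation"))
  ann <- annotate_nearest_gene(peaks, genes)
  write.table(ann, p("peak_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_line(out, "annotate: %d peaks, %d unassigned", nrow(ann),
           sum(ann$unassigned))
  invisible(ann)
}

stage_scan <- function(config, p, out) {
  genome <- Biostrings::readDNAStringSet(need_file(p("genome.fa"), "genome FASTA"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  pwms <- read_jaspar(need_file(p("pwms.jaspar"), "PWM file"))
  core <- pwms[intersect(c(config$anchor_motif, config$partner_motif),
                         names(pwms))]
  hits <- scan_genome(genome, core, threshold = config$scan_threshold)
  write_hits_bed(hits, p("scanned_hits.bed"))
  peaks <- read_bed(need_file(p("peaks.bed"), "peak BED"))
  pres <- motif_presence_matrix(peaks, hits)
  write.table(data.frame(region = rownames(pres), pres, check.names = FALSE),
              p("motif_presence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_line(out, "scan: %s", paste(sprintf("%s=%d", names(hits),
                                          vapply(hits, nrow, 1L)),
                                  collapse = " "))
  invisible(hits)
}

stage_cooccur <- function(config, p, out) {
  fg <- read_bed(need_file(p("fg_footprints.bed"), "footprint BED"))
  bg <- read_bed(need_file(p("bg_regions.bed"), "background-region BED"))
  hits <- read_hits_bed(need_file(p("motif_instances.bed"),
                                  "motif instance BED"))
  cc <- cooccurrence_zscores(fg, bg, hits, window = config$cooccur_window,
                             n_subsamples = config$n_subsamples,
                             seed = config$seed)
  write_zmatrix(cc, p("cooccurrence_z.tsv"))
  log_line(out, "cooccur: %d motifs, window=%d, subsamples=%d",
           length(cc$motifs), config$cooccur_window, config$n_subsamples)
  invisible(cc)
}

stage_spacing <- function(config, p, out) {
  hits <- read_hits_bed(need_file(p("motif_instances.bed"),
                                  "motif instance BED"))
  fg <- read_bed(need_file(p("fg_footprints.bed"), "footprint BED"))
  occ <- filter_occupied(hits, fg)
  a <- occ[[config$anchor_motif]]; b <- occ[[config$partner_motif]]
  if (is.null(a) || is.null(b))
    stop("missing input for this stage: anchor/partner motif hits (",
         config$anchor_motif, "/", config$partner_motif, ")")
  sp <- spacing_distribution(a, b, max_dist = config$spacing_max_dist,
                             convention = config$spacing_anchor)
  write.table(data.frame(distance = names(sp$counts), count = sp$counts,
                         row.names = NULL),
              p("spacing_histogram.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_line(out, "spacing: n_pairs=%d mode=%s", sp$n_pairs,
           if (sp$mode_defined) sp$mode else "undefined")
  invisible(sp)
}

stage_cluster_expr <- function(config, p, out) {
  ex <- read_expression(need_file(p("expression.tsv"), "expression TSV"),
                        need_file(p("sample_metadata.tsv"),
                                  "sample metadata TSV"))
  meta <- ex$meta
  unt <- meta[meta$condition == "untreated", ]
  stage_means <- vapply(unique(unt$stage), function(st) {
    rowMeans(ex$values[, unt$sample[unt$stage == st], drop = FALSE])
  }, numeric(nrow(ex$values)))
  cl <- kmeans_cluster(stage_means, k = config$kmeans_k_bound,
                       seed = config$seed)
  write.table(data.frame(gene = names(cl$cluster), cluster = cl$cluster),
              p("expression_clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ## per-peak-class expression fold change (treated vs untreated)
  ann <- read.table(need_file(p("peak_genes.tsv"), "peak-gene annotation"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  cls <- read.table(need_file(p("classified_peaks.tsv"),
                              "classified peak table"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gene_cls <- stats::setNames(
    cls$class_label[match(ann$peak, cls$region)], ann$gene)
  gene_cls <- gene_cls[!is.na(gene_cls) & !duplicated(names(gene_cls))]
  lfc <- contrast_log2fc(ex$values,
                         meta$sample[meta$condition == "untreated"],
                         meta$sample[meta$condition == "dox"])
  ct <- class_expression_test(gene_cls, lfc)
  write.table(as.data.frame(ct), p("class_expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_line(out, "cluster-expr: k=%d, classes tested: %s",
           config$kmeans_k_bound, paste(ct$class, collapse = ","))
  invisible(list(clusters = cl, class_expression = ct))
}

stage_report <- function(config, p, out) {
  cls <- read.table(need_file(p("classified_peaks.tsv"),
                              "classified peak table"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  zf <- need_file(p("cooccurrence_z.tsv"), "co-occurrence z matrix")
  zm <- as.matrix(read.table(zf, sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE))
  sp <- read.table(need_file(p("spacing_histogram.tsv"),
                             "spacing histogram"),
                   sep = "\t", header = TRUE)
  ce <- read.table(need_file(p("class_expression.tsv"),
                             "class expression table"),
                   sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  frac <- table(factor(cls$class, levels = 1:3)) / nrow(cls)
  ut <- upper.tri(zm, diag = TRUE)
  top_i <- which(ut & zm == max(zm[ut]), arr.ind = TRUE)[1, ]
  mode_row <- sp$distance[which.max(sp$count)]
  report <- list(
    n_peaks = nrow(cls),
    class_counts = as.integer(table(factor(cls$class, levels = 1:3))),
    class_fractions = round(as.numeric(frac), 4),
    top_pair = paste(rownames(zm)[top_i[1]], colnames(zm)[top_i[2]],
                     sep = "-"),
    top_pair_z = max(zm[ut]),
    spacing_mode = as.integer(mode_row),
    class_expression = ce)
  lines <- c(
    sprintf("peaks: %d", report$n_peaks),
    sprintf("class counts (lost/shared/gained): %s",
            paste(report$class_counts, collapse = "/")),
    sprintf("class fractions: %s",
            paste(sprintf("%.1f%%", 100 * report$class_fractions),
                  collapse = "/")),
    sprintf("top co-occurring pair: %s (z = %.2f)", report$top_pair,
            report$top_pair_z),
    sprintf("modal composite spacing: %d bp", report$spacing_mode),
    "per-class expression fold change (median [Q1, Q3], p vs rest):",
    sprintf("  %s: %.2f [%.2f, %.2f], p = %.3g", ce$class, ce$median,
            ce$q1, ce$q3, ce$p_value))
  writeLines(lines, p("report.txt"))
  log_line(out, "report: written")
  report
}
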