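## Synthetic regulatory landscape with planted ground truth: two-condition
## tag counts over peaks with lost/shared/gained structure, footprinted
## motif instances with planted co-occurrence and a fixed oriented spacer,
## and gene expression with planted cluster profiles and perturbation
## effects linked to peak classes.

#' Synthetic AP-1-like and TEAD-like PWMs shipped with the package
#'
#' Stand-in count matrices (TGACTCA- and GGAATG-shaped); not measured
#' binding data.
#'
#' @param ... Passed to [pwm_from_counts()] via [read_jaspar()].
#' @return Named list with `pwm` objects `AP1` and `TEAD`.
#' @export
default_pwms <- function(...) {
  read_jaspar(system.file("extdata", "pwm_ap1_synthetic.jaspar",
                          package = "peakgrammar", mustWork = TRUE), ...)
}

#' Specification of a synthetic regulatory landscape
#'
#' Defaults encode the study conditions the pipeline is designed to
#' recover: 30/65/5% lost/shared/gained peaks with +/-3 log2 planted
#' fold changes at 200 expected tags per peak, an AP-1-like motif planted
#' only in lost peaks and a TEAD-like motif in all classes, a TEAD-AP-1
#' composite with a 7 bp oriented spacer (+/-1 bp triangular jitter), 500
#' foreground footprint regions against a 10x larger background pool (kept
#' an order of magnitude above the subsample size so the without-replacement
#' finite-population correction stays mild and the bootstrap z is
#' calibrated) with one
#' planted co-occurring pair, and a 7-stage two-condition duplicate
#' expression design with 7 planted clusters and a -1.5 log2 perturbation
#' effect on genes linked to lost peaks.
#'
#' @param seed Integer seed (mandatory; all stages derive their RNG
#'   streams from it).
#' @param n_chroms,chrom_length Genome shape.
#' @param n_peaks,peak_width Peak count and width (bp).
#' @param class_proportions Named numeric (lost, shared, gained), sums to 1.
#' @param class_log2fc Planted log2 fold change (condition B over A) per
#'   class.
#' @param tags_per_peak Expected tag count per peak per condition.
#' @param tag_sd Gaussian s.d. of tag positions around the summit (bp).
#' @param flank Tag window half-width (bp).
#' @param plant_probs Named list: per motif, named probability per class
#'   of planting an instance at the peak.
#' @param pwms Named list of `pwm` objects used for planting/scanning.
#' @param composite_spacing,spacing_noise Oriented end-to-start spacer
#'   (bp) and maximal jitter for the planted composite.
#' @param n_footprints_fg,n_footprints_bg Foreground/background region
#'   counts (background must be >= foreground).
#' @param region_width Footprint/background region width (bp).
#' @param footprint_pad Padding around occupied instances when emitting
#'   footprint intervals (bp).
#' @param n_extra_motifs Additional synthetic motif families planted at
#'   chance in the regions (so co-occurrence matrices have many pairs).
#' @param motif_prob Per-region, per-motif inclusion probability.
#' @param cooccur_pairs List of `list(anchor=, partner=, prob=)` planted
#'   co-occurring pairs (probabilities in [0, 1]).
#' @param n_genes Number of genes (each linked to one peak).
#' @param gene_offset TSS offset from the linked peak summit (bp).
#' @param expr_k Number of planted expression clusters.
#' @param stages Ordered stage labels of the differentiation design.
#' @param n_replicates Replicates per (stage, condition).
#' @param noise_sd Replicate Gaussian noise s.d. (log2 units).
#' @param dox_effect Log2 effect added to perturbed-condition samples of
#'   genes linked to lost peaks.
#' @param profile_amplitude Stage-profile amplitude (log2 units).
#' @param baseline Baseline log2 expression.
#' @return Validated list of class `"landscape_spec"`.
#' @export
landscape_spec <- function(seed,
                           n_chroms = 5, chrom_length = 1.5e6,
                           n_peaks = 1000, peak_width = 400,
                           class_proportions = c(lost = 0.30, shared = 0.65,
                                                 gained = 0.05),
                           class_log2fc = c(lost = -3, shared = 0, gained = 3),
                           tags_per_peak = 200, tag_sd = 150, flank = 1000,
                           plant_probs = list(
                             AP1 = c(lost = 0.9, shared = 0, gained = 0),
                             TEAD = c(lost = 0.9, shared = 0.9, gained = 0.9)),
                           pwms = default_pwms(),
                           composite_spacing = 7, spacing_noise = 1,
                           n_footprints_fg = 500, n_footprints_bg = 10000,
                           region_width = 500, footprint_pad = 5,
                           n_extra_motifs = 13, motif_prob = 0.3,
                           cooccur_pairs = list(list(anchor = "TEAD",
                                                     partner = "AP1",
                                                     prob = 0.8)),
                           n_genes = 350, gene_offset = 500,
                           expr_k = 7,
                           stages = c("FLK1", "BC5h", "BCd1", "SM",
                                      "HE1", "HE2", "HP"),
                           n_replicates = 2, noise_sd = 0.25,
                           dox_effect = -1.5, profile_amplitude = 3,
                           baseline = 7) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  spec <- as.list(environment())
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  counts <- c(n_chroms, chrom_length, n_peaks, tags_per_peak,
              n_footprints_fg, n_footprints_bg, n_genes, n_replicates)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (n_footprints_bg < n_footprints_fg)
    stop("n_footprints_bg must be >= n_footprints_fg")
  for (cp in cooccur_pairs)
    if (cp$prob < 0 || cp$prob > 1)
      stop("co-occurrence probability must be in [0, 1]")
  if (expr_k > max(n_genes, 1)) stop("expr_k must not exceed n_genes")
  if (n_genes > n_peaks) stop("n_genes must not exceed n_peaks")
  structure(spec, class = "landscape_spec")
}

## Planted instances carry the consensus sequence; the count matrix's
## softness affects scoring only, so scan recovery of planted structure
## is not confounded by instance degeneracy.
sample_pwm_instance <- function(pwm) {
  pwm$consensus
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

draw_instance <- function(pwm, strand) {
  inst <- sample_pwm_instance(pwm)
  if (strand == "-") revcomp_chr(inst) else inst
}

## Write instance sequences into the genome in one pass per chromosome
## (per-instance string surgery would copy the chromosome each time).
apply_instances <- function(genome, chrom, start0, seqs) {
  for (ch in unique(chrom)) {
    v <- strsplit(genome[[ch]], "")[[1]]
    idx <- which(chrom == ch)
    for (i in idx) {
      b <- strsplit(seqs[i], "")[[1]]
      v[(start0[i] + 1):(start0[i] + length(b))] <- b
    }
    genome[[ch]] <- paste(v, collapse = "")
  }
  genome
}

rnorm_window <- function(n, center, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(n - length(out), center, sd))
    out <- c(out, x[x >= lo & x < hi])
  }
  out
}

#' Simulate the genome, peaks and two-condition tags of a landscape
#'
#' Background sequence is i.i.d. uniform over ACGT. Motif instances are
#' sampled from the PWM column probabilities and written into the genome
#' near the peak summits according to the per-class planting
#' probabilities. Tag counts per peak are Poisson with the condition-B
#' rate multiplied by `2^(planted log2fc)`; tag positions are Gaussian
#' around the summit, truncated to the `+/-flank` window.
#'
#' @param spec A [landscape_spec()].
#' @return A list of class `"landscape_sim"`: `spec`, `genome` (named
#'   character vector of chromosome strings), `peaks` (`GRanges` with
#'   names and summit offsets), `tags` (list `untreated`, `dox`),
#'   `pwms`, and `truth` (peak table and planted motif instances).
#' @export
simulate_regulatory_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  chroms <- sprintf("chrS%d", seq_len(spec$n_chroms))
  genome <- stats::setNames(vapply(chroms, function(ch) {
    paste(sample(DNA, spec$chrom_length, replace = TRUE), collapse = "")
  }, character(1)), chroms)

  n <- spec$n_peaks
  margin <- spec$flank + spec$peak_width
  chrom_of <- chroms[rep_len(seq_along(chroms), n)]
  starts <- numeric(n)
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    if (!length(idx)) next
    starts[idx] <- round(seq(margin,
                             spec$chrom_length - margin - spec$peak_width,
                             length.out = length(idx) + 1)[seq_along(idx)])
  }
  summit_off <- pmin(pmax(round(spec$peak_width / 2 +
                                  stats::rnorm(n, 0, 20)), 1),
                     spec$peak_width - 2)
  classes <- sample(names(spec$class_proportions), n, replace = TRUE,
                    prob = spec$class_proportions)
  lfc <- spec$class_log2fc[classes]

  peak_tab <- data.frame(
    peak = sprintf("peak%04d", seq_len(n)), chrom = chrom_of,
    start = starts, end = starts + spec$peak_width,
    summit = summit_off, class = classes, log2fc = as.numeric(lfc),
    stringsAsFactors = FALSE)

  ## plant motifs near summits: each motif at a fixed offset slot so
  ## instances never collide
  inst <- list()
  motif_names <- names(spec$plant_probs)
  slot_off <- stats::setNames(
    seq(-40, by = 20, length.out = length(motif_names)), motif_names)
  for (m in motif_names) {
    pwm <- spec$pwms[[m]]
    if (is.null(pwm)) stop("no PWM for planted motif ", m)
    p_class <- spec$plant_probs[[m]][classes]
    do_plant <- which(stats::runif(n) < p_class)
    if (!length(do_plant)) next
    strands <- sample(c("+", "-"), length(do_plant), replace = TRUE)
    s0 <- starts[do_plant] + summit_off[do_plant] + slot_off[[m]]
    inst[[length(inst) + 1]] <- data.frame(
      chrom = chrom_of[do_plant], start = s0, end = s0 + pwm$width,
      motif = m, strand = strands,
      seq = vapply(strands, function(st) draw_instance(pwm, st),
                   character(1)),
      peak = peak_tab$peak[do_plant], stringsAsFactors = FALSE)
  }
  instances <- if (length(inst)) do.call(rbind, inst) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               motif = character(0), strand = character(0),
               seq = character(0), peak = character(0))
  genome <- apply_instances(genome, instances$chrom, instances$start,
                            instances$seq)
  instances$seq <- NULL

  ## two-condition tags
  make_tags <- function(rates) {
    cnt <- stats::rpois(n, rates)
    df <- do.call(rbind, lapply(which(cnt > 0), function(i) {
      ctr <- starts[i] + summit_off[i]
      pos <- rnorm_window(cnt[i], ctr, spec$tag_sd,
                          max(ctr - spec$flank, 0),
                          min(ctr + spec$flank, spec$chrom_length))
      data.frame(chrom = chrom_of[i], pos = pos, stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(chrom = character(0), pos = numeric(0))
    df[order(df$chrom, df$pos), , drop = FALSE]
  }
  tags <- list(untreated = make_tags(rep(spec$tags_per_peak, n)),
               dox = make_tags(spec$tags_per_peak * 2^as.numeric(lfc)))

  peaks <- interval_set(chrom = peak_tab$chrom, start = peak_tab$start,
                        end = peak_tab$end, name = peak_tab$peak,
                        summit = peak_tab$summit, label = "peaks")
  structure(list(spec = spec, genome = genome, peaks = peaks, tags = tags,
                 pwms = spec$pwms,
                 truth = list(peaks = peak_tab, motif_instances = instances)),
            class = "landscape_sim")
}

random_motif_counts <- function(width) {
  cons <- sample(4, width, replace = TRUE)
  m <- matrix(5, 4, width, dimnames = list(DNA, NULL))
  m[cbind(cons, seq_len(width))] <- 85
  m
}

#' Simulate footprinted foreground and background regions with planted
#' motif co-occurrence
#'
#' Places non-overlapping DHS-like regions on the simulated genome (clear
#' of the peaks), fills each independently with motif instances at a
#' per-motif inclusion probability, and, in a stated fraction of
#' foreground regions, plants the configured anchor-partner pair at the
#' composite spacing. One footprint interval is emitted per foreground
#' region: the padded span of its occupied instances, or the whole region
#' when it holds none, so that an equally sized background draw is
#' exchangeable with the foreground under the null.
#'
#' @param spec A [landscape_spec()].
#' @param sim A `landscape_sim` from [simulate_regulatory_landscape()].
#' @return `sim`, extended with `fg_footprints` and `bg_regions`
#'   (`GRanges`), updated `genome`/`pwms`, and truth entries
#'   `regions` and `region_instances` (with `planted_pair` flags).
#' @export
simulate_footprints <- function(spec, sim) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (!inherits(sim, "landscape_sim"))
    stop("landscape must be simulated first")
  set.seed(spec$seed + 1L)
  genome <- sim$genome
  pwms <- sim$pwms
  for (i in seq_len(spec$n_extra_motifs)) {
    nm <- sprintf("M%02d", i)
    pwms[[nm]] <- pwm_from_counts(random_motif_counts(8), name = nm)
  }
  motifs <- names(pwms)
  n_total <- spec$n_footprints_fg + spec$n_footprints_bg
  if (n_total == 0)
    stop("no footprint regions requested")

  ## candidate slots clear of peaks, spaced so regions never interact
  spacing <- spec$region_width + 60
  chroms <- names(genome)
  slots <- do.call(rbind, lapply(chroms, function(ch) {
    s <- seq(spacing, spec$chrom_length - spacing - spec$region_width,
             by = spacing)
    data.frame(chrom = ch, start = s, stringsAsFactors = FALSE)
  }))
  slot_gr <- GenomicRanges::GRanges(slots$chrom,
                                    IRanges::IRanges(slots$start + 1,
                                                     slots$start + spec$region_width))
  free <- GenomicRanges::countOverlaps(slot_gr, sim$peaks,
                                       ignore.strand = TRUE) == 0
  slots <- slots[free, ]
  if (nrow(slots) < n_total)
    stop("genome too small for the requested number of regions")
  pick <- slots[sample.int(nrow(slots), n_total), ]
  role <- rep(c("fg", "bg"), c(spec$n_footprints_fg, spec$n_footprints_bg))
  regions <- data.frame(
    region = sprintf("%s%04d", role, unlist(lapply(
      c(spec$n_footprints_fg, spec$n_footprints_bg), seq_len))),
    chrom = pick$chrom, start = pick$start,
    end = pick$start + spec$region_width, role = role,
    planted_pair = FALSE, stringsAsFactors = FALSE)

  ## collect instances first, write them into the genome in one batch
  ic <- 0L
  cap <- 4L * n_total * length(motifs)
  i_chrom <- character(cap); i_start <- numeric(cap); i_end <- numeric(cap)
  i_motif <- character(cap); i_strand <- character(cap)
  i_seq <- character(cap); i_region <- character(cap)
  add_inst <- function(region, chrom, pwm, start0, strand) {
    ic <<- ic + 1L
    i_chrom[ic] <<- chrom; i_start[ic] <<- start0
    i_end[ic] <<- start0 + pwm$width; i_motif[ic] <<- pwm$name
    i_strand[ic] <<- strand; i_seq[ic] <<- draw_instance(pwm, strand)
    i_region[ic] <<- region
    c(start0, start0 + pwm$width)
  }
  r_chrom <- regions$chrom; r_start <- regions$start
  r_role <- regions$role; r_id <- regions$region
  ## balanced occupancy: each motif is assigned to an exact fraction
  ## motif_prob of the regions of each pool (membership random). Totals
  ## are then fixed, so the region-resampling null is never confounded by
  ## pool-level motif-count noise.
  member <- matrix(FALSE, nrow(regions), length(motifs),
                   dimnames = list(NULL, motifs))
  for (pool in c("fg", "bg")) {
    idx <- which(r_role == pool)
    for (m in motifs) {
      n_m <- round(spec$motif_prob * length(idx))
      if (n_m > 0) member[sample(idx, n_m), m] <- TRUE
    }
  }
  for (r in seq_len(nrow(regions))) {
    skip <- character(0)
    occupied <- matrix(numeric(0), ncol = 2)
    if (r_role[r] == "fg") {
      for (cp in spec$cooccur_pairs) {
        if (stats::runif(1) >= cp$prob) next
        regions$planted_pair[r] <- TRUE
        aw <- pwms[[cp$anchor]]$width; pw <- pwms[[cp$partner]]$width
        d <- spec$composite_spacing + if (spec$spacing_noise > 0)
          sample(seq(-spec$spacing_noise, spec$spacing_noise), 1,
                 prob = spacing_jitter_weights(spec$spacing_noise)) else 0
        span <- aw + d + pw
        a_strand <- sample(c("+", "-"), 1)
        a0 <- r_start[r] + sample.int(spec$region_width - span - 1, 1)
        if (a_strand == "-") a0 <- a0 + span - aw  # mirror: anchor right
        occupied <- rbind(occupied,
                          add_inst(r_id[r], r_chrom[r], pwms[[cp$anchor]],
                                   a0, a_strand))
        p0 <- if (a_strand == "+") a0 + aw + d else a0 - d - pw
        occupied <- rbind(occupied,
                          add_inst(r_id[r], r_chrom[r], pwms[[cp$partner]],
                                   p0, sample(c("+", "-"), 1)))
        skip <- c(skip, cp$anchor, cp$partner)
      }
    }
    for (m in setdiff(motifs, skip)) {
      if (!member[r, m]) next
      w <- pwms[[m]]$width
      for (try in 1:20) {
        s0 <- r_start[r] + sample.int(spec$region_width - w, 1) - 1
        clash <- nrow(occupied) > 0 &&
          any(s0 < occupied[, 2] & s0 + w > occupied[, 1])
        if (!clash) {
          occupied <- rbind(occupied,
                            add_inst(r_id[r], r_chrom[r], pwms[[m]], s0,
                                     sample(c("+", "-"), 1)))
          break
        }
      }
    }
  }
  keep <- seq_len(ic)
  region_instances <- data.frame(
    chrom = i_chrom[keep], start = i_start[keep], end = i_end[keep],
    motif = i_motif[keep], strand = i_strand[keep],
    region = i_region[keep], stringsAsFactors = FALSE)
  genome <- apply_instances(genome, i_chrom[keep], i_start[keep],
                            i_seq[keep])

  ## footprints: padded span of each fg region's instances, else the region
  fg <- regions[regions$role == "fg", ]
  fp <- do.call(rbind, lapply(seq_len(nrow(fg)), function(i) {
    ri <- region_instances[region_instances$region == fg$region[i], ]
    if (nrow(ri) == 0)
      data.frame(chrom = fg$chrom[i], start = fg$start[i], end = fg$end[i],
                 name = fg$region[i], stringsAsFactors = FALSE)
    else
      data.frame(chrom = fg$chrom[i],
                 start = max(min(ri$start) - spec$footprint_pad, fg$start[i]),
                 end = min(max(ri$end) + spec$footprint_pad, fg$end[i]),
                 name = fg$region[i], stringsAsFactors = FALSE)
  }))
  bg <- regions[regions$role == "bg", ]
  sim$genome <- genome
  sim$pwms <- pwms
  sim$fg_footprints <- if (is.null(fp)) NULL else
    interval_set(fp$chrom, fp$start, fp$end, name = fp$name,
                 label = "fg_footprints")
  sim$bg_regions <- interval_set(bg$chrom, bg$start, bg$end,
                                 name = bg$region, label = "bg_regions")
  sim$truth$regions <- regions
  sim$truth$region_instances <- region_instances
  sim
}

spacing_jitter_weights <- function(noise) {
  ## triangular: mass concentrated on zero so the planted spacing is the
  ## unambiguous histogram mode
  w <- noise + 1 - abs(seq(-noise, noise))
  w[noise + 1] <- w[noise + 1] + 3 * noise
  w / sum(w)
}

#' Simulate the stage/condition expression matrix linked to peak classes
#'
#' Each gene is linked to one peak (its TSS sits `gene_offset` bp from
#' the peak summit, so nearest-gene annotation recovers the link),
#' belongs to one of `expr_k` planted stage-profile clusters, and
#' receives the perturbation effect on treated samples when its peak is
#' of the lost class. Log2 values are baseline + cluster profile +
#' condition effect + Gaussian replicate noise.
#'
#' @param spec A [landscape_spec()].
#' @param sim A `landscape_sim` (landscape simulated first).
#' @return `sim`, extended with `expression` (list `values`, `meta`),
#'   `genes` (annotation data.frame), and a truth `genes` table
#'   (gene, peak, class, cluster, dox_effect).
#' @export
simulate_expression <- function(spec, sim) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (!inherits(sim, "landscape_sim"))
    stop("landscape must be simulated first")
  if (spec$n_replicates < 1) stop("need at least 1 replicate")
  set.seed(spec$seed + 2L)
  pk <- sim$truth$peaks[seq_len(spec$n_genes), ]
  genes <- data.frame(
    gene = sprintf("G%04d", seq_len(spec$n_genes)),
    chrom = pk$chrom,
    tss = pmin(pk$start + pk$summit + spec$gene_offset,
               spec$chrom_length - 1),
    strand = sample(c("+", "-"), spec$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  cluster <- sample(rep_len(seq_len(spec$expr_k), spec$n_genes))
  ns <- length(spec$stages)
  profile <- matrix(0, spec$expr_k, ns)
  for (cl in seq_len(spec$expr_k))
    profile[cl, ((cl - 1) %% ns) + 1] <- spec$profile_amplitude
  effect <- ifelse(pk$class == "lost", spec$dox_effect, 0)

  design <- expand.grid(replicate = seq_len(spec$n_replicates),
                        condition = c("untreated", "dox"),
                        stage = spec$stages, stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%s_r%d", design$stage, design$condition,
                           design$replicate)
  vals <- vapply(seq_len(nrow(design)), function(s) {
    st <- match(design$stage[s], spec$stages)
    mu <- spec$baseline + profile[cluster, st] +
      if (design$condition[s] == "dox") effect else 0
    mu + stats::rnorm(spec$n_genes, 0, spec$noise_sd)
  }, numeric(spec$n_genes))
  dimnames(vals) <- list(genes$gene, design$sample)

  sim$expression <- list(values = vals,
                         meta = design[c("sample", "stage", "condition",
                                         "replicate")])
  sim$genes <- genes
  sim$truth$genes <- data.frame(gene = genes$gene, peak = pk$peak,
                                class = pk$class, cluster = cluster,
                                dox_effect = effect,
                                stringsAsFactors = FALSE)
  sim
}

#' Hit lists (per motif) from the planted ground-truth instances
#'
#' @param sim A `landscape_sim`.
#' @param which `"regions"` (footprint/background instances, default),
#'   `"peaks"`, or `"all"`.
#' @return Named list of hit data.frames as consumed by
#'   [cooccurrence_zscores()] and [spacing_distribution()].
#' @export
truth_hits <- function(sim, which = c("regions", "peaks", "all")) {
  which <- match.arg(which)
  if (which != "peaks" && is.null(sim$truth$region_instances))
    stop("footprints not simulated yet; run simulate_footprints() first")
  cols <- c("chrom", "start", "end", "motif", "strand")
  h <- switch(which,
              regions = sim$truth$region_instances,
              peaks = sim$truth$motif_instances,
              all = rbind(sim$truth$region_instances[, cols],
                          sim$truth$motif_instances[, cols]))
  h <- h[, cols]
  h$score <- 0
  split(h, factor(h$motif, levels = names(sim$pwms)))
}

#' Keep only hits whose match overlaps a footprint interval
#' @param hits Named list of hit data.frames.
#' @param footprints `GRanges` of footprint intervals.
#' @return The filtered named list.
#' @export
filter_occupied <- function(hits, footprints) {
  lapply(hits, function(h) {
    if (is.null(h) || nrow(h) == 0) return(h)
    occ <- GenomicRanges::countOverlaps(hits_to_granges(h), footprints,
                                        ignore.strand = TRUE) > 0
    h[occ, , drop = FALSE]
  })
}

#' Write all simulated artifacts of a landscape to a directory
#'
#' Emits the formats the analysis functions consume: `genome.fa`,
#' `peaks.bed` (with 7th summit column), per-condition tag TSVs,
#' `fg_footprints.bed`, `bg_regions.bed`, `motif_instances.bed`,
#' `pwms.jaspar`, `expression.tsv`, `sample_metadata.tsv`, `genes.tsv`,
#' and the ground truth as a JSON sidecar.
#'
#' @param sim A `landscape_sim`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_landscape <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  p <- function(f) file.path(outdir, f)
  dna <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(dna, p("genome.fa"))
  paths["genome"] <- p("genome.fa")
  write_bed(sim$peaks, p("peaks.bed")); paths["peaks"] <- p("peaks.bed")
  for (cond in names(sim$tags)) {
    f <- p(sprintf("tags_%s.tsv", cond))
    write_tags(sim$tags[[cond]], f)
    paths[paste0("tags_", cond)] <- f
  }
  if (!is.null(sim$fg_footprints)) {
    write_bed(sim$fg_footprints, p("fg_footprints.bed"))
    write_bed(sim$bg_regions, p("bg_regions.bed"))
    hits <- truth_hits(sim, "all")
    write_hits_bed(hits[vapply(hits, nrow, 1L) > 0], p("motif_instances.bed"))
    paths[c("fg_footprints", "bg_regions", "motif_instances")] <-
      c(p("fg_footprints.bed"), p("bg_regions.bed"), p("motif_instances.bed"))
  }
  write_jaspar(sim$pwms, p("pwms.jaspar")); paths["pwms"] <- p("pwms.jaspar")
  if (!is.null(sim$expression)) {
    ex <- data.frame(gene = rownames(sim$expression$values),
                     sim$expression$values, check.names = FALSE)
    write.table(ex, p("expression.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sim$expression$meta, p("sample_metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$genes, p("genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[c("expression", "metadata", "genes")] <-
      c(p("expression.tsv"), p("sample_metadata.tsv"), p("genes.tsv"))
  }
  jsonlite::write_json(sim$truth, p("ground_truth.json"), digits = NA,
                       dataframe = "columns")
  paths["truth"] <- p("ground_truth.json")
  invisible(paths)
}
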