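test_that("intersect_sets handles empty sets, identity, and the worked example", {
  a <- interval_set("chr1", c(100, 300), c(200, 400))
  b <- interval_set("chr1", c(150, 390, 600), c(160, 500, 700))
  empty <- interval_set(character(0), numeric(0), numeric(0))

  expect_equal(intersect_sets(empty, b)$n_a_overlapping, 0)
  expect_equal(nrow(intersect_sets(empty, b)$pairs), 0)

  self <- intersect_sets(a, a)
  expect_equal(self$n_a_overlapping, 2)
  expect_equal(self$n_b_overlapping, 2)

  rep <- intersect_sets(a, b)
  expect_equal(rep$n_a_overlapping, 2)
  expect_equal(rep$n_b_overlapping, 2)
  expect_equal(nrow(rep$pairs), 2)
})

test_that("intersect_sets honours min_overlap and rejects invalid values", {
  a <- interval_set("chr1", 100, 200)
  b <- interval_set("chr1", 195, 300)  # 5 bp shared
  expect_equal(intersect_sets(a, b, min_overlap = 5)$n_a_overlapping, 1)
  expect_equal(intersect_sets(a, b, min_overlap = 6)$n_a_overlapping, 0)
  expect_error(intersect_sets(a, b, min_overlap = -1), "min_overlap")
})

test_that("intersect_sets agrees with all-pairs brute force on random sets", {
  set.seed(401)
  for (rep in 1:25) {
    a <- rand_intervals(sample.int(60, 1))
    b <- rand_intervals(sample.int(60, 1))
    mo <- sample.int(10, 1)
    got <- intersect_sets(a, b, min_overlap = mo)
    want <- bf_overlap_report(a, b, min_overlap = mo)
    expect_equal(got$n_a_overlapping, want$n_a)
    expect_equal(got$n_b_overlapping, want$n_b)
    expect_equal(nrow(got$pairs), want$n_pairs)
  }
})

test_that("nearest-gene annotation: single candidate, worked example, ties", {
  genes1 <- data.frame(gene = "gX", chrom = "chr1", tss = 500, strand = "+")
  pk <- interval_set("chr1", c(0, 900), c(10, 1000))
  ann <- annotate_nearest_gene(pk, genes1)
  expect_equal(ann$gene, c("gX", "gX"))
  expect_false(any(ann$unassigned))

  genes2 <- data.frame(gene = c("geneX", "geneY"), chrom = "chr1",
                       tss = c(800, 1150), strand = c("+", "+"))
  pk2 <- interval_set("chr1", 990, 1010)  # midpoint 1000
  expect_equal(annotate_nearest_gene(pk2, genes2)$gene, "geneY")

  ## equidistant TSSs: lower coordinate wins; same TSS: lexicographic gene
  genes3 <- data.frame(gene = c("gB", "gA"), chrom = "chr1",
                       tss = c(900, 1100), strand = c("+", "+"))
  expect_equal(annotate_nearest_gene(pk2, genes3)$gene, "gB")
  genes4 <- data.frame(gene = c("gB", "gA"), chrom = "chr1",
                       tss = c(900, 900), strand = c("+", "+"))
  expect_equal(annotate_nearest_gene(pk2, genes4)$gene, "gA")
})

test_that("nearest-gene distance is signed by the gene's reading direction", {
  ## reference point 1000; plus-strand gene at 900: peak is 100 bp
  ## downstream -> +100; minus-strand gene at 1100: 1000 is downstream of
  ## the TSS in reading direction -> +100 as well
  pk <- interval_set("chr1", 990, 1010)
  plus <- data.frame(gene = "gP", chrom = "chr1", tss = 900, strand = "+")
  minus <- data.frame(gene = "gM", chrom = "chr1", tss = 1100, strand = "-")
  expect_equal(annotate_nearest_gene(pk, plus)$distance, 100)
  expect_equal(annotate_nearest_gene(pk, minus)$distance, 100)
})

test_that("nearest-gene: empty annotation errors, bare chromosome flags", {
  pk <- interval_set(c("chr1", "chr9"), c(0, 0), c(10, 10))
  genes <- data.frame(gene = "gX", chrom = "chr1", tss = 5, strand = "+")
  expect_error(annotate_nearest_gene(pk, genes[0, ]), "non-empty")
  ann <- annotate_nearest_gene(pk, genes)
  expect_equal(ann$unassigned, c(FALSE, TRUE))
  expect_error(annotate_nearest_gene(
    pk, rbind(genes, genes)), "unique")
})

test_that("nearest-gene agrees with brute force on random instances", {
  set.seed(402)
  for (rep in 1:25) {
    pk <- rand_intervals(sample.int(40, 1), summit = TRUE)
    ng <- sample(3:30, 1)
    genes <- data.frame(gene = sprintf("g%02d", seq_len(ng)),
                        chrom = sample(c("cA", "cB"), ng, replace = TRUE),
                        tss = sample.int(2100, ng),
                        strand = sample(c("+", "-"), ng, replace = TRUE))
    got <- annotate_nearest_gene(pk, genes)
    expect_equal(got$gene, bf_nearest(pk, genes))
  }
})

test_that("venn counts partition the inputs and match enumeration", {
  v <- venn_counts(list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4")))
  expect_equal(v$A[v$category == "A"], 1)
  expect_equal(v$A[v$category == "A&B"], 2)
  expect_equal(v$B[v$category == "B"], 1)

  d <- venn_counts(list(A = c("x", "y"), B = c("p", "q")))
  expect_equal(d$A[d$category == "A&B"], 0)

  expect_error(venn_counts(list(A = "a", B = "b", C = "c", D = "d")),
               "2 or 3")
})

test_that("venn counts conserve set sizes for random 3-way interval sets", {
  set.seed(403)
  for (rep in 1:10) {
    sets <- list(A = rand_intervals(sample.int(30, 1)),
                 B = rand_intervals(sample.int(30, 1)),
                 C = rand_intervals(sample.int(30, 1)))
    v <- venn_counts(sets)
    for (nm in names(sets))
      expect_equal(sum(v[[nm]]), length(sets[[nm]]))
  }
})

test_that("hypergeometric overlap significance matches tail enumeration", {
  mk <- function(n, hit, other_chrom = FALSE) {
    interval_set(if (other_chrom) "cZ" else "cA",
                 seq(0, by = 100, length.out = n),
                 seq(0, by = 100, length.out = n) + 10)
  }
  ## |a| = 0 is degenerate: p = 1
  empty <- interval_set(character(0), numeric(0), numeric(0))
  b <- mk(5)
  expect_equal(overlap_significance(empty, b, population_size = 20)$p_value, 1)

  ## N=20, K=5, n=5, k=3 worked example
  a <- mk(5)
  b3 <- interval_set(c("cA", "cA", "cA", "cZ", "cZ"),
                     c(0, 100, 200, 5000, 6000),
                     c(10, 110, 210, 5010, 6010))
  res <- overlap_significance(a, b3, population_size = 20)
  expect_equal(res$overlap, 3)
  expect_equal(res$p_value, bf_hyper_tail(20, 5, 5, 3), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0726, tolerance = 1e-3)

  ## overlap at/below expectation -> p near 1
  disj <- interval_set("cA", 10000, 10010)
  expect_equal(overlap_significance(mk(3), disj,
                                    population_size = 1000)$p_value, 1)
})

test_that("hypergeometric p equals enumeration for random N <= 50 and is
          within 3 MC s.e. of a permutation estimate", {
  set.seed(404)
  for (rep in 1:20) {
    N <- sample(10:50, 1)
    K <- sample.int(N %/% 2, 1); n <- sample.int(N %/% 2, 1)
    k <- sample(0:min(K, n), 1)
    p_pkg <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p_pkg, bf_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
  ## Monte-Carlo cross-check at a larger population
  N <- 500; K <- 60; n <- 80; k <- 15
  p_exact <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  draws <- vapply(1:10000, function(i)
    sum(sample.int(N, n) <= K) >= k, logical(1))
  mc <- mean(draws); se <- sqrt(mc * (1 - mc) / 10000)
  expect_lt(abs(p_exact - mc), 3 * se + 1e-9)
})

test_that("population-size validation and data-driven default work", {
  a <- interval_set("cA", c(0, 100), c(50, 150))
  b <- interval_set("cA", c(0, 100), c(50, 150))
  expect_error(overlap_significance(a, b, population_size = 1),
               "population")
  res <- overlap_significance(a, b, genome_length = 5000)
  expect_equal(res$population_size, 100)  # 5000 / mean width 50
})

test_that("BED round trip is faithful including the summit column", {
  x <- interval_set(c("chr2", "chr1"), c(10, 5), c(100, 50),
                    name = c("p2", "p1"), score = c(1.5, 2),
                    strand = c("+", "-"), summit = c(30, 7))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(as_bed_frame(y), as_bed_frame(x))
  lines <- readLines(f)
  expect_equal(length(strsplit(lines[1], "\t")[[1]]), 7)
})
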