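toy_matrix <- function() {
  ## 10 genes x 4 samples; contrast B vs A with known mean fold changes
  lfc <- c(2, 1.5, 1, 0.5, 0, -0.25, -1, -1.5, -2, 0.99)
  vals <- cbind(a1 = rep(5, 10), a2 = rep(5, 10),
                b1 = 5 + lfc, b2 = 5 + lfc)
  rownames(vals) <- sprintf("g%02d", 1:10)
  vals
}

test_that("twofold filter matches hand enumeration, inclusively", {
  vals <- toy_matrix()
  dg <- diff_genes(vals, list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_setequal(dg$contrasts[[1]]$up, c("g01", "g02", "g03"))
  expect_setequal(dg$contrasts[[1]]$down, c("g07", "g08", "g09"))
  ## exactly 1.0 log2 is "at least twofold"; 0.99 is not
  expect_true("g03" %in% dg$contrasts[[1]]$up)
  expect_false("g10" %in% dg$contrasts[[1]]$up)
  expect_error(diff_genes(vals, list(A = "a1", B = "b1"),
                          threshold_fold = 1), "threshold_fold")
})

test_that("reversing a contrast swaps the up and down sets", {
  vals <- toy_matrix()
  fwd <- diff_genes(vals, list(A = c("a1", "a2"), B = c("b1", "b2")))
  rev <- diff_genes(vals, list(A = c("b1", "b2"), B = c("a1", "a2")))
  expect_setequal(fwd$contrasts[[1]]$up, rev$contrasts[[1]]$down)
  expect_setequal(fwd$contrasts[[1]]$down, rev$contrasts[[1]]$up)
})

test_that("identical condition means yield no differential genes", {
  vals <- cbind(a1 = 1:5, a2 = 3:7, b1 = 3:7, b2 = 1:5)
  rownames(vals) <- sprintf("g%d", 1:5)
  dg <- diff_genes(vals, list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_length(dg$contrasts[[1]]$up, 0)
  expect_length(dg$contrasts[[1]]$down, 0)
})

test_that("cross-contrast overlap table counts shared sets with sizes on the diagonal", {
  vals <- toy_matrix()
  cs <- list(c1 = list(A = c("a1", "a2"), B = c("b1", "b2")),
             c2 = list(A = c("a1", "a2"), B = c("b1", "b2")),
             c3 = list(A = c("b1", "b2"), B = c("a1", "a2")))
  dg <- diff_genes(vals, cs)
  expect_equal(dg$up_overlap["c1", "c1"], 3L)
  expect_equal(dg$up_overlap["c1", "c2"], 3L)
  expect_equal(dg$up_overlap["c1", "c3"], 0L)
  expect_equal(dg$down_overlap["c1", "c3"], 0L)
  expect_equal(dg$up_overlap, t(dg$up_overlap))
})

test_that("k-means: single cluster, determinism, separation of planted blobs", {
  set.seed(417)
  x <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  k1 <- kmeans_cluster(x, 1, seed = 5)
  expect_equal(unname(k1$centers[1, ]), unname(colMeans(x)))

  blobs <- rbind(matrix(rnorm(30, 0, 0.3), 10, 3),
                 matrix(rnorm(30, 8, 0.3), 10, 3))
  rownames(blobs) <- sprintf("b%02d", 1:20)
  k2 <- kmeans_cluster(blobs, 2, seed = 6)
  truth <- rep(1:2, each = 10)
  expect_equal(adjusted_rand(k2$cluster, truth), 1)

  again <- kmeans_cluster(blobs, 2, seed = 6)
  expect_equal(again$cluster, k2$cluster)
  expect_error(kmeans_cluster(blobs, 21, seed = 1), "exceed")
})

test_that("correlation distance clusters by profile shape, not level", {
  set.seed(418)
  shape <- rbind(c(1, 2, 3), c(3, 2, 1))
  x <- rbind(shape[1, ] + 0, shape[1, ] + 10, shape[2, ] + 0,
             shape[2, ] + 10) + matrix(rnorm(12, 0, 0.01), 4, 3)
  rownames(x) <- c("u1", "u2", "d1", "d2")
  k <- kmeans_cluster(x, 2, seed = 7, distance = "correlation")
  expect_equal(k$cluster[["u1"]], k$cluster[["u2"]])
  expect_equal(k$cluster[["d1"]], k$cluster[["d2"]])
  expect_false(k$cluster[["u1"]] == k$cluster[["d1"]])
})

test_that("rank-sum p for {1,2,3} vs {4,5,6} is exactly 0.1", {
  gcls <- stats::setNames(rep(c("a", "b"), each = 3),
                          sprintf("g%d", 1:6))
  fc <- stats::setNames(c(1, 2, 3, 4, 5, 6), sprintf("g%d", 1:6))
  ct <- class_expression_test(gcls, fc)
  expect_equal(ct$p_value, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(ct$median[ct$class == "a"], 2)
})

test_that("a planted downward shift in one class is detected", {
  set.seed(419)
  gcls <- stats::setNames(rep(c("lost", "shared"), each = 100),
                          sprintf("g%03d", 1:200))
  fc <- stats::setNames(c(rnorm(100, -1, 0.5), rnorm(100, 0, 0.5)),
                        names(gcls))
  ct <- class_expression_test(gcls, fc)
  lost <- ct[ct$class == "lost", ]
  expect_lt(lost$p_value, 0.01)
  expect_lt(lost$median, ct$median[ct$class == "shared"])
})

test_that("under the null, class-vs-rest p-values are roughly uniform", {
  set.seed(420)
  ps <- replicate(400, {
    gcls <- stats::setNames(rep(c("a", "b"), each = 15),
                            sprintf("g%02d", 1:30))
    fc <- stats::setNames(rnorm(30), names(gcls))
    class_expression_test(gcls, fc)$p_value[1]
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("undersized classes are excluded with a warning", {
  gcls <- stats::setNames(c(rep("a", 5), rep("b", 5), "c", "c"),
                          sprintf("g%02d", 1:12))
  fc <- stats::setNames(rnorm(12), names(gcls))
  expect_warning(ct <- class_expression_test(gcls, fc), "excluded")
  expect_setequal(ct$class, c("a", "b"))
  tiny <- stats::setNames(c("a", "a", "a", "b"), sprintf("g%d", 1:4))
  fct <- stats::setNames(rnorm(4), names(tiny))
  expect_error(suppressWarnings(class_expression_test(tiny, fct)),
               "at least 2 classes")
})

test_that("expression TSV and metadata round trip through the readers", {
  spec <- small_spec(seed = 421)
  sim <- simulate_regulatory_landscape(spec)
  sim <- simulate_expression(spec, sim)
  d <- withr::local_tempdir()
  ef <- file.path(d, "expr.tsv"); mf <- file.path(d, "meta.tsv")
  write.table(data.frame(gene = rownames(sim$expression$values),
                         sim$expression$values, check.names = FALSE),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$expression$meta, mf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ex <- read_expression(ef, mf)
  expect_equal(ex$values, sim$expression$values)
  expect_equal(nrow(ex$meta), nrow(sim$expression$meta))
})
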