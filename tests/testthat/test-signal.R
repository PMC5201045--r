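make_sm <- function(tags_a, tags_b, lib_a = 1e7, lib_b = 1e7) {
  ## minimal SignalMatrix with one bin per region; library sizes of 1e7
  ## make the tags-per-10-million normalisation the identity
  structure(list(
    regions = interval_set("c1", seq(0, by = 100,
                                     length.out = length(tags_a)),
                           seq(0, by = 100, length.out = length(tags_a)) + 50),
    offsets = 0, bin_width = 50, flank = 50,
    counts = list(A = matrix(tags_a, ncol = 1),
                  B = matrix(tags_b, ncol = 1)),
    library_size = c(A = lib_a, B = lib_b)
  ), class = "SignalMatrix")
}

test_that("summit_matrix bins tags around the reference point", {
  pk <- interval_set("c1", 1000, 1400, summit = 200)  # ref point 1200
  none <- list(u = data.frame(chrom = character(0), pos = numeric(0)))
  m0 <- summit_matrix(pk, none, flank = 200, bin_width = 50)
  expect_true(all(m0$counts$u == 0))
  expect_equal(dim(m0$counts$u), c(1, 8))

  ## a single tag exactly at the summit falls in the center-right bin
  one <- list(u = data.frame(chrom = "c1", pos = 1200))
  m1 <- summit_matrix(pk, one, flank = 200, bin_width = 50)
  expect_equal(which(m1$counts$u[1, ] == 1), 5)
  expect_equal(sum(m1$counts$u), 1)
  expect_equal(m1$offsets[5], 0)

  ## one bp left of the summit lands in the center-left bin
  m2 <- summit_matrix(pk, list(u = data.frame(chrom = "c1", pos = 1199)),
                      flank = 200, bin_width = 50)
  expect_equal(which(m2$counts$u[1, ] == 1), 4)
})

test_that("summit_matrix validates inputs", {
  pk <- interval_set("c1", 1000, 1400, summit = 200)
  tg <- list(u = data.frame(chrom = "c1", pos = c(50, 10)))
  expect_error(summit_matrix(pk, tg), "sorted")
  ok <- list(u = data.frame(chrom = "c1", pos = c(10, 50)))
  expect_error(summit_matrix(pk, ok, flank = 0), "positive")
  expect_error(summit_matrix(pk, ok, flank = 130, bin_width = 50),
               "multiple")
})

test_that("uniform random tags fill bins uniformly within binomial bounds", {
  set.seed(405)
  pk <- interval_set("c1", 4000, 6400, summit = 1200)  # ref 5200
  n <- 10000
  pos <- sort(sample(4200:6199, n, replace = TRUE))  # uniform over 2 kb
  m <- summit_matrix(pk, list(u = data.frame(chrom = "c1", pos = pos)),
                     flank = 1000, bin_width = 50)
  expect_equal(sum(m$counts$u), n)
  expected <- n * 50 / 2000
  sdev <- sqrt(n * (50 / 2000) * (1 - 50 / 2000))
  expect_true(all(abs(m$counts$u - expected) < 4 * sdev))
})

test_that("classification: identical conditions give all-shared at fold 0", {
  m <- make_sm(c(10, 20, 30), c(10, 20, 30))
  tab <- fold_change_classify(m, "A", "B")
  expect_equal(tab$log2fc, rep(0, 3))
  expect_equal(tab$class, rep(2L, 3))
})

test_that("classification boundary at exactly +/-cutoff goes to the extreme class", {
  ## (1+1)/(3+1) gives log2fc exactly -1; (3+1)/(1+1) exactly +1
  m <- make_sm(c(3, 1), c(1, 3))
  tab <- fold_change_classify(m, "A", "B", cutoff = 1)
  expect_equal(sort(tab$log2fc), c(-1, 1))
  expect_equal(tab$class[tab$log2fc == -1], 1L)
  expect_equal(tab$class[tab$log2fc == 1], 3L)
  expect_error(fold_change_classify(m, "A", "B", cutoff = 0), "cutoff")
})

test_that("classification is antisymmetric under condition swap", {
  set.seed(406)
  m <- make_sm(rpois(50, 40), rpois(50, 40))
  ab <- fold_change_classify(m, "A", "B")
  ba <- fold_change_classify(m, "B", "A")
  ab <- ab[order(ab$region_index), ]; ba <- ba[order(ba$region_index), ]
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$class, c(3L, 2L, 1L)[ba$class])
})

test_that("class counts conserve regions and shared class grows with cutoff", {
  set.seed(407)
  m <- make_sm(rpois(80, 30), rpois(80, 30) * sample(c(1, 4), 80, TRUE))
  t1 <- fold_change_classify(m, "A", "B", cutoff = 0.5)
  t2 <- fold_change_classify(m, "A", "B", cutoff = 1.5)
  expect_equal(sum(table(t1$class)), 80)
  expect_gte(sum(t2$class == 2), sum(t1$class == 2))
  expect_equal(t1$rank, seq_len(80))
  expect_false(is.unsorted(t1$log2fc))
})

test_that("planted three-class structure is recovered from a small landscape", {
  spec <- small_spec(seed = 408)
  sim <- simulate_regulatory_landscape(spec)
  m <- summit_matrix(sim$peaks, sim$tags)
  tab <- fold_change_classify(m, "untreated", "dox")
  tr <- sim$truth$peaks
  truthc <- c(lost = 1, shared = 2, gained = 3)[
    tr$class[match(tab$region, tr$peak)]]
  expect_gte(mean(tab$class == unname(truthc)), 0.95)
})

test_that("average profiles are group means, invariant to member order", {
  m <- make_sm(1:4, 5:8)
  m$counts <- list(A = rbind(c(0, 2), c(2, 0), c(5, 5), c(7, 9)))
  m$offsets <- c(-50, 0)
  prof <- average_profile(m, c("g1", "g1", "g2", "g3"), conditions = "A")
  expect_equal(unname(prof$A["g1", ]), c(1, 1))
  expect_equal(unname(prof$A["g3", ]), c(7, 9))  # singleton = its row

  set.seed(409)
  mm <- make_sm(rpois(6, 5), rpois(6, 5))
  mm$counts$A <- matrix(rpois(12, 9), 6, 2)
  mm$offsets <- c(-50, 0)
  g <- c("a", "a", "a", "b", "b", "b")
  p1 <- average_profile(mm, g, conditions = "A")$A
  perm <- c(3, 1, 2, 6, 5, 4)  # permute within groups
  mm2 <- mm; mm2$counts$A <- mm$counts$A[perm, ]
  p2 <- average_profile(mm2, g[perm], conditions = "A")$A
  expect_equal(p1, p2)

  expect_error(average_profile(mm, factor(g, levels = c("a", "b", "c"))),
               "empty group")
})
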