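test_that("rarefy hits exact depth, drops shallow samples, and is seeded", {
  m <- toy_counts(n_samples = 5, n_taxa = 10, seed = 1) * 20L
  m[1, ] <- 0L; m[1, 1] <- 99L # shallow sample
  depth <- 300
  suppressMessages(r1 <- rarefy(m, depth, seed = 5))
  expect_false("S01" %in% rownames(r1))
  expect_true(all(rowSums(r1) == depth))
  expect_true(all(r1 <= m[rownames(r1), ]))
  suppressMessages(r2 <- rarefy(m, depth, seed = 5))
  expect_identical(r1, r2)
  suppressMessages(r3 <- rarefy(m, depth, seed = 6))
  expect_false(identical(r1, r3))
})

test_that("rarefaction preserves expected per-taxon proportions", {
  x <- matrix(c(600L, 300L, 100L), 1, 3, dimnames = list("s", c("a", "b", "c")))
  reps <- sapply(1:100, function(s) rarefy(x, 200, seed = s)[1, ] / 200)
  # hypergeometric expectation equals the source proportions
  expect_equal(rowMeans(reps), c(a = 0.6, b = 0.3, c = 0.1), tolerance = 0.02)
})

test_that("prevalence_filter keeps taxa by sample occurrence", {
  m <- matrix(0L, 6, 3, dimnames = list(paste0("s", 1:6), c("a", "b", "c")))
  m[1:2, 1] <- 5L   # present in 2 samples
  m[1:3, 2] <- 1L   # present in 3 samples
  expect_equal(colnames(prevalence_filter(m, 3)), "b")
  expect_equal(colnames(prevalence_filter(m, 1)), c("a", "b")) # all-zero "c" removed
  expect_equal(prevalence_threshold(992), 248)
})

test_that("clr_transform centers rows and matches the two-taxon hand case", {
  m <- toy_counts()
  z <- clr_transform(m)
  expect_true(all(abs(rowSums(z)) < 1e-9))
  uniform <- matrix(7L, 1, 4, dimnames = list("u", paste0("t", 1:4)))
  expect_true(all(clr_transform(uniform) == 0))
  two <- matrix(c(9L, 99L), 1, 2, dimnames = list("s", c("a", "b")))
  expect_equal(as.numeric(clr_transform(two, 1)),
               c(-0.5 * log(10), 0.5 * log(10)))
  expect_error(clr_transform(m, pseudocount = 0), "positive")
})

test_that("alpha metrics match hand values", {
  m <- rbind(s1 = c(10L, 0L, 0L, 0L),
             s2 = c(5L, 5L, 5L, 5L),
             s3 = c(10L, 5L, 5L, 0L))
  colnames(m) <- paste0("t", 1:4)
  a <- alpha_metrics(m)
  expect_equal(a$shannon, c(0, 2, 1.5)) # single taxon; uniform 4; (.5,.25,.25)
  expect_equal(a$observed, c(1L, 4L, 3L))
  expect_true(is.na(a$pielou[1]))
  expect_equal(a$pielou[2], 1)
  zero <- matrix(0L, 1, 4, dimnames = list("z", paste0("t", 1:4)))
  expect_error(alpha_metrics(zero), "zero total")
})

test_that("Faith's PD matches the path-enumeration oracle and is monotone", {
  withr::local_seed(31)
  for (rep in 1:5) {
    ntip <- sample(4:8, 1)
    tree <- ape::rtree(ntip)
    tree$tip.label <- sprintf("t%02d", seq_len(ntip))
    m <- matrix(rbinom(3 * ntip, 1, 0.6), 3, ntip,
                dimnames = list(paste0("s", 1:3), tree$tip.label))
    m[rowSums(m) == 0, 1] <- 1L
    storage.mode(m) <- "integer"
    pd <- faith_pd(m, tree)
    oracle <- sapply(1:3, function(i) {
      oracle_faith_pd(tree, colnames(m)[m[i, ] > 0])
    })
    expect_equal(pd, oracle, tolerance = 1e-9)
    # adding an observed taxon never decreases PD
    i <- which(m[1, ] == 0)[1]
    if (!is.na(i)) {
      m2 <- m; m2[1, i] <- 1L
      expect_gte(faith_pd(m2, tree)[1], pd[1])
    }
  }
  # faith_pd is bounded by the total tree length
  tree <- ape::rtree(6); tree$tip.label <- sprintf("t%02d", 1:6)
  all_obs <- matrix(1L, 1, 6, dimnames = list("s", tree$tip.label))
  expect_lte(faith_pd(all_obs, tree), sum(tree$edge.length) + 1e-12)
})

test_that("unweighted UniFrac matches the branch-walk oracle and the trivial cases", {
  # identical presence sets -> 0
  m <- rbind(s1 = c(1L, 1L, 0L, 5L), s2 = c(2L, 7L, 0L, 1L))
  tree <- ape::rtree(4); tree$tip.label <- paste0("t", 1:4)
  colnames(m) <- tree$tip.label
  expect_equal(unweighted_unifrac(m, tree)["s1", "s2"], 0)

  # disjoint leaf sets on a star tree -> 1
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  md <- rbind(s1 = c(1L, 1L, 0L, 0L), s2 = c(0L, 0L, 1L, 1L))
  colnames(md) <- star$tip.label
  expect_equal(unweighted_unifrac(md, star)["s1", "s2"], 1)

  # 4-leaf tree with printed lengths vs exhaustive oracle
  toy <- ape::read.tree(text = "((a:0.1,b:0.2):0.3,(c:0.4,d:0.5):0.6);")
  mt <- rbind(s1 = c(1L, 0L, 1L, 0L), s2 = c(1L, 1L, 0L, 0L),
              s3 = c(0L, 0L, 0L, 1L))
  colnames(mt) <- c("a", "b", "c", "d")
  d <- unweighted_unifrac(mt, toy)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(d[i, j],
                 oracle_unifrac_pair(toy, colnames(mt)[mt[i, ] > 0],
                                     colnames(mt)[mt[j, ] > 0]),
                 tolerance = 1e-9)
  }
})

test_that("UniFrac satisfies metric axioms on random small instances", {
  withr::local_seed(8)
  for (rep in 1:5) {
    ntip <- sample(5:8, 1)
    tree <- ape::rtree(ntip); tree$tip.label <- sprintf("t%02d", seq_len(ntip))
    m <- matrix(rbinom(4 * ntip, 1, 0.5), 4, ntip,
                dimnames = list(paste0("s", 1:4), tree$tip.label))
    m[rowSums(m) == 0, 1] <- 1L
    storage.mode(m) <- "integer"
    d <- unweighted_unifrac(m, tree)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("pcoa embeds exact configurations and orders axes", {
  # collinear points: first axis reproduces the line
  x <- c(0, 1, 3, 7)
  d <- as.matrix(dist(x))
  p <- pcoa(d)
  recovered <- p$coordinates[, 1]
  expect_lt(max(abs(as.matrix(dist(recovered)) - d)), 1e-8)

  # 4-point planar configuration: distances reconstructed within 1e-8
  set.seed(2)
  pts <- matrix(rnorm(8), 4, 2)
  dp <- as.matrix(dist(pts))
  pp <- pcoa(dp)
  expect_lt(max(abs(as.matrix(dist(pp$coordinates)) - dp)), 1e-8)
  expect_true(all(diff(pp$eigenvalues) <= 1e-9))
  expect_lte(sum(pp$proportion_explained), 1 + 1e-12)
  expect_true(all(diff(pp$proportion_explained) <= 1e-12))

  # agreement with the ape reference implementation on a UniFrac matrix
  coh <- small_cohort(seed = 13, n = 12)
  du <- unweighted_unifrac(coh$feature_table, coh$tree)
  mine <- pcoa(du)
  ref <- ape::pcoa(as.dist(du))
  k <- min(3, ncol(mine$coordinates))
  for (ax in 1:k) {
    expect_equal(abs(cor(mine$coordinates[, ax], ref$vectors[, ax])), 1,
                 tolerance = 1e-6)
  }
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "asymmetric")
})
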