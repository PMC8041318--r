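test_that("SQ is the combined effect over summed single effects", {
  expect_equal(synergism_quotient(20, 20, 40), 1)
  expect_equal(synergism_quotient(20, 20, 50), 1.25)
  expect_equal(synergism_quotient(30, 30, 45), 0.75)
  expect_error(synergism_quotient(0, 0, 10), "undefined")
  expect_error(synergism_quotient(20, 120, 50), "\\[0, 100\\]")
})

test_that("SQ is scale invariant", {
  set.seed(13)
  for (r in 1:20) {
    a <- runif(1, 1, 40); b <- runif(1, 1, 40); cmb <- runif(1, 1, 90)
    cc <- runif(1, 0.2, min(1, 100 / max(a, b, cmb)))
    expect_equal(synergism_quotient(cc * a, cc * b, cc * cmb),
                 synergism_quotient(a, b, cmb), tolerance = 1e-12)
  }
})

test_that("classification honours the printed thresholds", {
  expect_identical(classify_sq(c(1.16, 1.02, 0.85)),
                   c("synergism", "additivity", "antagonism"))
  # closed additive band at both boundaries
  expect_identical(classify_sq(c(0.9, 1.1)),
                   c("additivity", "additivity"))
  expect_identical(classify_sq(1.1 + 1e-12), "synergism")
  expect_identical(classify_sq(0.9 - 1e-12), "antagonism")
  expect_error(classify_sq(0), "positive")
})

test_that("the +/-10 transform separates classes as printed", {
  expect_equal(transform_sq(0.85), -9.15)
  expect_equal(transform_sq(1.16), 11.16)
  expect_equal(transform_sq(1.0), 1.0)
  # the transform rule uses a closed bound at exactly 1.1
  expect_equal(transform_sq(1.1), 11.1)
  # monotone within classes, separated by >= 8.9 units across classes
  ant <- transform_sq(seq(0.01, 0.89, by = 0.01))
  add <- transform_sq(seq(0.90, 1.09, by = 0.01))
  syn <- transform_sq(seq(1.10, 3, by = 0.01))
  expect_true(all(diff(ant) > 0) && all(diff(add) > 0) &&
                all(diff(syn) > 0))
  expect_gte(min(add) - max(ant), 8.9)
  expect_gte(min(syn) - max(add), 8.9)
})

test_that("sq_matrix arranges combinations by cell line", {
  tab <- data.frame(cell_line = rep(c("A2780", "IGROV1"), each = 2),
                    drug_a = "FA-LR", dose_a = "250nM",
                    drug_b = rep(c("cDDP", "5FU"), 2), dose_b = "1uM",
                    inh_a_pct = 30, inh_b_pct = 30,
                    inh_combined_pct = c(45, 72, 60, 66))
  m <- sq_matrix(tab)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["FA-LR+cDDP@250nM/1uM", "A2780"], 0.75)
  expect_equal(m["FA-LR+5FU@250nM/1uM", "IGROV1"], 1.1)
  expect_error(sq_matrix(tab[, -1]), "missing column")
})

test_that("clustering is deterministic with class-dominated distances", {
  m <- rbind(ant1 = c(0.8, 0.8), ant2 = c(0.8, 0.8),
             syn1 = c(1.2, 1.2), add1 = c(1.0, 0.95))
  colnames(m) <- c("A2780", "IGROV1")
  cl <- cluster_sq(m)
  # identical rows merge first at height 0
  expect_equal(cl$hclust$height[1], 0)
  first <- cl$hclust$merge[1, ]
  expect_setequal(rownames(m)[-first], c("ant1", "ant2"))
  # transformed antagonism/synergism rows are >= 20*sqrt(2) - eps apart
  dd <- as.matrix(dist(transform_sq(m)))
  expect_gte(dd["ant1", "syn1"], 20 * sqrt(2) - 1)
  expect_error(cluster_sq(m[1, , drop = FALSE]), "at least 2")
  m2 <- m; m2[1] <- NA
  expect_error(cluster_sq(m2), "complete")
})

test_that("row permutation changes labels only, not topology", {
  set.seed(14)
  m <- matrix(runif(24, 0.5, 1.5), 8, 3,
              dimnames = list(paste0("c", 1:8), c("A", "B", "C")))
  cl1 <- cluster_sq(m)
  perm <- sample(8)
  cl2 <- cluster_sq(m[perm, ])
  expect_equal(sort(cl1$hclust$height), sort(cl2$hclust$height),
               tolerance = 1e-12)
  # cophenetic distances between the same labelled leaves are identical
  d1 <- as.matrix(stats::cophenetic(cl1$hclust))
  d2 <- as.matrix(stats::cophenetic(cl2$hclust))
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-12)
})

test_that("newick export round-trips through ape", {
  m <- rbind(a = c(0.8, 0.85), b = c(1.2, 1.3), c = c(1.0, 1.02))
  colnames(m) <- c("A", "B")
  nwk <- sq_newick(cluster_sq(m))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(m))
})
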