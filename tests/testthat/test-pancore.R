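test_that("percentages are truncated, not rounded", {
  expect_equal(truncate_percent(31, 77), 40.2)
  expect_equal(truncate_percent(2918, 3016), 96.7)
  expect_equal(truncate_percent(0, 5), 0.0)
  expect_equal(truncate_percent(1, 3), 33.3)
  expect_equal(truncate_percent(2, 3), 66.6)  # floor, not round-half-up
  expect_error(truncate_percent(1, 0), "denominator")
  expect_error(truncate_percent(5, 3), "numerator")
})

test_that("shared content summarises row sums with a lower median", {
  m <- matrix(1L, nrow = 5, ncol = 10,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:10)))
  sc <- shared_content(m)
  expect_equal(sc$min$count, 10L)
  expect_equal(sc$median$count, 10L)
  expect_equal(sc$max$percent, 100.0)

  m2 <- matrix(c(1L, 1L, 0L, 0L,
                 1L, 1L, 1L, 0L,
                 1L, 1L, 1L, 1L,
                 1L, 0L, 0L, 0L), nrow = 4, byrow = TRUE,
               dimnames = list(paste0("s", 1:4), paste0("g", 1:4)))
  sc2 <- shared_content(m2)
  expect_equal(sc2$per_strain$shared_count, c(2L, 3L, 4L, 1L))
  # even cohort: lower median of {1,2,3,4} is 2
  expect_equal(sc2$median$count, 2L)
  expect_equal(sc2$min$count, 1L)
  expect_equal(sc2$max$count, 4L)
})

test_that("core genome is the column-wise intersection", {
  m <- matrix(1L, nrow = 1, ncol = 7,
              dimnames = list("s1", paste0("g", 1:7)))
  expect_equal(core_genome(m)$core_size, 7L)
  set.seed(12)
  m2 <- matrix(rbinom(10 * 50, 1, 0.8), nrow = 10,
               dimnames = list(paste0("s", 1:10), paste0("g", 1:50)))
  storage.mode(m2) <- "integer"
  core <- core_genome(m2)
  # brute force: intersect the row supports
  supports <- lapply(1:10, function(i) colnames(m2)[m2[i, ] == 1L])
  expect_setequal(core$core_tags, Reduce(intersect, supports))
  expect_equal(core$core_percent, truncate_percent(core$core_size, 50))
  # invariants: core never exceeds the smallest row; adding strains shrinks it
  expect_lte(core$core_size, min(rowSums(m2)))
  expect_lte(core$core_size, core_genome(m2[1:5, ])$core_size)
})

test_that("accumulation curve matches exhaustive enumeration on a 5x20 matrix", {
  set.seed(4)
  m <- matrix(rbinom(5 * 20, 1, 0.7), nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:20)))
  storage.mode(m) <- "integer"
  acc <- core_accumulation(m, exact = TRUE)
  # independent oracle: the mean over permutation prefixes of size k equals
  # the mean core size over all k-subsets
  oracle <- vapply(1:5, function(k) {
    subsets <- utils::combn(5, k, simplify = FALSE)
    mean(vapply(subsets, function(s) {
      sum(colSums(m[s, , drop = FALSE]) == k)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(acc$mean_core, oracle)
  expect_equal(acc$mean_core[5], core_genome(m)$core_size)
  expect_equal(acc$mean_core[1], mean(rowSums(m)))
})

test_that("accumulation curves are monotone and constant for all-ones", {
  m <- matrix(1L, nrow = 6, ncol = 9,
              dimnames = list(paste0("s", 1:6), paste0("g", 1:9)))
  acc <- core_accumulation(m, n_permutations = 5, seed = 1)
  expect_true(all(acc$mean_core == 9))
  set.seed(77)
  for (i in 1:3) {
    m2 <- matrix(rbinom(8 * 30, 1, runif(1, 0.5, 0.95)), nrow = 8,
                 dimnames = list(paste0("s", 1:8), paste0("g", 1:30)))
    storage.mode(m2) <- "integer"
    acc2 <- core_accumulation(m2, n_permutations = 30, seed = i)
    expect_true(all(diff(acc2$mean_core) <= 1e-12))
    expect_equal(acc2$mean_core[8], core_genome(m2)$core_size)
  }
})

test_that("UPGMA heights match a brute-force implementation", {
  m <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L,
                1L, 1L, 0L, 0L, 0L, 1L,
                0L, 0L, 1L, 1L, 1L, 0L,
                0L, 1L, 1L, 1L, 0L, 0L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:6)))
  cl <- gene_content_clustering(m)
  expect_equal(sort(cl$hclust$height), upgma_heights_oracle(cl$dist))
  set.seed(19)
  m2 <- matrix(rbinom(7 * 40, 1, 0.6), nrow = 7,
               dimnames = list(paste0("s", 1:7), paste0("g", 1:40)))
  storage.mode(m2) <- "integer"
  m2[, 1] <- 1L  # no empty rows
  cl2 <- gene_content_clustering(m2)
  expect_equal(sort(cl2$hclust$height), upgma_heights_oracle(cl2$dist),
               tolerance = 1e-12)
})

test_that("identical gene content merges at height zero", {
  m <- matrix(c(1L, 0L, 1L,
                1L, 0L, 1L,
                0L, 1L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("g1", "g2", "g3")))
  cl <- gene_content_clustering(m)
  expect_equal(min(cl$hclust$height), 0)
  expect_equal(as.matrix(cl$dist)["a", "b"], 0)
})

test_that("SNP trees recover planted divergence structure", {
  ref <- tiny_ref()
  base <- as.character(ref$sequence)
  L <- nchar(base)
  set.seed(23)
  variant <- mutate_seq(ref$sequence, sample(L, round(0.04 * L)))
  mk <- function(id, src, rate) {
    s <- mutate_seq(Biostrings::DNAString(src), sample(L, round(rate * L)))
    strain_genome(id, "other", Biostrings::DNAStringSet(setNames(s, id)))
  }
  strains <- list(mk("a1", base, 0.005), mk("a2", base, 0.005),
                  mk("b1", variant, 0.005), mk("b2", variant, 0.005))
  core <- ref$genes$locus_tag
  res <- snp_distance_tree(strains, ref, core)
  dm <- as.matrix(res$dist)
  expect_equal(unname(diag(dm)), rep(0, 4))
  expect_equal(dm, t(dm))
  # within-pair distances are far smaller than between-pair ones
  expect_lt(dm["a1", "a2"], dm["a1", "b1"])
  expect_lt(dm["b1", "b2"], dm["b1", "a2"])
  # NJ groups the pairs: a1 and a2 are siblings
  tr <- res$tree
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("a1", "a2")))
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("b1", "b2")))
})

test_that("identical strains give a zero-distance star-like tree", {
  ref <- tiny_ref()
  s <- as.character(ref$sequence)
  strains <- lapply(c("x", "y", "z", "w"), function(id) {
    strain_genome(id, "other", Biostrings::DNAStringSet(setNames(s, id)))
  })
  res <- snp_distance_tree(strains, ref, ref$genes$locus_tag)
  expect_true(all(as.matrix(res$dist) == 0))
  expect_true(all(res$tree$edge.length < 1e-12))
})

test_that("tree concordance is 1 for a tree vs itself and ~0 for shuffles", {
  set.seed(6)
  tr <- ape::rtree(12)
  expect_equal(tree_concordance(tr, tr), 1.0)
  # leaf-order rotation does not change the score
  rot <- ape::rotate(tr, 14)
  expect_equal(tree_concordance(tr, rot), 1.0)
  scores <- replicate(100, {
    sh <- tr
    sh$tip.label <- sample(sh$tip.label)
    tree_concordance(tr, sh)
  })
  expect_lt(mean(scores), 0.25)
})

test_that("COG partitions tally non-core genes per category", {
  genes <- data.frame(
    locus_tag = paste0("g", 1:6),
    start = seq(1, 501, by = 100), end = seq(50, 550, by = 100),
    strand = "+", product = "p",
    cog_category = c("G", "G", "G", "L", "L", NA),
    stringsAsFactors = FALSE
  )
  ann <- reference_annotation("x", 1000L, genes)
  part <- cog_partition(ann, core_tags = c("g1", "g4", "g6"))
  g_row <- part[part$cog_category == "G", ]
  expect_equal(g_row$total, 3L)
  expect_equal(g_row$non_core, 2L)
  expect_equal(g_row$percent_non_core, 66.6)
  l_row <- part[part$cog_category == "L", ]
  expect_equal(l_row$non_core, 1L)
  # all genes core -> zero percentages
  part0 <- cog_partition(ann, core_tags = genes$locus_tag)
  expect_true(all(part0$percent_non_core == 0))
})

test_that("niche content comparison separates shifted groups", {
  n_genes <- 1000L
  counts <- c(round(rnorm(20, 900, 10)), round(rnorm(20, 960, 10)))
  m <- t(vapply(counts, function(k) {
    c(rep(1L, k), rep(0L, n_genes - k))
  }, integer(n_genes)))
  rownames(m) <- paste0("s", 1:40)
  colnames(m) <- paste0("g", 1:n_genes)
  sc <- shared_content(m)
  niches <- setNames(c(rep("dairy", 20), rep("intestinal", 20)),
                     rownames(m))
  res <- niche_content_comparison(sc, niches)
  expect_lt(res$p_value, 0.001)
  expect_lt(res$group_means[["dairy"]], res$group_means[["human"]])
  # identical groups: no evidence of a shift
  m_id <- m[c(1:5, 1:5), ]
  rownames(m_id) <- paste0("t", 1:10)
  sc_id <- shared_content(m_id)
  niches_id <- setNames(c(rep("dairy", 5), rep("intestinal", 5)),
                        rownames(m_id))
  expect_equal(niche_content_comparison(sc_id, niches_id)$p_value, 1,
               tolerance = 1e-9)
  # empty group errors
  expect_error(
    niche_content_comparison(sc, setNames(rep("dairy", 40), rownames(m))),
    "size 0")
})
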