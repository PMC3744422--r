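test_that("simulated references have the requested island structure", {
  ref <- simulate_reference(n_genes = 100, n_islands = 2,
                            island_sizes = c(8L, 10L), genome_length = 120000,
                            seed = 1)
  expect_equal(nrow(ref$genes), 100L)
  expect_equal(nrow(ref$islands), 2L)
  sizes <- ref$islands$last_index - ref$islands$first_index + 1L
  expect_equal(sizes, c(8L, 10L))
  # islands are contiguous gene runs
  for (j in 1:2) {
    run <- ref$islands$first_index[j]:ref$islands$last_index[j]
    expect_true(all(ref$genes$island_id[run] == ref$islands$island_id[j]))
  }
  expect_true(all(is.na(ref$genes$island_id[-unlist(
    lapply(1:2, function(j) ref$islands$first_index[j]:ref$islands$last_index[j])
  )])))
})

test_that("simulation is deterministic for a fixed seed", {
  r1 <- simulate_reference(n_genes = 50, n_islands = 1, island_sizes = 6L,
                           genome_length = 60000, seed = 9)
  r2 <- simulate_reference(n_genes = 50, n_islands = 1, island_sizes = 6L,
                           genome_length = 60000, seed = 9)
  expect_equal(as.character(r1$sequence), as.character(r2$sequence))
  expect_identical(r1$genes, r2$genes)
  prof <- default_niche_profiles()$dairy
  s1 <- simulate_strain(r1, prof, seed = 4)
  s2 <- simulate_strain(r2, prof, seed = 4)
  expect_equal(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$truth$lost_gene_tags, s2$truth$lost_gene_tags)
})

test_that("infeasible packings are rejected", {
  expect_error(simulate_reference(n_genes = 10, n_islands = 2,
                                  island_sizes = c(6L, 6L),
                                  genome_length = 20000, seed = 1),
               "infeasible")
  expect_error(simulate_reference(n_genes = 100, n_islands = 1,
                                  island_sizes = 3L,
                                  genome_length = 120000, seed = 1),
               "at least 5")
  expect_error(simulate_reference(n_genes = 100, n_islands = 0,
                                  island_sizes = integer(0),
                                  genome_length = 10000, seed = 1),
               "infeasible")
})

test_that("a loss-free, mutation-free profile reproduces the reference", {
  ref <- tiny_ref()
  prof <- niche_profile("intestinal",
                        island_loss_probs = c(GI1 = 0, GI2 = 0),
                        background_loss_prob = 0, snp_rate = 0,
                        spacer_retention = 8L)
  st <- simulate_strain(ref, prof, seed = 3)
  expect_equal(as.character(st$sequences[[1]]), as.character(ref$sequence))
  expect_length(st$truth$lost_gene_tags, 0)
  expect_equal(st$truth$retained_spacer_indices, 1:8)
})

test_that("island loss is all-or-none per island", {
  ref <- tiny_ref()
  prof <- niche_profile("dairy", island_loss_probs = c(GI1 = 1, GI2 = 1),
                        background_loss_prob = 0, snp_rate = 0,
                        spacer_retention = 2L)
  st <- simulate_strain(ref, prof, seed = 3)
  island_tags <- ref$genes$locus_tag[!is.na(ref$genes$island_id)]
  expect_setequal(st$truth$lost_gene_tags, island_tags)
  expect_setequal(st$truth$lost_islands, c("GI1", "GI2"))
})

test_that("observed mismatch fraction matches the binomial substitution model", {
  ref <- tiny_ref()
  rate <- 0.05
  prof <- niche_profile("other", island_loss_probs = c(GI1 = 0, GI2 = 0),
                        background_loss_prob = 0, snp_rate = rate,
                        spacer_retention = 8L)
  st <- simulate_strain(ref, prof, seed = 11)
  a <- strsplit(as.character(ref$sequence), "")[[1]]
  b <- strsplit(as.character(st$sequences[[1]]), "")[[1]]
  expect_length(b, length(a))
  frac <- mean(a != b)
  n <- length(a)
  sd3 <- 3 * sqrt(rate * (1 - rate) / n)
  expect_lt(abs(frac - rate), sd3)
})

test_that("cohorts have the requested composition and noiseless phenotypes", {
  ref <- tiny_ref()
  profs <- default_niche_profiles()
  # tiny_ref has islands GI1 (pili) and GI2 (fucose) only
  cohort <- simulate_cohort(ref, c(dairy = 23L, intestinal = 16L), profs,
                            seed = 2)
  expect_length(cohort$strains, 39L)
  expect_equal(sum(cohort$niches == "dairy"), 23L)
  expect_equal(sum(cohort$niches == "intestinal"), 16L)
  expect_equal(nrow(cohort$phenotypes), 39L)
  # phenotype_noise 0: observed phenotypes equal the rule outputs exactly
  for (i in c(1L, 30L)) {
    st <- cohort$strains[[i]]
    ph <- st$truth$true_phenotypes
    row <- cohort$phenotypes[cohort$phenotypes$strain_id == st$strain_id, ]
    expect_identical(row$bile, ph$bile)
    expect_identical(row$pilosotype, ph$pilosotype)
    expect_equal(row$mucus_binding, ph$mucus_binding)
    expect_identical(unname(unlist(row[paste0("api_", names(ph$api_calls))])),
                     unname(ph$api_calls))
  }
})

test_that("dairy pili-island loss frequency matches its loss probability", {
  ref <- tiny_ref()
  profs <- default_niche_profiles()
  cohort <- simulate_cohort(ref, c(dairy = 60L), profs, seed = 8)
  p <- profs$dairy$island_loss_probs[["GI1"]]
  lacking <- mean(vapply(cohort$strains,
                         function(s) "GI1" %in% s$truth$lost_islands,
                         logical(1)))
  sd3 <- 3 * sqrt(p * (1 - p) / 60)
  expect_lt(abs(lacking - p), sd3)
})

test_that("growth curves follow the logistic model and scale linearly", {
  tp <- seq(0, 15, by = 0.5)
  params <- list(K = 1.2, r = 0.6, t_mid = 6)
  ctrl <- simulate_growth_curve(params, 1, tp, noise_sd = 0)
  expected <- 1.2 / (1 + exp(-0.6 * (tp - 6)))
  expect_equal(ctrl$od, expected)
  half <- simulate_growth_curve(params, 0.5, tp, noise_sd = 0)
  expect_equal(trapezoid_auc(half), trapezoid_auc(ctrl) / 2)
  n1 <- simulate_growth_curve(params, 1, tp, noise_sd = 0.01, seed = 5)
  n2 <- simulate_growth_curve(params, 1, tp, noise_sd = 0.01, seed = 5)
  expect_identical(n1$od, n2$od)
  expect_true(all(n1$od >= 0))
})
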