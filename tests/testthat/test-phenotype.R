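test_that("trapezoid AUC matches closed forms and an independent recomputation", {
  flat <- growth_curve(c(0, 15), c(1, 1))
  expect_equal(trapezoid_auc(flat), 15.0)
  lin <- growth_curve(seq(0, 10, 0.5), seq(0, 1, 0.05))
  expect_equal(trapezoid_auc(lin), 5.0)
  noisy <- simulate_growth_curve(noise_sd = 0.01, seed = 2)
  manual <- sum(diff(noisy$timepoints) *
                  (head(noisy$od, -1) + tail(noisy$od, -1)) / 2)
  expect_equal(trapezoid_auc(noisy), manual, tolerance = 1e-9)
  expect_error(growth_curve(c(0, 1, 1), c(1, 1, 1)), "strictly increasing")
})

test_that("ARP is 0 for identical curves, 50 for half-scaled, negative for growth", {
  ctrl <- simulate_growth_curve()
  expect_equal(compute_arp(ctrl, ctrl), 0.0)
  half <- growth_curve(ctrl$timepoints, ctrl$od * 0.5)
  expect_equal(compute_arp(half, ctrl), 50.0)
  boosted <- growth_curve(ctrl$timepoints, ctrl$od * 1.3)
  expect_lt(compute_arp(boosted, ctrl), 0)
  # invariant under joint rescaling of both curves
  scaled_s <- growth_curve(ctrl$timepoints, half$od * 3.7)
  scaled_c <- growth_curve(ctrl$timepoints, ctrl$od * 3.7)
  expect_equal(compute_arp(scaled_s, scaled_c), 50.0)
  # grid mismatch and zero control are errors
  other <- growth_curve(ctrl$timepoints + 0.25, ctrl$od)
  expect_error(compute_arp(other, ctrl), "time grid")
  zero <- growth_curve(ctrl$timepoints, rep(0, length(ctrl$timepoints)))
  expect_error(compute_arp(ctrl, zero), "positive")
})

test_that("mucus binding percentages behave at the assay extremes", {
  expect_equal(mucus_binding_percent(0, 50), 0.0)
  expect_equal(mucus_binding_percent(50, 50), 100.0)
  expect_equal(mucus_binding_percent(29.9, 100), 29.9)
  expect_error(mucus_binding_percent(10, 0), "> 0")
  expect_error(mucus_binding_percent(60, 50), "bound_signal")
})

test_that("pilosotype combines the genomic call with assay evidence", {
  row <- setNames(c(1L, 1L, 1L, 0L), c("spaA", "spaB", "spaC", "other"))
  pili <- c("spaA", "spaB", "spaC")
  expect_identical(pilosotype_call(row, pili, "positive"), "positive")
  # conserved cluster but failed binding assay: negative
  expect_identical(pilosotype_call(row, pili, "negative"), "negative")
  expect_identical(pilosotype_call(row, pili), "positive")
  row["spaB"] <- 0L
  expect_identical(pilosotype_call(row, pili), "negative")
  expect_identical(pilosotype_call(row, pili, "positive"), "negative")
})

test_that("group contingency reproduces truncated percentages and tests", {
  calls <- setNames(c(rep("positive", 31), rep("negative", 46),
                      rep("positive", 3), rep("negative", 20)),
                    paste0("s", 1:100))
  labels <- setNames(c(rep("human", 77), rep("dairy", 23)),
                     paste0("s", 1:100))
  res <- group_contingency(calls, labels)
  tab <- res$table
  expect_equal(tab$percent[tab$group == "human"], 40.2)
  expect_equal(tab$percent[tab$group == "dairy"], 13.0)
  expect_equal(tab$total, c(77L, 23L))
  expect_false(is.na(res$p_value))
  # 9/16 intestinal sub-row
  sub <- group_contingency(
    setNames(c(rep("positive", 9), rep("negative", 7)), paste0("i", 1:16)),
    setNames(rep("intestinal", 16), paste0("i", 1:16)),
    test_groups = c("a", "b"))
  expect_equal(sub$table$percent, 56.2)
  expect_true(is.na(sub$p_value))
})

test_that("sugar group scores weigh partial calls at one half", {
  sugars <- unlist(sugar_groups)
  api <- setNames(rep("negative", length(sugars)), sugars)
  api[sugar_groups$I] <- "positive"
  s <- sugar_group_scores(api)
  expect_equal(unname(s), c(1, 0, 0))
  api2 <- setNames(rep("negative", length(sugars)), sugars)
  api2["D-maltose"] <- "partial"
  expect_equal(sugar_group_scores(api2)[["score_II"]], 0.125)
  expect_error(sugar_group_scores(api[-1]), "missing sugars")
})

mk_profile <- function(n_cons, n_total = 8) {
  structure(list(strain_id = "x",
                 spacer_status = c(rep("conserved", n_cons),
                                   rep("absent", n_total - n_cons)),
                 cas_status = rep("present", 2)),
            class = "crispr_profile")
}

mk_record <- function(fucose, bile, pilo) {
  sugars <- unlist(sugar_groups)
  api <- setNames(rep(if (fucose) "negative" else "positive",
                      length(sugars)), sugars)
  api[sugar_groups$I] <- if (fucose) "positive" else "negative"
  list(strain_id = "x", api_calls = api, bile = bile,
       mucus_binding = if (pilo) 18 else 0.4,
       pilosotype = if (pilo) "positive" else "negative")
}

test_that("the classifier separates A, B and B-delta-spaCBA strains", {
  tags <- paste0("g", 1:40)
  spacba <- paste0("g", 11:15)
  cfg <- genopheno_config(spacba_tags = spacba)
  # intestinal-like strain: everything B-oriented
  row_b <- setNames(rep(1L, 40), tags)
  gp_b <- score_genophenotype(row_b, mk_profile(8),
                              mk_record(TRUE, "resistant", TRUE), cfg)
  expect_identical(gp_b$class, "B")
  expect_true(all(gp_b$axis_scores >= 0 & gp_b$axis_scores <= 1))
  # dairy-like strain: pili and fucose islands lost, few spacers
  row_a <- setNames(rep(1L, 40), tags)
  row_a[paste0("g", 5:30)] <- 0L
  gp_a <- score_genophenotype(row_a, mk_profile(2),
                              mk_record(FALSE, "sensitive", FALSE), cfg)
  expect_identical(gp_a$class, "A")
  # B-trait strain with the spaCBA island deleted
  row_bd <- setNames(rep(1L, 40), tags)
  row_bd[spacba] <- 0L
  gp_bd <- score_genophenotype(row_bd, mk_profile(8),
                               mk_record(TRUE, "resistant", FALSE), cfg)
  expect_identical(gp_bd$class, "B_dspaCBA")
  # classification is a pure function: rerunning gives identical output
  gp_b2 <- score_genophenotype(row_b, mk_profile(8),
                               mk_record(TRUE, "resistant", TRUE), cfg)
  expect_identical(gp_b$axis_scores, gp_b2$axis_scores)
  expect_identical(gp_b$class, gp_b2$class)
})

test_that("intermediate strains stay unassigned", {
  tags <- paste0("g", 1:40)
  cfg <- genopheno_config(spacba_tags = paste0("g", 11:15))
  row <- setNames(rep(1L, 40), tags)
  gp <- score_genophenotype(row, mk_profile(4),
                            mk_record(FALSE, "resistant", TRUE), cfg)
  expect_gt(gp$mean_score, cfg$a_cut)
  expect_lt(gp$mean_score, cfg$b_cut)
  expect_identical(gp$class, "unassigned")
})

test_that("cohort reports count classes per niche", {
  ref <- tiny_ref()
  profs <- default_niche_profiles()
  cohort <- simulate_cohort(ref, c(dairy = 4L, intestinal = 4L), profs,
                            seed = 33)
  m <- build_presence_matrix(ref, cohort$strains)
  oli <- oligotype_cohort(ref$crispr, cohort$strains)
  classified <- classify_cohort(m, oli, cohort$phenotypes,
                                genopheno_config(ref))
  rep <- cohort_genophenotype_report(classified, cohort$niches)
  expect_equal(nrow(rep$class_counts), 2L)
  expect_equal(sum(unlist(rep$class_counts[, c("A", "B", "B_dspaCBA",
                                               "unassigned")])), 8L)
  expect_equal(nrow(rep$axis_means), 2L)
})
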