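test_that("reference CRISPR descriptors are validated", {
  sp <- Biostrings::DNAStringSet(c(a = rand_dna(30), b = rand_dna(30)))
  cas <- Biostrings::DNAStringSet(c(cas9 = rand_dna(300)))
  rc <- reference_crispr(sp, cas)
  expect_length(rc$spacers, 2L)
  expect_error(reference_crispr(Biostrings::DNAStringSet(c(rand_dna(10))),
                                cas), "20-50")
  dup <- rand_dna(30)
  expect_error(reference_crispr(Biostrings::DNAStringSet(c(dup, dup)), cas),
               "unique")
})

test_that("spacer typing distinguishes conserved, partial and absent", {
  set.seed(61)
  spacer <- rand_dna(30)
  strain_with <- Biostrings::DNAStringSet(
    paste0(rand_dna(3000), spacer, rand_dna(3000)))
  expect_identical(type_spacer(spacer, strain_with)$status, "conserved")
  # a single substitution stays conserved
  one_snp <- mutate_seq(Biostrings::DNAString(spacer), 15)
  strain_snp <- Biostrings::DNAStringSet(
    paste0(rand_dna(3000), one_snp, rand_dna(3000)))
  expect_identical(type_spacer(spacer, strain_snp)$status, "conserved")
  # 5' half exact, 3' half scrambled: partial
  half <- paste0(substr(spacer, 1, 15), rand_dna(15))
  strain_half <- Biostrings::DNAStringSet(
    paste0(rand_dna(3000), substr(spacer, 1, 15), rand_dna(3015)))
  res_half <- type_spacer(spacer, strain_half)
  expect_identical(res_half$status, "partial")
  expect_gte(res_half$coverage, 0.5)
  # strain lacking the locus entirely
  expect_identical(type_spacer(spacer,
                               Biostrings::DNAStringSet(rand_dna(6000)))$status,
                   "absent")
})

test_that("cas typing follows the ortholog presence rule", {
  set.seed(62)
  cas <- rand_dna(600)
  strain <- Biostrings::DNAStringSet(paste0(rand_dna(2000), cas,
                                            rand_dna(2000)))
  expect_identical(type_cas(cas, strain), "present")
  junk <- Biostrings::DNAStringSet(rand_dna(4600))
  expect_identical(type_cas(cas, junk), "absent")
  o <- sw_oracle(cas, as.character(junk[[1]]))
  expect_lt(o$coverage, 0.8)
})

test_that("the reference strain oligotypes as fully conserved", {
  ref <- tiny_ref()
  self <- strain_genome("self", "intestinal",
                        Biostrings::DNAStringSet(
                          setNames(as.character(ref$sequence), "chr")))
  oli <- oligotype_cohort(ref$crispr, list(self))
  p <- oli$profiles[[1]]
  expect_true(all(p$spacer_status == "conserved"))
  expect_true(all(p$cas_status == "present"))
  expect_equal(unname(oli$shared_counts), length(ref$crispr$spacers))
  expect_equal(nrow(oli$table), 1L)
})

test_that("simulated spacer retention is recovered exactly at snp_rate 0", {
  ref <- tiny_ref()
  for (keep in c(0L, 3L, 8L)) {
    prof <- niche_profile("dairy", island_loss_probs = c(GI1 = 0.5, GI2 = 0.5),
                          background_loss_prob = 0.02, snp_rate = 0,
                          spacer_retention = keep)
    st <- simulate_strain(ref, prof, seed = 70 + keep)
    oli <- oligotype_cohort(ref$crispr, list(st))
    expect_equal(unname(oli$shared_counts), keep)
    p <- oli$profiles[[1]]
    expect_true(all(p$spacer_status[st$truth$retained_spacer_indices] ==
                      "conserved"))
    expect_true(all(p$cas_status == "present"))
  }
})

test_that("a strain that kept cas but no spacers types accordingly", {
  ref <- tiny_ref()
  prof <- niche_profile("clinical", island_loss_probs = c(GI1 = 0, GI2 = 0),
                        background_loss_prob = 0, snp_rate = 0,
                        spacer_retention = 0L)
  st <- simulate_strain(ref, prof, seed = 81)
  oli <- oligotype_cohort(ref$crispr, list(st))
  p <- oli$profiles[[1]]
  expect_true(all(p$spacer_status == "absent"))
  expect_true(all(p$cas_status == "present"))
})

test_that("protospacer search finds planted targets and nothing else", {
  set.seed(63)
  spacers <- Biostrings::DNAStringSet(
    setNames(vapply(1:4, function(i) rand_dna(30), character(1)),
             paste0("sp", 1:4)))
  phage1 <- paste0(rand_dna(1200), as.character(spacers[[1]]), rand_dna(800))
  # spacer 2 planted in two phages (multi-hit case), one on the minus strand
  phage2 <- paste0(rand_dna(500), as.character(spacers[[2]]), rand_dna(1500))
  phage3 <- paste0(rand_dna(900),
                   as.character(Biostrings::reverseComplement(spacers[[2]])),
                   rand_dna(700))
  db <- Biostrings::DNAStringSet(c(phA = phage1, phB = phage2, phC = phage3))
  hits <- protospacer_search(spacers, db)
  expect_equal(sum(hits$spacer == "sp1"), 1L)
  expect_equal(hits$target[hits$spacer == "sp1"], "phA")
  expect_equal(hits$identity[hits$spacer == "sp1"], 1.0)
  expect_equal(hits$coverage[hits$spacer == "sp1"], 1.0)
  expect_setequal(hits$target[hits$spacer == "sp2"], c("phB", "phC"))
  expect_false(any(hits$spacer %in% c("sp3", "sp4")))
  expect_error(protospacer_search(spacers, Biostrings::DNAStringSet()),
               "empty database")
})

test_that("search is complete against an exhaustive-scan oracle", {
  set.seed(64)
  spacers <- Biostrings::DNAStringSet(
    setNames(vapply(1:6, function(i) rand_dna(32), character(1)),
             paste0("sp", 1:6)))
  # plant mildly mutated protospacers (>= 90% identity) in a larger database
  db_seqs <- vapply(1:3, function(i) rand_dna(20000), character(1))
  planted <- list()
  for (i in 1:5) {
    tgt <- sample(3, 1)
    proto <- mutate_seq(spacers[[i]], sample(32, 2))  # ~94% identity
    at <- sample(15000, 1)
    db_seqs[tgt] <- paste0(substr(db_seqs[tgt], 1, at), proto,
                           substr(db_seqs[tgt], at + 1, nchar(db_seqs[tgt])))
    planted[[i]] <- c(spacer = paste0("sp", i), target = paste0("db", tgt))
  }
  db <- Biostrings::DNAStringSet(setNames(db_seqs, paste0("db", 1:3)))
  hits <- protospacer_search(spacers, db)
  for (pl in planted) {
    expect_true(any(hits$spacer == pl["spacer"] &
                      hits$target == pl["target"]),
                info = paste("missed", pl["spacer"], "in", pl["target"]))
  }
  # oracle: direct full local alignment of each planted pair passes the cutoff
  for (pl in planted) {
    al <- panpheno:::local_align(
      spacers[pl["spacer"]], db[pl["target"]])
    st <- panpheno:::alignment_stats(al, 32)
    expect_gte(st$identity, 0.85)
    expect_gte(st$coverage, 0.80)
  }
})

test_that("profile distances count partial conservation as half a match", {
  mk <- function(sp, cas) {
    structure(list(strain_id = "x", spacer_status = sp, cas_status = cas),
              class = "crispr_profile")
  }
  a <- mk(rep("conserved", 4), c("present", "present"))
  expect_equal(profile_distance(a, a), 0)
  b <- mk(rep("absent", 4), c("absent", "absent"))
  expect_equal(profile_distance(a, b), 1)
  # hand-computed: statuses (C,P,A,C) vs (C,A,P,A), cas (1,1) vs (1,0)
  x <- mk(c("conserved", "partial", "absent", "conserved"),
          c("present", "present"))
  y <- mk(c("conserved", "absent", "partial", "absent"),
          c("present", "absent"))
  # mismatches: 0 + 0.5 + 0.5 + 1 + 0 + 1 = 3 over 6 slots
  expect_equal(profile_distance(x, y), 0.5)
  expect_error(profile_distance(a, mk(rep("absent", 3), c("absent"))),
               "different loci")
})
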