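#' Carbohydrate panels used by the geno-phenotype axes
#'
#' Sugar groups scored by the classifier: group I (dulcitol, D-arabinose,
#' L-fucose) marks intestinal-adapted strains, groups II (D-saccharose,
#' D-maltose, methyl-alpha-D-glucopyranoside, D-turanose) and III
#' (L-rhamnose, L-sorbose, D-ribose, D-lactose) mark dairy-adapted strains.
#'
#' @format named list of character vectors.
#' @export
sugar_groups <- list(
  I = c("dulcitol", "D-arabinose", "L-fucose"),
  II = c("D-saccharose", "D-maltose", "methyl-alpha-D-glucopyranoside",
         "D-turanose"),
  III = c("L-rhamnose", "L-sorbose", "D-ribose", "D-lactose")
)

basal_sugars <- c("D-glucose", "D-galactose", "D-fructose", "D-mannose")

niche_vocabulary <- c("dairy", "intestinal", "oral", "vaginal", "clinical",
                      "other")

arp_conditions <- c("E_coli_pH5.0", "E_coli_pH6.2",
                    "L_monocytogenes_pH5.0", "L_monocytogenes_pH6.2",
                    "Y_enterocolitica_pH5.0", "Y_enterocolitica_pH6.2")

#' Construct a niche profile for the cohort simulator
#'
#' A niche profile encodes how strains from one ecological niche diverge
#' from the reference: which genomic islands they tend to lose (all-or-none
#' per island), the background per-gene loss probability, the substitution
#' rate, how many reference CRISPR spacers they retain, and how noisy their
#' measured phenotypes are. Phenotypes themselves are produced by
#' `phenotype_rules`, a function of the island retention pattern, so that
#' genotype and phenotype stay deterministically coupled.
#'
#' @param niche_name one of dairy, intestinal, oral, vaginal, clinical, other.
#' @param island_loss_probs named vector, island_id -> loss probability.
#' @param background_loss_prob per-gene loss probability outside islands.
#' @param snp_rate substitutions per site in [0, 0.3].
#' @param spacer_retention number of reference spacers retained (the
#'   trailer-proximal, i.e. oldest, spacers are kept).
#' @param phenotype_rules function(islands_present, roles) returning the
#'   noiseless phenotype record; defaults to [default_phenotype_rules()].
#' @param phenotype_noise per-call flip probability in [0, 0.1].
#' @return an object of class `niche_profile`.
#' @export
niche_profile <- function(niche_name, island_loss_probs = numeric(0),
                          background_loss_prob = 0.01, snp_rate = 0.02,
                          spacer_retention = 24L,
                          phenotype_rules = default_phenotype_rules,
                          phenotype_noise = 0) {
  if (!niche_name %in% niche_vocabulary) {
    stop("`niche_name` must be one of: ",
         paste(niche_vocabulary, collapse = ", "), call. = FALSE)
  }
  for (p in island_loss_probs) stopifnot_scalar_prob(p, "island_loss_probs")
  stopifnot_scalar_prob(background_loss_prob, "background_loss_prob")
  if (!is.numeric(snp_rate) || snp_rate < 0 || snp_rate > 0.3) {
    stop("`snp_rate` must be in [0, 0.3]", call. = FALSE)
  }
  if (!is.numeric(phenotype_noise) || phenotype_noise < 0 ||
      phenotype_noise > 0.1) {
    stop("`phenotype_noise` must be in [0, 0.1]", call. = FALSE)
  }
  spacer_retention <- as.integer(spacer_retention)
  if (spacer_retention < 0) stop("`spacer_retention` must be >= 0",
                                 call. = FALSE)
  structure(
    list(niche_name = niche_name, island_loss_probs = island_loss_probs,
         background_loss_prob = background_loss_prob, snp_rate = snp_rate,
         spacer_retention = spacer_retention,
         phenotype_rules = phenotype_rules,
         phenotype_noise = phenotype_noise),
    class = "niche_profile"
  )
}

#' Default niche profiles of the synthetic cohort
#'
#' Seven profiles chosen to reproduce the qualitative niche contrasts of the
#' study system: dairy-type strains lose the pilus and fucose islands, keep
#' few reference spacers and ferment the dairy sugars; intestinal strains
#' stay close to the reference; oral and vaginal strains are dairy-like
#' (geno-phenotype A), vaginal ones keeping bile resistance; clinical strains
#' are an eclectic mix of an A-like and a B-like profile, the latter with an
#' elevated chance of losing just the pilus island (giving B-delta-spaCBA
#' strains); `other` sits in between. Quantitative rates are the package's
#' own calibration (the study system reports only qualitative contrasts).
#'
#' @param phenotype_noise flip probability applied to all profiles.
#' @return named list of [niche_profile()] objects.
#' @export
default_niche_profiles <- function(phenotype_noise = 0) {
  list(
    dairy = niche_profile(
      "dairy",
      c(GI1 = 0.90, GI2 = 0.85, GI3 = 0.10, GI4 = 0.85, GI5 = 0.70,
        GI6 = 0.75),
      background_loss_prob = 0.0015, snp_rate = 0.020,
      spacer_retention = 6L, phenotype_noise = phenotype_noise),
    intestinal = niche_profile(
      "intestinal",
      c(GI1 = 0.10, GI2 = 0.05, GI3 = 0.05, GI4 = 0.02, GI5 = 0.10,
        GI6 = 0.15),
      background_loss_prob = 0.0005, snp_rate = 0.008,
      spacer_retention = 24L, phenotype_noise = phenotype_noise),
    oral = niche_profile(
      "oral",
      c(GI1 = 0.85, GI2 = 0.80, GI3 = 0.15, GI4 = 0.70, GI5 = 0.65,
        GI6 = 0.70),
      background_loss_prob = 0.001, snp_rate = 0.015,
      spacer_retention = 8L, phenotype_noise = phenotype_noise),
    vaginal = niche_profile(
      "vaginal",
      c(GI1 = 0.85, GI2 = 0.80, GI3 = 0.10, GI4 = 0.05, GI5 = 0.65,
        GI6 = 0.70),
      background_loss_prob = 0.001, snp_rate = 0.015,
      spacer_retention = 8L, phenotype_noise = phenotype_noise),
    clinical_a = niche_profile(
      "clinical",
      c(GI1 = 0.90, GI2 = 0.85, GI3 = 0.10, GI4 = 0.85, GI5 = 0.70,
        GI6 = 0.75),
      background_loss_prob = 0.0015, snp_rate = 0.020,
      spacer_retention = 7L, phenotype_noise = phenotype_noise),
    clinical_b = niche_profile(
      "clinical",
      c(GI1 = 0.55, GI2 = 0.05, GI3 = 0.05, GI4 = 0.05, GI5 = 0.10,
        GI6 = 0.15),
      background_loss_prob = 0.0005, snp_rate = 0.008,
      spacer_retention = 22L, phenotype_noise = phenotype_noise),
    other = niche_profile(
      "other",
      c(GI1 = 0.40, GI2 = 0.40, GI3 = 0.10, GI4 = 0.20, GI5 = 0.20,
        GI6 = 0.30),
      background_loss_prob = 0.001, snp_rate = 0.012,
      spacer_retention = 12L, phenotype_noise = phenotype_noise)
  )
}

#' Default cohort composition
#'
#' 100 strains mirroring the study collection: 23 dairy, 16 intestinal,
#' 3 oral, 8 vaginal, 31 clinical (split between the A-like and B-like
#' clinical profiles) and 19 of other/unspecified origin.
#'
#' @return named integer vector of per-profile strain counts.
#' @export
default_niche_mix <- function() {
  c(dairy = 23L, intestinal = 16L, oral = 3L, vaginal = 8L,
    clinical_a = 12L, clinical_b = 19L, other = 19L)
}

island_role_products <- list(
  pili = c("pilin SpaA", "pilin SpaB", "pilin SpaC",
           "pilus-specific sortase SrtC1"),
  fucose = c("L-fucose isomerase FucI", "L-fuculose kinase FucK",
             "alpha-L-fucosidase", "fucose operon repressor FcsR",
             "L-fucose permease"),
  lactose_pts = c("lactose PTS EIIA component", "lactose PTS EIIBC component",
                  "phospho-beta-galactosidase LacG",
                  "transcription antiterminator LacT",
                  "maltose ABC transporter MalE"),
  taurine = c("taurine ABC transporter TauA", "taurine ABC transporter TauB",
              "taurine ABC transporter TauC", "transcriptional regulator"),
  eps = c("EPS biosynthesis glycosyltransferase", "EPS polymerase"),
  phage = c("phage-related protein", "phage integrase")
)

island_role_cog <- c(pili = "M", fucose = "G", lactose_pts = "G",
                     taurine = "P", eps = "M", phage = "L")

#' Simulate an annotated reference genome
#'
#' Generates a bacterial reference chromosome with `n_genes` random,
#' non-overlapping ORF-like genes, `n_islands` contiguous genomic-island
#' gene runs with biologically themed annotation (pilus cluster, fucose
#' utilization, lactose/maltose PTS, taurine transport, EPS, phage remnant),
#' and a Type II-A-like CRISPR locus (repeat-spacer array plus cas genes)
#' placed between background genes. Deterministic for a fixed seed.
#'
#' @param n_genes number of genes.
#' @param n_islands number of islands; `island_sizes` gives their gene
#'   counts (each >= 5).
#' @param island_sizes integer vector of length `n_islands`.
#' @param genome_length chromosome length in bp.
#' @param seed integer seed.
#' @param gene_length_range min/max gene length in bp.
#' @param island_roles character vector of island themes, recycled over
#'   islands; must be names of the built-in role set.
#' @param n_spacers,n_cas CRISPR locus dimensions (set `n_spacers = 0` to
#'   omit the locus).
#' @return a [reference_annotation()] with sequence, `islands` table and
#'   `crispr` descriptor.
#' @export
simulate_reference <- function(n_genes = 300, n_islands = 6,
                               island_sizes = c(8L, 10L, 12L, 9L, 7L, 6L),
                               genome_length = 300000, seed = 1,
                               gene_length_range = c(450, 750),
                               island_roles = names(island_role_products),
                               n_spacers = 24, n_cas = 4) {
  stopifnot(length(island_sizes) == n_islands)
  if (n_islands > 0 && any(island_sizes < 5)) {
    stop("each island must span at least 5 genes", call. = FALSE)
  }
  if (sum(island_sizes) > n_genes) {
    stop("infeasible packing: island sizes sum beyond `n_genes`",
         call. = FALSE)
  }
  with_seed(seed, {
    gene_len <- sample(gene_length_range[1]:gene_length_range[2], n_genes,
                       replace = TRUE)
    # make lengths multiples of 3 for ORF-like framing
    gene_len <- gene_len - gene_len %% 3L

    repeat_seq <- random_dna(36)
    spacers <- character(0)
    if (n_spacers > 0) {
      repeat {
        spacers <- vapply(seq_len(n_spacers), function(i) random_dna(30),
                          character(1))
        if (!anyDuplicated(spacers)) break
      }
    }
    cas_len <- c(1800L, 900L, 300L, 699L)[seq_len(n_cas)]
    cas_names <- c("cas9", "cas1", "cas2", "csn2")[seq_len(n_cas)]
    cas_seqs <- vapply(cas_len, function(l) {
      paste0("ATG", random_dna(l - 6L), "TAA")
    }, character(1))
    crispr_len <- if (n_spacers > 0) {
      36L * (n_spacers + 1L) + 30L * n_spacers + sum(cas_len) +
        20L * (n_cas + 1L)
    } else 0L

    min_gap <- 20L
    slack <- genome_length - sum(gene_len) - crispr_len -
      (n_genes + 1L) * min_gap
    if (slack < 0) {
      stop("infeasible packing: gene extents exceed `genome_length`",
           call. = FALSE)
    }
    gaps <- min_gap + as.integer(stats::rmultinom(1, slack,
                                                  rep(1, n_genes + 1L)))

    # island placement: contiguous gene runs separated by >= 2 background
    # genes so detected regions stay distinct
    island_of_gene <- rep(NA_character_, n_genes)
    if (n_islands > 0) {
      n_background <- n_genes - sum(island_sizes)
      n_sep <- n_islands + 1L
      if (n_background < 2L * n_sep) {
        stop("infeasible packing: not enough background genes between islands",
             call. = FALSE)
      }
      extra <- as.integer(stats::rmultinom(1, n_background - 2L * n_sep,
                                           rep(1, n_sep)))
      sep <- 2L + extra
      idx <- sep[1]
      island_start_idx <- integer(n_islands)
      for (j in seq_len(n_islands)) {
        island_start_idx[j] <- idx + 1L
        island_of_gene[(idx + 1L):(idx + island_sizes[j])] <-
          sprintf("GI%d", j)
        idx <- idx + island_sizes[j] + sep[j + 1L]
      }
    }
    roles <- rep_len(island_roles, max(n_islands, 1L))[seq_len(n_islands)]

    # choose a background gap for the CRISPR locus (not inside an island run)
    crispr_gap <- NA_integer_
    if (n_spacers > 0) {
      bg_gaps <- which(vapply(seq_len(n_genes + 1L), function(g) {
        before <- if (g > 1L) is.na(island_of_gene[g - 1L]) else TRUE
        after <- if (g <= n_genes) is.na(island_of_gene[g]) else TRUE
        before && after
      }, logical(1)))
      crispr_gap <- sample(bg_gaps[bg_gaps > n_genes %/% 2L], 1L)
    }

    # assemble the chromosome, tracking coordinates
    chunks <- character(0)
    pos <- 0L
    starts <- integer(n_genes)
    ends <- integer(n_genes)
    spacer_ranges <- NULL
    cas_ranges <- NULL
    array_range <- NULL
    add_chunk <- function(s) {
      chunks[[length(chunks) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add_crispr <- function() {
      array_start <- pos + 1L
      sp_start <- integer(n_spacers); sp_end <- integer(n_spacers)
      add_chunk(repeat_seq)
      for (i in seq_len(n_spacers)) {
        sp_start[i] <- pos + 1L
        add_chunk(spacers[i])
        sp_end[i] <- pos
        add_chunk(repeat_seq)
      }
      array_range <<- c(array_start, pos)
      spacer_ranges <<- IRanges::IRanges(start = sp_start, end = sp_end)
      cs <- integer(n_cas); ce <- integer(n_cas)
      for (i in seq_len(n_cas)) {
        add_chunk(random_dna(20))
        cs[i] <- pos + 1L
        add_chunk(cas_seqs[i])
        ce[i] <- pos
      }
      add_chunk(random_dna(20))
      cas_ranges <<- IRanges::IRanges(start = cs, end = ce)
    }
    for (i in seq_len(n_genes)) {
      add_chunk(random_dna(gaps[i]))
      if (!is.na(crispr_gap) && crispr_gap == i) add_crispr()
      starts[i] <- pos + 1L
      add_chunk(paste0("ATG", random_dna(gene_len[i] - 6L), "TAA"))
      ends[i] <- pos
    }
    add_chunk(random_dna(gaps[n_genes + 1L]))
    if (!is.na(crispr_gap) && crispr_gap == n_genes + 1L) add_crispr()
    sequence <- Biostrings::DNAString(paste(chunks, collapse = ""))

    cog_pool <- c("J", "K", "L", "C", "E", "F", "G", "H", "I", "M", "P", "T")
    genes <- data.frame(
      locus_tag = sprintf("SYN_%05d", seq_len(n_genes)),
      start = starts, end = ends,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      product = "hypothetical protein",
      cog_category = sample(cog_pool, n_genes, replace = TRUE),
      island_id = island_of_gene,
      is_IS_element = FALSE,
      stringsAsFactors = FALSE
    )
    islands_df <- NULL
    if (n_islands > 0) {
      islands_df <- data.frame(
        island_id = sprintf("GI%d", seq_len(n_islands)),
        role = roles,
        first_index = island_start_idx,
        last_index = island_start_idx + island_sizes - 1L,
        stringsAsFactors = FALSE
      )
      for (j in seq_len(n_islands)) {
        run <- island_start_idx[j]:(island_start_idx[j] + island_sizes[j] - 1L)
        prods <- rep_len(c(island_role_products[[roles[j]]],
                           "conserved protein"), length(run))
        genes$product[run] <- prods
        genes$cog_category[run] <- island_role_cog[[roles[j]]]
        # flag two IS-element genes per island (mobile-element-rich regions)
        is_idx <- run[c(1L, length(run))]
        genes$product[is_idx] <- "IS element transposase"
        genes$is_IS_element[is_idx] <- TRUE
        genes$cog_category[is_idx] <- "L"
      }
    }
    crispr <- NULL
    if (n_spacers > 0) {
      crispr <- reference_crispr(
        spacers = Biostrings::DNAStringSet(setNames(
          spacers, sprintf("spacer_%02d", seq_len(n_spacers)))),
        cas = Biostrings::DNAStringSet(setNames(cas_seqs, cas_names)),
        repeat_seq = Biostrings::DNAString(repeat_seq)
      )
      crispr$array_range <- array_range
      crispr$spacer_ranges <- spacer_ranges
      crispr$cas_ranges <- cas_ranges
    }
    reference_annotation("SYNREF", length(sequence), genes,
                         sequence = sequence, islands = islands_df,
                         crispr = crispr)
  })
}

#' Construct a strain genome object
#'
#' @param strain_id unique strain identifier.
#' @param niche ecological niche label from the closed vocabulary.
#' @param sequences [Biostrings::DNAStringSet] of one or more contigs.
#' @param truth optional simulation ground truth (see [simulate_strain()]).
#' @return object of class `strain_genome`.
#' @export
strain_genome <- function(strain_id, niche, sequences, truth = NULL) {
  if (!niche %in% niche_vocabulary) {
    stop("`niche` must be one of: ", paste(niche_vocabulary, collapse = ", "),
         call. = FALSE)
  }
  sequences <- Biostrings::DNAStringSet(sequences)
  if (length(sequences) == 0L || any(Biostrings::width(sequences) == 0L)) {
    stop("strain sequences must be non-empty", call. = FALSE)
  }
  af <- Biostrings::alphabetFrequency(sequences, baseOnly = TRUE)
  if (any(af[, "other"] > 0)) {
    stop("strain sequence alphabet must be within {A,C,G,T,N}",
         call. = FALSE)
  }
  structure(list(strain_id = strain_id, niche = niche,
                 sequences = sequences, truth = truth),
            class = "strain_genome")
}

#' @export
print.strain_genome <- function(x, ...) {
  cat(sprintf("<strain_genome> %s (%s): %d contig(s), %d bp\n",
              x$strain_id, x$niche, length(x$sequences),
              sum(Biostrings::width(x$sequences))))
  invisible(x)
}

apply_snps <- function(sequence, snp_rate) {
  L <- length(sequence)
  if (snp_rate <= 0) return(list(sequence = sequence, n_snps = 0L))
  pos <- which(stats::runif(L) < snp_rate)
  if (!length(pos)) return(list(sequence = sequence, n_snps = 0L))
  bases <- c("A", "C", "G", "T")
  s <- as.character(sequence)
  old <- strsplit(substring(s, 1, L), "")[[1]][pos]
  shift <- sample.int(3L, length(pos), replace = TRUE)
  new <- bases[((match(old, bases) - 1L + shift) %% 4L) + 1L]
  mutated <- Biostrings::replaceLetterAt(sequence, pos,
                                         paste(new, collapse = ""))
  list(sequence = mutated, n_snps = length(pos))
}

#' Simulate one strain genome from a reference and a niche profile
#'
#' Whole islands are deleted all-or-none with their island loss
#' probabilities, background genes are deleted independently, retained
#' sequence is mutated by random substitutions at `snp_rate`, and the CRISPR
#' array is truncated to the profile's retained spacers (the oldest,
#' trailer-proximal ones). The returned object records the full simulation
#' truth: lost gene tags, retained spacer indices and the noiseless
#' phenotypes (including the intended geno-phenotype class).
#'
#' @param reference a simulated [reference_annotation()] with sequence.
#' @param profile a [niche_profile()].
#' @param seed integer seed; output is deterministic per seed.
#' @param strain_id identifier (default derived from niche and seed).
#' @return a [strain_genome()] with `truth`.
#' @export
simulate_strain <- function(reference, profile, seed,
                            strain_id = NULL) {
  stopifnot(inherits(reference, "reference_annotation"),
            inherits(profile, "niche_profile"))
  if (is.null(reference$sequence)) {
    stop("reference carries no sequence", call. = FALSE)
  }
  if (is.null(strain_id)) {
    strain_id <- sprintf("%s_s%d", profile$niche_name, seed)
  }
  with_seed(seed, {
    genes <- reference$genes
    islands <- reference$islands
    lost_islands <- character(0)
    if (!is.null(islands)) {
      p <- profile$island_loss_probs[islands$island_id]
      p[is.na(p)] <- 0
      lost_islands <- islands$island_id[stats::runif(nrow(islands)) < p]
    }
    in_lost_island <- !is.na(genes$island_id) &
      genes$island_id %in% lost_islands
    background <- is.na(genes$island_id)
    lost_background <- background &
      stats::runif(nrow(genes)) < profile$background_loss_prob
    lost <- in_lost_island | lost_background
    lost_gene_tags <- genes$locus_tag[lost]

    n_spacers <- if (!is.null(reference$crispr)) {
      length(reference$crispr$spacers)
    } else 0L
    retention <- min(profile$spacer_retention, n_spacers)
    retained_spacer_indices <- if (n_spacers > 0 && retention > 0) {
      (n_spacers - retention + 1L):n_spacers
    } else integer(0)

    mut <- apply_snps(reference$sequence, profile$snp_rate)

    del <- IRanges::IRanges()
    if (any(lost)) {
      del <- c(del, IRanges::IRanges(start = genes$start[lost],
                                     end = genes$end[lost]))
    }
    if (n_spacers > 0) {
      drop_idx <- setdiff(seq_len(n_spacers), retained_spacer_indices)
      if (length(drop_idx)) {
        sp <- reference$crispr$spacer_ranges[drop_idx]
        # remove the spacer together with its downstream repeat copy
        del <- c(del, IRanges::IRanges(start = IRanges::start(sp),
                                       end = IRanges::end(sp) + 36L))
      }
    }
    seq_out <- mut$sequence
    if (length(del)) {
      keep <- IRanges::gaps(IRanges::reduce(del), start = 1L,
                            end = length(seq_out))
      seq_out <- unlist(Biostrings::extractAt(seq_out, keep))
    }

    islands_present <- logical(0)
    roles <- character(0)
    if (!is.null(islands)) {
      islands_present <- setNames(!(islands$island_id %in% lost_islands),
                                  islands$island_id)
      roles <- setNames(islands$role, islands$island_id)
    }
    phen <- profile$phenotype_rules(islands_present, roles)
    truth <- list(
      lost_gene_tags = lost_gene_tags,
      lost_islands = lost_islands,
      retained_spacer_indices = retained_spacer_indices,
      n_snps = mut$n_snps,
      true_phenotypes = phen
    )
    truth$true_phenotypes$class <-
      truth_class(reference, truth, phen)
    strain_genome(strain_id, profile$niche_name,
                  Biostrings::DNAStringSet(setNames(
                    as.character(seq_out), strain_id)),
                  truth = truth)
  })
}

#' Noiseless phenotypes implied by an island retention pattern
#'
#' The default genotype-to-phenotype coupling of the simulator: functional
#' pili require the pilus island; bile resistance requires the taurine
#' island; group I sugars are fermented iff the fucose island is present,
#' groups II/III iff it is absent (the dairy trade-off); mucus binding is
#' high only with pili; antagonistic activity (ARP) is strong in
#' fucose-positive, intestinal-adapted strains and weak otherwise. Islands
#' whose role is absent from the reference default to "present".
#'
#' @param islands_present named logical, island_id -> retained.
#' @param roles named character, island_id -> role.
#' @return list with `api_calls`, `bile`, `mucus_binding`, `pilosotype`,
#'   `tlr2_fold` and `arp` entries.
#' @export
default_phenotype_rules <- function(islands_present, roles) {
  has_role <- function(role) {
    ids <- names(roles)[roles == role]
    if (!length(ids)) return(TRUE)
    all(islands_present[ids])
  }
  pili <- has_role("pili")
  fucose <- has_role("fucose")
  taurine <- has_role("taurine")
  api <- c(
    setNames(rep(if (fucose) "positive" else "negative",
                 length(sugar_groups$I)), sugar_groups$I),
    setNames(rep(if (fucose) "negative" else "positive",
                 length(sugar_groups$II)), sugar_groups$II),
    setNames(rep(if (fucose) "negative" else "positive",
                 length(sugar_groups$III)), sugar_groups$III),
    setNames(rep("positive", length(basal_sugars)), basal_sugars)
  )
  arp_base <- c(E_coli = 45, L_monocytogenes = 35, Y_enterocolitica = 40)
  arp <- unlist(lapply(names(arp_base), function(p) {
    lvl <- arp_base[[p]] * (if (fucose) 1 else 0.25)
    setNames(c(lvl, lvl * 0.7),
             paste0(p, c("_pH5.0", "_pH6.2")))
  }))
  list(
    api_calls = api,
    bile = if (taurine) "resistant" else "sensitive",
    mucus_binding = if (pili) 18.0 else 0.4,
    pilosotype = if (pili) "positive" else "negative",
    tlr2_fold = 1.5,
    arp = arp[arp_conditions]
  )
}

# intended geno-phenotype class of a simulated strain, computed from the
# true genotype and the noiseless phenotypes through the same classifier the
# pipeline applies to measured data
truth_class <- function(reference, truth, phen) {
  tags <- reference$genes$locus_tag
  row <- setNames(rep(1L, length(tags)), tags)
  row[truth$lost_gene_tags] <- 0L
  n_spacers <- if (!is.null(reference$crispr)) {
    length(reference$crispr$spacers)
  } else 0L
  status <- rep("absent", n_spacers)
  status[truth$retained_spacer_indices] <- "conserved"
  profile <- list(strain_id = "truth", spacer_status = status,
                  cas_status = rep("present",
                                   if (!is.null(reference$crispr))
                                     length(reference$crispr$cas) else 0L))
  class(profile) <- "crispr_profile"
  record <- list(strain_id = "truth", api_calls = phen$api_calls,
                 bile = phen$bile, mucus_binding = phen$mucus_binding,
                 pilosotype = phen$pilosotype, tlr2_fold = phen$tlr2_fold,
                 arp = phen$arp)
  gp <- score_genophenotype(row, profile, record,
                            config = genopheno_config(reference))
  gp$class
}

flip_call <- function(values, levels, noise) {
  if (noise <= 0) return(values)
  flip <- stats::runif(length(values)) < noise
  if (any(flip)) {
    values[flip] <- vapply(values[flip], function(v) {
      sample(setdiff(levels, v), 1L)
    }, character(1))
  }
  values
}

#' Simulate a strain cohort with phenotypes
#'
#' Draws `niche_mix[p]` strains from each named profile, builds their
#' genomes with [simulate_strain()], and produces the observed phenotype
#' table by applying each profile's phenotype rules to the true genotype and
#' then flipping categorical calls with the profile's `phenotype_noise`
#' (numeric assay values get proportional Gaussian noise). All randomness
#' derives from `seed`.
#'
#' @param reference a simulated [reference_annotation()].
#' @param niche_mix named integer vector, profile name -> strain count.
#' @param profiles named list of [niche_profile()]s covering
#'   `names(niche_mix)`.
#' @param seed master integer seed.
#' @return list with `strains` (list of [strain_genome()]),
#'   `phenotypes` (data.frame, one row per strain) and `niches`
#'   (named character vector strain_id -> niche label).
#' @export
simulate_cohort <- function(reference, niche_mix = default_niche_mix(),
                            profiles = default_niche_profiles(), seed = 1) {
  if (is.null(names(niche_mix)) ||
      !all(names(niche_mix) %in% names(profiles))) {
    stop("`niche_mix` names must match `profiles` names", call. = FALSE)
  }
  n_total <- sum(niche_mix)
  seeds <- derive_seeds(seed, n_total + 1L)
  noise_seed <- seeds[n_total + 1L]
  strains <- vector("list", n_total)
  k <- 0L
  for (pname in names(niche_mix)) {
    prof <- profiles[[pname]]
    for (i in seq_len(niche_mix[[pname]])) {
      k <- k + 1L
      strains[[k]] <- simulate_strain(
        reference, prof, seeds[k],
        strain_id = sprintf("%s_%02d", pname, i))
    }
  }
  profile_of <- rep(names(niche_mix), niche_mix)
  rows <- with_seed(noise_seed, {
    lapply(seq_along(strains), function(j) {
      st <- strains[[j]]
      prof <- profiles[[profile_of[j]]]
      noise <- prof$phenotype_noise
      ph <- st$truth$true_phenotypes
      api <- flip_call(ph$api_calls,
                       c("positive", "partial", "negative"), noise)
      bile <- flip_call(ph$bile,
                        c("resistant", "moderately_resistant",
                          "poorly_resistant", "sensitive"), noise)
      pilo <- flip_call(ph$pilosotype, c("positive", "negative"), noise)
      jitter <- function(x, sd_frac) {
        if (noise <= 0) x else pmax(0, x * exp(stats::rnorm(length(x), 0,
                                                            sd_frac)))
      }
      mucus <- min(jitter(ph$mucus_binding, 10 * noise), 100)
      arp <- ph$arp + if (noise > 0) stats::rnorm(length(ph$arp), 0,
                                                  100 * noise) else 0
      tlr2 <- jitter(ph$tlr2_fold, 4 * noise)
      out <- data.frame(strain_id = st$strain_id, niche = st$niche,
                        bile = bile, mucus_binding = mucus,
                        pilosotype = pilo, tlr2_fold = tlr2,
                        stringsAsFactors = FALSE)
      for (s in names(api)) out[[paste0("api_", s)]] <- api[[s]]
      for (a in names(arp)) out[[paste0("arp_", a)]] <- arp[[a]]
      out
    })
  })
  phenotypes <- do.call(rbind, rows)
  rownames(phenotypes) <- NULL
  niches <- setNames(vapply(strains, function(s) s$niche, character(1)),
                     vapply(strains, function(s) s$strain_id, character(1)))
  list(strains = strains, phenotypes = phenotypes, niches = niches)
}

#' Simulate a logistic growth curve
#'
#' OD600 follows a logistic curve `K / (1 + exp(-r (t - t_mid)))` scaled by
#' `inhibition_factor`, with optional additive Gaussian noise; readings are
#' clamped at zero. With `noise_sd = 0` the curve is exactly proportional to
#' the control, so the area reduction percentage of a half-scaled curve is
#' exactly 50.
#'
#' @param model_params list with `K` (carrying capacity, OD units),
#'   `r` (growth rate, 1/h) and `t_mid` (inflection time, h).
#' @param inhibition_factor multiplicative factor in [0, ...]; 1 = control.
#' @param timepoints strictly increasing sampling times in hours (default:
#'   every 30 min over 15 h).
#' @param noise_sd additive Gaussian noise SD in OD units.
#' @param seed optional seed for the noise.
#' @return a [growth_curve()].
#' @export
simulate_growth_curve <- function(model_params = list(K = 1.2, r = 0.6,
                                                      t_mid = 6),
                                  inhibition_factor = 1,
                                  timepoints = seq(0, 15, by = 0.5),
                                  noise_sd = 0, seed = NULL) {
  od <- inhibition_factor * model_params$K /
    (1 + exp(-model_params$r * (timepoints - model_params$t_mid)))
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(od), 0, noise_sd)
             else with_seed(seed, stats::rnorm(length(od), 0, noise_sd))
    od <- od + noise
  }
  growth_curve(timepoints, pmax(od, 0))
}

#' Write a simulated cohort to disk
#'
#' Emits one FASTA per strain, a phenotype TSV, a niche-label TSV and a
#' ground-truth JSON; used by the analysis drivers.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta_dir <- file.path(dir, "strains")
  dir.create(fasta_dir, showWarnings = FALSE)
  for (st in cohort$strains) {
    Biostrings::writeXStringSet(
      st$sequences, file.path(fasta_dir, paste0(st$strain_id, ".fasta")))
  }
  write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(strain_id = names(cohort$niches),
                         niche = unname(cohort$niches)),
              file.path(dir, "niches.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- lapply(cohort$strains, function(st) {
    list(strain_id = st$strain_id,
         lost_gene_tags = st$truth$lost_gene_tags,
         lost_islands = st$truth$lost_islands,
         retained_spacer_indices = st$truth$retained_spacer_indices,
         class = st$truth$true_phenotypes$class)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
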