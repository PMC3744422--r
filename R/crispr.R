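#' Reference CRISPR-Cas locus descriptor
#'
#' Describes the reference Type II-A-like CRISPR-Cas locus used for spacer
#' oligotyping: the ordered spacer set of the CRISPR array and the cas gene
#' sequences.
#'
#' @param spacers named [Biostrings::DNAStringSet] (or FASTA path) of
#'   spacers in array order; each 20-50 bp, sequences unique.
#' @param cas named [Biostrings::DNAStringSet] (or FASTA path) of cas genes.
#' @param repeat_seq optional repeat sequence.
#' @return object of class `reference_crispr`.
#' @export
reference_crispr <- function(spacers, cas, repeat_seq = NULL) {
  if (is.character(spacers) && length(spacers) == 1L) {
    spacers <- Biostrings::readDNAStringSet(spacers)
  }
  if (is.character(cas) && length(cas) == 1L) {
    cas <- Biostrings::readDNAStringSet(cas)
  }
  spacers <- Biostrings::DNAStringSet(spacers)
  cas <- Biostrings::DNAStringSet(cas)
  if (length(spacers) < 1L) stop("need at least one spacer", call. = FALSE)
  w <- Biostrings::width(spacers)
  if (any(w < 20L | w > 50L)) {
    stop("spacer lengths must be within 20-50 bp", call. = FALSE)
  }
  if (anyDuplicated(as.character(spacers))) {
    stop("spacer sequences must be unique", call. = FALSE)
  }
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("spacer_%02d", seq_along(spacers))
  }
  if (is.null(names(cas)) && length(cas)) {
    names(cas) <- sprintf("cas%d", seq_along(cas))
  }
  structure(list(spacers = spacers, cas = cas, repeat_seq = repeat_seq),
            class = "reference_crispr")
}

spacer_status_levels <- c("conserved", "partial", "absent")

classify_spacer <- function(identity, coverage, match_frac = NULL,
                            conserved_match = 0.90,
                            partial = c(0.80, 0.50)) {
  # conserved: at least 90% of the spacer's bases matched (trim-invariant,
  # so a spacer with one terminal substitution still scores conserved)
  if (is.null(match_frac)) match_frac <- identity * coverage
  if (match_frac >= conserved_match) return("conserved")
  if (identity >= partial[1] && coverage >= partial[2]) return("partial")
  "absent"
}

# best seeded alignment of short queries (spacers) against strain contigs;
# word-size-7 seeds, many candidate windows since chance 7-mers are common
spacer_best_hit <- function(spacer_seqs, strain_seqs, word_size = 7L,
                            n_windows = 25L, dicts = NULL,
                            min_anchors = 3L) {
  # genome-scale candidate loci need >= 3 exact word-7 seeds on one
  # diagonal; chance seed pairs in hundreds of kb otherwise produce
  # spurious short "partial" matches
  seeded_alignments(spacer_seqs, strain_seqs, k = word_size, stride = 1L,
                    pad = 15L, n_windows = n_windows, dp_limit = 2000L,
                    dicts = dicts, min_anchors = min_anchors)
}

#' Type one reference spacer in a strain
#'
#' Searches both strands of all strain contigs for the spacer and classifies
#' it as `conserved` (at least 90% of the spacer's bases matched in the best
#' local alignment - a trim-invariant criterion, so a spacer with a single
#' terminal substitution stays conserved), `partial` (>= 80% identity over
#' >= 50% of the spacer length, e.g. a half-deleted spacer) or `absent`.
#' The class thresholds are the package's calibration of the three-colour
#' conservation classes used in spacer oligotyping.
#'
#' @param spacer_seq spacer sequence (>= 15 bp).
#' @param strain_seqs [Biostrings::DNAStringSet] of strain contigs.
#' @param word_size seed word size (default 7).
#' @return list with `status`, `identity`, `coverage`.
#' @export
type_spacer <- function(spacer_seq, strain_seqs, word_size = 7L) {
  spacer_seq <- Biostrings::DNAStringSet(spacer_seq)
  if (Biostrings::width(spacer_seq)[1] < 15L) {
    stop("spacer must be at least 15 bp", call. = FALSE)
  }
  res <- spacer_best_hit(spacer_seq, Biostrings::DNAStringSet(strain_seqs),
                         word_size = word_size)
  list(status = classify_spacer(res$identity[1], res$coverage[1],
                                res$match_frac[1]),
       identity = res$identity[1], coverage = res$coverage[1])
}

#' Type one cas gene in a strain
#'
#' Applies the same presence rule as ortholog calling (identity >= 0.40 and
#' coverage >= 0.80 of the best local alignment).
#'
#' @param cas_seq cas gene sequence.
#' @param strain_seqs [Biostrings::DNAStringSet] of strain contigs.
#' @param identity_threshold,coverage_threshold inclusive thresholds.
#' @return `"present"` or `"absent"`.
#' @export
type_cas <- function(cas_seq, strain_seqs, identity_threshold = 0.40,
                     coverage_threshold = 0.80) {
  res <- align_gene(cas_seq, strain_seqs)
  if (res$identity >= identity_threshold &&
      res$coverage >= coverage_threshold) "present" else "absent"
}

#' CRISPR oligotype of a whole cohort
#'
#' Types every reference spacer and cas gene in every strain, yielding one
#' CRISPR profile per strain plus the count of conserved (shared) spacers.
#'
#' @param reference_crispr a [reference_crispr()].
#' @param strains list of [strain_genome()] objects.
#' @return list with `profiles` (list of `crispr_profile`), `table`
#'   (data.frame, one row per strain, one column per spacer with C/P/A codes
#'   and per cas gene with 1/0) and `shared_counts` (named integer).
#' @export
oligotype_cohort <- function(reference_crispr, strains) {
  stopifnot(inherits(reference_crispr, "reference_crispr"))
  spacers <- reference_crispr$spacers
  cas <- reference_crispr$cas
  sp_dicts <- build_probe_dicts(spacers, 7L, 1L)
  cas_dicts <- if (length(cas)) build_probe_dicts(cas, 11L, 7L) else NULL
  profiles <- lapply(strains, function(st) {
    hits <- spacer_best_hit(spacers, st$sequences, dicts = sp_dicts)
    status <- vapply(seq_len(nrow(hits)), function(i) {
      classify_spacer(hits$identity[i], hits$coverage[i],
                      hits$match_frac[i])
    }, character(1))
    cas_status <- character(0)
    if (length(cas)) {
      cas_hits <- seeded_alignments(cas, st$sequences, dicts = cas_dicts)
      cas_status <- ifelse(cas_hits$identity >= 0.40 &
                             cas_hits$coverage >= 0.80,
                           "present", "absent")
    }
    structure(list(strain_id = st$strain_id, spacer_status = status,
                   cas_status = cas_status),
              class = "crispr_profile")
  })
  shared <- vapply(profiles, function(p) sum(p$spacer_status == "conserved"),
                   integer(1))
  names(shared) <- vapply(profiles, `[[`, character(1), "strain_id")
  code <- c(conserved = "C", partial = "P", absent = "A")
  tab <- data.frame(
    strain_id = names(shared),
    do.call(rbind, lapply(profiles, function(p) {
      setNames(code[p$spacer_status], names(spacers))
    })),
    do.call(rbind, lapply(profiles, function(p) {
      setNames(as.integer(p$cas_status == "present"), names(cas))
    })),
    shared_spacers = unname(shared),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  rownames(tab) <- NULL
  list(profiles = profiles, table = tab, shared_counts = shared)
}

#' Search spacers against a phage/plasmid sequence database
#'
#' Seed-and-extend protospacer search: word-size-7 exact seeds on both
#' strands anchor local alignments of each spacer against each database
#' sequence; hits with >= 85% identity over >= 80% of the spacer length are
#' reported. A spacer may hit multiple targets.
#'
#' @param spacers [Biostrings::DNAStringSet] of spacers (or a
#'   [reference_crispr()]).
#' @param database [Biostrings::DNAStringSet] or FASTA path of candidate
#'   phage/plasmid sequences; must be non-empty.
#' @param word_size seed word size (default 7).
#' @param min_identity,min_coverage hit thresholds.
#' @return data.frame with `spacer`, `spacer_index`, `target`, `identity`,
#'   `coverage`, `strand`.
#' @export
protospacer_search <- function(spacers, database, word_size = 7L,
                               min_identity = 0.85, min_coverage = 0.80) {
  if (inherits(spacers, "reference_crispr")) spacers <- spacers$spacers
  spacers <- Biostrings::DNAStringSet(spacers)
  if (is.character(database) && length(database) == 1L) {
    database <- Biostrings::readDNAStringSet(database)
  }
  database <- Biostrings::DNAStringSet(database)
  if (length(database) == 0L) stop("empty database", call. = FALSE)
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("spacer_%02d", seq_along(spacers))
  }
  rows <- list()
  for (ti in seq_along(database)) {
    hits <- spacer_best_hit(spacers, database[ti])
    pass <- hits$identity >= min_identity & hits$coverage >= min_coverage
    if (any(pass)) {
      rows[[length(rows) + 1L]] <- data.frame(
        spacer = names(spacers)[pass],
        spacer_index = which(pass),
        target = names(database)[ti] %||% sprintf("target_%d", ti),
        identity = hits$identity[pass],
        coverage = hits$coverage[pass],
        strand = hits$strand[pass],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(spacer = character(0), spacer_index = integer(0),
                      target = character(0), identity = numeric(0),
                      coverage = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$spacer_index, out$target), ]
  rownames(out) <- NULL
  out
}

#' Distance between two CRISPR profiles
#'
#' Normalised mismatch over the concatenated spacer and cas status vectors,
#' with partial conservation counted as a half-match: conserved vs absent
#' contributes 1, conserved vs partial (or partial vs absent) 1/2.
#'
#' @param profile_a,profile_b `crispr_profile` objects from
#'   [oligotype_cohort()].
#' @return distance in [0, 1].
#' @export
profile_distance <- function(profile_a, profile_b) {
  if (length(profile_a$spacer_status) != length(profile_b$spacer_status) ||
      length(profile_a$cas_status) != length(profile_b$cas_status)) {
    stop("profiles describe different loci", call. = FALSE)
  }
  sp_score <- c(conserved = 1, partial = 0.5, absent = 0)
  cas_score <- c(present = 1, absent = 0)
  a <- c(sp_score[profile_a$spacer_status], cas_score[profile_a$cas_status])
  b <- c(sp_score[profile_b$spacer_status], cas_score[profile_b$cas_status])
  mean(abs(a - b))
}

#' Write cohort CRISPR profiles as TSV
#'
#' @param oligotypes result of [oligotype_cohort()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_crispr_profiles <- function(oligotypes, path) {
  write.table(oligotypes$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
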