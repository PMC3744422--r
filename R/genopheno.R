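#' Configuration of the geno-phenotype classifier
#'
#' Bundles the tunable pieces of the A/B classification: the shared-content
#' rescaling bounds of the gene-content axis, the bile-category scores, the
#' class cut-offs on the mean axis score, and the locus tags of the
#' spaCBA-like pilus island that split class B from B-delta-spaCBA.
#'
#' @param reference optional [reference_annotation()]; when it carries an
#'   island table, the pilus-island tags are taken from the island with role
#'   `"pili"`.
#' @param gene_content_bounds shared-content fractions mapped to axis scores
#'   0 and 1 (values outside are clamped).
#' @param bile_scores named scores of the four bile categories.
#' @param a_cut,b_cut mean-score cut-offs: <= `a_cut` gives class A,
#'   >= `b_cut` gives the B family, in between is unassigned.
#' @param spacba_tags locus tags of the pilus island (overrides `reference`).
#' @return list of class `genopheno_config`.
#' @export
genopheno_config <- function(reference = NULL,
                             gene_content_bounds = c(0.85, 1.0),
                             bile_scores = c(resistant = 1,
                                             moderately_resistant = 0.67,
                                             poorly_resistant = 0.33,
                                             sensitive = 0),
                             a_cut = 0.4, b_cut = 0.6,
                             spacba_tags = NULL) {
  if (is.null(spacba_tags) && !is.null(reference) &&
      !is.null(reference$islands)) {
    isl <- reference$islands
    pili <- isl$island_id[which(isl$role == "pili")]
    if (length(pili)) {
      g <- reference$genes
      spacba_tags <- g$locus_tag[!is.na(g$island_id) &
                                   g$island_id %in% pili]
    }
  }
  structure(list(gene_content_bounds = gene_content_bounds,
                 bile_scores = bile_scores, a_cut = a_cut, b_cut = b_cut,
                 spacba_tags = spacba_tags),
            class = "genopheno_config")
}

genopheno_axes <- c("gene_content", "crispr_oligotype", "bile",
                    "pilosotype", "sugar_I", "sugar_II", "sugar_III")

#' Score the geno-phenotype of one strain
#'
#' Integrates a strain's genomic and phenotypic traits into seven axis
#' scores in [0, 1], oriented so that 1 is B-like (intestinal-adapted):
#' gene content (shared fraction with the reference rescaled over the
#' configured bounds), CRISPR oligotype (fraction of reference spacers
#' conserved), bile resistance (4-level score), pilosotype (1 if positive),
#' and the three sugar-group axes (group I fraction; groups II and III
#' inverted, as dairy-adapted strains ferment them). The class is derived
#' from the mean axis score: >= `b_cut` is the B family - split into B when
#' the pilus island is fully present and B-delta-spaCBA when it is not -
#' <= `a_cut` is A, anything between is unassigned.
#'
#' @param presence_row named 0/1 vector of presence calls for the strain.
#' @param crispr_profile a `crispr_profile` (see [oligotype_cohort()]).
#' @param phenotype_record list with `api_calls`, `bile`, `pilosotype`
#'   (a data.frame row in the [simulate_cohort()] phenotype layout also
#'   works).
#' @param config a [genopheno_config()]; must carry `spacba_tags`.
#' @return list of class `genophenotype` with `strain_id`, `axis_scores`,
#'   `mean_score`, `class`.
#' @export
score_genophenotype <- function(presence_row, crispr_profile,
                                phenotype_record, config) {
  stopifnot(inherits(config, "genopheno_config"))
  if (length(config$spacba_tags) == 0) {
    stop("config carries no pilus-island locus tags", call. = FALSE)
  }
  if (!all(config$spacba_tags %in% names(presence_row))) {
    stop("pilus-island tags missing from the presence row", call. = FALSE)
  }
  rec <- as_phenotype_record(phenotype_record)
  if (is.null(presence_row) || is.null(crispr_profile) || is.null(rec)) {
    stop("presence row, CRISPR profile and phenotype record are all required",
         call. = FALSE)
  }
  shared <- mean(presence_row)
  b <- config$gene_content_bounds
  gene_axis <- min(1, max(0, (shared - b[1]) / (b[2] - b[1])))
  crispr_axis <- mean(crispr_profile$spacer_status == "conserved")
  if (!rec$bile %in% names(config$bile_scores)) {
    stop("unknown bile category: ", rec$bile, call. = FALSE)
  }
  bile_axis <- unname(config$bile_scores[rec$bile])
  pilo_axis <- as.numeric(identical(rec$pilosotype, "positive"))
  sugars <- sugar_group_scores(rec$api_calls)
  axis_scores <- c(
    gene_content = gene_axis,
    crispr_oligotype = crispr_axis,
    bile = bile_axis,
    pilosotype = pilo_axis,
    sugar_I = unname(sugars["score_I"]),
    sugar_II = 1 - unname(sugars["score_II"]),
    sugar_III = 1 - unname(sugars["score_III"])
  )
  mean_score <- mean(axis_scores)
  island_present <- all(presence_row[config$spacba_tags] == 1L)
  cls <- if (mean_score >= config$b_cut) {
    if (island_present) "B" else "B_dspaCBA"
  } else if (mean_score <= config$a_cut) {
    "A"
  } else {
    "unassigned"
  }
  structure(list(strain_id = rec$strain_id, axis_scores = axis_scores,
                 mean_score = mean_score, class = cls),
            class = "genophenotype")
}

# accept either the native record list or one row of the cohort phenotype
# table (api_* columns)
as_phenotype_record <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.null(x$api_calls)) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("phenotype record must be a single row",
                            call. = FALSE)
    api_cols <- grep("^api_", names(x), value = TRUE)
    api <- setNames(unlist(x[1, api_cols], use.names = FALSE),
                    sub("^api_", "", api_cols))
    return(list(strain_id = x$strain_id[1], api_calls = api,
                bile = x$bile[1], mucus_binding = x$mucus_binding[1],
                pilosotype = x$pilosotype[1]))
  }
  stop("unrecognised phenotype record", call. = FALSE)
}

#' Geno-phenotype classification of a whole cohort
#'
#' Applies [score_genophenotype()] to every strain of a cohort, joining the
#' presence matrix, CRISPR profiles and phenotype table by strain id.
#'
#' @param matrix presence matrix.
#' @param oligotypes result of [oligotype_cohort()].
#' @param phenotypes cohort phenotype data.frame (one row per strain).
#' @param config a [genopheno_config()].
#' @return data.frame with one row per strain: `strain_id`, the seven axis
#'   scores, `mean_score` and `class`.
#' @export
classify_cohort <- function(matrix, oligotypes, phenotypes, config) {
  profs <- oligotypes$profiles
  names(profs) <- vapply(profs, `[[`, character(1), "strain_id")
  rows <- lapply(rownames(matrix), function(sid) {
    gp <- score_genophenotype(
      matrix[sid, ], profs[[sid]],
      phenotypes[phenotypes$strain_id == sid, , drop = FALSE], config)
    out <- data.frame(strain_id = sid, t(gp$axis_scores),
                      mean_score = gp$mean_score, class = gp$class,
                      stringsAsFactors = FALSE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-niche geno-phenotype report
#'
#' Class counts per (niche, class) and mean axis scores per niche - the
#' table behind a radar-plot view of the cohort.
#'
#' @param classified output of [classify_cohort()].
#' @param niche_labels named character vector, strain_id -> niche.
#' @return list with `class_counts` (data.frame niche x class) and
#'   `axis_means` (data.frame, one row per niche).
#' @export
cohort_genophenotype_report <- function(classified, niche_labels) {
  niche <- niche_labels[classified$strain_id]
  if (anyNA(niche)) stop("niche labels must cover all strains", call. = FALSE)
  classes <- c("A", "B", "B_dspaCBA", "unassigned")
  niches <- unique(niche)
  counts <- do.call(rbind, lapply(niches, function(nn) {
    sel <- niche == nn
    row <- vapply(classes, function(cl) sum(classified$class[sel] == cl),
                  integer(1))
    data.frame(niche = nn, t(row), n = sum(sel), stringsAsFactors = FALSE)
  }))
  axis_means <- do.call(rbind, lapply(niches, function(nn) {
    sel <- niche == nn
    data.frame(niche = nn,
               t(colMeans(classified[sel, genopheno_axes, drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- rownames(axis_means) <- NULL
  list(class_counts = counts, axis_means = axis_means)
}
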