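#' Growth curve container
#'
#' @param timepoints strictly increasing sampling times (hours), >= 2.
#' @param od OD600 readings, same length, all >= 0.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(timepoints, od) {
  if (length(timepoints) < 2L || length(od) != length(timepoints)) {
    stop("need >= 2 matched timepoints and OD readings", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (any(od < 0)) stop("OD readings must be >= 0", call. = FALSE)
  structure(list(timepoints = as.numeric(timepoints), od = as.numeric(od)),
            class = "growth_curve")
}

#' Area under a growth curve
#'
#' Trapezoidal rule over the curve's native time grid (no resampling),
#' in OD x hours.
#'
#' @param curve a [growth_curve()].
#' @return numeric area.
#' @export
trapezoid_auc <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  if (any(diff(curve$timepoints) <= 0)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  pracma::trapz(curve$timepoints, curve$od)
}

#' Area reduction percentage (ARP)
#'
#' Growth inhibition of a pathogen culture relative to its control:
#' `100 * (AUC_control - AUC_sample) / AUC_control`. Negative values mean
#' the sample grew above the control (inverse effect) and are returned
#' as-is.
#'
#' @param sample_curve,control_curve [growth_curve()]s on identical time
#'   grids; the control AUC must be positive.
#' @return ARP in percent.
#' @export
compute_arp <- function(sample_curve, control_curve) {
  if (!isTRUE(all.equal(sample_curve$timepoints,
                        control_curve$timepoints))) {
    stop("sample and control curves must share the same time grid",
         call. = FALSE)
  }
  auc_c <- trapezoid_auc(control_curve)
  if (auc_c <= 0) stop("control AUC must be positive", call. = FALSE)
  100 * (auc_c - trapezoid_auc(sample_curve)) / auc_c
}

#' Mucus binding percentage
#'
#' Percentage ratio of the mucus-bound signal over the total suspension
#' signal of a radiolabelled binding assay.
#'
#' @param bound_signal,total_signal non-negative signals with
#'   `bound_signal <= total_signal` and `total_signal > 0`.
#' @return percentage in [0, 100].
#' @export
mucus_binding_percent <- function(bound_signal, total_signal) {
  if (any(total_signal <= 0)) stop("`total_signal` must be > 0",
                                   call. = FALSE)
  if (any(bound_signal < 0) || any(bound_signal > total_signal)) {
    stop("`bound_signal` must be in [0, total_signal]", call. = FALSE)
  }
  100 * bound_signal / total_signal
}

#' Pilosotype call for one strain
#'
#' A strain is pilosotype-positive when it carries intact pilus-cluster
#' genes that encode functional pili: all pilus genes (pilin cluster plus
#' sortase) must be called present, and when assay evidence (immunoblot,
#' electron microscopy or blocking binding assay) is supplied it must also
#' be positive - a conserved but non-expressed cluster scores negative.
#' Without assay evidence the genomic call alone decides.
#'
#' @param matrix_row named 0/1 vector of presence calls for one strain.
#' @param pili_gene_tags locus tags of the pilus cluster genes.
#' @param phenotype_evidence optional `"positive"`/`"negative"` assay result.
#' @return `"positive"` or `"negative"`.
#' @export
pilosotype_call <- function(matrix_row, pili_gene_tags,
                            phenotype_evidence = NULL) {
  if (!all(pili_gene_tags %in% names(matrix_row))) {
    stop("pili gene tags missing from the presence row", call. = FALSE)
  }
  genomic <- all(matrix_row[pili_gene_tags] == 1L)
  if (!genomic) return("negative")
  if (!is.null(phenotype_evidence) && !is.na(phenotype_evidence)) {
    return(if (phenotype_evidence == "positive") "positive" else "negative")
  }
  "positive"
}

#' Per-group contingency table of a binary trait
#'
#' Tallies positive/negative calls per group, reports truncated
#' percentages, and tests the association between two chosen groups
#' (default human vs dairy) with a two-sided Fisher exact test.
#'
#' @param calls named character vector, strain_id -> "positive"/"negative".
#' @param group_labels named character vector, strain_id -> group; must
#'   cover all strains in `calls`.
#' @param test_groups two group names for the 2x2 association test.
#' @return list with `table` (data.frame group, positive, negative, total,
#'   percent) and `p_value` (NA when a test group is absent).
#' @export
group_contingency <- function(calls, group_labels,
                              test_groups = c("human", "dairy")) {
  if (!all(names(calls) %in% names(group_labels))) {
    stop("`group_labels` must cover all strains", call. = FALSE)
  }
  grp <- group_labels[names(calls)]
  groups <- unique(grp)
  rows <- lapply(groups, function(g) {
    sel <- grp == g
    pos <- sum(calls[sel] == "positive")
    tot <- sum(sel)
    data.frame(group = g, positive = pos, negative = tot - pos,
               total = tot, percent = truncate_percent(pos, tot),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  p <- NA_real_
  if (all(test_groups %in% groups)) {
    sub <- tab[match(test_groups, tab$group), ]
    p <- stats::fisher.test(as.matrix(sub[, c("positive", "negative")]))$p.value
  }
  list(table = tab, p_value = p)
}

#' Sugar-group fermentation scores
#'
#' Fraction of each diagnostic sugar group called positive (partial calls
#' weigh 0.5): group I (dulcitol, D-arabinose, L-fucose), group II
#' (D-saccharose, D-maltose, methyl-alpha-D-glucopyranoside, D-turanose),
#' group III (L-rhamnose, L-sorbose, D-ribose, D-lactose).
#'
#' @param api_calls named character vector over carbohydrate names with
#'   values "positive"/"partial"/"negative"; must cover all group sugars.
#' @return named numeric vector `c(score_I, score_II, score_III)` in [0,1].
#' @export
sugar_group_scores <- function(api_calls) {
  weights <- c(positive = 1, partial = 0.5, negative = 0)
  score <- vapply(sugar_groups, function(sugars) {
    if (!all(sugars %in% names(api_calls))) {
      stop("api_calls missing sugars: ",
           paste(setdiff(sugars, names(api_calls)), collapse = ", "),
           call. = FALSE)
    }
    v <- weights[api_calls[sugars]]
    if (anyNA(v)) stop("api calls must be positive/partial/negative",
                       call. = FALSE)
    mean(v)
  }, numeric(1))
  setNames(score, c("score_I", "score_II", "score_III"))
}
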