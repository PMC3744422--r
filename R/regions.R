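#' Per-gene loss frequency across a cohort
#'
#' Fraction of strains in which each reference gene is called
#' divergent/missing (1 minus the column mean of the presence matrix). Core
#' genes have frequency 0 by construction.
#'
#' @param matrix presence matrix.
#' @return named numeric vector over reference locus tags.
#' @export
loss_profile <- function(matrix) {
  validate_presence_matrix(matrix)
  if (nrow(matrix) < 1L) stop("need at least one strain", call. = FALSE)
  1 - colMeans(matrix)
}

#' Detect hyper-variable chromosomal regions
#'
#' Segments the reference gene order into maximal runs of frequently lost
#' genes: a region is a run of genes with loss frequency >=
#' `freq_threshold`, in which up to `max_gap` consecutive below-threshold
#' genes are tolerated, spanning at least `min_genes` genes. Regions start
#' and end on above-threshold genes, are disjoint and reported in
#' chromosome order, and are annotated with overlapping genomic-island ids
#' and IS-element counts from the annotation. Contiguity is defined in
#' gene-index space, not bp.
#'
#' @param profile loss profile from [loss_profile()], in reference order.
#' @param annotation the [reference_annotation()].
#' @param freq_threshold minimum loss frequency for a gene to seed/extend a
#'   run (default 0.10).
#' @param min_genes minimum region span in genes (default 5).
#' @param max_gap maximum below-threshold genes bridged inside a run
#'   (default 1).
#' @return data.frame of regions: `region_id`, `first_tag`, `last_tag`,
#'   `first_index`, `last_index`, `gene_count`, `mean_loss`, `max_loss`,
#'   `gi_overlap`, `is_count`.
#' @export
detect_regions <- function(profile, annotation, freq_threshold = 0.10,
                           min_genes = 5L, max_gap = 1L) {
  g <- annotation$genes
  if (length(profile) != nrow(g) ||
      !identical(names(profile), g$locus_tag)) {
    profile <- profile[g$locus_tag]
    if (anyNA(profile)) {
      stop("profile does not cover the annotation's locus tags",
           call. = FALSE)
    }
  }
  hot <- profile >= freq_threshold
  n <- length(hot)
  regions <- list()
  i <- 1L
  while (i <= n) {
    if (!hot[i]) { i <- i + 1L; next }
    start <- i
    end <- i
    j <- i + 1L
    gap <- 0L
    while (j <= n) {
      if (hot[j]) {
        end <- j
        gap <- 0L
      } else {
        gap <- gap + 1L
        if (gap > max_gap) break
      }
      j <- j + 1L
    }
    if (end - start + 1L >= min_genes) {
      regions[[length(regions) + 1L]] <- c(start = start, end = end)
    }
    i <- end + 1L
  }
  if (!length(regions)) {
    return(data.frame(region_id = integer(0), first_tag = character(0),
                      last_tag = character(0), first_index = integer(0),
                      last_index = integer(0), gene_count = integer(0),
                      mean_loss = numeric(0), max_loss = numeric(0),
                      gi_overlap = character(0), is_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(regions), function(r) {
    span <- regions[[r]]["start"]:regions[[r]]["end"]
    gis <- unique(g$island_id[span])
    gis <- gis[!is.na(gis)]
    data.frame(
      region_id = r,
      first_tag = g$locus_tag[span[1]],
      last_tag = g$locus_tag[span[length(span)]],
      first_index = span[1],
      last_index = span[length(span)],
      gene_count = length(span),
      mean_loss = mean(profile[span]),
      max_loss = max(profile[span]),
      gi_overlap = if (length(gis)) paste(gis, collapse = ",")
                   else NA_character_,
      is_count = sum(g$is_IS_element[span]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabular report of detected variable regions
#'
#' Adds, per region, a locus range string ("FIRST-LAST") and the distinct
#' annotated products of the region's genes (hypothetical/conserved
#' proteins and IS annotations collapsed to keywords).
#'
#' @param regions output of [detect_regions()].
#' @param annotation the [reference_annotation()].
#' @return data.frame extending `regions` with `locus_range` and `features`.
#' @export
region_report <- function(regions, annotation) {
  g <- annotation$genes
  if (!nrow(regions)) {
    regions$locus_range <- character(0)
    regions$features <- character(0)
    return(regions)
  }
  regions$locus_range <- paste0(regions$first_tag, "-", regions$last_tag)
  regions$features <- vapply(seq_len(nrow(regions)), function(r) {
    span <- regions$first_index[r]:regions$last_index[r]
    prods <- unique(g$product[span])
    prods <- prods[!is.na(prods)]
    paste(utils::head(prods, 6L), collapse = ", ")
  }, character(1))
  regions
}

#' Export detected regions as GFF3
#'
#' @param regions output of [detect_regions()].
#' @param annotation the [reference_annotation()].
#' @param path output GFF3 path.
#' @return invisibly, `path`.
#' @export
write_regions_gff <- function(regions, annotation, path) {
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$genome_id,
    ranges = IRanges::IRanges(
      start = g$start[regions$first_index],
      end = g$end[regions$last_index])
  )
  gr$type <- "sequence_variant_obs"
  gr$source <- "panpheno"
  gr$ID <- sprintf("region_%d", regions$region_id)
  gr$Name <- regions$locus_range %||% paste0(regions$first_tag, "-",
                                             regions$last_tag)
  gr$gene_count <- regions$gene_count
  gr$mean_loss <- regions$mean_loss
  gr$gi_overlap <- regions$gi_overlap
  gr$is_count <- regions$is_count
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
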