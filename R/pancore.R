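#' Shared gene content of each strain with the reference
#'
#' Counts, for each strain, the reference genes called present (row sums of
#' the presence matrix), plus the cohort minimum, (lower) median and
#' maximum. Percentages are truncated to one decimal via
#' [truncate_percent()].
#'
#' @param matrix presence matrix (strains x reference genes).
#' @return list with `per_strain` (data.frame strain_id, shared_count,
#'   shared_percent), `n_genes`, and `min`/`median`/`max`
#'   (each a count + percent pair).
#' @export
shared_content <- function(matrix) {
  validate_presence_matrix(matrix)
  if (nrow(matrix) < 1L) stop("empty matrix", call. = FALSE)
  n_genes <- ncol(matrix)
  counts <- rowSums(matrix)
  per_strain <- data.frame(strain_id = rownames(matrix),
                           shared_count = as.integer(counts),
                           shared_percent = truncate_percent(counts, n_genes),
                           stringsAsFactors = FALSE)
  srt <- sort(as.integer(counts))
  # lower median: an attainable row sum also for even cohort sizes
  med <- srt[floor((length(srt) + 1) / 2)]
  pair <- function(count) list(count = as.integer(count),
                               percent = truncate_percent(count, n_genes))
  list(per_strain = per_strain, n_genes = n_genes,
       min = pair(min(counts)), median = pair(med), max = pair(max(counts)))
}

#' Core genome of a strain collection
#'
#' The core is the set of reference genes present in every strain
#' (column-wise AND of the presence matrix).
#'
#' @param matrix presence matrix.
#' @return list with `core_tags`, `core_size`, `core_percent`.
#' @export
core_genome <- function(matrix) {
  validate_presence_matrix(matrix)
  if (nrow(matrix) < 1L) stop("need at least one strain", call. = FALSE)
  core <- colSums(matrix) == nrow(matrix)
  list(core_tags = colnames(matrix)[core],
       core_size = as.integer(sum(core)),
       core_percent = truncate_percent(sum(core), ncol(matrix)))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Core-genome accumulation curve
#'
#' Mean core-genome size over the first k genomes, k = 1..n, averaged over
#' random (or all) orderings of the strains. The curve is monotone
#' non-increasing and its value at k = n equals the core size regardless of
#' ordering; saturation of the curve indicates the cohort is large enough to
#' estimate the species core.
#'
#' @param matrix presence matrix.
#' @param n_permutations number of random strain orderings (>= 1).
#' @param seed integer seed for the orderings.
#' @param exact if TRUE, enumerate all n! orderings (n <= 8) instead.
#' @return data.frame with `k` and `mean_core`.
#' @export
core_accumulation <- function(matrix, n_permutations = 100, seed = 1,
                              exact = FALSE) {
  validate_presence_matrix(matrix)
  n <- nrow(matrix)
  if (!exact && n_permutations < 1) {
    stop("`n_permutations` must be >= 1", call. = FALSE)
  }
  perms <- if (exact) {
    if (n > 8L) stop("exact enumeration limited to 8 strains", call. = FALSE)
    all_permutations(n)
  } else {
    with_seed(seed, replicate(n_permutations, sample.int(n),
                              simplify = FALSE))
  }
  acc <- vapply(perms, function(p) {
    cum <- apply(matrix[p, , drop = FALSE], 2, cumprod)
    if (n == 1L) cum <- matrix(cum, nrow = 1L)
    rowSums(cum)
  }, numeric(n))
  data.frame(k = seq_len(n),
             mean_core = rowMeans(if (n == 1L) matrix(acc, nrow = 1L)
                                  else acc))
}

#' Hierarchical clustering of strains by gene content
#'
#' Clusters strains on their binary presence/absence rows, by default with
#' Jaccard distance and average linkage (UPGMA) - the standard pairing for
#' binary gene-content data. Merge order on tied heights follows
#' [stats::hclust()], which is deterministic.
#'
#' @param matrix presence matrix with >= 2 strains.
#' @param distance `"jaccard"` (binary, via [vegan::vegdist()]) or any
#'   method accepted by [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust`, `dist`, and (if `k` given) `clusters`.
#' @export
gene_content_clustering <- function(matrix, distance = "jaccard",
                                    linkage = "average", k = NULL) {
  validate_presence_matrix(matrix)
  if (nrow(matrix) < 2L) stop("need at least two strains", call. = FALSE)
  if (any(rowSums(matrix) == 0L)) {
    stop("strain with no shared genes cannot be placed", call. = FALSE)
  }
  d <- if (distance == "jaccard") {
    vegan::vegdist(matrix, method = "jaccard", binary = TRUE)
  } else {
    stats::dist(matrix, method = distance)
  }
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc, dist = d)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

# project a local alignment of gene vs window onto reference gene
# coordinates; returns a character vector of length qlen with '-' at
# unaligned positions
project_alignment <- function(al, qlen) {
  out <- rep("-", qlen)
  if (Biostrings::score(al) <= 0 || Biostrings::nchar(al) == 0) return(out)
  pch <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sch <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  qpos <- Biostrings::start(Biostrings::pattern(al)) - 1L
  for (i in seq_along(pch)) {
    if (pch[i] != "-") {
      qpos <- qpos + 1L
      out[qpos] <- sch[i]
    }
  }
  out
}

#' Reference-projected alignment of core genes across strains
#'
#' For each strain and each requested core gene, the best local alignment is
#' projected onto the reference gene coordinates, yielding one aligned
#' pseudo-sequence per strain (gaps where a position did not align).
#'
#' @param reference a [reference_annotation()] with sequence.
#' @param strains list of [strain_genome()].
#' @param core_tags locus tags to include (typically `core_genome()$core_tags`).
#' @return character matrix (strains x alignment columns).
#' @export
extract_core_alignment <- function(reference, strains, core_tags) {
  gene_seqs <- reference_gene_seqs(reference)
  core_tags <- intersect(names(gene_seqs), core_tags)
  if (length(core_tags) < 1L) stop("no core genes to align", call. = FALSE)
  gene_seqs <- gene_seqs[core_tags]
  qlen <- Biostrings::width(gene_seqs)
  rc_seqs <- Biostrings::reverseComplement(gene_seqs)
  dicts <- build_probe_dicts(gene_seqs, 11L, 7L)
  rows <- lapply(strains, function(st) {
    res <- seeded_alignments(gene_seqs, st$sequences, dicts = dicts)
    ok <- which(res$score > 0 & !is.na(res$subject))
    # re-align each best window once more to obtain the aligned strings
    windows <- Biostrings::DNAStringSet(lapply(ok, function(gi) {
      Biostrings::subseq(st$sequences[[res$subject[gi]]],
                         res$window_start[gi], res$window_end[gi])
    }))
    pats <- Biostrings::DNAStringSet(lapply(ok, function(gi) {
      if (res$strand[gi] == "+") gene_seqs[[gi]] else rc_seqs[[gi]]
    }))
    projections <- vector("list", length(gene_seqs))
    if (length(ok)) {
      al <- local_align(pats, windows)
      for (j in seq_along(ok)) {
        gi <- ok[j]
        proj <- project_alignment(al[j], qlen[gi])
        if (res$strand[gi] == "-") proj <- rev(chartr("ACGT", "TGCA", proj))
        projections[[gi]] <- proj
      }
    }
    for (gi in setdiff(seq_along(gene_seqs), ok)) {
      projections[[gi]] <- rep("-", qlen[gi])
    }
    unlist(projections)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(strains, function(s) s$strain_id, character(1))
  out
}

#' SNP distance tree over the core genome
#'
#' Computes pairwise substitution distances (proportion of differing sites,
#' pairwise deletion of gaps) over the concatenated reference-projected core
#' genes and builds a neighbor-joining tree.
#'
#' @param strains list of [strain_genome()] (>= 3).
#' @param reference a [reference_annotation()] with sequence.
#' @param core_tags core gene locus tags (>= 10 shared genes recommended).
#' @return list with `tree` ([ape::phylo]) and `dist` (distance matrix).
#' @export
snp_distance_tree <- function(strains, reference, core_tags) {
  if (length(strains) < 3L) stop("need at least three strains", call. = FALSE)
  if (length(core_tags) < 1L) stop("no shared core genes", call. = FALSE)
  aln <- extract_core_alignment(reference, strains, core_tags)
  bin <- ape::as.DNAbin(tolower(aln))
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  if (anyNA(d)) stop("no overlapping aligned sites for some strain pair",
                     call. = FALSE)
  tree <- if (length(strains) == 3L) {
    # NJ needs >= 4 leaves; solve the unrooted triple exactly
    dm <- as.matrix(d)
    ids <- rownames(dm)
    bl <- c((dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2,
            (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2,
            (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2)
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f,%s:%f);",
                                        ids[1], bl[1], ids[2], bl[2],
                                        ids[3], bl[3]))
    tr
  } else {
    ape::nj(d)
  }
  list(tree = tree, dist = d)
}

#' Concordance between two trees
#'
#' Pearson correlation between the cophenetic distance matrices of two trees
#' over their shared leaves, clamped to [0, 1]. Identical trees score 1;
#' trees with randomly shuffled leaves score near 0.
#'
#' @param tree_a,tree_b [ape::phylo] or `hclust` objects.
#' @return concordance score in [0, 1].
#' @export
tree_concordance <- function(tree_a, tree_b) {
  coph <- function(tr) {
    if (inherits(tr, "hclust")) return(as.matrix(stats::cophenetic(tr)))
    ape::cophenetic.phylo(tr)
  }
  ca <- coph(tree_a)
  cb <- coph(tree_b)
  common <- intersect(rownames(ca), rownames(cb))
  if (length(common) < 3L) stop("trees share fewer than 3 leaves",
                                call. = FALSE)
  ca <- ca[common, common]
  cb <- cb[common, common]
  lt <- lower.tri(ca)
  if (stats::sd(ca[lt]) == 0 && stats::sd(cb[lt]) == 0) return(1)
  if (stats::sd(ca[lt]) == 0 || stats::sd(cb[lt]) == 0) return(0)
  max(0, stats::cor(ca[lt], cb[lt]))
}

#' Non-core gene share per functional (COG) category
#'
#' Tallies, per COG category of the reference annotation, how many genes
#' fall outside the core genome; used to show which functions (typically
#' carbohydrate transport and metabolism) drive strain diversity.
#'
#' @param annotation a [reference_annotation()] with `cog_category` labels.
#' @param core_tags core gene locus tags.
#' @return data.frame with `cog_category`, `total`, `non_core`,
#'   `percent_non_core` (truncated percent).
#' @export
cog_partition <- function(annotation, core_tags) {
  g <- annotation$genes
  if (all(is.na(g$cog_category))) {
    stop("annotation carries no COG categories", call. = FALSE)
  }
  g$cog_category[is.na(g$cog_category)] <- "unassigned"
  cats <- sort(unique(g$cog_category))
  rows <- lapply(cats, function(cc) {
    sel <- g$cog_category == cc
    total <- sum(sel)
    non_core <- sum(sel & !(g$locus_tag %in% core_tags))
    data.frame(cog_category = cc, total = total, non_core = non_core,
               percent_non_core = truncate_percent(non_core, total),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare shared gene content between niche groups
#'
#' Computes the arithmetic mean shared-content percentage per group
#' (full precision) and a two-sided Mann-Whitney U test between the first
#' two groups. By default strains are grouped dairy vs human (intestinal,
#' oral, vaginal, other), with clinical isolates excluded.
#'
#' @param summary result of [shared_content()].
#' @param niche_labels named character vector, strain_id -> niche.
#' @param groups named list mapping group name -> niche labels included.
#' @param exclude niches dropped entirely.
#' @return list with `group_means`, `group_sizes`, `p_value`.
#' @export
niche_content_comparison <- function(summary, niche_labels,
                                     groups = list(
                                       dairy = "dairy",
                                       human = c("intestinal", "oral",
                                                 "vaginal", "other")),
                                     exclude = "clinical") {
  per <- summary$per_strain
  niche <- niche_labels[per$strain_id]
  keep <- !is.na(niche) & !(niche %in% exclude)
  per <- per[keep, ]
  niche <- niche[keep]
  pct <- per$shared_count / summary$n_genes * 100
  values <- lapply(groups, function(members) pct[niche %in% members])
  sizes <- vapply(values, length, integer(1))
  if (any(sizes == 0L)) {
    stop("group of size 0 after exclusion: ",
         paste(names(sizes)[sizes == 0], collapse = ", "), call. = FALSE)
  }
  means <- vapply(values, mean, numeric(1))
  p <- if (stats::sd(c(values[[1]], values[[2]])) == 0) {
    1  # all observations tied: no evidence of a shift
  } else {
    stats::wilcox.test(values[[1]], values[[2]], exact = FALSE,
                       correct = FALSE)$p.value
  }
  list(group_means = means, group_sizes = sizes, p_value = p)
}
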