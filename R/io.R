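#' Construct a reference annotation object
#'
#' A `reference_annotation` bundles an annotated reference chromosome: the
#' sequence, its length, and an ordered table of gene models. Genes are kept
#' sorted by start coordinate (locus tag breaks ties, since tags encode
#' chromosomal order in the reference annotation).
#'
#' @param genome_id single sequence identifier.
#' @param genome_length chromosome length in bp.
#' @param genes data.frame with columns `locus_tag`, `start`, `end`,
#'   `strand` (+/-), `product`, and optionally `cog_category`, `island_id`,
#'   `is_IS_element`. Coordinates are 1-based inclusive.
#' @param sequence optional [Biostrings::DNAString] of length `genome_length`.
#' @param islands optional data.frame describing island gene runs
#'   (`island_id`, `role`, `first_index`, `last_index`).
#' @param crispr optional CRISPR locus descriptor (see [reference_crispr()]).
#' @return an object of class `reference_annotation`.
#' @export
reference_annotation <- function(genome_id, genome_length, genes,
                                 sequence = NULL, islands = NULL,
                                 crispr = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  genome_length <- as.integer(genome_length)
  required <- c("locus_tag", "start", "end", "strand", "product")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop("`genes` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("cog_category", "island_id")) {
    if (is.null(genes[[opt]])) genes[[opt]] <- NA_character_
  }
  if (is.null(genes$is_IS_element)) genes$is_IS_element <- FALSE
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(is.na(genes$start)) || any(is.na(genes$end))) {
    stop("malformed gene coordinates", call. = FALSE)
  }
  if (any(genes$end < genes$start)) {
    stop("gene with end < start: ",
         paste(genes$locus_tag[genes$end < genes$start], collapse = ", "),
         call. = FALSE)
  }
  if (any(genes$start < 1L) || any(genes$end > genome_length)) {
    stop("gene interval outside [1, genome_length]", call. = FALSE)
  }
  if (anyDuplicated(genes$locus_tag)) {
    stop("duplicate locus tag: ",
         paste(unique(genes$locus_tag[duplicated(genes$locus_tag)]),
               collapse = ", "),
         call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  genes <- genes[order(genes$start, genes$locus_tag), , drop = FALSE]
  rownames(genes) <- NULL
  if (!is.null(sequence)) {
    sequence <- Biostrings::DNAString(sequence)
    if (length(sequence) != genome_length) {
      stop("sequence length does not match `genome_length`", call. = FALSE)
    }
  }
  structure(
    list(genome_id = genome_id, genome_length = genome_length,
         genes = genes, sequence = sequence, islands = islands,
         crispr = crispr),
    class = "reference_annotation"
  )
}

#' @export
print.reference_annotation <- function(x, ...) {
  cat(sprintf("<reference_annotation> %s: %d bp, %d genes\n",
              x$genome_id, x$genome_length, nrow(x$genes)))
  if (!is.null(x$islands)) {
    cat(sprintf("  islands: %s\n",
                paste(x$islands$island_id, collapse = ", ")))
  }
  if (!is.null(x$crispr)) {
    cat(sprintf("  CRISPR locus: %d spacers, %d cas genes\n",
                length(x$crispr$spacers), length(x$crispr$cas)))
  }
  invisible(x)
}

#' Read an annotated reference genome from FASTA + GFF3
#'
#' @param fasta_path single-record nucleotide FASTA.
#' @param gff_path GFF3 annotation; records of type `gene` are used. The
#'   `locus_tag` attribute (fallback: `ID`) names each gene; `product`,
#'   `cog_category`, `island_id` and `is_IS_element` attributes are carried
#'   through when present.
#' @return a [reference_annotation()].
#' @export
read_reference <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one sequence", call. = FALSE)
  }
  genome_id <- sub("\\s.*$", "", names(seqs)[1])
  gff <- tryCatch(
    rtracklayer::import(gff_path, format = "gff3"),
    error = function(e) stop("malformed GFF3: ", conditionMessage(e),
                             call. = FALSE)
  )
  gff <- gff[gff$type == "gene"]
  if (length(gff) == 0L) stop("GFF3 contains no gene records", call. = FALSE)
  seqids <- unique(as.character(GenomicRanges::seqnames(gff)))
  if (!identical(seqids, genome_id)) {
    stop(sprintf("GFF sequence id (%s) does not match FASTA id (%s)",
                 paste(seqids, collapse = ","), genome_id), call. = FALSE)
  }
  mc <- as.data.frame(gff)
  tag <- if (!is.null(mc$locus_tag)) mc$locus_tag else mc$ID
  if (is.null(tag) || anyNA(tag)) {
    stop("every gene record needs a locus_tag (or ID) attribute",
         call. = FALSE)
  }
  genes <- data.frame(
    locus_tag = as.character(tag),
    start = mc$start,
    end = mc$end,
    strand = as.character(mc$strand),
    product = if (!is.null(mc$product)) as.character(mc$product)
              else NA_character_,
    cog_category = if (!is.null(mc$cog_category))
      as.character(mc$cog_category) else NA_character_,
    island_id = if (!is.null(mc$island_id)) as.character(mc$island_id)
                else NA_character_,
    is_IS_element = if (!is.null(mc$is_IS_element))
      as.logical(mc$is_IS_element) else FALSE,
    stringsAsFactors = FALSE
  )
  genes$is_IS_element[is.na(genes$is_IS_element)] <- FALSE
  ref <- reference_annotation(genome_id, length(seqs[[1]]), genes,
                              sequence = seqs[[1]])
  # rebuild the island table from per-gene annotations
  gi <- ref$genes$island_id
  if (any(!is.na(gi))) {
    # realign raw GFF records to the sorted gene order
    raw_tag <- as.character(if (!is.null(mc$locus_tag)) mc$locus_tag
                            else mc$ID)
    ord <- match(ref$genes$locus_tag, raw_tag)
    gene_role <- if (!is.null(mc$island_role)) {
      as.character(mc$island_role)[ord]
    } else rep(NA_character_, nrow(ref$genes))
    ids <- unique(gi[!is.na(gi)])
    ref$islands <- do.call(rbind, lapply(ids, function(id) {
      idx <- which(gi == id)
      r <- gene_role[idx]
      r <- r[!is.na(r)]
      data.frame(island_id = id,
                 role = if (length(r)) r[1] else NA_character_,
                 first_index = min(idx), last_index = max(idx),
                 stringsAsFactors = FALSE)
    }))
  }
  ref
}

#' Write a reference annotation to FASTA + GFF3
#'
#' Inverse of [read_reference()]; island and IS-element labels are stored as
#' GFF3 attributes so a round trip preserves them.
#'
#' @param reference a [reference_annotation()] carrying a sequence.
#' @param fasta_path,gff_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta_path, gff_path) {
  stopifnot(inherits(reference, "reference_annotation"))
  if (is.null(reference$sequence)) {
    stop("reference carries no sequence", call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(reference$sequence)
  names(seqs) <- reference$genome_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  g <- reference$genes
  gr <- GenomicRanges::GRanges(
    seqnames = reference$genome_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  gr$type <- "gene"
  gr$source <- "panpheno"
  gr$ID <- g$locus_tag
  gr$locus_tag <- g$locus_tag
  gr$product <- g$product
  gr$cog_category <- g$cog_category
  gr$island_id <- g$island_id
  if (!is.null(reference$islands) && !is.null(reference$islands$role)) {
    gr$island_role <- reference$islands$role[
      match(g$island_id, reference$islands$island_id)]
  }
  gr$is_IS_element <- as.character(g$is_IS_element)
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}

validate_presence_matrix <- function(m) {
  if (!is.matrix(m)) stop("presence matrix must be a matrix", call. = FALSE)
  if (is.null(colnames(m)) || (nrow(m) > 0 && is.null(rownames(m)))) {
    stop("presence matrix needs strain rownames and locus-tag colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate strain ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate locus tags", call. = FALSE)
  if (nrow(m) > 0 && !all(m %in% c(0L, 1L))) {
    stop("presence matrix cells must be 0 or 1", call. = FALSE)
  }
  invisible(m)
}

#' Write / read a presence/absence matrix as TSV
#'
#' The native serialisation is a plain TSV with one row per strain and one
#' column per reference locus tag; cells are 1 (gene present) or 0
#' (divergent/missing gene). `read_matrix(write_matrix(m))` is bit-exact.
#'
#' @param matrix integer matrix with strain rownames and locus-tag colnames.
#' @param path file path.
#' @return `read_matrix` returns the integer matrix; `write_matrix` returns
#'   `path` invisibly.
#' @export
write_matrix <- function(matrix, path) {
  validate_presence_matrix(matrix)
  if (nrow(matrix) == 0L) {
    writeLines(paste(c("strain_id", colnames(matrix)), collapse = "\t"),
               path)
    return(invisible(path))
  }
  df <- data.frame(strain_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "strain_id") {
    stop("first column of a presence matrix TSV must be `strain_id`",
         call. = FALSE)
  }
  tags <- names(df)[-1]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) > 0) {
    storage.mode(m) <- "integer"
    if (anyNA(m) || !all(m %in% c(0L, 1L))) {
      stop("presence matrix cells must be 0 or 1", call. = FALSE)
    }
  } else {
    m <- matrix(integer(0), nrow = 0, ncol = length(tags))
  }
  rownames(m) <- df$strain_id
  colnames(m) <- tags
  validate_presence_matrix(m)
  m
}

#' Import a presence/absence table with unknown orientation
#'
#' Ingests an externally produced presence/absence table (TSV, CSV or XLSX;
#' XLSX needs the readxl package) whose orientation - strains as rows versus
#' genes as rows - is auto-detected: reference genes always outnumber
#' strains, so the longer axis is taken as the gene axis. Supply
#' `orientation` to override.
#'
#' @param path table path; extension selects the reader.
#' @param orientation `"auto"`, `"strains_as_rows"` or `"genes_as_rows"`.
#' @return integer matrix, strains in rows, locus tags in columns.
#' @export
import_presence_table <- function(path,
                                  orientation = c("auto", "strains_as_rows",
                                                  "genes_as_rows")) {
  orientation <- match.arg(orientation)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("XLSX import needs the readxl package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    stop("presence table cells must be 0 or 1", call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "auto") {
    orientation <- if (nrow(m) > ncol(m)) "genes_as_rows" else "strains_as_rows"
  }
  if (orientation == "genes_as_rows") m <- t(m)
  validate_presence_matrix(m)
  m
}

# ape's newick tokenizer drops whitespace, so labels containing spaces are
# swapped for placeholders around the ape call and restored afterwards.
quote_labels <- function(labels) {
  needs <- grepl("[ '():,;]", labels)
  labels[needs] <- sprintf("'%s'", gsub("'", "''", labels[needs]))
  labels
}

#' Write / read a phylogenetic tree in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] that preserve
#' branch lengths and quote leaf labels containing spaces or Newick
#' metacharacters.
#'
#' @param tree an [ape::phylo] object (or an `hclust`, which is converted).
#' @param path file path.
#' @return `read_newick` returns an `ape::phylo`; `write_newick` returns
#'   `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("tree leaves must be uniquely labelled", call. = FALSE)
  }
  orig <- tree$tip.label
  placeholder <- sprintf("PPTIP%06d", seq_along(orig))
  tree$tip.label <- placeholder
  txt <- ape::write.tree(tree)
  for (i in seq_along(orig)) {
    txt <- sub(placeholder[i], quote_labels(orig[i]), txt, fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("malformed newick: unbalanced parentheses", call. = FALSE)
  }
  # pull out quoted labels before handing the string to ape
  quoted <- regmatches(txt, gregexpr("'(?:[^']|'')*'", txt))[[1]]
  restored <- character(0)
  if (length(quoted)) {
    placeholder <- sprintf("PPTIP%06d", seq_along(quoted))
    restored <- gsub("''", "'", substr(quoted, 2, nchar(quoted) - 1))
    for (i in seq_along(quoted)) {
      txt <- sub(quoted[i], placeholder[i], txt, fixed = TRUE)
    }
    names(restored) <- placeholder
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  if (is.null(tree)) stop("malformed newick string", call. = FALSE)
  if (length(restored)) {
    hit <- tree$tip.label %in% names(restored)
    tree$tip.label[hit] <- unname(restored[tree$tip.label[hit]])
  }
  tree
}

#' Read a cohort niche configuration from YAML
#'
#' The YAML maps profile names to [niche_profile()] fields
#' (`niche`, `island_loss_probs`, `background_loss_prob`, `snp_rate`,
#' `spacer_retention`, `phenotype_noise`).
#'
#' @param path YAML file.
#' @return named list of [niche_profile()] objects.
#' @export
read_niche_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    x <- cfg[[nm]]
    niche_profile(
      niche_name = if (!is.null(x$niche)) x$niche else nm,
      island_loss_probs = unlist(x$island_loss_probs),
      background_loss_prob = x$background_loss_prob %||% 0.01,
      snp_rate = x$snp_rate %||% 0.02,
      spacer_retention = x$spacer_retention %||% 24L,
      phenotype_noise = x$phenotype_noise %||% 0
    )
  })
  names(out) <- names(cfg)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run manifest
#'
#' Records the package version, the master seed and the parameters of a run
#' so that any output can be regenerated. Content is deterministic (no
#' timestamps), so fixed-seed runs produce byte-identical manifests.
#'
#' @param path output JSON path.
#' @param seed master integer seed of the run.
#' @param params named list of parameters worth recording.
#' @return invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, seed, params = list()) {
  manifest <- list(
    package = "panpheno",
    version = as.character(utils::packageVersion("panpheno")),
    seed = as.integer(seed),
    params = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
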