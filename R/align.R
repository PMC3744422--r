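# Local alignment scoring used throughout the package: +2 match, -3 mismatch,
# affine gaps (open 5, extend 2). The scheme is subcritical on random DNA -
# chance local alignments stay short - while genes diverged by point
# mutations up to ~25% still extend over their full length (expected score
# per column at 20% divergence: 0.8*2 - 0.2*3 = +1).
align_scoring <- function() {
  list(mat = Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                      mismatch = -3,
                                                      baseOnly = FALSE),
       gap_opening = 5, gap_extension = 2)
}

local_align <- function(patterns, subjects) {
  sc <- align_scoring()
  Biostrings::pairwiseAlignment(patterns, subjects, type = "local",
                                substitutionMatrix = sc$mat,
                                gapOpening = sc$gap_opening,
                                gapExtension = sc$gap_extension)
}

# identity = matches / alignment columns; coverage = aligned fraction of the
# query. Both zero when nothing aligns with positive score.
alignment_stats <- function(al, query_len) {
  cols <- Biostrings::nchar(al)
  nm <- Biostrings::nmatch(al)
  id <- ifelse(cols > 0, nm / cols, 0)
  p <- Biostrings::pattern(al)
  cov <- ifelse(cols > 0,
                (Biostrings::end(p) - Biostrings::start(p) + 1) / query_len,
                0)
  mf <- nm / query_len  # matched fraction of the whole query; trim-invariant
  sc <- Biostrings::score(al)
  bad <- sc <= 0
  id[bad] <- 0
  cov[bad] <- 0
  mf[bad] <- 0
  data.frame(identity = pmin(id, 1), coverage = pmin(cov, 1),
             match_frac = pmin(mf, 1), score = sc)
}

probe_starts <- function(len, k, stride) {
  if (len < k) return(integer(0))
  unique(c(seq.int(1L, len - k + 1L, by = stride), len - k + 1L))
}

# k-mer probe dictionaries for a set of query genes, forward and
# reverse-complement, used to anchor candidate alignment windows
build_probe_dicts <- function(query_seqs, k, stride) {
  qchr <- as.character(query_seqs)
  rchr <- as.character(Biostrings::reverseComplement(query_seqs))
  make <- function(chr) {
    starts <- lapply(nchar(chr), probe_starts, k = k, stride = stride)
    n <- lengths(starts)
    qidx <- rep(seq_along(chr), n)
    qpos <- unlist(starts, use.names = FALSE)
    probes <- unname(substring(chr[qidx], qpos, qpos + k - 1L))
    keep <- !grepl("[^ACGT]", probes)
    list(pdict = Biostrings::PDict(Biostrings::DNAStringSet(probes[keep])),
         query = qidx[keep], qpos = qpos[keep])
  }
  list(fwd = make(qchr), rc = make(rchr),
       rc_seqs = Biostrings::reverseComplement(query_seqs), k = k)
}

match_anchors <- function(dict, subject) {
  mi <- Biostrings::matchPDict(dict$pdict, subject)
  n <- S4Vectors::elementNROWS(mi)
  if (sum(n) == 0L) {
    return(data.frame(query = integer(0), qpos = integer(0),
                      spos = integer(0)))
  }
  data.frame(query = rep(dict$query, n),
             qpos = rep(dict$qpos, n),
             spos = unlist(Biostrings::startIndex(mi), use.names = FALSE))
}

# candidate windows from anchor diagonals: anchors are binned by diagonal
# (subject pos - query pos); each well-supported bin, with its neighbours,
# defines one window on the subject
candidate_windows <- function(anchors, query_len, subject_len, pad,
                              n_windows, bin_width = 30L) {
  if (!nrow(anchors)) return(NULL)
  diag <- anchors$spos - anchors$qpos
  bin <- round(diag / bin_width)
  tab <- sort(table(bin), decreasing = TRUE)
  bins <- as.integer(names(tab))[seq_len(min(n_windows, length(tab)))]
  out <- lapply(bins, function(b) {
    sel <- abs(bin - b) <= 1L
    d <- diag[sel]
    c(count = sum(sel),
      start = max(1L, min(d) + 1L - pad),
      end = min(subject_len, max(d) + query_len + pad))
  })
  do.call(rbind, out)
}

# Core engine: best local alignment of each query against a set of subject
# sequences (both strands). Small subjects are aligned exactly; large ones
# through k-mer anchored windows. Candidate windows are ranked per query by
# anchor support across strands and subjects, and windows supported by fewer
# than a quarter of the best window's anchors are not aligned - chance
# k-mer hits on the wrong strand rarely survive this filter.
seeded_alignments <- function(query_seqs, subject_seqs, k = 11L,
                              stride = 7L, pad = 60L, n_windows = 2L,
                              dp_limit = 10000L, dicts = NULL,
                              min_anchors = 1L) {
  nq <- length(query_seqs)
  qlen <- Biostrings::width(query_seqs)
  b_mf <- numeric(nq)
  b_id <- numeric(nq); b_cov <- numeric(nq); b_score <- rep(-Inf, nq)
  b_sub <- rep(NA_integer_, nq); b_str <- rep(NA_character_, nq)
  b_ws <- rep(NA_integer_, nq); b_we <- rep(NA_integer_, nq)
  take_best <- function(stats, qidx, subj_idx, strand, ws, we) {
    for (r in seq_along(qidx)) {
      i <- qidx[r]
      if (stats$score[r] > b_score[i]) {
        b_id[i] <<- stats$identity[r]
        b_cov[i] <<- stats$coverage[r]
        b_mf[i] <<- stats$match_frac[r]
        b_score[i] <<- stats$score[r]
        b_sub[i] <<- subj_idx
        b_str[i] <<- strand
        b_ws[i] <<- ws[r]
        b_we[i] <<- we[r]
      }
    }
  }
  small <- Biostrings::width(subject_seqs) <= dp_limit
  rc_seqs <- NULL
  for (si in seq_along(subject_seqs)) {
    subject <- subject_seqs[[si]]
    if (small[si]) {
      for (strand in c("+", "-")) {
        pats <- if (strand == "+") query_seqs else {
          if (is.null(rc_seqs)) {
            rc_seqs <- Biostrings::reverseComplement(query_seqs)
          }
          rc_seqs
        }
        al <- local_align(pats, subject)
        take_best(alignment_stats(al, qlen), seq_len(nq), si, strand,
                  rep(1L, nq), rep(length(subject), nq))
      }
    } else {
      if (is.null(dicts)) dicts <- build_probe_dicts(query_seqs, k, stride)
      # gather candidate windows from both strands, then filter by support
      cand_q <- integer(0); cand_s <- integer(0); cand_e <- integer(0)
      cand_n <- integer(0); cand_strand <- character(0)
      for (strand in c("+", "-")) {
        d <- if (strand == "+") dicts$fwd else dicts$rc
        anchors <- match_anchors(d, subject)
        if (!nrow(anchors)) next
        by_query <- split(anchors, anchors$query)
        for (qs in names(by_query)) {
          qi <- as.integer(qs)
          w <- candidate_windows(by_query[[qs]], qlen[qi], length(subject),
                                 pad, n_windows)
          if (is.null(w)) next
          cand_q <- c(cand_q, rep(qi, nrow(w)))
          cand_s <- c(cand_s, w[, "start"])
          cand_e <- c(cand_e, w[, "end"])
          cand_n <- c(cand_n, w[, "count"])
          cand_strand <- c(cand_strand, rep(strand, nrow(w)))
        }
      }
      if (!length(cand_q)) next
      # per query: keep at most n_windows windows, dropping those with less
      # than a quarter of the best window's anchor support
      sel <- unlist(lapply(split(seq_along(cand_q), cand_q), function(idx) {
        idx <- idx[order(-cand_n[idx])]
        idx <- idx[cand_n[idx] >= max(min_anchors, cand_n[idx][1] / 4)]
        utils::head(idx, n_windows)
      }), use.names = FALSE)
      if (!length(sel)) next
      for (strand in c("+", "-")) {
        ss <- sel[cand_strand[sel] == strand]
        if (!length(ss)) next
        windows <- Biostrings::extractAt(
          subject, IRanges::IRanges(start = cand_s[ss], end = cand_e[ss]))
        pats <- if (strand == "+") query_seqs[cand_q[ss]]
                else dicts$rc_seqs[cand_q[ss]]
        al <- local_align(pats, windows)
        take_best(alignment_stats(al, qlen[cand_q[ss]]), cand_q[ss], si,
                  strand, cand_s[ss], cand_e[ss])
      }
    }
  }
  b_score[!is.finite(b_score)] <- 0
  data.frame(identity = b_id, coverage = b_cov, match_frac = b_mf,
             score = b_score, subject = b_sub, strand = b_str,
             window_start = b_ws, window_end = b_we)
}

#' Align one reference gene against a strain's sequences
#'
#' Finds the best local alignment of a gene in a strain genome (all contigs,
#' both strands) and reports its identity (matches over alignment columns)
#' and coverage (aligned fraction of the gene). Subjects up to `dp_limit` bp
#' are aligned by full local dynamic programming; larger subjects are first
#' anchored with exact k-mer probe matches and then aligned inside the
#' anchored window, which gives identical results whenever the true locus is
#' anchored.
#'
#' @param gene_seq [Biostrings::DNAString] (or string) of the gene, >= 30 bp.
#' @param strain_seqs [Biostrings::DNAStringSet] of strain contigs.
#' @param k,stride k-mer length and spacing of the anchor probes.
#' @param pad bp of context added around the anchored window.
#' @param dp_limit subject size up to which exact DP is used directly.
#' @return list with `identity`, `coverage`, `score`, `subject` (contig
#'   index) and `strand`.
#' @export
align_gene <- function(gene_seq, strain_seqs, k = 11L, stride = 7L,
                       pad = 60L, dp_limit = 10000L) {
  gene_seq <- Biostrings::DNAStringSet(gene_seq)
  if (Biostrings::width(gene_seq)[1] < 30L) {
    stop("gene must be at least 30 bp", call. = FALSE)
  }
  strain_seqs <- Biostrings::DNAStringSet(strain_seqs)
  if (length(strain_seqs) == 0L) {
    stop("empty strain sequence set", call. = FALSE)
  }
  res <- seeded_alignments(gene_seq, strain_seqs, k = k, stride = stride,
                           pad = pad, n_windows = 3L, dp_limit = dp_limit)
  as.list(res[1, ])
}

#' Call one gene present or absent in a strain
#'
#' A gene is called `present` when its best alignment reaches both the
#' identity threshold (default 0.40, inclusive, following the synteny-block
#' identity criterion of the study design) and the coverage threshold
#' (default 0.80, the package's surrogate for partial-overlap handling: a
#' half-deleted gene scores absent).
#'
#' @param gene either a list with `identity`/`coverage` (as returned by
#'   [align_gene()]) or a gene sequence to align against `strain`.
#' @param strain a [strain_genome()] or [Biostrings::DNAStringSet]; ignored
#'   when `gene` already carries alignment statistics.
#' @param identity_threshold,coverage_threshold inclusive thresholds.
#' @return list with `status` ("present"/"absent"), `best_identity`,
#'   `best_coverage`.
#' @export
call_gene <- function(gene, strain = NULL, identity_threshold = 0.40,
                      coverage_threshold = 0.80) {
  if (is.list(gene) && !is.null(gene$identity)) {
    id <- gene$identity
    cov <- gene$coverage
  } else {
    seqs <- if (inherits(strain, "strain_genome")) strain$sequences
            else Biostrings::DNAStringSet(strain)
    res <- align_gene(gene, seqs)
    id <- res$identity
    cov <- res$coverage
  }
  status <- if (id >= identity_threshold && cov >= coverage_threshold) {
    "present"
  } else "absent"
  list(status = status, best_identity = id, best_coverage = cov)
}

reference_gene_seqs <- function(reference) {
  if (is.null(reference$sequence)) {
    stop("reference carries no sequence", call. = FALSE)
  }
  g <- reference$genes
  seqs <- Biostrings::extractAt(
    reference$sequence, IRanges::IRanges(start = g$start, end = g$end))
  names(seqs) <- g$locus_tag
  seqs
}

#' Build a presence/absence matrix for a strain cohort
#'
#' Calls every reference gene present (1) or divergent/missing (0) in every
#' strain. Rows are strains, columns are the reference genes in chromosome
#' order. The per-gene best identity and coverage are attached as
#' `"identity"` and `"coverage"` matrix attributes for diagnostics.
#'
#' @param reference a [reference_annotation()] with sequence.
#' @param strains list of [strain_genome()] objects (or a single one).
#' @param identity_threshold,coverage_threshold call thresholds, see
#'   [call_gene()].
#' @param k,stride anchor probe k-mer length and spacing.
#' @return integer presence matrix.
#' @export
build_presence_matrix <- function(reference, strains,
                                  identity_threshold = 0.40,
                                  coverage_threshold = 0.80,
                                  k = 11L, stride = 7L) {
  if (inherits(strains, "strain_genome")) strains <- list(strains)
  if (length(strains) < 1L) stop("need at least one strain", call. = FALSE)
  gene_seqs <- reference_gene_seqs(reference)
  ids <- vapply(strains, function(s) s$strain_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate strain ids", call. = FALSE)
  dicts <- build_probe_dicts(gene_seqs, k, stride)
  n_genes <- length(gene_seqs)
  m <- matrix(0L, nrow = length(strains), ncol = n_genes,
              dimnames = list(ids, names(gene_seqs)))
  idm <- m * 0
  covm <- m * 0
  for (i in seq_along(strains)) {
    res <- seeded_alignments(gene_seqs, strains[[i]]$sequences,
                             k = k, stride = stride, dicts = dicts)
    present <- res$identity >= identity_threshold &
      res$coverage >= coverage_threshold
    m[i, ] <- as.integer(present)
    idm[i, ] <- res$identity
    covm[i, ] <- res$coverage
  }
  attr(m, "identity") <- idm
  attr(m, "coverage") <- covm
  validate_presence_matrix(m)
  m
}
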