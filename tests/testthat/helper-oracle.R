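# Independent Smith-Waterman (Gotoh affine) oracle, pure R. Used to verify
# the package's aligner; deliberately shares no code with it. Gap of length
# L costs open + extend * L.
sw_oracle <- function(pattern, subject, match = 2, mismatch = -3,
                      open = 5, extend = 2) {
  p <- strsplit(toupper(as.character(pattern)), "")[[1]]
  s <- strsplit(toupper(as.character(subject)), "")[[1]]
  n <- length(p)
  m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in pattern (move along subject)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (move along pattern)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      sub <- if (p[i - 1] == s[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
    }
  }
  best <- unname(which(H == max(H), arr.ind = TRUE)[1, ])
  score <- max(H)
  if (score <= 0) {
    return(list(score = 0, identity = 0, coverage = 0, matches = 0))
  }
  # traceback
  i <- best[1]; j <- best[2]
  matches <- 0L; cols <- 0L
  p_end <- i - 1L
  state <- "H"
  while (i > 1 && j > 1) {
    if (state == "H") {
      if (H[i, j] == 0) break
      sub <- if (p[i - 1] == s[j - 1]) match else mismatch
      if (H[i, j] == H[i - 1, j - 1] + sub) {
        matches <- matches + (p[i - 1] == s[j - 1])
        cols <- cols + 1L
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      cols <- cols + 1L
      if (E[i, j] == H[i, j - 1] - open - extend) state <- "H"
      j <- j - 1L
    } else {
      cols <- cols + 1L
      if (F[i, j] == H[i - 1, j] - open - extend) state <- "H"
      i <- i - 1L
    }
  }
  p_start <- i  # i is 1 + (0-based pattern index of alignment start)
  list(score = score, identity = matches / cols,
       coverage = (p_end - p_start + 1) / n, matches = matches)
}

# Brute-force UPGMA: returns sorted merge heights
upgma_heights_oracle <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    mean(dm[a, b])
  }
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (x in seq_along(active)) {
      for (y in seq_len(x - 1)) {
        h <- cluster_dist(active[[x]], active[[y]])
        if (h < bh) { bh <- h; best <- c(x, y) }
      }
    }
    heights <- c(heights, bh)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  sort(heights)
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# substitute a fraction of positions (never producing the same base)
mutate_seq <- function(seq, positions) {
  chars <- strsplit(as.character(seq), "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# truth presence row for a simulated strain
truth_row <- function(reference, strain) {
  tr <- stats::setNames(rep(1L, nrow(reference$genes)),
                        reference$genes$locus_tag)
  tr[strain$truth$lost_gene_tags] <- 0L
  tr
}

# small shared fixtures, built once per test run
tiny_ref <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_reference(n_genes = 40, n_islands = 2,
                                 island_sizes = c(5L, 6L),
                                 genome_length = 40000, seed = 101,
                                 n_spacers = 8, n_cas = 2)
    }
    val
  }
})

std_ref <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_reference(seed = 1)
    val
  }
})
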