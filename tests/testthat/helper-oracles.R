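# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive re-derivations (per-site loops, whole-genome
# translation) kept independent of the implementation they check.

# build a snp_matrix directly from a sites x isolates alt-frequency
# specification at fixed depth with no sampling noise
toy_matrix <- function(freqs, depth = 1000, ref = NULL, alt = NULL,
                       positions = NULL, reference_length = 10000) {
  n <- nrow(freqs)
  iso <- colnames(freqs) %||% paste0("iso", seq_len(ncol(freqs)))
  positions <- positions %||% seq(10, by = 10, length.out = n)
  ref <- ref %||% rep("A", n)
  alt <- alt %||% rep("G", n)
  depth <- if (length(depth) == 1) matrix(depth, n, ncol(freqs)) else depth
  counts <- array(0L, c(n, ncol(freqs), 4L),
                  dimnames = list(NULL, iso, c("A", "C", "G", "T")))
  for (i in seq_len(n)) for (j in seq_len(ncol(freqs))) {
    ac <- round(depth[i, j] * freqs[i, j])
    counts[i, j, alt[i]] <- as.integer(ac)
    counts[i, j, ref[i]] <- as.integer(depth[i, j] - ac)
  }
  snp_matrix(positions, ref, counts, isolates = iso,
             reference_length = reference_length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force specificity oracle: enumerate the variability rule per site
# and isolate directly from raw counts
oracle_specificity <- function(x, cfg = filter_config()) {
  depth <- apply(x$counts, c(1, 2), sum)
  totals <- apply(x$counts, c(1, 3), sum)
  labels <- character(0)
  positions <- integer(0)
  for (i in seq_len(length(x$position))) {
    tt <- totals[i, ]
    tt[x$ref[i]] <- -1
    if (max(tt) <= 0) next
    alt <- names(tt)[which.max(tt)]
    vars <- character(0)
    for (s in x$isolates) {
      d <- depth[i, s]
      ac <- x$counts[i, s, alt]
      if (d > cfg$min_total_depth && ac > cfg$min_alt_count &&
          d > 0 && ac / d > cfg$min_freq)
        vars <- c(vars, s)
    }
    if (length(vars) == 0) next
    positions <- c(positions, x$position[i])
    labels <- c(labels, paste(vars, collapse = "."))
  }
  data.frame(position = positions, label = labels,
             stringsAsFactors = FALSE)
}

# whole-genome translation oracle: rebuild the mutated genome and translate
# every ORF of the annotation in full; a SNP is synonymous in an ORF iff
# the two protein sequences are identical
oracle_synonymy <- function(position, alt_base, ann, reference) {
  mut <- reference$seq
  substr(mut, position, position) <- alt_base
  orf_seq <- function(genome, orf) {
    s <- if (orf$wraps)
      paste0(substr(genome, orf$start, reference$length),
             substr(genome, 1, orf$end))
    else substr(genome, orf$start, orf$end)
    if (orf$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  out <- list()
  for (i in seq_len(nrow(ann))) {
    orf <- ann[i, ]
    contained <- if (orf$wraps) position >= orf$start | position <= orf$end
      else position >= orf$start & position <= orf$end
    if (!contained) next
    p0 <- as.character(Biostrings::translate(
      Biostrings::DNAString(orf_seq(reference$seq, orf))))
    p1 <- as.character(Biostrings::translate(
      Biostrings::DNAString(orf_seq(mut, orf))))
    out[[orf$id]] <- identical(p0, p1)
  }
  out
}

# random annotation over a reference: non-overlapping ORFs on both strands,
# optionally one wrap-around ORF; lengths are multiples of 3
random_annotation <- function(reference, n_orfs = 5, wrap = TRUE) {
  L <- reference$length
  starts <- seq(50, L - 2000, length.out = n_orfs)
  ids <- sprintf("orf%02d", seq_len(n_orfs))
  lens <- 3 * sample(100:300, n_orfs)
  ann <- data.frame(id = ids, start = round(starts),
                    end = round(starts) + lens - 1,
                    strand = sample(c("+", "-"), n_orfs, replace = TRUE),
                    function_class = sample(ORF_CLASSES, n_orfs,
                                            replace = TRUE),
                    stringsAsFactors = FALSE)
  if (wrap) {
    wlen <- 3 * 120
    ann <- rbind(ann, data.frame(id = "orfwrap", start = L - wlen %/% 2 + 1,
                                 end = wlen - wlen %/% 2,
                                 strand = "+",
                                 function_class = "unknown",
                                 stringsAsFactors = FALSE))
  }
  orf_annotation(ann$id, ann$start, ann$end, ann$strand, ann$function_class,
                 reference_length = L, circular = TRUE)
}

# adjusted-Rand-free partition comparison: TRUE iff two labelings induce
# the same partition
same_partition <- function(a, b) {
  ta <- split(seq_along(a), a)
  tb <- split(seq_along(b), b)
  setequal(lapply(ta, sort), lapply(tb, sort))
}
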