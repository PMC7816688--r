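#' Specification of a flank-anchored tandem-repeat region
#'
#' The repeat locus is defined by a unique upstream flank, a unique
#' downstream flank, and the repeat unit between them (study case: a 12 nt
#' motif with 12 bp upstream and 10 bp downstream flanks in the pe38 gene).
#' Flanks shorter than 6 nt are rejected as too ambiguous, and neither flank
#' may contain a full copy of the motif.
#'
#' @param upstream_flank sequence immediately 5' of the repeat array
#' @param downstream_flank sequence immediately 3' of the repeat array
#' @param motif the repeat unit (study motif: GACACAGTGGAT)
#' @return a list of class `repeat_region_spec`
#' @export
repeat_region_spec <- function(upstream_flank, downstream_flank,
                               motif = "GACACAGTGGAT") {
  upstream_flank <- toupper(upstream_flank)
  downstream_flank <- toupper(downstream_flank)
  motif <- toupper(motif)
  if (nchar(upstream_flank) < 6 || nchar(downstream_flank) < 6)
    stop("flanks must be at least 6 nt (ambiguity guard)")
  if (grepl(motif, upstream_flank, fixed = TRUE) ||
      grepl(motif, downstream_flank, fixed = TRUE))
    stop("flanks must not contain a full copy of the motif")
  structure(list(upstream_flank = upstream_flank,
                 downstream_flank = downstream_flank,
                 motif = motif, unit_length = nchar(motif)),
            class = "repeat_region_spec")
}

match_starts <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

scan_read <- function(seq, spec, verify_motif = TRUE) {
  # returns list(status, copies); status one of informative, irregular,
  # chimeric, ambiguous, uninformative
  up <- match_starts(seq, spec$upstream_flank)
  dn <- match_starts(seq, spec$downstream_flank)
  if (length(up) == 0 || length(dn) == 0)
    return(list(status = "uninformative", copies = NA_integer_))
  if (length(up) > 1 || length(dn) > 1)
    return(list(status = "ambiguous", copies = NA_integer_))
  up_end <- up + nchar(spec$upstream_flank) - 1L
  if (dn <= up_end)
    return(list(status = "uninformative", copies = NA_integer_))
  distance <- dn - up_end - 1L
  if (distance %% spec$unit_length != 0L)
    return(list(status = "irregular", copies = NA_integer_))
  k <- distance %/% spec$unit_length
  if (verify_motif && k > 0) {
    spanned <- substr(seq, up_end + 1L, dn - 1L)
    if (spanned != strrep(spec$motif, k))
      return(list(status = "chimeric", copies = NA_integer_))
  }
  list(status = "informative", copies = k)
}

#' Count repeat-motif copies per read, anchored by both flanks
#'
#' A read is informative iff both flanks occur exactly once on the same
#' strand, upstream before downstream; each read is also scanned as its
#' reverse complement, so the histogram is strand-symmetric. The copy number
#' is the flank-to-flank distance divided by the unit length; non-multiple
#' distances are tallied as "irregular", reads whose spanned sequence is not
#' tandem copies of the motif as "chimeric" (disable with
#' `verify_motif = FALSE`), and reads with repeated flank occurrences as
#' "ambiguous".
#'
#' @param reads FASTA/FASTQ path, a `Biostrings::DNAStringSet`, or a
#'   character vector of read sequences.
#' @param spec a [repeat_region_spec]
#' @param verify_motif require the spanned sequence to be exact tandem
#'   copies of the motif (default TRUE)
#' @return list of class `repeat_histogram`: `counts` (named vector, copy
#'   number to read count), `freq`, `n_informative`, `n_reads`,
#'   `n_irregular`, `n_chimeric`, `n_ambiguous`
#' @export
count_repeats <- function(reads, spec, verify_motif = TRUE) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  seqs <- toupper(as.character(reads))
  status <- character(length(seqs))
  copies <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    r <- scan_read(seqs[i], spec, verify_motif)
    if (r$status == "uninformative") {
      r <- scan_read(revcomp(seqs[i]), spec, verify_motif)
    }
    status[i] <- r$status
    copies[i] <- if (is.na(r$copies)) NA_integer_ else r$copies
  }
  inf <- status == "informative"
  counts <- table(copies[inf])
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(counts = counts,
                 freq = if (sum(counts)) counts / sum(counts) else counts,
                 n_informative = sum(inf), n_reads = length(seqs),
                 n_irregular = sum(status == "irregular"),
                 n_chimeric = sum(status == "chimeric"),
                 n_ambiguous = sum(status == "ambiguous")),
            class = "repeat_histogram")
}

#' @method print repeat_histogram
#' @param x object to print
#' @param ... unused
#' @export
print.repeat_histogram <- function(x, ...) {
  cat(sprintf("repeat_histogram: %d informative of %d reads\n",
              x$n_informative, x$n_reads))
  if (length(x$counts))
    for (k in names(x$counts))
      cat(sprintf("  %sx: %d (%.1f%%)\n", k, x$counts[[k]],
                  100 * x$freq[[k]]))
  invisible(x)
}

#' Summarise repeat histograms across an isolate panel
#'
#' Per-isolate percentages for every observed copy-number class, the
#' dominant class, and (optionally) a flag for isolates whose dominant class
#' differs from a stated reference class. Isolates with zero informative
#' reads are reported with n = 0 and no frequencies.
#'
#' @param histograms named list of [count_repeats()] results (names =
#'   isolate ids)
#' @param reference_class optional copy number (integer) to compare dominant
#'   classes against
#' @return data.frame: isolate, n_informative, one `pct_<k>x` column per
#'   copy class, `dominant`, and `differs` when a reference class is given
#' @export
summarize_repeat_panel <- function(histograms, reference_class = NULL) {
  if (length(histograms) == 0) stop("need at least one histogram")
  classes <- sort(unique(as.integer(unlist(lapply(histograms, function(h)
    names(h$counts))))))
  rows <- lapply(names(histograms), function(id) {
    h <- histograms[[id]]
    pct <- setNames(rep(NA_real_, length(classes)),
                    paste0("pct_", classes, "x"))
    dominant <- NA_integer_
    if (h$n_informative > 0) {
      for (k in classes) {
        v <- unname(h$freq[as.character(k)])
        pct[paste0("pct_", k, "x")] <- if (length(v) == 0 || is.na(v)) 0
          else 100 * v
      }
      dominant <- as.integer(names(h$counts)[which.max(h$counts)])
    }
    cbind(data.frame(isolate = id, n_informative = h$n_informative,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(pct)), data.frame(dominant = dominant))
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference_class))
    out$differs <- !is.na(out$dominant) & out$dominant != reference_class
  out
}
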