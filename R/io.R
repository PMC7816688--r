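#' Read a per-site nucleotide count table
#'
#' Two TSV dialects are supported and auto-detected from the header:
#' \describe{
#'   \item{counts}{columns `position`, `ref`, then per-isolate columns
#'     `<id>:A`, `<id>:C`, `<id>:G`, `<id>:T` (optionally `<id>:depth`,
#'     validated against the sum of the four base counts).}
#'   \item{refalt}{the reduced supplementary-table dialect: columns
#'     `position`, `ref`, `alt`, then per-isolate `<id>:ref` and `<id>:alt`
#'     counts. The two bases not named by `ref`/`alt` receive zero counts.}
#' }
#'
#' Rows violating invariants (negative counts, duplicate positions, depth
#' mismatch, position beyond the reference length) are rejected with their
#' row number.
#'
#' @param path TSV file path.
#' @param dialect "auto" (default), "counts" or "refalt".
#' @param reference_name,reference_length,circular reference metadata; the
#'   length defaults to the largest position seen.
#' @return a [snp_matrix]
#' @export
read_count_table <- function(path, dialect = c("auto", "counts", "refalt"),
                             reference_name = "reference",
                             reference_length = NULL, circular = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  h <- names(tab)
  if (!all(c("position", "ref") %in% h))
    stop("malformed header: need `position` and `ref` columns")
  tab$position <- as.numeric(tab$position)
  if (dialect == "auto")
    dialect <- if ("alt" %in% h) "refalt" else "counts"
  reference_length <- reference_length %||% max(tab$position)
  n <- nrow(tab)

  bad_row <- function(i, why) stop(sprintf("row %d rejected: %s", i, why))
  for (i in seq_len(n)) {
    if (tab$position[i] < 1 || tab$position[i] > reference_length)
      bad_row(i, "position beyond reference_length")
  }
  if (anyDuplicated(tab$position))
    bad_row(which(duplicated(tab$position))[1], "duplicate position")

  if (dialect == "counts") {
    base_cols <- grep(":[ACGT]$", h, value = TRUE)
    ids <- unique(sub(":[ACGT]$", "", base_cols))
    if (length(ids) == 0) stop("malformed header: no `<id>:<base>` columns")
    missing <- unlist(lapply(ids, function(id)
      setdiff(paste0(id, ":", BASES), h)))
    if (length(missing))
      stop("malformed header: missing columns ", paste(missing, collapse = ", "))
    counts <- array(0L, c(n, length(ids), 4L),
                    dimnames = list(NULL, ids, BASES))
    for (id in ids) for (b in BASES)
      counts[, id, b] <- as.integer(tab[[paste0(id, ":", b)]])
    if (any(counts < 0, na.rm = TRUE))
      bad_row(which(apply(counts < 0, 1, any))[1], "negative count")
    depth_cols <- intersect(paste0(ids, ":depth"), h)
    for (dc in depth_cols) {
      id <- sub(":depth$", "", dc)
      claimed <- as.integer(tab[[dc]])
      actual <- rowSums(counts[, id, , drop = FALSE])
      if (any(claimed != actual))
        bad_row(which(claimed != actual)[1],
                sprintf("depth field for isolate %s does not equal the sum of base counts", id))
    }
  } else {
    if (!all(tab$alt %in% BASES) || any(tab$alt == tab$ref))
      bad_row(which(!(tab$alt %in% BASES) | tab$alt == tab$ref)[1],
              "invalid alt base")
    rcols <- grep(":ref$", h, value = TRUE)
    ids <- sub(":ref$", "", rcols)
    if (length(ids) == 0 || !all(paste0(ids, ":alt") %in% h))
      stop("malformed header: need paired `<id>:ref` and `<id>:alt` columns")
    counts <- array(0L, c(n, length(ids), 4L),
                    dimnames = list(NULL, ids, BASES))
    for (id in ids) {
      rc <- as.integer(tab[[paste0(id, ":ref")]])
      ac <- as.integer(tab[[paste0(id, ":alt")]])
      if (any(rc < 0 | ac < 0, na.rm = TRUE))
        bad_row(which(rc < 0 | ac < 0)[1], "negative count")
      for (i in seq_len(n)) {
        counts[i, id, tab$ref[i]] <- rc[i]
        counts[i, id, tab$alt[i]] <- ac[i]
      }
    }
  }
  snp_matrix(tab$position, tab$ref, counts,
             reference_name = reference_name,
             reference_length = reference_length, circular = circular)
}

#' Write a count table to TSV
#'
#' @param x a [snp_matrix]
#' @param path output path
#' @param dialect "counts" writes the four-base dialect read back by
#'   [read_count_table()]
#' @return `path`, invisibly
#' @export
write_count_table <- function(x, path, dialect = "counts") {
  tab <- data.frame(position = x$position, ref = x$ref,
                    check.names = FALSE)
  for (id in x$isolates) for (b in BASES)
    tab[[paste0(id, ":", b)]] <- x$counts[, id, b]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample allele depths from a multi-sample VCF
#'
#' The per-sample AD field (reference depth followed by one depth per ALT
#' allele) is mapped onto the four-base count model; multi-allelic records
#' are expanded so that every ALT base receives its own count.
#'
#' @param path VCF file path (plain text or bgzip).
#' @param reference_name,reference_length,circular reference metadata.
#' @return a [snp_matrix]
#' @export
read_vcf_counts <- function(path, reference_name = "reference",
                            reference_length = NULL, circular = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- v@gt[, 1]
  if (!all(grepl("AD", fmt))) stop("missing allele-depth (AD) field")
  samples <- colnames(v@gt)[-1]
  if (anyDuplicated(samples)) stop("sample names not unique")
  ad <- vcfR::extract.gt(v, element = "AD")
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  n <- length(pos)
  counts <- array(0L, c(n, length(samples), 4L),
                  dimnames = list(NULL, samples, BASES))
  for (i in seq_len(n)) {
    alleles <- c(ref[i], strsplit(alt[i], ",", fixed = TRUE)[[1]])
    alleles[alleles == "."] <- NA
    for (s in samples) {
      d <- suppressWarnings(as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
      for (k in seq_along(alleles)) {
        a <- alleles[k]
        if (!is.na(a) && a %in% BASES && k <= length(d) && !is.na(d[k]))
          counts[i, s, a] <- counts[i, s, a] + d[k]
      }
    }
  }
  reference_length <- reference_length %||% max(pos)
  snp_matrix(pos, ref, counts, reference_name = reference_name,
             reference_length = reference_length, circular = circular)
}

#' Write a SNP matrix as a minimal multi-sample VCF
#'
#' Every record carries the three non-reference bases as ALT alleles and a
#' per-sample AD field with the four counts, so that
#' [read_vcf_counts()] recovers the matrix exactly.
#'
#' @param x a [snp_matrix]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf_counts <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", x$reference_name,
                       x$reference_length),
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$isolates), collapse = "\t")), con)
  for (i in seq_len(n_sites(x))) {
    alts <- setdiff(BASES, x$ref[i])
    ad <- vapply(x$isolates, function(s)
      paste(x$counts[i, s, c(x$ref[i], alts)], collapse = ","), character(1))
    writeLines(paste(c(x$reference_name, x$position[i], ".", x$ref[i],
                       paste(alts, collapse = ","), ".", "PASS", ".",
                       "AD", ad), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a single-record reference genome FASTA
#'
#' @param path FASTA file with exactly one record.
#' @param circular logical; declared circularity of the genome.
#' @param allow_ambiguity logical; accept IUPAC ambiguity codes (they are
#'   rejected later if they coincide with a SNP-bearing position).
#' @return a `reference_genome`: list with `name`, `seq` (upper-case
#'   character string), `length`, `circular`.
#' @export
read_reference <- function(path, circular = FALSE, allow_ambiguity = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file")
  if (length(ss) > 1) stop("multi-record FASTA; a single reference is required")
  seq <- toupper(as.character(ss[[1]]))
  extra <- setdiff(unique(strsplit(seq, "")[[1]]), BASES)
  if (length(extra) && !allow_ambiguity)
    stop("non-ACGT characters in reference: ", paste(extra, collapse = ""))
  if (length(setdiff(extra, strsplit("RYSWKMBDHVN", "")[[1]])))
    stop("invalid characters in reference")
  reference_genome(seq, name = sub("\\s.*$", "", names(ss)[1]),
                   circular = circular)
}

#' Construct a reference genome object
#' @param seq character string of the sequence (A/C/G/T plus IUPAC codes)
#' @param name sequence name
#' @param circular declared circularity
#' @return a `reference_genome`
#' @export
reference_genome <- function(seq, name = "reference", circular = FALSE) {
  structure(list(name = name, seq = toupper(seq), length = nchar(seq),
                 circular = isTRUE(circular)),
            class = "reference_genome")
}

#' @method print reference_genome
#' @param x object to print
#' @param ... unused
#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("reference_genome %s: %s bp%s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Base(s) of the reference at given positions (wrap-aware)
#' @param ref a `reference_genome`
#' @param pos integer positions; on a circular reference positions are
#'   interpreted modulo the genome length
#' @return character vector of bases
#' @export
ref_base_at <- function(ref, pos) {
  if (ref$circular) pos <- ((pos - 1L) %% ref$length) + 1L
  if (any(pos < 1L | pos > ref$length)) stop("position outside reference")
  substring(ref$seq, pos, pos)
}

#' Read an ORF annotation (GFF3 or TSV)
#'
#' GFF3 features must carry `ID` and a `function_class` attribute; the TSV
#' dialect needs columns `id`, `start`, `end`, `strand`, `function_class`.
#' Wrap-around ORFs (end < start) are accepted on circular references and
#' flagged; their length is computed with modular arithmetic. ORF lengths
#' must be multiples of 3.
#'
#' @param path annotation file path (.gff/.gff3 or TSV).
#' @param reference_length genome length used for validation.
#' @param circular logical; whether wrap-around features are legal.
#' @return a data.frame of class `orf_annotation` with columns `id`, `start`,
#'   `end`, `strand`, `function_class`, `length`, `wraps`.
#' @export
read_annotation <- function(path, reference_length, circular = FALSE) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::readGFF(path)
    fc <- g$function_class
    if (is.null(fc)) stop("GFF features lack a function_class attribute")
    ann <- data.frame(id = as.character(g$ID), start = g$start, end = g$end,
                      strand = as.character(g$strand),
                      function_class = as.character(fc),
                      stringsAsFactors = FALSE)
  } else {
    ann <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "start", "end", "strand", "function_class")
    if (!all(need %in% names(ann)))
      stop("TSV annotation needs columns ", paste(need, collapse = ", "))
    ann <- ann[need]
  }
  orf_annotation(ann$id, ann$start, ann$end, ann$strand, ann$function_class,
                 reference_length = reference_length, circular = circular)
}

#' Construct and validate an ORF annotation
#'
#' @param id,start,end,strand,function_class per-ORF vectors; coordinates are
#'   1-based inclusive.
#' @param reference_length,circular see [read_annotation()]
#' @return a data.frame of class `orf_annotation`
#' @export
orf_annotation <- function(id, start, end, strand, function_class,
                           reference_length, circular = FALSE) {
  function_class <- sub("^structure protein$", "structural protein",
                        function_class)
  function_class <- sub("unknown function", "unknown", function_class)
  bad <- setdiff(unique(function_class), ORF_CLASSES)
  if (length(bad))
    stop("unknown function class: ", paste(bad, collapse = ", "))
  if (any(start < 1 | start > reference_length |
          end < 1 | end > reference_length))
    stop("ORF coordinates out of range")
  wraps <- end < start
  if (any(wraps) && !circular)
    stop("wrap-around ORF on a non-circular reference: ",
         paste(id[wraps], collapse = ", "))
  len <- ifelse(wraps, reference_length - start + 1L + end, end - start + 1L)
  if (any(len %% 3L != 0L))
    warning("ORF length not divisible by 3 (codon classification will ",
            "refuse these): ", paste(id[len %% 3L != 0L], collapse = ", "))
  if (!all(strand %in% c("+", "-"))) stop("strand must be + or -")
  ann <- data.frame(id = as.character(id), start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    function_class = function_class, length = as.integer(len),
                    wraps = wraps, stringsAsFactors = FALSE)
  attr(ann, "reference_length") <- as.integer(reference_length)
  attr(ann, "circular") <- isTRUE(circular)
  class(ann) <- c("orf_annotation", "data.frame")
  ann
}

#' Write an ORF annotation as GFF3
#' @param ann an `orf_annotation`
#' @param path output path
#' @param reference_name sequence name for column 1
#' @return `path`, invisibly
#' @export
write_annotation <- function(ann, path, reference_name = "reference") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tgvpop\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;function_class=%s",
                     reference_name, ann$start, ann$end, ann$strand, ann$id,
                     ann$function_class), con)
  invisible(path)
}
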