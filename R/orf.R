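# ORF-associated SNP classification and density statistics.
# All coordinate arithmetic is 1-based inclusive and wrap-aware on circular
# references; codon positions are computed from the in-frame offset,
# reverse-complemented for minus-strand ORFs.

orf_positions <- function(orf, L) {
  if (orf$wraps) c(orf$start:L, 1:orf$end) else orf$start:orf$end
}

# offset of a genomic position within the coding sequence (0-based)
orf_offset <- function(orf, position, L) {
  if (orf$strand == "+") {
    off <- position - orf$start
    if (orf$wraps && position < orf$start) off <- L - orf$start + position
  } else {
    off <- orf$end - position
    if (orf$wraps && position > orf$end) off <- orf$end + (L - position)
  }
  off
}

orf_contains <- function(orf, position, L) {
  if (!orf$wraps) position >= orf$start & position <= orf$end
  else position >= orf$start | position <= orf$end
}

codon_at <- function(ref, orf, codon_index) {
  L <- ref$length
  if (orf$strand == "+") {
    gpos <- orf$start + 3L * codon_index + 0:2
  } else {
    gpos <- orf$end - 3L * codon_index - 0:2
  }
  gpos <- ((gpos - 1L) %% L) + 1L
  b <- ref_base_at(ref, gpos)
  if (orf$strand == "-") b <- complement_base(b)
  paste(b, collapse = "")
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify a SNP against the ORF annotation
#'
#' For every ORF containing the position (several, when ORFs overlap) the
#' codon position (1, 2, 3) and the synonymous flag are computed by
#' translating the reference and alternative codons with the standard
#' genetic code. A position contained in no ORF is noncoding.
#'
#' @param position 1-based genomic position.
#' @param ref_base,alt_base reference and alternative bases (must differ).
#' @param annotation an `orf_annotation`.
#' @param reference a `reference_genome`.
#' @return list of class `snp_effect`: `position`, `coding`, `transition`,
#'   and a data.frame `orfs` (orf_id, codon_pos, codon_ref, codon_alt,
#'   aa_ref, aa_alt, synonymous).
#' @export
classify_snp <- function(position, ref_base, alt_base, annotation, reference) {
  if (ref_base == alt_base) stop("alt equals ref")
  if (position < 1 || position > reference$length)
    stop("position outside reference")
  actual <- ref_base_at(reference, position)
  if (actual != ref_base)
    stop(sprintf("reference base at %d is %s, not %s", position, actual,
                 ref_base))
  L <- reference$length
  hits <- which(vapply(seq_len(nrow(annotation)), function(i)
    orf_contains(annotation[i, ], position, L), logical(1)))
  rows <- lapply(hits, function(i) {
    orf <- annotation[i, ]
    if (orf$length %% 3L != 0L)
      stop("ORF length not divisible by 3: ", orf$id)
    off <- orf_offset(orf, position, L)
    cidx <- off %/% 3L
    cpos <- off %% 3L + 1L
    cref <- codon_at(reference, orf, cidx)
    b <- if (orf$strand == "+") alt_base else complement_base(alt_base)
    calt <- cref
    substr(calt, cpos, cpos) <- b
    aa_ref <- translate_codon(cref)
    aa_alt <- translate_codon(calt)
    data.frame(orf_id = orf$id, codon_pos = cpos, codon_ref = cref,
               codon_alt = calt, aa_ref = aa_ref, aa_alt = aa_alt,
               synonymous = aa_ref == aa_alt, stringsAsFactors = FALSE)
  })
  orfs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orf_id = character(), codon_pos = integer(),
               codon_ref = character(), codon_alt = character(),
               aa_ref = character(), aa_alt = character(),
               synonymous = logical(), stringsAsFactors = FALSE)
  structure(list(position = position, ref = ref_base, alt = alt_base,
                 coding = nrow(orfs) > 0,
                 transition = is_transition(ref_base, alt_base),
                 orfs = orfs),
            class = "snp_effect")
}

#' Classify all retained SNPs of a filtered matrix
#'
#' Genome-wide tallies count each SNP once: SNPs in overlapping ORFs are
#' assigned to the lexicographically lowest ORF id for the codon-position
#' tally (overlap counts reported separately), and a SNP synonymous in one
#' overlapping ORF but nonsynonymous in another is tallied genome-wide as
#' nonsynonymous (conservative). Per-ORF detail is preserved in `effects`.
#'
#' @param x a `filtered_snp_matrix`
#' @param annotation an `orf_annotation`
#' @param reference a `reference_genome`
#' @return list of class `snp_classification`: `effects` (list of
#'   [classify_snp()] results), `table` (one row per SNP with genome-wide
#'   category) and `tallies` (transition/transversion, coding/noncoding,
#'   codon positions, syn/nonsyn, overlap counts).
#' @export
classify_snps <- function(x, annotation, reference) {
  effects <- lapply(seq_len(n_sites(x)), function(i)
    classify_snp(x$position[i], x$ref[i], x$alt[i], annotation, reference))
  rows <- lapply(effects, function(e) {
    n_orf <- nrow(e$orfs)
    if (n_orf > 0) {
      k <- order(e$orfs$orf_id)[1]
      data.frame(position = e$position, transition = e$transition,
                 coding = TRUE, n_orfs = n_orf,
                 orf_id = e$orfs$orf_id[k], codon_pos = e$orfs$codon_pos[k],
                 synonymous = all(e$orfs$synonymous),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(position = e$position, transition = e$transition,
                 coding = FALSE, n_orfs = 0L, orf_id = NA_character_,
                 codon_pos = NA_integer_, synonymous = NA,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tallies <- list(
    n_snps = nrow(tab),
    transitions = sum(tab$transition),
    transversions = sum(!tab$transition),
    coding = sum(tab$coding),
    noncoding = sum(!tab$coding),
    codon_pos = vapply(1:3, function(p)
      sum(tab$codon_pos == p, na.rm = TRUE), integer(1)),
    codon_pos_overlap = vapply(1:3, function(p)
      sum(tab$codon_pos == p & tab$n_orfs > 1, na.rm = TRUE), integer(1)),
    synonymous = sum(tab$synonymous, na.rm = TRUE),
    nonsynonymous = sum(!tab$synonymous, na.rm = TRUE))
  structure(list(effects = effects, table = tab, tallies = tallies),
            class = "snp_classification")
}

#' Per-ORF SNP density and per-class summaries
#'
#' SNP density of an ORF is its SNP count per kbp of ORF length. Each SNP
#' counts in every ORF containing it. ORFs with zero SNPs are reported as
#' fully conserved.
#'
#' @param classification a `snp_classification` from [classify_snps()]
#' @param annotation an `orf_annotation`
#' @return list of class `orf_snp_stats`: `per_orf` (orf id, class,
#'   snp_count, density), `per_class` (n, mean density, SEM), `conserved`
#'   (ids of zero-SNP ORFs)
#' @export
density_table <- function(classification, annotation) {
  hits <- unlist(lapply(classification$effects, function(e) e$orfs$orf_id))
  cnt <- table(factor(hits, levels = annotation$id))
  per_orf <- data.frame(orf_id = annotation$id,
                        function_class = annotation$function_class,
                        length = annotation$length,
                        snp_count = as.integer(cnt),
                        density = as.integer(cnt) / (annotation$length / 1000),
                        stringsAsFactors = FALSE)
  agg <- lapply(split(per_orf$density, per_orf$function_class), function(d)
    c(n = length(d), mean = mean(d), sem = stats::sd(d) / sqrt(length(d))))
  per_class <- data.frame(function_class = names(agg),
                          do.call(rbind, agg), row.names = NULL)
  structure(list(per_orf = per_orf, per_class = per_class,
                 conserved = per_orf$orf_id[per_orf$snp_count == 0]),
            class = "orf_snp_stats")
}

#' Tukey ladder-of-powers transformation toward normality
#'
#' Chooses lambda on a fixed grid (default -2 to 2 in steps of 0.05, the
#' ladder's conventional range) to maximise the Shapiro-Wilk W statistic of
#' the transformed sample. The transform is x^lambda for lambda > 0, log(x)
#' for lambda = 0, and -(x^lambda) for lambda < 0, so it is monotone
#' increasing throughout. Non-positive lambdas are skipped when the data
#' contain zeros.
#'
#' @param values non-negative numeric vector, length >= 3, non-constant
#' @param lambdas grid of candidate exponents
#' @return list of class `tukey_transform`: `values` (transformed), `lambda`,
#'   `W` (Shapiro-Wilk statistic at the chosen lambda)
#' @export
tukey_transform <- function(values, lambdas = seq(-2, 2, by = 0.05)) {
  if (length(values) < 3) stop("need at least 3 values")
  if (any(values < 0)) stop("values must be >= 0")
  if (diff(range(values)) == 0) stop("constant input")
  if (any(values == 0)) lambdas <- lambdas[lambdas > 0]
  tf <- function(l) {
    if (l > 0) values^l else if (l == 0) log(values) else -(values^l)
  }
  W <- vapply(lambdas, function(l) {
    tryCatch(shapiro.test(tf(l))$statistic, error = function(e) NA_real_)
  }, numeric(1))
  best <- lambdas[which.max(W)]
  structure(list(values = tf(best), lambda = best, W = max(W, na.rm = TRUE)),
            class = "tukey_transform")
}

#' Compare SNP densities between ORF functional classes
#'
#' One-way ANOVA over the (transformed) densities grouped by class, Tukey
#' HSD pairwise comparisons, and a pooled two-sample t-test of all
#' known-function classes against the unknown-function class.
#'
#' @param values numeric vector of (transformed) densities
#' @param class factor/character of the same length; the level named
#'   `unknown_level` defines the pooled comparison
#' @param unknown_level class label treated as "unknown function"
#' @return list of class `class_comparison`: `anova` (F, df1, df2, p),
#'   `hsd` (TukeyHSD table), `ttest` (known vs unknown)
#' @export
compare_classes <- function(values, class, unknown_level = "unknown") {
  class <- factor(class)
  if (nlevels(class) < 2) stop("need at least 2 classes")
  if (any(table(class) < 2)) stop("every class needs n >= 2")
  fit <- aov(values ~ class)
  s <- summary(fit)[[1]]
  an <- list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
             p = s[["Pr(>F)"]][1])
  if (s[["Mean Sq"]][2] == 0) an$F <- NA_real_  # zero within-group variance
  hsd <- TukeyHSD(fit)$class
  tt <- NULL
  if (unknown_level %in% levels(class)) {
    unk <- class == unknown_level
    tt0 <- t.test(values[!unk], values[unk], var.equal = TRUE)
    tt <- list(t = unname(tt0$statistic), df = unname(tt0$parameter),
               p = tt0$p.value,
               mean_known = mean(values[!unk]),
               mean_unknown = mean(values[unk]))
  }
  structure(list(anova = an, hsd = hsd, ttest = tt),
            class = "class_comparison")
}
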