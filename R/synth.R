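# Synthetic references, genotype panels, mixed-isolate count matrices and
# repeat-region reads with known ground truth. All randomness flows from a
# single seed so outputs are reproducible byte for byte.

#' Generate a random reference genome
#' @param length genome length in bp
#' @param name sequence name
#' @param circular declared circularity
#' @return a `reference_genome`
#' @export
make_reference <- function(length, name = "synthref", circular = TRUE) {
  reference_genome(paste(sample(BASES, length, replace = TRUE),
                         collapse = ""), name = name, circular = circular)
}

#' Simulation configuration
#'
#' Depths are drawn per site and isolate from a truncated normal
#' (mean +/- sd, floored at `min_depth`), mirroring the mean +/- SD depth
#' reporting of deep-sequenced isolates; set `depth_sd = 0` for fixed depth.
#' The error model is a uniform base miscall: a read reports the true base
#' with probability 1 - error_rate and each wrong base with error_rate / 3.
#'
#' @param depth mean per-site depth
#' @param depth_sd depth standard deviation
#' @param min_depth truncation floor (>= 1)
#' @param error_rate per-base miscall rate, in [0, 0.05]
#' @param seed integer seed recorded in all outputs
#' @param read_length read length for repeat simulation
#' @return list of class `sim_config`
#' @export
sim_config <- function(depth = 2000, depth_sd = 0, min_depth = 1,
                       error_rate = 0.001, seed = 1, read_length = 151) {
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  if (min_depth < 1) stop("min_depth must be >= 1")
  structure(list(depth = depth, depth_sd = depth_sd, min_depth = min_depth,
                 error_rate = error_rate, seed = as.integer(seed),
                 read_length = read_length),
            class = "sim_config")
}

draw_depths <- function(n_sites, n_isolates, cfg, means = NULL, sds = NULL) {
  means <- means %||% rep(cfg$depth, n_isolates)
  sds <- sds %||% rep(cfg$depth_sd, n_isolates)
  d <- matrix(0L, n_sites, n_isolates)
  for (j in seq_len(n_isolates))
    d[, j] <- pmax(cfg$min_depth,
                   as.integer(round(rnorm(n_sites, means[j], sds[j]))))
  d
}

#' Generate a genotype panel over a synthetic reference
#'
#' Each genotype is defined by a private SNP set; optional group-shared
#' blocks assign additional SNPs jointly to several genotypes. All SNP
#' positions are distinct. The ground truth (positions, alternative bases,
#' genotype incidence) is returned alongside.
#'
#' @param n_genotypes number of genotypes
#' @param n_private_snps private SNPs per genotype
#' @param shared_group_spec optional list of `list(members = <genotype
#'   ids>, n = <count>)` blocks
#' @param reference_length genome length (total SNPs must stay below a
#'   tenth of it)
#' @param seed integer seed
#' @return list of class `genotype_panel`: `reference`, `genotypes` (list
#'   of id + snps data.frame), `snp_table` (position, alt, carriers)
#' @export
make_panel <- function(n_genotypes = 3, n_private_snps = 50,
                       shared_group_spec = NULL, reference_length = 50000,
                       seed = 1) {
  ids <- paste0("g", seq_len(n_genotypes))
  n_shared <- sum(vapply(shared_group_spec, function(b) b$n, numeric(1))) %||% 0
  if (length(shared_group_spec))
    for (b in shared_group_spec)
      if (!all(b$members %in% ids)) stop("unknown genotype in shared block")
  total <- n_genotypes * n_private_snps + sum(n_shared)
  if (total >= reference_length / 10)
    stop("collision-impossible parameterization: too many SNPs for the reference length")
  set.seed(seed)
  reference <- make_reference(reference_length)
  pos <- sort(sample.int(reference_length, total))
  ref_b <- ref_base_at(reference, pos)
  alt_b <- vapply(ref_b, function(r) sample(setdiff(BASES, r), 1), character(1),
                  USE.NAMES = FALSE)
  carriers <- vector("list", total)
  k <- 0L
  idx <- sample.int(total)  # scatter blocks over the coordinate range
  for (g in ids) {
    take <- idx[k + seq_len(n_private_snps)]
    for (i in take) carriers[[i]] <- g
    k <- k + n_private_snps
  }
  for (b in shared_group_spec) {
    take <- idx[k + seq_len(b$n)]
    for (i in take) carriers[[i]] <- b$members
    k <- k + b$n
  }
  snp_table <- data.frame(position = pos, ref = ref_b, alt = alt_b,
                          stringsAsFactors = FALSE)
  snp_table$carriers <- carriers
  genotypes <- lapply(ids, function(g) {
    sel <- vapply(carriers, function(cc) g %in% cc, logical(1))
    list(id = g, snps = snp_table[sel, c("position", "alt")])
  })
  names(genotypes) <- ids
  structure(list(reference = reference, genotypes = genotypes,
                 snp_table = snp_table, seed = seed),
            class = "genotype_panel")
}

#' Mixture design: genotype proportions per isolate
#'
#' @param proportions named list: isolate id -> named numeric vector of
#'   genotype proportions (non-negative, summing to 1)
#' @return list of class `mixture_design`
#' @export
mixture_design <- function(proportions) {
  for (iso in names(proportions)) {
    p <- proportions[[iso]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("proportions for ", iso, " must be >= 0 and sum to 1")
  }
  structure(list(proportions = proportions), class = "mixture_design")
}

# multinomial read-count draw for one site x isolate:
# fraction p of the population carries `alt`, 1 - p carries `ref`; each
# sequenced base is miscalled uniformly with rate eps.
site_counts <- function(depth, p, ref, alt, eps) {
  probs <- setNames(numeric(4), BASES)
  for (b in BASES) {
    probs[b] <- p * (if (b == alt) 1 - eps else eps / 3) +
      (1 - p) * (if (b == ref) 1 - eps else eps / 3)
  }
  as.integer(rmultinom(1, depth, probs))
}

#' Simulate a mixed-isolate count matrix from true alternative frequencies
#'
#' The low-level entry point: given the per-site, per-isolate true
#' alternative-allele frequency matrix P, draws base counts per (site,
#' isolate) from a multinomial with the uniform-miscall error model. The
#' genotype/mixture interface [simulate_counts()] builds P as (carriage
#' matrix) x (proportions); direct P input supports site-level
#' heterogeneity.
#'
#' @param snp_table data.frame with `position`, `ref`, `alt`
#' @param P numeric matrix, sites x isolates, true alternative frequency
#' @param cfg a [sim_config]; `cfg$seed` is consumed here
#' @param reference a `reference_genome`
#' @param depth_means,depth_sds optional per-isolate depth models
#'   (recycled from `cfg` when NULL)
#' @return list: `matrix` (a [snp_matrix]), `truth` (P, seed, depths)
#' @export
simulate_counts_from_freq <- function(snp_table, P, cfg, reference,
                                      depth_means = NULL, depth_sds = NULL) {
  set.seed(cfg$seed)
  n <- nrow(snp_table)
  isolates <- colnames(P)
  depth <- draw_depths(n, length(isolates), cfg, depth_means, depth_sds)
  counts <- array(0L, c(n, length(isolates), 4L),
                  dimnames = list(NULL, isolates, BASES))
  for (i in seq_len(n)) for (j in seq_along(isolates)) {
    counts[i, j, ] <- site_counts(depth[i, j], P[i, j], snp_table$ref[i],
                                  snp_table$alt[i], cfg$error_rate)
  }
  m <- snp_matrix(snp_table$position, snp_table$ref, counts,
                  isolates = isolates, reference_name = reference$name,
                  reference_length = reference$length,
                  circular = reference$circular)
  list(matrix = m,
       truth = list(P = P, snp_table = snp_table, seed = cfg$seed,
                    depth = depth))
}

#' Simulate sequencing counts for a genotype mixture panel
#'
#' At every SNP of the panel, an isolate's true alternative frequency is the
#' summed proportion of the genotypes carrying that SNP; counts are then
#' drawn under the uniform-miscall error model. With zero error and a pure
#' genotype, alternative frequencies are exactly 1 at its SNPs and 0
#' elsewhere.
#'
#' @param panel a `genotype_panel` from [make_panel()]
#' @param design a [mixture_design]; genotype names must match the panel
#' @param cfg a [sim_config]
#' @return list: `matrix` (a [snp_matrix]), `truth` (includes the designed
#'   frequency matrix P and the design itself)
#' @export
simulate_counts <- function(panel, design, cfg = sim_config()) {
  isolates <- names(design$proportions)
  st <- panel$snp_table
  P <- matrix(0, nrow(st), length(isolates),
              dimnames = list(NULL, isolates))
  for (j in seq_along(isolates)) {
    props <- design$proportions[[isolates[j]]]
    P[, j] <- vapply(st$carriers, function(cc)
      sum(props[intersect(names(props), cc)]), numeric(1))
  }
  out <- simulate_counts_from_freq(st[, c("position", "ref", "alt")], P,
                                   cfg, panel$reference)
  out$truth$design <- design
  out
}

apply_read_errors <- function(seq, eps) {
  if (eps <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < eps)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Simulate reads over a tandem-repeat locus
#'
#' For each read a copy-number class is drawn from `copy_distribution`; the
#' read is placed uniformly over a synthetic locus (`pad` random bases on
#' each side of flank + copies + flank), on a random strand, so a known
#' fraction of reads spans both flanks. Ground truth (designed distribution
#' and per-read class) is returned; tests never re-derive truth from the
#' reads.
#'
#' @param spec a [repeat_region_spec]
#' @param copy_distribution named numeric vector: copy number -> probability
#' @param cfg a [sim_config] (`read_length`, `error_rate`, `seed`)
#' @param n_reads number of reads to draw
#' @param pad context length flanking the locus on each side
#' @param fastq_path optional path; when given, reads are also written as
#'   FASTQ with constant Q40 qualities
#' @return list: `reads` (character vector), `truth` (distribution, classes,
#'   seed)
#' @export
simulate_repeat_reads <- function(spec, copy_distribution,
                                  cfg = sim_config(), n_reads = 1000,
                                  pad = 60, fastq_path = NULL) {
  ks <- as.integer(names(copy_distribution))
  if (abs(sum(copy_distribution) - 1) > 1e-8)
    stop("copy_distribution must sum to 1")
  R <- cfg$read_length
  max_span <- nchar(spec$upstream_flank) + nchar(spec$downstream_flank) +
    max(ks) * spec$unit_length
  if (R <= max_span)
    stop("read length too short for the largest copy class")
  set.seed(cfg$seed)
  left <- paste(sample(BASES, pad, replace = TRUE), collapse = "")
  right <- paste(sample(BASES, pad, replace = TRUE), collapse = "")
  loci <- setNames(vapply(ks, function(k) paste0(
    left, spec$upstream_flank, strrep(spec$motif, k),
    spec$downstream_flank, right), character(1)), as.character(ks))
  classes <- sample(ks, n_reads, replace = TRUE, prob = copy_distribution)
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    locus <- loci[[as.character(classes[i])]]
    start <- sample.int(nchar(locus) - R + 1L, 1)
    r <- substr(locus, start, start + R - 1L)
    if (runif(1) < 0.5) r <- revcomp(r)
    reads[i] <- apply_read_errors(r, cfg$error_rate)
  }
  if (!is.null(fastq_path)) {
    ss <- Biostrings::DNAStringSet(reads)
    names(ss) <- paste0("read", seq_len(n_reads), "_", classes, "x")
    q <- Biostrings::PhredQuality(
      vapply(nchar(reads), function(n) strrep("I", n), character(1)))
    Biostrings::writeXStringSet(ss, fastq_path, format = "fastq",
                                qualities = Biostrings::BStringSet(q))
  }
  list(reads = reads,
       truth = list(copy_distribution = copy_distribution,
                    classes = classes, seed = cfg$seed))
}
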