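test_that("codon positions follow the reading frame from the ORF start", {
  set.seed(110)
  ref <- make_reference(3000, circular = FALSE)
  ann <- orf_annotation("orf1", 100, 1299, "+", "DNA replication",
                        reference_length = 3000)
  rb <- ref_base_at(ref, 100)
  e <- classify_snp(100, rb, setdiff(c("A", "C", "G", "T"), rb)[1], ann, ref)
  expect_equal(e$orfs$codon_pos, 1)
  e2 <- classify_snp(104, ref_base_at(ref, 104),
                     setdiff(c("A", "C", "G", "T"),
                             ref_base_at(ref, 104))[1], ann, ref)
  expect_equal(e2$orfs$codon_pos, 2)
  # outside every ORF: noncoding
  e3 <- classify_snp(50, ref_base_at(ref, 50),
                     setdiff(c("A", "C", "G", "T"),
                             ref_base_at(ref, 50))[1], ann, ref)
  expect_false(e3$coding)
  expect_error(classify_snp(100, rb, rb, ann, ref), "alt equals ref")
})

test_that("third-position GGA to GGG is synonymous (both glycine)", {
  seq <- paste0("ATG", "GGA", "TAA", strrep("A", 91))  # 100 bp
  ref <- reference_genome(seq, circular = FALSE)
  ann <- orf_annotation("orf1", 1, 9, "+", "unknown", reference_length = 100)
  e <- classify_snp(6, "A", "G", ann, ref)
  expect_true(e$orfs$synonymous)
  expect_equal(e$orfs$aa_ref, "G")
  # second position GGA -> GCA is Gly -> Ala: nonsynonymous
  e2 <- classify_snp(5, "G", "C", ann, ref)
  expect_false(e2$orfs$synonymous)
})

test_that("classification agrees with a whole-genome translation oracle on random SNPs", {
  set.seed(120)
  ref <- make_reference(8000, circular = TRUE)
  ann <- random_annotation(ref, n_orfs = 5, wrap = TRUE)
  positions <- sample.int(8000, 200)
  for (p in positions) {
    rb <- ref_base_at(ref, p)
    ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    e <- classify_snp(p, rb, ab, ann, ref)
    want <- oracle_synonymy(p, ab, ann, ref)
    expect_equal(e$coding, length(want) > 0)
    for (oid in names(want))
      expect_equal(e$orfs$synonymous[e$orfs$orf_id == oid], want[[oid]],
                   info = sprintf("pos %d orf %s", p, oid))
  }
})

test_that("synonymy is invariant under reverse-complementing the genome", {
  set.seed(130)
  L <- 5000
  ref <- make_reference(L, circular = FALSE)
  ann <- random_annotation(ref, n_orfs = 4, wrap = FALSE)
  rc <- reference_genome(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref$seq))),
    circular = FALSE)
  ann_rc <- orf_annotation(ann$id, L + 1 - ann$end, L + 1 - ann$start,
                           ifelse(ann$strand == "+", "-", "+"),
                           ann$function_class, reference_length = L)
  for (rep in 1:50) {
    p <- sample.int(L, 1)
    rb <- ref_base_at(ref, p)
    ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    e1 <- classify_snp(p, rb, ab, ann, ref)
    e2 <- classify_snp(L + 1 - p, gvpop:::complement_base(rb), gvpop:::complement_base(ab),
                       ann_rc, rc)
    expect_equal(e1$coding, e2$coding)
    o1 <- e1$orfs[order(e1$orfs$orf_id), ]
    o2 <- e2$orfs[order(e2$orfs$orf_id), ]
    expect_equal(o1$synonymous, o2$synonymous)
    expect_equal(o1$codon_pos, o2$codon_pos)
  }
})

test_that("coding and noncoding counts partition the retained SNPs", {
  set.seed(140)
  ref <- make_reference(6000, circular = TRUE)
  ann <- random_annotation(ref, n_orfs = 4, wrap = TRUE)
  n <- 60
  pos <- sort(sample.int(6000, n))
  rb <- ref_base_at(ref, pos)
  ab <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
               character(1))
  freqs <- matrix(runif(n * 2, 0.2, 1), n, 2,
                  dimnames = list(NULL, c("x", "y")))
  m <- snp_matrix(pos, rb, local({
    cc <- array(0L, c(n, 2, 4), dimnames = list(NULL, c("x", "y"),
                                                c("A", "C", "G", "T")))
    for (i in seq_len(n)) for (j in 1:2) {
      a <- round(1000 * freqs[i, j])
      cc[i, j, ab[i]] <- as.integer(a)
      cc[i, j, rb[i]] <- as.integer(1000 - a)
    }
    cc
  }), reference_length = 6000, circular = TRUE)
  f <- apply_filters(m)
  cls <- classify_snps(f, ann, ref)
  tl <- cls$tallies
  expect_equal(tl$coding + tl$noncoding, n_sites(f))
  expect_equal(tl$transitions + tl$transversions, n_sites(f))
  expect_equal(tl$synonymous + tl$nonsynonymous, tl$coding)
  expect_equal(sum(tl$codon_pos), tl$coding)
})

test_that("density is SNPs per kbp and conserved ORFs are reported", {
  ref <- reference_genome(strrep("ACGT", 1000), circular = FALSE)  # 4000 bp
  ann <- orf_annotation(c("a", "b"), c(1, 2001), c(1200, 2300), c("+", "+"),
                        c("unknown", "metabolic process"),
                        reference_length = 4000)
  pos <- c(10, 500, 1100)  # 3 SNPs in orf a (1200 bp), none in b
  rb <- ref_base_at(ref, pos)
  ab <- ifelse(rb == "A", "G", "A")
  freqs <- matrix(0.9, 3, 2, dimnames = list(NULL, c("x", "y")))
  m <- toy_matrix(freqs, depth = 1000, ref = rb, alt = ab, positions = pos,
                  reference_length = 4000)
  f <- apply_filters(m)
  d <- density_table(classify_snps(f, ann, ref), ann)
  expect_equal(d$per_orf$density[d$per_orf$orf_id == "a"], 2.5)
  expect_equal(d$per_orf$density[d$per_orf$orf_id == "b"], 0)
  expect_equal(d$conserved, "b")
})

test_that("per-class densities recover designed Poisson rates within 2 SEM", {
  set.seed(150)
  n_per_class <- 40
  rates <- c("DNA replication" = 2.5, "unknown" = 6)
  lens <- rep(1500, n_per_class * 2)
  classes <- rep(names(rates), each = n_per_class)
  counts <- rpois(length(lens), rates[classes] * lens / 1000)
  density <- counts / (lens / 1000)
  for (cl in names(rates)) {
    d <- density[classes == cl]
    sem <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - rates[cl]), 2 * sem + 0.5)
  }
})

test_that("the Tukey ladder finds lambda near 1 for normal and 0 for log-normal data", {
  set.seed(160)
  # a strongly right-skewed sample is pulled toward the root/log end of the
  # ladder, a symmetric one stays near identity; the log-normal case is the
  # sharp one (lambda ~ 0), for the normal case the likelihood surface is
  # flat above ~0.5 so only the direction is asserted
  x <- rnorm(300, mean = 10, sd = 3)
  tt <- tukey_transform(x)
  expect_gt(tt$lambda, 0.5)
  y <- exp(rnorm(120, 0, 0.6))
  tt2 <- tukey_transform(y)
  expect_lt(abs(tt2$lambda), 0.35)
  # monotone: rank order preserved
  expect_identical(order(tt2$values), order(y))
  expect_error(tukey_transform(rep(3, 10)), "constant")
  # zeros restrict the grid to positive lambdas
  tz <- tukey_transform(c(0, runif(30)))
  expect_gt(tz$lambda, 0)
})

test_that("the one-way ANOVA matches a hand-computed sums-of-squares oracle", {
  vals <- c(2, 3, 4, 6, 7, 8, 1, 2, 3)
  grp <- rep(c("a", "b", "c"), each = 3)
  # independent oracle: explicit sums of squares
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  F_hand <- (ssb / 2) / (ssw / 6)
  cc <- compare_classes(vals, grp, unknown_level = "none")
  expect_equal(cc$anova$F, F_hand, tolerance = 1e-10)
  expect_equal(cc$anova$df1, 2)
  expect_equal(cc$anova$df2, 6)
})

test_that("ANOVA on two groups equals the squared t statistic", {
  set.seed(170)
  vals <- c(rnorm(12, 0), rnorm(12, 1))
  grp <- rep(c("known", "unknown"), each = 12)
  cc <- compare_classes(vals, grp)
  expect_equal(cc$anova$F, cc$ttest$t^2, tolerance = 1e-10)
  expect_equal(cc$anova$p, cc$ttest$p, tolerance = 1e-10)
})

test_that("the ANOVA p-value is uniform under the null and powerful under separation", {
  set.seed(180)
  ps <- replicate(300, {
    vals <- rnorm(18)
    compare_classes(vals, rep(c("a", "b", "c"), each = 6),
                    unknown_level = "none")$anova$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  hits <- replicate(50, {
    vals <- c(rnorm(20, 0, 1), rnorm(20, 3, 1))  # 3-SD mean separation
    compare_classes(vals, rep(c("k", "unknown"), each = 20))$ttest$p < 0.001
  })
  expect_gte(mean(hits), 0.99)
})
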