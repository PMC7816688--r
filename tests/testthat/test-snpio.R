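test_that("count-table TSV roundtrips and parsing is order-independent", {
  freqs <- matrix(c(0.5, 0, 0.2, 0.9, 0.1, 0), nrow = 2,
                  dimnames = list(NULL, c("a", "b", "c")))
  m <- toy_matrix(freqs, positions = c(10, 20))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(m, tf)
  m2 <- read_count_table(tf, reference_length = m$reference_length)
  expect_identical(m2$counts, m$counts)
  expect_identical(m2$position, m$position)
  expect_identical(m2$isolates, m$isolates)

  # shuffle rows: canonical object is the same
  tab <- read.delim(tf, check.names = FALSE)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[rev(seq_len(nrow(tab))), ], tf2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  m3 <- read_count_table(tf2, reference_length = m$reference_length)
  expect_identical(m3$counts, m$counts)
})

test_that("rows violating invariants are rejected with their row number", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tref\ts1:A\ts1:C\ts1:G\ts1:T\ts1:depth",
               "10\tA\t50\t0\t0\t0\t60"), tf)
  expect_error(read_count_table(tf), "row 1.*depth field")

  writeLines(c("position\tref\ts1:A\ts1:C\ts1:G\ts1:T",
               "10\tA\t50\t0\t0\t0",
               "10\tA\t40\t0\t0\t0"), tf)
  expect_error(read_count_table(tf), "duplicate position")

  writeLines(c("position\tref\ts1:A\ts1:C\ts1:G\ts1:T",
               "900\tA\t50\t0\t0\t0"), tf)
  expect_error(read_count_table(tf, reference_length = 100),
               "beyond reference_length")

  writeLines(c("position\tref\ts1:A\ts1:C\ts1:G\ts1:T",
               "10\tA\t-5\t0\t0\t0"), tf)
  expect_error(read_count_table(tf), "negative")

  writeLines(c("pos\tref\tstuff", "1\tA\t2"), tf)
  expect_error(read_count_table(tf), "malformed header")
})

test_that("the reduced ref/alt dialect is auto-detected and mapped onto four bases", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tref\talt\ts1:ref\ts1:alt\ts2:ref\ts2:alt",
               "5\tA\tG\t120\t35\t200\t0",
               "9\tC\tT\t80\t20\t10\t90"), tf)
  m <- read_count_table(tf, reference_length = 100)
  expect_equal(unname(m$counts[1, "s1", ]), c(120L, 0L, 35L, 0L))
  expect_equal(unname(m$counts[2, "s2", ]), c(0L, 10L, 0L, 90L))
})

test_that("VCF allele depths map onto base counts, expanding multi-allelic records", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "ref\t10\t.\tA\tG\t.\tPASS\t.\tAD\t120,35\t50,0",
               "ref\t20\t.\tA\tG,T\t.\tPASS\t.\tAD\t100,20,15\t10,1,2"), tf)
  m <- read_vcf_counts(tf, reference_length = 100)
  expect_equal(unname(m$counts[1, "s1", ]), c(120L, 0L, 35L, 0L))
  expect_equal(unname(m$counts[2, "s1", ]), c(100L, 0L, 20L, 15L))
  expect_equal(unname(m$counts[2, "s2", ]), c(10L, 0L, 1L, 2L))
})

test_that("a simulated matrix roundtrips through VCF exactly", {
  pan <- make_panel(n_genotypes = 2, n_private_snps = 15,
                    reference_length = 10000, seed = 11)
  des <- mixture_design(list(x = c(g1 = 1), y = c(g1 = 0.4, g2 = 0.6)))
  sim <- simulate_counts(pan, des, sim_config(depth = 500, seed = 12))
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_counts(sim$matrix, tf)
  m2 <- read_vcf_counts(tf, reference_length = sim$matrix$reference_length)
  expect_equal(unname(m2$counts), unname(sim$matrix$counts))
  expect_equal(m2$position, sim$matrix$position)
})

test_that("reference FASTA reading validates record count and roundtrips", {
  ref <- make_reference(5000, name = "syn1")
  tf <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(ref$seq), "syn1"), tf)
  r2 <- read_reference(tf, circular = TRUE)
  expect_equal(r2$length, 5000)
  expect_identical(r2$seq, ref$seq)
  expect_true(r2$circular)

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_reference(empty))

  multi <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), multi)
  expect_error(read_reference(multi), "multi-record")
})

test_that("annotation features validate lengths, classes and wrap-around", {
  ann <- orf_annotation("orf1", 100, 1299, "+", "DNA replication",
                        reference_length = 123529)
  expect_equal(ann$length, 1200L)
  expect_false(ann$wraps)

  # wrap-around length by independent modular arithmetic
  L <- 123529; s <- 123000; e <- 500
  expect_warning(
    wrap <- orf_annotation("w", s, e, "+", "unknown",
                           reference_length = L, circular = TRUE),
    "divisible by 3")
  expect_equal(wrap$length, (L - s + 1) + e)  # 1030
  expect_true(wrap$wraps)

  expect_error(orf_annotation("w", s, e, "+", "unknown",
                              reference_length = L, circular = FALSE),
               "wrap-around")
  expect_error(orf_annotation("x", 10, 99, "+", "virus budding",
                              reference_length = 1000),
               "unknown function class")
  expect_error(orf_annotation("x", 10, 2000, "+", "unknown",
                              reference_length = 1000), "out of range")

  # TSV reader and the structure-protein spelling variant
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tstart\tend\tstrand\tfunction_class",
               "orf1\t100\t1299\t+\tstructure protein"), tf)
  a2 <- read_annotation(tf, reference_length = 2000)
  expect_equal(a2$function_class, "structural protein")

  # GFF3 writer/reader roundtrip
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, gff)
  a3 <- read_annotation(gff, reference_length = 123529)
  expect_equal(a3$start, ann$start)
  expect_equal(a3$length, ann$length)
  expect_equal(a3$function_class, ann$function_class)
})

test_that("writer/reader pairs are identities on randomized matrices", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    k <- sample(2:5, 1)
    freqs <- matrix(runif(n * k), n, k,
                    dimnames = list(NULL, paste0("s", 1:k)))
    refb <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    m <- toy_matrix(freqs, depth = sample(200:2000, 1),
                    positions = sort(sample.int(5000, n)),
                    ref = refb, alt = ifelse(refb == "A", "C", "A"),
                    reference_length = 5000)
    tf <- tempfile(fileext = ".tsv")
    write_count_table(m, tf)
    m2 <- read_count_table(tf, reference_length = 5000)
    expect_identical(m2$counts, m$counts)
    vf <- tempfile(fileext = ".vcf")
    write_vcf_counts(m, vf)
    m3 <- read_vcf_counts(vf, reference_length = 5000)
    expect_equal(unname(m3$counts), unname(m$counts))
    unlink(c(tf, vf))
  }
})

test_that("base frequencies sum to one wherever depth is nonzero", {
  pan <- make_panel(n_genotypes = 2, n_private_snps = 10,
                    reference_length = 8000, seed = 3)
  des <- mixture_design(list(x = c(g1 = 0.5, g2 = 0.5)))
  sim <- simulate_counts(pan, des, sim_config(depth = 300, seed = 4))
  f <- base_freq(sim$matrix)
  sums <- apply(f, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
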