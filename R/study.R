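# A synthetic 20-isolate panel imitating the published CpGV study design:
# twelve field isolates and eight commercial/selected isolates, sequenced at
# the reported mean depths, whose genotype mixtures and marker-set structure
# reproduce the printed composition table. This is a synthetic stand-in for
# the study's raw data (which is not shipped): every number downstream is
# recomputed by running the pipeline on the simulated counts.

#' Isolate metadata of the synthetic study panel
#'
#' Twenty isolates with their study role (field / commercial / selected),
#' genome-group label and sequencing depth model (mean +/- SD), mirroring
#' the published sequencing summary.
#'
#' @return an [isolate_panel] with extra columns `depth_mean`, `depth_sd`
#' @export
cpgv_isolate_table <- function() {
  tab <- data.frame(
    id = c("M", "E2", "I12", "I0X", "S", "WW", "JQ", "ZY", "ZY2", "ALE",
           "KS1", "KS2", "R5", "V003", "0006P", "0006F", "V15", "0015",
           "0017", "V34"),
    group = c("A", "B", "D", "D", "E", "E", "F", "F", "F", "G", "AD", "AD",
              "AB", "A", "AB", "AB", "BE", "B", NA, NA),
    role = c(rep("field", 12), rep("commercial", 5), rep("selected", 3)),
    depth_mean = c(3995, 4045, 3603, 3406, 3320, 928, 950, 595, 968, 1076,
                   1057, 776, 540, 1301, 1584, 3734, 2654, 4345, 2361, 2389),
    depth_sd = c(622, 725, 593, 523, 614, 204, 184, 121, 195, 209,
                 214, 149, 162, 234, 438, 657, 448, 818, 371, 404),
    stringsAsFactors = FALSE)
  p <- isolate_panel(tab$id, group = tab$group, role = tab$role)
  p$depth_mean <- tab$depth_mean
  p$depth_sd <- tab$depth_sd
  p
}

#' Genotype mixture proportions of the synthetic study panel
#'
#' Rows are isolates, columns genotype components. "A" is the genotype of
#' the mapping reference itself; "B" the heterogenous group-B genotype;
#' "Dcore"/"Dfp" the Iranian genotype and its fingerprint-only variant;
#' "Es"/"Eww" the two group-E genotypes (differing in 30 fingerprint
#' sites); "Fzy2"/"Fjq" the two group-F genotypes; "G" the group-G
#' genotype. Proportions derive from the published composition medians,
#' with every nonzero component at least 0.09 so the design is identifiable
#' above the variability thresholds at the panel's depths.
#'
#' @return numeric matrix isolates x genotypes, rows summing to 1
#' @export
cpgv_mixture_proportions <- function() {
  g <- c("A", "B", "Dcore", "Dfp", "Es", "Eww", "Fzy2", "Fjq", "G")
  rows <- list(
    M     = c(A = 1),
    E2    = c(A = 0.20, B = 0.80),
    I12   = c(A = 0.56, Es = 0.34, Dcore = 0.10),
    I0X   = c(A = 0.60, Dfp = 0.30, Dcore = 0.10),
    S     = c(Es = 1),
    WW    = c(Eww = 1),
    JQ    = c(A = 0.03, Fjq = 0.80, Es = 0.17),
    ZY    = c(A = 0.77, Eww = 0.23),
    ZY2   = c(A = 0.15, Fzy2 = 0.70, Eww = 0.15),
    ALE   = c(A = 0.10, G = 0.80, Es = 0.10),
    KS1   = c(A = 0.69, Eww = 0.31),
    KS2   = c(A = 0.86, Eww = 0.14),
    R5    = c(A = 0.33, Es = 0.67),
    V003  = c(A = 1),
    `0006P` = c(A = 0.32, Es = 0.68),
    `0006F` = c(A = 0.26, Es = 0.74),
    V15   = c(A = 0.09, B = 0.42, Es = 0.49),
    `0015` = c(A = 0.20, B = 0.80),
    `0017` = c(A = 0.70, B = 0.11, Es = 0.19),
    V34   = c(A = 0.36, B = 0.37, Es = 0.27))
  P <- matrix(0, length(rows), length(g), dimnames = list(names(rows), g))
  for (iso in names(rows)) P[iso, names(rows[[iso]])] <- rows[[iso]]
  P
}

#' Marker-block structure of the synthetic study design
#'
#' The named blocks carry the published marker-set sizes; `carriers` lists
#' the genotype components whose genomes hold the alternative base at the
#' block's positions. The reference-genotype block (`m58`) is carried by
#' every non-reference-like component, so it surfaces as the set variable in
#' all field isolates except the reference isolate.
#'
#' @return named list of blocks: `size`, `carriers`
#' @export
cpgv_marker_blocks <- function() {
  list(
    m58     = list(size = 58, carriers = c("B", "Dcore", "Es", "Eww",
                                           "Fzy2", "Fjq")),
    e68     = list(size = 68, carriers = "B"),
    d24     = list(size = 24, carriers = c("Dcore", "Dfp")),
    fz30    = list(size = 30, carriers = "Fzy2"),
    f89     = list(size = 89, carriers = c("Fzy2", "Fjq")),
    g21     = list(size = 21, carriers = "G"),
    fg22    = list(size = 22, carriers = c("G", "Fjq")),
    bdefg75 = list(size = 75, carriers = c("B", "Es", "Eww", "Fjq")),
    defg45  = list(size = 45, carriers = c("Es", "Eww")))
}

# assorted low-frequency field combinations (labels avoid every named
# marker-set label and the no-private-sites claim for WW/S)
cpgv_extra_labels <- function() {
  list(list(c("KS1"), 30), list(c("KS2"), 30), list(c("ZY"), 25),
       list(c("I12"), 30), list(c("I0X"), 30), list(c("JQ"), 35),
       list(c("KS1", "KS2"), 20), list(c("E2", "I12"), 15),
       list(c("KS1", "KS2", "ZY"), 15), list(c("E2", "I12", "I0X"), 10),
       list(c("JQ", "ZY2", "ALE"), 10), list(c("ZY", "KS1"), 10))
}

#' Simulate the full synthetic study panel
#'
#' Builds a circular 123,529 bp reference, 753 designed variable sites (432
#' in the nine named marker blocks, 291 assorted field-specific sites
#' including 30 group-E fingerprint sites and the all-isolate
#' reference-anomaly site at position 105,178, and 30 commercial-only
#' sites), 544 of them transitions, plus 20 sub-threshold internal-variation
#' sites of the reference isolate that the stringency filters must remove.
#' Counts are drawn at the panel's depth models with the uniform-miscall
#' error model. The group-B genotype of the two heterogenous isolates gets a
#' shared per-site frequency profile (a beta-distributed "wave").
#'
#' @param seed integer seed for all randomness
#' @param error_rate per-base miscall rate (default 0.001)
#' @return list of class `study_simulation`: `matrix` (a [snp_matrix]),
#'   `reference`, `panel`, `truth` (designed P, block positions, expected
#'   field labels, proportions)
#' @export
simulate_study <- function(seed = 1, error_rate = 0.001) {
  panel <- cpgv_isolate_table()
  props <- cpgv_mixture_proportions()
  blocks <- cpgv_marker_blocks()
  extras <- cpgv_extra_labels()
  L <- 123529L
  anomaly_pos <- 105178L

  set.seed(seed)
  reference <- make_reference(L, name = "synthref-cpgv", circular = TRUE)

  n_named <- sum(vapply(blocks, `[[`, numeric(1), "size"))      # 432
  n_esfp <- 30L
  n_extra <- sum(vapply(extras, `[[`, numeric(1), 2))           # 260
  n_comm <- 30L
  n_sub <- 20L
  n_total <- n_named + n_esfp + 1L + n_extra + n_comm + n_sub   # 773

  pos <- sort(sample(setdiff(seq_len(L), anomaly_pos), n_total - 1L))
  slots <- sample.int(n_total - 1L)  # scatter site groups over coordinates
  take <- function(n) {
    out <- slots[seq_len(n)]
    slots <<- slots[-seq_len(n)]
    out
  }

  iso <- panel$id
  P <- matrix(0, n_total - 1L, length(iso), dimnames = list(NULL, iso))
  kind <- character(n_total - 1L)
  block_rows <- list()

  # group-B "wave": one per-site profile shared by the two heterogenous
  # B-carrying isolates (E2-like), bounded away from the 0.05 threshold
  b_wave <- function(n) 0.30 + 0.67 * stats::rbeta(n, 5, 1.5)

  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    rows <- take(b$size)
    block_rows[[bn]] <- rows
    kind[rows] <- bn
    carried <- props[, b$carriers, drop = FALSE]
    p_iso <- rowSums(carried)
    for (j in seq_along(iso)) P[rows, j] <- p_iso[iso[j]]
    if ("B" %in% b$carriers) {
      wv <- b_wave(b$size)
      P[rows, "E2"] <- wv
      P[rows, "0015"] <- wv
    }
  }

  # 30 group-E fingerprint sites: carried by the Es component only
  rows <- take(n_esfp)
  block_rows$es_fp <- rows
  kind[rows] <- "es_fp"
  for (j in seq_along(iso)) P[rows, j] <- props[iso[j], "Es"]

  # assorted low-frequency field-specific combinations
  extra_rows <- integer(0)
  for (ex in extras) {
    rows <- take(ex[[2]])
    extra_rows <- c(extra_rows, rows)
    kind[rows] <- "extra"
    for (id in ex[[1]]) P[rows, id] <- runif(ex[[2]], 0.15, 0.90)
  }

  # commercial-only sites (a selection hotspot plus scattered private sites)
  comm <- list(V003 = 20L, `0017` = 4L, V34 = 3L, V15 = 3L)
  for (id in names(comm)) {
    rows <- take(comm[[id]])
    kind[rows] <- "commercial"
    P[rows, id] <- if (id == "V003") runif(comm[[id]], 0.73, 0.95)
      else runif(comm[[id]], 0.15, 0.60)
  }

  # sub-threshold internal variation of the reference isolate
  rows <- take(n_sub)
  kind[rows] <- "subthreshold"
  P[rows, "M"] <- runif(n_sub, 0.01, 0.03)

  stopifnot(length(slots) == 0)

  # insert the reference-anomaly site (consensus error: high in everyone)
  P <- rbind(P, runif(length(iso), 0.93, 1.0))
  pos <- c(pos, anomaly_pos)
  kind <- c(kind, "anomaly")
  ord <- order(pos)
  P <- P[ord, , drop = FALSE]
  pos <- pos[ord]
  kind <- kind[ord]
  block_rows <- lapply(block_rows, function(r) match(r, ord))

  # ref/alt bases; 544 of the 753 designed variable sites are transitions
  ref_b <- ref_base_at(reference, pos)
  variable_idx <- which(kind != "subthreshold")
  ts_idx <- sample(variable_idx, 544)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  alt_b <- character(length(pos))
  for (i in seq_along(pos)) {
    if (i %in% ts_idx) alt_b[i] <- transition_of[[ref_b[i]]]
    else alt_b[i] <- sample(setdiff(BASES, c(ref_b[i],
                                             transition_of[[ref_b[i]]])), 1)
  }

  snp_table <- data.frame(position = pos, ref = ref_b, alt = alt_b,
                          stringsAsFactors = FALSE)
  cfg <- sim_config(min_depth = 150, error_rate = error_rate,
                    seed = sample.int(.Machine$integer.max, 1))
  sim <- simulate_counts_from_freq(snp_table, P, cfg, reference,
                                   depth_means = panel$depth_mean,
                                   depth_sds = panel$depth_sd)

  field <- panel$id[panel$role == "field"]
  expected_labels <- list(
    m58 = setdiff(field, "M"),
    e68 = "E2", d24 = c("I12", "I0X"), fz30 = "ZY2",
    f89 = c("JQ", "ZY2"), g21 = "ALE", fg22 = c("JQ", "ALE"),
    bdefg75 = setdiff(field, c("M", "I0X")),
    defg45 = setdiff(field, c("M", "I0X", "E2")),
    es_fp = c("I12", "S", "JQ", "ALE"))
  expected_labels <- lapply(expected_labels, function(m)
    paste(iso[iso %in% m], collapse = "."))

  structure(list(matrix = sim$matrix, reference = reference, panel = panel,
                 truth = list(P = P, position = pos, kind = kind,
                              block_rows = block_rows,
                              expected_labels = expected_labels,
                              proportions = props,
                              n_designed_variable = length(variable_idx),
                              n_transitions = 544L,
                              anomaly_position = anomaly_pos,
                              seed = seed)),
            class = "study_simulation")
}

#' Repeat-region design of the synthetic study panel
#'
#' Copy-number distributions of the 12 bp motif per isolate (1-5 copies
#' overall; the reference isolate nearly fixed for 2 copies with a trace of
#' the single-copy class, its commercial selection nearly fixed for the
#' single-copy resistance-breaking class) and per-isolate read counts.
#'
#' @return list with `spec` (a [repeat_region_spec]), `distributions`
#'   (named list per isolate), `n_reads` (named integer vector)
#' @export
cpgv_repeat_design <- function() {
  spec <- repeat_region_spec(upstream_flank = "ACGTTGCATCGA",
                             downstream_flank = "TTGACCGTAG",
                             motif = "GACACAGTGGAT")
  d <- list(
    M = c(`1` = 0.001, `2` = 0.999),
    E2 = c(`1` = 0.10, `2` = 0.90),
    I12 = c(`1` = 0.20, `2` = 0.40, `3` = 0.40),
    I0X = c(`1` = 0.30, `2` = 0.70),
    S = c(`1` = 0.15, `2` = 0.85),
    WW = c(`1` = 0.10, `2` = 0.90),
    JQ = c(`1` = 0.40, `2` = 0.60),
    ZY = c(`1` = 0.20, `2` = 0.30, `3` = 0.50),
    ZY2 = c(`1` = 0.20, `2` = 0.30, `3` = 0.50),
    ALE = c(`1` = 0.02, `2` = 0.38, `3` = 0.60),
    KS1 = c(`1` = 0.20, `2` = 0.25, `4` = 0.55),
    KS2 = c(`1` = 0.15, `2` = 0.20, `3` = 0.30, `4` = 0.25, `5` = 0.10),
    R5 = c(`1` = 0.30, `2` = 0.30, `3` = 0.40),
    V003 = c(`1` = 0.95, `2` = 0.05),
    `0006P` = c(`1` = 0.30, `2` = 0.30, `3` = 0.40),
    `0006F` = c(`1` = 0.30, `2` = 0.30, `3` = 0.40),
    V15 = c(`1` = 0.50, `2` = 0.50),
    `0015` = c(`1` = 0.10, `2` = 0.90),
    `0017` = c(`1` = 0.70, `2` = 0.30),
    V34 = c(`1` = 0.60, `2` = 0.40))
  n <- c(M = 2800, E2 = 1500, I12 = 1400, I0X = 1300, S = 1300, WW = 900,
         JQ = 900, ZY = 600, ZY2 = 900, ALE = 1000, KS1 = 1000, KS2 = 400,
         R5 = 540, V003 = 1430, `0006P` = 1500, `0006F` = 1500, V15 = 1500,
         `0015` = 3752, `0017` = 1200, V34 = 1200)
  list(spec = spec, distributions = d, n_reads = n)
}

#' Simulate repeat-region reads for the whole study panel
#'
#' @param seed integer seed
#' @param error_rate per-base miscall rate (default 0.001)
#' @return list: `histogram_input` (named list of read vectors), `spec`,
#'   `truth`
#' @export
simulate_study_repeats <- function(seed = 1, error_rate = 0.001) {
  des <- cpgv_repeat_design()
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(des$distributions))
  names(seeds) <- names(des$distributions)
  reads <- list()
  for (id in names(des$distributions)) {
    cfg <- sim_config(error_rate = error_rate, seed = seeds[[id]])
    reads[[id]] <- simulate_repeat_reads(des$spec, des$distributions[[id]],
                                         cfg, n_reads = des$n_reads[[id]])$reads
  }
  list(histogram_input = reads, spec = des$spec,
       truth = list(distributions = des$distributions, seed = seed))
}
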