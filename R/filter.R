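#' Stringency filter configuration
#'
#' All three bounds are strict (`>`): an isolate is called variable at a site
#' only if its total depth exceeds `min_total_depth`, its first-alternative
#' count exceeds `min_alt_count`, and its alternative frequency exceeds
#' `min_freq`. The study values are 100 / 10 / 0.05.
#'
#' @param min_total_depth strict lower bound on the four-base depth.
#' @param min_alt_count strict lower bound on the alternative read count.
#' @param min_freq strict lower bound on the alternative frequency.
#' @return a list of class `filter_config`
#' @export
filter_config <- function(min_total_depth = 100, min_alt_count = 10,
                          min_freq = 0.05) {
  if (min_total_depth < 0 || min_alt_count < 0 || min_freq < 0)
    stop("thresholds must be >= 0")
  if (min_freq >= 1) stop("min_freq must be < 1")
  structure(list(min_total_depth = min_total_depth,
                 min_alt_count = min_alt_count, min_freq = min_freq),
            class = "filter_config")
}

#' Select the first alternative base per site
#'
#' The first alternative is the non-reference base with the highest count
#' summed across all isolates, so a site's alternative identity is shared
#' across isolates (required for cross-isolate specificity to be
#' meaningful). Ties are broken by the fixed base order A < C < G < T. Sites
#' where all non-reference counts are zero are nonvariant and yield NA.
#'
#' @param x a [snp_matrix]
#' @return character vector of alternative bases (NA for nonvariant sites)
#' @export
select_first_alternative <- function(x) {
  totals <- apply(x$counts, c(1, 3), sum)  # sites x 4 bases
  vapply(seq_len(n_sites(x)), function(i) {
    tt <- totals[i, ]
    tt[x$ref[i]] <- -1
    if (max(tt) <= 0) return(NA_character_)
    BASES[which.max(tt)]  # which.max takes the first maximum: A < C < G < T
  }, character(1))
}

#' Apply the stringency filters and reduce sites to ref + first alternative
#'
#' For each (site, isolate) the variability flag is set iff all three strict
#' bounds of `cfg` are passed. Sites that are nonvariant (no alternative
#' observed at all) or variable in no isolate are removed, so the output
#' site set is a subset of the input. The alternative frequency denominator
#' is the isolate's full four-base depth.
#'
#' @param x a [snp_matrix]
#' @param cfg a [filter_config]
#' @return an object of class `filtered_snp_matrix`: positions, `ref`/`alt`
#'   bases, per-isolate `ref_count`, `alt_count`, `depth`, `alt_freq`,
#'   `ref_freq` and logical `variable` matrices, plus the config used.
#' @export
apply_filters <- function(x, cfg = filter_config()) {
  alt <- select_first_alternative(x)
  keep <- !is.na(alt)
  idx <- which(keep)
  n <- length(idx)
  iso <- x$isolates
  depth <- site_depth(x)[idx, , drop = FALSE]
  ref_count <- alt_count <- matrix(0L, n, length(iso),
                                   dimnames = list(NULL, iso))
  for (j in seq_len(n)) {
    i <- idx[j]
    ref_count[j, ] <- x$counts[i, , x$ref[i]]
    alt_count[j, ] <- x$counts[i, , alt[i]]
  }
  dd <- depth
  dd[dd == 0] <- NA_real_
  alt_freq <- alt_count / dd
  ref_freq <- ref_count / dd
  variable <- depth > cfg$min_total_depth &
    alt_count > cfg$min_alt_count &
    !is.na(alt_freq) & alt_freq > cfg$min_freq
  variable[is.na(variable)] <- FALSE
  has_var <- rowSums(variable) > 0
  out <- structure(list(position = x$position[idx][has_var],
                        ref = x$ref[idx][has_var],
                        alt = alt[idx][has_var],
                        ref_count = ref_count[has_var, , drop = FALSE],
                        alt_count = alt_count[has_var, , drop = FALSE],
                        depth = depth[has_var, , drop = FALSE],
                        alt_freq = alt_freq[has_var, , drop = FALSE],
                        ref_freq = ref_freq[has_var, , drop = FALSE],
                        variable = variable[has_var, , drop = FALSE],
                        isolates = iso, config = cfg,
                        reference_name = x$reference_name,
                        reference_length = x$reference_length,
                        circular = x$circular),
                   class = "filtered_snp_matrix")
  out
}

#' @method print filtered_snp_matrix
#' @param x object to print
#' @param ... unused
#' @export
print.filtered_snp_matrix <- function(x, ...) {
  cat(sprintf("filtered_snp_matrix: %d variable sites x %d isolates (depth > %g, alt > %g, f > %g)\n",
              n_sites(x), length(x$isolates), x$config$min_total_depth,
              x$config$min_alt_count, x$config$min_freq))
  invisible(x)
}

#' Flag putative reference-consensus errors
#'
#' Positions where the alternative frequency is at least `min_freq_all` in
#' every isolate (including a re-sequencing of the reference isolate itself)
#' are most plausibly annotation errors in the reference consensus rather
#' than genuine polymorphisms.
#'
#' @param x a `filtered_snp_matrix` with at least two isolates
#' @param min_freq_all frequency that every isolate must reach (default 0.92)
#' @return integer vector of flagged positions
#' @export
flag_reference_anomalies <- function(x, min_freq_all = 0.92) {
  if (length(x$isolates) < 2) stop("need at least 2 isolates")
  f <- x$alt_freq
  all_high <- apply(f, 1, function(r) all(!is.na(r) & r >= min_freq_all))
  x$position[all_high]
}

#' Extract the per-isolate alternative-frequency matrix
#'
#' Returns the isolates x positions matrix of alternative frequencies used
#' for clustering. Where an isolate is not variable at a position the entry
#' is 0 ("no alternative observed" is informative absence, not missingness).
#'
#' @param x a `filtered_snp_matrix`
#' @param only_variable logical; zero out sub-threshold frequencies
#'   (default TRUE)
#' @return numeric matrix, isolates x positions
#' @export
freq_matrix <- function(x, only_variable = TRUE) {
  f <- x$alt_freq
  f[is.na(f)] <- 0
  if (only_variable) f[!x$variable] <- 0
  m <- t(f)
  dimnames(m) <- list(x$isolates, as.character(x$position))
  m
}
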