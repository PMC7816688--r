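#' Quantify genotype composition over marker sets
#'
#' For every (isolate, marker set) pair, the median (or mean) and the 5th and
#' 95th percentiles of the alternative frequency across the set's positions,
#' expressed as percentages. The median of a genotype's marker set in another
#' isolate estimates that genotype component's proportion there. Marker sets
#' carrying `freq = "ref"` (see [reference_marker_set()]) are quantified on
#' the reference-base frequency instead.
#'
#' Percentiles use linear interpolation between order statistics; values are
#' rounded to integers only at report time.
#'
#' @param x a `filtered_snp_matrix`
#' @param sets a `marker_sets` object, or a list of marker-set entries
#' @param statistic "median" (the reported form) or "mean"
#' @return data.frame of class `marker_quantification` with columns
#'   `isolate`, `label`, `n_snps`, `statistic`, `value`, `p5`, `p95`
#'   (percent scale)
#' @export
quantify_marker_sets <- function(x, sets, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  is_entry <- function(s) is.list(s) && !is.null(s$label) &&
    !is.null(s$positions)
  set_list <- if (is_entry(sets)) list(sets) else sets
  if (!all(vapply(set_list, is_entry, logical(1))))
    stop("`sets` must be a marker_sets object, one marker-set entry, or a list of entries")
  rows <- list()
  for (s in set_list) {
    if (s$size == 0) stop("empty marker set: ", s$label)
    i <- match(s$positions, x$position)
    if (anyNA(i)) stop("marker-set positions missing from filtered matrix")
    fmat <- if (identical(s$freq, "ref")) x$ref_freq else x$alt_freq
    for (iso in x$isolates) {
      f <- fmat[i, iso]
      f <- f[!is.na(f)]
      stat <- if (statistic == "median") median(f) else mean(f)
      qs <- quantile(f, c(0.05, 0.95), names = FALSE, type = 7)
      rows[[length(rows) + 1L]] <-
        data.frame(isolate = iso, label = s$label, n_snps = s$size,
                   statistic = statistic, value = 100 * stat,
                   p5 = 100 * qs[1], p95 = 100 * qs[2],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("marker_quantification", "data.frame")
  out
}

#' Fetch one quantified cell
#' @param q a `marker_quantification`
#' @param isolate,label cell coordinates
#' @return one-row data.frame
#' @export
quantification_cell <- function(q, isolate, label) {
  q[q$isolate == isolate & q$label == label, , drop = FALSE]
}

#' Collapse combined genome-group labels using absence evidence
#'
#' Combined marker sets (e.g. covering groups B+D+E+F+G jointly) are
#' relabelled per isolate by removing member groups whose own specific sets
#' quantify below `absence_threshold` in that isolate. When both a collapsed
#' superset (e.g. BE) and its one-smaller subset (E) are quantified, the
#' difference is attributed to the remaining member (B = BE - E), clamped to
#' [0, 100]. A subset median exceeding its superset by more than `tol`
#' percentage points indicates genotype heterogeneity and triggers a warning
#' rather than an error.
#'
#' @param q a `marker_quantification`
#' @param group_map named list mapping marker-set labels to character vectors
#'   of genome-group members, e.g. `list("E2" = "B", "S.WW" = c("E"))`.
#' @param absence_threshold percentage below which a group's own set counts
#'   as absent (default 1).
#' @param tol heterogeneity tolerance in percentage points (default 5).
#' @return data.frame of class `group_proportions`: `isolate`, `group`,
#'   `pct`, `derivation` (which collapse rules fired).
#' @export
collapse_groups <- function(q, group_map, absence_threshold = 1, tol = 5) {
  clamp <- function(v) min(100, max(0, v))
  rows <- list()
  add <- function(iso, group, pct, derivation) {
    rows[[length(rows) + 1L]] <<- data.frame(
      isolate = iso, group = group, pct = clamp(pct),
      derivation = derivation, stringsAsFactors = FALSE)
  }
  for (iso in unique(q$isolate)) {
    qi <- q[q$isolate == iso, ]
    val <- setNames(qi$value, qi$label)
    # direct (single-group) evidence; best set per group
    single <- list()
    for (lab in intersect(names(group_map), names(val))) {
      g <- group_map[[lab]]
      if (length(g) == 1)
        single[[g]] <- max(single[[g]] %||% -Inf, val[[lab]])
    }
    for (g in names(single)) add(iso, g, single[[g]], "specific set")
    absent <- names(single)[unlist(single) < absence_threshold]
    # collapse combined labels by removing absent members
    combos <- list()
    for (lab in intersect(names(group_map), names(val))) {
      g0 <- group_map[[lab]]
      if (length(g0) < 2) next
      g <- setdiff(g0, absent)
      if (length(g) == 0) next
      note <- if (length(g) < length(g0))
        sprintf("%s collapsed to %s (absent: %s)", lab,
                paste(g, collapse = ""),
                paste(setdiff(g0, g), collapse = ",")) else lab
      if (length(g) == 1) {
        add(iso, g, val[[lab]], note)
      } else {
        combos[[paste(sort(g), collapse = "")]] <-
          list(groups = sort(g), value = val[[lab]], note = note)
      }
    }
    # known per-group values: direct singles plus combos collapsed to one
    gval <- single
    gnote <- setNames(rep("specific set", length(single)), names(single))
    for (lab in intersect(names(group_map), names(val))) {
      g0 <- group_map[[lab]]
      g <- setdiff(g0, absent)
      if (length(g0) >= 2 && length(g) == 1 && !g %in% names(gval)) {
        gval[[g]] <- val[[lab]]
        gnote[[g]] <- sprintf("%s collapsed", lab)
      }
    }
    # two-member combination minus a known member -> the remaining member
    for (sup in combos) {
      if (length(sup$groups) != 2) next
      for (g in intersect(sup$groups, names(gval))) {
        rem <- setdiff(sup$groups, g)
        diffv <- sup$value - gval[[g]]
        if (diffv < -tol)
          warning(sprintf(
            "%s: %s (%s) exceeds superset %s by %.1f points (heterogeneity)",
            iso, g, gnote[[g]], paste(sup$groups, collapse = ""), -diffv))
        add(iso, rem, diffv,
            sprintf("%s - %s (%s)", sup$note, g, gnote[[g]]))
      }
    }
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("group_proportions", "data.frame")
  out
}

#' Three-frequency mixture pattern of a two-genotype isolate
#'
#' An isolate mixing genotypes a and b shows a typical pattern of three
#' alternative-frequency levels: f_a on a's own marker set, f_b on b's, and
#' f_a+b (often 1) on positions the two genotypes share.
#'
#' @param x a `filtered_snp_matrix`
#' @param isolate isolate id
#' @param set_a,set_b disjoint marker-set entries for the two genotypes
#' @param set_shared optional marker set of positions shared by both
#' @return list of class `mixture_pattern` with `f_a`, `f_b`, `f_ab`
#'   (fractions in [0, 1]; `f_ab` NA when no shared set is supplied)
#' @export
mixture_pattern <- function(x, isolate, set_a, set_b, set_shared = NULL) {
  if (length(intersect(set_a$positions, set_b$positions)))
    stop("marker sets a and b must be disjoint")
  med <- function(s) {
    if (is.null(s)) return(NA_real_)
    if (s$size == 0) stop("empty marker set")
    f <- x$alt_freq[match(s$positions, x$position), isolate]
    median(f, na.rm = TRUE)
  }
  structure(list(f_a = med(set_a), f_b = med(set_b), f_ab = med(set_shared)),
            class = "mixture_pattern")
}

#' @method print mixture_pattern
#' @param x object to print
#' @param ... unused
#' @export
print.mixture_pattern <- function(x, ...) {
  cat(sprintf("mixture_pattern: f_a = %.3f, f_b = %.3f, f_a+b = %s\n",
              x$f_a, x$f_b,
              if (is.na(x$f_ab)) "NA" else sprintf("%.3f", x$f_ab)))
  invisible(x)
}

#' Format a quantification as a composition table
#'
#' Rows are isolates, columns marker sets, cells `"median (p5-p95)"` with
#' integer rounding (the printed report form). [parse_composition_cell()]
#' recovers the numeric triple.
#'
#' @param q a `marker_quantification`
#' @param labels optional column order (marker-set labels)
#' @return character matrix with isolate rows and marker-set columns
#' @export
composition_table <- function(q, labels = unique(q$label)) {
  isolates <- unique(q$isolate)
  m <- matrix("", length(isolates), length(labels),
              dimnames = list(isolates, labels))
  for (i in seq_len(nrow(q))) {
    if (!q$label[i] %in% labels) next
    m[q$isolate[i], q$label[i]] <-
      sprintf("%d (%d-%d)", round(q$value[i]), round(q$p5[i]),
              round(q$p95[i]))
  }
  m
}

#' Parse a composition-table cell back to numbers
#' @param cell character scalar like "70 (65-74)"
#' @return numeric vector c(value, p5, p95)
#' @export
parse_composition_cell <- function(cell) {
  m <- regmatches(cell, regexec("^(-?\\d+) \\((-?\\d+)-(-?\\d+)\\)$", cell))[[1]]
  if (length(m) != 4) stop("unparseable cell: ", cell)
  setNames(as.numeric(m[2:4]), c("value", "p5", "p95"))
}
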