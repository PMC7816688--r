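#' Assign every SNP position to the exact set of isolates in which it is
#' variable
#'
#' This is the consensus-free core: a position variable in exactly one
#' isolate is isolate-specific; a position variable in two or more isolates
#' is group-specific. The label is the exact set of variable isolates (not
#' "at least these"), printed canonically in matrix isolate order.
#'
#' "Missing alternative read counts" is operationalised as a false
#' variability flag (fails any of the three stringency thresholds); set
#' `raw_zero = TRUE` for the sensitivity-analysis mode in which only a raw
#' alternative count of zero counts as missing.
#'
#' @param x a `filtered_snp_matrix` from [apply_filters()]
#' @param isolates optional character vector restricting the labelling to a
#'   sub-panel (e.g. the field isolates); isolates outside the restriction
#'   are quantified on the resulting sets but never join a label. Positions
#'   variable in no restricted isolate get an NA label.
#' @param raw_zero logical; see above.
#' @return an object of class `specificity_assignment`: data.frame-like list
#'   with `position`, `ref`, `alt`, `label`, list-column `members`, the
#'   alt-frequency matrix and the isolate universe used.
#' @export
assign_specificity <- function(x, isolates = NULL, raw_zero = FALSE) {
  universe <- isolates %||% x$isolates
  if (!all(universe %in% x$isolates))
    stop("unknown isolates: ", paste(setdiff(universe, x$isolates), collapse = ", "))
  flags <- if (raw_zero) x$alt_count > 0 else x$variable
  flags <- flags[, universe, drop = FALSE]
  members <- apply(flags, 1, function(r) universe[r], simplify = FALSE)
  nmem <- lengths(members)
  if (is.null(isolates) && any(nmem == 0))
    stop("position with no variable isolate reached assign_specificity; ",
         "apply_filters must run first (pipeline-order violation)")
  label <- vapply(members, function(m)
    if (length(m)) paste(m, collapse = ".") else NA_character_, character(1))
  structure(list(position = x$position, ref = x$ref, alt = x$alt,
                 label = label, members = members,
                 alt_freq = x$alt_freq, ref_freq = x$ref_freq,
                 variable = x$variable,
                 isolates = x$isolates, universe = universe),
            class = "specificity_assignment")
}

#' @method print specificity_assignment
#' @param x object to print
#' @param ... unused
#' @export
print.specificity_assignment <- function(x, ...) {
  cat(sprintf("specificity_assignment: %d positions, %d distinct labels over %d isolates\n",
              length(x$position), length(unique(stats::na.omit(x$label))),
              length(x$universe)))
  invisible(x)
}

#' Group positions sharing a specificity label into marker sets
#'
#' One marker set per distinct label; positions are disjoint across labels
#' and their sizes sum to the number of labelled positions.
#'
#' @param assignment a `specificity_assignment`
#' @return a named list of class `marker_sets`; each element has `label`,
#'   `members`, `positions`, `size`.
#' @export
build_marker_sets <- function(assignment) {
  keep <- !is.na(assignment$label)
  sets <- split(assignment$position[keep], assignment$label[keep])
  out <- lapply(names(sets), function(lab) {
    list(label = lab, members = strsplit(lab, ".", fixed = TRUE)[[1]],
         positions = sets[[lab]], size = length(sets[[lab]]))
  })
  names(out) <- names(sets)
  structure(out, class = "marker_sets")
}

#' @method print marker_sets
#' @param x object to print
#' @param ... unused
#' @export
print.marker_sets <- function(x, ...) {
  sz <- vapply(x, `[[`, integer(1), "size")
  cat(sprintf("marker_sets: %d sets over %d positions\n", length(x), sum(sz)))
  ord <- order(-sz)
  for (i in head(ord, 10))
    cat(sprintf("  {%s}: %d\n", x[[i]]$label, sz[i]))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Sizes of all marker sets
#' @param sets a `marker_sets` object
#' @return named integer vector of set sizes
#' @export
marker_set_sizes <- function(sets) {
  vapply(sets, `[[`, integer(1), "size")
}

#' The reference-genotype marker set
#'
#' The genotype identical to the mapping reference leaves no alternative
#' trace in itself: its diagnostic positions are those variable in every
#' other isolate of the (sub-)panel. This helper finds the marker set whose
#' label is exactly the panel minus `ref_isolate`, relabels it with the
#' reference isolate's id and marks it for quantification by reference-base
#' frequency.
#'
#' @param sets a `marker_sets` object
#' @param panel_isolates the isolate universe the labels were computed on
#' @param ref_isolate id of the isolate the reference consensus derives from
#' @return a single marker-set entry (list) with `freq = "ref"`, or NULL if
#'   no such complement set exists
#' @export
reference_marker_set <- function(sets, panel_isolates, ref_isolate) {
  want <- setdiff(panel_isolates, ref_isolate)
  for (s in sets) {
    if (length(s$members) == length(want) && setequal(s$members, want)) {
      s$label <- ref_isolate
      s$freq <- "ref"
      return(s)
    }
  }
  NULL
}

#' Partition positions by panel role
#'
#' A position is "specific within the subset" iff its label intersects the
#' subset; otherwise it is specific only outside it.
#'
#' @param assignment a `specificity_assignment` computed on the full panel
#' @param panel an [isolate_panel]
#' @param roles roles defining the subset (e.g. "field")
#' @return list with `within` / `outside` position vectors and their counts
#' @export
partition_by_panel <- function(assignment, panel, roles = "field") {
  ids <- panel_subset(panel, roles)
  if (length(ids) == 0) stop("empty subset: no panel member has role ",
                             paste(roles, collapse = "/"))
  inside <- vapply(assignment$members, function(m)
    length(intersect(m, ids)) > 0, logical(1))
  list(within = assignment$position[inside],
       outside = assignment$position[!inside],
       n_within = sum(inside), n_outside = sum(!inside))
}
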