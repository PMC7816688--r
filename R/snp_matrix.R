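#' Per-site nucleotide count matrix across isolates
#'
#' The central container of the package: for every variable site of a common
#' reference, the A/C/G/T read counts observed in each sequenced isolate.
#' Sites are stored in strictly increasing coordinate order (1-based,
#' inclusive), so parsing is order-independent: shuffled input rows yield the
#' same canonical object.
#'
#' @param position integer vector of 1-based reference coordinates.
#' @param ref character vector of reference bases (A/C/G/T), one per site.
#' @param counts integer array of dimension `sites x isolates x 4`, with the
#'   third dimension named A, C, G, T. All counts must be non-negative.
#' @param isolates character vector of unique isolate identifiers; defaults
#'   to the column names of `counts`.
#' @param reference_name name of the reference sequence.
#' @param reference_length length of the reference in bp.
#' @param circular logical; is the reference a circular genome? Circularity
#'   is declared, never inferred.
#'
#' @return an object of class `snp_matrix` with elements `position`, `ref`,
#'   `counts`, `isolates`, `reference_name`, `reference_length`, `circular`.
#' @export
snp_matrix <- function(position, ref, counts, isolates = NULL,
                       reference_name = "reference",
                       reference_length = max(position),
                       circular = FALSE) {
  position <- as.integer(position)
  n <- length(position)
  if (length(dim(counts)) != 3L || dim(counts)[3] != 4L)
    stop("`counts` must be a sites x isolates x 4 array")
  if (dim(counts)[1] != n || length(ref) != n)
    stop("`position`, `ref` and `counts` disagree on the number of sites")
  isolates <- isolates %||% dimnames(counts)[[2]]
  if (is.null(isolates)) stop("isolate ids missing")
  if (anyDuplicated(isolates)) stop("isolate ids must be unique")
  if (anyDuplicated(position)) {
    dup <- position[duplicated(position)]
    stop("duplicate positions: ", paste(head(dup, 5), collapse = ", "))
  }
  if (any(position < 1L) || any(position > reference_length))
    stop("positions must lie in [1, reference_length]")
  if (!all(ref %in% BASES)) stop("reference bases must be one of A/C/G/T")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(NULL, isolates, BASES)
  ord <- order(position)
  x <- structure(list(position = position[ord], ref = ref[ord],
                      counts = counts[ord, , , drop = FALSE],
                      isolates = isolates,
                      reference_name = reference_name,
                      reference_length = as.integer(reference_length),
                      circular = isTRUE(circular)),
                 class = "snp_matrix")
  x
}

#' @method print snp_matrix
#' @param x object to print
#' @param ... unused
#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d sites x %d isolates on %s (%s bp%s)\n",
              n_sites(x), length(x$isolates), x$reference_name,
              format(x$reference_length, big.mark = ","),
              if (x$circular) ", circular" else ""))
  invisible(x)
}

#' Number of sites in a SNP matrix
#' @param x a `snp_matrix` or `filtered_snp_matrix`
#' @return integer count of sites
#' @export
n_sites <- function(x) length(x$position)

#' Per-site, per-isolate sequencing depth
#'
#' Depth is the sum of the four base counts, so the invariant
#' depth == A + C + G + T holds by construction.
#'
#' @param x a `snp_matrix`
#' @return integer matrix, sites x isolates
#' @export
site_depth <- function(x) {
  d <- apply(x$counts, c(1, 2), sum)
  dimnames(d) <- list(NULL, x$isolates)
  d
}

#' Relative base frequencies
#'
#' The relative frequency f(site, isolate, base) = count / depth. Where an
#' isolate has zero depth at a site the frequency is NA. Frequencies over the
#' four bases sum to 1 wherever depth is nonzero.
#'
#' @param x a `snp_matrix`
#' @return numeric array, sites x isolates x 4
#' @export
base_freq <- function(x) {
  d <- site_depth(x)
  d[d == 0] <- NA_real_
  f <- sweep(x$counts, c(1, 2), d, "/")
  f
}

#' Subset a SNP matrix by site index
#' @param x a `snp_matrix`
#' @param i integer or logical index over sites
#' @return a `snp_matrix` with the selected sites
#' @export
subset_sites <- function(x, i) {
  snp_matrix(x$position[i], x$ref[i], x$counts[i, , , drop = FALSE],
             isolates = x$isolates, reference_name = x$reference_name,
             reference_length = x$reference_length, circular = x$circular)
}

#' Isolate panel metadata
#'
#' Records, per isolate, its origin label, an optional genome-group label and
#' its role in the study design (field, commercial or selected isolate).
#' Commercially selected isolates count as commercial for partitioning.
#'
#' @param id character vector of isolate ids.
#' @param origin character vector of origin labels (country, company, ...).
#' @param group optional genome-group labels (e.g. A, B, D, E, F, G or
#'   combined labels); NA where unassigned.
#' @param role one of "field", "commercial", "selected" per isolate.
#' @return a data.frame of class `isolate_panel`
#' @export
isolate_panel <- function(id, origin = NA_character_, group = NA_character_,
                          role = "field") {
  if (anyDuplicated(id)) stop("panel isolate ids must be unique")
  role <- match.arg(role, c("field", "commercial", "selected"),
                    several.ok = TRUE)
  p <- data.frame(id = as.character(id), origin = origin, group = group,
                  role = rep_len(role, length(id)),
                  stringsAsFactors = FALSE)
  class(p) <- c("isolate_panel", "data.frame")
  p
}

#' Ids of panel members with the given roles
#' @param panel an `isolate_panel`
#' @param roles roles to keep; "commercial" includes "selected"
#' @return character vector of isolate ids
#' @export
panel_subset <- function(panel, roles) {
  if (length(roles) == 0) stop("empty role subset")
  if ("commercial" %in% roles) roles <- union(roles, "selected")
  panel$id[panel$role %in% roles]
}
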