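#' Assemble a pipeline configuration
#'
#' Paths may be replaced by in-memory objects (a [snp_matrix], a
#' `reference_genome`, ...), which is how the simulator output is fed
#' through the full pipeline. A YAML file with the same field names can be
#' loaded with [yaml::read_yaml()] and passed directly.
#'
#' @param counts count-table TSV/VCF path or a [snp_matrix]
#' @param reference reference FASTA path or a `reference_genome`
#' @param annotation optional annotation path or `orf_annotation`
#' @param reads optional named list (isolate -> FASTQ path or read vector)
#' @param panel optional [isolate_panel]
#' @param filter a [filter_config]
#' @param statistic "median" or "mean" for composition
#' @param components,k,scale HCPC parameters
#' @param repeat_spec optional [repeat_region_spec]
#' @param ref_isolate optional id of the reference-derived isolate (enables
#'   the reference marker set)
#' @param specificity_roles panel roles whose isolates define marker-set
#'   labels (default "field" when a panel is present)
#' @param out_dir output directory for [render_reports()]
#' @param seed integer seed recorded in the manifest
#' @param circular declared circularity when reading the reference
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(counts, reference = NULL, annotation = NULL,
                            reads = NULL, panel = NULL,
                            filter = filter_config(),
                            statistic = "median", components = 7, k = 6,
                            scale = TRUE, repeat_spec = NULL,
                            ref_isolate = NULL, specificity_roles = "field",
                            out_dir = NULL, seed = 1, circular = TRUE) {
  if (k < 2) stop("k must be >= 2")
  for (f in list(counts, reference, annotation)) {
    if (is.character(f) && length(f) == 1 && !file.exists(f))
      stop("referenced file does not exist: ", f)
  }
  structure(list(counts = counts, reference = reference,
                 annotation = annotation, reads = reads, panel = panel,
                 filter = filter, statistic = statistic,
                 components = components, k = k, scale = scale,
                 repeat_spec = repeat_spec, ref_isolate = ref_isolate,
                 specificity_roles = specificity_roles,
                 out_dir = out_dir, seed = seed, circular = circular),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML fields mirror the arguments of [pipeline_config()]; `filter` may
#' be a mapping with `min_total_depth` / `min_alt_count` / `min_freq` and
#' `repeat_spec` a mapping with `upstream_flank` / `downstream_flank` /
#' `motif`. Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path
#' @return a [pipeline_config]
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.character(p) && !file.exists(p))
    file.path(base, p) else p
  for (f in c("counts", "reference", "annotation"))
    if (!is.null(y[[f]])) y[[f]] <- resolve(y[[f]])
  if (!is.null(y$reads)) y$reads <- lapply(y$reads, resolve)
  if (!is.null(y$filter)) y$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$repeat_spec))
    y$repeat_spec <- do.call(repeat_region_spec, y$repeat_spec)
  do.call(pipeline_config, y)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage [%s] failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages: ingest counts and reference, stringency filtering, specificity
#' assignment and marker sets (field-restricted when a panel is given),
#' composition quantification, ORF statistics (when an annotation is
#' given), repeat counting (when reads are given), and HCPC. Any stage
#' error aborts with the failing stage named.
#'
#' @param config a [pipeline_config]
#' @return list of class `pipeline_bundle` with all stage results and a
#'   `manifest` of parameters and per-stage row counts
#' @export
run_pipeline <- function(config) {
  reference <- run_stage("reference", {
    r <- config$reference
    if (is.character(r)) read_reference(r, circular = config$circular) else r
  })
  mat <- run_stage("counts", {
    x <- config$counts
    if (is.character(x)) {
      if (grepl("\\.vcf(\\.gz)?$", x, ignore.case = TRUE))
        read_vcf_counts(x, reference_name = reference$name,
                        reference_length = reference$length,
                        circular = reference$circular)
      else read_count_table(x, reference_name = reference$name,
                            reference_length = reference$length,
                            circular = reference$circular)
    } else x
  })
  filtered <- run_stage("filter", apply_filters(mat, config$filter))
  anomalies <- run_stage("anomalies", flag_reference_anomalies(filtered))

  assignment_full <- run_stage("specificity",
                               assign_specificity(filtered))
  label_iso <- NULL
  partition <- NULL
  if (!is.null(config$panel)) {
    label_iso <- panel_subset(config$panel, config$specificity_roles)
    partition <- run_stage("partition",
      partition_by_panel(assignment_full, config$panel,
                         config$specificity_roles))
  }
  assignment <- if (is.null(label_iso)) assignment_full else
    run_stage("specificity", assign_specificity(filtered, label_iso))
  sets <- run_stage("marker_sets", build_marker_sets(assignment))

  quant_sets <- sets
  if (!is.null(config$ref_isolate)) {
    rs <- reference_marker_set(sets, label_iso %||% filtered$isolates,
                               config$ref_isolate)
    if (!is.null(rs)) {
      # replace the complement-labelled set by its reference relabel
      keep <- !vapply(sets, function(s)
        setequal(s$positions, rs$positions), logical(1))
      quant_sets <- c(sets[keep], setNames(list(rs), rs$label))
      class(quant_sets) <- "marker_sets"
    }
  }
  composition <- run_stage("composition",
    quantify_marker_sets(filtered, quant_sets, statistic = config$statistic))

  orf <- NULL
  if (!is.null(config$annotation)) {
    ann <- run_stage("annotation", {
      a <- config$annotation
      if (is.character(a)) read_annotation(a, reference$length,
                                           circular = reference$circular)
      else a
    })
    orf <- run_stage("orf_stats", {
      cls <- classify_snps(filtered, ann, reference)
      list(classification = cls, density = density_table(cls, ann))
    })
  }

  repeats <- NULL
  if (!is.null(config$reads)) {
    if (is.null(config$repeat_spec))
      stop("stage [repeats] failed: reads given without a repeat_spec")
    repeats <- run_stage("repeats", {
      h <- lapply(config$reads, count_repeats, spec = config$repeat_spec)
      list(histograms = h, panel_table = summarize_repeat_panel(h))
    })
  }

  hcpc <- run_stage("hcpc", {
    fm <- freq_matrix(filtered)
    pca <- run_pca(fm, scale = config$scale)
    hc <- hierarchical_cluster(pca, n_components =
                                 min(config$components, pca$n_components))
    list(pca = pca, hc = hc,
         result = cut_and_consolidate(hc, k = min(config$k, nrow(fm))))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("gvpop")),
    seed = config$seed,
    parameters = list(filter = unclass(config$filter),
                      statistic = config$statistic,
                      components = config$components, k = config$k,
                      scale = config$scale),
    counts = list(sites_in = n_sites(mat), isolates = length(mat$isolates)),
    filter = list(sites_retained = n_sites(filtered)),
    anomalies = anomalies,
    specificity = list(n_sets = length(sets),
                       set_sizes = as.list(marker_set_sizes(sets))),
    partition = if (!is.null(partition))
      list(n_within = partition$n_within, n_outside = partition$n_outside),
    hcpc = list(suggested_k = hcpc$hc$suggested_k, k = hcpc$result$k))

  structure(list(matrix = mat, reference = reference, filtered = filtered,
                 anomalies = anomalies, assignment = assignment,
                 assignment_full = assignment_full, partition = partition,
                 marker_sets = sets, quant_sets = quant_sets,
                 composition = composition, orf = orf, repeats = repeats,
                 hcpc = hcpc, manifest = manifest, config = config),
            class = "pipeline_bundle")
}

#' Write the report files of a pipeline bundle
#'
#' Produces the machine-readable analogues of the study's tables and
#' figures: `filtered.tsv`, `assignment.tsv`, `table2.tsv` (composition
#' grid, cells "median (p5-p95)"), `fig1_counts.tsv` (SNP category
#' tallies), `fig4_repeats.tsv`, `fig5_variance.tsv`, `tree.nwk`, and a
#' `manifest.json` listing every output with its content hash.
#'
#' @param bundle a `pipeline_bundle`
#' @param out_dir output directory (created if missing)
#' @return invisible character vector of written paths
#' @export
render_reports <- function(bundle, out_dir = bundle$config$out_dir) {
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  f <- bundle$filtered
  ftab <- data.frame(position = f$position, ref = f$ref, alt = f$alt)
  for (id in f$isolates) {
    ftab[[paste0(id, ":alt_freq")]] <- round(f$alt_freq[, id], 5)
    ftab[[paste0(id, ":variable")]] <- f$variable[, id]
  }
  wt(ftab, "filtered.tsv")
  a <- bundle$assignment
  wt(data.frame(position = a$position, ref = a$ref, alt = a$alt,
                label = a$label), "assignment.tsv")
  comp <- composition_table(bundle$composition,
                            labels = names(bundle$quant_sets))
  wt(data.frame(isolate = rownames(comp), comp, check.names = FALSE),
     "table2.tsv")
  if (!is.null(bundle$orf)) {
    t1 <- bundle$orf$classification$tallies
    wt(data.frame(category = c("transitions", "transversions", "coding",
                               "noncoding", "codon_pos1", "codon_pos2",
                               "codon_pos3", "synonymous", "nonsynonymous"),
                  count = c(t1$transitions, t1$transversions, t1$coding,
                            t1$noncoding, t1$codon_pos, t1$synonymous,
                            t1$nonsynonymous)),
       "fig1_counts.tsv")
    wt(bundle$orf$density$per_orf, "orf_density.tsv")
  }
  if (!is.null(bundle$repeats)) {
    wt(bundle$repeats$panel_table, "fig4_repeats.tsv")
  } else {
    wt(data.frame(isolate = character(), n_informative = integer()),
       "fig4_repeats.tsv")
  }
  pca <- bundle$hcpc$pca
  wt(data.frame(component = seq_along(pca$percent),
                percent = pca$percent, cumulative = pca$cumulative),
     "fig5_variance.tsv")
  wt(data.frame(isolate = names(bundle$hcpc$result$assignment),
                cluster_tree = bundle$hcpc$result$tree_assignment,
                cluster = bundle$hcpc$result$assignment,
                dim1 = bundle$hcpc$result$factor_map[, 1],
                dim2 = bundle$hcpc$result$factor_map[, 2]),
     "hcpc_assignment.tsv")
  nwk <- file.path(out_dir, "tree.nwk")
  writeLines(export_tree(bundle$hcpc$hc), nwk)
  paths <- c(paths, nwk)
  man <- bundle$manifest
  man$files <- lapply(setNames(basename(paths), basename(paths)),
                      function(b) unname(tools::md5sum(file.path(out_dir, b))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, mp))
}
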