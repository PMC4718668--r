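#' End-to-end pipeline
#'
#' One call runs the whole analysis: obtain subject-level expression (from a
#' file or a simulation design), build each group's intersubject
#' correlation network, threshold it, detect communities, compare each drug
#' group against the matched same-gene same-age baseline, and write all
#' matrices, partitions, difference maps and SVG renders together with a
#' reproducibility manifest of parameters and per-file checksums. Reruns
#' with the same config and seed are byte-identical.
#'
#' @name pipeline_cli
NULL

#' Assemble a pipeline configuration
#'
#' @param input path to an expression TSV/CSV, or NULL when simulating.
#' @param design a `simulation_design`, the string `"paper_like"`, or a
#'   design YAML path; ignored when `input` is given.
#' @param alpha edge-significance threshold (default 0.05).
#' @param q_level FDR level for network comparison (default 0.35).
#' @param fdr_method `"BH"` or `"BY"`.
#' @param gamma,seed,restarts community-detection options.
#' @param baseline treatment regarded as baseline (default `"saline"`).
#' @param contrasts data frame `gene, age, treatment_a, treatment_b`, or
#'   NULL for the default: every non-baseline treatment vs baseline within
#'   each (gene, age).
#' @param output_dir artifact directory.
#' @param allow_missing passed to the expression loader.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, design = "paper_like",
                            alpha = 0.05, q_level = 0.35,
                            fdr_method = "BH", gamma = 1, seed = 1L,
                            restarts = 20L, baseline = "saline",
                            contrasts = NULL, output_dir = "cge_out",
                            allow_missing = FALSE) {
  structure(list(input = input, design = design, alpha = alpha,
                 q_level = q_level, fdr_method = fdr_method, gamma = gamma,
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 baseline = baseline, contrasts = contrasts,
                 output_dir = output_dir, allow_missing = allow_missing),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `contrasts`
#' is a list of `[gene, age, treatment_a, treatment_b]` entries.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$contrasts)) {
    y$contrasts <- do.call(rbind, lapply(y$contrasts, function(cc) {
      data.frame(gene = cc[[1]], age = cc[[2]], treatment_a = cc[[3]],
                 treatment_b = cc[[4]], stringsAsFactors = FALSE)
    }))
  }
  do.call(pipeline_config, y)
}

default_contrasts <- function(groups, baseline) {
  ga <- unique(groups[c("gene", "age")])
  out <- list()
  for (i in seq_len(nrow(ga))) {
    sel <- groups$gene == ga$gene[i] & groups$age == ga$age[i]
    trts <- unique(groups$treatment[sel])
    if (!(baseline %in% trts)) next
    for (trt in setdiff(trts, baseline)) {
      out[[length(out) + 1L]] <- data.frame(
        gene = ga$gene[i], age = ga$age[i],
        treatment_a = trt, treatment_b = baseline,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

validate_contrasts <- function(contrasts, groups) {
  for (i in seq_len(nrow(contrasts))) {
    for (side in c("treatment_a", "treatment_b")) {
      hit <- groups$gene == contrasts$gene[i] &
        groups$age == contrasts$age[i] &
        groups$treatment == contrasts[[side]][i]
      if (!any(hit)) {
        stop("contrast references missing group: (",
             contrasts$gene[i], ", ", contrasts$age[i], ", ",
             contrasts[[side]][i], ")", call. = FALSE)
      }
    }
  }
  invisible(contrasts)
}

#' Run the full pipeline
#'
#' @param config a `pipeline_config` (or YAML path).
#' @param registry region registry.
#' @return (invisibly) a list with `table`, `networks`, `thresholded`,
#'   `partitions`, `diffs`, `manifest` (parsed) and `output_dir`.
#' @export
run_pipeline <- function(config, registry = default_region_registry()) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  for (d in file.path(out_dir, c("", "nets", "communities", "diffs",
                                 "renders"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }

  if (!is.null(config$input)) {
    table <- load_expression(config$input, registry,
                             allow_missing = config$allow_missing)
  } else {
    design <- config$design
    if (is.character(design)) {
      design <- if (identical(design, "paper_like")) {
        paper_like(seed = config$seed, registry = registry)
      } else {
        load_design(design, registry)
      }
    }
    table <- simulate_expression(design, registry)
  }
  write_expression(table, file.path(out_dir, "expression.tsv"))

  groups <- unique(as.data.frame(table)[c("gene", "age", "treatment")])
  groups <- groups[order(groups$gene, groups$age, groups$treatment,
                         method = "radix"), , drop = FALSE]
  networks <- list()
  thresholded <- list()
  partitions <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    lbl <- group_label(g$gene, g$age, g$treatment)
    net <- pearson_network(table, g$gene, g$age, g$treatment, registry)
    if (net$n < 6L) {
      message("group ", lbl, " has n = ", net$n,
              " subjects; typical designs use 6-7")
    }
    thr <- threshold_network(net, config$alpha)
    part <- detect_communities(thr, gamma = config$gamma,
                               seed = config$seed,
                               restarts = config$restarts)
    write_square_csv(net$r, file.path(out_dir, "nets",
                                      paste0(lbl, "_r.csv")))
    write_square_csv(net$p, file.path(out_dir, "nets",
                                      paste0(lbl, "_p.csv")))
    write_square_csv(thr$w, file.path(out_dir, "nets",
                                      paste0(lbl, "_thresholded.csv")))
    write_partition(part, file.path(out_dir, "communities",
                                    paste0(lbl, ".tsv")))
    render_network(thr, part, registry,
                   file.path(out_dir, "renders", paste0(lbl, ".svg")))
    networks[[lbl]] <- net
    thresholded[[lbl]] <- thr
    partitions[[lbl]] <- part
  }

  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    contrasts <- default_contrasts(groups, config$baseline)
  }
  diffs <- list()
  if (!is.null(contrasts)) {
    validate_contrasts(contrasts, groups)
    for (i in seq_len(nrow(contrasts))) {
      cc <- contrasts[i, ]
      la <- group_label(cc$gene, cc$age, cc$treatment_a)
      lb <- group_label(cc$gene, cc$age, cc$treatment_b)
      diff <- classify_edges(z_difference(networks[[la]], networks[[lb]]),
                             thresholded[[la]], thresholded[[lb]],
                             q_level = config$q_level,
                             method = config$fdr_method)
      clbl <- paste0(la, "_vs_", lb)
      write_difference_map(diff, file.path(out_dir, "diffs",
                                           paste0(clbl, ".tsv")))
      render_difference_map(diff, registry,
                            file.path(out_dir, "renders",
                                      paste0(clbl, ".svg")))
      diffs[[clbl]] <- diff
    }
  }

  manifest <- write_manifest(config, out_dir)
  invisible(list(table = table, networks = networks,
                 thresholded = thresholded, partitions = partitions,
                 diffs = diffs, manifest = manifest,
                 output_dir = out_dir))
}

write_manifest <- function(config, out_dir) {
  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(sort(files), "manifest.json")
  sums <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(
    package = "cgenet",
    version = as.character(utils::packageVersion("cgenet")),
    parameters = list(alpha = config$alpha, q_level = config$q_level,
                      fdr_method = config$fdr_method, gamma = config$gamma,
                      seed = config$seed, restarts = config$restarts,
                      baseline = config$baseline,
                      input = if (is.null(config$input)) "simulated"
                              else config$input),
    checksums = as.list(stats::setNames(sums, files))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest
}
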