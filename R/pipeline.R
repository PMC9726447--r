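#' Pipeline errors with exit-code semantics
#'
#' Validation problems (bad config, missing samples) signal a
#' `hybridpaint_validation_error`; problems with the data themselves signal
#' a `hybridpaint_data_error`. The command-line wrapper maps these to exit
#' codes 2 and 3.
#' @noRd
pipeline_stop <- function(kind, ...) {
  stop(structure(class = c(paste0("hybridpaint_", kind, "_error"), "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read a pipeline configuration file
#'
#' A single YAML file with blocks `paths` (vcf, index, outdir), `filters`
#' (fields of [filter_config()]), `rrhs` (fields of [rrhs_config()]),
#' `scheme` (query + populations with assign/exclude) and optionally `sim`
#' (fields of [sim_config()]).
#'
#' @param path Path to the YAML config.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) pipeline_stop("validation", "config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order
#' `simulate -> filter -> rrhs -> paint`. `simulate` writes a synthetic
#' dataset into `outdir` and later stages consume it when no input paths are
#' configured. `filter` runs the quality cascade and writes the filtered VCF
#' plus the cascade report; `rrhs` writes pseudo-haplotype alignments;
#' `paint` writes the ancestry BED, per-site TSV and per-population summary.
#' A `manifest.json` records the seed, package version and MD5 checksum of
#' every artifact, so identical config + seed reproduce identical manifests.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]) or an
#'   equivalently shaped list.
#' @param stages Character subset of `c("simulate", "filter", "rrhs",
#'   "paint")`.
#' @param outdir Output directory; overrides `config$paths$outdir`.
#' @param seed Integer seed; overrides `config$seed`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages = c("filter", "paint"), outdir = NULL,
                         seed = NULL) {
  canonical <- c("simulate", "filter", "rrhs", "paint")
  bad <- setdiff(stages, canonical)
  if (length(bad)) pipeline_stop("validation", "unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- canonical[canonical %in% stages]
  outdir <- outdir %||% config$paths$outdir
  if (is.null(outdir)) pipeline_stop("validation", "no output directory configured")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  artifacts <- character(0)
  log_info <- function(...) message("[hybridpaint] ", ...)

  vcf_path <- config$paths$vcf
  index_path <- config$paths$index
  scheme <- config$scheme

  if ("simulate" %in% stages) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(scfg)
    paths <- write_simulation(sim, outdir)
    artifacts <- c(artifacts, paths)
    vcf_path <- vcf_path %||% paths[["vcf"]]
    index_path <- index_path %||% paths[["fai"]]
    scheme <- scheme %||% list(query = sim$scheme$query,
                               populations = sim$scheme$populations)
    log_info("simulated ", n_sites(sim$table), " sites for ",
             n_samples(sim$table), " samples")
  }

  needs_data <- any(c("filter", "rrhs", "paint") %in% stages)
  filtered <- NULL
  if (needs_data) {
    if (is.null(vcf_path) || is.null(index_path)) {
      pipeline_stop("validation", "stages ", paste(stages, collapse = "+"),
                    " need paths$vcf and paths$index (or a simulate stage)")
    }
    if (!file.exists(vcf_path)) pipeline_stop("data", "VCF not found: ", vcf_path)
    if (!file.exists(index_path)) pipeline_stop("data", "genome index not found: ", index_path)
    index <- read_genome_index(index_path)
    table <- tryCatch(read_vcf(vcf_path, index),
                      error = function(e) pipeline_stop("data", conditionMessage(e)))
  }

  if ("filter" %in% stages) {
    fcfg <- do.call(filter_config, config$filters %||% list())
    res <- filter_variants(table, fcfg)
    filtered <- res$table
    p_vcf <- file.path(outdir, "filtered.vcf")
    p_rep <- file.path(outdir, "filter_report.tsv")
    write_vcf(filtered, p_vcf)
    write_filter_report(res$report, p_rep)
    artifacts <- c(artifacts, filtered_vcf = p_vcf, filter_report = p_rep)
    for (s in setdiff(names(res$report), "empty_output")) {
      log_info("filter ", s, " = ", res$report[[s]])
    }
  }

  if ("rrhs" %in% stages) {
    if (is.null(filtered)) {
      pipeline_stop("validation", "rrhs requires the filter stage in the same run")
    }
    rargs <- config$rrhs %||% list()
    if (is.null(rargs$seed)) rargs$seed <- seed
    rcfg <- do.call(rrhs_config, rargs)
    adir <- file.path(outdir, "alignments")
    paths <- generate_alignments(filtered, rcfg, adir)
    artifacts <- c(artifacts, stats::setNames(paths, basename(paths)))
    log_info("wrote ", length(paths), " RRHS alignments to ", adir)
  }

  if ("paint" %in% stages) {
    if (is.null(filtered)) {
      pipeline_stop("validation", "paint requires the filter stage in the same run")
    }
    if (is.null(scheme)) pipeline_stop("validation", "paint requires a scheme")
    sch <- if (inherits(scheme, "population_scheme")) scheme else {
      population_scheme(scheme$query, scheme$populations)
    }
    tryCatch(validate_scheme(sch, filtered$roster),
             error = function(e) pipeline_stop("validation", conditionMessage(e)))
    min_support <- config$paint$min_support %||% 2L
    painting <- paint_ancestry(filtered, sch, min_support = min_support)
    p_bed <- file.path(outdir, "blocks.bed")
    p_sum <- file.path(outdir, "summary.tsv")
    p_sites <- file.path(outdir, "sites.tsv")
    write_bed(painting$blocks, p_bed, index = filtered$index)
    write_summary(painting$summary, p_sum)
    utils::write.table(painting$sites, p_sites, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(artifacts, blocks_bed = p_bed, summary = p_sum, sites = p_sites)
    s <- painting$summary
    for (i in seq_len(nrow(s))) {
      log_info("assigned ", s$population[i], ": ", s$assigned_bp[i], " bp (",
               sprintf("%.2f", s$percent_of_assigned[i]), "% of assigned)")
    }
    log_info("unassigned: ", format(attr(s, "unassigned_bp"), scientific = FALSE),
             " bp of ", format(attr(s, "genome_bp"), scientific = FALSE), " bp")
  }

  manifest <- list(
    package = "hybridpaint",
    version = as.character(utils::packageVersion("hybridpaint")),
    seed = seed,
    stages = stages,
    artifacts = as.list(tools::md5sum(unname(artifacts)))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
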