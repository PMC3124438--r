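#' Load a pipeline configuration
#'
#' YAML with flat sections per stage: `input` (fasta, exclusion_fasta,
#' truth), `simulate` ([sim_config()] fields plus plant lists), `detector`
#' ([detector_params()] fields), `families` ([family_params()] fields),
#' `genome` (genome_bp, n_clones, insert_bp, coding_fraction,
#' gene_size_lo/hi, standard_pg, reference_bp), `seed` and `log_level`.
#' Unknown keys are rejected.
#'
#' @param file YAML path, or NULL for the defaults.
#' @param overrides Named list merged over the file values (CLI flags).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, overrides = list()) {
  cfg <- if (is.null(file)) list() else yaml::read_yaml(file)
  known <- c("input", "simulate", "detector", "families", "genome", "seed",
             "log_level")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    config_stop(extra[1], "unknown configuration section")
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$log_level <- if (is.null(cfg$log_level)) "info" else cfg$log_level
  check_keys <- function(section, allowed) {
    extra <- setdiff(names(cfg[[section]]), allowed)
    if (length(extra) > 0)
      config_stop(paste0(section, ".", extra[1]), "unknown configuration key")
  }
  check_keys("input", c("fasta", "exclusion_fasta", "truth", "flow_sample",
                        "flow_standard"))
  check_keys("detector", names(formals(detector_params)))
  check_keys("families", names(formals(family_params)))
  check_keys("simulate", c(names(formals(sim_config)), "ssrs", "families"))
  check_keys("genome", c("genome_bp", "n_clones", "insert_bp",
                         "coding_fraction", "gene_size_lo", "gene_size_hi",
                         "standard_pg", "reference_bp", "sampling_fraction"))
  # YAML renders scientific notation like "2.17e9" as a string; coerce all
  # numeric sections back to numbers
  for (sec in c("genome", "detector")) {
    cfg[[sec]] <- lapply(cfg[[sec]], function(v) {
      if (is.character(v) && !anyNA(suppressWarnings(as.numeric(v))))
        as.numeric(v) else v
    })
  }
  class(cfg) <- "pipeline_config"
  cfg
}

build_sim_config <- function(cfg) {
  sim <- cfg$simulate
  ssrs <- lapply(sim$ssrs, function(s) do.call(ssr_plant, s))
  fams <- lapply(sim$families, function(f) do.call(family_plant, f))
  args <- sim[setdiff(names(sim), c("ssrs", "families"))]
  args$planted_ssrs <- ssrs
  args$planted_families <- fams
  if (is.null(args$seed)) args$seed <- cfg$seed
  do.call(sim_config, args)
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[setdiff(names(cfg), "log_level")], f)
  unname(tools::md5sum(f))
}

#' Run the full survey pipeline
#'
#' Executes the stages in order: simulate (when no input FASTA is given),
#' tandem-array scan, landscape summary, masking, family discovery and
#' survey metrics, writing every table under `out_dir`. Each TSV carries a
#' provenance header (package version, config hash, seed). Re-running with
#' an identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()] object (or path to a YAML file).
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly; the run log is written alongside the
#'   outputs.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste("repeatscape", as.character(utils::packageVersion("repeatscape"))),
           paste("config", config_hash(config)),
           paste("seed", config$seed))

  stage <- "simulate"
  result <- tryCatch({
    if (is.null(config$input$fasta)) {
      log_msg(config, "stage simulate")
      sim <- simulate_reads(build_sim_config(config),
                            fasta = file.path(out_dir, "reads.fasta"),
                            truth_file = file.path(out_dir, "truth.tsv"))
      reads <- sim$reads
    } else {
      stage <- "scan-ssr"
      if (!file.exists(config$input$fasta))
        stop("input FASTA not found: ", config$input$fasta)
      reads <- read_reads_fasta(config$input$fasta)
    }

    stage <- "scan-ssr"
    log_msg(config, "stage scan-ssr (", length(reads), " reads)")
    det <- do.call(detector_params,
                   config$detector[!vapply(config$detector, is.null,
                                           logical(1))])
    arrays <- scan_tandem_arrays(reads, det)
    write_tandem_tsv(arrays, file.path(out_dir, "tandem_arrays.tsv"), hdr)
    if (nrow(arrays) > 0)
      write_tandem_gff3(arrays, file.path(out_dir, "tandem_arrays.gff3"))

    stage <- "summarize"
    surveyed <- sum(nchar(reads))
    if (nrow(arrays) > 0) {
      log_msg(config, "stage summarize (", nrow(arrays), " arrays)")
      report <- landscape_report(arrays, length(reads), surveyed, reads)
      write_landscape_tsv(report, arrays, out_dir, hdr)
    }

    stage <- "families"
    log_msg(config, "stage families")
    fp <- do.call(family_params,
                  config$families[!vapply(config$families, is.null,
                                          logical(1))])
    masked <- mask_tandem_arrays(reads, arrays)
    write_reads_fasta(masked, file.path(out_dir, "reads_masked.fasta"))
    hits <- allpairs_search(masked, fp, arrays)
    fams <- cluster_families(define_elements(hits, fp), hits, fp)
    fams <- filter_families(fams, fp)
    if (nrow(fams$families) > 0) {
      fams <- build_consensus(fams, reads, fp)
      fams <- curate_families(fams, reads, hits, fp)
      fams <- screen_exclusion(fams, config$input$exclusion_fasta)$kept
      sampling <- config$genome$sampling_fraction
      if (is.null(sampling))
        sampling <- if (!is.null(config$genome$genome_bp))
          surveyed / config$genome$genome_bp else 1
      acct <- family_accounting(fams, surveyed, sampling)
      write_family_outputs(fams, acct, out_dir, hdr)
    }

    stage <- "survey"
    log_msg(config, "stage survey")
    gs <- config$genome
    summ <- survey_summary(
      reads, genome_bp = if (is.null(gs$genome_bp)) 2.17e9 else gs$genome_bp,
      n_clones = gs$n_clones,
      insert_bp = if (is.null(gs$insert_bp)) 40000 else gs$insert_bp,
      coding_fraction = gs$coding_fraction,
      gene_size_lo = if (is.null(gs$gene_size_lo)) 7000 else gs$gene_size_lo,
      gene_size_hi = if (is.null(gs$gene_size_hi)) 10000 else gs$gene_size_hi)
    kv <- unlist(summ)
    con <- file(file.path(out_dir, "survey_summary.tsv"), "w")
    for (h in hdr) writeLines(paste0("# ", h), con)
    write.table(data.frame(key = names(kv), value = unname(kv)), con,
                sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    out_dir
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  log_msg(config, "pipeline complete: ", out_dir)
  invisible(result)
}
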