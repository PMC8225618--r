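#' Run the full analysis pipeline from a single config
#'
#' Executes the requested stages in order -- simulate (optional) ->
#' quantify and/or count-junctions -> cohort statistics -- writing every
#' output plus a run manifest into `out_dir`. The manifest (config
#' snapshot, input digests, seed, package version, output paths) fully
#' determines a rerun for the deterministic stages.
#'
#' The config is a YAML or JSON document (or an equivalent R list) with
#' optional top-level blocks:
#' \describe{
#'   \item{seed}{integer, required when any `simulate` block is present}
#'   \item{simulate}{sub-blocks `droplets` (`lambda_true`, `n_droplets`,
#'     ...), `reads` (`mixture`, `n_background`, ...), `cohort`
#'     (`n_subjects`, `prevalence`, ...); simulated files land in
#'     `out_dir` and feed the later stages}
#'   \item{quantify}{`droplets` (CSV path; omit when simulated),
#'     `threshold`, `droplet_volume_nl`, `reaction_volume_ul`,
#'     `sample_fraction_loaded`, optional `controls` (CSV with
#'     `well_id`, `role`), `ntc_tolerance`}
#'   \item{count_junctions}{`sam` (path; omit when simulated),
#'     `junctions` (junction-definition TSV; omit for the toy model),
#'     `min_overhang`, `positivity_threshold`}
#'   \item{cohort}{`input` (CSV path; omit when simulated),
#'     `threshold_copies`, `epcam_comparison` (logical)}
#' }
#'
#' @param config Path to a YAML/JSON config file, or a list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character()
  inputs <- character()
  seed <- cfg$seed

  if (!is.null(cfg$simulate)) {
    if (is.null(seed)) stop("config error: simulate stages require a seed")
    if (!is.null(cfg$simulate$droplets)) {
      sd_cfg <- cfg$simulate$droplets
      sim <- do.call(simulate_droplets,
                     c(sd_cfg[setdiff(names(sd_cfg), "seed")],
                       list(seed = seed)))
      p <- file.path(out_dir, "simulated_droplets.csv")
      utils::write.csv(sim$droplets, p, row.names = FALSE)
      cfg$quantify$droplets <- p
      outputs <- c(outputs, p)
      results$simulate_droplets <- sim$truth
    }
    if (!is.null(cfg$simulate$reads)) {
      sr_cfg <- cfg$simulate$reads
      model <- if (!is.null(cfg$count_junctions$junctions)) {
        load_model(cfg$count_junctions$junctions)
      } else build_toy_ar_model()
      sr_cfg$mixture <- unlist(sr_cfg$mixture)
      sim <- do.call(simulate_spliced_reads,
                     c(list(model = model),
                       sr_cfg[setdiff(names(sr_cfg), "seed")],
                       list(seed = seed)))
      p <- file.path(out_dir, "simulated_reads.sam")
      writeLines(sim$sam, p)
      cfg$count_junctions$sam <- p
      outputs <- c(outputs, p)
      results$simulate_reads <- sim$truth
    }
    if (!is.null(cfg$simulate$cohort)) {
      sc_cfg <- cfg$simulate$cohort
      if (!is.null(sc_cfg$prevalence)) {
        sc_cfg$prevalence <- unlist(sc_cfg$prevalence)
      }
      sim <- do.call(simulate_cohort,
                     c(sc_cfg[setdiff(names(sc_cfg), "seed")],
                       list(seed = seed)))
      p <- file.path(out_dir, "simulated_cohort.csv")
      utils::write.csv(sim$records, p, row.names = FALSE)
      cfg$cohort$input <- p
      outputs <- c(outputs, p)
      results$simulate_cohort <- sim$truth
    }
  }

  if (!is.null(cfg$quantify)) {
    q <- cfg$quantify
    if (is.null(q$droplets)) {
      stop("config error: quantify stage needs a 'droplets' file")
    }
    if (!file.exists(q$droplets)) {
      stop("config error: droplet file not found: ", q$droplets)
    }
    inputs <- c(inputs, q$droplets)
    droplets <- read_droplet_table(q$droplets)
    wells <- quantify_wells(
      droplets,
      threshold = if (is.null(q$threshold)) "auto" else q$threshold,
      droplet_volume_nl = q$droplet_volume_nl %||% 0.85,
      reaction_volume_ul = q$reaction_volume_ul %||% 22,
      sample_fraction_loaded = q$sample_fraction_loaded %||% 1)
    qc <- NULL
    if (!is.null(q$controls)) {
      inputs <- c(inputs, q$controls)
      control_map <- utils::read.csv(q$controls, stringsAsFactors = FALSE)
      qc <- apply_plate_controls(wells, control_map,
                                 ntc_tolerance = q$ntc_tolerance %||% 2L)
      wells <- qc$wells
    }
    p <- file.path(out_dir, "well_quantification.tsv")
    utils::write.table(wells, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, p)
    results$quantify <- list(wells = wells, qc = qc)
  }

  if (!is.null(cfg$count_junctions)) {
    cj <- cfg$count_junctions
    if (is.null(cj$sam)) {
      stop("config error: count_junctions stage needs a 'sam' file")
    }
    if (!file.exists(cj$sam)) {
      stop("config error: SAM file not found: ", cj$sam)
    }
    inputs <- c(inputs, cj$sam)
    model <- if (!is.null(cj$junctions)) {
      inputs <- c(inputs, cj$junctions)
      load_model(cj$junctions)
    } else build_toy_ar_model()
    reads <- parse_sam(cj$sam)
    counts <- count_junction_reads(
      reads, model,
      min_overhang = cj$min_overhang %||% 6L,
      positivity_threshold = cj$positivity_threshold %||% 1L)
    p1 <- file.path(out_dir, "junction_counts.tsv")
    p2 <- file.path(out_dir, "junction_counts.json")
    write_junction_counts(counts, tsv = p1, json = p2)
    outputs <- c(outputs, p1, p2)
    results$count_junctions <- counts
  }

  if (!is.null(cfg$cohort)) {
    co <- cfg$cohort
    if (is.null(co$input)) {
      stop("config error: cohort stage needs an 'input' file")
    }
    if (!file.exists(co$input)) {
      stop("config error: cohort file not found: ", co$input)
    }
    inputs <- c(inputs, co$input)
    records <- read_cohort_table(co$input)
    summary <- summarize_cohort(records,
                                threshold_copies = co$threshold_copies %||% 0)
    p <- file.path(out_dir, "cohort_summary.tsv")
    utils::write.table(summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, p)
    m <- heatmap_matrix(records)
    pm <- file.path(out_dir, "heatmap_matrix.tsv")
    write_heatmap_matrix(m, pm)
    outputs <- c(outputs, pm)
    results$cohort <- list(summary = summary)
    if (isTRUE(co$epcam_comparison)) {
      ep <- compare_epcam_fractions(records,
                                    threshold_copies = co$threshold_copies %||% 0)
      pe <- file.path(out_dir, "epcam_comparison.tsv")
      utils::write.table(ep, pe, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, pe)
      results$cohort$epcam <- ep
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ARVquant")),
    seed = seed,
    config = cfg,
    input_digests = as.list(tools::md5sum(unique(inputs))),
    outputs = outputs)
  mp <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a plain-text report of a pipeline run
#'
#' Deterministic human-readable summary of the outputs found in a
#' pipeline output directory; every number is read back from the tabular
#' outputs, so the report always matches the machine-readable files.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
render_report <- function(out_dir) {
  lines <- c("ARVquant pipeline report", strrep("=", 24))
  jc <- file.path(out_dir, "junction_counts.tsv")
  if (file.exists(jc)) {
    tab <- utils::read.delim(jc, stringsAsFactors = FALSE)
    lines <- c(lines, "", "Junction-spanning read counts:")
    lines <- c(lines, sprintf("  %-12s %6d / %d screened  %s",
                              tab$transcript_id, tab$spanning_reads,
                              tab$total_reads_screened,
                              ifelse(tab$positive, "POSITIVE", "negative")))
  }
  wq <- file.path(out_dir, "well_quantification.tsv")
  if (file.exists(wq)) {
    tab <- utils::read.delim(wq, stringsAsFactors = FALSE)
    lines <- c(lines, "", "ddPCR well quantification:")
    lines <- c(lines, sprintf(
      "  %-6s %-6s pos %5d/%-6d conc %10.3f copies/uL  %s",
      tab$well_id, tab$channel, tab$n_pos, tab$n_total, tab$conc_per_ul,
      ifelse(is.na(tab$flags) | tab$flags == "", "", tab$flags)))
    if ("reliable" %in% names(tab) &&
        any(!tab$reliable, na.rm = TRUE)) {
      lines <- c(lines, "  QC: plate controls FAILED; sample wells unreliable")
    }
  }
  cs <- file.path(out_dir, "cohort_summary.tsv")
  if (file.exists(cs)) {
    tab <- utils::read.delim(cs, stringsAsFactors = FALSE)
    lines <- c(lines, "", "Cohort summary (copies/sample):")
    lines <- c(lines, sprintf(
      "  %-12s %2d/%-3d positive (%d%%)  median %-8.4g mean %-8.4g range %g-%g",
      tab$transcript_id, tab$n_positive, tab$n_total,
      tab$prevalence_percent, tab$median, tab$mean, tab$min, tab$max))
  }
  ep <- file.path(out_dir, "epcam_comparison.tsv")
  if (file.exists(ep)) {
    tab <- utils::read.delim(ep, stringsAsFactors = FALSE)
    lines <- c(lines, "", "EpCAM-positive vs -negative CTC fractions:")
    lines <- c(lines, sprintf(
      "  %-12s pos-fraction %g%%  neg-fraction %g%%  Fisher p = %.4g",
      tab$transcript_id, tab$epcam_pos_prevalence,
      tab$epcam_neg_prevalence, tab$fisher_p))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
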