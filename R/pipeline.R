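# End-to-end analysis: flexibility comparison of two ensembles,
# representative-conformer selection, pocket sizing, and (optionally) the
# screening cascade -- driven by one configuration list or YAML file.
# The JSON report carries no wall-clock metadata, so identical inputs
# give byte-identical output.

#' Validate and normalise a pipeline configuration
#'
#' A configuration is an R list (or a YAML file with the same structure)
#' with components:
#' \describe{
#'   \item{ensembles}{either `list(synthetic = TRUE, params = list(...))`
#'     with [breathing_params()] arguments, or
#'     `list(free = "free.pdb", tethered = "tethered.pdb")` plus an
#'     optional `chains` character vector.}
#'   \item{pairs}{list of four `list(chain_a, resnum_a, chain_b, resnum_b,
#'     label)` entries, or `"synthetic"` to use [synthetic_pairs()];
#'     optional `species` tag (`rat`/`mouse`/`human`) records the
#'     numbering convention the pair residue numbers are stated in.}
#'   \item{distance_mode}{`"sidechain_centroid"` (default), `"ca"` or
#'     `"min_heavy"`.}
#'   \item{threshold}{exceedance threshold in Angstrom, default 1.8.}
#'   \item{bin_width}{SDRP bin width in Angstrom, default 2.}
#'   \item{scores}{optional: path to a score table (or `"synthetic"`) and
#'     `k_final` for the re-ranking stage.}
#'   \item{seed}{integer seed for synthetic generation.}
#' }
#'
#' @param config list or path to a YAML file.
#' @return The validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$ensembles)) stop("config is missing the ensembles block")
  if (is.null(config$pairs)) stop("config is missing the pairs block")
  config$distance_mode <- config$distance_mode %||% "sidechain_centroid"
  config$threshold <- config$threshold %||% 1.8
  config$bin_width <- config$bin_width %||% 2
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.list(config$pairs) && !is.null(config$pairs$species)) {
    config$pairs$species <- match.arg(config$pairs$species,
                                      c("rat", "mouse", "human"))
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_pairs <- function(config) {
  if (identical(config$pairs, "synthetic") ||
      identical(config$pairs$use, "synthetic")) {
    return(synthetic_pairs(config$distance_mode))
  }
  defs <- config$pairs$defs %||% config$pairs
  defs <- defs[vapply(defs, is.list, TRUE)]
  if (length(defs) != 4L) stop("the pairs block must define exactly 4 pairs")
  lapply(defs, function(p) {
    residue_pair(p$chain_a, p$resnum_a, p$chain_b, p$resnum_b,
                 label = p$label %||% NULL,
                 distance_mode = config$distance_mode)
  })
}

#' Run the full site-flexibility and screening pipeline
#'
#' Executes, in order: ensemble acquisition (synthetic generation or
#' multi-model PDB reading), two-ensemble flexibility comparison over the
#' configured pairs, representative-frame selection from the modal SDRP
#' bin, pocket sizing at the representatives, and -- when a score table is
#' configured -- the screening cascade.  Writes `report.json` plus TSV
#' sidecars (per-frame SDRP values and, if run, the cascade audit trail)
#' to `out_dir` when given.
#'
#' @param config see [pipeline_config()].
#' @param out_dir optional output directory (created if needed).
#' @return An object of class `"pipeline_report"` (also serialised as
#'   JSON): a list with sections `flexibility`, `representatives`,
#'   `pocket` and `cascade`.  Numeric fields carry units in their names.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- pipeline_config(config)
  pairs <- .config_pairs(config)

  if (isTRUE(config$ensembles$synthetic)) {
    par_args <- config$ensembles$params %||% list()
    par_args$seed <- par_args$seed %||% config$seed
    params <- do.call(breathing_params, par_args)
    free <- simulate_breathing_ensemble(params, "free")$ensemble
    teth <- simulate_breathing_ensemble(params, "tethered")$ensemble
  } else {
    chains <- config$ensembles$chains %||% NULL
    free <- read_ensemble(config$ensembles$free, chains)
    teth <- read_ensemble(config$ensembles$tethered, chains)
  }

  cmp <- compare_ensembles(free, teth, pairs,
                           threshold = config$threshold,
                           bin_width = config$bin_width)

  report <- list(
    flexibility = list(
      pair_labels = cmp$pair_labels,
      threshold_angstrom = config$threshold,
      exceedance_free_probability = unname(cmp$exceedance_a),
      exceedance_tethered_probability = unname(cmp$exceedance_b),
      delta_probability = unname(cmp$delta),
      verdict_per_pair = ifelse(cmp$verdict == "A", "free",
                                ifelse(cmp$verdict == "B", "tethered",
                                       "tie")),
      overall_more_flexible = switch(cmp$overall_verdict,
                                     A = "free", B = "tethered", "mixed")
    ),
    representatives = list(
      bin_width_angstrom = config$bin_width,
      modal_bin_free_angstrom = cmp$modal_bin_a,
      modal_bin_tethered_angstrom = cmp$modal_bin_b,
      representative_frame_free = cmp$representative_a,
      representative_frame_tethered = cmp$representative_b
    ),
    pocket = list(
      length_pair = cmp$pocket_a$length_pair$label,
      width_pair = cmp$pocket_a$width_pair$label,
      free_length_angstrom = cmp$pocket_a$length,
      free_width_angstrom = cmp$pocket_a$width,
      tethered_length_angstrom = cmp$pocket_b$length,
      tethered_width_angstrom = cmp$pocket_b$width
    ),
    cascade = NULL
  )

  cascade_res <- NULL
  if (!is.null(config$scores)) {
    if (identical(config$scores$table, "synthetic")) {
      sim <- simulate_score_tables(planted_screen(seed = config$seed))
      tab <- sim$table
    } else {
      tab <- load_score_table(config$scores$table)
    }
    cc <- default_cascade_config(config$scores$k_final %||% NULL)
    cascade_res <- run_cascade(tab, cc)
    report$cascade <- list(
      stage_labels = cascade_res$stage_labels,
      survivors_per_stage = vapply(cascade_res$survivors, length, 0L),
      final_survivor_count = length(cascade_res$final),
      final_survivors = cascade_res$final
    )
  }

  class(report) <- "pipeline_report"
  attr(report, "comparison") <- cmp
  attr(report, "cascade_result") <- cascade_res

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_report(report, file.path(out_dir, "report.json"))
    sdrp_tsv <- data.frame(frame = seq_along(cmp$profile_a$sdrp_values),
                           sdrp_free_angstrom = cmp$profile_a$sdrp_values,
                           sdrp_tethered_angstrom = cmp$profile_b$sdrp_values)
    utils::write.table(sdrp_tsv, file.path(out_dir, "sdrp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cascade_res)) {
      utils::write.table(cascade_res$audit,
                         file.path(out_dir, "cascade_audit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' Serialise a pipeline report as deterministic JSON
#'
#' @param report a [run_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  payload <- unclass(report)
  attributes(payload) <- list(names = names(payload))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat("  overall more flexible:", x$flexibility$overall_more_flexible, "\n")
  cat(sprintf("  modal SDRP bins: free [%g, %g) A, tethered [%g, %g) A\n",
              x$representatives$modal_bin_free_angstrom[1],
              x$representatives$modal_bin_free_angstrom[2],
              x$representatives$modal_bin_tethered_angstrom[1],
              x$representatives$modal_bin_tethered_angstrom[2]))
  if (!is.null(x$cascade)) {
    cat("  cascade final survivors:", x$cascade$final_survivor_count, "\n")
  }
  invisible(x)
}

#' Check a pipeline report against the shipped schema
#'
#' Verifies that the report (or a JSON file written by
#' [write_pipeline_report()]) contains every section and field named in
#' the schema shipped at `inst/extdata/report-schema.json`.
#'
#' @param report a `pipeline_report` object or a path to a report JSON.
#' @return `TRUE` invisibly; errors describe the first missing field.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema_path <- system.file("extdata", "report-schema.json",
                             package = "pocketflex")
  schema <- jsonlite::read_json(schema_path)
  for (section in names(schema$sections)) {
    if (!(section %in% names(report))) {
      stop("report is missing section '", section, "'")
    }
    if (is.null(report[[section]])) next  # cascade is optional
    for (field in unlist(schema$sections[[section]])) {
      if (!(field %in% names(report[[section]]))) {
        stop("report section '", section, "' is missing field '",
             field, "'")
      }
    }
  }
  invisible(TRUE)
}
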