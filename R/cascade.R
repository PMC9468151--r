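# Engine-agnostic virtual-screening triage cascade over docking-score
# tables.  Scores follow the docking convention: lower = stronger binding,
# and every cutoff is a strict "<".  Each stage records an audit entry for
# every compound it removes, so the funnel is fully reconstructable.

#' Validate a docking score table
#'
#' @param df data.frame with columns `compound_id`, `target_id`,
#'   `scorer_id`, `score` and optionally `stage_tag`.
#' @param provenance source path or `"synthetic"`.
#' @return The validated data.frame with class `"ScoreTable"` prepended.
#' @export
score_table <- function(df, provenance = "synthetic") {
  req <- c("compound_id", "target_id", "scorer_id", "score")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("score table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!("stage_tag" %in% names(df))) df$stage_tag <- NA_character_
  if (!is.numeric(df$score) || any(!is.finite(df$score))) {
    bad <- which(!is.numeric(df$score) | !is.finite(df$score))[1]
    stop("non-finite or non-numeric score at row ", bad)
  }
  key <- paste(df$compound_id, df$target_id, df$scorer_id, df$stage_tag,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate (compound, target, scorer, stage_tag) key at row ",
         dup[1], ": ", df$compound_id[dup[1]], "/", df$target_id[dup[1]],
         "/", df$scorer_id[dup[1]])
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("ScoreTable", "data.frame")
  df
}

#' Load a docking score table from CSV or TSV
#'
#' Expects a header row with columns `compound_id`, `target_id`,
#' `scorer_id`, `score` and optionally `stage_tag`.  The delimiter is
#' taken from the file extension (`.tsv` = tab, otherwise comma).
#'
#' @param path file path.
#' @return A [score_table()].
#' @export
load_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = NA, stringsAsFactors = FALSE)
  if ("score" %in% names(df)) {
    suppressWarnings(df$score <- as.numeric(df$score))
  }
  score_table(df, provenance = path)
}

# ---- stage constructors ------------------------------------------------

#' Screening-cascade stage constructors
#'
#' Three stage types compose a triage cascade:
#' * `stage_differential_binder()` keeps a compound iff its score against
#'   the positive target is strictly below `cutoff` while its score against
#'   the negative target is not (the "only docked with the soluble form"
#'   selection).  A missing score on the positive target fails the stage;
#'   a missing score on the negative target counts as not binding.
#' * `stage_threshold()` keeps compounds scoring strictly below `cutoff`
#'   against one target.
#' * `stage_rank_top()` keeps the `k` best (lowest) scores, ties broken by
#'   compound id; used to represent induced-fit re-ranking.
#'
#' @param scorer scorer identifier present in the score table.
#' @param positive,negative,target target identifiers.
#' @param cutoff strict upper bound on the score.
#' @param k number of compounds retained.
#' @param label optional stage label for the audit trail.
#' @return A stage object for [cascade_config()].
#' @name cascade_stages
NULL

#' @rdname cascade_stages
#' @export
stage_differential_binder <- function(scorer, positive, negative, cutoff,
                                      label = NULL) {
  if (is.null(label)) {
    label <- sprintf("differential(%s: %s<%g, not %s)", scorer, positive,
                     cutoff, negative)
  }
  structure(list(type = "differential_binder", scorer = scorer,
                 positive = positive, negative = negative,
                 cutoff = cutoff, label = label),
            class = "CascadeStage")
}

#' @rdname cascade_stages
#' @export
stage_threshold <- function(scorer, target, cutoff, label = NULL) {
  if (is.null(label)) {
    label <- sprintf("threshold(%s: %s<%g)", scorer, target, cutoff)
  }
  structure(list(type = "threshold", scorer = scorer, target = target,
                 cutoff = cutoff, label = label),
            class = "CascadeStage")
}

#' @rdname cascade_stages
#' @export
stage_rank_top <- function(scorer, target, k, label = NULL) {
  if (is.null(label)) {
    label <- sprintf("rank_top(%s: %s, k=%d)", scorer, target, as.integer(k))
  }
  structure(list(type = "rank_top", scorer = scorer, target = target,
                 k = as.integer(k), label = label),
            class = "CascadeStage")
}

#' Assemble an ordered cascade configuration
#'
#' @param ... stage objects from [cascade_stages], applied in order.
#' @return An object of class `"CascadeConfig"`.
#' @export
cascade_config <- function(...) {
  stages <- list(...)
  if (length(stages) == 0L) stop("a cascade needs at least one stage")
  if (!all(vapply(stages, inherits, TRUE, "CascadeStage"))) {
    stop("all arguments must be cascade stages")
  }
  structure(list(stages = stages), class = "CascadeConfig")
}

# score lookup: named numeric vector compound_id -> score, NA if absent
.score_lookup <- function(table, scorer, target) {
  if (!(scorer %in% table$scorer_id)) {
    stop("unknown scorer id '", scorer, "' in cascade config")
  }
  if (!(target %in% table$target_id)) {
    stop("unknown target id '", target, "' in cascade config")
  }
  sub <- table[table$scorer_id == scorer & table$target_id == target, ]
  stats::setNames(sub$score, sub$compound_id)
}

#' Apply a single cascade stage
#'
#' @param survivors character vector of compound ids entering the stage.
#' @param stage a stage object from [cascade_stages].
#' @param table a [score_table()].
#' @return A list with `survivors` (character vector) and `audit`
#'   (data.frame of removed compounds with the removal reason and the
#'   relevant scores).
#' @export
apply_stage <- function(survivors, stage, table) {
  stopifnot(inherits(stage, "CascadeStage"), inherits(table, "ScoreTable"))
  empty_audit <- data.frame(compound_id = character(0),
                            reason = character(0),
                            score_1 = numeric(0), score_2 = numeric(0),
                            stringsAsFactors = FALSE)
  if (length(survivors) == 0L) {
    return(list(survivors = character(0), audit = empty_audit))
  }
  if (stage$type == "differential_binder") {
    pos <- .score_lookup(table, stage$scorer, stage$positive)
    neg <- .score_lookup(table, stage$scorer, stage$negative)
    sp <- unname(pos[survivors]); sn <- unname(neg[survivors])
    pos_ok <- !is.na(sp) & sp < stage$cutoff
    neg_binds <- !is.na(sn) & sn < stage$cutoff   # missing = did not bind
    keep <- pos_ok & !neg_binds
    reason <- ifelse(is.na(sp), "no-score",
              ifelse(!pos_ok, "positive-target score above cutoff",
                     "also binds negative target"))
    audit <- data.frame(compound_id = survivors[!keep],
                        reason = reason[!keep],
                        score_1 = unname(sp[!keep]),
                        score_2 = unname(sn[!keep]),
                        stringsAsFactors = FALSE)
  } else if (stage$type == "threshold") {
    sc <- unname(.score_lookup(table, stage$scorer, stage$target)[survivors])
    keep <- !is.na(sc) & sc < stage$cutoff
    reason <- ifelse(is.na(sc), "no-score", "score above cutoff")
    audit <- data.frame(compound_id = survivors[!keep],
                        reason = reason[!keep],
                        score_1 = unname(sc[!keep]),
                        score_2 = rep(NA_real_, sum(!keep)),
                        stringsAsFactors = FALSE)
  } else if (stage$type == "rank_top") {
    sc <- unname(.score_lookup(table, stage$scorer, stage$target)[survivors])
    has <- !is.na(sc)
    ranked <- survivors[has][order(sc[has], survivors[has])]
    kept <- ranked[seq_len(min(stage$k, length(ranked)))]
    keep <- survivors %in% kept
    reason <- ifelse(is.na(sc), "no-score", "rank beyond k")
    audit <- data.frame(compound_id = survivors[!keep],
                        reason = reason[!keep],
                        score_1 = unname(sc[!keep]),
                        score_2 = rep(NA_real_, sum(!keep)),
                        stringsAsFactors = FALSE)
  } else {
    stop("unknown stage type: ", stage$type)
  }
  rownames(audit) <- NULL
  list(survivors = survivors[keep], audit = audit)
}

#' Run a screening cascade
#'
#' Applies the configured stages in order to a compound universe, keeping a
#' full audit trail: every input compound appears exactly once in the
#' terminal disposition, either removed at a named stage with a reason or
#' retained to the end.
#'
#' @param table a [score_table()] (bind multiple tables with `rbind`
#'   before calling).
#' @param config a [cascade_config()].
#' @param universe compound ids entering the funnel; defaults to all
#'   compound ids present in the table, sorted.
#' @return An object of class `"CascadeResult"` with `stage_labels`,
#'   `survivors` (list of per-stage survivor vectors), `final`, and
#'   `audit` (data.frame with one terminal row per input compound).
#' @export
run_cascade <- function(table, config, universe = NULL) {
  stopifnot(inherits(config, "CascadeConfig"), inherits(table, "ScoreTable"))
  if (is.null(universe)) universe <- sort(unique(table$compound_id))
  survivors <- universe
  per_stage <- list()
  audit_all <- list()
  for (i in seq_along(config$stages)) {
    stage <- config$stages[[i]]
    res <- apply_stage(survivors, stage, table)
    if (nrow(res$audit) > 0L) {
      res$audit$stage_index <- i
      res$audit$stage_label <- stage$label
      audit_all[[length(audit_all) + 1L]] <- res$audit
    }
    survivors <- res$survivors
    per_stage[[i]] <- survivors
  }
  removed <- if (length(audit_all) > 0L) {
    do.call(rbind, audit_all)
  } else {
    data.frame(compound_id = character(0), reason = character(0),
               score_1 = numeric(0), score_2 = numeric(0),
               stage_index = integer(0), stage_label = character(0),
               stringsAsFactors = FALSE)
  }
  n_ret <- length(survivors)
  retained <- data.frame(compound_id = survivors,
                         reason = rep("retained", n_ret),
                         score_1 = rep(NA_real_, n_ret),
                         score_2 = rep(NA_real_, n_ret),
                         stage_index = rep(NA_integer_, n_ret),
                         stage_label = rep("final", n_ret),
                         stringsAsFactors = FALSE)
  audit <- rbind(removed, retained)
  audit <- audit[order(audit$compound_id), ]
  rownames(audit) <- NULL
  structure(
    list(universe = universe,
         stage_labels = vapply(config$stages, `[[`, "", "label"),
         survivors = per_stage, final = survivors, audit = audit),
    class = "CascadeResult"
  )
}

#' @export
print.CascadeResult <- function(x, ...) {
  cat("Screening cascade:", length(x$universe), "compounds in\n")
  for (i in seq_along(x$stage_labels)) {
    cat(sprintf("  stage %d %-45s -> %d survivors\n", i,
                x$stage_labels[i], length(x$survivors[[i]])))
  }
  cat("final survivors:", length(x$final), "\n")
  invisible(x)
}

#' @export
summary.CascadeResult <- function(object, ...) {
  tab <- table(object$audit$stage_label)
  cat("Terminal dispositions:\n")
  print(tab)
  invisible(object)
}
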