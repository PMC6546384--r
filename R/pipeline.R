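#' Run the full homoplasy-quantification pipeline
#'
#' Orchestrates every stage on one character matrix and one (or more)
#' rooted trees, under both the ACCTRAN and DELTRAN resolutions: parsimony
#' reconstruction, per-character and ensemble indices (averaged over trees
#' when several are given), state categorization, pairwise mechanism
#' classification, reversal counting and their correlation, the
#' taxon-permutation null of the ensemble HI, and — when stage metadata are
#' present — the stage/organ tests and the hourglass regression.
#'
#' @param cm a [character_matrix()]
#' @param trees a rooted `phylo` or list of them; the first is the consensus
#'   used for reconstruction-based stages, the full list for averaging
#' @param n_perm permutations for the HI null (0 skips it)
#' @param seed integer seed for the permutation stage
#' @param mode pairing mode passed to [mechanism_proportions()]
#' @param out_dir optional directory; when given, every result table is
#'   written as TSV plus a single JSON summary
#' @return object of class `homoplasy_report`: nested list of all stage
#'   results (`indices`, `categories`, `mechanisms`, `reversals`,
#'   `correlations`, `null`, `stage_tests`, `hourglass`) keyed by model
#'   where applicable
#' @export
run_pipeline <- function(cm, trees, n_perm = 1000, seed = NULL,
                         mode = c("pooled", "per_char_mean"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, match_tree_matrix, cm = cm)
  consensus <- trees[[1]]
  models <- c("ACCTRAN", "DELTRAN")
  res <- list(models = list())
  for (model in models) {
    rec <- reconstruct_parsimony(cm, consensus, model = model)
    stats <- character_stats(rec)
    ens <- ensemble_indices(stats)
    avg <- if (length(trees) > 1) average_over_trees(cm, trees, model) else NULL
    cats <- categorize_states(rec)
    catsum <- category_summary(cats)
    recs <- derivation_records(rec)
    mech <- mechanism_proportions(recs, mode = mode)
    rev <- count_reversals(rec)
    corr <- tryCatch(
      reversal_mechanism_correlation(rev, mech$per_character),
      error = function(e) NULL)
    res$models[[model]] <- list(
      reconstruction = rec, character_stats = stats, ensemble = ens,
      tree_average = avg, categories = cats, category_summary = catsum,
      derivation_records = recs, mechanisms = mech, reversals = rev,
      correlations = corr
    )
  }
  if (n_perm > 0) {
    res$null <- permutation_null(cm, consensus, n_perm = n_perm, seed = seed)
  }
  if (!all(is.na(cm$char_meta$stage))) {
    base <- res$models$ACCTRAN$character_stats
    series <- stage_series(base, cm$char_meta)
    res$stage_tests <- tryCatch(stage_organ_tests(series),
                                error = function(e) NULL)
    res$hourglass <- tryCatch(hourglass_regression(series),
                              error = function(e) NULL)
  }
  res$n_taxa <- length(cm$taxa)
  res$n_char <- ncol(cm$states)
  res$total_states <- sum(state_counts(cm)$n_states)
  class(res) <- "homoplasy_report"
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' @export
print.homoplasy_report <- function(x, ...) {
  cat("<homoplasy_report> ", x$n_taxa, " taxa, ", x$n_char, " characters, ",
      x$total_states, " states\n", sep = "")
  for (model in names(x$models)) {
    m <- x$models[[model]]
    cat(sprintf("  %s: CI = %.3f  HI = %.3f  RI = %.3f\n", model,
                m$ensemble$CI, m$ensemble$HI, m$ensemble$RI))
  }
  if (!is.null(x$null)) {
    cat(sprintf("  HI null mean = %.3f over %d permutations\n",
                x$null$null_mean, x$null$n_perm))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One TSV per result table per model, plus `summary.json` holding the
#' headline numbers (ensemble indices, category totals, mechanism
#' proportions, reversal stats, test results).
#'
#' @param report a [run_pipeline()] result
#' @param out_dir output directory (created if absent)
#' @return `out_dir`, invisibly
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(n_taxa = report$n_taxa, n_char = report$n_char,
                  total_states = report$total_states)
  for (model in names(report$models)) {
    m <- report$models[[model]]
    pre <- file.path(out_dir, tolower(model))
    write_table(m$character_stats, paste0(pre, "_character_stats.tsv"))
    write_table(change_list(m$reconstruction), paste0(pre, "_changes.tsv"))
    write_table(m$categories, paste0(pre, "_state_categories.tsv"))
    write_table(m$mechanisms$proportions, paste0(pre, "_mechanisms.tsv"))
    write_table(m$reversals, paste0(pre, "_reversals.tsv"))
    summary[[model]] <- list(
      ensemble = as.list(m$ensemble),
      categories = as.list(m$category_summary$totals),
      mechanisms = setNames(as.list(m$mechanisms$proportions$proportion),
                            as.character(m$mechanisms$proportions$mechanism)),
      homoplasy_share_similar = m$mechanisms$homoplasy_share_similar,
      reversal_mean_fraction = mean(m$reversals$fraction, na.rm = TRUE),
      reversal_free_characters = sum(!m$reversals$any_reversal),
      correlations = if (!is.null(m$correlations))
        setNames(as.list(m$correlations$r_squared),
                 m$correlations$mechanism)
    )
  }
  if (!is.null(report$null)) {
    summary$permutation_null <- as.list(glance(report$null))
  }
  if (!is.null(report$stage_tests)) {
    write_table(report$stage_tests, file.path(out_dir, "stage_tests.tsv"))
    summary$stage_tests <- lapply(split(report$stage_tests,
                                        report$stage_tests$test), as.list)
  }
  if (!is.null(report$hourglass)) {
    summary$hourglass <- as.list(glance(report$hourglass))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
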