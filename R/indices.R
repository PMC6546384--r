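#' Per-character homoplasy indices
#'
#' From a reconstruction, computes for every character the step counts m
#' (minimum conceivable), s (observed on the tree) and g (star-tree maximum)
#' and the classical cladistic indices: consistency ci = m/s, homoplasy
#' hi = 1 - ci, retention ri = (g - s)/(g - m) and rescaled rc = ci * ri.
#' ci is undefined (NA, `invariant` flag) when s = 0 and ri is undefined when
#' g = m. `r_ic` is the retention index under the convention that characters
#' whose derived states all occur in a single terminal taxon (autapomorphic-
#' only characters, for which ri is undefined) are assigned the value 1;
#' invariant characters stay NA.
#'
#' @param rec a [reconstruct_parsimony()] result
#' @return tibble with `char_id`, `m`, `s`, `g`, `ci`, `hi`, `ri`, `rc`,
#'   `r_ic` and logical flags `invariant`, `autapomorphic_only`,
#'   `uninformative`
#' @export
character_stats <- function(rec) {
  stopifnot(inherits(rec, "parsimony_reconstruction"))
  st <- rec$steps
  root_state <- rec$node_states[rec$index$root, ]
  S <- rec$tip_states
  aut_only <- vapply(seq_len(ncol(S)), function(j) {
    obs <- S[, j][!is.na(S[, j])]
    tab <- table(obs)
    derived <- setdiff(as.integer(names(tab)), root_state[j])
    length(derived) > 0L && all(tab[as.character(derived)] == 1L)
  }, logical(1))
  ci <- ifelse(st$s > 0, st$m / st$s, NA_real_)
  ri <- ifelse(st$g > st$m, (st$g - st$s) / (st$g - st$m), NA_real_)
  tibble::tibble(
    char_id = st$char_id, m = st$m, s = st$s, g = st$g,
    ci = ci, hi = 1 - ci, ri = ri, rc = ci * ri,
    r_ic = ifelse(!is.na(ri), ri, ifelse(aut_only, 1, NA_real_)),
    invariant = st$s == 0L & st$m == 0L,
    autapomorphic_only = aut_only,
    uninformative = st$g == st$m
  )
}

#' Ensemble consistency, homoplasy and retention indices
#'
#' Ensemble indices sum step counts over characters before forming ratios:
#' CI = sum(m)/sum(s), RI = (sum(g) - sum(s))/(sum(g) - sum(m)) and
#' HI = 1 - CI. Invariant characters contribute zero to every sum and so drop
#' out of CI.
#'
#' @param stats a [character_stats()] tibble (or any tibble with `m`, `s`,
#'   `g` columns)
#' @return one-row tibble with `CI`, `HI`, `RI`, `n_char`, `sum_m`, `sum_s`,
#'   `sum_g`
#' @export
ensemble_indices <- function(stats) {
  sm <- sum(stats$m)
  ss <- sum(stats$s)
  sg <- sum(stats$g)
  if (ss == 0) stop("no observed steps: every character is invariant")
  tibble::tibble(
    CI = sm / ss, HI = 1 - sm / ss,
    RI = if (sg > sm) (sg - ss) / (sg - sm) else NA_real_,
    n_char = nrow(stats), sum_m = sm, sum_s = ss, sum_g = sg
  )
}

#' Indices averaged over a sample of trees
#'
#' Reconstructs every character on each tree, computes per-tree ensemble
#' indices and per-character indices, and averages: the ensemble mean and SD
#' across trees quantify topological uncertainty, while the per-character
#' averages (mean ci, ri, r_ic per character over trees) are the values used
#' for stage/organ comparisons.
#'
#' @param cm a [character_matrix()]
#' @param trees list of rooted `phylo` objects over the same taxa
#' @param model `"ACCTRAN"` or `"DELTRAN"`
#' @return object of class `tree_averaged_indices`: list with `per_tree`
#'   (tibble of CI/HI/RI per tree), `summary` (one-row tibble of means and
#'   SDs) and `per_character` (tibble of per-character means)
#' @export
average_over_trees <- function(cm, trees, model = c("ACCTRAN", "DELTRAN")) {
  model <- match.arg(model)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  per_char <- vector("list", length(trees))
  per_tree <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    rec <- reconstruct_parsimony(cm, trees[[i]], model = model)
    stats <- character_stats(rec)
    per_char[[i]] <- dplyr::mutate(stats, tree = i)
    per_tree[[i]] <- dplyr::mutate(ensemble_indices(stats), tree = i)
  }
  per_tree <- dplyr::bind_rows(per_tree)
  all_stats <- dplyr::bind_rows(per_char)
  per_character <- all_stats |>
    dplyr::group_by(.data$char_id) |>
    dplyr::summarise(
      ci = mean(.data$ci), hi = mean(.data$hi),
      ri = mean(.data$ri), rc = mean(.data$rc), r_ic = mean(.data$r_ic),
      s = mean(.data$s), m = mean(.data$m), g = mean(.data$g),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$char_id, per_char[[1]]$char_id))
  summary <- tibble::tibble(
    model = model, n_trees = length(trees),
    CI_mean = mean(per_tree$CI), CI_sd = sd(per_tree$CI),
    HI_mean = mean(per_tree$HI), HI_sd = sd(per_tree$HI),
    RI_mean = mean(per_tree$RI), RI_sd = sd(per_tree$RI)
  )
  structure(list(per_tree = per_tree, summary = summary,
                 per_character = per_character, model = model),
            class = "tree_averaged_indices")
}

#' @export
print.tree_averaged_indices <- function(x, ...) {
  cat("<tree_averaged_indices> ", x$model, " over ", x$summary$n_trees,
      " tree(s)\n", sep = "")
  cat(sprintf("  CI = %.4f (sd %.2e)  HI = %.4f  RI = %.4f\n",
              x$summary$CI_mean, x$summary$CI_sd, x$summary$HI_mean,
              x$summary$RI_mean))
  invisible(x)
}

#' Taxon-permutation null distribution of the ensemble homoplasy index
#'
#' Destroys phylogenetic signal by randomly permuting the assignment of
#' matrix rows (taxa) to tree tips, recomputing the ensemble HI on the fixed
#' topology for each replicate. m and g do not depend on the tree, so only
#' the tree length changes. Data with phylogenetic structure give an observed
#' HI below the null distribution.
#'
#' @param cm a [character_matrix()]
#' @param phy rooted `phylo`
#' @param n_perm number of random permutations (>= 1)
#' @param seed optional integer seed for reproducibility
#' @return object of class `permutation_null`: list with `observed` (HI),
#'   `null` (numeric vector of permuted HI values), `null_mean`, `null_sd`,
#'   `p_value` (proportion of replicates with HI <= observed, with the +1
#'   continuity correction) and `n_perm`
#' @export
permutation_null <- function(cm, phy, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(cm, "character_matrix"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  ti <- tree_index(phy)
  S <- .states_for_tips(ti, cm)
  engine <- .hartigan_engine(ti, S)
  m <- min_steps(cm)$m
  sum_m <- sum(m)
  obs_hi <- 1 - sum_m / sum(engine())
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      1 - sum_m / sum(engine(sample.int(ti$n_tip)))
    }, numeric(1))
  })
  structure(list(observed = obs_hi, null = null,
                 null_mean = mean(null), null_sd = sd(null),
                 p_value = (sum(null <= obs_hi) + 1) / (n_perm + 1),
                 n_perm = n_perm),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> observed HI = ", round(x$observed, 4),
      ", null mean = ", round(x$null_mean, 4),
      " (sd ", signif(x$null_sd, 3), ", ", x$n_perm, " permutations)\n",
      "  P(null <= observed) = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}
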