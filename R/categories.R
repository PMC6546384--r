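#' Categorize character states from a reconstruction
#'
#' Every observed state of every character is either the root (ancestral)
#' state or a derived state, and is classified by how often it was derived on
#' the tree and how many terminal taxa show it:
#' \itemize{
#'   \item `nonhomoplastic_root`: root state, never re-derived elsewhere;
#'   \item `homoplastic_root`: root state that is also secondarily derived
#'     at least once;
#'   \item `homoplastic_derived`: non-root state derived two or more times;
#'   \item `synapomorphic`: derived exactly once, shared by >= 2 taxa;
#'   \item `autapomorphic`: derived exactly once, present in exactly 1 taxon;
#'   \item `transient_apomorphic`: derived once but present at no terminal
#'     taxon (an internal-branch state, possible when changes stack on a
#'     path); reported separately so the synapomorphy/autapomorphy tallies
#'     stay comparable.
#' }
#' Tip counts use observed (non-missing) terminal states only.
#'
#' @param rec a [reconstruct_parsimony()] result
#' @return tibble (class amended for plotting) with `char_id`, `state`,
#'   `at_root`, `n_derivations`, `n_tips`, `category`, `model`
#' @export
categorize_states <- function(rec) {
  stopifnot(inherits(rec, "parsimony_reconstruction"))
  chars <- rec$char_meta$char_id
  root_state <- rec$node_states[rec$index$root, ]
  S <- rec$tip_states
  ch <- rec$changes
  out <- vector("list", length(chars))
  for (j in seq_along(chars)) {
    col <- S[, j]
    tab <- tabulate(col[!is.na(col)] + 1L, nbins = 9L)
    to <- ch$to[ch$char_id == chars[j]]
    states <- sort(unique(c(root_state[j], to)))
    n_der <- vapply(states, function(x) sum(to == x), integer(1))
    n_tip <- tab[states + 1L]
    at_root <- states == root_state[j]
    category <- ifelse(
      at_root,
      ifelse(n_der == 0L, "nonhomoplastic_root", "homoplastic_root"),
      ifelse(n_der >= 2L, "homoplastic_derived",
             ifelse(n_tip >= 2L, "synapomorphic",
                    ifelse(n_tip == 1L, "autapomorphic",
                           "transient_apomorphic")))
    )
    out[[j]] <- tibble::tibble(char_id = chars[j], state = states,
                               at_root = at_root,
                               n_derivations = n_der, n_tips = n_tip,
                               category = category)
  }
  res <- dplyr::bind_rows(out)
  res$category <- factor(res$category, levels = CATEGORY_LEVELS)
  res$model <- rec$model
  class(res) <- c("state_category_table", class(res))
  res
}

#' Summarise state categories
#'
#' Counts and fractions per category, split into ancestral (root) and derived
#' states, with headline totals: total states, derived states, once-derived
#' states, and the synapomorphic share among them.
#'
#' @param categories a [categorize_states()] table
#' @return list with `by_category` (tibble: category, n, fraction, ancestral)
#'   and `totals` (one-row tibble)
#' @export
category_summary <- function(categories) {
  if (!nrow(categories)) stop("empty category table")
  by_cat <- categories |>
    dplyr::count(.data$category, .drop = FALSE, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n),
                  ancestral = .data$category %in%
                    c("nonhomoplastic_root", "homoplastic_root"))
  n_derived <- sum(!categories$at_root)
  once <- categories$n_derivations == 1L & !categories$at_root
  totals <- tibble::tibble(
    model = categories$model[1],
    n_states = nrow(categories),
    n_root = sum(categories$at_root),
    n_root_homoplastic = sum(categories$category == "homoplastic_root"),
    n_derived = n_derived,
    n_derived_once = sum(once),
    n_synapomorphic = sum(categories$category == "synapomorphic"),
    n_autapomorphic = sum(categories$category == "autapomorphic"),
    n_transient = sum(categories$category == "transient_apomorphic"),
    synapomorphic_share_of_once =
      if (sum(once)) sum(categories$category == "synapomorphic") / sum(once)
      else NA_real_
  )
  list(by_category = by_cat, totals = totals)
}
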