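#' Per-taxon derivation records
#'
#' For every (taxon, character) with an observed state, walks the root-to-tip
#' path of reconstructed states and records: the current state at the tip,
#' the original state (the state immediately preceding the most recent change
#' on the path; the root state if the lineage never changed), the node at
#' which that change occurred (`change_node`, the child node of the change
#' edge; the root if none), the node the change departed from
#' (`depart_node`, the parent of the change edge; the root if none), and the
#' node at which the original state itself most recently arose
#' (`origin_of_original`, recursively; the root if it was never derived).
#' These fields are all the pairwise mechanism classification needs.
#'
#' @param rec a [reconstruct_parsimony()] result
#' @return tibble with `taxon`, `char_id`, `current`, `original`,
#'   `change_node`, `depart_node`, `origin_of_original`
#' @export
derivation_records <- function(rec) {
  stopifnot(inherits(rec, "parsimony_reconstruction"))
  ti <- rec$index
  chars <- rec$char_meta$char_id
  S <- rec$tip_states
  NS <- rec$node_states
  root <- ti$root
  cap <- ti$n_tip * length(chars)
  out_tip <- integer(cap); out_char <- integer(cap)
  cur <- integer(cap); orig <- integer(cap)
  chn <- integer(cap); dep <- integer(cap); oon <- integer(cap)
  k_out <- 0L
  for (j in seq_along(chars)) {
    ns <- NS[, j]
    for (i in seq_len(ti$n_tip)) {
      if (is.na(S[i, j])) next
      path <- ti$paths[[i]]
      sp <- ns[path]
      L <- length(sp)
      d <- which(sp[-1] != sp[-L])      # positions k where edge k->k+1 changes
      if (length(d)) {
        k <- d[length(d)]               # most recent change
        o <- sp[k]
        change_node <- path[k + 1L]
        depart_node <- path[k]
        # walk back through the run of `o` ending at position k
        r <- k
        while (r > 1L && sp[r - 1L] == o) r <- r - 1L
        origin <- if (r == 1L) root else path[r]
      } else {
        o <- sp[1L]
        change_node <- root
        depart_node <- root
        origin <- root
      }
      k_out <- k_out + 1L
      out_tip[k_out] <- i; out_char[k_out] <- j
      cur[k_out] <- sp[L]; orig[k_out] <- o
      chn[k_out] <- change_node; dep[k_out] <- depart_node
      oon[k_out] <- origin
    }
  }
  keep <- seq_len(k_out)
  tibble::tibble(taxon = ti$tip_label[out_tip[keep]],
                 char_id = chars[out_char[keep]],
                 current = cur[keep], original = orig[keep],
                 change_node = chn[keep], depart_node = dep[keep],
                 changed = chn[keep] != root,
                 origin_of_original = oon[keep])
}

# Vectorised six-way classification given record fields of two taxa.
# Divergence requires both lineages to have moved away from the same state,
# departing from the same ancestral node (sister edges leaving one point of
# the morphospace at their MRCA); equal-original pairs that do not meet that
# bar are disparity 1.
.classify_vec <- function(curA, origA, chnA, depA, chgA,
                          curB, origB, chnB, depB, chgB) {
  same_cur <- curA == curB
  same_chn <- chnA == chnB
  same_orig <- origA == origB
  same_dep <- depA == depB
  ifelse(same_cur,
         ifelse(same_chn, "inertia",
                ifelse(same_orig, "parallelism", "convergence")),
         ifelse(same_orig,
                ifelse(same_dep & chgA & chgB, "divergence", "disparity1"),
                "disparity2"))
}

#' Classify the evolutionary mechanism for one pair of taxa
#'
#' Compares the derivation records of two taxa for the same character in
#' morphospace terms. Equal current states: same change node means the state
#' was inherited from the common ancestor (phylogenetic inertia); different
#' change nodes but equal original states is parallelism; different original
#' states is convergence. Different current states: equal original states
#' with both lineages changed and departing from the same ancestral node is
#' divergence (the pair split away from one point of the morphospace at
#' their common ancestor); other equal-original pairs are disparity 1;
#' different original states is disparity 2. The classification is symmetric
#' in its two arguments.
#'
#' @param recA,recB one-row data frames (or lists) with fields `char_id`,
#'   `current`, `original`, `change_node`, `depart_node`, `changed`
#' @return one of `"inertia"`, `"parallelism"`, `"convergence"`,
#'   `"divergence"`, `"disparity1"`, `"disparity2"`
#' @export
classify_pair <- function(recA, recB) {
  if (!identical(as.character(recA$char_id), as.character(recB$char_id))) {
    stop("records belong to different characters")
  }
  .classify_vec(recA$current, recA$original, recA$change_node,
                recA$depart_node, recA$changed,
                recB$current, recB$original, recB$change_node,
                recB$depart_node, recB$changed)
}

#' Mechanism proportions over all taxon pairs
#'
#' Classifies every unordered pair of taxa with observed states, per
#' character, into the six mechanisms and tallies them. `pooled` mode counts
#' all pairs of all characters together (proportions sum to 1 over the whole
#' dataset); `per_char_mean` averages the per-character proportion vectors.
#' Also reports the similarity-conditional homoplasy share
#' (parallelism + convergence) / (inertia + parallelism + convergence): the
#' fraction of between-species similarities that are homoplastic rather than
#' inherited.
#'
#' @param records a [derivation_records()] tibble
#' @param mode `"pooled"` or `"per_char_mean"`
#' @return list with `proportions` (tibble: mechanism, n, proportion),
#'   `per_character` (tibble of per-character counts and proportions),
#'   `n_pairs`, `homoplasy_share_similar`, `mode`
#' @export
mechanism_proportions <- function(records, mode = c("pooled", "per_char_mean")) {
  mode <- match.arg(mode)
  per_char <- records |>
    dplyr::group_by(.data$char_id) |>
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      if (n < 2) return(NULL)
      pr <- utils::combn(n, 2)
      a <- pr[1, ]; b <- pr[2, ]
      mech <- .classify_vec(df$current[a], df$original[a], df$change_node[a],
                            df$depart_node[a], df$changed[a],
                            df$current[b], df$original[b], df$change_node[b],
                            df$depart_node[b], df$changed[b])
      cnt <- table(factor(mech, levels = MECHANISM_LEVELS))
      tibble::tibble(char_id = key$char_id,
                     mechanism = MECHANISM_LEVELS,
                     n = as.integer(cnt),
                     n_pairs = ncol(pr))
    }) |>
    dplyr::bind_rows()
  if (!nrow(per_char)) stop("no valid taxon pairs")
  per_char <- dplyr::mutate(per_char, proportion = .data$n / .data$n_pairs)
  if (mode == "pooled") {
    props <- per_char |>
      dplyr::group_by(.data$mechanism) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      dplyr::mutate(proportion = .data$n / sum(.data$n))
  } else {
    props <- per_char |>
      dplyr::group_by(.data$mechanism) |>
      dplyr::summarise(n = sum(.data$n),
                       proportion = mean(.data$proportion), .groups = "drop")
  }
  props$mechanism <- factor(props$mechanism, levels = MECHANISM_LEVELS)
  props <- dplyr::arrange(props, .data$mechanism)
  sim <- props$proportion[props$mechanism %in%
                            c("inertia", "parallelism", "convergence")]
  hom <- props$proportion[props$mechanism %in% c("parallelism", "convergence")]
  list(proportions = props,
       per_character = per_char,
       n_pairs = sum(props$n),
       homoplasy_share_similar = sum(hom) / sum(sim),
       mode = mode)
}

#' Reversal incidences per character
#'
#' A reversal incidence is a (taxon, ancestor) comparison in which the
#' ancestor has the same reconstructed state as the taxon's current state but
#' some node strictly between them differs (e.g. 0 -> 1 -> 0 along the
#' lineage). For each character the fraction of incidences over all
#' (taxon, ancestor) comparisons is reported, together with a flag for
#' characters free of reversals; taxa with missing observations are skipped.
#'
#' @param rec a [reconstruct_parsimony()] result
#' @return tibble with `char_id`, `n_incidences`, `n_comparisons`,
#'   `fraction`, `any_reversal`
#' @export
count_reversals <- function(rec) {
  stopifnot(inherits(rec, "parsimony_reconstruction"))
  ti <- rec$index
  chars <- rec$char_meta$char_id
  S <- rec$tip_states
  NS <- rec$node_states
  inc <- integer(length(chars))
  cmp <- integer(length(chars))
  for (j in seq_along(chars)) {
    ns <- NS[, j]
    n_inc <- 0L; n_cmp <- 0L
    for (i in seq_len(ti$n_tip)) {
      if (is.na(S[i, j])) next
      path <- ti$paths[[i]]
      L <- length(path)
      sp <- ns[path]
      tipstate <- sp[L]
      anc <- sp[-L]                     # ancestors, root first
      n_cmp <- n_cmp + (L - 1L)
      if (L > 2L) {
        differs <- anc != tipstate
        # does any node strictly between ancestor i and the tip differ?
        between <- rev(cumsum(rev(c(differs[-1], FALSE))) > 0)
        n_inc <- n_inc + sum(!differs & between)
      }
    }
    inc[j] <- n_inc
    cmp[j] <- n_cmp
  }
  tibble::tibble(char_id = chars, n_incidences = inc, n_comparisons = cmp,
                 fraction = ifelse(cmp > 0, inc / cmp, NA_real_),
                 any_reversal = inc > 0L)
}

#' Correlation between reversal frequency and homoplastic mechanisms
#'
#' Ordinary least-squares R-squared of the per-character convergence and
#' parallelism proportions regressed on the per-character reversal fraction.
#'
#' @param reversals a [count_reversals()] tibble
#' @param per_char_mechanisms the `per_character` element of
#'   [mechanism_proportions()]
#' @return tibble with `mechanism`, `r_squared`, `slope`, `n`
#' @export
reversal_mechanism_correlation <- function(reversals, per_char_mechanisms) {
  wide <- per_char_mechanisms |>
    dplyr::select("char_id", "mechanism", "proportion") |>
    tidyr::pivot_wider(names_from = "mechanism", values_from = "proportion") |>
    dplyr::inner_join(dplyr::select(reversals, "char_id", "fraction"),
                      by = "char_id")
  if (nrow(wide) < 3) stop("need >= 3 characters with defined values")
  if (sd(wide$fraction) == 0) stop("reversal fraction has zero variance")
  fit_one <- function(y) {
    fit <- lm(y ~ fraction, data = wide)
    tibble::tibble(r_squared = summary(fit)$r.squared,
                   slope = coef(fit)[[2]], n = nrow(wide))
  }
  dplyr::bind_rows(
    dplyr::mutate(fit_one(wide$convergence), mechanism = "convergence",
                  .before = 1),
    dplyr::mutate(fit_one(wide$parallelism), mechanism = "parallelism",
                  .before = 1)
  )
}
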