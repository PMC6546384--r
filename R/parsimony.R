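#' Minimum conceivable steps per character
#'
#' The smallest number of changes any tree could require: one fewer than the
#' number of distinct observed states (missing entries ignored).
#'
#' @param cm a [character_matrix()]
#' @return tibble with `char_id`, `m`
#' @export
min_steps <- function(cm) {
  stopifnot(inherits(cm, "character_matrix"))
  m <- apply(cm$states, 2, function(col) {
    obs <- col[!is.na(col)]
    if (!length(obs)) stop("character with all leaves missing")
    length(unique(obs)) - 1L
  })
  tibble::tibble(char_id = cm$char_meta$char_id, m = as.integer(m))
}

#' Maximum steps on a star tree per character
#'
#' The number of changes a completely unresolved tree requires: non-missing
#' leaf count minus the size of the largest state class. This is the
#' retention-index denominator term g.
#'
#' @param cm a [character_matrix()]
#' @return tibble with `char_id`, `g`
#' @export
max_steps <- function(cm) {
  stopifnot(inherits(cm, "character_matrix"))
  g <- apply(cm$states, 2, function(col) {
    obs <- col[!is.na(col)]
    if (!length(obs)) stop("character with all leaves missing")
    length(obs) - max(tabulate(obs + 1L))
  })
  tibble::tibble(char_id = cm$char_meta$char_id, g = as.integer(g))
}

# One indicator matrix (chars x states) per taxon row; a missing entry gets
# the full state set (Hartigan treats '?' as complete ambiguity).
.tip_indicators <- function(S, n_states) {
  nc <- ncol(S)
  lapply(seq_len(nrow(S)), function(i) {
    m <- matrix(FALSE, nc, n_states)
    s <- S[i, ]
    obs <- which(!is.na(s))
    m[cbind(obs, s[obs] + 1L)] <- TRUE
    if (length(obs) < nc) m[is.na(s), ] <- TRUE
    m
  })
}

.row_max_int <- function(M) do.call(pmax.int, lapply(seq_len(ncol(M)), function(j) M[, j]))
.row_min_num <- function(M) do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))

# Hartigan (1973) down-pass length for every character at once, on a rooted
# tree with polytomies. `rowperm` maps tip i to a row of S, so taxon
# permutations re-use the precomputed tip indicators.
.hartigan_engine <- function(ti, S) {
  n_states <- max(S, 0L, na.rm = TRUE) + 1L
  tips <- .tip_indicators(S, n_states)
  nc <- ncol(S)
  function(rowperm = seq_len(ti$n_tip)) {
    V <- vector("list", ti$n_node)
    V[seq_len(ti$n_tip)] <- tips[rowperm]
    cost <- integer(nc)
    for (v in ti$post_internal) {
      ch <- ti$children[[v]]
      cnt <- 0L + V[[ch[1]]]
      for (c2 in ch[-1]) cnt <- cnt + V[[c2]]
      K <- .row_max_int(cnt)
      cost <- cost + (length(ch) - K)
      V[[v]] <- cnt == K
    }
    cost
  }
}

#' Parsimony length of every character on a rooted tree
#'
#' Minimum number of unordered state changes (Fitch/Hartigan), polytomies
#' handled exactly; missing leaves carry the full state set.
#'
#' @param cm a [character_matrix()]
#' @param phy rooted `phylo` whose tips all have a row in `cm`
#' @return tibble with `char_id`, `s`
#' @export
parsimony_length <- function(cm, phy) {
  ti <- tree_index(phy)
  S <- .states_for_tips(ti, cm)
  s <- .hartigan_engine(ti, S)()
  tibble::tibble(char_id = cm$char_meta$char_id, s = as.integer(s))
}

#' Maximum-parsimony ancestral states under ACCTRAN or DELTRAN
#'
#' Computes one most-parsimonious reconstruction per character by dynamic
#' programming over unit transformation costs, then resolves ambiguity in a
#' single preorder sweep. ACCTRAN accelerates transformations: a node takes a
#' state different from its parent whenever doing so strictly lowers the cost
#' of its subtree, pulling changes toward the root (favouring reversals).
#' DELTRAN delays them: a node keeps the parental state whenever that is
#' compatible with a most-parsimonious reconstruction, pushing changes toward
#' the tips (favouring parallelisms). Remaining ties are broken toward the
#' smallest state code, so results are deterministic.
#'
#' @param cm a [character_matrix()]
#' @param phy rooted `phylo` (polytomies allowed); must have been rooted, e.g.
#'   with [root_with_outgroup()]
#' @param model `"ACCTRAN"` or `"DELTRAN"`
#' @return an object of class `parsimony_reconstruction`: list with `model`,
#'   `phy`, `node_states` (nodes x characters integer matrix; ape node
#'   numbering, root = n_tip + 1), `changes` (tibble: `char_id`, `parent`,
#'   `child`, `from`, `to`, `depth`), `steps` (tibble: `char_id`, `m`, `s`,
#'   `g`) and `tip_states` (the observed matrix in tip order).
#' @export
reconstruct_parsimony <- function(cm, phy, model = c("ACCTRAN", "DELTRAN")) {
  model <- match.arg(model)
  stopifnot(inherits(cm, "character_matrix"))
  ti <- tree_index(phy)
  S <- .states_for_tips(ti, cm)
  nc <- ncol(S)
  n_states <- max(S, 0L, na.rm = TRUE) + 1L
  BIG <- 1e6

  # per-character alphabet: internal nodes only take observed states
  A <- matrix(FALSE, nc, n_states)
  for (j in seq_len(n_states)) {
    A[, j] <- colSums(S == (j - 1L), na.rm = TRUE) > 0L
  }
  if (any(rowSums(A) == 0L)) stop("character with all leaves missing")

  cost <- vector("list", ti$n_node)
  for (i in seq_len(ti$n_tip)) {
    Ct <- matrix(BIG, nc, n_states)
    s <- S[i, ]
    obs <- which(!is.na(s))
    Ct[cbind(obs, s[obs] + 1L)] <- 0
    if (length(obs) < nc) {
      mis <- which(is.na(s))
      Ct[mis, ] <- ifelse(A[mis, , drop = FALSE], 0, BIG)
    }
    cost[[i]] <- Ct
  }
  for (v in ti$post_internal) {
    acc <- 0
    for (ch in ti$children[[v]]) {
      Cc <- cost[[ch]]
      acc <- acc + pmin(Cc, .row_min_num(Cc) + 1)
    }
    acc[!A] <- BIG
    cost[[v]] <- acc
  }

  node_states <- matrix(NA_integer_, ti$n_node, nc)
  node_states[ti$root, ] <- max.col(-cost[[ti$root]], ties.method = "first") - 1L
  idx <- seq_len(nc)
  for (v in ti$pre_internal) {
    p <- node_states[v, ]
    for (ch in ti$children[[v]]) {
      Cc <- cost[[ch]]
      rmin <- .row_min_num(Cc)
      cp <- Cc[cbind(idx, p + 1L)]
      chg <- if (model == "ACCTRAN") cp > rmin else cp > rmin + 1
      amin <- max.col(-Cc, ties.method = "first") - 1L
      node_states[ch, ] <- ifelse(chg, amin, p)
    }
  }

  kids <- setdiff(seq_len(ti$n_node), ti$root)
  diffs <- node_states[kids, , drop = FALSE] !=
    node_states[ti$parent[kids], , drop = FALSE]
  hit <- which(diffs, arr.ind = TRUE)
  child <- kids[hit[, 1]]
  parent <- ti$parent[child]
  changes <- tibble::tibble(
    char_id = cm$char_meta$char_id[hit[, 2]],
    parent = parent,
    child = child,
    from = node_states[cbind(parent, hit[, 2])],
    to = node_states[cbind(child, hit[, 2])],
    depth = ti$depth[child]
  )
  changes <- dplyr::arrange(changes, match(.data$char_id, cm$char_meta$char_id),
                            .data$child)
  s_vec <- as.integer(colSums(diffs))
  steps <- dplyr::left_join(min_steps(cm), max_steps(cm), by = "char_id")
  steps <- tibble::tibble(char_id = steps$char_id, m = steps$m,
                          s = s_vec, g = steps$g)
  structure(list(model = model, phy = phy, index = ti,
                 node_states = node_states, changes = changes, steps = steps,
                 tip_states = S, char_meta = cm$char_meta),
            class = "parsimony_reconstruction")
}

#' @export
print.parsimony_reconstruction <- function(x, ...) {
  cat("<parsimony_reconstruction> ", x$model, ": ",
      ncol(x$node_states), " characters on ", x$index$n_tip, " tips, ",
      "total length ", sum(x$steps$s), "\n", sep = "")
  invisible(x)
}

#' List of state changes of a reconstruction
#'
#' One row per inferred change: the edge (parent and child node ids), the
#' states on either side, and the depth of the child node (root depth 0).
#' The row count per character equals its observed step count s.
#'
#' @param rec a [reconstruct_parsimony()] result
#' @return tibble with `char_id`, `parent`, `child`, `from`, `to`, `depth`,
#'   `model`
#' @export
change_list <- function(rec) {
  stopifnot(inherits(rec, "parsimony_reconstruction"))
  dplyr::mutate(rec$changes, model = rec$model)
}
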