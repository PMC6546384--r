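# Independent oracles used across the suite. These work directly on the
# ape edge matrix and never call the package's traversal or DP code.

# Build a one-or-more-character matrix from named state vectors.
make_cm <- function(..., meta = NULL) {
  cols <- list(...)
  states <- do.call(cbind, cols)
  if (is.null(names(cols)) || any(names(cols) == "")) {
    colnames(states) <- paste0("c", seq_along(cols))
  }
  character_matrix(states, char_meta = meta)
}

# Exhaustive minimum parsimony length: enumerate every assignment of
# observed states to internal nodes; missing tips take the cost-free state
# of their parent. Feasible for <= 8 taxa and <= 4 states.
brute_force_length <- function(phy, states) {
  n <- ape::Ntip(phy)
  internals <- (n + 1):(n + phy$Nnode)
  alph <- sort(unique(states[!is.na(states)]))
  if (length(alph) == 0) stop("all states missing")
  grid <- as.matrix(expand.grid(rep(list(alph), length(internals))))
  edges <- phy$edge
  tipstate <- states[phy$tip.label]
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    asg <- integer(n + phy$Nnode)
    asg[internals] <- grid[r, ]
    cost <- 0L
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; ch <- edges[e, 2]
      sc <- if (ch <= n) tipstate[ch] else asg[ch]
      if (!is.na(sc) && sc != asg[p]) cost <- cost + 1L
    }
    if (cost < best) best <- cost
  }
  best
}

# All most-parsimonious assignments, with the summed depth of change edges
# (depth of the child node, root = 0). Returns a list with the minimum
# length and the range of depth sums over MPRs.
enumerate_mprs <- function(phy, states) {
  n <- ape::Ntip(phy)
  internals <- (n + 1):(n + phy$Nnode)
  alph <- sort(unique(states[!is.na(states)]))
  grid <- as.matrix(expand.grid(rep(list(alph), length(internals))))
  edges <- phy$edge
  tipstate <- states[phy$tip.label]
  # node depths from the edge matrix
  depth <- integer(n + phy$Nnode)
  ord <- edges[order(edges[, 1]), , drop = FALSE]
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; ch <- edges[e, 2]
      if (depth[ch] != depth[p] + 1L) { depth[ch] <- depth[p] + 1L; done <- FALSE }
    }
    if (done) break
  }
  res <- lapply(seq_len(nrow(grid)), function(r) {
    asg <- integer(n + phy$Nnode)
    asg[internals] <- grid[r, ]
    cost <- 0L; dsum <- 0L
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; ch <- edges[e, 2]
      sc <- if (ch <= n) tipstate[ch] else asg[ch]
      if (!is.na(sc) && sc != asg[p]) {
        cost <- cost + 1L
        dsum <- dsum + depth[ch]
      }
    }
    c(cost, dsum)
  })
  res <- do.call(rbind, res)
  s_min <- min(res[, 1])
  keep <- res[, 1] == s_min
  list(s = s_min, depth_min = min(res[keep, 2]), depth_max = max(res[keep, 2]))
}

# Random rooted tree (possibly polytomous) plus random states, for
# property-style loops.
random_fixture <- function(n_taxa, n_states, missing_frac = 0,
                           polytomy = FALSE) {
  phy <- if (polytomy) {
    ape::rtree(n_taxa, rooted = TRUE)
  } else {
    ape::rcoal(n_taxa)
  }
  if (polytomy && n_taxa >= 5) {
    phy <- ape::di2multi(phy, tol = quantile(phy$edge.length, 0.3))
  }
  phy$tip.label <- paste0("t", seq_len(ape::Ntip(phy)))
  states <- sample(0:(n_states - 1), ape::Ntip(phy), replace = TRUE)
  if (missing_frac > 0) {
    idx <- sample(ape::Ntip(phy),
                  floor(missing_frac * ape::Ntip(phy)))
    states[idx] <- NA
  }
  if (all(is.na(states))) states[1] <- 0L
  names(states) <- phy$tip.label
  list(phy = phy, states = states)
}

# Depth sum of the change edges of a reconstruction, per character.
change_depth_sum <- function(rec) {
  sum(rec$changes$depth)
}
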