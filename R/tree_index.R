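# Internal traversal index for a rooted (possibly polytomous) phylo.
# Node ids are ape's: tips 1..n in tip.label order, internals n+1..n+Nnode,
# root = n+1. Deterministic for a given newick, so reconstructions are
# referable across runs.
tree_index <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  # node n_tip + 1 is taken as the root; trees with a basal polytomy (e.g. a
  # consensus, or a star tree) are fine — rooting semantics are established
  # upstream by root_with_outgroup().
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  e <- stats::na.omit(ape::reorder.phylo(phy, "postorder")$edge)
  parent <- integer(n_node)
  parent[e[, 2]] <- e[, 1]
  root <- n_tip + 1L
  parent[root] <- 0L
  children <- vector("list", n_node)
  for (v in unique(e[, 1])) children[[v]] <- integer(0)
  children_split <- split(e[, 2], e[, 1])
  for (nm in names(children_split)) {
    children[[as.integer(nm)]] <- children_split[[nm]]
  }
  post_internal <- unique(e[, 1])           # children precede parents
  pre_internal <- rev(post_internal)
  depth <- integer(n_node)
  for (v in pre_internal) depth[children[[v]]] <- depth[v] + 1L
  paths <- vector("list", n_tip)            # root -> tip node sequences
  for (i in seq_len(n_tip)) {
    p <- i
    v <- i
    while (v != root) {
      v <- parent[v]
      p <- c(v, p)
    }
    paths[[i]] <- p
  }
  list(n_tip = n_tip, n_node = n_node, root = root, parent = parent,
       children = children, post_internal = post_internal,
       pre_internal = pre_internal, depth = depth, paths = paths,
       tip_label = phy$tip.label)
}

# taxa-by-characters state matrix reordered to tip order of the tree;
# errors if a tip has no row.
.states_for_tips <- function(ti, cm) {
  idx <- match(ti$tip_label, rownames(cm$states))
  if (anyNA(idx)) {
    stop("tip(s) without a state row: ",
         paste(ti$tip_label[is.na(idx)], collapse = ", "))
  }
  cm$states[idx, , drop = FALSE]
}
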