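#' Summarise a recorded trait range by its midpoint
#'
#' When a trait is published as a min-max range over specimens, the midpoint
#' (average of the extremes) is used as the single summarizing value.
#'
#' @param min,max numeric vectors of range extremes (recycled)
#' @return numeric vector of midpoints
#' @export
summarize_range <- function(min, max) {
  if (any(min > max, na.rm = TRUE)) stop("range minimum exceeds maximum")
  (min + max) / 2
}

# Ward (ward.D2) hierarchical clustering cut at k, on Euclidean distance.
.ward_cut <- function(X, k) {
  cutree(hclust(dist(X), method = "ward.D2"), k = k)
}

# Internal cluster-validity indices; each returns the index value for a
# labelled partition of the rows of X (larger is better unless stated).
.index_ch <- function(X, lab) {
  n <- nrow(X); k <- length(unique(lab))
  gm <- colMeans(X)
  cen <- rowsum(X, lab) / as.vector(table(lab))
  B <- sum(as.vector(table(lab)) * rowSums((cen - rep(gm, each = k))^2))
  W <- sum((X - cen[as.character(lab), , drop = FALSE])^2)
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

.index_db <- function(X, lab) {   # smaller is better
  k <- length(unique(lab))
  levs <- sort(unique(lab))
  cen <- rowsum(X, lab) / as.vector(table(lab))
  scat <- vapply(seq_len(k), function(i) {
    pts <- X[lab == levs[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - rep(cen[i, ], each = nrow(pts)))^2)))
  }, numeric(1))
  dcen <- as.matrix(dist(cen))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      if (dcen[i, j] == 0) Inf else (scat[i] + scat[j]) / dcen[i, j]
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

.index_dunn <- function(X, lab) {
  D <- as.matrix(dist(X))
  same <- outer(lab, lab, `==`)
  diam <- max(D[same & upper.tri(D)], 0)
  sep <- min(D[!same])
  if (diam == 0) return(Inf)
  sep / diam
}

.index_sil <- function(X, lab) {
  s <- cluster::silhouette(lab, dist(X))
  if (!is.matrix(s)) return(0)  # all-singleton partition: width 0 throughout
  mean(s[, "sil_width"])
}

# Majority vote of five validity indices over k = 2..k_max for Ward
# clustering; ties go to the smaller k. The gap statistic may vote k = 1.
# Callers clamp k_max to the number of distinct observations, so a tiny or
# genuinely discrete input may receive one state per distinct value.
.validity_vote <- function(X, k_max, seed = NULL, gap_B = 50) {
  n <- nrow(X)
  k_max <- min(k_max, n)
  ks <- 2:k_max
  labs <- lapply(ks, function(k) .ward_cut(X, k))
  per_k <- function(f) vapply(labs, function(l) f(X, l), numeric(1))
  sil <- per_k(.index_sil)
  ch <- per_k(.index_ch)
  db <- per_k(.index_db)
  dunn <- per_k(.index_dunn)
  gap_k <- with_local_seed(seed, {
    gp <- suppressWarnings(cluster::clusGap(
      X, FUNcluster = function(x, k) list(cluster = .ward_cut(x, k)),
      K.max = min(k_max, n - 1L), B = gap_B, verbose = FALSE))
    cluster::maxSE(gp$Tab[, "gap"], gp$Tab[, "SE.sim"],
                   method = "firstSEmax")
  })
  votes <- tibble::tibble(
    index = c("silhouette", "calinski_harabasz", "davies_bouldin", "dunn",
              "gap"),
    k = c(ks[which.max(sil)], ks[which.max(ch)], ks[which.min(db)],
          ks[which.max(dunn)], gap_k)
  )
  tab <- table(votes$k)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k = min(winners), votes = votes, labels = labs, ks = ks)
}

#' Discretize a numeric trait by Ward clustering with a validity-index vote
#'
#' Clusters the raw (unstandardized) trait values by agglomerative Ward
#' linkage on Euclidean distance; the number of states k is chosen by
#' majority vote of five cluster-validity indices (silhouette,
#' Calinski-Harabasz, Davies-Bouldin, Dunn, gap statistic) over k = 2..k_max,
#' ties resolved toward fewer states. Values in the same cluster share a
#' state code; codes are ordered by ascending cluster mean. A constant vector
#' yields a single state without a vote; missing values are excluded and
#' coded `NA`.
#'
#' @param values named numeric vector (names = taxa) or plain vector
#' @param k_max largest number of states considered (default 8, the NEXUS
#'   single-digit alphabet used here)
#' @param seed optional seed (the gap statistic is Monte-Carlo)
#' @param char_id optional identifier carried into the result
#' @param gap_B bootstrap references for the gap statistic
#' @return object of class `coding_result`: list with `char_id`, `k`,
#'   `labels` (integer state codes 0..k-1, `NA` where the value was missing),
#'   `votes` (tibble of per-index chosen k; `NULL` when no vote was needed)
#' @export
optimal_k <- function(values, k_max = 8, seed = NULL, char_id = NULL,
                      gap_B = 50) {
  v <- as.numeric(values)
  obs <- which(!is.na(v))
  if (length(obs) < 2) stop("need at least 2 non-missing values")
  x <- v[obs]
  n_distinct <- length(unique(x))
  labels <- rep(NA_integer_, length(v))
  if (n_distinct == 1L) {
    labels[obs] <- 0L
    res <- list(char_id = char_id, k = 1L, labels = labels, votes = NULL)
    return(structure(res, class = "coding_result"))
  }
  X <- matrix(x, ncol = 1)
  if (n_distinct == 2L) {
    k <- 2L
    lab <- .ward_cut(X, 2L)
    votes <- NULL
  } else {
    vote <- .validity_vote(X, k_max = min(k_max, n_distinct),
                           seed = seed, gap_B = gap_B)
    k <- vote$k
    votes <- vote$votes
    lab <- if (k == 1L) rep(1L, length(x)) else
      vote$labels[[match(k, vote$ks)]]
  }
  # state codes in order of ascending cluster mean
  mu <- tapply(x, lab, mean)
  code <- rank(mu, ties.method = "first") - 1L
  labels[obs] <- as.integer(code[as.character(lab)])
  if (!is.null(names(values))) names(labels) <- names(values)
  structure(list(char_id = char_id, k = as.integer(k), labels = labels,
                 votes = votes),
            class = "coding_result")
}

#' @export
print.coding_result <- function(x, ...) {
  cat("<coding_result>", if (!is.null(x$char_id)) x$char_id else "", "k =",
      x$k, "\n")
  if (!is.null(x$votes)) {
    cat("  votes:", paste(x$votes$index, x$votes$k, sep = "=",
                          collapse = " "), "\n")
  }
  invisible(x)
}

#' Code verbal colors into discrete states via PCA of RGB values
#'
#' Runs a principal component analysis on the RGB triples, projects each
#' color onto the first two components, and clusters the scores in that
#' plane (Ward linkage, Euclidean distance, validity-index vote as in
#' [optimal_k()]). All colors in one cluster share a state; state codes are
#' ordered by ascending brightness (mean R+G+B of the cluster), which makes
#' them independent of the arbitrary signs of the principal components.
#'
#' @param table data frame with columns `name`, `R`, `G`, `B` (0-255)
#' @param k_max largest number of color states considered
#' @param seed optional seed for the gap statistic
#' @param gap_B bootstrap references for the gap statistic
#' @return list of class `color_coding`: `k`, `states` (tibble `name`,
#'   `state`), `votes`, `scores` (tibble with PC1/PC2 per color)
#' @export
code_colors <- function(table, k_max = 8, seed = NULL, gap_B = 50) {
  stopifnot(all(c("name", "R", "G", "B") %in% names(table)))
  if (anyDuplicated(table$name)) stop("color names must be unique")
  rgb <- as.matrix(table[, c("R", "G", "B")])
  if (any(rgb < 0 | rgb > 255)) stop("RGB channels must lie in 0..255")
  if (nrow(rgb) < 3) stop("need at least 3 colors")
  if (all(apply(rgb, 2, function(c) length(unique(c))) == 1L)) {
    states <- tibble::tibble(name = table$name, state = 0L)
    return(structure(list(k = 1L, states = states, votes = NULL,
                          scores = NULL), class = "color_coding"))
  }
  pc <- prcomp(rgb, center = TRUE, scale. = FALSE)
  d <- min(2L, ncol(pc$x))
  X <- pc$x[, seq_len(d), drop = FALSE]
  vote <- .validity_vote(X, k_max = min(k_max, nrow(unique(X))),
                         seed = seed, gap_B = gap_B)
  k <- vote$k
  lab <- if (k == 1L) rep(1L, nrow(X)) else vote$labels[[match(k, vote$ks)]]
  bright <- tapply(rowSums(rgb), lab, mean)
  code <- rank(bright, ties.method = "first") - 1L
  states <- tibble::tibble(name = table$name,
                           state = as.integer(code[as.character(lab)]))
  scores <- tibble::tibble(name = table$name, PC1 = pc$x[, 1],
                           PC2 = if (d == 2) pc$x[, 2] else 0)
  structure(list(k = as.integer(k), states = states, votes = vote$votes,
                 scores = scores),
            class = "color_coding")
}

#' @export
print.color_coding <- function(x, ...) {
  cat("<color_coding> k =", x$k, "states over", nrow(x$states), "colors\n")
  invisible(x)
}
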