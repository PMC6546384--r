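#' Simulate a rooted ultrametric Yule tree
#'
#' @param n_taxa number of tips (>= 3)
#' @param birth speciation rate of the pure-birth process
#' @param seed optional integer seed
#' @return rooted ultrametric `phylo` with tips `t1..tn`
#' @export
simulate_tree <- function(n_taxa, birth = 1, seed = NULL) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  with_local_seed(seed, ape::rphylo(n_taxa, birth = birth, death = 0))
}

# Paper-shaped defaults: characters per developmental stage and, within
# adults, per body part.
stage_counts_default <- c(egg = 12, L1 = 13, L2 = 23, L3 = 26, pupa = 46,
                          adult = 370)
organ_counts_default <- c(head = 78, thorax = 90, abdomen = 40,
                          male_terminalia = 150, female_terminalia = 12)

# Hourglass profile: early and late stages evolve fast, mid-larval stages
# are conserved (rate multipliers, unitless).
hourglass_rates_default <- c(egg = 1.6, L1 = 0.5, L2 = 0.35, L3 = 0.4,
                             pupa = 0.8, adult = 1.5)

# State-number distribution over 1..8 with mean ~3 states per character.
state_number_probs_default <- c(0.02, 0.33, 0.30, 0.15, 0.10, 0.05, 0.03,
                                0.02)

#' Simulate discrete characters on a tree under an equal-rates Mk model
#'
#' Each character evolves along the tree as a continuous-time Markov jump
#' chain with k states: waiting times are exponential with the character's
#' total change rate (base rate x its stage's hourglass multiplier x branch
#' length), and each event moves to one of the other k - 1 states uniformly.
#' Every realized change is logged (edge, from-state, to-state), giving a
#' ground truth against which parsimony reconstructions can be compared.
#' Missing data are injected completely at random, or in clade x character
#' blocks mimicking structurally inapplicable characters.
#'
#' @param phy rooted `phylo`
#' @param stage_counts named integer vector of characters per stage
#' @param stage_rates named numeric vector of per-stage rate multipliers
#' @param base_rate changes per unit branch length for a multiplier of 1
#' @param state_number_probs sampling weights for the number of states 1..8
#' @param organ_counts named weights for assigning adult characters to body
#'   parts
#' @param missing_frac fraction of cells set to missing
#' @param block_missing if `TRUE`, missingness is applied to random clade x
#'   character blocks instead of single cells
#' @param seed optional integer seed
#' @return list with `matrix` (a [character_matrix()]) and `truth` (list:
#'   `node_states` nodes x characters matrix, `changes` tibble with
#'   `char_id`, `parent`, `child`, `from`, `to`)
#' @export
simulate_characters <- function(phy,
                                stage_counts = stage_counts_default,
                                stage_rates = hourglass_rates_default,
                                base_rate = 0.1,
                                state_number_probs = state_number_probs_default,
                                organ_counts = organ_counts_default,
                                missing_frac = 0.1,
                                block_missing = FALSE,
                                seed = NULL) {
  stopifnot(all(stage_rates > 0), missing_frac >= 0, missing_frac <= 1)
  with_local_seed(seed, {
    ti <- tree_index(phy)
    n_char <- sum(stage_counts)
    stage <- rep(names(stage_counts), stage_counts)
    char_id <- sprintf("c%03d", seq_len(n_char))
    organ <- ifelse(stage == "adult", NA, "none")
    n_adult <- sum(stage == "adult")
    if (n_adult > 0) {
      organ[stage == "adult"] <- sample(names(organ_counts), n_adult,
                                        replace = TRUE,
                                        prob = organ_counts /
                                          sum(organ_counts))
    }
    k_states <- sample(seq_along(state_number_probs), n_char, replace = TRUE,
                       prob = state_number_probs)
    edge_len <- numeric(ti$n_node)
    e <- phy$edge
    edge_len[e[, 2]] <- phy$edge.length
    node_states <- matrix(NA_integer_, ti$n_node, n_char)
    chg <- list()
    for (j in seq_len(n_char)) {
      k <- k_states[j]
      rate <- base_rate * stage_rates[[stage[j]]]
      ns <- integer(ti$n_node)
      ns[ti$root] <- sample.int(k, 1) - 1L
      if (k > 1) {
        for (v in ti$pre_internal) {
          for (ch in ti$children[[v]]) {
            s <- ns[v]
            t_left <- edge_len[ch]
            repeat {
              w <- rexp(1, rate)
              if (w >= t_left) break
              t_left <- t_left - w
              new <- sample.int(k, 1) - 1L
              while (new == s) new <- sample.int(k, 1) - 1L
              chg[[length(chg) + 1L]] <- c(j, v, ch, s, new)
              s <- new
            }
            ns[ch] <- s
          }
        }
      }
      node_states[, j] <- ns
    }
    S <- node_states[seq_len(ti$n_tip), , drop = FALSE]
    rownames(S) <- ti$tip_label
    # inject missing data, keeping >= 2 observed entries per character
    if (missing_frac > 0) {
      if (block_missing) {
        internals <- setdiff(ti$pre_internal, ti$root)
        target <- missing_frac * ti$n_tip * n_char
        made <- 0
        while (made < target && length(internals)) {
          v <- sample(internals, 1)
          tips <- which(vapply(seq_len(ti$n_tip),
                               function(i) v %in% ti$paths[[i]], logical(1)))
          cols <- sample(n_char, max(1, round(n_char * 0.02)))
          for (cc in cols) {
            keepable <- sum(!is.na(S[, cc])) - length(tips)
            if (keepable >= 2) {
              S[tips, cc] <- NA_integer_
              made <- made + length(tips)
            }
          }
        }
      } else {
        cells <- which(!is.na(S))
        drop <- sample(cells, round(missing_frac * length(cells)))
        S[drop] <- NA_integer_
        for (j in which(colSums(!is.na(S)) < 2)) {
          refill <- sample(ti$n_tip, 2)
          S[refill, j] <- node_states[refill, j]
        }
      }
    }
    changes <- if (length(chg)) {
      mt <- do.call(rbind, chg)
      tibble::tibble(char_id = char_id[mt[, 1]], parent = mt[, 2],
                     child = mt[, 3], from = mt[, 4], to = mt[, 5])
    } else {
      tibble::tibble(char_id = character(0), parent = integer(0),
                     child = integer(0), from = integer(0), to = integer(0))
    }
    meta <- tibble::tibble(char_id = char_id, label = char_id, stage = stage,
                           organ = organ)
    list(matrix = character_matrix(S, char_meta = meta),
         truth = list(node_states = node_states, changes = changes,
                      k_states = k_states))
  })
}

#' Simulate a numeric trait from a Gaussian mixture
#'
#' Component means are spaced `separation` within-component standard
#' deviations apart, so `separation >= 6` gives well-separated clusters.
#'
#' @param n_taxa number of values
#' @param k_true number of mixture components (>= 1)
#' @param separation spacing between adjacent component means, in within-SD
#'   units (>= 0)
#' @param sd_within within-component standard deviation (trait units)
#' @param seed optional integer seed
#' @return tibble with `taxon`, `value`, `component` (0-based true label,
#'   ordered by component mean)
#' @export
simulate_numeric_traits <- function(n_taxa, k_true, separation = 6,
                                    sd_within = 1, seed = NULL) {
  if (k_true < 1) stop("k_true must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  with_local_seed(seed, {
    comp <- sort(rep_len(seq_len(k_true), n_taxa))  # balanced components
    mu <- (comp - 1) * separation * sd_within
    tibble::tibble(
      taxon = paste0("t", seq_len(n_taxa)),
      value = rnorm(n_taxa, mean = mu, sd = sd_within),
      component = comp - 1L
    )
  })
}

# Anchor pigments in RGB space: dark melanin, yellow sclerotin, pale
# sclerotin.
color_anchors_default <- matrix(
  c(45, 35, 28,      # black/brown melanin
    208, 172, 60,    # yellow sclerotin
    240, 236, 224),  # whitish sclerotin
  nrow = 3, byrow = TRUE,
  dimnames = list(c("melanin", "yellow_sclerotin", "white_sclerotin"),
                  c("R", "G", "B"))
)

#' Simulate a verbal-color RGB table around pigment anchors
#'
#' Colors scatter (Gaussian, `spread` channel units) around a small set of
#' anchor pigments; channels are clamped to 0..255 (clamping is reported via
#' a message).
#'
#' @param n number of colors (>= number of anchors)
#' @param anchors matrix of anchor RGB rows (default: three pigment anchors)
#' @param spread per-channel Gaussian SD around the anchor
#' @param seed optional integer seed
#' @return tibble with `name`, `R`, `G`, `B`, `anchor` (0-based true label)
#' @export
simulate_colors <- function(n, anchors = color_anchors_default, spread = 10,
                            seed = NULL) {
  n_anchor <- nrow(anchors)
  if (n < n_anchor) stop("need n >= number of anchors")
  with_local_seed(seed, {
    lab <- sort(rep_len(seq_len(n_anchor), n))
    rgb <- anchors[lab, , drop = FALSE] +
      matrix(rnorm(3 * n, sd = spread), n, 3)
    n_clamped <- sum(rgb < 0 | rgb > 255)
    if (n_clamped > 0) {
      message("clamped ", n_clamped, " channel value(s) to 0..255")
    }
    rgb <- pmin(pmax(round(rgb), 0), 255)
    tibble::tibble(name = sprintf("color_%02d", seq_len(n)),
                   R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
                   anchor = lab - 1L)
  })
}

#' Simulate a complete paper-shaped dataset
#'
#' Convenience preset: a 56-taxon Yule tree and 490 characters distributed
#' over developmental stages as in the empirical matrix (egg 12, L1 13,
#' L2 23, L3 26, pupa 46, adult 370; adult characters spread over five body
#' parts), evolving under the hourglass rate profile with 10% missing data.
#'
#' @param seed integer seed (drives tree and characters)
#' @param n_taxa number of tips
#' @param ... passed on to [simulate_characters()]
#' @return list with `tree`, `matrix`, `truth`
#' @export
simulate_paperlike <- function(seed = 1, n_taxa = 56, ...) {
  tree <- simulate_tree(n_taxa, birth = 1, seed = seed)
  sim <- simulate_characters(tree, seed = seed + 1L, ...)
  list(tree = tree, matrix = sim$matrix, truth = sim$truth)
}
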