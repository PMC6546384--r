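rec_row <- function(current, original, change_node, depart, changed = TRUE,
                    char = "c1") {
  list(char_id = char, current = current, original = original,
       change_node = change_node, depart_node = depart, changed = changed)
}

test_that("derivation records capture current, original and change node", {
  tr <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  cm <- make_cm(c(O = 0, A = 1, B = 1, C = 0, D = 0))
  rec <- reconstruct_parsimony(cm, tr, "DELTRAN")
  dr <- derivation_records(rec)
  ab_node <- rec$changes$child[1]
  a <- dr[dr$taxon == "A", ]
  expect_equal(a$current, 1L)
  expect_equal(a$original, 0L)
  expect_equal(a$change_node, ab_node)
  o <- dr[dr$taxon == "O", ]
  expect_equal(o$current, 0L)
  expect_equal(o$original, 0L)
  expect_equal(o$change_node, rec$index$root)
  expect_equal(o$origin_of_original, rec$index$root)
  # missing observations yield no record
  cm2 <- make_cm(c(O = 0, A = 1, B = NA, C = 0, D = 0))
  dr2 <- derivation_records(reconstruct_parsimony(cm2, tr, "DELTRAN"))
  expect_false("B" %in% dr2$taxon)
  expect_equal(nrow(dr2), 4L)
})

test_that("records match the simulator's truth for once-changed characters", {
  sim <- simulate_paperlike(seed = 71, n_taxa = 6,
                            stage_counts = c(egg = 20, L1 = 20, L2 = 20,
                                             L3 = 20, pupa = 20, adult = 60),
                            base_rate = 0.02, missing_frac = 0)
  rec <- reconstruct_parsimony(sim$matrix, sim$tree, "DELTRAN")
  dr <- derivation_records(rec)
  truth <- sim$truth$changes
  once <- names(which(table(truth$char_id) == 1))
  tested <- 0L
  for (cid in once) {
    ev <- truth[truth$char_id == cid, ]
    ti <- rec$index
    j <- match(cid, sim$matrix$char_meta$char_id)
    # a change on a root-adjacent edge can be re-rooted with equal parsimony;
    # only compare characters whose reconstructed root state is the true one
    if (rec$node_states[ti$root, j] !=
        sim$truth$node_states[ti$root, j]) next
    # taxa below the changed edge vs outside it
    below <- vapply(seq_len(ti$n_tip),
                    function(i) ev$child %in% ti$paths[[i]], logical(1))
    drc <- dr[dr$char_id == cid, ]
    if (!all(drc$current == ifelse(below[match(drc$taxon, ti$tip_label)],
                                   ev$to, ev$from))) next  # masked by ties
    for (k in seq_len(nrow(drc))) {
      i <- match(drc$taxon[k], ti$tip_label)
      if (below[i]) {
        expect_equal(drc$original[k], ev$from)
        expect_equal(drc$change_node[k], ev$child)
      } else {
        expect_equal(drc$change_node[k], ti$root)
        expect_equal(drc$original[k], ev$from)
      }
      tested <- tested + 1L
    }
  }
  expect_gt(tested, 50L)
})

test_that("the six-way pair classification follows the morphospace rules", {
  # same current state
  expect_equal(classify_pair(rec_row(1, 0, 5, 9), rec_row(1, 0, 5, 9)),
               "inertia")
  expect_equal(classify_pair(rec_row(1, 0, 5, 9), rec_row(1, 0, 7, 9)),
               "parallelism")
  expect_equal(classify_pair(rec_row(1, 2, 5, 9), rec_row(1, 0, 7, 9)),
               "convergence")
  # different current states
  expect_equal(classify_pair(rec_row(1, 0, 5, 9), rec_row(2, 0, 7, 9)),
               "divergence")
  expect_equal(classify_pair(rec_row(1, 0, 5, 9), rec_row(2, 0, 7, 11)),
               "disparity1")
  # a lineage that never moved cannot take part in a divergence
  expect_equal(classify_pair(rec_row(1, 0, 5, 9),
                             rec_row(0, 0, 9, 9, changed = FALSE)),
               "disparity1")
  expect_equal(classify_pair(rec_row(1, 0, 5, 9), rec_row(2, 3, 7, 11)),
               "disparity2")
  expect_error(classify_pair(rec_row(1, 0, 5, 9),
                             rec_row(1, 0, 5, 9, char = "c2")),
               "different characters")
})

test_that("classification is symmetric in the two records", {
  set.seed(7)
  for (i in 1:50) {
    a <- rec_row(sample(0:2, 1), sample(0:2, 1), sample(1:9, 1),
                 sample(1:9, 1))
    b <- rec_row(sample(0:2, 1), sample(0:2, 1), sample(1:9, 1),
                 sample(1:9, 1))
    expect_identical(classify_pair(a, b), classify_pair(b, a))
  }
})

test_that("tree fixtures produce inertia, parallelism and convergence", {
  # sisters inheriting one gain: inertia; two independent gains: parallelism
  tr <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  cm <- make_cm(c(O = 0, A = 1, B = 1, C = 0, D = 0),
                c(O = 0, A = 1, B = 0, C = 1, D = 0))
  dr <- derivation_records(reconstruct_parsimony(cm, tr, "DELTRAN"))
  c1 <- dr[dr$char_id == "c1", ]
  expect_equal(classify_pair(c1[c1$taxon == "A", ], c1[c1$taxon == "B", ]),
               "inertia")
  c2 <- dr[dr$char_id == "c2", ]
  expect_equal(classify_pair(c2[c2$taxon == "A", ], c2[c2$taxon == "C", ]),
               "parallelism")
  # convergence: 1 reached from 0 on one side and from 2 on the other
  tr2 <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  cm2 <- make_cm(c(O = 0, A = 1, B = 0, C = 1, D = 2))
  dr2 <- derivation_records(reconstruct_parsimony(cm2, tr2, "DELTRAN"))
  a <- dr2[dr2$taxon == "A", ]
  c_ <- dr2[dr2$taxon == "C", ]
  if (a$original != c_$original) {
    expect_equal(classify_pair(a, c_), "convergence")
  }
})

test_that("mechanism proportions sum to one and detect pure inertia", {
  star <- ape::read.tree(text = "(A,B,C);")
  cm <- make_cm(c(A = 0, B = 0, C = 0))
  dr <- derivation_records(reconstruct_parsimony(cm, star, "ACCTRAN"))
  mp <- mechanism_proportions(dr)
  expect_equal(mp$proportions$proportion[mp$proportions$mechanism ==
                                           "inertia"], 1)
  expect_equal(sum(mp$proportions$proportion), 1)
  sim <- simulate_paperlike(seed = 31, n_taxa = 15,
                            stage_counts = c(egg = 4, L1 = 4, L2 = 5, L3 = 5,
                                             pupa = 6, adult = 26))
  for (model in c("ACCTRAN", "DELTRAN")) {
    dr <- derivation_records(
      reconstruct_parsimony(sim$matrix, sim$tree, model))
    for (mode in c("pooled", "per_char_mean")) {
      mp <- mechanism_proportions(dr, mode = mode)
      expect_equal(sum(mp$proportions$proportion), 1, tolerance = 1e-12)
    }
  }
})

test_that("resolution models shape the mechanism spectrum as expected", {
  # accelerated changes never leave sister-edge departures on binary trees
  # (divergence = 0); delayed changes allow a few and favour parallel gains
  # over convergent ones
  for (r in 1:3) {
    sim <- simulate_paperlike(seed = 500 + r, n_taxa = 20,
                              stage_counts = c(egg = 8, L1 = 8, L2 = 10,
                                               L3 = 10, pupa = 12,
                                               adult = 60))
    pa <- mechanism_proportions(derivation_records(
      reconstruct_parsimony(sim$matrix, sim$tree, "ACCTRAN")))$proportions
    pd <- mechanism_proportions(derivation_records(
      reconstruct_parsimony(sim$matrix, sim$tree, "DELTRAN")))$proportions
    expect_equal(pa$n[pa$mechanism == "divergence"], 0L)
    expect_gte(pd$n[pd$mechanism == "divergence"],
               pa$n[pa$mechanism == "divergence"])
    expect_gte(pd$n[pd$mechanism == "parallelism"],
               pd$n[pd$mechanism == "convergence"])
  }
})

test_that("reversal incidences match the hand-worked chain fixture", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  cm <- make_cm(c(A = 0, B = 1, C = 1, D = 0))
  rec <- reconstruct_parsimony(cm, tr, "ACCTRAN")
  rv <- count_reversals(rec)
  # A's lineage runs 0 -> 1 -> 1 -> 0: exactly one (taxon, ancestor)
  # incidence out of 3+3+2+1 comparisons
  expect_equal(rv$n_incidences, 1L)
  expect_equal(rv$n_comparisons, 9L)
  expect_equal(rv$fraction, 1 / 9)
  expect_true(rv$any_reversal)
})

test_that("ACCTRAN yields at least as many reversals as DELTRAN", {
  for (r in 1:4) {
    sim <- simulate_paperlike(seed = 400 + r, n_taxa = 14,
                              stage_counts = c(egg = 3, L1 = 3, L2 = 4,
                                               L3 = 4, pupa = 5, adult = 20))
    ra <- count_reversals(reconstruct_parsimony(sim$matrix, sim$tree,
                                                "ACCTRAN"))
    rd <- count_reversals(reconstruct_parsimony(sim$matrix, sim$tree,
                                                "DELTRAN"))
    expect_gte(mean(ra$fraction, na.rm = TRUE),
               mean(rd$fraction, na.rm = TRUE))
    expect_lte(sum(!ra$any_reversal), sum(!rd$any_reversal))
  }
})

test_that("reversal-mechanism regression recovers collinearity and noise", {
  pc <- tibble::tibble(
    char_id = rep(paste0("c", 1:10), each = 6),
    mechanism = rep(MECH <- c("inertia", "parallelism", "convergence",
                              "divergence", "disparity1", "disparity2"), 10),
    n = 1L, n_pairs = 6L,
    proportion = 0
  )
  x <- seq(0, 0.9, length.out = 10)
  pc$proportion[pc$mechanism == "convergence"] <- 2 * x
  pc$proportion[pc$mechanism == "parallelism"] <- 0.5 * x
  rv <- tibble::tibble(char_id = paste0("c", 1:10), fraction = x)
  rr <- suppressWarnings(reversal_mechanism_correlation(rv, pc))
  expect_equal(rr$r_squared, c(1, 1), tolerance = 1e-12)
  set.seed(9)
  rv_shuffled <- tibble::tibble(char_id = paste0("c", 1:10),
                                fraction = sample(x))
  rr2 <- reversal_mechanism_correlation(rv_shuffled, pc)
  expect_lt(max(rr2$r_squared), 0.5)
  expect_error(
    reversal_mechanism_correlation(
      tibble::tibble(char_id = paste0("c", 1:10), fraction = rep(0.2, 10)),
      pc),
    "zero variance")
})
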