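test_that("minimum and star-tree step counts follow their closed forms", {
  cm <- make_cm(
    c(A = 0, B = 1, C = 1, D = 0),
    c(A = 0, B = 1, C = 2, D = NA),
    c(A = 1, B = 1, C = 1, D = 1),
    c(A = 0, B = 0, C = 1, D = 1),
    c(A = 0, B = 1, C = 2, D = 2)
  )
  expect_equal(min_steps(cm)$m, c(1L, 2L, 0L, 1L, 2L))
  expect_equal(max_steps(cm)$g, c(2L, 2L, 0L, 2L, 2L))
  cm5 <- character_matrix(matrix(c(0, 1, 2, 2, 2), 5, 1,
                                 dimnames = list(paste0("t", 1:5), "c1")))
  expect_equal(max_steps(cm5)$g, 2L)
  all_missing <- character_matrix(matrix(NA_integer_, 3, 1,
                                         dimnames = list(c("A", "B", "C"),
                                                         "c1")))
  expect_error(min_steps(all_missing), "missing")
  expect_error(max_steps(all_missing), "missing")
})

test_that("parsimony length matches hand-checked four- and five-taxon cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  cm <- make_cm(
    c(A = 0, B = 1, C = 0, D = 1),   # incongruent: 2 steps
    c(A = 1, B = 1, C = 0, D = 0),   # perfect synapomorphy: 1 step
    c(A = 1, B = 1, C = 1, D = 1)    # invariant: 0 steps
  )
  expect_equal(parsimony_length(cm, tr)$s, c(2L, 1L, 0L))
  star <- ape::read.tree(text = "(A,B,C,D);")
  cmstar <- make_cm(c(A = 0, B = 0, C = 1, D = 2))
  expect_equal(parsimony_length(cmstar, star)$s, 2L)
})

test_that("parsimony length equals the brute-force minimum on random trees", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    k <- sample(2:4, 1)
    fx <- random_fixture(n, k, missing_frac = ifelse(i %% 3 == 0, 0.25, 0),
                         polytomy = i %% 2 == 0)
    cm <- character_matrix(matrix(fx$states, ncol = 1,
                                  dimnames = list(names(fx$states), "c1")))
    got <- parsimony_length(cm, fx$phy)$s
    expect_equal(got, brute_force_length(fx$phy, fx$states),
                 info = paste("fixture", i))
  }
})

test_that("parsimony length agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  phy <- ape::rcoal(20)
  phy$tip.label <- paste0("t", 1:20)
  states <- matrix(sample(0:3, 20 * 30, replace = TRUE), 20, 30,
                   dimnames = list(phy$tip.label, NULL))
  cm <- character_matrix(states)
  pd <- phangorn::phyDat(matrix(as.character(states), nrow = 20,
                                dimnames = dimnames(states)),
                         type = "USER", levels = as.character(0:3))
  expect_equal(sum(parsimony_length(cm, phy)$s),
               as.integer(phangorn::parsimony(phy, pd)))
})

test_that("both resolutions are most parsimonious and ACCTRAN pulls changes rootward", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    k <- sample(2:3, 1)
    fx <- random_fixture(n, k, polytomy = i %% 2 == 0)
    cm <- character_matrix(matrix(fx$states, ncol = 1,
                                  dimnames = list(names(fx$states), "c1")))
    mpr <- enumerate_mprs(fx$phy, fx$states)
    ra <- reconstruct_parsimony(cm, fx$phy, "ACCTRAN")
    rd <- reconstruct_parsimony(cm, fx$phy, "DELTRAN")
    expect_equal(ra$steps$s, mpr$s, info = paste("ACCTRAN length", i))
    expect_equal(rd$steps$s, mpr$s, info = paste("DELTRAN length", i))
    expect_lte(change_depth_sum(ra), change_depth_sum(rd))
    expect_gte(change_depth_sum(ra), mpr$depth_min)
    expect_lte(change_depth_sum(rd), mpr$depth_max)
  }
})

test_that("DELTRAN places parallel gains on terminal edges when the root is fixed", {
  # outgroup O pins the ancestral state at 0; A and C share a derived 1
  tr <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  cm <- make_cm(c(O = 0, A = 1, B = 0, C = 1, D = 0))
  rd <- reconstruct_parsimony(cm, tr, "DELTRAN")
  ch <- change_list(rd)
  tipA <- which(tr$tip.label == "A")
  tipC <- which(tr$tip.label == "C")
  expect_equal(nrow(ch), 2L)
  expect_setequal(ch$child, c(tipA, tipC))
  expect_true(all(ch$from == 0 & ch$to == 1))
  ra <- reconstruct_parsimony(cm, tr, "ACCTRAN")
  expect_equal(nrow(ra$changes), 2L)
  expect_lte(change_depth_sum(ra), change_depth_sum(rd))
})

test_that("invariant characters reconstruct with zero changes everywhere", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  cm <- make_cm(c(A = 2, B = 2, C = 2, D = 2, E = 2))
  for (model in c("ACCTRAN", "DELTRAN")) {
    rec <- reconstruct_parsimony(cm, tr, model)
    expect_equal(nrow(rec$changes), 0L)
    expect_true(all(rec$node_states == 2L))
  }
})

test_that("change lists have one row per step and match node states", {
  set.seed(41)
  sim <- simulate_paperlike(seed = 5, n_taxa = 16,
                            stage_counts = c(egg = 3, L1 = 3, L2 = 4, L3 = 4,
                                             pupa = 5, adult = 30))
  for (model in c("ACCTRAN", "DELTRAN")) {
    rec <- reconstruct_parsimony(sim$matrix, sim$tree, model)
    ch <- change_list(rec)
    per_char <- table(factor(ch$char_id, levels = rec$steps$char_id))
    expect_equal(as.integer(per_char), rec$steps$s)
    jj <- match(ch$char_id, rec$steps$char_id)
    expect_equal(ch$from, rec$node_states[cbind(ch$parent, jj)])
    expect_equal(ch$to, rec$node_states[cbind(ch$child, jj)])
    expect_true(all(rec$steps$s >= rec$steps$m))
  }
})

test_that("missing leaves never increase the tree length", {
  set.seed(51)
  for (i in 1:15) {
    fx <- random_fixture(7, 3)
    drop <- sample(7, 2)
    states_miss <- fx$states
    states_miss[drop] <- NA
    if (all(is.na(states_miss))) next
    cm_full <- character_matrix(matrix(fx$states, ncol = 1,
                                       dimnames = list(names(fx$states),
                                                       "c1")))
    cm_miss <- character_matrix(matrix(states_miss, ncol = 1,
                                       dimnames = list(names(fx$states),
                                                       "c1")))
    s_miss <- parsimony_length(cm_miss, fx$phy)$s
    pruned <- ape::drop.tip(fx$phy, names(states_miss)[drop])
    keep <- setdiff(names(fx$states), names(states_miss)[drop])
    cm_pruned <- character_matrix(
      matrix(fx$states[keep], ncol = 1, dimnames = list(keep, "c1")))
    s_pruned <- parsimony_length(cm_pruned, pruned)$s
    expect_equal(s_miss, s_pruned)
    expect_lte(s_miss, parsimony_length(cm_full, fx$phy)$s)
  }
})
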