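# Fitch scoring, exhaustive enumeration/search, tree statistics,
# rooting, bootstrap, consensus and Newick I/O.

test_that("Fitch equals the brute-force assignment oracle and phangorn", {
  skip_if_not_installed("phangorn")
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(4:6, 1)
    taxa <- paste0("t", seq_len(n))
    tr <- random_topology(taxa)
    m <- random_binary_matrix(taxa, 10, seed = seed + 1000)
    got <- fitch_steps(tr, m)
    expect_identical(got$total_steps, sum(got$per_character_steps))
    expect_identical(got$total_steps, brute_force_score(tr, m))
    pd <- phangorn::phyDat(m$states, type = "USER",
                           levels = c("0", "1"), ambiguity = "?")
    expect_identical(as.integer(phangorn::parsimony(tr, pd)),
                     as.integer(got$total_steps))
  }
})

test_that("simple score cases behave as expected", {
  tr <- read_newick("((A,B),(C,D),E);")
  m1 <- character_matrix(matrix("1", 5, 1,
                                dimnames = list(c("A","B","C","D","E"), "k")))
  expect_identical(fitch_steps(tr, m1)$total_steps, 0L)
  m2 <- character_matrix(matrix(c("1","1","0","0","0"), 5, 1,
                                dimnames = list(c("A","B","C","D","E"), "k")))
  expect_identical(fitch_steps(tr, m2)$total_steps, 1L)
  # missing taxa are rejected
  m3 <- character_matrix(matrix("1", 4, 1,
                                dimnames = list(c("A","B","C","D"), "k")))
  expect_error(fitch_steps(tr, m3), "differ")
})

test_that("score is invariant under rooting and leaf-order permutation", {
  for (seed in 1:10) {
    set.seed(seed)
    taxa <- paste0("t", 1:6)
    tr <- random_topology(taxa)
    m <- random_binary_matrix(taxa, 8, seed = seed + 99)
    s0 <- fitch_steps(tr, m)$total_steps
    rooted <- root_with_outgroup(tr, sample(taxa, 1))
    expect_identical(fitch_steps(rooted, m)$total_steps, s0)
    perm <- sample(length(taxa))
    m2 <- character_matrix(m$states[perm, , drop = FALSE],
                           labels = m$characters$label)
    expect_identical(fitch_steps(tr, m2)$total_steps, s0)
  }
})

test_that("enumeration yields each topology exactly once", {
  expect_length(enumerate_trees(LETTERS[1:4]), 3)
  trees5 <- enumerate_trees(LETTERS[1:5])
  expect_length(trees5, 15)
  trees7 <- enumerate_trees(paste0("t", 1:7))
  expect_length(trees7, 945)
  keys <- vapply(trees7, canonical_topology, "")
  expect_identical(anyDuplicated(keys), 0L)
  expect_error(enumerate_trees(paste0("t", 1:11)), "refusing")
  expect_error(enumerate_trees(c("A", "B")), "at least 3")
})

test_that("exhaustive search finds the minimum over all topologies", {
  # against a direct minimum over the enumerated tree list
  for (seed in 1:5) {
    taxa <- paste0("t", 1:5)
    m <- random_binary_matrix(taxa, 6, seed = seed)
    res <- exhaustive_search(m)
    expect_identical(res$n_trees_examined, 15L)
    all_scores <- vapply(enumerate_trees(taxa), function(tr)
      fitch_steps(tr, m)$total_steps, integer(1))
    expect_identical(res$length, min(all_scores))
    expect_length(res$mp_trees, sum(all_scores == min(all_scores)))
  }
  # constant matrix: all topologies tie at zero
  taxa <- paste0("t", 1:5)
  cm <- character_matrix(matrix("1", 5, 3, dimnames = list(taxa, NULL)),
                         labels = paste0("c", 1:3))
  res <- exhaustive_search(cm)
  expect_identical(res$length, 0L)
  expect_length(res$mp_trees, 15)
})

test_that("tree statistics follow the CI/RI/HI definitions", {
  # homoplasy-free limit
  st <- parsimony_indices(5, 5, 9)
  expect_identical(st$ci, 1)
  expect_identical(st$ri, 1)
  expect_identical(st$hi, 0)
  # profile with m = 44, g = 55 at 45 observed steps
  taxa <- paste0("t", 1:5)
  cols <- cbind(
    matrix(rep(c("1", "0", "0", "0", "0"), 33), nrow = 5),   # min 1 each
    matrix(rep(c("1", "1", "0", "0", "0"), 11), nrow = 5))   # min 2 each
  rownames(cols) <- taxa
  m4455 <- character_matrix(cols, labels = paste0("c", 1:44))
  st <- tree_stats(m4455, 45)
  expect_identical(st$m, 44L)
  expect_identical(st$g, 55L)
  expect_identical(karyophy:::round_half_up(st$ci), 0.978)
  expect_identical(karyophy:::round_half_up(st$ri), 0.909)
  expect_identical(karyophy:::round_half_up(st$hi), 0.022)
  expect_identical(st$hi, 1 - st$ci)
  # degenerate profile: no retention index
  expect_warning(st2 <- parsimony_indices(2, 1, 1), "undefined")
  expect_true(is.na(st2$ri))
  expect_error(parsimony_indices(1, 2, 3), "below")
})

test_that("m <= s <= g and HI + CI = 1 on searched matrices", {
  for (seed in 1:10) {
    taxa <- paste0("t", 1:5)
    m <- random_binary_matrix(taxa, 8, seed = seed + 500)
    res <- exhaustive_search(m)
    st <- res$stats
    expect_lte(st$m, res$length)
    expect_lte(res$length, st$g)
    expect_identical(st$hi + st$ci, 1)
    # column permutation changes nothing
    perm <- sample(8)
    mp <- character_matrix(m$states[, perm, drop = FALSE],
                           labels = m$characters$label[perm])
    resp <- exhaustive_search(mp)
    expect_identical(resp$length, res$length)
    expect_identical(resp$stats$ci, st$ci)
    expect_identical(resp$stats$ri, st$ri)
  }
})

test_that("outgroup rooting places the ingroup clade", {
  m <- pitheciinae_matrix()
  res <- exhaustive_search(m)
  rooted <- root_with_outgroup(res$mp_trees[[1]], c("BAR", "CAP"))
  # ingroup clade is (PIR,(CCR,CUT)): both clades appear below the root
  trav <- karyophy:::tree_traversal(rooted)
  clades <- list()
  below <- vector("list", length(trav$children))
  for (u in trav$postorder) {
    kids <- trav$children[[u]]
    below[[u]] <- if (length(kids) == 0) rooted$tip.label[u]
                  else sort(unlist(below[kids]))
    if (length(kids)) clades <- c(clades, list(below[[u]]))
  }
  has_clade <- function(x) any(vapply(clades, identical, logical(1), x))
  expect_true(has_clade(c("CCR", "CUT")))
  expect_true(has_clade(c("CCR", "CUT", "PIR")))

  # single-outgroup rooting on a triplet
  tr3 <- read_newick("(A,B,C);")
  r3 <- root_with_outgroup(tr3, "C")
  expect_true(ape::is.rooted(r3))

  # rooting then unrooting returns the unrooted topology
  for (seed in 1:5) {
    tr <- random_topology(paste0("t", 1:6), seed = seed)
    r <- root_with_outgroup(tr, c("t1"))
    expect_identical(canonical_topology(unroot_tree(r)),
                     canonical_topology(tr))
  }

  # non-monophyletic outgroup: warn, still rooted
  tr <- read_newick("((A,C),B,(D,E));")
  expect_warning(r <- root_with_outgroup(tr, c("A", "B")), "monophyletic")
  expect_true(ape::is.rooted(r))
  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D", "E")), "all")
})

test_that("bootstrap support is deterministic and reflects clean signal", {
  taxa <- c("A", "B", "C", "D", "E")
  clean <- character_matrix(
    matrix(rep(c("1", "1", "0", "0", "0"), 20), nrow = 5, byrow = FALSE,
           dimnames = list(taxa, NULL)),
    labels = paste0("c", 1:20))
  b <- bootstrap_support(clean, n_replicates = 50, seed = 42)
  # the {A,B}|{C,D,E} split is keyed by the side without the first leaf
  expect_equal(b$support$support[b$support$clade == "C,D,E"], 100)
  b2 <- bootstrap_support(clean, n_replicates = 50, seed = 42)
  expect_identical(b, b2)
})

test_that("sister-taxa support beats any PIR+CUT grouping on the fixture", {
  b <- bootstrap_support(pitheciinae_matrix(), n_replicates = 500, seed = 7)
  sup <- b$support
  ccr_cut <- sup$support[sup$clade == "CCR,CUT"]
  has_pir_cut <- vapply(strsplit(sup$clade, ",", fixed = TRUE), function(s)
    all(c("PIR", "CUT") %in% s) && !("CCR" %in% s), logical(1))
  expect_gt(ccr_cut, max(0, sup$support[has_pir_cut]))
})

test_that("majority-rule consensus keeps exactly the frequent splits", {
  tr <- read_newick("((A,B),C,(D,E));")
  same <- majority_rule_consensus(list(tr, tr, tr))
  expect_identical(canonical_topology(same), canonical_topology(tr))
  # three conflicting resolutions of one quartet collapse to a star
  qs <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
               read_newick)
  star <- majority_rule_consensus(qs)
  expect_length(tree_splits(star), 0)
  # recount: retained splits really exceed the threshold
  set.seed(9)
  trees <- lapply(1:20, function(i) random_topology(paste0("t", 1:6)))
  cons <- majority_rule_consensus(trees, threshold = 0.5)
  for (k in tree_splits(cons)) {
    freq <- mean(vapply(trees, function(t) k %in% tree_splits(t), logical(1)))
    expect_gt(freq, 0.5)
  }
  expect_error(majority_rule_consensus(list(tr, read_newick("(A,B,Z);"))),
               "leaf sets")
})

test_that("Newick I/O round-trips topologies and reports parse errors", {
  tr <- read_newick("((A,B),(C,D),E);")
  expect_length(tr$tip.label, 5)
  expect_false(ape::is.rooted(tr))
  back <- read_newick(write_newick(tr))
  expect_identical(canonical_topology(back), canonical_topology(tr))
  expect_error(read_newick("((A,B;"), "parse")
  # the fixture MP tree nests the sister taxa under some rotation
  res <- exhaustive_search(pitheciinae_matrix())
  expect_true("CCR,CUT" %in% tree_splits(res$mp_trees[[1]]))
  rooted <- root_with_outgroup(res$mp_trees[[1]], c("BAR", "CAP"))
  expect_match(write_newick(rooted), "\\((CCR,CUT|CUT,CCR)\\)")
})
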