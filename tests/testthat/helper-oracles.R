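# Independent oracles and generators used across the suite.

# Brute-force small parsimony: minimum number of state changes over all
# assignments of {0,1} to internal nodes (and to ?-leaves). Independent of
# the Fitch implementation: plain enumeration over the edge list.
brute_force_steps <- function(tree, states) {
  # states: named character vector ("0","1","?") over tip labels
  n <- length(tree$tip.label)
  n_node <- tree$Nnode
  edge <- tree$edge
  leaf <- states[tree$tip.label]
  free_leaves <- which(leaf == "?")
  fixed <- suppressWarnings(as.integer(leaf))
  n_free <- n_node + length(free_leaves)
  best <- Inf
  for (code in 0:(2^n_free - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(max(n_free, 1))]
    s <- integer(n + n_node)
    s[seq_len(n)] <- fixed
    s[n + seq_len(n_node)] <- bits[seq_len(n_node)]
    if (length(free_leaves))
      s[free_leaves] <- bits[n_node + seq_along(free_leaves)]
    cost <- sum(s[edge[, 1]] != s[edge[, 2]])
    if (cost < best) best <- cost
  }
  as.integer(best)
}

brute_force_score <- function(tree, matrix) {
  sum(vapply(seq_len(nrow(matrix$characters)), function(j)
    brute_force_steps(tree, setNames(matrix$states[, j], matrix$taxa)),
    integer(1)))
}

random_topology <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trees <- enumerate_trees(labels)
  trees[[sample.int(length(trees), 1)]]
}

random_binary_matrix <- function(taxa, n_char, p_missing = 0.1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    s <- matrix(sample(c("0", "1", "?"), length(taxa) * n_char,
                       replace = TRUE,
                       prob = c((1 - p_missing) / 2, (1 - p_missing) / 2,
                                p_missing)),
                length(taxa), n_char, dimnames = list(taxa, NULL))
    if (!any(apply(s, 2, function(col) all(col == "?")))) break
  }
  character_matrix(s, labels = paste0("chr", seq_len(n_char)))
}

# random valid homology map, built probe-major as the TSV dialect stores it
random_homology_map <- function(seed, n_probes = 8, n_targets = 6) {
  set.seed(seed)
  probes <- as.character(seq_len(n_probes))
  notes <- c(NA, "p", "q", "distal p", "proximal q")
  segs <- setNames(vector("list", n_targets), as.character(seq_len(n_targets)))
  for (p in probes) {
    k <- sample(1:2, 1)
    for (tgt in as.character(sample.int(n_targets, k)))
      segs[[tgt]] <- rbind(segs[[tgt]],
                           probe_segment(p, region_note = sample(notes, 1)))
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  chroms <- lapply(names(segs), function(id) target_chromosome(id, segs[[id]]))
  homology_map("PRB", "TGT", chroms, probe_chroms = probes,
               diploid_female = 2L * length(chroms) + 2L,
               diploid_male = 2L * length(chroms) + 2L)
}

# exact probability that a character simulated with per-branch flip
# probability p is variable across the leaves, by enumeration over all
# flip patterns (root state is irrelevant by symmetry)
variable_fraction_oracle <- function(tree, p) {
  edge <- tree$edge
  n_edge <- nrow(edge)
  n <- length(tree$tip.label)
  root <- setdiff(unique(edge[, 1]), edge[, 2])[1]
  parent_edge <- integer(max(edge))
  for (i in seq_len(n_edge)) parent_edge[edge[i, 2]] <- i
  parent <- integer(max(edge))
  for (i in seq_len(n_edge)) parent[edge[i, 2]] <- edge[i, 1]
  prob_variable <- 0
  for (code in 0:(2^n_edge - 1)) {
    flips <- as.integer(intToBits(code))[seq_len(n_edge)]
    leaf_state <- vapply(seq_len(n), function(tip) {
      s <- 0L; u <- tip
      while (u != root) { s <- bitwXor(s, flips[parent_edge[u]]); u <- parent[u] }
      s
    }, integer(1))
    w <- prod(ifelse(flips == 1L, p, 1 - p))
    if (length(unique(leaf_state)) > 1L) prob_variable <- prob_variable + w
  }
  prob_variable
}

fixture_path <- function(f) karyophy_example(f)

# segment alphabet of the default ancestral karyotype (incl. X)
ancestral_alphabet <- function() {
  k <- default_ancestral_karyotype()
  sort(c(unlist(k$autosomes), "X"))
}

map_segment_ids <- function(map) {
  sort(unname(unlist(lapply(map$chromosomes, function(ch) {
    s <- ch$segments
    if (nrow(s)) paste0(s$probe_chrom,
                        ifelse(is.na(s$sub_segment), "", s$sub_segment))
  }))))
}
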