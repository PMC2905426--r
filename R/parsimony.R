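# Maximum-parsimony engine: Fitch small parsimony for binary (0/1/?)
# characters, exhaustive enumeration of unrooted binary topologies by
# stepwise leaf addition, tree statistics (CI/RI/HI), outgroup rooting,
# character bootstrap and majority-rule consensus.
#
# Trees are ape "phylo" objects. Fitch state sets are bitmasks:
# 0 -> 1, 1 -> 2, ? -> 3 (the full state set, so missing data is free).

.ENUM_CAP <- 10L

#' Number of unrooted binary topologies, (2n-5)!!
#'
#' @param n number of leaves (n >= 3).
#' @return the double factorial (2n-5)!! as a double.
#' @export
n_unrooted_topologies <- function(n) {
  stopifnot(n >= 3)
  if (n == 3) return(1)
  prod(seq(3, 2 * n - 5, by = 2))
}

# ---- internal edge-list tree representation used during enumeration ----
# leaves 1..n, internal nodes n+1 .. 2n-2; edges: 2-column matrix.

# orient the undirected edge list from root `start`, returning a phylo
edges_to_phylo <- function(edges, labels, start = NULL) {
  n <- length(labels)
  m <- max(edges)
  adj <- vector("list", m)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  start <- start %||% (n + 1L)
  # iterative DFS: renumber internals in preorder, emit parent->child edges
  new_id <- integer(m)
  new_id[start] <- n + 1L
  next_internal <- n + 2L
  parent <- integer(m)
  stack <- start
  visited <- logical(m)
  visited[start] <- TRUE
  from <- integer(0); to <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (v in adj[[u]]) {
      if (visited[v]) next
      visited[v] <- TRUE
      if (v > n) { new_id[v] <- next_internal; next_internal <- next_internal + 1L }
      else new_id[v] <- v
      from <- c(from, new_id[u]); to <- c(to, new_id[v])
      stack <- c(stack, v)
    }
  }
  structure(list(edge = cbind(from, to), Nnode = m - n,
                 tip.label = labels),
            class = "phylo")
}

# call fun(edges) for every distinct unrooted binary topology on n leaves
walk_topologies <- function(n, fun) {
  if (n < 3L) stop("need at least 3 taxa")
  base <- cbind(c(1L, 2L, 3L), c(n + 1L, n + 1L, n + 1L))
  recurse <- function(edges, k) {
    if (k > n) { fun(edges); return(invisible()) }
    w <- n + k - 2L
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1]; v <- edges[i, 2]
      e2 <- rbind(edges[-i, , drop = FALSE],
                  c(u, w), c(w, v), c(w, k))
      recurse(e2, k + 1L)
    }
    invisible()
  }
  recurse(base, 4L)
}

#' Enumerate all unrooted binary topologies
#'
#' Exhaustive stepwise leaf addition over all edges, yielding each of the
#' (2n-5)!! distinct unrooted binary leaf-labelled topologies exactly once.
#'
#' @param taxa leaf labels (3 <= n <= `cap`).
#' @param cap refusal threshold; above it an exhaustive enumeration is not
#'   attempted (heuristic search is out of scope).
#' @return list of unrooted `phylo` trees.
#' @export
enumerate_trees <- function(taxa, cap = .ENUM_CAP) {
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  if (n > cap)
    stop("refusing exhaustive enumeration for ", n, " taxa (cap ", cap,
         "): (2n-5)!! grows too fast and heuristic search is out of scope")
  out <- vector("list", n_unrooted_topologies(n))
  i <- 0L
  walk_topologies(n, function(edges) {
    i <<- i + 1L
    out[[i]] <<- edges_to_phylo(edges, taxa)
  })
  out[seq_len(i)]
}

# children list + postorder over internal nodes for a phylo object
tree_traversal <- function(phy) {
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  children <- vector("list", m)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1]]] <- c(children[[phy$edge[i, 1]]],
                                    phy$edge[i, 2])
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])[1]
  # postorder: reverse of a preorder DFS
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, u)
    stack <- c(stack, children[[u]])
  }
  list(children = children, postorder = rev(ord), root = root, n_tip = n)
}

# character state bitmask matrix (taxa x characters)
state_masks <- function(matrix) {
  s <- matrix$states
  m <- matrix(3L, nrow(s), ncol(s), dimnames = dimnames(s))
  m[s == "0"] <- 1L
  m[s == "1"] <- 2L
  m
}

# Fitch engine on a traversal; leaf_masks: n_tip x n_char integer matrix
# (rows in node-id order 1..n_tip). Sequential pairwise folding at a node
# with three children equals rooting on the edge to the last child, so the
# score is exact for the basal trifurcation of unrooted trees.
fitch_engine <- function(trav, leaf_masks) {
  n_char <- ncol(leaf_masks)
  masks <- matrix(0L, length(trav$children), n_char)
  masks[seq_len(trav$n_tip), ] <- leaf_masks
  steps <- integer(n_char)
  for (u in trav$postorder) {
    kids <- trav$children[[u]]
    if (length(kids) == 0L) next
    acc <- masks[kids[1], ]
    for (k in kids[-1]) {
      inter <- bitwAnd(acc, masks[k, ])
      disjoint <- inter == 0L
      steps <- steps + disjoint
      acc <- ifelse(disjoint, bitwOr(acc, masks[k, ]), inter)
    }
    masks[u, ] <- acc
  }
  steps
}

#' Fitch parsimony score of a tree
#'
#' Bottom-up union/intersection count for unordered binary characters;
#' `?` is treated as the full state set (missing data is free). The score
#' is invariant under rooting.
#'
#' @param tree a `phylo` tree (rooted or unrooted) whose tips are the
#'   matrix taxa.
#' @param matrix a [character_matrix()].
#' @return list of class `parsimony_score`: `total_steps`,
#'   `per_character_steps`.
#' @export
fitch_steps <- function(tree, matrix) {
  idx <- match(tree$tip.label, matrix$taxa)
  if (anyNA(idx) || length(tree$tip.label) != length(matrix$taxa))
    stop("tree leaves and matrix taxa differ")
  trav <- tree_traversal(tree)
  lm <- state_masks(matrix)[idx, , drop = FALSE]
  steps <- fitch_engine(trav, lm)
  structure(list(total_steps = sum(steps), per_character_steps = steps),
            class = "parsimony_score")
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat("parsimony score:", x$total_steps, "steps over",
      length(x$per_character_steps), "characters\n")
  invisible(x)
}

# per-character minimum (m_i) and maximum (g_i) conceivable steps
char_bounds <- function(matrix) {
  m_i <- apply(matrix$states, 2, function(col) {
    max(0L, length(unique(col[col != "?"])) - 1L)
  })
  g_i <- apply(matrix$states, 2, function(col) {
    min(sum(col == "0"), sum(col == "1"))
  })
  list(m = m_i, g = g_i)
}

#' Parsimony indices from step sums
#'
#' Consistency index CI = m/s, retention index RI = (g-s)/(g-m) and
#' homoplasy index HI = 1 - CI, where s is the observed tree length, m the
#' minimum conceivable step sum and g the maximum conceivable step sum.
#'
#' @param s observed tree length (steps).
#' @param m minimum conceivable steps.
#' @param g maximum conceivable steps.
#' @return list of class `tree_stats` with `s`, `m`, `g`, `ci`, `ri`, `hi`.
#'   `ri` is `NA` (with a warning) when g = m but s > m.
#' @export
parsimony_indices <- function(s, m, g) {
  if (s < m) stop("s < m: observed length below the conceivable minimum")
  ci <- if (s == 0) 1 else m / s
  ri <- if (g > m) (g - s) / (g - m)
        else if (s == m) 1
        else { warning("retention index undefined: g = m with s > m"); NA_real_ }
  structure(list(s = s, m = m, g = g, ci = ci, ri = ri, hi = 1 - ci),
            class = "tree_stats")
}

#' Tree statistics for an observed length
#'
#' Computes m and g from the matrix (over all characters, including
#' parsimony-uninformative autapomorphies) and the CI/RI/HI indices for the
#' given length.
#'
#' @param matrix a [character_matrix()].
#' @param s observed tree length.
#' @return a `tree_stats` object (see [parsimony_indices()]).
#' @export
tree_stats <- function(matrix, s) {
  b <- char_bounds(matrix)
  parsimony_indices(s, sum(b$m), sum(b$g))
}

# half-up rounding to match conventionally printed 3-decimal indices
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.tree_stats <- function(x, digits = 3, ...) {
  cat(sprintf("length s = %d (m = %d, g = %d)\n", x$s, x$m, x$g))
  cat(sprintf("CI = %.3f  RI = %s  HI = %.3f\n",
              round_half_up(x$ci, digits),
              ifelse(is.na(x$ri), "NA",
                     sprintf("%.3f", round_half_up(x$ri, digits))),
              round_half_up(x$hi, digits)))
  invisible(x)
}

#' Exhaustive maximum-parsimony search
#'
#' Scores every unrooted binary topology on the matrix taxa and returns
#' all trees attaining the minimum length, with tree statistics.
#'
#' @param matrix a [character_matrix()].
#' @param cap enumeration cap (see [enumerate_trees()]).
#' @return list of class `search_result`: `mp_trees` (list of `phylo`),
#'   `length`, `stats` (a `tree_stats`), `n_trees_examined`.
#' @export
exhaustive_search <- function(matrix, cap = .ENUM_CAP) {
  taxa <- matrix$taxa
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  if (n > cap)
    stop("refusing exhaustive search for ", n, " taxa (cap ", cap,
         "); heuristic search is out of scope")
  lm <- state_masks(matrix)
  best <- Inf
  best_edges <- list()
  examined <- 0L
  walk_topologies(n, function(edges) {
    examined <<- examined + 1L
    trav <- edge_traversal(edges, n)
    s <- sum(fitch_engine(trav, lm))
    if (s < best) { best <<- s; best_edges <<- list(edges) }
    else if (s == best) best_edges[[length(best_edges) + 1L]] <<- edges
  })
  mp <- lapply(best_edges, edges_to_phylo, labels = taxa)
  structure(list(mp_trees = mp, length = as.integer(best),
                 stats = tree_stats(matrix, best),
                 n_trees_examined = examined),
            class = "search_result")
}

# traversal straight from an undirected edge list (root = first internal)
edge_traversal <- function(edges, n) {
  m <- max(edges)
  children <- vector("list", m)
  parent <- integer(m)
  root <- n + 1L
  visited <- logical(m); visited[root] <- TRUE
  adj <- vector("list", m)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  ord <- integer(0); stack <- root
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, u)
    for (v in adj[[u]]) if (!visited[v]) {
      visited[v] <- TRUE
      children[[u]] <- c(children[[u]], v)
      stack <- c(stack, v)
    }
  }
  list(children = children, postorder = rev(ord), root = root, n_tip = n)
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("exhaustive search: %d topologies examined, %d MP tree(s) of length %d\n",
              x$n_trees_examined, length(x$mp_trees), x$length))
  print(x$stats)
  invisible(x)
}

# ---- bipartitions -------------------------------------------------------

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the leaves in two; a split is keyed by the
#' sorted labels of the side not containing the alphabetically first leaf,
#' joined with commas.
#'
#' @param tree a `phylo` tree (rooted or unrooted).
#' @return character vector of split keys.
#' @export
tree_splits <- function(tree) {
  trav <- tree_traversal(tree)
  n <- trav$n_tip
  labels <- tree$tip.label
  ref <- sort(labels)[1]
  below <- vector("list", length(trav$children))
  keys <- character(0)
  for (u in trav$postorder) {
    kids <- trav$children[[u]]
    if (length(kids) == 0L) { below[[u]] <- labels[u]; next }
    tips <- sort(unlist(below[kids]))
    below[[u]] <- tips
    if (u != trav$root && length(tips) >= 2L && length(tips) <= n - 2L) {
      side <- if (ref %in% tips) sort(setdiff(labels, tips)) else tips
      keys <- c(keys, paste(side, collapse = ","))
    }
  }
  unique(keys)
}

split_key <- function(side, all_labels) {
  ref <- sort(all_labels)[1]
  side <- sort(side)
  if (ref %in% side) side <- sort(setdiff(all_labels, side))
  paste(side, collapse = ",")
}

#' Canonical form of an unrooted topology
#'
#' Two trees have the same canonical form iff they are the same unrooted
#' leaf-labelled topology.
#'
#' @param tree a `phylo` tree.
#' @return a single string.
#' @export
canonical_topology <- function(tree) {
  paste(c(paste(sort(tree$tip.label), collapse = ","),
          sort(tree_splits(tree))), collapse = ";")
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees (unweighted, unrooted).
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return integer distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# ---- rooting ------------------------------------------------------------

# re-root a tree on the edge identified by the tip set of one side
root_on_split <- function(tree, side_tips) {
  labels <- tree$tip.label
  n <- length(labels)
  trav <- tree_traversal(tree)
  below <- vector("list", length(trav$children))
  target_child <- NA_integer_
  for (u in trav$postorder) {
    kids <- trav$children[[u]]
    below[[u]] <- if (length(kids) == 0L) labels[u]
                  else sort(unlist(below[kids]))
    if (u != trav$root &&
        (setequal(below[[u]], side_tips) ||
         setequal(below[[u]], setdiff(labels, side_tips))))
      target_child <- u
  }
  if (is.na(target_child)) stop("no edge realizes the requested split")
  # insert a root node on the edge above target_child
  parent <- integer(length(trav$children))
  for (u in seq_along(trav$children))
    for (v in trav$children[[u]]) parent[v] <- u
  edges <- cbind(tree$edge[, 1], tree$edge[, 2])
  hit <- which(edges[, 1] == parent[target_child] &
                 edges[, 2] == target_child)
  newroot <- max(edges) + 1L
  edges[hit, ] <- c(parent[target_child], newroot)
  edges <- rbind(edges, c(newroot, target_child))
  edges_to_phylo(edges, labels, start = newroot)
}

#' Root a tree with an outgroup
#'
#' Places the root on the edge separating the outgroup from the ingroup
#' when the outgroup is monophyletic on the unrooted tree; otherwise roots
#' on the edge that best separates outgroup from ingroup, with a warning.
#'
#' @param tree an unrooted `phylo` tree.
#' @param outgroup character vector of outgroup taxa (a proper non-empty
#'   subset of the leaves).
#' @return a rooted `phylo` tree (binary root of degree 2).
#' @export
root_with_outgroup <- function(tree, outgroup) {
  labels <- tree$tip.label
  if (!length(outgroup) || !all(outgroup %in% labels))
    stop("outgroup must be a non-empty subset of the leaves")
  if (setequal(outgroup, labels))
    stop("outgroup cannot contain all leaves")
  if (length(outgroup) == 1L)
    return(root_on_split(tree, outgroup))
  key <- split_key(outgroup, labels)
  if (key %in% tree_splits(tree))
    return(root_on_split(tree, outgroup))
  # not monophyletic: pick the split with the best outgroup/ingroup
  # separation (max matched taxa over the two orientations)
  warning("outgroup is not monophyletic on this tree; ",
          "rooting on the best-separating edge")
  ingroup <- setdiff(labels, outgroup)
  cand <- c(tree_splits(tree), labels)  # internal splits + pendant edges
  score <- vapply(cand, function(k) {
    side <- strsplit(k, ",", fixed = TRUE)[[1]]
    other <- setdiff(labels, side)
    max(length(intersect(side, outgroup)) + length(intersect(other, ingroup)),
        length(intersect(other, outgroup)) + length(intersect(side, ingroup)))
  }, numeric(1))
  best <- strsplit(cand[which.max(score)], ",", fixed = TRUE)[[1]]
  og_in_side <- length(intersect(best, outgroup)) >= length(best) / 2
  root_on_split(tree, if (og_in_side) best else setdiff(labels, best))
}

#' Remove the root again
#'
#' @param tree a rooted `phylo` tree.
#' @return the unrooted topology (basal trifurcation), via `ape::unroot`.
#' @export
unroot_tree <- function(tree) ape::unroot(tree)

# ---- Newick I/O ---------------------------------------------------------

#' Read / write Newick
#'
#' Thin wrappers around `ape::read.tree` / `ape::write.tree` with error
#' reporting; labels with spaces must be quoted in the Newick string.
#'
#' @param text Newick string (or a file path for `file`).
#' @param file optional file path.
#' @return a `phylo` tree / a Newick string.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  res <- tryCatch(
    if (!is.null(file)) ape::read.tree(file)
    else ape::read.tree(text = text),
    error = function(e) NULL,
    warning = function(w) NULL)
  if (is.null(res) || !inherits(res, "phylo"))
    stop("Newick parse error in: ",
         substr(text %||% file, 1, 60))
  res
}

#' @rdname read_newick
#' @param tree a `phylo` tree.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(file) }
}

# ---- bootstrap and consensus -------------------------------------------

#' Character bootstrap support
#'
#' Resamples characters with replacement (same count), reruns the
#' exhaustive search on each replicate, and tallies non-trivial
#' bipartitions; when a replicate yields k MP trees each contributes
#' weight 1/k. Deterministic given `seed`.
#'
#' @param matrix a [character_matrix()].
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; all replicate resamplings are drawn from one
#'   generator seeded here, so identical seeds give identical support.
#' @param cap enumeration cap.
#' @return list of class `bootstrap_support`: `support` (data frame
#'   `clade`, `support` in percent), `n_replicates`, `seed`.
#' @export
bootstrap_support <- function(matrix, n_replicates = 1000, seed = 1,
                              cap = .ENUM_CAP) {
  stopifnot(n_replicates >= 1)
  n_char <- nrow(matrix$characters)
  set.seed(seed)
  idx <- matrix(sample.int(n_char, n_char * n_replicates, replace = TRUE),
                nrow = n_replicates)
  tally <- new.env(parent = emptyenv())
  for (r in seq_len(n_replicates)) {
    sub <- matrix$states[, idx[r, ], drop = FALSE]
    colnames(sub) <- paste0("r", seq_len(ncol(sub)))
    bm <- character_matrix(sub)
    res <- exhaustive_search(bm, cap = cap)
    w <- 1 / length(res$mp_trees)
    seen <- character(0)
    for (tr in res$mp_trees) {
      for (k in tree_splits(tr)) {
        # each split counted once per replicate per tree
        cur <- get0(k, envir = tally, ifnotfound = 0)
        assign(k, cur + w, envir = tally)
      }
    }
  }
  keys <- ls(tally)
  sup <- vapply(keys, get, numeric(1), envir = tally)
  out <- data.frame(clade = keys,
                    support = 100 * unname(sup) / n_replicates,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$clade), , drop = FALSE]
  row.names(out) <- NULL
  structure(list(support = out, n_replicates = n_replicates, seed = seed),
            class = "bootstrap_support")
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat(sprintf("bootstrap support (%d replicates, seed %d):\n",
              x$n_replicates, x$seed))
  print(x$support, row.names = FALSE)
  invisible(x)
}

#' Majority-rule consensus
#'
#' Retains bipartitions whose frequency among the input trees exceeds
#' `threshold` (>= 0.5, so retained splits are pairwise compatible) and
#' assembles them into a possibly multifurcating tree.
#'
#' @param trees list of `phylo` trees on one leaf set.
#' @param threshold retention threshold as a fraction (0.5 <= t <= 1).
#' @return a `phylo` tree; internal node labels carry the split frequency
#'   in percent.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1, threshold >= 0.5, threshold <= 1)
  labels <- trees[[1]]$tip.label
  for (tr in trees)
    if (!setequal(tr$tip.label, labels))
      stop("trees have inconsistent leaf sets")
  tab <- table(unlist(lapply(trees, tree_splits)))
  freq <- as.numeric(tab) / length(trees)
  keep <- names(tab)[freq > threshold]
  freq <- freq[freq > threshold]
  ref <- sort(labels)[1]
  clusters <- lapply(keep, function(k) strsplit(k, ",", fixed = TRUE)[[1]])
  quote_tip <- function(x)
    ifelse(grepl("[ ,();:]", x), paste0("'", x, "'"), x)
  # laminar (threshold >= 0.5): build the rooted-at-ref cluster hierarchy
  build <- function(tips, avail) {
    inside <- avail[vapply(avail, function(i)
      all(clusters[[i]] %in% tips), logical(1))]
    maximal <- inside[vapply(inside, function(i)
      !any(vapply(setdiff(inside, i), function(j)
        all(clusters[[i]] %in% clusters[[j]]), logical(1))),
      logical(1))]
    used <- unique(unlist(clusters[maximal]))
    parts <- c(
      lapply(maximal, function(i)
        paste0("(", build(clusters[[i]], setdiff(inside, i)), ")",
               round(100 * freq[i]))),
      as.list(quote_tip(setdiff(tips, used))))
    paste(unlist(parts), collapse = ",")
  }
  rest <- setdiff(labels, ref)
  nwk <- paste0("(", quote_tip(ref), ",",
                build(rest, seq_along(clusters)), ");")
  read_newick(nwk)
}

#' Annotate a rooted tree with bootstrap support
#'
#' Sets `node.label` on internal nodes to the support percentage of the
#' corresponding bipartition (empty where the split was never sampled).
#'
#' @param tree a rooted `phylo` tree.
#' @param support a `bootstrap_support` object (or its `support` frame).
#' @param digits rounding for the percentages.
#' @return the tree with `node.label` set.
#' @export
annotate_support <- function(tree, support, digits = 0) {
  sup <- if (inherits(support, "bootstrap_support")) support$support
         else support
  labels <- tree$tip.label
  n <- length(labels)
  trav <- tree_traversal(tree)
  below <- vector("list", length(trav$children))
  node_lab <- rep("", tree$Nnode)
  for (u in trav$postorder) {
    kids <- trav$children[[u]]
    below[[u]] <- if (length(kids) == 0L) labels[u]
                  else sort(unlist(below[kids]))
    if (u > n && length(below[[u]]) >= 2L &&
        length(below[[u]]) <= n - 2L) {
      k <- split_key(below[[u]], labels)
      hit <- match(k, sup$clade)
      if (!is.na(hit))
        node_lab[u - n] <- as.character(round(sup$support[hit], digits))
    }
  }
  tree$node.label <- node_lab
  tree
}
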