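# Synthetic data with known truth: binary characters evolved on a known
# tree by a symmetric per-branch flip process, and karyotypes evolved by
# stochastic rearrangement events (fusion, fission, inversions, tandem
# fusion, sex-autosome translocation). Both exist so every pipeline stage
# is testable without any external download.

#' Simulate binary characters on a tree
#'
#' Each character evolves independently from the root towards the tips,
#' flipping state on each branch with that branch's probability (a
#' symmetric two-state process; probability, not a rate).
#'
#' @param tree a `phylo` tree (a basal trifurcation is used as the root).
#' @param n_characters number of characters (>= 1).
#' @param p per-branch change probability in `[0, 0.5)`; scalar or one
#'   value per edge of `tree`.
#' @param root_state_prob probability of state 1 at the root.
#' @param seed integer seed; identical seeds give identical output.
#' @param informative_only when `TRUE`, characters are redrawn until
#'   parsimony-informative (both states in at least two leaves each) —
#'   used by recovery experiments, where constant and autapomorphic
#'   characters carry no topological signal.
#' @return list: `matrix` (a [character_matrix()] over the tips), `flips`
#'   (data frame `character`, `parent`, `child` listing every change).
#' @export
simulate_characters <- function(tree, n_characters, p = 0.05,
                                root_state_prob = 0.5, seed = NULL,
                                informative_only = FALSE) {
  stopifnot(n_characters >= 1, all(p >= 0), all(p < 0.5),
            root_state_prob >= 0, root_state_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_edge <- nrow(tree$edge)
  if (length(p) == 1L) p <- rep(p, n_edge)
  stopifnot(length(p) == n_edge)
  trav <- tree_traversal(tree)
  n_tip <- trav$n_tip
  preorder <- rev(trav$postorder)
  edge_of <- integer(n_tip + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(n_edge)

  parents <- integer(n_tip + tree$Nnode)
  for (i in seq_len(n_edge)) parents[tree$edge[i, 2]] <- tree$edge[i, 1]
  draw <- function(k) {
    root_state <- rbinom(k, 1L, root_state_prob)
    flips <- matrix(rbinom(n_edge * k, 1L, rep(p, times = k)), nrow = n_edge)
    states <- matrix(0L, n_tip + tree$Nnode, k)
    states[trav$root, ] <- root_state
    for (u in preorder) {
      if (u == trav$root) next
      states[u, ] <- bitwXor(states[parents[u], ], flips[edge_of[u], ])
    }
    list(states = states, flips = flips)
  }
  is_informative <- function(col)
    sum(col == 0L) >= 2L && sum(col == 1L) >= 2L

  d <- draw(n_characters)
  if (informative_only) {
    tries <- 0L
    repeat {
      leaf <- d$states[seq_len(n_tip), , drop = FALSE]
      bad <- which(!apply(leaf, 2, is_informative))
      if (!length(bad)) break
      tries <- tries + 1L
      if (tries > 10000L)
        stop("could not draw informative characters; is p too small?")
      r <- draw(length(bad))
      d$states[, bad] <- r$states
      d$flips[, bad] <- r$flips
    }
  }
  leaf_states <- d$states[seq_len(n_tip), , drop = FALSE]
  states <- matrix(as.character(leaf_states), n_tip, n_characters,
                   dimnames = list(tree$tip.label,
                                   paste0("c", seq_len(n_characters))))
  fl <- which(d$flips == 1L, arr.ind = TRUE)
  flips <- if (nrow(fl) == 0L)
    data.frame(character = character(0), parent = integer(0),
               child = integer(0), stringsAsFactors = FALSE)
  else
    data.frame(character = paste0("c", fl[, 2]),
               parent = tree$edge[fl[, 1], 1],
               child = tree$edge[fl[, 1], 2],
               stringsAsFactors = FALSE)
  list(matrix = character_matrix(states), flips = flips)
}

# ---- karyotype simulation ----------------------------------------------

.EVENT_TYPES <- c("centric_fusion", "centric_fission",
                  "pericentric_inversion", "paracentric_inversion",
                  "tandem_fusion", "sex_autosome_translocation")

#' Default ancestral karyotype for simulations
#'
#' A 22-autosome construction embedding the six catalogue associations of
#' the ancestral Platyrrhini karyotype (3a/21, 5/7a, 2b/16b, 8a/18,
#' 14/15a, 10a/16a) plus sixteen single-segment chromosomes. A package
#' fixture for the simulator, not a scientific claim.
#'
#' @return a karyotype: list with `autosomes` (list of character vectors
#'   of segment ids), `x`, `y`, `translocated`.
#' @export
default_ancestral_karyotype <- function() {
  assoc <- list(c("3a", "21"), c("5a", "7a"), c("2b", "16b"),
                c("8a", "18"), c("14", "15a"), c("10a", "16a"))
  singles <- as.list(c("1", "2a", "3b", "4", "5b", "6", "7b", "9", "10b",
                       "11", "12", "13", "15b", "17", "19", "20", "22"))
  # 6 + 16 = 22 autosomes; "22" completes the single-segment set
  singles <- singles[1:16]
  list(autosomes = c(assoc, singles), x = "X", y = character(0),
       translocated = FALSE)
}

karyotype_segments <- function(k)
  sort(c(unlist(k$autosomes), k$y))

# apply one rearrangement; returns NULL when inapplicable
apply_event <- function(k, type) {
  aut <- k$autosomes
  n <- length(aut)
  if (type == "centric_fusion" || type == "tandem_fusion") {
    if (n < 2L) return(NULL)
    ij <- sample.int(n, 2L)
    joined <- c(aut[[ij[1]]], aut[[ij[2]]])
    aut[[ij[1]]] <- joined
    aut[ij[2]] <- NULL
    k$autosomes <- aut
    list(k = k, desc = paste0(type, "(",
                              paste(joined, collapse = "+"), ")"))
  } else if (type == "centric_fission") {
    big <- which(vapply(aut, length, 0L) >= 2L)
    if (!length(big)) return(NULL)
    i <- if (length(big) == 1L) big else sample(big, 1L)
    v <- aut[[i]]
    cut <- sample.int(length(v) - 1L, 1L)
    k$autosomes <- c(aut[-i], list(v[seq_len(cut)]),
                     list(v[-seq_len(cut)]))
    list(k = k, desc = paste0("centric_fission(",
                              paste(v, collapse = "+"), "@", cut, ")"))
  } else if (type %in% c("pericentric_inversion", "paracentric_inversion")) {
    big <- which(vapply(aut, length, 0L) >= 2L)
    if (!length(big)) return(NULL)
    i <- if (length(big) == 1L) big else sample(big, 1L)
    v <- aut[[i]]
    span <- sort(sample.int(length(v), 2L))
    v[span[1]:span[2]] <- rev(v[span[1]:span[2]])
    k$autosomes[[i]] <- v
    list(k = k, desc = paste0(type, "(", paste(aut[[i]], collapse = "+"),
                              "@", span[1], "-", span[2], ")"))
  } else if (type == "sex_autosome_translocation") {
    if (k$translocated || n < 1L) return(NULL)
    i <- sample.int(n, 1L)
    k$y <- aut[[i]]
    k$autosomes <- aut[-i]
    k$translocated <- TRUE
    list(k = k, desc = paste0("sex_autosome_translocation(",
                              paste(k$y, collapse = "+"), ")"))
  } else stop("unknown event type: ", type)
}

# export a simulated karyotype as a homology map against the ancestral
# segment alphabet (probe species "ANC")
karyotype_to_map <- function(k, target_species = "SIM") {
  seg_to_rows <- function(v) {
    do.call(rbind, lapply(v, function(s) {
      m <- regmatches(s, regexec("^([0-9]+|X|Y)([a-z][0-9]?)?$", s))[[1]]
      probe_segment(m[2], if (nzchar(m[3])) m[3] else NA_character_)
    }))
  }
  chroms <- lapply(seq_along(k$autosomes), function(i)
    target_chromosome(as.character(i), seg_to_rows(k$autosomes[[i]])))
  chroms <- c(chroms, list(target_chromosome("X", seg_to_rows("X"))))
  if (k$translocated) {
    chroms <- c(chroms, list(target_chromosome("Y", seg_to_rows(k$y))),
                list(target_chromosome("X2")))
  }
  n_aut <- length(k$autosomes)
  female <- 2L * n_aut + 2L + if (k$translocated) 2L else 0L
  male <- female - if (k$translocated) 1L else 0L
  probe_chroms <- unique(c(
    vapply(karyotype_segments(k), function(s)
      sub("^([0-9]+|X|Y).*$", "\\1", s), character(1)), "X"))
  homology_map("ANC", target_species, chroms,
               probe_chroms = probe_chroms,
               diploid_female = female, diploid_male = male,
               sex_system = if (k$translocated) "X1X2Y" else "XY")
}

#' Simulate karyotype evolution on a tree
#'
#' Rearrangement events are drawn per branch (Poisson count, weighted
#' event types) and applied to the evolving karyotype: fusions concatenate
#' two chromosomes' segment lists, fissions split one, inversions reverse
#' a contiguous sub-list, tandem fusions concatenate without centromere
#' merge, and a sex-autosome translocation moves one autosome onto the Y
#' (creating X1/X2 bookkeeping and unequal male/female 2n). No event
#' creates or destroys segments, so every ancestral segment appears
#' exactly once in each leaf karyotype. Inapplicable draws are resampled
#' (bounded), then skipped with a log entry.
#'
#' @param tree a `phylo` tree; leaves become taxa.
#' @param ancestral ancestral karyotype (see
#'   [default_ancestral_karyotype()]).
#' @param mean_events mean number of events per branch.
#' @param weights named non-negative event-type weights over
#'   `centric_fusion`, `centric_fission`, `pericentric_inversion`,
#'   `paracentric_inversion`, `tandem_fusion`,
#'   `sex_autosome_translocation`.
#' @param seed integer seed.
#' @param max_retries resampling bound for inapplicable events.
#' @param forced_events optional list of event types forced (in order) on
#'   every branch instead of random draws — used for targeted tests.
#' @return list: `maps` (named list of per-leaf [homology_map()]s),
#'   `truth` (a [character_matrix()] coding each event's presence per
#'   taxon), `events` (data frame `branch_child`, `event`, `desc`),
#'   `skipped` (log of abandoned draws).
#' @export
simulate_karyotype_evolution <- function(tree,
                                         ancestral = default_ancestral_karyotype(),
                                         mean_events = 2,
                                         weights = c(centric_fusion = 2,
                                                     centric_fission = 2,
                                                     pericentric_inversion = 1,
                                                     paracentric_inversion = 1,
                                                     tandem_fusion = 0.5,
                                                     sex_autosome_translocation = 0.1),
                                         seed = NULL, max_retries = 10,
                                         forced_events = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(weights >= 0), any(weights > 0),
            all(names(weights) %in% .EVENT_TYPES))
  trav <- tree_traversal(tree)
  preorder <- rev(trav$postorder)
  n_tip <- trav$n_tip
  parents <- integer(n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    parents[tree$edge[i, 2]] <- tree$edge[i, 1]
  alphabet <- karyotype_segments(ancestral)

  kary <- vector("list", n_tip + tree$Nnode)
  kary[[trav$root]] <- ancestral
  events <- data.frame(branch_child = integer(), event = character(),
                       desc = character(), stringsAsFactors = FALSE)
  skipped <- character(0)
  eid <- 0L
  for (u in preorder) {
    if (u == trav$root) next
    k <- kary[[parents[u]]]
    n_ev <- if (!is.null(forced_events)) length(forced_events)
            else rpois(1L, mean_events)
    for (j in seq_len(n_ev)) {
      done <- FALSE
      for (try in seq_len(max_retries)) {
        type <- if (!is.null(forced_events)) forced_events[[j]]
                else sample(names(weights), 1L, prob = weights)
        res <- apply_event(k, type)
        if (!is.null(res)) {
          k <- res$k
          stopifnot(identical(karyotype_segments(k), alphabet))
          eid <- eid + 1L
          events <- rbind(events, data.frame(
            branch_child = u, event = sprintf("e%03d_%s", eid, type),
            desc = res$desc, stringsAsFactors = FALSE))
          done <- TRUE
          break
        }
        if (!is.null(forced_events)) break
      }
      if (!done)
        skipped <- c(skipped, sprintf("branch to node %d: no applicable event after %d draws",
                                      u, max_retries))
    }
    kary[[u]] <- k
  }
  maps <- setNames(
    lapply(seq_len(n_tip), function(i)
      karyotype_to_map(kary[[i]], target_species = tree$tip.label[i])),
    tree$tip.label)
  # truth matrix: a character per event, 1 for taxa descending from its branch
  descendants <- function(u) {
    out <- integer(0); stack <- u
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n_tip) out <- c(out, v)
      stack <- c(stack, trav$children[[v]])
    }
    out
  }
  if (nrow(events)) {
    st <- matrix("0", n_tip, nrow(events),
                 dimnames = list(tree$tip.label, events$event))
    for (i in seq_len(nrow(events)))
      st[descendants(events$branch_child[i]), i] <- "1"
    truth <- character_matrix(st)
  } else truth <- NULL
  list(maps = maps, truth = truth, events = events, skipped = skipped)
}

# association-form observations from a set of leaf maps
maps_to_observations <- function(maps) {
  rows <- list()
  for (taxon in names(maps)) {
    assoc <- detect_associations(maps[[taxon]])
    forms <- unique(vapply(assoc, function(a)
      paste(sort(a$form$tokens$base), collapse = "/"), character(1)))
    for (f in forms)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon, form = f, state = "present",
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' End-to-end topology recovery experiment
#'
#' For each run: simulate data on a known tree, code characters
#' (directly for character simulations; via [detect_associations()] +
#' [build_matrix()] for karyotype simulations), run [exhaustive_search()],
#' and compare the maximum-parsimony result with the generating topology.
#' A run is *recovered* when the generating topology is the unique MP
#' tree. Deterministic given `seed` (run r uses sub-seed `seed + r`).
#'
#' @param tree generating `phylo` topology.
#' @param n_runs number of independent runs.
#' @param seed integer base seed.
#' @param sim `"characters"` or `"karyotype"`.
#' @param n_characters,p character-simulation settings (see
#'   [simulate_characters()]); recovery runs draw informative characters.
#' @param mean_events karyotype-simulation setting.
#' @param ... further arguments to the simulator.
#' @return list of class `recovery_report`: `fraction_recovered` (`NA`
#'   when no run produced a variable matrix), `mean_rf` (mean
#'   Robinson-Foulds distance of MP trees to the truth), `n_runs`,
#'   `n_undefined`, `runs` (per-run detail).
#' @export
recovery_experiment <- function(tree, n_runs, seed = 1,
                                sim = c("characters", "karyotype"),
                                n_characters = 30, p = 0.05,
                                mean_events = 2, ...) {
  sim <- match.arg(sim)
  truth_key <- canonical_topology(tree)
  recovered <- logical(n_runs)
  undefined <- logical(n_runs)
  rf <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r
    mat <- if (sim == "characters") {
      # with p = 0 no informative character can exist; fall back to the
      # unconditioned draw so the run reports as undefined
      simulate_characters(tree, n_characters = n_characters, p = p,
                          seed = run_seed, informative_only = any(p > 0),
                          ...)$matrix
    } else {
      sk <- simulate_karyotype_evolution(tree, mean_events = mean_events,
                                         seed = run_seed, ...)
      obs <- maps_to_observations(sk$maps)
      if (is.null(obs) || length(unique(obs$form)) < 1L) NULL
      else build_matrix(obs, taxa = tree$tip.label, missing_state = "0")
    }
    n_var <- if (is.null(mat)) 0L else
      sum(apply(mat$states, 2, function(col)
        length(unique(col[col != "?"])) > 1L))
    if (n_var == 0L) {
      undefined[r] <- TRUE
      rf[r] <- NA_real_
      next
    }
    res <- exhaustive_search(mat)
    keys <- vapply(res$mp_trees, canonical_topology, character(1))
    recovered[r] <- length(keys) == 1L && keys == truth_key
    rf[r] <- mean(vapply(res$mp_trees, rf_distance, numeric(1), t2 = tree))
  }
  frac <- if (all(undefined)) NA_real_
          else mean(recovered[!undefined])
  structure(list(fraction_recovered = frac,
                 mean_rf = mean(rf, na.rm = TRUE),
                 n_runs = n_runs, n_undefined = sum(undefined),
                 runs = data.frame(run = seq_len(n_runs),
                                   recovered = recovered,
                                   undefined = undefined, rf = rf)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  if (is.na(x$fraction_recovered))
    cat("recovery undefined: no run produced variable characters\n")
  else
    cat(sprintf("recovered generating topology in %.1f%% of %d runs (mean RF %.2f; %d undefined)\n",
                100 * x$fraction_recovered, x$n_runs, x$mean_rf,
                x$n_undefined))
  invisible(x)
}
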