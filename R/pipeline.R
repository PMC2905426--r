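# Orchestration: homology tables -> synteny reports -> character matrix ->
# exhaustive MP search -> statistics -> bootstrap -> rooted annotated tree,
# with a plain-text run report. Logging goes to standard error; results go
# to files; reruns with the same config and seed are byte-identical
# (timestamps are confined to the log).

#' Assemble a pipeline configuration
#'
#' @param maps list of map inputs, each `list(path=, probe=, target=)`
#'   (`probe`/`target` optional when the file carries pragmas).
#' @param catalogue path to an ancestral catalogue file (default: the
#'   packaged six-association Platyrrhini catalogue).
#' @param matrix `"fixture"` for the packaged reconstructed matrix, or a
#'   path to a NEXUS / TSV character matrix.
#' @param outgroup outgroup taxa (must be matrix taxa).
#' @param outgroup_policy `"ancestral"` or `"unknown"` (fixture coding).
#' @param bootstrap number of bootstrap replicates (0 disables).
#' @param seed integer seed for all randomness.
#' @param outdir output directory (created if absent).
#' @param verbose logging tier: 0 quiet, 1 normal, 2 chatty.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(maps = list(),
                            catalogue = NULL,
                            matrix = "fixture",
                            outgroup = c("BAR", "CAP"),
                            outgroup_policy = "ancestral",
                            bootstrap = 1000,
                            seed = 1,
                            outdir = "karyophy_out",
                            verbose = 1) {
  structure(list(maps = maps, catalogue = catalogue, matrix = matrix,
                 outgroup = outgroup, outgroup_policy = outgroup_policy,
                 bootstrap = bootstrap, seed = seed, outdir = outdir,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML mirroring the [pipeline_config()] fields.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) read and validate each homology map and write its synteny
#' and association report; (2) load or build the character matrix and
#' write it as NEXUS and TSV; (3) exhaustive MP search with statistics;
#' (4) bootstrap; (5) outgroup rooting and support annotation. Any stage
#' error aborts with a stage-named message.
#'
#' @param config a [pipeline_config()] (or a path to a YAML config).
#' @return the run report (list), invisibly; files are written to
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t0 <- Sys.time()
  log_lines <- character(0)
  timings <- c()
  say <- function(..., level = 1) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (config$verbose >= level) message("[karyophy] ", msg)
  }
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[name] <<- round(as.numeric(Sys.time() - s, units = "secs"), 3)
    out
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say("seed = ", config$seed, "; output -> ", config$outdir)
  catalogue <- stage("catalogue",
                     ancestral_platyrrhini_catalogue(config$catalogue))

  report <- list(seed = config$seed, synteny = list())
  for (m in config$maps) {
    nm <- tools::file_path_sans_ext(basename(m$path))
    map <- stage(paste0("read_map:", nm), {
      if (!file.exists(m$path)) stop("missing input path: ", m$path)
      read_homology_table(m$path, probe_species = m$probe %||% NULL,
                          target_species = m$target %||% NULL)
    })
    stage(paste0("synteny:", nm),
          write_synteny_report(map, file.path(config$outdir, nm), catalogue))
    sc <- count_signals(map)
    cls <- classify_synteny(map)
    assoc <- detect_associations(map)
    matched <- match_ancestral(assoc, catalogue)
    report$synteny[[nm]] <- list(
      probe = map$probe_species, target = map$target_species,
      signals_autosomal = sc$total_autosomal,
      signals_total = sc$total_with_sex,
      conserved = sum(cls$class %in% c("WHOLE", "ASSOCIATED")),
      n_associations = length(assoc),
      n_ancestral_matched = sum(!is.na(matched$target_chrom) &
                                  matched$found),
      ancestral_found = sum(matched$found))
    say(sprintf("%s: %d autosomal signals, %d associations (%d matching the ancestral catalogue)",
                nm, sc$total_autosomal, length(assoc),
                report$synteny[[nm]]$n_ancestral_matched))
  }

  mat <- stage("matrix", {
    if (identical(config$matrix, "fixture"))
      pitheciinae_matrix(outgroup_policy = config$outgroup_policy)
    else if (!file.exists(config$matrix))
      stop("missing input path: ", config$matrix)
    else if (grepl("\\.(nex|nexus)$", config$matrix, ignore.case = TRUE))
      from_nexus(config$matrix)
    else read_matrix_tsv(config$matrix)
  })
  stage("write_matrix", {
    to_nexus(mat, file.path(config$outdir, "matrix.nex"))
    write_matrix_tsv(mat, file.path(config$outdir, "matrix.tsv"))
  })
  say(sprintf("character matrix: %d taxa x %d characters",
              length(mat$taxa), nrow(mat$characters)))

  res <- stage("search", exhaustive_search(mat))
  stage("write_trees", {
    con <- file(file.path(config$outdir, "mp_trees.nwk"), "w")
    for (tr in res$mp_trees) writeLines(write_newick(tr), con)
    close(con)
    stats_df <- data.frame(
      tree_index = seq_along(res$mp_trees),
      length = res$length,
      ci = round_half_up(res$stats$ci),
      ri = round_half_up(res$stats$ri),
      hi = round_half_up(res$stats$hi),
      trees_examined = res$n_trees_examined)
    write.table(stats_df, file.path(config$outdir, "statistics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })
  say(sprintf("%d MP tree(s), length %d, CI %.3f RI %s HI %.3f (%d topologies examined)",
              length(res$mp_trees), res$length,
              round_half_up(res$stats$ci),
              ifelse(is.na(res$stats$ri), "NA",
                     sprintf("%.3f", round_half_up(res$stats$ri))),
              round_half_up(res$stats$hi), res$n_trees_examined))
  report$search <- list(n_mp_trees = length(res$mp_trees),
                        length = res$length,
                        ci = res$stats$ci, ri = res$stats$ri,
                        hi = res$stats$hi,
                        n_trees_examined = res$n_trees_examined)

  boot <- NULL
  if (config$bootstrap > 0) {
    boot <- stage("bootstrap",
                  bootstrap_support(mat, n_replicates = config$bootstrap,
                                    seed = config$seed))
    stage("write_bootstrap",
          write.table(boot$support,
                      file.path(config$outdir, "bootstrap.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE))
    say(sprintf("bootstrap: %d replicates", boot$n_replicates))
  }

  stage("rooting", {
    og <- intersect(config$outgroup, mat$taxa)
    if (length(og)) {
      rooted <- root_with_outgroup(res$mp_trees[[1]], og)
      if (!is.null(boot)) rooted <- annotate_support(rooted, boot)
      write_newick(rooted, file.path(config$outdir, "rooted_tree.nwk"))
      report$rooted_tree <- write_newick(rooted)
    }
  })

  report$timings <- as.list(timings)
  log_path <- file.path(config$outdir, "run_log.txt")
  writeLines(c(
    sprintf("karyophy %s | R %s", as.character(packageVersion("karyophy")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("started %s, elapsed %.2fs", format(t0),
            as.numeric(Sys.time() - t0, units = "secs")),
    sprintf("seed: %d", config$seed),
    paste0("timing ", names(timings), ": ", timings, "s"),
    log_lines), log_path)
  invisible(report)
}
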