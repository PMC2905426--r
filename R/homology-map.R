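# Domain types and I/O for cross-species chromosome painting homology maps.
#
# A homology map records, for one painting experiment, which target-species
# chromosomes carry material homologous to each probe-species chromosome.
# Granularity is the hybridization signal: one contiguous painted block.

.MORPHOLOGIES <- c("metacentric", "submetacentric", "acrocentric", "unknown")

# Cytological position ranks along a chromosome, pter -> qter. Used to order
# probe segments within a target chromosome when the source table gives
# positional qualifiers, and to expand a probe occupying two separate
# regions (written "region- region") into two ordered tokens.
.REGION_RANK <- c(
  "distal p" = 1, "p" = 2, "proximal p" = 3,
  "proximal q" = 4, "q" = 5, "distal q" = 6
)

#' Create a probe segment
#'
#' One hybridization signal: a block of a target chromosome painted by a
#' single probe chromosome.
#'
#' @param probe_chrom bare probe chromosome label ("1".."22", "X", "Y").
#' @param sub_segment optional lowercase sub-block letter ("a", "b", "a1"),
#'   used only where a source names it; `NA` otherwise.
#' @param region_note optional positional qualifier, e.g. `"q"`,
#'   `"distal p"`, `"proximal q + p"` (one contiguous block spanning both
#'   regions) or `"proximal p- distal q"` (two separate regions).
#' @return a one-row data frame with columns `probe_chrom`, `sub_segment`,
#'   `region_note`.
#' @export
probe_segment <- function(probe_chrom, sub_segment = NA_character_,
                          region_note = NA_character_) {
  stopifnot(is.character(probe_chrom), length(probe_chrom) == 1L,
            nzchar(probe_chrom))
  if (!is.na(sub_segment) && !grepl("^[a-z][0-9]?$", sub_segment))
    stop("sub_segment must match letter + optional digit: ", sub_segment)
  data.frame(probe_chrom = probe_chrom,
             sub_segment = as.character(sub_segment),
             region_note = as.character(region_note),
             stringsAsFactors = FALSE)
}

#' Create a target chromosome
#'
#' @param chrom_id chromosome label ("1".."23", "X", "Y", "X1", "X2").
#' @param segments data frame of probe segments (rows from
#'   [probe_segment()]), ordered as in the source table.
#' @param morphology one of `"metacentric"`, `"submetacentric"`,
#'   `"acrocentric"`, `"unknown"`.
#' @param annotations free-text notes (C-band, NOR facts); never computed on.
#' @return a list of class `target_chromosome`.
#' @export
target_chromosome <- function(chrom_id, segments = NULL,
                              morphology = "unknown",
                              annotations = character()) {
  stopifnot(is.character(chrom_id), length(chrom_id) == 1L, nzchar(chrom_id))
  morphology <- match.arg(morphology, .MORPHOLOGIES)
  if (is.null(segments))
    segments <- probe_segment("1")[0, , drop = FALSE]
  structure(list(chrom_id = chrom_id, segments = segments,
                 morphology = morphology,
                 annotations = as.character(annotations)),
            class = "target_chromosome")
}

# natural chromosome order: numbered first, then X, X1, X2, Y, rest
order_chrom_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  sex_rank <- match(ids, c("X", "X1", "X2", "Y"))
  key <- ifelse(!is.na(num), num,
                ifelse(!is.na(sex_rank), 1000 + sex_rank, 2000))
  order(key, ids)
}

is_sex_chrom <- function(id) id %in% c("X", "Y", "X1", "X2")

#' Construct a homology map
#'
#' @param probe_species probe species code (e.g. `"HSA"`, `"SOE"`).
#' @param target_species target species code (e.g. `"PIR"`, `"CCR"`).
#' @param chromosomes list of [target_chromosome()] objects.
#' @param probe_chroms declared probe chromosome set (bare labels). Defaults
#'   to `1:22, X, Y` for `"HSA"`/`"SOE"`, otherwise the labels observed.
#' @param diploid_female,diploid_male diploid numbers (2n).
#' @param sex_system `"XY"` or `"X1X2Y"` (multiple sex system created by a
#'   Y-autosome translocation; implies male 2n = female 2n - 1).
#' @return a list of class `homology_map`. Chromosomes are stored in
#'   natural id order.
#' @export
homology_map <- function(probe_species, target_species, chromosomes,
                         probe_chroms = NULL,
                         diploid_female = NA_integer_,
                         diploid_male = NA_integer_,
                         sex_system = c("XY", "X1X2Y")) {
  sex_system <- match.arg(sex_system)
  ids <- vapply(chromosomes, function(ch) ch$chrom_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate target chromosome declaration: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chromosomes <- chromosomes[order_chrom_ids(ids)]
  names(chromosomes) <- vapply(chromosomes, `[[`, character(1), "chrom_id")
  if (is.null(probe_chroms)) {
    probe_chroms <- if (probe_species %in% c("HSA", "SOE"))
      c(as.character(1:22), "X", "Y")
    else
      unique(unlist(lapply(chromosomes, function(ch) ch$segments$probe_chrom)))
  }
  structure(list(probe_species = probe_species,
                 target_species = target_species,
                 probe_chroms = as.character(probe_chroms),
                 diploid_female = as.integer(diploid_female),
                 diploid_male = as.integer(diploid_male),
                 sex_system = sex_system,
                 chromosomes = chromosomes),
            class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  cat(sprintf("Homology map: %s probes on %s (2n = %s female / %s male, %s)\n",
              x$probe_species, x$target_species,
              x$diploid_female, x$diploid_male, x$sex_system))
  nseg <- sum(vapply(x$chromosomes, function(ch) nrow(ch$segments), 0L))
  cat(sprintf("  %d target chromosomes, %d probe segments\n",
              length(x$chromosomes), nseg))
  invisible(x)
}

# parse a probe label, optionally prefixed by the species code:
# "HSA1" -> chrom "1"; "5a1" -> chrom "5", sub "a1"
parse_probe_label <- function(label, species) {
  x <- label
  if (startsWith(x, species)) x <- substring(x, nchar(species) + 1L)
  m <- regmatches(x, regexec("^([0-9]+|X[12]?|Y)([a-z][0-9]?)?$", x))[[1]]
  if (length(m) == 0L)
    stop("cannot parse probe chromosome label: '", label, "'")
  list(chrom = m[2], sub = if (nzchar(m[3])) m[3] else NA_character_)
}

# "1-22,X,Y" -> c("1",...,"22","X","Y")
parse_chrom_spec <- function(spec) {
  parts <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  out <- lapply(parts, function(p) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      rng <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      as.character(seq(rng[1], rng[2]))
    } else p
  })
  unlist(out)
}

# Parse a positional qualifier into one or more occupied regions with ranks.
# "-" separates regions the probe occupies separately (two tokens);
# "+" joins regions into one contiguous block (one token, mean rank).
# Unqualified segments get rank 0 (listed before ranked material, in table
# order). Unknown wording is tolerated with rank 0.
qualifier_regions <- function(note) {
  if (is.null(note) || is.na(note) || !nzchar(trimws(note)))
    return(data.frame(region = NA_character_, rank = 0, stringsAsFactors = FALSE))
  parts <- trimws(strsplit(note, "-", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  ranks <- vapply(parts, function(p) {
    sub_parts <- trimws(strsplit(p, "+", fixed = TRUE)[[1]])
    r <- .REGION_RANK[sub_parts]
    if (all(is.na(r))) 0 else mean(r, na.rm = TRUE)
  }, numeric(1))
  data.frame(region = parts, rank = unname(ranks), stringsAsFactors = FALSE)
}

read_pragmas <- function(lines) {
  pl <- grep("^#%", lines, value = TRUE)
  out <- list()
  for (l in pl) {
    kv <- regmatches(l, regexec("^#%\\s*([a-z_]+)\\s*:\\s*(.*)$", l))[[1]]
    if (length(kv) == 3L) out[[kv[2]]] <- c(out[[kv[2]]], trimws(kv[3]))
  }
  out
}

#' Read a homology map from its TSV dialect
#'
#' The dialect is one row per probe chromosome: a header line
#' `probe_chrom<TAB>targets`, with `targets` a semicolon-separated list of
#' `chrom[:qualifier]` entries; `#` starts a comment and `#%key: value`
#' lines carry map metadata (`probe_species`, `target_species`,
#' `diploid_female`, `diploid_male`, `sex_system`, `probe_chromosomes`,
#' `extra_chromosomes`, `morphology`, `annotation`). Example row:
#' `HSA1<TAB>10;9:q;23`.
#'
#' @param path file path.
#' @param probe_species,target_species species codes; override the file's
#'   pragmas when given.
#' @param probe_chroms declared probe chromosome set; overrides pragma.
#' @return a validated [homology_map()].
#' @export
read_homology_table <- function(path, probe_species = NULL,
                                target_species = NULL, probe_chroms = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- read_pragmas(lines)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0L || !identical(strsplit(body[1], "\t")[[1]],
                                       c("probe_chrom", "targets")))
    stop("expected header 'probe_chrom<TAB>targets' in ", path)
  probe_species <- probe_species %||% meta$probe_species %||%
    stop("probe_species neither given nor declared in ", path)
  target_species <- target_species %||% meta$target_species %||%
    stop("target_species neither given nor declared in ", path)
  if (is.null(probe_chroms) && !is.null(meta$probe_chromosomes))
    probe_chroms <- parse_chrom_spec(meta$probe_chromosomes)
  if (is.null(probe_chroms) && probe_species %in% c("HSA", "SOE"))
    probe_chroms <- c(as.character(1:22), "X", "Y")

  rows <- body[-1]
  chroms <- list()   # chrom_id -> segments data frame (probe-major order)
  for (i in seq_along(rows)) {
    f <- strsplit(rows[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop("malformed row ", i, " in ", path, ": ", rows[i])
    pl <- tryCatch(parse_probe_label(f[1], probe_species),
                   error = function(e)
                     stop("row ", i, " (", f[1], "): ", conditionMessage(e)))
    if (!is.null(probe_chroms) && !(pl$chrom %in% probe_chroms))
      stop("row ", i, ": unknown probe chromosome '", f[1],
           "' for species ", probe_species)
    entries <- trimws(strsplit(f[2], ";", fixed = TRUE)[[1]])
    entries <- entries[nzchar(entries)]
    for (e in entries) {
      cp <- strsplit(e, ":", fixed = TRUE)[[1]]
      cid <- trimws(cp[1])
      note <- if (length(cp) > 1L)
        trimws(paste(cp[-1], collapse = ":")) else NA_character_
      seg <- probe_segment(pl$chrom, pl$sub, note)
      chroms[[cid]] <- rbind(chroms[[cid]], seg)
    }
  }
  extra <- if (!is.null(meta$extra_chromosomes))
    parse_chrom_spec(meta$extra_chromosomes) else character()
  tc <- lapply(names(chroms), function(cid)
    target_chromosome(cid, chroms[[cid]]))
  for (cid in setdiff(extra, names(chroms)))
    tc <- c(tc, list(target_chromosome(cid)))
  map <- homology_map(probe_species, target_species, tc,
                      probe_chroms = probe_chroms,
                      diploid_female = meta$diploid_female %||% NA,
                      diploid_male = meta$diploid_male %||% NA,
                      sex_system = meta$sex_system %||% "XY")
  # optional per-chromosome morphology / annotations
  for (m in meta$morphology %||% character()) {
    kv <- strsplit(m, "=", fixed = TRUE)[[1]]
    cid <- trimws(kv[1])
    if (cid %in% names(map$chromosomes))
      map$chromosomes[[cid]]$morphology <-
        match.arg(trimws(kv[2]), .MORPHOLOGIES)
  }
  for (a in meta$annotation %||% character()) {
    kv <- strsplit(a, "=", fixed = TRUE)[[1]]
    cid <- trimws(kv[1])
    if (cid %in% names(map$chromosomes))
      map$chromosomes[[cid]]$annotations <-
        c(map$chromosomes[[cid]]$annotations, trimws(kv[2]))
  }
  viol <- validate_map(map)
  if (length(viol))
    stop("invalid homology map in ", path, ":\n  ",
         paste(viol, collapse = "\n  "))
  map
}

#' Write a homology map in the TSV dialect
#'
#' Emits metadata pragmas followed by one row per probe chromosome (in
#' declared probe order); [read_homology_table()] inverts it exactly at the
#' map level. Within-chromosome segment order is carried by positional
#' qualifiers, not by file layout.
#'
#' @param map a [homology_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(map, path) {
  ls <- c(
    sprintf("#%%probe_species: %s", map$probe_species),
    sprintf("#%%target_species: %s", map$target_species),
    sprintf("#%%probe_chromosomes: %s", paste(map$probe_chroms, collapse = ",")),
    if (!is.na(map$diploid_female))
      sprintf("#%%diploid_female: %d", map$diploid_female),
    if (!is.na(map$diploid_male))
      sprintf("#%%diploid_male: %d", map$diploid_male),
    sprintf("#%%sex_system: %s", map$sex_system)
  )
  empties <- names(map$chromosomes)[vapply(map$chromosomes,
                                           function(ch) nrow(ch$segments) == 0L,
                                           logical(1))]
  if (length(empties))
    ls <- c(ls, sprintf("#%%extra_chromosomes: %s",
                        paste(empties, collapse = ",")))
  for (ch in map$chromosomes) {
    if (ch$morphology != "unknown")
      ls <- c(ls, sprintf("#%%morphology: %s=%s", ch$chrom_id, ch$morphology))
    for (a in ch$annotations)
      ls <- c(ls, sprintf("#%%annotation: %s=%s", ch$chrom_id, a))
  }
  ls <- c(ls, "probe_chrom\ttargets")
  for (p in map$probe_chroms) {
    entries <- character()
    for (ch in map$chromosomes) {
      segs <- ch$segments
      hit <- which(segs$probe_chrom == p)
      for (i in hit) {
        lab <- paste0(map$probe_species, p,
                      ifelse(is.na(segs$sub_segment[i]), "",
                             segs$sub_segment[i]))
        ent <- if (is.na(segs$region_note[i])) ch$chrom_id
               else paste0(ch$chrom_id, ":", segs$region_note[i])
        entries <- c(entries, ent)
        # sub-segments of the same probe chrom share one row label
      }
    }
    if (length(entries))
      ls <- c(ls, paste0(map$probe_species, p, "\t",
                         paste(entries, collapse = ";")))
  }
  writeLines(ls, path, useBytes = TRUE)
  invisible(path)
}

#' Validate a homology map
#'
#' @param map a [homology_map()].
#' @return character vector of violation descriptions, each naming the
#'   chromosome and the rule; empty when all invariants hold.
#' @export
validate_map <- function(map) {
  v <- character()
  ids <- names(map$chromosomes)
  if (anyDuplicated(ids))
    v <- c(v, paste0("duplicate chromosome ids: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (ch in map$chromosomes) {
    segs <- ch$segments
    if (nrow(segs) == 0L && !is_sex_chrom(ch$chrom_id))
      v <- c(v, paste0("chromosome ", ch$chrom_id,
                       ": autosome with no probe segments"))
    bad <- setdiff(unique(segs$probe_chrom), map$probe_chroms)
    if (length(bad))
      v <- c(v, paste0("chromosome ", ch$chrom_id,
                       ": probe chromosome(s) not in declared ",
                       map$probe_species, " set: ",
                       paste(bad, collapse = ", ")))
    bad_sub <- segs$sub_segment[!is.na(segs$sub_segment) &
                                  !grepl("^[a-z][0-9]?$", segs$sub_segment)]
    if (length(bad_sub))
      v <- c(v, paste0("chromosome ", ch$chrom_id,
                       ": malformed sub-segment: ",
                       paste(bad_sub, collapse = ", ")))
    if (!ch$morphology %in% .MORPHOLOGIES)
      v <- c(v, paste0("chromosome ", ch$chrom_id,
                       ": unknown morphology ", ch$morphology))
  }
  if (map$sex_system == "X1X2Y" &&
      !is.na(map$diploid_female) && !is.na(map$diploid_male) &&
      map$diploid_male != map$diploid_female - 1L)
    v <- c(v, "sex system X1X2Y requires male 2n = female 2n - 1")
  if (map$sex_system == "XY" &&
      !is.na(map$diploid_female) && !is.na(map$diploid_male) &&
      map$diploid_male != map$diploid_female)
    v <- c(v, "sex system XY requires equal male and female 2n")
  v
}

#' Path to a packaged example/fixture file
#'
#' @param file file name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return full path (or a character vector of file names).
#' @export
karyophy_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "karyophy")))
  p <- system.file("extdata", file, package = "karyophy")
  if (!nzchar(p)) stop("no packaged file called ", file)
  p
}

#' Load the packaged painting-experiment fixtures
#'
#' The three cross-species painting experiments (human probes on
#' *Pithecia irrorata*, human probes on *Cacajao calvus rubicundus*,
#' *Saguinus oedipus* probes on *C. c. rubicundus*) transcribed from the
#' published homology table, plus a partial reconstructed map for
#' *Chiropotes utahicki* covering its association-bearing chromosomes.
#'
#' @return named list of [homology_map()] objects:
#'   `hsa_pir`, `hsa_ccr`, `soe_ccr`, `hsa_cut`.
#' @export
load_painting_maps <- function() {
  list(
    hsa_pir = read_homology_table(karyophy_example("hsa_pir.tsv")),
    hsa_ccr = read_homology_table(karyophy_example("hsa_ccr.tsv")),
    soe_ccr = read_homology_table(karyophy_example("soe_ccr.tsv")),
    hsa_cut = read_homology_table(karyophy_example("hsa_cut_reconstructed.tsv"))
  )
}
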