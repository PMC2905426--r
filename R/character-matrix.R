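# Binary chromosomal character matrices: presence (1) / absence (0) /
# unknown (?) of discrete chromosome forms or rearrangements per taxon,
# with TSV and NEXUS serialization.

.STATE_ALPHABET <- c("0", "1", "?")

#' Construct a binary character matrix
#'
#' @param states character matrix over `{"0","1","?"}`; rows are taxa
#'   (rownames required), columns are characters.
#' @param labels character labels (chromosome-form or rearrangement names);
#'   default: column names or `c1..cn`.
#' @param sources optional per-character source notes.
#' @return list of class `character_matrix` with `taxa`, `characters`
#'   (data frame `id`, `label`, `source`) and `states`.
#' @export
character_matrix <- function(states, labels = NULL, sources = NULL) {
  if (!is.matrix(states) || is.null(rownames(states)))
    stop("states must be a matrix with taxon rownames")
  if (ncol(states) == 0L || nrow(states) == 0L)
    stop("empty character matrix")
  states[] <- as.character(states)
  bad <- setdiff(unique(as.vector(states)), .STATE_ALPHABET)
  if (length(bad))
    stop("states outside alphabet {0,1,?}: ", paste(bad, collapse = ", "))
  if (anyDuplicated(rownames(states)))
    stop("duplicate taxon names")
  all_missing <- apply(states, 2, function(col) all(col == "?"))
  if (any(all_missing))
    stop("column(s) with no observed state: ",
         paste(which(all_missing), collapse = ", "))
  labels <- labels %||% colnames(states) %||%
    paste0("c", seq_len(ncol(states)))
  if (anyDuplicated(labels)) stop("duplicate character labels")
  sources <- sources %||% rep(NA_character_, ncol(states))
  colnames(states) <- labels
  structure(list(taxa = rownames(states),
                 characters = data.frame(id = paste0("c", seq_along(labels)),
                                         label = labels,
                                         source = sources,
                                         stringsAsFactors = FALSE),
                 states = states),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("Binary character matrix: %d taxa x %d characters\n",
              length(x$taxa), nrow(x$characters)))
  v <- sum(apply(x$states, 2, function(col) {
    s <- unique(col[col != "?"]); length(s) > 1L
  }))
  cat(sprintf("  %d variable, %d constant; taxa: %s\n",
              v, nrow(x$characters) - v, paste(x$taxa, collapse = ", ")))
  invisible(x)
}

normalize_obs_state <- function(s) {
  s <- tolower(trimws(as.character(s)))
  out <- c("present" = "1", "1" = "1", "absent" = "0", "0" = "0",
           "unknown" = "?", "?" = "?")[s]
  if (anyNA(out)) stop("unrecognized observation state(s): ",
                       paste(unique(s[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Build a character matrix from per-taxon form observations
#'
#' @param observations data frame with columns `taxon`, `form` and `state`
#'   (`present`/`absent`/`unknown` or `1`/`0`/`?`).
#' @param taxa optional taxon order (and taxa to include even when they
#'   have no observation); default: order of first appearance.
#' @param missing_state state assigned to unobserved (taxon, form) pairs:
#'   `"?"` (default) or `"0"`.
#' @return a [character_matrix()]; columns are sorted by form label, so the
#'   result is deterministic given the observation set.
#' @export
build_matrix <- function(observations, taxa = NULL, missing_state = "?") {
  stopifnot(all(c("taxon", "form", "state") %in% names(observations)))
  missing_state <- match.arg(missing_state, c("?", "0"))
  obs <- data.frame(taxon = as.character(observations$taxon),
                    form = as.character(observations$form),
                    state = normalize_obs_state(observations$state),
                    stringsAsFactors = FALSE)
  taxa <- taxa %||% unique(obs$taxon)
  if (length(taxa) < 2L) stop("need at least two taxa")
  if (!all(obs$taxon %in% taxa))
    stop("observations for taxa outside the taxon set: ",
         paste(setdiff(obs$taxon, taxa), collapse = ", "))
  dup <- duplicated(obs[c("taxon", "form")])
  if (any(dup)) {
    key <- paste(obs$taxon, obs$form)
    for (k in unique(key[dup])) {
      st <- unique(obs$state[key == k])
      if (length(st) > 1L)
        stop("contradictory observations for ", k)
    }
    obs <- obs[!dup, , drop = FALSE]
  }
  forms <- sort(unique(obs$form))
  states <- matrix(missing_state, length(taxa), length(forms),
                   dimnames = list(taxa, forms))
  states[cbind(match(obs$taxon, taxa), match(obs$form, forms))] <- obs$state
  character_matrix(states, labels = forms)
}

#' Read back a character matrix as an observation table
#'
#' Inverse of [build_matrix()]: one row per (taxon, form) pair.
#'
#' @param matrix a [character_matrix()].
#' @return data frame (`taxon`, `form`, `state`).
#' @export
matrix_observations <- function(matrix) {
  data.frame(
    taxon = rep(matrix$taxa, times = nrow(matrix$characters)),
    form = rep(matrix$characters$label, each = length(matrix$taxa)),
    state = as.vector(matrix$states),
    stringsAsFactors = FALSE)
}

#' Reconstructed Pitheciinae character matrix
#'
#' A documented five-taxon reconstruction of the chromosomal character set
#' for *Pithecia irrorata* (PIR), *Cacajao calvus rubicundus* (CCR) and
#' *Chiropotes utahicki* (CUT), with *Brachyteles arachnoides* (BAR) and
#' *Cebus apella* (CAP) as outgroups. Columns encode: the subfamily-wide
#' shared derived forms (fusion 2a/10b, acrocentric 15/14, acrocentric 19,
#' and the pericentric inversion producing 16a/10a/16a/10a); the CCR+CUT
#' shared derived forms (fission of 5 into 5a1/5a2, fusion 20/15/14,
#' acrocentric 5/7a); the PIR+CCR shared derived forms (acrocentric 7b,
#' acrocentric 12); the six ancestral Platyrrhini association retention
#' characters; and per-taxon autapomorphies. Each column carries its source
#' note. This is a reconstruction, not the original supplementary matrix;
#' when that file is available, read it with [from_nexus()] or
#' [read_matrix_tsv()] instead.
#'
#' @param outgroup_policy how to code the outgroups where no direct
#'   observation is encoded: `"ancestral"` (default; derived forms 0,
#'   ancestral retention characters 1 — the standard cladistic convention)
#'   or `"unknown"` (`?`).
#' @return a [character_matrix()] over taxa PIR, CCR, CUT, BAR, CAP.
#' @export
pitheciinae_matrix <- function(outgroup_policy = c("ancestral", "unknown")) {
  outgroup_policy <- match.arg(outgroup_policy)
  og_derived <- if (outgroup_policy == "ancestral") "0" else "?"
  og_ancestral <- if (outgroup_policy == "ancestral") "1" else "?"
  # each row: label, PIR, CCR, CUT, source
  derived <- list(
    c("fusion 2a/10b",            "1", "1", "1", "shared derived form of the whole subfamily"),
    c("acrocentric 15/14",        "1", "1", "1", "shared derived form of the whole subfamily"),
    c("acrocentric 19",           "1", "1", "1", "shared derived form of the whole subfamily"),
    c("inversion 16a/10a/16a/10a","1", "1", "1", "pericentric inversion of the ancestral 10a/16a, shared with Callicebus"),
    c("fission 5a1+5a2",          "0", "1", "1", "CCR+CUT: human 5 homologue fissioned"),
    c("fusion 20/15/14",          "0", "1", "1", "CCR+CUT: 14/15a fused with the 20 homologue"),
    c("acrocentric 5/7a",         "0", "1", "1", "CCR+CUT: 5/7a on a derived acrocentric"),
    c("acrocentric 7b",           "1", "1", "0", "PIR+CCR shared derived form"),
    c("acrocentric 12",           "1", "1", "0", "PIR+CCR shared derived form"),
    c("paracentric inversion 3a/21", "1", "0", "0", "PIR: 3a/21 modified by paracentric inversion"),
    c("association 13/22",        "1", "0", "0", "PIR: 13 and 22 homologues fused (PIR 8)"),
    c("association 1b/15b",       "1", "0", "0", "PIR: 1b and 15b homologues fused (PIR 9)"),
    c("Y-autosome translocation 11", "0", "1", "0", "CCR: human 11 homologue translocated to the Y (X1X2Y system)"),
    c("association 3/20/15/14",   "0", "1", "0", "CCR: 20/15/14 further fused with the 3/20 homologue (CCR 1)"),
    c("fission 2b/16b",           "0", "0", "1", "CUT: retained 2b/16b material distributed over two chromosomes")
  )
  retention <- lapply(c("3a/21", "5/7a", "2b/16b", "8a/18", "14/15a",
                        "10a/16a"),
                      function(f) c(paste0("association ", f), "1", "1", "1",
                                    "ancestral Platyrrhini association, retained"))
  rows <- c(derived, retention)
  og <- c(rep(og_derived, length(derived)),
          rep(og_ancestral, length(retention)))
  states <- t(vapply(seq_along(rows), function(i)
    c(rows[[i]][2:4], og[i], og[i]), character(5)))
  labels <- vapply(rows, `[[`, "", 1)
  ord <- order(labels)
  states <- states[ord, , drop = FALSE]
  dimnames(states) <- NULL
  m <- t(states)
  rownames(m) <- c("PIR", "CCR", "CUT", "BAR", "CAP")
  character_matrix(m, labels = labels[ord],
                   sources = vapply(rows, `[[`, "", 5)[ord])
}

#' Write / read a character matrix as TSV
#'
#' Taxa as rows, characters as columns; a leading `taxon` column. Source
#' notes, when present, are written as `#%source:` pragma lines.
#'
#' @param matrix a [character_matrix()].
#' @param path file path.
#' @return `path` invisibly (write); a [character_matrix()] (read).
#' @export
write_matrix_tsv <- function(matrix, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  src <- matrix$characters$source
  for (i in which(!is.na(src)))
    writeLines(sprintf("#%%source: %s=%s",
                       matrix$characters$label[i], src[i]), con)
  writeLines(paste(c("taxon", matrix$characters$label), collapse = "\t"), con)
  for (i in seq_along(matrix$taxa))
    writeLines(paste(c(matrix$taxa[i], matrix$states[i, ]), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- read_pragmas(lines)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "taxon") stop("expected leading 'taxon' column in ", path)
  labels <- header[-1]
  rows <- fields[-1]
  states <- t(vapply(rows, function(f) f[-1], character(length(labels))))
  rownames(states) <- vapply(rows, `[[`, "", 1)
  sources <- rep(NA_character_, length(labels))
  for (s in meta$source %||% character()) {
    kv <- regmatches(s, regexec("^([^=]+)=(.*)$", s))[[1]]
    i <- match(trimws(kv[2]), labels)
    if (!is.na(i)) sources[i] <- kv[3]
  }
  character_matrix(states, labels = labels, sources = sources)
}

#' Write a character matrix as a NEXUS DATA block
#'
#' Standard datatype, `SYMBOLS="01" MISSING=?`, with a `CHARSTATELABELS`
#' command carrying the character labels. Taxon labels containing spaces
#' are quoted.
#'
#' @param matrix a [character_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
to_nexus <- function(matrix, path) {
  if (!inherits(matrix, "character_matrix")) stop("not a character_matrix")
  quote_label <- function(x) ifelse(grepl("[ '()\\[\\]]", x),
                                    paste0("'", gsub("'", "''", x), "'"), x)
  nchar_ <- nrow(matrix$characters)
  ls <- c("#NEXUS", "", "BEGIN DATA;",
          sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                  length(matrix$taxa), nchar_),
          "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
          paste0("  CHARSTATELABELS ",
                 paste(sprintf("%d %s", seq_len(nchar_),
                               quote_label(gsub(" ", "_",
                                                matrix$characters$label))),
                       collapse = ", "), ";"),
          "  MATRIX")
  w <- max(nchar(quote_label(matrix$taxa))) + 2L
  for (i in seq_along(matrix$taxa))
    ls <- c(ls, sprintf("    %-*s%s", w, quote_label(matrix$taxa[i]),
                        paste(matrix$states[i, ], collapse = "")))
  ls <- c(ls, "  ;", "END;")
  writeLines(ls, path, useBytes = TRUE)
  invisible(path)
}

#' Read a character matrix from a NEXUS DATA block
#'
#' Accepts a standard-datatype DATA block with `SYMBOLS="01" MISSING=?`
#' (the matrix itself is parsed with `ape::read.nexus.data`); a
#' `CHARSTATELABELS` command, when present, supplies the character labels.
#'
#' @param path file path.
#' @return a [character_matrix()].
#' @export
from_nexus <- function(path) {
  dat <- ape::read.nexus.data(path)
  states <- t(vapply(dat, function(x) toupper(as.character(x)),
                     character(length(dat[[1]]))))
  bad <- setdiff(unique(as.vector(states)), .STATE_ALPHABET)
  if (length(bad))
    stop("NEXUS matrix contains symbols outside {0,1,?}: ",
         paste(bad, collapse = ", "))
  txt <- paste(readLines(path, encoding = "UTF-8"), collapse = "\n")
  labels <- NULL
  m <- regmatches(txt, regexpr("(?i)CHARSTATELABELS[^;]*;", txt, perl = TRUE))
  if (length(m) == 1L) {
    body <- sub(";$", "", sub("(?i)^CHARSTATELABELS\\s*", "", m, perl = TRUE))
    items <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
    labels <- vapply(items, function(it) {
      lab <- sub("^[0-9]+\\s+", "", it)
      gsub("''", "'", sub("^'(.*)'$", "\\1", lab))
    }, character(1), USE.NAMES = FALSE)
    labels <- gsub("_", " ", labels)
    if (length(labels) != ncol(states)) labels <- NULL
  }
  character_matrix(states, labels = labels)
}
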