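# Descriptive comparative cytogenetics on homology maps: signal counts,
# conserved-synteny classes, syntenic associations, ancestral matching.
#
# Counting unit is the hybridization signal (one probe segment); a probe
# chromosome split over three target chromosomes contributes three. The X
# is excluded from autosomal totals and from association detection; a
# segment of an autosomal probe sitting on the Y (Y-autosome translocation)
# counts as one autosomal-probe signal.

all_segments <- function(map) {
  out <- lapply(map$chromosomes, function(ch) {
    s <- ch$segments
    if (nrow(s)) cbind(s, target_chrom = ch$chrom_id,
                       stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Count hybridization signals per haploid set
#'
#' @param map a [homology_map()].
#' @param include_sex when `TRUE` the `total` field includes signals of the
#'   sex-chromosome probes (X, Y); autosomal-probe signals on a
#'   Y-autosome composite always count as autosomal.
#' @return list of class `signal_count` with `per_probe_chrom` (named
#'   integer vector over probe chromosomes with signals),
#'   `total_autosomal`, `total_with_sex` and `total`.
#' @export
count_signals <- function(map, include_sex = FALSE) {
  segs <- all_segments(map)
  if (is.null(segs) || nrow(segs) == 0L) {
    per <- integer(0)
    out <- list(per_probe_chrom = per, total_autosomal = 0L,
                total_with_sex = 0L, total = 0L)
    class(out) <- "signal_count"
    return(out)
  }
  per <- table(factor(segs$probe_chrom,
                      levels = map$probe_chroms[map$probe_chroms %in%
                                                  segs$probe_chrom]))
  per <- setNames(as.integer(per), names(per))
  aut <- !is_sex_chrom(names(per))
  if (!include_sex) per_out <- per[aut] else per_out <- per
  out <- list(per_probe_chrom = per_out,
              total_autosomal = sum(per[aut]),
              total_with_sex = sum(per),
              total = if (include_sex) sum(per) else sum(per[aut]))
  class(out) <- "signal_count"
  out
}

#' @export
print.signal_count <- function(x, ...) {
  cat(sprintf("%d autosomal signals per haploid set (%d incl. sex probes)\n",
              x$total_autosomal, x$total_with_sex))
  invisible(x)
}

#' Classify conserved synteny per probe chromosome
#'
#' A probe autosome with one signal has conserved synteny: `WHOLE` when its
#' signal is the only probe material on its target chromosome (it paints an
#' entire chromosome), `ASSOCIATED` when the target also carries other
#' probes' material. Two or more signals make it `SPLIT`.
#'
#' @param map a [homology_map()].
#' @return data frame (`probe_chrom`, `class`, `n_signals`) over autosomal
#'   probe chromosomes with at least one signal.
#' @export
classify_synteny <- function(map) {
  segs <- all_segments(map)
  if (is.null(segs) || nrow(segs) == 0L)
    return(data.frame(probe_chrom = character(), class = character(),
                      n_signals = integer(), stringsAsFactors = FALSE))
  segs <- segs[!is_sex_chrom(segs$probe_chrom), , drop = FALSE]
  seg_per_target <- vapply(map$chromosomes, function(ch) nrow(ch$segments), 0L)
  probes <- map$probe_chroms[map$probe_chroms %in% segs$probe_chrom]
  cls <- vapply(probes, function(p) {
    mine <- segs[segs$probe_chrom == p, , drop = FALSE]
    if (nrow(mine) >= 2L) return("SPLIT")
    if (seg_per_target[[mine$target_chrom]] == 1L) "WHOLE" else "ASSOCIATED"
  }, character(1))
  n <- vapply(probes, function(p) sum(segs$probe_chrom == p), integer(1))
  data.frame(probe_chrom = probes, class = unname(cls),
             n_signals = unname(n), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Parse a chromosome-form label
#'
#' A chromosome form is a slash-joined association string over probe
#' segments, e.g. `"3/20/15/14"`, `"5/7a"`, `"2a/10b"`.
#'
#' @param label the form label.
#' @return list of class `chromosome_form` with `label` and a data frame
#'   `tokens` (`base`, `sub`).
#' @export
chromosome_form <- function(label) {
  toks <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(toks) < 1L || any(!nzchar(toks)))
    stop("empty token in form label: ", label)
  parsed <- lapply(toks, function(t) {
    m <- regmatches(t, regexec("^([0-9]+|X[12]?|Y)([a-z][0-9]?)?$", t))[[1]]
    if (length(m) == 0L) stop("cannot parse form token: '", t, "'")
    c(base = m[2], sub = if (nzchar(m[3])) m[3] else NA_character_)
  })
  structure(list(label = label,
                 tokens = data.frame(base = vapply(parsed, `[[`, "", "base"),
                                     sub = vapply(parsed, `[[`, "", "sub"),
                                     stringsAsFactors = FALSE)),
            class = "chromosome_form")
}

#' @export
print.chromosome_form <- function(x, ...) {
  cat("chromosome form", x$label, "\n")
  invisible(x)
}

# Expand a target chromosome into ordered probe tokens. Each segment yields
# one token per occupied region ("A- B" qualifiers give two); tokens are
# ordered by cytological rank (pter -> qter), unqualified segments first in
# table order; adjacent identical tokens collapse.
chromosome_tokens <- function(ch) {
  segs <- ch$segments
  if (nrow(segs) == 0L)
    return(data.frame(token = character(), probe_chrom = character(),
                      rank = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    reg <- qualifier_regions(segs$region_note[i])
    tok <- paste0(segs$probe_chrom[i],
                  ifelse(is.na(segs$sub_segment[i]), "", segs$sub_segment[i]))
    data.frame(token = tok, probe_chrom = segs$probe_chrom[i],
               rank = reg$rank, ord = i, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d <- d[order(d$rank, d$ord), , drop = FALSE]
  keep <- c(TRUE, d$token[-1] != d$token[-nrow(d)])
  d <- d[keep, c("token", "probe_chrom", "rank"), drop = FALSE]
  row.names(d) <- NULL
  d
}

#' Detect syntenic associations
#'
#' A syntenic association is a target chromosome carrying material of two
#' or more probe chromosomes (or one probe chromosome twice in separate,
#' non-adjacent regions, as after an inversion of an ancestral two-segment
#' form). Sex chromosomes are excluded from the autosomal list; a
#' Y-autosome composite is reported separately in the `sex_linked`
#' attribute.
#'
#' @param map a [homology_map()].
#' @return list of class `association_set`; each element has
#'   `target_chrom`, `form` (a [chromosome_form()] whose token order follows
#'   positional qualifiers) and `n_probes`. Attribute `sex_linked` is a data
#'   frame of sex-chromosome composites carrying autosomal probe material.
#' @export
detect_associations <- function(map) {
  assoc <- list()
  sex_linked <- data.frame(target_chrom = character(), form = character(),
                           stringsAsFactors = FALSE)
  for (ch in map$chromosomes) {
    tok <- chromosome_tokens(ch)
    if (nrow(tok) == 0L) next
    if (is_sex_chrom(ch$chrom_id)) {
      aut <- tok$probe_chrom[!is_sex_chrom(tok$probe_chrom)]
      if (length(aut))
        sex_linked <- rbind(sex_linked, data.frame(
          target_chrom = ch$chrom_id,
          form = paste(c(tok$token[!is_sex_chrom(tok$probe_chrom)],
                         ch$chrom_id), collapse = "/"),
          stringsAsFactors = FALSE))
      next
    }
    if (nrow(tok) >= 2L) {
      assoc[[length(assoc) + 1L]] <- list(
        target_chrom = ch$chrom_id,
        form = chromosome_form(paste(tok$token, collapse = "/")),
        n_probes = length(unique(tok$probe_chrom)))
    }
  }
  structure(assoc, class = "association_set", sex_linked = sex_linked)
}

#' @export
print.association_set <- function(x, ...) {
  cat(length(x), "syntenic association(s)\n")
  for (a in x)
    cat(sprintf("  chromosome %s: %s\n", a$target_chrom, a$form$label))
  sl <- attr(x, "sex_linked")
  if (nrow(sl))
    cat("sex-linked composite(s):",
        paste(sprintf("%s (%s)", sl$form, sl$target_chrom), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
as.data.frame.association_set <- function(x, ...) {
  data.frame(
    target_chrom = vapply(x, `[[`, "", "target_chrom"),
    form = vapply(x, function(a) a$form$label, ""),
    n_probes = vapply(x, `[[`, 0L, "n_probes"),
    stringsAsFactors = FALSE)
}

# does the catalogue form's token multiset embed in the association's?
# sub-segment letters are compared only when present on both sides.
tokens_contain <- function(assoc_tokens, cat_tokens) {
  used <- rep(FALSE, nrow(assoc_tokens))
  for (i in seq_len(nrow(cat_tokens))) {
    ok <- which(!used &
                  assoc_tokens$base == cat_tokens$base[i] &
                  (is.na(cat_tokens$sub[i]) | is.na(assoc_tokens$sub) |
                     assoc_tokens$sub == cat_tokens$sub[i]))
    if (length(ok) == 0L) return(FALSE)
    used[ok[1]] <- TRUE
  }
  TRUE
}

form_tokens <- function(form) {
  if (inherits(form, "chromosome_form")) form$tokens
  else chromosome_form(form)$tokens
}

#' Match detected associations against an ancestral catalogue
#'
#' A catalogue form is *found* when its probe-chromosome token multiset is
#' contained in one association's token multiset. Comparison is
#' order-insensitive and letter-lenient (sub-segment letters compared only
#' when both sides carry one), so the inverted 16/10/16/10 form still
#' matches the ancestral 10a/16a association.
#'
#' @param associations an `association_set` from [detect_associations()],
#'   or a list of form labels / [chromosome_form()] objects.
#' @param ancestral_catalogue character vector of form labels (or list of
#'   [chromosome_form()]); see [ancestral_platyrrhini_catalogue()].
#' @return data frame (`catalogue_form`, `found`, `target_chrom`,
#'   `matched_form`).
#' @export
match_ancestral <- function(associations, ancestral_catalogue) {
  if (length(ancestral_catalogue) == 0L)
    stop("ancestral catalogue is empty")
  cat_forms <- lapply(ancestral_catalogue, function(f)
    if (inherits(f, "chromosome_form")) f else chromosome_form(f))
  out <- data.frame(
    catalogue_form = vapply(cat_forms, `[[`, "", "label"),
    found = FALSE, target_chrom = NA_character_,
    matched_form = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(cat_forms)) {
    for (a in associations) {
      at <- if (is.list(a) && !is.null(a$form)) form_tokens(a$form)
            else form_tokens(a)
      if (tokens_contain(at, cat_forms[[i]]$tokens)) {
        out$found[i] <- TRUE
        out$target_chrom[i] <- if (is.list(a) && !is.null(a$target_chrom))
          a$target_chrom else NA_character_
        out$matched_form[i] <- if (is.list(a) && !is.null(a$form))
          a$form$label else chromosome_form(a)$label
        break
      }
    }
  }
  out
}

#' The six-association ancestral Platyrrhini catalogue
#'
#' Human-homologous syntenic associations inferred for the ancestral New
#' World monkey karyotype: 3a/21, 5/7a, 2b/16b, 8a/18, 14/15a and 10a/16a.
#' Shipped as a plain text file (one form per line).
#'
#' @param path optional path to an alternative catalogue file.
#' @return character vector of form labels.
#' @export
ancestral_platyrrhini_catalogue <- function(path = NULL) {
  p <- path %||% karyophy_example("ancestral_platyrrhini.txt")
  x <- readLines(p, encoding = "UTF-8")
  trimws(x[!grepl("^\\s*(#|$)", x)])
}

#' Write the per-map synteny report
#'
#' Two TSV files: `<stem>_synteny.tsv` (`probe_chrom`, `class`,
#' `n_signals`) and `<stem>_associations.tsv` (`target_chrom`, `form`,
#' `n_probes`, `matched_catalogue_entry`).
#'
#' @param map a [homology_map()].
#' @param stem output path stem.
#' @param catalogue ancestral catalogue labels used to annotate matches.
#' @return named character vector of the files written, invisibly.
#' @export
write_synteny_report <- function(map, stem,
                                 catalogue = ancestral_platyrrhini_catalogue()) {
  cls <- classify_synteny(map)
  f1 <- paste0(stem, "_synteny.tsv")
  write.table(cls, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  assoc <- detect_associations(map)
  ad <- as.data.frame(assoc)
  m <- match_ancestral(assoc, catalogue)
  ad$matched_catalogue_entry <- vapply(seq_len(nrow(ad)), function(i) {
    hit <- m$catalogue_form[!is.na(m$target_chrom) &
                              m$target_chrom == ad$target_chrom[i]]
    if (length(hit)) paste(hit, collapse = ",") else ""
  }, character(1))
  f2 <- paste0(stem, "_associations.tsv")
  write.table(ad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(synteny = f1, associations = f2))
}
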