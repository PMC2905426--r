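# Signal counting, conserved-synteny classification, association
# detection and ancestral-catalogue matching.

maps <- load_painting_maps()

test_that("signal totals and per-probe multiplicities match the experiments", {
  sc <- count_signals(maps$hsa_pir)
  expect_identical(sc$total_autosomal, 32L)
  # probes painting two / three chromosomes
  expect_setequal(names(sc$per_probe_chrom)[sc$per_probe_chrom == 2L],
                  c("2", "7", "8", "10", "15", "16"))
  expect_setequal(names(sc$per_probe_chrom)[sc$per_probe_chrom == 3L],
                  c("1", "3"))
  expect_identical(count_signals(maps$hsa_ccr)$total_autosomal, 33L)
  expect_identical(count_signals(maps$soe_ccr)$total_autosomal, 28L)
  # with sex probes included the total is just the segment count
  expect_identical(count_signals(maps$hsa_pir, include_sex = TRUE)$total, 33L)
})

test_that("signal totals equal segment counts on arbitrary maps", {
  for (seed in 1:25) {
    m <- random_homology_map(seed)
    n_seg <- sum(vapply(m$chromosomes, function(ch) nrow(ch$segments), 0L))
    sc <- count_signals(m, include_sex = TRUE)
    expect_identical(sc$total_with_sex, n_seg)
    expect_identical(sum(sc$per_probe_chrom), n_seg)
  }
  empty <- homology_map("PRB", "TGT", list(), probe_chroms = "1")
  expect_identical(count_signals(empty)$total, 0L)
})

test_that("conserved-synteny classes reproduce both experiments", {
  pir <- classify_synteny(maps$hsa_pir)
  expect_identical(sum(pir$class %in% c("WHOLE", "ASSOCIATED")), 14L)
  expect_setequal(pir$probe_chrom[pir$class == "WHOLE"],
                  c("4", "6", "9", "11", "12", "17", "19", "20"))
  expect_setequal(pir$probe_chrom[pir$class == "ASSOCIATED"],
                  c("5", "13", "14", "18", "21", "22"))
  ccr <- classify_synteny(maps$hsa_ccr)
  expect_identical(sum(ccr$class %in% c("WHOLE", "ASSOCIATED")), 13L)
  expect_setequal(ccr$probe_chrom[ccr$class == "WHOLE"],
                  c("4", "6", "9", "11", "13", "17", "19", "22"))
  expect_identical(sum(ccr$class == "SPLIT"), 9L)
  expect_setequal(ccr$probe_chrom[ccr$n_signals == 3L], c("1", "3"))
  # one-probe toy map: trivially WHOLE
  toy <- homology_map("PRB", "TGT",
                      list(target_chromosome("1", probe_segment("1"))),
                      probe_chroms = "1")
  expect_identical(classify_synteny(toy)$class, "WHOLE")
})

test_that("association detection reproduces the printed catalogues", {
  ccr <- detect_associations(maps$hsa_ccr)
  expect_length(ccr, 9)
  forms <- vapply(ccr, function(a) a$form$label, "")
  # the four-token chromosome, in qualifier order
  expect_true("3/20/15/14" %in% forms)
  # the inverted ancestral 10a/16a: alternating pattern from two signals
  expect_true("16/10/16/10" %in% forms)
  canon <- function(f) vapply(strsplit(f, "/"), function(t)
    paste(sort(unique(t)), collapse = "/"), "", USE.NAMES = FALSE)
  expect_setequal(canon(forms),
                  canon(c("1/12", "2/10", "2/16", "3/20/15/14", "3/5",
                           "3/21", "5/7", "8/18", "10/16")))
  # Y-autosome composite reported separately, not as an autosomal entry
  expect_identical(attr(ccr, "sex_linked")$form, "11/Y")

  soe <- detect_associations(maps$soe_ccr)
  expect_length(soe, 5)
  soe_forms <- vapply(soe, function(a) a$form$label, "")
  expect_true("19/2/11" %in% soe_forms)
  expect_setequal(canon(soe_forms),
                  canon(c("19/2/11", "17/6", "21/12", "22/9", "2/1")))

  # single-segment targets yield no associations
  toy <- homology_map("PRB", "TGT",
                      list(target_chromosome("1", probe_segment("1")),
                           target_chromosome("2", probe_segment("2"))),
                      probe_chroms = c("1", "2"))
  expect_length(detect_associations(toy), 0)
})

test_that("the six printed PIR associations are the ancestral-matching ones", {
  pir <- detect_associations(maps$hsa_pir)
  m <- match_ancestral(pir, ancestral_platyrrhini_catalogue())
  expect_true(all(m$found))
  # exactly the six printed target chromosomes
  expect_setequal(m$target_chrom, c("1", "4", "6", "7", "13", "19"))
  canon <- function(f) vapply(strsplit(f, "/"), function(t)
    paste(sort(unique(t)), collapse = "/"), "", USE.NAMES = FALSE)
  expect_setequal(canon(m$matched_form),
                  canon(c("5/7", "2/16", "10/16", "8/18", "15/14", "3/21")))
})

test_that("ancestral matching finds all six associations in each taxon", {
  cat6 <- ancestral_platyrrhini_catalogue()
  expect_length(cat6, 6)
  for (nm in c("hsa_pir", "hsa_ccr", "hsa_cut")) {
    m <- match_ancestral(detect_associations(maps[[nm]]), cat6)
    expect_true(all(m$found), label = paste("all ancestral found in", nm))
  }
  # the inverted form matches via token multisets
  cut <- detect_associations(maps$hsa_cut)
  m <- match_ancestral(cut, "10a/16a")
  expect_true(m$found)
  expect_identical(m$matched_form, "16/10/16/10")
  # empty association list: everything absent
  m0 <- match_ancestral(list(), cat6)
  expect_false(any(m0$found))
  expect_error(match_ancestral(cut, character()), "empty")
})

test_that("classification partitions probes and agrees with detection", {
  for (seed in 1:25) {
    m <- random_homology_map(seed)
    cls <- classify_synteny(m)
    segs <- karyophy:::all_segments(m)
    probes_with_signal <- unique(segs$probe_chrom[!karyophy:::is_sex_chrom(segs$probe_chrom)])
    expect_identical(nrow(cls), length(probes_with_signal))
    expect_true(all(cls$class %in% c("WHOLE", "ASSOCIATED", "SPLIT")))
    expect_identical(cls$class == "SPLIT", cls$n_signals >= 2L)
    assoc <- detect_associations(m)
    assoc_targets <- vapply(assoc, `[[`, "", "target_chrom")
    for (i in seq_len(nrow(cls))) {
      p <- cls$probe_chrom[i]
      tgt <- segs$target_chrom[segs$probe_chrom == p]
      on_assoc <- any(tgt %in% assoc_targets)
      if (cls$class[i] == "ASSOCIATED") expect_true(on_assoc)
      if (cls$class[i] == "WHOLE") expect_false(tgt[1] %in% assoc_targets)
    }
  }
})

test_that("synteny report files round their content through TSV", {
  stem <- file.path(withr::local_tempdir(), "pir")
  files <- write_synteny_report(maps$hsa_pir, stem)
  cls <- read.delim(paste0(stem, "_synteny.tsv"),
                    colClasses = c(probe_chrom = "character"))
  expect_identical(nrow(cls), 22L)
  assoc <- read.delim(paste0(stem, "_associations.tsv"),
                      colClasses = "character")
  expect_identical(nrow(assoc), 9L)
  expect_identical(sum(nzchar(assoc$matched_catalogue_entry)), 6L)
})
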