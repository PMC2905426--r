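# Character and karyotype simulators and the recovery experiment.

tr5 <- read_newick("((A,B),C,(D,E));")

test_that("character simulation is deterministic and respects p = 0", {
  s0 <- simulate_characters(tr5, 40, p = 0, seed = 3)
  expect_true(all(apply(s0$matrix$states, 2,
                        function(col) length(unique(col)) == 1L)))
  expect_identical(nrow(s0$flips), 0L)
  a <- simulate_characters(tr5, 60, p = 0.1, seed = 11)
  b <- simulate_characters(tr5, 60, p = 0.1, seed = 11)
  expect_identical(a$matrix$states, b$matrix$states)
  expect_identical(a$flips, b$flips)
  c <- simulate_characters(tr5, 60, p = 0.1, seed = 12)
  expect_false(identical(a$matrix$states, c$matrix$states))
})

test_that("fraction of variable characters matches exact enumeration", {
  p <- 0.05
  q <- variable_fraction_oracle(tr5, p)
  s <- simulate_characters(tr5, 1000, p = p, seed = 2024)
  obs <- mean(apply(s$matrix$states, 2,
                    function(col) length(unique(col)) > 1L))
  se <- sqrt(q * (1 - q) / 1000)
  expect_lt(abs(obs - q), 3 * se)
})

test_that("rearrangements conserve segments and signals", {
  # zero events: leaves identical to the ancestor, catalogue recovered
  sk0 <- simulate_karyotype_evolution(tr5, mean_events = 0, seed = 5)
  forms <- vapply(detect_associations(sk0$maps$A), function(a)
    a$form$label, "")
  expect_setequal(forms, c("3a/21", "5a/7a", "2b/16b", "8a/18", "14/15a",
                           "10a/16a"))
  m <- match_ancestral(detect_associations(sk0$maps$A),
                       ancestral_platyrrhini_catalogue())
  expect_true(all(m$found))
  for (nm in names(sk0$maps))
    expect_identical(sk0$maps[[nm]]$chromosomes, sk0$maps$A$chromosomes)

  # one forced fusion per branch (3-taxon tree: one branch per leaf):
  # signal totals unchanged, one chromosome fewer
  tr3 <- read_newick("(A,B,C);")
  skf <- simulate_karyotype_evolution(tr3, seed = 8,
                                      forced_events = list("centric_fusion"))
  anc_n_aut <- length(default_ancestral_karyotype()$autosomes)
  n_seg <- length(ancestral_alphabet())
  for (nm in names(skf$maps)) {
    mp <- skf$maps[[nm]]
    expect_identical(count_signals(mp, include_sex = TRUE)$total, n_seg)
    aut <- setdiff(names(mp$chromosomes), c("X", "X1", "X2", "Y"))
    expect_length(aut, anc_n_aut - 1L)
  }

  # forced sex-autosome translocation: X1X2Y bookkeeping
  skt <- simulate_karyotype_evolution(tr3, seed = 9,
                                      forced_events = list("sex_autosome_translocation"))
  mp <- skt$maps$A
  expect_identical(mp$sex_system, "X1X2Y")
  expect_identical(mp$diploid_male, mp$diploid_female - 1L)
  expect_true(all(c("Y", "X2") %in% names(mp$chromosomes)))
  expect_gt(nrow(mp$chromosomes$Y$segments), 0)

  # random histories never create or destroy segments
  for (seed in 1:10) {
    sk <- simulate_karyotype_evolution(tr5, mean_events = 3, seed = seed)
    for (nm in names(sk$maps))
      expect_identical(map_segment_ids(sk$maps[[nm]]), ancestral_alphabet())
  }

  # fusions alone leave every leaf's signal total unchanged
  skF <- simulate_karyotype_evolution(tr5, mean_events = 2, seed = 21,
                                      weights = c(centric_fusion = 1))
  for (nm in names(skF$maps))
    expect_identical(count_signals(skF$maps[[nm]], include_sex = TRUE)$total,
                     n_seg)
})

test_that("the event truth matrix codes descendants of each branch", {
  sk <- simulate_karyotype_evolution(tr5, mean_events = 2, seed = 31)
  if (!is.null(sk$truth)) {
    expect_identical(sk$truth$taxa, tr5$tip.label)
    expect_identical(nrow(sk$truth$characters), nrow(sk$events))
    expect_true(all(sk$truth$states %in% c("0", "1")))
    expect_true(all(colSums(sk$truth$states == "1") >= 1))
  }
})

test_that("recovery is undefined without variable characters", {
  rec <- recovery_experiment(tr5, n_runs = 3, seed = 1,
                             sim = "characters", p = 0,
                             n_characters = 5)
  expect_true(is.na(rec$fraction_recovered))
  expect_identical(rec$n_undefined, 3L)
})

test_that("recovery runs are reproducible and degrade with saturation", {
  r1 <- recovery_experiment(tr5, n_runs = 20, seed = 17,
                            sim = "characters")
  r2 <- recovery_experiment(tr5, n_runs = 20, seed = 17,
                            sim = "characters")
  expect_identical(r1$runs, r2$runs)
  expect_gte(r1$fraction_recovered, 0.9)

  # saturation: many events per branch destroy parsimony signal
  few <- recovery_experiment(tr5, n_runs = 100, seed = 23,
                             sim = "karyotype", mean_events = 2)
  many <- recovery_experiment(tr5, n_runs = 100, seed = 23,
                              sim = "karyotype", mean_events = 8)
  expect_gt(few$fraction_recovered, many$fraction_recovered)
})
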