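test_that("the default generator config pools to the planted cardinalities", {
  cfg <- synthetic_config(seed = 3)
  sigs <- generate_disease_signatures(cfg)
  expect_identical(length(sigs), 3L)
  pooled <- pool_signatures(sigs)
  expect_identical(length(pooled$up), 419L)
  expect_identical(length(pooled$down), 301L)
  expect_identical(length(signature_universe(pooled)), 716L)
  # the 4 conflict genes appear in both pooled directions
  expect_identical(length(intersect(pooled$up$members, pooled$down$members)), 4L)
})

test_that("a single conflict-free study pools to itself", {
  cfg <- synthetic_config(n_studies = 1, pooled_up = 20, pooled_down = 15,
                          pooled_universe = 35, drug_in_universe = 6,
                          drug_in_up = 4, drug_in_down = 2,
                          drug_source_size = 20, drug_extra_targets = 2,
                          inject_symbols = character(0),
                          pathway_plan = default_pathway_plan()[8, ],
                          seed = 9)
  sigs <- generate_disease_signatures(cfg)
  pooled <- pool_signatures(sigs)
  expect_identical(pooled$up$members, sigs[[1]]$up$members)
  expect_identical(pooled$down$members, sigs[[1]]$down$members)
})

test_that("different seeds change gene identities but not cardinalities", {
  b1 <- generate_bundle(small_synth_config(1), tempfile())
  b2 <- generate_bundle(small_synth_config(2), tempfile())
  v1 <- venn_counts(b1$pooled, map_homologs(b1$drug, b1$homology)$mapped)
  v2 <- venn_counts(b2$pooled, map_homologs(b2$drug, b2$homology)$mapped)
  expect_identical(unclass(v1), unclass(v2))
  expect_false(identical(b1$pooled$up$members, b2$pooled$up$members))
})

test_that("identical config and seed give byte-identical bundle files", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_bundle(small_synth_config(5), d1)
  generate_bundle(small_synth_config(5), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("random feasible plantings are reproduced exactly (round-trip property)", {
  set.seed(77)
  for (rep in 1:40) {
    U <- sample(30:120, 1)
    up <- sample(10:(U - 5), 1)
    down <- sample((U - up):(U - 1), 1)  # up + down >= U
    shared <- up + down - U
    diu <- pick1(0:min(up + down - shared, 20))
    # split drug overlap across up/down respecting the venn identity
    triple <- pick1(0:min(shared, diu))
    diup <- min(up - shared + triple, pick1(triple:min(diu, up)))
    didn <- diu - diup + triple
    if (didn > down - shared + triple || didn < triple) next
    cfg <- try(synthetic_config(
      n_studies = sample(1:3, 1), pooled_up = up, pooled_down = down,
      pooled_universe = U, drug_in_universe = diu, drug_in_up = diup,
      drug_in_down = didn, drug_source_size = 60, drug_extra_targets = 4,
      inject_symbols = character(0),
      pathway_plan = data.frame(name = "P", background_hits = min(3L, up),
                                foreground_hits = min(1L, diup),
                                decoy_size = 5L, stringsAsFactors = FALSE),
      seed = rep), silent = TRUE)
    if (inherits(cfg, "try-error")) next
    sigs <- generate_disease_signatures(cfg)
    pooled <- pool_signatures(sigs)
    bundle <- generate_drug_bundle(cfg, pooled)
    vc <- venn_counts(pooled, map_homologs(bundle$drug, bundle$homology)$mapped)
    expect_identical(
      c(vc$n_universe, vc$n_up, vc$n_down, vc$n_universe_drug,
        vc$n_up_drug, vc$n_down_drug),
      c(U, up, down, diu, diup, didn))
  }
})

test_that("pathway planting hits the planned background and foreground counts exactly", {
  cfg <- small_synth_config(21)
  b <- generate_bundle(cfg, tempfile())
  bg <- b$pooled$up$members
  fg <- b$commonality$members
  for (i in seq_len(nrow(cfg$pathway_plan))) {
    pw <- b$collection$pathways[[cfg$pathway_plan$name[i]]]
    expect_identical(length(intersect(bg, pw)), cfg$pathway_plan$background_hits[i])
    expect_identical(length(intersect(fg, pw)), cfg$pathway_plan$foreground_hits[i])
  }
})

test_that("infeasible configurations fail with constructive errors", {
  expect_error(synthetic_config(pooled_up = 10, pooled_down = 10,
                                pooled_universe = 30),
               class = "sigreverse_infeasible_config")
  expect_error(synthetic_config(drug_in_universe = 10, drug_in_up = 4,
                                drug_in_down = 4),
               class = "sigreverse_infeasible_config")
  expect_error(synthetic_config(drug_in_up = 500),
               class = "sigreverse_infeasible_config")
  expect_error(synthetic_config(multiplicity_probs = c(0.5, 0.5, 0.5)),
               class = "sigreverse_infeasible_config")
  bad_plan <- data.frame(name = "P", background_hits = 9L,
                         foreground_hits = 50L, decoy_size = 1L)
  expect_error(synthetic_config(pathway_plan = bad_plan),
               class = "sigreverse_infeasible_config")
})

test_that("the bundled paper-like YAML config matches the in-code defaults", {
  yml <- system.file("extdata", "paper_like.yaml", package = "sigreverse")
  cfg <- read_synthetic_config(yml)
  ref <- synthetic_config()
  for (f in setdiff(names(unclass(ref)), "pathway_plan")) {
    expect_identical(cfg[[f]], ref[[f]], info = f)
  }
  expect_equal(cfg$pathway_plan, ref$pathway_plan)
})
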