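# In-code fixture builders shared across test files.

# length-1-safe random picker
pick1 <- function(v) v[sample.int(length(v), 1L)]

# quick directional signature from character vectors
sig <- function(up, down, label = "s", species = "human") {
  directional_signature(up, down, study_label = label, species = species)
}

# write a one-symbol-per-line gene list, returning the path
write_list <- function(genes, path = tempfile(fileext = ".txt")) {
  writeLines(genes, path)
  path
}

# a 10-gene hand-enumerable pipeline input set:
#   pooled up = {U1..U4, B1}, down = {D1..D3, B1}  (B1 up in study 1, down in study 2)
#   drug sources g1..g5; g1->U1, g2->U2, g3->D1, g4 unmapped, g5->X1 (outside)
# mapped drug = {U1, U2, D1, X1}: universe 8, up 5, down 4,
# universe∩drug = 3, up∩drug = 2, down∩drug = 1, commonality = {U1, U2}
make_toy_inputs <- function(dir = tempfile("toy")) {
  dir.create(dir)
  p <- list(
    drug = write_list(c("# drug", "g1", "g2", "g3", "g4", "g5"),
                      file.path(dir, "drug.txt")),
    homology = {
      f <- file.path(dir, "hom.tsv")
      writeLines(c("# src\ttgt", "g1\tU1", "g2\tU2", "g3\tD1", "g5\tX1"), f)
      f
    },
    signatures = list(
      list(up = write_list(c("U1", "U2", "B1"), file.path(dir, "s1_up.txt")),
           down = write_list(c("D1", "D2"), file.path(dir, "s1_down.txt"))),
      list(up = write_list(c("U3", "U4"), file.path(dir, "s2_up.txt")),
           down = write_list(c("D3", "B1"), file.path(dir, "s2_down.txt")))
    ),
    gmt = {
      f <- file.path(dir, "p.gmt")
      writeLines(c("PW1\tdesc\tU1\tU2\tD5", "PW2\tdesc\tU3\tZ9"), f)
      f
    }
  )
  p
}

# small feasible synthetic config for fast round-trip tests
small_synth_config <- function(seed, ...) {
  synthetic_config(
    n_studies = 2, pooled_up = 40, pooled_down = 30, pooled_universe = 65,
    drug_in_universe = 12, drug_in_up = 9, drug_in_down = 4,
    drug_source_size = 30, drug_extra_targets = 5,
    pathway_plan = data.frame(
      name = c("PA", "PB"), background_hits = c(6L, 4L),
      foreground_hits = c(3L, 2L), decoy_size = c(10L, 5L),
      stringsAsFactors = FALSE),
    seed = seed, ...)
}
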