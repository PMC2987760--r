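test_that("GMT files parse with per-pathway dedup and informative errors", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tA\tA\tB", "P2\tdesc\tC"), f)
  col <- read_gmt(f)
  expect_identical(length(col), 2L)
  expect_identical(col$pathways$P1, c("A", "B"))

  writeLines(c("P1\tdesc\tA", "P1\tdesc\tB"), f)
  expect_error(read_gmt(f), class = "sigreverse_domain_error")

  writeLines(c("P1\tdesc\tA", "P2\tdesc"), f)
  err <- expect_error(read_gmt(f), class = "sigreverse_malformed_row")
  expect_match(conditionMessage(err), "line 2")

  writeLines(character(0), f)
  expect_warning(empty <- read_gmt(f), "no data lines")
  expect_identical(length(empty), 0L)
})

test_that("random GMT collections round-trip through write_gmt with oracle sizes", {
  set.seed(13)
  sets <- lapply(1:50, function(i) {
    unique(sprintf("G%03d", sample.int(400, sample(1:30, 1))))
  })
  names(sets) <- sprintf("PW%02d", 1:50)
  col <- pathway_collection(sets)
  expect_identical(unname(lengths(col$pathways)),
                   unname(vapply(sets, function(s) length(unique(s)), 1L)))
  f <- tempfile(fileext = ".gmt")
  write_gmt(col, f)
  back <- read_gmt(f)
  expect_identical(back$pathways, col$pathways)
})

test_that("pathway enrichment counts membership within the background", {
  bg <- gene_set(sprintf("B%03d", 1:419), "background")
  fg <- gene_set(sprintf("B%03d", 1:41), "foreground")
  pw <- c(sprintf("B%03d", 39:41),          # 3 foreground hits
          sprintf("B%03d", 100:105),        # 6 background-only hits
          sprintf("X%03d", 1:50))           # outside background: ignored
  rec <- pathway_enrichment(fg, bg, pw, "mapk_like", convention = "point")
  expect_identical(c(rec$background_size, rec$background_hits,
                     rec$foreground_size, rec$foreground_hits),
                   c(419L, 9L, 41L, 3L))
  expect_equal(round(rec$p_point, 3), 0.041)
  expect_true(rec$significant)
  expect_identical(rec$hit_genes, sprintf("B%03d", 39:41))

  # invariance to genes outside the background
  rec2 <- pathway_enrichment(fg, bg, c(pw, sprintf("Y%03d", 1:200)), "mapk_like",
                             convention = "point")
  expect_equal(rec2[c("background_hits", "foreground_hits", "p_point", "p_upper")],
               rec[c("background_hits", "foreground_hits", "p_point", "p_upper")])
})

test_that("degenerate and closed-form enrichment cases behave", {
  bg <- gene_set(sprintf("B%02d", 1:10), "bg")
  fg <- gene_set(sprintf("B%02d", 1:3), "fg")
  # disjoint pathway
  rec0 <- pathway_enrichment(fg, bg, c("Z1", "Z2"), "none")
  expect_identical(c(rec0$background_hits, rec0$foreground_hits), c(0L, 0L))
  expect_identical(rec0$p_upper, 1)
  expect_false(rec0$significant)
  # foreground fully inside the pathway: P = C(3,3)C(7,0)/C(10,3) = 1/120
  rec1 <- pathway_enrichment(fg, bg, sprintf("B%02d", 1:3), "full")
  expect_equal(rec1$p_point, 1 / 120, tolerance = 1e-14)

  err <- expect_error(
    pathway_enrichment(gene_set(c("B01", "Q99"), "fg"), bg, "B01", "x"),
    class = "sigreverse_containment_error")
  expect_match(conditionMessage(err), "Q99")
  expect_error(pathway_enrichment(fg, gene_set(character(0), "bg"), "B01", "x"),
               class = "sigreverse_domain_error")
})

test_that("pathway scans are deterministically ordered and honor min_hits and BH", {
  bg <- gene_set(sprintf("B%03d", 1:419), "bg")
  fg <- gene_set(sprintf("B%03d", 1:41), "fg")
  sets <- list(
    STRONG = c(sprintf("B%03d", 40:41), sprintf("B%03d", 39), sprintf("B%03d", 200:205)),
    SMALLK = c(sprintf("B%03d", 41), "ZDECOY1"),   # k = 1: ineligible
    WEAK = c(sprintf("B%03d", 300:310))
  )
  col <- pathway_collection(sets)
  scan <- scan_pathways(fg, bg, col, convention = "point")
  expect_identical(scan$pathway, scan$pathway[order(scan$p, scan$pathway)])
  expect_false(scan$eligible[scan$pathway == "SMALLK"])
  expect_false(scan$significant[scan$pathway == "SMALLK"])
  expect_true(scan$significant[scan$pathway == "STRONG"])

  scan_bh <- scan_pathways(fg, bg, col, convention = "point", bh = TRUE)
  ok <- scan_bh$eligible
  expect_true(all(scan_bh$p_adj[ok] >= scan_bh$p[ok] - 1e-15))

  empty <- scan_pathways(fg, bg, pathway_collection(list()))
  expect_identical(nrow(empty), 0L)
})
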