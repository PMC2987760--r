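# Exact-combinatorial synthetic input generator.
#
# The generator plants prescribed cardinalities by partitioning a synthetic
# gene universe and assigning genes to studies, to the drug set (through a
# lossy many-to-many homology table) and to pathways, rather than sampling
# memberships from distributions. The downstream statistics depend only on
# set cardinalities, so exact planting makes every stage testable against
# known counts. Synthetic symbols carry reserved prefixes (SYNDS/SYNHX/
# SYNCG/SYNPD) so that a handful of real human symbols (BRAF, PAK1, PRKCA)
# can be injected without collision.

#' Default pathway plan for the synthetic collection
#'
#' One row per pathway: the planted number of background hits (members of
#' the disease-upregulated background), foreground hits (members of the
#' commonality set), and decoy genes outside the background used to pad the
#' pathway to a realistic size. The default plan mirrors the hit counts of
#' a MAPK-signaling-centred KEGG-like scan (seven reported-like pathways
#' plus three null pathways at their expected hit rate).
#'
#' @return a data.frame with columns \code{name}, \code{background_hits},
#'   \code{foreground_hits}, \code{decoy_size}.
#' @export
default_pathway_plan <- function() {
  data.frame(
    name = c("MAPK_SIGNALING", "METABOLIC_PATHWAYS", "FOCAL_ADHESION",
             "ERBB_SIGNALING", "ARGININE_PROLINE_METABOLISM",
             "NK_CELL_CYTOTOXICITY", "VSMC_CONTRACTION",
             "NULL_PATHWAY_1", "NULL_PATHWAY_2", "NULL_PATHWAY_3"),
    background_hits = c(9L, 36L, 9L, 7L, 7L, 5L, 7L, 12L, 10L, 8L),
    foreground_hits = c(3L, 6L, 3L, 3L, 3L, 3L, 3L, 1L, 1L, 1L),
    decoy_size = c(200L, 900L, 180L, 80L, 40L, 120L, 110L, 100L, 90L, 60L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic input generator
#'
#' Defaults reproduce the cardinal structure of the motivating analysis:
#' three disease studies pooling to 419 upregulated and 301 downregulated
#' genes over a 716-gene universe (so 4 genes are up in one study and down
#' in another), a drug set whose human homologs hit 56 universe genes (41
#' up, 16 down, 1 in both), a lossy many-to-many homology table, and the
#' pathway plan of \code{\link{default_pathway_plan}}.
#'
#' @param n_studies number of disease studies to split the pool across.
#' @param pooled_up,pooled_down,pooled_universe target pooled cardinalities
#'   (|up|, |down|, |up ∪ down|).
#' @param drug_in_universe,drug_in_up,drug_in_down planted overlaps of the
#'   mapped drug set with the pooled universe and directional sets.
#' @param drug_source_size number of source-species drug genes.
#' @param drug_extra_targets mapped human genes falling outside the pooled
#'   universe (they do not enter the statistics).
#' @param multiplicity_probs probabilities of a source gene having 0, 1 or 2
#'   homology targets.
#' @param study_overlap_prob probability that a pooled gene is reported by a
#'   second study as well (low inter-study overlap).
#' @param inject_symbols real human symbols injected among the up-and-drug
#'   genes (and used as foreground hits of the MAPK-like pathway).
#' @param pathway_plan data.frame as \code{\link{default_pathway_plan}}.
#' @param source_species,target_species species tags.
#' @param seed integer seed; all generators derive their streams from it.
#' @return an object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_studies = 3,
                             pooled_up = 419, pooled_down = 301,
                             pooled_universe = 716,
                             drug_in_universe = 56, drug_in_up = 41,
                             drug_in_down = 16,
                             drug_source_size = 150,
                             drug_extra_targets = 30,
                             multiplicity_probs = c(0.15, 0.70, 0.15),
                             study_overlap_prob = 0.15,
                             inject_symbols = c("BRAF", "PAK1", "PRKCA"),
                             pathway_plan = default_pathway_plan(),
                             source_species = "drosophila",
                             target_species = "human",
                             seed = 20101028) {
  cfg <- structure(
    list(n_studies = as.integer(n_studies),
         pooled_up = as.integer(pooled_up),
         pooled_down = as.integer(pooled_down),
         pooled_universe = as.integer(pooled_universe),
         drug_in_universe = as.integer(drug_in_universe),
         drug_in_up = as.integer(drug_in_up),
         drug_in_down = as.integer(drug_in_down),
         drug_source_size = as.integer(drug_source_size),
         drug_extra_targets = as.integer(drug_extra_targets),
         multiplicity_probs = as.numeric(multiplicity_probs),
         study_overlap_prob = as.numeric(study_overlap_prob),
         inject_symbols = if (length(inject_symbols))
           normalize_gene_id(inject_symbols) else character(0),
         pathway_plan = pathway_plan,
         source_species = source_species,
         target_species = target_species,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  fail <- function(msg) stop_sigreverse(paste0("infeasible synthetic config: ", msg),
                                        "sigreverse_infeasible_config")
  shared <- cfg$pooled_up + cfg$pooled_down - cfg$pooled_universe
  if (cfg$n_studies < 1L) fail("need at least one study")
  if (cfg$pooled_up > cfg$pooled_universe || cfg$pooled_down > cfg$pooled_universe) {
    fail("pooled up/down cannot exceed the pooled universe")
  }
  if (shared < 0L) {
    fail(sprintf("|up| + |down| = %d < universe %d: the union cannot cover the universe",
                 cfg$pooled_up + cfg$pooled_down, cfg$pooled_universe))
  }
  triple <- cfg$drug_in_up + cfg$drug_in_down - cfg$drug_in_universe
  if (triple < 0L) {
    fail("drug overlaps violate the venn identity: |up∩D| + |down∩D| < |U∩D|")
  }
  if (triple > shared) {
    fail(sprintf("drug triple overlap %d exceeds the %d genes shared between pooled up and down",
                 triple, shared))
  }
  if (cfg$drug_in_up - triple > cfg$pooled_up - shared) {
    fail("not enough up-only genes to host the planted up-and-drug overlap")
  }
  if (cfg$drug_in_down - triple > cfg$pooled_down - shared) {
    fail("not enough down-only genes to host the planted down-and-drug overlap")
  }
  if (length(cfg$inject_symbols) > max(0L, cfg$drug_in_up - triple)) {
    fail("more injected symbols than up-only drug slots")
  }
  if (2L * cfg$drug_source_size < cfg$drug_in_universe + cfg$drug_extra_targets) {
    fail("drug_source_size too small: even two targets per source cannot cover the mapped target set")
  }
  if (length(cfg$multiplicity_probs) != 3L || any(cfg$multiplicity_probs < 0) ||
      abs(sum(cfg$multiplicity_probs) - 1) > 1e-8) {
    fail("multiplicity_probs must be three non-negative values summing to 1")
  }
  pp <- cfg$pathway_plan
  need <- c("name", "background_hits", "foreground_hits", "decoy_size")
  if (!all(need %in% names(pp))) fail("pathway_plan lacks required columns")
  if (anyDuplicated(pp$name)) fail("duplicate pathway names in plan")
  bad <- pp$background_hits > cfg$pooled_up |
    pp$foreground_hits > pmin(pp$background_hits, cfg$drug_in_up)
  if (any(bad)) {
    fail(sprintf("pathway plan row(s) %s infeasible: need k <= min(K, |foreground|) and K <= |background|",
                 paste(pp$name[bad], collapse = ", ")))
  }
  if (any(pp$background_hits - pp$foreground_hits > cfg$pooled_up - cfg$drug_in_up)) {
    fail("pathway plan needs more background-only genes than exist outside the foreground")
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d studies -> pooled (up %d, down %d, universe %d); drug overlaps (%d, %d, %d); %d pathways; seed %d\n",
              x$n_studies, x$pooled_up, x$pooled_down, x$pooled_universe,
              x$drug_in_universe, x$drug_in_up, x$drug_in_down,
              nrow(x$pathway_plan), x$seed))
  invisible(x)
}

#' Read a synthetic-generator configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{synthetic_config}}; absent keys
#' take the defaults. \code{pathway_plan} may be given as a list of
#' \code{{name, background_hits, foreground_hits, decoy_size}} records.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's value.
#' @return a \code{\link{synthetic_config}}.
#' @export
read_synthetic_config <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$pathway_plan)) {
    vals$pathway_plan <- do.call(rbind, lapply(vals$pathway_plan, function(r) {
      data.frame(name = r$name,
                 background_hits = as.integer(r$background_hits),
                 foreground_hits = as.integer(r$foreground_hits),
                 decoy_size = as.integer(r$decoy_size),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(seed)) vals$seed <- seed
  do.call(synthetic_config, vals[names(vals) %in% names(formals(synthetic_config))])
}

synth_symbols <- function(prefix, n, start = 1L) {
  if (n == 0L) return(character(0))
  sprintf("%s%05d", prefix, start - 1L + seq_len(n))
}

# Deterministic partition of the synthetic universe into up-only, shared
# (up-and-down) and down-only symbols, with real symbols injected into the
# up-only block so they can later host drug and pathway planting.
synth_universe <- function(cfg) {
  shared_n <- cfg$pooled_up + cfg$pooled_down - cfg$pooled_universe
  # gene identities are drawn from a 10x namespace so different seeds give
  # different symbols with the same planted cardinalities
  idx <- with_seed(cfg$seed,
                   sort(sample.int(10L * cfg$pooled_universe, cfg$pooled_universe)))
  uni <- sprintf("SYNDS%05d", idx)
  inj <- cfg$inject_symbols
  if (length(inj)) uni[seq_along(inj)] <- inj
  up_only <- uni[seq_len(cfg$pooled_up - shared_n)]
  shared <- uni[cfg$pooled_up - shared_n + seq_len(shared_n)]
  down_only <- uni[cfg$pooled_up + seq_len(cfg$pooled_universe - cfg$pooled_up)]
  list(up_only = up_only, shared = shared, down_only = down_only)
}

#' Generate synthetic disease signatures
#'
#' Splits a planted pooled universe across \code{n_studies} directional
#' signatures so that pooling them returns exactly the configured |up|,
#' |down| and |up ∪ down|. Each gene is reported by one primary study and,
#' with probability \code{study_overlap_prob}, by a second (emulating low
#' inter-study overlap); genes planted as both up and down are reported up
#' in one study and down in a different one.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return a list of \code{\link{directional_signature}} objects.
#' @export
generate_disease_signatures <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  validate_synthetic_config(cfg)
  parts <- synth_universe(cfg)
  with_seed(cfg$seed + 1L, {
    ns <- cfg$n_studies
    assign_dir <- function(genes) {
      # primary study per gene, plus an occasional second study
      primary <- sample.int(ns, length(genes), replace = TRUE)
      out <- split(genes, factor(primary, levels = seq_len(ns)))
      if (ns > 1L && cfg$study_overlap_prob > 0) {
        dup <- which(stats::runif(length(genes)) < cfg$study_overlap_prob)
        for (i in dup) {
          alt <- sample1(setdiff(seq_len(ns), primary[i]))
          out[[alt]] <- c(out[[alt]], genes[i])
        }
      }
      out
    }
    ups <- assign_dir(c(parts$up_only, parts$shared))
    downs <- assign_dir(parts$down_only)
    # conflict genes: up in one study, down in a different one
    for (g in parts$shared) {
      host <- if (ns > 1L) {
        in_up <- which(vapply(ups, function(u) g %in% u, TRUE))
        free <- setdiff(seq_len(ns), in_up)
        if (length(free)) sample1(free) else sample1(seq_len(ns))
      } else 1L
      downs[[host]] <- c(downs[[host]], g)
    }
    lapply(seq_len(ns), function(i) {
      directional_signature(ups[[i]], downs[[i]],
                            study_label = sprintf("synthetic_study_%d", i),
                            species = cfg$target_species)
    })
  })
}

#' Generate the synthetic drug set and homology table
#'
#' Chooses the planted drug-overlap genes inside the pooled signature
#' (preferring the injected real symbols among the up-only picks), adds
#' mapped targets outside the universe, and builds a lossy many-to-many
#' homology table from synthetic source-species IDs onto exactly that
#' target set, with 0/1/2 targets per source drawn from the configured
#' multiplicity distribution. Mapping the returned drug set through the
#' returned table and taking venn counts against \code{pooled} reproduces
#' the planted overlaps exactly.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param pooled the pooled \code{\link{directional_signature}} from
#'   \code{\link{generate_disease_signatures}}.
#' @return a list: \code{drug} (source-species \code{\link{gene_set}}),
#'   \code{homology} (\code{\link{homology_map}}), and
#'   \code{planted_targets} (the in-universe human genes the drug maps to).
#' @export
generate_drug_bundle <- function(cfg, pooled) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(pooled, "directional_signature"))
  shared <- intersect(pooled$up$members, pooled$down$members)
  up_only <- setdiff(pooled$up$members, shared)
  down_only <- setdiff(pooled$down$members, shared)
  triple <- cfg$drug_in_up + cfg$drug_in_down - cfg$drug_in_universe
  if (triple < 0L || triple > length(shared) ||
      cfg$drug_in_up - triple > length(up_only) ||
      cfg$drug_in_down - triple > length(down_only)) {
    stop_sigreverse(
      "infeasible drug planting: planted overlaps do not fit the pooled signature",
      "sigreverse_infeasible_config"
    )
  }
  with_seed(cfg$seed + 2L, {
    triple_genes <- if (triple > 0L) sample(shared, triple) else character(0)
    inj <- intersect(cfg$inject_symbols, up_only)
    inj <- utils::head(inj, cfg$drug_in_up - triple)
    up_genes <- c(inj, sample(setdiff(up_only, inj),
                              cfg$drug_in_up - triple - length(inj)))
    down_genes <- if (cfg$drug_in_down > triple) {
      sample(down_only, cfg$drug_in_down - triple)
    } else character(0)
    planted <- c(triple_genes, up_genes, down_genes)
    targets <- c(planted, synth_symbols("SYNHX", cfg$drug_extra_targets))
    targets <- sample(targets)

    sources <- synth_symbols("SYNCG", cfg$drug_source_size)
    mult <- sample(0:2, cfg$drug_source_size, replace = TRUE,
                   prob = cfg$multiplicity_probs)
    # every target must be covered: promote sources until enough slots
    while (sum(mult) < length(targets)) {
      i <- sample1(which(mult < 2L))
      mult[i] <- mult[i] + 1L
    }
    slot_source <- rep(sources, times = mult)
    slot_source <- sample(slot_source)
    slot_target <- character(length(slot_source))
    slot_target[seq_along(targets)] <- targets
    extra_slots <- length(slot_source) - length(targets)
    if (extra_slots > 0L) {
      slot_target[length(targets) + seq_len(extra_slots)] <-
        sample(targets, extra_slots, replace = TRUE)
    }
    keep <- !duplicated(paste(slot_source, slot_target, sep = "\r"))
    hm <- homology_map(slot_source[keep], slot_target[keep],
                       source_species = cfg$source_species,
                       target_species = cfg$target_species)
    list(
      drug = gene_set(sources, label = "synthetic_drug_downregulated",
                      species = cfg$source_species),
      homology = hm,
      planted_targets = sort(planted)
    )
  })
}

#' Generate a synthetic pathway collection with planted hit counts
#'
#' For each pathway in the plan, picks exactly \code{foreground_hits} genes
#' from the foreground (the MAPK-like pathway preferentially receives the
#' injected real symbols), \code{background_hits - foreground_hits} genes
#' from the background outside the foreground, and pads with fresh decoy
#' genes outside the background, so that \code{|background ∩ pathway|} and
#' \code{|foreground ∩ pathway|} equal the plan exactly.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param background the background \code{\link{gene_set}} (pooled
#'   disease-upregulated genes).
#' @param foreground the foreground \code{\link{gene_set}} (commonality
#'   genes), contained in the background.
#' @return a \code{\link{pathway_collection}}.
#' @export
generate_pathway_collection <- function(cfg, background, foreground) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(background, "gene_set"), inherits(foreground, "gene_set"))
  bg <- background$members
  fg <- foreground$members
  if (length(setdiff(fg, bg))) {
    stop_sigreverse("foreground must be contained in background",
                    "sigreverse_containment_error")
  }
  pp <- cfg$pathway_plan
  if (any(pp$foreground_hits > length(fg)) || any(pp$background_hits > length(bg)) ||
      any(pp$background_hits - pp$foreground_hits > length(bg) - length(fg))) {
    stop_sigreverse("infeasible pathway plan for the given background/foreground sizes",
                    "sigreverse_infeasible_config")
  }
  with_seed(cfg$seed + 3L, {
    decoy_next <- 1L
    sets <- lapply(seq_len(nrow(pp)), function(i) {
      k <- pp$foreground_hits[i]
      K <- pp$background_hits[i]
      prefer <- if (grepl("MAPK", pp$name[i])) intersect(cfg$inject_symbols, fg)
                else character(0)
      prefer <- utils::head(prefer, k)
      fg_hits <- c(prefer, if (k - length(prefer) > 0L)
        sample(setdiff(fg, prefer), k - length(prefer)) else character(0))
      bg_hits <- if (K - k > 0L) sample(setdiff(bg, fg), K - k) else character(0)
      decoys <- synth_symbols("SYNPD", pp$decoy_size[i], start = decoy_next)
      decoy_next <<- decoy_next + pp$decoy_size[i]
      c(fg_hits, bg_hits, decoys)
    })
    names(sets) <- pp$name
    pathway_collection(sets, name = "synthetic_pathways",
                       species = cfg$target_species)
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs the three generators, checks the round trip (mapping the drug set
#' and counting reproduces the planted overlaps), and writes every file the
#' pipeline consumes — per-study up/down gene lists, the drug list, the
#' homology TSV, the pathway GMT — plus a JSON manifest recording the
#' configuration. Identical config and seed give byte-identical files.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the written \code{paths} and the in-memory
#'   objects (\code{signatures}, \code{pooled}, \code{drug},
#'   \code{homology}, \code{collection}, \code{commonality}).
#' @export
generate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  signatures <- generate_disease_signatures(cfg)
  pooled <- pool_signatures(signatures)
  bundle <- generate_drug_bundle(cfg, pooled)
  mapped <- map_homologs(bundle$drug, bundle$homology)
  commonality <- extract_commonality(pooled, mapped$mapped)
  collection <- generate_pathway_collection(cfg, pooled$up, commonality)

  vc <- venn_counts(pooled, mapped$mapped)
  got <- c(vc$n_universe, vc$n_up, vc$n_down,
           vc$n_universe_drug, vc$n_up_drug, vc$n_down_drug)
  want <- c(cfg$pooled_universe, cfg$pooled_up, cfg$pooled_down,
            cfg$drug_in_universe, cfg$drug_in_up, cfg$drug_in_down)
  if (!identical(as.integer(got), as.integer(want))) {
    stop_sigreverse(
      sprintf("internal planting error: venn counts (%s) differ from plan (%s)",
              paste(got, collapse = ","), paste(want, collapse = ",")),
      "sigreverse_internal_error"
    )
  }

  paths <- list(drug = file.path(dir, "drug_genes.txt"),
                homology = file.path(dir, "homology.tsv"),
                gmt = file.path(dir, "pathways.gmt"),
                manifest = file.path(dir, "manifest.json"),
                signatures = lapply(seq_along(signatures), function(i) {
                  list(up = file.path(dir, sprintf("study%d_up.txt", i)),
                       down = file.path(dir, sprintf("study%d_down.txt", i)))
                }))
  writeLines(c("# synthetic drug-downregulated genes (source species)",
               bundle$drug$members), paths$drug)
  writeLines(c("# source_gene\ttarget_gene",
               paste(bundle$homology$pairs$source,
                     bundle$homology$pairs$target, sep = "\t")),
             paths$homology)
  write_gmt(collection, paths$gmt,
            descriptions = sprintf("synthetic pathway (planted K=%d, k=%d)",
                                   cfg$pathway_plan$background_hits,
                                   cfg$pathway_plan$foreground_hits))
  for (i in seq_along(signatures)) {
    writeLines(c("# synthetic disease upregulated genes",
                 signatures[[i]]$up$members), paths$signatures[[i]]$up)
    writeLines(c("# synthetic disease downregulated genes",
                 signatures[[i]]$down$members), paths$signatures[[i]]$down)
  }
  manifest <- list(
    generator = "sigreverse synthetic bundle",
    seed = cfg$seed,
    config = unclass(cfg)[setdiff(names(unclass(cfg)), "pathway_plan")],
    pathway_plan = cfg$pathway_plan,
    files = vapply(c(paths$drug, paths$homology, paths$gmt,
                     unlist(paths$signatures)),
                   function(p) unname(tools::md5sum(p)), "")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  # ready-to-run pipeline config pointing at the generated files
  paths$pipeline_yaml <- file.path(dir, "pipeline.yaml")
  yaml::write_yaml(
    list(drug_list = basename(paths$drug),
         homology = basename(paths$homology),
         gmt = basename(paths$gmt),
         signatures = lapply(paths$signatures, function(s)
           list(up = basename(s$up), down = basename(s$down)))),
    paths$pipeline_yaml)
  invisible(list(paths = paths, config = cfg, signatures = signatures,
                 pooled = pooled, drug = bundle$drug,
                 homology = bundle$homology, collection = collection,
                 commonality = commonality))
}
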