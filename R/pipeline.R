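#' Extract the counteracting commonality genes
#'
#' The genes both downregulated by the drug (via homologs) and upregulated
#' in the disease: the intersection of the pooled up-set with the mapped
#' drug set, returned sorted for determinism. These are the candidate
#' mediators of a therapeutic reversal and the foreground of the pathway
#' scan.
#'
#' @param pooled a pooled \code{\link{directional_signature}}.
#' @param drug a homolog-mapped \code{\link{gene_set}}, same species.
#' @return a \code{\link{gene_set}} labelled
#'   \code{"counteracting_commonality"}.
#' @export
extract_commonality <- function(pooled, drug) {
  stopifnot(inherits(pooled, "directional_signature"),
            inherits(drug, "gene_set"))
  if (!identical(pooled$species, drug$species)) {
    stop_sigreverse(
      sprintf("species mismatch: pooled signature is '%s', drug set is '%s'",
              pooled$species, drug$species),
      "sigreverse_species_mismatch"
    )
  }
  gene_set(intersect(pooled$up$members, drug$members),
           label = "counteracting_commonality", species = pooled$species)
}

#' Pipeline configuration
#'
#' Bundles the input paths and analysis parameters for
#' \code{\link{run_pipeline}}. All referenced paths must exist (fail fast —
#' silent identifier loss is the classic enrichment-analysis bug).
#'
#' @param drug_list path to the drug gene list (source species, one symbol
#'   per line).
#' @param signatures list with one element per study: either
#'   \code{list(up =, down =)} paths to two gene lists, or
#'   \code{list(tsv =)} for a combined gene/direction TSV.
#' @param homology path to the two-column homology TSV.
#' @param gmt path to the pathway GMT file (optional: \code{NULL} skips the
#'   pathway scan).
#' @param alpha nominal significance level in (0, 1).
#' @param convention \code{"tail"} or \code{"point"}; see
#'   \code{\link{overlap_test}}.
#' @param min_hits pathway-scan eligibility threshold.
#' @param bh apply Benjamini-Hochberg across the scan.
#' @param out_dir optional output directory for the report files.
#' @param source_species,target_species species tags for the drug list and
#'   the disease signatures.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(drug_list, signatures, homology, gmt = NULL,
                            alpha = 0.05, convention = c("tail", "point"),
                            min_hits = 3, bh = FALSE, out_dir = NULL,
                            source_species = "drosophila",
                            target_species = "human") {
  convention <- match.arg(convention)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is_count(min_hits), is.list(signatures), length(signatures) >= 1L)
  must_exist <- c(drug_list, homology, gmt,
                  unlist(signatures, use.names = FALSE))
  missing <- must_exist[!file.exists(must_exist)]
  if (length(missing)) {
    stop_sigreverse(
      sprintf("missing input file(s): %s", paste(missing, collapse = ", ")),
      "sigreverse_io_error"
    )
  }
  structure(
    list(drug_list = drug_list, signatures = signatures, homology = homology,
         gmt = gmt, alpha = alpha, convention = convention,
         min_hits = as.integer(min_hits), bh = isTRUE(bh), out_dir = out_dir,
         source_species = source_species, target_species = target_species),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror \code{\link{pipeline_config}} arguments; \code{signatures}
#' is a list of \code{{up, down}} or \code{{tsv}} records. Relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param ... overrides passed on to \code{\link{pipeline_config}} (e.g.
#'   from CLI flags).
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (key in c("drug_list", "homology", "gmt")) {
    vals[[key]] <- resolve(vals[[key]])
  }
  if (!is.null(vals$signatures)) {
    vals$signatures <- lapply(vals$signatures, function(s) lapply(s, resolve))
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' Run the full signature-reversal analysis
#'
#' Executes the whole chain: read and normalize the inputs, map the drug
#' set to the disease species through the homology table, pool the disease
#' signatures, compute venn counts and the directional overlap tests,
#' extract the counteracting commonality genes, and scan the pathway
#' collection with the commonality genes as foreground against the pooled
#' disease-upregulated background. If \code{out_dir} is set in the config,
#' the report files (\code{report.json}, \code{overlap.tsv},
#' \code{enrichment.tsv}, \code{commonality_genes.txt}, \code{run.log}) are
#' written; re-running with identical inputs yields identical files apart
#' from the timestamp line in the log.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return an object of class \code{analysis_report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  drug_raw <- read_gene_list(config$drug_list, label = "drug_downregulated",
                             species = config$source_species)
  note("read drug list: %d genes (%s)", length(drug_raw), config$drug_list)

  homology <- read_homology_table(config$homology,
                                  source_species = config$source_species,
                                  target_species = config$target_species)
  note("read homology table: %d pairs", nrow(homology$pairs))

  mapping <- map_homologs(drug_raw, homology)
  note("mapped drug genes: %d of %d sources -> %d %s genes",
       mapping$report$n_mapped_source, mapping$report$n_source,
       mapping$report$n_target_genes, config$target_species)
  if (mapping$report$n_target_genes == 0L) {
    warning("no drug genes mapped through the homology table; all overlap tests will be neutral")
    note("WARNING: empty mapped drug set")
  }

  signatures <- lapply(seq_along(config$signatures), function(i) {
    s <- config$signatures[[i]]
    lab <- sprintf("study_%d", i)
    if (!is.null(s$tsv)) {
      read_signature(tsv = s$tsv, study_label = lab,
                     species = config$target_species)
    } else {
      read_signature(up = s$up, down = s$down, study_label = lab,
                     species = config$target_species)
    }
  })
  for (s in signatures) {
    note("read %s: %d up, %d down", s$study_label, length(s$up), length(s$down))
  }
  pooled <- pool_signatures(signatures)
  note("pooled: %d up, %d down, universe %d",
       length(pooled$up), length(pooled$down),
       length(signature_universe(pooled)))

  overlap <- directional_overlap_test(pooled, mapping$mapped,
                                      alpha = config$alpha,
                                      convention = config$convention)
  note("directional tests: up %s (p_upper %.4g), down %s (p_lower %.4g)",
       overlap$up_test$call, overlap$up_test$p_upper,
       overlap$down_test$call, overlap$down_test$p_lower)

  commonality <- extract_commonality(pooled, mapping$mapped)
  note("counteracting commonality genes: %d", length(commonality))

  scan <- NULL
  if (!is.null(config$gmt)) {
    collection <- read_gmt(config$gmt)
    scan <- scan_pathways(commonality, pooled$up, collection,
                          alpha = config$alpha, min_hits = config$min_hits,
                          convention = config$convention, bh = config$bh)
    note("pathway scan: %d pathways, %d significant",
         nrow(scan), attr(scan, "n_significant"))
  }

  prov_files <- c(drug_list = config$drug_list, homology = config$homology,
                  gmt = if (is.null(config$gmt)) NULL else config$gmt,
                  unlist(config$signatures))
  report <- structure(
    list(mapping = mapping$report,
         venn = overlap$venn,
         overlap = overlap,
         commonality = commonality,
         scan = scan,
         provenance = list(
           tool = "sigreverse",
           version = as.character(utils::packageVersion("sigreverse")),
           parameters = list(alpha = config$alpha,
                             convention = config$convention,
                             min_hits = config$min_hits, bh = config$bh),
           input_md5 = as.list(tools::md5sum(prov_files))
         ),
         log = log),
    class = "analysis_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write an analysis report to disk
#'
#' Emits \code{report.json} (full precision), \code{overlap.tsv},
#' \code{enrichment.tsv}, \code{commonality_genes.txt} and \code{run.log}.
#'
#' @param report an \code{analysis_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "report.json"),
             overlap = file.path(dir, "overlap.tsv"),
             enrichment = file.path(dir, "enrichment.tsv"),
             commonality = file.path(dir, "commonality_genes.txt"),
             log = file.path(dir, "run.log"))

  ov <- as.data.frame(report$overlap)
  write_tsv(ov, paths[["overlap"]])
  if (!is.null(report$scan)) {
    write_tsv(as.data.frame(report$scan), paths[["enrichment"]])
  } else {
    writeLines("# no pathway collection supplied", paths[["enrichment"]])
  }
  writeLines(report$commonality$members, paths[["commonality"]])
  writeLines(c(format(Sys.time(), "# run at %Y-%m-%d %H:%M:%S %Z"),
               report$log), paths[["log"]])

  json <- list(
    provenance = report$provenance,
    mapping = list(n_source = report$mapping$n_source,
                   n_mapped_source = report$mapping$n_mapped_source,
                   n_target_genes = report$mapping$n_target_genes,
                   unmapped = report$mapping$unmapped),
    venn = unclass(report$venn),
    overlap = ov,
    commonality_genes = report$commonality$members,
    enrichment = if (is.null(report$scan)) NULL
                 else as.data.frame(report$scan)
  )
  jsonlite::write_json(json, paths[["json"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Drug-disease signature reversal report ==\n\n")
  print(x$mapping)
  cat("\n")
  print(x$venn)
  cat(sprintf("\nUp-set test: %s (p_point %.4g, p_upper %.4g, p_lower %.4g)\n",
              x$overlap$up_test$call, x$overlap$up_test$p_point,
              x$overlap$up_test$p_upper, x$overlap$up_test$p_lower))
  cat(sprintf("Down-set test: %s (p_point %.4g, p_upper %.4g, p_lower %.4g)\n",
              x$overlap$down_test$call, x$overlap$down_test$p_point,
              x$overlap$down_test$p_upper, x$overlap$down_test$p_lower))
  cat(sprintf("\nCounteracting commonality genes: %d\n", length(x$commonality)))
  if (!is.null(x$scan)) {
    cat("\n")
    print(x$scan)
  }
  invisible(x)
}

#' @export
summary.analysis_report <- function(object, ...) {
  out <- list(
    venn = unlist(unclass(object$venn)),
    up_call = object$overlap$up_test$call,
    down_call = object$overlap$down_test$call,
    n_commonality = length(object$commonality),
    n_significant_pathways = if (is.null(object$scan)) NA_integer_
                             else attr(object$scan, "n_significant")
  )
  class(out) <- "summary.analysis_report"
  out
}

#' @export
print.summary.analysis_report <- function(x, ...) {
  cat("venn:", paste(names(x$venn), x$venn, sep = "=", collapse = ", "), "\n")
  cat(sprintf("calls: up=%s, down=%s; commonality=%d; significant pathways=%s\n",
              x$up_call, x$down_call, x$n_commonality,
              x$n_significant_pathways))
  invisible(x)
}
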