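#' Construct a homology map
#'
#' A homology map is a multimap from source-species gene IDs to one or more
#' target-species gene symbols. Duplicate (source, target) pairs are
#' collapsed and all identifiers are normalized.
#'
#' @param source,target character vectors of equal length: one homolog pair
#'   per element.
#' @param source_species,target_species species tags.
#' @return an object of class \code{homology_map}.
#' @export
homology_map <- function(source, target,
                         source_species = "drosophila",
                         target_species = "human") {
  stopifnot(length(source) == length(target))
  if (length(source)) {
    source <- normalize_gene_id(source)
    target <- normalize_gene_id(target)
  } else {
    source <- target <- character(0)
  }
  pairs <- unique(data.frame(source = source, target = target,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(source_species = source_species, target_species = target_species,
         pairs = pairs),
    class = "homology_map"
  )
}

#' @export
print.homology_map <- function(x, ...) {
  cat(sprintf("<homology_map> %s -> %s: %d pairs, %d source genes, %d target genes\n",
              x$source_species, x$target_species, nrow(x$pairs),
              length(unique(x$pairs$source)), length(unique(x$pairs$target))))
  invisible(x)
}

#' Read a two-column homology table
#'
#' Parses a tab-separated table \code{source_gene<TAB>target_gene}, one pair
#' per line. Lines starting with \code{#} are treated as comments or header
#' and skipped; duplicate pairs are collapsed; row order is irrelevant.
#'
#' @param path path to the TSV file.
#' @param source_species,target_species species tags.
#' @return a \code{\link{homology_map}}.
#' @export
read_homology_table <- function(path,
                                source_species = "drosophila",
                                target_species = "human") {
  if (!file.exists(path)) {
    stop_sigreverse(sprintf("cannot read '%s': no such file", path), "sigreverse_io_error")
  }
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")
  if (!any(keep)) {
    warning(sprintf("homology table '%s' has no data rows; returning empty map", path))
    return(homology_map(character(0), character(0),
                        source_species, target_species))
  }
  parts <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- vapply(parts, function(p) sum(nzchar(trimws(p))), 1L)
  if (any(nf < 2L)) {
    stop_sigreverse(
      sprintf("malformed homology row (need >=2 tab-separated fields) at line %d of '%s'",
              which(keep)[which(nf < 2L)[1L]], path),
      "sigreverse_malformed_row"
    )
  }
  homology_map(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L),
               source_species, target_species)
}

#' Map a drug gene set across species
#'
#' Expands each drug gene through the homology multimap and returns the
#' deduplicated union of all targets, tagged with the target species. A
#' source gene with several homologs contributes all of them; sources
#' sharing one target collapse to a single output gene. Unmapped sources are
#' dropped from the output set but enumerated in the mapping report.
#'
#' @param drug a \code{\link{gene_set}} in the map's source species.
#' @param map a \code{\link{homology_map}}.
#' @return a list with components \code{mapped} (the target-species
#'   \code{\link{gene_set}}) and \code{report} (a \code{mapping_report}:
#'   source/mapped/target counts, targets-per-source multiplicity histogram,
#'   and the unmapped source IDs).
#' @export
map_homologs <- function(drug, map) {
  stopifnot(inherits(drug, "gene_set"), inherits(map, "homology_map"))
  if (!identical(drug$species, map$source_species)) {
    stop_sigreverse(
      sprintf("species mismatch: drug set is '%s' but homology map expects '%s' sources",
              drug$species, map$source_species),
      "sigreverse_species_mismatch"
    )
  }
  hit <- map$pairs[map$pairs$source %in% drug$members, , drop = FALSE]
  mapped_sources <- unique(hit$source)
  targets <- sort(unique(hit$target))
  mult <- table(factor(
    vapply(drug$members,
           function(g) sum(hit$source == g), 1L),
    levels = 0:max(1L, if (nrow(hit)) max(table(hit$source)) else 1L)
  ))
  report <- structure(
    list(
      n_source = length(drug$members),
      n_mapped_source = length(mapped_sources),
      n_target_genes = length(targets),
      multiplicity = mult,
      unmapped = sort(setdiff(drug$members, mapped_sources))
    ),
    class = "mapping_report"
  )
  mapped <- gene_set(targets,
                     label = paste0(drug$label, "_", map$target_species),
                     species = map$target_species)
  # gene_set() refuses empty labels, not empty member sets
  list(mapped = mapped, report = report)
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("Homology mapping: %d source genes, %d mapped (%d unmapped), %d target genes\n",
              x$n_source, x$n_mapped_source, x$n_source - x$n_mapped_source,
              x$n_target_genes))
  cat("  targets-per-source histogram:\n")
  print(x$multiplicity)
  invisible(x)
}
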