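#' Normalize gene identifiers
#'
#' Canonicalizes raw gene identifiers: strips surrounding whitespace and
#' upper-cases the symbol (the human gene-symbol convention, which the
#' disease-side studies report). The operation is deterministic and
#' idempotent, so identifiers can be re-normalized safely at any stage.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of canonical symbols.
#' @examples
#' normalize_gene_id(c(" braf ", "Pak1", "PRKCA"))
#' @export
normalize_gene_id <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  out <- toupper(trimws(x))
  if (any(!nzchar(out) | is.na(out))) {
    bad <- which(!nzchar(out) | is.na(out))
    stop_sigreverse(
      sprintf("malformed gene identifier at position %s: empty or blank",
              paste(bad, collapse = ", ")),
      "sigreverse_malformed_id"
    )
  }
  out
}

#' Construct a gene set
#'
#' A gene set is a labelled, species-tagged set of normalized gene symbols
#' with duplicates collapsed.
#'
#' @param members character vector of gene identifiers (normalized on entry).
#' @param label non-empty label for the set.
#' @param species species tag, e.g. \code{"human"} or \code{"drosophila"}.
#' @return an object of class \code{gene_set}.
#' @export
gene_set <- function(members, label, species = "human") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.character(species), length(species) == 1L, nzchar(species))
  members <- if (length(members)) normalize_gene_id(members) else character(0)
  structure(
    list(label = label, species = species,
         members = sort(unique(members))),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s]: %d genes\n", x$label, x$species,
              length(x$members)))
  if (length(x$members)) {
    shown <- utils::head(x$members, 6L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$members) > 6L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Read a gene list file
#'
#' Parses a plain-text gene list, one symbol per line. Blank lines and lines
#' starting with \code{#} are ignored; duplicates are collapsed after
#' normalization.
#'
#' @param path path to the list file.
#' @param label label for the resulting set (defaults to the file name).
#' @param species species tag.
#' @return a \code{\link{gene_set}}.
#' @export
read_gene_list <- function(path, label = basename(path), species = "human") {
  lines <- read_clean_lines(path)
  if (!length(lines)) {
    warning(sprintf("gene list '%s' contains no usable lines; returning empty set", path))
  }
  gene_set(lines, label = label, species = species)
}

#' Construct a directional signature
#'
#' A directional signature is a study's pair of up- and down-regulated gene
#' sets. The two sets must share a species tag; they may intersect (after
#' pooling across studies a gene can be up in one study and down in another).
#'
#' @param up,down \code{\link{gene_set}} objects, or character vectors.
#' @param study_label label for the study.
#' @param species species tag used when \code{up}/\code{down} are character.
#' @return an object of class \code{directional_signature}.
#' @export
directional_signature <- function(up, down, study_label, species = "human") {
  if (!inherits(up, "gene_set")) {
    up <- gene_set(up, label = paste0(study_label, "_up"), species = species)
  }
  if (!inherits(down, "gene_set")) {
    down <- gene_set(down, label = paste0(study_label, "_down"), species = species)
  }
  if (!identical(up$species, down$species)) {
    stop_sigreverse(
      sprintf("species mismatch within signature '%s': up is '%s', down is '%s'",
              study_label, up$species, down$species),
      "sigreverse_species_mismatch"
    )
  }
  structure(
    list(study_label = study_label, up = up, down = down,
         species = up$species),
    class = "directional_signature"
  )
}

#' @export
print.directional_signature <- function(x, ...) {
  both <- length(intersect(x$up$members, x$down$members))
  cat(sprintf("<directional_signature> %s [%s]: %d up, %d down (%d in both), universe %d\n",
              x$study_label, x$species, length(x$up), length(x$down), both,
              length(union(x$up$members, x$down$members))))
  invisible(x)
}

#' Read a directional signature from files
#'
#' Either two one-symbol-per-line files (\code{up}, \code{down}), or one
#' two-column TSV (\code{tsv}) with columns \code{gene<TAB>direction},
#' direction in \{up, down\}.
#'
#' @param up,down paths to up/down gene list files.
#' @param tsv path to a combined gene/direction TSV.
#' @param study_label label for the study.
#' @param species species tag.
#' @return a \code{\link{directional_signature}}.
#' @export
read_signature <- function(up = NULL, down = NULL, tsv = NULL,
                           study_label = "study", species = "human") {
  if (!is.null(tsv)) {
    lines <- read_clean_lines(tsv)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad)) {
      stop_sigreverse(
        sprintf("malformed signature row in '%s' (need gene<TAB>direction) at data line %d",
                tsv, bad[1L]),
        "sigreverse_malformed_row"
      )
    }
    genes <- vapply(parts, `[[`, "", 1L)
    dir <- tolower(trimws(vapply(parts, `[[`, "", 2L)))
    if (!all(dir %in% c("up", "down"))) {
      stop_sigreverse(
        sprintf("invalid direction value(s) in '%s': %s", tsv,
                paste(unique(dir[!dir %in% c("up", "down")]), collapse = ", ")),
        "sigreverse_malformed_row"
      )
    }
    return(directional_signature(genes[dir == "up"], genes[dir == "down"],
                                 study_label = study_label, species = species))
  }
  stopifnot(!is.null(up), !is.null(down))
  directional_signature(
    read_gene_list(up, species = species),
    read_gene_list(down, species = species),
    study_label = study_label, species = species
  )
}

#' Pool directional signatures across studies
#'
#' Unions the up-lists and the down-lists of several studies into one pooled
#' signature. A gene reported up in one study and down in another appears in
#' both pooled directional sets but is counted once in the pooled universe
#' (the union of up and down) — the population used by the overlap tests.
#'
#' @param signatures list of \code{\link{directional_signature}} objects.
#' @param label label for the pooled signature.
#' @return a pooled \code{\link{directional_signature}}.
#' @export
pool_signatures <- function(signatures, label = "pooled") {
  if (inherits(signatures, "directional_signature")) signatures <- list(signatures)
  stopifnot(length(signatures) >= 1L,
            all(vapply(signatures, inherits, TRUE, "directional_signature")))
  species <- vapply(signatures, function(s) s$species, "")
  if (length(unique(species)) != 1L) {
    stop_sigreverse(
      sprintf("species mismatch across signatures: %s",
              paste(unique(species), collapse = ", ")),
      "sigreverse_species_mismatch"
    )
  }
  up <- sort(unique(unlist(lapply(signatures, function(s) s$up$members))))
  down <- sort(unique(unlist(lapply(signatures, function(s) s$down$members))))
  directional_signature(
    gene_set(up, label = paste0(label, "_up"), species = species[1L]),
    gene_set(down, label = paste0(label, "_down"), species = species[1L]),
    study_label = label, species = species[1L]
  )
}

#' Universe of a directional signature
#'
#' @param signature a \code{\link{directional_signature}}.
#' @return character vector: union of the up and down members.
#' @export
signature_universe <- function(signature) {
  stopifnot(inherits(signature, "directional_signature"))
  sort(union(signature$up$members, signature$down$members))
}

#' Venn counts between a pooled signature and a drug set
#'
#' Computes the overlap cardinalities that parameterize the directional
#' tests: the pooled universe and directional set sizes, and their
#' intersections with the (homolog-mapped) drug set. The identity
#' \code{n_universe_drug = n_up_drug + n_down_drug - n_up_down_drug}
#' holds by construction.
#'
#' @param pooled a pooled \code{\link{directional_signature}}.
#' @param drug a \code{\link{gene_set}} already mapped to the signature's
#'   species.
#' @return an object of class \code{venn_counts}: a named list of the six
#'   cardinalities plus the triple intersection.
#' @export
venn_counts <- function(pooled, drug) {
  stopifnot(inherits(pooled, "directional_signature"),
            inherits(drug, "gene_set"))
  if (!identical(pooled$species, drug$species)) {
    stop_sigreverse(
      sprintf("species mismatch: pooled signature is '%s', drug set is '%s' (map homologs first)",
              pooled$species, drug$species),
      "sigreverse_species_mismatch"
    )
  }
  uni <- signature_universe(pooled)
  up <- pooled$up$members
  down <- pooled$down$members
  d <- drug$members
  structure(
    list(
      n_universe = length(uni),
      n_up = length(up),
      n_down = length(down),
      n_universe_drug = length(intersect(uni, d)),
      n_up_drug = length(intersect(up, d)),
      n_down_drug = length(intersect(down, d)),
      n_up_down_drug = length(Reduce(intersect, list(up, down, d)))
    ),
    class = "venn_counts"
  )
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Venn counts (disease universe vs drug set)\n")
  cat(sprintf("  universe: %d (up %d, down %d)\n", x$n_universe, x$n_up, x$n_down))
  cat(sprintf("  drug in universe: %d (in up %d, in down %d, in both %d)\n",
              x$n_universe_drug, x$n_up_drug, x$n_down_drug, x$n_up_down_drug))
  invisible(x)
}
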