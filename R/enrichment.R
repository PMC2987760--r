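#' Construct a pathway collection
#'
#' A named collection of pathway gene sets (as from a GMT file). Pathway
#' names must be unique and member sets non-empty.
#'
#' @param pathways named list of character vectors (pathway members).
#' @param name collection name.
#' @param species species tag applied to all member sets.
#' @return an object of class \code{pathway_collection}.
#' @export
pathway_collection <- function(pathways, name = "collection", species = "human") {
  stopifnot(is.list(pathways))
  if (length(pathways)) {
    nm <- names(pathways)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop_sigreverse("all pathways must be named", "sigreverse_domain_error")
    }
    if (anyDuplicated(nm)) {
      stop_sigreverse(
        sprintf("duplicate pathway name(s): %s",
                paste(unique(nm[duplicated(nm)]), collapse = ", ")),
        "sigreverse_domain_error"
      )
    }
    if (any(lengths(pathways) == 0L)) {
      stop_sigreverse("pathway member sets must be non-empty",
                      "sigreverse_domain_error")
    }
    pathways <- lapply(pathways, function(g) sort(unique(normalize_gene_id(g))))
  }
  structure(list(name = name, species = species, pathways = pathways),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %s [%s]: %d pathways (sizes %s)\n",
              x$name, x$species, length(x$pathways),
              if (length(x$pathways))
                paste0(min(lengths(x$pathways)), "-", max(lengths(x$pathways)))
              else "-"))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$pathways)

#' Read a GMT pathway file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Genes are normalized
#' and deduplicated per pathway; line order is irrelevant to the result.
#'
#' @param path path to the GMT file.
#' @param name collection name (defaults to the file name).
#' @param species species tag.
#' @return a \code{\link{pathway_collection}}.
#' @export
read_gmt <- function(path, name = basename(path), species = "human") {
  lines <- read_clean_lines(path)
  if (!length(lines)) {
    warning(sprintf("GMT file '%s' has no data lines; returning empty collection", path))
    return(pathway_collection(list(), name = name, species = species))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 3L)) {
    stop_sigreverse(
      sprintf("malformed GMT line %d in '%s': need name, description and >=1 gene",
              which(nf < 3L)[1L], path),
      "sigreverse_malformed_row"
    )
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop_sigreverse(
      sprintf("duplicate pathway name(s) in '%s': %s", path,
              paste(unique(nm[duplicated(nm)]), collapse = ", ")),
      "sigreverse_domain_error"
    )
  }
  sets <- lapply(parts, function(p) p[-(1:2)][nzchar(trimws(p[-(1:2)]))])
  names(sets) <- nm
  pathway_collection(sets, name = name, species = species)
}

#' Write a pathway collection as GMT
#'
#' @param collection a \code{\link{pathway_collection}}.
#' @param path output path.
#' @param descriptions optional character vector of per-pathway descriptions.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(collection$pathways))
  }
  lines <- vapply(seq_along(collection$pathways), function(i) {
    paste(c(names(collection$pathways)[i], descriptions[i],
            collection$pathways[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Pathway over-representation test
#'
#' Tests whether a foreground gene set (here: the counteracting commonality
#' genes) over-represents a pathway relative to a background universe (here:
#' the pooled disease-upregulated set, not the genome). Pathway membership
#' is counted within the background: N = |background|,
#' K = |background ∩ pathway|, n = |foreground|, k = |foreground ∩ pathway|.
#' The foreground must be contained in the background.
#'
#' @param foreground,background \code{\link{gene_set}} objects (or character
#'   vectors), foreground ⊆ background.
#' @param pathway a character vector or \code{gene_set} of pathway members.
#' @param pathway_name label for the pathway.
#' @param alpha nominal significance level.
#' @param convention \code{"tail"} (significance from P[X >= k]) or
#'   \code{"point"} (legacy spreadsheet compatibility).
#' @return an object of class \code{enrichment_record}.
#' @examples
#' bg <- gene_set(sprintf("G%03d", 1:419), "background")
#' fg <- gene_set(sprintf("G%03d", 1:41), "foreground")
#' pw <- c(sprintf("G%03d", 39:41), sprintf("G%03d", 100:105))
#' pathway_enrichment(fg, bg, pw, "example")  # point p ~0.041
#' @export
pathway_enrichment <- function(foreground, background, pathway,
                               pathway_name = "pathway", alpha = 0.05,
                               convention = c("tail", "point")) {
  convention <- match.arg(convention)
  fg <- if (inherits(foreground, "gene_set")) foreground$members
        else sort(unique(normalize_gene_id(foreground)))
  bg <- if (inherits(background, "gene_set")) background$members
        else sort(unique(normalize_gene_id(background)))
  pw <- if (inherits(pathway, "gene_set")) pathway$members
        else sort(unique(normalize_gene_id(pathway)))
  if (!length(bg)) {
    stop_sigreverse("pathway enrichment undefined: empty background",
                    "sigreverse_domain_error")
  }
  stray <- setdiff(fg, bg)
  if (length(stray)) {
    stop_sigreverse(
      sprintf("foreground is not contained in background; offending genes: %s",
              paste(utils::head(stray, 10L), collapse = ", ")),
      "sigreverse_containment_error"
    )
  }
  K <- length(intersect(bg, pw))
  hits <- intersect(fg, pw)
  counts <- overlap_counts(length(bg), K, length(fg), length(hits))
  res <- overlap_test(counts, alpha = alpha, convention = convention)
  p <- if (convention == "tail") res$p_upper else res$p_point
  structure(
    list(pathway = pathway_name,
         background_size = counts$N, background_hits = counts$K,
         foreground_size = counts$n, foreground_hits = counts$k,
         expected = res$expected,
         hit_genes = sort(hits),
         p_point = res$p_point, p_upper = res$p_upper,
         p = p, significant = p < alpha && counts$k > res$expected,
         alpha = alpha, convention = convention),
    class = "enrichment_record"
  )
}

#' @export
print.enrichment_record <- function(x, ...) {
  cat(sprintf("Pathway enrichment: %s\n", x$pathway))
  cat(sprintf("  background: %d of %d in pathway; foreground: %d of %d\n",
              x$background_hits, x$background_size,
              x$foreground_hits, x$foreground_size))
  cat(sprintf("  P[X = k] = %.4g, P[X >= k] = %.4g (%s convention, alpha = %g): %s\n",
              x$p_point, x$p_upper, x$convention, x$alpha,
              if (x$significant) "significant" else "not significant"))
  if (length(x$hit_genes)) {
    cat("  hit genes: ", paste(x$hit_genes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.enrichment_record <- function(x, ...) {
  data.frame(pathway = x$pathway,
             N = x$background_size, K = x$background_hits,
             n = x$foreground_size, k = x$foreground_hits,
             expected = x$expected,
             p_point = x$p_point, p_upper = x$p_upper, p = x$p,
             significant = x$significant,
             hit_genes = paste(x$hit_genes, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Scan a pathway collection for over-representation
#'
#' Applies \code{\link{pathway_enrichment}} to every pathway in a
#' collection. Records with fewer than \code{min_hits} foreground hits are
#' marked ineligible (never significant) regardless of p, since point-mass
#' "enrichment" at very small k is unstable. Output rows are sorted by the
#' convention p, ties broken by pathway name, so the order is a total order.
#'
#' @param foreground,background as in \code{\link{pathway_enrichment}}.
#' @param collection a \code{\link{pathway_collection}}.
#' @param alpha nominal significance level.
#' @param min_hits minimum foreground hits for eligibility (default 3).
#' @param convention \code{"tail"} or \code{"point"}.
#' @param bh apply Benjamini-Hochberg correction to the convention p across
#'   eligible pathways (default FALSE: nominal p-values).
#' @return a data.frame of class \code{enrichment_scan}, one row per
#'   pathway, with an \code{n_significant} attribute.
#' @export
scan_pathways <- function(foreground, background, collection,
                          alpha = 0.05, min_hits = 3,
                          convention = c("tail", "point"), bh = FALSE) {
  stopifnot(inherits(collection, "pathway_collection"), is_count(min_hits))
  convention <- match.arg(convention)
  if (!length(collection$pathways)) {
    out <- data.frame(pathway = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), expected = numeric(0),
                      p_point = numeric(0), p_upper = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      eligible = logical(0), significant = logical(0),
                      hit_genes = character(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("enrichment_scan", "data.frame"),
                     alpha = alpha, convention = convention,
                     n_significant = 0L))
  }
  recs <- lapply(names(collection$pathways), function(nm) {
    pathway_enrichment(foreground, background, collection$pathways[[nm]],
                       pathway_name = nm, alpha = alpha,
                       convention = convention)
  })
  df <- do.call(rbind, lapply(recs, as.data.frame))
  df$eligible <- df$k >= min_hits
  df$p_adj <- NA_real_
  if (bh) {
    df$p_adj[df$eligible] <- stats::p.adjust(df$p[df$eligible], method = "BH")
    df$significant <- df$eligible & !is.na(df$p_adj) & df$p_adj < alpha &
      df$k > df$expected
  } else {
    df$significant <- df$eligible & df$significant
  }
  ord <- order(df$p, df$pathway)
  df <- df[ord, c("pathway", "N", "K", "n", "k", "expected",
                  "p_point", "p_upper", "p", "p_adj",
                  "eligible", "significant", "hit_genes")]
  rownames(df) <- NULL
  structure(df, class = c("enrichment_scan", "data.frame"),
            alpha = alpha, convention = convention,
            n_significant = sum(df$significant))
}

#' @export
print.enrichment_scan <- function(x, ...) {
  cat(sprintf("Pathway scan: %d pathways, %d significant (alpha = %g, %s convention)\n",
              nrow(x), attr(x, "n_significant"), attr(x, "alpha"),
              attr(x, "convention")))
  if (nrow(x)) {
    shown <- as.data.frame(x)[, c("pathway", "K", "k", "p_point", "p_upper",
                                  "significant")]
    shown$p_point <- signif(shown$p_point, 4)
    shown$p_upper <- signif(shown$p_upper, 4)
    print(utils::head(shown, 15L), row.names = FALSE)
    if (nrow(x) > 15L) cat(sprintf("  ... and %d more\n", nrow(x) - 15L))
  }
  invisible(x)
}
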