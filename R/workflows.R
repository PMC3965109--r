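#' Probe selection sets
#'
#' A selection set is the file-backed replacement for the interactive
#' probe "cart": an ordered, duplicate-free list of probe ids, each with a
#' provenance note saying which tool or term added it. First-insertion
#' order is preserved.
#'
#' @param probe_ids Character vector of probe ids.
#' @param provenance Character vector (recycled) recording the origin of
#'   each probe.
#' @return A `selection_set` data.frame (`probe_id`, `provenance`).
#' @export
selection_set <- function(probe_ids = character(),
                          provenance = character(length(probe_ids))) {
  provenance <- rep_len(as.character(provenance), length(probe_ids))
  keep <- !duplicated(probe_ids)
  structure(data.frame(probe_id = as.character(probe_ids)[keep],
                       provenance = provenance[keep],
                       stringsAsFactors = FALSE),
            class = c("selection_set", "data.frame"))
}

#' @rdname selection_set
#' @param x A `selection_set`.
#' @param probes Probe ids to add.
#' @export
selection_add <- function(x, probes, provenance = "") {
  stopifnot(inherits(x, "selection_set"))
  new <- setdiff(probes, x$probe_id)
  selection_set(c(x$probe_id, new),
                c(x$provenance, rep_len(provenance, length(new))))
}

#' @rdname selection_set
#' @param path TSV path for reading/writing a selection.
#' @export
read_selection <- function(path) {
  tab <- read_table_file(path, required = c("probe_id", "provenance"))
  selection_set(tab$probe_id, tab$provenance)
}

#' @rdname selection_set
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "selection_set"))
  writeLines(c("probe_id\tprovenance",
               paste(x$probe_id, x$provenance, sep = "\t")), path)
  invisible(path)
}

# human term gene sets -> shared ortholog groups -> worm genes
human_terms_to_worm_genes <- function(term_ids, human_catalog, map) {
  genes <- unlist(lapply(term_ids, gene_set_for_term,
                         catalog = human_catalog), use.names = FALSE)
  groups <- project_set(unique(genes), "human", map)
  genes_of_groups(groups, "worm", map)
}

#' Disease-to-QTL workflow
#'
#' Starting from one or more human disease terms, collects their
#' associated genes, maps them through shared ortholog groups to worm
#' genes, and selects every expression probe annotated to those worm
#' genes. When a `qtl_scan` is supplied the probes' LOD profiles and
#' peaks are returned alongside, ready for plotting.
#'
#' @param term_ids Character vector of term ids in `human_catalog`.
#' @param human_catalog A human `geneset_catalog`.
#' @param map An `ortholog_map`.
#' @param annotation Probe annotation data.frame.
#' @param scan Optional `qtl_scan` for the probes' LOD profiles.
#' @param lod_threshold Threshold used for the peak report (default 0).
#' @return List with `selection` (a `selection_set`), `worm_genes`, and,
#'   when `scan` is given, `profiles` and `peaks`.
#' @export
disease2qtl <- function(term_ids, human_catalog, map, annotation,
                        scan = NULL, lod_threshold = 0) {
  sel <- selection_set()
  all_worm <- character()
  for (tid in term_ids) {
    wg <- human_terms_to_worm_genes(tid, human_catalog, map)
    all_worm <- union(all_worm, wg)
    probes <- annotation$probe_id[annotation$gene_id %in% wg]
    if (!length(wg)) {
      warning("term '", tid, "' has no orthologous worm genes",
              call. = FALSE)
    }
    sel <- selection_add(sel, probes, provenance = paste0("disease2qtl:", tid))
  }
  out <- list(selection = sel, worm_genes = sort(all_worm))
  if (!is.null(scan)) {
    found <- intersect(sel$probe_id, scan$probe_ids)
    out$profiles <- lod_profiles(scan, found)
    peaks <- lapply(found, find_peak, scan = scan,
                    lod_threshold = lod_threshold)
    out$peaks <- do.call(rbind, peaks[!vapply(peaks, is.null, logical(1L))])
  }
  out
}

# enrichment of a worm gene set against every term of each human catalog;
# results concatenated across catalogs with their source column, sorted by
# ascending p with lexicographic term-id tie-breaks
worm_genes_vs_catalogs <- function(worm_genes, human_catalogs, map,
                                   term1_id = NA_character_,
                                   term1_label = NA_character_,
                                   term1_source = NA_character_,
                                   N_override = NULL) {
  if (inherits(human_catalogs, "geneset_catalog")) {
    human_catalogs <- list(human_catalogs)
  }
  res <- lapply(human_catalogs, function(cat_h) {
    terms <- catalog_terms(cat_h)
    rows <- lapply(terms$term_id, function(tid) {
      r <- phenolog_test(worm_genes, gene_set_for_term(cat_h, tid), map,
                         N_override = N_override)
      r$term1_id <- term1_id; r$term1_label <- term1_label
      r$term1_source <- term1_source
      r$term2_id <- tid
      r$term2_label <- terms$label[terms$term_id == tid]
      r$term2_source <- attr(cat_h, "source")
      r
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty_phenolog_result())
  res <- res[res$k >= 1L, , drop = FALSE]
  if (nrow(res)) {
    res <- res[order(res$p, res$term1_id, res$term2_id), , drop = FALSE]
  }
  rownames(res) <- NULL
  class(res) <- c("phenolog_result", "data.frame")
  res
}

#' Region-to-disease workflow
#'
#' Finds all probes annotated in a worm genomic region (e.g. an eQTL
#' hotspot), collects their distinct genes, and runs the phenolog overlap
#' test of that gene set against every disease term of the supplied human
#' catalog(s).
#'
#' @param region A `genomic_region` (see [parse_region()]).
#' @param annotation Probe annotation data.frame.
#' @param map An `ortholog_map`.
#' @param human_catalogs A human `geneset_catalog` or list of them.
#' @param N_override Optional explicit background size.
#' @return A `phenolog_result` data.frame sorted by ascending p; attribute
#'   `probes` holds the region's probe ids, `genes` the distinct worm
#'   genes tested.
#' @export
region2disease <- function(region, annotation, map, human_catalogs,
                           N_override = NULL) {
  probes <- region_probes(region, annotation)
  genes <- sort(unique(annotation$gene_id[annotation$probe_id %in% probes]))
  genes <- genes[nzchar(genes)]
  res <- if (length(genes)) {
    worm_genes_vs_catalogs(genes, human_catalogs, map,
                           term1_id = sprintf("%s:%d-%d", region$chrom,
                                              region$start_bp, region$end_bp),
                           term1_label = "genomic region",
                           term1_source = "REGION", N_override = N_override)
  } else {
    worm_genes_vs_catalogs(character(), list(), map)
  }
  attr(res, "probes") <- probes
  attr(res, "genes") <- genes
  res
}

#' QTL-to-disease workflow
#'
#' Starting from one expression probe with a suspected QTL: locate its
#' highest-LOD marker; if that peak clears the threshold, take the closest
#' `count_per_side` probes on each side of the peak marker (plus the query
#' probe itself), collect their genes, and test the set against the human
#' catalog(s) for disease enrichment.
#'
#' @param probe_id Query probe present in `scan`.
#' @param scan A `qtl_scan` built with a marker map.
#' @param lod_threshold Strict LOD threshold for the peak.
#' @param annotation Probe annotation data.frame.
#' @param map An `ortholog_map`.
#' @param human_catalogs A human `geneset_catalog` or list of them.
#' @param count_per_side Window half-width in probes (default 50).
#' @param N_override Optional explicit background size.
#' @return A `phenolog_result` (empty, with a message, when no peak
#'   clears the threshold); attributes `peak`, `probes` (window), `genes`.
#' @export
qtl2disease <- function(probe_id, scan, lod_threshold, annotation, map,
                        human_catalogs, count_per_side = 50,
                        N_override = NULL) {
  peak <- find_peak(scan, probe_id, lod_threshold)
  if (is.null(peak)) {
    message("no QTL above LOD ", lod_threshold, " for probe '", probe_id, "'")
    res <- worm_genes_vs_catalogs(character(), list(), map)
    attr(res, "peak") <- NULL
    return(res)
  }
  if (is.null(peak$chrom)) {
    stop("domain error: qtl2disease needs a scan built with a marker map",
         call. = FALSE)
  }
  window <- flanking_probes(peak, annotation, count_per_side)
  window <- union(window, probe_id)    # query probe's gene always included
  genes <- sort(unique(annotation$gene_id[annotation$probe_id %in% window]))
  genes <- genes[nzchar(genes)]
  res <- worm_genes_vs_catalogs(genes, human_catalogs, map,
                                term1_id = peak$marker_id,
                                term1_label = sprintf("QTL peak %s (LOD %.2f)",
                                                      peak$marker_id, peak$lod),
                                term1_source = "QTL",
                                N_override = N_override)
  attr(res, "peak") <- peak
  attr(res, "probes") <- window
  attr(res, "genes") <- genes
  res
}

#' Phenotype comparison workflow
#'
#' Tests the gene set of each query term against every term of the
#' opposite species (phenolog search), or, with `within_species = TRUE`,
#' against every other term of its own catalog. The query species is
#' detected from the catalog containing the term.
#'
#' @param term_ids Query term ids.
#' @param worm_catalog A worm `geneset_catalog`.
#' @param human_catalogs A human `geneset_catalog` or list of them.
#' @param map An `ortholog_map`.
#' @param within_species Compare within the query's own catalog instead?
#' @param N_override Optional explicit background size.
#' @return A `phenolog_result` data.frame sorted by ascending p.
#' @export
comparepheno <- function(term_ids, worm_catalog, human_catalogs, map,
                         within_species = FALSE, N_override = NULL) {
  if (inherits(human_catalogs, "geneset_catalog")) {
    human_catalogs <- list(human_catalogs)
  }
  locate <- function(tid) {
    if (tid %in% worm_catalog$term_id) return(list(cat = worm_catalog))
    for (h in human_catalogs) if (tid %in% h$term_id) return(list(cat = h))
    gene_set_for_term(worm_catalog, tid)  # raises the lookup error
  }
  out <- lapply(term_ids, function(tid) {
    src <- locate(tid)$cat
    if (within_species) {
      return(within_species_sweep(src, tid))
    }
    qmeta <- catalog_terms(src)
    qmeta <- qmeta[qmeta$term_id == tid, ]
    qset <- gene_set_for_term(src, tid)
    if (attr(src, "species") == "worm") {
      worm_genes_vs_catalogs(qset, human_catalogs, map, term1_id = tid,
                             term1_label = qmeta$label,
                             term1_source = attr(src, "source"),
                             N_override = N_override)
    } else {
      # human query against all worm phenotype terms; roles stay
      # (term1 = worm, term2 = human) as in the result schema
      terms_w <- catalog_terms(worm_catalog)
      rows <- lapply(terms_w$term_id, function(wt) {
        r <- phenolog_test(gene_set_for_term(worm_catalog, wt), qset, map,
                           N_override = N_override)
        r$term1_id <- wt
        r$term1_label <- terms_w$label[terms_w$term_id == wt]
        r$term1_source <- attr(worm_catalog, "source")
        r$term2_id <- tid; r$term2_label <- qmeta$label
        r$term2_source <- attr(src, "source")
        r
      })
      res <- do.call(rbind, rows)
      res <- res[res$k >= 1L, , drop = FALSE]
      res <- res[order(res$p, res$term1_id, res$term2_id), , drop = FALSE]
      rownames(res) <- NULL
      class(res) <- c("phenolog_result", "data.frame")
      res
    }
  })
  merged <- do.call(rbind, out)
  if (is.null(merged)) merged <- empty_phenolog_result()
  if (nrow(merged)) {
    merged <- merged[order(merged$p, merged$term1_id, merged$term2_id), ,
                     drop = FALSE]
    rownames(merged) <- NULL
  }
  class(merged) <- c("phenolog_result", "data.frame")
  merged
}
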