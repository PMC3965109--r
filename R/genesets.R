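#' Construct a gene-set catalog
#'
#' A catalog holds gene-phenotype (worm) or gene-disease (human)
#' associations from one source. Worm catalogs come from WormBase-style
#' phenotype exports; human catalogs from OMIM-, DGA- or GWAS-style
#' exports. Duplicate (term, gene) rows are collapsed keeping the smallest
#' association p-value.
#'
#' @param associations Data.frame with columns `term_id`, `label`, `gene`
#'   and optionally `p_value` (association p-value in (0,1], `NA` for
#'   unscored rows as in OMIM/DGA/WormBase).
#' @param source One of `"OMIM"`, `"DGA"`, `"GWAS_CATALOGUE"`,
#'   `"GWAS_CENTRAL"` (human) or `"WORMBASE"` (worm).
#' @return A `geneset_catalog`: the deduplicated association data.frame
#'   with attributes `source`, `species`, `n_raw`, `n_removed`.
#' @export
geneset_catalog <- function(associations,
                            source = c("OMIM", "DGA", "GWAS_CATALOGUE",
                                       "GWAS_CENTRAL", "WORMBASE")) {
  source <- match.arg(source)
  req <- c("term_id", "label", "gene")
  missing_cols <- setdiff(req, names(associations))
  if (length(missing_cols)) {
    stop("format error: catalog lacks mandatory column(s) ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }
  df <- data.frame(term_id = as.character(associations$term_id),
                   label = as.character(associations$label),
                   gene = as.character(associations$gene),
                   stringsAsFactors = FALSE)
  df$p_value <- if ("p_value" %in% names(associations)) {
    suppressWarnings(as.numeric(associations$p_value))
  } else {
    NA_real_
  }
  if (any(!nzchar(df$term_id)) || any(!nzchar(df$gene))) {
    stop("validation error: empty term or gene identifier", call. = FALSE)
  }
  scored <- !is.na(df$p_value)
  if (any(df$p_value[scored] <= 0 | df$p_value[scored] > 1)) {
    stop("validation error: p_value outside (0,1]", call. = FALSE)
  }
  n_raw <- nrow(df)
  # collapse duplicate (term, gene) rows keeping the smallest p-value;
  # NA (unscored) sorts after any numeric p
  ord <- order(df$term_id, df$gene, df$p_value, na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  key <- paste(df$term_id, df$gene, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("geneset_catalog", "data.frame"),
            source = source,
            species = if (source == "WORMBASE") "worm" else "human",
            n_raw = n_raw, n_removed = n_raw - nrow(df))
}

#' Parse a gene-association catalog from a TSV file
#'
#' @param path TSV file with header `term_id`, `label`, `gene` and optional
#'   `p_value` column (empty string or `NA` = unscored).
#' @inheritParams geneset_catalog
#' @return A `geneset_catalog`.
#' @export
parse_catalog <- function(path, source = c("OMIM", "DGA", "GWAS_CATALOGUE",
                                           "GWAS_CENTRAL", "WORMBASE")) {
  source <- match.arg(source)
  tab <- read_table_file(path, required = c("term_id", "label", "gene"))
  if ("p_value" %in% names(tab)) {
    raw <- tab$p_value
    blank <- !nzchar(raw) | raw == "NA"
    p <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(p) & !blank)
    if (length(bad)) {
      stop("format error in '", path, "', line ", bad[1L] + 1L,
           ": p_value token '", raw[bad[1L]], "' is not a number",
           call. = FALSE)
    }
    tab$p_value <- p
  }
  cat_out <- geneset_catalog(tab, source)
  message("parse_catalog: ", attr(cat_out, "n_raw"), " rows read from '",
          path, "', ", attr(cat_out, "n_removed"),
          " duplicate (term, gene) row(s) collapsed")
  cat_out
}

#' @export
print.geneset_catalog <- function(x, ...) {
  cat("geneset_catalog [", attr(x, "source"), ", ", attr(x, "species"),
      "]: ", nrow(x), " associations, ",
      length(unique(x$term_id)), " terms, ",
      length(unique(x$gene)), " genes\n", sep = "")
  invisible(x)
}

#' Filter catalog associations by p-value
#'
#' Keeps associations whose p-value is strictly below `threshold`,
#' mirroring the GWAS input filters (catalogue entries at p < 1e-5, GWAS
#' Central entries at p < 1e-10). Unscored associations (no p-value, as in
#' OMIM/DGA/WormBase exports) are kept when `keep_unscored = TRUE`
#' (default).
#'
#' @param catalog A `geneset_catalog`.
#' @param threshold Probability in (0,1].
#' @param keep_unscored Keep rows lacking a p-value? Default `TRUE`.
#' @return The filtered `geneset_catalog`.
#' @export
filter_by_pvalue <- function(catalog, threshold, keep_unscored = TRUE) {
  stopifnot(inherits(catalog, "geneset_catalog"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("domain error: threshold must be in (0,1]", call. = FALSE)
  }
  keep <- ifelse(is.na(catalog$p_value), keep_unscored,
                 catalog$p_value < threshold)
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("source", "species")] <-
    attributes(catalog)[c("source", "species")]
  attr(out, "n_raw") <- attr(catalog, "n_raw")
  attr(out, "n_removed") <- attr(catalog, "n_removed")
  class(out) <- class(catalog)
  out
}

#' Terms of a catalog
#'
#' @param catalog A `geneset_catalog`.
#' @return Data.frame with one row per distinct term: `term_id`, `label`,
#'   `source`, `species`, `n_genes`.
#' @export
catalog_terms <- function(catalog) {
  stopifnot(inherits(catalog, "geneset_catalog"))
  first <- !duplicated(catalog$term_id)
  data.frame(term_id = catalog$term_id[first],
             label = catalog$label[first],
             source = attr(catalog, "source"),
             species = attr(catalog, "species"),
             n_genes = as.integer(table(catalog$term_id)[catalog$term_id[first]]),
             stringsAsFactors = FALSE)
}

#' Gene set associated with a phenotype or disease term
#'
#' @param catalog A `geneset_catalog`.
#' @param term_id Term identifier present in the catalog.
#' @return Sorted character vector of the distinct genes associated with
#'   the term.
#' @export
gene_set_for_term <- function(catalog, term_id) {
  stopifnot(inherits(catalog, "geneset_catalog"))
  hit <- catalog$term_id == term_id
  if (!any(hit)) {
    terms <- catalog_terms(catalog)
    d <- utils::adist(term_id, terms$term_id, ignore.case = TRUE)
    d2 <- utils::adist(term_id, terms$label, ignore.case = TRUE)
    near <- terms[order(pmin(d[1L, ], d2[1L, ]))[seq_len(min(3L, nrow(terms)))], ]
    stop("lookup error: term '", term_id, "' not in ",
         attr(catalog, "source"), " catalog; nearest terms: ",
         paste0(near$term_id, " ('", near$label, "')", collapse = ", "),
         call. = FALSE)
  }
  sort(unique(catalog$gene[hit]))
}
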