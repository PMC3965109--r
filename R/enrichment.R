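#' Upper-tail hypergeometric overlap probability
#'
#' The phenolog statistic: given a shared background of `N` ortholog
#' groups, a worm phenotype hitting `n1` of them and a human disease
#' hitting `n2`, the probability of observing `k` or more groups hit by
#' both under random draws,
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n1,n2)}
#'   \frac{\binom{n1}{i}\binom{N-n1}{n2-i}}{\binom{N}{n2}}.}
#' Each term is computed from log-gamma binomials and the sum is assembled
#' with log-sum-exp, so extreme tails (p down to the 1e-300 regime and
#' below, via `log.p`) are computed without underflow. Inputs are recycled
#' to a common length.
#'
#' @param N Background size (number of shared ortholog groups).
#' @param n1,n2 Sizes of the two projected gene sets (each `<= N`).
#' @param k Observed overlap, `0 <= k <= min(n1, n2)`.
#' @param log.p Return the natural-log probability instead?
#' @return Numeric vector of upper-tail probabilities (or their logs).
#' @examples
#' hypergeom_tail(4649, 16, 12, 3)   # ~7.2e-6
#' hypergeom_tail(5, 2, 2, 2)        # exactly 1/10
#' @export
hypergeom_tail <- function(N, n1, n2, k, log.p = FALSE) {
  n <- max(length(N), length(n1), length(n2), length(k))
  N <- rep_len(as.numeric(N), n); n1 <- rep_len(as.numeric(n1), n)
  n2 <- rep_len(as.numeric(n2), n); k <- rep_len(as.numeric(k), n)
  if (any(is.na(N) | is.na(n1) | is.na(n2) | is.na(k))) {
    stop("domain error: NA parameter", call. = FALSE)
  }
  if (any(N < 0 | n1 < 0 | n2 < 0 | k < 0 | n1 > N | n2 > N |
          k > pmin(n1, n2))) {
    stop("domain error: need 0 <= k <= min(n1,n2) and n1,n2 <= N",
         call. = FALSE)
  }
  logp <- numeric(n)
  todo <- which(k > 0)            # P(X >= 0) = 1 exactly
  if (length(todo)) {
    kmax <- pmin(n1, n2)
    width <- max(kmax[todo] - k[todo]) + 1L
    # matrix of summation indices i = k, k+1, ..., min(n1,n2); one row per
    # query, padded columns masked out
    i <- outer(k[todo], seq_len(width) - 1L, `+`)
    valid <- i <= kmax[todo]
    lt <- lchoose(n1[todo], i) + lchoose(N[todo] - n1[todo], n2[todo] - i) -
      lchoose(N[todo], n2[todo])
    dim(lt) <- dim(i)             # lchoose drops matrix dimensions
    # terms with i < n1 + n2 - N lie outside the support: lchoose = -Inf
    lt[!valid] <- -Inf
    m <- do.call(pmax, as.data.frame(lt))   # row max as log-sum-exp pivot
    s <- m + log(rowSums(exp(lt - m)))
    logp[todo] <- pmin(s, 0)      # clamp fp noise above log(1)
  }
  if (log.p) logp else exp(logp)
}

#' Phenolog overlap test for one pair of gene sets
#'
#' Projects a worm and a human gene set into shared ortholog-group space
#' and evaluates the upper-tail hypergeometric probability of their
#' overlap. With `counting = "genes"` the reported `n1`/`n2` are counts of
#' projecting genes rather than groups (the overlap `k` is always counted
#' in group space, the only space where the two species share units).
#'
#' @param worm_genes,human_genes Character vectors of gene identifiers.
#' @param map An `ortholog_map`.
#' @param N_override Optional explicit background size, e.g. to reproduce
#'   literature values computed on another ortholog mapping. Must be at
#'   least `max(n1, n2)`.
#' @param counting `"groups"` (default) or `"genes"`.
#' @return A one-row `phenolog_result` data.frame with columns `n1`, `n2`,
#'   `k`, `N`, `p` plus term metadata placeholders.
#' @export
phenolog_test <- function(worm_genes, human_genes, map, N_override = NULL,
                          counting = c("groups", "genes")) {
  counting <- match.arg(counting)
  g1 <- project_set(worm_genes, "worm", map)
  g2 <- project_set(human_genes, "human", map)
  k <- length(intersect(g1, g2))
  if (counting == "groups") {
    n1 <- length(g1); n2 <- length(g2)
  } else {
    n1 <- length(unique(worm_genes)) - attr(g1, "dropped")
    n2 <- length(unique(human_genes)) - attr(g2, "dropped")
  }
  N <- if (is.null(N_override)) background_size(map) else as.integer(N_override)
  if (N < max(n1, n2)) {
    stop("domain error: N_override (", N, ") smaller than a projected set (",
         max(n1, n2), ")", call. = FALSE)
  }
  p <- if (n1 == 0L || n2 == 0L) 1 else hypergeom_tail(N, n1, n2, k)
  phenolog_result(term1_id = NA_character_, term1_label = NA_character_,
                  term1_source = NA_character_, term2_id = NA_character_,
                  term2_label = NA_character_, term2_source = NA_character_,
                  n1 = n1, n2 = n2, k = k, N = N, p = p)
}

phenolog_result <- function(term1_id, term1_label, term1_source, term2_id,
                            term2_label, term2_source, n1, n2, k, N, p,
                            p_adjusted = NA_real_) {
  structure(data.frame(term1_id = term1_id, term1_label = term1_label,
                       term1_source = term1_source, term2_id = term2_id,
                       term2_label = term2_label, term2_source = term2_source,
                       n1 = as.integer(n1), n2 = as.integer(n2),
                       k = as.integer(k), N = as.integer(N),
                       p = p, p_adjusted = p_adjusted,
                       stringsAsFactors = FALSE),
            class = c("phenolog_result", "data.frame"))
}

empty_phenolog_result <- function() {
  phenolog_result(character(), character(), character(), character(),
                  character(), character(), integer(), integer(), integer(),
                  integer(), numeric(), numeric())
}

#' @export
print.phenolog_result <- function(x, ...) {
  cat("phenolog overlap results: ", nrow(x), " pair(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg adjustment with an explicit test count
#'
#' Step-up false-discovery-rate adjustment where the multiplicity
#' denominator `m` may exceed the number of p-values supplied (the omitted
#' tests all having p = 1, as for zero-overlap pairs dropped from sweep
#' output).
#'
#' @param p_values Numeric vector of raw p-values in (0,1].
#' @param m Total number of tests performed; `m >= length(p_values)`.
#' @return Adjusted p-values, each `>=` the raw value, capped at 1.
#' @export
bh_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    stop("domain error: m must be at least length(p_values)", call. = FALSE)
  }
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("domain error: p-values must lie in (0,1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH", n = m)
}

# project every term of a catalog to group space; returns a sparse
# term x shared-group incidence matrix (groups in fixed map order)
term_incidence <- function(catalog, map) {
  species <- attr(catalog, "species")
  mem <- map$membership
  mem <- mem[mem$species == species & mem$group %in% map$shared_groups, ,
             drop = FALSE]
  hit <- merge(data.frame(term_id = catalog$term_id, gene = catalog$gene,
                          stringsAsFactors = FALSE),
               mem[, c("gene", "group")], by = "gene")
  terms <- sort(unique(catalog$term_id))
  groups <- sort(map$shared_groups)
  if (!nrow(hit)) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                dims = c(length(terms), length(groups)),
                                dimnames = list(terms, groups)))
  }
  key <- paste(hit$term_id, hit$group, sep = "\r")
  hit <- hit[!duplicated(key), , drop = FALSE]
  Matrix::sparseMatrix(i = match(hit$term_id, terms),
                       j = match(hit$group, groups), x = 1,
                       dims = c(length(terms), length(groups)),
                       dimnames = list(terms, groups))
}

#' All-versus-all phenolog sweep between two catalogs
#'
#' Tests every worm phenotype term against every human disease term for
#' cross-species gene-set overlap in ortholog-group space. Pairs with zero
#' overlap are omitted from the output but still count in the multiplicity
#' denominator used for the optional Benjamini-Hochberg adjustment (their
#' p is exactly 1). Results are sorted by ascending p, ties broken
#' lexicographically by (worm term id, human term id).
#'
#' @param worm_catalog A worm `geneset_catalog` (source WORMBASE).
#' @param human_catalog A human `geneset_catalog`.
#' @param map An `ortholog_map`.
#' @param adjust `"none"` (default; uncorrected p-values as reported by
#'   the web tool) or `"bh"`.
#' @param N_override Optional explicit background size.
#' @return A `phenolog_result` data.frame; attribute `m` holds the total
#'   number of tested pairs including zero-overlap ones.
#' @export
broad_sweep <- function(worm_catalog, human_catalog, map,
                        adjust = c("none", "bh"), N_override = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(worm_catalog, "geneset_catalog"),
            inherits(human_catalog, "geneset_catalog"))
  if (attr(worm_catalog, "species") != "worm" ||
      attr(human_catalog, "species") != "human") {
    stop("domain error: broad_sweep needs a worm and a human catalog, in ",
         "that order", call. = FALSE)
  }
  if (!nrow(worm_catalog) || !nrow(human_catalog)) {
    stop("domain error: catalogs must be non-empty", call. = FALSE)
  }
  W <- term_incidence(worm_catalog, map)
  H <- term_incidence(human_catalog, map)
  N <- if (is.null(N_override)) background_size(map) else as.integer(N_override)
  n1 <- Matrix::rowSums(W)
  n2 <- Matrix::rowSums(H)
  if (N < max(c(n1, n2, 0))) {
    stop("domain error: N_override smaller than a projected set",
         call. = FALSE)
  }
  K <- as(W %*% Matrix::t(H), "TsparseMatrix")  # overlap counts, k >= 1 only
  m_total <- nrow(W) * nrow(H)
  if (!length(K@x)) {
    res <- phenolog_result(character(), character(), character(),
                           character(), character(), character(),
                           integer(), integer(), integer(), integer(),
                           numeric(), numeric())[0L, ]
    attr(res, "m") <- m_total
    return(res)
  }
  i <- K@i + 1L; j <- K@j + 1L; k <- as.integer(K@x)
  p <- hypergeom_tail(N, n1[i], n2[j], k)
  wt <- catalog_terms(worm_catalog); ht <- catalog_terms(human_catalog)
  wmeta <- wt[match(rownames(W)[i], wt$term_id), ]
  hmeta <- ht[match(rownames(H)[j], ht$term_id), ]
  res <- phenolog_result(term1_id = wmeta$term_id, term1_label = wmeta$label,
                         term1_source = wmeta$source,
                         term2_id = hmeta$term_id, term2_label = hmeta$label,
                         term2_source = hmeta$source,
                         n1 = n1[i], n2 = n2[j], k = k, N = N, p = p)
  if (adjust == "bh") res$p_adjusted <- bh_adjust(res$p, m_total)
  res <- res[order(res$p, res$term1_id, res$term2_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("phenolog_result", "data.frame")
  attr(res, "m") <- m_total
  res
}

#' Within-species enrichment of one term against all others
#'
#' Hypergeometric overlap of a query term's gene set against every other
#' term of the same catalog, in plain gene space; the background is the
#' number of distinct genes in the catalog. Useful to find the closest
#' related disease for an input disease. Zero-overlap terms are omitted;
#' sorting matches [broad_sweep()].
#'
#' @param catalog A `geneset_catalog`.
#' @param query_term_id Term id present in the catalog.
#' @param adjust `"none"` or `"bh"`.
#' @return A `phenolog_result` data.frame (query term as term1).
#' @export
within_species_sweep <- function(catalog, query_term_id,
                                 adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  qset <- gene_set_for_term(catalog, query_term_id)  # errors if unknown
  universe <- unique(catalog$gene)
  N <- length(universe)
  terms <- catalog_terms(catalog)
  others <- terms[terms$term_id != query_term_id, , drop = FALSE]
  qmeta <- terms[terms$term_id == query_term_id, ]
  sets <- split(catalog$gene, catalog$term_id)
  k <- vapply(others$term_id,
              function(t) length(intersect(qset, unique(sets[[t]]))),
              integer(1L))
  n2 <- vapply(others$term_id, function(t) length(unique(sets[[t]])),
               integer(1L))
  keep <- k >= 1L
  m_total <- nrow(others)
  others <- others[keep, , drop = FALSE]
  k <- k[keep]; n2 <- n2[keep]
  if (!nrow(others)) {
    res <- phenolog_result(character(), character(), character(),
                           character(), character(), character(),
                           integer(), integer(), integer(), integer(),
                           numeric(), numeric())[0L, ]
    attr(res, "m") <- m_total
    return(res)
  }
  p <- hypergeom_tail(N, length(qset), n2, k)
  res <- phenolog_result(term1_id = qmeta$term_id, term1_label = qmeta$label,
                         term1_source = qmeta$source,
                         term2_id = others$term_id,
                         term2_label = others$label,
                         term2_source = others$source,
                         n1 = length(qset), n2 = n2, k = k, N = N, p = p)
  if (adjust == "bh") res$p_adjusted <- bh_adjust(res$p, m_total)
  res <- res[order(res$p, res$term1_id, res$term2_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("phenolog_result", "data.frame")
  attr(res, "m") <- m_total
  res
}
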