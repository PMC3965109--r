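#' Read an ortholog pair table
#'
#' Expects a TSV with header columns `worm_gene`, `human_gene`, `bootstrap`.
#' The bootstrap value is the percentage of resampled alignments in which
#' the pair was found reciprocally best matched (100 = maximal support).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `worm_gene`, `human_gene`, `bootstrap`.
#' @export
read_ortholog_pairs <- function(path) {
  tab <- read_table_file(path, required = c("worm_gene", "human_gene",
                                            "bootstrap"))
  out <- data.frame(worm_gene = tab$worm_gene,
                    human_gene = tab$human_gene,
                    bootstrap = as.numeric(tab$bootstrap),
                    stringsAsFactors = FALSE)
  validate_ortholog_pairs(out, path)
  out
}

validate_ortholog_pairs <- function(pairs, origin = "<in-memory>") {
  if (!all(c("worm_gene", "human_gene", "bootstrap") %in% names(pairs))) {
    stop("format error: ortholog table needs columns worm_gene, human_gene, ",
         "bootstrap", call. = FALSE)
  }
  if (any(!nzchar(pairs$worm_gene)) || any(!nzchar(pairs$human_gene))) {
    stop("validation error in '", origin, "': empty gene identifier",
         call. = FALSE)
  }
  if (any(is.na(pairs$bootstrap)) ||
      any(pairs$bootstrap < 0 | pairs$bootstrap > 100)) {
    stop("validation error in '", origin,
         "': bootstrap values must be percentages in [0,100]", call. = FALSE)
  }
  key <- paste(pairs$worm_gene, pairs$human_gene, sep = "\r")
  if (anyDuplicated(key)) {
    stop("validation error in '", origin, "': duplicated ortholog pair (",
         sub("\r", ", ", key[duplicated(key)][1L]), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build an ortholog-group map from pairwise ortholog calls
#'
#' Pairs below `min_bootstrap` are discarded; the remaining pairs are edges
#' of a bipartite worm-human gene graph whose connected components are the
#' ortholog groups. The shared background size `N` -- the universe of the
#' phenolog overlap test -- is the number of groups containing at least one
#' gene of each species (all components built from cross-species pairs do).
#'
#' With `background = "pairs"` each retained pair is its own background
#' unit instead of the flattened component; a gene then belongs to every
#' pair that names it. This alternative background reproduces pair-level
#' counting for one-to-many ortholog tables.
#'
#' @param pairs Data.frame with columns `worm_gene`, `human_gene`,
#'   `bootstrap` (see [read_ortholog_pairs()]).
#' @param min_bootstrap Minimum bootstrap percentage to retain a pair
#'   (default 100: only maximally supported calls).
#' @param background `"groups"` (connected components, default) or
#'   `"pairs"`.
#' @return An `ortholog_map` object: list with `membership` (data.frame
#'   gene/species/group), `groups` (list of member genes per group id),
#'   `shared_groups`, `N`, `background`, `min_bootstrap`.
#' @examples
#' pairs <- data.frame(worm_gene = c("w1", "w1", "w2"),
#'                     human_gene = c("h1", "h2", "h2"),
#'                     bootstrap = 100)
#' m <- build_groups(pairs)
#' background_size(m)  # 1: all four genes collapse to one group
#' @export
build_groups <- function(pairs, min_bootstrap = 100,
                         background = c("groups", "pairs")) {
  background <- match.arg(background)
  validate_ortholog_pairs(pairs)
  if (min_bootstrap < 0 || min_bootstrap > 100) {
    stop("domain error: min_bootstrap must be in [0,100]", call. = FALSE)
  }
  keep <- pairs$bootstrap >= min_bootstrap
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) {
    return(new_ortholog_map(
      membership = data.frame(gene = character(), species = character(),
                              group = character(), stringsAsFactors = FALSE),
      background = background, min_bootstrap = min_bootstrap))
  }
  if (background == "pairs") {
    group <- paste0(pairs$worm_gene, "|", pairs$human_gene)
    membership <- data.frame(
      gene = c(pairs$worm_gene, pairs$human_gene),
      species = rep(c("worm", "human"), each = nrow(pairs)),
      group = c(group, group), stringsAsFactors = FALSE)
    return(new_ortholog_map(membership, background, min_bootstrap))
  }
  # species-tagged vertex names keep a worm and a human gene with the same
  # id distinct in the graph
  vw <- paste0("worm\r", pairs$worm_gene)
  vh <- paste0("human\r", pairs$human_gene)
  g <- igraph::graph_from_edgelist(cbind(vw, vh), directed = FALSE)
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  species <- sub("\r.*$", "", vnames)
  gene <- sub("^[^\r]*\r", "", vnames)
  # deterministic group id: lexicographically smallest member gene id
  grp_label <- vapply(split(gene, comp$membership),
                      function(g) sort(g)[1L], character(1L))
  membership <- data.frame(gene = gene, species = species,
                           group = unname(grp_label[as.character(comp$membership)]),
                           stringsAsFactors = FALSE)
  new_ortholog_map(membership, background, min_bootstrap)
}

new_ortholog_map <- function(membership, background, min_bootstrap) {
  if (!all(membership$species %in% c("worm", "human"))) {
    stop("validation error: species tag must be 'worm' or 'human'",
         call. = FALSE)
  }
  membership <- membership[order(membership$group, membership$species,
                                 membership$gene), , drop = FALSE]
  rownames(membership) <- NULL
  groups <- split(membership$gene, membership$group)
  has_worm <- vapply(split(membership$species == "worm", membership$group),
                     any, logical(1L))
  has_human <- vapply(split(membership$species == "human", membership$group),
                      any, logical(1L))
  shared <- names(groups)[has_worm & has_human]
  structure(list(membership = membership, groups = groups,
                 shared_groups = shared, N = length(shared),
                 background = background, min_bootstrap = min_bootstrap),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("ortholog_map (background = ", x$background, ")\n", sep = "")
  cat("  genes:  ", sum(x$membership$species == "worm"), " worm, ",
      sum(x$membership$species == "human"), " human\n", sep = "")
  cat("  groups: ", length(x$groups), " (shared background N = ", x$N,
      ")\n", sep = "")
  invisible(x)
}

#' Shared ortholog background size
#'
#' @param map An `ortholog_map`.
#' @return `N`, the number of ortholog groups containing genes of both
#'   species -- the universe of the phenolog hypergeometric test.
#' @export
background_size <- function(map) {
  stopifnot(inherits(map, "ortholog_map"))
  map$N
}

#' Project a gene set into ortholog-group space
#'
#' Maps genes of one species onto the shared ortholog groups they belong
#' to. Genes without an ortholog group (or belonging only to non-shared
#' groups) are dropped; their number is reported in the `"dropped"`
#' attribute of the result.
#'
#' @param genes Character vector of gene identifiers (exact,
#'   case-sensitive match).
#' @param species `"worm"` or `"human"`.
#' @param map An `ortholog_map`.
#' @return Character vector of group ids (sorted, distinct) with attribute
#'   `dropped` = number of input genes that did not project.
#' @export
project_set <- function(genes, species = c("worm", "human"), map) {
  species <- match.arg(species)
  stopifnot(inherits(map, "ortholog_map"))
  genes <- unique(as.character(genes))
  mem <- map$membership
  hit <- mem[mem$species == species & mem$gene %in% genes, , drop = FALSE]
  grp <- sort(unique(hit$group[hit$group %in% map$shared_groups]))
  projected_genes <- unique(hit$gene[hit$group %in% map$shared_groups])
  structure(grp, dropped = length(genes) - length(projected_genes))
}

#' Worm or human member genes of a set of ortholog groups
#'
#' The inverse direction of [project_set()]: collect all genes of one
#' species belonging to any of the given groups.
#'
#' @param group_ids Character vector of group ids.
#' @param species `"worm"` or `"human"`.
#' @param map An `ortholog_map`.
#' @return Sorted character vector of distinct gene ids.
#' @export
genes_of_groups <- function(group_ids, species = c("worm", "human"), map) {
  species <- match.arg(species)
  stopifnot(inherits(map, "ortholog_map"))
  mem <- map$membership
  sort(unique(mem$gene[mem$species == species & mem$group %in% group_ids]))
}
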