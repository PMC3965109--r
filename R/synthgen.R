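#' Define a synthetic study scenario
#'
#' Parameterises the synthetic test bed: an ortholog background, worm and
#' human association catalogs with planted phenologs among random decoy
#' terms, RIL-style genotypes, and expression traits with planted cis
#' eQTLs and one planted trans eQTL hotspot.
#'
#' Defaults describe a realistic worm-human study: a background of 4649
#' ortholog groups (the size of the worm-human orthologue complement at
#' 100% bootstrap support), one planted phenolog with 16 worm-side and 12
#' human-side groups overlapping in 3 (the high-incidence-male-progeny /
#' breast-cancer configuration), 200 decoy terms per species with 3-15
#' genes each (typical disease-catalog set sizes), 100 recombinant inbred
#' strains typed at 5 x 50 evenly spaced markers with a 0.1 flip
#' probability per marker interval, and 500 expression probes: 60 trans
#' targets of one hotspot marker, the rest cis-regulated or pure noise.
#' Effect sizes default to twice the noise standard deviation.
#'
#' @param seed Master seed; each artifact (orthologs, catalogs, genotypes,
#'   expression) draws from its own stream derived from it.
#' @param n_groups Number of one-to-one ortholog pairs seeding the
#'   background.
#' @param planted_phenologs List of `c(n1, n2, k)` integer triples.
#' @param n_decoy_terms Decoy terms per species.
#' @param decoy_size_range Inclusive range of decoy gene-set sizes.
#' @param many2many_frac Fraction of extra cross-edges creating
#'   many-to-many ortholog relations (merging groups).
#' @param low_boot_frac Fraction of extra decoy pairs with bootstrap < 100
#'   (removed by the default filter).
#' @param n_strains Number of RIL strains.
#' @param n_chrom,markers_per_chrom Genome layout; chromosomes are named
#'   I, II, III, IV, V, ...
#' @param chrom_length_bp Length of each chromosome in base pairs.
#' @param recomb_prob Genotype flip probability per adjacent marker
#'   interval, in (0, 0.5].
#' @param n_probes Number of expression probes.
#' @param cis_frac Fraction of non-hotspot probes given a cis effect at
#'   their nearest marker (the rest are pure noise).
#' @param cis_effect Cis allele-substitution effect (trait units).
#' @param hotspot_chrom,hotspot_marker_index Location of the planted trans
#'   hotspot (defaults: last chromosome, middle marker).
#' @param hotspot_n_targets Number of trans probes driven by the hotspot.
#' @param hotspot_effect Hotspot allele-substitution effect.
#' @param noise_sd Residual standard deviation of expression traits.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_groups = 4649L,
                               planted_phenologs = list(c(16L, 12L, 3L)),
                               n_decoy_terms = 200L,
                               decoy_size_range = c(3L, 15L),
                               many2many_frac = 0.05,
                               low_boot_frac = 0.05,
                               n_strains = 100L,
                               n_chrom = 5L,
                               markers_per_chrom = 50L,
                               chrom_length_bp = 2e7,
                               recomb_prob = 0.1,
                               n_probes = 500L,
                               cis_frac = 0.8,
                               cis_effect = 2,
                               hotspot_chrom = NULL,
                               hotspot_marker_index = NULL,
                               hotspot_n_targets = 60L,
                               hotspot_effect = 2,
                               noise_sd = 1) {
  scn <- list(seed = as.integer(seed), n_groups = as.integer(n_groups),
              planted_phenologs = planted_phenologs,
              n_decoy_terms = as.integer(n_decoy_terms),
              decoy_size_range = as.integer(decoy_size_range),
              many2many_frac = many2many_frac,
              low_boot_frac = low_boot_frac,
              n_strains = as.integer(n_strains),
              n_chrom = as.integer(n_chrom),
              markers_per_chrom = as.integer(markers_per_chrom),
              chrom_length_bp = chrom_length_bp,
              recomb_prob = recomb_prob,
              n_probes = as.integer(n_probes), cis_frac = cis_frac,
              cis_effect = cis_effect,
              hotspot_chrom = hotspot_chrom,
              hotspot_marker_index = hotspot_marker_index,
              hotspot_n_targets = as.integer(hotspot_n_targets),
              hotspot_effect = hotspot_effect, noise_sd = noise_sd)
  for (pl in scn$planted_phenologs) {
    if (length(pl) != 3L || pl[3L] > min(pl[1L], pl[2L]) ||
        max(pl[1L], pl[2L]) > scn$n_groups) {
      stop("domain error: planted phenolog needs k <= min(n1,n2) <= n_groups",
           call. = FALSE)
    }
  }
  if (scn$recomb_prob <= 0 || scn$recomb_prob > 0.5) {
    stop("domain error: recomb_prob must lie in (0, 0.5]", call. = FALSE)
  }
  if (scn$noise_sd <= 0) {
    stop("domain error: noise_sd must be positive", call. = FALSE)
  }
  if (diff(scn$decoy_size_range) < 0 || scn$decoy_size_range[1L] < 1L) {
    stop("domain error: bad decoy_size_range", call. = FALSE)
  }
  if (is.null(scn$hotspot_chrom)) scn$hotspot_chrom <- scn$n_chrom
  if (is.null(scn$hotspot_marker_index)) {
    scn$hotspot_marker_index <- ceiling(scn$markers_per_chrom / 2)
  }
  structure(scn, class = "synthetic_scenario")
}

# one stream per artifact so regenerating one file does not shift others
with_stream <- function(scenario, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(scenario$seed * 13L + offset)
  force(expr)
}

chrom_names <- function(n) as.character(utils::as.roman(seq_len(n)))

#' Generate an ortholog pair table
#'
#' `n_groups` one-to-one worm-human pairs at bootstrap 100, plus a
#' fraction of extra many-to-many edges (which merge groups when the map
#' is built) and a fraction of decoy pairs with sub-100 bootstrap support
#' (removed by the default filter).
#'
#' @param scenario A `synthetic_scenario`.
#' @return Ortholog pair data.frame (`worm_gene`, `human_gene`,
#'   `bootstrap`).
#' @export
gen_ortholog_map <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_stream(scenario, 1L, {
    n <- scenario$n_groups
    w <- sprintf("wg%05d", seq_len(n))
    h <- sprintf("hg%05d", seq_len(n))
    pairs <- data.frame(worm_gene = w, human_gene = h, bootstrap = 100,
                        stringsAsFactors = FALSE)
    n_extra <- round(scenario$many2many_frac * n)
    if (n_extra > 0) {
      iw <- sample.int(n, n_extra)
      ih <- sample.int(n, n_extra)
      extra <- data.frame(worm_gene = w[iw], human_gene = h[ih],
                          bootstrap = 100, stringsAsFactors = FALSE)
      pairs <- rbind(pairs, extra)
    }
    n_low <- round(scenario$low_boot_frac * n)
    if (n_low > 0) {
      low <- data.frame(worm_gene = sprintf("wx%05d", seq_len(n_low)),
                        human_gene = sprintf("hx%05d", seq_len(n_low)),
                        bootstrap = sample(50:99, n_low, replace = TRUE),
                        stringsAsFactors = FALSE)
      pairs <- rbind(pairs, low)
    }
    key <- paste(pairs$worm_gene, pairs$human_gene)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    rownames(pairs) <- NULL
    pairs
  })
}

#' Generate worm and human association catalogs with planted phenologs
#'
#' For each planted `(n1, n2, k)` triple, `k` shared ortholog groups are
#' hit by both species' term, `n1 - k` further groups by the worm term
#' only and `n2 - k` by the human term only, one member gene per group,
#' so the planted counts are recovered exactly by the overlap test. Decoy
#' terms draw their gene sets uniformly from the map's genes.
#'
#' @param scenario A `synthetic_scenario`.
#' @param map The `ortholog_map` built from [gen_ortholog_map()] output.
#' @return List: `worm` and `human` catalogs (`geneset_catalog`) and
#'   `truth`, a data.frame of planted term pairs with their group picks.
#' @export
gen_catalogs <- function(scenario, map) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(map, "ortholog_map"))
  with_stream(scenario, 2L, {
    shared <- sort(map$shared_groups)
    mem <- map$membership
    worm_genes <- sort(unique(mem$gene[mem$species == "worm"]))
    human_genes <- sort(unique(mem$gene[mem$species == "human"]))
    first_member <- function(groups, species) {
      vapply(groups, function(g) {
        cand <- mem$gene[mem$group == g & mem$species == species]
        sort(cand)[1L]
      }, character(1L))
    }
    worm_rows <- list(); human_rows <- list(); truth <- list()
    for (idx in seq_along(scenario$planted_phenologs)) {
      pl <- scenario$planted_phenologs[[idx]]
      n1 <- pl[1L]; n2 <- pl[2L]; k <- pl[3L]
      if (max(n1, n2) > length(shared)) {
        stop("domain error: planted set larger than shared background",
             call. = FALSE)
      }
      picks <- sample(shared, n1 + n2 - k)
      g_shared <- picks[seq_len(k)]
      g_worm <- picks[k + seq_len(n1 - k)]
      g_human <- picks[n1 + seq_len(n2 - k)]
      wt <- sprintf("wp%04d", idx); ht <- sprintf("hd%04d", idx)
      worm_rows[[length(worm_rows) + 1L]] <- data.frame(
        term_id = wt, label = sprintf("planted worm phenotype %d", idx),
        gene = first_member(c(g_shared, g_worm), "worm"),
        stringsAsFactors = FALSE)
      human_rows[[length(human_rows) + 1L]] <- data.frame(
        term_id = ht, label = sprintf("planted human disease %d", idx),
        gene = first_member(c(g_shared, g_human), "human"),
        stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(worm_term = wt, human_term = ht,
                                 n1 = n1, n2 = n2, k = k,
                                 stringsAsFactors = FALSE)
    }
    decoy <- function(prefix, label, pool) {
      sizes <- sample(scenario$decoy_size_range[1L]:scenario$decoy_size_range[2L],
                      scenario$n_decoy_terms, replace = TRUE)
      do.call(rbind, lapply(seq_len(scenario$n_decoy_terms), function(i) {
        data.frame(term_id = sprintf("%s%04d", prefix, i),
                   label = sprintf("%s %d", label, i),
                   gene = sample(pool, sizes[i]), stringsAsFactors = FALSE)
      }))
    }
    worm_df <- rbind(do.call(rbind, worm_rows),
                     decoy("wd", "decoy worm phenotype", worm_genes))
    human_df <- rbind(do.call(rbind, human_rows),
                      decoy("hx", "decoy human disease", human_genes))
    list(worm = geneset_catalog(worm_df, "WORMBASE"),
         human = geneset_catalog(human_df, "OMIM"),
         truth = do.call(rbind, truth))
  })
}

#' Generate RIL genotypes and a marker map
#'
#' Per strain and chromosome a two-state Markov chain over alleles A/B:
#' the first marker is Bernoulli(1/2), each following marker flips with
#' probability `recomb_prob`. Markers are evenly spaced along each
#' chromosome.
#'
#' @param scenario A `synthetic_scenario`.
#' @return List: `genotypes` (a `matrix_file`, strains x markers) and
#'   `markers` (marker map data.frame).
#' @export
gen_ril_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_stream(scenario, 3L, {
    S <- scenario$n_strains; M <- scenario$markers_per_chrom
    chroms <- chrom_names(scenario$n_chrom)
    strains <- sprintf("RIL%03d", seq_len(S))
    geno <- NULL; marker_tabs <- list()
    for (ci in seq_along(chroms)) {
      start <- matrix(stats::rbinom(S, 1L, 0.5), S, 1L)
      flips <- matrix(stats::rbinom(S * (M - 1L), 1L, scenario$recomb_prob),
                      S, M - 1L)
      states <- t(apply(cbind(start, flips), 1L, cumsum)) %% 2
      geno <- cbind(geno, states)
      marker_tabs[[ci]] <- data.frame(
        marker_id = sprintf("m_%s_%02d", chroms[ci], seq_len(M)),
        chrom = chroms[ci],
        pos_bp = round(seq(1, scenario$chrom_length_bp, length.out = M)),
        stringsAsFactors = FALSE)
    }
    markers <- do.call(rbind, marker_tabs)
    sym <- matrix(c("A", "B")[geno + 1L], nrow = S)
    dimnames(sym) <- list(strains, markers$marker_id)
    list(genotypes = matrix_file(strains, markers$marker_id, sym),
         markers = markers)
  })
}

#' Generate expression traits with planted cis eQTLs and a trans hotspot
#'
#' Probes are laid out uniformly over the genome and annotated to worm
#' genes of the scenario's ortholog table. `hotspot_n_targets` probes on
#' chromosomes other than the hotspot's receive `hotspot_effect` times the
#' hotspot marker's genotype (the trans band); a `cis_frac` share of the
#' remaining probes receive `cis_effect` times the genotype of the marker
#' nearest their own locus; every probe gets Gaussian noise.
#'
#' @param scenario A `synthetic_scenario`.
#' @param genotypes `matrix_file` from [gen_ril_genotypes()].
#' @param markers Marker map from [gen_ril_genotypes()].
#' @return List: `traits` (`matrix_file` probes x strains), `annotation`
#'   (probe annotation data.frame) and `truth` (per-probe type, true
#'   marker, hotspot marker id).
#' @export
gen_expression <- function(scenario, genotypes, markers) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(genotypes, "matrix_file"))
  with_stream(scenario, 4L, {
    P <- scenario$n_probes; S <- length(genotypes$row_ids)
    chroms <- chrom_names(scenario$n_chrom)
    hs_chrom <- chroms[scenario$hotspot_chrom]
    hs_marker <- markers$marker_id[markers$chrom == hs_chrom][
      scenario$hotspot_marker_index]
    probe_chrom <- sample(chroms, P, replace = TRUE)
    probe_start <- sample.int(scenario$chrom_length_bp - 1000L, P,
                              replace = TRUE)
    probe_end <- probe_start + sample(200:1000, P, replace = TRUE)
    # trans targets must sit away from the hotspot chromosome
    trans_idx <- sample(which(probe_chrom != hs_chrom),
                        scenario$hotspot_n_targets)
    rest <- setdiff(seq_len(P), trans_idx)
    n_cis <- round(scenario$cis_frac * length(rest))
    cis_idx <- sample(rest, n_cis)
    probe_ids <- sprintf("probe%04d", seq_len(P))
    gene_ids <- sprintf("wg%05d",
                        sample.int(scenario$n_groups, P,
                                   replace = P > scenario$n_groups))
    X <- matrix(as.numeric(genotypes$values == "B"),
                nrow = S, dimnames = dimnames(genotypes$values))
    nearest_marker <- vapply(seq_len(P), function(i) {
      cand <- markers[markers$chrom == probe_chrom[i], ]
      mid <- floor((probe_start[i] + probe_end[i]) / 2)
      cand$marker_id[which.min(abs(cand$pos_bp - mid))]
    }, character(1L))
    Y <- matrix(stats::rnorm(P * S, sd = scenario$noise_sd), P, S,
                dimnames = list(probe_ids, genotypes$row_ids))
    for (i in cis_idx) {
      Y[i, ] <- Y[i, ] + scenario$cis_effect * X[, nearest_marker[i]]
    }
    Y[trans_idx, ] <- Y[trans_idx, , drop = FALSE] +
      scenario$hotspot_effect *
      matrix(X[, hs_marker], length(trans_idx), S, byrow = TRUE)
    type <- rep("null", P)
    type[cis_idx] <- "cis"; type[trans_idx] <- "trans"
    truth <- data.frame(probe_id = probe_ids, type = type,
                        true_marker = ifelse(type == "cis", nearest_marker,
                                      ifelse(type == "trans", hs_marker, NA)),
                        stringsAsFactors = FALSE)
    annotation <- data.frame(probe_id = probe_ids, gene_id = gene_ids,
                             chrom = probe_chrom, start_bp = probe_start,
                             end_bp = probe_end,
                             mid_bp = floor((probe_start + probe_end) / 2),
                             stringsAsFactors = FALSE)
    list(traits = matrix_file(probe_ids, genotypes$row_ids, Y),
         annotation = annotation,
         truth = truth, hotspot_marker = hs_marker)
  })
}

#' Generate and write a complete scenario to a directory
#'
#' Emits every input file the toolkit reads (ortholog pairs, worm and
#' human catalogs, genotype and trait matrices, marker map, probe
#' annotation) plus a ground-truth manifest (planted phenolog pairs, true
#' eQTL markers, hotspot marker) as JSON.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- gen_ortholog_map(scenario)
  map <- build_groups(pairs)
  cats <- gen_catalogs(scenario, map)
  ril <- gen_ril_genotypes(scenario)
  expr <- gen_expression(scenario, ril$genotypes, ril$markers)
  paths <- c(orthologs = file.path(dir, "ortholog_pairs.tsv"),
             worm_catalog = file.path(dir, "worm_catalog.tsv"),
             human_catalog = file.path(dir, "human_catalog.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             traits = file.path(dir, "traits.tsv"),
             markers = file.path(dir, "markers.tsv"),
             annotation = file.path(dir, "probe_annotation.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_tsv_df <- function(df, path) {
    writeLines(c(paste(names(df), collapse = "\t"),
                 do.call(paste, c(lapply(df, as.character), sep = "\t"))),
               path)
  }
  write_tsv_df(pairs, paths["orthologs"])
  write_tsv_df(as.data.frame(cats$worm)[c("term_id", "label", "gene")],
               paths["worm_catalog"])
  write_tsv_df(as.data.frame(cats$human)[c("term_id", "label", "gene")],
               paths["human_catalog"])
  write_matrix(ril$genotypes, paths["genotypes"])
  write_matrix(expr$traits, paths["traits"])
  write_tsv_df(ril$markers, paths["markers"])
  write_tsv_df(expr$annotation[c("probe_id", "gene_id", "chrom",
                                 "start_bp", "end_bp")],
               paths["annotation"])
  manifest <- list(seed = scenario$seed,
                   background_N = background_size(map),
                   planted_phenologs = cats$truth,
                   hotspot_marker = expr$hotspot_marker,
                   probe_truth = expr$truth)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
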