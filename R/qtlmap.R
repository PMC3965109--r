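#' Read a marker map
#'
#' @param path TSV with header `marker_id`, `chrom`, `pos_bp` (1-based).
#' @return Data.frame ordered by (chrom, pos_bp) with those columns.
#' @export
read_marker_map <- function(path) {
  tab <- read_table_file(path, required = c("marker_id", "chrom", "pos_bp"))
  out <- data.frame(marker_id = tab$marker_id, chrom = tab$chrom,
                    pos_bp = as.numeric(tab$pos_bp),
                    stringsAsFactors = FALSE)
  validate_marker_map(out, path)
  out[order(out$chrom, out$pos_bp, out$marker_id), , drop = FALSE]
}

validate_marker_map <- function(markers, origin = "<in-memory>") {
  check_unique_ids(markers$marker_id, "marker_id", origin)
  if (any(is.na(markers$pos_bp)) || any(markers$pos_bp < 1)) {
    stop("validation error in '", origin, "': pos_bp must be >= 1",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a probe annotation table
#'
#' @param path TSV with header `probe_id`, `gene_id`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive; `gene_id` may be empty).
#' @return Data.frame with those columns plus `mid_bp`, the integer
#'   midpoint used for probe ordering.
#' @export
read_probe_annotation <- function(path) {
  tab <- read_table_file(path, required = c("probe_id", "gene_id", "chrom",
                                            "start_bp", "end_bp"))
  out <- data.frame(probe_id = tab$probe_id, gene_id = tab$gene_id,
                    chrom = tab$chrom,
                    start_bp = as.numeric(tab$start_bp),
                    end_bp = as.numeric(tab$end_bp),
                    stringsAsFactors = FALSE)
  validate_probe_annotation(out, path)
  out$mid_bp <- floor((out$start_bp + out$end_bp) / 2)
  out
}

validate_probe_annotation <- function(annotation, origin = "<in-memory>") {
  check_unique_ids(annotation$probe_id, "probe_id", origin)
  if (any(is.na(annotation$start_bp)) || any(is.na(annotation$end_bp)) ||
      any(annotation$start_bp > annotation$end_bp) ||
      any(annotation$start_bp < 1)) {
    stop("validation error in '", origin,
         "': need 1 <= start_bp <= end_bp", call. = FALSE)
  }
  invisible(TRUE)
}

# ensure a mid_bp column (in-memory annotations may lack it)
with_midpoints <- function(annotation) {
  if (is.null(annotation$mid_bp)) {
    annotation$mid_bp <- floor((annotation$start_bp + annotation$end_bp) / 2)
  }
  annotation
}

#' Single-marker LOD scan of expression traits
#'
#' For every (probe, marker) pair, fits the two-genotype group-mean model
#' to the strains with both a trait value and a genotype call and scores
#' it against the no-QTL model:
#' \deqn{LOD = (n/2)\,\log_{10}(RSS_0 / RSS_1)}
#' with `RSS0` the null (grand-mean) and `RSS1` the residual sum of
#' squares of the group-mean fit. A trait with no variance (`RSS0 = 0`)
#' and a monomorphic marker both score 0; a perfect fit (`RSS1 = 0`) is
#' clamped via `RSS1 >= eps * RSS0` (eps = 1e-12) so LOD stays finite.
#' Pairs with fewer than 3 complete strains get a missing LOD.
#'
#' @param traits A `matrix_file`, probes x strains (numeric).
#' @param genotypes A `matrix_file`, strains x markers, cells from a
#'   biallelic `alphabet`.
#' @param markers Optional marker map (data.frame `marker_id`, `chrom`,
#'   `pos_bp`); enables positional peak tie-breaks and hotspot ordering.
#' @param alphabet The two genotype symbols (default `c("A", "B")`).
#' @param eps Relative clamp for perfect fits (default 1e-12).
#' @return A `qtl_scan` object: list with `lod` (probes x markers matrix),
#'   `n` (strain counts used), `markers`, `probe_ids`, `marker_ids`.
#' @export
lod_scan <- function(traits, genotypes, markers = NULL,
                     alphabet = c("A", "B"), eps = 1e-12) {
  stopifnot(inherits(traits, "matrix_file"), inherits(genotypes, "matrix_file"))
  strains <- intersect(traits$col_ids, genotypes$row_ids)
  if (!length(strains)) {
    stop("validation error: trait and genotype matrices share no strains",
         call. = FALSE)
  }
  if (length(strains) < 3L) {
    stop("validation error: need at least 3 shared strains, found ",
         length(strains), call. = FALSE)
  }
  Y <- traits$values[, strains, drop = FALSE]          # probes x strains
  G <- genotypes$values[strains, , drop = FALSE]       # strains x markers
  bad <- setdiff(unique(G[!is.na(G)]), alphabet)
  if (length(bad)) {
    stop("validation error: genotype symbol '", bad[1L],
         "' not in alphabet {", paste(alphabet, collapse = ","), "}",
         call. = FALSE)
  }
  X <- array(NA_real_, dim(G))
  X[G == alphabet[1L]] <- 0; X[G == alphabet[2L]] <- 1
  if (!anyNA(Y) && !anyNA(X)) {
    scan <- lod_scan_complete(Y, X, eps)
  } else {
    scan <- lod_scan_missing(Y, X, eps)
  }
  lod <- scan$lod; nmat <- scan$n
  dimnames(lod) <- dimnames(nmat) <- list(traits$row_ids, genotypes$col_ids)
  if (!is.null(markers)) {
    validate_marker_map(markers)
    miss <- setdiff(genotypes$col_ids, markers$marker_id)
    if (length(miss)) {
      stop("validation error: marker(s) ", paste(miss[1:min(3, length(miss))],
           collapse = ", "), " absent from marker map", call. = FALSE)
    }
    markers <- markers[match(genotypes$col_ids, markers$marker_id), ,
                       drop = FALSE]
  }
  structure(list(lod = lod, n = nmat, markers = markers,
                 probe_ids = traits$row_ids, marker_ids = genotypes$col_ids),
            class = "qtl_scan")
}

# fast path: no missing data anywhere
lod_scan_complete <- function(Y, X, eps) {
  n <- ncol(Y)
  Yc <- Y - rowMeans(Y)
  Xc <- sweep(X, 2L, colMeans(X))
  rss0 <- rowSums(Yc * Yc)                       # per probe
  sxx <- colSums(Xc * Xc)                        # per marker
  sxy <- Yc %*% Xc                               # probes x markers
  mono <- sxx == 0
  sxx_safe <- ifelse(mono, 1, sxx)
  rss1 <- pmax(rss0 - sweep(sxy^2, 2L, sxx_safe, `/`), 0)
  lod <- lod_from_rss(rss0, rss1, n, eps)
  lod[, mono] <- 0
  lod[rss0 == 0, ] <- 0
  list(lod = lod, n = matrix(n, nrow(Y), ncol(X)))
}

# general path: per-marker loop with pairwise deletion
lod_scan_missing <- function(Y, X, eps) {
  P <- nrow(Y); M <- ncol(X)
  lod <- matrix(NA_real_, P, M)
  nmat <- matrix(0L, P, M)
  yobs <- !is.na(Y)
  for (j in seq_len(M)) {
    gj <- X[, j]
    sel <- !is.na(gj)
    Ys <- Y[, sel, drop = FALSE]
    obs <- yobs[, sel, drop = FALSE]
    g <- gj[sel]
    n <- rowSums(obs)
    Y0 <- Ys; Y0[!obs] <- 0
    tot <- rowSums(Y0)
    mu <- tot / n
    rss0 <- rowSums((Y0 - outer(mu, rep(1, length(g))))^2 * obs)
    nB <- rowSums(obs[, g == 1, drop = FALSE])
    nA <- n - nB
    totB <- rowSums(Y0[, g == 1, drop = FALSE])
    totA <- tot - totB
    muA <- ifelse(nA > 0, totA / nA, 0)
    muB <- ifelse(nB > 0, totB / nB, 0)
    fit <- outer(muA, 1 - g) + outer(muB, g)
    rss1 <- rowSums((Y0 - fit)^2 * obs)
    l <- lod_from_rss(rss0, rss1, n, eps)
    l[nA == 0 | nB == 0] <- 0          # monomorphic after deletion
    l[rss0 == 0] <- 0
    l[n < 3] <- NA_real_
    lod[, j] <- l
    nmat[, j] <- n
  }
  list(lod = lod, n = nmat)
}

lod_from_rss <- function(rss0, rss1, n, eps) {
  if (is.matrix(rss1) && !is.matrix(rss0)) {
    rss0 <- matrix(rss0, nrow(rss1), ncol(rss1))
  }
  rss1 <- pmax(rss1, eps * rss0)
  ratio <- rss0 / pmax(rss1, .Machine$double.xmin)
  ratio[rss0 == 0] <- 1               # no trait variance, no signal
  (n / 2) * log10(ratio)
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("qtl_scan: ", length(x$probe_ids), " probes x ", length(x$marker_ids),
      " markers\n", sep = "")
  finite <- x$lod[!is.na(x$lod)]
  cat("  LOD range: ", format(min(finite), digits = 3), " .. ",
      format(max(finite), digits = 3), "; ", sum(is.na(x$lod)),
      " missing\n", sep = "")
  invisible(x)
}

#' Highest-LOD marker for one probe
#'
#' Returns the marker maximising the probe's LOD profile, provided that
#' maximum is strictly above the threshold; ties are broken by the
#' smallest (chrom, pos_bp) when a marker map is attached, by column
#' order otherwise.
#'
#' @param scan A `qtl_scan`.
#' @param probe_id Probe identifier present in the scan.
#' @param lod_threshold Strict lower bound for a reported peak.
#' @return One-row data.frame (`probe_id`, `marker_id`, `lod`, plus
#'   `chrom`/`pos_bp` when a marker map is attached), or `NULL` when no
#'   marker exceeds the threshold.
#' @export
find_peak <- function(scan, probe_id, lod_threshold) {
  stopifnot(inherits(scan, "qtl_scan"))
  if (!probe_id %in% scan$probe_ids) {
    stop("lookup error: probe '", probe_id, "' not in scan", call. = FALSE)
  }
  row <- scan$lod[probe_id, ]
  ord <- marker_order(scan)
  row <- row[ord]
  if (all(is.na(row))) return(NULL)
  best <- which.max(row)          # first maximum in positional order
  if (!(row[best] > lod_threshold)) return(NULL)
  mid <- names(row)[best]
  out <- data.frame(probe_id = probe_id, marker_id = mid,
                    lod = unname(row[best]), stringsAsFactors = FALSE)
  if (!is.null(scan$markers)) {
    mrow <- scan$markers[scan$markers$marker_id == mid, ]
    out$chrom <- mrow$chrom; out$pos_bp <- mrow$pos_bp
  }
  out
}

marker_order <- function(scan) {
  if (is.null(scan$markers)) return(seq_along(scan$marker_ids))
  order(scan$markers$chrom, scan$markers$pos_bp, scan$markers$marker_id)
}

#' Probes flanking a peak marker
#'
#' Selects up to `count_per_side` probes on each side of a peak marker on
#' the peak's chromosome, nearest first by genomic distance between the
#' probe midpoint and the marker position; probes left of the peak are
#' those with midpoint strictly below it. The combined window is returned
#' in genomic order.
#'
#' @param peak_marker One-row data.frame or list with `chrom` and
#'   `pos_bp` (e.g. a [find_peak()] result).
#' @param annotation Probe annotation data.frame (see
#'   [read_probe_annotation()]).
#' @param count_per_side Probes to take on each side (default 50, the
#'   QTL-to-disease window).
#' @return Character vector of probe ids, ordered by (midpoint, probe_id).
#' @export
flanking_probes <- function(peak_marker, annotation, count_per_side = 50) {
  annotation <- with_midpoints(annotation)
  ann <- annotation[annotation$chrom == peak_marker$chrom, , drop = FALSE]
  ann <- ann[order(ann$mid_bp, ann$probe_id), , drop = FALSE]
  pos <- peak_marker$pos_bp
  left <- ann[ann$mid_bp < pos, , drop = FALSE]
  right <- ann[ann$mid_bp >= pos, , drop = FALSE]
  take_left <- utils::tail(left, count_per_side)      # nearest below
  take_right <- utils::head(right, count_per_side)    # nearest at/above
  c(take_left$probe_id, take_right$probe_id)
}

#' Parse a genomic region string
#'
#' Accepts `"ChrV:15430739-16430739"` style strings (optional `Chr`
#' prefix, hyphen or en-dash separator); coordinates are 1-based
#' inclusive.
#'
#' @param text Region string.
#' @return A `genomic_region`: list with `chrom`, `start_bp`, `end_bp`.
#' @export
parse_region <- function(text) {
  m <- regmatches(text,
                  regexec("^(?:[Cc]hr)?([A-Za-z0-9_]+):([0-9]+)[-–]([0-9]+)$",
                          text, perl = TRUE))
  m <- m[[1L]]
  if (!length(m)) {
    stop("format error: cannot parse region '", text,
         "' (expected Chr<NAME>:<start>-<end>)", call. = FALSE)
  }
  start <- as.numeric(m[3L]); end <- as.numeric(m[4L])
  if (start > end) {
    stop("validation error: region start ", m[3L], " exceeds end ", m[4L],
         call. = FALSE)
  }
  genomic_region(m[2L], start, end)
}

#' @rdname parse_region
#' @param chrom Chromosome name (canonical, no `Chr` prefix).
#' @param start_bp,end_bp 1-based inclusive bounds, `start_bp <= end_bp`.
#' @export
genomic_region <- function(chrom, start_bp, end_bp) {
  if (start_bp > end_bp || start_bp < 1) {
    stop("validation error: need 1 <= start_bp <= end_bp", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), start_bp = start_bp,
                 end_bp = end_bp), class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat("region ", x$chrom, ":", format(x$start_bp, scientific = FALSE), "-",
      format(x$end_bp, scientific = FALSE), "\n", sep = "")
  invisible(x)
}

#' Probes annotated within a genomic region
#'
#' Inclusive interval intersection: a probe is returned when its
#' `[start_bp, end_bp]` interval overlaps the region by at least one base.
#'
#' @param region A `genomic_region`.
#' @param annotation Probe annotation data.frame.
#' @return Character vector of probe ids sorted by (midpoint, probe_id).
#' @export
region_probes <- function(region, annotation) {
  stopifnot(inherits(region, "genomic_region"))
  annotation <- with_midpoints(annotation)
  hit <- annotation$chrom == region$chrom &
    annotation$start_bp <= region$end_bp &
    annotation$end_bp >= region$start_bp
  ann <- annotation[hit, , drop = FALSE]
  ann <- ann[order(ann$mid_bp, ann$probe_id), , drop = FALSE]
  ann$probe_id
}

#' Count probes peaking at each marker (eQTL hotspots)
#'
#' For every probe, locates its peak marker at the given threshold and
#' tallies peaks per marker. A marker where many expression traits
#' co-localise their peaks is an eQTL hotspot, suggesting a shared
#' regulator.
#'
#' @param scan A `qtl_scan`.
#' @param lod_threshold Strict LOD threshold for counting a peak.
#' @return A `hotspot_counts` object: data.frame (`marker_id`, `count`,
#'   plus `chrom`/`pos_bp` when mapped) in genomic order, with attribute
#'   `argmax` = the marker id with the highest count (smallest
#'   (chrom, pos_bp) on ties).
#' @export
hotspot_counts <- function(scan, lod_threshold) {
  stopifnot(inherits(scan, "qtl_scan"))
  ord <- marker_order(scan)
  lod <- scan$lod[, ord, drop = FALSE]
  lod_z <- lod; lod_z[is.na(lod_z)] <- -Inf
  best <- max.col(lod_z, ties.method = "first")
  maxv <- lod_z[cbind(seq_len(nrow(lod_z)), best)]
  counted <- maxv > lod_threshold
  counts <- tabulate(best[counted], nbins = ncol(lod))
  out <- data.frame(marker_id = colnames(lod), count = counts,
                    stringsAsFactors = FALSE)
  if (!is.null(scan$markers)) {
    idx <- match(out$marker_id, scan$markers$marker_id)
    out$chrom <- scan$markers$chrom[idx]
    out$pos_bp <- scan$markers$pos_bp[idx]
  }
  rownames(out) <- NULL
  structure(out, class = c("hotspot_counts", "data.frame"),
            argmax = out$marker_id[which.max(out$count)])
}

#' @export
print.hotspot_counts <- function(x, ...) {
  cat("hotspot counts over ", nrow(x), " markers; argmax = ",
      attr(x, "argmax"), " (", max(x$count), " probes)\n", sep = "")
  invisible(x)
}

#' Long-format LOD profile table for plotting
#'
#' @param scan A `qtl_scan`.
#' @param probe_ids Probes to include (default all).
#' @return Data.frame `probe_id`, `marker_id`, `lod` (+ `chrom`, `pos_bp`
#'   when mapped), markers in genomic order -- the plot-ready form of the
#'   scan.
#' @export
lod_profiles <- function(scan, probe_ids = scan$probe_ids) {
  stopifnot(inherits(scan, "qtl_scan"))
  missing_p <- setdiff(probe_ids, scan$probe_ids)
  if (length(missing_p)) {
    stop("lookup error: probe '", missing_p[1L], "' not in scan",
         call. = FALSE)
  }
  ord <- marker_order(scan)
  lod <- scan$lod[probe_ids, ord, drop = FALSE]
  out <- data.frame(probe_id = rep(probe_ids, times = ncol(lod)),
                    marker_id = rep(colnames(lod), each = length(probe_ids)),
                    lod = as.vector(lod), stringsAsFactors = FALSE)
  if (!is.null(scan$markers)) {
    idx <- match(out$marker_id, scan$markers$marker_id)
    out$chrom <- scan$markers$chrom[idx]
    out$pos_bp <- scan$markers$pos_bp[idx]
  }
  out
}
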