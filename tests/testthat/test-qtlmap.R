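mini_scan <- function(lod, markers = NULL) {
  structure(list(lod = lod, n = array(10L, dim(lod)), markers = markers,
                 probe_ids = rownames(lod), marker_ids = colnames(lod)),
            class = "qtl_scan")
}

trait_mf <- function(y, strains = paste0("s", seq_along(y)), probe = "p1") {
  matrix_file(probe, strains, matrix(y, 1, dimnames = list(probe, strains)))
}

geno_mf <- function(g, strains = paste0("s", seq_along(g)), marker = "m1") {
  matrix_file(strains, marker, matrix(g, ncol = 1))
}

test_that("lod_scan reproduces hand-computed group-mean fits", {
  # y=(1,2,3,4), genotype A,B,A,B: RSS0=5, RSS1=4, LOD = 2*log10(1.25)
  s <- lod_scan(trait_mf(c(1, 2, 3, 4)), geno_mf(c("A", "B", "A", "B")))
  expect_equal(s$lod[1, 1], 2 * log10(5 / 4), tolerance = 1e-12)
  # perfect separation clamps at (n/2)*log10(1/eps) = 36 for n=6
  s2 <- lod_scan(trait_mf(c(1, 1, 1, 2, 2, 2)),
                 geno_mf(c("A", "A", "A", "B", "B", "B")))
  expect_equal(s2$lod[1, 1], 36)
  # no trait variance scores zero
  s3 <- lod_scan(trait_mf(rep(2, 4)), geno_mf(c("A", "B", "A", "B")))
  expect_identical(s3$lod[1, 1], 0)
  # monomorphic marker scores zero
  s4 <- lod_scan(trait_mf(c(1, 2, 3, 4)), geno_mf(rep("A", 4)))
  expect_identical(s4$lod[1, 1], 0)
})

test_that("lod_scan agrees with linear-model fits and the r^2 identity", {
  set.seed(21)
  n <- 40
  g <- sample(c("A", "B"), n, replace = TRUE)
  Y <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:n)))
  Y[2, ] <- Y[2, ] + 1.5 * (g == "B")
  tr <- matrix_file(rownames(Y), colnames(Y), Y)
  ge <- geno_mf(g, strains = colnames(Y))
  s <- lod_scan(tr, ge)
  x <- as.numeric(g == "B")
  for (i in 1:5) {
    fit <- lm(Y[i, ] ~ x)
    lod_lm <- (n / 2) * log10(sum((Y[i, ] - mean(Y[i, ]))^2) /
                              sum(resid(fit)^2))
    expect_equal(s$lod[i, 1], lod_lm, tolerance = 1e-9)
    r <- cor(Y[i, ], x)
    expect_equal(s$lod[i, 1], (n / 2) * log10(1 / (1 - r^2)),
                 tolerance = 1e-9)
  }
})

test_that("LOD is invariant under affine trait transforms", {
  set.seed(31)
  n <- 30
  g <- sample(c("A", "B"), n, replace = TRUE)
  y <- rnorm(n) + (g == "B")
  base <- lod_scan(trait_mf(y, paste0("s", 1:n)),
                   geno_mf(g, paste0("s", 1:n)))$lod[1, 1]
  for (ab in list(c(3, 0), c(-2, 5), c(0.001, -7))) {
    tr <- lod_scan(trait_mf(ab[1] * y + ab[2], paste0("s", 1:n)),
                   geno_mf(g, paste0("s", 1:n)))$lod[1, 1]
    expect_equal(tr, base, tolerance = 1e-9)
  }
})

test_that("missing data is dropped pairwise; sparse pairs get missing LOD", {
  strains <- paste0("s", 1:8)
  y <- c(1, 2, 3, 4, 5, 6, NA, 8)
  g <- c("A", "B", "A", "B", NA, "B", "A", "B")
  s <- lod_scan(trait_mf(y, strains), geno_mf(g, strains))
  keep <- !is.na(y) & !is.na(g)
  fit <- lm(y[keep] ~ I(g[keep] == "B"))
  lod_ref <- (sum(keep) / 2) *
    log10(sum((y[keep] - mean(y[keep]))^2) / sum(resid(fit)^2))
  expect_equal(s$lod[1, 1], lod_ref, tolerance = 1e-9)
  expect_equal(s$n[1, 1], sum(keep))
  # fewer than 3 complete strains -> missing LOD
  y2 <- c(1, 2, NA, NA, NA, NA, NA, NA)
  s2 <- lod_scan(trait_mf(y2, strains), geno_mf(g, strains))
  expect_true(is.na(s2$lod[1, 1]))
  # zero strain overlap is a validation error
  expect_error(lod_scan(trait_mf(1:4, paste0("a", 1:4)),
                        geno_mf(rep("A", 4), paste0("b", 1:4))),
               "strains")
  # symbols outside the alphabet are rejected
  expect_error(lod_scan(trait_mf(1:4), geno_mf(c("A", "B", "H", "A"))),
               "alphabet")
})

test_that("find_peak applies a strict threshold and positional tie-breaks", {
  mk <- data.frame(marker_id = c("m1", "m2", "m3"),
                   chrom = c("I", "I", "II"), pos_bp = c(100, 200, 50))
  lod <- matrix(c(1, 6.2, 0.5,
                  0, 0, 0,
                  3, 3, 1), 3, 3, byrow = TRUE,
                dimnames = list(c("pA", "pB", "pC"), mk$marker_id))
  s <- mini_scan(lod, mk)
  pk <- find_peak(s, "pA", 5)
  expect_equal(pk$marker_id, "m2")
  expect_equal(pk$lod, 6.2)
  expect_equal(pk$chrom, "I")
  # strict inequality: all-zero row at threshold 0 gives no peak
  expect_null(find_peak(s, "pB", 0))
  # tie broken by smallest (chrom, pos_bp)
  expect_equal(find_peak(s, "pC", 1)$marker_id, "m1")
  expect_error(find_peak(s, "zz", 0), "lookup error")
})

test_that("flanking_probes picks nearest midpoints per side in genomic order", {
  ann <- data.frame(probe_id = paste0("p", 1:4), gene_id = "g",
                    chrom = "I", start_bp = c(90, 190, 290, 390),
                    end_bp = c(110, 210, 310, 410))
  peak <- list(chrom = "I", pos_bp = 250)
  expect_equal(flanking_probes(peak, ann, 1), c("p2", "p3"))
  # default window is 50 per side
  expect_equal(formals(flanking_probes)$count_per_side, 50)
  # fewer probes than requested: all returned, sorted
  expect_equal(flanking_probes(peak, ann, 50), paste0("p", 1:4))
  # off-chromosome probes never enter the window
  ann2 <- rbind(ann, data.frame(probe_id = "px", gene_id = "g", chrom = "X",
                                start_bp = 249, end_bp = 251))
  expect_false("px" %in% flanking_probes(peak, ann2, 50))
  out <- flanking_probes(peak, ann2, 2)
  expect_lte(length(out), 4L)
})

test_that("parse_region handles prefixes, dashes and bad input", {
  r <- parse_region("ChrV:15430739-16430739")
  expect_equal(r$chrom, "V")
  expect_equal(r$start_bp, 15430739)
  expect_equal(r$end_bp, 16430739)
  # en-dash variant and no prefix
  expect_equal(parse_region("V:15430739–16430739")$end_bp, 16430739)
  expect_equal(parse_region("I:1-1")$start_bp, 1)
  expect_error(parse_region("ChrX:10-5"), "validation error")
  expect_error(parse_region("whatever"), "format error")
})

test_that("region_probes uses inclusive interval intersection", {
  ann <- data.frame(probe_id = c("in1", "in2", "out1", "othchr"),
                    gene_id = "g", chrom = c("I", "I", "I", "II"),
                    start_bp = c(90, 150, 201, 100),
                    end_bp = c(110, 160, 210, 150))
  reg <- genomic_region("I", 100, 200)
  expect_equal(region_probes(reg, ann), c("in1", "in2"))
  expect_length(region_probes(genomic_region("III", 1, 100), ann), 0L)
  # whole-chromosome region returns every probe on the chromosome
  whole <- genomic_region("I", 1, 1e9)
  expect_setequal(region_probes(whole, ann), c("in1", "in2", "out1"))
})

test_that("hotspot_counts tallies peaks per marker above the threshold", {
  mk <- data.frame(marker_id = paste0("m", 1:3), chrom = "I",
                   pos_bp = c(10, 20, 30))
  lod <- matrix(c(6, 1, 0,
                  7, 2, 0,
                  0, 1, 8,
                  1, 1, 1), 4, 3, byrow = TRUE,
                dimnames = list(paste0("p", 1:4), mk$marker_id))
  hc <- hotspot_counts(mini_scan(lod, mk), 5)
  expect_equal(hc$count, c(2L, 0L, 1L))
  expect_equal(attr(hc, "argmax"), "m1")
  # threshold above the global max: all zero
  expect_equal(sum(hotspot_counts(mini_scan(lod, mk), 10)$count), 0L)
  # single probe
  hc1 <- hotspot_counts(mini_scan(lod[3, , drop = FALSE], mk), 5)
  expect_equal(hc1$count[hc1$marker_id == "m3"], 1L)
})

test_that("lod_profiles emits a plot-ready long table in genomic order", {
  mk <- data.frame(marker_id = c("mB", "mA"), chrom = "I", pos_bp = c(200, 100))
  lod <- matrix(c(1, 2), 1, 2, dimnames = list("p1", c("mB", "mA")))
  prof <- lod_profiles(mini_scan(lod, mk))
  expect_equal(prof$marker_id, c("mA", "mB"))  # reordered by position
  expect_equal(prof$lod, c(2, 1))
  expect_error(lod_profiles(mini_scan(lod, mk), "nope"), "lookup error")
})
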