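# shared hand-built fixture: 20-group one-to-one map, probes annotated to
# worm genes on two chromosomes
wf_fixture <- function() {
  map <- build_groups(one_to_one_pairs(20))
  ann <- data.frame(
    probe_id = sprintf("pr%02d", 1:12),
    gene_id = c(rep("wg1", 6),                 # six probes for one gene
                paste0("wg", c(2, 3, 4, 5, 6, 7))),
    chrom = c(rep("I", 9), rep("II", 3)),
    start_bp = c(seq(1000, 6000, by = 1000), 7000, 8000, 9000,
                 1000, 2000, 3000),
    end_bp = c(seq(1400, 6400, by = 1000), 7400, 8400, 9400,
               1400, 2400, 3400), stringsAsFactors = FALSE)
  human <- make_catalog(rep(c("d1", "d2", "d3"), c(1, 2, 3)),
                        c("hg1", "hg2", "hg3", "hg4", "hg5", "hg18"),
                        labels = c("antineoplastic response",
                                   rep("disease two", 2),
                                   rep("disease three", 3)))
  worm <- make_catalog(rep(c("wpa", "wpb"), c(3, 2)),
                       paste0("wg", c(2, 3, 4, 18, 19)), source = "WORMBASE")
  list(map = map, ann = ann, human = human, worm = worm)
}

test_that("disease2qtl maps disease genes to worm probes through orthology", {
  fx <- wf_fixture()
  # d1 -> hg1 -> group 1 -> wg1 -> six probes
  out <- disease2qtl("d1", fx$human, fx$map, fx$ann)
  expect_equal(nrow(out$selection), 6L)
  expect_setequal(out$selection$probe_id, sprintf("pr%02d", 1:6))
  expect_equal(out$worm_genes, "wg1")
  # term with no orthologous worm genes warns and selects nothing
  lonely <- make_catalog("dx", "hg_not_mapped")
  expect_warning(out2 <- disease2qtl("dx", lonely, fx$map, fx$ann),
                 "no orthologous")
  expect_equal(nrow(out2$selection), 0L)
  # two terms sharing a worm gene: probe appears once, first insertion wins
  shared <- make_catalog(c("da", "db"), c("hg2", "hg2"))
  out3 <- disease2qtl(c("da", "db"), shared, fx$map, fx$ann)
  expect_equal(out3$selection$probe_id, "pr07")
  expect_match(out3$selection$provenance, "da")
})

test_that("disease2qtl attaches LOD profiles and peaks when given a scan", {
  fx <- wf_fixture()
  mk <- data.frame(marker_id = c("mk1", "mk2"), chrom = "I",
                   pos_bp = c(1500, 8000))
  lod <- matrix(c(7, 1,
                  1, 2), 2, 2, byrow = TRUE,
                dimnames = list(c("pr01", "pr02"), mk$marker_id))
  scan <- structure(list(lod = lod, n = array(10L, dim(lod)), markers = mk,
                         probe_ids = rownames(lod), marker_ids = mk$marker_id),
                    class = "qtl_scan")
  out <- disease2qtl("d1", fx$human, fx$map, fx$ann, scan = scan,
                     lod_threshold = 5)
  expect_equal(sort(unique(out$profiles$probe_id)), c("pr01", "pr02"))
  expect_equal(out$peaks$probe_id, "pr01")
  expect_equal(out$peaks$marker_id, "mk1")
})

test_that("region2disease ranks the disease planted in the region first", {
  fx <- wf_fixture()
  # region covers pr07..pr09 -> genes wg2,wg3,wg4 -> groups {2,3,4};
  # d2 (groups 2,3) overlaps in both of its groups and ranks first,
  # d3 (groups 4,5,18) overlaps in one, d1 (group 1) is omitted (k=0)
  reg <- genomic_region("I", 6500, 9500)
  res <- region2disease(reg, fx$ann, fx$map, fx$human)
  expect_equal(attr(res, "probes"), sprintf("pr%02d", 7:9))
  expect_setequal(attr(res, "genes"), c("wg2", "wg3", "wg4"))
  expect_equal(res$term2_id, c("d2", "d3"))
  expect_equal(res$k, c(2L, 1L))
  expect_equal(res$p[1], exact_hyper_tail(20, 3, 2, 2), tolerance = 1e-12)
  expect_false(is.unsorted(res$p))
  # chromosome absent from the annotation: empty result
  res0 <- region2disease(genomic_region("X", 1, 100), fx$ann, fx$map,
                         fx$human)
  expect_equal(nrow(res0), 0L)
})

test_that("region2disease over the whole genome equals a full-complement test", {
  fx <- wf_fixture()
  genes_union <- sort(unique(fx$ann$gene_id))
  # a region spanning every probe is equivalent to testing the full gene
  # complement of the annotation directly
  all_on_I <- transform(fx$ann, chrom = "I")
  full <- region2disease(genomic_region("I", 1, 1e9), all_on_I,
                         fx$map, fx$human)
  direct <- phenolog_test(genes_union,
                          gene_set_for_term(fx$human, "d3"), fx$map)
  row_d3 <- full[full$term2_id == "d3", ]
  expect_equal(c(row_d3$n1, row_d3$n2, row_d3$k),
               c(direct$n1, direct$n2, direct$k))
  expect_equal(row_d3$p, direct$p, tolerance = 1e-12)
  # results over two disjoint regions covering everything equal the
  # full-complement enrichment computed on the union of their gene sets
  res_I <- region2disease(genomic_region("I", 1, 1e9), fx$ann, fx$map,
                          fx$human)
  res_II <- region2disease(genomic_region("II", 1, 1e9), fx$ann, fx$map,
                           fx$human)
  union_genes <- sort(union(attr(res_I, "genes"), attr(res_II, "genes")))
  expect_equal(union_genes, genes_union)
})

test_that("qtl2disease builds its window from the peak and finds the signal", {
  fx <- wf_fixture()
  mk <- data.frame(marker_id = c("mkA", "mkB"), chrom = c("I", "II"),
                   pos_bp = c(8000, 2000))
  probes <- fx$ann$probe_id
  lod <- matrix(0, length(probes), 2,
                dimnames = list(probes, mk$marker_id))
  lod["pr08", "mkA"] <- 9    # query probe peaks on chromosome I at 8000
  scan <- structure(list(lod = lod, n = array(12L, dim(lod)), markers = mk,
                         probe_ids = probes, marker_ids = mk$marker_id),
                    class = "qtl_scan")
  res <- qtl2disease("pr08", scan, 5, fx$ann, fx$map, fx$human,
                     count_per_side = 2)
  # window: 2 probes each side of pos 8000 on chrom I, incl. the query
  expect_true("pr08" %in% attr(res, "probes"))
  expect_lte(length(attr(res, "probes")), 5L)
  # window genes wg1..wg4 -> groups {1,2,3,4}; d2 (groups 2,3) wins on k=2
  expect_equal(res$term2_id[1], "d2")
  # threshold above the max: empty result with a message
  expect_message(res0 <- qtl2disease("pr08", scan, 20, fx$ann, fx$map,
                                     fx$human), "no QTL")
  expect_equal(nrow(res0), 0L)
  expect_error(qtl2disease("nope", scan, 5, fx$ann, fx$map, fx$human),
               "lookup error")
  # window truncated at the chromosome edge reports what it used
  res_edge <- qtl2disease("pr08", scan, 5, fx$ann, fx$map, fx$human,
                          count_per_side = 50)
  expect_equal(length(attr(res_edge, "probes")),
               sum(fx$ann$chrom == "I"))
})

test_that("comparepheno replicates the worked phenotype-to-disease lookup shape", {
  # 63-gene worm phenotype, 4-gene human disease, overlap 2 -- the
  # high-incidence-male-progeny / breast-cancer configuration
  map <- build_groups(one_to_one_pairs(200))
  worm <- make_catalog(rep("himp", 63), paste0("wg", 1:63),
                       source = "WORMBASE",
                       labels = "high incidence male progeny")
  human <- make_catalog(rep(c("brca", paste0("dec", 1:8)), c(4, rep(3, 8))),
                        c(paste0("hg", c(1, 2, 100, 101)),       # k = 2
                          paste0("hg", 120 + 1:24)),             # k = 0
                        labels = c(rep("breast cancer susceptibility", 4),
                                   rep("decoy disease", 24)))
  res <- comparepheno("himp", worm, human, map)
  expect_equal(res$term2_id[1], "brca")
  expect_equal(c(res$n1[1], res$n2[1], res$k[1]), c(63L, 4L, 2L))
  expect_equal(res$p[1], exact_hyper_tail(200, 63, 4, 2), tolerance = 1e-10)
  # symmetric call from the human side gives identical counts and p
  res_h <- comparepheno("brca", worm, human, map)
  row <- res_h[res_h$term1_id == "himp", ]
  expect_equal(c(row$n1, row$n2, row$k, row$p),
               c(res$n1[1], res$n2[1], res$k[1], res$p[1]))
  # empty query set produces empty output
  worm2 <- make_catalog(c("himp", "empty_t"), c("wg1", "not_a_gene"),
                        source = "WORMBASE")
  res_e <- comparepheno("empty_t", worm2, human, map)
  expect_equal(nrow(res_e), 0L)
  expect_error(comparepheno("ghost", worm, human, map), "lookup error")
})

test_that("comparepheno within-species mode delegates to the catalog sweep", {
  cat1 <- make_catalog(rep(c("q", "twin", "far"), each = 3),
                       c(paste0("g", 1:3), paste0("g", 1:3), paste0("g", 7:9)))
  res <- comparepheno("q", cat1, list(), build_groups(one_to_one_pairs(2)),
                      within_species = TRUE)
  expect_equal(res$term2_id[1], "twin")
  expect_equal(res$k[1], 3L)
})

test_that("selection sets deduplicate, keep order and round-trip via TSV", {
  s <- selection_set(c("p1", "p2", "p1"), c("a", "b", "c"))
  expect_equal(s$probe_id, c("p1", "p2"))
  s2 <- selection_add(s, c("p2", "p3"), "tool2")
  expect_equal(s2$probe_id, c("p1", "p2", "p3"))
  expect_equal(s2$provenance[3], "tool2")
  path <- tempfile(fileext = ".tsv")
  write_selection(s2, path)
  expect_equal(read_selection(path)$probe_id, s2$probe_id)
})

test_that("workflows are deterministic pure functions of their inputs", {
  fx <- wf_fixture()
  reg <- genomic_region("I", 1, 9500)
  r1 <- region2disease(reg, fx$ann, fx$map, fx$human)
  r2 <- region2disease(reg, fx$ann, fx$map, fx$human)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  p1 <- tempfile(); p2 <- tempfile()
  write_results(r1, p1); write_results(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
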