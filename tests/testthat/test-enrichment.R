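test_that("hypergeometric tail matches exact enumeration on worked examples", {
  expect_equal(hypergeom_p(10, 5, 2, 2), 10 / 45, tolerance = 1e-12)
  expect_equal(hypergeom_p(6, 3, 3, 3), 1 / 20, tolerance = 1e-12)
  expect_equal(hypergeom_p(50, 10, 8, 0), 1)
  expect_equal(hypergeom_p(10, 5, 2, 2), hyper_enum(10, 5, 2, 2))
  expect_error(hypergeom_p(10, 11, 2, 1), "universe")
  expect_error(hypergeom_p(10, 5, 2, 3), "min\\(K, n\\)")
  expect_error(hypergeom_p(10, 5, 2, -1), "nonnegative")
})

test_that("hypergeometric tail equals enumeration for moderate universes", {
  # spot-sweep across universe sizes; the acceptance suite does the full
  # N <= 50 sweep
  for (N in c(5, 12, 27, 50)) {
    for (K in c(1, floor(N / 2), N)) {
      for (n in c(1, floor(N / 3), N)) {
        if (n < 1) next
        k <- 0:min(K, n)
        expect_equal(hypergeom_p(N, K, n, k),
                     vapply(k, hyper_enum, numeric(1), N = N, K = K, n = n),
                     tolerance = 1e-12)
        # monotone non-increasing in the overlap
        expect_true(all(diff(hypergeom_p(N, K, n, k)) <= 1e-15))
      }
    }
  }
})

test_that("significant and enriched flags follow the two-level criterion", {
  # the published worked rows: large overlap -> enriched; tiny p but only
  # 2 genes -> significant only; 1 gene, p > alpha -> neither
  flags <- enrichment_flags(k = c(14, 2, 1),
                            p = c(9.69e-26, 6.66e-4, 7.59e-2))
  expect_equal(flags$significant, c(TRUE, TRUE, FALSE))
  expect_equal(flags$enriched, c(TRUE, FALSE, FALSE))
  # the full published enrichment table obeys enriched => significant
  tab <- read.delim(extdata("protein_kegg_enrichment.tsv"))
  f <- enrichment_flags(tab$overlap, tab$p_value)
  expect_true(all(!f$enriched | f$significant))
  # boundary: p exactly at alpha is significant (inclusive)
  expect_true(enrichment_flags(3, 0.05)$significant)
  # property over random inputs
  set.seed(4)
  f <- enrichment_flags(sample(0:20, 200, TRUE), runif(200))
  expect_true(all(!f$enriched | f$significant))
})

test_that("enrich computes counts in the universe and reports outsiders", {
  sets <- list(big = sprintf("g%02d", 1:10),
               small = sprintf("g%02d", 11:13),
               off = sprintf("g%02d", 90:99))
  coll <- suppressMessages(
    gene_set_collection(sets, universe = sprintf("g%02d", 1:60)))
  sig <- c("g01", "g02", "g03", "g11", "zzz")
  res <- suppressMessages(enrich(sig, coll))
  expect_setequal(attr(res, "outside_universe"), "zzz")
  expect_equal(attr(res, "n_signature"), 4)
  big <- res[res$set == "big", ]
  expect_equal(big$overlap, 3)
  expect_equal(big$p_value, hyper_enum(60, 10, 4, 3), tolerance = 1e-12)
  expect_equal(res$overlap_genes[res$set == "small"], "g11")
  # sets with zero overlap are absent; results sorted by p
  expect_false("off" %in% res$set)
  expect_true(all(diff(res$p_value) >= 0))
  expect_error(enrich("zzz", coll), "universe")
})

test_that("gene-level intersection of the two published microarray signatures", {
  s1297 <- read_signature(extdata("gse1297_signature.tsv"))
  s5281 <- read_signature(extdata("gse5281_signature.tsv"))
  ann <- rbind(attr(s1297, "annotation"), attr(s5281, "annotation"))
  ann <- ann[!duplicated(ann$probeset_id), ]
  out <- intersect_signatures(list(gse1297 = s1297, gse5281 = s5281),
                              annotation = ann)
  expect_setequal(out$all, c("RGS4", "MCTP1", "CD44", "XIST"))
  expect_equal(out$pairwise[["gse1297 & gse5281"]], sort(out$all))
})

test_that("signature intersection is commutative, associative, idempotent", {
  a <- c("XIST", "CD44", "TAC1")
  b <- c("CD44", "SST", "XIST")
  c3 <- c("XIST", "GFAP", "CD44")
  ab <- intersect_signatures(list(a = a, b = b))$all
  ba <- intersect_signatures(list(b = b, a = a))$all
  expect_identical(ab, ba)
  abc <- intersect_signatures(list(a = a, b = b, c = c3))$all
  ab_c <- intersect_signatures(list(ab = ab, c = c3))$all
  expect_identical(abc, ab_c)
  expect_identical(intersect_signatures(list(a = a, a2 = a))$all, sort(a))
  expect_identical(intersect_signatures(list(a = a, z = "PSPH"))$all,
                   character(0))
  # unmapped probesets raise an error naming them
  ann <- data.frame(probeset_id = "p1", gene_symbol = "XIST",
                    entrez_id = "7503")
  expect_error(intersect_signatures(list(x = c("p1", "p9")),
                                    annotation = ann), "p9")
})

test_that("pathway overlap table marks enriched vs significant per column", {
  mk <- function(set, category, k, p) {
    structure(
      cbind(data.frame(set = set, category = category, set_size = 20,
                       overlap = k,
                       overlap_genes = "", p_value = p,
                       p_bh = p.adjust(p, "BH")),
            enrichment_flags(k, p)),
      class = c("enrichment_result", "data.frame"))
  }
  r1 <- mk(c("Hematopoietic cell lineage", "Focal adhesion", "Private1"),
           c("Immune System", "Cell Communication", "Misc"),
           k = c(7, 2, 5), p = c(6e-14, 6.4e-3, 1e-4))
  r2 <- mk(c("Hematopoietic cell lineage", "Absent", "Focal adhesion"),
           c("Immune System", "Misc", "Cell Communication"),
           k = c(1, 1, 2), p = c(2.8e-2, 0.9, 1.7e-3))
  tab <- overlap_table(list(protein = r1, gse1297 = r2))
  row_h <- tab[tab$set == "Hematopoietic cell lineage", ]
  expect_equal(row_h$protein, "enriched")
  expect_equal(row_h$gse1297, "significant")
  # not significant anywhere -> no row at all
  expect_false("Absent" %in% tab$set)
  # present in a single signature only
  expect_equal(tab[tab$set == "Private1", ]$gse1297, "")
  expect_setequal(attr(tab, "shared_all"),
                  c("Hematopoietic cell lineage", "Focal adhesion"))
  # identical inputs: every row shared, both columns marked
  tab2 <- overlap_table(list(x = r1, y = r1))
  expect_true(all(tab2$x == tab2$y))
  expect_setequal(attr(tab2, "shared_all"), tab2$set)
  expect_error(overlap_table(list(r1)), "at least two")
})

test_that("the published cross-signature pathway reference is well-formed", {
  ref <- read.delim(extdata("kegg_overlap_reference.tsv"))
  expect_equal(nrow(ref), 8)
  marks <- as.matrix(ref[, c("protein", "gse1297", "gse5281")])
  expect_true(all(marks %in% c("", "enriched", "significant")))
  # rows marked in all three columns (the all-signature overlaps)
  shared <- ref$pathway[rowSums(marks != "") == 3]
  expect_true(all(c("Neuroactive ligand-receptor migration",
                    "Hematopoietic cell lineage",
                    "MAPK signaling pathway",
                    "Focal adhesion") %in% shared))
})
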