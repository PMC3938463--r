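test_that("normalization lands every array on mean 8 / SD 2 and is idempotent", {
  set.seed(91)
  m <- matrix(rnorm(200, 7, 1.3), 10, 20,
              dimnames = list(sprintf("S%02d", 1:10),
                              sprintf("t%02d", 1:20)))
  z <- normalize_expression(m)
  expect_lt(max(abs(rowMeans(z) - 8)), 1e-9)
  sdp <- sqrt(rowMeans((z - rowMeans(z))^2))
  expect_lt(max(abs(sdp - 2)), 1e-9)
  expect_lt(max(abs(normalize_expression(z) - z)), 1e-12)
  # order-preserving within each strain
  expect_identical(apply(z, 1, order), apply(m, 1, order))
  # hand vector, population-SD convention
  h <- normalize_expression(matrix(c(0, 2, 4), 1, 3,
                                   dimnames = list("S1", NULL)))
  expect_equal(as.numeric(h), c(5.551, 8, 10.449), tolerance = 5e-4)
  # zero-variance strain named in the error
  m[3, ] <- 5
  expect_error(normalize_expression(m), "S03")
})

test_that("transcript scans find planted cis signals and respect the cutoff", {
  p <- small_panel()
  ann <- simulate_annotation(p$geno, 40, seed = 92)
  gene <- ann$gene_id[8]
  mk <- nearest_marker(p$geno, ann$chr[8], ann$start_Mb[8])
  ex <- simulate_expression(p$geno, ann,
                            list(planted_eqtl(gene, mk, 2, "both")),
                            seed = 93)
  E <- normalize_expression(ex$treated)
  eq <- scan_transcripts(E, p$grid, suggestive_cutoff = 12)
  expect_true(gene %in% eq$transcript_id)
  row <- eq[eq$transcript_id == gene, ]
  expect_equal(row$chr, ann$chr[8])
  expect_lt(abs(row$peak_Mb - ann$start_Mb[8]), 10)
  # cutoff = Inf empties the list
  expect_equal(nrow(scan_transcripts(E, p$grid, Inf)), 0L)
  # disjoint strain sets are an alignment error
  E2 <- E
  rownames(E2) <- paste0("other_", rownames(E2))
  expect_error(scan_transcripts(E2, p$grid), "no strains")
  # pure-noise transcripts rarely clear LRS 12
  null_keep <- nrow(eq) / ncol(E)
  expect_lt(null_keep, 0.5)
})

test_that("cis/trans classification applies the inclusive 10-Mb rule", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC"),
                    chr = c("1", "1", "2"),
                    start_Mb = c(50, 50, 50), end_Mb = c(50.1, 50.1, 50.1),
                    has_nssnp = FALSE, stringsAsFactors = FALSE)
  eq <- structure(data.frame(
    transcript_id = c("gA", "gB", "gC"),
    peak_id = c("x", "y", "z"), chr = c("1", "1", "1"),
    peak_Mb = c(59.9, 60.0, 55), lrs_max = 20, effect = 1, n = 30,
    stringsAsFactors = FALSE), class = c("eqtl_set", "data.frame"),
    cutoff = 12)
  cl <- classify_cis_trans(eq, ann, cis_window_Mb = 10)
  expect_equal(cl$regulation, c("cis", "cis", "trans"))  # 10.0 inclusive
  expect_equal(cl$distance_Mb, c(9.9, 10, NA))
  eq$transcript_id[1] <- "ghost"
  expect_error(classify_cis_trans(eq, ann), "missing from annotation")
  # planted labels are recovered exactly when >= 1 Mb from the boundary
  p <- small_panel()
  ann2 <- simulate_annotation(p$geno, 60, seed = 94)
  planted <- lapply(c(5, 15, 25), function(i)
    planted_eqtl(ann2$gene_id[i],
                 nearest_marker(p$geno, ann2$chr[i], ann2$start_Mb[i]),
                 effect_size = 3, condition_scope = "both"))
  ex <- simulate_expression(p$geno, ann2, planted, seed = 95)
  cl2 <- classify_cis_trans(
    scan_transcripts(normalize_expression(ex$treated), p$grid, 12),
    ann2, 10)
  for (pe in planted) {
    expect_equal(
      cl2$regulation[cl2$transcript_id == pe$gene_id], "cis")
  }
})

test_that("region dissection reproduces construction truth and brute force", {
  ann <- data.frame(
    gene_id = sprintf("g%d", 1:7), chr = c(rep("1", 6), "2"),
    start_Mb = c(12, 15, 18, 22, 28, 60, 15),
    end_Mb = c(12.1, 15.1, 18.1, 22.1, 28.1, 60.1, 15.1),
    has_nssnp = FALSE, stringsAsFactors = FALSE)
  # five genes inside [10, 30] on chr 1; 2 cis + 1 trans eQTL peaking in
  eq <- structure(data.frame(
    transcript_id = c("g1", "g3", "g7"),
    peak_id = c("mA", "mB", "mC"), chr = "1",
    peak_Mb = c(13, 19, 25), lrs_max = c(20, 15, 18), effect = 1,
    n = 30, stringsAsFactors = FALSE),
    class = c("eqtl_set", "data.frame"), cutoff = 12)
  eq <- classify_cis_trans(eq, ann, 10)
  expect_equal(eq$regulation, c("cis", "cis", "trans"))
  pq <- structure(data.frame(
    trait = "t", dataset = "both", chr = "1", peak_Mb = 20,
    peak_id = "mB", lrs_max = 18, effect = 1, support_lo_Mb = 10,
    support_hi_Mb = 30, class = "significant",
    stringsAsFactors = FALSE), class = c("pqtl_set", "data.frame"))
  rs <- dissect_pqtl(pq, eq, ann, cutoff_lrs = 12)
  expect_equal(rs$n_genes, 5L)
  expect_equal(rs$n_eqtls, 3L)
  expect_equal(rs$n_cisqtls, 2L)
  expect_setequal(rs$cisqtgs, c("g1", "g3"))
  # empty annotation: all counts zero
  rs0 <- dissect_pqtl(pq, eq[0, ], ann[0, ], 12)
  expect_equal(c(rs0$n_genes, rs0$n_eqtls, rs0$n_cisqtls,
                 rs0$n_cisqtgs), rep(0L, 4))
  # brute-force enumeration oracle on a synthetic genome
  p <- small_panel()
  ann2 <- simulate_annotation(p$geno, 80, seed = 96)
  planted <- lapply(c(10, 30, 50), function(i)
    planted_eqtl(ann2$gene_id[i],
                 nearest_marker(p$geno, ann2$chr[i], ann2$start_Mb[i]),
                 3, "both"))
  ex <- simulate_expression(p$geno, ann2, planted, seed = 97)
  eq2 <- classify_cis_trans(
    scan_transcripts(normalize_expression(ex$treated), p$grid, 12),
    ann2, 10)
  pq2 <- structure(data.frame(
    trait = "t", dataset = "both", chr = ann2$chr[30],
    peak_Mb = ann2$start_Mb[30], peak_id = "na", lrs_max = 15,
    effect = 1, support_lo_Mb = max(0, ann2$start_Mb[30] - 15),
    support_hi_Mb = ann2$start_Mb[30] + 15, class = "significant",
    stringsAsFactors = FALSE), class = c("pqtl_set", "data.frame"))
  rs2 <- dissect_pqtl(pq2, eq2, ann2, 12)
  inside <- function(mb) mb >= pq2$support_lo_Mb & mb <= pq2$support_hi_Mb
  bf_genes <- sum(ann2$chr == pq2$chr & inside(ann2$start_Mb))
  bf_mark <- unique(eq2$peak_id[eq2$chr == pq2$chr & inside(eq2$peak_Mb)])
  bf_cis <- unique(eq2$peak_id[eq2$chr == pq2$chr & inside(eq2$peak_Mb) &
                                 eq2$regulation == "cis"])
  in_genes <- ann2$gene_id[ann2$chr == pq2$chr & inside(ann2$start_Mb)]
  bf_qtg <- unique(eq2$transcript_id[eq2$regulation == "cis" &
                                       eq2$lrs_max >= 12 &
                                       eq2$transcript_id %in% in_genes])
  expect_equal(rs2$n_genes, bf_genes)
  expect_setequal(rs2$eqtl_markers, bf_mark)
  expect_equal(rs2$n_cisqtls, length(bf_cis))
  expect_setequal(rs2$cisqtgs, bf_qtg)
  # funnel: genes in regions always at least the cisQTGs
  expect_gte(rs2$n_genes, rs2$n_cisqtgs)
})

test_that("strain-distribution concordance is perfect for monogenic patterns", {
  p <- small_panel()
  mk <- p$map$marker[20]
  dose <- fibroqtl:::call_dose(p$geno$calls[, mk])
  clean <- stats::setNames(8 + 2 * dose, p$geno$lines)
  expect_equal(sdp_concordance(clean, p$geno, mk), 1.0)
  # independent transcript sits near chance
  set.seed(98)
  noise <- stats::setNames(rnorm(30), p$geno$lines)
  expect_lt(abs(sdp_concordance(noise, p$geno, mk) - 0.5), 0.25)
  # label symmetry: swapping B and D leaves the value unchanged
  flipped <- p$geno
  flipped$calls[] <- ifelse(p$geno$calls == "B", "D", "B")
  expect_equal(sdp_concordance(clean, flipped, mk),
               sdp_concordance(clean, p$geno, mk))
  expect_error(sdp_concordance(clean, p$geno, "nope"), "unknown marker")
})
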