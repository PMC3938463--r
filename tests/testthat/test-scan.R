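test_that("pseudomarker dosages equal the RI Markov-chain conditional expectation", {
  calls <- rbind(c("B", "B"), c("B", "D"), c("D", "B"), c("U", "D"))
  g <- make_geno(calls, chr = c("1", "1"), mb = c(0, 20), cm = c(0, 10))
  grid <- dosage_grid(g, step_cM = 2.5)
  expect_error(dosage_grid(g, step_cM = 0), "step_cM")
  # midway pseudomarker
  mid <- which(grid$positions$cM == 5)
  expect_length(mid, 1L)
  dmid <- grid$dosage[, mid]
  # equal B flanks: certainty is not total but symmetric around -1 side
  R <- ri_recombination(haldane_r(5))
  p_same <- (1 - R)^2 / ((1 - R)^2 + R^2)
  expect_equal(unname(dmid[1]), -(2 * p_same - 1), tolerance = 1e-12)
  # opposite flanks at the midpoint: 0 by symmetry
  expect_equal(unname(dmid[2]), 0, tolerance = 1e-12)
  expect_equal(unname(dmid[3]), 0, tolerance = 1e-12)
  # single informative flank
  expect_equal(unname(dmid[4]), 1 * (1 - 2 * R), tolerance = 1e-12)
  # asymmetric pseudomarker (2.5 cM from left, 7.5 from right),
  # hand-enumerated two-interval chain
  q <- which(grid$positions$cM == 2.5)
  R1 <- ri_recombination(haldane_r(2.5))
  R2 <- ri_recombination(haldane_r(7.5))
  p_ne <- (1 - R1) * R2 / ((1 - R1) * R2 + R1 * (1 - R2))
  expect_equal(unname(grid$dosage[2, q]), -(2 * p_ne - 1),
               tolerance = 1e-12)
  # genotyped markers keep exact doses, missing stays missing
  expect_equal(unname(grid$dosage[, 1]), c(-1, -1, 1, NA))
})

test_that("scan LRS equals the naive regression oracle at every position", {
  p <- small_panel()
  ph <- simulate_phenotypes(p$geno,
                            list(planted_qtl(p$map$marker[40], 0.4)),
                            0.6, seed = 51)
  y <- strain_values(summarize_strains(ph), "trait", "both")
  sc <- scan_trait(y, p$grid)
  expect_equal(sc$lrs, lm_scan_oracle(y[attr(sc, "lines")], p$grid),
               tolerance = 1e-9)
  # with a CIM covariate too
  cov <- p$map$marker[40]
  sc2 <- scan_trait(y, p$grid, covariate_markers = cov)
  expect_equal(sc2$lrs,
               lm_scan_oracle(y[attr(sc2, "lines")], p$grid, cov),
               tolerance = 1e-9)
})

test_that("scan honors degenerate inputs and the sign/affine conventions", {
  p <- small_panel()
  lines <- p$geno$lines
  # constant trait: LRS identically zero
  sc0 <- scan_trait(stats::setNames(rep(3, 30), lines), p$grid)
  expect_true(all(sc0$lrs == 0))
  # trait equal to dosage at a marker: perfect fit there
  mk <- p$map$marker[12]
  y <- stats::setNames(fibroqtl:::call_dose(p$geno$calls[, mk]), lines)
  sc1 <- scan_trait(y, p$grid)
  pk <- sc1[which.max(sc1$lrs), ]
  expect_equal(pk$id, mk)
  expect_equal(pk$effect, 1.0, tolerance = 1e-9)
  # D-increases planting gives positive additive effect
  ph <- simulate_phenotypes(p$geno, list(planted_qtl(mk, 0.5)), 0.7,
                            seed = 52)
  ym <- strain_values(summarize_strains(ph), "trait", "both")
  scp <- scan_trait(ym, p$grid)
  expect_gt(scp$effect[scp$id == mk], 0)
  # affine rescaling: LRS invariant, effect scales
  sca <- scan_trait(2.5 * ym + 7, p$grid)
  expect_equal(sca$lrs, scp$lrs, tolerance = 1e-9)
  expect_equal(sca$effect, 2.5 * scp$effect, tolerance = 1e-9)
  # too few lines is an error
  expect_error(scan_trait(ym[1:5], p$grid), "fewer than")
})

test_that("composite interval mapping conditions out the covariate locus", {
  p <- small_panel()
  mk1 <- p$map$marker[30]   # chr 2
  mk2 <- p$map$marker[75]   # chr 4
  ph <- simulate_phenotypes(
    p$geno, list(planted_qtl(mk1, 0.35), planted_qtl(mk2, 0.25)),
    0.7, seed = 53)
  y <- strain_values(summarize_strains(ph), "trait", "both")
  single <- scan_trait(y, p$grid)
  cim <- scan_trait(y, p$grid, covariate_markers = mk1)
  # self-conditioning drives LRS at the covariate to ~0
  expect_lt(cim$lrs[cim$id == mk1], 1e-6)
  # conditioning on locus 1 sharpens locus 2 on average (paired sims)
  gain <- vapply(1:25, function(i) {
    phi <- simulate_phenotypes(
      p$geno, list(planted_qtl(mk1, 0.35), planted_qtl(mk2, 0.25)),
      0.7, seed = 600 + i)
    yi <- strain_values(summarize_strains(phi), "trait", "both")
    s1 <- scan_trait(yi, p$grid)
    s2 <- scan_trait(yi, p$grid, covariate_markers = mk1)
    s2$lrs[s2$id == mk2] - s1$lrs[s1$id == mk2]
  }, 0)
  expect_gt(mean(gain), 0)
})

test_that("pair scans recover additive and purely epistatic architectures", {
  p <- small_panel(n_lines = 40, seed = 61,
                   map = ri_map_spec(n_chr = 2, length_cM = 30,
                                     spacing_cM = 10))
  lines <- p$geno$lines
  d1 <- fibroqtl:::call_dose(p$geno$calls[, "c1_m002"])
  d2 <- fibroqtl:::call_dose(p$geno$calls[, "c2_m003"])
  # noiseless additive trait
  ps <- pair_scan(stats::setNames(d1 + d2, lines), p$grid, top_k = 3)
  expect_setequal(unlist(ps[1, c("marker1", "marker2")]),
                  c("c1_m002", "c2_m003"))
  # XOR-like product trait: marginals flat, interaction found
  yx <- stats::setNames(d1 * d2, lines)
  flat <- scan_trait(yx, p$grid)
  expect_lt(max(flat$lrs[flat$id %in% c("c1_m002", "c2_m003")]), 3)
  px <- pair_scan(yx, p$grid, top_k = 3)
  expect_setequal(unlist(px[1, c("marker1", "marker2")]),
                  c("c1_m002", "c2_m003"))
  # constant trait: all pair LRS zero
  pc <- pair_scan(stats::setNames(rep(1, 40), lines), p$grid)
  expect_true(all(pc$lrs == 0))
  one <- small_panel(map = data.frame(marker = "only", chr = "1",
                                      cM = 0, Mb = 0))
  expect_error(pair_scan(stats::setNames(rnorm(30), one$geno$lines),
                         one$grid), "at least 2")
})

test_that("permutation thresholds are ordered, seeded and flagged", {
  p <- small_panel()
  y <- stats::setNames(rnorm(30), p$geno$lines)
  th <- permutation_thresholds(y, p$grid, n_perm = 150, seed = 71)
  expect_gte(th$significant_lrs, th$suggestive_lrs)
  expect_gt(th$suggestive_lrs, 0)
  th2 <- permutation_thresholds(y, p$grid, n_perm = 150, seed = 71)
  expect_identical(th$max_lrs, th2$max_lrs)
  expect_error(permutation_thresholds(y, p$grid, n_perm = 0, seed = 1),
               "positive")
  low <- permutation_thresholds(y, p$grid, n_perm = 50, seed = 1)
  expect_match(low$warnings, "poorly resolved")
})

test_that("1.5-LOD support intervals follow the drop geometry", {
  # triangular LOD peaking at 5.0, slope 0.5 LOD/Mb -> peak +- 3 Mb
  mb <- 0:60
  tri <- make_scan("1", mb, pmax(5 - 0.5 * abs(mb - 30), 0))
  expect_equal(support_interval(tri, "1", 30), c(27, 33))
  # flat curve: whole chromosome
  flat <- make_scan("1", mb, rep(2, length(mb)))
  expect_equal(support_interval(flat, "1", 30), c(0, 60))
  # monotone rise to the end: right-clipped
  mono <- make_scan("1", mb, mb / 10)
  expect_equal(support_interval(mono, "1", 60), c(45, 60))
  # interpolation between grid points
  coarse <- make_scan("1", c(0, 10, 20, 30, 40),
                      c(1, 2.2, 6, 2.2, 1))
  si <- support_interval(coarse, "1", 20)
  expect_equal(si[1], 10 + (4.5 - 2.2) / (6 - 2.2) * 10)
  expect_equal(si[2], 30 - (4.5 - 2.2) / (6 - 2.2) * 10)
  expect_error(support_interval(tri, "1", 30.5), "not on the scan grid")
})

test_that("pQTL detection splits runs, breaks ties low and finds planted loci", {
  # flat null scan: nothing detected
  th <- make_thresholds(significant = 15, suggestive = 9)
  flat <- make_scan("1", 0:20, rep(0.2, 21))
  expect_equal(nrow(detect_pqtls(flat, th)), 0L)
  # two humps separated by a dip below suggestive -> two loci;
  # tied peak values resolve to the smaller Mb
  lod <- c(1, 2.5, 2.5, 1, 0.2, 0.2, 1, 3.6, 2, 1)
  hump <- make_scan("1", seq(0, 90, by = 10), lod)
  th2 <- make_thresholds(significant = 15, suggestive = 2 * 2 * log(10))
  pq <- detect_pqtls(hump, th2)
  expect_equal(nrow(pq), 2L)
  expect_equal(pq$peak_Mb, c(10, 70))   # first of the tied pair
  expect_equal(pq$class, c("suggestive", "significant"))
  expect_true(all(pq$support_lo_Mb <= pq$peak_Mb &
                    pq$peak_Mb <= pq$support_hi_Mb))
  # planted QTL at 0.4 strain-mean variance: detected on the correct
  # chromosome in >= 90% of simulations
  map5 <- ri_map_spec(n_chr = 5, length_cM = 60, spacing_cM = 3)
  hits <- vapply(1:60, function(i) {
    g <- simulate_ri_genotypes(30, map5, seed = 5000 + i)
    ph <- simulate_phenotypes(g, list(planted_qtl("c3_m011", 0.4)),
                              0.6, seed = 6000 + i)
    y <- strain_values(summarize_strains(ph), "trait", "both")
    gr <- dosage_grid(g, step_cM = 3)
    sc <- scan_trait(y, gr)
    tt <- permutation_thresholds(y, gr, n_perm = 300, seed = 7000 + i)
    any(detect_pqtls(sc, tt)$chr == "3")
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("pQTL overlap groups match a brute-force graph oracle", {
  mk_set <- function(chr, lo, hi) {
    structure(data.frame(
      trait = "t", dataset = "both", chr = chr,
      peak_Mb = (lo + hi) / 2, peak_id = "x", lrs_max = 12,
      effect = 1, support_lo_Mb = lo, support_hi_Mb = hi,
      class = "suggestive", stringsAsFactors = FALSE),
      class = c("pqtl_set", "data.frame"))
  }
  # shared endpoint counts as overlap (closed-closed)
  touch <- rbind(mk_set("1", 10, 20), mk_set("1", 20, 30))
  expect_equal(length(unique(overlap_pqtls(touch)$group)), 1L)
  # same coordinates on different chromosomes never group
  cross <- rbind(mk_set("1", 10, 20), mk_set("2", 10, 20))
  expect_equal(length(unique(overlap_pqtls(cross)$group)), 2L)
  # random interval sets vs connected components of the all-pairs graph
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    lo <- runif(n, 0, 100)
    sets <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_set(sample(c("1", "2"), 1), lo[i], lo[i] + runif(1, 1, 30))))
    got <- overlap_pqtls(sets)$group
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      sets$chr[i] == sets$chr[j] &&
        sets$support_lo_Mb[i] <= sets$support_hi_Mb[j] &&
        sets$support_lo_Mb[j] <= sets$support_hi_Mb[i]
    }))
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(comp$membership,
                                   levels = unique(comp$membership))))
  }
})
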