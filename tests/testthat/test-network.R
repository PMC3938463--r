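net_ann <- function(genes, chrs) {
  data.frame(gene_id = genes, chr = chrs,
             start_Mb = seq_along(genes), end_Mb = seq_along(genes) + 0.1,
             has_nssnp = FALSE, stringsAsFactors = FALSE)
}

test_that("correlation edges apply strict thresholds, scope and strength", {
  lines <- sprintf("S%02d", 1:10)
  set.seed(121)
  base <- rnorm(10)
  expr <- cbind(gA = base, gB = base, gC = rnorm(10))
  rownames(expr) <- lines
  ann <- net_ann(c("gA", "gB", "gC"), c("1", "2", "3"))
  net <- correlation_edges(expr, ann)
  # identical genes on different chromosomes: one strong inter edge
  e <- net$edges[net$edges$gene_a == "gA" & net$edges$gene_b == "gB", ]
  expect_equal(e$r, 1, tolerance = 1e-12)
  expect_equal(e$strength, "strong")
  expect_equal(e$scope, "inter")
  # boundary: |r| exactly at the weak cutoff is not an edge
  r_ac <- abs(cor(expr[, "gA"], expr[, "gC"]))
  net2 <- correlation_edges(expr, ann, weak = r_ac)
  expect_false(any(net2$edges$gene_a == "gA" &
                     net2$edges$gene_b == "gC"))
  expect_error(correlation_edges(expr[1:2, ], ann), "at least 3")
})

test_that("edge sets equal the all-pairs brute-force oracle and are order-invariant", {
  lines <- sprintf("S%02d", 1:25)
  set.seed(122)
  k <- 12
  block <- rnorm(25)
  expr <- sapply(1:k, function(j)
    if (j <= 3) block + rnorm(25, 0, 0.4) else rnorm(25))
  dimnames(expr) <- list(lines, sprintf("g%02d", 1:k))
  ann <- net_ann(colnames(expr),
                 as.character(rep(1:4, length.out = k)))
  net <- correlation_edges(expr, ann, weak = 0.36, strong = 0.5)
  # brute force
  bf <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    r <- cor(expr[, i], expr[, j])
    if (abs(r) > 0.36) {
      bf[[length(bf) + 1L]] <- data.frame(
        gene_a = colnames(expr)[i], gene_b = colnames(expr)[j], r = r,
        stringsAsFactors = FALSE)
    }
  }
  bf <- do.call(rbind, bf)
  expect_equal(nrow(net$edges), nrow(bf))
  expect_equal(paste(net$edges$gene_a, net$edges$gene_b),
               paste(bf$gene_a, bf$gene_b))
  expect_equal(net$edges$r, bf$r, tolerance = 1e-12)
  # planted 3-gene block is fully connected
  expect_true(all(c("g01", "g02", "g03") %in%
                    c(net$edges$gene_a, net$edges$gene_b)))
  # scope bookkeeping: inter + intra = total
  expect_equal(sum(net$edges$scope == "inter") +
                 sum(net$edges$scope == "intra"), nrow(net$edges))
  # gene-order permutation leaves the graph unchanged
  perm <- sample(k)
  net_p <- correlation_edges(expr[, perm], ann, 0.36, 0.5)
  key <- function(n) {
    e <- n$edges
    sort(sprintf("%s|%s|%.10f", pmin(e$gene_a, e$gene_b),
                 pmax(e$gene_a, e$gene_b), e$r))
  }
  expect_equal(key(net_p), key(net))
  # degree against an independent igraph oracle (inter edges only)
  inter <- net$edges[net$edges$scope == "inter", ]
  g <- igraph::graph_from_data_frame(inter, directed = FALSE,
                                     vertices = net$nodes$gene_id)
  expect_equal(net$nodes$degree_inter,
               unname(igraph::degree(g)[net$nodes$gene_id]))
})

test_that("connectivity ranking is stable, descending and tie-broken by name", {
  empty <- correlation_edges(
    matrix(rnorm(30), 10, 3,
           dimnames = list(sprintf("S%d", 1:10), c("a", "b", "c"))),
    net_ann(c("a", "b", "c"), c("1", "2", "3")), weak = 0.999)
  expect_equal(nrow(connectivity_ranking(empty)), 3L)
  expect_true(all(connectivity_ranking(empty)$degree_inter == 0L))
  # star graph: hub first
  lines <- sprintf("S%02d", 1:12)
  hub <- rnorm(12)
  expr <- cbind(hub = hub, sapply(1:5, function(i)
    hub + rnorm(12, 0, 0.25)))
  colnames(expr) <- c("hub", sprintf("leaf%d", 1:5))
  rownames(expr) <- lines
  ann <- net_ann(colnames(expr), c("1", "2", "3", "4", "5", "6"))
  rk <- connectivity_ranking(correlation_edges(expr, ann))
  expect_equal(rk$gene_id[1], "hub")
  expect_true(all(diff(rk$degree_inter) <= 0))
})

test_that("heatmap scores honor the p-value floor, sign and planted peaks", {
  mb <- seq(0, 60, by = 5)
  null_scan <- make_scan("1", mb, rep(0, length(mb)),
                         effect = rep(0, length(mb)))
  dist <- c(rep(5, 50), rep(9, 49))  # 99 permuted maxima
  hm0 <- heatmap_matrix(list(t0 = null_scan), list(t0 = dist))
  expect_true(all(hm0 == 0))   # p = 1 everywhere
  # above every permuted max: |score| at the flooring bound
  lod <- c(rep(0.2, 6), 5, rep(0.2, 6))
  eff <- c(rep(0.1, 6), -2, rep(0.1, 6))
  hot <- make_scan("1", mb, lod, effect = eff)
  hm1 <- heatmap_matrix(list(t1 = hot), list(t1 = dist))
  expect_equal(unname(hm1[1, 7]), -log10(100))  # sign of the effect
  expect_equal(max(abs(hm1)), log10(length(dist) + 1))
  expect_error(heatmap_matrix(list(t1 = hot), list(other = dist)),
               "missing permutation")
  # planted QTL: extreme cell at the planted position, sign positive
  p <- small_panel()
  mk <- p$map$marker[40]
  ph <- simulate_phenotypes(p$geno, list(planted_qtl(mk, 0.6)), 0.8,
                            seed = 131)
  y <- strain_values(summarize_strains(ph), "trait", "both")
  sc <- scan_trait(y, p$grid)
  th <- permutation_thresholds(y, p$grid, n_perm = 200, seed = 132)
  hm <- heatmap_matrix(list(trait = sc), list(trait = th))
  best <- which.max(abs(hm[1, ]))
  expect_equal(attr(hm, "positions")$chr[best], p$map$chr[40])
  expect_lt(abs(attr(hm, "positions")$Mb[best] - p$map$Mb[40]), 10)
  expect_gt(hm[1, best], 0)
})

test_that("co-localization reports transcripts peaking inside pQTL intervals", {
  p <- small_panel()
  ann <- simulate_annotation(p$geno, 30, seed = 141)
  i <- 12
  mk <- nearest_marker(p$geno, ann$chr[i], ann$start_Mb[i])
  gene <- ann$gene_id[i]
  ex <- simulate_expression(p$geno, ann,
                            list(planted_eqtl(gene, mk, 3, "both")),
                            seed = 142)
  E <- normalize_expression(ex$treated)
  sc <- scan_trait(E[, gene], p$grid, trait = gene)
  th <- permutation_thresholds(E[, gene], p$grid, 200, seed = 143)
  hm <- heatmap_matrix(stats::setNames(list(sc), gene),
                       stats::setNames(list(th), gene))
  pq <- structure(data.frame(
    trait = "t", dataset = "both", chr = ann$chr[i],
    peak_Mb = ann$start_Mb[i], peak_id = mk, lrs_max = 20, effect = 1,
    support_lo_Mb = max(0, ann$start_Mb[i] - 12),
    support_hi_Mb = ann$start_Mb[i] + 12, class = "significant",
    stringsAsFactors = FALSE), class = c("pqtl_set", "data.frame"))
  co <- colocalize(hm, pq)
  expect_true(gene %in% co$scan)
  # empty pQTL list: empty report
  expect_equal(nrow(colocalize(hm, pq[0, ])), 0L)
  # a pQTL on another chromosome does not capture the transcript
  pq2 <- pq
  pq2$chr <- setdiff(unique(p$map$chr), ann$chr[i])[1]
  expect_equal(nrow(colocalize(hm, pq2)), 0L)
})

test_that("network export writes edge lists and GraphML", {
  lines <- sprintf("S%02d", 1:10)
  base <- rnorm(10)
  expr <- cbind(a = base, b = base + rnorm(10, 0, 0.2), c = rnorm(10))
  rownames(expr) <- lines
  net <- correlation_edges(expr, net_ann(c("a", "b", "c"),
                                         c("1", "2", "3")))
  f1 <- tempfile(fileext = ".tsv")
  write_network(net, f1)
  re <- utils::read.table(f1, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  expect_equal(nrow(re), nrow(net$edges))
  f2 <- tempfile(fileext = ".graphml")
  write_network(net, f2, format = "graphml")
  g <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
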