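#' Candidate-gene co-expression network from pairwise correlations
#'
#' Computes all pairwise Pearson correlations among candidate-gene
#' expression profiles and keeps edges with |r| strictly greater than
#' `weak` (default 0.36, the p < 0.05 cutoff at 30 strains). Edges are
#' classed `strong` when |r| > `strong` and `weak` otherwise, and
#' scoped `inter` or `intra` by whether the genes sit on different
#' chromosomes. Node connectivity counts inter-chromosomal edges only
#' (intra edges are stored but excluded from the degree, matching the
#' convention of drawing only inter-chromosomal correlations).
#'
#' @param expr Strain x gene expression matrix restricted to the
#'   candidate genes (>= 3 strains).
#' @param annotation Gene annotation (chromosome lookup).
#' @param weak,strong Strict |r| cutoffs for edge retention and for the
#'   strong class.
#' @return A `fib_network`: list with `nodes` (`gene_id`, `chr`,
#'   `degree_inter`, `degree_intra`) and `edges` (`gene_a`, `gene_b`,
#'   `r`, `strength`, `scope`), undirected with `gene_a` < `gene_b` and
#'   no self-edges.
#' @export
correlation_edges <- function(expr, annotation, weak = 0.36,
                              strong = 0.5) {
  stopifnot(is.matrix(expr))
  if (nrow(expr) < 3L) stop("need at least 3 strains for correlations")
  genes <- colnames(expr)
  idx <- match(genes, annotation$gene_id)
  if (anyNA(idx)) {
    stop("gene(s) absent from annotation: ",
         paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
  }
  chr <- annotation$chr[idx]
  R <- stats::cor(expr)
  k <- length(genes)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      r <- R[i, j]
      if (is.na(r) || abs(r) <= weak) next   # strict cutoff
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = genes[i], gene_b = genes[j], r = r,
        strength = if (abs(r) > strong) "strong" else "weak",
        scope = if (chr[i] == chr[j]) "intra" else "inter",
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_a = character(), gene_b = character(), r = numeric(),
    strength = character(), scope = character(),
    stringsAsFactors = FALSE)
  deg <- function(scope) {
    e <- edges[edges$scope == scope, , drop = FALSE]
    tab <- table(factor(c(e$gene_a, e$gene_b), levels = genes))
    as.integer(tab)
  }
  nodes <- data.frame(gene_id = genes, chr = chr,
                      degree_inter = deg("inter"),
                      degree_intra = deg("intra"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, weak = weak,
                 strong = strong),
            class = "fib_network")
}

#' @export
print.fib_network <- function(x, ...) {
  cat(sprintf(
    "Co-expression network: %d genes, %d edges (|r| > %.2f; %d inter-, %d intra-chromosomal)\n",
    nrow(x$nodes), nrow(x$edges), x$weak,
    sum(x$edges$scope == "inter"), sum(x$edges$scope == "intra")))
  invisible(x)
}

#' Rank network genes by inter-chromosomal connectivity
#'
#' Stable sort, descending by inter-chromosomal degree with ties broken
#' alphabetically by gene id.
#'
#' @param net A `fib_network`.
#' @return The `nodes` data.frame reordered.
#' @export
connectivity_ranking <- function(net) {
  nodes <- net$nodes
  out <- nodes[order(-nodes$degree_inter, nodes$gene_id), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network as a TSV edge list or GraphML
#'
#' @param net A `fib_network`.
#' @param path Output path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Plot the candidate-gene network as a circular graph
#'
#' Nodes are laid out on a circle ordered by chromosome; by default
#' only inter-chromosomal edges are drawn (green positive, red
#' negative, solid strong, dashed weak) and node size tracks
#' inter-chromosomal connectivity.
#'
#' @param x A `fib_network`.
#' @param inter_only Draw only inter-chromosomal edges.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.fib_network <- function(x, inter_only = TRUE, ...) {
  nodes <- x$nodes[order(chr_rank(x$nodes$chr), x$nodes$gene_id), ,
                   drop = FALSE]
  k <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = k + 1L)[-1L]
  xy <- cbind(cos(theta), sin(theta))
  rownames(xy) <- nodes$gene_id
  graphics::plot(xy, asp = 1, axes = FALSE, xlab = "", ylab = "",
                 type = "n", main = "Candidate-gene network",
                 xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3))
  edges <- x$edges
  if (inter_only) edges <- edges[edges$scope == "inter", , drop = FALSE]
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- xy[edges$gene_a[i], ]
      b <- xy[edges$gene_b[i], ]
      graphics::segments(a[1L], a[2L], b[1L], b[2L],
                         col = if (edges$r[i] > 0) "darkgreen" else
                           "firebrick",
                         lty = if (edges$strength[i] == "strong") 1
                               else 2)
    }
  }
  cex <- 0.8 + 0.15 * nodes$degree_inter
  graphics::points(xy, pch = 21, bg = "grey85", cex = cex)
  graphics::text(xy * 1.15, labels = nodes$gene_id, cex = 0.6)
  invisible(x)
}

#' Signed permutation-p heatmap matrix across genome scans
#'
#' For a set of genome scans sharing one dosage grid, converts each
#' position's LRS into a genome-wide permutation p-value — the
#' add-one-smoothed fraction of permuted genome-wide maximum LRS values
#' at or above the observed LRS, so p is floored at 1/(n_perm + 1) —
#' and encodes each cell as sign(additive effect) x (-log10 p).
#' Positive cells mean the D allele increases the trait (the red/yellow
#' palette side), negative cells the B allele (blue/green side).
#'
#' @param scans Named list of `qtl_scan` objects on a common grid
#'   (traits and/or transcripts).
#' @param perm_dists Named list (same names) of `qtl_thresholds`
#'   objects or raw numeric max-LRS null distributions.
#' @return A `qtl_heatmap`: rows = scans, columns = genome positions,
#'   with the position table as attribute `positions`.
#' @export
heatmap_matrix <- function(scans, perm_dists) {
  stopifnot(length(scans) >= 1)
  nms <- names(scans)
  if (is.null(nms) || any(!nzchar(nms))) stop("scans must be named")
  missing_d <- setdiff(nms, names(perm_dists))
  if (length(missing_d)) {
    stop("missing permutation distribution for scan(s): ",
         paste(missing_d, collapse = ", "))
  }
  pos <- as.data.frame(scans[[1L]])[, c("id", "chr", "cM", "Mb")]
  M <- matrix(NA_real_, length(scans), nrow(pos),
              dimnames = list(nms, pos$id))
  for (nm in nms) {
    sc <- scans[[nm]]
    if (nrow(sc) != nrow(pos) || any(sc$id != pos$id)) {
      stop("scan ", nm, " is not on the common grid")
    }
    dist <- perm_dists[[nm]]
    if (inherits(dist, "qtl_thresholds")) dist <- dist$max_lrs
    np <- length(dist)
    cnt <- vapply(sc$lrs, function(l)
      if (is.na(l)) NA_real_ else sum(dist >= l), 0)
    p <- (cnt + 1) / (np + 1)
    score <- sign(ifelse(is.na(sc$effect), 0, sc$effect)) * (-log10(p))
    score[is.na(sc$lrs)] <- 0
    M[nm, ] <- score
  }
  structure(M, class = "qtl_heatmap", positions = pos)
}

#' @export
print.qtl_heatmap <- function(x, ...) {
  cat("Signed QTL heatmap:", nrow(x), "scan(s) x", ncol(x),
      "genome positions; |score| max =",
      round(max(abs(x), na.rm = TRUE), 2), "\n")
  invisible(x)
}

#' Plot a signed QTL heatmap
#'
#' @param x A `qtl_heatmap`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.qtl_heatmap <- function(x, ...) {
  pos <- attr(x, "positions")
  pal <- grDevices::colorRampPalette(c("navy", "steelblue", "black",
                                       "red", "yellow"))(61)
  lim <- max(abs(x), na.rm = TRUE)
  graphics::image(seq_len(ncol(x)), seq_len(nrow(x)), t(unclass(x)),
                  col = pal, zlim = c(-lim, lim), xlab = "genome position",
                  ylab = "", yaxt = "n", main = "Signed QTL heatmap", ...)
  graphics::axis(2, at = seq_len(nrow(x)), labels = rownames(x),
                 las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Co-localization of heatmap rows with pQTL support intervals
#'
#' For each pQTL, reports the scans (transcripts or traits) whose
#' strongest heatmap column — any position achieving the row's maximum
#' |score|; the p-value floor can tie a whole linked region — falls
#' inside the pQTL's closed support interval on the same chromosome.
#'
#' @param heatmap A `qtl_heatmap`.
#' @param pqtls A `pqtl_set`.
#' @return Data.frame `scan`, `pqtl_trait`, `pqtl_chr`, `peak_Mb`
#'   (of the scan's strongest column), `score`.
#' @export
colocalize <- function(heatmap, pqtls) {
  pos <- attr(heatmap, "positions")
  rows <- list()
  if (nrow(pqtls) == 0L || nrow(heatmap) == 0L) {
    return(data.frame(scan = character(), pqtl_trait = character(),
                      pqtl_chr = character(), peak_Mb = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  A <- abs(unclass(heatmap))
  for (i in seq_len(nrow(heatmap))) {
    # every column achieving the row maximum counts as the strongest
    # position: p-value flooring can tie a whole linked region
    best <- which(A[i, ] >= max(A[i, ]) - 1e-12)
    for (q in seq_len(nrow(pqtls))) {
      hit <- best[pos$chr[best] == pqtls$chr[q] &
                    pos$Mb[best] >= pqtls$support_lo_Mb[q] &
                    pos$Mb[best] <= pqtls$support_hi_Mb[q]]
      if (length(hit)) {
        b <- hit[1L]
        rows[[length(rows) + 1L]] <- data.frame(
          scan = rownames(heatmap)[i], pqtl_trait = pqtls$trait[q],
          pqtl_chr = pqtls$chr[q], peak_Mb = pos$Mb[b],
          score = unclass(heatmap)[i, b], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    scan = character(), pqtl_trait = character(),
    pqtl_chr = character(), peak_Mb = numeric(), score = numeric(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
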