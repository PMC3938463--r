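#' Per-array Z-score normalization to the mean-8 / SD-2 scale
#'
#' Each strain's (array's) expression vector is converted to Z-scores
#' using the population (divide-by-n) standard deviation, multiplied by
#' 2 and shifted by 8, so every array ends with mean exactly 8 and SD
#' exactly 2 and all values are positive in practice. One unit on this
#' scale corresponds to roughly a two-fold expression difference. The
#' transformation is idempotent on already-normalized arrays and
#' preserves the transcript order.
#'
#' @param raw Strain x transcript matrix of log2-scale values.
#' @return Matrix of the same shape on the normalized scale.
#' @export
normalize_expression <- function(raw) {
  stopifnot(is.matrix(raw), nrow(raw) >= 1, ncol(raw) >= 2)
  mu <- rowMeans(raw)
  sdp <- sqrt(rowMeans((raw - mu)^2))
  zero <- sdp <= 0
  if (any(zero)) {
    who <- rownames(raw)[zero] %||% as.character(which(zero))
    stop("zero-variance strain(s), cannot normalize: ",
         paste(who, collapse = ", "))
  }
  out <- 2 * (raw - mu) / sdp + 8
  dimnames(out) <- dimnames(raw)
  out
}

#' Map eQTLs for every transcript of an expression matrix
#'
#' Runs the Haley-Knott scan of [scan_trait()] for each transcript
#' (strain-mean expression as the quantitative trait), records the peak
#' position, LRS and additive effect, and keeps transcripts whose peak
#' LRS reaches `suggestive_cutoff` (default 12.0, the upper suggestive
#' threshold used for expression traits). Peak ties are broken toward
#' the smaller genome coordinate.
#'
#' @param expr Strain x transcript matrix (normalized or raw log2).
#' @param grid A [dosage_grid()].
#' @param suggestive_cutoff Minimum peak LRS to retain a transcript.
#' @param min_lines Minimum usable lines per position.
#' @return An `eqtl_set`: data.frame with `transcript_id`, `peak_id`,
#'   `chr`, `peak_Mb`, `lrs_max`, `effect`, `n`; attribute `cutoff`.
#' @export
scan_transcripts <- function(expr, grid, suggestive_cutoff = 12,
                             min_lines = 8) {
  stopifnot(is.matrix(expr), inherits(grid, "dosage_grid"))
  strains <- intersect(rownames(expr), rownames(grid$dosage))
  if (!length(strains)) {
    stop("expression matrix and dosage grid share no strains")
  }
  if (length(strains) < min_lines) {
    stop("fewer than ", min_lines, " strains shared with the grid")
  }
  E <- expr[strains, , drop = FALSE]
  D <- grid$dosage[strains, , drop = FALSE]
  nn <- length(strains)
  has_na <- colSums(is.na(D)) > 0L
  ntx <- ncol(E)
  p <- ncol(D)
  lrs <- matrix(0, ntx, p)
  eff <- matrix(NA_real_, ntx, p)
  Ec <- sweep(E, 2L, colMeans(E))
  sse <- colSums(Ec^2)
  if (any(!has_na)) {
    idx <- which(!has_na)
    dc <- sweep(D[, idx, drop = FALSE], 2L, colMeans(D[, idx,
                                                       drop = FALSE]))
    ssd <- colSums(dc^2)
    cross <- crossprod(Ec, dc)                       # ntx x p'
    keep <- ssd > 1e-12
    r2 <- matrix(0, ntx, length(idx))
    r2[, keep] <- cross[, keep, drop = FALSE]^2 /
      outer(pmax(sse, 1e-300), ssd[keep])
    r2 <- pmin(r2, 1 - 1e-12)
    r2[sse <= 1e-12, ] <- 0
    lrs[, idx] <- -nn * log1p(-r2)
    eff[, idx] <- sweep(cross, 2L, ifelse(keep, ssd, NA_real_), "/")
  }
  for (j in which(has_na)) {
    use <- !is.na(D[, j])
    if (sum(use) < min_lines) { lrs[, j] <- NA_real_; next }
    res <- marginal_lrs_matrix(E[use, , drop = FALSE], D[use, j])
    lrs[, j] <- res$lrs
    eff[, j] <- res$effect
  }
  pk <- max.col(replace(lrs, is.na(lrs), -Inf), ties.method = "first")
  sel <- cbind(seq_len(ntx), pk)
  out <- data.frame(transcript_id = colnames(E),
                    peak_id = grid$positions$id[pk],
                    chr = grid$positions$chr[pk],
                    peak_Mb = grid$positions$Mb[pk],
                    lrs_max = lrs[sel], effect = eff[sel], n = nn,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$lrs_max) & out$lrs_max >= suggestive_cutoff, ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("eqtl_set", "data.frame"),
            cutoff = suggestive_cutoff)
}

# LRS/effect of each column of E against a single dosage vector d
marginal_lrs_matrix <- function(E, d) {
  nn <- length(d)
  dc <- d - mean(d)
  ssd <- sum(dc^2)
  Ec <- sweep(E, 2L, colMeans(E))
  sse <- colSums(Ec^2)
  if (ssd <= 1e-12) {
    return(list(lrs = rep(0, ncol(E)), effect = rep(NA_real_, ncol(E))))
  }
  cross <- as.numeric(crossprod(Ec, dc))
  r2 <- pmin(cross^2 / (ssd * pmax(sse, 1e-300)), 1 - 1e-12)
  r2[sse <= 1e-12] <- 0
  list(lrs = -nn * log1p(-r2), effect = cross / ssd)
}

#' @export
print.eqtl_set <- function(x, ...) {
  cat("eQTL results:", nrow(x), "transcript(s) with peak LRS >=",
      attr(x, "cutoff"), "\n")
  if ("regulation" %in% names(x)) {
    cat("  cis:", sum(x$regulation == "cis"),
        " trans:", sum(x$regulation == "trans"), "\n")
  }
  invisible(x)
}

#' Classify eQTLs as cis or trans by the 10-Mb rule
#'
#' An eQTL is cis-acting when its peak marker lies on the same
#' chromosome as the regulated gene and within `cis_window_Mb` of the
#' gene start (inclusive boundary: exactly 10 Mb counts as cis); any
#' other configuration, including a peak on a different chromosome, is
#' trans.
#'
#' @param eqtls An `eqtl_set` from [scan_transcripts()].
#' @param annotation Gene annotation data.frame (transcript ids match
#'   `gene_id`).
#' @param cis_window_Mb Cis distance window in Mb.
#' @return The `eqtl_set` with `regulation` (`"cis"`/`"trans"`) and
#'   `distance_Mb` (NA for different-chromosome peaks) columns added.
#' @export
classify_cis_trans <- function(eqtls, annotation, cis_window_Mb = 10) {
  idx <- match(eqtls$transcript_id, annotation$gene_id)
  if (anyNA(idx)) {
    stop("transcript(s) missing from annotation: ",
         paste(utils::head(eqtls$transcript_id[is.na(idx)], 5),
               collapse = ", "))
  }
  same <- eqtls$chr == annotation$chr[idx]
  dist <- ifelse(same, abs(eqtls$peak_Mb - annotation$start_Mb[idx]),
                 NA_real_)
  out <- eqtls
  out$gene_chr <- annotation$chr[idx]
  out$gene_start_Mb <- annotation$start_Mb[idx]
  out$distance_Mb <- dist
  out$regulation <- ifelse(same & dist <= cis_window_Mb, "cis", "trans")
  attr(out, "cis_window_Mb") <- cis_window_Mb
  out
}

#' Dissect a pQTL region into gene / eQTL / cisQTL / cisQTG counts
#'
#' Counts, for one pQTL support interval: the annotated genes whose
#' start lies inside the closed interval; the distinct regulatory
#' markers (eQTL peak positions) inside the interval; the subset of
#' those markers whose linked transcript is cis-regulated (cisQTLs);
#' and the cis-regulated transcripts with peak LRS at or above
#' `cutoff_lrs` whose gene lies inside the interval (cisQTGs) — the
#' region-summary funnel.
#'
#' @param pqtl One row of a `pqtl_set`.
#' @param eqtls A classified `eqtl_set` (see [classify_cis_trans()]).
#' @param annotation Gene annotation data.frame.
#' @param cutoff_lrs Minimum LRS for a cisQTG.
#' @return A `region_summary` list: `chr`, `region_lo_Mb`,
#'   `region_hi_Mb`, `n_genes`, `eqtl_markers`, `n_eqtls`,
#'   `n_cisqtls`, `cisqtgs`, `n_cisqtgs`, plus the pQTL labels.
#' @export
dissect_pqtl <- function(pqtl, eqtls, annotation, cutoff_lrs = 12) {
  stopifnot(nrow(pqtl) == 1L)
  if (!"regulation" %in% names(eqtls)) {
    stop("eqtls must be classified with classify_cis_trans() first")
  }
  lo <- pqtl$support_lo_Mb
  hi <- pqtl$support_hi_Mb
  ch <- pqtl$chr
  genes_in <- annotation$chr == ch & annotation$start_Mb >= lo &
    annotation$start_Mb <= hi
  in_region <- eqtls$chr == ch & eqtls$peak_Mb >= lo &
    eqtls$peak_Mb <= hi
  markers <- unique(eqtls$peak_id[in_region])
  cis_markers <- unique(eqtls$peak_id[in_region &
                                        eqtls$regulation == "cis"])
  gene_in_region <- annotation$gene_id[genes_in]
  cisqtgs <- unique(eqtls$transcript_id[
    eqtls$regulation == "cis" & eqtls$lrs_max >= cutoff_lrs &
      eqtls$transcript_id %in% gene_in_region])
  structure(list(trait = pqtl$trait, dataset = pqtl$dataset, chr = ch,
                 region_lo_Mb = lo, region_hi_Mb = hi,
                 lrs_max = pqtl$lrs_max,
                 size_Mb = hi - lo, n_genes = sum(genes_in),
                 eqtl_markers = markers, n_eqtls = length(markers),
                 n_cisqtls = length(cis_markers), cisqtgs = cisqtgs,
                 n_cisqtgs = length(cisqtgs)),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf(
    "pQTL region chr %s %.1f-%.1f Mb (%.1f Mb): %d genes, %d eQTL markers, %d cisQTLs, %d cisQTGs\n",
    x$chr, x$region_lo_Mb, x$region_hi_Mb, x$size_Mb, x$n_genes,
    x$n_eqtls, x$n_cisqtls, x$n_cisqtgs))
  invisible(x)
}

#' Summarize several pQTL regions as a table
#'
#' Applies [dissect_pqtl()] to each row of a `pqtl_set` and binds the
#' counts into a region-summary table mirroring the published layout.
#'
#' @inheritParams dissect_pqtl
#' @param pqtls A `pqtl_set`.
#' @return Data.frame with one row per pQTL and the funnel counts, with
#'   the full `region_summary` objects as attribute `"regions"`.
#' @export
dissect_regions <- function(pqtls, eqtls, annotation, cutoff_lrs = 12) {
  regs <- lapply(seq_len(nrow(pqtls)), function(i)
    dissect_pqtl(pqtls[i, , drop = FALSE], eqtls, annotation,
                 cutoff_lrs))
  out <- do.call(rbind, lapply(regs, function(r) data.frame(
    trait = r$trait, dataset = r$dataset, chr = r$chr,
    region_lo_Mb = r$region_lo_Mb, region_hi_Mb = r$region_hi_Mb,
    lrs_max = r$lrs_max, size_Mb = r$size_Mb, n_genes = r$n_genes,
    n_eqtls = r$n_eqtls, n_cisqtls = r$n_cisqtls,
    n_cisqtgs = r$n_cisqtgs, stringsAsFactors = FALSE)))
  attr(out, "regions") <- regs
  out
}

#' Strain-distribution-pattern concordance of a transcript and a marker
#'
#' Dichotomizes the transcript at the midpoint of the two allele-group
#' means at the marker and returns the fraction of strains whose side
#' matches their allele. A transcript under clean monogenic cis control
#' scores 1.0 (perfect match); a transcript independent of the marker
#' scores about 0.5. The value is invariant to swapping the allele
#' labels.
#'
#' @param values Named expression values (one per strain).
#' @param genos A `geno` object.
#' @param marker Marker id.
#' @return Match fraction in \[0, 1\].
#' @export
sdp_concordance <- function(values, genos, marker) {
  if (!marker %in% genos$map$marker) stop("unknown marker: ", marker)
  strains <- intersect(names(values), genos$lines)
  calls <- genos$calls[strains, marker]
  use <- calls %in% c("B", "D")
  v <- values[strains][use]
  a <- calls[use]
  if (!length(v) || length(unique(a)) < 2L) {
    stop("need strains of both alleles at ", marker)
  }
  mB <- mean(v[a == "B"])
  mD <- mean(v[a == "D"])
  mid <- (mB + mD) / 2
  predicted <- ifelse(v >= mid, if (mD >= mB) "D" else "B",
                      if (mD >= mB) "B" else "D")
  mean(predicted == a)
}
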