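#' 1.5-LOD support interval around a scan peak
#'
#' The widest contiguous region around the peak within which LOD stays
#' at or above LOD_peak - `drop`, with linear interpolation of the
#' crossing point between grid positions and clipping at the
#' chromosome ends.
#'
#' @param scan A `qtl_scan`.
#' @param chr Chromosome of the peak.
#' @param peak_mb Peak position in Mb; must be a grid position of the
#'   scan (reference error otherwise).
#' @param drop LOD drop defining the interval (default 1.5).
#' @return Numeric `c(lo_Mb, hi_Mb)`.
#' @export
support_interval <- function(scan, chr, peak_mb, drop = 1.5) {
  d <- as.data.frame(scan)[scan$chr == chr & !is.na(scan$lod), ,
                           drop = FALSE]
  if (!nrow(d)) stop("no usable positions on chromosome ", chr)
  d <- d[order(d$Mb), , drop = FALSE]
  i0 <- which(abs(d$Mb - peak_mb) < 1e-9)
  if (!length(i0)) stop("peak position ", peak_mb,
                        " is not on the scan grid of chromosome ", chr)
  i0 <- i0[1L]
  thr <- d$lod[i0] - drop
  lo <- d$Mb[1L]
  if (i0 > 1L) {
    for (i in seq(i0, 2L)) {
      if (d$lod[i - 1L] < thr) {
        lo <- d$Mb[i] + (thr - d$lod[i]) / (d$lod[i - 1L] - d$lod[i]) *
          (d$Mb[i - 1L] - d$Mb[i])
        break
      }
    }
  }
  hi <- d$Mb[nrow(d)]
  if (i0 < nrow(d)) {
    for (i in seq(i0, nrow(d) - 1L)) {
      if (d$lod[i + 1L] < thr) {
        hi <- d$Mb[i] + (thr - d$lod[i]) / (d$lod[i + 1L] - d$lod[i]) *
          (d$Mb[i + 1L] - d$Mb[i])
        break
      }
    }
  }
  c(lo, hi)
}

#' Detect pQTLs in a genome scan
#'
#' Per chromosome, contiguous runs of positions with LRS at or above
#' the suggestive threshold become candidate loci; each run contributes
#' one pQTL at its maximum (ties broken toward the smaller Mb
#' coordinate), classed `significant` if the peak reaches the
#' significant threshold and `suggestive` otherwise. Each pQTL carries
#' its 1.5-LOD support interval and the additive effect at the peak.
#'
#' @param scan A `qtl_scan`.
#' @param thresholds A `qtl_thresholds` object.
#' @return A `pqtl_set`: data.frame with columns `trait`, `dataset`,
#'   `chr`, `peak_Mb`, `peak_id`, `lrs_max`, `effect`, `support_lo_Mb`,
#'   `support_hi_Mb`, `class` (zero rows if nothing reaches the
#'   suggestive threshold).
#' @export
detect_pqtls <- function(scan, thresholds) {
  stopifnot(inherits(scan, "qtl_scan"), inherits(thresholds,
                                                 "qtl_thresholds"))
  rows <- list()
  for (ch in unique(scan$chr)) {
    d <- as.data.frame(scan)[scan$chr == ch, , drop = FALSE]
    d <- d[order(d$Mb), , drop = FALSE]
    above <- !is.na(d$lrs) & d$lrs >= thresholds$suggestive_lrs
    if (!any(above)) next
    run <- rle(above)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (k in which(run$values)) {
      seg <- d[starts[k]:ends[k], , drop = FALSE]
      pk <- seg[which.max(seg$lrs), , drop = FALSE]
      si <- support_interval(scan, ch, pk$Mb)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = attr(scan, "trait"), dataset = attr(scan, "dataset"),
        chr = ch, peak_Mb = pk$Mb, peak_id = pk$id, lrs_max = pk$lrs,
        effect = pk$effect, support_lo_Mb = si[1L],
        support_hi_Mb = si[2L],
        class = if (pk$lrs >= thresholds$significant_lrs) "significant"
                else "suggestive",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    trait = character(), dataset = character(), chr = character(),
    peak_Mb = numeric(), peak_id = character(), lrs_max = numeric(),
    effect = numeric(), support_lo_Mb = numeric(),
    support_hi_Mb = numeric(), class = character(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("pqtl_set", "data.frame"))
}

#' @export
print.pqtl_set <- function(x, ...) {
  cat("Detected pQTLs:", nrow(x), "locus/loci\n")
  need <- c("trait", "dataset", "chr", "peak_Mb", "lrs_max",
            "support_lo_Mb", "support_hi_Mb", "effect", "class")
  if (!all(need %in% names(x))) {
    print.data.frame(x)
    return(invisible(x))
  }
  if (nrow(x)) {
    print.data.frame(
      data.frame(trait = x$trait, dataset = x$dataset, chr = x$chr,
                 peak_Mb = round(x$peak_Mb, 1),
                 LRS = round(x$lrs_max, 1),
                 interval = sprintf("%.1f-%.1f", x$support_lo_Mb,
                                    x$support_hi_Mb),
                 effect = round(x$effect, 3), class = x$class),
      row.names = FALSE)
  }
  invisible(x)
}

#' Group pQTLs whose support intervals overlap
#'
#' pQTLs (across traits and datasets) on the same chromosome whose
#' closed 1.5-LOD support intervals intersect — including at a shared
#' endpoint — are merged into overlap groups, the reconstruction of how
#' multi-phenotype loci are counted.
#'
#' @param pqtls A `pqtl_set` (typically several rbind-ed sets).
#' @return The input with an integer `group` column added; groups are
#'   numbered in genome order.
#' @export
overlap_pqtls <- function(pqtls) {
  n <- nrow(pqtls)
  group <- integer(n)
  g <- 0L
  for (ch in unique(pqtls$chr)) {
    idx <- which(pqtls$chr == ch)
    idx <- idx[order(pqtls$support_lo_Mb[idx])]
    cur_hi <- -Inf
    for (i in idx) {
      if (pqtls$support_lo_Mb[i] > cur_hi) {
        g <- g + 1L
        cur_hi <- pqtls$support_hi_Mb[i]
      } else {
        cur_hi <- max(cur_hi, pqtls$support_hi_Mb[i])
      }
      group[i] <- g
    }
  }
  out <- pqtls
  out$group <- group
  out
}
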