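#' Expected allele-dosage grid for Haley-Knott interval mapping
#'
#' Builds the position grid the genome scans run on: every genotyped
#' marker plus pseudomarkers inserted every `step_cM` between flanking
#' markers. At markers the dosage is the observed allele dose (B = -1,
#' D = +1; heterozygous or unknown calls become NA). At pseudomarkers it
#' is the conditional expectation of the dose given the flanking
#' genotypes under the RI Markov chain: cM distances are converted to
#' meiotic recombination fractions with the Haldane map function and
#' expanded to RI-line transition probabilities R = 4r/(1+6r). With one
#' informative flank the single-flank expectation g (1 - 2R) is used.
#'
#' @param genos A `geno` object.
#' @param step_cM Pseudomarker spacing in cM (> 0).
#' @return A `dosage_grid` object: list with `positions` (data.frame
#'   `id`, `chr`, `cM`, `Mb`, `is_pseudo`) and `dosage` (lines x
#'   positions matrix in \[-1, 1\]).
#' @export
dosage_grid <- function(genos, step_cM = 1) {
  stopifnot(inherits(genos, "geno"))
  if (step_cM <= 0) stop("step_cM must be > 0")
  dose_mk <- call_dose(genos$calls)
  pos_list <- list()
  col_list <- list()
  for (ch in unique(genos$map$chr)) {
    idx <- which(genos$map$chr == ch)
    sub <- genos$map[idx, , drop = FALSE]
    for (k in seq_along(idx)) {
      pos_list[[length(pos_list) + 1L]] <- data.frame(
        id = sub$marker[k], chr = ch, cM = sub$cM[k], Mb = sub$Mb[k],
        is_pseudo = FALSE, stringsAsFactors = FALSE)
      col_list[[length(col_list) + 1L]] <- dose_mk[, idx[k]]
      if (k == length(idx)) next
      gap <- sub$cM[k + 1L] - sub$cM[k]
      if (gap <= step_cM + 1e-9) next
      steps <- seq(sub$cM[k] + step_cM, sub$cM[k + 1L] - 1e-9,
                   by = step_cM)
      for (cm in steps) {
        d1 <- cm - sub$cM[k]
        d2 <- sub$cM[k + 1L] - cm
        frac <- d1 / gap
        mb <- sub$Mb[k] + frac * (sub$Mb[k + 1L] - sub$Mb[k])
        ed <- pseudo_dose(dose_mk[, idx[k]], dose_mk[, idx[k + 1L]],
                          ri_transition(d1), ri_transition(d2))
        pos_list[[length(pos_list) + 1L]] <- data.frame(
          id = sprintf("c%s.loc%.3f", ch, cm), chr = ch, cM = cm,
          Mb = mb, is_pseudo = TRUE, stringsAsFactors = FALSE)
        col_list[[length(col_list) + 1L]] <- ed
      }
    }
  }
  positions <- do.call(rbind, pos_list)
  ord <- order(chr_rank(positions$chr), positions$Mb)
  positions <- positions[ord, , drop = FALSE]
  rownames(positions) <- NULL
  dosage <- do.call(cbind, col_list)[, ord, drop = FALSE]
  dimnames(dosage) <- list(genos$lines, positions$id)
  structure(list(positions = positions, dosage = dosage),
            class = "dosage_grid")
}

# E[dose at pseudomarker | flanks], two-interval RI Markov chain.
# gl, gr in {-1, +1, NA}; R1, R2 transition probabilities.
pseudo_dose <- function(gl, gr, R1, R2) {
  p_same_eq <- (1 - R1) * (1 - R2) /
    ((1 - R1) * (1 - R2) + R1 * R2)        # flanks equal
  p_same_ne <- (1 - R1) * R2 /
    ((1 - R1) * R2 + R1 * (1 - R2))        # flanks differ
  out <- rep(NA_real_, length(gl))
  both <- !is.na(gl) & !is.na(gr)
  eq <- both & gl == gr
  ne <- both & gl != gr
  out[eq] <- gl[eq] * (2 * p_same_eq - 1)
  out[ne] <- gl[ne] * (2 * p_same_ne - 1)
  only_l <- !is.na(gl) & is.na(gr)
  only_r <- is.na(gl) & !is.na(gr)
  out[only_l] <- gl[only_l] * (1 - 2 * R1)
  out[only_r] <- gr[only_r] * (1 - 2 * R2)
  out
}

#' @export
print.dosage_grid <- function(x, ...) {
  cat("Dosage grid:", nrow(x$dosage), "lines x", nrow(x$positions),
      "positions (", sum(x$positions$is_pseudo), "pseudomarkers )\n")
  invisible(x)
}

#' Genome-wide single-QTL scan by Haley-Knott regression
#'
#' The package's core fitting function. At every grid position the
#' strain trait values are regressed on expected allele dosage (plus
#' any composite-interval-mapping covariate dosages), and the
#' likelihood-ratio statistic LRS = n ln(RSS_reduced / RSS_full) is
#' recorded together with LOD = LRS / (2 ln 10) and the additive effect
#' (the dosage slope; positive means the D allele increases the trait).
#' The reduced model contains intercept and covariates only. Lines with
#' missing dosage at a position are dropped position-wise; positions
#' with fewer than `min_lines` usable lines are flagged (LRS set NA),
#' never silently skipped.
#'
#' @param values Named numeric vector of per-line trait values (strain
#'   means or medians), names matching the grid's line ids.
#' @param grid A [dosage_grid()].
#' @param covariate_markers Optional character vector of grid position
#'   ids whose dosages enter both models as covariates (composite
#'   interval mapping).
#' @param trait,dataset Labels stored on the result.
#' @param min_lines Minimum usable lines per position (default 8).
#' @return A `qtl_scan` object: data.frame with one row per position
#'   (`id`, `chr`, `cM`, `Mb`, `is_pseudo`, `n`, `lrs`, `lod`,
#'   `effect`, `usable`) and attributes `trait`, `dataset`,
#'   `covariates`, `lines`.
#' @seealso [permutation_thresholds()], [detect_pqtls()],
#'   [support_interval()]
#' @export
scan_trait <- function(values, grid, covariate_markers = NULL,
                       trait = "trait", dataset = "both",
                       min_lines = 8) {
  stopifnot(inherits(grid, "dosage_grid"))
  if (is.null(names(values))) stop("trait values must be named by line")
  lines <- intersect(rownames(grid$dosage), names(values))
  lines <- lines[!is.na(values[lines])]
  if (length(lines) < min_lines) {
    stop("fewer than ", min_lines, " lines with both trait and genotypes")
  }
  y <- as.numeric(values[lines])
  D <- grid$dosage[lines, , drop = FALSE]
  if (is.null(covariate_markers) || !length(covariate_markers)) {
    res <- marginal_lrs(y, D, min_lines)
  } else {
    missing_cov <- setdiff(covariate_markers, colnames(D))
    if (length(missing_cov)) {
      stop("covariate marker(s) not on grid: ",
           paste(missing_cov, collapse = ", "))
    }
    C <- D[, covariate_markers, drop = FALSE]
    res <- covariate_lrs(y, D, C, min_lines)
  }
  out <- cbind(grid$positions,
               data.frame(n = res$n, lrs = res$lrs,
                          lod = res$lrs / (2 * log(10)),
                          effect = res$effect,
                          usable = res$n >= min_lines))
  structure(out, class = c("qtl_scan", "data.frame"),
            trait = trait, dataset = dataset,
            covariates = covariate_markers %||% character(),
            lines = lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-dosage regressions against y, complete cases per position.
# Returns lrs, effect (slope), n per column of D.
marginal_lrs <- function(y, D, min_lines) {
  p <- ncol(D)
  lrs <- effect <- rep(NA_real_, p)
  n <- integer(p)
  has_na <- colSums(is.na(D)) > 0L
  if (any(!has_na)) {
    idx <- which(!has_na)
    sub <- D[, idx, drop = FALSE]
    nn <- length(y)
    yc <- y - mean(y)
    ssy <- sum(yc^2)
    dc <- sweep(sub, 2L, colMeans(sub))
    ssd <- colSums(dc^2)
    cross <- as.numeric(crossprod(yc, dc))
    ok <- ssd > 1e-12 & ssy > 1e-12
    r2 <- numeric(length(idx))
    r2[ok] <- pmin(cross[ok]^2 / (ssd[ok] * ssy), 1 - 1e-12)
    lrs[idx] <- -nn * log1p(-r2)
    effect[idx] <- ifelse(ssd > 1e-12, cross / ssd, NA_real_)
    n[idx] <- nn
  }
  for (j in which(has_na)) {
    use <- !is.na(D[, j])
    n[j] <- sum(use)
    if (n[j] < min_lines) next
    yy <- y[use]
    dd <- D[use, j]
    yc <- yy - mean(yy)
    dc <- dd - mean(dd)
    ssy <- sum(yc^2)
    ssd <- sum(dc^2)
    if (ssd <= 1e-12 || ssy <= 1e-12) {
      lrs[j] <- 0
      effect[j] <- if (ssd > 1e-12) 0 else NA_real_
      next
    }
    cross <- sum(yc * dc)
    r2 <- min(cross^2 / (ssd * ssy), 1 - 1e-12)
    lrs[j] <- -n[j] * log1p(-r2)
    effect[j] <- cross / ssd
  }
  lrs[n < min_lines] <- NA_real_
  list(lrs = lrs, effect = effect, n = n)
}

# Position-wise least squares with covariates in both models.
covariate_lrs <- function(y, D, C, min_lines) {
  p <- ncol(D)
  lrs <- effect <- rep(NA_real_, p)
  n <- integer(p)
  for (j in seq_len(p)) {
    use <- !is.na(D[, j]) & rowSums(is.na(C)) == 0L
    n[j] <- sum(use)
    if (n[j] < min_lines) next
    yy <- y[use]
    Xr <- cbind(1, C[use, , drop = FALSE])
    Xf <- cbind(Xr, dose = D[use, j])
    fr <- stats::lm.fit(Xr, yy)
    ff <- stats::lm.fit(Xf, yy)
    rss_r <- sum(fr$residuals^2)
    rss_f <- sum(ff$residuals^2)
    if (rss_r <= 1e-12) {
      lrs[j] <- 0
      effect[j] <- 0
      next
    }
    lrs[j] <- max(n[j] * log(rss_r / max(rss_f, 1e-300)), 0)
    if (rss_f <= 1e-12 && rss_r <= 1e-12) lrs[j] <- 0
    cf <- ff$coefficients["dose"]
    effect[j] <- if (is.na(cf)) NA_real_ else unname(cf)
    if (is.na(cf)) lrs[j] <- 0  # dosage collinear with covariates
  }
  list(lrs = lrs, effect = effect, n = n)
}

#' Permutation-based genome-wide LRS thresholds
#'
#' Shuffles the strain labels of the trait vector `n_perm` times
#' (genotypes fixed), records the genome-wide maximum LRS of each
#' permuted scan, and reads off the significant threshold as the 95th
#' percentile (genome-wide p = 0.05) and the suggestive threshold as
#' the 37th percentile (genome-wide p = 0.63, the one-false-positive-
#' per-scan convention) of that null distribution.
#'
#' @param values Named per-line trait values.
#' @param grid A [dosage_grid()].
#' @param n_perm Number of permutations (2000 reproduces the usual
#'   genome-scan setting; < 100 triggers a provenance warning).
#' @param seed Integer seed for the permutations.
#' @param min_lines Minimum usable lines per position.
#' @return A `qtl_thresholds` object: list with `significant_lrs`,
#'   `suggestive_lrs`, `n_perm`, `seed`, `max_lrs` (the permutation
#'   null distribution) and `warnings`.
#' @export
permutation_thresholds <- function(values, grid, n_perm = 2000, seed,
                                   min_lines = 8) {
  if (n_perm <= 0) stop("n_perm must be positive")
  warn <- character()
  if (n_perm < 100) {
    warn <- "n_perm < 100: thresholds are poorly resolved"
  }
  lines <- intersect(rownames(grid$dosage), names(values))
  lines <- lines[!is.na(values[lines])]
  if (length(lines) < min_lines) stop("too few lines for permutations")
  y <- as.numeric(values[lines])
  D <- grid$dosage[lines, , drop = FALSE]
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  maxes <- perm_max_lrs(Y, D, min_lines)
  qs <- stats::quantile(maxes, c(0.95, 0.37), names = FALSE, type = 7)
  structure(list(significant_lrs = qs[1L], suggestive_lrs = qs[2L],
                 n_perm = n_perm, seed = seed, max_lrs = maxes,
                 warnings = warn),
            class = "qtl_thresholds")
}

# Genome-wide max LRS for each column of trait matrix Y (lines x q)
# against dosage matrix D (lines x p).
perm_max_lrs <- function(Y, D, min_lines = 8) {
  nn <- nrow(Y)
  q <- ncol(Y)
  has_na <- colSums(is.na(D)) > 0L
  maxes <- rep(0, q)
  Yc <- sweep(Y, 2L, colMeans(Y))
  ssy <- colSums(Yc^2)
  if (any(!has_na)) {
    sub <- D[, !has_na, drop = FALSE]
    dc <- sweep(sub, 2L, colMeans(sub))
    ssd <- colSums(dc^2)
    cross <- crossprod(dc, Yc)               # p x q
    keep <- ssd > 1e-12
    if (any(keep)) {
      r2 <- cross[keep, , drop = FALSE]^2 /
        outer(ssd[keep], pmax(ssy, 1e-300))
      r2 <- pmin(r2, 1 - 1e-12)
      lrs <- -nn * log1p(-r2)
      maxes <- pmax(maxes, apply(lrs, 2L, max))
    }
  }
  for (j in which(has_na)) {
    use <- !is.na(D[, j])
    if (sum(use) < min_lines) next
    dd <- D[use, j]
    dc <- dd - mean(dd)
    ssd <- sum(dc^2)
    if (ssd <= 1e-12) next
    Ym <- Y[use, , drop = FALSE]
    Ymc <- sweep(Ym, 2L, colMeans(Ym))
    ssym <- colSums(Ymc^2)
    cross <- as.numeric(crossprod(dc, Ymc))
    r2 <- pmin(cross^2 / (ssd * pmax(ssym, 1e-300)), 1 - 1e-12)
    maxes <- pmax(maxes, -sum(use) * log1p(-r2))
  }
  maxes
}

#' @export
print.qtl_thresholds <- function(x, ...) {
  cat(sprintf(
    "Genome-wide LRS thresholds (%d permutations, seed %s):\n  significant (pG = 0.05): %.2f\n  suggestive  (pG = 0.63): %.2f\n",
    x$n_perm, format(x$seed), x$significant_lrs, x$suggestive_lrs))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Two-locus pair scan to nominate interacting covariates
#'
#' For every pair of genotyped markers, fits the full two-locus model
#' (both dosages plus their product) against the intercept-only model
#' and ranks pairs by LRS. Used to nominate covariates for composite
#' interval mapping; only genotyped markers (not pseudomarkers) enter.
#'
#' @param values Named per-line trait values.
#' @param grid A [dosage_grid()].
#' @param top_k Number of top pairs to return.
#' @param min_lines Minimum usable lines per pair.
#' @return Data.frame `marker1`, `marker2`, `lrs`, `n`, sorted by
#'   decreasing LRS, at most `top_k` rows.
#' @export
pair_scan <- function(values, grid, top_k = 10, min_lines = 8) {
  mk <- grid$positions$id[!grid$positions$is_pseudo]
  if (length(mk) < 2L) stop("pair scan needs at least 2 markers")
  lines <- intersect(rownames(grid$dosage), names(values))
  lines <- lines[!is.na(values[lines])]
  y <- as.numeric(values[lines])
  D <- grid$dosage[lines, mk, drop = FALSE]
  pairs <- utils::combn(length(mk), 2L)
  lrs <- rep(NA_real_, ncol(pairs))
  nn <- integer(ncol(pairs))
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1L, c_i]; j <- pairs[2L, c_i]
    use <- !is.na(D[, i]) & !is.na(D[, j])
    nn[c_i] <- sum(use)
    if (nn[c_i] < min_lines) next
    yy <- y[use]
    X <- cbind(1, D[use, i], D[use, j], D[use, i] * D[use, j])
    rss_f <- sum(stats::lm.fit(X, yy)$residuals^2)
    rss_0 <- sum((yy - mean(yy))^2)
    lrs[c_i] <- if (rss_0 <= 1e-12) 0 else
      max(nn[c_i] * log(rss_0 / max(rss_f, 1e-300)), 0)
  }
  out <- data.frame(marker1 = mk[pairs[1L, ]], marker2 = mk[pairs[2L, ]],
                    lrs = lrs, n = nn, stringsAsFactors = FALSE)
  out <- out[order(-out$lrs), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' @export
print.qtl_scan <- function(x, ...) {
  pk <- peak_row(x)
  cat(sprintf("Genome scan of %s (%s dataset): %d positions, %d lines\n",
              attr(x, "trait"), attr(x, "dataset"), nrow(x),
              length(attr(x, "lines"))))
  if (length(attr(x, "covariates"))) {
    cat("  CIM covariates:", paste(attr(x, "covariates"), collapse = ", "),
        "\n")
  }
  if (!is.null(pk)) {
    cat(sprintf("  peak: chr %s @ %.1f Mb (%s), LRS = %.2f, effect = %.3f\n",
                pk$chr, pk$Mb, pk$id, pk$lrs, pk$effect))
  }
  invisible(x)
}

# row of the genome-wide peak (ties broken toward the smaller Mb,
# which is the first row because scans are position-sorted)
peak_row <- function(scan) {
  ok <- which(scan$usable & !is.na(scan$lrs))
  if (!length(ok)) return(NULL)
  scan[ok[which.max(scan$lrs[ok])], , drop = FALSE]
}

#' @export
summary.qtl_scan <- function(object, ...) {
  per_chr <- do.call(rbind, lapply(split(as.data.frame(object),
                                         object$chr), function(d) {
    i <- which.max(d$lrs)
    data.frame(chr = d$chr[i], peak_Mb = d$Mb[i], lrs_max = d$lrs[i],
               effect = d$effect[i], stringsAsFactors = FALSE)
  }))
  per_chr <- per_chr[order(chr_rank(per_chr$chr)), , drop = FALSE]
  rownames(per_chr) <- NULL
  per_chr
}

#' Plot a genome scan
#'
#' LRS along the genome with chromosomes laid end to end; optional
#' horizontal lines mark permutation thresholds.
#'
#' @param x A `qtl_scan`.
#' @param thresholds Optional `qtl_thresholds` to draw.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.qtl_scan <- function(x, thresholds = NULL, ...) {
  chrs <- unique(x$chr)
  offs <- 0
  xpos <- numeric(nrow(x))
  mids <- numeric(length(chrs))
  for (i in seq_along(chrs)) {
    sel <- x$chr == chrs[i]
    xpos[sel] <- x$Mb[sel] + offs
    mids[i] <- offs + max(x$Mb[sel]) / 2
    offs <- offs + max(x$Mb[sel]) + 5
  }
  graphics::plot(xpos, x$lrs, type = "n", xaxt = "n", xlab = "chromosome",
                 ylab = "LRS",
                 main = paste("Genome scan:", attr(x, "trait")), ...)
  for (ch in chrs) {
    sel <- x$chr == ch
    graphics::lines(xpos[sel], x$lrs[sel])
  }
  graphics::axis(1, at = mids, labels = chrs)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$significant_lrs, col = "red", lty = 2)
    graphics::abline(h = thresholds$suggestive_lrs, col = "grey40",
                     lty = 3)
  }
  invisible(x)
}
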