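#' Trim outliers from one group of trait values
#'
#' Operationalizes box-plot based outlier removal as the Tukey rule:
#' values outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] are removed. With three
#' or fewer observations nothing is removed (the fences are meaningless
#' at that group size).
#'
#' @param values Numeric vector of trait values for one line/sex/trait.
#' @return List with `kept` (values retained) and `removed` (integer
#'   indices into `values` of the omitted observations).
#' @export
trim_outliers <- function(values) {
  stopifnot(length(values) >= 1)
  if (length(values) <= 3L) {
    return(list(kept = values, removed = integer()))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[2L] + 1.5 * iqr
  out <- which(values < lo | values > hi)
  list(kept = if (length(out)) values[-out] else values, removed = out)
}

#' Per-line trait summaries for the female, male and combined datasets
#'
#' Collapses animal-level records to per-line mean, median, SE and n for
#' each trait, separately for females, males, and the combined dataset,
#' optionally trimming outliers within each line/sex/trait group first
#' (the combined dataset pools the per-sex trimmed values). These strain
#' summaries are what the QTL scans map.
#'
#' @param pheno Animal-level phenotype data.frame (see
#'   [read_phenotypes()]).
#' @param trim Apply [trim_outliers()] within each line/sex/trait group.
#' @return Data.frame with columns `line_id`, `trait`, `dataset`
#'   (`"female"`, `"male"`, `"both"`), `mean`, `median`, `se`
#'   (NA when n = 1) and `n`.
#' @export
summarize_strains <- function(pheno, trim = TRUE) {
  bad <- setdiff(unique(pheno$sex), c("F", "M"))
  if (length(bad)) stop("unknown sex code(s): ", paste(bad, collapse = ", "))
  key <- interaction(pheno$line_id, pheno$sex, pheno$trait, drop = TRUE)
  groups <- split(pheno, key)
  cells <- lapply(groups, function(g) {
    v <- if (trim) trim_outliers(g$value)$kept else g$value
    data.frame(line_id = g$line_id[1L], sex = g$sex[1L],
               trait = g$trait[1L], values = I(list(v)),
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, cells)
  one <- function(line, trait, dataset, v) {
    data.frame(line_id = line, trait = trait, dataset = dataset,
               mean = mean(v), median = stats::median(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    ds <- if (cells$sex[i] == "F") "female" else "male"
    rows[[length(rows) + 1L]] <-
      one(cells$line_id[i], cells$trait[i], ds, cells$values[[i]])
  }
  both_key <- interaction(cells$line_id, cells$trait, drop = TRUE)
  for (g in split(seq_len(nrow(cells)), both_key)) {
    v <- unlist(cells$values[g])
    rows[[length(rows) + 1L]] <-
      one(cells$line_id[g[1L]], cells$trait[g[1L]], "both", v)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$trait, out$dataset, out$line_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract per-line values of one trait/dataset as a named vector
#'
#' Convenience accessor feeding [scan_trait()]: returns the per-line
#' summary statistic named by line id.
#'
#' @param strain_table Output of [summarize_strains()].
#' @param trait Trait name.
#' @param dataset `"female"`, `"male"` or `"both"`.
#' @param stat `"mean"` (default) or `"median"`.
#' @return Named numeric vector.
#' @export
strain_values <- function(strain_table, trait,
                          dataset = c("both", "female", "male"),
                          stat = c("mean", "median")) {
  dataset <- match.arg(dataset)
  stat <- match.arg(stat)
  d <- strain_table[strain_table$trait == trait &
                      strain_table$dataset == dataset, , drop = FALSE]
  if (!nrow(d)) stop("no rows for trait ", trait, " in dataset ", dataset)
  stats::setNames(d[[stat]], d$line_id)
}

#' Intraclass heritability from one-way ANOVA variance components
#'
#' Estimates between-strain (Vb) and within-strain (Vw) variance
#' components by the method of moments from a one-way ANOVA of animals
#' grouped by line: Vw = MS_within and Vb = (MS_between - MS_within) /
#' n0, with n0 the standard unbalanced-design average group size.
#' Negative Vb estimates are clamped to zero and flagged. Heritability
#' is the intraclass ratio h2 = Vb / (Vb + Vw), which is bounded in
#' \[0, 1\].
#'
#' @param pheno Animal-level phenotype data.frame.
#' @param trait Trait to analyze.
#' @param dataset `"female"`, `"male"` or `"both"`.
#' @param trim Trim outliers per line/sex group before the ANOVA.
#' @return A `heritability` object: list with `trait`, `dataset`, `h2`,
#'   `var_between`, `var_within`, `n_lines`, `n_animals`, `clamped`.
#' @export
heritability <- function(pheno, trait,
                         dataset = c("both", "female", "male"),
                         trim = FALSE) {
  dataset <- match.arg(dataset)
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  if (dataset == "female") d <- d[d$sex == "F", , drop = FALSE]
  if (dataset == "male") d <- d[d$sex == "M", , drop = FALSE]
  if (!nrow(d)) stop("no records for trait ", trait)
  if (trim) {
    key <- interaction(d$line_id, d$sex, drop = TRUE)
    d <- do.call(rbind, lapply(split(d, key), function(g) {
      tr <- trim_outliers(g$value)
      if (length(tr$removed)) g[-tr$removed, , drop = FALSE] else g
    }))
  }
  counts <- table(d$line_id)
  if (sum(counts >= 2L) < 2L || length(counts) < 2L) {
    stop("heritability needs >= 2 lines with >= 2 animals each")
  }
  fit <- stats::aov(value ~ line_id, data = d)
  ms <- summary(fit)[[1L]][["Mean Sq"]]
  ms_between <- ms[1L]
  ms_within <- ms[2L]
  N <- nrow(d)
  k <- length(counts)
  n0 <- (N - sum(counts^2) / N) / (k - 1)
  vb <- (ms_between - ms_within) / n0
  clamped <- vb < 0
  vb <- max(vb, 0)
  structure(list(trait = trait, dataset = dataset,
                 h2 = vb / (vb + ms_within),
                 var_between = vb, var_within = ms_within,
                 n_lines = k, n_animals = N, clamped = clamped),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf(
    "Heritability of %s (%s dataset): h2 = %.3f  [Vb = %.3g, Vw = %.3g, %d lines, %d animals]%s\n",
    x$trait, x$dataset, x$h2, x$var_between, x$var_within,
    x$n_lines, x$n_animals,
    if (x$clamped) "  (negative Vb clamped to 0)" else ""))
  invisible(x)
}

#' Critical Pearson correlation at a given two-sided alpha
#'
#' The smallest |r| significant at level `alpha` for `n` paired strain
#' means, from the t distribution with n - 2 degrees of freedom. For
#' n = 30 this is 0.361, the familiar 0.36 cutoff used for trait and
#' candidate-gene correlations.
#'
#' @param n Number of pairs (>= 3).
#' @param alpha Two-sided significance level.
#' @return Critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  t <- stats::qt(1 - alpha / 2, df = n - 2)
  t / sqrt(t^2 + n - 2)
}

#' Pairwise Pearson correlations among strain-level trait means
#'
#' Correlates per-line summary values of each trait pair across the
#' lines present for both traits, with two-sided t-test p-values on
#' n - 2 degrees of freedom. Cells with fewer than 3 common lines are
#' left undefined (NA).
#'
#' @param strain_table Output of [summarize_strains()].
#' @param traits Traits to correlate (default: all in the table).
#' @param dataset Dataset to use.
#' @param stat Summary statistic to correlate.
#' @return A `trait_cor` object: list of square matrices `r`, `p`, `n`.
#' @export
trait_correlations <- function(strain_table, traits = NULL,
                               dataset = c("both", "female", "male"),
                               stat = c("mean", "median")) {
  dataset <- match.arg(dataset)
  stat <- match.arg(stat)
  if (is.null(traits)) traits <- sort(unique(strain_table$trait))
  vals <- lapply(traits, function(tr)
    strain_values(strain_table, tr, dataset, stat))
  names(vals) <- traits
  k <- length(traits)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      common <- intersect(names(vals[[i]]), names(vals[[j]]))
      nm[i, j] <- length(common)
      if (length(common) < 3L) next
      ct <- pearson_test(vals[[i]][common], vals[[j]][common])
      r[i, j] <- ct$r
      p[i, j] <- ct$p
    }
    r[i, i] <- 1
    p[i, i] <- 0
  }
  structure(list(r = r, p = p, n = nm, dataset = dataset, stat = stat),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 3, ...) {
  cat("Pairwise Pearson correlations of strain", x$stat, "values (",
      x$dataset, "dataset )\n")
  print(round(x$r, digits))
  invisible(x)
}

# Pearson r with two-sided t-test p; x, y aligned, n >= 3.
pearson_test <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  if (is.na(r) || abs(r) >= 1) {
    p <- if (is.na(r)) NA_real_ else 0
    return(list(r = r, p = p, n = n))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}
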