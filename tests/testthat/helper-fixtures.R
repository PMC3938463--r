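# Shared fixture builders: everything is generated in code at test time.

# hand-written .geno file content (2 strains x 3 markers by default)
toy_geno_text <- function() {
  c("@type:riset",
    "# toy panel",
    paste(c("Chr", "Locus", "cM", "Mb", "L1", "L2"), collapse = "\t"),
    paste(c("1", "m1", "0", "5", "B", "D"), collapse = "\t"),
    paste(c("1", "m2", "10", "25", "B", "B"), collapse = "\t"),
    paste(c("2", "m3", "0", "8", "D", "H"), collapse = "\t"))
}

write_toy_geno <- function(lines = toy_geno_text()) {
  f <- tempfile(fileext = ".geno")
  writeLines(lines, f)
  f
}

# a geno object built directly (bypasses file IO)
make_geno <- function(calls, chr, mb, cm = mb / 2,
                      markers = sprintf("mk%02d", seq_along(chr))) {
  dimnames(calls) <- list(sprintf("S%02d", seq_len(nrow(calls))), markers)
  fibroqtl:::new_geno(rownames(calls),
                      data.frame(marker = markers, chr = chr, cM = cm,
                                 Mb = mb, stringsAsFactors = FALSE),
                      calls)
}

# small RI panel + grid used by several scan tests
small_panel <- function(n_lines = 30, seed = 11,
                        map = ri_map_spec(n_chr = 5, length_cM = 60,
                                          spacing_cM = 3)) {
  g <- simulate_ri_genotypes(n_lines, map, seed = seed)
  list(geno = g, grid = dosage_grid(g, step_cM = 3), map = map)
}

# minimal qtl_scan object for geometry tests (support intervals etc.)
make_scan <- function(chr, mb, lod, effect = rep(1, length(mb))) {
  lrs <- lod * 2 * log(10)
  structure(data.frame(id = sprintf("p%03d", seq_along(mb)), chr = chr,
                       cM = mb / 2, Mb = mb, is_pseudo = FALSE,
                       n = 30L, lrs = lrs, lod = lod, effect = effect,
                       usable = TRUE, stringsAsFactors = FALSE),
            class = c("qtl_scan", "data.frame"), trait = "toy",
            dataset = "both", covariates = character(),
            lines = sprintf("S%02d", 1:30))
}

make_thresholds <- function(significant, suggestive,
                            max_lrs = numeric()) {
  structure(list(significant_lrs = significant,
                 suggestive_lrs = suggestive, n_perm = length(max_lrs),
                 seed = 1L, max_lrs = max_lrs, warnings = character()),
            class = "qtl_thresholds")
}

# naive per-position regression oracle for LRS (independent of the
# package's vectorized path): plain lm() at every position
lm_scan_oracle <- function(y, grid, covariates = NULL) {
  D <- grid$dosage[names(y), , drop = FALSE]
  vapply(seq_len(ncol(D)), function(j) {
    d <- data.frame(y = y, dose = D[, j])
    if (!is.null(covariates)) {
      d <- cbind(d, as.data.frame(grid$dosage[names(y), covariates,
                                              drop = FALSE]))
    }
    d <- d[stats::complete.cases(d), , drop = FALSE]
    covs <- setdiff(names(d), c("y", "dose"))
    f_red <- if (length(covs))
      stats::reformulate(covs, "y") else y ~ 1
    f_full <- if (length(covs))
      stats::reformulate(c("dose", covs), "y") else y ~ dose
    rss0 <- sum(stats::resid(stats::lm(f_red, d))^2)
    rss1 <- sum(stats::resid(stats::lm(f_full, d))^2)
    if (rss0 <= 1e-12) return(0)
    max(nrow(d) * log(rss0 / rss1), 0)
  }, 0)
}
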