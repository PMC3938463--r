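#' Configuration for a full pipeline run
#'
#' Collects every tunable constant of the funnel in one validated
#' object. The defaults are the constants of the published analysis
#' (2,000 pQTL permutations, 1,000 heatmap permutations, 10-Mb cis
#' window, LRS cutoff 12.0, correlation cutoffs 0.36 / 0.5) and a
#' synthetic-panel block emulating the study's structure: 35 RI lines
#' plus the two parents, six animals per sex and line, expression for
#' 30 strains.
#'
#' @param seed Integer seed; mandatory, drives every stochastic stage.
#' @param n_lines RI lines to simulate.
#' @param include_parents Include the two parental strains in mapping.
#' @param replicates_per_sex Animals per line and sex.
#' @param n_strains_expr Strains with expression data.
#' @param n_genes Genes in the synthetic annotation.
#' @param map Marker map data.frame (see [ri_map_spec()]).
#' @param traits List of trait blocks: each a list with `name`, `h2`,
#'   `mean`, `sd` and `qtls` (list of [planted_qtl()]).
#' @param eqtls List of [planted_eqtl()] objects.
#' @param datasets Which datasets to scan.
#' @param n_perm,n_perm_heatmap Permutation counts for thresholds and
#'   for the heatmap p-values.
#' @param step_cM Pseudomarker spacing.
#' @param cis_window_Mb,lrs_cutoff,r_threshold,r_strong Funnel
#'   constants.
#' @param use_median Map strain medians instead of means.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed,
                       n_lines = 35,
                       include_parents = TRUE,
                       replicates_per_sex = 6,
                       n_strains_expr = 30,
                       n_genes = 1000,
                       map = ri_map_spec(),
                       traits = NULL,
                       eqtls = NULL,
                       datasets = c("female", "male", "both"),
                       n_perm = 2000,
                       n_perm_heatmap = 1000,
                       step_cM = 1,
                       cis_window_Mb = 10,
                       lrs_cutoff = 12,
                       r_threshold = 0.36,
                       r_strong = 0.5,
                       use_median = FALSE) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_perm > 0, n_perm_heatmap > 0, step_cM > 0,
            cis_window_Mb > 0, lrs_cutoff > 0, r_threshold > 0,
            r_strong > 0, n_strains_expr >= 2)
  if (is.null(traits)) {
    pick <- function(frac) {
      ch <- unique(map$chr)[max(1L, round(frac * length(unique(map$chr))))]
      sub <- map[map$chr == ch, ]
      sub$marker[ceiling(nrow(sub) / 2)]
    }
    traits <- list(
      list(name = "collagen_area", h2 = 0.59, mean = 2.4, sd = 1.0,
           qtls = list(planted_qtl(pick(0.25), 0.35, sign = 1))),
      list(name = "hyp", h2 = 0.51, mean = 386.9, sd = 141.5,
           qtls = list(planted_qtl(pick(0.6), 0.35, sign = -1))),
      list(name = "f_score", h2 = 0.57, mean = 2.3, sd = 1.0,
           qtls = list(planted_qtl(pick(0.25), 0.3, sign = 1))))
  }
  structure(list(seed = as.integer(seed), n_lines = n_lines,
                 include_parents = include_parents,
                 replicates_per_sex = replicates_per_sex,
                 n_strains_expr = n_strains_expr, n_genes = n_genes,
                 map = map, traits = traits, eqtls = eqtls,
                 datasets = datasets, n_perm = n_perm,
                 n_perm_heatmap = n_perm_heatmap, step_cM = step_cM,
                 cis_window_Mb = cis_window_Mb,
                 lrs_cutoff = lrs_cutoff, r_threshold = r_threshold,
                 r_strong = r_strong, use_median = use_median),
            class = "run_config")
}

# deterministic sub-seed derivation, kept under 2^31
stage_seed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2147483L

#' Run the full funnel on a synthetic RI panel
#'
#' Config-driven orchestration of every stage: simulate genotypes,
#' phenotypes and expression; summarize strains, estimate heritability
#' and trait correlations; genome-scan every trait and dataset with
#' permutation thresholds and detect pQTLs; map eQTLs in treated and
#' control expression, classify cis/trans, dissect every pQTL region;
#' apply the three candidate criteria; build the candidate network and
#' the signed QTL heatmap. All numeric tables, a run report and a
#' provenance record are written to `out_dir`. Given the same config
#' (including seed) the run is fully deterministic.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every intermediate object (`geno`,
#'   `pheno`, `strain_table`, `heritability`, `scans`, `thresholds`,
#'   `pqtls`, `eqtls_treated`, `eqtls_control`, `regions`,
#'   `candidates`, `network`, `heatmap`, `colocalization`, `census`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ## --- synthetic data -------------------------------------------------
  geno <- stage("synth_genotypes",
                simulate_ri_genotypes(config$n_lines, config$map,
                                      seed = stage_seed(config$seed, 1L)))
  if (config$include_parents) geno <- add_parents(geno)
  ann <- stage("synth_annotation",
               simulate_annotation(geno, config$n_genes,
                                   seed = stage_seed(config$seed, 2L)))
  pheno <- stage("synth_phenotypes", do.call(rbind, lapply(
    seq_along(config$traits), function(i) {
      tr <- config$traits[[i]]
      simulate_phenotypes(geno, tr$qtls, tr$h2,
                          config$replicates_per_sex, tr$name,
                          mean = tr$mean %||% 0, sd = tr$sd %||% 1,
                          seed = stage_seed(config$seed, 10L + i))
    })))
  eqtls_planted <- config$eqtls
  if (is.null(eqtls_planted)) {
    # default: cis-regulate genes located under each planted pQTL
    # (the structure the funnel is built to find) — half treated-only,
    # half shared between conditions — plus two unlinked cis genes
    eqtls_planted <- list()
    for (tr in config$traits) {
      for (q in tr$qtls) {
        mi <- match(q$marker_id, geno$map$marker)
        near <- which(ann$chr == geno$map$chr[mi] &
                        abs(ann$start_Mb - geno$map$Mb[mi]) <= 8)
        for (k in utils::head(near, 3L)) {
          mk <- nearest_marker(geno, ann$chr[k], ann$start_Mb[k])
          scope <- if (length(eqtls_planted) %% 2L == 0L)
            "treated_only" else "both"
          eqtls_planted[[length(eqtls_planted) + 1L]] <-
            planted_eqtl(ann$gene_id[k], mk, effect_size = 2,
                         condition_scope = scope)
        }
      }
    }
    planted_ids <- vapply(eqtls_planted, `[[`, "", "gene_id")
    spare <- setdiff(seq_len(nrow(ann)), match(planted_ids,
                                               ann$gene_id))
    for (k in utils::head(spare, 2L)) {
      mk <- nearest_marker(geno, ann$chr[k], ann$start_Mb[k])
      eqtls_planted[[length(eqtls_planted) + 1L]] <-
        planted_eqtl(ann$gene_id[k], mk, effect_size = 2,
                     condition_scope = "both")
    }
  }
  expr_raw <- stage("synth_expression",
                    simulate_expression(geno, ann, eqtls_planted,
                                        config$n_strains_expr,
                                        seed = stage_seed(config$seed,
                                                          20L)))
  ## --- phenotype prep -------------------------------------------------
  strain_table <- stage("prep", summarize_strains(pheno))
  trait_names <- vapply(config$traits, `[[`, "", "name")
  herit <- do.call(rbind, lapply(trait_names, function(tr)
    do.call(rbind, lapply(config$datasets, function(ds) {
      h <- heritability(pheno, tr, ds)
      data.frame(trait = tr, dataset = ds, h2 = h$h2,
                 var_between = h$var_between,
                 var_within = h$var_within,
                 stringsAsFactors = FALSE)
    }))))
  tcor <- trait_correlations(strain_table, trait_names)
  ## --- pQTL scans -----------------------------------------------------
  grid <- stage("dosage_grid", dosage_grid(geno, config$step_cM))
  stat <- if (config$use_median) "median" else "mean"
  scans <- list()
  thresholds <- list()
  pqtl_list <- list()
  kseed <- 100L
  for (tr in trait_names) {
    for (ds in config$datasets) {
      kseed <- kseed + 1L
      y <- strain_values(strain_table, tr, ds, stat)
      sc <- stage("scan", scan_trait(y, grid, trait = tr, dataset = ds))
      th <- stage("thresholds",
                  permutation_thresholds(y, grid, config$n_perm,
                                         seed = stage_seed(config$seed,
                                                           kseed)))
      key <- paste(tr, ds, sep = ".")
      scans[[key]] <- sc
      thresholds[[key]] <- th
      pqtl_list[[key]] <- detect_pqtls(sc, th)
    }
  }
  pqtls <- structure(do.call(rbind, pqtl_list),
                     class = c("pqtl_set", "data.frame"))
  rownames(pqtls) <- NULL
  if (nrow(pqtls)) pqtls <- overlap_pqtls(pqtls)
  ## --- eQTL mapping ---------------------------------------------------
  expr_norm <- lapply(expr_raw, normalize_expression)
  eq <- lapply(expr_norm, function(e)
    classify_cis_trans(
      scan_transcripts(e, grid, config$lrs_cutoff), ann,
      config$cis_window_Mb))
  regions <- if (nrow(pqtls)) {
    dissect_regions(pqtls, eq$treated, ann, config$lrs_cutoff)
  } else NULL
  ## --- candidates -----------------------------------------------------
  cis_genes <- lapply(eq, function(e)
    unique(e$transcript_id[e$regulation == "cis"]))
  cisqtgs <- if (!is.null(regions)) {
    unique(unlist(lapply(attr(regions, "regions"), `[[`, "cisqtgs")))
  } else character()
  candidates <- select_candidates(cisqtgs, expr_norm$treated,
                                  strain_table, ann,
                                  cis_genes$treated, cis_genes$control,
                                  traits = trait_names,
                                  r_threshold = config$r_threshold)
  ## --- network + heatmap ----------------------------------------------
  network <- if (nrow(candidates) >= 2L) {
    correlation_edges(expr_norm$treated[, candidates$gene_id,
                                        drop = FALSE],
                      ann, config$r_threshold, config$r_strong)
  } else NULL
  hm_scans <- scans[paste(trait_names, "both", sep = ".")]
  names(hm_scans) <- trait_names
  hm_dists <- lapply(trait_names, function(tr) {
    y <- strain_values(strain_table, tr, "both", stat)
    permutation_thresholds(y, grid, config$n_perm_heatmap,
                           seed = stage_seed(config$seed, 500L +
                                               match(tr, trait_names)))
  })
  names(hm_dists) <- trait_names
  expr_t <- expr_norm$treated
  for (g in utils::head(candidates$gene_id, 25L)) {
    hm_scans[[g]] <- scan_trait(expr_t[, g], grid, trait = g,
                                dataset = "expression")
    hm_dists[[g]] <- permutation_thresholds(
      expr_t[, g], grid, config$n_perm_heatmap,
      seed = stage_seed(config$seed, 600L + match(g,
                                                  candidates$gene_id)))
  }
  heatmap <- heatmap_matrix(hm_scans, hm_dists)
  coloc <- colocalize(heatmap, pqtls)
  ## --- outputs --------------------------------------------------------
  census <- c(genes_in_regions = if (is.null(regions)) 0L else
                sum(regions$n_genes),
              cisqtgs = length(cisqtgs), attr(candidates, "census"))
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_geno(geno, file.path(out_dir, "genotypes.geno"))
  write_annotation(ann, file.path(out_dir, "annotation.tsv"))
  write_phenotypes(pheno, file.path(out_dir, "phenotypes.tsv"))
  write_expression(expr_norm$treated,
                   file.path(out_dir, "expression_treated.tsv"))
  write_expression(expr_norm$control,
                   file.path(out_dir, "expression_control.tsv"))
  wt(strain_table, "strain_summary.tsv")
  wt(herit, "heritability.tsv")
  for (key in names(scans)) {
    wt(as.data.frame(scans[[key]]), paste0("scan_", key, ".tsv"))
  }
  wt(as.data.frame(pqtls), "pqtls.tsv")
  for (cond in names(eq)) {
    wt(as.data.frame(eq[[cond]]), paste0("eqtls_", cond, ".tsv"))
  }
  if (!is.null(regions)) wt(regions, "regions.tsv")
  wt(as.data.frame(candidates), "candidates.tsv")
  if (!is.null(network)) {
    write_network(network, file.path(out_dir, "network_edges.tsv"))
    wt(network$nodes, "network_nodes.tsv")
  }
  utils::write.table(cbind(scan = rownames(heatmap),
                           as.data.frame(unclass(heatmap))),
                     file.path(out_dir, "heatmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wt(coloc, "colocalization.tsv")
  report <- c(
    "Run report",
    "==========",
    sprintf("lines: %d (+parents: %s), replicates/sex: %d",
            config$n_lines, config$include_parents,
            config$replicates_per_sex),
    sprintf("markers: %d, pseudomarker step: %g cM",
            nrow(geno$map), config$step_cM),
    sprintf("pQTLs detected (suggestive or better): %d", nrow(pqtls)),
    sprintf("funnel: %d genes in pQTL regions -> %d cisQTGs -> %d / %d / %d candidates (tier >=1 / >=2 / =3)",
            census["genes_in_regions"], census["cisqtgs"],
            census["tier1"], census["tier2"], census["tier3"]),
    if (!is.null(network)) sprintf(
      "network: %d edges (%d inter-, %d intra-chromosomal)",
      nrow(network$edges), sum(network$edges$scope == "inter"),
      sum(network$edges$scope == "intra")) else
        "network: skipped (fewer than 2 candidates)")
  writeLines(report, file.path(out_dir, "report.txt"))
  prov <- c(
    sprintf("package: fibroqtl %s",
            as.character(utils::packageVersion("fibroqtl"))),
    sprintf("R: %s", R.version.string),
    sprintf("seed: %d", config$seed),
    sprintf("n_perm: %d  n_perm_heatmap: %d", config$n_perm,
            config$n_perm_heatmap),
    sprintf("cis_window_Mb: %g  lrs_cutoff: %g  r_threshold: %g  r_strong: %g",
            config$cis_window_Mb, config$lrs_cutoff,
            config$r_threshold, config$r_strong),
    "peak ties: broken toward the smaller Mb coordinate",
    unlist(lapply(names(thresholds), function(k)
      sprintf("thresholds[%s]: significant=%.3f suggestive=%.3f %s", k,
              thresholds[[k]]$significant_lrs,
              thresholds[[k]]$suggestive_lrs,
              paste(thresholds[[k]]$warnings, collapse = "; ")))))
  writeLines(prov, file.path(out_dir, "provenance.txt"))
  invisible(list(geno = geno, annotation = ann, pheno = pheno,
                 strain_table = strain_table, heritability = herit,
                 trait_correlations = tcor, grid = grid, scans = scans,
                 thresholds = thresholds, pqtls = pqtls,
                 eqtls_treated = eq$treated,
                 eqtls_control = eq$control, regions = regions,
                 candidates = candidates, network = network,
                 heatmap = heatmap, colocalization = coloc,
                 census = census))
}
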