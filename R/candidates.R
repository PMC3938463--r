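#' Criterion (i): correlation of a cisQTG with a fibrosis phenotype
#'
#' A candidate passes when its strain-level expression shows |r| strictly
#' greater than `r_threshold` (default 0.36, the two-sided p < 0.05
#' critical value at 30 strains) with at least one of the fibrosis
#' traits; serum ALT is deliberately not among them. No multiple-testing
#' correction is applied across genes — the funnel is explorative by
#' design, and downstream output records this.
#'
#' @param gene_values Named expression values (one per strain).
#' @param strain_table Output of [summarize_strains()].
#' @param traits Fibrosis traits eligible for the criterion.
#' @param dataset Dataset of strain means to correlate against.
#' @param r_threshold Strict |r| cutoff.
#' @return List with `flag`, `best_trait`, `r`, `p`, `n` (of the best
#'   trait) and `reason` (non-NULL when undefined).
#' @export
criterion_correlation <- function(gene_values, strain_table,
                                  traits = c("collagen_area", "hyp",
                                             "f_score"),
                                  dataset = "both",
                                  r_threshold = 0.36) {
  best <- list(flag = FALSE, best_trait = NA_character_, r = NA_real_,
               p = NA_real_, n = 0L, reason = NULL)
  any_defined <- FALSE
  for (tr in traits) {
    tv <- tryCatch(strain_values(strain_table, tr, dataset),
                   error = function(e) NULL)
    if (is.null(tv)) next
    common <- intersect(names(gene_values), names(tv))
    if (length(common) < 3L) next
    ct <- pearson_test(gene_values[common], tv[common])
    if (is.na(ct$r)) next
    any_defined <- TRUE
    if (is.na(best$r) || abs(ct$r) > abs(best$r)) {
      best$best_trait <- tr
      best$r <- ct$r
      best$p <- ct$p
      best$n <- ct$n
    }
  }
  if (!any_defined) {
    best$reason <- "fewer than 3 common strains for every trait"
    return(best)
  }
  best$flag <- abs(best$r) > r_threshold   # strict inequality
  best
}

#' Criterion (ii): segregating non-synonymous SNP
#'
#' Pure annotation lookup: does the gene carry a non-synonymous SNP
#' that differs between the two parental strains?
#'
#' @param gene_id Gene symbol.
#' @param annotation Gene annotation data.frame.
#' @return Logical flag.
#' @export
criterion_nssnp <- function(gene_id, annotation) {
  i <- match(gene_id, annotation$gene_id)
  if (is.na(i)) stop("gene absent from annotation: ", gene_id)
  annotation$has_nssnp[i]
}

#' Criterion (iii): differential cis-regulation between conditions
#'
#' Class A ("fibrosis-specific", flag TRUE) when the gene is
#' cis-regulated in exactly one of the two conditions (treated XOR
#' control); class B ("fibrosis-independent", flag FALSE) when it is
#' cis-regulated in both. A gene cis in neither condition should have
#' been excluded upstream — reaching this function with both flags
#' FALSE signals a pipeline ordering bug and raises an error.
#'
#' @param cis_treated,cis_control Logical cis-status flags per
#'   condition.
#' @return List with `class` (`"A"`/`"B"`) and `flag`.
#' @export
criterion_differential <- function(cis_treated, cis_control) {
  stopifnot(is.logical(cis_treated), is.logical(cis_control))
  if (!cis_treated && !cis_control) {
    stop("gene is cis-regulated in neither condition; ",
         "it should have been excluded upstream")
  }
  if (xor(cis_treated, cis_control)) list(class = "A", flag = TRUE)
  else list(class = "B", flag = FALSE)
}

#' Apply the three selection criteria to a cisQTG list
#'
#' Evaluates, independently for each cis-regulated quantitative trait
#' gene: (i) correlation with a fibrosis trait, (ii) a segregating
#' nsSNP, and (iii) differential cis-regulation between the treated and
#' control expression datasets. Genes satisfying at least one criterion
#' are the candidate list; the census reports how many reach tiers
#' >= 1, >= 2 and = 3.
#'
#' @param cisqtgs Character vector of cisQTG gene ids.
#' @param expr Strain x transcript normalized expression matrix
#'   (treated condition) providing criterion-(i) values.
#' @param strain_table Strain trait summaries ([summarize_strains()]).
#' @param annotation Gene annotation data.frame.
#' @param cis_treated,cis_control Character vectors of gene ids that
#'   are cis-regulated in each condition.
#' @param traits,dataset,r_threshold Passed to
#'   [criterion_correlation()].
#' @return A `candidate_set`: data.frame of genes with tier >= 1
#'   (`gene_id`, `chr`, criterion flags, best correlation, `diff_class`,
#'   `tier`), with attributes `census` (named vector `tier1`, `tier2`,
#'   `tier3`) and `all_genes` (the unfiltered table).
#' @export
select_candidates <- function(cisqtgs, expr, strain_table, annotation,
                              cis_treated, cis_control,
                              traits = c("collagen_area", "hyp",
                                         "f_score"),
                              dataset = "both", r_threshold = 0.36) {
  rows <- lapply(cisqtgs, function(g) {
    if (!g %in% colnames(expr)) {
      stop("cisQTG absent from expression matrix: ", g)
    }
    c1 <- criterion_correlation(expr[, g], strain_table, traits,
                                dataset, r_threshold)
    c2 <- criterion_nssnp(g, annotation)
    c3 <- criterion_differential(g %in% cis_treated,
                                 g %in% cis_control)
    data.frame(gene_id = g,
               chr = annotation$chr[match(g, annotation$gene_id)],
               crit_correlation = c1$flag, best_trait = c1$best_trait,
               best_r = c1$r, best_p = c1$p, crit_nssnp = c2,
               crit_differential = c3$flag, diff_class = c3$class,
               tier = sum(c1$flag, c2, c3$flag),
               stringsAsFactors = FALSE)
  })
  all_genes <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_id = character(), chr = character(),
    crit_correlation = logical(), best_trait = character(),
    best_r = numeric(), best_p = numeric(), crit_nssnp = logical(),
    crit_differential = logical(), diff_class = character(),
    tier = integer(), stringsAsFactors = FALSE)
  census <- c(tier1 = sum(all_genes$tier >= 1),
              tier2 = sum(all_genes$tier >= 2),
              tier3 = sum(all_genes$tier == 3))
  out <- all_genes[all_genes$tier >= 1, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"),
            census = census, all_genes = all_genes,
            r_threshold = r_threshold,
            multiple_testing = "none (explorative screen)")
}

#' @export
print.candidate_set <- function(x, ...) {
  cen <- attr(x, "census")
  cat(sprintf(
    "Candidate genes: %d passed >= 1 criterion, %d passed >= 2, %d passed all 3 (of %d cisQTGs)\n",
    cen["tier1"], cen["tier2"], cen["tier3"],
    nrow(attr(x, "all_genes"))))
  invisible(x)
}
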