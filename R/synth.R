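#' Map expansion for recombinant inbred lines bred by sib mating
#'
#' For RI lines derived from an F2 by repeated sib mating (the BXD
#' breeding scheme), the per-interval probability that two loci carry
#' different parental alleles in the finished inbred line is larger than
#' the meiotic recombination fraction r: R = 4r / (1 + 6r)
#' (Haldane-Waddington expansion). The selfing formula 2r/(1+2r) does
#' not apply to sib-mated panels and is deliberately not used.
#'
#' @param r Meiotic recombination fraction(s) in \[0, 0.5\].
#' @return RI-line recombination fraction(s), same length as `r`.
#' @examples
#' ri_recombination(0.1)   # 0.25
#' @export
ri_recombination <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.5)) {
    stop("recombination fraction must lie in [0, 0.5]")
  }
  4 * r / (1 + 6 * r)
}

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a meiotic
#' recombination fraction assuming no crossover interference:
#' r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM Genetic distance(s) in cM (non-negative).
#' @return Recombination fraction(s) in \[0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("genetic distance must be non-negative")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

# RI-line transition probability across a cM interval
ri_transition <- function(d_cM) ri_recombination(haldane_r(d_cM))

#' Build a marker map specification for a synthetic RI genome
#'
#' The default emulates a mouse autosomal genome at GeneNetwork marker
#' density: 19 chromosomes of 70 cM with markers every 2 cM, physical
#' positions at 2 Mb per cM.
#'
#' @param n_chr Number of chromosomes (labelled "1", "2", ...).
#' @param length_cM Chromosome length(s) in cM (recycled).
#' @param spacing_cM Marker spacing in cM.
#' @param mb_per_cM Physical-to-genetic scaling for the synthetic map.
#' @return Map data.frame with columns `marker`, `chr`, `cM`, `Mb`.
#' @export
ri_map_spec <- function(n_chr = 19, length_cM = 70, spacing_cM = 2,
                        mb_per_cM = 2) {
  stopifnot(n_chr >= 1, all(length_cM > 0), spacing_cM > 0)
  length_cM <- rep_len(length_cM, n_chr)
  maps <- lapply(seq_len(n_chr), function(ch) {
    cm <- seq(0, length_cM[ch], by = spacing_cM)
    data.frame(marker = sprintf("c%d_m%03d", ch, seq_along(cm)),
               chr = as.character(ch), cM = cm, Mb = cm * mb_per_cM,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Simulate RI-line genotypes along a marker map
#'
#' Each line is an independent Markov chain along each chromosome: the
#' first marker is B or D with probability 1/2, and the allele flips
#' between adjacent markers with the RI-expanded recombination
#' probability R for that interval (cM distance converted through the
#' Haldane map function, then [ri_recombination()]). All calls are B or
#' D: the panel is modelled as fully inbred.
#'
#' @param n_lines Number of RI lines (>= 2).
#' @param map_spec Marker map data.frame as from [ri_map_spec()].
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return A `geno` object.
#' @export
simulate_ri_genotypes <- function(n_lines, map_spec = ri_map_spec(),
                                  seed) {
  stopifnot(n_lines >= 2, nrow(map_spec) >= 1)
  set.seed(seed)
  line_ids <- sprintf("RIL%03d", seq_len(n_lines))
  calls <- matrix("", n_lines, nrow(map_spec),
                  dimnames = list(line_ids, map_spec$marker))
  for (ch in unique(map_spec$chr)) {
    idx <- which(map_spec$chr == ch)
    cm <- map_spec$cM[idx]
    R <- ri_transition(diff(cm))
    g <- ifelse(stats::runif(n_lines) < 0.5, 1, -1)
    calls[, idx[1L]] <- ifelse(g > 0, "D", "B")
    for (k in seq_along(R)) {
      flip <- stats::runif(n_lines) < R[k]
      g <- ifelse(flip, -g, g)
      calls[, idx[k + 1L]] <- ifelse(g > 0, "D", "B")
    }
  }
  map <- map_spec[order(chr_rank(map_spec$chr), map_spec$Mb), ,
                  drop = FALSE]
  rownames(map) <- NULL
  new_geno(line_ids, map, calls[, map$marker, drop = FALSE])
}

#' Append the two parental strains to a genotype matrix
#'
#' Adds `C57BL/6J` (all-B) and `DBA/2J` (all-D) as extra lines, so that
#' mapping can include the parents alongside the RI set.
#'
#' @param geno A `geno` object.
#' @return The augmented `geno` object.
#' @export
add_parents <- function(geno) {
  stopifnot(inherits(geno, "geno"))
  if (any(c("C57BL/6J", "DBA/2J") %in% geno$lines)) {
    stop("parental strains already present")
  }
  m <- nrow(geno$map)
  calls <- rbind(geno$calls,
                 "C57BL/6J" = rep("B", m),
                 "DBA/2J" = rep("D", m))
  new_geno(c(geno$lines, "C57BL/6J", "DBA/2J"), geno$map, calls)
}

#' Describe a QTL to plant in simulated phenotypes
#'
#' @param marker_id Marker at which the effect acts.
#' @param variance_explained Fraction (0, 1) of the strain-mean variance
#'   attributable to this locus.
#' @param sign `+1` if the D allele increases the trait, `-1` otherwise
#'   (Table-style additive-effect convention, B = -1 / D = +1 dosage).
#' @param sex_scope One of `"both"`, `"female"`, `"male"`; sex-scoped
#'   effects act only on animals of that sex.
#' @return A `planted_qtl` list.
#' @export
planted_qtl <- function(marker_id, variance_explained, sign = 1,
                        sex_scope = c("both", "female", "male")) {
  stopifnot(variance_explained > 0, variance_explained < 1,
            sign %in% c(-1, 1))
  structure(list(marker_id = marker_id,
                 variance_explained = variance_explained,
                 sign = sign, sex_scope = match.arg(sex_scope)),
            class = "planted_qtl")
}

#' Simulate replicated animal-level phenotypes with planted QTLs
#'
#' Each animal's value is the sum of its strain's genetic value (planted
#' additive effects times the B=-1/D=+1 allele dose), a strain-level
#' residual, and within-strain Gaussian noise. Variance components are
#' scaled so that the intraclass ratio Vb / (Vb + Vw) equals `h2_target`
#' in expectation and each planted QTL explains its stated fraction of
#' the strain-mean variance (between-strain variance plus Vw divided by
#' the number of replicates). Sex-scoped effects are applied only to the
#' stated sex.
#'
#' @param genos A `geno` object.
#' @param qtls List of [planted_qtl()] objects (may be empty).
#' @param h2_target Target intraclass heritability in \[0, 1).
#' @param replicates_per_sex Animals per line per sex.
#' @param trait_name Trait label for the output records.
#' @param mean,sd Location and scale applied to the standardized values
#'   (trait units).
#' @param seed Integer seed.
#' @return Long-format phenotype data.frame (`animal_id`, `line_id`,
#'   `sex`, `trait`, `value`) with the per-line genetic values attached
#'   as attribute `"genetic_values"`.
#' @export
simulate_phenotypes <- function(genos, qtls = list(), h2_target,
                                replicates_per_sex = 6,
                                trait_name = "trait", mean = 0, sd = 1,
                                seed) {
  stopifnot(inherits(genos, "geno"), h2_target >= 0, h2_target < 1,
            replicates_per_sex >= 1)
  for (q in qtls) {
    if (!q$marker_id %in% genos$map$marker) {
      stop("planted QTL marker not in genotype map: ", q$marker_id)
    }
  }
  set.seed(seed)
  n <- length(genos$lines)
  m_rep <- 2L * replicates_per_sex
  vb <- h2_target
  vw <- 1 - h2_target
  v_sm <- vb + vw / m_rep        # expected strain-mean variance
  eff <- vapply(qtls, function(q) q$sign *
                  sqrt(q$variance_explained * v_sm), 0)
  scope <- vapply(qtls, function(q) q$sex_scope, "")
  vres <- vb - sum(eff^2)
  if (vres < -1e-12) {
    stop("planted variance_explained exceeds h2_target budget")
  }
  # one strain residual per line, shared by both sexes, so the pooled
  # intraclass ratio hits h2_target; sex-scoped effects make the
  # unaffected sex slightly less variable between strains
  resid <- stats::rnorm(n, 0, sqrt(max(vres, 0)))
  g_sex <- function(sx) {
    g <- resid
    for (j in which(scope %in% c("both", sx))) {
      dose <- call_dose(genos$calls[, qtls[[j]]$marker_id])
      dose[is.na(dose)] <- 0
      g <- g + eff[j] * dose
    }
    g
  }
  recs <- list()
  for (sx in c("female", "male")) {
    gv <- g_sex(sx)
    code <- if (sx == "female") "F" else "M"
    for (r in seq_len(replicates_per_sex)) {
      recs[[length(recs) + 1L]] <- data.frame(
        animal_id = sprintf("%s_%s%d", genos$lines, code, r),
        line_id = genos$lines, sex = code, trait = trait_name,
        value = mean + sd * (gv + stats::rnorm(n, 0, sqrt(vw))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Describe an eQTL to plant in simulated expression data
#'
#' @param gene_id Regulated transcript/gene.
#' @param marker_id Regulatory marker.
#' @param effect_size Additive effect in (log2-scale) expression units
#'   per allele substitution; one unit is roughly a two-fold change
#'   after normalization.
#' @param condition_scope `"both"`, `"treated_only"` or `"control_only"`:
#'   in which condition(s) the locus regulates the gene.
#' @return A `planted_eqtl` list.
#' @export
planted_eqtl <- function(gene_id, marker_id, effect_size = 1,
                         condition_scope = c("both", "treated_only",
                                             "control_only")) {
  structure(list(gene_id = gene_id, marker_id = marker_id,
                 effect_size = effect_size,
                 condition_scope = match.arg(condition_scope)),
            class = "planted_eqtl")
}

#' Simulate a gene annotation along a genotype map
#'
#' Genes are placed uniformly along the chromosomes of the map
#' (probability proportional to chromosome length), with short gene
#' bodies and a Bernoulli non-synonymous-SNP flag. The nsSNP rate
#' default (0.125) reflects the fraction typically seen between the two
#' parental mouse genomes in gene-dense QTL regions.
#'
#' @param geno A `geno` object supplying the chromosome extents.
#' @param n_genes Number of genes to place.
#' @param nssnp_rate Probability a gene carries a segregating nsSNP.
#' @param seed Integer seed.
#' @return Annotation data.frame as from [read_annotation()].
#' @export
simulate_annotation <- function(geno, n_genes, nssnp_rate = 0.125,
                                seed) {
  stopifnot(inherits(geno, "geno"), n_genes >= 1)
  set.seed(seed)
  ext <- tapply(geno$map$Mb, geno$map$chr, max)
  chrs <- names(ext)
  pick <- sample(chrs, n_genes, replace = TRUE, prob = as.numeric(ext))
  start <- stats::runif(n_genes, 0, as.numeric(ext[pick]))
  len <- stats::rexp(n_genes, rate = 1 / 0.02)  # ~20 kb gene bodies
  ann <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                    chr = pick, start_Mb = start, end_Mb = start + len,
                    has_nssnp = stats::runif(n_genes) < nssnp_rate,
                    stringsAsFactors = FALSE)
  ann <- ann[order(chr_rank(ann$chr), ann$start_Mb), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' The genotyped marker closest to a genomic position
#'
#' @param geno A `geno` object.
#' @param chr Chromosome label.
#' @param mb Position in Mb.
#' @return Marker id of the nearest marker on that chromosome.
#' @export
nearest_marker <- function(geno, chr, mb) {
  idx <- which(geno$map$chr == chr)
  if (!length(idx)) stop("no markers on chromosome ", chr)
  geno$map$marker[idx[which.min(abs(geno$map$Mb[idx] - mb))]]
}

#' Simulate raw (log2-scale) expression matrices with planted eQTLs
#'
#' Each transcript is a gene-specific baseline plus planted marker
#' effects (restricted by `condition_scope`) plus strain-level Gaussian
#' noise, produced for a treated and a control condition. Values are on
#' the raw log2 scale; [normalize_expression()] is the downstream
#' normalization step.
#'
#' @param genos A `geno` object.
#' @param annotation Gene annotation; one transcript per gene row.
#' @param eqtls List of [planted_eqtl()] objects.
#' @param n_strains_expr Number of lines profiled (the first
#'   `n_strains_expr` lines of the panel; expression studies typically
#'   profile a subset of the phenotyped panel).
#' @param conditions Character vector of conditions to generate.
#' @param baseline_mean,baseline_sd Distribution of per-gene baselines.
#' @param noise_sd Strain-level residual SD (expression units).
#' @param seed Integer seed.
#' @return Named list of strain x transcript matrices, one per
#'   condition.
#' @export
simulate_expression <- function(genos, annotation, eqtls = list(),
                                n_strains_expr = length(genos$lines),
                                conditions = c("treated", "control"),
                                baseline_mean = 7, baseline_sd = 1,
                                noise_sd = 0.5, seed) {
  stopifnot(inherits(genos, "geno"),
            n_strains_expr >= 2,
            n_strains_expr <= length(genos$lines))
  for (e in eqtls) {
    if (!e$gene_id %in% annotation$gene_id) {
      stop("planted eQTL gene not in annotation: ", e$gene_id)
    }
    if (!e$marker_id %in% genos$map$marker) {
      stop("planted eQTL marker not in genotype map: ", e$marker_id)
    }
  }
  set.seed(seed)
  strains <- genos$lines[seq_len(n_strains_expr)]
  genes <- annotation$gene_id
  baseline <- stats::rnorm(length(genes), baseline_mean, baseline_sd)
  names(baseline) <- genes
  scope_ok <- function(scope, cond) {
    scope == "both" ||
      (scope == "treated_only" && cond == "treated") ||
      (scope == "control_only" && cond == "control")
  }
  out <- lapply(conditions, function(cond) {
    m <- matrix(rep(baseline, each = length(strains)),
                nrow = length(strains),
                dimnames = list(strains, genes))
    for (e in eqtls) {
      if (!scope_ok(e$condition_scope, cond)) next
      dose <- call_dose(genos$calls[strains, e$marker_id])
      dose[is.na(dose)] <- 0
      m[, e$gene_id] <- m[, e$gene_id] + e$effect_size * dose
    }
    m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
  })
  names(out) <- conditions
  out
}

# B = -1, D = +1, heterozygous/unknown = NA (RI lines modelled as inbred)
call_dose <- function(calls) {
  d <- ifelse(calls == "D", 1, ifelse(calls == "B", -1, NA_real_))
  if (is.matrix(calls)) dim(d) <- dim(calls)
  d
}
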