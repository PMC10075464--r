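# Synthetic half-sib hybrid trials with known truth.
#
# The generator emulates the stated world of the study design it is built to
# test: ~400 diverse homozygous male lines, one shared female line, hybrids
# whose genotypes are the parental means, an additive (+ optional dominance /
# additive-x-additive epistasis) trait, and a randomized complete block
# design with three replicates.

#' Trait architecture for the synthetic generator
#'
#' @param n_qtl number of causal SNPs (>= 1).
#' @param additive_effect_sd standard deviation of per-QTL additive effects.
#' @param dominance_degree ratio of dominance to additive effect at each QTL;
#'   0 is purely additive. Dominance is expressed only in heterozygotes, so
#'   in this design only hybrids can show it.
#' @param n_epistatic_pairs number of additive-by-additive interacting QTL
#'   pairs.
#' @param epistatic_effect_sd standard deviation of pairwise interaction
#'   effects.
#' @param target_h2 narrow-sense heritability targeted in the parental-line
#'   population, in (0, 1).
#' @param block_effect_sd standard deviation of RCBD block effects.
#' @param n_blocks number of complete blocks (replicates).
#' @return a `trait_architecture` list.
#' @export
trait_architecture <- function(n_qtl = 100, additive_effect_sd = 1,
                               dominance_degree = 0, n_epistatic_pairs = 0,
                               epistatic_effect_sd = 0, target_h2 = 0.8,
                               block_effect_sd = 0.1, n_blocks = 3) {
  stopifnot(n_qtl >= 1, n_blocks >= 1,
            additive_effect_sd >= 0, epistatic_effect_sd >= 0,
            block_effect_sd >= 0, dominance_degree >= 0,
            n_epistatic_pairs >= 0)
  if (!(target_h2 > 0 && target_h2 < 1))
    stop("target_h2 must be strictly inside (0, 1)")
  structure(list(n_qtl = as.integer(n_qtl),
                 additive_effect_sd = additive_effect_sd,
                 dominance_degree = dominance_degree,
                 n_epistatic_pairs = as.integer(n_epistatic_pairs),
                 epistatic_effect_sd = epistatic_effect_sd,
                 target_h2 = target_h2,
                 block_effect_sd = block_effect_sd,
                 n_blocks = as.integer(n_blocks)),
            class = "trait_architecture")
}

#' Simulate a panel of homozygous parental lines
#'
#' Inbred lines are fully homozygous, so codes are 0 or 2 only. Linkage
#' disequilibrium between adjacent markers follows a first-order chain: each
#' line's allele at marker j copies its allele at marker j-1 with probability
#' `ld_decay`, otherwise it is drawn fresh at that marker's frequency. The
#' chain restarts at chromosome boundaries (markers are laid out on 12
#' chromosomes).
#'
#' @param n_lines number of lines (>= 2).
#' @param n_markers number of SNPs (>= 1).
#' @param maf_range length-2 interval for per-marker minor-allele
#'   frequencies, inside \[0, 0.5\].
#' @param ld_decay adjacent-marker copy probability in \[0, 1).
#' @param seed integer seed; runs are bit-reproducible.
#' @param n_chrom number of chromosomes markers are spread over.
#' @return a `geno_matrix` with map.
#' @export
simulate_parents <- function(n_lines, n_markers, maf_range = c(0.05, 0.5),
                             ld_decay = 0, seed = 1, n_chrom = 12) {
  stopifnot(n_lines >= 2, n_markers >= 1)
  if (length(maf_range) != 2 || any(maf_range < 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be a non-empty interval inside [0, 0.5]")
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must be in [0, 1)")
  set.seed(as.integer(seed))
  p <- runif(n_markers, maf_range[1], maf_range[2])
  n_chrom <- min(n_chrom, n_markers)
  chrom <- sort(rep_len(seq_len(n_chrom), n_markers))
  z <- matrix(0L, n_lines, n_markers)
  z[, 1] <- rbinom(n_lines, 1, p[1])
  if (n_markers > 1) {
    for (j in 2:n_markers) {
      fresh <- rbinom(n_lines, 1, p[j])
      if (ld_decay > 0 && chrom[j] == chrom[j - 1]) {
        copy <- runif(n_lines) < ld_decay
        z[, j] <- ifelse(copy, z[, j - 1], fresh)
      } else z[, j] <- fresh
    }
  }
  codes <- 2 * z
  rownames(codes) <- sprintf("L%04d", seq_len(n_lines))
  colnames(codes) <- sprintf("M%06d", seq_len(n_markers))
  pos <- integer(n_markers)
  for (cc in unique(chrom)) pos[chrom == cc] <- seq_len(sum(chrom == cc)) * 100000L
  geno_matrix(codes, data.frame(marker = colnames(codes), chrom = chrom,
                                pos = pos, stringsAsFactors = FALSE))
}

#' Derive half-sib hybrids from a parental panel
#'
#' Every line other than the shared female is crossed to her once; the hybrid
#' genotype at each SNP is the mean of the two parental codes.
#'
#' @param parents parental `geno_matrix` (homozygous codes expected).
#' @param female_id id of the shared female line; must be present.
#' @return list with `hybrids` (a `geno_matrix`) and `pedigree` (a
#'   `data.frame` with columns hybrid, female, male).
#' @export
simulate_halfsib_hybrids <- function(parents, female_id) {
  stopifnot(inherits(parents, "geno_matrix"))
  ids <- individual_ids(parents)
  if (!female_id %in% ids) stop("female_id '", female_id, "' not found among parents")
  males <- setdiff(ids, female_id)
  pedigree <- data.frame(hybrid = paste0("H.", males), female = female_id,
                         male = males, stringsAsFactors = FALSE)
  hyb <- deduce_hybrid_genotypes(parents, pedigree)
  list(hybrids = hyb, pedigree = pedigree)
}

#' Simulate a replicated trait on parents and hybrids
#'
#' Genetic values are built from a sampled QTL set: additive effects act on
#' centered codes, dominance deviations (scaled by `dominance_degree`) act in
#' heterozygotes only, and optional additive-by-additive interactions act on
#' products of centered codes. Residual variance is calibrated empirically so
#' that the realized single-replicate heritability in the parental-line
#' population equals `target_h2`.
#'
#' @param parents,hybrids `geno_matrix` objects over the same marker panel.
#' @param arch a [trait_architecture()].
#' @param seed integer seed.
#' @param grand_mean baseline trait value (default 2, a mesocotyl-like scale
#'   in cm).
#' @return list with `records` (data.frame genotype_id, block, value),
#'   `truth` (data.frame id, true_genetic_value) and `varcomp` (realized
#'   components: var_g_lines, var_g_hybrids, sigma_e2, h2_realized).
#' @export
simulate_trait <- function(parents, hybrids, arch, seed = 1, grand_mean = 2) {
  stopifnot(inherits(parents, "geno_matrix"), inherits(hybrids, "geno_matrix"),
            inherits(arch, "trait_architecture"))
  if (!identical(marker_ids(parents), marker_ids(hybrids)))
    stop("marker sets of parents and hybrids differ; align panels first")
  set.seed(as.integer(seed))
  X <- rbind(parents$codes, hybrids$codes)
  m <- ncol(X)
  n_qtl <- min(arch$n_qtl, m)
  qtl <- sort(sample.int(m, n_qtl))
  a <- rnorm(n_qtl, 0, arch$additive_effect_sd)
  d <- arch$dominance_degree * abs(a)
  Xq <- X[, qtl, drop = FALSE]
  g <- drop((Xq - 1) %*% a)
  if (arch$dominance_degree > 0) g <- g + drop((Xq == 1) %*% d)
  if (arch$n_epistatic_pairs > 0 && n_qtl >= 2) {
    npair <- arch$n_epistatic_pairs
    pairs <- replicate(npair, sample.int(n_qtl, 2))
    ee <- rnorm(npair, 0, arch$epistatic_effect_sd)
    for (k in seq_len(npair)) {
      g <- g + ee[k] * (Xq[, pairs[1, k]] - 1) * (Xq[, pairs[2, k]] - 1)
    }
  }
  names(g) <- rownames(X)
  idx_lines <- individual_ids(parents)
  var_g_lines <- var(g[idx_lines])
  if (var_g_lines <= 0) stop("degenerate genetic variance among lines; increase n_qtl or effect sd")
  sigma_e2 <- var_g_lines * (1 - arch$target_h2) / arch$target_h2
  blocks <- rnorm(arch$n_blocks, 0, arch$block_effect_sd)
  n_ind <- nrow(X)
  records <- data.frame(
    genotype_id = rep(rownames(X), times = arch$n_blocks),
    block = rep(sprintf("B%d", seq_len(arch$n_blocks)), each = n_ind),
    value = grand_mean + rep(blocks, each = n_ind) + rep(g, times = arch$n_blocks) +
      rnorm(n_ind * arch$n_blocks, 0, sqrt(sigma_e2)),
    stringsAsFactors = FALSE)
  truth <- data.frame(id = rownames(X), true_genetic_value = unname(g),
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth,
       varcomp = list(var_g_lines = var_g_lines,
                      var_g_hybrids = var(g[individual_ids(hybrids)]),
                      sigma_e2 = sigma_e2,
                      h2_realized = var_g_lines / (var_g_lines + sigma_e2)))
}

#' Simulate a complete half-sib trial in one call
#'
#' Convenience wrapper chaining [simulate_parents()],
#' [simulate_halfsib_hybrids()] and [simulate_trait()].
#'
#' @inheritParams simulate_parents
#' @param arch a [trait_architecture()].
#' @param female_id id of the shared female; defaults to the first line.
#' @param ... passed to [simulate_parents()].
#' @return list with `parents`, `hybrids`, `pedigree`, `records`, `truth`,
#'   `varcomp`, `female_id`.
#' @export
simulate_halfsib_trial <- function(n_lines = 402, n_markers = 2000,
                                   arch = trait_architecture(), seed = 1,
                                   female_id = NULL, ...) {
  parents <- simulate_parents(n_lines, n_markers, seed = seed, ...)
  if (is.null(female_id)) female_id <- individual_ids(parents)[1]
  hs <- simulate_halfsib_hybrids(parents, female_id)
  tr <- simulate_trait(parents, hs$hybrids, arch, seed = seed + 1)
  c(list(parents = parents, hybrids = hs$hybrids, pedigree = hs$pedigree,
         female_id = female_id), tr)
}
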