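# Genotype QC, imputation, LD pruning, hybrid deduction, relationship
# matrices and kernels, PCA, pairwise dissimilarity.

#' SNP quality-control filter
#'
#' Retains markers with minor allele frequency >= `maf_min`, call rate >=
#' `callrate_min` and heterozygote rate <= `het_max` (rates computed over
#' non-missing calls for MAF/het, over all individuals for call rate).
#'
#' @param G a `geno_matrix`.
#' @param maf_min,callrate_min,het_max filter thresholds.
#' @return filtered `geno_matrix`; attribute `"qc_report"` holds per-filter
#'   removal counts (a marker failing several filters is counted once, under
#'   the first in maf / callrate / het order).
#' @export
qc_filter <- function(G, maf_min = 0.05, callrate_min = 0.90, het_max = 0.10) {
  stopifnot(inherits(G, "geno_matrix"))
  if (ncol(G$codes) == 0) stop("empty genotype matrix")
  codes <- G$codes
  callrate <- colMeans(!is.na(codes))
  maf <- maf_of(codes)
  het <- colMeans(codes == 1, na.rm = TRUE)
  maf[is.nan(maf)] <- 0
  het[is.nan(het)] <- 0
  fail_maf <- maf < maf_min
  fail_cr <- !fail_maf & callrate < callrate_min
  fail_het <- !fail_maf & !fail_cr & het > het_max
  keep <- !(fail_maf | fail_cr | fail_het)
  if (!any(keep)) warning("all markers removed by QC; empty panel returned")
  out <- gm_subset(G, markers = which(keep))
  attr(out, "qc_report") <- c(removed_maf = sum(fail_maf),
                              removed_callrate = sum(fail_cr),
                              removed_het = sum(fail_het),
                              retained = sum(keep))
  out
}

#' Impute missing genotype codes
#'
#' In parental (inbred) panels heterozygous calls are treated as errors:
#' with `het_to_missing = TRUE` (default) all code-1 cells are first set to
#' missing, then every missing cell is filled per marker by the rounded
#' column mean or the column mode. A simple single-marker imputer standing in
#' for haplotype-based tools, which are out of scope here.
#'
#' @param G a `geno_matrix`.
#' @param mode `"column_mean_round"` or `"column_mode"`; mode ties go to the
#'   lower code.
#' @param het_to_missing set heterozygotes to missing before imputing.
#' @return imputed `geno_matrix` with no missing codes; markers that are
#'   entirely missing are dropped with a warning. Attribute
#'   `"imputed_mask"` is a logical matrix marking filled cells.
#' @export
impute_missing <- function(G, mode = c("column_mean_round", "column_mode"),
                           het_to_missing = TRUE) {
  stopifnot(inherits(G, "geno_matrix"))
  mode <- match.arg(mode)
  codes <- G$codes
  if (het_to_missing) codes[codes == 1] <- NA
  all_na <- colSums(!is.na(codes)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " marker(s) entirely missing; removed")
    codes <- codes[, !all_na, drop = FALSE]
  }
  mask <- is.na(codes)
  for (j in which(colSums(mask) > 0)) {
    x <- codes[, j]
    obs <- x[!is.na(x)]
    fill <- if (mode == "column_mean_round") {
      round(mean(obs))
    } else {
      counts <- table(obs)
      as.numeric(names(counts)[which.max(counts)])  # ties: first = lower code
    }
    codes[is.na(x), j] <- fill
  }
  map <- G$map
  if (!is.null(map)) map <- map[map$marker %in% colnames(codes), , drop = FALSE]
  out <- geno_matrix(codes, map)
  attr(out, "imputed_mask") <- mask
  out
}

#' Sliding-window LD pruning
#'
#' Within each window of `window` SNPs (advanced by `step`), pairs with
#' squared Pearson correlation above `r2_max` are resolved by removing one
#' SNP until no violating pair remains. The kept SNP of a pair is the one
#' with higher MAF; ties keep the lower position. Markers must be sorted by
#' (chromosome, position); windows never span chromosomes.
#'
#' @param G a `geno_matrix` with map, no missing codes.
#' @param window,step window size and shift, in SNPs.
#' @param r2_max squared-correlation threshold.
#' @return pruned `geno_matrix`.
#' @export
ld_prune <- function(G, window = 50, step = 5, r2_max = 0.1) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is.null(G$map)) stop("ld_prune needs a marker map (chromosome, position)")
  if (anyNA(G$codes)) stop("impute missing codes before pruning")
  map <- G$map
  o <- order(map$chrom, map$pos)
  if (!identical(o, seq_len(nrow(map))))
    stop("markers are not sorted by (chromosome, position)")
  keep_global <- character(0)
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    codes <- G$codes[, idx, drop = FALSE]
    maf <- maf_of(codes)
    pos <- map$pos[idx]
    m <- length(idx)
    keep <- rep(TRUE, m)
    s <- 1
    repeat {
      w <- seq(s, min(s + window - 1, m))
      cur <- w[keep[w]]
      while (length(cur) > 1) {
        cm <- suppressWarnings(cor(codes[, cur, drop = FALSE]))
        cm[!is.finite(cm)] <- 0
        diag(cm) <- 0
        viol <- which(cm^2 > r2_max, arr.ind = TRUE)
        if (nrow(viol) == 0) break
        viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
        i1 <- cur[viol[1, 1]]; i2 <- cur[viol[1, 2]]
        drop_i <- if (maf[i1] > maf[i2]) i2
                  else if (maf[i2] > maf[i1]) i1
                  else if (pos[i1] <= pos[i2]) i2 else i1
        keep[drop_i] <- FALSE
        cur <- setdiff(cur, drop_i)
      }
      if (s + window - 1 >= m) break
      s <- s + step
    }
    keep_global <- c(keep_global, colnames(codes)[keep])
  }
  gm_subset(G, markers = keep_global)
}

#' Deduce hybrid genotypes from parental genotypes
#'
#' At each SNP the hybrid code is the mean of the two parental codes, so a
#' cross of homozygous parents yields codes in \{0, 1, 2\} with 1 exactly
#' where the parents disagree.
#'
#' @param parents parental `geno_matrix` with homozygous (0/2) codes and no
#'   missing values.
#' @param pedigree data.frame with columns `hybrid`, `female`, `male`.
#' @return `geno_matrix` of hybrids, same marker panel as `parents`.
#' @export
deduce_hybrid_genotypes <- function(parents, pedigree) {
  stopifnot(inherits(parents, "geno_matrix"))
  need <- c("hybrid", "female", "male")
  if (!all(need %in% names(pedigree)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  ids <- individual_ids(parents)
  miss <- setdiff(unique(c(pedigree$female, pedigree$male)), ids)
  if (length(miss))
    stop("parent(s) absent from genotype matrix: ",
         paste(head(miss, 3), collapse = ", "))
  if (anyNA(parents$codes)) stop("parental codes contain missing values; impute first")
  if (any(parents$codes == 1))
    stop("parental codes contain heterozygotes; impute_missing() must run first")
  codes <- (parents$codes[pedigree$female, , drop = FALSE] +
            parents$codes[pedigree$male, , drop = FALSE]) / 2
  rownames(codes) <- pedigree$hybrid
  geno_matrix(codes, parents$map)
}

#' VanRaden additive genomic relationship matrix
#'
#' A = W W' / (2 sum_j p_j (1 - p_j)) with W the column-centered code matrix
#' (column means 2 p_j, p_j the alternative-allele frequency).
#'
#' @param G a `geno_matrix` with no missing codes and >= 1 polymorphic
#'   marker.
#' @return symmetric matrix with attribute `flavor = "vanraden"`.
#' @export
grm_vanraden <- function(G) {
  codes <- if (inherits(G, "geno_matrix")) G$codes else as.matrix(G)
  if (anyNA(codes)) stop("missing codes; impute first")
  p <- colMeans(codes) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic; relationship matrix undefined")
  W <- sweep(codes, 2, 2 * p)
  A <- tcrossprod(W) / denom
  attr(A, "flavor") <- "vanraden"
  A
}

#' Yang et al. additive genomic relationship matrix
#'
#' Per-marker standardized relationships: off-diagonals
#' A_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i));
#' diagonals A_jj = 1 + (1/m) sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) /
#' (2 p_i (1 - p_i)). Monomorphic markers carry no information and are
#' skipped with a warning.
#'
#' @param G a `geno_matrix` with no missing codes.
#' @return symmetric matrix with attribute `flavor = "yang"`.
#' @export
grm_yang <- function(G) {
  codes <- if (inherits(G, "geno_matrix")) G$codes else as.matrix(G)
  if (anyNA(codes)) stop("missing codes; impute first")
  p <- colMeans(codes) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic; relationship matrix undefined")
  if (any(!poly)) warning(sum(!poly), " monomorphic marker(s) skipped")
  X <- codes[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(X)
  h <- 2 * p * (1 - p)
  Wo <- sweep(X, 2, 2 * p)
  Wo <- sweep(Wo, 2, sqrt(h), "/")
  A <- tcrossprod(Wo) / m
  # replace diagonal with the inbreeding-corrected form
  D <- X^2 - sweep(X, 2, 1 + 2 * p, "*")
  D <- sweep(D, 2, 2 * p^2, "+")
  diag(A) <- 1 + rowSums(sweep(D, 2, h, "/")) / m
  attr(A, "flavor") <- "yang"
  A
}

#' Additive-by-additive epistatic kernel
#'
#' Hadamard (elementwise) square of an additive relationship matrix.
#'
#' @param A additive GRM (flavor `"vanraden"` or `"yang"`).
#' @return matrix with attribute `flavor = "epistatic"`.
#' @export
epistatic_kernel <- function(A) {
  fl <- attr(A, "flavor")
  if (!is.null(fl) && fl == "epistatic")
    stop("kernel is already epistatic; pass an additive GRM")
  K <- A * A
  attr(K, "flavor") <- "epistatic"
  K
}

#' Principal components of a genotype matrix
#'
#' PCA of the column-centered code matrix, components ordered by decreasing
#' explained variance.
#'
#' @param G a `geno_matrix` or plain code matrix, no missing codes.
#' @param k number of components requested; truncated to the matrix rank
#'   with a warning if larger.
#' @return list with `scores` (n x k) and `explained` (variance fractions).
#' @export
pca_components <- function(G, k = 3) {
  codes <- if (inherits(G, "geno_matrix")) G$codes else as.matrix(G)
  if (anyNA(codes)) stop("missing codes; impute first")
  pc <- prcomp(codes, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev_frac <- ev / sum(ev)
  rank <- sum(ev > max(ev) * 1e-12)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncated")
    k <- rank
  }
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = ev_frac[seq_len(k)])
}

#' Pairwise Euclidean dissimilarity with average-linkage ordering
#'
#' @param G a `geno_matrix` or code matrix, no missing codes.
#' @return list with `dist` (full symmetric matrix), `hclust` (average
#'   linkage tree) and `order` (leaf order).
#' @export
pairwise_dissimilarity <- function(G) {
  codes <- if (inherits(G, "geno_matrix")) G$codes else as.matrix(G)
  if (anyNA(codes)) stop("missing codes; impute first")
  d <- dist(codes)
  h <- hclust(d, method = "average")
  list(dist = as.matrix(d), hclust = h, order = h$order)
}
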