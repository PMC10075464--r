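# Mixed-linear-model GWAS with a polygenic background, TA-SNP selection,
# and the effective number of TA-SNPs.

#' Fit the GWAS null model (no candidate marker)
#'
#' REML fit of y = intercept + PCs + polygenic + residual where the
#' polygenic term has covariance A sigma_a2. Principal components are the
#' leading eigenvectors of the relationship matrix (equivalent, up to
#' scaling, to PCs of the centered genotype matrix that generated it).
#'
#' @param y named numeric vector of adjusted phenotypes; names must be rows
#'   of `A`.
#' @param A genomic relationship matrix (Yang flavour by convention for
#'   GWAS).
#' @param n_pcs number of ancestry principal components as fixed covariates.
#' @return list with `sigma_a2`, `sigma_e2`, `h2`, covariate matrix `X`,
#'   eigen pieces for reuse by [gwas_scan()].
#' @export
fit_null_mlm <- function(y, A, n_pcs = 3) {
  ids <- names(y)
  if (is.null(ids) || !all(ids %in% rownames(A)))
    stop("all phenotyped ids must appear in the relationship matrix")
  A <- A[ids, ids]
  n <- length(y)
  X <- matrix(1, n, 1)
  if (n_pcs > 0) {
    ev <- eigen(A, symmetric = TRUE)
    X <- cbind(X, ev$vectors[, seq_len(min(n_pcs, n - 1)), drop = FALSE])
  }
  colnames(X) <- c("intercept", if (n_pcs > 0) paste0("PC", seq_len(ncol(X) - 1)))
  fit <- reml_single_kernel(unname(y), A, X)
  fit$X <- X
  fit$ids <- ids
  fit$A <- A
  fit
}

#' Mixed-linear-model association scan
#'
#' Per-marker generalized-least-squares effect and Wald p-value with the
#' covariance matrix fixed at the null-model variance components (single-fit
#' approximation in the EMMAX style). Intercept and ancestry PCs are always
#' included. Monomorphic markers in the analyzed subset get effect 0 and
#' p = 1, flagged in the output.
#'
#' @param y named numeric phenotype vector.
#' @param G `geno_matrix` (or code matrix) covering the phenotyped ids.
#' @param A relationship matrix for the polygenic background.
#' @param n_pcs number of ancestry PCs.
#' @param null optional pre-computed [fit_null_mlm()] result.
#' @return data.frame with columns marker, chrom, pos (when a map exists),
#'   effect, se, stat, p, monomorphic.
#' @export
gwas_scan <- function(y, G, A, n_pcs = 3, null = NULL) {
  codes <- if (inherits(G, "geno_matrix")) G$codes else as.matrix(G)
  ids <- names(y)
  if (is.null(ids) || !all(ids %in% rownames(codes)))
    stop("all phenotyped ids must be genotyped")
  if (is.null(null)) null <- fit_null_mlm(y, A, n_pcs = n_pcs)
  if (!isTRUE(null$converged)) stop("null model did not converge")
  M <- codes[ids, , drop = FALSE]
  n <- length(y)
  if (is.null(null$eig)) {  # degenerate null (constant y)
    eigA <- eigen(null$A, symmetric = TRUE)
    null$eig <- list(values = pmax(eigA$values, 0), vectors = eigA$vectors)
    null$lambda <- 0
  }
  U <- null$eig$vectors
  w <- null$lambda * null$eig$values + 1     # Var(y~) = sigma_e2 * diag(w)
  sw <- sqrt(w)
  yt <- drop(crossprod(U, unname(y))) / sw
  Xt <- crossprod(U, null$X) / sw
  Mt <- crossprod(U, M) / sw
  qrX <- qr(Xt)
  yr <- qr.resid(qrX, yt)
  Mr <- qr.resid(qrX, Mt)
  ss <- colSums(Mr^2)
  mono <- ss < n * 1e-12
  b <- se <- stat <- p <- numeric(ncol(M))
  ok <- !mono
  b[ok] <- colSums(Mr[, ok, drop = FALSE] * yr) / ss[ok]
  sigma_e2 <- null$sigma_e2
  se[ok] <- sqrt(sigma_e2 / ss[ok])
  stat[ok] <- b[ok] / se[ok]
  p[ok] <- pchisq(stat[ok]^2, df = 1, lower.tail = FALSE)
  b[mono] <- 0; se[mono] <- NA_real_; stat[mono] <- 0; p[mono] <- 1
  out <- data.frame(marker = colnames(M), effect = b, se = se, stat = stat,
                    p = p, monomorphic = mono, stringsAsFactors = FALSE)
  if (inherits(G, "geno_matrix") && !is.null(G$map)) {
    out$chrom <- G$map$chrom[match(out$marker, G$map$marker)]
    out$pos <- G$map$pos[match(out$marker, G$map$marker)]
    out <- out[c("marker", "chrom", "pos", "effect", "se", "stat", "p",
                 "monomorphic")]
  }
  out
}

#' Select trait-associated SNPs at a raw p-value threshold
#'
#' @param res a [gwas_scan()] result.
#' @param threshold raw p-value cut-off in (0, 1); markers with p <=
#'   threshold are selected. No multiple-testing correction is applied: the
#'   threshold grid is swept as-is downstream.
#' @param G optional `geno_matrix`; when given, the effective number of
#'   TA-SNPs is computed via [effective_snp_number()].
#' @return list with `markers`, `threshold`, `effective_number` (NA without
#'   `G`, 0 for an empty set).
#' @export
select_ta_snps <- function(res, threshold, G = NULL) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must be a raw p-value strictly inside (0, 1)")
  markers <- res$marker[res$p <= threshold]
  eff <- NA_integer_
  if (!is.null(G)) {
    eff <- if (length(markers) == 0) 0L
           else effective_snp_number(gm_subset(G, markers = markers))
  }
  list(markers = markers, threshold = threshold,
       effective_number = eff)
}

#' Effective number of TA-SNPs
#'
#' The smallest number of principal components of the TA-SNP code matrix
#' whose cumulative explained variance reaches 95%.
#'
#' @param G_ta `geno_matrix` (or code matrix) restricted to the TA-SNPs.
#' @param cum_var cumulative explained-variance target.
#' @return integer count.
#' @export
effective_snp_number <- function(G_ta, cum_var = 0.95) {
  codes <- if (inherits(G_ta, "geno_matrix")) G_ta$codes else as.matrix(G_ta)
  if (ncol(codes) < 1) stop("need at least one TA-SNP")
  ev <- prcomp(codes, center = TRUE, scale. = FALSE)$sdev^2
  tot <- sum(ev)
  if (tot <= 0) return(0L)
  as.integer(which(cumsum(ev) / tot >= cum_var - 1e-12)[1])
}
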