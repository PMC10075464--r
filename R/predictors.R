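# Prediction engines: mid-parental value, two-step MAS, kernel BLUP
# (GBLUP / EGBLUP / TA-partitioned) by REML or Gibbs, and BayesB / BayesR
# whole-genome regression.

#' MCMC schedule for the Bayesian fitters
#'
#' Defaults follow the common whole-genome-regression schedule of 30,000
#' sweeps, 5,000 burn-in, thinning 5.
#'
#' @param n_iter,burn_in,thin integers.
#' @return list of settings.
#' @export
mcmc_settings <- function(n_iter = 30000, burn_in = 5000, thin = 5) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
       thin = as.integer(thin))
}

#' Mid-parental value prediction
#'
#' The baseline phenotypic predictor: each hybrid is predicted by the mean
#' of its parents' BLUEs. No training occurs, so the prediction is the same
#' in every cross-validation repeat.
#'
#' @param blue named numeric vector of BLUEs.
#' @param pedigree data.frame with columns hybrid, female, male.
#' @param test_ids hybrids to predict (default all in the pedigree).
#' @return named numeric vector; `NA` where a parental BLUE is missing.
#' @export
predict_midparent <- function(blue, pedigree, test_ids = pedigree$hybrid) {
  i <- match(test_ids, pedigree$hybrid)
  if (anyNA(i)) stop("test id(s) absent from pedigree")
  f <- blue[pedigree$female[i]]
  m <- blue[pedigree$male[i]]
  setNames((unname(f) + unname(m)) / 2, test_ids)
}

#' Two-step marker-assisted selection: calibration
#'
#' Joint ordinary-least-squares fit of intercept + all TA-SNP codes; when
#' the design is rank deficient (more TA-SNPs than training individuals, or
#' collinear markers) the minimum-norm least-squares solution is used, which
#' reproduces the accuracy collapse seen at liberal thresholds without
#' failing.
#'
#' @param y_train named numeric training phenotypes.
#' @param G_ta `geno_matrix` (or code matrix) restricted to the TA-SNPs,
#'   covering the training ids.
#' @return `mas_fit` object with `mu`, `effects`, `markers`.
#' @export
fit_mas <- function(y_train, G_ta) {
  codes <- if (inherits(G_ta, "geno_matrix")) G_ta$codes else as.matrix(G_ta)
  ids <- names(y_train)
  if (ncol(codes) == 0) {
    warning("no TA-SNPs; falling back to intercept-only prediction")
    return(structure(list(mu = mean(y_train), effects = numeric(0),
                          markers = character(0)), class = "mas_fit"))
  }
  if (is.null(ids) || !all(ids %in% rownames(codes)))
    stop("all training ids must be genotyped at the TA-SNPs")
  X <- cbind(1, codes[ids, , drop = FALSE])
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  coef <- sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], unname(y_train)) / sv$d[pos])
  structure(list(mu = coef[1], effects = setNames(drop(coef[-1]), colnames(codes)),
                 markers = colnames(codes)), class = "mas_fit")
}

#' Two-step marker-assisted selection: prediction
#'
#' @param fit a [fit_mas()] result.
#' @param G_test genotypes of the individuals to predict.
#' @return named numeric predictions.
#' @export
predict_mas <- function(fit, G_test) {
  codes <- if (inherits(G_test, "geno_matrix")) G_test$codes else as.matrix(G_test)
  if (length(fit$markers) == 0)
    return(setNames(rep(fit$mu, nrow(codes)), rownames(codes)))
  if (!all(fit$markers %in% colnames(codes)))
    stop("test genotypes lack fitted TA-SNPs")
  drop(fit$mu + codes[, fit$markers, drop = FALSE] %*% fit$effects)[rownames(codes)]
}

#' Kernel BLUP (GBLUP, EGBLUP, multi-kernel variants)
#'
#' Mixed model y = X b + sum_k g_k + e with g_k ~ N(0, K_k sigma_k^2) fitted
#' on the training ids. `method = "REML"` uses average-information REML with
#' EM fallback; `method = "Gibbs"` uses an eigendecomposition-based sampler
#' (each kernel reparameterized as independent regression on its scaled
#' eigenvectors) with scaled-inverse-chi-square variance updates. Untested
#' individuals are predicted through the relationship matrix:
#' g_k(new) = sigma_k^2 K_k\[new, train\] V^-1 (y - X b) for REML, and the
#' kernel-regression of the posterior-mean training effects for Gibbs.
#'
#' @param y named numeric phenotypes covering at least the training ids.
#' @param kernels list of relationship matrices over training and test ids
#'   (a single additive GRM for GBLUP; additive + epistatic for EGBLUP;
#'   TA-SNP + remaining-SNP kernels for the random marker partition).
#' @param covariates optional numeric matrix of fixed covariates (e.g. the
#'   mid-parental value), rows named by individual; the intercept is always
#'   added.
#' @param train_ids ids used for fitting (default: names of `y`).
#' @param method `"REML"` or `"Gibbs"`.
#' @param mcmc [mcmc_settings()] for the Gibbs route.
#' @param seed RNG seed for the Gibbs route.
#' @return `kernel_blup_fit` object; see [predict.kernel_blup_fit()].
#' @export
fit_kernel_blup <- function(y, kernels, covariates = NULL,
                            train_ids = names(y),
                            method = c("REML", "Gibbs"),
                            mcmc = mcmc_settings(), seed = 1) {
  method <- match.arg(method)
  if (!is.list(kernels)) kernels <- list(kernels)
  all_ids <- rownames(kernels[[1]])
  for (K in kernels) {
    if (is.null(rownames(K)) || !identical(rownames(K), all_ids))
      stop("kernels must share identical row/column ids")
    psd_check(K)
  }
  if (!all(train_ids %in% all_ids)) stop("kernel does not cover all training ids")
  if (!all(train_ids %in% names(y))) stop("phenotypes missing for training ids")
  yt <- unname(y[train_ids])
  n <- length(yt)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates)) || !all(train_ids %in% rownames(covariates)))
      stop("covariates must be row-named and cover the training ids")
    X <- cbind(X, covariates[train_ids, , drop = FALSE])
  }
  Ktt <- lapply(kernels, function(K) K[train_ids, train_ids])
  fit <- if (method == "REML" && length(Ktt) == 1) {
    # single kernel: robust 1-D profile REML via eigen rotation
    r <- suppressWarnings(reml_single_kernel(yt, Ktt[[1]], X))
    if (isTRUE(r$degenerate)) {
      list(varcomp = c(0, r$sigma_e2),
           beta = c(mean(yt), rep(0, ncol(X) - 1)), Py = rep(0, n),
           loglik = NA_real_, g_train = NULL)
    } else {
      w <- r$sigma_a2 * r$eig$values + r$sigma_e2
      resid <- yt - drop(X %*% r$beta)
      Py <- drop(r$eig$vectors %*% (crossprod(r$eig$vectors, resid) / w))
      list(varcomp = c(r$sigma_a2, r$sigma_e2), beta = r$beta, Py = Py,
           loglik = r$loglik, g_train = NULL)
    }
  } else if (method == "REML") {
    r <- reml_multi_kernel(yt, Ktt, X)
    list(varcomp = r$varcomp, beta = r$beta, Py = r$Py, loglik = r$loglik,
         g_train = NULL)
  } else {
    rkhs_gibbs(yt, Ktt, X, mcmc = mcmc, seed = seed)
  }
  structure(list(method = method, kernels = kernels, train_ids = train_ids,
                 covariates = covariates, varcomp = fit$varcomp,
                 beta = fit$beta, Py = fit$Py, g_train = fit$g_train,
                 loglik = fit$loglik,
                 flavors = vapply(kernels, function(K) {
                   f <- attr(K, "flavor"); if (is.null(f)) "kernel" else f
                 }, "")),
            class = "kernel_blup_fit")
}

#' Predict from a kernel BLUP fit
#'
#' @param object a [fit_kernel_blup()] result.
#' @param ids individuals to predict; must be rows of every kernel.
#' @param ... unused.
#' @return named numeric predictions (intercept + covariates + summed
#'   kernel effects).
#' @export
predict.kernel_blup_fit <- function(object, ids, ...) {
  all_ids <- rownames(object$kernels[[1]])
  if (!all(ids %in% all_ids)) stop("id(s) outside the kernel")
  nk <- length(object$kernels)
  pred <- rep(object$beta[1], length(ids))
  if (!is.null(object$covariates)) {
    if (!all(ids %in% rownames(object$covariates)))
      stop("covariate values missing for some prediction ids")
    pred <- pred + drop(object$covariates[ids, , drop = FALSE] %*%
                          object$beta[-1])
  }
  tr <- object$train_ids
  for (k in seq_len(nk)) {
    Kst <- object$kernels[[k]][ids, tr, drop = FALSE]
    if (object$method == "REML") {
      pred <- pred + object$varcomp[k] * drop(Kst %*% object$Py)
    } else {
      gk <- object$g_train[, k]
      Ktt <- object$kernels[[k]][tr, tr]
      sol <- solve(Ktt + diag(1e-8 * mean(diag(Ktt)) + 1e-12, nrow(Ktt)), gk)
      pred <- pred + drop(Kst %*% sol)
    }
  }
  setNames(pred, ids)
}

# jitter-then-error positive-semidefiniteness guard (cached per kernel)
psd_check <- function(K, tol = 1e-8) {
  if (isTRUE(attr(K, "psd_ok"))) return(invisible(TRUE))
  jit <- tol * max(1, mean(diag(K)))
  ok <- !inherits(tryCatch(chol(K + diag(jit, nrow(K))),
                           error = function(e) e), "error")
  if (!ok)
    stop("kernel is not positive semidefinite beyond tolerance ", tol)
  invisible(TRUE)
}

# Eigen-based Gibbs sampler for the multi-kernel model. Each kernel K = U D U'
# is rewritten as g = B u with B = U D^{1/2}, u ~ N(0, I sigma_k2), making
# B'B diagonal so the coordinate update is cheap.
rkhs_gibbs <- function(yt, Ktt, X, mcmc, seed, df0 = 4) {
  set.seed(as.integer(seed))
  n <- length(yt)
  nk <- length(Ktt)
  p <- ncol(X)
  basis <- lapply(Ktt, function(K) {
    e <- eigen(K, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-10
    list(B = e$vectors[, keep, drop = FALSE] %*%
           diag(sqrt(e$values[keep]), sum(keep)),
         d = e$values[keep])
  })
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX + diag(1e-10, p))
  vy <- var(yt)
  sk2 <- rep(vy / (nk + 1), nk)
  se2 <- vy / 2
  S0k <- sk2; S0e <- se2
  u <- lapply(basis, function(b) rep(0, length(b$d)))
  beta <- drop(XtX_inv %*% crossprod(X, yt))
  e <- yt - drop(X %*% beta)
  keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  acc_beta <- rep(0, p); acc_g <- matrix(0, n, nk)
  acc_s <- rep(0, nk + 1); n_samp <- 0
  for (it in seq_len(mcmc$n_iter)) {
    # fixed effects (flat prior)
    r <- e + drop(X %*% beta)
    bhat <- drop(XtX_inv %*% crossprod(X, r))
    beta <- bhat + drop(chol(XtX_inv * se2) %*% rnorm(p))
    e <- r - drop(X %*% beta)
    for (k in seq_len(nk)) {
      B <- basis[[k]]$B; d <- basis[[k]]$d
      r <- e + drop(B %*% u[[k]])
      prec <- d / se2 + 1 / sk2[k]
      mu_u <- (drop(crossprod(B, r)) / se2) / prec
      u[[k]] <- mu_u + rnorm(length(d)) / sqrt(prec)
      e <- r - drop(B %*% u[[k]])
      q <- length(d)
      sk2[k] <- (sum(u[[k]]^2) + df0 * S0k[k]) / rchisq(1, df0 + q)
    }
    se2 <- (sum(e^2) + df0 * S0e) / rchisq(1, df0 + n)
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0) {
      n_samp <- n_samp + 1
      acc_beta <- acc_beta + beta
      for (k in seq_len(nk)) acc_g[, k] <- acc_g[, k] + drop(basis[[k]]$B %*% u[[k]])
      acc_s <- acc_s + c(sk2, se2)
    }
  }
  list(varcomp = acc_s / n_samp, beta = acc_beta / n_samp,
       Py = NULL, g_train = acc_g / n_samp, loglik = NA_real_)
}

# shared prep for the marker samplers
marker_sampler_prep <- function(y_train, G_train, W) {
  codes <- if (inherits(G_train, "geno_matrix")) G_train$codes else as.matrix(G_train)
  ids <- names(y_train)
  if (is.null(ids) || !all(ids %in% rownames(codes)))
    stop("all training ids must be genotyped")
  X <- codes[ids, , drop = FALSE]
  Wv <- NULL
  if (!is.null(W)) {
    if (is.null(names(W)) || !all(ids %in% names(W)))
      stop("covariate must be named and cover the training ids")
    Wv <- unname(W[ids])
  }
  list(y = unname(y_train), X = X, W = Wv)
}

#' BayesB whole-genome regression
#'
#' Spike-and-slab prior on marker effects: a point mass at zero with
#' probability 1 - pi and a scaled-t slab (marker-specific
#' scaled-inverse-chi-square variances) with fixed probability `pi`. Fitted
#' by single-site Gibbs sampling; the chain is seeded and reproducible.
#'
#' @param y_train named numeric training phenotypes.
#' @param G_train training genotypes (no missing codes).
#' @param W optional named covariate vector (mid-parental values), covering
#'   training ids; test values are supplied at prediction time.
#' @param mcmc [mcmc_settings()].
#' @param pi slab (inclusion) probability, fixed.
#' @param df_slab slab degrees of freedom.
#' @param r2 prior fraction of phenotypic variance attributed to markers,
#'   used to set the slab scale.
#' @param seed RNG seed.
#' @return `marker_fit` object with posterior means (`mu`, `beta`, `gamma`,
#'   `pip`, `sigma_e2`).
#' @export
fit_bayesB <- function(y_train, G_train, W = NULL, mcmc = mcmc_settings(),
                       pi = 0.05, df_slab = 4, r2 = 0.5, seed = 1) {
  stopifnot(pi >= 0, pi < 1)
  d <- marker_sampler_prep(y_train, G_train, W)
  vy <- var(d$y)
  sum_vx <- sum(apply(d$X, 2, var))
  scale_slab <- if (pi > 0 && sum_vx > 0)
    vy * r2 * (df_slab - 2) / (df_slab * pi * sum_vx) else vy * 1e-4
  set.seed(as.integer(seed))
  res <- bayesB_gibbs(d$y, d$X, d$W, mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                      pi, df_slab, scale_slab, 4, vy / 2)
  structure(list(model = "BayesB", mu = res$mu, beta = res$beta,
                 gamma = setNames(res$gamma, colnames(d$X)),
                 pip = setNames(res$pip, colnames(d$X)),
                 sigma_e2 = res$sigma_e2, genetic_var = res$genetic_var,
                 has_covariate = !is.null(W), mcmc = mcmc, seed = seed),
            class = "marker_fit")
}

#' BayesR whole-genome regression
#'
#' Marker effects follow a four-component normal mixture with zero means
#' and variances `cvar * sigma_g2` (first component the point mass at zero);
#' mixture proportions get a Dirichlet(1,1,1,1) update and sum to one, and
#' sigma_g2 is updated each sweep by a scaled-inverse-chi-square draw.
#'
#' @inheritParams fit_bayesB
#' @param cvar relative component variances.
#' @param pi_init starting mixture proportions (length 4, sums to 1).
#' @param update_pi set `FALSE` to hold the proportions fixed at `pi_init`.
#' @return `marker_fit` object (adds posterior `pi`, `sigma_g2`).
#' @export
fit_bayesR <- function(y_train, G_train, W = NULL, mcmc = mcmc_settings(),
                       cvar = c(0, 1e-4, 1e-3, 1e-2),
                       pi_init = c(0.5, 0.3, 0.15, 0.05), update_pi = TRUE,
                       r2 = 0.5, seed = 1) {
  stopifnot(length(cvar) == length(pi_init),
            abs(sum(pi_init) - 1) < 1e-8, all(pi_init >= 0))
  d <- marker_sampler_prep(y_train, G_train, W)
  vy <- var(d$y)
  sum_vx <- sum(apply(d$X, 2, var))
  cmax <- max(cvar)
  sigma_g2_init <- if (cmax > 0 && sum_vx > 0) vy * r2 / (cmax * sum_vx) else vy
  set.seed(as.integer(seed))
  res <- bayesR_gibbs(d$y, d$X, d$W, mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                      cvar, pi_init, update_pi, sigma_g2_init, 4, 4, vy / 2)
  structure(list(model = "BayesR", mu = res$mu, beta = res$beta,
                 gamma = setNames(res$gamma, colnames(d$X)),
                 pi = res$pi, sigma_e2 = res$sigma_e2,
                 sigma_g2 = res$sigma_g2,
                 has_covariate = !is.null(W), mcmc = mcmc, seed = seed),
            class = "marker_fit")
}

#' Predict from a marker-effect fit (MAS, BayesB, BayesR)
#'
#' @param object a `marker_fit`.
#' @param G_test genotypes of the individuals to predict.
#' @param W_test named covariate values when the fit used one.
#' @param ... unused.
#' @return named numeric predictions.
#' @export
predict.marker_fit <- function(object, G_test, W_test = NULL, ...) {
  codes <- if (inherits(G_test, "geno_matrix")) G_test$codes else as.matrix(G_test)
  mk <- names(object$gamma)
  if (!all(mk %in% colnames(codes))) stop("test genotypes lack fitted markers")
  pred <- object$mu + drop(codes[, mk, drop = FALSE] %*% object$gamma)
  if (isTRUE(object$has_covariate)) {
    if (is.null(W_test) || !all(rownames(codes) %in% names(W_test)))
      stop("fit used a covariate; supply W_test for all prediction ids")
    pred <- pred + object$beta * unname(W_test[rownames(codes)])
  }
  setNames(pred, rownames(codes))
}

#' GBLUP with TA-SNPs as fixed-effect principal components
#'
#' The principal components of the TA-SNP code matrix explaining at least
#' 95% of its variance enter as fixed covariates (computed over training and
#' test individuals jointly, so test covariate values exist), while the
#' remaining markers form the single random kernel. TA-SNPs are excluded
#' from the kernel to avoid double counting.
#'
#' @param y named numeric phenotypes.
#' @param G `geno_matrix` over all individuals involved.
#' @param ta_markers character vector of TA-SNP ids (possibly empty).
#' @param train_ids training ids.
#' @param method,mcmc,seed passed to [fit_kernel_blup()].
#' @param cum_var cumulative-variance target for the PC count.
#' @return `kernel_blup_fit`; attribute `"n_ta_pcs"` holds the PC count.
#' @export
fit_gblup_ta_fixed <- function(y, G, ta_markers, train_ids = names(y),
                               method = "REML", mcmc = mcmc_settings(),
                               seed = 1, cum_var = 0.95) {
  stopifnot(inherits(G, "geno_matrix"))
  ta_markers <- intersect(ta_markers, marker_ids(G))
  rest <- setdiff(marker_ids(G), ta_markers)
  if (length(ta_markers) == 0) {
    warning("empty TA-SNP set; fitting plain GBLUP")
    K <- grm_vanraden(G)
    fit <- fit_kernel_blup(y, list(K), train_ids = train_ids,
                           method = method, mcmc = mcmc, seed = seed)
    attr(fit, "n_ta_pcs") <- 0L
    return(fit)
  }
  if (length(rest) < 2)
    stop("fewer than two markers left outside the TA set; kernel undefined")
  Gta <- gm_subset(G, markers = ta_markers)
  k <- effective_snp_number(Gta, cum_var = cum_var)
  pcs <- pca_components(Gta, k = k)$scores
  colnames(pcs) <- paste0("TA_PC", seq_len(ncol(pcs)))
  K <- grm_vanraden(gm_subset(G, markers = rest))
  fit <- fit_kernel_blup(y, list(K), covariates = pcs, train_ids = train_ids,
                         method = method, mcmc = mcmc, seed = seed)
  attr(fit, "n_ta_pcs") <- as.integer(k)
  fit
}

#' Estimate genomic heritability in a population
#'
#' Fits a single-kernel GBLUP by REML and returns
#' sigma_a^2 / (sigma_a^2 + sigma_e^2). The kernel is normalized to unit
#' mean diagonal before fitting so that sigma_a^2 is on the scale of the
#' realized genetic variance; without this, heritability from a VanRaden
#' GRM over fully inbred lines (mean diagonal near 2) is structurally
#' attenuated regardless of the estimator. Normalization leaves BLUP
#' predictions unchanged.
#'
#' @param y named numeric phenotypes (BLUEs).
#' @param G `geno_matrix` covering the phenotyped ids, or a precomputed
#'   GRM.
#' @return list with `h2`, `sigma_a2`, `sigma_e2` (normalized-kernel
#'   scale).
#' @export
estimate_genomic_h2 <- function(y, G) {
  A <- if (inherits(G, "geno_matrix"))
    grm_vanraden(gm_subset(G, individuals = names(y))) else G
  A <- A[names(y), names(y)]
  A <- A / mean(diag(A))
  fit <- fit_kernel_blup(y, list(A), train_ids = names(y))
  list(h2 = genomic_heritability(fit$varcomp[1], fit$varcomp[2]),
       sigma_a2 = fit$varcomp[1], sigma_e2 = fit$varcomp[2])
}

#' Genomic heritability from GBLUP variance components
#'
#' h_g^2 = sigma_a^2 / (sigma_a^2 + sigma_e^2).
#'
#' @param sigma_a2 additive variance component (or a list with elements
#'   `sigma_a2` and `sigma_e2`).
#' @param sigma_e2 residual variance component.
#' @return heritability in \[0, 1\].
#' @export
genomic_heritability <- function(sigma_a2, sigma_e2 = NULL) {
  if (is.list(sigma_a2)) {
    sigma_e2 <- sigma_a2$sigma_e2
    sigma_a2 <- sigma_a2$sigma_a2
  }
  stopifnot(sigma_a2 >= 0, sigma_e2 >= 0)
  if (sigma_a2 + sigma_e2 == 0)
    stop("both variance components are zero; heritability undefined")
  sigma_a2 / (sigma_a2 + sigma_e2)
}
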