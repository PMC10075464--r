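test_that("mid-parental prediction is the parents' mean BLUE", {
  blue <- c(f = 1, m1 = 3, m2 = 5, h1 = 9, h2 = 9)
  ped <- data.frame(hybrid = c("h1", "h2"), female = "f",
                    male = c("m1", "m2"), stringsAsFactors = FALSE)
  expect_equal(predict_midparent(blue, ped), c(h1 = 2, h2 = 3))
  expect_equal(predict_midparent(blue, ped, "h2"), c(h2 = 3))
  expect_error(predict_midparent(blue, ped, "h9"), "absent")
})

test_that("MAS recovers a noiseless linear trait and handles redundancy", {
  set.seed(2)
  x <- sample(c(0, 1, 2), 40, replace = TRUE)
  G <- fx_geno(cbind(snp = x))
  y <- setNames(2 + 0.5 * x, rownames(G$codes))
  fit <- fit_mas(y[1:30], gm_subset(G, individuals = names(y)[1:30]))
  expect_equal(fit$mu, 2, tolerance = 1e-8)
  expect_equal(unname(fit$effects), 0.5, tolerance = 1e-8)
  pred <- predict_mas(fit, gm_subset(G, individuals = names(y)[31:40]))
  expect_equal(pred, y[31:40], tolerance = 1e-8)
  # duplicated column leaves fitted values unchanged
  G2 <- fx_geno(cbind(snp = x, snp_dup = x))
  fit2 <- fit_mas(y[1:30], gm_subset(G2, individuals = names(y)[1:30]))
  expect_equal(predict_mas(fit2, gm_subset(G2, individuals = names(y)[31:40])),
               pred, tolerance = 1e-8)
})

test_that("rank-deficient MAS equals a pseudo-inverse oracle", {
  set.seed(3)
  codes <- matrix(sample(c(0, 1, 2), 60 * 30, replace = TRUE), 60, 30)
  G <- fx_geno(codes)
  codes <- G$codes  # fx_geno assigned row/column names
  y <- setNames(rnorm(60), rownames(codes))
  tr_ids <- rownames(codes)[1:50]
  te_ids <- rownames(codes)[51:60]
  fit <- fit_mas(y[tr_ids], gm_subset(G, individuals = tr_ids))
  pred <- predict_mas(fit, gm_subset(G, individuals = te_ids))
  # oracle: min-norm coefficients through the eigen route X'(XX')^+ y
  X <- cbind(1, codes[1:50, ])
  e <- eigen(tcrossprod(X), symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  XXp <- e$vectors[, pos] %*% diag(1 / e$values[pos]) %*% t(e$vectors[, pos])
  coef <- drop(crossprod(X, XXp %*% unname(y[tr_ids])))
  oracle <- drop(cbind(1, codes[51:60, ]) %*% coef)
  expect_equal(unname(pred), unname(oracle), tolerance = 1e-6)
  # zero TA-SNPs -> intercept-only with warning
  expect_warning(f0 <- fit_mas(y[tr_ids], codes[tr_ids, 0, drop = FALSE]),
                 "intercept-only")
  expect_equal(unname(predict_mas(f0, gm_subset(G, individuals = te_ids))),
               rep(mean(y[tr_ids]), 10))
})

test_that("kernel BLUP shrinks monotonically with noise and shifts with y", {
  # a panel large enough (and with LD) for REML to separate the components
  G <- simulate_parents(250, 300, ld_decay = 0.6, seed = 18)
  ids <- individual_ids(G)
  A <- grm_vanraden(G)
  set.seed(19)
  qtl <- sample(300, 50)
  g <- drop((G$codes[, qtl] - 1) %*% rnorm(50, 0, 0.3))
  train <- ids[1:200]; test <- ids[201:250]
  eps <- rnorm(250)
  ratio <- vapply(c(0.3, 1, 3, 10), function(sn) {
    y <- setNames(g + sd(g) * sn * eps, ids)
    fit <- fit_kernel_blup(y, list(A), train_ids = train)
    sd(predict(fit, test)) / sd(y[test])
  }, 0)
  # fitted dispersion regresses toward the mean as noise grows (tiny
  # epsilon tolerates float jitter once shrinkage is numerically total)
  expect_true(all(diff(ratio) <= 1e-4))
  expect_lt(ratio[4], 0.05)   # near-total shrinkage under pure noise
  # adding a constant shifts predictions by that constant
  y1 <- setNames(g + sd(g) * eps, ids)
  f1 <- fit_kernel_blup(y1, list(A), train_ids = train)
  f2 <- fit_kernel_blup(y1 + 3, list(A), train_ids = train)
  expect_equal(predict(f2, test), predict(f1, test) + 3, tolerance = 1e-6)
})

test_that("a saturated mid-parent covariate absorbs the signal", {
  tr <- fx_trial()
  d <- tr$data
  hyb <- d$hybrid_ids
  W <- matrix(d$blue[hyb], ncol = 1, dimnames = list(hyb, "w"))
  train <- hyb[1:40]; test <- hyb[41:59]
  fit <- fit_kernel_blup(d$blue[hyb], list(d$K_add), covariates = W,
                         train_ids = train)
  expect_equal(unname(fit$beta[2]), 1, tolerance = 1e-3)
  expect_equal(unname(predict(fit, test)), unname(W[test, 1]),
               tolerance = 1e-3)
})

test_that("Gibbs and REML GBLUP agree on test predictions", {
  tr <- fx_trial()
  d <- tr$data
  hyb <- d$hybrid_ids
  train <- hyb[1:45]; test <- hyb[46:59]
  y <- d$blue[hyb]
  fr <- fit_kernel_blup(y, list(d$K_add), train_ids = train, method = "REML")
  fg <- fit_kernel_blup(y, list(d$K_add), train_ids = train, method = "Gibbs",
                        mcmc = mcmc_settings(6000, 1000, 5), seed = 4)
  expect_gt(cor(predict(fr, test), predict(fg, test)), 0.98)
})

test_that("BayesB degenerates correctly and finds a planted QTL", {
  tr <- fx_trial()
  ids <- individual_ids(tr$parents)
  y <- tr$blue[ids]
  f0 <- fit_bayesB(y, tr$parents, mcmc = mcmc_settings(300, 100, 2), pi = 0)
  expect_true(all(f0$gamma == 0))
  p0 <- predict(f0, tr$parents)
  expect_lt(sd(p0), 1e-8)
  hits <- vapply(1:5, function(s) {
    G <- simulate_parents(200, 400, seed = 600 + s)
    set.seed(700 + s)
    x <- G$codes[, 200]
    vg <- var(x)
    yq <- setNames(x + rnorm(200, 0, sqrt(vg)), individual_ids(G))  # h2 ~ 0.5
    fit <- fit_bayesB(yq, G, mcmc = mcmc_settings(1500, 500, 2), seed = s)
    which.max(fit$pip) == 200
  }, TRUE)
  expect_gte(sum(hits), 4)
})

test_that("independent BayesB chains agree on predictions", {
  tr <- fx_trial()
  ids <- individual_ids(tr$parents)
  train <- ids[1:45]
  y <- tr$blue[train]
  f1 <- fit_bayesB(y, tr$parents, mcmc = mcmc_settings(4000, 1000, 2), seed = 1)
  f2 <- fit_bayesB(y, tr$parents, mcmc = mcmc_settings(4000, 1000, 2), seed = 99)
  test <- ids[46:60]
  Gt <- gm_subset(tr$parents, individuals = test)
  expect_gt(cor(predict(f1, Gt), predict(f2, Gt)), 0.98)
  # same seed is bit-reproducible
  f1b <- fit_bayesB(y, tr$parents, mcmc = mcmc_settings(4000, 1000, 2), seed = 1)
  expect_identical(f1$gamma, f1b$gamma)
})

test_that("BayesR mixture behaves across its limiting cases", {
  tr <- fx_trial()
  ids <- individual_ids(tr$parents)
  y <- tr$blue[ids]
  fnull <- fit_bayesR(y, tr$parents, mcmc = mcmc_settings(300, 100, 2),
                      pi_init = c(1, 0, 0, 0), update_pi = FALSE)
  expect_true(all(fnull$gamma == 0))
  # single active component approaches the GBLUP/ridge solution
  train <- ids[1:45]; test <- ids[46:60]
  fr <- fit_kernel_blup(y, list(tr$data$K_add), train_ids = train)
  fone <- fit_bayesR(y[train], tr$parents,
                     mcmc = mcmc_settings(8000, 2000, 2),
                     pi_init = c(0, 0, 0, 1), update_pi = FALSE, seed = 2)
  pr <- predict(fr, test)
  pb <- predict(fone, gm_subset(tr$parents, individuals = test))
  expect_gt(cor(pr, pb[test]), 0.98)
  # posterior mixture proportions live on the simplex
  ffree <- fit_bayesR(y, tr$parents, mcmc = mcmc_settings(500, 100, 2), seed = 3)
  expect_equal(sum(ffree$pi), 1, tolerance = 1e-9)
})

test_that("TA-SNPs as fixed PCs reduce and saturate as expected", {
  tr <- fx_trial()
  d <- tr$data
  hyb <- d$hybrid_ids
  y <- d$blue[hyb]
  train <- hyb[1:45]; test <- hyb[46:59]
  expect_warning(
    f_empty <- fit_gblup_ta_fixed(y, d$geno, character(0), train_ids = train),
    "empty TA-SNP")
  f_plain <- fit_kernel_blup(y, list(grm_vanraden(d$geno)), train_ids = train)
  expect_equal(predict(f_empty, test), predict(f_plain, test),
               tolerance = 1e-8)
  ta <- marker_ids(d$geno)[1:25]
  f_ta <- fit_gblup_ta_fixed(y, d$geno, ta, train_ids = train)
  expect_equal(attr(f_ta, "n_ta_pcs"),
               effective_snp_number(gm_subset(d$geno, markers = ta)))
})

test_that("genomic heritability follows the variance-component ratio", {
  expect_equal(round(genomic_heritability(1.22, 0.30), 2), 0.80)
  expect_equal(round(genomic_heritability(1.70, 1.21), 2), 0.58)
  expect_equal(genomic_heritability(0, 1), 0)
  expect_error(genomic_heritability(0, 0), "undefined")
})
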