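# Training-set scenario composition, repeated k-fold cross-validation,
# accuracy, Fisher-z statistics, ANOVA, and training-set subsampling curves.

#' Bundle the inputs a cross-validation run needs
#'
#' Stacks parental and hybrid genotypes, precomputes the additive
#' (VanRaden) and epistatic kernels over all individuals, and the
#' mid-parental values used by the covariate scenario.
#'
#' @param parents,hybrids `geno_matrix` objects on the same marker panel.
#' @param pedigree data.frame hybrid / female / male.
#' @param blue named numeric BLUEs for all lines and hybrids.
#' @return list of class `cv_data`.
#' @export
cv_data <- function(parents, hybrids, pedigree, blue) {
  geno <- gm_rbind(parents, hybrids)
  ids <- individual_ids(geno)
  miss <- setdiff(ids, names(blue))
  if (length(miss)) stop("BLUEs missing for ", length(miss), " individual(s)")
  K_add <- grm_vanraden(geno)
  rownames(K_add) <- colnames(K_add) <- ids
  K_epi <- epistatic_kernel(K_add)
  psd_check(K_add); psd_check(K_epi)
  attr(K_add, "psd_ok") <- TRUE
  attr(K_epi, "psd_ok") <- TRUE
  structure(list(parents = parents, hybrids = hybrids, geno = geno,
                 pedigree = pedigree, blue = blue,
                 line_ids = individual_ids(parents),
                 hybrid_ids = pedigree$hybrid,
                 K_add = K_add, K_epi = K_epi,
                 midparent = predict_midparent(blue, pedigree)),
            class = "cv_data")
}

#' Model specification for the CV engine
#'
#' @param model one of `"MPV"`, `"MAS"`, `"GBLUP"`, `"EGBLUP"`, `"BayesB"`,
#'   `"BayesR"`, `"GBLUP_TA_fixed"`, `"GBLUP_TA_random"`.
#' @param method `"REML"` or `"Gibbs"` for the kernel models.
#' @param threshold raw GWAS p-value threshold (MAS).
#' @param n_pcs ancestry PCs in the MAS GWAS.
#' @param mcmc [mcmc_settings()] for Bayesian / Gibbs fits.
#' @param ta_markers TA-SNP ids for the marker-partition models.
#' @param ... extra model arguments kept verbatim.
#' @return list of class `gp_model`.
#' @export
gp_model <- function(model = c("GBLUP", "EGBLUP", "MAS", "MPV", "BayesB",
                               "BayesR", "GBLUP_TA_fixed", "GBLUP_TA_random"),
                     method = "REML", threshold = NULL, n_pcs = 3,
                     mcmc = mcmc_settings(), ta_markers = NULL, ...) {
  model <- match.arg(model)
  if (model == "MAS" && is.null(threshold))
    stop("MAS needs a GWAS p-value threshold")
  if (model %in% c("GBLUP_TA_fixed", "GBLUP_TA_random") && is.null(ta_markers))
    stop(model, " needs the TA-SNP id set (run the GWAS upfront)")
  structure(list(model = model, method = method, threshold = threshold,
                 n_pcs = n_pcs, mcmc = mcmc, ta_markers = ta_markers, ...),
            class = "gp_model")
}

#' Stochastic even k-fold split
#'
#' @param ids individuals to split.
#' @param k number of folds (>= 2, <= length(ids)).
#' @param seed integer seed.
#' @return integer fold assignment named by id; fold sizes differ by at
#'   most one.
#' @export
make_folds <- function(ids, k = 5, seed = 1) {
  n <- length(ids)
  if (k < 2 || k > n) stop("k must be in [2, number of ids]")
  set.seed(as.integer(seed))
  setNames(sample(rep_len(seq_len(k), n)), ids)
}

#' Compose the training set for a scenario
#'
#' Scenario tags follow the half-sib design: S1 parents of the reference
#' hybrids; S2 the reference hybrids; S3 reference hybrids and their
#' parents; S4 reference hybrids and all lines; S5 reference hybrids and
#' the parents of the test hybrids; S2_MPVcov is S2 with the mid-parental
#' value of every hybrid as a fixed covariate. The shared female line is
#' counted once in every parent set. `subsample_rate` (percent) thins the
#' reference hybrids before composition (the training-set-size study); in
#' S1 the parents of the sampled reference hybrids form the training set.
#'
#' @param scenario one of "S1".."S5", "S2_MPVcov".
#' @param test_ids hybrids of the held-out fold.
#' @param pedigree data.frame hybrid / female / male.
#' @param all_line_ids ids of all parental lines.
#' @param subsample_rate percent of reference hybrids retained (0 < rate <=
#'   100).
#' @param subsample_seed seed for the thinning draw.
#' @return list with `train_ids` (disjoint from `test_ids`) and `covariate`
#'   (`"midparent"` or `NULL`).
#' @export
compose_training_set <- function(scenario, test_ids, pedigree, all_line_ids,
                                 subsample_rate = 100, subsample_seed = NULL) {
  scenario <- match.arg(scenario, c("S1", "S2", "S3", "S4", "S5", "S2_MPVcov"))
  if (!all(test_ids %in% pedigree$hybrid)) stop("test ids must be hybrids")
  if (subsample_rate <= 0 || subsample_rate > 100)
    stop("subsample_rate must be in (0, 100]")
  ref <- setdiff(pedigree$hybrid, test_ids)
  if (subsample_rate < 100) {
    if (is.null(subsample_seed)) stop("subsampling needs a seed")
    set.seed(as.integer(subsample_seed))
    ref <- sort(sample(ref, max(1, floor(subsample_rate / 100 * length(ref)))))
  }
  female <- unique(pedigree$female)
  male_of <- function(h) pedigree$male[match(h, pedigree$hybrid)]
  train <- switch(scenario,
    S1 = c(female, male_of(ref)),
    S2 = ref,
    S3 = c(ref, female, male_of(ref)),
    S4 = c(ref, all_line_ids),
    S5 = c(ref, female, male_of(test_ids)),
    S2_MPVcov = ref)
  train <- unique(train)
  stopifnot(length(intersect(train, test_ids)) == 0)
  list(train_ids = train,
       covariate = if (scenario == "S2_MPVcov") "midparent" else NULL)
}

#' Prediction accuracy over combined test folds
#'
#' Pearson correlation between predicted and observed (adjusted) values.
#'
#' @param predicted,observed named numeric vectors; matched by name when
#'   names are present.
#' @return correlation, or `NA` with attribute `undefined = TRUE` when
#'   either vector is constant.
#' @export
accuracy <- function(predicted, observed) {
  if (!is.null(names(predicted)) && !is.null(names(observed)))
    observed <- observed[names(predicted)]
  ok <- is.finite(predicted) & is.finite(observed)
  if (sum(ok) < 3) stop("need at least 3 prediction/observation pairs")
  if (sd(predicted[ok]) < 1e-12 || sd(observed[ok]) < 1e-12) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cor(predicted[ok], observed[ok])
}

#' Fisher z-transform of a correlation
#'
#' @param r correlation(s) in \[-1, 1\].
#' @return atanh(r); infinite (with a warning) at |r| = 1.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  if (any(abs(r) == 1, na.rm = TRUE)) warning("|r| = 1 transforms to infinity")
  atanh(r)
}

#' Compare two accuracy groups on the Fisher-z scale
#'
#' Two-sample Welch t-test on z-transformed repeat accuracies.
#'
#' @param a,b numeric vectors of accuracies.
#' @param alpha significance level.
#' @return list with `t`, `df`, `p`, `significant`, group z-means.
#' @export
compare_accuracies <- function(a, b, alpha = 0.05) {
  tt <- stats::t.test(fisher_z(a), fisher_z(b))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha,
       mean_z = c(mean(fisher_z(a)), mean(fisher_z(b))))
}

#' Two-way ANOVA of z-transformed accuracies
#'
#' Fits z ~ factor1 * factor2 and reports Df, Sum Sq, Mean Sq, F and p per
#' term (the S6/S7-style table).
#'
#' @param results data.frame of per-repeat accuracies.
#' @param factors length-2 character vector naming the factor columns.
#' @param response name of the accuracy column.
#' @return data.frame ANOVA table.
#' @export
anova_two_way <- function(results, factors = c("scenario", "threshold"),
                          response = "accuracy") {
  stopifnot(all(c(factors, response) %in% names(results)))
  d <- data.frame(z = fisher_z(results[[response]]),
                  f1 = factor(results[[factors[1]]]),
                  f2 = factor(results[[factors[2]]]))
  fit <- aov(z ~ f1 * f2, data = d)
  tab <- summary(fit)[[1]]
  out <- data.frame(term = c(factors, paste(factors, collapse = ":"),
                             "Residuals")[seq_len(nrow(tab))],
                    Df = tab$Df, SS = tab$`Sum Sq`, MS = tab$`Mean Sq`,
                    F = tab$`F value`, p = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# fit the requested model on one composed training set and predict test ids
fit_predict_fold <- function(spec, data, train_ids, test_ids,
                             use_covariate = FALSE, seed = 1) {
  blue <- data$blue
  W <- if (use_covariate) data$midparent else NULL
  switch(spec$model,
    MPV = predict_midparent(blue, data$pedigree, test_ids),
    MAS = {
      Gtr <- gm_subset(data$geno, individuals = train_ids)
      A <- grm_yang(Gtr)
      rownames(A) <- colnames(A) <- train_ids
      res <- gwas_scan(blue[train_ids], Gtr, A, n_pcs = spec$n_pcs)
      ta <- select_ta_snps(res, spec$threshold)
      fit <- if (length(ta$markers) == 0) fit_mas(blue[train_ids],
                                                  data$geno$codes[train_ids, 0])
             else fit_mas(blue[train_ids],
                          gm_subset(data$geno, individuals = train_ids,
                                    markers = ta$markers))
      predict_mas(fit, gm_subset(data$geno, individuals = test_ids))
    },
    GBLUP = {
      fit <- fit_kernel_blup(blue, list(data$K_add),
                             covariates = if (use_covariate)
                               matrix(W, ncol = 1,
                                      dimnames = list(names(W), "mpv")),
                             train_ids = train_ids, method = spec$method,
                             mcmc = spec$mcmc, seed = seed)
      predict(fit, test_ids)
    },
    EGBLUP = {
      fit <- fit_kernel_blup(blue, list(data$K_add, data$K_epi),
                             covariates = if (use_covariate)
                               matrix(W, ncol = 1,
                                      dimnames = list(names(W), "mpv")),
                             train_ids = train_ids, method = spec$method,
                             mcmc = spec$mcmc, seed = seed)
      predict(fit, test_ids)
    },
    BayesB = {
      fit <- fit_bayesB(blue[train_ids],
                        gm_subset(data$geno, individuals = train_ids),
                        W = W, mcmc = spec$mcmc, seed = seed)
      predict(fit, gm_subset(data$geno, individuals = test_ids),
              W_test = W)
    },
    BayesR = {
      fit <- fit_bayesR(blue[train_ids],
                        gm_subset(data$geno, individuals = train_ids),
                        W = W, mcmc = spec$mcmc, seed = seed)
      predict(fit, gm_subset(data$geno, individuals = test_ids),
              W_test = W)
    },
    GBLUP_TA_fixed = {
      fit <- fit_gblup_ta_fixed(blue, data$geno, spec$ta_markers,
                                train_ids = train_ids, method = spec$method,
                                mcmc = spec$mcmc, seed = seed)
      predict(fit, test_ids)
    },
    GBLUP_TA_random = {
      ta <- intersect(spec$ta_markers, marker_ids(data$geno))
      rest <- setdiff(marker_ids(data$geno), ta)
      if (length(ta) < 2 || length(rest) < 2)
        stop("TA partition leaves a kernel with < 2 markers")
      K1 <- grm_vanraden(gm_subset(data$geno, markers = ta))
      K2 <- grm_vanraden(gm_subset(data$geno, markers = rest))
      fit <- fit_kernel_blup(blue, list(K1, K2),
                             covariates = if (use_covariate)
                               matrix(W, ncol = 1,
                                      dimnames = list(names(W), "mpv")),
                             train_ids = train_ids, method = spec$method,
                             mcmc = spec$mcmc, seed = seed)
      predict(fit, test_ids)
    },
    stop("unknown model: ", spec$model))
}

#' Repeated k-fold cross-validation under a composition scenario
#'
#' Each repeat draws a fresh even k-fold split of the hybrids; per fold the
#' training set is composed per the scenario, the model fitted, the test
#' fold predicted; the k test folds are combined into a single accuracy per
#' repeat. `MPV_only` has no training and yields exactly one accuracy.
#' Per-repeat seeds derive deterministically from `seed` so scenarios share
#' fold splits within a repeat (paired comparisons).
#'
#' @param scenario "S1".."S5", "S2_MPVcov", or "MPV_only".
#' @param spec a [gp_model()].
#' @param data a [cv_data()].
#' @param repeats,k repeat and fold counts.
#' @param seed master integer seed.
#' @param subsample_rate,resample_seed internal hooks used by
#'   [subsample_training()].
#' @return data.frame (class `cv_result`) with columns scenario, model,
#'   threshold, repeat_id, accuracy; attributes `folds` (per repeat),
#'   `n_fits`, `seed`.
#' @export
run_cv <- function(scenario, spec, data, repeats = 20, k = 5, seed = 1,
                   subsample_rate = 100, resample_seed = NULL) {
  stopifnot(inherits(data, "cv_data"), inherits(spec, "gp_model"))
  hyb <- data$hybrid_ids
  if (scenario == "MPV_only") {
    pred <- predict_midparent(data$blue, data$pedigree, hyb)
    acc <- accuracy(pred, data$blue[hyb])
    out <- data.frame(scenario = scenario, model = "MPV",
                      threshold = NA_real_, repeat_id = 1L, accuracy = acc,
                      stringsAsFactors = FALSE)
    attr(out, "n_fits") <- 0L
    class(out) <- c("cv_result", class(out))
    return(out)
  }
  accs <- numeric(repeats)
  folds_list <- vector("list", repeats)
  n_fits <- 0L
  for (rep_i in seq_len(repeats)) {
    folds <- make_folds(hyb, k = k, seed = seed + rep_i - 1)
    folds_list[[rep_i]] <- folds
    pred_all <- setNames(rep(NA_real_, length(hyb)), hyb)
    for (fold in seq_len(k)) {
      test_ids <- names(folds)[folds == fold]
      ss_seed <- if (subsample_rate < 100)
        as.integer((if (is.null(resample_seed)) seed else resample_seed) +
                     1009L * rep_i + 97L * fold) else NULL
      comp <- compose_training_set(scenario, test_ids, data$pedigree,
                                   data$line_ids,
                                   subsample_rate = subsample_rate,
                                   subsample_seed = ss_seed)
      if (length(comp$train_ids) < 2) {
        warning("training set of size < 2; fold skipped")
        next
      }
      fold_seed <- as.integer(seed + 1009L * rep_i + 13L * fold)
      pred <- tryCatch(
        fit_predict_fold(spec, data, comp$train_ids, test_ids,
                         use_covariate = identical(comp$covariate,
                                                   "midparent"),
                         seed = fold_seed)[test_ids],
        error = function(e) {
          warning("repeat ", rep_i, " fold ", fold, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(pred)) next
      pred_all[test_ids] <- pred
      n_fits <- n_fits + 1L
    }
    done <- names(pred_all)[!is.na(pred_all)]
    accs[rep_i] <- if (length(done) < 3) NA_real_
                   else accuracy(pred_all[done], data$blue[done])
  }
  out <- data.frame(scenario = scenario, model = spec$model,
                    threshold = if (is.null(spec$threshold)) NA_real_
                                else spec$threshold,
                    repeat_id = seq_len(repeats), accuracy = accs,
                    stringsAsFactors = FALSE)
  attr(out, "folds") <- folds_list
  attr(out, "n_fits") <- n_fits
  attr(out, "seed") <- seed
  class(out) <- c("cv_result", class(out))
  out
}

#' Accuracy versus training-set size
#'
#' For each sampling rate, the reference hybrids of every composed training
#' set are thinned to that percentage (scenario S1 uses the parents of the
#' sampled reference hybrids) and the cross-validation is repeated. At rate
#' 100 the run reproduces [run_cv()] exactly under the same seed.
#'
#' @param scenario,spec,data,k,seed as in [run_cv()].
#' @param rates percentage grid in (0, 100].
#' @param resamples resampled CV repeats per rate.
#' @return data.frame with columns rate, resample, accuracy; per-rate mean
#'   and sd in attribute `"summary"`.
#' @export
subsample_training <- function(scenario, spec, data,
                               rates = c(5, 10, 20, 40, 60, 80, 100),
                               resamples = 20, k = 5, seed = 1) {
  if (any(rates <= 0 | rates > 100)) stop("rates must be in (0, 100]")
  rows <- list()
  for (rate in rates) {
    res <- run_cv(scenario, spec, data, repeats = resamples, k = k,
                  seed = seed, subsample_rate = rate,
                  resample_seed = seed + as.integer(rate))
    rows[[length(rows) + 1]] <- data.frame(rate = rate,
                                           resample = res$repeat_id,
                                           accuracy = res$accuracy)
  }
  out <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(out$accuracy, out$rate), function(a)
    data.frame(mean = mean(a, na.rm = TRUE), sd = sd(a))))
  sm$rate <- as.numeric(rownames(sm))
  attr(out, "summary") <- sm[order(sm$rate), c("rate", "mean", "sd")]
  out
}
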