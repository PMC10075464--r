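test_that("folds are even, seeded and sized like the half-sib design", {
  ids <- sprintf("H%03d", 1:401)
  f <- make_folds(ids, k = 5, seed = 3)
  expect_equal(sort(unname(table(f)), decreasing = TRUE),
               c(81, 80, 80, 80, 80), ignore_attr = TRUE)
  expect_identical(f, make_folds(ids, k = 5, seed = 3))
  expect_false(identical(f, make_folds(ids, k = 5, seed = 4)))
  expect_equal(unname(table(make_folds(letters[1:10], k = 5, seed = 1))),
               rep(2L, 5), ignore_attr = TRUE)
  expect_error(make_folds(letters[1:3], k = 5), "k must be")
})

test_that("scenario composition counts match the design arithmetic", {
  ped <- fx_pedigree_402()
  lines <- sprintf("L%04d", 1:402)
  test_ids <- ped$hybrid[1:80]
  n_of <- function(s)
    length(compose_training_set(s, test_ids, ped, lines)$train_ids)
  expect_equal(n_of("S2"), 321)
  expect_equal(n_of("S4"), 321 + 402)
  expect_equal(n_of("S5"), 321 + 80 + 1)
  expect_equal(n_of("S1"), 321 + 1)   # 321 males + the shared female
  expect_equal(n_of("S3"), 321 + 321 + 1)
  comp <- compose_training_set("S2_MPVcov", test_ids, ped, lines)
  expect_equal(length(comp$train_ids), 321)
  expect_equal(comp$covariate, "midparent")
})

test_that("training and test ids are disjoint in every scenario and fold", {
  ped <- fx_pedigree_402()
  lines <- sprintf("L%04d", 1:402)
  folds <- make_folds(ped$hybrid, k = 5, seed = 7)
  for (s in c("S1", "S2", "S3", "S4", "S5", "S2_MPVcov")) for (fo in 1:5) {
    test_ids <- names(folds)[folds == fo]
    comp <- compose_training_set(s, test_ids, ped, lines)
    expect_length(intersect(comp$train_ids, test_ids), 0)
  }
})

test_that("subsampled composition thins reference hybrids, S1 via parents", {
  ped <- fx_pedigree_402()
  lines <- sprintf("L%04d", 1:402)
  test_ids <- ped$hybrid[1:80]
  c2 <- compose_training_set("S2", test_ids, ped, lines,
                             subsample_rate = 20, subsample_seed = 5)
  expect_equal(length(c2$train_ids), floor(0.2 * 321))
  c1 <- compose_training_set("S1", test_ids, ped, lines,
                             subsample_rate = 20, subsample_seed = 5)
  # S1 = female + male parents of exactly the sampled reference hybrids
  expect_setequal(c1$train_ids,
                  unique(c("L0001", ped$male[match(c2$train_ids, ped$hybrid)])))
})

test_that("accuracy is Pearson r with degenerate inputs flagged", {
  obs <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  expect_equal(accuracy(obs, obs), 1)
  expect_equal(accuracy(-obs, obs), -1)
  pred <- c(a = 2, b = 4, c = 5, d = 4, e = 5)
  num <- sum((pred - mean(pred)) * (obs - mean(obs)))
  den <- sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  expect_equal(accuracy(pred, obs), num / den, tolerance = 1e-12)
  flat <- accuracy(c(a = 1, b = 1, c = 1), obs[1:3])
  expect_true(is.na(flat) && isTRUE(attr(flat, "undefined")))
  expect_error(accuracy(obs[1:2], obs[1:2]), "at least 3")
})

test_that("Fisher z and accuracy comparisons behave", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.9), 4), 1.4722)
  expect_warning(z1 <- fisher_z(1), "infinity")
  expect_true(is.infinite(z1))
  set.seed(20)
  a <- tanh(rnorm(20, 0.8, 0.05)); b <- tanh(rnorm(20, 0.5, 0.05))
  cmp <- compare_accuracies(a, b)
  expect_true(cmp$significant)
  expect_gt(cmp$mean_z[1], cmp$mean_z[2])
})

test_that("two-way ANOVA reports the table and a null interaction stays null", {
  flag <- vapply(1:20, function(s) {
    set.seed(s)
    d <- expand.grid(scenario = paste0("S", 1:4), threshold = 1:5,
                     rep = 1:10)
    eff <- c(S1 = 0, S2 = 0.2, S3 = 0.4, S4 = 0.6)
    d$accuracy <- tanh(0.3 + eff[d$scenario] + rnorm(nrow(d), 0, 0.08))
    tab <- anova_two_way(d)
    c(scen_p = tab$p[tab$term == "scenario"],
      int_p = tab$p[tab$term == "scenario:threshold"])
  }, c(0, 0))
  expect_true(all(flag["scen_p", ] < 0.05))
  expect_gte(sum(flag["int_p", ] > 0.05), 18)
})

test_that("run_cv wiring: repeats, fit counts, MPV singleton, noise floor", {
  tr <- fx_trial()
  d <- tr$data
  res <- run_cv("S2", gp_model("GBLUP"), d, repeats = 2, k = 3, seed = 5)
  expect_equal(nrow(res), 2)
  expect_equal(attr(res, "n_fits"), 2L * 3L)
  expect_true(all(res$accuracy >= -1 & res$accuracy <= 1))
  # same seed reproduces bit-identically
  res2 <- run_cv("S2", gp_model("GBLUP"), d, repeats = 2, k = 3, seed = 5)
  expect_identical(res$accuracy, res2$accuracy)
  mpv <- run_cv("MPV_only", gp_model("MPV"), d, repeats = 20)
  expect_equal(nrow(mpv), 1)
  expect_equal(attr(mpv, "n_fits"), 0L)
  # a pure-noise trait transfers nothing
  set.seed(31)
  noise_blue <- setNames(rnorm(length(d$blue)), names(d$blue))
  dn <- cv_data(tr$parents, tr$hybrids, tr$pedigree, noise_blue)
  rn <- run_cv("S2", gp_model("GBLUP"), dn, repeats = 4, k = 3, seed = 1)
  expect_lt(abs(mean(rn$accuracy)), 0.35)
})

test_that("dominance, absorbed by hybrid training sets, flips S1 vs S2", {
  # with dominance expressed in heterozygotes, hybrid phenotypes carry a
  # component only hybrid training sets can learn (in the single-female
  # design it is collinear with the male additive profile), so reference
  # hybrids out-predict their parents
  acc <- vapply(1:4, function(s) {
    trial <- simulate_halfsib_trial(
      n_lines = 402, n_markers = 600, ld_decay = 0.6,
      arch = trait_architecture(n_qtl = 80, target_h2 = 0.6,
                                dominance_degree = 1.2),
      seed = 8800 + s)
    blue <- compute_blue(trial$records)
    d <- cv_data(trial$parents, trial$hybrids, trial$pedigree, blue)
    vapply(c("S1", "S2"), function(sc)
      mean(run_cv(sc, gp_model("GBLUP"), d, repeats = 1, k = 5,
                  seed = s)$accuracy), 0)
  }, numeric(2))
  expect_true(all(acc["S2", ] > acc["S1", ]))
})

test_that("subsampling at 100% reproduces run_cv exactly", {
  tr <- fx_trial()
  d <- tr$data
  base <- run_cv("S2", gp_model("GBLUP"), d, repeats = 2, k = 3, seed = 9)
  sub <- subsample_training("S2", gp_model("GBLUP"), d, rates = c(40, 100),
                            resamples = 2, k = 3, seed = 9)
  expect_equal(sub$accuracy[sub$rate == 100], base$accuracy)
  sm <- attr(sub, "summary")
  expect_equal(sm$rate, c(40, 100))
  expect_true(all(is.finite(sm$mean)))
})
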