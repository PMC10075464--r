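test_that("qc_filter applies the three rules at their boundaries", {
  n <- 50
  m_keep <- c(rep(2, 5), rep(0, 45))          # MAF 0.05: kept
  m_rare <- c(rep(2, 2), rep(0, 48))          # MAF 0.04: removed
  m_het <- c(rep(1, 8), rep(2, 21), rep(0, 21))  # 16% het: removed
  m_miss <- c(rep(NA, 8), rep(2, 21), rep(0, 21))  # 84% call rate: removed
  m_ok <- rep(c(0, 2), 25)
  G <- fx_geno(cbind(keep = m_keep, rare = m_rare, het = m_het,
                     miss = m_miss, ok = m_ok))
  out <- qc_filter(G)
  expect_setequal(marker_ids(out), c("keep", "ok"))
  rep_ <- attr(out, "qc_report")
  expect_equal(unname(rep_["removed_maf"]), 1)
  expect_equal(unname(rep_["removed_callrate"]), 1)
  expect_equal(unname(rep_["removed_het"]), 1)
  # idempotent
  out2 <- qc_filter(out)
  expect_identical(out2$codes, out$codes)
})

test_that("impute_missing fills by mode/mean and erases parental heterozygotes", {
  G <- fx_geno(cbind(a = c(0, 2, NA, 0), b = c(0, 2, 2, NA),
                     c = c(0, 1, 2, 2), d = c(0, 2, 0, 2)))
  mo <- impute_missing(G, "column_mode")
  expect_false(anyNA(mo$codes))
  expect_equal(unname(mo$codes[3, "a"]), 0)   # tie 0/2 -> lower code
  expect_equal(unname(mo$codes[4, "b"]), 2)   # majority 2
  expect_true(all(mo$codes[, "c"] %in% c(0, 2)))  # het erased and refilled
  expect_equal(mo$codes[, "d"], G$codes[, "d"])   # untouched column
  me <- impute_missing(G, "column_mean_round")
  expect_equal(unname(me$codes[4, "b"]), round(mean(c(0, 2, 2))))
  expect_warning(impute_missing(fx_geno(cbind(x = c(NA, NA, 1)))),
                 "entirely missing")
})

test_that("ld_prune trivial cases behave as forced by the threshold", {
  set.seed(1)
  x <- sample(c(0, 2), 40, replace = TRUE)
  G <- fx_geno(cbind(a = x, b = x, c = sample(c(0, 2), 40, replace = TRUE)),
               chrom = c(1, 1, 1), pos = c(100, 200, 300))
  out <- ld_prune(G)
  expect_equal(sum(c("a", "b") %in% marker_ids(out)), 1)  # one of the pair
  # orthogonal block survives whole: build exactly uncorrelated columns
  H <- fx_geno(cbind(a = c(0, 0, 2, 2), b = c(0, 2, 0, 2), c = c(0, 2, 2, 0)),
               chrom = rep(1, 3), pos = c(1, 2, 3))
  expect_equal(ncol(ld_prune(H)$codes), 3)
  # unsorted map errors
  Gbad <- fx_geno(cbind(a = x, b = x), chrom = c(1, 1), pos = c(200, 100))
  expect_error(ld_prune(Gbad), "sorted")
})

test_that("ld_prune matches a brute-force window-pair oracle", {
  set.seed(33)
  n <- 60; m <- 60
  base <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
  # plant a correlated block: markers 20..30 mostly copy marker 20
  for (j in 21:30) {
    copy <- runif(n) < 0.9
    base[copy, j] <- base[copy, 20]
  }
  G <- fx_geno(base, chrom = rep(1, m), pos = seq_len(m) * 10)
  pruned <- marker_ids(ld_prune(G, window = 15, step = 5, r2_max = 0.1))
  # oracle: independent re-implementation, re-checking all pairs per window
  oracle_prune <- function(codes, pos, window, step, r2_max) {
    m <- ncol(codes)
    maf <- pmin(colMeans(codes) / 2, 1 - colMeans(codes) / 2)
    keep <- rep(TRUE, m)
    s <- 1
    repeat {
      w <- seq(s, min(s + window - 1, m))
      repeat {
        cur <- w[keep[w]]
        if (length(cur) < 2) break
        pairs <- which(upper.tri(matrix(0, length(cur), length(cur))),
                       arr.ind = TRUE)
        hit <- NULL
        cm <- suppressWarnings(cor(codes[, cur, drop = FALSE]))
        cm[!is.finite(cm)] <- 0
        for (r in seq_len(nrow(pairs))) {
          i <- pairs[r, 1]; j <- pairs[r, 2]
          if (i < j && cm[i, j]^2 > r2_max) { hit <- c(cur[i], cur[j]); break }
        }
        if (is.null(hit)) break
        drop_i <- if (maf[hit[1]] > maf[hit[2]]) hit[2]
                  else if (maf[hit[2]] > maf[hit[1]]) hit[1]
                  else if (pos[hit[1]] <= pos[hit[2]]) hit[2] else hit[1]
        keep[drop_i] <- FALSE
      }
      if (s + window - 1 >= m) break
      s <- s + step
    }
    colnames(codes)[keep]
  }
  expect_identical(pruned, oracle_prune(G$codes, G$map$pos, 15, 5, 0.1))
})

test_that("deduce_hybrid_genotypes enforces its contract", {
  P <- fx_geno(matrix(c(0, 2, 2, 2, 0, 0), 2, 3, byrow = TRUE))
  rownames(P$codes) <- c("f", "m")
  ped <- data.frame(hybrid = "h", female = "f", male = "m")
  H <- deduce_hybrid_genotypes(geno_matrix(P$codes), ped)
  expect_equal(unname(H$codes["h", ]), c(1, 1, 1))
  # code 1 exactly where parents disagree
  expect_equal(unname(H$codes["h", ]) == 1,
               unname(P$codes["f", ] != P$codes["m", ]))
  # selfing the female reproduces her row
  ped2 <- data.frame(hybrid = "self", female = "f", male = "f")
  expect_equal(unname(deduce_hybrid_genotypes(geno_matrix(P$codes),
                                              ped2)$codes["self", ]),
               unname(P$codes["f", ]))
  Phet <- geno_matrix(matrix(c(1, 0, 2, 0), 2, 2,
                             dimnames = list(c("f", "m"), c("a", "b"))))
  expect_error(deduce_hybrid_genotypes(Phet, ped), "heterozygotes")
  expect_error(deduce_hybrid_genotypes(geno_matrix(P$codes),
                                       data.frame(hybrid = "x", female = "f",
                                                  male = "zz")), "absent")
})

test_that("grm_vanraden reproduces the closed-form toy and its invariances", {
  G <- fx_geno(matrix(c(0, 2, 2, 0, 1, 1), 3, 2, byrow = TRUE))
  A <- grm_vanraden(G)
  expect_equal(matrix(A, 3, 3), matrix(c(2, -2, 0, -2, 2, 0, 0, 0, 0), 3, 3),
               tolerance = 1e-12)
  expect_equal(attr(A, "flavor"), "vanraden")
  # duplicating every marker leaves A unchanged
  dup <- G$codes
  colnames(dup) <- paste0(colnames(dup), "_dup")
  G2 <- fx_geno(cbind(G$codes, dup))
  expect_equal(matrix(grm_vanraden(G2), 3, 3), matrix(A, 3, 3),
               tolerance = 1e-12)
  # identical individuals -> identical rows
  c3 <- rbind(G$codes, G$codes[1, , drop = FALSE])
  rownames(c3) <- paste0("r", 1:4)
  G3 <- fx_geno(c3)
  A3 <- grm_vanraden(G3)
  expect_equal(A3[1, ], A3[4, ], tolerance = 1e-12)
  expect_error(grm_vanraden(fx_geno(matrix(2, 3, 2))), "monomorphic")
})

test_that("epistatic kernel is the Hadamard square", {
  G <- fx_geno(matrix(c(0, 2, 2, 0, 1, 1), 3, 2, byrow = TRUE))
  A <- grm_vanraden(G)
  K <- epistatic_kernel(A)
  expect_equal(matrix(K, 3, 3), matrix(c(4, 4, 0, 4, 4, 0, 0, 0, 0), 3, 3),
               tolerance = 1e-12)
  expect_equal(attr(K, "flavor"), "epistatic")
  I3 <- diag(3); attr(I3, "flavor") <- "vanraden"
  expect_equal(matrix(epistatic_kernel(I3), 3, 3), diag(3))
  expect_error(epistatic_kernel(K), "already epistatic")
})

test_that("grm_yang diagonal formula and near-zero unrelated off-diagonals", {
  # column (0,2,1,1): p = 0.5; scalar diagonal oracle per genotype code
  G <- fx_geno(matrix(c(0, 2, 1, 1), 4, 1))
  A <- grm_yang(G)
  expect_equal(unname(diag(A)), c(2, 2, 0, 0), tolerance = 1e-12)
  # equal-frequency panel: off-diagonals coincide with vanraden
  set.seed(8)
  codes <- matrix(sample(c(0, 2), 60, replace = TRUE), 10, 6)
  codes[1, ] <- 0; codes[2, ] <- 2  # keep every column polymorphic, p varies
  eqG <- fx_geno(rbind(c(0, 0, 0), c(2, 2, 2), c(0, 2, 0), c(2, 0, 2)))
  Ay <- grm_yang(eqG); Av <- grm_vanraden(eqG)
  off <- upper.tri(Ay)
  expect_equal(Ay[off], Av[off], tolerance = 1e-10)
  # unrelated simulated lines: mean off-diagonal near zero
  Gbig <- simulate_parents(150, 400, seed = 21)
  Aw <- grm_yang(Gbig)
  expect_lt(abs(mean(Aw[upper.tri(Aw)])), 0.05)
  expect_warning(grm_yang(fx_geno(cbind(a = c(0, 2, 0), b = c(2, 2, 2)))),
                 "monomorphic")
})

test_that("GRMs are symmetric and positive semidefinite", {
  tr <- fx_trial()
  for (A in list(tr$data$K_add, tr$data$K_epi)) {
    expect_equal(A, t(A), tolerance = 1e-10)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8 * max(diag(A)))
  }
})

test_that("pca_components orders variance and matches an eigen oracle", {
  one <- fx_geno(cbind(a = c(0, 2, 0, 2), b = rep(2, 4), c = rep(0, 4)))
  pc <- suppressWarnings(pca_components(one, k = 1))
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)
  set.seed(4)
  codes <- matrix(sample(c(0, 1, 2), 200, replace = TRUE), 10, 20)
  G <- fx_geno(codes)
  pc <- pca_components(G, k = 5)
  ev <- eigen(cov(codes), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc$explained, (ev / sum(ev))[1:5], tolerance = 1e-10)
  # permutation invariance (up to sign) of scores
  Gp <- fx_geno(codes[, sample(20)])
  pcp <- pca_components(Gp, k = 3)
  for (j in 1:3)
    expect_equal(abs(cor(pc$scores[, j], pcp$scores[, j])), 1,
                 tolerance = 1e-8)
  expect_warning(pca_components(one, k = 4), "rank")
})

test_that("pairwise dissimilarity matches brute-force average linkage", {
  expect_equal(pairwise_dissimilarity(fx_geno(rbind(c(0, 0), c(2, 2))))$dist[1, 2],
               sqrt(8))
  expect_equal(pairwise_dissimilarity(fx_geno(rbind(c(0, 2), c(0, 2))))$dist[1, 2],
               0)
  set.seed(14)
  codes <- matrix(sample(c(0, 1, 2), 6 * 8, replace = TRUE), 6, 8)
  res <- pairwise_dissimilarity(fx_geno(codes))
  # oracle: exhaustive agglomeration with average linkage
  D <- as.matrix(dist(codes))
  active <- as.list(1:6)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(active)) for (j in seq_along(active)) if (i < j) {
      h <- mean(D[active[[i]], active[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    active[[best[2]]] <- c(active[[best[2]]], active[[best[3]]])
    active[[best[3]]] <- NULL
  }
  expect_equal(res$hclust$height, heights, tolerance = 1e-10)
})
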