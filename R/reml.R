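# REML engines.
#
# Two routes: a fast eigendecomposition-based profile REML for a single
# kernel (used by the GWAS null model), and a general average-information
# REML with EM fallback for any number of kernels (used by the kernel BLUP
# predictors). Tolerance 1e-6 on the restricted log-likelihood, at most 200
# iterations.

# Single-kernel profile REML via eigen rotation.
# y = X b + g + e, g ~ N(0, K sigma_a2), e ~ N(0, I sigma_e2).
# Returns components, ratio, rotated data, REML log-likelihood.
reml_single_kernel <- function(y, K, X, tol = 1e-6) {
  n <- length(y)
  stopifnot(nrow(K) == n, nrow(X) == n)
  if (sd(y) < 1e-12) {
    warning("response is (near) constant; degenerate fit")
    return(list(sigma_a2 = 0, sigma_e2 = max(var(y), 0), h2 = 0,
                converged = TRUE, degenerate = TRUE))
  }
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)
  negll <- function(log_lambda) {
    lambda <- exp(log_lambda)            # sigma_a2 / sigma_e2
    w <- lambda * d + 1
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    b <- solve(XtWX, crossprod(Xw, yt))
    r <- yt - Xt %*% b
    rss <- sum(r^2 / w)
    s2 <- rss / (n - p)
    0.5 * ((n - p) * log(s2) + sum(log(w)) +
             determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }
  # coarse grid then Brent refine: the profile can be multimodal in theory
  grid <- seq(-12, 12, length.out = 49)
  vals <- vapply(grid, negll, 0)
  g0 <- grid[which.min(vals)]
  opt <- optimize(negll, lower = g0 - 1, upper = g0 + 1, tol = tol)
  lambda <- exp(opt$minimum)
  w <- lambda * d + 1
  Xw <- Xt / w
  XtWX <- crossprod(Xt, Xw)
  b <- solve(XtWX, crossprod(Xw, yt))
  r <- yt - Xt %*% b
  sigma_e2 <- sum(r^2 / w) / (n - p)
  sigma_a2 <- lambda * sigma_e2
  # treat boundary fits as converged but clamp tiny components
  if (lambda < 1e-10) sigma_a2 <- 0
  list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
       h2 = sigma_a2 / (sigma_a2 + sigma_e2),
       beta = drop(b), loglik = -opt$objective, converged = TRUE,
       degenerate = FALSE, eig = list(values = d, vectors = U),
       lambda = lambda)
}

# Multi-kernel AI-REML with EM fallback.
# y = X b + sum_k g_k + e, g_k ~ N(0, K_k s_k), e ~ N(0, I s_e).
# kernels: list of n x n matrices. Returns variance components
# (one per kernel + residual), beta, V^{-1}(y - X b), loglik.
reml_multi_kernel <- function(y, kernels, X, tol = 1e-6, max_iter = 200) {
  n <- length(y)
  nk <- length(kernels)
  for (K in kernels) stopifnot(nrow(K) == n, ncol(K) == n)
  if (sd(y) < 1e-12) {
    warning("response is (near) constant; degenerate fit")
    s <- c(rep(0, nk), max(var(y), 1e-12))
    b <- rep(0, ncol(X)); b[1] <- mean(y)
    return(list(varcomp = s, beta = b, Py = rep(0, n), converged = TRUE,
                degenerate = TRUE, loglik = NA_real_))
  }
  vy <- var(y)
  floor_s <- vy * 1e-9
  # evaluate restricted log-likelihood and the pieces reused by the updates
  eval_at <- function(s) {
    V <- diag(s[nk + 1], n)
    for (k in seq_len(nk)) V <- V + s[k] * kernels[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    XtViX_inv <- tryCatch(solve(XtViX), error = function(e) NULL)
    if (is.null(XtViX_inv)) return(NULL)
    P <- Vi - ViX %*% XtViX_inv %*% t(ViX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    as.numeric(determinant(XtViX, TRUE)$modulus) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll, XtViX_inv = XtViX_inv, ViX = ViX)
  }
  s <- rep(vy / (nk + 1), nk + 1)  # kernels then residual
  st <- eval_at(s)
  if (is.null(st)) stop("initial variance components give a singular system")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    PK <- vector("list", nk + 1)
    KPy <- vector("list", nk + 1)
    for (k in seq_len(nk)) {
      PK[[k]] <- st$P %*% kernels[[k]]
      KPy[[k]] <- drop(kernels[[k]] %*% st$Py)
    }
    PK[[nk + 1]] <- st$P
    KPy[[nk + 1]] <- st$Py
    grad <- vapply(seq_len(nk + 1), function(k)
      -0.5 * (sum(diag(PK[[k]])) - sum(st$Py * KPy[[k]])), 0)
    AI <- matrix(0, nk + 1, nk + 1)
    for (k in seq_len(nk + 1)) for (l in k:(nk + 1))
      AI[k, l] <- AI[l, k] <- 0.5 * sum(KPy[[k]] * drop(st$P %*% KPy[[l]]))
    em_step <- function() {
      s_new <- s
      for (k in seq_len(nk + 1))
        s_new[k] <- s[k] + s[k]^2 *
          (sum(st$Py * KPy[[k]]) - sum(diag(PK[[k]]))) / n
      pmax(s_new, floor_s)
    }
    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      # backtrack until the likelihood does not drop and components stay valid
      for (half in 0:5) {
        s_try <- pmax(s + step / 2^half, floor_s)
        st_try <- eval_at(s_try)
        if (!is.null(st_try) && st_try$ll >= st$ll - 1e-10) {
          s_new <- s_try; st_new <- st_try; accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) {
      s_new <- em_step()
      st_new <- eval_at(s_new)
      if (is.null(st_new)) { s_new <- s; st_new <- st }
    }
    dll <- abs(st_new$ll - st$ll)
    dpar <- max(abs(s_new - s) / (abs(s) + vy * 1e-8))
    s <- s_new; st <- st_new
    if (dll < tol || dpar < 1e-8) { converged <- TRUE; break }
  }
  if (!converged)
    stop("REML did not converge in ", max_iter,
         " iterations (last loglik ", signif(st$ll, 8), ")")
  beta <- drop(st$XtViX_inv %*% crossprod(st$ViX, y))
  s[s <= floor_s * 1.01] <- 0
  list(varcomp = s, beta = beta, Py = st$Py, loglik = st$ll,
       converged = TRUE, degenerate = FALSE)
}
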