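# Independent oracles used to cross-check the implementation.

# penalized weighted logistic objective, written independently of the solver
obj_wlasso <- function(X, y, w, b0, beta, lambda) {
  eta <- as.numeric(b0 + X %*% beta)
  loglik <- pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta
  mean(w * loglik) + lambda * sum(abs(beta))
}

# proximal-gradient (FISTA) solver for the same objective: a generic convex
# optimizer sharing no code with the coordinate-descent implementation
fista_wlasso <- function(X, y, w, lambda, iters = 50000, tol = 1e-14) {
  n <- nrow(X)
  A <- cbind(1, X)
  L <- max(eigen(crossprod(sqrt(w) * A), symmetric = TRUE,
                 only.values = TRUE)$values) / (4 * n)
  step <- 1 / L
  theta <- rep(0, ncol(A))
  z <- theta
  tk <- 1
  f_prev <- Inf
  for (it in seq_len(iters)) {
    p <- plogis(as.numeric(A %*% z))
    grad <- crossprod(A, w * (p - y)) / n
    theta_new <- z - step * as.numeric(grad)
    # soft-threshold all but the intercept
    b <- theta_new[-1]
    theta_new[-1] <- sign(b) * pmax(abs(b) - step * lambda, 0)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- theta_new + ((tk - 1) / tk_new) * (theta_new - theta)
    f <- obj_wlasso(X, y, w, theta_new[1], theta_new[-1], lambda)
    if (f > f_prev) { # restart momentum on objective increase
      z <- theta_new
      tk_new <- 1
    }
    if (abs(f_prev - f) < tol && it > 100) {
      theta <- theta_new
      break
    }
    f_prev <- min(f_prev, f)
    theta <- theta_new
    tk <- tk_new
  }
  list(b0 = theta[1], beta = theta[-1],
       objective = obj_wlasso(X, y, w, theta[1], theta[-1], lambda))
}

# brute-force two-stage grid minimization of the penalized objective for a
# single-column design (intercept + one coefficient)
grid_min_2param <- function(X, y, w, lambda) {
  eval_grid <- function(b0s, b1s) {
    g <- expand.grid(b0 = b0s, b1 = b1s)
    vals <- vapply(seq_len(nrow(g)),
                   function(i) obj_wlasso(X, y, w, g$b0[i], g$b1[i], lambda),
                   numeric(1))
    g[which.min(vals), ]
  }
  coarse <- eval_grid(seq(-3, 3, by = 0.02), seq(-1, 5, by = 0.02))
  eval_grid(seq(coarse$b0 - 0.05, coarse$b0 + 0.05, by = 0.002),
            seq(coarse$b1 - 0.05, coarse$b1 + 0.05, by = 0.002))
}

# two-sided exact test by explicit enumeration of all tables with the
# observed margins, point probabilities from binomial coefficients
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[, 2]); nn <- sum(tab[, 1]); k <- sum(tab[1, ])
  N <- m + nn
  support <- max(0, k - nn):min(k, m)
  pp <- choose(m, support) * choose(nn, k - support) / choose(N, k)
  p0 <- choose(m, tab[1, 2]) * choose(nn, tab[1, 1]) / choose(N, k)
  sum(pp[pp <= p0 * (1 + 1e-7)])
}

# ROC-AUC by enumerating every positive-negative pair
auc_pairs_oracle <- function(prob, y) {
  pos <- prob[y == 1]; neg <- prob[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small random weighted-lasso instance
random_lasso_instance <- function(seed) {
  set.seed(seed)
  n <- sample(10:30, 1)
  G <- sample(2:5, 1)
  X <- matrix(rbinom(n * G, 1, runif(1, 0.2, 0.6)), n, G)
  repeat {
    y <- rbinom(n, 1, 0.5)
    if (sum(y) > 0 && sum(y) < n) break
  }
  w <- as.numeric(class_weights(y)[as.character(y)])
  lam <- runif(1, 0.005, 0.8) * lambda_max(X, y)
  list(X = X, y = y, w = w, lambda = lam)
}

# tiny deterministic subject table builder
make_subjects <- function(n, ...) {
  defaults <- list(sex = "M", age = 40L, clinical_category = 0L,
                   cohort = "w1", pcr_confirmed = TRUE)
  args <- utils::modifyList(defaults, list(...))
  df <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (f in names(defaults)) df[[f]] <- args[[f]]
  df
}
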