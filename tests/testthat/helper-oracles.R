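# Independent oracles used across test files.

# Hand-written Breslow log partial likelihood (no survival-package code):
# sum over events of eta_i - log(sum of exp(eta_j) over the risk set).
breslow_loglik <- function(beta, time, event, X) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Brute-force maximization: coarse 3-D grid over [-5, 5]^3 to locate the
# basin, then Nelder-Mead/BFGS polish. Returns the interaction coefficient.
oracle_cox_gamma <- function(time, event, grs, arm) {
  X <- cbind(as.numeric(grs), as.numeric(arm), as.numeric(grs * arm))
  grid <- as.matrix(expand.grid(seq(-5, 5, length.out = 11),
                                seq(-5, 5, length.out = 11),
                                seq(-5, 5, length.out = 11)))
  vals <- vapply(seq_len(nrow(grid)),
                 function(i) breslow_loglik(grid[i, ], time, event, X),
                 numeric(1))
  start <- grid[which.max(vals), ]
  neg <- function(b) -breslow_loglik(b, time, event, X)
  opt <- stats::optim(start, neg, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  opt <- stats::optim(opt$par, neg, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  unname(opt$par[3])
}

# Normal-equations OLS: solve (X'X) b = X'y directly.
oracle_ols <- function(y, grs, arm) {
  X <- cbind(1, grs, arm, grs * arm)
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# A frame with prescribed genotype values (bypasses HWE simulation).
build_frame_fixed_genotypes <- function(g) {
  structure(list(genotypes = g, grs = rowSums(g), frame_size = nrow(g)),
            class = "sampling_frame")
}

# A fixed randomized cohort for outcome-generation tests.
make_test_cohort <- function(panel, frame_size = 500, n = 200,
                             design = "conventional", seed = 1) {
  set.seed(seed)
  frame <- build_frame(panel, frame_size)
  cohort <- if (design == "gbr") recruit_gbr(frame, n)
            else recruit_conventional(frame, n)
  randomize_arms(cohort)
}
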