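# Independent oracles and tiny-instance generators used across the
# suite. These deliberately avoid the package's own solver paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# classify a single mutation by first principles (independent of
# classify_mutation): complement lookup + string assembly
oracle_classify <- function(ref, alt, f5, f3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("A", "G")) {
    tmp5 <- comp[[f3]]; f3 <- comp[[f5]]; f5 <- tmp5
    ref <- comp[[ref]]; alt <- comp[[alt]]
  }
  paste0(f5, "[", ref, ">", alt, "]", f3)
}

# embed a small category-space toy into the 96-column layout
pad96 <- function(m) {
  out <- matrix(0, nrow(m), 96L)
  out[, seq_len(ncol(m))] <- m
  colnames(out) <- mutation_categories()
  rownames(out) <- rownames(m)
  out
}

# projected-gradient oracle for the signature subproblem
#   min ||R - alpha B||_F^2 + lambda sum(B),  B >= 0
pgd_nnlasso <- function(alpha, R, lambda, max_iter = 2e5, tol = 1e-13) {
  G <- crossprod(alpha)
  C <- crossprod(alpha, R)
  L <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  B <- matrix(0, ncol(alpha), ncol(R))
  for (i in seq_len(max_iter)) {
    grad <- 2 * (G %*% B - C) + lambda
    Bn <- B - step * grad
    Bn[Bn < 0] <- 0
    if (max(abs(Bn - B)) < tol) { B <- Bn; break }
    B <- Bn
  }
  B
}

# reference multiplicative-update NMF (squared error) from a given start
mu_nmf <- function(M, W0, H0, max_iter = 5e4, tol = 1e-13) {
  W <- W0; H <- H0; eps <- 1e-12
  obj_prev <- sum((M - W %*% H)^2)
  for (i in seq_len(max_iter)) {
    H <- H * (crossprod(W, M) / (crossprod(W) %*% H + eps))
    W <- W * (M %*% t(H) / (W %*% tcrossprod(H) + eps))
    if (i %% 50L == 0L) {
      obj <- sum((M - W %*% H)^2)
      if (abs(obj_prev - obj) < tol * max(1, obj_prev)) break
      obj_prev <- obj
    }
  }
  list(W = W, H = H, objective = sum((M - W %*% H)^2))
}

# small random instance for solver cross-checks: n samples, 96 columns
# with signal confined to the first n_cat, K signatures
random_instance <- function(seed, n = 4, n_cat = 6, K = 2) {
  set.seed(seed)
  alpha <- matrix(stats::rgamma(n * K, shape = 2, rate = 0.1), n, K)
  R_small <- matrix(stats::rgamma(n * n_cat, shape = 2), n, n_cat)
  list(alpha = alpha, R = pad96(R_small), n_cat = n_cat)
}

# quick generative cohort for fit-level tests
toy_cohort <- function(seed, n = 30, burden = c(2e3, 2e4),
                       rows = c("SYN-S1", "SYN-S2", "SYN-S3"),
                       counts_model = "poisson", presence = 1) {
  catalog <- synthetic_catalog()
  spec <- simulation_spec(
    rbind(Background = as.numeric(load_background_preset("germline")),
          catalog[rows, , drop = FALSE]),
    background_row = "Background", n_samples = n,
    presence_fraction = presence, burden_range = burden
  )
  simulate_dataset(spec, seed = seed, counts_model = counts_model)
}
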