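test_that("cosine similarity matches hand computations and basic identities", {
  v <- stats::runif(96)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0, rep(0, 94)), c(0, 1, rep(0, 94))), 0)
  u <- c(1, 2, 2, rep(0, 93)); w <- c(2, 1, 2, rep(0, 93))
  expect_equal(cosine_similarity(u, w), 8 / 9)
  expect_equal(cosine_similarity(u, 10 * w), 8 / 9)  # scale invariance
  expect_error(cosine_similarity(u, rep(0, 96)), "zero vector")
})

test_that("matching recovers permutations and allows shared best matches", {
  catalog <- synthetic_catalog()
  true_beta <- catalog[c("SYN-S1", "SYN-S2", "SYN-S3"), ]
  est <- true_beta[c(3, 1, 2), ]
  rownames(est) <- paste0("E", 1:3)
  rep <- match_signatures(true_beta, est)
  expect_equal(rep$cosine, rep(1, 3))
  expect_equal(rep$estimated, c("E2", "E3", "E1"))

  # one estimate closest to two true signatures: both map to it
  est2 <- rbind(E1 = true_beta[1, ] + true_beta[2, ],
                E2 = catalog["SYN-D1", ])
  r2 <- match_signatures(true_beta[1:2, ], est2, method = "per_true_best")
  expect_equal(r2$estimated, c("E1", "E1"))
})

test_that("one_to_one matching equals the brute-force assignment oracle", {
  set.seed(14)
  for (i in 1:5) {
    true_beta <- matrix(stats::rgamma(3 * 96, 1), 3, 96)
    est_beta <- matrix(stats::rgamma(3 * 96, 1), 3, 96)
    rownames(est_beta) <- paste0("E", 1:3)
    r <- match_signatures(true_beta, est_beta, method = "one_to_one")
    expect_equal(anyDuplicated(r$estimated), 0L)
    # exhaustive oracle over all 6 permutations
    S <- matrix(NA_real_, 3, 3)
    for (a in 1:3) for (b in 1:3) {
      S[a, b] <- cosine_similarity(true_beta[a, ], est_beta[b, ])
    }
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                  c(3, 2, 1))
    best <- max(vapply(perms, function(p) sum(S[cbind(1:3, p)]), numeric(1)))
    expect_equal(sum(r$cosine), best, tolerance = 1e-12)
  }
})

test_that("one_to_one total cosine dominates every permutation for K <= 5", {
  set.seed(15)
  true_beta <- matrix(stats::rgamma(5 * 96, 1), 5, 96)
  est_beta <- matrix(stats::rgamma(5 * 96, 1), 5, 96)
  r <- match_signatures(true_beta, est_beta, method = "one_to_one")
  S <- sapply(1:5, function(b) sapply(1:5, function(a)
    cosine_similarity(true_beta[a, ], est_beta[b, ])))
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ]
  totals <- apply(perms, 1, function(p) sum(S[cbind(1:5, p)]))
  expect_equal(sum(r$cosine), max(totals), tolerance = 1e-12)
})

test_that("exposure error obeys its closed forms and an independent recomputation", {
  set.seed(16)
  true_alpha <- matrix(stats::runif(10, 100, 1000), 5, 2,
                       dimnames = list(NULL, c("T1", "T2")))
  rep <- data.frame(true = c("T1", "T2"), estimated = c("E1", "E2"),
                    cosine = 1)
  est <- true_alpha; colnames(est) <- c("E1", "E2")
  expect_equal(unname(exposure_error(true_alpha, est, rep)), c(0, 0))

  est_c <- est + 7
  expect_equal(unname(exposure_error(true_alpha, est_c, rep)), c(49, 49))

  est_r <- matrix(stats::runif(10, 100, 1000), 5, 2,
                  dimnames = list(NULL, c("E1", "E2")))
  got <- exposure_error(true_alpha, est_r, rep)
  manual <- c(mean((true_alpha[, 1] - est_r[, 1])^2),
              mean((true_alpha[, 2] - est_r[, 2])^2))
  expect_equal(unname(got), manual)
  expect_error(exposure_error(true_alpha[1:3, ], est_r, rep), "disagree")
})

test_that("sparsity counts sub-threshold entries and is monotone in the threshold", {
  expect_equal(signature_sparsity(matrix(0, 3, 96)), 1)
  ident <- matrix(0, 4, 96)
  ident[cbind(1:4, 1:4)] <- 1
  expect_equal(signature_sparsity(ident, 1e-3), (384 - 4) / 384)
  set.seed(17)
  m <- matrix(stats::rgamma(2 * 96, 0.2, rate = 10), 2, 96)
  expect_lte(signature_sparsity(m, 1e-4), signature_sparsity(m, 1e-3))
  expect_error(signature_sparsity(matrix(0, 0, 96)), "empty")
})

test_that("diagnostics hit their exact-reconstruction limits", {
  catalog <- synthetic_catalog()
  bg <- load_background_preset("germline")
  sig <- catalog[c("SYN-S1", "SYN-S2"), ]
  set.seed(18)
  alpha <- matrix(stats::runif(12, 200, 4000), 6, 2,
                  dimnames = list(paste0("s", 1:6), rownames(sig)))
  alpha0 <- stats::runif(6, 500, 5000)
  M <- outer(alpha0, as.numeric(bg)) + alpha %*% sig
  colnames(M) <- mutation_categories()
  fit <- structure(list(signatures = sig, exposures = alpha, alpha0 = alpha0,
                        background = bg, K = 2L), class = "sparsesigs_fit")
  d <- fit_diagnostics(M, fit)
  expect_equal(d$explained_variance, 1, tolerance = 1e-12)
  expect_equal(unname(d$per_patient_correlation), rep(1, 6), tolerance = 1e-12)
  expect_equal(d$mse, 0, tolerance = 1e-12)
  # cross-signature similarity with 2 signatures + background = mean of 3 pairs
  cm <- c(cosine_similarity(bg, sig[1, ]), cosine_similarity(bg, sig[2, ]),
          cosine_similarity(sig[1, ], sig[2, ]))
  expect_equal(d$cross_signature_similarity, mean(cm), tolerance = 1e-12)
  expect_equal(d$background_contamination, mean(cm[1:2]), tolerance = 1e-12)

  # a single signature and no background: no pairs to compare
  fit1 <- structure(list(signatures = sig[1, , drop = FALSE],
                         exposures = alpha[, 1, drop = FALSE],
                         alpha0 = NULL, background = NULL, K = 1L),
                    class = "sparsesigs_fit")
  d1 <- fit_diagnostics(alpha[, 1, drop = FALSE] %*% sig[1, , drop = FALSE],
                        fit1)
  expect_true(is.na(d1$cross_signature_similarity))
  expect_true(is.na(d1$background_contamination))
})

test_that("rare-signature stratification reproduces a brute-force group-by", {
  set.seed(19)
  reports <- list(); presence <- list()
  for (d in 1:10) {
    cosines <- stats::runif(3, 0.7, 1)
    reports[[d]] <- data.frame(true = c("A", "B", "C"),
                               estimated = c("E1", "E2", "E3"),
                               cosine = cosines)
    presence[[d]] <- c(A = stats::runif(1, 0.05, 0.34),
                       B = stats::runif(1, 0.36, 0.69),
                       C = stats::runif(1, 0.71, 1))
  }
  out <- rare_signature_summary(reports, presence,
                                presence_breaks = c(0, 0.35, 0.7, 1))
  all_cos <- unlist(lapply(reports, `[[`, "cosine"))
  all_pres <- unlist(lapply(presence, function(p) unname(p)))
  for (b in seq_len(3)) {
    lo <- c(0, 0.35, 0.7)[b]; hi <- c(0.35, 0.7, 1)[b]
    idx <- all_pres > lo & all_pres <= hi
    expect_equal(out$by_presence$median_cosine[b], median(all_cos[idx]),
                 tolerance = 1e-12)
    expect_equal(out$by_presence$n[b], sum(idx))
  }

  # trivial cases
  one <- list(data.frame(true = "A", estimated = "E", cosine = 0.95))
  r <- rare_signature_summary(one, list(c(A = 0.2)))
  expect_equal(r$by_presence$median_cosine[1], 0.95)
})
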