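# objective evaluated through the internal kernel, for before/after checks
obj_of <- function(st, Xs, Slist, l1, l2) {
  grmec:::.objective(st$W, Xs, st$Vs, st$w, st$H, st$S, Slist, st$alpha,
                     l1, l2)$total
}

rand_state <- function(n, k, C, Xs, Slist, seed = 1) {
  set.seed(seed)
  m <- length(Xs)
  W <- matrix(runif(n * k), n, k)
  Vs <- lapply(Xs, function(X) matrix(runif(k * ncol(X)), k, ncol(X)))
  S0 <- matrix(runif(n * n), n, n)
  H <- matrix(runif(n * C), n, C)
  list(W = W, Vs = Vs, S = (S0 + t(S0)) / 2, H = H / rowSums(H),
       w = rep(1 / m, m), alpha = rep(1 / length(Slist), length(Slist)))
}

test_that("objective is zero at a perfect fit and reduces to plain NMF error in the degenerate limit", {
  inst <- random_instance(n = 10, m = 2, q = 2, C = 2, p = c(8, 6), seed = 3)
  Xs <- lapply(inst$views, as.matrix)
  set.seed(1)
  W <- matrix(runif(10 * 3), 10, 3)
  Vs <- lapply(Xs, function(X) matrix(runif(3 * ncol(X)), 3, ncol(X)))
  Xfit <- lapply(seq_along(Xs), function(v) W %*% Vs[[v]])
  S <- inst$Slist[[1]]
  obj <- grmec:::.objective(W, Xfit, Vs, w = c(1, 1), H = matrix(0.5, 10, 2),
                            S = S, Slist = list(S), alpha = 1,
                            lambda1 = 0, lambda2 = 0)
  expect_equal(obj$total, 0, tolerance = 1e-20)

  # m=1, w=1, lambda1=lambda2=0, no consensus mismatch: plain reconstruction
  obj2 <- grmec:::.objective(W, Xs[1], Vs[1], w = 1, H = matrix(0.5, 10, 2),
                             S = S, Slist = list(S), alpha = 1,
                             lambda1 = 0, lambda2 = 0)
  expect_equal(obj2$total, sum((Xs[[1]] - W %*% Vs[[1]])^2), tolerance = 1e-10)
})

test_that("lambda1 term equals the brute-force weighted distance sum on a 6-cell instance", {
  set.seed(11)
  n <- 6; k <- 3; C <- 2
  W <- matrix(runif(n * k), n, k)
  H <- matrix(runif(n * C), n, C); H <- H / rowSums(H)
  V <- matrix(runif(k * 4), k, 4)
  X <- W %*% V
  S <- diag(n)
  obj <- grmec:::.objective(W, list(X), list(V),
                            w = 0, H = H, S = S, Slist = list(S), alpha = 0,
                            lambda1 = 1, lambda2 = 0)
  SH <- H %*% t(H)
  brute <- 0
  for (i in 1:n) for (j in 1:n)
    brute <- brute + sum((W[i, ] - W[j, ])^2) * SH[i, j]
  expect_equal(obj$terms[["graph_W"]], brute / 2, tolerance = 1e-10)
})

test_that("W and V updates have the classical NMF fixed point and match the oracle at lambda1=0", {
  set.seed(5)
  n <- 12; k <- 3; p <- 9
  Wt <- matrix(runif(n * k), n, k)
  Vt <- matrix(runif(k * p), k, p)
  X <- Wt %*% Vt
  H <- matrix(1 / 2, n, 2)

  # exact factorization is a fixed point (numerator = denominator)
  W2 <- grmec:::.mu_update_W(Wt, list(X), list(Vt), w = 1, H, lambda1 = 0)
  expect_equal(W2, Wt, tolerance = 1e-12)
  V2 <- grmec:::.mu_update_V(Wt, list(X), list(Vt))
  expect_equal(V2[[1]], Vt, tolerance = 1e-12)

  # one sweep equals an independently coded classical multiplicative update
  set.seed(6)
  W0 <- matrix(runif(n * k), n, k)
  V0 <- matrix(runif(k * p), k, p)
  W1 <- grmec:::.mu_update_W(W0, list(X), list(V0), w = 1, H, lambda1 = 0)
  V1 <- grmec:::.mu_update_V(W1, list(X), list(V0))
  o <- nmf_oracle_step(W0, V0, X)
  expect_equal(W1, o$W, tolerance = 1e-10)
  expect_equal(V1[[1]], o$V, tolerance = 1e-10)
})

test_that("each factor update does not increase its objective on random instances", {
  for (seed in 1:5) {
    inst <- random_instance(n = 25, m = 2, q = 2, C = 3, p = c(20, 12),
                            seed = seed)
    Xs <- lapply(inst$views, as.matrix)
    st <- rand_state(25, 4, 3, Xs, inst$Slist, seed = seed + 50)
    l1 <- 0.1; l2 <- 0.1
    before <- obj_of(st, Xs, inst$Slist, l1, l2)
    st$W <- grmec:::.mu_update_W(st$W, Xs, st$Vs, st$w, st$H, l1)
    afterW <- obj_of(st, Xs, inst$Slist, l1, l2)
    expect_lte(afterW, before * (1 + 1e-8))
    st$Vs <- grmec:::.mu_update_V(st$W, Xs, st$Vs)
    afterV <- obj_of(st, Xs, inst$Slist, l1, l2)
    expect_lte(afterV, afterW * (1 + 1e-8))
    Dh <- pairwise_sq_dists(st$H)
    st$S <- grmec:::.mu_update_S(st$S, inst$Slist, st$alpha, Dh, l2)
    afterS <- obj_of(st, Xs, inst$Slist, l1, l2)
    expect_lte(afterS, afterV * (1 + 1e-8))
    # every update preserves nonnegativity
    expect_gte(min(st$W), 0)
    expect_gte(min(vapply(st$Vs, min, numeric(1))), 0)
    expect_gte(min(st$S), 0)
  }
})

test_that("S update cancels exactly onto a single base result and onto the weighted mean", {
  set.seed(8)
  n <- 9
  P <- random_labels(n, 3, seed = 8)
  S11 <- cocluster_indicator(P)
  S0 <- matrix(runif(n * n), n, n); S0 <- (S0 + t(S0)) / 2 + 0.1  # strictly positive
  # single base result, lambda2 = 0: one update returns S^11 exactly
  S1 <- grmec:::.mu_update_S(S0, list(S11), alpha = 0.37,
                             Dh = matrix(0, n, n), lambda2 = 0)
  expect_identical(unname(S1), unname(S11))

  # several base results, fixed alpha: one update lands on the closed-form
  # minimizer of the weighted consensus loss, sum(a*S^rv)/sum(a)
  Sl <- lapply(1:3, function(i) cocluster_indicator(random_labels(n, 3, i)))
  a <- c(0.2, 0.5, 0.3)
  S2 <- grmec:::.mu_update_S(S0, Sl, alpha = a, Dh = matrix(0, n, n),
                             lambda2 = 0)
  target <- (a[1] * Sl[[1]] + a[2] * Sl[[2]] + a[3] * Sl[[3]]) / sum(a)
  expect_equal(unname(S2), unname(target), tolerance = 1e-12)
  # and it is a fixed point of further updates wherever positive
  S3 <- grmec:::.mu_update_S(S2, Sl, alpha = a, Dh = matrix(0, n, n),
                             lambda2 = 0)
  expect_equal(S3, S2, tolerance = 1e-12)

  # identical base results: recovered exactly wherever S > 0
  S4 <- grmec:::.mu_update_S(S0, list(S11, S11), alpha = c(0.3, 0.3),
                             Dh = matrix(0, n, n), lambda2 = 0)
  expect_equal(unname(S4), unname(S11), tolerance = 1e-12)
})

test_that("H update keeps rows on the simplex and resets collapsed rows to uniform", {
  set.seed(9)
  n <- 10; C <- 3
  H <- matrix(runif(n * C), n, C); H <- H / rowSums(H)
  S <- cocluster_indicator(random_labels(n, C, 2)) * 1.0
  W <- matrix(runif(n * 4), n, 4)
  up <- grmec:::.mu_update_H(H, S, W, lambda1 = 0.5, lambda2 = 0.2,
                             warn = FALSE)
  expect_equal(unname(rowSums(up$H)), rep(1, n), tolerance = 1e-12)
  expect_gte(min(up$H), 0)
  expect_equal(up$n_reset, 0)

  # lambda2 = 0: numerator vanishes, every row reset to uniform 1/C
  expect_warning(
    up0 <- grmec:::.mu_update_H(H, S, W, lambda1 = 0.5, lambda2 = 0),
    "reset")
  expect_equal(unname(up0$H), matrix(1 / C, n, C))
  expect_equal(up0$n_reset, n)
})

test_that("iterated H updates resolve a strictly block-diagonal affinity into its blocks", {
  # 12 cells in 3 strict blocks (connected components of S)
  z <- rep(0:2, each = 4)
  S <- cocluster_indicator(label_vector(z, cell_ids(12))) * 1.0
  for (seed in 1:10) {
    set.seed(seed)
    W <- (diag(3)[z + 1, ] * 2 + 0.05) *
      matrix(exp(rnorm(12 * 3, 0, 0.05)), 12, 3)  # separated representation
    H <- matrix(runif(12 * 3), 12, 3); H <- H / rowSums(H)
    # lambda1 = 0: pure diffusion on S makes co-clustered cells identical
    Hd <- H
    for (t in 1:200)
      Hd <- grmec:::.mu_update_H(Hd, S, W, lambda1 = 0, lambda2 = 0.1,
                                 warn = FALSE)$H
    for (b in 0:2)
      expect_lt(max(apply(Hd[z == b, , drop = FALSE], 2,
                          function(x) diff(range(x)))), 1e-8)
    # with the representation repulsion active, the argmax partition equals
    # the blocks for every initialization
    Hr <- H
    for (t in 1:200)
      Hr <- grmec:::.mu_update_H(Hr, S, W, lambda1 = 0.1, lambda2 = 0.1,
                                 warn = FALSE)$H
    expect_equal(adjusted_rand_index(
      label_vector(unclass(assign_labels(Hr)), cell_ids(12)),
      label_vector(z, cell_ids(12))), 1)
  }
})

test_that("self-tuned weights follow the inverse-residual rule with flooring", {
  n <- 4; k <- 2; p <- 3
  W <- diag(1, n, k)
  V <- matrix(0, k, p)
  # residual norm 1: X differs from WV=0 by a unit-norm matrix
  X1 <- matrix(0, n, p); X1[1, 1] <- 1
  expect_equal(grmec:::.update_weight_w(W, list(X1), list(V)), 0.5)
  # residual norm 2
  X2 <- matrix(0, n, p); X2[1, 1] <- 2
  expect_equal(grmec:::.update_weight_w(W, list(X2), list(V)), 0.25)
  # exact fit: floored, finite
  expect_equal(grmec:::.update_weight_w(W, list(W %*% V), list(V)),
               1 / (2 * 1e-10))

  S <- diag(4); Sl <- list(diag(4), matrix(1, 4, 4))
  a <- grmec:::.update_weight_alpha(S, Sl)
  expect_equal(a[1], 1 / (2 * 1e-10))              # exact match floored
  expect_equal(a[2], 1 / (2 * sqrt(sum((S - 1)^2))))
  expect_gt(a[1], a[2])                            # closer base result weighs more
})

test_that("fit is deterministic, nonnegative, simplex-constrained and traces a finite objective", {
  inst <- random_instance(n = 20, m = 2, q = 2, C = 3, p = c(15, 10), seed = 2)
  f1 <- grmec(inst$views, inst$base, C = 3, k = 4, seed = 5, max_iter = 20)
  f2 <- grmec(inst$views, inst$base, C = 3, k = 4, seed = 5, max_iter = 20)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_identical(unclass(f1$labels), unclass(f2$labels))

  expect_gte(min(f1$W), 0)
  expect_gte(min(f1$S), 0)
  expect_gte(min(f1$H), 0)
  expect_equal(rowSums(f1$H), setNames(rep(1, 20), rownames(f1$H)),
               tolerance = 1e-12)
  expect_true(all(abs(f1$S - t(f1$S)) < 1e-12))
  expect_true(all(is.finite(f1$objective)))
  expect_length(f1$objective, f1$iterations + 1)

  # random-init variant is also deterministic and nonnegative
  f3 <- grmec(inst$views, inst$base, C = 3, k = 4, seed = 5, max_iter = 10,
              init = "random")
  expect_gte(min(f3$H), 0)
  expect_identical(f3$W,
                   grmec(inst$views, inst$base, C = 3, k = 4, seed = 5,
                         max_iter = 10, init = "random")$W)
})

test_that("objective trace is non-increasing on random instances for a lambda grid", {
  for (seed in 1:3) {
    inst <- random_instance(n = 30, m = 2, q = 2, C = 3, p = c(25, 15),
                            seed = seed)
    for (l1 in c(0, 0.5)) for (l2 in c(0, 0.5)) {
      fit <- suppressWarnings(grmec(inst$views, inst$base, C = 3,
                                    lambda1 = l1, lambda2 = l2, k = 5,
                                    seed = seed, max_iter = 30, tol = 0))
      rel <- diff(fit$objective) / head(fit$objective, -1)
      expect_lte(max(rel), 1e-8)
    }
  }
})

test_that("degenerate limit reproduces classical NMF iterates elementwise", {
  set.seed(20)
  n <- 15; p <- 10; k <- 3
  X <- matrix(runif(n * p), n, p,
              dimnames = list(cell_ids(n), paste0("f", 1:p)))
  set.seed(99)
  W <- matrix(runif(n * k), n, k)
  V <- matrix(runif(k * p), k, p)
  Wo <- W; Vo <- V
  H <- matrix(1 / 2, n, 2)
  for (t in 1:50) {
    W <- grmec:::.mu_update_W(W, list(X), list(V), w = 1, H, lambda1 = 0)
    V <- grmec:::.mu_update_V(W, list(X), list(V))[[1]]
    o <- nmf_oracle_step(Wo, Vo, X)
    Wo <- o$W; Vo <- o$V
    expect_equal(W, Wo, tolerance = 1e-10)
    expect_equal(V, Vo, tolerance = 1e-10)
  }
})

test_that("hard labels take the row argmax with lowest-index tie-breaking", {
  H <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0.0), c(0, 0, 1))
  rownames(H) <- cell_ids(3)
  lv <- assign_labels(H)
  expect_identical(unname(label_values(lv)), c("1", "0", "2"))

  # one-hot H recovers the encoded partition exactly
  z <- c(2, 0, 1, 1, 2)
  Hoh <- diag(3)[z + 1, ]; rownames(Hoh) <- cell_ids(5)
  expect_identical(unname(label_values(assign_labels(Hoh))), as.character(z))
})

test_that("fit validates inputs", {
  inst <- random_instance(n = 10, m = 1, q = 1, C = 2, p = 8, seed = 1)
  expect_error(grmec(inst$views, inst$base, C = 1), "C must satisfy")
  expect_error(grmec(inst$views, inst$base, C = 50), "C must satisfy")
  expect_warning(grmec(inst$views, inst$base, C = 2, k = 40, max_iter = 2),
                 "overparameterized")
})
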