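# Multiplicative-update kernels for the graph-regularized multi-view
# ensemble clustering objective
#
#   L = sum_v w_v ||X^v - W V^v||_F^2 + lambda1 tr(W' L_H W)
#     + sum_{r,v} alpha_rv ||S - S^rv||_F^2 + lambda2 tr(H' L_S H)
#
# with L_H the Laplacian of S_H = H H' and L_S the Laplacian of S.
# Each kernel is a pure function of its inputs; grmec() composes them.
# Denominators are floored with pmax() so the algebraic cancellations of the
# update rules are exact whenever the denominator exceeds the floor.
# The W-update uses the standard graph-NMF Laplacian split (S_H-part in the
# numerator, degree part in the denominator), which preserves nonnegativity
# and has the same fixed points as the raw Laplacian form.

.mu_update_W <- function(W, Xs, Vs, w, H, lambda1, floor = 1e-10) {
  num <- lambda1 * (H %*% crossprod(H, W))          # lambda1 * S_H W, O(nkC)
  den_core <- matrix(0, ncol(W), ncol(W))
  for (v in seq_along(Xs)) {
    num <- num + w[v] * (Xs[[v]] %*% t(Vs[[v]]))
    den_core <- den_core + w[v] * tcrossprod(Vs[[v]])
  }
  dH <- as.vector(H %*% colSums(H))                 # degree of H H'
  den <- W %*% den_core + lambda1 * dH * W
  Wn <- W * num / pmax(den, floor)
  if (!all(is.finite(Wn)))
    stop("nonfinite result in W update", call. = FALSE)
  Wn
}

.mu_update_V <- function(W, Xs, Vs, floor = 1e-10) {
  WtW <- crossprod(W)
  out <- Vs
  for (v in seq_along(Xs)) {
    Vn <- Vs[[v]] * crossprod(W, Xs[[v]]) / pmax(WtW %*% Vs[[v]], floor)
    if (!all(is.finite(Vn)))
      stop("nonfinite result in V update (view ", v, ")", call. = FALSE)
    out[[v]] <- Vn
  }
  out
}

.mu_update_S <- function(S, Slist, alpha, Dh, lambda2, floor = 1e-10) {
  num <- matrix(0, nrow(S), ncol(S))
  for (i in seq_along(Slist)) num <- num + alpha[i] * Slist[[i]]
  num <- 4 * num
  den <- 4 * sum(alpha) * S + lambda2 * Dh
  Sn <- S * num / pmax(den, floor)
  Sn <- (Sn + t(Sn)) / 2
  if (!all(is.finite(Sn)))
    stop("nonfinite result in S update", call. = FALSE)
  Sn
}

# Returns list(H = row-stochastic matrix, n_reset = rows that collapsed to
# zero before unitization and were reset to the uniform 1/C distribution).
.mu_update_H <- function(H, S, W, lambda1, lambda2, floor = 1e-10,
                         warn = TRUE) {
  DW <- pairwise_sq_dists(W)
  dS <- rowSums(S)
  num <- lambda2 * (S %*% H)
  den <- (lambda1 / 2) * (DW %*% H) + lambda2 * dS * H
  Hn <- H * num / pmax(den, floor)
  rs <- rowSums(Hn)
  zero <- rs <= 0 | !is.finite(rs)
  if (any(zero)) {
    Hn[zero, ] <- 1 / ncol(H)
    rs[zero] <- 1
    if (warn)
      warning(sum(zero), " row(s) of H collapsed to zero and were reset to ",
              "uniform", call. = FALSE)
  }
  Hn <- Hn / rs
  if (!all(is.finite(Hn)))
    stop("nonfinite result in H update", call. = FALSE)
  list(H = Hn, n_reset = sum(zero))
}

# Self-tuned weights: w_v = 1 / (2 ||X^v - W V^v||_F), floored at
# residual_floor so an exact fit stays finite.
.update_weight_w <- function(W, Xs, Vs, residual_floor = 1e-10) {
  vapply(seq_along(Xs), function(v) {
    1 / (2 * max(.frob(Xs[[v]] - W %*% Vs[[v]]), residual_floor))
  }, numeric(1))
}

# alpha_rv = 1 / (2 ||S - S^rv||_F), same flooring.
.update_weight_alpha <- function(S, Slist, residual_floor = 1e-10) {
  vapply(Slist, function(Si) {
    1 / (2 * max(.frob(S - Si), residual_floor))
  }, numeric(1))
}

# Full objective; graph terms use the trace identities
#   tr(W' L_H W) = sum_i dH_i ||W_i.||^2 - ||H'W||_F^2
#   tr(H' L_S H) = sum_i dS_i ||H_i.||^2 - tr(H' S H)
# avoiding any n x n intermediate for the H-graph coupling.
.objective <- function(W, Xs, Vs, w, H, S, Slist, alpha, lambda1, lambda2) {
  rec <- 0
  for (v in seq_along(Xs)) rec <- rec + w[v] * sum((Xs[[v]] - W %*% Vs[[v]])^2)
  dH <- as.vector(H %*% colSums(H))
  g1 <- lambda1 * (sum(dH * rowSums(W^2)) - sum(crossprod(H, W)^2))
  cons <- 0
  for (i in seq_along(Slist)) cons <- cons + alpha[i] * sum((S - Slist[[i]])^2)
  dS <- rowSums(S)
  g2 <- lambda2 * (sum(dS * rowSums(H^2)) - sum(H * (S %*% H)))
  terms <- c(reconstruction = rec, graph_W = g1, consensus = cons,
             graph_H = g2)
  bad <- !is.finite(terms)
  if (any(bad))
    stop("nonfinite objective term: ", paste(names(terms)[bad], collapse = ", "),
         call. = FALSE)
  list(total = sum(terms), terms = terms)
}
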