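# Small deterministic fixtures shared across test files.

cell_ids <- function(n) sprintf("cell%02d", seq_len(n))

# tiny dense view with named cells/features
tiny_view <- function(n = 4, p = 3, seed = 1, view_name = "rna") {
  set.seed(seed)
  X <- matrix(rpois(n * p, lambda = 5), n, p,
              dimnames = list(cell_ids(n), sprintf("%s_f%d", view_name, 1:p)))
  X <- X * 1.0
  attr(X, "view_name") <- view_name
  X
}

# pair of aligned views over the same cells
tiny_dataset <- function(n = 6, seed = 1) {
  align_views(list(rna = tiny_view(n, 5, seed, "rna"),
                   adt = tiny_view(n, 3, seed + 100, "adt")))
}

# random partition as a label_vector
random_labels <- function(n, C, seed = 1) {
  set.seed(seed)
  label_vector(sample(0:(C - 1), n, replace = TRUE), cell_ids(n))
}

# independently coded ARI from the contingency-table formula (oracle)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  den <- (sa + sb) / 2 - e
  if (den == 0) return(1)
  (sij - e) / den
}

# independently coded NMI (arithmetic-mean normalization) from entropies
nmi_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  hx <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- hx(rowSums(tab) / n)
  hb <- hx(colSums(tab) / n)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0)
      mi <- mi + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  mi / ((ha + hb) / 2)
}

# classical multiplicative-update NMF (Lee & Seung), independent oracle
nmf_oracle_step <- function(W, V, X, floor = 1e-10) {
  W <- W * (X %*% t(V)) / pmax(W %*% V %*% t(V), floor)
  V <- V * (t(W) %*% X) / pmax(t(W) %*% W %*% V, floor)
  list(W = W, V = V)
}

# random solver instance: views, base set, co-cluster list
random_instance <- function(n = 30, m = 2, q = 2, C = 3, p = c(40, 20),
                            seed = 1) {
  set.seed(seed)
  ids <- cell_ids(n)
  views <- lapply(seq_len(m), function(v) {
    X <- matrix(runif(n * p[v]), n, p[v],
                dimnames = list(ids, sprintf("v%d_f%d", v, seq_len(p[v]))))
    X
  })
  names(views) <- paste0("view", seq_len(m))
  labs <- lapply(seq_len(q * m), function(i)
    label_vector(sample(0:(C - 1), n, replace = TRUE), ids))
  base <- base_clustering_set(labs,
                              methods = rep(paste0("m", seq_len(q)), m),
                              views = rep(paste0("view", seq_len(m)), each = q))
  list(views = structure(views, class = "multiomics"), base = base,
       Slist = lapply(base$labelings, cocluster_indicator))
}
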