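# Independent oracles and small fixtures shared across the test files.
# Everything here is deliberately written as plain loops / textbook
# formulas, independent of the package's matrix-form implementations.

# minimal two-reaction chain: R1 takes up X1, R2 secretes it
chain_model <- function(uptake_ub = 10) {
  metabolic_model(
    metabolite_ids = "X1",
    reaction_ids = c("R1", "R2"),
    S = matrix(c(1, -1), 1, 2),
    reversible = c(FALSE, FALSE),
    lb = c(0, 0), ub = c(uptake_ub, 1000),
    objective = c(0, 1))
}

# unfolded production/consumption coefficients, recomputed from scratch
unfold_coeffs <- function(model) {
  n <- nrow(model$S); m <- ncol(model$S)
  cols <- vector("list", 2 * m)
  for (j in seq_len(m)) {
    cols[[j]] <- model$S[, j]
    cols[[m + j]] <- if (model$reversible[j]) -model$S[, j] else rep(0, n)
  }
  S2m <- do.call(cbind, cols)
  list(splus = pmax(S2m, 0), sminus = pmax(-S2m, 0))
}

# Eq.-by-eq. triple-loop evaluation of the normalised flow graph
nfg_bruteforce <- function(model) {
  uc <- unfold_coeffs(model)
  n <- nrow(model$S); m2 <- ncol(uc$splus)
  D <- matrix(0, m2, m2)
  for (k in seq_len(n)) {
    wp <- sum(uc$splus[k, ]); wm <- sum(uc$sminus[k, ])
    if (wp == 0 || wm == 0) next
    for (i in seq_len(m2)) {
      if (uc$splus[k, i] == 0) next
      for (j in seq_len(m2)) {
        D[i, j] <- D[i, j] + (uc$splus[k, i] / wp) * (uc$sminus[k, j] / wm) / n
      }
    }
  }
  D
}

# triple-loop mass flow graph from a balanced flux vector
mfg_bruteforce <- function(model, v) {
  uc <- unfold_coeffs(model)
  n <- nrow(model$S); m <- ncol(model$S)
  v2m <- c(pmax(v, 0), pmax(-v, 0))
  M <- matrix(0, 2 * m, 2 * m)
  for (k in seq_len(n)) {
    cons_tot <- sum(uc$sminus[k, ] * v2m)
    if (cons_tot <= 0) next
    for (i in seq_len(2 * m)) {
      prod_ki <- uc$splus[k, i] * v2m[i]
      if (prod_ki == 0) next
      for (j in seq_len(2 * m)) {
        M[i, j] <- M[i, j] + prod_ki * uc$sminus[k, j] * v2m[j] / cons_tot
      }
    }
  }
  M
}

# matrix exponential by scaling + Taylor series (independent of Matrix::expm)
expm_taylor <- function(A) {
  k <- max(0, ceiling(log2(max(1e-300, norm(A, "1")))) + 4)
  B <- A / 2^k
  E <- diag(nrow(A)); term <- diag(nrow(A))
  for (i in 1:40) {
    term <- term %*% B / i
    E <- E + term
  }
  for (i in seq_len(k)) E <- E %*% E
  E
}

# teleported walk pieces built with explicit loops
walk_pieces <- function(W, lambda = 0.85) {
  N <- nrow(W)
  B <- matrix(0, N, N)
  for (i in seq_len(N)) {
    k <- sum(W[i, ])
    for (j in seq_len(N)) {
      B[i, j] <- lambda * (if (k > 0) W[i, j] / k else 0) +
        ((1 - lambda) + lambda * (k == 0)) / N
    }
  }
  # stationary distribution from the null space of (B' - I)
  A <- rbind(t(B) - diag(N), rep(1, N))
  pi <- qr.solve(A, c(rep(0, N), 1))
  list(B = B, pi = pi)
}

# dense independent evaluation of the Markov stability of one partition
stability_bruteforce <- function(W, partition, t, lambda = 0.85) {
  wp <- walk_pieces(W, lambda)
  P <- expm_taylor(-t * (diag(nrow(W)) - wp$B))
  r <- 0
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(nrow(W))) {
      if (partition[i] == partition[j]) {
        r <- r + wp$pi[i] * P[i, j] - wp$pi[i] * wp$pi[j]
      }
    }
  }
  r
}

# all set partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (c in seq_len(next_max + 1L)) {
      recurse(c(labels, c), max(next_max, c))
    }
  }
  recurse(integer(0), 0L)
  out
}

random_partition <- function(n, C) {
  p <- sample.int(C, n, replace = TRUE)
  match(p, unique(p))
}

# small weighted directed graph helper
random_digraph <- function(N, density = 0.4, seed = 1) {
  set.seed(seed)
  W <- matrix(stats::runif(N * N), N, N) * (matrix(stats::runif(N * N), N, N) < density)
  diag(W) <- 0
  W
}
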