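#' Continuous-time Markov process underlying stability analysis
#'
#' Builds, once per graph, the ingredients shared by all Markov Stability
#' computations: the teleporting transition matrix `B`
#' ([transition_matrix()]; the same teleportation `lambda` as PageRank is
#' the single source of truth), the rate matrix `L = I - B` of the
#' continuous-time process `dx/dt = -L' x`, and its stationary
#' distribution `pi` (the leading left eigenvector of `B`).
#'
#' @param graph a `reaction_graph` or non-negative weight matrix.
#' @param lambda teleportation retention probability (default 0.85).
#' @return An object of class `stability_process`.
#' @export
stability_process <- function(graph, lambda = 0.85) {
  B <- transition_matrix(graph, lambda)
  pr <- pagerank(graph, lambda = lambda, tol = 1e-14)
  structure(list(B = B, L = diag(nrow(B)) - B, pi = unname(pr$scores),
                 node_ids = names(pr$scores), lambda = lambda),
            class = "stability_process")
}

# Pi %*% P(t) - pi pi', the matrix whose clustered trace is r(t, H).
# P(t) = expm(-t (I - B)) is the row-oriented transition kernel, so entry
# (i, j) of Pi P(t) is the probability that a stationary walker is in i now
# and in j a Markov time t later.
stability_matrix <- function(proc, t) {
  stopifnot(inherits(proc, "stability_process"), t >= 0)
  P <- as.matrix(Matrix::expm(-t * proc$L))
  if (any(!is.finite(P))) {
    stop("matrix exponential overflowed at t = ", t,
         " (condition of L too poor)", call. = FALSE)
  }
  proc$pi * P - tcrossprod(proc$pi)
}

as_partition <- function(assignment, node_ids = NULL) {
  p <- as.integer(assignment)
  if (anyNA(p)) stop("partition contains NA assignments", call. = FALSE)
  p <- match(p, unique(p))  # compact labels 1..C
  if (!is.null(node_ids)) names(p) <- node_ids
  p
}

partition_onehot <- function(partition) {
  C <- max(partition)
  H <- matrix(0, length(partition), C)
  H[cbind(seq_along(partition), partition)] <- 1
  H
}

#' Clustered autocovariance and Markov Stability of a partition
#'
#' For a partition encoded as the one-hot matrix `H`, the clustered
#' autocovariance of the teleporting Markov process at Markov time `t` is
#' `R(t, H) = H' (Pi P(t) - pi pi') H` with `P(t) = expm(-t (I - B))`
#' the transition kernel; its trace is the Markov
#' Stability `r(t, H)`, which measures how well the communities retain
#' probability flow over time scale `t`. At `t = 0` the all-singleton
#' partition attains `1 - sum(pi^2)`; the one-community partition scores 0
#' at every `t`; and `r -> 0` as `t -> Inf` for any partition.
#'
#' @param graph a `reaction_graph` or weight matrix (ignored when `proc`
#'   is supplied).
#' @param partition integer community labels, one per node.
#' @param t Markov time, `>= 0`.
#' @param lambda teleportation retention (default 0.85).
#' @param proc optionally a precomputed [stability_process()].
#' @return `autocovariance()`: a C x C matrix; `stability()`: its trace.
#' @export
autocovariance <- function(graph, partition, t, lambda = 0.85, proc = NULL) {
  if (is.null(proc)) proc <- stability_process(graph, lambda)
  p <- as_partition(partition)
  if (length(p) != nrow(proc$B)) {
    stop("partition length does not match the graph", call. = FALSE)
  }
  H <- partition_onehot(p)
  Fm <- stability_matrix(proc, t)
  crossprod(H, Fm %*% H)
}

#' @rdname autocovariance
#' @export
stability <- function(graph, partition, t, lambda = 0.85, proc = NULL) {
  sum(diag(autocovariance(graph, partition, t, lambda, proc)))
}

partition_quality <- function(Fm, p) {
  A1 <- rowsum(Fm, p, reorder = FALSE)
  A2 <- rowsum(t(A1), p, reorder = FALSE)
  sum(diag(as.matrix(A2)[seq_len(max(p)), seq_len(max(p)), drop = FALSE]))
}

#' Optimise Markov Stability with the Louvain heuristic
#'
#' Greedy multi-level Louvain optimisation of `r(t, H)` at a fixed Markov
#' time. The objective matrix `Pi P(t) - pi pi'` is symmetrised
#' first (the trace of the clustered autocovariance is invariant under
#' symmetrisation), then node moves and aggregation phases are applied
#' until no strictly improving move remains. The optimisation is a
#' heuristic for an NP-hard problem; running it from many seeds and
#' keeping the best result is what [scan_stability()] automates.
#'
#' @param graph a `reaction_graph` or weight matrix.
#' @param t Markov time, `> 0` (at `t -> 0` the optimum approaches the
#'   all-singleton partition).
#' @param seed integer seed controlling the node sweep order; the result
#'   is deterministic given the seed.
#' @param lambda teleportation retention (default 0.85).
#' @param proc optional precomputed [stability_process()].
#' @return named integer vector of community labels (1..C).
#' @export
louvain_optimise <- function(graph, t, seed = 1L, lambda = 0.85, proc = NULL) {
  if (is.null(proc)) proc <- stability_process(graph, lambda)
  Fm <- stability_matrix(proc, t)
  Fs <- (Fm + t(Fm)) / 2
  p <- .louvain_cpp(Fs, as.numeric(seed))
  as_partition(p, proc$node_ids)
}

#' Normalised variation of information between two partitions
#'
#' `VI = (2 * H(P, P') - H(P) - H(P')) / log(n)` where `H` denotes the
#' Shannon entropy of community frequencies (joint entropy for the pair).
#' The normalisation by `log(n)` bounds VI in [0, 1]: 0 for identical
#' partitions, 1 between the all-singleton and the one-community
#' partition. VI is a metric on the space of partitions.
#'
#' @param p,p2 integer community labels over the same node set, n >= 2.
#' @return a scalar in [0, 1].
#' @export
variation_of_information <- function(p, p2) {
  p <- as_partition(p); p2 <- as_partition(p2)
  n <- length(p)
  if (length(p2) != n) stop("partitions are over different node sets", call. = FALSE)
  if (n < 2) stop("variation of information needs at least 2 nodes", call. = FALSE)
  C1 <- max(p); C2 <- max(p2)
  joint <- tabulate((p - 1L) * C2 + p2, C1 * C2) / n
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  vi <- (2 * ent(joint) - ent(tabulate(p, C1) / n) - ent(tabulate(p2, C2) / n)) / log(n)
  max(0, vi)  # clip the tiny negative float noise of identical partitions
}

#' Mean pairwise variation of information of an ensemble
#'
#' Average VI over all pairs of partitions from repeated optimisations;
#' low values mean the optimiser lands on essentially the same partition
#' from every seed. Defined as 0 for an ensemble of size 1.
#'
#' @param partitions list of integer label vectors over one node set.
#' @return a scalar in [0, 1].
#' @export
ensemble_vi <- function(partitions) {
  l <- length(partitions)
  if (l < 2) return(0)
  tot <- 0
  for (i in seq_len(l - 1)) {
    for (j in (i + 1):l) {
      tot <- tot + variation_of_information(partitions[[i]], partitions[[j]])
    }
  }
  tot / (l * (l - 1) / 2)
}

#' Scan community structure across Markov times
#'
#' At each Markov time of a (log-spaced) grid, runs `n_repeats` seeded
#' Louvain optimisations of the stability objective, keeps the
#' best-stability partition, and records the ensemble mean variation of
#' information `VI(t)` (robustness to the optimiser) plus the cross-time
#' matrix `VI(t, t')` between the best partitions (robustness across
#' scales). Small `t` resolves fine partitions, large `t` coarse ones;
#' relevant partitions show as dips of `VI(t)` and extended low plateaux
#' of `VI(t, t')` -- see [robust_partitions()].
#'
#' @param graph a `reaction_graph` or non-negative weight matrix.
#' @param times increasing positive Markov times; default 100 log-spaced
#'   points on `[1e-2, 1e2]`.
#' @param n_repeats Louvain runs per time (default 100).
#' @param seed integer; run seeds are derived deterministically from it.
#' @param lambda teleportation retention (default 0.85).
#' @param propagate after the per-time optimisations, sweep forward and
#'   backward across the grid re-evaluating each time's best partition at
#'   its neighbours and keeping it when it scores higher (default TRUE).
#'   Louvain is a greedy heuristic, so a partition found at one Markov
#'   time is often the better optimum at adjacent times too; propagation
#'   stabilises the best-partition sequence without touching `VI(t)`,
#'   which always reflects the raw ensemble.
#' @return An object of class `stability_scan`: `times`, `partitions`
#'   (N x length(times) matrix of best labels), `n_communities`, `r`
#'   (best stability per time), `vi`, `vi_cross`, `n_repeats`, `seed`.
#' @export
scan_stability <- function(graph, times = NULL, n_repeats = 100, seed = 1L,
                           lambda = 0.85, propagate = TRUE) {
  if (is.null(times)) times <- 10^seq(-2, 2, length.out = 100)
  stopifnot(all(times > 0), !is.unsorted(times), n_repeats >= 1)
  proc <- stability_process(graph, lambda)
  N <- nrow(proc$B)
  nt <- length(times)
  parts <- matrix(NA_integer_, N, nt,
                  dimnames = list(proc$node_ids, NULL))
  r_best <- numeric(nt)
  vi_t <- numeric(nt)
  Fs_all <- vector("list", nt)
  for (ti in seq_len(nt)) {
    Fm <- stability_matrix(proc, times[ti])
    Fs <- (Fm + t(Fm)) / 2
    Fs_all[[ti]] <- Fs
    ensemble <- vector("list", n_repeats)
    quals <- numeric(n_repeats)
    for (rep in seq_len(n_repeats)) {
      p <- as_partition(.louvain_cpp(Fs, as.numeric(seed) * 1e6 + ti * 1e3 + rep))
      ensemble[[rep]] <- p
      quals[rep] <- partition_quality(Fs, p)
    }
    best <- which.max(quals)
    parts[, ti] <- ensemble[[best]]
    r_best[ti] <- quals[best]
    vi_t[ti] <- ensemble_vi(ensemble)
  }
  if (propagate && nt > 1) {
    for (sweep in 1:2) {
      order_ti <- if (sweep == 1) 2:nt else (nt - 1):1
      for (ti in order_ti) {
        nb <- if (sweep == 1) ti - 1L else ti + 1L
        q_nb <- partition_quality(Fs_all[[ti]], parts[, nb])
        if (q_nb > r_best[ti]) {
          parts[, ti] <- parts[, nb]
          r_best[ti] <- q_nb
        }
      }
    }
  }
  vi_cross <- matrix(0, nt, nt)
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      vi_cross[i, j] <- vi_cross[j, i] <-
        variation_of_information(parts[, i], parts[, j])
    }
  }
  structure(list(times = times, partitions = parts,
                 n_communities = apply(parts, 2, max),
                 r = r_best, vi = vi_t, vi_cross = vi_cross,
                 n_repeats = n_repeats, seed = seed, lambda = lambda),
            class = "stability_scan")
}

#' @export
print.stability_scan <- function(x, ...) {
  cat("<stability_scan> ", length(x$times), " Markov times in [",
      format(min(x$times)), ", ", format(max(x$times)), "], ",
      x$n_repeats, " repeats\n", sep = "")
  cat("  community counts: ", paste(rle(as.vector(x$n_communities))$values,
                                    collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Select robust partitions from a stability scan
#'
#' A Markov time `t` is flagged robust when (a) the optimiser is
#' consistent there -- the ensemble `VI(t)` is below `vi_threshold` --
#' and (b) its best partition persists across scales: the contiguous run
#' of grid points `t'` around `t` with cross-time
#' `VI(t, t') < vi_threshold` spans at least `min_plateau` points. The
#' plateau is judged on the cross-time VI itself, not on the community
#' count, so a level whose count wobbles by a splinter community still
#' forms one plateau. Contiguous flagged times with the same community
#' count are collapsed into one reported level. The thresholds are
#' heuristics for what a practitioner selects by inspecting the
#' `VI(t)` curve and the `VI(t, t')` map.
#'
#' @param scan a [scan_stability()] result.
#' @param vi_threshold VI dip / plateau threshold (default 0.05).
#' @param min_plateau minimal plateau length, in grid points (default 5).
#' @return data frame with one row per robust level: `n_communities`,
#'   `t_start`, `t_end`, `t_best` (lowest-VI flagged time of the level),
#'   `plateau_len` (longest plateau among the level's times), `vi_min`.
#' @export
robust_partitions <- function(scan, vi_threshold = 0.05, min_plateau = 5) {
  stopifnot(inherits(scan, "stability_scan"))
  nt <- length(scan$times)
  nc <- scan$n_communities
  plen <- integer(nt)
  for (ti in seq_len(nt)) {
    lo <- ti
    while (lo > 1L && scan$vi_cross[ti, lo - 1L] < vi_threshold) lo <- lo - 1L
    hi <- ti
    while (hi < nt && scan$vi_cross[ti, hi + 1L] < vi_threshold) hi <- hi + 1L
    plen[ti] <- hi - lo + 1L
  }
  flagged <- scan$vi < vi_threshold & plen >= min_plateau
  out <- list()
  i <- 1L
  while (i <= nt) {
    if (!flagged[i]) { i <- i + 1L; next }
    j <- i
    while (j < nt && flagged[j + 1L] && nc[j + 1L] == nc[i]) j <- j + 1L
    run <- i:j
    tb <- run[which.min(scan$vi[run])]
    out[[length(out) + 1L]] <- data.frame(
      n_communities = nc[i],
      t_start = scan$times[i], t_end = scan$times[j],
      t_best = scan$times[tb],
      plateau_len = max(plen[run]), vi_min = min(scan$vi[run]))
    i <- j + 1L
  }
  if (!length(out)) {
    return(data.frame(n_communities = integer(), t_start = numeric(),
                      t_end = numeric(), t_best = numeric(),
                      plateau_len = integer(), vi_min = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pathway-by-community contingency table
#'
#' Cross-tabulates the pathway annotation of graph nodes against a
#' partition -- a tabular account of which pathways compose each
#' community.
#'
#' @param graph a `reaction_graph` with subsystem labels.
#' @param partition integer community labels over the graph's nodes.
#' @return a contingency table (pathways x communities).
#' @export
pathway_community_table <- function(graph, partition) {
  stopifnot(inherits(graph, "reaction_graph"))
  p <- as_partition(partition)
  stopifnot(length(p) == nrow(graph$nodes))
  table(pathway = graph$nodes$subsystem, community = p)
}
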