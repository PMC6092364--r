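#' Toy metabolic network
#'
#' An 8-reaction, 5-metabolite network describing nutrient uptake,
#' biosynthesis of metabolic intermediates, secretion of waste products and
#' biomass production. The biomass reaction is `R8: X3 + 2 X4 + X5 ->`, and
#' `R4` (`X2 <-> X4`) is the only reversible reaction. The remaining
#' stoichiometry is a reconstruction consistent with those facts and with
#' the stated roles of the reactions (the originating figure's full
#' supplementary stoichiometry is not redistributed here):
#'
#' \preformatted{
#'   R1:  -> X1        (nutrient uptake, ub 10)
#'   R2: X1 -> X2
#'   R3: X2 -> X3
#'   R4: X2 <-> X4     (reversible)
#'   R5: X3 -> X5
#'   R6: X5 ->         (waste secretion)
#'   R7: X4 ->         (waste secretion)
#'   R8: X3 + 2 X4 + X5 ->   (biomass, the FBA objective)
#' }
#'
#' Every metabolite is both produced and consumed by the unfolded reaction
#' set, so the Normalised Flow Graph of this model sums to exactly 1.
#'
#' @return A [metabolic_model()].
#' @export
toy_network <- function() {
  mets <- paste0("X", 1:5)
  rxns <- paste0("R", 1:8)
  S <- matrix(0, 5, 8, dimnames = list(mets, rxns))
  S["X1", "R1"] <- 1
  S["X1", "R2"] <- -1; S["X2", "R2"] <- 1
  S["X2", "R3"] <- -1; S["X3", "R3"] <- 1
  S["X2", "R4"] <- -1; S["X4", "R4"] <- 1
  S["X3", "R5"] <- -1; S["X5", "R5"] <- 1
  S["X5", "R6"] <- -1
  S["X4", "R7"] <- -1
  S["X3", "R8"] <- -1; S["X4", "R8"] <- -2; S["X5", "R8"] <- -1
  rev <- rxns == "R4"
  lb <- ifelse(rev, -1000, 0)
  ub <- rep(1000, 8); ub[1] <- 10
  obj <- as.numeric(rxns == "R8")
  subsys <- stats::setNames(c("Uptake", "Biosynthesis", "Biosynthesis",
                              "Biosynthesis", "Biosynthesis", "Secretion",
                              "Secretion", "Biomass"), rxns)
  metabolic_model(mets, rxns, S, rev, lb, ub, obj, subsystem = subsys)
}

#' Generate a random sparse metabolic model
#'
#' Draws a random signed stoichiometric matrix with integer coefficients in
#' \{1, 2\} and the requested density, then (optionally) repairs rows so
#' every metabolite has at least one producing and one consuming unfolded
#' reaction column -- the condition under which the Normalised Flow Graph
#' sums to exactly 1. Reversible reactions get symmetric bounds
#' `[-10, 10]`, irreversible ones `[0, 10]`.
#'
#' @param n_metabolites,n_reactions model dimensions.
#' @param density expected fraction of non-zero stoichiometric entries, in
#'   (0, 1].
#' @param fraction_reversible fraction of reactions drawn reversible.
#' @param seed integer seed; the same seed reproduces the model exactly.
#' @param ensure_flow repair rows so each metabolite is both produced and
#'   consumed after unfolding (default TRUE).
#' @return A [metabolic_model()].
#' @export
random_model <- function(n_metabolites, n_reactions, density = 0.3,
                         fraction_reversible = 0.5, seed = 1L,
                         ensure_flow = TRUE) {
  stopifnot(density > 0, density <= 1,
            fraction_reversible >= 0, fraction_reversible <= 1,
            n_metabolites >= 1, n_reactions >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- n_metabolites; m <- n_reactions
  S <- matrix(0, n, m)
  nz <- stats::runif(n * m) < density
  S[nz] <- sample(c(-2L, -1L, 1L, 2L), sum(nz), replace = TRUE)
  rev <- stats::runif(m) < fraction_reversible
  if (ensure_flow) {
    for (i in seq_len(n)) {
      # a reversible column covers both roles once unfolded
      has_prod <- any(S[i, ] > 0) || any(S[i, ] != 0 & rev)
      if (!has_prod) {
        zc <- which(S[i, ] == 0)
        if (length(zc)) S[i, zc[sample.int(length(zc), 1L)]] <- 1
        else rev[which(S[i, ] != 0)[1]] <- TRUE
      }
      has_cons <- any(S[i, ] < 0) || any(S[i, ] != 0 & rev)
      if (!has_cons) {
        zc <- which(S[i, ] == 0)
        if (length(zc)) S[i, zc[sample.int(length(zc), 1L)]] <- -1
        else rev[which(S[i, ] != 0)[1]] <- TRUE
      }
    }
  }
  # no empty reaction column
  for (j in which(colSums(abs(S)) == 0)) S[sample.int(n, 1), j] <- 1
  lb <- ifelse(rev, -10, 0)
  ub <- rep(10, m)
  metabolic_model(paste0("X", seq_len(n)), paste0("R", seq_len(m)),
                  S, rev, lb, ub)
}

#' Draw a random balanced flux vector
#'
#' Samples a flux vector from the null space of the stoichiometric matrix,
#' so `S v = 0` holds to machine precision, then scales it into the flux
#' bounds. Components whose sign constraint (irreversible reactions cannot
#' run backwards) is violated by the draw are projected out by restricting
#' the null space, iterating until the vector is feasible.
#'
#' @param model a [metabolic_model()].
#' @param seed integer seed.
#' @return A length-m flux vector `v` with `S v = 0` and
#'   `lb <= v <= ub`.
#' @export
random_balanced_flux <- function(model, seed = 1L) {
  stopifnot(inherits(model, "metabolic_model"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  m <- n_reactions(model)
  Scon <- model$S
  repeat {
    N <- null_space(Scon)
    if (ncol(N) == 0) {
      stop("model has no non-trivial balanced flux (empty null space ",
           "after sign restrictions)", call. = FALSE)
    }
    v <- as.vector(N %*% stats::rnorm(ncol(N)))
    bad <- (!model$reversible & v < -1e-10) |
           (model$lb >= 0 & v < -1e-10) | (model$ub <= 0 & v > 1e-10)
    if (!any(bad)) break
    # flip helps when most violations share a sign
    if (sum(bad) > sum((!model$reversible & -v < -1e-10))) {
      v2 <- -v
      bad2 <- (!model$reversible & v2 < -1e-10) |
              (model$lb >= 0 & v2 < -1e-10) | (model$ub <= 0 & v2 > 1e-10)
      if (!any(bad2)) { v <- v2; break }
    }
    Scon <- rbind(Scon, diag(m)[which(bad)[1], , drop = FALSE])
  }
  # scale into bounds
  up <- ifelse(v > 0, model$ub / v, ifelse(v < 0, model$lb / v, Inf))
  alpha <- min(1, 0.9 * min(up))
  v * alpha
}

null_space <- function(A, tol = 1e-10) {
  s <- svd(A, nu = 0, nv = ncol(A))
  d <- c(s$d, rep(0, ncol(A) - length(s$d)))
  s$v[, d < tol * max(1, d[1]), drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
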