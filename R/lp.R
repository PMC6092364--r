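#' Solve a bounded-variable linear programme
#'
#' Maximises `obj' x` subject to `A x = b` and `lb <= x <= ub` with a
#' two-phase primal simplex on bounded variables. Entering and leaving
#' variables are chosen by Bland's smallest-index rule, which guarantees
#' termination on the highly degenerate linear programmes that flux balance
#' problems produce (stoichiometric matrices are rank deficient and FBA
#' optima sit on degenerate vertices). Redundant equality rows are removed
#' by QR factorisation before the solve; consistency of the full system is
#' re-checked on the returned vertex.
#'
#' This is deterministic: the same inputs always return the same vertex
#' solution.
#'
#' @param obj length-n objective vector.
#' @param A meq x n constraint matrix.
#' @param b length-meq right-hand side.
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize maximise (default) or minimise.
#' @param tol feasibility/optimality tolerance on reduced costs and bound
#'   violations.
#' @param max_iter iteration cap across both phases.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, or
#'   `"unbounded"`), `x` (the vertex solution, `NULL` unless optimal), and
#'   `value` (objective at `x`).
#' @export
simplex_lp <- function(obj, A, b, lb, ub, maximize = TRUE,
                       tol = 1e-9, max_iter = 50000L) {
  n <- length(obj)
  A <- as.matrix(A); storage.mode(A) <- "double"
  if (ncol(A) != n) stop("ncol(A) must equal length(obj)", call. = FALSE)
  b <- as.numeric(b)
  stopifnot(length(b) == nrow(A), length(lb) == n, length(ub) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  sgn <- if (maximize) 1 else -1
  A_full <- A; b_full <- b

  # drop linearly dependent rows (consistency re-checked at the end)
  if (nrow(A) > 0) {
    qrt <- qr(t(A))
    keep <- qrt$pivot[seq_len(qrt$rank)]
    A <- A[keep, , drop = FALSE]
    b <- b[keep]
  }
  meq <- nrow(A)

  if (meq == 0L) {
    # bounds-only problem: each variable sits at its favourable bound
    x <- ifelse(sgn * obj > tol, ub, ifelse(sgn * obj < -tol, lb,
                ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))))
    if (any(!is.finite(x) & abs(obj) > tol)) {
      return(list(status = "unbounded", x = NULL, value = NA_real_))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", x = x, value = sum(obj * x)))
  }

  ntot <- n + meq
  lball <- c(lb, rep(0, meq))
  uball <- c(ub, rep(Inf, meq))
  # start each structural variable at a finite bound (0 if free)
  x <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  r0 <- b - as.vector(A %*% x)
  art_sign <- ifelse(r0 >= 0, 1, -1)
  Aext <- cbind(A, diag(art_sign, meq))
  xall <- c(x, abs(r0))
  basis <- n + seq_len(meq)
  in_basis <- rep(FALSE, ntot); in_basis[basis] <- TRUE

  run_phase <- function(cvec, xall, basis, in_basis, iter_left) {
    piv_tol <- 1e-10
    repeat {
      if (iter_left <= 0L) {
        stop("simplex iteration limit reached; increase max_iter", call. = FALSE)
      }
      B <- Aext[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
      if (is.null(y)) stop("singular basis encountered in simplex", call. = FALSE)
      entering <- 0L; dir_up <- TRUE
      for (j in seq_len(ntot)) {       # Bland: smallest eligible index
        if (in_basis[j]) next
        if (lball[j] == uball[j]) next # fixed variable, never enters
        dj <- cvec[j] - sum(y * Aext[, j])
        at_lb <- is.finite(lball[j]) && abs(xall[j] - lball[j]) <= 1e-7 * (1 + abs(lball[j]))
        at_ub <- is.finite(uball[j]) && abs(xall[j] - uball[j]) <= 1e-7 * (1 + abs(uball[j]))
        free <- !at_lb && !at_ub
        if ((at_lb || free) && dj > tol) { entering <- j; dir_up <- TRUE; break }
        if ((at_ub || free) && dj < -tol) { entering <- j; dir_up <- FALSE; break }
      }
      if (entering == 0L) {
        return(list(xall = xall, basis = basis, in_basis = in_basis,
                    status = "optimal", iter_left = iter_left))
      }
      s <- if (dir_up) 1 else -1
      w <- solve(B, Aext[, entering])
      # basic values move as xB - delta * s * w; entering moves by s * delta
      delta <- Inf; leave_pos <- 0L; leave_to <- NA_character_
      for (i in seq_len(meq)) {
        vi <- basis[i]; swi <- s * w[i]
        if (swi > piv_tol) {
          if (is.finite(lball[vi])) {
            ratio <- (xall[vi] - lball[vi]) / swi
            if (ratio < delta - 1e-12 ||
                (ratio < delta + 1e-12 && (leave_pos == 0L || vi < basis[leave_pos]))) {
              delta <- max(ratio, 0); leave_pos <- i; leave_to <- "lb"
            }
          }
        } else if (swi < -piv_tol) {
          if (is.finite(uball[vi])) {
            ratio <- (uball[vi] - xall[vi]) / (-swi)
            if (ratio < delta - 1e-12 ||
                (ratio < delta + 1e-12 && (leave_pos == 0L || vi < basis[leave_pos]))) {
              delta <- max(ratio, 0); leave_pos <- i; leave_to <- "ub"
            }
          }
        }
      }
      span <- uball[entering] - lball[entering]
      if (is.finite(span) && span < delta) {
        delta <- span; leave_pos <- 0L      # bound flip, basis unchanged
      }
      if (!is.finite(delta)) {
        return(list(xall = xall, basis = basis, in_basis = in_basis,
                    status = "unbounded", iter_left = iter_left))
      }
      xall[basis] <- xall[basis] - delta * s * w
      xall[entering] <- xall[entering] + s * delta
      if (leave_pos > 0L) {
        vl <- basis[leave_pos]
        xall[vl] <- if (leave_to == "lb") lball[vl] else uball[vl]
        in_basis[vl] <- FALSE
        basis[leave_pos] <- entering
        in_basis[entering] <- TRUE
      }
      iter_left <- iter_left - 1L
    }
  }

  # phase 1: minimise the artificial mass
  c1 <- c(rep(0, n), rep(-1, meq))
  ph1 <- run_phase(c1, xall, basis, in_basis, max_iter)
  if (sum(ph1$xall[n + seq_len(meq)]) > 1e-7 * (1 + max(abs(b)))) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  uball[n + seq_len(meq)] <- 0
  ph1$xall[n + seq_len(meq)] <- pmax(0, pmin(ph1$xall[n + seq_len(meq)], 0))

  # phase 2: the user's objective
  c2 <- c(sgn * obj, rep(0, meq))
  ph2 <- run_phase(c2, ph1$xall, ph1$basis, ph1$in_basis, ph1$iter_left)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  x <- ph2$xall[seq_len(n)]
  resid <- if (nrow(A_full)) max(abs(A_full %*% x - b_full)) else 0
  scale <- max(1, abs(b_full), abs(x))
  if (resid > 1e-6 * scale) {
    # dependent rows were inconsistent with the kept ones
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  list(status = "optimal", x = x, value = sum(obj * x))
}
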