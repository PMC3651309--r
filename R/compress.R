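#' Build the compression target from selected probes
#'
#' The target `Y` of the sparse-representation problem `Y = Phi S` is simply
#' the selected-probe submatrix of the (normalized) training signal `S`:
#' each compressed coordinate is asked to reproduce one informative probe.
#'
#' @param s Numeric matrix `S` (N probes x c samples).
#' @param selected Ordered probe indices, e.g. from [select_features()].
#' @return The `length(selected)` x `c` matrix of selected rows, in
#'   selection order.
#' @export
build_target <- function(s, selected) {
  if (!length(selected)) stop("selected must be non-empty")
  selected <- as.integer(selected)
  if (anyNA(selected) || any(selected < 1L | selected > nrow(s)))
    stop(sprintf("selected indices out of range [1, %d]", nrow(s)))
  s[selected, , drop = FALSE]
}

#' Minimum-l1-norm solution of one compress-matrix row
#'
#' Solves the basis-pursuit problem
#' \deqn{\min \|\phi\|_1 \quad \mathrm{s.t.} \quad S^T \phi = y}
#' for a single row of the compress matrix by the homotopy (least-angle
#' path) method: the lasso regularization path of `||S^T phi - y||^2 / 2 +
#' lambda ||phi||_1` is followed from `lambda = max |S y|` down to (numerical)
#' zero, where the path limit is the minimum-l1 interpolating solution.  The
#' path is piecewise linear with at most `c` active coordinates, so each row
#' is cheap even for very large `N`.
#'
#' @param s Numeric matrix `S` (N x c); the constraint matrix is `t(s)`.
#' @param y Length-`c` right-hand side (for compression, a row of the
#'   target built by [build_target()], which is always feasible).
#' @param tol Feasibility tolerance on the residual `||S^T phi - y||_2`.
#' @param max_steps Cap on path steps (default scales with the system size).
#' @param warn_overdetermined Warn when `c >= N` (no compression motive).
#' @return Numeric length-`N` vector `phi` (exact zeros off the active set)
#'   with attribute `"report"`: list with `l1`, `residual`, `steps`,
#'   `degenerate`.
#' @export
solve_l1_row <- function(s, y, tol = 1e-6, max_steps = NULL,
                         warn_overdetermined = TRUE) {
  A <- t(s)                              # c x N constraint matrix
  cdim <- nrow(A); N <- ncol(A)
  if (length(y) != cdim)
    stop(sprintf("length(y) = %d does not match ncol(S) = %d",
                 length(y), cdim))
  if (cdim >= N && warn_overdetermined)
    warning("system is not underdetermined (c >= N); solving anyway")
  mk <- function(x, l1, res, steps, degen) {
    attr(x, "report") <- list(l1 = l1, residual = res, steps = steps,
                              degenerate = degen)
    x
  }
  x <- numeric(N)
  if (sqrt(sum(y^2)) == 0) return(mk(x, 0, 0, 0L, FALSE))

  cvec <- as.vector(crossprod(A, y))     # correlations A'(y - A x) at x = 0
  lambda0 <- max(abs(cvec))
  if (lambda0 == 0)
    mcsd_stop("infeasible", "y is non-zero but orthogonal to the row space of S^T")
  lt <- lambda0 * 1e-13                  # effective lambda -> 0
  eps_g <- lambda0 * 1e-12
  lambda <- lambda0
  j0 <- which.max(abs(cvec))
  active <- j0
  sgn <- sign(cvec[j0])
  if (is.null(max_steps)) max_steps <- 100L + 10L * min(N, 4L * cdim)
  degenerate <- FALSE

  for (step in seq_len(max_steps)) {
    if (!length(active)) {               # restart after removing everything
      j0 <- which.max(abs(cvec))
      lambda <- abs(cvec[j0])
      if (lambda <= lt) break
      active <- j0
      sgn <- sign(cvec[j0])
    }
    Aact <- A[, active, drop = FALSE]
    G <- crossprod(Aact)
    d <- tryCatch(solve(G, sgn), error = function(e) NULL)
    if (is.null(d)) {                    # duplicated/collinear active probes
      degenerate <- TRUE
      d <- solve(G + diag(1e-10 * max(diag(G)), length(active)), sgn)
    }
    v <- as.vector(crossprod(A, Aact %*% d))
    gmax <- lambda - lt

    g_add <- rep(Inf, N)
    den1 <- 1 - v
    ok1 <- den1 > 1e-12
    g1 <- ifelse(ok1, (lambda - cvec) / den1, Inf)
    den2 <- 1 + v
    ok2 <- den2 > 1e-12
    g2 <- ifelse(ok2, (lambda + cvec) / den2, Inf)
    g_add <- pmin(ifelse(g1 > eps_g, g1, Inf), ifelse(g2 > eps_g, g2, Inf))
    g_add[active] <- Inf
    g_rem <- ifelse(d != 0, -x[active] / d, Inf)
    g_rem[g_rem <= eps_g] <- Inf

    g <- min(min(g_add), min(g_rem), gmax)
    x[active] <- x[active] + g * d
    cvec <- cvec - g * v
    lambda <- lambda - g
    cvec[active] <- lambda * sgn         # pin active correlations (drift)

    if (g >= gmax) break
    if (min(g_rem) <= min(min(g_add), gmax) + 0) {
      k <- which.min(g_rem)
      x[active[k]] <- 0
      active <- active[-k]
      sgn <- sgn[-k]
    } else {
      jstar <- which.min(g_add)
      active <- c(active, jstar)
      sgn <- c(sgn, sign(cvec[jstar]))
    }
    if (step == max_steps) degenerate <- TRUE
  }

  res_fun <- function(z) sqrt(sum((y - as.vector(A %*% z))^2))
  res_cur <- res_fun(x)
  ## Polish: the path limit at lambda = 0 on the final segment is the least
  ## squares fit on the final active set.
  if (length(active)) {
    q <- qr(A[, active, drop = FALSE])
    xa <- qr.coef(q, y)
    xa[is.na(xa)] <- 0
    xp <- numeric(N)
    xp[active] <- xa
    res_pol <- res_fun(xp)
    if (res_pol <= tol && (res_pol <= res_cur || res_cur > tol)) {
      x <- xp
      res_cur <- res_pol
    }
  }
  if (res_cur > tol)
    mcsd_stop("infeasible",
              "constraint residual %.3g exceeds tol %.3g (inconsistent system?)",
              res_cur, tol)
  names(x) <- rownames(s)
  mk(x, sum(abs(x)), res_cur, step, degenerate)
}

#' Learn the sparse compress matrix by per-row l1-minimization
#'
#' Row `j` of the compress matrix `Phi` (M x N) is the minimum-l1 solution
#' of `S^T phi = (Y^T)_j` (see [solve_l1_row()]); rows are independent, so a
#' row permutation of `Y` permutes the rows of `Phi` identically.  When `Y`
#' is a row-submatrix of a \[0,1\]-normalized `S`, the unit selector row is
#' always feasible, hence every row satisfies `||phi_j||_1 <= 1 + tol`.
#'
#' @param s Numeric matrix `S` (N x c).
#' @param y Numeric matrix `Y` (M x c); typically [build_target()] output.
#' @param tol Per-row feasibility tolerance.
#' @return An object of class `"mcsd_compress"`: list with `phi` (a sparse
#'   `dgCMatrix`, M x N), `m`, `n`, `tol`, and `report`, a per-row data
#'   frame (`row`, `l1`, `residual`, `steps`, `degenerate`).
#' @export
solve_compress_matrix <- function(s, y, tol = 1e-6) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  if (ncol(y) != ncol(s))
    stop(sprintf("ncol(Y) = %d does not match ncol(S) = %d", ncol(y), ncol(s)))
  M <- nrow(y); N <- nrow(s)
  if (ncol(s) >= N)
    warning("system is not underdetermined (c >= N); solving anyway")
  rows <- vector("list", M)
  for (j in seq_len(M)) {
    rows[[j]] <- tryCatch(
      solve_l1_row(s, y[j, ], tol = tol, warn_overdetermined = FALSE),
      mcsd_error = function(e) {
        mcsd_stop("infeasible", "row %d: %s", j, conditionMessage(e))
      })
  }
  rep_df <- data.frame(
    row = seq_len(M),
    l1 = vapply(rows, function(r) attr(r, "report")$l1, numeric(1)),
    residual = vapply(rows, function(r) attr(r, "report")$residual, numeric(1)),
    steps = vapply(rows, function(r) attr(r, "report")$steps, numeric(1)),
    degenerate = vapply(rows, function(r) attr(r, "report")$degenerate, logical(1)))
  nz <- lapply(seq_len(M), function(j) which(rows[[j]] != 0))
  phi <- Matrix::sparseMatrix(
    i = rep(seq_len(M), lengths(nz)),
    j = unlist(nz),
    x = unlist(lapply(seq_len(M), function(j) rows[[j]][nz[[j]]])),
    dims = c(M, N))
  structure(list(phi = phi, m = M, n = N, tol = tol, report = rep_df),
            class = "mcsd_compress")
}

#' @export
print.mcsd_compress <- function(x, ...) {
  cat(sprintf("Sparse compress matrix: %d x %d (%.2f%% non-zero)\n",
              x$m, x$n, 100 * Matrix::nnzero(x$phi) / (x$m * x$n)))
  cat(sprintf("  max row l1 norm: %.6g   max residual: %.3g   tol: %g\n",
              max(x$report$l1), max(x$report$residual), x$tol))
  invisible(x)
}

#' Project signals into the compressed space
#'
#' Computes `Phi x`: the linear map from the N-dimensional probe space to
#' the M-dimensional compressed space.
#'
#' @param phi An `"mcsd_compress"` object, or any M x N matrix.
#' @param x Length-N vector or N x k matrix (columns = samples).
#' @return Length-M vector, or M x k matrix with `x`'s column names.
#' @export
project <- function(phi, x) {
  P <- if (inherits(phi, "mcsd_compress")) phi$phi else phi
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (nrow(x) != ncol(P))
    stop(sprintf("dimension mismatch: Phi is %d x %d but x has %d rows",
                 nrow(P), ncol(P), nrow(x)))
  out <- as.matrix(P %*% x)
  if (vec) as.vector(out) else out
}
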