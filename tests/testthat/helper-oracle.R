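# Independent basis-pursuit oracle: min ||x||_1 subject to A x = b.
#
# The minimum-l1 interpolation problem is a linear program, so its optimum is
# attained at a basic solution: one supported on a set of linearly
# independent columns of A (support size <= rank(A) <= nrow(A)).  For the
# tiny instances used in tests we enumerate every such support, solve the
# square/overdetermined system exactly, and keep the best feasible l1.  This
# shares no code with the package's homotopy solver.
bp_oracle <- function(A, b, feas_tol = 1e-8) {
  N <- ncol(A)
  cdim <- nrow(A)
  if (sqrt(sum(b^2)) <= feas_tol)
    return(list(l1 = 0, x = numeric(N)))
  best <- Inf
  best_x <- NULL
  for (k in seq_len(min(cdim, N))) {
    for (supp in utils::combn(N, k, simplify = FALSE)) {
      AT <- A[, supp, drop = FALSE]
      q <- qr(AT)
      if (q$rank < k) next
      xT <- qr.coef(q, b)
      if (anyNA(xT)) next
      if (sqrt(sum((AT %*% xT - b)^2)) > feas_tol) next
      l1 <- sum(abs(xT))
      if (l1 < best) {
        best <- l1
        best_x <- numeric(N)
        best_x[supp] <- xT
      }
    }
  }
  list(l1 = best, x = best_x)
}

# Random small compression instance: S (N x c) with iid uniform entries and a
# target built from a random subset of S's rows.
random_bp_instance <- function(seed) {
  set.seed(seed)
  N <- sample(4:10, 1)
  cdim <- sample(2:min(5, N - 1), 1)
  S <- matrix(runif(N * cdim), N, cdim)
  m <- sample.int(min(3, N), 1)
  sel <- sample.int(N, m)
  list(S = S, sel = sel, Y = S[sel, , drop = FALSE])
}
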