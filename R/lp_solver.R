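# Dense two-phase simplex with Bland's rule (anti-cycling). Problems here
# are tiny (a dozen variables, a couple of dozen constraints), so a clear
# tableau implementation is preferred over sparse machinery.
#
# Maximize  c'x  subject to  A x (dir) b,  x >= 0,
# dir in {"<=", ">=", "=="}.
simplex_solve <- function(obj, A, dir, rhs, maximize = TRUE,
                          tol = 1e-9, max_pivots = 10000) {
  n <- length(obj)
  m <- length(rhs)
  stopifnot(ncol(A) == n, nrow(A) == m, length(dir) == m)
  if (!maximize) obj <- -obj

  # normalize rhs >= 0 (flips the inequality direction)
  flip <- rhs < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]
  dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]

  n_slack <- sum(dir == "<=")
  n_surp <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  ncols <- n + n_slack + n_surp + n_art
  T <- matrix(0, m, ncols + 1)
  T[, 1:n] <- A
  T[, ncols + 1] <- rhs
  basis <- integer(m)
  si <- 0; pi_ <- 0; ai <- 0
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      si <- si + 1
      T[i, n + si] <- 1
      basis[i] <- n + si
    } else {
      if (dir[i] == ">=") {
        pi_ <- pi_ + 1
        T[i, n + n_slack + pi_] <- -1
      }
      ai <- ai + 1
      T[i, n + n_slack + n_surp + ai] <- 1
      basis[i] <- n + n_slack + n_surp + ai
    }
  }
  art_cols <- if (n_art > 0) (n + n_slack + n_surp + 1):ncols else integer(0)

  pivot <- function(T, basis, r, c) {
    T[r, ] <- T[r, ] / T[r, c]
    for (i in seq_len(nrow(T))) {
      if (i != r && abs(T[i, c]) > 0) T[i, ] <- T[i, ] - T[i, c] * T[r, ]
    }
    basis[r] <- c
    list(T = T, basis = basis)
  }

  run_phase <- function(T, basis, cost) {
    for (k in seq_len(max_pivots)) {
      cb <- cost[basis]
      z <- as.numeric(cb %*% T[, seq_len(ncols), drop = FALSE])
      rc <- cost - z
      enter <- which(rc > tol)
      if (length(enter) == 0) {
        return(list(T = T, basis = basis, status = "optimal"))
      }
      j <- min(enter) # Bland
      pos <- which(T[, j] > tol)
      if (length(pos) == 0) {
        return(list(T = T, basis = basis, status = "unbounded"))
      }
      ratio <- T[pos, ncols + 1] / T[pos, j]
      best <- pos[ratio <= min(ratio) + tol]
      r <- best[which.min(basis[best])] # Bland tie-break
      p <- pivot(T, basis, r, j)
      T <- p$T; basis <- p$basis
    }
    list(T = T, basis = basis, status = "pivot_limit")
  }

  if (n_art > 0) {
    cost1 <- numeric(ncols)
    cost1[art_cols] <- -1
    ph1 <- run_phase(T, basis, cost1)
    if (ph1$status != "optimal") return(list(status = "infeasible"))
    T <- ph1$T; basis <- ph1$basis
    obj1 <- sum(T[basis %in% art_cols, ncols + 1])
    if (obj1 > 1e-7) return(list(status = "infeasible"))
    # drive residual artificials out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      cand <- which(abs(T[i, seq_len(n + n_slack + n_surp)]) > tol)
      if (length(cand) > 0) {
        p <- pivot(T, basis, i, min(cand))
        T <- p$T; basis <- p$basis
      }
    }
    # forbid artificials from re-entering
    T[, art_cols] <- 0
  }

  cost2 <- numeric(ncols)
  cost2[1:n] <- obj
  ph2 <- run_phase(T, basis, cost2)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  if (ph2$status != "optimal") return(list(status = "degenerate"))
  T <- ph2$T; basis <- ph2$basis
  x <- numeric(n)
  in_x <- basis <= n
  x[basis[in_x]] <- T[in_x, ncols + 1]
  value <- sum(obj * x)
  list(status = "optimal", x = x, value = if (maximize) value else -value)
}
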