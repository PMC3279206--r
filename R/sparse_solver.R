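#' Sparse solver configuration
#'
#' Controls how a test spectrum is decomposed over the dictionary. Two
#' solvers are exposed: greedy orthogonal matching pursuit (the pipeline
#' default, fast) and basis pursuit, the convex l1 relaxation of the NP-hard
#' l0 problem (solvable as a linear program; here traced along a penalized
#' l1 path). `eps = 0` reproduces the equality-constrained formulation.
#'
#' @param method `"greedy"` (orthogonal matching pursuit) or
#'   `"basis_pursuit"`.
#' @param eps absolute reconstruction-error tolerance (the constraint
#'   `||y - A gamma||_2 <= eps`). If `NULL` (default), the tolerance is set
#'   per call to `eps_rel * ||y||_2`: reflectance noise scales with signal,
#'   so a relative default travels across scenes.
#' @param eps_rel relative tolerance used when `eps` is `NULL`; default 0.05.
#' @param max_atoms greedy sparsity cap (default 10: a handful of training
#'   spectra suffices to span a tissue class).
#' @param tol_cg tolerance of the inner least-squares refits.
#' @return A `solver_config` object.
#' @export
solver_config <- function(method = c("greedy", "basis_pursuit"),
                          eps = NULL, eps_rel = 0.05,
                          max_atoms = 10L, tol_cg = 1e-10) {
  method <- match.arg(method)
  if (!is.null(eps) && (length(eps) != 1L || !is.finite(eps) || eps < 0))
    stop_srhsi("`eps` must be a single non-negative number", "srhsi_parameter_error")
  if (eps_rel < 0)
    stop_srhsi("`eps_rel` must be non-negative", "srhsi_parameter_error")
  max_atoms <- as.integer(max_atoms)
  if (max_atoms < 1L)
    stop_srhsi("`max_atoms` must be a positive integer", "srhsi_parameter_error")
  structure(list(method = method, eps = eps, eps_rel = eps_rel,
                 max_atoms = max_atoms, tol_cg = tol_cg),
            class = "solver_config")
}

.effective_eps <- function(cfg, y) {
  if (!is.null(cfg$eps)) cfg$eps else cfg$eps_rel * l2norm(y)
}

# support threshold: numerical zeros must not pollute class residuals
.SUPPORT_TOL <- 1e-10

.as_coefficients <- function(values, y, A) {
  values <- as.numeric(values)
  structure(list(
    values = values,
    support = which(abs(values) > .SUPPORT_TOL),
    residual_norm = l2norm(y - as.vector(A %*% values))
  ), class = "sparse_coefficients")
}

#' @export
print.sparse_coefficients <- function(x, ...) {
  cat(sprintf("<sparse_coefficients> %d atoms, support size %d, residual %.3g\n",
              length(x$values), length(x$support), x$residual_norm))
  invisible(x)
}

# rank-tolerant least squares on a column subset
.ls_fit <- function(Asub, y) {
  fit <- stats::lm.fit(Asub, y)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  b
}

#' Greedy sparse recovery (orthogonal matching pursuit)
#'
#' At each step the atom with maximal absolute correlation with the current
#' residual is added to the support and the coefficients are re-fit by least
#' squares on the support; iteration stops when the residual norm drops to
#' the error tolerance, the sparsity cap is reached, or no atom can decrease
#' the residual. Residual norms are non-increasing across iterations.
#'
#' @param y length-B observation vector.
#' @param A B x N dictionary with unit l2-norm columns (enforced upstream by
#'   [build_dictionary()]).
#' @param cfg a [solver_config()] with `method = "greedy"`.
#' @return A `sparse_coefficients` object: `values` (length N), `support`
#'   (indices with `|value| > 1e-10`) and `residual_norm`.
#' @export
solve_greedy <- function(y, A, cfg = solver_config("greedy")) {
  stopifnot(is.matrix(A), length(y) == nrow(A))
  eps <- .effective_eps(cfg, y)
  N <- ncol(A)
  coef <- numeric(N)
  supp <- integer(0)
  r <- y
  rn <- l2norm(r)
  while (rn > eps && length(supp) < min(cfg$max_atoms, N)) {
    corr <- abs(as.vector(crossprod(A, r)))
    corr[supp] <- -Inf  # an already-selected atom has zero residual correlation
    j <- which.max(corr)
    if (!is.finite(corr[j]) || corr[j] < 1e-12) break
    cand <- c(supp, j)
    b <- .ls_fit(A[, cand, drop = FALSE], y)
    rnew <- y - as.vector(A[, cand, drop = FALSE] %*% b)
    rnnew <- l2norm(rnew)
    if (rnnew > rn - 1e-12) break  # no residual decrease: terminate
    supp <- cand
    coef[] <- 0
    coef[supp] <- b
    r <- rnew
    rn <- rnnew
  }
  .as_coefficients(coef, y, A)
}

#' Basis pursuit sparse recovery
#'
#' Solves `min ||gamma||_1 subject to ||y - A gamma||_2 <= eps`. For
#' effectively zero tolerances (`eps <= 1e-6`, covering the
#' equality-constrained formulation) the problem is solved exactly as a
#' linear program by an internal dense simplex, whose vertex optimum carries
#' exact zeros off the support. For noise-tolerant `eps` the equivalent
#' penalized l1 (lasso) path is traced with warm starts (via \pkg{glmnet})
#' and the penalty is bisected onto the error-constraint boundary, returning
#' the minimum-l1-norm solution that satisfies the constraint within `1e-6`.
#'
#' @inheritParams solve_greedy
#' @param cfg a [solver_config()] with `method = "basis_pursuit"`.
#' @return A `sparse_coefficients` object; `residual_norm <= eps + 1e-6`.
#' @export
solve_basis_pursuit <- function(y, A, cfg = solver_config("basis_pursuit")) {
  stopifnot(is.matrix(A), length(y) == nrow(A))
  eps <- .effective_eps(cfg, y)
  feas_tol <- 1e-6
  N <- ncol(A)
  if (l2norm(y) <= eps + feas_tol)
    return(.as_coefficients(numeric(N), y, A))
  if (N == 1L || nrow(A) == 1L) return(.bp_tiny(y, A, eps, feas_tol))

  if (eps <= feas_tol) {
    # (near-)equality form: solve the linear program exactly, so the returned
    # vertex solution carries exact zeros off its support
    gamma <- .bp_equality_lp(y, A)
    if (is.null(gamma)) {
      rmin <- l2norm(stats::lm.fit(A, y)$residuals)
      if (rmin > eps + feas_tol)
        stop_srhsi(sprintf(
          "infeasible error tolerance: eps = %.3g but the least-squares residual is %.3g",
          eps, rmin), "srhsi_solver_error",
          diagnostics = list(eps = eps, min_residual = rmin))
      stop_srhsi("equality basis pursuit did not converge", "srhsi_solver_error")
    }
    return(.as_coefficients(gamma, y, A))
  }

  lmax <- max(abs(crossprod(A, y))) / nrow(A)
  lams <- lmax * exp(seq(0, log(1e-9), length.out = 120L))
  fit <- tryCatch(
    glmnet::glmnet(A, y, family = "gaussian", lambda = lams,
                   standardize = FALSE, intercept = FALSE,
                   thresh = 1e-14, maxit = 1e7),
    error = function(e)
      stop_srhsi(sprintf("basis pursuit inner solver failed: %s",
                         conditionMessage(e)), "srhsi_solver_error"))
  Bm <- as.matrix(fit$beta)
  res <- sqrt(colSums((y - A %*% Bm)^2))
  feas <- which(res <= eps + feas_tol)
  if (length(feas) == 0L) {
    # eps below the attainable residual? check against the least-squares optimum
    rmin <- l2norm(stats::lm.fit(A, y)$residuals)
    if (rmin > eps + feas_tol)
      stop_srhsi(sprintf(
        "infeasible error tolerance: eps = %.3g but the least-squares residual is %.3g",
        eps, rmin), "srhsi_solver_error",
        diagnostics = list(eps = eps, min_residual = rmin, path_points = length(res)))
    stop_srhsi(sprintf(
      "basis pursuit path did not reach the tolerance (best residual %.3g > eps %.3g)",
      min(res), eps), "srhsi_solver_error",
      diagnostics = list(eps = eps, best_residual = min(res), path_points = length(res)))
  }
  i <- feas[1]  # largest feasible penalty = smallest l1 norm on the path
  if (i > 1L) {
    # sharpen to the constraint boundary: bisect the penalty between the last
    # infeasible and first feasible path points, so the returned solution is
    # the grid-independent lasso solution whose residual meets eps
    lo <- lams[i]; hi <- lams[i - 1L]
    best <- Bm[, i]
    for (it in 1:20) {
      mid <- sqrt(lo * hi)
      seq_mid <- exp(seq(log(lmax), log(mid), length.out = 30L))
      fm <- glmnet::glmnet(A, y, family = "gaussian", lambda = seq_mid,
                           standardize = FALSE, intercept = FALSE,
                           thresh = 1e-14, maxit = 1e7)
      bmid <- as.matrix(fm$beta)[, length(seq_mid)]
      if (l2norm(y - as.vector(A %*% bmid)) <= eps + feas_tol) {
        lo <- mid; best <- bmid
      } else hi <- mid
    }
    return(.as_coefficients(.bpdn_polish(y, A, best, eps), y, A))
  }
  .as_coefficients(.bpdn_polish(y, A, Bm[, i], eps), y, A)
}

# Sharpen an approximate constrained-l1 solution to the exact KKT point of
# its active set: gamma_S(l) = (A_S'A_S)^{-1}(A_S'y - l s) with the penalty
# l chosen so the residual sits exactly on the eps boundary. Falls back to
# the input when the active set's geometry rejects the polish (sign flips,
# eps below the active set's least-squares residual).
.bpdn_polish <- function(y, A, gamma, eps) {
  S <- which(abs(gamma) > .SUPPORT_TOL)
  if (length(S) == 0L) return(gamma)
  s <- sign(gamma[S])
  As <- A[, S, drop = FALSE]
  G <- crossprod(As)
  Aty <- as.vector(crossprod(As, y))
  gam_l <- function(l) tryCatch(solve(G, Aty - l * s), error = function(e) NULL)
  f <- function(l) {
    g <- gam_l(l)
    if (is.null(g)) return(NA_real_)
    l2norm(y - as.vector(As %*% g)) - eps
  }
  f0 <- f(0)
  if (is.na(f0) || f0 > 0) return(gamma)
  l_hi <- 1e-6
  while (!is.na(f(l_hi)) && f(l_hi) < 0 && l_hi < 1e6) l_hi <- l_hi * 4
  if (is.na(f(l_hi)) || f(l_hi) < 0) return(gamma)
  root <- stats::uniroot(f, c(0, l_hi), tol = 1e-14)$root
  g2 <- gam_l(root)
  if (is.null(g2) || any(sign(g2) * s < 0)) return(gamma)
  out <- numeric(length(gamma))
  out[S] <- g2
  if (sum(abs(out)) <= sum(abs(gamma)) + 1e-6) out else gamma
}

# Equality-constrained basis pursuit as a linear program:
#   min 1'(u + v)  s.t.  A(u - v) = y,  u, v >= 0,  gamma = u - v,
# solved by a dense two-phase simplex with Bland's rule. Problem sizes here
# are tiny (B rows, 2N + B columns), and a vertex optimum has exact zeros,
# which keeps reported supports clean. Returns NULL if the equality system
# is infeasible (y outside the column span).
.bp_equality_lp <- function(y, A, tol = 1e-9) {
  B <- nrow(A); N <- ncol(A)
  M <- cbind(A, -A)
  b <- y
  flip <- b < 0
  M[flip, ] <- -M[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  # phase 1: artificial basis
  Tm <- cbind(M, diag(B))
  cost1 <- c(rep(0, 2 * N), rep(1, B))
  basis <- 2L * N + seq_len(B)
  s1 <- .simplex(Tm, b, cost1, basis, tol)
  if (is.null(s1) || s1$obj > 1e-7) return(NULL)
  # drive any residual artificial variables out of the basis if possible
  basis <- s1$basis; Tm <- s1$Tm; b <- s1$b
  for (i in seq_len(B)) {
    if (basis[i] > 2L * N) {
      piv <- which(abs(Tm[i, seq_len(2L * N)]) > tol)[1]
      if (!is.na(piv)) {
        fac <- Tm[i, piv]
        Tm[i, ] <- Tm[i, ] / fac; b[i] <- b[i] / fac
        for (r in seq_len(B)[-i]) {
          f2 <- Tm[r, piv]
          Tm[r, ] <- Tm[r, ] - f2 * Tm[i, ]
          b[r] <- b[r] - f2 * b[i]
        }
        basis[i] <- piv
      }
    }
  }
  # phase 2 on the original columns
  keep <- seq_len(2L * N)
  drop_rows <- basis > 2L * N  # redundant constraints left with artificials
  s2 <- .simplex(Tm[!drop_rows, keep, drop = FALSE], b[!drop_rows],
                 rep(1, 2 * N), basis[!drop_rows], tol)
  if (is.null(s2)) return(NULL)
  x <- numeric(2L * N)
  x[s2$basis] <- s2$b
  x[seq_len(N)] - x[N + seq_len(N)]
}

# revised-tableau simplex minimizing cost'x, rows already in basic form for
# `basis`; Bland's rule for anti-cycling
.simplex <- function(Tm, b, cost, basis, tol) {
  m <- length(b)
  # normalize tableau to the given basis
  for (i in seq_len(m)) {
    f <- Tm[i, basis[i]]
    if (abs(f) < tol) return(NULL)
    Tm[i, ] <- Tm[i, ] / f; b[i] <- b[i] / f
    for (r in seq_len(m)[-i]) {
      f2 <- Tm[r, basis[i]]
      if (abs(f2) > 0) {
        Tm[r, ] <- Tm[r, ] - f2 * Tm[i, ]
        b[r] <- b[r] - f2 * b[i]
      }
    }
  }
  for (iter in seq_len(10000L)) {
    red <- cost - as.vector(cost[basis] %*% Tm)  # reduced costs
    enter <- which(red < -tol)[1]                # Bland: smallest index
    if (is.na(enter)) {
      return(list(basis = basis, b = b, Tm = Tm,
                  obj = sum(cost[basis] * b)))
    }
    col <- Tm[, enter]
    ratios <- ifelse(col > tol, b / col, Inf)
    if (all(!is.finite(ratios))) return(NULL)   # unbounded (cannot happen here)
    leave <- which(ratios == min(ratios))
    leave <- leave[which.min(basis[leave])]     # Bland on the leaving variable
    f <- Tm[leave, enter]
    Tm[leave, ] <- Tm[leave, ] / f; b[leave] <- b[leave] / f
    for (r in seq_len(nrow(Tm))[-leave]) {
      f2 <- Tm[r, enter]
      if (abs(f2) > 0) {
        Tm[r, ] <- Tm[r, ] - f2 * Tm[leave, ]
        b[r] <- b[r] - f2 * b[leave]
      }
    }
    basis[leave] <- enter
  }
  NULL
}

# closed-form basis pursuit for the degenerate one-atom / one-band cases
.bp_tiny <- function(y, A, eps, feas_tol) {
  if (ncol(A) == 1L) {
    a <- A[, 1]
    aty <- sum(a * y); a2 <- sum(a^2)
    disc <- aty^2 - a2 * (sum(y^2) - eps^2)
    if (disc < 0) {
      rmin <- l2norm(y - a * aty / a2)
      if (rmin > eps + feas_tol)
        stop_srhsi("infeasible error tolerance for one-atom dictionary",
                   "srhsi_solver_error")
      g <- aty / a2
    } else {
      g <- (aty - sign(aty) * sqrt(max(disc, 0))) / a2
      if (abs(aty) <= sqrt(max(disc, 0))) g <- 0
    }
    return(.as_coefficients(g, y, A))
  }
  # single band: put all mass on the largest-magnitude atom entry
  a <- A[1, ]
  j <- which.max(abs(a))
  g <- numeric(ncol(A))
  g[j] <- sign(y[1] / a[j]) * max(0, (abs(y[1]) - eps) / abs(a[j]))
  .as_coefficients(g, y, A)
}

#' Exhaustive minimum-l0 reference solver
#'
#' Enumerates every support of size `0..maxK`, solves least squares on each,
#' and returns the best solution: minimal residual, with ties (within
#' `1e-9`) broken toward smaller support size, then smaller residual, then
#' lexicographically smaller support. This is the combinatorial ground truth
#' against which the practical solvers are validated; it is intended for
#' small test instances only.
#'
#' @inheritParams solve_greedy
#' @param maxK maximal support size to enumerate; the total number of
#'   supports must not exceed 1e6.
#' @return A `sparse_coefficients` object.
#' @export
brute_force_l0 <- function(y, A, maxK) {
  stopifnot(is.matrix(A), length(y) == nrow(A))
  N <- ncol(A)
  maxK <- min(as.integer(maxK), N)
  n_supports <- sum(choose(N, 0:maxK))
  if (n_supports > 1e6)
    stop_srhsi(sprintf("combinatorial budget exceeded: %.3g supports to enumerate",
                       n_supports), "srhsi_budget_error")
  best_vals <- numeric(N)
  best_res <- l2norm(y)  # empty support
  best_k <- 0L
  for (k in seq_len(maxK)) {
    supports <- utils::combn(N, k)
    for (s in seq_len(ncol(supports))) {
      supp <- supports[, s]
      b <- .ls_fit(A[, supp, drop = FALSE], y)
      res <- l2norm(y - as.vector(A[, supp, drop = FALSE] %*% b))
      better <- res < best_res - 1e-9 || (k == best_k && res < best_res)
      if (better) {
        best_vals[] <- 0
        best_vals[supp] <- b
        best_res <- res
        best_k <- k
      }
    }
  }
  .as_coefficients(best_vals, y, A)
}

# internal dispatcher used by the detector
.sparse_fit <- function(y, A, cfg) {
  switch(cfg$method,
    greedy = solve_greedy(y, A, cfg),
    basis_pursuit = solve_basis_pursuit(y, A, cfg))
}
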