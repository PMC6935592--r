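# Core single-response REML engine for linear mixed models written in the
# variance-structure ("V-space") form V(theta) = sum_i theta_i * A_i, where the
# A_i are known PSD matrices (the last is usually the identity / residual).
#
# EM updates (monotone in the REML log-likelihood, naturally non-negative):
#   theta_i <- theta_i + theta_i^2 * (y'P A_i P y - tr(P A_i)) / n
# optionally accelerated with average-information (AI) Newton steps
#   AI_ij = 0.5 * y'P A_i P A_j P y,  score_i = -0.5 * (tr(P A_i) - y'P A_i P y)
# falling back to EM whenever an AI step leaves the feasible region or fails
# to improve the log-likelihood. The inverse AI matrix at convergence is kept
# as the asymptotic covariance of the variance-component estimates.

reml_vc <- function(y, X, Vlist, init = NULL,
                    algorithm = c("hybrid", "em", "ai"),
                    max_iter = 200L, tol_par = 1e-6, tol_ll = 1e-8,
                    floor_frac = 1e-8) {
  algorithm <- match.arg(algorithm)
  n <- length(y)
  k <- length(Vlist)
  stopifnot(nrow(X) == n, all(vapply(Vlist, nrow, 0L) == n))
  vy <- var(y)
  floor <- floor_frac * vy
  theta <- if (is.null(init)) rep(vy / k, k) else pmax(init, floor)
  names(theta) <- names(Vlist)

  state <- function(theta) {
    V <- matrix(0, n, n)
    for (i in seq_len(k)) V <- V + theta[i] * Vlist[[i]]
    cV <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-8 * vy, n)))
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    cXtViX <- chol(XtViX)
    W <- backsolve(cXtViX, forwardsolve(t(cXtViX), t(ViX)))
    P <- Vi - ViX %*% W
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXtViX))) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll, Vi = Vi, ViX = ViX, XtViX = XtViX)
  }

  st <- state(theta)
  traj <- st$ll
  converged <- FALSE
  ai_mat <- NULL
  for (iter in seq_len(max_iter)) {
    APy <- lapply(Vlist, function(A) drop(A %*% st$Py))
    quad <- vapply(APy, function(t_) sum(st$Py * t_), 0)     # y'P A P y
    trPA <- vapply(Vlist, function(A) sum(st$P * A), 0)      # tr(P A)
    score <- -0.5 * (trPA - quad)
    PAPy <- lapply(APy, function(t_) drop(st$P %*% t_))
    AI <- 0.5 * outer(seq_len(k), seq_len(k),
                      Vectorize(function(i, j) sum(APy[[i]] * PAPy[[j]])))
    ai_mat <- AI

    em_theta <- pmax(theta + theta^2 * (quad - trPA) / n, floor)
    use_ai <- algorithm %in% c("hybrid", "ai") &&
      (algorithm == "ai" || iter > 2L)
    new_theta <- NULL
    if (use_ai) {
      # active set: components pinned at the zero boundary with a negative
      # score stay pinned and are excluded from the Newton system
      act <- which(theta > 2 * floor | score > 0)
      if (length(act)) {
        step <- rep(0, k)
        s_act <- tryCatch(
          solve(AI[act, act, drop = FALSE] + diag(1e-10, length(act)),
                score[act]),
          error = function(e) NULL)
        if (!is.null(s_act)) {
          step[act] <- s_act
          h <- 1
          for (try in 1:6) {
            cand <- pmax(theta + h * step, floor)
            cand_st <- state(cand)
            if (is.finite(cand_st$ll) && cand_st$ll >= st$ll - 1e-10) {
              new_theta <- cand; new_st <- cand_st
              break
            }
            h <- h / 4
          }
        }
      }
    }
    if (is.null(new_theta)) {
      new_theta <- em_theta
      new_st <- state(new_theta)
    }
    traj <- c(traj, new_st$ll)
    delta_par <- max(abs(new_theta - theta)) / max(sum(theta), 1e-12)
    delta_ll <- abs(new_st$ll - st$ll)
    theta <- new_theta
    st <- new_st
    if (delta_par < tol_par || delta_ll < tol_ll) { converged <- TRUE; break }
  }
  theta[theta <= floor * 1.001] <- 0
  vcov_theta <- if (is.null(ai_mat)) matrix(NA_real_, k, k) else
    tryCatch(solve(ai_mat), error = function(e) matrix(NA_real_, k, k))
  dimnames(vcov_theta) <- list(names(Vlist), names(Vlist))
  list(theta = theta, loglik = st$ll, trajectory = traj,
       converged = converged, iterations = length(traj) - 1L,
       vcov_theta = vcov_theta, Py = st$Py, P = st$P,
       Vi = st$Vi, ViX = st$ViX, XtViX = st$XtViX)
}

# REML log-likelihood and projections at *fixed* variance components
reml_eval <- function(y, X, Vlist, theta) {
  reml_vc(y, X, Vlist, init = theta, max_iter = 0L, floor_frac = 0)
}
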