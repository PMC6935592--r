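# Multivariate REML engine for models of the form
#   y_t = trait mean + sum_g u_g(t) ,  u_g ~ N(0, V_g (x) M_g)
# where each group g (block, additive, residual, ...) has a p x p CORGH
# covariance V_g = D^{1/2} R_g D^{1/2} (unique variance per trait plus a
# correlation per trait pair) and a known n x n base matrix M_g (ZZ' for
# blocks, the kernel K for additive effects, I for residuals). Missing cells
# are handled by building the covariance over observed cells only. The REML
# log-likelihood is maximised by quasi-Newton iteration on log-variances and
# atanh-correlations with an analytic gradient; the asymptotic covariance of
# the raw parameters comes from the average-information matrix at the
# optimum. Correlations are bounded at |r| <= 0.999 and reported as
# boundary-pinned with a warning when they get there.

MT_COR_BOUND <- atanh(0.999)

mt_reml <- function(y_mat, comps, start = NULL, fix_cor = list(),
                    maxit = 200L) {
  p <- ncol(y_mat)
  n <- nrow(y_mat)
  stopifnot(all(vapply(comps, nrow, 0L) == n))
  gnames <- names(comps)
  obs <- lapply(seq_len(p), function(t) which(!is.na(y_mat[, t])))
  if (any(lengths(obs) == 0)) stop("a trait is 100% missing: no information",
                                   call. = FALSE)
  n_t <- lengths(obs)
  off <- cumsum(c(0L, n_t))
  rows <- lapply(seq_len(p), function(t) (off[t] + 1L):off[t + 1L])
  N <- off[p + 1L]
  y <- unlist(lapply(seq_len(p), function(t) y_mat[obs[[t]], t]))
  X <- matrix(0, N, p)
  for (t in seq_len(p)) X[rows[[t]], t] <- 1
  pairs <- if (p > 1) t(combn(p, 2L)) else matrix(0L, 0, 2)
  # pre-subset each base matrix to the observed cells of every trait pair
  Msub <- lapply(comps, function(M) {
    out <- vector("list", p * p)
    dim(out) <- c(p, p)
    for (t in seq_len(p)) for (u in t:p) {
      out[[t, u]] <- M[obs[[t]], obs[[u]], drop = FALSE]
    }
    out
  })

  # parameter table: one row per raw parameter (variance or correlation)
  ptab <- do.call(rbind, lapply(gnames, function(g) {
    v <- data.frame(group = g, type = "var", t1 = seq_len(p), t2 = seq_len(p),
                    fixed = NA_real_, stringsAsFactors = FALSE)
    cc <- if (nrow(pairs)) data.frame(group = g, type = "cor",
                                      t1 = pairs[, 1], t2 = pairs[, 2],
                                      fixed = NA_real_) else NULL
    rbind(v, cc)
  }))
  for (g in names(fix_cor)) {
    ptab$fixed[ptab$group == g & ptab$type == "cor"] <- fix_cor[[g]]
  }
  free <- which(is.na(ptab$fixed))
  vy <- apply(y_mat, 2, var, na.rm = TRUE)

  raw_default <- function() {
    r <- numeric(nrow(ptab))
    for (i in seq_len(nrow(ptab))) {
      r[i] <- if (ptab$type[i] == "var") {
        if (!is.null(start)) start[[ptab$group[i]]]$var[ptab$t1[i]]
        else vy[ptab$t1[i]] / length(gnames)
      } else {
        if (!is.null(start) && !is.null(start[[ptab$group[i]]]$cor))
          start[[ptab$group[i]]]$cor else 0
      }
    }
    r[!is.na(ptab$fixed)] <- ptab$fixed[!is.na(ptab$fixed)]
    r
  }
  raw0 <- raw_default()

  to_par <- function(raw) {
    ifelse(ptab$type == "var", log(pmax(raw, 1e-10)),
           atanh(pmin(pmax(raw, -0.999), 0.999)))[free]
  }
  to_raw <- function(par) {
    raw <- raw_default()
    raw[free] <- ifelse(ptab$type[free] == "var", exp(par), tanh(par))
    raw
  }
  group_mats <- function(raw) {
    lapply(gnames, function(g) {
      s <- raw[ptab$group == g & ptab$type == "var"]
      Vg <- diag(s, nrow = p)
      if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
        a <- pairs[k, 1]; b <- pairs[k, 2]
        r <- raw[ptab$group == g & ptab$type == "cor" &
                   ptab$t1 == a & ptab$t2 == b]
        Vg[a, b] <- Vg[b, a] <- r * sqrt(s[a] * s[b])
      }
      Vg
    }) |> setNames(gnames)
  }
  assemble_V <- function(Vg_list) {
    V <- matrix(0, N, N)
    for (g in gnames) {
      Vg <- Vg_list[[g]]
      for (t in seq_len(p)) for (u in t:p) {
        if (Vg[t, u] == 0) next
        blk <- Vg[t, u] * Msub[[g]][[t, u]]
        V[rows[[t]], rows[[u]]] <- V[rows[[t]], rows[[u]]] + blk
        if (u > t) V[rows[[u]], rows[[t]]] <- V[rows[[u]], rows[[t]]] + t(blk)
      }
    }
    V
  }

  cache <- new.env(parent = emptyenv())
  evaluate <- function(par, need_grad = FALSE) {
    key <- paste(format(par, digits = 17), collapse = ",")
    hit <- !is.null(cache$key) && identical(cache$key, key)
    if (hit && (!need_grad || !is.null(cache$state$grad))) return(cache$state)
    if (hit) {
      st <- cache$state
      if (is.null(st$cV)) return(st) # degenerate (non-PD) point
      raw <- st$raw; Vg_list <- st$Vg_list; cV <- st$cV
      Vy <- st$Vy; VX <- st$VX; XtViX <- st$XtViX; cXX <- st$cXX
      Py <- st$Py; ll <- st$ll
    } else {
      raw <- to_raw(par)
      Vg_list <- group_mats(raw)
      V <- assemble_V(Vg_list)
      cV <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(cV)) {
        st <- list(ll = -1e10, grad = rep(0, length(free)))
        cache$key <- key; cache$state <- st
        return(st)
      }
      # likelihood via triangular solves only (no dense inverse yet)
      Vy <- backsolve(cV, forwardsolve(t(cV), y))        # V^-1 y
      VX <- backsolve(cV, forwardsolve(t(cV), X))        # V^-1 X
      XtViX <- crossprod(X, VX)
      cXX <- chol(XtViX)
      bhat <- backsolve(cXX, forwardsolve(t(cXX), crossprod(X, Vy)))
      Py <- drop(Vy - VX %*% bhat)
      ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXX))) +
                      sum(y * Py))
    }
    grad <- NULL
    Vi <- NULL; P <- NULL
    if (need_grad) {
      Vi <- chol2inv(cV)
      P <- Vi - VX %*% backsolve(cXX, forwardsolve(t(cXX), t(VX)))
    }
    if (need_grad) {
      # per group, per (t,u): trace term sum(P_tu * M_tu) and quad q_t' M q_u
      svals <- list(); wvals <- list()
      q <- lapply(seq_len(p), function(t) Py[rows[[t]]])
      for (g in gnames) {
        s_m <- matrix(0, p, p); w_m <- matrix(0, p, p)
        for (t in seq_len(p)) for (u in t:p) {
          Mtu <- Msub[[g]][[t, u]]
          s_m[t, u] <- s_m[u, t] <- sum(P[rows[[t]], rows[[u]]] * Mtu)
          w_m[t, u] <- w_m[u, t] <- sum(q[[t]] * (Mtu %*% q[[u]]))
        }
        svals[[g]] <- s_m; wvals[[g]] <- w_m
      }
      dl_raw <- numeric(nrow(ptab))
      for (i in seq_len(nrow(ptab))) {
        g <- ptab$group[i]
        s <- raw[ptab$group == g & ptab$type == "var"]
        E <- matrix(0, p, p)
        if (ptab$type[i] == "var") {
          t1 <- ptab$t1[i]
          E[t1, t1] <- 1
          for (u in seq_len(p)) if (u != t1 && s[t1] > 0) {
            r <- Vg_list[[g]][t1, u] / sqrt(s[t1] * s[u])
            E[t1, u] <- E[u, t1] <- 0.5 * r * sqrt(s[u] / s[t1])
          }
        } else {
          a <- ptab$t1[i]; b <- ptab$t2[i]
          E[a, b] <- E[b, a] <- sqrt(s[a] * s[b])
        }
        tt <- sum(diag(E) * (diag(svals[[g]]) - diag(wvals[[g]])))
        if (p > 1) for (k in seq_len(nrow(pairs))) {
          a <- pairs[k, 1]; b <- pairs[k, 2]
          tt <- tt + 2 * E[a, b] * (svals[[g]][a, b] - wvals[[g]][a, b])
        }
        dl_raw[i] <- -0.5 * tt
      }
      # chain rule to the transformed scale, free parameters only
      grad <- vapply(seq_along(free), function(j) {
        i <- free[j]
        if (ptab$type[i] == "var") dl_raw[i] * raw[i]
        else dl_raw[i] * (1 - raw[i]^2)
      }, 0)
    }
    st <- list(ll = ll, grad = grad, P = P, Py = Py, Vi = Vi,
               cV = cV, Vy = Vy, VX = VX, cXX = cXX,
               XtViX = XtViX, Vg_list = Vg_list, raw = raw)
    cache$key <- key; cache$state <- st
    st
  }

  lower <- ifelse(ptab$type[free] == "var", log(1e-8 * max(vy)), -MT_COR_BOUND)
  upper <- ifelse(ptab$type[free] == "var", log(1e6 * max(vy)), MT_COR_BOUND)
  opt <- optim(to_par(raw0),
               fn = function(par) -evaluate(par)$ll,
               gr = function(par) -evaluate(par, need_grad = TRUE)$grad,
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = maxit, factr = 1e7))
  st <- evaluate(opt$par, need_grad = TRUE)
  raw <- st$raw
  pinned <- ptab$type[free] == "cor" &
    abs(abs(opt$par) - MT_COR_BOUND)[seq_along(free)] < 1e-6
  if (any(pinned)) warning("correlation estimate pinned at the 0.999 boundary",
                           call. = FALSE)

  # average-information covariance of the raw parameters at the optimum
  k_par <- length(free)
  tvecs <- vector("list", k_par)
  for (j in seq_len(k_par)) {
    i <- free[j]
    g <- ptab$group[i]
    s <- raw[ptab$group == g & ptab$type == "var"]
    E <- matrix(0, p, p)
    if (ptab$type[i] == "var") {
      t1 <- ptab$t1[i]; E[t1, t1] <- 1
      for (u in seq_len(p)) if (u != t1 && s[t1] > 0) {
        r <- st$Vg_list[[g]][t1, u] / sqrt(s[t1] * s[u])
        E[t1, u] <- E[u, t1] <- 0.5 * r * sqrt(s[u] / s[t1])
      }
    } else {
      a <- ptab$t1[i]; b <- ptab$t2[i]
      E[a, b] <- E[b, a] <- sqrt(s[a] * s[b])
    }
    tv <- numeric(N)
    q <- lapply(seq_len(p), function(t) st$Py[rows[[t]]])
    for (t in seq_len(p)) {
      acc <- numeric(n_t[t])
      for (u in seq_len(p)) if (E[t, u] != 0) {
        Mtu <- if (u >= t) Msub[[g]][[t, u]] else t(Msub[[g]][[u, t]])
        acc <- acc + E[t, u] * drop(Mtu %*% q[[u]])
      }
      tv[rows[[t]]] <- acc
    }
    tvecs[[j]] <- tv
  }
  AI <- matrix(0, k_par, k_par)
  Pt <- lapply(tvecs, function(v) drop(st$P %*% v))
  for (i in seq_len(k_par)) for (j in i:k_par) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(tvecs[[i]] * Pt[[j]])
  }
  vcov_raw <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, k_par, k_par))
  par_names <- paste0(ptab$group[free], "_", ptab$type[free], "_",
                      ptab$t1[free], ifelse(ptab$type[free] == "cor",
                                            paste0(".", ptab$t2[free]), ""))
  dimnames(vcov_raw) <- list(par_names, par_names)

  beta <- drop(solve(st$XtViX, crossprod(st$VX, y)))
  list(Vg = st$Vg_list, loglik = st$ll, beta = beta,
       vcov_raw = vcov_raw, raw = setNames(raw, paste0(
         ptab$group, "_", ptab$type, "_", ptab$t1,
         ifelse(ptab$type == "cor", paste0(".", ptab$t2), ""))),
       Py = st$Py, obs = obs, rows = rows,
       converged = opt$convergence == 0, pinned = any(pinned),
       ptab = ptab, free = free, n_obs = N)
}

# BLUP/GEBV of the additive effect for every kernel id at fixed components:
# a_hat[i, t] = sum_u VA[t, u] * K[i, obs_u] %*% Py_u
mt_gebv <- function(fit_or_parts, kernel, ids_all = rownames(kernel),
                    data_ids, VA = NULL) {
  f <- fit_or_parts
  VA <- VA %||% f$Vg$A
  p <- ncol(VA)
  out <- matrix(0, length(ids_all), p, dimnames = list(ids_all, NULL))
  for (t in seq_len(p)) {
    acc <- numeric(length(ids_all))
    for (u in seq_len(p)) {
      if (VA[t, u] == 0) next
      idx <- data_ids[f$obs[[u]]]
      acc <- acc + VA[t, u] * drop(kernel[ids_all, idx, drop = FALSE] %*%
                                     f$Py[f$rows[[u]]])
    }
    out[, t] <- acc
  }
  out
}

# evaluate the model at fixed group covariance matrices (no optimisation):
# returns the same projection pieces as mt_reml so mt_gebv() applies.
mt_eval <- function(y_mat, comps, Vg_list) {
  p <- ncol(y_mat)
  n <- nrow(y_mat)
  obs <- lapply(seq_len(p), function(t) which(!is.na(y_mat[, t])))
  if (any(lengths(obs) == 0)) stop("a trait is 100% missing: no information",
                                   call. = FALSE)
  n_t <- lengths(obs)
  off <- cumsum(c(0L, n_t))
  rows <- lapply(seq_len(p), function(t) (off[t] + 1L):off[t + 1L])
  N <- off[p + 1L]
  y <- unlist(lapply(seq_len(p), function(t) y_mat[obs[[t]], t]))
  X <- matrix(0, N, p)
  for (t in seq_len(p)) X[rows[[t]], t] <- 1
  V <- matrix(0, N, N)
  for (g in names(comps)) {
    M <- comps[[g]]; Vg <- Vg_list[[g]]
    for (t in seq_len(p)) for (u in t:p) {
      if (Vg[t, u] == 0) next
      blk <- Vg[t, u] * M[obs[[t]], obs[[u]], drop = FALSE]
      V[rows[[t]], rows[[u]]] <- V[rows[[t]], rows[[u]]] + blk
      if (u > t) V[rows[[u]], rows[[t]]] <- V[rows[[u]], rows[[t]]] + t(blk)
    }
  }
  cV <- chol(V)
  Vy <- backsolve(cV, forwardsolve(t(cV), y))
  VX <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, VX)
  cXX <- chol(XtViX)
  bhat <- backsolve(cXX, forwardsolve(t(cXX), crossprod(X, Vy)))
  Py <- drop(Vy - VX %*% bhat)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXX))) + sum(y * Py))
  list(Vg = Vg_list, loglik = ll, beta = drop(bhat), Py = Py, obs = obs,
       rows = rows, converged = TRUE, n_obs = N)
}
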