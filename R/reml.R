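# REML engine for the multi-environment GBLUP model
#
#   y = X b + Z1 u1 + sum_p Zp up + e
#
# with Var(u1) = Go (x) G (environment-major Kronecker), iid nuisance terms
# Var(up) = sigma2_p I, and heterogeneous diagonal residuals per analysis
# environment. Estimation is EM-REML with optional average-information (AI)
# acceleration; EM guarantees likelihood ascent, AI gives speed near the
# optimum and falls back to EM whenever a step would leave the parameter
# space or decrease the restricted likelihood.
#
# Two interchangeable solvers compute each iteration's mixed-model-equation
# quantities:
#  * a general dense solver (any missingness pattern), and
#  * a fast solver for balanced designs (every line has the same plot count
#    in each environment) that exploits the eigendecomposition of G: the
#    genetic block of the MME becomes block-diagonal over eigenvectors, so an
#    iteration costs O(g v^3) small inversions plus Schur absorption of the
#    fixed/nuisance block, instead of a dense Cholesky of order g*v.

# ---- shared preparation -----------------------------------------------------

reml_prepare <- function(design, G) {
  ids <- rownames(G)
  line_idx <- match(design$rec_line, ids)
  if (anyNA(line_idx)) {
    miss <- unique(design$rec_line[is.na(line_idx)])
    sgs_stop(paste0("line(s) absent from the relationship matrix: ",
                    paste(utils::head(miss, 5), collapse = ", ")), "sgs_join_error")
  }
  g <- nrow(G); v <- length(design$env_levels); n <- design$n
  counts <- matrix(tabulate((design$rec_env - 1L) * g + line_idx, g * v), g, v)
  balanced <- all(apply(counts, 2L, function(cc) cc[1] > 0L && all(cc == cc[1])))
  env_idx <- split(seq_len(n), design$rec_env)
  list(ids = ids, g = g, v = v, n = n, line_idx = line_idx, counts = counts,
       balanced = balanced, env_idx = env_idx,
       n_env = vapply(env_idx, length, integer(1)))
}

# aggregate a record-space vector into a g x v (line, env) matrix
agg_line_env <- function(x, line_idx, rec_env, g, v) {
  out <- matrix(0, g, v)
  sums <- rowsum(x, group = (rec_env - 1L) * g + line_idx)
  out[as.integer(rownames(sums))] <- sums
  out
}

init_theta <- function(design, prep, frac_g = 0.4, frac_e = 0.5, cor0 = 0.2) {
  v <- prep$v
  s2 <- vapply(seq_len(v), function(e) {
    yy <- design$y[prep$env_idx[[e]]]
    max(stats::var(yy), 1e-6)
  }, numeric(1))
  Go <- diag(frac_g * s2, v)
  for (i in seq_len(v)) for (j in seq_len(v)) if (i != j)
    Go[i, j] <- cor0 * frac_g * sqrt(s2[i] * s2[j])
  sig_p <- stats::setNames(rep(0.05 * mean(s2), length(design$s_blocks) - 1L),
                           setdiff(names(design$s_blocks), "fixed"))
  list(Go = Go, sig_p = sig_p, sig_e = frac_e * s2)
}

# ---- eigenbasis preparation shared by both solvers -------------------------
#
# Both solvers work with the genetic effects expressed in the eigenbasis of
# G (u1 -> (I_v (x) U') u1), where the Kronecker prior contributes
# Go^-1_{vw} / lambda_k on the diagonal of each eigen-index. This avoids ever
# forming G^-1 densely: with nearly singular DH relationship matrices
# (smallest eigenvalues at the regularization ridge) the explicit
# Go^-1 (x) G^-1 products cancel catastrophically in the trace terms.

eigen_backend <- function(design, G, prep, dense = FALSE) {
  eig <- eigen(G, symmetric = TRUE)
  if (min(eig$values) <= 0)
    sgs_stop("relationship matrix is not positive definite; regularize_grm() it first",
             "sgs_numeric_error")
  U <- eig$vectors; lam <- eig$values
  g <- prep$g; v <- prep$v; s <- ncol(design$Ws)
  Gram <- vector("list", v); Wy <- vector("list", v)
  Mt <- vector("list", v); yt <- matrix(0, g, v)
  Curly <- if (dense) vector("list", v) else NULL
  for (e in seq_len(v)) {
    idx <- prep$env_idx[[e]]
    Wse <- design$Ws[idx, , drop = FALSE]
    Gram[[e]] <- crossprod(Wse)
    Wy[[e]] <- drop(crossprod(Wse, design$y[idx]))
    Mfull <- matrix(0, g, s)
    Ms <- rowsum(Wse, group = prep$line_idx[idx])
    Mfull[as.integer(rownames(Ms)), ] <- Ms
    Mt[[e]] <- crossprod(U, Mfull)
    zy <- numeric(g)
    zs <- rowsum(design$y[idx], group = prep$line_idx[idx])
    zy[as.integer(rownames(zs))] <- zs
    yt[, e] <- crossprod(U, zy)
    if (dense)  # U' diag(plot counts) U, the data part of the genetic block
      Curly[[e]] <- crossprod(U * sqrt(prep$counts[, e]))
  }
  logdetG <- sum(log(lam))
  list(U = U, lam = lam, Gram = Gram, Wy = Wy, Mt = Mt, yt = yt,
       Curly = Curly, cvec = prep$counts[1L, ], logdetG = logdetG, s = s)
}

fast_backend <- function(design, G, prep) eigen_backend(design, G, prep, dense = FALSE)

fast_solve <- function(bk, design, prep, theta) {
  g <- prep$g; v <- prep$v; s <- bk$s
  iGo <- solve(theta$Go)
  sige <- theta$sig_e
  cinv <- bk$cvec / sige
  # per-eigenvalue v x v systems A_k = Go^-1 / lam_k + diag(counts / sig_e),
  # inverted for all k at once through the generalized eigendecomposition of
  # Go^-1 against the (positive) diagonal data part:
  #   A_k^-1 = P diag(lam_k / (mu_j + lam_k)) P',  P = D^-1/2 Q
  Dm <- 1 / sqrt(cinv)
  Em <- (Dm %o% Dm) * iGo
  eg <- eigen((Em + t(Em)) / 2, symmetric = TRUE)
  Pm <- Dm * eg$vectors
  mu <- pmax(eg$values, 0)
  Wk <- bk$lam / outer(bk$lam, mu, `+`)          # g x v weights
  Ainv <- array(0, c(g, v, v))
  for (a in seq_len(v)) for (b in seq_len(a)) {
    Ainv[, a, b] <- drop(Wk %*% (Pm[a, ] * Pm[b, ]))
    if (a != b) Ainv[, b, a] <- Ainv[, a, b]
  }
  logdetA <- sum(log1p(outer(1 / bk$lam, mu))) + g * sum(log(cinv))
  # B~_v = C_u1^-1 C_1s block v in the eigenbasis
  Bt <- vector("list", v)
  for (a in seq_len(v)) {
    acc <- matrix(0, g, s)
    for (w in seq_len(v)) acc <- acc + (Ainv[, a, w] / sige[w]) * bk$Mt[[w]]
    Bt[[a]] <- acc
  }
  Css <- matrix(0, s, s)
  for (e in seq_len(v)) Css <- Css + bk$Gram[[e]] / sige[e]
  for (p in setdiff(names(design$s_blocks), "fixed"))
    Css[cbind(design$s_blocks[[p]], design$s_blocks[[p]])] <-
      Css[cbind(design$s_blocks[[p]], design$s_blocks[[p]])] + 1 / theta$sig_p[p]
  Cs1B <- matrix(0, s, s)
  for (e in seq_len(v)) Cs1B <- Cs1B + crossprod(bk$Mt[[e]], Bt[[e]]) / sige[e]
  S <- Css - Cs1B
  chS <- chol((S + t(S)) / 2)
  Sinv <- chol2inv(chS)

  rt <- sweep(bk$yt, 2L, sige, "/")
  xt0 <- matrix(0, g, v)
  for (a in seq_len(v)) for (w in seq_len(v)) xt0[, a] <- xt0[, a] + Ainv[, a, w] * rt[, w]
  rhs_s <- Reduce(`+`, lapply(seq_len(v), function(e) bk$Wy[[e]] / sige[e]))
  cs1x <- Reduce(`+`, lapply(seq_len(v), function(e)
    drop(crossprod(bk$Mt[[e]], xt0[, e])) / sige[e]))
  x_s <- drop(Sinv %*% (rhs_s - cs1x))
  ut <- xt0 - vapply(seq_len(v), function(e) drop(Bt[[e]] %*% x_s), numeric(g))
  u1 <- bk$U %*% ut

  BtS <- lapply(Bt, function(b) b %*% Sinv)
  T1 <- matrix(0, v, v); T2 <- matrix(0, v, v)
  for (i in seq_len(v)) for (j in seq_len(v)) {
    T1[i, j] <- sum(Ainv[, i, j] / bk$lam)
    T2[i, j] <- sum((Bt[[i]] / bk$lam) * BtS[[j]])
  }
  Tm <- (T1 + T2 + t(T1 + T2)) / 2
  Uq <- crossprod(ut, ut / bk$lam)

  lev <- numeric(v)
  for (e in seq_len(v)) {
    MtB <- crossprod(bk$Mt[[e]], Bt[[e]])
    lev[e] <- sum(Sinv * bk$Gram[[e]]) - 2 * sum(Sinv * t(MtB)) +
      bk$cvec[e] * (sum(Ainv[, e, e]) + sum(Bt[[e]] * BtS[[e]]))
  }

  fitted <- as.numeric(design$Ws %*% x_s) + u1[cbind(prep$line_idx, design$rec_env)]
  resid <- design$y - fitted
  resid_ss <- vapply(seq_len(v), function(e) sum(resid[prep$env_idx[[e]]]^2), numeric(1))
  yry <- sum(design$y^2 / sige[design$rec_env])
  yPy <- yry - (sum(x_s * rhs_s) + sum(ut * rt))
  logdetC <- as.numeric(logdetA) + 2 * sum(log(diag(chS)))
  logL <- -0.5 * (sum(prep$n_env * log(sige)) + g * determinant(theta$Go, TRUE)$modulus +
                    v * bk$logdetG +
                    sum(lengths(design$s_blocks[-1]) * log(theta$sig_p)) +
                    logdetC + yPy)

  solveC <- function(rhs_s_in, rhs_1) {
    rt2 <- crossprod(bk$U, rhs_1)
    x0 <- matrix(0, g, v)
    for (a in seq_len(v)) for (w in seq_len(v)) x0[, a] <- x0[, a] + Ainv[, a, w] * rt2[, w]
    adj <- Reduce(`+`, lapply(seq_len(v), function(e)
      drop(crossprod(bk$Mt[[e]], x0[, e])) / sige[e]))
    xs <- drop(Sinv %*% (rhs_s_in - adj))
    xu <- x0 - vapply(seq_len(v), function(e) drop(Bt[[e]] %*% xs), numeric(g))
    list(x_s = xs, x1 = bk$U %*% xu)
  }

  list(logL = as.numeric(logL), x_s = x_s, u1 = u1, T = Tm, Uq = Uq,
       trS = diag(Sinv), lev = lev, resid = resid, resid_ss = resid_ss,
       fitted = fitted, solveC = solveC)
}

# ---- general solver (any missingness pattern) ------------------------------

dense_backend <- function(design, G, prep) eigen_backend(design, G, prep, dense = TRUE)

dense_solve <- function(bk, design, prep, theta) {
  g <- prep$g; v <- prep$v; s <- bk$s; q <- s + g * v
  iGo <- solve(theta$Go)
  sige <- theta$sig_e
  ilam <- 1 / bk$lam
  C <- matrix(0, q, q)
  si <- seq_len(s)
  C[si, si] <- Reduce(`+`, lapply(seq_len(v), function(e) bk$Gram[[e]] / sige[e]))
  for (p in setdiff(names(design$s_blocks), "fixed"))
    C[cbind(design$s_blocks[[p]], design$s_blocks[[p]])] <-
      C[cbind(design$s_blocks[[p]], design$s_blocks[[p]])] + 1 / theta$sig_p[p]
  ublk <- function(e) s + (e - 1L) * g + seq_len(g)
  for (e in seq_len(v)) {
    ue <- ublk(e)
    C[si, ue] <- t(bk$Mt[[e]]) / sige[e]
    C[ue, si] <- bk$Mt[[e]] / sige[e]
    for (w in seq_len(v)) {
      uw <- ublk(w)
      B <- if (e == w) bk$Curly[[e]] / sige[e] else matrix(0, g, g)
      diag(B) <- diag(B) + iGo[e, w] * ilam
      C[ue, uw] <- B
    }
  }
  chC <- chol(C)
  Cinv <- chol2inv(chC)
  rhs <- c(Reduce(`+`, lapply(seq_len(v), function(e) bk$Wy[[e]] / sige[e])),
           as.numeric(sweep(bk$yt, 2L, sige, "/")))
  th <- drop(Cinv %*% rhs)
  x_s <- th[si]
  ut <- matrix(th[-si], g, v)
  u1 <- bk$U %*% ut

  Tm <- matrix(0, v, v)
  for (i in seq_len(v)) for (j in seq_len(v))
    Tm[i, j] <- sum(ilam * Cinv[cbind(ublk(i), ublk(j))])
  Tm <- (Tm + t(Tm)) / 2
  Uq <- crossprod(ut, ut * ilam)

  lev <- vapply(seq_len(v), function(e) {
    ue <- ublk(e)
    sum(Cinv[si, si] * bk$Gram[[e]]) +
      2 * sum(Cinv[si, ue] * t(bk$Mt[[e]])) +
      sum(prep$counts[, e] * rowSums((bk$U %*% Cinv[ue, ue]) * bk$U))
  }, numeric(1))

  fitted <- as.numeric(design$Ws %*% x_s) + u1[cbind(prep$line_idx, design$rec_env)]
  resid <- design$y - fitted
  resid_ss <- vapply(seq_len(v), function(e) sum(resid[prep$env_idx[[e]]]^2), numeric(1))
  yPy <- sum(design$y^2 / sige[design$rec_env]) - sum(th * rhs)
  logL <- -0.5 * (sum(prep$n_env * log(sige)) + g * determinant(theta$Go, TRUE)$modulus +
                    v * bk$logdetG +
                    sum(lengths(design$s_blocks[-1]) * log(theta$sig_p)) +
                    2 * sum(log(diag(chC))) + yPy)

  solveC <- function(rhs_s_in, rhs_1) {
    r <- c(rhs_s_in, as.numeric(crossprod(bk$U, rhs_1)))
    sol <- backsolve(chC, backsolve(chC, r, transpose = TRUE))
    list(x_s = sol[si], x1 = bk$U %*% matrix(sol[-si], g, v))
  }

  list(logL = as.numeric(logL), x_s = x_s, u1 = u1, T = Tm, Uq = Uq,
       trS = diag(Cinv)[si], lev = lev, resid = resid,
       resid_ss = resid_ss, fitted = fitted, solveC = solveC)
}

# ---- parameter updates ------------------------------------------------------

# inner EM for the factor-analytic decomposition Sbar ~ Lambda Lambda' + Psi
fa_mstep <- function(Sbar, Lambda, Psi, floor = 1e-8, max_iter = 200, tol = 1e-10) {
  for (it in seq_len(max_iter)) {
    Sigma <- tcrossprod(Lambda) + diag(Psi, nrow(Sbar))
    Bmat <- crossprod(Lambda, solve(Sigma))            # m x v
    Eff <- diag(ncol(Lambda)) - Bmat %*% Lambda + Bmat %*% Sbar %*% t(Bmat)
    Lnew <- Sbar %*% t(Bmat) %*% solve(Eff)
    Pnew <- pmax(diag(Sbar - Lnew %*% Bmat %*% Sbar), floor)
    delta <- max(abs(Lnew - Lambda), abs(Pnew - Psi))
    Lambda <- Lnew; Psi <- Pnew
    if (delta < tol) break
  }
  list(Lambda = Lambda, Psi = Psi)
}

fa_init <- function(Go, m) {
  e <- eigen((Go + t(Go)) / 2, symmetric = TRUE)
  Lambda <- e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(m)], 1e-8)), m)
  Psi <- pmax(diag(Go - tcrossprod(Lambda)), 0.1 * diag(Go))
  list(Lambda = Lambda, Psi = Psi)
}

# lower-triangular rotation of the loadings (rotation is likelihood-free)
fa_rotate <- function(Lambda) {
  qrL <- qr(t(Lambda))
  L <- t(qr.R(qrL))
  sgn <- sign(diag(as.matrix(L[seq_len(ncol(L)), , drop = FALSE])))
  sgn[sgn == 0] <- 1
  sweep(L, 2L, sgn, "*")
}

em_update <- function(sol, theta, design, prep, structure, fa_state, floors) {
  g <- prep$g
  Sbar <- (sol$Uq + sol$T) / g
  Sbar <- (Sbar + t(Sbar)) / 2
  if (structure == "US") {
    Go <- Sbar
  } else if (structure == "DIAG") {
    Go <- diag(diag(Sbar), prep$v)
  } else {  # FA
    fa_state <- fa_mstep(Sbar, fa_state$Lambda, fa_state$Psi, floor = floors$psi)
    Go <- tcrossprod(fa_state$Lambda) + diag(fa_state$Psi, prep$v)
  }
  sig_p <- theta$sig_p
  for (p in names(sig_p)) {
    blk <- design$s_blocks[[p]]
    sig_p[p] <- max((sum(sol$x_s[blk]^2) + sum(sol$trS[blk])) / length(blk),
                    floors$var)
  }
  sig_e <- pmax((sol$resid_ss + sol$lev) / prep$n_env, floors$var)
  list(theta = list(Go = Go, sig_p = sig_p, sig_e = sig_e), fa_state = fa_state)
}

# Average-information step. The score and AI matrix are formed over the
# elements of Go (vech coordinates) plus the scalar variances; for the FA
# structure they are mapped onto (Lambda, Psi) by the chain rule through the
# Jacobian of Go = Lambda Lambda' + Psi.
ai_update <- function(sol, theta, design, prep, G, floors,
                      structure = "US", fa_state = NULL, damp = 1) {
  v <- prep$v; g <- prep$g
  H <- solve(theta$Go)
  Py <- sol$resid / theta$sig_e[design$rec_env]
  tmat <- agg_line_env(Py, prep$line_idx, design$rec_env, g, v)
  Gt <- G %*% tmat
  Mq <- crossprod(tmat, Gt)

  pairs <- if (structure == "DIAG") {
    cbind(seq_len(v), seq_len(v))
  } else {
    pp <- which(upper.tri(diag(v), diag = TRUE), arr.ind = TRUE)
    pp[order(pp[, 1], pp[, 2]), , drop = FALSE]
  }
  nuis <- names(theta$sig_p)
  npar <- nrow(pairs) + length(nuis) + v

  HTH <- H %*% sol$T %*% H
  score <- numeric(npar); Wmat <- matrix(0, prep$n, npar)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    mult <- if (i == j) 1 else 2
    score[k] <- -0.5 * mult * (g * H[i, j] - HTH[i, j] - Mq[i, j])
    w <- numeric(prep$n)
    ei <- design$rec_env == i; ej <- design$rec_env == j
    w[ei] <- w[ei] + Gt[prep$line_idx[ei], j]
    if (i != j) w[ej] <- w[ej] + Gt[prep$line_idx[ej], i]
    Wmat[, k] <- w
  }
  off <- nrow(pairs)
  for (k in seq_along(nuis)) {
    blk <- design$s_blocks[[nuis[k]]]
    zp <- drop(crossprod(design$Ws[, blk, drop = FALSE], Py))
    score[off + k] <- -0.5 * (length(blk) / theta$sig_p[nuis[k]] -
                                sum(sol$trS[blk]) / theta$sig_p[nuis[k]]^2 -
                                sum(zp^2))
    Wmat[, off + k] <- drop(design$Ws[, blk, drop = FALSE] %*% zp)
  }
  off <- off + length(nuis)
  for (e in seq_len(v)) {
    idx <- prep$env_idx[[e]]
    score[off + e] <- -0.5 * (prep$n_env[e] / theta$sig_e[e] -
                                sol$lev[e] / theta$sig_e[e]^2 -
                                sum(Py[idx]^2))
    w <- numeric(prep$n); w[idx] <- Py[idx]
    Wmat[, off + e] <- w
  }

  PW <- matrix(0, prep$n, npar)
  for (k in seq_len(npar)) {
    w <- Wmat[, k]
    rw <- w / theta$sig_e[design$rec_env]
    rhs_s <- drop(crossprod(design$Ws, rw))
    rhs_1 <- agg_line_env(rw, prep$line_idx, design$rec_env, g, v)
    cw <- sol$solveC(rhs_s, rhs_1)
    wc <- drop(design$Ws %*% cw$x_s) + cw$x1[cbind(prep$line_idx, design$rec_env)]
    PW[, k] <- rw - wc / theta$sig_e[design$rec_env]
  }
  AI <- 0.5 * crossprod(Wmat, PW)
  AI <- (AI + t(AI)) / 2

  if (structure == "FA") {
    # chain rule onto the lower-triangular loadings and specific variances;
    # rotate first (rotation leaves Go and the likelihood unchanged)
    Lam <- fa_rotate(fa_state$Lambda); Psi <- fa_state$Psi
    m <- ncol(Lam)
    lam_par <- which(row(Lam) >= col(Lam), arr.ind = TRUE)
    n_fa <- nrow(lam_par) + v
    Jac <- matrix(0, npar, n_fa + length(nuis) + v)
    for (p in seq_len(nrow(lam_par))) {
      cc <- lam_par[p, 1]; kk <- lam_par[p, 2]
      for (q in seq_len(nrow(pairs))) {
        i <- pairs[q, 1]; j <- pairs[q, 2]
        Jac[q, p] <- (i == cc) * Lam[j, kk] + (j == cc) * Lam[i, kk]
        if (i == j && i == cc) Jac[q, p] <- 2 * Lam[i, kk]
      }
    }
    for (p in seq_len(v)) {
      q <- which(pairs[, 1] == p & pairs[, 2] == p)
      Jac[q, nrow(lam_par) + p] <- 1
    }
    for (p in seq_len(length(nuis) + v))
      Jac[nrow(pairs) + p, n_fa + p] <- 1
    score <- drop(crossprod(Jac, score))
    AI <- crossprod(Jac, AI %*% Jac)
    J <- c(rep(1, nrow(lam_par)), pmax(Psi, floors$var), theta$sig_p, theta$sig_e)
    score_t <- J * score
    AI_t <- AI * tcrossprod(J)
    npar_t <- length(score_t)
    delta <- tryCatch(solve(AI_t + diag(1e-8 * max(diag(AI_t)), npar_t), score_t),
                      error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) return(NULL)
    # clamp each coordinate separately: a single runaway direction (e.g. a
    # variance collapsing to its floor on the log scale) must not shrink the
    # whole Newton step
    delta <- damp * pmin(pmax(delta, -4), 4)
    Lam[lam_par] <- Lam[lam_par] + delta[seq_len(nrow(lam_par))]
    Psi <- pmax(Psi * exp(delta[nrow(lam_par) + seq_len(v)]), floors$psi)
    sig_p <- pmax(theta$sig_p * exp(delta[n_fa + seq_along(nuis)]), floors$var)
    sig_e <- pmax(theta$sig_e * exp(delta[n_fa + length(nuis) + seq_len(v)]),
                  floors$var)
    Go <- tcrossprod(Lam) + diag(Psi, v)
    return(list(theta = list(Go = Go, sig_p = sig_p, sig_e = sig_e),
                fa_state = list(Lambda = Lam, Psi = Psi)))
  }

  # Newton step with variances on the log scale (keeps them positive and the
  # step well scaled when components sit near zero); Go entries stay linear
  # and are projected back to positive definite if the step overshoots.
  J <- c(rep(1, nrow(pairs)), theta$sig_p, theta$sig_e)
  score_t <- J * score
  AI_t <- AI * tcrossprod(J)
  delta <- tryCatch(solve(AI_t + diag(1e-8 * max(diag(AI_t)), npar), score_t),
                    error = function(e) NULL)
  if (is.null(delta) || !all(is.finite(delta))) return(NULL)
  delta <- damp * pmin(pmax(delta, -4), 4)  # per-coordinate cap, see FA branch
  Go <- theta$Go
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Go[i, j] <- Go[i, j] + delta[k]
    if (i != j) Go[j, i] <- Go[i, j]
  }
  eg <- eigen(Go, symmetric = TRUE)
  if (min(eg$values) < floors$var)
    Go <- eg$vectors %*% (pmax(eg$values, floors$var) * t(eg$vectors))
  sig_p <- pmax(theta$sig_p * exp(delta[nrow(pairs) + seq_along(nuis)]),
                floors$var)
  sig_e <- pmax(theta$sig_e * exp(delta[nrow(pairs) + length(nuis) + seq_len(v)]),
                floors$var)
  list(theta = list(Go = Go, sig_p = sig_p, sig_e = sig_e), fa_state = fa_state)
}

# pack the parameter state into one vector for EM extrapolation: loadings and
# Go entries linear, variances on the log scale
pack_state <- function(theta, fa_state, structure) {
  if (structure == "FA") {
    c(as.numeric(fa_state$Lambda), log(fa_state$Psi),
      log(theta$sig_p), log(theta$sig_e))
  } else {
    c(theta$Go[upper.tri(theta$Go, diag = TRUE)],
      log(theta$sig_p), log(theta$sig_e))
  }
}

unpack_state <- function(p, theta, fa_state, structure, floors) {
  v <- length(theta$sig_e)
  if (structure == "FA") {
    m <- ncol(fa_state$Lambda)
    Lam <- matrix(p[seq_len(v * m)], v, m)
    Psi <- pmax(exp(p[v * m + seq_len(v)]), floors$psi)
    fa_state <- list(Lambda = Lam, Psi = Psi)
    Go <- tcrossprod(Lam) + diag(Psi, v)
    off <- v * m + v
  } else {
    nv <- v * (v + 1) / 2
    Go <- matrix(0, v, v)
    Go[upper.tri(Go, diag = TRUE)] <- p[seq_len(nv)]
    Go <- Go + t(Go) - diag(diag(Go), v)
    if (structure == "DIAG") Go <- diag(diag(Go), v)
    eg <- eigen(Go, symmetric = TRUE)
    if (min(eg$values) < floors$var)
      Go <- eg$vectors %*% (pmax(eg$values, floors$var) * t(eg$vectors))
    off <- nv
  }
  np <- length(theta$sig_p)
  sig_p <- pmax(exp(p[off + seq_len(np)]), floors$var)
  names(sig_p) <- names(theta$sig_p)
  sig_e <- pmax(exp(p[off + np + seq_len(v)]), floors$var)
  if (!all(is.finite(Go)) || !all(is.finite(sig_e)) || !all(is.finite(sig_p)))
    return(NULL)
  list(theta = list(Go = Go, sig_p = sig_p, sig_e = sig_e), fa_state = fa_state)
}

# ---- the driver -------------------------------------------------------------

reml_engine <- function(design, G, structure = c("FA", "US", "DIAG"), m = NULL,
                        tol = 1e-6, max_iter = 200L,
                        method = c("auto", "ai", "em"), init = NULL,
                        verbose = FALSE, em_burnin = 3L) {
  structure <- match.arg(structure)
  method <- match.arg(method)
  prep <- reml_prepare(design, G)
  v <- prep$v
  if (structure == "FA") {
    if (v < 2L) sgs_stop("factor-analytic structure needs at least 2 environments",
                         "sgs_config_error")
    if (is.null(m)) m <- if (v < 4L) 1L else 2L
    if (m < 1L || m >= v) sgs_stop("need 1 <= m < n_environments", "sgs_config_error")
  }
  bk <- if (prep$balanced) fast_backend(design, G, prep) else dense_backend(design, G, prep)
  solve_fn <- if (prep$balanced) fast_solve else dense_solve

  theta <- init %||% init_theta(design, prep)
  theta$sig_p <- theta$sig_p[setdiff(names(design$s_blocks), "fixed")]
  if (structure == "DIAG") theta$Go <- diag(diag(theta$Go), v)
  fa_state <- if (structure == "FA") fa_init(theta$Go, m) else NULL
  if (structure == "FA")
    theta$Go <- tcrossprod(fa_state$Lambda) + diag(fa_state$Psi, v)
  floors <- list(var = 1e-8 * stats::var(design$y), psi = 1e-8 * stats::var(design$y))
  use_ai <- method %in% c("auto", "ai")

  sol <- solve_fn(bk, design, prep, theta)
  best <- list(theta = theta, sol = sol, fa = fa_state)
  hist <- sol$logL
  pinned <- character(0); converged <- FALSE
  ai_cooldown <- 0L; em_gain_prev <- NA_real_; stall <- 0L
  if (verbose) message(sprintf("iter %3d  logL %.6f  (init)", 1L, sol$logL))
  for (it in seq_len(max_iter)) {
    step_type <- "em"
    theta_new <- NULL; fa_new <- best$fa; sol_new <- NULL
    if (use_ai && it > em_burnin && it > ai_cooldown) {
      # try a full Newton step, then a damped one; an ascent-destroying step
      # is discarded and AI rests for a few iterations
      for (damp in c(1, 0.25)) {
        upd <- ai_update(best$sol, best$theta, design, prep, G, floors,
                         structure, best$fa, damp = damp)
        if (is.null(upd)) break
        cand <- solve_fn(bk, design, prep, upd$theta)
        if (cand$logL >= best$sol$logL - 1e-8) {
          theta_new <- upd$theta; fa_new <- upd$fa_state; sol_new <- cand
          step_type <- "ai"
          break
        }
      }
      if (is.null(theta_new)) ai_cooldown <- it + 4L
    }
    if (is.null(theta_new)) {
      upd <- em_update(best$sol, best$theta, design, prep, structure, best$fa, floors)
      theta_new <- upd$theta; fa_new <- upd$fa_state
      sol_new <- solve_fn(bk, design, prep, theta_new)
      # Aitken-style extrapolation of a geometrically creeping EM tail: jump
      # ahead along the EM direction by the factor the gain ratio implies,
      # guarded by the likelihood
      gain <- sol_new$logL - best$sol$logL
      if (is.finite(em_gain_prev) && gain > 0 && gain < em_gain_prev) {
        K <- min(1 / (1 - gain / em_gain_prev), 30)
        if (K > 2) {
          pb <- pack_state(best$theta, best$fa, structure)
          pn <- pack_state(theta_new, fa_new, structure)
          cand <- unpack_state(pn + (K - 1) * (pn - pb), theta_new, fa_new,
                               structure, floors)
          if (!is.null(cand)) {
            sol_x <- tryCatch(solve_fn(bk, design, prep, cand$theta),
                              error = function(e) NULL)
            if (!is.null(sol_x) && is.finite(sol_x$logL) &&
                sol_x$logL > sol_new$logL) {
              theta_new <- cand$theta; fa_new <- cand$fa_state
              sol_new <- sol_x; step_type <- "emx"
              gain <- sol_new$logL - best$sol$logL
            }
          }
        }
      }
      # boundary probing: a variance component creeping geometrically toward
      # zero (the reduced-rank "XFA" regime for Psi) is tested directly at
      # its floor, again guarded by the likelihood
      if (it %% 10L == 0L) {
        pb <- pack_state(best$theta, best$fa, structure)
        pn <- pack_state(theta_new, fa_new, structure)
        n_lin <- if (structure == "FA") length(fa_new$Lambda) else
          sum(upper.tri(theta_new$Go, diag = TRUE))
        logc <- seq(n_lin + 1L, length(pn))
        shrink <- logc[pn[logc] < pb[logc] - 0.01]
        if (length(shrink)) {
          px <- pn
          px[shrink] <- log(floors$var)
          cand <- unpack_state(px, theta_new, fa_new, structure, floors)
          if (!is.null(cand)) {
            sol_x <- tryCatch(solve_fn(bk, design, prep, cand$theta),
                              error = function(e) NULL)
            if (!is.null(sol_x) && is.finite(sol_x$logL) &&
                sol_x$logL > sol_new$logL) {
              theta_new <- cand$theta; fa_new <- cand$fa_state
              sol_new <- sol_x; step_type <- "emb"
            }
          }
        }
      }
      em_gain_prev <- if (step_type == "em") gain else NA_real_
    } else em_gain_prev <- NA_real_
    hist <- c(hist, sol_new$logL)
    if (verbose) message(sprintf("iter %3d  logL %.6f  (%s)", it + 1L,
                                 sol_new$logL, step_type))
    pinned <- union(pinned, c(
      names(theta_new$sig_p)[theta_new$sig_p <= floors$var],
      design$env_levels[theta_new$sig_e <= floors$var]))
    done <- abs(sol_new$logL - best$sol$logL) < tol
    if (sol_new$logL >= best$sol$logL) {
      best <- list(theta = theta_new, sol = sol_new, fa = fa_new)
      stall <- 0L
    } else if (startsWith(step_type, "em")) {
      # the EM fixed point can sit a hair below the best visited likelihood
      # in floating point; repeating the identical step forever is pointless
      stall <- stall + 1L
      if (stall >= 3L) {
        converged <- sol_new$logL > best$sol$logL - 1e-6
        break
      }
    }
    if (done) { converged <- TRUE; break }
  }
  theta <- best$theta; sol <- best$sol; fa_state <- best$fa

  Lambda <- Psi <- NULL
  if (structure == "FA") {
    Lambda <- fa_rotate(fa_state$Lambda)
    rownames(Lambda) <- design$env_levels
    Psi <- stats::setNames(fa_state$Psi, design$env_levels)
  }
  dimnames(theta$Go) <- list(design$env_levels, design$env_levels)
  rownames(sol$u1) <- prep$ids; colnames(sol$u1) <- design$env_levels
  beta <- stats::setNames(sol$x_s[design$s_blocks$fixed],
                          colnames(design$Ws)[design$s_blocks$fixed])
  u_nuis <- lapply(design$s_blocks[setdiff(names(design$s_blocks), "fixed")],
                   function(blk) stats::setNames(sol$x_s[blk], colnames(design$Ws)[blk]))

  list(Go = theta$Go, Lambda = Lambda, Psi = Psi, m = if (structure == "FA") m else NULL,
       sigma2_nuisance = theta$sig_p,
       sigma2_resid = stats::setNames(theta$sig_e, design$env_levels),
       beta = beta, u_nuisance = u_nuis, gebv = sol$u1,
       fitted = sol$fitted, residuals = sol$resid,
       logLik_trace = hist, logLik = sol$logL, converged = converged,
       n_iter = length(hist) - 1L, pinned = pinned,
       balanced = prep$balanced, structure = structure,
       counts = prep$counts)
}
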