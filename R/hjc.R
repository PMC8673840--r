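## Missed-event (dead-time) correction for aggregated Markov dwell densities.
##
## Observed ("apparent") dwells at a fixed dead time td are described by the
## survivor matrices ^X R(u): the probability (matrix over within-class
## states) that an apparent sojourn in class X lasts at least u + td, given
## undetected excursions into the other class shorter than td. The apparent
## dwell density factors as
##
##   G_X(t) = ^X R(t - td) exp(Q_XX td) Q_XY ,   t >= td.
##
## ^X R is computed two ways, joined at u_switch = 2 td:
##  * u <= 2 td: numerically exact solution of the Volterra equation
##    R'(u) = R(u) Q_XX + int_0^{min(u,td)} R(u-v) Q_XY e^{Q_YY v} Q_YX dv
##    on a fine grid (compiled predictor-corrector, step td/n_per_td);
##  * u > 2 td: the standard asymptotic form sum_i A_i exp(s_i u), where the
##    s_i are the roots of det W(s) = 0 with
##    W(s) = sI - Q_XX - Q_XY phi_td(sI - Q_YY) Q_YX,
##    phi_td(x) = (1 - e^{-x td}) / x  (entire, applied as a matrix function),
##    and A_i = (c_i r_i) / (r_i W'(s_i) c_i) from the null vectors of W(s_i).
##
## With a single open state the sequence likelihood telescopes into per-dwell
## scalar terms, so the whole apparatus reduces to two scalar functions of
## the excess duration u (one per class); everything below exploits that the
## "other" class is either one-dimensional or diagonalized once.

## phi_td and its derivative, with series fallback near 0 (both entire)
phi_td <- function(x, td) {
  small <- abs(x * td) < 1e-6
  out <- numeric(length(x))
  out[!small] <- (1 - exp(-x[!small] * td)) / x[!small]
  xs <- x[small]
  out[small] <- td * (1 - xs * td / 2 + (xs * td)^2 / 6)
  out
}

dphi_td <- function(x, td) {
  small <- abs(x * td) < 1e-6
  out <- numeric(length(x))
  xb <- x[!small]
  out[!small] <- (td * xb * exp(-xb * td) - 1 + exp(-xb * td)) / xb^2
  xs <- x[small]
  out[small] <- -td^2 / 2 + xs * td^3 / 3 - xs^2 * td^4 / 8
  out
}

## Vectorized det W(s), plus W(s) and W'(s) as matrices at scalar s, for one
## class. bl holds blocks relative to class X; ey the eigensystem of Qyy.
me_W_factory <- function(bl, ey, td) {
  kX <- nrow(bl$Qxx)
  if (kX == 1) {
    ## other class is 2x2: W scalar, s - qxx - sum_i w_i phi(s - lambda_i)
    wv <- as.numeric(bl$Qxy %*% ey$vectors) * as.numeric(ey$inv %*% bl$Qyx)
    lam <- ey$values
    qxx <- bl$Qxx[1, 1]
    detW <- function(s) {
      acc <- s - qxx
      for (i in seq_along(wv)) acc <- acc - wv[i] * phi_td(s - lam[i], td)
      acc
    }
    list(detW = detW,
         W = function(s) matrix(detW(s), 1, 1),
         dW = function(s) {
           acc <- 1
           for (i in seq_along(wv)) acc <- acc - wv[i] * dphi_td(s - lam[i], td)
           matrix(acc, 1, 1)
         })
  } else {
    ## other class is 1x1: W(s) = sI - Qxx - phi(s - lam) * C, C = Qxy Qyx
    C <- bl$Qxy %*% bl$Qyx
    lam <- ey$values[1]
    A <- bl$Qxx
    list(detW = function(s) {
           ph <- phi_td(s - lam, td)
           (s - A[1, 1] - ph * C[1, 1]) * (s - A[2, 2] - ph * C[2, 2]) -
             (A[1, 2] + ph * C[1, 2]) * (A[2, 1] + ph * C[2, 1])
         },
         W = function(s) diag(2) * s - A - phi_td(s - lam, td) * C,
         dW = function(s) diag(2) - dphi_td(s - lam, td) * C)
  }
}

## Roots of det W(s) = 0: kX real negative roots (the apparent time
## constants). Vectorized sign-change scan plus uniroot refinement; det W is
## entire in s, so the scan is safe.
me_roots <- function(wf, kX, rate_scale) {
  lo <- -60 * rate_scale
  hi <- -1e-9 * rate_scale
  grid <- -exp(seq(log(-lo), log(-hi), length.out = 600))
  vals <- wf$detW(grid)
  sgn <- sign(vals)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flips, function(i)
    stats::uniroot(wf$detW, c(grid[i], grid[i + 1]),
                   tol = 1e-13 * rate_scale)$root, numeric(1))
  roots <- sort(unique(roots), decreasing = TRUE)
  if (length(roots) < kX) {
    stop("missed-event asymptotics: found ", length(roots),
         " roots of det W(s), expected ", kX)
  }
  roots[seq_len(kX)]
}

## Asymptotic matrices A_i with R(u) ~ sum_i A_i exp(s_i u)
me_asymptotic <- function(bl, wf, td) {
  kX <- nrow(bl$Qxx)
  rate_scale <- max(abs(c(diag(bl$Qxx), diag(bl$Qyy))))
  s <- me_roots(wf, kX, rate_scale)
  A <- vector("list", kX)
  for (i in seq_len(kX)) {
    W <- wf$W(s[i])
    dW <- wf$dW(s[i])
    if (kX == 1) {
      A[[i]] <- matrix(1 / dW[1, 1], 1, 1)
    } else {
      ## right and left null vectors of the singular 2x2 W
      cvec <- if (abs(W[1, 1]) + abs(W[1, 2]) >= abs(W[2, 1]) + abs(W[2, 2]))
        c(W[1, 2], -W[1, 1]) else c(W[2, 2], -W[2, 1])
      rvec <- if (abs(W[1, 1]) + abs(W[2, 1]) >= abs(W[1, 2]) + abs(W[2, 2]))
        c(W[2, 1], -W[1, 1]) else c(W[2, 2], -W[1, 2])
      denom <- as.numeric(rvec %*% dW %*% cvec)
      A[[i]] <- outer(cvec, rvec) / denom
    }
  }
  list(s = s, A = A)
}

## Full missed-event apparatus for one class: exact grid on [0, 2 td] plus
## asymptotic parameters.
me_class <- function(model, class = c("open", "closed"), dead_time_ms,
                     n_per_td = 80L) {
  class <- match.arg(class)
  b <- class_blocks(model)
  bl <- if (class == "open") {
    list(Qxx = b$QAA, Qxy = b$QAF, Qyy = b$QFF, Qyx = b$QFA)
  } else {
    list(Qxx = b$QFF, Qxy = b$QFA, Qyy = b$QAA, Qyx = b$QAF)
  }
  td <- dead_time_ms / 1000
  kX <- nrow(bl$Qxx)
  ey <- eigen2(bl$Qyy)
  h <- td / n_per_td
  m <- n_per_td
  n_steps <- 2L * n_per_td
  v <- (0:m) * h
  ## kernel K(v) = Qxy exp(Qyy v) Qyx on the v grid, built from the
  ## eigensystem of the (small) other-class block
  Kflat <- if (kX == 1) {
    wv <- as.numeric(bl$Qxy %*% ey$vectors) * as.numeric(ey$inv %*% bl$Qyx)
    kv <- numeric(m + 1L)
    for (i in seq_along(wv)) kv <- kv + wv[i] * exp(ey$values[i] * v)
    kv
  } else {
    C <- bl$Qxy %*% bl$Qyx
    as.numeric(outer(as.numeric(C), exp(ey$values[1] * v)))
  }
  Rflat <- volterra_grid(kX, bl$Qxx, Kflat, h, n_steps, m)
  wf <- me_W_factory(bl, ey, td)
  asym <- me_asymptotic(bl, wf, td)
  list(class = class, k = kX, td = td, h = h, u_grid = (0:n_steps) * h,
       Rflat = Rflat, asym = asym, blocks = bl)
}

## Collapse the survivor matrix against fixed left/right vectors into a
## scalar function of the excess duration u: f(u) = wl' R(u) wr, evaluated
## vectorized over u (grid interpolation below 2 td, asymptotics above).
me_scalar_eval <- function(mc, u, wl, wr) {
  k <- mc$k
  w <- as.numeric(outer(as.numeric(wl), as.numeric(wr)))
  fgrid <- colSums(matrix(mc$Rflat, k * k) * w)
  u <- pmax(u, 0)
  out <- numeric(length(u))
  u_max <- mc$u_grid[length(mc$u_grid)]
  inside <- u <= u_max
  if (any(inside)) {
    out[inside] <- stats::approx(mc$u_grid, fgrid, u[inside], rule = 2)$y
  }
  if (any(!inside)) {
    co <- vapply(seq_along(mc$asym$s), function(i)
      sum(w * as.numeric(mc$asym$A[[i]])), numeric(1))
    ub <- u[!inside]
    acc <- 0
    for (i in seq_along(co)) acc <- acc + co[i] * exp(mc$asym$s[i] * ub)
    out[!inside] <- acc
  }
  out
}

#' Mean apparent dwell duration under a fixed dead time
#'
#' Computes the expected duration of apparent (dead-time-regularized) open or
#' closed dwells for a gating model: brief excursions shorter than the dead
#' time are unresolved, so apparent dwells are systematically longer than the
#' underlying state sojourns. Used to validate the missed-event-corrected
#' likelihood against simulation.
#'
#' @param model a [gating_model()].
#' @param class `"open"` or `"closed"`.
#' @param dead_time_ms dead time in ms (0 gives the ideal mean dwell).
#' @return Mean apparent dwell duration in ms.
#' @export
apparent_dwell_mean <- function(model, class = c("open", "closed"),
                                dead_time_ms) {
  class <- match.arg(class)
  b <- class_blocks(model)
  if (dead_time_ms == 0) {
    if (class == "open") {
      return(1000 / (-b$QAA[1, 1]))
    }
    phiF <- b$QAF / sum(b$QAF)
    return(1000 * sum(phiF %*% solve(-b$QFF)))
  }
  mc <- me_class(model, class, dead_time_ms)
  td <- mc$td
  eQtd <- expm_small(mc$blocks$Qxx, td)
  wr <- eQtd %*% mc$blocks$Qxy %*% rep(1, ncol(mc$blocks$Qxy))
  wl <- if (class == "open") matrix(1, 1, 1) else
    matrix(mc$blocks$Qyx[1, ] / sum(mc$blocks$Qyx[1, ]), 1)
  ## density of excess duration u: g(u) = wl R(u) wr, t = td + u
  u <- mc$u_grid
  g <- me_scalar_eval(mc, u, wl, wr)
  h <- mc$h
  ## grid part: integrals of g and u*g by trapezoid
  trap <- function(y) h * (sum(y) - (y[1] + y[length(y)]) / 2)
  m0 <- trap(g); m1 <- trap(u * g)
  ## asymptotic tail from u_max to infinity
  w <- as.numeric(outer(as.numeric(wl), as.numeric(wr)))
  co <- vapply(seq_along(mc$asym$s), function(i)
    sum(w * as.numeric(mc$asym$A[[i]])), numeric(1))
  u_max <- u[length(u)]
  for (i in seq_along(co)) {
    s <- mc$asym$s[i]
    e <- co[i] * exp(s * u_max)
    m0 <- m0 - e / s                      # int_{umax}^inf e^{s u} du
    m1 <- m1 + e * (1 - s * u_max) / s^2  # int_{umax}^inf u e^{s u} du
  }
  ## normalize: mean apparent duration = td + E[u]
  1000 * (td + m1 / m0)
}
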