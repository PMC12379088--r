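# Independent oracles, deliberately written with different algorithms than
# the package code paths they check.

# circumcircle curvature of a dense point matrix, plain loop implementation
oracle_curvature <- function(xy) {
  n <- nrow(xy)
  k <- numeric(n)
  for (i in 2:(n - 1)) {
    a <- xy[i - 1, ]
    b <- xy[i, ]
    d <- xy[i + 1, ]
    cross <- (b[1] - a[1]) * (d[2] - a[2]) - (b[2] - a[2]) * (d[1] - a[1])
    la <- sqrt(sum((b - a)^2))
    lb <- sqrt(sum((d - b)^2))
    lc <- sqrt(sum((d - a)^2))
    k[i] <- 2 * cross / (la * lb * lc)
  }
  k[1] <- k[2]
  k[n] <- k[n - 1]
  k
}

# brute-force trimmed sign-change recount on a dense curve, explicit loop;
# returns the reported NINFL (count + 1)
oracle_ninfl <- function(xy, trim_factor = 0.3, edge_fraction = 0.05) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  L <- sum(seg)
  s <- c(0, cumsum(seg)) / L
  kap <- oracle_curvature(xy)
  thr <- 1 / (trim_factor * L)
  count <- 0L
  last_sign <- 0L
  last_s <- NA_real_
  for (i in seq_along(kap)) {
    if (abs(kap[i]) < thr) next
    sg <- sign(kap[i])
    if (last_sign != 0 && sg != last_sign) {
      if (last_s >= edge_fraction && s[i] <= 1 - edge_fraction) {
        count <- count + 1L
      }
    }
    last_sign <- sg
    last_s <- s[i]
  }
  count + 1L
}

# dense trapezoid of |kappa| d(arc)/L-normalised: total turning in radians
oracle_mci <- function(xy) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  kap <- abs(oracle_curvature(xy))
  sum((kap[-1] + kap[-length(kap)]) / 2 * seg)
}

# direct maximum-likelihood ordered logit (no random effects), written from
# the cell-probability definition with a plain optimiser over raw
# (threshold, beta) parameters
oracle_ordered_logit <- function(y, X) {
  levs <- sort(unique(y))
  K <- length(levs)
  yy <- match(y, levs)
  p <- ncol(X)
  nll <- function(par) {
    alpha <- sort(par[1:(K - 1)])
    if (any(diff(alpha) < 1e-8)) return(1e10)
    beta <- par[K:(K - 1 + p)]
    eta <- drop(X %*% beta)
    ll <- 0
    for (i in seq_along(yy)) {
      hi <- if (yy[i] == K) 1 else plogis(alpha[yy[i]] - eta[i])
      lo <- if (yy[i] == 1) 0 else plogis(alpha[yy[i] - 1] - eta[i])
      ll <- ll + log(max(hi - lo, 1e-300))
    }
    -ll
  }
  start <- c(qlogis((1:(K - 1)) / K), rep(0, p))
  opt <- optim(start, nll, method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-14))
  opt2 <- optim(opt$par, nll, method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-14))
  list(alpha = sort(opt2$par[1:(K - 1)]), beta = opt2$par[K:(K - 1 + p)])
}

# analytic test curves as point tables
curve_tbl <- function(x, y, id = "tok") {
  tibble::tibble(token_id = id, point = seq_along(x), x = x, y = y)
}

circle_arc <- function(radius, angle, n = 200, id = "arc") {
  t <- seq(0, angle, length.out = n)
  curve_tbl(radius * cos(t), radius * sin(t), id)
}

# random bump-contour recipe inside the robust design window: shallow base,
# alternating supra-threshold bumps whose side lobes stay sub-threshold
random_bump_recipe <- function(k, seed) {
  withr::with_seed(seed, {
    theta <- runif(1, 0.25, 0.7)
    p_lo <- 4.3 + theta
    p_hi <- (3.0 - theta) / 0.446
    peak <- runif(1, p_lo, p_hi)
    w <- runif(1, 0.07, 0.09)
    base <- 70 * theta / (2 * sin(theta / 2))
    bumps <- if (k > 0) {
      centers <- seq(0.2, 0.8, length.out = max(k, 2))[1:k] +
        runif(k, -0.015, 0.015)
      tibble::tibble(
        center = sort(centers),
        amplitude = ifelse(seq_len(k) %% 2 == 1, 1, -1) * peak * w^2 * base,
        width = w
      )
    } else {
      NULL
    }
    R <- 70 / (2 * sin(theta / 2))
    contour_recipe(
      chord_mm = 70, bulge_mm = R * (1 - cos(theta / 2)),
      bumps = bumps, noise_sd = 0, n_points = 100, seed = seed
    )
  })
}
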