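#' Cumulative-link (ordinal) mixed model for the NINFL analyses
#'
#' The reported NINFL takes small ordered values (1-5 after exclusion), so
#' group and accuracy effects are modelled with a cumulative-logit mixed
#' model: `P(y <= k | eta) = logistic(alpha_k - eta)` with strictly ordered
#' thresholds `alpha_1 < ... < alpha_{K-1}`, linear predictor
#' `eta = x'beta + z'b`, and by-speaker random effects
#' `b ~ N(0, diag(sigma^2))` (independent components: intercept plus
#' contrast slopes). The marginal likelihood is maximised under the Laplace
#' approximation: for each speaker the joint mode of the random effects is
#' found by Newton's method (the cumulative-logit log-likelihood is concave
#' in eta, so the inner problem is well behaved), and the integral is
#' replaced by the Gaussian approximation at the mode.
#'
#' Thresholds are parameterised as `alpha_1` plus log-differences to keep
#' them ordered; random-effect SDs are log-parameterised. Standard errors
#' come from the numerically differentiated Hessian of the Laplace negative
#' log-likelihood at the optimum (Wald z tests for the fixed effects).
#'
#' @name clmm
NULL

#' Control parameters for the ordinal mixed fitter
#'
#' @param rel_tol Relative convergence tolerance of the outer optimiser.
#' @param max_iter Outer iteration cap.
#' @param inner_tol Gradient tolerance of the per-speaker Newton solver.
#' @param inner_max_iter Newton iteration cap.
#' @param se Compute standard errors (numeric Hessian; disable in tight
#'   simulation loops).
#' @export
clmm_control <- function(rel_tol = 1e-10, max_iter = 500,
                         inner_tol = 1e-9, inner_max_iter = 50, se = TRUE) {
  list(
    rel_tol = rel_tol, max_iter = max_iter,
    inner_tol = inner_tol, inner_max_iter = inner_max_iter, se = se
  )
}

# observation-level cumulative-logit log-likelihood and its first two
# derivatives in eta; alpha is the padded threshold vector (-Inf, ..., +Inf)
.clmm_obs <- function(eta, y, alpha) {
  a2 <- alpha[y + 1L] - eta
  a1 <- alpha[y] - eta
  F2 <- plogis(a2)
  F1 <- plogis(a1)
  pi <- pmax(F2 - F1, 1e-12)
  f2 <- F2 * (1 - F2)
  f1 <- F1 * (1 - F1)
  fp2 <- f2 * (1 - 2 * F2)
  fp1 <- f1 * (1 - 2 * F1)
  g1 <- (f1 - f2) / pi
  g2 <- (fp2 - fp1) / pi - g1^2
  list(ll = log(pi), g1 = g1, g2 = g2)
}

# Laplace negative log-likelihood; env caches warm-start modes across calls.
# Returns a large finite value on numerical failure (overflowing trial steps)
# so the outer optimiser can back off.
.clmm_nll <- function(psi, dat, cache) {
  out <- tryCatch(.clmm_nll_core(psi, dat, cache), error = function(e) NA_real_)
  if (!is.finite(out)) 1e10 else out
}

.clmm_nll_core <- function(psi, dat, cache) {
  K <- dat$K
  p <- dat$p
  d <- dat$d
  alpha_raw <- psi[seq_len(K - 1)]
  alpha <- c(-Inf, alpha_raw[1] + c(0, cumsum(exp(alpha_raw[-1]))), Inf)
  beta <- psi[K - 1 + seq_len(p)]
  eta_fix <- if (p) drop(dat$X %*% beta) else numeric(dat$n)
  if (d == 0L) {
    return(-sum(.clmm_obs(eta_fix, dat$y, alpha)$ll))
  }
  sig <- exp(psi[K - 1 + p + seq_len(d)])
  Zs <- dat$Z * rep(sig, each = dat$n) # columns scaled by sigma
  U <- cache$U # d x ngroups warm start
  g <- dat$group
  ng <- dat$ngroups
  obj_groups <- function(U) {
    eta <- eta_fix + rowSums(Zs * t(U)[g, , drop = FALSE])
    o <- .clmm_obs(eta, dat$y, alpha)
    nllg <- -drop(rowsum(o$ll, g)) + 0.5 * colSums(U^2)
    list(nll = nllg, o = o, eta = eta)
  }
  cur <- obj_groups(U)
  for (iter in seq_len(cache$control$inner_max_iter)) {
    # gradient: -Zs' g1 + u, per group
    Gr <- t(rowsum(Zs * -cur$o$g1, g)) + U # d x ngroups
    if (max(abs(Gr)) < cache$control$inner_tol) break
    # per-group Hessian: Zs' diag(-g2) Zs + I, assembled via rowsum
    W <- -cur$o$g2
    Hflat <- vapply(seq_len(d), function(j) {
      rowsum(Zs[, j] * Zs * W, g) # ngroups x d (block row j)
    }, matrix(0, ng, d)) # ngroups x d x d
    step <- matrix(0, d, ng)
    for (i in seq_len(ng)) {
      Hi <- matrix(Hflat[i, , ], d, d) + diag(d)
      step[, i] <- solve(Hi, Gr[, i])
    }
    lam <- rep(1, ng)
    for (ls in 1:20) {
      Unew <- U - step * rep(lam, each = d)
      new <- obj_groups(Unew)
      worse <- new$nll > cur$nll + 1e-12
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
    }
    U <- U - step * rep(lam, each = d)
    cur <- obj_groups(U)
  }
  cache$U <- U
  # log-determinant term at the mode
  W <- -cur$o$g2
  Hflat <- vapply(seq_len(d), function(j) rowsum(Zs[, j] * Zs * W, g), matrix(0, ng, d))
  ldet <- vapply(seq_len(ng), function(i) {
    Hi <- matrix(Hflat[i, , ], d, d) + diag(d)
    2 * sum(log(diag(chol(Hi))))
  }, numeric(1))
  sum(cur$nll) + 0.5 * sum(ldet)
}

# raw parameter vector -> ordered thresholds
.clmm_alpha <- function(psi, K) {
  a <- psi[seq_len(K - 1)]
  a[1] + c(0, cumsum(exp(a[-1])))
}

#' Fit a cumulative-logit (mixed) model
#'
#' Low-level fitter. `y` must be ordinal-coded integers; each observed level
#' needs at least one observation and at least two distinct levels must be
#' present.
#'
#' @param y Integer ordinal response.
#' @param X Fixed-effect model matrix without intercept (thresholds absorb
#'   it); may have zero columns.
#' @param group Grouping factor/vector for the random effects (NULL for a
#'   plain ordered-logit fit).
#' @param Z Random-effect design matrix (one column per random component,
#'   e.g. an all-ones intercept column plus contrast columns); NULL with
#'   `group = NULL`.
#' @param control See [clmm_control()].
#' @param start Optional start values on the raw parameter scale.
#' @return A list with `alpha` (ordered thresholds), `beta`, `re_sd`,
#'   `logLik` (Laplace), `vcov_beta`, SE tables, convergence info.
#' @export
clmm_fit <- function(y, X, group = NULL, Z = NULL, control = clmm_control(),
                     start = NULL) {
  levs <- sort(unique(y))
  if (length(levs) < 2) {
    abort("Ordinal outcome has a single observed level; model is undefined.",
      class = "tsc_model_error")
  }
  yy <- match(y, levs)
  K <- length(levs)
  X <- if (is.null(X)) matrix(0, length(y), 0) else as.matrix(X)
  p <- ncol(X)
  if (is.null(group)) {
    d <- 0L
    dat <- list(y = yy, X = X, Z = NULL, group = NULL, n = length(yy),
      K = K, p = p, d = 0L, ngroups = 0L)
  } else {
    gf <- factor(group)
    Z <- as.matrix(Z)
    d <- ncol(Z)
    dat <- list(
      y = yy, X = X, Z = Z, group = as.integer(gf), n = length(yy),
      K = K, p = p, d = d, ngroups = nlevels(gf)
    )
  }
  cache <- new.env()
  cache$control <- control
  cache$U <- if (d > 0) matrix(0, d, dat$ngroups)
  # starts: thresholds from marginal cumulative frequencies, beta = 0
  if (is.null(start)) {
    cum <- cumsum(tabulate(yy, K))[seq_len(K - 1)] / length(yy)
    a0 <- qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
    a0 <- cummax(a0 + seq_len(K - 1) * 1e-8)
    start <- c(a0[1], log(pmax(diff(a0), 1e-3)), rep(0, p), rep(log(0.5), d))
  }
  fn <- function(psi) .clmm_nll(psi, dat, cache)
  # unbounded quasi-Newton; numerically unsafe trial regions are handled by
  # the large-finite-value guard in .clmm_nll
  opt <- stats::nlminb(start, fn,
    control = list(rel.tol = control$rel_tol, iter.max = control$max_iter,
      eval.max = 200 * control$max_iter)
  )
  psi <- opt$par
  alpha <- .clmm_alpha(psi, K)
  beta <- psi[K - 1 + seq_len(p)]
  names(beta) <- colnames(X)
  re_sd <- if (d) exp(psi[K - 1 + p + seq_len(d)]) else numeric(0)
  if (d) names(re_sd) <- colnames(Z)
  out <- list(
    alpha = alpha, beta = beta, re_sd = re_sd,
    levels = levs, logLik = -opt$objective,
    n_obs = dat$n, n_groups = dat$ngroups,
    converged = opt$convergence == 0, message = opt$message,
    psi = psi, K = K, p = p, d = d
  )
  if (control$se) {
    m <- length(psi)
    h <- 1e-5 * pmax(abs(psi), 1)
    H <- matrix(0, m, m)
    f0 <- fn(psi)
    for (j in seq_len(m)) {
      for (k in j:m) {
        if (j == k) {
          H[j, j] <- (fn(psi + h * (seq_len(m) == j)) - 2 * f0 +
            fn(psi - h * (seq_len(m) == j))) / h[j]^2
        } else {
          ej <- h * (seq_len(m) == j)
          ek <- h * (seq_len(m) == k)
          H[j, k] <- H[k, j] <- (fn(psi + ej + ek) - fn(psi + ej - ek) -
            fn(psi - ej + ek) + fn(psi - ej - ek)) / (4 * h[j] * h[k])
        }
      }
    }
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V)) {
      out$se_beta <- rep(NA_real_, p)
      out$se_alpha <- rep(NA_real_, K - 1)
      out$se_re_sd <- rep(NA_real_, d)
      out$vcov_ok <- FALSE
    } else {
      # delta method: alpha_k = a1 + sum(exp(delta_2..k))
      J <- matrix(0, K - 1, m)
      J[, 1] <- 1
      if (K > 2) {
        for (k in 2:(K - 1)) J[k, 2:k] <- exp(psi[2:k])
      }
      Va <- J %*% V %*% t(J)
      out$se_alpha <- sqrt(pmax(diag(Va), 0))
      out$se_beta <- if (p) sqrt(pmax(diag(V)[K - 1 + seq_len(p)], 0)) else numeric(0)
      out$vcov_beta <- V[K - 1 + seq_len(p), K - 1 + seq_len(p), drop = FALSE]
      out$se_re_sd <- if (d) re_sd * sqrt(pmax(diag(V)[K - 1 + p + seq_len(d)], 0)) else numeric(0)
      out$vcov_ok <- TRUE
    }
  }
  out
}

#' Fit the ordinal mixed model for a NINFL design
#'
#' @param design A `tsc_design` with the ordinal (`ninfl`) outcome.
#' @param re `"slopes"` (by-speaker intercept + contrast slopes, default),
#'   `"intercept"`, or `"none"` (plain ordered logit).
#' @param control See [clmm_control()].
#' @return An object of class `tsc_clmm` with a `coefficients` tibble
#'   (Wald z tests), `thresholds`, `random_effects`, and convergence
#'   diagnostics. If the slopes model fails, the fitter falls back to a
#'   random-intercept-only model with a warning.
#' @export
fit_ninfl_model <- function(design, re = c("slopes", "intercept", "none"),
                            control = clmm_control()) {
  re <- match.arg(re)
  stopifnot(inherits(design, "tsc_design"), design$outcome_kind == "ordinal")
  d <- design$data
  y <- d[[design$outcome]]
  X <- design_matrix(design)
  group <- if (re == "none") NULL else d$speaker_id
  Z <- switch(re,
    none = NULL,
    intercept = matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)")),
    slopes = {
      z <- cbind(`(Intercept)` = 1, as.matrix(d[, design$re_slopes]))
      z
    }
  )
  res <- tryCatch(
    clmm_fit(y, X, group = group, Z = Z, control = control),
    error = function(e) e
  )
  fallback <- FALSE
  if ((inherits(res, "error") || !res$converged) && re == "slopes") {
    warn(paste0(
      "Random-slopes ordinal fit ",
      if (inherits(res, "error")) paste0("failed (", conditionMessage(res), ")")
      else "did not converge",
      "; falling back to random intercept only."
    ))
    fallback <- TRUE
    res <- clmm_fit(y, X,
      group = group,
      Z = matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)")),
      control = control
    )
  }
  if (inherits(res, "error")) abort(conditionMessage(res), class = "tsc_model_error")
  if (!res$converged) warn(paste0("Ordinal mixed fit did not converge: ", res$message))
  if (is.null(res$se_beta)) {
    res$se_beta <- rep(NA_real_, res$p)
    res$se_alpha <- rep(NA_real_, res$K - 1)
  }
  z <- res$beta / res$se_beta
  coefs <- tibble(
    term = names(res$beta), estimate = unname(res$beta),
    std.error = unname(res$se_beta), statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z))),
    label = unname(label_map(design)[names(res$beta)])
  )
  thr <- tibble(
    threshold = paste(res$levels[-res$K], res$levels[-1], sep = "|"),
    estimate = res$alpha, std.error = res$se_alpha %||% NA_real_
  )
  re_tab <- if (res$d) {
    tibble(group = "speaker_id", term = names(res$re_sd),
      sd = unname(res$re_sd), variance = unname(res$re_sd)^2)
  }
  structure(list(
    coefficients = coefs, thresholds = thr, random_effects = re_tab,
    logLik = res$logLik, n_obs = res$n_obs, n_speakers = res$n_groups,
    convergence = list(converged = res$converged, fallback = fallback,
      message = res$message),
    model_kind = "cumulative_link_mixed", fit = res,
    design = design[c("analysis", "outcome")]
  ), class = "tsc_clmm")
}
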