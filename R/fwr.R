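# Build the line x environment response matrix for one trait, averaging
# replicates within (line, environment). Lines seen in < 2 environments are
# dropped with a warning (their slope is unidentifiable).
build_response_matrix <- function(records, trait_name, min_env_per_line = 2) {
  rec <- records[records$trait == trait_name & !is.na(records$value), ,
                 drop = FALSE]
  if (nrow(rec) == 0) stop("no observations for trait '", trait_name, "'",
                           call. = FALSE)
  env_id <- paste(rec$year, rec$site, rec$block, sep = ":")
  envs <- sort(unique(env_id))
  if (length(envs) < 2) {
    stop("fewer than 2 environments for trait '", trait_name,
         "'; slopes are unidentifiable", call. = FALSE)
  }
  lines <- sort(unique(rec$line_id))
  Y <- matrix(NA_real_, length(lines), length(envs),
              dimnames = list(lines, envs))
  S <- matrix(0, length(lines), length(envs), dimnames = dimnames(Y))
  N <- matrix(0L, length(lines), length(envs), dimnames = dimnames(Y))
  i <- match(rec$line_id, lines)
  j <- match(env_id, envs)
  for (k in seq_along(i)) {
    S[i[k], j[k]] <- S[i[k], j[k]] + rec$value[k]
    N[i[k], j[k]] <- N[i[k], j[k]] + 1L
  }
  Y[N > 0] <- S[N > 0] / N[N > 0]
  n_env_line <- rowSums(N > 0)
  if (any(n_env_line < min_env_per_line)) {
    dropped <- lines[n_env_line < min_env_per_line]
    warning(length(dropped), " line(s) observed in fewer than ",
            min_env_per_line, " environments excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
    Y <- Y[n_env_line >= min_env_per_line, , drop = FALSE]
  }
  Y
}

# Exact reparameterisation onto the identified scale: environment effects
# mean zero, genetic values mean zero (absorbed into mu), slope deviations
# mean zero (absorbed into the scale of h). Leaves fitted values unchanged.
identify_fw <- function(mu, g, b, h) {
  hbar <- mean(h)
  g <- g + (1 + b) * hbar
  h <- h - hbar
  gbar <- mean(g)
  mu <- mu + gbar
  g <- g - gbar
  d <- mean(b)
  h <- h * (1 + d)
  b <- (1 + b) / (1 + d) - 1
  list(mu = mu, g = g, b = b, h = h)
}

fw_sse <- function(Y, mu, g, b, h) {
  R <- Y - mu - outer(g, rep(1, length(h))) - outer(1 + b, h)
  sum(R^2, na.rm = TRUE)
}

# Per-line residual variance with n_i - 2 degrees of freedom (intercept and
# slope estimated per line); lines with exactly 2 environments fit exactly,
# so their residual variance is 0 by convention.
fw_residual_variance <- function(Y, mu, g, b, h) {
  R <- Y - mu - outer(g, rep(1, length(h))) - outer(1 + b, h)
  sse <- rowSums(R^2, na.rm = TRUE)
  n_i <- rowSums(!is.na(Y))
  ifelse(n_i > 2, sse / (n_i - 2), 0)
}

#' Fit Finlay-Wilkinson regression by alternating least squares
#'
#' Fits `y_ij = mu + g_i + (1 + b_i) h_j + eps_ij` jointly for all lines of
#' one trait: `g_i` is the line's genetic value (main effect), `1 + b_i` its
#' linear plasticity (slope on the environment effects), and `h_j` the
#' environment effect. The model is bilinear in (b, h), so it is fitted by
#' alternating exact conditional least-squares updates: (1) intercepts
#' (mu, g) given slopes and environment effects, (2) environment effects
#' given the rest, (3) per-line slopes given the rest, with exact
#' reparameterisations after each sweep enforcing the identifiability
#' constraints (sum of h zero, mean of b zero, mean of g zero). Each update
#' is an exact conditional minimiser, so the residual sum of squares is
#' non-increasing across iterations.
#'
#' Replicated observations within (line, environment) are averaged before
#' fitting. The per-line residual variance around the fitted line (degrees
#' of freedom `n_i - 2`) measures nonlinear plasticity: lines that respond
#' to the environment, but not linearly along the environment gradient, get
#' large values.
#'
#' @param records Long-format phenotype records.
#' @param trait_name Trait to fit.
#' @param max_iter Maximum number of alternating sweeps.
#' @param tol Convergence tolerance on the largest absolute parameter
#'   change between sweeps.
#' @return An object of class `fw_fit` with elements `trait`, `mu`, `g`,
#'   `b`, `h` (named vectors), `residual_variance`, `n_env` (environments
#'   per line), `sse`, `converged`, `iterations`, and `method = "ols"`.
#' @seealso [fit_fw_bayes()] for the Bayesian posterior-mean estimator.
#' @examples
#' sim <- simulate_dataset(population_design(5), truth_config(), seed = 1)
#' fit <- fit_fw_ols(sim$records, "normal kernel number")
#' fit$mu
#' @export
fit_fw_ols <- function(records, trait_name, max_iter = 500, tol = 1e-8) {
  Y <- build_response_matrix(records, trait_name)
  n_l <- nrow(Y)
  n_e <- ncol(Y)
  M <- !is.na(Y)
  Y0 <- Y
  Y0[!M] <- 0

  mu <- mean(Y, na.rm = TRUE)
  h <- colMeans(Y, na.rm = TRUE) - mu
  h <- h - mean(h)
  b <- rep(0, n_l)
  g <- rowMeans(Y, na.rm = TRUE) - mu

  sse_prev <- fw_sse(Y, mu, g, b, h)
  converged <- FALSE
  iter <- 0
  sse_path <- sse_prev
  for (iter in seq_len(max_iter)) {
    mu_old <- mu; g_old <- g; b_old <- b; h_old <- h

    # (1) intercepts given (b, h)
    R <- Y - outer(1 + b, h)
    a <- rowMeans(R, na.rm = TRUE)
    mu <- mean(a)
    g <- a - mu

    # (2) environment effects given (mu, g, b)
    R <- Y0 - (mu + g) # recycled by column
    R[!M] <- 0
    w <- 1 + b
    num <- colSums(R * w)
    den <- colSums(M * w^2)
    h <- ifelse(den > 0, num / den, 0)

    # (3) per-line slopes given (mu, g, h)
    R <- Y0 - (mu + g)
    R[!M] <- 0
    H <- matrix(h, n_l, n_e, byrow = TRUE)
    num <- rowSums(R * H)
    den <- rowSums(M * H^2)
    slope <- ifelse(den > 0, num / den, 1)
    b <- slope - 1

    par <- identify_fw(mu, g, b, h)
    mu <- par$mu; g <- par$g; b <- par$b; h <- par$h

    sse <- fw_sse(Y, mu, g, b, h)
    sse_path <- c(sse_path, sse)
    delta <- max(abs(mu - mu_old), max(abs(g - g_old)), max(abs(b - b_old)),
                 max(abs(h - h_old)))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    sse_prev <- sse
  }
  if (!converged) {
    warning("Finlay-Wilkinson fit did not converge in ", max_iter,
            " iterations (last change ", signif(delta, 3), ")",
            call. = FALSE)
  }

  names(g) <- rownames(Y)
  names(b) <- rownames(Y)
  names(h) <- colnames(Y)
  structure(
    list(trait = trait_name, mu = mu, g = g, b = b, h = h,
         residual_variance = fw_residual_variance(Y, mu, g, b, h),
         n_env = rowSums(M), sse = fw_sse(Y, mu, g, b, h),
         sse_path = sse_path, converged = converged, iterations = iter,
         method = "ols"),
    class = "fw_fit"
  )
}

#' Fit Bayesian Finlay-Wilkinson regression by Gibbs sampling
#'
#' Bayesian formulation of the model fitted by [fit_fw_ols()]: Gaussian
#' exchangeable priors `g_i ~ N(0, s2_g)`, `b_i ~ N(0, s2_b)`,
#' `h_j ~ N(0, s2_h)`, homoscedastic Gaussian residuals with variance
#' `s2_e`, a flat prior on `mu`, and scaled-inverse-chi-square priors on all
#' four variance components. Every full conditional is conjugate, so the
#' sampler is a plain Gibbs scheme; the bilinearity is handled by
#' conditioning (given h, the slope update is a per-line linear regression,
#' and vice versa).
#'
#' Saved draws are mapped onto the identified scale (h centred, b centred
#' with the scale absorbed into h, g centred into mu) before averaging, so
#' posterior means satisfy the same constraints as the least-squares fit.
#' Per-line residual variances (nonlinear plasticity) are computed from the
#' posterior-mean parameters with `n_i - 2` degrees of freedom.
#'
#' @inheritParams fit_fw_ols
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before saving draws.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param prior List of prior settings: `nu` (prior degrees of freedom for
#'   every variance component, default 2, i.e. barely proper) and optional
#'   scales `s2_e`, `s2_g`, `s2_b`, `s2_h`; scales left `NULL` default to
#'   weakly informative values anchored at the least-squares variance
#'   decomposition of the same data (an empirical-Bayes choice that keeps
#'   the prior negligible against hundreds of observations while remaining
#'   on the right scale). The chain is initialised at the least-squares
#'   solution.
#' @param seed Integer seed; identical seeds give identical chains.
#' @return An object of class `fw_fit` (posterior means in `mu`, `g`, `b`,
#'   `h`) with `method = "bayes"`, the thinned chains in `chain`, and the
#'   sampler settings in `convergence`.
#' @export
fit_fw_bayes <- function(records, trait_name, n_iter = 30000,
                         burn_in = 5000, thin = 5,
                         prior = list(nu = 2), seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in", call. = FALSE)

  Y <- build_response_matrix(records, trait_name)
  n_l <- nrow(Y)
  n_e <- ncol(Y)
  M <- !is.na(Y)
  Y0 <- Y
  Y0[!M] <- 0
  n_obs <- sum(M)
  n_per_line <- rowSums(M)

  # anchor the weakly informative prior scales and the chain start at the
  # least-squares solution for the same data
  ols <- suppressWarnings(fit_fw_ols(records, trait_name))
  v_tot <- stats::var(as.vector(Y), na.rm = TRUE)
  eps <- max(1e-8 * max(v_tot, 1), 1e-12)
  nu <- if (is.null(prior$nu)) 2 else prior$nu
  s2_e0 <- if (is.null(prior$s2_e)) max(ols$sse / n_obs, eps) else prior$s2_e
  s2_g0 <- if (is.null(prior$s2_g)) max(stats::var(ols$g), eps) else
    prior$s2_g
  s2_h0 <- if (is.null(prior$s2_h)) max(stats::var(ols$h), eps) else
    prior$s2_h
  s2_b0 <- if (is.null(prior$s2_b)) max(stats::var(ols$b), 1e-4) else
    prior$s2_b

  set.seed(as.integer(seed))
  mu <- ols$mu
  h <- unname(ols$h)
  g <- unname(ols$g)
  b <- unname(ols$b)
  s2_e <- s2_e0
  s2_g <- s2_g0
  s2_b <- s2_b0
  s2_h <- s2_h0

  n_keep <- floor((n_iter - burn_in) / thin)
  draw_mu <- numeric(n_keep)
  draw_g <- matrix(0, n_keep, n_l)
  draw_b <- matrix(0, n_keep, n_l)
  draw_h <- matrix(0, n_keep, n_e)
  draw_s2e <- numeric(n_keep)
  keep <- 0L

  rinvchisq <- function(df, scale) df * scale / stats::rchisq(1, df)

  for (it in seq_len(n_iter)) {
    w <- 1 + b
    # mu | .
    R <- Y0 - g - outer(w, h)
    R[!M] <- 0
    mu <- stats::rnorm(1, sum(R) / n_obs, sqrt(s2_e / n_obs))
    # g | .
    R <- Y0 - mu - outer(w, h)
    R[!M] <- 0
    prec <- n_per_line / s2_e + 1 / s2_g
    g <- stats::rnorm(n_l, (rowSums(R) / s2_e) / prec, sqrt(1 / prec))
    # h | .
    R <- Y0 - mu - g
    R[!M] <- 0
    prec <- colSums(M * w^2) / s2_e + 1 / s2_h
    h <- stats::rnorm(n_e, (colSums(R * w) / s2_e) / prec, sqrt(1 / prec))
    # b | .  (z = y - mu - g - h regressed on h per line)
    H <- matrix(h, n_l, n_e, byrow = TRUE)
    Z <- Y0 - mu - g - H
    Z[!M] <- 0
    prec <- rowSums(M * H^2) / s2_e + 1 / s2_b
    b <- stats::rnorm(n_l, (rowSums(Z * H) / s2_e) / prec, sqrt(1 / prec))
    # variance components
    R <- Y0 - mu - g - outer(1 + b, h)
    R[!M] <- 0
    s2_e <- rinvchisq(nu + n_obs, (nu * s2_e0 + sum(R^2)) / (nu + n_obs))
    s2_g <- rinvchisq(nu + n_l, (nu * s2_g0 + sum(g^2)) / (nu + n_l))
    s2_b <- rinvchisq(nu + n_l, (nu * s2_b0 + sum(b^2)) / (nu + n_l))
    s2_h <- rinvchisq(nu + n_e, (nu * s2_h0 + sum(h^2)) / (nu + n_e))
    if (!all(is.finite(c(mu, g, b, h, s2_e, s2_g, s2_b, s2_h))) ||
        s2_e > 1e12 * max(v_tot, 1)) {
      stop("divergent variance draw at iteration ", it, call. = FALSE)
    }

    if (it > burn_in && (it - burn_in) %% thin == 0 && keep < n_keep) {
      keep <- keep + 1L
      par <- identify_fw(mu, g, b, h)
      draw_mu[keep] <- par$mu
      draw_g[keep, ] <- par$g
      draw_b[keep, ] <- par$b
      draw_h[keep, ] <- par$h
      draw_s2e[keep] <- s2_e
    }
  }

  mu_hat <- mean(draw_mu)
  g_hat <- colMeans(draw_g)
  b_hat <- colMeans(draw_b)
  h_hat <- colMeans(draw_h)
  par <- identify_fw(mu_hat, g_hat, b_hat, h_hat)
  names(par$g) <- rownames(Y)
  names(par$b) <- rownames(Y)
  names(par$h) <- colnames(Y)

  structure(
    list(trait = trait_name, mu = par$mu, g = par$g, b = par$b, h = par$h,
         residual_variance = fw_residual_variance(Y, par$mu, par$g, par$b,
                                                  par$h),
         n_env = n_per_line,
         sse = fw_sse(Y, par$mu, par$g, par$b, par$h),
         converged = TRUE, iterations = n_iter,
         chain = list(mu = draw_mu, g = draw_g, b = draw_b, h = draw_h,
                      s2_e = draw_s2e),
         convergence = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                            seed = as.integer(seed)),
         method = "bayes"),
    class = "fw_fit"
  )
}

#' Nonlinear plasticity of each line
#'
#' Returns the per-line residual variance of a Finlay-Wilkinson fit: the
#' variance of a line's observations around its own fitted regression on
#' the environment effects. Lines whose environmental response is captured
#' by the linear term have values near zero; large values indicate a
#' response the linear model does not explain.
#'
#' @param fit An `fw_fit` from [fit_fw_ols()] or [fit_fw_bayes()].
#' @return Named numeric vector of per-line residual variances.
#' @export
nonlinear_plasticity <- function(fit) {
  stopifnot(inherits(fit, "fw_fit"))
  fit$residual_variance
}

#' @export
print.fw_fit <- function(x, ...) {
  cat("Finlay-Wilkinson fit (", x$method, ") for trait '", x$trait, "'\n",
      sep = "")
  cat("  lines:", length(x$g), " environments:", length(x$h), "\n")
  cat("  mu =", format(x$mu, digits = 6),
      " sse =", format(x$sse, digits = 6), "\n")
  if (x$method == "ols") {
    cat("  converged:", x$converged, "in", x$iterations, "iterations\n")
  } else {
    cv <- x$convergence
    cat("  chain:", cv$n_iter, "iterations, burn-in", cv$burn_in,
        ", thin", cv$thin, "\n")
  }
  invisible(x)
}

#' Reaction-norm plot of a Finlay-Wilkinson fit
#'
#' Plots each line's fitted regression on the environment effects (its
#' reaction norm); the wild-type line, if named, is drawn in black.
#'
#' @param x An `fw_fit`.
#' @param wildtype_id Optional line to highlight.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.fw_fit <- function(x, wildtype_id = NULL, ...) {
  hs <- sort(x$h)
  fitted <- sapply(seq_along(x$g),
                   function(i) x$mu + x$g[i] + (1 + x$b[i]) * hs)
  graphics::matplot(hs, fitted, type = "l", lty = 1, col = "grey60",
                    xlab = "environment effect h", ylab = x$trait, ...)
  if (!is.null(wildtype_id) && wildtype_id %in% names(x$g)) {
    i <- match(wildtype_id, names(x$g))
    graphics::lines(hs, x$mu + x$g[i] + (1 + x$b[i]) * hs, col = "black",
                    lwd = 2)
  }
  invisible(x)
}
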