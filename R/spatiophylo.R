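#' Penalized-complexity prior on a random-effect standard deviation
#'
#' Exponential prior on the standard deviation with
#' \eqn{P(\sigma > u) = \alpha}, i.e. rate \eqn{-\log(\alpha)/u}. The
#' default (u = 1, alpha = 0.1) gives about a 10\% chance of the latent
#' variance exceeding 1.
#'
#' @param u threshold (> 0)
#' @param alpha tail probability in (0, 1)
#' @return list of class \code{pc_prior}
#' @export
pc_prior <- function(u = 1, alpha = 0.1) {
  if (!is.numeric(u) || u <= 0) stop("u must be > 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  structure(list(u = u, alpha = alpha, rate = -log(alpha) / u),
            class = "pc_prior")
}

## Residual variance of the standard logistic distribution, the constant
## completing the latent-scale variance partition for logit models.
LOGIT_RESID_VAR <- pi^2 / 3

## One Laplace evaluation of the log joint posterior of the
## hyperparameters t = (log sigma2_phylo, log sigma2_spatial), with the
## latent field (intercept alpha, combined effect w = u + v) integrated
## out by a Gaussian approximation at its conditional mode.
## Returns the log density (up to a constant) plus the mode details.
laplace_eval <- function(t, y_obs, obs, Sp, Ss, rate_p, rate_s,
                         alpha_var = 100, details = FALSE) {
  n <- nrow(Sp)
  s2p <- exp(t[1]); s2s <- exp(t[2])
  Sw <- s2p * Sp + s2s * Ss
  diag(Sw) <- diag(Sw) + 1e-8
  cS <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(cS)) return(if (details) NULL else -1e10)
  Qw <- chol2inv(cS)
  logdetSw <- 2 * sum(log(diag(cS)))
  alpha <- 0; w <- rep(0, n)
  H <- matrix(0, n + 1, n + 1)
  cH <- NULL
  for (it in 1:40) {
    eta <- alpha + w[obs]
    p <- stats::plogis(eta)
    Wt <- pmax(p * (1 - p), 1e-10)
    gl <- y_obs - p
    g <- numeric(n + 1)
    g[1] <- sum(gl) - alpha / alpha_var
    g[obs + 1] <- gl
    g[-1] <- g[-1] - Qw %*% w
    H[1, 1] <- sum(Wt) + 1 / alpha_var
    hw <- numeric(n); hw[obs] <- Wt
    H[1, -1] <- hw; H[-1, 1] <- hw
    H[2:(n + 1), 2:(n + 1)] <- Qw
    dq <- diag(Qw); dq[obs] <- dq[obs] + Wt
    H[cbind(2:(n + 1), 2:(n + 1))] <- dq
    cH <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(cH)) return(if (details) NULL else -1e10)
    step <- backsolve(cH, forwardsolve(t(cH), g))
    ## dampen huge steps (rare, near-degenerate responses)
    smax <- max(abs(step))
    if (smax > 10) step <- step * (10 / smax)
    alpha <- alpha + step[1]; w <- w + step[-1]
    if (smax < 1e-7) break
  }
  eta <- alpha + w[obs]
  ll <- sum(y_obs * eta) - sum(log1p(exp(eta)))
  lprior_x <- -0.5 * alpha^2 / alpha_var - 0.5 * sum(w * (Qw %*% w)) -
    0.5 * logdetSw
  logdetH <- 2 * sum(log(diag(cH)))
  sig <- sqrt(c(s2p, s2s))
  lpr_t <- (log(rate_p) - rate_p * sig[1] + log(sig[1] / 2)) +
    (log(rate_s) - rate_s * sig[2] + log(sig[2] / 2))
  lp <- ll + lprior_x - 0.5 * logdetH + lpr_t
  if (!details) return(lp)
  ## conditional variance of alpha at the mode
  Hinv1 <- backsolve(cH, forwardsolve(t(cH), c(1, rep(0, n))))[1]
  list(lp = lp, alpha = alpha, w = w, alpha_var = Hinv1, Qw = Qw)
}

#' Fit the binomial spatiophylogenetic model to one binary feature
#'
#' Latent Gaussian model \eqn{\mathrm{logit} P(y_i = 1) = \alpha + u_i +
#' v_i} with a phylogenetic Brownian random effect \eqn{u \sim N(0,
#' \sigma^2_p \Sigma_p)} and a spatial Matern random effect \eqn{v \sim
#' N(0, \sigma^2_s \Sigma_s)}, penalized-complexity priors on both
#' standard deviations. Inference is an approximate Bayesian scheme for
#' latent Gaussian models: the latent field is integrated out by a
#' Laplace approximation and the two log-variances are integrated over a
#' grid centred on their joint posterior mode.
#'
#' Missing responses are simply unobserved; the latent field is still
#' defined (and predicted) for those taxa.
#'
#' @param y named binary vector (0/1/NA) indexed by taxon
#' @param phylo_cov,spatial_cov \code{covariance_model}s or plain
#'   covariance matrices over the same taxa (standardized internally)
#' @param prior \code{pc_prior} applied to both standard deviations
#' @param grid_size,grid_span hyperparameter grid: \code{grid_size}^2
#'   points spanning +/- \code{grid_span} around the mode in each
#'   log-variance
#' @return object of class \code{signal_fit} with posterior summaries of
#'   the variance components, variance proportions (phylogenetic,
#'   spatial, residual pi^2/3 convention) and intercept
#' @export
fit_feature <- function(y, phylo_cov, spatial_cov, prior = pc_prior(),
                        grid_size = 5, grid_span = 2) {
  Sp <- standardized_cov(phylo_cov)
  Ss <- standardized_cov(spatial_cov)
  n <- nrow(Sp)
  if (nrow(Ss) != n) stop("dimension mismatch between covariance models")
  if (!is.null(names(y)) && !is.null(rownames(Sp))) {
    if (!all(rownames(Sp) %in% names(y)))
      stop("y does not cover the taxa of the covariance models")
    y <- y[rownames(Sp)]
  }
  if (length(y) != n) stop("length(y) does not match the covariance models")
  obs <- which(!is.na(y))
  if (length(obs) == 0) stop("no observed values in y")
  y_obs <- as.numeric(y[obs])
  if (!all(y_obs %in% c(0, 1))) stop("y must be binary (0/1/NA)")
  degenerate <- length(unique(y_obs)) < 2
  if (degenerate)
    warning("constant response among observed taxa: fit flagged degenerate")

  rate <- prior$rate
  f <- function(t) -laplace_eval(t, y_obs, obs, Sp, Ss, rate, rate)
  o <- stats::optim(c(-1, -1), f, method = "Nelder-Mead",
                    control = list(maxit = 80, reltol = 1e-4))
  gg <- seq(-grid_span, grid_span, length.out = grid_size)
  gr <- expand.grid(t1 = o$par[1] + gg, t2 = o$par[2] + gg)
  lp <- mapply(function(a, b)
    laplace_eval(c(a, b), y_obs, obs, Sp, Ss, rate, rate), gr$t1, gr$t2)
  wgt <- exp(lp - max(lp)); wgt <- wgt / sum(wgt)
  s2p <- exp(gr$t1); s2s <- exp(gr$t2)
  tot <- s2p + s2s + LOGIT_RESID_VAR
  pp <- s2p / tot; ps <- s2s / tot
  wsum <- function(q) {
    m <- sum(wgt * q); s <- sqrt(max(sum(wgt * q^2) - m^2, 0))
    o <- order(q); cw <- cumsum(wgt[o])
    ci <- c(q[o][which(cw >= 0.025)[1]], q[o][which(cw >= 0.975)[1]])
    c(mean = m, sd = s, lower = ci[1], upper = ci[2])
  }
  det <- laplace_eval(o$par, y_obs, obs, Sp, Ss, rate, rate, details = TRUE)
  structure(list(
    sigma2_phylo = wsum(s2p), sigma2_spatial = wsum(s2s),
    prop_phylo = wsum(pp), prop_spatial = wsum(ps),
    intercept = c(mean = det$alpha, sd = sqrt(det$alpha_var)),
    mode = c(log_s2p = o$par[1], log_s2s = o$par[2]),
    latent_mode = det$w,
    grid = data.frame(t1 = gr$t1, t2 = gr$t2, weight = wgt),
    degenerate = degenerate, n_obs = length(obs), prior = prior
  ), class = "signal_fit")
}

#' @export
print.signal_fit <- function(x, ...) {
  cat(sprintf(paste0("<signal_fit> n_obs=%d%s\n",
                     "  prop_phylo   %.3f (sd %.3f)\n",
                     "  prop_spatial %.3f (sd %.3f)\n"),
              x$n_obs, if (x$degenerate) " [degenerate]" else "",
              x$prop_phylo["mean"], x$prop_phylo["sd"],
              x$prop_spatial["mean"], x$prop_spatial["sd"]))
  invisible(x)
}

standardized_cov <- function(x) {
  V <- if (inherits(x, "covariance_model")) x$vcv else x
  scale_and_invert(V)$scaled
}

#' Variance partition of a fitted feature
#'
#' Latent-logit-scale proportions \eqn{\sigma^2_k / (\sigma^2_p +
#' \sigma^2_s + \pi^2/3)}, the intraclass-correlation convention for
#' logit models; the \eqn{\pi^2/3} term is the residual variance of the
#' logistic link. With \code{raw = TRUE} the residual constant is
#' omitted and raw variance ratios are returned instead.
#'
#' @param fit a \code{signal_fit}
#' @param raw report raw \eqn{\sigma^2} ratios instead
#' @return named vector \code{c(prop_phylo, prop_spatial)} (posterior
#'   means)
#' @export
variance_partition <- function(fit, raw = FALSE) {
  if (!inherits(fit, "signal_fit")) stop("expected a signal_fit")
  if (!raw)
    return(c(prop_phylo = unname(fit$prop_phylo["mean"]),
             prop_spatial = unname(fit$prop_spatial["mean"])))
  g <- fit$grid
  s2p <- exp(g$t1); s2s <- exp(g$t2); tot <- s2p + s2s
  c(prop_phylo = sum(g$weight * s2p / tot),
    prop_spatial = sum(g$weight * s2s / tot))
}

#' Simulate a binary trait with controlled phylogenetic signal
#'
#' A two-state continuous-time Markov chain is evolved along the
#' lambda-rescaled tree. The transition rates are redrawn and the
#' simulation repeated until the realized tip prevalence falls within
#' \code{tol} of the target (and the trait is non-constant), so draws
#' that lose the intended structure are rejected rather than kept.
#'
#' The overall transition rate is drawn uniformly from
#' \code{rate_range} expected events per unit of tree depth, split
#' between the gain and loss rates so that the stationary frequency of
#' state 1 equals the target prevalence. Rates much above this range
#' drive every tip to the stationary distribution regardless of lambda,
#' erasing the signal the rescaling is meant to impose.
#'
#' @param tree ultrametric \code{phylo}
#' @param lambda Pagel's lambda in [0, 1]
#' @param prevalence target frequency of state 1, in (0, 1)
#' @param seed integer seed
#' @param tol tolerance on the realized prevalence
#' @param max_tries resampling budget before giving up
#' @param rate_range range of the total transition rate, in expected
#'   events per unit of tree depth
#' @return named integer vector of tip states (0/1)
#' @export
simulate_binary_trait <- function(tree, lambda, prevalence, seed = NULL,
                                  tol = 0.05, max_tries = 10000,
                                  rate_range = c(0.5, 2)) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  trl <- ape::reorder.phylo(pagel_rescale(tree, lambda), "cladewise")
  depth <- max(ape::node.depth.edgelength(tree))
  ntip <- ape::Ntip(trl)
  nnode <- ntip + trl$Nnode
  for (i in seq_len(max_tries)) {
    rho <- stats::runif(1, rate_range[1], rate_range[2]) / depth
    q01 <- rho * prevalence; q10 <- rho * (1 - prevalence)
    x <- sim_two_state(trl, q01, q10, ntip, nnode)
    names(x) <- trl$tip.label
    x <- x[tree$tip.label]
    if (abs(mean(x) - prevalence) <= tol && stats::var(x) > 0) return(x)
  }
  stop("could not reach target prevalence ", prevalence,
       " within tol ", tol, " in ", max_tries, " attempts")
}

## Exact simulation of a two-state CTMC down a (cladewise-ordered) tree:
## transition probabilities over an edge of length t are
## P(0->1) = pi1 (1 - e^{-qt}), P(1->1) = pi1 + (1-pi1) e^{-qt},
## with q = q01 + q10 and stationary frequency pi1 = q01/q.
sim_two_state <- function(tree, q01, q10, ntip, nnode) {
  q <- q01 + q10
  pi1 <- q01 / q
  decay <- exp(-q * tree$edge.length)
  state <- integer(nnode)
  root <- ntip + 1L
  state[root] <- stats::rbinom(1, 1, pi1)
  u <- stats::runif(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    par <- state[tree$edge[e, 1]]
    p1 <- pi1 + (par - pi1) * decay[e]
    state[tree$edge[e, 2]] <- as.integer(u[e] < p1)
  }
  state[seq_len(ntip)]
}

#' Ancestral state reconstruction under the spatiophylogenetic model
#'
#' Fits the dual (phylogeny + space) model at the tips, then extends the
#' phylogenetic random effect to the internal nodes of the tree through
#' the Brownian covariance between nodes and tips. Internal nodes carry
#' no data and no coordinates: their predictions are made with the
#' spatial field set to zero, so spatial variation estimated at the tips
#' is removed before projecting up the tree.
#'
#' @param y named binary tip vector (0/1, no missing)
#' @param tree rooted \code{phylo} whose tips cover \code{names(y)}
#' @param spatial_cov spatial \code{covariance_model} over the same taxa
#' @param prior \code{pc_prior}
#' @return data frame with one row per internal node: \code{node} (ape
#'   node number) and \code{prob} (posterior predictive probability of
#'   state 1)
#' @export
ancestral_reconstruction <- function(y, tree, spatial_cov,
                                     prior = pc_prior()) {
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("ancestral reconstruction expects complete binary observations")
  pc <- brownian_vcv(tree, taxa_order = names(y))
  fit <- fit_feature(y, pc, spatial_cov, prior = prior)

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ## shared-path covariance between every pair of nodes (tips + internal)
  dep <- ape::node.depth.edgelength(tree)
  dmat <- ape::dist.nodes(tree)
  allV <- outer(dep, dep, "+") - dmat
  allV <- allV / 2
  tipidx <- seq_len(ntip)
  intidx <- ntip + seq_len(nnode)
  ## same standardization as the fit (geometric mean of the tip diagonal)
  g <- exp(mean(log(diag(allV)[tipidx][diag(allV)[tipidx] > 0])))
  Sp_tt <- allV[tipidx, tipidx] / g
  dimnames(Sp_tt) <- list(tree$tip.label, tree$tip.label)
  ord <- match(names(y), tree$tip.label)
  Sp_tt <- Sp_tt[ord, ord]
  C_it <- allV[intidx, tipidx, drop = FALSE][, ord, drop = FALSE] / g
  Sp_ii <- allV[intidx, intidx, drop = FALSE] / g

  s2 <- exp(fit$mode)
  s2p <- s2[1]; s2s <- s2[2]
  Ss <- standardized_cov(spatial_cov)
  Sw <- s2p * Sp_tt + s2s * Ss + diag(1e-8, ntip)
  ## E[u_tips | w-hat] under the joint Gaussian (u, w = u + v)
  w_hat <- fit$latent_mode
  K <- s2p * Sp_tt %*% solve(Sw)
  u_tip <- K %*% w_hat
  ## project to internal nodes through the Brownian structure
  Qtt <- solve(s2p * Sp_tt + diag(1e-8, ntip))
  A <- (s2p * C_it) %*% Qtt
  u_int <- A %*% u_tip
  var_int <- pmax(s2p * diag(Sp_ii) - rowSums((A * (s2p * C_it))), 0)
  ## logistic-normal approximation to the posterior predictive
  kappa <- 1 / sqrt(1 + (16 * sqrt(3) / (15 * pi))^2 * var_int)
  prob <- stats::plogis(kappa * (fit$intercept["mean"] + u_int))
  data.frame(node = intidx, prob = as.numeric(prob))
}

#' Fit the spatiophylogenetic model to every feature of a matrix
#'
#' @param x binarized trait matrix (missing allowed; not imputed)
#' @param phylo_cov,spatial_cov covariance models over the matrix taxa
#' @param prior \code{pc_prior}
#' @param ... passed to \code{\link{fit_feature}}
#' @return data frame with one row per feature (posterior means/sds of
#'   variance proportions, intercept, degeneracy flag); a summary row of
#'   cross-feature means/sds over non-degenerate features is attached as
#'   attribute \code{"summary"}
#' @export
run_all_features <- function(x, phylo_cov, spatial_cov, prior = pc_prior(),
                             ...) {
  v <- as_trait_values(x, binary = TRUE)
  Sp <- if (inherits(phylo_cov, "covariance_model")) phylo_cov$vcv else phylo_cov
  common <- intersect(rownames(v), rownames(Sp))
  if (length(common) == 0) stop("no taxa shared between matrix and tree")
  rows <- lapply(colnames(v), function(fid) {
    yy <- v[, fid]; names(yy) <- rownames(v)
    fit <- suppressWarnings(fit_feature(yy, phylo_cov, spatial_cov,
                                        prior = prior, ...))
    data.frame(feature_id = fid,
               prop_phylo = fit$prop_phylo["mean"],
               prop_phylo_sd = fit$prop_phylo["sd"],
               prop_phylo_lower = fit$prop_phylo["lower"],
               prop_phylo_upper = fit$prop_phylo["upper"],
               prop_spatial = fit$prop_spatial["mean"],
               prop_spatial_sd = fit$prop_spatial["sd"],
               prop_spatial_lower = fit$prop_spatial["lower"],
               prop_spatial_upper = fit$prop_spatial["upper"],
               intercept = fit$intercept["mean"],
               degenerate = fit$degenerate,
               n_obs = fit$n_obs,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  ok <- !out$degenerate
  attr(out, "summary") <- data.frame(
    mean_prop_phylo = mean(out$prop_phylo[ok]),
    sd_prop_phylo = stats::sd(out$prop_phylo[ok]),
    mean_prop_spatial = mean(out$prop_spatial[ok]),
    sd_prop_spatial = stats::sd(out$prop_spatial[ok]),
    n_features = sum(ok)
  )
  out
}

#' Do grammar domains predict the variance proportions?
#'
#' Bayesian beta-likelihood regressions of a per-feature variance
#' proportion on its grammar domain, compared by WAIC against the
#' intercept-only model. Proportions exactly at 0 or 1 are nudged into
#' the open interval by a logged epsilon. The conclusion is "no
#' improvement" when the absolute WAIC difference is smaller than its
#' standard error.
#'
#' @param props numeric vector of per-feature proportions in [0, 1]
#' @param domains factor/character of grammar domains, same length
#' @param n_iter,n_burn MCMC size per chain (2 chains)
#' @param seed integer seed
#' @param epsilon nudge applied to boundary proportions
#' @return list with \code{waic_null}, \code{waic_domain},
#'   \code{delta_waic} (null - domain), \code{se_delta},
#'   \code{improvement} (logical)
#' @export
domain_effect_test <- function(props, domains, n_iter = 2000, n_burn = 500,
                               seed = 1, epsilon = 1e-4) {
  domains <- factor(domains)
  if (nlevels(domains) < 2)
    stop("domain_effect_test needs at least two domains")
  if (length(props) != length(domains)) stop("length mismatch")
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  nudged <- props <= 0 | props >= 1
  if (any(nudged)) {
    message(sprintf("domain_effect_test: nudged %d boundary proportions by %g",
                    sum(nudged), epsilon))
    props <- pmin(pmax(props, epsilon), 1 - epsilon)
  }
  fit_beta <- function(X) {
    model <- "
      model {
        for (i in 1:n) {
          logit(mu[i]) <- inprod(X[i,], beta)
          y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
        }
        for (j in 1:p) { beta[j] ~ dnorm(0, 0.01) }
        phi ~ dgamma(0.1, 0.01)
      }"
    jm <- rjags::jags.model(textConnection(model),
                            data = list(y = props, X = X, n = length(props),
                                        p = ncol(X)),
                            inits = list(.RNG.name = "base::Mersenne-Twister",
                                         .RNG.seed = seed),
                            n.chains = 1, quiet = TRUE)
    stats::update(jm, n_burn, progress.bar = "none")
    sm <- rjags::coda.samples(jm, c("beta", "phi"), n_iter,
                              progress.bar = "none")
    draws <- as.matrix(sm[[1]])
    bcols <- grep("^beta", colnames(draws))
    mu <- stats::plogis(draws[, bcols, drop = FALSE] %*% t(X))
    phi <- draws[, "phi"]
    ## pointwise log-likelihood, draws x observations
    ll <- matrix(NA_real_, nrow(draws), length(props))
    for (i in seq_along(props))
      ll[, i] <- stats::dbeta(props[i], mu[, i] * phi,
                              (1 - mu[, i]) * phi, log = TRUE)
    ll
  }
  waic_pointwise <- function(ll) {
    lpd <- apply(ll, 2, function(c) {
      m <- max(c); m + log(mean(exp(c - m)))
    })
    pwaic <- apply(ll, 2, stats::var)
    -2 * (lpd - pwaic)
  }
  X0 <- matrix(1, length(props), 1)
  X1 <- stats::model.matrix(~domains)
  w0 <- waic_pointwise(fit_beta(X0))
  w1 <- waic_pointwise(fit_beta(X1))
  delta <- sum(w0) - sum(w1)
  se <- sqrt(length(w0) * stats::var(w0 - w1))
  list(waic_null = sum(w0), waic_domain = sum(w1),
       delta_waic = delta, se_delta = se,
       improvement = abs(delta) > se & delta > 0)
}
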