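#' Gower distance between two binary records
#'
#' The fraction of mutually observed features on which the two records
#' disagree. Undefined (NA) when no feature is mutually observed.
#'
#' @param row_i,row_j binary vectors (NA allowed)
#' @return distance in [0, 1], or NA
#' @export
gower_distance <- function(row_i, row_j) {
  ok <- !is.na(row_i) & !is.na(row_j)
  if (!any(ok)) return(NA_real_)
  mean(row_i[ok] != row_j[ok])
}

#' All pairwise Gower distances of a trait matrix
#'
#' @param x binarized trait matrix
#' @return symmetric taxa x taxa matrix (NA where no mutual coverage)
#' @export
gower_matrix <- function(x) {
  v <- as_trait_values(x, binary = TRUE)
  M <- !is.na(v)
  X <- v; X[!M] <- 0
  Ms <- M * 1
  both <- Ms %*% t(Ms)                      # mutually observed counts
  P <- X %*% t(Ms)                          # sum x_i over mutual features
  Q <- X %*% t(X)                           # sum x_i x_j
  diffs <- P + t(P) - 2 * Q                 # differing mutual features
  D <- ifelse(both > 0, diffs / both, NA_real_)
  diag(D)[rowSums(M) > 0] <- 0
  dimnames(D) <- list(rownames(v), rownames(v))
  D
}

#' Unnormalized kernel density score of each grammar
#'
#' \eqn{\tilde P_i = \sum_l \exp(-k d_{il})}, summing over all taxa
#' including i itself (the self term contributes exp(0) = 1, so the
#' score is at least 1 and the surprisal \eqn{U = -\log \tilde P} is
#' finite). Larger k means a more local estimator.
#'
#' @param x complete binarized trait matrix
#' @param k kernel parameter (> 0)
#' @return named vector of \eqn{\tilde P_i}
#' @export
kernel_scores <- function(x, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be > 0")
  v <- as_trait_values(x, binary = TRUE)
  if (any(is.na(v))) stop("kernel_scores requires a complete matrix")
  D <- gower_matrix(v)
  rowSums(exp(-k * D))
}

#' Surprisal of each grammar under a score vector
#'
#' @param p_tilde (unnormalized) probabilities
#' @return \eqn{U = -\log \tilde P}
#' @export
surprisal <- function(p_tilde) -log(p_tilde)

#' Kernel surprisal computed on a numerically stable path
#'
#' Identical in definition to \code{surprisal(kernel_scores(x, k))}, but
#' the self term (exp(0) = 1) is separated out and the neighbour mass is
#' folded in through \code{log1p}, so very local kernels (large k) keep
#' their resolution instead of rounding \eqn{1 + \epsilon} to 1.
#'
#' @inheritParams kernel_scores
#' @return named surprisal vector
#' @export
kernel_surprisal <- function(x, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be > 0")
  v <- as_trait_values(x, binary = TRUE)
  if (any(is.na(v))) stop("kernel_surprisal requires a complete matrix")
  D <- gower_matrix(v)
  E <- exp(-k * D)
  diag(E) <- 0
  -log1p(rowSums(E))
}

#' Cluster features into bundles
#'
#' Hierarchical clustering (average linkage) of the feature columns
#' under the disagreement distance (fraction of taxa where two features
#' differ), with the bundle count chosen by the gap statistic against
#' uniform-random reference matrices of the same shape.
#'
#' @param x complete binarized trait matrix
#' @param seed integer seed (reference matrices are random)
#' @param k_max largest bundle count considered
#' @param n_ref reference matrices per k
#' @return list of class \code{feature_bundles}: \code{bundle} (named
#'   integer vector over features), \code{k}, \code{gap} (per-k table)
#' @export
bundle_features <- function(x, seed = 1, k_max = 12, n_ref = 20) {
  v <- as_trait_values(x, binary = TRUE)
  if (any(is.na(v))) stop("bundle_features requires a complete matrix")
  p <- ncol(v)
  if (p < 2) stop("need at least 2 features")
  set.seed(seed)
  k_max <- min(k_max, p - 1)

  feature_dist <- function(m) {
    d <- as.matrix(stats::dist(t(m), method = "manhattan")) / nrow(m)
    stats::as.dist(d)
  }
  logW <- function(d, cl) {
    dm <- as.matrix(d)
    w <- 0
    for (g in unique(cl)) {
      idx <- which(cl == g)
      if (length(idx) > 1)
        w <- w + sum(dm[idx, idx]) / (2 * length(idx))
    }
    log(max(w, 1e-12))
  }
  cluster_at <- function(d, k) {
    if (k == 1) rep(1L, attr(d, "Size"))
    else stats::cutree(stats::hclust(d, method = "average"), k)
  }
  d_obs <- feature_dist(v)
  lw_obs <- vapply(1:k_max, function(k) logW(d_obs, cluster_at(d_obs, k)),
                   numeric(1))
  lw_ref <- matrix(NA_real_, n_ref, k_max)
  for (b in seq_len(n_ref)) {
    ref <- matrix(stats::rbinom(length(v), 1, 0.5), nrow(v))
    d_ref <- feature_dist(ref)
    lw_ref[b, ] <- vapply(1:k_max, function(k) logW(d_ref, cluster_at(d_ref, k)),
                          numeric(1))
  }
  gap <- colMeans(lw_ref) - lw_obs
  sk <- apply(lw_ref, 2, stats::sd) * sqrt(1 + 1 / n_ref)
  ## smallest k with Gap(k) >= Gap(k+1) - s_{k+1}
  k <- k_max
  for (i in seq_len(k_max - 1)) {
    if (gap[i] >= gap[i + 1] - sk[i + 1]) { k <- i; break }
  }
  bundle <- cluster_at(d_obs, k)
  names(bundle) <- colnames(v)
  structure(list(bundle = bundle, k = k,
                 gap = data.frame(k = 1:k_max, gap = gap, se = sk)),
            class = "feature_bundles")
}

## EM for a latent class model (mixture of independent Bernoullis) on a
## binary matrix; add-one (Beta(1,1) posterior-mean) smoothing keeps all
## cell probabilities strictly inside (0, 1).
lca_em <- function(m, n_classes, max_iter = 200, tol = 1e-6) {
  n <- nrow(m); p <- ncol(m)
  theta <- matrix(stats::runif(n_classes * p, 0.25, 0.75), n_classes, p)
  pi_c <- rep(1 / n_classes, n_classes)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- sapply(seq_len(n_classes), function(c)
      log(pi_c[c]) + colSums(t(m) * log(theta[c, ]) +
                             t(1 - m) * log(1 - theta[c, ])))
    lp <- matrix(lp, n, n_classes)
    mx <- apply(lp, 1, max)
    po <- exp(lp - mx)
    denom <- rowSums(po)
    ll <- sum(mx + log(denom))
    r <- po / denom
    nk <- colSums(r)
    pi_c <- (nk + 1) / (n + n_classes)
    theta <- (t(r) %*% m + 1) / (nk + 2)
    theta <- pmin(pmax(theta, 1e-8), 1 - 1e-8)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(pi = pi_c, theta = theta, loglik = ll,
       bic = -2 * ll + ((n_classes - 1) + n_classes * p) * log(n),
       converged = it < max_iter)
}

#' Latent class probability of each grammar
#'
#' Per feature bundle, latent class models with 1..\code{max_classes}
#' classes are fitted by EM (10 random restarts, best likelihood kept)
#' and the class count is selected by BIC. The probability of a grammar
#' is the product over bundles of its mixture probability, and the
#' surprisal is \eqn{-\log P}. Class-conditional probabilities are
#' smoothed (add-one / Beta(1,1) posterior mean) so no grammar gets
#' probability zero.
#'
#' @param x complete binarized trait matrix
#' @param bundles a \code{feature_bundles} object (or named integer
#'   vector over the features of x)
#' @param max_classes largest class count tried per bundle
#' @param seed integer seed (EM restarts are random)
#' @param n_restarts EM restarts per class count
#' @return list: \code{prob} (named per-taxon probability),
#'   \code{classes} (selected class count per bundle), \code{models}
#' @export
lca_probability <- function(x, bundles, max_classes = 6, seed = 1,
                            n_restarts = 10) {
  v <- as_trait_values(x, binary = TRUE)
  if (any(is.na(v))) stop("lca_probability requires a complete matrix")
  bundle <- if (inherits(bundles, "feature_bundles")) bundles$bundle else bundles
  if (!all(colnames(v) %in% names(bundle)))
    stop("bundles must partition the feature set of x")
  set.seed(seed)
  prob <- rep(1, nrow(v)); names(prob) <- rownames(v)
  classes <- integer(0); models <- list()
  for (g in sort(unique(bundle))) {
    feats <- names(bundle)[bundle == g]
    m <- v[, feats, drop = FALSE]
    fits <- list()
    for (cc in seq_len(max_classes)) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        f <- lca_em(m, cc)
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      if (!best$converged && cc == 1)
        stop("EM failed to converge for bundle ", g)
      fits[[cc]] <- best
    }
    sel <- which.min(vapply(fits, `[[`, numeric(1), "bic"))
    fit <- fits[[sel]]
    lik <- sapply(seq_len(sel), function(c)
      fit$pi[c] * exp(colSums(t(m) * log(fit$theta[c, ]) +
                              t(1 - m) * log(1 - fit$theta[c, ]))))
    lik <- matrix(lik, nrow(v), sel)
    prob <- prob * rowSums(lik)
    classes[as.character(g)] <- sel
    models[[as.character(g)]] <- fit[c("pi", "theta")]
    models[[as.character(g)]]$features <- feats
  }
  list(prob = prob, classes = classes, models = models)
}

#' Probability of arbitrary grammars under a fitted latent class model
#'
#' Evaluates the bundle-product mixture density at new grammar vectors;
#' summing it over the full grammar space {0,1}^p gives exactly 1, which
#' is the normalization property of the estimator.
#'
#' @param grammars matrix of 0/1 rows with the fitted feature columns
#' @param models the \code{models} element of
#'   \code{\link{lca_probability}}'s result
#' @return numeric vector of probabilities
#' @export
lca_grammar_probability <- function(grammars, models) {
  prob <- rep(1, nrow(grammars))
  for (mod in models) {
    m <- grammars[, mod$features, drop = FALSE]
    lik <- sapply(seq_along(mod$pi), function(c)
      mod$pi[c] * exp(colSums(t(m) * log(mod$theta[c, ]) +
                              t(1 - m) * log(1 - mod$theta[c, ]))))
    lik <- matrix(lik, nrow(grammars), length(mod$pi))
    prob <- prob * rowSums(lik)
  }
  prob
}

#' Pick the estimator whose surprisal distribution is least skewed
#'
#' Candidates concentrated at either end of the scale (heavily skewed)
#' are poor summaries of the middle of the distribution; the estimator
#' with minimum absolute sample skewness (third standardized moment) is
#' selected. Ties go to the lexicographically first tag (logged).
#'
#' @param score_sets named list of surprisal vectors over the same taxa
#' @return list with \code{chosen} (tag), \code{skewness} (named vector)
#' @export
select_estimator <- function(score_sets) {
  if (length(score_sets) < 2) stop("need at least two candidate estimators")
  skew <- vapply(score_sets, function(u) {
    if (stats::sd(u) == 0) return(NA_real_)
    m <- mean(u)
    mean((u - m)^3) / (mean((u - m)^2))^1.5
  }, numeric(1))
  if (any(is.na(skew))) {
    warning("excluding constant score vectors: ",
            paste(names(skew)[is.na(skew)], collapse = ", "))
  }
  ok <- which(!is.na(skew))
  if (!length(ok)) stop("no usable estimator")
  a <- abs(skew[ok])
  winners <- names(a)[a == min(a)]
  if (length(winners) > 1)
    message("select_estimator: tie on |skewness|, keeping ",
            sort(winners)[1])
  list(chosen = sort(winners)[1], skewness = skew)
}

#' Surprisal scores under a sweep of kernels and the latent class model
#'
#' @param x complete binarized trait matrix
#' @param kernels kernel parameters to sweep
#' @param lca also fit the latent-class estimator
#' @param seed seed for bundling/EM
#' @return list: \code{scores} (data frame, one surprisal column per
#'   estimator), \code{selection} (from \code{\link{select_estimator}})
#' @export
surprisal_scores <- function(x, kernels = c(1, 5, 10, 15, 20, 25, 30, 40),
                             lca = TRUE, seed = 1) {
  v <- as_trait_values(x, binary = TRUE)
  out <- data.frame(taxon_id = rownames(v), stringsAsFactors = FALSE)
  sets <- list()
  for (k in kernels) {
    u <- kernel_surprisal(v, k)
    tag <- sprintf("kernel_%g", k)
    out[[tag]] <- u
    sets[[tag]] <- u
  }
  if (lca) {
    b <- bundle_features(v, seed = seed)
    u <- surprisal(lca_probability(v, b, seed = seed)$prob)
    out[["lca"]] <- u
    sets[["lca"]] <- u
  }
  list(scores = out, selection = select_estimator(sets))
}

#' The most unusual taxa under a surprisal vector
#'
#' "Most unusual" is defined as the top share of the surprisal
#' distribution (default: the top decile). The threshold is configurable
#' because no canonical cut-off exists.
#'
#' @param u named surprisal vector
#' @param share fraction of taxa to return, in (0, 1)
#' @return taxon ids of the top \code{share}, most unusual first
#' @export
most_unusual <- function(u, share = 0.1) {
  if (share <= 0 || share >= 1) stop("share must be in (0, 1)")
  n <- max(1L, floor(length(u) * share))
  names(sort(u, decreasing = TRUE))[seq_len(n)]
}

#' Manhattan distances between taxa with the missing-skip rule
#'
#' Counts, for every pair of taxa, the features where both values are
#' observed and differ; a feature with a missing value in either member
#' of the pair is ignored. The count is not normalized.
#'
#' @param x binarized trait matrix (missing allowed)
#' @return symmetric integer matrix with zero diagonal
#' @export
manhattan_matrix <- function(x) {
  v <- as_trait_values(x, binary = TRUE)
  M <- !is.na(v)
  X <- v; X[!M] <- 0
  Ms <- M * 1
  P <- X %*% t(Ms)
  Q <- X %*% t(X)
  D <- P + t(P) - 2 * Q
  diag(D) <- 0
  storage.mode(D) <- "integer"
  dimnames(D) <- list(rownames(v), rownames(v))
  D
}

#' Bayesian regression of unusualness on family and area
#'
#' Gaussian regression of the surprisal score on language family and
#' cultural area (treatment-coded fixed effects) with two correlated
#' random effects whose covariance structures are the phylogenetic
#' (Brownian) and spatial (Matern) matrices:
#' \deqn{y = X\beta + u + v + e, \quad u \sim N(0, \sigma_p^2 \Sigma_p),
#' \ v \sim N(0, \sigma_s^2 \Sigma_s), \ e \sim N(0, \sigma^2 I).}
#'
#' Family fixed effects and the phylogenetic random effect are partially
#' confounded (a family's mean shift can be absorbed by the tree
#' effect), which makes single-site Gibbs samplers mix extremely slowly
#' on this posterior. The sampler therefore collapses the Gaussian part:
#' with a flat prior, beta is integrated out analytically and
#' Metropolis-Hastings (adaptive scale, burn-in discarded) runs on the
#' three log-standard-deviations only, under half-Student-t(3, 0,
#' 2.5 sd(y)) priors; beta and the combined random effect are then drawn
#' exactly from their Gaussian conditionals for each retained draw.
#' Convergence is still summarized by potential scale reduction factors
#' across independent chains.
#'
#' The reported Bayesian R-squared measures the family/area component:
#' per posterior draw it is var(X beta) / (var(X beta) + var(random
#' effects) + residual variance), so the two correlated random effects
#' count as structured nuisance rather than explained signal. This keeps
#' the statistic near zero when the response is pure noise (which the
#' spatial effect, being nearly uncorrelated at long range, could
#' otherwise absorb).
#'
#' @param u named surprisal vector
#' @param family,area character vectors aligned with u
#' @param phylo_vcv,spatial_vcv covariance models/matrices over the same
#'   taxa (standardized internally)
#' @param chains,iterations MCMC chains and post-burnin iterations per
#'   chain
#' @param burnin burn-in iterations
#' @param seed integer seed
#' @return list of class \code{unusualness_fit}: \code{coefficients}
#'   (posterior summary frame), \code{bayes_r2} (mean, sd),
#'   \code{rhat_max}, \code{converged}, \code{sigma}
#' @export
unusualness_regression <- function(u, family, area, phylo_vcv, spatial_vcv,
                                   chains = 4, iterations = 6000,
                                   burnin = 1000, seed = 1) {
  n <- length(u)
  y <- as.numeric(u)
  Sp <- standardized_cov(phylo_vcv)
  Ss <- standardized_cov(spatial_vcv)
  if (nrow(Sp) != n || nrow(Ss) != n) stop("dimension mismatch")
  X <- stats::model.matrix(~ factor(family) + factor(area))
  p <- ncol(X)
  prior_scale <- 2.5 * stats::sd(y)

  ## log posterior of theta = log(sigma_p, sigma_s, sigma), beta collapsed
  log_post <- function(th) {
    s <- exp(th)
    V <- s[1]^2 * Sp + s[2]^2 * Ss
    diag(V) <- diag(V) + s[3]^2 + 1e-10
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(-Inf)
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    XtViX <- crossprod(X, Vi_X)
    cXX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cXX)) return(-Inf)
    bhat <- backsolve(cXX, forwardsolve(t(cXX), crossprod(X, Vi_y)))
    r <- y - X %*% bhat
    Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
    ll <- -sum(log(diag(cV))) - sum(log(diag(cXX))) -
      0.5 * sum(r * Vi_r)
    ## half-t(3) priors on the sds, with the log-scale Jacobian
    lpr <- sum(stats::dt(s / prior_scale, df = 3, log = TRUE) + th)
    ll + lpr
  }

  keep_per_chain <- min(500, iterations)
  thin <- max(1, floor(iterations / keep_per_chain))
  beta_ch <- vector("list", chains)
  theta_ch <- vector("list", chains)
  r2_all <- sig_all <- sigp_all <- sigs_all <- numeric(0)
  for (ch in seq_len(chains)) {
    set.seed(seed + 7919L * ch)
    th <- log(c(stats::sd(y) / 2, stats::sd(y) / 2, stats::sd(y) / 2)) +
      stats::rnorm(3, 0, 0.3)
    lp <- log_post(th)
    step <- 0.3
    acc <- 0
    kept_th <- matrix(NA_real_, 0, 3)
    for (it in seq_len(burnin + iterations)) {
      prop <- th + stats::rnorm(3, 0, step)
      lp2 <- log_post(prop)
      if (log(stats::runif(1)) < lp2 - lp) {
        th <- prop; lp <- lp2; acc <- acc + 1
      }
      if (it <= burnin && it %% 100 == 0) {  # adapt during burn-in
        rate <- acc / 100
        step <- step * exp(rate - 0.3)
        acc <- 0
      }
      if (it > burnin && (it - burnin) %% thin == 0)
        kept_th <- rbind(kept_th, th)
    }
    ## conditional draws of beta and the combined random effect
    nb <- nrow(kept_th)
    bs <- matrix(NA_real_, nb, p)
    r2s <- numeric(nb)
    for (k in seq_len(nb)) {
      s <- exp(kept_th[k, ])
      C <- s[1]^2 * Sp + s[2]^2 * Ss
      V <- C; diag(V) <- diag(V) + s[3]^2 + 1e-10
      cV <- chol(V)
      Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
      Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
      XtViX <- crossprod(X, Vi_X)
      cXX <- chol(XtViX)
      bhat <- backsolve(cXX, forwardsolve(t(cXX), crossprod(X, Vi_y)))
      bdraw <- bhat + backsolve(cXX, stats::rnorm(p))
      r <- y - X %*% bdraw
      Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
      m_re <- C %*% Vi_r
      cond_cov <- C - C %*% backsolve(cV, forwardsolve(t(cV), C))
      cond_cov <- (cond_cov + t(cond_cov)) / 2
      ev <- eigen(cond_cov, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
      re <- m_re + L %*% stats::rnorm(n)
      fixed <- X %*% bdraw
      r2s[k] <- stats::var(fixed) /
        (stats::var(fixed) + stats::var(as.numeric(re)) + s[3]^2)
      bs[k, ] <- bdraw
    }
    beta_ch[[ch]] <- bs
    theta_ch[[ch]] <- kept_th
    r2_all <- c(r2_all, r2s)
    sig_all <- c(sig_all, exp(kept_th[, 3]))
    sigp_all <- c(sigp_all, exp(kept_th[, 1]))
    sigs_all <- c(sigs_all, exp(kept_th[, 2]))
  }
  mc <- coda::mcmc.list(lapply(seq_len(chains), function(ch)
    coda::mcmc(cbind(beta_ch[[ch]], theta_ch[[ch]]))))
  gd <- tryCatch(coda::gelman.diag(mc, autoburnin = FALSE,
                                   multivariate = FALSE),
                 error = function(e) NULL)
  rhat_max <- if (is.null(gd)) NA_real_ else max(gd$psrf[, 1], na.rm = TRUE)
  converged <- !is.na(rhat_max) && rhat_max <= 1.05
  if (!converged)
    warning(sprintf("convergence flagged: max Rhat = %.3f", rhat_max))
  bdraws <- do.call(rbind, beta_ch)
  co <- data.frame(
    term = colnames(X),
    mean = colMeans(bdraws),
    sd = apply(bdraws, 2, stats::sd),
    lower = apply(bdraws, 2, stats::quantile, 0.025),
    upper = apply(bdraws, 2, stats::quantile, 0.975),
    row.names = NULL)
  structure(list(coefficients = co,
                 bayes_r2 = c(mean = mean(r2_all), sd = stats::sd(r2_all)),
                 rhat_max = rhat_max, converged = converged,
                 sigma = c(mean = mean(sig_all), phylo = mean(sigp_all),
                           spatial = mean(sigs_all))),
            class = "unusualness_fit")
}

#' @export
print.unusualness_fit <- function(x, ...) {
  cat(sprintf("<unusualness_fit> Bayesian R2 = %.3f (sd %.3f), max Rhat %.3f\n",
              x$bayes_r2["mean"], x$bayes_r2["sd"], x$rhat_max))
  invisible(x)
}
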