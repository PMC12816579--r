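# Mean-field variational Bayesian neural network regressor.
#
# One hidden ReLU layer; the output layer has two nodes, the predictive
# mean and (through a softplus) the predictive SD of a heteroscedastic
# Gaussian. Every weight and bias carries a diagonal-Gaussian variational
# posterior q(w | mu, softplus(rho)^2); the prior is a scale mixture of two
# zero-mean Gaussians (one wide, one narrow). Training minimizes the
# negative ELBO with the KL term estimated by Monte Carlo from the same
# weight samples as the likelihood term, and gradients taken through the
# reparameterization w = mu + softplus(rho) * eps.

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Configuration for the Bayesian neural network
#'
#' @param n_hidden Hidden-layer width (default 128).
#' @param prior_pi Mixture weight of the wide prior component, in (0, 1).
#' @param prior_sigma1 SD of the wide prior component (must exceed
#'   `prior_sigma2`).
#' @param prior_sigma2 SD of the narrow prior component.
#' @param learning_rate Adam step size.
#' @param n_epochs Training epochs (full-batch).
#' @param mc_train_samples Monte Carlo weight samples per gradient step.
#' @param predict_samples Default number of predictive draws (>= 2).
#' @param seed Integer RNG seed.
#' @return A list of class `bnn_config`.
#' @export
bnn_config <- function(n_hidden = 128, prior_pi = 0.5, prior_sigma1 = 1.0,
                       prior_sigma2 = 0.0025, learning_rate = 0.01,
                       n_epochs = 500, mc_train_samples = 1,
                       predict_samples = 500, seed = 1) {
  stopifnot(prior_pi > 0, prior_pi < 1,
            prior_sigma1 > prior_sigma2, prior_sigma2 > 0,
            predict_samples >= 2, n_hidden >= 1, n_epochs >= 1,
            mc_train_samples >= 1)
  structure(list(n_hidden = n_hidden, prior_pi = prior_pi,
                 prior_sigma1 = prior_sigma1, prior_sigma2 = prior_sigma2,
                 learning_rate = learning_rate, n_epochs = n_epochs,
                 mc_train_samples = mc_train_samples,
                 predict_samples = predict_samples, seed = seed),
            class = "bnn_config")
}

# log of the scale-mixture prior density, computed in log space so the
# narrow component cannot underflow.
.log_mix_prior <- function(w, cfg) {
  l1 <- dnorm(w, 0, cfg$prior_sigma1, log = TRUE) + log(cfg$prior_pi)
  l2 <- dnorm(w, 0, cfg$prior_sigma2, log = TRUE) + log(1 - cfg$prior_pi)
  mx <- pmax(l1, l2)
  mx + log(exp(l1 - mx) + exp(l2 - mx))
}

# d(-log p)/dw for the mixture prior (responsibility-weighted).
.dneg_log_mix_prior <- function(w, cfg) {
  l1 <- dnorm(w, 0, cfg$prior_sigma1, log = TRUE) + log(cfg$prior_pi)
  l2 <- dnorm(w, 0, cfg$prior_sigma2, log = TRUE) + log(1 - cfg$prior_pi)
  mx <- pmax(l1, l2)
  r1 <- exp(l1 - mx); r2 <- exp(l2 - mx)
  z <- r1 + r2
  (r1 / z) * w / cfg$prior_sigma1^2 + (r2 / z) * w / cfg$prior_sigma2^2
}

.bnn_shapes <- function(d, h) {
  list(W1 = c(d, h), b1 = c(1, h), W2 = c(h, 2), b2 = c(1, 2))
}

.bnn_init <- function(d, h) {
  shapes <- .bnn_shapes(d, h)
  mu <- list(
    W1 = matrix(rnorm(d * h, 0, 1 / sqrt(d)), d, h),
    b1 = matrix(0, 1, h),
    W2 = matrix(rnorm(h * 2, 0, 1 / sqrt(h)), h, 2),
    b2 = matrix(c(0, 0), 1, 2)
  )
  rho <- lapply(shapes, function(s) matrix(-5, s[1], s[2]))
  list(mu = mu, rho = rho)
}

.bnn_forward <- function(w, X) {
  Z1 <- sweep(X %*% w$W1, 2, w$b1, "+")
  A <- pmax(Z1, 0)
  O <- sweep(A %*% w$W2, 2, w$b2, "+")
  s <- .softplus(O[, 2]) + 1e-6
  list(Z1 = Z1, A = A, O = O, mu_y = O[, 1], s = s)
}

#' Fit a variational Bayesian neural network
#'
#' Trains the mean-field BNN by minimizing the negative evidence lower
#' bound: a Monte Carlo estimate of KL(q || mixture prior) minus the
#' expected heteroscedastic Gaussian log-likelihood. Training is full-batch
#' Adam and fully reproducible given `config$seed`.
#'
#' @param X Feature matrix (use a fitted [feature_pipeline] upstream, as
#'   for the other regressors).
#' @param y Numeric targets.
#' @param config A [bnn_config()].
#' @return An object of class `bnn_posterior` holding the variational means
#'   and scales, the config, and the per-epoch negative-ELBO trace.
#' @export
fit_bnn <- function(X, y, config = bnn_config()) {
  stopifnot(inherits(config, "bnn_config"))
  X <- .as_plain_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (length(y) < 2L) stop("need at least 2 training points")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("features and targets must be finite")
  }
  d <- ncol(X); h <- config$n_hidden; n <- length(y)
  set.seed(config$seed)
  par <- .bnn_init(d, h)
  nm <- names(par$mu)
  adam <- list(
    m_mu = lapply(par$mu, function(p) p * 0),
    v_mu = lapply(par$mu, function(p) p * 0),
    m_rho = lapply(par$rho, function(p) p * 0),
    v_rho = lapply(par$rho, function(p) p * 0)
  )
  b1 <- 0.9; b2 <- 0.999; ee <- 1e-8; lr <- config$learning_rate
  trace <- numeric(config$n_epochs)
  for (epoch in seq_len(config$n_epochs)) {
    g_mu <- lapply(par$mu, function(p) p * 0)
    g_rho <- lapply(par$rho, function(p) p * 0)
    loss_acc <- 0
    for (s_idx in seq_len(config$mc_train_samples)) {
      eps <- lapply(par$mu, function(p) matrix(rnorm(length(p)), nrow(p), ncol(p)))
      sig <- lapply(par$rho, .softplus)
      w <- lapply(nm, function(k) par$mu[[k]] + sig[[k]] * eps[[k]])
      names(w) <- nm
      fw <- .bnn_forward(w, X)
      resid <- y - fw$mu_y
      nll <- sum(log(fw$s) + 0.5 * (resid / fw$s)^2) + 0.5 * n * log(2 * pi)
      logq <- sum(vapply(nm, function(k) {
        sum(-log(sig[[k]]) - 0.5 * eps[[k]]^2 - 0.5 * log(2 * pi))
      }, numeric(1)))
      logp <- sum(vapply(nm, function(k) sum(.log_mix_prior(w[[k]], config)),
                         numeric(1)))
      loss <- (logq - logp) + nll
      if (!is.finite(loss)) {
        stop("divergent BNN loss (non-finite) at epoch ", epoch)
      }
      loss_acc <- loss_acc + loss
      # Backprop of the NLL through the network.
      d_mu_y <- -resid / fw$s^2
      d_sraw <- (1 / fw$s - resid^2 / fw$s^3) * plogis(fw$O[, 2])
      dO <- cbind(d_mu_y, d_sraw)
      gw <- list()
      gw$W2 <- t(fw$A) %*% dO
      gw$b2 <- matrix(colSums(dO), 1, 2)
      dA <- dO %*% t(w$W2)
      dZ1 <- dA * (fw$Z1 > 0)
      gw$W1 <- t(X) %*% dZ1
      gw$b1 <- matrix(colSums(dZ1), 1, h)
      for (k in nm) {
        # dF/dw: KL pathwise terms plus the likelihood gradient.
        dlogq_dw <- -(w[[k]] - par$mu[[k]]) / sig[[k]]^2
        dF_dw <- dlogq_dw + .dneg_log_mix_prior(w[[k]], config) + gw[[k]]
        sgm <- plogis(par$rho[[k]])
        g_mu[[k]] <- g_mu[[k]] + dF_dw + (w[[k]] - par$mu[[k]]) / sig[[k]]^2
        g_rho[[k]] <- g_rho[[k]] + dF_dw * eps[[k]] * sgm +
          (-1 / sig[[k]] + (w[[k]] - par$mu[[k]])^2 / sig[[k]]^3) * sgm
      }
    }
    S <- config$mc_train_samples
    trace[epoch] <- loss_acc / S
    t_ad <- epoch
    for (k in nm) {
      gm <- g_mu[[k]] / S; gr <- g_rho[[k]] / S
      adam$m_mu[[k]] <- b1 * adam$m_mu[[k]] + (1 - b1) * gm
      adam$v_mu[[k]] <- b2 * adam$v_mu[[k]] + (1 - b2) * gm^2
      adam$m_rho[[k]] <- b1 * adam$m_rho[[k]] + (1 - b1) * gr
      adam$v_rho[[k]] <- b2 * adam$v_rho[[k]] + (1 - b2) * gr^2
      mh <- adam$m_mu[[k]] / (1 - b1^t_ad)
      vh <- adam$v_mu[[k]] / (1 - b2^t_ad)
      par$mu[[k]] <- par$mu[[k]] - lr * mh / (sqrt(vh) + ee)
      mh <- adam$m_rho[[k]] / (1 - b1^t_ad)
      vh <- adam$v_rho[[k]] / (1 - b2^t_ad)
      par$rho[[k]] <- par$rho[[k]] - lr * mh / (sqrt(vh) + ee)
    }
  }
  structure(list(mu = par$mu, rho = par$rho, config = config,
                 d = d, feature_names = colnames(X), loss_trace = trace),
            class = "bnn_posterior")
}

#' @export
print.bnn_posterior <- function(x, ...) {
  cat(sprintf(
    "<bnn_posterior> %d -> %d -> 2 (ReLU), %d epochs, final -ELBO %.3f\n",
    x$d, x$config$n_hidden, x$config$n_epochs,
    x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Sample from the BNN posterior predictive distribution
#'
#' Each draw samples one weight configuration from the variational
#' posterior (epistemic variability) and then one target from the
#' heteroscedastic Gaussian output (aleatoric variability).
#'
#' @param post A [fit_bnn()] posterior.
#' @param X Query feature matrix.
#' @param n_draws Number of draws per chemical (default 500).
#' @param seed Integer RNG seed.
#' @return Matrix of draws, one row per query chemical, `n_draws` columns.
#' @export
sample_predictions <- function(post, X, n_draws = NULL, seed = 1) {
  stopifnot(inherits(post, "bnn_posterior"))
  if (is.null(n_draws)) n_draws <- post$config$predict_samples
  if (n_draws < 2) stop("n_draws must be >= 2")
  X <- .as_plain_matrix(X)
  if (ncol(X) != post$d) stop("feature dimension mismatch")
  set.seed(seed)
  n <- nrow(X)
  draws <- matrix(NA_real_, n, n_draws)
  sig <- lapply(post$rho, .softplus)
  nm <- names(post$mu)
  for (k_draw in seq_len(n_draws)) {
    w <- lapply(nm, function(k) {
      post$mu[[k]] + sig[[k]] *
        matrix(rnorm(length(post$mu[[k]])), nrow(post$mu[[k]]),
               ncol(post$mu[[k]]))
    })
    names(w) <- nm
    fw <- .bnn_forward(w, X)
    draws[, k_draw] <- fw$mu_y + fw$s * rnorm(n)
  }
  rownames(draws) <- rownames(X)
  draws
}

#' Predicted aleatoric noise SD
#'
#' The network's heteroscedastic output head predicts a per-input Gaussian
#' noise SD (aleatoric uncertainty). This returns that SD averaged over
#' weight samples from the variational posterior, separating it from the
#' epistemic spread contained in full predictive draws.
#'
#' @param post A [fit_bnn()] posterior.
#' @param X Query feature matrix.
#' @param n_weight_draws Weight samples to average over (default 100).
#' @param seed Integer RNG seed.
#' @return Numeric vector of per-input aleatoric SDs (strictly positive).
#' @export
predict_aleatoric_sd <- function(post, X, n_weight_draws = 100, seed = 1) {
  stopifnot(inherits(post, "bnn_posterior"), n_weight_draws >= 1)
  X <- .as_plain_matrix(X)
  if (ncol(X) != post$d) stop("feature dimension mismatch")
  set.seed(seed)
  sig <- lapply(post$rho, .softplus)
  nm <- names(post$mu)
  acc <- numeric(nrow(X))
  for (k_draw in seq_len(n_weight_draws)) {
    w <- lapply(nm, function(k) {
      post$mu[[k]] + sig[[k]] *
        matrix(rnorm(length(post$mu[[k]])), nrow(post$mu[[k]]),
               ncol(post$mu[[k]]))
    })
    names(w) <- nm
    acc <- acc + .bnn_forward(w, X)$s
  }
  acc / n_weight_draws
}

#' Summarize predictive draws into an interval prediction
#'
#' Percentiles use linear interpolation between order statistics
#' (`quantile` type 7): median = 50th percentile, bounds at
#' (1-level)/2 and 1-(1-level)/2; `sigma` is the SD of the draws.
#'
#' @param samples Draw matrix from [sample_predictions()] (rows =
#'   chemicals).
#' @param level Confidence level (default 0.95).
#' @param chem_ids Optional identifiers (default: row names).
#' @return Interval prediction data.frame with `chem_id`, `median`,
#'   `lower`, `upper`, `level`, `width`, `sigma`.
#' @export
summarize_predictive <- function(samples, level = 0.95, chem_ids = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 2L) stop("need at least 2 draws")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  if (is.null(chem_ids)) {
    chem_ids <- if (!is.null(rownames(samples))) rownames(samples)
                else sprintf("x%d", seq_len(nrow(samples)))
  }
  a <- (1 - level) / 2
  qs <- t(apply(samples, 1, quantile, probs = c(a, 0.5, 1 - a), type = 7,
                names = FALSE))
  sig <- apply(samples, 1, sd)
  data.frame(chem_id = chem_ids, median = qs[, 2], lower = qs[, 1],
             upper = qs[, 3], level = level, width = qs[, 3] - qs[, 1],
             sigma = sig, stringsAsFactors = FALSE, row.names = NULL)
}
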