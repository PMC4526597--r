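# Hierarchical Bayesian estimation of the hybrid agent by MCMC.
#
# Subject-level parameters live on transformed scales (logit for the
# learning rate and the model-based weight, log for the inverse
# temperature, identity for perseveration) and are drawn from independent
# group Gaussians. The group mean of transformed w is a linear function
# a + b * deval_z of each subject's standardized devaluation sensitivity;
# b is the quantity of interest. Weakly informative hyperpriors: N(0, 1.5^2)
# on group means and the slope, half-normal(0, 1) on group SDs.
#
# Sampler: Metropolis-within-Gibbs. Subject vectors are updated jointly by
# random-walk Metropolis (one vectorized likelihood call per sweep over the
# whole cohort; subjects are conditionally independent, so acceptance is
# per subject). Group means/slopes are conjugate Gibbs draws; group SDs use
# random-walk Metropolis on the log scale. Proposal scales adapt during
# warmup only.

PARAM_NAMES <- c("alpha", "beta", "w", "pi")

# split-Rhat over a chains x iterations matrix
split_rhat <- function(draws) {
  half <- floor(ncol(draws) / 2)
  if (half < 2) return(NA_real_)
  sub <- rbind(draws[, seq_len(half), drop = FALSE],
               draws[, half + seq_len(half), drop = FALSE])
  m <- nrow(sub); n <- ncol(sub)
  means <- rowMeans(sub)
  b <- n * stats::var(means)
  w <- mean(apply(sub, 1, stats::var))
  if (w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# basic multi-chain effective sample size (Geyer initial positive sequence)
ess_basic <- function(draws) {
  m <- nrow(draws); n <- ncol(draws)
  if (n < 4) return(NA_real_)
  centered <- draws - rowMeans(draws)
  max_lag <- min(n - 2, 200)
  rho <- sapply(0:max_lag, function(l) {
    mean(sapply(seq_len(m), function(c) {
      v <- centered[c, ]
      sum(v[1:(n - l)] * v[(1 + l):n]) / n
    }))
  })
  if (rho[1] == 0) return(NA_real_)
  rho <- rho / rho[1]
  s <- 0; l <- 1
  while (l + 1 <= length(rho) - 1) {
    pair <- rho[l + 1] + rho[l + 2]
    if (pair < 0) break
    s <- s + pair
    l <- l + 2
  }
  m * n / (1 + 2 * s)
}

#' Hierarchical Bayesian fit of the hybrid agent with a devaluation slope
#'
#' Fits all subjects jointly: transformed per-subject parameters are drawn
#' from group Gaussians, and the group mean of transformed `w` is a linear
#' function `a + b * deval_z` of each subject's standardized devaluation
#' sensitivity. The posterior of the slope `b` is the group-level estimate
#' of how devaluation sensitivity tracks model-based control. With
#' `covariate_all = TRUE` every parameter's group mean gets its own slope
#' (the specificity analysis).
#'
#' @param trials cohort trial records.
#' @param deval_z standardized devaluation sensitivity (named vector by
#'   subject, or data frame with columns `subject`, `deval_z`).
#' @param config a [task_config()].
#' @param n_chains,n_warmup,n_iter MCMC size (defaults 4 chains of
#'   1000 + 1000).
#' @param profile `"full"` (4 x 1500+1500) or `"ci"` (2 x 600+600);
#'   overrides the explicit sizes.
#' @param seed integer seed; chain c uses `seed + c`.
#' @param covariate_all regress every group mean (not just `w`'s) on
#'   `deval_z`.
#' @param lambda eligibility parameter held fixed.
#' @param include_test passed to the likelihood.
#' @param init `"mle"` (quick per-subject fits, jittered per chain) or
#'   `"random"`.
#' @return Object of class `hier_fit`: `b_summary` (posterior median, 95%
#'   interval, Rhat, ESS; one row per slope), `group` (posterior summaries
#'   of group means and SDs), `subject` (posterior-mean parameters per
#'   subject), `p_value` (two-sided posterior sign probability for `b`,
#'   doubled), `draws`, `diagnostics`, and `status` (`"ok"` or
#'   `"warning"`).
#' @export
fit_hierarchical <- function(trials, deval_z, config, n_chains = 4,
                             n_warmup = 1000, n_iter = 1000, profile = NULL,
                             seed = NULL, covariate_all = FALSE, lambda = 1,
                             include_test = FALSE, init = c("mle", "random")) {
  init <- match.arg(init)
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("full", "ci"))
    if (profile == "ci") { n_chains <- 2; n_warmup <- 600; n_iter <- 600 }
    else { n_chains <- 4; n_warmup <- 1500; n_iter <- 1500 }
  }
  dz <- deval_z_lookup(deval_z)
  kd <- kernel_data_cohort(trials, config, include_test)
  subjects <- names(kd)
  n <- length(subjects)
  if (n < 10) stop("hierarchical fit needs at least 10 subjects",
                   call. = FALSE)
  z <- unname(dz[subjects])
  if (anyNA(z)) stop("deval_z missing for some subjects", call. = FALSE)
  if (abs(mean(z)) > 0.3 || abs(stats::sd(z) - 1) > 0.3)
    warning("deval_z does not look standardized")
  cov_dims <- if (covariate_all) 1:4 else 3L   # which group means get a slope
  tau0 <- 1.5                                  # prior SD, means and slopes

  theta_ll <- function(theta) {
    nat <- cbind(stats::plogis(theta[, 1]), pmin(exp(theta[, 2]), 1e3),
                 stats::plogis(theta[, 3]), theta[, 4])
    -cohort_nll_cpp(nat, lambda, config$p_common, config$n_games, kd)
  }

  theta0 <- matrix(0, n, 4)
  if (init == "mle") {
    for (i in seq_len(n)) {
      f <- tryCatch(fit_mle(trials[trials$subject == subjects[i], ], config,
                            n_restarts = 2, seed = if (is.null(seed)) NULL
                            else (seed + i) %% 2147483646L,
                            lambda = lambda, include_test = include_test,
                            maxit = 200),
                    error = function(e) NULL)
      if (!is.null(f))
        theta0[i, ] <- natural_to_theta(f$estimate[["alpha"]],
                                        min(f$estimate[["beta"]], 50),
                                        f$estimate[["w"]],
                                        f$estimate[["pi"]])
    }
    theta0 <- pmin(pmax(theta0, -4), 4)
  }

  n_slopes <- length(cov_dims)
  b_keep <- array(NA_real_, c(n_chains, n_iter, n_slopes))
  a_keep <- array(NA_real_, c(n_chains, n_iter, 4))
  s_keep <- array(NA_real_, c(n_chains, n_iter, 4))
  subj_sum <- matrix(0, n, 4)
  acc_total <- 0; acc_count <- 0

  base_scale <- c(0.45, 0.35, 0.6, 0.3)
  for (chain in seq_len(n_chains)) {
    if (!is.null(seed)) set.seed((seed + chain) %% 2147483646L)
    theta <- theta0 + matrix(stats::rnorm(n * 4, 0, 0.2), n, 4)
    a <- colMeans(theta)
    b <- stats::setNames(rep(0, n_slopes), PARAM_NAMES[cov_dims])
    sigma <- pmax(apply(theta, 2, stats::sd), 0.3)
    # per-subject, per-dimension proposal scales (one dimension at a time)
    s_scale <- matrix(rep(base_scale, each = n), n, 4)
    sig_scale <- rep(0.3, 4)     # log-sigma proposal sd
    sig_acc <- rep(0, 4)
    ll <- theta_ll(theta)
    acc_win <- matrix(0, n, 4); win <- 0

    group_mu <- function() {
      mu <- matrix(a, n, 4, byrow = TRUE)
      for (j in seq_along(cov_dims)) mu[, cov_dims[j]] <-
          a[cov_dims[j]] + b[j] * z
      mu
    }

    for (it in seq_len(n_warmup + n_iter)) {
      warm <- it <= n_warmup
      # --- subject-level Metropolis: one dimension at a time, vectorized
      # across subjects (subjects are conditionally independent)
      mu <- group_mu()
      for (k in 1:4) {
        prop <- theta
        prop[, k] <- theta[, k] + stats::rnorm(n) * s_scale[, k]
        ll_prop <- theta_ll(prop)
        lp_cur <- stats::dnorm(theta[, k], mu[, k], sigma[k], log = TRUE)
        lp_prop <- stats::dnorm(prop[, k], mu[, k], sigma[k], log = TRUE)
        acc <- log(stats::runif(n)) < (ll_prop + lp_prop - ll - lp_cur)
        theta[acc, k] <- prop[acc, k]
        ll[acc] <- ll_prop[acc]
        acc_win[, k] <- acc_win[, k] + acc
        if (!warm) { acc_total <- acc_total + sum(acc); acc_count <- acc_count + n }
      }
      win <- win + 1

      # --- conjugate group means / slopes
      for (k in 1:4) {
        if (k %in% cov_dims) {
          j <- match(k, cov_dims)
          x <- cbind(1, z)
          prec <- crossprod(x) / sigma[k]^2 + diag(2) / tau0^2
          v <- solve(prec)
          m <- v %*% (crossprod(x, theta[, k]) / sigma[k]^2)
          ch <- chol(v)
          draw <- drop(m + t(ch) %*% stats::rnorm(2))
          a[k] <- draw[1]; b[j] <- draw[2]
        } else {
          prec <- n / sigma[k]^2 + 1 / tau0^2
          m <- sum(theta[, k]) / sigma[k]^2 / prec
          a[k] <- stats::rnorm(1, m, sqrt(1 / prec))
        }
      }

      # --- group SDs: random-walk on log scale, half-normal(0,1) prior
      mu <- group_mu()
      for (k in 1:4) {
        cur <- sigma[k]
        prop_s <- cur * exp(stats::rnorm(1, 0, sig_scale[k]))
        lp_c <- sum(stats::dnorm(theta[, k], mu[, k], cur, log = TRUE)) +
          stats::dnorm(cur, 0, 1, log = TRUE) + log(cur)
        lp_p <- sum(stats::dnorm(theta[, k], mu[, k], prop_s, log = TRUE)) +
          stats::dnorm(prop_s, 0, 1, log = TRUE) + log(prop_s)
        if (log(stats::runif(1)) < lp_p - lp_c) {
          sigma[k] <- prop_s
          sig_acc[k] <- sig_acc[k] + 1
        }
      }

      # --- warmup adaptation of proposal scales (subject and SD updates)
      if (warm && win == 25) {
        rate <- acc_win / win
        s_scale <- pmin(pmax(s_scale * exp(1.5 * (rate - 0.44)), 0.02), 8)
        sig_scale <- pmin(pmax(sig_scale * exp(1.5 * (sig_acc / win - 0.44)),
                               0.02), 2)
        acc_win[] <- 0; sig_acc[] <- 0; win <- 0
      }

      if (!warm) {
        kept <- it - n_warmup
        b_keep[chain, kept, ] <- b
        a_keep[chain, kept, ] <- a
        s_keep[chain, kept, ] <- sigma
        subj_sum <- subj_sum + cbind(stats::plogis(theta[, 1]),
                                     pmin(exp(theta[, 2]), 1e3),
                                     stats::plogis(theta[, 3]), theta[, 4])
      }
    }
  }

  slope_names <- paste0("b_", PARAM_NAMES[cov_dims])
  summarize <- function(arr, dim_names) {
    do.call(rbind, lapply(seq_len(dim(arr)[3]), function(j) {
      dr <- arr[, , j, drop = FALSE][, , 1]
      if (is.null(dim(dr))) dr <- matrix(dr, nrow = 1)
      all_d <- as.vector(dr)
      data.frame(name = dim_names[j], median = stats::median(all_d),
                 mean = mean(all_d),
                 ci_lower = stats::quantile(all_d, 0.025),
                 ci_upper = stats::quantile(all_d, 0.975),
                 rhat = split_rhat(dr), ess = ess_basic(dr),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  b_summary <- summarize(b_keep, slope_names)
  # two-sided posterior probability of sign, doubled (labelled as such)
  b_summary$p_sign <- sapply(seq_len(n_slopes), function(j) {
    d <- as.vector(b_keep[, , j])
    min(1, 2 * min(mean(d > 0), mean(d < 0)))
  })
  group <- rbind(summarize(a_keep, paste0("mu_", PARAM_NAMES)),
                 summarize(s_keep, paste0("sigma_", PARAM_NAMES)))
  subject <- data.frame(subject = subjects,
                        subj_sum / (n_chains * n_iter),
                        stringsAsFactors = FALSE)
  names(subject)[2:5] <- PARAM_NAMES
  if (is.numeric(trials$subject)) subject$subject <- as.numeric(subject$subject)

  rhats <- c(b_summary$rhat, group$rhat)
  warnings_out <- character()
  if (any(rhats > 1.1, na.rm = TRUE))
    warnings_out <- c(warnings_out,
                      "split-Rhat > 1.1 on some group quantities; chains may not have converged")
  if (acc_count > 0 && acc_total / acc_count < 0.05)
    warnings_out <- c(warnings_out, "very low subject-level acceptance rate")
  status <- if (length(warnings_out)) "warning" else "ok"
  if (length(warnings_out)) warning(paste(warnings_out, collapse = "; "))

  structure(list(
    b_summary = b_summary, group = group, subject = subject,
    p_value = b_summary$p_sign[match("b_w", b_summary$name)],
    draws = list(b = b_keep, a = a_keep, sigma = s_keep,
                 slope_names = slope_names),
    diagnostics = list(rhat = stats::setNames(rhats,
                                              c(b_summary$name, group$name)),
                       acceptance = if (acc_count) acc_total / acc_count
                                    else NA_real_,
                       n_chains = n_chains, n_warmup = n_warmup,
                       n_iter = n_iter, warnings = warnings_out),
    status = status), class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("Hierarchical hybrid-agent fit (", x$diagnostics$n_chains, " chains, ",
      x$diagnostics$n_warmup, "+", x$diagnostics$n_iter, "; status ",
      x$status, ")\n", sep = "")
  cat("Devaluation slope on transformed w:\n")
  print(x$b_summary, digits = 3)
  invisible(x)
}
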