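#' Build the design for the task-preference model
#'
#' Turns a labeled trial log into the model data of the hierarchical
#' categorical (multinomial-logit) model of task choice: one categorical
#' outcome per trial (every button press counts as a choice, whatever the
#' subsequent trial outcome), with the picture task as the reference
#' category; for each non-reference task, the position (left/middle/right,
#' middle reference) of *that task's* button in the trial's layout; time
#' of day as hours since session start, z-scored; session index, z-scored;
#' and animal, group and day (session date) identifiers. Covariates that
#' are constant over the modeled trials are dropped with a warning;
#' unlabeled trials are excluded with a message. Pairwise Pearson
#' correlations between the numeric predictors are reported.
#'
#' @param log Trial-log data frame.
#' @return Object of class `mci_model_data`: list with `y` (integer codes,
#'   1 = picture, 2 = static, 3 = dynamic), `pos_static`, `pos_dynamic`
#'   (integer codes 1 = left, 2 = middle, 3 = right), `z_time`,
#'   `z_session`, `animal`, `group`, `day` (factors), `n_dropped_unlabeled`,
#'   `dropped_covariates`, `predictor_correlations`.
#' @export
build_design <- function(log) {
  unlabeled <- is.na(log$animal_id)
  if (any(unlabeled))
    message(sum(unlabeled), " unlabeled trial(s) excluded from the design")
  log <- log[!unlabeled, , drop = FALSE]
  if (nrow(log) == 0) stop("no labeled trials")
  y <- match(log$chosen_task, c("picture", "static", "dynamic"))
  pos_of <- function(task) {
    p <- ifelse(log$layout_left == task, 1L,
         ifelse(log$layout_middle == task, 2L, 3L))
    p
  }
  hours_in <- log$t_init_s / 3600
  session_idx <- as.integer(factor(log$session_date,
                                   levels = sort(unique(log$session_date))))
  zsc <- function(x) {
    if (stats::sd(x) == 0) return(NULL)
    as.numeric(scale(x))
  }
  dropped <- character(0)
  z_time <- zsc(hours_in)
  if (is.null(z_time)) {
    dropped <- c(dropped, "time")
    warning("time-of-day covariate constant over the modeled trials; dropped")
    z_time <- rep(0, nrow(log))
  }
  z_session <- zsc(session_idx)
  if (is.null(z_session)) {
    dropped <- c(dropped, "session")
    warning("session covariate constant over the modeled trials; dropped")
    z_session <- rep(0, nrow(log))
  }
  num <- cbind(pos_static = pos_of("static"), pos_dynamic = pos_of("dynamic"),
               z_time = z_time, z_session = z_session)
  keep <- apply(num, 2, stats::sd) > 0
  corr <- if (sum(keep) >= 2) stats::cor(num[, keep, drop = FALSE]) else NULL
  out <- list(y = y,
              pos_static = pos_of("static"), pos_dynamic = pos_of("dynamic"),
              z_time = z_time, z_session = z_session,
              animal = factor(log$animal_id),
              group = factor(log$group_id),
              day = factor(log$session_date),
              n_dropped_unlabeled = sum(unlabeled),
              dropped_covariates = dropped,
              predictor_correlations = corr)
  class(out) <- "mci_model_data"
  out
}

#' @method print mci_model_data
#' @export
print.mci_model_data <- function(x, ...) {
  cat(sprintf("Model data: %d trials, %d animals, %d groups, %d days\n",
              length(x$y), nlevels(x$animal), nlevels(x$group),
              nlevels(x$day)))
  cat(sprintf("  outcome counts: picture %d, static %d, dynamic %d\n",
              sum(x$y == 1), sum(x$y == 2), sum(x$y == 3)))
  invisible(x)
}

# --- internal: design matrices and prior layout -----------------------------

# one block of random effects: a grouping factor x an effect (a covariate
# interacted with the factor's dummies); correlated across the two
# non-reference categories
re_block <- function(factor_name, effect_name, levels) {
  list(factor = factor_name, effect = effect_name, levels = levels)
}

# Build, for category k (1 = static, 2 = dynamic), the N x p design matrix,
# the prior sd of each fixed column, and the random-block column index map.
pref_design_matrix <- function(data, k, blocks, sd_intercept, sd_beta) {
  n <- length(data$y)
  pos <- if (k == 1) data$pos_static else data$pos_dynamic
  fixed <- cbind("(Intercept)" = rep(1, n),
                 pos_left = as.numeric(pos == 1L),
                 pos_right = as.numeric(pos == 3L),
                 z_time = data$z_time, z_session = data$z_session)
  prior_sd <- c(sd_intercept, rep(sd_beta, 4))
  cols <- list(fixed = seq_len(ncol(fixed)))
  parts <- list(Matrix::Matrix(fixed, sparse = TRUE))
  ncol_total <- ncol(fixed)
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    f <- data[[bl$factor]]
    cov <- switch(bl$effect,
                  "(Intercept)" = rep(1, n),
                  pos_left = as.numeric(pos == 1L),
                  pos_right = as.numeric(pos == 3L),
                  z_time = data$z_time, z_session = data$z_session)
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f), x = cov,
                              dims = c(n, nlevels(f)))
    colnames(Z) <- paste0(bl$factor, "[", levels(f), "]:", bl$effect)
    cols[[paste0("block", b)]] <- ncol_total + seq_len(ncol(Z))
    ncol_total <- ncol_total + ncol(Z)
    parts[[length(parts) + 1]] <- Z
  }
  X <- do.call(cbind, parts)
  list(X = X, prior_sd = prior_sd, cols = cols)
}

# log posterior of one block's hyperparameters given its effects
# u: L x 2 matrix; th = (log s1, log s2, atanh rho); priors: sd ~ Exp(rate),
# rho ~ LKJ(eta) for 2x2, density prop. to (1 - rho^2)^(eta - 1)
block_hyper_logpost <- function(th, u, rate_sd, lkj_eta) {
  s1 <- exp(th[1]); s2 <- exp(th[2]); rho <- tanh(th[3])
  L <- nrow(u)
  det_part <- -L * (log(s1) + log(s2) + 0.5 * log(1 - rho^2))
  q <- (u[, 1] / s1)^2 - 2 * rho * (u[, 1] / s1) * (u[, 2] / s2) +
       (u[, 2] / s2)^2
  ll <- det_part - sum(q) / (2 * (1 - rho^2))
  # priors + Jacobians of the transforms
  lp <- -rate_sd * (s1 + s2) + th[1] + th[2] +
        (lkj_eta - 1) * log(1 - rho^2) + log(1 - rho^2)
  ll + lp
}

# univariate stepping-out slice sampler (Neal 2003); NA/NaN evaluations
# (numerical overflow far in the tails) are treated as -Inf
slice1 <- function(x0, logf0, w = 1, max_step = 20) {
  logf <- function(x) { v <- logf0(x); if (is.na(v)) -Inf else v }
  y <- logf(x0) - stats::rexp(1, 1)
  lo <- x0 - stats::runif(1) * w
  hi <- lo + w
  i <- 0
  while (logf(lo) > y && i < max_step) { lo <- lo - w; i <- i + 1 }
  i <- 0
  while (logf(hi) > y && i < max_step) { hi <- hi + w; i <- i + 1 }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# Over-relaxed slice update (Neal 2003, sec. 8) for smooth unimodal
# conditionals: locate the slice endpoints by stepping-out plus bisection,
# reflect the current point through the slice midpoint, and fall back to
# keeping the current point if numerical endpoint error puts the
# reflection outside the slice. The negative autocorrelation this induces
# suppresses chain-mean noise in short chains.
slice1_or <- function(x0, logf0, w = 1, max_step = 20, bisect = 10) {
  logf <- function(x) { v <- logf0(x); if (is.na(v)) -Inf else v }
  y <- logf(x0) - stats::rexp(1, 1)
  lo <- x0 - w; hi <- x0 + w
  i <- 0
  while (logf(lo) > y && i < max_step) { lo <- lo - w; i <- i + 1 }
  i <- 0
  while (logf(hi) > y && i < max_step) { hi <- hi + w; i <- i + 1 }
  # bisection refinement of both endpoints; inner points bound the slice
  lo_in <- x0; hi_in <- x0
  for (i in seq_len(bisect)) {
    mlo <- (lo + lo_in) / 2
    if (logf(mlo) > y) lo_in <- mlo else lo <- mlo
    mhi <- (hi + hi_in) / 2
    if (logf(mhi) > y) hi_in <- mhi else hi <- mhi
  }
  x1 <- lo_in + hi_in - x0
  if (logf(x1) > y) x1 else x0
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half and the classic between/within variance
#' ratio `sqrt((n-1)/n + B/(n W))` computed over the resulting half
#' chains -- the split R-hat convention of modern Bayesian samplers, which
#' also flags within-chain drift. Constant parameters return `NA`.
#'
#' @param draws List of matrices (one per chain), kept iterations x
#'   parameters, equal column names.
#' @return Named vector of R-hat values.
#' @export
split_rhat <- function(draws) {
  n2 <- nrow(draws[[1]]) %/% 2
  sub <- do.call(cbind, lapply(draws, function(m) {
    rbind2 <- list(m[seq_len(n2), , drop = FALSE],
                   m[n2 + seq_len(n2), , drop = FALSE])
    rbind2
  }))
  p <- ncol(draws[[1]])
  out <- vapply(seq_len(p), function(j) {
    cols <- vapply(sub, function(m) m[, j], numeric(n2))
    W <- mean(apply(cols, 2, stats::var))
    if (!is.finite(W) || W == 0) return(NA_real_)
    B_n <- stats::var(colMeans(cols))
    sqrt((n2 - 1) / n2 + B_n / W)
  }, 0)
  stats::setNames(out, colnames(draws[[1]]))
}

#' Fit the hierarchical Bayesian categorical model of task preference
#'
#' Multinomial-logit mixed model of the trial-by-trial task choice with
#' the picture task as the reference category. The linear predictor of
#' category k (static, dynamic) is
#' `eta_k = b0_k + position effects + b_time_k z(time) + b_sess_k z(session)
#' + random effects`, and `P(k) = softmax(0, eta_static, eta_dynamic)`.
#' Random effects comprise intercepts by animal, group and day, plus
#' position/time/session slopes by animal and by group; each (factor,
#' effect) pair is bivariate-normal across the two categories with its own
#' standard deviations and correlation.
#'
#' Priors are weakly informative: N(0, 1) for intercepts, N(0, 0.5) for
#' the other fixed effects, Exponential(1) for random-effect standard
#' deviations, and an LKJ(2) prior on each across-category correlation.
#'
#' Sampling is by exact Polya-Gamma data augmentation: conditional on the
#' PG latent variables the full set of category-k coefficients (fixed and
#' random jointly) has a closed-form Gaussian conditional, and the
#' variance/correlation hyperparameters are updated by slice sampling.
#' Being a conjugate Gibbs scheme it has no divergent transitions;
#' convergence is judged on split-chain R-hat (threshold 1.01). Grouping
#' factors with a single level are dropped with a message.
#'
#' @param data An [build_design()] object.
#' @param chains Number of MCMC chains.
#' @param iter Total iterations per chain (including warm-up). The
#'   desk-scale default is 2 chains x 1000 iterations; the reported-run
#'   scale of the original protocol is 4 chains x 2500 with 1000 warm-up.
#' @param warmup Warm-up iterations discarded per chain.
#' @param re_slopes Include random slopes by animal and group (intercepts
#'   only by day).
#' @param priors List overriding `sd_intercept` (1), `sd_beta` (0.5),
#'   `rate_sd` (1), `lkj_eta` (2).
#' @param seed Optional integer seed.
#' @return Object of class `mci_preference_fit`: list with `draws` (one
#'   coefficient matrix per chain, kept iterations x parameters),
#'   `rhat` (named vector), `max_rhat`, `divergences` (0 by construction),
#'   `converged`, plus the design/bookkeeping needed by
#'   [posterior_task_probs()].
#' @export
fit_preference_model <- function(data, chains = 2, iter = 1000,
                                 warmup = floor(iter / 2),
                                 re_slopes = TRUE, priors = list(),
                                 seed = NULL, control = list()) {
  stopifnot(inherits(data, "mci_model_data"), iter > warmup, warmup >= 1)
  if (!is.null(seed)) set.seed(seed)
  pr <- utils::modifyList(list(sd_intercept = 1, sd_beta = 0.5,
                               rate_sd = 1, lkj_eta = 2), priors)
  ctl <- utils::modifyList(list(or_alpha = 0, sweeps = 4), control)
  or_alpha <- ctl$or_alpha  # over-relaxation strength, Gaussian updates
  # drop single-level grouping factors
  factors <- c("animal", "group", "day")
  usable <- factors[vapply(factors, function(f) nlevels(data[[f]]) >= 2, TRUE)]
  for (f in setdiff(factors, usable))
    message("grouping factor '", f, "' has a single level; dropped")
  blocks <- list()
  for (f in intersect(c("animal", "group"), usable)) {
    effs <- if (re_slopes) c("(Intercept)", "pos_left", "pos_right",
                             "z_time", "z_session") else "(Intercept)"
    for (e in effs) blocks <- c(blocks, list(re_block(f, e, levels(data[[f]]))))
  }
  if ("day" %in% usable)
    blocks <- c(blocks, list(re_block("day", "(Intercept)",
                                      levels(data$day))))
  des <- lapply(1:2, pref_design_matrix, data = data, blocks = blocks,
                sd_intercept = pr$sd_intercept, sd_beta = pr$sd_beta)
  p <- ncol(des[[1]]$X)
  n <- length(data$y)
  n_fixed <- length(des[[1]]$cols$fixed)
  kept <- iter - warmup
  cat_names <- c("static", "dynamic")
  par_names <- c(
    as.vector(t(outer(cat_names, colnames(des[[1]]$X), paste, sep = ":"))),
    unlist(lapply(seq_along(blocks), function(b) {
      bl <- blocks[[b]]
      paste0("sd_", bl$factor, ":", bl$effect, ":", cat_names)
    })),
    vapply(blocks, function(bl) paste0("cor_", bl$factor, ":", bl$effect),
           "")
  )
  draws <- replicate(chains,
                     matrix(NA_real_, kept, length(par_names),
                            dimnames = list(NULL, par_names)),
                     simplify = FALSE)
  # dense design pays off below ~4e6 cells; sparse above
  if (as.numeric(n) * p <= 4e6)
    for (k in 1:2) des[[k]]$X <- as.matrix(des[[k]]$X)
  kappa <- cbind(as.numeric(data$y == 2) - 0.5, as.numeric(data$y == 3) - 0.5)
  for (ch in seq_len(chains)) {
    theta <- list(rep(0, p), rep(0, p))    # coefficients per category
    hyp <- lapply(blocks, function(b) c(0, 0, 0))  # log s1, log s2, atanh rho
    eta <- cbind(drop(as.matrix(des[[1]]$X %*% theta[[1]])),
                 drop(as.matrix(des[[2]]$X %*% theta[[2]])))
    for (it in seq_len(iter)) {
     # Each stored iteration is a composite kernel of several sweeps. A sweep
     # updates, per category: the Polya-Gamma latents; then, while that
     # category's augmentation is in force, each random-effect block's
     # scale from its partially collapsed conditional (the block's effects
     # analytically marginalized out -- the classic scale/effect funnel is
     # removed entirely) followed by an exact redraw of those effects; and
     # finally all of the category's coefficients jointly from their exact
     # Gaussian conditional (Adler over-relaxed after warm-up). Sweeps
     # close with the sufficient-parameterization update of every block's
     # (sd, sd, correlation) triple.
     slice_fn <- if (it > warmup) slice1_or else slice1
     for (sweep in seq_len(ctl$sweeps)) {
      for (k in 1:2) {
        other <- 3 - k
        cvec <- softplus(eta[, other])      # log(exp(0) + exp(eta_other))
        psi <- eta[, k] - cvec
        omega <- rpolyagamma(psi)
        X <- des[[k]]$X
        kap <- kappa[, k]
        # the one O(n) pass of the sweep: augmented-likelihood precision
        # and linear term; subsequent updates work in p dimensions
        if (is.matrix(X)) {
          prec_data <- crossprod(X, X * omega)
          lin_data <- drop(crossprod(X, kap + omega * cvec))
        } else {
          prec_data <- as.matrix(Matrix::crossprod(X, X * omega))
          lin_data <- drop(as.matrix(Matrix::crossprod(X,
                                                       kap + omega * cvec)))
        }
        g <- drop(prec_data %*% theta[[k]])          # X' Omega eta_k
        # partially collapsed scale updates: each block's effects are
        # marginalized analytically (M and v read off the precomputed
        # quantities; M eigendecomposed so slice evaluations are O(L)),
        # then redrawn exactly under the new scale
        for (b in seq_along(blocks)) {
          idx <- des[[k]]$cols[[paste0("block", b)]]
          idx_o <- des[[other]]$cols[[paste0("block", b)]]
          L <- length(idx)
          u_cur <- theta[[k]][idx]
          M <- prec_data[idx, idx, drop = FALSE]
          v <- lin_data[idx] - g[idx] + drop(M %*% u_cur)
          rho <- tanh(hyp[[b]][3])
          c2 <- 1 - rho^2
          a <- rho * theta[[other]][idx_o] / exp(hyp[[b]][other])
          eig <- eigen(M, symmetric = TRUE)
          lam <- pmax(eig$values, 0)
          Qv <- drop(crossprod(eig$vectors, v))
          Qa <- drop(crossprod(eig$vectors, a))
          logf <- function(ls) {
            s <- exp(ls)
            cc <- 1 / (s^2 * c2)
            Qw <- Qv + Qa / (s * c2)
            -L * ls - 0.5 * sum(log(lam + cc)) +
              0.5 * sum(Qw^2 / (lam + cc)) - pr$rate_sd * s + ls
          }
          ls_new <- slice_fn(hyp[[b]][k], logf)
          hyp[[b]][k] <- ls_new
          s_new <- exp(ls_new)
          # exact redraw of the block's effects under the new scale
          cc <- 1 / (s_new^2 * c2)
          Qw <- Qv + Qa / (s_new * c2)
          u_new <- drop(eig$vectors %*%
                          (Qw / (lam + cc) +
                           stats::rnorm(L) / sqrt(lam + cc)))
          theta[[k]][idx] <- u_new
          g <- g + drop(prec_data[, idx, drop = FALSE] %*% (u_new - u_cur))
        }
        # joint update of all category-k coefficients
        prior_prec <- numeric(p)
        prior_mean <- numeric(p)
        prior_prec[des[[k]]$cols$fixed] <- 1 / des[[k]]$prior_sd^2
        for (b in seq_along(blocks)) {
          idx_k <- des[[k]]$cols[[paste0("block", b)]]
          idx_o <- des[[other]]$cols[[paste0("block", b)]]
          s <- exp(hyp[[b]][1:2]); rho <- tanh(hyp[[b]][3])
          sk <- s[k]; so <- s[other]
          prior_mean[idx_k] <- rho * sk / so * theta[[other]][idx_o]
          prior_prec[idx_k] <- 1 / (sk^2 * (1 - rho^2))
        }
        prec <- prec_data
        diag(prec) <- diag(prec) + prior_prec
        lin <- lin_data + prior_prec * prior_mean
        R <- chol(prec)
        m <- drop(backsolve(R, backsolve(R, lin, transpose = TRUE)))
        # Adler over-relaxation of the exact Gaussian conditional
        # (identity kernel at the default or_alpha = 0)
        theta[[k]] <- m - or_alpha * (theta[[k]] - m) +
          sqrt(1 - or_alpha^2) * drop(backsolve(R, stats::rnorm(p)))
        eta[, k] <- drop(as.matrix(X %*% theta[[k]]))
      }
      for (b in seq_along(blocks)) {
        idx1 <- des[[1]]$cols[[paste0("block", b)]]
        idx2 <- des[[2]]$cols[[paste0("block", b)]]
        u <- cbind(theta[[1]][idx1], theta[[2]][idx2])
        # sufficient-parameterization update of (sd1, sd2, cor) given u
        th <- hyp[[b]]
        for (d in 1:3) {
          th[d] <- slice_fn(th[d], function(v) {
            tt <- th; tt[d] <- v
            block_hyper_logpost(tt, u, pr$rate_sd, pr$lkj_eta)
          })
        }
        hyp[[b]] <- th
      }
     }
      if (it > warmup) {
        row <- c(theta[[1]], theta[[2]],
                 unlist(lapply(hyp, function(h) exp(h[1:2]))),
                 vapply(hyp, function(h) tanh(h[3]), 0))
        draws[[ch]][it - warmup, ] <- row
      }
    }
  }
  rhat <- split_rhat(draws)
  max_rhat <- suppressWarnings(max(rhat, na.rm = TRUE))
  fit <- list(draws = draws, par_names = par_names,
              col_names = colnames(des[[1]]$X),
              blocks = blocks, n_fixed = n_fixed, p = p,
              animal_levels = levels(data$animal),
              group_levels = levels(data$group),
              animal_group = stats::setNames(
                as.character(data$group)[match(levels(data$animal),
                                               as.character(data$animal))],
                levels(data$animal)),
              chains = chains, iter = iter, warmup = warmup,
              rhat = rhat, max_rhat = max_rhat,
              divergences = 0L,
              converged = is.finite(max_rhat) && max_rhat <= 1.01)
  class(fit) <- "mci_preference_fit"
  if (!fit$converged)
    warning("preference model flagged as non-converged (max R-hat = ",
            round(max_rhat, 3), ")")
  fit
}

#' @method print mci_preference_fit
#' @export
print.mci_preference_fit <- function(x, ...) {
  cat("Bayesian categorical task-preference model (Polya-Gamma Gibbs)\n")
  cat(sprintf("  %d chains x %d iterations (%d warm-up); %d parameters\n",
              x$chains, x$iter, x$warmup, length(x$par_names)))
  cat(sprintf("  max R-hat %.3f; divergences %d; %s\n", x$max_rhat,
              x$divergences,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

# stacked draws (all chains) for a named subset of parameters
fit_draws <- function(fit, pars) {
  do.call(rbind, lapply(fit$draws, function(m) m[, pars, drop = FALSE]))
}

#' Posterior per-animal task probabilities
#'
#' Evaluates, for every posterior draw, the softmax probability of each
#' task for one animal with covariates at 0 (the z-scale mean), the
#' buttons at the queried position (middle contributes nothing, the
#' neutral convention used to report preferences), and the animal's own
#' and its group's random effects. Day effects enter as their per-draw
#' average -- the prediction is "an average observed day" -- because the
#' fixed intercept and the day intercepts are only jointly identified;
#' conditioning the day effects at the prior mean of 0 instead would
#' leak that ridge's variance into every per-animal interval.
#'
#' @param fit An [fit_preference_model()] object.
#' @param animal Animal identifier.
#' @param position `"middle"` (default), `"left"` or `"right"`.
#' @param prob Credible-interval mass.
#' @return Data frame with one row per task: posterior `mean`, `lower`,
#'   `upper`.
#' @export
posterior_task_probs <- function(fit, animal, position = "middle",
                                 prob = 0.95) {
  if (!animal %in% fit$animal_levels) stop("unknown animal: ", animal)
  pos_col <- switch(position, middle = NULL, left = "pos_left",
                    right = "pos_right",
                    stop("position must be left/middle/right"))
  grp <- fit$animal_group[animal]
  eta_cat <- function(cat) {
    pars <- paste0(cat, ":(Intercept)")
    wanted <- c(sprintf("%s:animal[%s]:(Intercept)", cat, animal),
                sprintf("%s:group[%s]:(Intercept)", cat, grp))
    if (!is.null(pos_col)) {
      wanted <- c(wanted, paste0(cat, ":", pos_col),
                  sprintf("%s:animal[%s]:%s", cat, animal, pos_col),
                  sprintf("%s:group[%s]:%s", cat, grp, pos_col))
    }
    pars <- c(pars, intersect(wanted, fit$par_names))
    eta <- rowSums(fit_draws(fit, pars))
    day_pars <- grep(sprintf("^%s:day\\[.*\\]:\\(Intercept\\)$", cat),
                     fit$par_names, value = TRUE)
    if (length(day_pars))
      eta <- eta + rowMeans(fit_draws(fit, day_pars))
    eta
  }
  eta <- cbind(0, eta_cat("static"), eta_cat("dynamic"))
  pmat <- exp(eta - apply(eta, 1, max))
  pmat <- pmat / rowSums(pmat)
  colnames(pmat) <- c("picture", "static", "dynamic")
  a <- (1 - prob) / 2
  out <- data.frame(
    task = colnames(pmat),
    mean = colMeans(pmat),
    lower = apply(pmat, 2, stats::quantile, a),
    upper = apply(pmat, 2, stats::quantile, 1 - a),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "draws") <- pmat
  out
}

#' Per-animal preference verdict
#'
#' Task i shows evidence over task j when the lower bound of P(i)'s 95%
#' credible interval exceeds the upper bound of P(j)'s. The verdict is the
#' highest-posterior-mean task among those with evidence over at least one
#' other task, or `"none"`.
#'
#' @param fit An [fit_preference_model()] object.
#' @param animal Animal identifier.
#' @param position Button position at which probabilities are evaluated.
#' @return List with `verdict` and the probability `table`.
#' @export
preference_verdict <- function(fit, animal, position = "middle") {
  tab <- posterior_task_probs(fit, animal, position)
  has_evidence <- vapply(seq_len(3), function(i)
    any(tab$lower[i] > tab$upper[-i]), TRUE)
  verdict <- if (any(has_evidence)) {
    cand <- which(has_evidence)
    tab$task[cand[which.max(tab$mean[cand])]]
  } else "none"
  list(verdict = verdict, table = tab)
}

#' Prior-predictive task probabilities
#'
#' Draws fixed-effect intercepts and one animal effect from the model
#' priors and returns the implied per-task probabilities at the middle
#' position. The priors are exchangeable between the two non-reference
#' categories, so static and dynamic have identical prior-predictive
#' means; all three means are close to (but, for the reference category,
#' not exactly) 1/3 -- the softmax is nonlinear, so the reference
#' category's mean sits slightly below a third under wide priors.
#'
#' @param n_draws Number of prior draws.
#' @param sd_intercept,rate_sd Prior scales (defaults as in
#'   [fit_preference_model()]).
#' @return Matrix `n_draws` x 3 of task probabilities.
#' @export
prior_predictive_probs <- function(n_draws = 4000, sd_intercept = 1,
                                   rate_sd = 1) {
  b0 <- matrix(stats::rnorm(2 * n_draws, 0, sd_intercept), n_draws)
  sdu <- matrix(stats::rexp(2 * n_draws, rate_sd), n_draws)
  u <- matrix(stats::rnorm(2 * n_draws, 0, 1), n_draws) * sdu
  eta <- cbind(0, b0 + u)
  pmat <- exp(eta - apply(eta, 1, max))
  pmat <- pmat / rowSums(pmat)
  colnames(pmat) <- c("picture", "static", "dynamic")
  pmat
}

#' Full preference analysis of a trial log
#'
#' [build_design()] + [fit_preference_model()] + per-animal posterior
#' probabilities and verdicts at the middle button position.
#'
#' @param log Labeled trial-log data frame.
#' @param ... Passed to [fit_preference_model()].
#' @return Object of class `mci_preference`: list with `fit`, `probs`
#'   (per animal x task data frame) and `verdicts` (data frame).
#' @export
analyze_preference <- function(log, ...) {
  data <- build_design(log)
  fit <- fit_preference_model(data, ...)
  probs <- list(); verdicts <- list()
  for (a in fit$animal_levels) {
    v <- preference_verdict(fit, a)
    tab <- v$table
    tab$animal_id <- a
    probs[[a]] <- tab
    verdicts[[a]] <- data.frame(animal_id = a, verdict = v$verdict,
                                stringsAsFactors = FALSE)
  }
  out <- list(fit = fit,
              probs = do.call(rbind, c(probs, list(make.row.names = FALSE))),
              verdicts = do.call(rbind, c(verdicts,
                                          list(make.row.names = FALSE))))
  class(out) <- "mci_preference"
  out
}

#' @method print mci_preference
#' @export
print.mci_preference <- function(x, ...) {
  cat("Task-preference analysis\n")
  print(x$fit)
  tab <- table(x$verdicts$verdict)
  cat("  verdicts:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
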