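#' Full conditional of latent abundance in an N-mixture model
#'
#' With `N ~ Poisson(lambda)` and replicate counts
#' `y_j | N ~ Binomial(N, p_j)`, the full conditional
#' `P(N = n | y)` is proportional to
#' `dpois(n, lambda) * prod_j dbinom(y_j, n, p_j)` for
#' `n >= max(y)`.  The distribution is evaluated by truncated enumeration
#' with a Poisson-tail bound guaranteeing the neglected mass is below
#' `tol`; for a single all-zero replicate this reduces to the familiar
#' thinning identity `N - y ~ Poisson(lambda * (1 - p))`.
#'
#' @param y_vec Nonnegative integer counts across replicates.
#' @param lambda Poisson mean (> 0).
#' @param p_vec Per-replicate detection probabilities.
#' @param n_cap Hard upper bound on the enumeration; exceeding it is an
#'   error suggesting a larger cap.
#' @param tol Neglected tail mass bound.
#' @param prob_only If `TRUE`, return the support and normalized pmf
#'   instead of a draw.
#' @return An integer draw of `N` (or a list `n`, `prob`).
#' @examples
#' update_N(c(2), lambda = 3, p_vec = 1)  # always 2
#' @export
update_N <- function(y_vec, lambda, p_vec, n_cap = 1000L, tol = 1e-10,
                     prob_only = FALSE) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  check_prob(p_vec)
  if (any(y_vec < 0) || any(y_vec != round(y_vec)))
    stop("y_vec must hold nonnegative integers", call. = FALSE)
  if (length(p_vec) == 1L) p_vec <- rep(p_vec, length(y_vec))
  stopifnot(length(p_vec) == length(y_vec))
  n_lo <- max(y_vec)
  ## cap where the Poisson tail (an upper bound on the unnormalized
  ## conditional tail, since the binomial factors are <= 1) is negligible
  n_hi <- max(n_lo, stats::qpois(tol / 10, lambda, lower.tail = FALSE)) + 5L
  if (n_hi > n_cap)
    stop("enumeration cap ", n_cap, " exceeded (needs ", n_hi,
         "); raise 'n_cap'", call. = FALSE)
  n <- n_lo:n_hi
  logw <- dpois(n, lambda, log = TRUE)
  for (j in seq_along(y_vec))
    logw <- logw + dbinom(y_vec[j], n, p_vec[j], log = TRUE)
  w <- exp(logw - max(logw))
  pr <- w / sum(w)
  if (prob_only) return(list(n = n, prob = pr))
  sample(n, 1L, prob = pr)
}

#' Fit a community N-mixture model to replicated count data
#'
#' The abundance analogue of [fit_msom()]: latent abundance
#' `N_ik ~ Poisson(w_k * lambda_ik)` with
#' `log(lambda_ik) = llambda_k + beta_k . x_i`, replicate counts
#' `y_ijk | N_ik ~ Binomial(N_ik, p_ijk)` with a logit-linear detection
#' model, taxon-level parameters drawn from community normal
#' distributions (log-normal abundance heterogeneity across taxa), and
#' the same data-augmentation machinery (`w`, `Omega`) for taxa never
#' counted.  Latent `N` is drawn from its exact full conditional by
#' truncated enumeration each sweep.
#'
#' Stored abundance parameters reuse the `lpsi`/`betalpsi` naming of the
#' occupancy fit, read on the log-abundance scale.
#'
#' @param data A `detection_dataset` in count mode.
#' @param control An [mcmc_control()]; `n_cap` bounds the abundance
#'   enumeration.
#' @param prior A [prior_spec()].
#' @param seed Integer seed.
#' @return An object of class `nmix_fit` (also `msom_fit` for shared
#'   methods), with an extra per-chain store of latent-N posterior means.
#' @export
fit_nmixture <- function(data, control = mcmc_control(),
                         prior = prior_spec(), seed = NULL) {
  stopifnot(inherits(data, "detection_dataset"))
  if (data$mode != "count")
    stop("fit_nmixture() requires count-mode data", call. = FALSE)
  K <- dim(data$y)[3]
  M <- control$M %||% max(2L * K, K + 10L)
  if (M < K) stop("M smaller than the number of data taxa", call. = FALSE)
  chain_seeds <- derive_seeds(seed, control$n_chains)
  prep <- prepare_fit_data(data, M)
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    set_seed_if(chain_seeds[[ch]])
    run_nmix_chain(prep, control, prior)
  })
  structure(list(
    draws = lapply(chains, `[[`, "draws"),
    N_mean = Reduce(`+`, lapply(chains, `[[`, "N_sum")) /
      (length(chains) * nrow(chains[[1]]$draws)),
    N_min = Reduce(pmin, lapply(chains, `[[`, "N_min")),
    accept = lapply(chains, `[[`, "accept"),
    inclusion = NULL,
    taxa = data$taxa, M = M, n_data_taxa = K,
    observed_richness = observed_richness(data),
    data = data, control = control, prior = prior, seed = seed,
    model = "nmixture"), class = c("nmix_fit", "msom_fit"))
}

run_nmix_chain <- function(prep, control, prior) {
  M <- prep$M; n_v <- prep$n_v; n_s <- prep$n_s
  Po <- prep$Po; Pd <- prep$Pd
  Xocc <- prep$Xocc; Wdet <- prep$Wdet; Y <- prep$Y
  su <- prep$slot_unit
  fixed <- prior$fixed
  maxy <- matrix(0, n_v, M)
  for (u in seq_len(n_v)) {
    rows <- which(su == u)
    maxy[u, ] <- if (length(rows) > 1L)
      apply(Y[rows, , drop = FALSE], 2, max) else Y[rows, ]
  }

  ## initial state
  mean_y <- pmax(colMeans(rowsum(Y, su) / tabulate(su, n_v)), 0.05)
  llam <- log(mean_y / 0.5) + rnorm(M, 0, 0.2)
  betal <- matrix(0, M, Po)
  lp <- rnorm(M, qlogis(0.5), 0.2)
  betalp <- matrix(0, M, Pd)
  hy <- list(mu_lpsi = fixed$mu_lpsi %||% mean(llam),
             sigma_lpsi = fixed$sigma_lpsi %||%
               max(sd(llam), 0.5, na.rm = TRUE),
             mu_lp = fixed$mu_lp %||% mean(lp),
             sigma_lp = fixed$sigma_lp %||% 0.5,
             mu_betalpsi = fixed$mu_betalpsi %||% rep(0, Po),
             sigma_betalpsi = fixed$sigma_betalpsi %||% rep(0.5, Po),
             mu_betalp = fixed$mu_betalp %||% rep(0, Pd),
             sigma_betalp = fixed$sigma_betalp %||% rep(0.5, Pd))
  w <- ifelse(prep$det_any, 1L, rbinom(M, 1L, 0.5))
  omega <- mean(w)
  N <- maxy + matrix(rpois(n_v * M, 0.5), n_v, M)
  N[, w == 0] <- 0L

  ls <- list(llam = rep(log(0.3), M), lp = rep(log(0.4), M),
             betal = matrix(log(0.3), M, Po),
             betalp = matrix(log(0.4), M, Pd),
             sigma = rep(log(0.3), 4))

  lam_mat <- function() {
    e <- matrix(llam, n_v, M, byrow = TRUE)
    if (Po) e <- e + Xocc %*% t(betal)
    exp(e)
  }
  p_mat <- function() {
    e <- matrix(lp, n_s, M, byrow = TRUE)
    if (Pd) e <- e + Wdet %*% t(betalp)
    plogis(e)
  }
  pois_ll <- function(lam) {
    ll <- dpois(N, lam, log = TRUE)
    ll[, w == 0] <- 0
    colSums(ll)
  }
  binom_ll <- function(P) {
    ll <- dbinom(Y, N[su, , drop = FALSE], P, log = TRUE)
    ll[, w == 0] <- 0
    colSums(ll)
  }

  n_keep <- (control$n_iter - control$n_burnin) %/% control$thin
  pn <- msom_param_names(prep, Po, Pd)
  draws <- matrix(NA_real_, n_keep, length(pn), dimnames = list(NULL, pn))
  N_sum <- matrix(0, n_v, prep$K)
  N_min <- matrix(Inf, n_v, prep$K)
  acc_count <- c(llam = 0, lp = 0, betal = 0, betalp = 0, sigma = 0)
  acc_tot <- acc_count
  keep_i <- 0L

  for (iter in seq_len(control$n_iter)) {
    adapting <- iter <= control$n_burnin
    Lam <- lam_mat()
    P <- p_mat()
    ## per-unit probability a present individual escapes every replicate
    logq <- matrix(0, n_v, M)
    rs <- rowsum(log1p(-P), su)
    logq[as.integer(rownames(rs)), ] <- rs
    pdet_unit <- 1 - exp(logq)   # P(an individual is counted at least once)

    ## --- w, Omega: marginal P(all y = 0 | w = 1) = exp(-lambda * pdet)
    und <- which(!prep$det_any)
    if (length(und)) {
      logL <- colSums(-Lam[, und, drop = FALSE] *
                        pdet_unit[, und, drop = FALSE])
      pw <- 1 / (1 + exp(log1p(-omega) - (log(omega) + logL)))
      w[und] <- rbinom(length(und), 1L, pw)
    }
    op <- update_omega(w, prior$omega_a, prior$omega_b, draw = FALSE)
    omega <- rbeta(1, op[1], op[2])

    ## --- N from its exact full conditional (vectorized enumeration) ---
    N <- draw_N_all(Y, su, Lam, P, maxy, w, n_v, M, control$n_cap)

    ## --- detection parameters ---------------------------------------
    lld_cur <- binom_ll(P)
    del <- rnorm(M, 0, exp(ls$lp))
    P_prop <- plogis(qlogis(P) + matrix(del, n_s, M, byrow = TRUE))
    lld_prop <- binom_ll(P_prop)
    lr <- (lld_prop - lld_cur) +
      dnorm(lp + del, hy$mu_lp, hy$sigma_lp, log = TRUE) -
      dnorm(lp, hy$mu_lp, hy$sigma_lp, log = TRUE)
    acc <- log(runif(M)) < lr
    lp <- lp + del * acc
    acc_count["lp"] <- acc_count["lp"] + mean(acc)
    acc_tot["lp"] <- acc_tot["lp"] + 1
    if (adapting) ls$lp <- adapt_ls(ls$lp, acc, iter,
                                    control$target_accept)
    P <- p_mat()
    lld_cur <- binom_ll(P)
    if (Pd) for (pp in seq_len(Pd)) {
      del <- rnorm(M, 0, exp(ls$betalp[, pp]))
      e_prop <- qlogis(P) + outer(Wdet[, pp], del)
      lld_prop <- binom_ll(plogis(e_prop))
      lr <- (lld_prop - lld_cur) +
        dnorm(betalp[, pp] + del, hy$mu_betalp[pp], hy$sigma_betalp[pp],
              log = TRUE) -
        dnorm(betalp[, pp], hy$mu_betalp[pp], hy$sigma_betalp[pp],
              log = TRUE)
      acc <- log(runif(M)) < lr
      betalp[, pp] <- betalp[, pp] + del * acc
      acc_count["betalp"] <- acc_count["betalp"] + mean(acc)
      acc_tot["betalp"] <- acc_tot["betalp"] + 1
      if (adapting) ls$betalp[, pp] <- adapt_ls(ls$betalp[, pp], acc,
                                                iter,
                                                control$target_accept)
      P <- p_mat()
      lld_cur <- binom_ll(P)
    }
    ## prior redraw where there is no counting weight
    nw <- colSums(N) == 0
    if (any(nw)) {
      lp[nw] <- rnorm(sum(nw), hy$mu_lp, hy$sigma_lp)
      if (Pd) for (pp in seq_len(Pd))
        betalp[nw, pp] <- rnorm(sum(nw), hy$mu_betalp[pp],
                                hy$sigma_betalp[pp])
    }

    ## --- abundance parameters ----------------------------------------
    Lam <- lam_mat()
    llp_cur <- pois_ll(Lam)
    del <- rnorm(M, 0, exp(ls$llam))
    llp_prop <- pois_ll(Lam * matrix(exp(del), n_v, M, byrow = TRUE))
    lr <- (llp_prop - llp_cur) +
      dnorm(llam + del, hy$mu_lpsi, hy$sigma_lpsi, log = TRUE) -
      dnorm(llam, hy$mu_lpsi, hy$sigma_lpsi, log = TRUE)
    acc <- log(runif(M)) < lr
    llam <- llam + del * acc
    acc_count["llam"] <- acc_count["llam"] + mean(acc)
    acc_tot["llam"] <- acc_tot["llam"] + 1
    if (adapting) ls$llam <- adapt_ls(ls$llam, acc, iter,
                                      control$target_accept)
    if (Po) for (pp in seq_len(Po)) {
      Lam <- lam_mat()
      llp_cur <- pois_ll(Lam)
      del <- rnorm(M, 0, exp(ls$betal[, pp]))
      llp_prop <- pois_ll(Lam * exp(outer(Xocc[, pp], del)))
      lr <- (llp_prop - llp_cur) +
        dnorm(betal[, pp] + del, hy$mu_betalpsi[pp],
              hy$sigma_betalpsi[pp], log = TRUE) -
        dnorm(betal[, pp], hy$mu_betalpsi[pp], hy$sigma_betalpsi[pp],
              log = TRUE)
      acc <- log(runif(M)) < lr
      betal[, pp] <- betal[, pp] + del * acc
      acc_count["betal"] <- acc_count["betal"] + mean(acc)
      acc_tot["betal"] <- acc_tot["betal"] + 1
      if (adapting) ls$betal[, pp] <- adapt_ls(ls$betal[, pp], acc, iter,
                                               control$target_accept)
    }
    off <- w == 0
    if (any(off)) {
      llam[off] <- rnorm(sum(off), hy$mu_lpsi, hy$sigma_lpsi)
      if (Po) for (pp in seq_len(Po))
        betal[off, pp] <- rnorm(sum(off), hy$mu_betalpsi[pp],
                                hy$sigma_betalpsi[pp])
    }

    ## --- hyperparameters (conjugate means, Metropolis SDs) -----------
    hb <- update_hypers_generic(list(lpsi = llam, lp = lp,
                                     betalpsi = betal, betalp = betalp),
                                hy, fixed, prior, ls$sigma)
    hy <- hb$hy
    if (hb$n > 0) {
      if (adapting) ls$sigma <- adapt_ls(ls$sigma, hb$acc / hb$n, iter,
                                         control$target_accept)
      acc_count["sigma"] <- acc_count["sigma"] + hb$acc / hb$n
      acc_tot["sigma"] <- acc_tot["sigma"] + 1
    }

    if (!adapting && (iter - control$n_burnin) %% control$thin == 0) {
      keep_i <- keep_i + 1L
      draws[keep_i, ] <- msom_param_vector(hy, omega, w,
                                           rep(1L, Po), rep(1L, Pd),
                                           llam, lp, betal, betalp,
                                           prep, Po, Pd)
      N_sum <- N_sum + N[, seq_len(prep$K), drop = FALSE]
      N_min <- pmin(N_min, N[, seq_len(prep$K), drop = FALSE])
    }
  }
  list(draws = draws, N_sum = N_sum, N_min = N_min,
       accept = acc_count / pmax(acc_tot, 1))
}

## exact vectorized full-conditional draw of N over all (unit, taxon)
## cells: enumerate n = 0..cap with log-weights
## dpois(n, lambda) + sum_j dbinom(y_j, n, p_j), then inverse-CDF sample.
draw_N_all <- function(Y, su, Lam, P, maxy, w, n_v, M, n_cap) {
  lam_max <- max(Lam[, w == 1, drop = FALSE], 0)
  n_hi <- max(maxy) +
    max(stats::qpois(1e-12, lam_max + 1e-9, lower.tail = FALSE), 5L) + 5L
  if (n_hi > n_cap)
    stop("latent-abundance enumeration cap ", n_cap, " exceeded (needs ",
         n_hi, "); raise 'n_cap' in mcmc_control()", call. = FALSE)
  ns <- 0:n_hi
  ## cumulative weights streamed over n; inverse-CDF via per-cell uniform
  logw_max <- matrix(-Inf, n_v, M)
  store <- vector("list", length(ns))
  for (ii in seq_along(ns)) {
    n <- ns[ii]
    lw <- dpois(n, Lam, log = TRUE)
    lb <- dbinom(Y, n, P, log = TRUE)
    lw <- lw + rowsum_all(lb, su, n_v)
    lw[maxy > n] <- -Inf
    store[[ii]] <- lw
    logw_max <- pmax(logw_max, lw)
  }
  tot <- matrix(0, n_v, M)
  for (ii in seq_along(ns)) {
    store[[ii]] <- exp(store[[ii]] - logw_max)
    tot <- tot + store[[ii]]
  }
  u <- matrix(runif(n_v * M), n_v, M) * tot
  N <- matrix(0L, n_v, M)
  cum <- matrix(0, n_v, M)
  remaining <- matrix(TRUE, n_v, M)
  for (ii in seq_along(ns)) {
    cum <- cum + store[[ii]]
    hit <- remaining & (u <= cum)
    N[hit] <- ns[ii]
    remaining <- remaining & !hit
  }
  N[, w == 0] <- 0L
  N
}

rowsum_all <- function(x, group, n_groups) {
  out <- matrix(0, n_groups, ncol(x))
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

## shared conjugate-mean / Metropolis-SD hyperparameter sweep
update_hypers_generic <- function(params, hy, fixed, prior, ls_sigma) {
  acc <- 0; n <- 0
  upd <- function(x, mu_nm, sg_nm, ls_i, idx = NULL) {
    get_h <- function(nm) if (is.null(idx)) hy[[nm]] else hy[[nm]][idx]
    set_h <- function(nm, v) {
      if (is.null(idx)) hy[[nm]] <<- v else hy[[nm]][idx] <<- v
    }
    fx_mu <- if (is.null(idx)) fixed[[mu_nm]] else fixed[[mu_nm]]
    if (is.null(fx_mu)) {
      prec <- length(x) / get_h(sg_nm)^2 + 1 / prior$mu_sd^2
      mn <- (sum(x) / get_h(sg_nm)^2 + prior$mu_mean / prior$mu_sd^2) /
        prec
      set_h(mu_nm, rnorm(1, mn, sqrt(1 / prec)))
    }
    if (is.null(fixed[[sg_nm]])) {
      s_cur <- get_h(sg_nm)
      s_prop <- exp(log(s_cur) + rnorm(1, 0, exp(ls_sigma[ls_i])))
      if (s_prop < prior$sigma_upper) {
        lr <- sum(dnorm(x, get_h(mu_nm), s_prop, log = TRUE)) -
          sum(dnorm(x, get_h(mu_nm), s_cur, log = TRUE)) +
          log(s_prop) - log(s_cur)
        if (log(runif(1)) < lr) {
          set_h(sg_nm, s_prop)
          acc <<- acc + 1
        }
      }
      n <<- n + 1
    }
  }
  upd(params$lpsi, "mu_lpsi", "sigma_lpsi", 1)
  upd(params$lp, "mu_lp", "sigma_lp", 2)
  if (ncol(params$betalpsi))
    for (pp in seq_len(ncol(params$betalpsi)))
      upd(params$betalpsi[, pp], "mu_betalpsi", "sigma_betalpsi", 3, pp)
  if (ncol(params$betalp))
    for (pp in seq_len(ncol(params$betalp)))
      upd(params$betalp[, pp], "mu_betalp", "sigma_betalp", 4, pp)
  list(hy = hy, acc = acc, n = n)
}

#' Expected observed richness under random sampling of individuals
#'
#' The misspecification check for the count model: given fitted relative
#' abundances `pi_k = lambda_k / sum(lambda)` and a survey effort of `n`
#' individuals drawn at random from the pool, the expected number of taxa
#' observed is `sum_k [1 - (1 - pi_k)^n]`.  Comparing this to the
#' richness actually observed reveals nonrandom aggregation of
#' individuals.
#'
#' @param fit An `nmix_fit`, or a numeric vector of (relative) abundances.
#' @param n_individuals Number of individuals counted (>= 1).
#' @return For a vector input, the expected richness; for a fit, a list
#'   with per-draw values and a `mean` and 95% interval.
#' @examples
#' expected_richness_under_count_model(c(0.9, 0.1), 2)  # 1.18
#' @export
expected_richness_under_count_model <- function(fit, n_individuals) {
  stopifnot(n_individuals >= 1)
  pt_est <- function(lam) {
    if (all(lam == 0)) stop("all abundances are zero", call. = FALSE)
    pi_k <- lam / sum(lam)
    sum(1 - (1 - pi_k)^n_individuals)
  }
  if (is.numeric(fit)) return(pt_est(fit))
  stopifnot(inherits(fit, "nmix_fit"))
  K <- fit$n_data_taxa
  cols <- paste0("lpsi[", seq_len(K), "]")
  all_d <- do.call(rbind, fit$draws)[, cols, drop = FALSE]
  vals <- apply(exp(all_d), 1, pt_est)
  list(draws = vals, mean = mean(vals),
       ci = unname(quantile(vals, c(0.025, 0.975))))
}
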