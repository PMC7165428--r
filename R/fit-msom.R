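#' Prior specification for community occupancy and N-mixture models
#'
#' Weakly informative defaults, standard for community occupancy models:
#' community hyper-means are Normal(0, 1.5^2) on the logit scale,
#' hyper-SDs are Uniform(0, 5), and the augmentation inclusion
#' probability Omega has a Beta(1, 1) prior.
#'
#' @param mu_mean,mu_sd Normal prior for every community hyper-mean.
#' @param sigma_upper Upper bound of the Uniform(0, upper) prior on every
#'   community hyper-SD.
#' @param omega_a,omega_b Beta prior for Omega.
#' @param fixed Named list of hyperparameters to hold fixed instead of
#'   sampling (e.g. `list(mu_lpsi = 0, sigma_lpsi = 1.5)`); used for
#'   prior-sensitivity and exact small-instance checks.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(mu_mean = 0, mu_sd = 1.5, sigma_upper = 5,
                       omega_a = 1, omega_b = 1, fixed = list()) {
  stopifnot(mu_sd > 0, sigma_upper > 0, omega_a > 0, omega_b > 0)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_upper = sigma_upper,
                 omega_a = omega_a, omega_b = omega_b, fixed = fixed),
            class = "prior_spec")
}

#' MCMC settings for [fit_msom()] and [fit_nmixture()]
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burnin Burn-in iterations discarded; proposal adaptation runs
#'   only during burn-in and is frozen afterwards.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param M Superpopulation size for data augmentation; default twice the
#'   number of taxa in the data (minimum +10).  `M` equal to the number of
#'   data taxa disables augmentation of extra taxa.
#' @param select Which covariate blocks get Kuo-Mallick indicator-variable
#'   selection (`V_x ~ Bernoulli(0.5)` priors, one shared indicator per
#'   covariate across all taxa): `"none"` fits the full model.
#' @param store_z Store thinned draws of the latent occupancy matrix
#'   (needed by [corrected_matrices()]).
#' @param target_accept Target acceptance rate for the adaptive
#'   random-walk proposals (within the usual 0.2-0.5 band).
#' @param n_cap Upper bound for latent-abundance enumeration
#'   ([fit_nmixture()] only).
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 3L, n_iter = 20000L, n_burnin = 10000L,
                         thin = 10L, M = NULL,
                         select = c("none", "occupancy", "detection", "both"),
                         store_z = FALSE, target_accept = 0.35,
                         n_cap = 1000L) {
  select <- match.arg(select)
  stopifnot(n_iter > n_burnin, n_chains >= 1, thin >= 1,
            target_accept > 0.1, target_accept < 0.6)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), M = M, select = select,
                 store_z = store_z, target_accept = target_accept,
                 n_cap = as.integer(n_cap)),
            class = "mcmc_control")
}

## Flatten a detection dataset to the slot-level arrays used by the
## samplers.  A "slot" is one sampled (visit, replicate) pair; masked
## replicates never become slots.
prepare_fit_data <- function(data, M) {
  y <- data$y
  n_v <- dim(y)[1]; n_r <- dim(y)[2]; K <- dim(y)[3]
  sampled <- !is.na(y[, , 1, drop = FALSE])[, , 1, drop = TRUE]
  sampled <- matrix(sampled, n_v, n_r)
  if (any(rowSums(sampled) == 0))
    stop("visits with zero sampled replicates are not allowed",
         call. = FALSE)
  idx <- which(sampled, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n_s <- nrow(idx)
  Y <- matrix(0, n_s, K)
  for (s in seq_len(n_s)) Y[s, ] <- y[idx[s, 1], idx[s, 2], ]
  Pd <- dim(data$det_covariates)[3]
  Wdet <- matrix(0, n_s, Pd)
  if (Pd > 0)
    for (s in seq_len(n_s))
      Wdet[s, ] <- data$det_covariates[idx[s, 1], idx[s, 2], ]
  if (anyNA(Wdet))
    stop("detection covariates missing for sampled replicates",
         call. = FALSE)
  Xocc <- data$occ_covariates
  if (anyNA(Xocc))
    stop("occupancy covariates contain missing values", call. = FALSE)
  n_aug <- M - K
  Yaug <- cbind(Y, matrix(0, n_s, n_aug))
  detected_vk <- rowsum((Yaug > 0) * 1L, idx[, 1]) > 0  # n_v x M
  det_any <- colSums(detected_vk) > 0
  list(Y = Yaug, slot_unit = idx[, 1], Xocc = Xocc, Wdet = Wdet,
       n_v = n_v, n_s = n_s, K = K, M = M, n_aug = n_aug,
       detected_vk = detected_vk, det_any = det_any,
       Po = ncol(Xocc), Pd = Pd)
}

## occupancy loglik per taxon given latent z; zero for non-members
occ_loglik_by_taxon <- function(z, psi, w) {
  cl <- colSums(bern_loglik(z, psi))
  cl[w == 0] <- 0
  cl
}

## detection loglik per taxon over occupied slots
det_loglik_by_taxon <- function(Y, P, Zslot) {
  ll <- bern_loglik(Y, P)
  ll[Zslot == 0] <- 0
  colSums(ll)
}

## Robbins-Monro step for log proposal SDs
adapt_ls <- function(ls, accepted, iter, target) {
  step <- 0.25 / sqrt(1 + iter / 50)
  ls + step * (accepted - target)
}

#' Fit a hierarchical multispecies occupancy model by MCMC
#'
#' Fits the four-level hierarchy by Metropolis-within-Gibbs:
#' membership `w_k ~ Bernoulli(Omega)` (data augmentation), latent
#' occupancy `z_ik ~ Bernoulli(w_k * psi_ik)`, detections
#' `y_ijk | z_ik ~ Bernoulli(z_ik * p_ijk)`, with
#' `logit(psi_ik) = lpsi_k + betalpsi_k . x_i` and
#' `logit(p_ijk) = lp_k + betalp_k . v_ij`, and taxon-level intercepts and
#' slopes drawn as random effects from community normal distributions.
#' Latent states are drawn from their exact full conditionals; taxon
#' parameters and hyper-SDs use adaptive random-walk Metropolis (adapted
#' during burn-in only); hyper-means are conjugate; optional Kuo-Mallick
#' indicators give posterior covariate-inclusion probabilities.
#'
#' Convergence is advisory: the fit always returns all chains together
#' with Gelman-Rubin diagnostics (see [summary.msom_fit()]); nothing is
#' silently discarded.
#'
#' @param data A `detection_dataset` in presence-absence mode.
#' @param control An [mcmc_control()].
#' @param prior A [prior_spec()].
#' @param seed Integer seed; chain seeds are derived from it.
#' @return An object of class `msom_fit` with per-chain draw matrices
#'   (`draws`), acceptance rates, covariate inclusion probabilities, and
#'   (optionally) thinned latent `z` draws.
#' @seealso [estimate_gamma()], [gelman_rubin()], [dunn_smyth_residuals()]
#' @export
fit_msom <- function(data, control = mcmc_control(), prior = prior_spec(),
                     seed = NULL) {
  stopifnot(inherits(data, "detection_dataset"))
  if (data$mode != "presence_absence")
    stop("fit_msom() requires presence-absence data; see fit_nmixture()",
         call. = FALSE)
  K <- dim(data$y)[3]
  M <- control$M %||% max(2L * K, K + 10L)
  if (M < K)
    stop("augmentation size M (", M, ") is smaller than the ", K,
         " taxa in the data", call. = FALSE)
  chain_seeds <- derive_seeds(seed, control$n_chains)
  prep <- prepare_fit_data(data, M)
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    set_seed_if(chain_seeds[[ch]])
    run_msom_chain(prep, control, prior)
  })
  out <- structure(list(
    draws = lapply(chains, `[[`, "draws"),
    z_draws = if (control$store_z) lapply(chains, `[[`, "z_draws"),
    accept = lapply(chains, `[[`, "accept"),
    inclusion = average_inclusion(chains),
    taxa = data$taxa, M = M, n_data_taxa = K,
    observed_richness = observed_richness(data),
    data = data, control = control, prior = prior, seed = seed,
    model = "msom"), class = "msom_fit")
  out
}

average_inclusion <- function(chains) {
  inc <- lapply(chains, `[[`, "inclusion")
  if (is.null(inc[[1]])) return(NULL)
  avg <- function(name) {
    vs <- lapply(inc, `[[`, name)
    if (is.null(vs[[1]])) return(NULL)
    Reduce(`+`, vs) / length(vs)
  }
  list(occupancy = avg("occupancy"), detection = avg("detection"))
}

## One MCMC chain; RNG state set by caller.
run_msom_chain <- function(prep, control, prior) {
  M <- prep$M; n_v <- prep$n_v
  Po <- prep$Po; Pd <- prep$Pd
  Xocc <- prep$Xocc; Wdet <- prep$Wdet; Y <- prep$Y
  su <- prep$slot_unit
  fixed <- prior$fixed

  ## --- initial state ------------------------------------------------
  naive_psi <- pmin(pmax(colMeans(prep$detected_vk), 0.05), 0.95)
  lpsi <- qlogis(naive_psi) + rnorm(M, 0, 0.2)
  lp <- rnorm(M, qlogis(0.3), 0.2)
  betalpsi <- matrix(0, M, Po)
  betalp <- matrix(0, M, Pd)
  hy <- list(mu_lpsi = fixed$mu_lpsi %||% mean(lpsi),
             sigma_lpsi = fixed$sigma_lpsi %||%
               max(sd(lpsi), 0.5, na.rm = TRUE),
             mu_lp = fixed$mu_lp %||% mean(lp),
             sigma_lp = fixed$sigma_lp %||% 0.5,
             mu_betalpsi = fixed$mu_betalpsi %||% rep(0, Po),
             sigma_betalpsi = fixed$sigma_betalpsi %||% rep(0.5, Po),
             mu_betalp = fixed$mu_betalp %||% rep(0, Pd),
             sigma_betalp = fixed$sigma_betalp %||% rep(0.5, Pd))
  w <- ifelse(prep$det_any, 1L, rbinom(M, 1L, 0.5))
  omega <- mean(w)
  z <- (prep$detected_vk * 1L) | matrix(rbinom(n_v * M, 1L, 0.3), n_v, M)
  z <- z * rep(w, each = n_v)
  sel_occ <- control$select %in% c("occupancy", "both") && Po > 0
  sel_det <- control$select %in% c("detection", "both") && Pd > 0
  V_occ <- rep(1L, Po); V_det <- rep(1L, Pd)

  ## adaptive proposal log-SDs
  ls <- list(lpsi = rep(log(0.5), M), lp = rep(log(0.5), M),
             betalpsi = matrix(log(0.5), M, Po),
             betalp = matrix(log(0.5), M, Pd),
             sigma = rep(log(0.3), 4))  # lpsi, lp, betalpsi, betalp blocks

  eta_occ <- function() {
    e <- matrix(lpsi, n_v, M, byrow = TRUE)
    if (Po) e <- e + Xocc %*% t(betalpsi * rep(V_occ, each = M))
    e
  }
  eta_det <- function() {
    e <- matrix(lp, prep$n_s, M, byrow = TRUE)
    if (Pd) e <- e + Wdet %*% t(betalp * rep(V_det, each = M))
    e
  }

  n_keep <- (control$n_iter - control$n_burnin) %/% control$thin
  pn <- msom_param_names(prep, Po, Pd)
  draws <- matrix(NA_real_, n_keep, length(pn),
                  dimnames = list(NULL, pn))
  z_store <- if (control$store_z)
    array(NA_integer_, dim = c(n_keep, n_v, M))
  inc_sum_occ <- rep(0, Po); inc_sum_det <- rep(0, Pd); inc_n <- 0
  acc_count <- c(lpsi = 0, lp = 0, betalpsi = 0, betalp = 0, sigma = 0)
  acc_tot <- c(lpsi = 0, lp = 0, betalpsi = 0, betalp = 0, sigma = 0)
  keep_i <- 0L

  for (iter in seq_len(control$n_iter)) {
    adapting <- iter <= control$n_burnin
    psi <- plogis(eta_occ())
    P <- plogis(eta_det())
    logq <- matrix(0, n_v, M)
    rs <- rowsum(log1p(-P), su)
    logq[as.integer(rownames(rs)), ] <- rs

    ## --- w, Omega ---------------------------------------------------
    und <- which(!prep$det_any)
    if (length(und)) {
      pnd <- psi[, und, drop = FALSE] * exp(logq[, und, drop = FALSE]) +
        (1 - psi[, und, drop = FALSE])
      logL <- colSums(log(pnd))
      pw <- 1 / (1 + exp(log1p(-omega) - (log(omega) + logL)))
      pw[omega == 0] <- 0
      w[und] <- rbinom(length(und), 1L, pw)
    }
    omega_post <- update_omega(w, prior$omega_a, prior$omega_b,
                               draw = FALSE)
    omega <- rbeta(1, omega_post[1], omega_post[2])

    ## --- z ----------------------------------------------------------
    q <- exp(logq)
    zp <- psi * q / (psi * q + 1 - psi)
    z <- matrix(rbinom(n_v * M, 1L, as.vector(zp)), n_v, M)
    z[prep$detected_vk] <- 1L
    z[, w == 0] <- 0L
    Zslot <- z[su, , drop = FALSE]

    ## --- taxon occupancy parameters ----------------------------------
    e_occ <- eta_occ()
    ll_cur <- occ_loglik_by_taxon(z, plogis(e_occ), w)
    ## intercepts
    del <- rnorm(M, 0, exp(ls$lpsi))
    ll_prop <- occ_loglik_by_taxon(
      z, plogis(e_occ + matrix(del, n_v, M, byrow = TRUE)), w)
    lr <- (ll_prop - ll_cur) +
      dnorm(lpsi + del, hy$mu_lpsi, hy$sigma_lpsi, log = TRUE) -
      dnorm(lpsi, hy$mu_lpsi, hy$sigma_lpsi, log = TRUE)
    acc <- log(runif(M)) < lr
    lpsi <- lpsi + del * acc
    ll_cur <- ifelse(acc, ll_prop, ll_cur)
    e_occ <- e_occ + matrix(del * acc, n_v, M, byrow = TRUE)
    if (adapting) ls$lpsi <- adapt_ls(ls$lpsi, acc, iter,
                                      control$target_accept)
    acc_count["lpsi"] <- acc_count["lpsi"] + mean(acc)
    acc_tot["lpsi"] <- acc_tot["lpsi"] + 1
    ## slopes
    if (Po) for (pp in seq_len(Po)) {
      if (V_occ[pp] == 0) {
        betalpsi[, pp] <- rnorm(M, hy$mu_betalpsi[pp],
                                hy$sigma_betalpsi[pp])
        next
      }
      del <- rnorm(M, 0, exp(ls$betalpsi[, pp]))
      ll_prop <- occ_loglik_by_taxon(
        z, plogis(e_occ + outer(Xocc[, pp], del)), w)
      lr <- (ll_prop - ll_cur) +
        dnorm(betalpsi[, pp] + del, hy$mu_betalpsi[pp],
              hy$sigma_betalpsi[pp], log = TRUE) -
        dnorm(betalpsi[, pp], hy$mu_betalpsi[pp],
              hy$sigma_betalpsi[pp], log = TRUE)
      acc <- log(runif(M)) < lr
      betalpsi[, pp] <- betalpsi[, pp] + del * acc
      ll_cur <- ifelse(acc, ll_prop, ll_cur)
      e_occ <- e_occ + outer(Xocc[, pp], del * acc)
      if (adapting) ls$betalpsi[, pp] <- adapt_ls(ls$betalpsi[, pp], acc,
                                                  iter,
                                                  control$target_accept)
      acc_count["betalpsi"] <- acc_count["betalpsi"] + mean(acc)
      acc_tot["betalpsi"] <- acc_tot["betalpsi"] + 1
    }
    ## members with no data weight (w = 0): exact prior redraw
    off <- w == 0
    if (any(off)) {
      lpsi[off] <- rnorm(sum(off), hy$mu_lpsi, hy$sigma_lpsi)
      if (Po) for (pp in seq_len(Po))
        betalpsi[off, pp] <- rnorm(sum(off), hy$mu_betalpsi[pp],
                                   hy$sigma_betalpsi[pp])
    }

    ## --- taxon detection parameters ----------------------------------
    e_det <- eta_det()
    lld_cur <- det_loglik_by_taxon(Y, plogis(e_det), Zslot)
    del <- rnorm(M, 0, exp(ls$lp))
    lld_prop <- det_loglik_by_taxon(
      Y, plogis(e_det + matrix(del, prep$n_s, M, byrow = TRUE)), Zslot)
    lr <- (lld_prop - lld_cur) +
      dnorm(lp + del, hy$mu_lp, hy$sigma_lp, log = TRUE) -
      dnorm(lp, hy$mu_lp, hy$sigma_lp, log = TRUE)
    acc <- log(runif(M)) < lr
    lp <- lp + del * acc
    lld_cur <- ifelse(acc, lld_prop, lld_cur)
    e_det <- e_det + matrix(del * acc, prep$n_s, M, byrow = TRUE)
    if (adapting) ls$lp <- adapt_ls(ls$lp, acc, iter,
                                    control$target_accept)
    acc_count["lp"] <- acc_count["lp"] + mean(acc)
    acc_tot["lp"] <- acc_tot["lp"] + 1
    if (Pd) for (pp in seq_len(Pd)) {
      if (V_det[pp] == 0) {
        betalp[, pp] <- rnorm(M, hy$mu_betalp[pp], hy$sigma_betalp[pp])
        next
      }
      del <- rnorm(M, 0, exp(ls$betalp[, pp]))
      lld_prop <- det_loglik_by_taxon(
        Y, plogis(e_det + outer(Wdet[, pp], del)), Zslot)
      lr <- (lld_prop - lld_cur) +
        dnorm(betalp[, pp] + del, hy$mu_betalp[pp], hy$sigma_betalp[pp],
              log = TRUE) -
        dnorm(betalp[, pp], hy$mu_betalp[pp], hy$sigma_betalp[pp],
              log = TRUE)
      acc <- log(runif(M)) < lr
      betalp[, pp] <- betalp[, pp] + del * acc
      lld_cur <- ifelse(acc, lld_prop, lld_cur)
      e_det <- e_det + outer(Wdet[, pp], del * acc)
      if (adapting) ls$betalp[, pp] <- adapt_ls(ls$betalp[, pp], acc,
                                                iter,
                                                control$target_accept)
      acc_count["betalp"] <- acc_count["betalp"] + mean(acc)
      acc_tot["betalp"] <- acc_tot["betalp"] + 1
    }
    ## taxa with zero detection weight: occupied nowhere => prior redraw
    nw <- colSums(Zslot) == 0
    if (any(nw)) {
      lp[nw] <- rnorm(sum(nw), hy$mu_lp, hy$sigma_lp)
      if (Pd) for (pp in seq_len(Pd))
        betalp[nw, pp] <- rnorm(sum(nw), hy$mu_betalp[pp],
                                hy$sigma_betalp[pp])
    }

    ## --- hyperparameters ---------------------------------------------
    hsig_acc <- 0; hsig_n <- 0
    upd_pair <- function(x, mu_name, sigma_name, ls_i) {
      if (is.null(fixed[[mu_name]])) {
        prec <- length(x) / hy[[sigma_name]]^2 + 1 / prior$mu_sd^2
        mn <- (sum(x) / hy[[sigma_name]]^2 + prior$mu_mean / prior$mu_sd^2) /
          prec
        hy[[mu_name]] <<- rnorm(1, mn, sqrt(1 / prec))
      }
      if (is.null(fixed[[sigma_name]])) {
        s_cur <- hy[[sigma_name]]
        s_prop <- exp(log(s_cur) + rnorm(1, 0, exp(ls$sigma[ls_i])))
        if (s_prop < prior$sigma_upper) {
          lr <- sum(dnorm(x, hy[[mu_name]], s_prop, log = TRUE)) -
            sum(dnorm(x, hy[[mu_name]], s_cur, log = TRUE)) +
            log(s_prop) - log(s_cur)
          if (log(runif(1)) < lr) {
            hy[[sigma_name]] <<- s_prop
            hsig_acc <<- hsig_acc + 1
          }
        }
        hsig_n <<- hsig_n + 1
      }
      invisible(NULL)
    }
    upd_pair(lpsi, "mu_lpsi", "sigma_lpsi", 1)
    upd_pair(lp, "mu_lp", "sigma_lp", 2)
    if (Po) for (pp in seq_len(Po)) {
      x <- betalpsi[, pp]
      if (is.null(fixed$mu_betalpsi)) {
        prec <- M / hy$sigma_betalpsi[pp]^2 + 1 / prior$mu_sd^2
        mn <- (sum(x) / hy$sigma_betalpsi[pp]^2 +
                 prior$mu_mean / prior$mu_sd^2) / prec
        hy$mu_betalpsi[pp] <- rnorm(1, mn, sqrt(1 / prec))
      }
      if (is.null(fixed$sigma_betalpsi)) {
        s_cur <- hy$sigma_betalpsi[pp]
        s_prop <- exp(log(s_cur) + rnorm(1, 0, exp(ls$sigma[3])))
        if (s_prop < prior$sigma_upper) {
          lr <- sum(dnorm(x, hy$mu_betalpsi[pp], s_prop, log = TRUE)) -
            sum(dnorm(x, hy$mu_betalpsi[pp], s_cur, log = TRUE)) +
            log(s_prop) - log(s_cur)
          if (log(runif(1)) < lr) {
            hy$sigma_betalpsi[pp] <- s_prop
            hsig_acc <- hsig_acc + 1
          }
        }
        hsig_n <- hsig_n + 1
      }
    }
    if (Pd) for (pp in seq_len(Pd)) {
      x <- betalp[, pp]
      if (is.null(fixed$mu_betalp)) {
        prec <- M / hy$sigma_betalp[pp]^2 + 1 / prior$mu_sd^2
        mn <- (sum(x) / hy$sigma_betalp[pp]^2 +
                 prior$mu_mean / prior$mu_sd^2) / prec
        hy$mu_betalp[pp] <- rnorm(1, mn, sqrt(1 / prec))
      }
      if (is.null(fixed$sigma_betalp)) {
        s_cur <- hy$sigma_betalp[pp]
        s_prop <- exp(log(s_cur) + rnorm(1, 0, exp(ls$sigma[4])))
        if (s_prop < prior$sigma_upper) {
          lr <- sum(dnorm(x, hy$mu_betalp[pp], s_prop, log = TRUE)) -
            sum(dnorm(x, hy$mu_betalp[pp], s_cur, log = TRUE)) +
            log(s_prop) - log(s_cur)
          if (log(runif(1)) < lr) {
            hy$sigma_betalp[pp] <- s_prop
            hsig_acc <- hsig_acc + 1
          }
        }
        hsig_n <- hsig_n + 1
      }
    }
    if (hsig_n > 0) {
      if (adapting)
        ls$sigma <- adapt_ls(ls$sigma, hsig_acc / hsig_n, iter,
                             control$target_accept)
      acc_count["sigma"] <- acc_count["sigma"] + hsig_acc / hsig_n
      acc_tot["sigma"] <- acc_tot["sigma"] + 1
    }

    ## --- Kuo-Mallick indicators --------------------------------------
    if (sel_occ) {
      for (pp in seq_len(Po)) {
        V0 <- V_occ; V0[pp] <- 0L
        e0 <- matrix(lpsi, n_v, M, byrow = TRUE) +
          Xocc %*% t(betalpsi * rep(V0, each = M))
        ll0 <- sum(occ_loglik_by_taxon(z, plogis(e0), w))
        ll1 <- sum(occ_loglik_by_taxon(
          z, plogis(e0 + outer(Xocc[, pp], betalpsi[, pp])), w))
        V_occ[pp] <- rbinom(1L, 1L, 1 / (1 + exp(ll0 - ll1)))
      }
    }
    if (sel_det) {
      for (pp in seq_len(Pd)) {
        V0 <- V_det; V0[pp] <- 0L
        e0 <- matrix(lp, prep$n_s, M, byrow = TRUE) +
          Wdet %*% t(betalp * rep(V0, each = M))
        ll0 <- sum(det_loglik_by_taxon(Y, plogis(e0), Zslot))
        ll1 <- sum(det_loglik_by_taxon(
          Y, plogis(e0 + outer(Wdet[, pp], betalp[, pp])), Zslot))
        V_det[pp] <- rbinom(1L, 1L, 1 / (1 + exp(ll0 - ll1)))
      }
    }

    ## --- store -------------------------------------------------------
    if (!adapting && (iter - control$n_burnin) %% control$thin == 0) {
      keep_i <- keep_i + 1L
      draws[keep_i, ] <- msom_param_vector(hy, omega, w, V_occ, V_det,
                                           lpsi, lp, betalpsi, betalp,
                                           prep, Po, Pd)
      if (control$store_z) z_store[keep_i, , ] <- z
      inc_sum_occ <- inc_sum_occ + V_occ
      inc_sum_det <- inc_sum_det + V_det
      inc_n <- inc_n + 1
    }
  }

  inclusion <- NULL
  if (sel_occ || sel_det)
    inclusion <- list(
      occupancy = if (sel_occ) inc_sum_occ / inc_n,
      detection = if (sel_det) inc_sum_det / inc_n)
  list(draws = draws, z_draws = z_store,
       accept = acc_count / pmax(acc_tot, 1), inclusion = inclusion)
}

msom_param_names <- function(prep, Po, Pd) {
  K <- prep$K
  nm <- c("mu_lpsi", "sigma_lpsi", "mu_lp", "sigma_lp")
  if (Po) nm <- c(nm, paste0("mu_betalpsi[", seq_len(Po), "]"),
                  paste0("sigma_betalpsi[", seq_len(Po), "]"))
  if (Pd) nm <- c(nm, paste0("mu_betalp[", seq_len(Pd), "]"),
                  paste0("sigma_betalp[", seq_len(Pd), "]"))
  nm <- c(nm, "Omega", "gamma")
  if (Po) nm <- c(nm, paste0("V_occ[", seq_len(Po), "]"))
  if (Pd) nm <- c(nm, paste0("V_det[", seq_len(Pd), "]"))
  nm <- c(nm, paste0("lpsi[", seq_len(K), "]"),
          paste0("lp[", seq_len(K), "]"))
  if (Po) nm <- c(nm, paste0("betalpsi[", rep(seq_len(K), Po), ",",
                             rep(seq_len(Po), each = K), "]"))
  if (Pd) nm <- c(nm, paste0("betalp[", rep(seq_len(K), Pd), ",",
                             rep(seq_len(Pd), each = K), "]"))
  nm
}

msom_param_vector <- function(hy, omega, w, V_occ, V_det,
                              lpsi, lp, betalpsi, betalp, prep, Po, Pd) {
  K <- prep$K
  v <- c(hy$mu_lpsi, hy$sigma_lpsi, hy$mu_lp, hy$sigma_lp)
  if (Po) v <- c(v, hy$mu_betalpsi, hy$sigma_betalpsi)
  if (Pd) v <- c(v, hy$mu_betalp, hy$sigma_betalp)
  v <- c(v, omega, sum(w))
  if (Po) v <- c(v, V_occ)
  if (Pd) v <- c(v, V_det)
  v <- c(v, lpsi[seq_len(K)], lp[seq_len(K)])
  if (Po) v <- c(v, as.vector(betalpsi[seq_len(K), , drop = FALSE]))
  if (Pd) v <- c(v, as.vector(betalp[seq_len(K), , drop = FALSE]))
  v
}

#' Extract all post-burn-in draws of one parameter
#' @param fit An `msom_fit`.
#' @param par Parameter name as stored (e.g. `"mu_lpsi"`, `"gamma"`).
#' @param combine Concatenate chains (`TRUE`) or return a list.
#' @return Numeric vector (or list of per-chain vectors).
#' @export
posterior_draws <- function(fit, par, combine = TRUE) {
  stopifnot(inherits(fit, c("msom_fit", "nmix_fit")))
  v <- lapply(fit$draws, function(d) d[, par])
  if (combine) unlist(v, use.names = FALSE) else v
}

#' Posterior distribution of regional richness (gamma diversity)
#'
#' Regional richness under data augmentation is the per-draw sum of the
#' membership indicators `w_k`; observed richness is its hard lower
#' bound in every draw.
#'
#' @param fit An `msom_fit` (or `nmix_fit`).
#' @param prob Credible-interval mass.
#' @return List with the per-draw vector `draws`, `mean`, and `ci`.
#' @export
estimate_gamma <- function(fit, prob = 0.95) {
  g <- posterior_draws(fit, "gamma")
  a <- (1 - prob) / 2
  list(draws = g, mean = mean(g),
       ci = unname(quantile(g, c(a, 1 - a))),
       observed = fit$observed_richness)
}

#' @export
print.msom_fit <- function(x, ...) {
  nk <- nrow(x$draws[[1]])
  cat("Community occupancy fit:", length(x$draws), "chain(s) x", nk,
      "kept draws;", x$n_data_taxa, "data taxa; M =", x$M, "\n")
  g <- estimate_gamma(x)
  cat(sprintf("  observed richness %d; posterior gamma %.1f [%.0f, %.0f]\n",
              x$observed_richness, g$mean, g$ci[1], g$ci[2]))
  if (!is.null(x$inclusion)) {
    if (!is.null(x$inclusion$occupancy))
      cat("  occupancy covariate inclusion:",
          paste(sprintf("%.2f", x$inclusion$occupancy), collapse = " "),
          "\n")
    if (!is.null(x$inclusion$detection))
      cat("  detection covariate inclusion:",
          paste(sprintf("%.2f", x$inclusion$detection), collapse = " "),
          "\n")
  }
  invisible(x)
}

#' Summarize an MCMC fit with convergence diagnostics
#'
#' Computes posterior means, SDs and credible intervals per stored
#' parameter, plus the Gelman-Rubin statistic across chains when at least
#' two chains were run.  Parameters with R-hat >= 1.1 (the conventional
#' cutoff) are flagged in the returned table; constant parameters have
#' `NA` R-hat.
#'
#' @param object An `msom_fit` or `nmix_fit`.
#' @param prob Credible-interval mass.
#' @param ... Unused.
#' @return Data.frame with one row per parameter.
#' @export
summary.msom_fit <- function(object, prob = 0.95, ...) {
  pn <- colnames(object$draws[[1]])
  all_d <- do.call(rbind, object$draws)
  a <- (1 - prob) / 2
  rhat <- rep(NA_real_, length(pn))
  if (length(object$draws) >= 2) {
    rhat <- vapply(pn, function(p)
      gelman_rubin(lapply(object$draws, function(d) d[, p])),
      numeric(1))
  }
  data.frame(parameter = pn,
             mean = colMeans(all_d),
             sd = apply(all_d, 2, sd),
             lower = apply(all_d, 2, quantile, a),
             upper = apply(all_d, 2, quantile, 1 - a),
             rhat = rhat,
             converged = is.na(rhat) | rhat < 1.1,
             row.names = NULL)
}

#' @export
summary.nmix_fit <- summary.msom_fit
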