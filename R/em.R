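# Expectation-maximization fitting of staPAW and its nested model
# families, plus the expected complete-data log-likelihood (ECLL).
#
# The E-step runs forward-backward per track. The M-step introduces the
# within-state turn/weathervane responsibilities as a further latent layer,
# which splits the emission objective into independent blocks (turn
# decision, turn heading mixture, weathervane regression, two Gamma speed
# blocks) that are maximized separately; the transition block is maximized
# with an analytic-gradient quasi-Newton step. Every block keeps its
# previous value if the optimizer fails to improve it, so the data
# log-likelihood is non-decreasing across iterations (generalized EM).

#' Model family specification
#'
#' Determines which parameters are free: `"stapaw"` frees everything;
#' `"hmm"` clamps the sensory transition kernels (baselines stay free);
#' `"dpaw"` is the single-state model with free emission kernels; `"null"`
#' is single-state with every kernel clamped to zero and a single constant
#' turn probability (M = m).
#'
#' @param family one of `"stapaw"`, `"hmm"`, `"dpaw"`, `"null"`.
#' @param Z number of states (forced to 1 for dpaw/null).
#' @param n_basis,n_lag kernel basis configuration.
#' @param opto include stimulus kernels in transitions and turn decisions.
#' @return an object of class `stapaw_spec`.
#' @export
model_spec <- function(family = c("stapaw", "hmm", "dpaw", "null"), Z = 2,
                       n_basis = 4, n_lag = 14, opto = FALSE) {
  family <- match.arg(family)
  if (family %in% c("dpaw", "null")) Z <- 1L
  if (family %in% c("stapaw", "hmm") && Z < 2)
    stop("multi-state families need Z >= 2", call. = FALSE)
  structure(list(
    family = family, Z = as.integer(Z),
    n_basis = n_basis, n_lag = n_lag, opto = opto,
    free_em_kernels = family != "null",
    free_trans_kernels = family == "stapaw",
    tie_Mm = family == "null"),
    class = "stapaw_spec")
}

#' @export
print.stapaw_spec <- function(x, ...) {
  cat(sprintf("<stapaw model spec: family %s, Z = %d, basis %d/%d%s>\n",
              x$family, x$Z, x$n_basis, x$n_lag,
              if (x$opto) ", opto" else ""))
  invisible(x)
}

# ---- pooled data ----------------------------------------------------------

# Precompute designs for every track and stacked matrices used by the
# M-step. Standardization constants come from `params` and stay fixed.
pool_designs <- function(dataset, params) {
  designs <- lapply(dataset$tracks, stapaw_design, params = params)
  stack <- function(f) do.call(rbind, lapply(designs, `[[`, f))
  has_O <- all(vapply(designs, function(d) !is.null(d$X_O), logical(1)))
  list(designs = designs,
       X_C = stack("X_C"), X_h = stack("X_h"), X_dCp = stack("X_dCp"),
       X_O = if (has_O) stack("X_O") else NULL,
       dtheta = unlist(lapply(designs, `[[`, "dtheta")),
       dr = unlist(lapply(designs, `[[`, "dr")),
       n = vapply(designs, `[[`, integer(1), "n"))
}

# E-step over all tracks: per-track decodes plus stacked gamma/xi.
e_step <- function(params, pooled) {
  decodes <- lapply(pooled$designs, function(d) {
    logB <- emission_loglik_design(params, d)
    A <- transition_array(params, d)
    fb_raw(logB, aperm(A, c(2, 3, 1)), params$init_dist)
  })
  gamma <- do.call(rbind, lapply(decodes, `[[`, "gamma"))
  xi <- do.call(rbind, lapply(decodes, `[[`, "xi"))
  # stacked design rows matching xi rows (t >= 2 within each track)
  list(decodes = decodes, gamma = gamma, xi = xi,
       loglik = sum(vapply(decodes, `[[`, numeric(1), "loglik")))
}

trans_rows <- function(pooled, what) {
  X <- pooled[[what]]
  if (is.null(X)) return(NULL)
  keep <- unlist(lapply(pooled$n, function(n) c(FALSE, rep(TRUE, n - 1))))
  X[keep, , drop = FALSE]
}

#' Expected complete-data log-likelihood
#'
#' The EM surrogate objective: posterior-weighted initial, transition and
#' emission log-probabilities, summed over tracks.
#'
#' @param params a `stapaw_params` object (the point of evaluation).
#' @param decodes list of `stapaw_decode` objects, one per track, computed
#'   under the reference (old) parameters.
#' @param dataset the `stapaw_dataset` the decodes belong to.
#' @return scalar ECLL value.
#' @export
ecll <- function(params, decodes, dataset) {
  stopifnot(length(decodes) == length(dataset$tracks))
  total <- 0
  for (k in seq_along(decodes)) {
    d <- stapaw_design(dataset$tracks[[k]], params)
    dec <- decodes[[k]]
    if (nrow(dec$gamma) != d$n)
      stop("decode/track length mismatch", call. = FALSE)
    logB <- emission_loglik_design(params, d)
    total <- total + sum(dec$gamma * logB) +
      sum(dec$gamma[1, ] * log(params$init_dist))
    if (params$Z > 1 && d$n > 1) {
      A <- transition_array(params, d)
      lA <- log(pmax(A[-1, , , drop = FALSE], 1e-300))
      dim(lA) <- c(d$n - 1, params$Z^2)
      total <- total + sum(dec$xi * lA)
    }
  }
  total
}

# ---- M-step blocks --------------------------------------------------------

opt_block <- function(par, fn, gr = NULL, maxit = 60) {
  f0 <- fn(par)
  res <- tryCatch(
    stats::optim(par, fn, gr = gr, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$par)) || res$value > f0) {
    list(par = par, improved = FALSE)
  } else list(par = res$par, improved = TRUE)
}

# turn-decision block: minimize -[sum w1 log p + w0 log(1 - p)]
update_turn_decision <- function(em, spec, pooled, w1, w0) {
  use_O <- spec$opto && !is.null(pooled$X_O) && !is.null(em$k_O)
  nb <- length(em$k_C)
  eta_of <- function(kC, kh, kO) {
    eta <- drop(pooled$X_C %*% kC) + drop(pooled$X_h %*% kh)
    if (use_O) eta <- eta + drop(pooled$X_O %*% kO)
    eta
  }
  nll <- function(M, m, eta) {
    p <- m + (M - m) * stats::plogis(-eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(w1 * log(p) + w0 * log1p(-p))
  }
  if (spec$tie_Mm) {
    # constant turn probability
    p <- sum(w1) / (sum(w1) + sum(w0))
    p <- min(max(p, 1e-6), 1 - 1e-6)
    em$M <- p; em$m <- p
    em$k_C <- rep(0, nb); em$k_h <- rep(0, nb)
    if (!is.null(em$k_O)) em$k_O <- rep(0, nb)
    return(em)
  }
  if (spec$free_em_kernels) {
    unpack <- function(v) {
      M <- stats::plogis(v[1]); m <- M * stats::plogis(v[2])
      kC <- v[3:(2 + nb)]; kh <- v[(3 + nb):(2 + 2 * nb)]
      kO <- if (use_O) v[(3 + 2 * nb):(2 + 3 * nb)] else NULL
      list(M = M, m = m, kC = kC, kh = kh, kO = kO)
    }
    par0 <- c(stats::qlogis(min(max(em$M, 1e-6), 1 - 1e-6)),
              stats::qlogis(min(max(em$m / em$M, 1e-6), 1 - 1e-6)),
              em$k_C, em$k_h, if (use_O) em$k_O)
    fn <- function(v) {
      u <- unpack(v)
      nll(u$M, u$m, eta_of(u$kC, u$kh, u$kO))
    }
    grad <- function(v) {
      u <- unpack(v)
      s <- stats::plogis(-eta_of(u$kC, u$kh, u$kO))
      p <- u$m + (u$M - u$m) * s
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      r <- w1 / p - w0 / (1 - p)
      sm <- stats::plogis(v[2])
      dp_duM <- (1 - u$M) * p
      dp_dum <- u$m * (1 - sm) * (1 - s)
      dp_deta <- -(u$M - u$m) * s * (1 - s)
      g <- c(sum(r * dp_duM), sum(r * dp_dum),
             drop(crossprod(pooled$X_C, r * dp_deta)),
             drop(crossprod(pooled$X_h, r * dp_deta)),
             if (use_O) drop(crossprod(pooled$X_O, r * dp_deta)))
      -g
    }
    res <- opt_block(par0, fn, gr = grad, maxit = 40)
    u <- unpack(res$par)
    em$M <- u$M; em$m <- u$m; em$k_C <- u$kC; em$k_h <- u$kh
    if (use_O) em$k_O <- u$kO
  } else {
    eta <- eta_of(em$k_C, em$k_h, em$k_O)
    par0 <- c(stats::qlogis(min(max(em$M, 1e-6), 1 - 1e-6)),
              stats::qlogis(min(max(em$m / em$M, 1e-6), 1 - 1e-6)))
    fn <- function(v) {
      M <- stats::plogis(v[1]); m <- M * stats::plogis(v[2])
      nll(M, m, eta)
    }
    res <- opt_block(par0, fn)
    em$M <- stats::plogis(res$par[1])
    em$m <- em$M * stats::plogis(res$par[2])
  }
  em
}

# turn-heading block: uniform/von Mises mixture around pi, weights w1
update_turn_heading <- function(em, pooled, w1) {
  dth <- pooled$dtheta
  fn <- function(v) {
    a <- stats::plogis(v[1]); k <- exp(v[2])
    if (!is.finite(k) || k > 500) return(1e10)
    -sum(w1 * log(a / (2 * pi) + (1 - a) * dvonmises(dth, pi, k)))
  }
  # the uniform weight and the concentration form a ridge with local
  # optima; multi-start from the current value and generic mixtures
  starts <- list(
    c(stats::qlogis(min(max(em$alpha, 1e-4), 1 - 1e-4)), log(em$kappa_turn)),
    c(stats::qlogis(0.15), log(2.5)),
    c(stats::qlogis(0.5), log(1)),
    c(stats::qlogis(0.85), log(8)))
  best <- NULL
  for (par0 in starts) {
    res <- opt_block(par0, fn, maxit = 25)
    val <- fn(res$par)
    if (is.null(best) || val < best$val) best <- list(par = res$par, val = val)
  }
  em$alpha <- stats::plogis(best$par[1])
  em$kappa_turn <- exp(best$par[2])
  em
}

# weathervane block: von Mises regression of dtheta on filtered dCp
update_weathervane <- function(em, spec, pooled, w0) {
  dth <- pooled$dtheta
  nb <- length(em$k_dCp)
  if (spec$free_em_kernels) {
    fn <- function(v) {
      k <- exp(v[1]); if (!is.finite(k) || k > 500) return(1e10)
      mu <- -drop(pooled$X_dCp %*% v[-1])
      -sum(w0 * (k * (cos(dth - mu) - 1) -
                   log(besselI(k, 0, expon.scaled = TRUE))))
    }
    grad <- function(v) {
      k <- exp(v[1]); if (!is.finite(k) || k > 500) return(rep(0, length(v)))
      delta <- dth + drop(pooled$X_dCp %*% v[-1])  # dth - mu
      Ak <- besselI(k, 1, expon.scaled = TRUE) /
        besselI(k, 0, expon.scaled = TRUE)
      c(-k * sum(w0 * (cos(delta) - Ak)),
        k * drop(crossprod(pooled$X_dCp, w0 * sin(delta))))
    }
    par0 <- c(log(em$kappa_wv), em$k_dCp)
    res <- opt_block(par0, fn, gr = grad, maxit = 50)
    em$kappa_wv <- exp(res$par[1])
    em$k_dCp <- res$par[-1]
  } else {
    fn <- function(v) {
      k <- exp(v[1]); if (!is.finite(k) || k > 500) return(1e10)
      -sum(w0 * (k * (cos(dth) - 1) -
                   log(besselI(k, 0, expon.scaled = TRUE))))
    }
    res <- opt_block(log(em$kappa_wv), fn, maxit = 30)
    em$kappa_wv <- exp(res$par[1])
    em$k_dCp <- rep(0, nb)
  }
  em
}

# weighted Gamma MLE (shape/scale), Newton on the shape equation
weighted_gamma_mle <- function(x, w, fallback) {
  sw <- sum(w)
  if (sw < 10) return(fallback)
  mu <- sum(w * x) / sw
  ml <- sum(w * log(x)) / sw
  s <- log(mu) - ml
  if (!is.finite(s) || s <= 0) return(fallback)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:25) {
    a_new <- a - (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    if (!is.finite(a_new) || a_new <= 0) break
    if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
    a <- a_new
  }
  if (!is.finite(a) || a <= 0) return(fallback)
  c(a, mu / a)
}

update_emission <- function(params, z, spec, pooled, gamma_z) {
  em <- params$emissions[[z]]
  cm <- emission_components(params, z, pooled)
  a <- log(cm$p) + cm$l_tr
  b <- log1p(-cm$p) + cm$l_wv
  mx <- pmax(a, b)
  r1 <- exp(a - mx) / (exp(a - mx) + exp(b - mx))
  w1 <- gamma_z * r1
  w0 <- gamma_z - w1
  em <- update_turn_decision(em, spec, pooled, w1, w0)
  em <- update_turn_heading(em, pooled, w1)
  em <- update_weathervane(em, spec, pooled, w0)
  em$gamma_turn <- weighted_gamma_mle(pooled$dr, w1, em$gamma_turn)
  em$gamma_run <- weighted_gamma_mle(pooled$dr, w0, em$gamma_run)
  em
}

# transition block with analytic gradient
update_transition <- function(params, spec, pooled, es) {
  Z <- params$Z
  if (Z == 1) return(params$transition)
  tr <- params$transition
  X <- trans_rows(pooled, "X_C")
  XO <- if (spec$opto) trans_rows(pooled, "X_O") else NULL
  use_O <- spec$opto && !is.null(XO)
  xi <- es$xi  # stacked, columns i + Z*(j-1)
  nb <- params$basis$n_basis
  pairs <- list()
  for (i in seq_len(Z)) for (j in seq_len(Z)) if (i != j)
    pairs[[length(pairs) + 1]] <- c(i, j)

  pack <- function(tr) {
    v <- tr$baseline
    if (spec$free_trans_kernels)
      for (p in pairs) v <- c(v, tr$kernels[[p[1]]][[p[2]]])
    if (use_O)
      for (p in pairs) v <- c(v, tr$opto[[p[1]]][[p[2]]])
    v
  }
  unpack <- function(v) {
    out <- tr
    out$baseline <- v[seq_len(Z)]
    idx <- Z
    if (spec$free_trans_kernels)
      for (p in pairs) {
        out$kernels[[p[1]]][[p[2]]] <- v[idx + seq_len(nb)]
        idx <- idx + nb
      }
    if (use_O)
      for (p in pairs) {
        out$opto[[p[1]]][[p[2]]] <- v[idx + seq_len(nb)]
        idx <- idx + nb
      }
    out
  }
  # per-row logits for row-state i: N x Z
  logits_for <- function(trv, i) {
    L <- matrix(0, nrow(X), Z)
    L[, i] <- trv$baseline[i]
    for (j in seq_len(Z)) {
      if (i == j) next
      L[, j] <- drop(X %*% trv$kernels[[i]][[j]])
      if (use_O) {
        o <- trv$opto[[i]][[j]]
        if (!is.null(o)) L[, j] <- L[, j] + drop(XO %*% o)
      }
    }
    L
  }
  xicol <- function(i, j) xi[, i + Z * (j - 1)]
  fn <- function(v) {
    trv <- unpack(v)
    val <- 0
    for (i in seq_len(Z)) {
      L <- logits_for(trv, i)
      mx <- row_max(L)
      lse <- mx + log(rowSums(exp(L - mx)))
      for (j in seq_len(Z)) val <- val + sum(xicol(i, j) * (L[, j] - lse))
    }
    -val
  }
  gr <- function(v) {
    trv <- unpack(v)
    gb <- numeric(Z)
    gk <- list(); go <- list()
    for (i in seq_len(Z)) {
      L <- logits_for(trv, i)
      mx <- row_max(L)
      E <- exp(L - mx)
      A <- E / rowSums(E)
      gfrom <- rowSums(sapply(seq_len(Z), function(j) xicol(i, j)))
      for (j in seq_len(Z)) {
        resid <- xicol(i, j) - gfrom * A[, j]
        if (i == j) {
          gb[i] <- gb[i] + sum(resid)
        } else {
          if (spec$free_trans_kernels)
            gk[[paste(i, j)]] <- drop(crossprod(X, resid))
          if (use_O)
            go[[paste(i, j)]] <- drop(crossprod(XO, resid))
        }
      }
    }
    g <- gb
    if (spec$free_trans_kernels)
      for (p in pairs) g <- c(g, gk[[paste(p[1], p[2])]])
    if (use_O)
      for (p in pairs) g <- c(g, go[[paste(p[1], p[2])]])
    -g
  }
  res <- opt_block(pack(tr), fn, gr = gr, maxit = 40)
  unpack(res$par)
}

#' One M-step of the EM algorithm
#'
#' Updates all free parameter blocks given posterior decodes; clamped
#' blocks (per the model spec) are left at zero. The ECLL does not
#' decrease: any block whose optimizer fails to improve keeps its previous
#' value.
#'
#' @param dataset a `stapaw_dataset`.
#' @param decodes per-track `stapaw_decode` list from the E-step.
#' @param spec a [model_spec()].
#' @param params current parameters.
#' @return updated `stapaw_params`.
#' @export
m_step <- function(dataset, decodes, spec, params) {
  pooled <- pool_designs(dataset, params)
  es <- list(decodes = decodes,
             gamma = do.call(rbind, lapply(decodes, `[[`, "gamma")),
             xi = do.call(rbind, lapply(decodes, `[[`, "xi")))
  m_step_pooled(params, spec, pooled, es)
}

m_step_pooled <- function(params, spec, pooled, es) {
  # pooled design doubles as an emission "design" (same field names)
  pooled_design <- list(X_C = pooled$X_C, X_h = pooled$X_h,
                        X_dCp = pooled$X_dCp, X_O = pooled$X_O,
                        dtheta = pooled$dtheta, dr = pooled$dr,
                        n = sum(pooled$n))
  for (z in seq_len(params$Z))
    params$emissions[[z]] <- update_emission(params, z, spec, pooled_design,
                                             es$gamma[, z])
  params$transition <- update_transition(params, spec, pooled, es)
  if (params$Z > 1) {
    g1 <- do.call(rbind, lapply(es$decodes, function(d) d$gamma[1, ]))
    pi_new <- colMeans(g1)
    params$init_dist <- pi_new / sum(pi_new)
  }
  params
}

# note: update_emission() consumes the pooled emission design via the
# emission_components() path, which expects $X_C etc on `design`.

#' Fit a staPAW-family model by EM
#'
#' Alternates forward-backward E-steps with blockwise constrained M-steps
#' until the data log-likelihood changes by less than `tol` or `max_iters`
#' is reached.
#'
#' @param dataset a `stapaw_dataset` with sensory series attached.
#' @param spec a [model_spec()].
#' @param init optional initial `stapaw_params`; defaults to
#'   [stapaw_init()] with the given seed.
#' @param max_iters maximum EM iterations (default 100).
#' @param tol absolute log-likelihood tolerance; default `1e-4` per 1000
#'   data steps.
#' @param seed seed for the default initialization.
#' @param verbose print per-iteration log-likelihoods.
#' @return an object of class `stapaw_fit`: list with `params`,
#'   `loglik_history`, `converged`, `n_iters`, `seed`, `spec`.
#' @export
em_fit <- function(dataset, spec, init = NULL, max_iters = 100, tol = NULL,
                   seed = 0, verbose = FALSE) {
  stopifnot(inherits(dataset, "stapaw_dataset"))
  n_steps <- dataset_steps(dataset)
  if (is.null(tol)) tol <- 1e-4 * n_steps / 1000
  if (is.null(init)) init <- stapaw_init(dataset, spec, seed = seed)
  params <- init
  pooled <- pool_designs(dataset, params)
  history <- numeric(0)
  converged <- FALSE
  last_ll <- -Inf
  for (it in seq_len(max_iters)) {
    es <- e_step(params, pooled)
    if (!is.finite(es$loglik)) {
      warning("non-finite log-likelihood; stopping at last finite parameters")
      break
    }
    history <- c(history, es$loglik)
    if (verbose)
      message(sprintf("EM iter %3d: loglik %.4f", it, es$loglik))
    if (it > 1 && abs(es$loglik - last_ll) < tol) {
      converged <- TRUE
      break
    }
    last_ll <- es$loglik
    params <- m_step_pooled(params, spec, pooled, es)
  }
  fit <- structure(list(params = params, loglik_history = history,
                        converged = converged, n_iters = length(history),
                        seed = seed, spec = spec),
                   class = "stapaw_fit")
  if (params$Z > 1) fit <- order_fit_states(fit, dataset)
  fit
}

#' @export
print.stapaw_fit <- function(x, ...) {
  cat(sprintf(
    "<stapaw fit: family %s, Z = %d, %d EM iterations, loglik %.3f%s>\n",
    x$spec$family, x$params$Z, x$n_iters,
    utils::tail(x$loglik_history, 1),
    if (x$converged) ", converged" else ""))
  invisible(x)
}

# Deterministic state identity: order states by their posterior-weighted
# mean turn probability, so state 1 is steer-enriched (S) and the last
# state is turn-enriched (T). Resolves label switching.
order_fit_states <- function(fit, dataset) {
  params <- fit$params
  pooled <- pool_designs(dataset, params)
  es <- e_step(params, pooled)
  pooled_design <- list(X_C = pooled$X_C, X_h = pooled$X_h,
                        X_dCp = pooled$X_dCp, X_O = pooled$X_O,
                        dtheta = pooled$dtheta, dr = pooled$dr,
                        n = sum(pooled$n))
  mean_p <- vapply(seq_len(params$Z), function(z) {
    p <- turn_prob_series(params$emissions[[z]], pooled_design)
    sum(es$gamma[, z] * p) / sum(es$gamma[, z])
  }, numeric(1))
  perm <- order(mean_p)
  fit$params <- permute_states(params, perm)
  fit
}

permute_states <- function(params, perm) {
  Z <- params$Z
  if (identical(perm, seq_len(Z))) return(params)
  tr <- params$transition
  new_k <- tr$kernels
  new_o <- tr$opto
  for (i in seq_len(Z)) for (j in seq_len(Z)) {
    if (!is.null(tr$kernels)) new_k[[i]][[j]] <-
        if (i == j) NULL else tr$kernels[[perm[i]]][[perm[j]]]
    if (!is.null(tr$opto)) new_o[[i]][[j]] <-
        if (i == j) NULL else tr$opto[[perm[i]]][[perm[j]]]
  }
  params$emissions <- params$emissions[perm]
  params$transition <- transition_params(Z, tr$baseline[perm], new_k, new_o)
  params$init_dist <- params$init_dist[perm]
  params
}

#' Align estimated states to reference labels
#'
#' Searches all state permutations for the one maximizing stepwise
#' agreement with a reference labeling (feasible for the small state
#' counts used here).
#'
#' @param ref integer reference state sequence.
#' @param est integer estimated state sequence (same length).
#' @param Z number of states.
#' @return list with `perm` (permutation applied to `est`) and `accuracy`.
#' @export
align_states <- function(ref, est, Z = max(ref, est)) {
  stopifnot(length(ref) == length(est))
  perms <- perms_of(Z)
  best <- NULL; best_acc <- -1
  for (p in perms) {
    acc <- mean(p[est] == ref)
    if (acc > best_acc) { best_acc <- acc; best <- p }
  }
  list(perm = best, accuracy = best_acc, aligned = best[est])
}

perms_of <- function(Z) {
  if (Z == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0) { out[[length(out) + 1]] <<- prefix; return() }
    for (r in rest) rec(c(prefix, r), setdiff(rest, r))
  }
  rec(integer(0), seq_len(Z))
  out
}
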