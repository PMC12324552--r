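# EM initialization: fit the single-state (dPAW) model first, then
# replicate it across states with seeded perturbations.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

zero_kernel_matrix <- function(Z, nb) {
  lapply(seq_len(Z), function(i)
    lapply(seq_len(Z), function(j) if (i == j) NULL else rep(0, nb)))
}

# Moment-based single-state starting point.
base_init_params <- function(dataset, spec) {
  basis <- stapaw_basis(spec$n_basis, spec$n_lag)
  Cs <- unlist(lapply(dataset$tracks, `[[`, "C"))
  dCps <- unlist(lapply(dataset$tracks, `[[`, "dCp"))
  dr <- pmax(unlist(lapply(dataset$tracks, `[[`, "dr")), DR_FLOOR)
  std <- list(C = standardize_constants(Cs),
              dCp = standardize_constants(dCps))
  mu <- mean(dr); v <- stats::var(dr)
  a <- max(mu^2 / max(v, 1e-12), 0.2); b <- mu / a
  nb <- basis$n_basis
  kO <- if (spec$opto) rep(0, nb) else NULL
  em <- emission_params(M = 0.3, m = 0.02, alpha = 0.1,
                        kappa_turn = 1, kappa_wv = 5,
                        k_C = rep(0, nb), k_h = rep(0, nb),
                        k_dCp = rep(0, nb),
                        gamma_turn = c(a, b * 0.6), gamma_run = c(a, b),
                        k_O = kO)
  stapaw_params(Z = 1, dt = dataset$dt, basis = basis, emissions = list(em),
                transition = transition_params(1, baseline = 0),
                init_dist = 1, standardize = std)
}

#' Initialize EM from a single-state fit
#'
#' Fits the stateless model to the dataset, replicates its emission block
#' across the requested number of states, and applies seeded perturbations
#' to kernels, baselines and (mildly) emission scalars so that the states
#' can differentiate. With Z = 1 the single-state estimate is returned
#' unperturbed.
#'
#' @param dataset a `stapaw_dataset`.
#' @param spec a [model_spec()].
#' @param seed integer seed controlling the perturbation.
#' @param dpaw_iters EM iterations for the single-state pre-fit.
#' @return a `stapaw_params` starting point.
#' @export
stapaw_init <- function(dataset, spec, seed = 0, dpaw_iters = 10) {
  core <- init_core(dataset, spec, seed = seed, dpaw_iters = dpaw_iters)
  if (spec$Z == 1) return(core)
  perturb_init(core, spec, seed)
}

# Shared initialization core: the single-state fit, and for Z > 1 the
# turn-intensity segmentation plus one supervised M-step from its hard
# labels. Computed once and perturbed per initialization seed.
init_core <- function(dataset, spec, seed = 0, dpaw_iters = 10) {
  spec1 <- model_spec(family = if (spec$family == "null") "null" else "dpaw",
                      n_basis = spec$n_basis, n_lag = spec$n_lag,
                      opto = spec$opto)
  base <- base_init_params(dataset, spec1)
  fit1 <- em_fit(dataset, spec1, init = base, max_iters = dpaw_iters,
                 seed = seed)
  p1 <- fit1$params
  if (spec$Z == 1) return(p1)

  Z <- spec$Z
  nb <- p1$basis$n_basis

  # Replicating the single-state fit and hoping EM differentiates the
  # copies tends to end in local optima that split steps by the
  # turn/weathervane strategy rather than by persistent state. Instead,
  # segment steps by their local turning intensity and local speed
  # (clustered into Z levels) and take one supervised M-step from those
  # hard labels.
  labels <- turn_intensity_labels(dataset, Z)
  start <- stapaw_params(
    Z = Z, dt = p1$dt, basis = p1$basis,
    emissions = replicate(Z, p1$emissions[[1]], simplify = FALSE),
    transition = transition_params(
      Z, baseline = rep(2, Z),
      kernels = zero_kernel_matrix(Z, nb),
      opto = if (spec$opto) zero_kernel_matrix(Z, nb) else NULL),
    init_dist = rep(1 / Z, Z), standardize = p1$standardize)
  es <- hard_label_estep(labels, Z)
  pooled <- pool_designs(dataset, start)
  m_step_pooled(start, spec, pooled, es)
}

# Seeded perturbation of the shared core, with the kernel-dictionary
# variants cycled by seed.
perturb_init <- function(start, spec, seed) {
  Z <- spec$Z
  nb <- start$basis$n_basis
  with_seed(sub_seed(seed, 1L), {
    start$emissions <- lapply(start$emissions, function(em) {
      jit <- function(x, scale = 0.05)
        x * exp(scale * stats::rnorm(length(x)))
      em$kappa_turn <- jit(em$kappa_turn)
      em$kappa_wv <- jit(em$kappa_wv)
      em$gamma_turn <- jit(em$gamma_turn)
      em$gamma_run <- jit(em$gamma_run)
      em$k_C <- em$k_C + 0.1 * stats::rnorm(nb) * (1 + abs(em$k_C))
      em$k_h <- em$k_h + 0.1 * stats::rnorm(nb) * (1 + abs(em$k_h))
      em$k_dCp <- em$k_dCp + 0.1 * stats::rnorm(nb) * (1 + abs(em$k_dCp))
      if (!is.null(em$k_O)) em$k_O <- em$k_O + 0.1 * stats::rnorm(nb)
      em
    })
    if (spec$free_trans_kernels) {
      # The label-supervised kernel estimate is strongly attenuated by
      # boundary noise, and EM started from small kernels can settle in a
      # solution where sensory-driven transitions are absorbed into the
      # baselines. Different initializations therefore seed the kernels
      # with different members of a small dictionary of smooth zero-sum
      # trend-detector patterns (both signs) plus the supervised estimate;
      # the training likelihood arbitrates.
      patt <- trend_pattern(start$basis)
      variant <- seed %% 4L
      for (i in seq_len(Z)) for (j in seq_len(Z)) if (i != j) {
        k0 <- start$transition$kernels[[i]][[j]]
        sgn <- if (i < j) 1 else -1
        k0 <- switch(as.character(variant),
                     "0" = k0,
                     "1" = 20 * sgn * patt,
                     "2" = -20 * sgn * patt,
                     "3" = 8 * stats::rnorm(nb))
        start$transition$kernels[[i]][[j]] <-
          k0 + 0.1 * stats::rnorm(nb) * (1 + abs(k0))
      }
    }
    start$transition$baseline <- start$transition$baseline +
      0.1 * stats::rnorm(Z)
    start
  })
}

# Per-track hard state labels from the smoothed turn-rate profile:
# fraction of supra-threshold |dtheta| steps in a centered ~5 s window,
# clustered into Z levels (jointly with a smoothed speed profile for
# Z > 2); label 1 is the least turn-intense cluster.
turn_intensity_labels <- function(dataset, Z, window = 15,
                                  threshold = 50 * pi / 180) {
  feats <- lapply(dataset$tracks, function(tr) {
    sm <- function(x) {
      y <- stats::filter(x, rep(1 / window, window), sides = 2)
      y <- as.numeric(y)
      y[!is.finite(y)] <- mean(x)
      y
    }
    cbind(sm(as.numeric(abs(tr$dtheta) > threshold)), sm(tr$dr))
  })
  X <- do.call(rbind, feats)
  X2 <- scale(X)
  km <- with_seed(1L, stats::kmeans(X2, centers = Z, nstart = 5))
  ord <- order(tapply(X[, 1], km$cluster, mean))
  relabel <- match(seq_len(Z), ord)
  labels <- relabel[km$cluster]
  n <- vapply(dataset$tracks, track_length, integer(1))
  split(labels, rep(seq_along(n), n))
}

# one-hot gamma/xi pseudo-decodes from hard labels
hard_label_estep <- function(labels, Z) {
  decodes <- lapply(labels, function(z) {
    Tn <- length(z)
    gamma <- matrix(0, Tn, Z)
    gamma[cbind(seq_len(Tn), z)] <- 1
    xi <- matrix(0, max(Tn - 1, 0), Z * Z)
    if (Tn > 1)
      xi[cbind(seq_len(Tn - 1), z[-Tn] + Z * (z[-1] - 1))] <- 1
    structure(list(gamma = gamma, xi = xi, loglik = NA_real_),
              class = "stapaw_decode")
  })
  list(decodes = decodes,
       gamma = do.call(rbind, lapply(decodes, `[[`, "gamma")),
       xi = do.call(rbind, lapply(decodes, `[[`, "xi")))
}


# normalized zero-sum first-derivative-like pattern in the basis span,
# used to seed transition-kernel initializations
trend_pattern <- function(basis) {
  coef <- numeric(basis$n_basis)
  coef[1] <- 1
  if (basis$n_basis >= 2) coef[2] <- -0.5
  if (basis$n_basis >= 3) coef[3] <- -0.5
  s <- colSums(basis$Phi)
  coef <- coef - s * sum(s * coef) / sum(s * s)
  coef / max(abs(drop(basis$Phi %*% coef)))
}


#' Generate a family of EM initializations
#'
#' Computes the shared initialization core (single-state fit plus
#' supervised segmentation step) once and returns one perturbed variant
#' per seed, cycling through the transition-kernel dictionary.
#'
#' @param dataset a `stapaw_dataset`.
#' @param spec a [model_spec()].
#' @param seeds integer vector of initialization seeds.
#' @param dpaw_iters EM iterations for the single-state pre-fit.
#' @return list of `stapaw_params` starting points.
#' @export
stapaw_inits <- function(dataset, spec, seeds, dpaw_iters = 10) {
  core <- init_core(dataset, spec, seed = seeds[1], dpaw_iters = dpaw_iters)
  if (spec$Z == 1) return(replicate(length(seeds), core, simplify = FALSE))
  lapply(seeds, function(s) perturb_init(core, spec, s))
}
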