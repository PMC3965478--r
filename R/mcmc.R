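# Posterior inference over genotypes, mixture weights, mass and nuisance
# parameters by Metropolis-within-Gibbs MCMC. Each contributor's per-locus
# allele pair is redrawn from its exact full conditional (enumerated over
# the pair support); mixture weights take a logit-simplex random walk; mass
# (per locus), stutter and variance scale take lognormal / logit random
# walks. Discrete enumeration makes small cases exactly checkable against
# brute force.

#' MCMC inference settings
#'
#' @param n_contributors assumed contributor count K (>= 1); the contributor
#'   number is user-supplied, not inferred (see
#'   [suggest_contributor_count()])
#' @param iterations total MCMC sweeps
#' @param burn_in sweeps discarded before recording (must be < iterations)
#' @param seed integer seed; identical seeds give identical results
#' @param theta co-ancestry coefficient for the genotype priors
#' @param population population label in the frequency table
#' @param assumed optional list of [contributor_profile()] held fixed at
#'   their known pairs (pinned to the first slots)
#' @param fix_weights optional weight vector held fixed (no weight updates)
#' @param fix_mass optional per-locus mass held fixed
#' @param sample_stutter,sample_variance,sample_degradation toggle nuisance
#'   parameter updates
#' @return object of class `inference_settings`
#' @export
inference_settings <- function(n_contributors, iterations = 20000,
                               burn_in = 5000, seed = 1, theta = 0.01,
                               population = NULL, assumed = NULL,
                               fix_weights = NULL, fix_mass = NULL,
                               sample_stutter = TRUE, sample_variance = TRUE,
                               sample_degradation = FALSE) {
  if (n_contributors < 1) stop_input("n_contributors must be >= 1")
  if (burn_in >= iterations) stop_input("burn_in must be < iterations")
  if (inherits(assumed, "contributor_profile")) assumed <- list(assumed)
  if (!is.null(assumed) && length(assumed) > n_contributors) {
    stop_input("more assumed contributors than n_contributors")
  }
  check_theta(theta)
  structure(list(n_contributors = n_contributors, iterations = iterations,
                 burn_in = burn_in, seed = seed, theta = theta,
                 population = population, assumed = assumed,
                 fix_weights = fix_weights, fix_mass = fix_mass,
                 sample_stutter = sample_stutter,
                 sample_variance = sample_variance,
                 sample_degradation = sample_degradation),
            class = "inference_settings")
}

#' Suggest a contributor count from allele counts
#'
#' Half the maximum number of distinct peaks at any locus, rounded up: the
#' minimum contributor number that can explain the evidence without shared
#' alleles.
#'
#' @param peaks a [peak_table()]
#' @return integer suggestion
#' @export
suggest_contributor_count <- function(peaks) {
  counts <- tapply(peaks$allele, peaks$locus, function(a) length(unique(a)))
  max(1L, as.integer(ceiling(max(counts) / 2)))
}

# --- internal locus context -------------------------------------------------

# Fixed per-locus structures: the allele grid (union of the prior support,
# its back-stutter positions and the observed peaks -- fixed so that MVN
# normalizing terms are comparable across genotype hypotheses), the aligned
# data vector, the enumerated pair support and per-contributor log priors.
build_locus_context <- function(rows, priors_k, geom) {
  alleles <- order_alleles(unique(c(priors_k[[1]]$a1, priors_k[[1]]$a2)))
  pairs <- enumerate_pairs(alleles)
  keys <- pair_key(pairs$a1, pairs$a2)
  logprior <- lapply(priors_k, function(pr) {
    p <- stats::setNames(pr$prob, pair_key(pr$a1, pr$a2))[keys]
    p[is.na(p)] <- 0
    log(unname(p))
  })
  grid <- order_alleles(unique(c(alleles, stutter_allele(alleles),
                                 if (nrow(rows)) rows$allele)))
  d <- align_heights(rows$height_rfu, rows$allele, grid)
  obs <- if (nrow(rows)) rows$allele else character(0)
  list(locus = geom$locus, geom = geom, alleles = alleles, pairs = pairs,
       keys = keys, logprior = logprior, grid = grid, d = unname(d),
       dmat = NULL, i1 = match(pairs$a1, alleles),
       i2 = match(pairs$a2, alleles), n_pairs = nrow(pairs),
       obs_pair_idx = which(pairs$a1 %in% obs & pairs$a2 %in% obs),
       has_data = nrow(rows) > 0)
}

# pair patterns (P x G) for unit mass and weight, given stutter/degradation
locus_patterns <- function(ctx, stutter_rate, degradation_rate) {
  A <- allele_contribution(ctx$alleles, ctx$grid, ctx$geom, stutter_rate,
                           degradation_rate)
  (A[ctx$i1, , drop = FALSE] + A[ctx$i2, , drop = FALSE]) / 2
}

ll_vec <- function(d, mu, vfloor, vscale) {
  v <- vfloor + vscale * mu
  -0.5 * sum(log(2 * pi * v) + (d - mu)^2 / v)
}

# log-likelihood for every candidate pair at once: MU is P x G
ll_rows <- function(dmat, MU, vfloor, vscale) {
  V <- vfloor + vscale * MU
  -0.5 * rowSums(log(2 * pi * V) + (dmat - MU)^2 / V)
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

sample_cat <- function(logp) {
  p <- exp(logp - max(logp))
  sample.int(length(logp), 1, prob = p)
}

# --- the sampler ------------------------------------------------------------

#' Infer genotype posteriors from mixture peak data
#'
#' Metropolis-within-Gibbs sampling of the joint posterior over contributor
#' genotypes, mixture weights, per-locus mass and nuisance parameters, under
#' the [log_likelihood()] peak-pattern model with theta-corrected genotype
#' priors. Inference uses only the evidence data: no reference genotype
#' enters. Contributor slots are ordered by posterior mean weight
#' (descending) at reporting time; assumed contributors keep the first
#' slots.
#'
#' @param peaks a [peak_table()] for one sample
#' @param settings an [inference_settings()]
#' @param freqs a [freq_table()]
#' @param panel an [read_panel()] object
#' @param params a [model_params()] carrying initial values for stutter,
#'   degradation and variance (variance is re-estimated from the profile by
#'   [estimate_variance_params()] unless sampled)
#' @return object of class `inference_result`: per contributor per locus a
#'   [genotype_dist()] posterior, weight/mass/nuisance summaries, and
#'   per-chain diagnostics
#' @export
infer <- function(peaks, settings, freqs, panel, params = model_params()) {
  if (nrow(peaks) == 0) stop_input("empty peak profile")
  K <- settings$n_contributors
  loci <- intersect(panel_loci(panel),
                    ft_loci(freqs, settings$population))
  obs_loci <- intersect(loci, unique(peaks$locus))
  if (!length(obs_loci)) stop_input("no panel loci with observed peaks")

  n_alleles <- tapply(peaks$allele, peaks$locus, function(a) length(unique(a)))
  if (max(n_alleles) > 2 * K) {
    warning("locus ", names(which.max(n_alleles)), " shows ",
            max(n_alleles), " alleles; K = ", K,
            " can only explain them via shared alleles", call. = FALSE)
  }

  priors <- lapply(obs_loci, function(loc) {
    build_prior_distribution(loc, freqs, settings$theta, settings$population)
  })
  names(priors) <- obs_loci
  ctxs <- lapply(obs_loci, function(loc) {
    build_locus_context(peaks[peaks$locus == loc, , drop = FALSE],
                        rep(list(priors[[loc]]), K),
                        panel_locus(panel, loc))
  })
  names(ctxs) <- obs_loci

  with_seed(settings$seed,
            run_chain(ctxs, priors, settings, params, peaks, obs_loci))
}

run_chain <- function(ctxs, priors, settings, params, peaks, loci) {
  K <- settings$n_contributors
  L <- length(loci)
  n_assumed <- length(settings$assumed %||% list())
  free_k <- setdiff(seq_len(K), seq_len(n_assumed))

  vp <- if (settings$sample_variance) {
    list(variance_scale = params$variance_scale,
         variance_floor = params$variance_floor)
  } else {
    estimate_variance_params(peaks, params)
  }
  vfloor <- vp$variance_floor
  vs <- vp$variance_scale
  s <- params$stutter_rate
  deg <- params$degradation_rate
  smax <- 0.3

  # state: pair index per contributor x locus
  g <- matrix(0L, K, L)
  for (l in seq_len(L)) {
    ctx <- ctxs[[l]]
    for (k in seq_len(K)) {
      if (k <= n_assumed) {
        pair <- settings$assumed[[k]]$genotypes[[ctx$locus]]
        if (is.null(pair)) stop_input("assumed contributor ", k,
                                      " lacks a genotype at ", ctx$locus)
        idx <- which(ctx$keys == pair_key(pair[1], pair[2]))
        if (!length(idx)) stop_input("assumed genotype outside prior support at ",
                                     ctx$locus)
        g[k, l] <- idx
      } else {
        g[k, l] <- sample_cat(ctx$logprior[[k]])
      }
    }
  }

  fixed_w <- !is.null(settings$fix_weights) || K == 1
  # asymmetric start (2:1:... ratios) so contributor slots take coherent
  # major/minor roles across loci before the weights are released
  w <- settings$fix_weights %||% (rev(seq_len(K)) / sum(seq_len(K)))
  z <- log(w) - log(w[1])
  w_freeze <- if (fixed_w) 0L else floor(settings$burn_in / 2)
  fixed_m <- !is.null(settings$fix_mass)
  M <- if (fixed_m) {
    rep_len(settings$fix_mass, L)
  } else {
    vapply(seq_len(L), function(l) max(sum(ctxs[[l]]$d), 100), 0)
  }
  M_init <- M

  pats <- lapply(ctxs, locus_patterns, stutter_rate = s,
                 degradation_rate = deg)
  dmats <- lapply(ctxs, function(ctx) {
    matrix(ctx$d, ctx$n_pairs, length(ctx$grid), byrow = TRUE)
  })

  mu_of <- function(l, w_, M_, pats_) {
    mu <- numeric(length(ctxs[[l]]$grid))
    for (k in seq_len(K)) mu <- mu + w_[k] * pats_[[l]][g[k, l], ]
    M_ * mu
  }
  ll_of <- function(l, mu) ll_vec(ctxs[[l]]$d, mu, vfloor, vs)

  mu_cur <- lapply(seq_len(L), function(l) mu_of(l, w, M[l], pats))
  ll_cur <- vapply(seq_len(L), function(l) ll_of(l, mu_cur[[l]]), 0)

  n_rec <- settings$iterations - settings$burn_in
  counts <- lapply(seq_len(K), function(k) {
    lapply(seq_len(L), function(l) numeric(ctxs[[l]]$n_pairs))
  })
  w_sum <- numeric(K); w_sq <- numeric(K)
  keep_every <- max(1L, floor(n_rec / 1000))
  w_samples <- matrix(NA_real_, ceiling(n_rec / keep_every), K)
  m_sum <- numeric(L)
  s_sum <- 0; vs_sum <- 0
  acc <- c(w = 0, m = 0, s = 0, vs = 0, deg = 0)
  prop <- c(w = 0, m = 0, s = 0, vs = 0, deg = 0)
  step <- c(w = 0.15, m = 0.06, s = 0.35, vs = 0.3, deg = 0.3)

  for (it in seq_len(settings$iterations)) {
    rec <- it > settings$burn_in
    # genotype Gibbs sweeps; marginals are Rao-Blackwellized (the full
    # conditional is accumulated, not the sampled indicator), which reduces
    # Monte-Carlo error and avoids spurious sampling zeros
    for (l in seq_len(L)) {
      ctx <- ctxs[[l]]
      if (!ctx$has_data) {
        for (k in free_k) {
          g[k, l] <- sample_cat(ctx$logprior[[k]])
          if (rec) {
            p <- exp(ctx$logprior[[k]] - max(ctx$logprior[[k]]))
            counts[[k]][[l]] <- counts[[k]][[l]] + p / sum(p)
          }
        }
        next
      }
      for (k in free_k) {
        mu_others <- mu_cur[[l]] - M[l] * w[k] * pats[[l]][g[k, l], ]
        MU <- matrix(mu_others, ctx$n_pairs, length(ctx$grid), byrow = TRUE) +
          (M[l] * w[k]) * pats[[l]]
        lp <- ll_rows(dmats[[l]], MU, vfloor, vs) + ctx$logprior[[k]]
        if (rec) {
          p <- exp(lp - max(lp))
          counts[[k]][[l]] <- counts[[k]][[l]] + p / sum(p)
        }
        g[k, l] <- sample_cat(lp)
        mu_cur[[l]] <- MU[g[k, l], ]
      }
      # slot-swap move: exchanging two free contributors' pairs at this
      # locus jumps directly between labelings (priors cancel: same pairs)
      if (length(free_k) >= 2) {
        ks <- if (length(free_k) == 2) free_k else sample(free_k, 2)
        if (g[ks[1], l] != g[ks[2], l]) {
          delta <- (w[ks[1]] - w[ks[2]]) *
            (pats[[l]][g[ks[2], l], ] - pats[[l]][g[ks[1], l], ])
          mu_new <- mu_cur[[l]] + M[l] * delta
          ll_new <- ll_of(l, mu_new)
          if (log(stats::runif(1)) < ll_new - ll_of(l, mu_cur[[l]])) {
            tmp <- g[ks[1], l]; g[ks[1], l] <- g[ks[2], l]; g[ks[2], l] <- tmp
            mu_cur[[l]] <- mu_new
          }
        }
        # joint block update of the two slots over all pairs of observed
        # alleles: an exact independence draw within that subspace
        # (always-accept Metropolized Gibbs when the current state lies in
        # it), which crosses likelihood valleys that single-slot updates
        # cannot. Run periodically; skipped when a current pair involves an
        # unobserved allele (the reverse proposal would be zero).
        O <- ctx$obs_pair_idx
        if (it %% 5 == 0 && length(O) >= 2 &&
            g[ks[1], l] %in% O && g[ks[2], l] %in% O) {
          base <- mu_cur[[l]] - M[l] * (w[ks[1]] * pats[[l]][g[ks[1], l], ] +
                                          w[ks[2]] * pats[[l]][g[ks[2], l], ])
          m <- length(O)
          A1 <- (M[l] * w[ks[1]]) * pats[[l]][O, , drop = FALSE]
          A2 <- (M[l] * w[ks[2]]) * pats[[l]][O, , drop = FALSE]
          i_idx <- rep(seq_len(m), each = m); j_idx <- rep(seq_len(m), m)
          MU <- A1[i_idx, , drop = FALSE] + A2[j_idx, , drop = FALSE] +
            matrix(base, m * m, length(base), byrow = TRUE)
          D <- matrix(ctx$d, m * m, length(base), byrow = TRUE)
          lp <- ll_rows(D, MU, vfloor, vs) +
            ctx$logprior[[ks[1]]][O[i_idx]] + ctx$logprior[[ks[2]]][O[j_idx]]
          pick <- sample_cat(lp)
          g[ks[1], l] <- O[i_idx[pick]]; g[ks[2], l] <- O[j_idx[pick]]
          mu_cur[[l]] <- MU[pick, ]
        }
      }
      ll_cur[l] <- ll_of(l, mu_cur[[l]])

      if (!fixed_m) {
        prop["m"] <- prop["m"] + 1
        m_new <- M[l] * exp(stats::rnorm(1, 0, step["m"]))
        mu_new <- mu_cur[[l]] * (m_new / M[l])
        ll_new <- ll_of(l, mu_new)
        lr <- (ll_new - ll_cur[l]) +
          (stats::dlnorm(m_new, log(M_init[l]), 1, log = TRUE) -
             stats::dlnorm(M[l], log(M_init[l]), 1, log = TRUE)) +
          (log(m_new) - log(M[l]))  # lognormal RW Hastings term
        if (log(stats::runif(1)) < lr) {
          M[l] <- m_new; mu_cur[[l]] <- mu_new; ll_cur[l] <- ll_new
          acc["m"] <- acc["m"] + 1
        }
      }
    }

    if (!fixed_w && it > w_freeze) {
      prop["w"] <- prop["w"] + 1
      z_new <- z
      z_new[-1] <- z[-1] + stats::rnorm(K - 1, 0, step["w"])
      w_new <- softmax(z_new)
      mu_new <- lapply(seq_len(L), function(l) mu_of(l, w_new, M[l], pats))
      ll_new <- vapply(seq_len(L), function(l) ll_of(l, mu_new[[l]]), 0)
      lr <- sum(ll_new) - sum(ll_cur) +
        sum(log(w_new)) - sum(log(w))  # flat Dirichlet prior Jacobian on z
      if (log(stats::runif(1)) < lr) {
        z <- z_new; w <- w_new; mu_cur <- mu_new; ll_cur <- ll_new
        acc["w"] <- acc["w"] + 1
      }
    }

    if (settings$sample_stutter) {
      prop["s"] <- prop["s"] + 1
      u <- stats::qlogis(pmin(pmax(s / smax, 1e-6), 1 - 1e-6))
      u_new <- u + stats::rnorm(1, 0, step["s"])
      s_new <- smax * stats::plogis(u_new)
      pats_new <- lapply(ctxs, locus_patterns, stutter_rate = s_new,
                         degradation_rate = deg)
      mu_new <- lapply(seq_len(L), function(l) mu_of(l, w, M[l], pats_new))
      ll_new <- vapply(seq_len(L), function(l) ll_of(l, mu_new[[l]]), 0)
      # flat prior on (0, smax); Jacobian of the logit transform
      lr <- sum(ll_new) - sum(ll_cur) +
        log(s_new * (smax - s_new)) - log(s * (smax - s))
      if (log(stats::runif(1)) < lr) {
        s <- s_new; pats <- pats_new; mu_cur <- mu_new; ll_cur <- ll_new
        acc["s"] <- acc["s"] + 1
      }
    }

    if (settings$sample_degradation) {
      prop["deg"] <- prop["deg"] + 1
      d_new <- max(deg + stats::rnorm(1, 0, 0.02 * step["deg"]), 0)
      if (d_new != deg) {
        pats_new <- lapply(ctxs, locus_patterns, stutter_rate = s,
                           degradation_rate = d_new)
        mu_new <- lapply(seq_len(L), function(l) mu_of(l, w, M[l], pats_new))
        ll_new <- vapply(seq_len(L), function(l) ll_of(l, mu_new[[l]]), 0)
        lr <- sum(ll_new) - sum(ll_cur) +
          stats::dexp(d_new, 10, log = TRUE) - stats::dexp(deg, 10, log = TRUE)
        if (log(stats::runif(1)) < lr) {
          deg <- d_new; pats <- pats_new; mu_cur <- mu_new; ll_cur <- ll_new
          acc["deg"] <- acc["deg"] + 1
        }
      }
    }

    if (settings$sample_variance) {
      prop["vs"] <- prop["vs"] + 1
      vs_new <- vs * exp(stats::rnorm(1, 0, step["vs"]))
      ll_new <- vapply(seq_len(L), function(l) {
        ll_vec(ctxs[[l]]$d, mu_cur[[l]], vfloor, vs_new)
      }, 0)
      lr <- sum(ll_new) - sum(ll_cur) +
        (stats::dlnorm(vs_new, log(5), 1.5, log = TRUE) -
           stats::dlnorm(vs, log(5), 1.5, log = TRUE)) +
        (log(vs_new) - log(vs))
      if (log(stats::runif(1)) < lr) {
        vs <- vs_new; ll_cur <- ll_new
        acc["vs"] <- acc["vs"] + 1
      }
    }

    if (rec) {
      r <- it - settings$burn_in
      for (k in seq_len(n_assumed)) {
        for (l in seq_len(L)) {
          counts[[k]][[l]][g[k, l]] <- counts[[k]][[l]][g[k, l]] + 1
        }
      }
      w_sum <- w_sum + w; w_sq <- w_sq + w^2
      if (r %% keep_every == 0) w_samples[r / keep_every, ] <- w
      m_sum <- m_sum + M
      s_sum <- s_sum + s; vs_sum <- vs_sum + vs
    }
  }

  n_rec <- settings$iterations - settings$burn_in
  w_mean <- w_sum / n_rec
  # label alignment: order free slots by posterior mean weight, descending
  ord <- c(seq_len(n_assumed),
           free_k[order(w_mean[free_k], decreasing = TRUE)])

  posteriors <- lapply(ord, function(k) {
    out <- lapply(seq_len(L), function(l) {
      ctx <- ctxs[[l]]
      genotype_dist(ctx$locus, ctx$pairs$a1, ctx$pairs$a2,
                    counts[[k]][[l]] / n_rec)
    })
    names(out) <- loci
    out
  })

  w_samples <- w_samples[stats::complete.cases(w_samples), ord, drop = FALSE]
  structure(list(
    posteriors = posteriors,
    weights = list(mean = w_mean[ord],
                   sd = sqrt(pmax(w_sq[ord] / n_rec - w_mean[ord]^2, 0)),
                   samples = w_samples),
    mass = list(mean = stats::setNames(m_sum / n_rec, loci)),
    stutter = s_sum / n_rec,
    variance_scale = if (settings$sample_variance) vs_sum / n_rec else vs,
    variance_floor = vfloor,
    diagnostics = list(acceptance = ifelse(prop > 0, acc / prop, NA),
                       recorded = n_rec,
                       skipped_loci = loci[!vapply(ctxs, `[[`, TRUE, "has_data")]),
    priors = priors,
    loci = loci,
    settings = settings,
    seed = settings$seed), class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("Mixture inference:", length(x$posteriors), "contributor(s),",
      length(x$loci), "loci\n")
  cat("Posterior mean weights:",
      paste(sprintf("%.3f", x$weights$mean), collapse = ", "), "\n")
  cat("Recorded sweeps:", x$diagnostics$recorded,
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Extract one contributor's evidence genotype
#'
#' @param result an [infer()] result
#' @param contributor slot index (1 = largest posterior mean weight, with
#'   assumed contributors first)
#' @return named list: locus -> [genotype_dist()]
#' @export
evidence_genotype <- function(result, contributor = 1) {
  result$posteriors[[contributor]]
}

#' Run inference under two contributor-count assumptions
#'
#' Convenience for ambiguous mixtures: runs `K` and `K + 1` and returns both
#' results for side-by-side review.
#'
#' @inheritParams infer
#' @return named list of two `inference_result`s
#' @export
infer_contributor_range <- function(peaks, settings, freqs, panel,
                                    params = model_params()) {
  k <- settings$n_contributors
  s2 <- settings
  s2$n_contributors <- k + 1L
  out <- list(infer(peaks, settings, freqs, panel, params),
              infer(peaks, s2, freqs, panel, params))
  names(out) <- paste0("K", c(k, k + 1L))
  out
}

# --- brute-force oracle -----------------------------------------------------

#' Brute-force genotype posterior by exhaustive enumeration
#'
#' For small problems (K <= 2, few alleles) the joint genotype posterior at
#' fixed weights/mass/nuisance parameters can be enumerated exactly:
#' posterior(g_1..g_K) over all pair combinations, proportional to
#' likelihood x priors. Used as the independent check of the MCMC marginals.
#'
#' @param peaks a [peak_table()] (one sample)
#' @param params a [model_params()] with the fixed weights and mass
#' @param freqs a [freq_table()]
#' @param panel an [read_panel()] object
#' @param theta,population prior settings
#' @return list per contributor of (list locus -> [genotype_dist()])
#' @export
enumerate_genotype_posterior <- function(peaks, params, freqs, panel,
                                         theta = 0.01, population = NULL) {
  K <- length(params$weights)
  loci <- intersect(panel_loci(panel), unique(peaks$locus))
  out <- lapply(seq_len(K), function(k) stats::setNames(vector("list", length(loci)), loci))
  for (loc in loci) {
    prior <- build_prior_distribution(loc, freqs, theta, population)
    ctx <- build_locus_context(peaks[peaks$locus == loc, , drop = FALSE],
                               rep(list(prior), K), panel_locus(panel, loc))
    pats <- locus_patterns(ctx, params$stutter_rate, params$degradation_rate)
    P <- ctx$n_pairs
    combos <- as.matrix(expand.grid(rep(list(seq_len(P)), K)))
    lp <- apply(combos, 1, function(idx) {
      mu <- numeric(length(ctx$grid))
      for (k in seq_len(K)) mu <- mu + params$weights[k] * pats[idx[k], ]
      mu <- params$mass * mu
      ll_vec(ctx$d, mu, params$variance_floor, params$variance_scale) +
        sum(vapply(seq_len(K), function(k) ctx$logprior[[k]][idx[k]], 0))
    })
    post <- exp(lp - max(lp)); post <- post / sum(post)
    for (k in seq_len(K)) {
      marg <- vapply(seq_len(P), function(i) sum(post[combos[, k] == i]), 0)
      out[[k]][[loc]] <- genotype_dist(loc, ctx$pairs$a1, ctx$pairs$a2, marg)
    }
  }
  out
}

# --- concordance ------------------------------------------------------------

#' Kullback-Leibler divergence between genotype distributions (ban)
#'
#' KL(p || q) in base-10 units; >= 0, zero iff the distributions agree.
#' Errors when p puts mass outside q's support.
#'
#' @param p,q [genotype_dist()] objects on the same locus
#' @return divergence in ban
#' @export
genotype_kl <- function(p, q) {
  qv <- stats::setNames(q$prob, pair_key(q$a1, q$a2))
  pv <- stats::setNames(p$prob, pair_key(p$a1, p$a2))
  on <- pv > 0
  qq <- qv[names(pv)[on]]
  if (any(is.na(qq) | qq == 0)) {
    stop_input("support of p is not contained in support of q")
  }
  sum(pv[on] * log10(pv[on] / qq))
}

# symmetrized, smoothed KL for replicate comparison (tolerant of sampling
# zeros in either run)
kl_sym_smoothed <- function(p, q, eps = 1e-6) {
  keys <- union(pair_key(p$a1, p$a2), pair_key(q$a1, q$a2))
  pv <- stats::setNames(p$prob, pair_key(p$a1, p$a2))[keys]
  qv <- stats::setNames(q$prob, pair_key(q$a1, q$a2))[keys]
  pv[is.na(pv)] <- 0; qv[is.na(qv)] <- 0
  pv <- (pv + eps) / sum(pv + eps); qv <- (qv + eps) / sum(qv + eps)
  0.5 * (sum(pv * log10(pv / qv)) + sum(qv * log10(qv / pv)))
}

#' Check concordance of two replicate inference runs
#'
#' Mirrors the replication rule that reportable results must agree across
#' independent computer runs: flags loci whose genotype marginals differ by
#' symmetrized KL above `tolerance` (ban) or whose weight summaries
#' disagree.
#'
#' @param run1,run2 [infer()] results on the same data and settings
#'   (different seeds allowed)
#' @param tolerance KL tolerance in ban (default 0.05)
#' @param weight_tolerance allowed difference of posterior mean weights
#' @return list with `pass`, per-locus `kl` per contributor, `flagged`
#' @export
check_concordance <- function(run1, run2, tolerance = 0.05,
                              weight_tolerance = 0.05) {
  s1 <- run1$settings; s2 <- run2$settings
  same <- s1$n_contributors == s2$n_contributors &&
    identical(s1$theta, s2$theta) &&
    identical(s1$population, s2$population) &&
    identical(run1$loci, run2$loci)
  if (!same) stop_input("runs have mismatched settings or loci")
  K <- s1$n_contributors
  kl <- matrix(NA_real_, length(run1$loci), K,
               dimnames = list(run1$loci, paste0("contributor", seq_len(K))))
  for (k in seq_len(K)) {
    for (loc in run1$loci) {
      kl[loc, k] <- kl_sym_smoothed(run1$posteriors[[k]][[loc]],
                                    run2$posteriors[[k]][[loc]])
    }
  }
  flagged <- rownames(kl)[apply(kl, 1, max) > tolerance]
  w_ok <- all(abs(run1$weights$mean - run2$weights$mean) <= weight_tolerance)
  list(pass = length(flagged) == 0 && w_ok, kl = kl, flagged = flagged,
       weights_agree = w_ok)
}
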