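# Three-state beta-mixture EM fit. States correspond to unmethylated,
# hemimethylated and methylated CpGs. Components are beta densities whose
# shape parameters are updated by weighted moment matching; initialization
# is a deterministic quantile split so the fit does not depend on RNG
# state.
fit_beta_mixture <- function(x, k = 3, max_iter = 100, tol = 1e-4) {
  x <- clip_beta(x, 1e-4)
  n <- length(x)
  cuts <- quantile(x, seq(0, 1, length.out = k + 1), type = 7)
  cuts[1] <- -Inf
  cuts[k + 1] <- Inf
  z <- cut(x, cuts, labels = FALSE, include.lowest = TRUE)
  r <- matrix(0, n, k)
  r[cbind(seq_len(n), z)] <- 1
  moments_to_shape <- function(m, v) {
    v <- min(v, m * (1 - m) * 0.95)
    v <- max(v, 1e-6)
    common <- m * (1 - m) / v - 1
    c(a = m * common, b = (1 - m) * common)
  }
  pi_k <- colMeans(r)
  shapes <- matrix(0, k, 2)
  update_shapes <- function(r) {
    for (j in seq_len(k)) {
      w <- r[, j] / sum(r[, j])
      m <- sum(w * x)
      v <- sum(w * (x - m)^2)
      shapes[j, ] <<- moments_to_shape(m, v)
    }
  }
  update_shapes(r)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      pi_k[j] * dbeta(x, shapes[j, 1], shapes[j, 2])
    }, numeric(n))
    tot <- rowSums(dens)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- dens / tot
    r[!is.finite(r)] <- 1 / k
    pi_k <- colMeans(r)
    update_shapes(r)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ord <- order(shapes[, 1] / rowSums(shapes))  # by component mean
  list(pi = pi_k[ord], shapes = shapes[ord, , drop = FALSE],
       converged = converged)
}

# Posterior state assignment under a fitted mixture
assign_states <- function(x, fit) {
  x <- clip_beta(x, 1e-4)
  dens <- vapply(seq_len(nrow(fit$shapes)), function(j) {
    fit$pi[j] * dbeta(x, fit$shapes[j, 1], fit$shapes[j, 2])
  }, numeric(length(x)))
  max.col(dens, ties.method = "first")
}

# Map one sample's type-II values onto the type-I mixture. U and M states
# go through beta-CDF quantile matching (monotone); the middle state is
# linearly rescaled between gap-preserving anchors: the empty intervals
# separating the hemimethylated cluster from its flanking states in the
# input are carried over to the output, so the cluster is shifted and
# dilated but never stretched across the gaps. The overall map stays
# monotone within each state.
bmiq_transform_sample <- function(x2, fit1, fit2) {
  st <- assign_states(x2, fit2)
  y <- x2
  map_state <- function(vals, j) {
    p <- pbeta(clip_beta(vals, 1e-4), fit2$shapes[j, 1], fit2$shapes[j, 2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    qbeta(p, fit1$shapes[j, 1], fit1$shapes[j, 2])
  }
  if (any(st == 1)) y[st == 1] <- map_state(x2[st == 1], 1)
  if (any(st == 3)) y[st == 3] <- map_state(x2[st == 3], 3)
  if (any(st == 2)) {
    h <- x2[st == 2]
    lo <- min(h)
    hi <- max(h)
    left <- if (any(st == 1)) {
      max(y[st == 1]) + (lo - max(x2[st == 1]))  # preserve the U-H gap
    } else {
      map_state(lo, 2)
    }
    right <- if (any(st == 3)) {
      min(y[st == 3]) - (min(x2[st == 3]) - hi)  # preserve the H-M gap
    } else {
      map_state(hi, 2)
    }
    if (right <= left || hi <= lo) {
      y[st == 2] <- h  # degenerate middle state: leave untouched
    } else {
      y[st == 2] <- left + (h - lo) / (hi - lo) * (right - left)
    }
  }
  clip_beta(y, 1e-6)
}

#' Beta-mixture quantile (BMIQ) normalization of type-II probes
#'
#' EPIC arrays mix two probe chemistries whose beta-value distributions
#' differ systematically. BMIQ leaves type-I probes untouched and maps
#' each sample's type-II values onto the type-I distribution via a
#' three-state beta mixture (unmethylated / hemimethylated / methylated):
#' both distributions are fitted by EM, each type-II value is assigned to
#' its most probable state, and state-wise quantile matching carries it
#' onto the type-I mixture. The map is monotone within each state. If the
#' EM fails to converge for a sample, that sample is passed through
#' unchanged with a warning.
#'
#' @param m A [methylation_matrix()] with `design_type` set; at least 100
#'   probes of each design type are required.
#' @param max_iter,tol EM controls (defaults 100 iterations, relative
#'   log-likelihood tolerance 1e-4).
#' @return A [methylation_matrix()] with normalized type-II betas.
#' @export
bmiq_normalize <- function(m, max_iter = 100, tol = 1e-4) {
  stopifnot(inherits(m, "methylation_matrix"))
  if (is.null(m$design_type)) stop("design_type is required for BMIQ")
  t1 <- m$design_type == "I"
  t2 <- m$design_type == "II"
  if (sum(t1) < 100 || sum(t2) < 100) {
    stop("BMIQ requires >= 100 probes of each design type")
  }
  beta <- m$beta
  for (s in seq_len(ncol(beta))) {
    fit1 <- fit_beta_mixture(beta[t1, s], max_iter = max_iter, tol = tol)
    fit2 <- fit_beta_mixture(beta[t2, s], max_iter = max_iter, tol = tol)
    if (!fit1$converged || !fit2$converged) {
      warning(sprintf(
        "BMIQ EM did not converge for sample %s; left unnormalized",
        colnames(beta)[s]
      ))
      next
    }
    beta[t2, s] <- bmiq_transform_sample(beta[t2, s], fit1, fit2)
  }
  methylation_matrix(beta, design_type = m$design_type,
                     detection_p = m$detection_p, bead_count = m$bead_count)
}
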