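#' Covariance of a context matrix
#'
#' Neuron-by-neuron covariance across the condition-time columns. Rows of a
#' context matrix already have zero mean (the across-condition mean was
#' subtracted at every time bin), so this is `M M' / (cols - 1)`.
#'
#' @param cm a `context_matrix` (or plain matrix).
#' @return A symmetric covariance matrix.
#' @export
context_covariance <- function(cm) {
  m <- unclass(cm)
  tcrossprod(m) / (ncol(m) - 1)
}

#' Principal components of one context's activity
#'
#' Top-`k` principal components (neuron-weight vectors, via singular value
#' decomposition of the context matrix) with the variance of each context's
#' activity captured per component and cumulatively.
#'
#' @param cm a `context_matrix`.
#' @param k number of components.
#' @param other_cm optional second `context_matrix` whose variance captured
#'   by these components is also reported.
#' @return An object of class `subspace_set`: `components` (neurons x k,
#'   orthonormal), `eigenvalues` (all), `var_captured_own`,
#'   `cum_var_own`, and (with `other_cm`) `var_captured_other`,
#'   `cum_var_other`.
#' @export
context_pca <- function(cm, k = 10, other_cm = NULL) {
  m <- unclass(cm)
  if (k > min(dim(m))) stop("k exceeds the rank bound of the matrix")
  sv <- svd(m, nu = k, nv = 0)
  eig <- sv$d^2 / (ncol(m) - 1)
  comp <- sv$u
  rownames(comp) <- rownames(m)
  out <- list(
    components = comp,
    eigenvalues = eig,
    var_captured_own = eig[seq_len(k)] / sum(eig),
    cum_var_own = cumsum(eig[seq_len(k)]) / sum(eig),
    k = k, context = attr(cm, "context")
  )
  if (!is.null(other_cm)) {
    cov_o <- context_covariance(other_cm)
    per <- colSums(comp * (cov_o %*% comp))
    out$var_captured_other <- per / sum(diag(cov_o))
    out$cum_var_other <- cumsum(per) / sum(diag(cov_o))
  }
  structure(out, class = "subspace_set")
}

#' Alignment index of a basis with a covariance
#'
#' Variance of the other context's activity captured by the basis, divided
#' by the most any `k` orthonormal directions could capture (the sum of the
#' covariance's top-`k` eigenvalues). Ranges from 0 (orthogonal) to 1
#' (perfectly aligned).
#'
#' @param basis neurons x k matrix with orthonormal columns.
#' @param other_cov symmetric positive semi-definite covariance.
#' @param k number of eigenvalues in the normalizer (default `ncol(basis)`).
#' @return Scalar in `[0, 1]`.
#' @export
alignment_index <- function(basis, other_cov, k = ncol(basis)) {
  check_orthonormal(basis, "basis")
  ev <- eigen(other_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("covariance is not positive semi-definite")
  num <- sum(diag(crossprod(basis, other_cov %*% basis)))
  den <- sum(pmax(ev, 0)[seq_len(k)])
  if (den == 0) stop("covariance has no variance in the top-k eigenvalues")
  min(max(num / den, 0), 1)
}

#' Observed alignment indices between two contexts
#'
#' @param cm_contra,cm_ipsi `context_matrix` objects.
#' @param k number of principal components.
#' @return A list: `A_contra_on_ipsi`, `A_ipsi_on_contra`, `mean`, and the
#'   two `subspace_set`s.
#' @export
observed_alignment <- function(cm_contra, cm_ipsi, k = 10) {
  pc_c <- context_pca(cm_contra, k, other_cm = cm_ipsi)
  pc_i <- context_pca(cm_ipsi, k, other_cm = cm_contra)
  cov_c <- context_covariance(cm_contra)
  cov_i <- context_covariance(cm_ipsi)
  a_ci <- alignment_index(pc_c$components, cov_i, k)
  a_ic <- alignment_index(pc_i$components, cov_c, k)
  list(A_contra_on_ipsi = a_ci, A_ipsi_on_contra = a_ic,
       mean = (a_ci + a_ic) / 2, pca_contra = pc_c, pca_ipsi = pc_i)
}

#' Variance-weighted random-subspace null for the alignment index
#'
#' PCA is performed on the column-wise concatenation of the two context
#' matrices. Each replicate draws two sets of `k` of those components,
#' sampling without replacement with selection probability proportional to
#' the variance each component captures; the first set plays the role of the
#' contralateral components (scored against the ipsilateral covariance) and
#' the second the ipsilateral role, and the two indices are averaged. By
#' default the two sets are drawn independently; `disjoint = TRUE` forces
#' them to be disjoint.
#'
#' @param cm_contra,cm_ipsi `context_matrix` objects.
#' @param k number of components per set.
#' @param n_boot number of replicates.
#' @param seed integer seed.
#' @param disjoint whether the two sampled sets must be disjoint.
#' @return A list: `null` (mean-index samples), `null_mean`, `null_sd`,
#'   observed indices, and `p` per index (fraction of null at or below the
#'   observed value; small values mean more orthogonal than chance).
#' @export
alignment_null <- function(cm_contra, cm_ipsi, k = 10, n_boot = 1000,
                           seed = 1L, disjoint = FALSE) {
  obs <- observed_alignment(cm_contra, cm_ipsi, k)
  both <- cbind(unclass(cm_contra), unclass(cm_ipsi))
  sv <- svd(both, nv = 0)
  n_comp <- sum(sv$d > 1e-12 * sv$d[1])
  if (n_comp < 2 * k) stop("fewer than 2k components available in the concatenated data")
  comps <- sv$u[, seq_len(n_comp), drop = FALSE]
  wts <- sv$d[seq_len(n_comp)]^2
  cov_c <- context_covariance(cm_contra)
  cov_i <- context_covariance(cm_ipsi)
  den_c <- sum(eigen(cov_c, symmetric = TRUE, only.values = TRUE)$values[1:k])
  den_i <- sum(eigen(cov_i, symmetric = TRUE, only.values = TRUE)$values[1:k])

  set.seed(seed)
  null <- vapply(seq_len(n_boot), function(b) {
    set1 <- sample(n_comp, k, prob = wts)
    if (disjoint) {
      rest <- setdiff(seq_len(n_comp), set1)
      set2 <- rest[sample.int(length(rest), k, prob = wts[rest])]
    } else {
      set2 <- sample(n_comp, k, prob = wts)
    }
    b1 <- comps[, set1, drop = FALSE]
    b2 <- comps[, set2, drop = FALSE]
    a1 <- sum(diag(crossprod(b1, cov_i %*% b1))) / den_i
    a2 <- sum(diag(crossprod(b2, cov_c %*% b2))) / den_c
    (a1 + a2) / 2
  }, numeric(1))

  list(null = null, null_mean = mean(null), null_sd = stats::sd(null),
       A_contra_on_ipsi = obs$A_contra_on_ipsi,
       A_ipsi_on_contra = obs$A_ipsi_on_contra,
       observed_mean = obs$mean,
       p_mean = mean(null <= obs$mean),
       p_contra_on_ipsi = mean(null <= obs$A_contra_on_ipsi),
       p_ipsi_on_contra = mean(null <= obs$A_ipsi_on_contra),
       n_boot = n_boot, seed = seed, disjoint = disjoint)
}

#' Jointly orthogonal context subspaces (Stiefel-manifold optimization)
#'
#' Finds `d`-dimensional bases for each context that are orthonormal jointly
#' (every contralateral component orthogonal to every ipsilateral one),
#' maximizing the average normalized variance captured:
#' `(Tr(Qc' Cc Qc)/s_c + Tr(Qi' Ci Qi)/s_i) / 2`, where `s_c`, `s_i` are the
#' sums of the top-`d` eigenvalues of each covariance. Solved by Riemannian
#' gradient ascent on the Stiefel manifold of `2d`-frames with QR
#' retraction, Barzilai-Borwein steps with Armijo backtracking, and
#' multi-start (the polar-projected top-`d` PCA pair plus random frames).
#'
#' @param cov_contra,cov_ipsi symmetric PSD covariances of equal size.
#' @param d dimensions per context.
#' @param seed integer seed for the random restarts.
#' @param n_starts number of starts (>= 5 including the PCA start).
#' @param max_iter,tol iteration cap and gradient-norm tolerance per start.
#' @return A list of class `orthogonal_pair`: `Q_contra`, `Q_ipsi`,
#'   `objective` in `(0, 1]`, per-context variance captured in each basis,
#'   and convergence diagnostics.
#' @export
joint_orthogonal_subspaces <- function(cov_contra, cov_ipsi, d = 3, seed = 1L,
                                       n_starts = 5, max_iter = 2000,
                                       tol = 1e-6) {
  n <- nrow(cov_contra)
  stopifnot(nrow(cov_ipsi) == n, 2 * d <= n)
  s_c <- sum(eigen(cov_contra, symmetric = TRUE, only.values = TRUE)$values[1:d])
  s_i <- sum(eigen(cov_ipsi, symmetric = TRUE, only.values = TRUE)$values[1:d])
  if (s_c <= 0 || s_i <= 0) stop("covariances must have positive top-d variance")
  A <- cov_contra / s_c
  B <- cov_ipsi / s_i
  objective <- function(Q) {
    Q1 <- Q[, 1:d, drop = FALSE]; Q2 <- Q[, (d + 1):(2 * d), drop = FALSE]
    (sum(Q1 * (A %*% Q1)) + sum(Q2 * (B %*% Q2))) / 2
  }
  egrad <- function(Q) {
    cbind(A %*% Q[, 1:d, drop = FALSE], B %*% Q[, (d + 1):(2 * d), drop = FALSE])
  }

  set.seed(seed)
  starts <- list(pca_start(cov_contra, cov_ipsi, d))
  for (i in seq_len(max(n_starts, 5) - 1)) {
    starts[[i + 1]] <- qr_retract(matrix(stats::rnorm(n * 2 * d), n, 2 * d))
  }

  best <- NULL
  diags <- list()
  for (st in seq_along(starts)) {
    res <- stiefel_ascent(starts[[st]], objective, egrad, max_iter, tol)
    diags[[st]] <- res[c("converged", "iterations", "grad_norm", "value")]
    if (is.null(best) || res$value > best$value) best <- res
  }
  if (!any(vapply(diags, `[[`, logical(1), "converged"))) {
    stop("joint orthogonalization did not converge in any restart; ",
         "best gradient norm ",
         format(min(vapply(diags, `[[`, numeric(1), "grad_norm"))))
  }
  Q <- best$Q
  Q_c <- Q[, 1:d, drop = FALSE]
  Q_i <- Q[, (d + 1):(2 * d), drop = FALSE]
  structure(list(
    Q_contra = Q_c, Q_ipsi = Q_i, objective = best$value,
    var_captured = list(
      contra_in_contra = sum(Q_c * (cov_contra %*% Q_c)) / sum(diag(cov_contra)),
      ipsi_in_contra = sum(Q_c * (cov_ipsi %*% Q_c)) / sum(diag(cov_ipsi)),
      ipsi_in_ipsi = sum(Q_i * (cov_ipsi %*% Q_i)) / sum(diag(cov_ipsi)),
      contra_in_ipsi = sum(Q_i * (cov_contra %*% Q_i)) / sum(diag(cov_contra))
    ),
    d = d, starts = diags
  ), class = "orthogonal_pair")
}

# feasible start: per-context top-d eigenvectors projected to the nearest
# jointly orthonormal frame (polar factor of the concatenation)
pca_start <- function(cov_contra, cov_ipsi, d) {
  v_c <- eigen(cov_contra, symmetric = TRUE)$vectors[, 1:d, drop = FALSE]
  v_i <- eigen(cov_ipsi, symmetric = TRUE)$vectors[, 1:d, drop = FALSE]
  m <- cbind(v_c, v_i)
  sv <- svd(m)
  sv$u %*% t(sv$v)
}

qr_retract <- function(M) {
  f <- qr(M)
  Q <- qr.Q(f)
  s <- sign(diag(qr.R(f)))
  s[s == 0] <- 1
  Q * rep(s, each = nrow(Q))
}

# Riemannian gradient ascent on the Stiefel manifold with QR retraction,
# Barzilai-Borwein step length and Armijo backtracking
stiefel_ascent <- function(Q, f, egrad, max_iter, tol) {
  rgrad <- function(Q, G) {
    QtG <- crossprod(Q, G)
    G - Q %*% ((QtG + t(QtG)) / 2)
  }
  val <- f(Q)
  G <- rgrad(Q, egrad(Q))
  step <- 1
  prev_Q <- NULL
  prev_G <- NULL
  it <- 0
  gn <- sqrt(sum(G^2))
  while (it < max_iter && gn > tol) {
    it <- it + 1
    if (!is.null(prev_Q)) {
      sdiff <- Q - prev_Q
      ydiff <- G - prev_G
      denom <- abs(sum(sdiff * ydiff))
      step <- if (denom > 1e-30) sum(sdiff * sdiff) / denom else 1
      step <- min(max(step, 1e-10), 1e6)
    }
    ok <- FALSE
    t_try <- step
    for (ls in 1:40) {
      Q_new <- qr_retract(Q + t_try * G)
      val_new <- f(Q_new)
      if (val_new >= val + 1e-4 * t_try * gn^2) { ok <- TRUE; break }
      t_try <- t_try / 2
    }
    if (!ok) break
    prev_Q <- Q; prev_G <- G
    Q <- Q_new; val <- val_new
    G <- rgrad(Q, egrad(Q))
    gn <- sqrt(sum(G^2))
  }
  list(Q = Q, value = val, grad_norm = gn, iterations = it,
       converged = gn <= tol)
}

#' Relative projection difference between contexts in a common basis
#'
#' Projects both context matrices onto a basis from
#' [joint_orthogonal_subspaces()] and reports the Frobenius-norm relative
#' difference `||P_ref - P_other|| / ||P_ref|| * 100` with the reference
#' context in the denominator. Variability and significance come from
#' resampling the non-reference context's trials with replacement within
#' every load condition and recomputing the difference.
#'
#' @param Q neurons x d basis (`Q_contra` or `Q_ipsi`).
#' @param cm_contra,cm_ipsi `context_matrix` objects.
#' @param reference which context the basis belongs to and which
#'   projection sits in the denominator.
#' @param rs the [smooth_spike_trains()] result (per-trial rates for the
#'   bootstrapped, non-reference context).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param bin_ms,soft_norm_hz as in [build_context_matrices()].
#' @return A list: `percent`, bootstrap `ci` (2.5/97.5 percentiles), `p`
#'   (fraction of replicates at or below zero), `boot` samples.
#' @export
relative_projection_difference <- function(Q, cm_contra, cm_ipsi,
                                           reference = c("contra", "ipsi"),
                                           rs = NULL, n_boot = 1000, seed = 1L,
                                           bin_ms = 10, soft_norm_hz = 5) {
  reference <- match.arg(reference)
  ref_cm <- if (reference == "contra") cm_contra else cm_ipsi
  oth_cm <- if (reference == "contra") cm_ipsi else cm_contra
  other_ctx <- setdiff(c("contra", "ipsi"), reference)
  p_ref <- crossprod(Q, unclass(ref_cm))
  ref_norm <- sqrt(sum(p_ref^2))
  if (ref_norm == 0) stop("reference projection has zero norm")
  rel_diff <- function(p_oth) sqrt(sum((p_ref - p_oth)^2)) / ref_norm * 100
  observed <- rel_diff(crossprod(Q, unclass(oth_cm)))

  boot <- NULL
  if (!is.null(rs) && n_boot > 0) {
    pt <- rs$windows$perturbation
    sample_t <- seq(pt[1], pt[2] - 1, by = bin_ms)
    sample_idx <- match(sample_t, rs$times_ms)
    ds <- lapply(rs$rates[[other_ctx]],
                 function(a) a[, sample_idx, , drop = FALSE])
    divisors <- soft_norm_divisors(rs, soft_norm_hz)
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      avgs <- lapply(ds, function(a) {
        n_tr <- dim(a)[3]
        rowMeans(a[, , sample.int(n_tr, n_tr, replace = TRUE),
                   drop = FALSE], dims = 2)
      })
      m <- context_matrix_from_avgs(avgs, divisors, other_ctx, sample_t)
      rel_diff(crossprod(Q, unclass(m)))
    }, numeric(1))
  }
  list(
    percent = observed,
    ci = if (is.null(boot)) NULL else
      stats::quantile(boot, c(0.025, 0.975), names = FALSE),
    p = if (is.null(boot)) NULL else mean(boot <= 0),
    boot = boot, reference = reference, n_boot = n_boot, seed = seed
  )
}

#' Neuron-weight balance between the two contexts' components
#'
#' For each neuron, sums the absolute weights across the top-`k` components
#' of each context and forms `(w_ipsi - w_contra) / (w_ipsi + w_contra)` in
#' `[-1, 1]`: +1 loads only on ipsilateral components, 0 is balanced. A
#' one-sample Kolmogorov-Smirnov test compares the standardized indices to
#' the normal distribution (a bimodal result would indicate two separate
#' neuron groups).
#'
#' @param pcs_contra,pcs_ipsi `subspace_set`s over the same neurons.
#' @return A list: per-neuron `index`, `ks_statistic`, `ks_p`, `n`,
#'   `excluded` neuron ids (zero total weight).
#' @export
weight_balance_index <- function(pcs_contra, pcs_ipsi) {
  wc <- rowSums(abs(pcs_contra$components))
  wi <- rowSums(abs(pcs_ipsi$components))
  stopifnot(length(wc) == length(wi))
  tot <- wi + wc
  excluded <- names(wc)[tot == 0]
  if (length(excluded)) {
    warning("excluding neurons with zero total weight: ",
            paste(excluded, collapse = ", "))
  }
  keep <- tot > 0
  idx <- (wi[keep] - wc[keep]) / tot[keep]
  if (length(idx) >= 3 && stats::sd(idx) > 0) {
    ks <- suppressWarnings(stats::ks.test(as.numeric(scale(idx)), "pnorm"))
    ks_stat <- unname(ks$statistic)
    ks_p <- ks$p.value
  } else {
    ks_stat <- NA_real_
    ks_p <- NA_real_
  }
  list(index = idx, ks_statistic = ks_stat, ks_p = ks_p,
       n = sum(keep), excluded = excluded)
}
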