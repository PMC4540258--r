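# Quantitative fatty acid signature analysis (QFASA).
#
# A predator's FA signature is modelled as a convex mixture of prey-taxon
# mean signatures, optionally corrected by per-FA calibration coefficients
# for predator metabolism.  The diet-proportion vector is estimated by
# minimizing the symmetrized Kullback-Leibler distance between the predator
# signature and the modelled mixture over the probability simplex.

#' Build a prey basis (taxon mean signatures) for diet estimation
#'
#' @param x an [fa_library()] of prey individuals, or a numeric matrix of
#'   mean signatures with FA bins in rows and taxa in columns (fractions or
#'   percent; columns are re-closed)
#' @param by metadata column naming the taxon of each prey sample (default
#'   `"group"`); used only for the `fa_library` input
#' @param calibration per-FA multipliers correcting for predator metabolism
#'   of dietary FA; default all 1 (identity), appropriate when metabolism is
#'   unknown
#' @param eps zero-replacement floor applied to mean signatures containing
#'   zeros, so the KL distance is defined (see [replace_zeros()]; strictly
#'   positive signatures pass through unchanged)
#' @return object of class `prey_basis`: `taxa`, `bins`, `M` (bins x taxa
#'   matrix of strictly positive mean signatures), `calibration`
#' @export
prey_basis <- function(x, by = "group", calibration = NULL, eps = 1e-5) {
  if (inherits(x, "fa_library")) {
    g <- x$meta[[by]]
    taxa <- unique(g)
    M <- vapply(taxa, function(tx) {
      colMeans(x$proportions[g == tx, , drop = FALSE])
    }, numeric(length(x$bins)))
    rownames(M) <- x$bins
  } else {
    M <- as.matrix(x)
    if (any(M < 0)) stop("mean signatures must be non-negative")
    M <- sweep(M, 2, colSums(M), "/")
    taxa <- colnames(M)
    if (is.null(taxa)) taxa <- sprintf("taxon%d", seq_len(ncol(M)))
  }
  M <- apply(M, 2, .ensure_positive, eps = eps)
  if (is.null(calibration)) calibration <- rep(1, nrow(M))
  if (length(calibration) != nrow(M)) {
    stop("calibration length must equal the number of FA bins")
  }
  if (any(calibration <= 0)) stop("calibration coefficients must be positive")
  structure(list(taxa = taxa, bins = rownames(M), M = M,
                 calibration = as.numeric(calibration)),
            class = "prey_basis")
}

#' Modelled predator signature implied by a diet
#'
#' `yhat = close(calibration * (M %*% p))`.  With identity calibration this
#' is exactly the convex mixture of the prey mean signatures.
#'
#' @param p diet proportions on the simplex (length = number of taxa)
#' @param basis a [prey_basis()]
#' @return FA composition vector summing to one
#' @export
mixture <- function(p, basis) {
  stopifnot(inherits(basis, "prey_basis"))
  if (length(p) != length(basis$taxa)) {
    stop("diet vector length must match the number of prey taxa")
  }
  if (any(p < 0)) stop("diet proportions must be non-negative")
  u <- basis$calibration * drop(basis$M %*% p)
  u / sum(u)
}

#' Symmetrized Kullback-Leibler distance between two compositions
#'
#' `sum((y - yhat) * log(y / yhat))`: non-negative, zero iff `y == yhat`,
#' symmetric in its arguments, and giving greater weight to discrepancies
#' in rare FA than a squared-error distance.  The one-sided (directed)
#' divergence `sum(y * log(y / yhat))` is available via `form`.
#'
#' @param y,yhat strictly positive compositions of equal length (apply
#'   [replace_zeros()] first)
#' @param form `"symmetric"` (default) or `"directed"`
#' @return non-negative scalar
#' @export
kl_distance <- function(y, yhat, form = c("symmetric", "directed")) {
  form <- match.arg(form)
  if (length(y) != length(yhat)) stop("compositions differ in length")
  if (any(y <= 0) || any(yhat <= 0)) {
    stop("KL distance needs strictly positive entries; apply replace_zeros() first")
  }
  lr <- log(y) - log(yhat)
  if (form == "symmetric") sum((y - yhat) * lr) else sum(y * lr)
}

# objective, gradient and (identity-calibration) Hessian in softmax
# coordinates: p = softmax(c(z, 0)), the last logit pinned at 0 so the
# parameterization has no flat direction.  The exact Hessian matters: the
# objective has very flat valleys along near-collinear prey directions, and
# quasi-Newton steps stall in them; Newton steps do not.
.kl_objective <- function(y, basis, form) {
  M <- basis$M
  cal <- basis$calibration
  identity_cal <- all(cal == 1)
  softmax <- function(z) {
    e <- exp(c(z, 0) - max(z, 0))
    e / sum(e)
  }
  grad_p <- function(p) {
    u <- cal * drop(M %*% p)
    s <- sum(u)
    yhat <- u / s
    lr <- log(y) - log(yhat)
    dfdyhat <- if (form == "symmetric") -lr - y / yhat + 1 else -y / yhat
    dfdu <- (dfdyhat - sum(dfdyhat * yhat)) / s
    drop(crossprod(M, cal * dfdu))
  }
  out <- list(
    softmax = softmax,
    fn = function(z) {
      p <- softmax(z)
      u <- cal * drop(M %*% p)
      yhat <- u / sum(u)
      lr <- log(y) - log(yhat)
      if (form == "symmetric") sum((y - yhat) * lr) else sum(y * lr)
    },
    gr = function(z) {
      p <- softmax(z)
      dfdp <- grad_p(p)
      g <- p * (dfdp - sum(dfdp * p))
      g[-length(g)]
    },
    he = NULL
  )
  if (identity_cal) {
    # with c = 1 the model is yhat = M p (already closed), so
    # d2f/dp2 = M' diag(D) M with D the per-bin curvature
    out$he <- function(z) {
      p <- softmax(z)
      k <- length(p)
      yhat <- drop(M %*% p)
      D <- if (form == "symmetric") 1 / yhat + y / yhat^2 else y / yhat^2
      Hp <- crossprod(M, M * D)
      J <- (diag(p) - tcrossprod(p))[, -k, drop = FALSE]
      H1 <- crossprod(J, Hp %*% J)
      g <- grad_p(p)
      w <- g * p
      wk <- w[-k]; pk <- p[-k]; W <- sum(w)
      H2 <- diag(wk, k - 1) - tcrossprod(wk, pk) - tcrossprod(pk, wk) +
        2 * W * tcrossprod(pk) - W * diag(pk, k - 1)
      H1 + H2
    }
  }
  out
}

# close a signature and replace zeros only when replacement is needed, so
# an already strictly positive composition passes through unchanged
.ensure_positive <- function(x, eps) {
  x <- as.numeric(x)
  if (all(x > 0)) x / sum(x) else replace_zeros(x, eps)
}

#' Estimate diet proportions for one predator
#'
#' Minimizes the KL distance between the predator signature and the
#' modelled mixture over the diet simplex.  Signatures containing zeros
#' are first passed through [replace_zeros()] (strictly positive input is
#' only re-closed, so a predator that is itself an exact mixture of the
#' basis signatures is recovered with distance 0).  The simplex constraint
#' is handled by a softmax reparameterization (last logit pinned at 0)
#' optimized with PORT (`nlminb`); the barycenter start is always used and
#' `restarts` additional random (flat-Dirichlet) starts guard against
#' local minima (with identity calibration the symmetrized-KL objective is
#' convex in the diet, so the barycenter start alone already finds the
#' global minimum).
#'
#' @param predator an [fa_library()] row, or a numeric composition vector
#' @param basis a [prey_basis()]
#' @param eps zero-replacement floor applied to the predator signature
#' @param restarts extra random starts beyond the barycenter (default 10)
#' @param tol relative convergence tolerance on the objective (the
#'   optimizer additionally stops when the objective falls below 1e-14)
#' @param seed optional seed for the random starts
#' @param form KL form, `"symmetric"` (default) or `"directed"`
#' @return object of class `diet_estimate`: `proportions` (named simplex
#'   vector over taxa), `distance` (achieved KL), `form`, `convergence`
#' @export
estimate_diet <- function(predator, basis, eps = 1e-5, restarts = 10,
                          tol = 1e-12, seed = NULL,
                          form = c("symmetric", "directed")) {
  form <- match.arg(form)
  stopifnot(inherits(basis, "prey_basis"))
  if (inherits(predator, "fa_library")) {
    if (nrow(predator$proportions) != 1) {
      stop("pass a single predator signature (see bootstrap_diet for libraries)")
    }
    predator <- drop(predator$proportions)
  }
  y <- .ensure_positive(predator, eps)
  if (length(y) != nrow(basis$M)) {
    stop("predator signature and prey basis differ in FA bins")
  }
  k <- length(basis$taxa)
  obj <- .kl_objective(y, basis, form)
  if (!is.null(seed)) set.seed(seed)
  starts <- c(list(rep(1 / k, k)),
              if (restarts > 0) {
                lapply(seq_len(restarts), function(i) {
                  e <- stats::rexp(k); e / sum(e)
                })
              })
  best <- NULL
  conv <- 1L
  for (p0 in starts) {
    z0 <- log(p0[-k]) - log(p0[k])
    fit <- stats::nlminb(z0, obj$fn, obj$gr, obj$he,
                         control = list(rel.tol = tol, abs.tol = 1e-14,
                                        iter.max = 1000, eval.max = 2000))
    fit$value <- fit$objective
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence
    }
  }
  if (is.null(best)) stop("diet optimization failed from every start")
  p <- obj$softmax(best$par)
  value <- best$value

  # polish: coordinates that collapsed to the boundary leave the softmax
  # parameterization ill-conditioned, so re-solve on the active face and
  # verify the simplex KKT conditions (for active i, grad_i = lambda; for
  # inactive i, grad_i >= lambda), re-admitting any violating taxon
  grad_p_full <- function(p) {
    u <- basis$calibration * drop(basis$M %*% p)
    s <- sum(u)
    yhat <- u / s
    lr <- log(y) - log(yhat)
    dfdyhat <- if (form == "symmetric") -lr - y / yhat + 1 else -y / yhat
    dfdu <- (dfdyhat - sum(dfdyhat * yhat)) / s
    drop(crossprod(basis$M, basis$calibration * dfdu))
  }
  solve_on_face <- function(p_start, active) {
    if (sum(active) == 1) {
      p_out <- as.numeric(active)
      return(list(p = p_out,
                  value = kl_distance(y, mixture(p_out, basis), form)))
    }
    sub_basis <- structure(list(taxa = basis$taxa[active],
                                bins = basis$bins,
                                M = basis$M[, active, drop = FALSE],
                                calibration = basis$calibration),
                           class = "prey_basis")
    sub_obj <- .kl_objective(y, sub_basis, form)
    q <- pmax(p_start[active], 1e-12)
    q <- q / sum(q)
    m <- length(q)
    fit <- stats::nlminb(log(q[-m]) - log(q[m]), sub_obj$fn, sub_obj$gr,
                         sub_obj$he,
                         control = list(rel.tol = tol, abs.tol = 1e-14,
                                        iter.max = 1000, eval.max = 2000))
    p_out <- numeric(k)
    p_out[active] <- sub_obj$softmax(fit$par)
    list(p = p_out, value = fit$objective)
  }
  for (round in 1:3) {
    active <- p >= 1e-6
    if (!all(active)) {
      face <- solve_on_face(p, active)
      if (face$value <= value + 1e-15) {
        p <- face$p
        value <- face$value
      }
    }
    g <- grad_p_full(pmax(p, 0))
    lambda <- min(g[p >= 1e-6])
    viol <- which(p < 1e-6 & g < lambda - 1e-8 * max(1, abs(lambda)))
    if (!length(viol)) break
    # pull the most violating taxon off the boundary and re-solve
    j <- viol[which.min(g[viol])]
    p_start <- 0.9 * p + 0.1 * (seq_len(k) == j)
    refit <- solve_on_face(p_start, rep(TRUE, k))
    if (refit$value < value) {
      p <- refit$p
      value <- refit$value
    } else break
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- basis$taxa
  best$value <- value
  structure(list(proportions = p, distance = best$value, form = form,
                 convergence = conv, se = NULL, reps = NULL),
            class = "diet_estimate")
}

#' @export
print.diet_estimate <- function(x, ...) {
  cat("diet_estimate",
      if (!is.null(x$reps)) sprintf(" (bootstrap, %d reps)", x$reps),
      ":\n", sep = "")
  for (i in seq_along(x$proportions)) {
    if (is.null(x$se)) {
      cat(sprintf("  %-10s %5.1f%%\n", names(x$proportions)[i],
                  100 * x$proportions[i]))
    } else {
      cat(sprintf("  %-10s %5.1f +/- %.1f%% (SE)\n",
                  names(x$proportions)[i], 100 * x$proportions[i],
                  100 * x$se[i]))
    }
  }
  if (!is.null(x$distance)) {
    cat(sprintf("  achieved KL distance: %.4g\n", x$distance))
  }
  invisible(x)
}

#' Bootstrap diet estimate over a predator library
#'
#' Each bootstrap replicate resamples predators with replacement and prey
#' individuals with replacement within each taxon, rebuilds the taxon mean
#' signatures, and estimates the replicate's diet.  With `unit = "mean"`
#' (the default) the replicate fits the mean signature of the resampled
#' predators: individual-level signature noise then averages out before the
#' nonlinear fit, avoiding the inflation of rare prey that averaging many
#' simplex-constrained individual estimates produces.  With
#' `unit = "individual"` every resampled predator is fitted separately and
#' the replicate records the across-predator mean diet.  Reported
#' proportions are the mean over replicates and the standard error is the
#' standard deviation over replicates.
#'
#' @param predators [fa_library()] of predator signatures (e.g. tail-adipose
#'   otters only)
#' @param prey [fa_library()] of prey individuals with taxon labels
#' @param reps bootstrap replicates (default 500; must be >= 2)
#' @param seed integer seed
#' @param by prey metadata column naming the taxon
#' @param scheme which side to resample: `"both"` (default), `"predators"`
#'   or `"prey"`
#' @param unit fit the replicate-mean predator signature (`"mean"`,
#'   default) or fit every predator and average (`"individual"`)
#' @param eps zero-replacement floor
#' @param restarts random restarts per inner fit (default 0: barycenter
#'   start only, sufficient for the convex identity-calibration objective)
#' @param calibration optional per-FA calibration vector
#' @param form KL form
#' @return `diet_estimate` with `proportions` (mean over reps), `se`,
#'   `reps`, and the per-replicate means in `rep_matrix`
#' @export
bootstrap_diet <- function(predators, prey, reps = 500, seed = NULL,
                           by = "group", scheme = c("both", "predators", "prey"),
                           unit = c("mean", "individual"),
                           eps = 1e-5, restarts = 0, calibration = NULL,
                           form = c("symmetric", "directed")) {
  scheme <- match.arg(scheme)
  unit <- match.arg(unit)
  form <- match.arg(form)
  stopifnot(inherits(predators, "fa_library"), inherits(prey, "fa_library"))
  if (reps < 2) stop("reps must be at least 2")
  if (!identical(predators$bins, prey$bins)) {
    stop("predator and prey libraries must share the FA bin set")
  }
  np <- nrow(predators$proportions)
  if (np < 1) stop("need at least 1 predator")
  g <- prey$meta[[by]]
  taxa <- unique(g)
  taxon_rows <- lapply(taxa, function(tx) which(g == tx))
  if (any(!lengths(taxon_rows))) stop("every prey taxon must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  pred_y <- t(apply(predators$proportions, 1, .ensure_positive, eps = eps))
  rep_matrix <- matrix(NA_real_, reps, length(taxa),
                       dimnames = list(NULL, taxa))
  for (r in seq_len(reps)) {
    pi_idx <- if (scheme %in% c("both", "predators")) {
      sample.int(np, np, replace = TRUE)
    } else seq_len(np)
    M <- vapply(taxon_rows, function(rows) {
      rows_r <- if (scheme %in% c("both", "prey")) {
        rows[sample.int(length(rows), length(rows), replace = TRUE)]
      } else rows
      colMeans(prey$proportions[rows_r, , drop = FALSE])
    }, numeric(length(prey$bins)))
    colnames(M) <- taxa
    basis <- prey_basis(M, calibration = calibration, eps = eps)
    if (unit == "mean") {
      ybar <- colMeans(pred_y[pi_idx, , drop = FALSE])
      rep_matrix[r, ] <- estimate_diet(ybar, basis, eps = eps,
                                       restarts = restarts,
                                       form = form)$proportions
    } else {
      fits <- vapply(pi_idx, function(i) {
        estimate_diet(pred_y[i, ], basis, eps = eps, restarts = restarts,
                      form = form)$proportions
      }, numeric(length(taxa)))
      rep_matrix[r, ] <- rowMeans(fits)
    }
  }
  p_mean <- colMeans(rep_matrix)
  se <- apply(rep_matrix, 2, stats::sd)
  structure(list(proportions = p_mean, se = se, reps = reps,
                 rep_matrix = rep_matrix, distance = NULL, form = form,
                 scheme = scheme, unit = unit),
            class = "diet_estimate")
}
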