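#' Feature classes for the maximum-entropy model
#'
#' The six allowed feature-class combinations. `l` linear, `q` quadratic,
#' `p` product, `h` hinge, `t` threshold.
#' @export
MAXENT_COMBOS <- c("l", "lq", "h", "lqh", "lqhp", "lqhpt")

#' Default regularization multipliers for the candidate grid
#' @export
MAXENT_RMS <- c(1, 2, 3, 5, 10)

combo_classes <- function(combo) {
  combo <- match.arg(combo, MAXENT_COMBOS)
  strsplit(combo, "")[[1]]
}

# Published Maxent per-feature-class default regularization constants,
# interpolated by presence sample size m (rule = 2 clamps at the ends).
maxent_beta_default <- function(kind, m) {
  switch(kind,
    linear = ,
    quadratic = ,
    product = approx(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05), m, rule = 2)$y,
    hinge = 0.5,
    threshold = approx(c(0, 100), c(2, 1), m, rule = 2)$y,
    stop("unknown feature kind: ", kind))
}

#' Build the feature expansion for a variable set and feature combo
#'
#' Base variables are min/max-scaled to `[0, 1]` using their range over
#' the background (every native-region cell); scaling bounds are frozen
#' here and reused, with clamping, for any later prediction extent.
#' Features: linear = scaled variable; quadratic = its square; product =
#' pairwise products of scaled variables; hinge = forward and reverse
#' piecewise-linear ramps at `n_knots` evenly spaced knots per variable;
#' threshold = step indicators at `n_knots` interior knots. Variables
#' that are constant over the background are dropped with a warning.
#'
#' The full background feature matrix is cached on the expansion so that
#' repeated fits (cross-validation folds, regularization multipliers)
#' reuse it.
#'
#' @param env an [env_stack()].
#' @param native a [region_mask()]; its member cells are the background.
#' @param variables character vector of layer names to use.
#' @param combo one of [MAXENT_COMBOS].
#' @param n_knots hinge/threshold knots per variable (default 50).
#' @return object of class `feature_expansion`.
#' @export
build_features <- function(env, native, variables, combo, n_knots = 50) {
  combo <- match.arg(combo, MAXENT_COMBOS)
  if (length(variables) == 0) stop("empty variable list")
  missing <- setdiff(variables, names(env$layers))
  if (length(missing) > 0)
    stop("variables not in stack: ", paste(missing, collapse = ", "))
  cells <- mask_cells(native)
  V <- vapply(variables, function(v) env$layers[[v]][cells],
              numeric(length(cells)))
  V <- matrix(V, nrow = length(cells),
              dimnames = list(NULL, variables))
  rng <- apply(V, 2, range, na.rm = TRUE)
  const <- rng[2, ] - rng[1, ] <= 0
  if (any(const)) {
    warning("dropping constant variable(s) over background: ",
            paste(variables[const], collapse = ", "))
    variables <- variables[!const]
    if (length(variables) == 0) stop("all variables constant over background")
    V <- V[, !const, drop = FALSE]
    rng <- rng[, !const, drop = FALSE]
  }
  classes <- combo_classes(combo)
  knots_fwd <- seq(0, 1, length.out = n_knots + 1)[seq_len(n_knots)]
  knots_rev <- seq(0, 1, length.out = n_knots + 1)[-1]
  knots_thr <- seq(0, 1, length.out = n_knots + 2)[seq_len(n_knots) + 1]
  desc <- list()
  add <- function(kind, var, var2 = NA_character_, knot = NA_real_) {
    desc[[length(desc) + 1]] <<- data.frame(
      kind = kind, var = var, var2 = var2, knot = knot,
      stringsAsFactors = FALSE)
  }
  if ("l" %in% classes) for (v in variables) add("linear", v)
  if ("q" %in% classes) for (v in variables) add("quadratic", v)
  if ("h" %in% classes) for (v in variables) {
    for (k in knots_fwd) add("hinge_fwd", v, knot = k)
    for (k in knots_rev) add("hinge_rev", v, knot = k)
  }
  if ("p" %in% classes && length(variables) >= 2) {
    for (i in seq_len(length(variables) - 1))
      for (j in (i + 1):length(variables))
        add("product", variables[i], variables[j])
  }
  if ("t" %in% classes) for (v in variables) {
    for (k in knots_thr) add("threshold", v, knot = k)
  }
  desc <- do.call(rbind, desc)
  exp_obj <- structure(list(combo = combo, variables = variables,
                            bounds = rng, descriptors = desc,
                            n_knots = n_knots, cells = cells,
                            grid = env$grid),
                       class = "feature_expansion")
  exp_obj$F_bg <- feature_matrix_from_values(exp_obj, V)
  exp_obj
}

#' @export
print.feature_expansion <- function(x, ...) {
  cat(sprintf("<feature_expansion:%s> %d features over %d variables, %d background cells\n",
              x$combo, nrow(x$descriptors), length(x$variables),
              length(x$cells)))
  invisible(x)
}

# scale raw variable values with the frozen background bounds, clamped
scale_values <- function(expansion, V) {
  out <- V
  for (j in seq_along(expansion$variables)) {
    lo <- expansion$bounds[1, j]; hi <- expansion$bounds[2, j]
    out[, j] <- pmin(pmax((V[, j] - lo) / (hi - lo), 0), 1)
  }
  out
}

# features from a raw value matrix (columns = expansion$variables)
feature_matrix_from_values <- function(expansion, V) {
  S <- scale_values(expansion, V)
  d <- expansion$descriptors
  Fm <- matrix(0, nrow(S), nrow(d))
  for (f in seq_len(nrow(d))) {
    x <- S[, d$var[f]]
    Fm[, f] <- switch(d$kind[f],
      linear = x,
      quadratic = x^2,
      product = x * S[, d$var2[f]],
      hinge_fwd = pmax(0, x - d$knot[f]) / (1 - d$knot[f]),
      hinge_rev = pmax(0, d$knot[f] - x) / d$knot[f],
      threshold = as.numeric(x >= d$knot[f]))
  }
  Fm
}

#' Feature matrix at arbitrary cells
#'
#' @param expansion a [build_features()] result.
#' @param env an [env_stack()] containing the expansion's variables.
#' @param cells integer cell ids on the expansion's grid.
#' @return numeric matrix (cells x features).
#' @export
feature_matrix <- function(expansion, env, cells) {
  missing <- setdiff(expansion$variables, names(env$layers))
  if (length(missing) > 0)
    stop("variables missing from env: ", paste(missing, collapse = ", "))
  V <- vapply(expansion$variables, function(v) env$layers[[v]][cells],
              numeric(length(cells)))
  V <- matrix(V, nrow = length(cells),
              dimnames = list(NULL, expansion$variables))
  feature_matrix_from_values(expansion, V)
}

# rows of the cached background matrix for given cells (presences may repeat)
bg_rows <- function(expansion, cells) {
  rows <- match(cells, expansion$cells)
  if (anyNA(rows)) stop("cells outside the expansion background")
  rows
}

#' Fit the L1-regularized maximum-entropy model
#'
#' Estimates the Gibbs density `q(x) proportional to exp(beta' f(x))`
#' over the background cells by minimizing the penalized negative
#' presence log-likelihood. The per-feature penalty is
#' `lambda_j = rm * beta_default(kind_j, m) * s_j / sqrt(m)` with `m` the
#' presence count and `s_j` the presence sample standard deviation of
#' feature `j`, floored at 0.05 on the `[0, 1]` feature scale. The convex
#' objective is solved by accelerated proximal gradient descent to a
#' relative tolerance of 1e-7 (at most 10000 iterations).
#'
#' @param expansion a [build_features()] result.
#' @param presence_cells integer cell ids of presences (duplicates allowed
#'   for the raw data type); must be a subset of the background.
#' @param background_cells integer cell ids of the background; defaults to
#'   every cell of the expansion (the full native region).
#' @param rm regularization multiplier (default 1).
#' @param tol,max_iter solver controls.
#' @param beta_init optional warm/alternative start for the solver.
#' @return object of class `maxent_model` with the fitted coefficients,
#'   log-normalizer, entropy `H` of the background distribution, and
#'   settings.
#' @export
fit_maxent <- function(expansion, presence_cells,
                       background_cells = expansion$cells, rm = 1,
                       tol = 1e-7, max_iter = 10000L, beta_init = NULL) {
  if (length(presence_cells) < 1) stop("at least one presence required")
  if (length(background_cells) < 2) stop("at least two background cells required")
  prow <- bg_rows(expansion, presence_cells)
  brow <- bg_rows(expansion, background_cells)
  if (!all(presence_cells %in% background_cells))
    stop("presence cells must be a subset of the background")
  Fb <- expansion$F_bg[brow, , drop = FALSE]
  Fp <- expansion$F_bg[prow, , drop = FALSE]
  m <- length(presence_cells)
  fbar <- colMeans(Fp)
  s <- if (m > 1) apply(Fp, 2, sd) else rep(0, ncol(Fp))
  s <- pmax(s, 0.05)
  lambda <- rm * vapply(expansion$descriptors$kind, function(k)
    maxent_beta_default(sub("_(fwd|rev)$", "", k), m), numeric(1)) *
    s / sqrt(m)
  if (is.null(beta_init)) beta_init <- numeric(0)
  res <- maxent_solve_cpp(Fb, fbar, lambda, tol, as.integer(max_iter),
                          as.numeric(beta_init))
  if (!res$converged)
    stop(sprintf("maxent solver did not converge (objective %.8g after %d iterations)",
                 res$objective, res$iterations))
  eta <- drop(Fb %*% res$beta)
  raw <- exp(eta - res$log_normalizer)
  H <- -sum(raw * log(raw))
  structure(list(expansion = expansion, beta = drop(res$beta), rm = rm,
                 log_normalizer = res$log_normalizer, entropy = H,
                 n_presence = m, background_cells = background_cells,
                 objective = res$objective, iterations = res$iterations),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model:%s rm=%g> %d/%d nonzero features, m=%d, H=%.4f\n",
              x$expansion$combo, x$rm, sum(x$beta != 0), length(x$beta),
              x$n_presence, x$entropy))
  invisible(x)
}

#' Raw (relative occurrence rate) prediction
#'
#' `raw_i = exp(beta' f(x_i) - log_normalizer)`; on the training
#' background this sums to 1.
#'
#' @param model a [fit_maxent()] result.
#' @param env an [env_stack()] covering the cells.
#' @param cells integer cell ids, or a [region_mask()] whose member cells
#'   are used. Default: the model's training background.
#' @return numeric vector of raw values (one per cell).
#' @export
predict_raw <- function(model, env = NULL, cells = model$background_cells) {
  if (inherits(cells, "region_mask")) cells <- mask_cells(cells)
  Fm <- if (is.null(env)) {
    model$expansion$F_bg[bg_rows(model$expansion, cells), , drop = FALSE]
  } else {
    feature_matrix(model$expansion, env, cells)
  }
  exp(drop(Fm %*% model$beta) - model$log_normalizer)
}

#' Cloglog-transformed prediction
#'
#' `cloglog_i = 1 - exp(-exp(H) * raw_i)` with `H` the entropy of the
#' training background distribution (fixed at training time for any
#' prediction extent). Strictly increasing in raw; 0 at raw = 0.
#'
#' @param model a [fit_maxent()] result.
#' @param raw numeric vector of raw predictions.
#' @return numeric vector in `[0, 1)`.
#' @export
predict_cloglog <- function(model, raw) {
  1 - exp(-exp(model$entropy) * raw)
}

#' Permutation importance of variables
#'
#' For each variable, its values are permuted jointly across the
#' background (presences, being background cells, inherit the permuted
#' values), all features of that variable are recomputed, and the drop
#' in training AUC (presences vs background, no refitting) is measured.
#' Negative drops are floored at 0 and the result normalized to sum to
#' 100 (an all-zero profile is split uniformly).
#'
#' @param model a [fit_maxent()] result.
#' @param presence_cells,background_cells cell ids; default the model's
#'   training background.
#' @param env an [env_stack()] with the original variable values.
#' @param seed integer seed for the permutations.
#' @return named numeric vector of percentages summing to 100.
#' @export
permutation_importance <- function(model, presence_cells,
                                   background_cells = model$background_cells,
                                   env, seed = 1) {
  expn <- model$expansion
  brow <- bg_rows(expn, background_cells)
  prow_in_bg <- match(presence_cells, background_cells)
  if (anyNA(prow_in_bg)) stop("presences must be background cells")
  V <- vapply(expn$variables, function(v) env$layers[[v]][background_cells],
              numeric(length(background_cells)))
  V <- matrix(V, nrow = length(background_cells),
              dimnames = list(NULL, expn$variables))
  score <- function(Vmat) {
    Fm <- feature_matrix_from_values(expn, Vmat)
    eta <- drop(Fm %*% model$beta)
    roc_auc(eta[prow_in_bg], eta)
  }
  auc0 <- score(V)
  drops <- with_seed(seed, {
    vapply(seq_along(expn$variables), function(j) {
      Vp <- V
      Vp[, j] <- V[sample.int(nrow(V)), j]
      max(0, auc0 - score(Vp))
    }, numeric(1))
  })
  names(drops) <- expn$variables
  if (sum(drops) == 0) {
    rep(100 / length(drops), length(drops)) |> setNames(expn$variables)
  } else {
    100 * drops / sum(drops)
  }
}

#' Sample-size corrected AIC of a maxent model
#'
#' `K` is the number of nonzero coefficients; the log-likelihood is the
#' sum over presences of the log raw prediction standardized to sum to 1
#' over the full native grid; `AICc = 2K - 2 lnL + 2K(K+1)/(n-K-1)` with
#' `n` the presence count. Returns `NA` (unavailable) when
#' `n - K - 1 <= 0` or any presence has zero raw prediction.
#'
#' @param model a [fit_maxent()] result.
#' @param presence_cells integer cell ids of the presences.
#' @param raw_full raw prediction over the full native grid.
#' @param raw_cells the cell ids `raw_full` corresponds to; default the
#'   expansion's background cells.
#' @return AICc, or `NA_real_` when unavailable.
#' @export
aicc <- function(model, presence_cells, raw_full,
                 raw_cells = model$expansion$cells) {
  K <- sum(model$beta != 0)
  n <- length(presence_cells)
  p <- raw_full / sum(raw_full)
  pr <- p[match(presence_cells, raw_cells)]
  if (anyNA(pr)) stop("presence cells not covered by raw_full")
  if (n - K - 1 <= 0 || any(pr == 0)) return(NA_real_)
  lnL <- sum(log(pr))
  2 * K - 2 * lnL + 2 * K * (K + 1) / (n - K - 1)
}
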