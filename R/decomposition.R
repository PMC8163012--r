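# Decomposition of molecular substituent constants into additive
# per-substituent contributions. All forms fix the baseline group (default
# "H") at alpha = 0, so alpha reads as the inductive effect relative to the
# unsubstituted scaffold. With barriers as the response and rho > 0, a
# negative alpha marks an electron-withdrawing group (it lowers the barrier
# of the negatively charged transition state).

.decay_fun <- function(form) {
  switch(form,
         power = function(d, t) d^(-t),
         exponential = function(d, t) exp(-d / t),
         stop("unknown decay form '", form, "'"))
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "+")
}

# groups matrix (n_sets x n_positions) from set keys
.groups_matrix <- function(keys, positions) {
  gl <- split_set_key(keys)
  len <- lengths(gl)
  if (any(len != length(positions))) {
    stop("substituent-set key arity does not match the position vocabulary")
  }
  m <- do.call(rbind, gl)
  colnames(m) <- positions
  m
}

.new_alpha_model <- function(form, ...) {
  structure(list(form = form, ...), class = "alpha_model")
}

#' @export
print.alpha_model <- function(x, ...) {
  cat("alpha_model (", x$form, "), baseline '", x$baseline_group,
      "'", sep = "")
  if (!is.null(x$decay_param)) {
    cat(", decay parameter ", format(x$decay_param),
        if (!isTRUE(x$decay_identifiable)) " (not identifiable)")
  }
  cat("; R^2 = ", format(x$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Categorical (dummy-encoding) decomposition of molecular sigma
#'
#' Least-squares fit of \eqn{\sigma_{mol}(s) = \sum_p \alpha_{g_p(s),p}} with
#' the baseline group constrained to alpha = 0 at every position. One free
#' parameter per (group, position) pair: N_P * N_G parameters counting the
#' constrained baseline row. Needs no geometry.
#'
#' @param sigma named numeric vector of molecular sigma values; names are
#'   substituent-set keys (groups joined by `"|"` in position order).
#' @param positions character vector of position labels (key arity).
#' @param baseline_group group constrained to zero (default `"H"`, falling
#'   back to the lexicographically first observed group).
#' @return an `alpha_model` with `alpha_by_group_position` (groups x
#'   positions matrix), residual diagnostics, and `r_squared`.
#' @export
fit_categorical <- function(sigma, positions, baseline_group = "H") {
  G <- .groups_matrix(names(sigma), positions)
  groups <- sort(unique(as.vector(G)))
  if (!baseline_group %in% groups) baseline_group <- groups[1L]
  free <- expand.grid(group = setdiff(groups, baseline_group),
                      position = positions, stringsAsFactors = FALSE)
  X <- matrix(0, nrow = length(sigma), ncol = nrow(free),
              dimnames = list(NULL, paste(free$group, free$position, sep = "@")))
  for (k in seq_len(nrow(free))) {
    X[, k] <- as.numeric(G[, free$position[k]] == free$group[k])
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("identifiability error: rank-deficient design; unresolvable ",
         "(group, position) pairs: ", paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, sigma)
  alpha <- matrix(0, nrow = length(groups), ncol = length(positions),
                  dimnames = list(groups, positions))
  alpha[cbind(free$group, free$position)] <- coefs
  fitted <- as.numeric(X %*% coefs)
  .new_alpha_model("categorical",
                   alpha_by_group_position = alpha, groups = groups,
                   positions = positions, baseline_group = baseline_group,
                   sse = sum((sigma - fitted)^2),
                   r_squared = r_squared(unname(sigma), fitted),
                   n_parameters = length(groups) * length(positions))
}

# Linear solve of alpha (and optionally beta) given a fixed decay parameter.
.decay_design <- function(G, groups, baseline_group, fd, pair_cols = NULL) {
  free_g <- setdiff(groups, baseline_group)
  X <- matrix(0, nrow = nrow(G), ncol = length(free_g),
              dimnames = list(NULL, free_g))
  for (g in free_g) X[, g] <- (G == matrix(g, nrow(G), ncol(G))) %*% fd
  if (!is.null(pair_cols)) X <- cbind(X, pair_cols)
  X
}

.profile_decay_fit <- function(sigma, G, groups, baseline_group, distances,
                               form, pair_cols = NULL,
                               grid = c(0.25, 0.5, 1, 2, 4),
                               bounds = c(0.1, 8)) {
  f <- .decay_fun(form)
  sse_at <- function(t) {
    X <- .decay_design(G, groups, baseline_group, f(distances, t), pair_cols)
    fit <- qr(X)
    co <- qr.coef(fit, sigma)
    co[is.na(co)] <- 0
    sum((sigma - as.numeric(X %*% co))^2)
  }
  sse_grid <- vapply(grid, sse_at, numeric(1))
  t0 <- grid[which.min(sse_grid)]
  # local refinement, clamped to an Angstrom-scale physical window: decay
  # constants far outside it only arise from degenerate small-sample fits
  opt <- optimize(sse_at, interval = c(max(t0 / 4, bounds[1L]),
                                       min(t0 * 4, bounds[2L])), tol = 1e-10)
  if (opt$objective <= min(sse_grid)) {
    list(t = opt$minimum, sse = opt$objective)
  } else {
    list(t = t0, sse = min(sse_grid))
  }
}

#' Distance-decay decomposition of molecular sigma
#'
#' Fits \eqn{\sigma_{mol}(s) = \sum_p \alpha_{g_p(s)} f(d_p)} where the decay
#' function is a power law \eqn{f(d) = d^{-\gamma}} or an exponential
#' \eqn{f(d) = e^{-d/\lambda}}; one alpha per group plus one decay parameter
#' (N_G + 1 parameters). The decay parameter is profiled: for each candidate
#' value the alphas solve a linear least-squares problem, and the candidate
#' is optimized from a multistart grid (0.25, 0.5, 1, 2, 4 on the Angstrom
#' scale). With a single position or all-equal distances the decay parameter
#' is not identifiable (the decay factor is a common scale absorbed into
#' alpha); it is then fixed at 1 and flagged.
#'
#' @inheritParams fit_categorical
#' @param geometry a `scaffold_geometry` covering all positions.
#' @param form `"power"` or `"exponential"`.
#' @return an `alpha_model` with `alpha_by_group`, `decay_param`,
#'   `decay_identifiable`, and diagnostics.
#' @export
fit_distance_decay <- function(sigma, geometry, form = c("power", "exponential"),
                               baseline_group = "H") {
  form <- match.arg(form)
  positions <- geometry$positions
  G <- .groups_matrix(names(sigma), positions)
  groups <- sort(unique(as.vector(G)))
  if (!baseline_group %in% groups) baseline_group <- groups[1L]
  d <- unname(geometry$distances[positions])
  identifiable <- length(positions) > 1L && length(unique(d)) > 1L
  f <- .decay_fun(form)
  if (identifiable) {
    prof <- .profile_decay_fit(sigma, G, groups, baseline_group, d, form)
    t_hat <- prof$t
  } else {
    t_hat <- 1
  }
  X <- .decay_design(G, groups, baseline_group, f(d, t_hat))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("identifiability error: unresolvable group(s): ",
         paste(bad, collapse = ", "))
  }
  co <- qr.coef(qx, sigma)
  alpha <- setNames(rep(0, length(groups)), groups)
  alpha[names(co)] <- co
  fitted <- as.numeric(X %*% co)
  .new_alpha_model(form,
                   alpha_by_group = alpha, groups = groups,
                   positions = positions, baseline_group = baseline_group,
                   decay_param = t_hat, decay_identifiable = identifiable,
                   distances = setNames(d, positions),
                   sse = sum((sigma - fitted)^2),
                   r_squared = r_squared(unname(sigma), fitted),
                   n_parameters = length(groups) + 1L)
}

# Axilrod-Teller-Muto geometric factor for the triangle (p, q, center):
# (1 + 3 cos t_p cos t_q cos t_C) / (d_pC d_qC d_pq)^3, with the interior
# angles of the triangle.
atm_geometry_factor <- function(geometry) {
  if (is.null(geometry$coordinates)) {
    stop("geometry error: three-body model requires Cartesian coordinates")
  }
  pos <- geometry$positions
  C <- geometry$reaction_center
  xyz <- geometry$coordinates
  pairs <- utils::combn(pos, 2L)
  out <- numeric(ncol(pairs))
  names(out) <- paste(pairs[1L, ], pairs[2L, ], sep = "+")
  for (k in seq_len(ncol(pairs))) {
    p <- xyz[pairs[1L, k], ]; q <- xyz[pairs[2L, k], ]
    d_pC <- sqrt(sum((p - C)^2)); d_qC <- sqrt(sum((q - C)^2))
    d_pq <- sqrt(sum((p - q)^2))
    if (min(d_pC, d_qC, d_pq) < 1e-9) {
      stop("geometry error: coincident points in triangle (",
           pairs[1L, k], ", ", pairs[2L, k], ", center)")
    }
    area <- sqrt(sum(pracma_cross(p - C, q - C)^2)) / 2
    if (area < 1e-9 * max(d_pC, d_qC, d_pq)^2) {
      stop("geometry error: collinear triangle (", pairs[1L, k], ", ",
           pairs[2L, k], ", center)")
    }
    cos_p <- sum((C - p) * (q - p)) / (d_pC * d_pq)
    cos_q <- sum((C - q) * (p - q)) / (d_qC * d_pq)
    cos_C <- sum((p - C) * (q - C)) / (d_pC * d_qC)
    out[k] <- (1 + 3 * cos_p * cos_q * cos_C) / (d_pC * d_qC * d_pq)^3
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Three-body (Axilrod-Teller-Muto) decomposition of molecular sigma
#'
#' Extends the distance-decay model with a pairwise interaction between the
#' groups at any two positions:
#' \deqn{\sigma_{mol} = \sum_p \alpha_{g_p} f(d_p) + \sum_{p<q}
#'   \beta_{\{g_p, g_q\}} \frac{1 + 3\cos\theta_p \cos\theta_q \cos\theta_C}
#'   {(d_{pC}\, d_{qC}\, d_{pq})^3}}
#' with the interior angles of the (position p, position q, reaction center)
#' triangle. One beta per unordered group pair, including same-group pairs:
#' N_G + (N_G^2 + N_G)/2 + 1 parameters in total. The baseline alpha is 0;
#' beta is unconstrained. The decay parameter is profiled as in
#' [fit_distance_decay()].
#'
#' @inheritParams fit_distance_decay
#' @return an `alpha_model` with `alpha_by_group`, `beta_by_pair`,
#'   `decay_param`, and diagnostics.
#' @export
fit_atm <- function(sigma, geometry, form = c("power", "exponential"),
                    baseline_group = "H") {
  form <- match.arg(form)
  positions <- geometry$positions
  G <- .groups_matrix(names(sigma), positions)
  groups <- sort(unique(as.vector(G)))
  if (!baseline_group %in% groups) baseline_group <- groups[1L]
  d <- unname(geometry$distances[positions])
  gfac <- atm_geometry_factor(geometry)

  # design block for the pair interactions (independent of the decay param)
  pair_keys <- apply(utils::combn(groups, 2L), 2L, paste, collapse = "+")
  pair_keys <- sort(c(pair_keys, paste(groups, groups, sep = "+")))
  P <- matrix(0, nrow = nrow(G), ncol = length(pair_keys),
              dimnames = list(NULL, pair_keys))
  pos_pairs <- utils::combn(positions, 2L)
  for (k in seq_len(ncol(pos_pairs))) {
    pk <- .pair_key(G[, pos_pairs[1L, k]], G[, pos_pairs[2L, k]])
    g_pq <- gfac[paste(pos_pairs[1L, k], pos_pairs[2L, k], sep = "+")]
    for (key in unique(pk)) P[pk == key, key] <- P[pk == key, key] + g_pq
  }
  observed_pairs <- colnames(P)[colSums(abs(P)) > 0]
  P <- P[, observed_pairs, drop = FALSE]

  identifiable <- length(positions) > 1L && length(unique(d)) > 1L
  if (identifiable) {
    prof <- .profile_decay_fit(sigma, G, groups, baseline_group, d, form,
                               pair_cols = P)
    t_hat <- prof$t
  } else {
    t_hat <- 1
  }
  f <- .decay_fun(form)
  X <- .decay_design(G, groups, baseline_group, f(d, t_hat), pair_cols = P)
  qx <- qr(X)
  co <- qr.coef(qx, sigma)
  co[is.na(co)] <- 0  # unidentifiable pair terms pinned at 0, reported below
  alpha <- setNames(rep(0, length(groups)), groups)
  free_g <- setdiff(groups, baseline_group)
  alpha[free_g] <- co[free_g]
  beta <- setNames(rep(0, length(pair_keys)), pair_keys)
  beta[observed_pairs] <- co[observed_pairs]
  fitted <- as.numeric(X %*% co)
  .new_alpha_model("atm",
                   decay_form = form,
                   alpha_by_group = alpha, beta_by_pair = beta,
                   groups = groups, positions = positions,
                   baseline_group = baseline_group,
                   decay_param = t_hat, decay_identifiable = identifiable,
                   distances = setNames(d, positions),
                   coordinates = geometry$coordinates,
                   reaction_center = geometry$reaction_center,
                   atm_factors = gfac,
                   sse = sum((sigma - fitted)^2),
                   r_squared = r_squared(unname(sigma), fitted),
                   n_parameters = length(groups) +
                     (length(groups)^2 + length(groups)) / 2 + 1L)
}

#' Predict molecular sigma from an additive decomposition
#'
#' Deterministic evaluation of the fitted form for any substituent set over
#' the model's group vocabulary — including sets never observed during
#' fitting, which is what makes the decomposition transferable.
#'
#' @param model an `alpha_model`.
#' @param substituent_set character vector of set keys, or a single named
#'   vector (position -> group).
#' @return numeric vector of predicted molecular sigma values.
#' @export
predict_sigma <- function(model, substituent_set) {
  stopifnot(inherits(model, "alpha_model"))
  if (!is.null(names(substituent_set))) {
    substituent_set <- set_key_from_groups(substituent_set[model$positions])
  }
  G <- .groups_matrix(substituent_set, model$positions)
  unknown <- setdiff(unique(as.vector(G)), model$groups)
  if (length(unknown) > 0L) {
    stop("lookup error: unknown group(s) ", paste(unknown, collapse = ", "))
  }
  if (model$form == "categorical") {
    out <- numeric(nrow(G))
    for (p in model$positions) {
      out <- out + model$alpha_by_group_position[cbind(G[, p], p)]
    }
    return(unname(out))
  }
  f <- .decay_fun(if (model$form == "atm") attr_decay(model) else model$form)
  fd <- f(unname(model$distances[model$positions]), model$decay_param)
  A <- matrix(model$alpha_by_group[as.vector(G)], nrow = nrow(G))
  out <- as.numeric(A %*% fd)
  if (model$form == "atm") {
    pos_pairs <- utils::combn(model$positions, 2L)
    for (k in seq_len(ncol(pos_pairs))) {
      pk <- .pair_key(G[, pos_pairs[1L, k]], G[, pos_pairs[2L, k]])
      g_pq <- model$atm_factors[paste(pos_pairs[1L, k], pos_pairs[2L, k],
                                      sep = "+")]
      out <- out + model$beta_by_pair[pk] * g_pq
    }
  }
  unname(out)
}

# ATM models store the radial form used for the one-body part in a field
# shared with the plain decay models; default power.
attr_decay <- function(model) {
  if (!is.null(model$decay_form)) model$decay_form else "power"
}

#' Parameter counts of the sigma decomposition models
#'
#' Closed-form parameter counts: categorical needs one term per (group,
#' position) pair, N_P * N_G; the distance-decay forms need one alpha per
#' group plus the decay constant, N_G + 1; the three-body form adds one beta
#' per unordered group pair (same-group pairs included),
#' N_G + (N_G^2 + N_G)/2 + 1; and the full additive Hammett model over a
#' dataset additionally carries one rho per reaction, N_R + N_G + 1.
#'
#' @param form one of `"categorical"`, `"power"`, `"exponential"`, `"atm"`,
#'   `"alpha_hammett_total"`.
#' @param n_groups,n_positions,n_reactions positive integers (`n_positions`
#'   only used by `categorical`, `n_reactions` only by
#'   `alpha_hammett_total`).
#' @return integer parameter count.
#' @export
count_parameters <- function(form, n_groups, n_positions = NULL,
                             n_reactions = NULL) {
  stopifnot(n_groups >= 1)
  switch(form,
         categorical = {
           stopifnot(!is.null(n_positions), n_positions >= 1)
           as.integer(n_positions * n_groups)
         },
         power = ,
         exponential = as.integer(n_groups + 1),
         atm = as.integer(n_groups + (n_groups^2 + n_groups) / 2 + 1),
         alpha_hammett_total = {
           stopifnot(!is.null(n_reactions), n_reactions >= 1)
           as.integer(n_reactions + n_groups + 1)
         },
         stop("unknown form '", form, "'"))
}

#' Coefficient of determination
#'
#' Standard \eqn{R^2 = 1 - SS_{res}/SS_{tot}} of model values against
#' reference values.
#'
#' @param sigma_true,sigma_model numeric vectors of equal length (>= 2).
#' @return numeric R-squared.
#' @export
r_squared <- function(sigma_true, sigma_model) {
  stopifnot(length(sigma_true) == length(sigma_model),
            length(sigma_true) >= 2L)
  ss_tot <- sum((sigma_true - mean(sigma_true))^2)
  if (ss_tot == 0) stop("degenerate input: zero variance in sigma_true")
  1 - sum((sigma_true - sigma_model)^2) / ss_tot
}
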