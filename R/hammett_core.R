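#' Theil-Sen slope estimator
#'
#' Robust slope of y against x: the median of the slopes of all lines through
#' each pair of points. Pairs with equal x are skipped; an even number of
#' slopes is resolved by the midpoint of the two central values (the
#' `stats::median` convention). Breakdown point is about 29 percent.
#'
#' @param x,y numeric vectors of equal length (>= 2 points).
#' @return the median pairwise slope.
#' @export
theil_sen_slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  dx <- outer(x, x, "-")
  keep <- upper.tri(dx) & dx != 0
  if (!any(keep)) {
    stop("degenerate input: all x values identical, no pairwise slope defined")
  }
  dy <- outer(y, y, "-")
  median(dy[keep] / dx[keep])
}

# Median of pairwise slope ratios in both orientations from one pass:
# slopes of (x -> y) are elementwise reciprocals of slopes of (y -> x).
.theil_sen_both <- function(x, y) {
  dx <- outer(x, x, "-")
  keep_xy <- upper.tri(dx) & dx != 0
  dy <- outer(y, y, "-")
  keep_yx <- upper.tri(dy) & dy != 0
  list(
    xy = if (any(keep_xy)) median(dy[keep_xy] / dx[keep_xy]) else NA_real_,
    yx = if (any(keep_yx)) median(dx[keep_yx] / dy[keep_yx]) else NA_real_)
}

#' Pairwise Theil-Sen slopes between reactions
#'
#' For every ordered reaction pair (i, j) sharing at least two substituent
#' sets, regresses the responses of reaction j on those of reaction i over
#' the common sets. Under the Hammett model the slope estimates
#' \eqn{\rho_j / \rho_i}. Pairs with fewer than two common sets (or whose
#' common responses are constant in the predictor) are omitted.
#'
#' @param table a `reaction_table`.
#' @return data.frame with columns `from`, `to`, `slope`, `support` (number
#'   of common substituent sets).
#' @export
pairwise_reaction_slopes <- function(table) {
  stopifnot(inherits(table, "reaction_table"))
  Y <- response_matrix(table)
  rxns <- colnames(Y)
  out <- list()
  n <- length(rxns)
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        ok <- complete.cases(Y[, c(a, b)])
        support <- sum(ok)
        if (support < 2L) next
        ts <- .theil_sen_both(Y[ok, a], Y[ok, b])
        if (!is.na(ts$xy)) {
          out[[length(out) + 1L]] <- data.frame(
            from = rxns[a], to = rxns[b], slope = ts$xy, support = support)
        }
        if (!is.na(ts$yx)) {
          out[[length(out) + 1L]] <- data.frame(
            from = rxns[b], to = rxns[a], slope = ts$yx, support = support)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(from = character(), to = character(),
                      slope = numeric(), support = integer()))
  }
  do.call(rbind, out)
}

# Wide response matrix: one row per substituent-set key, one column per
# reaction, NA where unobserved.
response_matrix <- function(table) {
  sk <- set_keys(table)
  Y <- matrix(NA_real_, nrow = length(sk$levels), ncol = length(table$reactions),
              dimnames = list(sk$levels, table$reactions))
  Y[cbind(match(sk$key, sk$levels),
          match(table$records$reaction_id, table$reactions))] <-
    table$records$response
  Y
}

# Connected components of the reaction graph implied by a slope table.
.reaction_components <- function(reactions, edges) {
  comp <- setNames(seq_along(reactions), reactions)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (k in seq_len(nrow(edges))) {
    i <- find(match(edges$from[k], reactions))
    j <- find(match(edges$to[k], reactions))
    if (i != j) comp[j] <- i
  }
  roots <- vapply(seq_along(reactions), find, integer(1))
  split(reactions, roots)
}

#' Solve for all reaction constants at once
#'
#' Given pairwise slope estimates \eqn{m_{ij} \approx \rho_j/\rho_i}, solves
#' the support-weighted least-squares system
#' \eqn{\log\rho_j - \log\rho_i = \log m_{ij}} over all supported pairs, then
#' rescales so that the anchor reaction has \eqn{\rho = 1}. Every pair
#' contributes, so no single reference reaction biases the result; the anchor
#' only fixes the overall scale (gauge).
#'
#' @param slopes data.frame from [pairwise_reaction_slopes()].
#' @param anchor reaction id whose rho is fixed to 1.
#' @param reactions optional full reaction vocabulary (defaults to ids seen in
#'   `slopes` plus the anchor).
#' @param allow_negative if `FALSE` (default) a non-positive slope is an
#'   error; if `TRUE`, signs are propagated over a maximum-support spanning
#'   tree and magnitudes fitted in log space.
#' @return named numeric vector of rho, anchor exactly 1.
#' @export
fit_global_rho <- function(slopes, anchor, reactions = NULL,
                           allow_negative = FALSE) {
  if (is.null(reactions)) {
    reactions <- sort(unique(c(slopes$from, slopes$to, anchor)))
  }
  if (!anchor %in% reactions) stop("anchor reaction '", anchor, "' unknown")
  if (length(reactions) == 1L) return(setNames(1, reactions))

  comps <- .reaction_components(reactions, slopes)
  if (length(comps) > 1L) {
    stop("connectivity error: reaction graph is disconnected; components: ",
         paste(vapply(comps, paste, "", collapse = ","), collapse = " / "))
  }
  sgn <- setNames(rep(1, length(reactions)), reactions)
  if (any(slopes$slope == 0)) stop("sign error: zero pairwise slope")
  if (any(slopes$slope < 0)) {
    if (!allow_negative) {
      stop("sign error: non-positive pairwise slope encountered; ",
           "set allow_negative = TRUE to propagate signs")
    }
    # propagate signs over a maximum-support spanning tree
    ord <- order(-slopes$support)
    seen <- setNames(rep(FALSE, length(reactions)), reactions)
    seen[anchor] <- TRUE
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (k in ord) {
        f <- slopes$from[k]; t <- slopes$to[k]
        if (seen[f] && !seen[t]) {
          sgn[t] <- sgn[f] * sign(slopes$slope[k]); seen[t] <- TRUE
          changed <- TRUE
        } else if (seen[t] && !seen[f]) {
          sgn[f] <- sgn[t] * sign(slopes$slope[k]); seen[f] <- TRUE
          changed <- TRUE
        }
      }
    }
  }

  # weighted LS on log|m| with the anchor's log-rho fixed at 0
  idx <- setNames(seq_along(reactions), reactions)
  free <- setdiff(reactions, anchor)
  A <- matrix(0, nrow = nrow(slopes), ncol = length(free),
              dimnames = list(NULL, free))
  b <- log(abs(slopes$slope))
  for (k in seq_len(nrow(slopes))) {
    f <- slopes$from[k]; t <- slopes$to[k]
    if (t != anchor) A[k, t] <- 1
    if (f != anchor) A[k, f] <- -1
  }
  w <- sqrt(slopes$support)
  fit <- qr.solve(A * w, b * w)
  logrho <- setNames(rep(0, length(reactions)), reactions)
  logrho[free] <- fit
  rho <- sgn * exp(logrho) / (sgn[anchor])
  rho[anchor] <- 1  # exact by construction
  rho[reactions]
}

#' Recover substituent constants and per-reaction offsets
#'
#' With rho fixed, alternates robust coordinate updates until convergence:
#' the offset \eqn{c_j} is the median over substituent sets observed in
#' reaction j of \eqn{y_{s,j} - \rho_j \sigma_s}, and each \eqn{\sigma_s} is
#' the unweighted mean over reactions observing s of
#' \eqn{(y_{s,j} - c_j)/\rho_j} (inverting the Hammett equation and averaging
#' over reactions). Finally the gauge is shifted so the reference substituent
#' set has sigma exactly 0, with the offsets absorbing the shift.
#'
#' @param table a `reaction_table`.
#' @param rho named numeric vector of reaction constants.
#' @param weighted if `TRUE`, average sigma across reactions with weights
#'   proportional to `rho^2` (precision of the inverted equation); default
#'   unweighted.
#' @param tol convergence tolerance on the max parameter change.
#' @param max_iter iteration cap.
#' @return list with named vectors `sigma` (by substituent-set key) and
#'   `offsets` (by reaction), plus `iterations` and `converged`.
#' @export
fit_sigma_offsets <- function(table, rho, weighted = FALSE, tol = 1e-10,
                              max_iter = 200L) {
  stopifnot(inherits(table, "reaction_table"))
  sk <- set_keys(table)
  y <- table$records$response
  j <- match(table$records$reaction_id, table$reactions)
  s <- match(sk$key, sk$levels)
  rho <- rho[table$reactions]
  if (anyNA(rho)) stop("rho missing for some reactions")
  rho_r <- unname(rho)[j]

  sigma <- setNames(rep(0, length(sk$levels)), sk$levels)
  offsets <- setNames(rep(0, length(table$reactions)), table$reactions)
  w <- if (weighted) rho_r^2 else rep(1, length(y))
  rho_by_rxn <- unname(rho)

  # the model is invariant along the gauge orbit sigma -> sigma + e,
  # c_j -> c_j - rho_j e; the median/mean disagreement would otherwise drift
  # the iterates along it indefinitely, so each iteration pins the gauge
  ref <- reference_key(table)
  pin_gauge <- function(sig, offs) {
    shift <- if (ref %in% names(sig)) sig[[ref]] else mean(sig)
    list(sigma = sig - shift, offsets = offs + rho_by_rxn * shift)
  }

  sigma_prev2 <- NULL
  offs_prev2 <- NULL
  for (it in seq_len(max_iter)) {
    # the median c-step is piecewise constant, so on noisy data the
    # iteration can fall into a small two-cycle straddling the solution;
    # damping shrinks the step and a period-2 repeat is resolved by taking
    # the cycle midpoint (exact fits converge undamped within a few steps)
    damp <- if (it > 30L) 0.5 else 1
    c_new <- tapply(y - rho_r * sigma[s], j, median)
    c_rec <- as.numeric(c_new)[match(j, as.integer(names(c_new)))]
    contrib <- (y - c_rec) / rho_r
    s_new <- vapply(split(seq_along(y), s), function(ix) {
      sum(w[ix] * contrib[ix]) / sum(w[ix])
    }, numeric(1))
    sigma_new <- sigma
    sigma_new[as.integer(names(s_new))] <- s_new
    offs_new <- offsets
    offs_new[as.integer(names(c_new))] <- as.numeric(c_new)
    sigma_new <- sigma + damp * (sigma_new - sigma)
    offs_new <- offsets + damp * (offs_new - offsets)
    pinned <- pin_gauge(sigma_new, offs_new)
    sigma_new <- pinned$sigma
    offs_new <- setNames(pinned$offsets, table$reactions)
    delta <- max(abs(sigma_new - sigma), abs(offs_new - offsets))
    if (!is.null(sigma_prev2)) {
      delta2 <- max(abs(sigma_new - sigma_prev2), abs(offs_new - offs_prev2))
      if (delta2 < tol && delta >= tol) {
        sigma <- (sigma_new + sigma) / 2
        offsets <- setNames((offs_new + offsets) / 2, table$reactions)
        return(.apply_sigma_gauge(table, rho, sigma, offsets, it, TRUE))
      }
    }
    sigma_prev2 <- sigma
    offs_prev2 <- offsets
    sigma <- sigma_new
    offsets <- setNames(offs_new, table$reactions)
    if (delta < tol) {
      return(.apply_sigma_gauge(table, rho, sigma, offsets, it, TRUE))
    }
  }
  warning("fit_sigma_offsets: no convergence after ", max_iter,
          " iterations (last max change ", format(delta), ")")
  .apply_sigma_gauge(table, rho, sigma, offsets, max_iter, FALSE)
}

.apply_sigma_gauge <- function(table, rho, sigma, offsets, iterations,
                               converged) {
  ref <- reference_key(table)
  if (ref %in% names(sigma)) {
    shift <- sigma[[ref]]
    sigma <- sigma - shift
    offsets <- offsets + unname(rho[names(offsets)]) * shift
    sigma[[ref]] <- 0  # exact
  }
  list(sigma = sigma, offsets = offsets, iterations = iterations,
       converged = converged)
}

#' Global (reference-free) Hammett fit
#'
#' The full revised procedure: Theil-Sen slopes over every supported reaction
#' pair, a single weighted least-squares solve for all reaction constants
#' at once (anchored to rho = 1 for one reaction, which fixes only the
#' scale), then substituent constants by inverting the model and averaging
#' over reactions. The result does not depend on input row order, and apart
#' from the anchor gauge does not depend on any reference-reaction choice.
#'
#' @param table a `reaction_table`.
#' @param anchor reaction id fixed to rho = 1; default the lexicographically
#'   first reaction.
#' @param allow_negative passed to [fit_global_rho()].
#' @param weighted passed to [fit_sigma_offsets()].
#' @return object of class `hammett_params` with fields `rho`, `sigma`,
#'   `offsets`, `anchor_reaction`, `method`, `reference_set_key`, and fit
#'   diagnostics.
#' @export
fit_sigma_hammett <- function(table, anchor = NULL, allow_negative = FALSE,
                              weighted = FALSE) {
  stopifnot(inherits(table, "reaction_table"))
  if (is.null(anchor)) anchor <- table$reactions[1L]
  slopes <- pairwise_reaction_slopes(table)
  rho <- fit_global_rho(slopes, anchor, reactions = table$reactions,
                        allow_negative = allow_negative)
  so <- fit_sigma_offsets(table, rho, weighted = weighted)
  structure(
    list(rho = rho, sigma = so$sigma, offsets = so$offsets,
         anchor_reaction = anchor, method = "sigma_hammett_global",
         reference_set_key = reference_key(table),
         iterations = so$iterations, converged = so$converged),
    class = "hammett_params")
}

#' @export
print.hammett_params <- function(x, ...) {
  cat("hammett_params (", x$method, "): ", length(x$rho), " reactions, ",
      length(x$sigma), " substituent sets; anchor '", x$anchor_reaction,
      "' (rho = 1)\n", sep = "")
  invisible(x)
}

#' Original sequential Hammett procedure
#'
#' Hammett's classic recipe: (i) pick a reference reaction and fix its rho to
#' 1, (ii) read off sigma for the substituent sets it observes, (iii) fit the
#' next reaction's rho (and offset) by ordinary least squares against the
#' known sigmas, (iv) extend the sigma set using the new rho, (v) repeat.
#' The outcome depends on the reference reaction and on the expansion order;
#' with N_R reactions up to N_R! distinct parameter sets exist.
#'
#' @param table a `reaction_table`.
#' @param reference_reaction reaction fixed to rho = 1; must observe the
#'   reference substituent set (its offset is read there directly).
#' @param expansion_order optional explicit order over the remaining
#'   reactions. Default: repeatedly take the reaction sharing the most
#'   already-assigned substituent sets.
#' @return a `hammett_params` with `method = "original_hammett"`; reactions or
#'   sets unreachable by the expansion are reported in `unassigned_reactions`
#'   / `unassigned_sets`.
#' @export
original_hammett_fit <- function(table, reference_reaction,
                                 expansion_order = NULL) {
  stopifnot(inherits(table, "reaction_table"))
  if (!reference_reaction %in% table$reactions) {
    stop("configuration error: unknown reference reaction '",
         reference_reaction, "'")
  }
  Y <- response_matrix(table)
  ref_key <- reference_key(table)
  if (!(ref_key %in% rownames(Y)) || is.na(Y[ref_key, reference_reaction])) {
    stop("configuration error: reference reaction '", reference_reaction,
         "' does not observe the reference substituent set")
  }
  rho <- setNames(rep(NA_real_, ncol(Y)), colnames(Y))
  offsets <- rho
  sigma <- setNames(rep(NA_real_, nrow(Y)), rownames(Y))

  rho[reference_reaction] <- 1
  offsets[reference_reaction] <- Y[ref_key, reference_reaction]
  obs <- !is.na(Y[, reference_reaction])
  sigma[obs] <- Y[obs, reference_reaction] - offsets[reference_reaction]

  remaining <- setdiff(colnames(Y), reference_reaction)
  if (!is.null(expansion_order)) {
    if (!setequal(expansion_order, remaining)) {
      stop("configuration error: expansion_order must list every non-",
           "reference reaction exactly once")
    }
  }
  repeat {
    if (length(remaining) == 0L) break
    n_known <- vapply(remaining, function(r) {
      sum(!is.na(Y[, r]) & !is.na(sigma))
    }, integer(1))
    nxt <- if (!is.null(expansion_order)) {
      cand <- expansion_order[expansion_order %in% remaining][1L]
      if (n_known[cand] < 2L) NA_character_ else cand
    } else {
      if (max(n_known) < 2L) NA_character_ else remaining[which.max(n_known)]
    }
    if (is.na(nxt)) break  # unreachable from the covered set
    use <- !is.na(Y[, nxt]) & !is.na(sigma)
    fit <- lm(Y[use, nxt] ~ sigma[use])
    offsets[nxt] <- coef(fit)[[1L]]
    rho[nxt] <- coef(fit)[[2L]]
    new_sets <- !is.na(Y[, nxt]) & is.na(sigma)
    sigma[new_sets] <- (Y[new_sets, nxt] - offsets[nxt]) / rho[nxt]
    remaining <- setdiff(remaining, nxt)
  }

  unassigned_rxn <- names(rho)[is.na(rho)]
  unassigned_set <- names(sigma)[is.na(sigma)]
  structure(
    list(rho = rho[!is.na(rho)], sigma = sigma[!is.na(sigma)],
         offsets = offsets[!is.na(offsets)],
         anchor_reaction = reference_reaction, method = "original_hammett",
         reference_set_key = ref_key,
         unassigned_reactions = unassigned_rxn,
         unassigned_sets = unassigned_set),
    class = "hammett_params")
}

#' Predict responses from fitted Hammett parameters
#'
#' Evaluates \eqn{\hat y = c_j + \rho_j \sigma_s}. Both reaction and
#' substituent set must be present in the fitted parameters; extrapolation to
#' unseen sets is the job of the additive sigma decomposition.
#'
#' @param object a `hammett_params`.
#' @param reaction_id character vector of reaction ids.
#' @param substituent_set character vector of substituent-set keys (groups
#'   joined by `"|"` in position order), recycled against `reaction_id`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.hammett_params <- function(object, reaction_id, substituent_set, ...) {
  n <- max(length(reaction_id), length(substituent_set))
  reaction_id <- rep_len(reaction_id, n)
  substituent_set <- rep_len(substituent_set, n)
  bad_r <- setdiff(unique(reaction_id), names(object$rho))
  if (length(bad_r) > 0L) {
    stop("lookup error: unknown reaction(s) ", paste(bad_r, collapse = ", "))
  }
  bad_s <- setdiff(unique(substituent_set), names(object$sigma))
  if (length(bad_s) > 0L) {
    stop("lookup error: unknown substituent set(s) ",
         paste(bad_s, collapse = ", "))
  }
  unname(object$offsets[reaction_id] +
           object$rho[reaction_id] * object$sigma[substituent_set])
}

# Predictions for every record of a table; NA where parameters lack coverage.
predict_table <- function(params, table) UseMethod("predict_table")

#' @export
predict_table.hammett_params <- function(params, table) {
  sk <- set_keys(table)
  r <- table$records$reaction_id
  ok <- r %in% names(params$rho) & sk$key %in% names(params$sigma)
  out <- rep(NA_real_, nrow(table$records))
  if (any(ok)) {
    out[ok] <- unname(params$offsets[r[ok]] +
                        params$rho[r[ok]] * params$sigma[sk$key[ok]])
  }
  out
}

#' Mean absolute error of a fitted model on a table
#'
#' Records whose reaction or substituent set is not covered by the parameters
#' are skipped and counted.
#'
#' @param params a `hammett_params` (or any object with a `predict_table`
#'   compatible structure).
#' @param table a `reaction_table`.
#' @param per `"global"` for one pooled MAE, `"reaction"` for a named vector.
#' @return numeric MAE (global) or named vector; attribute `n_skipped` gives
#'   the number of uncovered records.
#' @export
evaluate_mae <- function(params, table, per = c("global", "reaction")) {
  per <- match.arg(per)
  yhat <- predict_table(params, table)
  ok <- !is.na(yhat)
  if (!any(ok)) stop("evaluation error: no record covered by the parameters")
  err <- abs(yhat[ok] - table$records$response[ok])
  res <- if (per == "global") {
    mean(err)
  } else {
    vapply(split(err, table$records$reaction_id[ok]), mean, numeric(1))
  }
  attr(res, "n_skipped") <- sum(!ok)
  res
}

#' Number of parameter sets reachable by the original procedure
#'
#' The sequential procedure can visit up to N_R! distinct (rho, sigma) sets
#' for N_R reactions. Returned exactly: as a numeric for N_R <= 18 (where
#' the factorial is exactly representable as a double), as an exact decimal
#' string for larger N_R.
#'
#' @param n_reactions positive integer.
#' @return numeric (n <= 18) or character (exact decimal, n > 18).
#' @export
enumeration_bound <- function(n_reactions) {
  stopifnot(length(n_reactions) == 1L, n_reactions >= 1)
  n <- as.integer(n_reactions)
  if (n <= 18L) return(prod(as.numeric(seq_len(n))))
  # schoolbook base-1e9 multiplication for exactness beyond double range
  digits <- 1  # little-endian base-1e9 limbs
  base <- 1e9
  for (k in 2:n) {
    digits <- digits * k
    carry <- 0
    for (i in seq_along(digits)) {
      v <- digits[i] + carry
      digits[i] <- v %% base
      carry <- v %/% base
    }
    while (carry > 0) {
      digits <- c(digits, carry %% base)
      carry <- carry %/% base
    }
  }
  limbs <- rev(digits)  # big-endian
  paste0(c(format(limbs[1L], scientific = FALSE),
           if (length(limbs) > 1L) sprintf("%09.0f", limbs[-1L])),
         collapse = "")
}
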