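#' Fit the additive (alpha-) Hammett model
#'
#' The additive model writes the response as
#' \eqn{y_{s,j} = c_j + \rho_j \, \hat\sigma(s)} with the molecular sigma
#' assembled from per-group contributions,
#' \eqn{\hat\sigma(s) = \sum_p \alpha_{g_p(s)} f(d_p)} (decay forms; the
#' categorical and three-body forms are also available). In the decay forms
#' the whole model carries only N_R + N_G + 1 parameters and generalizes to
#' substituent sets never seen in training.
#'
#' Two fitting modes:
#' \describe{
#'   \item{two-stage (default)}{first the global reference-free Hammett fit
#'     ([fit_sigma_hammett()]) for rho, offsets and molecular sigma, then the
#'     decomposition of those sigmas. Requires enough pairwise support to
#'     connect the reaction graph.}
#'   \item{joint (`joint = TRUE`)}{alternating least squares on rho, offsets
#'     and the decomposition together, initialized from the two-stage fit
#'     when possible and from a neutral gauge (rho = 1, offsets = per-
#'     reaction medians) otherwise. Fittable from very small samples — the
#'     regime where the additive model is most useful, e.g. as a delta-ML
#'     baseline.}
#' }
#'
#' @param table a `reaction_table`.
#' @param geometry a `scaffold_geometry` (required for decay/atm forms).
#' @param form decomposition form: `"power"`, `"exponential"`,
#'   `"categorical"`, or `"atm"`.
#' @param anchor anchor reaction for the rho gauge (default lexicographically
#'   first fitted reaction).
#' @param joint logical; use the alternating joint fit.
#' @param joint_iter iterations of the alternation (default 15).
#' @param allow_negative passed to the first stage; default `TRUE` here
#'   (on sparse subsamples an occasional sign-flipped slope estimate is
#'   noise, and sign propagation keeps the fit going).
#' @return object of class `alpha_hammett` bundling per-reaction `rho` and
#'   `offsets` with the `alpha_model` in field `alpha`.
#' @export
fit_alpha_hammett <- function(table, geometry = NULL,
                              form = c("power", "exponential", "categorical",
                                       "atm"),
                              anchor = NULL, joint = FALSE, joint_iter = 15L,
                              allow_negative = TRUE) {
  form <- match.arg(form)
  baseline_group <- table$reference_set[[1L]]
  fit_decomp <- function(sig) {
    switch(form,
           categorical = fit_categorical(sig, table$positions,
                                         baseline_group = baseline_group),
           atm = fit_atm(sig, geometry, baseline_group = baseline_group),
           fit_distance_decay(sig, geometry, form = form,
                              baseline_group = baseline_group))
  }

  sk <- set_keys(table)
  y <- table$records$response
  rid <- table$records$reaction_id

  two_stage <- tryCatch({
    hp <- fit_sigma_hammett(table, anchor = anchor,
                            allow_negative = allow_negative)
    list(rho = hp$rho, offsets = hp$offsets, sigma = hp$sigma,
         anchor = hp$anchor_reaction)
  }, error = function(e) NULL)
  if (is.null(two_stage) && !joint) {
    stop("two-stage alpha-Hammett fit failed (reaction graph too sparse?); ",
         "retry with joint = TRUE")
  }

  if (!is.null(two_stage)) {
    rho <- two_stage$rho; offsets <- two_stage$offsets
    am <- fit_decomp(two_stage$sigma)
    anchor <- two_stage$anchor
  } else {
    # neutral init for the joint mode
    rho <- setNames(rep(1, length(table$reactions)), table$reactions)
    offsets <- vapply(split(y, rid), median, numeric(1))[table$reactions]
    names(offsets) <- table$reactions
    inv <- y - offsets[rid]
    am <- fit_decomp(vapply(split(inv, sk$key), mean, numeric(1)))
    if (is.null(anchor)) anchor <- table$reactions[1L]
  }

  if (joint) {
    # prior strength (pseudo-observations) for partial pooling of the
    # per-reaction slopes: with a handful of records per reaction the OLS
    # slope is shrunk toward the consensus rho, preventing the unstable
    # near-singular updates a tiny sample can produce; with tens of records
    # the shrinkage is negligible
    k_pool <- 4
    for (it in seq_len(joint_iter)) {
      sig_hat <- predict_sigma(am, sk$key)
      rho_med <- median(rho)
      for (r in table$reactions) {
        ix <- rid == r
        n_r <- sum(ix)
        if (n_r >= 2L && sd(sig_hat[ix]) > 0) {
          fit <- lm(y[ix] ~ sig_hat[ix])
          rho[r] <- (n_r * coef(fit)[[2L]] + k_pool * rho_med) /
            (n_r + k_pool)
        }
        offsets[r] <- mean(y[ix] - rho[r] * sig_hat[ix])
      }
      rho[abs(rho) < 1e-8] <- 1e-8  # keep the inversion defined
      inv <- (y - offsets[rid]) / rho[rid]
      w <- rho[rid]^2  # precision weights for the pooled inversion
      sig_pool <- vapply(split(seq_along(y), sk$key), function(ix) {
        sum(w[ix] * inv[ix]) / sum(w[ix])
      }, numeric(1))
      am <- fit_decomp(sig_pool)
    }
    # gauge: anchor rho to 1, absorb the scale into alpha (and beta)
    s <- rho[[anchor]]
    rho <- rho / s
    if (!is.null(am$alpha_by_group)) am$alpha_by_group <- am$alpha_by_group * s
    if (!is.null(am$alpha_by_group_position)) {
      am$alpha_by_group_position <- am$alpha_by_group_position * s
    }
    if (!is.null(am$beta_by_pair)) am$beta_by_pair <- am$beta_by_pair * s
  }

  structure(list(rho = rho, offsets = offsets, alpha = am,
                 anchor_reaction = anchor,
                 method = paste0("alpha_hammett_", form,
                                 if (joint) "_joint"),
                 reference_set_key = reference_key(table),
                 fallback_rho = exp(mean(log(abs(rho)))) *
                   sign(median(rho)),
                 fallback_offset = mean(offsets)),
            class = "alpha_hammett")
}

#' @export
print.alpha_hammett <- function(x, ...) {
  cat("alpha_hammett (", x$method, "): ", length(x$rho),
      " reactions; decomposition R^2 = ",
      format(x$alpha$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict responses from an additive Hammett model
#'
#' Unlike the plain global fit, the additive model generalizes to substituent
#' sets outside the training table. Reactions absent from training fall back
#' to the geometric-mean rho and mean offset of the fitted reactions (flagged
#' via the `"n_fallback"` attribute); this keeps the model defined as a
#' delta-ML baseline on arbitrary splits.
#'
#' @param object an `alpha_hammett`.
#' @param reaction_id character vector of reaction ids.
#' @param substituent_set character vector of set keys (recycled).
#' @param ... unused.
#' @return numeric predictions with attribute `n_fallback`.
#' @export
predict.alpha_hammett <- function(object, reaction_id, substituent_set, ...) {
  n <- max(length(reaction_id), length(substituent_set))
  reaction_id <- rep_len(reaction_id, n)
  substituent_set <- rep_len(substituent_set, n)
  sig <- predict_sigma(object$alpha, substituent_set)
  known <- reaction_id %in% names(object$rho)
  rho <- ifelse(known, object$rho[reaction_id], object$fallback_rho)
  off <- ifelse(known, object$offsets[reaction_id], object$fallback_offset)
  out <- unname(off + rho * sig)
  attr(out, "n_fallback") <- sum(!known)
  out
}

# table-wise prediction used by evaluate/learning-curve machinery
#' @export
predict_table.alpha_hammett <- function(params, table) {
  sk <- set_keys(table)
  p <- predict(params, table$records$reaction_id, sk$key)
  attributes(p) <- NULL
  p
}
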