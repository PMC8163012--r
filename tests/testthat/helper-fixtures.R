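# Small in-code fixtures shared across test files.

# Minimal hand-written long-format table: one position, groups H/X/Y,
# two reactions with exact Hammett structure y = c_j + rho_j * sigma_s.
tiny_table <- function(rho = c(A = 1, B = 2), offs = c(A = 0.5, B = -1),
                       sigma = c(H = 0, X = 1, Y = -0.5)) {
  grid <- expand.grid(g = names(sigma), r = names(rho),
                      stringsAsFactors = FALSE)
  rec <- data.frame(reaction_id = grid$r, R1 = grid$g,
                    response = offs[grid$r] + rho[grid$r] * sigma[grid$g],
                    response_type = "log10_k", stringsAsFactors = FALSE)
  reaction_table(rec, positions = "R1",
                 reference_set = c(R1 = "H"))
}

# gauge-aligned comparison of fitted vs true hammett parameters: fitted
# sigma = scale * true sigma, rho = true rho / scale with the anchor at 1
expect_hammett_recovery <- function(fit, truth, tol = 1e-8) {
  scale <- truth$rho[[fit$anchor_reaction]]
  expect_equal(unname(fit$rho[names(truth$rho)]),
               unname(truth$rho / scale), tolerance = tol)
  sig_true <- truth$sigma[names(fit$sigma)] * scale
  expect_equal(unname(fit$sigma), unname(sig_true), tolerance = tol)
  expect_equal(unname(fit$offsets[names(truth$offsets)]),
               unname(truth$offsets), tolerance = tol)
}

# random beta pair-interaction map over the default sn2 groups
random_pair_beta <- function(groups = c("H", "NO2", "CN", "NH2", "CH3"),
                             seed = 42, sd = 15) {
  g <- sort(groups)
  keys <- sort(c(apply(utils::combn(g, 2), 2, paste, collapse = "+"),
                 paste(g, g, sep = "+")))
  hammettr:::with_seed(seed, stats::setNames(stats::rnorm(length(keys), 0, sd),
                                             keys))
}

# OLS analogue of pairwise_reaction_slopes, used as the non-robust control
ols_reaction_slopes <- function(tbl) {
  Y <- hammettr:::response_matrix(tbl)
  out <- list()
  for (a in seq_len(ncol(Y) - 1)) {
    for (b in seq(a + 1, ncol(Y))) {
      ok <- stats::complete.cases(Y[, c(a, b)])
      if (sum(ok) < 2) next
      out[[length(out) + 1]] <- data.frame(
        from = colnames(Y)[a], to = colnames(Y)[b],
        slope = stats::coef(stats::lm(Y[ok, b] ~ Y[ok, a]))[[2]],
        support = sum(ok))
      out[[length(out) + 1]] <- data.frame(
        from = colnames(Y)[b], to = colnames(Y)[a],
        slope = stats::coef(stats::lm(Y[ok, a] ~ Y[ok, b]))[[2]],
        support = sum(ok))
    }
  }
  do.call(rbind, out)
}

# worst relative deviation of all fitted rho ratios from the true ratios
max_ratio_deviation <- function(rho_hat, rho_true) {
  rho_true <- rho_true[names(rho_hat)]
  M <- outer(rho_hat, rho_hat, "/") / outer(rho_true, rho_true, "/")
  max(abs(M - 1))
}
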