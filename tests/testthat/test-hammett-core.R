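# global Theil-Sen Hammett fit: slopes, rho solve, sigma/offsets, the
# original sequential procedure, prediction and scoring

# independent oracle: explicit double loop over all point pairs
brute_force_ts <- function(x, y) {
  s <- c()
  for (a in seq_along(x)) for (b in seq_along(x)) {
    if (b > a && x[b] != x[a]) s <- c(s, (y[b] - y[a]) / (x[b] - x[a]))
  }
  median(s)
}

test_that("theil_sen_slope matches hand cases and the exhaustive enumeration oracle", {
  expect_equal(theil_sen_slope(c(0, 1, 2), c(0, 2, 4)), 2.0)
  expect_equal(theil_sen_slope(c(0, 1, 2), c(5, 5, 5)), 0.0)
  # 4-point case: slopes {1, 1, 10/3, 1, 9/2, 8}, even count -> midpoint
  x <- c(0, 1, 2, 3); y <- c(0, 1, 2, 10)
  expect_equal(brute_force_ts(x, y), (1 + 10 / 3) / 2)
  expect_equal(theil_sen_slope(x, y), brute_force_ts(x, y))
  expect_error(theil_sen_slope(c(1, 1, 1), c(1, 2, 3)), "degenerate")

  # property: agreement with the oracle for all n <= 8, incl. duplicate x
  for (i in 1:20) {
    n <- 2 + (i %% 7)
    x <- hammettr:::with_seed(1000 + i, sample(0:4, n, replace = TRUE))
    y <- hammettr:::with_seed(2000 + i, round(rnorm(n), 2))
    if (length(unique(x)) < 2) next
    expect_equal(theil_sen_slope(x, y), brute_force_ts(x, y),
                 info = paste("case", i))
  }
})

test_that("pairwise_reaction_slopes recovers exact proportionality and omits unsupported pairs", {
  rec <- data.frame(
    reaction_id = rep(c("a", "b"), each = 5),
    R1 = rep(c("H", "V", "W", "X", "Y"), 2),
    response = c(1, 2, 3, 4, 5, 3, 6, 9, 12, 15),
    response_type = "log10_k")
  tbl <- reaction_table(rec, positions = "R1")
  sl <- pairwise_reaction_slopes(tbl)
  expect_equal(sl$slope[sl$from == "a" & sl$to == "b"], 3.0)
  expect_equal(sl$slope[sl$from == "b" & sl$to == "a"], 1 / 3)
  expect_equal(unique(sl$support), 5L)

  # disjoint substituent sets -> no pair has support
  rec2 <- data.frame(
    reaction_id = rep(c("a", "b"), each = 2),
    R1 = c("H", "X", "Y", "Z"),
    response = 1:4, response_type = "log10_k")
  tbl2 <- reaction_table(rec2, positions = "R1")
  expect_identical(nrow(pairwise_reaction_slopes(tbl2)), 0L)
})

test_that("pairwise slopes on a noiseless table equal the true rho ratios", {
  d <- make_sn2_like(seed = 8, max_sets = 40)
  sl <- pairwise_reaction_slopes(d$table)
  truth <- d$truth$rho[sl$to] / d$truth$rho[sl$from]
  expect_lt(max(abs(sl$slope - truth)), 1e-10)
})

test_that("fit_global_rho solves exact and perturbed reaction graphs", {
  # single reaction: anchor only
  expect_identical(fit_global_rho(
    data.frame(from = character(), to = character(), slope = numeric(),
               support = integer()), anchor = "a", reactions = "a"),
    c(a = 1))

  # exact consistent triangle
  sl <- data.frame(from = c("r1", "r1", "r2"), to = c("r2", "r3", "r3"),
                   slope = c(2, 4, 2), support = c(3, 3, 3))
  expect_equal(fit_global_rho(sl, "r1"), c(r1 = 1, r2 = 2, r3 = 4),
               tolerance = 1e-12)

  # perturbed triangle: matches an independent dense weighted normal-equations
  # solve on log-slopes with the anchor column dropped
  sl$slope <- c(2.1, 3.9, 2.05)
  got <- fit_global_rho(sl, "r1")
  A <- rbind(c(1, 0), c(0, 1), c(-1, 1))  # columns r2, r3; r1 fixed at 0
  w <- diag(sl$support)
  beta <- solve(t(A) %*% w %*% A, t(A) %*% w %*% log(sl$slope))
  expect_equal(unname(got[c("r2", "r3")]), exp(as.numeric(beta)),
               tolerance = 1e-10)

  # disconnected graph is a connectivity error naming components
  sl2 <- data.frame(from = "r1", to = "r2", slope = 2, support = 2)
  expect_error(fit_global_rho(sl2, "r1", reactions = c("r1", "r2", "r9")),
               "disconnected.*r9")
  # negative slope requires the sign-propagation flag
  sl3 <- data.frame(from = "r1", to = "r2", slope = -2, support = 2)
  expect_error(fit_global_rho(sl3, "r1"), "sign error")
  rho_neg <- fit_global_rho(sl3, "r1", allow_negative = TRUE)
  expect_equal(unname(rho_neg), c(1, -2), tolerance = 1e-12)
})

test_that("fit_sigma_offsets has the right closed forms and gauge", {
  # single reaction, rho = 1: sigma is the response difference to reference
  rec <- data.frame(reaction_id = "a", R1 = c("H", "X", "Y"),
                    response = c(2, 5, 1), response_type = "log10_k")
  tbl <- reaction_table(rec, positions = "R1", reference_set = c(R1 = "H"))
  so <- fit_sigma_offsets(tbl, rho = c(a = 1))
  expect_equal(so$sigma[["X"]], 3)
  expect_equal(so$sigma[["Y"]], -1)
  expect_identical(so$sigma[["H"]], 0)
  expect_equal(so$offsets[["a"]], 2)
  expect_true(so$converged)
})

test_that("the full global fit exactly recovers a noiseless synthetic world", {
  d <- make_sn2_like(seed = 21, max_sets = 80)
  fit <- fit_sigma_hammett(d$table)
  expect_hammett_recovery(fit, d$truth, tol = 1e-8)
  expect_identical(fit$rho[[fit$anchor_reaction]], 1)
  expect_identical(fit$sigma[[fit$reference_set_key]], 0)
  # self-consistency: zero training error
  expect_lt(evaluate_mae(fit, d$table), 1e-8)
})

test_that("the global fit is invariant to input row order", {
  d <- make_sn2_like(seed = 13, max_sets = 30, noise_sd = 0.2)
  fit1 <- fit_sigma_hammett(d$table)
  rec <- d$table$records
  shuffled <- rec[hammettr:::with_seed(5, sample(nrow(rec))), ]
  fit2 <- fit_sigma_hammett(
    reaction_table(shuffled, positions = d$table$positions,
                   reference_set = d$table$reference_set))
  expect_identical(fit1$rho, fit2$rho)
  expect_identical(fit1$sigma, fit2$sigma)
  expect_identical(fit1$offsets, fit2$offsets)
})

test_that("gauge invariance: rescaling true rho and sigma leaves the fit unchanged", {
  base <- synthetic_config(n_reactions = 4L, seed = 9, max_sets = 30)
  d1 <- generate_hammett_data(base)
  # same world with rho scaled by c and alpha (hence sigma) by 1/c
  cfg2 <- synthetic_config(n_reactions = 4L, seed = 9, max_sets = 30,
                           rho_range = base$rho_range * 3,
                           alpha = base$alpha / 3)
  d2 <- generate_hammett_data(cfg2)
  expect_equal(d1$table$records$response, d2$table$records$response,
               tolerance = 1e-12)
  f1 <- fit_sigma_hammett(d1$table)
  f2 <- fit_sigma_hammett(d2$table)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-10)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-10)
})

test_that("original sequential procedure: noiseless equivalence, order dependence, reachability", {
  d <- make_sn2_like(seed = 5, max_sets = 30)
  g <- fit_sigma_hammett(d$table)
  o <- original_hammett_fit(d$table, reference_reaction = d$table$reactions[1])
  keys <- set_keys(d$table)$key
  expect_equal(predict(g, d$table$records$reaction_id, keys),
               predict(o, d$table$records$reaction_id, keys),
               tolerance = 1e-10)

  # on noisy, partially observed data two expansion orders give different
  # parameters (with fully shared sets every sigma comes from the reference
  # reaction and the order is immaterial)
  dn <- make_sn2_like(seed = 6, max_sets = 30, noise_sd = 0.5,
                      missing_fraction = 0.4)
  # a reference must observe the reference substituent set
  Yn <- hammettr:::response_matrix(dn$table)
  ref_rxn <- names(which(!is.na(Yn[hammettr:::reference_key(dn$table), ])))[1]
  rest <- setdiff(dn$table$reactions, ref_rxn)
  o1 <- original_hammett_fit(dn$table, ref_rxn, expansion_order = rest)
  o2 <- original_hammett_fit(dn$table, ref_rxn, expansion_order = rev(rest))
  expect_gt(max(abs(o1$rho[names(o2$rho)] - o2$rho)), 1e-8)

  # a reference reaction without the reference set is a configuration error
  rec <- dn$table$records
  ref_key <- hammettr:::reference_key(dn$table)
  drop <- set_keys(dn$table)$key == ref_key &
    rec$reaction_id == dn$table$reactions[2]
  tbl2 <- reaction_table(rec[!drop, ], positions = dn$table$positions,
                         reference_set = dn$table$reference_set)
  expect_error(original_hammett_fit(tbl2, dn$table$reactions[2]),
               "configuration error")
})

test_that("sigma ordering agrees between the global and the original procedure", {
  d <- make_sn2_like(seed = 31, max_sets = 40, noise_sd = 0.15)
  g <- fit_sigma_hammett(d$table)
  o <- original_hammett_fit(d$table, reference_reaction = d$table$reactions[3])
  common <- intersect(names(g$sigma), names(o$sigma))
  expect_gt(cor(rank(g$sigma[common]), rank(o$sigma[common])), 0.95)
})

test_that("predict and evaluate_mae follow the model arithmetic", {
  tbl <- tiny_table()
  fit <- fit_sigma_hammett(tbl)
  # reference set predicts the offset exactly
  expect_equal(predict(fit, "A", "H"), fit$offsets[["A"]])
  # anchor reaction has rho 1
  expect_equal(predict(fit, fit$anchor_reaction, "X"),
               fit$offsets[[fit$anchor_reaction]] + fit$sigma[["X"]])
  expect_error(predict(fit, "nope", "X"), "lookup error")
  expect_error(predict(fit, "A", "Z|Z"), "lookup error")

  expect_lt(evaluate_mae(fit, tbl), 1e-10)
  # constant +1 offset injection gives MAE exactly 1
  shifted <- fit
  shifted$offsets <- fit$offsets + 1
  expect_equal(as.numeric(evaluate_mae(shifted, tbl)), 1.0)
  per <- evaluate_mae(shifted, tbl, per = "reaction")
  expect_equal(unname(per), c(1, 1), ignore_attr = TRUE)
})

test_that("global MAE of the true model under Gaussian noise matches the half-normal mean", {
  # |N(0, sd)| has mean sd * sqrt(2/pi)
  d <- make_sn2_like(seed = 77, max_sets = 625, noise_sd = 0.5)
  truth_params <- structure(
    list(rho = d$truth$rho, sigma = d$truth$sigma, offsets = d$truth$offsets,
         anchor_reaction = names(d$truth$rho)[1],
         method = "sigma_hammett_global"),
    class = "hammett_params")
  mae <- as.numeric(evaluate_mae(truth_params, d$table))
  expect_equal(mae, 0.5 * sqrt(2 / pi), tolerance = 0.03)
})

test_that("enumeration_bound returns exact factorials", {
  expect_identical(enumeration_bound(1), 1)
  expect_identical(enumeration_bound(12), prod(1:12))
  oracle <- 1
  for (k in 1:12) oracle <- oracle * k
  expect_identical(enumeration_bound(12), oracle)
  expect_gte(enumeration_bound(12), 1e8)
  # exact big-integer path agrees with the double path at the boundary
  expect_identical(enumeration_bound(20),
                   "2432902008176640000")
})

test_that("Theil-Sen rho estimates beat the OLS control under series outliers", {
  devs <- sapply(1:4, function(s) {
    d <- make_sn2_like(seed = 500 + s, max_sets = 60, noise_sd = 0.3,
                       outlier_fraction = 0.2, outlier_shift = 3)
    anchor <- d$table$reactions[1]
    rho_ts <- fit_global_rho(pairwise_reaction_slopes(d$table), anchor,
                             d$table$reactions)
    rho_ols <- fit_global_rho(ols_reaction_slopes(d$table), anchor,
                              d$table$reactions, allow_negative = TRUE)
    c(ts = max_ratio_deviation(rho_ts, d$truth$rho),
      ols = max_ratio_deviation(rho_ols, d$truth$rho))
  })
  # robustness is relative: the median-based estimator is strictly less
  # distorted than least squares on every seed
  expect_true(all(devs["ts", ] < devs["ols", ]))
})
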