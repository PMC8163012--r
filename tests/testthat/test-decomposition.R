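# additive decomposition of molecular sigma: categorical, distance-decay,
# three-body; parameter counts and R^2

# small geometry with distinct distances and non-collinear coordinates
demo_geometry <- function() {
  pos <- c("R1", "R2", "R3", "R4")
  d <- c(R1 = 1.5, R2 = 1.5, R3 = 2.5, R4 = 2.5)
  xyz <- hammettr:::.default_sn2_coordinates(pos, d[pos])
  scaffold_geometry(pos, d[pos], xyz)
}

# sigma table built additively from known alpha under a known decay
make_sigma_table <- function(alpha, geometry, gamma = 2, n = 120, seed = 1) {
  groups <- names(alpha)
  P <- length(geometry$positions)
  G <- hammettr:::with_seed(seed,
    matrix(sample(groups, n * P, replace = TRUE), ncol = P))
  G[1, ] <- "H"
  G <- G[!duplicated(G), , drop = FALSE]
  colnames(G) <- geometry$positions
  fd <- unname(geometry$distances)^(-gamma)
  sig <- as.numeric(matrix(alpha[as.vector(G)], nrow = nrow(G)) %*% fd)
  names(sig) <- apply(G, 1, paste, collapse = "|")
  sig
}

true_alpha <- c(H = 0, A = -2, B = 1.3, C = 0.4)

test_that("categorical regression exactly recovers additive per-position alphas", {
  geom <- demo_geometry()
  # per-(group,position) construction: alpha * f(d_p) is itself categorical
  sig <- make_sigma_table(true_alpha, geom, gamma = 2, n = 200)
  fit <- fit_categorical(sig, geom$positions, baseline_group = "H")
  fd <- unname(geom$distances)^(-2)
  for (p in seq_along(geom$positions)) {
    expect_equal(fit$alpha_by_group_position[names(true_alpha),
                                             geom$positions[p]],
                 true_alpha * fd[p], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  # baseline gauge: the all-H set predicts exactly 0
  expect_identical(predict_sigma(fit, paste(rep("H", 4), collapse = "|")), 0)
  # equal-distance positions carry identical contributions
  expect_equal(fit$alpha_by_group_position[, "R1"],
               fit$alpha_by_group_position[, "R2"], tolerance = 1e-10)
})

test_that("rank-deficient categorical designs raise an identifiability error", {
  geom <- demo_geometry()
  sig <- make_sigma_table(true_alpha, geom, n = 200)
  # keep only sets where R1 == R2: those two columns become confounded
  G <- do.call(rbind, strsplit(names(sig), "|", fixed = TRUE))
  sub <- sig[G[, 1] == G[, 2]]
  expect_error(fit_categorical(sub, geom$positions, baseline_group = "H"),
               "identifiability error")
})

test_that("distance-decay fit recovers alpha and the decay exponent", {
  geom <- demo_geometry()
  sig <- make_sigma_table(true_alpha, geom, gamma = 2, n = 200)
  fit <- fit_distance_decay(sig, geom, form = "power")
  expect_true(fit$decay_identifiable)
  expect_equal(fit$decay_param, 2, tolerance = 1e-4)
  expect_equal(fit$alpha_by_group[names(true_alpha)], true_alpha,
               tolerance = 1e-6, ignore_attr = TRUE)

  # exponential world, recovered by the exponential form
  lam <- 1.6
  fd <- exp(-unname(geom$distances) / lam)
  keys <- names(sig)
  G <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  sig_exp <- setNames(as.numeric(
    matrix(true_alpha[as.vector(G)], nrow = nrow(G)) %*% fd), keys)
  fit_e <- fit_distance_decay(sig_exp, geom, form = "exponential")
  expect_equal(fit_e$decay_param, lam, tolerance = 1e-4)
  expect_equal(fit_e$alpha_by_group[names(true_alpha)], true_alpha,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate geometries flag the decay parameter as non-identifiable", {
  # single position: reduces to a categorical fit with f absorbed into alpha
  g1 <- scaffold_geometry("R1", c(R1 = 2))
  sig1 <- setNames(c(0, -1, 0.5), c("H", "A", "B"))
  f1 <- fit_distance_decay(sig1, g1, form = "power")
  expect_false(f1$decay_identifiable)
  expect_equal(predict_sigma(f1, c("H", "A", "B")), unname(sig1),
               tolerance = 1e-10)

  # all distances equal: alpha recovered up to a common scale only
  g2 <- scaffold_geometry(c("R1", "R2"), c(R1 = 2, R2 = 2))
  a <- c(H = 0, A = -1, B = 0.7)
  keys <- as.matrix(expand.grid(names(a), names(a), stringsAsFactors = FALSE))
  sig2 <- setNames((a[keys[, 1]] + a[keys[, 2]]) * 2^-1.5,
                   apply(keys, 1, paste, collapse = "|"))
  f2 <- fit_distance_decay(sig2, g2, form = "power")
  expect_false(f2$decay_identifiable)
  ratio <- f2$alpha_by_group[c("A", "B")] / (a[c("A", "B")] * 2^-1.5 * 2^f2$decay_param)
  expect_equal(unname(ratio), c(1, 1), tolerance = 1e-8)
})

test_that("three-body fit nests the decay fit and recovers zero pair terms", {
  geom <- demo_geometry()
  sig <- make_sigma_table(true_alpha, geom, gamma = 2, n = 250)
  decay <- fit_distance_decay(sig, geom, form = "power")
  atm <- fit_atm(sig, geom, form = "power")
  # generated without pair interactions: beta ~ 0 and alpha agrees
  expect_lt(max(abs(atm$beta_by_pair)), 1e-6)
  expect_equal(atm$alpha_by_group, decay$alpha_by_group, tolerance = 1e-5)
  expect_lte(atm$sse, decay$sse + 1e-10)

  # now add genuine pair interactions: ATM must fit strictly better
  gfac <- hammettr:::atm_geometry_factor(geom)
  G <- do.call(rbind, strsplit(names(sig), "|", fixed = TRUE))
  colnames(G) <- geom$positions
  beta <- setNames(rep(0, 0), character())
  sig2 <- sig
  pos_pairs <- utils::combn(geom$positions, 2)
  bmap <- c("A+A" = 30, "A+B" = -20, "B+C" = 15)
  for (k in seq_len(ncol(pos_pairs))) {
    pk <- hammettr:::.pair_key(G[, pos_pairs[1, k]], G[, pos_pairs[2, k]])
    g_pq <- gfac[paste(pos_pairs[1, k], pos_pairs[2, k], sep = "+")]
    b <- bmap[pk]; b[is.na(b)] <- 0
    sig2 <- sig2 + unname(b) * g_pq
  }
  decay2 <- fit_distance_decay(sig2, geom, form = "power")
  atm2 <- fit_atm(sig2, geom, form = "power")
  expect_lt(atm2$sse, decay2$sse)
  expect_equal(atm2$beta_by_pair[names(bmap)], bmap, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("three-body predictions respect the unordered-pair symmetry", {
  # symmetric geometry: R1 and R2 mirror images w.r.t. the center
  pos <- c("R1", "R2")
  xyz <- rbind(c(1.2, 0.9, 0), c(-1.2, 0.9, 0))
  geom <- scaffold_geometry(pos, sqrt(rowSums(xyz^2)), xyz)
  a <- c(H = 0, A = -1, B = 0.6)
  keys <- as.matrix(expand.grid(names(a), names(a), stringsAsFactors = FALSE))
  fd <- sqrt(rowSums(xyz^2))^-2
  sig <- setNames(a[keys[, 1]] * fd[1] + a[keys[, 2]] * fd[2] +
                    10 * hammettr:::atm_geometry_factor(geom),
                  apply(keys, 1, paste, collapse = "|"))
  fit <- fit_atm(sig, geom, form = "power")
  # swapping the groups between the two equivalent positions leaves the
  # predicted sigma unchanged
  expect_equal(predict_sigma(fit, "A|B"), predict_sigma(fit, "B|A"),
               tolerance = 1e-8)
})

test_that("collinear triangles are a geometry error", {
  pos <- c("R1", "R2")
  xyz <- rbind(c(1, 0, 0), c(2, 0, 0))  # both on a line through the center
  geom <- scaffold_geometry(pos, c(1, 2), xyz)
  expect_error(hammettr:::atm_geometry_factor(geom), "collinear")
})

test_that("distance decay is strictly monotone for both forms", {
  d <- seq(0.5, 6, by = 0.25)
  for (t in c(0.5, 1, 2)) {
    expect_true(all(diff(abs(2 * d^-t)) < 0))
    expect_true(all(diff(abs(2 * exp(-d / t))) < 0))
  }
})

test_that("count_parameters reproduces the printed counts and the allocated counts", {
  # headline counts for the 5-group, 4-position, 12-reaction campaign
  expect_identical(count_parameters("categorical", 5, 4), 20L)
  expect_identical(count_parameters("power", 5), 6L)
  expect_identical(count_parameters("exponential", 5), 6L)
  expect_identical(count_parameters("atm", 5), 21L)
  expect_identical(count_parameters("alpha_hammett_total", 5,
                                    n_reactions = 12), 18L)
  # increments: one more position costs N_G (categorical); one more group
  # costs one alpha, one cross pair per old group, and the same-group pair
  expect_identical(count_parameters("categorical", 5, 5) -
                     count_parameters("categorical", 5, 4), 5L)
  expect_identical(count_parameters("atm", 6) - count_parameters("atm", 5),
                   1L + 5L + 1L)

  # the closed forms match the parameter lists the fits actually allocate
  for (ng in c(3, 4)) for (np in c(2, 3)) {
    alpha <- setNames(c(0, seq_len(ng - 1)), c("H", paste0("g", seq_len(ng - 1))))
    pos <- paste0("P", seq_len(np))
    dist <- setNames(seq_len(np) + 0.5, pos)
    xyz <- hammettr:::.default_sn2_coordinates(pos, unname(dist))
    geom <- scaffold_geometry(pos, dist, xyz)
    G <- as.matrix(do.call(expand.grid, c(rep(list(names(alpha)), np),
                                          list(stringsAsFactors = FALSE))))
    colnames(G) <- pos
    fd <- unname(dist)^-1
    sig <- setNames(as.numeric(matrix(alpha[as.vector(G)],
                                      nrow = nrow(G)) %*% fd),
                    apply(G, 1, paste, collapse = "|"))
    fc <- fit_categorical(sig, pos, baseline_group = "H")
    expect_identical(length(fc$alpha_by_group_position),
                     count_parameters("categorical", ng, np) |> as.integer())
    fdk <- fit_distance_decay(sig, geom, form = "power")
    expect_identical(length(fdk$alpha_by_group) + 1L,
                     count_parameters("power", ng))
    fa <- fit_atm(sig, geom, form = "power")
    expect_identical(length(fa$alpha_by_group) + length(fa$beta_by_pair) + 1L,
                     count_parameters("atm", ng))
  }
})

test_that("r_squared follows the sum-of-squares definition", {
  expect_equal(r_squared(1:5, 1:5), 1.0)
  expect_equal(r_squared(c(1, 2, 3, 4), rep(2.5, 4)), 0.0)
  x <- hammettr:::with_seed(3, rnorm(100))
  y <- hammettr:::with_seed(4, rnorm(100))
  oracle <- 1 - sum((x - y)^2) / sum((x - mean(x))^2)
  expect_equal(r_squared(x, y), oracle, tolerance = 1e-12)
  expect_error(r_squared(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("recovered alpha signs and ordering track the generator's inductive effects", {
  # barrier-lowering groups (negative alpha under rho > 0) come out negative
  d <- make_sn2_like(seed = 17, max_sets = 150, noise_sd = 0.2)
  fit <- fit_sigma_hammett(d$table)
  dec <- fit_distance_decay(fit$sigma, d$geometry, form = "power")
  scale <- d$truth$rho[[fit$anchor_reaction]]
  a_true <- d$truth$alpha[names(dec$alpha_by_group)] * scale
  expect_identical(sign(dec$alpha_by_group[abs(a_true) > 0.5]),
                   sign(a_true[abs(a_true) > 0.5]))
  expect_identical(order(dec$alpha_by_group), order(a_true))
})

test_that("predicted sigma from a fitted noiseless model matches the Hammett sigma", {
  d <- make_sn2_like(seed = 23, max_sets = 100)
  fit <- fit_sigma_hammett(d$table)
  dec <- fit_distance_decay(fit$sigma, d$geometry, form = "power")
  pred <- predict_sigma(dec, names(fit$sigma))
  expect_equal(pred, unname(fit$sigma), tolerance = 1e-6)
  # single-substitution set reads off one alpha * f(d)
  catm <- fit_categorical(fit$sigma, d$table$positions)
  key <- "NO2|H|H|H"
  expect_equal(predict_sigma(catm, key),
               unname(catm$alpha_by_group_position["NO2", "R1"]),
               tolerance = 1e-10)
  expect_error(predict_sigma(dec, "H|H|H|ZZZ"), "unknown group")
})
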