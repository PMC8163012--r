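# Hammett-consistent synthetic data with known ground truth. The generator
# states a concrete world: responses are built exactly as
# y_{s,j} = c_j + rho_j * sigma_s + noise, with molecular sigma assembled
# additively from per-group alpha terms scaled by a distance-decay function
# (plus optional three-body pair terms), so every fitting stage has an exact
# recovery target.

#' Configuration for the synthetic Hammett generator
#'
#' @param n_reactions number of reactions (>= 1).
#' @param alpha named numeric vector of true per-group alpha values; the
#'   baseline group must be present with alpha 0.
#' @param positions character vector of position labels.
#' @param distances named numeric vector of distances to the reaction
#'   center (A), one per position.
#' @param coordinates optional position coordinate matrix (rows = positions)
#'   for three-body terms.
#' @param decay `"none"`, `"power"`, or `"exponential"`.
#' @param decay_param gamma (power) or lambda (exponential).
#' @param beta optional named numeric vector of pair interactions, names
#'   like `"A+B"` with the two group labels sorted.
#' @param rho_range positive interval for log-uniform rho draws (default
#'   0.2..5, all positive, matching barrier data where every reaction
#'   responds in the same direction).
#' @param offset_range interval for the per-reaction offsets c_j.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param outlier_fraction fraction of outliers (in [0, 0.5)).
#' @param outlier_shift additive response shift magnitude for outlier rows;
#'   each affected record is shifted by `outlier_shift` times a random sign.
#' @param outlier_unit `"set"` (default) marks whole substituent-set series
#'   as anomalous — every record of a selected set is shifted, emulating a
#'   compound whose whole series misbehaves, and keeping the contamination
#'   of every pairwise reaction scatter equal to `outlier_fraction` (below
#'   the Theil-Sen breakdown for fractions < 0.29). `"record"` shifts
#'   records drawn uniformly, in which case a pairwise scatter is
#'   contaminated at roughly twice the nominal fraction.
#' @param missing_fraction fraction of (reaction, set) cells dropped
#'   uniformly at random (in [0, 1)).
#' @param max_sets cap on the number of substituent sets (full enumeration
#'   if the combinatorial count fits, else a seeded sample of distinct sets).
#' @param response_type `"activation_energy_kcal_mol"` or `"log10_k"`.
#' @param reaction_ids optional explicit reaction labels.
#' @param signed_rho if `TRUE`, a random half of the rho values are negated
#'   (stress testing; real barrier datasets have rho > 0 throughout).
#' @param seed integer seed; identical configs give identical output.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reactions = 12L,
                             alpha = c(H = 0, NO2 = -3.5, CN = -2.5,
                                       CH3 = 1, NH2 = 2.2),
                             positions = c("R1", "R2", "R3", "R4"),
                             distances = c(R1 = 1.5, R2 = 1.5,
                                           R3 = 2.5, R4 = 2.5),
                             coordinates = NULL,
                             decay = c("power", "exponential", "none"),
                             decay_param = 2,
                             beta = NULL,
                             rho_range = c(0.2, 5),
                             offset_range = c(8, 30),
                             noise_sd = 0,
                             outlier_fraction = 0,
                             outlier_shift = 0,
                             outlier_unit = c("set", "record"),
                             missing_fraction = 0,
                             max_sets = 625L,
                             response_type = "activation_energy_kcal_mol",
                             reaction_ids = NULL,
                             signed_rho = FALSE,
                             seed = 1L) {
  decay <- match.arg(decay)
  outlier_unit <- match.arg(outlier_unit)
  stopifnot(n_reactions >= 1, length(alpha) >= 2, !is.null(names(alpha)),
            noise_sd >= 0, outlier_fraction >= 0, outlier_fraction < 0.5,
            missing_fraction >= 0, missing_fraction < 1,
            all(rho_range > 0), length(positions) >= 1,
            any(alpha == 0))  # a baseline group with alpha 0 must exist
  if (decay != "none") stopifnot(decay_param > 0)
  stopifnot(setequal(names(distances), positions))
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    rownames(coordinates) <- positions
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# true molecular sigma for a groups-matrix under a config
.true_sigma <- function(G, config) {
  fd <- switch(config$decay,
               none = rep(1, length(config$positions)),
               power = unname(config$distances[config$positions])^
                 (-config$decay_param),
               exponential = exp(-unname(config$distances[config$positions]) /
                                   config$decay_param))
  A <- matrix(config$alpha[as.vector(G)], nrow = nrow(G))
  sig <- as.numeric(A %*% fd)
  if (!is.null(config$beta)) {
    geom <- scaffold_geometry(config$positions,
                              config$distances[config$positions],
                              config$coordinates)
    gfac <- atm_geometry_factor(geom)
    pos_pairs <- utils::combn(config$positions, 2L)
    for (k in seq_len(ncol(pos_pairs))) {
      pk <- .pair_key(G[, pos_pairs[1L, k]], G[, pos_pairs[2L, k]])
      g_pq <- gfac[paste(pos_pairs[1L, k], pos_pairs[2L, k], sep = "+")]
      b <- config$beta[pk]
      b[is.na(b)] <- 0
      sig <- sig + unname(b) * g_pq
    }
  }
  sig
}

#' Generate a synthetic reaction table with known ground truth
#'
#' Enumerates all group-per-position combinations when their count does not
#' exceed `max_sets`, otherwise samples that many distinct sets. Molecular
#' sigma is built additively from the true alphas (and optional pair terms);
#' responses are \eqn{c_j + \rho_j \sigma_s} plus Gaussian noise, with
#' optional outlier shifts and uniformly-missing cells. If missingness
#' disconnects the reaction graph the missing mask is redrawn (up to 10
#' attempts, with a warning).
#'
#' @param config a `synthetic_config`.
#' @return list with `table` (a `reaction_table`) and `truth` (a
#'   `synthetic_truth`: `rho`, `offsets`, `sigma` by set key, `alpha`,
#'   `beta`, `decay`, `decay_param`, `outlier_rows`).
#' @export
generate_hammett_data <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  groups <- names(config$alpha)
  P <- length(config$positions)
  n_all <- length(groups)^P

  with_seed(config$seed, {
    if (n_all <= config$max_sets) {
      G <- as.matrix(do.call(expand.grid,
                             c(rep(list(groups), P),
                               list(stringsAsFactors = FALSE))))
    } else {
      # always include the all-baseline (reference) set: it anchors the
      # sigma gauge, like the unsubstituted compound in a real campaign
      base_row <- rep(names(config$alpha)[which(config$alpha == 0)[1L]], P)
      draw <- rbind(base_row,
                    matrix(sample(groups, (config$max_sets - 1L) * P,
                                  replace = TRUE), ncol = P))
      keys <- apply(draw, 1L, set_key_from_groups)
      while (anyDuplicated(keys)) {
        dup <- which(duplicated(keys))
        draw[dup, ] <- sample(groups, length(dup) * P, replace = TRUE)
        keys <- apply(draw, 1L, set_key_from_groups)
      }
      G <- draw
    }
    colnames(G) <- config$positions
    keys <- apply(G, 1L, set_key_from_groups)
    sigma <- setNames(.true_sigma(G, config), keys)

    rids <- if (!is.null(config$reaction_ids)) {
      config$reaction_ids
    } else {
      sprintf("rxn%02d", seq_len(config$n_reactions))
    }
    lr <- log(config$rho_range)
    rho <- setNames(exp(runif(length(rids), lr[1L], lr[2L])), rids)
    if (config$signed_rho) {
      rho <- rho * sample(c(-1, 1), length(rho), replace = TRUE)
    }
    offsets <- setNames(runif(length(rids), config$offset_range[1L],
                              config$offset_range[2L]), rids)

    grid <- expand.grid(set = seq_along(keys), rxn = seq_along(rids))
    y_clean <- offsets[grid$rxn] + rho[grid$rxn] * sigma[grid$set]
    y <- y_clean + rnorm(length(y_clean), 0, config$noise_sd)
    out_rows <- integer(0)
    if (config$outlier_fraction > 0) {
      if (config$outlier_unit == "set") {
        bad_sets <- sample(length(keys),
                           size = round(config$outlier_fraction * length(keys)))
        out_rows <- which(grid$set %in% bad_sets)
      } else {
        out_rows <- sample(length(y),
                           size = round(config$outlier_fraction * length(y)))
      }
      y[out_rows] <- y[out_rows] +
        config$outlier_shift * sample(c(-1, 1), length(out_rows),
                                      replace = TRUE)
    }

    build <- function(keep) {
      rec <- data.frame(reaction_id = rids[grid$rxn[keep]],
                        stringsAsFactors = FALSE)
      rec <- cbind(rec, as.data.frame(G[grid$set[keep], , drop = FALSE],
                                      stringsAsFactors = FALSE))
      rec$response <- unname(y[keep])
      rec$response_type <- config$response_type
      ref <- setNames(rep(groups[which(config$alpha == 0)[1L]], P),
                      config$positions)
      reaction_table(rec, positions = config$positions, reference_set = ref)
    }

    keep <- seq_along(y)
    if (config$missing_fraction > 0) {
      tbl <- NULL
      for (attempt in seq_len(10L)) {
        keep_try <- sort(sample(length(y),
                                size = round((1 - config$missing_fraction) *
                                               length(y))))
        tbl <- tryCatch({
          cand <- build(keep_try)
          slopes <- pairwise_reaction_slopes(cand)
          comps <- .reaction_components(cand$reactions, slopes)
          if (length(comps) > 1L) stop("disconnected")
          keep <- keep_try
          cand
        }, error = function(e) NULL)
        if (!is.null(tbl)) break
        warning("missingness disconnected the reaction graph; redrawing (",
                "attempt ", attempt, ")")
      }
      if (is.null(tbl)) {
        stop("could not generate a connected table in 10 attempts; lower ",
             "missing_fraction")
      }
    } else {
      tbl <- build(keep)
    }

    truth <- structure(
      list(rho = rho, offsets = offsets, sigma = sigma,
           alpha = config$alpha, beta = config$beta,
           decay = config$decay, decay_param = config$decay_param,
           outlier_rows = match(intersect(out_rows, keep), keep),
           config = config),
      class = "synthetic_truth")
    list(table = tbl, truth = truth)
  })
}

# Tetrahedral-ish coordinates for the default two-near/two-far scaffold:
# reaction center at the origin, positions fanned out with distinct angles so
# no (p, q, center) triangle is collinear.
.default_sn2_coordinates <- function(positions, distances) {
  angles <- seq(0.6, 2.4, length.out = length(positions))
  phi <- seq(0, pi, length.out = length(positions))
  xyz <- cbind(distances * sin(angles) * cos(phi),
               distances * sin(angles) * sin(phi),
               distances * cos(angles))
  rownames(xyz) <- positions
  xyz
}

#' Preset: SN2-style activation-energy table
#'
#' Emulates a computational SN2 campaign on a two-carbon scaffold: 12
#' reactions (every ordered nucleophile/leaving-group pair from H, F, Cl,
#' Br with Nu != LG, ids like `"F_Cl"`), five groups (H, NO2, CN, NH2, CH3)
#' on four positions R1..R4 — R1 and R2 near the reacting carbon (1.5 A),
#' R3 and R4 on the neighboring carbon (2.5 A) — with a power-law distance
#' decay (gamma = 2) and responses as activation energies in kcal/mol.
#' Equal-distance positions have identical true per-position effects by
#' construction. Default offsets and rho span barriers of roughly 3 to 40
#' kcal/mol.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_config()] (e.g. `noise_sd`,
#'   `outlier_fraction`, `max_sets`, `beta`).
#' @return list with `table`, `truth`, and `geometry` (a
#'   `scaffold_geometry` with coordinates).
#' @export
make_sn2_like <- function(seed = 1L, ...) {
  species <- c("H", "F", "Cl", "Br")
  pairs <- expand.grid(nu = species, lg = species, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$nu != pairs$lg, ]
  rids <- sort(paste(pairs$nu, pairs$lg, sep = "_"))
  positions <- c("R1", "R2", "R3", "R4")
  distances <- c(R1 = 1.5, R2 = 1.5, R3 = 2.5, R4 = 2.5)
  coords <- .default_sn2_coordinates(positions, distances[positions])
  config <- synthetic_config(n_reactions = 12L,
                             positions = positions, distances = distances,
                             coordinates = coords,
                             decay = "power", decay_param = 2,
                             rho_range = c(0.5, 2), offset_range = c(8, 30),
                             reaction_ids = rids, seed = seed, ...)
  out <- generate_hammett_data(config)
  out$geometry <- scaffold_geometry(positions, distances[positions], coords)
  out
}

#' Preset: single-substituent rate-constant series
#'
#' Emulates experimental single-position datasets (one varying substituent,
#' several reactions playing the role of co-reactants or temperatures) with
#' log10 rate constants as the response: about ten groups, no distance
#' decay. Optionally injects one anomalous substituent series whose response
#' is linear in the reaction index — the kind of unphysical behaviour
#' (against the Arrhenius-like trend of every other series) that a robust
#' global fit flags through its residuals.
#'
#' @param n_reactions number of reactions (>= 2, default 6).
#' @param seed integer seed.
#' @param inject_anomaly logical; replace one group's series by a linear
#'   ramp across reactions.
#' @param ... overrides passed to [synthetic_config()].
#' @return list with `table`, `truth`, and (if injected) `anomalous_group`.
#' @export
make_single_substituent_like <- function(n_reactions = 6L, seed = 1L,
                                         inject_anomaly = FALSE, ...) {
  stopifnot(n_reactions >= 2L)
  alpha <- c(H = 0, Me = 0.35, Et = 0.3, OMe = 0.6, F = -0.25, Cl = -0.45,
             Br = -0.5, CN = -1.1, NO2 = -1.4, Ph = 0.15)
  config <- synthetic_config(n_reactions = n_reactions, alpha = alpha,
                             positions = "R1", distances = c(R1 = 1),
                             decay = "none",
                             rho_range = c(0.5, 3), offset_range = c(-4, 1),
                             response_type = "log10_k",
                             max_sets = length(alpha), seed = seed, ...)
  out <- generate_hammett_data(config)
  if (inject_anomaly) {
    grp <- names(alpha)[length(alpha)]  # deterministic pick
    rec <- out$table$records
    ix <- which(rec$R1 == grp)
    ridx <- match(rec$reaction_id[ix], out$table$reactions)
    rec$response[ix] <- -2 + 0.15 * ridx  # linear in reaction index
    out$table <- reaction_table(rec, positions = out$table$positions,
                                reference_set = out$table$reference_set)
    out$anomalous_group <- grp
  }
  out
}
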