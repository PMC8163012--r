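#' Construct a validated reaction table
#'
#' A reaction table holds long-format observations of one response per
#' (reaction, substituent set) pair. Each record carries a reaction id, one
#' group label per scaffold position, and a response that is either a decadic
#' log rate constant (`log10_k`) or an activation energy in kcal/mol
#' (`activation_energy_kcal_mol`). Barriers and rate constants are never
#' inter-converted: a fitted model's sign conventions simply flip between the
#' two response types.
#'
#' @param records data.frame with columns `reaction_id`, one column per
#'   scaffold position, `response`, and `response_type`.
#' @param positions character vector of position column names. If `NULL`,
#'   every column other than `reaction_id`, `response`, `response_type` is
#'   taken as a position; positions are sorted lexicographically.
#' @param reference_set named character vector (position -> group) designating
#'   the unsubstituted reference set. Defaults to all-`"H"` when `"H"` is in
#'   the group vocabulary, otherwise the lexicographically first group.
#' @param validate if `FALSE`, skip the integrity checks (uniqueness, at
#'   least two sets per reaction). Used internally for training subsamples,
#'   which need not be complete campaigns.
#' @return object of class `reaction_table` with elements `records`,
#'   `positions`, `groups`, `reactions`, `reference_set`.
#' @export
reaction_table <- function(records, positions = NULL, reference_set = NULL,
                           validate = TRUE) {
  stopifnot(is.data.frame(records))
  required <- c("reaction_id", "response", "response_type")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("reaction table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(positions)) {
    positions <- sort(setdiff(names(records), required))
  }
  if (length(positions) < 1L) {
    stop("reaction table schema error: no position columns found")
  }
  missing_pos <- setdiff(positions, names(records))
  if (length(missing_pos) > 0L) {
    stop("reaction table schema error: missing position column(s) ",
         paste(missing_pos, collapse = ", "))
  }
  positions <- sort(positions)

  records$reaction_id <- as.character(records$reaction_id)
  for (p in positions) records[[p]] <- as.character(records[[p]])
  if (!is.numeric(records$response) || any(!is.finite(records$response))) {
    stop("reaction table value error: non-finite or non-numeric response")
  }
  rtype <- unique(as.character(records$response_type))
  if (length(rtype) != 1L ||
      !rtype %in% c("log10_k", "activation_energy_kcal_mol")) {
    stop("reaction table schema error: response_type must be uniform and one ",
         "of 'log10_k', 'activation_energy_kcal_mol'")
  }

  groups <- sort(unique(unlist(records[positions], use.names = FALSE)))
  if (any(grepl(.KEY_SEP, groups, fixed = TRUE))) {
    stop("group labels may not contain '", .KEY_SEP, "'")
  }
  reactions <- sort(unique(records$reaction_id))
  if (validate) {
    if (length(groups) < 2L) {
      stop("reaction table integrity error: need at least 2 distinct groups")
    }
    keys <- apply(as.matrix(records[positions]), 1L, set_key_from_groups)
    dup <- duplicated(paste(records$reaction_id, keys, sep = "\r"))
    if (any(dup)) {
      stop("reaction table integrity error: duplicate (reaction, substituent ",
           "set) rows at ", paste(which(dup), collapse = ", "))
    }
    sets_per_rxn <- tapply(keys, records$reaction_id,
                           function(k) length(unique(k)))
    if (any(sets_per_rxn < 2L)) {
      stop("reaction table integrity error: reaction(s) with fewer than 2 ",
           "substituent sets: ",
           paste(names(sets_per_rxn)[sets_per_rxn < 2L], collapse = ", "))
    }
  }

  if (is.null(reference_set)) {
    ref_group <- if ("H" %in% groups) "H" else groups[1L]
    reference_set <- setNames(rep(ref_group, length(positions)), positions)
  } else {
    if (!setequal(names(reference_set), positions)) {
      stop("reference_set must name exactly the table positions")
    }
    reference_set <- reference_set[positions]
  }

  rownames(records) <- NULL
  structure(
    list(records = records[, c("reaction_id", positions, "response",
                               "response_type")],
         positions = positions, groups = groups, reactions = reactions,
         reference_set = reference_set),
    class = "reaction_table")
}

#' @export
print.reaction_table <- function(x, ...) {
  cat("reaction_table:", nrow(x$records), "records,",
      length(x$reactions), "reactions,",
      length(set_keys(x)$levels), "substituent sets,",
      length(x$groups), "groups at", length(x$positions), "positions\n")
  cat("  response_type:", x$records$response_type[1L], "\n")
  cat("  reference set:", set_key_from_groups(x$reference_set), "\n")
  invisible(x)
}

#' Substituent-set keys of a reaction table
#'
#' @param table a `reaction_table`.
#' @return list with `key` (one key per record, groups joined in position
#'   order) and `levels` (sorted unique keys).
#' @export
set_keys <- function(table) {
  key <- apply(as.matrix(table$records[table$positions]), 1L,
               set_key_from_groups)
  list(key = key, levels = sort(unique(key)))
}

reference_key <- function(table) set_key_from_groups(table$reference_set)

#' Read a reaction table from CSV
#'
#' The CSV is long format, UTF-8, '.' decimal separator, one row per
#' (reaction, substituent set), with header columns `reaction_id`, one column
#' per scaffold position, `response`, `response_type`.
#'
#' @inheritParams reaction_table
#' @param path CSV file path.
#' @return a `reaction_table`; vocabularies are inferred and sorted
#'   lexicographically, so identical input always yields identical ordering.
#' @export
read_reaction_table <- function(path, positions = NULL, reference_set = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  reaction_table(df, positions = positions, reference_set = reference_set)
}

#' Write a reaction table to CSV
#'
#' @param table a `reaction_table`.
#' @param path output CSV path.
#' @export
write_reaction_table <- function(table, path) {
  stopifnot(inherits(table, "reaction_table"))
  write.csv(table$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a scaffold geometry
#'
#' Describes where each substitution position sits relative to the reaction
#' center: a through-space distance in Angstrom, and (optionally, required
#' only for the three-body model) Cartesian coordinates.
#'
#' @param positions character vector of position labels.
#' @param distances numeric vector of distances to the reaction center (A, > 0).
#' @param coordinates optional numeric matrix (length(positions) x 3) of
#'   Cartesian coordinates (A); must be consistent with `distances` to 1e-6 A.
#' @param reaction_center numeric length-3 center coordinates (default origin).
#' @return object of class `scaffold_geometry`.
#' @export
scaffold_geometry <- function(positions, distances, coordinates = NULL,
                              reaction_center = c(0, 0, 0)) {
  stopifnot(length(positions) == length(distances))
  if (any(!is.finite(distances)) || any(distances <= 0)) {
    stop("geometry error: distances must be finite and strictly positive")
  }
  names(distances) <- positions
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    stopifnot(nrow(coordinates) == length(positions), ncol(coordinates) == 3L)
    rownames(coordinates) <- positions
    d_from_xyz <- sqrt(rowSums(sweep(coordinates, 2L, reaction_center)^2))
    if (any(abs(d_from_xyz - distances) > 1e-6)) {
      bad <- positions[abs(d_from_xyz - distances) > 1e-6]
      stop("geometry error: coordinates inconsistent with distances at ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(positions = positions, distances = distances,
                 coordinates = coordinates,
                 reaction_center = as.numeric(reaction_center)),
            class = "scaffold_geometry")
}

#' Read a scaffold geometry from CSV
#'
#' Columns: `position`, `distance_A`, and optionally `x`, `y`, `z`.
#'
#' @param path CSV path.
#' @param reaction_center numeric length-3; default origin.
#' @return a `scaffold_geometry`.
#' @export
read_geometry <- function(path, reaction_center = c(0, 0, 0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("position", "distance_A") %in% names(df))) {
    stop("geometry schema error: need columns position, distance_A")
  }
  coords <- NULL
  if (all(c("x", "y", "z") %in% names(df)) && !anyNA(df[c("x", "y", "z")])) {
    coords <- as.matrix(df[c("x", "y", "z")])
  }
  scaffold_geometry(as.character(df$position), df$distance_A, coords,
                    reaction_center)
}

#' Write a scaffold geometry to CSV
#' @param geometry a `scaffold_geometry`.
#' @param path output CSV path.
#' @export
write_geometry <- function(geometry, path) {
  df <- data.frame(position = geometry$positions,
                   distance_A = unname(geometry$distances))
  if (!is.null(geometry$coordinates)) {
    df$x <- geometry$coordinates[, 1L]
    df$y <- geometry$coordinates[, 2L]
    df$z <- geometry$coordinates[, 3L]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize fitted parameters to JSON
#'
#' Writes a `hammett_params` or `alpha_model` object to a human-readable JSON
#' file at full double precision, including gauge anchors and fit
#' diagnostics, such that [read_parameters()] reproduces the object exactly.
#'
#' @param params a `hammett_params` or `alpha_model`.
#' @param path output JSON path.
#' @export
write_parameters <- function(params, path) {
  if (!inherits(params, c("hammett_params", "alpha_model"))) {
    stop("write_parameters expects a hammett_params or alpha_model object")
  }
  payload <- unclass(params)
  # jsonlite drops names on atomic vectors and serializes matrices as bare
  # arrays; convert to named lists so keys survive the round trip
  payload <- lapply(payload, function(v) {
    if (is.matrix(v)) {
      cols <- lapply(seq_len(ncol(v)), function(j) as.list(v[, j]))
      names(cols) <- if (!is.null(colnames(v))) colnames(v) else
        paste0("c", seq_len(ncol(v)))
      cols
    } else if (is.atomic(v) && !is.null(names(v))) {
      as.list(v)
    } else {
      v
    }
  })
  payload$.class <- class(params)[1L]
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing parameters: ", conditionMessage(ok))
  invisible(path)
}

#' Read fitted parameters from JSON
#'
#' @param path JSON path written by [write_parameters()].
#' @return the restored `hammett_params` or `alpha_model`.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- x$.class
  if (is.null(cls)) stop("parameter parse error: missing .class tag")
  x$.class <- NULL
  as_named_num <- function(v) {
    if (is.null(v)) return(NULL)
    setNames(vapply(v, as.numeric, numeric(1)), names(v))
  }
  as_matrix <- function(v) {
    if (is.null(v)) return(NULL)
    cols <- lapply(v, as_named_num)
    m <- do.call(cbind, cols)
    colnames(m) <- names(v)
    m
  }
  unscalar <- function(v) if (is.list(v)) unlist(v) else v
  # scalars arrive as length-1 lists under simplifyVector = FALSE
  scalar_pass <- function(x) {
    lapply(x, function(v) {
      if (is.list(v) && length(v) == 1L && is.null(names(v)) &&
          is.atomic(v[[1L]]) && length(v[[1L]]) == 1L) v[[1L]] else v
    })
  }
  x <- scalar_pass(x)
  if (cls == "hammett_params") {
    for (f in c("rho", "sigma", "offsets")) x[[f]] <- as_named_num(x[[f]])
    for (f in c("unassigned_reactions", "unassigned_sets")) {
      x[[f]] <- unscalar(x[[f]])
    }
    if (is.null(x$anchor_reaction)) {
      stop("parameter parse error: missing gauge anchor (anchor_reaction)")
    }
    structure(x, class = "hammett_params")
  } else if (cls == "alpha_model") {
    if (is.null(x$baseline_group)) {
      stop("parameter parse error: missing gauge anchor (baseline_group)")
    }
    for (f in c("alpha_by_group_position", "coordinates")) {
      x[[f]] <- as_matrix(x[[f]])
    }
    for (f in c("alpha_by_group", "beta_by_pair", "distances",
                "atm_factors")) {
      x[[f]] <- as_named_num(x[[f]])
    }
    for (f in c("groups", "positions", "reaction_center")) {
      x[[f]] <- unscalar(x[[f]])
    }
    structure(x, class = "alpha_model")
  } else {
    stop("parameter parse error: unknown class tag '", cls, "'")
  }
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; top-level keys are option names.
#' @param defaults named list of defaults; file values override defaults.
#' @return named list.
#' @export
read_run_config <- function(path, defaults = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  modifyList(defaults, cfg)
}
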