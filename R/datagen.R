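# Parameter sweep designs and mechanistic dataset generation.

# Boustrophedon (snake) ordering of a full-factorial grid: consecutive rows
# differ in exactly one dimension by exactly one level, which makes the
# sweep continuation-friendly (every solve is warm-started from an adjacent
# parameter set).
.snake_indices <- function(levels) {
  k <- length(levels)
  idx <- matrix(seq_len(levels[1]), ncol = 1)
  if (k == 1) return(idx)
  for (d in 2:k) {
    blocks <- vector("list", levels[d])
    for (i in seq_len(levels[d])) {
      blk <- if (i %% 2 == 1) idx else idx[rev(seq_len(nrow(idx))), , drop = FALSE]
      blocks[[i]] <- cbind(blk, rep(i, nrow(blk)))
    }
    idx <- do.call(rbind, blocks)
  }
  unname(idx)
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Default parameter ranges for a variant's four varied parameters
#'
#' Multiplicative bounds on baseline, defaulting to the 50%-200% training
#' box.
#'
#' @param cell_type "PCT" or "mTAL"
#' @param lo_frac,hi_frac multiplicative bounds (0 < lo < hi)
#' @return named list of `c(lo_frac, hi_frac)` pairs
#' @export
parameter_ranges <- function(cell_type, lo_frac = 0.5, hi_frac = 2.0) {
  stopifnot(lo_frac > 0, lo_frac < hi_frac)
  nm <- varied_parameters(cell_type)
  stats::setNames(rep(list(c(lo_frac = lo_frac, hi_frac = hi_frac)), length(nm)), nm)
}

#' Build a parameter design (grid, random, or inhibition-shifted)
#'
#' \describe{
#'   \item{grid}{full factorial with `levels` log-spaced levels per parameter
#'     over its range, ordered along a snake path so that consecutive points
#'     differ in exactly one parameter by one level (continuation-friendly).}
#'   \item{random}{`n` vectors i.i.d. log-uniform over each range.}
#'   \item{inhibition}{the named parameter is drawn uniformly on
#'     `[mean - half_width, mean + half_width]` times baseline, with
#'     `mean = 1 - mean_reduction_frac`; the other parameters stay log-uniform
#'     over their training ranges.}
#' }
#' An optional `nuisance` jitter (e.g. `list(SGLT2 = 0.10)`) adds a column of
#' log-uniform multipliers on `[1 - a, 1 + a]` for a fixed-baseline pathway.
#'
#' @param ranges result of [parameter_ranges()] (exactly four parameters)
#' @param mode "grid", "random" or "inhibition"
#' @param n_or_levels grid levels per parameter (>= 2), or sample count (>= 1)
#' @param seed RNG seed (used by random/inhibition modes and nuisance jitter)
#' @param inhibition list with `parameter`, `mean_reduction_frac`,
#'   `half_width_frac` (required for inhibition mode)
#' @param nuisance optional named list of jitter half-widths for nuisance
#'   pathways (applied multiplicatively around 1)
#' @return object of class `sweep_design`
#' @export
build_design <- function(ranges, mode = c("grid", "random", "inhibition"),
                         n_or_levels, seed = 1L, inhibition = NULL,
                         nuisance = NULL) {
  mode <- match.arg(mode)
  params <- names(ranges)
  if (length(params) != 4) stop("build_design expects exactly four parameter ranges")
  lo <- vapply(ranges, `[[`, numeric(1), 1)
  hi <- vapply(ranges, `[[`, numeric(1), 2)

  if (mode == "grid") {
    levels <- as.integer(n_or_levels)
    if (levels < 2) stop("grid mode requires levels >= 2")
    grids <- mapply(function(l, h) exp(seq(log(l), log(h), length.out = levels)),
                    lo, hi, SIMPLIFY = FALSE)
    idx <- .snake_indices(rep(levels, 4L))
    pts <- vapply(1:4, function(j) grids[[j]][idx[, j]], numeric(nrow(idx)))
  } else {
    n <- as.integer(n_or_levels)
    if (n < 1) stop("random/inhibition modes require n >= 1")
    if (mode == "inhibition") {
      if (is.null(inhibition) ||
          !all(c("parameter", "mean_reduction_frac") %in% names(inhibition))) {
        stop("inhibition mode requires inhibition = list(parameter, mean_reduction_frac, half_width_frac)")
      }
      if (!inhibition$parameter %in% params) {
        stop("inhibition parameter '", inhibition$parameter,
             "' is not among the design parameters")
      }
      hw <- inhibition$half_width_frac %||% 0.2
    }
    pts <- .with_seed(seed, {
      m <- matrix(0, n, 4)
      for (j in 1:4) {
        if (mode == "inhibition" && params[j] == inhibition$parameter) {
          mu <- 1 - inhibition$mean_reduction_frac
          m[, j] <- stats::runif(n, mu - hw, mu + hw)
        } else {
          m[, j] <- exp(stats::runif(n, log(lo[j]), log(hi[j])))
        }
      }
      m
    })
    idx <- NULL
  }
  colnames(pts) <- params

  nuis <- NULL
  if (!is.null(nuisance)) {
    nuis <- .with_seed(seed + 1L, {
      m <- vapply(names(nuisance), function(nm) {
        a <- nuisance[[nm]]
        exp(stats::runif(nrow(pts), log(1 - a), log(1 + a)))
      }, numeric(nrow(pts)))
      m <- matrix(m, nrow = nrow(pts),
                  dimnames = list(NULL, names(nuisance)))
      m
    })
  }

  structure(list(
    mode = mode, params = params, points = pts, nuisance = nuis,
    ranges = ranges, seed = seed, inhibition = inhibition,
    grid_index = idx
  ), class = "sweep_design")
}

#' @export
print.sweep_design <- function(x, ...) {
  cat(sprintf("<sweep_design> mode=%s, %d points x [%s]%s\n", x$mode,
              nrow(x$points), paste(x$params, collapse = ", "),
              if (!is.null(x$nuisance))
                paste0(" + nuisance [", paste(colnames(x$nuisance), collapse = ", "), "]")
              else ""))
  invisible(x)
}

.dataset_output_cols <- c("Na_cell", "K_cell", "Va", "Vb", "J_Na", "J_K")

#' Run the mechanistic model over a design
#'
#' Solves each design point in order.  Grid designs are warm-started from the
#' previous converged solution along the snake path; random/inhibition
#' designs from the nearest already-solved point in log-fraction space.  On
#' failure the solver falls back to the cold start and finally to the
#' pseudo-transient relaxation oracle (used as an initial guess for a final
#' Newton polish).  Rows that remain unsolved are flagged and the dataset is
#' marked incomplete.
#'
#' @param variant a `model_variant`
#' @param design a `sweep_design` whose parameters match the variant
#' @return object of class `transport_dataset`: a table pairing parameter
#'   fractions (and absolute values) with solved outputs (cytosolic Na+ and
#'   K+, Va, Vb, transcellular Na+ and K+ fluxes), plus provenance metadata
#' @export
generate_dataset <- function(variant, design) {
  if (!identical(design$params, variant$varied)) {
    stop("design parameters do not match variant: expected ",
         paste(variant$varied, collapse = ", "))
  }
  pts <- design$points
  n <- nrow(pts)
  logpts <- log(pts)

  out <- matrix(NA_real_, n, length(.dataset_output_cols),
                dimnames = list(NULL, .dataset_output_cols))
  iters <- integer(n)
  conv <- logical(n)

  base_state <- solve_steady_state(variant)
  prev <- if (isTRUE(base_state$converged)) base_state else NULL
  solved_states <- list()
  solved_log <- matrix(numeric(0), 0, 4)

  for (i in seq_len(n)) {
    frac <- pts[i, ]
    if (!is.null(design$nuisance)) {
      frac <- c(frac, design$nuisance[i, ])
    }
    pm <- apply_parameters(variant, frac)

    guesses <- list()
    if (design$mode == "grid") {
      if (!is.null(prev)) guesses <- c(guesses, list(prev))
    } else if (nrow(solved_log) > 0) {
      d2 <- colSums((t(solved_log) - logpts[i, ])^2)
      guesses <- c(guesses, list(solved_states[[which.min(d2)]]))
    } else if (!is.null(prev)) {
      guesses <- c(guesses, list(prev))
    }
    guesses <- c(guesses, list(NULL))  # cold start fallback

    st <- NULL
    for (g in guesses) {
      st <- suppressWarnings(
        solve_steady_state(variant, pm$activities, pm$membranes,
                           initial_guess = g))
      if (isTRUE(st$converged)) break
    }
    if (!isTRUE(st$converged)) {
      rx <- tryCatch(
        relax_to_steady_state(variant, pm$activities, pm$membranes),
        error = function(e) NULL)
      if (!is.null(rx) && isTRUE(rx$converged)) {
        st <- suppressWarnings(
          solve_steady_state(variant, pm$activities, pm$membranes,
                             initial_guess = rx))
      }
    }

    if (isTRUE(st$converged)) {
      out[i, ] <- c(st$conc[["Na"]], st$conc[["K"]], st$Va, st$Vb,
                    st$fluxes$basolateral[["Na"]],
                    st$fluxes$basolateral[["K"]])
      conv[i] <- TRUE
      iters[i] <- st$iterations
      if (design$mode == "grid") {
        prev <- st
      } else {
        solved_states[[length(solved_states) + 1L]] <- st
        solved_log <- rbind(solved_log, logpts[i, ])
      }
    } else {
      .nn_log(sprintf("dataset row %d unsolved after all fallbacks", i),
              warn = TRUE)
    }
  }

  tab <- data.frame(pts, check.names = FALSE)
  names(tab) <- paste0("f_", design$params)
  if (!is.null(design$nuisance)) {
    nt <- data.frame(design$nuisance, check.names = FALSE)
    names(nt) <- paste0("f_", colnames(design$nuisance))
    tab <- cbind(tab, nt)
  }
  abs_base <- absolute_parameters(variant)
  for (p in design$params) {
    tab[[paste0("x_", p)]] <- pts[, p] * abs_base[[p]]
  }
  tab <- cbind(tab, as.data.frame(out))
  tab$converged <- conv
  tab$iterations <- iters

  structure(list(
    table = tab,
    meta = list(
      cell_type = variant$cell_type,
      sex = variant$sex,
      params = design$params,
      design_mode = design$mode,
      design_seed = design$seed,
      inhibition = design$inhibition,
      nuisance = if (is.null(design$nuisance)) NULL
                 else as.list(colnames(design$nuisance)),
      n = n,
      n_unconverged = sum(!conv),
      incomplete = any(!conv),
      failed_rows = if (any(!conv)) which(!conv) else NULL,
      created = format(Sys.time(), tz = "UTC", usetz = TRUE),
      version = as.character(utils::packageVersion("nephroNN"))
    )
  ), class = "transport_dataset")
}

#' @export
print.transport_dataset <- function(x, ...) {
  cat(sprintf("<transport_dataset> %s/%s, %d rows (%s design)%s\n",
              x$meta$cell_type, x$meta$sex, nrow(x$table),
              x$meta$design_mode,
              if (isTRUE(x$meta$incomplete))
                sprintf(" [INCOMPLETE: %d unsolved]", x$meta$n_unconverged)
              else ""))
  invisible(x)
}

#' Merge datasets (e.g. male + female for sex-inclusive training)
#'
#' @param ... `transport_dataset` objects with identical columns
#' @return merged `transport_dataset`
#' @export
merge_datasets <- function(...) {
  ds <- list(...)
  stopifnot(length(ds) >= 1)
  tabs <- lapply(ds, `[[`, "table")
  cols <- Reduce(intersect, lapply(tabs, names))
  tab <- do.call(rbind, lapply(tabs, function(t) t[, cols, drop = FALSE]))
  rownames(tab) <- NULL
  meta <- ds[[1]]$meta
  meta$sex <- paste(unique(vapply(ds, function(d) d$meta$sex, "")),
                    collapse = "+")
  meta$n <- nrow(tab)
  meta$incomplete <- any(vapply(ds, function(d) isTRUE(d$meta$incomplete), TRUE))
  structure(list(table = tab, meta = meta), class = "transport_dataset")
}

#' Write / read a dataset as CSV plus JSON metadata sidecar
#'
#' The table goes to `<path>.csv` (RFC-4180, header row, '.' decimal) and
#' the metadata to `<path>.json`.  The round trip is lossless to full double
#' precision.  Incomplete datasets (unconverged rows) are refused.
#'
#' @param ds a `transport_dataset`
#' @param path file stem (without extension)
#' @export
write_dataset <- function(ds, path) {
  if (isTRUE(ds$meta$incomplete)) {
    stop("refusing to write an incomplete dataset (",
         ds$meta$n_unconverged, " unconverged rows)")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tab <- ds$table
  utils::write.csv(format(tab, digits = 17, scientific = TRUE, trim = TRUE),
                   paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- ds$meta
  meta$n_rows <- nrow(tab)
  meta$columns <- names(tab)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @return `read_dataset`: the reconstructed `transport_dataset`
#' @export
read_dataset <- function(path) {
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(js)) {
    stop("dataset file pair not found at stem: ", path)
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  tab <- utils::read.csv(csv, check.names = FALSE)
  if (!identical(nrow(tab), as.integer(meta$n_rows))) {
    stop("dataset format error: sidecar declares ", meta$n_rows,
         " rows but table has ", nrow(tab))
  }
  missing <- setdiff(meta$columns, names(tab))
  if (length(missing) > 0) {
    stop("dataset format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab$converged <- as.logical(tab$converged)
  meta$n_rows <- NULL
  meta$columns <- NULL
  if (is.null(meta$failed_rows) || length(meta$failed_rows) == 0) meta["failed_rows"] <- list(NULL)
  structure(list(table = tab, meta = as.list(meta)),
            class = "transport_dataset")
}
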