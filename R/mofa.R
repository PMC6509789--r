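#' Multi-objective flux analysis via the Normalized Normal Constraint method
#'
#' MOFA maps the n-dimensional Pareto front of competing flux objectives on a
#' stoichiometric model. The NNC method: (1) finds the n anchor points, each
#' the lexicographic optimum of one objective; (2) normalises objective space
#' so each anchor attains 1 in its own coordinate (making the result
#' independent of objective scales); (3) lays an even lattice of points on the
#' utopia hyperplane through the normalised anchors; (4) at each lattice point
#' adds the n-1 normal half-space constraints and optimises the remaining
#' (last-declared) objective; (5) filters the collected solutions for
#' dominance and duplicates.
#'
#' @name mofa
NULL

#' Define a multi-objective flux problem
#'
#' @param model A `stoich_model`.
#' @param objectives List of at least two [flux_objective()]s with unique
#'   labels. The last one is the "lone" objective optimised at each lattice
#'   point; reorder the list to change it.
#' @param spacing Positive integer m: the utopia-plane lattice step is 1/m of
#'   the normalised range (m = 10 reproduces a 1/10-interval examination).
#' @return A `mofa_problem`.
#' @export
mofa_problem <- function(model, objectives, spacing = 10) {
  stopifnot(length(objectives) >= 2, spacing >= 1, spacing == round(spacing))
  labels <- vapply(objectives, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("objective labels must be unique", call. = FALSE)
  for (o in objectives) objective_vector(model, o) # id resolution check
  structure(list(model = model, objectives = objectives,
                 spacing = as.integer(spacing), labels = labels),
            class = "mofa_problem")
}

# Raw (model-scale) objective values of a flux vector, in declared order.
objective_values <- function(problem, x) {
  vapply(problem$objectives, function(o) {
    sum(objective_vector(problem$model, o) * x)
  }, numeric(1))
}

# sense: +1 for maximise, -1 for minimise (all work happens in max sense)
objective_senses <- function(problem) {
  vapply(problem$objectives, function(o) if (o$direction == "max") 1 else -1,
         numeric(1))
}

#' Compute the NNC anchor points and normalisation geometry
#'
#' Anchor k is the lexicographic solution optimising objective k, refined to
#' the minimum-total-flux representative among its alternate optima. The
#' utopia point collects the per-objective bests, the nadir the worsts over
#' the anchors, and the affine normalisation maps each objective onto [0, 1]
#' in maximisation sense.
#'
#' @param problem A `mofa_problem`.
#' @return An `nnc_geometry`: `anchors_raw` (n x n, row k = objective values at
#'   anchor k), `anchors_norm`, `utopia`, `nadir` (in max sense), `sense`,
#'   `anchor_solutions` (list of `flux_solution`).
#' @export
compute_anchor_points <- function(problem) {
  n <- length(problem$objectives)
  sols <- vector("list", n)
  anchors_raw <- matrix(NA_real_, n, n,
                        dimnames = list(problem$labels, problem$labels))
  for (k in seq_len(n)) {
    sol <- fba(problem$model, problem$objectives[[k]], refine = "parsimonious")
    if (sol$status != "optimal") {
      stop("anchor optimisation failed for objective '", problem$labels[k],
           "' (status ", sol$status,
           "); cap any unbounded exchange (e.g. photon uptake)", call. = FALSE)
    }
    sols[[k]] <- sol
    anchors_raw[k, ] <- objective_values(problem, fluxes(sol))
  }
  sense <- objective_senses(problem)
  Zmax <- sweep(anchors_raw, 2, sense, `*`)
  utopia <- apply(Zmax, 2, max)
  nadir <- apply(Zmax, 2, min)
  range_ <- utopia - nadir
  scale_ <- ifelse(range_ > 1e-12, range_, 1)
  anchors_norm <- sweep(sweep(Zmax, 2, nadir, `-`), 2, scale_, `/`)
  structure(list(anchors_raw = anchors_raw, anchors_norm = anchors_norm,
                 utopia = utopia, nadir = nadir, scale = scale_,
                 sense = sense, anchor_solutions = sols,
                 labels = problem$labels),
            class = "nnc_geometry")
}

#' @export
print.nnc_geometry <- function(x, ...) {
  cat("<nnc_geometry>", length(x$labels), "anchors\n")
  print(round(x$anchors_norm, 4))
  invisible(x)
}

normalize_values <- function(geometry, raw) {
  (geometry$sense * raw - geometry$nadir) / geometry$scale
}

#' Even lattice of weights on the utopia simplex
#'
#' All weight vectors `(w1, ..., wn)` with entries in `{0, 1/m, ..., 1}` and
#' unit sum, in deterministic lexicographic order. The count is the simplex
#' lattice number `choose(m + n - 1, n - 1)`.
#'
#' @param n Number of objectives (>= 2).
#' @param m Spacing denominator (>= 1).
#' @return Matrix with one weight vector per row.
#' @examples
#' nrow(generate_utopia_lattice(3, 5)) # choose(7, 2) = 21
#' @export
generate_utopia_lattice <- function(n, m) {
  stopifnot(n >= 2, m >= 1)
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- vector("list", total + 1)
    for (first in total:0) {
      rest <- compositions(total - first, parts - 1)
      out[[total - first + 1]] <- cbind(first, rest, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  w <- compositions(m, n) / m
  dimnames(w) <- NULL
  w
}

# Build the lone-objective LP for one lattice point and solve it.
# Returns list(feasible, raw, norm, solution).
nnc_point_lp <- function(problem, geometry, weights, refine = TRUE) {
  model <- problem$model
  n_obj <- length(problem$objectives)
  n_rxn <- nrow(model$reactions)
  sense <- geometry$sense
  # normalised objective j as an affine map of v:
  #   zbar_j(v) = (sense_j * c_j . v - nadir_j) / scale_j
  C <- vapply(problem$objectives, function(o) objective_vector(model, o),
              numeric(n_rxn))                       # n_rxn x n_obj
  Cn <- sweep(C, 2, sense / geometry$scale, `*`)    # rows of zbar in v-space
  offset <- geometry$nadir / geometry$scale
  p <- as.numeric(weights %*% geometry$anchors_norm) # utopia-plane point
  # normal constraints: (e_n - e_k) . (zbar - p) <= 0 for k < n, i.e. the
  # Messac half-spaces translated to maximisation sense; stated here as the
  # equivalent (e_k - e_n) . (zbar - p) >= 0
  A_ge <- NULL; b_ge <- NULL
  en <- geometry$anchors_norm[n_obj, ]
  for (k in seq_len(n_obj - 1)) {
    d <- geometry$anchors_norm[k, ] - en
    A_ge <- rbind(A_ge, as.numeric(Cn %*% d))
    b_ge <- c(b_ge, sum(d * p) + sum(d * offset))
  }
  lone <- C[, n_obj] * sense[n_obj]  # maximise the last objective in max sense
  res <- fba_lp(model, lone, maximize = TRUE, A_ge = A_ge, b_ge = b_ge)
  if (res$status != "optimal") {
    return(list(feasible = FALSE, raw = NULL, norm = NULL, solution = NULL))
  }
  x <- res$x
  if (refine) {
    x2 <- parsimonious_lp(model, lone, res$objective_value,
                          A_ge = A_ge, b_ge = b_ge)
    if (!is.null(x2)) x <- x2
  }
  raw <- objective_values(problem, x)
  list(feasible = TRUE, raw = raw, norm = normalize_values(geometry, raw),
       solution = new_flux_solution(model, x, res$objective_value, "optimal",
                                    problem$labels[n_obj], "max"))
}

#' Solve one utopia-lattice point
#'
#' In normalised (all-maximise) space, the utopia-plane point is the
#' weight-combination of the normalised anchors; the n-1 normal half-space
#' constraints `(e_n - e_k) . (zbar - p) <= 0` are added and the last
#' objective is maximised (the standard normal-constraint geometry, restated
#' in maximisation sense).
#'
#' @param problem A `mofa_problem`.
#' @param geometry From [compute_anchor_points()].
#' @param weights Weight vector on the anchors (non-negative, unit sum).
#' @param refine Apply minimum-total-flux refinement to the solution.
#' @return List with `feasible`, `raw` and `norm` objective vectors, and the
#'   `flux_solution` (or `feasible = FALSE` for a skipped point).
#' @export
solve_lattice_point <- function(problem, geometry, weights, refine = TRUE) {
  stopifnot(length(weights) == length(problem$objectives),
            all(weights >= -1e-12), abs(sum(weights) - 1) < 1e-9)
  nnc_point_lp(problem, geometry, weights, refine = refine)
}

#' Filter a solution set to its Pareto-optimal members
#'
#' Removes duplicates (equal within `tol` after rounding) and dominated points
#' (another point at least as good in every coordinate and strictly better in
#' one, in maximisation sense, beyond `tol`). Order is stable.
#'
#' @param solutions Numeric matrix (rows = points, maximisation sense) or a
#'   data frame of numeric columns.
#' @param tol Dominance/duplicate tolerance.
#' @return Integer vector of kept row indices.
#' @export
pareto_filter <- function(solutions, tol = 1e-6) {
  M <- as.matrix(solutions)
  storage.mode(M) <- "double"
  n <- nrow(M)
  if (n == 0) return(integer(0))
  keep <- rep(TRUE, n)
  digits <- max(0L, ceiling(-log10(tol)))
  key <- apply(round(M, digits), 1, paste, collapse = "|")
  keep[duplicated(key)] <- FALSE
  idx <- which(keep)
  for (i in idx) {
    if (!keep[i]) next
    others <- idx[keep[idx] & idx != i]
    if (length(others) == 0) next
    diffs <- sweep(M[others, , drop = FALSE], 2, M[i, ], `-`)
    dominates <- apply(diffs, 1, function(d) all(d >= -tol) && any(d > tol))
    if (any(dominates)) keep[i] <- FALSE
  }
  which(keep)
}

#' Run a full MOFA analysis
#'
#' Anchors, utopia lattice, per-point constrained LPs, then Pareto filtering.
#' Infeasible lattice points are expected on non-convex reachable sets; they
#' are counted, not fatal.
#'
#' @param problem A `mofa_problem`.
#' @param refine Apply minimum-total-flux refinement at each point.
#' @param progress Emit a message every `progress` points (0 = quiet).
#' @return A `pareto_front`: `solutions` (tibble of unique Pareto-optimal
#'   points: weights, raw and normalised objective values, fluxes as a
#'   list-column), `all` (every feasible lattice point), `n_skipped`,
#'   `geometry`, `spacing`, `labels`. Has `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @examples
#' toy <- make_toy(P = 50, A = 10)
#' prob <- mofa_problem(toy, list(
#'   biomass_objective(toy),
#'   reaction_objective("EX_h2", label = "H2")
#' ), spacing = 10)
#' front <- run_mofa(prob)
#' glance(front)
#' @export
run_mofa <- function(problem, refine = TRUE, progress = 0) {
  geometry <- compute_anchor_points(problem)
  W <- generate_utopia_lattice(length(problem$objectives), problem$spacing)
  rows <- vector("list", nrow(W))
  n_skipped <- 0L
  for (i in seq_len(nrow(W))) {
    res <- solve_lattice_point(problem, geometry, W[i, ], refine = refine)
    if (!res$feasible) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[i]] <- tibble::tibble(
      point = i,
      weights = list(W[i, ]),
      raw = list(stats::setNames(res$raw, problem$labels)),
      norm = list(stats::setNames(res$norm, problem$labels)),
      flux = list(res$solution)
    )
    if (progress > 0 && i %% progress == 0) {
      message("MOFA: ", i, "/", nrow(W), " lattice points")
    }
  }
  all_tbl <- dplyr::bind_rows(rows)
  if (nrow(all_tbl) == 0) stop("every lattice point was infeasible", call. = FALSE)
  norm_mat <- do.call(rbind, all_tbl$norm)
  kept <- pareto_filter(norm_mat, tol = 1e-6)
  structure(list(
    solutions = all_tbl[kept, ],
    all = all_tbl,
    n_skipped = n_skipped,
    geometry = geometry,
    spacing = problem$spacing,
    labels = problem$labels
  ), class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf(
    "<pareto_front> %d objectives, spacing %d: %d unique Pareto-optimal of %d feasible lattice points (%d skipped)\n",
    length(x$labels), x$spacing, nrow(x$solutions), nrow(x$all), x$n_skipped))
  invisible(x)
}

#' @export
tidy.pareto_front <- function(x, ...) {
  norm_mat <- do.call(rbind, x$solutions$norm)
  raw_mat <- do.call(rbind, x$solutions$raw)
  colnames(norm_mat) <- paste0("norm_", x$labels)
  colnames(raw_mat) <- paste0("raw_", x$labels)
  dplyr::bind_cols(
    tibble::tibble(point = x$solutions$point),
    tibble::as_tibble(norm_mat),
    tibble::as_tibble(raw_mat)
  )
}

#' @export
glance.pareto_front <- function(x, ...) {
  tibble::tibble(
    n_objectives = length(x$labels),
    spacing = x$spacing,
    n_lattice = nrow(x$all) + x$n_skipped,
    n_feasible = nrow(x$all),
    n_unique = nrow(x$solutions),
    n_skipped = x$n_skipped
  )
}

#' Export a Pareto front as TSV
#'
#' One row per unique Pareto-optimal solution; normalised objective columns
#' (`norm_*`) in declared order followed by raw columns (`raw_*`) — the layout
#' used for heat-map rendering.
#'
#' @param front A `pareto_front`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_front <- function(front, path) {
  if (nrow(front$solutions) == 0) stop("front is empty", call. = FALSE)
  utils::write.table(as.data.frame(tidy(front)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an exported Pareto front
#'
#' @param path TSV written by [export_front()].
#' @return Tibble in the [tidy()] layout.
#' @export
read_front <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
}

#' Heat-map of a Pareto front
#'
#' Solutions (rows, ordered by the first objective) against objectives
#' (columns), filled by normalised value — the standard way to display
#' high-dimensional fronts.
#'
#' @param object A `pareto_front`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pareto_front <- function(object, ...) {
  tt <- tidy(object)
  norm_cols <- paste0("norm_", object$labels)
  ord <- order(tt[[norm_cols[1]]], decreasing = TRUE)
  long <- tt[ord, c("point", norm_cols)]
  long$rank <- seq_len(nrow(long))
  long <- tidyr::pivot_longer(long, dplyr::all_of(norm_cols),
                              names_to = "objective", values_to = "value")
  long$objective <- factor(sub("^norm_", "", long$objective),
                           levels = object$labels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$objective, y = .data$rank,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "normalised\nvalue", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Pareto-optimal solution",
                  title = sprintf("%d-objective Pareto front (spacing 1/%d)",
                                  length(object$labels), object$spacing)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
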