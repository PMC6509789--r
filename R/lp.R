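#' Internal linear-programming interface
#'
#' One narrow surface over the LP machinery so that the analysis code never
#' manipulates a solver directly. The core is a dense bounded-variable
#' two-phase primal simplex written for the moderate problem sizes of
#' constraint-based models used here: variables carry explicit lower/upper
#' bounds, inequality rows get slack columns, phase 1 drives artificial
#' variables out of the basis, and the basis system is re-solved from scratch
#' every iteration (numerical stability over speed). Dantzig pricing with a
#' Bland's-rule fallback guards against cycling. All structural bounds are
#' kept finite (the package uses 1e6 for "unlimited"), so a failed phase 1
#' always means infeasible, never unbounded.
#'
#' @name lp-internal
#' @keywords internal
NULL

# Bounded-variable primal simplex for min c'x s.t. A x = b, lb <= x <= ub.
# Slack/artificial columns may have infinite upper bounds. Returns
# list(status, x, objective_value).
bounded_simplex <- function(cc, A, b, lb, ub, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  if (m == 0L) {
    # pure bound problem
    x <- ifelse(cc > 0, lb, ifelse(cc < 0, ub, lb))
    return(list(status = "optimal", x = x, objective_value = sum(cc * x)))
  }
  max_iter <- max_iter %||% (200L + 50L * (n + m))

  # start: structural variables at their finite lower (or upper) bound
  start_val <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  at_upper <- !is.finite(lb) & is.finite(ub)

  r <- b - as.numeric(A %*% start_val)
  art_sign <- ifelse(r >= 0, 1, -1)
  A_full <- cbind(A, diag(art_sign, m))
  lb_full <- c(lb, rep(0, m))
  ub_full <- c(ub, rep(Inf, m))
  n_full <- n + m

  basis <- n + seq_len(m)
  nb_at_upper <- at_upper   # length n status for structural nonbasic vars

  run_phase <- function(cost, basis, nb_at_upper, fixed_art) {
    if (fixed_art) ub_full[n + seq_len(m)] <<- 0
    bland <- FALSE
    for (it in seq_len(max_iter)) {
      nonbasic <- setdiff(seq_len(n_full), basis)
      x <- numeric(n_full)
      x[nonbasic] <- ifelse(nb_at_upper[nonbasic] & is.finite(ub_full[nonbasic]),
                            ub_full[nonbasic],
                            ifelse(is.finite(lb_full[nonbasic]), lb_full[nonbasic], 0))
      B <- A_full[, basis, drop = FALSE]
      rhs <- b - as.numeric(A_full[, nonbasic, drop = FALSE] %*% x[nonbasic])
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) {
        return(list(status = "numerical", basis = basis,
                    nb_at_upper = nb_at_upper, x = NULL))
      }
      x[basis] <- xB
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) {
        return(list(status = "numerical", basis = basis,
                    nb_at_upper = nb_at_upper, x = NULL))
      }
      d <- cost[nonbasic] - as.numeric(t(A_full[, nonbasic, drop = FALSE]) %*% y)
      eff <- ifelse(nb_at_upper[nonbasic], -d, d)
      cand <- which(eff < -tol)
      if (length(cand) == 0) {
        return(list(status = "optimal", basis = basis,
                    nb_at_upper = nb_at_upper, x = x,
                    objective = sum(cost * x)))
      }
      pick <- if (bland) cand[which.min(nonbasic[cand])] else cand[which.min(eff[cand])]
      q <- nonbasic[pick]
      dir <- if (nb_at_upper[q]) -1 else 1
      w <- as.numeric(solve(B, A_full[, q])) * dir

      # ratio test: basic vars hitting their bounds, or q flipping bound
      t_best <- if (is.finite(lb_full[q]) && is.finite(ub_full[q])) {
        ub_full[q] - lb_full[q]
      } else Inf
      leave <- 0L
      leave_to <- NA_character_
      for (i in seq_len(m)) {
        if (w[i] > tol) {
          if (is.finite(lb_full[basis[i]])) {
            t_i <- (xB[i] - lb_full[basis[i]]) / w[i]
            if (t_i < t_best - 1e-12) { t_best <- t_i; leave <- i; leave_to <- "lb" }
          }
        } else if (w[i] < -tol) {
          if (is.finite(ub_full[basis[i]])) {
            t_i <- (ub_full[basis[i]] - xB[i]) / (-w[i])
            if (t_i < t_best - 1e-12) { t_best <- t_i; leave <- i; leave_to <- "ub" }
          }
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded", basis = basis,
                    nb_at_upper = nb_at_upper, x = NULL))
      }
      if (leave == 0L) {
        # bound-to-bound flip of the entering variable
        nb_at_upper[q] <- !nb_at_upper[q]
      } else {
        out_var <- basis[leave]
        basis[leave] <- q
        nb_at_upper[out_var] <- identical(leave_to, "ub")
        nb_at_upper[q] <- FALSE
      }
      if (it > 10L * (n + m)) bland <- TRUE
    }
    list(status = "maxiter", basis = basis, nb_at_upper = nb_at_upper, x = NULL)
  }

  nb_full <- c(nb_at_upper, rep(FALSE, m))
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(c1, basis, nb_full, fixed_art = FALSE)
  if (p1$status != "optimal") {
    return(list(status = if (p1$status == "maxiter") "maxiter" else "numerical",
                x = rep(NA_real_, n), objective_value = NA_real_))
  }
  if (p1$objective > 1e-6) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective_value = NA_real_))
  }
  c2 <- c(cc, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$nb_at_upper, fixed_art = TRUE)
  if (p2$status != "optimal") {
    return(list(status = p2$status, x = rep(NA_real_, n),
                objective_value = NA_real_))
  }
  x <- p2$x[seq_len(n)]
  list(status = "optimal", x = x, objective_value = sum(cc * x))
}

#' Solve a bounded LP with equality and >= rows
#'
#' @param objective Numeric coefficient vector (length n).
#' @param lb,ub Finite variable bounds (length n).
#' @param A_eq,b_eq Equality rows `A_eq x = b_eq`.
#' @param A_ge,b_ge Inequality rows `A_ge x >= b_ge`.
#' @param maximize Direction.
#' @param eps Pivot tolerance.
#' @return List: `status` ("optimal", "infeasible", "maxiter", "numerical"),
#'   `x`, `objective_value`.
#' @keywords internal
lp_solve <- function(objective, lb, ub, A_eq = NULL, b_eq = NULL,
                     A_ge = NULL, b_ge = NULL, maximize = FALSE,
                     eps = 1e-9) {
  n <- length(objective)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve requires finite variable bounds", call. = FALSE)
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective_value = NA_real_))
  }
  A <- NULL
  b <- NULL
  if (!is.null(A_eq)) {
    A_eq <- matrix(A_eq, ncol = n)
    A <- A_eq
    b <- b_eq
  }
  n_slack <- 0L
  if (!is.null(A_ge)) {
    A_ge <- matrix(A_ge, ncol = n)
    n_slack <- nrow(A_ge)
    if (!is.null(A)) A <- cbind(A, matrix(0, nrow(A), n_slack))
    A <- rbind(A, cbind(A_ge, diag(-1, n_slack)))
    b <- c(b, b_ge)
  } else if (!is.null(A)) {
    # no slack columns needed
  }
  if (is.null(A)) {
    A <- matrix(0, 0, n)
    b <- numeric(0)
  }
  cc <- c(if (maximize) -objective else objective, rep(0, n_slack))
  res <- bounded_simplex(cc, A, b,
                         lb = c(lb, rep(0, n_slack)),
                         ub = c(ub, rep(Inf, n_slack)),
                         tol = eps)
  if (res$status != "optimal") {
    return(list(status = res$status, x = rep(NA_real_, n),
                objective_value = NA_real_))
  }
  x <- res$x[seq_len(n)]
  list(status = "optimal", x = x, objective_value = sum(objective * x))
}
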