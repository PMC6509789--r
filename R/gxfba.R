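#' Transcriptome-constrained flux prediction (GX-FBA)
#'
#' GX-FBA predicts the flux state after an environment or carbon-source
#' transition by combining the pre-transition flux distribution with gene
#' expression log2 fold changes. The procedure: (1) a reference flux
#' distribution for condition 1; (2) flux variability envelopes for condition
#' 2 with the biomass floor at zero, giving each reaction's mean possible flux
#' and the average capacity of active reactions; (3) a set T of reactions with
#' usable, sign-consistent expression changes; (4) maximisation of
#' `Z = sum over T of log2(fold change) * v_i / vbar_i` under condition-2
#' constraints.
#'
#' @name gxfba
NULL

#' Map gene expression changes onto reactions (the T set)
#'
#' Genes with |log2 fold change| below `threshold` are ignored. Among a
#' reaction's remaining genes, the maximal-magnitude value is used when all
#' surviving values share a sign; reactions with mixed up- and down-regulation
#' are excluded, as are reactions with no surviving gene.
#'
#' @param model A `stoich_model` with GPRs.
#' @param expr Tibble/data frame with columns `gene`, `log2fc`, or a named
#'   numeric vector.
#' @param threshold Minimum |log2 fold change| (default 0.5, i.e. at least a
#'   50 percent change).
#' @return Tibble: `reaction`, `log2fc` (the signed value applied).
#' @export
build_t_set <- function(model, expr, threshold = 0.5) {
  if (is.numeric(expr) && !is.null(names(expr))) {
    expr <- tibble::tibble(gene = names(expr), log2fc = unname(expr))
  }
  expr <- tibble::as_tibble(expr)
  stopifnot(all(c("gene", "log2fc") %in% names(expr)))
  if (any(!is.finite(expr$log2fc))) stop("non-finite expression values",
                                         call. = FALSE)
  expr <- expr[abs(expr$log2fc) >= threshold, ]
  vals <- stats::setNames(expr$log2fc, expr$gene)
  rows <- purrr::map(seq_len(nrow(model$reactions)), function(i) {
    g <- gpr_genes(model$reactions$gpr[i])
    g <- intersect(g, names(vals))
    if (length(g) == 0) return(NULL)
    v <- vals[g]
    if (any(v > 0) && any(v < 0)) return(NULL)  # inconsistent -> excluded
    tibble::tibble(reaction = model$reactions$id[i],
                   log2fc = unname(v[which.max(abs(v))]))
  })
  dplyr::bind_rows(rows)
}

#' Run GX-FBA across a condition transition
#'
#' @param model A `stoich_model`.
#' @param medium1,medium2 `medium_config`s for the pre- and post-transition
#'   environments.
#' @param expr Gene expression log2 fold changes (condition 2 vs 1); see
#'   [build_t_set()].
#' @param objective1 Objective for the condition-1 reference solve (default
#'   biomass). The reference optimum is refined to its minimum-total-flux
#'   representative, a reproducible stand-in for an interior-point centred
#'   solution.
#' @param threshold Expression threshold passed to [build_t_set()].
#' @param active_tol Envelope width below which a reaction counts as inactive.
#' @return A `flux_solution` under condition-2 constraints whose
#'   `objective_value` is the achieved Z; attributes `t_set` (tibble with the
#'   per-reaction expression values and denominators) and `reference`
#'   (condition-1 solution).
#' @export
run_gxfba <- function(model, medium1, medium2, expr, objective1 = NULL,
                      threshold = 0.5, active_tol = 1e-9) {
  m1 <- apply_medium(model, medium1)
  m2 <- apply_medium(model, medium2)
  ref <- fba(m1, objective1 %||% biomass_objective(m1), refine = "parsimonious")
  if (ref$status != "optimal") stop("condition-1 reference solve failed: ",
                                    ref$status, call. = FALSE)
  env <- fva(m2, biomass_fraction = 0)
  env$mean_flux <- (env$min + env$max) / 2
  env$active <- (env$max - env$min) > active_tol
  if (!any(env$active)) stop("condition 2 admits no active reaction", call. = FALSE)
  vbar_all <- mean(abs(env$mean_flux[env$active]))

  tset <- build_t_set(model, expr, threshold)
  if (nrow(tset) == 0) stop("no usable expression: T set is empty", call. = FALSE)

  ref_v <- fluxes(ref)
  tset <- dplyr::left_join(tset, env[, c("reaction", "min", "max", "mean_flux")],
                           by = "reaction")
  denom <- purrr::map_dbl(seq_len(nrow(tset)), function(i) {
    rid <- tset$reaction[i]
    if (abs(ref_v[[rid]]) < active_tol) return(vbar_all)
    d <- tset$mean_flux[i]
    if (tset$min[i] < 0 && tset$max[i] > 0) d <- abs(d)  # envelope spans zero
    d
  })
  usable <- abs(denom) >= active_tol
  if (any(!usable)) {
    warning("excluding reaction(s) with near-zero flux denominator from Z: ",
            paste(tset$reaction[!usable], collapse = ", "))
  }
  tset <- tset[usable, ]
  denom <- denom[usable]
  if (nrow(tset) == 0) stop("no usable expression: all denominators vanish",
                            call. = FALSE)
  tset$denominator <- denom
  tset$coefficient <- tset$log2fc / denom

  obj <- stats::setNames(numeric(nrow(m2$reactions)), m2$reactions$id)
  obj[tset$reaction] <- tset$coefficient
  res <- fba_lp(m2, obj, maximize = TRUE)
  if (res$status != "optimal") {
    return(new_flux_solution(m2, NA_real_, NA_real_, res$status, "GX-FBA Z", "max"))
  }
  x <- res$x
  x2 <- parsimonious_lp(m2, obj, res$objective_value)
  if (!is.null(x2)) x <- x2
  out <- new_flux_solution(m2, x, sum(obj * x), "optimal", "GX-FBA Z", "max")
  attr(out, "t_set") <- tset
  attr(out, "reference") <- ref
  out
}
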