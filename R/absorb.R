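#' Fixed-effects specification
#'
#' Declares which group structures are absorbed ("within" transformation)
#' before a least-squares fit. The two structures used by the panel designs
#' are plot fixed effects (every plot gets its own intercept, which removes
#' all time-invariant plot and site attributes) and site-by-year fixed
#' effects (every site-year cell gets its own intercept, which removes
#' site-level shocks such as weather or herbivory in a given year).
#'
#' @param plot Logical; absorb plot intercepts.
#' @param site_year Logical; absorb site-by-year intercepts.
#' @return An object of class `fe_spec`.
#' @export
fe_spec <- function(plot = TRUE, site_year = TRUE) {
  structure(list(plot = isTRUE(plot), site_year = isTRUE(site_year)),
            class = "fe_spec")
}

fe_factors <- function(panel, spec) {
  stopifnot(inherits(spec, "fe_spec"))
  fac <- list()
  if (spec$plot) fac$plot <- interaction(panel$site_id, panel$plot_id, drop = TRUE)
  if (spec$site_year) fac$site_year <- interaction(panel$site_id, panel$year, drop = TRUE)
  fac
}

#' Absorb fixed effects by alternating within-group demeaning
#'
#' Residualizes numeric columns on the indicator space of one or more
#' grouping factors. With a single factor this is one pass of group
#' demeaning; with several factors the demeaning alternates over factors
#' until the largest absolute change in any value falls below `tol`
#' (the standard iterative algorithm for multi-way fixed effects). The
#' result is identical, up to `tol`, to the residuals from a least-squares
#' regression on explicit dummy columns for every factor level, but does
#' not require forming that (potentially huge) dummy matrix.
#'
#' @param x Numeric matrix (or data.frame of numeric columns); one column
#'   per variable to residualize.
#' @param factors List of factors (or vectors coercible to factor), all of
#'   length `nrow(x)`.
#' @param tol Convergence tolerance on the maximum absolute update.
#' @param max_iter Maximum number of full sweeps over the factor list.
#' @return List with `x` (residualized matrix), `iterations`, `converged`,
#'   and `max_change` (last sweep's largest update).
#' @export
absorb_fixed_effects <- function(x, factors, tol = 1e-10, max_iter = 1000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!length(factors)) {
    return(list(x = x, iterations = 0L, converged = TRUE, max_change = 0))
  }
  factors <- lapply(factors, function(f) {
    f <- as.factor(f)
    if (length(f) != nrow(x)) stop("factor length does not match rows of 'x'")
    f
  })
  demean <- function(v, f) v - ave(v, f)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta <- 0
    for (f in factors) {
      for (j in seq_len(ncol(x))) {
        new <- demean(x[, j], f)
        delta <- max(delta, max(abs(new - x[, j]), 0))
        x[, j] <- new
      }
    }
    if (delta < tol || length(factors) == 1L) break
    if (iter >= max_iter) {
      warning("fixed-effect absorption did not converge in ", max_iter,
              " sweeps (last change ", format(delta), ")")
      return(list(x = x, iterations = iter, converged = FALSE,
                  max_change = delta))
    }
  }
  list(x = x, iterations = iter, converged = TRUE, max_change = 0)
}

#' Degrees of freedom absorbed by a set of fixed-effect factors
#'
#' Number of linearly independent indicator columns spanned by the factors
#' (including one overall intercept). For one factor this is its number of
#' levels. For two factors it is `L1 + L2 - C`, where `C` is the number of
#' connected components of the bipartite graph linking levels of the first
#' factor to levels of the second (each component contributes one
#' redundancy, the classic two-way fixed-effects rank result).
#'
#' @param factors List of factors as passed to [absorb_fixed_effects()].
#' @return Integer count of absorbed model degrees of freedom.
#' @export
fe_degrees_of_freedom <- function(factors) {
  factors <- lapply(factors, function(f) droplevels(as.factor(f)))
  if (!length(factors)) return(0L)
  if (length(factors) == 1L) return(nlevels(factors[[1L]]))
  if (length(factors) > 2L) stop("only one- or two-factor specifications are supported")
  f1 <- factors[[1L]]; f2 <- factors[[2L]]
  n1 <- nlevels(f1); n2 <- nlevels(f2)
  # union-find over the bipartite level graph
  parent <- seq_len(n1 + n2)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- as.integer(f1); b <- as.integer(f2) + n1
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[rb] <- ra
  }
  comps <- length(unique(vapply(seq_len(n1 + n2), find, integer(1))))
  as.integer(n1 + n2 - comps)
}
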