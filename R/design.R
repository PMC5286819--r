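# Translation of a design-threshold vector x into the pair of linear flux
# regions consumed by the dual MILP: the undesired (target) region to be
# eliminated and the desired region that must survive.

#' Specify a strain-design problem
#'
#' A design names one or more yield-ratio objectives over a common
#' reference uptake.  Exactly one objective has role
#' \code{"product_min_yield"}: its threshold \code{x_1} defines the
#' undesired region (flux states with product yield strictly below
#' \code{x_1}).  Objectives with role \code{"growth_min_yield"} (or
#' \code{"custom"}) add existence rows to the desired region: a flux
#' state with that yield at or above its threshold must survive the
#' knockout.  The number of objectives is the dimension \code{j} of the
#' particle swarm's search space.
#'
#' @param objectives list of lists with elements \code{name},
#'   \code{numerator} (reaction id), optional \code{denominators}
#'   (defaults to \code{reference}) and \code{role}.
#' @param reference character vector of uptake reaction ids; their summed
#'   flux is the normalization (fixed to 1) in every region.
#' @param include_product_in_desired should the desired region also
#'   require product yield >= x_1 (default), or only the existence rows?
#' @return object of class \code{design_spec}.
#' @export
design_spec <- function(objectives, reference,
                        include_product_in_desired = TRUE) {
  stopifnot(length(objectives) >= 1, length(reference) >= 1)
  roles <- vapply(objectives, function(o) {
    match.arg(o$role, c("product_min_yield", "growth_min_yield", "custom"))
  }, "")
  if (sum(roles == "product_min_yield") != 1L)
    stop("exactly one objective must have role 'product_min_yield'")
  objectives <- lapply(seq_along(objectives), function(k) {
    o <- objectives[[k]]
    o$role <- roles[k]
    if (is.null(o$denominators)) o$denominators <- reference
    if (is.null(o$name)) o$name <- o$numerator
    o
  })
  structure(list(objectives = objectives,
                 reference = as.character(reference),
                 j = length(objectives),
                 include_product_in_desired = include_product_in_desired),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("design spec:", x$j, "objective dimension(s); reference uptake {",
      paste(x$reference, collapse = ", "), "}\n")
  for (o in x$objectives)
    cat("  ", o$name, ": ", o$numerator, " / sum(",
        paste(o$denominators, collapse = "+"), ")  [", o$role, "]\n",
        sep = "")
  invisible(x)
}

#' Build the undesired/desired regions for a threshold vector
#'
#' The target (undesired) region is: unit reference uptake and product
#' yield strictly below \code{x[1]} (the strict row is handled by the
#' dual's strictness constant, not an explicit epsilon).  The desired
#' region is: unit reference uptake, product yield >= \code{x[1]} (if
#' \code{include_product_in_desired}), and each existence objective's
#' yield >= its threshold.  Both regions carry the normalization rows so
#' that the zero flux vector lies in neither.
#'
#' @param spec a \code{\link{design_spec}}.
#' @param x numeric threshold vector of length \code{spec$j}, one entry
#'   per objective in the order they appear in \code{spec$objectives}.
#' @param net a \code{\link{metabolic_network}}.
#' @param bounds optional data.frame from \code{\link{yield_bounds}}; when
#'   supplied, \code{x} is checked against it.
#' @return object of class \code{intervention_problem} with elements
#'   \code{target}, \code{desired} (both \code{\link{linear_region}}) and
#'   \code{x}.
#' @export
build_intervention <- function(spec, x, net, bounds = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (length(x) != spec$j)
    stop("x has length ", length(x), " but the design has ", spec$j,
         " dimensions")
  ord <- order(vapply(spec$objectives, function(o)
    o$role != "product_min_yield", TRUE))
  objs <- spec$objectives[ord]   # product first
  xo <- x[ord]
  if (!is.null(bounds)) {
    tol <- 1e-7
    for (k in seq_along(objs)) {
      if (xo[k] < bounds$min[ord[k]] - tol || xo[k] > bounds$max[ord[k]] + tol)
        stop("threshold for '", objs[[k]]$name, "' (", xo[k],
             ") outside achievable yield range [", bounds$min[ord[k]], ", ",
             bounds$max[ord[k]], "]")
    }
  }
  n <- length(net$reaction_ids)
  s <- numeric(n)
  s[.rxn_index(net, spec$reference)] <- 1
  rowvec <- function(o, thr) {
    num <- numeric(n)
    num[.rxn_index(net, o$numerator)] <- 1
    den <- numeric(n)
    den[.rxn_index(net, o$denominators)] <- 1
    list(num = num, den = den, thr = thr)
  }
  prod_o <- rowvec(objs[[1]], xo[1])

  # target: s.r = 1 (two rows), product yield < x1
  Tm <- rbind(s, -s, prod_o$num - prod_o$thr * prod_o$den)
  tv <- c(1, -1, 0)
  strict <- c(FALSE, FALSE, TRUE)

  # desired: s.r = 1, yield rows >= thresholds
  Dm <- rbind(s, -s)
  dv <- c(1, -1)
  if (isTRUE(spec$include_product_in_desired)) {
    Dm <- rbind(Dm, prod_o$thr * prod_o$den - prod_o$num)
    dv <- c(dv, 0)
  }
  if (length(objs) > 1L) {
    for (k in 2:length(objs)) {
      o <- rowvec(objs[[k]], xo[k])
      Dm <- rbind(Dm, o$thr * o$den - o$num)
      dv <- c(dv, 0)
    }
  }
  rownames(Tm) <- NULL
  rownames(Dm) <- NULL
  structure(list(target = linear_region(Tm, tv, strict),
                 desired = linear_region(Dm, dv),
                 x = as.numeric(x)),
            class = "intervention_problem")
}
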