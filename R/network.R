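#' Construct a metabolic network
#'
#' The central container of the package: a stoichiometric matrix
#' \code{N} (m metabolites x n reactions) together with per-reaction
#' reversibility, flux bounds and structural annotations.  A steady-state
#' flux vector \code{r} satisfies \code{N r = 0} with \code{r_i >= 0} for
#' every irreversible reaction.
#'
#' Exchange reactions are auto-detected as columns with a single nonzero
#' stoichiometric entry.  \code{knockout_allowed} starts \code{TRUE}
#' everywhere and is narrowed by \code{\link{apply_knockout_exclusions}}.
#'
#' @param stoich numeric matrix, metabolites in rows, reactions in columns.
#' @param reaction_ids,metabolite_ids unique identifier vectors.
#' @param reversible logical per reaction.
#' @param lower_bound,upper_bound flux bounds; defaults are
#'   \code{-1000/0} and \code{1000} depending on reversibility.
#' @param is_spontaneous logical per reaction (no standard SBML flag; supply
#'   from model metadata).
#' @param knockout_allowed logical per reaction.
#' @return object of class \code{metabolic_network}.
#' @export
metabolic_network <- function(stoich, reaction_ids, metabolite_ids,
                              reversible,
                              lower_bound = NULL, upper_bound = NULL,
                              is_spontaneous = NULL,
                              knockout_allowed = NULL) {
  stoich <- as.matrix(stoich)
  m <- nrow(stoich)
  n <- ncol(stoich)
  if (length(reaction_ids) != n)
    stop("stoich has ", n, " columns but ", length(reaction_ids),
         " reaction ids")
  if (length(metabolite_ids) != m)
    stop("stoich has ", m, " rows but ", length(metabolite_ids),
         " metabolite ids")
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction ids: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "))
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  reversible <- as.logical(reversible)
  if (length(reversible) != n) stop("reversible must have length n")
  if (is.null(lower_bound)) lower_bound <- ifelse(reversible, -1000, 0)
  if (is.null(upper_bound)) upper_bound <- rep(1000, n)
  if (any(!reversible & lower_bound < 0))
    stop("irreversible reactions must have lower_bound >= 0")
  if (any(lower_bound > upper_bound)) stop("lower_bound > upper_bound")
  if (is.null(is_spontaneous)) is_spontaneous <- rep(FALSE, n)
  if (is.null(knockout_allowed)) knockout_allowed <- rep(TRUE, n)
  zero_cols <- colSums(abs(stoich) > 0) == 0L
  if (any(zero_cols))
    warning("reaction(s) with all-zero stoichiometry: ",
            paste(reaction_ids[zero_cols], collapse = ", "))
  dimnames(stoich) <- list(metabolite_ids, reaction_ids)
  structure(list(
    stoich = stoich,
    reaction_ids = as.character(reaction_ids),
    metabolite_ids = as.character(metabolite_ids),
    reversible = reversible,
    lower_bound = as.numeric(lower_bound),
    upper_bound = as.numeric(upper_bound),
    is_exchange = unname(colSums(abs(stoich) > 0) == 1L),
    is_spontaneous = as.logical(is_spontaneous),
    knockout_allowed = as.logical(knockout_allowed)
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic network:", length(x$metabolite_ids), "metabolites,",
      length(x$reaction_ids), "reactions (",
      sum(x$reversible), "reversible,", sum(x$is_exchange), "exchanges )\n")
  invisible(x)
}

#' @export
dim.metabolic_network <- function(x) dim(x$stoich)

.rxn_index <- function(net, ids) {
  i <- match(ids, net$reaction_ids)
  if (anyNA(i))
    stop("unknown reaction id(s): ", paste(ids[is.na(i)], collapse = ", "))
  i
}

#' Load a metabolic network from a file
#'
#' Two dialects are supported: \code{"tabular"}, the package's plain-text
#' fixture format (one reaction per line:
#' \code{id  rev  met:coeff met:coeff ...  [lb=x] [ub=y]}, \code{#}
#' comments), and \code{"sbml"} for SBML Level 3 with the FBC extension
#' (species flagged \code{boundaryCondition="true"} are dropped, which
#' leaves exchange reactions with single-entry columns).
#'
#' @param source path to the model file.
#' @param dialect \code{"tabular"} or \code{"sbml"}.
#' @param spontaneous character vector of reaction ids to flag spontaneous.
#' @return a \code{\link{metabolic_network}}.
#' @export
load_network <- function(source, dialect = c("tabular", "sbml"),
                         spontaneous = character()) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("model file not found: ", source)
  net <- switch(dialect,
    tabular = .read_tabular(source),
    sbml = .read_sbml(source))
  if (length(spontaneous)) {
    net$is_spontaneous[.rxn_index(net, spontaneous)] <- TRUE
  }
  net
}

.read_tabular <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty tabular model: ", path)
  ids <- character()
  rev <- logical()
  lbs <- numeric()
  ubs <- numeric()
  entries <- list()  # per reaction: named numeric of met coefficients
  for (ln in lines) {
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (length(tok) < 2L) stop("malformed tabular line: ", ln)
    id <- tok[1]
    r <- tok[2] %in% c("1", "R", "rev", "TRUE", "true")
    lb <- NA_real_
    ub <- NA_real_
    co <- numeric()
    for (t in tok[-(1:2)]) {
      if (grepl("^lb=", t)) {
        lb <- as.numeric(sub("^lb=", "", t))
      } else if (grepl("^ub=", t)) {
        ub <- as.numeric(sub("^ub=", "", t))
      } else {
        kv <- strsplit(t, ":", fixed = TRUE)[[1]]
        if (length(kv) != 2L) stop("malformed met:coeff token '", t,
                                   "' in line: ", ln)
        v <- as.numeric(kv[2])
        if (is.na(v)) stop("non-numeric coefficient in token '", t, "'")
        co[kv[1]] <- if (kv[1] %in% names(co)) co[[kv[1]]] + v else v
      }
    }
    ids <- c(ids, id)
    rev <- c(rev, r)
    lbs <- c(lbs, lb)
    ubs <- c(ubs, ub)
    entries[[length(entries) + 1L]] <- co
  }
  if (anyDuplicated(ids))
    stop("duplicate reaction ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mets <- unique(unlist(lapply(entries, names)))
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  for (j in seq_along(entries)) {
    S[names(entries[[j]]), j] <- entries[[j]]
  }
  lbs[is.na(lbs)] <- ifelse(rev[is.na(lbs)], -1000, 0)
  ubs[is.na(ubs)] <- 1000
  metabolic_network(S, ids, mets, rev, lbs, ubs)
}

# Compact reader for the SBML Level 3 (v1/v2) core + FBC subset used by
# constraint-based models: species (boundaryCondition), reactions with
# speciesReference stoichiometries, flux bounds via fbc bound parameters.
.read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  att <- function(nodes, a) xml2::xml_attr(nodes, a)

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- att(sp_nodes, "id")
  sp_boundary <- tolower(ifelse(is.na(att(sp_nodes, "boundaryCondition")),
                                "false", att(sp_nodes, "boundaryCondition")))
  mets <- sp_id[sp_boundary != "true"]

  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- as.numeric(att(par_nodes, "value"))
  names(par_val) <- att(par_nodes, "id")

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx_nodes)) stop("no reactions found in SBML file ", path)
  ids <- att(rx_nodes, "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rev <- tolower(ifelse(is.na(att(rx_nodes, "reversible")), "true",
                        att(rx_nodes, "reversible"))) == "true"
  n <- length(ids)
  S <- matrix(0, length(mets), n, dimnames = list(mets, ids))
  lbs <- ifelse(rev, -1000, 0)
  ubs <- rep(1000, n)
  bound_attr <- function(node, which) {
    v <- xml2::xml_attr(node, which)  # e.g. fbc:lowerFluxBound
    if (!is.na(v) && v %in% names(par_val)) par_val[[v]] else NA_real_
  }
  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node,
        paste0("./s:", side, "/s:speciesReference"), ns)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        stoi <- xml2::xml_attr(ref, "stoichiometry")
        stoi <- if (is.na(stoi)) 1 else as.numeric(stoi)
        if (sp %in% mets) S[sp, j] <- S[sp, j] + sgn * stoi
      }
    }
    lbv <- bound_attr(node, "lowerFluxBound")
    ubv <- bound_attr(node, "upperFluxBound")
    if (!is.na(lbv)) lbs[j] <- lbv
    if (!is.na(ubv)) ubs[j] <- ubv
    rev[j] <- lbs[j] < 0
  }
  metabolic_network(S, ids, mets, rev, lbs, ubs)
}

#' Write a network in the tabular fixture dialect
#'
#' @param net a \code{\link{metabolic_network}}.
#' @param path output file.
#' @export
write_network_tabular <- function(net, path) {
  n <- length(net$reaction_ids)
  lines <- character(n)
  for (j in seq_len(n)) {
    nz <- which(net$stoich[, j] != 0)
    toks <- paste0(net$metabolite_ids[nz], ":",
                   format(net$stoich[nz, j], trim = TRUE, scientific = FALSE))
    lines[j] <- paste(net$reaction_ids[j],
                      as.integer(net$reversible[j]),
                      paste(toks, collapse = " "),
                      paste0("lb=", net$lower_bound[j]),
                      paste0("ub=", net$upper_bound[j]))
  }
  writeLines(lines, path)
  invisible(path)
}

# restrict a network to a subset of reactions (and drop orphan metabolites)
.subset_network <- function(net, keep_rxn) {
  S <- net$stoich[, keep_rxn, drop = FALSE]
  keep_met <- rowSums(abs(S) > 0) > 0L
  metabolic_network(S[keep_met, , drop = FALSE],
                    net$reaction_ids[keep_rxn],
                    net$metabolite_ids[keep_met],
                    net$reversible[keep_rxn],
                    net$lower_bound[keep_rxn],
                    net$upper_bound[keep_rxn],
                    net$is_spontaneous[keep_rxn],
                    net$knockout_allowed[keep_rxn])
}
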