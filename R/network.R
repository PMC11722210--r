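# Mass-action reaction networks and the nested candidate models.
#
# A network couples a species list to a set of reactions whose rate
# constants are either fixed numbers or references to one of the freely
# varying parameters theta_1..theta_3. Conserved moieties (weighted sums
# of species left invariant by every reaction) are derived at
# construction and used downstream as integration sanity checks.

#' Construct a mass-action reaction network
#'
#' @param species character vector of unique species names; the order
#'   defines the column order of every state matrix in the package.
#' @param reactions list of reactions, each created by [reaction()] or
#'   parsed from a string by [parse_reaction()].
#' @return an object of class `reaction_network` with elements `species`,
#'   `reactions`, the reactant and net stoichiometry matrices
#'   (reactions x species), and `conserved_moieties`, a matrix whose
#'   columns span the left-invariant space (net %*% v = 0).
#' @export
reaction_network <- function(species, reactions) {
  if (anyDuplicated(species)) {
    stop_config("species names must be unique")
  }
  if (length(reactions) == 0) stop_config("a network needs at least one reaction")
  ns <- length(species)
  nr <- length(reactions)
  reac <- matrix(0, nr, ns, dimnames = list(NULL, species))
  prod <- matrix(0, nr, ns, dimnames = list(NULL, species))
  for (j in seq_len(nr)) {
    r <- reactions[[j]]
    if (length(r$reactants) + length(r$products) == 0) {
      stop_config("reaction ", j, " has neither reactants nor products")
    }
    for (side in c("reactants", "products")) {
      st <- r[[side]]
      if (length(st) == 0) next
      if (any(st < 1)) stop_config("stoichiometric coefficients must be >= 1")
      unknown <- setdiff(names(st), species)
      if (length(unknown)) {
        stop_config("reaction ", j, " references unknown species: ",
                    paste(unknown, collapse = ", "))
      }
      m <- if (side == "reactants") reac else prod
      m[j, names(st)] <- st
      if (side == "reactants") reac <- m else prod <- m
    }
    rt <- r$rate
    if (identical(rt$type, "fixed")) {
      if (!is.numeric(rt$value) || rt$value < 0) {
        stop_config("fixed rate constants must be >= 0 (reaction ", j, ")")
      }
    } else if (identical(rt$type, "free")) {
      if (!rt$index %in% 1:3) {
        stop_config("free rate references must use parameter index 1..3")
      }
    } else {
      stop_config("reaction ", j, ": rate must be fixed:VALUE or free:K")
    }
  }
  net <- prod - reac
  structure(
    list(species = species, reactions = reactions,
         reactant_stoich = reac, product_stoich = prod, net_stoich = net,
         conserved_moieties = .nullspace(net)),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions) cat("  ", format_reaction(r), "\n", sep = "")
  cat("Conserved moieties:", ncol(x$conserved_moieties), "\n")
  invisible(x)
}

#' Define a single mass-action reaction
#'
#' @param reactants,products named integer vectors of stoichiometric
#'   coefficients (may be empty for pure production/degradation).
#' @param rate either `list(type = "fixed", value = k)` with `k >= 0`
#'   (units 1/s for unimolecular, 1/(abundance s) for bimolecular steps)
#'   or `list(type = "free", index = k)` referencing theta_k.
#' @return a list of class `reaction`.
#' @export
reaction <- function(reactants, products, rate) {
  structure(list(reactants = reactants, products = products, rate = rate),
            class = "reaction")
}

format_reaction <- function(r) {
  side <- function(st) {
    if (length(st) == 0) return("0")
    paste(ifelse(st > 1, paste0(st, " "), ""), names(st),
          sep = "", collapse = " + ")
  }
  tag <- if (r$rate$type == "fixed") paste0("fixed:", r$rate$value)
         else paste0("free:", r$rate$index)
  paste0(side(r$reactants), " -> ", side(r$products), " @ ", tag)
}

#' Parse a reaction from its text form
#'
#' The text form used in network config files is
#' `"A + 2 B -> C @ fixed:0.12"` or `"A -> B @ free:2"`.
#'
#' @param text a single reaction string.
#' @return a [reaction()] object.
#' @export
parse_reaction <- function(text) {
  parts <- strsplit(text, "@", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop_config("reaction '", text, "' lacks an '@ rate' part")
  arrow <- strsplit(parts[[1]], "->", fixed = TRUE)[[1]]
  if (length(arrow) != 2) stop_config("reaction '", text, "' lacks '->'")
  parse_side <- function(s) {
    s <- trimws(s)
    if (s == "" || s == "0") return(integer(0))
    out <- integer(0)
    for (term in strsplit(s, "+", fixed = TRUE)[[1]]) {
      term <- trimws(term)
      m <- regmatches(term, regexec("^([0-9]+)?\\s*([A-Za-z][A-Za-z0-9_.-]*)$", term))[[1]]
      if (length(m) == 0) stop_config("cannot parse species term '", term, "'")
      k <- if (m[2] == "") 1L else as.integer(m[2])
      out[m[3]] <- (if (m[3] %in% names(out)) out[[m[3]]] else 0L) + k
    }
    out
  }
  rt <- trimws(parts[[2]])
  if (grepl("^fixed:", rt)) {
    rate <- list(type = "fixed", value = as.numeric(sub("^fixed:", "", rt)))
  } else if (grepl("^free:", rt)) {
    rate <- list(type = "free", index = as.integer(sub("^free:", "", rt)))
  } else {
    stop_config("rate spec '", rt, "' must be fixed:VALUE or free:K")
  }
  reaction(parse_side(arrow[[1]]), parse_side(arrow[[2]]), rate)
}

# Basis of {v : M v = 0} via SVD; columns are orthonormal vectors.
.nullspace <- function(M, tol = 1e-10) {
  s <- svd(M, nu = 0, nv = ncol(M))
  null_cols <- c(which(s$d <= tol * max(s$d, 1)),
                 setdiff(seq_len(ncol(M)), seq_along(s$d)))
  v <- s$v[, null_cols, drop = FALSE]
  rownames(v) <- colnames(M)
  v
}

#' Build the default minimal NK-cell signaling network
#'
#' Six species (Syk, Vav1, the Syk-Vav1 complex, phosphorylated Vav1,
#' SHP1, and the SHP1-pVav1 complex) connected by six reactions:
#' Syk/Vav1 association (theta_1), dissociation (fixed 0.12),
#' phosphorylation-release producing pVav1 (theta_2), SHP1/pVav1
#' association (theta_3), dissociation (fixed 0.14), and
#' dephosphorylation-release returning Vav1 (fixed 0.05). The exact
#' arrow layout and the placement of the three fixed rates are package
#' defaults; pass a network config file to change either without
#' touching code.
#'
#' @param config optional path to a YAML network config
#'   (see [read_network_config()]); when given it replaces the default.
#' @return a [reaction_network()].
#' @export
build_minimal_nk_network <- function(config = NULL) {
  if (!is.null(config)) return(read_network_config(config))
  species <- c("Syk", "Vav1", "SykVav1", "pVav1", "SHP1", "SHP1pVav1")
  rx <- c(
    "Syk + Vav1 -> SykVav1 @ free:1",
    "SykVav1 -> Syk + Vav1 @ fixed:0.12",
    "SykVav1 -> Syk + pVav1 @ free:2",
    "SHP1 + pVav1 -> SHP1pVav1 @ free:3",
    "SHP1pVav1 -> SHP1 + pVav1 @ fixed:0.14",
    "SHP1pVav1 -> SHP1 + Vav1 @ fixed:0.05"
  )
  reaction_network(species, lapply(rx, parse_reaction))
}

#' Read a reaction network from a YAML config file
#'
#' The schema has two keys: `species`, a list of names in column order,
#' and `reactions`, a list of strings in the form
#' `"reactants -> products @ fixed:VALUE"` or `"... @ free:K"` with
#' `K` in 1..3. Conserved moieties are recomputed and validated on load.
#'
#' @param path file path.
#' @return a [reaction_network()].
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) stop_config("network config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species) || is.null(cfg$reactions)) {
    stop_config("network config needs 'species' and 'reactions' keys")
  }
  net <- reaction_network(unlist(cfg$species),
                          lapply(unlist(cfg$reactions), parse_reaction))
  chk <- max(abs(net$net_stoich %*% net$conserved_moieties))
  if (chk > 1e-8) stop_config("conserved-moiety check failed on load")
  net
}

# Substitute free parameters into the per-reaction rate constants.
resolved_rate_constants <- function(network, theta) {
  vapply(network$reactions, function(r) {
    if (r$rate$type == "fixed") r$rate$value else theta[[r$rate$index]]
  }, numeric(1))
}

#' Mass-action time derivative of one cell state
#'
#' @param network a [reaction_network()].
#' @param rates full rate vector `(theta_1, theta_2, theta_3)` for the
#'   free slots; fixed rates are taken from the network.
#' @param state nonnegative abundance vector, one entry per species.
#' @return the derivative vector (abundance/s). Every conserved moiety
#'   `v` satisfies `sum(v * result) == 0` exactly up to rounding.
#' @export
mass_action_rhs <- function(network, rates, state) {
  if (length(state) != length(network$species)) {
    stop_data("state length ", length(state), " != number of species ",
              length(network$species))
  }
  if (any(state < 0)) stop_data("negative abundances are not allowed")
  k <- resolved_rate_constants(network, rates)
  flux <- k * apply(network$reactant_stoich, 1, function(s) {
    prod(state[s > 0]^s[s > 0])
  })
  drop(t(network$net_stoich) %*% flux)
}

#' The three nested candidate models
#'
#' Candidate 1 varies only theta_1 with `theta_2 = 9 theta_1` and
#' `theta_3 = 2 theta_1`; candidate 2 keeps `theta_2 = 9 theta_1` and
#' frees theta_3; candidate 3 frees all three rates. Every rate vector
#' reachable by candidate 1 is reachable by candidate 2 and 3 (nesting).
#'
#' @param network the shared [reaction_network()]; defaults to
#'   [build_minimal_nk_network()].
#' @return a list of three `candidate_model` objects.
#' @export
nk_candidate_models <- function(network = build_minimal_nk_network()) {
  list(
    candidate_model(1L, network, 1L,
                    function(p) c(p[1], 9 * p[1], 2 * p[1]),
                    "theta2 = 9*theta1, theta3 = 2*theta1"),
    candidate_model(2L, network, 2L,
                    function(p) c(p[1], 9 * p[1], p[2]),
                    "theta2 = 9*theta1"),
    candidate_model(3L, network, 3L,
                    function(p) c(p[1], p[2], p[3]),
                    "none")
  )
}

#' Construct a candidate model
#'
#' @param id integer identifier.
#' @param network the [reaction_network()] shared by all candidates.
#' @param n_free number of freely varying parameters.
#' @param constraint_map function mapping the free parameters to the
#'   full rate vector `(theta_1, theta_2, theta_3)`.
#' @param constraints human-readable description of the constraints.
#' @return an object of class `candidate_model`.
#' @export
candidate_model <- function(id, network, n_free, constraint_map,
                            constraints = "") {
  stopifnot(n_free >= 1)
  structure(list(id = as.integer(id), network = network,
                 n_free = as.integer(n_free),
                 constraint_map = constraint_map,
                 constraints = constraints),
            class = "candidate_model")
}

#' @export
print.candidate_model <- function(x, ...) {
  cat("Candidate model", x$id, "-", x$n_free, "free parameter(s);",
      "constraints:", if (nzchar(x$constraints)) x$constraints else "none", "\n")
  invisible(x)
}

#' Resolve a candidate's free parameters to the full rate vector
#'
#' @param model a [candidate_model()].
#' @param free_params strictly positive numeric vector of length
#'   `model$n_free`.
#' @return the full rate vector `(theta_1, theta_2, theta_3)`.
#' @export
resolve_rates <- function(model, free_params) {
  if (length(free_params) != model$n_free) {
    stop_data("expected ", model$n_free, " free parameter(s), got ",
              length(free_params))
  }
  if (any(!is.finite(free_params)) || any(free_params <= 0)) {
    stop_data("free parameters must be strictly positive")
  }
  theta <- model$constraint_map(as.numeric(free_params))
  names(theta) <- paste0("theta", seq_along(theta))
  theta
}
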