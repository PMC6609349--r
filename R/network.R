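# The metabolic network container: metabolite and reaction tables plus a
# sparse stoichiometric matrix S (metabolites x reactions).

new_metnet <- function(metabolites, reactions, S, genes = list(), id = "network") {
  structure(
    list(metabolites = metabolites, reactions = reactions, S = S,
         genes = genes, id = id),
    class = "metnet"
  )
}

#' Construct a metabolic network
#'
#' Builds a validated stoichiometric network from a metabolite table and a
#' reaction table.  The network is stored as two tibbles plus a sparse
#' stoichiometric matrix `S` (metabolites as rows, reactions as columns);
#' negative coefficients are substrates, positive coefficients products.
#'
#' @param metabolites data frame with columns `id` and optionally `name` and
#'   `compartment` (a compartment tag such as `"c"`, `"e"`, `"c0"`).
#' @param reactions data frame with columns `id`, a list-column `stoich` of
#'   named numeric vectors (names are metabolite ids), and optionally `name`,
#'   `lb`, `ub`.  Missing bounds default to `[-1000, 1000]` (treating the
#'   reaction as reversible); set `lb = 0` for irreversible reactions.
#' @param genes named list mapping gene ids to character vectors of reaction
#'   ids (may be empty).
#' @param id a label for the network (used as the organism id downstream).
#' @return an object of class `metnet`.
#' @examples
#' net <- metabolic_network(
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = tibble::tibble(id = "R1", stoich = list(c(A = -1, B = 1)), lb = 0, ub = 1000)
#' )
#' net
#' @export
metabolic_network <- function(metabolites, reactions, genes = list(), id = "network") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- ""
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"lb" %in% names(reactions)) reactions$lb <- -1000
  if (!"ub" %in% names(reactions)) reactions$ub <- 1000
  metabolites <- metabolites[, c("id", "name", "compartment")]
  stoich <- reactions$stoich
  reactions <- reactions[, c("id", "name", "lb", "ub")]

  m <- nrow(metabolites)
  n <- nrow(reactions)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- stats::setNames(seq_len(m), metabolites$id)
  for (j in seq_len(n)) {
    sj <- stoich[[j]]
    if (is.null(sj) || length(sj) == 0) {
      stop("reaction '", reactions$id[j], "' has an empty stoichiometry")
    }
    idx <- met_index[names(sj)]
    if (anyNA(idx)) {
      stop("reaction '", reactions$id[j], "' refers to undeclared metabolite(s): ",
           paste(names(sj)[is.na(idx)], collapse = ", "))
    }
    ii <- c(ii, unname(idx)); jj <- c(jj, rep(j, length(sj))); xx <- c(xx, unname(sj))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n),
                            dimnames = list(metabolites$id, reactions$id))
  net <- new_metnet(metabolites, reactions, S, genes, id)
  validate_metnet(net)
}

#' @export
print.metnet <- function(x, ...) {
  cat("<metnet> ", x$id, ": ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions", sep = "")
  if (length(x$genes)) cat(", ", length(x$genes), " genes", sep = "")
  cat("\n")
  invisible(x)
}

validate_metnet <- function(net) {
  stopifnot(inherits(net, "metnet"))
  if (anyDuplicated(net$metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(net$metabolites$id[duplicated(net$metabolites$id)]), collapse = ", "))
  }
  if (anyDuplicated(net$reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(net$reactions$id[duplicated(net$reactions$id)]), collapse = ", "))
  }
  if (any(net$reactions$lb > net$reactions$ub)) {
    bad <- net$reactions$id[net$reactions$lb > net$reactions$ub]
    stop("lb > ub for reaction(s): ", paste(bad, collapse = ", "))
  }
  if (any(Matrix::colSums(net$S != 0) == 0)) {
    bad <- net$reactions$id[Matrix::colSums(net$S != 0) == 0]
    stop("empty stoichiometry for reaction(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(identical(rownames(net$S), net$metabolites$id),
            identical(colnames(net$S), net$reactions$id))
  if (length(net$genes)) {
    unknown <- setdiff(unique(unlist(net$genes)), net$reactions$id)
    if (length(unknown)) {
      stop("gene associations refer to unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  net
}

#' Stoichiometry of one reaction as a named vector
#' @param net a `metnet`.
#' @param reaction a reaction id.
#' @return named numeric vector of nonzero coefficients.
#' @export
reaction_stoich <- function(net, reaction) {
  j <- match(reaction, net$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", reaction)
  col <- net$S[, j]
  col[col != 0]
}
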