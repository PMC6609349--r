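# Inter-organism metabolic metrics: PM-based distances/complementarity,
# NetSeed-style seed sets, reaction-content distances, genus collapsing.

#' L1 distance between two PM vectors
#'
#' `sum_i |PM_i^A - PM_i^B|` over metabolites with values in both vectors
#' (missing entries are dropped pairwise).
#'
#' @param a,b aligned numeric PM vectors.
#' @export
pm_distance <- function(a, b) {
  if (length(a) != length(b)) stop("PM vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  sum(abs(a[ok] - b[ok]))
}

#' Directional PM complementarity (A supplementing B)
#'
#' `sum_i (max(PM_i^A, PM_i^B) - PM_i^B) / sum_i PM_i^A`: the fraction of
#' A's producibility that would raise B's.  0 when B already matches or
#' exceeds A everywhere; 1 when B produces nothing that A can.
#'
#' @param a,b aligned numeric PM vectors (`a` is the supplementing organism).
#' @return value in `[0, 1]`, or `NA` when `sum(a)` is 0.
#' @export
pm_complementarity <- function(a, b) {
  if (length(a) != length(b)) stop("PM vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (sum(a) <= 0) return(NA_real_)
  sum(pmax(a, b) - b) / sum(a)
}

#' All pairwise PM metrics over a PM matrix
#'
#' @param m a [pm_matrix()] (organisms x metabolites).
#' @param metric `"distance"` (symmetric) or `"complementarity"`
#'   (directional; entry `[A, B]` is A supplementing B).
#' @return square organisms x organisms matrix.
#' @export
pm_pairwise <- function(m, metric = c("distance", "complementarity")) {
  metric <- match.arg(metric)
  f <- if (metric == "distance") pm_distance else pm_complementarity
  orgs <- rownames(m)
  out <- matrix(NA_real_, length(orgs), length(orgs), dimnames = list(orgs, orgs))
  for (i in seq_along(orgs)) {
    for (j in seq_along(orgs)) {
      out[i, j] <- if (i == j && metric == "distance") 0 else f(m[i, ], m[j, ])
    }
  }
  out
}

#' Seed set of a network (NetSeed-style)
#'
#' Builds the directed metabolite graph (an edge from every reactant to
#' every product of each reaction; both directions when the reaction is
#' reversible, i.e. `lb < 0`), condenses it into strongly connected
#' components, and declares the members of source components (no incoming
#' edges from outside) to be seed metabolites -- compounds the organism must
#' acquire exogenously.  Each seed scores `1 / |component|`; no minimum
#' component size is imposed and isolated metabolites count as their own
#' source component.
#'
#' @param net a [metabolic_network()].
#' @return object of class `seed_set`: `organism`, `seed_score` (named
#'   vector, seeds only), `network_metabolites`.
#' @export
seed_set <- function(net) {
  net <- validate_metnet(net)
  mets <- net$metabolites$id
  from <- character(0); to <- character(0)
  for (j in seq_len(nrow(net$reactions))) {
    st <- reaction_stoich(net, net$reactions$id[j])
    subs <- names(st)[st < 0]
    prods <- names(st)[st > 0]
    if (!length(subs) || !length(prods)) next
    e <- expand.grid(subs, prods, stringsAsFactors = FALSE)
    from <- c(from, e[[1]]); to <- c(to, e[[2]])
    if (net$reactions$lb[j] < 0) { from <- c(from, e[[2]]); to <- c(to, e[[1]]) }
  }
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = TRUE,
                                     vertices = data.frame(name = mets))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  el <- igraph::as_edgelist(g, names = TRUE)
  has_incoming <- rep(FALSE, comp$no)
  if (nrow(el)) {
    cross <- memb[el[, 1]] != memb[el[, 2]]
    has_incoming[unique(memb[el[cross, 2]])] <- TRUE
  }
  is_seed <- !has_incoming[memb]
  score <- 1 / comp$csize[memb]
  structure(
    list(organism = net$id,
         seed_score = stats::setNames(score[is_seed], names(memb)[is_seed]),
         network_metabolites = mets),
    class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", x$organism, ": ", length(x$seed_score), " seeds of ",
      length(x$network_metabolites), " metabolites\n", sep = "")
  invisible(x)
}

#' L1 distance between two seed-score vectors
#'
#' Scores are aligned on a common metabolite universe (0 where a metabolite
#' is not a seed or absent from the network).
#'
#' @param a,b [seed_set()] objects.
#' @param universe metabolite ids to align on; defaults to the union of both
#'   networks' metabolites.
#' @export
seed_distance <- function(a, b, universe = NULL) {
  if (is.null(universe)) universe <- union(a$network_metabolites, b$network_metabolites)
  va <- ifelse(universe %in% names(a$seed_score), a$seed_score[universe], 0)
  vb <- ifelse(universe %in% names(b$seed_score), b$seed_score[universe], 0)
  sum(abs(va - vb))
}

#' Seed competition (A against B)
#'
#' Fraction of A's seeds that are also seeds of B.
#'
#' @param a,b [seed_set()] objects.
#' @export
seed_competition <- function(a, b) {
  sa <- names(a$seed_score)
  if (!length(sa)) return(NA_real_)
  length(intersect(sa, names(b$seed_score))) / length(sa)
}

#' Seed complementarity (B supplying A)
#'
#' Fraction of A's seeds that occur in B's network without being seeds of B
#' -- compounds A needs that B can make.
#'
#' @param a,b [seed_set()] objects.
#' @export
seed_complementarity <- function(a, b) {
  sa <- names(a$seed_score)
  if (!length(sa)) return(NA_real_)
  sum(sa %in% b$network_metabolites & !(sa %in% names(b$seed_score))) / length(sa)
}

#' Reaction-content distances
#'
#' `reaction_distance` is the L1 norm between two 0/1 reaction presence
#' vectors aligned on a common reaction universe; `reaction_jaccard` is
#' `1 - |intersection| / |union|`.
#'
#' @param a,b character vectors of reaction ids, or logical/0-1 vectors on a
#'   shared universe.
#' @export
reaction_distance <- function(a, b) {
  v <- reaction_presence(a, b)
  sum(abs(v$a - v$b))
}

#' @rdname reaction_distance
#' @export
reaction_jaccard <- function(a, b) {
  v <- reaction_presence(a, b)
  uni <- sum(v$a | v$b)
  if (uni == 0) return(NA_real_)
  1 - sum(v$a & v$b) / uni
}

reaction_presence <- function(a, b) {
  if (is.character(a) || is.character(b)) {
    universe <- union(a, b)
    list(a = universe %in% a, b = universe %in% b)
  } else {
    if (length(a) != length(b)) stop("presence vectors differ in length")
    list(a = as.logical(a), b = as.logical(b))
  }
}

#' Collapse a pairwise organism matrix to genus level
#'
#' Entry `(G1, G2)` is the mean of the metric over all ordered organism
#' pairs `(i in G1, j in G2)`, excluding self-pairs `i == j` (so a
#' within-genus entry averages the distinct-organism values, and a genus
#' with a single member gets `NA` on the diagonal).
#'
#' @param m square organism x organism matrix with dimnames.
#' @param genus_of named character vector mapping organism id to genus.
#' @return square genus x genus matrix.
#' @export
collapse_to_genus <- function(m, genus_of) {
  orgs <- rownames(m)
  if (is.null(orgs) || !identical(orgs, colnames(m))) {
    stop("m must be a square matrix with matching dimnames")
  }
  missing <- setdiff(orgs, names(genus_of))
  if (length(missing)) stop("no genus label for: ", paste(missing, collapse = ", "))
  gen <- genus_of[orgs]
  genera <- sort(unique(unname(gen)))
  out <- matrix(NA_real_, length(genera), length(genera),
                dimnames = list(genera, genera))
  for (g1 in genera) {
    for (g2 in genera) {
      i <- which(gen == g1); j <- which(gen == g2)
      pairs <- expand.grid(i = i, j = j)
      pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
      if (nrow(pairs)) out[g1, g2] <- mean(m[cbind(pairs$i, pairs$j)], na.rm = TRUE)
    }
  }
  out
}
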