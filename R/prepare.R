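# Standardisation of a network for producibility analysis: native boundary
# and maintenance reactions are silenced, and every metabolite gets a pair of
# fresh exchange handles (one importing, one exporting) through which the
# sampled environment and the inequality mass-balance relaxation are applied.

#' Partition metabolites into intracellular and extracellular sets
#'
#' Metabolites whose compartment tag (or, failing that, id suffix) matches an
#' extracellular naming convention -- `e`, `e0`, a compartment named
#' "extracellular", or an id ending in `_e`, `_e0`, `[e]` -- are classified as
#' extracellular; everything else, including metabolites with unrecognised
#' tags, is intracellular (the conservative default, since the candidate
#' input pool is drawn from the intracellular side).
#'
#' @param net a [metabolic_network()].
#' @return list with character vectors `intracellular` and `extracellular`.
#' @export
classify_compartments <- function(net) {
  comp <- tolower(net$metabolites$compartment)
  id <- net$metabolites$id
  is_extra <- grepl("^e[0-9]*$", comp) | grepl("extracellular", comp)
  no_tag <- is.na(comp) | comp == ""
  is_extra[no_tag] <- grepl("(_e[0-9]*$)|(\\[e[0-9]*\\]$)", id[no_tag])
  list(intracellular = id[!is_extra], extracellular = id[is_extra])
}

#' Prepare a network for producibility analysis
#'
#' Silences all native boundary reactions (reactions touching a single
#' metabolite, or with an `EX_`/`DM_`/`SK_` id prefix) and maintenance
#' reactions (id `ATPM`, or a name containing "maintenance"), then appends an
#' importing exchange (`0 -> met`) and an exporting exchange (`met -> 0`) for
#' every metabolite, both initially closed.  Feasibility queries open the
#' import handles of the sampled input metabolites and use the export handles
#' to implement inequality mass balance and the production objective.
#'
#' @param net a [metabolic_network()].
#' @return an object of class `prepared_metnet`: the augmented network plus
#'   the import/export reaction maps, the intracellular/extracellular
#'   partition, and the ids of the silenced native reactions.
#' @export
prepare_model <- function(net) {
  net <- validate_metnet(net)
  m <- nrow(net$metabolites)
  n <- nrow(net$reactions)

  single_met <- Matrix::colSums(net$S != 0) == 1
  prefixed <- grepl("^(EX_|DM_|SK_)", net$reactions$id)
  maintenance <- toupper(net$reactions$id) == "ATPM" |
    grepl("maintenance", net$reactions$name, ignore.case = TRUE)
  disabled <- single_met | prefixed | maintenance

  lb <- net$reactions$lb
  ub <- net$reactions$ub
  lb[disabled] <- 0
  ub[disabled] <- 0

  imp_ids <- paste0("IMP__", net$metabolites$id)
  exp_ids <- paste0("EXP__", net$metabolites$id)
  eye <- Matrix::sparseMatrix(i = seq_len(m), j = seq_len(m), x = 1, dims = c(m, m))
  S_aug <- cbind(net$S, eye, -eye)
  colnames(S_aug) <- c(net$reactions$id, imp_ids, exp_ids)

  reactions <- tibble::tibble(
    id = colnames(S_aug),
    name = c(net$reactions$name, imp_ids, exp_ids),
    lb = c(lb, rep(0, 2 * m)),
    ub = c(ub, rep(0, 2 * m))
  )
  aug <- new_metnet(net$metabolites, reactions, S_aug, net$genes, net$id)

  comp <- classify_compartments(net)
  structure(
    list(
      net = aug,
      n_base = n,
      import = stats::setNames(imp_ids, net$metabolites$id),
      export = stats::setNames(exp_ids, net$metabolites$id),
      import_idx = stats::setNames(n + seq_len(m), net$metabolites$id),
      export_idx = stats::setNames(n + m + seq_len(m), net$metabolites$id),
      intracellular = comp$intracellular,
      extracellular = comp$extracellular,
      disabled_native = net$reactions$id[disabled]
    ),
    class = "prepared_metnet"
  )
}

#' @export
print.prepared_metnet <- function(x, ...) {
  cat("<prepared_metnet> ", x$net$id, ": ", nrow(x$net$metabolites),
      " metabolites, ", x$n_base, " base reactions (",
      length(x$disabled_native), " native boundary/maintenance silenced), ",
      "2x", nrow(x$net$metabolites), " exchange handles\n", sep = "")
  invisible(x)
}
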