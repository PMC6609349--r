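# Structured in-silico experiments: random reaction removal with PM-vs-FBA
# accuracy tracking, and gene knockouts.

#' Remove n random reactions from a network
#'
#' Sampled uniformly without replacement from the non-protected reactions;
#' removed reactions are deleted outright (metabolites are kept, possibly
#' orphaned).
#'
#' @param net a [metabolic_network()].
#' @param n number of reactions to remove.
#' @param protected reaction ids never removed (e.g. biomass, maintenance).
#' @return the reduced network.
#' @export
remove_random_reactions <- function(net, n, protected = character()) {
  net <- validate_metnet(net)
  removable <- setdiff(net$reactions$id, protected)
  if (n > length(removable)) {
    stop("cannot remove ", n, " reactions; only ", length(removable), " are removable")
  }
  if (n == 0) return(net)
  drop <- sample(removable, n)
  keep <- !(net$reactions$id %in% drop)
  genes <- lapply(net$genes, function(rr) setdiff(rr, drop))
  genes <- genes[lengths(genes) > 0]
  out <- new_metnet(net$metabolites,
                    net$reactions[keep, , drop = FALSE],
                    net$S[, keep, drop = FALSE],
                    genes, net$id)
  # carry over experiment annotations if present
  for (f in c("nutrients", "biomass_components", "objective_reaction")) {
    if (!is.null(net[[f]])) out[[f]] <- net[[f]]
  }
  out
}

#' Knock out genes
#'
#' Every reaction associated with any of the given genes -- including
#' reactions shared with isoenzymes -- has both flux bounds set to zero.
#' Stoichiometry and reaction count are unchanged.
#'
#' @param net a [metabolic_network()] with gene associations.
#' @param genes character vector of gene ids (unknown ids are an error).
#' @return the constrained network.
#' @export
knockout_genes <- function(net, genes) {
  net <- validate_metnet(net)
  unknown <- setdiff(genes, names(net$genes))
  if (length(unknown)) stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  rxns <- unique(unlist(net$genes[genes]))
  j <- match(rxns, net$reactions$id)
  net$reactions$lb[j] <- 0
  net$reactions$ub[j] <- 0
  net
}

#' Random reaction-removal robustness experiment (PM versus FBA)
#'
#' At each removal level, `reps` perturbed networks are generated by
#' deleting that many random reactions (biomass and maintenance reactions
#' are protected).  For each perturbed network the experiment records
#' quantitative accuracies against the unperturbed network --
#' `1 - |flux - flux_orig| / flux_orig` for FBA (minimal and complete
#' medium) and `1 - sum_i |PM_i - PM_i_orig| / sum_i PM_i_orig` for the PM
#' over the biomass components, both floored at 0 -- plus qualitative
#' biomass-production calls: FBA flux above 1% of the original, and all
#' component PMs above 0.1 (low) or 0.6 (high).
#'
#' @param net a network carrying `nutrients`, `biomass_components` and
#'   `objective_reaction` fields (see [make_perturbation_network()]), or
#'   pass those explicitly.
#' @param biomass_components metabolite ids scored by PM; components whose
#'   unperturbed PM is 0 are dropped (they carry no signal).
#' @param objective_reaction FBA objective reaction id.
#' @param minimal_medium metabolite ids of the minimal medium.
#' @param levels removal levels (levels exceeding the removable count are
#'   dropped with a message).
#' @param reps perturbed networks per level.
#' @param params a [pm_params()] for the PM calculations.
#' @param protected extra reaction ids excluded from removal.
#' @param seed master seed; each (level, replicate) derives its own stream.
#' @return tibble of per-replicate results, class `perturbation_study`.
#' @export
perturbation_study <- function(net,
                               biomass_components = net$biomass_components,
                               objective_reaction = net$objective_reaction,
                               minimal_medium = net$nutrients,
                               levels = c(4, 16, 64, 256, 1024),
                               reps = 50,
                               params = pm_params(),
                               protected = character(),
                               seed = 1L) {
  net <- validate_metnet(net)
  if (is.null(biomass_components) || is.null(objective_reaction) || is.null(minimal_medium)) {
    stop("biomass_components, objective_reaction and minimal_medium are required")
  }
  maintenance <- net$reactions$id[toupper(net$reactions$id) == "ATPM" |
                                    grepl("maintenance", net$reactions$name, ignore.case = TRUE)]
  protected <- unique(c(protected, objective_reaction, maintenance))
  complete_medium <- native_exchange_metabolites(net)

  flux0_min <- fba_biomass(net, minimal_medium, objective_reaction)
  flux0_com <- fba_biomass(net, complete_medium, objective_reaction)
  if (flux0_min <= 0 || flux0_com <= 0) {
    stop("original network cannot produce biomass; check medium and objective")
  }

  pm_of <- function(network, seed_base) {
    prep <- prepare_model(network)
    vapply(seq_along(biomass_components), function(k) {
      calc_pm(prep, biomass_components[k], params = params,
              seed = as.integer((seed_base + 97 * k) %% 2147483647))$pm
    }, numeric(1))
  }
  pm0 <- pm_of(net, seed_base = as.double(seed))
  if (any(pm0 == 0)) {
    message("dropping ", sum(pm0 == 0), " biomass component(s) with baseline PM 0")
    biomass_components <- biomass_components[pm0 > 0]
    pm0 <- pm0[pm0 > 0]
    if (!length(biomass_components)) stop("no biomass component has nonzero baseline PM")
  }

  removable <- length(setdiff(net$reactions$id, protected))
  keep_levels <- levels[levels <= removable]
  if (length(keep_levels) < length(levels)) {
    message("dropping removal level(s) beyond the ", removable, " removable reactions")
  }

  rows <- list()
  job <- 0L
  for (lv in keep_levels) {
    for (rep_i in seq_len(reps)) {
      job <- job + 1L
      set.seed(as.integer((as.double(seed) + 7919 * job) %% 2147483647))
      pert <- remove_random_reactions(net, lv, protected)
      flux_min <- fba_biomass(pert, intersect(minimal_medium, native_exchange_metabolites(pert)),
                              objective_reaction)
      flux_com <- fba_biomass(pert, native_exchange_metabolites(pert), objective_reaction)
      pmv <- pm_of(pert, seed_base = as.double(seed) + 7919 * job)
      rows[[job]] <- tibble::tibble(
        level = lv, replicate = rep_i,
        fba_accuracy_minimal = max(0, 1 - abs(flux_min - flux0_min) / flux0_min),
        fba_accuracy_complete = max(0, 1 - abs(flux_com - flux0_com) / flux0_com),
        pm_accuracy = max(0, 1 - sum(abs(pmv - pm0)) / sum(pm0)),
        fba_biomass_ok_minimal = flux_min > 0.01 * flux0_min,
        fba_biomass_ok_complete = flux_com > 0.01 * flux0_com,
        pm_biomass_ok_low = all(pmv > 0.1),
        pm_biomass_ok_high = all(pmv > 0.6)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline") <- list(flux_minimal = flux0_min, flux_complete = flux0_com,
                                pm = stats::setNames(pm0, biomass_components))
  class(out) <- c("perturbation_study", class(out))
  out
}

native_exchange_metabolites <- function(net) {
  nz <- Matrix::colSums(net$S != 0)
  cols <- which(nz == 1)
  if (!length(cols)) return(character(0))
  unique(net$metabolites$id[Matrix::rowSums(net$S[, cols, drop = FALSE] != 0) > 0])
}

#' Per-level summary of a perturbation study
#'
#' Means and standard errors of the accuracy measures, plus the fraction of
#' replicates passing each biomass-production call.
#'
#' @param x a [perturbation_study()] result.
#' @export
summarize_perturbation <- function(x) {
  stopifnot(inherits(x, "perturbation_study"))
  se <- function(v) stats::sd(v) / sqrt(length(v))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$level),
    n = dplyr::n(),
    fba_minimal_mean = mean(.data$fba_accuracy_minimal),
    fba_minimal_se = se(.data$fba_accuracy_minimal),
    fba_complete_mean = mean(.data$fba_accuracy_complete),
    fba_complete_se = se(.data$fba_accuracy_complete),
    pm_mean = mean(.data$pm_accuracy),
    pm_se = se(.data$pm_accuracy),
    fba_ok_minimal = mean(.data$fba_biomass_ok_minimal),
    fba_ok_complete = mean(.data$fba_biomass_ok_complete),
    pm_ok_low = mean(.data$pm_biomass_ok_low),
    pm_ok_high = mean(.data$pm_biomass_ok_high),
    .groups = "drop")
}
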