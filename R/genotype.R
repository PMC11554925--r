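#' Genotype edits on a metabolic network
#'
#' A genotype edit is a set of reaction deletions plus reaction additions
#' (with stoichiometry and bounds), representing gene knockouts and
#' heterologous pathway insertions.
#'
#' @param deletions character vector of reaction identifiers to remove.
#' @param additions list of additions; each is a list with elements
#'   `id` (character), `stoich` (named numeric: metabolite -> coefficient;
#'   unknown metabolites are appended to the network), `lower`, `upper`
#'   (bounds, defaults 0 / 1000) and optional `objective` (default 0).
#' @return an object of class `genotype_edit`.
#' @export
genotype_edit <- function(deletions = character(), additions = list()) {
  for (a in additions) {
    if (is.null(a$id) || is.null(a$stoich)) {
      stop_edit("each addition needs an 'id' and a named 'stoich' vector")
    }
  }
  structure(list(deletions = as.character(deletions), additions = additions),
            class = "genotype_edit")
}

#' Canonical production-strain edit
#'
#' The edit that turns a wild-type core network into the 2,3-butanediol
#' production strain: knock out the fermentative NAD+ regeneration routes
#' (ethanol via the bifunctional alcohol/acetaldehyde dehydrogenase, i.e.
#' both ACALD and ALCD2x; lactate via LDH_D; succinate via FRD7) and the
#' phosphotransacetylase step of acetate excretion (PTAr), then add the
#' heterologous acetolactate synthase (ACLS), acetolactate decarboxylase
#' (ACLDC) and acetoin/butanediol dehydrogenase (BDH) reactions together
#' with acetoin and 2,3-butanediol transport and exchange.
#'
#' @param dialect `"ecoli_core"` for a published core-model namespace
#'   (metabolites `*_c`/`*_e`), or `"builtin"` for the built-in minimal
#'   network, which already encodes the production strain and therefore
#'   needs no edit (the returned edit is empty).
#' @return a [genotype_edit()].
#' @export
btd_genotype_edit <- function(dialect = c("ecoli_core", "builtin")) {
  dialect <- match.arg(dialect)
  if (dialect == "builtin") return(genotype_edit())
  add <- function(id, stoich, lower = 0, upper = 1000) {
    list(id = id, stoich = stoich, lower = lower, upper = upper)
  }
  genotype_edit(
    deletions = c("ACALD", "ALCD2x", "LDH_D", "FRD7", "PTAr"),
    additions = list(
      add("ACLS",  c(pyr_c = -2, alac_c = 1, co2_c = 1)),
      add("ACLDC", c(alac_c = -1, actn_c = 1, co2_c = 1)),
      add("BDH",   c(actn_c = -1, nadh_c = -1, btd_c = 1, nad_c = 1)),
      add("ACTNt", c(actn_c = -1, actn_e = 1), lower = -1000),
      add("BTDt",  c(btd_c = -1, btd_e = 1), lower = -1000),
      add("EX_actn_e", c(actn_e = -1), lower = -1000),
      add("EX_btd_e",  c(btd_e = -1), lower = -1000)
    ))
}

#' Apply a genotype edit to a network
#'
#' @param net a [metabolic_network()].
#' @param edit a [genotype_edit()].
#' @return the edited network (a new object; `net` is unchanged).
#' @export
apply_genotype <- function(net, edit) {
  stopifnot(inherits(net, "metabolic_network"), inherits(edit, "genotype_edit"))
  miss <- setdiff(edit$deletions, net$reactions)
  if (length(miss)) {
    stop_edit(sprintf("deletion of nonexistent reaction(s): %s",
                      paste(miss, collapse = ", ")))
  }
  add_ids <- vapply(edit$additions, `[[`, character(1), "id")
  clash <- intersect(add_ids, setdiff(net$reactions, edit$deletions))
  if (length(clash)) {
    stop_edit(sprintf("addition id(s) collide with existing reactions: %s",
                      paste(clash, collapse = ", ")))
  }
  keep <- !(net$reactions %in% edit$deletions)
  S <- net$stoich[, keep, drop = FALSE]
  rx <- net$reactions[keep]
  lower <- net$lower[keep]; upper <- net$upper[keep]; objective <- net$objective[keep]
  mets <- net$metabolites
  for (a in edit$additions) {
    new_mets <- setdiff(names(a$stoich), mets)
    if (length(new_mets)) {
      S <- rbind(S, Matrix::Matrix(0, length(new_mets), ncol(S), sparse = TRUE))
      mets <- c(mets, new_mets)
    }
    col <- numeric(length(mets))
    col[match(names(a$stoich), mets)] <- a$stoich
    S <- cbind(S, col)
    rx <- c(rx, a$id)
    lower <- c(lower, if (is.null(a$lower)) 0 else a$lower)
    upper <- c(upper, if (is.null(a$upper)) 1000 else a$upper)
    objective <- c(objective, if (is.null(a$objective)) 0 else a$objective)
  }
  metabolic_network(mets, rx, S, lower, upper, objective)
}

#' Invert a genotype edit
#'
#' Builds the edit that undoes `edit` on the network it was applied to:
#' deleting what was added and re-adding what was deleted (with the original
#' stoichiometry and bounds taken from `net`). Applying the result to
#' `apply_genotype(net, edit)` restores the original reaction set.
#'
#' @param net the original (pre-edit) network.
#' @param edit the edit to invert.
#' @return a [genotype_edit()].
#' @export
invert_genotype_edit <- function(net, edit) {
  adds <- lapply(edit$deletions, function(id) {
    j <- match(id, net$reactions)
    col <- net$stoich[, j]
    list(id = id, stoich = col[col != 0],
         lower = unname(net$lower[j]), upper = unname(net$upper[j]),
         objective = unname(net$objective[j]))
  })
  genotype_edit(
    deletions = vapply(edit$additions, `[[`, character(1), "id"),
    additions = adds)
}
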