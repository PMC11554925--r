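#' Stoichiometric metabolic network
#'
#' Container for a (small) constraint-based metabolic model: a sparse
#' stoichiometric matrix (metabolites x reactions), per-reaction flux bounds
#' and objective coefficients. Internal fluxes are in mmol/gDW/h; the
#' biomass reaction flux is in 1/h.
#'
#' @param metabolites character vector of metabolite identifiers.
#' @param reactions character vector of reaction identifiers.
#' @param stoich matrix (dense or `Matrix` sparse) of stoichiometric
#'   coefficients, `length(metabolites)` rows by `length(reactions)` columns.
#' @param lower,upper per-reaction flux bounds (named or positional).
#' @param objective per-reaction objective coefficients (default all zero).
#' @return an object of class `metabolic_network`.
#' @seealso [builtin_network()], [load_network()], [fba_optimize()]
#' @export
metabolic_network <- function(metabolites, reactions, stoich,
                              lower, upper, objective = NULL) {
  stoich <- Matrix::Matrix(stoich, sparse = TRUE)
  dimnames(stoich) <- list(metabolites, reactions)
  if (is.null(objective)) objective <- numeric(length(reactions))
  net <- structure(
    list(metabolites = as.character(metabolites),
         reactions = as.character(reactions),
         stoich = stoich,
         lower = setNames(as.numeric(lower), reactions),
         upper = setNames(as.numeric(upper), reactions),
         objective = setNames(as.numeric(objective), reactions)),
    class = "metabolic_network")
  validate_network(net)
}

validate_network <- function(net) {
  n_r <- length(net$reactions); n_m <- length(net$metabolites)
  if (ncol(net$stoich) != n_r) {
    stop_model("stoichiometric matrix column count does not match reaction count")
  }
  if (nrow(net$stoich) != n_m) {
    stop_model("stoichiometric matrix row count does not match metabolite count")
  }
  if (anyDuplicated(net$reactions)) stop_model("duplicated reaction identifiers")
  if (anyDuplicated(net$metabolites)) stop_model("duplicated metabolite identifiers")
  bad <- which(net$lower > net$upper)
  if (length(bad)) {
    stop_model(sprintf("lower bound exceeds upper bound for reaction(s): %s",
                       paste(net$reactions[bad], collapse = ", ")))
  }
  ## boundary reactions must touch exactly one metabolite
  ex <- grep("^(EX_|DM_|SK_)", net$reactions)
  for (j in ex) {
    if (sum(net$stoich[, j] != 0) != 1) {
      stop_model(sprintf("exchange reaction %s touches %d metabolites (expected 1)",
                         net$reactions[j], sum(net$stoich[, j] != 0)))
    }
  }
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites x %d reactions\n",
              length(x$metabolites), length(x$reactions)))
  cat("  exchanges:", paste(grep("^(EX_|DM_|SK_)", x$reactions, value = TRUE),
                            collapse = ", "), "\n")
  obj <- which(x$objective != 0)
  if (length(obj)) cat("  objective:", paste(x$reactions[obj], collapse = ", "), "\n")
  invisible(x)
}

#' Built-in minimal network of the 2,3-butanediol production strain
#'
#' A 13-metabolite, 15-reaction redox/energy-coupled network that captures
#' the flux routes relevant for 2,3-butanediol production in the engineered
#' strain: glycolysis to pyruvate, pyruvate oxidation and a lumped TCA cycle,
#' respiration as the only NADH sink besides acetoin reduction, an ATP
#' maintenance requirement, the acetolactate -> acetoin -> 2,3-butanediol
#' pathway, and exchanges for glucose, oxygen, CO2, acetoin, butanediol and
#' biomass. Fermentative NAD+ regeneration routes (ethanol, lactate,
#' succinate, acetate) are absent, mirroring the production strain's
#' deletions, so glycolytic NADH can only be reoxidized by respiration or by
#' acetoin reduction to 2,3-butanediol.
#'
#' Biomass draws 11 mmol pyruvate and 165 mmol ATP per gDW; the ATP
#' coefficient is calibrated so that the maximal aerobic biomass yield on
#' glucose is ~0.49 g/g (LP check, see the methods vignette).
#'
#' @param glucose_lb lower bound on the glucose exchange flux (mmol/gDW/h,
#'   negative = uptake). Default -10.
#' @param maintenance lower bound of the ATP maintenance reaction
#'   (mmol/gDW/h). Default 8.39.
#' @param big default magnitude for otherwise unbounded fluxes.
#' @return a [metabolic_network()] with the biomass reaction as objective.
#' @export
builtin_network <- function(glucose_lb = -10, maintenance = 8.39, big = 1000) {
  mets <- c("glc", "pyr", "accoa", "alac", "actn", "btd",
            "nadh", "nad", "atp", "adp", "o2", "co2", "X")
  rxn <- function(...) {
    v <- numeric(length(mets)); names(v) <- mets
    coefs <- c(...)
    v[names(coefs)] <- coefs
    v
  }
  cols <- list(
    GLYC    = rxn(glc = -1, adp = -2, nad = -2, pyr = 2, atp = 2, nadh = 2),
    PDH     = rxn(pyr = -1, nad = -1, accoa = 1, nadh = 1, co2 = 1),
    TCA     = rxn(accoa = -1, nad = -3, adp = -1, co2 = 2, nadh = 3, atp = 1),
    RESP    = rxn(nadh = -1, o2 = -0.5, adp = -2, nad = 1, atp = 2),
    ATPM    = rxn(atp = -1, adp = 1),
    ACLS    = rxn(pyr = -2, alac = 1, co2 = 1),
    ACLDC   = rxn(alac = -1, actn = 1, co2 = 1),
    BDH     = rxn(actn = -1, nadh = -1, btd = 1, nad = 1),
    BIOMASS = rxn(pyr = -11, atp = -165, adp = 165, X = 1),
    EX_glc  = rxn(glc = -1),
    EX_o2   = rxn(o2 = -1),
    EX_co2  = rxn(co2 = -1),
    EX_actn = rxn(actn = -1),
    EX_btd  = rxn(btd = -1),
    EX_X    = rxn(X = -1)
  )
  S <- do.call(cbind, cols)
  lower <- c(GLYC = 0, PDH = 0, TCA = 0, RESP = 0, ATPM = maintenance,
             ACLS = 0, ACLDC = 0, BDH = 0, BIOMASS = 0,
             EX_glc = glucose_lb, EX_o2 = -big, EX_co2 = -big,
             EX_actn = -big, EX_btd = -big, EX_X = 0)
  upper <- setNames(rep(big, length(cols)), names(cols))
  obj <- setNames(numeric(length(cols)), names(cols)); obj["BIOMASS"] <- 1
  metabolic_network(mets, names(cols), S, lower[names(cols)], upper, obj)
}

#' Load a metabolic network
#'
#' Reads a stoichiometric model either from an SBML Level 3 file (with the
#' `fbc` flux-bounds package, the dialect used for published core models) or
#' constructs the built-in minimal production-strain network.
#'
#' @param source path to an SBML file, or the tag `"builtin"` for the
#'   built-in network (constructed entirely in code, no download).
#' @param ... passed to [builtin_network()] when `source == "builtin"`.
#' @return a [metabolic_network()].
#' @export
load_network <- function(source, ...) {
  if (identical(source, "builtin") || identical(source, "minimal")) {
    return(builtin_network(...))
  }
  if (!is.character(source) || length(source) != 1 || !file.exists(source)) {
    stop_parse(sprintf("SBML source '%s' is not a readable file",
                       paste(source, collapse = ",")))
  }
  read_sbml_network(source)
}

read_sbml_network <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_parse(
                    sprintf("malformed SBML in '%s': %s", path, conditionMessage(e))))
  find <- function(node, what) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  }
  model <- find(doc, "model")
  if (length(model) == 0) stop_parse(sprintf("no <model> element in '%s'", path))

  sp <- find(doc, "species")
  if (length(sp) == 0) stop_parse(sprintf("no <species> elements in '%s'", path))
  sp_id <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  mets <- sp_id[!boundary]

  ## fbc parameters for flux bounds
  pars <- find(doc, "parameter")
  par_val <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                      xml2::xml_attr(pars, "id"))

  rx_nodes <- find(doc, "reaction")
  if (length(rx_nodes) == 0) stop_parse(sprintf("no <reaction> elements in '%s'", path))
  n_r <- length(rx_nodes)
  rx_id <- xml2::xml_attr(rx_nodes, "id")
  lower <- numeric(n_r); upper <- numeric(n_r)
  trip <- list()
  for (j in seq_len(n_r)) {
    node <- rx_nodes[[j]]
    refs <- function(tag, sign) {
      srefs <- xml2::xml_find_all(
        node, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (length(srefs) == 0) return(NULL)
      st <- xml2::xml_attr(srefs, "stoichiometry")
      st[is.na(st)] <- "1"
      data.frame(met = xml2::xml_attr(srefs, "species"),
                 coef = sign * as.numeric(st))
    }
    sref <- rbind(refs("listOfReactants", -1), refs("listOfProducts", +1))
    if (!is.null(sref)) {
      sref <- sref[sref$met %in% mets, , drop = FALSE]
      if (nrow(sref)) trip[[length(trip) + 1L]] <-
          cbind(i = match(sref$met, mets), j = j, x = sref$coef)
    }
    ## bounds: fbc attributes referencing parameters, else reversibility
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    rev <- !(xml2::xml_attr(node, "reversible") %in% c("false", "0"))
    lower[j] <- if (!is.na(lb_ref)) {
      if (is.na(par_val[lb_ref])) stop_parse(
        sprintf("reaction %s references undefined bound parameter '%s'", rx_id[j], lb_ref))
      par_val[[lb_ref]]
    } else if (rev) -1000 else 0
    upper[j] <- if (!is.na(ub_ref)) {
      if (is.na(par_val[ub_ref])) stop_parse(
        sprintf("reaction %s references undefined bound parameter '%s'", rx_id[j], ub_ref))
      par_val[[ub_ref]]
    } else 1000
  }
  trip <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "x"],
                            dims = c(length(mets), n_r))

  ## objective: fbc fluxObjective, falling back to a biomass-named reaction
  fobj <- find(doc, "fluxObjective")
  obj <- numeric(n_r)
  if (length(fobj)) {
    orx <- xml2::xml_attr(fobj, "reaction")
    oco <- as.numeric(xml2::xml_attr(fobj, "coefficient"))
    oco[is.na(oco)] <- 1
    obj[match(orx, rx_id)] <- oco
  } else {
    bio <- grep("biomass", rx_id, ignore.case = TRUE)
    if (length(bio) == 0) {
      stop_model(sprintf("no objective and no biomass reaction found in '%s'", path))
    }
    obj[bio[1]] <- 1
  }
  metabolic_network(mets, rx_id, S, lower, upper, obj)
}

#' Set flux bounds on a network
#'
#' @param net a [metabolic_network()].
#' @param reaction reaction identifier(s).
#' @param lower,upper new bounds (recycled); `NULL` leaves a side unchanged.
#' @return the modified network.
#' @export
set_bounds <- function(net, reaction, lower = NULL, upper = NULL) {
  miss <- setdiff(reaction, net$reactions)
  if (length(miss)) stop_model(sprintf("unknown reaction(s): %s",
                                       paste(miss, collapse = ", ")))
  if (!is.null(lower)) net$lower[reaction] <- lower
  if (!is.null(upper)) net$upper[reaction] <- upper
  validate_network(net)
}

#' Fix a flux to a single value (equal lower and upper bound)
#' @rdname set_bounds
#' @param value flux value to pin the reaction(s) at.
#' @export
fix_flux <- function(net, reaction, value) {
  set_bounds(net, reaction, lower = value, upper = value)
}
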