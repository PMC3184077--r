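#' Construct a reaction universe
#'
#' A reaction universe is the global set of reactions from which metabolic
#' network genotypes are drawn: a stoichiometric matrix over all metabolites,
#' per-reaction reversibility, a role for every reaction (`metabolic`,
#' `exchange` or `biomass`), and a flag saying which reactions a sampler may
#' swap in and out.  Exchange reactions cross the system boundary and are
#' oriented so that positive flux secretes and negative flux imports their
#' single external metabolite.  The (at most one) biomass reaction consumes
#' the biomass precursors; its demands define viability.
#'
#' @param metabolites data.frame with columns `id` (unique character) and
#'   `external` (logical: may the metabolite cross the system boundary).
#' @param reactions data.frame with columns `id` (unique character),
#'   `equation` (see [parse_equation()]), `role` (one of `"metabolic"`,
#'   `"exchange"`, `"biomass"`) and `swappable` (logical).
#' @param check validate the assembled universe (default `TRUE`).
#' @return An object of class `reaction_universe`.
#' @seealso [read_universe()], [write_universe()], [validate_universe()]
#' @export
reaction_universe <- function(metabolites, reactions, check = TRUE) {
  met_ids <- as.character(metabolites$id)
  rxn_ids <- as.character(reactions$id)
  if (anyDuplicated(met_ids))
    fm_error("fm_duplicate_id", "duplicate metabolite identifiers")
  if (anyDuplicated(rxn_ids))
    fm_error("fm_duplicate_id", "duplicate reaction identifiers")

  m <- length(met_ids)
  n <- length(rxn_ids)
  met_index <- setNames(seq_len(m), met_ids)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  reversible <- logical(n)
  for (k in seq_len(n)) {
    eq <- parse_equation(reactions$equation[k])
    reversible[k] <- eq$reversible
    unknown <- setdiff(names(eq$coef), met_ids)
    if (length(unknown))
      fm_error("fm_unknown_metabolite",
               sprintf("reaction '%s' uses unknown metabolite(s): %s",
                       rxn_ids[k], paste(unknown, collapse = ", ")))
    ii <- c(ii, met_index[names(eq$coef)])
    jj <- c(jj, rep.int(k, length(eq$coef)))
    xx <- c(xx, unname(eq$coef))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n),
                            dimnames = list(met_ids, rxn_ids))

  role <- as.character(reactions$role)
  bio <- which(role == "biomass")
  precursors <- numeric(0)
  if (length(bio) == 1L) {
    col <- S[, bio]
    precursors <- -col[col < 0]
  }

  u <- structure(list(
    met_ids = met_ids,
    external = as.logical(metabolites$external),
    rxn_ids = rxn_ids,
    role = role,
    reversible = reversible,
    swappable = as.logical(reactions$swappable),
    S = S,
    biomass_precursors = precursors,
    cache = new.env(parent = emptyenv())
  ), class = "reaction_universe")
  if (check) validate_universe(u)
  u
}

#' Validate a reaction universe
#'
#' Checks every structural invariant: unique identifiers, matching
#' dimensions, exchange reactions with exactly one (negative) entry on an
#' external metabolite, at most one biomass reaction whose consumed
#' metabolites are the biomass precursors, and swappability restricted to
#' metabolic reactions.  Each violation raises a distinct condition class.
#'
#' @param u a `reaction_universe`.
#' @return `u`, invisibly.
#' @export
validate_universe <- function(u) {
  if (!inherits(u, "reaction_universe"))
    fm_error("fm_parse_error", "not a reaction_universe")
  m <- length(u$met_ids); n <- length(u$rxn_ids)
  if (anyDuplicated(u$met_ids) || anyDuplicated(u$rxn_ids))
    fm_error("fm_duplicate_id", "identifiers are not unique")
  if (!identical(dim(u$S), c(m, n)))
    fm_error("fm_parse_error", "stoichiometric matrix dimensions disagree")
  for (k in which(u$role == "exchange")) {
    col <- u$S[, k]
    nz <- which(col != 0)
    if (length(nz) != 1L || col[nz] >= 0)
      fm_error("fm_bad_exchange",
               sprintf("exchange '%s' must have exactly one negative entry",
                       u$rxn_ids[k]))
    if (!u$external[nz])
      fm_error("fm_bad_exchange",
               sprintf("exchange '%s' acts on a non-external metabolite",
                       u$rxn_ids[k]))
  }
  bio <- which(u$role == "biomass")
  if (length(bio) > 1L)
    fm_error("fm_no_biomass", "more than one biomass reaction")
  if (length(bio) == 1L) {
    col <- u$S[, bio]
    consumed <- u$met_ids[col < 0]
    if (!setequal(consumed, names(u$biomass_precursors)))
      fm_error("fm_no_biomass",
               "biomass precursors do not match the biomass reaction")
  }
  if (any(u$swappable & u$role != "metabolic"))
    fm_error("fm_parse_error", "only metabolic reactions may be swappable")
  invisible(u)
}

#' Parse a reaction equation
#'
#' Grammar: `coef? metab (" + " coef? metab)* (" => " | " <=> ") [products]`,
#' with a default coefficient of 1 and `<=>` marking the reaction
#' reversible.  Either side may be empty (boundary reactions such as
#' `"A_ext =>"`).  Coefficients on the left are negated.
#'
#' @param eq equation string.
#' @return list with `coef` (named numeric, net stoichiometry) and
#'   `reversible` (logical).
#' @export
parse_equation <- function(eq) {
  eq <- trimws(eq)
  rev_arrow <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (rev_arrow) "<=>" else "=>"
  parts <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (!grepl("=>", eq, fixed = TRUE) || length(parts) > 2L)
    fm_error("fm_parse_error", sprintf("malformed equation: '%s'", eq))
  lhs <- if (length(parts) >= 1L) trimws(parts[1]) else ""
  rhs <- if (length(parts) == 2L) trimws(parts[2]) else ""
  if (!nzchar(lhs) && !nzchar(rhs))
    fm_error("fm_parse_error", sprintf("empty equation: '%s'", eq))

  side <- function(s, sign) {
    if (!nzchar(s)) return(numeric(0))
    out <- numeric(0)
    for (term in trimws(strsplit(s, " + ", fixed = TRUE)[[1]])) {
      toks <- strsplit(term, "[ ]+")[[1]]
      if (length(toks) == 1L) {
        coef <- 1; met <- toks
      } else if (length(toks) == 2L && grepl("^[0-9.]+$", toks[1])) {
        coef <- as.numeric(toks[1]); met <- toks[2]
      } else {
        fm_error("fm_parse_error", sprintf("malformed term: '%s'", term))
      }
      if (is.na(coef) || !nzchar(met))
        fm_error("fm_parse_error", sprintf("malformed term: '%s'", term))
      cur <- if (met %in% names(out)) out[[met]] else 0
      out[met] <- cur + sign * coef
    }
    out
  }
  l <- side(lhs, -1)
  r <- side(rhs, +1)
  coef <- l
  for (metab in names(r)) coef[metab] <- (if (metab %in% names(coef)) coef[metab] else 0) + r[metab]
  coef <- coef[coef != 0]
  list(coef = coef, reversible = rev_arrow)
}

# canonical textual form of one stoichiometric column
deparse_equation <- function(coef, reversible) {
  fmt <- function(v, ids) {
    if (!length(ids)) return("")
    paste(ifelse(v == 1, ids, paste(format(v, trim = TRUE, scientific = FALSE), ids)),
          collapse = " + ")
  }
  ids <- names(coef)
  o <- order(ids)
  coef <- coef[o]; ids <- ids[o]
  neg <- coef < 0; pos <- coef > 0
  arrow <- if (reversible) "<=>" else "=>"
  lhs <- fmt(-coef[neg], ids[neg])
  rhs <- fmt(coef[pos], ids[pos])
  trimws(paste(lhs, arrow, rhs))
}

#' Read a reaction universe from disk
#'
#' The TSV dialect expects a directory containing `reactions.tsv`
#' (`reaction_id`, `equation`, `role`, `swappable`) and `metabolites.tsv`
#' (`metabolite_id`, `external`).  The SBML dialect reads a single
#' level-2/3 file, mapping species `boundaryCondition` to the external flag
#' (requires the xml2 package).
#'
#' @param path directory (tsv) or file (sbml).
#' @param dialect `"tsv"` (default) or `"sbml"`.
#' @return a `reaction_universe`.
#' @export
read_universe <- function(path, dialect = c("tsv", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "sbml") return(read_universe_sbml(path))
  rfile <- file.path(path, "reactions.tsv")
  mfile <- file.path(path, "metabolites.tsv")
  if (!file.exists(rfile) || !file.exists(mfile))
    fm_error("fm_parse_error",
             sprintf("expected reactions.tsv and metabolites.tsv under '%s'", path))
  rx <- read.delim(rfile, stringsAsFactors = FALSE, colClasses = "character")
  mt <- read.delim(mfile, stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(rx) || !nrow(mt))
    fm_error("fm_empty_file", "empty reaction or metabolite table")
  reaction_universe(
    metabolites = data.frame(id = mt$metabolite_id,
                             external = mt$external == "1",
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = rx$reaction_id,
                           equation = rx$equation,
                           role = rx$role,
                           swappable = rx$swappable == "1",
                           stringsAsFactors = FALSE)
  )
}

#' Write a reaction universe as canonical TSV
#'
#' Emits `reactions.tsv` and `metabolites.tsv` under `path` with rows sorted
#' by identifier and equations in canonical form (metabolites sorted within
#' each side), so that writing is independent of construction order and
#' write-then-read round-trips are byte-identical.
#'
#' @param u a `reaction_universe`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_universe <- function(u, path) {
  validate_universe(u)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  o <- order(u$rxn_ids)
  eqs <- vapply(seq_along(u$rxn_ids), function(k) {
    col <- u$S[, k]
    deparse_equation(col[col != 0], u$reversible[k])
  }, character(1))
  rx <- data.frame(reaction_id = u$rxn_ids[o], equation = eqs[o],
                   role = u$role[o], swappable = as.integer(u$swappable[o]),
                   stringsAsFactors = FALSE)
  om <- order(u$met_ids)
  mt <- data.frame(metabolite_id = u$met_ids[om],
                   external = as.integer(u$external[om]),
                   stringsAsFactors = FALSE)
  write.table(rx, file.path(path, "reactions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(mt, file.path(path, "metabolites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define a minimal growth environment
#'
#' An environment is a minimal medium: the set of external metabolites whose
#' uptake is open (typically a shared inorganic base set plus one carbon
#' source).  All other exchange reactions may only secrete.
#'
#' @param label short name, conventionally the carbon source.
#' @param importable character vector of external metabolite ids.
#' @return an object of class `growth_environment`.
#' @export
growth_environment <- function(label, importable) {
  structure(list(label = as.character(label),
                 importable = unique(as.character(importable))),
            class = "growth_environment")
}

#' Read minimal environments from JSON
#'
#' Expects a JSON array of objects `{label, importable: [...]}`.  Importable
#' metabolites are checked against the universe's external metabolites when
#' one is supplied.
#'
#' @param path JSON file.
#' @param universe optional `reaction_universe` used for validation.
#' @return list of [growth_environment()] objects.
#' @export
read_environments <- function(path, universe = NULL) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(raw)) fm_error("fm_empty_file", "no environments in file")
  envs <- lapply(raw, function(e)
    growth_environment(e$label, unlist(e$importable)))
  if (!is.null(universe)) {
    ext <- universe$met_ids[universe$external]
    for (e in envs) {
      bad <- setdiff(e$importable, ext)
      if (length(bad))
        fm_error("fm_unknown_metabolite",
                 sprintf("environment '%s': not external metabolites: %s",
                         e$label, paste(bad, collapse = ", ")))
    }
  }
  envs
}

#' Write environments to JSON
#' @param environments list of [growth_environment()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_environments <- function(environments, path) {
  jsonlite::write_json(
    lapply(environments, function(e)
      list(label = e$label, importable = e$importable)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read reaction-to-pathway annotations
#'
#' TSV with columns `reaction_id` and `pathway`; multiple rows per reaction
#' accumulate into that reaction's annotation set.
#'
#' @param path TSV file.
#' @param universe optional `reaction_universe`; annotated reactions must
#'   exist in it.
#' @return named list mapping reaction id to a character vector of pathways.
#' @export
read_annotations <- function(path, universe = NULL) {
  tb <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(tb)) fm_error("fm_empty_file", "no annotations in file")
  if (!is.null(universe)) {
    bad <- setdiff(unique(tb$reaction_id), universe$rxn_ids)
    if (length(bad))
      fm_error("fm_unknown_reaction",
               sprintf("annotations for unknown reaction(s): %s",
                       paste(bad, collapse = ", ")))
  }
  lapply(split(tb$pathway, tb$reaction_id), unique)
}

#' Write annotations as TSV
#' @param annotations named list, reaction id to character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  ids <- rep(names(annotations), lengths(annotations))
  tb <- data.frame(reaction_id = ids, pathway = unlist(annotations, use.names = FALSE),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$reaction_id, tb$pathway), ]
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# minimal SBML level-2/3 import (species boundaryCondition -> external flag)
read_universe_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    fm_error("fm_parse_error", "SBML import requires the xml2 package")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    external = xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1"),
    stringsAsFactors = FALSE)
  rxns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  build_side <- function(node, xp) {
    refs <- xml2::xml_find_all(node, xp)
    if (!length(refs)) return(numeric(0))
    coefs <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    coefs[is.na(coefs)] <- 1
    setNames(coefs, xml2::xml_attr(refs, "species"))
  }
  eqs <- vapply(rxns, function(r) {
    sub <- build_side(r, "./listOfReactants/speciesReference")
    prod <- build_side(r, "./listOfProducts/speciesReference")
    coef <- setNames(numeric(0), character(0))
    for (s in names(sub)) coef[s] <- -sub[[s]]
    for (p in names(prod)) coef[p] <- (if (p %in% names(coef)) coef[p] else 0) + prod[[p]]
    rev <- xml2::xml_attr(r, "reversible") %in% c(NA, "true", "1")
    deparse_equation(coef[coef != 0], rev)
  }, character(1))
  reaction_universe(
    metabolites = met,
    reactions = data.frame(
      id = xml2::xml_attr(rxns, "id"),
      equation = eqs,
      role = "metabolic",
      swappable = TRUE,
      stringsAsFactors = FALSE))
}
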