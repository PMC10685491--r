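#' Plasmid specification
#'
#' Describes a (dummy) plasmid by length and GC content and derives its
#' deoxyribonucleotide stoichiometry and molecular weight. The polymerization
#' energy demand defaults to 1.36 mol ATP per mol dNTP incorporated.
#'
#' Working with a short dummy plasmid (the 8 bp, 50% GC default) keeps the
#' molecular weight of the plasmid species small, which avoids numerical
#' trouble in flux computations; results expressed in grams of plasmid are
#' invariant to the length because the underlying stoichiometry per base pair
#' is unchanged.
#'
#' @param length_bp plasmid length in base pairs (integer >= 1).
#' @param gc_fraction GC content as a fraction in \[0, 1\].
#' @param atp_per_dntp polymerization cost, mol ATP per mol dNTP.
#' @return object of class `plasmid_spec` with fields `length_bp`,
#'   `gc_fraction`, `atp_per_dntp`, `counts` (named integer vector over
#'   datp/dttp/dgtp/dctp), and `molecular_weight` (g/mol).
#' @export
plasmid_spec <- function(length_bp = 8, gc_fraction = 0.5, atp_per_dntp = 1.36) {
  counts <- dntp_counts(length_bp, gc_fraction)
  structure(list(length_bp = as.integer(length_bp),
                 gc_fraction = gc_fraction,
                 atp_per_dntp = atp_per_dntp,
                 counts = counts,
                 molecular_weight = plasmid_mw(counts)),
            class = "plasmid_spec")
}

#' @export
print.plasmid_spec <- function(x, ...) {
  cat(sprintf("<plasmid_spec> %d bp, %.0f%% GC\n", x$length_bp, 100 * x$gc_fraction))
  cat("  dNTP counts:", paste(names(x$counts), x$counts, collapse = ", "), "\n")
  cat(sprintf("  ATP cost: %.2f per dNTP (%.2f total)\n",
              x$atp_per_dntp, x$atp_per_dntp * 2 * x$length_bp))
  cat(sprintf("  MW: %.2f g/mol\n", x$molecular_weight))
  invisible(x)
}

#' dNTP counts of a double-stranded plasmid
#'
#' The number of GC base pairs is `round(gc_fraction * length_bp)`
#' (round-half-up so that counts are deterministic); both strands together
#' then contain equal numbers of dATP/dTTP and of dGTP/dCTP, summing to
#' `2 * length_bp` nucleotides.
#'
#' @inheritParams plasmid_spec
#' @return named integer vector `c(datp, dttp, dgtp, dctp)`.
#' @export
dntp_counts <- function(length_bp, gc_fraction) {
  if (length_bp < 1 || length_bp != round(length_bp))
    stop("length_bp must be a positive integer")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  gc_pairs <- floor(gc_fraction * length_bp + 0.5)  # round half up
  at_pairs <- length_bp - gc_pairs
  c(datp = at_pairs, dttp = at_pairs, dgtp = gc_pairs, dctp = gc_pairs)
}

# average masses of dNMP residues in a DNA chain (dNTP minus pyrophosphate),
# neutral species, g/mol
.dnmp_residue_mass <- c(datp = 313.21, dttp = 304.20, dgtp = 329.21, dctp = 289.18)

#' Molecular weight of a plasmid polymer
#'
#' Sum over the incorporated dNMP residues (dNTP minus pyrophosphate) using
#' average neutral residue masses of 313.21 (dAMP), 304.20 (dTMP), 329.21
#' (dGMP), and 289.18 (dCMP) g/mol. For the 8 bp, 50% GC dummy plasmid this
#' gives 4943.2 g/mol.
#'
#' @param counts named vector of dNTP counts as from [dntp_counts()].
#' @return molecular weight in g/mol.
#' @export
plasmid_mw <- function(counts) {
  stopifnot(all(names(.dnmp_residue_mass) %in% names(counts)))
  sum(.dnmp_residue_mass * counts[names(.dnmp_residue_mass)])
}

# formula bookkeeping: parse "C10H12N5O12P3" into a named element count vector
parse_formula <- function(f) {
  if (is.na(f) || !nzchar(f)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)(\\d*\\.?\\d*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)(\\d*\\.?\\d*)", f))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(ct == "", 1, as.numeric(ct))
  tapply(ct, el, sum)
}

format_formula <- function(counts) {
  counts <- counts[counts != 0]
  ord <- order(names(counts))
  paste0(names(counts)[ord],
         ifelse(counts[ord] == 1, "", format(counts[ord], trim = TRUE)),
         collapse = "")
}

#' Add a plasmid synthesis pathway to a model
#'
#' Introduces a plasmid (pDNA) metabolite whose formula and charge are the
#' sums over the incorporated dNMP residues (each dNTP minus one
#' pyrophosphate), a synthesis reaction consuming the dNTPs plus the
#' polymerization ATP (hydrolyzed to ADP and phosphate, releasing one
#' pyrophosphate per nucleotide), and a sink reaction that makes synthesis
#' flux feasible. The plasmid does not enter the biomass reaction: changes in
#' overall biomass composition due to plasmid synthesis are assumed
#' negligible.
#'
#' @param model a `metabolic_model` containing the precursor metabolites.
#' @param spec a [plasmid_spec()].
#' @param met_ids named character vector mapping the roles
#'   `datp, dttp, dgtp, dctp, atp, adp, pi, ppi, h2o, h` to metabolite ids in
#'   `model`.
#' @param pdna_id,synthesis_id,sink_id ids for the new metabolite/reactions.
#' @return the augmented `metabolic_model` (also carries `spec` as attribute
#'   `plasmid_spec`).
#' @export
add_plasmid_pathway <- function(model, spec = plasmid_spec(),
                                met_ids = c(datp = "datp_c", dttp = "dttp_c",
                                            dgtp = "dgtp_c", dctp = "dctp_c",
                                            atp = "atp_c", adp = "adp_c",
                                            pi = "pi_c", ppi = "ppi_c",
                                            h2o = "h2o_c", h = "h_c"),
                                pdna_id = "pdna_c",
                                synthesis_id = "PDNAS", sink_id = "SK_pdna_c") {
  stopifnot(inherits(spec, "plasmid_spec"))
  miss <- setdiff(met_ids, model$mets$id)
  if (length(miss))
    stop("model lacks plasmid precursor metabolite(s): ", paste(miss, collapse = ", "))
  if (pdna_id %in% model$mets$id || synthesis_id %in% model$rxns$id ||
      sink_id %in% model$rxns$id)
    stop("plasmid pathway already present (id exists): ",
         paste(intersect(c(pdna_id, synthesis_id, sink_id),
                         c(model$mets$id, model$rxns$id)), collapse = ", "))

  n_nt <- 2 * spec$length_bp
  atp_total <- spec$atp_per_dntp * n_nt

  # plasmid formula/charge = sum of dNTP species minus one pyrophosphate each
  midx <- match(met_ids, model$mets$id)
  names(midx) <- names(met_ids)
  elem <- function(role) parse_formula(model$mets$formula[midx[[role]]])
  chg <- function(role) model$mets$charge[midx[role]]
  tot <- numeric(0)
  addel <- function(tot, add, mult) {
    for (e in names(add)) tot[e] <- (if (e %in% names(tot)) tot[e] else 0) + mult * add[[e]]
    tot
  }
  have_formulas <- all(!is.na(model$mets$formula[midx[c("datp", "dttp", "dgtp", "dctp", "ppi")]]))
  pdna_formula <- NA_character_
  pdna_charge <- 0
  if (have_formulas) {
    for (role in c("datp", "dttp", "dgtp", "dctp"))
      tot <- addel(tot, elem(role), spec$counts[[role]])
    tot <- addel(tot, elem("ppi"), -n_nt)
    pdna_formula <- format_formula(tot)
    pdna_charge <- sum(chg(c("datp", "dttp", "dgtp", "dctp")) *
                         spec$counts[c("datp", "dttp", "dgtp", "dctp")]) -
                   n_nt * chg("ppi")
  }

  model <- add_metabolite(model, pdna_id, formula = pdna_formula,
                          charge = pdna_charge, compartment = "c")
  stoich <- c(
    stats::setNames(-as.numeric(spec$counts),
                    met_ids[c("datp", "dttp", "dgtp", "dctp")]),
    stats::setNames(-atp_total, met_ids[["atp"]]),
    stats::setNames(-atp_total, met_ids[["h2o"]]),
    stats::setNames(atp_total, met_ids[["adp"]]),
    stats::setNames(atp_total, met_ids[["pi"]]),
    stats::setNames(atp_total, met_ids[["h"]]),
    stats::setNames(n_nt, met_ids[["ppi"]]))
  stoich[pdna_id] <- 1
  model <- add_reaction(model, synthesis_id, stoich, lb = 0, ub = 1000)
  model <- add_reaction(model, sink_id, stats::setNames(-1, pdna_id),
                        lb = 0, ub = 1000)
  attr(model, "plasmid_spec") <- spec
  attr(model, "pdna_synthesis_id") <- synthesis_id
  attr(model, "pdna_sink_id") <- sink_id
  model
}
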