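#' Coarse-grained force-field parameters
#'
#' Pairwise 8-6 potential plus Coulomb electrostatics. For an attractive
#' type pair the pair energy is \eqn{\epsilon[(R/r)^8 - (R/r)^6]} (minimum
#' \eqn{-27\epsilon/256} at \eqn{r^* = R\sqrt{4/3}}); for a non-attractive
#' pair the two terms add, giving a purely repulsive wall. Electrostatics
#' use \eqn{332.0636\, q_i q_j / (\epsilon(r)\, r)} with either a constant
#' dielectric of 1 or the distance-dependent \eqn{\epsilon(r) = r}.
#'
#' @param pair_table data.frame with columns \code{type_i}, \code{type_j},
#'   \code{epsilon} (kcal/mol, >= 0), \code{R} (Angstrom, > 0),
#'   \code{attractive} (logical). Symmetrized on construction.
#' @param dielectric_model \code{"distance"} (default, eps(r) = r) or
#'   \code{"constant"}.
#' @param coulomb_scale multiplier on the Coulomb term.
#' @param cutoff_sq re-scoring cutoff. With \code{cutoff_mode = "squared"}
#'   (default) it is a squared-distance threshold in Angstrom^2 (the
#'   literal reading of a "squared distance of 50 A"); with
#'   \code{"plain"} it is a distance in Angstrom.
#' @param cutoff_mode see \code{cutoff_sq}.
#' @param com_restraint_k harmonic constant (kcal/mol/A^2) of the restraint
#'   pulling the fragment center of mass toward the receptor center of mass
#'   during minimization.
#' @return object of class \code{forcefield_params}.
#' @export
forcefield_params <- function(pair_table,
                              dielectric_model = c("distance", "constant"),
                              coulomb_scale = 1.0,
                              cutoff_sq = 50,
                              cutoff_mode = c("squared", "plain"),
                              com_restraint_k = 0.0015) {
  dielectric_model <- match.arg(dielectric_model)
  cutoff_mode <- match.arg(cutoff_mode)
  need <- c("type_i", "type_j", "epsilon", "R", "attractive")
  stopifnot(all(need %in% names(pair_table)))
  if (any(pair_table$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(pair_table$R <= 0)) stop("R must be > 0")
  swapped <- pair_table
  swapped$type_i <- pair_table$type_j
  swapped$type_j <- pair_table$type_i
  tab <- unique(rbind(pair_table[need], swapped[need]))
  structure(list(pair_table = tab,
                 dielectric_model = dielectric_model,
                 coulomb_scale = coulomb_scale,
                 cutoff_sq = cutoff_sq,
                 cutoff_mode = cutoff_mode,
                 com_restraint_k = com_restraint_k),
            class = "forcefield_params")
}

#' Read a force-field pair table
#'
#' Tab-separated columns \code{type_i}, \code{type_j}, \code{epsilon},
#' \code{R}, \code{attractive} (0/1 or TRUE/FALSE); \code{#} comments
#' allowed. Remaining parameters are taken from the arguments.
#'
#' @param path parameter table file; the default is the toy table shipped
#'   with the package.
#' @param ... passed to \code{\link{forcefield_params}}.
#' @return a \code{forcefield_params}.
#' @export
read_forcefield <- function(path = system.file("extdata", "toy_forcefield.tsv",
                                               package = "rnafragdock"),
                            ...) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$attractive <- as.logical(tab$attractive)
  forcefield_params(tab, ...)
}

# Compile a force field into dense matrices over the compact code set
# needed for a (fragment codes) x (receptor codes) interaction. Errors on
# any needed pair that has no table entry.
compile_ff <- function(ff, frag_codes, rec_codes) {
  codes <- sort(unique(c(frag_codes, rec_codes)))
  n <- length(codes)
  EPS <- matrix(NA_real_, n, n)
  RB <- matrix(1, n, n)
  ATTR <- matrix(FALSE, n, n)
  tab <- ff$pair_table
  ii <- match(tab$type_i, codes)
  jj <- match(tab$type_j, codes)
  ok <- !is.na(ii) & !is.na(jj)
  EPS[cbind(ii[ok], jj[ok])] <- tab$epsilon[ok]
  RB[cbind(ii[ok], jj[ok])] <- tab$R[ok]
  ATTR[cbind(ii[ok], jj[ok])] <- tab$attractive[ok]
  for (a in unique(frag_codes)) {
    for (b in unique(rec_codes)) {
      if (is.na(EPS[match(a, codes), match(b, codes)])) {
        stop("no force-field entry for type pair (", a, ", ", b, ")")
      }
    }
  }
  EPS[is.na(EPS)] <- 0
  list(codes = codes, EPS = EPS, RB = RB, ATTR = ATTR,
       dd = ff$dielectric_model == "distance",
       coulomb_scale = ff$coulomb_scale,
       cutoff2 = if (ff$cutoff_mode == "squared") ff$cutoff_sq
                 else ff$cutoff_sq^2)
}

code_slots <- function(codes, compiled) match(codes, compiled$codes) - 1L

#' Interaction energy between a receptor and a placed fragment
#'
#' Direct pairwise sum of the 8-6 potential and Coulomb term over all
#' receptor-fragment bead pairs, with pairs beyond the force-field cutoff
#' excluded. Optionally adds the center-of-mass restraint
#' \eqn{k d^2} used during docking minimization.
#'
#' @param protein receptor \code{cg_structure}.
#' @param fragment placed fragment \code{cg_structure}.
#' @param ff a \code{forcefield_params}.
#' @param com_restraint logical; include the COM restraint term.
#' @param use_cutoff logical; apply the pair cutoff (default TRUE).
#' @return energy in kcal/mol.
#' @export
energy <- function(protein, fragment, ff, com_restraint = FALSE,
                   use_cutoff = TRUE) {
  cf <- compile_ff(ff, fragment$type_code, protein$type_code)
  e <- pair_energy_cpp(fragment$pos, code_slots(fragment$type_code, cf),
                       fragment$charge, protein$pos,
                       code_slots(protein$type_code, cf), protein$charge,
                       cf$EPS, cf$RB, cf$ATTR, cf$cutoff2, use_cutoff,
                       cf$dd, cf$coulomb_scale)
  if (com_restraint) {
    d <- cg_com(fragment) - cg_com(protein)
    e <- e + ff$com_restraint_k * sum(d^2)
  }
  e
}
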