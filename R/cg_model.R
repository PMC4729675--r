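#' Coarse-grained structure container
#'
#' A \code{cg_structure} holds an ordered set of coarse-grained beads, each
#' positioned at the unweighted center of mass of a small group of heavy
#' atoms. Nucleotides are represented by 6 beads (pyrimidines) or 7 beads
#' (purines): one phosphate bead, two sugar/backbone beads and 3-4 base
#' beads. Amino acids carry 3-4 beads (mainchain + sidechain).
#'
#' @param pos n x 3 numeric matrix of bead positions, Angstrom.
#' @param bead_name character(n) bead labels.
#' @param role character(n), each one of \code{"phosphate"}, \code{"sugar"},
#'   \code{"backbone"}, \code{"base"}, \code{"mainchain"}, \code{"sidechain"}.
#' @param type_code integer(n) force-field type codes (>= 0).
#' @param charge numeric(n) partial charges, e.
#' @param residue_index integer(n) 1-based ordinal of the parent residue
#'   within its chain.
#' @param chain_id character(n) chain labels.
#' @param residue_name character(n) parent residue names.
#' @param auth_seq integer(n) author residue numbers (defaults to
#'   \code{residue_index}); used to detect chain breaks.
#' @return An object of class \code{cg_structure}.
#' @export
cg_structure <- function(pos, bead_name, role, type_code, charge,
                         residue_index, chain_id, residue_name,
                         auth_seq = residue_index) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  n <- nrow(pos)
  rec <- function(v) if (length(v) == 1L && n > 1L) rep(v, n) else v
  bead_name <- rec(bead_name); role <- rec(role)
  type_code <- rec(type_code); charge <- rec(charge)
  residue_index <- rec(residue_index); chain_id <- rec(chain_id)
  residue_name <- rec(residue_name); auth_seq <- rec(auth_seq)
  stopifnot(all(is.finite(pos)),
            length(bead_name) == n, length(role) == n,
            length(type_code) == n, length(charge) == n,
            length(residue_index) == n, length(chain_id) == n,
            length(residue_name) == n)
  bad <- setdiff(unique(role),
                 c("phosphate", "sugar", "backbone", "base",
                   "mainchain", "sidechain"))
  if (length(bad)) stop("unknown bead role(s): ", paste(bad, collapse = ", "))
  if (any(type_code < 0)) stop("type_code must be >= 0")
  res <- unique(data.frame(chain_id = as.character(chain_id),
                           residue_index = as.integer(residue_index),
                           residue_name = as.character(residue_name),
                           auth_seq = as.integer(auth_seq),
                           stringsAsFactors = FALSE))
  structure(list(
    pos = pos,
    bead_name = as.character(bead_name),
    role = as.character(role),
    type_code = as.integer(type_code),
    charge = as.numeric(charge),
    residue_index = as.integer(residue_index),
    chain_id = as.character(chain_id),
    residue_name = as.character(residue_name),
    auth_seq = as.integer(auth_seq),
    residues = res
  ), class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat(sprintf("cg_structure: %d beads, %d residues, %d chain(s)\n",
              nrow(x$pos), nrow(x$residues), length(unique(x$chain_id))))
  invisible(x)
}

#' Number of beads
#' @param x a \code{cg_structure}.
#' @return integer bead count.
#' @export
n_beads <- function(x) nrow(x$pos)

#' Unweighted center of mass of the beads
#' @param x a \code{cg_structure}.
#' @return numeric(3).
#' @export
cg_com <- function(x) colMeans(x$pos)

#' Subset a cg_structure by bead index
#' @param x a \code{cg_structure}.
#' @param idx integer/logical bead selector.
#' @return a \code{cg_structure}.
#' @export
cg_subset <- function(x, idx) {
  cg_structure(x$pos[idx, , drop = FALSE], x$bead_name[idx], x$role[idx],
               x$type_code[idx], x$charge[idx], x$residue_index[idx],
               x$chain_id[idx], x$residue_name[idx], x$auth_seq[idx])
}

#' Apply a rigid transform to a coarse-grained structure
#'
#' Rotates then translates every bead position; all bookkeeping (types,
#' charges, roles, residues) is unchanged.
#'
#' @param conformer a \code{cg_structure}.
#' @param tr a \code{rigid_transform}.
#' @return the transformed \code{cg_structure}.
#' @export
apply_transform <- function(conformer, tr) {
  out <- conformer
  out$pos <- transform_coords(conformer$pos, tr)
  out
}

# --- all-atom structure I/O ------------------------------------------------

normalize_atom_name <- function(x) {
  x <- gsub("\\*", "'", x)
  x[x == "O1P"] <- "OP1"
  x[x == "O2P"] <- "OP2"
  x
}

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read an all-atom structure from PDB or mmCIF
#'
#' Minimal reader for the standard dialects. Keeps ATOM records of the
#' requested model, excludes heteroatoms and waters by default, keeps the
#' first alternate location (blank or "A"), and preserves author residue
#' numbering. Format is chosen by file extension (\code{.cif} /
#' \code{.mmcif} for mmCIF, anything else is parsed as PDB).
#'
#' @param path file path.
#' @param model_index 1-based model number to load.
#' @param keep_hetero keep non-water HETATM records (default FALSE).
#' @return A list of class \code{aa_structure} with \code{atoms} (data.frame:
#'   name, residue_name, chain_id, auth_seq, icode, x, y, z, element, het)
#'   and \code{residues} (data.frame: chain_id, residue_index, residue_name,
#'   auth_seq, icode).
#' @export
load_structure <- function(path, model_index = 1L, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  atoms <- if (ext %in% c("cif", "mmcif")) {
    read_mmcif_atoms(path, model_index)
  } else {
    read_pdb_atoms(path, model_index)
  }
  if (!keep_hetero) atoms <- atoms[!atoms$het, , drop = FALSE]
  atoms <- atoms[!(atoms$residue_name %in% WATER_NAMES), , drop = FALSE]
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  atoms$name <- normalize_atom_name(atoms$name)
  rkey <- paste(atoms$chain_id, atoms$auth_seq, atoms$icode, sep = "\r")
  # residue ordinal: order of first appearance within each chain
  residues <- atoms[!duplicated(rkey), c("chain_id", "residue_name",
                                         "auth_seq", "icode")]
  residues$residue_index <- stats::ave(seq_len(nrow(residues)),
                                       residues$chain_id,
                                       FUN = seq_along)
  rownames(residues) <- NULL
  idx <- match(rkey, paste(residues$chain_id, residues$auth_seq,
                           residues$icode, sep = "\r"))
  atoms$residue_index <- residues$residue_index[idx]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 residues = residues[, c("chain_id", "residue_index",
                                         "residue_name", "auth_seq",
                                         "icode")]),
            class = "aa_structure")
}

read_pdb_atoms <- function(path, model_index = 1L) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0) {
    if (model_index != 1L) stop("model ", model_index, " not present in ", path)
    sel <- seq_along(lines)
  } else {
    if (model_index > length(model_starts))
      stop("model ", model_index, " not present in ", path,
           " (", length(model_starts), " models)")
    start <- model_starts[model_index]
    ends <- which(trimws(rec) == "ENDMDL")
    end <- ends[ends > start][1]
    if (is.na(end)) end <- length(lines) + 1L
    sel <- seq(start, end - 1L)
  }
  lines <- lines[sel]
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_het <- rec == "HETATM"
  keep <- is_atom | is_het
  if (!any(keep)) stop("parse error: no ATOM/HETATM records in ", path)
  lines <- lines[keep]
  xyz <- cbind(as.numeric(substr(lines, 31, 38)),
               as.numeric(substr(lines, 39, 46)),
               as.numeric(substr(lines, 47, 54)))
  if (any(!is.finite(xyz))) {
    bad <- which(!stats::complete.cases(xyz))[1]
    stop("parse error in ", path, " at ATOM record ", bad,
         ": unreadable coordinates")
  }
  data.frame(
    name = trimws(substr(lines, 13, 16)),
    altloc = trimws(substr(lines, 17, 17)),
    residue_name = trimws(substr(lines, 18, 20)),
    chain_id = trimws(substr(lines, 22, 22)),
    auth_seq = as.integer(substr(lines, 23, 26)),
    icode = trimws(substr(lines, 27, 27)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = trimws(substr(lines, 77, 78)),
    het = is_het[keep],
    stringsAsFactors = FALSE
  )
}

read_mmcif_atoms <- function(path, model_index = 1L) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (length(tags) && all(startsWith(tags, "_atom_site."))) {
      j <- i
      while (j <= length(lines)) {
        l <- trimws(lines[j])
        if (l == "" || startsWith(l, "#") || startsWith(l, "loop_") ||
            startsWith(l, "_")) break
        j <- j + 1L
      }
      body <- trimws(lines[i:(j - 1L)])
      body <- body[body != ""]
      con <- textConnection(body)
      on.exit(close(con), add = TRUE)
      tab <- utils::read.table(con, stringsAsFactors = FALSE,
                               comment.char = "", quote = "\"'")
      names(tab) <- sub("^_atom_site\\.", "", tags)
      return(mmcif_table_to_atoms(tab, model_index, path))
    }
  }
  stop("parse error: no _atom_site loop found in ", path)
}

mmcif_table_to_atoms <- function(tab, model_index, path) {
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    NULL
  }
  model <- pick("pdbx_PDB_model_num")
  if (!is.null(model)) {
    models <- sort(unique(as.integer(model)))
    if (model_index > length(models))
      stop("model ", model_index, " not present in ", path)
    tab <- tab[as.integer(model) == models[model_index], , drop = FALSE]
  } else if (model_index != 1L) {
    stop("model ", model_index, " not present in ", path)
  }
  blank <- function(v) {
    if (is.null(v) || length(v) == 0) return("")
    v <- as.character(v)
    v[v %in% c(".", "?")] <- ""
    v
  }
  grp <- pick("group_PDB")
  data.frame(
    name = gsub("\"", "", as.character(pick("auth_atom_id", "label_atom_id"))),
    altloc = blank(pick("label_alt_id")),
    residue_name = as.character(pick("auth_comp_id", "label_comp_id")),
    chain_id = as.character(pick("auth_asym_id", "label_asym_id")),
    auth_seq = as.integer(pick("auth_seq_id", "label_seq_id")),
    icode = blank(pick("pdbx_PDB_ins_code")),
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    element = blank(pick("type_symbol")),
    het = if (is.null(grp)) FALSE else grp == "HETATM",
    stringsAsFactors = FALSE
  )
}

# --- bead mapping ----------------------------------------------------------

#' Read a coarse-grain bead mapping table
#'
#' Tab-separated columns: \code{residue_name}, \code{bead_name}, \code{role},
#' \code{type_code}, \code{charge}, \code{source_atoms} (comma-joined atom
#' names). One row per bead, rows ordered within each residue.
#'
#' @param path mapping file; default is the mapping shipped with the package.
#' @return data.frame with the columns above (class \code{cg_mapping}).
#' @export
read_mapping <- function(path = system.file("extdata", "cg_mapping.tsv",
                                            package = "rnafragdock")) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("residue_name", "bead_name", "role", "type_code", "charge",
            "source_atoms")
  if (!all(need %in% names(m))) {
    stop("mapping file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(m$source_atoms))) stop("source_atoms must be non-empty")
  if (any(m$type_code < 0)) stop("type_code must be >= 0")
  class(m) <- c("cg_mapping", class(m))
  m
}

#' Convert an all-atom structure to coarse-grained beads
#'
#' Each mapping entry produces one bead at the unweighted center of mass of
#' its source atoms. Residues with no mapping entry are skipped with a
#' warning. A residue whose mapping entry exists but for which any bead is
#' missing more than half of its source atoms is a conversion error.
#'
#' @param structure an \code{aa_structure} from \code{\link{load_structure}}.
#' @param mapping a mapping from \code{\link{read_mapping}}.
#' @return a \code{cg_structure}.
#' @export
coarse_grain <- function(structure, mapping = read_mapping()) {
  atoms <- structure$atoms
  res <- structure$residues
  out <- vector("list", nrow(res))
  skipped <- character()
  for (k in seq_len(nrow(res))) {
    r <- res[k, ]
    spec <- mapping[mapping$residue_name == r$residue_name, , drop = FALSE]
    if (nrow(spec) == 0) {
      skipped <- c(skipped, r$residue_name)
      next
    }
    ra <- atoms[atoms$chain_id == r$chain_id &
                  atoms$residue_index == r$residue_index, , drop = FALSE]
    pos <- matrix(NA_real_, nrow(spec), 3)
    for (b in seq_len(nrow(spec))) {
      src <- normalize_atom_name(trimws(strsplit(spec$source_atoms[b], ",")[[1]]))
      hit <- ra[ra$name %in% src, , drop = FALSE]
      if (nrow(hit) < length(src) / 2) {
        stop(sprintf(
          "cannot coarse-grain residue %s %s%d (chain %s): bead %s has %d of %d source atoms",
          r$residue_name, r$chain_id, r$auth_seq, r$chain_id,
          spec$bead_name[b], nrow(hit), length(src)))
      }
      pos[b, ] <- c(mean(hit$x), mean(hit$y), mean(hit$z))
    }
    out[[k]] <- list(pos = pos, spec = spec, r = r)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(skipped)) {
    warning("skipped residues with no mapping entry: ",
            paste(unique(skipped), collapse = ", "))
  }
  if (length(out) == 0) {
    return(cg_structure(matrix(numeric(), 0, 3), character(), character(),
                        integer(), numeric(), integer(), character(),
                        character(), integer()))
  }
  cg_structure(
    pos = do.call(rbind, lapply(out, `[[`, "pos")),
    bead_name = unlist(lapply(out, function(o) o$spec$bead_name)),
    role = unlist(lapply(out, function(o) o$spec$role)),
    type_code = unlist(lapply(out, function(o) o$spec$type_code)),
    charge = unlist(lapply(out, function(o) o$spec$charge)),
    residue_index = unlist(lapply(out, function(o)
      rep(o$r$residue_index, nrow(o$spec)))),
    chain_id = unlist(lapply(out, function(o)
      rep(o$r$chain_id, nrow(o$spec)))),
    residue_name = unlist(lapply(out, function(o)
      rep(o$r$residue_name, nrow(o$spec)))),
    auth_seq = unlist(lapply(out, function(o)
      rep(o$r$auth_seq, nrow(o$spec))))
  )
}

# --- CG-PDB I/O ------------------------------------------------------------

ROLE_SEGID <- c(phosphate = "PHO", sugar = "SUG", backbone = "BBN",
                base = "BAS", mainchain = "MCH", sidechain = "SCH")

#' Write coarse-grained structures as pseudo-atom PDB
#'
#' One ATOM record per bead: bead name in the atom-name field, bead role
#' abbreviated in the segment-id field (columns 73-76), type code in the
#' B-factor field and charge in the occupancy field. A list of structures is
#' written as a multi-MODEL file (one model per conformer).
#'
#' @param x a \code{cg_structure} or a list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_cgpdb <- function(x, path) {
  if (inherits(x, "cg_structure")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x) > 1
  for (m in seq_along(x)) {
    s <- x[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    seg <- ROLE_SEGID[s$role]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
      seq_len(n_beads(s)), substr(s$bead_name, 1, 4),
      substr(s$residue_name, 1, 3), substr(s$chain_id, 1, 1),
      s$residue_index, s$pos[, 1], s$pos[, 2], s$pos[, 3],
      s$charge, s$type_code, seg)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read coarse-grained structures written by \code{\link{write_cgpdb}}
#'
#' @param path a CG-PDB file.
#' @return a list of \code{cg_structure} (one per model).
#' @export
read_cgpdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_id <- cumsum(trimws(rec) == "MODEL")
  if (max(model_id) == 0) model_id <- rep(1L, length(lines))
  keep <- rec == "ATOM  "
  seg2role <- stats::setNames(names(ROLE_SEGID), ROLE_SEGID)
  out <- lapply(split(lines[keep], model_id[keep]), function(ln) {
    cg_structure(
      pos = cbind(as.numeric(substr(ln, 31, 38)),
                  as.numeric(substr(ln, 39, 46)),
                  as.numeric(substr(ln, 47, 54))),
      bead_name = trimws(substr(ln, 13, 16)),
      role = unname(seg2role[trimws(substr(ln, 73, 76))]),
      type_code = as.integer(round(as.numeric(substr(ln, 61, 66)))),
      charge = as.numeric(substr(ln, 55, 60)),
      residue_index = as.integer(substr(ln, 23, 26)),
      chain_id = trimws(substr(ln, 22, 22)),
      residue_name = trimws(substr(ln, 18, 20))
    )
  })
  names(out) <- NULL
  out
}
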