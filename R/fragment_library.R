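#' Trinucleotide fragment
#'
#' A coarse-grained conformer of three consecutive nucleotides cut from a
#' protein-bound RNA chain, with provenance. Fragments whose three bases are
#' all pyrimidines belong to sequence class \code{"UUU"}, all purines to
#' \code{"AAA"}, anything else to \code{"other"}.
#'
#' @param conformer \code{cg_structure} restricted to exactly 3 consecutive
#'   nucleotides.
#' @param source_id complex identifier (e.g. PDB id).
#' @param chain_id source chain label.
#' @param start_residue 1-based ordinal of the first nucleotide.
#' @param native_sequence 3-letter string over A/C/G/U.
#' @param contacts_protein logical: any bead within the contact cutoff of a
#'   protein bead (NA when unknown).
#' @return object of class \code{trinucleotide_fragment}.
#' @export
trinucleotide_fragment <- function(conformer, source_id = "synthetic",
                                   chain_id = "R", start_residue = 1L,
                                   native_sequence = NULL,
                                   contacts_protein = NA) {
  stopifnot(inherits(conformer, "cg_structure"))
  nres <- nrow(conformer$residues)
  if (nres != 3L) stop("a trinucleotide fragment must have 3 residues, got ", nres)
  if (is.null(native_sequence)) {
    native_sequence <- paste(conformer$residues$residue_name, collapse = "")
  }
  structure(list(conformer = conformer,
                 source_id = source_id,
                 chain_id = chain_id,
                 start_residue = as.integer(start_residue),
                 native_sequence = native_sequence,
                 sequence_class = sequence_class_of(native_sequence),
                 contacts_protein = contacts_protein),
            class = "trinucleotide_fragment")
}

sequence_class_of <- function(seq3) {
  b <- strsplit(seq3, "")[[1]]
  if (length(b) != 3) return("other")
  if (all(b %in% c("C", "U"))) "UUU"
  else if (all(b %in% c("A", "G"))) "AAA"
  else "other"
}

#' Extract all trinucleotide fragments from protein-RNA complexes
#'
#' Every sliding window of 3 consecutive nucleotides of every RNA chain
#' yields one fragment; windows spanning a chain break (non-consecutive
#' author numbering) are excluded. Each fragment is tagged with whether any
#' of its beads lies within \code{contact_cutoff} of a protein bead.
#'
#' @param complexes list of lists with elements \code{protein} and
#'   \code{rna} (both \code{cg_structure}), optionally \code{id}.
#' @param contact_cutoff Angstrom; protein-contact tagging distance.
#' @return list of \code{trinucleotide_fragment}.
#' @export
extract_trinucleotides <- function(complexes, contact_cutoff = 5.0) {
  out <- list()
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    id <- if (!is.null(cx$id)) cx$id else paste0("complex", ci)
    rna <- cx$rna
    for (ch in unique(rna$residues$chain_id)) {
      res <- rna$residues[rna$residues$chain_id == ch, , drop = FALSE]
      res <- res[order(res$residue_index), , drop = FALSE]
      if (nrow(res) < 3) next
      for (w in seq_len(nrow(res) - 2L)) {
        win <- res[w:(w + 2L), ]
        if (any(diff(win$auth_seq) != 1L)) next  # chain break
        idx <- rna$chain_id == ch & rna$residue_index %in% win$residue_index
        conf <- cg_subset(rna, idx)
        touching <- NA
        if (!is.null(cx$protein) && n_beads(cx$protein) > 0) {
          d2 <- min_cross_dist2(conf$pos, cx$protein$pos)
          touching <- d2 <= contact_cutoff^2
        }
        out[[length(out) + 1L]] <- trinucleotide_fragment(
          conf, source_id = id, chain_id = ch,
          start_residue = win$residue_index[1],
          contacts_protein = touching)
      }
    }
  }
  out
}

min_cross_dist2 <- function(a, b) {
  # min squared distance between two point sets (small n; vectorized)
  m <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  max(min(m), 0)
}

#' Canonicalize a fragment to its homopolymer sequence class
#'
#' All-pyrimidine fragments are re-typed to UUU and all-purine fragments to
#' AAA; bead positions are never changed. With the default mapping, guanine
#' and adenine carry the same bead layout (the extra guanine substituents
#' are merged into shared-scaffold beads), so purine canonicalization is a
#' pure re-typing as well. Mixed-sequence fragments are returned unchanged
#' with class \code{"other"}.
#'
#' @param frag a \code{trinucleotide_fragment}.
#' @param mapping bead mapping (see \code{\link{read_mapping}}).
#' @return the canonicalized \code{trinucleotide_fragment}.
#' @export
canonicalize <- function(frag, mapping = read_mapping()) {
  cls <- frag$sequence_class
  if (cls == "other") return(frag)
  target <- if (cls == "UUU") "U" else "A"
  conf <- frag$conformer
  tspec <- mapping[mapping$residue_name == target, , drop = FALSE]
  for (ri in unique(conf$residue_index)) {
    sel <- which(conf$residue_index == ri)
    if (conf$residue_name[sel[1]] == target) next
    if (length(sel) != nrow(tspec)) {
      stop("cannot re-type residue ", conf$residue_name[sel[1]], " to ",
           target, ": bead count ", length(sel), " vs ", nrow(tspec))
    }
    conf$bead_name[sel] <- tspec$bead_name
    conf$role[sel] <- tspec$role
    conf$type_code[sel] <- tspec$type_code
    conf$charge[sel] <- tspec$charge
    conf$residue_name[sel] <- target
  }
  conf$residues$residue_name <- target
  frag$conformer <- conf
  frag
}

#' Fragment library
#'
#' Per-sequence-class sets of trinucleotide conformers; within a class no
#' two retained conformers are closer than \code{dedup_threshold} after
#' optimal superposition.
#'
#' @param classes named list: sequence class -> list of fragments.
#' @param dedup_threshold Angstrom.
#' @param provenance character log lines.
#' @return object of class \code{fragment_library}.
#' @export
fragment_library <- function(classes, dedup_threshold = 0.2,
                             provenance = character()) {
  structure(list(classes = classes, dedup_threshold = dedup_threshold,
                 provenance = provenance),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("fragment_library (dedup ", x$dedup_threshold, " A):\n", sep = "")
  for (cl in names(x$classes)) {
    cat("  ", cl, ": ", length(x$classes[[cl]]), " conformers\n", sep = "")
  }
  invisible(x)
}

#' Greedy redundancy removal for one sequence class
#'
#' Walks the fragments in input order and keeps a fragment iff its
#' optimally-superposed RMSD to every previously kept fragment exceeds
#' \code{threshold}. The retained set therefore depends on input order
#' (typically energy or provenance order); this is the conventional
#' leader-style dedup.
#'
#' @param frags list of \code{trinucleotide_fragment}, all of one class.
#' @param threshold Angstrom, > 0; use \code{Inf} to keep everything... a
#'   threshold of 0 or below is a parameter error.
#' @return a \code{fragment_library} holding the surviving fragments.
#' @export
deduplicate_library <- function(frags, threshold = 0.2) {
  if (threshold <= 0) stop("dedup threshold must be > 0")
  if (length(frags) == 0) {
    return(fragment_library(list(), threshold, "empty input"))
  }
  cls <- unique(vapply(frags, `[[`, "", "sequence_class"))
  if (length(cls) != 1) {
    stop("all fragments must share one sequence class, got: ",
         paste(cls, collapse = ", "))
  }
  kept <- list()
  for (f in frags) {
    dup <- FALSE
    for (k in kept) {
      if (superposed_rmsd(f$conformer, k$conformer) <= threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- f
  }
  lib <- list()
  lib[[cls]] <- kept
  fragment_library(lib, threshold,
                   sprintf("%d/%d fragments kept at %.3g A",
                           length(kept), length(frags), threshold))
}

#' Best-fitting library conformer for a target fragment
#'
#' @param library a \code{fragment_library}.
#' @param target a \code{trinucleotide_fragment}.
#' @return list with \code{conformer} (the fragment), \code{index} and
#'   \code{rmsd} (optimal-superposition RMSD, Angstrom). Ties are broken by
#'   the lowest conformer index.
#' @export
best_fit <- function(library, target) {
  cls <- target$sequence_class
  members <- library$classes[[cls]]
  if (is.null(members) || length(members) == 0) {
    stop("library has no conformers for class ", cls)
  }
  rmsds <- vapply(members, function(m)
    superposed_rmsd(m$conformer, target$conformer), numeric(1))
  i <- which.min(rmsds)  # which.min takes the first of ties
  list(conformer = members[[i]], index = i, rmsd = rmsds[i])
}

#' Write a fragment library to disk
#'
#' One multi-model CG-PDB per sequence class plus a tab-separated index
#' (conformer_id, source_id, chain, start_residue, native_sequence).
#'
#' @param library a \code{fragment_library}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(library$classes)) {
    frags <- library$classes[[cl]]
    write_cgpdb(lapply(frags, `[[`, "conformer"),
                file.path(dir, paste0(cl, ".cgpdb")))
    idx <- data.frame(
      conformer_id = seq_along(frags),
      source_id = vapply(frags, `[[`, "", "source_id"),
      chain = vapply(frags, `[[`, "", "chain_id"),
      start_residue = vapply(frags, `[[`, 0L, "start_residue"),
      native_sequence = vapply(frags, `[[`, "", "native_sequence"))
    utils::write.table(idx, file.path(dir, paste0(cl, ".index.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a fragment library written by \code{\link{write_library}}
#'
#' @param dir library directory.
#' @param dedup_threshold recorded threshold (metadata only).
#' @return a \code{fragment_library}.
#' @export
read_library <- function(dir, dedup_threshold = 0.2) {
  files <- list.files(dir, pattern = "\\.cgpdb$", full.names = TRUE)
  classes <- list()
  for (f in files) {
    cl <- sub("\\.cgpdb$", "", basename(f))
    confs <- read_cgpdb(f)
    idx_path <- file.path(dir, paste0(cl, ".index.tsv"))
    idx <- if (file.exists(idx_path)) {
      utils::read.delim(idx_path, stringsAsFactors = FALSE)
    } else NULL
    classes[[cl]] <- lapply(seq_along(confs), function(i) {
      trinucleotide_fragment(
        confs[[i]],
        source_id = if (is.null(idx)) "unknown" else idx$source_id[i],
        chain_id = if (is.null(idx)) "R" else as.character(idx$chain[i]),
        start_residue = if (is.null(idx)) 1L else idx$start_residue[i],
        native_sequence = if (is.null(idx)) NULL else idx$native_sequence[i])
    })
  }
  fragment_library(classes, dedup_threshold,
                   sprintf("read from %s", dir))
}

#' Flag nucleotides with an apparent Watson-Crick partner
#'
#' Heuristic helper for excluding base-paired (non-single-stranded) regions
#' when curating library inputs: two nucleotides are flagged as paired when
#' their base-bead centroids lie within \code{dist_cutoff} and they are at
#' least 3 residues apart in sequence (or on different chains).
#'
#' @param rna a \code{cg_structure} of RNA.
#' @param dist_cutoff Angstrom between base centroids (default 5.5).
#' @return logical vector over rows of \code{rna$residues}.
#' @export
flag_paired_nucleotides <- function(rna, dist_cutoff = 5.5) {
  res <- rna$residues
  cent <- t(vapply(seq_len(nrow(res)), function(i) {
    sel <- rna$chain_id == res$chain_id[i] &
      rna$residue_index == res$residue_index[i] & rna$role == "base"
    if (!any(sel)) return(c(NA_real_, NA_real_, NA_real_))
    colMeans(rna$pos[sel, , drop = FALSE])
  }, numeric(3)))
  n <- nrow(res)
  paired <- rep(FALSE, n)
  if (n < 2) return(paired)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (any(is.na(cent[i, ])) || any(is.na(cent[j, ]))) next
      far_in_seq <- res$chain_id[i] != res$chain_id[j] ||
        abs(res$residue_index[i] - res$residue_index[j]) >= 3
      if (far_in_seq && sqrt(sum((cent[i, ] - cent[j, ])^2)) <= dist_cutoff) {
        paired[i] <- paired[j] <- TRUE
      }
    }
  }
  paired
}
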