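# Ligand 3D preparation (protonation at physiological pH, distance-geometry
# embedding, MMFF94 minimization with azo-geometry verification) and receptor
# preparation (chain selection, het stripping, binding-site definition).
# 3D work is delegated to the OpenBabel command line tools.

.obabel <- function(args, input = NULL) {
  exe <- Sys.which("obabel")
  if (!nzchar(exe))
    stop("the obabel executable is required for 3D ligand preparation ",
         "but was not found on PATH")
  out <- tryCatch(
    suppressWarnings(system2(exe, args, input = input, stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  out
}

.obabel_smiles_to <- function(smiles, outfmt, extra = character(0)) {
  out <- .obabel(c(paste0("-:", shQuote(smiles)), paste0("-o", outfmt), extra))
  if (length(out) == 0) return(NULL)
  paste(out, collapse = "\n")
}

# MMFF94 single-point energy of an SDF (kcal/mol); NA on failure
.mmff94_energy <- function(sdf_text) {
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f))
  writeLines(sdf_text, f)
  exe <- Sys.which("obenergy")
  if (!nzchar(exe)) return(NA_real_)
  out <- tryCatch(suppressWarnings(
    system2(exe, c("-ff", "MMFF94", f), stdout = TRUE, stderr = TRUE)),
    error = function(e) character(0))
  ln <- grep("TOTAL ENERGY", out, value = TRUE)
  if (length(ln) == 0) return(NA_real_)
  as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1", ln[1]))
}

# parse heavy-atom coordinates + elements from a (single-molecule) SDF text
.sdf_coords <- function(sdf_text) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdf_text)))),
    error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) == 0) return(NULL)
  ab <- ChemmineR::atomblock(sdfset[[1]])
  elem <- sub("_.*$", "", rownames(ab))
  list(coords = unname(ab[, 1:3, drop = FALSE]), elem = elem)
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Azo dihedral angle of a 3D structure
#'
#' Returns the C-N=N-C dihedral (degrees) of the first azo motif of the
#' molecule whose SMILES is given, measured on the supplied coordinates
#' (heavy atoms in SMILES atom order).
#'
#' @param smiles the molecule's SMILES (atom order defines the mapping).
#' @param coords numeric matrix of heavy-atom coordinates in that order.
#' @return dihedral in degrees, or NA when no azo motif exists.
#' @export
azo_dihedral <- function(smiles, coords) {
  mol <- mol_from_smiles(smiles)
  if (is.null(mol)) return(NA_real_)
  az <- find_azo_motifs(mol)
  if (length(az) == 0) return(NA_real_)
  m <- az[[1]]
  .dihedral(coords[m["c1"], ], coords[m["n1"], ], coords[m["n2"], ], coords[m["c2"], ])
}

#' Prepare 3D ligand variants for docking
#'
#' For each isomer of a design, generates protonation-state variants at the
#' given pH (via OpenBabel's pH model), embeds each variant in 3D and
#' minimizes it in the MMFF94 force field. The azo E/Z geometry is verified
#' after minimization (C-N=N-C dihedral within \code{tol_deg} of 180/0
#' degrees); when minimization breaks the geometry, the embedded
#' pre-minimization structure is kept instead.
#'
#' @param design one row of a \code{psw_designs} data.frame, or a named
#'   character vector / list of SMILES (names become isomer labels).
#' @param pH protonation pH (default 7.4).
#' @param max_variants cap on protonation/tautomer variants per isomer.
#' @param tol_deg allowed azo-dihedral deviation in degrees.
#' @param minimize_steps MMFF94 steepest-descent steps.
#' @return list of class \code{prepared_ligands}; each element has
#'   \code{variant_id}, \code{isomer}, \code{label}, \code{smiles},
#'   \code{formal_charge}, \code{coords}, \code{elem}, \code{energy},
#'   \code{energy_start}, \code{sdf}.
#' @export
prepare_ligand_variants <- function(design, pH = 7.4, max_variants = 4,
                                    tol_deg = 30, minimize_steps = 500) {
  if (is.data.frame(design)) {
    smis <- c(trans = design$trans_smiles[1], cis = design$cis_smiles[1])
    fam <- design$family_id[1]
  } else {
    smis <- unlist(design)
    if (is.null(names(smis))) names(smis) <- paste0("iso", seq_along(smis))
    fam <- "ligand"
  }
  out <- list()
  for (iso in names(smis)) {
    smi <- smis[[iso]]
    # protonation-state variants at the requested pH, plus the input state
    prot <- .obabel_smiles_to(smi, "smi", c("-p", format(pH)))
    prot <- if (is.null(prot)) smi else strsplit(trimws(prot), "[ \t]")[[1]][1]
    variants <- unique(c(stats::setNames(prot, sprintf("pH%.1f", pH)),
                         stats::setNames(smi, "neutral")))
    names(variants) <- c(sprintf("pH%.1f", pH), "neutral")[seq_along(variants)]
    variants <- variants[seq_len(min(length(variants), max_variants))]
    for (lab in names(variants)) {
      vsmi <- variants[[lab]]
      emb <- .obabel_smiles_to(vsmi, "sdf", "--gen3d")
      if (is.null(emb) || !grepl("V2000", emb)) {
        warning("3D embedding failed for ", vsmi, "; variant skipped")
        next
      }
      e0 <- .mmff94_energy(emb)
      f_in <- tempfile(fileext = ".sdf"); f_out <- tempfile(fileext = ".sdf")
      writeLines(emb, f_in)
      .obabel(c(f_in, "-osdf", "-O", f_out, "--minimize", "--ff", "MMFF94",
                "--steps", format(minimize_steps)))
      minsdf <- if (file.exists(f_out) && file.size(f_out) > 0)
        paste(readLines(f_out), collapse = "\n") else emb
      unlink(c(f_in, f_out))
      e1 <- .mmff94_energy(minsdf)
      use <- minsdf; energy <- e1
      geom <- .sdf_coords(use)
      if (is.null(geom)) next
      dih <- azo_dihedral(vsmi, geom$coords)
      if (!is.na(dih)) {
        target <- if (iso == "cis") 0 else 180
        dev <- abs(abs(dih) - target)
        if (min(dev, 360 - dev) > tol_deg) {
          # minimization flipped the azo geometry: keep the embedded structure
          use <- emb; energy <- e0
          geom <- .sdf_coords(use)
          dih <- azo_dihedral(vsmi, geom$coords)
        }
      }
      mol <- mol_from_smiles(vsmi)
      out[[length(out) + 1]] <- list(
        variant_id = paste(fam, iso, lab, sep = "_"),
        family_id = fam, isomer = iso, label = lab, smiles = vsmi,
        formal_charge = if (is.null(mol)) NA_integer_ else sum(mol$atoms$charge),
        coords = geom$coords, elem = geom$elem,
        energy = energy, energy_start = e0, azo_dihedral = dih, sdf = use)
    }
    if (!any(vapply(out, function(v) v$isomer == iso, TRUE)))
      warning("all variants failed 3D preparation for isomer ", iso,
              " of ", fam)
  }
  structure(out, class = "prepared_ligands")
}

#' Write prepared ligand variants to SDF or MOL2
#'
#' @param prepared a \code{prepared_ligands} list.
#' @param path output file (.sdf or .mol2 inferred from extension).
#' @return the path, invisibly.
#' @export
write_prepared_ligands <- function(prepared, path) {
  fmt <- tolower(tools::file_ext(path))
  sdf_all <- paste(vapply(prepared, function(v) {
    txt <- sub("^[^\n]*", v$variant_id, v$sdf)  # title line = variant id
    if (!grepl("\\$\\$\\$\\$\\s*$", txt)) txt <- paste0(txt, "\n$$$$")
    txt
  }, ""), collapse = "\n")
  if (fmt == "mol2") {
    f <- tempfile(fileext = ".sdf")
    writeLines(sdf_all, f)
    .obabel(c(f, "-omol2", "-O", path))
    unlink(f)
  } else {
    writeLines(sdf_all, path)
  }
  invisible(path)
}

# ---- receptor handling ------------------------------------------------------

#' Load a structure from a local PDB file
#'
#' @param path PDB file path.
#' @return object of class \code{psw_structure} holding the parsed model
#'   (bio3d pdb), source path, title and resolution (NA when unrecorded).
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e)
                    stop("cannot parse PDB file ", path, ": ", conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("cannot parse PDB file ", path, ": no ATOM/HETATM records found")
  lines <- readLines(path, warn = FALSE)
  title <- paste(trimws(sub("^TITLE\\s{0,5}[0-9]?", "", grep("^TITLE", lines, value = TRUE))),
                 collapse = " ")
  resol <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl) > 0) {
    num <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.?\\s*([0-9.]+).*", "\\1", rl[1])))
    if (!is.na(num)) resol <- num
  }
  structure(list(pdb = pdb, path = path, title = title, resolution = resol),
            class = "psw_structure")
}

#' Fetch a structure from the PDB by id
#'
#' Downloads the entry via bio3d and loads it. Requires network access; the
#' test suite only ever uses \code{\link{load_structure}} on local files.
#'
#' @param pdb_id 4-character PDB id.
#' @param path download directory.
#' @return a \code{psw_structure}.
#' @export
fetch_structure <- function(pdb_id, path = tempdir()) {
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", pdb_id))
    stop("malformed PDB id: ", pdb_id)
  f <- tryCatch(bio3d::get.pdb(pdb_id, path = path),
                error = function(e)
                  stop("could not retrieve PDB entry ", pdb_id, ": ",
                       conditionMessage(e)))
  load_structure(f)
}

#' @export
print.psw_structure <- function(x, ...) {
  cat("<psw_structure>", x$path, "\n  chains:",
      paste(unique(x$pdb$atom$chain), collapse = ", "),
      "\n  resolution:", ifelse(is.na(x$resolution), "(unrecorded)", x$resolution), "\n")
  invisible(x)
}

#' Prepare a receptor chain for docking
#'
#' Keeps a single protein chain, removes waters, ions and other heteroatom
#' groups except those listed in \code{keep_het_ids}, drops alternate
#' locations, and flags residues with missing backbone atoms. The operation
#' is deterministic and idempotent.
#'
#' @param structure a \code{psw_structure} (or a \code{psw_receptor}, which
#'   is passed through the same normalization).
#' @param chain chain identifier to keep.
#' @param keep_het_ids heteroatom residue names to retain (e.g. the bound
#'   reference ligand).
#' @return object of class \code{psw_receptor} with \code{atom}
#'   (data.frame), \code{het} (retained het atoms), \code{chain},
#'   \code{flagged_residues}.
#' @export
prepare_receptor <- function(structure, chain, keep_het_ids = character(0)) {
  atom <- if (inherits(structure, "psw_receptor"))
    rbind(structure$atom, structure$het) else structure$pdb$atom
  chains <- sort(unique(atom$chain))
  if (!chain %in% chains)
    stop("chain ", chain, " not present; available chains: ",
         paste(chains, collapse = ", "))
  atom <- atom[atom$chain == chain, , drop = FALSE]
  if ("alt" %in% names(atom))
    atom <- atom[is.na(atom$alt) | atom$alt %in% c("", "A"), , drop = FALSE]
  is_het <- atom$type == "HETATM"
  het <- atom[is_het & atom$resid %in% keep_het_ids, , drop = FALSE]
  prot <- atom[!is_het, , drop = FALSE]
  flagged <- character(0)
  for (rn in unique(prot$resno)) {
    names_r <- prot$elety[prot$resno == rn]
    if (!all(c("N", "CA", "C") %in% names_r))
      flagged <- c(flagged, paste0(chain, rn))
  }
  structure(list(atom = prot, het = het, chain = chain,
                 flagged_residues = flagged,
                 source = if (!is.null(structure$path)) structure$path else NA),
            class = "psw_receptor")
}

#' @export
print.psw_receptor <- function(x, ...) {
  cat("<psw_receptor> chain", x$chain, "-", nrow(x$atom), "protein atoms,",
      nrow(x$het), "retained het atoms\n")
  if (length(x$flagged_residues))
    cat("  residues with incomplete backbone:",
        paste(x$flagged_residues, collapse = ", "), "\n")
  invisible(x)
}

receptor_coords <- function(receptor) {
  at <- receptor$atom[receptor$atom$elesy != "H" | is.na(receptor$atom$elesy), ,
                      drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Define a spherical binding site from a bound reference ligand
#'
#' Center is the heavy-atom centroid of the reference ligand; the radius is
#' the maximum heavy-atom distance from that centroid plus
#' \code{extra_radius} (default 2.0 Angstrom), so every reference heavy atom
#' lies inside the sphere.
#'
#' @param receptor a \code{psw_receptor} whose \code{het} table holds the
#'   reference ligand, or NULL when \code{reference_ligand} is a coordinate
#'   matrix.
#' @param reference_ligand residue name (resid) of the bound ligand in the
#'   receptor's het table, or a numeric coordinate matrix of its heavy atoms.
#' @param extra_radius additional radius in Angstrom.
#' @return object of class \code{binding_site} with \code{center},
#'   \code{radius}, \code{reference_ligand_id}.
#' @export
define_binding_site <- function(receptor = NULL, reference_ligand,
                                extra_radius = 2.0) {
  if (is.matrix(reference_ligand)) {
    xyz <- reference_ligand
    ref_id <- "coords"
  } else {
    stopifnot(inherits(receptor, "psw_receptor"))
    sel <- receptor$het[receptor$het$resid == reference_ligand, , drop = FALSE]
    if (nrow(sel) == 0)
      stop("reference ligand ", reference_ligand, " not found in receptor het atoms")
    sel <- sel[sel$elesy != "H" | is.na(sel$elesy), , drop = FALSE]
    xyz <- as.matrix(sel[, c("x", "y", "z")])
    ref_id <- reference_ligand
  }
  if (nrow(xyz) == 0) stop("reference ligand has no heavy atoms")
  center <- colMeans(xyz)
  dmax <- max(sqrt(rowSums(sweep(xyz, 2, center)^2)))
  structure(list(center = as.numeric(center), radius = dmax + extra_radius,
                 reference_ligand_id = ref_id),
            class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("<binding_site> center (%.2f, %.2f, %.2f), radius %.2f A (ref: %s)\n",
              x$center[1], x$center[2], x$center[3], x$radius,
              x$reference_ligand_id))
  invisible(x)
}

#' Write a binding site as a key-value text block
#' @param site a \code{binding_site}.
#' @param path output path.
#' @export
write_binding_site <- function(site, path) {
  writeLines(c(sprintf("center %.4f %.4f %.4f", site$center[1], site$center[2],
                       site$center[3]),
               sprintf("radius %.4f", site$radius),
               sprintf("reference %s", site$reference_ligand_id)), path)
  invisible(path)
}
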